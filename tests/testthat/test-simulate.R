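test_that("simulation is deterministic under a fixed seed", {
  cfg <- small_config(seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$apa, b$apa)
  expect_identical(a$expression, b$expression)
  expect_identical(a$gene_sets, b$gene_sets)
  expect_identical(a$parents, b$parents)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(small_config(seed = 12))
  expect_false(identical(a$apa, c$apa))
})

test_that("cohort axes are consistent and annotation covers every cell once", {
  co <- simulate_cohort(small_config(seed = 3))
  expect_identical(co$apa$gene, co$expression$gene)
  expect_identical(names(co$apa)[-1], names(co$expression)[-1])
  expect_setequal(co$annotation$cell, names(co$apa)[-1])
  expect_false(anyDuplicated(co$annotation$cell) > 0)
  # every planted gene occurs in >= 1 planted set
  for (ty in names(co$truth)) {
    members <- unlist(co$gene_sets$genes[co$gene_sets$set %in% co$truth[[ty]]$sets])
    expect_true(all(co$truth[[ty]]$genes %in% members))
  }
})

test_that("APA dropout matches the configured rate within binomial bounds", {
  cfg <- sim_config(n_cell_types = 5, cells_per_type = 20, n_genes = 100,
                    n_gene_sets = 10, genes_per_set = c(3, 6),
                    planted_sets_per_type = 1, dropout_rate_apa = 0.3,
                    seed = 5)
  co <- simulate_cohort(cfg)
  m <- as.matrix(co$apa[-1])
  n <- length(m)
  expect_identical(dim(m), c(100L, 100L))
  lim <- qbinom(c(0.0005, 0.9995), n, 0.3)
  expect_gte(sum(is.na(m)), lim[1])
  expect_lte(sum(is.na(m)), lim[2])
})

test_that("null configuration leaves planted genes at the background mean", {
  cfg <- small_config(shortening_effect = 0, expression_effect = 0, seed = 8,
                      dropout_rate_apa = 0)
  co <- simulate_cohort(cfg)
  m <- as.matrix(co$apa[-1])
  rownames(m) <- co$apa$gene
  planted <- unique(unlist(lapply(co$truth, `[[`, "genes")))
  x <- m[planted, ]
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - mean(m[setdiff(rownames(m), planted), ])), 3 * se)
})

test_that("the two APA dialects obey their ranges and share the latent signal", {
  base <- list(n_cell_types = 3, cells_per_type = 15, n_genes = 300,
               n_gene_sets = 40, genes_per_set = c(8, 15),
               planted_sets_per_type = 2, seed = 21)
  dap <- simulate_cohort(do.call(sim_config, c(base, apa_dialect = "dapars")))
  roa <- simulate_cohort(do.call(sim_config, c(base, apa_dialect = "roar")))
  md <- as.matrix(dap$apa[-1]); mr <- as.matrix(roa$apa[-1])
  expect_true(all(md >= -1 & md <= 1, na.rm = TRUE))
  expect_true(all(mr > 0, na.rm = TRUE))
  # identical latent shortening: -delta-PDUI == log2(roar)
  expect_equal(-md, log2(mr), tolerance = 1e-12)
  # planted genes shift negative in delta-PDUI, > 1 in roar
  g1 <- dap$truth[[1]]$genes
  cells1 <- dap$annotation$cell[dap$annotation$cell_type == names(dap$truth)[1]]
  rownames(md) <- dap$apa$gene
  expect_lt(mean(md[g1, cells1], na.rm = TRUE), -0.3)
})

test_that("config validation rejects infeasible designs", {
  expect_error(sim_config(planted_sets_per_type = 10, n_cell_types = 5,
                          n_gene_sets = 20), "planted")
  expect_error(sim_config(dropout_rate_apa = 1.2), "dropout_rate_apa")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(genes_per_set = c(10, 5)), "genes_per_set")
})

test_that("the toy GO hierarchy gives every term parents and themed planted sets", {
  cfg <- small_config(seed = 13)
  go <- simulate_go_hierarchy(cfg)
  expect_setequal(unique(go$parents$term), go$gene_sets$set)
  n_parents <- table(go$parents$term)
  expect_true(all(n_parents >= 1 & n_parents <= 3))
  # planted sets of one type share their parent pool exactly
  for (ty in names(go$planted_sets)) {
    sets <- go$planted_sets[[ty]]
    pp <- lapply(sets, function(s) sort(go$parents$parent[go$parents$term == s]))
    expect_true(all(vapply(pp, identical, logical(1), pp[[1]])))
    expect_equal(parent_jaccard(sets[1], sets[2], go$parents), 1)
  }
  expect_identical(go, simulate_go_hierarchy(cfg))
})

test_that("survival simulation respects hazards, censoring and determinism", {
  cfg <- survival_sim_config(n_patients = 100, seed = 4)
  grp <- rep(c(0, 1), 50)
  a <- simulate_survival(cfg, grp)
  expect_identical(a, simulate_survival(cfg, grp))
  expect_true(all(a$time <= cfg$max_followup))
  expect_true(all(a$event %in% 0:1))
  # heavy censoring: censor rate 100x baseline leaves < 5% events
  heavy <- survival_sim_config(n_patients = 400, baseline_hazard = 0.1,
                               censor_rate = 10, seed = 9)
  b <- simulate_survival(heavy, rep(0, 400))
  expect_lt(mean(b$event), 0.05)
  expect_error(survival_sim_config(baseline_hazard = 0), "rates")
  expect_error(simulate_survival(cfg, rep(0, 3)), "length")
})

test_that("write_cohort emits round-trippable pipeline inputs", {
  co <- simulate_cohort(small_config(seed = 2, apa_dialect = "roar"))
  dir <- withr::local_tempdir()
  sv <- simulate_survival(survival_sim_config(n_patients = 20, seed = 2),
                          rep(c(0, 1), 10))
  write_cohort(co, dir, survival = sv)
  apa2 <- read_apa_matrix(file.path(dir, "apa.tsv"), dialect = "roar")
  expect_equal(as.data.frame(apa2), as.data.frame(co$apa))
  expr2 <- read_expression_matrix(file.path(dir, "expression.tsv"))
  expect_equal(as.data.frame(expr2), as.data.frame(co$expression),
               tolerance = 1e-9)
  gmt2 <- read_gmt(file.path(dir, "gene_sets.gmt"))
  expect_identical(gmt2$set, co$gene_sets$set)
  expect_identical(gmt2$genes, co$gene_sets$genes)
  par2 <- read_parent_table(file.path(dir, "parents.tsv"))
  expect_setequal(paste(par2$term, par2$parent),
                  paste(co$parents$term, co$parents$parent))
  ann2 <- read_cell_annotation(file.path(dir, "annotation.tsv"))
  expect_identical(ann2$cell, co$annotation$cell)
  sv2 <- read_survival_table(file.path(dir, "survival.tsv"))
  expect_equal(sv2$time, sv$time, tolerance = 1e-9)
})
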