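#' Configuration for a synthetic single-cell APA cohort
#'
#' Bundles and validates the generator parameters. The defaults describe
#' the reference simulation used throughout the package's tests: 5 cell
#' types of 40 cells drawn from 11 patients, 2,000 genes, 300 GO-like
#' gene sets of 15-40 genes, 3 planted signature sets per cell type, and
#' planted effects equal to three times the per-entry noise s.d.
#'
#' @param n_cell_types Number of cell types.
#' @param cells_per_type Cells per cell type.
#' @param n_patients Patients cells are assigned to (round-robin).
#' @param n_genes Number of genes.
#' @param n_gene_sets Number of gene sets.
#' @param genes_per_set Length-2 range (min, max) of set sizes.
#' @param planted_sets_per_type Signature gene sets planted per cell type.
#' @param shortening_effect Shift, in shortening-score units, applied to
#'   planted genes in cells of the matching type.
#' @param expression_effect Shift in log2-expression units, same cells.
#' @param dropout_rate_apa Fraction of APA entries set missing.
#' @param noise_sd S.d. of the per-entry Gaussian noise (both channels).
#' @param apa_dialect `"dapars"` (delta-PDUI in \[-1, 1\], shortening
#'   negative) or `"roar"` (positive ratios, shortening > 1).
#' @param seed Integer seed; the same config is bit-reproducible.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cell_types = 5, cells_per_type = 40, n_patients = 11,
                       n_genes = 2000, n_gene_sets = 300,
                       genes_per_set = c(15, 40), planted_sets_per_type = 3,
                       shortening_effect = 0.6, expression_effect = 0.6,
                       dropout_rate_apa = 0.3, noise_sd = 0.2,
                       apa_dialect = c("dapars", "roar"), seed = 1L) {
  cfg <- list(
    n_cell_types = check_count(n_cell_types, "n_cell_types"),
    cells_per_type = check_count(cells_per_type, "cells_per_type"),
    n_patients = check_count(n_patients, "n_patients"),
    n_genes = check_count(n_genes, "n_genes"),
    n_gene_sets = check_count(n_gene_sets, "n_gene_sets"),
    genes_per_set = genes_per_set,
    planted_sets_per_type = check_count(planted_sets_per_type,
                                        "planted_sets_per_type", min = 0),
    shortening_effect = shortening_effect,
    expression_effect = expression_effect,
    dropout_rate_apa = check_fraction(dropout_rate_apa, "dropout_rate_apa"),
    noise_sd = noise_sd,
    apa_dialect = match.arg(apa_dialect),
    seed = check_count(seed, "seed", min = 0)
  )
  if (length(genes_per_set) != 2 || any(genes_per_set < 1) ||
      genes_per_set[1] > genes_per_set[2]) {
    abort("genes_per_set must be an increasing (min, max) pair >= 1")
  }
  if (!all(is.finite(c(shortening_effect, expression_effect, noise_sd))) ||
      noise_sd <= 0) {
    abort("effects must be finite and noise_sd > 0")
  }
  if (cfg$planted_sets_per_type * cfg$n_cell_types > cfg$n_gene_sets) {
    abort("more planted sets than gene sets: reduce planted_sets_per_type")
  }
  if (cfg$planted_sets_per_type * cfg$n_cell_types * genes_per_set[2] >
      cfg$n_genes) {
    abort("planted sets cannot be filled with disjoint genes; increase n_genes")
  }
  structure(cfg, class = "sim_config")
}

cell_type_names <- function(n) {
  base <- c("tumor", "B", "T", "myeloid", "stromal")
  if (n <= length(base)) base[seq_len(n)] else c(base, paste0("type", seq_len(n - length(base))))
}

#' Simulate a toy GO hierarchy with themed parents
#'
#' Generates the cohort's gene sets and a term-to-parent table. Each term
#' receives 1-3 parents from a small pool. Sets planted for the same cell
#' type share that type's dedicated parent pair exactly, and a fraction
#' of background sets adopt one of a few shared background "themes", so
#' parent-Jaccard clusters larger than 9 members can form. Planted sets
#' occupy the first `planted_sets_per_type * n_cell_types` set ids and
#' draw disjoint gene blocks; background sets sample from the remaining
#' genes, keeping the planted/background ground truth unambiguous.
#'
#' @param config A [sim_config()].
#' @return A list with elements `gene_sets` (tibble `set`, `description`,
#'   `genes`), `parents` (tibble `term`, `parent`) and `planted_sets`
#'   (named list: cell type -> planted set ids).
#' @export
simulate_go_hierarchy <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n_sets <- config$n_gene_sets
  n_planted <- config$planted_sets_per_type * config$n_cell_types
  set_ids <- sprintf("GS%04d", seq_len(n_sets))
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  types <- cell_type_names(config$n_cell_types)

  sizes <- sample(config$genes_per_set[1]:config$genes_per_set[2],
                  n_sets, replace = TRUE)
  # planted sets: disjoint blocks from a shuffled reserved pool
  pool <- sample(genes)
  members <- vector("list", n_sets)
  offset <- 0
  for (i in seq_len(n_planted)) {
    members[[i]] <- sort(pool[(offset + 1):(offset + sizes[i])])
    offset <- offset + sizes[i]
  }
  background_genes <- sort(pool[-seq_len(offset)])
  for (i in seq_len(n_sets)) {
    if (i > n_planted) members[[i]] <- sort(sample(background_genes, sizes[i]))
  }

  planted_sets <- if (n_planted > 0) {
    split(set_ids[seq_len(n_planted)],
          rep(types, each = config$planted_sets_per_type))[types]
  } else {
    stats::setNames(rep(list(character()), length(types)), types)
  }

  # parents: one theme pair per cell type, a few background themes,
  # unthemed sets draw 1-3 parents from a generic pool
  n_bg_themes <- 6L
  type_parents <- lapply(seq_along(types), function(i) {
    sprintf("P_%s_%d", types[i], 1:2)
  })
  bg_themes <- lapply(seq_len(n_bg_themes), function(i) {
    sprintf("P_theme%02d_%d", i, 1:2)
  })
  generic_pool <- sprintf("P_gen%02d", 1:20)
  parent_of <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    if (i <= n_planted) {
      parent_of[[i]] <- type_parents[[ceiling(i / config$planted_sets_per_type)]]
    } else if (stats::runif(1) < 0.4) {
      parent_of[[i]] <- bg_themes[[sample.int(n_bg_themes, 1)]]
    } else {
      parent_of[[i]] <- sample(generic_pool, sample(1:3, 1))
    }
  }
  parents <- tibble(
    term = rep(set_ids, lengths(parent_of)),
    parent = unlist(parent_of)
  )
  gene_sets <- tibble(
    set = set_ids,
    description = ifelse(seq_len(n_sets) <= n_planted,
                         paste0("planted:", rep(types, each = config$planted_sets_per_type,
                                                length.out = n_planted)),
                         "background"),
    genes = members
  )
  list(gene_sets = gene_sets, parents = parents, planted_sets = planted_sets)
}

#' Simulate a single-cell cohort with planted APA signatures
#'
#' Draws a cohort with the statistical structure the pipeline assumes.
#' One latent per-(gene, cell) shortening variable `s` serves both APA
#' dialects: background `s` is Gaussian noise around 0 clamped to
#' \[-1, 1\]; the dapars matrix stores `-s` (delta-PDUI, shortening
#' negative) and the roar matrix stores `2^s` (shortening > 1). Log2
#' expression is a per-gene baseline plus Gaussian noise; TPM is obtained
#' by exponentiating and rescaling each cell to a million.
#'
#' In cells of cell type `t`, genes belonging to `t`'s planted sets are
#' shifted by `+shortening_effect` in `s` and `+expression_effect` in
#' log2 expression, both scaled by a shared per-cell activity factor
#' (mean 1). The shared factor is what couples shortening with
#' over-expression within the type, giving planted components a positive
#' within-type correlation on top of the location shift. APA entries are
#' then set missing independently at `dropout_rate_apa`.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort`: `apa` (wide tibble, dialect
#'   attribute set), `expression` (wide TPM tibble), `annotation`,
#'   `gene_sets`, `parents`, and `truth` (per cell type, the planted set
#'   ids and planted gene ids).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  go <- simulate_go_hierarchy(config)
  types <- cell_type_names(config$n_cell_types)
  n_cells <- config$n_cell_types * config$cells_per_type
  cells <- sprintf("cell_%04d", seq_len(n_cells))
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  type_of <- rep(types, each = config$cells_per_type)
  annotation <- tibble(
    cell = cells,
    patient = sprintf("patient_%02d",
                      rep_len(seq_len(config$n_patients), n_cells)),
    cell_type = type_of,
    tumor_type = "BC"
  )

  truth <- lapply(types, function(ty) {
    sets <- go$planted_sets[[ty]]
    gmem <- go$gene_sets$genes[go$gene_sets$set %in% sets]
    list(sets = sets, genes = sort(unique(unlist(gmem))))
  })
  names(truth) <- types

  # per-cell activity factor shared by both channels (the planted coupling)
  set.seed(config$seed + 2L)
  activity <- pmin(pmax(stats::rnorm(n_cells, 1, 0.3), 0.25), 1.75)

  plant <- matrix(0, config$n_genes, n_cells, dimnames = list(genes, cells))
  for (ty in types) {
    g_idx <- match(truth[[ty]]$genes, genes)
    c_idx <- which(type_of == ty)
    if (length(g_idx)) {
      plant[g_idx, c_idx] <- rep(activity[c_idx], each = length(g_idx))
    }
  }

  # latent shortening
  set.seed(config$seed + 3L)
  s <- matrix(stats::rnorm(config$n_genes * n_cells, 0, config$noise_sd),
              config$n_genes, n_cells, dimnames = list(genes, cells))
  s <- s + plant * config$shortening_effect
  s <- pmin(pmax(s, -1), 1)
  set.seed(config$seed + 4L)
  drop_mask <- matrix(stats::runif(length(s)) < config$dropout_rate_apa,
                      nrow = nrow(s))
  apa_vals <- if (config$apa_dialect == "dapars") -s else 2^s
  apa_vals[drop_mask] <- NA_real_

  # expression
  set.seed(config$seed + 5L)
  baseline <- stats::runif(config$n_genes, 1, 8)
  log_expr <- baseline +
    matrix(stats::rnorm(config$n_genes * n_cells, 0, config$noise_sd),
           config$n_genes, n_cells) +
    plant * config$expression_effect
  tpm <- 2^log_expr
  tpm <- sweep(tpm, 2, colSums(tpm), "/") * 1e6
  dimnames(tpm) <- list(genes, cells)

  apa <- score_tbl(apa_vals)
  attr(apa, "dialect") <- config$apa_dialect
  structure(list(
    apa = apa,
    expression = score_tbl(tpm),
    annotation = annotation,
    gene_sets = go$gene_sets,
    parents = go$parents,
    truth = truth,
    config = config
  ), class = "sim_cohort")
}

#' Simulate a multi-tumor-type cohort of tumor cells
#'
#' Companion generator for the tumor-type contrast: every cell is a tumor
#' cell from one of `n_tumor_types` cancer types, and each type has
#' `planted_sets_per_type` gene sets whose member genes are shifted toward
#' shortening in that type's cells only. Uses the same latent-shortening
#' construction as [simulate_cohort()].
#'
#' @param config A [sim_config()]; `n_cell_types` is reinterpreted as the
#'   number of tumor types.
#' @return A `sim_cohort`-like list with `apa`, `annotation` (all
#'   `cell_type == "tumor"`, `tumor_type` in `TT1..TTn`), `gene_sets`,
#'   `parents` and `truth` (per tumor type).
#' @export
simulate_tumor_cohort <- function(config) {
  base <- simulate_cohort(config)
  tumor_types <- sprintf("TT%d", seq_len(config$n_cell_types))
  lookup <- stats::setNames(tumor_types, cell_type_names(config$n_cell_types))
  base$annotation$tumor_type <- unname(lookup[base$annotation$cell_type])
  base$annotation$cell_type <- "tumor"
  names(base$truth) <- unname(lookup[names(base$truth)])
  base
}

#' Configuration for simulated survival cohorts
#'
#' @param n_patients Number of patients.
#' @param baseline_hazard Event rate per year in the reference group.
#' @param log_hazard_ratio Log hazard ratio per unit of the group
#'   indicator.
#' @param censor_rate Rate of the independent exponential censoring.
#' @param max_followup Administrative censoring horizon, years.
#' @param seed Integer seed.
#' @return A validated list of class `survival_sim_config`.
#' @export
survival_sim_config <- function(n_patients = 200, baseline_hazard = 0.1,
                                log_hazard_ratio = 0, censor_rate = 0.02,
                                max_followup = 10, seed = 1L) {
  if (baseline_hazard <= 0 || censor_rate <= 0 || max_followup <= 0) {
    abort("rates and max_followup must be > 0")
  }
  if (!is.finite(log_hazard_ratio)) abort("log_hazard_ratio must be finite")
  structure(list(
    n_patients = check_count(n_patients, "n_patients"),
    baseline_hazard = baseline_hazard,
    log_hazard_ratio = log_hazard_ratio,
    censor_rate = censor_rate,
    max_followup = max_followup,
    seed = check_count(seed, "seed", min = 0)
  ), class = "survival_sim_config")
}

#' Simulate a two-group survival table
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(log_hazard_ratio * group)`; censoring combines
#' an independent exponential at `censor_rate` with administrative
#' censoring at `max_followup`.
#'
#' @param config A [survival_sim_config()].
#' @param group Binary (0/1) vector of length `n_patients`.
#' @return A tibble with columns `patient`, `time`, `event`, `group` and
#'   covariate `age`.
#' @export
simulate_survival <- function(config, group) {
  stopifnot(inherits(config, "survival_sim_config"))
  group <- as.integer(group)
  if (length(group) != config$n_patients || !all(group %in% c(0L, 1L))) {
    abort("group must be a 0/1 vector of length n_patients")
  }
  set.seed(config$seed + 6L)
  hazard <- config$baseline_hazard * exp(config$log_hazard_ratio * group)
  t_event <- stats::rexp(config$n_patients, rate = hazard)
  t_censor <- pmin(stats::rexp(config$n_patients, rate = config$censor_rate),
                   config$max_followup)
  tibble(
    patient = sprintf("patient_%04d", seq_len(config$n_patients)),
    time = pmin(t_event, t_censor),
    event = as.integer(t_event <= t_censor),
    group = group,
    age = round(stats::rnorm(config$n_patients, 60, 10), 1)
  )
}

#' Write a simulated cohort's input files to a directory
#'
#' Emits the pipeline's external files: APA and TPM matrices (TSV),
#' annotation (TSV), gene sets (GMT), parent table (TSV) and the planted
#' truth (JSON), so a run can start from disk exactly as it would with
#' real caller output.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory, created if needed.
#' @param survival Optional [simulate_survival()] table, written as
#'   `survival.tsv`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, survival = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(cohort$apa, file.path(dir, "apa.tsv"))
  write_matrix_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(cohort$annotation, file.path(dir, "annotation.tsv"))
  write_gmt(cohort$gene_sets, file.path(dir, "gene_sets.gmt"))
  readr::write_tsv(cohort$parents, file.path(dir, "parents.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"))
  if (!is.null(survival)) {
    readr::write_tsv(survival, file.path(dir, "survival.tsv"))
  }
  invisible(dir)
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "<sim_cohort> %d genes x %d cells, %d cell type(s), %d gene set(s), dialect '%s'\n",
    nrow(x$apa), ncol(x$apa) - 1, length(unique(x$annotation$cell_type)),
    nrow(x$gene_sets), x$config$apa_dialect))
  invisible(x)
}
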