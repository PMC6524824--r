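wide1 <- function(values, cells, id = "X") {
  dplyr::bind_cols(tibble::tibble(component = id),
                   tibble::as_tibble(as.data.frame(
                     matrix(values, 1, dimnames = list(NULL, cells)))))
}

test_that("median-split flags follow the strict above-both rule", {
  cells <- paste0("c", 1:4)
  # anti-correlated: no cell exceeds both medians
  f <- shortening_overexpression_flags(wide1(1:4, cells), wide1(4:1, cells), "X")
  expect_identical(f$flag, rep(FALSE, 4))
  # identical ranks: the top half is flagged
  f2 <- shortening_overexpression_flags(wide1(1:4, cells), wide1(1:4, cells), "X")
  expect_identical(f2$flag, c(FALSE, FALSE, TRUE, TRUE))
  # constant component: nothing exceeds its own median
  f3 <- shortening_overexpression_flags(wide1(rep(2, 4), cells),
                                        wide1(1:4, cells), "X")
  expect_identical(f3$flag, rep(FALSE, 4))
  expect_error(
    shortening_overexpression_flags(wide1(1:3, paste0("c", 1:3)),
                                    wide1(1:3, paste0("c", 1:3)), "X"),
    "fewer than 4")
})

test_that("flags ignore cells missing either value and survive monotone maps", {
  cells <- paste0("c", 1:6)
  s <- c(1, 2, 3, 4, NA, 6)
  e <- c(2, 1, 4, 3, 5, NA)
  f <- shortening_overexpression_flags(wide1(s, cells), wide1(e, cells), "X")
  expect_identical(f$cell, paste0("c", 1:4))
  f2 <- shortening_overexpression_flags(wide1(exp(s), cells),
                                        wide1(e^3, cells), "X")
  expect_identical(f$flag, f2$flag)
})

test_that("contingency counts partition cells by type and flag", {
  ann <- tibble::tibble(cell = paste0("c", 1:20), patient = "p1",
                        cell_type = rep(c("tumor", "B"), each = 10))
  flags <- tibble::tibble(cell = paste0("c", 1:20),
                          flag = rep(c(TRUE, FALSE), each = 10))
  expect_identical(contingency_counts(flags, ann, "tumor"),
                   c(A = 10L, B = 0L, C = 0L, D = 10L))
  none <- dplyr::mutate(flags, flag = FALSE)
  expect_identical(contingency_counts(none, ann, "tumor"),
                   c(A = 0L, B = 0L, C = 10L, D = 10L))
  expect_error(contingency_counts(flags, ann, "stromal"), "absent")
})

test_that("odds ratio and Fisher p reproduce the worked tables", {
  res <- fisher_odds_ratio(c(8, 2, 2, 8))
  expect_equal(res$odds_ratio, 16)
  res2 <- fisher_odds_ratio(c(5, 0, 0, 5))
  expect_equal(res2$p_value, 2 / 252, tolerance = 1e-12)
  # Haldane-Anscombe correction only when a zero is present
  expect_equal(res2$odds_ratio, (5.5 * 5.5) / (0.5 * 0.5))
  sym <- fisher_odds_ratio(c(3, 3, 3, 3))
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p_value, 1)
  expect_error(fisher_odds_ratio(c(0, 0, 0, 0)), "total")
})

test_that("Fisher p matches exhaustive enumeration over fixed margins", {
  set.seed(101)
  for (i in 1:60) {
    tab <- as.vector(stats::rmultinom(1, sample(4:40, 1), runif(4, 0.1, 1)))
    res <- fisher_odds_ratio(tab)
    expect_equal(res$p_value,
                 fisher_oracle_p(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
    # cross-check against the stock implementation as a second oracle
    ft <- stats::fisher.test(matrix(tab[c(1, 3, 2, 4)], 2))
    expect_equal(res$p_value, ft$p.value, tolerance = 1e-9)
  }
})

test_that("swapping in-type and out-of-type inverts the OR and keeps p", {
  set.seed(55)
  for (i in 1:20) {
    tab <- as.vector(stats::rmultinom(1, 30, runif(4, 0.2, 1))) + 1L
    a <- fisher_odds_ratio(tab)
    b <- fisher_odds_ratio(tab[c(2, 1, 4, 3)])
    expect_equal(a$odds_ratio, 1 / b$odds_ratio, tolerance = 1e-12)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  }
})

test_that("Fisher-Z correlation p-values match their closed form", {
  cells <- paste0("c", 1:12)
  ann <- tibble::tibble(cell = cells, patient = "p", cell_type = "tumor")
  # r = 0.5 at n = 12
  set.seed(3)
  x <- rnorm(12)
  y <- rnorm(12)
  y <- x * 0.5 + sqrt(1 - 0.25) * scale(resid(lm(y ~ x)))[, 1] /
    sd(scale(resid(lm(y ~ x)))[, 1]) * sd(x)
  # force exact r = 0.5 via construction check
  r <- cor(x, y)
  res <- within_type_pcc(wide1(x, cells), wide1(y, cells), "X", ann, "tumor")
  expect_equal(res$r, r, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pnorm(-abs(atanh(r)) * 3), tolerance = 1e-12)
  # the worked value: r = 0.5, n = 12 -> p ~ 0.0994
  expect_equal(2 * pnorm(-atanh(0.5) * sqrt(12 - 3)), 0.0994, tolerance = 1e-3)
  # collinear vectors: p reported as 0 with a warning
  expect_warning(
    res2 <- within_type_pcc(wide1(1:12, cells), wide1(2 * (1:12), cells),
                            "X", ann, "tumor"),
    "collinear")
  expect_equal(res2$p_value, 0)
  # degenerate inputs give NA statistics
  res3 <- within_type_pcc(wide1(rep(1, 12), cells), wide1(1:12, cells),
                          "X", ann, "tumor")
  expect_true(is.na(res3$r))
})

test_that("signature hits require every joint cutoff strictly", {
  set.seed(77)
  n <- 60
  cells <- sprintf("c%03d", 1:n)
  ann <- tibble::tibble(cell = cells, patient = "p",
                        cell_type = rep(c("tumor", "B", "T"), each = n / 3))
  # planted: correlated and jointly high in tumor cells only
  act <- c(runif(n / 3, 0.5, 1.5), rep(0, 2 * n / 3))
  s <- act * 2 + rnorm(n, sd = 0.3)
  e <- act * 2 + rnorm(n, sd = 0.3)
  # negative control: anti-correlated within tumor
  s_neg <- c(seq(2, 3, length.out = n / 3) + rnorm(n / 3, sd = 0.05),
             rnorm(2 * n / 3, sd = 0.3))
  e_neg <- c(seq(3, 2, length.out = n / 3) + rnorm(n / 3, sd = 0.05),
             rnorm(2 * n / 3, sd = 0.3))
  apa_es <- dplyr::bind_rows(wide1(s, cells, "planted"),
                             wide1(s_neg, cells, "anti"))
  expr_es <- dplyr::bind_rows(wide1(e, cells, "planted"),
                              wide1(e_neg, cells, "anti"))
  sig <- select_signatures(apa_es, expr_es, ann)
  stats_p <- dplyr::filter(sig, component == "planted", cell_type == "tumor")
  expect_true(stats_p$hit)
  expect_gt(stats_p$pcc, 0)
  expect_gt(stats_p$odds_ratio, 2)
  # the anti-correlated component is specific but fails PCC > 0
  stats_a <- dplyr::filter(sig, component == "anti", cell_type == "tumor")
  expect_lt(stats_a$pcc, 0)
  expect_false(stats_a$hit)
  expect_gt(stats_a$odds_ratio, 2)
  # output is sorted by cell type then odds ratio
  expect_identical(sig$cell_type, sort(sig$cell_type))
  glanced <- glance(sig)
  expect_identical(sum(glanced$n_hits), sum(sig$hit))
})

test_that("hit calls react to each cutoff independently", {
  # same screen, tightened cutoffs knock out the hit
  set.seed(88)
  n <- 40
  cells <- sprintf("c%03d", 1:n)
  ann <- tibble::tibble(cell = cells, patient = "p",
                        cell_type = rep(c("tumor", "B"), each = n / 2))
  act <- c(runif(n / 2, 0.5, 1.5), rep(0, n / 2))
  apa_es <- wide1(act * 2 + rnorm(n, sd = 0.4), cells, "S")
  expr_es <- wide1(act * 2 + rnorm(n, sd = 0.4), cells, "S")
  loose <- select_signatures(apa_es, expr_es, ann)
  expect_true(any(loose$hit))
  strict_or <- select_signatures(apa_es, expr_es, ann, or_min = 1e6)
  expect_false(any(strict_or$hit))
  strict_p <- select_signatures(apa_es, expr_es, ann, alpha_pcc = 1e-12)
  expect_false(any(strict_p$hit))
  bh <- select_signatures(apa_es, expr_es, ann, adjust = "BH")
  expect_true(all(c("pcc_p_adj", "or_p_adj") %in% names(bh)))
})
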