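#' Filter cells by APA detection rate
#'
#' Keeps cells whose number of non-missing APA estimates is at least
#' `min_fraction` of the total gene count (the boundary is inclusive).
#' The surviving cell set should then be used to subset the expression
#' matrix and annotation.
#'
#' @param apa Wide gene-by-cell APA tibble.
#' @param min_fraction Minimum detected-gene fraction per cell, in (0, 1].
#' @return The input tibble restricted to surviving cells.
#' @export
filter_cells <- function(apa, min_fraction = 0.10) {
  check_fraction(min_fraction, "min_fraction", allow_zero = FALSE)
  m <- as_score_matrix(apa, "APA matrix")
  keep <- colSums(!is.na(m)) >= min_fraction * nrow(m)
  if (!any(keep)) abort("cell filter removed every cell")
  out <- dplyr::select(apa, 1, dplyr::all_of(colnames(m)[keep]))
  attr(out, "dialect") <- attr(apa, "dialect")
  out
}

#' Filter genes by detection rate across cells
#'
#' Keeps genes with a non-missing estimate in at least
#' `min_detect_fraction` of cells (inclusive). Intended for gene-level
#' analyses, where sparsely estimated genes are uninformative.
#'
#' @param apa Wide gene-by-cell APA tibble.
#' @param min_detect_fraction Minimum detection fraction per gene.
#' @return The input tibble restricted to surviving genes.
#' @export
filter_genes <- function(apa, min_detect_fraction = 0.30) {
  check_fraction(min_detect_fraction, "min_detect_fraction")
  m <- as_score_matrix(apa, "APA matrix")
  keep <- rowSums(!is.na(m)) >= min_detect_fraction * ncol(m)
  if (!any(keep)) warn("gene filter removed every gene")
  out <- apa[keep, , drop = FALSE]
  attr(out, "dialect") <- attr(apa, "dialect")
  out
}

#' Select variable components against a mean + s.d. baseline
#'
#' Scores every component (gene or gene set) by its variation level, the
#' sample standard deviation across cells (missing entries excluded), then
#' selects components whose variation level lies strictly above the
#' baseline `mean + baseline_multiplier * s.d.` of all variation levels.
#'
#' @param scores Wide component-by-cell tibble (>= 2 cells).
#' @param baseline_multiplier Multiplier on the s.d. term of the baseline.
#' @return A tibble with columns `component`, `variation`, `n_obs` and
#'   `selected`, carrying the baseline as attribute `baseline`.
#'   Components observed in fewer than 2 cells get `NA` variation and are
#'   never selected.
#' @export
select_variable <- function(scores, baseline_multiplier = 1) {
  m <- as_score_matrix(scores, "score matrix")
  if (ncol(m) < 2) abort("select_variable needs at least 2 cells")
  n_obs <- rowSums(!is.na(m))
  variation <- apply(m, 1, stats::sd, na.rm = TRUE)
  variation[n_obs < 2] <- NA_real_
  baseline <- mean(variation, na.rm = TRUE) +
    baseline_multiplier * stats::sd(variation, na.rm = TRUE)
  if (is.na(baseline)) baseline <- Inf
  out <- tibble(
    component = rownames(m),
    variation = unname(variation),
    n_obs = as.integer(unname(n_obs)),
    selected = !is.na(variation) & variation > baseline
  )
  attr(out, "baseline") <- baseline
  out
}
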