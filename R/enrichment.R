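#' Log-transform a TPM expression matrix
#'
#' Applies `log2(TPM + 1)` entry-wise, the scale on which expression enters
#' both the enrichment scoring and the median-split signature statistic.
#'
#' @param expr Wide gene-by-cell TPM tibble (see [read_expression_matrix()]).
#' @return A wide tibble of the same shape with log2-transformed values.
#' @export
log_transform_expression <- function(expr) {
  m <- as_score_matrix(expr, "expression matrix")
  if (anyNA(m)) abort("expression matrix must not contain missing values")
  if (any(m < 0)) abort("TPM values must be non-negative")
  score_tbl(log2(m + 1), id_col = id_col_name(expr))
}

#' Orient APA scores so that larger means shorter 3'UTR
#'
#' The two APA dialects point in opposite directions: DaPars reports
#' delta-PDUI, where *negative* values mean 3'UTR shortening, while Roar
#' reports a ratio that is *greater than one* under shortening. This step
#' maps both onto a common shortening score `s` where larger is shorter:
#' `s = -delta-PDUI` for dapars and `s = log2(ratio)` for roar. Missing
#' entries stay missing.
#'
#' @param apa Wide gene-by-cell APA tibble.
#' @param dialect `"dapars"` or `"roar"`; defaults to the `dialect`
#'   attribute attached by [read_apa_matrix()].
#' @return A wide tibble of shortening scores.
#' @export
orient_shortening <- function(apa, dialect = NULL) {
  dialect <- dialect %||% attr(apa, "dialect")
  if (is.null(dialect)) abort("dialect must be given or attached to the matrix")
  dialect <- match.arg(dialect, c("dapars", "roar"))
  m <- as_score_matrix(apa, "APA matrix")
  if (dialect == "roar" && any(m <= 0, na.rm = TRUE)) {
    abort("roar values must be > 0")
  }
  out <- if (dialect == "dapars") -m else log2(m)
  score_tbl(out, id_col = id_col_name(apa))
}

#' Single-sample GSEA enrichment scores
#'
#' Computes one enrichment score per (gene set, cell). Within each cell,
#' genes with missing values are dropped from that cell's universe; the
#' remaining `N` genes are ranked by decreasing value (ties broken by
#' ascending gene id). The gene at descending rank `j` receives rank score
#' `r_j = N - j + 1` and weight `|r_j|^tau`. Walking down the ranked list,
#' the in-set cumulative weight fraction `P_in` and the out-of-set
#' cumulative count fraction `P_out` (step `1/(N - m)` for a set with `m`
#' members in the universe) are accumulated, and the enrichment score is
#' the sum of `P_in - P_out` over all `N` positions — the ssGSEA integral
#' of the running difference, not its maximum deviation.
#'
#' Sets with fewer than `min_overlap` members in a cell's universe, or
#' with no out-of-set genes, score `NA` in that cell. With
#' `normalize = TRUE` all scores are divided by the global range
#' (max minus min over the whole matrix).
#'
#' @param scores Wide feature-by-cell tibble; the APA channel passes the
#'   oriented shortening scores, the expression channel passes
#'   `log2(TPM + 1)` values.
#' @param gene_sets Gene-set tibble ([read_gmt()]) or named list.
#' @param tau Rank-weight exponent, >= 0. 0 makes the score purely
#'   rank-based; 0.25 is the conventional ssGSEA default.
#' @param min_overlap Minimum number of set members required in a cell's
#'   observed universe.
#' @param normalize Divide all scores by the matrix-wide score range.
#' @param channel Label recorded on the result, `"apa"` or `"expression"`.
#' @return A wide tibble with column `component` (gene-set ids) followed by
#'   one column per cell, with attribute `channel`.
#' @export
ssgsea_scores <- function(scores, gene_sets, tau = 0.25, min_overlap = 3,
                          normalize = TRUE,
                          channel = c("apa", "expression")) {
  channel <- match.arg(channel)
  if (!is.numeric(tau) || length(tau) != 1 || tau < 0) abort("tau must be >= 0")
  min_overlap <- check_count(min_overlap, "min_overlap", min = 1)
  m <- as_score_matrix(scores, "score matrix")
  sets <- gene_set_list(gene_sets)
  genes <- rownames(m)
  set_idx <- lapply(sets, function(g) which(genes %in% g))

  es <- matrix(NA_real_, nrow = length(sets), ncol = ncol(m),
               dimnames = list(names(sets), colnames(m)))
  for (ci in seq_len(ncol(m))) {
    v <- m[, ci]
    obs <- which(!is.na(v))
    N <- length(obs)
    if (N == 0) {
      abort(sprintf("cell '%s' has no observed values (empty universe)",
                    colnames(m)[ci]))
    }
    ord <- obs[order(-v[obs], genes[obs])]
    pos <- integer(length(genes))
    pos[ord] <- seq_len(N)
    tail_len <- N - seq_len(N) + 1          # positions j..N count
    w <- tail_len^tau                        # |r_j|^tau with r_j = N - j + 1
    tot_tail <- N * (N + 1) / 2
    for (si in seq_along(set_idx)) {
      p <- pos[set_idx[[si]]]
      p <- p[p > 0L]
      mS <- length(p)
      if (mS < min_overlap || mS == N) next
      es[si, ci] <- sum(w[p] * tail_len[p]) / sum(w[p]) -
        (tot_tail - sum(tail_len[p])) / (N - mS)
    }
  }
  if (normalize) {
    rng <- suppressWarnings(range(es, na.rm = TRUE))
    if (is.finite(rng[1]) && rng[2] > rng[1]) {
      es <- es / (rng[2] - rng[1])
    } else {
      warn("degenerate score range; normalization skipped")
    }
  }
  out <- score_tbl(es, id_col = "component")
  attr(out, "channel") <- channel
  out
}
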