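#' Contrast tumor types on gene-set APA enrichment
#'
#' Restricted to cells annotated `cell_type == "tumor"`, each (gene set,
#' tumor type) pair is scored by its delta — the mean enrichment score in
#' the type minus the mean over all other tumor cells — with a two-sided
#' t-test p-value (Welch by default).
#'
#' @param apa_es Wide component-by-cell APA enrichment tibble of oriented
#'   shortening scores.
#' @param annotation Cell annotation tibble with `cell_type` and
#'   `tumor_type` columns.
#' @param alpha Significance level for the `significant` flag.
#' @param var_equal Use the pooled-variance Student t instead of Welch.
#' @return A tibble of class `tumor_contrasts` with columns `set`,
#'   `tumor_type`, `n_type`, `n_other`, `delta`, `t_stat`, `p_value`,
#'   `significant`. Pairs where the test is undefined (a group with < 2
#'   observed scores, or zero variance throughout) report `NA`.
#' @export
contrast_tumor_types <- function(apa_es, annotation, alpha = 0.01,
                                 var_equal = FALSE) {
  check_fraction(alpha, "alpha", allow_zero = FALSE)
  m <- as_score_matrix(apa_es, "APA enrichment matrix")
  annotation <- validate_annotation(annotation)
  if (!"tumor_type" %in% names(annotation)) {
    abort("annotation needs a 'tumor_type' column")
  }
  tumor <- annotation[annotation$cell_type == "tumor" &
                        !is.na(annotation$tumor_type), ]
  cells <- intersect(colnames(m), tumor$cell)
  types <- sort(unique(tumor$tumor_type[match(cells, tumor$cell)]))
  if (length(types) < 2) abort("need >= 2 tumor types among the cells")
  m <- m[, cells, drop = FALSE]
  type_of <- tumor$tumor_type[match(cells, tumor$cell)]

  grid <- tidyr::expand_grid(set = rownames(m), tumor_type = types)
  res <- purrr::pmap(grid, function(set, tumor_type) {
    v <- m[set, ]
    x <- v[type_of == tumor_type & !is.na(v)]
    y <- v[type_of != tumor_type & !is.na(v)]
    if (length(x) < 2 || length(y) < 2) {
      return(list(n_type = length(x), n_other = length(y), delta = NA_real_,
                  t_stat = NA_real_, p_value = NA_real_))
    }
    delta <- mean(x) - mean(y)
    tt <- tryCatch(
      stats::t.test(x, y, var.equal = var_equal),
      error = function(e) NULL
    )
    list(n_type = length(x), n_other = length(y), delta = delta,
         t_stat = if (is.null(tt)) NA_real_ else unname(tt$statistic),
         p_value = if (is.null(tt)) NA_real_ else tt$p.value)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  structure(out, class = c("tumor_contrasts", class(tibble())), alpha = alpha)
}

#' Top differential gene sets for one tumor type
#'
#' Among significant contrasts for the given type, returns the `k` sets
#' with the largest delta in the shortening direction (largest oriented
#' shortening enrichment), ties broken by smaller p-value then set id.
#'
#' @param contrasts Result of [contrast_tumor_types()].
#' @param tumor_type Tumor type to rank.
#' @param k Number of sets to return.
#' @return A tibble of at most `k` rows, ordered.
#' @export
top_contrasts <- function(contrasts, tumor_type, k = 10) {
  k <- check_count(k, "k")
  sig <- dplyr::filter(contrasts, .data$tumor_type == !!tumor_type,
                       .data$significant)
  sig <- dplyr::arrange(sig, dplyr::desc(.data$delta), .data$p_value, .data$set)
  if (nrow(sig) < k) {
    rlang::inform(sprintf("only %d significant set(s) for '%s' (k = %d)",
                          nrow(sig), tumor_type, k))
  }
  utils::head(sig, k)
}
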