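#' Run the cell-type signature pipeline end to end
#'
#' Chains the stages the package is built around: cell filtering on APA
#' detection, orientation of the APA scores toward shortening,
#' log-transformation of expression, single-sample GSEA of both channels
#' (at gene-set level), variable-component selection on the APA channel,
#' and the joint correlation / odds-ratio signature screen on the
#' selected components.
#'
#' At `level = "gene"` the enrichment step is skipped (a gene's own
#' shortening and log-expression scores are its "enrichment"), the
#' sparse-gene filter is applied instead, and components are genes.
#'
#' @param apa Wide gene-by-cell APA tibble.
#' @param expression Wide gene-by-cell TPM tibble.
#' @param annotation Cell annotation tibble.
#' @param gene_sets Gene-set collection; required at gene-set level.
#' @param dialect APA dialect; defaults to the matrix's attribute.
#' @param level `"gene_set"` or `"gene"`.
#' @param min_cell_fraction Cell filter threshold (fraction of genes that
#'   must be detected per cell).
#' @param min_gene_detect Gene filter threshold, gene level only.
#' @param tau,min_overlap,normalize Passed to [ssgsea_scores()].
#' @param baseline_multiplier Passed to [select_variable()].
#' @param variable_only Screen only variable components (the default); if
#'   `FALSE`, every component is screened.
#' @param ... Passed on to [select_signatures()] (cutoffs, scope).
#' @return A list of class `apa_pipeline` with elements `apa_es`,
#'   `expr_es` (component-by-cell tibbles), `variation` (the
#'   [select_variable()] report) and `signatures` (the
#'   [select_signatures()] screen).
#' @export
run_signature_pipeline <- function(apa, expression, annotation,
                                   gene_sets = NULL, dialect = NULL,
                                   level = c("gene_set", "gene"),
                                   min_cell_fraction = 0.10,
                                   min_gene_detect = 0.30,
                                   tau = 0.25, min_overlap = 3,
                                   normalize = TRUE,
                                   baseline_multiplier = 1,
                                   variable_only = TRUE, ...) {
  level <- match.arg(level)
  apa <- filter_cells(apa, min_cell_fraction)
  short <- orient_shortening(apa, dialect)
  log_expr <- log_transform_expression(expression)
  if (level == "gene_set") {
    if (is.null(gene_sets)) abort("gene_sets required at gene-set level")
    apa_es <- ssgsea_scores(short, gene_sets, tau = tau,
                            min_overlap = min_overlap, normalize = normalize,
                            channel = "apa")
    expr_es <- ssgsea_scores(log_expr, gene_sets, tau = tau,
                             min_overlap = min_overlap, normalize = normalize,
                             channel = "expression")
  } else {
    short <- filter_genes(short, min_gene_detect)
    apa_es <- stats::setNames(short, c("component", names(short)[-1]))
    expr_es <- stats::setNames(
      log_expr[log_expr$gene %in% short$gene, ],
      c("component", names(log_expr)[-1]))
  }
  variation <- select_variable(apa_es, baseline_multiplier)
  if (variable_only) {
    keep <- variation$component[variation$selected]
    apa_screen <- apa_es[apa_es$component %in% keep, ]
    expr_screen <- expr_es[expr_es$component %in% keep, ]
  } else {
    apa_screen <- apa_es
    expr_screen <- expr_es
  }
  signatures <- select_signatures(apa_screen, expr_screen, annotation, ...)
  structure(list(apa_es = apa_es, expr_es = expr_es, variation = variation,
                 signatures = signatures),
            class = "apa_pipeline")
}

#' @export
print.apa_pipeline <- function(x, ...) {
  cat(sprintf(
    "<apa_pipeline> %d component(s) scored, %d variable, %d hit pair(s)\n",
    nrow(x$apa_es), sum(x$variation$selected), sum(x$signatures$hit)))
  invisible(x)
}
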