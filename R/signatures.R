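#' Flag cells jointly above the median for shortening and expression
#'
#' For one component, computes the median shortening score and the median
#' expression score over all cells where both are observed, and flags a
#' cell when it lies strictly above both medians — the "3'UTR shortening
#' and over-expression" state. Cells at exactly a median are not flagged;
#' cells missing either value are excluded altogether.
#'
#' @param apa_es,expr_es Wide component-by-cell enrichment tibbles sharing
#'   a cell axis (gene-level analyses pass the oriented shortening and
#'   log-expression matrices directly).
#' @param component Component id present in both matrices.
#' @return A tibble with columns `cell` and logical `flag`, one row per
#'   cell with both values observed.
#' @export
shortening_overexpression_flags <- function(apa_es, expr_es, component) {
  v <- component_pair(apa_es, expr_es, component)
  if (length(v$cells) < 4) {
    abort(sprintf("component '%s': fewer than 4 cells with both values observed",
                  component))
  }
  med_s <- stats::median(v$s)
  med_e <- stats::median(v$e)
  tibble(cell = v$cells, flag = v$s > med_s & v$e > med_e)
}

component_pair <- function(apa_es, expr_es, component) {
  ma <- as_score_matrix(apa_es, "APA enrichment matrix")
  me <- as_score_matrix(expr_es, "expression enrichment matrix")
  if (!component %in% rownames(ma) || !component %in% rownames(me)) {
    abort(sprintf("component '%s' absent from one of the matrices", component))
  }
  cells <- intersect(colnames(ma), colnames(me))
  s <- ma[component, cells]
  e <- me[component, cells]
  ok <- !is.na(s) & !is.na(e)
  list(cells = cells[ok], s = unname(s[ok]), e = unname(e[ok]))
}

#' Cross-tabulate flags against a cell type
#'
#' Builds the 2x2 table behind the odds ratio: A = in-type cells flagged,
#' B = out-of-type cells flagged, C = in-type not flagged, D = out-of-type
#' not flagged. Only flagged-table cells present in the annotation enter.
#'
#' @param flags Tibble from [shortening_overexpression_flags()].
#' @param annotation Cell annotation tibble (`cell`, `cell_type`, ...).
#' @param cell_type The cell type defining "in-type".
#' @return Named integer vector `c(A, B, C, D)`.
#' @export
contingency_counts <- function(flags, annotation, cell_type) {
  if (!cell_type %in% annotation$cell_type) {
    abort(sprintf("cell type '%s' absent from annotation", cell_type))
  }
  joined <- dplyr::inner_join(flags, annotation[, c("cell", "cell_type")],
                              by = "cell")
  in_type <- joined$cell_type == cell_type
  c(A = sum(in_type & joined$flag),
    B = sum(!in_type & joined$flag),
    C = sum(in_type & !joined$flag),
    D = sum(!in_type & !joined$flag))
}

#' Odds ratio and two-sided Fisher exact p for a 2x2 table
#'
#' The odds ratio is `AD / BC`, with the Haldane-Anscombe 0.5 added to all
#' four cells only when some cell is zero. The p-value is the two-sided
#' Fisher exact probability on the *uncorrected* table: with margins
#' fixed, the sum of hypergeometric probabilities of all tables no more
#' likely than the observed one.
#'
#' @param table Counts `c(A, B, C, D)` as laid out by
#'   [contingency_counts()].
#' @return A list with elements `odds_ratio` and `p_value`.
#' @export
fisher_odds_ratio <- function(table) {
  if (length(table) != 4 || any(table < 0) || any(table != floor(table))) {
    abort("table must be four non-negative counts (A, B, C, D)")
  }
  a <- table[[1]]; b <- table[[2]]; c <- table[[3]]; d <- table[[4]]
  if (a + b + c + d < 1) abort("table total must be >= 1")
  or <- if (any(c(a, b, c, d) == 0)) {
    (a + 0.5) * (d + 0.5) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }
  list(odds_ratio = unname(or), p_value = fisher_p2(a, b, c, d))
}

# Two-sided Fisher exact p by the minimum-likelihood rule. k = A drawn
# from a+b flagged among a+c in-type draws; relative tolerance guards
# against floating-point ties in the hypergeometric probabilities.
fisher_p2 <- function(a, b, c, d) {
  m1 <- a + b      # flagged
  n1 <- c + d      # not flagged
  k1 <- a + c      # in-type draws
  support <- max(0L, k1 - n1):min(m1, k1)
  dk <- stats::dhyper(support, m1, n1, k1)
  p_obs <- stats::dhyper(a, m1, n1, k1)
  min(1, sum(dk[dk <= p_obs * (1 + 1e-7)]))
}

#' Within-type Pearson correlation with a Fisher-Z p-value
#'
#' Correlates a component's shortening score with its expression score
#' across the cells of one cell type (both values observed). Significance
#' comes from the Fisher Z transformation: `z = atanh(r)` is treated as
#' normal with standard error `1/sqrt(n - 3)`.
#'
#' @inheritParams shortening_overexpression_flags
#' @param annotation Cell annotation tibble.
#' @param cell_type Cell type whose cells enter the correlation; `NULL`
#'   uses all annotated cells (the "all-cells" scope).
#' @return A list with elements `r`, `p_value` and `n`. Fewer than 4
#'   usable cells or a zero-variance vector yields `NA` statistics.
#' @export
within_type_pcc <- function(apa_es, expr_es, component, annotation,
                            cell_type = NULL) {
  v <- component_pair(apa_es, expr_es, component)
  keep <- if (is.null(cell_type)) {
    v$cells %in% annotation$cell
  } else {
    v$cells %in% annotation$cell[annotation$cell_type == cell_type]
  }
  s <- v$s[keep]; e <- v$e[keep]
  n <- length(s)
  if (n < 4 || stats::sd(s) == 0 || stats::sd(e) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = n))
  }
  r <- stats::cor(s, e)
  list(r = r, p_value = fisher_z_p(r, n), n = n)
}

fisher_z_p <- function(r, n) {
  if (abs(r) >= 1) {
    warn("perfectly collinear scores: Fisher-Z p reported as 0")
    return(0)
  }
  2 * stats::pnorm(-abs(atanh(r)) * sqrt(n - 3))
}

#' Call cell-type-specific shortening/over-expression signatures
#'
#' The package's core screen. Every (component, cell type) pair is scored
#' on two axes: (i) the within-type Pearson correlation between the
#' component's shortening and expression scores, with a Fisher-Z p-value,
#' and (ii) the odds ratio of the global median-split 2x2 table of
#' "shortening and over-expression" cells in the type versus the rest,
#' with a two-sided Fisher exact p. A pair is a hit when
#' `pcc > 0 & pcc_p < alpha_pcc` and `odds_ratio > or_min & or_p < alpha_or`
#' simultaneously (all inequalities strict). The same component may be a
#' hit in several cell types. No multiple-testing correction is applied by
#' default; `adjust = "BH"` adds Benjamini-Hochberg-adjusted columns and
#' applies the cutoffs to those instead.
#'
#' @inheritParams shortening_overexpression_flags
#' @param annotation Cell annotation tibble covering the shared cells.
#' @param cell_types Cell types to screen; defaults to all annotated types.
#' @param alpha_pcc,alpha_or Significance cutoffs for the two axes.
#' @param or_min Minimum odds ratio.
#' @param pcc_scope `"within"` correlates inside the candidate type (the
#'   default); `"all"` uses every annotated cell.
#' @param adjust `"none"` (raw cutoffs) or `"BH"`.
#' @return A tibble of class `apa_signatures`, one row per (component,
#'   cell type), sorted by cell type then decreasing odds ratio, with
#'   columns `component`, `cell_type`, `n_type`, `pcc`, `pcc_p`,
#'   `A`, `B`, `C`, `D`, `odds_ratio`, `or_p`, `hit`. Pairs whose
#'   statistics are undefined (too few cells, zero variance) keep `NA`
#'   statistics and `hit = FALSE`.
#' @export
select_signatures <- function(apa_es, expr_es, annotation, cell_types = NULL,
                              alpha_pcc = 0.05, alpha_or = 0.01, or_min = 2,
                              pcc_scope = c("within", "all"),
                              adjust = c("none", "BH")) {
  pcc_scope <- match.arg(pcc_scope)
  adjust <- match.arg(adjust)
  for (a in list(alpha_pcc, alpha_or)) {
    if (!is.numeric(a) || a <= 0 || a > 1) abort("alpha cutoffs must be in (0, 1]")
  }
  ma <- as_score_matrix(apa_es, "APA enrichment matrix")
  me <- as_score_matrix(expr_es, "expression enrichment matrix")
  annotation <- validate_annotation(annotation)
  cells <- intersect(intersect(colnames(ma), colnames(me)), annotation$cell)
  if (length(cells) < 4) abort("fewer than 4 cells shared by matrices and annotation")
  ma <- ma[, cells, drop = FALSE]
  me <- me[intersect(rownames(ma), rownames(me)), cells, drop = FALSE]
  components <- intersect(rownames(ma), rownames(me))
  type_of <- annotation$cell_type[match(cells, annotation$cell)]
  cell_types <- cell_types %||% sort(unique(type_of))

  rows <- vector("list", length(components) * length(cell_types))
  k <- 0L
  for (comp in components) {
    s <- ma[comp, ]; e <- me[comp, ]
    ok <- !is.na(s) & !is.na(e)
    s_ok <- s[ok]; e_ok <- e[ok]; ty <- type_of[ok]
    eligible <- sum(ok) >= 4
    if (eligible) {
      flag <- s_ok > stats::median(s_ok) & e_ok > stats::median(e_ok)
    }
    for (ct in cell_types) {
      k <- k + 1L
      if (!eligible || !any(ty == ct)) {
        rows[[k]] <- tibble(component = comp, cell_type = ct,
                            n_type = sum(ty == ct), pcc = NA_real_,
                            pcc_p = NA_real_, A = NA_integer_, B = NA_integer_,
                            C = NA_integer_, D = NA_integer_,
                            odds_ratio = NA_real_, or_p = NA_real_)
        next
      }
      in_type <- ty == ct
      tab <- c(sum(in_type & flag), sum(!in_type & flag),
               sum(in_type & !flag), sum(!in_type & !flag))
      fo <- fisher_odds_ratio(tab)
      sp <- if (pcc_scope == "within") s_ok[in_type] else s_ok
      ep <- if (pcc_scope == "within") e_ok[in_type] else e_ok
      if (length(sp) >= 4 && stats::sd(sp) > 0 && stats::sd(ep) > 0) {
        r <- stats::cor(sp, ep)
        pp <- fisher_z_p(r, length(sp))
      } else {
        r <- NA_real_; pp <- NA_real_
      }
      rows[[k]] <- tibble(component = comp, cell_type = ct,
                          n_type = sum(in_type), pcc = r, pcc_p = pp,
                          A = tab[1], B = tab[2], C = tab[3], D = tab[4],
                          odds_ratio = fo$odds_ratio, or_p = fo$p_value)
    }
  }
  out <- dplyr::bind_rows(rows)
  pcc_p_use <- out$pcc_p
  or_p_use <- out$or_p
  if (adjust == "BH") {
    out$pcc_p_adj <- stats::p.adjust(out$pcc_p, method = "BH")
    out$or_p_adj <- stats::p.adjust(out$or_p, method = "BH")
    pcc_p_use <- out$pcc_p_adj
    or_p_use <- out$or_p_adj
  }
  out$hit <- !is.na(out$pcc) & out$pcc > 0 & pcc_p_use < alpha_pcc &
    !is.na(out$odds_ratio) & out$odds_ratio > or_min & or_p_use < alpha_or
  out <- dplyr::arrange(out, .data$cell_type,
                        dplyr::desc(dplyr::coalesce(.data$odds_ratio, -Inf)))
  structure(out,
            class = c("apa_signatures", class(tibble())),
            alpha_pcc = alpha_pcc, alpha_or = alpha_or, or_min = or_min,
            pcc_scope = pcc_scope)
}
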