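#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a signature screen
#'
#' @param x An `apa_signatures` result.
#' @param ... Unused.
#' @return The underlying per-(component, cell type) tibble.
#' @method tidy apa_signatures
#' @export
tidy.apa_signatures <- function(x, ...) {
  as_tibble(x)
}

#' Summarise a signature screen
#'
#' @param x An `apa_signatures` result.
#' @param ... Unused.
#' @return One row per cell type: pairs tested, eligible pairs and hits,
#'   plus the cutoffs used.
#' @method glance apa_signatures
#' @export
glance.apa_signatures <- function(x, ...) {
  out <- dplyr::summarise(
    dplyr::group_by(as_tibble(x), .data$cell_type),
    n_tested = dplyr::n(),
    n_eligible = sum(!is.na(.data$odds_ratio) & !is.na(.data$pcc)),
    n_hits = sum(.data$hit),
    .groups = "drop"
  )
  out$alpha_pcc <- attr(x, "alpha_pcc")
  out$alpha_or <- attr(x, "alpha_or")
  out$or_min <- attr(x, "or_min")
  out
}

#' Plot a signature screen
#'
#' Odds ratio (log scale) against within-type correlation, one panel per
#' cell type, hits highlighted.
#'
#' @param object An `apa_signatures` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot apa_signatures
#' @export
autoplot.apa_signatures <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), !is.na(.data$odds_ratio),
                      !is.na(.data$pcc))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pcc, y = .data$odds_ratio,
                                   colour = .data$hit)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = attr(object, "or_min"),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$cell_type)) +
    ggplot2::labs(x = "within-type Pearson r (shortening vs expression)",
                  y = "odds ratio (median split)", colour = "hit")
}

#' Tidy a tumor-type contrast table
#'
#' @param x A `tumor_contrasts` result.
#' @param ... Unused.
#' @method tidy tumor_contrasts
#' @export
tidy.tumor_contrasts <- function(x, ...) as_tibble(x)

#' Summarise a tumor-type contrast table
#'
#' @param x A `tumor_contrasts` result.
#' @param ... Unused.
#' @return One row per tumor type with counts of tested and significant
#'   sets.
#' @method glance tumor_contrasts
#' @export
glance.tumor_contrasts <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(as_tibble(x), .data$tumor_type),
    n_tested = dplyr::n(),
    n_significant = sum(.data$significant, na.rm = TRUE),
    .groups = "drop"
  )
}

#' Plot tumor-type contrasts
#'
#' Volcano-style view: delta against -log10 p, per tumor type.
#'
#' @param object A `tumor_contrasts` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tumor_contrasts
#' @export
autoplot.tumor_contrasts <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), !is.na(.data$p_value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta,
                                   y = -log10(.data$p_value),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$tumor_type)) +
    ggplot2::labs(x = "delta (mean shortening enrichment, type - others)",
                  y = expression(-log[10]~p), colour = "significant")
}

#' Tidy a Kaplan-Meier fit
#'
#' @param x An `apa_km` object.
#' @param ... Unused.
#' @return The step-curve tibble (`group`, `time`, `n_risk`, `n_event`,
#'   `survival`).
#' @method tidy apa_km
#' @export
tidy.apa_km <- function(x, ...) as_tibble(x)

#' Summarise a Kaplan-Meier fit
#'
#' @param x An `apa_km` object.
#' @param ... Unused.
#' @return One row per group: records, events, final survival estimate.
#' @method glance apa_km
#' @export
glance.apa_km <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(as_tibble(x), .data$group),
    n_event_times = dplyr::n(),
    n_events = sum(.data$n_event),
    final_survival = dplyr::last(.data$survival),
    .groups = "drop"
  )
}

#' Plot Kaplan-Meier curves
#'
#' @param object An `apa_km` object.
#' @param ... Unused.
#' @return A ggplot object with one step curve per group.
#' @method autoplot apa_km
#' @export
autoplot.apa_km <- function(object, ...) {
  df <- as_tibble(object)
  start <- dplyr::distinct(df, .data$group)
  start$time <- 0
  start$survival <- 1
  df <- dplyr::bind_rows(start, df[, c("group", "time", "survival")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "years since diagnosis", y = "survival probability",
                  colour = NULL)
}

#' Tidy a Cox fit
#'
#' @param x An `apa_cox` object.
#' @param ... Unused.
#' @method tidy apa_cox
#' @export
tidy.apa_cox <- function(x, ...) as_tibble(x)

#' Summarise a Cox fit
#'
#' @param x An `apa_cox` object.
#' @param ... Unused.
#' @return One-row tibble with sample size, events, concordance and
#'   likelihood-ratio p.
#' @method glance apa_cox
#' @export
glance.apa_cox <- function(x, ...) {
  fit <- attr(x, "fit")
  s <- summary(fit)
  tibble(
    n = s$n,
    n_events = s$nevent,
    concordance = unname(s$concordance[1]),
    logtest_p = unname(s$logtest["pvalue"])
  )
}
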