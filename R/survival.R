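#' Administratively censor survival records at a horizon
#'
#' Implements the long-term survival rule: any patient whose recorded time
#' exceeds the horizon is treated as alive at the horizon — a death after
#' 10 years counts as survival for the 10-year analysis. The operation is
#' idempotent.
#'
#' @param records Survival tibble with columns `time` (years) and `event`
#'   (1 = death, 0 = censored).
#' @param horizon Censoring horizon in years.
#' @return The records with times capped at `horizon` and events beyond it
#'   set to 0.
#' @export
censor_at_horizon <- function(records, horizon = 10) {
  if (!is.numeric(horizon) || horizon <= 0) abort("horizon must be > 0")
  if (any(records$time < 0, na.rm = TRUE)) abort("survival times must be >= 0")
  beyond <- records$time > horizon
  records$event[beyond] <- 0L
  records$time[beyond] <- horizon
  records
}

#' Assign patients to expression quartile groups
#'
#' Splits patients into a `low` class (expression at or below the 25th
#' percentile) and a `high` class (at or above the 75th percentile);
#' everyone strictly between is `excluded` and takes no part in the
#' two-group tests. Percentiles are computed by linear interpolation
#' between order statistics.
#'
#' @param expression Tibble with columns `patient` and `value` (one
#'   expression value per patient for the target gene).
#' @return The input with an added factor column `group` with levels
#'   `low`, `excluded`, `high`.
#' @export
quartile_groups <- function(expression) {
  if (!all(c("patient", "value") %in% names(expression))) {
    abort("expression must have columns 'patient' and 'value'")
  }
  v <- expression$value
  if (length(v) < 4) abort("need >= 4 patients to form quartile groups")
  q <- stats::quantile(v, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  group <- dplyr::case_when(
    v <= q[1] ~ "low",
    v >= q[2] ~ "high",
    .default = "excluded"
  )
  if (q[1] == q[2]) {
    warn("constant (or near-constant) expression: quartile boundaries coincide")
    group <- rep("excluded", length(v))
  }
  dplyr::mutate(expression,
                group = factor(group, levels = c("low", "excluded", "high")))
}

#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function of each group by the product-limit
#' formula: at each distinct event time `t_i` with `d_i` deaths among
#' `n_i` at risk, the curve drops by the factor `1 - d_i/n_i`; censored
#' times shrink the risk set but contribute no factor.
#'
#' @param records Survival tibble with `time` and `event`, and optionally
#'   a `group` column (rows with `group == "excluded"` are dropped).
#' @return An object of class `apa_km`: a tibble with columns `group`,
#'   `time`, `n_risk`, `n_event`, `survival`, one row per distinct event
#'   time per group.
#' @export
km_fit <- function(records) {
  if (!"group" %in% names(records)) records$group <- "all"
  records <- records[records$group != "excluded" & !is.na(records$group), ]
  if (nrow(records) == 0) abort("no records to fit")
  out <- dplyr::group_modify(
    dplyr::group_by(records, .data$group),
    ~ km_one(.x$time, .x$event)
  )
  out <- dplyr::ungroup(out)
  structure(out, class = c("apa_km", class(tibble())))
}

km_one <- function(time, event) {
  stopifnot(length(time) >= 1)
  d_times <- sort(unique(time[event == 1]))
  n_risk <- vapply(d_times, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(d_times, function(t) sum(time == t & event == 1), numeric(1))
  tibble(time = d_times, n_risk = n_risk, n_event = n_event,
         survival = cumprod(1 - n_event / n_risk))
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param km An `apa_km` object (single group or with a `group` column).
#' @param times Times at which to read off the step function.
#' @param group Which group to evaluate (default: the only one).
#' @return Numeric survival probabilities, `S(0) = 1` before the first
#'   event.
#' @export
km_survival_at <- function(km, times, group = NULL) {
  if (is.null(group)) {
    groups <- unique(km$group)
    if (length(groups) != 1) abort("specify 'group' for a multi-group fit")
    group <- groups
  }
  curve <- km[km$group == group, ]
  vapply(times, function(t) {
    i <- which(curve$time <= t)
    if (length(i) == 0) 1 else curve$survival[max(i)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' At each distinct event time, the observed deaths in the first group are
#' compared with their hypergeometric expectation given the pooled risk
#' set; the statistic `(sum O - sum E)^2 / sum V` is referred to a
#' chi-square distribution with 1 degree of freedom.
#'
#' @param records Survival tibble with `time`, `event` and a `group`
#'   column holding exactly two non-excluded levels.
#' @return A list with `chi_square`, `p_value`, `observed`, `expected`
#'   (both for the first group in sorted level order) and `n` per group.
#' @export
logrank_test <- function(records) {
  records <- records[records$group != "excluded" & !is.na(records$group), ]
  groups <- sort(unique(as.character(records$group)))
  if (length(groups) != 2) abort("log-rank test needs exactly 2 groups")
  g1 <- records$group == groups[1]
  time <- records$time; event <- records$event
  if (sum(event) == 0) abort("no events: log-rank test undefined")
  d_times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in d_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- if (V > 0) (O - E)^2 / V else 0
  list(chi_square = chi,
       p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
       observed = O, expected = E,
       n = stats::setNames(c(sum(g1), sum(!g1)), groups))
}

#' Multivariate Cox proportional-hazards regression
#'
#' Fits a Cox partial-likelihood model (Efron tie handling) of survival on
#' the quartile-group indicator plus clinical covariates, and reports a
#' hazard ratio and Wald p-value per term. The group indicator being
#' significant alongside the covariates is the "independent prognostic
#' factor" criterion.
#'
#' @param records Survival tibble with `time`, `event`, a `group` column
#'   (levels `low`/`high` after exclusion) and the covariate columns.
#' @param covariates Character vector of covariate column names.
#' @return A tibble of class `apa_cox` with columns `term`, `estimate`
#'   (log hazard ratio), `hazard_ratio`, `se`, `p_value`, carrying the
#'   `survival::coxph` fit as attribute `fit`. Non-convergence or
#'   separation is reported as an error condition, never silently.
#' @export
cox_multivariate <- function(records, covariates = character()) {
  records <- records[records$group != "excluded" & !is.na(records$group), ]
  if (!all(covariates %in% names(records))) {
    abort("missing covariate columns: ",
          paste(setdiff(covariates, names(records)), collapse = ", "))
  }
  for (cv in covariates) {
    if (dplyr::n_distinct(records[[cv]]) < 2) {
      abort(sprintf("covariate '%s' is constant", cv))
    }
  }
  records$group <- droplevels(factor(records$group))
  n_terms <- 1 + length(covariates)
  if (sum(records$event) < n_terms) {
    abort("fewer events than model terms; refusing to fit")
  }
  fml <- stats::reformulate(c("group", covariates),
                            response = "survival::Surv(time, event)")
  fit <- tryCatch(
    survival::coxph(fml, data = records, ties = "efron"),
    error = function(e) abort(paste("Cox fit failed:", conditionMessage(e))),
    warning = function(w) {
      abort(paste("Cox fit did not converge cleanly:", conditionMessage(w)))
    }
  )
  if (any(is.na(stats::coef(fit)))) {
    abort("Cox fit dropped collinear terms; check the covariate design")
  }
  s <- summary(fit)$coefficients
  out <- tibble(
    term = rownames(s),
    estimate = s[, "coef"],
    hazard_ratio = s[, "exp(coef)"],
    se = s[, "se(coef)"],
    p_value = s[, "Pr(>|z|)"]
  )
  structure(out, class = c("apa_cox", class(tibble())), fit = fit)
}
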