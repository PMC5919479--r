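# Time-to-event analysis. Estimation is delegated to the survival package
# (survfit / survdiff / coxph); these wrappers fix the conventions used
# throughout the pipeline (day scale, Breslow ties, Wald intervals) and
# return plain lists the report writers consume.

#' Kaplan-Meier fit by group
#'
#' Product-limit estimator of survival, optionally stratified by a group
#' label.
#'
#' @param time follow-up time, days (> 0).
#' @param event event indicator (1 = death/event, 0 = censored).
#' @param group optional group labels.
#' @return object of class `rvl_km` wrapping the `survfit` object, with the
#'   group labels attached.
#' @export
km_fit <- function(time, event, group = NULL) {
  check_positive(time, "time")
  event <- as.integer(as.logical(event))
  if (is.null(group)) group <- rep("all", length(time))
  d <- data.frame(time = time, event = event, group = factor(group))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  structure(list(fit = fit, groups = levels(d$group), data = d),
    class = "rvl_km"
  )
}

#' Survival probability at a landmark time
#'
#' Reads the Kaplan-Meier estimate at time `t` per group (the estimate is
#' carried forward past the last observed time). With no censoring before
#' `t` this equals 1 - deaths/n.
#'
#' @param km an [km_fit()] object.
#' @param t landmark time in days (default 365).
#' @return named vector of survival fractions, one per group.
#' @export
survival_at <- function(km, t = 365) {
  stopifnot(inherits(km, "rvl_km"))
  s <- summary(km$fit, times = t, extend = TRUE)
  grp <- if (is.null(s$strata)) km$groups else sub("^group=", "", s$strata)
  stats::setNames(s$surv, grp)
}

#' Kaplan-Meier curve coordinates
#'
#' Step-function coordinates (time, survival, at-risk) per group, as a plain
#' table suitable for plotting or text export.
#'
#' @param km an [km_fit()] object.
#' @return data.frame with `group`, `time`, `survival`, `at_risk`.
#' @export
km_coordinates <- function(km) {
  stopifnot(inherits(km, "rvl_km"))
  s <- summary(km$fit, censored = TRUE)
  grp <- if (is.null(s$strata)) {
    rep(km$groups[1], length(s$time))
  } else {
    sub("^group=", "", as.character(s$strata))
  }
  data.frame(
    group = grp, time = s$time, survival = s$surv, at_risk = s$n.risk
  )
}

#' Log-rank test between two groups
#'
#' @param time follow-up time, days.
#' @param event event indicator.
#' @param group two-level group label.
#' @return list with `statistic` (chi-square, df = 1) and `p`.
#' @export
logrank <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) != 2) stop_invalid("log-rank wrapper expects 2 groups")
  if (sum(event) < 1) stop_invalid("need at least one event")
  d <- data.frame(time = time, event = as.integer(as.logical(event)),
    group = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  list(
    statistic = sd$chisq,
    p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  )
}

#' Univariable Cox screen
#'
#' Fits one Cox model per candidate covariate and retains those with Wald
#' p < `alpha` (default 0.1), the conventional liberal screen before a
#' multivariable model.
#'
#' @param data data.frame holding the covariates.
#' @param candidates character vector of covariate column names.
#' @param time,event outcome columns (vectors, same length as `data` rows).
#' @param alpha screening level (default 0.1).
#' @return data.frame with `covariate`, `hr`, `p`, `selected`.
#' @export
univariable_screen <- function(data, candidates, time, event, alpha = 0.1) {
  event <- as.integer(as.logical(event))
  rows <- lapply(candidates, function(v) {
    d <- data.frame(time = time, event = event, x = data[[v]])
    fit <- survival::coxph(survival::Surv(time, event) ~ x, data = d)
    s <- summary(fit)$coefficients
    data.frame(covariate = v, hr = s[1, "exp(coef)"], p = s[1, 5])
  })
  out <- do.call(rbind, rows)
  out$selected <- out$p < alpha
  out
}

#' Adjusted Cox proportional-hazards model
#'
#' Multivariable Cox fit with Breslow tie handling by default (Efron by
#' option), Wald 95% confidence intervals and two-sided p-values per
#' covariate. Warns when events are fewer than five per covariate; a
#' zero-variance covariate is rejected before fitting.
#'
#' @param data data.frame holding the covariates.
#' @param time,event outcome vectors.
#' @param covariates character vector of covariate columns (e.g. the RVL
#'   risk flag plus the screened clinical covariates).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return data.frame of class `cox_result` with `covariate`, `hr`,
#'   `ci_lo`, `ci_hi`, `p`.
#' @export
cox_adjusted <- function(data, time, event, covariates, ties = "breslow") {
  event <- as.integer(as.logical(event))
  d <- data[, covariates, drop = FALSE]
  novar <- vapply(d, function(x) stats::var(as.numeric(x)) == 0, logical(1))
  if (any(novar)) {
    stop_invalid(
      "zero-variance covariate(s): ",
      paste(covariates[novar], collapse = ", ")
    )
  }
  if (sum(event) < 5 * length(covariates)) {
    warning(sprintf(
      "only %d events for %d covariates (< 5 per covariate)",
      sum(event), length(covariates)
    ), call. = FALSE)
  }
  d$time <- time
  d$event <- event
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(covariates, collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = d, ties = ties)
  if (any(is.na(stats::coef(fit)))) {
    stop(
      "Cox model did not yield estimates for: ",
      paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", ")
    )
  }
  s <- summary(fit)
  out <- data.frame(
    covariate = rownames(s$coefficients),
    hr = s$coefficients[, "exp(coef)"],
    ci_lo = s$conf.int[, "lower .95"],
    ci_hi = s$conf.int[, "upper .95"],
    p = s$coefficients[, 5],
    row.names = NULL
  )
  class(out) <- c("cox_result", "data.frame")
  out
}
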