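# Pipeline orchestration: the canonical cohort CSV schema (unit-suffixed
# column names guard against the cm/m and ml/m^2 mistakes this formula
# chain invites), the run configuration, and the derive / evaluate /
# simulate / reproduce-tables stages. Reports are emitted as plain
# data.frames plus machine-readable JSON.

cohort_schema <- c(
  "patient_id", "lvot_diameter_cm", "vti_lvot_cm", "vti_av_cm",
  "v_max_ms", "v_lvot_ms", "sbp_mmhg", "bsa_m2", "lvef_pct", "rhythm",
  "mg_mmhg", "time_days", "event"
)

#' Run configuration
#'
#' Dichotomization rules per index (cutoff, direction, strictness), the
#' gradient rule for phenotyping, and the chi-square variant. Defaults are
#' the literature cutoffs: RVL <= 7.95 ml/m^2, MG < 40 mmHg,
#' AVA > 0.75 cm^2, %SWL <= 25, Zva >= 5 mmHg.m^2/ml, SVI <= 35 ml/m^2.
#'
#' @param cutoffs named numeric overrides for index cutoffs.
#' @param gradient_rule `"lt"` (MG < 40 is low gradient) or `"le"`.
#' @param chi2_correct Yates correction flag for chi-square tests.
#' @param cox_ties `"breslow"` or `"efron"`.
#' @param seed RNG seed recorded in reports.
#' @return list of class `run_config` with an `indices` rule table.
#' @export
run_config <- function(cutoffs = NULL, gradient_rule = "lt",
                       chi2_correct = FALSE, cox_ties = "breslow",
                       seed = 1) {
  rules <- data.frame(
    index = c("rvl", "mg", "ava", "swl_pct", "zva", "svi"),
    cutoff = c(7.95, 40, 0.75, 25, 5, 35),
    direction = c(
      "low_positive", "low_positive", "high_positive",
      "low_positive", "high_positive", "low_positive"
    ),
    strict = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE)
  )
  if (!is.null(cutoffs)) {
    for (nm in names(cutoffs)) {
      if (!nm %in% rules$index) stop_invalid("unknown index: ", nm)
      if (cutoffs[[nm]] <= 0) stop_invalid("cutoffs must be positive")
      rules$cutoff[rules$index == nm] <- cutoffs[[nm]]
    }
  }
  structure(
    list(
      indices = rules, gradient_rule = gradient_rule,
      chi2_correct = chi2_correct, cox_ties = cox_ties, seed = seed
    ),
    class = "run_config"
  )
}

#' Validate and read a cohort CSV
#'
#' @param path file path of a cohort table written by [write_cohort()] or
#'   conforming to the documented schema (unit-suffixed column names,
#'   missing values as empty cells).
#' @return the cohort data.frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
  df
}

#' @rdname read_cohort
#' @param df cohort data.frame.
#' @export
write_cohort <- function(df, path) {
  validate_cohort(df)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

validate_cohort <- function(df) {
  if (!is.data.frame(df) || nrow(df) == 0) {
    stop_invalid("cohort table is empty or not tabular")
  }
  missing_cols <- setdiff(cohort_schema, names(df))
  if (length(missing_cols)) {
    stop_invalid(
      "cohort schema violation; missing columns: ",
      paste(missing_cols, collapse = ", ")
    )
  }
  invisible(df)
}

#' Derive indices and phenotypes for a cohort table
#'
#' Appends every derived hemodynamic index and the phenotype labels to a
#' schema-valid cohort table. Rows whose primitives fail validation are kept
#' with an explanatory `derive_error` string rather than dropped; the
#' operation is idempotent on its own output.
#'
#' @param df cohort data.frame (see [read_cohort()]).
#' @param config a [run_config()].
#' @return the input with appended columns `csa_lvot_cm2`, `sv_ml`,
#'   `svi_ml_m2`, `ava_cm2`, `ava_indexed_cm2_m2`, `swl_pct`,
#'   `zva_mmhg_m2_ml`, `rvl_ml_m2`, `flow`, `gradient`, `subclass`,
#'   `rvl_high_risk`, `severe_as`, `derive_error`.
#' @export
derive_cohort <- function(df, config = run_config()) {
  validate_cohort(df)
  rule <- config$indices
  rvl_cut <- rule$cutoff[rule$index == "rvl"]
  out <- df
  cols <- c(
    "csa_lvot_cm2", "sv_ml", "svi_ml_m2", "ava_cm2", "ava_indexed_cm2_m2",
    "swl_pct", "zva_mmhg_m2_ml", "rvl_ml_m2"
  )
  for (cl in cols) out[[cl]] <- NA_real_
  out$derive_error <- NA_character_
  for (i in seq_len(nrow(df))) {
    res <- tryCatch(
      derive_all(list(
        lvot_diameter = df$lvot_diameter_cm[i],
        vti_lvot = df$vti_lvot_cm[i],
        vti_av = df$vti_av_cm[i],
        sbp = df$sbp_mmhg[i],
        bsa = df$bsa_m2[i],
        mg_measured = df$mg_mmhg[i],
        v_max = df$v_max_ms[i],
        v_lvot = df$v_lvot_ms[i]
      )),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      out$derive_error[i] <- conditionMessage(res)
    } else {
      out[i, cols] <- c(
        res$csa_lvot, res$sv, res$svi, res$ava, res$ava_indexed,
        res$swl_pct, res$zva, res$rvl
      )
    }
  }
  ok <- is.na(out$derive_error)
  cls <- classify_flow_gradient(
    out$svi_ml_m2[ok], out$mg_mmhg[ok], out$lvef_pct[ok],
    gradient_rule = config$gradient_rule
  )
  out$flow <- out$gradient <- out$subclass <- NA_character_
  out$flow[ok] <- cls$flow
  out$gradient[ok] <- cls$gradient
  out$subclass[ok] <- cls$subclass
  out$rvl_high_risk <- NA
  out$rvl_high_risk[ok] <- dichotomize_rvl(out$rvl_ml_m2[ok], rvl_cut)
  out$severe_as <- NA
  out$severe_as[ok] <- is_severe_as(out$ava_cm2[ok], out$ava_indexed_cm2_m2[ok])
  out
}

endpoint_events <- function(df, endpoint = c("death", "cv_death", "death_or_readmit")) {
  endpoint <- match.arg(endpoint)
  switch(endpoint,
    death = df$event == 1,
    cv_death = df$event == 1 & !is.na(df$cause) & df$cause == "cardiovascular",
    death_or_readmit = df$event == 1 |
      (!is.na(df$readmit_hf) & df$readmit_hf == 1)
  )
}

index_column <- function(index) {
  c(
    rvl = "rvl_ml_m2", mg = "mg_mmhg", ava = "ava_cm2",
    swl_pct = "swl_pct", zva = "zva_mmhg_m2_ml", svi = "svi_ml_m2"
  )[[index]]
}

#' Evaluate the prognostic value of every index on a derived cohort
#'
#' Produces the full evaluation report for one endpoint: per-index AUC with
#' DeLong p-values against RVL, sensitivity/specificity at the literature
#' cutoffs with exact McNemar p-values against RVL, the Youden-optimal RVL
#' cutoff, flow and low-gradient subgroup chi-squares, Kaplan-Meier
#' coordinates and 1-year survival by RVL group with the log-rank test, the
#' univariable screen and the adjusted Cox model.
#'
#' @param df derived cohort (output of [derive_cohort()] plus outcome
#'   columns `time_days`, `event`, optionally `cause`, `readmit_hf`,
#'   `afib`, `euroscore2`).
#' @param config a [run_config()].
#' @param endpoint `"death"`, `"cv_death"` or `"death_or_readmit"`.
#' @return list of class `rvl_report`.
#' @export
evaluate_cohort <- function(df, config = run_config(),
                            endpoint = "death") {
  if (!"rvl_ml_m2" %in% names(df)) {
    stop_invalid("run derive_cohort() first: no derived index columns")
  }
  ok <- is.na(df$derive_error)
  df <- df[ok, , drop = FALSE]
  ev <- endpoint_events(df, endpoint)
  if (sum(ev, na.rm = TRUE) == 0) {
    stop_invalid("no events for endpoint '", endpoint, "': nothing to evaluate")
  }
  rules <- config$indices
  rvl_rule <- rules[rules$index == "rvl", ]
  rvl_scores <- df[[index_column("rvl")]]

  # ROC / AUC table with paired DeLong comparisons against RVL
  roc_rvl <- roc_curve(rvl_scores, ev, rvl_rule$direction)
  auc_tab <- do.call(rbind, lapply(seq_len(nrow(rules)), function(i) {
    r <- rules[i, ]
    sc <- df[[index_column(r$index)]]
    auc_i <- roc_curve(sc, ev, r$direction)$auc
    p <- if (r$index == "rvl") NA_real_ else {
      delong_auc_test(rvl_scores, sc, ev,
        direction_a = rvl_rule$direction, direction_b = r$direction
      )$p
    }
    data.frame(index = r$index, auc_pct = 100 * auc_i, p_vs_rvl = p)
  }))

  # sensitivity/specificity at literature cutoffs, McNemar vs RVL
  calls <- lapply(seq_len(nrow(rules)), function(i) {
    r <- rules[i, ]
    sc <- df[[index_column(r$index)]]
    if (r$direction == "low_positive") {
      if (r$strict) sc < r$cutoff else sc <= r$cutoff
    } else {
      if (r$strict) sc > r$cutoff else sc >= r$cutoff
    }
  })
  names(calls) <- rules$index
  sens_spec_tab <- do.call(rbind, lapply(seq_len(nrow(rules)), function(i) {
    r <- rules[i, ]
    ct <- confusion_at_cutoff(
      df[[index_column(r$index)]], ev, r$cutoff, r$direction, r$strict
    )
    if (r$index == "rvl") {
      p_sens <- p_spec <- NA_real_
    } else {
      p_sens <- mcnemar_paired(calls$rvl, calls[[r$index]], ev, "events")
      p_spec <- mcnemar_paired(calls$rvl, calls[[r$index]], ev, "nonevents")
    }
    data.frame(
      index = r$index, cutoff = r$cutoff,
      sens_pct = pct(ct$tp, ct$tp + ct$fn),
      p_sens_vs_rvl = p_sens,
      spec_pct = pct(ct$tn, ct$tn + ct$fp),
      p_spec_vs_rvl = p_spec
    )
  }))

  youden <- youden_cutoff(roc_rvl)

  # subgroup chi-squares: RVL risk group vs endpoint within flow states and
  # the pooled low-gradient stratum
  subgroup_chi2 <- function(sel) {
    if (sum(sel) == 0 || sum(ev[sel]) == 0) {
      return(data.frame(
        n = sum(sel), chi2 = NA_real_, lr = NA_real_, p = NA_real_
      ))
    }
    tab <- table(
      factor(df$rvl_high_risk[sel], levels = c(TRUE, FALSE)),
      factor(ev[sel], levels = c(TRUE, FALSE))
    )
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      return(data.frame(
        n = sum(sel), chi2 = NA_real_, lr = NA_real_, p = NA_real_
      ))
    }
    px <- pearson_chi2(tab, correct = config$chi2_correct)
    data.frame(
      n = sum(sel), chi2 = px$statistic, lr = lr_chi2(tab)$statistic, p = px$p
    )
  }
  subgroups <- rbind(
    cbind(stratum = "normal_flow", subgroup_chi2(df$flow == "normal")),
    cbind(stratum = "low_flow", subgroup_chi2(df$flow == "low")),
    cbind(stratum = "low_gradient", subgroup_chi2(df$gradient == "low"))
  )

  # Kaplan-Meier by RVL group, log-rank, 1-year survival
  grp <- ifelse(df$rvl_high_risk, "rvl_le_cutoff", "rvl_gt_cutoff")
  km <- km_fit(df$time_days, df$event, grp)
  lr_test <- logrank(df$time_days, df$event, grp)

  # univariable screen then adjusted Cox for the primary endpoint variables
  cand <- intersect(c("lvef_le40", "afib", "euroscore2"), names(df))
  screen <- if (length(cand)) {
    univariable_screen(df, cand, df$time_days, df$event)
  }
  cox_covs <- c(
    "rvl_high_risk",
    if (!is.null(screen)) screen$covariate[screen$selected]
  )
  dd <- df
  dd$rvl_high_risk <- as.integer(dd$rvl_high_risk)
  cox <- tryCatch(
    cox_adjusted(dd, df$time_days, df$event, cox_covs, ties = config$cox_ties),
    error = function(e) e
  )

  structure(
    list(
      endpoint = endpoint, n = nrow(df), n_events = sum(ev),
      auc = auc_tab, sens_spec = sens_spec_tab, youden_rvl = youden,
      subgroups = subgroups,
      km = km_coordinates(km),
      survival_1yr = survival_at(km, 365),
      logrank = lr_test,
      screen = screen, cox = cox,
      seed = config$seed
    ),
    class = "rvl_report"
  )
}

#' @export
print.rvl_report <- function(x, ...) {
  cat(sprintf(
    "Endpoint %s: %d patients, %d events\n", x$endpoint, x$n, x$n_events
  ))
  cat("\nAUC (%):\n")
  print(x$auc, digits = 4)
  cat("\nSensitivity/specificity at literature cutoffs:\n")
  print(x$sens_spec, digits = 4)
  cat(sprintf(
    "\nYouden-optimal RVL cutoff: %.3f (J = %.3f, sens %.1f%%, spec %.1f%%)\n",
    x$youden_rvl$cutoff, x$youden_rvl$j,
    100 * x$youden_rvl$sens, 100 * x$youden_rvl$spec
  ))
  if (!inherits(x$cox, "error")) {
    cat("\nAdjusted Cox model:\n")
    print(x$cox, digits = 3)
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits the machine-readable JSON report plus delimited tables (AUC,
#' sensitivity/specificity, KM coordinates) mirroring the published table
#' layouts.
#'
#' @param report an [evaluate_cohort()] report.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "rvl_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    json = file.path(dir, "report.json"),
    auc = file.path(dir, "auc.csv"),
    sens_spec = file.path(dir, "sens_spec.csv"),
    km = file.path(dir, "km_coordinates.csv")
  )
  utils::write.csv(report$auc, paths["auc"], row.names = FALSE)
  utils::write.csv(report$sens_spec, paths["sens_spec"], row.names = FALSE)
  utils::write.csv(report$km, paths["km"], row.names = FALSE)
  js <- report
  js$km <- NULL
  js$cox <- if (inherits(report$cox, "error")) {
    list(error = conditionMessage(report$cox))
  } else {
    report$cox
  }
  class(js) <- NULL
  jsonlite::write_json(js, paths["json"], auto_unbox = TRUE, digits = NA,
    force = TRUE, pretty = TRUE)
  invisible(paths)
}

# printed summary constants the consistency checker recomputes; a versioned
# fixture, compared cell by cell in reproduce_tables()
published_constants <- function() {
  list(
    low_gradient_2x2 = c(a = 26, b = 36, c = 3, d = 36), # deaths/survivors by RVL group
    chi2_low_gradient = 13.72,
    p_low_gradient = 0.0002,
    deaths = 53, n = 258, mortality_pct = 20.5,
    cv_deaths = 26, cv_pct = 49.1,
    lg_n = 101, lg_deaths = 29, lg_mortality_pct = 28.7,
    n_events = 53, n_nonevents = 205, rvl_group_size = 83,
    spec_pct = 75.1, sens_pct = 60.4,
    surv_high_rvl_pct = 88.0, surv_low_rvl_pct = 61.4,
    ar3_2x2 = c(a = 6, b = 169, c = 2, d = 81), fisher_ar3_p = 1.0000
  )
}

#' Recompute the published derivable summaries
#'
#' Recomputes every number in the published results that is derivable from
#' printed counts alone — the low-gradient chi-square, the rounded mortality
#' proportions, the 2x2 reconstruction from margins and rounded specificity
#' with its implied sensitivity and per-group 1-year survival, and the
#' Fisher exact p for paravalvular regurgitation by RVL group — and compares
#' each against the printed value.
#'
#' @param constants the printed-constant fixture (exposed so tampering can
#'   be demonstrated to fail loudly).
#' @return data.frame with `check`, `computed`, `printed`, `tol`, `pass`.
#' @export
reproduce_tables <- function(constants = published_constants()) {
  k <- constants
  rows <- list()
  add <- function(check, computed, printed, tol) {
    rows[[length(rows) + 1]] <<- data.frame(
      check = check, computed = computed, printed = printed, tol = tol,
      pass = is.finite(computed) & abs(computed - printed) <= tol
    )
  }
  m <- matrix(k$low_gradient_2x2, 2, byrow = TRUE)
  px <- pearson_chi2(m)
  add("chi2_low_gradient", px$statistic, k$chi2_low_gradient, 0.01)
  add("p_low_gradient", px$p, k$p_low_gradient, 5e-5)
  add("mortality_pct", pct(k$deaths, k$n), k$mortality_pct, 0)
  add("cv_death_pct", pct(k$cv_deaths, k$deaths), k$cv_pct, 0)
  add("lg_mortality_pct", pct(k$lg_deaths, k$lg_n), k$lg_mortality_pct, 0)
  rec <- tryCatch(
    reconstruct_2x2_from_summary(
      k$n_events, k$n_nonevents, k$rvl_group_size, k$spec_pct, "spec"
    ),
    error = function(e) NULL
  )
  if (is.null(rec)) {
    add("reconstructed_sens_pct", NA_real_, k$sens_pct, 0)
    add("surv_high_rvl_pct", NA_real_, k$surv_high_rvl_pct, 0)
    add("surv_low_rvl_pct", NA_real_, k$surv_low_rvl_pct, 0)
  } else {
    add("reconstructed_sens_pct", pct(rec$tp, k$n_events), k$sens_pct, 0)
    # no censoring before day 365: survival = 1 - deaths/n per RVL group
    n_pos <- rec$tp + rec$fp
    n_neg <- rec$fn + rec$tn
    add("surv_high_rvl_pct", pct(rec$tn, n_neg), k$surv_high_rvl_pct, 0)
    add("surv_low_rvl_pct", pct(rec$fp, n_pos), k$surv_low_rvl_pct, 0)
  }
  ar <- matrix(k$ar3_2x2, 2, byrow = TRUE)
  add("fisher_ar3_p", round_half_up(fisher_exact(ar), 4), k$fisher_ar3_p, 0)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
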