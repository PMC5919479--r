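#' Confusion table at a fixed cutoff
#'
#' Counts true/false positives and negatives for an index dichotomized at a
#' cutoff. Direction and strictness follow the literature cutoffs: e.g.
#' MG < 40 mmHg is strict, SVI <= 35 ml/m^2 inclusive, Zva >= 5 inclusive,
#' AVA > 0.75 cm^2 strict.
#'
#' @param scores index values.
#' @param events event indicator.
#' @param cutoff threshold on the index scale.
#' @param direction `"low_positive"` (value below/at cutoff predicts event)
#'   or `"high_positive"`.
#' @param strict when TRUE the inequality is strict (`<` or `>`); when FALSE
#'   it is inclusive (`<=` or `>=`).
#' @return object of class `confusion_table`: list with integer `tp`, `fp`,
#'   `fn`, `tn` and fractions `sens`, `spec`.
#' @export
confusion_at_cutoff <- function(scores, events, cutoff,
                                direction = c("low_positive", "high_positive"),
                                strict = FALSE) {
  direction <- match.arg(direction)
  keep <- !is.na(scores) & !is.na(events)
  scores <- scores[keep]
  events <- as.logical(events[keep])
  call <- switch(direction,
    low_positive = if (strict) scores < cutoff else scores <= cutoff,
    high_positive = if (strict) scores > cutoff else scores >= cutoff
  )
  confusion_table(
    tp = sum(call & events), fp = sum(call & !events),
    fn = sum(!call & events), tn = sum(!call & !events)
  )
}

#' Construct a confusion table from counts
#'
#' @param tp,fp,fn,tn non-negative integer cell counts.
#' @return `confusion_table` object with sensitivity and specificity.
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop_invalid("confusion cells must be non-negative integers")
  }
  structure(
    list(
      tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tn = as.integer(tn),
      sens = tp / (tp + fn), spec = tn / (tn + fp)
    ),
    class = "confusion_table"
  )
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf(
    "2x2: tp %d fp %d / fn %d tn %d  (sens %.1f%%, spec %.1f%%)\n",
    x$tp, x$fp, x$fn, x$tn, 100 * x$sens, 100 * x$spec
  ))
  invisible(x)
}

as_matrix_2x2 <- function(x) {
  if (inherits(x, "confusion_table")) {
    matrix(c(x$tp, x$fn, x$fp, x$tn), 2,
      dimnames = list(c("event", "no_event"), c("positive", "negative"))
    )
  } else {
    m <- as.matrix(x)
    if (!all(dim(m) == c(2, 2))) stop_invalid("expected a 2x2 table")
    m
  }
}

#' Reconstruct a 2x2 table from a rounded published summary
#'
#' Published reports often give only margins, a positive-call group size and
#' a rounded sensitivity or specificity. This searches every integer table
#' consistent with the margins and returns the unique one whose recomputed
#' percentage rounds (half-up, [round_half_up()]) to the reported value.
#'
#' @param n_events,n_nonevents outcome margins.
#' @param group_size number of positive calls (tp + fp).
#' @param reported_pct the published percentage.
#' @param which whether `reported_pct` is `"sens"` or `"spec"`.
#' @param decimals decimals the report was rounded to (default 1).
#' @return a [confusion_table()].
#' @export
reconstruct_2x2_from_summary <- function(n_events, n_nonevents, group_size,
                                         reported_pct,
                                         which = c("spec", "sens"),
                                         decimals = 1) {
  which <- match.arg(which)
  if (group_size > n_events + n_nonevents) {
    stop(errorCondition("group_size exceeds total n",
      class = c("rvload_inconsistency", "error")
    ))
  }
  tp <- max(0, group_size - n_nonevents):min(group_size, n_events)
  fp <- group_size - tp
  fn <- n_events - tp
  tn <- n_nonevents - fp
  pct_val <- if (which == "sens") 100 * tp / n_events else 100 * tn / n_nonevents
  ok <- round_half_up(pct_val, decimals) == reported_pct
  if (!any(ok)) {
    stop(errorCondition(
      sprintf(
        "no integer 2x2 with margins %d/%d, group %d reproduces %s = %s%%",
        n_events, n_nonevents, group_size, which, format(reported_pct)
      ),
      class = c("rvload_inconsistency", "error")
    ))
  }
  if (sum(ok) > 1) {
    cand <- data.frame(tp = tp[ok], fp = fp[ok], fn = fn[ok], tn = tn[ok])
    stop(errorCondition(
      paste0(
        "ambiguous reconstruction; candidates:\n",
        paste(utils::capture.output(print(cand)), collapse = "\n")
      ),
      candidates = cand,
      class = c("rvload_ambiguity", "error")
    ))
  }
  confusion_table(tp = tp[ok], fp = fp[ok], fn = fn[ok], tn = tn[ok])
}
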