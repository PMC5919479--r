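#' Receiver operating characteristic curve
#'
#' Builds an ROC curve for an index against a binary outcome. Candidate
#' thresholds are the midpoints between consecutive sorted unique index
#' values, plus -Inf and +Inf sentinels (no calls / all calls), so every
#' distinct classification of the sample appears exactly once and ties
#' are handled in grouped fashion. `direction = "low_positive"` means a
#' value at or below the threshold predicts the event (the RVL convention);
#' `"high_positive"` means at or above. The AUC is the trapezoidal area of
#' the curve, which equals the tie-corrected Mann-Whitney concordance
#' probability.
#'
#' @param scores numeric index values.
#' @param events event indicator (logical or 0/1).
#' @param direction `"low_positive"` or `"high_positive"`.
#' @return object of class `rvl_roc`: list with `thresholds`, `sens`,
#'   `spec`, `direction`, `auc`, `n_event`, `n_nonevent`.
#' @export
roc_curve <- function(scores, events,
                      direction = c("low_positive", "high_positive")) {
  direction <- match.arg(direction)
  keep <- !is.na(scores) & !is.na(events)
  scores <- scores[keep]
  events <- as.logical(events[keep])
  n_pos <- sum(events)
  n_neg <- sum(!events)
  if (n_pos < 1 || n_neg < 1) {
    stop_invalid("need at least one event and one non-event")
  }

  u <- sort(unique(scores))
  mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  # events/non-events carried per unique value, cumulated from the
  # positive-calling end of the scale
  ev_at <- vapply(u, function(v) sum(events & scores == v), numeric(1))
  nv_at <- vapply(u, function(v) sum(!events & scores == v), numeric(1))
  if (direction == "low_positive") {
    thresholds <- c(-Inf, mids, Inf)
    tp <- c(0, cumsum(ev_at)) # calls: score <= threshold
    fp <- c(0, cumsum(nv_at))
  } else {
    thresholds <- c(Inf, rev(mids), -Inf)
    tp <- c(0, cumsum(rev(ev_at))) # calls: score >= threshold
    fp <- c(0, cumsum(rev(nv_at)))
  }
  sens <- tp / n_pos
  fpr <- fp / n_neg
  auc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  structure(
    list(
      thresholds = thresholds, sens = sens, spec = 1 - fpr,
      direction = direction, auc = auc,
      n_event = n_pos, n_nonevent = n_neg
    ),
    class = "rvl_roc"
  )
}

#' @export
print.rvl_roc <- function(x, ...) {
  cat(sprintf(
    "ROC curve (%s): AUC = %.4f, %d events / %d non-events, %d thresholds\n",
    x$direction, x$auc, x$n_event, x$n_nonevent, length(x$thresholds)
  ))
  invisible(x)
}

#' Youden-index optimal cutoff
#'
#' Selects the threshold maximising J = sensitivity + specificity - 1.
#' Ties in J are broken toward higher specificity, then toward the lower
#' cutoff, so the result is deterministic.
#'
#' @param roc an [roc_curve()] object.
#' @return list with `cutoff`, `j`, `sens`, `spec`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "rvl_roc"))
  j <- roc$sens + roc$spec - 1
  best <- which(j > max(j) - 1e-12)
  if (length(best) > 1) {
    best <- best[order(-roc$spec[best], roc$thresholds[best])][1]
  }
  list(
    cutoff = roc$thresholds[best], j = j[best],
    sens = roc$sens[best], spec = roc$spec[best]
  )
}

# orient scores so that larger means "predicts event"
orient_scores <- function(scores, direction) {
  if (direction == "low_positive") -scores else scores
}

# midrank-based placement values (fast DeLong components).
# Returns list(v10, v01, auc): v10 over events, v01 over non-events.
placements <- function(scores, events) {
  x <- scores[events]
  y <- scores[!events]
  m <- length(x)
  n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_x) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two paired AUCs
#'
#' Compares the areas under two ROC curves computed from paired scores on
#' the same subjects, using DeLong's placement-value variance estimate and a
#' two-sided normal reference. Each score may have its own orientation.
#'
#' @param scores_a,scores_b paired index values.
#' @param events event indicator.
#' @param direction_a,direction_b orientation of each score
#'   (`"low_positive"` or `"high_positive"`).
#' @return list with `auc_a`, `auc_b`, `delta`, `z`, `p`.
#' @export
delong_auc_test <- function(scores_a, scores_b, events,
                            direction_a = "low_positive",
                            direction_b = "low_positive") {
  keep <- !is.na(scores_a) & !is.na(scores_b) & !is.na(events)
  events <- as.logical(events[keep])
  if (sum(events) < 2 || sum(!events) < 2) {
    stop_invalid("need at least two events and two non-events")
  }
  sa <- orient_scores(scores_a[keep], direction_a)
  sb <- orient_scores(scores_b[keep], direction_b)
  pa <- placements(sa, events)
  pb <- placements(sb, events)
  m <- sum(events)
  n <- sum(!events)
  s10 <- stats::var(pa$v10 - pb$v10)
  s01 <- stats::var(pa$v01 - pb$v01)
  v <- s10 / m + s01 / n
  delta <- pa$auc - pb$auc
  if (v <= .Machine$double.eps) {
    if (abs(delta) < 1e-12) {
      return(list(auc_a = pa$auc, auc_b = pb$auc, delta = 0, z = 0, p = 1))
    }
    stop_invalid("degenerate DeLong variance with unequal AUCs")
  }
  z <- delta / sqrt(v)
  list(
    auc_a = pa$auc, auc_b = pb$auc, delta = delta, z = z,
    p = 2 * stats::pnorm(-abs(z))
  )
}
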