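# 2x2 contingency tests. Pearson and likelihood-ratio chi-squares are
# evaluated from their closed forms (the package's consistency checks anchor
# on the uncorrected Pearson statistic); the Fisher exact p comes from
# stats::fisher.test.

#' Pearson chi-square for a 2x2 table
#'
#' Uncorrected by default: X^2 = n (ad - bc)^2 / (r1 r2 c1 c2), df = 1.
#' The Yates continuity correction is available behind a flag.
#'
#' @param table a [confusion_table()] or 2x2 matrix-like of counts.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return list with `statistic` and two-sided `p`.
#' @export
pearson_chi2 <- function(table, correct = FALSE) {
  m <- as_matrix_2x2(table)
  r <- rowSums(m)
  cs <- colSums(m)
  if (any(r == 0) || any(cs == 0)) {
    stop_invalid("chi-square undefined with a zero margin")
  }
  n <- sum(m)
  dev <- abs(m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])
  if (correct) dev <- max(0, dev - n / 2)
  stat <- n * dev^2 / prod(r, cs)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Likelihood-ratio (G^2) chi-square for a 2x2 table
#'
#' G^2 = 2 sum O log(O/E) with df = 1; empty cells contribute zero
#' (0 log 0 := 0).
#'
#' @inheritParams pearson_chi2
#' @return list with `statistic` and `p`.
#' @export
lr_chi2 <- function(table) {
  m <- as_matrix_2x2(table)
  r <- rowSums(m)
  cs <- colSums(m)
  if (any(r == 0) || any(cs == 0)) {
    stop_invalid("likelihood-ratio chi-square undefined with a zero margin")
  }
  e <- outer(r, cs) / sum(m)
  terms <- ifelse(m == 0, 0, m * log(m / e))
  stat <- 2 * sum(terms)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Fisher exact test for a 2x2 table
#'
#' Two-sided p-value: the sum over all tables with the observed margins whose
#' hypergeometric probability does not exceed the observed table's.
#'
#' @inheritParams pearson_chi2
#' @return two-sided p-value.
#' @export
fisher_exact <- function(table) {
  m <- as_matrix_2x2(table)
  stats::fisher.test(m)$p.value
}

#' Exact McNemar test for paired binary classifiers
#'
#' Compares two classification rules applied to the same subjects (e.g. the
#' sensitivity of two indices, restricted to the patients who died) via the
#' exact binomial test on discordant pairs. With b and c discordant pairs,
#' p = min(1, 2 P(Bin(b + c, 1/2) <= min(b, c))); the mid-p variant halves
#' the probability of the observed discordant count.
#'
#' @param calls_a,calls_b logical positive-call vectors on the same subjects.
#' @param events optional event indicator; with `restrict`, limits the
#'   comparison to events (sensitivity comparison) or non-events
#'   (specificity comparison).
#' @param restrict `"all"`, `"events"` or `"nonevents"`.
#' @param mid_p use the mid-p variant (default FALSE).
#' @return two-sided p-value (1.0 when there are no discordant pairs).
#' @export
mcnemar_paired <- function(calls_a, calls_b, events = NULL,
                           restrict = c("all", "events", "nonevents"),
                           mid_p = FALSE) {
  restrict <- match.arg(restrict)
  calls_a <- as.logical(calls_a)
  calls_b <- as.logical(calls_b)
  if (length(calls_a) != length(calls_b)) {
    stop_invalid("paired call vectors must have equal length")
  }
  if (restrict != "all") {
    if (is.null(events)) stop_invalid("restrict requires an events vector")
    keep <- if (restrict == "events") as.logical(events) else !as.logical(events)
    calls_a <- calls_a[keep]
    calls_b <- calls_b[keep]
  }
  b <- sum(calls_a & !calls_b)
  cc <- sum(!calls_a & calls_b)
  nd <- b + cc
  if (nd == 0) {
    return(1.0)
  }
  k <- min(b, cc)
  p <- 2 * stats::pbinom(k, nd, 0.5)
  if (mid_p) p <- p - stats::dbinom(k, nd, 0.5)
  min(1, p)
}
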