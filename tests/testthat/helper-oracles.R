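# Independent oracles used across the suite. These stay deliberately naive
# (brute force / enumeration) so they never share code with the paths they
# check.

# O(n^2) pairwise concordance AUC on oriented scores (higher = event-like)
auc_concordance_oracle <- function(scores, events, direction) {
  s <- if (direction == "low_positive") -scores else scores
  x <- s[as.logical(events)]
  y <- s[!as.logical(events)]
  mean(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# exhaustive Youden scan over every midpoint threshold plus sentinels
youden_scan_oracle <- function(scores, events, direction) {
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  ev <- as.logical(events)
  best <- NULL
  for (t in cand) {
    call <- if (direction == "low_positive") scores <= t else scores >= t
    sens <- sum(call & ev) / sum(ev)
    spec <- sum(!call & !ev) / sum(!ev)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
      (abs(j - best$j) <= 1e-12 && (spec > best$spec + 1e-12 ||
        (abs(spec - best$spec) <= 1e-12 && t < best$cutoff)))) {
      best <- list(cutoff = t, j = j, sens = sens, spec = spec)
    }
  }
  best
}

# two-sided Fisher exact p by full enumeration over the hypergeometric
# support of tables with the observed margins
fisher_enumeration_oracle <- function(m) {
  r1 <- sum(m[1, ])
  c1 <- sum(m[, 1])
  n <- sum(m)
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(support, r1, n - r1, c1)
  p_obs <- stats::dhyper(m[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# naive DeLong components via the full psi kernel matrix
delong_naive_oracle <- function(sa, sb, events) {
  psi <- function(x, y) outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  comp <- function(s) {
    x <- s[events]
    y <- s[!events]
    k <- psi(x, y)
    list(v10 = rowMeans(k), v01 = colMeans(k), auc = mean(k))
  }
  a <- comp(sa)
  b <- comp(sb)
  v <- stats::var(a$v10 - b$v10) / length(a$v10) +
    stats::var(a$v01 - b$v01) / length(a$v01)
  z <- (a$auc - b$auc) / sqrt(v)
  list(auc_a = a$auc, auc_b = b$auc, p = 2 * stats::pnorm(-abs(z)))
}

# a tiny valid exam for derive_all tests
baseline_exam <- function(...) {
  utils::modifyList(
    list(
      lvot_diameter = 2.0, vti_lvot = 20, vti_av = 100,
      mg_measured = 40, sbp = 120, bsa = 2.0
    ),
    list(...)
  )
}
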