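test_that("cohort spec validates its parameters", {
  expect_s3_class(cohort_spec(), "cohort_spec")
  expect_error(cohort_spec(n = 0), class = "rvload_invalid_input")
  expect_error(
    cohort_spec(hazard = list(target_mortality = 1.2)),
    class = "rvload_invalid_input"
  )
  expect_error(
    cohort_spec(hazard = list(hr_rvl = -1)),
    class = "rvload_invalid_input"
  )
  expect_error(
    cohort_spec(rank_corr = c(mg_svi = 0.99, mg_sbp = 0.99, sbp_svi = -0.99)),
    class = "rvload_invalid_input"
  )
})

test_that("fixed seed gives identical cohorts", {
  a <- simulate_cohort(cohort_spec(seed = 123))
  b <- simulate_cohort(cohort_spec(seed = 123))
  attr(a, "spec") <- attr(b, "spec") <- NULL
  expect_identical(a, b)
  c2 <- simulate_cohort(cohort_spec(seed = 124))
  expect_false(identical(a$mg, c2$mg))
})

test_that("marginals reproduce the generating targets within 3 MC SE", {
  spec <- cohort_spec(n = 10000, seed = 9)
  set.seed(spec$seed)
  lat <- draw_hemodynamics(spec)
  n <- nrow(lat)
  targets <- list(
    mg = c(44.8, 14.9), sbp = c(134.6, 28.5), svi = c(40.2, 12.4),
    ava = c(0.69, 0.17), age = c(84.4, 6.5)
  )
  for (v in names(targets)) {
    expect_lt(
      abs(mean(lat[[v]]) - targets[[v]][1]),
      3 * targets[[v]][2] / sqrt(n)
    )
  }
  # copula reproduces the requested rank correlations approximately
  expect_equal(cor(lat$mg, lat$svi, method = "spearman"), 0.3,
    tolerance = 0.15
  )
  expect_equal(cor(lat$mg, lat$sbp, method = "spearman"), -0.1,
    tolerance = 0.35
  )
  # RVL follows the algebraic identity exactly
  expect_equal(lat$rvl, lat$mg * lat$svi / (lat$sbp + lat$mg),
    tolerance = 1e-12
  )
})

test_that("EuroSCORE II lognormal recovers its fitted quantiles", {
  spec <- cohort_spec(n = 100000, seed = 10)
  set.seed(spec$seed)
  lat <- draw_hemodynamics(spec)
  # fitted lognormal: least squares on log quantiles of median 5.4, IQR 3.2-9.9
  z <- qnorm(0.75)
  lq <- log(c(3.2, 5.4, 9.9))
  meanlog <- mean(lq)
  sdlog <- (lq[3] - lq[1]) / (2 * z)
  q <- quantile(lat$euroscore2, c(0.25, 0.5, 0.75))
  expect_equal(unname(q), qlnorm(c(0.25, 0.5, 0.75), meanlog, sdlog),
    tolerance = 0.02
  )
  # and those fitted quantiles sit close to the published summary
  expect_equal(unname(q[2]), 5.4, tolerance = 0.05)
})

test_that("RVL-linked covariate prevalences reproduce the group contrasts", {
  spec <- cohort_spec(n = 50000, seed = 11)
  set.seed(spec$seed)
  lat <- draw_hemodynamics(spec)
  hi <- lat$rvl_high_risk
  expect_equal(mean(lat$afib[hi]), 0.578, tolerance = 0.03)
  expect_equal(mean(lat$afib[!hi]), 0.309, tolerance = 0.03)
  expect_equal(mean(lat$lvef_le40[hi]), 0.398, tolerance = 0.03)
  expect_equal(mean(lat$lvef_le40[!hi]), 0.137, tolerance = 0.03)
  # continuous LVEF is consistent with its flag
  expect_true(all(lat$lvef[lat$lvef_le40] <= 40))
  expect_true(all(lat$lvef[!lat$lvef_le40] > 40))
})

test_that("zero-variance marginals collapse to identical patients", {
  marg <- list(
    mg = c(mean = 40, sd = 0, floor = 5),
    sbp = c(mean = 130, sd = 0, floor = 60),
    svi = c(mean = 38, sd = 0, floor = 10)
  )
  spec <- cohort_spec(n = 50, seed = 5, marginals = marg)
  set.seed(5)
  lat <- draw_hemodynamics(spec)
  expect_equal(length(unique(lat$mg)), 1)
  expect_equal(length(unique(lat$svi)), 1)
  expect_equal(length(unique(lat$rvl)), 1)
})

test_that("back-filled primitives round-trip through derive_all", {
  spec <- cohort_spec(n = 200, seed = 21)
  co <- simulate_cohort(spec)
  d <- derive_cohort(co)
  expect_true(all(is.na(d$derive_error)))
  rel <- function(a, b) max(abs(a - b) / abs(b))
  expect_lt(rel(d$mg_mmhg, co$mg), 1e-6)
  expect_lt(rel(d$svi_ml_m2, co$svi), 1e-6)
  expect_lt(rel(d$ava_cm2, co$ava), 1e-6)
  expect_lt(rel(d$sbp_mmhg, co$sbp), 1e-6)
  expect_lt(rel(d$rvl_ml_m2, co$rvl), 1e-6)
  # an AVA of 0.69 at BSA 1.9 is indexed below 0.6, i.e. severe
  expect_true(all(d$severe_as[co$ava < 0.9]))
  # LVOT geometry stayed inside its truncation band and above the valve area
  expect_true(all(co$lvot_diameter_cm >= 1.7 & co$lvot_diameter_cm <= 2.6))
  expect_true(all(d$csa_lvot_cm2 > co$ava))
})

test_that("infeasible latent valve areas trigger the diameter resample path", {
  spec <- cohort_spec(n = 30, seed = 3)
  set.seed(3)
  lat <- draw_hemodynamics(spec)
  lat$ava <- 4.0 # near the ceiling of any feasible LVOT area
  set.seed(4)
  prim <- backfill_primitives(lat, spec)
  csa <- pi * (prim$lvot_diameter_cm / 2)^2
  expect_true(all(csa > 4.0))
  # a truly unreachable area fails loudly
  lat$ava <- 10
  expect_error(
    backfill_primitives(lat, spec, max_resample = 50),
    class = "rvload_invalid_input"
  )
})

test_that("outcome model calibrates mortality and honours its hazard ratios", {
  spec <- cohort_spec(n = 40000, seed = 31)
  set.seed(31)
  lat <- draw_hemodynamics(spec)
  out <- draw_outcomes(lat, spec)
  expect_equal(mean(out$event), 0.205, tolerance = 0.03)
  expect_true(all(out$time_days > 0 & out$time_days <= 365))
  expect_true(all(out$time_days[out$event == 0] == 365))
  expect_true(all(is.na(out$cause[out$event == 0])))
  cv <- mean(out$cause[out$event == 1] == "cardiovascular")
  expect_equal(cv, 0.491, tolerance = 0.03)

  # all hazard ratios at 1: group mortalities equalise
  flat <- cohort_spec(
    n = 40000, seed = 32,
    hazard = list(hr_rvl = 1, hr_lvef = 1, hr_af = 1, hr_euroscore = 1)
  )
  set.seed(32)
  lat2 <- draw_hemodynamics(flat)
  out2 <- draw_outcomes(lat2, flat)
  gap0 <- abs(
    mean(out2$event[lat2$rvl_high_risk]) - mean(out2$event[!lat2$rvl_high_risk])
  )
  expect_lt(gap0, 0.015)

  # increasing the RVL hazard ratio widens the mortality gap monotonically
  gaps <- vapply(c(1, 2, 4), function(hr) {
    s <- cohort_spec(n = 30000, seed = 33, hazard = list(hr_rvl = hr))
    set.seed(33)
    l <- draw_hemodynamics(s)
    o <- draw_outcomes(l, s)
    mean(o$event[l$rvl_high_risk]) - mean(o$event[!l$rvl_high_risk])
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("a lone RVL effect is recovered by a univariable Cox fit", {
  spec <- cohort_spec(
    n = 5000, seed = 55,
    hazard = list(hr_lvef = 1, hr_af = 1, hr_euroscore = 1)
  )
  co <- simulate_cohort(spec)
  co$rvl_flag <- as.integer(co$rvl_high_risk)
  fit <- cox_adjusted(co, co$time_days, co$event, "rvl_flag")
  expect_true(fit$ci_lo <= 3.2 && 3.2 <= fit$ci_hi)
  expect_equal(log(fit$hr), log(3.2), tolerance = 0.15)
})

test_that("eligibility fixture reproduces the screening counts under any order", {
  for (s in c(1, 9)) {
    stream <- make_fig1_stream(seed = s)
    expect_equal(nrow(stream), 303)
    res <- apply_inclusion_criteria(stream)
    expect_equal(nrow(res$included), 258)
    expect_equal(
      res$tally,
      c(
        incomplete_echo = 21L, ar_ge3 = 10L, valve_in_valve = 3L,
        intraprocedural_death = 3L, converted_to_savr = 8L,
        not_severe_as = 0L
      )
    )
  }
})
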