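test_that("Kaplan-Meier matches closed forms without censoring", {
  # 175 patients, 21 deaths before day 365, censoring only at day 365:
  # S(365) = 1 - 21/175 = 0.88
  time <- c(seq(30, 330, length.out = 21), rep(365, 154))
  event <- c(rep(1, 21), rep(0, 154))
  km <- km_fit(time, event)
  expect_equal(unname(survival_at(km, 365)), 1 - 21 / 175)

  # no events: survival is identically 1
  km0 <- km_fit(rep(365, 20), rep(0, 20))
  expect_equal(unname(survival_at(km0, 365)), 1)

  # all events at distinct times: product-limit equals the empirical
  # survival function
  set.seed(2)
  tt <- sort(sample(1:1000, 40))
  km1 <- km_fit(tt, rep(1, 40))
  emp <- 1 - ecdf(tt)(tt)
  co <- km_coordinates(km1)
  expect_equal(co$survival, emp, tolerance = 1e-12)
  expect_true(all(diff(co$survival) <= 0))
  expect_equal(co$survival[1], 1 - 1 / 40)
})

test_that("log-rank behaves at the null and detects a strong hazard ratio", {
  time <- c(1:20, 1:20)
  event <- rep(1, 40)
  group <- rep(c("a", "b"), each = 20)
  null_res <- logrank(time, event, group)
  expect_lt(null_res$statistic, 1e-10)
  expect_equal(null_res$p, 1, tolerance = 1e-6)

  # single event time with equal risk sets: O - E = 1 - 1/2, V = 1/4,
  # statistic = (1/2)^2 / (1/4) = 1
  one <- logrank(c(5, 10), c(1, 0), c("a", "b"))
  expect_equal(one$statistic, 1, tolerance = 1e-9)

  set.seed(12)
  n <- 500
  g <- rep(0:1, each = n / 2)
  t_raw <- rexp(n, rate = 0.002 * 3^g)
  ev <- as.integer(t_raw <= 365)
  res <- logrank(pmin(t_raw, 365), ev, g)
  expect_lt(res$p, 0.001)
})

test_that("univariable screen selects real effects and respects its level", {
  set.seed(33)
  n <- 400
  x_true <- rbinom(n, 1, 0.4)
  t_raw <- rexp(n, rate = 0.001 * exp(1.2 * x_true))
  time <- pmin(t_raw, 365)
  event <- as.integer(t_raw <= 365)
  d <- data.frame(x_true = x_true, x_noise = rnorm(n))
  res <- univariable_screen(d, c("x_true", "x_noise"), time, event)
  expect_true(res$selected[res$covariate == "x_true"])
  # screen p-value matches a direct Cox fit
  direct <- summary(
    survival::coxph(survival::Surv(time, event) ~ x_true)
  )$coefficients[1, 5]
  expect_equal(res$p[res$covariate == "x_true"], direct, tolerance = 1e-12)

  # under the null the screen keeps a covariate ~10% of the time
  reps <- 400
  kept <- logical(reps)
  for (i in seq_len(reps)) {
    dd <- data.frame(z = rnorm(n))
    kept[i] <- univariable_screen(dd, "z", time, event)$selected
  }
  expect_gte(mean(kept), 0.055)
  expect_lte(mean(kept), 0.145)
})

test_that("adjusted Cox recovers parameters, covers the null, rejects degeneracy", {
  set.seed(44)
  n <- 4000
  x <- rbinom(n, 1, 0.5)
  t_raw <- rexp(n, rate = 0.0008 * exp(log(2.5) * x))
  time <- pmin(t_raw, 365)
  event <- as.integer(t_raw <= 365)
  d <- data.frame(x = x)
  fit <- cox_adjusted(d, time, event, "x")
  expect_equal(log(fit$hr), log(2.5), tolerance = 0.15)
  expect_true(fit$ci_lo <= 2.5 && 2.5 <= fit$ci_hi)
  expect_true(fit$ci_lo <= fit$hr && fit$hr <= fit$ci_hi)

  # permuted covariate: the CI covers HR = 1 at close to nominal rate
  set.seed(45)
  covered <- logical(1500)
  nn <- 300
  for (i in seq_len(1500)) {
    xx <- rbinom(nn, 1, 0.5)
    tr <- rexp(nn, rate = 0.002)
    tm <- pmin(tr, 365)
    evn <- as.integer(tr <= 365)
    f <- cox_adjusted(data.frame(x = sample(xx)), tm, evn, "x")
    covered[i] <- f$ci_lo <= 1 && 1 <= f$ci_hi
  }
  expect_gte(mean(covered), 0.94)

  expect_error(
    cox_adjusted(data.frame(x = rep(1, 50)), rexp(50, 0.01), rep(1, 50), "x"),
    "zero-variance"
  )
  set.seed(46)
  few <- data.frame(x = rbinom(80, 1, 0.5), y = rnorm(80), z = rnorm(80))
  expect_warning(
    cox_adjusted(
      few, c(sort(runif(10, 10, 300)), rep(365, 70)),
      c(rep(1, 10), rep(0, 70)), c("x", "y", "z")
    ),
    "covariate"
  )
})
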