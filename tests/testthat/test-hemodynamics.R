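test_that("single-index formulas reproduce hand-computed values", {
  expect_equal(csa_lvot(2.0), pi)
  expect_equal(csa_lvot(2.2), 3.8013, tolerance = 1e-4)
  expect_error(csa_lvot(0), class = "rvload_invalid_input")

  expect_equal(stroke_volume(20, 3.5), 70)
  expect_equal(stroke_volume(1, 1), 1)
  expect_equal(stroke_volume(22, csa_lvot(2.2)), 83.63, tolerance = 1e-4)
  expect_error(stroke_volume(-1, 3), class = "rvload_invalid_input")

  expect_equal(stroke_volume_index(70, 2.0), 35)
  expect_equal(stroke_volume_index(70, 1.0), 70)
  expect_error(stroke_volume_index(0, 2), class = "rvload_invalid_input")

  expect_equal(peak_gradient(4.0, 1.0), 60)
  expect_equal(peak_gradient(2.5, 2.5), 0)
  expect_equal(peak_gradient(5.0, 0), 100)
  expect_error(peak_gradient(1.0, 2.0), class = "rvload_invalid_input")

  expect_equal(aortic_valve_area(20, 3.5, 100), 0.70)
  expect_equal(aortic_valve_area(20, 3.5, 20), 3.5) # no-stenosis limit
  expect_equal(aortic_valve_area(22, csa_lvot(2.2), 110), 0.760,
    tolerance = 1e-3
  )
  expect_warning(aortic_valve_area(20, 3.5, 15), "implausible")
  expect_error(aortic_valve_area(20, 3.5, 0), class = "rvload_invalid_input")

  expect_equal(stroke_work_loss_pct(40, 120), 25.0)
  expect_equal(stroke_work_loss_pct(100, 100), 50)
  expect_error(stroke_work_loss_pct(0, 120), class = "rvload_invalid_input")

  expect_equal(valvuloarterial_impedance(40, 120, 40), 4.0)
  expect_equal(valvuloarterial_impedance(45, 135, 36), 5.0)
  expect_error(valvuloarterial_impedance(40, 120, 0),
    class = "rvload_invalid_input"
  )

  expect_equal(relative_valve_load(40, 4.0), 10.0)
  expect_error(relative_valve_load(40, 0), class = "rvload_invalid_input")
})

test_that("mean gradient time-averages the instantaneous Bernoulli gradient", {
  # constant 3 m/s: 4 * 9 = 36 mmHg regardless of grid
  tt <- seq(0, 0.31, length.out = 7)
  expect_equal(mean_gradient(tt, rep(3, 7)), 36)
  # half-sine v(t) = 4 sin(pi t): mean of sin^2 is 1/2, so 4*16/2 = 32
  tt <- seq(0, 1, length.out = 5001)
  expect_equal(mean_gradient(tt, 4 * sin(pi * tt)), 32, tolerance = 1e-5)
  # LVOT correction cancels an identical proximal trace
  v <- 2 + sin(pi * tt)
  expect_equal(mean_gradient(tt, v, v, correct_for_lvot = TRUE), 0)
  # mean never exceeds the peak instantaneous gradient
  set.seed(1)
  for (k in 1:20) {
    v <- abs(rnorm(25, 3, 1))
    tt <- sort(runif(25))
    expect_lte(mean_gradient(tt, v), max(4 * v^2))
  }
  expect_error(mean_gradient(c(0, 1), c(1, 2)), class = "rvload_invalid_input")
  expect_error(
    mean_gradient(c(0, 0.5, 0.5), c(1, 2, 1)),
    class = "rvload_invalid_input"
  )
})

test_that("derive_all composes the chain and enforces a gradient source", {
  res <- derive_all(baseline_exam())
  expect_equal(res$csa_lvot, 3.1416, tolerance = 1e-4)
  expect_equal(res$sv, 62.83, tolerance = 1e-3)
  expect_equal(res$svi, 31.42, tolerance = 1e-3)
  expect_equal(res$ava, 0.628, tolerance = 1e-3)
  expect_equal(res$swl_pct, 25.0)
  expect_equal(res$zva, 5.092, tolerance = 1e-3)
  expect_equal(res$rvl, 7.855, tolerance = 1e-3)
  # this canonical exam sits on the high-risk side of the 7.95 cutoff
  expect_true(res$rvl <= 7.95)

  same <- derive_all(baseline_exam(vti_av = 20))
  expect_equal(same$ava, same$csa_lvot)

  err <- tryCatch(
    derive_all(baseline_exam(mg_measured = NA)),
    error = function(e) e
  )
  expect_s3_class(err, "rvload_missing_data")
  expect_true(all(c("mg_measured", "trace") %in% err$fields))

  # measured MG wins over the trace; the trace value is kept for QC
  tr <- list(times = seq(0, 1, 0.01), v_av = rep(3, 101))
  both <- derive_all(baseline_exam(), trace = tr)
  expect_equal(both$mg, 40)
  expect_equal(both$mg_trace, 36)
  tronly <- derive_all(baseline_exam(mg_measured = NULL), trace = tr)
  expect_equal(tronly$mg, 36)
})

test_that("RVL identities, bounds and monotonicity hold across random inputs", {
  set.seed(42)
  n <- 500
  mg <- runif(n, 10, 90)
  sbp <- runif(n, 80, 200)
  svi <- runif(n, 15, 70)
  zva <- valvuloarterial_impedance(mg, sbp, svi)
  rvl <- relative_valve_load(mg, zva)
  # algebraic identity RVL = MG.SVI/(SBP+MG) = (SWL/100).SVI
  expect_equal(rvl, mg * svi / (sbp + mg), tolerance = 1e-9)
  expect_equal(rvl, stroke_work_loss_pct(mg, sbp) / 100 * svi,
    tolerance = 1e-9
  )
  expect_true(all(rvl < svi))
  # rvl -> svi as arterial pressure vanishes
  expect_equal(
    relative_valve_load(50, valvuloarterial_impedance(50, 1e-9, 40)), 40,
    tolerance = 1e-9
  )
  # strict monotonicity in mg and svi; zva decreasing in svi
  mg_grid <- seq(10, 80, by = 5)
  r1 <- mg_grid * 40 / (130 + mg_grid)
  expect_true(all(diff(r1) > 0))
  svi_grid <- seq(15, 60, by = 5)
  expect_true(all(diff(50 * svi_grid / (130 + 50)) > 0))
  expect_true(all(diff(valvuloarterial_impedance(50, 130, svi_grid)) < 0))
})

test_that("beat averaging collapses rows and checks rhythm conventions", {
  beats <- data.frame(
    patient_id = rep(c("a", "b"), c(3, 5)),
    rhythm = rep(c("sinus", "afib"), c(3, 5)),
    vti_lvot = c(19, 20, 21, 14, 15, 16, 15, 15)
  )
  avg <- average_beats(beats)
  expect_equal(nrow(avg), 2)
  expect_equal(avg$vti_lvot[avg$patient_id == "a"], 20)
  expect_equal(avg$vti_lvot[avg$patient_id == "b"], 15)
  short <- beats[c(1, 4:8), ]
  expect_warning(average_beats(short), "beats averaged")
})
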