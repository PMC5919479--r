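#' Left ventricular outflow tract cross-sectional area
#'
#' Computes the LVOT cross-sectional area from its diameter under the
#' standard circular assumption, CSA = pi (d/2)^2.
#'
#' @param lvot_diameter LVOT diameter in cm (mid-systole, inner edge to
#'   inner edge).
#' @return cross-sectional area in cm^2.
#' @export
csa_lvot <- function(lvot_diameter) {
  check_positive(lvot_diameter, "lvot_diameter")
  pi * (lvot_diameter / 2)^2
}

#' Doppler stroke volume
#'
#' SV = VTI_LVOT x CSA_LVOT. Units: cm x cm^2 = cm^3 = ml.
#'
#' @param vti_lvot LVOT velocity-time integral, cm.
#' @param csa LVOT cross-sectional area, cm^2.
#' @return stroke volume in ml.
#' @export
stroke_volume <- function(vti_lvot, csa) {
  check_positive(vti_lvot, "vti_lvot")
  check_positive(csa, "csa")
  vti_lvot * csa
}

#' Stroke volume index
#'
#' Stroke volume indexed to body surface area. SVI <= 35 ml/m^2 defines the
#' low-flow state.
#'
#' @param sv stroke volume, ml.
#' @param bsa body surface area, m^2.
#' @return stroke volume index, ml/m^2.
#' @export
stroke_volume_index <- function(sv, bsa) {
  check_positive(sv, "sv")
  check_positive(bsa, "bsa")
  sv / bsa
}

#' Peak transvalvular pressure gradient
#'
#' Modified Bernoulli equation accounting for the proximal (LVOT) velocity:
#' PG = 4 (Vmax^2 - V_LVOT^2), in mmHg.
#'
#' @param v_max peak transvalvular velocity, m/s.
#' @param v_lvot LVOT velocity, m/s.
#' @return peak gradient, mmHg.
#' @export
peak_gradient <- function(v_max, v_lvot) {
  if (any(v_lvot < 0)) stop_invalid("v_lvot must be non-negative")
  if (any(v_max < v_lvot)) {
    stop_invalid("v_max must be >= v_lvot (jet accelerates across the valve)")
  }
  4 * (v_max^2 - v_lvot^2)
}

#' Mean transvalvular pressure gradient from a velocity trace
#'
#' Time-averages instantaneous Bernoulli gradients over the ejection period
#' by trapezoidal integration of 4 v(t)^2. By default the clinically standard
#' uncorrected form 4 v_av(t)^2 is averaged; `correct_for_lvot = TRUE`
#' subtracts the instantaneous LVOT term, mirroring the peak-gradient
#' formula.
#'
#' @param times sample times, s, strictly increasing over ejection.
#' @param v_av transvalvular velocity samples, m/s.
#' @param v_lvot_samples optional LVOT velocity samples on the same grid,
#'   required when `correct_for_lvot = TRUE`.
#' @param correct_for_lvot subtract the LVOT term per sample (default FALSE).
#' @return mean gradient, mmHg.
#' @export
mean_gradient <- function(times, v_av, v_lvot_samples = NULL,
                          correct_for_lvot = FALSE) {
  if (length(times) < 3 || length(v_av) != length(times)) {
    stop_invalid("velocity trace needs >= 3 samples on a matching time grid")
  }
  if (any(diff(times) <= 0)) stop_invalid("times must be strictly increasing")
  if (any(v_av < 0)) stop_invalid("velocities must be non-negative")
  inst <- 4 * v_av^2
  if (correct_for_lvot) {
    if (is.null(v_lvot_samples)) {
      stop_missing_data("correct_for_lvot requires v_lvot_samples",
        fields = "v_lvot_samples"
      )
    }
    inst <- inst - 4 * v_lvot_samples^2
  }
  # trapezoid over the ejection window, normalised by its duration
  dt <- diff(times)
  sum(dt * (inst[-1] + inst[-length(inst)]) / 2) / (max(times) - min(times))
}

#' Aortic valve area by the continuity equation
#'
#' AVA = (VTI_LVOT x CSA_LVOT) / VTI_AV. When the transvalvular VTI is
#' smaller than the LVOT VTI the configuration is physiologically
#' implausible (jet slower than outflow tract) and a warning is raised while
#' the arithmetic result is still returned.
#'
#' @param vti_lvot LVOT velocity-time integral, cm.
#' @param csa LVOT cross-sectional area, cm^2.
#' @param vti_av transvalvular velocity-time integral, cm.
#' @return valve area, cm^2.
#' @export
aortic_valve_area <- function(vti_lvot, csa, vti_av) {
  check_positive(vti_lvot, "vti_lvot")
  check_positive(csa, "csa")
  check_positive(vti_av, "vti_av")
  if (any(vti_av < vti_lvot)) {
    warning("vti_av < vti_lvot: implausible (AVA exceeds LVOT area)",
      call. = FALSE
    )
  }
  vti_lvot * csa / vti_av
}

#' Percent stroke work loss
#'
#' The share of left ventricular stroke work expended crossing the stenotic
#' valve: %SWL = 100 MG / (SBP + MG), where SBP + MG estimates the mean LV
#' systolic pressure.
#'
#' @param mg mean transvalvular gradient, mmHg.
#' @param sbp systolic cuff blood pressure, mmHg.
#' @return percent stroke work loss, strictly in (0, 100).
#' @export
stroke_work_loss_pct <- function(mg, sbp) {
  check_positive(mg, "mg")
  check_positive(sbp, "sbp")
  100 * mg / (sbp + mg)
}

#' Valvuloarterial impedance
#'
#' Global (valvular + arterial) left ventricular afterload:
#' Zva = (SBP + MG) / SVI, in mmHg.m^2/ml.
#'
#' @param mg mean gradient, mmHg.
#' @param sbp systolic blood pressure, mmHg.
#' @param svi stroke volume index, ml/m^2.
#' @return valvuloarterial impedance.
#' @export
valvuloarterial_impedance <- function(mg, sbp, svi) {
  check_positive(svi, "svi")
  (sbp + mg) / svi
}

#' Relative valve load
#'
#' RVL = MG / Zva, in ml/m^2: the valvular share of the global LV load.
#' Algebraically RVL = MG.SVI / (SBP + MG) = (SWL fraction) x SVI, so RVL is
#' always strictly below SVI and approaches it as arterial pressure vanishes.
#' A low RVL flags an arterially dominated afterload, where relieving the
#' valve alone leaves most of the load in place.
#'
#' @param mg mean gradient, mmHg.
#' @param zva valvuloarterial impedance, mmHg.m^2/ml.
#' @return relative valve load, ml/m^2.
#' @export
relative_valve_load <- function(mg, zva) {
  check_positive(zva, "zva")
  mg / zva
}

#' Derive the full hemodynamic index set for one examination
#'
#' Composes the individual index calculations into the complete derived set
#' for a single echocardiographic examination. The mean gradient comes from
#' `mg_measured` when supplied; otherwise it is computed from the velocity
#' trace. When both are present the measured value takes precedence and the
#' trace-derived value is returned as `mg_trace` for quality control.
#'
#' @param exam a list or one-row data.frame with fields `lvot_diameter` (cm),
#'   `vti_lvot` (cm), `vti_av` (cm), `sbp` (mmHg), `bsa` (m^2), and optionally
#'   `mg_measured` (mmHg), `v_max` / `v_lvot` (m/s), `lvef` (%).
#' @param trace optional velocity trace: a list with `times`, `v_av` and
#'   optionally `v_lvot_samples`.
#' @param correct_for_lvot passed to [mean_gradient()] when the trace is used.
#' @return a list of class `derived_indices` with elements `csa_lvot`, `sv`,
#'   `svi`, `pg` (when velocities supplied), `mg`, `mg_trace` (QC, when both
#'   sources present), `ava`, `ava_indexed`, `lvp_mean`, `swl_pct`, `zva`,
#'   `rvl`.
#' @examples
#' derive_all(list(
#'   lvot_diameter = 2.0, vti_lvot = 20, vti_av = 100,
#'   mg_measured = 40, sbp = 120, bsa = 2.0
#' ))
#' @export
derive_all <- function(exam, trace = NULL, correct_for_lvot = FALSE) {
  exam <- as.list(exam)
  need <- c("lvot_diameter", "vti_lvot", "vti_av", "sbp", "bsa")
  absent <- need[!vapply(
    need, function(f) !is.null(exam[[f]]) && !is.na(exam[[f]]), logical(1)
  )]
  if (length(absent)) {
    stop_missing_data(
      paste("missing exam fields:", paste(absent, collapse = ", ")),
      fields = absent
    )
  }
  if (!is.na(exam$bsa) && (exam$bsa <= 0.5 || exam$bsa >= 3.5)) {
    stop_invalid("bsa outside plausible range (0.5, 3.5) m^2: ", exam$bsa)
  }

  mg_measured <- exam$mg_measured
  has_measured <- !is.null(mg_measured) && !is.na(mg_measured)
  mg_trace <- if (!is.null(trace)) {
    mean_gradient(trace$times, trace$v_av, trace$v_lvot_samples,
      correct_for_lvot = correct_for_lvot
    )
  }
  if (!has_measured && is.null(mg_trace)) {
    stop_missing_data(
      "no mean-gradient source: supply mg_measured or a velocity trace",
      fields = c("mg_measured", "trace")
    )
  }
  mg <- if (has_measured) mg_measured else mg_trace

  csa <- csa_lvot(exam$lvot_diameter)
  sv <- stroke_volume(exam$vti_lvot, csa)
  svi <- stroke_volume_index(sv, exam$bsa)
  ava <- aortic_valve_area(exam$vti_lvot, csa, exam$vti_av)
  zva <- valvuloarterial_impedance(mg, exam$sbp, svi)
  out <- list(
    csa_lvot = csa,
    sv = sv,
    svi = svi,
    pg = if (!is.null(exam$v_max) && !is.null(exam$v_lvot) &&
      !is.na(exam$v_max) && !is.na(exam$v_lvot)) {
      peak_gradient(exam$v_max, exam$v_lvot)
    },
    mg = mg,
    mg_trace = if (has_measured && !is.null(mg_trace)) mg_trace,
    ava = ava,
    ava_indexed = ava / exam$bsa,
    lvp_mean = exam$sbp + mg,
    swl_pct = stroke_work_loss_pct(mg, exam$sbp),
    zva = zva,
    rvl = relative_valve_load(mg, zva)
  )
  structure(out[!vapply(out, is.null, logical(1))],
    class = "derived_indices"
  )
}

#' Average per-beat primitives
#'
#' Echo measurements are conventionally averaged over at least 3 cardiac
#' cycles in sinus rhythm and 5 in atrial fibrillation before index
#' derivation. When a table carries multiple rows per patient this helper
#' collapses them to one averaged row; it also checks the beat count against
#' the rhythm-specific minimum.
#'
#' @param beats data.frame of per-beat primitives with a `patient_id` column
#'   and a `rhythm` column (`"sinus"` or `"afib"`).
#' @param enforce_minimum warn when fewer beats than convention requires.
#' @return one averaged row per patient.
#' @export
average_beats <- function(beats, enforce_minimum = TRUE) {
  stopifnot(is.data.frame(beats), "patient_id" %in% names(beats))
  num <- vapply(beats, is.numeric, logical(1))
  split_rows <- split(beats, beats$patient_id)
  out <- lapply(split_rows, function(b) {
    if (enforce_minimum) {
      needed <- if (identical(b$rhythm[1], "afib")) 5L else 3L
      if (nrow(b) < needed) {
        warning(sprintf(
          "patient %s: %d beats averaged, convention expects >= %d for %s",
          b$patient_id[1], nrow(b), needed, b$rhythm[1]
        ), call. = FALSE)
      }
    }
    row <- b[1, , drop = FALSE]
    row[num] <- lapply(b[num], mean)
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
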