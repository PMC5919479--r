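#' Hemodynamically severe aortic stenosis
#'
#' Severe AS is defined as AVA <= 1.0 cm^2 and/or indexed AVA < 0.6 cm^2/m^2.
#' Boundary semantics (inclusive on AVA, strict on the indexed value) are
#' frozen and tested.
#'
#' @param ava aortic valve area, cm^2.
#' @param ava_indexed AVA / BSA, cm^2/m^2.
#' @return logical: TRUE when hemodynamically severe.
#' @export
is_severe_as <- function(ava, ava_indexed) {
  check_positive(ava, "ava")
  check_positive(ava_indexed, "ava_indexed")
  ava <= 1.0 | ava_indexed < 0.6
}

#' Flow state from stroke volume index
#'
#' Low flow is SVI <= 35 ml/m^2 (inclusive boundary).
#'
#' @param svi stroke volume index, ml/m^2.
#' @return `"low"` or `"normal"`.
#' @export
flow_state <- function(svi) {
  check_positive(svi, "svi")
  ifelse(svi <= 35, "low", "normal")
}

#' Flow-gradient phenotype classification
#'
#' Assigns each patient exactly one of the severe-AS flow-gradient
#' phenotypes:
#'
#' * NF-HG / LF-HG: high gradient, split by flow state
#' * NFLG: normal flow (SVI > 35), low gradient
#' * PLFLG: paradoxical low flow low gradient (SVI <= 35, LVEF >= 50)
#' * CLFLG: classical low flow low gradient (SVI <= 35, LVEF < 50)
#'
#' The low-gradient threshold is MG < 40 mmHg by default (`gradient_rule =
#' "lt"`); `"le"` switches to MG <= 40. A low-flow low-gradient patient with
#' missing LVEF is labelled `"LFLG-unspecified"` rather than silently
#' assigned or dropped.
#'
#' @param svi stroke volume index, ml/m^2.
#' @param mg mean gradient, mmHg.
#' @param lvef left ventricular ejection fraction, % (may be NA).
#' @param gradient_rule `"lt"` (MG < 40, default) or `"le"` (MG <= 40).
#' @return data.frame with columns `flow`, `gradient`, `subclass`.
#' @export
classify_flow_gradient <- function(svi, mg, lvef = NA_real_,
                                   gradient_rule = c("lt", "le")) {
  gradient_rule <- match.arg(gradient_rule)
  check_positive(svi, "svi")
  check_positive(mg, "mg")
  n <- max(length(svi), length(mg), length(lvef))
  svi <- rep_len(svi, n)
  mg <- rep_len(mg, n)
  lvef <- rep_len(lvef, n)

  flow <- flow_state(svi)
  low_grad <- if (gradient_rule == "lt") mg < 40 else mg <= 40
  gradient <- ifelse(low_grad, "low", "high")
  subclass <- character(n)
  subclass[!low_grad & flow == "normal"] <- "NF-HG"
  subclass[!low_grad & flow == "low"] <- "LF-HG"
  subclass[low_grad & flow == "normal"] <- "NFLG"
  lf_lg <- low_grad & flow == "low"
  subclass[lf_lg & !is.na(lvef) & lvef >= 50] <- "PLFLG"
  subclass[lf_lg & !is.na(lvef) & lvef < 50] <- "CLFLG"
  subclass[lf_lg & is.na(lvef)] <- "LFLG-unspecified"
  data.frame(flow = flow, gradient = gradient, subclass = subclass)
}

#' Dichotomize relative valve load at the prognostic cutoff
#'
#' RVL at or below the cutoff (default 7.95 ml/m^2, inclusive) flags the
#' high-risk, arterially dominated phenotype.
#'
#' @param rvl relative valve load, ml/m^2.
#' @param cutoff risk threshold, ml/m^2 (default 7.95).
#' @return logical: TRUE for high risk (RVL <= cutoff).
#' @export
dichotomize_rvl <- function(rvl, cutoff = 7.95) {
  check_positive(rvl, "rvl")
  rvl <= cutoff
}

# fixed exclusion cascade; first matching reason is tallied
exclusion_reasons <- c(
  "incomplete_echo", "ar_ge3", "valve_in_valve",
  "intraprocedural_death", "converted_to_savr", "not_severe_as"
)

#' Apply the cohort inclusion and exclusion cascade
#'
#' Excludes records in a fixed order so tallies are reproducible:
#' incomplete echocardiographic data; predominant aortic regurgitation
#' (grade >= 3+); valve-in-valve procedure; intraprocedural death;
#' conversion to surgical valve replacement; and finally absence of
#' hemodynamically severe AS. Each excluded record is tallied under the
#' first matching reason only.
#'
#' @param records data.frame with columns `echo_complete`, `ar_grade`
#'   (ordinal 0-4), `valve_in_valve`, `intraprocedural_death`,
#'   `converted_to_savr` (logical), `ava`, `ava_indexed`.
#' @return list with `included` (the retained rows), `tally` (named counts
#'   per exclusion reason) and `exclusion_reason` (per input row, NA when
#'   included).
#' @export
apply_inclusion_criteria <- function(records) {
  stopifnot(is.data.frame(records))
  if (any(!records$ar_grade %in% 0:4)) {
    stop_invalid("ar_grade must be an integer grade 0-4")
  }
  reason <- rep(NA_character_, nrow(records))
  mark <- function(cond, label) ifelse(is.na(reason) & cond, label, reason)
  reason <- mark(!records$echo_complete, "incomplete_echo")
  reason <- mark(records$ar_grade >= 3, "ar_ge3")
  reason <- mark(records$valve_in_valve, "valve_in_valve")
  reason <- mark(records$intraprocedural_death, "intraprocedural_death")
  reason <- mark(records$converted_to_savr, "converted_to_savr")
  reason <- mark(
    !is_severe_as(records$ava, records$ava_indexed),
    "not_severe_as"
  )
  tally <- vapply(
    exclusion_reasons,
    function(r) sum(reason == r, na.rm = TRUE), integer(1)
  )
  list(
    included = records[is.na(reason), , drop = FALSE],
    tally = tally,
    exclusion_reason = reason
  )
}
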