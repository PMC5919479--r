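---
title: "Relative valve load: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative valve load: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvload)
```

## The problem

In aortic stenosis (AS) the left ventricle ejects against a combined
afterload: the stenotic valve and the systemic arterial tree. Transcatheter
aortic valve replacement (TAVR) relieves only the valvular component, so a
patient whose global afterload is dominated by the arterial side may gain
little from the procedure. The standard severity indices do not separate the
two components:

* **MG** (mean transvalvular gradient, mmHg) measures valvular load alone
  and is flow-dependent;
* **AVA** (aortic valve area by the continuity equation, cm²) measures
  orifice size, not load;
* **Zva** = (SBP + MG)/SVI (mmHg·m²/ml) measures the *global* afterload
  without apportioning it;
* **%SWL** = 100·MG/(SBP + MG) measures the share of stroke work lost at the
  valve.

The **relative valve load**, RVL = MG/Zva (ml/m²), is the valvular share of
the global load. Algebraically

$$\mathrm{RVL} = \frac{\mathrm{MG}\cdot\mathrm{SVI}}{\mathrm{SBP}+\mathrm{MG}}
 = \frac{\%\mathrm{SWL}}{100}\cdot \mathrm{SVI},$$

so RVL is strictly below SVI and rises toward it as arterial pressure
vanishes. A *low* RVL flags an arterially dominated afterload and, in the
TAVR setting, a worse one-year prognosis; the package's default risk
threshold is RVL ≤ 7.95 ml/m² (inclusive).

`derive_all()` composes the whole chain from Doppler primitives (LVOT
diameter and VTI, transvalvular VTI, peak velocities, cuff systolic
pressure, body surface area). The identity above, the bound RVL < SVI, and
strict monotonicity in MG and SVI are enforced as property tests at relative
tolerance 1e-9 — the chain is pure arithmetic, so nothing looser is needed.

### Conventions frozen in the code

* **Mean gradient from a velocity trace** time-averages the *uncorrected*
  instantaneous Bernoulli gradient 4·v(t)² by trapezoid, the convention of
  clinical echo labs. The peak gradient formula subtracts the LVOT term, so
  a `correct_for_lvot` flag exposes the corrected average as well (default
  off). A measured MG always wins over a trace-derived one; the trace value
  is kept as `mg_trace` for quality control.
* **Beat averaging** (≥3 cycles in sinus rhythm, ≥5 in atrial fibrillation)
  is assumed done at acquisition; `average_beats()` is provided for tables
  that still carry per-beat rows.
* **BSA is an input.** No body-surface formula is computed: indices are
  defined on whatever BSA the echo report used.
* **Boundary semantics** are inclusive/strict exactly as the phenotype
  definitions require: severe AS is AVA ≤ 1.0 cm² *or* indexed AVA
  < 0.6 cm²/m²; low flow is SVI ≤ 35 ml/m²; low gradient is MG < 40 mmHg by
  default (`gradient_rule = "le"` switches to ≤ 40, a variant that appears
  in some phenotype footnotes); the LVEF split is < 50 vs ≥ 50%; the RVL
  cutoff is inclusive. A low-flow low-gradient patient with missing LVEF is
  labelled `LFLG-unspecified`, never silently dropped.
* **Exclusion cascade** order is fixed (incomplete echo → AR ≥ 3+ →
  valve-in-valve → intraprocedural death → conversion to surgery → not
  severe), each record tallied under its first matching reason, so
  screening tallies are reproducible regardless of row order.

## Prognostic evaluation

`evaluate_cohort()` assesses each index (RVL, MG, AVA, %SWL, Zva, SVI)
against an endpoint (all-cause death, cardiovascular death, or death or
heart-failure readmission at one year):

* **ROC curves** use midpoint thresholds between consecutive unique values
  plus ±Inf sentinels; the trapezoidal AUC equals the tie-corrected
  Mann–Whitney statistic (tested against an O(n²) concordance oracle and
  against pROC).
* **Youden cutoff** maximises J = sens + spec − 1; ties are broken toward
  higher specificity, then the lower cutoff, making the selection
  deterministic. Specificity is preferred because the clinical use of a low
  RVL is ruling *in* high risk. No bootstrap optimism correction is applied
  to the selected cutoff (future work).
* **Paired AUC comparison** uses DeLong's placement-value variance with
  midrank placements (validated against the naive kernel-matrix form and
  pROC). **Paired sensitivity/specificity comparison** uses the exact
  binomial McNemar test on discordant pairs, restricted to events or
  non-events respectively; a mid-p variant exists behind a flag. Neither
  test is uniquely dictated by convention; both choices are declared, not
  inferred.
* **Contingency tests**: Pearson chi-square is *uncorrected* by default —
  this is the variant that reproduces the published low-gradient statistic
  13.72 from its printed counts — with Yates behind a flag; the
  likelihood-ratio G² handles empty cells as 0·log0 = 0; Fisher's exact
  test is two-sided hypergeometric.
* **Survival**: Kaplan–Meier, log-rank, a univariable Cox screen at p < 0.1
  (conventional liberal level), and a multivariable Cox model with Breslow
  tie handling by default (Efron by option) and Wald intervals. All
  p-values are two-sided at α = 0.05; no multiple-testing correction is
  applied anywhere, matching the reporting style the pipeline mirrors.
* **Rounding**: every reported percentage goes through one half-up rounding
  utility (`round_half_up()`); the 2×2 reconstruction below depends on that
  exact rule.

`reconstruct_2x2_from_summary()` inverts rounded published summaries: given
the event margins, a positive-call group size, and a sensitivity or
specificity rounded to a stated number of decimals, it enumerates every
integer table consistent with the margins and returns the unique one that
re-rounds to the report, erroring explicitly on none (inconsistency) or
several (ambiguity, listing candidates).

## The synthetic cohort generator

No patient-level data accompany the analysis this pipeline operationalises,
so `simulate_cohort()` generates cohorts with the published statistical
structure:

* **Marginals** (defaults): MG 44.8 ± 14.9 mmHg, SBP 134.6 ± 28.5 mmHg,
  SVI 40.2 ± 12.4 ml/m², AVA 0.69 ± 0.17 cm², age 84.4 ± 6.5 y, male 50%;
  EuroSCORE II lognormal with median 5.4% and IQR 3.2–9.9%. Continuous
  marginals are normal truncated at physiological floors (MG > 5,
  SBP > 60, SVI > 10, AVA > 0.3); the location parameter is solved so the
  *truncated* mean equals the target — the floors are guards, and an
  unadjusted floor would bias e.g. the SVI mean by ~0.26 ml/m², comparable
  to the Monte-Carlo band the calibration is tested at. The three EuroSCORE
  quantiles overdetermine a lognormal (the IQR midpoint in log space is
  5.63, not 5.4), so its parameters are a least-squares fit on the log
  quantiles.
* **Dependence**: (MG, SBP, SVI) are drawn through a Gaussian copula with
  rank correlations MG–SVI +0.3, MG–SBP −0.1, SBP–SVI 0 (converted to the
  normal-score scale by 2·sin(πρ/6)). No joint structure is published;
  these defaults produce realistic low-flow/low-gradient co-occurrence and
  are plainly configurable. AVA, age, BSA and EuroSCORE II are independent.
* **BSA** (1.80 ± 0.20 m², floor 1.30) and the **LVOT diameter**
  (2.1 ± 0.2 cm, truncated to 1.7–2.6 cm) are invented solely for
  back-filling primitives — typical values for an elderly TAVR population —
  and never affect derived-index correctness: `backfill_primitives()`
  solves the VTIs and velocities so that `derive_all()` reproduces the
  latent (MG, SVI, SBP, AVA) exactly (round-trip tested to 1e-6 relative),
  resampling the diameter when the latent valve area would exceed the
  outflow-tract area. The peak gradient is set at ~1.65× MG, a plausible
  ratio that feeds nothing downstream.
* **Covariate links**: atrial fibrillation and LVEF ≤ 40% are Bernoulli
  draws whose probabilities depend on the dichotomized RVL — 57.8% vs 30.9%
  AF and 39.8% vs 13.7% low LVEF in the RVL ≤ 7.95 vs > 7.95 groups, the
  published contrasts taken as the two-point logistic link. The implied
  overall prevalences (~40% AF, ~23% low LVEF) land near the published
  cohort margins (38.0%, 22.1%).
* **Outcomes**: exponential survival within year one — the simplest model
  consistent with a single one-year endpoint — with log hazard
  log h₀ + log 3.2·1{RVL≤7.95} + log 1.3·1{LVEF≤40} + log 1.5·AF +
  log 1.03·(EuroSCORE II − 5.4). The covariate hazard ratios besides the
  RVL effect are declared synthetic defaults (no adjusted values are
  published for them). h₀ is solved numerically so expected one-year
  mortality is 20.5%; follow-up is administratively censored at day 365
  (the source protocol reports one-year follow-up, so the generator assumes
  no earlier censoring; the estimators support it regardless). Deaths are
  labelled cardiovascular with probability 0.491; heart-failure readmission
  is an independent Bernoulli (0.14) among survivors — a deliberately crude
  stand-in that merely exercises the composite endpoint.
* **Determinism**: one `set.seed()` per simulation (Mersenne-Twister),
  draws in a fixed order, so a seed reproduces a cohort bit-identically.

### What passing tests do and do not show

The generator emulates marginal moments, one dependence structure, the
covariate contrasts and a proportional-hazards outcome. It does *not*
emulate measurement error in Doppler primitives, intra-patient beat
variability, informative censoring, competing risks, non-proportional
hazards, or any association the published tables do not constrain. Tests
passing on synthetic cohorts therefore validate the *pipeline arithmetic
and inference machinery*, not the clinical performance of RVL on new data.
In particular the published cohort AUCs (69.3% / 75.0% / 61.7%), the
table-level p-values and the 7.95 cutoff itself depend on the unavailable
patient data and are deliberately not asserted; the suite instead checks
that on default-size cohorts (n = 258) the Youden-selected RVL cutoff lands
in a clinically sensible band and the adjusted Cox interval covers the
generating hazard ratio across seeds.

## Problem sizes and numerical choices

The test suite and the acceptance script use problem sizes chosen to keep
Monte-Carlo error well inside each tolerance while remaining quick on one
core: n = 10⁴–10⁵ draws for marginal and mortality calibration (3 MC
standard errors), 100 replicates of n = 2000 for hazard-ratio recovery,
1500 replicates for Wald-coverage of the null, 2000 replicates for the
DeLong size check, and 100 random instances (n ≤ 500) for the
oracle-equivalence sweeps. Identity checks on the arithmetic chain use
relative tolerance 1e-9; round-trip through the primitive back-fill uses
1e-6. Degenerate inputs fail loudly with typed conditions
(`rvload_invalid_input`, `rvload_missing_data`, `rvload_inconsistency`,
`rvload_ambiguity`) rather than propagating NA.

## Known limitations

* No pressure-recovery correction, dobutamine-stress adjudication of
  true- versus pseudo-severe AS, or projected valve area.
* No competing-risks analysis or time-varying covariates; the one-year
  horizon makes the constant-hazard assumption tolerable but untested
  beyond it.
* The Youden cutoff is reported without optimism correction.
* The readmission process in the generator is a placeholder Bernoulli; the
  composite endpoint exercises plumbing, not epidemiology.
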