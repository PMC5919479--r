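# rvload

Doppler-echocardiographic hemodynamic indices of aortic stenosis (AS)
severity, flow–gradient phenotyping, and prognostic evaluation of those
indices for one-year outcome after transcatheter aortic valve replacement
(TAVR) — built around the **relative valve load**,

```
RVL = MG / Zva          (ml/m²)
```

where MG is the mean transvalvular gradient (mmHg) and
Zva = (SBP + MG)/SVI is the valvuloarterial impedance (mmHg·m²/ml), the
global left-ventricular afterload. Algebraically
RVL = MG·SVI/(SBP + MG): the *valvular share* of the global load. TAVR
relieves only the valvular load, so a low RVL (≤ 7.95 ml/m² by default)
marks an arterially dominated afterload and a worse post-procedural
prognosis.

The package is aimed at cardiology researchers who want to compute these
indices from routine echo primitives, classify flow–gradient phenotypes
(NF-HG, LF-HG, NFLG, PLFLG, CLFLG), and evaluate candidate indices against
survival endpoints with the standard machinery: ROC curves with
Youden-index cutoff selection, DeLong paired AUC comparison, exact McNemar
sensitivity/specificity comparison, Pearson/likelihood-ratio/Fisher
contingency tests, Kaplan–Meier with log-rank, and adjusted Cox
proportional-hazards models. Because no patient-level cohort is public, a
calibrated synthetic TAVR cohort generator (`simulate_cohort()`) makes
every stage testable end to end; utilities also reconstruct exact 2×2
tables from rounded published summaries.

## Worked example

Derive the full index set for one examination:

```r
library(rvload)
ex <- derive_all(list(
  lvot_diameter = 2.1,  # cm
  vti_lvot      = 21,   # cm
  vti_av        = 102,  # cm
  mg_measured   = 42,   # mmHg
  sbp           = 128,  # mmHg
  bsa           = 1.85  # m^2
))
unlist(ex)
#>    csa_lvot          sv         svi          mg         ava ava_indexed
#>      3.4636     72.7357     39.3166     42.0000      0.7131      0.3855
#>    lvp_mean     swl_pct         zva         rvl
#>    170.0000     24.7059      4.3239      9.7135
```

This patient has severe AS (AVA 0.71 cm², indexed 0.39 < 0.6 cm²/m²),
normal flow (SVI 39.3 > 35 ml/m²), and RVL 9.71 ml/m² — above the 7.95
cutoff, i.e. a valve-dominated load expected to respond well to TAVR.

Simulate a study-sized cohort and evaluate every index against one-year
all-cause mortality:

```r
co <- simulate_cohort(cohort_spec(seed = 1))   # n = 258
d  <- derive_cohort(co)
evaluate_cohort(d)
#> Endpoint death: 258 patients, 53 events
#>
#> AUC (%):
#>     index auc_pct p_vs_rvl
#> 1     rvl   61.77       NA
#> 2      mg   56.13  0.13383
#> ...
#> Youden-optimal RVL cutoff: 9.409 (J = 0.249, sens 69.8%, spec 55.1%)
#>
#> Adjusted Cox model:
#>       covariate   hr ci_lo ci_hi       p
#> 1 rvl_high_risk 1.77  1.00  3.12 0.04839
#> 2      afibTRUE 2.49  1.38  4.50 0.00237
#> 3    euroscore2 1.04  1.01  1.07 0.00619
```

The report carries, per endpoint: the AUC table with DeLong p-values
against RVL, sensitivity/specificity at the literature cutoffs
(MG < 40 mmHg, AVA > 0.75 cm², %SWL ≤ 25, Zva ≥ 5, SVI ≤ 35, RVL ≤ 7.95)
with exact McNemar p-values, flow and low-gradient subgroup chi-squares,
Kaplan–Meier coordinates, and the univariable screen feeding the adjusted
Cox model. `write_report()` emits it as JSON plus CSV tables. At a single
n = 258 draw the estimates are noisy (the Cox interval above only brushes
its generating value); the test suite characterises behaviour across seeds
and at larger n.

Recompute the published-count consistency checks:

```r
reproduce_tables()
# 9 rows, all pass = TRUE: chi-square 13.715 vs printed 13.72, rounded
# mortality proportions, the unique reconstructed 2x2 {tn 154, fp 51,
# tp 32, fn 21} with implied sensitivity 60.4% and per-group 1-year
# survival 88.0% / 61.4%, Fisher p = 1.0000
```

A thin command-line wrapper with `simulate` / `derive` / `evaluate` /
`reproduce-tables` subcommands lives at `inst/cli/rvl_pipeline.R`.

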