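# melcirc — modelling diurnal melatonin secretion

Melatonin, the pineal hormone, shows a pronounced nocturnal blood peak over a
nearly flat daytime baseline. Clinical studies of circadian disruption — for
example comparing children with epilepsy against a non-epileptic comparison
group — sample blood every 3 hours over a day and need each subject's sparse
8–9 point profile reduced to a handful of interpretable numbers before any
group statistics can be run.

`melcirc` is an R package for exactly that workflow. Its core is a
four-parameter periodic Gaussian model of the diurnal secretion curve,

```
MLT(t) = b1 + b2 * exp(-[(cos(pi*t/12 - pi*b3/12) - 1)/s]^2),
     s = (cos(pi*b4/24) - 1)/sqrt(ln 2),
```

where `t` is clock time in hours and

* `b1` — minimum (baseline) melatonin concentration \[pg/mL\],
* `b2` — release amplitude; the peak is `b_max = b1 + b2` \[pg/mL\],
* `b3` — phase shift: clock time of the peak \[h\], circular on \[0, 24),
* `b4` — full width at half maximum, read as sleep duration \[h\], in (0, 12).

The curve has period exactly 24 h, peaks at `t = b3` with value `b1 + b2`,
and its FWHM equals `b4` by construction. Around this model the package
provides:

* **fitting** — bounded Levenberg–Marquardt nonlinear least squares for one
  subject's profile, with deterministic initialisation, multi-start phase
  fallback, and the fit-quality gates used to admit subjects into cohort
  statistics (explained variance > 90%, R > 0.95, residual normality,
  bell-shape screening of flat or double-peaked profiles);
* **cohort statistics** — Mann–Whitney U group comparisons (exact for tiny
  samples), Spearman rank correlations against clinical covariates, Pearson
  chi-square homogeneity checks, and logistic regression of binary clinical
  flags on the fitted parameters, with separation detection;
* **a synthetic cohort generator** — 52 epilepsy-group (EG) + 30
  comparison-group (CG) subjects by default, 3-hourly sampling,
  group parameter locations at the published group medians, multiplicative
  assay noise, and covariate–parameter correlation structure with the
  published signs — so the whole pipeline is testable without any
  patient data;
* **a pipeline and CLI** — `simulate` → `fit` → `compare` as R functions
  (`run_end_to_end()`) or as subcommands of the `inst/scripts/melcirc`
  Rscript, fully reproducible from a seed.

## Worked example

Simulate one subject at the default assay noise (CV 5%) and fit it back:

```r
library(melcirc)
truth <- secretion_params(b1 = 6, b2 = 140, b3 = 2, b4 = 8)
set.seed(1)
prof <- synthesize_profile(truth, generator_config(), "S01")
fit_profile(prof)
#> Secretion model fit for subject S01
#>   b1  =     6.2661  (SE 1.1840)
#>   b2  =   138.0582  (SE 2.0160)
#>   b3  =     1.9644  (SE 0.0420)
#>   b4  =     7.9795  (SE 0.0926)
#>   R = 0.9996, explained variance = 0.9992
#>   converged: TRUE (6 iterations), bell-shaped: TRUE, quality pass: TRUE
```

All four parameters are recovered within a few percent from eight noisy
samples: a baseline near 6 pg/mL, an amplitude near 140 pg/mL (peak
`b_max ≈ 144` pg/mL), a secretion peak just before 2 am, and an estimated
sleep duration just under 8 h. The diagnostics line is the quality gate used
by the cohort pipeline.

A full study-sized run — simulate 82 subjects, fit each, compare the groups —
is one call:

```r
report <- run_end_to_end(generator_config(), out_dir = "melcirc_run", seed = 1)
print(report)
```

which prints the per-parameter group medians with Mann–Whitney p-values —
under the default calibration the phase shift `b3` comes out later in the
EG group (at seed 1: medians 2.68 vs 1.45 h, p = 0.00085) — the significant
Spearman correlation cells per group,
and the logit summaries, and writes all tables as CSV into the run directory
alongside a `manifest.yaml` recording configuration and seed.

Or from a shell:

```sh
Rscript inst/scripts/melcirc run --out melcirc_run --seed 1
```

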