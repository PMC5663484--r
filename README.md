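# breathcomplex

Complexity analysis of breathing patterns from whole-body
plethysmography recordings.

## What it does

Respiratory dynamics carry structure beyond their mean rate and depth:
the irregularity of the rhythm, the long-range temporal correlation of
breath amplitudes, and the synchronization between rhythm and depth all
change in airway disease. In experimental asthma the characteristic
pattern is a *more regular* rhythm (lower sample entropy of the
inter-breath interval, IBI), *more variable* intervals (higher CV), a
*more persistent* amplitude series (higher detrended-fluctuation
scaling exponent of the respiratory volume, RV), and *tighter* IBI–RV
synchronization (lower cross-sample entropy).

`breathcomplex` implements the measurement chain end to end, for
researchers analysing plethysmography recordings of small animals:

- **Signal handling** — read/write 1 kHz pressure traces (plain-text
  csv dialect with an `# fs=` header) and select the lowest-artifact
  20-minute analysis window.
- **Breath extraction** — zero-phase drift removal and smoothing,
  prominence-based peak detection with a refractory constraint, and
  construction of the IBI (s) and RV (a.u.) series.
- **Complexity metrics** — sample entropy
  `SampEn(m = 2, r = 0.2·SD) = −ln(A/B)` with Chebyshev template
  matching and no self-matches; cross-sample entropy on z-normalized
  series (symmetric; larger = more asynchrony); DFA-1 scaling exponent
  α from the slope of `log F(s)` vs `log s` over log-spaced scales
  `4..n/4` (α ≈ 0.5 for white noise, ≈ H for fractional Gaussian
  noise, ≈ 1.5 for integrated noise).
- **Group statistics** — one-way ANOVA with Bonferroni-adjusted
  pooled-t pairwise tests, tie-corrected Kruskal–Wallis with Dunn's
  post test, an automatic normality-screened choice between them, and
  a direction-and-significance report of the asthma-vs-control effect
  pattern.
- **Synthetic ground truth** — exact (circulant-embedding) fractional
  Gaussian noise, a stochastic breath-process generator with
  controllable entropy, Hurst exponents and rhythm–depth coupling,
  waveform rendering with noise/drift/artifacts, and reproducible
  labeled cohorts, so every stage of the pipeline is testable against
  known complexity.

## A worked example

```r
library(breathcomplex)

cfg <- synth_cohort_config(
  groups = list(saline = control_like_spec(), OVA = asthma_like_spec()),
  n_per_group = 10, record_duration = 1500, master_seed = 7)
res <- run_pipeline(generate_cohort(cfg))

aggregate(res$table[, c("sampen_ibi", "cv_ibi", "alpha_rv", "cross_sampen")],
          list(group = res$table$group), mean)
#>    group sampen_ibi     cv_ibi  alpha_rv cross_sampen
#> 1    OVA   1.715709 0.12057191 0.6696524     1.942026
#> 2 saline   2.171547 0.08063974 0.5832930     2.094737

reproduce_effect_pattern(res, control_label = "saline")
#> Effect-pattern report (case vs control):
#>        metric case_group expected   estimate adjusted_p significant consistent
#>    sampen_ibi        OVA    lower -0.4558380  1.360e-13        TRUE       TRUE
#>        cv_ibi        OVA   higher  0.0399322  1.863e-20        TRUE       TRUE
#>      alpha_rv        OVA   higher  0.0863594  5.607e-06        TRUE       TRUE
#>  cross_sampen        OVA    lower -0.1527104  1.060e-09        TRUE       TRUE
#>      mean_ibi        OVA     none  0.0006316  7.173e-01       FALSE       TRUE
#>       mean_rv        OVA     none  0.0045569  5.823e-01       FALSE       TRUE
#>     sampen_rv        OVA     none -0.1152800  6.724e-04        TRUE      FALSE
#>     alpha_ibi        OVA     none -0.0097744  4.279e-01       FALSE       TRUE
#>         cv_rv        OVA     none  0.0026149  4.237e-01       FALSE       TRUE
```

Reading the report: the asthma-like group shows the four primary
disease signatures (lower `sampen_ibi`, higher `cv_ibi`, higher
`alpha_rv`, lower `cross_sampen`, all significant after Bonferroni
adjustment) while the first moments (`mean_ibi`, `mean_rv`) do not
shift. The `sampen_rv` row is a known generator side effect discussed
in the methods vignette.

A thin command-line wrapper over the same functions is installed at
`inst/cli/breathcomplex.R` (subcommands `simulate`, `extract`,
`complexity`, `compare`, `reproduce`).

## Method documentation

The methods vignette
(`vignettes/breathing-pattern-complexity.Rmd`) describes the model
assumptions, parameter meanings and defaults, the generator's design
and its limitations, and the numerical conventions (tie-breaks,
degenerate inputs, tolerance semantics).
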