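---
title: "Quantifying breathing-pattern complexity from plethysmography signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying breathing-pattern complexity from plethysmography signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathcomplex)
```

## The problem

Healthy breathing is not metronomic. Both the respiratory rhythm (the
inter-breath interval, IBI) and the depth of breathing (the respiratory
volume, RV, measured as breath-peak amplitude on a whole-body
plethysmograph trace) fluctuate continuously, and the *structure* of
those fluctuations — their irregularity, their long-range temporal
correlation, and the coupling between rhythm and depth — carries
information about the integrity of respiratory control. In experimental
asthma, the respiratory rhythm becomes more regular (lower entropy) and
more variable in magnitude (higher coefficient of variation), the
amplitude series develops stronger long-range correlation, and rhythm
and depth become more tightly synchronized. `breathcomplex` implements
the full analysis chain needed to measure these properties from a raw
pressure recording, together with a synthetic generator that produces
recordings with *known* complexity so that every stage can be verified
quantitatively.

## The analysis pipeline

A recording enters as a uniformly sampled single-channel pressure trace
(typically 60 min at 1 kHz). The pipeline is:

1. **Window selection** (`select_analysis_window`): a 20-minute window
   with the lowest artifact burden is chosen by sliding a window in
   30-s steps and scoring each position. No operational artifact
   definition accompanies recordings like these, so the package defines
   a two-term score, each term in [0, 1] and weighted 1/2:
   the fraction of samples further than 5 robust SDs (1.4826 × MAD)
   from the window median (movement and pressure transients), plus the
   fraction of spectral power outside the breathing band, 0.5–5 Hz by
   default (guinea-pig breathing rates are roughly 1–3 Hz; the band is
   configurable). Ties break to the earliest window. Scoring runs on a
   ~50 Hz block-mean decimated copy of the trace: the breathing band is
   far below the decimated Nyquist frequency, and this keeps the
   per-window spectra cheap at 1 kHz input rates.
2. **Preprocessing** (`preprocess`): baseline drift is removed by
   subtracting a triangular moving-average baseline of width
   `1/highpass_cutoff` (default 10 s). The triangular kernel (a boxcar
   applied twice) is used instead of a single boxcar because the
   boxcar's spectral sidelobes leave a ripple at the breathing
   frequency of up to ~2% of the pulse amplitude, which contaminates
   amplitude estimates; squaring the sidelobes removes it. A centered
   20-ms moving average then suppresses measurement noise. Both filters
   are symmetric, hence zero-phase: peak *times* are never shifted by
   filtering, which matters because the IBI series must not inherit a
   filter delay.
3. **Peak detection** (`detect_breath_peaks`): local maxima are kept if
   their topographic prominence reaches `min_prominence` (default 0.3)
   times a robust amplitude scale (MAD × 1.4826 × 4). Prominence is
   used rather than raw height because plethysmograph units are
   uncalibrated and baselines imperfect. A refractory constraint
   (default 0.15 s, well below the shortest physiological interval)
   suppresses double detections: the higher of two conflicting
   candidates wins, ties go to the earlier.
4. **Series construction** (`build_breath_series`): IBIs are
   peak-to-peak intervals in seconds; RV is the peak value minus the
   minimum between the neighbouring peaks. Referencing each amplitude
   to its local troughs (rather than to zero) makes RV immune to
   residual drift; an `"absolute"` mode is provided for comparison.
   Deep inspirations (sighs) are retained — they are part of the
   pattern, and no exclusion rule is applied.
5. **Complexity metrics** (`complexity_profile`), described next.

## The complexity measures

**Sample entropy.** `sample_entropy(x, m = 2, r = 0.2)` is the negative
natural log of the conditional probability that two template sequences
matching within a tolerance for `m` consecutive points still match at
point `m + 1`, using the Chebyshev (max-coordinate) distance and
excluding self-matches: with `B` the number of matching `m`-template
pairs (i < j) and `A` the matching `(m+1)`-template pairs,
`SampEn = -ln(A/B)`. Lower values mean a more regular series. The
tolerance is `r` times the sample SD of the series — the established
convention for physiological signals — so the statistic is invariant
under affine rescaling. A constant series returns 0 (every template
matches); if no `(m+1)`-matches exist the result is `Inf`, a
distinguished "no matches" value that the group statistics later treat
as missing rather than capping it arbitrarily.

**Cross-sample entropy.** `cross_sample_entropy(x, y)` counts template
matches *across* two series, z-normalizing each first (IBI is in
seconds, RV in arbitrary units; the scales are incommensurate, so `r`
becomes a tolerance in SD units). Matches are counted over all ordered
(i, j) pairs, so the statistic is symmetric in its arguments. Larger
values mean fewer shared sub-patterns, i.e. more asynchrony; smaller
values mean stronger rhythm-depth synchronization. One property worth
knowing: because all cross-pairs are counted, not just simultaneous
ones, the statistic responds to *shared recurring patterns* far more
than to instantaneous correlation — two jointly Gaussian series with
correlation 0.9 but no repeating structure score almost the same as
independent ones. This shapes how the synthetic generator implements
coupling (below).

**Detrended fluctuation analysis.** `dfa(x)` integrates the series
(cumulative sum of deviations from the mean), partitions the profile at
each scale `s` into non-overlapping windows taken from both the start
and the end (`2*floor(n/s)` windows, so no data are wasted when `n` is
not a multiple of `s`), removes an order-1 polynomial trend from each
window by least squares, and computes the RMS residual `F(s)`. The
scaling exponent alpha is the OLS slope of `log F(s)` against `log s`.
Scales are 16 log-spaced integers from 4 to `n/4` (duplicates removed;
at least 6 must remain). Alpha is 0.5 for uncorrelated noise, above 0.5
for persistent long-range correlation, and about 1.5 for integrated
noise. Whether DFA should integrate the breath series first is
sometimes left unstated in applied work; this package uses the standard
profile integration, and its calibration tests rely on that convention
(alpha ≈ H for fractional Gaussian noise).

Per recording, `complexity_profile()` assembles: mean and CV of IBI and
RV (CV uses the n−1 sample SD), SampEn of each, DFA alpha of each, and
the IBI–RV cross-sample entropy (RV truncated to the IBI length, i.e.
the last RV value is dropped). Profiles from fewer than 100 breaths
trigger a validity warning, not an error.

## The synthetic generator and what it emulates

Every stage above needs an oracle. The generator builds recordings in
three layers, each with exact ground truth:

**Fractional Gaussian noise** (`generate_fgn`): synthesized by
Davies–Harte circulant embedding, which matches the target
autocovariance exactly rather than approximating it with an AR fit.
This matters because the DFA calibration (alpha within ±0.05 of H)
requires unbiased scaling across the whole window range; an
approximate synthesis would bias exactly the quantity under test.

**Breath process** (`generate_breath_series`): intervals are
`ibi_mean * (1 + ibi_cv * z)` and amplitudes `rv_mean * (1 + rv_cv *
y)`, where `z` and `y` are unit-variance innovations built from three
ingredients:

- independent fGn streams with the requested Hurst exponents;
- a shared fGn stream with weight `coupling_rho` (its Hurst exponent is
  the mean of the two series' exponents — a neutral choice that only
  matters when they differ);
- a shared deterministic period-3 cycle, blended in with weight
  `regularity` for the intervals and `coupling_rho * regularity` for
  the amplitudes. The blend is rescaled to unit SD, so `regularity`
  lowers entropy while leaving the mean and CV untouched; at
  `regularity = 1` the interval sequence is strictly periodic with
  sample entropy ~0 (a constant rhythm is obtained by additionally
  setting `ibi_cv = 0`).

The cycle is deliberately the *shared* regular component: as noted
above, cross-sample entropy responds to shared recurring sub-patterns,
so routing the regular rhythm into the amplitude series in proportion
to the coupling is what makes strongly coupled recordings measurably
synchronized. Keeping the amplitude's cycle weight below the
interval's also preserves the amplitude series' Hurst structure: a
dominant bounded periodic component would flatten its DFA slope toward
zero and mask the long-range correlation the generator is supposed to
plant. A period of 3 is the shortest that is non-trivial for `m = 2`
templates, which isolates the entropy effect cleanly.

Intervals are forced positive by flooring at `0.2 * ibi_mean`
(truncations are counted in an attribute); a floor rather than a
log-transform keeps the coupling construction linear. Sighs (deep
inspirations) occur with probability `sigh_rate` per breath and
multiply the amplitude by `sigh_amplitude_factor` (default 2.5; an
option lengthens the following interval as a post-sigh pause). The
default rate of 0.002/breath — roughly one sigh every four minutes at
2 Hz — is at the conservative end of rodent sigh rates; because the
entropy tolerance is SD-relative, sigh outliers inflate the amplitude
SD, and a much higher rate would coarsen the template matching enough
to wash out the fine-grained structure the other parameters control.

**Rendering** (`render_signal`): each breath becomes a raised-cosine
(or Gaussian) pulse peaking at the breath's ground-truth time with the
breath's RV as amplitude. Pulse width adapts to 90% of the smaller
neighbouring gap (capped at the mean gap), so pulses never overlap and
the signal maxima sit exactly on the ground truth. Gaussian
measurement noise, sinusoidal baseline drift, and gain-multiplied
artifact epochs are applied on top. The ground-truth series rides along
as an attribute, so detection accuracy can always be scored without
re-simulation.

**Cohorts** (`generate_cohort`): `control_like_spec()` uses
`ibi_hurst = 0.6`, `regularity = 0.1`, `coupling_rho = 0.2`,
`ibi_cv = 0.08`, `rv_hurst = 0.6`; `asthma_like_spec()` raises
`regularity` to 0.6, `ibi_cv` by 1.5x to 0.12, `rv_hurst` to 0.9 and
`coupling_rho` to 0.8, with identical means. These shifts reproduce,
qualitatively, the reported disease pattern: lower SampEn of IBI,
higher CV of IBI, higher DFA alpha of RV, lower cross-SampEn, and no
change in mean IBI or RV. No quantitative effect sizes are available
for these metrics (the source results are significance patterns, not
tabulated values), so the synthetic effect sizes are calibration
choices of this package, not measured ones. One known side effect:
with `rv_hurst = 0.9` and the shared cycle, SampEn of RV also drops
somewhat in the asthma-like group, whereas in the animal data it did
not change significantly; the effect-pattern report shows this row
honestly. Per-recording seeds are a deterministic hash of
`(master_seed, group label, index)`, so cohorts are bit-reproducible
from a single seed while recordings remain independent.

## Group statistics

`one_way_anova_bonferroni()` computes the omnibus F from the group sums
of squares and compares the reference group to every other group with
pooled-MSE two-sample t statistics on `N - k` degrees of freedom,
multiplying raw p-values by the number of comparisons (capped at 1).
`kruskal_dunn()` computes the tie-corrected Kruskal–Wallis H from
mid-ranks and Dunn's z statistics with the ties-adjusted pooled
variance, Bonferroni-adjusted across the pairwise set (matching the
parametric arm; Holm would be less conservative but mixing adjustment
styles across the two arms would make them incomparable).
`compare_groups(method = "auto")` screens the within-group residuals
with a Shapiro–Wilk test at the 0.05 level to choose between the two
routes — the source analyses used "ANOVA/Bonferroni or
Kruskal–Wallis/Dunn" without stating the per-metric choice, and a
normality screen mirrors that decision rule without guessing.
Non-finite metric values (e.g. undefined entropies) are excluded
pairwise with a warning stating the count, rather than imputed or
capped. `reproduce_effect_pattern()` evaluates the full
direction-and-significance pattern against a control group and returns
one row per (metric, case group) with the expectation, the observed
contrast, the adjusted p-value, and a consistency flag.

## Numerical choices and degenerate inputs

- Entropies: `length >= m + 2` is required; SD = 0 returns the
  closed-form 0; `A = 0` returns `Inf` with a warning.
- DFA: requires `4 <= min_scale < max_scale <= n/4` and at least 6
  distinct scales; zero-variance input is an error, not NaN.
- Peak detection: a flat signal returns an empty peak set (not an
  error); fewer than 3 peaks is an error when building a series.
- Ties: equal-height peak conflicts keep the earlier peak; equal
  window scores keep the earliest window; rank ties use mid-ranks with
  the standard corrections.
- The artifact score's amplitude term degrades gracefully when the MAD
  is zero (constant window: score 0).

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the full pipeline on
two groups of 10 recordings of 1500 s each (the analysis window is the
standard 1200 s, so each recording carries ~3000 breaths of which
~2400 enter the analysis) — the group size of the emulated study
design at a record length that exercises window selection. Estimator
calibrations use series of length 8192 averaged over 20 seeds; oracle
equivalence uses 200 random series up to length 200; the type-I
calibration simulates 1000 null cohorts at the metric-table level
(identical sampling distributions in every group), which is the level
at which the omnibus test operates.

## What passing tests do and do not show

The generator emulates the statistical skeleton of real recordings:
stochastic rhythm and depth with controllable entropy, long-range
correlation and coupling, sighs, drift, noise, and artifact epochs. It
does not emulate lung mechanics, CO2 dynamics, posture or activity
states, inspiratory/expiratory waveform asymmetry, or drug effects.
Passing the shipped checks therefore demonstrates that the estimators
are correct and calibrated on processes with known ground truth and
that the pipeline recovers planted effects of realistic size — not
that any particular biological effect size will be detectable in a
given animal experiment.

## A worked example

```{r example, eval = FALSE}
cfg <- synth_cohort_config(
  groups = list(saline = control_like_spec(), OVA = asthma_like_spec()),
  n_per_group = 10, record_duration = 1500, master_seed = 7)
res <- run_pipeline(generate_cohort(cfg))
reproduce_effect_pattern(res, control_label = "saline")
```
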