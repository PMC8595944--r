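---
title: "Spectral phenotyping and correlation networks for pediatric sleep EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral phenotyping and correlation networks for pediatric sleep EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osanet)
```

## Scope and model

`osanet` characterizes overnight sleep EEG in children along two
complementary axes — *activity* (relative spectral power, RP) and
*irregularity* (spectral entropy, SpecEn) — and relates them to
polysomnographic (PSG) variables and cognitive scores through bootstrap
partial-correlation networks, stratified by obstructive-sleep-apnea
severity (AHI ≤ 1 events/h: controls; 1 < AHI < 5: mild; AHI ≥ 5:
moderate/severe). This vignette records the methodological choices, their
assumptions, and what the synthetic-data verification does and does not
establish.

## Pre-processing

Four stages, in order:

1. **Common-average re-reference.** Each sample has the instantaneous
   cross-channel mean removed. This is idempotent and commutes with the
   (linear) filter; both properties are tested.
2. **Filtering.** A 0.1–70 Hz band-pass and a 60 Hz notch, both designed as
   Hamming-window FIR filters (orders 1000 and 500 at 200 Hz). The combined
   kernel is applied through its magnitude response in the frequency
   domain, which is an exactly zero-phase realization — no group delay, so
   epoch boundaries are not displaced — and costs O(n log n) on whole-night
   signals. Measured responses: −76 dB at 60 Hz, −79 dB at 90 Hz, ripple
   below 0.01 dB across 1–50 Hz. The circular wrap-around of the
   frequency-domain product affects only the outermost ~7.5 s of the
   recording, which edge trimming discards anyway.
3. **Epoch-adaptive artifact rejection.** The recording is cut into 30 s
   epochs (6000 samples, anchored at the first sample; a partial trailing
   epoch is dropped). Per channel, an epoch is flagged if its peak absolute
   amplitude exceeds `k_amp` (default 5) times the median per-epoch peak,
   or its power exceeds `k_pow` (default 10) times the median per-epoch
   power; an epoch is rejected if any channel flags it. The literature this
   step descends from does not publish its exact statistic, so the
   median-multiplier scheme here is an explicit, documented stand-in: it is
   adaptive per recording and channel, robust to heavy tails, and invariant
   to common rescaling (tested). Both multipliers are exposed in the
   configuration.
4. **Edge trimming.** The first and last `trim_minutes` (default 5) are
   rejected to exclude awake periods around lights-off/on. The amount is a
   free parameter; 5 min is a conservative default for whole-night
   recordings, and short test recordings use smaller values.

## Spectral estimation

The per-epoch PSD uses the Blackman–Tukey estimator with a rectangular lag
window spanning the full 6000-sample epoch. With a full-length rectangular
lag window the estimator is mathematically identical to the epoch
periodogram; this identity is the package's free oracle — the test suite
checks `epoch_psd()` against a direct DFT periodogram to 1e-8 relative.
Epoch PSDs are averaged over all kept epochs of the night, restricted to
the 0.1–70 Hz analysis range (content outside is filter artifact), and
normalized to unit sum (PSDn). At 200 Hz the grid step is 1/30 Hz and every
canonical band edge (0.1, 2, 4, 8, 10, 13, 16, 19, 30, 70 Hz) falls exactly
on a grid point.

Bands are half-open `[f1, f2)`, so the seven tiling bands partition the
analysis range with no double counting at shared edges and their relative
powers sum to one exactly. Sigma (10–16 Hz) intentionally overlaps alpha
and beta1; it is carried for its relation to sleep spindles.

**Spectral entropy** is Shannon entropy applied to the band-restricted
spectrum after renormalizing it to a unit-sum distribution, scaled by
`1/log N` (`N` = bins in the band, `0 log 0 = 0`). Renormalization is the
reading adopted here because it is the one under which the stated [0, 1]
range is attained for every band: without it, a band holding only a small
share of total power could never reach entropy 1 regardless of its shape.
The logarithm base cancels after the `1/log N` normalization; natural log
is used. Degenerate inputs are defined explicitly: a band with zero total
mass is an error (entropy undefined), a constant band maps to 1, a
single-line band to 0.

## Correlation networks

All 76 node variables (64 EEG features of one measure + 6 PSG + 6
cognitive) are compared by **partial Spearman correlation adjusted for age
and sex**: every variable — covariates included, sex as a 0/1 indicator —
is midrank-transformed, covariate effects are removed from the ranked
variables by least squares, and the Pearson correlation of the residuals is
taken. This residual form equals the classical recursive partial-correlation
formula on the Spearman matrix (tested against it) and extends cleanly to
the bootstrap.

To equalize effective sample size across groups of very different sizes,
each group's matrix is the entrywise **median of 1000 bootstrap runs**,
each run drawing 20 subjects with replacement and uniform probability and
computing all pairwise adjusted correlations within the draw (ranks and
residualization are recomputed inside each run; resampling first and
residualizing per run is the reading adopted where the alternative —
residualize once, then resample — was also defensible). The 2.5/97.5
percentiles accompany every entry. A variable can be constant within a
20-subject draw, leaving some correlations undefined in that run; such runs
are excluded from the aggregation entry-wise rather than imputed as zero,
and per-entry valid-run counts are reported, with entries defined in fewer
than half the runs flagged. Subjects are canonically ordered by id before
resampling so row order cannot perturb seeded results.

Networks keep edges with |median ρ| ≥ 0.30 (inclusive), preserving signed
weights; isolated nodes stay in the node set. Layout is Fruchterman–
Reingold, 500 iterations, attraction proportional to |ρ|, seeded.
**Modularity** is maximized on the absolute weights of the thresholded
graph — the paper-scale networks carry both signs and the partition should
treat a strong negative dependence as connectivity; the signed network is
preserved for display. The search is greedy agglomeration from singletons
followed by Kernighan–Lin refinement: full passes of locked single-node
moves in which the best available move is applied even when its immediate
gain is negative and the best intermediate state of the pass is kept. The
refinement matters: plain hill climbing stalls in local optima as small as
a 6-node path, while the KL pass reaches the exhaustive-search optimum on
every ≤ 8-node graph in the test suite (checked to 1e-9, with
`igraph::modularity` as the independent scorer). An empty edge set is
defined as singleton modules with Q = 0. Centrality uses strength (sum of
incident |ρ|), and closeness/betweenness on distances 1/|ρ|; a node
reaching `r` of the other `n−1` nodes gets closeness
`(r/(n−1)) · (r/Σd)`, so isolated nodes score 0.

## Synthetic data: what it emulates

The generator exists so that every stage has a recoverable ground truth.

**EEG.** Each channel is synthesized in the frequency domain: a Hermitian
complex-Gaussian spectrum shaped `1/f^slope` (default slope 1) inside each
tiling band, with the realized coefficients rescaled so each band's share
of total power equals its prescribed fraction *exactly*. The inverse
transform is a sum of independent band-limited Gaussian processes with
exact per-band power — total power 1600 µV² (40 µV RMS) by default, delta-
dominant fractions (0.45/0.20/0.14/0.08/0.05/0.04/0.04 across
δ₁/δ₂/θ/α/β₁/β₂/γ). Frequency-domain synthesis was chosen over
forward-backward IIR band-pass filtering after the latter proved
numerically unstable for the 0.1–2 Hz band at a 200 Hz rate (an order-4
Butterworth band-pass there has poles effectively on the unit circle) and
leaked several percent of power across band edges at stable orders,
defeating exact power control. A slow-oscillation-like peak is a
random-phase sinusoid at a configurable frequency and power fraction;
severity presets plant it at 0.75/0.417/0.267 Hz with power fraction
0.10/0.14/0.18 of background and shift the band fractions slightly further
toward δ₁, emulating the slowing-and-growing low-frequency peak of
group-median spectra as severity increases. Artifacts are raised-cosine
bursts of 0.5–2 s at a multiple (default 8×) of background RMS, placed by a
Poisson process and applied across channels.

**Cohort.** Subjects are drawn per severity group with a Gaussian copula:
targets are interpreted as Spearman correlations and converted through
`ρ_P = 2 sin(πρ_S/6)` before the copula draw, because the downstream
statistic is rank-based. Marginals are parameterized by median and
quartiles matched to published clinical summaries per group — log-normal
for positive skewed rates (AHI, AR, AS, WASO), truncated normal for
bounded scores — with AHI truncated to its group's severity interval so
labels and values can never disagree. Sex is Bernoulli(0.57 male), age a
truncated normal within 5–9 years. The default latent correlation preset
(AHI–AR +0.6, AHI–nadir −0.5, cognitive inter-correlations +0.4,
AHI–cognitive −0.25, etc.) is a *free parameter* of the generator: the
source material publishes only marginal summaries, so these magnitudes are
modest clinically plausible choices, not estimates, and any analysis that
depends on them should set them explicitly.

**What passing tests show — and do not.** Plant-and-recover tests
demonstrate that the estimators recover known spectral fractions, peaks,
correlations and block structure under Gaussian, stationary, hypnogram-free
conditions. Real sleep EEG is non-stationary across sleep stages, has
spindles, K-complexes and REM/NREM cycling, and its artifacts are not
raised-cosine bursts; the generator deliberately reproduces only the
spectral-statistical structure the analysis consumes. Passing therefore
validates the pipeline's correctness, not any clinical claim about real
recordings.

## Numerical choices and problem sizes

- Band bins, threshold comparisons and search bands use half-open
  intervals with a 1e-9 guard against floating-point edge effects; the
  |ρ| ≥ 0.30 threshold is inclusive.
- Undefined correlations return `NA` (a signal distinct from an error);
  `n < 4` observations or an empty epoch mask are errors.
- Feature tables serialize through `write_feature_table()` /
  `read_feature_table()` at 17 significant digits with a correctly-rounded
  parser, so values round-trip bit-exactly and pipeline reruns are
  checksum-identical.
- One master seed drives everything; per-subject and per-(group × measure)
  substreams are derived by fixed offsets, so adding a group or subject
  does not perturb the others' streams.
- Test problem sizes are chosen to exercise the estimators at meaningful
  precision while keeping the suite quick: 10-minute to 1-hour synthetic
  recordings (whole-night duration is a configuration choice, not a code
  path difference), cohorts of 20–294, bootstrap sizes of 200–1000 runs.
  The end-to-end determinism check runs 30 subjects × 10 min twice at the
  full 1000-run bootstrap.

## Known limitations

- Sleep staging, spindle/K-complex modeling, REM/NREM-resolved spectra and
  bad-channel interpolation are out of scope by design.
- The artifact-rejection statistic is a documented stand-in for an
  unpublished method (see above); its defaults were chosen for robustness,
  not fitted to data.
- Closeness centrality on partially connected graphs follows one of
  several reasonable conventions (documented above); comparisons with
  other software should account for this.
- With 20-subject groups resampled by themselves, the bootstrap median
  cannot beat the sampling error of the group estimate (~0.15 sd at
  ρ = 0.6, n = 20); the percentile interval is the honest uncertainty
  statement in that regime.
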