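# osanet

Overnight-EEG spectral phenotyping and correlation networks for pediatric
obstructive sleep apnea (OSA).

## The problem

Pediatric OSA disturbs sleep and is associated with cognitive morbidity, but
how it reshapes the overnight EEG — and whether those changes track
polysomnographic burden and cognitive performance — is not visible from any
single summary statistic. `osanet` implements a two-step analysis for
multi-channel overnight sleep EEG (8 channels, 200 Hz):

1. **Spectral phenotyping.** After four-stage pre-processing
   (common-average re-reference; zero-phase 0.1–70 Hz band-pass plus 60 Hz
   notch, Hamming-window FIR; epoch-adaptive artifact rejection; edge
   trimming), each channel's whole-night spectrum is estimated by averaging
   Blackman–Tukey PSDs of non-overlapping 30 s epochs (rectangular window,
   6000 samples) and normalized to unit sum (PSDn). Two measures are taken
   per channel in each band δ₁ (0.1–2 Hz), δ₂ (2–4), θ (4–8), α (8–13),
   σ (10–16), β₁ (13–19), β₂ (19–30), γ (30–70):

   - *activity*, the relative power
     `RP = Σ_{f1≤f<f2} PSDn(f)`;
   - *irregularity*, the spectral entropy
     `SpecEn = −(1/log N) Σ p(f) log p(f)` with `p` the band-restricted,
     renormalized PSDn and `N` the number of bins in the band, so
     `SpecEn ∈ [0, 1]` (0 = a single spectral line, 1 = flat/white).

2. **Correlation networks.** Per severity group (controls AHI ≤ 1 e/h,
   mild 1 < AHI < 5, moderate/severe AHI ≥ 5) and per measure, the 64 EEG
   features (8 bands × 8 channels), 6 PSG variables and 6 cognitive scores
   form 76 nodes. Edges are bootstrap-median partial Spearman correlations
   adjusted for age and sex (1000 runs of 20 subjects drawn with
   replacement; 2.5/97.5 percentile companions retained), thresholded at
   |ρ| ≥ 0.30. Networks are laid out with Fruchterman–Reingold (500
   iterations), partitioned by maximizing Newman modularity (greedy
   agglomeration with Kernighan–Lin refinement on absolute weights), and
   annotated with strength/closeness/betweenness centrality and radar-style
   band summaries.

A synthetic-data module generates EEG (band-limited colored noise with
exact planted band-power fractions, an optional slow-oscillation-like
spectral peak, artifact transients) and cohort tables (Gaussian copula with
clinical-table marginals) so every stage can be verified against a known
ground truth — the original clinical recordings are not public.

## Worked example

```r
library(osanet)
library(dplyr)

# a small synthetic cohort with severity-dependent EEG
cohort <- synthesize_cohort(cohort_synthesis_spec(
  group_sizes = c(8, 8, 8), eeg = list(duration = 600), seed = 1))

# per-subject spectra after the four-stage pre-processing
spectra <- lapply(seq_len(nrow(cohort)), function(i) {
  rec <- synthesize_eeg(cohort$eeg_spec[[i]])
  pp <- preprocess_eeg(rec, trim_minutes = 1)
  epoch_psd(pp$rec, pp$mask)
})
names(spectra) <- cohort$subject_id

# slow-oscillation peak per severity group
group_median_spectrum(spectra, cohort) |> find_spectral_peak()
#> # A tibble: 3 × 4
#>   group      peak_frequency peak_amplitude at_boundary
#>   <chr>               <dbl>          <dbl> <lgl>
#> 1 controls            0.733         0.0436 FALSE
#> 2 mild                0.433         0.0659 FALSE
#> 3 mod_severe          0.267         0.160  FALSE

# bootstrap partial-Spearman network for one group and measure
features <- build_feature_table(cohort, spectra)
mat <- bootstrap_matrix(features, group = "mod_severe", measure = "specen",
                        n_boot = 1000, n_subsample = 20, seed = 2)
net <- threshold_network(mat, 0.30) |> annotate_network(seed = 3)
glance(net)
#> # A tibble: 1 × 8
#>   group      measure n_nodes n_edges density threshold n_modules     Q
#>   <chr>      <chr>     <dbl>   <dbl>   <dbl>     <dbl>     <int> <dbl>
#> 1 mod_severe specen       76    1581   0.555       0.3         3 0.199
```

The peak table shows the planted slow-oscillation regime recovered from the
group-median spectra: the peak slows (0.75 → 0.27 Hz) and grows as severity
increases. The network summary gives the edge density above the |ρ| ≥ 0.30
threshold, the number of modules, and the maximized modularity Q for the
chosen group × measure.

`run_pipeline(run_config(...))` (or a YAML config via `read_run_config()`)
chains synthesize → preprocess → features → network → report into a run
directory with EDF files, masks, a lossless `features.csv`, correlation
matrices (median and percentile companions), annotated network JSON/GraphML
exports, radar summaries, a clinical-style cohort table, and a manifest
with the configuration hash and per-stage counts. Reruns with the same
configuration reproduce every numeric output checksum-identically.

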