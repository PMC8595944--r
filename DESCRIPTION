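Package: osanet
Title: Overnight EEG Spectral Phenotyping and Correlation Networks for
    Pediatric Sleep Apnea
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize the overnight sleep electroencephalogram
    of children with obstructive sleep apnea and relate it to polysomnographic
    variables and cognitive scores. Implements the full analysis pipeline:
    common-average re-referencing, zero-phase Hamming-window filtering,
    epoch-adaptive artifact rejection, Blackman-Tukey spectral estimation with
    whole-night averaging and unit-sum normalization, band-wise relative power
    (activity) and spectral entropy (irregularity), group-median spectra with
    slow-oscillation peak localization, bootstrap partial Spearman correlation
    networks (adjusted for age and sex) with inclusive absolute-correlation
    thresholding, Fruchterman-Reingold layout, Newman modularity with
    Kernighan-Lin refinement, strength/closeness/betweenness centrality, and
    radar-style band summaries. A synthetic-data module generates EEG as
    band-limited colored noise with planted spectral structure and cohort
    tables via a Gaussian copula with Table-style marginals, so every stage is
    verifiable against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
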