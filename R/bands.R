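#' Canonical sleep-EEG frequency bands
#'
#' The eight analysis bands: delta1 (0.1--2 Hz), delta2 (2--4), theta (4--8),
#' alpha (8--13), sigma (10--16), beta1 (13--19), beta2 (19--30) and gamma
#' (30--70). Bands are half-open intervals `[f1, f2)` so that the seven
#' "tiling" bands (all except sigma) partition the 0.1--70 Hz analysis range
#' exactly with no double-counting at the shared edges. Sigma deliberately
#' overlaps alpha and beta1: it is carried separately because of its relation
#' to sleep spindles.
#'
#' @param tiling If `TRUE`, return only the seven non-overlapping bands
#'   (sigma excluded), whose relative powers sum to 1.
#' @return A tibble with columns `band`, `f1`, `f2` (Hz).
#' @export
#' @examples
#' eeg_bands()
#' eeg_bands(tiling = TRUE)
eeg_bands <- function(tiling = FALSE) {
  b <- tibble::tibble(
    band = c("delta1", "delta2", "theta", "alpha", "sigma", "beta1", "beta2", "gamma"),
    f1   = c(0.1, 2, 4, 8, 10, 13, 19, 30),
    f2   = c(2, 4, 8, 13, 16, 19, 30, 70)
  )
  if (tiling) b <- b[b$band != "sigma", ]
  b
}

# names of the seven tiling bands, in frequency order
tiling_band_names <- function() eeg_bands(tiling = TRUE)$band

# analysis range used for total-power normalization (band-pass range)
analysis_range <- function() c(0.1, 70)

validate_band <- function(band) {
  if (is.character(band) && length(band) == 1L) {
    tab <- eeg_bands()
    if (!band %in% tab$band) abort_field("band", sprintf("unknown band name '%s'", band))
    return(tab[tab$band == band, ])
  }
  if (is.numeric(band) && length(band) == 2L) {
    if (!(band[1] < band[2])) abort_field("band", "f1 must be < f2")
    f1 <- band[1]; f2 <- band[2]
    return(tibble::tibble(band = sprintf("%g-%g", f1, f2), f1 = f1, f2 = f2))
  }
  if (is.data.frame(band) && all(c("band", "f1", "f2") %in% names(band))) {
    if (any(band$f1 >= band$f2)) abort_field("band", "f1 must be < f2")
    return(tibble::as_tibble(band[, c("band", "f1", "f2")]))
  }
  abort_field("band", "must be a band name, a numeric c(f1, f2), or a bands tibble")
}

#' Default PSG and cognitive variable names
#'
#' The six polysomnographic variables (apnea--hypopnea index AHI, respiratory
#' arousal index AR, spontaneous arousal index AS, overnight minimum oxygen
#' saturation NadirSpO2, wake after sleep onset WASO, sleep efficiency
#' SleepEff) and the six cognitive scores (DAS, PPVT3, EVT, DesCop, PhPro,
#' Tow) that enter the correlation networks alongside the EEG features.
#'
#' @return A character vector of 6 names.
#' @export
psg_variables <- function() c("AHI", "AR", "AS", "NadirSpO2", "WASO", "SleepEff")

#' @rdname psg_variables
#' @export
cognitive_variables <- function() c("DAS", "PPVT3", "EVT", "DesCop", "PhPro", "Tow")

# ordered severity group labels
severity_levels <- function() c("controls", "mild", "mod_severe")
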