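#' Normalized whole-night spectrum container
#'
#' Per-channel averaged power spectral density on a fixed frequency grid,
#' normalized to unit sum over the 0.1--70 Hz analysis range. Construct with
#' [epoch_psd()] for real signals, or directly (e.g. for analytic fixtures).
#'
#' @param frequencies Frequency grid in Hz (ascending, inside the analysis
#'   range).
#' @param psdn Channels x frequencies matrix of nonnegative values; each row
#'   is renormalized to unit sum.
#' @param channel_labels Channel names (one per row).
#' @param n_epochs_used Number of epochs averaged.
#' @param subject_id Identifier.
#' @return An object of class `eeg_spectrum`.
#' @export
eeg_spectrum <- function(frequencies, psdn, channel_labels = NULL,
                         n_epochs_used = NA_integer_, subject_id = "subject") {
  if (is.vector(psdn)) psdn <- matrix(psdn, nrow = 1)
  if (ncol(psdn) != length(frequencies)) {
    abort_field("psdn", "number of columns must match the frequency grid")
  }
  if (any(psdn < 0)) abort_field("psdn", "values must be nonnegative")
  if (is.unsorted(frequencies, strictly = TRUE)) {
    abort_field("frequencies", "must be strictly increasing")
  }
  tot <- rowSums(psdn)
  if (any(tot <= 0)) abort_field("psdn", "each channel needs positive total power")
  psdn <- psdn / tot
  if (is.null(channel_labels)) channel_labels <- sprintf("ch%d", seq_len(nrow(psdn)))
  rownames(psdn) <- channel_labels
  structure(
    list(frequencies = as.numeric(frequencies), psdn = psdn,
         channel_labels = as.character(channel_labels),
         n_epochs_used = as.integer(n_epochs_used),
         subject_id = as.character(subject_id)),
    class = "eeg_spectrum"
  )
}

#' @export
print.eeg_spectrum <- function(x, ...) {
  cat(sprintf("<eeg_spectrum> subject '%s': %d channels, %d bins (%.4g-%.4g Hz), %s epochs\n",
              x$subject_id, nrow(x$psdn), length(x$frequencies),
              min(x$frequencies), max(x$frequencies),
              ifelse(is.na(x$n_epochs_used), "?", x$n_epochs_used)))
  invisible(x)
}

#' Tidy a normalized spectrum
#'
#' @param x An [eeg_spectrum()].
#' @param ... Unused.
#' @return A tibble with columns `subject_id`, `channel`, `frequency`, `psdn`.
#' @method tidy eeg_spectrum
#' @export
tidy.eeg_spectrum <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id,
    channel = rep(x$channel_labels, each = length(x$frequencies)),
    frequency = rep(x$frequencies, times = nrow(x$psdn)),
    psdn = as.vector(t(x$psdn))
  )
}

#' Whole-night normalized spectrum by epoch-averaged Blackman--Tukey PSD
#'
#' Estimates each kept epoch's PSD by the Blackman--Tukey route with a
#' rectangular lag window spanning the full epoch, which is mathematically
#' identical to the epoch periodogram (this identity is exploited as a test
#' oracle). Epoch PSDs are averaged per channel over the whole night, the
#' average is restricted to the 0.1--70 Hz analysis range, and divided by its
#' total power so each channel's spectrum sums to one. With 6000-sample
#' epochs at 200 Hz the grid resolution is 1/30 Hz and every canonical band
#' edge falls exactly on a grid point.
#'
#' @param rec An [eeg_recording()].
#' @param mask Optional `epoch_mask`; `NULL` keeps every complete epoch.
#' @param epoch_length Epoch length in samples when `mask` is `NULL`
#'   (default 6000).
#' @return An [eeg_spectrum()].
#' @export
epoch_psd <- function(rec, mask = NULL, epoch_length = 6000) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(mask)) {
    n_ep <- floor(ncol(rec$samples) / epoch_length)
    mask <- new_epoch_mask(epoch_length, rep(TRUE, n_ep))
  }
  stopifnot(inherits(mask, "epoch_mask"))
  L <- mask$epoch_length
  kept <- which(mask$keep)
  if (length(kept) == 0) {
    rlang::abort(sprintf("subject '%s': no kept epochs to average", rec$subject_id),
                 class = "osanet_no_epochs_error")
  }
  fs <- rec$sampling_rate
  freqs_all <- (seq_len(L) - 1) * fs / L
  rng <- analysis_range()
  sel <- which(freqs_all >= rng[1] - 1e-12 & freqs_all < rng[2] - 1e-12 &
               freqs_all <= fs / 2)
  acc <- matrix(0, nrow = nrow(rec$samples), ncol = length(sel))
  for (e in kept) {
    seg <- rec$samples[, ((e - 1) * L + 1):(e * L), drop = FALSE]
    for (ch in seq_len(nrow(seg))) {
      P <- Mod(fft(seg[ch, ]))^2 / L   # periodogram = full-lag Blackman-Tukey
      acc[ch, ] <- acc[ch, ] + P[sel]
    }
  }
  acc <- acc / length(kept)
  eeg_spectrum(freqs_all[sel], acc, rec$channel_labels,
               n_epochs_used = length(kept), subject_id = rec$subject_id)
}

# indices of spectrum bins inside half-open band [f1, f2)
band_bins <- function(spectrum, f1, f2) {
  which(spectrum$frequencies >= f1 - 1e-9 & spectrum$frequencies < f2 - 1e-9)
}

#' Relative spectral power per band (EEG activity)
#'
#' The sum of the normalized spectrum over a half-open band `[f1, f2)`.
#' Because the spectrum is unit-sum over the analysis range, relative powers
#' of the seven tiling bands partition 1 exactly.
#'
#' @param spectrum An [eeg_spectrum()].
#' @param bands A band name, a numeric `c(f1, f2)`, or a bands tibble
#'   (default: all eight canonical bands from [eeg_bands()]).
#' @return A tibble with columns `subject_id`, `channel`, `band`, `rp`.
#' @export
#' @examples
#' s <- eeg_spectrum((3:2099) / 30, rep(1, 2097))
#' relative_power(s, "delta2")$rp  # flat spectrum: share of bins in 2-4 Hz
relative_power <- function(spectrum, bands = eeg_bands()) {
  stopifnot(inherits(spectrum, "eeg_spectrum"))
  bands <- validate_band(bands)
  check_bands_on_grid(spectrum, bands)
  purrr::pmap_dfr(bands, function(band, f1, f2) {
    idx <- band_bins(spectrum, f1, f2)
    tibble::tibble(subject_id = spectrum$subject_id,
                   channel = spectrum$channel_labels,
                   band = band,
                   rp = unname(rowSums(spectrum$psdn[, idx, drop = FALSE])))
  })
}

#' Spectral entropy per band (EEG irregularity)
#'
#' Shannon entropy of the band-restricted normalized spectrum. The
#' within-band values are renormalized to a unit-sum distribution `p`, then
#' `SpecEn = -(1/log N) * sum(p log p)` where `N` is the number of grid bins
#' in the band and `0 log 0 = 0`. The result lies in `[0, 1]`: 0 when a
#' single spectral component carries all the band's power (a pure sinusoid),
#' 1 when power is spread exactly uniformly (white noise). Invariant to
#' positive rescaling of the spectrum.
#'
#' @inheritParams relative_power
#' @return A tibble with columns `subject_id`, `channel`, `band`, `specen`.
#' @export
spectral_entropy <- function(spectrum, bands = eeg_bands()) {
  stopifnot(inherits(spectrum, "eeg_spectrum"))
  bands <- validate_band(bands)
  check_bands_on_grid(spectrum, bands)
  purrr::pmap_dfr(bands, function(band, f1, f2) {
    idx <- band_bins(spectrum, f1, f2)
    N <- length(idx)
    se <- apply(spectrum$psdn[, idx, drop = FALSE], 1, function(p) {
      tot <- sum(p)
      if (tot <= 0) {
        rlang::abort(sprintf("band '%s': zero within-band power, entropy undefined", band),
                     class = "osanet_entropy_error")
      }
      p <- p / tot
      nz <- p > 0
      if (N <= 1) return(0)
      -sum(p[nz] * log(p[nz])) / log(N) + 0  # + 0 normalizes IEEE -0
    })
    tibble::tibble(subject_id = spectrum$subject_id,
                   channel = spectrum$channel_labels,
                   band = band, specen = unname(se))
  })
}

check_bands_on_grid <- function(spectrum, bands) {
  f <- spectrum$frequencies
  bad <- bands$f1 > max(f) | bands$f2 < min(f)
  if (any(bad)) {
    abort_field("band", sprintf("band(s) %s outside the spectrum grid (%.4g-%.4g Hz)",
                                paste(bands$band[bad], collapse = ", "), min(f), max(f)))
  }
  invisible(TRUE)
}

#' Group-median normalized spectra
#'
#' For each subject the normalized spectrum is averaged across channels;
#' per severity group the median and 25/75% quartiles are then taken at each
#' frequency, yielding the group-level summary curves from which the
#' slow-oscillation peak is localized.
#'
#' @param spectra Named list of [eeg_spectrum()] objects keyed by subject id,
#'   or keyed implicitly by each spectrum's `subject_id`.
#' @param groups Either a named character/factor vector of group labels keyed
#'   by subject id, or a data frame with `subject_id` and `group` columns.
#' @return A tibble with columns `group`, `frequency`, `median`, `q25`, `q75`
#'   and `n_subjects`.
#' @export
group_median_spectrum <- function(spectra, groups) {
  if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups$group), groups$subject_id)
  }
  if (is.null(names(spectra))) {
    names(spectra) <- vapply(spectra, function(s) s$subject_id, character(1))
  }
  ids <- intersect(names(spectra), names(groups))
  if (length(ids) == 0) abort_field("groups", "no subjects shared between spectra and groups")
  ref_freq <- spectra[[ids[1]]]$frequencies
  per_subj <- purrr::map_dfr(ids, function(id) {
    s <- spectra[[id]]
    if (length(s$frequencies) != length(ref_freq) ||
        max(abs(s$frequencies - ref_freq)) > 1e-9) {
      abort_field("spectra", sprintf("subject '%s' is on a different frequency grid", id))
    }
    tibble::tibble(subject_id = id, group = unname(groups[id]),
                   frequency = ref_freq, psdn = colMeans(s$psdn))
  })
  counts <- per_subj %>% dplyr::distinct(.data$subject_id, .data$group) %>%
    dplyr::count(.data$group, name = "n_subjects")
  if (any(counts$n_subjects < 1)) abort_field("groups", "empty group")
  per_subj %>%
    dplyr::group_by(.data$group, .data$frequency) %>%
    dplyr::summarise(median = median(.data$psdn),
                     q25 = unname(quantile(.data$psdn, 0.25)),
                     q75 = unname(quantile(.data$psdn, 0.75)),
                     .groups = "drop") %>%
    dplyr::left_join(counts, by = "group") %>%
    dplyr::arrange(.data$group, .data$frequency)
}

#' Locate a spectral peak in a summary curve
#'
#' Argmax of the curve inside a search band (half-open `[f1, f2)`),
#' typically used to localize the slow-oscillation peak in the group-median
#' spectrum. A peak landing on the search-band edge is flagged as a boundary
#' hit (e.g. a monotone curve has no interior peak).
#'
#' @param curve A tibble with `frequency` and a value column; if a `group`
#'   column is present, the peak is located per group.
#' @param search_band Numeric `c(f1, f2)` in Hz (default `c(0.2, 1.2)`, the
#'   slow-oscillation range).
#' @param value_col Name of the value column (default `"median"`).
#' @return A tibble with columns (`group`,) `peak_frequency`,
#'   `peak_amplitude`, `at_boundary`.
#' @export
find_spectral_peak <- function(curve, search_band = c(0.2, 1.2), value_col = "median") {
  stopifnot(is.data.frame(curve), all(c("frequency", value_col) %in% names(curve)))
  if (length(search_band) != 2 || search_band[1] >= search_band[2]) {
    abort_field("search_band", "must be increasing c(f1, f2)")
  }
  one <- function(d) {
    idx <- which(d$frequency >= search_band[1] - 1e-9 & d$frequency < search_band[2] - 1e-9)
    if (length(idx) == 0) abort_field("search_band", "no grid frequencies inside the search band")
    v <- d[[value_col]][idx]
    k <- idx[which.max(v)]
    tibble::tibble(peak_frequency = d$frequency[k],
                   peak_amplitude = d[[value_col]][k],
                   at_boundary = k == idx[1] | k == idx[length(idx)])
  }
  if ("group" %in% names(curve)) {
    curve %>% dplyr::group_by(.data$group) %>% dplyr::group_modify(~ one(.x)) %>% dplyr::ungroup()
  } else {
    one(curve)
  }
}
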