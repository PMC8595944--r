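#' Specification for a synthetic EEG recording
#'
#' Describes a multi-channel synthetic sleep-EEG signal: a sum of independent
#' band-limited Gaussian processes with prescribed power fractions over the
#' seven tiling bands, shaped by a `1/f^slope` broadband floor, plus an
#' optional narrowband low-frequency peak (emulating the slow-oscillation
#' spectral peak) and Poisson-placed high-amplitude artifact transients.
#'
#' @param duration Recording length in seconds (>= 60).
#' @param n_channels Number of channels (default 8, the standard sleep
#'   montage F3, F4, C3, C4, O1, O2, T3, T4).
#' @param sampling_rate Sampling rate in Hz (default 200).
#' @param band_power_fractions Named numeric vector over (a subset of) the
#'   seven tiling bands (`delta1`, `delta2`, `theta`, `alpha`, `beta1`,
#'   `beta2`, `gamma`); must sum to 1 within 1e-9.
#' @param background_exponent Slope of the `1/f^slope` spectral floor shaping
#'   each band-limited component (default 1, pink).
#' @param peak_frequency Center frequency (Hz) of the optional narrowband
#'   peak, inside `[0.1, 70]`, or `NULL` for none.
#' @param peak_relative_amplitude Power of the peak component as a fraction
#'   of total background power (default 0.12 when a peak is requested).
#' @param artifact_rate Expected artifact transients per hour (default 0).
#' @param artifact_amplitude_factor Artifact burst amplitude as a multiple of
#'   the background RMS (default 8).
#' @param total_power Total background power in microvolts squared (default
#'   1600, i.e. 40 uV RMS).
#' @param subject_id Identifier carried into the recording.
#' @param seed Integer seed; the same spec with the same seed synthesizes a
#'   bit-identical signal.
#' @return An object of class `eeg_synthesis_spec`.
#' @seealso [synthesize_eeg()]
#' @export
eeg_synthesis_spec <- function(duration,
                               n_channels = 8,
                               sampling_rate = 200,
                               band_power_fractions = default_band_fractions(),
                               background_exponent = 1,
                               peak_frequency = NULL,
                               peak_relative_amplitude = if (is.null(peak_frequency)) 0 else 0.12,
                               artifact_rate = 0,
                               artifact_amplitude_factor = 8,
                               total_power = 1600,
                               subject_id = "synthetic",
                               seed = NULL) {
  assert_scalar_number(duration, "duration", lower = 60)
  assert_scalar_number(n_channels, "n_channels", lower = 1)
  assert_scalar_number(sampling_rate, "sampling_rate", lower = 2 * analysis_range()[2] + 1e-9)
  assert_scalar_number(background_exponent, "background_exponent", lower = 0, upper = 4)
  assert_scalar_number(artifact_rate, "artifact_rate", lower = 0)
  assert_scalar_number(artifact_amplitude_factor, "artifact_amplitude_factor", lower = 0)
  assert_scalar_number(total_power, "total_power", lower = 1e-12)
  assert_scalar_number(peak_relative_amplitude, "peak_relative_amplitude", lower = 0)

  if (is.null(names(band_power_fractions)) ||
      !all(names(band_power_fractions) %in% tiling_band_names())) {
    abort_field("band_power_fractions", sprintf(
      "names must be a subset of {%s}", paste(tiling_band_names(), collapse = ", ")))
  }
  if (any(band_power_fractions < 0) || any(band_power_fractions > 1)) {
    abort_field("band_power_fractions", "values must lie in [0, 1]")
  }
  if (abs(sum(band_power_fractions) - 1) > 1e-9) {
    abort_field("band_power_fractions", sprintf(
      "values must sum to 1 (got %.12f)", sum(band_power_fractions)))
  }
  if (!is.null(peak_frequency)) {
    assert_scalar_number(peak_frequency, "peak_frequency", lower = 0.1, upper = 70)
  }
  if (!is.null(seed)) assert_scalar_number(seed, "seed")

  structure(
    list(duration = duration, n_channels = as.integer(n_channels),
         sampling_rate = sampling_rate,
         band_power_fractions = band_power_fractions,
         background_exponent = background_exponent,
         peak_frequency = peak_frequency,
         peak_relative_amplitude = peak_relative_amplitude,
         artifact_rate = artifact_rate,
         artifact_amplitude_factor = artifact_amplitude_factor,
         total_power = total_power,
         subject_id = as.character(subject_id),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "eeg_synthesis_spec"
  )
}

#' Default band-power fractions for synthetic sleep EEG
#'
#' Delta-dominant fractions over the seven tiling bands, emulating the
#' low-frequency weighting of pediatric sleep EEG.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_band_fractions <- function() {
  c(delta1 = 0.45, delta2 = 0.20, theta = 0.14, alpha = 0.08,
    beta1 = 0.05, beta2 = 0.04, gamma = 0.04)
}

#' Synthesize a multi-channel EEG recording
#'
#' Generates each channel independently in the frequency domain: a Hermitian
#' complex-Gaussian spectrum is shaped by the `1/f^slope` floor, and within
#' each requested band the realized Fourier coefficients are rescaled so the
#' band's share of total power equals its prescribed fraction exactly. The
#' inverse transform is therefore a sum of independent band-limited Gaussian
#' processes with exact per-band power. A narrowband peak is added as a
#' random-phase sinusoid, and artifact transients as raised-cosine-windowed
#' bursts (0.5--2 s) at a multiple of the background RMS, placed by a Poisson
#' process and applied to all channels simultaneously (movement-like).
#'
#' @param spec An [eeg_synthesis_spec()].
#' @return An [eeg_recording()]. Reproducible: the same spec and seed yield a
#'   bit-identical signal.
#' @export
#' @examples
#' spec <- eeg_synthesis_spec(duration = 60, n_channels = 2, seed = 1)
#' rec <- synthesize_eeg(spec)
#' rec
synthesize_eeg <- function(spec) {
  if (!inherits(spec, "eeg_synthesis_spec")) {
    abort_field("spec", "must be an eeg_synthesis_spec")
  }
  fs <- spec$sampling_rate
  n <- round(spec$duration * fs)
  with_seed(spec$seed, {
    bands <- eeg_bands(tiling = TRUE)
    bands <- bands[bands$band %in% names(spec$band_power_fractions), ]
    x <- matrix(0, nrow = spec$n_channels, ncol = n)
    for (ch in seq_len(spec$n_channels)) {
      x[ch, ] <- synth_channel(n, fs, bands, spec$band_power_fractions,
                               spec$background_exponent, spec$total_power)
      if (!is.null(spec$peak_frequency) && spec$peak_relative_amplitude > 0) {
        amp <- sqrt(2 * spec$peak_relative_amplitude * spec$total_power)
        phase <- runif(1, 0, 2 * pi)
        tt <- (seq_len(n) - 1) / fs
        x[ch, ] <- x[ch, ] + amp * sin(2 * pi * spec$peak_frequency * tt + phase)
      }
    }
    if (spec$artifact_rate > 0) {
      x <- add_artifacts(x, fs, spec$artifact_rate, spec$artifact_amplitude_factor,
                         sqrt(spec$total_power))
    }
    eeg_recording(x, fs, default_channels_n(spec$n_channels), spec$subject_id)
  })
}

default_channels_n <- function(k) {
  std <- default_channels()
  if (k <= length(std)) std[seq_len(k)] else c(std, sprintf("EXT%d", seq_len(k - length(std))))
}

# one channel of band-limited 1/f-shaped Gaussian noise with exact band powers
synth_channel <- function(n, fs, bands, fractions, slope, total_power) {
  freqs <- (seq_len(n) - 1) * fs / n          # DFT bin frequencies
  half <- 2:(floor((n - 1) / 2) + 1)          # positive-frequency bins (no DC/Nyquist)
  f_pos <- freqs[half]
  coef <- complex(real = rnorm(length(half)), imaginary = rnorm(length(half)))
  coef <- coef * f_pos^(-slope / 2)
  spec_full <- complex(real = numeric(n), imaginary = numeric(n))
  for (b in seq_len(nrow(bands))) {
    idx <- which(f_pos >= bands$f1[b] & f_pos < bands$f2[b])
    if (length(idx) == 0) next
    target <- fractions[[bands$band[b]]] * total_power
    realized <- 2 * sum(Mod(coef[idx])^2) / n^2
    scale <- if (realized > 0) sqrt(target / realized) else 0
    spec_full[half[idx]] <- coef[idx] * scale
  }
  # Hermitian symmetry -> real signal
  spec_full[n + 2 - half] <- Conj(spec_full[half])
  Re(fft(spec_full, inverse = TRUE)) / n
}

# Poisson-placed raised-cosine bursts applied across all channels
add_artifacts <- function(x, fs, rate_per_hour, amp_factor, background_rms) {
  n <- ncol(x)
  duration_h <- n / fs / 3600
  k <- rpois(1, rate_per_hour * duration_h)
  if (k == 0) return(x)
  centers <- runif(k, 0, n / fs)
  for (i in seq_len(k)) {
    dur <- runif(1, 0.5, 2)
    f_a <- runif(1, 1, 3)
    phase <- runif(1, 0, 2 * pi)
    m <- round(dur * fs)
    start <- round(centers[i] * fs - m / 2)
    idx <- seq(start, start + m - 1)
    keep <- idx >= 1 & idx <= n
    if (!any(keep)) next
    tt <- (seq_len(m) - 1) / fs
    burst <- amp_factor * background_rms *
      0.5 * (1 - cos(2 * pi * seq_len(m) / (m + 1))) * sin(2 * pi * f_a * tt + phase)
    x[, idx[keep]] <- sweep(x[, idx[keep], drop = FALSE], 2, burst[keep], "+")
  }
  x
}
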