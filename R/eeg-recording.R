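#' EEG recording container
#'
#' A lightweight container for a multi-channel EEG signal: a channels x time
#' numeric matrix of amplitudes (microvolts) plus sampling rate, channel
#' labels and a subject identifier. All channels share one sampling rate and
#' length.
#'
#' @param samples Numeric matrix, channels x time (microvolts).
#' @param sampling_rate Sampling rate in Hz; must exceed twice the upper
#'   analysis frequency (70 Hz).
#' @param channel_labels Character vector, one label per channel.
#' @param subject_id Subject identifier.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, sampling_rate, channel_labels = NULL,
                          subject_id = "subject") {
  if (!is.matrix(samples) || !is.numeric(samples)) {
    abort_field("samples", "must be a numeric channels x time matrix")
  }
  assert_scalar_number(sampling_rate, "sampling_rate", lower = 1e-6)
  if (sampling_rate <= 2 * analysis_range()[2]) {
    abort_field("sampling_rate", sprintf(
      "must exceed twice the upper analysis frequency (> %g Hz)", 2 * analysis_range()[2]))
  }
  if (is.null(channel_labels)) {
    channel_labels <- default_channels()[seq_len(nrow(samples))]
  }
  if (length(channel_labels) != nrow(samples)) {
    abort_field("channel_labels", "length must equal the number of channels")
  }
  rownames(samples) <- channel_labels
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         channel_labels = as.character(channel_labels),
         subject_id = as.character(subject_id)),
    class = "eeg_recording"
  )
}

# standard 8-channel sleep montage (referenced to mastoids at acquisition)
default_channels <- function() c("F3", "F4", "C3", "C4", "O1", "O2", "T3", "T4")

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject '%s': %d channels x %d samples (%.1f s @ %g Hz)\n",
              x$subject_id, nrow(x$samples), ncol(x$samples),
              ncol(x$samples) / x$sampling_rate, x$sampling_rate))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$samples)

n_samples <- function(rec) ncol(rec$samples)
n_channels <- function(rec) nrow(rec$samples)
rec_duration <- function(rec) ncol(rec$samples) / rec$sampling_rate

#' Tidy an EEG recording into a long tibble
#'
#' @param x An [eeg_recording()].
#' @param ... Unused.
#' @return A tibble with columns `subject_id`, `channel`, `time` (s), `value`
#'   (microvolts). Intended for short excerpts and plotting; whole-night
#'   recordings tidy to very long tables.
#' @method tidy eeg_recording
#' @export
tidy.eeg_recording <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id,
    channel = rep(x$channel_labels, each = ncol(x$samples)),
    time = rep(seq_len(ncol(x$samples)) - 1, times = nrow(x$samples)) / x$sampling_rate,
    value = as.vector(t(x$samples))
  )
}
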