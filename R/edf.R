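# Minimal EDF (European Data Format) reader/writer: 16-bit samples, 1-second
# data records, one header per file. Covers the plain-EDF subset this
# pipeline exchanges between stages (continuous multi-channel signals at one
# sampling rate); EDF+ annotations are out of scope.

edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) rlang::abort(sprintf("EDF field too long: '%s' (> %d chars)", s, width))
  formatC(s, width = -width, flag = "-")
}

#' Write an EEG recording to an EDF file
#'
#' Samples are quantized to 16-bit integers over a symmetric per-channel
#' physical range (so round-trips are exact up to 1/65534 of the range) and
#' stored in one-second data records. The sampling rate must be a whole
#' number of samples per second; a trailing partial second is dropped.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  if (abs(fs - round(fs)) > 1e-9) abort_field("sampling_rate", "EDF writer needs integer Hz")
  fs <- as.integer(round(fs))
  nc <- nrow(rec$samples)
  n_rec <- floor(ncol(rec$samples) / fs)
  if (n_rec < 1) abort_field("rec", "shorter than one EDF data record (1 s)")
  x <- rec$samples[, seq_len(n_rec * fs), drop = FALSE]

  pmax_ch <- pmax(ceiling(apply(abs(x), 1, max)), 1)
  dig_min <- -32767L; dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wr <- function(s, width) writeChar(edf_field(s, width), con, nchars = width, eos = NULL)
  # fixed header (256 bytes)
  wr("0", 8)
  wr(rec$subject_id, 80)
  wr("osanet synthetic EEG", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (1 + nc), 8)
  wr("", 44)
  wr(n_rec, 8)
  wr(1, 8)
  wr(nc, 4)
  # signal headers
  for (lbl in rec$channel_labels) wr(paste("EEG", lbl), 16)
  for (i in seq_len(nc)) wr("AgAgCl electrode", 80)
  for (i in seq_len(nc)) wr("uV", 8)
  for (i in seq_len(nc)) wr(-pmax_ch[i], 8)
  for (i in seq_len(nc)) wr(pmax_ch[i], 8)
  for (i in seq_len(nc)) wr(dig_min, 8)
  for (i in seq_len(nc)) wr(dig_max, 8)
  for (i in seq_len(nc)) wr("", 80)
  for (i in seq_len(nc)) wr(fs, 8)
  for (i in seq_len(nc)) wr("", 32)
  # data records: per record, per signal, fs int16 samples
  scale <- (dig_max - dig_min) / (2 * pmax_ch)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    block <- round((x[, cols, drop = FALSE] + pmax_ch) * scale) + dig_min
    block <- pmin(pmax(block, dig_min), dig_max)
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into an EEG recording
#'
#' Reads the plain-EDF subset written by [write_edf()] (equal sampling rate
#' across signals, 16-bit records).
#'
#' @param path EDF file path.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                               # version
  subject_id <- rd(80)
  rd(80); rd(8); rd(8)
  rd(8)                               # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  labels <- sub("^EEG ", "", vapply(seq_len(nc), function(i) rd(16), character(1)))
  for (i in seq_len(nc)) rd(80)       # transducer
  for (i in seq_len(nc)) rd(8)        # physical dimension
  phys_min <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), numeric(1))
  phys_max <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), numeric(1))
  dig_min <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), numeric(1))
  dig_max <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(nc)) rd(80)       # prefiltering
  spr <- vapply(seq_len(nc), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(nc)) rd(32)
  if (length(unique(spr)) != 1) rlang::abort("EDF reader supports one sampling rate per file")
  fs <- spr[1] / rec_dur
  x <- matrix(0, nrow = nc, ncol = n_rec * spr[1])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, what = "integer", n = nc * spr[1], size = 2,
                   endian = "little", signed = TRUE)
    block <- matrix(raw, nrow = spr[1])   # columns = signals
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    x[, cols] <- t((block - matrix(dig_min, spr[1], nc, byrow = TRUE)) *
                     matrix(gain, spr[1], nc, byrow = TRUE) +
                     matrix(phys_min, spr[1], nc, byrow = TRUE))
  }
  eeg_recording(x, fs, labels, subject_id)
}
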