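# four-stage pre-processing: re-reference, filter, artifact mask, edge trim

make_rec <- function(x, fs = 200, labels = NULL) {
  eeg_recording(x, fs, labels)
}

test_that("common-average re-referencing subtracts the instantaneous mean", {
  x <- matrix(c(3, 1, 5, -5), nrow = 2, byrow = TRUE)  # channels a, b
  out <- rereference_common_average(make_rec(x))
  expect_equal(out$samples[1, ], (x[1, ] - x[2, ]) / 2)
  expect_equal(out$samples[2, ], (x[2, ] - x[1, ]) / 2)

  same <- matrix(rep(rnorm(100), 3), nrow = 3, byrow = TRUE)
  expect_equal(max(abs(rereference_common_average(make_rec(same))$samples)), 0)

  set.seed(1)
  r <- make_rec(matrix(rnorm(8000), nrow = 8))
  out <- rereference_common_average(r)
  expect_lt(max(abs(colSums(out$samples))), 1e-9)
})

test_that("re-referencing is idempotent and rejects single-channel input", {
  set.seed(2)
  r <- make_rec(matrix(rnorm(4000), nrow = 4))
  once <- rereference_common_average(r)
  twice <- rereference_common_average(once)
  expect_lt(max(abs(once$samples - twice$samples)), 1e-9)
  expect_error(rereference_common_average(make_rec(matrix(rnorm(100), 1))), "2 channels")
})

test_that("filter meets stop-band, pass-band and out-of-band contracts", {
  fs <- 200
  tt <- (0:(fs * 60 - 1)) / fs
  rms <- function(v) sqrt(mean(v^2))
  mid <- (fs * 10):(fs * 50)  # avoid edge transients when measuring
  tone <- function(f) make_rec(matrix(rep(sin(2 * pi * f * tt), 2), nrow = 2, byrow = TRUE))

  out60 <- filter_eeg(tone(60))
  expect_lte(rms(out60$samples[1, mid]), 0.01 * rms(sin(2 * pi * 60 * tt)))

  out10 <- filter_eeg(tone(10))
  expect_lt(abs(rms(out10$samples[1, mid]) / rms(sin(2 * pi * 10 * tt)) - 1), 0.11)

  out90 <- filter_eeg(tone(90))
  expect_lte(rms(out90$samples[1, mid]), 0.10 * rms(sin(2 * pi * 90 * tt)))
})

test_that("filtering rejects sampling rates too low for the pass-band", {
  x <- matrix(rnorm(2 * 20000), nrow = 2)
  rec <- eeg_recording(x, 150)
  expect_error(filter_eeg(rec, band_hz = c(0.1, 80)), "pass-band")
})

test_that("filtering and re-referencing commute (both linear)", {
  set.seed(3)
  r <- make_rec(matrix(rnorm(4 * 12000), nrow = 4))
  a <- rereference_common_average(filter_eeg(r))$samples
  b <- filter_eeg(rereference_common_average(r))$samples
  expect_lt(max(abs(a - b)) / max(abs(a)), 1e-6)
})

test_that("an injected high-amplitude burst rejects exactly its epoch", {
  spec <- eeg_synthesis_spec(duration = 600, n_channels = 2, seed = 13)
  rec <- synthesize_eeg(spec)
  rms <- sqrt(mean(rec$samples^2))
  hit <- 7  # epoch to corrupt
  idx <- ((hit - 1) * 6000 + 1):((hit - 1) * 6000 + 400)
  burst <- 20 * rms * sin(2 * pi * 2 * (seq_along(idx) - 1) / 200)
  rec$samples[1, idx] <- rec$samples[1, idx] + burst
  mask <- reject_artifacts(rec, epoch_length = 6000, k_amp = 5, k_pow = 10)
  expect_identical(which(!mask$keep), as.integer(hit))
  expect_match(mask$reject_reason[hit], "amplitude")
})

test_that("clean constant-variance noise keeps nearly all epochs", {
  set.seed(4)
  rec <- make_rec(matrix(rnorm(2 * 6000 * 40), nrow = 2))
  mask <- reject_artifacts(rec, epoch_length = 6000)
  expect_gte(mean(mask$keep), 0.95)
})

test_that("artifact-free synthesis keeps all epochs at a loose threshold", {
  rec <- synthesize_eeg(eeg_synthesis_spec(duration = 300, n_channels = 2,
                                           artifact_rate = 0, seed = 9))
  mask <- reject_artifacts(rec, epoch_length = 6000, k_amp = 10, k_pow = 10)
  expect_true(all(mask$keep))
})

test_that("artifact mask is invariant to common amplitude rescaling", {
  rec <- synthesize_eeg(eeg_synthesis_spec(duration = 300, n_channels = 2,
                                           artifact_rate = 60, seed = 10))
  m1 <- reject_artifacts(rec, 6000)
  rec$samples <- rec$samples * 37.5
  m2 <- reject_artifacts(rec, 6000)
  expect_identical(m1$keep, m2$keep)
})

test_that("edge trimming follows the arithmetic and its preconditions", {
  rec <- make_rec(matrix(0, nrow = 2, ncol = 200 * 3600))  # 60 min
  mask <- structure(
    list(epoch_length = 6000L, keep = rep(TRUE, 120),
         reject_reason = rep(NA_character_, 120)), class = "epoch_mask")
  out <- trim_edges(rec, mask, trim_minutes = 5)
  expect_identical(which(!out$keep), as.integer(c(1:10, 111:120)))
  expect_identical(trim_edges(rec, mask, 0), mask)
  rec20 <- make_rec(matrix(0, nrow = 2, ncol = 200 * 1200))
  mask20 <- structure(list(epoch_length = 6000L, keep = rep(TRUE, 40),
                           reject_reason = rep(NA_character_, 40)),
                      class = "epoch_mask")
  expect_error(trim_edges(rec20, mask20, 15), "half the recording")
})

test_that("EDF files round-trip signal, labels, rate and subject id", {
  spec <- eeg_synthesis_spec(duration = 60, n_channels = 3, seed = 17,
                             subject_id = "S042")
  rec <- synthesize_eeg(spec)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_identical(back$subject_id, "S042")
  expect_identical(back$channel_labels, rec$channel_labels)
  expect_equal(back$sampling_rate, 200)
  # 16-bit quantization: error bounded by one digitization step
  step <- 2 * max(pmax(ceiling(apply(abs(rec$samples), 1, max)), 1)) / 65534
  expect_lt(max(abs(back$samples - rec$samples)), step)
})
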