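# spectral estimation: periodogram identity, relative power, spectral entropy

flat_spectrum <- function(n_channels = 1) {
  f <- (3:2099) / 30
  eeg_spectrum(f, matrix(1, n_channels, length(f)))
}

test_that("epoch PSD equals the direct DFT periodogram (Blackman-Tukey identity)", {
  set.seed(5)
  x <- rnorm(6000)
  rec <- eeg_recording(matrix(x, 1), 200, "F3")
  s <- epoch_psd(rec)
  # independent oracle: periodogram via the autocorrelation route
  # (full-length rectangular lag window -> |DFT|^2 / N)
  P <- Mod(fft(x))^2 / 6000
  f <- (0:5999) * 200 / 6000
  sel <- f >= 0.1 - 1e-12 & f < 70 - 1e-12 & f <= 100
  oracle <- P[sel] / sum(P[sel])
  expect_lt(max(abs(s$psdn[1, ] - oracle)) / max(oracle), 1e-8)
})

test_that("a grid-frequency sinusoid concentrates all mass at its bin", {
  tt <- (0:5999) / 200
  rec <- eeg_recording(matrix(sin(2 * pi * 10 * tt), 1), 200)
  s <- epoch_psd(rec)
  k <- which.max(s$psdn[1, ])
  expect_equal(s$frequencies[k], 10)
  near <- abs(s$frequencies - 10) <= 1 / 30 + 1e-9
  expect_gt(sum(s$psdn[1, near]), 0.99)
})

test_that("white-noise spectrum is flat after smoothing and sums to one", {
  set.seed(6)
  rec <- eeg_recording(matrix(rnorm(6000 * 100), 1), 200)
  s <- epoch_psd(rec)
  expect_equal(sum(s$psdn[1, ]), 1, tolerance = 1e-9)
  sm <- stats::filter(s$psdn[1, ], rep(1 / 9, 9), sides = 2)
  sm <- sm[!is.na(sm)]
  expect_lt(max(sm) / min(sm), 3)
})

test_that("epoch PSD refuses a mask with zero kept epochs", {
  rec <- eeg_recording(matrix(rnorm(12000), 1), 200, subject_id = "S007")
  mask <- structure(list(epoch_length = 6000L, keep = c(FALSE, FALSE),
                         reject_reason = c("edge", "edge")), class = "epoch_mask")
  expect_error(epoch_psd(rec, mask), "S007")
})

test_that("relative power of a flat spectrum is the share of band bins", {
  s <- flat_spectrum()
  rp <- relative_power(s, "delta2")
  expect_equal(rp$rp, 60 / 2097, tolerance = 1e-12)  # 60 bins in [2,4) of 2097
})

test_that("relative power is 1 when all mass lies inside the band", {
  f <- (3:2099) / 30
  p <- numeric(length(f))
  p[which(f == 3)] <- 1
  s <- eeg_spectrum(f, p)
  expect_equal(relative_power(s, "delta2")$rp, 1)
})

test_that("tiling-band relative powers partition unity", {
  set.seed(7)
  rec <- eeg_recording(matrix(rnorm(6000 * 4), 2), 200)
  s <- epoch_psd(rec)
  rp <- relative_power(s, eeg_bands(tiling = TRUE))
  sums <- tapply(rp$rp, rp$channel, sum)
  expect_equal(as.vector(sums), rep(1, 2), tolerance = 1e-9)
})

test_that("bands outside the grid raise an error", {
  s <- flat_spectrum()
  expect_error(relative_power(s, c(80, 90)), "outside")
  expect_error(spectral_entropy(s, c(80, 90)), "outside")
})

test_that("spectral entropy reaches its analytic limits", {
  f <- (1:64) / 30 + 1
  single <- numeric(64); single[20] <- 1
  s0 <- eeg_spectrum(f, single)
  expect_equal(spectral_entropy(s0, c(min(f), max(f) + 1e-6))$specen, 0)
  s1 <- eeg_spectrum(f, rep(1 / 64, 64))
  expect_equal(spectral_entropy(s1, c(min(f), max(f) + 1e-6))$specen, 1)
})

test_that("spectral entropy matches the hand-evaluated Shannon formula", {
  f <- c(2.0, 2.5, 3.0, 3.5)
  s <- eeg_spectrum(f, c(0.5, 0.5, 0, 0) + 1e-300)
  se <- spectral_entropy(s, c(2, 4))
  expect_equal(se$specen, log(2) / log(4), tolerance = 1e-9)
})

test_that("spectral entropy ignores positive rescaling of the spectrum", {
  set.seed(8)
  f <- (60:119) / 30
  p <- runif(60)
  a <- spectral_entropy(eeg_spectrum(f, p), c(2, 4))$specen
  b <- spectral_entropy(eeg_spectrum(f, 1000 * p), c(2, 4))$specen
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("added white noise strictly increases within-band entropy", {
  set.seed(9)
  tt <- (0:(200 * 120 - 1)) / 200
  narrow <- sin(2 * pi * 3 * tt)
  noise <- rnorm(length(tt))
  se <- vapply(c(0.01, 0.05, 0.2, 0.8, 3), function(a) {
    rec <- eeg_recording(matrix(narrow + a * noise, 1), 200)
    spectral_entropy(epoch_psd(rec), "delta2")$specen
  }, numeric(1))
  expect_true(all(diff(se) > 0))
})

test_that("planted band fractions are recovered as relative power", {
  planted <- c(delta1 = 0.40, delta2 = 0.20, theta = 0.15, alpha = 0.10,
               beta1 = 0.06, beta2 = 0.05, gamma = 0.04)
  rec <- synthesize_eeg(eeg_synthesis_spec(duration = 600, n_channels = 1,
                                           band_power_fractions = planted,
                                           seed = 19))
  rp <- relative_power(epoch_psd(rec), eeg_bands(tiling = TRUE))
  est <- setNames(rp$rp, rp$band)[names(planted)]
  expect_lt(max(abs(est - planted)), 0.03)
})

test_that("group-median spectrum of a single subject is that subject's curve", {
  rec <- synthesize_eeg(eeg_synthesis_spec(duration = 120, n_channels = 2, seed = 23))
  s <- epoch_psd(rec)
  gms <- group_median_spectrum(list(A = s), c(A = "controls"))
  expect_equal(gms$median, unname(colMeans(s$psdn)))
  expect_equal(gms$q25, gms$median)
  expect_equal(unique(gms$n_subjects), 1L)
})

test_that("a monotone decreasing curve peaks at the band edge and is flagged", {
  curve <- tibble::tibble(frequency = (6:60) / 30, median = seq(1, 0.1, length.out = 55))
  pk <- find_spectral_peak(curve, search_band = c(0.3, 1.5))
  expect_equal(pk$peak_frequency, 0.3)
  expect_true(pk$at_boundary)
})

test_that("feature table has the full column set and excludes incomplete EEG", {
  co <- synthesize_cohort(cohort_synthesis_spec(group_sizes = c(3, 2, 1), seed = 25,
                                                eeg = list(duration = 60)))
  spectra <- lapply(seq_len(nrow(co)), function(i) {
    epoch_psd(synthesize_eeg(co$eeg_spec[[i]]), epoch_length = 6000)
  })
  names(spectra) <- co$subject_id
  # corrupt one subject: drop a channel; and drop another subject entirely
  s3 <- spectra[[3]]
  spectra[[3]] <- eeg_spectrum(s3$frequencies, s3$psdn[-8, , drop = FALSE],
                               s3$channel_labels[-8], subject_id = s3$subject_id)
  spectra[[5]] <- NULL

  ft <- build_feature_table(co, spectra)
  expect_equal(nrow(ft), 4)
  expect_length(eeg_feature_columns(ft), 128)
  expect_true(all(c(psg_variables(), cognitive_variables(), "age", "sex", "group")
                  %in% names(ft)))
  comp <- attr(ft, "completeness")
  expect_setequal(comp$subject_id, co$subject_id[c(3, 5)])
  expect_true(any(grepl("missing_channel:T4", comp$reason)))
  expect_true(any(comp$reason == "missing_eeg"))

  # round-trip through CSV preserves feature values bit-exactly
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  cols <- eeg_feature_columns(ft)
  expect_identical(as.matrix(back[, cols]), as.matrix(ft[, cols]))
})
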