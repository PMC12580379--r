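test_that("EDF files round-trip within 16-bit quantization error", {
  fx <- fixture_synthetic(seed = 1, snr = 4, duration_s = 4)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(fx$eeg$data, fx$eeg$channel_labels, 500, path)
  back <- read_edf(path)
  step <- 2 * max(abs(fx$eeg$data)) / 65535
  expect_lt(max(abs(back$data - fx$eeg$data)), 2 * step)
  expect_identical(back$channel_labels, fx$eeg$channel_labels)
  expect_equal(back$sampling_rate_hz, 500)
  rec <- read_recording(path, "edf")
  expect_s3_class(rec, "eeg_recording")
  expect_equal(nrow(rec$data), 19)
})

test_that("delimited EEG tables round-trip and unknown labels are named", {
  fx <- fixture_synthetic(seed = 2, snr = 4, duration_s = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_eeg_delimited(fx$eeg$data, fx$eeg$channel_labels, path)
  rec <- read_recording(path, "delimited", sampling_rate_hz = 500)
  expect_equal(nrow(rec$data), 19)
  expect_equal(unname(rec$data), unname(fx$eeg$data), tolerance = 1e-6)
  expect_error(read_recording(path, "delimited"), "sampling_rate_hz")

  # legacy temporal labels resolve; junk labels error by name
  expect_identical(resolve_1020_labels(c("T3", "t6")), c("T7", "P8"))
  expect_error(eeg_recording(matrix(0, 2, 10), c("Fp1", "XX9"), 500),
               "XX9")
})

test_that("notch filter attenuates the line frequency and spares the passband", {
  fs <- 500; n <- fs * 60; tt <- (0:(n - 1)) / fs
  s50 <- matrix(rep(sin(2 * pi * 50 * tt), 4), 4, byrow = TRUE)
  out <- notch_filter(make_recording(s50))
  expect_lte(sqrt(mean(out$data^2)) / sqrt(mean(s50^2)), 0.032)

  s10 <- matrix(rep(sin(2 * pi * 10 * tt[1:(fs * 10)]), 4), 4,
                byrow = TRUE)
  out10 <- notch_filter(make_recording(s10))
  expect_lt(abs(sqrt(mean(out10$data^2)) / sqrt(mean(s10^2)) - 1), 0.02)

  # < 1 dB ripple just outside +/- 3 Hz of the notch
  s47 <- matrix(rep(sin(2 * pi * 47 * tt), 2), 2, byrow = TRUE)
  out47 <- notch_filter(make_recording(s47))
  expect_gt(sqrt(mean(out47$data^2)) / sqrt(mean(s47^2)), 10^(-1 / 20))

  expect_equal(dim(out10$data), dim(s10))
  expect_error(notch_filter(make_recording(s10), freq_hz = 300),
               "Nyquist")
})

test_that("band-pass filter has the specified band edges and zero phase", {
  fs <- 500; n <- fs * 10; tt <- (0:(n - 1)) / fs
  mk <- function(f) matrix(rep(sin(2 * pi * f * tt), 4), 4, byrow = TRUE)

  s02 <- mk(0.2)
  expect_lte(sqrt(mean(bandpass_filter(make_recording(s02))$data^2)) /
               sqrt(mean(s02^2)), 0.1)

  s10 <- mk(10)
  out <- bandpass_filter(make_recording(s10))
  expect_lt(abs(sqrt(mean(out$data^2)) / sqrt(mean(s10^2)) - 1), 0.05)
  xc <- stats::ccf(out$data[1, ], s10[1, ], lag.max = 10, plot = FALSE)
  expect_equal(xc$lag[which.max(xc$acf)], 0)

  dc <- matrix(5, 4, n)
  expect_lt(max(abs(bandpass_filter(make_recording(dc))$data)), 1e-8)

  expect_error(bandpass_filter(make_recording(s10), 45, 1), "band edges")
})

test_that("filtering is linear", {
  fs <- 500
  set.seed(31)
  x <- matrix(rnorm(4 * fs * 4), 4)
  y <- matrix(rnorm(4 * fs * 4), 4)
  for (f in list(notch_filter, bandpass_filter)) {
    lhs <- f(make_recording(2 * x + 3 * y))$data
    rhs <- 2 * f(make_recording(x))$data + 3 * f(make_recording(y))$data
    expect_lt(max(abs(lhs - rhs)), 1e-9 * max(abs(lhs)))
  }
})

test_that("bad-channel detection flags scaled channels and spares clean data", {
  fs <- 500
  # i.i.d. same-scale noise: no flags across several draws
  for (sd in 1:5) {
    set.seed(sd)
    rec <- make_recording(matrix(rnorm(19 * 2000), 19))
    expect_length(detect_bad_channels(rec), 0)
  }
  set.seed(6)
  base <- matrix(rnorm(19 * 2000), 19)
  one <- base; one[7, ] <- one[7, ] * 50
  expect_identical(detect_bad_channels(make_recording(one)),
                   montage_1020()$label[7])
  three <- base; three[c(2, 7, 15), ] <- three[c(2, 7, 15), ] * 50
  bad <- detect_bad_channels(make_recording(three))
  expect_setequal(bad, montage_1020()$label[c(2, 7, 15)])
  expect_identical(exclude_if_too_many_bad(bad), "exclude")
})

test_that("the dataset exclusion boundary sits at more than two bad channels", {
  expect_identical(exclude_if_too_many_bad(character(0)), "keep")
  expect_identical(exclude_if_too_many_bad(c("F3", "C4")), "keep")
  expect_identical(exclude_if_too_many_bad(c("F3", "C4", "O1")),
                   "exclude")
})

test_that("spherical-spline interpolation reconstructs interpolable channels", {
  fx <- fixture_synthetic(seed = 5, snr = 4, duration_s = 2)
  rec <- eeg_recording(fx$eeg$data, fx$eeg$channel_labels, 500)
  # plant Cz as the spline prediction from its neighbours, corrupt it,
  # and check the reconstruction recovers the planted series
  planted <- interpolate_spherical(rec, "Cz")
  truth <- planted$data["Cz", ]
  corrupted <- planted
  set.seed(1); corrupted$data["Cz", ] <- rnorm(ncol(rec$data))
  rebuilt <- interpolate_spherical(corrupted, "Cz")
  expect_gte(cor(rebuilt$data["Cz", ], truth), 0.99)

  # empty bad list: identity
  expect_identical(interpolate_spherical(rec, character(0)), rec)

  # constant field is reproduced exactly
  const <- make_recording(matrix(7.5, 19, 50))
  out <- interpolate_spherical(const, "F3")
  expect_lt(max(abs(out$data["F3", ] - 7.5)), 1e-6)

  # too few good channels
  small <- make_recording(matrix(rnorm(5 * 100), 5))
  expect_error(interpolate_spherical(small, c("Fp1", "Fp2")),
               "too few good")
})

test_that("average referencing zeroes column means and is idempotent", {
  set.seed(9)
  rec <- make_recording(matrix(rnorm(19 * 500) + 3, 19))
  out <- rereference_average(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-12)
  expect_identical(out$reference, "average")
  expect_equal(rereference_average(out)$data, out$data)
  single <- eeg_recording(matrix(rnorm(100), 1), "Cz", 500)
  expect_true(all(rereference_average(single)$data == 0))
})

test_that("epoch selection avoids the high-variance window and tiles exact-length input", {
  fs <- 500
  set.seed(13)
  base <- matrix(rnorm(19 * fs * 60), 19)
  burst <- base
  burst[, (fs * 23 + 1):(fs * 24)] <- burst[, (fs * 23 + 1):(fs * 24)] * 100
  rec <- make_recording(burst)
  eps <- select_epochs(rec, 5, 10)
  burst_window_start <- fs * 20 + 1  # window 3 of 6 holds the burst
  expect_false(burst_window_start %in% eps$start_samples)
  expect_length(eps$epochs, 5)

  exact <- make_recording(base[, 1:(fs * 50)])
  tiled <- select_epochs(exact, 5, 10)
  expect_identical(tiled$start_samples, (0:4) * fs * 10 + 1)

  expect_identical(select_epochs(rec, 5, 10)$start_samples,
                   eps$start_samples)
  expect_error(select_epochs(make_recording(base[, 1:fs]), 5, 10),
               "too short")
})

test_that("the full preprocessing chain preserves template recoverability at snr 4", {
  for (sd in 1:2) {
    fx <- fixture_synthetic(seed = sd, snr = 4, duration_s = 60)
    rec <- eeg_recording(fx$eeg$data, fx$eeg$channel_labels, 500)
    pp <- preprocess_recording(rec)
    expect_identical(pp$decision, "keep")
    pk <- microdyn:::collect_peak_maps(pp$epochs)
    model <- modified_kmeans(pk$maps, k = 4, n_restarts = 10,
                             seed = sd + 40L)
    al <- microdyn:::best_alignment(fx$templates$maps, model$maps)
    expect_gte(min(al$corrs), 0.95)
  }
})

test_that("preprocessing excludes recordings with three planted bad channels", {
  fx <- fixture_synthetic(seed = 3, snr = 4, duration_s = 60)
  data <- fx$eeg$data
  data[c(1, 5, 12), ] <- data[c(1, 5, 12), ] * 50
  rec <- eeg_recording(data, fx$eeg$channel_labels, 500)
  pp <- preprocess_recording(rec)
  expect_identical(pp$decision, "exclude")
  expect_null(pp$epochs)
  expect_length(pp$bad_channels, 3)
})
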