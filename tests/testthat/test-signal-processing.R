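# Signal cleaning: band-pass behaviour, common average reference, median
# filtering, normalization, trimming and ROI arithmetic.

test_that("band-pass preserves in-band tones and attenuates out-of-band ones", {
  rate <- 128
  t <- (0:(20 * rate - 1)) / rate
  mid <- seq(round(length(t) * 0.1), round(length(t) * 0.9))
  rms <- function(x) sqrt(mean(x[mid]^2))
  tone10 <- sin(2 * pi * 10 * t)
  tone60 <- sin(2 * pi * 60 * t)
  y10 <- bandpass(tone10, rate, 1, 45)
  y60 <- bandpass(tone60, rate, 1, 45)
  expect_lt(abs(rms(y10) / rms(tone10) - 1), 0.05)
  expect_gt(20 * log10(rms(tone60) / rms(y60)), 20)
  expect_equal(bandpass(numeric(1000), rate, 1, 45), numeric(1000))
})

test_that("band-pass is linear and validates its band edges", {
  rate <- 128
  set.seed(3)
  x <- rnorm(1000)
  expect_equal(bandpass(3.7 * x, rate, 1, 45), 3.7 * bandpass(x, rate, 1, 45),
               tolerance = 1e-8)
  expect_error(bandpass(x, rate, 1, 70), "Nyquist")
  expect_error(bandpass(x, rate, 10, 5), "low < high")
  m <- rbind(x, 2 * x)
  fm <- bandpass(m, rate, 1, 45)
  expect_identical(dim(fm), dim(m))
  expect_equal(fm[2, ], 2 * fm[1, ], tolerance = 1e-8)
})

test_that("common average reference matches its definition and is idempotent", {
  expect_equal(common_average_reference(rbind(c(1, 1), c(3, 3))),
               rbind(c(-1, -1), c(1, 1)))
  set.seed(5)
  eeg <- matrix(rnorm(32 * 1000), 32, 1000)
  ref <- common_average_reference(eeg)
  expect_lt(max(abs(colMeans(ref))), 1e-10)
  expect_equal(common_average_reference(ref), ref, tolerance = 1e-12)
  # brute-force per-sample subtraction oracle
  oracle <- eeg
  for (j in seq_len(ncol(eeg))) oracle[, j] <- eeg[, j] - mean(eeg[, j])
  expect_equal(ref, oracle, tolerance = 1e-12)
  expect_error(common_average_reference(matrix(1, 1, 10)), "2 channels")
})

test_that("median filter removes spikes and matches a naive sliding oracle", {
  expect_equal(median_filter_gsr(c(0, 0, 9, 0, 0), 3), rep(0, 5))
  ramp <- seq(0, 1, length.out = 50)
  expect_equal(median_filter_gsr(ramp, 5)[3:48], ramp[3:48])
  expect_error(median_filter_gsr(ramp, 4), "odd")

  set.seed(11)
  x <- rnorm(200)
  k <- 9; h <- (k - 1) / 2; n <- length(x)
  padded <- c(x[(h + 1):2], x, x[(n - 1):(n - h)])
  oracle <- vapply(seq_len(n), function(i) median(padded[i:(i + k - 1)]),
                   numeric(1))
  expect_lt(max(abs(median_filter_gsr(x, k) - oracle)), 1e-10)
})

test_that("normalization yields zero mean, unit SD, zeros for constants", {
  z <- normalize_signal(c(1, 2, 3))
  expect_lt(abs(mean(z)), 1e-10)
  expect_lt(abs(sqrt(mean(z^2)) - 1), 1e-10)
  expect_warning(zc <- normalize_signal(rep(4, 10)), "constant")
  expect_equal(zc, rep(0, 10))
  set.seed(7)
  m <- matrix(rnorm(5 * 100, mean = 3, sd = 2), 5, 100)
  zm <- normalize_signal(m)
  expect_lt(max(abs(rowMeans(zm))), 1e-10)
  expect_lt(max(abs(apply(zm, 1, function(v) sqrt(mean((v - mean(v))^2))) - 1)), 1e-10)
})

test_that("lead-in trimming drops exactly the configured span", {
  x <- rnorm(63 * 128)
  expect_length(trim_lead(x, 128, 8), 7040)
  expect_identical(trim_lead(x, 128, 0), x)
  expect_error(trim_lead(rnorm(5 * 128), 128, 8), "not longer")
  m <- matrix(rnorm(2 * 63 * 128), 2)
  expect_identical(ncol(trim_lead(m, 128, 8)), 7040L)
})

test_that("frame-to-sample mapping follows round(frame / fps * rate)", {
  expect_identical(frame_to_sample(1500, 50, 128), 3840L)
  expect_identical(frame_to_sample(0, 50, 128), 0L)
  expect_identical(frame_to_sample(900, 30, 128), 3840L)
})

test_that("signal ROI is centred, boundary-shifted, exact in length", {
  rate <- 128
  x <- rnorm(40 * rate)
  roi <- extract_signal_roi(x, rate, apex_sample = 20 * rate, seconds = 15)
  expect_identical(roi$end_sample - roi$start_sample, 1920L)
  expect_identical(roi$start_sample, as.integer(20 * rate - 960))
  expect_identical(roi$data, x[(roi$start_sample + 1):roi$end_sample])

  near <- extract_signal_roi(x, rate, apex_sample = 10, seconds = 15)
  expect_identical(c(near$start_sample, near$end_sample), c(0L, 1920L))

  all_roi <- extract_signal_roi(x, rate, apex_sample = 10, seconds = "all")
  expect_identical(all_roi$data, x)

  expect_error(extract_signal_roi(rnorm(100), rate, 10, seconds = 15), "longer")

  set.seed(13)
  for (i in 1:20) {
    n <- sample(2000:6000, 1)
    secs <- runif(1, 0.5, n / rate)
    apex <- sample(0:(n - 1), 1)
    r <- extract_signal_roi(rnorm(n), rate, apex, secs)
    expect_identical(r$end_sample - r$start_sample, as.integer(round(secs * rate)))
    expect_gte(r$start_sample, 0L)
    expect_lte(r$end_sample, n)
  }
})

test_that("the EEG cleaning chain returns referenced, normalized channels", {
  set.seed(23)
  eeg <- matrix(rnorm(8 * 2560, sd = 4), 8, 2560)
  out <- clean_eeg(eeg, 128)
  expect_identical(dim(out), dim(eeg))
  expect_lt(max(abs(rowMeans(out))), 1e-8)
})
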