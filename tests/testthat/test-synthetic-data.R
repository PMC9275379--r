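# Synthetic generator: determinism, planted effects, label fidelity, and
# the localization of signal effects around the apex.

test_that("identical config and seed reproduce the dataset bit for bit", {
  cfg <- tiny_config(seed = 5)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
  expect_length(d1, n_trials(cfg))
  # trials can also be generated lazily, in any order
  expect_identical(generate_trial(cfg, 2, 1), d1[[3]])
})

test_that("trial counts and shapes follow the configuration", {
  expect_identical(n_trials(generator_config(n_subjects = 23,
                                             trials_per_subject = 10)), 230L)
  cfg <- tiny_config()
  trial <- generate_trial(cfg, 1, 2)
  expect_equal(dim(trial$frames),
               c(round(cfg$trial_seconds * cfg$fps), cfg$frame_size))
  expect_equal(dim(trial$eeg),
               c(cfg$eeg_channels, round(cfg$trial_seconds * cfg$eeg_rate)))
  expect_length(trial$gsr, round(cfg$trial_seconds * cfg$physio_rate))
  expect_length(trial$ppg, round(cfg$trial_seconds * cfg$physio_rate))
  expect_true(trial$rating_arousal %in% 1:9 && trial$rating_valence %in% 1:9)
  expect_true(all(trial$frames >= 0 & trial$frames <= 1))
})

test_that("invalid configurations raise explicit parameter errors", {
  expect_error(generator_config(n_subjects = 0), "n_subjects")
  expect_error(generator_config(trial_seconds = 1, fps = 30), "60")
  expect_error(generator_config(noise_sd = -1), "noise_sd")
  expect_error(generator_config(rating_fidelity = 1.5), "rating_fidelity")
  expect_error(generator_config(eeg_channels = 1), "eeg_channels")
})

test_that("plant_micro_expression is additive, triangular, apex-peaked", {
  frames <- array(0.5, dim = c(50, 16, 16))
  expect_identical(plant_micro_expression(frames, 25, 10, 0, c(2, 2, 4, 4)),
                   frames)
  planted <- plant_micro_expression(frames, 25, 10, 0.2, c(2, 2, 4, 4))
  # untouched outside the region
  expect_identical(planted[, 10:16, 10:16], frames[, 10:16, 10:16])
  # per-pixel mean |frame - first| over the region is maximal exactly at apex
  dif <- vapply(1:50, function(f) mean(abs(planted[f, 3:6, 3:6] - planted[1, 3:6, 3:6])),
                numeric(1))
  expect_identical(which.max(dif) - 1L, 25L)
  expect_equal(max(dif), 0.2)
  # triangular ramp: halfway up at half the half-width
  expect_equal(dif[26 - 3], 0.2 * (1 - 3 / 5))
  expect_error(plant_micro_expression(frames, 25, 10, 0.2, c(14, 14, 4, 4)),
               "outside")
})

test_that("micro-expression durations correspond to 65-500 ms", {
  cfg <- tiny_config(n_subjects = 1, trials_per_subject = 8, seed = 3)
  for (tr in 1:8) {
    d <- generate_trial(cfg, 1, tr)$truth$me_duration_frames
    expect_gte(d / cfg$fps, 0.065 - 1 / cfg$fps)
    expect_lte(d / cfg$fps, 0.5)
  }
})

test_that("zero apex amplitude leaves only noise in the difference curve", {
  cfg0 <- tiny_config(apex_effect_amplitude = 0, seed = 8)
  cfg1 <- tiny_config(apex_effect_amplitude = 0.1, seed = 8)
  t0 <- generate_trial(cfg0, 1, 1)
  t1 <- generate_trial(cfg1, 1, 1)
  c0 <- difference_curve(t0$frames, facial_regions(t0$truth$face_box))
  c1 <- difference_curve(t1$frames, facial_regions(t1$truth$face_box))
  inner <- 2:(length(c0) - 1)
  expect_lt(max(c0[inner]) / median(c0[inner]), 1.5)   # flat noise curve
  expect_gt(max(c1[inner]) / median(c1[inner]), 1.5)   # planted peak
})

test_that("binarized ratings match the latent state at the configured fidelity", {
  cfg <- tiny_config(n_subjects = 5, trials_per_subject = 10, seed = 13)
  trials <- generate_dataset(cfg)
  match <- unlist(lapply(trials, function(tr) {
    c((tr$rating_arousal > 5) == (tr$truth$latent_arousal == "high"),
      (tr$rating_valence > 5) == (tr$truth$latent_valence == "high"))
  }))
  n <- length(match)
  se <- sqrt(0.95 * 0.05 / n)
  expect_gte(mean(match), 0.95 - 3 * se)
})

test_that("latent states are balanced across the dataset up to rounding", {
  cfg <- tiny_config(n_subjects = 4, trials_per_subject = 8, seed = 2)
  trials <- generate_dataset(cfg)
  ar <- vapply(trials, function(tr) tr$truth$latent_arousal, character(1))
  va <- vapply(trials, function(tr) tr$truth$latent_valence, character(1))
  expect_equal(mean(ar == "high"), 0.5, tolerance = 0.01)
  expect_equal(mean(va == "high"), 0.5, tolerance = 0.01)
})

test_that("EEG band-power shift is present inside the apex window, absent outside", {
  cfg <- tiny_config(trial_seconds = 20, eeg_rate = 128, eeg_channels = 4,
                     signal_effect_seconds = 8, band_shift_strength = 1.5,
                     seed = 4)
  truth <- make_truth(arousal = "high", apex_frame = 300)  # apex at 10 s
  # direct DFT band power oracle on a window, independent of the package path
  beta_power <- function(x, rate) {
    n <- length(x)
    sp <- abs(fft(x))^2 / n
    f <- (0:(n - 1)) * rate / n
    mean(sp[f >= 12 & f < 30 & f <= rate / 2])
  }
  set.seed(31)
  eeg <- generate_eeg(truth, cfg)
  rate <- cfg$eeg_rate
  inside <- (8 * rate):(12 * rate)            # around the 10 s apex
  outside <- 1:(4 * rate)                     # well before the effect window
  b_in <- mean(apply(eeg[, inside], 1, beta_power, rate = rate))
  b_out <- mean(apply(eeg[, outside], 1, beta_power, rate = rate))
  expect_gt(b_in, 2 * b_out)

  cfg0 <- tiny_config(trial_seconds = 20, eeg_rate = 128, eeg_channels = 4,
                      signal_effect_seconds = 8, band_shift_strength = 0,
                      seed = 4)
  eeg0 <- generate_eeg(truth, cfg0)
  b_in0 <- mean(apply(eeg0[, inside], 1, beta_power, rate = rate))
  b_out0 <- mean(apply(eeg0[, outside], 1, beta_power, rate = rate))
  expect_lt(abs(b_in0 / b_out0 - 1), 0.5)     # indistinguishable within noise
})

test_that("GSR first-difference statistic separates arousal groups", {
  cfg <- tiny_config(trial_seconds = 20, physio_rate = 64,
                     signal_effect_seconds = 8, physio_effect_strength = 1)
  set.seed(17)
  stat <- function(arousal) {
    replicate(50, {
      g <- generate_gsr(make_truth(arousal = arousal, apex_frame = 300), cfg)
      mean(abs(diff(g)))
    })
  }
  hi <- stat("high"); lo <- stat("low")
  expect_gt(mean(hi), mean(lo))
  expect_lt(t.test(hi, lo)$p.value, 0.01)
})

test_that("zero physio effect strength leaves tonic + noise only", {
  cfg <- tiny_config(trial_seconds = 20, physio_rate = 64,
                     signal_effect_seconds = 8, physio_effect_strength = 0)
  set.seed(18)
  g_hi <- replicate(20, max(abs(diff(generate_gsr(make_truth("high", apex_frame = 300), cfg)))))
  g_lo <- replicate(20, max(abs(diff(generate_gsr(make_truth("low", apex_frame = 300), cfg)))))
  expect_lt(abs(mean(g_hi) - mean(g_lo)), 0.05)
})

test_that("the PPG pulse survives its 0.7-2.5 Hz passband", {
  cfg <- tiny_config(trial_seconds = 20, physio_rate = 64,
                     signal_effect_seconds = 8)
  set.seed(19)
  ppg <- generate_ppg(make_truth("high", apex_frame = 300), cfg)
  filtered <- bandpass(ppg, cfg$physio_rate, 0.7, 2.5)
  mid <- seq(round(length(ppg) * 0.1), round(length(ppg) * 0.9))
  expect_gt(sqrt(mean(filtered[mid]^2)), 0.5 * sqrt(mean(ppg[mid]^2)))
})
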