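# Synthetic multimodal trial generator.
#
# Emulates the acquisition protocol of an affective video-watching study:
# per trial a poker-face frame sequence with one planted micro-expression,
# multi-channel EEG whose band-power composition shifts with the latent
# emotional state only near the apex time, GSR with tonic drift plus
# arousal-modulated phasic bumps, PPG with an emotion-modulated pulse train,
# and a SAM-style 1-9 rating consistent with the latent state. Every trial
# carries its ground truth so downstream modules can be validated.

#' Synthetic generator configuration
#'
#' Defaults mirror the acquisition conditions the pipeline targets: 23
#' subjects x 10 trials of 80 s, video at 30 frames/s, EEG at 128 Hz with 32
#' channels, GSR/PPG at 128 Hz.
#'
#' @param n_subjects,trials_per_subject Counts (>= 1).
#' @param trial_seconds Trial duration in seconds; `trial_seconds * fps`
#'   must be at least 60 so a 60-frame ROI fits.
#' @param fps Video frame rate (frames/s).
#' @param frame_size Frame dimensions `c(H, W)` in pixels.
#' @param eeg_rate,physio_rate Sampling rates in Hz.
#' @param eeg_channels EEG channel count.
#' @param apex_effect_amplitude Peak additive intensity of the planted
#'   micro-expression bumps (frame values live in [0, 1]). 0 disables the
#'   video effect entirely.
#' @param band_shift_strength Amplitude of the latent-state-dependent EEG
#'   oscillations, relative to the unit-variance pink-noise baseline. 0
#'   yields stationary noise.
#' @param physio_effect_strength Scale of the GSR phasic bumps and of the
#'   PPG rate/amplitude modulation. 0 yields tonic/periodic baselines only.
#' @param noise_sd Per-pixel Gaussian noise SD of the video frames.
#' @param rating_fidelity Probability that the binarized self-report rating
#'   (rating > 5) matches the latent state.
#' @param signal_effect_seconds Span of the EEG/physiological effect window
#'   centred on the apex time, in seconds.
#' @param seed Integer seed; identical config + seed reproduces the dataset
#'   bit for bit.
#' @return A validated list of class `"generator_config"`.
#' @export
generator_config <- function(n_subjects = 23, trials_per_subject = 10,
                             trial_seconds = 80, fps = 30,
                             frame_size = c(64, 64),
                             eeg_rate = 128, eeg_channels = 32,
                             physio_rate = 128,
                             apex_effect_amplitude = 0.1,
                             band_shift_strength = 1,
                             physio_effect_strength = 1,
                             noise_sd = 0.02,
                             rating_fidelity = 0.95,
                             signal_effect_seconds = 15,
                             seed = 1) {
  assert_that(is_count(n_subjects), "n_subjects must be a count >= 1")
  assert_that(is_count(trials_per_subject), "trials_per_subject must be a count >= 1")
  assert_that(is_number(trial_seconds, min = 1e-9), "trial_seconds must be > 0")
  assert_that(is_number(fps, min = 1e-9), "fps must be > 0")
  assert_that(length(frame_size) == 2 && all(vapply(frame_size, is_count, TRUE)) &&
                all(frame_size >= 32), "frame_size must be c(H, W), each >= 32")
  assert_that(is_number(eeg_rate, min = 1e-9), "eeg_rate must be > 0")
  assert_that(is_count(eeg_channels, min = 2L), "eeg_channels must be a count >= 2")
  assert_that(is_number(physio_rate, min = 1e-9), "physio_rate must be > 0")
  assert_that(trial_seconds * fps >= 60,
              "trial_seconds * fps must be >= 60 (room for a 60-frame ROI)")
  assert_that(is_number(apex_effect_amplitude, min = 0), "apex_effect_amplitude must be >= 0")
  assert_that(is_number(band_shift_strength, min = 0), "band_shift_strength must be >= 0")
  assert_that(is_number(physio_effect_strength, min = 0), "physio_effect_strength must be >= 0")
  assert_that(is_number(noise_sd, min = 0), "noise_sd must be >= 0")
  assert_that(is_number(rating_fidelity, min = 0) && rating_fidelity <= 1,
              "rating_fidelity must be in [0, 1]")
  assert_that(is_number(signal_effect_seconds, min = 1e-9) &&
                signal_effect_seconds <= trial_seconds,
              "signal_effect_seconds must be in (0, trial_seconds]")
  assert_that(is_count(seed, min = 0L) && seed < 2^31, "seed must be a non-negative integer")
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_subject = as.integer(trials_per_subject),
                 trial_seconds = trial_seconds, fps = fps,
                 frame_size = as.integer(frame_size),
                 eeg_rate = eeg_rate, eeg_channels = as.integer(eeg_channels),
                 physio_rate = physio_rate,
                 apex_effect_amplitude = apex_effect_amplitude,
                 band_shift_strength = band_shift_strength,
                 physio_effect_strength = physio_effect_strength,
                 noise_sd = noise_sd, rating_fidelity = rating_fidelity,
                 signal_effect_seconds = signal_effect_seconds,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Number of trials a configuration generates
#' @param config A [generator_config()].
#' @export
n_trials <- function(config) config$n_subjects * config$trials_per_subject

# Face bounding box used for all synthetic subjects: a fixed margin inside
# the frame. 0-based c(top, left, height, width).
synthetic_face_box <- function(frame_size) {
  m <- pmax(2L, as.integer(round(0.06 * frame_size)))
  c(top = m[1], left = m[2],
    height = frame_size[1] - 2L * m[1], width = frame_size[2] - 2L * m[2])
}

#' Plant a synthetic micro-expression into a frame sequence
#'
#' Adds an intensity bump inside `region` with a triangular temporal profile
#' over `duration_frames` frames: zero outside the window, ramping linearly
#' up to `amplitude` exactly at `apex_frame` and back down. Pixels outside
#' the region, and frames outside the window, are untouched. The window is
#' clipped at the sequence boundaries.
#'
#' @param frames Array `n_frames x H x W`.
#' @param apex_frame 0-based apex frame index.
#' @param duration_frames Width of the triangular profile in frames.
#' @param amplitude Peak additive intensity (0 returns the input unchanged).
#' @param region Pixel box `c(top, left, height, width)`, 0-based.
#' @return The modified frame array.
#' @export
plant_micro_expression <- function(frames, apex_frame, duration_frames,
                                   amplitude, region) {
  assert_that(is.array(frames) && length(dim(frames)) == 3,
              "frames must be an n_frames x H x W array")
  n <- dim(frames)[1]; H <- dim(frames)[2]; W <- dim(frames)[3]
  assert_that(is_count(apex_frame, min = 0L) && apex_frame < n,
              "apex_frame out of range")
  assert_that(is_count(duration_frames), "duration_frames must be a count >= 1")
  assert_that(is_number(amplitude, min = 0), "amplitude must be >= 0")
  region <- validate_box(region, H, W)
  if (amplitude == 0) return(frames)
  half <- duration_frames / 2
  f0 <- 0:(n - 1)
  w <- if (half > 0) pmax(0, 1 - abs(f0 - apex_frame) / half) else as.numeric(f0 == apex_frame)
  rows <- (region[1] + 1):(region[1] + region[3])
  cols <- (region[2] + 1):(region[2] + region[4])
  for (f in which(w > 0)) {
    frames[f, rows, cols] <- frames[f, rows, cols] + amplitude * w[f]
  }
  frames
}

# Static synthetic face pattern (H x W): bright face ellipse on a dark
# background with darker eye/mouth patches. Spotting operates on pixel
# differences, so a landmark-like intensity field is sufficient; no attempt
# at photorealism.
synthetic_face_pattern <- function(frame_size) {
  H <- frame_size[1]; W <- frame_size[2]
  fb <- synthetic_face_box(frame_size)
  cy <- fb[1] + fb[3] / 2; cx <- fb[2] + fb[4] / 2
  ry <- fb[3] / 2; rx <- fb[4] / 2
  y <- matrix(seq_len(H) - 0.5, H, W)
  x <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
  ellipse <- ((y - cy) / ry)^2 + ((x - cx) / rx)^2 <= 1
  base <- matrix(0.22, H, W)
  base[ellipse] <- 0.58
  regions <- facial_regions(fb)
  for (nm in c("left_eye", "right_eye", "left_mouth_corner",
               "right_mouth_corner", "nose_root")) {
    b <- regions[[nm]]
    base[(b[1] + 1):(b[1] + b[3]), (b[2] + 1):(b[2] + b[4])] <-
      base[(b[1] + 1):(b[1] + b[3]), (b[2] + 1):(b[2] + b[4])] - 0.18
  }
  base
}

# Latent state plan for one subject: the four arousal/valence combinations
# dealt as evenly as possible over the subject's trials, in seeded random
# order, so the dataset is balanced up to rounding.
subject_latent_plan <- function(config, subject) {
  combos <- expand.grid(arousal = c("low", "high"), valence = c("low", "high"),
                        stringsAsFactors = FALSE)
  k <- rep(seq_len(4), length.out = config$trials_per_subject)
  ord <- with_seed(derive_seed(config$seed, subject, 104729L),
                   sample(length(k)))
  combos[k[ord], , drop = FALSE]
}

# Hann-tapered effect envelope over samples, centred at the apex time and
# spanning signal_effect_seconds.
effect_envelope <- function(n_samples, rate, apex_time, span_seconds) {
  t <- (0:(n_samples - 1)) / rate
  half <- span_seconds / 2
  inside <- abs(t - apex_time) <= half
  env <- numeric(n_samples)
  env[inside] <- 0.5 * (1 + cos(pi * (t[inside] - apex_time) / half))
  env
}

#' Generate a synthetic EEG trial
#'
#' Per channel: unit-variance pink-noise baseline plus, inside a window of
#' `signal_effect_seconds` centred on the apex time, latent-state-dependent
#' oscillations scaled by `band_shift_strength`. High arousal adds a
#' beta/gamma component (22 and 38 Hz) on all channels; valence adds an
#' asymmetry-style alpha (10 Hz) change whose left/right channel amplitudes
#' differ by state.
#'
#' @param truth Ground-truth list with `latent_arousal`, `latent_valence`,
#'   `apex_frame`.
#' @param config A [generator_config()].
#' @return Matrix `eeg_channels x round(trial_seconds * eeg_rate)`.
#' @export
generate_eeg <- function(truth, config) {
  ns <- round(config$trial_seconds * config$eeg_rate)
  ch <- config$eeg_channels
  rate <- config$eeg_rate
  t <- (0:(ns - 1)) / rate
  apex_time <- truth$apex_frame / config$fps
  env <- effect_envelope(ns, rate, apex_time, config$signal_effect_seconds)
  s <- config$band_shift_strength
  af <- if (truth$latent_arousal == "high") 1 else 0.25
  left <- seq_len(ch) <= ch / 2
  alpha_amp <- if (truth$latent_valence == "high") {
    ifelse(left, 1.2, 0.4)
  } else {
    ifelse(left, 0.4, 0.8)
  }
  eeg <- matrix(0, ch, ns)
  for (c_i in seq_len(ch)) {
    # pink-noise baseline via 1/f spectral shaping of white noise
    white <- stats::rnorm(ns)
    f <- pmin(0:(ns - 1), ns - (0:(ns - 1))) * rate / ns
    shape <- 1 / sqrt(pmax(f, 1))
    x <- Re(stats::fft(stats::fft(white) * shape, inverse = TRUE)) / ns
    x <- x / sd_pop(x)
    phase <- stats::runif(3, 0, 2 * pi)
    x <- x + s * af * env * (sin(2 * pi * 22 * t + phase[1]) +
                               0.7 * sin(2 * pi * 38 * t + phase[2]))
    x <- x + s * alpha_amp[c_i] * env * sin(2 * pi * 10 * t + phase[3])
    eeg[c_i, ] <- x
  }
  rownames(eeg) <- sprintf("EEG%02d", seq_len(ch))
  eeg
}

# Skin-conductance response kernel: difference of exponentials (fast rise,
# slow decay), normalized to unit peak.
scr_kernel <- function(t, rise = 0.7, decay = 3) {
  k <- exp(-t / decay) - exp(-t / rise)
  k[t < 0] <- 0
  m <- max(k)
  if (m > 0) k / m else k
}

#' Generate a synthetic GSR trial
#'
#' Slow tonic drift (baseline level, gentle sinusoid and linear drift) plus
#' phasic exponential-decay bumps whose count and amplitude increase with
#' high latent arousal and whose times cluster inside the effect window
#' around the apex, all scaled by `physio_effect_strength`, plus measurement
#' noise.
#'
#' @inheritParams generate_eeg
#' @return Numeric vector of `round(trial_seconds * physio_rate)` samples.
#' @export
generate_gsr <- function(truth, config) {
  ns <- round(config$trial_seconds * config$physio_rate)
  rate <- config$physio_rate
  t <- (0:(ns - 1)) / rate
  apex_time <- truth$apex_frame / config$fps
  s <- config$physio_effect_strength
  tonic <- 2 + 0.2 * sin(2 * pi * t / 60 + stats::runif(1, 0, 2 * pi)) +
    stats::runif(1, -0.004, 0.004) * t
  x <- tonic + stats::rnorm(ns, sd = 0.02)
  if (s > 0) {
    half <- config$signal_effect_seconds / 2
    if (truth$latent_arousal == "high") {
      n_ev <- 2 + stats::rpois(1, 3)
      times <- stats::runif(n_ev, apex_time - half, apex_time + half)
      amps <- s * stats::runif(n_ev, 0.5, 1.2)
    } else {
      n_ev <- stats::rpois(1, 1)
      times <- stats::runif(n_ev, 0, config$trial_seconds)
      amps <- s * stats::runif(n_ev, 0.1, 0.3)
    }
    for (i in seq_len(n_ev)) {
      x <- x + amps[i] * scr_kernel(t - times[i])
    }
  }
  x
}

#' Generate a synthetic PPG trial
#'
#' A periodic pulse train (fundamental plus one harmonic) with baseline rate
#' drawn in 1.0-1.2 Hz. High latent arousal raises the instantaneous rate
#' and pulse amplitude inside the effect window around the apex, scaled by
#' `physio_effect_strength`, plus measurement noise.
#'
#' @inheritParams generate_eeg
#' @return Numeric vector of `round(trial_seconds * physio_rate)` samples.
#' @export
generate_ppg <- function(truth, config) {
  ns <- round(config$trial_seconds * config$physio_rate)
  rate <- config$physio_rate
  apex_time <- truth$apex_frame / config$fps
  env <- effect_envelope(ns, rate, apex_time, config$signal_effect_seconds)
  s <- config$physio_effect_strength
  af <- if (truth$latent_arousal == "high") 1 else 0
  r0 <- stats::runif(1, 1.0, 1.2)
  inst_rate <- r0 + 0.3 * s * af * env
  phase <- 2 * pi * cumsum(inst_rate) / rate
  amp <- 1 + 0.4 * s * af * env
  amp * (sin(phase) + 0.35 * sin(2 * phase - 0.8)) + stats::rnorm(ns, sd = 0.05)
}

# Draw a 1-9 SAM-style rating whose binarization (rating > 5) matches the
# latent state with probability `fidelity`.
draw_rating <- function(latent, fidelity) {
  match <- stats::runif(1) < fidelity
  high <- (latent == "high") == match
  if (high) sample(6:9, 1) else sample(1:5, 1)
}

#' Generate one synthetic multimodal trial
#'
#' Deterministic given `(config, subject, trial)`: the per-trial RNG seed is
#' derived from the configuration seed, so trials can be generated
#' independently (and lazily) in any order.
#'
#' @param config A [generator_config()].
#' @param subject Subject number in `1:n_subjects`.
#' @param trial Trial number in `1:trials_per_subject`.
#' @return A list of class `"multimodal_trial"` with elements `subject_id`,
#'   `trial_id`, `frames` (n_frames x H x W in [0, 1]), `eeg` (channels x
#'   samples), `gsr`, `ppg`, `rating_arousal`, `rating_valence`, `fps`,
#'   `eeg_rate`, `physio_rate` and `truth` (latent states, 0-based
#'   `apex_frame`, `me_duration_frames`, `face_box`).
#' @export
generate_trial <- function(config, subject, trial) {
  assert_that(inherits(config, "generator_config"), "config must be a generator_config")
  assert_that(is_count(subject) && subject <= config$n_subjects, "bad subject index")
  assert_that(is_count(trial) && trial <= config$trials_per_subject, "bad trial index")
  plan <- subject_latent_plan(config, subject)
  latent <- plan[trial, ]
  with_seed(derive_seed(config$seed, subject, trial), {
    n_frames <- round(config$trial_seconds * config$fps)
    H <- config$frame_size[1]; W <- config$frame_size[2]
    apex_frame <- sample(floor(0.35 * n_frames):floor(0.65 * n_frames), 1)
    dur_lo <- max(2L, ceiling(0.065 * config$fps))
    dur_hi <- max(dur_lo, floor(0.5 * config$fps))
    me_dur <- sample(dur_lo:dur_hi, 1)
    face_box <- synthetic_face_box(config$frame_size)
    truth <- list(latent_arousal = latent$arousal,
                  latent_valence = latent$valence,
                  apex_frame = as.integer(apex_frame),
                  me_duration_frames = as.integer(me_dur),
                  face_box = face_box)

    base <- synthetic_face_pattern(config$frame_size)
    frames <- array(rep(as.vector(base), each = n_frames), dim = c(n_frames, H, W))
    if (config$noise_sd > 0) {
      frames <- frames + stats::rnorm(length(frames), sd = config$noise_sd)
    }
    if (config$apex_effect_amplitude > 0) {
      regions <- facial_regions(face_box)
      arousal_regions <- if (latent$arousal == "high") {
        regions[c("left_eyebrow", "right_eyebrow")]
      } else {
        regions["chin"]
      }
      valence_regions <- if (latent$valence == "high") {
        regions[c("left_mouth_corner", "right_mouth_corner")]
      } else {
        regions["nose_root"]
      }
      for (b in c(arousal_regions, valence_regions)) {
        frames <- plant_micro_expression(frames, apex_frame, me_dur,
                                         config$apex_effect_amplitude, b)
      }
    }
    frames <- pmin(pmax(frames, 0), 1)

    structure(list(subject_id = sprintf("S%02d", subject),
                   trial_id = sprintf("S%02d_T%02d", subject, trial),
                   frames = frames,
                   eeg = generate_eeg(truth, config),
                   gsr = generate_gsr(truth, config),
                   ppg = generate_ppg(truth, config),
                   rating_arousal = draw_rating(latent$arousal, config$rating_fidelity),
                   rating_valence = draw_rating(latent$valence, config$rating_fidelity),
                   fps = config$fps, eeg_rate = config$eeg_rate,
                   physio_rate = config$physio_rate,
                   truth = truth),
              class = "multimodal_trial")
  })
}

#' Generate a full synthetic dataset
#'
#' @param config A [generator_config()].
#' @return List of `n_subjects * trials_per_subject`
#'   [generate_trial()] objects. Identical config and seed reproduce the
#'   dataset exactly. For large configurations consider generating trials
#'   lazily with [generate_trial()] instead of materializing the whole list
#'   (each 80 s, 30 fps trial holds ~20 MB of frames).
#' @export
generate_dataset <- function(config) {
  assert_that(inherits(config, "generator_config"), "config must be a generator_config")
  out <- vector("list", n_trials(config))
  k <- 0L
  for (s in seq_len(config$n_subjects)) {
    for (tr in seq_len(config$trials_per_subject)) {
      k <- k + 1L
      out[[k]] <- generate_trial(config, s, tr)
    }
  }
  out
}

#' @export
print.multimodal_trial <- function(x, ...) {
  cat(sprintf("multimodal_trial %s: %d frames @%g fps, EEG %dx%d @%g Hz, ratings A=%d V=%d\n",
              x$trial_id, dim(x$frames)[1], x$fps, nrow(x$eeg), ncol(x$eeg),
              x$eeg_rate, x$rating_arousal, x$rating_valence))
  invisible(x)
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("generator_config: %d subjects x %d trials, %g s @%g fps, EEG %d ch @%g Hz, seed %d\n",
              x$n_subjects, x$trials_per_subject, x$trial_seconds, x$fps,
              x$eeg_channels, x$eeg_rate, x$seed))
  invisible(x)
}
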