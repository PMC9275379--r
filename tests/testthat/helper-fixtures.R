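# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the suite stays fast.

# A small, fast generator configuration (2 s trials at 30 fps = 60 frames,
# the minimum the ROI contract allows).
tiny_config <- function(...) {
  defaults <- list(n_subjects = 2, trials_per_subject = 2, trial_seconds = 2,
                   fps = 30, frame_size = c(32, 32), eeg_rate = 128,
                   eeg_channels = 4, physio_rate = 64,
                   signal_effect_seconds = 1, seed = 42)
  args <- utils::modifyList(defaults, list(...))
  do.call(generator_config, args)
}

# Minimal ground-truth list for driving the signal generators directly.
make_truth <- function(arousal = "high", valence = "low", apex_frame = 300,
                       me_duration_frames = 10) {
  list(latent_arousal = arousal, latent_valence = valence,
       apex_frame = as.integer(apex_frame),
       me_duration_frames = as.integer(me_duration_frames))
}

# Feature sequences with a class-dependent mean shift in the middle
# windows; used for classifier learnability checks.
make_shifted_sequences <- function(n_per_class, T_ = 15, D = 5, shift = 1.2,
                                   seed = 1) {
  set.seed(seed)
  labels <- rep(c("low", "high"), each = n_per_class)
  seqs <- lapply(labels, function(cl) {
    m <- matrix(rnorm(T_ * D), T_, D)
    if (cl == "high") {
      rows <- seq(floor(T_ / 3), floor(2 * T_ / 3))
      m[rows, seq(max(1, D - 1), D)] <- m[rows, seq(max(1, D - 1), D)] + shift
    }
    m
  })
  list(sequences = seqs, labels = labels)
}

# Video ROI tensors with a class-dependent bright patch location.
make_patterned_rois <- function(n_per_class, window = 20, seed = 1) {
  set.seed(seed)
  labels <- rep(c("low", "high"), each = n_per_class)
  rois <- lapply(labels, function(cl) {
    a <- array(0.5 + rnorm(window * 64 * 64, sd = 0.1), dim = c(window, 64, 64))
    mid <- seq(window %/% 2 - 2, window %/% 2 + 2)
    if (cl == "high") a[mid, 10:20, 10:20] <- a[mid, 10:20, 10:20] + 0.5
    else a[mid, 44:54, 44:54] <- a[mid, 44:54, 44:54] + 0.5
    pmin(pmax(a, 0), 1)
  })
  list(rois = rois, labels = labels)
}

decisions_of <- function(P) ifelse(P[, "high"] >= P[, "low"], "high", "low")
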