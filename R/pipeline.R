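# End-to-end experiment orchestration: generate or load trials, spot the
# apex, cut the video and signal ROIs, extract features, train per-modality
# models under leave-some-subject-out folds, fuse the decisions and report
# fold-averaged metrics.

#' Experiment configuration
#'
#' @param generator A [generator_config()] describing the synthetic data
#'   source; ignored when `data_dir` is given.
#' @param data_dir Optional dataset directory (see [load_dataset()]).
#' @param target Which rating to classify: `"arousal"` or `"valence"`.
#' @param video_window ROI length in frames (20 and 60 are the standard
#'   presets).
#' @param signal_roi_seconds EEG/physiological ROI duration in seconds, or
#'   `"all"` for the whole trial.
#' @param classifier Signal-modality classifier: `"lstm"`, `"svm"`,
#'   `"knn"` or `"rf"` (the video modality always uses the 3D
#'   convolutional model).
#' @param fusion Fusion methods to evaluate (subset of `"majority"`,
#'   `"weighted"`).
#' @param n_folds Leave-some-subject-out fold count.
#' @param seed Master seed for fold shuffling and per-fold training seeds.
#' @param video A [video_net_config()].
#' @param lstm An [lstm_spec()] (batch size is overridden per modality).
#' @param classical A [classical_spec()].
#' @param window_seconds Feature window length in seconds.
#' @param verbose Emit progress messages.
#' @return A list of class `"experiment_config"`.
#' @export
experiment_config <- function(generator = generator_config(),
                              data_dir = NULL,
                              target = c("arousal", "valence"),
                              video_window = 60,
                              signal_roi_seconds = 15,
                              classifier = c("lstm", "svm", "knn", "rf"),
                              fusion = c("majority", "weighted"),
                              n_folds = 6, seed = 1,
                              video = NULL, lstm = lstm_spec(),
                              classical = classical_spec(),
                              window_seconds = 1,
                              verbose = TRUE) {
  target <- match.arg(target)
  classifier <- match.arg(classifier)
  assert_that(all(fusion %in% c("majority", "weighted")) && length(fusion) >= 1,
              "fusion must be a subset of majority/weighted")
  assert_that(is_count(video_window), "video_window must be a count")
  assert_that(identical(signal_roi_seconds, "all") ||
                is_number(signal_roi_seconds, min = 1e-9),
              "signal_roi_seconds must be > 0 or \"all\"")
  if (is.null(video)) video <- video_net_config(window = video_window)
  structure(list(generator = generator, data_dir = data_dir, target = target,
                 video_window = as.integer(video_window),
                 signal_roi_seconds = signal_roi_seconds,
                 classifier = classifier, fusion = fusion,
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 video = video, lstm = lstm, classical = classical,
                 window_seconds = window_seconds, verbose = verbose),
            class = "experiment_config")
}

# Reduce one trial to the quantities the classifiers consume: video
# features of the apex-centred ROI, EEG/physiological feature sequences of
# the signal ROI, labels, subject id.
process_trial <- function(trial, config, filters) {
  face_box <- trial$truth$face_box %||% detect_face(trial$frames[1, , ])
  spot <- spot_apex(trial$frames, face_box, config$video_window)
  roi <- preprocess_roi(spot$frames, face_box, size = config$video$size)
  vfeat <- video_features(roi, config$video, filters)

  eeg <- clean_eeg(trial$eeg, trial$eeg_rate)
  gsr <- clean_gsr(trial$gsr, trial$physio_rate)
  ppg <- clean_ppg(trial$ppg, trial$physio_rate)
  eroi <- extract_signal_roi(eeg, trial$eeg_rate,
                             frame_to_sample(spot$apex_frame, trial$fps, trial$eeg_rate),
                             config$signal_roi_seconds)
  proi_g <- extract_signal_roi(gsr, trial$physio_rate,
                               frame_to_sample(spot$apex_frame, trial$fps, trial$physio_rate),
                               config$signal_roi_seconds)
  proi_p <- extract_signal_roi(ppg, trial$physio_rate,
                               frame_to_sample(spot$apex_frame, trial$fps, trial$physio_rate),
                               config$signal_roi_seconds)
  list(subject = trial$subject_id,
       trial_id = trial$trial_id,
       apex_frame = spot$apex_frame,
       video = vfeat,
       eeg_seq = eeg_feature_sequence(eroi$data, trial$eeg_rate, config$window_seconds),
       physio_seq = physio_feature_sequence(proi_g$data, proi_p$data,
                                            trial$physio_rate, config$window_seconds),
       label_arousal = binarize_rating(trial$rating_arousal),
       label_valence = binarize_rating(trial$rating_valence))
}

pair_decisions <- function(P) ifelse(P[, "high"] >= P[, "low"], "high", "low")

train_signal_model <- function(seqs, labels, weights, subjects, config,
                               modality, fold) {
  if (config$classifier == "lstm") {
    spec <- config$lstm
    spec$batch_size <- lstm_batch_size(modality)
    spec$seed <- derive_seed(config$seed, fold,
                             if (modality == "eeg") 41L else 43L)
    model <- train_lstm(seqs, labels, weights, spec, subjects = subjects)
    list(predict = function(s) predict_lstm(model, s), model = model)
  } else {
    spec <- config$classical
    spec$seed <- derive_seed(config$seed, fold,
                             if (modality == "eeg") 41L else 43L)
    X <- flatten_feature_sequences(seqs)
    model <- train_classical(X, labels, weights, which = config$classifier,
                             spec = spec)
    list(predict = function(s) predict_classical(model, flatten_feature_sequences(s)),
         model = model)
  }
}

#' Run the full multimodal emotion-recognition experiment
#'
#' Executes the whole per-fold pipeline: spotting, ROI extraction, feature
#' extraction, per-modality training, decision fusion and Eq.-style
#' metrics, averaged over leave-some-subject-out folds. Repeated runs with
#' the same configuration and seed produce identical reports. Trials whose
#' face cannot be detected are excluded with a warning; a fold whose
#' training set degenerates to a single class is recorded as failed and
#' skipped in the averages.
#'
#' @param config An [experiment_config()].
#' @return A list of class `"run_report"`: `summary` (fold-averaged metrics
#'   per method), `folds` (per-fold metric sets, fusion weights and test
#'   subjects), `excluded_trials`, `config`, `seed` and `version`.
#' @export
run_experiment <- function(config) {
  assert_that(inherits(config, "experiment_config"), "config must be an experiment_config")
  say <- function(...) if (config$verbose) message(...)

  filters <- video_filters(config$video)
  if (!is.null(config$data_dir)) {
    trials <- load_dataset(config$data_dir)
    n <- length(trials)
    get_trial <- function(i) trials[[i]]
  } else {
    gc_ <- config$generator
    n <- n_trials(gc_)
    get_trial <- function(i) {
      s <- (i - 1) %/% gc_$trials_per_subject + 1
      tr <- (i - 1) %% gc_$trials_per_subject + 1
      generate_trial(gc_, s, tr)
    }
  }

  say("processing ", n, " trials")
  records <- vector("list", n)
  excluded <- character(0)
  for (i in seq_len(n)) {
    trial <- get_trial(i)
    rec <- tryCatch(process_trial(trial, config, filters),
                    microfusion_no_face = function(e) NULL)
    if (is.null(rec)) {
      warning("trial ", trial$trial_id, " excluded: no face detected")
      excluded <- c(excluded, trial$trial_id)
    }
    records[[i]] <- rec
    if (config$verbose && i %% 50 == 0) say("  ", i, "/", n)
  }
  records <- Filter(Negate(is.null), records)
  n <- length(records)
  assert_that(n > 0, "no usable trials")

  subjects <- vapply(records, `[[`, character(1), "subject")
  labels <- vapply(records, `[[`, character(1),
                   if (config$target == "arousal") "label_arousal" else "label_valence")
  Xv <- t(vapply(records, `[[`, numeric(length(records[[1]]$video)), "video"))
  eeg_seqs <- lapply(records, `[[`, "eeg_seq")
  physio_seqs <- lapply(records, `[[`, "physio_seq")

  plan <- make_folds(unique(subjects), config$n_folds, config$seed)
  methods <- c("video", "eeg", "physio",
               if ("majority" %in% config$fusion) "fusion_majority",
               if ("weighted" %in% config$fusion) "fusion_weighted")
  fold_metrics <- stats::setNames(lapply(methods, function(m) list()), methods)
  fold_info <- list()

  for (k in seq_along(plan)) {
    tr_idx <- which(subjects %in% plan[[k]]$train)
    te_idx <- which(subjects %in% plan[[k]]$test)
    if (length(unique(labels[tr_idx])) < 2 || length(te_idx) == 0) {
      fold_info[[k]] <- list(fold = k, status = "failed",
                             reason = "degenerate training labels or empty test set")
      next
    }
    say("fold ", k, "/", length(plan), ": ", length(tr_idx), " train / ",
        length(te_idx), " test trials")
    cw <- compute_class_weights(labels[tr_idx])

    vmodel <- train_video_model(Xv[tr_idx, , drop = FALSE], labels[tr_idx],
                                cw, config$video)
    P_tr <- list(video = predict_video(vmodel, Xv[tr_idx, , drop = FALSE]))
    P_te <- list(video = predict_video(vmodel, Xv[te_idx, , drop = FALSE]))

    em <- train_signal_model(eeg_seqs[tr_idx], labels[tr_idx], cw,
                             subjects[tr_idx], config, "eeg", k)
    P_tr$eeg <- em$predict(eeg_seqs[tr_idx]); P_te$eeg <- em$predict(eeg_seqs[te_idx])
    pm <- train_signal_model(physio_seqs[tr_idx], labels[tr_idx], cw,
                             subjects[tr_idx], config, "physio", k)
    P_tr$physio <- pm$predict(physio_seqs[tr_idx])
    P_te$physio <- pm$predict(physio_seqs[te_idx])

    for (m in c("video", "eeg", "physio")) {
      fold_metrics[[m]][[k]] <-
        confusion_and_metrics(pair_decisions(P_te[[m]]), labels[te_idx])$metrics
    }
    w <- NULL
    if ("majority" %in% config$fusion) {
      votes <- cbind(pair_decisions(P_te$video), pair_decisions(P_te$eeg),
                     pair_decisions(P_te$physio))
      fused <- apply(votes, 1, majority_vote)
      fold_metrics$fusion_majority[[k]] <-
        confusion_and_metrics(fused, labels[te_idx])$metrics
    }
    if ("weighted" %in% config$fusion) {
      w <- search_fusion_weights(P_tr$video, P_tr$eeg, P_tr$physio, labels[tr_idx])
      fused_high <- w[1] * P_te$video[, "high"] + w[2] * P_te$eeg[, "high"] +
        w[3] * P_te$physio[, "high"]
      fused <- ifelse(fused_high >= 0.5, "high", "low")
      fold_metrics$fusion_weighted[[k]] <-
        confusion_and_metrics(fused, labels[te_idx])$metrics
    }
    fold_info[[k]] <- list(fold = k, status = "ok", test_subjects = plan[[k]]$test,
                           n_train = length(tr_idx), n_test = length(te_idx),
                           fusion_weights = w,
                           metrics = lapply(fold_metrics, function(mm) mm[[k]]))
  }

  ok <- vapply(fold_info, function(f) identical(f$status, "ok"), logical(1))
  assert_that(any(ok), "all folds failed")
  summary <- do.call(rbind, lapply(methods, function(m) {
    avg <- fold_average(fold_metrics[[m]][ok])
    data.frame(method = m, t(avg))
  }))
  rownames(summary) <- NULL

  structure(list(summary = summary, folds = fold_info,
                 excluded_trials = excluded,
                 target = config$target, config = config, seed = config$seed,
                 version = as.character(utils::packageVersion("microfusion"))),
            class = "run_report")
}

#' Standard synthetic validation experiment
#'
#' The configuration used for end-to-end validation of the pipeline: 23
#' subjects x 10 trials of 20 s at 30 fps, 32-channel EEG at 128 Hz, a
#' 60-frame video ROI and a 15 s signal ROI, stacked-LSTM signal
#' classifiers and both fusion methods over 6 leave-some-subject-out folds.
#' With `effects = "strong"` the generator plants its default
#' (recoverable) effect sizes; with `effects = "none"` all effect
#' strengths are zero, so classifiers should perform at chance.
#'
#' @param seed Master seed.
#' @param effects `"strong"` or `"none"`.
#' @param n_subjects Number of subjects (the zero-effect null uses 12).
#' @param verbose Progress messages.
#' @return An [experiment_config()].
#' @export
synthetic_experiment_config <- function(seed = 1, effects = c("strong", "none"),
                                        n_subjects = if (effects == "strong") 23 else 12,
                                        verbose = FALSE) {
  effects <- match.arg(effects)
  z <- if (effects == "none") 0 else NULL
  gen <- generator_config(n_subjects = n_subjects, trials_per_subject = 10,
                          trial_seconds = 20, fps = 30,
                          eeg_rate = 128, eeg_channels = 32, physio_rate = 128,
                          apex_effect_amplitude = z %||% 0.1,
                          band_shift_strength = z %||% 1,
                          physio_effect_strength = z %||% 1,
                          signal_effect_seconds = 15,
                          seed = derive_seed(seed, 53L))
  experiment_config(generator = gen, target = "arousal", video_window = 60,
                    signal_roi_seconds = 15, classifier = "lstm",
                    fusion = c("majority", "weighted"), n_folds = 6,
                    seed = seed, verbose = verbose)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: target=%s, %d folds, seed=%d (microfusion %s)\n",
              x$target, length(x$folds), x$seed, x$version))
  if (length(x$excluded_trials)) {
    cat("excluded trials:", length(x$excluded_trials), "\n")
  }
  cat("fold-averaged metrics:\n")
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Write a run report to disk
#'
#' Writes `report.json` (full report), `summary.csv` (fold-averaged
#' metrics) into `dir`.
#'
#' @param report A [run_experiment()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  out <- report
  out$config$generator <- unclass(out$config$generator)
  out$config <- lapply(unclass(out$config), function(v) if (is.list(v)) unclass(v) else v)
  jsonlite::write_json(out[c("summary", "folds", "excluded_trials", "target",
                             "seed", "version", "config")],
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
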