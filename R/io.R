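# On-disk trial layout: one directory per trial containing
#   frames/frame_%04d.png   8-bit grayscale frame stack
#   eeg.csv                 sample index + one column per channel
#   gsr.csv / ppg.csv       sample index + one value column
#   meta.json               ids, rates, ratings and (synthetic) ground truth
# Sample indices on disk are 0-based, matching the package convention.

write_signal_csv <- function(path, x, colnames_) {
  m <- if (is.matrix(x)) t(x) else matrix(x, ncol = 1)
  df <- data.frame(sample = 0:(nrow(m) - 1), m)
  names(df) <- c("sample", colnames_)
  utils::write.csv(df, path, row.names = FALSE)
}

read_signal_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- NULL
  m
}

#' Write trials to a dataset directory
#'
#' @param trials List of `"multimodal_trial"` objects.
#' @param dir Output directory (created if missing); one sub-directory per
#'   trial. Frames are quantized to 8-bit PNG.
#' @return `dir`, invisibly.
#' @export
write_trials <- function(trials, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (trial in trials) {
    td <- file.path(dir, trial$trial_id)
    dir.create(file.path(td, "frames"), recursive = TRUE, showWarnings = FALSE)
    n <- dim(trial$frames)[1]
    for (f in seq_len(n)) {
      png::writePNG(trial$frames[f, , ],
                    file.path(td, "frames", sprintf("frame_%04d.png", f - 1)))
    }
    write_signal_csv(file.path(td, "eeg.csv"), trial$eeg,
                     rownames(trial$eeg) %||% sprintf("EEG%02d", seq_len(nrow(trial$eeg))))
    write_signal_csv(file.path(td, "gsr.csv"), trial$gsr, "GSR")
    write_signal_csv(file.path(td, "ppg.csv"), trial$ppg, "PPG")
    meta <- list(subject_id = trial$subject_id, trial_id = trial$trial_id,
                 fps = trial$fps, eeg_rate = trial$eeg_rate,
                 physio_rate = trial$physio_rate,
                 rating_arousal = trial$rating_arousal,
                 rating_valence = trial$rating_valence,
                 truth = trial$truth)
    jsonlite::write_json(meta, file.path(td, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

read_trial_dir <- function(td) {
  meta_path <- file.path(td, "meta.json")
  if (!file.exists(meta_path)) {
    stop_param("trial ", basename(td), ": missing meta.json (ratings/metadata)")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c("rating_arousal", "rating_valence", "fps", "eeg_rate", "physio_rate")) {
    if (is.null(meta[[field]])) {
      stop_param("trial ", basename(td), ": meta.json lacks ", field)
    }
  }
  frame_files <- sort(list.files(file.path(td, "frames"), pattern = "\\.png$",
                                 full.names = TRUE))
  if (length(frame_files) == 0) stop_param("trial ", basename(td), ": no frames found")
  first <- png::readPNG(frame_files[1])
  if (length(dim(first)) == 3) first <- first[, , 1]
  frames <- array(0, dim = c(length(frame_files), nrow(first), ncol(first)))
  frames[1, , ] <- first
  for (f in seq_along(frame_files)[-1]) {
    img <- png::readPNG(frame_files[f])
    if (length(dim(img)) == 3) img <- img[, , 1]
    frames[f, , ] <- img
  }
  truth <- meta$truth
  if (!is.null(truth)) {
    truth$face_box <- as.integer(truth$face_box)
    names(truth$face_box) <- c("top", "left", "height", "width")
  }
  structure(list(subject_id = meta$subject_id, trial_id = meta$trial_id,
                 frames = frames,
                 eeg = t(read_signal_csv(file.path(td, "eeg.csv"))),
                 gsr = as.vector(read_signal_csv(file.path(td, "gsr.csv"))),
                 ppg = as.vector(read_signal_csv(file.path(td, "ppg.csv"))),
                 rating_arousal = meta$rating_arousal,
                 rating_valence = meta$rating_valence,
                 fps = meta$fps, eeg_rate = meta$eeg_rate,
                 physio_rate = meta$physio_rate, truth = truth),
            class = "multimodal_trial")
}

#' Load a dataset directory
#'
#' Reads every trial sub-directory written by [write_trials()]. Trials must
#' agree on their sampling rates; a missing ratings/metadata file is an
#' error naming the trial.
#'
#' @param dir Dataset directory.
#' @return List of `"multimodal_trial"` objects.
#' @export
load_dataset <- function(dir) {
  assert_that(dir.exists(dir), "dataset directory not found: ", dir)
  tds <- sort(list.dirs(dir, recursive = FALSE))
  assert_that(length(tds) > 0, "no trial directories in ", dir)
  trials <- lapply(tds, read_trial_dir)
  rates <- vapply(trials, function(tr) c(tr$fps, tr$eeg_rate, tr$physio_rate),
                  numeric(3))
  assert_that(all(rates == rates[, 1]),
              "mixed sampling rates across trials in ", dir)
  trials
}
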