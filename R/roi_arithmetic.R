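# Small worked-example arithmetic around ROI sizing: how many frames a
# micro-expression spans at a given frame rate, and how much the apex ROI
# shrinks the classifier input relative to the full trial.

#' Frames spanned by a micro-expression
#'
#' Micro-expressions last 65-500 ms; at the upper bound of half a second
#' this is 25 frames at 50 fps and 15 frames at 30 fps.
#'
#' @param fps Video frame rate (frames/s).
#' @param duration_s Micro-expression duration in seconds (default 0.5).
#' @return Frame count (rounded).
#' @export
micro_expression_frames <- function(fps, duration_s = 0.5) {
  assert_that(is_number(fps, min = 1e-9), "fps must be > 0")
  assert_that(is_number(duration_s, min = 1e-9), "duration_s must be > 0")
  as.integer(round(duration_s * fps))
}

#' Input-size reduction from ROI extraction
#'
#' Using only a `window`-frame ROI instead of all `n_frames` frames reduces
#' the video-model input by the factor `window / n_frames` (e.g. 60/3,000
#' for an 60 s trial at 50 fps).
#'
#' @param window ROI length in frames.
#' @param n_frames Full trial length in frames.
#' @return The reduction ratio in (0, 1].
#' @export
roi_reduction_ratio <- function(window, n_frames) {
  assert_that(is_count(window) && is_count(n_frames) && window <= n_frames,
              "window must be a count <= n_frames")
  window / n_frames
}
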