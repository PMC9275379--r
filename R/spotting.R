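# Micro-expression spotting: locate the apex frame of a trial from regional
# absolute pixel differences against the first (onset) and last (offset)
# frames, then cut a fixed-length window of frames around it.
#
# Frames are stored as an array n_frames x H x W with values in [0, 1].
# Pixel boxes are integer vectors c(top, left, height, width) with 0-based
# top/left corners. All frame indices are 0-based.

# ---- pixel boxes -----------------------------------------------------------

validate_box <- function(box, H, W, what = "region") {
  assert_that(is.numeric(box) && length(box) == 4 && all(is.finite(box)),
              what, " must be a numeric c(top, left, height, width) box")
  box <- as.integer(round(box))
  names(box) <- c("top", "left", "height", "width")
  assert_that(box["height"] >= 1 && box["width"] >= 1,
              what, " must have positive height and width")
  assert_that(box["top"] >= 0 && box["left"] >= 0 &&
                box["top"] + box["height"] <= H &&
                box["left"] + box["width"] <= W,
              what, " lies outside the ", H, "x", W, " frame")
  box
}

# Clip a box to frame bounds, preserving as much of it as possible.
clip_box <- function(box, H, W) {
  top <- max(0L, as.integer(round(box[1])))
  left <- max(0L, as.integer(round(box[2])))
  bottom <- min(H, as.integer(round(box[1] + box[3])))
  right <- min(W, as.integer(round(box[2] + box[4])))
  assert_that(bottom > top && right > left, "box does not intersect the frame")
  c(top = top, left = left, height = bottom - top, width = right - left)
}

box_pixel_index <- function(box, H) {
  rows <- (box[1] + 1L):(box[1] + box[3])
  cols <- (box[2] + 1L):(box[2] + box[4])
  as.vector(outer(rows, (cols - 1L) * H, "+"))
}

# ---- facial region geometry ------------------------------------------------

#' Default facial region layout
#'
#' Ten regions around facial components where muscle movements occur
#' frequently (eyebrows, eyes, nose root and wings, mouth corners, chin),
#' expressed as fractions of the face crop: each row is
#' (top, left, height, width) in [0, 1] relative to the face bounding box.
#'
#' @return A 10 x 4 numeric matrix with region names as row names.
#' @export
facial_region_fractions <- function() {
  m <- rbind(
    left_eyebrow       = c(0.20, 0.12, 0.10, 0.24),
    right_eyebrow      = c(0.20, 0.64, 0.10, 0.24),
    left_eye           = c(0.34, 0.14, 0.12, 0.20),
    right_eye          = c(0.34, 0.66, 0.12, 0.20),
    nose_root          = c(0.34, 0.42, 0.16, 0.16),
    left_nose_wing     = c(0.52, 0.28, 0.10, 0.14),
    right_nose_wing    = c(0.52, 0.58, 0.10, 0.14),
    left_mouth_corner  = c(0.68, 0.20, 0.14, 0.18),
    right_mouth_corner = c(0.68, 0.62, 0.14, 0.18),
    chin               = c(0.84, 0.34, 0.12, 0.32))
  colnames(m) <- c("top", "left", "height", "width")
  m
}

#' Facial regions in absolute pixel coordinates
#'
#' Maps the fractional region layout into a face bounding box, yielding the
#' list of pixel boxes used by [difference_curve()].
#'
#' @param face_box Face bounding box `c(top, left, height, width)`, 0-based.
#' @param fractions Fractional layout, as from [facial_region_fractions()].
#' @return Named list of 10 integer boxes `c(top, left, height, width)`.
#' @export
facial_regions <- function(face_box, fractions = facial_region_fractions()) {
  assert_that(nrow(fractions) == 10, "exactly 10 facial regions are required")
  fh <- face_box[3]; fw <- face_box[4]
  out <- lapply(seq_len(nrow(fractions)), function(i) {
    f <- fractions[i, ]
    c(top = as.integer(face_box[1] + round(f[1] * fh)),
      left = as.integer(face_box[2] + round(f[2] * fw)),
      height = max(1L, as.integer(round(f[3] * fh))),
      width = max(1L, as.integer(round(f[4] * fw))))
  })
  names(out) <- rownames(fractions)
  out
}

# ---- face detection --------------------------------------------------------

#' Detect the face bounding box in a frame
#'
#' The detector is pluggable: any function mapping a grayscale frame matrix
#' to a `c(top, left, height, width)` box (or `NULL` when no face is found)
#' can be supplied, e.g. an adapter around an external detector. Boxes that
#' extend past the frame are clipped to its bounds. When the detector finds
#' no face an error of class `"microfusion_no_face"` is signalled so that
#' callers can exclude the trial.
#'
#' @param frame Grayscale matrix (H x W).
#' @param detector Function `frame -> box` or `NULL`.
#' @return Integer box `c(top, left, height, width)`, 0-based.
#' @seealso [oracle_face_detector()], [intensity_face_detector()]
#' @export
detect_face <- function(frame, detector = intensity_face_detector()) {
  assert_that(is.matrix(frame) && length(frame) > 0, "frame must be a non-empty matrix")
  box <- detector(frame)
  if (is.null(box)) {
    stop(structure(class = c("microfusion_no_face", "error", "condition"),
                   list(message = "no face detected in frame", call = sys.call())))
  }
  clip_box(box, nrow(frame), ncol(frame))
}

#' Oracle face detector for synthetic trials
#'
#' Returns a detector that always reports the known face box, as recorded by
#' the synthetic generator's ground truth.
#'
#' @param face_box Known face box `c(top, left, height, width)`.
#' @return A detector function for [detect_face()].
#' @export
oracle_face_detector <- function(face_box) {
  force(face_box)
  function(frame) face_box
}

#' Simple intensity-based face detector
#'
#' Finds the bounding box of pixels that deviate from the frame mean by more
#' than `k` standard deviations (the face region in the synthetic frames is
#' brighter than the background). Returns `NULL` when no pixel qualifies,
#' e.g. on a constant frame.
#'
#' @param k Threshold in frame-level standard deviations.
#' @return A detector function for [detect_face()].
#' @export
intensity_face_detector <- function(k = 1) {
  function(frame) {
    s <- sd(as.vector(frame))
    hits <- which(abs(frame - mean(frame)) > k * s, arr.ind = TRUE)
    if (s == 0 || nrow(hits) == 0) return(NULL)
    c(top = min(hits[, 1]) - 1L, left = min(hits[, 2]) - 1L,
      height = diff(range(hits[, 1])) + 1L, width = diff(range(hits[, 2])) + 1L)
  }
}

# ---- difference curve and apex ---------------------------------------------

#' Per-frame regional difference curve
#'
#' For each frame f the score is the mean, over every pixel of the 10 facial
#' regions, of `(|f - first frame| + |f - last frame|) / 2`: the first frame
#' stands in for the micro-expression onset and the last frame for the
#' offset, both depicting a neutral face. Overlapping regions contribute
#' their pixels once per region.
#'
#' @param frames Array `n_frames x H x W`.
#' @param regions List of pixel boxes, as from [facial_regions()].
#' @return Numeric vector of length `n_frames` with class
#'   `"difference_curve"`; scores are >= 0 and the two end frames score half
#'   their mutual mean absolute difference.
#' @export
difference_curve <- function(frames, regions) {
  assert_that(is.array(frames) && length(dim(frames)) == 3,
              "frames must be an n_frames x H x W array")
  n <- dim(frames)[1]; H <- dim(frames)[2]; W <- dim(frames)[3]
  assert_that(n >= 3, "at least 3 frames are required")
  assert_that(is.list(regions) && length(regions) > 0, "region set is empty")
  idx <- unlist(lapply(regions, function(b) {
    box_pixel_index(validate_box(b, H, W), H)
  }), use.names = FALSE)
  P <- matrix(frames, nrow = n)[, idx, drop = FALSE]
  first <- matrix(P[1, ], n, ncol(P), byrow = TRUE)
  last <- matrix(P[n, ], n, ncol(P), byrow = TRUE)
  values <- rowMeans((abs(P - first) + abs(P - last)) / 2)
  structure(values, class = "difference_curve")
}

#' Apex frame of a difference curve
#'
#' @param curve Numeric vector of per-frame scores (a
#'   [difference_curve()] result or any non-empty numeric vector).
#' @return 0-based index of the maximum score; ties resolve to the earliest
#'   tied frame.
#' @export
find_apex <- function(curve) {
  values <- unclass(curve)
  assert_that(is.numeric(values) && length(values) > 0, "curve is empty")
  which.max(values) - 1L
}

#' Cut the video region of interest around the apex frame
#'
#' The window is centred on the apex (`floor(window/2)` frames before it);
#' when the centred window would overrun either end of the trial it is
#' shifted, not shrunk, so the returned span always has exactly `window`
#' frames and contains the apex.
#'
#' @param frames Array `n_frames x H x W`.
#' @param apex_frame 0-based apex frame index.
#' @param window Number of frames to keep (e.g. 20 or 60).
#' @param curve Optional difference curve to carry in the result.
#' @return An object of class `"apex_result"`: list with `apex_frame`,
#'   `roi_start`, `roi_end` (0-based, half-open), `frames` (the
#'   `window x H x W` sub-array) and `curve`.
#' @export
extract_video_roi <- function(frames, apex_frame, window, curve = NULL) {
  assert_that(is.array(frames) && length(dim(frames)) == 3,
              "frames must be an n_frames x H x W array")
  n <- dim(frames)[1]
  assert_that(is_count(window), "window must be a positive count")
  assert_that(window <= n, "window (", window, ") exceeds trial length (", n, ")")
  assert_that(is_count(apex_frame, min = 0L) && apex_frame < n,
              "apex_frame out of range")
  start <- apex_frame - floor(window / 2)
  start <- min(max(start, 0L), n - window)
  structure(list(apex_frame = as.integer(apex_frame),
                 roi_start = as.integer(start),
                 roi_end = as.integer(start + window),
                 frames = frames[(start + 1):(start + window), , , drop = FALSE],
                 curve = curve),
            class = "apex_result")
}

#' Spot the apex and cut the video ROI in one step
#'
#' Convenience wrapper: difference curve over the facial regions of the
#' detected face box, apex selection, and ROI extraction.
#'
#' @inheritParams extract_video_roi
#' @param face_box Face bounding box used to place the facial regions.
#' @return An `"apex_result"` (see [extract_video_roi()]).
#' @export
spot_apex <- function(frames, face_box, window = 60) {
  regions <- facial_regions(clip_box(face_box, dim(frames)[2], dim(frames)[3]))
  curve <- difference_curve(frames, regions)
  extract_video_roi(frames, find_apex(curve), window, curve = curve)
}

#' @export
print.apex_result <- function(x, ...) {
  cat("apex_result: apex frame", x$apex_frame,
      sprintf("ROI [%d, %d)", x$roi_start, x$roi_end), "\n")
  invisible(x)
}
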