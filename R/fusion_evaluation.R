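# Label binarization, decision-level fusion (majority vote and weighted
# probability sum with grid-searched weights), leave-some-subject-out fold
# construction, and confusion-based metrics.
#
# Throughout, "high" is the positive class.

#' Binarize a 1-9 self-report rating
#'
#' Ratings above 5 map to `"high"`, ratings of 5 or below to `"low"` (5 is
#' the threshold; the boundary value itself is low).
#'
#' @param rating Integer rating(s) in 1..9 (vectorized).
#' @return Character vector of `"low"`/`"high"`.
#' @export
binarize_rating <- function(rating) {
  assert_that(is.numeric(rating) && all(is.finite(rating)) &&
                all(rating == round(rating)) &&
                all(rating >= 1 & rating <= 9),
              "ratings must be integers in 1..9")
  ifelse(rating > 5, "high", "low")
}

#' Majority vote over the three modality decisions
#'
#' @param votes Exactly 3 `"low"`/`"high"` decisions (video, EEG,
#'   physiological); with three binary voters a tie is impossible.
#' @return The majority class.
#' @export
majority_vote <- function(votes) {
  assert_that(length(votes) == 3, "exactly 3 votes are required")
  votes <- as_binary_labels(votes)
  if (sum(votes == "high") >= 2) "high" else "low"
}

#' Fusion weight grid
#'
#' All weight triples `(a, b, c)` with `a, b in {0, 0.01, ..., 1}`,
#' `c = 1 - a - b >= 0`: 5,151 candidates, ordered by `a` then `b`
#' ascending (the tie-break order of [search_fusion_weights()]).
#'
#' @param step Grid step (default 0.01).
#' @return Data frame with columns `a`, `b`, `c`.
#' @export
fusion_weight_grid <- function(step = 0.01) {
  m <- round(1 / step)
  ai <- unlist(lapply(0:m, function(i) rep(i, m - i + 1)))
  bi <- unlist(lapply(0:m, function(i) 0:(m - i)))
  data.frame(a = ai / m, b = bi / m, c = (m - ai - bi) / m)
}

validate_weights <- function(w) {
  w <- as.numeric(w)
  assert_that(length(w) == 3 && all(is.finite(w)) && all(w >= 0) &&
                abs(sum(w) - 1) < 1e-9,
              "fusion weights must be 3 non-negative values summing to 1")
  w
}

validate_pair <- function(p, what) {
  p <- as.numeric(p)
  assert_that(length(p) == 2 && all(is.finite(p)) && all(p >= -1e-9) &&
                abs(sum(p) - 1) < 1e-6, what, " must be a normalized probability pair")
  p
}

#' Weighted-sum decision fusion
#'
#' Fuses the three per-modality probability pairs as
#' `p^x = a p_video^x + b p_eeg^x + c p_physio^x` for each class `x`; the
#' fused pair still sums to 1 by linearity. The decision is the fused
#' argmax, with a tie at 0.5 resolved to `"high"`.
#'
#' @param p_video,p_eeg,p_physio Probability pairs `c(low, high)`.
#' @param w Weights `c(a, b, c)` on the simplex.
#' @return List with `pair` (named fused pair) and `decision`.
#' @export
weighted_fusion <- function(p_video, p_eeg, p_physio, w) {
  w <- validate_weights(w)
  pv <- validate_pair(p_video, "p_video")
  pe <- validate_pair(p_eeg, "p_eeg")
  pp <- validate_pair(p_physio, "p_physio")
  pair <- w[1] * pv + w[2] * pe + w[3] * pp
  names(pair) <- c("low", "high")
  list(pair = pair, decision = if (pair["high"] >= pair["low"]) "high" else "low")
}

#' Grid search for the fusion weights
#'
#' Exhaustively scans the 0.01-step weight simplex (5,151 triples) and
#' returns the triple maximizing the F-score of the fused decisions on the
#' training trials; ties resolve to the lexicographically smallest
#' `(a, b)`.
#'
#' @param p_video,p_eeg,p_physio `n x 2` probability matrices (columns
#'   `low`, `high`) for the training trials.
#' @param labels `"low"`/`"high"` training labels.
#' @param step Grid step.
#' @return Named weight vector `c(a, b, c)` with attribute `"f1"` (the
#'   achieved training F-score).
#' @export
search_fusion_weights <- function(p_video, p_eeg, p_physio, labels, step = 0.01) {
  lv <- as_binary_labels(labels)
  n <- length(lv)
  assert_that(!is.null(p_video) && !is.null(p_eeg) && !is.null(p_physio),
              "all three modalities must be predicted for every training trial")
  P <- cbind(p_video[, 2], p_eeg[, 2], p_physio[, 2])
  assert_that(nrow(P) == n && !anyNA(P), "probabilities and labels disagree in length")
  grid <- fusion_weight_grid(step)
  Fh <- as.matrix(grid) %*% t(P)          # candidates x trials, fused p_high
  D <- Fh >= 0.5                          # tie at 0.5 -> high
  truth <- lv == "high"
  TP <- as.vector(D %*% truth)
  FP <- rowSums(D) - TP
  FN <- sum(truth) - TP
  prec <- ifelse(TP + FP > 0, TP / (TP + FP), 0)
  rec <- ifelse(TP + FN > 0, TP / (TP + FN), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  best <- which.max(f1)                   # earliest = smallest (a, b)
  out <- c(a = grid$a[best], b = grid$b[best], c = grid$c[best])
  attr(out, "f1") <- f1[best]
  out
}

#' Leave-some-subject-out fold plan
#'
#' Subjects are shuffled with the given seed and dealt into `n_folds`
#' near-equal test groups (larger groups first); every trial of a test
#' subject is excluded from that fold's training set, so test subjects are
#' never seen at training.
#'
#' @param subject_ids Vector of unique subject identifiers.
#' @param n_folds Number of folds (default 6).
#' @param seed Shuffle seed.
#' @return A list of class `"fold_plan"`: per fold a list with `train` and
#'   `test` subject id vectors.
#' @export
make_folds <- function(subject_ids, n_folds = 6, seed = 1) {
  subject_ids <- unique(subject_ids)
  n <- length(subject_ids)
  assert_that(is_count(n_folds), "n_folds must be a count")
  assert_that(n >= n_folds, "fewer subjects (", n, ") than folds (", n_folds, ")")
  shuffled <- with_seed(derive_seed(seed, 31L), sample(subject_ids))
  sizes <- rep(n %/% n_folds, n_folds)
  extra <- n %% n_folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  folds <- lapply(seq_len(n_folds), function(k) {
    test <- shuffled[starts[k]:ends[k]]
    list(train = setdiff(subject_ids, test), test = test)
  })
  structure(folds, class = "fold_plan")
}

#' Confusion counts and binary metrics
#'
#' `"high"` is the positive class. Accuracy, precision, recall and F1 follow
#' the standard confusion identities; an undefined ratio (empty denominator)
#' is reported as 0.
#'
#' @param predictions,labels `"low"`/`"high"` vectors of equal length.
#' @return List with `counts` (`TP`, `FP`, `FN`, `TN`) and `metrics`
#'   (`accuracy`, `precision`, `recall`, `f1`).
#' @export
confusion_and_metrics <- function(predictions, labels) {
  pred <- as_binary_labels(predictions)
  lv <- as_binary_labels(labels)
  assert_that(length(pred) > 0, "empty input")
  assert_that(length(pred) == length(lv), "predictions and labels differ in length")
  TP <- sum(pred == "high" & lv == "high")
  FP <- sum(pred == "high" & lv == "low")
  FN <- sum(pred == "low" & lv == "high")
  TN <- sum(pred == "low" & lv == "low")
  precision <- if (TP + FP > 0) TP / (TP + FP) else 0
  recall <- if (TP + FN > 0) TP / (TP + FN) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(counts = c(TP = TP, FP = FP, FN = FN, TN = TN),
       metrics = c(accuracy = (TP + TN) / length(pred),
                   precision = precision, recall = recall, f1 = f1))
}

#' Unweighted mean of per-fold metrics
#'
#' The reported cross-validation result: the plain average of each metric
#' over folds.
#'
#' @param metric_list List of `metrics` vectors from
#'   [confusion_and_metrics()].
#' @return Named numeric vector of averaged metrics.
#' @export
fold_average <- function(metric_list) {
  colMeans(do.call(rbind, metric_list))
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("fold_plan:", length(x), "folds; test sizes",
      paste(vapply(x, function(f) length(f$test), integer(1)), collapse = ", "), "\n")
  invisible(x)
}
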