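# Video ROI preprocessing and binary arousal/valence classification with a
# compact 3D spatiotemporal convolutional model.
#
# The model is a two-block 3D convolutional feature extractor (3x3x3
# kernels, 8 then 16 filters, stride-2 valid convolutions, ReLU) whose
# filters are fixed and seeded, followed by average pooling over time and a
# spatial grid, feeding a class-weighted softmax head trained with Adam.
# Fixing the convolutional filters (random-feature convolutions) keeps
# training deterministic and fast in the low-sample regime this pipeline
# operates in; the input/output contract (window x 64 x 64 in, 2-class
# probabilities out) is unchanged, and the architecture is configurable.

#' Bilinear image resize
#'
#' Pixel-center-aligned bilinear resampling: output pixel centre `(i + 0.5,
#' j + 0.5)` maps to input coordinates scaled by `H_in/H_out`, clamped at
#' the borders. Resizing to the input size is the identity.
#'
#' @param img Numeric matrix.
#' @param out_h,out_w Output dimensions.
#' @return `out_h x out_w` matrix.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  H <- nrow(img); W <- ncol(img)
  src_of <- function(out_n, in_n) {
    s <- ((seq_len(out_n) - 0.5) * in_n / out_n) - 0.5
    pmin(pmax(s, 0), in_n - 1)
  }
  sy <- src_of(out_h, H); sx <- src_of(out_w, W)
  y0 <- pmin(floor(sy), H - 2) + 1; x0 <- pmin(floor(sx), W - 2) + 1
  wy <- sy - (y0 - 1); wx <- sx - (x0 - 1)
  a <- img[y0, x0, drop = FALSE]; b <- img[y0, x0 + 1, drop = FALSE]
  c_ <- img[y0 + 1, x0, drop = FALSE]; d <- img[y0 + 1, x0 + 1, drop = FALSE]
  WY <- matrix(wy, out_h, out_w); WX <- matrix(wx, out_h, out_w, byrow = TRUE)
  a * (1 - WY) * (1 - WX) + b * (1 - WY) * WX + c_ * WY * (1 - WX) + d * WY * WX
}

#' Preprocess a video ROI for classification
#'
#' Per frame: crop to the face box, min-max normalize to [0, 1] and resize
#' (bilinear) to `size x size`; frames are stacked in temporal order. If the
#' face is lost mid-window (a `NULL` box) the last valid box is reused. A
#' constant frame has no intensity range and is passed through clamped to
#' [0, 1] instead of rescaled.
#'
#' @param frames Array `window x H x W` (grayscale ROI frames).
#' @param face_box One pixel box applied to all frames, or a list with one
#'   box (or `NULL`) per frame.
#' @param size Output spatial size (default 64).
#' @return Array `window x size x size`, values in [0, 1].
#' @export
preprocess_roi <- function(frames, face_box, size = 64) {
  assert_that(is.array(frames) && length(dim(frames)) == 3 && dim(frames)[1] >= 1,
              "frames must be a non-empty window x H x W array")
  n <- dim(frames)[1]; H <- dim(frames)[2]; W <- dim(frames)[3]
  boxes <- if (is.list(face_box)) face_box else rep(list(face_box), n)
  assert_that(length(boxes) == n, "need one face box per frame")
  out <- array(0, dim = c(n, size, size))
  last_box <- NULL
  for (f in seq_len(n)) {
    box <- boxes[[f]]
    if (is.null(box)) {
      assert_that(!is.null(last_box), "face box missing for the first frame")
      box <- last_box
    }
    box <- clip_box(box, H, W)
    last_box <- box
    crop <- frames[f, (box[1] + 1):(box[1] + box[3]),
                   (box[2] + 1):(box[2] + box[4])]
    crop <- matrix(crop, box[3], box[4])
    rng <- range(crop)
    crop <- if (rng[2] > rng[1]) (crop - rng[1]) / (rng[2] - rng[1])
            else pmin(pmax(crop, 0), 1)
    out[f, , ] <- resize_bilinear(crop, size, size)
  }
  out
}

#' Video model configuration
#'
#' @param window ROI length in frames (20 or 60 in the standard presets).
#' @param size Spatial input size (frames are `size x size`).
#' @param filters Filter counts of the two convolutional blocks.
#' @param pool_grid Spatial pooling grid `c(rows, cols)` applied after the
#'   second block (features are averaged over time within each cell).
#' @param epochs Training epochs of the softmax head.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param l2 L2 penalty on the head weights.
#' @param seed Seed for the fixed convolutional filters, head
#'   initialization and minibatch shuffling.
#' @return A list of class `"video_net_config"`.
#' @export
video_net_config <- function(window = 60, size = 64, filters = c(8, 16),
                             pool_grid = c(4, 4), epochs = 50, lr = 1e-3,
                             batch_size = 8, l2 = 1e-3, seed = 0) {
  assert_that(is_count(window), "window must be a count")
  assert_that(is_count(epochs), "epochs must be a count")
  assert_that(length(filters) == 2 && all(vapply(filters, is_count, TRUE)),
              "filters must be two counts")
  structure(list(window = as.integer(window), size = as.integer(size),
                 filters = as.integer(filters), pool_grid = as.integer(pool_grid),
                 epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), l2 = l2,
                 seed = as.integer(seed)),
            class = "video_net_config")
}

# Valid 3D convolution via im2col + GEMM. x: T x H x W x C array,
# w: k x k x k x C x F, stride applied along all three axes.
conv3d <- function(x, w, stride = 2) {
  dx <- dim(x); k <- dim(w)[1]; C <- dim(w)[4]; F_ <- dim(w)[5]
  To <- (dx[1] - k) %/% stride + 1
  Ho <- (dx[2] - k) %/% stride + 1
  Wo <- (dx[3] - k) %/% stride + 1
  pt <- (0:(To - 1)) * stride; ph <- (0:(Ho - 1)) * stride; pw <- (0:(Wo - 1)) * stride
  Tn <- dx[1]; Hn <- dx[2]; Wn <- dx[3]
  base <- as.vector(outer(outer(pt, Tn * ph, "+"), Tn * Hn * pw, "+")) + 1
  d <- 0:(k - 1)
  offs <- as.vector(outer(outer(outer(d, Tn * d, "+"), Tn * Hn * d, "+"),
                          Tn * Hn * Wn * (seq_len(C) - 1), "+"))
  M <- outer(base, offs, "+")
  out <- matrix(x[M], nrow = length(base)) %*% matrix(w, ncol = F_)
  array(out, dim = c(To, Ho, Wo, F_))
}

video_filters <- function(config) {
  k <- 3
  with_seed(derive_seed(config$seed, 7L), {
    f1 <- array(stats::rnorm(k^3 * 1 * config$filters[1], sd = sqrt(2 / k^3)),
                dim = c(k, k, k, 1, config$filters[1]))
    f2 <- array(stats::rnorm(k^3 * config$filters[1] * config$filters[2],
                             sd = sqrt(2 / (k^3 * config$filters[1]))),
                dim = c(k, k, k, config$filters[1], config$filters[2]))
    list(f1 = f1, f2 = f2)
  })
}

#' Spatiotemporal feature vector of one preprocessed ROI
#'
#' Runs the two fixed convolutional blocks (stride 2, ReLU) and averages the
#' activations over time and a `pool_grid` spatial grid per filter.
#'
#' @param roi Array `window x size x size` from [preprocess_roi()].
#' @param config A [video_net_config()].
#' @param filters Optional precomputed [video_filters()] (an internal
#'   cache; they are fully determined by `config`).
#' @return Numeric feature vector of length
#'   `prod(pool_grid) * filters[2]`.
#' @export
video_features <- function(roi, config = video_net_config(),
                           filters = NULL) {
  assert_that(length(dim(roi)) == 3 && dim(roi)[2] == config$size &&
                dim(roi)[3] == config$size,
              "roi must be window x ", config$size, " x ", config$size)
  if (is.null(filters)) filters <- video_filters(config)
  x <- array(roi, dim = c(dim(roi), 1))
  a1 <- pmax(conv3d(x, filters$f1, 2), 0)
  a2 <- pmax(conv3d(a1, filters$f2, 2), 0)
  d <- dim(a2)
  gr <- config$pool_grid
  rows <- split(seq_len(d[2]), cut(seq_len(d[2]), gr[1], labels = FALSE))
  cols <- split(seq_len(d[3]), cut(seq_len(d[3]), gr[2], labels = FALSE))
  out <- numeric(gr[1] * gr[2] * d[4])
  i <- 0L
  for (f in seq_len(d[4])) for (r in rows) for (cc in cols) {
    i <- i + 1L
    out[i] <- mean(a2[, r, cc, f])
  }
  out
}

# ---- class-weighted softmax head ------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Train a 2-class softmax (multinomial logistic) head with Adam and
# per-sample weights. X: n x p, y: integer 0/1 (1 = "high").
train_softmax_head <- function(X, y, sample_w, epochs, lr, batch_size, l2, seed) {
  n <- nrow(X); p <- ncol(X)
  W <- with_seed(derive_seed(seed, 11L), matrix(stats::rnorm(p * 2, sd = 0.01), p, 2))
  b <- c(0, 0)
  mW <- vW <- matrix(0, p, 2); mb <- vb <- c(0, 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0
  Y <- cbind(1 - y, y)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, 13L, ep), sample(n))
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      Xb <- X[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
      wb <- sample_w[idx]
      P <- softmax_rows(Xb %*% W + matrix(b, length(idx), 2, byrow = TRUE))
      G <- (P - Yb) * (wb / sum(wb))
      gW <- t(Xb) %*% G + 2 * l2 * W
      gb <- colSums(G)
      step <- step + 1
      mW <- b1 * mW + (1 - b1) * gW; vW <- b2 * vW + (1 - b2) * gW^2
      mb <- b1 * mb + (1 - b1) * gb; vb <- b2 * vb + (1 - b2) * gb^2
      W <- W - lr * (mW / (1 - b1^step)) / (sqrt(vW / (1 - b2^step)) + eps)
      b <- b - lr * (mb / (1 - b1^step)) / (sqrt(vb / (1 - b2^step)) + eps)
    }
  }
  list(W = W, b = b)
}

# ---- training and prediction ----------------------------------------------

as_binary_labels <- function(labels) {
  lv <- as.character(labels)
  assert_that(all(lv %in% c("low", "high")), "labels must be \"low\"/\"high\"")
  lv
}

video_feature_matrix <- function(rois, config, filters) {
  if (is.matrix(rois)) return(rois)
  assert_that(is.list(rois), "rois must be a list of arrays or a feature matrix")
  t(vapply(rois, video_features, numeric(prod(config$pool_grid) * config$filters[2]),
           config = config, filters = filters))
}

#' Train the video arousal/valence model
#'
#' Extracts the fixed convolutional features of every training ROI and fits
#' the class-weighted softmax head. Training is fully determined by
#' `config$seed`.
#'
#' @param rois List of preprocessed ROI arrays (`window x size x size`), or
#'   an already-extracted feature matrix (rows = trials) from
#'   [video_features()].
#' @param labels `"low"`/`"high"` per trial (character or factor).
#' @param class_weights A [compute_class_weights()] result; computed from
#'   `labels` when `NULL`.
#' @param config A [video_net_config()].
#' @return A model of class `"video_model"`.
#' @export
train_video_model <- function(rois, labels, class_weights = NULL,
                              config = video_net_config()) {
  lv <- as_binary_labels(labels)
  assert_that(length(unique(lv)) == 2, "training data must contain both classes")
  if (is.null(class_weights)) class_weights <- compute_class_weights(lv)
  filters <- video_filters(config)
  X <- video_feature_matrix(rois, config, filters)
  assert_that(nrow(X) == length(lv), "one label per trial required")
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd_pop); sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  y <- as.integer(lv == "high")
  w <- ifelse(y == 1, class_weights["high"], class_weights["low"])
  head <- train_softmax_head(Xs, y, w, config$epochs, config$lr,
                             config$batch_size, config$l2, config$seed)
  structure(list(config = config, mu = mu, sd = sdv, head = head),
            class = "video_model")
}

#' Predict class probabilities with the video model
#'
#' @param model A [train_video_model()] result.
#' @param roi A single preprocessed ROI array, a list of them, or a feature
#'   matrix.
#' @return For a single ROI, a named probability pair `c(low, high)`
#'   (summing to 1); otherwise a matrix with columns `low`, `high`.
#' @export
predict_video <- function(model, roi) {
  single <- is.array(roi) && !is.matrix(roi) && length(dim(roi)) == 3
  rois <- if (single) list(roi) else roi
  X <- video_feature_matrix(rois, model$config, video_filters(model$config))
  Xs <- sweep(sweep(X, 2, model$mu), 2, model$sd, "/")
  P <- softmax_rows(Xs %*% model$head$W +
                      matrix(model$head$b, nrow(Xs), 2, byrow = TRUE))
  colnames(P) <- c("low", "high")
  if (single) P[1, ] else P
}
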