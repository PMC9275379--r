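# Per-modality binary classifiers: a stacked LSTM over windowed feature
# sequences and cost-sensitive SVM/KNN/random-forest baselines over flat
# feature vectors.
#
# The LSTM (two recurrent layers, class-weighted softmax output, Adam,
# reduce-on-plateau learning rate) is implemented directly in base R with
# batched matrix operations and full backpropagation through time; its
# gradients are checked against numerical differentiation in the test
# suite.

#' Balanced class weights for cost-sensitive training
#'
#' `weight_c = N_total / (2 * N_c)`, so the weighted class masses are equal:
#' errors in the minority class cost proportionally more.
#'
#' @param labels `"low"`/`"high"` per trial; both classes must be present.
#' @return Named numeric vector `c(low, high)`.
#' @export
compute_class_weights <- function(labels) {
  lv <- as_binary_labels(labels)
  n_low <- sum(lv == "low"); n_high <- sum(lv == "high")
  assert_that(n_low > 0 && n_high > 0, "both classes must be present")
  n <- n_low + n_high
  c(low = n / (2 * n_low), high = n / (2 * n_high))
}

#' Stacked LSTM hyper-parameters
#'
#' Defaults follow the tuned sequence model: two LSTM layers of 80 and 30
#' units, 100 epochs, Adam starting at learning rate 0.001, halved on a
#' validation-loss plateau down to a floor of 0.0001. Batch sizes of 128
#' (EEG), 32 (GSR) and 64 (PPG) are the per-modality presets; the fused
#' physiological sequence uses 32.
#'
#' @param layer1_units,layer2_units LSTM layer widths.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size (see [lstm_batch_size()] for presets).
#' @param lr_start,lr_floor,lr_decay_factor Learning-rate schedule.
#' @param patience Epochs without validation improvement before decay.
#' @param val_fraction Fraction of training trials (grouped by subject when
#'   subject ids are supplied) held out for the plateau criterion.
#' @param seed Seed for initialization and shuffling.
#' @return A list of class `"lstm_spec"`.
#' @export
lstm_spec <- function(layer1_units = 80, layer2_units = 30, epochs = 100,
                      batch_size = 32, lr_start = 1e-3, lr_floor = 1e-4,
                      lr_decay_factor = 0.5, patience = 5,
                      val_fraction = 0.2, seed = 0) {
  assert_that(is_count(layer1_units) && is_count(layer2_units),
              "layer units must be counts")
  assert_that(is_count(epochs) && is_count(batch_size), "epochs/batch_size must be counts")
  assert_that(lr_floor <= lr_start, "lr_floor must not exceed lr_start")
  structure(list(layer1_units = as.integer(layer1_units),
                 layer2_units = as.integer(layer2_units),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr_start = lr_start, lr_floor = lr_floor,
                 lr_decay_factor = lr_decay_factor,
                 patience = as.integer(patience), val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "lstm_spec")
}

#' Preset LSTM batch size per modality
#' @param modality One of `"eeg"`, `"gsr"`, `"ppg"`, `"physio"`.
#' @export
lstm_batch_size <- function(modality) {
  switch(modality, eeg = 128L, gsr = 32L, ppg = 64L, physio = 32L,
         stop_param("unknown modality: ", modality))
}

# ---- parameter plumbing ----------------------------------------------------

lstm_init_params <- function(D, H1, H2, seed) {
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  with_seed(derive_seed(seed, 17L), {
    b1 <- rep(0, 4 * H1); b1[(H1 + 1):(2 * H1)] <- 1   # forget-gate bias 1
    b2 <- rep(0, 4 * H2); b2[(H2 + 1):(2 * H2)] <- 1
    list(W1 = glorot(D, 4 * H1), U1 = glorot(H1, 4 * H1), b1 = b1,
         W2 = glorot(H1, 4 * H2), U2 = glorot(H2, 4 * H2), b2 = b2,
         Wd = glorot(H2, 2), bd = c(0, 0))
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward pass of one LSTM layer over a list of T input matrices (n x D).
lstm_layer_forward <- function(Xs, W, U, b) {
  T_ <- length(Xs); n <- nrow(Xs[[1]]); H <- ncol(U)
  H <- H / 4
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  hs <- vector("list", T_); caches <- vector("list", T_)
  bmat <- matrix(b, n, 4 * H, byrow = TRUE)
  for (t in seq_len(T_)) {
    z <- Xs[[t]] %*% W + h %*% U + bmat
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    caches[[t]] <- list(x = Xs[[t]], i = i, f = f, g = g, o = o,
                        c = c_new, tc = tc, c_prev = cc, h_prev = h)
    h <- h_new; cc <- c_new
    hs[[t]] <- h
  }
  list(hs = hs, caches = caches)
}

# Backward pass of one LSTM layer. dhs: list of T gradients w.r.t. h_t
# (zero matrices where nothing flows in). Returns parameter gradients and
# the gradients w.r.t. the layer inputs.
lstm_layer_backward <- function(caches, dhs, W, U) {
  T_ <- length(caches); n <- nrow(dhs[[1]]); H <- ncol(dhs[[1]])
  dW <- matrix(0, nrow(W), ncol(W)); dU <- matrix(0, nrow(U), ncol(U))
  db <- rep(0, 4 * H)
  dXs <- vector("list", T_)
  dh_next <- matrix(0, n, H); dc_next <- matrix(0, n, H)
  for (t in rev(seq_len(T_))) {
    cz <- caches[[t]]
    dh <- dhs[[t]] + dh_next
    dc <- dc_next + dh * cz$o * (1 - cz$tc^2)
    di <- dc * cz$g
    df <- dc * cz$c_prev
    dg <- dc * cz$i
    do_ <- dh * cz$tc
    dz <- cbind(di * cz$i * (1 - cz$i),
                df * cz$f * (1 - cz$f),
                dg * (1 - cz$g^2),
                do_ * cz$o * (1 - cz$o))
    dW <- dW + crossprod(cz$x, dz)
    dU <- dU + crossprod(cz$h_prev, dz)
    db <- db + colSums(dz)
    dXs[[t]] <- tcrossprod(dz, W)
    dh_next <- tcrossprod(dz, U)
    dc_next <- dc * cz$f
  }
  list(dW = dW, dU = dU, db = db, dXs = dXs)
}

# Full network forward: returns 2-class probabilities and caches.
lstm_forward <- function(params, Xs) {
  l1 <- lstm_layer_forward(Xs, params$W1, params$U1, params$b1)
  l2 <- lstm_layer_forward(l1$hs, params$W2, params$U2, params$b2)
  hT <- l2$hs[[length(Xs)]]
  logits <- hT %*% params$Wd + matrix(params$bd, nrow(hT), 2, byrow = TRUE)
  list(P = softmax_rows(logits), l1 = l1, l2 = l2, hT = hT)
}

# Weighted cross-entropy loss and gradients for a batch.
# Xs: list of T (n x D) matrices; y: 0/1; w: per-sample weights.
lstm_loss_grads <- function(params, Xs, y, w) {
  T_ <- length(Xs); n <- nrow(Xs[[1]])
  fw <- lstm_forward(params, Xs)
  Y <- cbind(1 - y, y)
  wn <- w / sum(w)
  loss <- -sum(wn * log(rowSums(fw$P * Y) + 1e-12))
  dlogits <- (fw$P - Y) * wn
  dWd <- crossprod(fw$hT, dlogits)
  dbd <- colSums(dlogits)
  H2 <- ncol(params$U2) / 4
  dhs2 <- rep(list(matrix(0, n, H2)), T_)
  dhs2[[T_]] <- tcrossprod(dlogits, params$Wd)
  bk2 <- lstm_layer_backward(fw$l2$caches, dhs2, params$W2, params$U2)
  bk1 <- lstm_layer_backward(fw$l1$caches, bk2$dXs, params$W1, params$U1)
  list(loss = loss,
       grads = list(W1 = bk1$dW, U1 = bk1$dU, b1 = bk1$db,
                    W2 = bk2$dW, U2 = bk2$dU, b2 = bk2$db,
                    Wd = dWd, bd = dbd))
}

lstm_loss <- function(params, Xs, y, w) {
  P <- lstm_forward(params, Xs)$P
  wn <- w / sum(w)
  -sum(wn * log(P[cbind(seq_along(y), y + 1)] + 1e-12))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grads[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- sequence plumbing -----------------------------------------------------

# Accepts a list of feature_sequence objects, a list of T x D matrices, or
# an n x T x D array; returns an n x T x D array.
sequences_to_array <- function(sequences) {
  if (is.array(sequences) && length(dim(sequences)) == 3) return(sequences)
  assert_that(is.list(sequences) && length(sequences) > 0, "no sequences supplied")
  mats <- lapply(sequences, function(s) {
    if (inherits(s, "feature_sequence")) s$windows else s
  })
  dims <- vapply(mats, dim, integer(2))
  assert_that(all(dims[1, ] == dims[1, 1]) && all(dims[2, ] == dims[2, 1]),
              "ragged sequences: all trials need the same window count and feature width")
  arr <- array(0, dim = c(length(mats), dims[1, 1], dims[2, 1]))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  arr
}

array_to_steps <- function(arr, idx) {
  D <- dim(arr)[3]
  lapply(seq_len(dim(arr)[2]), function(t) matrix(arr[idx, t, ], length(idx), D))
}

# ---- LSTM training ---------------------------------------------------------

#' Train the stacked LSTM sequence classifier
#'
#' Two LSTM layers followed by a 2-unit softmax read out at the last window;
#' the cross-entropy loss is class-weighted, optimized with Adam under a
#' reduce-on-plateau learning-rate schedule monitored on a held-out
#' validation split (the last `val_fraction` of training trials, grouped by
#' subject when `subjects` is given). Fully reproducible for a fixed
#' `spec$seed`.
#'
#' @param sequences List of `"feature_sequence"` objects (or `T x D`
#'   matrices, or an `n x T x D` array); all trials must share window count
#'   and feature width.
#' @param labels `"low"`/`"high"` per trial.
#' @param class_weights A [compute_class_weights()] result; computed from
#'   `labels` when `NULL`.
#' @param spec An [lstm_spec()].
#' @param subjects Optional subject id per trial for the grouped validation
#'   split.
#' @return A model of class `"lstm_model"` with a `history` data frame
#'   (epoch, loss, val_loss, lr).
#' @export
train_lstm <- function(sequences, labels, class_weights = NULL,
                       spec = lstm_spec(), subjects = NULL) {
  arr <- sequences_to_array(sequences)
  n <- dim(arr)[1]; T_ <- dim(arr)[2]; D <- dim(arr)[3]
  lv <- as_binary_labels(labels)
  assert_that(length(lv) == n, "one label per sequence required")
  assert_that(sum(lv == "low") >= 2 && sum(lv == "high") >= 2,
              "need at least 2 trials per class")
  if (is.null(class_weights)) class_weights <- compute_class_weights(lv)
  y <- as.integer(lv == "high")
  w <- ifelse(y == 1, class_weights["high"], class_weights["low"])

  mu <- apply(arr, 3, mean)
  sdv <- apply(arr, 3, sd_pop); sdv[sdv == 0] <- 1
  for (d in seq_len(D)) arr[, , d] <- (arr[, , d] - mu[d]) / sdv[d]

  # validation split for the plateau criterion
  val_idx <- integer(0)
  if (spec$val_fraction > 0 && n >= 10) {
    if (!is.null(subjects)) {
      subj <- unique(subjects)
      n_val <- max(1, ceiling(spec$val_fraction * length(subj)))
      val_subj <- tail(subj, n_val)
      val_idx <- which(subjects %in% val_subj)
    } else {
      val_idx <- tail(seq_len(n), max(1, ceiling(spec$val_fraction * n)))
    }
    if (length(unique(y[-val_idx])) < 2) val_idx <- integer(0)
  }
  train_idx <- setdiff(seq_len(n), val_idx)

  params <- lstm_init_params(D, spec$layer1_units, spec$layer2_units, spec$seed)
  state <- adam_init(params)
  lr <- spec$lr_start
  best_val <- Inf; wait <- 0
  hist <- vector("list", spec$epochs)
  Xs_val <- if (length(val_idx)) array_to_steps(arr, val_idx) else NULL

  for (ep in seq_len(spec$epochs)) {
    ord <- train_idx[with_seed(derive_seed(spec$seed, 19L, ep),
                               sample(length(train_idx)))]
    ep_loss <- 0; n_batches <- 0
    for (start in seq(1, length(ord), by = spec$batch_size)) {
      idx <- ord[start:min(start + spec$batch_size - 1, length(ord))]
      lg <- lstm_loss_grads(params, array_to_steps(arr, idx), y[idx], w[idx])
      upd <- adam_step(params, lg$grads, state, lr)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + lg$loss; n_batches <- n_batches + 1
    }
    val_loss <- NA_real_
    if (!is.null(Xs_val)) {
      val_loss <- lstm_loss(params, Xs_val, y[val_idx], w[val_idx])
      if (val_loss < best_val - 1e-5) {
        best_val <- val_loss; wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= spec$patience) {
          lr <- max(lr * spec$lr_decay_factor, spec$lr_floor)
          wait <- 0
        }
      }
    }
    hist[[ep]] <- data.frame(epoch = ep, loss = ep_loss / n_batches,
                             val_loss = val_loss, lr = lr)
  }

  structure(list(params = params, spec = spec, mu = mu, sd = sdv,
                 T_ = T_, D = D, history = do.call(rbind, hist)),
            class = "lstm_model")
}

#' Predict class probabilities with a trained LSTM
#'
#' @param model A [train_lstm()] result.
#' @param sequences Sequences in any form accepted by [train_lstm()].
#' @return Matrix with columns `low`, `high`; each row sums to 1.
#' @export
predict_lstm <- function(model, sequences) {
  arr <- sequences_to_array(sequences)
  assert_that(dim(arr)[2] == model$T_ && dim(arr)[3] == model$D,
              "sequence shape differs from the training shape")
  for (d in seq_len(model$D)) {
    arr[, , d] <- (arr[, , d] - model$mu[d]) / model$sd[d]
  }
  P <- lstm_forward(model$params, array_to_steps(arr, seq_len(dim(arr)[1])))$P
  colnames(P) <- c("low", "high")
  P
}

# ---- classical baselines ---------------------------------------------------

#' Classical classifier hyper-parameters
#'
#' RBF-kernel SVM with regularization 200, 5-neighbour KNN, 500-tree random
#' forest.
#'
#' @param svm_cost SVM regularization parameter.
#' @param knn_k Neighbour count.
#' @param rf_trees Tree count.
#' @param seed Seed for the stochastic trainers.
#' @return A list of class `"classical_spec"`.
#' @export
classical_spec <- function(svm_cost = 200, knn_k = 5, rf_trees = 500, seed = 0) {
  structure(list(svm_cost = svm_cost, knn_k = as.integer(knn_k),
                 rf_trees = as.integer(rf_trees), seed = as.integer(seed)),
            class = "classical_spec")
}

#' Collapse windowed feature sequences to flat per-trial vectors
#'
#' The flat representation for the classical classifiers: the mean over
#' windows of each per-window feature.
#'
#' @param sequences List of `"feature_sequence"` objects (or matrices/array
#'   as in [train_lstm()]).
#' @return `n x p` feature matrix.
#' @export
flatten_feature_sequences <- function(sequences) {
  arr <- sequences_to_array(sequences)
  apply(arr, c(1, 3), mean)
}

#' Train a cost-sensitive classical classifier
#'
#' `svm` and `rf` receive the class weights natively; KNN has no native
#' cost weighting, so its neighbour-vote fractions are re-weighted by the
#' class weights at prediction time.
#'
#' @param features `n x p` matrix of flat feature vectors (see
#'   [flatten_feature_sequences()]).
#' @param labels `"low"`/`"high"` per trial.
#' @param class_weights A [compute_class_weights()] result; computed from
#'   `labels` when `NULL`.
#' @param which One of `"svm"`, `"knn"`, `"rf"`.
#' @param spec A [classical_spec()].
#' @return A model of class `"classical_model"`.
#' @export
train_classical <- function(features, labels, class_weights = NULL,
                            which = c("svm", "knn", "rf"),
                            spec = classical_spec()) {
  assert_that(length(which) == 1 || identical(which, c("svm", "knn", "rf")),
              "which must be one of svm/knn/rf")
  which <- match.arg(which)
  features <- as.matrix(features)
  lv <- as_binary_labels(labels)
  assert_that(nrow(features) == length(lv), "one label per row required")
  if (is.null(class_weights)) class_weights <- compute_class_weights(lv)
  mu <- colMeans(features)
  sdv <- apply(features, 2, sd_pop); sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(features, 2, mu), 2, sdv, "/")
  yf <- factor(lv, levels = c("low", "high"))
  fit <- switch(which,
    svm = with_seed(derive_seed(spec$seed, 23L),
                    e1071::svm(x = Xs, y = yf, kernel = "radial",
                               cost = spec$svm_cost,
                               class.weights = class_weights,
                               probability = TRUE, scale = FALSE)),
    rf = with_seed(derive_seed(spec$seed, 29L),
                   randomForest::randomForest(x = Xs, y = yf,
                                              ntree = spec$rf_trees,
                                              classwt = class_weights)),
    knn = list(X = Xs, y = yf))
  structure(list(kind = which, fit = fit, spec = spec,
                 class_weights = class_weights, mu = mu, sd = sdv),
            class = "classical_model")
}

#' Predict class probabilities with a classical classifier
#'
#' @param model A [train_classical()] result.
#' @param features `n x p` matrix (same columns as at training).
#' @return Matrix with columns `low`, `high`; rows sum to 1.
#' @export
predict_classical <- function(model, features) {
  features <- as.matrix(features)
  Xs <- sweep(sweep(features, 2, model$mu), 2, model$sd, "/")
  P <- switch(model$kind,
    svm = {
      pr <- attr(predict(model$fit, Xs, probability = TRUE), "probabilities")
      pr[, c("low", "high"), drop = FALSE]
    },
    rf = {
      pr <- predict(model$fit, Xs, type = "prob")
      pr[, c("low", "high"), drop = FALSE]
    },
    knn = {
      k <- model$spec$knn_k
      w <- model$class_weights
      out <- matrix(0, nrow(Xs), 2)
      for (i in seq_len(nrow(Xs))) {
        d2 <- colSums((t(model$fit$X) - Xs[i, ])^2)
        nn <- order(d2)[seq_len(min(k, length(d2)))]
        n_high <- sum(model$fit$y[nn] == "high")
        n_low <- length(nn) - n_high
        mass_h <- w["high"] * n_high; mass_l <- w["low"] * n_low
        out[i, ] <- c(mass_l, mass_h) / (mass_l + mass_h)
      }
      out
    })
  P <- as.matrix(P)
  colnames(P) <- c("low", "high")
  rownames(P) <- NULL
  P
}
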