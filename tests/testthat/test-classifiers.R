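# Classifiers: class weights, the stacked LSTM (gradients, determinism,
# learnability, null behaviour) and the classical baselines.

test_that("balanced class weights follow N / (2 * N_c)", {
  w <- compute_class_weights(rep(c("low", "high"), c(339, 381)))
  expect_equal(unname(w), c(720 / 678, 720 / 762), tolerance = 1e-12)
  expect_equal(unname(compute_class_weights(rep(c("low", "high"), c(10, 10)))),
               c(1, 1))
  set.seed(1)
  for (i in 1:10) {
    nl <- sample(1:50, 1); nh <- sample(1:50, 1)
    w <- compute_class_weights(rep(c("low", "high"), c(nl, nh)))
    expect_equal(w["low"] * nl, w["high"] * nh, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_error(compute_class_weights(rep("high", 5)), "both classes")
})

test_that("LSTM backpropagation matches numerical gradients", {
  set.seed(42)
  n <- 5; T_ <- 4; D <- 3
  params <- microfusion:::lstm_init_params(D, 6, 4, seed = 1)
  Xs <- lapply(seq_len(T_), function(t) matrix(rnorm(n * D), n, D))
  y <- c(0, 1, 1, 0, 1)
  w <- c(1, 0.8, 1.2, 1, 0.9)
  lg <- microfusion:::lstm_loss_grads(params, Xs, y, w)
  eps <- 1e-6
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(8, length(params[[nm]])))
    for (i in idx) {
      up <- params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
      num <- (microfusion:::lstm_loss(up, Xs, y, w) -
                microfusion:::lstm_loss(dn, Xs, y, w)) / (2 * eps)
      expect_equal(unname(lg$grads[[nm]][i]), num, tolerance = 1e-4)
    }
  }
})

test_that("LSTM training is reproducible and predictions are normalized", {
  sim <- make_shifted_sequences(20, seed = 2)
  spec <- lstm_spec(epochs = 3, batch_size = 16, seed = 9)
  m1 <- train_lstm(sim$sequences, sim$labels, spec = spec)
  m2 <- train_lstm(sim$sequences, sim$labels, spec = spec)
  P1 <- predict_lstm(m1, sim$sequences)
  P2 <- predict_lstm(m2, sim$sequences)
  expect_identical(P1, P2)
  expect_lt(max(abs(rowSums(P1) - 1)), 1e-6)
  expect_true(all(P1 >= 0 & P1 <= 1))
  expect_identical(colnames(P1), c("low", "high"))
})

test_that("LSTM learns a separable band-shift pattern and stays at chance on noise", {
  sim <- make_shifted_sequences(90, shift = 1.2, seed = 3)
  tr <- c(1:60, 91:150); te <- setdiff(seq_along(sim$labels), tr)
  m <- train_lstm(sim$sequences[tr], sim$labels[tr],
                  spec = lstm_spec(epochs = 60, batch_size = 32, seed = 4))
  f1 <- confusion_and_metrics(decisions_of(predict_lstm(m, sim$sequences[te])),
                              sim$labels[te])$metrics["f1"]
  expect_gt(f1, 0.75)

  null <- make_shifted_sequences(90, shift = 0, seed = 5)
  m0 <- train_lstm(null$sequences[tr], null$labels[tr],
                   spec = lstm_spec(epochs = 30, batch_size = 32, seed = 4))
  f1_0 <- confusion_and_metrics(decisions_of(predict_lstm(m0, null$sequences[te])),
                                null$labels[te])$metrics["f1"]
  expect_lt(abs(f1_0 - 0.5), 0.3)   # chance up to sampling/model noise at n=60
})

test_that("LSTM rejects ragged input and single-class training sets", {
  sim <- make_shifted_sequences(5, seed = 6)
  ragged <- sim$sequences
  ragged[[2]] <- ragged[[2]][1:7, ]
  expect_error(train_lstm(ragged, sim$labels), "ragged")
  expect_error(train_lstm(sim$sequences, rep("high", 10)), "2 trials per class")
})

test_that("classical baselines fit a separable toy problem perfectly", {
  set.seed(8)
  X <- rbind(matrix(rnorm(40, mean = 0, sd = 0.3), 20, 2),
             matrix(rnorm(40, mean = 4, sd = 0.3), 20, 2))
  labels <- rep(c("low", "high"), each = 20)
  for (kind in c("svm", "knn", "rf")) {
    m <- train_classical(X, labels, which = kind)
    acc <- mean(decisions_of(predict_classical(m, X)) == labels)
    expect_equal(acc, 1.0, info = kind)
  }
  expect_error(train_classical(X, labels, which = "boost"), "arg")
})

test_that("KNN reports class-weighted neighbour-vote fractions", {
  X <- matrix(c(0.1, 0.2, 0.3, 0.8, 0.9, 10), ncol = 1)
  labels <- c("high", "high", "high", "low", "low", "low")
  m <- train_classical(X, labels, class_weights = c(low = 1, high = 1),
                       which = "knn", spec = classical_spec(knn_k = 5))
  p <- predict_classical(m, matrix(0.15, 1, 1))
  expect_equal(unname(p[1, "high"]), 0.6)   # 3 of 5 neighbours are high
  # re-weighting shifts the vote mass
  m2 <- train_classical(X, labels, class_weights = c(low = 3, high = 1),
                        which = "knn", spec = classical_spec(knn_k = 5))
  p2 <- predict_classical(m2, matrix(0.15, 1, 1))
  expect_equal(unname(p2[1, "high"]), 3 / (3 + 6))
})

test_that("random forest retrains identically under a fixed seed", {
  set.seed(10)
  X <- matrix(rnorm(60), 30, 2)
  labels <- rep(c("low", "high"), 15)
  spec <- classical_spec(rf_trees = 100, seed = 3)
  m1 <- train_classical(X, labels, which = "rf", spec = spec)
  m2 <- train_classical(X, labels, which = "rf", spec = spec)
  expect_identical(predict_classical(m1, X), predict_classical(m2, X))
})

test_that("class weighting does not hurt minority recall on imbalanced data", {
  set.seed(12)
  n_maj <- 90; n_min <- 10
  X <- rbind(matrix(rnorm(n_maj * 2, mean = 0), n_maj, 2),
             matrix(rnorm(n_min * 2, mean = 1.2), n_min, 2))
  labels <- rep(c("low", "high"), c(n_maj, n_min))
  Xt <- rbind(matrix(rnorm(400, mean = 0), 200, 2),
              matrix(rnorm(400, mean = 1.2), 200, 2))
  lt <- rep(c("low", "high"), c(200, 200))

  knn_recall <- function(cw) {
    m <- train_classical(X, labels, class_weights = cw, which = "knn")
    confusion_and_metrics(decisions_of(predict_classical(m, Xt)), lt)$metrics["recall"]
  }
  expect_gte(knn_recall(compute_class_weights(labels)),
             knn_recall(c(low = 1, high = 1)))

  # the weighted cross-entropy of the LSTM shifts decisions the same way
  mkseq <- function(M) lapply(seq_len(nrow(M)), function(i) {
    matrix(rep(M[i, ], each = 6), 6, 2) + rnorm(12, sd = 0.05)
  })
  str_tr <- mkseq(X); str_te <- mkseq(Xt)
  lstm_recall <- function(cw) {
    m <- train_lstm(str_tr, labels, class_weights = cw,
                    spec = lstm_spec(epochs = 20, batch_size = 32, seed = 3,
                                     layer1_units = 16, layer2_units = 8))
    confusion_and_metrics(decisions_of(predict_lstm(m, str_te)), lt)$metrics["recall"]
  }
  expect_gte(lstm_recall(compute_class_weights(labels)),
             lstm_recall(c(low = 1, high = 1)))
})

test_that("per-modality LSTM batch presets are exposed", {
  expect_identical(lstm_batch_size("eeg"), 128L)
  expect_identical(lstm_batch_size("gsr"), 32L)
  expect_identical(lstm_batch_size("ppg"), 64L)
  expect_identical(lstm_batch_size("physio"), 32L)
  expect_error(lstm_batch_size("emg"), "unknown")
})

test_that("flat vectors are the window means of the sequences", {
  sim <- make_shifted_sequences(3, T_ = 6, D = 4, seed = 13)
  flat <- flatten_feature_sequences(sim$sequences)
  expect_identical(dim(flat), c(6L, 4L))
  expect_equal(flat[2, ], colMeans(sim$sequences[[2]]), tolerance = 1e-12)
})
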