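# Label binarization, decision fusion, fold construction and metrics.

test_that("rating binarization uses 5 as the (low-inclusive) threshold", {
  expect_identical(binarize_rating(7), "high")
  expect_identical(binarize_rating(3), "low")
  expect_identical(binarize_rating(5), "low")
  expect_identical(binarize_rating(c(1, 5, 6, 9)), c("low", "low", "high", "high"))
  expect_error(binarize_rating(0), "1..9")
  expect_error(binarize_rating(10), "1..9")
  expect_error(binarize_rating(4.5), "1..9")
})

test_that("majority vote matches exhaustive enumeration on all 8 patterns", {
  patterns <- expand.grid(v1 = c("low", "high"), v2 = c("low", "high"),
                          v3 = c("low", "high"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(patterns))) {
    votes <- unlist(patterns[i, ])
    n_high <- 0
    for (v in votes) if (v == "high") n_high <- n_high + 1
    expect_identical(majority_vote(votes), if (n_high > 1) "high" else "low")
  }
  expect_error(majority_vote(c("low", "high")), "3 votes")
})

test_that("weighted fusion is the stated convex combination", {
  pv <- c(0.6, 0.4); pe <- c(0.2, 0.8); pp <- c(0.4, 0.6)
  f <- weighted_fusion(pv, pe, pp, c(1 / 3, 1 / 3, 1 / 3))
  expect_equal(unname(f$pair), c(0.4, 0.6))
  expect_identical(f$decision, "high")
  # corner weights reproduce the single modality exactly
  expect_identical(unname(weighted_fusion(pv, pe, pp, c(1, 0, 0))$pair), pv)
  expect_identical(unname(weighted_fusion(pv, pe, pp, c(0, 1, 0))$pair), pe)
  expect_identical(unname(weighted_fusion(pv, pe, pp, c(0, 0, 1))$pair), pp)
  # a 0.5 tie resolves to high
  expect_identical(weighted_fusion(c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.5),
                                   c(0.2, 0.3, 0.5))$decision, "high")
  set.seed(1)
  for (i in 1:20) {
    w <- diff(c(0, sort(runif(2)), 1))
    pairs <- lapply(1:3, function(j) { p <- runif(1); c(p, 1 - p) })
    fused <- weighted_fusion(pairs[[1]], pairs[[2]], pairs[[3]], w)$pair
    expect_equal(unname(sum(fused)), 1, tolerance = 1e-12)
  }
  expect_error(weighted_fusion(pv, pe, pp, c(0.5, 0.4, 0.4)), "summing to 1")
})

test_that("the weight grid enumerates the 0.01 simplex in tie-break order", {
  grid <- fusion_weight_grid()
  expect_identical(nrow(grid), 5151L)
  expect_true(all(abs(grid$a + grid$b + grid$c - 1) < 1e-12))
  expect_true(all(grid$c >= 0))
  ord <- order(grid$a, grid$b)
  expect_identical(ord, seq_len(nrow(grid)))
})

test_that("weight search finds a perfect modality and ties to (0,0,1)", {
  set.seed(3)
  n <- 40
  labels <- rep(c("low", "high"), each = n / 2)
  truth_high <- labels == "high"
  perfect <- cbind(low = ifelse(truth_high, 0.1, 0.9),
                   high = ifelse(truth_high, 0.9, 0.1))
  noise <- function() { p <- runif(n); cbind(low = 1 - p, high = p) }
  w <- search_fusion_weights(perfect, noise(), noise(), labels)
  expect_equal(attr(w, "f1"), 1)
  # identical modalities make the F-score constant: lexicographic tie-break
  same <- noise()
  w_tie <- search_fusion_weights(same, same, same, labels)
  expect_equal(unname(w_tie), c(0, 0, 1), ignore_attr = TRUE)
})

test_that("learned weights never fall below the best single modality in training", {
  set.seed(4)
  n <- 60
  labels <- sample(c("low", "high"), n, replace = TRUE, prob = c(0.45, 0.55))
  mk <- function(acc) {
    p <- ifelse(labels == "high", acc, 1 - acc) + rnorm(n, sd = 0.15)
    p <- pmin(pmax(p, 0.01), 0.99)
    cbind(low = 1 - p, high = p)
  }
  Pv <- mk(0.7); Pe <- mk(0.8); Pp <- mk(0.6)
  w <- search_fusion_weights(Pv, Pe, Pp, labels)
  f_single <- vapply(list(Pv, Pe, Pp), function(P) {
    confusion_and_metrics(ifelse(P[, "high"] >= 0.5, "high", "low"),
                          labels)$metrics["f1"]
  }, numeric(1))
  expect_gte(attr(w, "f1"), max(f_single))
})

test_that("fold plans partition subjects with near-equal test sizes", {
  ids18 <- sprintf("P%02d", 1:18)
  plan18 <- make_folds(ids18, 6, seed = 2)
  sizes18 <- vapply(plan18, function(f) length(f$test), integer(1))
  expect_identical(sizes18, rep(3L, 6))

  ids23 <- sprintf("P%02d", 1:23)
  plan23 <- make_folds(ids23, 6, seed = 2)
  sizes23 <- vapply(plan23, function(f) length(f$test), integer(1))
  expect_identical(sort(sizes23, decreasing = TRUE), c(4L, 4L, 4L, 4L, 4L, 3L))

  for (plan in list(plan18, plan23)) {
    tests <- unlist(lapply(plan, `[[`, "test"))
    expect_identical(sort(tests), sort(if (length(tests) == 18) ids18 else ids23))
    expect_identical(anyDuplicated(tests), 0L)
    for (f in plan) {
      expect_length(intersect(f$train, f$test), 0)
      expect_setequal(c(f$train, f$test), if (length(tests) == 18) ids18 else ids23)
    }
  }
  expect_identical(make_folds(ids23, 6, seed = 2), plan23)
  expect_error(make_folds(ids18[1:5], 6), "fewer subjects")
})

test_that("confusion metrics follow the standard identities", {
  pred <- rep(c("high", "high", "low", "low"), c(3, 1, 2, 4))
  labs <- rep(c("high", "low", "high", "low"), c(3, 1, 2, 4))
  cm <- confusion_and_metrics(pred, labs)
  expect_identical(unname(cm$counts), c(3L, 1L, 2L, 4L))
  expect_equal(unname(cm$metrics),
               c(0.7, 0.75, 0.6, 2 * (0.75 * 0.6) / 1.35))

  perfect <- confusion_and_metrics(labs, labs)
  expect_equal(unname(perfect$metrics), rep(1, 4))

  degenerate <- confusion_and_metrics(rep("high", 4), rep("low", 4))
  expect_equal(unname(degenerate$metrics), c(0, 0, 0, 0))

  set.seed(5)
  for (i in 1:10) {
    p <- sample(c("low", "high"), 30, replace = TRUE)
    l <- sample(c("low", "high"), 30, replace = TRUE)
    cm <- confusion_and_metrics(p, l)
    with(as.list(cm$counts), {
      expect_identical(TP + FP + FN + TN, 30L)
      expect_equal(unname(cm$metrics["accuracy"]), (TP + TN) / 30)
    })
    P <- cm$metrics["precision"]; R <- cm$metrics["recall"]
    if (P + R > 0) {
      expect_equal(unname(cm$metrics["f1"]), unname(2 * P * R / (P + R)),
                   tolerance = 1e-12)
    }
  }
  expect_error(confusion_and_metrics(character(0), character(0)), "empty")
})

test_that("fold averaging is the unweighted mean of per-fold metrics", {
  m <- list(c(accuracy = 1, precision = 1, recall = 1, f1 = 1),
            c(accuracy = 0.5, precision = 0, recall = 0, f1 = 0))
  expect_equal(unname(fold_average(m)), c(0.75, 0.5, 0.5, 0.5))
})
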