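two_clusters <- function(n = 40, gap = 8, p = 2, seed = 1) {
  set.seed(seed)
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X <- matrix(rnorm(n * p), n)
  X[y, ] <- X[y, ] + gap
  colnames(X) <- sprintf("f%d", seq_len(p))
  list(X = X, y = y)
}

test_that("CV objective is zero for separable clusters, deterministic, and near chance for shuffled labels", {
  d <- two_clusters()
  expect_equal(cv_objective(d$X, d$y, colnames(d$X), seed = 1), 0)
  v1 <- cv_objective(d$X, d$y, "f1", repeats = 3, seed = 7)
  v2 <- cv_objective(d$X, d$y, "f1", repeats = 3, seed = 7)
  expect_identical(v1, v2)

  set.seed(2)
  n <- 200
  X <- matrix(rnorm(n * 2), n); colnames(X) <- c("a", "b")
  y <- sample(rep(c(TRUE, FALSE), each = n / 2))
  # on non-separable data the fold draw matters, so different seeds must
  # produce more than one distinct value
  vals <- vapply(1:5, function(s) cv_objective(X, y, "a", repeats = 1,
                                               seed = s), numeric(1))
  expect_gt(length(unique(vals)), 1)
  err <- cv_objective(X, y, c("a", "b"), repeats = 20, seed = 3)
  # null error 0.5 with SE ~ sqrt(0.25/200); allow 3 SE
  expect_lt(abs(err - 0.5), 3 * sqrt(0.25 / n))
  expect_error(cv_objective(X, rep(TRUE, n), "a"), "two classes")
  expect_error(cv_objective(X, y, character(0)), "nonempty")
})

test_that("sequential selection returns nothing under an infinite tolerance and respects max_features", {
  d <- two_clusters(p = 4)
  s0 <- sequential_select(d$X, d$y, tol = Inf, repeats = 1)
  expect_length(s0$selected, 0)
  expect_equal(s0$stopping, "tolerance")
  s1 <- sequential_select(d$X, d$y, tol = 1e-6, repeats = 1,
                          max_features = 1)
  expect_length(s1$selected, 1)
  expect_equal(s1$stopping, "max_features")
  # accepted objectives strictly improve by at least the tolerance
  expect_true(all(-diff(s1$objective) >= 1e-6))
})

test_that("selection recovers a small planted signal ahead of noise features", {
  hits <- vapply(1:5, function(rep) {
    set.seed(500 + rep)
    n <- 60
    y <- rep(c(TRUE, FALSE), each = n / 2)
    X <- matrix(rnorm(n * 12), n)
    colnames(X) <- c("sig1", "sig2", sprintf("noise%02d", 1:10))
    X[y, 1:2] <- X[y, 1:2] + 3
    sel <- sequential_select(X, y, repeats = 3, max_features = 2,
                             seed = rep)
    all(grepl("^sig", sel$selected))
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("selection is invariant to feature column order", {
  d <- two_clusters(n = 30, gap = 3, p = 5, seed = 4)
  s1 <- sequential_select(d$X, d$y, repeats = 2, max_features = 2, seed = 1)
  perm <- c(4, 2, 5, 1, 3)
  s2 <- sequential_select(d$X[, perm], d$y, repeats = 2, max_features = 2,
                          seed = 1)
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$objective, s2$objective)
})

test_that("the trained SVM reproduces its own decision values through the explicit score equation", {
  d <- two_clusters(n = 40, gap = 2.5, p = 3, seed = 6)
  m <- train_svm(d$X, d$y)
  # training accuracy on separable-ish data
  acc <- mean((svm_score(m, d$X) >= 0) == d$y)
  expect_gte(acc, 0.95)
  # internal consistency: e1071 decision values vs explicit f(x)
  z <- scale(d$X, center = m$center, scale = m$scale)
  dec <- attr(stats::predict(m$fit, z, decision.values = TRUE),
              "decision.values")
  ours <- svm_score(m, d$X)
  expect_lt(max(abs(abs(dec) - abs(ours))), 1e-8)

  # permuting the training order leaves the decision function unchanged
  set.seed(8); perm <- sample(nrow(d$X))
  m2 <- train_svm(d$X[perm, ], d$y[perm])
  expect_lt(max(abs(svm_score(m2, d$X) - ours)), 1e-6)

  Xc <- cbind(d$X, const = 1)
  expect_error(train_svm(Xc, d$y), "constant")
})

test_that("svm_score evaluates the kernel expansion exactly as written", {
  base <- list(sv = matrix(0, 1, 1), weights = 0, b = 0,
               center = 0, scale = 1, features = "x", levels = c("neg", "pos"))
  m0 <- structure(base, class = "svm_model")
  expect_equal(svm_score(m0, 0.3), 0)

  m1 <- structure(utils::modifyList(base, list(weights = 1)),
                  class = "svm_model")
  expect_equal(svm_score(m1, 0), 1)  # G at zero distance is 1

  # two support vectors at distances 1 and 2, weights +1/-1, bias 0.5
  m2 <- structure(list(sv = matrix(c(1, 2), 2, 1), weights = c(1, -1),
                       b = 0.5, center = 0, scale = 1, features = "x",
                       levels = c("neg", "pos")),
                  class = "svm_model")
  expect_equal(svm_score(m2, 0), exp(-1) - exp(-4) + 0.5, tolerance = 1e-12)
  expect_error(svm_score(m2, NA_real_), "finite")

  # score bounded by sum |w| + |b|
  set.seed(10)
  xs <- matrix(rnorm(200), 200, 1)
  expect_true(all(abs(svm_score(m2, xs)) <= sum(abs(m2$weights)) +
                    abs(m2$b) + 1e-12))
})

test_that("ROC analysis: trapezoid AUC equals the normalized rank-sum statistic", {
  set.seed(12)
  for (i in 1:5) {
    sc <- rnorm(50)
    y <- runif(50) < plogis(sc)
    if (length(unique(y)) < 2) next
    r <- roc_analysis(sc, y)
    n1 <- sum(y); n0 <- sum(!y)
    u <- sum(rank(sc)[y]) - n1 * (n1 + 1) / 2
    expect_equal(r$auc, u / (n1 * n0), tolerance = 1e-10)
  }
  # perfectly separated scores
  r <- roc_analysis(c(rep(1, 5), rep(0, 5)),
                    c(rep(TRUE, 5), rep(FALSE, 5)))
  expect_equal(r$auc, 1)
  expect_lte(r$cutoff, 1); expect_gt(r$cutoff, 0)
  expect_error(roc_analysis(1:5, rep(TRUE, 5)), "two classes")
})

test_that("ROC under the null is near 0.5 and agrees with pROC", {
  set.seed(13)
  sc <- rnorm(2000); y <- sample(rep(c(TRUE, FALSE), 1000))
  expect_lt(abs(roc_analysis(sc, y)$auc - 0.5), 0.03)
  skip_if_not_installed("pROC")
  sc2 <- rnorm(80); y2 <- runif(80) < plogis(1.5 * sc2)
  ours <- roc_analysis(sc2, y2)
  ref <- pROC::roc(y2, sc2, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  yj <- pROC::coords(ref, "best", best.method = "youden",
                     transpose = FALSE)
  expect_equal(max(ours$roc$tpr - ours$roc$fpr),
               max(yj$sensitivity + yj$specificity - 1), tolerance = 1e-10)
})

test_that("confusion counts, accuracy and the >= cutoff rule are exact", {
  sc <- c(0.9, 0.8, 0.3, 0.7, 0.2, 0.6)
  y <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  cf <- confusion(sc, y, 0.6)
  expect_equal(c(cf$tp, cf$tn, cf$fp, cf$fn), c(2, 1, 2, 1))
  expect_equal(cf$tp + cf$tn + cf$fp + cf$fn, length(y))
  expect_equal(cf$accuracy, (cf$tp + cf$tn) / 6)
  # boundary: score equal to the cutoff is called positive
  cf2 <- confusion(c(0.5, 0.4), c(TRUE, FALSE), 0.5)
  expect_equal(cf2$tp, 1); expect_equal(cf2$tn, 1)
  all_right <- confusion(c(1, 1, 0), c(TRUE, TRUE, FALSE), 0.5)
  expect_equal(all_right$accuracy, 1)
})
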