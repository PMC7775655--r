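## Standardization helper: center/scale columns by training statistics.
## A zero-variance column is an error for model fitting (train_svm) but is
## tolerated inside CV folds (scale 1) so a candidate feature that is
## constant in one fold does not abort a whole selection run.
std_params <- function(X, on_constant = c("keep", "error")) {
  on_constant <- match.arg(on_constant)
  n <- nrow(X)
  ctr <- colMeans(X)
  scl <- sqrt(pmax(colSums(X^2) - n * ctr^2, 0) / (n - 1))
  if (any(scl == 0)) {
    if (on_constant == "error")
      stop_if_not(FALSE, "degenerate (constant) feature: %s",
                  paste(colnames(X)[scl == 0], collapse = ", "))
    scl[scl == 0] <- 1
  }
  list(center = ctr, scale = scl)
}

apply_std <- function(X, p) scale(X, center = p$center, scale = p$scale)

as_binary_factor <- function(y) {
  if (is.logical(y)) y <- factor(y, levels = c(FALSE, TRUE),
                                 labels = c("neg", "pos"))
  y <- droplevels(as.factor(y))
  stop_if_not(nlevels(y) == 2, "y must contain exactly two classes (got %d)",
              nlevels(y))
  y
}

## Positive class = second factor level (TRUE for logical input).
positive_level <- function(y) levels(y)[2]

#' Cross-validated SVM objective for a feature subset
#'
#' Mean misclassification rate of a Gaussian-kernel SVM (kernel
#' `exp(-||u - v||^2)`, box constraint C = 1) over stratified k-fold
#' cross-validation, repeated with re-randomized folds.  Features are
#' standardized inside each training fold only; the held-out fold is
#' standardized with the training statistics.
#'
#' @param X numeric matrix or data.frame of features (cases x features).
#' @param y two-class outcome (logical or factor).
#' @param feature_subset nonempty column names or indices to use.
#' @param folds number of CV folds (default 10); folds are stratified and
#'   capped at the smaller class size.
#' @param repeats number of fold re-randomizations averaged over.
#' @param seed integer seed controlling the fold draws (identical seeds
#'   give identical values).
#' @param metric `"error"` (default): misclassification rate at the
#'   decision boundary; `"auc"`: 1 - AUC of the pooled out-of-fold
#'   decision values (a finer-grained loss for small samples).
#' @return mean loss in `[0, 1]` (error rate or 1 - AUC).
#' @export
cv_objective <- function(X, y, feature_subset, folds = 10, repeats = 1,
                         seed = 1L, metric = c("error", "auc")) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  y <- as_binary_factor(y)
  stop_if_not(length(feature_subset) >= 1, "feature subset must be nonempty")
  stop_if_not(min(table(y)) >= 2, "need at least 2 cases per class")
  Xs <- X[, feature_subset, drop = FALSE]
  n <- nrow(Xs)
  k <- min(folds, min(table(y)))
  with_seed(seed, {
    errs <- numeric(repeats)
    for (r in seq_len(repeats)) {
      fold <- integer(n)
      for (cl in levels(y)) {
        id <- which(y == cl)
        fold[id] <- sample(rep_len(seq_len(k), length(id)))
      }
      wrong <- 0
      oof <- numeric(n)   # out-of-fold decision values, oriented to "pos"
      for (f in seq_len(k)) {
        tr <- fold != f
        p <- std_params(Xs[tr, , drop = FALSE], on_constant = "keep")
        fit <- e1071::svm(apply_std(Xs[tr, , drop = FALSE], p), y[tr],
                          type = "C-classification", kernel = "radial",
                          gamma = 1, cost = 1, scale = FALSE, fitted = FALSE)
        # decision values computed directly from the support-vector
        # expansion (equivalent to predict(), cheaper inside the loop)
        zt <- apply_std(Xs[!tr, , drop = FALSE], p)
        d2 <- outer(rowSums(zt^2), rowSums(fit$SV^2), `+`) -
          2 * zt %*% t(fit$SV)
        dec <- exp(-pmax(d2, 0)) %*% fit$coefs - fit$rho
        # positive decision = first class in libsvm's internal order
        lvl_pos <- fit$levels[fit$labels[1]]
        wrong <- wrong + sum((dec > 0) != (y[!tr] == lvl_pos))
        oof[!tr] <- if (lvl_pos == positive_level(y)) dec else -dec
      }
      errs[r] <- if (metric == "error") wrong / n else {
        pos <- y == positive_level(y)
        u <- sum(rank(oof)[pos]) - sum(pos) * (sum(pos) + 1) / 2
        1 - u / (sum(pos) * sum(!pos))
      }
    }
    mean(errs)
  })
}

#' Train the Gaussian-kernel SVM on selected features
#'
#' Fits a C-classification SVM with kernel `G(x_n, x) = exp(-||x_n - x||^2)`
#' and C = 1 on standardized selected features and stores the explicit
#' decision-function representation: support vectors `x_n`, signed weights
#' `w_n y_n`, bias `b` and the standardization parameters.  The stored
#' representation is oriented so that higher [svm_score()] means the
#' positive class (second level of `y`; `TRUE` for logical outcomes).
#'
#' @param X feature matrix or data.frame.
#' @param y two-class outcome.
#' @param subset column names or indices of the features to use (defaults
#'   to all columns).
#' @return an `svm_model` list with elements `sv`, `weights` (= w_n y_n),
#'   `b`, `center`, `scale`, `features`, `levels`, and the underlying
#'   e1071 fit as `fit`.
#' @export
train_svm <- function(X, y, subset = colnames(X) %||% seq_len(ncol(X))) {
  X <- as.matrix(X)
  y <- as_binary_factor(y)
  Xs <- X[, subset, drop = FALSE]
  p <- std_params(Xs, on_constant = "error")
  Z <- apply_std(Xs, p)
  # tight optimizer tolerance so the stored decision function is
  # invariant to training order well below the score scale
  fit <- e1071::svm(Z, y, type = "C-classification", kernel = "radial",
                    gamma = 1, cost = 1, scale = FALSE, tolerance = 1e-8)
  model <- structure(list(sv = unname(as.matrix(fit$SV)),
                          weights = as.numeric(fit$coefs),
                          b = -fit$rho,
                          center = p$center, scale = p$scale,
                          features = colnames(Xs) %||% subset,
                          levels = levels(y), fit = fit),
                     class = "svm_model")
  # orient the score so that larger values indicate the positive class
  sc <- svm_score(model, Xs)
  if (mean(sc[y == positive_level(y)]) < mean(sc[y != positive_level(y)])) {
    model$weights <- -model$weights
    model$b <- -model$b
  }
  model
}

#' Evaluate the SVM decision score
#'
#' Computes `f(x) = sum_n w_n y_n exp(-||x_n - x||^2) + b` over the stored
#' support vectors, after applying the model's feature standardization to
#' `x`.  This continuous decision value is the per-case radiomics risk
#' score.
#'
#' @param model an `svm_model` from [train_svm()].
#' @param x numeric vector (one case) or matrix (cases x features) on the
#'   original feature scale.
#' @return numeric score(s).
#' @export
svm_score <- function(model, x) {
  stopifnot(inherits(model, "svm_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  stop_if_not(ncol(x) == ncol(model$sv),
              "input has %d features; model expects %d", ncol(x),
              ncol(model$sv))
  stop_if_not(all(is.finite(x)), "non-finite feature values in input")
  z <- scale(x, center = model$center, scale = model$scale)
  d2 <- outer(rowSums(z^2), rowSums(model$sv^2), `+`) -
    2 * z %*% t(model$sv)
  as.numeric(exp(-pmax(d2, 0)) %*% model$weights + model$b)
}
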