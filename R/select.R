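#' Sequential forward feature selection under an SVM objective
#'
#' Starting from an empty candidate set, every unselected feature is
#' evaluated by the cross-validated Gaussian-kernel SVM misclassification
#' rate ([cv_objective()]) with the candidate added; the best feature is
#' accepted if it improves the objective by at least `tol`, and selection
#' stops otherwise (or at `max_features`).  All candidates within a step
#' share the same fold randomization, so comparisons are paired.  Ties are
#' broken toward the first feature in canonical (sorted-name) order.
#'
#' The baseline objective of the empty set is the misclassification rate of
#' the majority-class predictor.
#'
#' @param X feature matrix or data.frame (>= 1 column).
#' @param y two-class outcome.
#' @param tol termination tolerance on objective improvement (default 1e-6).
#' @param repeats fold re-randomizations per evaluation (the study setting
#'   is 1000; tests use reduced values).
#' @param max_features cap on the number of selected features (the study
#'   model uses 3).
#' @param folds CV folds (default 10).
#' @param metric CV loss passed to [cv_objective()]: `"error"` or `"auc"`.
#' @param seed integer seed; step s uses fold seed `seed + s`.
#' @return a `selection_result`: `selected` (ordered names), `objective`
#'   (per-step accepted CV error, starting with the baseline), `stopping`
#'   (`"tolerance"` or `"max_features"`), `repeats`, `seed`.
#' @export
sequential_select <- function(X, y, tol = 1e-6, repeats = 1000,
                              max_features = Inf, folds = 10,
                              metric = c("error", "auc"), seed = 1L) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  stop_if_not(ncol(X) >= 1, "X must have at least one feature column")
  stop_if_not(repeats >= 1, "repeats must be >= 1")
  y <- as_binary_factor(y)
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%04d", seq_len(ncol(X)))
  canon <- order(colnames(X))  # canonical candidate order for tie-breaks
  selected <- character(0)
  # baseline: majority-class error, or chance AUC loss of 0.5
  objective <- if (metric == "error") 1 - max(table(y)) / length(y) else 0.5
  stopping <- "tolerance"
  step <- 0L
  while (length(selected) < min(max_features, ncol(X))) {
    step <- step + 1L
    cands <- setdiff(colnames(X)[canon], selected)
    # reference: the current set re-evaluated under this step's folds, so
    # acceptance is a paired comparison (a feature that changes nothing
    # cannot look like an improvement through fold noise alone)
    ref <- if (length(selected) == 0) objective[1] else
      cv_objective(X, y, selected, folds = folds, repeats = repeats,
                   seed = seed + step, metric = metric)
    vals <- vapply(cands, function(f) {
      cv_objective(X, y, c(selected, f), folds = folds, repeats = repeats,
                   seed = seed + step, metric = metric)
    }, numeric(1))
    best <- which.min(vals)  # first minimum in canonical order
    if (ref - vals[best] < tol) break
    selected <- c(selected, cands[best])
    objective <- c(objective, vals[best])
    if (length(selected) >= max_features) { stopping <- "max_features"; break }
  }
  structure(list(selected = selected, objective = objective,
                 stopping = stopping, repeats = repeats, seed = seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d feature(s): %s\n", length(x$selected),
              paste(x$selected, collapse = ", ")))
  cat(sprintf("  CV error: %s (stopped by %s, %d repeats)\n",
              paste(signif(x$objective, 4), collapse = " -> "),
              x$stopping, x$repeats))
  invisible(x)
}
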