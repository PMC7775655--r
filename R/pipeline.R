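#' Pipeline configuration
#'
#' Validates and freezes every tunable of the end-to-end run: cohort
#' simulation, segmentation (FCM), ROI erosion depths, discretization,
#' SVM feature selection, cutoff criterion and reporting.  The full
#' configuration (plus its hash and seed) is serialized into every output
#' for provenance.
#'
#' @param out_dir run directory to create.
#' @param seed master seed; all stage seeds derive from it.
#' @param cohort a [cohort_spec()] (its own seed is overridden by `seed`).
#' @param segment if `TRUE`, segment tumors from the images with FCM; if
#'   `FALSE`, use the simulation truth masks (fast path).
#' @param fcm list of FCM parameters: `n_clusters`, `m`, `tol`, `max_iter`.
#' @param erosion_depths_cm ROI variants to analyse (subset of
#'   c(0, 0.25, 0.5)).
#' @param n_bins discretization levels.
#' @param selection list: `tol`, `repeats`, `max_features`, `folds`.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            cohort = cohort_spec(),
                            segment = TRUE,
                            fcm = list(n_clusters = 2, m = 2, tol = 1e-5,
                                       max_iter = 300),
                            erosion_depths_cm = c(0, 0.25, 0.5),
                            n_bins = 32,
                            selection = list(tol = 1e-6, repeats = 5,
                                             max_features = 3, folds = 10)) {
  stop_if_not(is.character(out_dir) && nzchar(out_dir), "out_dir is required")
  stop_if_not(inherits(cohort, "cohort_spec"), "cohort must be a cohort_spec")
  stop_if_not(all(erosion_depths_cm %in% c(0, 0.25, 0.5)),
              "erosion depths must be within {0, 0.25, 0.5}")
  fcm <- utils::modifyList(list(n_clusters = 2, m = 2, tol = 1e-5,
                                max_iter = 300), fcm)
  selection <- utils::modifyList(list(tol = 1e-6, repeats = 5,
                                      max_features = 3, folds = 10),
                                 selection)
  stop_if_not(n_bins >= 2 && selection$repeats >= 1, "invalid configuration")
  structure(list(out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
                 segment = isTRUE(segment), fcm = fcm,
                 erosion_depths_cm = erosion_depths_cm, n_bins = n_bins,
                 selection = selection),
            class = "pipeline_config")
}

variant_name <- function(depth) {
  if (depth == 0) "original" else if (depth == 0.25) "eroded_025"
  else "eroded_05"
}

## Cross-validated SVM scores: each case is scored by a model trained on
## the folds it does not belong to, so the confusion table is out-of-fold.
cv_scores <- function(X, y, subset, folds = 10, seed = 1L) {
  X <- as.matrix(X)
  y <- as_binary_factor(y)
  k <- min(folds, min(table(y)))
  with_seed(seed, {
    fold <- integer(nrow(X))
    for (cl in levels(y)) {
      id <- which(y == cl)
      fold[id] <- sample(rep_len(seq_len(k), length(id)))
    }
    sc <- numeric(nrow(X))
    for (f in seq_len(k)) {
      tr <- fold != f
      m <- train_svm(X[tr, , drop = FALSE], y[tr], subset)
      sc[!tr] <- svm_score(m, X[!tr, subset, drop = FALSE])
    }
    sc
  })
}

## Segment one case with the configured chain: isotropic resampling of
## both channels, box normalization, slice-wise FCM on T1CE, 3D cleanup,
## and mask transfer onto the (identically resampled) T2 grid.
segment_case <- function(cs, fcm_par, seed) {
  target <- min(cs$t1ce$spacing)
  t1r <- resample_isotropic(cs$t1ce, target)
  t2r <- resample_isotropic(cs$t2, target)
  ## surrogate for the operator's initialization: in-plane rectangle with
  ## margin, slice range exactly covering the lesion
  truth_r <- transfer_mask(cs$mask, diag(4), t1r)
  bb <- mask_bbox(truth_r$data, pad = 4L)
  bbz <- mask_bbox(truth_r$data, pad = 0L)
  roi <- bounding_roi(rect = c(bb$lo[1], bb$hi[1], bb$lo[2], bb$hi[2]),
                      slices = c(bbz$lo[3], bbz$hi[3]))
  box <- array(FALSE, dim = dim(t1r$data))
  box[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bbz$lo[3]:bbz$hi[3]] <- TRUE
  t1n <- normalize_roi(t1r, box)
  raw <- fcm_segment(t1n, roi, n_clusters = fcm_par$n_clusters,
                     m = fcm_par$m, tol = fcm_par$tol,
                     max_iter = fcm_par$max_iter, seed = seed)
  mask <- postprocess_mask(raw)
  list(t1ce = t1r, t2 = t2r, mask = mask, truth = truth_r,
       record = cs$record)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full radiomics pipeline
#'
#' Executes simulate -> segment -> features (one pass per ROI variant) ->
#' sequential selection -> cross-validated SVM scores -> ROC/cutoff ->
#' confusion table per variant -> survival analysis, writing masks,
#' feature CSVs, the model JSON, scores and reports under the run
#' directory.  Deterministic under a fixed config seed.
#'
#' @param config a [pipeline_config()].
#' @param cases optional pre-existing list of cases (each
#'   `list(t1ce, t2, mask, record)`), bypassing cohort simulation.
#' @return (invisibly) a list with the per-variant results and the paths
#'   written.
#' @export
run_pipeline <- function(config, cases = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  for (d in c("", "masks", "features", "model", "reports"))
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)

  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                               auto_unbox = TRUE, digits = NA, force = TRUE)
  cfg_path <- file.path(out, "config.json")
  writeLines(cfg_json, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  sim <- if (is.null(cases)) {
    cohort <- config$cohort
    cohort$rng_seed <- config$seed
    stage("simulate", generate_cohort(cohort, keep_images = TRUE))
  } else {
    list(records = do.call(rbind, lapply(cases, `[[`, "record")),
         cases = cases)
  }
  stage("simulate", {
    for (i in seq_along(sim$cases)) {
      cs <- sim$cases[[i]]
      for (ch in c("t1ce", "t2", "mask"))
        stop_if_not(!is.null(cs[[ch]]), "case %s is missing the %s channel",
                    cs$record$case_id, ch)
    }
  })
  write_cohort_csv(sim$records, file.path(out, "cohort.csv"))

  cases <- stage("segment", {
    if (config$segment) {
      lapply(seq_along(sim$cases), function(i)
        segment_case(sim$cases[[i]], config$fcm, seed = config$seed + i))
    } else sim$cases
  })
  dice_truth <- if (config$segment) {
    vapply(cases, function(cs) {
      2 * sum(cs$mask$data & cs$truth$data) /
        (sum(cs$mask$data) + sum(cs$truth$data))
    }, numeric(1))
  } else rep(NA_real_, length(cases))
  for (i in seq_along(cases))
    write_mask(cases[[i]]$mask,
               file.path(out, "masks", paste0(cases[[i]]$record$case_id,
                                              "_mask.nii.gz")))

  y <- sim$records$pr
  results <- list()
  for (depth in config$erosion_depths_cm) {
    vn <- variant_name(depth)
    feats <- stage(paste0("features_", vn),
                   extract_cohort_features(cases, erosion_cm = depth,
                                           n_bins = config$n_bins))
    fpath <- file.path(out, "features", paste0("features_", vn, ".csv"))
    utils::write.csv(cbind(config_hash = cfg_hash, seed = config$seed, feats),
                     fpath, row.names = FALSE)
    X <- as.matrix(feats[, setdiff(names(feats), "case_id")])
    yv <- y[match(feats$case_id, sim$records$case_id)]
    sel <- stage(paste0("select_", vn),
                 sequential_select(X, yv, tol = config$selection$tol,
                                   repeats = config$selection$repeats,
                                   max_features = config$selection$max_features,
                                   folds = config$selection$folds,
                                   seed = config$seed))
    subset <- sel$selected
    if (length(subset) == 0)  # tolerance stopped before any feature
      subset <- colnames(X)[1]
    model <- stage(paste0("model_", vn), train_svm(X, yv, subset))
    scores <- stage(paste0("score_", vn),
                    cv_scores(X, yv, subset,
                              folds = config$selection$folds,
                              seed = config$seed + 1000L))
    roc <- roc_analysis(scores, yv)
    conf <- confusion(scores, yv, roc$cutoff)
    jsonlite::write_json(
      list(config_hash = cfg_hash, seed = config$seed, variant = vn,
           selected = sel$selected, objective = sel$objective,
           support_vectors = model$sv, weights = model$weights, b = model$b,
           center = as.list(model$center), scale = as.list(model$scale)),
      file.path(out, "model", paste0("model_", vn, ".json")),
      auto_unbox = TRUE, digits = NA)
    utils::write.csv(data.frame(config_hash = cfg_hash, seed = config$seed,
                                case_id = feats$case_id, score = scores,
                                pr = yv),
                     file.path(out, "features",
                               paste0("scores_", vn, ".csv")),
                     row.names = FALSE)
    results[[vn]] <- list(selection = sel, model = model, scores = scores,
                          roc = roc, confusion = conf,
                          feature_csv = fpath)
  }

  ## survival analysis on the original-variant score
  vn0 <- variant_name(config$erosion_depths_cm[1])
  rec <- sim$records
  rec$svm_score <- results[[vn0]]$scores
  cut <- results[[vn0]]$roc$cutoff
  km <- stage("outcome", km_logrank(rec, function(r) r$svm_score >= cut))
  cox_uni <- stage("outcome",
                   cox_fit(rec, c("sex_male", "age", "height_mm",
                                  "volume_cm3", "svm_score"),
                           mode = "univariate"))
  table3 <- do.call(rbind, lapply(names(results), function(vn) {
    cf <- results[[vn]]$confusion
    data.frame(variant = vn, tp = cf$tp, tn = cf$tn, fp = cf$fp, fn = cf$fn,
               accuracy = cf$accuracy, auc = cf$auc)
  }))
  utils::write.csv(cbind(config_hash = cfg_hash, seed = config$seed, table3),
                   file.path(out, "reports", "performance_by_variant.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(config_hash = cfg_hash, seed = config$seed, cox_uni),
                   file.path(out, "reports", "cox_univariate.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(config_hash = cfg_hash, seed = config$seed,
         km_logrank_p = km$p,
         cutoff = cut,
         median_dice_vs_truth = stats::median(dice_truth),
         performance = table3),
    file.path(out, "reports", "summary.json"), auto_unbox = TRUE,
    digits = NA, dataframe = "rows")
  invisible(list(results = results, records = rec, km = km,
                 cox = cox_uni, table3 = table3, dice = dice_truth,
                 config_hash = cfg_hash))
}
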