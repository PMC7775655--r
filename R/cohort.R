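#' Specify a phantom cohort
#'
#' A cohort emulates the study population the analysis assumes: ~50 cases in
#' two outcome classes (progression/recurrence, P/R, vs stable), with
#' class-conditional tumor size and texture-coarseness distributions,
#' censored time-to-event follow-up and paired baseline/follow-up lesion
#' dimensions that encode the >2 mm progression rule exactly.
#'
#' Class-conditional defaults reproduce the cohort summaries the analysis
#' targets: maximum tumor height lognormal with median 35.5 mm (IQR
#' 27.5-43.5) for P/R and 18 mm (IQR 10-26) for stable cases, coarser
#' within-tumor texture in the P/R class, event times with unconditional
#' median 20 months and follow-up times with median 38 months (range
#' clamped to 12-115).  Class sizes are fixed at `round(n_cases *
#' pr_prevalence)` so the target prevalence is met exactly for every seed.
#'
#' @param n_cases number of cases (>= 4 so each class has >= 2).
#' @param pr_prevalence fraction of P/R cases, strictly inside (0, 1).
#' @param class_params list with elements `pr` and `nonpr`, each a list of
#'   phantom parameter distributions (see defaults in the function body).
#' @param survival list of survival-model parameters: Weibull `shape`
#'   (1 = exponential), `baseline_rate` (1/months), log-hazard `coef` on the
#'   latent severity (class indicator), and the lognormal follow-up
#'   distribution (`followup_meanlog`, `followup_sdlog`, clamped to
#'   `followup_range` months).
#' @param grid_shape,voxel_spacing_mm phantom grid geometry shared by all
#'   cases; tumor heights are truncated to fit the grid with margin.
#' @param rng_seed integer seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_cases = 50L,
                        pr_prevalence = 0.56,
                        class_params = NULL,
                        survival = NULL,
                        grid_shape = c(64L, 64L, 32L),
                        voxel_spacing_mm = c(1, 1, 1.5),
                        rng_seed = 1L) {
  stop_if_not(pr_prevalence > 0 && pr_prevalence < 1,
              "pr_prevalence must be strictly between 0 and 1 (got %s): a single-class cohort is degenerate",
              format(pr_prevalence))
  n_pr <- round(n_cases * pr_prevalence)
  stop_if_not(n_pr >= 2 && n_cases - n_pr >= 2,
              "each outcome class needs >= 2 cases (got %d P/R, %d stable)",
              n_pr, n_cases - n_pr)
  defaults <- list(
    pr = list(height_meanlog = log(35.5), height_sdlog = 0.34,
              granularity_mean = 3, granularity_sd = 0.4,
              heterogeneity_sd = 0.7, intensity_contrast = 3),
    nonpr = list(height_meanlog = log(18), height_sdlog = 0.55,
                 granularity_mean = 1.2, granularity_sd = 0.25,
                 heterogeneity_sd = 0.4, intensity_contrast = 3))
  cp <- utils::modifyList(defaults, class_params %||% list())
  sv <- utils::modifyList(
    list(shape = 1, baseline_rate = log(2) / 60, coef = log(3),
         followup_meanlog = log(38), followup_sdlog = 0.45,
         followup_range = c(12, 115)),
    survival %||% list())
  stop_if_not(sv$shape > 0 && sv$baseline_rate > 0,
              "hazard shape and baseline rate must be positive")
  structure(list(n_cases = as.integer(n_cases),
                 pr_prevalence = pr_prevalence,
                 class_params = cp, survival = sv,
                 grid_shape = as.integer(grid_shape),
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

#' Simulate censored survival times under a proportional-hazards model
#'
#' Event times follow a Weibull model whose log hazard is linear in the
#' latent severity: S(t | z) = exp(-(rate * t)^shape * exp(coef * z)),
#' so `exp(coef)` is the hazard ratio per unit of latent severity.
#' Times are right-censored administratively at `censor_months`.
#'
#' @param latent numeric vector of latent severities (one per subject).
#' @param hazard_params list with `baseline_rate` (> 0, 1/months), `coef`,
#'   and Weibull `shape` (> 0, default 1 = exponential).
#' @param censor_months administrative censoring time (> 0).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return data.frame with `time_months` (> 0) and `event` (FALSE iff
#'   censored at `censor_months`).
#' @export
simulate_survival <- function(latent, hazard_params, censor_months,
                              seed = NULL) {
  hp <- utils::modifyList(list(shape = 1), hazard_params)
  stop_if_not(is.numeric(censor_months) && censor_months > 0,
              "censor_months must be positive")
  stop_if_not(hp$baseline_rate > 0 && hp$shape > 0,
              "baseline_rate and shape must be positive")
  draw <- function() {
    u <- stats::runif(length(latent))
    t_event <- (-log(u) / exp(hp$coef * latent))^(1 / hp$shape) /
      hp$baseline_rate
    event <- t_event <= censor_months
    data.frame(time_months = pmin(t_event, censor_months), event = event)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

## Inverse-CDF draw of an exponential event time conditioned on occurring
## before the follow-up time fu (used so the recorded P/R label, the event
## flag and the time are mutually consistent).
rexp_before <- function(rate, fu) {
  u <- stats::runif(length(fu))
  -log(1 - u * (1 - exp(-rate * fu))) / rate
}

sample_cat <- function(n, p) stats::runif(n) < p

#' Generate a full phantom cohort
#'
#' Draws class labels at the specified prevalence (fixed counts), samples
#' class-conditional phantom parameters, renders the two-channel volumes
#' and truth masks, and builds the per-case clinical record: covariates
#' with class-conditional frequencies mirroring the target cohort table,
#' baseline/follow-up maximum dimensions consistent with the >2 mm
#' progression rule, resection extent consistent with the <10 % residual
#' rule, and censored time-to-event follow-up from the proportional-hazards
#' model (event times conditioned to precede follow-up for P/R cases).
#'
#' @param spec a [cohort_spec()].
#' @param keep_images if `FALSE`, skip volume rendering and return records
#'   only (fast path for outcome-level simulations).
#' @return list with `records` (one data.frame row per case) and, when
#'   `keep_images` is `TRUE`, `cases`: a list of
#'   `list(t1ce, t2, mask, record)` per case.
#' @export
generate_cohort <- function(spec, keep_images = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_cases
  n_pr <- round(n * spec$pr_prevalence)
  with_seed(spec$rng_seed, {
    pr <- rep(c(TRUE, FALSE), c(n_pr, n - n_pr))
    grid_shape <- spec$grid_shape
    sp <- spec$voxel_spacing_mm
    extent <- (grid_shape - 1) * sp
    zcap <- extent[3] / 2 - 2 * sp[3] - 1
    height_cap <- min(2 * (extent[1] / 2 - 2 * sp[1] - 1), 58)
    # truncated lognormal by rejection so the class medians stay at their
    # nominal values (the tails clipped by the grid are rare)
    rheight <- function(meanlog, sdlog) {
      for (try in 1:50) {
        h <- stats::rlnorm(1, meanlog, sdlog)
        if (h >= 11 && h <= height_cap) return(h)
      }
      min(max(h, 11), height_cap)
    }
    recs <- vector("list", n)
    cases <- if (keep_images) vector("list", n) else NULL
    for (i in seq_len(n)) {
      p <- spec$class_params[[if (pr[i]) "pr" else "nonpr"]]
      height <- rheight(p$height_meanlog, p$height_sdlog)
      rmax <- height / 2
      ry <- rmax * stats::runif(1, 0.55, 0.95)
      rz <- min(rmax * stats::runif(1, 0.55, 0.95), zcap)
      gran <- max(stats::rnorm(1, p$granularity_mean, p$granularity_sd), 0.4)
      ps <- phantom_spec(grid_shape = grid_shape, voxel_spacing_mm = sp,
                         tumor_radii_mm = c(rmax, ry, rz),
                         intensity_contrast = p$intensity_contrast,
                         texture_granularity_mm = gran,
                         heterogeneity_sd = p$heterogeneity_sd,
                         rng_seed = sample.int(.Machine$integer.max, 1))
      base_dims <- 2 * c(rmax, ry, rz)
      if (pr[i]) {
        # at least one axis grows by > 2 mm
        grow_axis <- sample.int(3, 1)
        delta <- stats::runif(3, -1, 1.8)
        delta[grow_axis] <- stats::runif(1, 3, 12)
        fu_dims <- base_dims + delta
      } else {
        fu_dims <- base_dims + stats::runif(3, -2, 1.8)
      }
      # resection extent: residual fraction < 10 % defines GTR
      gtr <- sample_cat(1, if (pr[i]) 3 / 28 else 6 / 22)
      resid_frac <- if (gtr) stats::runif(1, 0, 0.095)
                    else stats::runif(1, 0.105, 0.6)
      sv <- spec$survival
      fu <- min(max(stats::rlnorm(1, sv$followup_meanlog, sv$followup_sdlog),
                    sv$followup_range[1]), sv$followup_range[2])
      if (pr[i]) {
        rate <- sv$baseline_rate * exp(sv$coef)
        tt <- rexp_before(rate, fu)
      } else {
        tt <- fu
      }
      hypo <- sample(c("none", "single", "multiple"), 1,
                     prob = if (pr[i]) c(12, 8, 8) else c(17, 3, 2))
      recs[[i]] <- data.frame(
        case_id = sprintf("case%03d", i),
        pr = pr[i], event = pr[i], time_months = tt,
        base_d1 = base_dims[1], base_d2 = base_dims[2], base_d3 = base_dims[3],
        fu_d1 = fu_dims[1], fu_d2 = fu_dims[2], fu_d3 = fu_dims[3],
        sex_male = sample_cat(1, if (pr[i]) 19 / 28 else 10 / 22),
        age = round(min(max(stats::rnorm(1, if (pr[i]) 53.5 else 42,
                                         if (pr[i]) 13 else 18), 19), 80)),
        visual_disturbance = sample_cat(1, if (pr[i]) 26 / 28 else 13 / 22),
        headache = sample_cat(1, if (pr[i]) 8 / 28 else 11 / 22),
        sex_hormone_symptoms = sample_cat(1, if (pr[i]) 5 / 28 else 1 / 22),
        incidental = sample_cat(1, if (pr[i]) 2 / 28 else 4 / 22),
        hypopituitarism = hypo,
        hyperprolactinemia = sample_cat(1, if (pr[i]) 10 / 28 else 6 / 22),
        resection = if (gtr) "GTR" else "STR",
        residual_fraction = resid_frac,
        chiasm_decompressed = sample_cat(1, if (pr[i]) 9 / 28 else 17 / 22),
        knosp_high = sample_cat(1, if (pr[i]) 10 / 28 else 3 / 22),
        hardy_high = sample_cat(1, if (pr[i]) 11 / 28 else 3 / 22),
        chiasm_compression = sample_cat(1, if (pr[i]) 27 / 28 else 17 / 22),
        third_ventricle_compression =
          sample_cat(1, if (pr[i]) 21 / 28 else 9 / 22),
        hydrocephalus = sample_cat(1, if (pr[i]) 2 / 28 else 1 / 22),
        height_mm = height,
        giant = height > 40,
        volume_cm3 = 4 / 3 * pi * rmax * ry * rz / 1000,
        texture_granularity_mm = gran,
        stringsAsFactors = FALSE)
      if (keep_images) {
        ph <- generate_phantom(ps)
        cases[[i]] <- list(t1ce = ph$t1ce, t2 = ph$t2, mask = ph$mask,
                           record = recs[[i]])
      }
    }
    records <- do.call(rbind, recs)
    rownames(records) <- NULL
    out <- list(records = records)
    if (keep_images) out$cases <- cases
    out
  })
}

#' Write a cohort record table to CSV
#'
#' @param records the `records` data.frame from [generate_cohort()].
#' @param file output path.
#' @export
write_cohort_csv <- function(records, file) {
  utils::write.csv(records, file, row.names = FALSE)
  invisible(file)
}
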