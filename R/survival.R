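#' Kaplan-Meier curves and log-rank test by group
#'
#' Product-limit estimates of progression-free survival per group (with
#' censoring marks) and the two-sided log-rank test of group difference.
#'
#' @param records data.frame with `time_months` and `event` columns.
#' @param group_rule either a column name, or a function of `records`
#'   returning the grouping vector (e.g. a rule thresholding the SVM score
#'   at its optimal cutoff).
#' @return list with `fit` (a [survival::survfit] object), `chisq`
#'   (log-rank statistic), `p` and `groups`.
#' @export
km_logrank <- function(records, group_rule) {
  stop_if_not(all(c("time_months", "event") %in% names(records)),
              "records need time_months and event columns")
  stop_if_not(sum(records$event) >= 1, "need at least one event")
  grp <- if (is.function(group_rule)) group_rule(records)
         else records[[group_rule]]
  grp <- factor(grp)
  stop_if_not(all(table(grp) > 0) && nlevels(grp) >= 2,
              "every group must contain at least one case")
  df <- data.frame(time = records$time_months, event = records$event,
                   group = grp)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  p <- stats::pchisq(lr$chisq, df = nlevels(grp) - 1, lower.tail = FALSE)
  list(fit = fit, chisq = unname(lr$chisq), p = p, groups = levels(grp))
}

#' Univariate and multivariate Cox proportional-hazards analysis
#'
#' Univariate mode fits each covariate alone; multivariate mode first runs
#' the univariate screen and jointly fits exactly the covariates with
#' univariate p < `promote_p` (the conventional 0.05 promotion rule).
#' Ties are handled by the Efron approximation.  Non-convergence or
#' infinite coefficients are flagged per variable, not silently dropped.
#'
#' @param records data.frame with `time_months`, `event` and covariates.
#' @param covariates character vector of covariate columns.
#' @param mode `"univariate"` or `"multivariate"`.
#' @param promote_p promotion threshold for the multivariate screen.
#' @return a `cox_result` data.frame with columns variable, hr, ci_low,
#'   ci_high, p, flagged, and attributes `mode` and `variables_included`.
#' @export
cox_fit <- function(records, covariates, mode = c("univariate",
                                                  "multivariate"),
                    promote_p = 0.05) {
  mode <- match.arg(mode)
  stop_if_not(all(covariates %in% names(records)),
              "missing covariate columns: %s",
              paste(setdiff(covariates, names(records)), collapse = ", "))
  n_events <- sum(records$event)
  one_fit <- function(vars) {
    fml <- stats::as.formula(paste(
      "survival::Surv(time_months, event) ~",
      paste(sprintf("`%s`", vars), collapse = " + ")))
    flagged <- FALSE
    fit <- withCallingHandlers(
      survival::coxph(fml, data = records, ties = "efron"),
      warning = function(w) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      })
    s <- summary(fit)
    co <- s$coefficients
    ci <- s$conf.int
    data.frame(variable = rownames(co),
               hr = unname(ci[, "exp(coef)"]),
               ci_low = unname(ci[, 3]), ci_high = unname(ci[, 4]),
               p = unname(co[, "Pr(>|z|)"]),
               flagged = flagged | !is.finite(co[, "coef"]) |
                 abs(co[, "coef"]) > 15,
               row.names = NULL)
  }
  uni <- do.call(rbind, lapply(covariates, one_fit))
  if (mode == "univariate") {
    attr(uni, "mode") <- "univariate"
    attr(uni, "variables_included") <- covariates
    class(uni) <- c("cox_result", class(uni))
    return(uni)
  }
  promoted <- covariates[vapply(covariates, function(v) {
    any(uni$p[startsWith(uni$variable, v)] < promote_p)
  }, logical(1))]
  stop_if_not(length(promoted) >= 1,
              "no covariate reached univariate p < %.3g; nothing to promote",
              promote_p)
  if (n_events < length(promoted))
    warning(sprintf("only %d events for %d promoted covariates", n_events,
                    length(promoted)))
  multi <- one_fit(promoted)
  attr(multi, "mode") <- "multivariate"
  attr(multi, "variables_included") <- promoted
  attr(multi, "univariate") <- uni
  class(multi) <- c("cox_result", class(multi))
  multi
}
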