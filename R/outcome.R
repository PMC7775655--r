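#' Progression/recurrence labelling from lesion dimensions
#'
#' A lesion progresses when at least one dimension increases by strictly
#' more than 2.0 mm between the baseline (postoperative) and follow-up
#' measurement; an increase of exactly 2.0 mm does not qualify.
#'
#' @param baseline_dims_mm,followup_dims_mm positive numeric vectors of
#'   per-axis maximum diameters (mm), matching lengths.
#' @return logical.
#' @export
label_progression <- function(baseline_dims_mm, followup_dims_mm) {
  stop_if_not(length(baseline_dims_mm) == length(followup_dims_mm),
              "dimension vectors differ in length")
  stop_if_not(all(baseline_dims_mm > 0) && all(followup_dims_mm > 0),
              "lesion dimensions must be positive")
  any(followup_dims_mm - baseline_dims_mm > 2.0)
}

#' Classify the extent of resection
#'
#' Gross-total resection (GTR) means the residual tumor volume is less
#' than 10 % of the original volume; otherwise subtotal resection (STR).
#'
#' @param original_volume_cm3 original tumor volume (> 0).
#' @param residual_volume_cm3 residual volume (>= 0, <= original).
#' @return `"GTR"` or `"STR"`.
#' @export
classify_resection <- function(original_volume_cm3, residual_volume_cm3) {
  stop_if_not(original_volume_cm3 > 0, "original volume must be positive")
  stop_if_not(residual_volume_cm3 >= 0, "residual volume must be >= 0")
  stop_if_not(residual_volume_cm3 <= original_volume_cm3,
              "residual volume exceeds the original volume")
  if (residual_volume_cm3 / original_volume_cm3 < 0.10) "GTR" else "STR"
}

#' Compare a variable between outcome groups
#'
#' Categorical variables are compared by the chi-square test, switching to
#' Fisher's exact test when any expected cell count is below 5; continuous
#' variables by the two-sided Mann-Whitney U (Wilcoxon rank-sum) test.
#' Continuous variables are summarized as median (IQR) per group.
#'
#' @param records data.frame of case records (e.g. from
#'   [generate_cohort()]).
#' @param variable column name to compare.
#' @param group name of the logical grouping column (default `"pr"`).
#' @return list with `test` (name), `statistic`, `p`, and `summary` (a
#'   per-group description: counts for categorical, median (IQR) for
#'   continuous).
#' @export
compare_groups <- function(records, variable, group = "pr") {
  stop_if_not(variable %in% names(records), "no column '%s' in records",
              variable)
  stop_if_not(group %in% names(records), "no column '%s' in records", group)
  g <- factor(records[[group]])
  stop_if_not(nlevels(g) >= 2, "need at least two groups")
  v <- records[[variable]]
  stop_if_not(length(unique(v[!is.na(v)])) > 1,
              "variable '%s' is constant; nothing to compare", variable)
  categorical <- is.logical(v) || is.character(v) || is.factor(v)
  if (categorical) {
    tab <- table(factor(v), g)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      ft <- stats::fisher.test(tab)
      list(test = "fisher", statistic = NA_real_, p = ft$p.value,
           summary = tab)
    } else {
      ct <- stats::chisq.test(tab)
      list(test = "chi-square", statistic = unname(ct$statistic),
           p = ct$p.value, summary = tab)
    }
  } else {
    wt <- stats::wilcox.test(v ~ g, exact = FALSE)
    summ <- vapply(levels(g), function(l) {
      q <- stats::quantile(v[g == l], c(0.25, 0.5, 0.75), na.rm = TRUE)
      sprintf("%.1f (%.1f, %.1f)", q[2], q[1], q[3])
    }, character(1))
    list(test = "mann-whitney", statistic = unname(wt$statistic),
         p = wt$p.value, summary = summ)
  }
}
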