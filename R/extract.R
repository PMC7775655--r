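modality_prefix <- function(modality) c(T1CE = "T1", T2 = "T2")[[modality]]

## 107 features for one modality: 18 first-order + 14 shape + 24 GLCM +
## 16 GLRLM + 16 GLSZM + 5 NGTDM + 14 GLDM.  Intensities are ROI
## z-normalized before first-order statistics and discretization, so every
## feature is invariant under affine intensity rescaling of the input.
extract_modality <- function(vol, mask, n_bins = 32, shape = NULL) {
  voln <- normalize_roi(vol, mask)
  d <- discretize(voln, mask, n_bins)
  if (is.null(shape)) shape <- shape_features(mask)
  fam <- list(firstorder = first_order_features(voln, mask, n_bins),
              shape = shape,
              glcm = glcm_features(d),
              glrlm = glrlm_features(d),
              glszm = glszm_features(d),
              ngtdm = ngtdm_features(d),
              gldm = gldm_features(d))
  pre <- modality_prefix(vol$modality)
  out <- unlist(lapply(names(fam), function(f) {
    stats::setNames(fam[[f]], paste(pre, f, names(fam[[f]]), sep = "_"))
  }))
  out
}

#' Extract the full 214-feature vector for one case
#'
#' 107 features per modality (18 first-order, 14 shape, 24 GLCM, 16 GLRLM,
#' 16 GLSZM, 5 NGTDM, 14 GLDM) from the contrast-enhanced T1 and the T2
#' channel under a shared lesion mask.  The shape family depends only on
#' the mask and is computed once; its values are duplicated under both
#' modality namespaces so every case has a stable 214-name schema.
#'
#' @param t1ce,t2 [image_volume()]s on the same grid as `mask`.
#' @param mask a [lesion_mask()] (any ROI variant).
#' @param n_bins gray levels for discretization (default 32).
#' @return named numeric vector of 214 finite features, names
#'   `{T1|T2}_{family}_{feature}`.
#' @export
extract_all <- function(t1ce, t2, mask, n_bins = 32) {
  stopifnot(inherits(t1ce, "image_volume"), inherits(t2, "image_volume"))
  stop_if_not(t1ce$modality == "T1CE" && t2$modality == "T2",
              "extract_all expects a T1CE and a T2 volume (in that order)")
  stop_if_not(identical(dim(t1ce$data), dim(mask$data)) &&
                identical(dim(t2$data), dim(mask$data)),
              "both volumes must share the mask grid (run transfer_mask first)")
  shape <- shape_features(mask)
  out <- c(extract_modality(t1ce, mask, n_bins, shape = shape),
           extract_modality(t2, mask, n_bins, shape = shape))
  stop_if_not(length(out) == 214, "internal error: expected 214 features, got %d",
              length(out))
  bad <- names(out)[!is.finite(out)]
  stop_if_not(length(bad) == 0, "non-finite feature values: %s",
              paste(bad, collapse = ", "))
  out
}

#' Feature extraction over a cohort
#'
#' Runs [extract_all()] on every case of a [generate_cohort()] result (or
#' any list of `list(t1ce, t2, mask)` cases), optionally after eroding the
#' mask by a boundary shell.
#'
#' @param cases list of cases with `t1ce`, `t2`, `mask` elements.
#' @param erosion_cm shell depth passed to [erode_shell()] (0 = original
#'   mask).  Cases whose mask is emptied by the erosion are dropped with a
#'   warning.
#' @param n_bins gray levels for discretization.
#' @return data.frame: one row per case, `case_id` plus 214 feature columns.
#' @export
extract_cohort_features <- function(cases, erosion_cm = 0, n_bins = 32) {
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    mk <- cs$mask
    if (erosion_cm > 0) {
      mk <- tryCatch(erode_shell(mk, erosion_cm), error = function(e) NULL)
      if (is.null(mk)) {
        warning(sprintf("case %d: erosion emptied the mask; case dropped", i))
        return(NULL)
      }
    }
    fv <- extract_all(cs$t1ce, cs$t2, mk, n_bins = n_bins)
    cbind(data.frame(case_id = cs$record$case_id %||% sprintf("case%03d", i),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)))
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
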