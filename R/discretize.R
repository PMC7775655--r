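#' Discretize ROI intensities into equal-width gray levels
#'
#' Equal-width binning of the in-mask intensities into `n_bins` levels:
#' the minimum maps to level 1 and the maximum to level `n_bins`.  All
#' texture families (GLCM, GLRLM, GLSZM, NGTDM, GLDM) operate on the
#' resulting integer gray-level grid.
#'
#' @param vol an [image_volume()].
#' @param mask a [lesion_mask()] on the same grid.
#' @param n_bins number of gray levels (>= 2).
#' @return a `discretized_roi`: integer `levels` array (NA outside the
#'   mask), `n_levels`, `bin_edges`, the logical `mask` array, `spacing`
#'   and originating `modality`/`variant` tags.
#' @export
discretize <- function(vol, mask, n_bins = 32) {
  stopifnot(inherits(vol, "image_volume"), inherits(mask, "lesion_mask"))
  stop_if_not(identical(dim(vol$data), dim(mask$data)),
              "volume and mask grids differ")
  stop_if_not(n_bins >= 2, "n_bins must be >= 2")
  m <- mask$data
  stop_if_not(sum(m) > 0, "mask is empty")
  v <- vol$data[m]
  lev <- array(NA_integer_, dim = dim(m))
  rng <- range(v)
  if (rng[1] == rng[2]) {
    warning("constant ROI: all voxels assigned gray level 1")
    lev[m] <- 1L
    edges <- c(rng[1], rng[1])
  } else {
    w <- (rng[2] - rng[1]) / n_bins
    lev[m] <- pmin(floor((v - rng[1]) / w) + 1L, n_bins)
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  }
  structure(list(levels = lev, n_levels = as.integer(n_bins),
                 bin_edges = edges, mask = m, spacing = mask$spacing,
                 modality = vol$modality, variant = mask$variant),
            class = "discretized_roi")
}
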