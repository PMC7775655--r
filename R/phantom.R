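#' Specify a single phantom tumor volume
#'
#' A phantom emulates one case of the study population: an enhancing,
#' texture-bearing ellipsoidal tumor embedded in a noisy background, imaged
#' in two co-registered channels (contrast-enhanced T1-weighted and
#' T2-weighted).  Texture coarseness is controlled by a single spatial
#' correlation length so that downstream NGTDM coarseness responds
#' monotonically to it.
#'
#' @param grid_shape integer length-3, grid size in voxels.
#' @param voxel_spacing_mm positive length-3 numeric (anisotropic allowed).
#' @param tumor_center center in mm (world coordinates); defaults to the
#'   grid center.
#' @param tumor_radii_mm positive length-3 ellipsoid semi-axes in mm.
#' @param intensity_contrast separation of tumor and background means in
#'   units of `noise_sd`.
#' @param texture_granularity_mm spatial correlation length (Gaussian
#'   smoothing sigma, mm) of the within-tumor texture field.
#' @param heterogeneity_sd standard deviation of the within-tumor texture
#'   field, in intensity units.
#' @param noise_sd standard deviation of the i.i.d. background noise.
#' @param rng_seed integer seed; identical seeds give bit-identical phantoms.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 32L),
                         voxel_spacing_mm = c(1, 1, 1.5),
                         tumor_center = NULL,
                         tumor_radii_mm = c(15, 12, 12),
                         intensity_contrast = 3,
                         texture_granularity_mm = 2,
                         heterogeneity_sd = 0.5,
                         noise_sd = 1,
                         rng_seed = 1L) {
  stop_if_not(length(grid_shape) == 3 && all(grid_shape >= 8),
              "grid_shape must be 3 values >= 8")
  stop_if_not(all(voxel_spacing_mm > 0), "voxel spacing must be positive")
  stop_if_not(all(tumor_radii_mm > 0), "tumor radii must be positive")
  stop_if_not(texture_granularity_mm > 0 && heterogeneity_sd >= 0 &&
                noise_sd > 0, "texture/noise parameters must be positive")
  extent <- (grid_shape - 1) * voxel_spacing_mm
  if (is.null(tumor_center)) tumor_center <- extent / 2
  margin <- 2 * voxel_spacing_mm  # >= 2 voxels clearance on every side
  fits <- all(tumor_center - tumor_radii_mm >= margin) &&
    all(tumor_center + tumor_radii_mm <= extent - margin)
  stop_if_not(fits,
              paste("tumor (center %s mm, radii %s mm) does not fit inside",
                    "the %s mm grid with a 2-voxel margin"),
              paste(signif(tumor_center, 3), collapse = ","),
              paste(signif(tumor_radii_mm, 3), collapse = ","),
              paste(signif(extent, 3), collapse = ","))
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 tumor_center = as.numeric(tumor_center),
                 tumor_radii_mm = as.numeric(tumor_radii_mm),
                 intensity_contrast = intensity_contrast,
                 texture_granularity_mm = texture_granularity_mm,
                 heterogeneity_sd = heterogeneity_sd,
                 noise_sd = noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

## Smoothed Gaussian random field with per-axis smoothing sigma in voxels,
## rescaled to zero mean / unit SD.  Separable truncated-Gaussian filtering;
## edge effects are normalized away by filtering a field of ones.
gaussian_field <- function(dim3, sigma_vox) {
  x <- array(stats::rnorm(prod(dim3)), dim = dim3)
  w <- array(1, dim = dim3)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s < 0.05) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    x <- filter_axis(x, k, ax)
    w <- filter_axis(w, k, ax)
  }
  x <- x / w
  (x - mean(x)) / stats::sd(x)
}

## 1D convolution of a 3D array along one axis (zero padding).
filter_axis <- function(a, k, axis) {
  d <- dim(a)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, nrow = dp[1])
  n <- dp[1]; r <- (length(k) - 1L) / 2L
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (t in seq_along(k)) {
    off <- t - r - 1L
    src <- seq_len(n) + off
    ok <- src >= 1 & src <= n
    out[ok, ] <- out[ok, ] + k[t] * m[src[ok], ]
  }
  ap <- array(out, dim = dp)
  aperm(ap, order(perm))
}

#' Generate one two-channel phantom and its ground-truth mask
#'
#' Both channels share the grid and the exact ellipsoid digitization as
#' truth mask.  The tumor is brighter than background on T1CE (contrast
#' enhancement) and mildly hyperintense on T2; each channel carries its own
#' noise realization and its own texture field at the specified granularity.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `t1ce`, `t2` ([image_volume()]) and
#'   `mask` ([lesion_mask()], the exact ellipsoid digitization).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$rng_seed, {
    d <- spec$grid_shape
    sp <- spec$voxel_spacing_mm
    cx <- spec$tumor_center
    co <- list((seq_len(d[1]) - 1) * sp[1],
               (seq_len(d[2]) - 1) * sp[2],
               (seq_len(d[3]) - 1) * sp[3])
    u1 <- (co[[1]] - cx[1]) / spec$tumor_radii_mm[1]
    u2 <- (co[[2]] - cx[2]) / spec$tumor_radii_mm[2]
    u3 <- (co[[3]] - cx[3]) / spec$tumor_radii_mm[3]
    rsq <- outer(outer(u1^2, u2^2, `+`), u3^2, `+`)
    mask <- rsq <= 1
    sigma_vox <- spec$texture_granularity_mm / sp
    # background carries i.i.d. noise; tumor voxels carry the correlated
    # texture field (the enhancement pattern) on top of the class contrast
    chan <- function(contrast_mult) {
      base <- array(stats::rnorm(prod(d), sd = spec$noise_sd), dim = d)
      tex <- gaussian_field(d, sigma_vox) * spec$heterogeneity_sd
      base[mask] <- contrast_mult * spec$intensity_contrast * spec$noise_sd +
        tex[mask]
      base
    }
    t1 <- chan(1)    # enhancing tumor
    t2 <- chan(0.8)  # mildly hyperintense
    list(t1ce = image_volume(t1, sp, "T1CE"),
         t2 = image_volume(t2, sp, "T2"),
         mask = lesion_mask(mask, sp))
  })
}
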