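## Trilinear sampling of a 3D array at fractional 0-based voxel coordinates.
## Points outside the grid return `outside`; points on the boundary are
## handled exactly (interpolation weights collapse to the edge sample).
sample_trilinear <- function(a, pts, outside = 0) {
  d <- dim(a)
  n <- nrow(pts)
  out <- rep(outside, n)
  eps <- 1e-9
  inside <- pts[, 1] >= -eps & pts[, 1] <= d[1] - 1 + eps &
    pts[, 2] >= -eps & pts[, 2] <= d[2] - 1 + eps &
    pts[, 3] >= -eps & pts[, 3] <= d[3] - 1 + eps
  if (!any(inside)) return(out)
  p <- pts[inside, , drop = FALSE]
  p[, 1] <- pmin(pmax(p[, 1], 0), d[1] - 1)
  p[, 2] <- pmin(pmax(p[, 2], 0), d[2] - 1)
  p[, 3] <- pmin(pmax(p[, 3], 0), d[3] - 1)
  i0 <- pmin(floor(p), rep(pmax(d - 2, 0), each = nrow(p)))
  f <- p - i0
  acc <- numeric(nrow(p))
  for (ci in 0:1) for (cj in 0:1) for (ck in 0:1) {
    w <- (if (ci) f[, 1] else 1 - f[, 1]) *
      (if (cj) f[, 2] else 1 - f[, 2]) *
      (if (ck) f[, 3] else 1 - f[, 3])
    nz <- w > 0
    if (!any(nz)) next
    lin <- (pmin(i0[nz, 1] + ci, d[1] - 1) + 1) +
      pmin(i0[nz, 2] + cj, d[2] - 1) * d[1] +
      pmin(i0[nz, 3] + ck, d[3] - 1) * d[1] * d[2]
    acc[nz] <- acc[nz] + w[nz] * a[lin]
  }
  out[inside] <- acc
  out
}

#' Resample a volume to isotropic voxel spacing
#'
#' Intensities are linearly interpolated onto a grid of spacing
#' `(target_mm, target_mm, target_mm)` covering the same world extent
#' (within one voxel).
#'
#' @param vol an [image_volume()].
#' @param target_mm target isotropic spacing (> 0, mm); default is the
#'   minimum input spacing, so no axis is downsampled.
#' @return an [image_volume()] with isotropic spacing.
#' @export
resample_isotropic <- function(vol, target_mm = min(vol$spacing)) {
  stopifnot(inherits(vol, "image_volume"))
  stop_if_not(target_mm > 0, "target_mm must be positive")
  d <- dim(vol$data)
  stop_if_not(all(d > 0) && length(vol$data) > 0, "cannot resample an empty volume")
  if (all(abs(vol$spacing - target_mm) < 1e-12)) return(vol)
  extent <- (d - 1) * vol$spacing
  nd <- pmax(floor(extent / target_mm + 1e-9), 1) + 1
  co <- lapply(1:3, function(ax) (seq_len(nd[ax]) - 1) * target_mm /
                 vol$spacing[ax])
  pts <- cbind(rep(co[[1]], times = nd[2] * nd[3]),
               rep(rep(co[[2]], each = nd[1]), times = nd[3]),
               rep(co[[3]], each = nd[1] * nd[2]))
  vals <- sample_trilinear(vol$data, pts)
  image_volume(array(vals, dim = nd), rep(target_mm, 3), vol$modality)
}

#' Transfer a mask onto another grid by affine transformation
#'
#' The mask is resampled as a continuous 0/1 field with linear
#' interpolation and binarized at `threshold` (predicted in-mask when the
#' interpolated value is >= threshold).  `affine` maps source world
#' coordinates to target world coordinates; the identity transform on the
#' same grid returns the input mask exactly.
#'
#' @param mask a [lesion_mask()].
#' @param affine invertible 4x4 world-to-world transform (source -> target).
#' @param target an [image_volume()] providing the destination grid.
#' @param threshold binarization threshold in (0, 1); default 0.5.
#' @return a [lesion_mask()] on the target grid.
#' @export
transfer_mask <- function(mask, affine, target, threshold = 0.5) {
  stopifnot(inherits(mask, "lesion_mask"), inherits(target, "image_volume"))
  stop_if_not(is.matrix(affine) && all(dim(affine) == c(4, 4)),
              "affine must be a 4x4 matrix")
  det_a <- det(affine)
  stop_if_not(is.finite(det_a) && abs(det_a) > 1e-12,
              "affine transform is singular and cannot be inverted")
  nd <- dim(target$data)
  idx <- cbind(rep(seq_len(nd[1]) - 1, times = nd[2] * nd[3]),
               rep(rep(seq_len(nd[2]) - 1, each = nd[1]), times = nd[3]),
               rep(seq_len(nd[3]) - 1, each = nd[1] * nd[2]))
  tgt_world <- cbind(idx, 1) %*% t(target$affine)
  src_world <- tgt_world %*% t(solve(affine))
  src_affine <- affine_from_spacing(mask$spacing)
  src_vox <- src_world %*% t(solve(src_affine))
  vals <- sample_trilinear(mask$data + 0, src_vox[, 1:3, drop = FALSE])
  lesion_mask(array(vals >= threshold, dim = nd), target$spacing,
              variant = mask$variant)
}
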