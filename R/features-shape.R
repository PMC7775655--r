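## --- Shape features ------------------------------------------------------
## Surface area and mesh volume come from a marching-tetrahedra isosurface
## of the binary mask at iso-level 0.5: each grid cell between 8 voxel
## centers is split into 6 tetrahedra around the main diagonal; within a
## tetrahedron the linear interpolant crosses 0.5 at edge midpoints, so the
## per-case triangle geometry is constant per (tetrahedron, sign case) and
## the inside-volume fraction is exactly 0, 1/8, 1/2, 7/8 or 1.

## Cube vertex c (0..7) has offset (c & 1, c>>1 & 1, c>>2 & 1).
.tet_vertices <- local({
  # six tetrahedra (0, e_a, e_a+e_b, 7) over axis orderings
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  bit <- c(1L, 2L, 4L)
  t(apply(perms, 1, function(p) {
    c(0L, bit[p[1]], bit[p[1]] + bit[p[2]], 7L)
  }))
})

.vertex_offset <- function(c) c(bitwAnd(c, 1L), bitwAnd(bitwShiftR(c, 1L), 1L),
                                bitwAnd(bitwShiftR(c, 2L), 1L))

## Triangles (as pairs of local tet-vertex indices whose edge midpoints are
## the triangle corners) and inside-volume fraction per sign case 0..15.
.tet_cases <- local({
  cases <- vector("list", 16)
  for (cs in 0:15) {
    ins <- which(bitwAnd(cs, c(1L, 2L, 4L, 8L)) > 0)
    outs <- setdiff(1:4, ins)
    tris <- list()
    if (length(ins) == 1) {
      p <- ins
      tris <- list(rbind(c(p, outs[1]), c(p, outs[2]), c(p, outs[3])))
    } else if (length(ins) == 3) {
      p <- outs
      tris <- list(rbind(c(p, ins[1]), c(p, ins[2]), c(p, ins[3])))
    } else if (length(ins) == 2) {
      p <- ins[1]; q <- ins[2]; r <- outs[1]; s <- outs[2]
      # quad m_pr, m_ps, m_qs, m_qr split into two triangles
      tris <- list(rbind(c(p, r), c(p, s), c(q, s)),
                   rbind(c(p, r), c(q, s), c(q, r)))
    }
    frac <- c(`0` = 0, `1` = 1 / 8, `2` = 1 / 2, `3` = 7 / 8,
              `4` = 1)[[as.character(length(ins))]]
    cases[[cs + 1]] <- list(tris = tris, frac = frac)
  }
  cases
})

## Signed implicit field for the mask surface: Gaussian-smoothed binary
## minus 1/2 (positive inside).  Smoothing recovers sub-voxel surface
## placement on curved boundaries while leaving flat faces at the
## half-voxel midplane.
## sigma 0.7 voxels balances sub-voxel placement on curved boundaries
## against corner rounding on flat-faced lesions (both sphere and cube
## reproduce their analytic A/V within 5 %).
mask_field <- function(m, sigma_vox = 0.7) {
  x <- array(as.numeric(m), dim = dim(m))
  for (ax in 1:3) {
    r <- max(1L, ceiling(3 * sigma_vox))
    k <- stats::dnorm(seq(-r, r), sd = sigma_vox)
    k <- k / sum(k)
    x <- filter_axis(x, k, ax)
  }
  x - 0.5
}

## Surface area and enclosed volume of the zero-isosurface of field `phi`
## (positive inside, assumed negative on the array border), by marching
## tetrahedra with linear edge interpolation.  Volume comes from the
## divergence theorem over the outward-oriented triangles.
mesh_surface_volume <- function(phi, sp) {
  d <- dim(phi)
  nc <- d - 1L
  corner_idx <- function(off) {
    ii <- seq_len(nc[1]) + off[1]; jj <- seq_len(nc[2]) + off[2]
    kk <- seq_len(nc[3]) + off[3]
    as.numeric(phi[ii, jj, kk])
  }
  vals <- lapply(0:7, function(c) corner_idx(.vertex_offset(c)))
  # cell-origin physical coordinates, aligned with the flattened cell order
  oi <- (seq_len(nc[1]) - 1) * sp[1]
  oj <- (seq_len(nc[2]) - 1) * sp[2]
  ok <- (seq_len(nc[3]) - 1) * sp[3]
  org <- cbind(rep(oi, times = nc[2] * nc[3]),
               rep(rep(oj, each = nc[1]), times = nc[3]),
               rep(ok, each = nc[1] * nc[2]))
  area <- 0; volume <- 0
  cross3 <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
  for (t in seq_len(nrow(.tet_vertices))) {
    tv <- .tet_vertices[t, ]
    f <- lapply(1:4, function(v) vals[[tv[v] + 1]])
    pos <- lapply(1:4, function(v) (f[[v]] > 0) + 0L)
    b <- pos[[1]] + 2L * pos[[2]] + 4L * pos[[3]] + 8L * pos[[4]]
    vcoord <- t(vapply(tv, function(c) .vertex_offset(c) * sp, numeric(3)))
    for (cs in 1:14) {  # mixed sign cases only (0 and 15 give no surface)
      sel <- which(b == cs)
      if (length(sel) == 0) next
      cc <- .tet_cases[[cs + 1]]
      ins <- which(bitwAnd(cs, c(1L, 2L, 4L, 8L)) > 0)
      # reference point on the inside, for outward orientation
      ref <- org[sel, , drop = FALSE] +
        matrix(colMeans(vcoord[ins, , drop = FALSE]),
               length(sel), 3, byrow = TRUE)
      for (tri in cc$tris) {
        pt <- vector("list", 3)
        for (v in 1:3) {
          a <- tri[v, 1]; bb <- tri[v, 2]
          fa <- f[[a]][sel]; fb <- f[[bb]][sel]
          tt <- fa / (fa - fb)
          pt[[v]] <- org[sel, , drop = FALSE] +
            matrix(vcoord[a, ], length(sel), 3, byrow = TRUE) +
            tt * matrix(vcoord[bb, ] - vcoord[a, ], length(sel), 3,
                        byrow = TRUE)
        }
        cr <- cross3(pt[[2]] - pt[[1]], pt[[3]] - pt[[1]])
        centroid <- (pt[[1]] + pt[[2]] + pt[[3]]) / 3
        flip <- rowSums(cr * (centroid - ref)) < 0
        cr[flip, ] <- -cr[flip, ]
        area <- area + sum(sqrt(rowSums(cr^2))) / 2
        # divergence theorem: V = sum a . (b x c) / 6, outward orientation
        bxc <- cross3(pt[[2]][, , drop = FALSE], pt[[3]][, , drop = FALSE])
        svol <- rowSums(pt[[1]] * bxc) / 6
        svol[flip] <- -svol[flip]
        volume <- volume + sum(svol)
      }
    }
  }
  list(area = area, volume = volume)
}

## Largest pairwise distance between rows of pts (n x d), chunked.
max_pairwise_dist <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(0)
  best <- 0
  chunk <- 512L
  sq <- rowSums(pts^2)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    g <- pts %*% t(pts[s:e, , drop = FALSE])
    d2 <- outer(sq, rep(1, e - s + 1)) + outer(rep(1, n), sq[s:e]) - 2 * g
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

#' Shape features of a lesion mask
#'
#' The 14 standard 3D shape descriptors.  Surface area and mesh volume come
#' from a marching-tetrahedra triangulated isosurface of the (zero-padded)
#' mask; `SurfaceVolumeRatio = A / V`; sphericity is
#' `(36 pi V^2)^(1/3) / A`; axis lengths are `4 * sqrt(lambda)` from the
#' principal components of the physical voxel coordinates; maximum 2D/3D
#' diameters are largest pairwise distances between boundary voxel centers
#' (per plane orientation for the 2D variants).
#'
#' @param mask a nonempty, single-component [lesion_mask()].
#' @param spacing voxel spacing override (mm); defaults to the mask's.
#' @return named numeric vector of 14 features.
#' @export
shape_features <- function(mask, spacing = mask$spacing) {
  stopifnot(inherits(mask, "lesion_mask"))
  m0 <- mask$data
  stop_if_not(sum(m0) > 0, "mask is empty")
  d0 <- dim(m0)
  # pad so the isosurface closes even when the mask touches the grid edge
  # (padding covers the smoothing radius of the implicit field)
  pad <- 4L
  m <- array(FALSE, dim = d0 + 2L * pad)
  m[pad + seq_len(d0[1]), pad + seq_len(d0[2]), pad + seq_len(d0[3])] <- m0
  sp <- as.numeric(spacing)
  ms <- mesh_surface_volume(mask_field(m), sp)
  nvox <- sum(m0)
  voxel_volume <- nvox * prod(sp)
  # physical coordinates of in-mask voxel centers (original grid)
  idx <- which(m0, arr.ind = TRUE)
  pts <- sweep(idx - 1, 2, sp, `*`)
  # principal axes
  if (nvox >= 2) {
    ev <- sort(eigen(stats::cov(pts), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else ev <- c(0, 0, 0)
  # boundary voxels: any of the 6 face neighbors outside the mask
  inb <- array(TRUE, dim = d0)
  for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
    shifted <- array(FALSE, dim = d0)
    spair <- shift_pairs(d0, off)
    shifted[spair[, 1]] <- m0[spair[, 2]]
    inb <- inb & shifted
  }
  boundary <- m0 & !inb
  bidx <- which(boundary, arr.ind = TRUE)
  bpts <- sweep(bidx - 1, 2, sp, `*`)
  max3d <- max_pairwise_dist(bpts)
  plane_max <- function(axis) {
    keep <- setdiff(1:3, axis)
    mx <- 0
    for (u in unique(bidx[, axis])) {
      sel <- bidx[, axis] == u
      mx <- max(mx, max_pairwise_dist(bpts[sel, keep, drop = FALSE]))
    }
    mx
  }
  area <- ms$area; vol <- ms$volume
  c(MeshVolume = vol,
    VoxelVolume = voxel_volume,
    SurfaceArea = area,
    SurfaceVolumeRatio = area / vol,
    Sphericity = (36 * pi * vol^2)^(1 / 3) / area,
    Maximum3DDiameter = max3d,
    Maximum2DDiameterSlice = plane_max(3),
    Maximum2DDiameterColumn = plane_max(1),
    Maximum2DDiameterRow = plane_max(2),
    MajorAxisLength = 4 * sqrt(ev[1]),
    MinorAxisLength = 4 * sqrt(ev[2]),
    LeastAxisLength = 4 * sqrt(ev[3]),
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0)
}
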