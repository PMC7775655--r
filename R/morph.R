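## Connected-component labelling of a logical 3D array via the adjacency
## graph of in-mask voxels (igraph does the union-find).  connectivity 26
## (vertex-adjacent, used for lesions and texture zones) or 6
## (face-adjacent, used for background flood fill).
label_components <- function(m, connectivity = 26) {
  stop_if_not(connectivity %in% c(6, 26), "connectivity must be 6 or 26")
  idx <- which(m)
  labels <- array(0L, dim = dim(m))
  if (length(idx) == 0) return(labels)
  node <- array(0L, dim = dim(m))
  node[idx] <- seq_along(idx)
  offs <- neighbor_offsets(half = TRUE)
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  edges <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    sp <- shift_pairs(dim(m), offs[r, ])
    keep <- m[sp[, 1]] & m[sp[, 2]]
    edges[[r]] <- cbind(node[sp[keep, 1]], node[sp[keep, 2]])
  }
  e <- do.call(rbind, edges)
  g <- igraph::make_graph(t(e), n = length(idx), directed = FALSE)
  labels[idx] <- igraph::components(g)$membership
  labels
}

## Fill cavities: any background component (by `connectivity`) that does
## not touch the border of the grid/slice is converted to foreground.
fill_background_holes <- function(m, connectivity) {
  bg <- !m
  lab <- label_components(bg, connectivity)
  d <- dim(m)
  border <- array(FALSE, dim = d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  if (d[3] > 1 || connectivity == 6) border[, , c(1, d[3])] <- TRUE
  outside <- unique(lab[border & bg])
  holes <- bg & !(lab %in% outside)
  m | holes
}

#' Clean a raw segmentation mask
#'
#' Keeps only the largest 3D-connected component (face/6-connectivity,
#' removing scattered voxels: diagonal-only contacts do not count, so salt
#' noise cannot chain itself onto the lesion), then fills internal holes:
#' per-slice 2D filling (4-connectivity within each slice) followed by a
#' 3D fill (6-connectivity), so both in-plane and fully enclosed 3D
#' cavities end up inside the mask.  Idempotent on already-clean masks.
#'
#' @param raw a nonempty raw [lesion_mask()] (e.g. from [fcm_segment()]).
#' @param connectivity neighbourhood for the component step (6 or 26).
#' @return a cleaned [lesion_mask()]: one connected component, no holes.
#' @export
postprocess_mask <- function(raw, connectivity = 6) {
  stopifnot(inherits(raw, "lesion_mask"))
  stop_if_not(sum(raw$data) > 0, "raw mask is empty; nothing to post-process")
  lab <- label_components(raw$data, connectivity)
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  m <- lab == keep
  for (s in seq_len(dim(m)[3])) {
    sl <- m[, , s, drop = FALSE]
    m[, , s] <- fill_background_holes(sl, connectivity = 6)[, , 1]
  }
  m <- fill_background_holes(m, connectivity = 6)
  lesion_mask(m, raw$spacing, raw$variant)
}

## Exact 1D squared distance transform (lower envelope of parabolas),
## sample spacing `step`.  f is the squared distance so far (Inf allowed).
dt1d <- function(f, step) {
  n <- length(f)
  if (n == 1) return(f)
  x <- (seq_len(n) - 1) * step
  v <- integer(n); z <- numeric(n + 1)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in 2:n) {
    if (!is.finite(f[q])) next
    repeat {
      p <- v[k]
      if (!is.finite(f[p])) { k <- k - 1L; if (k == 0L) break; next }
      s <- ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * x[q] - 2 * x[p])
      if (s <= z[k]) { k <- k - 1L; if (k == 0L) break } else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- if (k == 1L) -Inf else s
    z[k + 1] <- Inf
  }
  if (all(!is.finite(f))) return(f)
  d <- numeric(n); k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1] < x[q]) k <- k + 1L
    d[q] <- (x[q] - x[v[k]])^2 + f[v[k]]
  }
  d
}

## Exact 2D squared Euclidean distance transform to the TRUE pixels of
## `seed`, with anisotropic pixel spacing sp = c(s_row, s_col).
sq_edt_2d <- function(seed, sp) {
  d0 <- ifelse(seed, 0, Inf)
  d1 <- apply(d0, 2, dt1d, step = sp[1])
  if (is.null(dim(d1))) d1 <- matrix(d1, nrow = nrow(d0))
  d2 <- t(apply(d1, 1, dt1d, step = sp[2]))
  if (is.null(dim(d2))) d2 <- matrix(d2, ncol = ncol(d0))
  d2
}

#' Remove a boundary shell from a mask by slice-wise binary erosion
#'
#' On each slice, the exact Euclidean distance (in mm, spacing-aware) from
#' every in-mask pixel to the nearest background pixel is computed; pixels
#' closer than the shell depth to the boundary are removed, so every
#' retained pixel lies at least `depth_cm` inside the original in-plane
#' boundary.  Depth 0 is the identity.
#'
#' @param mask a nonempty [lesion_mask()].
#' @param depth_cm shell depth in cm: 0, 0.25 or 0.5.
#' @param spacing voxel spacing override (mm); defaults to the mask's.
#' @return the eroded [lesion_mask()] with its variant tag updated.
#' @export
erode_shell <- function(mask, depth_cm, spacing = mask$spacing) {
  stopifnot(inherits(mask, "lesion_mask"))
  stop_if_not(sum(mask$data) > 0, "mask is empty")
  stop_if_not(depth_cm %in% c(0, 0.25, 0.5),
              "depth_cm must be one of 0, 0.25, 0.5")
  if (depth_cm == 0) return(mask)
  depth_mm <- depth_cm * 10
  m <- mask$data
  out <- array(FALSE, dim = dim(m))
  for (s in seq_len(dim(m)[3])) {
    sl <- m[, , s]
    if (!any(sl)) next
    d2 <- sq_edt_2d(!sl, spacing[1:2])
    out[, , s] <- sl & sqrt(d2) > depth_mm
  }
  stop_if_not(sum(out) > 0,
              "erosion by %.2f cm empties the mask; use the original variant for this lesion",
              depth_cm)
  lesion_mask(out, mask$spacing,
              variant = if (depth_cm == 0.25) "eroded_025" else "eroded_05")
}
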