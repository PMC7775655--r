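#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

#' The 26-neighbourhood offsets of a voxel
#'
#' @param half if `TRUE`, return only the 13 unique direction vectors
#'   (one of each antipodal pair), the set used for direction-aggregated
#'   texture matrices.
#' @return integer matrix with one offset per row and columns (di, dj, dk).
#' @keywords internal
neighbor_offsets <- function(half = FALSE) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (half) {
    # keep the lexicographically positive member of each antipodal pair
    keep <- (g[, 3] > 0) |
      (g[, 3] == 0 & g[, 2] > 0) |
      (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
    g <- g[keep, , drop = FALSE]
  }
  storage.mode(g) <- "integer"
  g
}

## Linear indices of voxels shifted by an offset, staying inside the grid.
## Returns a two-column matrix of (from, to) linear indices.
shift_pairs <- function(dim3, off) {
  ni <- dim3[1]; nj <- dim3[2]; nk <- dim3[3]
  ri <- seq_len(ni); rj <- seq_len(nj); rk <- seq_len(nk)
  si <- ri + off[1]; sj <- rj + off[2]; sk <- rk + off[3]
  oki <- si >= 1 & si <= ni; okj <- sj >= 1 & sj <= nj; okk <- sk >= 1 & sk <= nk
  ii <- ri[oki]; jj <- rj[okj]; kk <- rk[okk]
  from <- outer(outer(ii, (jj - 1L) * ni, `+`), (kk - 1L) * ni * nj, `+`)
  ii2 <- si[oki]; jj2 <- sj[okj]; kk2 <- sk[okk]
  to <- outer(outer(ii2, (jj2 - 1L) * ni, `+`), (kk2 - 1L) * ni * nj, `+`)
  cbind(from = as.integer(from), to = as.integer(to))
}

## Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's
## RNG state afterwards so generators do not perturb outer simulations.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Bounding box (index ranges) of TRUE voxels, optionally padded.
mask_bbox <- function(m, pad = 0L) {
  idx <- which(m, arr.ind = TRUE)
  stop_if_not(nrow(idx) > 0, "mask is empty")
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, dim(m))
  list(lo = lo, hi = hi)
}
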