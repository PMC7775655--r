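#' Rectangular bounding ROI for segmentation
#'
#' Mimics the operator's initialization: an in-plane rectangle locating the
#' tumor plus the range of slices containing the lesion.
#'
#' @param rect integer c(i_min, i_max, j_min, j_max), in-plane voxel indices.
#' @param slices integer c(first, last) slice indices (third array axis).
#' @return a `bounding_roi` list.
#' @export
bounding_roi <- function(rect, slices) {
  stop_if_not(length(rect) == 4 && rect[1] <= rect[2] && rect[3] <= rect[4],
              "rect must be c(i_min, i_max, j_min, j_max) with min <= max")
  stop_if_not(length(slices) == 2 && slices[1] <= slices[2],
              "slices must be c(first, last) with first <= last")
  structure(list(rect = as.integer(rect), slices = as.integer(slices)),
            class = "bounding_roi")
}

#' Normalize intensities to zero mean / unit SD within an ROI
#'
#' The affine intensity transform (x - mean) / sd, with mean and population
#' SD computed over the in-mask voxels, is applied to the whole volume, so
#' the in-mask intensities have mean 0 and SD 1 afterwards.
#'
#' @param vol an [image_volume()].
#' @param mask a [lesion_mask()] (or logical array) with >= 2 voxels and
#'   nonzero intensity variance inside.
#' @return the normalized [image_volume()].
#' @export
normalize_roi <- function(vol, mask) {
  stopifnot(inherits(vol, "image_volume"))
  m <- if (inherits(mask, "lesion_mask")) mask$data else mask
  stop_if_not(identical(dim(m), dim(vol$data)),
              "mask grid does not match the volume grid")
  v <- vol$data[m]
  stop_if_not(length(v) >= 2, "ROI must contain at least 2 voxels")
  mu <- mean(v)
  sd_pop <- sqrt(mean((v - mu)^2))  # population SD (n denominator)
  stop_if_not(sd_pop > 0,
              "ROI intensities of the %s volume have zero variance; cannot normalize",
              vol$modality)
  image_volume((vol$data - mu) / sd_pop, vol$spacing, vol$modality,
               vol$affine)
}

## Fuzzy c-means on a numeric vector (1D intensity clustering).
## Alternating minimization of J = sum_i sum_k u_ik^m (x_i - v_k)^2 with
## k-means++-style center initialization.  The objective trace is returned
## so tests can assert monotone non-increase.
fcm_cluster <- function(x, k = 2, m = 2, tol = 1e-5, max_iter = 300) {
  stop_if_not(length(unique(x)) >= k,
              "FCM needs at least %d distinct intensities (got %d)",
              k, length(unique(x)))
  centers <- numeric(k)
  centers[1] <- x[sample.int(length(x), 1)]
  for (j in 2:k) {
    d2 <- apply(outer(x, centers[1:(j - 1)], `-`)^2, 1, min)
    if (all(d2 == 0)) centers[j] <- x[sample.int(length(x), 1)]
    else centers[j] <- x[sample.int(length(x), 1, prob = d2)]
  }
  memb <- function(centers) {
    d2 <- outer(x, centers, `-`)^2
    zero <- d2 < .Machine$double.eps
    u <- (d2 + .Machine$double.xmin)^(-1 / (m - 1))
    u <- u / rowSums(u)
    hit <- rowSums(zero) > 0
    if (any(hit)) u[hit, ] <- zero[hit, , drop = FALSE] /
        rowSums(zero[hit, , drop = FALSE])
    u
  }
  obj <- numeric(0)
  u <- memb(centers)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    um <- u^m
    centers <- colSums(um * x) / colSums(um)
    u <- memb(centers)
    j_now <- sum(u^m * outer(x, centers, `-`)^2)
    obj <- c(obj, j_now)
    if (it > 1 && abs(obj[it - 1] - j_now) < tol) { converged <- TRUE; break }
  }
  list(centers = centers, membership = u, objective = obj,
       converged = converged)
}

#' Slice-wise fuzzy c-means lesion segmentation
#'
#' Within the operator rectangle, each slice of the slice range is
#' clustered into `n_clusters` fuzzy clusters of intensity; voxels whose
#' maximum membership belongs to the lesion cluster (the cluster with the
#' highest center — the enhancing tumor on contrast-enhanced T1) form the
#' raw mask.  The raw mask is typically passed to [postprocess_mask()].
#'
#' @param vol an [image_volume()] (normally the z-normalized T1CE volume).
#' @param roi a [bounding_roi()].
#' @param n_clusters number of clusters (default 2: lesion vs background).
#' @param m fuzzifier (> 1, default 2).
#' @param tol absolute termination tolerance on the objective (default 1e-5).
#' @param max_iter iteration cap per slice (default 300); non-convergence
#'   returns the best solution and sets the `converged` attribute to FALSE
#'   with a warning.
#' @param seed integer seed for the center initialization.
#' @return a raw [lesion_mask()] on the full grid, with attributes
#'   `converged` (logical) and `objective` (list of per-slice traces).
#' @export
fcm_segment <- function(vol, roi, n_clusters = 2, m = 2, tol = 1e-5,
                        max_iter = 300, seed = 1L) {
  stopifnot(inherits(vol, "image_volume"), inherits(roi, "bounding_roi"))
  d <- dim(vol$data)
  stop_if_not(roi$rect[2] <= d[1] && roi$rect[4] <= d[2] &&
                roi$slices[2] <= d[3] && all(c(roi$rect, roi$slices) >= 1),
              "bounding ROI exceeds the volume grid")
  ii <- roi$rect[1]:roi$rect[2]
  jj <- roi$rect[3]:roi$rect[4]
  out <- array(FALSE, dim = d)
  traces <- list()
  all_conv <- TRUE
  with_seed(seed, {
    for (s in roi$slices[1]:roi$slices[2]) {
      sl <- vol$data[ii, jj, s]
      fit <- fcm_cluster(as.numeric(sl), k = n_clusters, m = m, tol = tol,
                         max_iter = max_iter)
      lesion_k <- which.max(fit$centers)
      assign_k <- max.col(fit$membership, ties.method = "first")
      out[ii, jj, s] <- array(assign_k == lesion_k, dim = dim(sl))
      traces[[as.character(s)]] <- fit$objective
      all_conv <- all_conv && fit$converged
    }
  })
  if (!all_conv)
    warning("FCM did not converge on every slice within max_iter; returning best solution")
  res <- lesion_mask(out, vol$spacing)
  attr(res, "converged") <- all_conv
  attr(res, "objective") <- traces
  res
}
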