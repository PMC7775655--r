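#' First-order intensity features
#'
#' The 18 standard first-order statistics of the in-mask intensities.
#' Entropy and Uniformity are computed on the equal-width discretized
#' histogram (`n_bins` levels); moments use population (n) denominators;
#' Kurtosis is the Pearson (non-excess) convention; percentiles use linear
#' interpolation.  A constant ROI yields variance 0, entropy 0 and, by
#' documented convention, skewness and kurtosis 0.
#'
#' @param vol an [image_volume()].
#' @param mask a [lesion_mask()] on the same grid with >= 2 voxels.
#' @param n_bins histogram bins for Entropy/Uniformity (default 32).
#' @return named numeric vector of 18 features.
#' @export
first_order_features <- function(vol, mask, n_bins = 32) {
  stopifnot(inherits(vol, "image_volume"), inherits(mask, "lesion_mask"))
  x <- vol$data[mask$data]
  stop_if_not(length(x) >= 2, "ROI must contain at least 2 voxels")
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  rob <- x[x >= q[1] & x <= q[5]]
  rng <- range(x)
  if (rng[1] == rng[2]) {
    p <- 1
  } else {
    w <- (rng[2] - rng[1]) / n_bins
    lev <- pmin(floor((x - rng[1]) / w) + 1L, n_bins)
    p <- tabulate(lev, n_bins) / n
    p <- p[p > 0]
  }
  vvol <- prod(vol$spacing)
  c(Energy = sum(x^2),
    TotalEnergy = vvol * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = rng[1],
    Percentile10 = q[1],
    Percentile90 = q[5],
    Maximum = rng[2],
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = rng[2] - rng[1],
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(rob - mean(rob))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}
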