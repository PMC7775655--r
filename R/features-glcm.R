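## Symmetric normalized co-occurrence matrix for one direction offset, or
## NULL when the direction yields no in-mask voxel pairs.
glcm_matrix <- function(d, off) {
  ng <- d$n_levels
  sp <- shift_pairs(dim(d$levels), off)
  a <- d$levels[sp[, 1]]; b <- d$levels[sp[, 2]]
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) return(NULL)
  a <- a[keep]; b <- b[keep]
  cnt <- matrix(tabulate(a + (b - 1L) * ng, ng * ng), ng, ng)
  p <- cnt + t(cnt)  # symmetric
  p / sum(p)
}

glcm_features_one <- function(p) {
  ng <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p)  # == colSums(p) by symmetry
  mu <- sum(i * p)
  sigma2 <- sum((i - mu)^2 * p)
  k_diff <- 0:(ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(p[abs(i - j) == k]), numeric(1))
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(p[(i + j) == k]), numeric(1))
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  hx <- ent(px)
  hxy <- ent(p)
  pospair <- p > 0
  pxy <- outer(px, px)
  hxy1 <- -sum(p[pospair] * log2(pxy[pospair]))
  pos2 <- pxy > 0
  hxy2 <- -sum(pxy[pos2] * log2(pxy[pos2]))
  da <- sum(k_diff * p_diff)
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  # MCC: second-largest sqrt-eigenvalue of the Markov transition matrix Q
  mcc <- 1
  act <- which(px > 0)
  if (length(act) >= 2) {
    ps <- p[act, act, drop = FALSE]
    pxa <- px[act]
    q <- matrix(0, length(act), length(act))
    for (kk in seq_along(act))
      q <- q + outer(ps[, kk], ps[, kk]) / (pxa * pxa[kk])
    evq <- sort(Re(eigen(q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(pmax(evq[2], 0))
  }
  offdiag <- i != j
  c(Autocorrelation = sum(i * j * p),
    JointAverage = mu,
    ClusterProminence = sum((i + j - 2 * mu)^4 * p),
    ClusterShade = sum((i + j - 2 * mu)^3 * p),
    ClusterTendency = sum((i + j - 2 * mu)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = if (sigma2 > 0) (sum(i * j * p) - mu^2) / sigma2 else 1,
    DifferenceAverage = da,
    DifferenceEntropy = ent(p_diff),
    DifferenceVariance = sum((k_diff - da)^2 * p_diff),
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + ((i - j) / ng)^2)),
    Id = sum(p / (1 + abs(i - j))),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    InverseVariance = sum(p[offdiag] / (i[offdiag] - j[offdiag])^2),
    MaximumProbability = max(p),
    MCC = mcc,
    SumAverage = sum(k_sum * p_sum),
    SumEntropy = ent(p_sum),
    SumSquares = sigma2)
}

#' Gray-level co-occurrence matrix features
#'
#' The co-occurrence matrix is built per direction at distance 1 over the
#' 13 unique 3D directions, made symmetric and normalized; the 24 features
#' are computed per direction and averaged.  The informational measure of
#' correlation 1 is `(HXY - HXY1) / max(HX, HY)` and is defined as 0 for a
#' constant ROI (HX = HY = 0).
#'
#' @param d a [discretize()]d ROI.
#' @return named numeric vector of 24 features.
#' @export
glcm_features <- function(d) {
  stopifnot(inherits(d, "discretized_roi"))
  offs <- neighbor_offsets(half = TRUE)
  mats <- lapply(seq_len(nrow(offs)),
                 function(r) glcm_matrix(d, offs[r, ]))
  mats <- Filter(Negate(is.null), mats)
  stop_if_not(length(mats) > 0,
              "ROI has no voxel pairs in any direction (single voxel?)")
  rowMeans(vapply(mats, glcm_features_one,
                  numeric(24)))
}
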