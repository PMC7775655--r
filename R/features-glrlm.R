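## Run-length matrix (levels x run length, counts) for one direction.
glrlm_matrix <- function(d, off) {
  lev <- d$levels
  dims <- dim(lev)
  idx <- which(!is.na(lev))
  ai <- arrayInd(idx, dims)
  step <- sum(off^2)
  # integer line parameterization: pos advances by `step` per voxel along
  # the direction, and step*ai - pos*off is constant along a line
  pos <- as.integer(ai %*% as.integer(off))
  lineid <- step * ai - outer(pos, as.integer(off))
  key <- paste(lineid[, 1], lineid[, 2], lineid[, 3])
  ord <- order(key, pos)
  g <- lev[idx][ord]
  contig <- c(FALSE, diff(pos[ord]) == step &
                key[ord][-1] == key[ord][-length(ord)])
  newrun <- !(contig & g == c(NA, g[-length(g)]))
  runid <- cumsum(newrun)
  rl <- tabulate(runid)
  rg <- g[newrun]
  max_rl <- max(rl)
  matrix(tabulate(rg + (rl - 1L) * d$n_levels, d$n_levels * max_rl),
         d$n_levels, max_rl)
}

## Shared feature formulas for run-length-style matrices: P is a
## gray-level x size matrix of counts, np the number of in-mask voxels.
## `size_name` selects the naming family (Run / Zone / area wording).
rl_type_features <- function(P, np, names16) {
  nr <- sum(P)
  g <- row(P); l <- col(P)
  p <- P / nr
  mu_g <- sum(g * p); mu_l <- sum(l * p)
  ppos <- p[p > 0]
  vals <- c(
    sum(P / l^2) / nr,
    sum(P * l^2) / nr,
    sum(rowSums(P)^2) / nr,
    sum(rowSums(P)^2) / nr^2,
    sum(colSums(P)^2) / nr,
    sum(colSums(P)^2) / nr^2,
    nr / np,
    sum((g - mu_g)^2 * p),
    sum((l - mu_l)^2 * p),
    -sum(ppos * log2(ppos)),
    sum(P / g^2) / nr,
    sum(P * g^2) / nr,
    sum(P / (g^2 * l^2)) / nr,
    sum(P * g^2 / l^2) / nr,
    sum(P * l^2 / g^2) / nr,
    sum(P * g^2 * l^2) / nr)
  stats::setNames(vals, names16)
}

#' Gray-level run-length matrix features
#'
#' Runs of equal gray level are counted along each of the 13 unique 3D
#' directions; the 16 standard features are computed per direction and
#' averaged.
#'
#' @param d a [discretize()]d ROI.
#' @return named numeric vector of 16 features.
#' @export
glrlm_features <- function(d) {
  stopifnot(inherits(d, "discretized_roi"))
  np <- sum(!is.na(d$levels))
  stop_if_not(np > 0, "mask is empty")
  offs <- neighbor_offsets(half = TRUE)
  nm <- c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
          "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
          "RunLengthNonUniformityNormalized", "RunPercentage",
          "GrayLevelVariance", "RunVariance", "RunEntropy",
          "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
          "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
          "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")
  feats <- vapply(seq_len(nrow(offs)), function(r) {
    rl_type_features(glrlm_matrix(d, offs[r, ]), np, nm)
  }, numeric(16))
  rowMeans(feats)
}

#' Gray-level size-zone matrix features
#'
#' Zones are 26-connected components of equal gray level (direction-free;
#' a single matrix per ROI); the 16 standard features parallel the
#' run-length family with zone size in place of run length.
#'
#' @param d a [discretize()]d ROI.
#' @return named numeric vector of 16 features.
#' @export
glszm_features <- function(d) {
  stopifnot(inherits(d, "discretized_roi"))
  lev <- d$levels
  np <- sum(!is.na(lev))
  stop_if_not(np > 0, "mask is empty")
  # one component pass: connect neighbours only when levels are equal
  dims <- dim(lev)
  idx <- which(!is.na(lev))
  node <- array(0L, dim = dims)
  node[idx] <- seq_along(idx)
  offs <- neighbor_offsets(half = TRUE)
  edges <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    sp <- shift_pairs(dims, offs[r, ])
    keep <- !is.na(lev[sp[, 1]]) & !is.na(lev[sp[, 2]]) &
      lev[sp[, 1]] == lev[sp[, 2]]
    edges[[r]] <- cbind(node[sp[keep, 1]], node[sp[keep, 2]])
  }
  g <- igraph::make_graph(t(do.call(rbind, edges)), n = length(idx),
                          directed = FALSE)
  memb <- igraph::components(g)$membership
  zone_size <- tabulate(memb)
  zone_level <- lev[idx][match(seq_along(zone_size), memb)]
  P <- matrix(tabulate(zone_level + (zone_size - 1L) * d$n_levels,
                       d$n_levels * max(zone_size)),
              d$n_levels, max(zone_size))
  nm <- c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
          "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
          "SizeZoneNonUniformityNormalized", "ZonePercentage",
          "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
          "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
          "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
          "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")
  rl_type_features(P, np, nm)
}

#' Gray-level dependence matrix features
#'
#' A voxel's dependence is the number of its 26 in-mask neighbours with the
#' same gray level (dependence threshold alpha = 0); the matrix counts
#' voxels by (level, dependence + 1).
#'
#' @param d a [discretize()]d ROI.
#' @return named numeric vector of 14 features.
#' @export
gldm_features <- function(d) {
  stopifnot(inherits(d, "discretized_roi"))
  lev <- d$levels
  dims <- dim(lev)
  np <- sum(!is.na(lev))
  stop_if_not(np > 0, "mask is empty")
  dep <- array(0L, dim = dims)
  offs <- neighbor_offsets(half = FALSE)
  for (r in seq_len(nrow(offs))) {
    sp <- shift_pairs(dims, offs[r, ])
    ok <- !is.na(lev[sp[, 1]]) & !is.na(lev[sp[, 2]]) &
      lev[sp[, 1]] == lev[sp[, 2]]
    f <- sp[ok, 1]
    dep[f] <- dep[f] + 1L
  }
  idx <- !is.na(lev)
  j <- dep[idx] + 1L  # dependence size including the center voxel
  g <- lev[idx]
  P <- matrix(tabulate(g + (j - 1L) * d$n_levels, d$n_levels * max(j)),
              d$n_levels, max(j))
  nz <- sum(P)
  gg <- row(P); jj <- col(P)
  p <- P / nz
  mu_g <- sum(gg * p); mu_j <- sum(jj * p)
  ppos <- p[p > 0]
  c(SmallDependenceEmphasis = sum(P / jj^2) / nz,
    LargeDependenceEmphasis = sum(P * jj^2) / nz,
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nz,
    DependenceNonUniformity = sum(colSums(P)^2) / nz,
    DependenceNonUniformityNormalized = sum(colSums(P)^2) / nz^2,
    GrayLevelVariance = sum((gg - mu_g)^2 * p),
    DependenceVariance = sum((jj - mu_j)^2 * p),
    DependenceEntropy = -sum(ppos * log2(ppos)),
    LowGrayLevelEmphasis = sum(P / gg^2) / nz,
    HighGrayLevelEmphasis = sum(P * gg^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / (gg^2 * jj^2)) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * gg^2 / jj^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * jj^2 / gg^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * gg^2 * jj^2) / nz)
}
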