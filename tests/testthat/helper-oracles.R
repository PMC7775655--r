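# Fixture builders and independent brute-force oracles.  The oracles use
# plain voxel-by-voxel loops and share no code with the package internals.

sphere_mask <- function(r = 10, sp = c(1, 1, 1), n = c(40, 40, 40),
                        center = (n - 1) * sp / 2) {
  co <- lapply(1:3, function(a) (seq_len(n[a]) - 1) * sp[a] - center[a])
  rsq <- outer(outer(co[[1]]^2, co[[2]]^2, `+`), co[[3]]^2, `+`)
  lesion_mask(rsq <= r^2, sp)
}

cube_mask <- function(side_vox = 20, n = c(30, 30, 30), sp = c(1, 1, 1)) {
  m <- array(FALSE, dim = n)
  lo <- floor((n - side_vox) / 2) + 1
  m[lo[1]:(lo[1] + side_vox - 1), lo[2]:(lo[2] + side_vox - 1),
    lo[3]:(lo[3] + side_vox - 1)] <- TRUE
  lesion_mask(m, sp)
}

dice <- function(a, b) {
  a <- if (inherits(a, "lesion_mask")) a$data else a
  b <- if (inherits(b, "lesion_mask")) b$data else b
  2 * sum(a & b) / (sum(a) + sum(b))
}

# wrap an integer level array (NA outside mask) as a discretized ROI
as_droi <- function(lev, n_levels = max(lev, na.rm = TRUE),
                    sp = c(1, 1, 1)) {
  if (length(dim(lev)) == 2) lev <- array(lev, dim = c(dim(lev), 1))
  structure(list(levels = lev, n_levels = as.integer(n_levels),
                 bin_edges = NULL, mask = !is.na(lev), spacing = sp,
                 modality = "T1CE", variant = "original"),
            class = "discretized_roi")
}

random_droi <- function(dims, n_levels, p_mask = 0.85, seed = 1) {
  set.seed(seed)
  lev <- array(sample.int(n_levels, prod(dims), replace = TRUE), dim = dims)
  lev[array(runif(prod(dims)) > p_mask, dim = dims)] <- NA
  as_droi(lev, n_levels)
}

all_offsets <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

half_offsets <- function() {
  g <- all_offsets()
  g[g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
      (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0), , drop = FALSE]
}

inside <- function(p, dims) all(p >= 1) && all(p <= dims)

# exhaustive pair enumeration -> symmetric normalized GLCM per direction
bf_glcm_matrix <- function(lev, off, ng) {
  dims <- dim(lev)
  cnt <- matrix(0, ng, ng)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      a <- lev[i, j, k]
      if (is.na(a)) next
      q <- c(i, j, k) + off
      if (!inside(q, dims)) next
      b <- lev[q[1], q[2], q[3]]
      if (is.na(b)) next
      cnt[a, b] <- cnt[a, b] + 1
      cnt[b, a] <- cnt[b, a] + 1
    }
  if (sum(cnt) == 0) return(NULL)
  cnt / sum(cnt)
}

# exhaustive run enumeration -> run-length count matrix per direction
bf_glrlm_matrix <- function(lev, off, ng) {
  dims <- dim(lev)
  runs <- integer(0)
  glev <- integer(0)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      p <- c(i, j, k)
      if (inside(p - off, dims)) next  # not a line start
      curg <- NA; curl <- 0
      while (inside(p, dims)) {
        v <- lev[p[1], p[2], p[3]]
        if (is.na(v)) {
          if (!is.na(curg)) { runs <- c(runs, curl); glev <- c(glev, curg) }
          curg <- NA; curl <- 0
        } else if (!is.na(curg) && v == curg) {
          curl <- curl + 1
        } else {
          if (!is.na(curg)) { runs <- c(runs, curl); glev <- c(glev, curg) }
          curg <- v; curl <- 1
        }
        p <- p + off
      }
      if (!is.na(curg)) { runs <- c(runs, curl); glev <- c(glev, curg) }
    }
  P <- matrix(0, ng, max(runs))
  for (t in seq_along(runs)) P[glev[t], runs[t]] <- P[glev[t], runs[t]] + 1
  P
}

# zone enumeration by repeated flood fill (26-connectivity, equal level)
bf_glszm_zones <- function(lev) {
  dims <- dim(lev)
  seen <- array(FALSE, dim = dims)
  offs <- all_offsets()
  zones <- list()
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      if (seen[i, j, k] || is.na(lev[i, j, k])) next
      g <- lev[i, j, k]
      stack <- list(c(i, j, k)); seen[i, j, k] <- TRUE; size <- 0
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        size <- size + 1
        for (r in seq_len(nrow(offs))) {
          q <- p + offs[r, ]
          if (inside(q, dims) && !seen[q[1], q[2], q[3]] &&
              !is.na(lev[q[1], q[2], q[3]]) &&
              lev[q[1], q[2], q[3]] == g) {
            seen[q[1], q[2], q[3]] <- TRUE
            stack[[length(stack) + 1]] <- q
          }
        }
      }
      zones[[length(zones) + 1]] <- c(g, size)
    }
  do.call(rbind, zones)
}

# per-voxel dependence counts (alpha = 0: equal level)
bf_gldm_matrix <- function(lev, ng) {
  dims <- dim(lev)
  offs <- all_offsets()
  recs <- list()
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      g <- lev[i, j, k]
      if (is.na(g)) next
      dep <- 0
      for (r in seq_len(nrow(offs))) {
        q <- c(i, j, k) + offs[r, ]
        if (inside(q, dims) && !is.na(lev[q[1], q[2], q[3]]) &&
            lev[q[1], q[2], q[3]] == g) dep <- dep + 1
      }
      recs[[length(recs) + 1]] <- c(g, dep + 1)
    }
  recs <- do.call(rbind, recs)
  P <- matrix(0, ng, max(recs[, 2]))
  for (t in seq_len(nrow(recs)))
    P[recs[t, 1], recs[t, 2]] <- P[recs[t, 1], recs[t, 2]] + 1
  P
}

# neighbourhood gray-tone sums s_i and probabilities p_i by enumeration
bf_ngtdm <- function(lev, ng) {
  dims <- dim(lev)
  offs <- all_offsets()
  s_i <- numeric(ng); n_i <- numeric(ng)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      g <- lev[i, j, k]
      if (is.na(g)) next
      nb <- c()
      for (r in seq_len(nrow(offs))) {
        q <- c(i, j, k) + offs[r, ]
        if (inside(q, dims) && !is.na(lev[q[1], q[2], q[3]]))
          nb <- c(nb, lev[q[1], q[2], q[3]])
      }
      if (length(nb) == 0) next
      s_i[g] <- s_i[g] + abs(g - mean(nb))
      n_i[g] <- n_i[g] + 1
    }
  list(s = s_i, p = n_i / sum(n_i), nvp = sum(n_i))
}
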