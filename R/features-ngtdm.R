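#' Neighbourhood gray-tone difference matrix features
#'
#' For every in-mask voxel with at least one in-mask 26-neighbour, the
#' absolute difference between its gray level and the mean level of its
#' in-mask neighbours is accumulated per level (`s_i`); `p_i` is the level
#' probability.  Coarseness is `1 / sum(p_i s_i)` — the inverse of the
#' probability-weighted local intensity change rate, large for locally
#' uniform texture — and is set to the documented sentinel `1e6` when the
#' denominator is zero (uniform ROI).
#'
#' @param d a [discretize()]d ROI.
#' @return named numeric vector: Coarseness, Contrast, Busyness,
#'   Complexity, Strength.
#' @export
ngtdm_features <- function(d) {
  stopifnot(inherits(d, "discretized_roi"))
  lev <- d$levels
  dims <- dim(lev)
  ng <- d$n_levels
  nb_sum <- array(0, dim = dims)
  nb_cnt <- array(0L, dim = dims)
  offs <- neighbor_offsets(half = FALSE)
  for (r in seq_len(nrow(offs))) {
    sp <- shift_pairs(dims, offs[r, ])
    ok <- !is.na(lev[sp[, 1]]) & !is.na(lev[sp[, 2]])
    f <- sp[ok, 1]; t <- sp[ok, 2]
    nb_sum[f] <- nb_sum[f] + lev[t]
    nb_cnt[f] <- nb_cnt[f] + 1L
  }
  valid <- !is.na(lev) & nb_cnt > 0
  stop_if_not(any(valid), "no voxel has an in-mask neighbourhood")
  g <- lev[valid]
  abar <- nb_sum[valid] / nb_cnt[valid]
  nvp <- sum(valid)
  n_i <- tabulate(g, ng)
  s_i <- vapply(seq_len(ng), function(i) sum(abs(i - abar)[g == i]),
                numeric(1))
  p_i <- n_i / nvp
  act <- which(p_i > 0)
  ngp <- length(act)
  denom_coarse <- sum(p_i * s_i)
  coarseness <- if (denom_coarse > 0) 1 / denom_coarse else 1e6
  contrast <- if (ngp > 1) {
    sum(outer(p_i[act], p_i[act]) * outer(act, act, `-`)^2) /
      (ngp * (ngp - 1)) * sum(s_i) / nvp
  } else 0
  busy_den <- sum(abs(outer(act * p_i[act], act * p_i[act], `-`)))
  busyness <- if (busy_den > 0) sum(p_i * s_i) / busy_den else 0
  pi_a <- p_i[act]; si_a <- s_i[act]
  complexity <- sum(abs(outer(act, act, `-`)) *
                      (outer(pi_a * si_a, pi_a * si_a, `+`)) /
                      outer(pi_a, pi_a, `+`)) / nvp
  strength_num <- sum(outer(pi_a, pi_a, `+`) * outer(act, act, `-`)^2)
  strength <- if (sum(s_i) > 0) strength_num / sum(s_i) else 0
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}
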