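vol_from <- function(x, sp = c(1, 1, 1), modality = "T1CE") {
  if (length(dim(x)) == 2) x <- array(x, dim = c(dim(x), 1))
  image_volume(array(as.numeric(x), dim = dim(x)), sp, modality)
}
mask_of <- function(x, sp = c(1, 1, 1)) {
  if (length(dim(x)) == 2) x <- array(x, dim = c(dim(x), 1))
  lesion_mask(array(TRUE, dim = dim(x)), sp)
}

test_that("equal-width discretization maps min to level 1, max to n_bins, conserving voxels", {
  v <- vol_from(array(0:31, dim = c(32, 1, 1)))
  d <- discretize(v, mask_of(v$data), 32)
  expect_identical(as.integer(d$levels[, 1, 1]), 1:32)

  cv <- vol_from(array(5, dim = c(3, 3, 1)))
  expect_warning(dc <- discretize(cv, mask_of(cv$data), 8), "constant")
  expect_true(all(dc$levels[!is.na(dc$levels)] == 1L))

  set.seed(2)
  rv <- vol_from(array(rnorm(60), dim = c(5, 4, 3)))
  m <- lesion_mask(array(runif(60) < 0.7, dim = c(5, 4, 3)), c(1, 1, 1))
  dr <- discretize(rv, m, 6)
  expect_equal(sum(tabulate(dr$levels[m$data], 6)), sum(m$data))
  expect_true(all(dr$levels[m$data] %in% 1:6))
})

test_that("first-order features match direct moment computations", {
  v <- vol_from(array(c(1, 2, 3), dim = c(3, 1, 1)))
  f <- first_order_features(v, mask_of(v$data))
  expect_equal(unname(f["Mean"]), 2)
  expect_equal(unname(f["Range"]), 2)
  expect_equal(unname(f["Median"]), 2)

  cv <- vol_from(array(4, dim = c(4, 2, 1)))
  fc <- first_order_features(cv, mask_of(cv$data))
  expect_equal(unname(fc[c("Variance", "Entropy", "Skewness", "Kurtosis")]),
               c(0, 0, 0, 0))
  expect_equal(unname(fc["Uniformity"]), 1)

  set.seed(11)
  x <- rnorm(1000)
  vx <- vol_from(array(x, dim = c(10, 10, 10)))
  fx <- first_order_features(vx, mask_of(vx$data))
  mu <- mean(x); m2 <- mean((x - mu)^2)
  expect_equal(unname(fx["Skewness"]), mean((x - mu)^3) / m2^1.5,
               tolerance = 1e-12)
  expect_lt(abs(fx["Skewness"]), 0.2)
  # Pearson convention: the normal reference value is 3, not 0
  expect_equal(unname(fx["Kurtosis"]), mean((x - mu)^4) / m2^2,
               tolerance = 1e-12)
  expect_lt(abs(fx["Kurtosis"] - 3), 0.5)
  expect_equal(unname(fx["Energy"]), sum(x^2))
  expect_equal(unname(fx["RootMeanSquared"]), sqrt(mean(x^2)))
})

test_that("surface-to-volume ratio matches analytic solids and scales inversely with size", {
  sph <- shape_features(sphere_mask(10))
  expect_lt(abs(sph["SurfaceVolumeRatio"] - 0.3) / 0.3, 0.05)
  expect_gt(sph["Sphericity"], 0.95)
  expect_lt(abs(sph["Maximum3DDiameter"] - 20) / 20, 0.1)

  cub <- shape_features(cube_mask(20))
  expect_lt(abs(cub["SurfaceVolumeRatio"] - 0.3) / 0.3, 0.05)
  expect_lt(cub["Sphericity"], 0.95)

  # same voxel grid at doubled spacing: every length doubles, A/V halves
  half <- shape_features(sphere_mask(10), spacing = c(2, 2, 2))
  expect_equal(unname(half["SurfaceVolumeRatio"]),
               unname(sph["SurfaceVolumeRatio"]) / 2, tolerance = 1e-10)
  expect_equal(unname(half["Maximum3DDiameter"]),
               2 * unname(sph["Maximum3DDiameter"]), tolerance = 1e-10)
})

test_that("GLCM matches exhaustive pair enumeration, including IMC1, on a toy grid", {
  lev <- matrix(c(1, 1, 2, 2), 2, byrow = TRUE)
  d <- as_droi(lev, 2)
  offs <- half_offsets()
  for (r in seq_len(nrow(offs))) {
    p_bf <- bf_glcm_matrix(d$levels, offs[r, ], 2)
    p_us <- pitradiomics:::glcm_matrix(d, offs[r, ])
    expect_equal(p_us, p_bf)
  }
  # IMC1 by hand from the within-row direction: p = [[1/2,0],[0,1/2]]
  p <- bf_glcm_matrix(d$levels, c(0, 1, 0), 2)
  expect_equal(p, matrix(c(0.5, 0, 0, 0.5), 2))
  hx <- 1; hxy <- 1; hxy1 <- -sum(p[p > 0] * log2(outer(rowSums(p),
                                                        rowSums(p))[p > 0]))
  imc1_hand <- (hxy - hxy1) / hx
  f <- glcm_features(d)
  # aggregated IMC1 averages directions; check the single-direction value
  f1 <- pitradiomics:::glcm_features_one(p)
  expect_equal(unname(f1["Imc1"]), imc1_hand)
  expect_equal(length(f), 24L)
})

test_that("GLCM degenerate conventions: constant ROI and single voxel", {
  dc <- as_droi(matrix(1, 3, 3), 2)
  f <- glcm_features(dc)
  expect_equal(unname(f["Imc1"]), 0)
  expect_equal(unname(f["Contrast"]), 0)
  expect_equal(unname(f["JointEntropy"]), 0)
  d1 <- as_droi(matrix(c(1, NA, NA, NA), 2), 2)
  expect_error(glcm_features(d1), "pairs")
})

test_that("checkerboard attains the maximal axis-direction GLCM contrast among two-level images", {
  dims <- c(6, 6, 3)
  idx <- which(array(TRUE, dim = dims), arr.ind = TRUE)
  chk <- array(1L + (rowSums(idx) %% 2L), dim = dims)
  d_chk <- as_droi(chk, 2)
  # along every unit axis all neighbour pairs differ: per-direction
  # contrast is exactly 1, the maximum possible for two levels
  for (off in list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))) {
    p <- pitradiomics:::glcm_matrix(d_chk, off)
    f1 <- pitradiomics:::glcm_features_one(p)
    expect_equal(unname(f1["Contrast"]), 1)
    set.seed(5)
    for (i in 1:5) {
      rnd <- array(sample(1:2, prod(dims), TRUE), dim = dims)
      p_r <- pitradiomics:::glcm_matrix(as_droi(rnd, 2), off)
      expect_lte(pitradiomics:::glcm_features_one(p_r)["Contrast"],
                 1 + 1e-12)
    }
  }
})

test_that("NGTDM matches hand enumeration on a toy grid and handles the uniform sentinel", {
  lev <- matrix(1, 3, 3); lev[2, 2] <- 2
  d <- as_droi(lev, 2)
  bf <- bf_ngtdm(d$levels, 2)
  # hand check: the 8 border pixels each see the deviant center
  expect_equal(bf$s[2], abs(2 - 1))           # center vs mean of its 8 ones
  f <- ngtdm_features(d)
  expect_equal(unname(f["Coarseness"]), 1 / sum(bf$p * bf$s))

  expect_equal(unname(ngtdm_features(as_droi(matrix(1, 4, 4), 2))["Coarseness"]),
               1e6)
})

test_that("run-length, size-zone and dependence matrices match trivial structures", {
  # 1 x n alternating two levels: n runs of length 1 horizontally
  alt <- matrix(rep(c(1, 2), 5), nrow = 10, ncol = 1)
  P <- pitradiomics:::glrlm_matrix(as_droi(alt, 2), c(1L, 0L, 0L))
  expect_equal(ncol(P), 1L)
  expect_equal(sum(P), 10)

  # single-level ROI of n voxels: one zone of size n
  one <- as_droi(matrix(1, 4, 5), 2)
  z <- glszm_features(one)
  expect_equal(unname(z["ZonePercentage"]), 1 / 20)
  expect_equal(unname(z["LargeAreaEmphasis"]), 20^2)

  # fully dependent uniform ROI: interior voxel has dependence 27
  g <- gldm_features(as_droi(array(1L, dim = c(5, 5, 5)), 2))
  expect_equal(unname(g["LargeDependenceEmphasis"]) >= 20^2 / 25, TRUE)
})

test_that("texture matrices equal exhaustive brute-force enumeration on random ROIs", {
  for (seed in 1:4) {
    d <- random_droi(c(6, 6, 3), n_levels = 4, seed = seed)
    offs <- half_offsets()
    for (r in seq_len(nrow(offs))) {
      expect_equal(pitradiomics:::glcm_matrix(d, offs[r, ]),
                   bf_glcm_matrix(d$levels, offs[r, ], 4))
      expect_equal(pitradiomics:::glrlm_matrix(d, offs[r, ]),
                   bf_glrlm_matrix(d$levels, offs[r, ], 4))
    }
    # GLSZM zones
    zones <- bf_glszm_zones(d$levels)
    np <- sum(!is.na(d$levels))
    zp <- glszm_features(d)
    expect_equal(unname(zp["ZonePercentage"]), nrow(zones) / np)
    expect_equal(unname(zp["LargeAreaEmphasis"]),
                 sum(zones[, 2]^2) / nrow(zones))
    # GLDM
    Pd <- bf_gldm_matrix(d$levels, 4)
    gd <- gldm_features(d)
    nz <- sum(Pd)
    jj <- matrix(seq_len(ncol(Pd)), nrow(Pd), ncol(Pd), byrow = TRUE)
    expect_equal(unname(gd["LargeDependenceEmphasis"]),
                 sum(Pd * jj^2) / nz)
    expect_equal(unname(gd["GrayLevelNonUniformity"]),
                 sum(rowSums(Pd)^2) / nz)
    # NGTDM
    bf <- bf_ngtdm(d$levels, 4)
    f <- ngtdm_features(d)
    expect_equal(unname(f["Coarseness"]),
                 if (sum(bf$p * bf$s) > 0) 1 / sum(bf$p * bf$s) else 1e6)
  }
})

test_that("probability matrices are normalized and features are intensity-rescale invariant", {
  d <- random_droi(c(7, 6, 4), n_levels = 5, seed = 9)
  offs <- half_offsets()
  for (r in seq_len(nrow(offs))) {
    p <- pitradiomics:::glcm_matrix(d, offs[r, ])
    expect_lt(abs(sum(p) - 1), 1e-10)
  }
  bf <- bf_ngtdm(d$levels, 5)
  expect_lt(abs(sum(bf$p) - 1), 1e-10)

  set.seed(21)
  arr <- array(rnorm(6 * 6 * 4), dim = c(6, 6, 4))
  m <- lesion_mask(array(TRUE, dim = dim(arr)), c(1, 1, 1))
  v1 <- vol_from(arr)
  v2 <- vol_from(3.2 * arr + 17)   # affine intensity rescale
  f1 <- pitradiomics:::extract_modality(v1, m)
  f2 <- pitradiomics:::extract_modality(v2, m)
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("direction-aggregated GLCM features are stable under 90-degree in-plane rotation", {
  p <- generate_phantom(phantom_spec(voxel_spacing_mm = c(1, 1, 1),
                                     grid_shape = c(48, 48, 48),
                                     tumor_radii_mm = c(14, 10, 10),
                                     rng_seed = 6))
  vn <- normalize_roi(p$t1ce, p$mask)
  d1 <- discretize(vn, p$mask, 32)
  rot <- function(a) {
    n <- dim(a)[1]
    array(aperm(a, c(2, 1, 3))[, n:1, , drop = FALSE], dim = dim(a))
  }
  vr <- image_volume(rot(vn$data), c(1, 1, 1), "T1CE")
  mr <- lesion_mask(rot(p$mask$data), c(1, 1, 1))
  d2 <- discretize(vr, mr, 32)
  f1 <- glcm_features(d1); f2 <- glcm_features(d2)
  expect_lt(max(abs(f2 - f1) / pmax(abs(f1), 1e-8)), 0.01)
})

test_that("extract_all returns the stable 214-feature schema deterministically", {
  p <- generate_phantom(phantom_spec(grid_shape = c(48, 48, 24),
                                     tumor_radii_mm = c(10, 9, 8),
                                     rng_seed = 12))
  fv <- extract_all(p$t1ce, p$t2, p$mask)
  expect_length(fv, 214)
  expect_true(all(is.finite(fv)))
  expect_equal(sum(startsWith(names(fv), "T1_")), 107)
  expect_equal(sum(startsWith(names(fv), "T2_")), 107)
  fv2 <- extract_all(p$t1ce, p$t2, p$mask)
  expect_identical(fv, fv2)
  # shape family is mask-only and identical across modality namespaces
  expect_equal(unname(fv["T1_shape_SurfaceVolumeRatio"]),
               unname(fv["T2_shape_SurfaceVolumeRatio"]))
  expect_error(extract_all(p$t2, p$t2, p$mask), "T1CE")
})
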