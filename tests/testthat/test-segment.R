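test_that("isotropic resampling preserves constants and linear ramps", {
  const <- image_volume(array(3.7, dim = c(10, 12, 8)), c(1, 1, 2.5))
  r <- resample_isotropic(const, 1)
  expect_equal(r$spacing, c(1, 1, 1))
  expect_true(all(abs(r$data - 3.7) < 1e-12))
  # world extent preserved within one voxel
  expect_lte(abs((dim(r$data)[3] - 1) * 1 - (8 - 1) * 2.5), 1)

  # ramp along z: value = world z coordinate; linear interpolation is exact
  ramp <- image_volume(array(rep((0:7) * 2.5, each = 100),
                             dim = c(10, 10, 8)), c(1, 1, 2.5))
  rr <- resample_isotropic(ramp, 1)
  want <- rep((seq_len(dim(rr$data)[3]) - 1) * 1, each = 100)
  expect_lt(max(abs(as.numeric(rr$data) - want)), 1e-6 * diff(range(want)))

  # already-isotropic at target: returned unchanged
  iso <- image_volume(array(rnorm(8^3), dim = c(8, 8, 8)), c(2, 2, 2))
  expect_identical(resample_isotropic(iso, 2)$data, iso$data)
})

test_that("ROI normalization uses the population SD and is idempotent", {
  v <- array(0, dim = c(3, 1, 1)); v[] <- c(1, 2, 3)
  vol <- image_volume(v, c(1, 1, 1))
  m <- lesion_mask(array(TRUE, dim = c(3, 1, 1)), c(1, 1, 1))
  out <- normalize_roi(vol, m)
  expect_equal(as.numeric(out$data), c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-12)  # population SD = sqrt(2/3)
  out2 <- normalize_roi(out, m)
  expect_equal(out2$data, out$data, tolerance = 1e-10)

  set.seed(1)
  vol2 <- image_volume(array(rnorm(1000, 50, 7), dim = c(10, 10, 10)),
                       c(1, 1, 1))
  m2 <- lesion_mask(array(runif(1000) < 0.3, dim = c(10, 10, 10)), c(1, 1, 1))
  o2 <- normalize_roi(vol2, m2)
  roi <- o2$data[m2$data]
  expect_lt(abs(mean(roi)), 1e-10)
  expect_lt(abs(sqrt(mean((roi - mean(roi))^2)) - 1), 1e-10)

  czero <- image_volume(array(5, dim = c(4, 4, 4)), c(1, 1, 1))
  expect_error(normalize_roi(czero, lesion_mask(array(TRUE, dim = c(4, 4, 4)),
                                                c(1, 1, 1))),
               "zero variance")
})

test_that("FCM on well-separated intensities equals the optimal threshold and its objective is monotone", {
  set.seed(3)
  n <- c(24, 24, 1)
  truth <- array(FALSE, dim = n); truth[7:18, 7:18, 1] <- TRUE
  img <- array(rnorm(prod(n), 0, 1), dim = n)
  img[truth] <- img[truth] + 10   # delta mu = 10 sigma
  vol <- image_volume(img, c(1, 1, 1))
  roi <- bounding_roi(c(1, 24, 1, 24), c(1, 1))
  raw <- fcm_segment(vol, roi, seed = 1)
  # brute-force optimal threshold over all candidate midpoints
  xs <- sort(as.numeric(img))
  errs <- vapply(xs, function(t) sum((img >= t) != truth), numeric(1))
  thr <- xs[which.min(errs)]
  expect_identical(raw$data, img >= thr)
  expect_equal(dice(raw, truth), 1.0)
  obj <- attr(raw, "objective")[["1"]]
  expect_true(all(diff(obj) <= 1e-8))
})

test_that("FCM segmentation errors on constant slices and flags non-convergence", {
  vol <- image_volume(array(1, dim = c(8, 8, 2)), c(1, 1, 1))
  expect_error(fcm_segment(vol, bounding_roi(c(1, 8, 1, 8), c(1, 2))),
               "distinct")
  set.seed(2)
  vol2 <- image_volume(array(rnorm(8 * 8 * 1), dim = c(8, 8, 1)), c(1, 1, 1))
  expect_warning(fcm_segment(vol2, bounding_roi(c(1, 8, 1, 8), c(1, 1)),
                             max_iter = 1, seed = 1), "converge")
})

test_that("mask cleanup removes specks, fills cavities and is idempotent", {
  m <- array(FALSE, dim = c(20, 20, 20))
  m[5:12, 5:12, 5:12] <- TRUE
  m[18, 18, 18] <- TRUE  # distant speck
  cleaned <- postprocess_mask(lesion_mask(m, c(1, 1, 1)))
  expect_false(cleaned$data[18, 18, 18])
  expect_equal(sum(cleaned$data), 8^3)

  # hollow digitized sphere: interior refilled to the solid volume
  solid <- sphere_mask(8, n = c(24, 24, 24))
  shell <- solid$data & !sphere_mask(5, n = c(24, 24, 24))$data
  filled <- postprocess_mask(lesion_mask(shell, c(1, 1, 1)))
  expect_equal(sum(filled$data), sum(solid$data))

  again <- postprocess_mask(filled)
  expect_identical(again$data, filled$data)
  expect_error(postprocess_mask(lesion_mask(array(FALSE, dim = c(4, 4, 4)),
                                            c(1, 1, 1))), "empty")
})

test_that("affine mask transfer is exact for identity and integer translations and accurate for rigid motion", {
  sp <- sphere_mask(8, n = c(30, 30, 30))
  tgt <- image_volume(array(0, dim = c(30, 30, 30)), c(1, 1, 1))
  expect_identical(transfer_mask(sp, diag(4), tgt)$data, sp$data)

  tr <- diag(4); tr[1:3, 4] <- c(3, -2, 1)   # integer-voxel translation
  shifted <- transfer_mask(sp, tr, tgt)
  expect_identical(shifted$data,
                   sphere_mask(8, n = c(30, 30, 30),
                               center = c(14.5 + 3, 14.5 - 2, 14.5 + 1))$data)

  th <- 17 * pi / 180
  rot <- diag(4)
  rot[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  ctr <- c(14.5, 14.5, 14.5)
  rig <- diag(4); rig[1:3, 4] <- c(1.3, -0.7, 0.4)
  rig <- rig %*% rot
  # analytic image of the sphere: sphere at the transformed center
  newc <- (rig %*% c(ctr, 1))[1:3]
  got <- transfer_mask(sp, rig, tgt)
  want <- sphere_mask(8, n = c(30, 30, 30), center = newc)
  expect_gt(dice(got, want), 0.95)

  sing <- diag(4); sing[1, 1] <- 0
  expect_error(transfer_mask(sp, sing, tgt), "singular")
})

test_that("shell erosion matches the analytic eroded sphere and nests properly", {
  sp <- sphere_mask(20, n = c(50, 50, 50))
  er <- erode_shell(sp, 0.25)
  expect_equal(er$variant, "eroded_025")
  v_got <- sum(er$data)
  # analytic volume of the slice-wise eroded sphere: each z-slice is a
  # disk of radius sqrt(r^2 - z^2) eroded in-plane by 2.5 mm
  z <- (0:49) - 24.5
  rz <- sqrt(pmax(20^2 - z^2, 0))
  v_want <- sum(pi * pmax(rz - 2.5, 0)^2)
  expect_lt(abs(v_got - v_want) / v_want, 0.10)
  # cross-section at the equator matches the analytically eroded disk
  eq <- which.max(vapply(1:50, function(k) sum(sp$data[, , k]), numeric(1)))
  expect_lt(abs(sum(er$data[, , eq]) - pi * 17.5^2) / (pi * 17.5^2), 0.05)

  expect_identical(erode_shell(sp, 0)$data, sp$data)
  expect_error(erode_shell(sphere_mask(4, n = c(20, 20, 20)), 0.5),
               "original variant")

  # nesting holds for an irregular mask too
  set.seed(4)
  ph <- generate_phantom(phantom_spec(rng_seed = 4))
  for (mk in list(sp, ph$mask)) {
    e1 <- erode_shell(mk, 0.25)
    e2 <- erode_shell(mk, 0.5)
    expect_true(all(mk$data[e1$data]))
    expect_true(all(e1$data[e2$data]))
  }
})
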