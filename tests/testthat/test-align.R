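test_that("landmark initialization is the landmark difference", {
  expect_equal(init_translation(c(1, 2, 3), c(1, 2, 3))$translation,
               c(0, 0, 0))
  tr <- init_translation(c(0, 0, 0), c(5, -3, 10))
  expect_equal(tr$translation, c(5, -3, 10))
  expect_equal(tr$rotation, diag(3))
  expect_error(init_translation(c(NA, 0, 0), c(0, 0, 0)), "finite")
})

test_that("self-registration stays at the identity", {
  cs <- generate_case(small_spec(seed = 31, bulge_amplitude = 0,
                                 noise_sd = 0, rigid = rigid_transform()))
  bones <- segment_bones(cs$t1)
  T <- register_rigid(cs$t1, cs$t1, bones, rigid_transform(), max_iter = 30)
  expect_lt(sqrt(sum(T$translation^2)), 0.1)
  expect_lt(rotation_error_deg(T$rotation, diag(3)), 0.1)
  expect_false(attr(T, "flagged"))
  expect_error(register_rigid(cs$t1, cs$t1,
                              binary_mask(array(0L, dim(cs$t1$voxels)),
                                          cs$t1$spacing)), "empty")
})

test_that("a known phantom motion is recovered within 0.5 mm / 0.5 deg", {
  sp <- small_spec(seed = 32, bulge_amplitude = 0, shrink_amplitude = 0,
                   perturb_amplitude = 0,
                   rigid = euler_rigid(c(0, 0, 4), c(10, 5, -8),
                                       center = c(34.65, 34.65, 55.3)))
  cs <- generate_case(sp)
  tr <- cs$truth
  bones <- segment_bones(cs$t1)
  T <- register_rigid(cs$t1, cs$t2, bones,
                      init_translation(tr$landmark_t1, tr$landmark_t2))
  w <- which(bones$voxels == 1L)
  d <- dim(bones$voxels)
  co <- cbind((w - 1) %% d[1], ((w - 1) %/% d[1]) %% d[2],
              (w - 1) %/% (d[1] * d[2])) *
    matrix(cs$t1$spacing, length(w), 3, byrow = TRUE)
  tre <- max(sqrt(rowSums((transform_points(T, co) -
                           transform_points(tr$rigid, co))^2)))
  expect_lt(tre, 0.5)
  expect_lt(rotation_error_deg(T$rotation, tr$rigid$rotation), 0.5)
  # the returned metric never exceeds the metric at the initialization
  expect_lte(attr(T, "metric"), attr(T, "metric_init"))
})

test_that("straightening a straight tube is an axis-centred crop", {
  d <- c(41, 41, 60)
  vox <- array(40, d)
  d2 <- outer((1:41 - 21)^2, (1:41 - 21)^2, "+")
  for (k in 1:60) vox[, , k][d2 <= 64] <- 400
  v <- image_volume(vox, c(1, 1, 1))
  cl <- resample_centerline(centerline(cbind(20, 20, seq(5, 54, 2))), 1)
  s <- straighten(v, cl, in_plane_extent = 30, in_plane_spacing = 1)
  for (k in c(1, 10, 25, 48)) {
    expect_equal(s$voxels[, , k], vox[6:36, 6:36, 5 + k], tolerance = 1e-12)
  }
  # frames are orthonormal
  fr <- s$frames
  expect_lt(max(abs(rowSums(fr$u^2) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(fr$v^2) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(fr$u * fr$v))), 1e-9)
  expect_lt(max(abs(rowSums(fr$u * fr$tangent))), 1e-9)
  expect_lt(max(abs(rowSums(fr$v * fr$tangent))), 1e-9)
  # translation invariance: the reformation follows the centerline
  vox2 <- array(40, d)
  d2b <- outer((1:41 - 24)^2, (1:41 - 19)^2, "+")
  for (k in 1:60) vox2[, , k][d2b <= 64] <- 400
  cl2 <- resample_centerline(centerline(cbind(23, 18, seq(5, 54, 2))), 1)
  s2 <- straighten(image_volume(vox2, c(1, 1, 1)), cl2, 30, 1)
  expect_equal(s2$voxels, s$voxels, tolerance = 1e-12)
  # projection direction parallel to the tangent is rejected
  clx <- resample_centerline(centerline(cbind(seq(5, 30, 2), 20, 20)), 1)
  expect_error(straighten(v, clx, 20, 1, projection_direction = c(1, 0, 0)),
               "5 degrees")
})

test_that("a curved tube straightens to centred discs", {
  d3 <- c(80, 80, 80)
  vox <- array(40, d3)
  pts <- evarstrain:::.lattice_points(d3, c(1, 1, 1))
  rad <- sqrt(pts[, 1]^2 + pts[, 3]^2)
  vox[sqrt((rad - 40)^2 + (pts[, 2] - 40)^2) <= 7] <- 400
  v <- image_volume(array(vox, d3), c(1, 1, 1))
  th <- seq(0.12, pi / 2 - 0.12, length.out = 60)
  cl <- resample_centerline(centerline(cbind(40 * sin(th), 40,
                                             40 * cos(th))), 1)
  s <- straighten(v, cl, 30, 1, projection_direction = c(0, 1, 0))
  cent_err <- sapply(seq_len(dim(s$voxels)[3]), function(k) {
    w <- which(s$voxels[, , k] > 200, arr.ind = TRUE)
    if (nrow(w) == 0) return(NA)
    max(abs(colMeans(w) - 16))
  })
  expect_lt(max(cent_err, na.rm = TRUE), 1)
})

test_that("points map into straightened indices through the slice frames", {
  cl <- resample_centerline(centerline(cbind(20, 20, seq(0, 40, 2))), 1)
  v <- image_volume(array(0, c(41, 41, 50)), c(1, 1, 1))
  s <- straighten(v, cl, 30, 1)
  c0 <- (dim(s$voxels)[1] - 1) / 2
  # a centerline sample maps to the slice centre
  expect_equal(straighten_point(c(20, 20, 7), s), c(c0, c0, 7))
  # +3 mm along the first frame axis (u = +y here since tangent is +z,
  # proj +x gives u = x...) -- verify via the frame itself
  k <- 11
  p <- c(20, 20, k) + 3 * s$frames$u[k + 1, ]
  expect_equal(straighten_point(p, s), c(c0 + 3, c0, k))
  expect_error(straighten_point(c(20 + 100, 20, 7), s), "extent")
})

test_that("straightened alignment shifts by the landmark offset", {
  set.seed(5)
  arr <- array(rnorm(31 * 31 * 40), c(31, 31, 40))
  v <- image_volume(arr, c(1, 1, 1))
  cl <- resample_centerline(centerline(cbind(15, 15, seq(0, 39, 1))), 1)
  s <- straighten(v, cl, 30, 1)
  # identical landmarks: unchanged
  s0 <- align_straightened(s, s, c(15, 15, 10), c(15, 15, 10))
  expect_equal(s0$voxels, s$voxels)
  # 3-slice offset shifts content by 3 slices
  s3 <- align_straightened(s, s, c(15, 15, 13), c(15, 15, 10))
  expect_equal(s3$voxels[, , 4:40], s$voxels[, , 1:37])
  expect_equal(attr(s3, "offset"), c(0L, 0L, 3L))
  # spacing mismatch rejected
  s_bad <- straighten(v, cl, 30, 0.5)
  expect_error(align_straightened(s, s_bad, c(0, 0, 0), c(0, 0, 0)),
               "spacing")
})
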