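test_that("phantom generation is deterministic and honours the null case", {
  sp <- small_spec(seed = 5)
  a <- generate_case(sp)
  b <- generate_case(sp)
  expect_identical(a$t1$voxels, b$t1$voxels)
  expect_identical(a$t2$voxels, b$t2$voxels)
  # amplitude 0, identity rigid, zero noise: t2 equals t1 exactly
  sp0 <- small_spec(seed = 5, bulge_amplitude = 0, noise_sd = 0,
                    rigid = rigid_transform())
  c0 <- generate_case(sp0)
  expect_identical(c0$t1$voxels, c0$t2$voxels)
  expect_error(phantom_spec(lumen_radius = 20), "smaller")
  expect_error(phantom_spec(noise_sd = -1), ">= 0")
})

test_that("deforming and moving t1 reproduces t2 (self-consistency)", {
  for (lab in c("unfavorable", "favorable")) {
    cs <- generate_case(small_spec(seed = 8, label = lab, noise_sd = 0))
    tr <- cs$truth
    inv <- inverse_displacement_field(tr)
    pred <- resample(warp(cs$t1, inv, "linear"), cs$t1,
                     invert_transform(tr$rigid), "linear")
    ncc <- cor(as.numeric(pred$voxels), as.numeric(cs$t2$voxels))
    expect_gt(ncc, 0.98)
    # thrombus mask transport consistency
    m1t <- resample(warp(tr$masks_t1$thrombus, inv, "nearest"), cs$t1,
                    invert_transform(tr$rigid), "nearest")
    m2 <- tr$masks_t2$thrombus
    expect_gt(dice(m1t, m2), 0.95)
  }
})

test_that("thrombus volume grows for unfavorable and shrinks for favorable", {
  cu <- generate_case(small_spec(seed = 9, label = "unfavorable"))
  expect_gt(sum(cu$truth$masks_t2$thrombus$voxels),
            sum(cu$truth$masks_t1$thrombus$voxels))
  cf <- generate_case(small_spec(seed = 9, label = "favorable"))
  expect_lte(sum(cf$truth$masks_t2$thrombus$voxels),
             sum(cf$truth$masks_t1$thrombus$voxels))
})

test_that("affine fields carry their matrix exactly", {
  ref <- image_volume(array(0, c(12, 12, 12)), c(0.8, 0.8, 1))
  # identity -> zero field
  f0 <- analytic_affine_field(diag(3), ref)
  expect_equal(max(abs(f0$u)), 0)
  # diagonal stretch
  f1 <- analytic_affine_field(diag(c(1.1, 1, 1)), ref)
  pts <- cbind(rep(0.8 * (0:11), 144))
  expect_equal(as.numeric(f1$u[, , , 1]),
               rep(0.1 * 0.8 * (0:11), 144), tolerance = 1e-12)
  expect_equal(max(abs(f1$u[, , , 2:3])), 0)
  # rotation: |U(x)| = 2 sin(theta/2) * r_xy
  th <- 30 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  fr <- analytic_affine_field(Rz, ref)
  lat <- expand.grid(x = 0.8 * (0:11), y = 0.8 * (0:11), z = 0:11)
  un <- sqrt(fr$u[, , , 1]^2 + fr$u[, , , 2]^2 + fr$u[, , , 3]^2)
  expect_equal(as.numeric(un),
               2 * sin(th / 2) * sqrt(lat$x^2 + lat$y^2), tolerance = 1e-9)
})

test_that("the analytic bulge matches its closed-form Jacobian at order 2", {
  # zero amplitude: zero field and Jacobian
  ref <- image_volume(array(0, c(10, 10, 10)), c(1, 1, 1))
  b0 <- analytic_bulge_field(ref, 0, c(5, 5), 5, 4)
  expect_equal(max(abs(b0$field$u)), 0)
  expect_equal(max(abs(b0$jacobian(cbind(4, 5, 5)))), 0)
  # exact circumferential stretch 1 + a/r on the bulge equator
  bf <- analytic_bulge_field(ref, 3, c(5, 5), 5, 12, r_ramp = c(1, 4))
  J <- bf$jacobian(matrix(c(5 + 8, 5, 5), 1, 3))[1, , ]
  Fm <- J + diag(3)
  stretches <- sqrt(eigen(t(Fm) %*% Fm, symmetric = TRUE)$values)
  expect_equal(max(stretches), 1 + 3 / 8, tolerance = 1e-9)
  # central differences of the sampled field converge to the Jacobian at
  # order ~2 under grid halving
  errs <- sapply(c(1.2, 0.6, 0.3), function(h) {
    dd <- round(c(30, 30, 30) / h)
    refb <- image_volume(array(0, dd), rep(h, 3))
    bb <- analytic_bulge_field(refb, 3, c(15, 15), 15, 12, r_ramp = c(2, 8))
    dom <- binary_mask(array(1L, dd), rep(h, 3))
    gr <- displacement_gradient(bb$field, dom)
    idx <- which(gr$valid)
    pts <- cbind(h * ((idx - 1) %% dd[1]),
                 h * (((idx - 1) %/% dd[1]) %% dd[2]),
                 h * ((idx - 1) %/% (dd[1] * dd[2])))
    J <- bb$jacobian(pts)
    m <- 0
    for (a in 1:3) for (b in 1:3)
      m <- max(m, max(abs(gr$a[, , , a + 3 * (b - 1)][idx] - J[, a, b])))
    m
  })
  expect_lt(errs[3], 0.02)
  orders <- log2(errs[-3] / errs[-1])
  expect_gt(orders[2], 1.9)
})

test_that("cohort generation is labelled, jittered and deterministic", {
  coh <- generate_cohort(22, 9, small_spec(), seed = 42)
  expect_equal(sum(coh$labels == "unfavorable"), 9)
  expect_equal(sum(coh$labels == "favorable"), 13)
  coh2 <- generate_cohort(22, 9, small_spec(), seed = 42)
  expect_identical(coh$labels, coh2$labels)
  # materialized volumes are voxel-identical for the same seed
  i <- 3L
  expect_identical(generate_case(coh$specs[[i]])$t1$voxels,
                   generate_case(coh2$specs[[i]])$t1$voxels)
  # geometry jitter differs between cases
  expect_false(identical(coh$specs[[1]]$axis_xy, coh$specs[[2]]$axis_xy))
  expect_true(all(vapply(coh$specs, function(s)
    s$bulge_amplitude >= 3 && s$bulge_amplitude <= 6, logical(1))))
  coh0 <- generate_cohort(5, 0, small_spec(), seed = 1)
  expect_true(all(coh0$labels == "favorable"))
  expect_error(generate_cohort(5, 6, small_spec()), "between")
})
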