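test_that("skeletonization reduces a cylinder to its axis", {
  m <- cylinder_mask(radius = 5)
  sk <- skeletonize(m)
  w <- which(sk$voxels == 1L, arr.ind = TRUE)
  # within 1 voxel of the true axis at every z, full z coverage
  expect_lt(max(sqrt((w[, 1] - 20)^2 + (w[, 2] - 20)^2)), 1 + 1e-9)
  expect_equal(sort(unique(w[, 3])), 1:40)
  # single voxel is a fixed point
  sv <- array(0L, c(5, 5, 5))
  sv[3, 3, 3] <- 1L
  expect_identical(skeletonize(binary_mask(sv))$voxels, sv)
  expect_error(skeletonize(binary_mask(array(0L, c(5, 5, 5)))), "empty")
})

test_that("skeletonization preserves connected-component count", {
  m <- cylinder_mask()$voxels
  m[, , 18:22] <- 0L  # split into two components
  sk <- skeletonize(binary_mask(m, c(1, 1, 1)))
  cc_in <- evarstrain:::connected_components_cpp(m, dim(m))
  cc_out <- evarstrain:::connected_components_cpp(sk$voxels, dim(m))
  expect_equal(length(cc_out$sizes), length(cc_in$sizes))
})

test_that("a Y-shaped tube yields three branches and one junction", {
  msk <- y_tube_mask()
  sk <- skeletonize(msk)
  g <- evarstrain:::.skel_graph(sk)
  expect_equal(sum(g$deg <= 1L), 3L)
  br <- prune_to_main_branches(sk, 3, mask = msk)
  expect_length(br, 3L)
  expect_false(isTRUE(attr(br, "flagged")))
  lens <- sort(sapply(br, path_length), decreasing = TRUE)
  expect_gt(lens[1], 45)           # trunk spans ~50 mm
  expect_gt(min(lens), 25)         # both limbs ~30 mm
  # the three paths share one junction point
  ends <- do.call(rbind, lapply(br, function(p) rbind(p[1, ], p[nrow(p), ])))
  expect_true(any(duplicated(round(ends, 6))))
  # straight tube: one branch, flagged
  tube <- cylinder_mask()
  expect_warning(b1 <- prune_to_main_branches(skeletonize(tube), 3), "only")
  expect_length(b1, 1L)
  expect_true(attr(b1, "flagged"))
})

test_that("short spurs are never selected as the third branch", {
  msk <- y_tube_mask()
  vox <- msk$voxels
  vox[31:33, 30, 60] <- 1L  # 3 mm spur off the trunk
  sk <- skeletonize(binary_mask(vox, c(1, 1, 1)))
  br <- prune_to_main_branches(sk, 3)
  expect_length(br, 3L)
  # no returned branch is the 3 mm spur
  expect_true(all(sapply(br, path_length) > 5))
})

test_that("bifurcation merging takes limb midpoints at arc fractions", {
  # symmetric Y: merged path continues the trunk axis
  z <- seq(0, 30, by = 1)
  trunk <- cbind(0, 0, seq(30, 60, by = 1))
  limb1 <- cbind(-0.5 * (30 - z), 0, z)[31:1, ]
  limb2 <- cbind(0.5 * (30 - z), 0, z)[31:1, ]
  cl <- merge_bifurcation(list(trunk, limb1, limb2))
  expect_lt(max(abs(cl$points[, 1])), 1e-9)
  expect_lt(max(abs(cl$points[, 2])), 1e-9)
  # continuity at the junction
  seg <- sqrt(rowSums(diff(cl$points)^2))
  expect_lt(max(seg), 2 * stats::median(seg) + 1e-9)
  # asymmetric Y: merged x = (a - b)/2 per level
  limb3 <- cbind(-0.2 * (30 - z), 0, z)[31:1, ]
  cl2 <- merge_bifurcation(list(trunk, limb2, limb3))
  zq <- cl2$points[, 3]
  below <- cl2$points[zq < 29.5, ]
  expect_equal(below[, 1], (0.5 - 0.2) / 2 * (30 - below[, 3]),
               tolerance = 1e-6)
  # limbs with disjoint axial extents are rejected
  limb_far <- cbind(0.5 * z, 0, z + 200)
  expect_error(merge_bifurcation(list(trunk, limb1, limb_far)), "disjoint")
})

test_that("equidistant resampling hits the spec point counts", {
  # straight 10 mm segment at 1 mm -> 11 points
  cl <- centerline(cbind(0, 0, c(0, 10)))
  rs <- resample_centerline(cl, 1)
  expect_equal(nrow(rs$points), 11L)
  expect_equal(rs$points[, 3], 0:10, tolerance = 1e-12)
  # semicircle radius 10: chord lengths all within [0.99, 1] mm
  th <- seq(0, pi, length.out = 400)
  semi <- centerline(cbind(10 * cos(th), 10 * sin(th), 0))
  rsemi <- resample_centerline(semi, 1)
  ch <- sqrt(rowSums(diff(rsemi$points)^2))
  expect_true(all(ch[-length(ch)] >= 0.99 & ch[-length(ch)] <= 1 + 1e-9))
  # idempotence
  r2 <- resample_centerline(rsemi, 1)
  expect_equal(r2$points, rsemi$points, tolerance = 1e-9)
  # count invariant: floor(L/delta) + 1 (+1 for a partial end step)
  L <- path_length(rsemi$points)
  expect_true(nrow(rsemi$points) %in% (floor(L / 1) + 1:2))
  expect_error(resample_centerline(cl, 0), "> 0")
})

test_that("centerline smoothing removes jag without shifting the course", {
  set.seed(7)
  z <- seq(0, 60, by = 1)
  jag <- cbind(5 + rnorm(61, 0, 0.4), 5 + rnorm(61, 0, 0.4), z)
  sm <- smooth_centerline(centerline(jag, sampling_distance = 1), 3)
  expect_lt(path_length(sm$points), path_length(jag))
  mid <- sm$points[10:50, ]
  expect_lt(max(abs(mid[, 1] - 5)), 0.6)
})

test_that("phantom centerline matches ground truth", {
  cs <- generate_case(small_spec(seed = 23))
  tr <- cs$truth
  lum <- fill_holes(segment_lumen(cs$t1,
                                  world_to_index(cs$t1, tr$landmark_t1)))
  br <- prune_to_main_branches(skeletonize(lum), 3, mask = lum)
  expect_length(br, 3L)
  cl <- orient_centerline(merge_bifurcation(br), tr$landmark_t1)
  rcl <- resample_centerline(smooth_centerline(
    resample_centerline(cl, 1), 5), 1)
  # lateral deviation from the true (straight) axis
  ax <- tr$spec$axis_xy
  dev <- sqrt((rcl$points[, 1] - ax[1])^2 + (rcl$points[, 2] - ax[2])^2)
  expect_lt(mean(dev), 1.5)
  # total length within 5% of ground truth
  expect_lt(abs(path_length(rcl$points) - path_length(tr$centerline_t1)) /
              path_length(tr$centerline_t1), 0.05)
  # branch endpoints reach near the ground-truth branch ends
  gt_ends <- rbind(tr$branches_t1$trunk[nrow(tr$branches_t1$trunk), ],
                   tr$branches_t1$left[1, ], tr$branches_t1$right[1, ])
  got_ends <- t(sapply(br, function(p) p[nrow(p), ]))
  for (i in 1:3) {
    dmin <- min(sqrt(rowSums((got_ends -
      matrix(gt_ends[i, ], 3, 3, byrow = TRUE))^2)))
    expect_lt(dmin, 5)
  }
})
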