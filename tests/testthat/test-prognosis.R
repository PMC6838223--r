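test_that("orientation PCA handles rank-1, isotropic and planar sets", {
  # mixed-sign x-axis vectors: rank one, eigenvalues (1, 0, 0)
  V <- rbind(c(1, 0, 0), c(-1, 0, 0), c(1, 0, 0), c(-1, 0, 0))
  pc <- orientation_pca(V)
  expect_equal(pc$eigenvalues, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(abs(pc$axes[, 1]), c(1, 0, 0), tolerance = 1e-12)
  expect_gte(pc$axes[1, 1], 0)  # sign canonicalization
  # uniform sphere: eigenvalues near 1/3 each
  set.seed(14)
  U <- matrix(rnorm(30000), ncol = 3)
  U <- U / sqrt(rowSums(U^2))
  pcu <- orientation_pca(U)
  expect_lt(max(abs(pcu$eigenvalues - 1 / 3)), 0.02)
  # vectors confined to the xy-plane: third axis is +-z, eigenvalue ~0
  th <- seq(0, 2 * pi, length.out = 721)[-1]
  P <- cbind(cos(th), sin(th), 0)
  pcp <- orientation_pca(P)
  expect_lt(pcp$eigenvalues[3], 1e-12)
  expect_equal(abs(pcp$axes[, 3]), c(0, 0, 1), tolerance = 1e-9)
  # eigenvalues are a partition of unity
  expect_equal(sum(pcu$eigenvalues), 1, tolerance = 1e-9)
  expect_error(orientation_pca(U[1:2, ]), "3")
})

test_that("features have the documented dimensions and sign invariance", {
  set.seed(15)
  fake_sf <- function(nv, tilt = c(1, 0, 0)) {
    V <- matrix(rnorm(nv * 3), ncol = 3) + matrix(tilt, nv, 3, byrow = TRUE)
    V <- V / sqrt(rowSums(V^2))
    structure(list(vectors = cbind(V, matrix(0, nv, 3), V[, 3:1]),
                   tensile = rep(TRUE, nv), compressive = rep(TRUE, nv)),
              class = "strain_field")
  }
  sfs <- list(fake_sf(50), fake_sf(60, c(0, 1, 0)), fake_sf(40, c(0, 0, 1)),
              fake_sf(55))
  labs <- c("favorable", "unfavorable", "favorable", "unfavorable")
  fb <- build_features(sfs, labs, "both")
  expect_equal(ncol(fb$features), 18L)
  expect_equal(nrow(fb$features), 4L)
  ft <- build_features(sfs, labs, "tensile")
  expect_equal(ncol(ft$features), 9L)
  fc <- build_features(sfs, labs, "compressive")
  expect_equal(ncol(fc$features), 9L)
  # flipping every unit vector's sign changes no feature
  sfs_flip <- sfs
  sfs_flip[[1]]$vectors <- -sfs_flip[[1]]$vectors
  ff <- build_features(sfs_flip, labs, "both")
  expect_equal(ff$features, fb$features, tolerance = 1e-12)
  # a case with too few vectors is excluded with a warning
  sfs2 <- sfs
  sfs2[[2]]$tensile <- c(TRUE, rep(FALSE, 59))
  expect_warning(fe <- build_features(sfs2, labs, "tensile"), "excluded")
  expect_equal(nrow(fe$features), 3L)
  expect_equal(fe$excluded, 2L)
})

test_that("cross-validation separates separable data and not noise", {
  set.seed(16)
  # perfectly separated classes
  n <- 24
  y <- rep(c("favorable", "unfavorable"), each = n / 2)
  X <- matrix(rnorm(n * 4), n, 4)
  X[y == "unfavorable", 1] <- X[y == "unfavorable", 1] + 20
  r <- evaluate_cv(X, y, folds = 4, runs = 10, seed = 1)
  expect_equal(r$mean_auc, 1.0)
  expect_equal(dim(r$fold_auc), c(10L, 4L))
  # label-independent noise concentrates at AUC 0.5
  n2 <- 200
  y2 <- rep(c("favorable", "unfavorable"), each = n2 / 2)
  X2 <- matrix(rnorm(n2 * 6), n2, 6)
  r2 <- evaluate_cv(X2, y2, folds = 4, runs = 10, seed = 2)
  expect_lt(abs(r2$mean_auc - 0.5), 0.1)
  # reproducible given the seed
  r3 <- evaluate_cv(X2, y2, folds = 4, runs = 10, seed = 2)
  expect_identical(r2$fold_auc, r3$fold_auc)
  expect_identical(r2$mean_tpr, r3$mean_tpr)
  # degenerate inputs rejected
  expect_error(evaluate_cv(X2, rep("favorable", n2)), "classes")
  expect_error(evaluate_cv(X[1:6, ], y[c(1:3, 13:15)], folds = 4), "at least")
})

test_that("maximum diameter is the worst axial Feret caliper", {
  # digital sphere radius 15 mm
  d <- c(40, 40, 40)
  pts <- evarstrain:::.lattice_points(d, c(1, 1, 1))
  sph <- binary_mask(array(as.integer(rowSums((pts - 19.5)^2) <= 15^2), d),
                     c(1, 1, 1))
  expect_lt(abs(max_diameter(sph) - 30), sqrt(2) + 1e-9)
  # axis-aligned box 20 x 40 mm in-plane: Feret = diagonal
  box <- array(0L, c(60, 60, 12))
  box[11:30, 11:50, 3:10] <- 1L
  bm <- binary_mask(box, c(1, 1, 1))
  expect_lt(abs(max_diameter(bm) - sqrt(19^2 + 39^2)), 2)
  # single voxel: 0 by definition
  sv <- array(0L, c(5, 5, 5))
  sv[3, 3, 3] <- 1L
  expect_equal(max_diameter(binary_mask(sv)), 0)
  expect_error(max_diameter(binary_mask(array(0L, c(4, 4, 4)))), "empty")
  # identical masks: zero difference
  expect_equal(diameter_difference(sph, sph), 0)
})

test_that("phantom diameter change follows the label", {
  cu <- generate_case(small_spec(seed = 24, label = "unfavorable",
                                 bulge_amplitude = 6))
  dd_u <- diameter_difference(cu$truth$masks_t1$thrombus,
                              cu$truth$masks_t2$thrombus)
  expect_gt(dd_u, 5)  # exceeds the clinically relevant 5 mm threshold
  cf <- generate_case(small_spec(seed = 24, label = "favorable"))
  dd_f <- diameter_difference(cf$truth$masks_t1$thrombus,
                              cf$truth$masks_t2$thrombus)
  expect_lt(dd_f, 0)
})
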