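# Strain-math oracles: on affine displacement fields central differences are
# exact, so every quantity must match its closed form to near machine
# precision.

ref12 <- image_volume(array(0, c(12, 12, 12)), c(0.8, 0.8, 1))
dom12 <- binary_mask(array(1L, c(12, 12, 12)), c(0.8, 0.8, 1))

strain_of_affine <- function(A) {
  f <- analytic_affine_field(A, ref12)
  gr <- displacement_gradient(f, dom12)
  Fm <- deformation_tensor(gr)
  C <- right_cauchy_green(Fm)
  list(gr = gr, Fm = Fm, C = C, sf = principal_strain_fields(C))
}

test_that("affine fields reproduce F, C and stretches to 1e-10", {
  A <- matrix(c(1.1, 0.02, 0, 0.01, 0.95, 0.03, 0, -0.02, 1.05), 3, 3)
  s <- strain_of_affine(A)
  idx <- which(s$Fm$valid)
  for (a in 1:3) for (b in 1:3)
    expect_lt(max(abs(s$Fm$a[, , , a + 3 * (b - 1)][idx] - A[a, b])), 1e-10)
  CA <- t(A) %*% A
  ev <- eigen(CA, symmetric = TRUE)$values
  expect_lt(max(abs(t(s$sf$lambda) - ev)), 1e-10)
  # zero field: F = I, no tensile or compressive presence
  s0 <- strain_of_affine(diag(3))
  expect_equal(sum(s0$sf$tensile), 0L)
  expect_equal(sum(s0$sf$compressive), 0L)
  # diagonal gradient: F = diag(1.1, .95, 1.05) entries exactly
  expect_equal(s$sf$tensile_mag[1], sqrt(max(ev)) - 1, tolerance = 1e-10)
})

test_that("pure rotations produce no strain", {
  th <- 30 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  s <- strain_of_affine(Rz)
  idx <- which(s$C$valid)
  iv <- c(1, 0, 0, 1, 0, 1)
  for (cch in 1:6)
    expect_lt(max(abs(s$C$a6[, , , cch][idx] - iv[cch])), 1e-10)
  expect_equal(sum(s$sf$tensile), 0L)
  expect_equal(sum(s$sf$compressive), 0L)
})

test_that("rotation invariance: C is unchanged by F -> R F", {
  set.seed(11)
  A <- diag(3) + matrix(rnorm(9, 0, 0.05), 3, 3)
  th <- 47 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  s1 <- strain_of_affine(A)
  s2 <- strain_of_affine(Rz %*% A)
  expect_lt(max(abs(s1$sf$lambda - s2$sf$lambda)), 1e-10)
  expect_lt(max(abs(s1$sf$tensile_mag - s2$sf$tensile_mag)), 1e-10)
  expect_lt(max(abs(s1$sf$compressive_mag - s2$sf$compressive_mag)), 1e-10)
})

test_that("hand eigendecomposition case and eigen-structure invariants", {
  eg <- evarstrain:::eig_sym3_cpp(matrix(c(1.21, 0, 0, 1, 0, 0.81), 1, 6))
  expect_equal(as.numeric(eg$values), c(1.21, 1, 0.81))
  expect_equal(as.numeric(eg$vectors[1, 1:3]), c(1, 0, 0))
  expect_equal(as.numeric(eg$vectors[1, 7:9]), c(0, 0, 1))
  # random symmetric PSD tensors: ordering, orthonormality, sign rule
  set.seed(12)
  C6 <- t(replicate(200, {
    B <- matrix(rnorm(9), 3, 3)
    S <- crossprod(B)
    c(S[1, 1], S[2, 1], S[3, 1], S[2, 2], S[3, 2], S[3, 3])
  }))
  eg <- evarstrain:::eig_sym3_cpp(C6)
  expect_true(all(diff(t(eg$values)) <= 1e-12))
  for (q in sample(200, 20)) {
    V <- matrix(eg$vectors[q, ], 3, 3)
    expect_lt(max(abs(crossprod(V) - diag(3))), 1e-9)
    for (cc in 1:3) {
      v <- V[, cc]
      expect_gte(v[which.max(abs(v))], 0)
    }
  }
})

test_that("green_lagrange is the spectral map (lambda - 1)/2", {
  A <- diag(c(1.1, 1, 1))
  f <- analytic_affine_field(A, ref12)
  C <- right_cauchy_green(deformation_tensor(displacement_gradient(f, dom12)))
  E <- green_lagrange(C)
  idx <- which(E$valid)[1]
  expect_equal(E$a6[, , , 1][idx], (1.21 - 1) / 2, tolerance = 1e-12)
  expect_equal(E$a6[, , , 4][idx], 0, tolerance = 1e-12)
  # eigenvalues of E equal (lambda_i - 1)/2 for random PSD C
  set.seed(13)
  for (i in 1:20) {
    B <- diag(3) + matrix(rnorm(9, 0, 0.1), 3, 3)
    S <- crossprod(B)
    lam <- eigen(S, symmetric = TRUE)$values
    lamE <- eigen((S - diag(3)) / 2, symmetric = TRUE)$values
    expect_equal(lamE, (lam - 1) / 2, tolerance = 1e-12)
  }
})

test_that("strain summaries count uniform expansion and contraction", {
  s_exp <- strain_of_affine(1.1 * diag(3))
  sm <- strain_summary(s_exp$sf)
  expect_equal(sm$mean_tensile_mag, 0.1, tolerance = 1e-10)
  expect_equal(sm$n_compressive, 0L)
  expect_equal(sm$n_triaxial_tensed, sm$n_valid)
  s_con <- strain_of_affine(0.9 * diag(3))
  sm2 <- strain_summary(s_con$sf)
  expect_equal(sm2$mean_compressive_mag, 0.1, tolerance = 1e-10)
  expect_equal(sm2$n_tensile, 0L)
})

test_that("folded voxels (det F <= 0) are excluded with a warning", {
  A <- diag(c(-0.5, 1, 1))  # reflection: det F < 0
  f <- analytic_affine_field(A, ref12)
  gr <- displacement_gradient(f, dom12)
  C <- right_cauchy_green(deformation_tensor(gr))
  expect_warning(sf <- principal_strain_fields(C), "folding")
  expect_equal(length(sf$idx), 0L)
  expect_gt(sf$n_folded, 0L)
})

test_that("bulge strain orientations are tangential-tensile, radial-compressive", {
  # analytic kinematic bulge: at the equator wall the tensile unit vectors
  # align with the circumferential direction and the compressive ones with
  # the radial direction
  h <- 0.8
  dd <- c(50, 50, 50)
  ref <- image_volume(array(0, dd), rep(h, 3))
  bf <- analytic_bulge_field(ref, 4, c(20, 20), 20, 15, r_ramp = c(4, 10))
  dom <- binary_mask(array(1L, dd), rep(h, 3))
  gr <- displacement_gradient(bf$field, dom)
  sf <- principal_strain_fields(right_cauchy_green(deformation_tensor(gr)))
  pts <- evarstrain:::.lattice_points(dd, rep(h, 3))
  dx <- pts[, 1] - 20
  dy <- pts[, 2] - 20
  rr <- sqrt(dx^2 + dy^2)
  wall <- rr > 11 & rr < 16 & abs(pts[, 3] - 20) < 5  # equator wall band
  rhat <- cbind(dx / pmax(rr, 1e-9), dy / pmax(rr, 1e-9), 0)
  that <- cbind(-rhat[, 2], rhat[, 1], 0)
  sel_t <- sf$tensile & wall[sf$idx]
  TU <- sf$vectors[sel_t, 1:3, drop = FALSE]
  RH <- rhat[sf$idx[sel_t], ]
  TH <- that[sf$idx[sel_t], ]
  expect_gt(mean(abs(rowSums(TU * TH))), mean(abs(rowSums(TU * RH))))
  sel_c <- sf$compressive & wall[sf$idx]
  CU <- sf$vectors[sel_c, 7:9, drop = FALSE]
  RHc <- rhat[sf$idx[sel_c], ]
  THc <- that[sf$idx[sel_c], ]
  expect_gt(mean(abs(rowSums(CU * RHc))), mean(abs(rowSums(CU * THc))))
})
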