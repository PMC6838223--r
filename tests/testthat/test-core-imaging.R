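test_that("containers validate their invariants", {
  expect_error(image_volume(array(1, c(1, 5, 5))), "at least 2")
  expect_error(image_volume(array(1, c(4, 4, 4)), spacing = c(0, 1, 1)),
               "spacing")
  expect_error(image_volume(array(c(NA, rep(1, 63)), c(4, 4, 4))), "finite")
  expect_error(binary_mask(array(2L, c(4, 4, 4))), "0 or 1")
  expect_error(vector_field(array(0, c(4, 4, 4, 2))), "dimension 3")
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  # rotations compose and invert exactly
  a <- euler_rigid(c(3, -2, 5), c(1, 2, 3))
  b <- euler_rigid(c(-1, 4, 0), c(-2, 0, 7))
  pt <- c(10, -5, 3)
  expect_equal(transform_points(compose_transform(a, b), pt),
               transform_points(a, transform_points(b, pt)),
               tolerance = 1e-12)
  expect_equal(transform_points(compose_transform(a, invert_transform(a)),
                                pt), pt, tolerance = 1e-10)
})

test_that("index/world mapping follows origin + spacing * index", {
  v <- image_volume(array(0, c(8, 8, 8)), c(0.8, 1, 1), c(10, 0, -5))
  expect_equal(index_to_world(v, c(0, 0, 0)), c(10, 0, -5))
  expect_equal(index_to_world(v, c(2, 0, 0)), c(11.6, 0, -5))
  expect_error(index_to_world(v, c(8, 0, 0)), "bounds")
  set.seed(1)
  idx <- cbind(sample(0:7, 100, TRUE), sample(0:7, 100, TRUE),
               sample(0:7, 100, TRUE))
  expect_equal(world_to_index(v, index_to_world(v, idx)), idx * 1.0)
})

test_that("volume I/O round-trips intensities and geometry", {
  set.seed(2)
  v <- image_volume(array(rnorm(16^3), c(16, 16, 16)), c(0.8, 0.8, 1.0),
                    c(10, 0, -5))
  for (ext in c(".nii.gz", ".nii", ".mha", ".mhd")) {
    tf <- tempfile(fileext = ext)
    write_volume(v, tf)
    v2 <- read_volume(tf)
    expect_equal(v2$voxels, v$voxels, tolerance = 0, info = ext)
    expect_equal(v2$spacing, v$spacing, tolerance = 1e-6, info = ext)
    expect_equal(v2$origin, v$origin, tolerance = 1e-4, info = ext)
  }
  # constant volume exact roundtrip
  cv <- image_volume(array(7, c(8, 8, 8)))
  tf <- tempfile(fileext = ".nii.gz")
  write_volume(cv, tf)
  expect_identical(read_volume(tf)$voxels, cv$voxels)
  # masks as unsigned 8-bit keep their value set
  m <- binary_mask(array(as.integer(runif(8^3) > 0.5), c(8, 8, 8)))
  tm <- tempfile(fileext = ".mha")
  write_volume(m, tm)
  expect_true(all(read_volume(tm)$voxels %in% c(0, 1)))
})

test_that("I/O failures raise errors naming the problem", {
  expect_error(read_volume("/nonexistent/vol.nii"), "exist")
  expect_error(read_volume(tempfile(fileext = ".xyz")), "unsupported|exist")
  # truncated MetaImage
  v <- image_volume(array(1.0, c(8, 8, 8)))
  tf <- tempfile(fileext = ".mha")
  write_volume(v, tf)
  raw <- readBin(tf, "raw", file.info(tf)$size)
  writeBin(raw[1:(length(raw) - 100)], tf)
  expect_error(read_volume(tf), "truncated")
  expect_error(write_volume(v, "/nonexistent/dir/out.nii"), "exist")
})

test_that("resample reproduces exact-lattice transforms", {
  set.seed(3)
  v <- image_volume(array(rnorm(16^3), c(16, 16, 16)), c(0.8, 0.8, 1.0),
                    c(10, 0, -5))
  # identity
  r <- resample(v, v, rigid_transform(), "linear")
  expect_lt(max(abs(r$voxels - v$voxels)), 1e-12)
  # one-voxel translation along x: index shift with boundary fill
  r2 <- resample(v, v, rigid_transform(diag(3), c(0.8, 0, 0)), "linear")
  expect_lt(max(abs(r2$voxels[1:15, , ] - v$voxels[2:16, , ])), 1e-12)
  expect_equal(unique(as.numeric(r2$voxels[16, , ])), min(v$voxels))
  # nearest resampling of a mask keeps the value set
  m <- binary_mask(array(as.integer(v$voxels > 0), dim(v$voxels)),
                   v$spacing, v$origin)
  rm_ <- resample(m, v, euler_rigid(c(2, 1, -3), c(1.3, -0.7, 2)), "nearest")
  expect_true(all(rm_$voxels %in% c(0L, 1L)))
})

test_that("resample by T then T^-1 recovers a smooth volume's interior", {
  v <- gauss_blob_volume(width2 = 120)
  tr <- euler_rigid(c(4, -3, 2), c(2.5, -1.5, 3), center = c(15, 15, 15))
  fwd <- resample(v, v, tr, "linear")
  bwd <- resample(fwd, v, invert_transform(tr), "linear")
  core <- 8:23
  rng <- diff(range(v$voxels))
  err <- max(abs(bwd$voxels[core, core, core] - v$voxels[core, core, core]))
  expect_lt(err, 0.02 * rng)
})

test_that("warp agrees with resample for constant fields and moves centroids", {
  set.seed(4)
  v <- gauss_blob_volume()
  d <- dim(v$voxels)
  # zero field is the identity
  z <- vector_field(array(0, c(d, 3)), v$spacing)
  expect_identical(warp(v, z, "linear")$voxels, v$voxels)
  expect_error(warp(v, vector_field(array(0, c(4, 4, 4, 3)))), "lattice")
  # constant one-voxel field equals the translation resample
  f <- vector_field(array(rep(c(1, 0, 0), each = prod(d)), c(d, 3)),
                    v$spacing)
  w <- warp(v, f, "linear")
  r <- resample(v, v, rigid_transform(diag(3), c(1, 0, 0)), "linear")
  expect_lt(max(abs(w$voxels - r$voxels)), 1e-12)
  # centroid of a smooth blob moves by the constant (pull-back: -delta)
  delta <- c(2, -1, 1.5)
  fc <- vector_field(array(rep(delta, each = prod(d)), c(d, 3)), v$spacing)
  wc <- warp(v, fc, "linear")
  centroid <- function(x) {
    w8 <- x$voxels - min(x$voxels)
    idx <- which(w8 > 0.05 * max(w8), arr.ind = TRUE)
    colSums(idx * w8[w8 > 0.05 * max(w8)]) / sum(w8[w8 > 0.05 * max(w8)])
  }
  shift <- centroid(wc) - centroid(v)
  expect_lt(max(abs(shift + delta)), 0.1)
})
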