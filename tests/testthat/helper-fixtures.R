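# Shared fixtures: reduced-lattice phantom (same physical geometry, coarser
# voxels) and small geometric objects used across test files.

small_spec <- function(...) {
  phantom_spec(shape = c(64, 64, 80), spacing = c(1.1, 1.1, 1.4), ...)
}

small_params <- function(...) {
  pipeline_params(cpr = list(in_plane_extent = 64, in_plane_spacing = 1.1,
                             delta = 1, projection = c(1, 0, 0),
                             smooth_sigma = 5), ...)
}

# solid cylinder mask along z
cylinder_mask <- function(dim = c(40, 40, 40), center = c(20, 20),
                          radius = 5, spacing = c(1, 1, 1)) {
  m <- array(0L, dim)
  d2 <- outer((seq_len(dim[1]) - center[1])^2,
              (seq_len(dim[2]) - center[2])^2, "+")
  for (k in seq_len(dim[3])) m[, , k][d2 <= radius^2] <- 1L
  binary_mask(m, spacing)
}

# Y-shaped tube: trunk along z for z >= split, two limbs spreading below
y_tube_mask <- function(dim = c(60, 60, 80), cx = 30, split = 30,
                        r_trunk = 5, r_limb = 4, slope = 0.45) {
  m <- array(0L, dim)
  for (k in seq_len(dim[3])) {
    z <- k - 1
    sl <- m[, , k]
    if (z >= split) {
      sl[outer((seq_len(dim[1]) - cx)^2, (seq_len(dim[2]) - cx)^2,
               "+") <= r_trunk^2] <- 1L
    } else {
      s <- (split - z) * slope
      sl[outer((seq_len(dim[1]) - (cx - s))^2,
               (seq_len(dim[2]) - cx)^2, "+") <= r_limb^2] <- 1L
      sl[outer((seq_len(dim[1]) - (cx + s))^2,
               (seq_len(dim[2]) - cx)^2, "+") <= r_limb^2] <- 1L
    }
    m[, , k] <- sl
  }
  binary_mask(m, c(1, 1, 1))
}

gauss_blob_volume <- function(dim = c(30, 30, 30), center = c(15, 15, 15),
                              width2 = 50, base = 40, amp = 100) {
  pts <- expand.grid(x = seq_len(dim[1]) - 1, y = seq_len(dim[2]) - 1,
                     z = seq_len(dim[3]) - 1)
  d2 <- (pts$x - center[1])^2 + (pts$y - center[2])^2 + (pts$z - center[3])^2
  image_volume(array(base + amp * exp(-d2 / width2), dim), c(1, 1, 1))
}

rotation_error_deg <- function(R1, R2) {
  co <- (sum(diag(t(R1) %*% R2)) - 1) / 2
  acos(max(-1, min(1, co))) * 180 / pi
}
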