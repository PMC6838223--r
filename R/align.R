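# Timepoint alignment: landmark-initialized rigid registration of bone
# anatomy, straightened curved planar reformation (CPR) along the merged
# centerline, and translation alignment of straightened volumes via the
# straightened renal landmark.

#' Landmark-based translation initialization
#'
#' Identity rotation with translation `landmark_moving - landmark_fixed`,
#' mapping fixed-space points toward moving space for resampling.
#'
#' @param landmark_fixed,landmark_moving length-3 world points (mm), e.g. the
#'   lowest renal artery position in each scan.
#' @return A [rigid_transform()].
#' @export
init_translation <- function(landmark_fixed, landmark_moving) {
  if (any(!is.finite(landmark_fixed)) || any(!is.finite(landmark_moving)))
    stop("landmarks must be finite")
  rigid_transform(diag(3), as.numeric(landmark_moving) -
                    as.numeric(landmark_fixed))
}

# Euler angles (deg, R = Rz Ry Rx) of a rotation matrix
.euler_of <- function(R) {
  ry <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-8) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  c(rx, ry, rz) * 180 / pi
}

# regular-step gradient descent on the 6 rigid parameters (deg, mm) with
# rotation parameters scaled by the mask's lever arm
.rigid_gd <- function(metric, p0, lever, max_iter, step0 = 2, min_step = 5e-3) {
  # optimize in mm-equivalent coordinates: one unit of a scaled rotation
  # parameter moves a mask voxel by about one mm
  scale <- c(rep(pi / 180 * lever, 3), rep(1, 3))
  to_p <- function(q) q / scale
  q <- p0 * scale
  f <- function(q) metric(to_p(q))
  fq <- f(q)
  lambda <- step0
  h <- 0.05
  for (it in seq_len(max_iter)) {
    g <- vapply(1:6, function(d) {
      e <- numeric(6); e[d] <- h
      (f(q + e) - f(q - e)) / (2 * h)
    }, numeric(1))
    gn <- sqrt(sum(g^2))
    if (gn < 1e-14) break
    dirn <- -g / gn
    repeat {
      cand <- q + lambda * dirn
      fc <- f(cand)
      if (fc < fq) {
        q <- cand
        fq <- fc
        break
      }
      lambda <- lambda / 2
      if (lambda < min_step) break
    }
    if (lambda < min_step) break
  }
  list(p = to_p(q), value = fq)
}

#' Rigid registration of bone anatomy
#'
#' Finds the 6-degree-of-freedom transform minimizing the mean squared
#' intensity difference evaluated over the fixed bone mask (dilated by 2
#' voxels), optimized by regular-step gradient descent from `init` with a
#' 2-level multi-resolution schedule (subsampled, then dense metric
#' sampling). The returned transform maps fixed world points into moving
#' space; its metric never exceeds the metric at `init`.
#'
#' @param fixed,moving [image_volume()]s.
#' @param bone_fixed non-empty [binary_mask()] of the fixed scan's bones.
#' @param init [rigid_transform()] initialization (e.g.
#'   [init_translation()]).
#' @param max_iter iterations per resolution level.
#' @return A [rigid_transform()] with attributes `metric` (final MSD),
#'   `metric_init` and `flagged` (TRUE when optimization failed to improve
#'   and `init` was returned).
#' @export
register_rigid <- function(fixed, moving, bone_fixed, init = rigid_transform(),
                           max_iter = 60) {
  if (sum(bone_fixed$voxels) == 0L) stop("bone mask is empty")
  d <- dim(fixed$voxels)
  dil <- dilate_cpp(bone_fixed$voxels, d, 2L)
  lin <- which(dil == 1L)
  coord0 <- cbind((lin - 1) %% d[1],
                  ((lin - 1) %/% d[1]) %% d[2],
                  (lin - 1) %/% (d[1] * d[2]))
  coords <- coord0 * matrix(fixed$spacing, length(lin), 3, byrow = TRUE) +
    matrix(fixed$origin, length(lin), 3, byrow = TRUE)
  fvals <- as.numeric(fixed$voxels)[lin]
  ctr <- fixed$origin + (d - 1) * fixed$spacing / 2
  lever <- mean(sqrt(rowSums((coords - matrix(ctr, length(lin), 3,
                                              byrow = TRUE))^2)))
  bg <- min(moving$voxels)
  mdim <- dim(moving$voxels)
  # per-level Gaussian smoothing of both images: without it the trilinear
  # interpolation of sharp bone edges biases the MSD optimum off the truth
  smooth_lvl <- function(vol, sg)
    as.numeric(gaussian_smooth3_cpp(vol$voxels, dim(vol$voxels), rep(sg, 3)))
  lvl <- list(list(sigma = 2, sub = 8L, step0 = 2, min_step = 5e-3),
              list(sigma = 1, sub = 2L, step0 = 0.25, min_step = 1e-3))
  make_T <- function(p) {
    # p: rx, ry, rz (deg), tx, ty, tz (mm); rotation about the volume centre
    euler_rigid(p[1:3], p[4:6], ctr)
  }
  metric_with <- function(fv, mv, sub) {
    idx <- seq(1, length(fv), by = sub)
    fvi <- fv[idx]
    coi <- coords[idx, , drop = FALSE]
    function(p) {
      tr <- make_T(p)
      msd_rigid_cpp(fvi, coi, mv, mdim, moving$spacing, moving$origin,
                    tr$rotation, tr$translation, bg)
    }
  }
  p0 <- c(.euler_of(init$rotation),
          as.numeric(init$rotation %*% ctr) + init$translation - ctr)
  res <- list(p = p0)
  for (lv in lvl) {
    fv <- smooth_lvl(fixed, lv$sigma)[lin]
    mv <- smooth_lvl(moving, lv$sigma)
    res <- .rigid_gd(metric_with(fv, mv, lv$sub), res$p, lever, max_iter,
                     step0 = lv$step0, min_step = lv$min_step)
  }
  m_full <- metric_with(fvals, as.numeric(moving$voxels), 1L)
  m_init <- m_full(p0)
  m_fin <- m_full(res$p)
  if (m_fin <= m_init) {
    out <- make_T(res$p)
    attr(out, "flagged") <- FALSE
    attr(out, "metric") <- m_fin
  } else {
    warning("rigid optimization did not improve the metric; returning init")
    out <- init
    attr(out, "flagged") <- TRUE
    attr(out, "metric") <- m_init
  }
  attr(out, "metric_init") <- m_init
  out
}

#' Straightened curved planar reformation (CPR)
#'
#' For each sample of an equidistantly resampled centerline, an orthonormal
#' in-plane frame is built from the unit tangent `t` and a fixed projection
#' direction: `u = normalize(proj - (proj . t) t)`, `v = t x u`. Slice voxel
#' `(i, j)` samples the volume at `p + (i - c) s u + (j - c) s v` and slices
#' are stacked in arc-length order, producing a rectified volume in which the
#' vessel runs along the slice axis.
#'
#' @param volume [image_volume()] (or [binary_mask()]) to reformat.
#' @param cl [centerline()] resampled by [resample_centerline()].
#' @param in_plane_extent in-plane slice size in mm (default 80).
#' @param in_plane_spacing in-plane sample spacing in mm (default 1).
#' @param projection_direction fixed world direction defining the frame
#'   (default +x, the patient left-right axis); must stay at >= 5 degrees
#'   from every centerline tangent.
#' @param interpolation `"linear"` (default) or `"nearest"` (for masks).
#' @param background out-of-support fill (default volume minimum).
#' @return An object of class `c("straightened_volume", "image_volume")` with
#'   `frames` (per-slice origin, tangent, u, v), `in_plane_spacing` and
#'   `slice_spacing` fields.
#' @export
straighten <- function(volume, cl, in_plane_extent = 80,
                       in_plane_spacing = 1,
                       projection_direction = c(1, 0, 0),
                       interpolation = c("linear", "nearest"),
                       background = NULL) {
  interpolation <- match.arg(interpolation)
  if (is.na(cl$sampling_distance))
    stop("centerline must be resampled first (resample_centerline)")
  pts <- cl$points
  n <- nrow(pts)
  tang <- pts * 0
  tang[2:(n - 1), ] <- pts[3:n, ] - pts[1:(n - 2), ]
  tang[1, ] <- pts[2, ] - pts[1, ]
  tang[n, ] <- pts[n, ] - pts[n - 1, ]
  tang <- tang / sqrt(rowSums(tang^2))
  proj <- projection_direction / sqrt(sum(projection_direction^2))
  dt <- tang %*% proj
  if (any(abs(dt) > cos(5 * pi / 180))) {
    bad <- which(abs(dt) > cos(5 * pi / 180))[1]
    stop(sprintf("projection direction is within 5 degrees of the tangent at slice %d",
                 bad))
  }
  u <- matrix(proj, n, 3, byrow = TRUE) - as.numeric(dt) * tang
  u <- u / sqrt(rowSums(u^2))
  v <- cbind(tang[, 2] * u[, 3] - tang[, 3] * u[, 2],
             tang[, 3] * u[, 1] - tang[, 1] * u[, 3],
             tang[, 1] * u[, 2] - tang[, 2] * u[, 1])
  n_in <- 2L * floor(in_plane_extent / (2 * in_plane_spacing)) + 1L
  if (is.null(background)) background <- min(volume$voxels)
  vox <- straighten_cpp(as.numeric(volume$voxels), dim(volume$voxels),
                        volume$spacing, volume$origin, pts, u, v, n_in,
                        in_plane_spacing, interpolation == "linear",
                        background)
  dim(vox) <- c(n_in, n_in, n)
  out <- if (inherits(volume, "binary_mask") && interpolation == "nearest")
    binary_mask(vox, c(in_plane_spacing, in_plane_spacing,
                       cl$sampling_distance))
  else image_volume(vox, c(in_plane_spacing, in_plane_spacing,
                           cl$sampling_distance))
  out$frames <- list(origin = pts, tangent = tang, u = u, v = v)
  out$in_plane_spacing <- in_plane_spacing
  out$slice_spacing <- cl$sampling_distance
  class(out) <- unique(c("straightened_volume", class(out)))
  out
}

#' Map a world point into straightened-volume indices
#'
#' Returns the 0-based index `(i, j, slice)` of the point in the straightened
#' lattice: the slice of the nearest centerline sample and the in-plane
#' coordinates through that slice's frame.
#'
#' @param point length-3 world point (mm) within the swept region.
#' @param straightened a [straighten()] result.
#' @return numeric length-3 `(i, j, slice)`, 0-based, continuous.
#' @export
straighten_point <- function(point, straightened) {
  fr <- straightened$frames
  d2 <- rowSums((fr$origin - matrix(point, nrow(fr$origin), 3,
                                    byrow = TRUE))^2)
  k <- which.min(d2)
  rel <- as.numeric(point) - fr$origin[k, ]
  a <- sum(rel * fr$u[k, ])
  b <- sum(rel * fr$v[k, ])
  half <- (dim(straightened$voxels)[1] - 1) / 2 * straightened$in_plane_spacing
  if (abs(a) > half || abs(b) > half)
    stop("point lies outside the straightened in-plane extent")
  c0 <- (dim(straightened$voxels)[1] - 1) / 2
  c(c0 + a / straightened$in_plane_spacing,
    c0 + b / straightened$in_plane_spacing, k - 1)
}

#' Shift a straightened volume by an integer index offset
#'
#' `out[i] = vol[i - offset]`, padded with the volume minimum and cropped or
#' padded to `out_dim`.
#'
#' @param vol straightened [image_volume()] or [binary_mask()].
#' @param offset integer length-3 index offset.
#' @param out_dim output lattice size (default: input size).
#' @return The shifted volume, same class.
#' @export
shift_straightened <- function(vol, offset, out_dim = dim(vol$voxels)) {
  offset <- as.integer(round(offset))
  d <- dim(vol$voxels)
  bg <- min(vol$voxels)
  out <- array(bg, out_dim)
  src_lo <- pmax(1L, 1L - offset)
  src_hi <- pmin(d, out_dim - offset)
  if (all(src_hi >= src_lo)) {
    dst_lo <- src_lo + offset
    dst_hi <- src_hi + offset
    out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
      vol$voxels[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2],
                 src_lo[3]:src_hi[3]]
  }
  res <- if (inherits(vol, "binary_mask"))
    binary_mask(out, vol$spacing, vol$origin)
  else image_volume(out, vol$spacing, vol$origin)
  res$in_plane_spacing <- vol$in_plane_spacing
  res$slice_spacing <- vol$slice_spacing
  class(res) <- unique(c(class(vol), class(res)))
  res
}

#' Translation alignment of straightened volumes via the renal landmark
#'
#' Shifts the moving straightened volume by the integer-rounded index offset
#' `lm_fixed - lm_moving` (no interpolation, keeping masks crisp) and crops
#' or pads it to the fixed lattice.
#'
#' @param s_fixed,s_moving [straighten()] results sharing in-plane spacing
#'   and slice spacing.
#' @param lm_fixed,lm_moving straightened-space indices of the renal landmark
#'   from [straighten_point()].
#' @return The aligned moving volume on the fixed lattice, with attribute
#'   `offset` (the applied integer shift, reusable for masks via
#'   [shift_straightened()]).
#' @export
align_straightened <- function(s_fixed, s_moving, lm_fixed, lm_moving) {
  if (abs(s_fixed$in_plane_spacing - s_moving$in_plane_spacing) > 1e-9 ||
      abs(s_fixed$slice_spacing - s_moving$slice_spacing) > 1e-9)
    stop("straightened volumes have mismatched spacing")
  offset <- as.integer(round(lm_fixed - lm_moving))
  out <- shift_straightened(s_moving, offset, dim(s_fixed$voxels))
  attr(out, "offset") <- offset
  out
}
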