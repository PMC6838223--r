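# Core image containers and physical-space geometry.
#
# Convention used throughout the package: world = origin + spacing * index,
# with 0-based indices, voxel centres as sample points, axis-aligned
# orientation (identity direction matrix), and displacement fields in mm.

#' 3D scalar image with physical geometry
#'
#' The carrier for all CTA-like data: a 3D voxel lattice plus per-axis voxel
#' spacing (mm) and the world position of voxel (0,0,0) (mm).
#'
#' @param voxels 3D numeric array of intensities (HU-like).
#' @param spacing numeric length-3, voxel size in mm per axis; all > 0.
#' @param origin numeric length-3, world position of voxel (0,0,0) in mm.
#' @return An object of class `image_volume` with fields `voxels`, `spacing`,
#'   `origin`.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array")
  if (any(dim(voxels) < 2L))
    stop("image lattice must have at least 2 voxels per axis")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)")
  if (any(!is.finite(voxels)))
    stop("all intensities must be finite")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' Binary mask on an image lattice
#'
#' Same geometry as [image_volume()] but values restricted to \{0, 1\}.
#'
#' @inheritParams image_volume
#' @return An object of class `c("binary_mask", "image_volume")`.
#' @export
binary_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  storage.mode(voxels) <- "integer"
  if (!all(voxels %in% c(0L, 1L)))
    stop("mask values must be 0 or 1")
  v <- image_volume(voxels, spacing, origin)
  class(v) <- c("binary_mask", "image_volume")
  v
}

#' Per-voxel 3-vector displacement field (mm)
#'
#' Stores the displacement U relating reference (timepoint-1) voxel positions
#' to their deformed positions, on the reference lattice, in mm.
#'
#' @param u 4D numeric array `(nx, ny, nz, 3)` of displacement components.
#' @param spacing,origin geometry of the reference lattice (see
#'   [image_volume()]).
#' @param mask optional [binary_mask()] giving the domain where the field is
#'   defined.
#' @return An object of class `vector_field`.
#' @export
vector_field <- function(u, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         mask = NULL) {
  u <- as.array(u)
  if (length(dim(u)) != 4L || dim(u)[4] != 3L)
    stop("u must be a 4D array with last dimension 3")
  if (any(!is.finite(u)))
    stop("vector components must be finite")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "binary_mask"))
    if (!all(dim(mask$voxels) == dim(u)[1:3]))
      stop("mask lattice does not match field lattice")
  }
  structure(list(u = u, spacing = spacing, origin = origin, mask = mask),
            class = "vector_field")
}

#' Rigid 3D transform (rotation + translation)
#'
#' Represents the world-coordinate map `x -> R x + t`. The rotation must be
#' orthonormal with determinant +1 (tolerance 1e-8).
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation in mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (length(translation) != 3L || any(!is.finite(translation)))
    stop("translation must be 3 finite values")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin %s mm\n",
              class(x)[1], paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n  rotation:\n")
  print(signif(x$rotation, 6))
  cat("  translation (mm):", paste(signif(x$translation, 6), collapse = ", "),
      "\n")
  invisible(x)
}

#' Build a rigid transform from Euler angles about a centre
#'
#' Rotations are applied in the order Rz Ry Rx about `center`, then
#' `translation` is added: `x -> R (x - c) + c + translation`.
#'
#' @param angles length-3, rotations about x, y, z in degrees.
#' @param translation length-3 translation in mm.
#' @param center length-3 rotation centre in mm.
#' @return A [rigid_transform()].
#' @export
euler_rigid <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                        center = c(0, 0, 0)) {
  a <- angles * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  R <- Rz %*% Ry %*% Rx
  center <- as.numeric(center)
  rigid_transform(R, as.numeric(center - R %*% center) + as.numeric(translation))
}

#' Compose two rigid transforms
#'
#' Returns the transform `x -> a(b(x))`.
#' @param a,b [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param x A [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_transform <- function(x) {
  Rt <- t(x$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% x$translation))
}

#' Apply a rigid transform to points
#' @param transform A [rigid_transform()].
#' @param points numeric n x 3 matrix (or length-3 vector) of world points, mm.
#' @return Transformed points, same shape.
#' @export
transform_points <- function(transform, points) {
  vec <- is.null(dim(points))
  pts <- if (vec) matrix(points, 1, 3) else as.matrix(points)
  out <- pts %*% t(transform$rotation) +
    matrix(transform$translation, nrow(pts), 3, byrow = TRUE)
  if (vec) as.numeric(out) else out
}

#' Map a 0-based voxel index to world coordinates
#'
#' `world = origin + spacing * index` under the package's axis-aligned
#' orientation convention.
#'
#' @param volume An [image_volume()].
#' @param index integer triple (0-based) or n x 3 matrix of indices.
#' @return World coordinates in mm (vector or n x 3 matrix).
#' @export
index_to_world <- function(volume, index) {
  vec <- is.null(dim(index))
  idx <- if (vec) matrix(index, 1, 3) else as.matrix(index)
  d <- dim(volume$voxels)
  if (any(idx < 0) || any(idx > matrix(d - 1L, nrow(idx), 3, byrow = TRUE)))
    stop("index out of lattice bounds")
  out <- idx * matrix(volume$spacing, nrow(idx), 3, byrow = TRUE) +
    matrix(volume$origin, nrow(idx), 3, byrow = TRUE)
  if (vec) as.numeric(out) else out
}

#' Map world coordinates to (continuous) 0-based voxel indices
#' @param volume An [image_volume()].
#' @param world length-3 vector or n x 3 matrix of world points (mm).
#' @param round round to the nearest integer index (default TRUE).
#' @return 0-based voxel indices.
#' @export
world_to_index <- function(volume, world, round = TRUE) {
  vec <- is.null(dim(world))
  w <- if (vec) matrix(world, 1, 3) else as.matrix(world)
  idx <- (w - matrix(volume$origin, nrow(w), 3, byrow = TRUE)) /
    matrix(volume$spacing, nrow(w), 3, byrow = TRUE)
  if (round) idx <- round(idx)
  if (vec) as.numeric(idx) else idx
}

#' Resample a volume onto a reference lattice through a rigid transform
#'
#' Each reference voxel's world position `w` is mapped to `transform(w)` and
#' the input volume is sampled there, so the output shows `volume` pulled into
#' the reference frame. With `transform` equal to a registration result that
#' maps fixed-space points into moving space, this aligns the moving volume
#' onto the fixed lattice.
#'
#' @param volume [image_volume()] to sample from (the moving image).
#' @param reference [image_volume()] defining the output lattice.
#' @param transform [rigid_transform()] mapping reference world coordinates
#'   into `volume`'s world coordinates. Default identity.
#' @param interpolation `"linear"` or `"nearest"`.
#' @param background fill value for out-of-support positions; defaults to the
#'   minimum of `volume` (CT air).
#' @return An [image_volume()] (or [binary_mask()] if the input was a mask and
#'   nearest interpolation is used) on the reference lattice.
#' @export
resample <- function(volume, reference, transform = rigid_transform(),
                     interpolation = c("linear", "nearest"),
                     background = NULL) {
  interpolation <- match.arg(interpolation)
  if (is.null(background)) background <- min(volume$voxels)
  vox <- resample_affine_cpp(
    as.numeric(volume$voxels), dim(volume$voxels), volume$spacing,
    volume$origin, dim(reference$voxels), reference$spacing, reference$origin,
    transform$rotation, transform$translation,
    interpolation == "linear", background)
  dim(vox) <- dim(reference$voxels)
  if (inherits(volume, "binary_mask") && interpolation == "nearest")
    binary_mask(vox, reference$spacing, reference$origin)
  else image_volume(vox, reference$spacing, reference$origin)
}

#' Warp a volume by a displacement field
#'
#' Pull-back warp: `output(x) = volume(x + U(x))` with `U` in mm on the same
#' lattice as the volume. With `U` equal to a registration field mapping
#' fixed-lattice points into moving space, `warp(moving, U)` reconstructs the
#' fixed image from the moving one.
#'
#' @param volume [image_volume()] on the field's lattice.
#' @param field [vector_field()].
#' @param interpolation `"linear"` or `"nearest"`.
#' @param background fill value for out-of-support positions (default: volume
#'   minimum).
#' @return Warped [image_volume()] (or [binary_mask()] under nearest
#'   interpolation of a mask).
#' @export
warp <- function(volume, field, interpolation = c("linear", "nearest"),
                 background = NULL) {
  interpolation <- match.arg(interpolation)
  if (!all(dim(volume$voxels) == dim(field$u)[1:3]))
    stop("field is not on the same lattice as the volume")
  if (is.null(background)) background <- min(volume$voxels)
  vox <- warp_field_cpp(as.numeric(volume$voxels), dim(volume$voxels),
                        volume$spacing, as.numeric(field$u[, , , 1]),
                        as.numeric(field$u[, , , 2]),
                        as.numeric(field$u[, , , 3]),
                        interpolation == "linear", background)
  dim(vox) <- dim(volume$voxels)
  if (inherits(volume, "binary_mask") && interpolation == "nearest")
    binary_mask(vox, volume$spacing, volume$origin)
  else image_volume(vox, volume$spacing, volume$origin)
}
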