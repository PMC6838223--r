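# Voxel-wise finite-strain analysis of a displacement field: deformation
# gradient F = grad(U) + I, right Cauchy-Green tensor C = F'F, principal
# stretches sqrt(lambda_i), and tensile/compressive strain unit-vector
# fields. A principal stretch > 1 marks the maximum tensile strain
# direction, < 1 the maximum compressive one; a voxel whose largest stretch
# is <= 1 is triaxially compressed (no tensile vector) and one whose
# smallest stretch is >= 1 triaxially tensed (no compressive vector).

#' Displacement gradient by central differences
#'
#' Computes `dU_a/dx_b` with physical spacing (mm) per axis. The gradient is
#' defined only at voxels whose +/-1 neighbours along every axis are inside
#' both the lattice and the domain mask; elsewhere marked invalid.
#'
#' @param field [vector_field()] (mm).
#' @param domain [binary_mask()] on the same lattice (e.g. the thrombus).
#' @return A `tensor_lattice` list: `a` (array `(nx,ny,nz,9)`, entry
#'   `a + 3(b-1)` holding `dU_a/dx_b`), `valid` (logical array), `spacing`,
#'   `kind = "gradU"`.
#' @export
displacement_gradient <- function(field, domain) {
  if (!all(dim(field$u)[1:3] == dim(domain$voxels)))
    stop("field and domain are not on the same lattice")
  res <- displacement_gradient_cpp(as.numeric(field$u[, , , 1]),
                                   as.numeric(field$u[, , , 2]),
                                   as.numeric(field$u[, , , 3]),
                                   dim(domain$voxels), field$spacing,
                                   domain$voxels)
  structure(list(a = res$grad, valid = array(res$valid, dim(domain$voxels)),
                 spacing = field$spacing, kind = "gradU"),
            class = "tensor_lattice")
}

#' Deformation gradient tensor F = grad(U) + I
#'
#' @param gradU a `tensor_lattice` from [displacement_gradient()].
#' @return A `tensor_lattice` with `kind = "F"` and a `det` array (Jacobian
#'   determinant, for fold detection).
#' @export
deformation_tensor <- function(gradU) {
  stopifnot(inherits(gradU, "tensor_lattice"), gradU$kind == "gradU")
  Fa <- gradU$a
  d <- dim(Fa)[1:3]
  for (c in c(1L, 5L, 9L)) Fa[, , , c] <- Fa[, , , c] + 1
  dt <- Fa[, , , 1] * (Fa[, , , 5] * Fa[, , , 9] - Fa[, , , 8] * Fa[, , , 6]) -
    Fa[, , , 4] * (Fa[, , , 2] * Fa[, , , 9] - Fa[, , , 8] * Fa[, , , 3]) +
    Fa[, , , 7] * (Fa[, , , 2] * Fa[, , , 6] - Fa[, , , 5] * Fa[, , , 3])
  structure(list(a = Fa, valid = gradU$valid, spacing = gradU$spacing,
                 det = dt, kind = "F"),
            class = "tensor_lattice")
}

#' Right Cauchy-Green tensor C = F'F
#'
#' Symmetric positive semidefinite by construction; stored as the six unique
#' entries (c11, c21, c31, c22, c32, c33).
#'
#' @param F_lat a `tensor_lattice` with `kind = "F"`.
#' @return A `tensor_lattice` with `kind = "C"` (field `a6`).
#' @export
right_cauchy_green <- function(F_lat) {
  stopifnot(inherits(F_lat, "tensor_lattice"), F_lat$kind == "F")
  Fa <- F_lat$a
  d <- dim(Fa)[1:3]
  # columns of F: f.1 = (F11,F21,F31) etc.; C_ab = sum_c F_ca F_cb
  a6 <- array(0, c(d, 6))
  a6[, , , 1] <- Fa[, , , 1]^2 + Fa[, , , 2]^2 + Fa[, , , 3]^2
  a6[, , , 2] <- Fa[, , , 1] * Fa[, , , 4] + Fa[, , , 2] * Fa[, , , 5] +
    Fa[, , , 3] * Fa[, , , 6]
  a6[, , , 3] <- Fa[, , , 1] * Fa[, , , 7] + Fa[, , , 2] * Fa[, , , 8] +
    Fa[, , , 3] * Fa[, , , 9]
  a6[, , , 4] <- Fa[, , , 4]^2 + Fa[, , , 5]^2 + Fa[, , , 6]^2
  a6[, , , 5] <- Fa[, , , 4] * Fa[, , , 7] + Fa[, , , 5] * Fa[, , , 8] +
    Fa[, , , 6] * Fa[, , , 9]
  a6[, , , 6] <- Fa[, , , 7]^2 + Fa[, , , 8]^2 + Fa[, , , 9]^2
  structure(list(a6 = a6, valid = F_lat$valid, spacing = F_lat$spacing,
                 det_f = F_lat$det, kind = "C"),
            class = "tensor_lattice")
}

#' Green-Lagrange strain tensor E = (C - I) / 2
#'
#' @param C_lat a `tensor_lattice` with `kind = "C"`.
#' @return A `tensor_lattice` with `kind = "E"` (six-entry storage).
#' @export
green_lagrange <- function(C_lat) {
  stopifnot(inherits(C_lat, "tensor_lattice"), C_lat$kind == "C")
  E <- C_lat$a6
  for (c in c(1L, 4L, 6L)) E[, , , c] <- E[, , , c] - 1
  E <- E / 2
  structure(list(a6 = E, valid = C_lat$valid, spacing = C_lat$spacing,
                 kind = "E"),
            class = "tensor_lattice")
}

#' Principal strain fields from the right Cauchy-Green tensor
#'
#' Per valid voxel, the symmetric eigendecomposition of C gives eigenvalues
#' `lambda_1 >= lambda_2 >= lambda_3` (squared principal stretches) and an
#' orthonormal eigenbasis. The tensile unit vector is the `lambda_1`
#' eigenvector where `sqrt(lambda_1) > 1` (magnitude `sqrt(lambda_1) - 1`);
#' the compressive unit vector is the `lambda_3` eigenvector where
#' `sqrt(lambda_3) < 1` (magnitude `1 - sqrt(lambda_3)`). Strict
#' inequalities: a voxel at exactly 1 contributes neither. Eigenvector signs
#' are canonicalized (largest-magnitude component positive). Voxels with
#' `det F <= 0` (folding) are excluded and counted.
#'
#' @param C_lat a `tensor_lattice` with `kind = "C"`.
#' @return An object of class `strain_field`: `dim`, `spacing`, `valid`
#'   (logical array), `idx` (linear indices of valid voxels), `lambda`
#'   (n x 3, descending), `vectors` (n x 9: the three eigenvectors),
#'   `tensile`/`compressive` (logical per valid voxel), `tensile_mag`/
#'   `compressive_mag` (per valid voxel), `n_folded`.
#' @export
principal_strain_fields <- function(C_lat) {
  stopifnot(inherits(C_lat, "tensor_lattice"), C_lat$kind == "C")
  d <- dim(C_lat$a6)[1:3]
  valid <- C_lat$valid
  n_folded <- 0L
  if (!is.null(C_lat$det_f)) {
    folded <- valid & C_lat$det_f <= 0
    n_folded <- sum(folded)
    if (n_folded > 0L) {
      warning(sprintf("%d voxel(s) with det F <= 0 (folding) excluded",
                      n_folded))
      valid <- valid & !folded
    }
  }
  idx <- which(valid)
  nn <- prod(d)
  C6 <- matrix(0, length(idx), 6)
  for (c in 1:6) C6[, c] <- C_lat$a6[idx + (c - 1) * nn]
  eg <- eig_sym3_cpp(C6)
  lam <- pmax(eg$values, 0)
  s1 <- sqrt(lam[, 1])
  s3 <- sqrt(lam[, 3])
  # strict inequalities with a guard far below any physical strain, so an
  # identity (or pure-rotation) tensor yields neither vector
  tol <- 1e-12
  structure(list(dim = d, spacing = C_lat$spacing, valid = valid, idx = idx,
                 lambda = lam, vectors = eg$vectors,
                 tensile = s1 > 1 + tol, compressive = s3 < 1 - tol,
                 tensile_mag = pmax(s1 - 1, 0),
                 compressive_mag = pmax(1 - s3, 0),
                 n_folded = n_folded),
            class = "strain_field")
}

#' @export
print.strain_field <- function(x, ...) {
  cat(sprintf("<strain_field> %d valid voxels (%d tensile, %d compressive, %d folded)\n",
              length(x$idx), sum(x$tensile), sum(x$compressive), x$n_folded))
  invisible(x)
}

#' Tensile strain unit vectors of a strain field
#' @param sf A [principal_strain_fields()] result.
#' @return m x 3 matrix of unit vectors (voxels with tensile presence).
#' @export
tensile_units <- function(sf) {
  sf$vectors[sf$tensile, 1:3, drop = FALSE]
}

#' Compressive strain unit vectors of a strain field
#' @param sf A [principal_strain_fields()] result.
#' @return m x 3 matrix of unit vectors (voxels with compressive presence).
#' @export
compressive_units <- function(sf) {
  sf$vectors[sf$compressive, 7:9, drop = FALSE]
}

#' Per-case strain summary
#'
#' Mean tensile and compressive strain magnitudes over the voxels where the
#' respective vector is present (0 when none), plus voxel counts.
#'
#' @param sf A [principal_strain_fields()] result.
#' @return A list: `mean_tensile_mag`, `mean_compressive_mag`, `n_valid`,
#'   `n_tensile`, `n_compressive`, `n_triaxial_tensed` (no compressive
#'   vector), `n_triaxial_compressed` (no tensile vector), `n_folded`.
#' @export
strain_summary <- function(sf) {
  stopifnot(inherits(sf, "strain_field"))
  list(mean_tensile_mag = if (any(sf$tensile))
         mean(sf$tensile_mag[sf$tensile]) else 0,
       mean_compressive_mag = if (any(sf$compressive))
         mean(sf$compressive_mag[sf$compressive]) else 0,
       n_valid = length(sf$idx),
       n_tensile = sum(sf$tensile),
       n_compressive = sum(sf$compressive),
       n_triaxial_tensed = sum(!sf$compressive),
       n_triaxial_compressed = sum(!sf$tensile),
       n_folded = sf$n_folded)
}

#' Convert a strain field to sampled unit-vector volumes
#'
#' Returns the tensile and compressive unit-vector fields as
#' [vector_field()]s on the full lattice (zero where absent), for export via
#' [write_vtk_field()] or [write_field()].
#'
#' @param sf A [principal_strain_fields()] result.
#' @return list of two [vector_field()]s: `tensile`, `compressive`.
#' @export
strain_unit_fields <- function(sf) {
  nn <- prod(sf$dim)
  tens <- array(0, c(sf$dim, 3))
  comp <- array(0, c(sf$dim, 3))
  it <- sf$idx[sf$tensile]
  ic <- sf$idx[sf$compressive]
  for (c in 1:3) {
    tens[it + (c - 1) * nn] <- sf$vectors[sf$tensile, c]
    comp[ic + (c - 1) * nn] <- sf$vectors[sf$compressive, 6 + c]
  }
  list(tensile = vector_field(tens, sf$spacing),
       compressive = vector_field(comp, sf$spacing))
}
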