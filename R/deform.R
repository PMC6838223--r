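# Level-set-motion deformable registration of straightened thrombus volumes.
# The second-timepoint volume evolves so that its level sets move along
# their normals to minimize the mean square difference against the first
# timepoint, for a fixed number of iterations; the recovered field is the
# displacement consumed by the strain analysis.

#' Deformable registration parameters
#'
#' @param iterations evolution iterations (default 200).
#' @param smoothing_sigma Gaussian regularization of the accumulated field,
#'   in voxels (default 1.0).
#' @param step_cap per-iteration velocity cap in voxels (default 0.5).
#' @param epsilon gradient-magnitude stabilizer in the velocity denominator;
#'   default `1e-3 * (intensity range)^2`, resolved at registration time.
#' @return An object of class `deformable_params`.
#' @export
deformable_params <- function(iterations = 200, smoothing_sigma = 1.0,
                              step_cap = 0.5, epsilon = NULL) {
  if (iterations < 0) stop("iterations must be >= 0")
  if (smoothing_sigma < 0) stop("smoothing sigma must be >= 0")
  if (step_cap <= 0) stop("step cap must be > 0")
  structure(list(iterations = as.integer(iterations),
                 smoothing_sigma = smoothing_sigma, step_cap = step_cap,
                 epsilon = epsilon),
            class = "deformable_params")
}

#' Level-set-motion registration
#'
#' Iterates for exactly `params$iterations`: the moving image is warped by
#' the current field `U`; the residual (fixed minus warped) drives a velocity
#' `residual * grad(w) / (|grad w|^2 + eps)` along the warped image's normals; the
#' per-voxel step is capped and the accumulated field Gaussian-smoothed. The
#' field maps fixed-lattice points into moving space (the Lagrangian
#' displacement with the first timepoint as reference), in mm. The final
#' mean-square difference never exceeds the initial one.
#'
#' @param fixed,moving [image_volume()]s on the same lattice (after
#'   [align_straightened()]).
#' @param params [deformable_params()].
#' @param fixed_mask,moving_mask optional [binary_mask()]s (e.g. thrombus);
#'   when both are given, the Dice overlap of the warped moving mask against
#'   the fixed mask is reported.
#' @return An object of class `registration_result`: `field`
#'   ([vector_field()]), `msd_initial`, `msd_final`, `trace` (per-iteration
#'   MSD), `dice` (or NA), `warped_mask` (or NULL).
#' @export
level_set_register <- function(fixed, moving, params = deformable_params(),
                               fixed_mask = NULL, moving_mask = NULL) {
  if (!all(dim(fixed$voxels) == dim(moving$voxels)))
    stop("fixed and moving volumes are not on the same lattice")
  rng <- diff(range(fixed$voxels))
  eps <- if (is.null(params$epsilon)) 1e-3 * rng^2 else params$epsilon
  if (eps <= 0) eps <- 1e-9
  d <- dim(fixed$voxels)
  res <- level_set_cpp(as.numeric(fixed$voxels), as.numeric(moving$voxels),
                       d, fixed$spacing, params$iterations,
                       params$smoothing_sigma, params$step_cap, eps,
                       min(moving$voxels))
  fld <- vector_field(res$field, fixed$spacing, fixed$origin)
  dsc <- NA_real_
  wmask <- NULL
  if (!is.null(fixed_mask) && !is.null(moving_mask)) {
    # anti-aliased mask warping: linear-warp the indicator, threshold at half
    wi <- warp(image_volume(moving_mask$voxels + 0, moving_mask$spacing,
                            moving_mask$origin), fld, "linear",
               background = 0)
    wmask <- binary_mask(array(as.integer(wi$voxels > 0.5), dim(wi$voxels)),
                         moving_mask$spacing, moving_mask$origin)
    dsc <- dice(fixed_mask, wmask)
  }
  structure(list(field = fld,
                 msd_initial = res$trace[1],
                 msd_final = res$final_msd,
                 trace = res$trace,
                 reverted = res$reverted,
                 dice = dsc, warped_mask = wmask),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> %d iterations, MSD %.3f -> %.3f, Dice %s\n",
              length(x$trace) - 1L, x$msd_initial, x$msd_final,
              ifelse(is.na(x$dice), "NA", sprintf("%.4f", x$dice))))
  invisible(x)
}

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b [binary_mask()]s on the same lattice.
#' @return Overlap ratio in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!all(dim(a$voxels) == dim(b$voxels)))
    stop("masks are not on the same lattice")
  sa <- sum(a$voxels)
  sb <- sum(b$voxels)
  if (sa + sb == 0L) return(1.0)
  2 * sum(a$voxels * b$voxels) / (sa + sb)
}
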