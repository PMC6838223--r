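# Bone and lumen segmentation: prerequisites for rigid alignment and
# centerline extraction. Bones are bright enough for thresholding plus
# connected-component filtering; the contrasted lumen is grown adaptively
# from a seed.

#' Segmentation parameters
#'
#' @param bone_hu_threshold intensity threshold (HU) above which voxels are
#'   candidate bone (default 1100).
#' @param bone_min_component_voxels minimum 26-connected component size kept
#'   (default 500).
#' @param lumen_multiplier acceptance half-width `k` in units of the region
#'   standard deviation (default 2.5).
#' @param lumen_max_iterations maximum region-growing sweeps (default 50).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(bone_hu_threshold = 1100,
                                bone_min_component_voxels = 500,
                                lumen_multiplier = 2.5,
                                lumen_max_iterations = 50) {
  if (!is.finite(bone_hu_threshold)) stop("threshold must be finite")
  if (lumen_multiplier <= 0) stop("lumen multiplier must be > 0")
  if (bone_min_component_voxels < 1) stop("min component size must be >= 1")
  structure(list(bone_hu_threshold = bone_hu_threshold,
                 bone_min_component_voxels = bone_min_component_voxels,
                 lumen_multiplier = lumen_multiplier,
                 lumen_max_iterations = lumen_max_iterations),
            class = "segmentation_params")
}

#' Coarse bone segmentation by thresholding and component filtering
#'
#' Keeps the union of 26-connected components of
#' `{voxel >= bone_hu_threshold}` with at least
#' `bone_min_component_voxels` voxels. Monotone in the threshold: raising it
#' never adds voxels.
#'
#' @param volume An [image_volume()].
#' @param params A [segmentation_params()].
#' @return A [binary_mask()] (possibly empty).
#' @export
segment_bones <- function(volume, params = segmentation_params()) {
  d <- dim(volume$voxels)
  cand <- array(as.integer(volume$voxels >= params$bone_hu_threshold), d)
  cc <- connected_components_cpp(cand, d)
  keep <- which(cc$sizes >= params$bone_min_component_voxels)
  out <- array(as.integer(cc$labels %in% keep & cc$labels > 0L), d)
  binary_mask(out, volume$spacing, volume$origin)
}

#' Fill interior cavities of a binary mask
#'
#' Background components not connected to the volume border are converted to
#' foreground. Image noise leaves small interior cavities in region-grown
#' masks; topology-preserving thinning would otherwise wrap around every one
#' of them.
#'
#' @param mask A [binary_mask()].
#' @return The filled [binary_mask()].
#' @export
fill_holes <- function(mask) {
  d <- dim(mask$voxels)
  inv <- array(1L - mask$voxels, d)
  cc <- connected_components_cpp(inv, d)
  lab <- array(cc$labels, d)
  border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                     lab[, , 1], lab[, , d[3]]))
  border <- border[border > 0L]
  fill <- lab > 0L & !(lab %in% border)
  out <- mask$voxels
  out[fill] <- 1L
  binary_mask(out, mask$spacing, mask$origin)
}

#' Adaptive region-growing lumen segmentation
#'
#' Starting from the 3x3x3 neighbourhood of the seed, each sweep accepts
#' 26-neighbours of the current region whose intensity lies within
#' `mu +/- k*sd` of the region's running mean and standard deviation (sd
#' floored at 1 HU), until a fixed point or `lumen_max_iterations`.
#'
#' @param volume An [image_volume()].
#' @param seed integer triple, 0-based voxel index inside the contrasted
#'   lumen.
#' @param params A [segmentation_params()].
#' @return A [binary_mask()] with attributes `degenerate` (TRUE when growth
#'   hit the iteration cap or exceeded half the volume) and `iterations`.
#' @export
segment_lumen <- function(volume, seed, params = segmentation_params()) {
  d <- dim(volume$voxels)
  seed <- as.integer(round(seed))
  if (length(seed) != 3L || any(seed < 0L) || any(seed >= d))
    stop("seed must be a voxel index inside the volume")
  res <- region_grow_cpp(as.numeric(volume$voxels), d, seed,
                         params$lumen_multiplier,
                         as.integer(params$lumen_max_iterations))
  m <- binary_mask(array(res$mask, d), volume$spacing, volume$origin)
  attr(m, "degenerate") <- res$degenerate
  attr(m, "iterations") <- res$iterations
  if (res$degenerate)
    warning("lumen region growing is degenerate (hit the iteration cap or >50% of the volume)")
  m
}
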