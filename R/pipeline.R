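# End-to-end pipeline orchestration: segmentation -> rigid alignment ->
# straightened CPR -> translation alignment -> level-set deformable
# registration -> strain analysis -> per-case features, plus the cohort
# driver with cross-validated prognosis evaluation.

.bbox_of <- function(mask, dilate = 0L) {
  w <- which(mask == 1L, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("mask is empty")
  d <- dim(mask)
  lo <- pmax(apply(w, 2, min) - dilate, 1L)
  hi <- pmin(apply(w, 2, max) + dilate, d)
  list(lo = lo, hi = hi)
}

.crop <- function(vol, bb) {
  vox <- vol$voxels[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2],
                    bb$lo[3]:bb$hi[3], drop = FALSE]
  orig <- vol$origin + (bb$lo - 1) * vol$spacing
  if (inherits(vol, "binary_mask")) binary_mask(vox, vol$spacing, orig)
  else image_volume(vox, vol$spacing, orig)
}

#' Pipeline parameters
#'
#' Bundles the per-stage settings of [run_pipeline()].
#'
#' @param seg [segmentation_params()].
#' @param cpr list: `in_plane_extent` (mm, default 80), `in_plane_spacing`
#'   (mm, default 0.8, matching the scans' in-plane resolution), `delta`
#'   (centerline sampling distance, mm, default 1), `projection` (CPR
#'   projection direction, default +x), `smooth_sigma` (centerline
#'   smoothing scale, mm, default 5).
#' @param deform [deformable_params()].
#' @param bbox_dilate voxels of dilation of the thrombus bounding box on
#'   which the deformable registration runs (default 10).
#' @return list of class `pipeline_params`.
#' @export
pipeline_params <- function(seg = segmentation_params(),
                            cpr = list(in_plane_extent = 80,
                                       in_plane_spacing = 0.8, delta = 1,
                                       projection = c(1, 0, 0),
                                       smooth_sigma = 5),
                            deform = deformable_params(),
                            bbox_dilate = 10L) {
  structure(list(seg = seg, cpr = cpr, deform = deform,
                 bbox_dilate = as.integer(bbox_dilate)),
            class = "pipeline_params")
}

# anti-aliased mask transport: masks are moved as linearly interpolated
# indicator images thresholded at half occupancy, which carries sub-voxel
# boundary position instead of nearest-neighbour quantization
.resample_mask_aa <- function(mask, reference, transform) {
  ind <- image_volume(mask$voxels + 0, mask$spacing, mask$origin)
  r <- resample(ind, reference, transform, "linear", background = 0)
  binary_mask(array(as.integer(r$voxels > 0.5), dim(r$voxels)),
              reference$spacing, reference$origin)
}

.straighten_mask_aa <- function(mask, cl, extent, sp, proj) {
  ind <- image_volume(mask$voxels + 0, mask$spacing, mask$origin)
  s <- straighten(ind, cl, extent, sp, proj, "linear", background = 0)
  out <- binary_mask(array(as.integer(s$voxels > 0.5), dim(s$voxels)),
                     s$spacing, s$origin)
  out$frames <- s$frames
  out$in_plane_spacing <- s$in_plane_spacing
  out$slice_spacing <- s$slice_spacing
  class(out) <- unique(c("straightened_volume", class(out)))
  out
}

# centerline for one (already aligned) volume: lumen -> skeleton -> 3
# branches -> merged path -> oriented -> resampled
.extract_centerline <- function(volume, lumen_seed_idx, landmark, params,
                                transform = NULL) {
  lum <- fill_holes(segment_lumen(volume, lumen_seed_idx, params$seg))
  sk <- skeletonize(lum)
  brs <- prune_to_main_branches(sk, 3, mask = lum)
  cl <- if (isTRUE(attr(brs, "flagged")) || length(brs) < 3L) {
    centerline(brs[[1]])
  } else {
    merge_bifurcation(brs)
  }
  # segmentation runs in the scan's native space; an optional rigid map
  # carries the path into the aligned (fixed) space afterwards
  if (!is.null(transform))
    cl <- centerline(transform_points(transform, cl$points), cl$branch)
  cl <- orient_centerline(cl, landmark)
  cl <- smooth_centerline(resample_centerline(cl, params$cpr$delta),
                          params$cpr$smooth_sigma %||% 3)
  resample_centerline(cl, params$cpr$delta)
}

#' Run the full registration and strain pipeline on one case
#'
#' Executes bone segmentation, landmark-initialized rigid registration,
#' resampling of the second scan onto the first lattice, lumen segmentation
#' and centerline extraction per scan, straightened CPR of volumes and
#' thrombus masks, landmark-based translation alignment of the straightened
#' volumes, level-set-motion deformable registration restricted to the
#' dilated thrombus bounding box, and voxel-wise principal strain analysis
#' on the recovered displacement field.
#'
#' @param t1,t2 [image_volume()]s (first and second follow-up scan).
#' @param thrombus_t1,thrombus_t2 thrombus [binary_mask()]s per scan
#'   (pipeline inputs, spanning renal to iliac levels).
#' @param landmark_t1,landmark_t2 lowest renal artery world positions (mm).
#' @param params [pipeline_params()].
#' @param out_dir optional directory for intermediate artifacts and the
#'   summary manifest.
#' @param case_id label used in artifacts and error messages.
#' @return A result bundle (list): `rigid` (recovered transform), `dice`
#'   (thrombus overlap after deformable registration), `registration`
#'   ([level_set_register()] result), `strain` ([principal_strain_fields()]
#'   result), `summary` ([strain_summary()]), `diameter_difference` (mm, in
#'   rigidly aligned space), `centerline_t1`/`centerline_t2`, `timings`.
#' @export
run_pipeline <- function(t1, t2, thrombus_t1, thrombus_t2, landmark_t1,
                         landmark_t2, params = pipeline_params(),
                         out_dir = NULL, case_id = "case") {
  tic <- function() Sys.time()
  el <- function(t0) round(as.numeric(Sys.time() - t0, units = "secs"), 2)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- tic()
    r <- tryCatch(expr, error = function(e)
      stop(sprintf("[%s] stage '%s' failed: %s", case_id, name,
                   conditionMessage(e)), call. = FALSE))
    timings[[name]] <<- el(t0)
    r
  }

  bones <- stage("segment_bones", segment_bones(t1, params$seg))
  rigid <- stage("register_rigid", {
    init <- init_translation(landmark_t1, landmark_t2)
    register_rigid(t1, t2, bones, init)
  })
  t2a <- stage("resample_t2", resample(t2, t1, rigid, "linear"))
  thr2a <- .resample_mask_aa(thrombus_t2, t1, rigid)
  lm2a <- transform_points(invert_transform(rigid), landmark_t2)

  cl1 <- stage("centerline_t1",
               .extract_centerline(t1, world_to_index(t1, landmark_t1),
                                   landmark_t1, params))
  cl2 <- stage("centerline_t2",
               .extract_centerline(t2, world_to_index(t2, landmark_t2),
                                   lm2a, params,
                                   transform = invert_transform(rigid)))

  cpr <- params$cpr
  s1 <- stage("straighten", {
    straighten(t1, cl1, cpr$in_plane_extent, cpr$in_plane_spacing,
               cpr$projection)
  })
  sm1 <- .straighten_mask_aa(thrombus_t1, cl1, cpr$in_plane_extent,
                             cpr$in_plane_spacing, cpr$projection)
  s2 <- straighten(t2a, cl2, cpr$in_plane_extent, cpr$in_plane_spacing,
                   cpr$projection)
  sm2 <- .straighten_mask_aa(thr2a, cl2, cpr$in_plane_extent,
                             cpr$in_plane_spacing, cpr$projection)
  lmx1 <- straighten_point(landmark_t1, s1)
  lmx2 <- straighten_point(lm2a, s2)
  s2al <- align_straightened(s1, s2, lmx1, lmx2)
  off <- attr(s2al, "offset")
  sm2al <- shift_straightened(sm2, off, dim(s1$voxels))

  bb <- .bbox_of(sm1$voxels, params$bbox_dilate)
  reg <- stage("deformable", {
    # the deformable stage registers the straightened thrombus volumes:
    # the segmentation indicator (0/100), lightly smoothed so the level
    # sets carry sub-voxel boundary position
    mk_ind <- function(mk) {
      v <- 100 * mk$voxels
      image_volume(array(gaussian_smooth3_cpp(v, dim(v), rep(1, 3)),
                         dim(v)), mk$spacing, mk$origin)
    }
    level_set_register(mk_ind(.crop(sm1, bb)), mk_ind(.crop(sm2al, bb)),
                       params$deform,
                       fixed_mask = .crop(sm1, bb),
                       moving_mask = .crop(sm2al, bb))
  })
  sf <- stage("strain", {
    gr <- displacement_gradient(reg$field, .crop(sm1, bb))
    principal_strain_fields(right_cauchy_green(deformation_tensor(gr)))
  })
  summ <- strain_summary(sf)
  dd <- stage("diameter", diameter_difference(thrombus_t1, thr2a))

  bundle <- list(case_id = case_id, rigid = rigid, dice = reg$dice,
                 registration = reg, strain = sf, summary = summ,
                 diameter_difference = dd, centerline_t1 = cl1,
                 centerline_t2 = cl2, straightened_offset = off,
                 bbox = bb, timings = timings)
  if (!is.null(out_dir)) .write_case_artifacts(bundle, s1, sm1, s2al, out_dir)
  bundle
}

.write_case_artifacts <- function(bundle, s1, sm1, s2al, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pfx <- file.path(out_dir, bundle$case_id)
  write_transform(bundle$rigid, paste0(pfx, "_rigid.json"))
  write_volume(s1, paste0(pfx, "_straightened_t1.nii.gz"), "float")
  write_volume(s2al, paste0(pfx, "_straightened_t2_aligned.nii.gz"), "float")
  write_volume(sm1, paste0(pfx, "_straightened_thrombus_t1.nii.gz"))
  write_field(bundle$registration$field, paste0(pfx, "_displacement.nii.gz"))
  write_vtk_field(bundle$registration$field, paste0(pfx, "_displacement.vtk"))
  uf <- strain_unit_fields(bundle$strain)
  write_vtk_field(uf$tensile, paste0(pfx, "_tensile_units.vtk"), "tensile")
  write_vtk_field(uf$compressive, paste0(pfx, "_compressive_units.vtk"),
                  "compressive")
  write_centerline_csv(bundle$centerline_t1, paste0(pfx, "_centerline_t1.csv"))
  write_vtk_polyline(bundle$centerline_t1, paste0(pfx, "_centerline_t1.vtk"))
  summary_json <- c(list(case_id = bundle$case_id, dice = bundle$dice,
                         diameter_difference_mm = bundle$diameter_difference,
                         msd_initial = bundle$registration$msd_initial,
                         msd_final = bundle$registration$msd_final,
                         timings_s = bundle$timings),
                    bundle$summary)
  jsonlite::write_json(summary_json, paste0(pfx, "_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Run the pipeline over a phantom cohort and evaluate prognosis features
#'
#' Materializes each case of a [generate_cohort()] specification, runs
#' [run_pipeline()] with the phantom-provided thrombus masks and renal
#' landmarks, builds orientation-PCA features, and evaluates stratified
#' cross-validated linear-SVM classification for the tensile, compressive
#' and combined feature sets.
#'
#' @param cohort a `phantom_cohort` from [generate_cohort()].
#' @param params [pipeline_params()].
#' @param cv_folds,cv_runs,cv_seed cross-validation settings (default 4
#'   folds, 10 runs).
#' @param out_dir optional artifact directory.
#' @param progress print per-case progress lines.
#' @return list: `cases` (per-case bundles, failed cases as `NULL`),
#'   `labels`, `dice` (per-case), `diameter_difference`, `features`
#'   (per-mode [build_features()] output), `reports` (per-mode
#'   [evaluate_cv()] reports), `failed` (indices).
#' @export
run_cohort <- function(cohort, params = pipeline_params(), cv_folds = 4,
                       cv_runs = 10, cv_seed = 42, out_dir = NULL,
                       progress = interactive()) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  n <- length(cohort$specs)
  cases <- vector("list", n)
  failed <- integer(0)
  for (i in seq_len(n)) {
    t0 <- Sys.time()
    res <- tryCatch({
      cs <- generate_case(cohort$specs[[i]])
      tr <- cs$truth
      run_pipeline(cs$t1, cs$t2, tr$masks_t1$thrombus, tr$masks_t2$thrombus,
                   tr$landmark_t1, tr$landmark_t2, params,
                   out_dir = out_dir, case_id = sprintf("case%02d", i))
    }, error = function(e) {
      warning(sprintf("case %d failed: %s", i, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) failed <- c(failed, i) else cases[[i]] <- res
    if (progress)
      message(sprintf("case %02d/%d [%s] %.1fs %s", i, n, cohort$labels[i],
                      as.numeric(Sys.time() - t0, units = "secs"),
                      if (is.null(res)) "FAILED" else
                        sprintf("dice %.3f", res$dice)))
  }
  if (length(failed) > 0.2 * n)
    stop(sprintf("%d of %d cases failed (> 20%%)", length(failed), n))
  ok <- setdiff(seq_len(n), failed)
  sfs <- lapply(cases[ok], `[[`, "strain")
  labs <- cohort$labels[ok]
  feats <- list()
  reports <- list()
  for (mode in c("tensile", "compressive", "both")) {
    fb <- build_features(sfs, labs, mode)
    feats[[mode]] <- fb
    reports[[mode]] <- evaluate_cv(fb$features, fb$labels, folds = cv_folds,
                                   runs = cv_runs, seed = cv_seed)
  }
  out <- list(cases = cases, labels = cohort$labels,
              dice = vapply(cases, function(b)
                if (is.null(b)) NA_real_ else b$dice, numeric(1)),
              diameter_difference = vapply(cases, function(b)
                if (is.null(b)) NA_real_ else b$diameter_difference,
                numeric(1)),
              features = feats, reports = reports, failed = failed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (mode in names(reports)) {
      rp <- reports[[mode]]
      jsonlite::write_json(
        list(mode = mode, mean_auc = rp$mean_auc, fold_auc = rp$fold_auc,
             fpr_grid = rp$fpr_grid, mean_tpr = rp$mean_tpr,
             recall_grid = rp$recall_grid,
             mean_precision = rp$mean_precision, seed = rp$seed),
        file.path(out_dir, sprintf("cv_report_%s.json", mode)),
        digits = NA, pretty = TRUE)
      ft <- feats[[mode]]
      df <- data.frame(label = as.character(ft$labels), ft$features)
      write.csv(df, file.path(out_dir, sprintf("features_%s.csv", mode)),
                row.names = FALSE)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
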