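# Synthetic CTA phantom generator.
#
# Emulates paired post-EVAR follow-up scans: high-intensity bone structures
# (vertebral column with disc gaps, pedicles, iliac/hip blocks), a contrasted
# lumen that bifurcates distally, an aneurysm thrombus sheath around the
# lumen, anisotropic voxel spacing, a between-timepoint rigid body motion and
# a smooth, closed-form aneurysm deformation. Unfavorable cases bulge
# outward (anterolaterally; the spine posteriorly constrains real AAAs and
# keeping bones exactly rigid is required for rigid-registration ground
# truth); favorable cases shrink mildly with low-amplitude random-harmonic
# perturbations.

# septic smootherstep: C^3 at both ends, so deformation profiles built from
# it have continuous third derivatives and central differences converge at
# second order in the max norm
.smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t^4 * (35 - 84 * t + 70 * t^2 - 20 * t^3)
}
.smoothstep_d <- function(t) {
  ifelse(t > 0 & t < 1, 140 * t^3 * (1 - t)^3, 0)
}

#' Phantom specification
#'
#' Parameters of one synthetic case. Geometry is in mm on a lattice of
#' `shape` voxels with `spacing` mm; intensities are HU-like (background ~40,
#' thrombus ~60, contrasted lumen ~400, bone ~1200).
#'
#' @param shape integer length-3 lattice size.
#' @param spacing voxel size in mm (default `c(0.8, 0.8, 1.0)`, within the
#'   clinical range of 0.725-0.977 mm in-plane and 0.625-1 mm slice).
#' @param axis_xy x,y position (mm) of the (straight) aortic axis.
#' @param lumen_radius,branch_radius radii (mm) of the aortic trunk and of
#'   each iliac branch.
#' @param bifurcation_fraction fraction of the z extent below which the lumen
#'   splits into two branches.
#' @param branch_angle_deg half-opening angle of the iliac branches.
#' @param sac_semiaxes ellipsoidal thrombus sheath semi-axes (mm).
#' @param sac_center_z z (mm) of the sheath centre.
#' @param renal_z z (mm) of the lowest renal artery landmark (on the axis).
#' @param intensities named list: `background`, `thrombus`, `lumen`, `bone`.
#' @param noise_sd additive Gaussian noise sd (HU) applied to each scan.
#' @param psf_sigma reconstruction blur sd in voxels.
#' @param label `"favorable"` or `"unfavorable"` long-term evolution.
#' @param bulge_amplitude outward bulge amplitude `a` (mm), used for
#'   unfavorable cases.
#' @param bulge_halfwidth axial half-width (mm) of the cosine bulge profile.
#' @param shrink_amplitude inward shrink amplitude (mm), favorable cases.
#' @param perturb_amplitude per-harmonic amplitude scale (mm) of the random
#'   smooth perturbation added to favorable cases (10 harmonics).
#' @param rot_range,trans_range maximum rigid rotation (deg) and translation
#'   magnitude (mm) drawn between the two timepoints.
#' @param rigid optional fixed [rigid_transform()] overriding the random draw
#'   (use `rigid_transform()` for an identity motion).
#' @param seed random seed for this case.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(88, 88, 112), spacing = c(0.8, 0.8, 1.0),
                         axis_xy = c(35.2, 42), lumen_radius = 6,
                         branch_radius = 4.5, bifurcation_fraction = 0.3,
                         branch_angle_deg = 15, sac_semiaxes = c(16, 14, 24),
                         sac_center_z = 60, renal_z = 94,
                         intensities = list(background = 40, thrombus = 60,
                                            lumen = 400, bone = 1200),
                         noise_sd = 5, psf_sigma = 0.6,
                         label = c("unfavorable", "favorable"),
                         bulge_amplitude = 4.5, bulge_halfwidth = 20,
                         shrink_amplitude = 2.0, perturb_amplitude = 0.35,
                         rot_range = 4, trans_range = 8, rigid = NULL,
                         seed = 1L) {
  label <- match.arg(label)
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               axis_xy = axis_xy, lumen_radius = lumen_radius,
               branch_radius = branch_radius,
               bifurcation_fraction = bifurcation_fraction,
               branch_angle_deg = branch_angle_deg,
               sac_semiaxes = as.numeric(sac_semiaxes),
               sac_center_z = sac_center_z, renal_z = renal_z,
               intensities = intensities, noise_sd = noise_sd,
               psf_sigma = psf_sigma, label = label,
               bulge_amplitude = bulge_amplitude,
               bulge_halfwidth = bulge_halfwidth,
               shrink_amplitude = shrink_amplitude,
               perturb_amplitude = perturb_amplitude,
               rot_range = rot_range, trans_range = trans_range,
               rigid = rigid, seed = as.integer(seed))
  if (spec$lumen_radius >= min(spec$sac_semiaxes[1:2]))
    stop("lumen radius must be smaller than the thrombus sheath radii")
  if (spec$bulge_amplitude < 0 || spec$shrink_amplitude < 0)
    stop("deformation amplitudes must be >= 0")
  if (spec$noise_sd < 0) stop("noise sd must be >= 0")
  if (any(spec$spacing <= 0)) stop("spacing must be positive")
  class(spec) <- "phantom_spec"
  spec
}

# world coordinates of every lattice point, as an N x 3 matrix
.lattice_points <- function(shape, spacing, origin = c(0, 0, 0)) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  x <- origin[1] + spacing[1] * (seq_len(nx) - 1)
  y <- origin[2] + spacing[2] * (seq_len(ny) - 1)
  z <- origin[3] + spacing[3] * (seq_len(nz) - 1)
  cbind(rep(x, times = ny * nz),
        rep(rep(y, each = nx), times = nz),
        rep(z, each = nx * ny))
}

# Analytic scene at arbitrary points. Intensities are composited from
# signed-distance occupancy profiles with a ~1-voxel soft edge: real CT
# encodes sub-voxel boundary positions through partial-volume averaging, and
# point-sampling hard membership would quantize every edge to the lattice
# phase (which visibly biases intensity-based registration). Masks remain
# hard membership at the half-occupancy surface.
.scene <- function(spec, pts) {
  cx <- spec$axis_xy[1]; cy <- spec$axis_xy[2]
  dx <- pts[, 1] - cx; dy <- pts[, 2] - cy; z <- pts[, 3]
  ext_z <- spec$spacing[3] * (spec$shape[3] - 1)
  z_bif <- spec$bifurcation_fraction * ext_z
  z_bot <- 4; z_top <- ext_z - 5
  w <- mean(spec$spacing)  # soft-edge width, mm
  occ <- function(d) .smoothstep(0.5 - d / w)  # d: signed distance, <0 inside
  slab <- function(zv, lo, hi) pmax(lo - zv, zv - hi)  # signed dist to slab

  r <- sqrt(dx * dx + dy * dy)
  # trunk and branch segments overlap by 2 mm across the bifurcation plane:
  # abutting slabs would meet edge-to-edge and leave a soft partial-volume
  # gap across the junction, which no real (continuous) vessel has
  d_trunk <- pmax(r - spec$lumen_radius, slab(z, z_bif - 2, z_top))
  s_off <- (z_bif - z) * tan(spec$branch_angle_deg * pi / 180)
  d_bra <- pmax(sqrt((dx - s_off)^2 + dy^2) - spec$branch_radius,
                slab(z, z_bot, z_bif + 2))
  d_brb <- pmax(sqrt((dx + s_off)^2 + dy^2) - spec$branch_radius,
                slab(z, z_bot, z_bif + 2))
  d_lumen <- pmin(d_trunk, d_bra, d_brb)
  o_lumen <- occ(d_lumen)

  sa <- spec$sac_semiaxes
  q <- sqrt((dx / sa[1])^2 + (dy / sa[2])^2 +
            ((z - spec$sac_center_z) / sa[3])^2)
  d_sac <- (q - 1) * min(sa)  # approximate signed distance
  o_sac <- occ(d_sac)

  # bones: vertebral rod with disc gaps, two pedicle rods, two hip blocks
  ys <- 14
  zc <- z %% 14  # vertebral bodies occupy [0, 11) of each 14 mm period
  d_z <- ifelse(zc < 11, -pmin(11 - zc, zc), pmin(zc - 11, 14 - zc))
  d_vert <- pmax(sqrt(dx^2 + (pts[, 2] - ys)^2) - 8, d_z)
  d_ped <- pmax(pmin(sqrt((pts[, 1] - (cx - 12))^2 + (pts[, 2] - ys)^2),
                     sqrt((pts[, 1] - (cx + 12))^2 + (pts[, 2] - ys)^2)) - 3,
                d_z)
  d_hip <- pmax(pmin(abs(pts[, 1] - (cx - 23)),
                     abs(pts[, 1] - (cx + 23))) - 7,
                abs(pts[, 2] - 28) - 6, abs(z - 10) - 8)
  d_bone <- pmin(d_vert, d_ped, d_hip)
  o_bone <- occ(d_bone)

  ii <- spec$intensities
  val <- ii$background + (ii$thrombus - ii$background) * o_sac
  val <- val * (1 - o_lumen) + ii$lumen * o_lumen
  val <- val * (1 - o_bone) + ii$bone * o_bone

  lumen <- d_lumen <= 0
  sac <- d_sac <= 0
  bone <- d_bone <= 0
  list(intensity = val, lumen = lumen, sac = sac, bone = bone,
       thrombus = sac & !lumen)
}

# ---- closed-form deformation fields ----

# compact C^2 axial bump g(z) = S(1 - |z - z0|/L) and its derivative
.gfun <- function(z, z0, L) {
  .smoothstep(1 - abs(z - z0) / L)
}
.gfun_d <- function(z, z0, L) {
  -.smoothstep_d(1 - abs(z - z0) / L) * sign(z - z0) / L
}

# radial ramp vanishing at the axis
.hfun <- function(r, ra, rb) .smoothstep((r - ra) / (rb - ra))
.hfun_d <- function(r, ra, rb) .smoothstep_d((r - ra) / (rb - ra)) / (rb - ra)

# angular window on u = sin(angle from the x axis toward anterior +y)
.wfun <- function(u, lo, hi) {
  if (is.null(lo)) rep(1, length(u)) else .smoothstep((u - lo) / (hi - lo))
}
.wfun_d <- function(u, lo, hi) {
  if (is.null(lo)) rep(0, length(u))
  else .smoothstep_d((u - lo) / (hi - lo)) / (hi - lo)
}

.bulge_u <- function(pts, p) {
  par <- c(p$a, p$cx, p$cy, p$z0, p$L, p$ra, p$rb,
           if (is.null(p$ulo)) c(0, 1, 0) else c(p$ulo, p$uhi, 1))
  bulge_u_cpp(as.matrix(pts), par)
}

.bulge_jac <- function(pts, p) {
  n <- nrow(pts)
  dx <- pts[, 1] - p$cx; dy <- pts[, 2] - p$cy; z <- pts[, 3]
  r <- sqrt(dx * dx + dy * dy)
  rs <- pmax(r, 1e-9)
  nxv <- dx / rs; nyv <- dy / rs
  u <- dy / rs
  g <- .gfun(z, p$z0, p$L); gd <- .gfun_d(z, p$z0, p$L)
  h <- .hfun(r, p$ra, p$rb); hd <- .hfun_d(r, p$ra, p$rb)
  w <- .wfun(u, p$ulo, p$uhi); wd <- .wfun_d(u, p$ulo, p$uhi)
  phi <- p$a * g * h * w
  u_x <- -dx * dy / rs^3
  u_y <- dx * dx / rs^3
  dphi_x <- p$a * g * (hd * nxv * w + h * wd * u_x)
  dphi_y <- p$a * g * (hd * nyv * w + h * wd * u_y)
  dphi_z <- p$a * gd * h * w
  nx_x <- 1 / rs - dx * dx / rs^3
  nx_y <- -dx * dy / rs^3
  ny_y <- 1 / rs - dy * dy / rs^3
  J <- array(0, c(n, 3, 3))
  J[, 1, 1] <- dphi_x * nxv + phi * nx_x
  J[, 1, 2] <- dphi_y * nxv + phi * nx_y
  J[, 1, 3] <- dphi_z * nxv
  J[, 2, 1] <- dphi_x * nyv + phi * nx_y
  J[, 2, 2] <- dphi_y * nyv + phi * ny_y
  J[, 2, 3] <- dphi_z * nyv
  inert <- r <= p$ra  # field identically zero at and inside the ramp start
  if (any(inert)) J[inert, , ] <- 0
  J
}

#' Affine displacement field on a reference lattice
#'
#' `U(x) = (A - I) x`, so the exact deformation gradient is `A` everywhere.
#' Used as an oracle for the strain computation (central differences are
#' exact on affine fields).
#'
#' @param A 3x3 matrix.
#' @param reference [image_volume()] providing the lattice.
#' @return A [vector_field()].
#' @export
analytic_affine_field <- function(A, reference) {
  A <- matrix(as.numeric(A), 3, 3)
  if (any(!is.finite(A))) stop("A must be finite")
  pts <- .lattice_points(dim(reference$voxels), reference$spacing,
                         reference$origin)
  U <- pts %*% t(A - diag(3))
  d <- dim(reference$voxels)
  vector_field(array(U, c(d, 3)), reference$spacing, reference$origin)
}

#' Analytic radial bulge field with closed-form Jacobian
#'
#' `U(x) = a g(z) h(r) r_hat` in cylindrical coordinates about a straight
#' tube axis: `g` is a cosine bump of half-width `z_halfwidth` centred at
#' `z_center`, `h` a smoothstep radial ramp vanishing at the axis
#' (zero at radii up to `r_ramp[1]`, one beyond `r_ramp[2]`). An optional
#' angular window suppresses the displacement toward `-y`. The returned
#' Jacobian evaluator is the hand-differentiated closed form.
#'
#' @param reference [image_volume()] providing the lattice.
#' @param amplitude bulge amplitude `a` in mm (>= 0).
#' @param axis_xy x,y of the tube axis (mm).
#' @param z_center,z_halfwidth centre and half-width (mm) of the axial bump.
#' @param r_ramp length-2, start and end (mm) of the radial ramp.
#' @param angular_window `NULL` for an axisymmetric bulge, or length-2
#'   `c(lo, hi)` bounds on `sin(angle)` between which the window rises 0 to 1.
#' @return A list with `field` (the sampled [vector_field()]), `jacobian`
#'   (function: n x 3 points -> n x 3 x 3 array `dU_a/dx_b`) and `u_fn`
#'   (function: n x 3 points -> n x 3 displacements).
#' @export
analytic_bulge_field <- function(reference, amplitude, axis_xy = c(0, 0),
                                 z_center = 0, z_halfwidth = 20,
                                 r_ramp = c(2, 8), angular_window = NULL) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  p <- list(a = amplitude, cx = axis_xy[1], cy = axis_xy[2], z0 = z_center,
            L = z_halfwidth, ra = r_ramp[1], rb = r_ramp[2],
            ulo = if (is.null(angular_window)) NULL else angular_window[1],
            uhi = if (is.null(angular_window)) NULL else angular_window[2])
  pts <- .lattice_points(dim(reference$voxels), reference$spacing,
                         reference$origin)
  U <- .bulge_u(pts, p)
  d <- dim(reference$voxels)
  list(field = vector_field(array(U, c(d, 3)), reference$spacing,
                            reference$origin),
       jacobian = function(q) .bulge_jac(q, p),
       u_fn = function(q) .bulge_u(q, p))
}

# random smooth harmonic perturbation with the same compact envelope
.harmonics_fn <- function(p, n_harm, amp) {
  kz <- runif(n_harm, 0.05, 0.25)
  ph <- runif(n_harm, 0, 2 * pi)
  m <- sample(0:3, n_harm, replace = TRUE)
  ps <- runif(n_harm, 0, 2 * pi)
  eps <- amp * runif(n_harm, 0.5, 1.5)
  dir <- sample(1:3, n_harm, replace = TRUE)  # 1 radial, 2 axial, 3 azimuthal
  env <- c(p$cx, p$cy, p$z0, p$L, p$ra, p$rb,
           if (is.null(p$ulo)) c(0, 1, 0) else c(p$ulo, p$uhi, 1))
  function(pts)
    harmonics_u_cpp(as.matrix(pts), env, kz, ph, as.integer(m), ps, eps,
                    as.integer(dir))
}

# deformation closure for a case; drawn parts use the current RNG state
.case_deformation <- function(spec) {
  # radial ramp starts outside the stented lumen so the lumen stays rigid
  p <- list(cx = spec$axis_xy[1], cy = spec$axis_xy[2],
            z0 = spec$sac_center_z, L = spec$bulge_halfwidth,
            ra = spec$lumen_radius + 1, rb = spec$lumen_radius + 6,
            ulo = -0.85, uhi = 0.05)
  if (spec$label == "unfavorable") {
    pb <- p; pb$a <- spec$bulge_amplitude
    fn <- function(pts) .bulge_u(pts, pb)
  } else {
    pb <- p; pb$a <- -spec$shrink_amplitude
    hf <- .harmonics_fn(p, 10L, spec$perturb_amplitude)
    fn <- function(pts) .bulge_u(pts, pb) + hf(pts)
  }
  fn
}

# Damped fixed-point inversion of x = p + U(p). The plain iteration
# p <- x - U(p) requires |grad U| < 1; the steep radial ramp violates that
# at large bulge amplitudes, so a relaxation factor is used (converges for
# eigenvalues of I + grad U anywhere in (0, 2/omega)). Points whose residual
# has dropped below `tol` leave the active set.
.invert_deformation <- function(u_fn, pts, max_iter = 80L, omega = 0.45,
                                tol = 0.01) {
  p <- pts
  active <- seq_len(nrow(pts))
  for (i in seq_len(max_iter)) {
    pa <- p[active, , drop = FALSE]
    res <- pa + u_fn(pa) - pts[active, , drop = FALSE]
    p[active, ] <- pa - omega * res
    conv <- rowSums(res^2) <= tol^2
    active <- active[!conv]
    if (length(active) == 0L) break
  }
  p
}

.draw_rigid <- function(spec) {
  if (!is.null(spec$rigid)) return(spec$rigid)
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, spec$rot_range) * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  td <- rnorm(3); td <- td / sqrt(sum(td^2))
  tr <- td * runif(1, 0, spec$trans_range)
  ctr <- (spec$shape - 1) * spec$spacing / 2
  rigid_transform(R, as.numeric(ctr - R %*% ctr) + tr)
}

.blur_noise <- function(vals, spec) {
  arr <- array(vals, spec$shape)
  if (spec$psf_sigma > 0)
    arr <- gaussian_smooth3_cpp(arr, spec$shape, rep(spec$psf_sigma, 3))
  if (spec$noise_sd > 0)
    arr <- arr + array(rnorm(length(arr), 0, spec$noise_sd), spec$shape)
  array(arr, spec$shape)
}

#' Generate one paired-phantom case
#'
#' Builds the timepoint-1 scan analytically, then the timepoint-2 scan as the
#' rigid motion of the aneurysm-deformed anatomy imaged with independent
#' noise: each t2 lattice point is mapped back through the inverse rigid
#' motion and the inverted deformation before evaluating the same analytic
#' scene, so both scans and all ground-truth masks are exact up to
#' voxelization.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `t1`, `t2` ([image_volume()]s) and `truth`, a ground
#'   truth bundle: `rigid` (the body motion, mapping t1 world points to t2),
#'   `aneurysm_field` (sampled forward displacement on the t1 lattice, Eq.-1
#'   semantics: reference point -> deformed point), `u_fn` (the closed-form
#'   displacement closure), `masks_t1`/`masks_t2` (bone, lumen, thrombus
#'   [binary_mask()]s), `centerline_t1`/`centerline_t2` (axis points, mm),
#'   `branches_t1` (trunk and two iliac branch point paths),
#'   `landmark_t1`/`landmark_t2` (lowest renal artery, mm), `label`, `spec`.
#' @export
generate_case <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  rigid <- .draw_rigid(spec)
  u_fn <- .case_deformation(spec)
  pts <- .lattice_points(spec$shape, spec$spacing)
  sc1 <- .scene(spec, pts)
  t1_vox <- .blur_noise(sc1$intensity, spec)

  # t2: pull each lattice point back through rigid^-1 then (id + U)^-1
  rinv <- invert_transform(rigid)
  y <- transform_points(rinv, pts)
  p2 <- y
  # restrict the inversion to points reachable from the deformation support:
  # the bulge motion is radial (angular window and z invariant along it), so
  # only the slab/window/radius tests plus harmonic margins are needed
  dxr <- y[, 1] - spec$axis_xy[1]
  dyr <- y[, 2] - spec$axis_xy[2]
  rr <- sqrt(dxr^2 + dyr^2)
  sel <- abs(y[, 3] - spec$sac_center_z) <= spec$bulge_halfwidth + 4 &
    rr > spec$lumen_radius - 1 &
    dyr / pmax(rr, 1e-9) > -0.85 - 0.2
  if (any(sel)) p2[sel, ] <- .invert_deformation(u_fn, y[sel, , drop = FALSE])
  sc2 <- .scene(spec, p2)
  t2_vox <- .blur_noise(sc2$intensity, spec)

  msk <- function(v) binary_mask(array(as.integer(v), spec$shape),
                                 spec$spacing)
  U <- u_fn(pts)
  d <- spec$shape
  fld <- vector_field(array(U, c(d, 3)), spec$spacing,
                      mask = msk(sc1$thrombus))

  ext_z <- spec$spacing[3] * (d[3] - 1)
  z_bif <- spec$bifurcation_fraction * ext_z
  z_top <- ext_z - 5; z_bot <- 4
  cx <- spec$axis_xy[1]; cy <- spec$axis_xy[2]
  ztr <- seq(z_bif, z_top, by = 1)
  trunk <- cbind(cx, cy, ztr)
  zbr <- seq(z_bot, z_bif, by = 1)
  s_off <- (z_bif - zbr) * tan(spec$branch_angle_deg * pi / 180)
  left <- cbind(cx - s_off, cy, zbr)
  right <- cbind(cx + s_off, cy, zbr)
  # merged ground-truth centerline: limb midpoints coincide with the axis,
  # so the combined path is the axis from the renal end down to the iliacs
  cl1 <- cbind(cx, cy, seq(z_top, z_bot, by = -1))
  lm1 <- c(cx, cy, spec$renal_z)

  truth <- list(rigid = rigid, aneurysm_field = fld, u_fn = u_fn,
                masks_t1 = list(bone = msk(sc1$bone), lumen = msk(sc1$lumen),
                                thrombus = msk(sc1$thrombus)),
                masks_t2 = list(bone = msk(sc2$bone), lumen = msk(sc2$lumen),
                                thrombus = msk(sc2$thrombus)),
                centerline_t1 = cl1,
                centerline_t2 = transform_points(rigid, cl1),
                branches_t1 = list(trunk = trunk, left = left, right = right),
                landmark_t1 = lm1,
                landmark_t2 = transform_points(rigid, lm1),
                label = spec$label, spec = spec)
  list(t1 = image_volume(t1_vox, spec$spacing),
       t2 = image_volume(t2_vox, spec$spacing),
       truth = truth)
}

#' Sample the inverse aneurysm displacement on the t1 lattice
#'
#' Returns the field `V` with `V(x) = Phi^-1(x) - x` for `Phi = id + U`,
#' computed by fixed-point iteration. Warping the t1 scan by `V` (a
#' pull-back) reproduces the deformed-but-not-moved anatomy.
#'
#' @param truth ground-truth bundle from [generate_case()].
#' @return A [vector_field()].
#' @export
inverse_displacement_field <- function(truth) {
  spec <- truth$spec
  pts <- .lattice_points(spec$shape, spec$spacing)
  p <- .invert_deformation(truth$u_fn, pts)
  vector_field(array(p - pts, c(spec$shape, 3)), spec$spacing)
}

#' Generate a labelled phantom cohort
#'
#' Builds per-case [phantom_spec()]s with independent seeds, random geometry
#' jitter and exactly `n_unfavorable` unfavorable labels (bulge amplitudes
#' drawn in 3-6 mm; favorable shrink amplitudes in 1.5-2.5 mm). Cases are
#' returned as specs; call [generate_case()] to materialize the volumes
#' (deterministic per spec).
#'
#' @param n_cases number of cases.
#' @param n_unfavorable number of unfavorable cases (0 <= n <= n_cases).
#' @param base_spec template [phantom_spec()].
#' @param seed cohort seed.
#' @return An object of class `phantom_cohort`: list with `specs` (list of
#'   [phantom_spec()]), `labels` (character vector) and `seed`.
#' @export
generate_cohort <- function(n_cases, n_unfavorable,
                            base_spec = phantom_spec(), seed = 42L) {
  if (n_unfavorable < 0 || n_unfavorable > n_cases)
    stop("n_unfavorable must be between 0 and n_cases")
  set.seed(seed)
  labels <- sample(c(rep("unfavorable", n_unfavorable),
                     rep("favorable", n_cases - n_unfavorable)))
  specs <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    sp <- base_spec
    sp$axis_xy <- base_spec$axis_xy + runif(2, -2, 2)
    sp$sac_semiaxes <- base_spec$sac_semiaxes * runif(3, 0.92, 1.08)
    sp$sac_center_z <- base_spec$sac_center_z + runif(1, -4, 4)
    sp$label <- labels[i]
    sp$bulge_amplitude <- runif(1, 3, 6)
    sp$shrink_amplitude <- runif(1, 1.5, 2.5)
    sp$seed <- as.integer((seed + 104729 * i) %% .Machine$integer.max)
    specs[[i]] <- sp
  }
  structure(list(specs = specs, labels = labels, seed = seed),
            class = "phantom_cohort")
}
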