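# Centerline extraction: homotopic thinning of the lumen, decomposition of
# the skeleton into branches, bifurcation merging into a single path, and
# equidistant resampling.

#' Centerline container
#'
#' An ordered 3D point path (mm), proximal to distal, with per-point branch
#' labels.
#'
#' @param points n x 3 matrix of points in mm (n >= 2, no duplicate
#'   consecutive points).
#' @param branch integer branch label per point.
#' @param sampling_distance sampling distance in mm after
#'   [resample_centerline()], NA before.
#' @return An object of class `centerline`.
#' @export
centerline <- function(points, branch = rep(1L, nrow(points)),
                       sampling_distance = NA_real_) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 2L)
    stop("centerline needs an n x 3 matrix with n >= 2")
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  if (any(seg < 1e-12))
    stop("centerline has duplicate consecutive points")
  structure(list(points = points, branch = as.integer(branch),
                 sampling_distance = sampling_distance),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, length %.1f mm, %d branch label(s)\n",
              nrow(x$points), path_length(x$points),
              length(unique(x$branch))))
  invisible(x)
}

#' Total polyline length in mm
#' @param points n x 3 matrix.
#' @return Length in mm.
#' @export
path_length <- function(points) {
  if (nrow(points) < 2L) return(0)
  sum(sqrt(rowSums((points[-1, , drop = FALSE] -
                    points[-nrow(points), , drop = FALSE])^2)))
}

# linear interpolation of a polyline at arc-length positions s (mm)
.interp_path <- function(points, s) {
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  cs <- c(0, cumsum(seg))
  L <- cs[length(cs)]
  s <- pmin(pmax(s, 0), L)
  idx <- findInterval(s, cs, rightmost.closed = TRUE)
  idx <- pmin(idx, length(seg))
  f <- (s - cs[idx]) / pmax(seg[idx], 1e-12)
  points[idx, , drop = FALSE] * (1 - f) +
    points[idx + 1, , drop = FALSE] * f
}

#' Skeletonize a lumen mask by distance-ordered homotopic thinning
#'
#' Simple points (in the (26,6) digital topology) are removed in increasing
#' distance-transform order while curve endpoints are preserved, yielding a
#' 1-voxel-wide 26-connected curve set with the same number of connected
#' components as the input.
#'
#' @param lumen A non-empty [binary_mask()].
#' @return A [binary_mask()] skeleton.
#' @export
skeletonize <- function(lumen) {
  stopifnot(inherits(lumen, "binary_mask"))
  if (sum(lumen$voxels) == 0L) stop("cannot skeletonize an empty mask")
  d <- dim(lumen$voxels)
  sk <- homotopic_thin_cpp(lumen$voxels, d, lumen$spacing)
  binary_mask(array(sk, d), lumen$spacing, lumen$origin)
}

# ---- skeleton graph decomposition ----

# 26-neighbour adjacency among skeleton voxels; coords are 0-based indices
.skel_graph <- function(skeleton) {
  d <- dim(skeleton$voxels)
  lin <- which(skeleton$voxels == 1L)  # 1-based linear
  n <- length(lin)
  coord <- cbind((lin - 1) %% d[1],
                 ((lin - 1) %/% d[1]) %% d[2],
                 (lin - 1) %/% (d[1] * d[2]))
  id_of <- new.env(hash = TRUE, size = max(64L, n))
  for (q in seq_len(n)) assign(as.character(lin[q]), q, envir = id_of)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  adj <- vector("list", n)
  for (q in seq_len(n)) {
    nb <- integer(0)
    for (e in seq_len(nrow(offs))) {
      ci <- coord[q, 1] + offs[e, 1]
      cj <- coord[q, 2] + offs[e, 2]
      ck <- coord[q, 3] + offs[e, 3]
      if (ci < 0 || cj < 0 || ck < 0 || ci >= d[1] || cj >= d[2] ||
          ck >= d[3]) next
      l2 <- 1 + ci + d[1] * (cj + d[2] * ck)
      hit <- id_of[[as.character(l2)]]
      if (!is.null(hit)) nb <- c(nb, hit)
    }
    adj[[q]] <- nb
  }
  deg <- lengths(adj)
  list(coord = coord, adj = adj, deg = deg, n = n,
       world = coord * matrix(skeleton$spacing, n, 3, byrow = TRUE) +
         matrix(skeleton$origin, n, 3, byrow = TRUE))
}

#' Decompose a skeleton into its main branches
#'
#' Branches are extracted geodesically: the main path is the longest
#' geodesic between two skeleton endpoints; the third branch is the endpoint
#' whose geodesic distance to the main path is largest (it must exceed
#' `spur_min_mm`, so short spurs are never selected), attached at the
#' nearest main-path voxel, which splits the main path in two. Loops in the
#' skeleton are harmless because geodesics ignore them. When `mask` is
#' given, free branch ends are extrapolated along their end tangent to the
#' mask boundary (homotopic thinning retracts tube ends by about the tube
#' radius).
#'
#' @param skeleton A [binary_mask()] from [skeletonize()].
#' @param n number of branches to keep (default 3: aortic trunk plus the two
#'   endograft-limb branches).
#' @param spur_min_mm minimum length (mm) for a side branch; anything
#'   shorter is treated as a spur (default 5 mm).
#' @param mask optional lumen [binary_mask()] for end extension.
#' @return A list of n x 3 point-path matrices (mm), longest first, with
#'   attribute `flagged` = TRUE when fewer than `n` branches exist.
#' @export
prune_to_main_branches <- function(skeleton, n = 3, spur_min_mm = 5,
                                   mask = NULL) {
  d <- dim(skeleton$voxels)
  lin <- which(skeleton$voxels == 1L)
  if (length(lin) == 0L) stop("empty skeleton")
  world_of <- function(ix) {
    cbind((ix - 1) %% d[1], ((ix - 1) %/% d[1]) %% d[2],
          (ix - 1) %/% (d[1] * d[2])) *
      matrix(skeleton$spacing, length(ix), 3, byrow = TRUE) +
      matrix(skeleton$origin, length(ix), 3, byrow = TRUE)
  }
  finish <- function(paths, flagged) {
    if (!is.null(mask))
      paths <- lapply(paths, .extend_path_to_mask, mask = mask,
                      shared = .shared_endpoints(paths))
    attr(paths, "flagged") <- flagged
    if (flagged)
      warning(sprintf("only %d branch(es) found, %d requested",
                      length(paths), n))
    paths
  }
  if (length(lin) < 3L)
    return(finish(list(world_of(lin)), n > 1L))
  geo <- function(src)
    skeleton_geodesic_cpp(skeleton$voxels, d, skeleton$spacing,
                          as.integer(src - 1L))
  back <- function(res, to) {
    path <- integer(0)
    cur <- to
    while (cur != 0L) {
      path <- c(cur, path)
      cur <- res$prev[cur]
    }
    path
  }
  fin_max <- function(vals) {
    vals[!is.finite(vals)] <- -1
    which.max(vals)
  }
  # geodesic diameter of the skeleton = the main (trunk + one limb) path;
  # works whether or not the thinning left clean degree-1 tips
  r1 <- geo(lin[1])
  a <- lin[fin_max(r1$dist[lin])]
  ra <- geo(a)
  b <- lin[fin_max(ra$dist[lin])]
  main <- back(ra, b)  # linear indices, a -> b
  if (n <= 1L)
    return(finish(list(world_of(main)), FALSE))
  # third branch: the voxel geodesically farthest from the main path
  rm <- geo(main)
  val <- rm$dist[lin]
  val[!is.finite(val)] <- -1
  e <- lin[which.max(val)]
  if (max(val) < spur_min_mm)
    return(finish(list(world_of(main)), TRUE))
  limb <- back(rm, e)  # attachment (on main) -> e
  j <- match(limb[1], main)
  if (is.na(j) || j <= 2L || j >= length(main) - 1L)
    return(finish(list(world_of(main), world_of(limb)), n > 2L))
  seg1 <- main[j:1]                     # attachment -> a
  seg2 <- main[j:length(main)]          # attachment -> b
  paths <- list(seg1, seg2, limb)       # all attachment-first
  lens <- vapply(paths, function(p) path_length(world_of(p)), numeric(1))
  paths <- lapply(paths[order(lens, decreasing = TRUE)[seq_len(min(n,
                    length(paths)))]], world_of)
  finish(paths, length(paths) < n)
}

.shared_endpoints <- function(paths) {
  ends <- do.call(rbind, lapply(paths, function(p)
    rbind(p[1, ], p[nrow(p), ])))
  ends
}

# extend a path's free ends along the end tangent until leaving the mask
.extend_path_to_mask <- function(path, mask, shared) {
  d <- dim(mask$voxels)
  inside <- function(pt) {
    idx <- round((pt - mask$origin) / mask$spacing)
    if (any(idx < 0) || any(idx > d - 1)) return(FALSE)
    mask$voxels[idx[1] + 1, idx[2] + 1, idx[3] + 1] == 1L
  }
  near_other <- function(pt) {
    dmin <- sqrt(rowSums((shared - matrix(pt, nrow(shared), 3,
                                          byrow = TRUE))^2))
    sum(dmin < 1e-6) > 1L  # this endpoint coincides with another branch's
  }
  step <- 0.5 * min(mask$spacing)
  for (side in c(1L, 2L)) {
    endp <- if (side == 1L) path[1, ] else path[nrow(path), ]
    if (near_other(endp)) next
    k <- min(5L, nrow(path) - 1L)
    ref <- if (side == 1L) path[1 + k, ] else path[nrow(path) - k, ]
    tang <- endp - ref
    tl <- sqrt(sum(tang^2))
    if (tl < 1e-9) next
    tang <- tang / tl
    ext <- NULL
    pt <- endp
    for (s in seq_len(200L)) {
      cand <- pt + step * tang
      if (!inside(cand)) break
      pt <- cand
      if (s %% 2L == 0L) ext <- rbind(ext, pt)
    }
    if (!is.null(ext)) {
      path <- if (side == 1L) rbind(ext[nrow(ext):1, , drop = FALSE], path)
      else rbind(path, ext)
    }
  }
  path
}

#' Merge a bifurcation into a single centerline
#'
#' Given the aortic trunk and the two endograft-limb branches, emulates a
#' combined lumen below the bifurcation: the merged path is the trunk
#' followed by the midpoint of the two limbs at matched arc-length fractions.
#'
#' @param branches list of exactly 3 point-path matrices (mm): one trunk and
#'   two limbs overlapping in axial extent (any order; detected
#'   automatically).
#' @return A [centerline()] (branch label 1 on the trunk part, 2 on the
#'   merged limb part), ordered trunk-first.
#' @export
merge_bifurcation <- function(branches) {
  if (length(branches) != 3L) stop("exactly 3 branches required")
  branches <- lapply(branches, as.matrix)
  # junction = the triple of endpoints (one per branch) with minimal spread
  best <- NULL
  for (s1 in 1:2) for (s2 in 1:2) for (s3 in 1:2) {
    e <- rbind(
      if (s1 == 1) branches[[1]][1, ] else branches[[1]][nrow(branches[[1]]), ],
      if (s2 == 1) branches[[2]][1, ] else branches[[2]][nrow(branches[[2]]), ],
      if (s3 == 1) branches[[3]][1, ] else branches[[3]][nrow(branches[[3]]), ])
    spread <- max(dist(e))
    if (is.null(best) || spread < best$spread)
      best <- list(spread = spread, sides = c(s1, s2, s3),
                   junction = colMeans(e))
  }
  # orient every branch junction-first
  oriented <- lapply(1:3, function(i) {
    p <- branches[[i]]
    if (best$sides[i] == 1) p else p[nrow(p):1, , drop = FALSE]
  })
  dirs <- t(vapply(oriented, function(p) {
    v <- p[nrow(p), ] - p[1, ]
    v / max(sqrt(sum(v^2)), 1e-12)
  }, numeric(3)))
  sims <- c(sum(dirs[1, ] * dirs[2, ]), sum(dirs[1, ] * dirs[3, ]),
            sum(dirs[2, ] * dirs[3, ]))
  pair <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))[[which.max(sims)]]
  trunk_i <- setdiff(1:3, pair)
  trunk <- oriented[[trunk_i]]
  limb1 <- oriented[[pair[1]]]
  limb2 <- oriented[[pair[2]]]
  zr1 <- range(limb1[, 3]); zr2 <- range(limb2[, 3])
  if (zr1[2] < zr2[1] || zr2[2] < zr1[1])
    stop("limb branches have disjoint axial extents; cannot merge")
  # trunk ordered free-end -> junction, then limb midpoints by arc fraction
  trunk <- trunk[nrow(trunk):1, , drop = FALSE]
  k <- max(nrow(limb1), nrow(limb2))
  fr <- seq(0, 1, length.out = k)
  l1 <- .interp_path(limb1, fr * path_length(limb1))
  l2 <- .interp_path(limb2, fr * path_length(limb2))
  mid <- (l1 + l2) / 2
  if (sqrt(sum((mid[1, ] - trunk[nrow(trunk), ])^2)) < 1e-9)
    mid <- mid[-1, , drop = FALSE]
  pts <- rbind(trunk, mid)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                       pts[-nrow(pts), , drop = FALSE])^2))
  keep <- c(TRUE, seg > 1e-9)
  pts <- pts[keep, , drop = FALSE]
  lab <- c(rep(1L, nrow(trunk)), rep(2L, nrow(mid)))[keep]
  centerline(pts, lab)
}

#' Resample a centerline equidistantly
#'
#' Arc-length parameterized linear interpolation at distances 0, delta,
#' 2*delta, ...; the start point is always included and the path endpoint is
#' appended as the final sample.
#'
#' @param cl A [centerline()].
#' @param delta sampling distance in mm (default 1).
#' @return A resampled [centerline()] with `sampling_distance = delta`.
#' @export
resample_centerline <- function(cl, delta = 1.0) {
  if (delta <= 0) stop("sampling distance must be > 0")
  if (!is.na(cl$sampling_distance) &&
      abs(cl$sampling_distance - delta) < 1e-12)
    return(cl)  # already sampled at delta: exact idempotence
  L <- path_length(cl$points)
  if (L < delta) stop("centerline shorter than the sampling distance")
  s <- seq(0, L, by = delta)
  if (L - s[length(s)] > 1e-9) s <- c(s, L)
  pts <- .interp_path(cl$points, s)
  # carry branch labels from the nearest original arc position
  seg <- sqrt(rowSums((cl$points[-1, , drop = FALSE] -
                       cl$points[-nrow(cl$points), , drop = FALSE])^2))
  cs <- c(0, cumsum(seg))
  lab <- cl$branch[pmax(1L, findInterval(s, cs, rightmost.closed = TRUE))]
  centerline(pts, lab, sampling_distance = delta)
}

#' Smooth a centerline along its arc length
#'
#' Gaussian-weighted smoothing of each coordinate as a function of arc
#' length. Voxel-scale jaggedness of a thinned skeleton inflates the arc
#' length of the path (and hence drifts the slice parameterization of a
#' straightened reformation); smoothing at a few-mm scale removes it while
#' preserving the vessel course. Endpoints are kept fixed.
#'
#' @param cl A [centerline()].
#' @param sigma_mm smoothing scale in mm (default 3).
#' @return The smoothed [centerline()].
#' @export
smooth_centerline <- function(cl, sigma_mm = 3) {
  pts <- cl$points
  n <- nrow(pts)
  if (n < 5L || sigma_mm <= 0) return(cl)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  out <- pts
  for (i in 2:(n - 1)) {
    wgt <- exp(-0.5 * ((s - s[i]) / sigma_mm)^2)
    out[i, ] <- colSums(pts * wgt) / sum(wgt)
  }
  keep <- c(TRUE, rowSums((out[-1, , drop = FALSE] -
                           out[-n, , drop = FALSE])^2) > 1e-18)
  centerline(out[keep, , drop = FALSE], cl$branch[keep],
             cl$sampling_distance)
}

#' Orient a centerline proximal-first using the renal landmark
#'
#' The proximal end is the one nearer the lowest renal artery landmark.
#'
#' @param cl A [centerline()].
#' @param landmark length-3 world point (mm).
#' @return The (possibly reversed) [centerline()].
#' @export
orient_centerline <- function(cl, landmark) {
  d_start <- sqrt(sum((cl$points[1, ] - landmark)^2))
  d_end <- sqrt(sum((cl$points[nrow(cl$points), ] - landmark)^2))
  if (d_end < d_start)
    centerline(cl$points[nrow(cl$points):1, , drop = FALSE], rev(cl$branch),
               cl$sampling_distance)
  else cl
}
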