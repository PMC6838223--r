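# Prognosis analysis: orientation principal components of the strain
# unit-vector fields as per-case features, linear-SVM stratified
# cross-validation with ROC/PR summaries, and the maximum-diameter baseline.

#' Orientation PCA of a set of unit vectors
#'
#' Eigendecomposition of the orientation (second-moment) matrix
#' `M = (1/N) sum v v'`, the standard sign-invariant statistic for axial
#' direction data: strain eigenvectors carry no meaningful sign, and the
#' question of interest is whether a field is globally tangential or normal
#' to the wall. Axes are ordered by descending eigenvalue; eigenvalues are
#' non-negative and sum to 1; axis signs are canonicalized
#' (largest-magnitude component positive). A mean-centred variant is
#' available behind `center` for comparison.
#'
#' @param unit_vectors n x 3 matrix of unit vectors, n >= 3.
#' @param center subtract the mean vector first (default FALSE; the centred
#'   variant is not sign-invariant).
#' @return list with `axes` (3 x 3 matrix, columns = principal axes) and
#'   `eigenvalues` (length 3, descending, summing to 1 when uncentred).
#' @export
orientation_pca <- function(unit_vectors, center = FALSE) {
  V <- as.matrix(unit_vectors)
  if (ncol(V) != 3L || nrow(V) < 3L)
    stop("at least 3 unit vectors are required")
  if (center) V <- sweep(V, 2, colMeans(V))
  M <- crossprod(V) / nrow(V)
  eg <- eigen(M, symmetric = TRUE)  # descending eigenvalues
  axes <- eg$vectors
  for (c in 1:3) {
    a <- axes[, c]
    lead <- which.max(abs(a))
    if (a[lead] < 0) axes[, c] <- -a
  }
  list(axes = axes, eigenvalues = pmax(eg$values, 0))
}

#' Build per-case orientation-PCA feature vectors
#'
#' For each case, the three orientation principal axes of the selected
#' strain field(s) are flattened in eigenvalue order: 9 features per field
#' (3 axes x 3 coordinates), 18 for both fields combined.
#'
#' @param strain_fields list of [principal_strain_fields()] results, one per
#'   case.
#' @param labels character/factor vector of case labels (`favorable` /
#'   `unfavorable`).
#' @param mode `"both"` (18 features), `"tensile"` or `"compressive"`
#'   (9 features).
#' @return list with `features` (matrix, cases x columns), `labels` (factor,
#'   levels favorable < unfavorable), `eigenvalues` (diagnostic list) and
#'   `excluded` (indices of cases with an empty unit-vector set, dropped
#'   with a warning).
#' @export
build_features <- function(strain_fields, labels,
                           mode = c("both", "tensile", "compressive")) {
  mode <- match.arg(mode)
  n <- length(strain_fields)
  stopifnot(length(labels) == n)
  need <- switch(mode, both = c("tensile", "compressive"),
                 tensile = "tensile", compressive = "compressive")
  feats <- list()
  eigs <- list()
  excluded <- integer(0)
  for (i in seq_len(n)) {
    sf <- strain_fields[[i]]
    row <- numeric(0)
    eg_i <- list()
    ok <- TRUE
    for (wh in need) {
      V <- if (wh == "tensile") tensile_units(sf) else compressive_units(sf)
      if (nrow(V) < 3L) {
        ok <- FALSE
        break
      }
      pc <- orientation_pca(V)
      row <- c(row, as.numeric(pc$axes))
      eg_i[[wh]] <- pc$eigenvalues
    }
    if (!ok) {
      excluded <- c(excluded, i)
      next
    }
    feats[[length(feats) + 1L]] <- row
    eigs[[length(eigs) + 1L]] <- eg_i
  }
  if (length(excluded))
    warning(sprintf("%d case(s) with an empty %s unit-vector set excluded",
                    length(excluded), mode))
  keep <- setdiff(seq_len(n), excluded)
  list(features = do.call(rbind, feats),
       labels = factor(as.character(labels)[keep],
                       levels = c("favorable", "unfavorable")),
       eigenvalues = eigs, excluded = excluded)
}

# stepwise ROC of scores (higher = unfavorable); returns vertical-averaged
# TPR on an FPR grid and interpolated precision on a recall grid
.roc_curves <- function(score, y, fpr_grid, rec_grid) {
  pos <- y == "unfavorable"
  ord <- order(score, decreasing = TRUE)
  tp <- cumsum(pos[ord])
  fp <- cumsum(!pos[ord])
  P <- sum(pos)
  N <- sum(!pos)
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  prec <- c(1, tp / (tp + fp))
  tpr_g <- approx(fpr, tpr, xout = fpr_grid, method = "constant", f = 0,
                  ties = max, rule = 2)$y
  # interpolated precision: max precision at recall >= r
  rec <- tpr
  pr <- rev(cummax(rev(prec)))
  prec_g <- approx(rec, pr, xout = rec_grid, method = "constant", f = 1,
                   ties = max, rule = 2)$y
  list(tpr = tpr_g, prec = prec_g)
}

#' Stratified cross-validated linear-SVM evaluation
#'
#' Runs `runs` repetitions of stratified `folds`-fold cross-validation
#' (class proportions preserved in every fold). Per fold, features are
#' z-scored with statistics fitted on the training folds only, a linear SVM
#' (cost 1) is trained, and decision scores on the validation fold give the
#' fold ROC-AUC. Mean ROC and precision-recall curves are vertically
#' averaged on fixed 101-point grids. Deterministic given `seed`.
#'
#' @param features numeric matrix (cases x features).
#' @param labels factor/character with classes favorable/unfavorable; both
#'   classes need at least `folds` cases.
#' @param folds folds per run (default 4).
#' @param runs repetitions (default 10).
#' @param seed RNG seed.
#' @param cost SVM regularization parameter (default 1).
#' @return An object of class `cv_report`: `fold_auc` (runs x folds matrix),
#'   `mean_auc`, `fpr_grid`/`mean_tpr`, `recall_grid`/`mean_precision`,
#'   `folds`, `runs`, `seed`.
#' @export
evaluate_cv <- function(features, labels, folds = 4, runs = 10, seed = 1,
                        cost = 1) {
  features <- as.matrix(features)
  y <- factor(as.character(labels), levels = c("favorable", "unfavorable"))
  if (any(is.na(y))) stop("labels must be favorable/unfavorable")
  if (nlevels(droplevels(y)) < 2L)
    stop("both classes must be present")
  if (min(table(y)) < folds)
    stop(sprintf("each class needs at least %d cases for %d-fold stratified CV",
                 folds, folds))
  set.seed(seed)
  fpr_grid <- seq(0, 1, length.out = 101)
  rec_grid <- seq(0, 1, length.out = 101)
  fold_auc <- matrix(NA_real_, runs, folds)
  tpr_acc <- matrix(0, runs * folds, length(fpr_grid))
  prec_acc <- matrix(0, runs * folds, length(rec_grid))
  row <- 0L
  for (r in seq_len(runs)) {
    # stratified fold assignment: shuffle within class, deal round-robin
    fold_of <- integer(length(y))
    for (cl in levels(y)) {
      at <- sample(which(y == cl))
      fold_of[at] <- rep_len(seq_len(folds), length(at))
    }
    for (f in seq_len(folds)) {
      tr <- fold_of != f
      mu <- colMeans(features[tr, , drop = FALSE])
      sg <- apply(features[tr, , drop = FALSE], 2, sd)
      sg[sg < 1e-12] <- 1
      xs <- sweep(sweep(features, 2, mu), 2, sg, "/")
      fit <- e1071::svm(xs[tr, , drop = FALSE], y[tr], kernel = "linear",
                        cost = cost, scale = FALSE)
      pr <- predict(fit, xs[!tr, , drop = FALSE], decision.values = TRUE)
      dv <- drop(attr(pr, "decision.values"))
      # orient scores so larger = unfavorable
      if (grepl("^favorable/", colnames(attr(pr, "decision.values"))[1]))
        dv <- -dv
      yv <- y[!tr]
      auc <- as.numeric(pROC::auc(pROC::roc(
        response = yv, predictor = dv, levels = c("favorable", "unfavorable"),
        direction = "<", quiet = TRUE)))
      fold_auc[r, f] <- auc
      row <- row + 1L
      cv <- .roc_curves(dv, yv, fpr_grid, rec_grid)
      tpr_acc[row, ] <- cv$tpr
      prec_acc[row, ] <- cv$prec
    }
  }
  structure(list(fold_auc = fold_auc, mean_auc = mean(fold_auc),
                 fpr_grid = fpr_grid, mean_tpr = colMeans(tpr_acc),
                 recall_grid = rec_grid,
                 mean_precision = colMeans(prec_acc),
                 folds = folds, runs = runs, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d x %d-fold stratified CV, mean ROC-AUC %.3f (fold sd %.3f)\n",
              x$runs, x$folds, x$mean_auc, sd(x$fold_auc)))
  invisible(x)
}

#' Maximum aneurysm diameter (axial Feret)
#'
#' Maximum over axial slices of the maximal in-plane Feret diameter of the
#' thrombus cross-section: the largest pairwise distance between boundary
#' voxel centres, in mm.
#'
#' @param thrombus non-empty [binary_mask()].
#' @return Diameter in mm (0 for a single-voxel mask).
#' @export
max_diameter <- function(thrombus) {
  m <- thrombus$voxels
  if (sum(m) == 0L) stop("mask is empty")
  best <- 0
  for (k in seq_len(dim(m)[3])) {
    sl <- m[, , k]
    n_sl <- sum(sl)
    if (n_sl < 2L) next
    w <- which(sl == 1L, arr.ind = TRUE)
    pts <- cbind((w[, 1] - 1) * thrombus$spacing[1],
                 (w[, 2] - 1) * thrombus$spacing[2])
    hull <- grDevices::chull(pts)
    hp <- pts[hull, , drop = FALSE]
    dmax <- max(dist(hp))
    if (dmax > best) best <- dmax
  }
  best
}

#' Signed maximum-diameter difference between timepoints
#'
#' `max_diameter(t2) - max_diameter(t1)`; positive values indicate growth. A
#' difference above the 5-10 mm range is the conventional clinical trigger
#' for further evaluation.
#'
#' @param thrombus_t1,thrombus_t2 non-empty [binary_mask()]s.
#' @return Signed difference in mm.
#' @export
diameter_difference <- function(thrombus_t1, thrombus_t2) {
  max_diameter(thrombus_t2) - max_diameter(thrombus_t1)
}
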