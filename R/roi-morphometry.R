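# Long-axis subdivision of a labelled structure into thirds and group
# comparison of section volumes. The "long axis" is the first principal
# component of the labelled voxels' world coordinates; sections are
# equal-length intervals of the projection onto that axis.

#' Principal (long) axis of a labelled structure
#'
#' First principal component of the world coordinates of voxels carrying the
#' given label. The sign is fixed so the superior (+z world) component is
#' non-negative (falling back to +y, then +x, for axes orthogonal to z).
#'
#' @param labels 3D integer array (0 = background) or a `label_volume`.
#' @param affine 4x4 voxel-to-world matrix (taken from the `label_volume` if
#'   omitted).
#' @param id Label id to analyse.
#' @param min_aspect Minimum ratio of first to second eigenvalue below which
#'   the long axis is declared non-unique (default 1.05).
#' @return List with `axis` (unit 3-vector), `centroid` (world mm), and
#'   `eigenvalues`.
#' @export
principal_axis <- function(labels, affine = NULL, id = 1L, min_aspect = 1.05) {
  if (inherits(labels, "label_volume")) {
    affine <- affine %||% labels$affine
    labels <- labels$labels
  }
  if (is.null(affine)) stop_named("affine", "required")
  idx <- which(labels == id)
  if (length(idx) < 3L) stop_named("label", "needs at least 3 voxels")
  ijk <- arrayInd(idx, dim(labels)) - 1L
  W <- voxel_to_world(affine, ijk)
  centroid <- colMeans(W)
  S <- crossprod(sweep(W, 2, centroid)) / (nrow(W) - 1)
  eg <- eigen(S, symmetric = TRUE)
  if (eg$values[1] < min_aspect * eg$values[2])
    stop_named("label",
               "no unique long axis (leading eigenvalues are tied)")
  ax <- eg$vectors[, 1]
  for (comp in c(3L, 2L, 1L)) {
    if (abs(ax[comp]) > 1e-8) {
      if (ax[comp] < 0) ax <- -ax
      break
    }
  }
  list(axis = ax / sqrt(sum(ax^2)), centroid = centroid,
       eigenvalues = eg$values)
}

#' Split a labelled structure into thirds along its long axis
#'
#' Each labelled voxel is assigned by the projection of its world coordinate
#' onto the axis into three equal-length intervals of the projected extent
#' (or equal voxel-count tertiles with `method = "count"`). The "top" section
#' is the one with the highest mean world z (ties broken by the higher mean
#' projection).
#'
#' @param labels 3D integer array or `label_volume`.
#' @param affine Affine (from the `label_volume` if omitted).
#' @param id Label id to split.
#' @param axis,centroid Long axis and centroid; computed with
#'   [principal_axis] when omitted.
#' @param method `"length"` (equal-length intervals, default) or `"count"`.
#' @return Object of class `section_set`: `sections` (3D integer array, 1 =
#'   top, 2 = middle, 3 = bottom), `axis`, `centroid`, `cuts` (interval
#'   boundaries on the projection), `codes`.
#' @export
split_thirds <- function(labels, affine = NULL, id = 1L, axis = NULL,
                         centroid = NULL, method = c("length", "count")) {
  method <- match.arg(method)
  if (inherits(labels, "label_volume")) {
    affine <- affine %||% labels$affine
    labels <- labels$labels
  }
  if (is.null(axis) || is.null(centroid)) {
    pa <- principal_axis(labels, affine, id)
    axis <- pa$axis; centroid <- pa$centroid
  }
  idx <- which(labels == id)
  if (!length(idx)) stop_named("label", "empty label")
  ijk <- arrayInd(idx, dim(labels)) - 1L
  W <- voxel_to_world(affine, ijk)
  proj <- as.vector(sweep(W, 2, centroid) %*% axis)
  if (method == "length") {
    lo <- min(proj); hi <- max(proj)
    cuts <- c(lo, lo + (hi - lo) / 3, lo + 2 * (hi - lo) / 3, hi)
    sec <- findInterval(proj, cuts[2:3]) + 1L   # 1, 2, 3 along the axis
  } else {
    qs <- quantile(proj, c(1, 2) / 3, names = FALSE, type = 1)
    cuts <- c(min(proj), qs, max(proj))
    sec <- findInterval(proj, qs, left.open = TRUE) + 1L
  }
  # identify "top" by the mean world z of each interval
  mean_z <- tapply(W[, 3], sec, mean)
  mean_p <- tapply(proj, sec, mean)
  present <- as.integer(names(mean_z))
  ord <- present[order(round(mean_z, 9), mean_p, decreasing = TRUE)]
  code <- integer(3)          # interval -> 1 top, 2 middle, 3 bottom
  code[ord] <- seq_along(ord)
  out <- array(0L, dim(labels))
  out[idx] <- code[sec]
  structure(list(sections = out, axis = axis, centroid = centroid,
                 cuts = cuts, codes = c(top = 1L, middle = 2L, bottom = 3L),
                 affine = affine),
            class = "section_set")
}

#' Volume of a section in mm^3
#'
#' @param sections A `section_set`, or a 3D integer array with `affine` given.
#' @param which Section code or name (`"top"`, `"middle"`, `"bottom"`).
#' @param affine Affine when `sections` is a bare array.
#' @return Volume in mm^3 (voxel count times voxel volume).
#' @export
section_volume <- function(sections, which = "top", affine = NULL) {
  if (inherits(sections, "section_set")) {
    affine <- affine %||% sections$affine
    code <- if (is.character(which)) sections$codes[[which]] else which
    arr <- sections$sections
  } else {
    arr <- sections
    code <- which
  }
  if (is.null(affine)) stop_named("affine", "required")
  n <- sum(arr == code)
  if (n == 0L) stop_named("section", "empty section")
  n * affine_voxel_volume(affine)
}

#' Bilateral volume
#'
#' @param left_mm3,right_mm3 Section volumes for the two sides.
#' @return Their sum in mm^3.
#' @export
bilateral_volume <- function(left_mm3, right_mm3) {
  if (is.null(left_mm3) || is.null(right_mm3) ||
      !is.finite(left_mm3) || !is.finite(right_mm3) ||
      left_mm3 <= 0 || right_mm3 <= 0)
    stop_named("volume", "both sides must be present with positive volume")
  left_mm3 + right_mm3
}

#' Compare section volumes between groups
#'
#' Without covariates: pooled-variance two-sample t test. With covariates:
#' linear model `volume ~ group + covariates`, reporting the group
#' coefficient.
#'
#' @param volumesA,volumesB Per-subject volumes (mm^3) for the two groups.
#' @param covariates Optional data frame, rows matching `c(volumesA,
#'   volumesB)`.
#' @return List with `estimate` (mean difference or adjusted group
#'   coefficient), `t`, `df`, `p`, and `model` (the `lm` fit, covariate case
#'   only).
#' @export
compare_group_volumes <- function(volumesA, volumesB, covariates = NULL) {
  if (length(volumesA) < 2L || length(volumesB) < 2L)
    stop_named("volumes", "need at least 2 subjects per group")
  if (is.null(covariates)) {
    tt <- stats::t.test(volumesA, volumesB, var.equal = TRUE)
    return(list(estimate = mean(volumesA) - mean(volumesB),
                t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value, model = NULL))
  }
  covariates <- as.data.frame(covariates)
  n <- length(volumesA) + length(volumesB)
  if (nrow(covariates) != n)
    stop_named("covariates", "row count must match the pooled subjects")
  dat <- cbind(data.frame(
    volume = c(volumesA, volumesB),
    group = factor(rep(c("A", "B"), c(length(volumesA), length(volumesB))),
                   levels = c("B", "A"))
  ), covariates)
  fit <- lm(volume ~ ., data = dat)
  cf <- summary(fit)$coefficients
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop_named("covariates", paste("collinear terms:",
                                   paste(bad, collapse = ", ")))
  }
  row <- grep("^groupA$", rownames(cf))
  list(estimate = cf[row, 1], t = cf[row, 3], df = fit$df.residual,
       p = cf[row, 4], model = fit)
}
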