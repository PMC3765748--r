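# Group-level inference on z-normalised degree maps: two-sample, paired and
# covariate-regression statistic maps, conversion of t to z, cluster-forming
# thresholds with connected-component labelling, and permutation
# max-cluster-size correction for family-wise error.

new_stat_map <- function(t, z, df, contrast, mask = NULL, affine = NULL) {
  structure(list(t = t, z = z, df = df, contrast = contrast,
                 mask = mask, affine = affine), class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat("<stat_map> ", length(x$t), " voxels | df ", x$df, " | ", x$contrast,
      "\n", sep = "")
  invisible(x)
}

# Guard degenerate voxels: where the variance estimate is zero, the t statistic
# is undefined (or infinite); set z (and t) to 0 with a warning.
zero_degenerate <- function(t, bad, what) {
  if (any(bad)) {
    warning(sprintf("%d voxel(s) with zero %s variance; z set to 0", sum(bad),
                    what))
    t[bad] <- 0
  }
  t
}

#' Convert t statistics to z scores
#'
#' `z = qnorm(pt(t, df))`, evaluated through log tail probabilities so large
#' magnitudes survive; monotone in `t` and antisymmetric.
#'
#' @param t Numeric vector of t statistics.
#' @param df Degrees of freedom (scalar, >= 1).
#' @return Numeric vector of z scores.
#' @export
t_to_z <- function(t, df) {
  check_scalar(df, "df", lo = 1)
  z <- -sign(t) * qnorm(pt(abs(t), df = df, lower.tail = FALSE, log.p = TRUE),
                        log.p = TRUE)
  z[t == 0] <- 0
  z
}

#' Two-sample t map (pooled variance)
#'
#' Per-voxel pooled-variance two-sample t for the contrast A - B, with
#' `df = nA + nB - 2`, converted to z with [t_to_z].
#'
#' @param mapsA,mapsB Lists of `zmap` objects (identical masks), or numeric
#'   matrices (subjects x voxels).
#' @param contrast Text label recorded in the result.
#' @return A `stat_map`.
#' @export
two_sample_t_map <- function(mapsA, mapsB, contrast = "A > B") {
  A <- stack_zmaps(mapsA); B <- stack_zmaps(mapsB)
  if (!is.null(A$mask) && !is.null(B$mask) &&
      !identical(which(A$mask), which(B$mask)))
    stop_named("maps", "mask mismatch between groups")
  if (ncol(A$Z) != ncol(B$Z)) stop_named("maps", "voxel count mismatch")
  nA <- nrow(A$Z); nB <- nrow(B$Z)
  if (nA < 2L || nB < 2L) stop_named("maps", "need at least 2 maps per group")
  mA <- colMeans(A$Z); mB <- colMeans(B$Z)
  vA <- colSums(sweep(A$Z, 2, mA)^2) / (nA - 1)
  vB <- colSums(sweep(B$Z, 2, mB)^2) / (nB - 1)
  sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  md <- mA - mB
  bad <- se <= abs(md) * 1e-10       # exact or numerically-zero variance
  t <- md / se
  t[se == 0 & md == 0] <- 0
  t <- zero_degenerate(t, bad & md != 0, "pooled")
  t[bad] <- 0
  t[!is.finite(t)] <- 0
  df <- nA + nB - 2
  new_stat_map(t, t_to_z(t, df), df, contrast, A$mask %||% B$mask,
               A$affine %||% B$affine)
}

#' Paired t map
#'
#' Per-voxel paired t on within-subject differences (cond1 - cond2),
#' `df = n - 1`. Lists must be subject-matched; when both carry `subject_id`s
#' the pairing is checked.
#'
#' @param maps_cond1,maps_cond2 Matched lists of `zmap`s (or matrices).
#' @param contrast Text label.
#' @return A `stat_map`.
#' @export
paired_t_map <- function(maps_cond1, maps_cond2, contrast = "cond1 > cond2") {
  if (is.list(maps_cond1) && is.list(maps_cond2)) {
    id1 <- vapply(maps_cond1, function(m) m$subject_id %||% NA_character_, "")
    id2 <- vapply(maps_cond2, function(m) m$subject_id %||% NA_character_, "")
    if (!anyNA(id1) && !anyNA(id2) && !identical(id1, id2))
      stop_named("maps", "subject order mismatch between conditions")
  }
  A <- stack_zmaps(maps_cond1); B <- stack_zmaps(maps_cond2)
  if (nrow(A$Z) != nrow(B$Z)) stop_named("maps", "condition lists differ in length")
  n <- nrow(A$Z)
  if (n < 2L) stop_named("maps", "need at least 2 subjects")
  D <- A$Z - B$Z
  md <- colMeans(D)
  sdd <- sqrt(colSums(sweep(D, 2, md)^2) / (n - 1))
  se <- sdd / sqrt(n)
  bad <- se <= abs(md) * 1e-10
  t <- md / se
  t[se == 0 & md == 0] <- 0
  t <- zero_degenerate(t, bad & md != 0, "within-pair")
  t[bad] <- 0
  t[!is.finite(t)] <- 0
  new_stat_map(t, t_to_z(t, n - 1), n - 1, contrast, A$mask, A$affine)
}

#' Covariate regression map
#'
#' Per-voxel simple linear regression of subject difference maps on a
#' covariate (e.g. the change in pain rating, high minus low); reports the t
#' statistic of the slope with `df = n - 2`.
#'
#' @param delta_maps List of `zmap` difference maps (or matrix, subjects x
#'   voxels), one per subject.
#' @param covariate Numeric vector, one value per subject; must have nonzero
#'   variance.
#' @param contrast Text label.
#' @return A `stat_map` with an extra element `slope` (per-voxel slope).
#' @export
covariate_regression_map <- function(delta_maps, covariate,
                                     contrast = "slope > 0") {
  A <- stack_zmaps(delta_maps)
  n <- nrow(A$Z)
  if (length(covariate) != n)
    stop_named("covariate", "length must match the number of maps")
  if (n < 3L) stop_named("maps", "need at least 3 subjects")
  if (var(covariate) == 0)
    stop_named("covariate", "has zero variance")
  xc <- covariate - mean(covariate)
  sxx <- sum(xc^2)
  Dc <- sweep(A$Z, 2, colMeans(A$Z))
  slope <- as.vector(crossprod(xc, Dc)) / sxx
  rss <- colSums(Dc^2) - slope^2 * sxx
  rss[rss < 0] <- 0
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 / sxx)
  bad <- se <= abs(slope) * 1e-10
  t <- slope / se
  t[se == 0 & slope == 0] <- 0
  t <- zero_degenerate(t, bad & slope != 0, "residual")
  t[bad] <- 0
  t[!is.finite(t)] <- 0
  sm <- new_stat_map(t, t_to_z(t, n - 2), n - 2, contrast, A$mask, A$affine)
  sm$slope <- slope
  sm
}

#' Label suprathreshold clusters
#'
#' Connected components of `{z > z_threshold}` under 6-, 18- or
#' 26-connectivity; components smaller than `min_voxels` are discarded and the
#' survivors are relabelled 1, 2, ... by decreasing size (ties keep their
#' original scan order).
#'
#' @param z A `stat_map`, or a 3D array of z values.
#' @param z_threshold Cluster-forming threshold (default 2.3).
#' @param min_voxels Minimum cluster extent in voxels (default 10).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return Integer 3D label array with attribute `sizes` (voxel counts per
#'   retained label).
#' @export
label_clusters <- function(z, z_threshold = 2.3, min_voxels = 10L,
                           connectivity = 26L) {
  check_scalar(z_threshold, "z_threshold", lo = .Machine$double.eps)
  check_scalar(min_voxels, "min_voxels", lo = 1, integer = TRUE)
  z3 <- if (inherits(z, "stat_map")) {
    if (is.null(z$mask)) stop_named("z", "stat_map carries no grid")
    map_to_array(z$z, z$mask, fill = -Inf)
  } else z
  comp <- connected_components3d(z3 > z_threshold, connectivity)
  keep <- which(comp$sizes >= min_voxels)
  out <- array(0L, dim(z3))
  if (length(keep)) {
    ord <- keep[order(comp$sizes[keep], decreasing = TRUE)]
    for (new in seq_along(ord)) out[comp$labels == ord[new]] <- new
    attr(out, "sizes") <- comp$sizes[ord]
  } else {
    attr(out, "sizes") <- integer(0)
  }
  out
}

#' Cluster report table
#'
#' One row per cluster: extent in voxels and mm^3 (voxel count times the voxel
#' volume from the affine), the peak z, and the world coordinate of the peak
#' voxel. Ties on the peak z are broken by the lowest linear voxel index.
#'
#' @param stat A `stat_map` carrying grid information.
#' @param clusters Integer label array from [label_clusters].
#' @param region Optional character vector of free-text region names.
#' @return Data frame with columns `region`, `n_voxels`, `cluster_mm3`,
#'   `z_max`, `peak_x`, `peak_y`, `peak_z`.
#' @export
cluster_report <- function(stat, clusters, region = NULL) {
  stopifnot(inherits(stat, "stat_map"))
  if (is.null(stat$mask)) stop_named("stat", "stat_map carries no grid")
  z3 <- map_to_array(stat$z, stat$mask, fill = -Inf)
  vol <- affine_voxel_volume(stat$affine)
  labs <- sort(unique(clusters[clusters > 0]))
  rows <- lapply(labs, function(l) {
    idx <- which(clusters == l)
    zl <- z3[idx]
    peak <- idx[which.max(zl)]   # which.max: first (lowest index) on ties
    ijk <- arrayInd(peak, dim(clusters)) - 1L
    world <- voxel_to_world(stat$affine, ijk)
    data.frame(region = sprintf("cluster_%d", l), n_voxels = length(idx),
               cluster_mm3 = length(idx) * vol, z_max = max(zl),
               peak_x = world[1], peak_y = world[2], peak_z = world[3])
  })
  if (!length(rows)) {
    out <- data.frame(region = character(0), n_voxels = integer(0),
                      cluster_mm3 = numeric(0), z_max = numeric(0),
                      peak_x = numeric(0), peak_y = numeric(0),
                      peak_z = numeric(0))
  } else {
    out <- do.call(rbind, rows)
  }
  if (!is.null(region) && nrow(out)) out$region <- region
  rownames(out) <- NULL
  out
}

# Permuted t statistics, vectorised over permutations. Returns an n_perm x V
# matrix of t values under the scheme's null.
permuted_t_matrix <- function(test_kind, Z, group = NULL, covariate = NULL,
                              n_perm) {
  if (test_kind == "two_sample") {
    n <- nrow(Z); nA <- sum(group == levels(factor(group))[1])
    Zsq <- Z^2
    tot <- colSums(Z); tot2 <- colSums(Zsq)
    out <- matrix(0, n_perm, ncol(Z))
    for (p in seq_len(n_perm)) {
      ia <- sample.int(n, nA)
      sA <- colSums(Z[ia, , drop = FALSE]); qA <- colSums(Zsq[ia, , drop = FALSE])
      nB <- n - nA
      mA <- sA / nA; mB <- (tot - sA) / nB
      ssA <- qA - sA^2 / nA; ssB <- (tot2 - qA) - (tot - sA)^2 / nB
      sp2 <- (ssA + ssB) / (n - 2)
      se <- sqrt(sp2 * (1 / nA + 1 / nB))
      tt <- (mA - mB) / se
      tt[!is.finite(tt)] <- 0
      out[p, ] <- tt
    }
    out
  } else if (test_kind == "paired") {
    n <- nrow(Z)
    ss <- colSums(Z^2)
    Sg <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    M <- (Sg %*% Z) / n
    Vr <- (matrix(ss, n_perm, ncol(Z), byrow = TRUE) - n * M^2) / (n - 1)
    Vr[Vr < 0] <- 0
    tt <- M / sqrt(Vr / n)
    tt[!is.finite(tt)] <- 0
    tt
  } else {  # regression: sign-flip the difference maps
    n <- nrow(Z)
    xc <- covariate - mean(covariate)
    sxx <- sum(xc^2)
    Zc <- sweep(Z, 2, colMeans(Z))
    ss <- colSums(Zc^2)
    Sg <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    num <- (Sg * matrix(xc, n_perm, n, byrow = TRUE)) %*% Zc
    slope <- num / sxx
    rss <- matrix(ss, n_perm, ncol(Z), byrow = TRUE) - slope^2 * sxx
    rss[rss < 0] <- 0
    tt <- slope / sqrt((rss / (n - 2)) / sxx)
    tt[!is.finite(tt)] <- 0
    tt
  }
}

#' Permutation max-cluster-size correction
#'
#' Computes the observed statistic map for the requested test, labels
#' suprathreshold clusters, and assigns each candidate cluster a family-wise
#' corrected p value by reference to the permutation null distribution of the
#' maximum suprathreshold cluster size:
#' `p = (1 + #\{perm max size >= observed size\}) / (n_perm + 1)`.
#' Group labels are shuffled for two-sample tests; subject difference maps are
#' sign-flipped for paired and regression tests.
#'
#' @param maps List of `zmap`s (all subjects for `two_sample`; condition-1
#'   maps for `paired`; per-subject difference maps for `regression`).
#' @param maps2 Condition-2 maps (paired test only).
#' @param group Factor/vector of two group labels (two-sample only); the
#'   contrast is first level minus second level.
#' @param covariate Numeric covariate (regression only).
#' @param test_kind `"two_sample"`, `"paired"` or `"regression"`.
#' @param z_threshold Cluster-forming threshold on the z map (default 2.3).
#' @param min_voxels Minimum candidate cluster extent (default 10).
#' @param connectivity Neighbourhood for contiguity (default 26).
#' @param n_perm Number of permutations (>= 99; default 499).
#' @param alpha Cluster-level significance level (default 0.05).
#' @param seed Optional integer seed for the permutation draws.
#' @return List with `stat` (the observed `stat_map`), `clusters` (label
#'   array), `table` (cluster report of candidates with `cluster_p` and
#'   `significant` columns), `table_significant` (rows with `p < alpha`), and
#'   `perm_max_size` (the null max-size draws).
#' @export
permutation_cluster_correct <- function(maps, maps2 = NULL, group = NULL,
                                        covariate = NULL,
                                        test_kind = c("two_sample", "paired",
                                                      "regression"),
                                        z_threshold = 2.3, min_voxels = 10L,
                                        connectivity = 26L, n_perm = 499L,
                                        alpha = 0.05, seed = NULL) {
  test_kind <- match.arg(test_kind)
  check_scalar(n_perm, "n_perm", lo = 99, integer = TRUE)
  if (!is.null(seed)) set.seed(seed)

  if (test_kind == "two_sample") {
    if (is.null(group)) stop_named("group", "required for two-sample test")
    group <- factor(group)
    if (nlevels(group) != 2L) stop_named("group", "needs exactly 2 levels")
    st <- stack_zmaps(maps)
    gA <- group == levels(group)[1]
    if (sum(gA) < 2L || sum(!gA) < 2L)
      stop_named("group", "need at least 2 subjects per group")
    if (choose(length(group), sum(gA)) <= n_perm)
      stop_named("maps", "too few subjects for the requested permutation count")
    obs <- two_sample_t_map(st$Z[gA, , drop = FALSE],
                            st$Z[!gA, , drop = FALSE],
                            contrast = paste(levels(group)[1], ">",
                                             levels(group)[2]))
    obs$mask <- st$mask; obs$affine <- st$affine
    Zperm <- st$Z
  } else if (test_kind == "paired") {
    if (is.null(maps2)) stop_named("maps2", "required for paired test")
    obs <- paired_t_map(maps, maps2)
    st1 <- stack_zmaps(maps); st2 <- stack_zmaps(maps2)
    Zperm <- st1$Z - st2$Z
    if (nrow(Zperm) < 7L)
      stop_named("maps", "too few subjects for sign-flip permutation")
    if (is.null(obs$mask)) { obs$mask <- st1$mask; obs$affine <- st1$affine }
  } else {
    obs <- covariate_regression_map(maps, covariate)
    st1 <- stack_zmaps(maps)
    Zperm <- st1$Z
    if (nrow(Zperm) < 7L)
      stop_named("maps", "too few subjects for sign-flip permutation")
  }
  if (is.null(obs$mask)) stop_named("maps", "maps carry no grid information")

  clusters <- label_clusters(obs, z_threshold, min_voxels, connectivity)
  tab <- cluster_report(obs, clusters)

  # threshold on z is equivalent to a threshold on t (monotone map)
  t_thr <- qt(pnorm(z_threshold, lower.tail = FALSE), df = obs$df,
              lower.tail = FALSE)
  Tperm <- permuted_t_matrix(test_kind, Zperm, group = group,
                             covariate = covariate, n_perm = n_perm)
  mask <- obs$mask
  perm_max <- integer(n_perm)
  for (p in seq_len(n_perm)) {
    supra <- map_to_array(Tperm[p, ] > t_thr, mask, fill = FALSE)
    sz <- component_sizes3d(supra, connectivity)
    perm_max[p] <- if (length(sz)) max(sz) else 0L
  }
  if (nrow(tab)) {
    tab$cluster_p <- vapply(tab$n_voxels, function(s)
      (1 + sum(perm_max >= s)) / (n_perm + 1), numeric(1))
    tab$significant <- tab$cluster_p < alpha
  } else {
    tab$cluster_p <- numeric(0)
    tab$significant <- logical(0)
  }
  list(stat = obs, clusters = clusters, table = tab,
       table_significant = tab[tab$significant, , drop = FALSE],
       perm_max_size = perm_max, z_threshold = z_threshold,
       min_voxels = min_voxels, n_perm = n_perm, alpha = alpha)
}

#' Per-subject mean z over a cluster
#'
#' @param maps List of `zmap`s (identical grids).
#' @param cluster_mask 3D logical array (or integer labels, where > 0 selects)
#'   within the image mask.
#' @return Data frame with `subject_id`, `condition`, `mean_z`.
#' @export
extract_mean_z <- function(maps, cluster_mask) {
  st <- stack_zmaps(maps)
  if (is.null(st$mask)) stop_named("maps", "maps carry no grid information")
  sel3 <- cluster_mask > 0
  if (!identical(dim(sel3), dim(st$mask)))
    stop_named("cluster_mask", "grid mismatch")
  if (!sum(sel3)) stop_named("cluster_mask", "empty cluster")
  if (any(sel3 & !st$mask))
    stop_named("cluster_mask", "cluster extends outside the image mask")
  sel <- sel3[st$mask]
  mz <- rowMeans(st$Z[, sel, drop = FALSE])
  data.frame(
    subject_id = if (is.list(maps))
      vapply(maps, function(m) m$subject_id %||% NA_character_, "") else
        NA_character_,
    condition = if (is.list(maps))
      vapply(maps, function(m) m$condition %||% NA_character_, "") else
        NA_character_,
    mean_z = mz
  )
}

#' Two-sample t test from printed summary statistics
#'
#' Reconstructs the two-sample t test from group means, SDs and sizes, either
#' pooled (equal variances) or Welch.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @param pooled Use the pooled-variance test (default) or Welch.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
t_test_from_summary <- function(m1, s1, n1, m2, s2, n2, pooled = TRUE) {
  if (s1 < 0 || s2 < 0) stop_named("sd", "must be non-negative")
  if (n1 < 2 || n2 < 2) stop_named("n", "need at least 2 per group")
  if (s1 == 0 && s2 == 0) {
    if (m1 == m2) return(list(t = 0, df = n1 + n2 - 2, p = 1))
    stop_named("sd", "both SDs zero with unequal means: t undefined")
  }
  if (pooled) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
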