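# Voxel-wise weighted-degree ("hub") connectivity. Each voxel's degree is the
# number of other voxels whose Pearson correlation with it exceeds a threshold
# (positive side only, self excluded); the map is then z-normalised across
# voxels within the subject for group comparison.

#' Standardise rows to zero mean and unit norm
#'
#' After standardisation the dot product of two rows equals their Pearson
#' correlation. Zero-variance rows are flagged degenerate and set to zero, so
#' they correlate 0 with everything and receive degree 0 downstream.
#'
#' @param x A [voxel_ts] or numeric matrix (rows are series).
#' @return List with `data` (standardised matrix) and `degenerate`
#'   (logical flag per row).
#' @export
standardize_rows <- function(x) {
  m <- if (inherits(x, "voxel_ts")) x$data else as.matrix(x)
  if (ncol(m) < 3L) stop_named("timepoints", "need at least 3 frames")
  mu <- rowMeans(m)
  m <- m - mu
  nrm <- sqrt(rowSums(m^2))
  degenerate <- nrm <= max(nrm) * 1e-12 | nrm == 0
  nrm[degenerate] <- 1
  m <- m / nrm
  m[degenerate, ] <- 0
  list(data = m, degenerate = degenerate)
}

#' Voxel-wise weighted-degree connectivity map
#'
#' For every in-mask voxel, counts the other voxels whose Pearson correlation
#' with it strictly exceeds `r_threshold` (positive correlations only; the
#' self-correlation is excluded). Computed in column blocks so peak memory is
#' `O(n_voxels * block_size)`; the result does not depend on `block_size`.
#'
#' @param x A [voxel_ts] or numeric matrix (rows are voxel series).
#' @param r_threshold Correlation threshold in (0, 1); default 0.25.
#' @param block_size Number of voxels correlated per block (default 2048).
#' @param weighted If `TRUE`, sum the supra-threshold correlation values
#'   instead of counting links (non-default variant).
#' @param subject_id,condition Optional identifiers carried in the result.
#' @return An object of class `degree_map`: per-voxel `values`, plus `mask`,
#'   `affine`, `r_threshold`, `degenerate`, `subject_id`, `condition` (grid
#'   fields are `NULL` for bare-matrix input).
#' @export
degree_map <- function(x, r_threshold = 0.25, block_size = 2048L,
                       weighted = FALSE, subject_id = NULL, condition = NULL) {
  if (!is.numeric(r_threshold) || length(r_threshold) != 1L ||
      r_threshold <= 0 || r_threshold >= 1)
    stop_named("r_threshold", "must lie strictly between 0 and 1")
  std <- standardize_rows(x)
  S <- std$data
  V <- nrow(S)
  check_scalar(block_size, "block_size", lo = 1, integer = TRUE)
  deg <- numeric(V)
  start <- 1L
  while (start <= V) {
    end <- min(start + as.integer(block_size) - 1L, V)
    C <- S %*% t(S[start:end, , drop = FALSE])
    if (weighted) {
      C[C <= r_threshold] <- 0
      deg <- deg + rowSums(C)
    } else {
      deg <- deg + rowSums(C > r_threshold)
    }
    start <- end + 1L
  }
  # remove the self term (r_ii = 1 > threshold for non-degenerate rows)
  deg <- deg - ifelse(std$degenerate, 0, 1)
  deg[std$degenerate] <- 0
  if (!weighted) deg <- as.integer(round(deg))
  structure(list(
    values = deg,
    mask = if (inherits(x, "voxel_ts")) x$mask else NULL,
    affine = if (inherits(x, "voxel_ts")) x$affine else NULL,
    r_threshold = r_threshold,
    degenerate = std$degenerate,
    weighted = weighted,
    subject_id = subject_id,
    condition = condition
  ), class = "degree_map")
}

#' @export
print.degree_map <- function(x, ...) {
  cat("<degree_map> ", length(x$values), " voxels | r > ", x$r_threshold,
      " | degree range [", min(x$values), ", ", max(x$values), "]\n", sep = "")
  invisible(x)
}

#' z-normalise a degree map within subject
#'
#' Standardises the degree values across in-mask voxels (sample SD) so maps
#' are comparable across subjects; the transform is monotone, so the spatial
#' topography (rank order of voxels) is unchanged. When the degree SD is zero
#' all z values are set to 0 with a warning.
#'
#' @param d A [degree_map], or a numeric vector of degrees.
#' @return An object of class `zmap` with the same grid fields.
#' @export
z_normalize <- function(d) {
  vals <- if (inherits(d, "degree_map")) d$values else as.numeric(d)
  if (length(vals) == 0L) stop_named("mask", "empty mask: no voxels")
  s <- sd(vals)
  if (!is.finite(s) || s == 0) {
    warning("degree SD is zero; z map set to 0 everywhere")
    z <- rep(0, length(vals))
  } else {
    z <- (vals - mean(vals)) / s
  }
  structure(list(
    values = z,
    mask = if (inherits(d, "degree_map")) d$mask else NULL,
    affine = if (inherits(d, "degree_map")) d$affine else NULL,
    subject_id = if (inherits(d, "degree_map")) d$subject_id else NULL,
    condition = if (inherits(d, "degree_map")) d$condition else NULL
  ), class = "zmap")
}

#' @export
print.zmap <- function(x, ...) {
  cat("<zmap> ", length(x$values), " voxels",
      if (!is.null(x$subject_id)) paste0(" | ", x$subject_id), "\n", sep = "")
  invisible(x)
}

#' Per-subject hub connectivity map
#'
#' Convenience composition: [run_preprocess], [degree_map], [z_normalize].
#'
#' @inheritParams run_preprocess
#' @param subject_id,condition Identifiers recorded in the map.
#' @return A `zmap` with provenance attached as attribute `"provenance"`.
#' @export
subject_fc_map <- function(scan, nuisance = NULL, config = run_config(),
                           subject_id = NULL, condition = NULL) {
  ts <- run_preprocess(scan, nuisance, config)
  d <- degree_map(ts, r_threshold = config$r_threshold %||% 0.25,
                  subject_id = subject_id, condition = condition)
  z <- z_normalize(d)
  attr(z, "provenance") <- ts$provenance
  z
}

# Stack a list of zmaps (identical masks required) into a subjects x voxels
# matrix; returns list(Z, mask, affine).
stack_zmaps <- function(maps) {
  if (is.matrix(maps)) return(list(Z = maps, mask = NULL, affine = NULL))
  stopifnot(is.list(maps), length(maps) >= 1L)
  ref <- maps[[1]]
  for (m in maps) {
    if (!inherits(m, "zmap")) stop_named("maps", "expected a list of zmap objects")
    if (length(m$values) != length(ref$values) ||
        (!is.null(m$mask) && !identical(dim(m$mask), dim(ref$mask))) ||
        (!is.null(m$mask) && !identical(which(m$mask), which(ref$mask))) ||
        (!is.null(m$affine) && !isTRUE(all.equal(m$affine, ref$affine))))
      stop_named("maps", "mask/affine mismatch between maps")
  }
  list(Z = do.call(rbind, lapply(maps, `[[`, "values")),
       mask = ref$mask, affine = ref$affine)
}
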