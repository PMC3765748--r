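# Shared fixtures and independent oracles, built in code at test time.

# Naive per-pair degree oracle: full correlation matrix via stats::cor,
# strict positive threshold, self excluded, zero-variance rows -> degree 0.
oracle_degree <- function(X, r_threshold = 0.25) {
  keep <- apply(X, 1, sd) > 0
  C <- suppressWarnings(cor(t(X)))
  C[is.na(C)] <- 0
  diag(C) <- 0
  out <- rowSums(C > r_threshold & keep)
  out[!keep] <- 0
  as.integer(out)
}

# Brute-force flood fill (BFS) for connected components of a 3D logical
# array, independent of the package's shifted-offset/graph implementation.
oracle_components <- function(supra, connectivity = 26L) {
  d <- dim(supra)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(offs))
  offs <- switch(as.character(connectivity),
                 "6" = offs[nz == 1, , drop = FALSE],
                 "18" = offs[nz >= 1 & nz <= 2, , drop = FALSE],
                 offs[nz >= 1, , drop = FALSE])
  labels <- array(0L, d)
  nxt <- 0L
  for (start in which(supra)) {
    if (labels[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    labels[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      cc <- arrayInd(cur, d)
      for (r in seq_len(nrow(offs))) {
        nb <- cc + offs[r, ]
        if (any(nb < 1) || any(nb > d)) next
        lin <- nb[1] + d[1] * (nb[2] - 1) + d[1] * d[2] * (nb[3] - 1)
        if (supra[lin] && labels[lin] == 0L) {
          labels[lin] <- nxt
          queue <- c(queue, lin)
        }
      }
    }
  }
  labels
}

# Partition of voxel indices by label, as a canonical set-of-sets (for
# comparing labelings that may number components differently).
partition_sets <- function(labels) {
  lab <- labels[labels > 0]
  idx <- which(labels > 0)
  sets <- split(idx, lab)
  unname(sets[order(vapply(sets, min, 0))])
}

# Small zmap lists on a toy grid, for group-stats tests.
toy_grid <- function(d = c(10L, 10L, 8L), voxel_mm = 4) {
  mask <- array(TRUE, d)
  affine <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  affine[1:3, 4] <- -(d - 1) / 2 * voxel_mm
  list(dim = d, mask = mask, affine = affine)
}

make_zmap <- function(values, grid, subject_id = NULL, condition = NULL) {
  structure(list(values = values, mask = grid$mask, affine = grid$affine,
                 subject_id = subject_id, condition = condition),
            class = "zmap")
}

random_zmaps <- function(n, grid, shift = NULL, sd = 1) {
  V <- sum(grid$mask)
  lapply(seq_len(n), function(i) {
    v <- rnorm(V, sd = sd)
    if (!is.null(shift)) v <- v + shift
    make_zmap(v, grid, subject_id = sprintf("s%02d", i))
  })
}

# Map a spec's source-grid hub region onto a zmap's analysis grid.
hub_on_analysis_grid <- function(spec, z) {
  A_src <- hubfc:::centered_affine(spec$grid_shape, spec$voxel_size_mm)
  W <- hubfc:::trilinear_matrix(spec$grid_shape, A_src, dim(z$mask), z$affine)
  array(as.vector(W %*% as.numeric(spec$hub_region)) >= 0.5, dim(z$mask))
}

# Tiny acquisition spec for fast end-to-end runs.
tiny_spec <- function(n_per_group = 2L, seed = 1L, ...) {
  cohort_spec(n_per_group = n_per_group, grid_shape = c(14L, 14L, 12L),
              n_timepoints = 30L, seed = seed, ...)
}
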