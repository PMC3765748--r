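# Shared internal helpers: affine geometry, Gaussian kernels, grid resampling,
# connected components. World coordinates use the NIfTI convention: the affine
# maps 0-based voxel indices (i, j, k, 1) to world mm.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_named <- function(field, msg) {
  stop(sprintf("[%s] %s", field, msg), call. = FALSE)
}

#' Voxel sizes implied by an affine
#'
#' @param affine 4x4 voxel-to-world matrix.
#' @return Length-3 numeric vector of voxel edge lengths in mm.
#' @keywords internal
affine_voxel_size <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

#' Voxel volume in mm^3 from an affine
#' @keywords internal
affine_voxel_volume <- function(affine) {
  abs(det(affine[1:3, 1:3]))
}

#' Map 0-based voxel indices to world coordinates
#'
#' @param affine 4x4 matrix.
#' @param ijk n x 3 matrix of 0-based voxel indices.
#' @return n x 3 matrix of world mm coordinates.
#' @keywords internal
voxel_to_world <- function(affine, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  out <- cbind(ijk, 1) %*% t(affine)
  out[, 1:3, drop = FALSE]
}

# Default affine for a synthetic grid: isotropic spacing, origin at the grid
# centre so the world frame is centred (left/right mirror pairs share |x|).
centered_affine <- function(dim3, voxel_mm) {
  A <- diag(4)
  A[1, 1] <- A[2, 2] <- A[3, 3] <- voxel_mm
  A[1:3, 4] <- -(dim3 - 1) / 2 * voxel_mm
  A
}

# --- Gaussian smoothing ------------------------------------------------------

# Band matrix applying a discrete Gaussian (sum-normalised, zero-padded at the
# edges) along one axis of length n.
gaussian_band_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  k <- dnorm(seq(-r, r), sd = sigma_vox)
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - r):min(n, i + r)
    K[i, j] <- k[j - i + r + 1L]
  }
  K
}

# Separable 3D Gaussian convolution of a 3D array; sigma in voxels per axis.
smooth_array3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  stopifnot(length(d) == 3L, length(sigma_vox) == 3L)
  if (all(sigma_vox <= 0)) return(arr)
  K1 <- gaussian_band_matrix(d[1], sigma_vox[1])
  K2 <- gaussian_band_matrix(d[2], sigma_vox[2])
  K3 <- gaussian_band_matrix(d[3], sigma_vox[3])
  arr <- array(K1 %*% matrix(arr, d[1]), d)
  a <- aperm(arr, c(2, 1, 3))
  a <- array(K2 %*% matrix(a, d[2]), d[c(2, 1, 3)])
  arr <- aperm(a, c(2, 1, 3))
  a <- aperm(arr, c(3, 1, 2))
  a <- array(K3 %*% matrix(a, d[3]), d[c(3, 1, 2)])
  aperm(a, c(2, 3, 1))
}

# --- Trilinear resampling ----------------------------------------------------

# Sparse matrix mapping a source grid (0-based voxel frame `src_affine`) onto a
# target grid, by trilinear interpolation; out-of-range corners are clamped to
# the boundary (target grids are constructed inside the source FOV).
trilinear_matrix <- function(src_dim, src_affine, tgt_dim, tgt_affine) {
  tg <- as.matrix(expand.grid(
    i = 0:(tgt_dim[1] - 1), j = 0:(tgt_dim[2] - 1), k = 0:(tgt_dim[3] - 1)
  ))
  # target voxel -> world -> source voxel (0-based, fractional)
  world <- cbind(tg, 1) %*% t(tgt_affine)
  src <- world %*% t(solve(src_affine))
  src <- src[, 1:3, drop = FALSE]
  src <- pmax(src, 0)
  src <- sweep(src, 2, src_dim - 1, pmin)
  i0 <- floor(src)
  f <- src - i0
  n_t <- nrow(tg)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ii <- pmin(i0[, 1] + dx, src_dim[1] - 1)
    jj <- pmin(i0[, 2] + dy, src_dim[2] - 1)
    kk <- pmin(i0[, 3] + dz, src_dim[3] - 1)
    w <- (if (dx == 1) f[, 1] else 1 - f[, 1]) *
         (if (dy == 1) f[, 2] else 1 - f[, 2]) *
         (if (dz == 1) f[, 3] else 1 - f[, 3])
    keep <- w > 0
    if (!any(keep)) next
    lin <- ii[keep] + src_dim[1] * (jj[keep] + src_dim[2] * kk[keep]) + 1
    rows <- c(rows, which(keep)); cols <- c(cols, lin)
    vals <- c(vals, w[keep])
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                       dims = c(n_t, prod(src_dim)))
}

# --- Connected components ----------------------------------------------------

connectivity_offsets <- function(connectivity = 26L) {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(offs))
  offs <- switch(as.character(connectivity),
    "6"  = offs[nz == 1, , drop = FALSE],
    "18" = offs[nz >= 1 & nz <= 2, , drop = FALSE],
    "26" = offs[nz >= 1, , drop = FALSE],
    stop_named("connectivity", "must be 6, 18 or 26")
  )
  # keep one offset per +/- pair (edges are undirected)
  keep <- apply(offs, 1, function(o) {
    i <- which(o != 0)
    o[i[1]] > 0
  })
  offs[keep, , drop = FALSE]
}

# Connected components of a 3D logical array. Returns an integer array with
# components labelled 1..n in arbitrary order, plus their sizes.
connected_components3d <- function(supra, connectivity = 26L) {
  d <- dim(supra)
  idx <- which(supra)
  out <- array(0L, d)
  if (length(idx) == 0L) {
    return(list(labels = out, sizes = integer(0)))
  }
  rank <- array(0L, d)
  rank[idx] <- seq_along(idx)
  co <- arrayInd(idx, d)
  offs <- connectivity_offsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(co, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nbl <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1) + d[1] * d[2] * (nb[ok, 3] - 1)
    nr <- rank[nbl]
    sel <- nr > 0L
    if (any(sel)) {
      from <- c(from, rank[idx[ok]][sel])
      to <- c(to, nr[sel])
    }
  }
  g <- igraph::make_graph(edges = rbind(from, to), n = length(idx),
                          directed = FALSE)
  memb <- igraph::components(g)$membership
  out[idx] <- as.integer(memb)
  list(labels = out, sizes = as.integer(table(memb)))
}

# Fast path used inside permutation loops: sizes only.
component_sizes3d <- function(supra, connectivity = 26L) {
  connected_components3d(supra, connectivity)$sizes
}

# --- misc --------------------------------------------------------------------

# AR(1) series with unit marginal variance, vectorised over columns.
# x: T x n matrix of innovations ~ N(0, 1); returns T x n.
ar1_colour <- function(x, phi) {
  if (phi == 0) return(x)
  stopifnot(phi > -1, phi < 1)
  s <- sqrt(1 - phi^2)
  for (t in 2:nrow(x)) x[t, ] <- phi * x[t - 1, ] + s * x[t, ]
  x
}

# Precomputed separable Gaussian smoother for a fixed (grid, frames) shape:
# axis 1 as a dense left multiply, axes 2 and 3 as sparse block-diagonal
# right multiplies (one block per trailing slab), avoiding array permutes.
make_grid_smoother <- function(dim3, n_frames, sigma_vox) {
  d <- as.integer(dim3)
  K1 <- gaussian_band_matrix(d[1], sigma_vox)
  blockdiag_t <- function(K, n_blocks) {
    nz <- which(K != 0, arr.ind = TRUE)   # K[i, j]: out_i <- sum_j K[i,j] in_j
    nb <- nrow(K)
    i <- rep(nz[, 2], n_blocks) + rep((seq_len(n_blocks) - 1L) * nb,
                                      each = nrow(nz))
    j <- rep(nz[, 1], n_blocks) + rep((seq_len(n_blocks) - 1L) * nb,
                                      each = nrow(nz))
    Matrix::sparseMatrix(i = i, j = j, x = rep(K[nz], n_blocks),
                         dims = c(nb * n_blocks, nb * n_blocks))
  }
  B2 <- blockdiag_t(gaussian_band_matrix(d[2], sigma_vox),
                    d[3] * n_frames)
  B3 <- blockdiag_t(gaussian_band_matrix(d[3], sigma_vox), n_frames)
  list(dim = d, n_frames = n_frames, K1 = K1, B2 = B2, B3 = B3)
}

# Apply a make_grid_smoother() operator to a (prod(dim3) x n_frames) matrix.
apply_grid_smoother <- function(sm, m) {
  d <- sm$dim
  Tn <- sm$n_frames
  x <- sm$K1 %*% matrix(m, d[1], d[2] * d[3] * Tn)        # axis 1
  x <- as.matrix(x %*% sm$B2)                             # axis 2 (blockwise)
  x <- as.matrix(matrix(x, d[1] * d[2], d[3] * Tn) %*% sm$B3)  # axis 3
  matrix(x, prod(d), Tn)
}

check_scalar <- function(x, field, lo = -Inf, hi = Inf,
                         integer = FALSE, open_hi = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_named(field, "must be a single finite number")
  if (x < lo || x > hi || (open_hi && x >= hi))
    stop_named(field, sprintf("must be in [%s, %s%s", format(lo),
                              format(hi), if (open_hi) ")" else "]"))
  if (integer && x != round(x))
    stop_named(field, "must be an integer")
  invisible(x)
}
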