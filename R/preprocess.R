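# Resting-state preprocessing chain for already-aligned 4D images:
# drop initial frames -> linear detrend -> zero-phase low-pass -> nine-parameter
# nuisance regression -> Gaussian smoothing -> resampling to the analysis grid.
# Temporal operations act on voxel x time matrices (rows are series).

#' Remove initial non-steady-state frames
#'
#' @param image A [brain_image] (4D) or 4D array.
#' @param k Number of leading frames to drop.
#' @return Same type as the input, with `k` fewer frames.
#' @export
drop_initial_volumes <- function(image, k = 4L) {
  arr <- if (inherits(image, "brain_image")) image$data else image
  if (length(dim(arr)) != 4L) stop_named("image", "must be 4D")
  n <- dim(arr)[4]
  check_scalar(k, "k", lo = 0, integer = TRUE)
  if (k >= n)
    stop_named("k", sprintf("cannot drop %d of %d frames (empty output)", k, n))
  out <- arr[, , , (k + 1L):n, drop = FALSE]
  if (inherits(image, "brain_image")) brain_image(out, image$affine) else out
}

# Accept a voxel_ts or a bare matrix; apply `fn` to the matrix and rebuild.
apply_rows <- function(x, fn, step = NULL) {
  if (inherits(x, "voxel_ts")) {
    out <- x
    out$data <- fn(x$data)
    if (!is.null(step)) out$provenance <- c(x$provenance, list(step))
    out
  } else {
    fn(as.matrix(x))
  }
}

#' Remove per-voxel linear trends
#'
#' Fits and subtracts a least-squares line (intercept + slope * t) from each
#' row; residuals are exactly orthogonal to the constant and linear terms.
#'
#' @param x A [voxel_ts] or a numeric matrix (rows are time series).
#' @return Same type as the input.
#' @export
detrend_linear <- function(x) {
  apply_rows(x, function(m) {
    n <- ncol(m)
    if (n < 3L) stop_named("timepoints", "need at least 3 frames to detrend")
    D <- cbind(1, seq_len(n))
    Q <- qr.Q(qr(D))
    m - (m %*% Q) %*% t(Q)
  }, step = list(op = "detrend_linear"))
}

# Direct-form-II-transposed IIR filter with initial state, vectorised over
# rows of x. b, a: coefficient vectors (a[1] = 1). zi: per-stage state scale
# (as from lfilter_zi), multiplied by the first sample of each row.
iir_filter_rows <- function(x, b, a, zi = NULL) {
  nb <- length(b)
  V <- nrow(x); Tn <- ncol(x)
  z <- matrix(0, V, nb - 1L)
  if (!is.null(zi)) z <- outer(x[, 1], zi)
  y <- matrix(0, V, Tn)
  for (t in seq_len(Tn)) {
    xt <- x[, t]
    yt <- b[1] * xt + z[, 1]
    for (s in seq_len(nb - 2L)) {
      z[, s] <- b[s + 1L] * xt + z[, s + 1L] - a[s + 1L] * yt
    }
    z[, nb - 1L] <- b[nb] * xt - a[nb] * yt
    y[, t] <- yt
  }
  y
}

# Steady-state initial conditions for the direct-form-II-transposed filter
# (unit-step response), so startup transients are minimised.
iir_steady_state <- function(b, a) {
  n <- length(a)
  if (n == 1L) return(numeric(0))
  # companion matrix of a (first column -a[2:n], superdiagonal identity)
  A <- matrix(0, n - 1L, n - 1L)
  A[, 1] <- -a[-1]
  if (n > 2L) A[cbind(seq_len(n - 2L), seq_len(n - 2L) + 1L)] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1L) - A, B)
}

#' Zero-phase low-pass filter
#'
#' Applies a 4th-order Butterworth filter forward and backward (zero net phase)
#' with odd-reflection end padding and steady-state initial conditions, or an
#' FFT brick-wall filter when `kind = "fft"`.
#'
#' @param x A [voxel_ts] or a matrix (rows are series).
#' @param tr_s Sampling interval in seconds (taken from the `voxel_ts` if
#'   omitted).
#' @param cutoff_hz Low-pass cutoff in Hz; must be below Nyquist `1/(2 tr_s)`.
#' @param kind `"butterworth"` (default) or `"fft"`.
#' @param order Butterworth order (default 4).
#' @return Same type as the input.
#' @export
lowpass_filter <- function(x, tr_s = NULL, cutoff_hz = 0.08,
                           kind = c("butterworth", "fft"), order = 4L) {
  kind <- match.arg(kind)
  if (is.null(tr_s) && inherits(x, "voxel_ts")) tr_s <- x$tr_s
  check_scalar(tr_s, "tr_s", lo = .Machine$double.eps)
  nyq <- 1 / (2 * tr_s)
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= nyq)
    stop_named("cutoff_hz",
               sprintf("must lie in (0, Nyquist = %.4g Hz)", nyq))
  fn <- if (kind == "fft") {
    function(m) {
      Tn <- ncol(m)
      freqs <- (seq_len(Tn) - 1) / (Tn * tr_s)
      freqs <- pmin(freqs, 1 / tr_s - freqs)   # two-sided bin frequencies
      keep <- freqs <= cutoff_hz
      ft <- t(stats::mvfft(t(m)))
      ft[, !keep] <- 0
      Re(t(stats::mvfft(t(ft), inverse = TRUE))) / Tn
    }
  } else {
    flt <- signal::butter(order, cutoff_hz / nyq, type = "low")
    b <- flt$b; a <- flt$a
    zi <- iir_steady_state(b, a)
    npad <- 3L * (length(b) - 1L)
    function(m) {
      Tn <- ncol(m)
      if (Tn <= npad)
        stop_named("timepoints",
                   sprintf("need more than %d frames for filtering", npad))
      # odd reflection padding at both ends
      lpad <- 2 * m[, 1] - m[, (npad + 1L):2, drop = FALSE]
      rpad <- 2 * m[, Tn] - m[, (Tn - 1L):(Tn - npad), drop = FALSE]
      mp <- cbind(lpad, m, rpad)
      y <- iir_filter_rows(mp, b, a, zi)
      y <- iir_filter_rows(y[, ncol(y):1, drop = FALSE], b, a, zi)
      y <- y[, ncol(y):1, drop = FALSE]
      y[, (npad + 1L):(npad + Tn), drop = FALSE]
    }
  }
  apply_rows(x, fn, step = list(op = "lowpass_filter", cutoff_hz = cutoff_hz,
                                kind = kind))
}

#' Regress out nuisance series
#'
#' Projects each voxel series onto the orthogonal complement of the nuisance
#' design (an intercept plus the supplied regressors); residuals are orthogonal
#' to every regressor.
#'
#' @param x A [voxel_ts] or matrix (rows are series).
#' @param nuisance Data frame or matrix of nuisance series (columns), same
#'   length as the series in `x`. The conventional set is six motion
#'   parameters plus whole-brain, white-matter and CSF means.
#' @return Same type as the input.
#' @export
regress_nuisance <- function(x, nuisance) {
  N <- as.matrix(nuisance)
  if (anyNA(N)) stop_named("nuisance", "contains missing values")
  fn <- function(m) {
    if (nrow(N) != ncol(m))
      stop_named("nuisance",
                 sprintf("length (%d) must match number of frames (%d)",
                         nrow(N), ncol(m)))
    D <- cbind(intercept = 1, N)
    qrD <- qr(D)
    if (qrD$rank < ncol(D)) {
      bad <- colnames(D)[qrD$pivot[(qrD$rank + 1L):ncol(D)]]
      stop_named("nuisance", paste("design is rank deficient; collinear:",
                                   paste(bad, collapse = ", ")))
    }
    Q <- qr.Q(qrD)
    m - (m %*% Q) %*% t(Q)
  }
  apply_rows(x, fn, step = list(op = "regress_nuisance", n_regressors = ncol(N)))
}

#' Gaussian spatial smoothing
#'
#' Per-frame separable 3D Gaussian convolution with
#' `sigma_mm = fwhm_mm / 2.3548`, converted to voxels per axis from the affine.
#' Kernels are sum-normalised with zero padding, so the image sum is preserved
#' away from the boundary.
#'
#' @param image A [brain_image] (3D or 4D), or an array with `voxel_mm` given.
#' @param fwhm_mm Full width at half maximum in mm; 0 is the identity.
#' @param voxel_mm Voxel sizes (length 1 or 3) when `image` is a bare array.
#' @return Same type as the input.
#' @export
smooth_gaussian <- function(image, fwhm_mm = 4, voxel_mm = NULL) {
  if (!is.numeric(fwhm_mm) || fwhm_mm < 0)
    stop_named("fwhm_mm", "must be >= 0")
  is_bi <- inherits(image, "brain_image")
  arr <- if (is_bi) image$data else image
  vox <- if (is_bi) affine_voxel_size(image$affine) else rep(voxel_mm, length.out = 3)
  if (is.null(vox[1]) || anyNA(vox)) stop_named("voxel_mm", "voxel sizes required")
  if (fwhm_mm == 0) return(image)
  sigma_vox <- (fwhm_mm / 2.3548) / vox
  d <- dim(arr)
  if (length(d) == 3L) {
    out <- smooth_array3d(arr, sigma_vox)
  } else {
    out <- arr
    for (t in seq_len(d[4])) out[, , , t] <- smooth_array3d(arr[, , , t], sigma_vox)
  }
  if (is_bi) brain_image(out, image$affine) else out
}

#' Resample onto an isotropic analysis grid
#'
#' Builds a target grid with the requested isotropic spacing sharing the source
#' origin and lying inside the source field of view, then interpolates.
#' `"trilinear"` works for any factor; `"blockmean"` requires the spacing ratio
#' to be an integer and averages each block of child voxels.
#'
#' @param image A [brain_image] (3D or 4D).
#' @param target_mm Target isotropic voxel size in mm (default 4).
#' @param method `"trilinear"` (default) or `"blockmean"`.
#' @return A [brain_image] on the target grid (frame count unchanged).
#' @export
resample_to_grid <- function(image, target_mm = 4,
                             method = c("trilinear", "blockmean")) {
  method <- match.arg(method)
  image <- as_brain_image(image)
  check_scalar(target_mm, "target_mm", lo = .Machine$double.eps)
  arr <- image$data
  d <- dim(arr)
  sdim <- d[1:3]
  nframes <- if (length(d) == 4L) d[4] else 1L
  vox <- affine_voxel_size(image$affine)

  if (method == "blockmean") {
    fac <- target_mm / vox
    if (any(abs(fac - round(fac)) > 1e-8))
      stop_named("method", "blockmean requires an integer spacing ratio")
    fac <- as.integer(round(fac))
    tdim <- sdim %/% fac
    if (any(tdim < 1L)) stop_named("target_mm", "target grid is empty")
    crop <- arr
    if (length(d) == 3L) dim(crop) <- c(sdim, 1L)
    crop <- crop[seq_len(tdim[1] * fac[1]), seq_len(tdim[2] * fac[2]),
                 seq_len(tdim[3] * fac[3]), , drop = FALSE]
    dim(crop) <- c(fac[1], tdim[1], fac[2], tdim[2], fac[3], tdim[3], nframes)
    out <- apply(crop, c(2, 4, 6, 7), mean)
    tA <- image$affine
    # block centre: offset origin by (fac-1)/2 source voxels, scale spacing
    tA[1:3, 4] <- tA[1:3, 4] + tA[1:3, 1:3] %*% ((fac - 1) / 2)
    tA[1:3, 1:3] <- tA[1:3, 1:3] %*% diag(fac)
  } else {
    tdim <- pmax(1L, as.integer(floor((sdim - 1) * vox / target_mm)) + 1L)
    tA <- image$affine
    tA[1:3, 1:3] <- tA[1:3, 1:3] %*% diag(target_mm / vox)
    W <- trilinear_matrix(sdim, image$affine, tdim, tA)
    m <- matrix(arr, prod(sdim), nframes)
    out <- as.matrix(W %*% m)
    dim(out) <- c(tdim, nframes)
  }
  if (length(d) == 3L) dim(out) <- dim(out)[1:3]
  brain_image(out, tA)
}

#' Brain mask from mean intensity and temporal variance
#'
#' Voxels with nonzero temporal variance and mean intensity above a fraction of
#' the robust image maximum (0.98 quantile of the mean image).
#'
#' @param image 4D [brain_image] or array.
#' @param frac Intensity fraction (default 0.10).
#' @return 3D logical array.
#' @export
mask_from_image <- function(image, frac = 0.10) {
  arr <- if (inherits(image, "brain_image")) image$data else image
  if (length(dim(arr)) != 4L) stop_named("image", "must be 4D")
  d <- dim(arr)
  m <- matrix(arr, prod(d[1:3]), d[4])
  mu <- rowMeans(m)
  v <- rowSums((m - mu)^2)
  robust_max <- quantile(mu, 0.98, names = FALSE)
  array(mu > frac * robust_max & v > 0, d[1:3])
}

#' Full preprocessing chain
#'
#' Applies, in order: initial-volume dropping, linear detrending, zero-phase
#' low-pass filtering, nuisance regression, Gaussian smoothing, resampling to
#' the analysis grid, and in-mask extraction. Each stage can be disabled
#' through the configuration; a provenance log of applied steps is attached.
#'
#' @param scan Path to a 4D NIfTI, a [brain_image], or a 4D array with the
#'   affine supplied via `config$affine`.
#' @param nuisance Path to a nuisance TSV (columns `mot1..mot6, global, wm,
#'   csf`), a data frame, or `NULL` to skip nuisance regression.
#' @param config A [run_config] list; relevant keys: `drop_k`, `detrend`,
#'   `cutoff_hz` (`NULL` disables), `filter_kind`, `fwhm_mm`, `target_mm`
#'   (`NULL` disables), `mask_source` (`"auto"`, `"all"`, or a 3D mask array
#'   on the analysis grid), `tr_s`.
#' @return A [voxel_ts] on the analysis grid with provenance.
#' @export
run_preprocess <- function(scan, nuisance = NULL, config = run_config()) {
  img <- if (is.character(scan)) read_volume(scan) else
    as_brain_image(scan, config$affine)
  if (length(dim(img$data)) != 4L) stop_named("scan", "must be 4D")
  tr_s <- config$tr_s %||% 3
  prov <- list()
  nuis <- NULL
  if (!is.null(nuisance)) {
    nuis <- if (is.character(nuisance)) read_nuisance(nuisance) else
      as.data.frame(nuisance)
  }

  k <- config$drop_k %||% 4L
  if (k > 0) {
    img <- drop_initial_volumes(img, k)
    if (!is.null(nuis)) nuis <- nuis[-seq_len(k), , drop = FALSE]
    prov <- c(prov, list(list(op = "drop_initial_volumes", k = k)))
  }
  d <- dim(img$data)
  nframes <- d[4]
  if (!is.null(nuis) && nrow(nuis) != nframes)
    stop_named("nuisance",
               sprintf("length (%d) must match number of frames (%d)",
                       nrow(nuis), nframes))

  # mask is estimated from the raw (post-drop) data, before mean removal
  mask_src <- NULL
  if (identical(config$mask_source %||% "auto", "auto"))
    mask_src <- mask_from_image(img)

  m <- matrix(img$data, prod(d[1:3]), nframes)
  nmat <- if (!is.null(nuis)) t(as.matrix(nuis)) else NULL
  if (isTRUE(config$detrend %||% TRUE)) {
    m <- detrend_linear(m)
    # regressors receive the same treatment as the data, so regression
    # removes exactly the nuisance component the data still carry
    if (!is.null(nmat)) nmat <- detrend_linear(nmat)
    prov <- c(prov, list(list(op = "detrend_linear")))
  }
  if (!is.null(config$cutoff_hz)) {
    m <- lowpass_filter(m, tr_s = tr_s, cutoff_hz = config$cutoff_hz,
                        kind = config$filter_kind %||% "butterworth")
    if (!is.null(nmat))
      nmat <- lowpass_filter(nmat, tr_s = tr_s, cutoff_hz = config$cutoff_hz,
                             kind = config$filter_kind %||% "butterworth")
    prov <- c(prov, list(list(op = "lowpass_filter",
                              cutoff_hz = config$cutoff_hz)))
  }
  if (!is.null(nmat)) {
    keep <- apply(nmat, 1, function(r) sd(r) > 1e-10)
    m <- regress_nuisance(m, t(nmat[keep, , drop = FALSE]))
    prov <- c(prov, list(list(op = "regress_nuisance")))
  }
  img <- brain_image(array(m, d), img$affine)

  fwhm <- config$fwhm_mm %||% 4
  if (fwhm > 0) {
    img <- smooth_gaussian(img, fwhm_mm = fwhm)
    prov <- c(prov, list(list(op = "smooth_gaussian", fwhm_mm = fwhm)))
  }

  if (!is.null(config$target_mm)) {
    src_affine <- img$affine
    src_dim <- dim(img$data)[1:3]
    img <- resample_to_grid(img, target_mm = config$target_mm,
                            method = config$resample_method %||% "trilinear")
    if (!is.null(mask_src)) {
      W <- trilinear_matrix(src_dim, src_affine, dim(img$data)[1:3], img$affine)
      mask_src <- array(as.vector(W %*% as.numeric(mask_src)) >= 0.5,
                        dim(img$data)[1:3])
    }
    prov <- c(prov, list(list(op = "resample_to_grid",
                              target_mm = config$target_mm)))
  }

  ms <- config$mask_source %||% "auto"
  mask <- if (is.array(ms)) {
    array(as.logical(ms), dim(ms))
  } else if (identical(ms, "all")) {
    array(TRUE, dim(img$data)[1:3])
  } else {
    mask_src
  }
  if (!identical(dim(mask), dim(img$data)[1:3]))
    stop_named("mask_source", "mask grid does not match the analysis grid")

  d2 <- dim(img$data)
  dat <- matrix(img$data, prod(d2[1:3]), d2[4])[as.vector(mask), , drop = FALSE]
  voxel_ts(dat, mask, img$affine, tr_s, provenance = prov)
}

#' Read a nuisance table
#'
#' @param path TSV with header columns `mot1..mot6, global, wm, csf`.
#' @return Data frame of nuisance series.
#' @export
read_nuisance <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c(paste0("mot", 1:6), "global", "wm", "csf")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_named("nuisance", paste("missing columns:",
                                 paste(missing_cols, collapse = ", ")))
  if (anyNA(df)) stop_named("nuisance", "contains missing values")
  df[need]
}
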