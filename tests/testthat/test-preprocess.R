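# Preprocessing chain: frame dropping, detrending, zero-phase low-pass,
# nuisance regression, smoothing, resampling, and the composed pipeline.

test_that("initial volumes are dropped frame-exactly", {
  arr <- array(rnorm(4 * 4 * 3 * 12), c(4, 4, 3, 12))
  out <- drop_initial_volumes(arr, 4)
  expect_equal(dim(out)[4], 8L)
  expect_equal(out[, , , 1], arr[, , , 5])
  expect_identical(drop_initial_volumes(arr, 0), arr)
  expect_error(drop_initial_volumes(arr[, , , 1:10, drop = FALSE], 10), "k")
})

test_that("linear detrending removes trends and matches least squares", {
  t <- 1:40
  # pure trend -> zeros; constants -> zeros
  expect_equal(max(abs(detrend_linear(rbind(2 + 0.5 * t)))), 0,
               tolerance = 1e-10)
  expect_equal(max(abs(detrend_linear(rbind(rep(3, 40))))), 0,
               tolerance = 1e-10)
  # an oscillation even about the midpoint is orthogonal to the trend on
  # symmetric support: unchanged up to numerical tolerance
  y <- cos(2 * pi * (t - mean(t)) / 20)
  dt <- as.vector(detrend_linear(rbind(y)))
  ref <- unname(resid(lm(y ~ t)))
  expect_equal(dt, ref, tolerance = 1e-10)
  expect_lt(max(abs(dt - y)), 1e-8)
  # a sinusoid with a trend-correlated phase is handled by the same oracle
  y2 <- sin(2 * pi * t / 20)
  expect_equal(as.vector(detrend_linear(rbind(y2))),
               unname(resid(lm(y2 ~ t))), tolerance = 1e-10)
  # residual orthogonality to [1, t]
  set.seed(1)
  m <- matrix(rnorm(30 * 40), 30)
  r <- detrend_linear(m)
  expect_lt(max(abs(r %*% cbind(1, t))) / max(abs(m)), 1e-8)
  expect_error(detrend_linear(matrix(1, 2, 2)), "timepoints")
})

test_that("low-pass filter passes slow and rejects fast components", {
  tr <- 3; t <- seq_len(116)
  slow <- sin(2 * pi * 0.01 * tr * t)
  fast <- sin(2 * pi * 0.15 * tr * t)
  fs <- lowpass_filter(rbind(slow), tr_s = tr)
  ff <- lowpass_filter(rbind(fast), tr_s = tr)
  expect_gt(max(abs(fs)), 0.9 * max(abs(slow)))             # within 10%
  expect_lt(max(abs(ff[20:90])), max(abs(fast)) / 10)       # >= 10x reduced
  # stopband attenuation at 1.5x cutoff exceeds 20 dB
  mid <- sin(2 * pi * 0.12 * tr * t)
  fm <- lowpass_filter(rbind(mid), tr_s = tr)
  expect_lt(max(abs(fm[20:90])), max(abs(mid)) / 10)
  # constants (DC) unchanged; cutoff must stay below Nyquist
  expect_equal(as.vector(lowpass_filter(rbind(rep(5, 116)), tr_s = 3)),
               rep(5, 116), tolerance = 1e-10)
  expect_error(lowpass_filter(rbind(slow), tr_s = 3, cutoff_hz = 0.2),
               "cutoff")
})

test_that("low-pass filter is zero-phase and matches the reference IIR", {
  tr <- 3; t <- seq_len(116)
  x <- sin(2 * pi * 0.03 * tr * t)
  y <- as.vector(lowpass_filter(rbind(x), tr_s = tr))
  lags <- -3:3
  cc <- sapply(lags, function(l) cor(x[(20 + l):(90 + l)], y[20:90]))
  expect_equal(lags[which.max(cc)], 0)
  # the vectorised recursion agrees with signal::filter (single pass, zero IC)
  flt <- signal::butter(4, 0.08 / (1 / 6), "low")
  set.seed(2)
  z <- rnorm(200)
  mine <- as.vector(hubfc:::iir_filter_rows(rbind(z), flt$b, flt$a))
  ref <- as.vector(signal::filter(flt, z))
  expect_equal(mine, ref, tolerance = 1e-12)
  # FFT variant removes an exact-bin stopband sinusoid entirely
  f_bin <- 50 / (116 * tr)    # ~0.144 Hz, an exact DFT bin above cutoff
  yf <- lowpass_filter(rbind(sin(2 * pi * f_bin * tr * t)), tr_s = tr,
                       kind = "fft")
  expect_lt(max(abs(yf)), 1e-10)
})

test_that("nuisance regression orthogonalises against the design", {
  set.seed(3)
  n <- 60
  N <- as.data.frame(matrix(rnorm(n * 9), n))
  names(N) <- c(paste0("mot", 1:6), "global", "wm", "csf")
  # voxel equal to a regressor -> residual zero
  r1 <- regress_nuisance(rbind(N$mot1), N)
  expect_lt(max(abs(r1)), 1e-10)
  # voxel orthogonal to all regressors -> unchanged
  Q <- qr.Q(qr(cbind(1, as.matrix(N))))
  v <- rnorm(n); v <- v - Q %*% crossprod(Q, v)
  expect_equal(as.vector(regress_nuisance(rbind(as.vector(v)), N)),
               as.vector(v), tolerance = 1e-8)
  # mixed voxel: residual decorrelated from the global series
  x <- rnorm(n) + 0.7 * N$global
  rx <- as.vector(regress_nuisance(rbind(x), N))
  expect_lt(abs(sum(rx * N$global)), 1e-10)
  expect_equal(rx, unname(resid(lm(x ~ ., data = N))), tolerance = 1e-8)
  # collinear design names the offending columns
  N2 <- N; N2$csf <- N2$wm
  expect_error(regress_nuisance(rbind(x), N2), "csf|wm")
})

test_that("Gaussian smoothing preserves mass and matches the kernel", {
  arr <- array(0, c(11, 11, 9))
  arr[6, 6, 5] <- 1
  sm <- smooth_gaussian(arr, fwhm_mm = 4, voxel_mm = 3)
  # peak equals the product of the three 1D kernel centres
  sigma <- (4 / 2.3548) / 3
  r <- ceiling(4 * sigma)
  k <- dnorm(seq(-r, r), sd = sigma); k <- k / sum(k)
  expect_equal(sm[6, 6, 5], k[r + 1]^3, tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-3)   # interior support
  # identity and invariances
  expect_identical(smooth_gaussian(arr, fwhm_mm = 0, voxel_mm = 3), arr)
  const <- array(2, c(8, 8, 8))
  smc <- smooth_gaussian(const, fwhm_mm = 4, voxel_mm = 3)
  expect_equal(smc[3:6, 3:6, 3:6], const[3:6, 3:6, 3:6], tolerance = 1e-6)
  expect_error(smooth_gaussian(arr, fwhm_mm = -1, voxel_mm = 3), "fwhm")
})

test_that("resampling handles constants, block means and linear ramps", {
  A2 <- diag(c(2, 2, 2, 1))
  # constant image stays constant on the new grid
  cimg <- brain_image(array(7, c(8, 8, 8)), A2)
  out <- resample_to_grid(cimg, target_mm = 4)
  expect_equal(affine_voxel_size(out$affine), rep(4, 3))
  expect_equal(as.vector(out$data), rep(7, length(out$data)))
  # integer-factor block mean equals the mean of the 8 children
  set.seed(4)
  arr <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  bm <- resample_to_grid(brain_image(arr, A2), target_mm = 4,
                         method = "blockmean")
  expect_equal(dim(bm$data), c(4L, 4L, 4L))
  expect_equal(bm$data[2, 3, 1], mean(arr[3:4, 5:6, 1:2]), tolerance = 1e-12)
  # trilinear reproduces a world-linear ramp exactly at the sample points
  A3 <- diag(c(3, 3, 3, 1)); A3[1:3, 4] <- c(-10, -8, -6)
  d <- c(10L, 9L, 8L)
  g <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                             k = 0:(d[3] - 1)))
  W <- cbind(g, 1) %*% t(A3)
  ramp <- array(2 + 0.5 * W[, 1] - 0.25 * W[, 2] + 0.1 * W[, 3], d)
  rs <- resample_to_grid(brain_image(ramp, A3), target_mm = 4)
  d2 <- dim(rs$data)
  g2 <- as.matrix(expand.grid(i = 0:(d2[1] - 1), j = 0:(d2[2] - 1),
                              k = 0:(d2[3] - 1)))
  W2 <- cbind(g2, 1) %*% t(rs$affine)
  expect_equal(as.vector(rs$data),
               as.vector(2 + 0.5 * W2[, 1] - 0.25 * W2[, 2] + 0.1 * W2[, 3]),
               tolerance = 1e-10)
  expect_error(resample_to_grid(cimg, target_mm = 3, method = "blockmean"),
               "integer")
})

test_that("the composed pipeline yields the documented analysis grid", {
  spec <- cohort_spec(n_per_group = 1L, seed = 5L)   # default 24x24x18, T=120
  dd <- withr::local_tempdir()
  co <- generate_cohort(spec, dd, write_labels = FALSE)
  i <- which(co$condition == "single")[1]
  ts <- run_preprocess(co$image[i], co$nuisance[i], run_config())
  expect_s3_class(ts, "voxel_ts")
  expect_equal(ncol(ts$data), 116L)                        # 120 - 4 frames
  expect_equal(affine_voxel_size(ts$affine), rep(4, 3))    # 4 mm grid
  expect_equal(nrow(ts$data), sum(ts$mask))
  ops <- vapply(ts$provenance, `[[`, "", "op")
  expect_equal(ops, c("drop_initial_volumes", "detrend_linear",
                      "lowpass_filter", "regress_nuisance",
                      "smooth_gaussian", "resample_to_grid"))
  # determinism: the same inputs give bit-identical outputs
  ts2 <- run_preprocess(co$image[i], co$nuisance[i], run_config())
  expect_identical(ts$data, ts2$data)
  # residual orthogonality to the (filtered) nuisance design happens on the
  # acquisition grid; here check the mask is stable across frames
  expect_true(all(colSums(abs(ts$data)) > 0))
})

test_that("a disabled configuration passes data through unchanged", {
  set.seed(6)
  arr <- array(rnorm(6 * 6 * 5 * 10, mean = 100), c(6, 6, 5, 10))
  A <- diag(c(3, 3, 3, 1))
  cfg <- run_config(drop_k = 0L, detrend = FALSE, cutoff_hz = NULL,
                    fwhm_mm = 0, target_mm = NULL, mask_source = "all",
                    affine = A)
  ts <- run_preprocess(arr, nuisance = NULL, config = cfg)
  expect_equal(ts$data, matrix(arr, 180, 10))
  expect_length(ts$provenance, 0L)
})

test_that("mismatched nuisance length is rejected", {
  arr <- array(rnorm(6 * 6 * 5 * 10, mean = 100), c(6, 6, 5, 10))
  N <- as.data.frame(matrix(rnorm(9 * 9), 9))
  names(N) <- c(paste0("mot", 1:6), "global", "wm", "csf")
  cfg <- run_config(drop_k = 0L, affine = diag(c(3, 3, 3, 1)))
  expect_error(run_preprocess(arr, N, cfg), "nuisance")
})
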