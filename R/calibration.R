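# Reduced-scale calibration harnesses for the group-level inference: the
# family-wise false-positive rate of the permutation cluster correction under
# pure-noise cohorts, and the recovery of a planted hub-coupling effect.
#
# Subject maps are synthesised directly at the 4 mm analysis grid: spatially
# correlated AR(1) noise (the pipeline's net spatial smoothness: 4 mm FWHM
# acquisition-grid smoothing plus the smoothing introduced by trilinear
# resampling from 3 to 4 mm), an optional planted hub, then the actual
# degree-map and z-normalisation code. The temporal preprocessing stages
# (detrend, low-pass, nuisance regression) are linear and preserve the null,
# so they are skipped here for speed; the full chain is exercised end to end
# elsewhere.

# Net spatial smoothing sigma (in 4 mm analysis voxels) reproducing the
# pipeline's spatial correlation structure (4 mm FWHM smoothing on the 3 mm
# acquisition grid followed by trilinear resampling). Calibrated so the
# harness's null z maps match the full pipeline's z-map neighbour correlation
# (~0.37 for adjacent in-mask voxels, measured over pipeline scans).
net_sigma_vox_4mm <- 0.68

# Low-pass filtering with the ideal (FFT) filter confines every series to the
# passband subspace: for AR(1) noise at TR 3 s filtered at 0.08 Hz, a
# 116-frame series is exactly a weighted sum of 27 cosine/sine pairs (the DC
# term is removed by mean-centring). Pearson correlations between voxels
# equal the correlations of their weighted Fourier coefficients, so subjects
# can be simulated in this 54-dimensional representation at identical
# statistics and less than half the cost. Coefficient SDs follow the AR(1)
# spectrum at the passband frequencies.
harness_basis_sd <- function(n_timepoints = 116L, tr_s = 3, ar1_coef = 0.3,
                             cutoff_hz = 0.08) {
  k <- seq_len(n_timepoints - 1L)
  f <- k / (n_timepoints * tr_s)
  keep <- k[f <= cutoff_hz & k <= n_timepoints / 2]
  om <- 2 * pi * keep / n_timepoints
  s_ar <- (1 - ar1_coef^2) / (1 - 2 * ar1_coef * cos(om) + ar1_coef^2)
  rep(sqrt(s_ar), each = 2L)   # cosine and sine coefficient per frequency
}

# Precomputed operators shared by all simulated subjects on one grid.
make_harness_ops <- function(grid, n_timepoints = 116L,
                             sigma_vox = net_sigma_vox_4mm, ar1_coef = 0.3,
                             cutoff_hz = 0.08, tr_s = 3) {
  sd_k <- harness_basis_sd(n_timepoints, tr_s, ar1_coef, cutoff_hz)
  list(
    smoother = make_grid_smoother(grid$dim, length(sd_k), sigma_vox),
    sd_k = sd_k,
    n_timepoints = n_timepoints
  )
}

#' Analysis-grid geometry used by the calibration harnesses
#'
#' The default acquisition grid (24 x 24 x 18 at 3 mm) resampled to the 4 mm
#' analysis grid, with the ellipsoidal brain mask.
#'
#' @param grid_shape Acquisition grid (default `c(24, 24, 18)`).
#' @param voxel_size_mm Acquisition voxel size (default 3).
#' @param target_mm Analysis voxel size (default 4).
#' @return List with `dim`, `affine`, `mask` (3D logical).
#' @export
analysis_grid <- function(grid_shape = c(24L, 24L, 18L), voxel_size_mm = 3,
                          target_mm = 4) {
  src_affine <- centered_affine(grid_shape, voxel_size_mm)
  tdim <- pmax(1L, as.integer(floor((grid_shape - 1) * voxel_size_mm /
                                      target_mm)) + 1L)
  tA <- src_affine
  tA[1:3, 1:3] <- tA[1:3, 1:3] %*% diag(rep(target_mm / voxel_size_mm, 3))
  W <- trilinear_matrix(grid_shape, src_affine, tdim, tA)
  mask_src <- brain_mask_for(grid_shape)
  mask <- array(as.vector(W %*% as.numeric(mask_src)) >= 0.5, tdim)
  list(dim = tdim, affine = tA, mask = mask)
}

#' Simulate one subject's z map at the analysis grid
#'
#' Spectrally coloured Gaussian noise (AR(1) background shaped by the
#' zero-phase low-pass) over the analysis grid, an optional planted hub
#' (shared latent series added to hub voxels before spatial smoothing), the
#' pipeline-equivalent spatial smoothing, in-mask extraction, then
#' [degree_map] and [z_normalize].
#'
#' @param grid An [analysis_grid] list.
#' @param n_timepoints Frames (default 116, a 6-min run at TR 3 s after
#'   dropping 4 volumes).
#' @param hub_idx In-mask voxel indices of the hub (or `NULL`).
#' @param rho Target hub pairwise correlation before smoothing.
#' @param ar1_coef Temporal AR(1) coefficient (default 0.3).
#' @param sigma_vox Spatial smoothing sigma in voxels (default: the
#'   pipeline-equivalent net smoothness).
#' @param r_threshold Degree threshold (default 0.25).
#' @param subject_id,condition Identifiers for the resulting map.
#' @param ops Precomputed operators from an internal cache; computed when
#'   `NULL`.
#' @return A `zmap`.
#' @export
simulate_subject_zmap <- function(grid, n_timepoints = 116L, hub_idx = NULL,
                                  rho = 0, ar1_coef = 0.3,
                                  sigma_vox = net_sigma_vox_4mm,
                                  r_threshold = 0.25, subject_id = NULL,
                                  condition = NULL, ops = NULL) {
  d <- grid$dim
  V <- prod(d)
  ops <- ops %||% make_harness_ops(grid, n_timepoints, sigma_vox, ar1_coef)
  nk <- length(ops$sd_k)
  e <- matrix(rnorm(nk * V), nk, V) * ops$sd_k
  X <- apply_grid_smoother(ops$smoother, t(e))
  X <- X[as.vector(grid$mask), , drop = FALSE]
  if (!is.null(hub_idx) && rho > 0) {
    # plant the shared latent after smoothing, scaled per voxel, so the hub
    # voxels' pairwise correlation at the analysis stage is rho (smoothing
    # the latent itself would inflate the realised coupling: spatial
    # averaging alone pushes pre-smoothing correlations far above rho)
    w <- sqrt(rho / (1 - rho))
    s <- rnorm(nk) * ops$sd_k
    s <- s / sqrt(sum(s^2))
    nrm <- sqrt(rowSums(X[hub_idx, , drop = FALSE]^2))
    X[hub_idx, ] <- X[hub_idx, ] + outer(w * nrm, s)
  }
  dm <- degree_map(voxel_ts(X, grid$mask, grid$affine, 3),
                   r_threshold = r_threshold, subject_id = subject_id,
                   condition = condition)
  z_normalize(dm)
}

#' Family-wise false-positive rate of the cluster correction
#'
#' Simulates pure-noise cohorts (two groups, no planted effect), runs the
#' two-sample permutation cluster correction on each, and reports whether any
#' cluster reached significance. With `min_voxels = 1` (default here) this
#' measures the calibration of the permutation mechanism itself; the
#' analysis-default 10-voxel candidate filter can only remove candidates and
#' therefore only lowers the rate.
#'
#' @param n_reps Number of simulated cohorts (default 200).
#' @param n_per_group Subjects per group (default 18).
#' @param n_timepoints Frames per scan (default 116).
#' @param n_perm Permutations per cohort (default 99).
#' @param z_threshold Cluster-forming threshold (default 2.3).
#' @param min_voxels Candidate filter (default 1; see above).
#' @param alpha Cluster-level level (default 0.05).
#' @param seed Integer seed.
#' @param grid An [analysis_grid]; default geometry when `NULL`.
#' @return Logical vector (length `n_reps`): any significant cluster; with
#'   attribute `"min_p"` (smallest cluster p per rep, `NA` when no
#'   candidates).
#' @export
calibrate_fwer <- function(n_reps = 200L, n_per_group = 18L,
                           n_timepoints = 116L, n_perm = 99L,
                           z_threshold = 2.3, min_voxels = 1L, alpha = 0.05,
                           seed = 1L, grid = NULL) {
  grid <- grid %||% analysis_grid()
  set.seed(seed)
  ops <- make_harness_ops(grid, n_timepoints)
  any_sig <- logical(n_reps)
  min_p <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    maps <- lapply(seq_len(2L * n_per_group), function(i)
      simulate_subject_zmap(grid, n_timepoints,
                            subject_id = sprintf("s%02d", i), ops = ops))
    res <- permutation_cluster_correct(
      maps, group = rep(c("A", "B"), each = n_per_group),
      test_kind = "two_sample", z_threshold = z_threshold,
      min_voxels = min_voxels, n_perm = n_perm, alpha = alpha)
    any_sig[r] <- any(res$table$significant)
    if (nrow(res$table)) min_p[r] <- min(res$table$cluster_p)
  }
  attr(any_sig, "min_p") <- min_p
  any_sig
}

#' Recovery of a planted hub-coupling effect
#'
#' Simulates paired patient cohorts in which hub coupling rises from
#' `rho_lp` to `rho_hp` (per-subject couplings jittered), with pain-rating
#' changes generated as `intercept + slope * delta_coupling + noise`. For each
#' replicate, reports whether the paired high-vs-low contrast yields a
#' corrected significant cluster overlapping the hub, and whether the
#' regression of map changes on rating changes recovers a positive slope at
#' the hub.
#'
#' @param n_reps Replicates (default 50).
#' @param n_subjects Patients (default 18).
#' @param hub_size Hub size in analysis-grid voxels (default 50).
#' @param rho_lp,rho_hp Low-/high-pain hub couplings (defaults 0.3, 0.5).
#' @param coupling_sd Between-subject coupling SD (default 0.06).
#' @param pain_slope,pain_intercept,pain_noise_sd Rating-change model
#'   (defaults 9.5, 1, 0.8).
#' @param n_timepoints Frames (default 116).
#' @param n_perm Permutations (default 99).
#' @param z_threshold,min_voxels Cluster parameters (defaults 2.3, 10).
#' @param alpha Cluster level (default 0.05).
#' @param seed Integer seed.
#' @return Data frame per replicate: `detected` (significant cluster
#'   overlapping the hub), `slope_positive` (hub-mean regression slope > 0).
#' @export
planted_effect_recovery <- function(n_reps = 50L, n_subjects = 18L,
                                    hub_size = 50L, rho_lp = 0.3,
                                    rho_hp = 0.5, coupling_sd = 0.06,
                                    pain_slope = 9.5, pain_intercept = 1,
                                    pain_noise_sd = 0.8, n_timepoints = 116L,
                                    n_perm = 99L, z_threshold = 2.3,
                                    min_voxels = 10L, alpha = 0.05,
                                    seed = 1L) {
  grid <- analysis_grid()
  set.seed(seed)
  ops <- make_harness_ops(grid, n_timepoints)
  # compact hub: the `hub_size` in-mask voxels closest to an interior point
  d <- grid$dim
  co <- arrayInd(which(grid$mask), d)
  target <- colMeans(co) + c(2, 0, 1)
  dist2 <- rowSums(sweep(co, 2, target)^2)
  hub_idx <- order(dist2)[seq_len(hub_size)]
  hub_mask3 <- array(FALSE, d)
  hub_mask3[which(grid$mask)[hub_idx]] <- TRUE

  out <- data.frame(detected = logical(n_reps),
                    slope_positive = logical(n_reps))
  for (r in seq_len(n_reps)) {
    lp <- vector("list", n_subjects); hp <- vector("list", n_subjects)
    d_pain <- numeric(n_subjects)
    for (i in seq_len(n_subjects)) {
      r_lp <- clip01(rho_lp + rnorm(1, sd = coupling_sd), 0.02, 0.95)
      r_hp <- clip01(rho_hp + rnorm(1, sd = coupling_sd), 0.02, 0.95)
      sid <- sprintf("s%02d", i)
      lp[[i]] <- simulate_subject_zmap(grid, n_timepoints, hub_idx, r_lp,
                                       subject_id = sid, condition = "LP",
                                       ops = ops)
      hp[[i]] <- simulate_subject_zmap(grid, n_timepoints, hub_idx, r_hp,
                                       subject_id = sid, condition = "HP",
                                       ops = ops)
      d_pain[i] <- pain_intercept + pain_slope * (r_hp - r_lp) +
        rnorm(1, sd = pain_noise_sd)
    }
    res <- permutation_cluster_correct(
      hp, maps2 = lp, test_kind = "paired", z_threshold = z_threshold,
      min_voxels = min_voxels, n_perm = n_perm, alpha = alpha)
    det <- FALSE
    if (nrow(res$table_significant)) {
      sig_ids <- as.integer(sub("cluster_", "", res$table_significant$region))
      overlap <- (res$clusters > 0) &
        array(res$clusters %in% sig_ids, dim(res$clusters)) & hub_mask3
      det <- any(overlap)
    }
    delta <- mapply(function(a, b) {
      z <- a; z$values <- a$values - b$values; z
    }, hp, lp, SIMPLIFY = FALSE)
    reg <- covariate_regression_map(delta, d_pain)
    out$detected[r] <- det
    out$slope_positive[r] <- mean(reg$slope[hub_idx]) > 0
  }
  out
}
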