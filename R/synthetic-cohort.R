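# Seeded synthetic cohorts emulating the study design: two groups of 18
# subjects, controls scanned once, patients scanned in a low-pain (LP) and a
# high-pain (HP) state; a compact "hub" region whose inter-voxel coupling
# differs by group and condition; pain-rating changes linearly related to
# coupling changes. All signal and noise parameters are plain-number defaults
# chosen to make the preprocessing stages consequential, not fitted to data.

#' Specification of a synthetic cohort
#'
#' @param n_per_group Subjects per group (default 18).
#' @param grid_shape Acquisition grid in voxels (default 24 x 24 x 18).
#' @param voxel_size_mm Acquisition voxel size (default 3 mm isotropic).
#' @param n_timepoints Frames per scan (default 120: a 6-minute run at TR 3 s).
#' @param tr_s Repetition time in seconds (default 3).
#' @param hub_region 3D logical array on the grid, or `NULL` for the default
#'   compact box (6 x 6 x 3 voxels) inside the brain.
#' @param coupling_control,coupling_lp,coupling_hp Target pairwise correlation
#'   of hub voxels for controls and for the patients' low-/high-pain scans
#'   (defaults 0.4, 0.3, 0.5).
#' @param coupling_sd Between-subject SD of the per-scan coupling (default
#'   0.06); couplings are truncated to `[0.02, 0.95]`.
#' @param ar1_coef Temporal AR(1) coefficient of the noise, in `[0, 1)`
#'   (default 0.3).
#' @param drift_amplitude Peak-to-peak linear drift, in baseline units
#'   (default 2).
#' @param nuisance_amplitude Mixing weight of the global nuisance series into
#'   voxel signals (default 0.5).
#' @param bold_amplitude Scale of the neural signal component (default 1).
#' @param baseline Mean in-brain image intensity (default 1000).
#' @param pain_slope,pain_intercept,pain_noise_sd Parameters of
#'   `delta_pain = intercept + slope * delta_coupling + noise` (defaults 9.5,
#'   1, 0.8; with the default couplings the mean rating increase is ~2.9
#'   points on the 0-10 scale).
#' @param rating_lp_mean,rating_lp_sd Low-pain rating distribution (defaults
#'   3.8, 2).
#' @param rating_jitter_sd SD of the pre/post rating jitter around the scan's
#'   rating level (default 0.3).
#' @param resting_subjects Integer indices of patients whose planted coupling
#'   change is forced to zero (a patient who rested instead of exercising);
#'   default none.
#' @param seed Integer seed; identical spec + seed gives byte-identical files.
#' @return Validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 18L,
                        grid_shape = c(24L, 24L, 18L),
                        voxel_size_mm = 3,
                        n_timepoints = 120L,
                        tr_s = 3,
                        hub_region = NULL,
                        coupling_control = 0.4,
                        coupling_lp = 0.3,
                        coupling_hp = 0.5,
                        coupling_sd = 0.06,
                        ar1_coef = 0.3,
                        drift_amplitude = 2,
                        nuisance_amplitude = 0.5,
                        bold_amplitude = 1,
                        baseline = 1000,
                        pain_slope = 9.5,
                        pain_intercept = 1,
                        pain_noise_sd = 0.8,
                        rating_lp_mean = 3.8,
                        rating_lp_sd = 2,
                        rating_jitter_sd = 0.3,
                        resting_subjects = integer(0),
                        seed = 1L) {
  check_scalar(n_per_group, "n_per_group", lo = 1, integer = TRUE)
  if (length(grid_shape) != 3L || any(grid_shape < 4))
    stop_named("grid_shape", "must be 3 positive dimensions (>= 4 voxels)")
  check_scalar(voxel_size_mm, "voxel_size_mm", lo = .Machine$double.eps)
  check_scalar(n_timepoints, "n_timepoints", lo = 8, integer = TRUE)
  check_scalar(tr_s, "tr_s", lo = .Machine$double.eps)
  check_scalar(coupling_control, "coupling_control", lo = 0, hi = 1,
               open_hi = TRUE)
  check_scalar(coupling_lp, "coupling_lp", lo = 0, hi = 1, open_hi = TRUE)
  check_scalar(coupling_hp, "coupling_hp", lo = 0, hi = 1, open_hi = TRUE)
  check_scalar(coupling_sd, "coupling_sd", lo = 0)
  check_scalar(ar1_coef, "ar1_coef", lo = 0, hi = 1, open_hi = TRUE)
  check_scalar(drift_amplitude, "drift_amplitude", lo = 0)
  check_scalar(nuisance_amplitude, "nuisance_amplitude", lo = 0)
  check_scalar(bold_amplitude, "bold_amplitude", lo = 0)
  check_scalar(pain_noise_sd, "pain_noise_sd", lo = 0)
  check_scalar(rating_jitter_sd, "rating_jitter_sd", lo = 0)
  check_scalar(seed, "seed", integer = TRUE)
  grid_shape <- as.integer(grid_shape)
  if (!is.null(hub_region)) {
    if (!identical(dim(hub_region), grid_shape))
      stop_named("hub_region", "mask must match grid_shape")
    hub_region <- array(as.logical(hub_region), grid_shape)
  }
  structure(as.list(environment()), class = "cohort_spec")
}

# Ellipsoidal "brain" mask filling ~30% of the acquisition grid.
brain_mask_for <- function(grid_shape, frac = 0.42) {
  d <- grid_shape
  c0 <- (d - 1) / 2
  ax <- frac * d
  g <- expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1), k = 0:(d[3] - 1))
  array(((g$i - c0[1]) / ax[1])^2 + ((g$j - c0[2]) / ax[2])^2 +
          ((g$k - c0[3]) / ax[3])^2 <= 1, d)
}

# Default hub: a compact box near the grid centre (inside the brain mask).
default_hub_region <- function(grid_shape) {
  d <- grid_shape
  hub <- array(FALSE, d)
  cx <- round(d / 2)
  hub[(cx[1] - 2):(cx[1] + 3), (cx[2] - 2):(cx[2] + 3),
      (cx[3] - 1):(cx[3] + 1)] <- TRUE
  hub
}

#' Plant a correlated hub into a noise volume
#'
#' Hub voxels receive `w * s(t) + e_i(t)` with a shared unit-variance latent
#' series `s` and unit-variance noise `e_i`, where `w = sqrt(rho / (1 - rho))`,
#' so the expected pairwise correlation of two hub voxels is `rho`
#' (`r = w^2 / (w^2 + 1)`). Non-hub voxels are pure noise.
#'
#' @param grid_shape 3D grid dimensions.
#' @param hub_mask 3D logical array marking hub voxels.
#' @param rho Target pairwise correlation, in `[0, 1)`.
#' @param n_timepoints Number of frames.
#' @param ar1_coef Optional AR(1) colouring of latent and noise (unit marginal
#'   variance, so `rho` is unchanged); default 0 (i.i.d.).
#' @return 4D array (`grid_shape` x `n_timepoints`).
#' @export
plant_hub_signal <- function(grid_shape, hub_mask, rho, n_timepoints,
                             ar1_coef = 0) {
  check_scalar(rho, "rho", lo = 0, hi = 1, open_hi = TRUE)
  check_scalar(n_timepoints, "n_timepoints", lo = 2, integer = TRUE)
  d <- as.integer(grid_shape)
  V <- prod(d)
  if (!identical(dim(hub_mask), d))
    stop_named("hub_mask", "must match grid_shape")
  w <- sqrt(rho / (1 - rho))
  e <- matrix(rnorm(n_timepoints * V), n_timepoints, V)
  if (ar1_coef > 0) e <- ar1_colour(e, ar1_coef)
  if (w > 0) {
    s <- rnorm(n_timepoints)
    if (ar1_coef > 0) s <- as.vector(ar1_colour(matrix(s), ar1_coef))
    hub <- as.vector(hub_mask)
    e[, hub] <- e[, hub] + w * s
  }
  array(t(e), c(d, n_timepoints))
}

# Nuisance series for one scan: six slow motion traces plus global/WM/CSF
# means, written as the conventional nine-column table.
make_nuisance <- function(n_timepoints, ar1_coef) {
  mot <- sapply(1:6, function(i)
    cumsum(rnorm(n_timepoints, sd = 0.02)))
  phys <- sapply(1:3, function(i)
    as.vector(ar1_colour(matrix(rnorm(n_timepoints)), max(ar1_coef, 0.5))))
  df <- as.data.frame(cbind(mot, phys))
  names(df) <- c(paste0("mot", 1:6), "global", "wm", "csf")
  df
}

# Assemble one scan: baseline + hub/noise signal + drift + nuisance mixing,
# with near-zero background outside the brain mask.
synthesize_scan <- function(spec, brain, hub, rho, nuisance) {
  d <- spec$grid_shape
  Tn <- spec$n_timepoints
  arr <- plant_hub_signal(d, hub, rho, Tn, ar1_coef = spec$ar1_coef)
  m <- matrix(arr, prod(d), Tn)
  m <- m * spec$bold_amplitude
  drift <- spec$drift_amplitude * (seq_len(Tn) / Tn - 0.5)
  g_load <- rnorm(prod(d), mean = 1, sd = 0.3)
  m <- m + outer(rep(1, prod(d)), drift) +
    spec$nuisance_amplitude * outer(g_load, nuisance$global)
  b <- as.vector(brain)
  m[b, ] <- m[b, ] + spec$baseline
  m[!b, ] <- m[!b, ] * 0.01
  array(m, c(d, Tn))
}

clip01 <- function(x, lo = 0, hi = 10) pmin(hi, pmax(lo, x))

#' Generate a synthetic cohort on disk
#'
#' Writes, per scan, a 4D NIfTI image and a nine-column nuisance TSV; one
#' label-volume NIfTI per subject (patients carry the inflated top third) plus
#' a template label image; and a cohort TSV with columns `subject_id, group,
#' condition, image, nuisance, labels, rating_pre, rating_post`. Patients get
#' LP and HP scans, controls a single scan. Deterministic under the spec seed.
#'
#' @param spec A [cohort_spec].
#' @param out_dir Output directory (created if needed).
#' @param write_labels Write per-subject label volumes (default `TRUE`).
#' @return The cohort table (invisibly also written to
#'   `file.path(out_dir, "cohort.tsv")`), with attribute `"spec"`.
#' @export
generate_cohort <- function(spec = cohort_spec(), out_dir,
                            write_labels = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0) stop_named("out_dir", "not writable")
  set.seed(spec$seed)
  d <- spec$grid_shape
  affine <- centered_affine(d, spec$voxel_size_mm)
  brain <- brain_mask_for(d)
  hub <- spec$hub_region %||% default_hub_region(d)
  if (!any(hub & brain))
    stop_named("hub_region", "hub does not intersect the brain mask")

  write_volume(brain_image(array(as.numeric(brain), d), affine),
               file.path(out_dir, "brain_mask.nii.gz"), datatype = "uint8")

  rows <- list()
  add_scan <- function(sid, group, condition, rho, rating) {
    nuis <- make_nuisance(spec$n_timepoints, spec$ar1_coef)
    img <- synthesize_scan(spec, brain, hub, rho, nuis)
    img_path <- file.path(out_dir, sprintf("%s_%s.nii.gz", sid, condition))
    nuis_path <- file.path(out_dir, sprintf("%s_%s_nuisance.tsv", sid,
                                            condition))
    write_volume(brain_image(img, affine), img_path)
    utils::write.table(format(nuis, digits = 8, trim = TRUE), nuis_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jit <- rnorm(2, sd = spec$rating_jitter_sd)
    rows[[length(rows) + 1L]] <<- data.frame(
      subject_id = sid, group = group, condition = condition,
      image = basename(img_path), nuisance = basename(nuis_path),
      labels = NA_character_,
      rating_pre = round(clip01(rating + jit[1]), 2),
      rating_post = round(clip01(rating + jit[2]), 2)
    )
  }

  truncate_rho <- function(x) clip01(x, 0.02, 0.95)
  n <- spec$n_per_group
  for (i in seq_len(n)) {
    sid <- sprintf("sub-P%02d", i)
    rho_lp <- truncate_rho(spec$coupling_lp + rnorm(1, sd = spec$coupling_sd))
    rho_hp <- if (i %in% spec$resting_subjects) rho_lp else
      truncate_rho(spec$coupling_hp + rnorm(1, sd = spec$coupling_sd))
    d_pain <- spec$pain_intercept + spec$pain_slope * (rho_hp - rho_lp) +
      rnorm(1, sd = spec$pain_noise_sd)
    r_lp <- clip01(rnorm(1, spec$rating_lp_mean, spec$rating_lp_sd))
    r_hp <- clip01(r_lp + d_pain)
    add_scan(sid, "patient", "LP", rho_lp, r_lp)
    add_scan(sid, "patient", "HP", rho_hp, r_hp)
  }
  for (i in seq_len(n)) {
    sid <- sprintf("sub-C%02d", i)
    rho <- truncate_rho(spec$coupling_control +
                          rnorm(1, sd = spec$coupling_sd))
    add_scan(sid, "control", "single", rho, 0)
  }
  cohort <- do.call(rbind, rows)

  lv <- generate_label_volume()
  write_volume(brain_image(lv$labels, lv$affine),
               file.path(out_dir, "labels_template.nii.gz"),
               datatype = "int16")
  if (write_labels) {
    for (sid in unique(cohort$subject_id)) {
      is_pat <- cohort$group[match(sid, cohort$subject_id)] == "patient"
      vs <- clip01(rnorm(1, 1, 0.17), 0.5, 1.6)
      lvs <- generate_label_volume(
        top_third_scale = if (is_pat) 1.13 else 1,
        volume_scale = vs
      )
      lp <- file.path(out_dir, sprintf("%s_labels.nii.gz", sid))
      write_volume(brain_image(lvs$labels, lvs$affine), lp,
                   datatype = "int16")
      cohort$labels[cohort$subject_id == sid] <- basename(lp)
    }
  }
  utils::write.table(cohort, file.path(out_dir, "cohort.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  # returned table carries resolved paths; the TSV stays relative/portable
  for (col in c("image", "nuisance", "labels")) {
    ok <- !is.na(cohort[[col]])
    cohort[[col]][ok] <- file.path(out_dir, cohort[[col]][ok])
  }
  attr(cohort, "spec") <- spec
  invisible(cohort)
}

#' Generate a mirror-symmetric pair of elongated labels
#'
#' Ellipsoidal (or box) stand-in for an elongated cortical structure, with a
#' controllable long axis and an optional inflation of the top third
#' (patient-like labels). Left (label 1) and right (label 2) structures are
#' mirror images across the world x = 0 plane.
#'
#' @param grid_shape Label grid (default 48 x 48 x 50).
#' @param voxel_mm Isotropic voxel size (default 1.2 mm, a typical structural
#'   resolution).
#' @param axis World-space direction of the long axis before mirroring
#'   (default mostly superior); need not be normalised.
#' @param length_mm Full axial length (default 40).
#' @param radius_mm Cross-section radius (default 10.5; with the default
#'   length the bilateral top third measures ~4.8 cm^3, a realistic scale for
#'   an elongated cortical structure).
#' @param center_mm World centre of the right-side structure (default
#'   `c(14, -4, 6)`); the left side is its x mirror.
#' @param top_third_scale Volume inflation factor of the top third (cross
#'   section widened by its square root; default 1 = none).
#' @param volume_scale Whole-structure volume scale (linear dimensions scaled
#'   by its cube root; default 1).
#' @param shape `"ellipsoid"` (default) or `"box"`.
#' @param rotation Optional 3x3 rotation applied to the axis frame.
#' @return Object of class `label_volume`: `labels` (0/1/2 int array),
#'   `affine`, `ids = c(left = 1, right = 2)`, and `meta` (true axes, centres
#'   and construction parameters).
#' @export
generate_label_volume <- function(grid_shape = c(48L, 48L, 50L),
                                  voxel_mm = 1.2,
                                  axis = c(0, 0.35, 0.94),
                                  length_mm = 40, radius_mm = 10.5,
                                  center_mm = c(14, -4, 6),
                                  top_third_scale = 1,
                                  volume_scale = 1,
                                  shape = c("ellipsoid", "box"),
                                  rotation = NULL) {
  shape <- match.arg(shape)
  if (sqrt(sum(axis^2)) < 1e-12) stop_named("axis", "must be nonzero")
  check_scalar(length_mm, "length_mm", lo = .Machine$double.eps)
  check_scalar(radius_mm, "radius_mm", lo = .Machine$double.eps)
  check_scalar(top_third_scale, "top_third_scale", lo = .Machine$double.eps)
  check_scalar(volume_scale, "volume_scale", lo = .Machine$double.eps)
  grid_shape <- as.integer(grid_shape)
  affine <- centered_affine(grid_shape, voxel_mm)
  ax <- axis / sqrt(sum(axis^2))
  if (!is.null(rotation)) ax <- as.vector(rotation %*% ax)
  s_lin <- volume_scale^(1 / 3)
  half_len <- length_mm / 2 * s_lin
  rad <- radius_mm * s_lin

  g <- expand.grid(i = 0:(grid_shape[1] - 1), j = 0:(grid_shape[2] - 1),
                   k = 0:(grid_shape[3] - 1))
  W <- voxel_to_world(affine, as.matrix(g))

  inside_side <- function(center, ax_side) {
    P <- sweep(W, 2, center)
    q <- as.vector(P %*% ax_side)             # axial coordinate, mm
    r_eff <- rep(rad, nrow(P))
    if (top_third_scale != 1) {
      top <- q > half_len / 3                 # upper third of the axial extent
      r_eff[top] <- rad * sqrt(top_third_scale)
    }
    if (shape == "ellipsoid") {
      perp2 <- pmax(0, rowSums(P^2) - q^2)
      (q / half_len)^2 + perp2 / r_eff^2 <= 1
    } else {
      # square cross-section: orthonormal frame perpendicular to the axis
      e <- if (abs(ax_side[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      u1 <- e - sum(e * ax_side) * ax_side
      u1 <- u1 / sqrt(sum(u1^2))
      u2 <- c(ax_side[2] * u1[3] - ax_side[3] * u1[2],
              ax_side[3] * u1[1] - ax_side[1] * u1[3],
              ax_side[1] * u1[2] - ax_side[2] * u1[1])
      abs(q) <= half_len & abs(P %*% u1) <= r_eff & abs(P %*% u2) <= r_eff
    }
  }
  cR <- center_mm
  cL <- center_mm * c(-1, 1, 1)
  axR <- ax
  axL <- ax * c(-1, 1, 1)
  half_extent <- (grid_shape - 1) / 2 * voxel_mm
  r_max <- rad * sqrt(max(top_third_scale, 1))
  for (side in list(list(c = cR, a = axR), list(c = cL, a = axL))) {
    # axis-aligned support of the (inflated) ellipsoid/box around its centre
    ext <- sqrt(half_len^2 * side$a^2 + r_max^2 * (1 - side$a^2))
    if (shape == "box") ext <- half_len * abs(side$a) +
        r_max * sqrt(pmax(0, 1 - side$a^2)) * sqrt(2)
    if (any(abs(side$c) + ext > half_extent + voxel_mm / 2))
      stop_named("grid_shape", "label exceeds the grid")
  }
  labs <- array(0L, grid_shape)
  labs[inside_side(cL, axL)] <- 1L
  labs[inside_side(cR, axR)] <- 2L
  structure(list(labels = labs, affine = affine,
                 ids = c(left = 1L, right = 2L),
                 meta = list(axis_left = axL, axis_right = axR,
                             center_left = cL, center_right = cR,
                             length_mm = length_mm * s_lin,
                             radius_mm = rad,
                             top_third_scale = top_third_scale,
                             volume_scale = volume_scale, shape = shape)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$labels), collapse = " x "),
      " | left ", sum(x$labels == 1L), " vox, right ", sum(x$labels == 2L),
      " vox\n", sep = "")
  invisible(x)
}

#' Simulate per-subject section volumes for two groups
#'
#' Generates one label volume per subject with a lognormal-like whole-structure
#' size jitter (so the between-subject coefficient of variation is
#' controllable) and, for the first group, an inflated top third; measures the
#' bilateral top-third volume through [principal_axis], [split_thirds] and
#' [section_volume].
#'
#' @param n_per_group Subjects per group (default 18).
#' @param top_third_scale_patients Inflation factor of patients' top third
#'   (default 1.13).
#' @param cv Between-subject coefficient of variation of structure volume
#'   (default 0.17).
#' @param seed Integer seed.
#' @param ... Passed to [generate_label_volume].
#' @return Data frame: `subject_id`, `group`, `top_mm3`, `middle_mm3`,
#'   `bottom_mm3`, `total_mm3` (bilateral sums).
#' @export
simulate_volumetry_cohort <- function(n_per_group = 18L,
                                      top_third_scale_patients = 1.13,
                                      cv = 0.17, seed = 1L, ...) {
  set.seed(seed)
  one <- function(sid, group) {
    vs <- clip01(rnorm(1, 1, cv), 0.4, 2)
    lv <- generate_label_volume(
      top_third_scale = if (group == "patient") top_third_scale_patients else 1,
      volume_scale = vs, ...)
    vols <- sapply(c(left = 1L, right = 2L), function(id) {
      ss <- split_thirds(lv, id = id)
      c(top = section_volume(ss, "top"),
        middle = section_volume(ss, "middle"),
        bottom = section_volume(ss, "bottom"))
    })
    data.frame(subject_id = sid, group = group,
               top_mm3 = sum(vols["top", ]),
               middle_mm3 = sum(vols["middle", ]),
               bottom_mm3 = sum(vols["bottom", ]),
               total_mm3 = sum(vols))
  }
  out <- list()
  for (i in seq_len(n_per_group))
    out[[length(out) + 1L]] <- one(sprintf("sub-P%02d", i), "patient")
  for (i in seq_len(n_per_group))
    out[[length(out) + 1L]] <- one(sprintf("sub-C%02d", i), "control")
  do.call(rbind, out)
}

#' Packaged demographics table
#'
#' Loads the demographics and clinical characteristics fixture shipped with
#' the package: 18 chronic low-back-pain patients (gender, age, race,
#' depression score, pain duration in years, average pain inventory score on
#' the 0-10 scale) and 18 matched pain-free controls (gender, age, race).
#'
#' @return Data frame with columns `subject_id`, `group`, `gender`, `age`,
#'   `race`, `bdi`, `duration_yrs`, `bpi_avg` (clinical columns are `NA` for
#'   controls).
#' @export
load_demographics_fixture <- function() {
  path <- system.file("extdata", "cohort_demographics.tsv", package = "hubfc",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
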