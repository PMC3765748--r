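# Run configuration and the umbrella end-to-end analysis: per-scan hub maps,
# the three group contrasts (controls vs LP, controls vs HP, HP vs LP paired),
# the pain-change regression, and the ROI-thirds volumetric comparison.

#' Analysis configuration with study defaults
#'
#' All stage parameters in one validated list. Unknown keys are rejected.
#'
#' @param ... Overrides of the defaults: `drop_k` (4), `detrend` (TRUE),
#'   `cutoff_hz` (0.08; `NULL` disables), `filter_kind` ("butterworth"),
#'   `fwhm_mm` (4), `target_mm` (4; `NULL` disables), `resample_method`
#'   ("trilinear"), `mask_source` ("auto"), `tr_s` (3), `r_threshold` (0.25),
#'   `z_threshold` (2.3), `min_voxels` (10), `connectivity` (26), `n_perm`
#'   (499), `alpha` (0.05), `seed` (1), `affine` (for bare-array input).
#' @return Named list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    drop_k = 4L, detrend = TRUE, cutoff_hz = 0.08,
    filter_kind = "butterworth", fwhm_mm = 4, target_mm = 4,
    resample_method = "trilinear", mask_source = "auto", tr_s = 3,
    r_threshold = 0.25, z_threshold = 2.3, min_voxels = 10L,
    connectivity = 26L, n_perm = 499L, alpha = 0.05, seed = 1L,
    affine = NULL
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop_named("config", paste("unknown keys:", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, over, keep.null = TRUE)
  check_scalar(cfg$drop_k, "drop_k", lo = 0, integer = TRUE)
  if (!is.null(cfg$cutoff_hz)) check_scalar(cfg$cutoff_hz, "cutoff_hz",
                                            lo = .Machine$double.eps)
  check_scalar(cfg$fwhm_mm, "fwhm_mm", lo = 0)
  if (!is.null(cfg$target_mm)) check_scalar(cfg$target_mm, "target_mm",
                                            lo = .Machine$double.eps)
  check_scalar(cfg$r_threshold, "r_threshold", lo = 0, hi = 1, open_hi = TRUE)
  if (cfg$r_threshold <= 0) stop_named("r_threshold", "must be positive")
  check_scalar(cfg$z_threshold, "z_threshold", lo = .Machine$double.eps)
  check_scalar(cfg$min_voxels, "min_voxels", lo = 1, integer = TRUE)
  if (!cfg$connectivity %in% c(6L, 18L, 26L))
    stop_named("connectivity", "must be 6, 18 or 26")
  check_scalar(cfg$n_perm, "n_perm", lo = 99, integer = TRUE)
  check_scalar(cfg$alpha, "alpha", lo = 1e-6, hi = 0.5)
  check_scalar(cfg$seed, "seed", integer = TRUE)
  structure(cfg, class = c("run_config", "list"))
}

#' Load a configuration from YAML
#'
#' @param path YAML file with `key: value` overrides.
#' @return A [run_config].
#' @export
read_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  writeLines(msg, con)
  message(msg)
}

#' End-to-end hub connectivity analysis
#'
#' Runs the whole pipeline on a cohort: per-scan z-normalised degree maps;
#' two-sample contrasts between controls and each patient condition (both
#' directions), the paired high-pain vs low-pain contrast (both directions),
#' and the regression of the per-patient map change on the pain-rating change;
#' cluster tables with permutation-corrected p values; per-subject mean z over
#' the top significant cluster; and, when per-subject label volumes are
#' available, the bilateral top-third volume comparison.
#'
#' @param cohort Path to a cohort TSV (see [read_cohort]) or a `cohort_table`.
#' @param out_dir Report directory (created if needed).
#' @param config A [run_config].
#' @return List of result objects (contrast tables, volumes, paths), invisibly
#'   written under `out_dir`.
#' @export
run_end_to_end <- function(cohort, out_dir, config = run_config()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (!"rating" %in% names(cohort))
    cohort$rating <- (cohort$rating_pre + cohort$rating_post) / 2
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(logf), add = TRUE)
  set.seed(config$seed)
  scalar <- vapply(config, function(x) is.atomic(x) && length(x) == 1L, TRUE)
  yaml::write_yaml(unclass(config)[scalar],
                   file.path(out_dir, "config_resolved.yaml"))
  log_line(logf, "cohort: ", nrow(cohort), " scans, seed ", config$seed)

  maps <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    maps[[i]] <- subject_fc_map(cohort$image[i], cohort$nuisance[i], config,
                                subject_id = cohort$subject_id[i],
                                condition = cohort$condition[i])
  }
  log_line(logf, "computed ", length(maps), " z maps (",
           length(maps[[1]]$values), " in-mask voxels)")
  zdir <- file.path(out_dir, "zmaps")
  dir.create(zdir, showWarnings = FALSE)
  for (m in maps) {
    write_volume(brain_image(map_to_array(m$values, m$mask), m$affine),
                 file.path(zdir, sprintf("%s_%s_zmap.nii.gz", m$subject_id,
                                         m$condition)))
  }

  is_ctrl <- cohort$condition == "single"
  is_lp <- cohort$condition == "LP"
  is_hp <- cohort$condition == "HP"
  ctrl <- maps[is_ctrl]; lp <- maps[is_lp]; hp <- maps[is_hp]
  results <- list(maps = maps, contrasts = list())

  run_two_sample <- function(mA, mB, name) {
    res <- permutation_cluster_correct(
      c(mA, mB), group = rep(c("A", "B"), c(length(mA), length(mB))),
      test_kind = "two_sample", z_threshold = config$z_threshold,
      min_voxels = config$min_voxels, connectivity = config$connectivity,
      n_perm = config$n_perm, alpha = config$alpha)
    write_cluster_table(res$table,
                        file.path(out_dir, paste0(name, "_clusters.tsv")))
    log_line(logf, name, ": ", nrow(res$table), " candidate cluster(s), ",
             sum(res$table$significant), " significant")
    res
  }

  if (length(ctrl) >= 2 && length(lp) >= 2) {
    results$contrasts$controls_gt_lp <-
      run_two_sample(ctrl, lp, "controls_gt_lp")
    results$contrasts$lp_gt_controls <-
      run_two_sample(lp, ctrl, "lp_gt_controls")
    results$contrasts$controls_gt_hp <-
      run_two_sample(ctrl, hp, "controls_gt_hp")
    results$contrasts$hp_gt_controls <-
      run_two_sample(hp, ctrl, "hp_gt_controls")
  }

  if (length(lp) >= 7 && length(hp) == length(lp)) {
    for (dir_name in c("hp_gt_lp", "lp_gt_hp")) {
      m1 <- if (dir_name == "hp_gt_lp") hp else lp
      m2 <- if (dir_name == "hp_gt_lp") lp else hp
      res <- permutation_cluster_correct(
        m1, maps2 = m2, test_kind = "paired",
        z_threshold = config$z_threshold, min_voxels = config$min_voxels,
        connectivity = config$connectivity, n_perm = config$n_perm,
        alpha = config$alpha)
      write_cluster_table(res$table,
                          file.path(out_dir, paste0(dir_name, "_clusters.tsv")))
      log_line(logf, dir_name, ": ", nrow(res$table),
               " candidate cluster(s), ", sum(res$table$significant),
               " significant")
      results$contrasts[[dir_name]] <- res
    }
    # mean z over the top paired cluster, per subject and condition (scatter data)
    top <- results$contrasts$hp_gt_lp
    if (nrow(top$table_significant)) {
      cl_mask <- top$clusters == 1L
      scatter <- rbind(extract_mean_z(lp, cl_mask), extract_mean_z(hp, cl_mask))
      write_cluster_table(scatter, file.path(out_dir, "mean_z_scatter.tsv"))
      results$mean_z <- scatter
    }
    # regression of the HP-LP map change on the pain-rating change
    pat_ids <- vapply(lp, `[[`, "", "subject_id")
    hp_ids <- vapply(hp, `[[`, "", "subject_id")
    hp <- hp[match(pat_ids, hp_ids)]
    delta <- mapply(function(a, b) {
      d <- a; d$values <- a$values - b$values; d$condition <- "HP-LP"; d
    }, hp, lp, SIMPLIFY = FALSE)
    ratings <- function(cond) cohort$rating[match(paste(pat_ids, cond),
                                paste(cohort$subject_id, cohort$condition))]
    d_pain <- ratings("HP") - ratings("LP")
    if (var(d_pain) > 0) {
      reg <- permutation_cluster_correct(
        delta, covariate = d_pain, test_kind = "regression",
        z_threshold = config$z_threshold, min_voxels = config$min_voxels,
        connectivity = config$connectivity, n_perm = config$n_perm,
        alpha = config$alpha)
      write_cluster_table(reg$table,
                          file.path(out_dir, "pain_regression_clusters.tsv"))
      log_line(logf, "pain regression: ", nrow(reg$table),
               " candidate cluster(s), ", sum(reg$table$significant),
               " significant")
      results$contrasts$pain_regression <- reg
    } else {
      log_line(logf, "pain regression skipped: zero rating-change variance")
    }
  } else if (!length(lp)) {
    warning("no patient scans: paired and regression stages skipped")
    log_line(logf, "paired/regression stages skipped (controls only)")
  }

  if ("labels" %in% names(cohort) && !anyNA(cohort$labels)) {
    first <- !duplicated(cohort$subject_id)
    vols <- do.call(rbind, lapply(which(first), function(i) {
      lv <- read_volume(cohort$labels[i])
      tops <- sapply(1:2, function(id) {
        ss <- split_thirds(lv$data, lv$affine, id = id)
        section_volume(ss, "top")
      })
      data.frame(subject_id = cohort$subject_id[i], group = cohort$group[i],
                 top_mm3 = bilateral_volume(tops[1], tops[2]))
    }))
    write_cluster_table(vols, file.path(out_dir, "roi_top_third_volumes.tsv"))
    pat <- vols$top_mm3[vols$group == "patient"]
    ctl <- vols$top_mm3[vols$group == "control"]
    if (length(pat) >= 2 && length(ctl) >= 2) {
      cmpv <- compare_group_volumes(pat, ctl)
      log_line(logf, sprintf(
        "top third volumes: patients %.0f mm3, controls %.0f mm3, p = %.3g",
        mean(pat), mean(ctl), cmpv$p))
      results$volumes <- list(table = vols, comparison = cmpv)
    } else {
      results$volumes <- list(table = vols, comparison = NULL)
    }
  }
  log_line(logf, "done")
  invisible(results)
}
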