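# Cohort bookkeeping: validated loading of the scan table, descriptive
# statistics in the style of a demographics table, and lossless cluster-table
# round trips.

#' Read and validate a cohort table
#'
#' The cohort TSV has one row per scan with columns `subject_id, group,
#' condition, image, nuisance, rating_pre, rating_post` (an optional `labels`
#' column is carried through). Controls must have exactly one scan
#' (`condition = "single"`); patients exactly two (`LP` and `HP`). Each scan's
#' rating is the mean of its pre- and post-scan ratings, added as `rating`.
#'
#' @param path Path to the TSV.
#' @param base_dir Directory against which relative file paths are resolved
#'   (default: the TSV's directory).
#' @return Validated data frame of class `cohort_table`.
#' @export
read_cohort <- function(path, base_dir = dirname(path)) {
  if (!file.exists(path)) stop_named("path", paste("no such file:", path))
  df <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                 error = function(e) stop_named("cohort", "empty or unreadable file"))
  if (nrow(df) == 0L) stop_named("cohort", "empty cohort table")
  need <- c("subject_id", "group", "condition", "image", "nuisance",
            "rating_pre", "rating_post")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_named("cohort", paste("missing columns:",
                               paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(df[c("subject_id", "condition")]))
    stop_named("cohort", "duplicate subject_id/condition rows")
  if (!all(df$group %in% c("patient", "control")))
    stop_named("group", "must be 'patient' or 'control'")
  for (col in c("rating_pre", "rating_post")) {
    if (!is.numeric(df[[col]]) || anyNA(df[[col]]) ||
        any(df[[col]] < 0 | df[[col]] > 10))
      stop_named(col, "ratings must be numeric within [0, 10]")
  }
  for (sid in unique(df$subject_id)) {
    rows <- df[df$subject_id == sid, ]
    if (rows$group[1] == "control") {
      if (nrow(rows) != 1L || rows$condition != "single")
        stop_named("cohort", sprintf(
          "control %s must have exactly one 'single' scan", sid))
    } else {
      if (nrow(rows) != 2L || !setequal(rows$condition, c("LP", "HP")))
        stop_named("cohort", sprintf(
          "patient %s must have exactly one LP and one HP scan", sid))
    }
  }
  df$rating <- (df$rating_pre + df$rating_post) / 2
  for (col in c("image", "nuisance", "labels")) {
    if (col %in% names(df)) {
      rel <- !is.na(df[[col]]) & !grepl("^(/|[A-Za-z]:)", df[[col]])
      df[[col]][rel] <- file.path(base_dir, df[[col]][rel])
    }
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Descriptive statistics per group
#'
#' Group-wise mean and sample SD (n - 1 denominator) of the demographic and
#' clinical columns present (`age`, `bdi`, `duration_yrs`, `bpi_avg`), plus
#' gender counts. Means and SDs of age are rounded to one decimal, other
#' variables to two. Groups with a single subject report `NA` for the SD.
#'
#' @param table Data frame with a `group` column (e.g. from
#'   [load_demographics_fixture]).
#' @return Data frame with one row per group and summary columns.
#' @export
summarize_cohort <- function(table) {
  if (!nrow(table)) stop_named("table", "empty table")
  num_cols <- intersect(c("age", "bdi", "duration_yrs", "bpi_avg"),
                        names(table))
  groups <- unique(table$group)
  rows <- lapply(groups, function(g) {
    sub <- table[table$group == g, , drop = FALSE]
    out <- data.frame(group = g, n = nrow(sub))
    if ("gender" %in% names(table)) {
      out$n_female <- sum(sub$gender == "F", na.rm = TRUE)
      out$n_male <- sum(sub$gender == "M", na.rm = TRUE)
    }
    for (col in num_cols) {
      v <- sub[[col]][!is.na(sub[[col]])]
      digits <- if (col == "age") 1L else 2L
      out[[paste0(col, "_mean")]] <-
        if (length(v)) round(mean(v), digits) else NA_real_
      out[[paste0(col, "_sd")]] <-
        if (length(v) >= 2L) round(sd(v), digits) else NA_real_
    }
    out
  })
  do.call(rbind, rows)
}

#' Write / read a cluster table
#'
#' TSV serialisation of cluster report tables; write-then-read round-trips
#' losslessly (including the empty, header-only case).
#'
#' @param ct Cluster table data frame.
#' @param path Output path.
#' @return `path` invisibly (write); the table (read).
#' @export
write_cluster_table <- function(ct, path) {
  ok <- tryCatch({
    utils::write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_named("path", paste("cannot write", path))
  invisible(path)
}

#' @rdname write_cluster_table
#' @export
read_cluster_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
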