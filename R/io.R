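#' Write a study to CSV (plus ground truth as JSON)
#'
#' Writes `observations.csv`, `profiles.csv`, `reference_means.csv`, and —
#' for synthetic studies — `truth.json` into `dir`.
#'
#' @param study A `sim_study` from [generate_study()], or a list with
#'   `observations`, `profiles`, `reference` (and optionally `truth`).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the named vector of written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(observations = file.path(dir, "observations.csv"),
             profiles = file.path(dir, "profiles.csv"),
             reference = file.path(dir, "reference_means.csv"))
  write.csv(study$observations, paths["observations"], row.names = FALSE)
  write.csv(study$profiles, paths["profiles"], row.names = FALSE)
  write.csv(study$reference, paths["reference"], row.names = FALSE)
  if (!is.null(study$truth)) {
    paths <- c(paths, truth = file.path(dir, "truth.json"))
    jsonlite::write_json(unclass(study$truth), paths["truth"],
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, colnames(df))
  if (length(miss) > 0)
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read study tables from CSV
#'
#' @param path CSV file path.
#' @return data.frame with the expected schema.
#' @name read_tables
NULL

#' @rdname read_tables
#' @export
read_observations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("school_id", "domain", "grade", "year", "mean", "se"),
                "observations table")
  if (is.null(df$cohort_id)) df$cohort_id <- assign_cohort(df$year, df$grade)
  if (is.null(df$centred)) df$centred <- FALSE
  df
}

#' @rdname read_tables
#' @export
read_profiles <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("school_id", "year", "icsea", "enrolments",
                      "prop_girls", "sector", "exposure_group"),
                "profiles table")
  df
}

#' @rdname read_tables
#' @export
read_reference_means <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("year", "grade", "domain", "reference_mean"),
                "reference-means table")
  dup <- duplicated(df[, c("year", "grade", "domain")])
  if (any(dup))
    stop("reference-means table has duplicate (year, grade, domain) rows")
  df
}
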