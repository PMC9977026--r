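#' Assign a student cohort id to (year, grade)
#'
#' Tests are biennial: a cohort sitting grade 3 in year `y` sits grade 5 in
#' `y + 2`, grade 7 in `y + 4`, grade 9 in `y + 6`. Cohorts are therefore
#' labelled by the year the cohort sat (or would have sat) grade 3:
#' `cohort_id = year - (grade - 3)`. Students retested two grades later at
#' the same school share the id, e.g. grade 3 in 2014 and grade 5 in 2016
#' both map to cohort 2014.
#'
#' @param year Calendar year(s) of the test.
#' @param grade Grade level(s); must be in `grades`.
#' @param grades Set of tested grade levels.
#' @return Integer cohort id(s), vectorized over inputs.
#' @examples
#' assign_cohort(2014, 3) # 2014
#' assign_cohort(2016, 5) # 2014, the same cohort
#' @export
assign_cohort <- function(year, grade, grades = c(3, 5, 7, 9)) {
  if (!all(grade %in% grades))
    stop("grade must be one of {", paste(grades, collapse = ", "), "}")
  as.integer(year) - (as.integer(grade) - 3L)
}

#' Centre school mean scores against regional reference means
#'
#' Subtracts from each raw cell mean the regional reference mean for the
#' matching (year, grade, domain). The reference mean is treated as a known
#' constant — it is computed from a pool far larger than any single cell —
#' so standard errors are unchanged. Scores are centred, not standardized:
#' the centred value stays on the score-point scale and keeps its
#' interpretation in terms of academic progression.
#'
#' @param observations data.frame with columns `year`, `grade`, `domain`,
#'   `mean`, `se` (and optionally a logical `centred` flag).
#' @param reference Reference-means grid as from [generate_reference_means()].
#' @return `observations` with `mean` replaced by the centred mean and
#'   `centred = TRUE`.
#' @export
center_scores <- function(observations, reference) {
  if (isTRUE(observations$centred[1]) && all(observations$centred))
    stop("observations are already centred")
  key_obs <- paste(observations$year, observations$grade, observations$domain,
                   sep = "|")
  key_ref <- paste(reference$year, reference$grade, reference$domain, sep = "|")
  idx <- match(key_obs, key_ref)
  if (anyNA(idx)) {
    miss <- sort(unique(key_obs[is.na(idx)]))
    stop("no reference mean for (year|grade|domain): ",
         paste(utils::head(miss, 10), collapse = ", "),
         if (length(miss) > 10) sprintf(" ... and %d more", length(miss) - 10))
  }
  observations$mean <- observations$mean - reference$reference_mean[idx]
  observations$centred <- TRUE
  observations
}

#' Validate observation and profile tables
#'
#' Screens the raw tables for structural problems before design construction:
#' non-positive or missing standard errors, observations whose school has no
#' profile row at all, and profile rows outside the span of observed study
#' years. By default the function only reports; with `drop = TRUE` offending
#' rows are removed, and with `strict = TRUE` the first violated rule raises
#' an error instead.
#'
#' Cells with missing or non-positive SE can never be dropped silently: the
#' SE is the meta-analytic weight, so imputing it would distort the
#' weighting. They are reported (and removed only under `drop = TRUE`).
#'
#' @param observations,profiles Tables as produced by [generate_study()] or
#'   read from CSV.
#' @param drop Remove violating rows from the returned tables.
#' @param strict Raise an error on the first violated rule.
#' @return A list of class `its_validation` with elements `report`
#'   (data.frame of rule / n_violations), `observations`, `profiles`.
#' @export
validate_tables <- function(observations, profiles, drop = FALSE,
                            strict = FALSE) {
  bad_se <- is.na(observations$se) | observations$se <= 0
  orphan <- !(observations$school_id %in% profiles$school_id)
  yr_range <- range(observations$year)
  out_year <- profiles$year < yr_range[1] | profiles$year > yr_range[2]

  report <- data.frame(
    rule = c("nonpositive_se", "orphan_school", "profile_year_outside"),
    n_violations = c(sum(bad_se), sum(orphan), sum(out_year)),
    stringsAsFactors = FALSE)

  if (strict) {
    first <- report$rule[report$n_violations > 0][1]
    if (!is.na(first))
      stop("validation failed on rule '", first, "' (",
           report$n_violations[report$rule == first], " rows)")
  }
  if (drop) {
    observations <- observations[!(bad_se | orphan), , drop = FALSE]
    profiles <- profiles[!out_year, , drop = FALSE]
  }
  structure(list(report = report, observations = observations,
                 profiles = profiles), class = "its_validation")
}

#' @export
print.its_validation <- function(x, ...) {
  cat("Table validation report\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
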