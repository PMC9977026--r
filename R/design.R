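#' Segmented (interrupted) time-series terms for one cell
#'
#' Computes the seven interrupted-time-series predictors for a given year and
#' exposure group: the common linear trend `T` (0 in the first study year, 1
#' in the second, ...), pre-event group offsets `E_m`, `E_h` (one-hot, the
#' no/low group is the reference and is zero in all six exposure columns),
#' the interruption indicators `E_m:I_post`, `E_h:I_post` where
#' `I_post = 1` from the event year onwards, and the post-event trend terms
#' `E_m:I_post:T_post`, `E_h:I_post:T_post` with
#' `T_post = max(0, year - event_year)` (0 through the event year, 1 the
#' year after, ...).
#'
#' @param year Calendar year of the observation.
#' @param exposure_group One of `"no_low"`, `"moderate"`, `"high"`.
#' @param event_year Year of the interruption.
#' @param first_year First year of the study span (origin of `T`).
#' @return Named numeric vector of length 7.
#' @examples
#' its_terms(2015, "high", event_year = 2014, first_year = 2008)
#' @export
its_terms <- function(year, exposure_group, event_year, first_year = 2008) {
  if (length(year) != 1) stop("its_terms() takes a single year")
  if (!exposure_group %in% c("no_low", "moderate", "high"))
    stop("unknown exposure group: '", exposure_group, "'")
  t_var <- year - first_year
  e_m <- as.numeric(exposure_group == "moderate")
  e_h <- as.numeric(exposure_group == "high")
  i_post <- as.numeric(year >= event_year)
  t_post <- max(0, year - event_year)
  c(T = t_var, E_m = e_m, E_h = e_h,
    `E_m:I_post` = e_m * i_post, `E_h:I_post` = e_h * i_post,
    `E_m:I_post:T_post` = e_m * i_post * t_post,
    `E_h:I_post:T_post` = e_h * i_post * t_post)
}

.its_colnames <- c("T", "E_m", "E_h", "E_m:I_post", "E_h:I_post",
                   "E_m:I_post:T_post", "E_h:I_post:T_post")

#' Build the fixed-effects design for one testing domain
#'
#' Joins centred observations to school profiles on (school_id, year) —
#' carrying the last available profile forward over gap years — and
#' assembles the design matrix: intercept, the seven segmented time-series
#' terms of [its_terms()], and the confounders ICSEA, total enrolments,
#' proportion of girls (each centred at the sample mean and scaled by the
#' sample SD, with the centring/scale recorded for back-transformation),
#' a non-government sector indicator, and grade-level indicators with
#' grade 3 as reference. Random-effect grouping indices are built from
#' `school_id` and from (school_id, cohort_id).
#'
#' One model is fitted per domain, so the observations passed in (or the
#' `domain` filter) must contain exactly one domain.
#'
#' @param observations Centred observations (see [center_scores()]).
#' @param profiles School-profile table.
#' @param domain Testing domain to select; may be omitted if `observations`
#'   holds a single domain.
#' @param event_year Year of the interruption.
#' @param scale_covariates Centre/scale the continuous confounders (default
#'   TRUE; turn off for debugging only).
#' @return An object of class `its_design`: list with the model matrix `X`,
#'   response `y`, standard errors `se`, grouping indices `school_index`,
#'   `cohort_index` (with level tables `school_levels`, `cohort_levels`),
#'   `scaling` metadata, and the row-level `data` used.
#' @export
build_design <- function(observations, profiles, domain = NULL,
                         event_year = 2014, scale_covariates = TRUE) {
  if (!is.null(domain)) {
    observations <- observations[observations$domain %in% domain, , drop = FALSE]
    if (nrow(observations) == 0)
      stop("no observations for domain '", domain, "'")
  }
  doms <- unique(observations$domain)
  if (length(doms) != 1)
    stop("observations contain ", length(doms),
         " domains; pass `domain` to select one (separate models per domain)")
  if (!is.null(observations$centred) && !all(observations$centred))
    stop("observations must be centred first (see center_scores())")
  if (any(is.na(observations$se) | observations$se <= 0))
    stop("all standard errors must be positive; run validate_tables() first")
  if (is.null(observations$cohort_id))
    observations$cohort_id <- assign_cohort(observations$year, observations$grade)

  # join profiles on (school_id, year), last observation carried forward
  prof <- profiles[order(profiles$school_id, profiles$year), , drop = FALSE]
  key_exact <- paste(observations$school_id, observations$year)
  idx <- match(key_exact, paste(prof$school_id, prof$year))
  if (anyNA(idx)) {
    for (j in which(is.na(idx))) {
      cand <- which(prof$school_id == observations$school_id[j] &
                      prof$year <= observations$year[j])
      if (length(cand) > 0) idx[j] <- cand[length(cand)]
    }
    still <- is.na(idx)
    if (any(still)) {
      miss <- sort(unique(paste(observations$school_id[still],
                                observations$year[still])))
      stop("no profile row (even carrying forward) for: ",
           paste(utils::head(miss, 10), collapse = ", "))
    }
    message(sum(!is.na(idx) & is.na(match(key_exact, paste(prof$school_id, prof$year)))),
            " observation rows used a carried-forward profile year")
  }
  dat <- cbind(observations,
               prof[idx, c("icsea", "enrolments", "prop_girls", "sector",
                           "exposure_group")])
  rownames(dat) <- NULL

  first_year <- min(dat$year)
  its <- t(mapply(function(y, g) its_terms(y, g, event_year, first_year),
                  dat$year, as.character(dat$exposure_group)))
  colnames(its) <- .its_colnames

  scale_col <- function(x, name) {
    if (!scale_covariates) return(list(x = x, centre = 0, scale = 1))
    ctr <- mean(x); scl <- sd(x)
    if (!is.finite(scl) || scl == 0) scl <- 1
    list(x = (x - ctr) / scl, centre = ctr, scale = scl)
  }
  ic <- scale_col(dat$icsea, "icsea")
  en <- scale_col(dat$enrolments, "enrolments")
  pg <- scale_col(dat$prop_girls, "prop_girls")

  grades_present <- sort(unique(dat$grade))
  grade_cols <- NULL
  for (g in setdiff(grades_present, min(grades_present))) {
    grade_cols <- cbind(grade_cols, as.numeric(dat$grade == g))
    colnames(grade_cols)[ncol(grade_cols)] <- paste0("grade", g)
  }

  X <- cbind(`(Intercept)` = 1, its,
             icsea = ic$x, enrolments = en$x, prop_girls = pg$x,
             sector_nongov = as.numeric(dat$sector == "non-government"))
  if (!is.null(grade_cols)) X <- cbind(X, grade_cols)

  # drop structurally-empty columns (e.g. no high-exposure schools present),
  # then check the rest for rank
  nonzero <- colSums(abs(X)) > 0
  dropped <- colnames(X)[!nonzero]
  X <- X[, nonzero, drop = FALSE]
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  school_levels <- sort(unique(dat$school_id))
  cohort_key <- paste(dat$school_id, dat$cohort_id, sep = "|")
  cohort_levels <- sort(unique(cohort_key))

  structure(list(
    X = X, y = dat$mean, se = dat$se,
    school_index = match(dat$school_id, school_levels),
    cohort_index = match(cohort_key, cohort_levels),
    school_levels = school_levels, cohort_levels = cohort_levels,
    scaling = data.frame(
      column = c("icsea", "enrolments", "prop_girls"),
      centre = c(ic$centre, en$centre, pg$centre),
      scale = c(ic$scale, en$scale, pg$scale), stringsAsFactors = FALSE),
    domain = doms, event_year = event_year, first_year = first_year,
    dropped_columns = dropped,
    data = dat, profiles = profiles
  ), class = "its_design")
}

#' @export
print.its_design <- function(x, ...) {
  cat("Interrupted time-series design (domain: ", x$domain, ")\n", sep = "")
  cat("  cells:   ", nrow(x$X), "\n")
  cat("  columns: ", paste(colnames(x$X), collapse = ", "), "\n")
  cat("  schools: ", length(x$school_levels),
      "  school-cohorts: ", length(x$cohort_levels), "\n")
  invisible(x)
}
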