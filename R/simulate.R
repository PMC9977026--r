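#' Ground-truth parameters for a synthetic study
#'
#' Collects the generating parameter values of a synthetic school panel:
#' the segmented time-series coefficients for the two exposed groups, the
#' confounder coefficients, and the variance components. These are the values
#' that parameter-recovery tests compare posterior estimates against.
#'
#' Interruption coefficients are on the centred-score scale (score points).
#' `beta_t` is the common long-term trend in points per year; `*_pre` are
#' pre-event group offsets relative to the no/low-exposure group; `*_int` are
#' immediate post-event level shifts; `*_trend` are post-event changes in the
#' annual slope. Confounder coefficients apply to deviations of each covariate
#' from a regional-typical value (ICSEA 960, enrolments 150, proportion of
#' girls 0.49), so a school at those values tracks its reference mean exactly
#' when all other effects are zero.
#'
#' @param beta_t Long-term trend, points per year.
#' @param beta_m_pre,beta_h_pre Pre-event offsets for moderate / high exposure.
#' @param beta_m_int,beta_h_int Interruption (level-shift) effects.
#' @param beta_m_trend,beta_h_trend Post-event trend differences, points/year.
#' @param confounder_betas Named numeric vector with elements `icsea`
#'   (points per ICSEA point), `enrolments` (points per student), `prop_girls`
#'   (points per unit fraction), `sector_nongov` (offset for non-government
#'   schools), `grade5`, `grade7`, `grade9` (offsets relative to grade 3).
#' @param sigma_cohort,sigma_school,sigma_e Random-effect and residual SDs
#'   (score points), all `>= 0`.
#' @param event_year Calendar year of the interruption.
#'
#' @return An object of class `sim_truth` (a named list).
#' @seealso [generate_study()], [sim_config()]
#' @export
sim_truth <- function(beta_t = -1,
                      beta_m_pre = -2, beta_h_pre = -10,
                      beta_m_int = -2, beta_h_int = -10,
                      beta_m_trend = 0.5, beta_h_trend = 2,
                      confounder_betas = c(icsea = 0.1, enrolments = 0.005,
                                           prop_girls = 10, sector_nongov = 3,
                                           grade5 = 1, grade7 = 2, grade9 = 2),
                      sigma_cohort = 5, sigma_school = 5, sigma_e = 5,
                      event_year = 2014) {
  needed <- c("icsea", "enrolments", "prop_girls", "sector_nongov",
              "grade5", "grade7", "grade9")
  missing <- setdiff(needed, names(confounder_betas))
  if (length(missing) > 0)
    stop("confounder_betas is missing elements: ", paste(missing, collapse = ", "))
  for (nm in c("sigma_cohort", "sigma_school", "sigma_e")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1 || is.na(val) || val < 0)
      stop("'", nm, "' must be a single non-negative number")
  }
  structure(list(
    beta_t = beta_t,
    beta_m_pre = beta_m_pre, beta_h_pre = beta_h_pre,
    beta_m_int = beta_m_int, beta_h_int = beta_h_int,
    beta_m_trend = beta_m_trend, beta_h_trend = beta_h_trend,
    confounder_betas = confounder_betas[needed],
    sigma_cohort = sigma_cohort, sigma_school = sigma_school,
    sigma_e = sigma_e, event_year = event_year
  ), class = "sim_truth")
}

#' Configuration of a synthetic school panel study
#'
#' Defaults emulate the structure of the motivating study: 69 regional
#' schools split 34/28/7 across no/low, moderate, and high exposure groups,
#' tested annually 2008--2018 in grades 3/5/7/9 across five domains, with an
#' event interrupting the series in 2014. Covariate distributions (ICSEA,
#' enrolments, proportion of girls, sector, school type) follow the observed
#' group medians/IQRs of that study population.
#'
#' `within_school_sd` is the SD of individual student scores within one
#' school x grade x year cell; the standard error of each cell mean is exactly
#' `within_school_sd / sqrt(n)` where `n` is the number of tested students in
#' the cell.
#'
#' @param n_schools_by_group Named counts for groups `no_low`, `moderate`,
#'   `high`; all `>= 1`.
#' @param years Inclusive integer vector of study years; must contain at
#'   least one pre-event and one post-event year.
#' @param grades Tested grade levels.
#' @param domains Character vector of testing domains.
#' @param within_school_sd SD of student scores within a cell (points), `> 0`.
#' @param enrolment_meanlog,enrolment_sdlog Per-group log-normal parameters
#'   for total school enrolments (named `no_low`, `moderate`, `high`).
#' @param icsea_mean Per-group mean ICSEA; common SD `icsea_sd`.
#' @param icsea_sd ICSEA SD within group.
#' @param prop_girls_mean,prop_girls_kappa Beta-distribution mean and
#'   concentration for the proportion of girls.
#' @param p_nongov Per-group probability that a school is non-government.
#' @param school_type_probs Per-group probabilities over
#'   `c(primary, secondary, combined)`, rows named by group.
#' @param missingness_rate Probability that any school x year x grade cell is
#'   absent from the panel (unbalanced panel), in `[0, 1)`.
#' @param truth A [sim_truth()] object.
#' @param seed Integer seed; the generated study is deterministic given it.
#'
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_schools_by_group = c(no_low = 34, moderate = 28, high = 7),
                       years = 2008:2018,
                       grades = c(3, 5, 7, 9),
                       domains = c("Reading", "Writing", "Spelling",
                                   "Grammar", "Numeracy"),
                       within_school_sd = 70,
                       enrolment_meanlog = c(no_low = log(108),
                                             moderate = log(165),
                                             high = log(204)),
                       enrolment_sdlog = c(no_low = 1.25, moderate = 0.79,
                                           high = 0.50),
                       icsea_mean = c(no_low = 974, moderate = 962, high = 922),
                       icsea_sd = 40,
                       prop_girls_mean = 0.49,
                       prop_girls_kappa = 120,
                       p_nongov = c(no_low = 0.24, moderate = 0.21, high = 0.29),
                       school_type_probs = rbind(
                         no_low = c(primary = 29, secondary = 4, combined = 1) / 34,
                         moderate = c(primary = 25, secondary = 3, combined = 0) / 28,
                         high = c(primary = 6, secondary = 1, combined = 0) / 7),
                       missingness_rate = 0,
                       truth = sim_truth(),
                       seed = 1L) {
  groups <- c("no_low", "moderate", "high")
  if (!all(groups %in% names(n_schools_by_group)))
    stop("n_schools_by_group must be named with: ", paste(groups, collapse = ", "))
  if (any(n_schools_by_group[groups] < 1))
    stop("n_schools_by_group: all counts must be >= 1")
  if (!is.numeric(within_school_sd) || within_school_sd <= 0)
    stop("within_school_sd must be > 0")
  if (!inherits(truth, "sim_truth")) stop("truth must be a sim_truth object")
  years <- sort(as.integer(years))
  if (!(truth$event_year %in% years))
    stop("event_year (", truth$event_year, ") must lie inside the study years")
  if (min(years) >= truth$event_year)
    stop("years must include at least one pre-event year")
  if (missingness_rate < 0 || missingness_rate >= 1)
    stop("missingness_rate must be in [0, 1)")
  if (length(domains) < 1) stop("domains must be non-empty")
  structure(list(
    n_schools_by_group = n_schools_by_group[groups],
    years = years, grades = sort(grades), domains = domains,
    within_school_sd = within_school_sd,
    enrolment_meanlog = enrolment_meanlog, enrolment_sdlog = enrolment_sdlog,
    icsea_mean = icsea_mean, icsea_sd = icsea_sd,
    prop_girls_mean = prop_girls_mean, prop_girls_kappa = prop_girls_kappa,
    p_nongov = p_nongov, school_type_probs = school_type_probs,
    missingness_rate = missingness_rate,
    truth = truth, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Regional reference means per year, grade, and domain
#'
#' Builds the complete grid of regional average scores used for centring.
#' Scores rise with grade: the default base of 420 points at grade 3 with a
#' per-grade-step of (580 - 420) / 3 reproduces the typical progression from
#' about 420 at grade 3 to 580 at grade 9 (tests are biennial, so one "step"
#' is two grade levels). An optional linear drift moves all means over
#' calendar time.
#'
#' @param years,grades,domains Grid axes; grades must be sorted ascending.
#' @param base_grade3 Reference mean at the lowest tested grade (points).
#' @param per_grade_step Increase per biennial grade step (points).
#' @param per_year_drift Change per calendar year (points), default 0.
#'
#' @return A data.frame with columns `year`, `grade`, `domain`,
#'   `reference_mean`, one row per grid combination.
#' @export
generate_reference_means <- function(years, grades, domains,
                                     base_grade3 = 420,
                                     per_grade_step = (580 - 420) / 3,
                                     per_year_drift = 0) {
  if (length(years) == 0 || length(grades) == 0 || length(domains) == 0)
    stop("years, grades and domains must all be non-empty")
  if (is.unsorted(grades)) stop("grades must be sorted ascending")
  grid <- expand.grid(year = as.integer(years), grade = as.integer(grades),
                      domain = as.character(domains),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$reference_mean <- base_grade3 +
    per_grade_step * (grid$grade - min(grades)) / 2 +
    per_year_drift * (grid$year - min(years))
  grid[order(grid$domain, grid$grade, grid$year), , drop = FALSE]
}

# grade span a school covers, used to turn total enrolments into cell sizes
.grade_span <- function(school_type) {
  c(primary = 7, secondary = 6, combined = 13)[school_type]
}

.grades_taught <- function(school_type, grades) {
  switch(school_type,
         primary = intersect(grades, c(3, 5)),
         secondary = intersect(grades, c(7, 9)),
         combined = grades,
         stop("unknown school_type: ", school_type))
}

#' Generate a synthetic aggregated school-level study
#'
#' Draws a full synthetic panel with known ground truth under the model the
#' package fits: for each school, tested grade and year, one cell per domain
#' whose raw mean equals the regional reference mean plus the fixed-effect
#' contribution (segmented time-series terms and confounder effects), a
#' school random intercept, a cohort-within-school random intercept, a
#' cell-level residual of SD `sigma_e`, and mean-sampling noise of SD
#' `within_school_sd / sqrt(n)`. The emitted standard error is exactly
#' `within_school_sd / sqrt(n)`.
#'
#' School and cohort random effects are shared across domains (a school that
#' performs well does so in every domain); the residual is drawn
#' independently per cell. Cohorts are indexed by the calendar year the
#' cohort sat (or would have sat) grade 3, so students retested two grades
#' later at the same school share a cohort effect.
#'
#' @param config A [sim_config()] object.
#'
#' @return A list of class `sim_study` with elements
#'   \describe{
#'     \item{observations}{data.frame: `school_id`, `domain`, `grade`, `year`,
#'       `cohort_id`, `mean` (raw points), `se`, `n`, `centred` (FALSE).}
#'     \item{profiles}{data.frame: `school_id`, `year`, `icsea`, `enrolments`,
#'       `prop_girls`, `sector`, `school_type`, `exposure_group`.}
#'     \item{reference}{reference-means grid, see [generate_reference_means()].}
#'     \item{truth}{the [sim_truth()] used.}
#'     \item{config}{the input configuration.}
#'   }
#' @export
generate_study <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config object")
  truth <- config$truth
  set.seed(config$seed)

  groups <- rep(names(config$n_schools_by_group), config$n_schools_by_group)
  n_schools <- length(groups)
  school_id <- sprintf("S%03d", seq_len(n_schools))

  school_type <- character(n_schools)
  sector <- character(n_schools)
  icsea <- numeric(n_schools)
  enrol_base <- numeric(n_schools)
  prop_girls <- numeric(n_schools)
  for (i in seq_len(n_schools)) {
    g <- groups[i]
    school_type[i] <- sample(colnames(config$school_type_probs), 1,
                             prob = config$school_type_probs[g, ])
    sector[i] <- if (runif(1) < config$p_nongov[[g]]) "non-government" else "government"
    icsea[i] <- min(1300, max(500, rnorm(1, config$icsea_mean[[g]], config$icsea_sd)))
    enrol_base[i] <- rlnorm(1, config$enrolment_meanlog[[g]],
                            config$enrolment_sdlog[[g]])
    a <- config$prop_girls_mean * config$prop_girls_kappa
    b <- (1 - config$prop_girls_mean) * config$prop_girls_kappa
    prop_girls[i] <- rbeta(1, a, b)
  }

  theta_school <- rnorm(n_schools, 0, truth$sigma_school)

  years <- config$years
  first_year <- min(years)
  reference <- generate_reference_means(years, config$grades, config$domains)
  ref_key <- paste(reference$year, reference$grade, reference$domain, sep = "|")
  ref_lookup <- setNames(reference$reference_mean, ref_key)

  # per-year profiles: covariates held at the school's values, enrolments
  # jittered mildly year to year
  profiles <- do.call(rbind, lapply(seq_len(n_schools), function(i) {
    data.frame(school_id = school_id[i], year = years,
               icsea = round(icsea[i]),
               enrolments = pmax(5L, as.integer(round(
                 enrol_base[i] * exp(rnorm(length(years), 0, 0.05))))),
               prop_girls = round(prop_girls[i], 3),
               sector = sector[i], school_type = school_type[i],
               exposure_group = groups[i], stringsAsFactors = FALSE)
  }))
  rownames(profiles) <- NULL

  cb <- truth$confounder_betas
  obs_list <- vector("list", n_schools)
  for (i in seq_len(n_schools)) {
    taught <- .grades_taught(school_type[i], config$grades)
    if (length(taught) == 0) next
    cells <- expand.grid(grade = taught, year = years,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    if (config$missingness_rate > 0) {
      keep <- runif(nrow(cells)) >= config$missingness_rate
      cells <- cells[keep, , drop = FALSE]
      if (nrow(cells) == 0) next
    }
    cells$cohort_id <- cells$year - (cells$grade - 3L)

    # cohort random effects, one per distinct cohort at this school
    coh <- sort(unique(cells$cohort_id))
    theta_cohort <- setNames(rnorm(length(coh), 0, truth$sigma_cohort), coh)

    prof_i <- profiles[profiles$school_id == school_id[i], ]
    enrol_year <- setNames(prof_i$enrolments, prof_i$year)

    span <- .grade_span(school_type[i])
    n_cell <- pmax(5L, as.integer(round(rlnorm(
      nrow(cells),
      meanlog = log(pmax(5, enrol_year[as.character(cells$year)] / span)),
      sdlog = 0.25))))
    se_cell <- config$within_school_sd / sqrt(n_cell)

    # fixed-effect contribution shared by all domains of a cell
    its <- t(vapply(cells$year, its_terms, numeric(7),
                    exposure_group = groups[i],
                    event_year = truth$event_year, first_year = first_year))
    its_beta <- c(truth$beta_t, truth$beta_m_pre, truth$beta_h_pre,
                  truth$beta_m_int, truth$beta_h_int,
                  truth$beta_m_trend, truth$beta_h_trend)
    fixed <- as.vector(its %*% its_beta) +
      cb[["icsea"]] * (round(icsea[i]) - 960) +
      cb[["enrolments"]] * (enrol_year[as.character(cells$year)] - 150) +
      cb[["prop_girls"]] * (round(prop_girls[i], 3) - 0.49) +
      cb[["sector_nongov"]] * (sector[i] == "non-government") +
      ifelse(cells$grade == 5, cb[["grade5"]],
             ifelse(cells$grade == 7, cb[["grade7"]],
                    ifelse(cells$grade == 9, cb[["grade9"]], 0)))

    per_domain <- lapply(config$domains, function(dom) {
      key <- paste(cells$year, cells$grade, dom, sep = "|")
      mu <- ref_lookup[key] + fixed + theta_school[i] +
        theta_cohort[as.character(cells$cohort_id)] +
        rnorm(nrow(cells), 0, truth$sigma_e) +
        rnorm(nrow(cells), 0, se_cell)
      data.frame(school_id = school_id[i], domain = dom,
                 grade = cells$grade, year = cells$year,
                 cohort_id = cells$cohort_id,
                 mean = as.numeric(mu), se = se_cell, n = n_cell,
                 centred = FALSE, stringsAsFactors = FALSE)
    })
    obs_list[[i]] <- do.call(rbind, per_domain)
  }
  observations <- do.call(rbind, obs_list)
  observations <- observations[order(observations$school_id, observations$domain,
                                     observations$grade, observations$year), ]
  rownames(observations) <- NULL

  structure(list(observations = observations, profiles = profiles,
                 reference = reference, truth = truth, config = config),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Synthetic school panel study\n")
  cat("  schools:     ", length(unique(x$profiles$school_id)),
      " (", paste(x$config$n_schools_by_group, collapse = "/"), " by group)\n", sep = "")
  cat("  years:       ", min(x$config$years), "-", max(x$config$years),
      " (event ", x$truth$event_year, ")\n", sep = "")
  cat("  domains:     ", paste(x$config$domains, collapse = ", "), "\n", sep = "")
  cat("  observations:", nrow(x$observations), "\n")
  invisible(x)
}
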