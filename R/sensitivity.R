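#' Define a sensitivity-analysis variant
#'
#' A variant re-fits the base model with exactly the stated modification:
#' alternative priors, removal of the cohort-within-school random effect
#' (only school-level clustering retained), and/or exclusion of named
#' schools (e.g. schools relocated during the event). At least one
#' modification must be set; a "null" variant for sampler-noise checks can
#' be expressed by passing the base priors as `prior_override`.
#'
#' @param name Label carried through to the comparison table.
#' @param prior_override Optional [prior_spec()] replacing the base priors.
#' @param drop_cohort_random_effect Remove the cohort random intercept.
#' @param exclude_school_ids Character vector of schools to drop before the
#'   design is rebuilt.
#' @return An object of class `sensitivity_variant`.
#' @export
sensitivity_variant <- function(name, prior_override = NULL,
                                drop_cohort_random_effect = FALSE,
                                exclude_school_ids = NULL) {
  if (is.null(prior_override) && !drop_cohort_random_effect &&
      length(exclude_school_ids) == 0)
    stop("variant '", name, "' sets no modification")
  if (!is.null(prior_override) && !inherits(prior_override, "prior_spec"))
    stop("prior_override must be a prior_spec()")
  structure(list(name = name, prior_override = prior_override,
                 drop_cohort_random_effect = isTRUE(drop_cohort_random_effect),
                 exclude_school_ids = exclude_school_ids),
            class = "sensitivity_variant")
}

#' Re-fit the model under a sensitivity variant
#'
#' Applies the variant's modification to the base analysis and returns a
#' coefficient table in the same schema as the base fit, tagged with the
#' variant name. School exclusions are applied to the underlying tables and
#' the design rebuilt, so covariate scaling reflects the reduced sample;
#' dropping the cohort random effect pins `sigma_cohort` at zero. Variants
#' reuse the base seed so that differences reflect the modification, not
#' sampler noise.
#'
#' @param base_design The [build_design()] of the base analysis.
#' @param base_priors The base [prior_spec()].
#' @param variant A [sensitivity_variant()].
#' @param mcmc An [mcmc_config()]; the base configuration by default.
#' @return A `coef_table` with attribute `"variant"` set, plus the fit in
#'   attribute `"fit"`.
#' @export
run_variant <- function(base_design, base_priors, variant,
                        mcmc = mcmc_config()) {
  if (!inherits(variant, "sensitivity_variant"))
    stop("variant must be a sensitivity_variant()")
  design <- base_design
  if (length(variant$exclude_school_ids) > 0) {
    dat <- base_design$data
    unknown <- setdiff(variant$exclude_school_ids, unique(dat$school_id))
    if (length(unknown) > 0)
      stop("excluded school ids not in the study: ",
           paste(unknown, collapse = ", "))
    keep <- !(dat$school_id %in% variant$exclude_school_ids)
    lost_groups <- setdiff(unique(as.character(dat$exposure_group)),
                           unique(as.character(dat$exposure_group[keep])))
    if (length(lost_groups) > 0)
      stop("excluding these schools removes every school of group(s): ",
           paste(lost_groups, collapse = ", "),
           " — group coefficients would be unidentifiable")
    obs_cols <- c("school_id", "domain", "grade", "year", "cohort_id",
                  "mean", "se", "n", "centred")
    obs <- dat[keep, intersect(obs_cols, colnames(dat)), drop = FALSE]
    design <- build_design(obs, base_design$profiles,
                           domain = base_design$domain,
                           event_year = base_design$event_year)
  }
  priors <- if (is.null(variant$prior_override)) base_priors else
    variant$prior_override
  if (variant$drop_cohort_random_effect)
    priors <- prior_spec(beta_mean = priors$beta_mean,
                         beta_sd = priors$beta_sd,
                         sigma_cohort = 0,
                         sigma_school = priors$sigma_school,
                         sigma_e = priors$sigma_e)
  fit <- fit_model(design, priors, mcmc)
  tab <- coef_table(fit)
  attr(tab, "variant") <- variant$name
  attr(tab, "fit") <- fit
  tab
}

#' Compare coefficient tables across variants
#'
#' Lays the posterior means and credible intervals of two or more variants
#' side by side and flags, for each segmented time-series coefficient,
#' whether the sign of the posterior mean agrees across all variants.
#'
#' @param tables Named list of `coef_table`s (names default to their
#'   `"variant"` attributes) sharing the same coefficient set for shared
#'   columns.
#' @return data.frame with one row per coefficient common to all tables:
#'   `mean_<name>`, `lower_<name>`, `upper_<name>` blocks per variant and a
#'   logical `sign_agreement` column for ITS terms (NA otherwise).
#' @export
compare_variants <- function(tables) {
  if (length(tables) < 2) stop("need at least two tables to compare")
  if (is.null(names(tables)) || any(names(tables) == ""))
    names(tables) <- vapply(tables, function(t) {
      v <- attr(t, "variant"); if (is.null(v)) "unnamed" else v
    }, character(1))
  terms <- lapply(tables, `[[`, "term")
  common <- Reduce(intersect, terms)
  extra <- unique(unlist(lapply(terms, setdiff, common)))
  if (length(common) == 0)
    stop("tables share no coefficients")
  only_some <- lapply(seq_along(tables), function(i) setdiff(terms[[i]], common))
  mismatch <- unique(unlist(only_some))
  if (length(mismatch) > 0 && !all(mismatch %in% c("sigma_cohort")))
    stop("coefficient sets differ beyond the cohort SD: ",
         paste(setdiff(mismatch, "sigma_cohort"), collapse = ", "))

  out <- data.frame(term = common, stringsAsFactors = FALSE)
  for (nm in names(tables)) {
    t <- tables[[nm]]
    idx <- match(common, t$term)
    out[[paste0("mean_", nm)]] <- t$mean[idx]
    out[[paste0("lower_", nm)]] <- t$lower[idx]
    out[[paste0("upper_", nm)]] <- t$upper[idx]
  }
  signs <- sapply(tables, function(t) sign(t$mean[match(common, t$term)]))
  agree <- apply(signs, 1, function(s) length(unique(s)) == 1)
  out$sign_agreement <- ifelse(common %in% .its_colnames, agree, NA)
  out
}
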