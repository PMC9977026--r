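# small synthetic studies used across tests; sizes chosen so a fit takes
# about a second

small_config <- function(seed = 1L, domains = "Writing", truth = sim_truth(),
                         ...) {
  sim_config(n_schools_by_group = c(no_low = 10, moderate = 8, high = 4),
             domains = domains, truth = truth, seed = seed, ...)
}

small_fit <- function(seed = 1L, truth = sim_truth(),
                      priors = prior_spec(),
                      mcmc = mcmc_config(chains = 2, iterations = 600,
                                         seed = seed)) {
  study <- generate_study(small_config(seed = seed, truth = truth))
  obs <- center_scores(study$observations, study$reference)
  design <- build_design(obs, study$profiles, domain = "Writing")
  list(fit = fit_model(design, priors, mcmc), design = design, study = study)
}

# intercept-only setting: one school, one year, one grade, constant
# covariates, so every non-intercept column is structurally empty
intercept_only_design <- function(y, se) {
  n <- length(y)
  obs <- data.frame(school_id = "S001", domain = "Writing", grade = 3,
                    year = 2008, cohort_id = 2005, mean = y, se = se,
                    n = 10, centred = TRUE)
  prof <- data.frame(school_id = "S001", year = 2008, icsea = 960,
                     enrolments = 100, prop_girls = 0.49,
                     sector = "government", school_type = "primary",
                     exposure_group = "no_low")
  build_design(obs, prof, domain = "Writing", event_year = 2014)
}
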