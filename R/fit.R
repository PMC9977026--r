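#' Fit the Bayesian hierarchical meta-regression
#'
#' Samples the posterior of the interrupted-time-series meta-regression:
#' each centred cell mean `y_i` with known sampling SE `tau_i` is modelled as
#' `y_i ~ N(X_i beta + theta_school + theta_cohort, tau_i^2 + sigma_e^2)`,
#' with `theta_school ~ N(0, sigma_school^2)` and nested
#' `theta_cohort ~ N(0, sigma_cohort^2)` random intercepts. The cell-level
#' residual with SD `sigma_e` is marginalized exactly into the observation
#' variance. Sampling uses a blocked Gibbs scheme: joint conjugate Gaussian
#' updates for `beta` and each random-effect block, slice updates for the
#' three SDs under their truncated-normal priors.
#'
#' Convergence is summarized by split-Rhat over all chains and by the
#' effective sample size of the fixed effects and SDs; values of Rhat above
#' 1.01 produce a warning, never a silent repair.
#'
#' @param design An [build_design()] object.
#' @param priors A [prior_spec()]; SD priors may be fixed values (0 removes
#'   the component).
#' @param mcmc An [mcmc_config()].
#' @return An object of class `its_fit` holding per-chain draws (kept
#'   iterations x chains), diagnostics, and the design metadata needed for
#'   reporting.
#' @export
fit_model <- function(design, priors = prior_spec(), mcmc = mcmc_config()) {
  if (!inherits(design, "its_design")) stop("design must be an its_design")
  if (!inherits(priors, "prior_spec")) stop("priors must be a prior_spec")
  if (!inherits(mcmc, "mcmc_config")) stop("mcmc must be an mcmc_config")
  if (any(design$se <= 0)) stop("all standard errors must be positive")

  tau2 <- design$se^2
  chains <- lapply(seq_len(mcmc$chains), function(ch) {
    .gibbs_chain(y = design$y, X = design$X, tau2 = tau2,
                 school = design$school_index, cohort = design$cohort_index,
                 priors = priors, iterations = mcmc$iterations,
                 warmup = mcmc$warmup, seed = mcmc$seed + ch - 1L)
  })

  par_chains <- lapply(chains, function(ch) cbind(ch$beta, ch$sigma))
  rhat <- .split_rhat(par_chains)
  stacked <- do.call(rbind, par_chains)

  mcl <- coda::mcmc.list(lapply(par_chains, coda::mcmc))
  ess <- tryCatch(coda::effectiveSize(mcl), error = function(e)
    rep(NA_real_, ncol(stacked)))

  sampled <- c(!.is_fixed(priors$sigma_cohort) &&
                 length(design$cohort_levels) > 0,
               !.is_fixed(priors$sigma_school) &&
                 length(design$school_levels) > 0,
               !.is_fixed(priors$sigma_e))
  names(sampled) <- c("sigma_cohort", "sigma_school", "sigma_e")

  diag_pars <- c(colnames(design$X), names(sampled)[sampled])
  diagnostics <- data.frame(
    parameter = diag_pars,
    rhat = rhat[diag_pars],
    ess = as.numeric(ess[diag_pars]),
    stringsAsFactors = FALSE, row.names = NULL)
  diagnostics$mcse <- apply(stacked[, diag_pars, drop = FALSE], 2, sd) /
    sqrt(diagnostics$ess)

  bad <- diagnostics$parameter[!is.na(diagnostics$rhat) &
                                 diagnostics$rhat > 1.01]
  if (length(bad) > 0)
    warning("split-Rhat > 1.01 for: ", paste(bad, collapse = ", "),
            " — inspect convergence before reporting", call. = FALSE)

  structure(list(
    draws = stacked,                      # (chains * kept) x parameters
    chains = par_chains,                  # list per chain
    theta_school = lapply(chains, `[[`, "theta_school"),
    theta_cohort = lapply(chains, `[[`, "theta_cohort"),
    sampled_sigmas = sampled,
    diagnostics = diagnostics,
    divergences = 0L,                     # Gibbs transitions cannot diverge
    priors = priors, mcmc = mcmc,
    design_columns = colnames(design$X),
    scaling = design$scaling,
    domain = design$domain,
    event_year = design$event_year, first_year = design$first_year,
    years = sort(unique(design$data$year)),
    groups_present = sort(unique(as.character(design$data$exposure_group))),
    reference_row = .reference_row(design)
  ), class = "its_fit")
}

# modal/mean covariate values on the scale of the design columns, used as
# the reference profile for predicted margins
.reference_row <- function(design) {
  X <- design$X
  ref <- setNames(numeric(ncol(X)), colnames(X))
  ref["(Intercept)"] <- 1
  for (nm in colnames(X)) {
    if (nm %in% c("(Intercept)", .its_colnames)) next
    x <- X[, nm]
    if (all(x %in% c(0, 1))) {
      ref[nm] <- as.numeric(mean(x) > 0.5)     # modal category
    } else {
      ref[nm] <- mean(x)                       # sample mean (0 if scaled)
    }
  }
  ref
}

#' @export
print.its_fit <- function(x, ...) {
  cat("Bayesian ITS hierarchical meta-regression fit (domain: ",
      x$domain, ")\n", sep = "")
  cat("  chains: ", x$mcmc$chains, " x ", x$mcmc$iterations,
      " iterations (", x$mcmc$warmup, " warmup)\n", sep = "")
  cat("  kept draws: ", nrow(x$draws), "\n", sep = "")
  cat("  max split-Rhat: ",
      round(max(x$diagnostics$rhat, na.rm = TRUE), 4), "\n", sep = "")
  invisible(x)
}

#' Posterior coefficient table
#'
#' Summarizes each fixed effect (and sampled SD) by its posterior mean,
#' 2.5/97.5 percentile credible interval, and the posterior probabilities of
#' lying below and above zero, computed as fractions of draws. Continuous
#' confounders that entered the design centred and scaled are reported in
#' natural units by dividing their draws by the recorded scale.
#'
#' @param fit An [fit_model()] result.
#' @param natural_units Report scaled covariates per natural unit
#'   (default TRUE).
#' @param prob Credible-interval mass (default 0.95).
#' @return A data.frame of class `coef_table` with columns `term`, `mean`,
#'   `sd`, `lower`, `upper`, `p_below_0`, `p_above_0`.
#' @export
coef_table <- function(fit, natural_units = TRUE, prob = 0.95) {
  if (!inherits(fit, "its_fit")) stop("fit must be an its_fit")
  draws <- fit$draws
  if (nrow(draws) < 100) stop("need at least 100 kept draws to summarize")
  keep <- c(fit$design_columns, names(fit$sampled_sigmas)[fit$sampled_sigmas])
  draws <- draws[, keep, drop = FALSE]
  if (natural_units) {
    for (k in seq_len(nrow(fit$scaling))) {
      cn <- fit$scaling$column[k]
      if (cn %in% colnames(draws))
        draws[, cn] <- draws[, cn] / fit$scaling$scale[k]
    }
  }
  a <- (1 - prob) / 2
  qs <- apply(draws, 2, quantile, probs = c(a, 1 - a))
  out <- data.frame(
    term = colnames(draws),
    mean = colMeans(draws),
    sd = apply(draws, 2, sd),
    lower = qs[1, ], upper = qs[2, ],
    p_below_0 = colMeans(draws < 0),
    p_above_0 = colMeans(draws > 0),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "domain") <- fit$domain
  attr(out, "prob") <- prob
  class(out) <- c("coef_table", "data.frame")
  out
}

#' @export
summary.its_fit <- function(object, ...) coef_table(object, ...)

#' @export
print.coef_table <- function(x, digits = 3, ...) {
  cat("Posterior summary (domain: ", attr(x, "domain"), ", ",
      round(100 * attr(x, "prob")), "% CI)\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Predicted margins by year and exposure group
#'
#' For each requested year and exposure group, computes the predicted
#' centred score per posterior draw with the segmented time-series terms set
#' by [its_terms()], all confounders fixed at reference values (sample means
#' for continuous covariates, the modal category for indicators), and random
#' effects at zero; then summarizes the draws by mean and percentile CI.
#'
#' @param fit An [fit_model()] result.
#' @param years Years to predict at; default the fitted study span.
#' @param exposure_groups Groups to predict for; default those present.
#' @param reference_covariates Optional named vector overriding the
#'   reference value of any non-ITS design column (on the design scale).
#' @param prob Credible-interval mass.
#' @return data.frame with `domain`, `year`, `exposure_group`, `mean`,
#'   `lower`, `upper`.
#' @export
predicted_margins <- function(fit, years = NULL, exposure_groups = NULL,
                              reference_covariates = NULL, prob = 0.95) {
  if (!inherits(fit, "its_fit")) stop("fit must be an its_fit")
  if (is.null(years)) years <- fit$years
  if (any(years < min(fit$years) | years > max(fit$years)))
    stop("years outside the fitted study span (", min(fit$years), "-",
         max(fit$years), ")")
  if (is.null(exposure_groups)) exposure_groups <- fit$groups_present

  ref <- fit$reference_row
  if (!is.null(reference_covariates)) {
    unknown <- setdiff(names(reference_covariates), names(ref))
    if (length(unknown) > 0)
      stop("unknown reference covariates: ", paste(unknown, collapse = ", "))
    ref[names(reference_covariates)] <- reference_covariates
  }

  beta <- fit$draws[, fit$design_columns, drop = FALSE]
  a <- (1 - prob) / 2
  out <- expand.grid(year = years, exposure_group = exposure_groups,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- t(apply(out, 1, function(row) {
    x <- ref
    terms <- its_terms(as.integer(row[["year"]]), row[["exposure_group"]],
                       fit$event_year, fit$first_year)
    present <- intersect(names(terms), names(x))
    x[present] <- terms[present]
    mu <- as.vector(beta %*% x)
    c(mean(mu), quantile(mu, c(a, 1 - a)))
  }))
  data.frame(domain = fit$domain, year = out$year,
             exposure_group = out$exposure_group,
             mean = res[, 1], lower = res[, 2], upper = res[, 3],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Convert a score-point effect into months of learning
#'
#' Scores typically increase by about 27 points per school year, so a
#' score-point effect maps onto an equivalent amount of learning time:
#' `months = effect / points_per_year * 12`.
#'
#' @param effect Effect size in score points.
#' @param points_per_year Typical yearly score gain (default 27 points).
#' @return Equivalent months of learning, same sign as `effect`.
#' @examples
#' effect_to_months(11.09) # about 4.9 months
#' @export
effect_to_months <- function(effect, points_per_year = 27) {
  if (!is.numeric(points_per_year) || points_per_year <= 0)
    stop("points_per_year must be > 0")
  effect / points_per_year * 12
}
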