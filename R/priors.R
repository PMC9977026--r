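#' Truncated-normal prior on a standard deviation
#'
#' @param mean,sd Location and scale of the underlying normal.
#' @param lower Lower truncation bound; 0 is the natural bound for an SD.
#' @return An object of class `tn_prior`.
#' @export
tn_prior <- function(mean = 10, sd = 5, lower = 0) {
  if (sd <= 0) stop("prior sd must be > 0")
  if (lower < 0) stop("truncation lower bound must be >= 0")
  structure(list(mean = mean, sd = sd, lower = lower), class = "tn_prior")
}

# a variance-component prior is either a tn_prior or a fixed non-negative value
.check_sigma_prior <- function(p, name) {
  if (inherits(p, "tn_prior")) return(p)
  if (is.numeric(p) && length(p) == 1 && !is.na(p) && p >= 0)
    return(structure(list(value = p), class = "fixed_sigma"))
  stop("'", name, "' must be a tn_prior() or a single fixed value >= 0")
}

.is_fixed <- function(p) inherits(p, "fixed_sigma")

#' Prior specification for the hierarchical meta-regression
#'
#' Defaults are the weakly informative priors of the model: `N(0, 50^2)` on
#' every fixed-effect coefficient and `TN(10, 5^2)` truncated at zero on the
#' cohort, school and residual SDs. The TN location of 10 score points (not
#' the usual 0) reflects prior knowledge that between-school and
#' between-cohort spread on the centred-score scale is of that order.
#'
#' Any SD prior may be replaced by a single fixed number, which pins the
#' component at that value (0 removes it entirely); this is how the
#' oracle-comparison limits and the "no cohort random effect" sensitivity
#' variant are expressed.
#'
#' @param beta_mean,beta_sd Normal prior on fixed effects.
#' @param sigma_cohort,sigma_school,sigma_e [tn_prior()] objects or fixed
#'   non-negative values.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(beta_mean = 0, beta_sd = 50,
                       sigma_cohort = tn_prior(10, 5),
                       sigma_school = tn_prior(10, 5),
                       sigma_e = tn_prior(10, 5)) {
  if (beta_sd <= 0) stop("beta_sd must be > 0")
  structure(list(
    beta_mean = beta_mean, beta_sd = beta_sd,
    sigma_cohort = .check_sigma_prior(sigma_cohort, "sigma_cohort"),
    sigma_school = .check_sigma_prior(sigma_school, "sigma_school"),
    sigma_e = .check_sigma_prior(sigma_e, "sigma_e")
  ), class = "prior_spec")
}

#' MCMC configuration
#'
#' Defaults follow the estimation setup of the model: 4 chains of 2000
#' iterations each, the first half of every chain discarded as warmup.
#'
#' @param chains Number of chains (>= 2, so split-Rhat is meaningful).
#' @param iterations Total iterations per chain.
#' @param warmup Iterations discarded per chain; default half.
#' @param seed Integer seed; chain c uses `seed + c - 1`.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4, iterations = 2000,
                        warmup = floor(iterations / 2), seed = 1L) {
  if (chains < 2) stop("chains must be >= 2 for convergence diagnostics")
  if (warmup >= iterations) stop("iterations must exceed warmup")
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup = as.integer(warmup), seed = as.integer(seed)),
            class = "mcmc_config")
}
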