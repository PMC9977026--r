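test_that("prior and sampler configuration are validated", {
  expect_error(prior_spec(beta_sd = 0), "beta_sd")
  expect_error(prior_spec(sigma_e = -2), "sigma_e")
  expect_error(tn_prior(sd = 0), "sd")
  expect_error(tn_prior(lower = -1), "lower")
  expect_error(mcmc_config(chains = 1), "chains")
  expect_error(mcmc_config(iterations = 100, warmup = 100), "warmup")
})

test_that("intercept-only fit matches the conjugate closed form", {
  set.seed(101)
  n <- 30
  se <- runif(n, 2, 6)
  y <- rnorm(n, 4, se)
  d <- intercept_only_design(y, se)
  pr <- prior_spec(beta_sd = 50, sigma_cohort = 0, sigma_school = 0,
                   sigma_e = 0)
  fit <- fit_model(d, pr, mcmc_config(chains = 2, iterations = 1000,
                                      seed = 7))
  prec <- sum(1 / se^2) + 1 / 50^2
  m_exact <- sum(y / se^2) / prec
  mcse <- fit$diagnostics$mcse[1]
  expect_lt(abs(mean(fit$draws[, "(Intercept)"]) - m_exact), 3 * mcse)
  expect_equal(sd(fit$draws[, "(Intercept)"]), 1 / sqrt(prec),
               tolerance = 0.1)
})

test_that("no-signal data shrink every coefficient toward zero", {
  tabs_study <- generate_study(small_config(seed = 41))
  obs <- center_scores(tabs_study$observations, tabs_study$reference)
  obs$mean <- 0
  obs$se <- 3
  d <- build_design(obs, tabs_study$profiles, domain = "Writing")
  pr <- prior_spec(sigma_cohort = 0, sigma_school = 0, sigma_e = 0)
  fit <- fit_model(d, pr, mcmc_config(chains = 2, iterations = 600, seed = 8))
  tab <- coef_table(fit, natural_units = FALSE)
  expect_true(all(abs(tab$mean) < 0.5 * 50))
})

test_that("posterior tail probabilities are draw fractions that sum to one", {
  res <- small_fit(seed = 42)
  tab <- coef_table(res$fit)
  expect_equal(tab$p_below_0 + tab$p_above_0, rep(1, nrow(tab)))
  expect_true(all(tab$lower <= tab$mean & tab$mean <= tab$upper))

  # summaries are plain draw functionals: check against a frozen draw set
  fake <- res$fit
  fake$draws <- matrix(rep(c(-1, -2, 3, 4), 25), ncol = 1,
                       dimnames = list(NULL, "(Intercept)"))
  fake$design_columns <- "(Intercept)"
  fake$sampled_sigmas <- c(sigma_cohort = FALSE, sigma_school = FALSE,
                           sigma_e = FALSE)
  ftab <- coef_table(fake)
  expect_equal(ftab$mean, 1.0)
  expect_equal(ftab$p_below_0, 0.5)
  expect_equal(ftab$p_above_0, 0.5)

  fake$draws <- matrix(abs(fake$draws) + 0.1, ncol = 1,
                       dimnames = list(NULL, "(Intercept)"))
  ftab <- coef_table(fake)
  expect_equal(ftab$p_above_0, 1)
  expect_equal(ftab$p_below_0, 0)
})

test_that("margins obey the linear algebra of the codings", {
  res <- small_fit(seed = 43)
  fit <- res$fit
  m <- predicted_margins(fit, years = 2008:2018,
                         exposure_groups = c("no_low", "moderate", "high"))
  expect_equal(nrow(m), 11 * 3)

  draws <- fit$draws[, fit$design_columns]
  pick <- function(year, group, col)
    m[[col]][m$year == year & m$exposure_group == group]
  # pre-event difference high - no_low equals the pre-event offset, per draw
  expect_equal(pick(2010, "high", "mean") - pick(2010, "no_low", "mean"),
               mean(draws[, "E_h"]), tolerance = 1e-10)
  # event-year jump within the high group equals trend + interruption
  expect_equal(pick(2014, "high", "mean") - pick(2013, "high", "mean"),
               mean(draws[, "T"]) + mean(draws[, "E_h:I_post"]),
               tolerance = 1e-10)
  expect_error(predicted_margins(fit, years = 2030), "span")
})

test_that("score-point effects convert to months of learning", {
  expect_equal(effect_to_months(27), 12)
  expect_equal(effect_to_months(0), 0)
  expect_equal(round(effect_to_months(11.09), 2), 4.93)
  expect_error(effect_to_months(10, points_per_year = 0), "points_per_year")
})

test_that("posterior is stable when iterations double", {
  res1 <- small_fit(seed = 44,
                    mcmc = mcmc_config(chains = 2, iterations = 600,
                                       seed = 44))
  res2 <- small_fit(seed = 44,
                    mcmc = mcmc_config(chains = 2, iterations = 1200,
                                       seed = 44))
  for (cn in c("E_h:I_post", "T")) {
    m1 <- mean(res1$fit$draws[, cn])
    m2 <- mean(res2$fit$draws[, cn])
    mcse <- sqrt(res1$fit$diagnostics$mcse[res1$fit$diagnostics$parameter == cn]^2 +
                   res2$fit$diagnostics$mcse[res2$fit$diagnostics$parameter == cn]^2)
    expect_lt(abs(m1 - m2), 3 * mcse)
  }
})

test_that("estimates agree with an independent REML meta-regression", {
  skip_if_not_installed("metafor")
  res <- small_fit(seed = 45,
                   priors = prior_spec(beta_sd = 1e4),
                   mcmc = mcmc_config(chains = 2, iterations = 1000,
                                      seed = 45))
  d <- res$design
  dat <- data.frame(yi = d$y, school = d$school_index, cohort = d$cohort_index)
  rma <- metafor::rma.mv(yi, V = d$se^2,
                         mods = d$X[, -1, drop = FALSE],
                         random = list(~ 1 | school, ~ 1 | cohort),
                         data = dat, sparse = TRUE)
  bayes <- colMeans(res$fit$draws[, res$fit$design_columns])
  reml <- c(rma$beta)
  names(reml) <- rownames(rma$beta)
  for (cn in c("T", "E_h:I_post", "E_h:I_post:T_post")) {
    bse <- sd(res$fit$draws[, cn])
    expect_lt(abs(bayes[cn] - reml[cn]), 1.0 + 0.5 * bse)
  }
})

test_that("posterior matches an independent Gibbs implementation (JAGS)", {
  skip_if_not_installed("rjags")
  study <- generate_study(
    sim_config(n_schools_by_group = c(no_low = 6, moderate = 4, high = 3),
               years = 2010:2017, domains = "Writing", seed = 46,
               truth = sim_truth(event_year = 2014)))
  obs <- center_scores(study$observations, study$reference)
  d <- build_design(obs, study$profiles, domain = "Writing")
  fit <- fit_model(d, mcmc = mcmc_config(chains = 2, iterations = 2000,
                                         seed = 46))

  model_str <- "model {
    for (i in 1:n) {
      y[i] ~ dnorm(inprod(X[i,], beta) + theta_s[school[i]] + theta_c[cohort[i]],
                   1 / (tau2[i] + sig_e^2))
    }
    for (s in 1:S) { theta_s[s] ~ dnorm(0, 1 / sig_s^2) }
    for (c in 1:C) { theta_c[c] ~ dnorm(0, 1 / sig_c^2) }
    for (j in 1:p) { beta[j] ~ dnorm(0, 1 / 50^2) }
    sig_s ~ dnorm(10, 1 / 25) T(0,)
    sig_c ~ dnorm(10, 1 / 25) T(0,)
    sig_e ~ dnorm(10, 1 / 25) T(0,)
  }"
  jm <- rjags::jags.model(
    textConnection(model_str),
    data = list(y = d$y, X = d$X, tau2 = d$se^2, n = nrow(d$X),
                p = ncol(d$X), school = d$school_index,
                cohort = d$cohort_index,
                S = length(d$school_levels), C = length(d$cohort_levels)),
    n.chains = 2, quiet = TRUE,
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 46))
  update(jm, 1500, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("beta", "sig_s", "sig_c", "sig_e"),
                              n.iter = 3000, progress.bar = "none")
  jdraw <- as.matrix(samp)
  jmeans <- colMeans(jdraw)
  jess <- pmax(coda::effectiveSize(samp), 5)

  for (k in seq_along(fit$design_columns)) {
    cn <- fit$design_columns[k]
    jn <- paste0("beta[", k, "]")
    ours <- mean(fit$draws[, cn])
    theirs <- jmeans[jn]
    # both sides carry Monte-Carlo error; JAGS single-site updates mix
    # slowly for school-level columns, so use its measured ESS
    tol <- 4 * sqrt(fit$diagnostics$mcse[k]^2 +
                      sd(jdraw[, jn])^2 / jess[jn]) + 0.05
    expect_lt(abs(ours - theirs), max(tol, 0.25))
  }
  expect_lt(abs(mean(fit$draws[, "sigma_e"]) - jmeans["sig_e"]), 1.0)
  expect_lt(abs(mean(fit$draws[, "sigma_school"]) - jmeans["sig_s"]), 1.0)
})
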