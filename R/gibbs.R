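# Blocked Gibbs sampler for the known-variance hierarchical meta-regression
#
#   y_i ~ N(X_i beta + theta_school(i) + theta_cohort(i), tau_i^2 + sigma_e^2)
#   theta_s ~ N(0, sigma_school^2), theta_c ~ N(0, sigma_cohort^2)
#
# The cell-level residual is marginalized into the observation variance,
# which is exact and removes one latent vector. Conditional on the three
# SDs, every remaining full conditional is Gaussian and is drawn jointly per
# block; the SDs get univariate slice updates (stepping-out + shrinkage)
# under their truncated-normal priors.

# Univariate slice sampler on (lower, Inf); logf need not be normalized.
.slice_pos <- function(x0, logf, w = 1, lower = 0, max_steps = 100L) {
  logy <- logf(x0) - rexp(1)
  u <- runif(1) * w
  L <- x0 - u
  R <- x0 + (w - u)
  k <- max_steps
  while (k > 0L && L > lower && logf(L) > logy) {
    L <- L - w; k <- k - 1L
  }
  L <- max(L, lower)
  k <- max_steps
  while (k > 0L && logf(R) > logy) {
    R <- R + w; k <- k - 1L
  }
  repeat {
    x1 <- runif(1, L, R)
    if (logf(x1) >= logy) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

.log_tn <- function(x, prior) {
  if (x <= prior$lower) return(-Inf)
  -0.5 * ((x - prior$mean) / prior$sd)^2
}

# columns of X that are constant within every level of `index`; returns the
# level-by-column matrix of those constant values (NULL if none)
.group_constant_cols <- function(X, index, nlev) {
  counts <- tabulate(index, nlev)
  means <- rowsum(X, index) / counts
  dev <- abs(X - means[index, , drop = FALSE])
  const <- apply(dev, 2, max) < 1e-10
  if (!any(const)) return(NULL)
  means[, const, drop = FALSE]
}

# one chain; returns matrices of kept draws
.gibbs_chain <- function(y, X, tau2, school, cohort, priors, iterations,
                         warmup, seed) {
  set.seed(seed)
  n <- length(y)
  p <- ncol(X)
  S <- if (is.null(school)) 0L else max(school)
  C <- if (is.null(cohort)) 0L else max(cohort)

  fix_s <- .is_fixed(priors$sigma_school)
  fix_c <- .is_fixed(priors$sigma_cohort)
  fix_e <- .is_fixed(priors$sigma_e)

  sig_s <- if (fix_s) priors$sigma_school$value else max(0.5, priors$sigma_school$mean)
  sig_c <- if (fix_c) priors$sigma_cohort$value else max(0.5, priors$sigma_cohort$mean)
  sig_e <- if (fix_e) priors$sigma_e$value else max(0.5, priors$sigma_e$mean)

  use_s <- S > 0L && sig_s > 0
  use_c <- C > 0L && sig_c > 0

  theta_s <- numeric(max(S, 1L))
  theta_c <- numeric(max(C, 1L))
  beta <- numeric(p)

  prior_prec <- setNames(rep(1 / priors$beta_sd^2, p), colnames(X))
  prior_mb <- rep(priors$beta_mean, p) * prior_prec

  kept <- iterations - warmup
  out_beta <- matrix(NA_real_, kept, p, dimnames = list(NULL, colnames(X)))
  out_sigma <- matrix(NA_real_, kept, 3,
                      dimnames = list(NULL, c("sigma_cohort", "sigma_school",
                                              "sigma_e")))
  out_theta_s <- if (use_s) matrix(NA_real_, kept, S) else NULL
  out_theta_c <- if (use_c) matrix(NA_real_, kept, C) else NULL

  re_s <- function() if (use_s) theta_s[school] else 0
  re_c <- function() if (use_c) theta_c[cohort] else 0

  # interweaving (translation) moves for the cohort block: for a design
  # column constant within every cohort, the likelihood is invariant to
  # shifting its coefficient into the cohort effects, so the shift has a
  # Gaussian full conditional driven by the priors alone; sampling it
  # decorrelates e.g. the intercept from the mean cohort effect
  const_c <- if (use_c) .group_constant_cols(X, cohort, C) else NULL

  if (use_s) {
    Ajoint <- matrix(0, p + S, p + S)
    ip <- seq_len(p)
    is_ <- p + seq_len(S)
  }

  # fast group sums over a fixed index: pre-sort once, then each call is a
  # single cumsum + diff (rowsum re-derives the grouping on every call)
  make_groupsum <- function(index, nlev) {
    ord <- order(index)
    ends <- cumsum(tabulate(index, nlev))
    vec <- function(x) {
      cs <- cumsum(x[ord])
      diff(c(0, cs[ends]))
    }
    mat <- function(M) {
      cs <- apply(M[ord, , drop = FALSE], 2, cumsum)
      rbind(cs[ends[1], ], diff(cs[ends, , drop = FALSE]))
    }
    list(vec = vec, mat = mat)
  }
  gs_s <- if (use_s) make_groupsum(school, S) else NULL
  gs_c <- if (use_c) make_groupsum(cohort, C) else NULL

  interweave <- function(theta, const, sig, beta) {
    for (j in colnames(const)) {
      xg <- const[, j]
      prec <- sum(xg^2) / sig^2 + prior_prec[j]
      m <- (sum(theta * xg) / sig^2 -
              (beta[j] - priors$beta_mean) * prior_prec[j]) / prec
      delta <- m + rnorm(1) / sqrt(prec)
      beta[j] <- beta[j] + delta
      theta <- theta - delta * xg
    }
    list(theta = theta, beta = beta)
  }

  for (it in seq_len(iterations)) {
    v <- tau2 + sig_e^2
    w <- 1 / v

    # (beta, theta_school) | rest: one joint Gaussian block via Cholesky of
    # the (p + S) precision matrix — jointly sampling the school effects
    # with the fixed effects removes their posterior correlation with
    # school-level (and nearly school-level) covariates
    r <- y - re_c()
    Xw <- X * w
    A11 <- crossprod(X, Xw)
    diag(A11) <- diag(A11) + prior_prec
    b1 <- crossprod(Xw, r) + prior_mb
    if (use_s) {
      A12 <- gs_s$mat(Xw)                           # S x p
      a22 <- gs_s$vec(w) + 1 / sig_s^2
      b2 <- gs_s$vec(w * r)
      A <- Ajoint                                   # preallocated (p+S)^2
      A[ip, ip] <- A11
      A[ip, is_] <- t(A12)
      A[is_, ip] <- A12
      A[cbind(is_, is_)] <- a22
      b <- c(b1, b2)
    } else {
      A <- A11
      b <- b1
    }
    U <- chol(A)
    mu <- backsolve(U, forwardsolve(t(U), b))
    draw <- as.vector(mu + backsolve(U, rnorm(length(b))))
    beta <- setNames(draw[seq_len(p)], colnames(X))
    if (use_s) theta_s <- draw[(p + 1):(p + S)]

    xb <- as.vector(X %*% beta)

    # (sigma_school, theta_school) block: slice-update the SD with the
    # school effects integrated out (same determinant-lemma structure as
    # the cohort block below), then redraw the effects given the new SD —
    # collapsing sidesteps the SD/effects funnel
    if (!fix_s && use_s) {
      r <- y - xb - re_c()
      d_a <- gs_s$vec(w)
      d_b <- gs_s$vec(w * r)
      # terms free of sig_s drop out of the slice density
      sig_s <- .slice_pos(sig_s, function(s) {
        -0.5 * (sum(log1p(s^2 * d_a)) - s^2 * sum(d_b^2 / (1 + s^2 * d_a))) +
          .log_tn(s, priors$sigma_school)
      }, w = priors$sigma_school$sd / 2)
      prec <- d_a + 1 / sig_s^2
      theta_s <- d_b / prec + rnorm(S) / sqrt(prec)
    }

    if (use_c) {
      # partially collapsed block: update (sigma_cohort, sigma_e) with the
      # cohort effects integrated out — the per-cohort marginal covariance
      # is diag(tau^2 + sigma_e^2) + sigma_c^2 * 11', handled by the
      # determinant lemma — then redraw the cohort effects. Collapsing
      # removes the funnel between sigma_cohort and sigma_e that makes the
      # conditional updates mix slowly when cohorts hold few cells.
      r <- y - xb - re_s()
      marg_stats <- function(se) {
        d <- tau2 + se^2
        di <- 1 / d
        list(a = gs_c$vec(di),
             bb = gs_c$vec(r * di),
             base = sum(log(d)) + sum(r^2 * di))
      }
      marg_ll <- function(sc, st)
        -0.5 * (st$base + sum(log1p(sc^2 * st$a)) -
                  sc^2 * sum(st$bb^2 / (1 + sc^2 * st$a)))
      if (!fix_c) {
        st <- marg_stats(sig_e)
        sig_c <- .slice_pos(sig_c, function(s)
          marg_ll(s, st) + .log_tn(s, priors$sigma_cohort),
          w = priors$sigma_cohort$sd / 2)
      }
      if (!fix_e)
        sig_e <- .slice_pos(sig_e, function(s)
          marg_ll(sig_c, marg_stats(s)) + .log_tn(s, priors$sigma_e),
          w = priors$sigma_e$sd / 2)

      # cohort effects | sigmas, rest
      v <- tau2 + sig_e^2
      w <- 1 / v
      prec <- gs_c$vec(w) + 1 / sig_c^2
      m <- gs_c$vec(w * r) / prec
      theta_c <- m + rnorm(C) / sqrt(prec)

      if (!is.null(const_c) && sig_c > 0) {
        iw <- interweave(theta_c, const_c, sig_c, beta)
        theta_c <- iw$theta; beta <- iw$beta
        xb <- as.vector(X %*% beta)
      }
    } else if (!fix_e) {
      r2 <- (y - xb - re_s())^2
      sig_e <- .slice_pos(sig_e, function(s) {
        vv <- tau2 + s^2
        -0.5 * sum(log(vv) + r2 / vv) + .log_tn(s, priors$sigma_e)
      }, w = priors$sigma_e$sd / 2)
    }

    if (it > warmup) {
      k <- it - warmup
      out_beta[k, ] <- beta
      out_sigma[k, ] <- c(sig_c, sig_s, sig_e)
      if (use_s) out_theta_s[k, ] <- theta_s
      if (use_c) out_theta_c[k, ] <- theta_c
    }
  }
  list(beta = out_beta, sigma = out_sigma,
       theta_school = out_theta_s, theta_cohort = out_theta_c)
}

# split-Rhat (Gelman et al.): each chain halved, potential scale reduction
# across the 2 * chains half-sequences; vectorized over parameters
.split_rhat <- function(draws_by_chain) {
  halves <- list()
  for (ch in draws_by_chain) {
    n <- nrow(ch)
    h <- floor(n / 2)
    halves <- c(halves, list(ch[seq_len(h), , drop = FALSE],
                             ch[(n - h + 1):n, , drop = FALSE]))
  }
  m <- length(halves)
  n <- nrow(halves[[1]])
  means <- sapply(halves, colMeans)
  vars <- sapply(halves, function(h) apply(h, 2, var))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1)
    vars <- matrix(vars, nrow = 1)
  }
  B <- n * apply(means, 1, var)
  W <- rowMeans(vars)
  rhat <- sqrt(((n - 1) / n * W + B / n) / W)
  rhat[W == 0] <- 1
  names(rhat) <- colnames(draws_by_chain[[1]])
  rhat
}
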