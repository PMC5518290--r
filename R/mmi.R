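#' Multilevel imputation configuration
#'
#' Settings for the Bayesian random-intercept probit imputation model:
#' number of imputations `Q` (15 by default), burn-in iterations (100),
#' thinning between retained draws (25), whether the imputation model
#' includes the arm-by-covariate interaction, and the seed. Priors are an
#' improper flat prior on the regression coefficients and
#' inverse-gamma(0.001, 0.001) on the random-intercept variance.
#'
#' @param Q Number of imputations (>= 2).
#' @param burn_in Burn-in iterations (>= 0).
#' @param thin Iterations between retained draws (>= 1).
#' @param include_interaction Include arm-by-centred-covariate interaction
#'   in the imputation model.
#' @param prior_a,prior_b Inverse-gamma hyperparameters for the
#'   random-intercept variance.
#' @param seed Integer seed.
#' @return An object of class `imputation_config`.
#' @export
imputation_config <- function(Q = 15L, burn_in = 100L, thin = 25L,
                              include_interaction = FALSE,
                              prior_a = 0.001, prior_b = 0.001, seed = 1L) {
  stopifnot(Q >= 2, burn_in >= 0, thin >= 1)
  structure(list(Q = as.integer(Q), burn_in = as.integer(burn_in),
                 thin = as.integer(thin),
                 include_interaction = include_interaction,
                 prior_a = prior_a, prior_b = prior_b,
                 seed = as.integer(seed)),
            class = "imputation_config")
}

# One-sided/two-sided truncated standard-normal-location draws via the
# inverse CDF; lower/upper are vectors of truncation bounds for N(mean, 1).
rtnorm1 <- function(mean, lower, upper) {
  pl <- pnorm(lower - mean)
  pu <- pnorm(upper - mean)
  u <- pl + runif(length(mean)) * (pu - pl)
  # guard against u hitting 0/1 in the far tails
  u <- pmin(pmax(u, 1e-15), 1 - 1e-15)
  mean + qnorm(u)
}

#' Gibbs sampler for the random-intercept probit imputation model
#'
#' Data-augmentation Gibbs sampler for
#' `probit P(Y=1) = W gamma + b_cluster`, `b ~ N(0, tau2)`: each iteration
#' draws (i) latent normals truncated to (0, Inf) or (-Inf, 0) by the
#' observed outcome, and from the untruncated predictive at missing
#' positions, (ii) the coefficients from their multivariate-normal full
#' conditional under a flat prior, (iii) the cluster effects from their
#' normal full conditionals, and (iv) tau2 from its inverse-gamma full
#' conditional. Deterministic given `cfg$seed`.
#'
#' @param data A trial tibble (may contain missing outcomes).
#' @param cfg An [imputation_config()].
#' @return An object of class `crt_gibbs`: matrices of retained draws of
#'   `gamma` (Q x p), `tau2` (length Q), `b` (Q x n_clusters), the list of
#'   imputed outcome vectors at missing positions, and the design info.
#' @export
gibbs_probit_fit <- function(data, cfg = imputation_config()) {
  stopifnot(inherits(cfg, "imputation_config"))
  data <- validate_trial(data)
  for (a in 0:1) {
    if (!any(data$arm == a & data$r == 1)) {
      stop("arm ", a, " has no observed outcomes to fit the imputation model")
    }
  }
  design <- build_design(data, cfg$include_interaction)
  W <- design_matrix(data, design)
  p <- ncol(W)
  g <- as.integer(global_cluster(data))
  J <- max(g)
  n_j <- tabulate(g, J)
  obs <- data$r == 1
  y <- data$y
  n <- nrow(data)

  set.seed(cfg$seed)
  # Deterministic start: probit GLM on observed records, b = 0, tau2 = 0.1.
  start <- glm.fit(W[obs, , drop = FALSE], y[obs],
                   family = binomial(link = "probit"))
  gamma <- coef(start)
  gamma[!is.finite(gamma)] <- 0
  b <- numeric(J)
  tau2 <- 0.1

  WtWinv <- solve(crossprod(W))
  cholWtWinv <- chol(WtWinv)

  n_iter <- cfg$burn_in + cfg$thin * cfg$Q
  keep <- cfg$burn_in + cfg$thin * seq_len(cfg$Q)
  G <- matrix(NA_real_, cfg$Q, p, dimnames = list(NULL, colnames(W)))
  T2 <- numeric(cfg$Q)
  Bdraws <- matrix(NA_real_, cfg$Q, J)
  imputed <- vector("list", cfg$Q)
  lower <- ifelse(obs & y == 1, 0, -Inf)
  upper <- ifelse(obs & y == 0, 0, Inf)
  ki <- 0L
  for (it in seq_len(n_iter)) {
    eta <- drop(W %*% gamma) + b[g]
    z <- rtnorm1(eta, lower, upper)
    # coefficients | z, b  (flat prior)
    resid <- z - b[g]
    mean_g <- drop(WtWinv %*% crossprod(W, resid))
    gamma <- mean_g + drop(crossprod(cholWtWinv, rnorm(p)))
    # cluster effects | z, gamma, tau2
    rz <- z - drop(W %*% gamma)
    prec <- n_j + 1 / tau2
    b <- drop(rowsum(rz, g)) / prec + rnorm(J) / sqrt(prec)
    # tau2 | b
    tau2 <- 1 / stats::rgamma(1, cfg$prior_a + J / 2,
                              cfg$prior_b + sum(b^2) / 2)
    if (it %in% keep) {
      ki <- ki + 1L
      G[ki, ] <- gamma
      T2[ki] <- tau2
      Bdraws[ki, ] <- b
      # Bernoulli imputation at missing positions from the current state.
      pm <- pnorm(drop(W[!obs, , drop = FALSE] %*% gamma) + b[g[!obs]])
      imputed[[ki]] <- as.integer(runif(sum(!obs)) < pm)
    }
  }
  structure(list(gamma = G, tau2 = T2, b = Bdraws, imputed = imputed,
                 design = design, missing_idx = which(!obs), cfg = cfg),
            class = "crt_gibbs")
}

#' @method print crt_gibbs
#' @export
print.crt_gibbs <- function(x, ...) {
  cat("<crt_gibbs> ", nrow(x$gamma), " retained draws, ",
      length(x$missing_idx), " missing outcomes\n", sep = "")
  print(round(colMeans(x$gamma), 4))
  invisible(x)
}

#' Tidy the retained Gibbs draws
#'
#' @param x A `crt_gibbs`.
#' @param ... Unused.
#' @return One row per imputation-model parameter with posterior mean and SD
#'   over the retained draws.
#' @method tidy crt_gibbs
#' @export
tidy.crt_gibbs <- function(x, ...) {
  draws <- cbind(x$gamma, tau2 = x$tau2)
  tibble::tibble(
    term = colnames(draws),
    estimate = colMeans(draws),
    std.error = apply(draws, 2, sd))
}

#' Multiply impute missing outcomes
#'
#' Runs [gibbs_probit_fit()] and assembles `Q` completed datasets, one per
#' retained draw. Observed outcomes are identical in every completed
#' dataset; only missing positions vary.
#'
#' @param data A trial tibble.
#' @param cfg An [imputation_config()].
#' @return A list of `Q` completed trial tibbles with the `crt_gibbs`
#'   sampler attached as attribute `"sampler"`.
#' @export
impute <- function(data, cfg = imputation_config()) {
  data <- validate_trial(data)
  fit <- gibbs_probit_fit(data, cfg)
  sets <- lapply(seq_len(cfg$Q), function(q) {
    d <- data
    d$y[fit$missing_idx] <- fit$imputed[[q]]
    d$r <- 1L
    d
  })
  attr(sets, "sampler") <- fit
  class(sets) <- c("crt_imputations", class(sets))
  sets
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Combines `Q` completed-data estimates and variances: pooled estimate is
#' the mean; total variance is `W + (1 + 1/Q) B` with `W` the average
#' within-imputation variance and `B` the between-imputation variance. The
#' usual MI degrees of freedom are
#' `upsilon = (Q-1) (1 + Q W / ((Q+1) B))^2`, which can exceed the
#' complete-data df `nu_com` (here 2k - 2); the Barnard-Rubin adjusted df
#' `nu_adj = (1/upsilon + 1/nu_obs_hat)^-1` with
#' `nu_obs_hat = ((nu_com+1)/(nu_com+3)) nu_com (1 + ((Q+1)/Q) B/W)^-1`
#' never does, and is used for the confidence interval.
#'
#' @param estimates Numeric vector of Q completed-data estimates.
#' @param variances Numeric vector of Q completed-data variances (se^2).
#' @param nu_com Complete-data degrees of freedom.
#' @param scale Effect scale label (see [effect_estimate()]).
#' @param level Confidence level.
#' @return An object of class `crt_pooled`.
#' @export
rubin_pool <- function(estimates, variances, nu_com, scale = "RD",
                       level = 0.95) {
  Q <- length(estimates)
  stopifnot(Q >= 2, length(variances) == Q, all(variances >= 0), nu_com > 0)
  est <- mean(estimates)
  W <- mean(variances)
  B <- var(estimates)
  if (W == 0 && B > 0) stop("degenerate pooling: W = 0 with B > 0")
  total <- W + (1 + 1 / Q) * B
  if (B > 0) {
    upsilon <- (Q - 1) * (1 + Q * W / ((Q + 1) * B))^2
    nu_obs <- (nu_com + 1) / (nu_com + 3) * nu_com /
      (1 + (Q + 1) / Q * B / W)
    nu_adj <- 1 / (1 / upsilon + 1 / nu_obs)
  } else {
    upsilon <- Inf
    nu_obs <- (nu_com + 1) / (nu_com + 3) * nu_com
    nu_adj <- nu_obs
  }
  se <- sqrt(total)
  ci <- t_interval(est, se, nu_adj, level)
  structure(
    list(scale = scale, estimate = est, W = W, B = B, Q = Q,
         total_var = total, upsilon = upsilon, nu_com = nu_com,
         nu_obs = nu_obs, nu_adj = nu_adj, se = se,
         ci_low = ci[1], ci_high = ci[2], level = level,
         p_value = if (se > 0) 2 * pt(-abs(est / se), nu_adj)
                   else as.numeric(est == 0)),
    class = "crt_pooled")
}

#' @method print crt_pooled
#' @export
print.crt_pooled <- function(x, ...) {
  cat("<crt_pooled> ", x$scale, " over Q = ", x$Q, " imputations\n", sep = "")
  cat(sprintf("  estimate %.4f  se %.4f (W %.4g, B %.4g)\n",
              x$estimate, x$se, x$W, x$B))
  cat(sprintf("  df: upsilon %.2f, Barnard-Rubin %.2f (complete-data %g)\n",
              x$upsilon, x$nu_adj, x$nu_com))
  cat(sprintf("  %d%% CI (%.4f, %.4f)\n", round(100 * x$level),
              x$ci_low, x$ci_high))
  invisible(x)
}

#' @method tidy crt_pooled
#' @export
tidy.crt_pooled <- function(x, ...) {
  tibble::tibble(
    scale = x$scale, estimate = x$estimate, std.error = x$se,
    W = x$W, B = x$B, Q = x$Q, df = x$nu_adj, upsilon = x$upsilon,
    nu_com = x$nu_com, conf.low = x$ci_low, conf.high = x$ci_high,
    p.value = x$p_value)
}

#' @method glance crt_pooled
#' @export
glance.crt_pooled <- function(x, ...) tidy(x, ...)

run_estimator <- function(data, method, effect = NULL, use = "full",
                          interaction = FALSE, nagq = 15L) {
  switch(
    method,
    cl_u = {
      s <- cluster_summaries(data, use)
      if (effect == "rd") estimate_rd_unadjusted(s)
      else estimate_rr_unadjusted(s)
    },
    cl_a = {
      if (effect == "rd") estimate_rd_adjusted(data, use)
      else estimate_rr_adjusted(data, use)
    },
    relr = fit_relr(data, build_design(data, interaction), use,
                    nagq = nagq)$effect,
    gee = fit_gee(data, build_design(data, interaction), use)$effect,
    stop("unknown method: ", method)
  )
}

#' Analyse an incomplete dataset with multilevel multiple imputation
#'
#' Imputes the missing outcomes `Q` times, runs the requested estimator on
#' each completed dataset (ratio effects on the log scale), and pools with
#' Rubin's rules using complete-data df `2k - 2`.
#'
#' @param data A trial tibble with missing outcomes.
#' @param method `"cl_u"`, `"cl_a"`, `"relr"` or `"gee"`.
#' @param effect `"rd"` or `"rr"` for the cluster-level methods; ignored
#'   for `relr`/`gee`.
#' @param cfg An [imputation_config()].
#' @param interaction Include the arm-by-covariate interaction in the
#'   analysis model (`relr`/`gee`).
#' @param nagq Quadrature nodes for `relr`.
#' @return A `crt_pooled`.
#' @export
analyze_with_mmi <- function(data, method = c("cl_u", "cl_a", "relr", "gee"),
                             effect = c("rd", "rr"),
                             cfg = imputation_config(),
                             interaction = FALSE, nagq = 15L) {
  method <- match.arg(method)
  effect <- match.arg(effect)
  data <- validate_trial(data)
  k <- clusters_per_arm(data)[1]
  sets <- impute(data, cfg)
  pool_over_sets(sets, method, effect, k, interaction = interaction,
                 nagq = nagq)
}
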