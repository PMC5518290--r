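#' Outcome data-generating configuration
#'
#' Describes the generative model for a balanced two-arm CRT with a clustered
#' continuous baseline covariate and a binary outcome. The covariate is
#' X = alpha_cluster + u_individual with alpha ~ N(mu_x, sigma_alpha2) and
#' u ~ N(0, sigma_u2), so Var(X) = sigma_alpha2 + sigma_u2 and the covariate
#' ICC is sigma_alpha2 / Var(X). The outcome success probability is
#' `link^-1(beta0 + beta1 * arm + beta2[arm] * X + delta_cluster)` with
#' delta ~ N(0, sigma_b2) and Y ~ Bernoulli.
#'
#' @param beta0 Intercept of the outcome model.
#' @param beta1 Intervention effect, conditional on cluster effect and X
#'   (log odds ratio under the logit link, log risk ratio under the log
#'   link).
#' @param beta2 Covariate effect per arm; length-2 vector `c(control,
#'   intervention)` (a scalar is recycled).
#' @param sigma_b2 Variance of the cluster random intercept of the outcome
#'   model (>= 0).
#' @param mu_x Mean of the covariate.
#' @param sigma_alpha2 Between-cluster variance of the covariate (>= 0).
#' @param sigma_u2 Within-cluster variance of the covariate (> 0).
#' @param link `"logit"` (default) or `"log"`. Under the log link the
#'   covariate and cluster effect are truncated at +/- 4 SD and the
#'   configuration is rejected unless the maximum achievable linear
#'   predictor is negative, so that all success probabilities stay below 1.
#' @param k Number of clusters per arm.
#' @param m Individuals per cluster (before missingness).
#' @return An object of class `dgm_config`.
#' @export
dgm_config <- function(beta0 = 0, beta1 = 0, beta2 = c(0, 0),
                       sigma_b2 = 0, mu_x = 0, sigma_alpha2 = 0,
                       sigma_u2 = 1, link = c("logit", "log"),
                       k = 10L, m = 50L) {
  link <- match.arg(link)
  if (length(beta2) == 1) beta2 <- rep(beta2, 2)
  stopifnot(length(beta2) == 2, sigma_b2 >= 0, sigma_alpha2 >= 0,
            sigma_u2 > 0, k >= 1, m >= 1)
  cfg <- structure(
    list(beta0 = beta0, beta1 = beta1, beta2 = as.numeric(beta2),
         sigma_b2 = sigma_b2, mu_x = mu_x, sigma_alpha2 = sigma_alpha2,
         sigma_u2 = sigma_u2, link = link, k = as.integer(k),
         m = as.integer(m)),
    class = "dgm_config")
  if (link == "log") {
    sx <- sqrt(cfg$sigma_alpha2 + cfg$sigma_u2)
    x_hi <- c(mu_x - 4 * sx, mu_x + 4 * sx)
    d_hi <- 4 * sqrt(sigma_b2)
    for (i in 0:1) {
      lp_max <- beta0 + beta1 * i + max(cfg$beta2[i + 1] * x_hi) + d_hi
      if (lp_max >= 0) {
        stop("log-link config invalid: maximum linear predictor ",
             signif(lp_max, 4), " in arm ", i,
             " reaches a success probability >= 1")
      }
    }
  }
  cfg
}

#' Covariate-dependent missingness configuration
#'
#' Outcomes are set missing independently per individual with probability
#' `expit(psi[arm] + phi[arm] * X)`; missingness depends only on the fully
#' observed baseline covariate (a covariate-dependent, MAR, mechanism).
#'
#' @param psi Intercept per arm (length-2 or scalar).
#' @param phi Covariate effect per arm (length-2 or scalar); `exp(phi)` is
#'   the odds ratio of being missing for a one-unit increase in X.
#' @return An object of class `missingness_config`.
#' @export
missingness_config <- function(psi = c(-Inf, -Inf), phi = c(0, 0)) {
  if (length(psi) == 1) psi <- rep(psi, 2)
  if (length(phi) == 1) phi <- rep(phi, 2)
  stopifnot(length(psi) == 2, length(phi) == 2, all(is.finite(phi)))
  structure(list(psi = as.numeric(psi), phi = as.numeric(phi)),
            class = "missingness_config")
}

#' Published simulation scenarios
#'
#' The four study scenarios share mu_x = 0, sigma_u2 = 3.37,
#' sigma_alpha2 = 0.18, sigma_b2 = 0.20, beta0 = 0, beta1 = 1.36,
#' phi = 1 and m = 50 under the logit link, and differ in whether the
#' covariate effect on the outcome and the missingness mechanism are the
#' same in the two arms:
#' * S1: beta2 = (1, 1), psi = (-1.34, -1.34) — same effect, same mechanism
#'   (30\% missing in both arms);
#' * S2: beta2 = (1, 1), psi = (-1.34, 0.65) — same effect, different
#'   mechanism (30\% / 60\% missing);
#' * S3: beta2 = (0.588, 1), psi = (-1.34, -1.34);
#' * S4: beta2 = (0.588, 1), psi = (-1.34, 0.65).
#'
#' @param name One of `"S1"`, `"S2"`, `"S3"`, `"S4"`.
#' @param k Clusters per arm (the study varied k in 5, 10, 20, 50).
#' @param m Cluster size (50 in the study).
#' @return A list with elements `dgm` (a [dgm_config()]) and `missingness`
#'   (a [missingness_config()]); also carries `interaction`, TRUE when the
#'   covariate effect differs between arms so analysis and imputation
#'   models need an arm-by-covariate interaction.
#' @export
scenario_preset <- function(name, k = 10L, m = 50L) {
  pars <- switch(
    as.character(name),
    S1 = list(beta2 = c(1, 1),     psi = c(-1.34, -1.34)),
    S2 = list(beta2 = c(1, 1),     psi = c(-1.34, 0.65)),
    S3 = list(beta2 = c(0.588, 1), psi = c(-1.34, -1.34)),
    S4 = list(beta2 = c(0.588, 1), psi = c(-1.34, 0.65)),
    stop("unknown scenario: ", name)
  )
  list(
    dgm = dgm_config(beta0 = 0, beta1 = 1.36, beta2 = pars$beta2,
                     sigma_b2 = 0.20, mu_x = 0, sigma_alpha2 = 0.18,
                     sigma_u2 = 3.37, link = "logit", k = k, m = m),
    missingness = missingness_config(psi = pars$psi, phi = c(1, 1)),
    interaction = pars$beta2[1] != pars$beta2[2]
  )
}

inv_link <- function(lp, link) {
  if (link == "logit") expit(lp) else exp(lp)
}

trunc_norm <- function(n, mean, sd, bound_sd = Inf) {
  z <- rnorm(n, mean, sd)
  if (is.finite(bound_sd) && sd > 0) {
    z <- pmin(pmax(z, mean - bound_sd * sd), mean + bound_sd * sd)
  }
  z
}

#' Simulate a full (no missingness) trial dataset
#'
#' Generates a balanced dataset under a [dgm_config()]: cluster covariate
#' means, individual covariate errors, outcome-model cluster intercepts and
#' Bernoulli outcomes, in that fixed order, so results are reproducible
#' given `seed`.
#'
#' @param cfg A [dgm_config()].
#' @param seed Integer seed.
#' @return A trial tibble with all outcomes observed (`r == 1`).
#' @export
simulate_full_data <- function(cfg, seed) {
  stopifnot(inherits(cfg, "dgm_config"))
  set.seed(seed)
  k <- cfg$k; m <- cfg$m
  bound <- if (cfg$link == "log") 4 else Inf
  n_cl <- 2L * k
  arm_cl <- rep(0:1, each = k)
  alpha <- trunc_norm(n_cl, cfg$mu_x, sqrt(cfg$sigma_alpha2), Inf)
  u <- rnorm(n_cl * m, 0, sqrt(cfg$sigma_u2))
  delta <- trunc_norm(n_cl, 0, sqrt(cfg$sigma_b2), bound)
  cl_idx <- rep(seq_len(n_cl), each = m)
  x <- alpha[cl_idx] + u
  if (cfg$link == "log") {
    sx <- sqrt(cfg$sigma_alpha2 + cfg$sigma_u2)
    x <- pmin(pmax(x, cfg$mu_x - 4 * sx), cfg$mu_x + 4 * sx)
  }
  arm <- arm_cl[cl_idx]
  lp <- cfg$beta0 + cfg$beta1 * arm + cfg$beta2[arm + 1] * x + delta[cl_idx]
  p <- inv_link(lp, cfg$link)
  if (any(p >= 1 | p < 0)) {
    stop("success probabilities outside [0, 1) under the ", cfg$link, " link")
  }
  y <- rbinom(length(p), 1L, p)
  tibble::tibble(
    arm = as.integer(arm),
    cluster = as.integer(rep(rep(seq_len(k), each = m), 2)),
    individual = as.integer(rep(seq_len(m), n_cl)),
    x = x,
    y = as.integer(y),
    r = 1L
  )
}

#' Impose covariate-dependent missingness on a full dataset
#'
#' Independently for each individual, the outcome is deleted with
#' probability `expit(psi[arm] + phi[arm] * x)`. The covariate is never
#' removed.
#'
#' @param data A trial tibble with all outcomes observed.
#' @param mcfg A [missingness_config()].
#' @param seed Integer seed.
#' @return The dataset with `y` set to `NA` (and `r` to 0) where missing.
#' @export
impose_cdm_missingness <- function(data, mcfg, seed) {
  stopifnot(inherits(mcfg, "missingness_config"))
  data <- validate_trial(data)
  set.seed(seed)
  p_miss <- expit(mcfg$psi[data$arm + 1] + mcfg$phi[data$arm + 1] * data$x)
  miss <- runif(nrow(data)) < p_miss
  data$y[miss] <- NA_integer_
  data$r <- as.integer(!miss)
  data
}

#' Marginal success probability in one arm by quadrature
#'
#' Integrates the inverse-link success probability over the normal laws of
#' the covariate (marginally N(mu_x, sigma_alpha2 + sigma_u2)) and the
#' outcome-model cluster effect, using a tensor Gauss-Hermite rule.
#'
#' @param cfg A [dgm_config()] with logit link.
#' @param arm 0 or 1.
#' @param nodes Quadrature nodes per dimension.
#' @return The population success probability pi_i.
#' @export
marginal_success_probability <- function(cfg, arm, nodes = 64) {
  stopifnot(inherits(cfg, "dgm_config"), cfg$link == "logit",
            arm %in% c(0, 1))
  s2x <- cfg$sigma_alpha2 + cfg$sigma_u2
  b2 <- cfg$beta2[arm + 1]
  gh_expect2(
    function(x, d) expit(cfg$beta0 + cfg$beta1 * arm + b2 * x + d),
    cfg$mu_x, s2x, 0, cfg$sigma_b2, n = nodes)
}

#' Expected proportion of missing outcomes in one arm
#'
#' Integrates `expit(psi + phi * x)` over the marginal normal law of the
#' covariate.
#'
#' @inheritParams marginal_success_probability
#' @param mcfg A [missingness_config()].
#' @return Expected missing proportion in `arm`.
#' @export
expected_missing_proportion <- function(cfg, mcfg, arm, nodes = 64) {
  stopifnot(inherits(cfg, "dgm_config"), inherits(mcfg, "missingness_config"),
            arm %in% c(0, 1))
  s2x <- cfg$sigma_alpha2 + cfg$sigma_u2
  psi <- mcfg$psi[arm + 1]; phi <- mcfg$phi[arm + 1]
  if (phi == 0) return(expit(psi))
  gh_expect(function(x) expit(psi + phi * x), cfg$mu_x, s2x, n = nodes)
}

#' Estimate the outcome intraclass correlation per arm by simulation
#'
#' Simulates a very large dataset of true cluster-level success
#' probabilities: for each cluster, draws the covariate cluster mean and the
#' outcome cluster effect, averages the individual success probabilities
#' over `m_big` covariate errors, and returns
#' `Var(pi_ij) / (pi_i * (1 - pi_i))` with pi_i from quadrature.
#'
#' @param cfg A [dgm_config()] with logit link.
#' @param n_clusters Clusters per arm to simulate (large, e.g. >= 1000).
#' @param m_big Individuals per cluster used to average within cluster.
#' @param seed Integer seed.
#' @return Named numeric `c(rho0, rho1)`.
#' @export
estimate_outcome_icc <- function(cfg, n_clusters = 2000L, m_big = 1000L,
                                 seed = 1L) {
  stopifnot(inherits(cfg, "dgm_config"), cfg$link == "logit")
  set.seed(seed)
  out <- numeric(2)
  for (i in 0:1) {
    pi_i <- marginal_success_probability(cfg, i)
    if (pi_i <= 0 || pi_i >= 1) stop("ICC undefined: pi_", i, " is ", pi_i)
    alpha <- rnorm(n_clusters, cfg$mu_x, sqrt(cfg$sigma_alpha2))
    delta <- rnorm(n_clusters, 0, sqrt(cfg$sigma_b2))
    pij <- vapply(seq_len(n_clusters), function(j) {
      u <- rnorm(m_big, 0, sqrt(cfg$sigma_u2))
      mean(expit(cfg$beta0 + cfg$beta1 * i +
                   cfg$beta2[i + 1] * (alpha[j] + u) + delta[j]))
    }, numeric(1))
    out[i + 1] <- var(pij) / (pi_i * (1 - pi_i))
  }
  c(rho0 = out[1], rho1 = out[2])
}

#' Calibrate the missingness intercept for a target missing proportion
#'
#' Root-finds psi so that [expected_missing_proportion()] equals `target`
#' for the given covariate law and slope.
#'
#' @param cfg A [dgm_config()] (supplies the covariate law).
#' @param target Desired missing proportion, in (0, 1).
#' @param phi Covariate effect on missingness.
#' @param arm 0 or 1.
#' @return The calibrated psi.
#' @export
calibrate_psi <- function(cfg, target, phi, arm = 0) {
  stopifnot(target > 0, target < 1)
  f <- function(psi) {
    m <- missingness_config(psi = psi, phi = phi)
    expected_missing_proportion(cfg, m, arm) - target
  }
  uniroot(f, c(-50, 50), tol = 1e-9)$root
}
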