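test_that("Rubin pooling reproduces hand arithmetic and its limits", {
  # Q = 3, W = 1, B = 0.5, nu_com = 8: worked by hand from the printed
  # formulas. Estimates chosen so their sample variance is exactly 0.5.
  est <- c(1 - sqrt(0.5), 1, 1 + sqrt(0.5))
  expect_equal(var(est), 0.5)
  p <- rubin_pool(est, rep(1, 3), nu_com = 8)
  expect_equal(p$estimate, 1)
  expect_equal(p$W, 1)
  expect_equal(p$B, 0.5)
  expect_equal(p$total_var, 1 + (4 / 3) * 0.5, tolerance = 1e-12)  # 1.6667
  expect_equal(p$upsilon, 2 * (1 + 3 / (4 * 0.5))^2, tolerance = 1e-12)  # 12.5
  expect_equal(p$nu_obs, (9 / 11) * 8 / (1 + (4 / 3) * 0.5),
               tolerance = 1e-12)                                  # 3.927
  expect_equal(p$nu_adj, 2.988, tolerance = 1e-3)
  expect_lte(p$nu_adj, p$nu_com)

  # B = 0 limit: total variance is W, df fall back to nu_obs <= nu_com
  p0 <- rubin_pool(rep(0.3, 4), rep(0.02, 4), nu_com = 18)
  expect_equal(p0$B, 0)
  expect_equal(p0$total_var, p0$W)
  expect_equal(p0$upsilon, Inf)
  expect_equal(p0$nu_adj, p0$nu_obs)
  expect_lte(p0$nu_adj, 18)

  expect_error(rubin_pool(c(0, 1), c(0, 0), nu_com = 8), "degenerate")
})

test_that("nu_adj never exceeds nu_com over random pooling inputs", {
  set.seed(42)
  for (i in 1:50) {
    Q <- sample(2:20, 1)
    est <- rnorm(Q)
    v <- rexp(Q) + 1e-3
    nu_com <- sample(2:100, 1)
    p <- rubin_pool(est, v, nu_com)
    expect_lte(p$nu_adj, nu_com)
    expect_gte(p$total_var, p$W)
  }
})

test_that("imputation returns the input when nothing is missing", {
  sc <- scenario_preset("S1", k = 3, m = 10)
  d <- simulate_full_data(sc$dgm, 15)
  sets <- impute(d, imputation_config(Q = 3, burn_in = 20, thin = 5,
                                      seed = 6))
  expect_length(sets, 3L)
  for (s in sets) expect_identical(s$y, d$y)
  # pooling a complete dataset reproduces the single-dataset estimate
  pooled <- analyze_with_mmi(d, "cl_u", "rd",
                             imputation_config(Q = 3, burn_in = 20,
                                               thin = 5, seed = 6))
  single <- estimate_rd_unadjusted(cluster_summaries(d, "full"))
  expect_equal(pooled$estimate, single$estimate)
  expect_equal(pooled$B, 0)
})

test_that("imputation never alters observed outcomes and completes all", {
  sc <- scenario_preset("S2", k = 6, m = 20)
  d <- simulate_full_data(sc$dgm, 33)
  di <- impose_cdm_missingness(d, sc$missingness, 34)
  sets <- impute(di, imputation_config(Q = 5, burn_in = 50, thin = 10,
                                       seed = 35))
  obs <- di$r == 1
  for (s in sets) {
    expect_false(anyNA(s$y))
    expect_identical(s$y[obs], di$y[obs])
  }
  # at least two sets differ somewhere in the imputed positions
  imp <- vapply(sets, function(s) paste(s$y[!obs], collapse = ""), "")
  expect_gt(length(unique(imp)), 1L)
})

test_that("Gibbs sampler recovers probit generative parameters", {
  # Large probit-generated dataset with known coefficients and
  # random-intercept variance.
  set.seed(77)
  k <- 200L; m <- 50L
  gamma_true <- c(-0.3, 0.7, 0.45)
  tau2_true <- 0.15
  arm <- rep(c(0L, 1L), each = k * m)
  cl <- rep(seq_len(2L * k), each = m)
  x <- rnorm(2L * k * m, 0, 1.3)
  b <- rnorm(2L * k, 0, sqrt(tau2_true))
  y <- as.integer(runif(2L * k * m) <
                    pnorm(gamma_true[1] + gamma_true[2] * arm +
                            gamma_true[3] * x + b[cl]))
  d <- tibble::tibble(arm = arm, cluster = rep(rep(seq_len(k), each = m), 2),
                      individual = rep(seq_len(m), 2L * k), x = x, y = y)
  fit <- gibbs_probit_fit(d, imputation_config(Q = 30, burn_in = 100,
                                               thin = 5, seed = 99))
  post <- tidy(fit)
  for (j in 1:3) {
    expect_lt(abs(post$estimate[j] - gamma_true[j]),
              3 * max(post$std.error[j], 0.01))
  }
  expect_lt(abs(mean(fit$tau2) - tau2_true), 3 * max(sd(fit$tau2), 0.02))
  # two chains with different seeds agree on the arm coefficient
  fit2 <- gibbs_probit_fit(d, imputation_config(Q = 30, burn_in = 100,
                                                thin = 5, seed = 1234))
  post2 <- tidy(fit2)
  comb <- sqrt(post$std.error[2]^2 / 30 + post2$std.error[2]^2 / 30) + 0.005
  expect_lt(abs(post$estimate[2] - post2$estimate[2]), 3 * comb)
})

test_that("imputed success rate among missing records matches quadrature", {
  sc <- scenario_preset("S2", k = 100, m = 50)
  d <- simulate_full_data(sc$dgm, 404)
  di <- impose_cdm_missingness(d, sc$missingness, 405)
  sets <- impute(di, imputation_config(seed = 406))
  miss1 <- di$arm == 1 & di$r == 0
  props <- vapply(sets, function(s) mean(s$y[miss1]), numeric(1))
  # True conditional success rate among missing arm-1 individuals:
  # E[pi_1(X) w(X)] / E[w(X)] with w the missingness probability, both by
  # Gauss-Hermite quadrature over X ~ N(0, sigma_x^2), and pi_1 integrating
  # over the outcome cluster effect.
  cfg <- sc$dgm; mc <- sc$missingness
  s2x <- cfg$sigma_alpha2 + cfg$sigma_u2
  pi1 <- function(x) {
    vapply(x, function(xi) {
      crtmiss:::gh_expect(function(dd) expit_(cfg$beta0 + cfg$beta1 +
                                                cfg$beta2[2] * xi + dd),
                          0, cfg$sigma_b2)
    }, numeric(1))
  }
  w <- function(x) expit_(mc$psi[2] + mc$phi[2] * x)
  num <- crtmiss:::gh_expect(function(x) pi1(x) * w(x), 0, s2x)
  den <- crtmiss:::gh_expect(w, 0, s2x)
  truth <- num / den
  mc_se <- sd(props) / sqrt(length(props)) +
    sqrt(truth * (1 - truth) / sum(miss1))
  expect_lt(abs(mean(props) - truth), 3 * mc_se + 0.02)
})
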