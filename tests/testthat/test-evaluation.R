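test_that("replications are deterministic and respect the handling set", {
  cfg <- sim_config("S1", k_grid = 5L, m = 20L, n_reps = 2L,
                    methods = c("cl_u_rd", "gee"), handling = "full",
                    seed = 77L)
  r1 <- run_replication(cfg, k = 5L, rep_index = 1L)
  r2 <- run_replication(cfg, k = 5L, rep_index = 1L)
  expect_identical(r1, r2)
  expect_setequal(r1$handling, "full")
  expect_setequal(r1$method_id, c("cl_u_rd", "gee"))
  r3 <- run_replication(cfg, k = 5L, rep_index = 2L)
  expect_false(identical(r1$estimate, r3$estimate))
})

test_that("per-method failures are recorded, not raised", {
  # k = 2 with heavy missingness makes cluster-dropping failures likely;
  # use an extreme mechanism so one arm often loses a whole cluster
  cfg <- sim_config(
    "custom",
    dgm = dgm_config(beta1 = 1, beta2 = c(1, 1), sigma_b2 = 0.2,
                     sigma_u2 = 1, k = 2, m = 3),
    missingness = missingness_config(psi = 2, phi = 1),
    k_grid = 2L, m = 3L, n_reps = 2L,
    methods = "cl_u_rd", handling = "cra", seed = 5L)
  out <- purrr::map_dfr(1:8, function(r) run_replication(cfg, 2L, r))
  expect_true(any(!is.na(out$error)))
  expect_true(all(is.na(out$estimate) == !is.na(out$error)))
})

test_that("run_study aggregates coverage against quadrature truth", {
  cfg <- sim_config("S1", k_grid = 10L, m = 30L, n_reps = 30L,
                    methods = c("cl_u_rd", "cl_u_rr"), handling = "full",
                    seed = 11L)
  res <- run_study(cfg)
  expect_s3_class(res, "crt_sim_results")
  expect_equal(nrow(res), 2L)
  rd <- res[res$method_id == "cl_u_rd", ]
  sc <- scenario_preset("S1")
  truth <- marginal_success_probability(sc$dgm, 1) -
    marginal_success_probability(sc$dgm, 0)
  expect_equal(rd$true_value, truth)
  # full-data unadjusted RD is unbiased: mean within 4 MC errors
  expect_lt(abs(rd$mean_estimate - truth), 4 * rd$mc_error_estimate)
  expect_true(all(res$coverage_pct >= 0 & res$coverage_pct <= 100))
  expect_true(all(res$n_failed == 0))
})

test_that("condition oracle: no missingness means E[g] = 0 in both arms", {
  sc <- scenario_preset("S1")
  none <- missingness_config(psi = -50, phi = 0)
  rep <- check_condition(sc$dgm, none, "rd", n_mc = 2e5, seed = 1)
  expect_lt(abs(rep$lhs), 3 * rep$mc_se)
  expect_lt(abs(rep$rhs), 3 * rep$mc_se)
  expect_true(rep$satisfied)
})

test_that("condition oracle flags the logit-link RD violation under S1", {
  sc <- scenario_preset("S1")
  rep <- check_condition(sc$dgm, sc$missingness, "rd", n_mc = 2e5, seed = 2)
  expect_false(rep$satisfied)
  expect_gt(abs(rep$value), 3 * rep$mc_se)
  # under the null (beta1 = 0) with matched arms the condition holds
  null_dgm <- dgm_config(0, 0, c(1, 1), 0.20, 0, 0.18, 3.37, "logit",
                         k = 10, m = 50)
  rep0 <- check_condition(null_dgm, sc$missingness, "rd", n_mc = 2e5,
                          seed = 3)
  expect_true(rep0$satisfied)
})

test_that("condition oracle: log link with matched arms satisfies the RR
           condition", {
  log_dgm <- dgm_config(beta0 = -3, beta1 = 0.4, beta2 = c(0.15, 0.15),
                        sigma_b2 = 0.04, mu_x = 0, sigma_alpha2 = 0.3,
                        sigma_u2 = 1.2, link = "log", k = 10, m = 50)
  mcfg <- missingness_config(psi = -1, phi = 0.8)
  rep <- check_condition(log_dgm, mcfg, "rr", n_mc = 4e5, seed = 4)
  expect_true(rep$satisfied)
  expect_lt(abs(rep$value - 1), 0.02)
})

test_that("condition oracle agrees with a brute-force discretised grid", {
  cfg <- dgm_config(beta0 = 0.1, beta1 = 0.7, beta2 = c(0.5, 0.5),
                    sigma_b2 = 0.1, sigma_u2 = 1, k = 5, m = 10)
  mcfg <- missingness_config(psi = -0.5, phi = 0.6)
  rep <- check_condition(cfg, mcfg, "rd", n_mc = 4e5, seed = 5)
  # brute force: fine grid over (x, delta) with normal weights
  xs <- seq(-5, 5, length.out = 401)
  ds <- seq(-4 * sqrt(0.1), 4 * sqrt(0.1), length.out = 201)
  wx <- dnorm(xs, 0, 1); wx <- wx / sum(wx)
  wd <- dnorm(ds, 0, sqrt(0.1)); wd <- wd / sum(wd)
  cond_mean <- function(arm) {
    pi_i <- crtmiss:::gh_expect2(
      function(x, d) expit_(0.1 + 0.7 * arm + 0.5 * x + d), 0, 1, 0, 0.1)
    pobs <- 1 - expit_(-0.5 + 0.6 * xs)          # depends on x only
    g <- outer(xs, ds, function(x, d) expit_(0.1 + 0.7 * arm + 0.5 * x + d)) -
      pi_i
    num <- sum((wx * pobs) * drop(g %*% wd))
    den <- sum(wx * pobs)
    num / den
  }
  brute <- cond_mean(1) - cond_mean(0)
  expect_lt(abs(rep$value - brute), 3 * rep$mc_se)
})

test_that("results tables round-trip through report_table", {
  cfg <- sim_config("S1", k_grid = 5L, m = 10L, n_reps = 5L,
                    methods = "cl_u_rd", handling = "full", seed = 2L)
  res <- run_study(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  report_table(res, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(res))
  expect_equal(back$mean_estimate, res$mean_estimate)
  expect_true(file.exists(sub("\\.csv$", ".txt", path)))
  # empty table: header-only CSV
  report_table(res[0, ], path)
  expect_equal(nrow(readr::read_csv(path, show_col_types = FALSE)), 0L)
})
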