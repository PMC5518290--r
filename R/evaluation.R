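#' Simulation study configuration
#'
#' @param scenario `"S1"`..`"S4"` for the published parameter sets, or
#'   `"custom"` with `dgm` and `missingness` supplied.
#' @param k_grid Clusters per arm to study (the published grid is
#'   5, 10, 20, 50).
#' @param m Cluster size.
#' @param n_reps Replications per cell (1000 in the published study).
#' @param methods Subset of `"cl_u_rd"`, `"cl_a_rd"`, `"cl_u_rr"`,
#'   `"cl_a_rr"`, `"relr"`, `"gee"`.
#' @param handling Subset of `"full"`, `"cra"`, `"mmi"`.
#' @param seed Integer root seed; every replication derives its own
#'   sub-stream from it, so results do not depend on execution order.
#' @param mmi An [imputation_config()] (its seed field is ignored; per-rep
#'   seeds are derived from `seed`).
#' @param dgm,missingness Custom configs when `scenario = "custom"`.
#' @param interaction Include arm-by-covariate interactions in analysis and
#'   imputation models; defaults to whether the covariate effect differs
#'   between arms.
#' @param nagq Quadrature nodes for RELR.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(scenario = "S1", k_grid = c(5L, 10L, 20L, 50L),
                       m = 50L, n_reps = 1000L,
                       methods = c("cl_u_rd", "cl_a_rd", "cl_u_rr",
                                   "cl_a_rr", "relr", "gee"),
                       handling = c("full", "cra", "mmi"),
                       seed = 1L, mmi = imputation_config(),
                       dgm = NULL, missingness = NULL,
                       interaction = NULL, nagq = 15L) {
  methods <- match.arg(methods, several.ok = TRUE)
  handling <- match.arg(handling, several.ok = TRUE)
  stopifnot(n_reps >= 2, all(k_grid >= 2))
  if (scenario == "custom") {
    stopifnot(inherits(dgm, "dgm_config"),
              inherits(missingness, "missingness_config"))
  } else {
    preset <- scenario_preset(scenario, k = k_grid[1], m = m)
    dgm <- preset$dgm
    missingness <- preset$missingness
    if (is.null(interaction)) interaction <- preset$interaction
  }
  if (is.null(interaction)) interaction <- dgm$beta2[1] != dgm$beta2[2]
  structure(
    list(scenario = scenario, k_grid = as.integer(k_grid), m = as.integer(m),
         n_reps = as.integer(n_reps), methods = methods, handling = handling,
         seed = as.integer(seed), mmi = mmi, dgm = dgm,
         missingness = missingness, interaction = interaction,
         nagq = as.integer(nagq)),
    class = "sim_config")
}

pool_over_sets <- function(sets, method, effect, k, interaction, nagq) {
  res <- lapply(sets, function(d) {
    run_estimator(d, method, effect, use = "full",
                  interaction = interaction, nagq = nagq)
  })
  rubin_pool(vapply(res, function(e) e$estimate, numeric(1)),
             vapply(res, function(e) e$se^2, numeric(1)),
             nu_com = 2 * k - 2, scale = res[[1]]$scale)
}

method_parts <- function(m) {
  if (m %in% c("relr", "gee")) list(method = m, effect = "rd")
  else list(method = sub("_r[dr]$", "", m),
            effect = sub("^cl_[ua]_", "", m))
}

#' Run one simulation replication
#'
#' Simulates one full dataset, imposes the missingness mechanism, and runs
#' every requested method-by-handling combination. Per-method failures are
#' recorded, not raised. Deterministic given `(cfg$seed, k, rep_index)`:
#' seeds for the covariate/outcome stage, the missingness stage and the
#' imputation stage are derived sub-streams, so the same full dataset
#' underlies every handling.
#'
#' @param cfg A [sim_config()].
#' @param k Clusters per arm for this replication.
#' @param rep_index Replication index (1-based).
#' @return A tibble with one row per method x handling: estimate, se, df,
#'   CI, scale and an `error` column (`NA` on success).
#' @export
run_replication <- function(cfg, k, rep_index) {
  dgm <- dgm_config(cfg$dgm$beta0, cfg$dgm$beta1, cfg$dgm$beta2,
                    cfg$dgm$sigma_b2, cfg$dgm$mu_x, cfg$dgm$sigma_alpha2,
                    cfg$dgm$sigma_u2, cfg$dgm$link, k = k, m = cfg$m)
  full <- simulate_full_data(dgm, derive_seed(cfg$seed, 1L, k, rep_index))
  incomplete <- NULL
  if (any(c("cra", "mmi") %in% cfg$handling)) {
    incomplete <- impose_cdm_missingness(
      full, cfg$missingness, derive_seed(cfg$seed, 2L, k, rep_index))
  }
  # One imputation run per replicate, shared by every MMI method.
  mmi_sets <- NULL
  if ("mmi" %in% cfg$handling) {
    icfg <- cfg$mmi
    icfg$seed <- derive_seed(cfg$seed, 3L, k, rep_index)
    icfg$include_interaction <- cfg$interaction
    mmi_sets <- tryCatch(impute(incomplete, icfg), error = function(e) e)
  }
  cl_set <- c("cl_u_rd", "cl_a_rd", "cl_u_rr", "cl_a_rr")
  cl_meths <- intersect(cfg$methods, cl_set)
  ind_meths <- intersect(cfg$methods, c("relr", "gee"))
  err_row <- function(meth, h, e) {
    tibble::tibble(method = meth, handling = h, scale = NA_character_,
                   estimate = NA_real_, std.error = NA_real_,
                   df = NA_real_, conf.low = NA_real_, conf.high = NA_real_,
                   p.value = NA_real_, k0_used = NA_integer_,
                   k1_used = NA_integer_, error = conditionMessage(e))
  }
  pooled_row <- function(meth, h, p) {
    tibble::tibble(method = meth, handling = h, scale = p$scale,
                   estimate = p$estimate, std.error = p$se, df = p$nu_adj,
                   conf.low = p$ci_low, conf.high = p$ci_high,
                   p.value = p$p_value, k0_used = k, k1_used = k,
                   error = NA_character_)
  }
  rows <- list()
  add <- function(meth, h, row) {
    if (!"error" %in% names(row)) row$error <- NA_character_
    row$method_id <- meth
    row$handling <- h
    rows[[length(rows) + 1L]] <<- row
  }
  for (h in setdiff(cfg$handling, "mmi")) {
    dat <- if (h == "full") full else incomplete
    use <- if (h == "full") "full" else "complete_records"
    # cluster-level methods share the summaries and stage-1 fit
    if (length(cl_meths) > 0) {
      eff <- cl_effects(dat, use, cl_meths)
      for (meth in cl_meths) {
        if (inherits(eff[[meth]], "error")) {
          add(meth, h, err_row(meth, h, eff[[meth]]))
        } else {
          add(meth, h, tidy(eff[[meth]]))
        }
      }
    }
    for (meth in ind_meths) {
      row <- tryCatch(
        tidy(run_estimator(dat, meth, "rd", use = use,
                           interaction = cfg$interaction,
                           nagq = cfg$nagq)),
        error = function(e) err_row(meth, h, e))
      add(meth, h, row)
    }
  }
  if ("mmi" %in% cfg$handling) {
    if (inherits(mmi_sets, "error")) {
      for (meth in cfg$methods) add(meth, "mmi",
                                    err_row(meth, "mmi", mmi_sets))
    } else {
      # one pass over the imputed sets for all cluster-level methods
      if (length(cl_meths) > 0) {
        per_set <- lapply(mmi_sets, function(d) cl_effects(d, "full",
                                                           cl_meths))
        for (meth in cl_meths) {
          row <- tryCatch({
            bad <- vapply(per_set, function(ee) inherits(ee[[meth]], "error"),
                          logical(1))
            if (any(bad)) stop(per_set[[which(bad)[1]]][[meth]])
            est <- vapply(per_set, function(ee) ee[[meth]]$estimate,
                          numeric(1))
            v <- vapply(per_set, function(ee) ee[[meth]]$se^2, numeric(1))
            p <- rubin_pool(est, v, nu_com = 2 * k - 2,
                            scale = per_set[[1]][[meth]]$scale)
            pooled_row(meth, "mmi", p)
          }, error = function(e) err_row(meth, "mmi", e))
          add(meth, "mmi", row)
        }
      }
      for (meth in ind_meths) {
        row <- tryCatch({
          p <- pool_over_sets(mmi_sets, meth, "rd", k,
                              interaction = cfg$interaction,
                              nagq = cfg$nagq)
          pooled_row(meth, "mmi", p)
        }, error = function(e) err_row(meth, "mmi", e))
        add(meth, "mmi", row)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  # keep the configured method order for readability
  out$method_id <- factor(out$method_id, levels = cfg$methods)
  out <- out[order(out$method_id, out$handling), ]
  out$method_id <- as.character(out$method_id)
  out$k <- k
  out$rep <- rep_index
  out
}

true_values <- function(cfg, full_gee_mean = NULL) {
  pi0 <- marginal_success_probability(cfg$dgm, 0)
  pi1 <- marginal_success_probability(cfg$dgm, 1)
  function(method_id, scale) {
    if (method_id %in% c("cl_u_rd", "cl_a_rd")) return(pi1 - pi0)
    if (method_id %in% c("cl_u_rr", "cl_a_rr")) return(log(pi1 / pi0))
    if (method_id == "relr") return(cfg$dgm$beta1)
    if (method_id == "gee") {
      if (!is.null(full_gee_mean) && is.finite(full_gee_mean))
        return(full_gee_mean)
      return(empirical_marginal_logor(cfg$dgm, reps = 200L, k = 50L,
                                      m = cfg$m,
                                      seed = cfg$seed)$estimate)
    }
    NA_real_
  }
}

#' Run the full simulation study
#'
#' Aggregates [run_replication()] over the k grid and replications into a
#' results table: per (scenario, k, method, handling) the average estimate,
#' its Monte-Carlo error, the average estimated SE, its Monte-Carlo error,
#' coverage of the nominal CIs against the true value, and the number of
#' failed replications. True values: RD and log RR from quadrature;
#' conditional log OR = beta1; the marginal log OR (GEE) is the mean of
#' the study's own full-data GEE estimates when `"full"` is among the
#' handlings, otherwise [empirical_marginal_logor()].
#'
#' @param cfg A [sim_config()].
#' @param progress Print a line per (k, 100 reps) block.
#' @return A tibble of class `crt_sim_results`.
#' @export
run_study <- function(cfg, progress = FALSE) {
  reps <- list()
  for (k in cfg$k_grid) {
    for (r in seq_len(cfg$n_reps)) {
      reps[[length(reps) + 1L]] <- run_replication(cfg, k, r)
      if (progress && r %% 100 == 0) {
        message("k = ", k, ": ", r, "/", cfg$n_reps)
      }
    }
  }
  raw <- dplyr::bind_rows(reps)
  gee_full <- raw |>
    dplyr::filter(.data$method_id == "gee", .data$handling == "full",
                  is.na(.data$error))
  full_gee_mean <- if (nrow(gee_full) > 0) mean(gee_full$estimate) else NULL
  truth_of <- true_values(cfg, full_gee_mean)
  out <- raw |>
    dplyr::group_by(.data$k, .data$method_id, .data$handling) |>
    dplyr::summarise(
      scale = .data$scale[!is.na(.data$scale)][1],
      n_reps = dplyr::n(),
      n_failed = sum(!is.na(.data$error)),
      mean_estimate = mean(.data$estimate, na.rm = TRUE),
      mc_error_estimate = sd(.data$estimate, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$estimate))),
      mean_se = mean(.data$std.error, na.rm = TRUE),
      mc_error_se = sd(.data$std.error, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$std.error))),
      .groups = "drop")
  out$true_value <- vapply(seq_len(nrow(out)), function(i) {
    truth_of(out$method_id[i], out$scale[i])
  }, numeric(1))
  cov <- vapply(seq_len(nrow(out)), function(i) {
    sub <- raw[raw$k == out$k[i] & raw$method_id == out$method_id[i] &
                 raw$handling == out$handling[i] & is.na(raw$error), ]
    tv <- out$true_value[i]
    100 * mean(sub$conf.low <= tv & tv <= sub$conf.high)
  }, numeric(1))
  out$coverage_pct <- cov
  out$flagged <- out$n_failed > 0.10 * out$n_reps
  out$scenario <- cfg$scenario
  out <- dplyr::select(out, "scenario", "k", "method_id", "handling",
                       "scale", dplyr::everything())
  class(out) <- c("crt_sim_results", class(out))
  attr(out, "config") <- cfg
  out
}

#' Monte-Carlo check of the complete-records bias/consistency conditions
#'
#' Writes the individual success probability as
#' `pi_ijl = pi_i + g_i(X, delta)` (risk-difference form) or
#' `pi_ijl = pi_i * h_i(X, delta)` (risk-ratio form). The unadjusted
#' complete-records cluster-level RD is unbiased iff
#' `E[g_1 | R = 1] = E[g_0 | R = 1]`, and the RR version consistent iff
#' `E[h_1 | R = 1] / E[h_0 | R = 1] = 1`. This estimates both sides by
#' Monte Carlo over (X, delta, R), with pi_i from quadrature, and flags
#' whether the condition holds within 3 Monte-Carlo SEs.
#'
#' @param cfg A [dgm_config()].
#' @param mcfg A [missingness_config()].
#' @param kind `"rd"` (difference of conditional expectations) or `"rr"`
#'   (their ratio).
#' @param n_mc Monte-Carlo draws per arm.
#' @param seed Integer seed.
#' @return A list: `kind`, per-arm conditional expectations `lhs` (arm 1)
#'   and `rhs` (arm 0), `value` (difference or ratio), `mc_se`, `n_mc`,
#'   `satisfied`.
#' @export
check_condition <- function(cfg, mcfg, kind = c("rd", "rr"), n_mc = 1e5,
                            seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(inherits(cfg, "dgm_config"), inherits(mcfg, "missingness_config"))
  set.seed(seed)
  s2x <- cfg$sigma_alpha2 + cfg$sigma_u2
  est <- list()
  for (i in 0:1) {
    if (cfg$link == "logit") {
      pi_i <- marginal_success_probability(cfg, i)
    } else {
      pi_i <- gh_expect2(
        function(x, d) exp(cfg$beta0 + cfg$beta1 * i + cfg$beta2[i + 1] * x + d),
        cfg$mu_x, s2x, 0, cfg$sigma_b2)
    }
    if (pi_i <= 0) stop("undefined ratio form: pi_", i, " = 0")
    x <- rnorm(n_mc, cfg$mu_x, sqrt(s2x))
    if (cfg$link == "log") {
      sx <- sqrt(s2x)
      x <- pmin(pmax(x, cfg$mu_x - 4 * sx), cfg$mu_x + 4 * sx)
    }
    d <- rnorm(n_mc, 0, sqrt(cfg$sigma_b2))
    if (cfg$link == "log" && cfg$sigma_b2 > 0) {
      sb <- sqrt(cfg$sigma_b2)
      d <- pmin(pmax(d, -4 * sb), 4 * sb)
    }
    pij <- inv_link(cfg$beta0 + cfg$beta1 * i + cfg$beta2[i + 1] * x + d,
                    cfg$link)
    r_obs <- runif(n_mc) >= expit(mcfg$psi[i + 1] + mcfg$phi[i + 1] * x)
    vals <- if (kind == "rd") pij[r_obs] - pi_i else pij[r_obs] / pi_i
    est[[i + 1]] <- c(mean(vals), sd(vals) / sqrt(length(vals)))
  }
  e0 <- est[[1]]; e1 <- est[[2]]
  if (kind == "rd") {
    value <- e1[1] - e0[1]
    mc_se <- sqrt(e0[2]^2 + e1[2]^2)
    target <- 0
  } else {
    value <- e1[1] / e0[1]
    # delta method for the ratio
    mc_se <- abs(value) * sqrt((e1[2] / e1[1])^2 + (e0[2] / e0[1])^2)
    target <- 1
  }
  list(kind = paste0(kind, "_condition"), lhs = e1[1], rhs = e0[1],
       value = value, mc_se = mc_se, n_mc = n_mc,
       satisfied = abs(value - target) <= 3 * mc_se)
}

#' Write a results table to disk
#'
#' Writes the aggregated simulation results both as a plain CSV (lossless
#' round trip via [readr::read_csv()]) and as an aligned text table grouped
#' by scenario and k with full/CRA/MMI column blocks.
#'
#' @param results A `crt_sim_results` tibble.
#' @param path Output CSV path; the text rendering goes to
#'   `sub("\\\\.csv$", ".txt", path)`.
#' @return `path`, invisibly.
#' @export
report_table <- function(results, path) {
  readr::write_csv(as.data.frame(results), path)
  txt <- sub("\\.csv$", ".txt", path)
  if (nrow(results) > 0) {
    wide <- results |>
      dplyr::select("scenario", "k", "method_id", "handling",
                    "mean_estimate", "mean_se", "coverage_pct") |>
      tidyr::pivot_wider(
        names_from = "handling",
        values_from = c("mean_estimate", "mean_se", "coverage_pct"))
    utils::capture.output(print(as.data.frame(wide), row.names = FALSE),
                          file = txt)
  } else {
    utils::capture.output(print(as.data.frame(results)), file = txt)
  }
  invisible(path)
}
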