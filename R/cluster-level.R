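#' Per-cluster outcome summaries
#'
#' First stage of a cluster-level analysis: one row per cluster with the
#' number of contributing records, the observed number of successes and the
#' cluster proportion of success. With `use = "complete_records"` only
#' observed outcomes count and clusters without any observed outcome drop
#' out.
#'
#' @param data A trial tibble.
#' @param use `"full"` (requires a fully observed dataset) or
#'   `"complete_records"`.
#' @return A tibble with columns `arm`, `cluster`, `n_obs`, `successes`,
#'   `p`.
#' @export
cluster_summaries <- function(data, use = c("full", "complete_records")) {
  use <- match.arg(use)
  data <- validate_trial(data, balanced = FALSE)
  if (use == "full") {
    if (any(data$r == 0)) {
      stop("use = \"full\" but the dataset has missing outcomes")
    }
  } else {
    data <- complete_records(data)
  }
  cluster_agg(data)
}

# rowsum-based aggregation: called once per cluster-level estimate, and once
# per imputed dataset inside MMI pooling, so it is kept loop-free.
cluster_agg <- function(data, fitted = NULL) {
  id <- data$arm * (max(data$cluster) + 1) + data$cluster
  uid <- !duplicated(id)
  ord <- order(id[uid])
  n_obs <- unname(drop(rowsum(rep(1L, nrow(data)), id)))
  succ <- unname(drop(rowsum(data$y, id)))
  out <- tibble::tibble(
    arm = data$arm[uid][ord],
    cluster = data$cluster[uid][ord],
    n_obs = as.integer(n_obs),
    successes = as.integer(succ),
    p = succ / n_obs)
  if (!is.null(fitted)) out$predicted <- unname(drop(rowsum(fitted, id)))
  out
}

two_sample_t <- function(v0, v1, scale, method, handling) {
  k0 <- length(v0); k1 <- length(v1)
  if (k0 < 2 || k1 < 2) {
    stop("need at least 2 clusters per arm for the t-based analysis (got ",
         k0, " and ", k1, ")")
  }
  df <- k0 + k1 - 2
  sp2 <- ((k0 - 1) * var(v0) + (k1 - 1) * var(v1)) / df
  se <- sqrt(sp2 * (1 / k0 + 1 / k1))
  effect_estimate(scale, mean(v1) - mean(v0), se, df, c(k0, k1),
                  method = method, handling = handling)
}

#' Unadjusted cluster-level risk difference
#'
#' The risk difference is the difference of the unweighted means of the
#' cluster proportions; inference is a standard two-sample t test on the
#' cluster proportions with df `k0 + k1 - 2`.
#'
#' @param summaries Output of [cluster_summaries()].
#' @return A [effect_estimate()] on the RD scale.
#' @export
estimate_rd_unadjusted <- function(summaries) {
  two_sample_t(summaries$p[summaries$arm == 0],
               summaries$p[summaries$arm == 1],
               "RD", "cl_u", NA_character_)
}

ratio_scale_estimate <- function(v0, v1, method) {
  k0 <- length(v0); k1 <- length(v1)
  if (k0 < 2 || k1 < 2) stop("need at least 2 clusters per arm")
  m0 <- mean(v0); m1 <- mean(v1)
  if (m0 <= 0 || m1 <= 0) {
    stop("ratio undefined: a per-arm mean is non-positive")
  }
  # Delta-method variance of log(m1/m0) with per-arm realised cluster counts.
  se <- sqrt(var(v0) / (k0 * m0^2) + var(v1) / (k1 * m1^2))
  effect_estimate("logRR", log(m1 / m0), se, k0 + k1 - 2, c(k0, k1),
                  method = method)
}

#' Unadjusted cluster-level (log) risk ratio
#'
#' The risk ratio is the ratio of the unweighted means of the cluster
#' proportions; the variance of its log is
#' `s0^2/(k0 p0bar^2) + s1^2/(k1 p1bar^2)` with `s_i^2` the sample variance
#' of the cluster proportions, and inference uses t with df `k0 + k1 - 2`.
#'
#' @inheritParams estimate_rd_unadjusted
#' @return A [effect_estimate()] on the logRR scale.
#' @export
estimate_rr_unadjusted <- function(summaries) {
  ratio_scale_estimate(summaries$p[summaries$arm == 0],
                       summaries$p[summaries$arm == 1],
                       "cl_u")
}

#' Stage-1 covariate-only logistic regression
#'
#' Fits `logit P(Y = 1) = lambda1 + lambda2 * X` by maximum likelihood to
#' the pooled records of both arms, deliberately ignoring arm and
#' clustering; its predictions feed the covariate-adjusted cluster-level
#' residuals. A constant covariate degenerates to the intercept-only fit; a
#' constant outcome (complete separation) is an error.
#'
#' @param data A trial tibble.
#' @param use `"full"` or `"complete_records"`.
#' @return A list with `lambda1`, `lambda2` (`NA` when the covariate is
#'   constant) and `converged`.
#' @export
fit_stage1_logistic <- function(data, use = c("full", "complete_records")) {
  use <- match.arg(use)
  obs <- if (use == "full") validate_trial(data) else complete_records(data)
  if (use == "full" && any(obs$r == 0)) {
    stop("use = \"full\" but the dataset has missing outcomes")
  }
  y <- obs$y
  if (length(unique(y)) < 2) {
    stop("complete separation: pooled outcome is constant")
  }
  if (var(obs$x) == 0) {
    return(list(lambda1 = qlogis(mean(y)), lambda2 = NA_real_,
                converged = TRUE))
  }
  fit <- glm.fit(cbind(1, obs$x), y, family = binomial(),
                 control = list(epsilon = 1e-10, maxit = 100))
  if (!fit$converged || max(abs(coef(fit))) > 30) {
    stop("stage-1 logistic regression did not converge (separation?)")
  }
  list(lambda1 = unname(coef(fit)[1]), lambda2 = unname(coef(fit)[2]),
       converged = TRUE)
}

#' Predicted successes per cluster from the stage-1 model
#'
#' Adds to the cluster summaries the predicted number of successes
#' `Nhat_ij`, the sum of fitted probabilities `expit(lambda1 + lambda2 X)`
#' over exactly the records that contribute to the observed count.
#'
#' @param data A trial tibble.
#' @param model Output of [fit_stage1_logistic()].
#' @param use `"full"` or `"complete_records"`.
#' @return [cluster_summaries()] output with an extra `predicted` column.
#' @export
predicted_successes <- function(data, model,
                                use = c("full", "complete_records")) {
  use <- match.arg(use)
  obs <- if (use == "full") validate_trial(data) else complete_records(data)
  l2 <- if (is.na(model$lambda2)) 0 else model$lambda2
  cluster_agg(obs, fitted = expit(model$lambda1 + l2 * obs$x))
}

#' Covariate-adjusted cluster-level risk difference
#'
#' Two-stage adjusted analysis: the difference residual of each cluster is
#' `(N_ij - Nhat_ij) / m` under full data and
#' `(N_ij - Nhat_ij) / n_obs_ij` under complete records, and the adjusted RD
#' is the difference of per-arm mean residuals, with two-sample t inference
#' on the residuals. Under full data the adjusted estimate satisfies the
#' algebraic identity
#' `RD_adj = RD_unadj + (1/(m k)) * sum_j (Nhat_0j - Nhat_1j)`.
#'
#' @param data A trial tibble.
#' @param use `"full"` or `"complete_records"`.
#' @return A [effect_estimate()] on the RD scale.
#' @export
estimate_rd_adjusted <- function(data, use = c("full", "complete_records")) {
  use <- match.arg(use)
  model <- fit_stage1_logistic(data, use)
  rd_adjusted_from(predicted_successes(data, model, use))
}

rd_adjusted_from <- function(s) {
  resid <- (s$successes - s$predicted) / s$n_obs
  two_sample_t(resid[s$arm == 0], resid[s$arm == 1],
               "RD", "cl_a", NA_character_)
}

rr_adjusted_from <- function(s) {
  if (any(s$predicted <= 0)) {
    stop("ratio residual undefined: a cluster has predicted successes <= 0")
  }
  resid <- s$successes / s$predicted
  ratio_scale_estimate(resid[s$arm == 0], resid[s$arm == 1], "cl_a")
}

# All requested cluster-level effects of one dataset, sharing the cluster
# summaries and the stage-1 fit; used by the simulation harness. Each entry
# is either a crt_effect or the condition object of its failure, so one
# method's failure never discards another's result.
cl_effects <- function(data, use, methods) {
  out <- list()
  grab <- function(expr) tryCatch(expr, error = function(e) e)
  u_meths <- intersect(methods, c("cl_u_rd", "cl_u_rr"))
  if (length(u_meths) > 0) {
    s <- grab(cluster_summaries(data, use))
    for (meth in u_meths) {
      out[[meth]] <- if (inherits(s, "error")) s
      else if (meth == "cl_u_rd") grab(estimate_rd_unadjusted(s))
      else grab(estimate_rr_unadjusted(s))
    }
  }
  a_meths <- intersect(methods, c("cl_a_rd", "cl_a_rr"))
  if (length(a_meths) > 0) {
    sp <- grab(predicted_successes(data, fit_stage1_logistic(data, use),
                                   use))
    for (meth in a_meths) {
      out[[meth]] <- if (inherits(sp, "error")) sp
      else if (meth == "cl_a_rd") grab(rd_adjusted_from(sp))
      else grab(rr_adjusted_from(sp))
    }
  }
  out
}

#' Covariate-adjusted cluster-level (log) risk ratio
#'
#' The ratio residual of each cluster is `N_ij / Nhat_ij`; the adjusted RR
#' is the ratio of per-arm mean residuals, with delta-method variance
#' `s_e0^2/(k0 e0bar^2) + s_e1^2/(k1 e1bar^2)` for the log and t inference
#' with df `k0 + k1 - 2`.
#'
#' @inheritParams estimate_rd_adjusted
#' @return A [effect_estimate()] on the logRR scale.
#' @export
estimate_rr_adjusted <- function(data, use = c("full", "complete_records")) {
  use <- match.arg(use)
  model <- fit_stage1_logistic(data, use)
  rr_adjusted_from(predicted_successes(data, model, use))
}
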