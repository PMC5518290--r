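#' Construct an effect estimate
#'
#' Container for a single analysis result: the point estimate on its scale
#' (risk difference, log risk ratio, or conditional/marginal log odds
#' ratio), its standard error, t degrees of freedom, confidence interval and
#' p-value, and the per-arm number of clusters that contributed.
#'
#' @param scale One of `"RD"`, `"logRR"`, `"logOR_conditional"`,
#'   `"logOR_marginal"`.
#' @param estimate,se Point estimate and standard error (se >= 0).
#' @param df Degrees of freedom of the reference t distribution (> 0).
#' @param n_clusters_used Length-2 integer vector, clusters per arm.
#' @param level Confidence level (default 0.95).
#' @param method,handling Optional labels carried through to [tidy()].
#' @return An object of class `crt_effect`.
#' @export
effect_estimate <- function(scale, estimate, se, df, n_clusters_used,
                            level = 0.95, method = NA_character_,
                            handling = NA_character_) {
  scale <- match.arg(scale, c("RD", "logRR", "logOR_conditional",
                              "logOR_marginal"))
  stopifnot(se >= 0, df > 0)
  ci <- t_interval(estimate, se, df, level)
  p <- if (se > 0) 2 * pt(-abs(estimate / se), df) else as.numeric(estimate == 0)
  structure(
    list(scale = scale, estimate = estimate, se = se, df = df,
         ci_low = ci[1], ci_high = ci[2], p_value = p,
         n_clusters_used = as.integer(n_clusters_used),
         level = level, method = method, handling = handling),
    class = "crt_effect")
}

#' @method print crt_effect
#' @export
print.crt_effect <- function(x, ...) {
  cat("<crt_effect> ", x$scale,
      if (!is.na(x$method)) paste0(" [", x$method, "]"), "\n", sep = "")
  cat(sprintf("  estimate %.4f  se %.4f  df %.1f\n", x$estimate, x$se, x$df))
  cat(sprintf("  %d%% CI (%.4f, %.4f)  p = %.4g\n",
              round(100 * x$level), x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an effect estimate into a one-row tibble
#'
#' @param x A `crt_effect`.
#' @param ... Unused.
#' @method tidy crt_effect
#' @export
tidy.crt_effect <- function(x, ...) {
  tibble::tibble(
    method = x$method, handling = x$handling, scale = x$scale,
    estimate = x$estimate, std.error = x$se, df = x$df,
    conf.low = x$ci_low, conf.high = x$ci_high, p.value = x$p_value,
    k0_used = x$n_clusters_used[1], k1_used = x$n_clusters_used[2])
}

#' @method glance crt_effect
#' @export
glance.crt_effect <- function(x, ...) tidy(x, ...)
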