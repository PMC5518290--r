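# Small builders and independent oracles shared across test files.

# A tiny balanced dataset built by hand.
toy_trial <- function() {
  tibble::tibble(
    arm = rep(c(0L, 1L), each = 4L),
    cluster = rep(c(1L, 2L, 1L, 2L), each = 2L),
    individual = rep(1:2, 4L),
    x = c(-1.2, 0.5, 0.3, 1.1, -0.4, 0.8, 1.5, -0.9),
    y = c(0L, 1L, 1L, 1L, 0L, 1L, 1L, 0L)
  )
}

# A dataset whose cluster proportions are exactly the given vectors, one
# individual per proportion denominator of 10.
trial_from_props <- function(p0, p1, n = 10L) {
  build_arm <- function(props, arm) {
    purrr::imap_dfr(props, function(p, j) {
      ones <- round(p * n)
      tibble::tibble(arm = arm, cluster = as.integer(j),
                     individual = seq_len(n), x = 0,
                     y = c(rep(1L, ones), rep(0L, n - ones)))
    })
  }
  dplyr::bind_rows(build_arm(p0, 0L), build_arm(p1, 1L))
}

# Independent IRLS (Newton-Raphson) oracle for the covariate-only logistic
# regression, written without glm().
irls_logistic <- function(x, y, tol = 1e-12, maxit = 100) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    score <- crossprod(X, y - mu)
    info <- crossprod(X * w, X)
    step <- solve(info, score)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  unname(beta)
}

expit_ <- function(t) 1 / (1 + exp(-t))
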