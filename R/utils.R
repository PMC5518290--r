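#' @importFrom stats plogis qlogis rnorm rbinom runif qnorm pnorm qt pt
#' @importFrom stats glm binomial coef vcov fitted var sd uniroot aggregate
#' @importFrom rlang .data
NULL

expit <- function(t) plogis(t)

# Deterministic sub-stream seeds: a small LCG-style fold of the root seed and
# stage indices, kept inside the 32-bit signed range required by set.seed().
derive_seed <- function(root, ...) {
  idx <- c(...)
  s <- as.double(root) %% 2147483629
  for (v in idx) s <- (s * 69069 + as.double(v) + 1) %% 2147483629
  as.integer(s + 1)
}

# Gauss-Hermite rule cached per node count; transformed so that
# gh_expect(f, mu, s2) = E[f(Z)] with Z ~ N(mu, s2).
gh_cache <- new.env(parent = emptyenv())

gh_rule <- function(n = 64) {
  key <- as.character(n)
  if (is.null(gh_cache[[key]])) gh_cache[[key]] <- pracma::gaussHermite(n)
  gh_cache[[key]]
}

gh_expect <- function(f, mu, s2, n = 64) {
  if (s2 <= 0) return(f(mu))
  r <- gh_rule(n)
  sum(r$w / sqrt(pi) * f(mu + sqrt(2 * s2) * r$x))
}

# Two-dimensional tensor rule for independent normals.
gh_expect2 <- function(f, mu1, s21, mu2, s22, n = 64) {
  if (s21 <= 0) return(gh_expect(function(z) f(mu1, z), mu2, s22, n))
  if (s22 <= 0) return(gh_expect(function(z) f(z, mu2), mu1, s21, n))
  r <- gh_rule(n)
  z1 <- mu1 + sqrt(2 * s21) * r$x
  z2 <- mu2 + sqrt(2 * s22) * r$x
  w <- r$w / sqrt(pi)
  fv <- outer(z1, z2, f)
  as.numeric(w %*% fv %*% w)
}

t_interval <- function(estimate, se, df, level = 0.95) {
  tc <- qt(1 - (1 - level) / 2, df)
  c(estimate - tc * se, estimate + tc * se)
}
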