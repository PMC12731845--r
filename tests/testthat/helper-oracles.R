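# Independent oracles used across the test files.  Everything here is
# deliberately brute-force / quadrature-based and shares no code with the
# package internals it checks.

# Example pair of distributions on (0,1) with crossing Lorenz curves:
# F(x) = 2x - x^2 (decreasing density) and G(x) = x^2 (increasing density).
model_F_2xmx2 <- function() {
  dist_model("F = 2x - x^2", quantile = function(u) 1 - sqrt(1 - u),
             cdf = function(x) 2 * x - x^2,
             sampler = function(n) 1 - sqrt(1 - stats::runif(n)))
}
model_G_x2 <- function() {
  dist_model("G = x^2", quantile = function(u) sqrt(u),
             cdf = function(x) x^2,
             sampler = function(n) sqrt(stats::runif(n)))
}

# x-space quadrature of the defining integrals (no quantile functions):
# CRE = -int S log S dx, CE = -int F log F dx over the support.
xspace_cre <- function(cdf, upper) {
  stats::integrate(function(x) {
    s <- 1 - cdf(x)
    ifelse(s <= 0 | s >= 1, 0, -s * log(s))
  }, 0, upper, rel.tol = 1e-10)$value
}
xspace_ce <- function(cdf, upper) {
  stats::integrate(function(x) {
    f <- cdf(x)
    ifelse(f <= 0 | f >= 1, 0, -f * log(f))
  }, 0, upper, rel.tol = 1e-10)$value
}

# Brute-force Gini mean difference: mean over all ordered pairs.
gmd_brute <- function(v) {
  n <- length(v)
  sum(abs(outer(v, v, "-"))) / (n * (n - 1))
}

# Brute-force O(n^2) double-sum spacings variance (direct transcription of
# the estimator definition, independent of the O(n) contraction in the
# package).
spacings_variance_brute <- function(sorted, score) {
  n <- length(sorted)
  idx <- seq_len(n - 1)
  p <- idx / n
  d <- diff(sorted)
  total <- 0
  for (i in idx) {
    for (j in idx) {
      total <- total +
        (min(p[i], p[j]) - p[i] * p[j]) * score(p[i]) * score(p[j]) *
        d[i] * d[j]
    }
  }
  total
}

# 2-D Gauss-Legendre quadrature of the asymptotic variance
#   sigma^2 = int int [F(min(x,y)) - F(x)F(y)] J(F(x)) J(F(y)) dx dy
# after substituting u = F(x): the Jacobian is 1/f(F^-1(u)).  `dens_q(u)`
# is f(F^-1(u)).
variance_oracle_2d <- function(score, dens_q, nodes = 600) {
  gl <- pracma::gaussLegendre(nodes, 0, 1)
  u <- gl$x
  a <- score(u) / dens_q(u) * gl$w
  K <- outer(u, u, pmin) - outer(u, u)
  drop(t(a) %*% K %*% a)
}

# scores re-declared locally so the oracle does not depend on package
# internals
oracle_J <- function(u) -log(1 - u) - 1
oracle_Jbar <- function(u) log(u) + 1
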