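# Competitor dispersion statistics for the power study.  Every two-sample
# statistic in the package (including D1/D2) is a signed L-statistic
#   T = sum_i wx_i X_{i:n} + sum_i wy_i Y_{i:m},
# so each is defined by a pair of weight vectors; the Monte-Carlo engine
# precomputes these once per (statistic, n, m).

# Aly's spacings statistic: delta_r(s) = (1/r^2) sum_{i=2}^r
# (i-1)(r-i+1)(s_i - s_{i-1}), re-expressed as coefficients on the order
# statistics themselves.
aly_coeffs <- function(r) {
  i <- seq_len(r)
  ((i - 1) * (r - i + 1) - i * (r - i)) / r^2
}

# Gini mean difference as an order-statistic L-statistic:
# GMD(s) = 2/(r(r-1)) * sum_i (2i - r - 1) s_{i:r}.
gmd_coeffs <- function(r) {
  i <- seq_len(r)
  2 * (2 * i - r - 1) / (r * (r - 1))
}

#' Belzunce dilation-test coefficients
#'
#' Piecewise coefficients \eqn{c_{i,r}(\alpha_1)} used by
#' [belzunce_delta()].  They are the subinterval averages
#' \eqn{c_{i,r} = r \int_{(i-1)/r}^{i/r} h_{\alpha_1}(u)\, du} of the kernel
#' \deqn{h_\alpha(u) = 1/2 - u^2/(2\alpha) \ (u < \alpha), \qquad
#'       h_\alpha(u) = (1-u)^2/2 \ (u \ge \alpha),}
#' which yields the closed forms
#' \eqn{(3r^2\alpha - 3i^2 + 3i - 1)/(6r^2\alpha)} for \eqn{i < k+1} and
#' \eqn{(3(r-i)^2 + 3(r-i) + 1)/(6r^2)} for \eqn{i > k+1}, with
#' \eqn{k/r \le \alpha < (k+1)/r}; the straddling cell \eqn{i = k+1} is the
#' exact integral across the kink.
#'
#' @param r sample size.
#' @param alpha1 kernel split point in (0, 1).
#' @return numeric vector of length `r`, decreasing in `i`.
#' @keywords internal
belzunce_coefficients <- function(r, alpha1) {
  stopifnot(r >= 2, alpha1 > 0, alpha1 < 1)
  k <- floor(r * alpha1)
  i <- seq_len(r)
  out <- numeric(r)
  lo <- i < k + 1
  hi <- i > k + 1
  out[lo] <- (3 * r^2 * alpha1 - 3 * i[lo]^2 + 3 * i[lo] - 1) / (6 * r^2 * alpha1)
  out[hi] <- (3 * (r - i[hi])^2 + 3 * (r - i[hi]) + 1) / (6 * r^2)
  if (k + 1 <= r) {
    a <- alpha1
    kl <- k / r
    kr <- (k + 1) / r
    left <- (a - kl) / 2 - (a^3 - kl^3) / (6 * a)
    right <- ((1 - a)^3 - (1 - kr)^3) / 6
    out[k + 1] <- r * (left + right)
  }
  out
}

# Weight-vector factory shared by the public statistic functions, the MC
# decision rules, and the power engine.
make_stat_weights <- function(name, n, m, alpha1 = 0.5, alpha2 = 2) {
  switch(name,
    D1 = list(wx = -cre_weights(n), wy = cre_weights(m)),
    D2 = list(wx = -ce_weights(n), wy = ce_weights(m)),
    tN = list(wx = -aly_coeffs(n), wy = aly_coeffs(m)),
    gini = list(wx = -gmd_coeffs(n), wy = gmd_coeffs(m)),
    zardasht = {
      stopifnot(alpha2 > 0, alpha2 != 1)
      list(wx = -score_Jalpha((1:n) / n, alpha2) / n,
           wy = score_Jalpha((1:m) / m, alpha2) / m)
    },
    belzunce = {
      cc <- (1 - alpha1)^2 / 6
      # sign as printed: X-term minus Y-term
      list(wx = (belzunce_coefficients(n, alpha1) - cc) / n,
           wy = -(belzunce_coefficients(m, alpha1) - cc) / m)
    },
    stopf("unknown statistic '%s'", name)
  )
}

eval_stat <- function(w, xs, ys) sum(w$wx * xs) + sum(w$wy * ys)

compute_statistic <- function(name, xs, ys, alpha1 = 0.5, alpha2 = 2) {
  eval_stat(make_stat_weights(name, length(xs), length(ys), alpha1, alpha2),
            xs, ys)
}

#' Gini mean difference
#'
#' \eqn{E|X_1 - X_2|} for i.i.d. copies, computed exactly from the order
#' statistics as \eqn{\frac{2}{r(r-1)} \sum_i (2i - r - 1)\, s_{i:r}}.
#'
#' @param x an [observed_sample()] or numeric vector.
#' @return nonnegative scalar.
#' @export
gini_mean_difference <- function(x) {
  x <- observed_sample(x)
  sum(gmd_coeffs(x$n) * x$sorted)
}

#' Competitor two-sample dispersion statistics
#'
#' The four statistics used alongside the entropy contrasts in the power
#' study:
#' \describe{
#'   \item{`aly_tN`}{difference of the spacings functionals
#'     \eqn{\delta_r(s) = r^{-2} \sum_{i=2}^{r} (i-1)(r-i+1)
#'     (s_{i:r} - s_{(i-1):r})}, second sample minus first.}
#'   \item{`gini_delta`}{difference of Gini mean differences,
#'     second sample minus first.}
#'   \item{`zardasht_T`}{difference of L-statistics with score
#'     \eqn{J_{\alpha_2}(u) = (1 - \alpha_2 (1-u)^{\alpha_2-1})/(1-\alpha_2)}
#'     (for \eqn{\alpha_2 = 2} this is \eqn{1 - 2u}), second minus first.}
#'   \item{`belzunce_delta`}{Lorenz-kernel statistic with piecewise
#'     coefficients [belzunce_coefficients()]; sign convention is
#'     first-sample term minus second-sample term.}
#' }
#' All four are location-shift invariant up to \eqn{O(1/r)} grid bias and
#' (except `belzunce_delta`'s centring constant) exactly scale-equivariant.
#'
#' @param x,y samples ([observed_sample()] or numeric vectors).
#' @param alpha1 Belzunce split parameter in (0, 1); default 0.5.
#' @param alpha2 Zardasht score parameter, positive and not 1; default 2.
#' @return scalar statistic value.
#' @name competitor_statistics
#' @examples
#' x <- rexp(30); y <- 2 * rexp(30)
#' aly_tN(x, y); gini_delta(x, y); zardasht_T(x, y)
NULL

#' @rdname competitor_statistics
#' @export
aly_tN <- function(x, y) {
  x <- observed_sample(x); y <- observed_sample(y)
  compute_statistic("tN", x$sorted, y$sorted)
}

#' @rdname competitor_statistics
#' @export
gini_delta <- function(x, y) {
  x <- observed_sample(x); y <- observed_sample(y)
  compute_statistic("gini", x$sorted, y$sorted)
}

#' @rdname competitor_statistics
#' @export
zardasht_T <- function(x, y, alpha2 = 2) {
  x <- observed_sample(x); y <- observed_sample(y)
  compute_statistic("zardasht", x$sorted, y$sorted, alpha2 = alpha2)
}

#' @rdname competitor_statistics
#' @export
belzunce_delta <- function(x, y, alpha1 = 0.5) {
  x <- observed_sample(x); y <- observed_sample(y)
  compute_statistic("belzunce", x$sorted, y$sorted, alpha1 = alpha1)
}

#' Monte-Carlo decision rule for a competitor statistic
#'
#' Thin wrapper around [mc_test()] restricted to the competitor
#' statistics, so all six statistics share one decision interface in the
#' power study.
#'
#' @inheritParams mc_test
#' @return a `dil_test_result`.
#' @export
competitor_test <- function(x, y, table) {
  if (!table$statistic_name %in% c("tN", "gini", "zardasht", "belzunce")) {
    stopf("'%s' is not a competitor statistic", table$statistic_name)
  }
  mc_test(x, y, table)
}
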