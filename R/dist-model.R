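#' Distribution model objects
#'
#' A `dist_model` wraps the pieces of a univariate distribution the package
#' needs on the population side: a quantile function (mandatory — all
#' entropy and Lorenz quantities are quantile integrals), optionally a cdf,
#' a sampler, and the mean.  The mean is computed by quadrature of the
#' quantile function when not supplied.
#'
#' @param name character label.
#' @param quantile vectorised quantile function on (0, 1).
#' @param cdf optional vectorised cdf, consistent with `quantile`.
#' @param sampler optional function of `n` returning `n` i.i.d. draws.
#' @param mean optional known mean; computed as \eqn{\int_0^1 F^{-1}(u)\,du}
#'   when missing.
#' @param params named list of parameters (metadata).
#' @param support_lo lower support endpoint (`-Inf` allowed).
#'
#' @return an object of class `dist_model`.
#' @examples
#' m <- dist_exponential(mean = 2)
#' population_cre(m) # equals the mean for an exponential
#' @export
dist_model <- function(name, quantile, cdf = NULL, sampler = NULL,
                       mean = NULL, params = list(), support_lo = 0) {
  stopifnot(is.function(quantile))
  ugrid <- seq(0.005, 0.995, length.out = 200)
  qs <- quantile(ugrid)
  if (any(!is.finite(qs))) {
    stopf("quantile function returned non-finite values on (0,1)")
  }
  if (any(diff(qs) < -1e-10 * (1 + max(abs(qs))))) {
    stopf("quantile function is not nondecreasing")
  }
  if (!is.null(cdf)) {
    err <- max(abs(cdf(qs) - ugrid))
    if (err > 1e-6) {
      stopf("cdf and quantile are inconsistent (max |F(F^-1(u)) - u| = %.3g)", err)
    }
  }
  if (is.null(mean)) {
    mean <- quad01(quantile)
  }
  if (!is.finite(mean)) {
    stopf("model '%s' has non-finite mean", name)
  }
  structure(
    list(name = name, params = params, quantile = quantile, cdf = cdf,
         sampler = sampler, mean = mean, support_lo = support_lo),
    class = "dist_model"
  )
}

#' @export
print.dist_model <- function(x, ...) {
  ps <- if (length(x$params)) {
    paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  } else "none"
  cat(sprintf("<dist_model> %s  (params: %s; mean = %.6g)\n", x$name, ps, x$mean))
  invisible(x)
}

# Adaptive quadrature of g over (0,1) with explicit splitting near both
# endpoints: the integrands used here (quantile times log scores) have
# integrable logarithmic/power singularities at u = 0 and u = 1.
quad01 <- function(g, tol = 1e-9) {
  cuts <- c(0, 1e-12, 1e-6, 1e-3, 0.5, 1 - 1e-3, 1 - 1e-6, 1 - 1e-12, 1)
  total <- 0
  for (k in seq_len(length(cuts) - 1)) {
    piece <- stats::integrate(g, cuts[k], cuts[k + 1],
                              rel.tol = tol, abs.tol = tol,
                              stop.on.error = FALSE)
    if (piece$message == "the integral is probably divergent") {
      stopf("integral appears divergent near u = %g", cuts[k + 1])
    }
    if (piece$message != "OK") {
      stopf("quadrature failed on (%g, %g): %s", cuts[k], cuts[k + 1], piece$message)
    }
    total <- total + piece$value
  }
  total
}

## ---- family constructors -------------------------------------------------

#' Built-in distribution models
#'
#' Constructors for the parametric families used throughout: exponential
#' (scale = mean), Lomax (Pareto type II, with density
#' \eqn{\beta \gamma^\beta / (x+\gamma)^{\beta+1}}), gamma and Weibull in
#' shape/scale form, an equal-weight two-component Weibull mixture,
#' uniform, and a degenerate point mass.
#'
#' @param mean,rate exponential mean or rate (give one).
#' @param scale,shape positive scale/shape parameters.
#' @param shape1,shape2 Weibull shapes of the two mixture components
#'   (both with scale 1).
#' @param min,max uniform endpoints.
#' @param value location of the point mass.
#' @return a [dist_model()].
#' @name dist_families
NULL

#' @rdname dist_families
#' @export
dist_exponential <- function(mean = 1, rate = NULL) {
  if (!is.null(rate)) mean <- 1 / rate
  stopifnot(mean > 0)
  dist_model(
    name = sprintf("exponential(mean=%g)", mean),
    quantile = function(u) stats::qexp(u, rate = 1 / mean),
    cdf = function(x) stats::pexp(x, rate = 1 / mean),
    sampler = function(n) stats::rexp(n, rate = 1 / mean),
    mean = mean, params = list(mean = mean)
  )
}

#' @rdname dist_families
#' @export
dist_lomax <- function(scale = 10, shape = 3) {
  stopifnot(scale > 0, shape > 0)
  if (shape <= 1) {
    stopf("Lomax with shape <= 1 has no finite mean; CRE/CE are undefined")
  }
  dist_model(
    name = sprintf("lomax(scale=%g, shape=%g)", scale, shape),
    quantile = function(u) scale * ((1 - u)^(-1 / shape) - 1),
    cdf = function(x) 1 - (scale / (x + scale))^shape,
    sampler = function(n) scale * ((stats::runif(n))^(-1 / shape) - 1),
    mean = scale / (shape - 1), params = list(scale = scale, shape = shape)
  )
}

#' @rdname dist_families
#' @export
dist_gamma <- function(shape = 2, scale = 1) {
  stopifnot(shape > 0, scale > 0)
  dist_model(
    name = sprintf("gamma(shape=%g, scale=%g)", shape, scale),
    quantile = function(u) stats::qgamma(u, shape = shape, scale = scale),
    cdf = function(x) stats::pgamma(x, shape = shape, scale = scale),
    sampler = function(n) stats::rgamma(n, shape = shape, scale = scale),
    mean = shape * scale, params = list(shape = shape, scale = scale)
  )
}

#' @rdname dist_families
#' @export
dist_weibull <- function(shape = 2, scale = 1) {
  stopifnot(shape > 0, scale > 0)
  dist_model(
    name = sprintf("weibull(shape=%g, scale=%g)", shape, scale),
    quantile = function(u) stats::qweibull(u, shape = shape, scale = scale),
    cdf = function(x) stats::pweibull(x, shape = shape, scale = scale),
    sampler = function(n) stats::rweibull(n, shape = shape, scale = scale),
    mean = scale * gamma(1 + 1 / shape),
    params = list(shape = shape, scale = scale)
  )
}

#' @rdname dist_families
#' @export
dist_weibull_mixture <- function(shape1 = 2, shape2 = 2) {
  stopifnot(shape1 > 0, shape2 > 0)
  cdf <- function(x) {
    0.5 * (stats::pweibull(x, shape1, 1) + stats::pweibull(x, shape2, 1))
  }
  # numeric inversion of the mixture cdf; bracket from the component quantiles
  qf <- function(u) {
    vapply(u, function(ui) {
      if (ui <= 0) return(0)
      if (ui >= 1) return(Inf)
      hi <- max(stats::qweibull(ui, shape1, 1), stats::qweibull(ui, shape2, 1))
      stats::uniroot(function(x) cdf(x) - ui, lower = 0, upper = hi + 1e-9,
                     tol = 1e-12)$root
    }, numeric(1))
  }
  dist_model(
    name = sprintf("weibull_mixture(shapes=%g,%g)", shape1, shape2),
    quantile = qf, cdf = cdf,
    sampler = function(n) {
      pick <- stats::runif(n) < 0.5
      out <- numeric(n)
      out[pick] <- stats::rweibull(sum(pick), shape1, 1)
      out[!pick] <- stats::rweibull(sum(!pick), shape2, 1)
      out
    },
    mean = 0.5 * (gamma(1 + 1 / shape1) + gamma(1 + 1 / shape2)),
    params = list(shape1 = shape1, shape2 = shape2)
  )
}

#' @rdname dist_families
#' @export
dist_uniform <- function(min = 0, max = 1) {
  stopifnot(max > min)
  dist_model(
    name = sprintf("uniform(%g, %g)", min, max),
    quantile = function(u) min + u * (max - min),
    cdf = function(x) stats::punif(x, min, max),
    sampler = function(n) stats::runif(n, min, max),
    mean = (min + max) / 2, params = list(min = min, max = max),
    support_lo = min
  )
}

#' @rdname dist_families
#' @export
dist_degenerate <- function(value = 0) {
  dist_model(
    name = sprintf("degenerate(%g)", value),
    quantile = function(u) rep(value, length(u)),
    sampler = function(n) rep(value, n),
    mean = value, params = list(value = value), support_lo = value
  )
}
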