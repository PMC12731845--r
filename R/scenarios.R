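#' Simulation scenario catalogue
#'
#' The power study compares a fixed baseline group against a
#' `beta`-indexed alternative within five families.  `scenario_spec()`
#' builds the pair of models for a given family and `beta`:
#'
#' \describe{
#'   \item{exponential}{X ~ Exp(mean 1) vs Y ~ Exp(mean `beta`); null at
#'     `beta = 1`.  Power tables conventionally label the alternative by the
#'     rate `gamma = 1/beta` of the second group, so `gamma = 0.5`
#'     corresponds to `beta = 2` (second-sample mean 2).}
#'   \item{pareto}{X ~ Lomax(shape 10, scale 3) vs Y ~ Lomax(shape
#'     `10/beta`, scale 3); null at `beta = 1`.  Dividing the tail index
#'     by `beta` makes the second group strictly more dispersed, which is
#'     what drives the power sweep.}
#'   \item{gamma}{X ~ Gamma(shape 2, scale 1) vs Y ~ Gamma(shape `beta`,
#'     scale 1); null at `beta = 2`.}
#'   \item{weibull}{X ~ Weibull(shape 2, scale 1) vs Y ~ Weibull(shape
#'     `beta`, scale 1); null at `beta = 2`.}
#'   \item{mixture_weibull}{X ~ Weibull(2, 1) vs Z an equal-probability
#'     mixture of Weibull(2, 1) and Weibull(`beta`, 1); at the null
#'     `beta = 2` the mixture collapses to Weibull(2, 1).}
#' }
#'
#' @param family one of `"exponential"`, `"pareto"`, `"gamma"`,
#'   `"weibull"`, `"mixture_weibull"`.
#' @param beta alternative parameter (see above for the per-family null
#'   value).
#' @return an object of class `scenario_spec`: list with elements `family`,
#'   `beta`, `null_beta`, `model1`, `model2` (both [dist_model()]).
#' @examples
#' sp <- scenario_spec("exponential", beta = 2)
#' sp$model2$mean # 2
#' @export
scenario_spec <- function(family = c("exponential", "pareto", "gamma",
                                     "weibull", "mixture_weibull"),
                          beta) {
  family <- match.arg(family)
  stopifnot(is.numeric(beta), length(beta) == 1, is.finite(beta), beta > 0)
  built <- switch(family,
    exponential = list(
      null_beta = 1,
      model1 = dist_exponential(mean = 1),
      model2 = dist_exponential(mean = beta)
    ),
    pareto = list(
      null_beta = 1,
      model1 = dist_lomax(scale = 3, shape = 10),
      model2 = dist_lomax(scale = 3, shape = 10 / beta)
    ),
    gamma = list(
      null_beta = 2,
      model1 = dist_gamma(shape = 2, scale = 1),
      model2 = dist_gamma(shape = beta, scale = 1)
    ),
    weibull = list(
      null_beta = 2,
      model1 = dist_weibull(shape = 2, scale = 1),
      model2 = dist_weibull(shape = beta, scale = 1)
    ),
    mixture_weibull = list(
      null_beta = 2,
      model1 = dist_weibull(shape = 2, scale = 1),
      model2 = dist_weibull_mixture(shape1 = 2, shape2 = beta)
    )
  )
  structure(
    c(list(family = family, beta = beta), built),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %s, beta = %g (null beta = %g)\n  group 1: %s\n  group 2: %s\n",
              x$family, x$beta, x$null_beta, x$model1$name, x$model2$name))
  invisible(x)
}

#' Draw a sample from one group of a scenario
#'
#' @param spec a [scenario_spec()].
#' @param group 1 (fixed baseline) or 2 (`beta`-indexed alternative).
#' @param n sample size (at least 2).
#' @param seed optional integer seed; when given the caller's RNG state is
#'   left untouched.
#' @return an [observed_sample()] of `n` i.i.d. draws.
#' @examples
#' s <- sample_scenario(scenario_spec("weibull", 1), group = 2, n = 20, seed = 1)
#' @export
sample_scenario <- function(spec, group = 1, n, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"), group %in% c(1, 2), n >= 2)
  model <- if (group == 1) spec$model1 else spec$model2
  observed_sample(with_seed(seed, model$sampler(n)))
}
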