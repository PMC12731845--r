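# Monte-Carlo engine: null critical values, size/power tables, and
# QQ normality diagnostics for the null distributions of the statistics.

all_statistics <- c("tN", "belzunce", "gini", "zardasht", "D1", "D2")

# Simulate `reps` pairs of samples (sampler1 for X, sampler2 for Y) and
# evaluate every requested statistic on each pair.  Returns a reps x K
# matrix.  The statistics are all signed L-statistics, so the whole batch
# reduces to two matrix products against the sorted samples.
simulate_statistics <- function(sampler1, sampler2, n, m, statistics,
                                reps, alpha1 = 0.5, alpha2 = 2) {
  ws <- lapply(statistics, make_stat_weights, n = n, m = m,
               alpha1 = alpha1, alpha2 = alpha2)
  Wx <- vapply(ws, `[[`, numeric(n), "wx")
  Wy <- vapply(ws, `[[`, numeric(m), "wy")
  Xs <- matrix(sampler1(n * reps), nrow = n)
  Ys <- matrix(sampler2(m * reps), nrow = m)
  Xs <- apply(Xs, 2, sort)
  Ys <- apply(Ys, 2, sort)
  out <- t(crossprod(Xs, Wx) + crossprod(Ys, Wy))
  rownames(out) <- statistics
  t(out)
}

#' Empirical size/power table for the dilation-order tests
#'
#' Reproduces the standard two-stage Monte-Carlo protocol: for each sample
#' size, two-sided critical values for every statistic are estimated from
#' `crit_reps` pairs of samples drawn from the scenario's null
#' distribution (equal-tail `q/2` / `1 - q/2` quantiles); then, for each
#' `beta`, `power_reps` fresh pairs are drawn from the (baseline,
#' alternative) models and the rejection proportion of each statistic is
#' recorded.  One critical-value set per (statistic, n, family) is reused
#' across the `beta` sweep.  The run is deterministic given `seed`:
#' independent child seeds are derived per (family, n, stage, beta), and
#' all statistics are evaluated on identical sample pairs (paired
#' comparison across columns, as in joint power tables).
#'
#' @param family scenario family (see [scenario_spec()]).
#' @param beta_grid alternative parameter values (include the null
#'   `beta` to obtain empirical size rows).
#' @param n_list sample sizes (used with `n = m`).
#' @param statistics which statistics to tabulate; default all six.
#' @param q two-sided level.
#' @param crit_reps,power_reps Monte-Carlo replication counts for the
#'   critical-value and power stages.
#' @param seed integer master seed.
#' @param alpha1,alpha2 Belzunce/Zardasht score parameters.
#' @return a data.frame of class `power_table` with columns `family`,
#'   `n`, `beta`, then one rejection-proportion column per statistic;
#'   attributes `q`, `crit_reps`, `power_reps`, `seed`.
#' @examples
#' run_power_table("exponential", beta_grid = c(1, 2), n_list = 25,
#'                 crit_reps = 200, power_reps = 200, seed = 1)
#' @export
run_power_table <- function(family, beta_grid, n_list,
                            statistics = all_statistics, q = 0.05,
                            crit_reps = 5000, power_reps = 5000,
                            seed = 1, alpha1 = 0.5, alpha2 = 2) {
  statistics <- match.arg(statistics, all_statistics, several.ok = TRUE)
  stopifnot(length(beta_grid) >= 1, length(n_list) >= 1)
  if (crit_reps < 100 || power_reps < 100) {
    stopf("reps must be at least 100")
  }
  rows <- list()
  for (n in n_list) {
    null_spec <- scenario_spec(family, scenario_spec(family, 1)$null_beta)
    null_sampler <- null_spec$model1$sampler
    crit_vals <- with_seed(derive_seed(seed, family, n, "crit"), {
      simulate_statistics(null_sampler, null_sampler, n, n, statistics,
                          crit_reps, alpha1, alpha2)
    })
    lo <- apply(crit_vals, 2, stats::quantile, probs = q / 2, type = 7)
    hi <- apply(crit_vals, 2, stats::quantile, probs = 1 - q / 2, type = 7)
    for (beta in beta_grid) {
      spec <- scenario_spec(family, beta)
      vals <- with_seed(derive_seed(seed, family, n, "power", beta), {
        simulate_statistics(spec$model1$sampler, spec$model2$sampler,
                            n, n, statistics, power_reps, alpha1, alpha2)
      })
      rej <- colMeans(sweep(vals, 2, lo, "<") | sweep(vals, 2, hi, ">"))
      rows[[length(rows) + 1]] <-
        c(list(family = family, n = n, beta = beta), as.list(rej))
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  attr(out, "q") <- q
  attr(out, "crit_reps") <- crit_reps
  attr(out, "power_reps") <- power_reps
  attr(out, "seed") <- seed
  class(out) <- c("power_table", "data.frame")
  out
}

#' @export
print.power_table <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Empirical rejection proportions (q = %g, crit_reps = %d, power_reps = %d, seed = %s)\n",
    attr(x, "q"), attr(x, "crit_reps"), attr(x, "power_reps"),
    format(attr(x, "seed"))))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Normality diagnostic for a statistic's null distribution
#'
#' Simulates `reps` null replicates of the chosen statistic at sample
#' sizes `n = m`, standardises them by their empirical mean and standard
#' deviation, and pairs the sorted values with standard-normal quantiles
#' at \eqn{(i - 0.5)/reps}.  The QQ correlation approaches 1 as `n` grows,
#' reflecting the asymptotic normality of the estimators.
#'
#' @param statistic_name one of the six statistics.
#' @param family scenario family; null replicates are drawn from its
#'   baseline model.
#' @param n sample size per group.
#' @param reps number of null replicates (at least 500).
#' @param seed integer seed.
#' @param alpha1,alpha2 score parameters.
#' @return an object of class `qq_diag` with sorted standardised values,
#'   theoretical quantiles, and the QQ correlation; see
#'   [qq_correlation()].
#' @examples
#' d <- qq_diagnostic("D1", "exponential", n = 25, reps = 500, seed = 1)
#' qq_correlation(d)
#' @export
qq_diagnostic <- function(statistic_name, family, n, reps = 2000, seed = 1,
                          alpha1 = 0.5, alpha2 = 2) {
  statistic_name <- match.arg(statistic_name, all_statistics)
  if (reps < 500) stopf("reps must be at least 500")
  null_spec <- scenario_spec(family, scenario_spec(family, 1)$null_beta)
  sampler <- null_spec$model1$sampler
  vals <- with_seed(derive_seed(seed, family, n, "qq", statistic_name), {
    simulate_statistics(sampler, sampler, n, n, statistic_name, reps,
                        alpha1, alpha2)[, 1]
  })
  s <- stats::sd(vals)
  if (!is.finite(s) || s == 0) {
    stopf("degenerate null statistic distribution (zero spread)")
  }
  std <- sort((vals - mean(vals)) / s)
  theo <- stats::qnorm((seq_len(reps) - 0.5) / reps)
  structure(
    list(statistic = statistic_name, family = family, n = n, reps = reps,
         sample_quantiles = std, theoretical_quantiles = theo,
         correlation = stats::cor(std, theo)),
    class = "qq_diag"
  )
}

#' @rdname qq_diagnostic
#' @param d a `qq_diag` object.
#' @export
qq_correlation <- function(d) {
  stopifnot(inherits(d, "qq_diag"))
  d$correlation
}

#' @export
print.qq_diag <- function(x, ...) {
  cat(sprintf(
    "<qq_diag> %s under %s null, n = m = %d, %d replicates\n  QQ correlation with N(0,1): %.5f\n",
    x$statistic, x$family, x$n, x$reps, x$correlation))
  invisible(x)
}

#' @export
plot.qq_diag <- function(x, ...) {
  graphics::plot(x$theoretical_quantiles, x$sample_quantiles,
                 xlab = "theoretical N(0,1) quantiles",
                 ylab = "standardised null statistic",
                 main = sprintf("%s null QQ (n = m = %d)", x$statistic, x$n),
                 ...)
  graphics::abline(0, 1, col = "red")
  invisible(x)
}
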