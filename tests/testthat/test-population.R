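test_that("population CRE and CE match closed forms", {
  expect_equal(population_cre(dist_exponential(mean = 1)), 1, tolerance = 1e-6)
  expect_equal(population_cre(dist_exponential(mean = 3)), 3, tolerance = 1e-6)
  expect_equal(population_cre(dist_uniform()), 0.25, tolerance = 1e-6)
  expect_equal(population_ce(dist_exponential(mean = 1)), pi^2 / 6 - 1,
               tolerance = 1e-6)
  expect_equal(population_ce(dist_exponential(mean = 2)), 2 * (pi^2 / 6 - 1),
               tolerance = 1e-6)
  # degenerate distribution: both entropies vanish
  expect_equal(population_cre(dist_degenerate(3)), 0, tolerance = 1e-8)
  expect_equal(population_ce(dist_degenerate(3)), 0, tolerance = 1e-8)
})

test_that("worked-example pair on (0,1) gives the known CE values", {
  expect_equal(population_ce(model_F_2xmx2()), 0.187, tolerance = 0.0005)
  expect_equal(population_ce(model_G_x2()), 2 / 9, tolerance = 1e-6)
})

test_that("quantile-space entropies agree with x-space quadrature", {
  cases <- list(
    list(m = dist_exponential(mean = 1), up = 60),
    list(m = dist_gamma(shape = 2, scale = 1), up = 80),
    list(m = dist_weibull(shape = 2, scale = 1), up = 15),
    list(m = model_G_x2(), up = 1)
  )
  for (cs in cases) {
    expect_equal(population_cre(cs$m), xspace_cre(cs$m$cdf, cs$up),
                 tolerance = 1e-6, label = cs$m$name)
    expect_equal(population_ce(cs$m), xspace_ce(cs$m$cdf, cs$up),
                 tolerance = 1e-6, label = cs$m$name)
  }
})

test_that("entropies are shift-invariant and scale-equivariant", {
  base <- dist_gamma(shape = 2, scale = 1)
  shifted <- dist_model("shifted", function(u) base$quantile(u) + 5)
  scaled <- dist_model("scaled", function(u) 3 * base$quantile(u))
  expect_equal(population_cre(shifted), population_cre(base), tolerance = 1e-6)
  expect_equal(population_ce(shifted), population_ce(base), tolerance = 1e-6)
  expect_equal(population_cre(scaled), 3 * population_cre(base),
               tolerance = 1e-6)
  expect_equal(population_ce(scaled), 3 * population_ce(base),
               tolerance = 1e-6)
})

test_that("models with divergent mean are rejected", {
  expect_error(dist_lomax(scale = 1, shape = 1), "no finite mean")
  expect_error(dist_lomax(scale = 1, shape = 0.5), "no finite mean")
})

test_that("Lorenz curves satisfy their structural invariants", {
  grid <- seq(0, 1, length.out = 161)
  for (m in list(dist_exponential(1), dist_uniform(),
                 dist_weibull(2, 1), model_F_2xmx2())) {
    lc <- lorenz_lower(m, grid)
    expect_equal(lc$values[1], 0, tolerance = 1e-8)
    expect_equal(lc$values[length(grid)], 0, tolerance = 1e-7)
    expect_true(all(lc$values <= 1e-8))
    # discrete convexity on the uniform grid
    expect_true(all(diff(lc$values, differences = 2) >= -1e-8))
  }
})

test_that("Lorenz curves match closed forms where known", {
  grid <- seq(0, 0.999, length.out = 120)
  lc_exp <- lorenz_lower(dist_exponential(1), grid)
  expect_equal(lc_exp$values, (1 - grid) * log(1 - grid), tolerance = 1e-7)
  lc_unif <- lorenz_lower(dist_uniform(), grid)
  expect_equal(lc_unif$values, -grid * (1 - grid) / 2, tolerance = 1e-8)
})

test_that("dilation-order verdicts are correct on known pairs", {
  e2 <- dist_exponential(mean = 0.5)
  e1 <- dist_exponential(mean = 1)
  expect_identical(check_dilation_order(e2, e1), "x_dil_leq_y")
  expect_identical(check_dilation_order(e1, e2), "y_dil_leq_x")
  expect_identical(check_dilation_order(e1, dist_exponential(mean = 1)),
                   "equal")
  # crossing Lorenz curves: not comparable
  expect_identical(check_dilation_order(model_F_2xmx2(), model_G_x2()),
                   "not_ordered")
  expect_error(check_dilation_order(e1, e2, grid = seq(0, 1, length.out = 50)),
               "at least 100")
})

test_that("dilation order implies ordered CRE and CE over the catalogue", {
  pairs <- list(
    list(x = dist_exponential(0.5), y = dist_exponential(1)),
    list(x = dist_weibull(2, 1), y = dist_weibull(1, 1)),
    list(x = dist_gamma(2, 1), y = dist_gamma(3, 1)),
    list(x = dist_lomax(3, 10), y = dist_lomax(3, 5))
  )
  for (p in pairs) {
    verdict <- check_dilation_order(p$x, p$y)
    expect_identical(verdict, "x_dil_leq_y", label = p$y$name)
    expect_lte(population_cre(p$x), population_cre(p$y) + 1e-8)
    expect_lte(population_ce(p$x), population_ce(p$y) + 1e-8)
  }
})

test_that("scenario samplers draw from the advertised distributions", {
  for (fam in c("exponential", "pareto", "gamma", "weibull",
                "mixture_weibull")) {
    sp <- scenario_spec(fam, beta = sp_null <- scenario_spec(fam, 1)$null_beta)
    s <- sample_scenario(sp, group = 1, n = 1e5, seed = 42)
    expect_equal(mean(s$values), sp$model1$mean,
                 tolerance = 0.03 * (1 + sp$model1$mean), label = fam)
  }
  # at the null beta the mixture collapses to Weibull(2, 1)
  spm <- scenario_spec("mixture_weibull", beta = 2)
  z <- sample_scenario(spm, group = 2, n = 2e4, seed = 7)
  ks <- suppressWarnings(stats::ks.test(z$values, function(q)
    stats::pweibull(q, 2, 1)))
  expect_gt(ks$p.value, 0.01)
})

test_that("scenario sampling is reproducible and validates inputs", {
  sp <- scenario_spec("weibull", beta = 1.4)
  s1 <- sample_scenario(sp, 2, 50, seed = 9)
  s2 <- sample_scenario(sp, 2, 50, seed = 9)
  expect_identical(s1$values, s2$values)
  expect_error(scenario_spec("cauchyish", 1), "arg")
  expect_error(scenario_spec("gamma", -1))
})
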