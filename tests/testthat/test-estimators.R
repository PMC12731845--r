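test_that("observed_sample validates and caches order statistics", {
  s <- observed_sample(c(3, 1, 2, 2))
  expect_identical(s$sorted, c(1, 2, 2, 3))
  expect_identical(sort(s$values), s$sorted)
  expect_error(observed_sample(5), "at least 2")
  expect_error(observed_sample(c(1, NA)), "non-finite")
  expect_warning(observed_sample(c(-1, 2)), "negative")
})

test_that("empirical CRE and CE reproduce hand-computed values", {
  # n = 2 cases evaluate the L-statistic sums directly
  expect_equal(empirical_cre(c(0, 1)), (log(2) - 1) / 2, tolerance = 1e-12)
  expect_equal(empirical_ce(c(0, 1)), 0.5, tolerance = 1e-12)
  # order of input values is irrelevant
  expect_equal(empirical_cre(c(1, 0)), empirical_cre(c(0, 1)))
})

test_that("empirical entropies are exactly scale-equivariant", {
  set.seed(101)
  x <- rgamma(200, 2)
  for (a in c(0.5, 3, 17.2)) {
    expect_equal(empirical_cre(a * x), a * empirical_cre(x), tolerance = 1e-12)
    expect_equal(empirical_ce(a * x), a * empirical_ce(x), tolerance = 1e-12)
    expect_equal(variance_cre(a * x), a^2 * variance_cre(x), tolerance = 1e-9)
    expect_equal(variance_ce(a * x), a^2 * variance_ce(x), tolerance = 1e-9)
  }
})

test_that("shift changes the estimators by at most |b| * |mean score sum|", {
  set.seed(102)
  for (n in c(20, 100, 1000)) {
    x <- rexp(n)
    # Riemann-sum defect of the zero-integral scores on the i/n grids
    defect_J <- abs(mean(diltest:::score_J((0:(n - 1)) / n)))
    defect_Jbar <- abs(mean(diltest:::score_Jbar((1:n) / n)))
    for (b in c(-0.5, 2, 10)) {
      # b = -0.5 makes some values negative, which warns by design
      suppressWarnings({
        expect_lte(abs(empirical_cre(x + b) - empirical_cre(x)),
                   abs(b) * defect_J + 1e-10)
        expect_lte(abs(empirical_ce(x + b) - empirical_ce(x)),
                   abs(b) * defect_Jbar + 1e-10)
      })
    }
  }
  # the defect decays like log(n)/n
  ns <- c(50, 500, 5000)
  defects <- sapply(ns, function(n) abs(mean(diltest:::score_J((0:(n - 1)) / n))))
  expect_true(all(diff(defects) < 0))
  expect_lt(defects[3], 2 * log(5000) / 5000)
})

test_that("estimators are consistent for known populations", {
  set.seed(103)
  x <- rexp(1e5)
  expect_equal(empirical_cre(x), 1, tolerance = 0.02)
  expect_equal(empirical_ce(x), pi^2 / 6 - 1, tolerance = 0.02)
  # cdf x^2 on (0,1): CE = 2/9
  y <- sqrt(runif(1e5))
  expect_equal(empirical_ce(y), 2 / 9, tolerance = 0.01)
})

test_that("spacings variance estimators match the O(n^2) double sum", {
  set.seed(104)
  for (n in c(5, 17, 40)) {
    x <- sort(rweibull(n, 2))
    expect_equal(variance_cre(x),
                 spacings_variance_brute(x, diltest:::score_J),
                 tolerance = 1e-12)
    expect_equal(variance_ce(x),
                 spacings_variance_brute(x, diltest:::score_Jbar),
                 tolerance = 1e-12)
  }
})

test_that("variance estimators are nonnegative and vanish on constants", {
  set.seed(105)
  for (r in 1:20) {
    x <- switch(r %% 4 + 1, rexp(30), rlnorm(25), runif(40),
                round(rexp(30), 1)) # includes ties
    expect_gte(variance_cre(x), 0)
    expect_gte(variance_ce(x), 0)
  }
  expect_equal(variance_cre(rep(2.5, 20)), 0)
  expect_equal(variance_ce(rep(2.5, 20)), 0)
})

test_that("standardised null estimators are asymptotically normal", {
  set.seed(106)
  reps <- 2000
  n <- 100
  vals <- vapply(seq_len(reps), function(r) empirical_cre(rexp(n)), numeric(1))
  std <- sort((vals - mean(vals)) / sd(vals))
  theo <- qnorm((seq_len(reps) - 0.5) / reps)
  expect_gt(cor(std, theo), 0.99)
})
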