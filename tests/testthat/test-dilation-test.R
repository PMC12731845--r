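test_that("dilation statistics are antisymmetric and vanish on equal data", {
  set.seed(201)
  x <- rexp(40)
  expect_identical(unname(dilation_statistics(x, x)), c(0, 0))
  y <- rexp(60)
  fwd <- dilation_statistics(x, y)
  rev <- dilation_statistics(y, x)
  expect_equal(unname(fwd), -unname(rev), tolerance = 1e-12)
})

test_that("D1 estimates the CRE contrast between exponential groups", {
  set.seed(202)
  d <- dilation_statistics(rexp(1e5), rexp(1e5, rate = 0.5))
  expect_equal(unname(d["D1"]), 1, tolerance = 0.05) # CRE(Exp(mu)) = mu
})

test_that("asymptotic test behaves correctly at the boundary cases", {
  set.seed(203)
  x <- rexp(50)
  res <- asymptotic_test(x, x, "D1")
  expect_equal(res$z, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$reject)
  expect_error(asymptotic_test(rep(1, 20), rep(2, 20), "D2"),
               "degenerate")
  expect_error(asymptotic_test(x, x, "D1", q = 1.2))
})

test_that("asymptotic test is calibrated at the null and powerful apart", {
  set.seed(204)
  n <- 100
  null_rej <- mean(vapply(seq_len(600), function(r) {
    asymptotic_test(rexp(n), rexp(n), "D2")$reject
  }, logical(1)))
  expect_gt(null_rej, 0.02)
  expect_lt(null_rej, 0.09)
  alt_rej <- mean(vapply(seq_len(300), function(r) {
    asymptotic_test(rexp(n), rexp(n, 0.5), "D2")$reject
  }, logical(1)))
  expect_gt(alt_rej, 0.9)
})

test_that("MC critical values form a symmetric, calibrated, shrinking band", {
  tab100 <- mc_critical_values(function(n) rexp(n), 100, 100, "D1",
                               reps = 2000, seed = 5)
  expect_lte(tab100$lower, tab100$upper)
  # exchange symmetry of the null statistic when n = m
  expect_lt(abs(tab100$lower + tab100$upper), 0.08)
  # stored null replicates fall outside the band with frequency ~ q
  out_frac <- mean(tab100$values < tab100$lower | tab100$values > tab100$upper)
  expect_lt(abs(out_frac - 0.05), 0.01)
  # fresh null data rejected at ~ q (threshold-estimation noise shifts the
  # rate for all replicates jointly, hence the allowance beyond 3 SE)
  set.seed(6)
  rej <- mean(vapply(seq_len(1000), function(r) {
    mc_test(rexp(100), rexp(100), tab100)$reject
  }, logical(1)))
  expect_lt(abs(rej - 0.05), 0.025)
  # sqrt(n)-consistency: the band tightens with n
  tab25 <- mc_critical_values(function(n) rexp(n), 25, 25, "D1",
                              reps = 2000, seed = 5)
  expect_gt(tab100$lower, tab25$lower)
  expect_lt(tab100$upper, tab25$upper)
})

test_that("MC test enforces size matching and strict rejection boundary", {
  tab <- mc_critical_values(function(n) rexp(n), 30, 30, "D2",
                            reps = 200, seed = 8)
  expect_error(mc_test(rexp(31), rexp(30), tab), "do not match")
  set.seed(9)
  x <- rexp(30)
  expect_false(mc_test(x, x, tab)$reject)
  # a statistic exactly at a threshold is not rejected
  fake <- tab
  fake$lower <- -1
  fake$upper <- unname(dilation_statistics(x, x * 0 + x)["D2"]) # = 0
  expect_false(mc_test(x, x, fake)$reject)
})

test_that("asymptotic and MC rejection rates agree at n = m = 100", {
  tab <- mc_critical_values(function(n) rexp(n), 100, 100, "D2",
                            reps = 3000, seed = 11)
  set.seed(12)
  res <- vapply(seq_len(1000), function(r) {
    x <- rexp(100)
    y <- rexp(100)
    c(asym = asymptotic_test(x, y, "D2")$reject,
      mc = mc_test(x, y, tab)$reject)
  }, logical(2))
  expect_lt(abs(mean(res["asym", ]) - mean(res["mc", ])), 0.02)
})

test_that("location shifts barely move the dilation statistics", {
  set.seed(213)
  x <- rexp(80)
  y <- rexp(120, 0.5)
  base <- dilation_statistics(x, y)
  defect <- function(n) abs(mean(diltest:::score_J((0:(n - 1)) / n)))
  for (b in c(1, 25)) {
    both <- dilation_statistics(x + b, y + b)
    bound_d1 <- b * (defect(80) + defect(120)) + 1e-10
    expect_lte(abs(both["D1"] - base["D1"]), bound_d1)
    one <- dilation_statistics(x + b, y)
    expect_lte(abs(one["D1"] - base["D1"]), b * defect(80) + 1e-10)
  }
})

test_that("mean contrast grows with dilation separation", {
  set.seed(214)
  means_at <- function(mu) {
    rowMeans(vapply(seq_len(300), function(r) {
      dilation_statistics(rexp(50), rexp(50, 1 / mu))
    }, numeric(2)))
  }
  d_weak <- means_at(1.25)
  d_strong <- means_at(2)
  expect_true(all(d_weak > 0))
  expect_true(all(d_strong > d_weak))
})

test_that("dilation_test wrapper dispatches both methods", {
  set.seed(215)
  x <- rexp(40)
  y <- rexp(40, 0.5)
  res <- dilation_test(x, y)
  expect_named(res, c("D1", "D2"))
  expect_s3_class(res$D1, "dil_test_result")
  res_mc <- dilation_test(x, y, which = "D2", method = "mc",
                          null_model = scenario_spec("exponential", 1),
                          reps = 300, seed = 3)
  expect_identical(res_mc$D2$method, "mc_critical")
  expect_error(dilation_test(x, y, method = "mc"), "null_model")
})
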