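# diltest

Entropy-based two-sample tests for the **dilation order** — a
nonparametric way to ask *"is one population more dispersed than the
other?"* without comparing means, without assuming a model, and without
relying on variance (which can be badly misleading for heavy-tailed
data).

The package is aimed at statisticians and applied researchers in
reliability, survival analysis, insurance and finance who need evidence
about differences in *variability* between two groups: lifetimes under
two treatments, claims under two portfolios, returns under two regimes.

## The statistics

A random variable X precedes Y in the dilation order (X ≤_dil Y) when
E[φ(X − EX)] ≤ E[φ(Y − EY)] for every convex φ — Y is more dispersed,
in a location-free, partial-order sense that implies Var(X) ≤ Var(Y).

Two cumulative entropies track this order:

- cumulative residual entropy, CRE(X) = −∫ S(x) log S(x) dx
  (S the survival function), equal to the expected mean residual life;
- cumulative entropy, CE(X) = −∫ F(x) log F(x) dx, equal to the
  expected mean inactivity time, zero iff X is degenerate.

If X ≤_dil Y then CRE(X) ≤ CRE(Y) and CE(X) ≤ CE(Y), with equality only
when X and Y coincide up to a location shift.  The evidence contrasts

    D1(X, Y) = CRE(Y) − CRE(X),      D2(X, Y) = CE(Y) − CE(X)

are therefore zero under H0 : X =_dil Y and positive when Y strictly
dominates.  They are estimated by L-statistics on the order statistics,

    CRE_n = (1/n) Σ_{i=0}^{n−1} J(i/n) X_{(i+1):n},   J(u)  = −log(1−u) − 1,
    CE_n  = (1/n) Σ_{i=1}^{n}   J̄(i/n) X_{i:n},       J̄(u) = log(u) + 1,

with spacings-based variance estimators feeding either an asymptotic
normal decision rule or finite-sample Monte-Carlo critical values.
The same machinery yields a one-sample test of exponentiality against
HNBUE/HNWUE aging alternatives, four competitor dispersion statistics
(Aly, Belzunce, Gini-difference, Zardasht), absolute-Lorenz-curve
verification of the dilation order between parametric models, and a
simulation engine for size/power tables and null-normality diagnostics.

## Worked example

```r
library(diltest)
set.seed(42)
conventional <- rexp(40, rate = 1)    # baseline lifetimes, mean 1
germfree     <- rexp(40, rate = 0.5)  # more dispersed group, mean 2

res <- dilation_test(conventional, germfree)
res$D2
#> Two-sided asymptotic test of equal dispersion (dilation order)
#>   statistic: D2        estimate = 1.39016   (n = 40, m = 40)
#>   stderr = 0.529924, z = 2.6233, p-value = 0.008708
#>   reject H0 at level q = 0.05: yes
```

The estimate 1.39 is the CE contrast: the second sample's cumulative
entropy exceeds the first's by about 1.39, against a population contrast
of CE(Exp(2)) − CE(Exp(1)) = (2 − 1)(π²/6 − 1) ≈ 0.64 — within 1.5
standard errors.  The standard error 0.53 gives z = 2.62, so at the 5% level the
data provide clear evidence that the second group is the more dispersed
one; `res$D1` gives the matching CRE-based result (z = 2.80).

Population-side verification of an ordering, and a one-sample
exponentiality check:

```r
check_dilation_order(dist_weibull(2, 1), dist_weibull(1, 1))
#> [1] "x_dil_leq_y"        # shape 1 (exponential) is more dispersed

hnbue_test(rweibull(150, shape = 2), which = 1)
#>   statistic: hnbue1    estimate = 0.530386   (n = 150)
#>   stderr = 0.0387239, z = 11.3976, p-value = 4.298e-30
#>   reject H0 at level q = 0.05: yes  # strongly non-exponential (HNBUE)
```

Monte-Carlo power tables over the built-in scenario families:

```r
run_power_table("exponential", beta_grid = c(1, 2), n_list = 25,
                crit_reps = 5000, power_reps = 5000, seed = 1)
```

A thin command-line interface over these functions lives at
`inst/cli/diltest.R` (verbs `test`, `hnbue`, `simulate`).

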