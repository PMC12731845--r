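---
title: "Entropy-based evidence for the dilation order: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-based evidence for the dilation order: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diltest)
```

## The problem and the model

Many applied questions are about *dispersion*, not location: does a
germ-free environment make lifetimes more variable, does a policy change
widen the distribution of returns?  The dilation order formalises "more
dispersed": X ≤_dil Y when E[φ(X − EX)] ≤ E[φ(Y − EY)] for all convex φ.
It is location-free, implies Var(X) ≤ Var(Y), and — being a partial
order — refuses to rank distributions whose spread profiles genuinely
cross.

Two cumulative entropies are monotone along this order.  For a
nonnegative, absolutely continuous X with cdf F, survival S = 1 − F and
finite mean,

* CRE(X) = −∫ S log S dx = −∫₀¹ F⁻¹(u) log(1−u) du − E(X),
* CE(X)  = −∫ F log F dx = ∫₀¹ F⁻¹(u) log(u) du + E(X).

CRE equals the expected mean residual life, CE the expected mean
inactivity time; CE(X) = 0 iff X is degenerate.  If X ≤_dil Y then
CRE(X) ≤ CRE(Y) and CE(X) ≤ CE(Y), and equality of either entropy under
the ordering forces equality in distribution up to a location shift.
The contrasts D1 = CRE(Y) − CRE(X) and D2 = CE(Y) − CE(X) are therefore
*evidence functions* for dispersion: zero under H0 (equal dispersion up
to location), positive under strict dominance.  The converse fails — a
positive contrast does not certify the ordering (curves can cross), which
is why the tests are two-sided and why the package also ships the
population-side Lorenz check below.

The absolute lower Lorenz curve A_X(p) = ∫₀ᵖ (F⁻¹(t) − EX) dt is convex,
nonpositive, and zero at both endpoints; X ≤_dil Y iff A_X(p) ≥ A_Y(p)
for all p.  `check_dilation_order()` compares two curves on a grid and
returns one of four verdicts (`x_dil_leq_y`, `y_dil_leq_x`, `equal`,
`not_ordered`).

## Estimators

The empirical entropies are L-statistics with zero-integral scores
J(u) = −log(1−u) − 1 and J̄(u) = log(u) + 1:

* CRÊ_n = (1/n) Σ_{i=0}^{n−1} J(i/n) X_{(i+1):n},
* CÊ_n  = (1/n) Σ_{i=1}^{n} J̄(i/n) X_{i:n}.

**Grid conventions.**  A literal i/n grid cannot pair every score value
with an order statistic: J diverges at u = 1 and J̄ at u = 0.  We pair
J(i/n), i = 0..n−1, with the (i+1)-th order statistic, and J̄(i/n),
i = 1..n, with the i-th.  Both are asymptotically equivalent
discretisations of the quantile integrals; the choice was validated
against the package's own Monte-Carlo power tables (the alternative
"drop the divergent endpoint" pairing shifts small-sample power by
several points) and is used consistently for every score in the package,
including the exponentiality scores below.

Both estimators are exactly scale-equivariant and shift-invariant up to
|b| times the Riemann defect of the score sum, which decays like
log(n)/n; the test statistics D̂1 = CRÊ_m(Y) − CRÊ_n(X) and
D̂2 = CÊ_m(Y) − CÊ_n(X) inherit these properties, which is what makes
the procedure location-free in practice.

**Variance.**  √n(CRÊ_n − CRE) is asymptotically normal with variance
σ² = ∬ [F(min(x,y)) − F(x)F(y)] J(F(x)) J(F(y)) dx dy, estimated by the
spacings quadratic form

σ̂²_n = Σ_{i,j=1}^{n−1} [min(i,j)/n − ij/n²] J(i/n) J(j/n) Δ_i Δ_j,

with Δ_i the sample spacings (and J̄ for the CE version).  The
Brownian-bridge kernel min(p_i,p_j) − p_i p_j is positive semidefinite,
so the estimate is nonnegative for every sample.  The double sum is
contracted exactly in O(n) via suffix sums of the weighted spacings —
algebraically identical to the naive O(n²) sum (the test suite checks
them against each other to 1e−12), and fast enough to run at n = 10⁵.

## Decision rules

* **Asymptotic** (`asymptotic_test()`, the default for observed data):
  z = D̂ / √(σ̂²_x/n + σ̂²_y/m) referred to N(0,1), two-sided at level q.
* **Monte-Carlo** (`mc_critical_values()` + `mc_test()`): equal-tail
  q/2 and 1 − q/2 empirical quantiles (type-7 interpolation, so
  thresholds are bit-reproducible given the seed) of the signed statistic
  over null replicates, both groups drawn from the same null model.  For
  n = m the null law is symmetric under sample swap, making the band
  symmetric up to MC error and the rule equivalent to |T| exceeding the
  (1−q) quantile of |T|.  Rejection requires falling *strictly outside*
  the band.  MC p-values are the empirical two-sided tail proportion,
  resolution-limited by the replicate count.

The two rules agree in rejection rate to within MC error at moderate n
(checked at n = m = 100 in the suite).  A permutation/pooled null is
deliberately not offered: the method's null allows a location shift
between groups, which pooling would destroy.

The wording of two-sided Monte-Carlo thresholds in the literature mixes
(1−q) and (1−q/2) quantiles; the equal-tail signed convention used here
is the one that reproduces nominal size 0.05 in the null rows of the
power tables.

Each test is reported separately per statistic (D1-based and D2-based),
as in the reference power tables; a conjunction rule ("reject only if
both exceed their thresholds") appears in parts of the literature but is
not implemented.

## Scenario catalogue — the study conditions

`scenario_spec()` fixes the simulation conditions; these defaults *are*
the study design, not tuning knobs:

| family | group 1 (baseline) | group 2 (alternative) | null |
|---|---|---|---|
| exponential | Exp(mean 1) | Exp(mean β) | β = 1 |
| pareto | Lomax(shape 10, scale 3) | Lomax(shape 10/β, scale 3) | β = 1 |
| gamma | Gamma(2, 1) | Gamma(β, 1) | β = 2 |
| weibull | Weibull(2, 1) | Weibull(β, 1) | β = 2 |
| mixture_weibull | Weibull(2, 1) | ½W(2,1) + ½W(β,1) | β = 2 |

Power tables conventionally label the exponential alternative by the
second group's rate γ = 1/β.  For the Pareto family the "P(10, 3)"
notation is read shape-first: dividing the *tail index* by β is what
makes the second group strictly more dispersed and reproduces the
published monotone power pattern for this family; the alternative
scale-first reading (downscaling the second group) yields an almost
powerless sweep and is inconsistent with those tables.  The mixture at
its null β = 2 collapses exactly to Weibull(2, 1).

`run_power_table()` implements the two-stage protocol: per (statistic,
n, family) one set of critical values from `crit_reps` null pairs, then
per β a rejection proportion over `power_reps` fresh pairs — 5000/5000
by default, matching the reference protocol.  All statistics are signed
L-statistics, so each batch reduces to two matrix products against the
sorted samples; a full 5000/5000 cell at n = 100 takes about a second.
Child seeds are derived per (family, n, stage, β) with a 31-bit string
hash, so runs are bit-reproducible given the master seed and all
statistics are evaluated on identical sample pairs (paired columns).
`qq_diagnostic()` standardises null replicates and reports the
correlation with normal quantiles at (i − ½)/reps.

## Competitor statistics

Four published dispersion statistics share the decision interface: Aly's
spacings functional, the Belzunce Lorenz-kernel statistic (α₁ = 0.5),
the Gini-mean-difference contrast, and Zardasht's score statistic
(α₂ = 2, score 1 − 2u).  Two implementation notes:

* Aly's δ_m(G) is printed in the source formula with X order statistics;
  it is computed here from the second sample (otherwise the statistic
  would ignore Y entirely).  Expanding both into order-statistic
  coefficients shows Aly's tN is *exactly proportional* to the Gini
  contrast when n = m — their MC tests are then the same test, and the
  package's power columns for the two coincide by construction.
* The Belzunce coefficient for the cell straddling α₁ is typographically
  garbled in the source; it is reconstructed as the exact subinterval
  integral of the piecewise kernel h(u) = 1/2 − u²/(2α₁) (u < α₁),
  (1−u)²/2 (u ≥ α₁), whose closed forms reproduce the two intact
  branches.  Published power values for this statistic are not
  reproduced by this reconstruction, so only structural properties
  (monotone coefficients, zero on equal samples, sign flip) are asserted
  for it.

## Exponentiality testing (HNBUE/HNWUE)

X is HNBUE (HNWUE) iff X ≤_dil (≥_dil) an exponential with the same
mean.  The contrasts D′₁ = E(X) − CRE(X) and
D′₂ = E(X)(π²/6 − 1) − CE(X) vanish exactly iff X is exponential; their
estimators use scores J′(u) = 2 + log(1−u) and
J̄′(u) = −log(u) + π²/6 − 2, re-derived from the defining contrasts
(both integrate the exponential quantile to zero — the self-validating
identity CE(Exp(μ)) = μ(π²/6 − 1), via ∫₀¹ log(u)log(1−u) du = 2 − π²/6,
is checked in the suite).  Published variants of these scores with
flipped signs/constants are retained behind `weights = "printed"` for
comparison; they do not vanish at the null.

**Null centring.**  The J′ score concentrates on the upper tail, so the
plug-in estimator of D′₁ carries a finite-sample null bias that decays
only like log(n)/n — about 1.6 null standard deviations at n = 100,
enough to quadruple the nominal size.  Because the estimator is
scale-equivariant, its exact null expectation is μ·b_n with b_n a
constant computed from harmonic numbers (E[Z_{k:n}] = H_n − H_{n−k} for
standard exponential Z).  `hnbue_test()` therefore standardises
D̂′ − X̄·b_n, which has exactly zero expectation under *every*
exponential null, restores nominal size in moderate samples, and changes
nothing asymptotically (b_n → 0).  The scale-invariant reported
statistic D̂′/X̄ is unchanged.

## Numerical choices

* Quadrature on (0,1) splits explicitly at 10⁻¹², 10⁻⁶, 10⁻³ from both
  endpoints before adaptive integration (absolute tolerance 10⁻⁹): the
  integrands have integrable logarithmic/power endpoint singularities.
* Models with divergent mean (e.g. Lomax tail index ≤ 1) are rejected at
  construction — CRE/CE are undefined there.
* Dilation verdicts use per-point tolerance 10⁻⁷·(1 + |EX| + |EY|) on a
  grid of at least 100 points (default 201).
* Mixture quantiles invert the mixture cdf by bisection (`uniroot`,
  tolerance 10⁻¹²) bracketed by the component quantiles.
* Variance estimates are clamped at zero against roundoff; ties in the
  data are allowed (tied spacings contribute zero).
* Empirical quantiles everywhere are type-7 (R's default), making
  thresholds reproducible across platforms.

## What the generator emulates — and what it does not

The synthetic scenarios cover light tails (gamma, Weibull), an
exponential boundary case, a genuinely heavy tail (Lomax), and a
two-component mixture, all strictly positive and absolutely continuous.
They do not emulate censoring, ties from coarse measurement, negative
support, or dependence between groups — so a green simulation suite
says nothing about those features.  Real data with heavy rounding will
produce zero spacings (handled, but eroding the variance estimate), and
censored survival data are outside the method's scope entirely.

## Problem sizes used by the tests

The unit suite runs at n between 2 and a few hundred with replicate
counts of a few hundred to 2000; the consistency and variance-oracle
checks use single samples of n = 10⁵; the acceptance checks run the
simulation engine at the full 5000/5000 replicates for eight cells
(n = m ∈ {25, 50, 100}) and complete in a few seconds each.  The
normality diagnostic uses 2000 null replicates at n = m = 100.

## Known limitations

* One-sided versions and confidence intervals for the contrasts are not
  provided (derivable from the same asymptotics).
* The Belzunce column is structural-only, as described above.
* The Aly/Gini equivalence at n = m means the package's six statistics
  collapse to five distinct tests in equal-size designs.
* MC p-values have resolution 1/reps and the thresholds are n-specific:
  `mc_test()` refuses size mismatches rather than interpolating.
* Small-sample CRÊ can be negative (the population CRE cannot); this is
  expected L-statistic discretisation error, not a bug.
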