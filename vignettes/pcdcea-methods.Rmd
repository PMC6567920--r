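---
title: "Methods: decision-analytic evaluation of PCD diagnostic algorithms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decision-analytic evaluation of PCD diagnostic algorithms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcdcea)
```

## The problem

Primary ciliary dyskinesia is genetically heterogeneous: no single test —
nasal nitric oxide (nNO), high-speed video microscopy (HSVM), transmission
electron microscopy (TEM) — is both perfectly sensitive and specific, and
centres combine them in different orders. Whether a centre confirms a
positive nNO screen with HSVM or with TEM, or runs nNO and HSVM in
parallel with TEM as tie-breaker, changes (i) how many of the truly
diseased referrals are found, and (ii) the annual testing budget. This
package quantifies both under parameter uncertainty.

## Classification model and its assumptions

Each referral is diseased with probability π (prevalence among suspect
referrals, default best estimate 0.32 for a cohort of 1000/year, i.e. 320
expected cases). Each administered test is a Bernoulli trial whose success
probability is the test's sensitivity for diseased patients and
1 − specificity for healthy ones.

The load-bearing assumption is **conditional independence of test results
given disease status**. It is what licenses feeding the Bayes posterior
after a positive screen in as the prior of the confirmatory test, and it
is exactly how the expected-value tree is expanded
(`classify_sequential()`, `classify_parallel_arbiter()`). The test suite
verifies algebraically that posterior chaining and the direct tree
expansion coincide to 1e-9. In reality the assumption is doubtful —
secondary ciliary dyskinesia can degrade both HSVM and TEM on the same
brushing — which is why `test_accuracy()` carries optional
*conditional* (post-positive-screen) sensitivity/specificity slots: if
second-stage accuracy estimates conditional on a positive screen are
available, they replace the marginals in both the analytic model and the
microsimulation. The shipped defaults use marginal values because the
conditional estimates behind the published classification table were never
printed; consequently `accuracy_table()` at the defaults yields, e.g., 304
expected true positives for nNO+HSVM where the published table reports
273. That discrepancy is structural (missing inputs), not a bug, and the
package deliberately does not guess the missing values —
`reference_counts()` ships the published cells as data for the net-metric
identities instead.

Expected counts are kept as reals; rounding happens only in report
formatting (integer percentages, with one decimal in the 99–100% band
where integer rounding would misreport, so 99.7% does not become 100%).

## Parameter distributions

Each parameter is a `dist_spec`: family, best estimate, 95% CI, and
family-specific extras. Choices made where the published descriptors were
ambiguous or inconsistent:

* **Beta accuracies.** The printed beta parameters have the form
  (a, b) = (mean, 1 − mean), which cannot reproduce the narrow printed
  CIs. They are read as mean/complement shorthand: the fit fixes the mean
  at the best estimate and root-finds the concentration that best matches
  the (0.025, 0.975) quantiles to the CI, reporting the residual
  (`fit_distribution()$residual`). The HSVM sensitivity best estimate of
  1.00 is a degenerate beta mean, and its printed distribution uses 0.99;
  the spec therefore allows an explicit sampling `mean` (0.99) distinct
  from the deterministic best (1.00).
* **Gamma costs** print only a mean; shape/scale are solved from mean +
  CI the same way. For near-symmetric CIs this lands on large shapes
  (near-normal), which is acceptable.
* **Normal** rows use the printed SD when given (prevalence: SD 0.028),
  otherwise SD = CI half-width / 1.959964.
* **Lognormal** (TEM duration) is exact in (median 10 h, gsd 1.3); its
  fitted 95% interval (5.98, 16.7) differs from the printed (6, 18) and
  the residual records by how much.
* **Probability-typed draws** are kept in [0, 1] by renormalizing the
  uniform into the feasible quantile range before inversion (truncation,
  not clipping at the density level), so a wide normal prevalence can
  never leak outside the unit interval.
* The brushing time (0.2 h) is a point mass; the physician rate and
  brushing time are *shared* parameters between HSVM and TEM (one LHS
  column each), since both tests work on the same kind of nasal brushing.

## Latin Hypercube sampling

`sample_lhs()` cuts each parameter's probability scale into `n_iter`
equal strata, draws one uniform per stratum, permutes the strata
**independently per parameter** (the published description does not say
whether permutations were paired; independent permutation is the
conventional reading and is what maximizes marginal stratification
without imposing correlation), and pushes the uniforms through the fitted
quantile functions. The stratified uniforms are retained as an attribute
for audit. Seeding is explicit and mandatory; two runs with the same seed
are bitwise identical.

## Micro-costing

The published cost build-up lives in an unavailable technical appendix, so
the package implements a transparent formula instead of imitating
unpublished numbers:

* fixed annual cost per test type: capital / lifespan + maintenance
  (straight-line annualization, no discounting — the simplest defensible
  reading of "equipment lifespan in years");
* variable cost per test: consumables + operator rate × duration +
  physician rate × brushing time;
* one brushing per sampled patient: when TEM arbitrates after HSVM in the
  parallel arm it reuses HSVM's brushing, so TEM's sampling term is
  suppressed there;
* an optional flat per-referral overhead (default 0) lets users add the
  site-level costs (replication across centres, travel, overheads) that
  unit prices alone do not carry.

With the shipped unit prices this yields ~63 K EUR/year for nNO+HSVM,
far below the ~136 K EUR/year of the published model — the missing
difference is exactly those unrecoverable appendix components. What *is*
reproduced, and is asserted in the acceptance suite, is the qualitative
economics: nNO+TEM costs more and finds fewer cases than nNO+HSVM (simple
dominance), and the frontier is Do-nothing → nNO+HSVM → nNO/HSVM+TEM.

A consequence worth noting: the often-quoted claim that the parallel arm
must be the most expensive holds only when the test types share a cost
profile (it performs a superset of first-line tests but *fewer* arbiter
tests); with the shipped heterogeneous prices, sequential nNO+TEM is
actually dearer than the parallel arm because it sends 345 rather than
105 patients/year to TEM. The test suite pins both facts.

## PSA, estimators, and decision statistics

`run_psa()` evaluates every strategy on the same draw row (common random
numbers), with effect defined as expected true positives per iteration
(continuous; the tree is an expectation, so no second layer of binomial
noise is added) and cost as the micro-costed annual total.

Ratio statistics are estimator-sensitive: the published summary means
imply a frontier ICER of (209000 − 136000)/(313 − 273) = 1825 EUR/case,
while the published headline ICER is 2097 EUR/case — consistent with
averaging per-iteration ratios rather than taking the ratio of means.
`ratio_estimates()` therefore always reports both, with a percentile CI
on the per-iteration ratios; iterations with zero incremental effect are
excluded from the mean-of-ratios and counted. The two estimators coincide
exactly for a degenerate (all-point) PSA, which the tests assert.

Dominance pruning removes simply dominated strategies first (cost no
lower, effect no higher, with a lexicographic tie-break so exact ties are
deterministic), then iteratively removes extended-dominance violations
until ICERs strictly increase along the frontier; equal-ICER collinear
triples lose their middle member under the strict-increase rule.

The CEAC reports, per willingness-to-pay λ, the fraction of iterations
with incremental net monetary benefit λ·Δe − Δc ≥ 0; ties count as
cost-effective. Percentile (type-7) intervals are used throughout rather
than normal approximations, since cost draws are skewed.

`tornado()` is the deterministic one-way analysis: each parameter in turn
is set to its 95% CI endpoints with everything else at best estimates,
and the ICER span is recorded; point parameters produce zero span and
sort last.

## What the synthetic data does and does not establish

`generate_cohort()` + `simulate_algorithm()` emulate the stated world:
Bernoulli disease states at the stated prevalence and per-patient,
per-test Bernoulli outcomes at the stated accuracies, with the decision
logic applied patient by patient (no confirmatory test after a negative
screen; arbiter only on discordant pairs). Uniform streams are derived
per (seed, test), so adding a strategy to a comparison never perturbs the
draws of the others, and strategies share test outcomes at the same seed.

A green oracle test (simulated cell frequencies within 3 binomial SEs of
the analytic expectations at n = 10^6) establishes that the analytic tree
and the simulation encode the *same* model — it cannot validate the
conditional-independence assumption itself, nor the accuracy estimates,
against reality. Within-patient correlation of HSVM/TEM errors is an
explicit non-goal of the generator.

## Numerical choices and limitations

* Beta/gamma CI fitting is a 1-D log-scale optimization of the
  concentration over [1e-3, 1e8]; residuals for the shipped table are all
  below 0.01 on the parameter scale.
* Bayes updates return 0 for 0/0 (zero prior with a perfectly specific
  test); a zero denominator with positive numerator cannot arise for
  valid inputs.
* The conservation identities (cells sum to n; disease margin equals
  π·n) hold to 1e-9 and are asserted as properties.
* Published absolute outputs that depend on unpublished inputs
  (classification counts 198/273/313, cost levels 136/150/209 K EUR,
  CERs, the 2097 ICER, CEAC probabilities at 2500/3500 EUR) are *not*
  reproduced and not asserted; the package documents the gap rather than
  calibrating toward it.
* Costing ignores currency conversion, inflation and discounting;
  sampling is uncorrelated across parameters (no copulas);
  value-of-information analysis is out of scope.
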