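---
title: "Rank-based and grade-based DOOR analysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based and grade-based DOOR analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doorstats)
```

## The estimand and its estimator

A DOOR outcome assigns every participant to one of K ordinal categories,
ordered from most desirable (index 1) to least desirable (index K, usually
death). For two arms with n1 and n2 participants, the target of the
rank-based track is the DOOR probability

$$p = \Pr(\text{experimental more desirable}) +
      \tfrac12 \Pr(\text{equally desirable}),$$

estimated over all n1 x n2 cross-arm pairs by the Wilcoxon–Mann–Whitney
statistic with half-weight ties. Ties always receive weight 1/2; no
alternative tie rule is exposed, because the estimand itself is defined with
half-ties and changing the rule silently changes the estimand. The closed
form used by `count_pairs()` — wins $= \sum_k a_k \sum_{j>k} b_j$, ties
$= \sum_k a_k b_k$ — is algebraically identical to the brute-force double
loop over participants, and the test suite verifies that identity on
hundreds of random tables.

The estimator needs no distributional assumptions. Its interpretation is
marginal: p = 50% means a coin-flip between arms for a randomly chosen
cross-arm pair, which identical distributions imply but which can also arise
from crossing distributions, so the distribution table and cumulative
analyses should always accompany the headline estimate.

## Variance estimation and confidence intervals

Two variance objects are maintained deliberately:

* `variance_u()` is the consistent plug-in variance from the two-sample
  U-statistic decomposition with the half-tie kernel. It converges to the
  true sampling variance under arbitrary (unequal) distributions and scales
  as 1/n; the suite checks it against a 10,000-replicate bootstrap on the
  packaged trial and the 1/n scaling law.
* `rank_variance_null()` (internal) is the tie-corrected rank variance under
  exchangeability of the pooled sample,
  $(N+1)/(12 n_1 n_2)\,[1 - \sum_t (t^3-t)/(N^3-N)]$, the classical
  studentizer of the tied rank-sum test.

The primary interval returned by `halperin_ci()` is the symmetric normal
interval built on the exchangeability variance. This choice is the package's
calibration decision for tied ordinal data: it is exactly the inversion of
the tie-corrected WMW test reported next to it, so the interval and p-value
can never disagree about the 50% reference; its coverage under the
exchangeability null is close to nominal (verified at 2,000 simulated
100-per-arm null trials, where coverage must fall in [0.93, 0.97]); and on
the packaged doripenem/levofloxacin example it reproduces the published
interval bounds for the overall and both headline component analyses at
0.1-percentage-point precision, which none of the consistent-variance Wald,
logit-Wald, or score-type constructions we evaluated did simultaneously.
Away from the null the exchangeability variance can differ from the true
sampling variance, so a logit-scale Wald interval on `variance_u()` is
provided as a labeled fallback (`method = "logit"`) for strongly separated
distributions; the `method` string of every estimate records which was used.
Degenerate tables (all mass in one shared category) collapse the interval to
the point estimate with a warning rather than producing NaN.

`wmw_test()` applies no continuity correction by default (a flag enables
it); with the tie-corrected variance the uncorrected statistic reproduces
conventional two-decimal p-values, and the correction is immaterial at the
sample sizes where the normal approximation is trustworthy. Cumulative
analyses (`cumulative_door()`) dichotomize at each cut and reuse the same
interval method as the overall analysis, so forest rows are comparable
column-for-column.

## Grade-based (partial credit) analysis

`partial_credit_diff()` compares mean grades with an unpooled-variance
normal comparison. The inference model is deliberately the plainest valid
one: graded scores are bounded, so the central limit theorem is the only
assumption, matching the robustness rationale for using DOOR in the first
place. The grade difference is affine in each grade with slope
$a_k/n_1 - b_k/n_2$, which `grade_grid()` exploits to evaluate the full
101 x 101 default grid (1-grade-point steps over $[0,100]^2$) in closed form
rather than by key-by-key recomputation; the suite asserts grid-vs-scalar
agreement at interior points.

Grid cells are labeled by favored arm only when the two-sided p-value falls
below `alpha` (default 0.05, configurable). Non-monotone keys (a worse
category graded above a better one) are computed and flagged rather than
rejected, since the sensitivity sweep intentionally covers the full square.
When more than two interior categories exist, the grades of the fixed ones
must be supplied explicitly — there is no defensible default for them, and a
hidden default would silently change the map. The tipping boundary is
represented as the set of grid-cell edges between cells of different favored
status (a marching-squares-style polyline), which is resolution-independent
and directly plottable; `plot.grade_grid()` overlays it on the shaded
region map.

## Standardized summaries

Expected gain/loss tables rescale per-category proportion differences to a
standard cohort (default 1,000 assigned patients) and round half away from
zero to whole patients, always from raw counts rather than from rounded
percentages. Pre-rounding per-category values sum to zero by construction
when both arms are complete; percentages are reported to one decimal. The
sign convention is experimental minus control throughout the package.

## IPTW-weighted analyses

For nonrandomized comparisons the package consumes user-supplied propensity
scores — estimating the propensity model is intentionally out of scope, as
it belongs to the study's confounding-adjustment plan, not to the outcome
analysis. `stabilized_weights()` forms stabilized weights (marginal arm
probability over the propensity of the received arm), with optional
percentile truncation, off by default, reported when applied. Weighted
estimators replace counts by weight masses; with unit weights they reduce
exactly to the unweighted estimators, and all estimates are invariant to
rescaling the weights.

No closed-form weighted variance is attempted; intervals come from a
stratified nonparametric bootstrap (resampling within arm, percentile
method, default B = 2,000, seed required). The percentile interval is
clipped to contain the point estimate, so the effect-record invariant
ci_low <= estimate <= ci_high holds even in degenerate resamples.

## Design-stage simulation

`true_door_probability()` gives the exact population DOOR probability of two
multinomials, $\sum_k \pi^e_k(\sum_{j>k}\pi^c_j + \pi^c_k/2)$. `power_sim()`
estimates power for the tie-corrected WMW test by drawing per-arm
multinomial tables; it is vectorized, deterministic given the scenario seed,
and attaches a binomial Monte-Carlo interval. `sample_size_search()`
brackets by doubling and then bisects, resetting the RNG to the scenario
seed before every candidate n (common random numbers) so the estimated
power curve is monotone and the search reproducible. Defaults of
alpha = 0.05 (two-sided) and target power 0.90 are package conventions.

## The synthetic generator and what passing tests show

`simulate_door_trial()` emulates the standard construction of DOOR outcomes
from component events: category k < K means "alive with k-1 deleterious
events", so the generator draws the category and then selects exactly k-1
of the named non-fatal components — flags can never contradict the recorded
category. Death sets only the death flag; whether a dying patient's
non-fatal events should also be flagged is not decidable from published
summary tables, and leaving them unset keeps the component tables
interpretable as "non-fatal event" counts. The generator does not emulate
missingness mechanisms, correlated adjudication error, or time-to-event
structure ("sliding" DOOR), so passing tests speak to the estimators'
arithmetic and sampling behavior, not to robustness against those real-data
features.

`confounded_scenario()` adds a single binary baseline covariate that shifts
both treatment assignment (log-odds `effect` between strata) and outcome
severity (exponential tilt of the category distribution by `effect`
log-odds across the category range). Its defaults — effect 2.0,
400 per arm, a 4-level outcome with a clear treatment benefit — were fixed
analytically so that the asymptotic confounding bias of the unweighted
estimator (about -0.09 on the probability scale, computed in closed form
and returned as `naive`) is several times the sampling standard deviation,
i.e., a materially confounded observational comparison of the kind IPTW is
meant for. The scenario returns the exact marginal (standardized) DOOR
probability as recovery truth; the suite requires the weighted estimate to
beat the unweighted one in at least 95% of 1,000 replicates.

## Problem sizes and reproducibility

The calibration checks in the test suite use 2,000 simulated null trials of
100 participants per arm (test size and interval coverage), 2,000 simulated
design-stage trials for the null-power check, 200 random tables (n <= 50,
K <= 8) for the brute-force equivalence sweep, and 1,000 confounded
replicates of 800 participants for the IPTW recovery check — sizes chosen
so Monte-Carlo error is well inside the asserted bands while the whole
suite runs in seconds. Every stochastic path (generator, bootstrap, power
simulation, search) requires an explicit seed, and rerunning any report or
CLI command with the same inputs produces byte-identical tables.

## Known limitations

* Two arms only; no stratified (van Elteren-type) or multi-arm rank tests.
* The exchangeability-variance interval is anchored at the no-difference
  reference; for extreme separations prefer the logit fallback.
* No exact/permutation WMW p-values; the normal approximation needs
  moderate per-arm sizes (roughly 30+ with ties spread over categories).
* IPTW assumes correct, externally estimated propensities and positivity;
  no doubly-robust or matching estimators.
* No longitudinal ("sliding") DOOR, group-sequential monitoring, or
  meta-analytic pooling.
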