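# doorstats

Benefit:risk analysis of two-arm clinical studies with **desirability of
outcome ranking (DOOR)** outcomes.

Conventional trials analyze efficacy and safety one endpoint at a time, which
obscures how benefits and harms accumulate in individual patients. A DOOR
outcome instead orders each participant's overall experience on an ordinal
scale from most desirable (e.g., *alive with no deleterious events*) to least
desirable (*death*). `doorstats` implements the two complementary analysis
tracks for such outcomes, their supporting summaries, weighted variants for
nonrandomized comparisons, and design-stage simulation tools.

## The statistics

**Rank-based.** With n₁ experimental and n₂ control participants there are
n₁ × n₂ cross-arm pairs. The DOOR probability — the probability that a random
experimental participant has a more desirable outcome than a random control
participant, ties counted half — is estimated by the
Wilcoxon–Mann–Whitney statistic

    p̂ = (#[more desirable] + ½ #[ties]) / (n₁ n₂).

Identical distributions give p̂ → 50%. Confidence intervals use the
tie-corrected rank variance of p̂,
σ₀² = (N+1)/(12 n₁ n₂) · (1 − Σ(t³−t)/(N³−N)) with N = n₁+n₂ and t the pooled
category sizes — the same variance that studentizes the tie-corrected WMW
test of the 50% null — with a logit-scale Wald interval on the consistent
U-statistic variance available as a labeled fallback. Related pairwise
metrics are derived from the same pair counts: win ratio (wins/losses),
win odds ((wins+½ties)/(losses+½ties)) and net treatment benefit (2p̂ − 1).

**Grade-based (partial credit).** A grading key assigns each category a grade
like an academic test: 100 for the best category, 0 for death, partial credit
between. Arms are compared by the difference in mean grades with a
large-sample unpooled-variance test. Sweeping the grades of two free
categories over [0,100]² yields the contour map of the contrast and its
**tipping boundary** — the locus separating grading keys that favor one
therapy from keys favoring the other.

Also provided: distribution tables with cumulative percentages and expected
gain/loss per 1,000 treated patients; IPTW-weighted DOOR and partial-credit
estimators with stratified bootstrap intervals (for observational
comparisons with user-supplied propensity scores); closed-form population
DOOR probabilities, simulation-based power, and sample-size search.

## Worked example

The packaged fixture holds the 2 × 5 category counts of a randomized cUTI /
pyelonephritis trial (374 participants per arm):

```r
library(doorstats)
tb <- door_fixture("dori05_door")
rep <- door_analyze(tb, components = door_fixture("dori05_components"),
                    keys = list(even = c(100, 75, 50, 25, 0)))
print(rep)
print(gain_loss(tb))
```

```
DOOR analysis (doripenem vs levofloxacin)
  DOOR probability 51.0% (95% CI: 47.6%, 54.3%; P = 0.58)
  win ratio 1.089, win odds 1.039, NTB 0.019
  partial credit [even]: +0.000 grade points (P = 1.00)
Expected gain/loss per 1,000 assigned patients (experimental - control):
             category gain_or_loss cumulative
 Alive with no events           27         27
   Alive with 1 event          -48        -21
  Alive with 2 events           19         -3
  Alive with 3 events            0         -3
                Death            3          0
```

Reading: a participant on doripenem had a 51.0% probability of a more
desirable overall outcome than one on levofloxacin — compatible with no
overall difference (P = 0.58) — even though per 1,000 patients doripenem
would yield 86 fewer clinical failures *and* 48 more infectious
complications (`component_gain_loss`); the equal-spacing grading key scores
the arms identically. The composite view shows how an efficacy advantage and
a safety disadvantage offset each other, which siloed analyses cannot.

Cumulative and component forest data come from `door_forest()`, grading-key
sensitivity maps from `grade_grid()` + `tipping_boundary()`, and the same
operations are scriptable via

```sh
Rscript inst/cli/door.R analyze --table counts.csv --experimental DOR --out out/
```

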