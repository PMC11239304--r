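---
title: "Optimizing multicomponent interventions for equitability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing multicomponent interventions for equitability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daivequity)
```

## The decision problem

A `2^k` factorial optimization randomized controlled trial (ORCT) estimates
how `k` candidate intervention components, each On or Off, contribute to a
continuous health outcome. The trial yields one expected outcome gain per
candidate intervention (one of the `2^k` On/Off combinations), and the
optimized intervention is chosen by balancing that gain against delivery
cost. `daivequity` extends this posterior-expected-value workflow with an
explicit equity criterion: how evenly an intervention's expected benefits are
distributed across levels of systemic advantage.

Throughout, advantage is a continuous score $S \in [0,1]$, increasing in
advantage, stratified into $G$ equal-probability groups $g = 1,\dots,G$
(quintiles by default). The analysis has four stages.

**1. Expected gains.** A linear regression of the outcome gain on the factor
structure — all main effects and two-way interactions by default — is fitted
to the full sample and, separately, within each advantage group, giving
$\hat Y_t$ and $\hat Y_{t,g}$ for every condition $t$. Factors enter under
effect coding ($-1/+1$), the convention in factorial optimization trials;
the model-implied cell means used downstream are invariant to the coding.
The reference inference backend is the flat-prior conjugate posterior, whose
posterior mean coincides with least squares; an optional sampling backend
draws from the matching normal-inverse-gamma posterior and agrees up to
Monte-Carlo error. We deliberately avoid a heavier MCMC dependency: the
downstream decision rules consume posterior means of cell means, for which
the closed form is exact.

**2. Equitability.** Groups ordered by advantage have population shares
$w_g$ (equal for simulated quintiles, observed proportions for loaded data)
and cumulative rank boundaries $R_g = \sum_{j \le g} w_j$, $R_0 \equiv 0$.
The concentration curve of condition $t$,
$h_t(R_g) = \sum_{j\le g}\hat Y_{t,j} \big/ \sum_{j\le G}\hat Y_{t,j}$,
tracks the cumulative share of expected gains accruing to the least
advantaged; gains independent of advantage put it on the 45° line. The
health-gain concentration index $H_t$ is twice the signed area between the
45° line and the curve, accumulated exactly by the trapezoid rule over the
group intervals, and equitability is $Q_t = -H_t$, positive for
equity-enhancing interventions. Because group gains may be negative
(iatrogenic components), $H_t$ is not confined to $[-1, 1]$; the test suite
constructs a two-group case with $H = 4.5$. Conditions whose total expected
gain $\sum_g w_g \hat Y_{t,g}$ is not positive are excluded before $h_t$ is
formed — the curve's denominator degenerates there, and an intervention with
no overall gain is not a candidate however its non-gains are distributed.

**3. Net health value.** Cost and gain collapse to one scale per
willingness-to-pay threshold $\lambda$ (money per unit outcome gain):
$NHV_t(\lambda) = \lambda \hat Y_t - C_t$, with $C_t$ the sum of the
component costs set to On.

**4. Frontiers.** Two convex hulls organize the decision. The *value
efficiency frontier* is the lower-right hull of (cost, gain), anchored at
the least costly condition; its consecutive slopes are the incremental
cost-effectiveness ratios (ICERs), strictly increasing once dominated and
extended-dominated conditions are removed. The *net health equity frontier*
at a given $\lambda$ is the upper-right hull of $(Q_t, NHV_t)$ over the
non-excluded conditions, running from the maximum-NHV member to the
maximum-$Q$ member; hull members are the decision contenders, and each is
labelled by its quadrant (signs of $Q$ and $NHV$), which summarizes the
equity/value trade it embodies.

## The synthetic ORCT generator

`simulate_orct()` emulates a single-level, fixed-intervention factorial
trial in which component effects are functions of advantage. The built-in
case study (`case_study_design()`, `case_study_effects()`) is a `2^4`
adherence trial: Motivational Interviewing $\mu_A = 0.5 + 0.5S$ and Peer
Support $\mu_B = S$ work less well for the less advantaged; the Navigator is
inert alone ($\mu_C = 0$) but offsets Peer Support's gradient through a B×C
interaction of $1 - S$, so the BC combination gains exactly 1 at every $S$;
Skill-Building $\mu_D = 1 - S$ favors the less advantaged. Costs are
$C_A, C_B, C_C, C_D = 100, 125, 200, 250$ and outcomes are
$Y_i \sim N(\mu_t(S_i), 1)$, gains relative to a zero-effect minimal
condition. Defaults are $G = 5$ quintiles and 10 individuals per group per
condition ($N = 800$).

Two readings of "uniform advantage with exactly balanced quintile cells" are
possible; we draw $S$ uniformly *within* each of the $G$ equal-width strata,
which preserves both the marginal uniform distribution and exact cell
balance. Group labels for simulated data therefore use population quantile
boundaries $g/G$; for loaded data `assign_groups()` stratifies by sample
quantiles instead. Each (group, condition) cell draws from its own seeded
substream (advantage and noise separately), so enlarging a cell extends it
without reshuffling existing individuals, and the whole dataset is
bit-reproducible from one seed.

What the generator does *not* emulate — and hence what passing tests cannot
certify about real trials: measurement error in the advantage score,
non-uniform or clustered advantage distributions, missing data, attrition,
outcome distributions other than homoscedastic normal, higher-order
interactions, and multilevel delivery. Effect functions are linear in $S$ in
the case study (any finite function of $S$ is accepted programmatically;
configurations declare $a + bS$ forms to stay serializable).

## Tunable parameters

| parameter | default | units | notes |
|---|---|---|---|
| `G` | 5 | groups | advantage strata; 2 is the minimum meaningful |
| `per_cell_n` | 10 | individuals | per group × condition cell |
| `noise_sd` | 1 | outcome units | outcome SD around the true gain |
| `terms` | two-way | — | `main`, `two-way`, `saturated` |
| `backend` | closed | — | `sampling` adds posterior draws |
| `wtp` | derived | money / outcome unit | explicit list, or bracketing strategy |
| `exclusion_tolerance` | `"2sd"` (pipeline), 0 (low level) | outcome units | see below |
| `quadrant_tol` | 0 | — | half-width of the on-axis band |

**Exclusion tolerance.** The rule excludes conditions with total gain at or
below the tolerance. On analytic (noise-free) inputs the natural boundary is
exactly zero, and that is the low-level default. On estimated inputs a
strictly zero threshold would include a truly null condition whenever its
estimate lands a hair above zero — with a near-zero denominator its
concentration shares explode. The pipeline therefore defaults to excluding
conditions whose total gain is within two posterior standard deviations of
zero, i.e. not credibly positive; in the case study this removes the minimal
condition and the inert Navigator-only condition in the large majority of
runs, as intended.

**Willingness-to-pay selection.** When no explicit thresholds are given, the
bracketing strategy picks one value inside every decision-relevant range
delimited by the frontier ICERs: half the smallest ICER, the midpoints of
consecutive ICERs, and 1.5 times the largest. Reproduction runs of the case
study instead pass the conventional set $\{170, 330, 580, 830\}$ explicitly.

## Numerical and tie-breaking choices

Hull construction sorts by the abscissa, removes dominated points, and scans
with a slope test using an absolute tolerance of $10^{-12}$; collinear
points are excluded (strict hull) unless `include_collinear = TRUE`. Exact
coordinate ties are resolved deterministically: keep the higher ordinate,
then the condition with fewer On components, then the lexicographically
smaller label. Degenerate inputs behave predictably: a single point is its
own frontier, equal-cost points collapse to the best one, and ICERs are
refused on a one-member frontier. Concentration-index arithmetic is exact
trapezoid summation (the curve is piecewise linear); the test suite verifies
it against an independent fine-grid numeric integration to $10^{-12}$ and
verifies both hull routines against exhaustive dominance/segment
enumeration. Rank-deficient model fits (for example a saturated model with
an empty cell) abort with the inestimable terms named. Reports serialize
floating point with 12 significant digits so identical configurations diff
identically.

## Problem sizes used in the packaged checks

The test suite exercises the case study at its native size ($N = 800$) for
single-run behavior, 50-replicate batches for frontier-membership frequency,
and 20 replicates of a scaled-up trial (1000 per cell, $N = 80{,}000$) for
parameter recovery, where the per-group estimates recover the
quintile-averaged true gains to within 0.05 in the mean. These sizes keep
the full suite under a minute of estimation work while leaving Monte-Carlo
error well below the margins being checked.

## Known limitations: near-ties make exact frontier membership unstable

Two features of the case-study truth deserve emphasis because they are easy
to misread as estimation failures.

First, condition ABC lies only 0.056 outcome units above the segment joining
AB and ABCD on the true cost–gain plane, while the corresponding estimated
contrast at $N = 800$ has a standard deviation of about 0.12. Exact recovery
of the full four-member value efficiency frontier is therefore close to a
coin flip at this sample size (roughly half of the packaged 50-seed batch),
even though the estimator is unbiased with exactly its theoretical variance
and recovery at 1000 per cell is near-certain.

Second, conditions D and CD have *identical* true group-gain profiles (the
Navigator adds nothing without Peer Support), hence identical true
equitability. Whichever of the two gets the larger estimated $Q$ — a fair
coin at any sample size — claims the maximum-equitability endpoint of the
net health equity frontier, so the frontier gains a third member in about
half of replicates. No unbiased estimator can push exact two-member recovery
at $\lambda = 170$ much above one half.

The practical recommendation follows directly: treat frontier membership
from a single ORCT as an estimate, and report membership *frequencies*
across simulated replicates (as the test suite does) rather than the hull of
one dataset, especially when candidate conditions are near-equivalent by
design.

Other limitations: no inference (intervals) is provided for $H_t$ or for
frontier membership; decision rules act on posterior means, with posterior
uncertainty carried along for reporting only; a single outcome is supported
(no multi-outcome value functions); and adaptive or multilevel designs are
out of scope.
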