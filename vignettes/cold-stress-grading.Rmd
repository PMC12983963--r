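---
title: "Grading cold stress in suckling calves: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading cold stress in suckling calves: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldstress)
```

## The problem

Calves reared outdoors through a northern winter experience cold stress that
no single indicator captures well: air temperature, humidity and wind act
together with the animal's condition (body weight and frame growth) and its
behavioural thermoregulation (lying longer, breathing more slowly, urinating
more often). `coldstress` implements a multi-criteria grading system that
combines the **analytic hierarchy process** (AHP), which converts pairwise
expert judgments into indicator weights, with **fuzzy comprehensive
evaluation** (FCE), which converts indicator readings into graded memberships
over an ordered five-level severity scale — none, mild, moderate, severe,
extreme — and classifies by the maximum-membership principle.

The package also carries the satellite analyses such a study needs:
environmental indices (THI, wind-chill), rank association (Kendall's tau-b),
two-group summary tables in the animal-science single-SEM convention, and
VIP-based differential-metabolite screening on top of an in-house PLS-DA.
A seeded synthetic-cohort generator makes every stage testable end to end
without farm data.

## The AHP layer

Indicators are organised in a two-level hierarchy: three first-level factor
groups — environmental (temperature, humidity, wind), physiological (body
weight, height, diagonal length, chest circumference), behavioural (lying
time, standing time, respiratory rate, urination count) — each carrying a
pairwise **judgment matrix** on Saaty's 1–9 scale, plus one first-level
matrix comparing the groups themselves.

Judgment matrices are *reciprocal*: $a_{ii} = 1$ and $a_{ji} = 1/a_{ij}$.
`judgment_matrix()` takes only the upper triangle and completes the rest
**exactly**. This matters numerically: published tables typically display
reciprocals rounded to two decimals (0.33 for 1/3, 0.25 for 1/4), and feeding
those rounded values back into the arithmetic shifts consistency ratios by an
order of magnitude. Reciprocals are therefore always recomputed from the
upper triangle, never read from a rounded display.

Weights come from **column normalization with row averaging**: normalize each
column to sum 1, sum across columns per row, normalize the result. This is
the additive-normalization estimator classical AHP practice uses alongside
the principal eigenvector; we make it the default (the eigenvector method is
available as `principal_weights()` for cross-checking) because it is exact,
closed-form, and reproduces conventional published weight tables at the
displayed precision. For a perfectly consistent matrix both methods coincide
with the generating weight vector.

The consistency check uses the standard estimator
$\lambda_{\max} = \frac{1}{n}\sum_i \frac{(Aw)_i}{w_i}$, then
$CI = (\lambda_{\max} - n)/(n - 1)$ and $CR = CI / RI(n)$ with the tabulated
random index ($RI = 0, 0, 0.58, 0.90, 1.12, \dots$ for $n = 1 \dots 10$;
orders above 10 are rejected). Acceptance is **strict**: $CR < 0.10$ passes,
$CR = 0.10$ fails; orders 1–2 have $RI = 0$ and are defined as $CR = 0$.
Global ("total-sorting") weights multiply each indicator's local weight by
its group's first-level weight, so the eleven second-level global weights sum
to 1.

`hierarchy_model()` refuses to assemble a hierarchy containing an
inconsistent matrix unless `force = TRUE`, in which case it warns and
proceeds — real elicitation panels do occasionally produce a matrix above the
threshold (the shipped farmer-panel fixture is one), and downstream analyses
may still want its first-level weights.

## The FCE layer

For each factor group, a **membership matrix** $E$ holds one row per
indicator: its degrees of membership in the five severity levels, each row
summing to 1. Group vectors are composed as $B_g = W_g \cdot E_g$, stacked
into a relation matrix, and aggregated with the first-level weights:
$V = W \cdot (B_1; B_2; B_3)$. After normalization, the calf is assigned the
level of maximum membership.

Design choices made here:

* **Composition operator.** The default is the weighted-average operator
  $M(\cdot, +)$ — the ordinary vector–matrix product — which preserves all
  membership information and reproduces worked evaluations in the field's
  reports. The classical max–min operator $\max_i \min(w_i, e_{ik})$ is
  available behind `operator = "max_min"` for comparison but is never the
  default: it discards most of the weight structure.
* **Weight modes.** In `"global"` mode the group compositions use *global*
  indicator weights and the first-level weights are applied again at
  aggregation; the resulting vector sums to less than 1 and the final
  normalization absorbs the double weighting. This mirrors how worked
  examples in the applied AHP-FCE literature are commonly printed. In
  `"standard"` mode both stages use local (sum-1) weights, so the aggregate
  is already a probability-like vector. Both modes give identical
  classifications because the maximum-membership rule is scale-invariant;
  the package defaults to `"global"` so shipped fixtures reproduce their
  printed intermediates.
* **Tie-breaking.** An exact tie in maximum membership is resolved toward
  the *more severe* level — the welfare-conservative choice. Ties are
  measure-zero for continuous inputs but reachable with hand-built
  membership matrices.
* **Membership source precedence.** Explicit membership matrices (expert
  scoring) override membership functions. When no explicit matrices are
  given, trapezoidal membership functions evaluate the record's indicator
  values.

### Trapezoidal membership functions

`membership_spec()` builds, per indicator, five trapezoids from four
cutpoints partitioning the axis into severity bands, with a linear crossfade
of half-width `overlap` at each cutpoint. Constructed this way the five
memberships form a partition of unity — they sum to exactly 1 at every
in-domain value — so no renormalization distortion occurs. A `direction`
flag orients the axis (lower temperature is more severe; longer lying time
is more severe). `default_membership_spec()` ships a complete set of
cutpoints for all eleven indicators so the pipeline runs out of the box;
these defaults are **illustrative plumbing chosen to span plausible winter
calf ranges, not elicited expert knowledge**, and any deployment should
replace them or supply expert membership matrices.

## Environmental indices

* **THI**: the NRC-style livestock form
  $(1.8T + 32) - (0.55 - 0.0055\,RH)(1.8T - 26)$, $T$ in °C, $RH$ in
  percent. It is strictly increasing in $T$ below saturation and collapses
  to the Fahrenheit temperature at $RH = 100$.
* **WCT**: the JAG/TI wind-chill formula
  $13.12 + 0.6215T - 11.37v^{0.16} + 0.3965Tv^{0.16}$ for wind above
  4.8 km/h, and the air temperature itself in calmer air — the standard
  calm-air convention, which makes the index discontinuous at the 4.8 km/h
  boundary. Wind is in **km/h everywhere** in this package; when source
  records are ambiguous between km/h and m/s, the magnitudes of winter
  station data (8–10 in either reading) make km/h the physically coherent
  choice for calf-hutch conditions and it is adopted uniformly.
* `thi_category()` bins an index against increasing cutpoints, right-closed
  (a value equal to a cutpoint takes the lower bin), for use as an ordinal
  covariate in rank association.

## Association and group statistics

`kendall_tau_b()` is an in-house implementation of the tie-corrected
tau-b with the standard tie-corrected normal approximation for the p-value;
the test suite checks it pairwise against an $O(n^2)$ brute-force counting
oracle and against `stats::cor.test`. `two_group_table()` reports group
means, a single pooled SEM column ($s_p/\sqrt{n}$ for balanced groups),
a two-sided t-test (Student's pooled-variance by default — Welch behind a
flag — since equal-variance designs dominate this literature), and a/b
significance letters that differ exactly when $p < 0.05$.

Mixed-model (GLMM) estimation of repeated-measures effects is deliberately
out of scope: it is off-the-shelf machinery whose raw inputs a reader of a
summary table does not have, and this package only ships statistics it can
verify against independent oracles.

## PLS-DA, VIP and metabolite screening

`plsda()` fits a two-group PLS1 model by NIPALS on autoscaled features with
the centered group indicator as response. $R^2Y$ is the cumulative fraction
of response variance explained; $Q^2$ is its cross-validated counterpart
from stratified K-fold prediction (default 7 folds, refitting scaling and
model within each training fold). VIP scores follow the standard definition
$\mathrm{vip}_j = \sqrt{p \sum_a (SSY_a\, w_{aj}^2) / \sum_a SSY_a}$, which
forces the mean squared VIP to 1 — an identity the tests verify numerically,
along with agreement with `mixOmics` on scores and VIP ranking.

`screen_metabolites()` applies the three-criterion differential rule with
**inclusive** thresholds exactly as conventionally printed:
VIP $\ge 1$, fold-change ratio $\ge 1.5$ or $\le 1/1.5$, and $p \le 0.05$,
all three simultaneously; passing features are called "up" (ratio > 1) or
"down" (ratio < 1). The ratio is the treatment/control mean on the raw
abundance scale (treatment defaulting to the later sort-order label, e.g.
outdoor over indoor); the per-feature test is a two-sided Welch t-test on
log2 abundances by default, with a raw-scale option, since metabolite
abundances are approximately log-normal. `screen_calls()` exposes the bare
decision rule so published statistic triples can be re-screened directly.

The model-quality statistics of any particular LC-MS study ($R^2Y$, $Q^2$ on
real spectra) are functions of raw data this package does not ship; the
tests instead pin the screening logic, its boundary semantics, and recovery
behaviour on synthetic spike-ins.

## The synthetic cohort generator

`simulate_cohort()` emulates a 60-day two-group winter trial with 10 calves
per group:

* **Environment**: one shared outdoor daily path — a cosine descent across
  the trial from the warm to the cold end of $[-26, 1.21]$ °C plus AR(1)
  noise ($\rho = 0.7$, innovation SD 3 °C), clipped to that envelope;
  humidity around 71–75 % and wind around 8.46–9.34 km/h generated the same
  way; the indoor barn constant at 5 °C, RH 75 %, wind 0.
* **Growth**: initial weight $\mathcal{N}(35.39, 1.57^2)$ kg; piecewise
  constant ADG with a break at day 30 (indoor 0.76 → 0.71, outdoor
  0.66 → 1.22 kg/d) modulated by a per-calf log-normal frailty (SD 0.05);
  body-size trajectories linearly interpolate day-1/30/60 anchor means.
* **Behaviour**: daily lying minutes Gaussian around per-group means
  (indoor 918.68, outdoor 1027.12), with standing defined as the 1440-minute
  complement so the day always balances; respiratory rate Gaussian (44.86 vs
  34.51); urination and defecation Poisson counts (1.42/1.91 and 1.47/1.83).
  Continuous-noise SDs are reconstructed from published-style SEM columns as
  $SEM \times \sqrt{10}$, the balanced-group inversion of the pooled SEM.

`simulate_metabolome()` draws log-normal abundances (log2 baseline uniform
in [10, 20], within-group SD 0.4) and spikes a configurable number of
features with fold changes drawn log-uniformly in magnitude from the
1.5–4.86 envelope typical of reported differential metabolites, random
direction, returning the ground-truth spike list for recovery tests.

What the generator does **not** emulate — and hence what green tests do not
show about real data: no thermoregulatory feedback (behaviour does not react
to the weather path), no within-day time structure, indicators independent
given group, no missingness, no batch or instrument effects in the
metabolome, no correlation structure among features. The generator's job is
to provide data with the documented marginal structure so that pipeline
logic, determinism and recovery rates are testable — not to simulate calf
physiology.

Both generators are byte-deterministic under a fixed `seed` (the RNG state
is set locally and restored).

## Numerical conventions and degenerate inputs

* Internal arithmetic is at full double precision; the conventional
  report rounding (weights 2 dp, CR 3 dp, membership vectors 2 dp) is
  applied only at display/serialization boundaries.
* Weight-sum and row-stochasticity checks use 1e-9 tolerances; reciprocity
  after completion is exact by construction and tested to 1e-12.
* All-zero membership vectors, constant series in tau-b, single-label or
  undersized groups, out-of-domain indicator values, off-scale judgments,
  and missing record columns all raise classed errors
  (`coldstress_error_*`) naming the offending quantity.
* Test and fixture problem sizes (cohorts of 2–10 calves over 5–60 days,
  metabolomes of 10–200 features, 12–20 seed replicates for stochastic
  checks) were chosen as the smallest sizes at which the checked properties
  are stable.

## Known limitations

* The evaluation hierarchy is fixed at two levels with the standard eleven
  indicators when membership functions are used; extending the record
  schema requires supplying a matching membership specification.
* Membership-function defaults are illustrative; classifications from them
  should not be read as validated welfare grades.
* PLS-DA is PLS1 on a two-group response; multi-class discrimination and
  orthogonalized variants (OPLS-DA) are out of scope.
* The p-value of tau-b is asymptotic; for very short series an exact
  permutation test would be preferable.
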