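---
title: "Methods: Rasch calibration, diagnostics and scoring in ctclqol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Rasch calibration, diagnostics and scoring in ctclqol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical machinery in `ctclqol`: the model
family, the estimator and its numerical choices, the diagnostics, the
scoring construction, what the synthetic-data generator does and does not
emulate, and the design decisions taken where more than one defensible
option existed.

## The measurement model

A respondent rates each item on five ordered categories. We model the
keyed category score $X_{ni} \in \{0,\dots,4\}$ with an adjacent-category
Rasch model,

$$
P(X_{ni}=k) \;=\;
\frac{\exp\!\big(k(\theta_n-\delta_i)-\sum_{j\le k}\tau_{g(i),j}\big)}
     {\sum_{l=0}^{4}\exp\!\big(l(\theta_n-\delta_i)-\sum_{j\le l}\tau_{g(i),j}\big)},
$$

with person measure $\theta_n$ and item difficulty $\delta_i$ on a common
logit scale and Andrich thresholds $\tau_{g,1..4}$ shared within the
item's rating-scale group $g$. The three supported variants differ only in
the threshold-sharing map: one set for all items (RSM), one per
scale group (G-RSM; the instrument's two groups are frequency-worded and
intensity-worded items), or one per item (PCM). Raw totals are sufficient
for $\theta$ in all three, which is what makes a raw-to-measure conversion
table possible. `category_probs()`, `expected_score()` and
`item_variance()` expose the kernel directly; the same code path feeds the
estimator, the diagnostics and the simulator, and the test suite checks it
against an independently coded brute-force evaluation to 1e-10.

The two higher-rating worded items of the published instrument
("how confident…", "able to cope…") are flipped (`6 − code`) onto the
interference direction before calibration and totalling, so that higher
always means more interference. Whether the original developers reverse-
coded them before summing is not recoverable from the published scoring
table; the flag is per-item configurable.

## Estimation

`rasch_fit()` maximizes the joint (unconditional) likelihood over persons,
items and thresholds — the estimation paradigm of the Winsteps family this
instrument was developed with — by cycling Newton steps:

* $\theta_n$: one step on $r_n-\sum_i E_{ni}$ over the person's observed
  cells, with curvature $\sum_i V_{ni}$;
* $\delta_i$: one step on $\sum_n E_{ni}-t_i$;
* $\tau_g$: a full 4×4 Newton step from the gradient
  $\sum(Q_j - \mathbf 1\{x\ge j\})$ and the covariance matrix of the
  cumulative-category indicators, with a small ridge.

Steps are clipped at 1 logit for stability. Identification — mean item
difficulty 0, thresholds summing to 0 within each group — is applied every
cycle as a likelihood-preserving reparameterization (threshold recentering
is compensated through the group's difficulties, difficulty recentering
through the person measures). Convergence is declared when the largest
absolute parameter change in a cycle falls below `tol = 1e-4` logits;
after `max_iter = 200` cycles the result is returned flagged
`converged = FALSE` rather than raising an error. Standard errors are
inverse square roots of the corresponding observed information.

Cells coded 0 ("Does not apply") or left blank are simply skipped: the
likelihood runs over observed cells only. The 0 re-enters only in raw
scoring, where it counts as zero points — both published conventions are
kept, each in its own stage. Persons or items whose observed responses are
all-minimum or all-maximum carry no information about their own location;
they are excluded from calibration and afterwards assigned measures by
solving the expected-score equation at their raw score nudged
`extreme_adjust = 0.3` score points inward (the conventional adjustment in
this software lineage; configurable). A rating-scale group that never
observes a category has it collapsed into its neighbour with a warning,
since its threshold is inestimable; diagnostics always reuse the fit's
collapse map rather than re-deriving it from whatever data they are given.

Two caveats are inherent to JMLE and documented rather than hidden. First,
estimates for a fixed number of items are not consistent as persons
accumulate; in practice this shows as a mild outward spread of estimated
thresholds (visible in the parameter-recovery tests, and within their
stated error budgets). Second, the G-RSM-vs-RSM likelihood-ratio statistic
computed from JMLE fits is only approximately chi-square with
$(G-1)(K-2)=3$ degrees of freedom; the package implements the test as
defined and the acceptance suite verifies empirically that its null
rejection rate at $\alpha=.05$ stays in a calibrated band.

## Diagnostics

**Item fit.** Standardized residuals are
$z_{ni}=(x_{ni}-E_{ni})/\sqrt{V_{ni}}$. Outfit is the unweighted mean of
$z^2$, infit the variance-weighted version $\sum V z^2/\sum V$; both are
computed per item and per person. `purge_items()` iterates: fit, flag
items with infit or outfit above the cutoff (default 1.33, the
conventional mean-square bound), remove the single worst offender, refit.
One-at-a-time removal and the tie-breaks (largest outfit, then largest
infit, then lowest item position) are this package's choices — the
original procedure is described only as "iterative" — made so removal
order is deterministic and each removal's effect on the remaining items is
re-assessed. The purge aborts rather than going below 3 items.

**Dimensionality.** `pca_first_contrast()` performs an unrotated PCA of
the item-by-item correlation matrix of standardized residuals, imputing
missing residuals as 0 (the convention of the procedure this follows). A
first eigenvalue near 2 or more suggests a second dimension. The variance
explained by the Rasch measures is reported as model sum of squares over
model-plus-residual sum of squares, as a percentage.

**Rating scale.** `thresholds_ordered()` checks strict ordering of each
group's thresholds; `category_curves()` returns category probabilities on
a $\theta-\delta$ grid (adjacent curves cross exactly at the thresholds).
`test_information()` sums item score variances; its inverse square root is
the conditional standard error of measurement. `person_item_map()` returns
both distributions on the common logit ruler plus a targeting summary
(mean person-item offset and the proportions of persons outside the item
range).

**DIF.** `dif()` uses an anchored separate-calibration contrast: person
measures and thresholds are held at their pooled estimates and each item's
difficulty is re-estimated within each group; the contrast in logits is
tested with a two-sample t statistic (joint SE, Welch-type df). An item is
flagged when $|{\rm contrast}|>1.0$ logit **and** $p<.05$ — exactly the
published decision rule, which is what motivated choosing this method over
Mantel–Haenszel (only the anchored-contrast approach yields the rule's
logit metric directly). A numeric covariate such as age is dichotomized at
the sample median (cut configurable); the grouping needs at least 20
persons per group by default.

**Reliability and validity.** Separation reliability is
$(\mathrm{var}-\overline{SE^2})/\mathrm{var}$, clamped to $[0,1]$, applied
to person measures or item difficulties. Test-retest is a Pearson
correlation of total scores over complete pairs (totals and scaled scores
are monotonically related for complete data, so the choice is immaterial).
For convergent vs discriminant validity the two correlations share the
instrument score, so the difference is tested with Steiger's z for
dependent correlations (documented and swappable); disease stage enters as
ordinal integers (IA = 1, IB = 2, II+ = 3), the simplest coding consistent
with a Pearson framing.

## Scoring

`build_score_table()` inverts the expected-total-score function by
bisection for every attainable raw total (extremes nudged 0.3 inward so
the end rows stay finite), then standardizes measures on the calibration
sample to mean 100 and SD 15 and rounds half-up (the published table is
integer-valued; its rounding rule is unstated). By construction the
calibration sample's unrounded scaled scores have exactly mean 100 and
SD 15. The published 12-item conversion and interpretation tables are
embedded verbatim and used by `published_score()`; raw totals of 10 or 11
(reachable only through "Does not apply") score as 12, and scaled values
falling in the gaps between bands (90, 134, …) are rejected by
`categorize()` rather than guessed, because no raw total produces them.
How the original table's non-uniform extreme spacing was computed is not
documented; only the embedded table is authoritative for published
scoring, while `build_score_table()` is for new calibrations.

The composition of the final 12-item instrument (which 2 of the 14 bank
items were dropped) and the identity of the 4 bank items carrying the
"Does not apply" option were never published. The shipped default takes
bank items 1–12 as active and places the option on the two most
symptom-contingent active items (7 and 10) plus items 13 and 14 — a
documented stand-in, configurable via `published_instrument(active =)`.

## The synthetic-data generator

`simulate_responses()` draws every cell from the same G-RSM kernel the
estimator uses, at user-specified true $\theta$, $\delta$, $\tau$; a
study-mimicking preset (`study_preset()`) reproduces the development
study's structure: n = 126, 12 items in two rating-scale groups (5
frequency, 7 intensity), two "Does not apply" items, a 52.4% retest
subsample, and binary gender plus age and race covariates. The latent
trait is standard normal by default — the study never reported its trait
distribution, so this is an assumption, stated here and configurable.
Off-model features needed to exercise the pipeline are explicit:
misfitting items respond uniformly at random (maximally off-model, which
guarantees elevated outfit and makes purge tests sharp); DIF shifts one
item's difficulty by half the contrast in opposite directions per group;
"Does not apply" arrives as an independent coin flip per DNA-capable cell;
retest administrations share item parameters with latent correlation
`retest_rho` (a Gaussian copula, so the observed total-score correlation
is attenuated below the latent value). All randomness derives from one
root seed through per-purpose substreams, so switching one feature on
never perturbs another's draws.

What the generator does **not** emulate: real response styles (central
tendency, acquiescence), local dependence between items, the development
sample's demographic composition, missingness beyond "Does not apply",
and any drift of item functioning between administrations. Passing tests
therefore demonstrate that the algorithms are correct and well-calibrated
under the stated model, not that the published instrument's sample-
dependent statistics (person reliability .87, test-retest .89, and so on)
are recovered from data this generator produces — the original N = 126
dataset is not publicly deposited, so those quantities are covered by
property-based checks instead of replay.

## Problem sizes and tolerances in the test suite

Simulation-based checks use sizes chosen to make their Monte-Carlo error
small relative to the property being asserted while keeping the default
suite quick: parameter recovery and item-fit nulls at n = 1000,
purge fixtures at n = 400, the LRT null calibration over 500 replicates at
n = 300, DIF type-I and power over 200 replicates at n = 300–600, and
score-table stability at n = 1000. Oracle comparisons (probability kernel,
information, residuals, fit statistics on a hand-computed micro grid) are
asserted at 1e-10; identification constraints at 1e-6.

## Known limitations

* JMLE estimates are biased for a fixed test length; no bias correction is
  applied, matching the software lineage the instrument came from.
* The LRT's chi-square reference is approximate under JMLE (checked
  empirically, not derived).
* The person-measure scale is only identified up to the model's
  conventions; comparisons across separately calibrated samples require
  anchoring, which the package supports only through the DIF machinery's
  pooled-anchor pattern.
* `published_score()` is exact for the published tables, but the default
  item composition of `published_instrument()` is a documented stand-in
  (see above).
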