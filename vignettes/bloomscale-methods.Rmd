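---
title: "Models and methods in bloomscale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in bloomscale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloomscale)
```

bloomscale estimates whole-tree floral resources by chaining four pieces:
a branch-level hurdle model of flower counts, a geometric upscaling over
cylinder tree models (QSMs), tree-level allometries, and resource budgets
with propagated uncertainty. This vignette explains each model, the
parameters that matter, the numerical choices made where more than one
defensible option existed, and what the synthetic-data tests do and do not
demonstrate.

## The branch-level hurdle model

Flower counts on cut branches have two awkward features: many branches carry
no flowers at all, and the positive counts are strongly overdispersed. A
two-part hurdle model addresses both. The occurrence part is a binomial GLMM
on the logit scale; the abundance part is a zero-truncated negative binomial
(ZTNB, NB2 parameterisation) GLMM with log link, fitted to the flowering
branches only. Both share the covariates log branch diameter `ln D` (mm),
stem diameter `dbh` (cm), crown layer (`out` reference) and crown stratum
(`bot` reference) with a layer × stratum interaction; the abundance part
adds `ln D : dbh`, which lets the diameter effect steepen on larger trees.
A random intercept for the cut-off branch nested in the tree absorbs
remaining within-branch similarity.

Two conventions deserve emphasis:

* **The abundance linear predictor is `ln mu` of the *untruncated* NB.**
  This is how truncated-NB2 software parameterises the model, so published
  coefficient tables drop in directly. The reported conditional expectation
  applies the truncation: `mu / (1 - (theta/(theta+mu))^theta)`, which is
  always at least `max(mu, 1)`.
* **Marginal prediction for new branches sets random intercepts to zero.**
  Upscaling applies the model to branches of trees that were never part of
  the fitting data, where no random-effect estimate exists.

Fitting is maximum likelihood with the Laplace approximation (glmmTMB, the
standard engine for this model family). With `random_effects = FALSE` the
parts reduce to ordinary logistic and ZTNB regressions; this deterministic
route is what the parameter-recovery simulations use. Boundary fits — a
random-effect variance collapsing to zero, which optimisers report as
"singular convergence" — keep usable estimates, so the fitter warns rather
than fails; it fails only when estimates are genuinely non-finite. With a
single tree the tree-level random intercept is unidentifiable and is dropped
from the random term with a warning.

Model selection is by manual stepwise reduction using
`likelihood_ratio_test()` (terms retained when dropping them worsens the fit
at p < 0.05); `fit_flower_hurdle()` accepts formula overrides for that
purpose, and hard-codes the selected wild-cherry formulas as defaults.
Crown-position effects are summarised by estimated marginal means over a
balanced reference grid with continuous covariates at their means
(emmeans), with Tukey-adjusted pairwise comparisons. A balanced grid was
chosen over observed-frequency weighting because the crown sections are
design cells of roughly equal interest, not population strata.

Fit quality is reported as marginal/conditional Nakagawa-style R² (the
distribution-specific variance is `pi^2/3` for the logit part and the
delta-method form `1/lambda + 1/theta` for the log-link NB part, with
`lambda` evaluated at the mean linear predictor plus half the total
variance), MAE and RMSE, and leave-one-out cross-validation. The CV unit is
the cut-off branch — the random-effect group — and held-out predictions use
fixed effects only, so the CV score measures exactly the marginal
predictions that upscaling relies on.

## Subsampling the branch hierarchy

Because every subbranch of a measured branch is itself a record, naive
fitting would pseudo-replicate: a branch's total contains its descendants'
totals. The package therefore subsamples before fitting. Each branch is a
point in a six-dimensional space (log diameter, layer, stratum, compass,
tree identity, dbh); categorical variables are coded along their natural
orderings (bot/mid/top → 0/1/2, in/out → 0/1, the eight compass directions →
0..7, tree id → dense index) and every dimension is z-standardised so no
variable dominates. Selection starts from the largest-diameter branch and
repeatedly takes the candidate with the greatest minimum distance to the
already-selected set — farthest-point sampling against the set, which serves
the balance goal better than chaining from only the previous pick. Each
selection removes the pick's ancestors and descendants from the pool, and
selection runs until the pool is empty, so the result is maximal. Ties (in
diameter or distance) go to the lexicographically smallest branch id, making
the procedure deterministic and order-independent — a property the tests
check by permuting input rows.

## From cylinders to branch units and crown sections

A QSM is a rooted tree of cylinders. Flowers sit on fine branches, and QSM
radii below about 3 cm are unreliable, so upscaling works on *branch
units*: walking from the root, the first cylinder on any path whose
diameter drops to ≤ 30 mm opens a unit consisting of that cylinder and its
whole subtree; claimed cylinders are never claimed twice, so units
partition the eligible cylinders. The unit's diameter for prediction is its
root cylinder's diameter in mm.

Each unit is placed in the crown by its bounding-box centre:

* **Stratum** — the crown length (crown base to tree top) is split into
  equal thirds with half-open boundaries; centres below the crown base fall
  into `bot`. The crown base is the base height of the lowest branch
  cylinder (configurable only through the cylinder table itself; synthetic
  trees put all non-trunk cylinders in the crown).
* **Layer** — the crown is sliced into 0.5 m horizontal cross sections; the
  convex hull of the crown points in the centre's slice is eroded *inward*
  by 2 m (the outer layer being defined from the crown surface inward), and
  centres inside the eroded hull are `in`, all others `out`. For a convex
  hull the erosion test is exact: a point lies in the eroded polygon iff
  its signed distance to every edge's supporting line is at least the
  depth. Degenerate slices (fewer than three distinct points, or hulls
  thinner than twice the depth) classify as `out` — with a 2 m shell on
  each side, a sliver of crown has no interior. Points exactly on a slice
  boundary belong to the upper slice.

Tree metrics come from the same geometry: dbh from the trunk cylinder
spanning 1.3 m above the base; height from the vertical extent; crown
projection area from the 2D hull of crown cylinder endpoints; crown
diameter as the mean horizontal extent over eight azimuthal directions
(max-extent available as an option). Crown volume is computed by slicing
the crown into the same 0.5 m sections, taking each slice's 2D hull area,
and summing area × height — a *sliced convex-hull volume*. For convex
crowns this converges to the convex-hull volume (the package's cuboid
oracle test recovers 80 m³ exactly), while still following vertical
concavity of the crown profile the way an alpha shape would; it was chosen
over a true 3D alpha shape as a transparent, dependency-free estimator
whose behaviour is easy to reason about and test. Slice membership uses
cylinder start/end points.

## Upscaling and aggregation

For every branch unit, the occurrence part gives a probability (random
intercepts at zero); a Bernoulli draw decides whether the unit flowers.
Flowering units contribute the ZTNB *expected* count by default — occurrence
is the only explicitly randomised stage, which keeps the replicate-to-
replicate variance attributable to occurrence and geometry; full ZTNB count
sampling is available behind a flag. Expected counts are kept fractional
rather than rounded; rounding would add nothing but discretisation noise at
tree scale. Unit contributions sum to a per-QSM total, and the tree's
estimate is the *median* total across its replicate QSMs (even counts
average the central pair), which is robust to occasional reconstruction
outliers. Each replicate draws from its own random stream derived from the
master seed and the replicate's position, so runs are reproducible while
replicates stay independent. Forcing occurrence to one yields a fully
deterministic total equal to the analytic sum of ZTNB means — the oracle
the tests compare against to machine precision.

Hurdle-coefficient uncertainty is deliberately *not* propagated into
per-tree totals; uncertainty enters once, at the resource stage, which
keeps the two variance sources from being double counted.

## Tree-level allometries

Candidate predictors (dbh, height, crown diameter, crown projection area,
crown volume) are screened by Pearson correlation with the per-tree totals;
predictor pairs with |r| > 0.7 are flagged collinear, which is why single-
predictor models are fitted rather than a joint one. The allometry itself is
a negative-binomial GLM with log link, `ln FN = b0 + b1 x`, fitted by
`MASS::glm.nb` with a freely estimated intercept (very young trees flower
differently, so forcing the origin would be wrong on substance). Totals from
upscaling are continuous; they are rounded to the nearest integer for the
count likelihood, and the rounding is part of the documented contract.
Predictions outside the calibration range warn rather than error — the
exponential form extrapolates smoothly, but the warning marks where data
support ends. The log-link form gives the fold-change identity used for
scenario comparisons: increasing a 10 cm tree's dbh by x % multiplies
predicted flowers by `exp(slope · 10 · x / 100)`.

## Resource budgets and uncertainty

Per-flower constants convert flower totals to resources: spherical pollen
grains (volume `(pi/6) d³` at d = 32.63 µm, 16,059 grains per flower ≈ 0.29
mm³ of pollen per flower), 3.7 mg nectar per flower per 24 h, 23.5 % sugar.
Bee larvae are pollen volume divided by a per-larva requirement, rounded to
the nearest larva. The shipped requirements (≈ 10.98 mm³ for *Lasioglossum
laticeps*, ≈ 61.6 mm³ for *Bombus terrestris*) are back-solved reference
values, clearly labelled as such; species with measured requirements should
override them.

Confidence intervals combine bootstrap and Monte Carlo: each of B = 1000
repetitions resamples trees with replacement, refits the dbh allometry, and
draws the four per-flower constants from normal distributions — measured
SEs as SDs for the pollen quantities, and range width / 4 for the two
literature ranges, treating a published range as an approximate 95 %
interval. Normal draws can go negative; they are floored at 1 % of the mean,
a pragmatic guard that keeps physically impossible values out without
distorting the bulk of the distribution. CIs are the 2.5 %/97.5 %
percentiles of the B predictions; larvae CIs transform the same pollen
predictions per species rather than re-resampling, so all quantities share
one coherent uncertainty. Failed refits are dropped (more than 10 %
failures aborts).

## The synthetic-data generator

The generator exists so every stage is testable with known truth. Its
defaults mirror the study conditions the package targets: 39 trees spanning
9–28 cm dbh, 30 replicate QSMs per tree, a branch campaign of 16 trees with
several cut-off branches each and subbranch hierarchies (hundreds of
branches before subsampling), flower counts drawn from the wild-cherry
hurdle coefficients with nested normal random intercepts, flower attachment
restricted to shoot segments under 20 mm diameter, and cylinder trees with
monotone taper down to a 3 mm minimum diameter. Where no published value
exists, the generator makes a fixed choice: ZTNB dispersion θ = 1.5 and
random-intercept SDs of 0.3 (plausible for moderately overdispersed counts
with modest tree-to-tree heterogeneity), heights of `3 + 0.55·dbh` m and
crown bases at 45 % of height (placing synthetic trees inside the observed
height range), and 5 % multiplicative reconstruction noise for replicates
(radius jitter per cylinder plus one global scale per replicate, preserving
connectivity).

Synthetic geometry is plumbing, not biology: crowns have no phyllotaxis,
no pruning history, no competition asymmetry, and their cylinder counts
(a few hundred) are well below real QSMs (thousands). Passing tests
therefore demonstrate that the *algorithms* are correct — counts cumulate,
sampling respects the hierarchy, geometry classifies as specified, fitting
recovers generating parameters, upscaling matches its analytic oracle —
not that the shipped coefficients transfer to any particular orchard.

## Simulation sizes and numerical choices

The recovery simulations use sizes where asymptotic inference is reliable
but runs stay quick: 50 replicates of 400 branches (diameters log-uniform
on 2–25 mm, the range where occurrence is informative) for the hurdle
parts, and 100 replicates of 39 trees for the tree-level slope, each
requiring estimates within two standard errors of truth at least 90 % of
the time. With extreme covariates the occurrence part can separate
(a factor cell with no zeros); estimates then diverge with commensurately
huge SEs, which Wald coverage absorbs, but significance tests in that
regime are meaningless — the marginal-means tests use designs with zeros
in every cell. Other fixed choices: half-open intervals everywhere a value
can sit on a boundary (diameter classes, strata, slices) so nothing is
counted twice; lexicographic tie-breaks in the subsampler; ZTNB draws by
inverse CDF restricted above the zero mass; and the ZTNB mean's closed
form rather than summation, with the summation kept as an independent
test oracle.

## Known limitations

* The crown-volume estimator is not a true alpha shape; strongly
  non-convex slice geometry (split crowns) inflates it toward the slice
  hull.
* The layer classifier's erosion test is exact only for convex slice
  outlines — which the convex hull guarantees, but a concave crown's
  true surface may differ.
* LOOCV refits a GLMM per held-out group; on large fits this is the
  pipeline's slowest step.
* The shipped bee-larva requirements are derived, not measured.
* Upscaled totals inherit any bias in the QSM radii; the package mitigates
  (3 cm unit threshold) but cannot remove it.
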