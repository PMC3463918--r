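---
title: "Morphometry and constructive generation of hepatic vascular trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometry and constructive generation of hepatic vascular trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasctree)
```

## The problem

The liver is supplied and drained by tree-shaped vascular systems (portal
vein, hepatic artery, hepatic vein).  In vivo CT resolves these trees only
down to a few hundred micrometres, far above the lobular scale at which
blood actually perfuses tissue, so blood-flow models need *algorithmically
generated* fine detail grafted onto the measured coarse anatomy.  That
raises two questions this package answers:

1. **How similar are two vascular trees, or two populations of trees, in
   quantitative geometric terms?**  (Needed both to describe inter-patient
   variability and to judge generated trees.)
2. **How can a measured tree be extended with realistic detail?**

## Data model and graph correction

A vascular tree is a strictly bifurcative rooted geometric tree: nodes
carry 3-D positions (mm), edges carry radii (mm) and are straight
cylinders; lengths are always derived from the endpoint positions.  Exactly
one edge is incident to the root node and every edge has zero or two
daughters.

Skeletons extracted from images violate this freely.  `correct_graph()`
repairs, in a fixed order: self-loop edges are dropped; parallel parent
edges are merged preserving total cross-section area
(\(r = \sqrt{\sum r_i^2}\)); of several parent edges with distinct initial
nodes only the one of maximal radius survives; monofurcations are merged
with the arithmetic mean of the two radii (radius estimates are noisy at
the voxel scale, so this is comparable to skeletonization error);
multifurcations are split into chains of bifurcations connected by
zero-length *trivial* edges, which leaves the geometry untouched; isolated
nodes are dropped; root nodes get a trivial trunk edge if they carry two
daughters.  Proper loops (directed cycles) are not repairable and raise an
error.  Every repair is logged, and `replay_corrections()` reproduces the
corrected tree mechanically from the log — a useful audit when the
correction of a large clinical skeleton needs to be reviewed.

Where several root components exist, the component with the most edges is
returned (ties: smallest root id).  Trivial edges inserted by the
multifurcation split carry the radius of the incoming parent edge; the
synthetic trunk of a two-daughter root carries the area-preserving
\(\sqrt{\sum r_i^2}\), consistent with the parallel-merge rule.

## Strahler* orders

Strahler (stream) order is 1 on leaf edges; a parent takes the larger
daughter order, or the common order plus one on ties.  Because trees
resolved to different levels of detail have different root orders, all
analyses use the root-normalised **Strahler\*** order, root order minus
edge order, so the root edge is 0 everywhere and edges of equal Strahler\*
order play the same role relative to the root.  `order_census()` and
`connectivity_histogram()` summarise populations; for the histogram both
mean per-tree pair counts and percent-of-all-pairs are reported, since
either normalisation is in use in the morphometry literature.

## Geometric features

`feature_table()` computes per edge: radius \(r\), length \(l\), decrease
ratios \(\eta_r = r_\text{parent}/r\), \(\eta_l\), asymmetry ratios
\(\sigma_r, \sigma_l \ge 1\) (larger/smaller daughter), the bifurcation
exponent \(\gamma\) solving \(r_1^\gamma + r_2^\gamma = r_p^\gamma\)
(Murray's law is \(\gamma = 3\)), and the three bifurcation angles: the
daughter angle \(\varphi_a\), the inclination \(\varphi_b\) of the parent
to the daughter plane, and the in-plane angle \(\varphi_c\) between the
parent's projection and the daughter bisector.  Exponent and angles are
attached to the parent edge of the bifurcation, including the bifurcation
below the root edge.  Any feature that cannot be computed (root edge for
\(\eta\), terminal edges for \(\sigma\)/\(\gamma\)/angles, zero lengths or
radii, no positive root for \(\gamma\)) is `NA` and excluded from every
downstream statistic, so different features rest on different bifurcation
counts.  \(\gamma\) is sought in \([10^{-3}, 50]\) by bisection to
\(10^{-10}\); measured hepatic distributions lie well inside that
bracket.  \(\varphi_b\) is reported unsigned in \([0°, 90°]\); which side
of the daughter plane the parent leans to is not a feature.

The angle convention makes a straight pass-through yield
\(\varphi_c = 0\): the parent direction is taken *into* the bifurcation
(flow direction).

## Similarity framework

Similarity is quantified in six steps: (1) Strahler\* orders and features
per edge; (2) empirical CDFs per feature and order per tree; (3) a binary
similarity decision per tree pair, feature and order from the two-sample
Kolmogorov–Smirnov test at significance \(P\) (default 0.05, purely
conventional), giving a ratio of non-rejected pairs among all pairs;
(4) a weighted average over orders; (5) weighted averages for the radius,
length and angle feature groups; (6) a weighted total.

Two modes exist.  In the *single-population* mode, all distinct pairs
within one population are compared and averages over features are
arithmetic.  In the *two-population* mode (e.g. measured vs generated),
the full cross product is tested and per-feature values are weighted by
the feature's single-population similarity among the *measured* trees, so
that agreement is demanded most where measured anatomy is most invariant
("similarity where it is expected").  The two totals are computed by
different formulas and must not be compared with each other.

Order averaging runs over orders where at least half of the trees (both
populations in two-population mode) still have edges; weights are the
per-order tree counts, geometric means of the two counts in two-population
mode.  Orders with no valid pair are skipped with their weight.  Pairs in
which either tree has no defined value of the feature at the order are
excluded from numerator and denominator.  Group weights are the summed
measured per-feature similarities divided by the group size; with
undefined features the group size is the count of defined ones.

Because the decision is a statistical test at level \(P\), even identical
populations of i.i.d. trees cannot score above \(1 - P\) in expectation;
the acceptance suite checks that i.i.d. synthetic populations land in
\([0.85, 1]\).

### KS test implementation

The statistic \(D\) is the sup-distance of the two empirical CDFs on the
merged support in double precision; the asymptotic p-value evaluates the
limiting Kolmogorov distribution at \(D\sqrt{n_0 n_1/(n_0+n_1)}\).  The
limiting CDF uses the alternating exponential series for arguments
\(\ge 1\) and the Jacobi-theta form below 1, where the alternating series
cancels catastrophically; both are truncated at terms below \(10^{-16}\).

The asymptotic form overestimates p for small samples, so for
\(n_0 + n_1 \le 25\) (configurable) the p-value comes from the exact
permutation distribution of \(D\) over all \(\binom{n_0+n_1}{n_0}\) splits
of the pooled sample.  It is computed by tie-aware lattice-path counting
in \(O(n_0 n_1)\) per test — mathematically identical to exhaustive
enumeration (the test suite cross-checks against an explicit
`combn()` enumeration) but fast enough for the thousands of small-sample
tests inside a similarity report.

One caveat worth knowing: with equal sample sizes \(n\) the statistic
lives on a lattice of multiples of \(1/n\), so the test's exact size at
nominal \(P = 0.05\) can sit visibly below 0.05 (for \(n_0 = n_1 = 20\)
it is 0.0335 — the nearest attainable rejection regions have probability
0.0335 and 0.081).  Calibration checks of rejection *rates* should be read
against that discrete size, not against the nominal level.

## Constructive generation (CCO)

Trees are generated by Constrained Constructive Optimization: leaves are
added one at a time, each time committing the locally optimal new
bifurcation.  The cost is
\[
F(T) = \sum_e l(e)\, r(e)^\lambda \;+\; C \sum_n \mathrm{dist}^2(n,\ \text{organ}),
\]
with \(\lambda = 2\) (the first term is then proportional to intravascular
volume) and \(C = 42\ \mathrm{mm}^{\lambda-1}\) when lengths are in mm.
The penalty term handles nonconvex organs: bifurcations may wander outside
the domain but pay the squared distance.  It is node-based and ignores the
cylinder radius, adequate because the straight cylinders are themselves
only approximations of curved vessels.

**Physiology constraints.**  Every leaf receives equal flow; at each
bifurcation daughter radius fractions obey
\(\beta_1^\gamma + \beta_2^\gamma = 1\) with \(\gamma = 3\) fixed; radii
are balanced so the Hagen–Poiseuille pressure drop from root to every
leaf is equal.  `rebalance_radii()` solves this with one post-order sweep
(reduced subtree resistances and \(\beta\)-fractions) plus one root-to-leaf
propagation — exact in closed form under constant viscosity.  With the
radius-dependent apparent viscosity
\(\mu(r) = \mu_\infty(1+\delta/r)^2\) (\(\mu_\infty = 4\) cP,
\(\delta = 4.29\) µm, valid below 140 µm, linearly blended to
\(\mu_\infty\) over 140–160 µm, clamped below 4 µm) the sweep pair is
iterated to a fixed point (relative radius change \(< 10^{-10}\), at most
200 sweeps), since subtree resistances can no longer be cached relative to
an unknown absolute radius.  The absolute scale comes either from a fixed
root radius (the natural choice when extending a measured tree) or from a
prescribed pressure drop and total flow (defaults 533 Pa ≈ 4 mmHg and
1.17·10⁻⁵ m³/s ≈ 700 mL/min, resting portal values).

**Candidate search.**  For each new leaf the 40 edges with nearest
midpoints are tried (trivial edges cannot be split); each temporary
bifurcation starts at the target edge's midpoint and is optimized by
gradient descent with central-difference gradients and Armijo
backtracking, *rebalancing all radii at every cost evaluation* — skipping
that produces substantially different trees.  Candidates are first
optimized at a rough tolerance (the square root of the final tolerance,
default 10⁻³ mm), the best 20 are re-optimized fully, and the cheapest
connection is committed.  Gradient steps are normalised; the
finite-difference step is \(\max(10^{-4} l_\text{loc}, 10^{-6}\,
\mathrm{mm})\), backtracking halves the step with slope parameter
\(10^{-4}\), and descent stops when the accepted step falls below the
tolerance or after 200 iterations.  These optimizer constants are
implementation choices; the structure of the search (40 candidates, 20
shortlisted, rough = √final) follows the established scheme.  Adding one
leaf to an \(n\)-node tree costs \(O(n)\) per cost evaluation here (no
caching), which at the tree sizes used throughout (tens to a few hundred
leaves) is entirely dominated by the optimizer's bounded number of
evaluations.

## Calibration pipeline

To compare generated against measured-style trees under equal conditions,
`calibration_run()` mimics the acquisition process: the seed tree is
pruned to coarse anatomy (keep the root and, recursively, daughters whose
initial node lies outside the organ or whose radius exceeds 0.25 of the
tree maximum — measured trees enter the organ from outside); leaf targets
are sampled uniformly inside the organ with a minimal pairwise distance;
*1/0.27 times* the desired leaf count is generated because afterwards one
full bifurcation level (all leaf edges) is pruned again — clinical CT
misses at least the finest level, and the 0.27 factor compensates the
pruning; edges shorter than 0.1 mm are contracted to trivial edges to
avoid numerical artifacts in the feature ratios; optionally the angle
postprocessing below is applied; finally the generated population is
scored against a reference population with the two-population similarity.

The defaults here are desk-scale — leaf counts 30–80 and 3 repetitions per
seed tree — so that a full calibration fits in minutes on one core; the
full-scale study settings (150–350 leaves, 12 repetitions) are plain
configuration values.  `lambda_sweep()` repeats the pipeline over a grid
of cost exponents \(\lambda\) and tabulates group and total similarities.

## Angle postprocessing ("improved" generation)

Volume-optimal bifurcations are too narrow and too flat compared to
measured hepatic bifurcations: daughter angles \(\varphi_a\) cluster near
the symmetric Murray optimum (≈ 75°) and inclinations \(\varphi_b\) near
0°.  Two surgical steps repair this without touching radii:

* `bisector_shift()` moves every bifurcation point along the unit bisector
  of its daughter directions (towards the daughters) by 9 % of the mean
  daughter length, which widens \(\varphi_a\); the 9 % value is the
  calibration that matches generated mean daughter angles to measured
  ones.  Displacements are computed from the input geometry and applied
  simultaneously; radii are deliberately *not* rebalanced afterwards
  (rebalancing after the shift lowers similarity further).
* `nonflatness_adjust()` samples, for every bifurcation, a target
  *nonflatness* — distance of the bifurcation point from the triangle
  spanned by the parent's initial node and the daughters' endpoints,
  relative to the triangle's longest side — from an empirical distribution
  and moves the point along the triangle normal until the target is met
  exactly.  The sampling is uniform over the tree, not per Strahler\*
  order.  Because neighbouring bifurcation points sit in each other's
  triangles, the assignment is iterated (Gauss–Seidel sweeps, up to 1000,
  until the largest move falls below 10⁻¹² mm); deep trees can need a few
  hundred sweeps.  Where a target is smaller than the residual in-plane
  distance of the point from its triangle, the smallest move achieving the
  target is used instead of a purely normal one; on generated and
  synthetic trees this fallback is virtually never needed.

The packaged default nonflatness distribution is **synthetic** (half-normal
with scale 0.05) and labelled as such; measured distributions are supplied
as a one-column CSV via `read_nonflatness_csv()`.

A known limitation: on freshly generated trees the bisector shift slightly
*increases* intravascular volume (a fraction of a percent across seeds in
the test suite).  This is geometrically forced — committed bifurcation
positions minimise the volume-like cost, so no fixed-radius perturbation
can reduce it to first order — and is why no volume-reduction property is
asserted here.

## Synthetic populations

`make_population()` stands in for clinical cohorts, which are not public.
Topologies are grown by uniform random leaf splitting to a leaf count
uniform in a range (default 150–350, matching the measured trees' range);
geometry is then assigned per edge from Strahler\*-order-dependent
distributions: lengths and radii decay geometrically per order with
log-normal noise, and bifurcation angles are drawn independently
(truncated normal \(\varphi_a\), half-normal \(\varphi_b, \varphi_c\))
and realised *exactly* by construction of the daughter directions.
Defaults (root radius 4 mm, radius decay 0.6/order with 0.25 log-noise,
length scale 30 mm, decay 0.55/order with 0.4 log-noise,
\(\varphi_a \sim N(100°, 25°)\), \(\varphi_b, \varphi_c\) half-normal with
scales 20°/25°) were chosen once as plausible coarse-hepatic magnitudes:
portal trunk radii of a few mm, daughter angles near or above a right
angle, mild inclinations.

Because every feature at a given order is i.i.d. across trees, two
populations from the same spec differ only by sampling noise — which is
exactly what the similarity framework's null calibration needs.  What the
generator does *not* emulate: spatial embedding in an organ (trees may
self-intersect), radius–flow consistency (\(\gamma\) scatters around
nothing in particular rather than around 3), curved vessels, and
inter-feature correlations.  Tests passing on these populations therefore
validate the *statistical machinery*, not anatomical realism of the
fixtures.

## Numerical choices, degenerate inputs

* Lengths are always derived from positions; trivial edges are flagged and
  excluded from ratio/angle features rather than producing infinities.
* \(\gamma\) undefined when the parent radius does not exceed the larger
  daughter radius (no positive root) — frequent in noisy measured radii.
* Ties in candidate ordering and parallel-parent merges break by edge id;
  node repairs visit ascending ids, making correction deterministic.
* The optimizer perturbs degenerate starts (coincident points) by 10⁻⁶ mm.
* Analytic domain distances are exact for spheres and boxes; ellipsoids
  solve the exterior closest-point problem by bisection to ~10⁻¹⁴ and use
  a smooth standard approximation inside; CSG combinations use min/max
  signed-distance estimates with exact zero sets (the penalty only needs
  correct interiors and a continuous exterior distance).  Voxel domains
  carry an exact Euclidean distance transform, trilinearly interpolated.
* Leaf-target sampling is plain seeded rejection sampling with an explicit
  infeasibility error after \(10^4 n\) draws.

## Problem sizes in the test suite

The suite validates orders and correction on hundreds of seeded random
trees (≤ 127 edges), the KS null on 2000 sample pairs, generation physics
on a 50-leaf sphere tree, the optimizer against a 41³ grid search on a
3-edge toy, and the standard-vs-postprocessed comparison on three
desk-scale pipeline runs (about 30–40 final leaves each) against a 6-tree
synthetic reference.  These sizes were chosen so that the full suite runs
in minutes on a single core while each check retains the statistical power
it needs; every threshold above is stated where the corresponding test
asserts it.

## Session

```{r session, eval = FALSE}
sessionInfo()
```
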