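---
title: "Functional connectome topology for presbycusis cohorts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional connectome topology for presbycusis cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(presbynet)
```

# Scope

`presbynet` implements a complete resting-state functional-connectome
topology analysis for a three-group hearing-loss study design: presbycusis
with cognitive decline (PCD), presbycusis without cognitive decline (PNCD),
and healthy controls (HC). The pipeline starts from ROI-level BOLD time
series (90 regions of the AAL90 atlas), so image-space processing (slice
timing, realignment, spatial normalization) is assumed to have happened
upstream; everything from signal cleaning to group statistics is covered
here. Because patient imaging data cannot be redistributed, the package
ships a synthetic-cohort generator whose outputs have the statistical
structure every downstream stage needs, making the full pipeline testable
and reproducible from a single seed.

# The processing model

## Signal preprocessing

Per subject, in fixed order:

1. **Initial-volume discard** (default 10 of 230 acquired, leaving 220
   retained time points at TR = 2 s). The acquired length is configuration,
   not hard-coded: the functional run length implies more volumes than the
   retained count, so retained length is treated as data-driven.
2. **Head-motion screening**: exclude a subject when any translation
   exceeds 2.0 mm or any rotation exceeds 2.0 degrees, *strictly* — a value
   of exactly 2.0 is retained, matching the strictly-greater exclusion
   wording conventional in this literature.
3. **Nuisance regression**: each ROI column is replaced by its OLS residual
   against an intercept, the six motion parameters, the global mean
   (defined signal-side as the row mean over the 90 ROI columns), and any
   supplied white-matter/CSF columns. Residuals are orthogonal to every
   confound by construction.
4. **Detrend + bandpass** (0.01–0.08 Hz): the linear trend is removed
   first — filtering a ramp would ring through the Gibbs phenomenon — then
   an FFT-domain ideal filter with cosine-tapered edges (taper half-width
   0.002 Hz) is applied. This design is deterministic and has no
   filter-order ambiguity. One consequence of any finite-window
   implementation: the chain is not an exact projection. A second
   application re-fits a small trend to the filtered series and the
   subtracted ramp leaks roughly 1% of its energy back into the band, so
   "apply twice equals apply once" holds only to about 2% relative norm.

## Network construction

The conditional-dependence network is the estimand: entry *(i, j)* of the
connectivity matrix is the partial correlation of regions *i* and *j* given
all 88 remaining regions, computed from the precision matrix *P* as
−*P*~ij~ / √(*P*~ii~ *P*~jj~).

**Shrinkage is not optional in practice.** Bandpass filtering keeps only
the frequency components inside 0.01–0.08 Hz — about 62 independent
components at T = 220, TR = 2 s — which is fewer than the 90 regions, so
the post-filter sample covariance is exactly rank-deficient and plain
inversion is undefined. `partial_correlation_matrix()` therefore exposes a
diagonal-loading parameter (`shrinkage`, a multiple of the mean diagonal
added before inversion). The standalone function defaults to 0 and raises a
conditioning error suggesting shrinkage; the pipeline defaults to 1.0.
That default was chosen from estimator-noise measurements: at T = 220 the
null partial-correlation spread is ≈ 0.088 unshrunk versus ≈ 0.031 at
loading 1.0, and since binarization only consumes the *ranking* of absolute
weights, heavier loading strictly improves recovery of planted structure
(bias in the values is irrelevant to the edge ranking).

Each subject's matrix is binarized over a sparsity grid: at sparsity *S*,
the round(*S* · N(N−1)/2) node pairs with the largest absolute partial
correlation become edges (round half away from zero; ties broken by
lexicographic pair order with a warning). The default grid is 0.06 to 0.40
in steps of 0.01 — 35 binary graphs per subject, each with an identical
edge count across subjects. The textbook minimum-sparsity rule
(mean degree = 2 ln N, i.e. S = 2 ln 90 / 89 ≈ 0.101) is exposed as the
advisory `minimum_sparsity_rule()`; note it is mutually inconsistent with
the conventional 0.06 lower bound under any log base, so the grid bounds
are plain configuration.

## Graph metrics

Global: clustering coefficient Cp, characteristic path length Lp, global
and local efficiency (Eglob, Eloc), and the small-world indices
γ = Cp/Cp~rand~, λ = Lp/Lp~rand~, σ = γ/λ. Nodal: degree centrality (DC),
betweenness centrality (BC, raw geodesic-fraction sums; normalization by
(N−1)(N−2)/2 is an option since group contrasts are scale-invariant),
nodal efficiency (NE) and nodal local efficiency (NLE). Shortest paths,
betweenness and degrees are computed through igraph; every metric is
cross-checked in the test suite against independent brute-force BFS,
triangle-enumeration and geodesic-counting oracles on small graphs.

Numerical conventions that matter:

* **Lp on disconnected graphs** is the mean over *reachable* pairs, with an
  explicit unreachable-pair count attached (the convention of the major
  connectome toolboxes). This keeps the statistic finite at the low end of
  the grid. Eglob counts unreachable pairs as zero efficiency.
* **NLE** uses the neighbour-induced subgraph *excluding* the index node
  (the standard local-efficiency convention); the literal
  "node plus neighbours" variant is available behind `include_node = TRUE`.
* **Null model**: γ and λ normalize against degree-preserving random
  networks generated by Maslov–Sneppen double-edge swaps targeting
  10·|E| accepted swaps with a proposal cap of 100·|E| per null. The swap
  loop is compiled (Rcpp) and draws from R's RNG, so ensembles are exactly
  reproducible under a seed. The ensemble size defaults to 100 nulls per
  graph and is configurable; the acceptance checks use 20, which keeps the
  ensemble-mean noise in Cp~rand~/Lp~rand~ well below the effect scales
  involved. Graphs whose degree sequence admits no swap (stars) yield
  identity ensembles with a warning rather than an error.
* **AUC** over the grid uses the composite trapezoid rule; it is linear in
  the metric values, which the suite verifies directly.

## Modular architecture and rich club

The six-lobe anatomical partition (frontal, prefrontal, subcortical,
temporal, occipital, parietal) is fixed by the packaged atlas table — no
community detection. Per subject, intra-module strength is the number of
edges with both endpoints in the module and inter-module strength the
number with exactly one, averaged over the sparsity grid (both the
grid-average and per-sparsity counts are reported since the averaging
convention is not fixed by the field). A conservation identity — intra
totals plus unordered inter-pair totals equal |E| — is enforced at every
sparsity. Note that *raw counts* cannot exceed inter counts for small
modules (an 8-node module has 28 intra pairs versus 656 inter pairs), so
planted-structure recovery is a statement about *densities* (edges per
available pair), which the tests check. Weighted strengths (sums of
absolute partial correlations) are available behind a flag.

Rich-club nodes are the top floor(0.12 · 90) = 10 regions by average nodal
degree on the group-average network, selected per group (the reported
rich-club memberships differ between groups), with degree averaged over
subjects and the full sparsity grid. Edges are classified as **rich**
(both endpoints rich), **feeder** (exactly one) or **local** (neither);
the three classes partition the edge set by construction.

## Group statistics

The statistical flow mirrors standard practice for three-group imaging
cohorts: Shapiro–Wilk normality gate per group (a variable is non-normal if
any group fails at 0.05), one-way ANOVA when normal and Kruskal–Wallis
otherwise (the non-parametric choice is ours; the convention is not fixed),
Pearson chi-squared without continuity correction for categorical tables,
and pairwise post hocs only when the omnibus is significant. Post hocs fit
`value ~ group + age + sex + education` per pair and report the group
indicator's *t* and *p*; with no covariates this reduces *exactly* to the
pooled-variance two-sample t-test (verified numerically), which also fixes
the variance assumption (Student, pooled). Sex enters as a 0/1 indicator.
Bonferroni correction uses family size m = 90 (the nodes) within each nodal
metric and contrast; the family definition is a package choice since
"correction for nodal analysis" does not pin one down. A
summary-statistic ANOVA (`summary_stat_anova()`) reproduces published
demographic tests from printed means/SDs/sizes; it is algebraically
identical to raw-data ANOVA when the summaries are exact.

# The synthetic cohort generator

## What it emulates

Each synthetic subject is T × 90 zero-mean Gaussian with a planted
covariance, a 6-column motion random walk (optionally planted above the
exclusion limits, in the second half of the run so the excursion survives
the initial-volume discard), and demographics drawn from per-group
truncated normals at the published means/SDs: age truncated at 60
(inclusion criterion), education at 8 years, better-ear PTA above 25 dB HL
for patients and at most 25 for controls, MoCA integer-valued and truncated
at the 26-point cognitive boundary per group, and sex assigned to exact
M/F counts so the categorical worked example is deterministic. Default
sizes are 30/30/50 (110 subjects).

## Two planting domains

`covariance_spec()` plants structure in the **marginal** correlations:
exact block-constant matrices (within-module correlation 0.5,
between-module 0.1 by default) with optional hub enrichment through a
latent-factor construction (a flat additive hub boost of useful size is
indefinite — it is a rank-2 perturbation with a large negative
eigenvalue — whereas extra hub loadings on the shared factor keep the
matrix positive definite by construction and reduce to the exact
block-constant form with no hubs).

During development we measured that marginal planting is largely invisible
to this pipeline: conditioning on 88 regions explains the shared-factor
structure away, leaving population between-module *partial* correlations
near 5·10⁻⁴, so scaling the marginal between-module correlation moved Lp
AUC by under 0.1% and planted hubs were not recoverable. The block design
is retained because it does produce clearly small-world graphs (its
within-module partials, ≈ 0.06, dominate the thresholded edge ranking at
low sparsity) and it is the basis of the small-world acceptance runs.

`conditional_spec()` therefore plants structure in the **conditional**
domain the pipeline actually estimates — a Gaussian graphical model
`P = I − W` where W holds the planted partial correlations: a short-range
lattice along a ring ordered by module (graded weights, peak 0.09,
e-folding 2.5 steps, radius 8), making nearby same-module regions strongly
conditionally coupled, plus 10 hub regions spread around the ring with 12
long-range shortcuts each (weight 0.07). Positive definiteness is checked
via the largest eigenvalue of W. Sampling inverts P and rescales to unit
variance; partial correlations are scale-invariant, so planted values
survive exactly.

## Group effects

Effects are multiplicative scales on the planted *partial* correlations:
`within_scale` on the short-range lattice and `between_scale` on the
long-range shortcuts. Patients get `within_scale > 1` with
`between_scale < 1` — increased segregation, decreased integration — which
produces the reported patient profile (higher Cp and Lp, lower Eglob).
This lever was chosen because it is the one that demonstrably moves path
length in sparsity-thresholded graphs: at fixed edge count, estimation
noise contributes uniformly random edges that are themselves efficient
shortcuts, so *removing* planted shortcuts merely swaps in equally good
random ones; what lengthens paths is stronger short-range signal claiming
more of the top-ranked slots and displacing noise shortcuts. Default
planted magnitudes (PCD 1.25/0.6, PNCD 1.10/0.8 against HC 1/1) are free
parameters of the generator — clinical reports in this area give
significance levels, not effect sizes — chosen to be moderate and
direction-consistent; the
parameter-recovery tests plant a stronger, unambiguous effect (1.35/0.5).

## What passing tests do and do not show

The generator produces stationary Gaussian series with exact planted
covariance; it does not emulate scanner drift, spikes, physiological
noise spectra, spatial smoothness, or hemodynamic autocorrelation.
Recovery results on synthetic cohorts therefore validate the *pipeline
mechanics* (estimation, thresholding, metrics, statistics) under known
ground truth, not the empirical sensitivity of the method on real fMRI.
In particular, group differences observed in real patient cohorts cannot
be reproduced without the original scans, and no test here claims to.

# Problem sizes and reproducibility

Every random stage (series sampling, demographics, null rewiring) draws
from a private seeded RNG stream fanned out deterministically from one
master seed, so cohorts, null ensembles and full pipeline reports are
bit-identical across runs. Simulation-heavy checks use deliberately
scaled problem sizes chosen as the package's own test design: small-world
curves use 3-subject cohorts with 20-null ensembles; parameter-recovery
uses 20 replicates of 10-per-group cohorts; the null false-positive audit
uses 200 replicates of 8-per-group cohorts with degree-centrality AUCs on
the full 35-level grid and clustering AUCs on a 5-level subgrid; hub
recovery uses 5 replicates of 30-subject groups. The end-to-end default
(110 subjects, 100 nulls per graph per sparsity) is sized for analysis
use, not for test suites.

# Known limitations

* Partial correlations after ideal bandpass filtering require diagonal
  loading; reported values are biased toward zero at the default loading,
  and only the edge ranking should be interpreted.
* The minimum-sparsity rule and the conventional 0.06 grid lower bound are
  mutually inconsistent; the rule is advisory only.
* Rich-club analysis uses the fixed top-12% definition, not the normalized
  rich-club coefficient curve φ(k)/φ~rand~(k).
* Binary graphs only; no weighted or directed variants.
* The schematic atlas coordinates shipped for viewer export are a synthetic
  layout for visualization, not measured MNI centroids.
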