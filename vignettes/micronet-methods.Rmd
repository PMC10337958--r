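---
title: "Co-abundance networks and single-sample network impact: methods"
author: "micronet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-abundance networks and single-sample network impact: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micronet)
```

## The problem

Conventional community-level analysis of 16S amplicon data — beta-diversity
distances, ordination, per-taxon differential abundance — asks whether the
*abundances* of taxa differ between groups of subjects.  It can miss changes
in the *ecological balance* of a community: shifts in which taxa co-vary,
even when every marginal abundance distribution stays put.  micronet
implements a complementary workflow that represents each cohort of subjects
as a binary co-abundance network over OTUs, compares cohorts through the
overlap of their networks against explicit null models, and scores how much
each individual sample perturbs its cohort's network.

## Network reconstruction

For one cohort (a set of samples), with relative abundances
$x_i$ per OTU $i$:

1. The Pearson correlation $C_{ij}$ is computed for every unordered OTU
   pair across the cohort's samples.
2. Significance is assessed per pair against a *data-shuffle null*: each
   OTU's abundance vector is independently permuted across samples
   (a resample from its own empirical abundance distribution that preserves
   the marginal exactly and destroys all association), the correlation is
   recomputed, and over `nShuffles` (default 1000) realizations the Z-score
   $$W_{ij} = \frac{C_{ij} - \mathrm{mean}(C^{\mathrm{shuffle}}_{ij})}
   {\mathrm{sd}(C^{\mathrm{shuffle}}_{ij})}$$
   is formed.  Pairs with $W < 1$ (default threshold) are discarded as
   non-significant.
3. The surviving pairs are ranked by signed Pearson coefficient in
   decreasing order, and the top `nEdges` (default 500) become the edges of
   a binary network.  Fixing the edge count removes the size bias that
   would otherwise confound comparisons between cohorts — at any fixed
   $W$ threshold different cohorts yield different network sizes
   (see `networkSizeSweep()`).  If fewer pairs survive the filter, all are
   kept and the shortfall is recorded.

Implementation notes.  All pairs share one shuffled table per Monte-Carlo
realization: every OTU column is permuted independently, so each pair's
null draw is exact, and one matrix cross-product serves all
$\binom{p}{2}$ pairs.  Samples and OTUs are put into lexicographic order
before the draws, making the result invariant to input order under a fixed
seed.  Ranking uses the signed coefficient — strong negative correlations
never enter the network — because the edge set is meant to capture
co-abundance; `rankAbs = TRUE` is available for sensitivity analysis.  Ties
at the cutoff are broken by the lexicographic order of the OTU-id pair.
Zero-variance OTUs have undefined correlations and are excluded before
ranking.  Correlations are computed on relative abundances directly; no
log-ratio or other compositionality correction is applied, since the method
is defined on, and its null models operate on, the closed compositions
themselves (see Limitations).

## Network comparison

The similarity of two cohorts' networks is the Jaccard index of their edge
sets, $J = |E_A \cap E_B| / |E_A \cup E_B|$.  Its significance is judged
against an *edge-shuffle null*: each network's edge set is replaced by a
uniformly random set of the same size over all node pairs (no degree
preservation), and the fraction of null realizations with a Jaccard at
least the observed value is the one-sided empirical p (reported as
$< 1/N$ when no realization reaches it).  For 108-node networks of 500
edges the null expectation is $\mathbb{E}|{\cap}| = m n / \binom{108}{2}
\approx 43.3$ shared edges, i.e. a null Jaccard near 0.045 — any observed
similarity well above $\sim 0.05$ indicates genuinely shared structure.

A single cohort pair yields a single Jaccard value.  Where a distribution
of similarities is needed (rank-based comparisons of similarity between
group pairs), `jaccardBootstrap()` resamples each cohort's subjects with
replacement and rebuilds both networks per replicate.  This subject-level
bootstrap is this package's own construction for that step; its p-values
are a reconstruction, not a canonical procedure.

## Single-sample network impact

The impact of sample $k$ on its cohort's network $B^n$ is estimated by
leave-one-out reconstruction of $B^{n-k}$ under identical parameters and
seed:

* direct impact $= 1 - J(B^n, B^{n-k})$, in $[0, 1]$: how much the
  cohort's network changes when $k$ is removed;
* indirect impact $= J(A, B^{n-k}) - J(A, B^n)$, in $[-1, 1]$, for a
  reference cohort network $A$ (e.g. healthy subjects at the first
  timepoint): positive when removing $k$ makes the cohort *more* similar
  to the reference, i.e. $k$ deviates from the reference more than the
  rest of its cohort.

`impactProfile()` computes $B^n$ (and $A$) once and reuses them for every
$k$, so all samples are judged against the same baseline.  Per-sample
outlier significance uses a one-sided Wilcoxon signed-rank test of the
differences between the other samples' scores and $k$'s; this construction
is again the package's own, offered because flagged individuals need a
calibrated reference distribution.  This is deliberately not single-sample
network *inference*: one sample's network is never estimated, only its
influence on the cohort estimate.

## Community-analysis baseline

The comparator workflow uses the root Jensen–Shannon divergence between
two relative-abundance profiles restricted to — and renormalized over —
their shared support:
$$D_{\mathrm{rJSD}}(\hat x, \hat y) = \sqrt{\tfrac12\!\left[
D_{KL}(\hat x \,\|\, m) + D_{KL}(\hat y \,\|\, m)\right]},
\qquad m = \tfrac{\hat x + \hat y}{2}.$$
Logarithms are base 2, so the distance lies in $[0,1]$; the base is a
package choice (it affects absolute distances, not any rank-based test).
The shared-support restriction is the definition used throughout; the more
common union-support variant is available via `sharedSupport = FALSE`.
On top of the distance: within-group beta diversity (all pairwise
distances), mean distance of a sample to a reference cohort, classical
PCoA (double-centering, eigendecomposition; explained fractions over the
positive spectrum, negative eigenvalues dropped and their magnitude
reported — rJSD matrices need not be Euclidean-embeddable), two-sided
Wilcoxon rank-sum tests, and a per-OTU differential-abundance screen with
Bonferroni correction.

## The synthetic-community generator

No cohort data ship with the package; every analysis is exercised on
synthetic cohorts with *known* structure.  `generateCohort()` draws latent
multivariate-normal scores whose correlation matrix is the identity plus
`rho` on each planted OTU pair (repaired to the nearest correlation matrix
when needed; generation aborts if the repair moves any planted value by
more than 0.05), maps them through per-OTU log-normal marginals, closes to
relative abundances, and draws integer counts by one multinomial per sample
at fixed sequencing depth.  Defaults — `logSd = 1` (an OTU's abundance
across subjects spans roughly $e^{\pm 2}$, i.e. ~50-fold), depth 50000 —
are chosen to resemble filtered 16S OTU tables.  The log-normal transform,
the closure and the counting noise all attenuate the realized Pearson
correlation below the latent `rho`; a planted `rho = 0.9` typically
realizes $r \approx 0.75{-}0.85$.  What the generator does *not* emulate:
zero inflation, taxon-specific dispersion, phylogenetic structure, and the
strong per-subject individuality of real microbiomes — so passing tests
demonstrate correctness of the machinery under a known truth, not
performance guarantees on real data.

`simulateStudyCohorts()` builds a four-cohort study (30 + 30 healthy,
27 + 27 disease-group samples, 108 OTUs) whose planted networks are nine
equicorrelated blocks of 11 OTUs (495 pairs, near the 500-edge budget);
block structure keeps the correlation matrix positive definite at any
`rho` and gives the planted network realistic clique-like motifs.  The
disease-group network shares a configurable fraction of the healthy blocks;
its second timepoint is rewired again to emulate a perturbation such as a
diet intervention.

Outlier samples are disrupted in one of three ways: `"permute"` shuffles
the sample's counts across OTU labels (full or partial via `strength`),
`"foreign"` redraws the sample from a rewired planted network with
identical per-OTU marginals, and `"inverted"` redraws it with the planted
correlations scaled by $1 - 2\lambda$ for strength $\lambda$ — an
independent sample at $\lambda = 0.5$, a fully anti-correlated one at
$\lambda = 1$ — again with marginals untouched.  All three destroy the
sample's participation in the cohort's correlation pattern while leaving
its community-level profile (and hence rJSD distances) essentially or
exactly unchanged.

The modes are not equally detectable, for a quantifiable reason.  Writing
$z_x, z_y$ for a planted pair's latent scores, a sample's leave-one-out
influence on that pair's correlation is driven by $\rho - z_x z_y$.  For
a typical cohort sample this has second moment $1 + \rho^2 - \rho^2 \cdot
0 = 1 + \rho^2$; for a permuted or foreign sample (independent scores) it
is $\rho^2 + 1$ — *identical*.  At the Gaussian level a fully scrambled
sample is therefore indistinguishable from ordinary sampling noise, and
its detection rides only on higher-order (heavy-tail) effects.  An
inverted sample has second moment $1 + 5\rho^2$: a genuinely stronger,
and tunable, disruption.  This is why the packaged outlier-recovery
checks use `"inverted"` outliers; `"permute"`-mode outliers are typically
ranked near, but not reliably at, the top of the impact profile.

## Fixture and problem sizes used by the test-suite

The packaged checks run, as the package's own choice of problem sizes:
null-ensemble calibration on 108-node/500-edge networks with 1000
realizations; Z-score calibration on a 30-sample, 100-OTU independent
cohort with 1000 shuffles; planted-edge recovery on 108 OTUs, 30 samples,
50 disjoint planted pairs at `rho` 0.3/0.6/0.9 with a 50-edge budget; and
outlier recovery on ten replicate 27-sample cohorts with 54 disjoint
planted pairs (`rho = 0.9`, homogeneous log-normal marginals with
`logSd = 0.6`, depth 50000) containing one fully `"inverted"` outlier
each, profiled with a 40-edge budget.  The 40-edge budget places the
cutoff *inside* the planted structure: leave-one-out membership changes
then reflect how a sample supports the planted correlation ranking, which
is the signal the impact score is designed to see.  Budgets at or beyond
the planted size put the cutoff into the noise floor, where sampling
churn from every sample dominates and single-sample attribution washes
out.

## Numerical choices and edge cases

* All Monte-Carlo stages accept explicit integer seeds; a master seed
  spawns deterministic sub-seeds per workflow stage, and every pipeline
  output is byte-reproducible under a fixed seed.
* Empirical p-values use the inclusive comparison (null $\ge$ observed).
* `0 \cdot \log(0/q)` is treated as 0 in all divergences.
* Zero-variance OTUs, all-zero samples, empty shared support, empty edge
  sets (Jaccard 0/0) and infeasible planted structures raise informative
  errors rather than propagating NaN.
* OTU filtering interprets the "at least 10 instances" rule as total read
  count across samples (the sample-prevalence reading is covered by the
  separate 10%-prevalence rule); filtering precedes normalization and is
  applied to the full study so all cohorts share one OTU universe.

## Limitations

* Pearson correlations on closed compositions carry the usual
  compositional artefacts; the workflow is faithful to its design rather
  than to log-ratio orthodoxy, and SparCC-style inference is out of scope.
* The Z-score $W$ standardizes against the permutation null's mean and
  standard deviation, but the permutation null of a correlation is itself
  *not* normal for heavy-tailed abundances at moderate $n$.  With
  log-normal marginals (`logSd = 1`, $n = 30$) the tail mass beyond
  $W = 2$ is roughly 0.04 rather than the normal 0.023 — so $W$
  thresholds should be read as ranking devices, not calibrated p-values.
  Under milder marginals (`logSd` around 0.4) the normal calibration is
  recovered.
* Single-sample impact is an influence measure on a cohort estimate; with
  $n \approx 27$ subjects one sample's leverage is intrinsically $O(1/n)$,
  and detection of disrupted samples degrades when the cohort carries
  little genuine correlation structure or when the edge budget sits in
  the noise floor (see above).
* The signed-rank outlier p-values and the bootstrap similarity
  distributions are the package's own constructions for under-determined
  steps and should be interpreted as such.
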