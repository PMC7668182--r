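---
title: "Methods: surface-based asymmetry statistics in asymmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surface-based asymmetry statistics in asymmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
models behind each statistic, the assumptions they make, the parameters that
matter, and the design decisions taken where more than one reasonable choice
existed. Nothing here reports an empirical number that the test suite or
`scripts/acceptance.R` does not itself compute.

## Data model

All analyses operate on triangulated hemisphere meshes with a vertex
correspondence: a bijective, involutive pairing of left and right vertices.
Two kinds of per-vertex data enter: task-contrast statistics (z units, one
scalar per vertex per subject per hemisphere) and resting time series
(timepoints x vertices). Vertices are 1-based inside R; all on-disk formats
(mask index lists, correspondence TSVs) are 0-based and converted at the
boundary, which keeps files interoperable with the wider surface-analysis
ecosystem while the R API stays idiomatic. GIFTI metric support is a minimal
single-data-array float32 reader/writer (ASCII and gzip/base64 encodings);
geometry files and CIFTI are out of scope.

Cluster contiguity is triangle-edge adjacency (two vertices are neighbours
iff they share a triangle edge), the standard deterministic mesh
connectivity; vertex-sharing-only contact does not connect clusters.

## Activity asymmetry (RRA)

For each subject the left map is mirrored through the correspondence and the
signed difference right − left is formed at every mask vertex; the unsigned
map is its absolute value. The signed convention is fixed (positive = right
dominance) and all dominance reports follow it. The group-level cluster test
runs on the *unsigned* map: the scientific question is "is this location
lateralized in most subjects", irrespective of direction. The package
z-scores each subject's unsigned map across mask vertices before the
randomization test; z-scoring the unsigned rather than the signed map is a
choice (the tested map is the unsigned one, and the permutation null
shuffles within-subject spatial labels, which requires per-subject
standardization), and the signed variant remains available by passing signed
values directly.

## Connectivity asymmetry (FCA)

The FCA coefficient of a homologous seed pair is the mean absolute
difference of the two seeds' whole-brain correlation profiles. "Whole brain"
is taken literally: all vertices of both hemispheres, including the seed
mask itself and the seeds' own columns. A consequence worth knowing: even
with perfectly symmetric coupling, FCA has a small positive floor of about
`2 * (1 - rho_homotopic) / m` per seed, because each seed correlates 1 with
itself but `rho_homotopic < 1` with its homologue; the test suite verifies
the sample FCA against this closed-form population value. Undefined
correlations (constant series) are excluded pairwise with the denominator
adjusted, never imputed. Raw Pearson r is used throughout — profiles are
averaged and reported on the correlation scale, with no Fisher transform.

Group-level FCA maps can be computed from the MIGP pseudo-time-series;
subject-level maps (the ones entering t tests and the cluster test) come
from each subject's own series. Both paths share `fca_map()`.

## MIGP

Incremental group PCA streams subjects through a running state `W`:
stack `W` with the next subject's demeaned series, take the top
`internal_dim` temporal eigenvectors, project, repeat. The state's spatial
Gram matrix equals that of all data seen so far up to truncation, so the
output approximates the principal subspace of the full concatenation; with
`internal_dim` at least the total timepoint count the recovery is exact, and
the suite checks both the exact regime (principal angles < 1e-6 rad) and the
compressed regime (top-10 angles < 5 degrees at `internal_dim = 60` for
8 x 100 timepoints over 2000 vertices). The first subject is rotated through
the same PCA step, so even a single-subject "group" yields principal
components. `internal_dim` defaults to twice the output dimension; subjects
are processed in the order given.

## Cluster-mass randomization inference

The observed statistic is the mass (sum of t values) of each connected
supra-threshold component of the group one-sample t map, thresholded at
z = 2.3 (the conventional p = 0.01 one-sided cluster-forming threshold;
configurable). The test is one-sided in positive t because both tested maps
(unsigned RRA, FCA) are nonnegative quantities. The null shuffles each
subject's z-scored values independently and uniformly across the mask and
records the maximal cluster mass per shuffle; corrected p-values are
`(1 + #{null >= observed}) / (1 + n_perm)`, so ties count toward the null
and p is never zero. The plain proportion (which can be zero) is available
behind `plus_one = FALSE` for comparison against exhaustive enumeration.

The null assumes spatial exchangeability of the per-subject maps within the
mask. That assumption fails for spatially smoothed noise, and the test is
then *anticonservative*: smooth maps produce larger observed clusters than
the shuffled null predicts. The package does not hide this — a property test
generates null cohorts with smoothed noise and asserts that the rejection
rate exceeds the nominal level — and the type-I-error validation therefore
uses spatially exchangeable (unsmoothed) null cohorts, the condition under
which the randomization null is actually true. Users applying the test to
smooth real data should interpret corrected p-values accordingly (or smooth
less, or raise the cluster-forming threshold).

Degenerate vertices (zero between-subject variance) get t = 0 when the mean
is zero and infinite t otherwise, and are flagged rather than dropped.

## Conjunction, coefficients, screens

The FA cluster is the set intersection of the significant activity and
connectivity clusters. Per-subject coefficients are plain means over the
region; both signed and unsigned RRA coefficients are emitted because either
may be wanted downstream. The combined FA coefficient averages the RRA and
FCA coefficients after z-scoring each across subjects — they live on
different scales (z units vs correlation units) and raw averaging would let
one dominate; `standardize = FALSE` restores the raw mean. The covariate
screen computes one Pearson correlation per behavioural measure with
pairwise deletion (per-covariate n always reported; fewer than 3 pairs flags
the covariate untestable) against a fixed alpha of 0.001, a deliberate
multiple-comparison allowance for batteries of ~170 measures. The temporal
SNR control compares mean/SD of the raw series (the constant series baseline
exists precisely so tSNR is defined) between hemispheres with a paired t
test.

## Profile ANOVA

The seed x network x network-hemisphere analysis is a fixed-effects 2x2x2
ANOVA on subject-by-cell observations (8 cells per subject), matching the
error-degrees-of-freedom convention of treating subject-cells as
observations; a repeated-measures treatment would be stricter and can be
assembled from the returned table. Sums of squares come from `stats::aov`;
the acceptance suite checks them against an independent orthogonal-
projection (normal-equations) oracle to 1e-8 relative error, plus the
conservation identity (effect SS + residual SS = total SS). The degenerate
zero-residual case is guarded explicitly: effects with numerically zero SS
report F = 0, p = 1. Post hoc contrasts are paired t tests of right vs left
seed within each network (averaging over network hemisphere), with a
single-step Sidak family-wise adjustment over the requested family — for a
two-contrast family, Tukey's studentized-range construction is not defined,
and Sidak preserves the invariant adjusted p >= raw p.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the conditions under
which every downstream claim is validated.

*Geometry.* Both hemispheres are the same subdivided icosahedron (12, 42,
162, 642, 2562, ... vertices) with identity correspondence; masks are
deterministic breadth-first patches. Defaults: 642 vertices per hemisphere,
a 150-vertex analysis mask, a 20-vertex contiguous planted region inside it,
and two 60-vertex network patches (DMN-like, ExN-like) outside it.

*Contrast maps.* Bilateral baseline (constant 1) + the subject's activity
magnitude added to the planted region of the dominant hemisphere + Gaussian
noise (SD 1) smoothed by 2 rounds of neighbour averaging. Neighbour-
averaging rounds stand in for geodesic Gaussian smoothing: they are
geometry-independent, deterministic and fast; one round couples first-ring
neighbours, two rounds give noise correlation reaching the second ring,
qualitatively like the mild surface smoothing of preprocessed contrast maps.

*Time series.* A linear two-latent model: DMN-like and ExN-like latents,
i.i.d. standard normal over time, with vertex loadings 1 on their own
network patches and 0.3 from every mask vertex to both latents; white noise
SD 1; constant raw baseline 100 so temporal SNR is defined (correlations are
unaffected). Planted-seed vertices of the dominant hemisphere carry a DMN
loading increased by the subject's connectivity magnitude, and that
increment is *variance-compensated* through the vertex noise (floored at 10%
of nominal noise variance): total series variance is unchanged, so the
manipulation changes the DMN coupling and nothing else — without the
compensation it would leak into ExN correlations and temporal SNR, which the
design intends to keep hemispherically matched. The linear-latent choice
makes every population correlation available in closed form
(`cov = a_u . a_v`, `var = |a|^2 + noise_sd^2`), which the oracle tests use.

*Asymmetry magnitudes.* Activity magnitude `rra_effect * (1 + latent_sd*a)`
and connectivity magnitude `fca_effect * (1 + latent_sd*c)` with defaults
1.5 z units, 0.4 coupling units and latent_sd 0.5 — large enough for
desk-scale recovery at 12-20 subjects, small enough that unit-SD map noise
is a real obstacle. The standardized latents (a, c) are constructed by
in-sample orthogonalization so their *realized sample correlation equals the
configured target exactly* in every cohort (for n >= 3): the target is
defined as the correlation of the planted magnitudes across the cohort's
subjects, and fixing it keeps recovery tests about estimator error rather
than cohort-level sampling noise. Dominance is all-right by default or
per-subject random sign with probability `p_right` under the mixed scheme;
swapping hemisphere labels flips all signed ground truth and leaves unsigned
quantities invariant (asserted bit-exactly for maps; FCA and ANOVA
quantities are asserted at 1e-10 to 1e-12 relative tolerance because the
swap permutes floating-point summation order).

*What the generator does not emulate.* Hemodynamics, temporal
autocorrelation, realistic cortical geometry or curvature-dependent
smoothing, registration error in the hemispheric correspondence, and
structured physiological noise. Passing recovery tests therefore shows the
estimators and inference machinery are correct under the stated model, not
that real effects of these sizes would be detected at these sample sizes.

## Problem sizes and numerics

The validation suite runs at deliberate desk scale: 642-vertex hemispheres,
150-300-vertex masks, 12-60 subjects, 60-300 timepoints, 200-5000
randomizations per test and 20-200 replicates per property; the full
pipeline at 10,000 randomizations (`scripts/acceptance.R`) completes in
seconds. Tolerances: exact identities at 1e-10 to 1e-12 relative; sampling
comparisons at 3 Monte-Carlo standard errors or explicit bands; float32
round-trips at 1e-6. Ties in the permutation null count toward the null.
All randomness flows from explicit integer seeds; identical seeds give
bit-identical cohorts and corrected p-values.

## Known limitations

- The spatial-shuffle null is anticonservative under smooth noise (measured,
  see above); spin/rotation nulls are not implemented.
- The hemispheric correspondence is assumed exact; residual misregistration
  would inflate FCA and is not modelled.
- The fixed-effects profile ANOVA treats subject-cells as independent
  observations; a mixed-model treatment would be more stringent.
- GIFTI support covers single-array float32/float64 metric files only.
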