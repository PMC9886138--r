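---
title: "Particle-based shape models of multi-organ anatomies with shared boundaries"
author: "shapeshared"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Particle-based shape models of multi-organ anatomies with shared boundaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Many anatomies of interest are not single organs but assemblies of organs
in physical contact: the right ventricle and the left ventricle wall meet
at the interventricular septum; femur and pelvis articulate through shared
cartilage surfaces. Point distribution models (PDMs) describe each shape by
an ordered set of *correspondence particles* — point m on one subject marks
the same anatomical location as point m on every other subject — so that
population statistics (mean shape, modes of variation, group differences)
can be computed coordinate-wise. When each organ is modelled independently,
nothing ties the two particle systems together at the contact surface:
reconstructed modes of variation show particles of one organ penetrating
the other, or gaps opening between organs, and the contact surface itself —
often the clinically interesting structure — has no explicit
representation.

`shapeshared` builds PDMs that represent the shared boundary explicitly.
A subject is modelled as four coupled domains: the two organ remainders
(`A_r`, `B_r`), the shared boundary surface (`M`), and the shared
boundary's exterior outline, a closed 3D contour (`C`). The package covers
the whole workflow: extraction of the four parts from a pair of adjoining
triangle meshes, rigid cohort alignment, entropy-based particle
optimization with contour coupling, and the downstream statistics.

## Shared-boundary extraction

Given adjoining meshes `A_o` and `B_o`, the extraction pipeline
(`extract_shared_boundary()`) performs four steps:

1. **Isotropic remeshing** of both inputs toward a common target edge
   length (default: the mean input edge length), using the standard
   split-long / collapse-short / flip-for-valence / tangential-relax cycle
   with re-projection onto the input surface. Uniform, equal-sized
   triangles make the distance threshold in step 2 meaningful on both
   meshes.
2. **Close-triangle classification.** A triangle of `A_o` belongs to the
   shared patch `A_s` iff *all three* of its vertices lie within a distance
   threshold of `B_o` (and symmetrically for `B_s`). Triangles with only
   one or two close vertices straddle the cutoff and are excluded. The
   threshold defaults to half the remeshing target edge length: any
   sub-edge value works for genuinely coincident patches, and tying it to
   the edge length makes it scale with resolution. Small disconnected
   islands (< 1% of the candidate area) are dropped as classification
   specks. As surfaces `A_s` and `B_s` coincide; `B_s` is (arbitrarily)
   designated the shared surface `M`, and the remainders `A_r`, `B_r` are
   the inputs minus their close faces. Each boundary vertex of `M` is then
   snapped to the closest point on the boundary polyline of `A_r` —
   segment projection rather than nearest-vertex copying, because after
   independent remeshing the two openings have different vertex counts.
3. **Laplacian smoothing** (uniform weights, 30 iterations, relaxation 1
   by default) of the three outputs, with boundary-loop vertices held
   fixed so the snapped opening stays exactly coincident. Uniform rather
   than cotangent weights: the meshes enter this step near-uniform, where
   the two coincide. Note that uniform Laplacian smoothing contracts
   curved surfaces toward their boundary span; the amount scales with
   (edge length)² × iterations, so at coarse synthetic resolutions it
   visibly shrinks a curved cap while at fine clinical resolutions the
   same 30 iterations are mild. For this reason the extraction report
   records the shared-surface area *before* smoothing, and geometric
   accuracy checks are made against that quantity.
4. **Contour extraction**: the longest boundary loop of `M`, traversed in
   face orientation order, becomes the closed contour `C`.

## The correspondence objective

A cohort of N subjects, each with M corresponding particles
x<sub>1</sub>…x<sub>M</sub> on its surface, defines per-subject *shape
vectors* z<sub>n</sub> ∈ R<sup>3M</sup> (concatenated coordinates) assumed
Gaussian in shape space. Correspondence is optimized by minimizing

Q = H(Z) − Σ<sub>n</sub> H(X<sub>n</sub>)

where H(Z) = ½ log |Σ| is the shape-space entropy (small when the cohort's
shape distribution is compact, i.e. particles are in correspondence), and
H(X<sub>n</sub>) is the per-subject *sampling entropy*, estimated by Parzen
windowing with isotropic Gaussian kernels over the particle set (large when
particles spread uniformly over the surface — geometric fidelity). With
several organs the sampling term is decoupled per organ (particles interact
only within their own domain), while the covariance Σ spans all domains
jointly, so the shape statistics remain coupled.

For shared-boundary anatomies the sampling term of the organ domains
(`A_r`, `M`, `B_r`) is made *conditional on the contour*: the Parzen
neighbour set of every organ particle additionally contains that subject's
contour particles, normalized by 1/(M<sub>k</sub> + M<sub>C</sub> − 1).
Contour particles therefore repel organ particles — creating a buffer that
keeps organ particles from crowding or crossing the shared-boundary edge —
but receive no gradient from organ terms, and their own sampling objective
is unchanged: gradients from the much larger organ particle sets could
otherwise push contour particles past each other, and with a single degree
of freedom on a contour that ordering error is unrecoverable. Both
sampling sums are subtracted in Q (maximized), consistent with the role of
the sampling term in the single-organ objective.

### Numerical realization

Decisions the objective does not fix, and how this package makes them:

* **Kernel bandwidths.** Per particle, σ = distance to its 6th nearest
  neighbour within its Parzen neighbour set, capped at 3× the
  nearest-neighbour distance and floored at 10⁻³ of the domain
  bounding-box diagonal. The cap matters: right after a split round
  particles sit in tight pairs, the 6th neighbour lies across the whole
  configuration, and uncapped kernels become so flat that pairs never
  separate. On a well-spread configuration the cap is inactive. When
  contour particles act as frozen neighbours of an organ domain, their
  bandwidths are computed within that joint organ-plus-contour set, so
  their kernels repel at the organ's local scale.
* **Initialization by binary splitting.** Each domain starts with one
  particle (the surface point nearest the vertex centroid; for contours a
  deterministic geometric anchor — the vertex extremal along a fixed axis
  — because contour vertex numbering is a meshing accident that differs
  per subject). Counts double per round: children offset ±ε (0.5% of the
  domain diagonal) along a tangent direction shared across subjects, then
  re-projected, followed by a sampling-only relaxation phase. The first
  two rounds split along fixed axes (y, then z) rather than random
  directions: they pin the layout's gauge — e.g. the azimuth of the
  particle pattern on a near-axisymmetric organ — identically across
  subjects. Without this anchoring the azimuth is a soft mode that the
  correspondence term corrects only over hundreds of iterations, and it
  dominates the apparent shape variance meanwhile.
* **Updates.** Statistics (mean, covariance spectrum via the N×N Gram
  matrix) are recomputed once per outer iteration (*lagging statistics*).
  The per-particle move is −step · M<sub>k</sub> · σ² (w ∇H(Z) − ∇H(X)),
  clamped to 0.3 σ; the M<sub>k</sub> factor undoes the 1/M normalization
  of the entropy so move sizes are count-independent, and the clamp keeps
  moves inside the kernel support. A single global step factor halves
  (with revert to the previous state) when Q increases and grows by 10%
  when it decreases. Contour particle updates are projected onto the local
  segment direction before re-projection (one degree of freedom). The
  correspondence weight w defaults to 1; the cohort analyses in the test
  suite use w = 2, which tightens correspondence noticeably on the
  synthetic cohort without visible loss of sampling uniformity.
* **Regularization.** With N ≪ 3M the sample covariance is singular; the
  entropy and its gradient use Σ + αI with α decaying geometrically from
  10⁻² to 10⁻⁵ of the mean eigenvalue over the run. The entropy value is
  the *full* regularized log-determinant ½ Σ<sub>i</sub> log(λ<sub>i</sub> + α)
  over all 3M eigenvalues (those beyond the data rank are exactly zero),
  which is what a dense computation yields.
* **Kernel truncation.** Gaussian kernels are truncated at 6σ (relative
  error ~10⁻⁸). Truncating at 4σ would be faster still but the dropped
  mass (~3·10⁻⁴) is visible at the 10⁻⁴ relative tolerance to which the
  analytic gradients are verified against central finite differences.

## The synthetic peanut cohort

`generate_peanut_cohort()` is the package's self-contained test bed. Each
sample is two intersecting spheres, centres 1 unit apart, with one sphere
subtracted from the other, so the two surface meshes share an exactly
coincident spherical-cap patch. The radii vary inversely (r₁ + r₂ = 2,
with r₁ evenly spaced over [0.8, 1.2] within each group — even spacing
makes the dominant mode analytically predictable); pathology is emulated by
replacing the second sphere with an ellipsoid whose y and z semi-axes are
shrunk by independent uniform draws from [0.6, 0.9]. The cohort is 15
controls + 15 pathology, every composite centred at the origin. Geometry is
built by analytic clipping of subdivided icospheres at the intersection
surface (exact quadric roots along edges), not by boolean mesh operations:
clipping guarantees the coincident shared patch that the extraction
threshold relies on. The equal-radius control sample has a shared cap of
analytically known area (2π r₂ h with h = r₂ − d/2 + (r₁² − r₂²)/(2d)),
used as a geometric oracle.

What the generator does *not* emulate: cardiac-like asymmetric geometry,
pose perturbations (the samples are generated pre-aligned; the alignment
module is exercised with explicit synthetic transforms), segmentation
noise, and non-Gaussian shape variation. Passing tests on this cohort
demonstrate the machinery — extraction, coupling, correspondence, scoring —
not clinical performance on real anatomy.

## Downstream statistics

* **PCA modes** (`pca_modes()`): eigen-decomposition of the sample
  covariance via the Gram trick; `mode_walk()` reconstructs shapes at ±c
  standard deviations along a mode, and `warp_mesh()` carries a reference
  mesh along by thin-plate-spline interpolation of the particle
  displacements (3D kernel U(r) = r).
* **MLCA** (`mlca()`): the shape matrix is split into a *between-organ*
  component (per-domain particle centroids, centred — the relative pose of
  the organs) and a *within-organ* component (centroid-removed residuals,
  centred), with grand mean + between + within reconstructing the data
  exactly; separate PCAs of the two components disentangle pose modes from
  shape modes. The centroid-offset decomposition is the minimal reading of
  "relative alignment variation"; a full Procrustes between-component is a
  known variant and out of scope.
* **Shape-based scores** (`group_difference()`): the difference vector
  between the two groups' particle-wise mean shapes; each subject's shape
  vector is projected onto it and affinely normalized so the pathology-like
  group mean sits at −1 and the control-like group mean at +1 exactly.
  Univariate Gaussians (maximum-likelihood variance) summarize each group's
  score distribution.
* **Class-imbalance experiment** (`imbalance_experiment()`): repeatedly
  optimizes a model on a balanced random training subset (default 6 per
  group), predicts particles on the held-out subjects *without*
  re-optimizing (initialization at the trained mean configuration projected
  onto the held-out surfaces, then refinement against frozen statistics),
  scores everyone with the trial's difference vector, and per subject runs
  a two-sided one-sample t-test of the 10 trial scores against the
  full-model score. When trial scores have zero variance the statistic is
  undefined; p is reported as 1 if the mean equals the reference (and 0
  otherwise) and the subject is flagged. We report raw p-values and flag
  p < α (default α = 0.01) as imbalance-sensitive, keeping the standard
  hypothesis-testing convention.

## Rigid alignment

`align_cohort()` centres every sample (bounding-box centre — a documented,
configurable choice), picks a medoid reference (the sample whose fixed-seed
area-weighted surface resampling is closest, by symmetric Chamfer distance,
to the pointwise mean cloud), registers each subject's *reference domain*
to the medoid with rigid ICP (closest-point matching + closed-form SVD
fit), and applies each subject's single transform to all of its domains, so
intra-subject geometry is untouched. Alignment is rigid by default; the
paper-level ideal of also factoring out scale is exposed through the
transform utilities but not applied by default, matching how the
experiments were run (scale variability is part of the observed signal).
The pointwise-mean cloud is meaningful because all clouds are sampled with
a common seed from meshes built on a common template; for meshes of
unrelated provenance the medoid choice degrades gracefully (it is only a
reference selection).

## Problem sizes and known limitations

The test suite and the acceptance script run the cohort analyses at
reduced scale, chosen as the smallest sizes at which every qualitative
property is stable: icosphere subdivision 3 (1280 faces per mesh) for
cohort-level work, 128/32/128/32 particles with 40 main iterations for the
converged model used in mode-recovery checks, 64/16/64/16 with 15
iterations per trial for the imbalance experiment, and subdivision 4
(5120 faces, the generator default) for single-pair extraction and
generator checks. The full-scale configuration (512 particles per organ,
64 on shared surface and contour) is exercised through split-only
initialization, which fixes the particle counts without the full
refinement budget.

Known limitations:

* The distance threshold is per-pair, not population-informed; strongly
  varying cohorts need per-dataset tuning.
* Gaussian shape statistics: highly variable shared surfaces can violate
  the compact-Gaussian assumption; non-linear extensions are out of scope.
* The minimum organ-particle-to-contour distance produced by the coupling
  is strictly positive but small near the fence "holes" between contour
  particles; denser contour sampling widens the buffer.
* Uniform-Laplacian smoothing shrinkage at coarse resolutions, discussed
  above.
* Remeshing assumes manifold inputs; mesh repair beyond duplicate-vertex
  merging is out of scope.
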