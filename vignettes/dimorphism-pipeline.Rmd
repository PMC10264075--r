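---
title: "Detecting size-independent shape dimorphism in long bones"
author: "osteomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting size-independent shape dimorphism in long bones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteomorph)
```

## The problem

Detecting sexual dimorphism in a skeletal population is hard when the
dimorphism is not a size difference: two morphs may share the same body
size and differ only in subtle, localized shape features such as the
lateromedial curvature of a femoral shaft or the relative width of the
distal epiphysis.  `osteomorph` implements an end-to-end high-density
3D geometric-morphometrics pipeline for this problem: dense landmarking
with sliding semilandmarks, spline relaxation against a template and a
Procrustes consensus, generalized Procrustes analysis (GPA), principal
component analysis (PCA), and per-axis univariate Gaussian mixture
modeling with BIC model selection, gated by an allometry test.  A
population is called dimorphic on an axis when the mixture prefers exactly
two Gaussian components there *and* the axis scores do not correlate with
log centroid size.

Because real bone scans require manual landmarking, the package ships a
synthetic femur-population generator that reproduces the statistical
structure this analysis is designed to detect, so the whole pipeline is
testable end to end.

## The model and its steps

### High-density landmarks

Each specimen is an ordered set of 3D points with one of three classes:

* **anatomical landmarks** — homologous by definition, never moved;
* **curve semilandmarks** — points along ridge curves anchored at
  anatomical landmarks at both ends, free to slide along their curve;
* **surface semilandmarks** — points on the bone surface, free to slide
  within their local tangent plane.

The default femur census is 25/99/495 (anatomical/curve/surface; 619
points); a complete tibia uses 23/219/483 (725 points).  Fragment
subsets (479 points each) cover the proximal part down to the
anteromedial-flange anchor (11/26/442) and the distal part up to the
fourth-trochanter anchor (10/45/424), so the two share the mid-shaft
surface band.

### Thin-plate splines and bending energy

Semilandmark treatment rests on the 3D thin-plate spline with kernel
U(r) = r and affine terms {1, x, y, z}.  The interpolant maps each source
landmark exactly onto its target; its roughness is the bending energy.
Because the Euclidean-distance kernel is conditionally *negative* definite
in 3D, the non-negative energy is computed as the negated quadratic form
of the non-affine weights against the kernel matrix (equivalently through
the negated upper-left block of the inverted bordered system, the
bending-energy matrix **E**).  The energy is zero exactly for affine
deformations, so location, rotation, and scale differences cost nothing.

### Sliding (spline relaxation)

One sliding iteration solves, in closed form, the generalized
least-squares problem: displace every semilandmark along its permitted
tangent direction(s) so that the bending energy of the reference-to-
specimen deformation is minimal.  Curve tangents are central differences
of curve neighbours; surface tangent pairs come from mesh normals when a
specimen mesh is available, otherwise from a local plane fit of patch
neighbours.  In the landmark-only mode, the *neighbour sets* for the
plane fit are fixed from the template geometry rather than recomputed per
specimen: recomputing them lets each specimen's noise select a different
neighbour combination, which we found manufactures discrete artifact
clusters on higher principal components (the mixture step then reports
them as genuine groups).  After sliding, curve points are re-projected
onto their curve polyline and surface points onto the mesh (when
present); without a mesh the tangent-plane position is kept.  A
step-halving safeguard rejects any update that would increase the
energy, so each relaxation's energy trace is non-increasing by
construction.

The full protocol mirrors standard template-based practice:

1. *(meshes only)* project the template's surface patch onto every
   specimen (TPS warp of the template surface points by the fixed-landmark
   deformation, then snap to the specimen mesh);
2. five sliding iterations against the template;
3. a partial-Procrustes consensus is computed **once**, then two sliding
   iterations against it.  (Re-computing the consensus every iteration is
   available via `recompute_consensus = TRUE`; the fixed target is the
   default because it makes the energy trace provably monotone and
   matches the protocol of computing one consensus for the final
   relaxation.)

Energy traces from the two stages are not numerically comparable: the
reference changes (template vs unit-size consensus) and the bending
energy is not scale-free.  Each trace is monotone within its own stage.

### Superimposition and ordination

GPA is partial Procrustes: every configuration is centered, scaled to
unit centroid size once, and iteratively rotated (proper rotations only;
right-side bones should be mirrored beforehand — `mirror_config`, toggle
in the pipeline) to the evolving consensus until the consensus moves less
than 1e-10 (at most 100 iterations).  The result is rotated into the
consensus' principal-axes frame with deterministic sign choices so output
does not depend on input order or the orientation of any input.  PCA is
the eigendecomposition of the covariance of flattened aligned
coordinates; loadings are sign-fixed (largest element positive) and
components are capped at min(n − 1, 3p).

### Mixture modeling and the dimorphism call

Each scanned PC axis gets a univariate Gaussian mixture fitted by EM for
G = 1..9 under equal-variance and free-variance models; the fit maximizing
BIC = 2·loglik − k·log n is selected (the maximized-BIC convention; negate
the table for the minimized convention).  Initialization is
deterministic — a quantile partition plus ten internally-seeded random
restarts, each run briefly and the best polished to convergence — so the
fit is a pure function of the data.  Fits are rejected from selection
(but still reported) when a component's variance collapses below 1e-12 of
the data variance or its effective membership drops below two points;
without this, spiky zero-variance components win BIC arbitrarily often.
Ties go to smaller G, then to the equal-variance model.

An axis is flagged *dimorphic, size-independent* when the selected G is
exactly 2 and the Pearson correlation between its scores and log centroid
size (`cor.test`) is non-significant at `alpha` (default 0.05;
configurable, and an optional Benjamini–Hochberg correction across axes
can be enabled — none is applied by default).  The scan covers axes 1–5
by default; fragments are re-analysed the same way, and cluster
assignments shared between analyses are compared after the optimal label
bijection.

## The synthetic population

`build_ideal_femur()` constructs a parametric left femur of unit length
(tubular shaft, offset head sphere, greater-trochanter lobe, two distal
condyles) carrying the full landmark census, a triangle mesh, and the
fragment index subsets.  `generate_population()` draws specimens from a
two-morph model:

* **morph A** — laterally bowed shaft (quadratic x-offset peaking at
  mid-shaft, amplitude `curvature_effect`, default 0.03 of bone length)
  with a slight ventromedial head inclination;
* **morph B** — straight shaft with the distal epiphysis widened
  lateromedially (`width_effect`, default 1.10 about the sagittal plane).

The two features are coupled within morph (bowed + narrow vs straight +
wide), matching the empirical observation the analysis targets; an
uncoupled mode exists for ablation.  Mixing is 0.5 (a 1:1 ratio) by
default.  Isotropic Gaussian noise (`noise_sd`, default 0.005 of bone
length) models digitization error; the same mechanism with a smaller sd
serves as operator noise in the repeatability experiment.  Size is drawn
log-normally (`size_sd` = 0.08, about 8% coefficient of variation, a
realistic within-population spread) and applied after the morphed shape
is renormalized to the template's centroid size, so size is carried
exclusively by the drawn factor and is exactly decoupled from morph at
`size_morph_coupling = 0`.  Morph, size, and noise are drawn in separate
blocks from the seed, so a specimen's morph and size do not depend on the
template's landmark count.

What the generator does *not* emulate: taphonomic distortion, ontogenetic
allometry, asymmetry, correlated (non-isotropic) digitization error, and
any within-morph shape covariance beyond noise.  Passing tests therefore
show that the pipeline recovers the structure it assumes, not that real
fossil populations satisfy those assumptions.

## Numerical choices

* TPS systems are solved densely; duplicated source landmarks are an
  error (they make the kernel singular).
* Sliding normal equations get a ridge of 1e-10 times the mean diagonal;
  offsets are exact GLS otherwise.
* The closest-point-on-mesh query prefilters the 48 nearest faces by
  centroid before the exact point-triangle test; on the meshes used here
  this is exact (verified against exhaustive search) and keeps the
  mesh-based protocol fast.
* GPA convergence: consensus shift < 1e-10, max 100 iterations.
  Rank-deficient rotation problems take the deterministic tie-break
  (flip the smallest singular vector to keep det = +1).
* EM convergence: relative log-likelihood change < 1e-6, max 200
  iterations; variance floor 1e-12 of data variance.
* All randomness in the generator, the GMM restarts, and the
  repeatability experiment flows from explicit seeds, and internal RNG
  use restores the caller's RNG state.

## Validation sizes

The test suite validates the statistical claims at these problem sizes:
mixture-selection null and recovery suites at n = 500 over 100 seeds
(G = 1 selected at least 95 times on single-Gaussian data; G = 2 with
mixing proportions within ±0.15 at least 95 times on a ±3 two-component
mixture); the full mesh-based pipeline once at the default census
(619 landmarks) with n = 40 specimens; monomorphic and size-confounded
null experiments on a reduced-census femur (15/30/120) at n = 100 over
100 seeds (n = 100 because BIC component selection is only calibrated to
be consistent at large-enough samples — at a few dozen specimens
occasional spurious two-component calls are expected, as noted under
limitations); and oracle equivalences (grid-search sliding, restarted GPA,
brute-force label bijection, independently coded bending-energy
quadratic form) on small configurations.

## Known limitations

* Landmark-only (mesh-free) sliding keeps tangent-plane positions rather
  than re-projecting onto a surface; after many iterations points can
  drift slightly off the (unknown) surface.  With meshes the drift is
  eliminated by re-projection.
* The mixture scan inherits the small-sample behaviour of BIC: at n of a
  few dozen, occasional spurious two-component calls on noise axes are
  expected (both here and in the reference mixture software), and a true
  1:1 dimorphism can be missed when the sample's morph–size correlation
  is accidentally significant (about one seed in twenty).
* The MNI combination rule (fragment count plus same-side complete count,
  maximized over side and portion) is inferred from the published counts
  it reproduces; other accounting conventions exist.
* Bending energy is computed in the reference frame of each relaxation
  stage; cross-stage energy comparisons are not meaningful.
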