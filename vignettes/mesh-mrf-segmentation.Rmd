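---
title: "Mesh-based multimodal segmentation with an MRF shape prior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesh-based multimodal segmentation with an MRF shape prior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meshseg)
```

## The problem

Small iron-rich nuclei — the substantia nigra, subthalamic nucleus and red
nucleus — are nearly invisible on T1-weighted MRI but show strong contrast
on T2\*-weighted magnitude images and quantitative susceptibility maps
(QSM) at high field.  They are only a few millimetres across, so whole-atlas
registration approaches delineate them poorly, and manual tracing is slow
and rater-dependent.  `meshseg` segments such structures with a deformable
triangle mesh: a single reference mesh per structure is roughly aligned to
each subject, and every vertex then searches for the structure boundary
along its outward normal.

Two models cooperate:

* an **intensity model** that learns, from *unlabelled* training volumes,
  what the boundary looks like in each modality at each vertex, starting
  from rule-based priors (no manual tracings are needed for training); and
* a **shape model**: a Markov random field (MRF) over the per-vertex
  displacements that rewards locally smooth deformations.

## The displacement MRF

Each vertex $i$ carries a scalar displacement $\delta_i$ (mm) along its
outward normal, restricted to the discrete grid on which intensity
profiles were sampled.  The prior over the displacement field is a product
of per-triangle factors,

$$p(\delta) \propto \exp\Big(-\sum_{(ijk)\in T} U(\delta_i, \delta_j, \delta_k)\Big),
\qquad
U(\delta_i,\delta_j,\delta_k) = w\big[(\delta_i-\bar\delta)^2 +
(\delta_j-\bar\delta)^2 + (\delta_k-\bar\delta)^2\big],$$

with $\bar\delta$ the triangle mean.  $U$ is the (scaled) variance of the
three displacements: zero when they agree, increasingly unlikely as they
spread.  Because $U$ depends only on deviations from the triangle mean, a
constant offset of the whole field costs nothing — the prior penalizes
*roughness*, not overall inflation or deflation, which stays driven by the
images.  The weight $w$ is the single user-facing smoothness knob
(dimensionless; defaults 10 for the substantia nigra and red nucleus, 100
for the subthalamic nucleus, whose reference mesh is built at a finer
resolution and therefore has shorter edges).

MAP displacements are found by iterated conditional modes (ICM): starting
from the per-vertex likelihood argmax (the intensity-only solution), each
sweep visits vertices in ascending index order and assigns the grid value
minimizing the local posterior energy, until a sweep changes nothing (cap:
100 sweeps).  ICM only finds local optima, but the displacement posteriors
produced by the intensity model are smooth and the initialization is close
to the optimum; on 12-vertex test meshes where all $3^{12}$ configurations
can be enumerated, ICM attains the global optimum in well over 90% of
random smooth-likelihood instances (the acceptance suite recomputes this).
Ties are broken toward the smaller $|\delta|$, then toward negative
$\delta$, so results are deterministic.

## The intensity model

At each vertex, a profile of $k = \Delta + 1$ samples is taken by
trilinear interpolation at positions $s_j = (j - \Delta/2)\,\ell$ along
the normal.  The step $\ell$ is half the acquisition voxel size and
$\Delta = 2\times 2\,\mathrm{mm}/\ell$, so profiles span $\pm 2$ mm — with
0.5 mm voxels, $\ell = 0.25$ mm and $k = 17$.  The displacement grid
coincides with the sampling grid.

Edge appearance per modality is a mixture over template families declared
by rules:

* **step** templates (inside level for $s<0$, outside for $s\ge 0$), and
* **exponential** templates, $\mathrm{in} + (\mathrm{out}-\mathrm{in})
  (1-e^{-s/\lambda})$ for $s>0$, with decay scales $\lambda$ of 1–3 mm;

each rule row contributes one component per scale, and a flat "no edge"
component is always appended.  Levels are absolute for quantitative
modalities (QSM, e.g. inside 0.1–0.15, outside 0.0–0.05 in susceptibility
units) and relative to "Self" — the modal intensity inside the structure —
for T2\*-like modalities, which carry arbitrary global scaling (profiles
are divided by Self, so templates live on a scale-free axis).  Templates
are convolved with a Gaussian of sd $\sigma^I = 0.5$ samples; we interpret
this smoothness parameter as partial-volume blur of the ideal edge.

Training is EM over latent (component, displacement) pairs, per vertex and
modality, with conjugate priors: template means enter as Normal prior
means with $n_0 = 3$ pseudo-observations; diagonal precisions (one per
sample position on an extended grid of $2\Delta+1$ positions, so that
integer-grid shifts stay tabulated) get a Gamma prior of shape
$\alpha^0 = (k-1)/2 + 3$ whose mean matches the modality's prior residual
sd $\beta/f$ (0.1 relative, 0.0003 absolute); mixture weights get a
symmetric Dirichlet($\alpha = 2$); and displacements carry a Gaussian
prior of width $\sigma_\delta = 2$ mm, normalized on the grid.  All
updates are exact conditional maximizers, so the penalized log-posterior
is non-decreasing — asserted in the tests.  Initialization is
deterministic (at the prior), with at most 100 iterations and a relative
tolerance of $10^{-6}$.

Why an extended-grid parameterization?  A displacement $\delta = m\ell$
means the observed window reads the template $m$ samples off-centre; by
learning means and precisions on positions $-\Delta\ell \dots
+\Delta\ell$, every window is a contiguous slice and the complete-data
likelihood stays an ordinary diagonal Gaussian — which is what makes the
conjugate updates exact.  Positions rarely visited by data windows simply
stay at their prior values.

At segmentation time the displacement log-posterior per vertex adds the
mixture log-likelihoods across modalities (conditional independence) plus
the displacement prior.  Sharper modalities (QSM, whose deconvolution
yields crisper edges) have higher learned precisions and therefore
automatically dominate the posterior — no manual modality weighting
exists anywhere in the package.

## Geometry

Reference meshes are built from voxel masks: a 3×3×3 box erosion (removes
marginal topological defects), nearest-neighbour resampling to an
isotropic working resolution (1 mm for the larger nuclei, native 0.5 mm
for the subthalamic nucleus), then iso-surfacing at level 0.5.  We use
marching tetrahedra on the Kuhn 6-tet cube subdivision rather than
classic marching cubes: it needs no 256-case table, has no ambiguous
configurations, and provably yields a closed orientable manifold, which
the rest of the pipeline depends on.  Ten iterations of mild Laplacian
smoothing (factor 0.2) remove the voxelization staircase; this shrinks
thin features slightly, which is acceptable for the blob-like structures
targeted here.  Orientation is fixed by requiring positive enclosed
volume; 0-based voxel indices map to world mm through the NIfTI affine,
and all geometry is in world mm.

Rasterization marks voxels whose *center* is strictly inside the surface,
by even–odd ray casting along +x with a deterministic perturbation retry
for rays grazing an edge — bit-reproducible across runs.  Signed
distances are negative inside, positive outside; displacements are
positive outward.

## Shape statistics

Because all subjects deform the same reference mesh along its normals,
vertex $i$ corresponds across subjects.  Each subject mesh is registered
to the reference by translation only (the closed form: centroid
difference) — rotations are deliberately excluded because near-spherical
and near-cylindrical shapes make them ill-determined — and the per-vertex
signed distance to the reference surface forms a subjects × vertices data
matrix.  Group contrasts are fitted by OLS per vertex; inference uses
freely-exchangeable label permutations with a mesh TFCE statistic,

$$\mathrm{TFCE}(v) = \sum_h e_v(h)^{E}\, h^{H}\, \mathrm{d}h,$$

where $e_v(h)$ is the surface area (one-ring barycentric vertex areas) of
the suprathreshold component containing $v$.  Defaults $H = 2$, $E = 1$,
$\mathrm{d}h = \max/100$ follow standard surface-TFCE practice; the
familywise error rate is controlled with the permutation null of the
maximum TFCE statistic, both contrast signs reported separately for
thresholding at 0.025 per tail.  When the number of distinct two-group
assignments does not exceed the requested permutation count the space is
enumerated exhaustively, making p-values seed-free.

## The phantom generator

The synthetic module renders deformed ellipsoids ("nuclei") on isotropic
grids in two modalities whose contrasts mimic the application: a
T2\*-like modality with outside/inside ratio 1.33 and a QSM-like modality
with absolute levels 0.12 inside / 0.02 outside, both with exponential
edges ($\lambda = 1$ mm) and additive Gaussian voxel noise (sd 0.02
relative and 0.01 susceptibility units — a high-SNR 7 T-like regime,
chosen once as defaults).  Intensity is a function of the radial signed
distance to the implicit surface — exact for spheres, near-exact for the
mild deformations used — so the edge profile along any normal matches the
model's template family by construction.  Truth masks are defined as the
rasterization of the truth mesh, making mask/mesh consistency exact.
Cohorts jitter structure size log-normally (sd 5%) and can plant
multiplicative group volume effects and additive intensity effects; a
manifest records every true parameter and per-subject seed, so cohorts
re-render bit-identically.

What the phantoms deliberately do *not* emulate: MR physics (no k-space,
no dipole convolution or phase unwrapping), anatomy beyond smooth blobs,
bias fields, or inter-scanner intensity variation.  Passing the phantom
recovery tests therefore demonstrates the correctness of the estimation
machinery under the model's own assumptions, not performance on real
scans.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: a 44³ grid at 0.5 mm
with a 5 mm-radius structure; 10 training and 5 held-out subjects for the
end-to-end study (reference mesh ≈ 1400 vertices at 1 mm working
resolution); 50 exhaustive-enumeration ICM instances on a 12-vertex
icosahedron with a 3-point grid; 100 null cohorts × 250 permutations for
FWER calibration and 25 replicates × 500 permutations for power, on a
162-vertex icosphere.  These sizes were chosen so the whole suite runs on
a laptop-class single core in a few minutes while keeping every estimate
well away from its decision boundary.

Numerical details worth knowing:

* Field values lying exactly on the iso-level are nudged inside by
  $10^{-4}$ of the field range before extraction, so no degenerate
  triangles arise.
* ICM ties break toward smaller $|\delta|$, then negative $\delta$;
  sweeps visit vertices in ascending index order.  The MRF weight
  multiplies each triangle energy before summation (equivalent to
  multiplying the sum).
* The likelihood tables are normalized per vertex
  ($\sum_\delta e^{\log p} = 1$ to $10^{-9}$); ICM asserts a finite table
  and the posterior energy decreases monotonically across accepted
  updates.
* Increasing $w$ weakly decreases the variance of the output field;
  because ICM is a local optimizer this holds up to rare exceptions
  (observed in about 1% of random instances), and the test suite asserts
  a ≤ 5% violation rate rather than strict monotonicity.
* The modal ("Self") intensity uses 100 equal-width bins between the 1st
  and 99th percentiles inside the mask — deterministic and robust to
  outliers.

## Known limitations

* Per-vertex models are trained independently (hyperparameters shared);
  sharing components across vertices could be more statistically
  efficient for very small training sets but is not implemented.
* No self-intersection check after displacement; with $|\delta| \le 2$ mm
  and the MRF smoothing this has not been observed on the target
  geometry.
* Non-rigid registration to a template space is consumed as an input
  (affine text file or dense warp NIfTI), never computed.
* No bias-field correction or cross-scanner harmonization; T2\*-like
  modalities rely on the Self normalization being sufficient.
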