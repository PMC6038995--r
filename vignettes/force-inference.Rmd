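---
title: "Reconstruction and force inference: models, conventions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstruction and force inference: models, conventions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The mechanical model

`embryoforce` treats the early embryo as a collection of fluid-like cells:
each cell `c` carries a uniform pressure `P_c`, each membrane face `k` (the
interface between one pair of cells, or between a cell and the exterior
medium) carries a single isotropic tension `T_k`. Dissipative forces are
ignored, so the observable geometry is assumed to be an equilibrium of two
kinds of balance relations:

* **Young–Laplace**, one per membrane face: `P_i − P_j = 2 H_k T_k`, where
  `H_k` is the face-averaged mean curvature;
* **junction balance**, two per triple junction: the three membrane tensions
  pulling on the junction line must cancel in the plane normal to the
  junction tangent, `T_i + T_j cos θ_ij + T_k cos θ_ik = 0` and
  `T_j sin θ_ij − T_k sin θ_ik = 0`, with `θ` the dihedral sector angles
  averaged along the junction.

Two gauge rows close the system: the exterior pressure is pinned
(`P_0 = P_b`, default 0) and the mean tension is set to 1
(`Σ T = n_m`). Stacked together these give an overdetermined linear system
`M x = b` for `x = (P_0, P_1..P_nc, T_1..T_nm)`, of size
`(n_m + 2 n_j + 2) × (n_m + n_c + 1)`; the inequality
`n_m + n_c + 1 ≤ n_m + 2 n_j + 2` holds for every topology the package
accepts, and `solve_forces()` returns the unique least-squares solution
(computed by QR; identical to the pseudoinverse `(MᵀM)⁻¹Mᵀ b` for a
full-column-rank `M`, and rank deficiency is an error rather than a silently
regularised solve).

Everything the matrix needs — the topology, the `H_k` and the `θ`'s — is
measured from a 3D membrane image by the reconstruction stages described
next.

# Sign conventions (the one place to get them right)

All stages share one orientation convention, stated here once:

* For face `{i, j}` with `i < j`, normals point **from region i into region
  j**. The exterior is region 0, so exterior-face normals point *into* the
  cell.
* Mean curvature follows `κ = −n·dt̂/ds`: a convex surface with *outward*
  normals has `κ = +1/R`; consequently an exterior face under the i→j
  convention (inward normals) reports `H = −1/R`.
* With these two choices the Young–Laplace rows `P_i − P_j − 2 H_k T_k = 0`
  reproduce the physics: a single pressurised cell gets
  `P_1 = P_0 + 2T/R`, and an interface bulges towards the lower-pressure
  neighbour.

Any globally consistent alternative would work equally well; mixing
conventions between stages is the chief implementation hazard, which is why
the package fixes them centrally and the synthetic ground truth is generated
in the same convention.

# Morphological reconstruction

**Segmentation.** The input is a membrane *probability volume* (per-voxel
membrane-ness in `[0, 1]`, e.g. from supervised pixel classification, which
is outside this package's scope). `segment_cells()` quantises the landscape
to 256 levels and floods it with Meyer's watershed (26-connectivity) from
regional-minimum seeds; seed plateaus whose voxel sets come within
`min_seed_distance` (default 5 voxels) are merged first. Voxels where two
fronts meet form the one-voxel membrane ridge; ridge voxels seeing exactly
two region labels in their 26-neighbourhood belong to that pair's face,
voxels seeing three or more seed the junction topology. The exterior is the
largest border-touching region whose mean probability is below
`exterior_threshold` (default 0.5); ambiguity is an error, not a guess. The
256-level quantisation is a numerical choice: it bounds the flooding-queue
memory and discards probability differences below 1/255, which is far below
any meaningful class-probability resolution.

**Sub-voxel crest refinement.** Ridge voxels carry integer coordinates. For
shallow surfaces this is destructive: an interface whose sagitta is one or
two voxels (the nearly-flat membrane between two cells of similar pressure)
is terraced into flat plateaus and its tilt near the junction is lost
entirely, which in turn biases every dihedral angle. The probability map
still contains the sub-voxel membrane location, so `refine_cloud_crest()`
moves every ridge point along its estimated normal to the
quadratic-interpolated maximum of the probability profile (samples one voxel
either side, trilinear interpolation, move clamped to one voxel). This is
the standard sub-pixel ridge localisation of image analysis, applied once
between ridge extraction and the final smoothing pass.

**Smoothing and normals.** Each face's point set is smoothed by the local
PCA scheme: for every point, the normal `η` and a shift `t` along it
minimise `Σ ((x_k − (p + tη))·η)²` over the `K_S` nearest same-face
neighbours; the closed form takes `η` as the smallest-eigenvalue eigenvector
of the neighbour covariance and `t` as the projection of the centroid
offset. Signs are made consistent by propagating along the minimum spanning
tree of the k-nearest-neighbour graph (`k = 8`, Euclidean weights) — the
standard practical surrogate for the exact Euclidean MST, which would cost
quadratic time at these cloud sizes — and the global per-face sign is
calibrated against the label volume by probing both sides of sampled
points.

**Curvature.** At every smoothed point a quadric
`z = a u + b v + c/2 u² + d u v + e/2 v²` is fitted over the `K_C` nearest
neighbours in the local tangent frame; the Weingarten map of the fitted
patch gives the mean curvature (in the sign convention above) and the
normal is updated by the fitted slope, `η → η − (a t₁ + b t₂)/√(1+a²+b²)`.
`K_C = 50` is the default; on dense clouds the *face-averaged* `H_k` is
insensitive to this choice over more than an order of magnitude (the test
suite checks a 10 % band across `K_C ∈ {50, 800, 3200}` on a sphere cloud),
which is why the fast small value is used. `K_S` defaults to the same 50.
Points with degenerate neighbourhoods (covariance eigenvalue gap ratio
below `1e-6`, or a rank-deficient quadric design) are excluded from face
averages.

**Junctions.** A membrane point belongs to a junction when it lies within
`d_T` (default 2 voxels) of both other member faces. The band of points is
thinned onto a curve by replacing every point with the centroid of its
`K_J = 50` nearest junction points (single pass). At each thinned point the
junction tangent is `m̂ ∝ n̂₁×n̂₂ + n̂₂×n̂₃ + n̂₃×n̂₁`; each face normal is
projected into the plane normal to `m̂`, the in-plane surface tangents
`t̂_i = m̂ × n̂'_i` are flipped to point along their own membrane (using the
local direction towards the face), and the three *sector* angles partition
2π exactly — the partition is resolved with the orientation of the normal
plane rather than unsigned vector angles, so θ₁₂ + θ₁₃ + θ₂₃ = 2π holds
per point by construction. Per-junction angles are plain arithmetic means
along the curve, with no endpoint trimming.

**Where the junction normals come from.** Within a few blur widths of a
junction, all three membranes contribute intensity: ridge positions, crest
refinement and local fits are all systematically distorted there, and the
distortion does not shrink with resolution because it is tied to the
physical width of the membrane profile. The package therefore evaluates
each face's normal at a junction point by *transport from a clean anchor*:
the nearest face point at least `anchor_dist` away (default 12 voxels,
about eight blur widths for the default profile) supplies its fitted
quadric, whose normal field is evaluated at the junction point
(`quadric_normal_at()`); eight anchors are averaged to suppress per-anchor
fit noise. The transport cost is third order in (distance / surface
radius), so it vanishes for well-resolved cells, while anchoring removes
the junction-zone bias. Setting `anchor_dist = 0` recovers the plain
closest-point evaluation.

# The synthetic two-cell family

`two_cell_truth(L, pressure_ratio)` builds the axisymmetric equilibrium of
two spherical caps (radii `R1 = 5L`, `R2 = 4L`) joined by a spherical-cap
interface across a circular junction of radius `d = 3L`, all in voxel
units. Fixing `P_1 = 1` and the exterior at 0, the outer-cap tensions follow
from Young–Laplace; the interface tension and direction follow from the
meridian tension balance, and the interface curvature
`H_3 = (P_1 − P_2)/(2 T_3)` is automatically consistent with the junction
geometry (`|t_{3,x}| = d/R_3`). Tensions are rescaled to mean 1. The
configuration satisfies every balance relation to machine precision, which
the tests verify both through the stored closed forms and through a
brute-force finite-difference tangent balance at 10⁴ sampled junction
points. `pressure_ratio = 1` gives an exactly flat interface; the feasible
ratio interval (all sector angles away from 0 and π by 10°) is computed by
bisection and spans roughly 0.22–7.

`render_two_cell()` emulates a pixel-classification probability map: the
per-voxel probability is a Gaussian profile of the distance to the nearest
analytic surface, truncated to exactly zero beyond four widths (below the
quantisation step, and it keeps cell interiors as flat watershed seeds).
The default width is `0.15 L` voxels — *fixed in physical units* across the
resolution family, 1.5 voxels at the coarsest scale `L = 10`. This is the
deliberate reading of a resolution study: the same specimen and optics
sampled on finer grids, so the membrane profile spans proportionally more
voxels as `L` grows. What the generator does **not** emulate: photon shot
noise, anisotropic PSFs, classification errors, intensity inhomogeneity —
so passing the synthetic acceptance bounds demonstrates correctness of the
geometry and inference machinery, not robustness to real microscope noise.

The reproducibility perturbation (`reprocess_volume()`) rounds the smoothed
cloud back onto the voxel grid, diffuses it three voxels with a linear
intensity decay, and re-runs the pipeline. Because the rounding erases
sub-voxel information by construction, the round trip is meaningful for the
integer-grid workflow (`refine_crest = FALSE` on both sides), where inferred
forces reproduce to within a few percent; the refined workflow is *more
accurate* but necessarily sensitive to rasterisation of its input, so
comparing a refined run against a reprocessed one measures the value of the
sub-voxel information rather than reproducibility.

# Error reporting and sensitivity

`membrane_residuals()` reports the signed relative Young–Laplace error
`(P_i − P_j − 2H_kT_k)/(|P_i| + |P_j| + |2H_kT_k|)` (pressures measured from
`P_b`), split into outer and inner faces. `junction_residuals()` reports the
norm of the two balance-equation residuals divided by the mean total
junction tension. `sensitivity_spectrum()` returns the singular values of
the pseudoinverse (the amplification factors of perturbations `δb → δx`;
"eigenvalues" of the rectangular pseudoinverse are read as singular values,
cross-checked against the eigenvalues of `(MᵀM)⁻¹` being their squares).
The dominant mode is always the constant-pressure/zero-tension direction —
amplified, but harmless, because only pressure differences from the
exterior are interpreted.

# Cell tensors

`cell_stress_tensors()` integrates the interfacial traction over each
cell's membranes: `σ = −(P_c − P_b) I + (1/V) Σ_k T_k ∫ (I − n̂n̂ᵀ) dS`,
the unique form consistent with Young–Laplace on a closed surface (by the
surface divergence theorem it equals the volume-averaged moment of the
traction `2HTn̂`). For an isolated equilibrium sphere the two parts cancel
exactly — the mean stress of a self-balanced droplet vanishes — which the
tests use as the closed-form oracle. Negative principal values flag
compressive directions. `cell_shape_tensors()` is the area-weighted second
moment of the membrane surface about the cell centroid divided by volume
(`τ = R·I` for a sphere); it is written as a surface integral, and a
volume-integrated variant is available behind `volume_integral = TRUE`.

Surface integrals over mesh-free clouds need an area element: each point
gets `a_i = π r_K²/K` from the radius of its `K = 16` nearest-neighbour
disk. This estimate is orientation-unbiased on smooth uniformly sampled
clouds (counting exposed voxel faces instead would overestimate tilted
surfaces by up to √3) and automatically compensates non-uniform sampling
density. Cell volumes and centroids come from the label volume (voxel
counts times voxel volume).

# Problem sizes and defaults

The acceptance computations run the full pipeline on the two-cell family at
`L ∈ {10, 20, 40}` (cell diameters of roughly 45–180 voxels across the
family, volumes up to ~1.4×10⁸ voxels) for five pressure ratios spanning
0.7–1.1, and assert the tension-recovery, Young–Laplace-residual and
junction-residual bounds at every grid point. The routine test suite runs
the same checks at `L ∈ {10, 20}`, which keeps the whole suite in a few
minutes; nothing about the method changes with `L` beyond memory and time.

Parameter defaults, collected: `K_S = K_C = K_J = 50`, `d_T = 2` voxels,
`anchor_dist = 12` voxels (scaled with the blur width by the two-cell
driver), `min_seed_distance = 5` voxels, `exterior_threshold = 0.5`,
`P_b = 0`, `length_scale = 1` (curvatures stay in 1/voxel; pressures are
then tension per voxel — supply the physical voxel edge to convert).

# Known limitations

* Tension is one scalar per face: anisotropic or spatially varying tensions
  are out of scope, as are bending elasticity, external (eggshell)
  tractions, and viscous forces. The inference is an equilibrium snapshot.
* Junctions are curvilinear triple lines; four-fold vertices are not given
  their own geometry (candidate voxels seeing four labels are simply not
  used as junction evidence).
* The watershed ridge convention needs membranes at least faintly visible
  everywhere; holes in the probability map become label leaks.
* Sub-voxel refinement assumes a locally symmetric intensity profile across
  the membrane; strongly one-sided staining would bias it.
* The normal-transport anchor distance trades junction-zone bias against
  extrapolation error; for cells only a few blur widths across there is no
  clean anchor zone, and angle quality degrades accordingly.
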