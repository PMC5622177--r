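---
title: "Methods: image-based finite element models of vertebrae"
author: "vertefem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based finite element models of vertebrae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The modelling problem

A vertebral body potted between two cement endcaps is compressed axially in
a materials testing machine until failure; its apparent stiffness is the
steepest slope of the load-displacement record. A specimen-specific
continuum-level finite element model of the same test is built from a
micro-CT scan: the image is normalised to 8-bit grayscale, down-sampled to
the element size, segmented into bone and cement, meshed with uniform
voxel-sized elements, and each bone element is given an isotropic elastic
modulus proportional to its average grayscale,

$$E_\mathrm{ele} = \alpha \, GS_\mathrm{ele} \quad \mathrm{(GPa)},$$

with a single species-level conversion factor $\alpha$ (GPa per grayscale
unit). Because grayscale encodes mineral density at continuum scale, this
one linear law absorbs bone volume fraction, mineralisation and (in an
averaged way) architecture. $\alpha$ is calibrated by minimising, over a
calibration group of specimens, the normalised stiffness RMSE

$$\mathrm{RMSE} = \sqrt{\tfrac{1}{N}\sum_i
  \left(\tfrac{k^\mathrm{sim}_i - k^\mathrm{exp}_i}{k^\mathrm{exp}_i}\right)^2},$$

and then assessed on an independent validation group, with agreement
summarised by Lin's concordance correlation coefficient and a Bland-Altman
analysis. Trabecular morphometry (BV/TV, mean-intercept-length fabric,
degree of anisotropy, trabecular orientation) characterises the
architecture that the continuum law averages out.

Everything in this package runs end-to-end on synthetic phantoms, so the
entire chain is testable on a desk without scan data.

# Units

Millimetres, GPa and kN throughout: since GPa·mm² = kN, reaction forces
come out in kN and stiffness in kN/mm with no conversion factors.

# Pipeline stages and their parameters

## Grayscale normalisation

Raw scanner volumes may contain negative values; these are truncated to
zero, then values are scaled by $255/M$ and rounded half-away-from-zero to
integers in $[0,255]$. $M$ is by default the volume's own post-truncation
maximum; supplying `referenceMax` instead keeps the grayscale scale
consistent across the specimens of one study, which matters because a
single $\alpha$ is calibrated per species. Both behaviours are supported
because either reading of "consistently normalised" is defensible; the
choice is recorded in the pipeline log. Half-away-from-zero rounding is
used everywhere grayscale becomes an integer, for predictable behaviour at
`.5` boundaries.

Images from a second scanner type are mapped onto the reference scanner's
grayscale convention by a configurable affine map
`clamp(round(gain*g + offset), 0, 255)`; the gain and offset come from an
external cross-scanner phantom calibration, which is outside this
package's scope.

## Partial-volume down-sampling

Each coarse voxel's value is the overlap-weighted mean of the fine voxels
it covers (a fractional-overlap box filter, not interpolation), so mean
intensity is conserved up to rounding — the property that makes
grayscale-derived moduli insensitive to the resolution change. Boundary
voxels only partially covered by the source grid are normalised by the
covered volume. The default target spacing of 1 mm is the continuum
element size: larger than individual trabeculae, small against the
vertebral body.

## Segmentation

Continuum masks are produced by thresholding (default: Otsu on the
nonzero-voxel histogram), morphological closing with a ball of
`closingRadius` voxels (default 2) to fill trabecular porosity, keeping
the largest connected component, and splitting the foreground axially at
two user-supplied cement-plane coordinates: between the planes is bone,
outside is cement. Plane-based splitting replaces the interactive
separation a GUI tool would offer: it is deterministic and scriptable. The
closing treats the volume boundary as background for dilation but counts
only the in-bounds kernel for erosion, so endcaps touching the image faces
are not eroded away.

## Meshing and materials

One 8-node trilinear brick per labelled voxel, nodes de-duplicated,
element size equal to the down-sampled voxel size. The mesh is hex-only by
design: voxel hexes keep the stiffness matrix well-defined and exactly
reproducible, at the price of stair-stepped surfaces; mixed
tetrahedral/hexahedral surface meshing is a property of proprietary
pipelines and is deliberately not replicated. Bone elements get
$E = \max(\alpha\,GS, E_\mathrm{floor})$ with $E_\mathrm{floor} =
0.001$ GPa so zero-gray elements cannot make the system singular; cement
elements get 2.45 GPa. Poisson's ratio is 0.3 for both. The Abaqus deck
writer groups element moduli into at most 255 material sections, mirroring
8-bit grayscale resolution; with fewer distinct moduli than sections the
file round-trips losslessly.

## The compression solve

Small-strain linear isotropic elasticity on trilinear bricks with 2x2x2
Gauss quadrature. The experiment is reproduced by clamping the bottom
endcap surface and tying the top surface to a rigid plate through the
linearised rigid-body constraint $u = u_\mathrm{ref} + \theta \times (x -
x_\mathrm{ref})$ with a 6-dof reference point: axial translation
prescribed (default 1 mm), lateral translations fixed, all rotations free
— the kinematics of a ball-loaded plate, without contact. Apparent
stiffness is the axial reaction at the plate divided by the prescribed
displacement. The reduced system is solved by sparse Cholesky
factorisation below 300k dof and by Jacobi-preconditioned conjugate
gradients (relative tolerance 1e-9) above.

The experiment itself is quasi-static and geometrically non-linear; this
package deliberately uses linear kinematics. At ~1 mm displacement on
~40 mm specimens geometric effects are small, but a calibrated $\alpha$
can differ by a few percent from one obtained with a non-linear solver;
comparisons against published conversion factors should expect that
offset, compounded by the hex-only meshing.

A separate `uniaxial-oracle` boundary mode prescribes only axial
displacements on both faces, leaves lateral motion free and pins the
in-plane rigid-body modes at locations compatible with a uniform-strain
state. In that mode constant-strain fields are exactly representable, so
closed-form answers ($EA/L$ for a homogeneous cuboid; the series-spring
formula for layered ones) hold to machine precision and serve as solver
oracles. The two-layer series formula is exact only at $\nu = 0$ —
differing Poisson contractions otherwise couple the layers at their
interface and stiffen the model (about +0.6% at $\nu = 0.3$) — so the
oracle tests set $\nu = 0$ and the material container accepts that value;
all physical runs keep 0.3.

## Experimental stiffness extraction

"Largest slope over a 0.6 mm moving aperture" is implemented as the
ordinary-least-squares slope of load on displacement in a window whose
left edge steps one sample at a time, maximised over window positions.
OLS-per-window rather than differentiating a smoothed curve: both agree
exactly on noiseless piecewise-linear curves, and OLS has a well-defined,
noise-robust estimator variance. Windows with fewer than three samples
are skipped; trailing windows truncated by the end of the record are not
used. Input CSVs may carry load in N or kN (declared by the header);
everything is stored as kN.

## Calibration

Brent scalar minimisation of the normalised RMSE over $\alpha$ — the
golden-section/parabolic algorithm as implemented in `stats::optimize` —
with every objective evaluation re-running the FE solve at the probed
$\alpha$ (cached per specimen and $\alpha$, so optimizer traces are
reproducible). Stiffness is exactly proportional to $\alpha$ only for
all-bone or rigid-cement models; with deformable fixed-modulus cement the
endcaps act in series with the bone, so no shortcut is taken and each
probe is solved.

Two early-termination criteria are provided, reflecting the common
practice of stopping a stiffness calibration once the fit is good enough:
stop when the objective reaches `rmseStop` (default 0.1, i.e. 10% RMSE),
or when the objective changes between successive evaluations by less than
`relChangeStop` (default 1e-3) of its current value. The "0.1 threshold
on the objective or its variation" is genuinely ambiguous between those
two readings, so both are implemented, both are configurable, and the
termination reason is recorded in the result. Precision studies (oracle
equivalence, parameter recovery) must disable both stops — at 10% RMSE
the search is orders of magnitude looser than a 0.5% recovery tolerance.

The default bracket (1e-5, 0.1) GPa per gray spans plausible vertebral
conversion factors (published values cluster near 0.007-0.010) with two
orders of margin on either side. If the minimiser lands on a bracket end,
the bracket is widened once by a factor of ten on that side; a second
boundary hit is an error rather than a silent extrapolation.

The analytic companion `closedFormAlpha` gives the exact minimiser
$\alpha^* = \sum r_i / \sum r_i^2$, $r_i = k^\mathrm{unit}_i /
k^\mathrm{exp}_i$, valid when stiffness is proportional to $\alpha$; it
is used as the independent oracle against which the Brent path is tested,
never as the production path.

## Morphometry

Morphometry runs on the high-resolution binary microstructure, not the
1 mm continuum image — at continuum resolution there is no architecture
left to measure. The ROI is the largest cylinder, axis fixed to the
superior/inferior direction, inscribed in the intersection of the
per-slice convex supports of the trabecular compartment between the
endplates (via a 2-D distance transform). Mean intercept lengths are
measured along a deterministic golden-angle hemisphere spiral of
directions (default 512), with parallel test lines spaced 2 voxels apart
(grid origin jittered per direction by a seeded uniform offset to break
aliasing against the voxel lattice) and samples every half voxel;
crossings are bone/background sign changes at voxel resolution. The
ellipsoid tensor is fitted by least squares on $n^\top H n = 1/\mathrm{MIL}^2$,
eigen-lengths are $1/\sqrt{\lambda}$, and the degree of anisotropy is the
`1 - Lmin/Lmax` convention of BoneJ 1.x, consistent with published DA
values for these species lying in roughly 0.32-0.79 on a $[0,1)$ scale.

Degenerate, plate-like structures drive the in-plane MIL toward infinity
and the corresponding eigenvalues of $H$ toward zero; fit noise can then
push them slightly negative. Eigenvalues down to -5% of the largest are
treated as noise around the singular limit and floored at 1e-6 of the
largest (DA then saturates just below 1); anything more negative is an
error. Directions with zero crossings are dropped; if more than 20% drop
the structure is outside MIL's working range and an error is raised.

## Statistics

Shapiro-Wilk, Kruskal-Wallis and pairwise rank tests are delegated to the
standard library implementations; p-values are reported raw, without
multiplicity correction, as is conventional for small exploratory
between-species comparisons. The between-species comparisons are
unpaired, so the post hoc test used here is the unpaired Wilcoxon
rank-sum test (a signed-rank test would presume a pairing between
species groups, which does not exist for groups of unequal size). Lin's
CCC uses population (1/n) moments per its original definition — worth
stating because group sizes are small and the 1/n vs 1/(n-1) choice is
visible at n = 6-8.

# The synthetic phantom

The phantom emulates exactly the features the pipeline consumes: a
cylindrical vertebral body (default 24 mm diameter, 20 mm height) with a
solid cortical shell (1 mm), a trabecular interior, uniform cement slabs
above and below (4 mm), 8-bit-range grayscale levels (bone 180, cement
90, background/marrow 20) and optional additive Gaussian noise, at 0.5 mm
voxels — small enough that every stage runs in seconds on one CPU.

The trabecular texture is white noise smoothed by a Gaussian kernel
(lateral correlation length 0.5 mm, axially elongated by the
`anisotropyStretch` factor) and thresholded at the quantile that realises
the requested BV/TV, so bone volume fraction and degree of anisotropy are
continuously and independently controllable, and identical seeds give
bit-identical volumes. Synthetic load-displacement curves have a
quadratic toe (slope continuous at its end), a linear region of known
slope and a post-yield plateau, with seeded additive load noise.

What the phantom does *not* emulate: posterior elements, endplate
curvature, growth plates, marrow heterogeneity, beam hardening, scatter,
or any scanner point-spread function. Passing tests therefore demonstrate
the correctness and internal consistency of the algorithms — segmentation
scored against known labels, stiffness extraction against known slopes,
calibration against known conversion factors — not fidelity to any real
scanner or species. Published per-species values (conversion factors
around 0.007-0.010 GPa per gray, calibration RMSE below 16%, validation
below 22%) require the original scan repository and are treated as
external benchmarks outside the test suite.

# The packaged demonstration study

`makeDemoStudy()` writes six phantoms (12 mm diameter, 10 mm body, 3 mm
caps, 0.5 mm voxels; BV/TV drawn from 0.35-0.55 and stretch from 1-2.5),
simulates each specimen's "experimental" stiffness at a known
$\alpha_\mathrm{true} = 0.008$ by running the same image pipeline and FE
solve, wraps those stiffness values in synthetic test curves, and emits a
pipeline config with a 3/3 calibration/validation split and the
early-termination stops disabled (the study is noiseless, so the
calibration is run to bracket convergence). `runPipeline()` on that
config must recover $\alpha_\mathrm{true}$ — the tests require 0.5% — and
report near-zero validation RMSE and CCC near 1. These sizes (about 1 800
elements and 20k dof per specimen, 128 test directions where morphometry
appears in tests) are the package's chosen desk-scale defaults: large
enough that BV/TV realisation, segmentation overlap and calibration
recovery are meaningful, small enough to keep the full suite pleasant to
run.

# Known limitations

- Linear kinematics and hex-only meshes: calibrated conversion factors
  are expected to sit a few percent away from values obtained with
  geometrically non-linear solvers on mixed meshes.
- The rigid-plate tie has no contact or lift-off; it is the linearised
  kinematics of the experiment's ball joint.
- MIL direction counts and line spacings reproduce the convention, not
  any specific tool's numerics; exact numeric agreement with legacy
  morphometry software is not claimed.
- The cross-scanner grayscale map is an affine stand-in supplied by
  configuration; deriving it from phantom scans is out of scope.
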