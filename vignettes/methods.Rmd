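---
title: "Methods: epifluorescence 3D traction force microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epifluorescence 3D traction force microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`eftfm` reconstructs three-dimensional substrate displacements and surface
tractions from paired epifluorescence z-stacks of a single layer of
fluorescent microbeads embedded at the surface of a soft elastic hydrogel.
The chain is: Richardson–Lucy deconvolution with an empirically extracted
point spread function (PSF); subvoxel bead localization by the
radial-symmetry method; topology-based particle tracking between the
reference and deformed stacks; rejection of out-of-plane outliers and
curvature-regularized resampling of the scattered displacements onto the
best-fit bead plane; a finite-element forward solve of the compressible
neo-Hookean substrate with the planarized displacements as the top-surface
Dirichlet condition; and Cauchy traction recovery on the deformed top
surface.  A synthetic-data generator produces bead-layer image pairs with
analytically known displacement and traction fields, so every stage can be
scored without experimental data.

# The forward model and its assumptions

The substrate is a homogeneous isotropic hyperelastic solid with strain
energy density

$$\Psi = \tfrac{\mu}{2}(\operatorname{Tr}\mathbf{C} - 3)
        - \mu \ln J + \tfrac{\lambda}{2}(\ln J)^2,$$

with $\mathbf{C} = \mathbf{F}^T\mathbf{F}$, $J = \det\mathbf{F} > 0$, and
Lamé constants $\mu = E/2(1{+}\nu)$, $\lambda = E\nu/(1{+}\nu)(1{-}2\nu)$
from the user-supplied Young's modulus and Poisson's ratio.  The
volumetric term carries the coefficient $\mu$ on $\ln J$: without it the
reference configuration would not be stress-free, since
$\partial\Psi/\partial\mathbf{F}|_{\mathbf{F}=I} = (\mu - c)\,I$ for a
$c\ln J$ term.  One occasionally sees the form typeset without that
coefficient; the implementation uses the standard stress-free form and the
test suite pins $\Psi(\mathbf{F}=I)=0$ and
$\Psi(\operatorname{diag}(1.1,1,1)) = 26.16$ Pa at $E=1500$ Pa,
$\nu=0.45$.

The Cauchy stress follows as
$\sigma = \mu J^{-1}(\mathbf{B} - I) + \lambda J^{-1}\ln J\, I$ with
$\mathbf{B} = \mathbf{F}\mathbf{F}^T$, and the surface traction is
$\mathbf{T}(\mathbf{n}) = \mathbf{n}\cdot\sigma$ on the deformed top
surface with outward unit normals from a triangulation of the deformed
surface grid.

## Elements and locking

Hydrogels used for traction microscopy are nearly incompressible
($\nu = 0.45$ here), where standard trilinear hexahedra lock
volumetrically.  The solver uses first-order (trilinear) bricks with an
F-bar treatment: the volumetric part of the deformation gradient at each
quadrature point is replaced by its element-centroid value,
$\bar{\mathbf{F}} = (J_c/J)^{1/3}\mathbf{F}$.  The residual integrates
$\sigma(\bar{\mathbf{F}})$ against the standard spatial gradients; in the
tangent, the $\lambda$-stiffness couples the centroid divergences
(consistent with the centroid volumetric sampling) while the deviatoric
and geometric parts remain at the quadrature points.  This tangent is
symmetric and gives fast superlinear Newton convergence at the strains
relevant here (typically 4–12 iterations to a $10^{-8}$ relative
residual); a uniaxial confined-compression patch test is reproduced to
machine precision, and a rotated element is exactly stress-free.

Quadrature is $2\times2\times2$ Gauss.  Stresses are projected to surface
vertices by trilinear extrapolation from the quadrature points of the
top-layer elements with averaging at shared vertices, which reproduces
constant and linear stress fields exactly.  (A natural-neighbor
interpolant is the classical choice for scattered quadrature clouds; on
the structured top-surface grid used here the elementwise extrapolation
has the same reproduction properties and no external geometry
dependency.)

## Mesh

The baseline mesh is a $38 \times 38 \times 18$ tensor-product brick grid
(25,992 elements), graded so the in-plane element density decays as a
Gaussian away from the refinement centre (the region of the cell;
density ratio 3, width 1/6 of the domain) and increases geometrically
towards the top surface where displacement gradients concentrate.  The
grading moves nodes but not the count, so any refinement configuration
with the default counts yields 25,992 elements.  The base mesh lives on a
unit box and is affinely warped per axis to the physical volume; node
positions come from equal-mass quantiles of the density profile, which
keeps all Jacobians positive by construction.  One uniform refinement
(doubling each count) changes the forward solution by well under 1% on
the synthetic validation case, which is the convergence evidence for the
baseline grading.

## Boundary conditions

The default face scheme fixes the left face in $x$, the back face in $y$,
and the bottom face in all components; the top surface carries the
measured planarized displacement vectors.  For the *synthetic validation
scenes* the package instead uses frictionless (roller) walls on all four
lateral faces, and this choice is load-bearing: see "Self-consistency of
the synthetic truth" below.

# Synthetic ground truth

The generator applies a Gaussian out-of-plane traction profile
$t_z(r) = t_0 e^{-r^2/2s^2}$ (full-width half-magnitude
$W = 2\sqrt{2\ln 2}\,s$) to the substrate surface and evaluates the
resulting surface displacement by convolution with the substrate's
surface Green's function in Fourier space.  Exactly one of the total
force $F$ or the peak displacement is prescribed; the solution is linear,
so the other follows by scaling.

Two kernels are available:

* **Half-space** (`depth = Inf`): the convolution with the Boussinesq
  surface Green's function is evaluated in the continuum limit through
  its closed forms,
  $u_z(r) = (1-\nu^2) t_0 s \sqrt{2\pi}/E \; e^{-x} I_0(x)$ with
  $x = r^2/4s^2$, and
  $u_r(r) = (1+\nu)(1-2\nu) F_{enc}(r) / 2\pi E r$ with $F_{enc}$ the
  force enclosed within radius $r$.  These are exact, free of
  periodic-grid artifacts, and reproduce the point-load far field
  $u_z = F(1-\nu^2)/\pi E r$; they serve as the independent oracle in the
  tests.  Note the slow $1/r$ decay: the displacement is still several
  percent of its peak at ten widths from the centre, which is why a
  half-space truth cannot be imposed consistently on a finite
  computational box (below).

* **Bonded layer of finite thickness $h$**: the per-wavenumber surface
  compliance of a layer fixed to a rigid base is computed by direct
  integration of the Navier equations in the transform domain (a
  $4\times4$ matrix exponential per wavenumber; half-space and
  confined-compression limits are recovered at large and small $kh$ and
  pinned in the tests), tabulated over $|k|$ and applied to the analytic
  Gaussian spectrum on an FFT grid.  Sampled values are interpolated
  bilinearly between grid nodes.

## Self-consistency of the synthetic truth

Imposing the surface displacement of an *isolated* load (half-space or
generously padded layer solution) on a finite box with a fixed bottom is
mechanically inconsistent: the imposed field carries long-wavelength
content whose support, in the infinite medium, comes from material
outside the box.  Empirically this inflates the integrated surface
traction by 15–30% *independently of mesh refinement, domain size and
load amplitude* — it is a property of the validation geometry, not of the
solver (per-mode comparisons of the discrete operator against the layer
compliance agree to a few percent, and uniform-compression response is
exact).  The validation scenes therefore define the truth as one unit
cell of a doubly periodic load array: the sampler's Fourier cell is set
exactly to the lateral domain size, and the box uses frictionless walls
on all four lateral faces, which is the exact mirror-symmetry reduction
of the periodic problem for a centred scene.  With this construction the
imposed displacement, the analytic traction, and the finite-element
domain describe identical mechanics, and global force balance closes to
discretization plus measurement error (about 2–3% at the baseline mesh
with noise-free boundary data).  The substrate depth of the validation
scenes is 30.3 µm, matching the axial extent of a typical 101-slice
stack at a 0.3 µm z-step.

## Bead layer, rendering and noise

Bead centres are seeded by dart throwing at 0.0625 beads/µm² (mean
nearest-neighbour spacing ≈ 2 µm ≈ 3 template widths, emulating a dense
but resolvable experimental field) with a 1 µm exclusion radius, and
z-heights drawn from a normal with σ = 0.15 µm (half a z-step) about the
layer plane.  Each bead is rendered by inserting an anisotropic Gaussian
template (σ 0.30 µm in-plane and 1.35 µm axially — the elongated axial
spread of out-of-focus epifluorescence light is what makes deconvolution
necessary) at its subvoxel position via a Fourier phase shift inside a
zero-padded patch, cropped back to the template footprint; overlapping
beads sum.  A constant background of 5% of range and Gaussian white read
noise of 2% of range (a typical sCMOS noise floor) are added last and
intensities are clipped to the dynamic range.  Deformed stacks translate
every bead by the analytic surface displacement at its lateral position,
with row order preserved so ground-truth correspondences are known.

What the generator does *not* emulate: optical aberrations (skew,
spherical aberration), depth-dependent PSF variation, photobleaching
between frames, bead polydispersity, and cell-body autofluorescence.
Passing the synthetic suites therefore demonstrates the correctness and
noise behaviour of the algorithmic chain, not robustness to every
experimental artifact.

# Measurement chain choices

**Deconvolution.**  Classic multiplicative Richardson–Lucy (Poisson
likelihood) with the PSF extracted from an isolated bead: ROI border
median subtracted, clipped, recentred, unit-normalized.  The volume-wide
median background is removed before iterating, edges are handled by
reflective padding, and the mirrored PSF drives the correction step.  The
default is 10 iterations with early stopping once the relative update
norm falls below $10^{-4}$; mixed Poisson–Gaussian extensions are out of
scope.  On the synthetic stacks this compacts the axial bead extent from
≈ 11 slices to well inside the tracker's 3–9 voxel working range.

**Localization.**  Candidate maxima (26-connected) are refined by the 3D
radial-symmetry method — the least-squares intersection of voxel gradient
lines, exact for any radially symmetric blob — inside a window of the
bead radius plus one voxel laterally and two axially.  The detection
threshold is expressed as a fraction of the 99.9th percentile of positive
intensities rather than the maximum, because deconvolution concentrates a
few beads into much brighter peaks than the typical one; duplicates
within one bead radius are merged.

**Tracking.**  Feature vectors are the distance-sorted offsets to the
k = 8 nearest neighbours (translation-invariant by construction); the
match cost is the summed squared difference of the sorted offsets.
Candidates within `max_disp` (default ten median bead spacings) are
scored, mutual-best links kept, and three iterative-deformation passes
warp the reference positions by a neighbour-averaged displacement
estimate while shrinking the search radius.  The normalized-median test
(threshold 2.0 over 8 neighbours, noise floor 0.05 µm) removes vector
outliers.  Ties break by feature cost, then positional distance, then
index, so tracking is deterministic and permutation-invariant.

**Planarization.**  Out-of-plane outliers beyond `n_std = 3` standard
deviations of bead z-height are rejected; the bead plane is fit by total
least squares (orthogonal PCA), correcting stage or gel tilt.  Each
displacement component is then resampled onto the finite-element
top-surface node grid by penalized least squares: bilinear data fidelity
at the projected bead positions plus a discrete thin-plate penalty
$\lambda\,\bar h^4\,(\|D_{xx}u\|^2 + \|D_{yy}u\|^2 + 2\|D_{xy}u\|^2)$
with non-uniform-grid second-difference stencils, where $\bar h$ is the
mean grid spacing, making $\lambda$ dimensionless ("grid units").
In-plane components share `lambda_xy`; the out-of-plane component uses
`lambda_z`; both default to $10^{-3}$ (a default of $10^{-2}$ in this discretization over-smooths the narrowest validation scenes: the thin-plate undershoot halo around the Gaussian core biases the integrated surface force by several percent).  The penalty annihilates affine
fields exactly, so constant and linear displacement fields pass through
unchanged for any $\lambda$; nodes outside the bead hull are filled by
the regularizer and flagged.  The grid *is* the top-surface mesh — one
shared definition, so the hand-off to the solver is exact by
construction.

# Numerical choices and degenerate inputs

* Newton: relative residual $10^{-8}$, at most 25 iterations, load
  stepping doubling up to 10 increments on non-convergence; sparse
  supernodal Cholesky with an LU fallback when a tangent loses positive
  definiteness mid-iteration.
* The linear-elastic reference solution (used by the small-strain
  consistency test) is one tangent solve about the reference state —
  the exact linearization, not a small-load approximation.
* Inverted elements ($J \le 0$) abort assembly with the offending
  element id; degenerate crops, collinear plane fits, empty bead sets,
  unnormalized PSFs and mismatched BC grids are all rejected with
  specific errors.
* The layer compliance switches to its analytic half-space limit for
  $kh > 12$ (relative error $< e^{-24}$), avoiding overflow in the
  matrix exponential.
* Fourier subvoxel shifts are exact for band-limited signals; a zero
  shift bypasses the FFT so integer-positioned insertions are bitwise.

# Validation metrics

The reconstruction error metric is
$|\mathrm{Uncertainty}| = \sqrt{\sum_n (\chi_{meas} - \chi_{imp})^2}/N$
over the $N$ top-surface grid nodes.  As printed, this divides by $N$
(not $\sqrt N$): for a uniform pointwise error $e$ it equals
$e/\sqrt N$, so it shrinks with the number of measurement points.  The
conventional RMS error and the pointwise standard error
($\mathrm{sd}(|e_i|)/\sqrt N$) are reported alongside.  The SNR is the
peak signal magnitude divided by the mean uncertainty — the orientation
that makes the reference values ≈ 300 (displacement) and ≈ 100
(traction) come out as large-is-good ratios.

Problem sizes used by the shipped validation runs: the acceptance script
reconstructs a 512 × 512 × 32 voxel pair (0.16 µm/px, 0.3 µm z-step,
≈ 420 beads) on the 25,992-element mesh; the test suite uses
384 × 384 × 32 pairs and smaller meshes for the property suites.  The
rigid-body suite tracks 256 × 256 phantom pairs translated by
1–15 µm per axis without deconvolution, since the rendered beads already
satisfy the tracker's size requirement and the suite isolates
localization and tracking accuracy.

# Known limitations

* Tractions are attributed entirely to the imposed surface displacement;
  no background-field subtraction is performed.
* The constitutive family is fixed to compressible neo-Hookean;
  viscoelastic or user-supplied energies are out of scope.
* Planarization assumes a single dominant bead layer; volumetrically
  dispersed phantoms are not supported.
* The force integral over the top surface is sensitive to uniform
  offsets of the measured out-of-plane displacement (stiffness
  $\sim M A/h$ for the quasi-uniform mode): nanometre-scale systematic
  bias in $u_z$ moves the integrated force by several percent at the
  smallest validation amplitudes.  This is intrinsic to displacement-
  controlled traction recovery on a finite-thickness substrate, not a
  solver artifact.
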