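---
title: "Modelling implant-bone load transfer and SED-driven remodelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling implant-bone load transfer and SED-driven remodelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osseofe)
```

## The model

`osseofe` models the mechanics of a percutaneous bone-anchored implant
stem cemented into a residual femur.  The construct is idealised as four
concentric, fully bonded parts: a tapered titanium-alloy stem, a PMMA
cement mantle, a 2 mm periprosthetic bone layer, and an outer cortical
wall that continues proximally beyond the stem tip to the residual bone
length.  The global frame is X = lateral, Y = proximal (the bone axis),
Z = anterior; the distal cut is at y = 0.

The governing physics is small-strain linear elasticity.  Given a
stance load applied over the proximal face and a fixed distal face, the
solver returns displacement, strain and stress fields, from which the
strain energy density

$$U = \tfrac12\,\boldsymbol\sigma : \boldsymbol\varepsilon
\qquad [\mathrm{J\,m^{-3}}]$$

acts as the remodelling stimulus.  Under the mechanostat hypothesis,
bone holds a mass-specific stimulus $U/\rho$ inside a homeostatic band;
tissue below the band tends to resorb and tissue above it to appose.
The analysis classifies the cross-sectional area of the bone layer
against that band, slice by slice, and repeats the whole solve for stem
moduli of 20, 115 and 210 GPa to quantify how stem flexibility
redistributes load into the periprosthetic bone.

Key modelling assumptions, each discussed below:

* all part interfaces are fully bonded (osseointegration and an intact
  cement bond are assumed; no frictional contact or slip);
* material behaviour is linear elastic — no viscoelasticity, damage, or
  time-stepping remodelling update;
* the anatomical femur (head, trochanter, curvature) is replaced by a
  parametric cylindrical wall, so the model is desk-scale and fully
  reproducible from a handful of printed dimensions;
* SED classification is a likelihood statement about the *initial*
  remodelling response, not a simulation of bone adaptation over time.

## Geometry and meshing

`assembly_spec()` holds the dimensions: a 0.12 m stem tapering from
12 mm (distal) to 9 mm diameter, a cement mantle 1 mm thick distally,
a uniform 2 mm bone layer, a 5 mm outer wall, and a 0.201 m residual
length.  Where a profile was open, the package fixes it once:

* **Cement taper.** Only "thicker proximally" is known for the mantle;
  the default rule grows the thickness linearly from 1 mm distally to a
  configurable 2 mm at the stem tip.  A `uniform` rule is available for
  verification geometries.
* **Stem bore.** The mesh is a pure structured annulus (concentric
  rings x circumferential sectors x axial layers, no O-grid core
  block), which requires a nonzero innermost radius.  The stem
  therefore carries a 1.5 mm axial cannulation — under 2 % of its
  cross-sectional area, and consistent with the guide-wire cannulation
  of real stems.  All analytic comparisons use the same annular
  geometry, so no verification slack is lost.
* **Distal fixation.** The implant spigot is potted rigidly in the
  experiment and the collar bears on the cut bone surface.  The mesh
  emulates both with one constraint: every distal-face node within the
  18 mm collar/spigot diameter (stem, cement and bone-layer faces) is
  fully fixed.  This matters physically: if only the stem face is held,
  the distal bone layer terminates in a free surface, sheds its load,
  and the distal-to-proximal remodelling gradient reverses.  The outer
  wall's distal annulus (beyond the collar) remains free.
* **Sectors.** Linear elements approximate each circular boundary by a
  polygon whose area is low by $1-\sin\Delta\theta/\Delta\theta$; the
  default minimum of 32 sectors keeps that under 0.7 %, within the 1 %
  volume fidelity budget.  Quadratic (20-node) meshes place mid-edge
  nodes on the true circle and reproduce part volumes to ~0.005 %.
* **Slices.** Remodelling cross sections are 11 equidistant bins,
  1.09 mm apart, starting at the distal end of the bone layer; mesh
  layers are aligned with the slice boundaries so each element belongs
  to exactly one slice.  Trends are reported over slices 1-10.

Element quality is guarded by a positive-Jacobian check at every
integration point, and `refine()` rebuilds the mesh with all division
counts scaled, which is what the convergence analysis uses.

## Materials

Cortical bone is orthotropic with EX = 12, EY = 20, EZ = 13.4 GPa,
Poisson ratios 0.22/0.35/0.38 and shear moduli 5.61/6.23/4.53 GPa,
defined in a cylindrical frame (X radial, Y axial, Z circumferential)
and rotated per element to the global frame with the Bond 6x6
transformation.  Only one Poisson triangle is specified; the conjugate
ratios follow from compliance symmetry
($\nu_{ji} = \nu_{ij} E_j / E_i$), and the completed stiffness must be
symmetric positive definite or the card is rejected.  Cement is
isotropic (2 GPa, 0.40), the stem isotropic (115 GPa, 0.30) with 20 and
210 GPa variants.  Cancellous bone is omitted: the bone plug occupies
the canal, and the dominant diaphyseal response is mediolateral bending
carried by cortex.

The homeostasis band is specified per unit mass (0.0036-0.0044
J g^-1).  Its conversion to volumetric bounds needs an apparent
density, which the source tables never state; the package defaults to
1.8 g cm^-3 — a standard cortical value — giving 6480-7920 J m^-3, and
exposes it as a parameter because the classification scales linearly
with it.

## Load cases

The bench load case (`lc1()`) is a vertical test-machine force of one
body weight, 86 kg x 9.8 m s^-2 = 842.8 N, applied to a femur held at
6.9 degrees adduction, 2.0 degrees flexion, 12.7 degrees anteversion.
The decomposition uses per-component direction cosines
(FX = F sin(add) cos(flex), FY = -F cos(add) cos(flex),
FZ = -F cos(add) sin(flex)); this reproduces all three tabulated
components (+101.19, -836.19, -29.20 N) exactly, which no single Euler
rotation ordering does, and implies the anteversion angle spins the
specimen about its own axis without entering the axial decomposition.
The norm is preserved to 0.2 % at these angles.  The musculoskeletal
stance case (`lc2()`) takes its components (-804.05, -1957.53,
-141.95 N) verbatim rather than re-deriving them from gait data.

Loads are distributed over the proximal face by the rigid-distribution
form $f_i = \alpha + \beta \times r_i$, the unique distribution of that
family matching the resultant force and the moment of a virtual load
point offset from the face centroid.  The default offset of 40 mm
medially stands in for the femoral-head contact, producing the
distally increasing mediolateral bending moment that dominates the
construct's response.  Linearity of the solver makes body-weight
multiples exact scalings, so the 0.33-3.5 BW schedule never requires
re-solving.

## Numerics

* Elements: 8-node trilinear (default) and 20-node serendipity
  hexahedra, full Gauss integration (2^3 and 3^3), no reduced
  integration or hourglass control — chosen so that closed-form
  verification is exact up to quadrature.  Linear is the default
  because the Richardson criterion, not element order, certifies
  accuracy; the bending verification uses quadratic elements, which
  capture curved boundaries and bending fields far more efficiently.
* Solver: sparse supernodal Cholesky (CHOLMOD via `Matrix`), residual
  contract 1e-8 (achieved ~1e-13), factor cached per system for
  repeated load cases.
* Conservation: every solve satisfies the energy identity
  $\sum_e U_e V_e = \tfrac12 f^\top u$ and global equilibrium to 1e-8
  relative, both checked in the test suite.
* Gauges: axial surface strain is evaluated at the element nodes (not
  extrapolated from centroids — centroid sampling underestimates
  surface bending strain by the centroid-to-surface radius ratio) and
  averaged over a 1 mm footprint on the nearest circumferential node
  column, mirroring uniaxial foil gauges.
* Degenerate inputs fail loudly: non-PD material cards name the
  offending eigenvalue, under-constrained systems are reported at
  factorisation, oscillatory convergence sequences are rejected rather
  than extrapolated, zero-mean sensitivity gauges are flagged NA.

### Verification oracles

Two independent mechanics solutions bracket the solver:

* **Axial composite.** A uniform-section bonded composite under a pure
  axial load approaches the transformed-section strain
  $\varepsilon = -F / \sum_i E_i A_i$ in its far field.  The shear-lag
  transfer length through the compliant cement is ~20 mm, so the
  verification geometry is 0.24 m long and measured at mid-length;
  agreement is ~0.05 %, against a 2 % budget.
* **Bending.** A homogeneous cylinder under a transverse tip load obeys
  $\varepsilon_{yy} = M(y)\,x / (EI)$ away from the ends; the quadratic
  mesh agrees to ~1 %, against a 3 % budget.

Section properties for both oracles are computed for the geometry the
mesh actually represents (polygonal boundaries for linear meshes,
circular for quadratic), keeping discretised geometry out of the error
budget.

### Mesh convergence

Accuracy at the working resolution is certified by Richardson
extrapolation over meshes refined by a factor of two in every
direction.  The study solves the bench load case at three levels
(coarsest ~0.6 k, finest ~18 k elements), reads four fixed surface
gauge sites chosen on axial stations present at every level (so the
measurand is the same physical point throughout), and fits the observed
order $p = \ln[(u_{2h}-u_h)/(u_h-u_{h/2})]/\ln 2$.  The observed order
is ~2.2 and the relative error at the finest level is 0.6-0.8 %, under
the 1 % acceptance threshold.  Two design notes: the study meshes carry
no slice band (the band's fixed 1.09 mm layers would refine
non-uniformly and contaminate the ratio), and gauge footprints scale
with the local element so each level samples exactly one station.

## Remodelling classification

`classify()` weights each bone-layer element by its exact
cross-sectional area (volume / axial extent) — there is no
image-based area measurement step, hence no rasterisation error — and
reports per-slice fractions below/within/above the band, which sum to
one by construction.  `stiffness_sweep()` re-solves the same mesh per
stem modulus and summarises peak and mean SED; `trend()` reports the
mean per-step relative change of the apposition and resorption
fractions from distal to proximal, skipping (with a note) steps whose
baseline fraction is zero — the mean-change convention itself is a
package choice, since the source of the headline percentages never
defines one, and those percentages are therefore not reproduction
targets.

At the default study conditions the expected directions emerge: mean
bone-layer SED falls monotonically with stem modulus; per slice, the
apposition fraction is non-increasing and the resorption fraction
non-decreasing in stem modulus, strictly so in aggregate over the
distal slices; and for the 115 and 210 GPa stems apposition falls and
resorption rises moving proximally.  The 20 GPa stem saturates above
the apposition threshold across most slices under the musculoskeletal
load — consistent with the reported anomaly of the most flexible stem
— so slice-trend assertions are made on the stiffer two models.

## Synthetic measurements

The virtual experiment emulates the in vitro instrumentation: four
uniaxial 1 mm gauges (distal/proximal x medial/lateral, at 30 and
95 mm — the exact bench gauge coordinates are not published, so these
stations over the stem are a package convention), read at load steps of
0.33-3.5 BW with independent Gaussian noise per reading at the
per-gauge repeatability SDs (5.2, 8.5, 2.9, 12.7 microstrain), plus a
DIC-like displacement sample over the visible outer surface with 1
micrometre isotropic noise.  All draws are seeded and leave the
caller's RNG stream untouched.

What this does *not* emulate: gauge misalignment, adhesive and surface
preparation effects, loading-ramp hysteresis (the model is elastic;
the dwell protocol is represented as independent repeated readings),
speckle-correlation artefacts, and the camera-dependent visibility
boundary (the DIC region is a configurable axial window instead).
Passing the recovery tests therefore shows the *pipeline* is unbiased
and noise-consistent — not that the model would match a real
experiment, where geometry and contact fidelity dominate the error
budget.

## Problem sizes and runtime choices

The package's own studies run on one CPU in minutes: the working
assembly mesh is 5.5 k linear hexahedra (4 mm edges, 32 sectors), the
stiffness sweep three solves of it, the convergence study 0.6/2.2/18 k
elements, and the bending verification 1.3 k quadratic elements.  All
sizes are parameters; the same code scales to sub-millimetre meshes
(a 0.625 mm edge gives ~0.6 M elements) when a
workstation-class budget is available.

## Known limitations

* Fully bonded interfaces everywhere: the frictional contact states of
  the physical osteotomy interface (and their large effect on distal
  gauges reported experimentally) are out of scope, and this is the
  model's main fidelity deviation.
* Parametric cylinder in place of the anatomical femur: absolute SED
  magnitudes and the cadaver-specific headline percentages are not
  reproducible here; only directions and conservation properties are
  asserted.
* Static, single-step remodelling likelihoods; no density-update law.
* The strain-gauge concordance printed for the bench validation (0.934)
  cannot be recomputed from the four tabulated mean pairs under either
  moment convention and likely involves the untabulated per-increment
  data; it is documented but not a target.
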