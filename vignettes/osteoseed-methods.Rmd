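---
title: "Models and numerical methods in osteoseed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in osteoseed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

osteoseed simulates the first seconds after a multi-layer osteochondral
scaffold is press-fit into a truncated-cone bone defect: marrow floods the
void space around the titanium lattice, carrying bone mesenchymal stem
cells (BMSCs) that attach to the beams and to the surrounding trabecular
walls.  The package also implements the radiograph analysis used to score
bone ingrowth around such scaffolds.  This vignette records the models, the
numerical choices, and the judgement calls a maintainer would want spelled
out.

## Geometry

The titanium layer is a truncated cone (8.0 mm top / 5.9 mm bottom
diameter) filled with sublayers of parallel cylindrical beams, 0.5 mm in
diameter on a 1 mm pitch, each sublayer perpendicular to the one below —
the printed "1 × 1 mm pore" architecture.  Two quantities are not fixed by
the published morphometrics: the sublayer count and the vertical pitch
between sublayer centrelines.  We froze them once at 9 sublayers × 0.92 mm:
the lattice height (8.28 mm) plus the 0.5 mm dense cap then fills the
8.8 mm defect, and the analytic porosity of the infinite lattice,
$1 - \pi r_b^2 / (p\,h) = 0.787$, matches the printed part's 78.6%
characterisation.  Voxelization at 0.05 mm yields 78.3%.  Beams sit at
half-pitch offsets from the cone axis so the layout is symmetric and no
beam degenerates into an axial rod in the axisymmetric surrogate below.

Voxelization is deterministic centre-sampling; porosity is the void
fraction inside the bounding frustum, and the surface area uses a
smoothed-gradient (co-area) estimator — the occupancy indicator is
smoothed with a small binomial kernel and the gradient magnitude is
integrated.  The estimator is within 5% on cubes and capped cylinders at
0.02 mm spacing; for the default lattice it reports roughly 560 mm², with
the estimator tagged in the output because voxel-based area is
convention-dependent in a way porosity is not.

The defect is the drilled truncated cone (8.2 / 5.88 mm, 8.8 mm deep).
The 0.1 mm annular gap between the defect wall and the scaffold top is the
air vent; without it the cavity is sealed, the displaced air has nowhere to
go, and `initialize_flow()` refuses to run.

## Marrow rheology

Bone marrow is a shear-thinning power-law fluid,
$\eta = k\,\dot\gamma^{\,n-1} H(T)$ with $k = 0.017$, $n = 0.708$, clamped
to $[0.001, 0.01]$ Pa s, density 1050 kg/m³.  Units of $k$ are taken as SI
(Pa sⁿ), the standard convention in CFD solvers.  Note $k$ itself exceeds
the upper clamp: below the crossover shear rate
$(k/\eta_{max})^{1/(1-n)} \approx 6.15$ s⁻¹ the viscosity sits on the
upper limit.  We honour the clamps as stated rather than "fixing" $k$.
The Arrhenius temperature factor is the identity (isothermal run); the
enabled form is implemented and clamping is applied after $H(T)$, which is
immaterial when $H \equiv 1$.

## Two-phase flow solver

The filling flow is solved on a 2D axisymmetric $r$–$z$ section
(64 × 96 cells by default) rather than in 3D: the geometry is
near-axisymmetric and the reported attachment trends are radial and
vertical, so a section captures them at a small fraction of the cost.  The
lattice enters the section as a *ring surrogate*: each sublayer's parallel
beams become concentric tori at the beams' distances from the axis,
preserving beam diameter, pitch, layer pitch and therefore porosity and
blockage.  A planar Cartesian metric drives the same kernels for
benchmarks; a full 3D solver mode is deliberately out of scope.

Discretisation: MAC staggered grid, finite-volume continuity with exact
axisymmetric metrics (face areas $2\pi r\,\Delta z$, volumes
$2\pi r\,\Delta r\,\Delta z$), hybrid central/upwind momentum advection
(central wherever the cell Péclet number is below 2 — everywhere at these
Reynolds numbers), implicit viscous step, and an incremental pressure
projection solved with symmetric-Gauss-Seidel-preconditioned conjugate
gradients.  The axisymmetric curvature term $-\mu u_r/r^2$ in the momentum
diffusion is dropped (planar approximation); continuity, which drives the
filling, is exact.  Mixture properties are volume-fraction-weighted;
gravity acts along $-z$; marrow–air surface tension is neglected (no value
is available for that pair, and the Bond number of the 4 mm pool is large);
wall roughness is zero.

The marrow fraction is advected with a conservative van Leer flux-limited
(TVD) scheme.  We chose boundedness and exact conservation over interface
compression: the interface smears over a few cells, which is acceptable at
desk scale, while volume bookkeeping (inflow minus outflow versus resident
volume) closes to machine precision and is asserted to 1% in tests.  The
post-projection divergence tolerance defaults to $10^{-8}$ of the
characteristic rate $u_{char}/\Delta$; the large shared runs in the test
suite use $10^{-6}$–$10^{-7}$, still far below any dynamically relevant
rate, to keep the conjugate-gradient work proportionate.

The solver lands time steps exactly on the fill time and the end time, and
otherwise adapts dt to a CFL limit of 0.4 against the fastest velocity —
in practice the air (later marrow) jet through the vent ring.

Validation: the planar kernels reproduce the classic Re = 100 lid-driven
cavity centreline velocity profile within 0.01 of the lid speed on a 64²
grid, against the standard multigrid reference values; a quiescent closed
cavity is a machine-precision fixed point; with $n = 1$ the power law
degenerates to a constant viscosity and the fields match a
constant-viscosity run to machine precision.

## Cell transport and adhesion

BMSCs are spherical, non-rotating point particles (25 µm, 1000 kg/m³,
surface tension 0.03 N/m — the stated "N/s" is read as the unit typo it
must be), carried one-way by the resolved flow.  The drag is Stokes with
the Schiller–Naumann finite-Re correction; because the response time
$\tau = \rho_p d^2/(18\mu) \approx 7\,\mu s$ is far below any stable dt,
the velocity update uses an exponential integrator that is exact for
carrier velocity and drag frozen over the step — this is what lets the
relaxation and terminal-velocity tests hit closed forms within 1% at any
dt.  50,000 cells (5,000 at trend scale) are injected uniformly over the
inlet faces during the 2.5 s filling window, apportioned by largest
remainder so the cumulative count is met exactly whatever the step
sequence.

Impingements are detected when a particle path enters a solid cell, and by
*touch capture*: a particle whose centre comes within one radius of a
surface has contacted it.  Touch capture matters because inertialess
particles following a no-slip flow approach walls only asymptotically; the
near-wall velocity is linear in the distance, so the travel time to
contact is finite and capture is physical, not a numerical artefact.
Each contact is classified by the impact Weber number
$We = \rho_p d v_n^2/\sigma$: stick for $We \le 5$, rebound to 10, spread
beyond — thresholds in the droplet-impingement tradition, config-exposed,
and essentially irrelevant here because $We \sim 10^{-6}$ at 1 mm/s, so
contacts stick.  Spread is recorded as an attached cell with a footprint
factor; rebounds reflect the normal velocity scaled by the restitution
(0.9 by default; elastic during the pre-attachment window).

Timing of attachment follows the filling protocol: during the first 2.5 s
every boundary face is an active marrow inlet, and a face that is blowing
fluid inward cannot trap cells, so contacts rebound; from 2.5 s the
scaffold "starts to absorb" and the walls — no longer injecting — capture
as well.  The two post-fill working conditions differ only in the cell
source: `no_injection` stops releasing cells at 2.5 s, while
`continued_injection` keeps releasing them from the boundary faces at the
same number rate with a 1 mm/s initial speed.  In the near-stagnant
post-fill fluid those late cells deposit on and near the faces that
released them, which is precisely the rapid growth of boundary-face
density that distinguishes the two scenarios.

Attachments are ledgered per ring (the "beam" of the surrogate), per
sublayer, and per the five-part edge-to-middle split used for reporting
(outer bands 1/5, middle band 3; the symmetric halves pool).  Densities
normalise by torus lateral area for rings and by the stair-step face area
for the boundary.

## Radiograph quantification

Classification is the three-band thresholding rule: scaffold above 250
(titanium saturates the detector), bone in $[60, 180)$ — the displayed
rule's inclusive lower bound wins over the loose prose paraphrase — and
everything else `other`, on 8-bit grayscale images (the "binary image"
wording in the source material cannot be literal, since the thresholds
only make sense on a 0–255 range).  Images are cut into an
`n_rows × n_cols` grid (default 10 × 10; the original grid count is
unstated) with integer strides and the remainder absorbed by the last
row/column, and each grid cell gets
$P_b = S_{bone}/(S_{all} - S_s)$, undefined (and excluded) when the cell
is pure scaffold.  Profiles pool grid rows or columns, including the
five-column grouping used for edge-to-middle comparisons.

The bone–scaffold contact score needed one definitional decision: the
denominator.  We define the interface as the scaffold perimeter (scaffold
pixels with a non-scaffold 4-neighbour) regardless of the connectivity
parameter, which then only governs the bone-neighbour test.  With a
connectivity-dependent denominator the 8-connected score could fall below
the 4-connected one (an 8-only interface pixel with no bone neighbour
dilutes the ratio), violating the monotonicity any user would assume.
Both connectivities are always reported, as the analysis itself leaves
open which one a given published percentage used.

## Synthetic radiographs

The generator projects the lattice through the viewing axis (saturated at
255, so noise is applied only to non-scaffold pixels — saturated detector
regions clip), and plants bone speckle among the in-silhouette void pixels
by ranking a box-blurred noise field against a target fraction field:
base fraction 0.3, +0.2 per normalised radius, +0.1 per normalised depth,
emulating the observed ~30% middle / ~40% sub-side / ~50% edge ingrowth
pattern with a slight bottom-to-top decrease.  Rank selection makes a
spatially uniform target exact to one pixel before noise, which is what
the exact-recovery tests exploit.  Bone intensities are drawn from
$[70, 170]$ — inside the bone band with margin so that σ = 5 noise leaks
less than a tenth of a percent of pixels out of class.  The generator
emulates class geometry and texture, not X-ray physics: no beam hardening,
scatter, or printing defects (the powder-with-air edge artefacts real
scans show), so passing recovery tests demonstrates the analysis code is
correct, not that real radiographs are this easy.

## Problem sizes and determinism

Defaults and test scales, chosen once: morphometrics at 0.05 mm voxels
(~4.4M voxels, seconds); trend runs at 64 × 96 cells with 3 × 5,000
particles over 5 s; the full-count run (50,000 cells) on a 32 × 48 grid.
The flow is deterministic, so all seeds of a scenario share one flow
solution; each seed owns an RNG stream used only for injection sampling,
and identical seeds reproduce particle CSVs byte for byte.

## Known limitations

The 2D axisymmetric ring surrogate cannot represent the discrete beam
crossings or azimuthal channels of the true lattice; edge-to-middle and
scenario *orderings* are meaningful, absolute attached masses are not.
One-way coupling ignores the (dilute) particle load on the fluid.  No
proliferation, migration, differentiation, particle–particle collisions,
or detachment under shear.  The attachment ledger is compared against
3-month ingrowth only at the level of spatial trends — the simulation
covers seconds, biology the months after.
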