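# osteoseed

Cell-seeding simulation and bone-ingrowth quantification for 3D-printed
titanium osteochondral scaffolds.

When a multi-layer osteochondral scaffold is press-fit into a truncated-cone
bone defect, bone marrow floods the void space within seconds, carrying bone
mesenchymal stem cells (BMSCs) that attach to the titanium beams and the
surrounding trabecular walls.  Where those cells land in the first seconds
foreshadows where bone regenerates over the following months, so a faithful
simulation of the filling-and-attachment process is a cheap proxy for animal
experiments when iterating on scaffold geometry and materials.  osteoseed is
for tissue-engineering modellers who want that simulation, and for image
analysts who want the matching radiograph-based ingrowth metrics,
in one tested package with no external data dependencies.

## What it computes

**Filling flow.** Marrow and air are immiscible incompressible phases
tracked with a volume-of-fluid (VOF) marrow fraction per cell, driven by
the Navier–Stokes equations with mixture properties.  Marrow is
shear-thinning power-law:

    eta = k * gamma_dot^(n-1) * H(T),   clamped to [eta_min, eta_max]

with k = 0.017, n = 0.708, clamps 0.01/0.001 Pa s, density 1050 kg/m³, and
H ≡ 1 (isothermal).  Marrow enters the lateral and bottom defect surfaces
at 1 mm/s for 2.5 s; displaced air leaves through the 0.1 mm annular vent
at the top.  The solver is a MAC-staggered projection method on a 2D
axisymmetric section of the defect, with the beam lattice represented by a
porosity-preserving ring surrogate.

**Cell transport and adhesion.** 50,000 BMSCs (25 µm, 1000 kg/m³,
σ = 0.03 N/m) are injected uniformly over the inlet faces during filling
and tracked as Lagrangian particles with Schiller–Naumann-corrected Stokes
drag.  Each wall/beam contact is classified by its impact Weber number
We = ρ_p d v_n²/σ into stick, rebound, or spread regimes; at marrow-filling
speeds We ~ 1e-6, so contacting cells stick.  Attached mass is ledgered per
beam, per sublayer, per the five-part edge-to-middle split, and for the
boundary (trabecular) walls, under the two post-fill working conditions
(cell injection stopped vs continued at 1 mm/s).

**Ingrowth quantification.** 8-bit radiographs are thresholded into
scaffold (intensity > 250), bone (60 ≤ intensity < 180), and other; each
grid cell of an equal-stride partition gets the bone fraction

    P_b = S_bone / (S_all - S_s)

plus row/column profiles and the bone–scaffold contact percentage under
4- and 8-connected neighbourhoods.  A synthetic radiograph generator
produces ground-truthed images (configurable ingrowth gradients, speckle,
noise) so the whole analysis path is verifiable.

## Worked example

```r
library(osteoseed)

# marrow viscosity: at 1 1/s the raw power law (0.017) exceeds the upper
# clamp, so the limit is returned; at 100 1/s it is inside the clamps
rheo <- marrow_rheology()
apparent_viscosity(rheo, 1)     # 0.01
apparent_viscosity(rheo, 100)   # 0.004430461

# default titanium lattice morphometrics at 0.05 mm voxels
morphometrics_report(scaffold_spec(), spacing = 0.05)
#    porosity surface_area_mm2 spacing_mm                 estimator
#   0.7831074         558.4237       0.05 smoothed-gradient co-area

# synthetic radiograph (edge-heavy ingrowth, sigma = 5 noise) and its analysis
lat   <- build_titanium_lattice(scaffold_spec())
synth <- render_radiograph(lat, ingrowth_model(seed = 7, noise_sigma = 5),
                           width_px = 300)
out <- run_quantification(list(synth$image), n_rows = 10, n_cols = 10)
out[[1]]$summary
#   global_P_b contact_pct_4 contact_pct_8
#    0.4748785       47.1778      67.16839
grid_profiles(out[[1]]$grid_stats, "columns", n_groups = 5)
#   group  mean_P_b
#       1 0.5296894     <- scaffold edge
#       3 0.3683944     <- middle
#       5 0.5570413     <- opposite edge
```

The recovered global bone fraction (0.4749) matches the planted ground
truth (0.4754) to half a percent despite the noise, the five-column profile
shows the planted edge-to-middle gradient, and the 8-connected contact
percentage exceeds the 4-connected one, as it must.

A full coupled run (both post-fill scenarios, three seeds each, sharing
one flow solution):

```r
res <- run_simulation(
  simulation_config(nr = 64, nz = 96, seeds = c(11, 22, 33),
                    schedule = injection_schedule(n_cells = 5000)),
  scenarios = c("continued_injection", "no_injection"),
  output_dir = "sim_out")
region_density(res$ensembles[[1]]$ledger, res$domain, "radial5")
```

At this reduced scale the outer radial bands end the 5 s run with roughly
an order of magnitude more attached mass per beam than the middle band,
and the continued-injection condition leaves the boundary walls an order
of magnitude denser than the stopped-injection condition — the two
qualitative signatures of the seeding process.

A command-line front end over the same functions lives at
`inst/cli/osteoseed.R` (subcommands `geom`, `sim`, `quantify`, `synth`,
`rheology`).

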