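# porewatch

Analysis toolkit for quantifying how water, monatomic ions and small
metabolites permeate the central pore of a bacterial-microcompartment
(BMC) shell-protein hexamer — and for the matching in vitro
permeability assay based on enzyme kinetics.

BMC shells are selectively permeable protein layers; substrates enter
through the charged central pores of the hexameric tiles. Anions such as
Cl⁻ can occupy the pore constriction and compete with substrate passage,
while cations are excluded. `porewatch` provides the complete analysis
chain used to quantify this, for trajectory data on the simulation side
and plate-reader time courses on the experimental side:

* **Trajectory input** — PDB/GRO structures, DCD / multi-frame XYZ /
  multi-MODEL PDB trajectories (nm/ns internally), species selections,
  per-molecule center-of-geometry tracks with minimum-image reassembly
  across periodic boundaries.
* **Pore frame** — Kabsch least-squares superposition of every frame
  onto the crystallographic reference (proper rotation enforced), pore
  axis along z, axial coordinate `d_pore` zeroed at the centroid of the
  six pore-residue Cα atoms; `d_pore > 0` is the concave (outward) face.
* **Occupancy** — time-averaged molecule counts `N_mol(d_pore)` in a
  0.7 nm-radius cylinder, replica means ± standard errors, enrichment
  over the ideal-solution bulk expectation
  `ρ_bulk · π r² · Δz` (ρ at 150 mM = 0.09033 nm⁻³).
* **Permeation** — completed side-to-side traversals of a 2 nm-radius,
  ±0.6 nm detection cylinder, counted by a per-molecule state machine
  (arm on axial entry, fire on opposite-side exit, disarm on lateral
  exit), reported as events/ns with replica uncertainty.
* **Spatial distribution functions** — 3D densities on a 0.05 nm grid,
  thresholded enrichment regions (e.g. 10× and 30× bulk), OpenDX export.
* **Synthetic data** — a Brownian-dynamics generator (overdamped
  Langevin, reduced units kT = 1) of particles crossing a slab-embedded
  cylindrical channel with species-specific affinity and optional
  single-file blocking, logging ground-truth crossings at every step;
  plus a plate-reader assay generator with a linear V0-vs-salt truth.
* **Kinetics** — initial velocities from absorbance time courses,
  V0 vs [NaCl] regression (100–500 mM window), slope comparison between
  intact and broken compartments (t test on independent OLS slopes),
  broken/native V0 ratios with compounded errors, dilution arithmetic.

## Worked example

Suppress a neutral tracer's permeation with a channel-blocking anion
analog, using the built-in generator:

```r
library(porewatch)

rate_demo <- function(n_blockers, seed) {
  sp <- data.frame(label = c("PD", "Cl"), count = c(150, n_blockers),
                   D = c(2, 1.5), U = c(-1, -4), blocker = c(FALSE, TRUE))
  if (n_blockers == 0) sp <- sp[1, ]
  p <- bd_params(species = sp, slab_half = 0.8, n_steps = 6e5, stride = 20,
                 blocking = TRUE)
  bd <- simulate_bd(p, seed = seed)
  ev <- detect_events(bd$tracks$PD, p$detection, box_z = p$box)
  permeation_rate(ev)
}
rate_demo(0, 11)   # tracer alone
#> permeation rate: 0.4167 +/- 0 events/ns (50 events / 120 ns, 1 replicas)
rate_demo(60, 11)  # with the blocking species at ~40 mM
#> permeation rate: 0.1833 +/- 0 events/ns (22 events / 120 ns, 1 replicas)
```

The blocker occupies the channel most of the time and the tracer's
measured rate drops by more than half — the desk-scale analog of salt
suppressing substrate permeation through the pore. The generator's own
crossing log (`bd$crossings`) provides ground truth: at save stride 1 the
detector reproduces it event for event.

On the kinetics side:

```r
d <- simulate_assay(assay_params(), seed = 42)      # quadruplicate plate
v <- fit_initial_velocities(d, window = "fixed", fixed_window = c(1, 15))
fitN <- regress_v0_vs_salt(v[v$state == "native", ])
fitB <- regress_v0_vs_salt(v[v$state == "broken", ])
fitN
#> V0 ~ [NaCl]: slope 2.173e-07 +/- 4.8e-08 per mM, intercept 8.833e-05 (n=5, R^2 0.873)
fitB
#> V0 ~ [NaCl]: slope 7.145e-07 +/- 1.2e-07 per mM, intercept 0.0001139 (n=5, R^2 0.919)
compare_slopes(fitB, fitN)
#> slope difference 4.972e-07 +/- 1.3e-07, t = 3.792 (df 6), p = 0.00905
```

The broken state gains activity with salt ~3× faster than the intact
state (slopes in absorbance·s⁻¹·mM⁻¹); the significant difference is the
signature of the shell limiting permeation. See
`vignettes/porewatch-methods.Rmd` for the models, conventions and
limitations.

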