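---
title: "Quantifying pore permeation and ion occupancy with porewatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pore permeation and ion occupancy with porewatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porewatch)
```

## The scientific problem

Bacterial microcompartments (BMCs) are protein organelles whose enzymatic
core is enclosed by a selectively permeable shell.  Substrates reach the
core mainly through the central pores of the hexameric shell tiles
(BMC-H), and those pores are strongly charged: anions such as Cl⁻ can
occupy the constriction and compete with metabolite passage, while
cations are excluded.  Two complementary measurements probe this:

1. **Simulation side.** Given trajectories of a shell-protein hexamer in
   solution with ions and metabolites, count how often each permeant
   species actually traverses the pore, and map where each species
   accumulates relative to the pore axis.
2. **Wet-lab side.** Compare product-formation initial velocities between
   intact compartments (rate governed by both shell permeation,
   k_permeation, and enzymatic turnover, k_turnover) and
   sonication-broken compartments (k_turnover only), across a NaCl
   titration.  A salt-dependent divergence between the two implicates
   the shell.

`porewatch` implements the full analysis chain for both sides, plus a
Brownian-dynamics (BD) generator that produces trajectories with known
ground truth so that every stage of the chain can be validated.

## The pore coordinate frame

Every trajectory frame is superposed onto the crystallographic reference
by minimizing the sum of squared displacements of all hexamer C-alpha
atoms (Kabsch algorithm: SVD of the cross-covariance with a determinant
correction on the smallest singular vector, so a proper rotation is always
returned; degenerate — collinear or coincident — point sets are rejected).
After superposition the pore normal lies along z.  The origin of the
axial coordinate `d_pore` is the centroid of the six C-alpha atoms of the
pore-lining residue (residue 40 by default, one per protomer).  Positive
`d_pore` is the concave face — the outside of an assembled shell — under
the default orientation sign `+1`; the sign is explicit because nothing
in a bare coordinate file fixes which face is which.

Two design points deserve note:

* **All hexamer C-alpha atoms** drive the superposition; the pore residue
  only defines the origin.  Using only pore atoms would let the fit tilt
  with local constriction flexibility.
* **Origin convention.** The axial origin can be taken from the
  reference structure (`origin = "reference"`, the default, so `d_pore`
  is strictly a reference-frame coordinate) or from the per-frame
  centroid of the aligned pore C-alpha atoms
  (`origin = "instantaneous"`).  The two differ only when the
  constriction drifts axially after alignment; both are exposed because
  the choice is not forced by anything in the data.

Alignment is idempotent to 1e-9 nm, invariant under any rigid motion of
the input frame, and never increases the C-alpha RMSD — all three are
asserted in the test suite.

## Occupancy profiles and enrichment

The axial occupancy `N_mol(d_pore)` is the time-averaged number of
molecule centres inside a cylinder of radius 0.7 nm around the pore axis,
histogrammed along `d_pore`.  Molecules enter by centre position only;
cylinder boundaries are inclusive (a measure-zero convention, fixed for
determinism).  The histogram bin width defaults to 0.1 nm and the profiled
range to ±3 nm; neither affects per-bin values, only resolution and range.
Replicas are aggregated as mean ± standard error with the sample-SD
(n−1) convention, the usual meaning of "standard errors across repeat
simulations".

Enrichment divides `N_mol` per bin by the count an ideal solution at the
stated bulk concentration would put in the same bin volume,
`rho_bulk * pi * r^2 * dz`.  The bulk number density conversion is
`rho = c[mol/L] * N_A * 1e-24 / nm^3`; at 150 mM this is 0.09033 nm⁻³,
the no-enrichment expectation used for Cl⁻ throughout.  (That constant is
sometimes printed with units "per nm"; dimensional analysis fixes it as
per nm³ — 0.150 × 0.60221 — and the package treats it so.)

## Permeation events

A permeation event is a completed side-to-side traversal of a detection
cylinder of radius 2 nm spanning −0.6 nm ≤ `d_pore` ≤ 0.6 nm.  The radius
is deliberately much larger than the occupancy cylinder so a permeant
cannot slip out and back in laterally near the axial centre and be
double-counted.  Detection is a per-molecule finite-state machine over
frame-wise regions (below / inside / above / outside-lateral):

* arming on a below→inside or above→inside transition;
* firing on a subsequent inside→opposite-side transition;
* disarming on inside→same-side, and (by default) on a lateral exit —
  the conservative reading, consistent with the rationale for the wide
  radius; `disarm_on_lateral = FALSE` is available;
* molecules that start inside are unarmed until they first leave.

A molecule that jumps directly from below to above within one frame
stride is counted (flagged `interpolated`) when the straight-line path
stays within the radius.  Because the below/above regions already require
r ≤ radius and r² is convex along a segment, a genuine axial jump always
satisfies this; the rule's practical bite is the periodic-wrap guard:
when the box length is supplied, a jump whose z displacement exceeds half
the box is a wrap across the periodic face, never a crossing.

Rates are events per ns: per replica events/duration, summarized as
mean ± sample-SD/√n across replicas, with the pooled rate alongside.

## Spatial distribution functions

Molecule centres are histogrammed on a 0.05 nm grid in the aligned frame;
voxel counts divided by frames × voxel volume give a time-averaged number
density, pooled frame-weighted over replicas (a time-and-ensemble
average).  Voxels are half-open `[lo, hi)` with the last bin closed.
Mass conservation (voxel densities × volume summing to the mean in-grid
molecule count) holds to 1e-9 relative by construction and is asserted.
Thresholding at k× bulk yields nested enrichment regions (30× ⊆ 10× by
construction); grids export to plain-text OpenDX for molecular viewers.

## The Brownian-dynamics generator

Microsecond all-atom trajectories are far beyond desk scale, so the
package ships a generator that reproduces the *statistical structure* the
analysis assumes: several species diffusing in a periodic cubic box
across a slab pierced by a single cylindrical channel.  The propagator is
overdamped Langevin, `x <- x + D F dt + sqrt(2 D dt) xi`, in reduced
units kT = 1 (the laboratory temperature, 310 K, matters only for
mapping D and U to physical values).

The potential is separable and smooth: an axial weight `w_z(|z|)` that is
1 deep inside the slab and falls to 0 over a cosine ramp at the faces,
and a radial channel weight `c(r)` that is 1 inside the channel and falls
to 0 at its wall.  The energy is
`E = w_z * ((1 - c) B + c U_i)`, with `B` the slab exclusion barrier
(default 8 kT) and `U_i` the species' channel well (negative =
attractive).  Cosine ramps keep forces finite; an optional `cos(6θ)`
modulation of the well emulates the six-fold symmetry of a hexamer pore.

Defaults mirror the simulated systems the analyses target: an 11.5 nm
box, a 2 nm-thick slab, a 0.5 nm channel, ion species at 150 mM and a
metabolite tracer at 175 mM, an attractive 2 kT well for the anion
analog, a repulsive 2 kT barrier for the cation analog, and diffusion
coefficients of small aqueous solutes (1–2.5 nm²/ns).

**Time step.** The default is 2e-4 ns.  The binding constraint is not
the RMS free-flight step (which must merely stay below half the channel
radius) but the sampled-distribution bias of the Euler–Maruyama scheme
near the potential ramps: the drift per step, `D dt |grad E|`, must stay
several-fold below the ramp width, or the stationary distribution — and
with it the measured channel enrichment — departs from the Boltzmann
factor.  At the default parameters the drift per step is under a third
of the ramp width for every species, and the test suite verifies that
the measured enrichment for a −2 kT well agrees with e² within sampling
error.

**Ground truth.** The generator logs true channel crossings at *every
integration step*, using exactly the region rules of the analysis
detector.  At save stride 1 the analysis pipeline therefore must (and
does) reproduce the crossing log event for event.  At larger strides the
detector can miss fast recrossings; with the default geometry and a
stride of 10 the documented tolerance on the recovered rate is 20%, and
in practice the discrepancy is far smaller because the per-stride RMS
displacement (~0.03 nm) is small against the 1.2 nm detection cylinder.

**Single-file blocking.** With `blocking = TRUE`, at most one particle of
a blocking species may occupy the channel, and any other particle's move
*into* the occupied channel is rejected (the blocker's own exit is always
free).  This is a deliberate caricature of competitive anion occupancy of
the pore — the minimal mechanism that reproduces suppression of tracer
permeation with increasing blocker concentration — not a physical model
of ion–substrate interaction.

**Equilibration.** Particles start in the bulk, so channel statistics
need a fill-in period; `channel_enrichment()` discards the first quarter
of frames by default before measuring the channel-core/bulk density
ratio.

What the generator does *not* emulate: electrostatics and hydration
structure, protein flexibility (the "hexamer" is a static potential),
finite-size and force-field artefacts, and correlated ion–substrate
dynamics beyond hard blocking.  Passing tests therefore validate the
*analysis chain* — geometry, counting, statistics — on data with the
right gross structure; they say nothing about force-field realism.

## Kinetics of the permeability assay

Absorbance time courses (product formation read at 280 nm every 30 s for
an hour) are reduced to initial velocities V0 by an OLS slope over an
early-time window.  Two window policies are exposed:

* `"r2_prefix"` (default): the longest initial prefix (≥ 5 points) whose
  linear fit has R² ≥ 0.99.  When noise caps the attainable R² below the
  threshold — which happens already at a noise SD of a few percent of the
  signal amplitude — the prefix maximizing R² is used.  This policy reads
  well on clean, strongly linear data but tolerates substantial curvature
  before R² reacts, so its V0 systematically underestimates the true
  initial slope on saturating curves (by roughly w/(2τ) for window w and
  saturation constant τ).
* `"fixed"`: an explicit index window.  For estimation pipelines where an
  unbiased V0 matters, a short fixed window (the first ~7 minutes of a
  1-hour read at 30 s spacing) bounds the curvature bias at the percent
  level; this is what the package's own recovery tests use.

Replicate V0s (quadruplicates in the emulated design) are averaged to
one value ± SE per condition and state by default; a flag keeps all
replicates for the regression instead, which is preferable when the
regression's residual degrees of freedom would otherwise be very small.

V0 is regressed on [NaCl] over the 100–500 mM window (inclusive); slopes
for the native and broken states are compared with a two-sided t test on
the difference of independent OLS slopes, `df = n_a + n_b − 4` —
algebraically the interaction term of an ANCOVA with separate
intercepts.  Under a simulated null this test holds its 5% size (asserted
at 1000 replicates against a 3-SE binomial band).  Broken/native V0
ratios carry first-order compounded errors,
`SE = ratio * sqrt(cv_b² + cv_n²)`, which agrees with Monte-Carlo
propagation within 5% for CVs up to 10%.  V0 stays in absorbance/s
throughout: without an extinction coefficient there is no defensible
conversion to molar product.

The synthetic assay generator draws
`A(t) = baseline + V0 τ (1 − e^{−t/τ}) + noise`, with V0 linear in salt
with state-specific intercepts and slopes (defaults: native
1.0e-4 + 2.0e-7·c, broken 1.5e-4 + 6.0e-7·c absorbance/s, c in mM —
broken faster everywhere, with a steeper salt slope, so the broken/native
ratio rises with salt), τ = 10800 s (mild curvature within the hour, as
plate-reader curves show), and noise SD defaulting to 5% of each series'
amplitude.

## Statistical conventions in the validation suite

Stochastic assertions use explicit error models rather than tuned
tolerances: Poisson errors for counts, binomial bands for rejection
rates, sample SEs across replicas for BD observables.  Where only three
replicas are prescribed, a plain n = 3 standard error is so heavy-tailed
that a 3-SE test would fail ~10% of the time on perfectly correct code;
the suite therefore estimates the SE from half-run blocks (6 blocks over
3 replicas, each block far longer than the channel-residence correlation
time), which tightens the degrees of freedom without touching the
measured quantity.  Problem sizes (2e5-step runs, 600 particles,
1000-replicate null simulations, 100 random-walk trajectories of 1000
frames × 50 molecules for the detector–oracle comparison) were chosen as
the smallest giving those error models comfortable resolution.

## Degenerate inputs and numerical conventions

* Readers reject non-finite coordinates, truncated files (naming the
  line), atom-count mismatches, and unsorted frame times.
* Missing per-frame box vectors inherit the previous frame's; the first
  frame must have one.
* Periodic molecule reassembly chains minimum-image displacements from
  the molecule's first atom — adequate for permeants a few bonds across,
  not for polymers that span half the box.
* Zero-variance absorbance series fit as V0 = 0 ± 0 (R² defined as 1).
* Identical slopes with zero pooled SE compare as p = 1 by convention.
* Histogram bins are half-open with the final bin closed, everywhere.

## Known limitations

* No XTC reader: trajectories come in as DCD, multi-frame XYZ, or
  multi-MODEL PDB; tracks round-trip through delimited text.
* The BD generator's blocking rule is first-come-first-served and
  rejects moves rather than resolving forces; occupancy statistics of
  the *blocker itself* under blocking are therefore approximate.
* The occupancy module bins by molecule centre only; fractional-overlap
  assignment is not implemented.
* No potential-of-mean-force estimation from occupancy profiles and no
  isosurface rendering of enrichment regions — voxel sets and plain-text
  exports only.
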