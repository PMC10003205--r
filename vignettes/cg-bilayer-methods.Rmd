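---
title: "Models and methods: coarse-grained pH-sensitive bilayers"
author: "cgbilayer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: coarse-grained pH-sensitive bilayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgbilayer)
```

## The physical model

`cgbilayer` studies planar lipid bilayers made of POPC and three
ISUCA-derived lipids (palmitoyl/palmitoyl, oleoyl/oleoyl and mixed
palmitoyl/oleoyl tails on an imidazole-bearing headgroup). The imidazole
ring protonates at mildly acidic pH, so the same lipid exists in a
neutral and a +1-charged form; the charged form is the handle by which a
pH drop can disorder and destabilise a membrane.

Lipids are represented at MARTINI resolution (roughly four heavy atoms
per bead). POPC maps to 12 beads: a +1 choline bead (Q0) and a −1
phosphate bead (Qa), two glycerol beads (Na) and two tails of four beads
each. The ISUCA-derived lipids map to 13 beads: three small ring beads
for the imidazole, two glycerol beads and the same two 4-bead tails.
Saturated (palmitoyl-derived) tails use the apolar C1 bead class
throughout; oleoyl-derived tails carry one cis-unsaturated bead (C3
class) at the second tail position together with a 120° equilibrium
angle, which produces the kink that disorders unsaturated chains.
Protonation switches one ring bead to a +1 charged type; the assembled
acidic-condition systems are then neutralised with Cl⁻ counterion beads
(a charged Qa-class particle) that replace randomly chosen water beads.
Solvent is the standard CG water bead (four real waters each); 30% of
the solvent beads are antifreeze particles, the usual remedy for the CG
water model's artificially high freezing point, which matters in
confined periodic geometries like these.

All interaction parameters live in a structured YAML configuration
(`inst/extdata/martini_v2.yaml`): a per-type-pair interaction-level
matrix mapped onto the MARTINI v2 epsilon ladder (5.6 down to 2.0
kJ/mol, sigma 0.47 nm, with the 0.62 nm super-repulsive class, the
small-ring-bead scaling, and the enlarged antifreeze–water sigma), plus
bonded templates per lipid. The headgroup bonded terms of the
ISUCA-derived lipids were originally parameterised against all-atom
simulations; those published supplementary values are *not* bundled
here, so the `isuca_head` template ships placeholder ring bonds/angles
and is flagged `supplementary_required: true`. Dropping the published
numbers into the YAML reproduces the original headgroup mechanics
without touching code — no bonded parameter is hard-coded anywhere.

## Simulation protocol

The engine integrates velocity Verlet at a 20 fs time step, 310 K and
1 bar in the NPT ensemble:

* **Nonbonded**: Lennard-Jones with the potential shifted to zero at the
  12.5 Å bead-based cutoff (forces untouched), so the energy is exactly
  continuous at the cutoff. First bonded neighbours are excluded.
* **Electrostatics**: smooth Ewald summation (real space under the same
  12.5 Å cutoff, reciprocal space sized from a relative accuracy target,
  default 1e-4, plus self and excluded-pair corrections) with relative
  dielectric 15, the standard screening constant for non-polarisable CG
  water.
* **Thermostat**: Nose–Hoover, single chain, 1 ps coupling. The exact
  discretisation used by the original (closed-source) engine is not
  published, so agreement is property-level: the suite checks the
  thermostat holds 310 K within 2% and that disabling it yields NVE with
  second-order-convergent energy drift.
* **Barostat**: an Andersen-type extended-variable piston with weak
  damping on the piston velocity (a Langevin-piston-style friction
  without the stochastic term, for stability at this system size).
  Coupling is semi-isotropic by default — the two lateral box lengths
  scale together, the normal independently — which is the standard
  choice for planar bilayers because it lets the area per lipid
  equilibrate at fixed lateral isotropy. A fully isotropic mode is a
  config option.
* **Effective time**: CG dynamics on a smoothed energy landscape runs
  "faster" than atomistic dynamics; all reported times are actual
  simulation time multiplied by 4, and the diffusion analysis applies
  the same factor to lag times before fitting.

Initial configurations start in the bilayer state: a jittered square
lattice per leaflet (spacing from the target box), tails inward, heads
outward, species shuffled within each leaflet by the build seed, then
solvated on an adaptive cubic grid above and below the membrane and
energy-minimised (adaptive steepest descent with backtracking) to remove
bad contacts. Identical seeds reproduce every stage bit-for-bit.

## The four metrics

* **Area per lipid**: per-frame `Lx·Ly / N_leaflet`. The box surface
  divided by — not multiplied by — the monolayer lipid count; the
  reference POPC geometry (62.4 Å × 62.4 Å, 58 lipids) gives 67 Å².
* **Hydrophobic thickness**: the tail region is delimited schematically
  in the literature, so an operational definition is needed. We use the
  distance along the normal between the mean z of the C1 beads (first
  tail beads, both chains) of the upper and lower leaflets. An
  independent density-profile estimate (distance between half-maximum
  edges of the tail-bead z histogram) guards this choice in the tests;
  the two agree within a histogram bin on synthetic bilayers.
* **Order parameters**: `P2 = ⟨(3 cos²θ − 1)/2⟩` against the z axis.
  The bilayer normal is taken as z throughout — the systems are planar
  bilayers in rectangular boxes, so no instantaneous-tilt correction is
  applied. P2b is computed per consecutive tail bond (c1-c2, c2-c3,
  c3-c4) and P2t on the C1→C4 vector, each grouped by species and chain
  kind (palmitoyl vs oleoyl), averaged over lipids and frames with
  minimum-image bond vectors.
* **Lateral diffusion**: lipid centres of mass are unwrapped by
  nearest-image continuity between consecutive frames (valid while no
  bead moves half a box length between frames — the emission stride
  must respect this), the per-leaflet centre-of-mass drift is removed,
  and the MSD in x,y is averaged over all time origins at the
  trajectory stride. D comes from a least-squares fit of `MSD = 4Dt`
  over 10–50% of the maximal lag by default — below that the curve may
  carry short-lag transients, above it too few origins average the
  estimate — and the window used is reported with the fit. A negative
  fitted slope (possible on very short noisy runs) reports D = 0 with a
  warning rather than a negative coefficient.

Uncertainties on APL and thickness use block averaging (5 blocks); the
averaging protocol behind the original tables is unstated, so block
means are this package's own choice, reported alongside the per-frame
standard deviation.

## The synthetic generator as test bed

`gen_bilayer_trajectory()` builds two leaflets of rigid pseudo-lipids
whose tail bonds make *fixed* polar angles with the normal, with the
azimuth drawn uniformly per chain so tilted tails have no preferred
lateral direction — P2 then depends only on the polar angle and each
per-bond P2b equals `(3 cos²θ − 1)/2` exactly, while the C1→C4 vector of
a coplanar chain gives P2t in closed form from the summed bond vectors.
C1 beads sit on planes at ±thickness/2, the box area is APL ×
lipids-per-leaflet, and whole lipids perform independent 2-D Brownian
motion with per-axis step variance `2·D·dt` on the effective time scale.
`gen_brownian()` exposes the bare walkers for direct Einstein-relation
tests. Coordinates are wrapped into the box exactly as engine frames
are, so the analysis code cannot distinguish the two sources.

This closure — generate with known truth, analyse, recover — is the
backbone of the test suite. What it does *not* establish: the generator
has no inter-lipid correlations, no undulations, no headgroup/tail
density structure beyond the C1 planes, and its lipids are rigid. Tests
passing on synthetic data therefore validate the *estimators*
(definitions, averaging, unwrapping, fitting), not the realism of
engine-produced ensembles.

Defaults mirror the fluid POPC reference state: 58 lipids per monolayer,
APL 67 Å², thickness 14.8 Å, D = 2.2 × 10⁻⁷ cm²/s, and tilt angles
(20°, 35°, 50°) chosen to give the decreasing bond-order sequence
characteristic of fluid chains.

## Numerical choices and degenerate inputs

* Unit system: GROMACS-style internally (nm, ps, amu, kJ/mol, e), with
  user-facing coordinates in Å; the single conversion
  1 Å²/ns = 10⁻⁷ cm²/s lives in one constants table.
* The pair loop is an exact O(N²) pass with minimum-image convention —
  adequate for the ≤ 3300-bead systems studied; cutoffs are validated
  against half the smallest box length on every call.
* Ideal-gas pressure checks come out at (3N−3)/3N of NkT/V because the
  centre-of-mass momentum is removed at velocity initialisation; for
  N = 125 that is a systematic 0.8%, within the tolerance of the check.
* An already-minimal configuration passes through `minimize()`
  unchanged; a hard bead overlap (< 1 Å) is flagged as a diagnostic; a
  diverging NPT energy aborts with the offending frame attached.
* Zero-length vectors are an error in `p2()`; one-leaflet systems are an
  error in the thickness metric; `add_counterions()` on a neutral system
  warns and returns the input unchanged.
* Test and acceptance problem sizes are desk-scale by design: LJ fluids
  of 64–500 beads for the engine property checks, tens to hundreds of
  frames for the estimator closures, and ≤ ~150 NPT steps on a reduced
  mixed bilayer for the end-to-end smoke test. The production protocol
  (4 μs effective on 116-lipid systems) is supported by the same code
  path but is not exercised by the suite.

## Known limitations

* The published supplementary headgroup parameters are consumed via
  config but not bundled; with the placeholders, ISUCA headgroup
  mechanics are qualitative.
* Trajectory-level agreement with the original closed-source engine is
  out of reach (its nonbonded shift and thermostat/barostat
  discretisations are unpublished); the package targets property-level
  correctness instead, which is what the test suite asserts.
* No bond constraints, virtual sites, neighbour lists or parallelism;
  no deuterium-order, area-compressibility or undulation analyses;
  leaflets are symmetric by construction and lipid flip-flop is not
  tracked.
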