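---
title: "Modeling deformation-coupled corrosion of coated magnesium stent struts"
author: "stentCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling deformation-coupled corrosion of coated magnesium stent struts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stentCA)
```

## The problem

Biodegradable magnesium-alloy stents corrode too quickly in physiological
fluid unless protected. A common remedy is a polymer coating over the
fluoride (MgF2) conversion film and native oxide, but stents undergo a
harsh crimp-expansion cycle during deployment: the strut arc is compressed
onto a balloon and then expanded in the vessel. Strain concentrates at the
arc apex; a brittle coating such as PDLLA (elongation at break about 3%)
cracks there, while a ductile one such as PBAT (about 533%) stretches and
stays closed. Cracks and strain-induced porosity open transport paths for
water, chloride and protons, and corrosion then localizes exactly where
the mechanical damage is.

`stentCA` models this coupling with a stochastic cellular automaton on a
discrete cross-section of a coated strut, driven by an analytic surrogate
of the deformation strain field. It is a mechanism model: its purpose is
to reproduce the relative degradation behavior of coating systems and
regions, not absolute corrosion rates in days.

## Lattice and scenario geometry

The strut cross-section is unrolled along the arc: rows run through the
thickness, columns along the arclength (apex at normalized position
s = 0.5). The default stack at 0.5 um/cell, applied symmetrically to both
faces of a 30 um magnesium core, is

| layer | thickness | cells |
|---|---|---|
| electrolyte band | -- | 29 rows per face |
| polymer (PDLLA or PBAT) | 4 um | 8 |
| MgF2 conversion film | 1 um | 2 |
| native MgO | 0.5 um | 1 |
| Mg substrate | 30 um | 60 |

giving the default 140 x 600 lattice. The fluoride and oxide films are
sub-micrometre in reality; they are resolved with the minimal one-to-two
cells a lattice model needs for them to exist as layers. An optional thin
extrusion (`extrudeLattice`) turns the cross-section into a voxel slab for
3-d cloud renders, evolved by the same rules with 6-neighbor adjacency.

Of the 29-row electrolyte band, only the outermost rows (default 11) are
*reservoir* rows, reset to the bulk concentrations every step; the
remaining 18 rows start walker-free. This stand-off is a deliberate model
element: corrosive species must diffuse across it, so the attack on the
coating builds up over a few hundred steps rather than starting at full
intensity at step 0. The stand-off depth is one of the calibrated
parameters (below).

## Deformation surrogate and damage

The crimp-expansion strain field is represented analytically rather than
by finite elements: along the arc, the strain magnitude is a raised cosine
centred on the apex column with half-support `width` (default 0.15 of
arclength), scaled per face. Compression peaks at 0.30 (inner face) and
0.25 (outer); tension at 0.20 and 0.15. Signs follow the loading phase
(inner tensile under compression, reversed under tension), but damage
consumes only the magnitude: the observations this model targets do not
separate tensile from compressive damage, and cracks appear where the
magnitude is largest. Because loading is sequential, the damaging strain
is the per-cell envelope `max(|compression|, |tension|)`.

Coating damage has two channels:

* **Porosity.** Local porosity follows
  \(P(\varepsilon) = (1 - K^{\varepsilon + 1}) \times 100\%\) with a
  material constant \(K \in (0, 1]\). P grows exponentially in strain, is
  \((1-K)\times 100\) at zero strain, and vanishes identically at K = 1.
  Each polymer cell independently becomes a pore with probability P/100.
  Defaults K = 0.85 (PDLLA) and 0.99 (PBAT) keep the PDLLA coating
  everywhere the more porous, matching the measured porosity ordering of
  the two coatings.
* **Cracking.** A polymer column whose strain magnitude exceeds the
  coating's elongation at break becomes a through-thickness crack: the
  whole band is relabeled electrolyte, so crack sites are open to the
  medium from step 0. This is deterministic. At the default strains PDLLA
  cracks over the apex zone on both faces; PBAT never cracks.

Cracks do not grow during the simulation, and mechanics does not evolve
after the initial damage; the model's mechanochemistry is entirely in the
initial condition.

## The automaton

Cells carry one of six components (electrolyte/pore, polymer, MgF2, MgO,
Mg, Mg(OH)2 product); mobile species (H2O, Cl-, H+) are discrete walkers
with per-cell counts, several walkers may share a cell. Each step is a
synchronous two-phase update with von Neumann adjacency by default:

1. **Transport.** Every walker attempts a uniformly random neighbor move:
   into electrolyte freely, into intact polymer with the material's
   permeation probability, never into the other solids; blocked walkers
   stay. Reservoir rows are then reset to the bulk concentrations
   (defaults per cell: 2 H2O, 1 Cl-, 0.2 H+, fractional parts realized as
   Bernoulli draws).
2. **Reactions**, evaluated against a frozen copy of the post-transport
   state so the outcome is independent of cell visiting order:
   * polymer with water in its neighborhood hydrolyses to pore
     (`hydrolysis_prob`; PDLLA's default is fixed at twice PBAT's);
   * MgF2 and MgO in contact with water-bearing electrolyte dissolve
     (`dissolution_prob`, multiplied by `acid_boost` when a proton is
     adjacent, capped at 1);
   * Mg in contact with water-bearing electrolyte converts to hydroxide
     product; Mg whose only such contact is through product converts at
     `dissolution_prob * shielding_factor` (default 0.2), the partially
     passivating hydroxide layer;
   * product with an adjacent chloride walker dissolves (chloride attack);
     plain water never dissolves the product.

   Each cell changes at most once per step; the five rules act on disjoint
   source states, and a fixed priority order is defined for completeness.

Walkers on a dissolving cell remain in the resulting electrolyte cell, so
transport quantities are conserved outside the reservoir reset. The only
allowed transitions are POLY/MGF2/MGO/PRODUCT to ELEC and MG to PRODUCT,
which makes every per-component degraded fraction
\(F_c(t) = 1 - N_c(t)/N_c(0)\) monotone (for Mg, both the product and the
dissolved outcome count as degraded).

One master seed spawns separate streams for the damage realization and
the evolution, so a run is bit-reproducible from its config echo.

## Outputs and operational definitions

`runSim` records per-component cell counts each step for the whole
lattice, the *high-strain region* (cells at or above half the peak
envelope strain; for a zero field this mask is undefined and signalled
explicitly) and the *crack-site region* (all cells of cracked
face-columns). Quantities reported on top of the traces use frozen
operational definitions, needed because the qualitative vocabulary of
degradation ("initial rate", "began", "significant degradation") has no
units by itself:

* rate = degraded fraction per 100-step window, `r(t) = F(t) - F(t-100)`;
* initial rate = mean of the first three windows;
* onset = first step with F >= 0.01;
* half-degradation = first step with F >= 0.5 in the region of interest;
* stabilization = first window after which the rate's change stays below
  a tolerance for three consecutive windows.

Steps are left symbolic; no step-to-days conversion is attempted because
none is defined for this class of model.

## Calibration of the free parameters

The reaction and permeation probabilities, the porosity constants and the
reservoir stand-off are free parameters. They were fixed once with
`calibrateDefaults`, a coordinate-descent grid search that scores
candidate parameter sets by the mean relative error of four milestone
statistics over a 10-seed bank of full-size runs (each anchor tolerated at
+/-30%, reflecting that the milestones are approximate values): the
initial MgF2 degradation rate in the high-strain region (0.025 per
window) and lattice-wide (0.004) for the deformed PDLLA strut, crack-site
MgF2 half-degradation near step 700, and PBAT coating onset near step
1200. The frozen outcome is the packaged default table
(`defaultMaterials()`) plus the 11-row reservoir default; at these values
the four statistics land at about 0.020, 0.0044, step 550 and step 1180
respectively on seeds 1--10 (the acceptance tests recompute them). The
defaults are never changed silently -- every run directory echoes the
full material table -- and the calibration routine remains available for
re-calibration; when a feasible set cannot meet the anchors it reports
best-found with a failure flag rather than accepting silently.

The mechanics of the timing are worth stating because they are the least
obvious calibration outcome: the first-300-step rates constrain the early
attack to be slow, while half-degradation of the crack-site fluoride by
step ~700 requires it to be fast soon after. Both are satisfied by the
diffusive stand-off: water reaches the crack floors in appreciable
concentration only after a few hundred steps, so the early windows see a
rising hazard rather than a constant one.

## What the scenario generator does and does not emulate

The presets (`listScenarios()`) reproduce the simulated study conditions:
PDLLA/PBAT coatings on the deformed strut, their undeformed counterparts
(zero strain, included as clearly-labeled extensions for isolating the
deformation effect), and bare / fluoride-only stacks. The generator
emulates layered geometry, strain-localized damage and species-limited
corrosion kinetics. It does not emulate: electrochemical potentials or
impedance, pH evolution and hydrogen gas, crack growth under cyclic
loading, coating delamination, drug-eluting layers, or the curvilinear
geometry of a real sine-wave strut (the lattice is an unrolled strip with
arc position as a coordinate). Passing tests therefore support claims
about relative, mechanism-level behavior of this model class -- not
quantitative predictions for a deployed stent.

## Numerical choices and degenerate inputs

* The porosity exponent law is evaluated with P clipped to [0, 100); K
  outside (0, 1] and negative strain are rejected, not clamped.
* Layers thinner than half a cell at the chosen resolution are an error
  (resolution too coarse), not silently rounded away.
* The apex is anchored to the lattice column nearest s = 0.5 so the
  configured peak strain is attained exactly on a cell for any column
  count.
* A zero strain field makes the half-peak high-strain mask undefined;
  `highStrainMask` raises a typed `emptyMask` condition rather than
  returning an arbitrary empty set.
* Components absent at step 0 report degraded fraction 0 rather than NaN.
* Walkers found inside inorganic cells abort the run with a diagnostic;
  this is an internal-corruption check, not a recoverable state.
* With fewer than four rate windows, stabilization detection returns NA.

One discreteness property deserves a note: early degradation events are
single cells, so pointwise region comparisons (for instance "high-strain
degraded fraction at least the overall fraction at *every* step") can be
transiently violated when the very first event happens to fall inside the
crack zone but outside the half-peak mask -- the mask covers about 60% of
cracked columns, so this occurs in roughly a third of seeds and heals
within roughly a hundred steps. Window-level rate comparisons, and the
same pointwise comparison started from the first in-mask event, are
stable. This is an artifact of comparing fractions of very few events,
not a property of the mechanism.

## Problem sizes used in the checks

The packaged tests exercise the full default geometry (600 x 140, 4000
steps, seeds 1--10) for the milestone and ordering checks, and reduced
geometries (about 60 x 36) for the mechanism, oracle and round-trip
checks; the enumeration oracle runs 10^4 one-step trials on a 3 x 3
lattice with a single walker. The acceptance script re-runs the two
headline statistics (lattice-wide MgF2 initial rate and PBAT onset) on
the full geometry over a 10-seed bank derived from its `--seed` argument.

## Known limitations

* All kinetics are per-step probabilities; there is no mapping to wall
  time, temperature, or solution chemistry.
* The strain surrogate is a two-parameter shape, not mechanics: residual
  stresses, wrinkling, peeling and delamination are out of scope.
* The hydroxide product occupies one cell per consumed Mg cell; volume
  expansion of the corrosion layer is not represented.
* Polymer molecular-weight loss, autocatalytic hydrolysis and
  crystallinity effects are not modeled; hydrolysis is a single
  probability per material.
* Calibration anchors are reproduced as multi-seed statistics; individual
  seeds vary by roughly +/-30% on rate anchors and +/-15% on onset
  anchors.
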