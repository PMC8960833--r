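---
title: "Methods: biophysical larval dispersal in an idealized boundary-current system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biophysical larval dispersal in an idealized boundary-current system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Invasive benthic species with a planktonic larval phase — the sun-corals
(*Tubastraea* spp.) fouling offshore oil platforms in the Southwest
Atlantic are the motivating case — spread along coastlines by riding the
regional surface circulation during their pelagic larval duration (PLD).
`larvadrift` implements the full individual-based analysis chain for this
question: where do larvae released from platform clusters end up, how many
die on the way, and which stretches of coast are most exposed?

The chain has four parts: (i) a gridded, time-varying ocean (either
supplied by the user or generated by the package's idealized
boundary-current module), (ii) release geometry built from platform
coordinates, (iii) a Lagrangian particle simulation with mortality rules,
and (iv) connectivity statistics.

## The Lagrangian model

Each larva is a passive particle. Per time step `dt` the update order is
fixed: RK4 advection, turbulent displacement, coastline bounce, domain
check, temperature check, ageing, and (at the record stride) position
recording and path-length accumulation.

**Advection.** Classical fourth-order Runge–Kutta on the multilinearly
interpolated velocity, with degree/meter conversion at each stage's
latitude (spherical Earth, R = 6371 km; `cos(lat)` for zonal meters). On
the solid-body-rotation oracle field — whose bilinear interpolation is
exact because the velocity is linear in the tangent-plane coordinates —
orbits close to well under 0.1% radius drift per day at `dt = 1800` s and
the empirical self-convergence order is ~4, which is what the test suite
asserts.

**Turbulence.** An isotropic random walk with per-axis standard deviation
`sqrt(2 K_h dt)`, `K_h = eps^(1/3) l^(4/3)` (Okubo 4/3 scaling, `l` the
grid cell size), the scheme used by individual-based larval models such
as Ichthyop. The default dissipation rate is `eps = 1e-9 m2 s-3`. Note
that at `l ~ 9 km` this gives `K_h ~ 193 m2 s-1`; the law, not any fixed
diffusivity, is what the tests check. Setting `eps = 0` disables the walk
exactly.

**Coastline.** "Bouncing": a proposed position on a land cell has the
crossing component of its displacement mirrored about the crossed cell
face; if no single- or double-axis reflection lands at sea the particle
stays put. Coast contact is never lethal. Because steps are CFL-limited
to less than one cell, only adjacent-cell crossings occur.

**Mortality.** Two one-way rules, advection checked first (a particle
outside the domain samples no temperature): crossing the open boundary
kills (`dead_advection`), and sampling water at or below the lethal
temperature kills (`dead_temperature`; the threshold is inclusive,
default 12.5 °C, the minimum lethal SST reported for sun-coral larvae).
The larval density (1016 kg m⁻³) is carried as provenance metadata only:
a buoyancy model would also need a larval diameter, which is not
established for these species, so particles are vertically passive (they
keep their release depth on single-level fields, or follow `w` when a 3-D
field provides it).

**Interpolation and land.** Velocity interpolation lets land nodes
contribute exactly zero without renormalization, so the flow stalls
smoothly approaching the coast and bouncing handles residual contact.
Temperature *is* renormalized over sea nodes: a coastal particle should
sample water temperature, and an unrenormalized land zero would read as
lethally cold water.

**Path length** is accumulated at the record stride (default daily) as
great-circle segments between recorded positions. The stride matters
under eddies — a finer stride lengthens paths — so it is part of the
configuration and recorded in provenance.

## The idealized ocean

The synthetic module generates the circulation regime the analysis needs,
standing in for an eddy-resolving hindcast:

- an onshore inflow bifurcating at latitude `b(t) = mean + amplitude *
  phase(t)` into an equatorward jet north of `b` and a poleward jet south
  of it, both Gaussian-confined within `jet_width` of a straight
  meridional coastline. The phase is +1 in austral summer (bifurcation at
  its northernmost) and −1 in winter (southernmost), encoding the
  ITCZ-driven seasonal migration of the South Equatorial Current
  bifurcation, bounded near 10–14°S (defaults: mean −12°, amplitude 2°);
- a band of mesoscale eddies between 20 and 30°S, built as a superposition
  of Gaussian streamfunction bumps with random centers and signs drifting
  slowly westward. Deriving velocities analytically from the
  (coast-tapered) streamfunction makes the eddy component divergence-free
  and gives zero normal flow at the coast. The paper-scale system offers
  no quantitative eddy statistics to match, so amplitude (0.3 m/s), length
  scale (100 km) and count (12) are free parameters chosen at typical
  western-boundary mesoscale values and documented as free;
- a linear meridional temperature gradient (28 °C at the equatorward edge
  to 10 °C at 36°S), putting the 12.5 °C isotherm near 30°S so the lethal
  rule is exercised by poleward transport.

Jet core speeds default to 0.6 m/s (equatorward, NBC-like) and 0.4 m/s
(poleward, BC-like). All fields are generated on a regular lon/lat grid
(default 0.5°, daily frames — the circulation evolves on seasonal and
eddy-drift time scales, so daily frames resolve it) and are
bit-reproducible given the seed.

Two analytic oracle fields (solid-body rotation, uniform jet) exist only
to verify the advection machinery against closed forms.

## Release and destination geometry

Source areas are connected components of the union of 9-km geodesic discs
around platform positions (metric buffering in a local tangent plane;
chained overlaps merge transitively). Released larvae are allocated to
source areas proportionally to area with largest-remainder rounding —
counts sum exactly to the configured total (default 70,000) — and placed
uniformly over each area with depths uniform in 1–30 m.

The bundled platform table is **synthetic**: the coordinates are idealized
positions in the package's domain, not a real inventory, but its shape
matches the documented structure of the Brazilian case (136 platforms, 26
clusters across seven basins, a single-platform Camamu site, 59 platforms
in Campos, near-coast northern clusters vs offshore southern clusters
inside the eddy band).

Receiving areas are twelve disjoint shelf strips bounded landward by the
idealized coastline and seaward by a 60-km shelf width standing in for
the 200-m isobath, with spherical-geometry areas; alongshore breaks are
placed so each strip faces its source basin. Users can supply arbitrary
polygons instead. Destination membership uses horizontal position only.

## Statistics

- **Mortality by advection**: `MA = sum(a_sa) / sum(d_sa)` per source
  area (advected-out over released), recomputed from raw statuses and
  cross-checked against counters maintained during the run.
- **Larval supply**: a larva reaches a receiving area iff it is alive on
  the last simulated day and its final position lies in the polygon;
  `LS(SA, RA) = 100 * arrivals(SA, RA) / arrivals(RA)`, so every column
  with arrivals sums to 100%. Any-time crossings are available from the
  recorded trajectories but deliberately not used for supply.
- **Effectiveness**: percent of a basin's released larvae alive and
  inside any receiving area at the end.
- **Incidence**: arrivals divided by shelf area (larvae/km²), the
  shelf-size-corrected exposure measure.
- **Distances**: haversine path sums for surviving larvae (dead larvae
  are excluded from distance summaries by default).
- **Kernel density**: Gaussian product kernel over pooled recorded
  positions of surviving larvae, computed in tangent-plane kilometers,
  Scott's-rule bandwidth unless overridden, normalized to integrate to 1
  over the domain.
- **Group comparisons**: Mann–Whitney for two groups (e.g. seasonal MA
  contrast), Kruskal–Wallis for more (e.g. interannual), both two-sided
  at 5%.

## Numerical choices and degenerate inputs

- `dt = 1800` s with daily frames is CFL-safe for ~0.5–1 m/s jets on
  0.25–1° grids; the simulator aborts with a diagnostic if `dt` exceeds
  the cell-crossing time at the fastest grid speed.
- `dt` must divide the record stride so records land exactly on steps.
- Ties/edges: cell faces belong to the eastern/northern cell
  (`findInterval` convention); a reflection landing exactly on a face is
  at sea; temperature exactly at the threshold kills (inclusive rule).
- Degenerate geometry is rejected: zero-area source polygons, unsorted
  receiving-area breaks, zero-variance KDE inputs.
- All randomness (eddy phases, release positions, turbulence) is
  seed-controlled; identical spec + seed reproduces outputs byte for
  byte.

## What the synthetic world does and does not show

The generator reproduces the *mechanisms* the analysis depends on —
opposing boundary jets with a seasonally migrating bifurcation, offshore
eddy trapping, a lethal poleward temperature gradient — so pipeline
properties (conservation, supply normalization, the winter-vs-summer
northward shift of mid-latitude releases) are meaningful. It does not
reproduce any real hindcast's shelf dynamics, tides, river plumes or
interannual variability, so absolute magnitudes (mortality percentages,
larvae/km², kilometers traveled) are properties of the synthetic
configuration, not predictions for the real coast. Test problem sizes
(typically 400–5,000 particles, 5–30 day drifts, 0.5–1° grids) were
chosen so the whole analysis runs at desk scale; the statistics code is
size-agnostic and handles the full 70,000-particle, 90-day configuration.

## Known limitations

- No larval behaviour (swimming, vertical migration), growth or
  settlement competency; any larva in a receiving area at the end of its
  PLD counts as potential supply.
- The 2-D default ignores vertical shear within the 1–30 m release layer.
- Bouncing assumes axis-aligned cell faces; a curved coastline is
  approximated at grid resolution.
- The JSON field container is convenient and exact but not a NetCDF
  reader; gridded hindcast input must be converted to it first.
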