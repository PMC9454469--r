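---
title: "celldose: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{celldose: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the cell and transport models and their assumptions, the
parameters that matter, the conventions chosen where more than one
reasonable convention exists, and the numerical machinery behind the
results. Nothing here states an empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## The cell model

Every cell is two concentric spheres of liquid water at unit density:
the cell of radius $r_C$ and its nucleus of radius $r_N \le r_C$
(micrometers). Source regions for radioactivity are the whole cell
(C), the nucleus (N), the cytoplasm (Cy, the shell between $r_N$ and
$r_C$) and the cell surface (CS, the sphere of radius $r_C$); dose
targets are C, N and Cy. Region masses follow from the volumes at
$\rho = 1\,$g/cm³. All cells in a population share one geometry —
cell-to-cell size variation is out of scope. Radii above 10 µm are
accepted with a warning: the quadrature remains valid, but the
configuration leaves the regime in which the engine has been
exercised, and the neglect of photons (below) grows less defensible
with size.

## Radiation sources

A source is a list of emission lines (type code, yield per nuclear
transition, energy in MeV); the per-line mean energy emitted per
transition is $\Delta = y \times E$. Radiation-type codes distinguish
α particles, β⁻/β⁺ (represented by their average-energy line — full β
spectra are not modeled), internal-conversion electrons,
Auger/Coster–Kronig electrons, and photons (γ, X ray). Photon lines
are parsed and carried through for completeness but contribute
nothing to any dose: photon transport is deliberately excluded, which
is accurate for micrometer-scale self and cross doses and becomes a
visible approximation only for large clusters.

Decay chains are expanded under secular equilibrium: every
descendant's yields are scaled by the product of branching fractions
along the chain, so one parent transition carries the whole chain's
emissions. This is exact for short-lived daughters (the ²¹³Bi chain)
and an idealization for long-lived ones; chain terminators
(quasi-stable nuclides) contribute nothing. The packaged emission
tables (`inst/extdata/emissions.csv` and friends) are best-effort
condensed transcriptions of standard decay-scheme compilations,
documented in their headers; only the ²¹³Bi chain is anchored by the
package's reference example, the other chains (²¹¹At, ²²³Ra, ²²⁵Ac,
¹¹¹In) ship as-is for exploration.

## Transport: range–energy relations and the point kernel

Charged particles travel straight lines and slow down continuously
(CSDA): angular scattering, straggling, δ rays and bremsstrahlung are
all ignored. Each particle type carries a range–energy relation
$R(E)$ in unit-density water:

* **Electrons (default).** A Cole-type empirical power law,
  $R(\mu m) = 0.0431 (E_{keV} + 0.367)^{1.77} - 0.007$, the classic
  relation of cellular dosimetry; stated validity 1 keV–2 MeV (it
  runs high above a few hundred keV against tabulated CSDA ranges).
* **Electrons (alternative).** `relation = "tabulated"` interpolates a
  packaged table of CSDA ranges for liquid water log-log; use it when
  fidelity to tabulated stopping data matters more than closed forms.
* **α particles.** A packaged range table generated from the classic
  Geiger/Bragg–Kleeman air-range rule scaled to water
  ($R \approx 3.21\,E^{1.5}$ µm with $E$ in MeV), within a few
  percent of reference CSDA ranges over the 4–9 MeV therapy window,
  interpolated log-log.

Outside a relation's validity window the package extrapolates and
warns rather than failing — an extrapolated range is more useful than
an error in a sweep, but the warning is kept loud.

From $R(E)$ follow the residual energy after a path $x$,
$E(x) = R^{-1}(R(E_0) - x)$, the stopping power
$S(E) = (dR/dE)^{-1}$, and the isotropic point-source dose kernel
$D(r) = S(E(r)) / (4\pi r^2 \rho)$, zero at and beyond the range.
The kernel conserves energy by construction; the test suite verifies
$\int 4\pi r^2 \rho D(r)\,dr = E_0$ to 0.5 %.

## Absorbed fractions and S coefficients

The absorbed fraction φ(T ← S) reduces to nested one-dimensional
Gauss–Legendre quadratures. The innermost kernel is the mean energy
a point emission at distance $u$ from a target sphere's centre
deposits inside the sphere: per ray direction the deposit is the
difference of residual energies at the chord entry and exit points
(exact under CSDA), averaged over the direction cosine (48 nodes).
Around it:

* *Self* terms: the source radius is integrated over the source
  region with weight $r^2$ (24 nodes); by symmetry $u$ equals the
  source radius, so no angular integral is needed. The cytoplasm
  target is evaluated as cell-sphere minus nucleus-sphere deposits.
* *Cross* terms: the source point's angular position adds one more
  integral (32 nodes) over the distance
  $u = \sqrt{r_s^2 + d^2 - 2 r_s d w}$. The full source-region
  geometry is always integrated — no point-source approximation at
  any distance, which removes the main source of near-field error.

For cross doses the direction-averaged deposit profile $F(u)$ of each
(line, target-radius) pair is tabulated once on a dense grid (481
points inside the sphere, 1441 outside, clustered toward the
$u = R_t$ kink) and reused by linear interpolation across all lattice
distances; self terms always use direct quadrature. The combined
quadrature error is at the $10^{-3}$ relative level, far below the
2 % / 5 % bands at which the Monte Carlo cross-check operates. Cross
S coefficients are exactly zero beyond the longest particle range
plus one cell diameter; `s_table()` records this cutoff and the dose
accumulator prunes cell pairs past it.

S values follow as $S = \sum_i \Delta_i \varphi_i / m(T)$ in
Gy/(Bq·s), resolved by radiation-type code. Two internal identities
are enforced by tests: energy partition
($S(C\!\leftarrow\!s)\,m_C = S(N\!\leftarrow\!s)\,m_N +
S(Cy\!\leftarrow\!s)\,m_{Cy}$) and reciprocity of specific absorbed
fractions between nucleus and cytoplasm.

## The Monte Carlo cross-check

`mc_estimate_s()` estimates the same S coefficients by brute force:
decay positions sampled uniformly in the source region, isotropic
directions, and per-track deposits computed from residual energies at
the analytic chord intersections (no stepping, hence no step-size
artifacts). It shares only the range–energy model with the analytic
engine — positions, directions and chord bookkeeping are independent
code — so agreement is a genuine check of the quadrature, not a
tautology. The estimator reports a standard error; test tolerances
(2 % self, 5 % cross) sit several standard errors above the Monte
Carlo noise at the history counts used ($2\times10^5$–$5\times10^5$),
keeping flake probability negligible.

## Cluster geometry and the lattice convention

Populations live on a simple cubic lattice of pitch equal to the
user's centre-to-centre spacing (which must be at least one cell
diameter — cells never overlap). Cells are kept when they lie inside
the requested shape shrunk by a fixed margin, and returned in
deterministic (z, y, x) order so every downstream accumulation is
reproducible bit for bit.

Two frozen constants pin the convention: the lattice is anchored at
the cluster centre with a fractional offset of 0.07 × spacing along
each axis, and the shape is shrunk by 0.23 × spacing. They were
calibrated **once** so that the package's reference spheroid — cluster
radius 125 µm, cell radius 6 µm, spacing 13 µm, the configuration of
the surface-labeled ²¹³Bi spheroid study the package reproduces —
contains exactly 3,473 cells, and then frozen for every geometry. The
calibration needs both knobs: on an origin-anchored lattice no
inclusion radius attains 3,473 (the attainable counts jump from 3,431
to 3,575 across a single degenerate lattice shell of 144 points whose
octahedral symmetry admits no subset of the required size), while
$|c| \le 125$ µm on that lattice gives 3,743 — notably the continuum
estimate $\tfrac{4}{3}\pi R^3/d^3 \approx 3.7\times10^3$ sits between
the two. A face-centred packing was rejected because it would
overshoot the anchor count by ~40 %. One visible consequence: a
cluster smaller than one spacing contains a single cell *near*, not
exactly at, the origin.

Penetration depth is classified against the exact distance from the
cell centre to the cluster's outer surface (closed forms for sphere,
circle, rectangle and rod; the Lagrange-parameter root for ellipse
and ellipsoid; distance to the generating segment for the cone). A
cell is eligible for labeling iff that distance does not exceed the
drug-penetration depth; depth 0 leaves nothing eligible and labeling
fails loudly. Tomographic slices partition a 3-D population into
axial layers of a user-chosen thickness in cell diameters.

## Labeling conventions

The labeled subset is a uniform random draw of
round(percent/100 × *all* cells) from the eligible cells — the
percentage refers to the whole population, so requesting more than
the penetration depth allows triggers a clamp to all eligible cells
with a warning; this mirrors how a capped label request behaves in
practice and makes the "let the clamp decide" workflow natural.

Activity distributions among labeled cells:

* **uniform** — every labeled cell receives ⟨A⟩.
* **normal** — draws from N(⟨A⟩, σ²) redrawn until positive. The
  redraw slightly shifts the realized mean when σ is comparable to
  ⟨A⟩; tests exercise the σ ≪ ⟨A⟩ regime where the shift is
  negligible.
* **lognormal** — $\ln A \sim N(\ln\langle A\rangle - \sigma^2/2,
  \sigma^2)$, so the analytic mean equals ⟨A⟩ for every shape
  parameter σ (verified in the tests by both the closed form and
  sampling).
* **radial profiles** (linear, polynomial to degree 10, 4-parameter
  lognormal $a\,e^{-\ln^2((r-c)/b)/2s^2}$, user table) — the mean
  activity is a function of the distance r from the cluster centre
  (r = 0 at the centre), rescaled so the maximum over labeled cells
  equals the activity cap `max_mean_activity_Bq` exactly. Negative
  profiles over the labeled range are rejected. User tables are
  linearly interpolated with constant extension and restricted to
  spherical clusters; ellipsoids accept only the uniform, normal and
  lognormal methods.
* **radial exponential** — decays inward from the outermost labeled
  radius $R_{ref}$ with the user's factor k (µm⁻¹). When assigned to
  a population the depth $R_{ref} - r$ is first discretized into
  whole cell layers (one cell diameter each): a radiopharmaceutical
  binds layer by layer, and lattice-shell radii within one geometric
  layer spread over most of a spacing, which under a continuous
  exponential would split a single bound layer into a ~30-fold
  activity range for k = 0.4. With the layered convention a single
  labeled outer layer receives identical activities whatever the
  factor — the behavior the reference spheroid requires. The
  continuous form remains available through
  `radial_profile(..., layer_um = NULL)`.

Every cell carries the same subcellular split (f_N, f_Cy, f_CS),
summing to one.

## Dosimetry

Initial activities become decay numbers through the time-integrated
activity coefficient τ (hours): decays = A × τ × 3600. For pure
physical decay τ = T_p/ln 2 (`tau_physical_hours()`); with the
packaged ²¹³Bi half-life of 45.61 min this evaluates to 1.097 h,
about 1 % below the 1.11 h conventionally quoted for this setting —
the difference traces to the half-life datum and rounding, and either
value may be supplied. Any τ override models biological clearance.

Per-cell dose breakdowns are resolved by (radiation type, source
region, self/cross): self components are
$f_{region} \tilde A_k S^{self}$, cross components sum
$f_{region} \tilde A_j S^{cross}(d_{kj})$ over labeled neighbours
within the range cutoff, with the S values looked up exactly in the
precomputed distance table (a realized lattice distance missing from
the table is a hard error, never an interpolation). Accumulation
runs in fixed cell order, so totals are reproducible run to run.
Radial summaries report, per radial bin: mean activity per labeled
cell, mean self-dose and cross-dose to labeled cells, mean cross-dose
to unlabeled cells, mean decays per labeled cell, and mean dose to
all cells, with empty bins as `NA`.

## Bioeffect modeling

Survival follows the linear-quadratic model with self- and cross-dose
acting independently. The simple form uses one (α, β) pair per
self/cross; the complex form resolves every (radiation type, source
region, self/cross, target) component and multiplies the component
survivals — an independent-interaction model with no synergy terms
(interaction effects between radiation types are a known limitation,
not modeled). A parameter missing for a present dose component is a
hard error; the shipped default table (α = 0.1 Gy⁻¹, β = 0.01 Gy⁻²
everywhere) is an arbitrary placeholder and using it untouched warns
at compute time.

Cell fates are Monte Carlo: cell k survives iff a uniform draw
$u_k \in [0,1)$ satisfies $u_k < P_k$, realizing survival with
probability exactly $P_k$ (the comparison direction is a convention;
this one is exact for both endpoints). SF curves sweep the assigned
activity pattern linearly from zero to its nominal scale over 21
points (configurable), holding the labeling pattern fixed; each point
reports every domain (mean activity per cell and per labeled cell,
mean dose to all/labeled/unlabeled cells, mean decays per cell and
per labeled cell), the expected SF (mean of $P_k$ — the stable,
noise-free column), one fresh MC realization per point (independent
sub-streams, so curves are reproducible yet points are independent),
and both TCP formulations: Poisson $(1-\mathrm{SF})^n$ with n the
*total* cell count, and the per-cell product $\prod_i (1 - P_i)$
evaluated on the pre-draw probabilities. For identical $P_i$ the two
coincide; heterogeneity pushes the product below the Poisson value.

## Randomness and reproducibility

One master seed governs a run. Each stochastic stage — labeled-subset
selection, activity sampling, per-sweep-point fates, the MC oracle —
draws from its own named sub-stream derived by hashing the stream
name with the master seed, so changing one stochastic choice never
scrambles another, and a full run is bit-reproducible from its echoed
configuration alone (`run()` writes the echo, and the test suite
asserts file-level identity of repeated runs).

## What the reference conditions do and do not show

The packaged reference example — 3,473 cells, 12 µm penetration,
exponential factor 0.4, τ = 1.11 h, 0.02 Bq cap, α_α = 0.56 Gy⁻¹ with
β/Auger response zeroed — reproduces the qualitative physics of a
surface-labeled α-emitter spheroid: a steep α-driven first component
and a high-dose tail from the cold core, with survivors confined to
unlabeled interior cells. Passing it shows the geometry, dosimetry
and bioeffect chain is wired correctly at realistic scale. It does
not validate the underlying nuclear data to evaluation grade, photon
contributions (excluded), stochastic α-hit variance (means only),
bystander/abscopal effects, dose-rate or proliferation kinetics, or
non-lattice packings — all outside the model. Test problem sizes
(clusters of 30–125 µm radius, 10⁵-scale Monte Carlo histories) were
chosen to keep the full suite comfortably fast while leaving the
statistical checks several standard errors of headroom.
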