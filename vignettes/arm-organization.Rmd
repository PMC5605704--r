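---
title: "Crowding-driven organization of a confined ring polymer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crowding-driven organization of a confined ring polymer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(crowdring)
```

## The model

The circular chromosome of a rod-shaped bacterium such as *E. coli* can be
pictured, at scales above ~100 nm, as a ring polymer whose two halves — the
"arms" between the replication origin and terminus — lie side by side in a
cylindrical cell. The cytoplasm around it is dense with soluble proteins and
ribosomes. These crowders interact with the chromosome only by excluded
volume, yet their entropy generates effective (depletion) attractions between
chain segments, and between segments and the cell wall, that are strong
enough to compact the chromosome and to reposition its arms.

`crowdring` implements this picture as a minimal bead–spring model:

* **Ring**: N monomers of diameter *a* (the length unit), consecutive beads
  connected by FENE bonds,
  \(U_{\mathrm{FENE}}(r) = -\tfrac12 k r_0^2 \ln[1-(r/r_0)^2]\) with
  \(k = 30\,\epsilon/\sigma^2\), \(r_0 = 1.5\,\sigma\) — the standard
  Kremer–Grest choice, which together with the pair repulsion prevents chain
  crossing.
* **Crowders**: \(N_c\) spheres of diameter \(a_c = 0.3a\) at volume fraction
  \(\phi_c\) (bookkept against the nominal cylinder volume \(\pi (D/2)^2 L\)).
* **Excluded volume**: every pair interacts through the purely repulsive
  Weeks–Chandler–Andersen potential
  \(U_{\mathrm{WCA}}(r) = 4\epsilon_{ij}[(\sigma_{ij}/r)^{12} -
  (\sigma_{ij}/r)^{6} + \tfrac14]\) for \(r < 2^{1/6}\sigma_{ij}\), zero
  beyond, with Lorentz mixing for the lengths. The solvent is implicit
  (athermal); there are no attractive potentials anywhere — every effective
  attraction in the results is entropic.
* **Confinement**: a cylinder of diameter D (default 5a), either periodic
  along its axis (length \(L = 3R_0\), three relaxed chain sizes, so the
  chain cannot feel its image) or closed by repulsive caps.
* **Dynamics**: Langevin dynamics at \(k_BT = \epsilon\) with friction
  \(\gamma = 0.1\,\tau_0^{-1}\) and time step \(0.002\,\tau_0\), integrated
  by velocity Verlet with the exact Ornstein–Uhlenbeck velocity update
  applied once per step; \(\gamma = 0\) recovers symplectic NVE integration.
  The friction only sets the dynamics' time scale — equilibrium ensembles do
  not depend on it.

The single biological tuning parameter is the monomer–wall repulsion strength
\(\epsilon_{13}\) (in units of \(\epsilon\)). It coarse-grains everything
that modulates chromosome–membrane contact — most prominently transertion,
the co-transcriptional insertion of membrane proteins that tethers loci to
the inner membrane. Small \(\epsilon_{13}\) (soft wall) lets depletion push
the chain onto the wall; large \(\epsilon_{13}\) keeps it off.

### Wall convention

The wall is smooth and analytic by default: a particle of species *i* at
radial distance \(\rho\) feels the WCA law with parameters
\((\epsilon_{i3}, \sigma_{i3})\) applied to the effective gap
\(h = (D/2 + \sigma_{i3}) - \rho\). With this convention a particle whose
*center* sits on the nominal surface \(\rho = D/2\) is exactly at wall
contact (energy \(\epsilon_{i3}\)), the repulsion onset lies only
\((2^{1/6}-1)\sigma_{i3} \approx 0.12\,\sigma_{i3}\) inside the surface, and
the rescaled radial coordinate \(r = 2\rho/D\) spans essentially the full
interval \([0, 1]\) (with small thermal excursions past 1). This is the
convention under which the package's radial observables behave as intended: a
uniform monomer distribution gives \(\langle r^2\rangle = 0.5\) and a
wall-adsorbed chain approaches \(\langle r^2\rangle \to 1\). An explicit
bead-built wall (`wall_model = "beads"`, rings of species-3 beads with
configurable lattice spacing, handled through the ordinary pair path) is
available for fidelity checks; it is geometrically rough and considerably
slower, so the smooth wall is the production default.

### Observables

Three numbers characterize one configuration (`frame_observables()`):

* **R** — the longitudinal span of the ring after unwrapping the bonded path
  across the periodic boundary; the length of the imaginary tube enclosing
  the chain.
* **⟨r²⟩** — the mean squared radial monomer position rescaled by D/2:
  0.5 for a uniform cross-section, below it for a centrally biased chain,
  toward 1 for an adsorbed chain.
* **⟨r_L·r_R⟩** — the mean dot product of the rescaled transverse positions
  of opposing-arm monomer pairs: −1 when the arms face each other across the
  cylinder at the wall, +1 when they collapse onto each other, 0 when their
  angular positions are uncorrelated. The ring is split at beads 1 and
  ⌊N/2⌋+1 (the fold points of the initial condition, playing the role of
  origin and terminus); bead i+1 pairs with bead N−i+1 and the two split
  beads are excluded, giving ⌊N/2⌋−1 pairs.

`projected_profile()` histograms the rescaled in-plane transverse coordinate
of every monomer — both x and y projections, by azimuthal symmetry — over
`[-1, 1]`, emulating the projected locus densities measured by imaging. The
signed axis makes the arm-separated state visible as an "M"-shaped two-peak
profile; a folded |x| variant is attached since either axis convention is
defensible. The default of 41 bins resolves the wall peaks at desk-scale
sample counts.

`is_bimodal()` makes the visual two-peak judgement operational: maxima
off-center by at least 0.15 with a central dip of at least 5% of the peak;
both thresholds are arguments. By default the judgement is made on the
symmetrized profile *divided by the uniform (semicircle) baseline*. The raw
line-of-sight marginal is geometrically center-filled — a uniform
cross-section already projects to a semicircle — so even a strongly
wall-layered radial distribution (annulus density rising by a factor of two
from axis to wall, as in the narrow capped cylinder) dips only a few
percent at the center of the raw marginal. Relative to the uniform
baseline, "flat" means "uniform over the cross-section", wall layering
appears as genuine off-center maxima, and a centrally biased chain stays
single-peaked — which is what the two-peak judgement is meant to detect.
`baseline = "raw"` applies the same thresholds to the marginal itself.

`classify_state()` maps an ensemble summary to one of five organization
states: (i) weakly anticorrelated and centrally biased (the crowder-free
baseline), (ii) arms separated onto opposite sides at the wall, (iii) arms
intermingled near the wall (⟨r²⟩ high, correlation near zero), (iii′)
centrally condensed with uncorrelated arms, (iv) arms collapsed onto each
other (positive correlation). The thresholds (+0.1 / −0.2 on the
correlation, 0.8 / 0.6 on ⟨r²⟩) are read off the qualitative regime
descriptions and are configurable, because the boundaries are smooth,
model-dependent crossovers, not sharp transitions. The near-zero band is a
strict inequality so that the baseline's weak anticorrelation (≈ −0.1) stays
in state (i).

## What the generator builds

`build_system()` constructs the initial condition the analysis assumes:

* **Helical ring** (`build_ring()`): the ring is folded in half and the
  folded pair wound along a helix of radius ≈ D/4 — a deterministic, closed,
  self-avoiding coil whose bonds all sit within 5% of one bead diameter.
  In capped boxes the rise per bead shrinks so the coil fits between the
  caps; for extremely compressed boxes (monomer packing fractions near 0.5,
  e.g. D = 3a with L/R₀ ≲ 0.55) no clash-free coil of this family exists and
  construction fails with an explicit error rather than an overlapping start.
* **Crowders** (`place_crowders()`): random sequential insertion, uniform
  over the nominal cross-section and length, rejecting overlaps deeper than
  0.9 of the contact distance. Sequential insertion stalls well below the
  jamming fraction, so above \(\phi_c = 0.25\) crowders are inserted at 70%
  diameter and inflated back to full size over \(10^4\) relaxation steps
  (20 stages), after which velocities are redrawn from the
  Maxwell–Boltzmann distribution.
* **Velocities**: Maxwell–Boltzmann at the thermostat temperature.

Everything is derived deterministically from the spec's single integer seed;
replicate k of an ensemble uses `seed + k - 1` (sweeps space their cells
1000 seeds apart).

## Reference scales and presets

The relaxed chain size \(R_0 = R(\phi_c = 0)\) sets the box length
(\(L = 3R_0\) open, fractions of \(R_0\) capped). It is measured once per
(N, D) with `measure_r0()` and cached:

| N | D | R₀ (a) |
|---|---|--------|
| 135 | 5 | 29.9 |
| 135 | 4 | 33.9 |
| 135 | 3 | 39.3 |
| 60 | 5 | 13.2 |
| 40 | 5 | 8.8 |
| 20 | 5 | 4.3 |

measured at 4 replicates × 2×10⁶ steps with the first 20% discarded
(replicate standard errors < 0.1a). For comparison, the reference study of
this system reports R₀ ≈ 26a at (N = 135, D = 5a) with a bead-built wall;
our smooth-wall value sits ≈ 15% above it, which is the kind of sensitivity
to the wall microstructure one should expect for a confined chain, and is
why the package normalizes by its own measured R₀.

Two scale presets (`scale_preset()`) make the cost structure explicit.
`"paper"` mirrors the reference conditions — N = 135 everywhere, L = 3R₀,
5×10⁷ steps, 16 replicates — and is cluster-scale. `"desk"` is the package's
default study condition: N = 135 for crowder-free runs, a reduced chain
(N = 40) in a shorter box (L = 1.5R₀) for crowded runs, 2×10⁶ steps and 4
replicates. At these sizes the chain's Rouse-type relaxation is a few
thousand steps and the slowest observable (the arm correlation under dense
crowding) plateaus within the first 20–30% of a run, which is the basis for
the default 20% equilibration discard — the reference procedure states only
that averaging starts "after equilibration", so the discard fraction is
exposed as a parameter rather than guessed as a criterion.

One observable needs more than the desk default: the crowder-free arm
correlation. At φ_c = 0 the arms barely interact in a 5a tube, so
⟨r_L·r_R⟩ is small (about −0.01) and fluctuates slowly (its frame mean
wanders by ±0.03 over 10⁶-step stretches). The crowder-free reference
ensemble used by the acceptance checks therefore runs 8 replicates × 3×10⁶
steps — enough to pin R₀ to ±0.05a and the arm correlation to ±0.01, and
still about thirty-fold less sampling than the cluster-scale reference
conditions.

## Numerical choices

* **Integrator splitting**: kick–drift–kick velocity Verlet with one exact
  OU velocity update per step. At \(\gamma\,\mathrm{d}t = 2\times10^{-4}\)
  the thermostat discretization bias is negligible; the residual kinetic-
  temperature offset at dt = 0.002 τ₀ (≈1% for monomer-scale interactions,
  up to ≈3% for the stiffest crowder–crowder contacts, σ = 0.3a) is the
  usual finite-time-step effect of sampling velocities at integer steps and
  shrinks quadratically with dt.
* **Failure handling**: a bond reaching the FENE maximum extension or a
  particle found past the wall raises a classed integration-failure error
  naming the step, with the trajectory up to the last stable frame attached;
  overstretch is never clamped, since clamping would silently mask an
  unstable time step.
* **Forces**: the production path uses two linked-cell grids — one for
  monomers (and wall beads), one at the finer crowder cutoff — with the
  monomer–crowder interaction found by searching the fine grid with a wider
  stencil. A plain O(n²) brute-force path written independently in R serves
  as the oracle; the two agree to 10⁻¹⁰ per force component on every
  fixture, and energies are consistent with forces to 10⁻⁶ by central
  differences.
* **Determinism**: the engine uses its own counter-seeded xoshiro256++
  stream, so trajectories and observable tables are bit-reproducible from
  `(spec, seed)` regardless of R's RNG state; R-level randomness
  (placement, velocities) runs under a local seed that restores the
  caller's RNG.
* **Profile normalization**: histograms are normalized to unit integral over
  the rescaled interval; rare thermal excursions past |x| = 1 are clamped
  into the edge bins rather than dropped, preserving normalization.

## What desk-scale results do and do not show

The desk preset reproduces the mechanism, not the reference statistics at
publication scale: crowder-free chain size and radial structure at N = 135;
crowding-induced longitudinal shrinkage; adsorption at weak wall repulsion
and dense crowding (⟨r²⟩ → 1, on a reduced N = 40 system); and the
capped-cylinder contrast in which only the narrow D = 3a cylinder develops a
bimodal transverse profile. Full (φ_c, ε₁₃) phase diagrams at N = 135 with
~3×10⁴ crowders and 16 replicates of 5×10⁷ steps are out of desk reach by
orders of magnitude; `run_sweep()` will execute them under the `"paper"`
preset on appropriate hardware.

The synthetic systems emulate excluded volume, confinement and crowding
only. Real nucleoids add replication topology, supercoiling, heterogeneous
locus sizes (rRNA operons decorated with RNA polymerases), polydisperse
crowders, and active processes; none of these are modelled, so passing
desk-scale checks validates the entropic mechanism, not a quantitative
match to any particular cell.

## Known limitations

* The integrator supports the bead-built wall only as static particles on
  the barrel; in capped mode the end caps are always analytic.
* Initial-condition construction fails (by design, with an error) for
  capped boxes so short that the monomer packing fraction approaches 0.5.
* `phi_c` is bookkept against the nominal cylinder volume; the
  crowder-accessible volume is slightly smaller, so the effective crowding
  at a stated φ_c is marginally higher than in a accessible-volume
  convention. The convention is echoed into every run's metadata.
* Organization-state boundaries are smooth crossovers; labels near a
  threshold are sensitive to the configurable thresholds.
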