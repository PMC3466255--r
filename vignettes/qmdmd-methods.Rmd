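---
title: "Iterative QM/DMD sampling of metal-dependent active sites: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative QM/DMD sampling of metal-dependent active sites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmdmd)
```

## The problem this package addresses

Metalloenzymes such as catechol-O-methyltransferase (COMT) couple two length
scales: the chemistry at the metal center (here, an SN2 methyl transfer from a
sulfonium donor to a catecholate oxygen) and the packing of the surrounding
protein, which positions the reacting groups. Swapping the native Mg(II) for
Ca(II), Fe(II) or Fe(III) changes activity through two distinct channels — the
size of the cation (a structural, protein-scale effect) and its charge (an
electronic, active-site-scale effect). Studying that interplay requires a
sampling scheme that lets the protein respond to the metal and the metal
chemistry respond to the protein.

`qmdmd` implements such a scheme as a reusable pipeline: iterative alternation
between event-driven discrete molecular dynamics (DMD) of the whole system and
quantum-style relaxation of an extracted, hydrogen-capped active-site cluster,
with a breathing boundary between the two. Because real density-functional
calculations are far outside desk scale, the quantum stage is a *pluggable
backend*: the package ships an analytic surrogate potential engineered to
respond to metal radius, metal charge and donor-acceptor collinearity in the
directions the real chemistry responds. Everything downstream of the backend —
partitioning, capping, constrained sampling, clustering, scoring, acceptance,
stationary-point analysis — is exactly the protocol logic, and is what this
package exists to test.

## Three domains and the breathing boundary

The system is partitioned into three domains:

* **QM-only**: the metal and every heavy atom within a coordination cutoff
  (default 2.6 Å) of it at the current geometry. These atoms are *frozen
  during DMD* — the sampler moves the protein around a fixed coordination
  core — and free during the quantum stage.
* **QM-DMD**: the shared domain (selected side-chain fragments, substrate,
  water, a donor-group fragment). Both stages move these atoms.
* **DMD-only**: the remainder. The quantum stage never sees these atoms.

The "breathing" of the boundary is realized as two static masks applied in
alternation, not as a per-step repartition: DMD sees the QM-only core frozen;
the quantum stage sees the extracted cluster with its boundary frozen. The
domain assignment (including donor identification) is recomputed at the start
of every iteration, so a donor that drifts out of the coordination sphere is
reassigned.

Severed boundary bonds are saturated with hydrogen caps placed along the
original bond at 0.7052 × R(inner–outer). The factor is applied uniformly; a
boundary bond that severs a non-C/N atom (as happens at the donor-group
scaffold of the toy sites) is flagged with a warning. Caps and their inner
bond partners are frozen during cluster optimization, pinning the cluster in
the frame dictated by the rest of the system.

## Constrained event-driven DMD

The sampler propagates atoms ballistically between instantaneous events on
stepwise pair potentials:

* covalent bonds: infinite square wells spanning ±5% of the reference length;
* 1–3 pairs: infinite wells spanning ±10% (the standard DMD device for
  angular stiffness);
* pocket-frame reference pairs (toy systems only, see below): wide hard
  windows spanning ±15%;
* constraint pairs ("green lines"): hard windows of ±0.01 Å around the
  distance found in the previous QM-optimized cluster — this is how quantum
  information steers the classical sampling;
* everything else: a 3-step nonbonded stand-in — hard core at 0.85 × the
  van-der-Waals-radius sum and two attractive shells at 1.0× and 1.25× with
  depths −0.10 and −0.05 kcal/mol. The published all-atom DMD force field is
  deliberately not reproduced; sampling behaviour, not force-field fidelity,
  is what the downstream stages need. The metal has no nonbonded terms at
  all: its coordination is handled by freezing and constraints.

A hard core that would already swallow a declared native contact (hydrogen
bonds, coordination contacts) is shrunk below the observed distance — those
contacts are chemistry, not clashes.

Temperatures are *reduced*: θ in kcal/mol with ⟨KE⟩ = (3N_free/2)·θ. The
printed protocol temperatures (0.10, 0.20) are taken as θ; one DMD time unit
corresponds to about 50 fs (and in fact the internal unit system — kcal/mol,
amu, Å — implies a time unit of 48.9 fs). An Andersen thermostat hits each
free atom as a Poisson process (production rate 0.1 t.u.⁻¹), resampling its
velocity from the Maxwell–Boltzmann distribution; between ghost collisions the
event-driven update conserves total energy to rounding (≤10⁻⁹ kcal/mol over
10⁴ events, asserted in the tests).

A phase schedule mirrors the published protocol: an instantaneous ramp to
θ = 0.20 followed by five 500-t.u. anneal stages stepping down by equal
decrements (0.20, 0.18, 0.16, 0.14, 0.12), then a 10,000-t.u. production
phase at θ = 0.10 saving a snapshot every 10 t.u. — exactly 1,000 poses per
phase. The ramp's duration and the anneal exchange rate are not stated in the
protocol; the package uses an instantaneous set-point change and the
production exchange rate. A separate preparation run (1,000 t.u. at θ = 0.10
with exchange 10 t.u.⁻¹) relieves clashes once, before the first iteration.

## Ensemble reduction and the acceptance rule

Each production ensemble is clustered into 5 clusters by average-linkage
agglomerative clustering on the pairwise Kabsch-RMSD matrix of the QM-DMD
region's heavy atoms (the region the quantum stage will see). Two
representatives per cluster are taken: the centroid (minimal summed RMSD to
its cluster) and the lowest-DMD-energy member. Each representative's capped
cluster gets a single-point backend energy, and one structure is chosen by a
*rank-sum score*: rank by QM energy plus rank by DMD energy, ties broken by
lower QM energy, then lower snapshot index. The rank sum is scale-free, which
matters because the two energy scales are not commensurable; the protocol
source defers the exact scoring formula to prior work, so the package makes
this choice explicitly.

The chosen cluster is partially optimized on the backend (caps and partners
fixed), reinstalled, and the iteration ends with an energy-based acceptance:
the backend energy of the active-site *subset* (site residues + metal +
substrate + water) is evaluated for the iteration's input and output
structures, and the lower one is carried forward (ties prefer the output).
This makes the carried subset energy non-increasing by construction — the
property the convergence traces (backbone RMSD, active-site RMSD, subset
energy per iteration) report. Twenty iterations is the protocol default;
there is deliberately no automatic early stopping.

Before iteration 1 the pipeline runs one extract → optimize → reinstall pass:
the first DMD phase needs QM-derived constraint targets, and the QM-only core
must be frozen at positions consistent with them. Freezing a distorted core
against native-referenced wells would make the window system infeasible.

## The synthetic toy sites

`make_toy_site()` builds a desk-scale stand-in for a metal-dependent active
site with *known ground truth*: a central cation octahedrally coordinated by
carboxylate- and amide-like donor arms on anchored zigzag linkers, an aqua
ligand, a bidentate catechol-like substrate carrying the acceptor oxygen and
its abstractable proton, a frozen S–CH3 donor group aimed at the acceptor at
the near-attack angle, and a base site positioned to receive the proton. The
default native distances are the experimentally observed values for the
Mg-bound site (e.g. metal–water 2.04 Å, metal–acceptor O 2.21 Å,
donor-carbon–acceptor O 2.71 Å, S–C–O angle 170°); every requested metric is
met exactly (to 10⁻⁶ Å) at the constructed geometry, which therefore doubles
as the recovery oracle. One printed inconsistency is worth noting: the
experimental triple (O–C 2.71, S–C 1.80, O–S 4.51 Å) is exactly collinear,
contradicting the printed 170°; the toy constrains O–C and the angle and lets
O–S be derived (≈4.49 Å).

Metal presets use six-coordinate Shannon-style ionic radii: Mg 0.72 Å (+2),
Ca 1.00 Å (+2), Fe(II) 0.78 Å (+2), Fe(III) 0.645 Å (+3).
`make_metal_variant()` swaps parameters without touching geometry —
relaxation is the pipeline's job, which is exactly what the no-repacking
control (`static_cluster_mode()`) switches off.

Because the toy has no protein matrix, ligand orientations would have
zero-stiffness modes a real pocket removes (free rotation of the water, of
the methyl about the S···O axis, torsional flips of anchored chains — and a
pure mirror ambiguity: three distance references pin an atom only up to
reflection). The generator therefore emits *pocket-frame reference pairs*:
each mobile atom is tied to its four nearest frame-target atoms (the
outermost linker of each arm and the donor scaffold — atoms that are present
and frozen in the extracted cluster, so the stiffness survives extraction)
with weak harmonics (k = 6 kcal/mol/Å², native-referenced), plus 1–4
reference pairs (k = 8) for torsional stiffness. The DMD stand-in carries the
same pairs as wide hard windows. These restraints are generator artifacts
standing in for pocket packing; systems read from PDB files do not get them.

What the toy deliberately does *not* emulate: real protein topology,
rotamers, solvent, electrostatics, or the absolute energetics of any real
enzyme. Passing tests on the toy demonstrate that the protocol machinery —
partitioning, capping, constrained sampling, selection, acceptance, saddle
searches — behaves correctly and responds to metal parameters in the right
directions; they say nothing quantitative about real COMT.

## The surrogate backend

The backend contract is {energy, gradient, partial_optimize, hessian}; any
engine honouring it can be plugged in. The shipped surrogate is smooth (C²
away from the 12-6 core), rotation- and translation-invariant (all terms are
built from interatomic distances and angles), with analytic gradients
verified against central differences at 10⁻⁵ relative tolerance:

* **Metal–donor Morse wells**, equilibrium = native distance + (r_ion −
  0.72 Å), depth = 30·(q/2) kcal/mol, range 2 Å⁻¹. Radius moves equilibria
  outward monotonically; charge deepens the wells monotonically.
* **Bonded/1–3/frame harmonics** at the system's reference lengths
  (k = 300 / 60 / as-tagged kcal/mol/Å²).
* **12-6 nonbonded** (ε = 0.02 kcal/mol, r_min = 0.9 × vdW sum) between heavy
  atoms at graph distance ≥ 3; hydrogens and the transferring methyl carbon
  are excluded (their interactions are owned by bonded and coupled terms),
  as are pairs closer than r_min at the reference geometry (declared native
  contacts).
* **The two-well transfer term** along ξ = R(O–C) − R(S–C) (reactant ξ > 0,
  product ξ < 0; ξ decreases as the methyl moves S→O):
  V(ξ) = A_b(α)·b·((ξ/w)² − 1)² + Δ·(2 − 3u + u³)/4 + k_σ·(σ − σ₀)² with
  u = ξ/w, σ = R(O–C) + R(S–C). The cubic switch puts the minima exactly at
  ξ = ±w for any asymmetry Δ (its slope vanishes at both ends), the barrier
  is b + Δ/2 near ξ = 0, and the interior saddle sits at u = −3Δ/(16b): an
  endothermic shift moves the saddle toward the product, the Hammond–Leffler
  direction, as a closed-form property. Defaults: b = 18, w and σ₀ from the
  native geometry, Δ = 3 + 4·(q − 2) kcal/mol — the charge coupling
  stabilizes the reactant side for more electrophilic cations.
* **Collinearity coupling**: A_b = 1 + κ·(1 + cos α) with α the O–C–S angle
  scales the barrier instantaneously (κ = 1). Applying the same
  instantaneous factor to the asymmetry proved self-defeating — the relaxed
  product simply re-collinearizes and the factor anneals away — so the
  asymmetry response is applied per ensemble member instead:
  `reaction_profile()` scales each member's Δ by
  1 + κ_rxn·(1 + cos α_reactant) (κ_rxn = 6) using the member's *reactant*
  near-attack angle, then keeps that surface fixed along the member's path.
  This encodes the physical claim that a misaligned pocket destabilizes the
  bound product, as a property of the pocket conformation rather than of the
  instantaneous geometry.
* **Proton coupling**: the abstractable H is tethered (k = 150) to the point
  a fraction λ(ξ) along the acceptor-O → base-N axis, with λ sliding from the
  native O–H distance to near the base as a C² smootherstep of ξ. R(O–H)
  therefore elongates monotonically reactant → TS → product; with the
  coupling off it stays at its reference. A distance-well formulation was
  rejected because two collinear reference points leave the proton an
  azimuthal degeneracy.

Hessians are central finite differences of the analytic gradient (step
10⁻³ Å for characterization, 10⁻⁴ within the saddle polish), mass-weighted;
eigenvalues below −10⁻⁵ count as imaginary; the zero-point energy is
½·ħ·Σω over the positive modes only, with ħ = 0.3105 in internal units
(kcal/mol · 48.9 fs).

## Stationary points and profiles

`find_minimum()` relaxes and confirms (0 imaginary modes, else flagged —
never silently accepted). `find_product()` drags the system down the product
side by a restrained ξ-scan and relaxes freely. `find_ts()` scans ξ between
the two minima (41 points by default, each relaxing all other free
coordinates under a k = 500 restraint), takes the highest interior point, and
polishes it with Newton steps on the full free-space Hessian (step cap 0.3 Å;
divergence returns the scan maximum flagged "unpolished"). The saddle must
have exactly one imaginary mode, and its eigenvector is checked to lie on the
transferring group. `reaction_profile()` assembles ZPE-corrected ΔE‡ and
ΔE_rxn relative to each member's reactant, reports ensemble mean (SD) plus
the key structural parameters at each stationary point, and counts (never
hides) members whose search failed. When several product conformers exist the
product reached by downhill relaxation from the scan's end is the one used.

## Numerical choices and degenerate inputs

* Optimizers: L-BFGS-B with analytic gradients; partial optimization
  converges the largest free gradient component below 10⁻⁴ kcal/mol/Å
  (10⁻³ inside the iteration loop, where the sampler immediately re-thermalizes).
* Event queue: lazy invalidation by per-pair sequence stamps; a pair left a
  rounding sliver (< 0.01 Å) outside its window after clash relief is snapped
  to the adjacent allowed region and reflected back by its first wall event.
* Clash relief: L-BFGS minimization of squared hard-wall violation depths
  over the free atoms, iterated to machine-level residuals, with a warning.
* Identical snapshots under clustering: `stats::hclust`/`cutree` proceed;
  ties resolve by snapshot index, deterministically.
* Degenerate (collinear) Kabsch selections proceed (the SVD handles them);
  fewer than 3 atoms is an error.
* All randomness flows from explicit integer seeds: the engine uses a
  dedicated 64-bit generator seeded from the phase seed, and per-stage seeds
  derive deterministically from the run seed, so reruns are bit-identical.

## Problem sizes used in the tests

The shipped tests exercise the full protocol at the study conditions
(10,000-t.u. production phases, 1,000 poses, 5 clusters, ±0.01 Å windows) on
toy sites of 34 atoms (three arms) and 69 atoms (six long arms, > 50 free
atoms, used for the thermostat check). The recovery experiment distorts the
Mg-like site by σ = 0.4 Å and runs 4 iterations for each of 10 seeds;
reaction profiles in the trend checks use 2-member ensembles with a 31-point
scan. Mechanistic closed-form checks run on a 3-atom S–CH3···O system that
isolates the transfer term.

## Known limitations

* The surrogate's absolute energies are meaningless; only directions and
  protocol-level quantities (counts, temperatures, window enforcement,
  conservation) are asserted. Reproducing the published per-metal barriers
  would require density-functional theory on the real enzyme.
* The DMD stand-in has no hydrogen-bond directionality, implicit solvent, or
  electrostatics; the real all-atom DMD parameterization is out of scope.
* Spin states, charge compensation for the +3 cation, and embedding are
  outside the surrogate's vocabulary (charge is a scalar parameter).
* The no-repacking control shares the surrogate's limitations; it is a
  protocol control, not an independent method.
* The toy's pocket-frame restraints make recovery easier than for a real
  protein; the recovery acceptance is a machinery test, not a claim about
  folding.
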