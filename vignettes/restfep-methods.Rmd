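---
title: "Models and methods behind restfep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind restfep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restfep)
```

restfep estimates relative binding free energies of fragment-like
ligands by Metropolis Monte Carlo free energy perturbation (MC/FEP),
with replica exchange with solute tempering (REST) to sample the
binding-mode torsions that plain Metropolis chains cannot cross.  This
vignette records the model, the choices that were genuinely open, and
what the validation does and does not demonstrate.

## The energy model

A system is a set of point particles grouped into rigid fragments that
are joined by rotatable torsions.  The degrees of freedom are the
torsion angles and the rigid-body placement of mobile bodies; bond
lengths and angles never change, mirroring internal-coordinate Monte
Carlo practice and keeping exact oracles computable.  The potential is
a reduced OPLS-style form:

* Lennard-Jones 12-6 plus Coulomb (constant 332.06 kcal Å mol⁻¹ e⁻²)
  over all non-excluded pairs, geometric combination for both σ and ε,
  1-2/1-3 pairs excluded and 1-4 pairs scaled by 0.5 in both terms;
* OPLS Fourier torsions
  `V(θ) = V₁/2(1+cos θ) + V₂/2(1−cos 2θ) + V₃/2(1+cos 3θ)`, with
  angles kept in degrees on [0, 360);
* no cutoffs, no periodic boundary, no explicit solvent — the systems
  are tens of atoms, so every pair is summed.

Note a consequence of the OPLS V₂ sign convention: a positive-V₂
"double well" has its minima at 0° and 180° (where cos 2θ = 1), not at
90°/270°.  All double-well examples and tests use the 0°/180° wells.

Every atom carries a region label — `LIGAND`, `HOT_RESIDUE`, or
`ENVIRONMENT` — and the total energy is decomposed into solute–solute,
solute–environment and environment–environment components (solute =
ligand ∪ hot residue).  Pairs are classified by their two atoms;
torsions by the majority region of their four atoms, with ties counting
as solute–solute.  Both flexible torsions (the ligand linker φ and the
side-chain χ) therefore sit in the solute–solute component, which is
exactly what REST needs to temper their flips.  The decomposition is
validated against a brute-force single-loop sum on randomized systems.

## Alchemical mutations

Mutations are single-topology: a fixed atom set whose charge, σ, ε
(and optionally torsion amplitudes) interpolate linearly between end
states A and B.  λ = 0 and λ = 1 reproduce the pure endpoints to
machine precision (a tested invariant).  Pairs involving an atom whose
LJ well depth vanishes at one endpoint switch to a separation-shifted
soft-core form (α = 0.5, power-6 shift) whose offending term is turned
off linearly in λ, so energies stay finite as the atom decouples.  The
packaged substituent swaps never annihilate an atom, so soft-core is
dormant in the shipped workflows, but it is exercised by tests with a
deliberately vanishing atom.

## Sampling

Moves are symmetric proposals: rigid-body translations (≤ 0.15 Å) and
rotations (≤ 15°) of the ligand, and torsion perturbations (≤ 15°).  A
torsion move proposes, with probability 0.1 by default, a *flip* of
±120° or 180° instead — the move class that hops directly between
rotamer wells.  The default mix is 40% rigid-body, 40% ligand torsion,
20% hot-residue torsion, which gives roughly 40% acceptance on the
default pocket; all of this is configuration, not hard-coded.  The
default temperature is 298.15 K with k = 0.0019872 kcal mol⁻¹ K⁻¹.
Each chain is driven by its own counter-seeded xoshiro256++ stream, so
a (system, moves, config, seed) tuple reproduces its trajectory
bit-for-bit on any platform; the seed is mandatory.

The incremental energy of a move sums only the interactions of the
moved atoms (precomputed per move class); agreement with a full
recomputation is a tested invariant, as is the convergence of an
isolated rotor's sampled marginal to the quadrature Boltzmann density.

## REST

The hot region is the solute: ligand plus the designated pocket
residue.  Replica m runs at the thermal temperature under the REST2
scaling `E_m = r·E_ss + √r·E_sw + E_ww` with `r = T₀/T_eff`; the
original-REST alternative (scaling only solute internal terms) was
rejected in favor of the variant used by the MC/FEP implementations
this package emulates.  The default ladder has 6 replicas, effective
temperatures geometric from 298.15 K to 1200 K, swaps attempted every
100 steps on alternating even/odd neighbor pairs.  Swap acceptance uses
the Hamiltonian-exchange exponent at the common thermal β; the
environment–environment component cancels algebraically (tested on
random decompositions).  Because swaps exchange *configurations*, the
ladder-position-0 replica always samples the physical ensemble and is
the only source of frames for downstream estimators.

Whether the real protocol scales the whole residue or only its torsion
is not decidable from the sources this model abstracts; the package
scales the whole residue (all its nonbonded terms and its torsion), the
simpler and more aggressive choice, and the region labels make the
alternative a one-line system edit rather than a config switch.

## Free energy estimation

Windows sit on an 11-point equally spaced λ schedule by default.  Each
window simulates at λᵢ and stores, for every recorded frame, the energy
gaps to both neighbors (double-wide sampling); the Zwanzig estimator
with a log-sum-exp guard turns each gap list into an increment, block
averaging (10 blocks) gives its standard error, and window errors
combine in quadrature.  The leg total is the symmetrized
`(forward − backward)/2` with `|forward + backward|` reported as
hysteresis.  The Zwanzig average is deliberately the *only* estimator:
it keeps the oracle surface small, and acceptance-ratio estimators are
out of scope.

The unbound leg is the ligand alone, in vacuum, with the same force
field — a documented simplification of a solvated unbound state.  Mean
offsets and relative comparisons downstream do not depend on it being
solvated, but absolute leg values should not be interpreted.

Validation is oracle-first: for an isolated rotor the partition
function is a 0.1° trapezoidal quadrature (halving the grid moves ΔG by
< 1e-8 kcal/mol), the V₁-only mutation has the closed form
`ΔG = V₁/2 − kT ln I₀(V₁/2kT)`, and FEP totals must agree within three
standard errors.  On the pocket complex, three-substituent cycle
closure and A→B vs B→A antisymmetry are tested the same way.

## The toy pocket

The fixture generator emulates the geometry that makes this problem
interesting: a hydrophobic cage (14 sites, hemispherical shell of
radius 6.5 Å below the ligand plane, ε 0.12, σ 3.5, neutral), a
three-site side-chain rotor anchored at the cage wall with a 3-fold χ
(V₃ = 4 kcal/mol), and a two-ring ligand (hexagons of σ 3.55 / ε 0.07
carbons) joined by a linker torsion φ with one substituent site at the
meta position of the distal ring.  Substituent parameters (H, F, Cl,
Br, CH3) are synthetic, OPLS-flavored magnitudes chosen so that σ grows
along the halogen series and the bulkier substituents sterically couple
to the rotor; they are fixture definitions, not measurements.

The construction is deterministic given a seed (the seed jitters the
shell sites by ±0.15 Å).  Three placement rules shape the landscape:

* the rotor tip is built at the cone azimuth nearest the substituent
  site and the (fixed) anchor site is placed so that this rotamer reads
  χ = 180°, making rotamer labels geometry-independent;
* shell sites that would crowd the χ = 60° or χ = 180° rotamer are
  pushed radially outward (the side chain replaces the wall there),
  while the site nearest the third 3-fold position is moved to press
  against it, leaving two reachable rotamers like a buried leucine;
* at χ = 180° the tip reaches ~2.5 Å from the substituent site, so the
  substituent and the tip compete for the same pocket corner: with a
  small substituent both rotamers are populated, with Cl/Br the direct
  χ flip into the occupied corner is a several-kcal clash that only a
  concerted φ/χ rearrangement (or REST) can get around.

A 36×36 grid scan with flood-fill saddle detection verifies, for every
substituent, that at least two binding modes exist in different χ
rotamers behind a barrier above 2 kT.  The low-lying modes sit at
(φ ≈ 180°, χ = 180°/60°) and at twisted-linker states φ ≈ 70–80° and
280–290°; for mode-population analysis the two twisted basins pool into
the non-planar mode center at 330°, the package default (centers φ
{180°, 330°}, χ {60°, 180°}).

What the toy does *not* emulate: explicit water and its entropy,
protein backbone response, long-range electrostatics, and any real
chemistry of the fragments — so passing tests demonstrate correctness
of the estimators and the sampling machinery, not predictive accuracy
for a real target.  The shipped benchmark table is accordingly a table
of *published* computed-vs-measured numbers, not something the toy
engine regenerates.

## Benchmarking analytics

Experimental relative free energies derive from IC50 as RT ln(IC50/μM)
at 298.15 K (natural log); the additive constant of the unit choice is
irrelevant because computed values are offset to the experimental mean
before computing the mean unsigned error, RMSE, and Pearson r (offset
invariance is a tested property).  Ki-based alternatives
(Cheng–Prusoff) are out of scope.  The packaged table carries ten
compounds of the published fragment series; the two without a measured
IC50 are excluded by the statistics (n = 8).  Recomputing on this
subset gives MUE 0.267, RMSE 0.338, r 0.848 against the published
0.24 / 0.32 / 0.86 — the small residual is consistent with the
published correlation including additional compounds whose computed
values are not printed in the main text.

Mode populations use nearest-center circular assignment (ties to the
first center) and report the symmetric-mode entropy term
`T·ΔS = −kT Σ pᵢ ln pᵢ`, the free-energy cost of losing equivalent
binding modes; it is kT ln M for M equal modes (0.411 kcal/mol for two
at 298.15 K).

## Numerical and statistical choices

* Zwanzig averages are computed with a max-shift guard; Metropolis
  accepts ΔE ≤ 0 unconditionally, guarding `exp` overflow.
* Dihedrals use the atan2 convention wrapped to [0, 360); a torsion set
  to angle θ reproduces θ to 1e-9°.
* The first 20% of each chain is discarded before recording (a config
  key, not a constant); recording strides are chosen per experiment.
* Statistical tests on sampled histograms pool reference bins below
  probability 5e-3 and, for REST-demuxed series, estimate the effective
  sample size by block averaging — demuxed frames carry long-range
  correlation through walker identities that frame-level
  autocorrelation underestimates — then thin to ~independent frames
  before a χ² comparison.
* Starting-structure consistency passes when repeat totals agree within
  three combined standard errors (the default tolerance).

## Problem sizes used in the shipped validation

Rotor FEP runs use 11 windows × 2×10⁵ steps; pocket binding cycles use
11 windows × 3×10⁴ REST steps per window for the complex leg (6
replicas) and plain chains for the vacuum ligand; the double-well REST
demonstration uses 2×10⁶ steps with flips disabled, which is what makes
the equal-length plain chain stay trapped in its starting well while
REST recovers the symmetric 50/50 populations.  These sizes give
standard errors a few thousandths of a kcal/mol on the toy systems and
were fixed once when the experiments were designed.

## Known limitations

* The unbound leg is in vacuo; solvation thermodynamics of the free
  ligand is absent.
* The Zwanzig estimator is asymptotically inefficient compared to
  acceptance-ratio estimators when window overlap is poor; the shipped
  schedules have generous overlap, and hysteresis is reported so poor
  overlap is visible.
* Block-averaged errors understate badly under-converged runs (as all
  block estimators do); the starting-structure check exists precisely
  to catch that failure mode.
* The toy pocket's twisted-linker modes are a feature of its reduced
  sterics; their positions (±70–80° from planar) should not be read as
  chemistry.
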