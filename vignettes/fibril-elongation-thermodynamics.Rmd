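---
title: "Thermodynamics of seeded amyloid fibril elongation on a lattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamics of seeded amyloid fibril elongation on a lattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

Amyloid fibrils are β-strand-dominated protein polymers whose thermodynamic
stability is much less well characterised than that of folded proteins.
Calorimetry shows that fibril elongation — the addition of a monomer to a
pre-formed fibril end — is usually exothermic with a strongly negative heat
capacity, and a few systems even dissolve on cooling (cold denaturation).
Both observations are classic signatures of the hydrophobic effect, whose
strength is maximal near a temperature `T0` and weakens on either side.

`fibrilMC` implements a coarse-grained lattice model of seeded elongation in
which this temperature dependence is explicit, together with the analysis
layer used to read thermodynamics out of it and the regression tools used to
connect it to calorimetric and chemical-depolymerisation experiments.

# The hydrophobic-effect model

The free energy of keeping a hydrophobic side chain in contact with solvent
is modelled as a downward parabola,

$$F_{hydr} = -\alpha\,C_h\,(T - T_0)^2,$$

with `C_h` the number of solvent-exposed hydrophobic contacts, `alpha` the
strength of the temperature dependence, and `T0` the temperature of the
maximal hydrophobic effect (0.4 in reduced units; 343.15 K is used when
fitting experimental enthalpies).  Because the Hamiltonian depends on
temperature, the mean energy is not `<H>` but the β-derivative of `βH`,
which gives the exposure enthalpy

$$E_{hydr} = -\alpha\,C_h\,(T_0^2 - T^2), \qquad
  -T S_{hydr} = F_{hydr} - E_{hydr}.$$

For an elongation step that buries `ΔC_h` hydrophobic contacts these
closed forms give the estimates

$$\Delta\hat G(T) = \gamma (T-T_0)^2 + E_{int}, \qquad
  \Delta\hat E(T) = \gamma (T_0^2 - T^2) + E_{int}, \qquad
  \gamma = \alpha\,|\Delta C_h|,$$

implemented in `estimate_elongation()`.  Burial means the free-energy
penalty grows on both sides of `T0` (the origin of cold and heat
destabilisation), while the enthalpy falls monotonically with slope
`-2γT`: a negative heat capacity.  We adopt `γ ≥ 0` for burial-driven
assembly throughout; the literature writes the same relation with either
sign depending on whether exposure or burial is counted, and only the
burial convention reproduces the negative measured heat capacities.
`crossover_temperature()` returns the root of `Δ\hat E`, the temperature at
which elongation switches from exothermic (high `T`) to endothermic
(low `T`).

# The lattice model

Each residue occupies one site of a cubic lattice (hard walls, default edge
20 sites) and carries a side-chain direction (one of the six axis
directions) and a β-strand flag.  The Hamiltonian, in reduced `k_B T`
units, is

$$H = E_{hb} + E_{steric} + E_{state} + E_{aa} + \Phi_{solvent}(T),$$

and only the solvation term depends on temperature.  The concrete rules
are:

* **Pair interactions** (`E_aa`): residues on adjacent sites interact with
  `ε_{ij}` only when their side chains point at each other.  The default
  table is derived from an octanol–water side-chain transfer scale
  restricted to the nine hydrophobic residue types `C F L W V I M Y A`
  (so `ε_FF < ε_LL < 0`, making leucine fibrils weaker than phenylalanine
  fibrils).  An orientation-blind contact rule was tried first and rejected:
  it lets non-specific adsorbed blobs out-compete every ordered state.
* **Hydrogen bonds** (`E_hb`): formed between residues of different chains
  on adjacent sites, both in the β-state, with parallel side chains
  perpendicular to their separation.  Two concretisations beyond that rule
  proved essential.  Bonds *saturate*: a residue contributes at most two
  bonds (one per neighbouring strand in a sheet),
  `E_hb = (ε_{hb}/2)\sum_i \min(2, n_i)`; without saturation, crumpled
  two-chain β-crystallites with multiply-bonded residues dominate the
  ensemble.  And bonding requires a *locally extended backbone* (interior
  residues collinear with both neighbours), the lattice rendering of the
  fact that β-strands are extended.
* **β-state entropy** (`E_state`): each β residue pays `ln N_β`, the
  entropy of the coil substates it gives up.  Default `N_β = e` (one unit
  per residue).
* **Sterics**: backbone excluded volume is a hard constraint of the
  sampler; in addition each pair of side chains pointing at the same site
  pays a penalty (default 2).
* **Solvation**: `Φ = \sum_i (F_{hydr}(i) + ε_{a_i,solv})K_{i,solv}`, with
  `K = 1` when the side chain points at a site not occupied by *another*
  molecule.  Hydrophobic residues are exactly those with
  `ε_{a,solv} > 0`.  Counting only intermolecular shielding matters: if a
  chain could bury its own side chains against its backbone, the monomeric
  ensemble would partially bury its phenylalanines and the buried-contact
  difference between the monomeric and fibrillar states would drift below
  its geometric value of 6, corrupting the heat-capacity signature.

## Geometry and order parameters

The seed is a double β-sheet: each layer is two in-register, anti-facing
strands whose hydrophobic side chains point into the inter-sheet core;
four layers (8 chains) stack along the fibril axis and are rigid during
sampling (only rigid-body seed moves are allowed).  Two free chains of the
same sequence (default `TFTFTFT`) attach and detach.  For this geometry a
fully docked extra layer makes exactly 21 external contacts (7 inside the
layer + 7 from each strand to the seed layer below) and buries the 6
phenylalanine side chains of the two chains — the constants used
throughout the analysis.  The order parameters are the external contact
count `c_ext`, the in-register (native) contact fraction, and the exposed
hydrophobic count `c_h`.

Configurations are classified as monomeric (`c_ext ≤ 1`), fibrillar
(native fraction `≥ 18/21`), fully aggregated (all 21 native contacts) or
amorphous (everything else); the thresholds are explicit arguments
(`state_thresholds()`) because the underlying cutoffs are a modelling
choice, not a measurement.

## Calibration of the default tables

The qualitative physics pins the energy scales only loosely, so the
shipped tables were calibrated once, against the state diagram itself, and
then frozen: pair-scale 0.50, solvent-scale 0.95, `ε_hb = -1.60`,
`N_β = e`, steric penalty 2.  With the hydrophobic temperature dependence
off (`alpha = 0`) the `TFTFTFT` fibril is then the dominant state from the
lowest temperatures up to `T ≈ 0.3` and is lost on heating, with no
cold-side loss; at `alpha = 60` a fibrillar window at `T ≈ 0.25–0.30` is
bounded *below* by denaturation into monomers (`T ≈ 0.2–0.225`) and into a
disordered attached state at the very lowest temperatures — the
fibril-attached-but-no-core ensemble — and *above* by heat denaturation.
The heat-denaturation boundary sits near `T ≈ 0.3` at `alpha = 0`, on the
low side of where comparable lattice models of fibril growth place it
(`~0.4`); pushing it higher requires interaction strengths that freeze the
sampler at desk scale, and we chose sampling correctness over that
boundary.

# Sampling

`run_elongation()` is a Metropolis Monte Carlo sampler (in C++) over
single-residue moves (end rotation, corner flip, crankshaft), side-chain
and β flips, rigid chain translations/rotations/jumps and rigid seed
moves, all with symmetric proposal distributions; acceptance uses the full
temperature-dependent `H(T)`, treating the solvation term as a potential
of mean force.  Parallel tempering couples the temperature grid, with an
exchange criterion that evaluates each configuration under both
temperatures (required because `H` itself depends on `T`).  A single PCG32
stream seeded from `rng_seed` drives the whole run, so sample streams are
bit-identical across repeats.

Two protocol decisions deserve emphasis:

* **Two-sided initialisation.**  Spontaneous docking of both free chains
  into register is a rare event far beyond desk-scale runs (the
  transition is strongly first-order-like).  The default protocol
  therefore starts alternating replicas from the fibrillar and monomeric
  reference states; replica exchange sorts configurations to the
  temperatures where their basin is favoured and conversions at the hot
  end of the ladder renormalise the populations.  Dominant-state diagrams
  read from such runs recover the correct transition topology; absolute
  free-energy differences at temperatures deep inside one basin remain
  unreliable and are flagged (`sampled = FALSE`) rather than reported.
* **Basin-restrained conditional sampling.**  The elongation enthalpy
  `ΔE(T)` is a difference of conditional means between the fully docked
  (`c_ext = 21`) and fully dissociated (`c_ext = 0`) states.  Restrained
  runs (`restrict = "fibrillar"` / `"monomeric"`) reject moves that leave
  the basin — a correctly sampled conditional ensemble — and make the
  difference available at every temperature
  (`elongation_curves_restrained()`).  Conditional means are unbiased by
  the initialisation, unlike visitation ratios.

The enthalpy recorded with every sample is the β-derivative estimator
`E = E_{int} + \sum K ε_{solv} + \sum e_{hydr}(T)`, not `H`: with a
temperature-dependent Hamiltonian `<H>` is not the enthalpy.  At
`alpha = 0` the estimator coincides with `H` exactly.

## Default problem sizes

Defaults are chosen for a desk-scale machine: 17 temperatures spanning
0.15–0.55, 4×10⁴ sweeps with the first quarter discarded, samples every 10
sweeps, swaps every 10 sweeps.  A full elongation run takes on the order
of a minute; the supporting analyses in the tests use the same sizes or
smaller.  At these sizes the dominant-state boundary at the cold end moves
by at most one grid step (0.025) between seeds.

## Validation against exact enumeration

For a single free chain of length ≤ 4 the complete configuration space
(self-avoiding backbone × side-chain directions × β flags) is enumerated
exactly (`enumerate_states()`), giving Boltzmann state probabilities and
partition-function ratios at any temperature.  The test suite holds the
sampler to these references at several temperatures (state occupancies
within Monte Carlo error, visitation free energies against exact ratios),
with the seed pinned, since with hard walls a mobile seed and a pinned
seed are genuinely different ensembles.

# Experimental-analysis layer

* `fit_enthalpy_vs_temperature()` fits calorimetric elongation enthalpies
  to `ΔH(T) = γ(T_0^2 - T^2) + E_{int}` with `T0 = 343.15 K` — linear in
  `(γ, E_{int})`, solved by ordinary (optionally sigma-weighted) least
  squares; the implied heat capacity is `ΔC_p(T) = -2γT`.
* `fit_isodesmic()` fits chemical-depolymerisation curves with the
  isodesmic linear-polymerisation model.  The monomer fraction used is
  the closed form `y = (2x + 1 - \sqrt{4x+1})/(2x^2)` with
  `x = K[M]_T` and `K = \exp(-(ΔG^0 + m[D])/RT)` on a 1 M standard state;
  this is the algebraically consistent solution of the isodesmic ladder
  with the correct limits (`y → 1` as `x → 0`, `y ∈ (0,1]`), which the
  printed form of the source equation garbles typographically.  Starting
  values come from the mid-transition denaturant concentration and the
  transition width; optimisation is Levenberg–Marquardt.
* `hydrophobic_area()` computes `A_h = \sum_i h_i a_i` over a fibril-core
  sequence with the nine-residue hydrophobic set and a shipped table of
  theoretical maximum per-residue solvent-accessible areas (editable);
  `fit_gamma_vs_area()` regresses fitted `γ` values on `A_h` through the
  origin (no buried area, no hydrophobic signal).
* `generate_synthetic_itc()` / `generate_synthetic_depoly()` produce
  deterministic synthetic data sets from known truth parameters; the test
  suite validates every fit by exact recovery at zero noise and
  bias/coverage checks over 200 noisy replicates.  Published experimental
  numbers of this kind (heat capacities of specific proteins, fibril
  stabilities, per-area slopes) depend on raw calorimetry and per-system
  core-region area tables that are not distributed with this package, so
  they are not reproduction targets; the procedures that produce them
  are.

# What the synthetic data do and do not show

The generators emulate clean versions of the experimental designs:
temperature grids typical of ITC elongation series with Gaussian enthalpy
noise, and denaturation series with Gaussian noise on the monomer
fraction.  They do not emulate instrument baselines, heats of dilution,
incomplete equilibration of depolymerisation, or concentration-dependent
deviations from the isodesmic picture — passing recovery tests therefore
demonstrates correctness of the estimators, not robustness to every
experimental pathology.

# Numerical choices and degenerate inputs

Temperatures must be strictly positive; `t = T0` and `c_h = 0` are exact
zeros of the hydrophobic terms.  `crossover_temperature()` reports `NA`
when `T_0^2 + E_{int}/γ ≤ 0` (elongation endothermic everywhere) and
refuses `γ ≤ 0`.  The isodesmic closed form switches to its series
expansion below `x = 10^{-6}` to avoid cancellation.  Landscape and
diagram code never interpolates unvisited bins or cells; they are flagged
absent.  Collinear designs (all temperatures equal, all areas zero,
transition outside the measured range) are rejected with descriptive
errors rather than fitted.

# Known limitations

* Absolute `ΔG` values from visitation are only available near state
  coexistence; the two-sided protocol gives topology, not a full
  free-energy profile, away from it.  The model's `ΔG = 0` corresponds to
  the simulation's nominal monomer concentration (2 chains per 20³ box,
  the two-free-chain convention); experimental free-energy scales differ
  by several `k_B T` and must not be compared directly.
* The default tables are a calibrated concretisation, not a published
  parameter set; all of their files are plain text and overridable.
* Only two free chains are simulated (one added layer): no nucleation,
  oligomer pathways, kinetics or fibril polymorphism.
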