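---
title: "Conformational analysis of charged homo-polypeptides with polyion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational analysis of charged homo-polypeptides with polyion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Polyelectrolytic intrinsically disordered regions — runs of consecutive
Asp/Glu (D/E) or Lys/Arg (K/R) residues — behave very differently from
neutral disordered sequences. Their like-charge repulsion keeps them
extended, their dimensions respond to salt concentration and cation valency,
and counterion adsorption couples directly to their compaction. `polyion`
provides a tested pipeline for quantifying these effects on conformational
ensembles of single coarse-grained chains:

* radius-of-gyration (Rg) distributions and time series,
* Flory scaling exponents from internal distance profiles,
* Rg relaxation times from autocorrelation fits,
* ion-adsorption statistics at a distance cutoff,
* principal component analysis of superposed conformations,
* a homorepeat census over proteome FASTA files,

together with a synthetic-ensemble module whose centrepiece is a
coarse-grained explicit-ion Metropolis Monte Carlo simulator. The simulator
is the package's trajectory source: it emulates the statistical structure of
all-atom simulations of 30-residue homo-polypeptides (polyD/E/K/R and a
neutral polyGS control) at salt conditions of 0 M (neutralising counterions
only), 0.125 M and 0.25 M of 1:1 or 2:1 salt.

## The coarse-grained model

Each residue is one bead. The configuration energy, in units of kT, is

* **harmonic bonds** between consecutive beads,
  `U = k/2 (r - b)^2` with stiffness `k = 100 kT/Å²` and rest length
  `b = 3.8 Å` (the Cα–Cα virtual bond). The implied thermal bond width is
  `sqrt(kT/k) = 0.1 Å`, so bonds are effectively rigid;
* **Weeks–Chandler–Andersen (WCA) excluded volume** between all particle
  pairs, with per-species diameters combined arithmetically and a well depth
  of 1 kT. Defaults: charged-chain beads 3.8 Å, monovalent cations 2.3 Å,
  divalent cations 3.0 Å, anions 3.6 Å. The neutral polyGS surrogate uses a
  1.0 Å bead so that its measured internal scaling stays near the ideal-coil
  exponent of 0.5, matching the near-random-coil statistics of real Gly/Ser
  controls;
* **Coulomb interactions** `λ_B z_i z_j / r` truncated at a cutoff (default
  half the box edge). The Bjerrum length is computed from the relative
  permittivity and temperature; at the defaults (78.5, 300 K) it is 7.1 Å,
  water at room temperature.

The solvent is implicit and the ensemble is constant-volume in a cubic
periodic box (default edge 75 Å). All nonbonded pairs use the minimum-image
convention; bonds are computed on direct distances and the chain is stored
whole (its beads are never wrapped, ions are). Because the 30-mer's contour
length (110 Å) exceeds the default box, a fully stretched conformation
interacts with its own periodic images — the simulated system is a periodic
array of chains at the box concentration rather than a single chain at
infinite dilution. This is the standard periodic treatment and it is what
gives the model its well-behaved salt response; the image interactions
penalise near-rod conformations, so absolute dimensions should be read as
those of a weakly interacting periodic system (they in fact land close to
the 20–25 Å scale reported for atomistic 30-mers). Truncated minimum-image
electrostatics instead of Ewald summation is likewise deliberate: at this
scale and for the qualitative screening and valency trends the package
targets, the truncation error is far below the seed-to-seed spread, at a
small fraction of the cost.

Salt is added in whole formula units, `n = round(c · N_A · V)` (one cation
plus `z` anions for a `z`:1 salt), and a charged chain is neutralised by
counterions; every frame is exactly charge neutral, by construction and by a
tested invariant. For a chain charge not divisible by the cation valence the
remainder is balanced with extra anions.

Moves are single-particle displacements plus chain pivots (a random
axis–angle rotation of the shorter tail about a random interior bead, which
preserves all bond lengths). The displacement step is auto-tuned to 30–50%
acceptance during equilibration only and then frozen, keeping the production
chain Markovian. Trajectories are bit-reproducible under a fixed seed.

## Reference generators and what they validate

The analysis estimators are validated against ensembles with known answers:

* `make_rod()` — collinear beads; internal rms distances are exactly
  `b·s`, so the scaling exponent is exactly 1 and `Rg = b·sqrt((N²-1)/12)`;
* `make_compact()` — beads along a 3-d Hilbert curve through a cubic
  lattice; the compact-globule limit with exponent ≈ 1/3;
* `sample_ideal_chain()` — freely jointed chains; `E[R²(s)] = b²s`, the
  ideal-coil exponent 0.5 and `E[Rg²] = b²(N²-1)/(6N)`;
* `sample_saw_chain()` — pivot-algorithm self-avoiding walks; the
  excluded-volume reference, and the oracle for the neutral Monte Carlo
  chain (a WCA chain with near-rigid bonds should be statistically
  indistinguishable from a hard-sphere SAW at matched diameter);
* `sample_ou_series()` — a stationary AR(1)/Ornstein–Uhlenbeck series with
  exactly known autocorrelation `exp(-Δ/τ)`, the ground truth for the
  relaxation-time estimator.

A note on terminology: "random coil" is used here for the ideal
(non-self-avoiding) chain with exponent 0.5; the swollen, self-avoiding coil
has exponent ≈ 0.588.

## Estimator conventions

**Internal scaling.** The default profile estimator is the root-mean-square
pair distance at each sequence separation `s = |i-j|`, averaged over all
pairs and frames (0-based residue indices; the separation is the same either
way). The alternative `subchain_rg` estimator (mean Rg of the contiguous
segment) is provided because size-versus-separation analyses are sometimes
phrased that way, but it carries finite-size curvature — on the rod it
approaches 1 only from below — so `rms_distance` is the default. The default
fit window for a 30-mer is `s ∈ [2, 15]`: `s = 1` is fixed by the bond
length, and the largest separations have few pairs and end effects. The
window is a parameter and is always reported in the result object.

**Relaxation times.** The autocorrelation uses the biased (1/n)
normalisation, so `G(0) = 1` exactly. The single-exponential fit runs from
lag 1 to the first lag where the ACF drops below 0.05, capped at 20% of the
series length and extended to at least 5 points; the residual RMSE is
reported so multi-exponential decay is visible rather than silently
absorbed. For Monte Carlo trajectories τ is reported in sweeps; no physical
time mapping to molecular dynamics is claimed. A fitted τ below one frame
spacing is flagged unresolved.

**Ion adsorption.** An ion is adsorbed when its minimum-image
centre-to-centre distance to the nearest bead is ≤ 4 Å (inclusive boundary;
cutoff configurable and always recorded). At bead resolution there is no
"any peptide atom" to measure from — a documented limitation of the
coarse-grained data model. The default species filter counts counterions
(ions opposing the chain's net charge), matching how adsorption is usually
plotted against compaction; an "all" mode exists, and for cross-valency
comparisons the adsorbed counter-charge (count × |valence|) is the
meaningful quantity, since one divalent cation neutralises two chain
charges.

**PCA.** Frames are superposed by Kabsch rotation (proper rotations only,
so mirror images are never matched) onto the mean structure, iterated twice.
Components are eigenvectors of the covariance of the flattened 3N
coordinates, with signs fixed so each component's largest-magnitude loading
is positive — scores are reproducible across runs. For the
control-in-background display the components are fitted on the charged
system and the control is projected into that space after alignment to the
same mean structure; fitting on the control or on the union are available
alternatives, since either convention is defensible.

**Homorepeats.** Runs are pure and maximal ("consecutive" residues of one
charge class); any character outside the class alphabet breaks a run, and
the shortest repeat considered is 10 residues by default. The cumulative
curve counts each protein once per threshold via its longest run
(`up_to` mode: proteins whose longest run r satisfies `min ≤ r ≤ L`); an
`at_least` mode (proteins with any run ≥ L) is provided because published
curves are sometimes plotted that way, and neither is claimed to be the
exact published counting rule.

## Worked example

```{r, eval = FALSE}
library(polyion)

# fully charged 30-mer with neutralising counterions, no added salt
ens <- run_cg_simulation(
  poly_chain("E"), salt_spec(0), box_edge = 75,
  params = mc_params(n_sweeps = 50000, equilibration_sweeps = 10000,
                     sample_interval = 50, seed = 1))

rg_series(ens)               # mean Rg ~ 20.5 A: strongly extended
flory_exponent(ens)          # nu ~ 0.85, the extended-polyelectrolyte range
adsorption_series(ens)       # ~7 of 30 counterions condensed within 4 A

# the neutral control is ~2.5x more compact
ctrl <- sample_ideal_chain(poly_chain("GS"), 2000, seed = 1)
rg_series(ctrl)              # mean Rg ~ 8.2 A
flory_exponent(ctrl)         # nu ~ 0.50
```

## What the synthetic ensembles do and do not show

The simulator reproduces, at desk scale, the qualitative physics probed by
all-atom studies of these systems: charged chains are at least twice as
expanded as the neutral control with scaling exponents in the extended
range (≥ 0.8 versus ≈ 0.5); counterions condense on the charged chain
(about 7 of 30 within the 4 Å shell) while a neutral chain adsorbs almost
nothing (well under one ion on average even at 0.25 M); added salt screens
the repulsion and compacts the chain monotonically across 0 → 0.125 →
0.25 M while the number of adsorbed counterions rises; a divalent 2:1 salt
compacts the anionic chain far more than a 1:1 salt at the same
concentration; adsorbed counter-charge and mean Rg are anticorrelated
across the condition grid; and the PC1–PC2 footprint of the ensemble grows
with salt as screening unlocks more compact conformations.

Caveats are documented rather than hidden. Chemistry is absent: beads
differ only in charge sign, charge density and diameter, so differences
between D and E (or K and R) chains — different hydration, the roughly
two-fold higher ion adsorption of cationic versus anionic chains seen in
atomistic work — are out of scope and not claimed. Absolute comparisons to
atomistic Rg values are qualitative only: the uniform-mass, bead-level Rg
of a periodic chain system is not an all-atom mass-weighted Rg, even though
the simulated dimensions (≈ 20 Å charged, ≈ 8 Å neutral) land in the right
range. Rg relaxation here is measured in Monte Carlo sweeps and says
nothing about nanosecond-scale dynamics; with condensed ions the mixing
time reaches ~10⁴ sweeps, which sets the equilibration defaults.

## Numerical choices and degenerate inputs

* Problem sizes in the shipped tests are chosen to make each check sharp
  but cheap: analytic identities use single frames; stochastic estimator
  checks use 800–2000 frames; Boltzmann-sampling checks use 1e5 stored
  samples of toy systems; Monte Carlo physics contracts use 5 seeds at
  5e4–2e5 sweeps per condition, with 1.5e4–2e4 equilibration sweeps chosen
  from the measured Rg mixing times.
* Ordinary least squares on log–log profiles needs ≥ 3 usable separations;
  the exponential τ fit needs ≥ 5 lags and falls back to the lag-1 estimate
  `-Δ/log G(1)` if the optimizer fails.
* A zero-variance Rg series (e.g. a rigid ensemble) is a degenerate-series
  error, not a τ of infinity.
* Collinear references cannot define a rotation; alignment falls back to
  the first frame with a warning.
* Imported trajectories must contain whole chains; a bond longer than half
  the box raises an error instead of silently unwrapping.
* Ion counts are rounded to whole formula units (never breaking
  neutrality); the rounding is recorded in the ensemble metadata.

## Pipeline reproducibility

`run_pipeline()` executes a full system × condition × replicate grid from a
single config (list or YAML), writes one tidy CSV per analysis and a JSON
manifest (parameters, derived seeds, checksums), and records failures
per stage instead of aborting the grid. Replicate seeds are derived from the
global seed by fixed integer mixing, so reruns are byte-identical while
replicates remain distinct. `summarize_conditions()` aggregates replicate
metrics to mean ± sd, reporting a single replicate's sd as `NA`, never 0.
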