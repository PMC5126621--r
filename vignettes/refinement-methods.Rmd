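---
title: "Monte Carlo pocket refinement: model, protocol and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo pocket refinement: model, protocol and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pocketmc` implements an iterative Monte Carlo refinement protocol for
protein–cofactor–ligand complexes, of the kind used to compare
qualitative binding energies of competing ligands at an NADP(H)-dependent
steroid-reductase active site, together with everything needed to
exercise it end to end on self-contained synthetic systems: a scoring
function, conformational move operators, side-chain repacking, a
quasi-Newton minimiser, a binding-energy ladder, pose classification,
interaction fingerprints, and a generator of mini-pocket fixtures with
planted ligand poses and property-matched decoy ligands.

This vignette describes the model and the protocol, the tunable
parameters and their defaults, what the synthetic systems do and do not
emulate, and the numerical choices made where the design was open.

## The scoring function

The score is a deliberately small four-term model in kcal/mol,
evaluated over all atom pairs not excluded as 1-2 or 1-3 bonded
neighbours:

* **Lennard-Jones 12-6** with per-element well depths and radii
  combined by Lorentz–Berthelot rules. Carbons are united atoms with
  enlarged radii (σ = 3.55 Å); nonpolar hydrogens are implicit. Only
  polar hydrogens (N–H, O–H) are represented explicitly, because the
  hydrogen-bond term needs their geometry.
* **Coulomb with a distance-dependent dielectric** ε(r) = 4r and the
  standard electrostatic constant 332.0637 kcal·Å/(mol·e²) — the usual
  implicit-screening choice for docking-style scores. Partial charges
  come from a small built-in table (backbone amide groups, hydroxyl and
  carbonyl groups, TIP3P-like water); side chains are neutral as
  groups.
* **A directional hydrogen bond**: donor–acceptor pairs within 3.5 Å
  whose D–H···A angle exceeds 120° receive a bonus of up to
  −2 kcal/mol, scaled linearly in the angle above the cutoff and
  tapered in distance, so the term is continuous everywhere.
* **A torsion prior**: a threefold cosine, k(1 + cos 3φ) with
  k = 0.6 kcal/mol, over side-chain χ angles and ligand rotatable
  torsions, with minima at the staggered conformations.

LJ and Coulomb are switched smoothly to zero over the last 1 Å before
the 9 Å cutoff (cubic switching), so minimisation gradients are
continuous. This is a declared stand-in score: it captures shape
complementarity, electrostatics and hydrogen bonding well enough to
rank ligands and to give the protocol a meaningful energy landscape,
but its absolute magnitudes are not comparable with any published
forcefield, and it has no solvation or entropy terms (entropic effects
are assumed near-identical across compared ligands, which is the same
assumption the binding-energy ladder itself makes).

Synthetic fixtures additionally carry **harmonic positional tethers**
(k = 3 kcal/mol/Å²) on pocket backbone atoms and on the cofactor
stand-in. A 10–40-residue pocket fragment has no hydrophobic core to
hold it together, so without tethers long refinement runs slowly
remodel the scaffold itself; the tethers emulate the rigidity the
surrounding protein would provide while leaving side chains, water and
ligand fully mobile. They are anchored in the lab frame by design,
which is why the rigid-motion invariance of the score applies to
untethered structures.

## The refinement protocol

One **decoy trajectory** runs 8 outer annealing cycles × 4 blocks × 6
steps = 192 perturbation steps. Each step:

1. perturbs every hetero component (ligand, cofactor, catalytic water)
   by a random rigid-body move (translation ≤ 0.5 Å, rotation ≤ 10°;
   the ligand also receives one random rotatable-torsion twist),
2. applies a *small* move (φ, ψ each uniform in ±5°) to a random
   flexible residue and a compensating *shear* move (+δ on one φ, −δ
   on the neighbouring ψ) to an adjacent pair,
3. repacks the flexible side chains over the rotamer library,
4. minimises over the declared degrees of freedom (DFP quasi-Newton,
   capped at `inner_min_iter` = 30 iterations inside a trajectory),
5. accepts or rejects against the last accepted state by the
   Metropolis criterion at the current kT.

kT anneals linearly from 3.0 (first outer cycle) to 1.0 (last) within
each trajectory; trajectories anneal independently. The trajectory
returns its **lowest-energy accepted state** (recover-low). That choice
matters: at kT = 3 a random walk of 192 steps reliably diffuses a
ligand out of a desk-scale pocket, so the literal final state of the
walk is the wrong object to keep — recovering the low point is the
standard Monte Carlo-object convention in Rosetta-style protocols and
is what makes "the lowest-energy decoy of the round" meaningful.

An **optimization round** generates `n_decoys` = 200 trajectories from
independent child seeds and keeps the lowest-energy decoy (ties break
to the lowest index). The selected decoy is then polished by a deeper
minimisation (the per-step minimisations inside trajectories are
iteration-capped). Rounds repeat **K times until convergence**: the
incumbent best is carried forward (so the energy trace is
non-increasing by construction), and the loop stops when two subsequent
round energies agree within `convergence_tol`, or at `max_K` = 50
rounds. Exact energy equality is numerically meaningless, so "the same
energy" is operationalised as |ΔE| ≤ tol (default 10⁻³ kcal/mol; the
reduced-scale runs below use 0.1, the micro-minimum granularity of the
synthetic systems).

**Flexible residues** are selected by the 4 Å rule: in the first round,
every residue with an atom within 4 Å of any cofactor or ligand atom,
united with the declared catalytically active residues; in later
rounds, residues within 4 Å of the ligand only. The catalytic water is
always declared by the user, never inferred.

The **rotamer library** is a minimal built-in: χ angles at all
combinations of −60°/+60°/180° with uniform priors. Repacking assigns
each flexible residue the library rotamer minimising its interaction
energy with the fixed environment plus its own torsion prior, sweeping
to a fixed point (≤ 5 sweeps). Backbone atoms never move during
repacking; dihedral moves preserve all bond lengths exactly (rotations
about bond axes).

The **minimiser** is Davidon–Fletcher–Powell with central-difference
gradients over internal coordinates (flexible φ/ψ/χ, ligand rotatable
torsions) plus one rigid-body block (3 rotation + 3 translation
parameters) per hetero component. Line-search steps are capped at 1
unit (degree/Å) in the infinity norm — with a unit initial inverse
Hessian an uncapped first step can eject a clashed ligand tens of Å
from the pocket. Convergence is gradient norm < 10⁻⁴ or 200 iterations
(standalone; capped harder inside trajectories).

## The binding-energy ladder

For each complex the protocol optimises, with the same algorithm, the
apo protein, the protein + catalytic water, + cofactor, and the full
complex; the ligand alone receives a single energy evaluation with its
coordinates untouched. The qualitative binding energy is

> E_bind = E_complex − (E_ref + E_lig)

with E_ref the refined protein + cofactor + catalytic-water state.
E_ref is computed once per screen and shared across ligands (the
equation treats it as a common reference). A record is flagged **not
binding** when E_bind > 0 or the ligand centroid drifts more than 8 Å
from the pocket centre during refinement — the source analyses report
such entries qualitatively without defining them, so the rule is
declared here.

**Pose classification** measures the angle between best-fit-plane
normals of the ligand heavy atoms and of the cofactor ring: ≤ 30° is
the unproductive (cofactor-parallel) orientation, ≥ 60° the productive
(perpendicular) one, in between ambiguous. The thresholds are declared;
the source material gives only the qualitative parallel/perpendicular
dichotomy. **Pose RMSD** is heavy-atom, matched by atom name, in the
fixed receptor frame with no re-superposition.

**Interaction fingerprints** follow LigPlot-like conventions
(config-exposed): hydrogen bonds at D···A ≤ 3.5 Å and D–H···A ≥ 120°,
hydrophobic contacts as ligand–protein carbon–carbon pairs ≤ 3.9 Å
aggregated to one row per residue, and the cross-ligand consensus as
residues appearing in at least a threshold fraction (default 0.8) of
reports.

## Synthetic systems

`make_mini_pocket()` builds self-contained fixtures so every stage is
testable without external structures. The planted **active ligand** is
a flat six-carbon ring with a two-point pharmacophore at fixed
geometry — a hydroxyl and, on the opposite rim ~5.4 Å away, a
carbonyl-like acceptor — plus a methyl, and one rotatable (hydroxyl)
torsion. Pocket residues sit on a spherical band of directions around
it (Fibonacci-spread, leaving a sector open for the cofactor), side
chains pointing inward: one serine aimed at each ligand polar site, the
rest a VAL/ALA/LEU lining of which a `complementarity` fraction
(default 0.8) sits at Lennard-Jones contact distance and the rest one
shell further out. The cofactor stand-in is a planar six-ring parallel
to the planted ligand plane — so the planted pose is the unproductive
orientation and its 90° rotation the productive one — with the
catalytic water adjacent.

After assembly the generator repacks all side chains, relaxes all
residue dihedrals and components, polishes the hetero components to
tight tolerance, and runs a short basin search (restarts from perturbed
component placements, adopting any deeper minimum). Backbone and
cofactor tethers are then anchored on the relaxed scaffold, and the
planted pose is verified to be a strict local minimum (random 0.3 Å
ligand displacements must raise the energy); infeasible draws are
retried with fresh direction jitter. Generation is deterministic in
(seed, parameters).

Because the hydroxyl torsion, water orientation and side-chain
micro-states create dense local minima ~0.1 kcal/mol apart, the planted
state dominates its basin to that granularity rather than exactly;
property tests therefore compare decoy energies against the planted
energy with a 0.1 kcal/mol allowance.

**Decoy ligands** (`make_decoy_ligands()`) match the active's
heavy-atom count (within 0 to +2) and net formal charge but are
topologically distinct — rigid helical branched chains versus the flat
ring, enforced by a cycle-rank/degree-sequence check — with the two
oxygens placed so their through-space spacing differs from the
active's by ≥ 1.2 Å ("scrambled polar-atom placement"). Matching
extends to flexibility: like the active, each decoy exposes a single
rotatable torsion. This mirrors how decoy-set generators pick
physicochemically matched but dissimilar molecules as negative
controls.

What the fixtures do **not** emulate: real protein folds and loop
geometry (the scaffold has no realistic peptide geometry between
residues and is held by tethers, not by a core), solvation, crystal
packing, or cofactor chemistry (the stand-in is a plain ring used for
plane geometry). Passing the recovery and discrimination checks on
these systems demonstrates that the protocol's machinery — sampling,
repacking, minimisation, annealing, selection, the ladder arithmetic —
behaves correctly on a landscape with a known answer; it does not
certify accuracy on real complexes, whose energetics this score does
not claim to reproduce in magnitude.

## Problem sizes and reduced-scale runs

The full protocol (192 steps × 200 decoys × K rounds) is what the
defaults encode. The package's own analyses, tests and the
reproduction script run reduced configurations chosen once and used
throughout: 15-residue pockets (10-residue for the convergence check);
20-decoy rounds of 1 × 1 × 2 steps with `inner_min_iter` = 6 and
`convergence_tol` = 0.1 for pose recovery (ten 1.5 Å-perturbed starts);
5-decoy rounds with `max_K` = 3 for the ten-system decoy-ligand
discrimination screen; and a single default-configuration trajectory to
exercise the 192-step cycle structure. These sizes keep a full
recovery-plus-discrimination study in the minutes range on one CPU
while leaving every protocol element (annealing, repacking,
minimisation, Metropolis, round selection, carry-forward) active.

## Known limitations

* The score has no solvation, polarisation or entropy; binding
  energies are qualitative rankings, not affinities.
* Backbone moves propagate downstream rigidly (no loop closure), so
  large φ/ψ changes are almost always rejected; sampling is local.
* The repacker is greedy residue-by-residue to a fixed point; it can
  miss strongly coupled rotamer pairs (none exist by construction in
  the synthetic pockets).
* Annealing is per trajectory; replica exchange or cross-trajectory
  schedules are out of scope.
* `read_pdb()` covers ATOM/HETATM/TER records with altloc filtering;
  mmCIF, symmetry expansion and automatic protonation-state prediction
  are out of scope. Hydrogen placement is geometric and polar-only — a
  declared substitute for whatever protonation rules an interactive
  modelling tool would apply.
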