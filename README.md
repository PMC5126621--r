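# pocketmc

Iterative Monte Carlo refinement and binding-energy analysis of
protein–cofactor–ligand pocket complexes, in R.

## The problem

Structure-based comparison of competing ligands at an enzyme active
site — for example, candidate competitive inhibitors of an
NADP(H)-dependent steroid reductase — needs three things: a way to relax
each docked complex to a comparable low-energy state, a common scale on
which to score binding, and negative controls showing the scoring
discriminates real binders from property-matched impostors. `pocketmc`
implements that workflow as a reusable, fully tested pipeline:

* a **Metropolis Monte Carlo refinement protocol** with simulated
  annealing (kT 3.0 → 1.0): per trajectory, 8 × 4 × 6 = 192 steps of
  rigid-body perturbation of the ligand, cofactor and catalytic water,
  backbone *small*/*shear* moves and rotamer repacking of the residues
  within 4 Å of the site, each followed by quasi-Newton (DFP)
  minimisation and a Metropolis accept/reject; 200 such decoy
  trajectories per optimization round, the lowest-energy decoy seeding
  the next round, repeated K rounds to convergence;
* a four-term docking-style **scoring function** (Lennard-Jones,
  Coulomb with ε(r) = 4r, directional hydrogen bond, torsion prior);
* the **binding-energy ladder** `E_bind = E_complex − (E_ref + E_lig)`,
  where `E_ref` is the refined enzyme–cofactor–water reference and
  `E_lig` the ligand's internal energy, with classification of each
  pose as *productive* (perpendicular to the cofactor plane) or
  *unproductive* (parallel);
* LigPlot-style **interaction fingerprints** (hydrogen bonds,
  hydrophobic contacts, cross-ligand shared residues);
* a **synthetic mini-pocket generator**: 10–40-residue pockets built
  around a planted ligand pose that is a verified minimum of the
  scoring function, plus property-matched decoy ligands, so the whole
  pipeline is exercisable end to end with no external structures.

PDB I/O goes through `bio3d`, SDF parsing through `ChemmineR`; the
inner energy/kinematics loops are in C++ via `Rcpp`.

## Worked example

```r
library(pocketmc)

sys    <- make_mini_pocket(seed = 42, n_residues = 15)
active <- ligand_from_structure(sys$structure)
decoys <- make_decoy_ligands(active, n = 3, seed = 42)

cfg <- screen_config(
  refinement = refinement_config(outer_cycles = 1, mid_blocks = 1,
                                 inner_steps = 2, n_decoys = 5,
                                 inner_min_iter = 6, max_K = 3,
                                 convergence_tol = 0.1),
  positions = c("unproductive", "productive"), seed = 42)

report <- run_screen(sys, c(setNames(list(active), active$name), decoys),
                     cfg)
screen_table(report)
```

```
  substrate unproductive_position productive_position
1       LG1                -14.12              -13.40
2      DEC1                 -5.24               -6.62
3      DEC2                 -4.94               -5.43
4      DEC3                 -4.46               -4.34
```

Binding energies are in kcal/mol on the package's own scoring scale;
more negative is better. The planted active ligand (`LG1`) out-scores
all three topology-scrambled decoy ligands in both orientations — the
desk-scale analogue of validating a docking protocol against generated
decoy sets. `report$interactions` holds the per-complex fingerprints
(here the two designed serine hydrogen bonds at 2.9 Å plus the
hydrophobic lining contacts), and `report$shared` the residues common
to most complexes.

The numbered scripts under `analysis/` run the full study on the
synthetic system and write their tables under `results/`:
`01_simulate.R` (system + decoy generation), `02_refine.R` (pose
recovery from 1.5 Å-perturbed starts), `03_binding_screen.R` (the
screen above), `04_interactions.R` (fingerprints and shared residues).

## Documentation

The methods vignette (`vignettes/refinement-methods.Rmd`) describes the
scoring function and its parameters, the protocol and its
interpretation choices, the synthetic-system design (including what it
does and does not emulate about real complexes), and the package's
numerical conventions and limitations.
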