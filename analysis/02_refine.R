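#!/usr/bin/env Rscript
# Self-docking analogue at desk scale: perturb the planted ligand pose
# by 1.5 A, refine to convergence with the Monte Carlo protocol, and
# measure how close the refined pose lands to the planted one. Writes
# the per-seed recovery table and one energy trace under results/.

suppressPackageStartupMessages(library(pocketmc))

dir.create("results", showWarnings = FALSE)
sys <- make_mini_pocket(seed = 42, n_residues = 15)
p <- default_energy_params()
lig0 <- ligand_from_structure(sys$structure)

# reduced-scale protocol: 20 decoys of 1 x 1 x 2 steps per round,
# convergence at the 0.1 kcal/mol micro-minimum granularity
cfg <- refinement_config(outer_cycles = 1, mid_blocks = 1,
                         inner_steps = 2, n_decoys = 20,
                         inner_min_iter = 6, max_K = 5,
                         convergence_tol = 0.1)

rows <- list()
for (sd in 1:10) {
  s_p <- perturb_pose(sys, 1.5, seed = sd)
  start_rmsd <- pose_rmsd(ligand_from_structure(s_p), lig0)
  cfg$seed <- 1000 + sd
  res <- refine_to_convergence(s_p, cfg, p)
  final_rmsd <- pose_rmsd(ligand_from_structure(res$structure), lig0)
  rows[[sd]] <- data.frame(
    seed = sd, start_rmsd = start_rmsd, final_rmsd = final_rmsd,
    K = res$trace$K, converged = res$trace$converged,
    final_energy = tail(res$trace$cycle_energies, 1))
  message(sprintf("seed %2d: %.2f A -> %.3f A (K = %d, %s)", sd,
                  start_rmsd, final_rmsd, res$trace$K,
                  if (res$trace$converged) "converged" else "max_K"))
  if (sd == 1) {
    utils::write.table(
      data.frame(cycle = seq_along(res$trace$cycle_energies),
                 energy = res$trace$cycle_energies),
      "results/refinement_trace_seed1.tsv", sep = "\t",
      quote = FALSE, row.names = FALSE)
    write_pdb(res$structure, "results/refined_complex_seed1.pdb")
  }
}
tab <- do.call(rbind, rows)
utils::write.table(tab, "results/pose_recovery.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("Recovered within 0.5 A in %d/10 seeds (mean %.3f A)",
                sum(tab$final_rmsd <= 0.5), mean(tab$final_rmsd)))
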