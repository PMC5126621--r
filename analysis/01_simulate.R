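#!/usr/bin/env Rscript
# Generate the synthetic study system: a 15-residue mini-pocket with a
# planted ligand pose (verified local minimum of the scoring function),
# plus six property-matched decoy ligands, and write everything under
# results/system/.

suppressPackageStartupMessages(library(pocketmc))

seed <- 42
out <- "results/system"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("Generating mini-pocket (seed ", seed, ") ...")
sys <- make_mini_pocket(seed = seed, n_residues = 15)
print(sys)

e <- complex_energy(sys$structure)
message(sprintf("Planted-complex energy: %.3f kcal/mol (lj %.2f, coulomb %.2f, hbond %.2f, torsion %.2f)",
                e$total, e$lj, e$coulomb, e$hbond, e$torsion))
cls <- classify_pose(sys$structure)
message(sprintf("Planted pose: %s (plane angle %.1f deg)", cls$position,
                cls$angle))

active <- ligand_from_structure(sys$structure)
decoys <- make_decoy_ligands(active, n = 6, seed = seed)

write_pdb(sys$structure, file.path(out, "pocket_complex.pdb"))
write_ligand_sdf(active, file.path(out, "active_ligand.sdf"))
for (nm in names(decoys))
  write_ligand_sdf(decoys[[nm]], file.path(out, paste0(nm, ".sdf")))

desc <- c(sys$descriptor[c("n_residues", "complementarity", "serine")],
          list(seed = seed, planted_energy = e$total,
               planted_position = cls$position,
               n_decoy_ligands = length(decoys)))
jsonlite::write_json(desc, file.path(out, "descriptor.json"),
                     auto_unbox = TRUE, digits = NA)
message("Wrote ", out, "/: pocket PDB, active + 6 decoy SDFs, descriptor")
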