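#!/usr/bin/env Rscript
# Build the study system: synthetic flipped-base complex, charge merge,
# and the methyl -> hydroxymethyl residue patch. Writes the structure,
# the residue topology, and the patch as a PRES block.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

tc <- make_toy_complex(study_spec(n_frames = 1))
cat("built synthetic complex:", n_atoms(tc$topology), "atoms,",
    nrow(residue_table(tc$topology)), "residues\n")
cat("total charge:", sprintf("%+.3f e", total_charge(tc$topology)), "\n")

writeLines(write_structure(tc$topology, get_frame(tc$trajectory, 1)),
           file.path(RESULTS_DIR, "complex_5mc.pdb"))
writeLines(toy_charge_topology(),
           file.path(RESULTS_DIR, "residues.rtf"))

# 5hmC construction: swap one methyl H for a serine-charged hydroxyl
rtf <- read_charge_topology(toy_charge_topology())
patch <- build_5hmc_patch(rtf$`5MC`, rtf$SER)
writeLines(format_patch_rtf(patch, name = "5HMC"),
           file.path(RESULTS_DIR, "patch_5hmc.rtf"))
patched <- apply_patch(tc$topology, "B", 10, patch)
cat("patched residue B:10 ->", n_atoms(patched), "atoms;",
    "charge drift", format(total_charge(patched) -
                             total_charge(tc$topology)), "e\n")
cat("hydroxyl charges (O, H):",
    patched$atoms$charge[patched$atoms$name %in% c("OH5", "HO5")], "\n")

# restraint set that would hold a free DNA in the flipped state
restr <- flipped_backbone_selection(tc$topology, "B")
write.table(restr, file.path(RESULTS_DIR, "backbone_restraints.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("backbone restraint atoms:", nrow(restr), "->",
    file.path(RESULTS_DIR, "backbone_restraints.tsv"), "\n")
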