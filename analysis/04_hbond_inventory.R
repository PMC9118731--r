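#!/usr/bin/env Rscript
# Interface hydrogen-bond inventory of the ternary transcription complex.
#
# The published counts (ANK<->MAML-1 total 8, of which 5 involve GLU-2008 /
# ASP-1972; ASP-1994 <-> GLN-347 of RBPJ count 2) refer to the DNA-bound
# complex structure (PDB entry 2F8X). When that file is present locally the
# inventory runs on it; otherwise the same machinery is exercised on a
# synthetic complex with the published counts planted, which validates the
# detector exactly but is not evidence about the real complex.

suppressMessages(library(ankthermo))
dir.create("results", showWarnings = FALSE)

pdb <- file.path("inst", "extdata", "2f8x.pdb")
if (file.exists(pdb)) {
  model <- read_structure(pdb)
  groups <- list(ANK = "A", RBPJ = "B", MAML1 = "C")
  label <- "PDB 2F8X"
} else {
  cat("2f8x.pdb not found locally; running on a synthetic planted complex\n")
  bonds <- rbind(
    data.frame(donor_chain = "M", donor_resno = 300 + 1:3,
               acc_chain = "A", acc_resno = c(2008, 2008, 1972)),
    data.frame(donor_chain = "A", donor_resno = c(2008, 1972),
               acc_chain = "M", acc_resno = 310:311),
    data.frame(donor_chain = "M", donor_resno = 320:322,
               acc_chain = "A", acc_resno = c(1975, 2011, 2035)),
    data.frame(donor_chain = "R", donor_resno = c(347, 347),
               acc_chain = "A", acc_resno = c(1994, 1994)))
  model <- make_planted_complex(c("A", "M", "R"), bonds)
  groups <- list(ANK = "A", MAML1 = "M", RBPJ = "R")
  label <- "synthetic planted complex"
}

inv <- interface_inventory(model, groups, d_max = 3.5, angle_min = 120)
cat("inventory on", label, "(criteria: 3.5 A, 120 deg):\n")
print(inv)
write.table(inv$bonds, "results/hbonds.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

total <- if ("ANK|MAML1" %in% names(inv$counts)) inv$counts[["ANK|MAML1"]] else 0
key <- interface_bonds_involving(inv, c("ANK", "MAML1"), c(2008, 1972))
rbpj <- interface_bonds_involving(inv, c("ANK", "RBPJ"), 1994)
cat(sprintf("ANK<->MAML1 bonds: %d (published: 8); involving E2008/D1972: %d (published: 5)\n",
            total, nrow(key)))
cat(sprintf("ANK<->RBPJ bonds at D1994: %d (published: 2, to GLN-347)\n",
            nrow(rbpj)))
cat("wrote results/hbonds.tsv\n")
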