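#!/usr/bin/env Rscript
# Cellular RNA mass bookkeeping: what a read weighs, how many reads it
# takes to sequence one cell's RNA without physical rRNA depletion, and
# how little of the informative pool a polyA selection retains.

suppressMessages(library(vlincr))

out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

model <- cell_rna_model()
rn <- reads_needed(model)
pf <- polya_informative_fraction(model)

lines <- c(
  sprintf("mass of one %d-nt read:            %.3g g", model$mean_read_length_nt,
          read_mass(model$mean_read_length_nt, model$residue_mass_g_mol)),
  sprintf("total RNA per cell:               %.3g g", model$total_rna_g),
  sprintf("reads to sequence one cell:       %.3g (> 1e8)", rn$total_reads),
  sprintf("informative reads among them:     %.3g (at %.0f%% informative)",
          rn$informative_reads, 100 * model$informative_fraction),
  sprintf("polyA share of informative RNA:   %.2f%%-%.0f%%",
          100 * pf["lower"], 100 * pf["upper"]))
writeLines(lines)
writeLines(lines, file.path(out, "mass_bookkeeping.txt"))
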