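#!/usr/bin/env Rscript
# The idealized Hopfield recognition cycle as the analytic reference for the
# strand-displacement motif: exact steady states of the five-state master
# equation across the drive, for several single-step discrimination factors.
#
# Finding: at detailed balance the enrichment of correct over incorrect
# product equals the single-step factor f0; under strong drive with slow
# product formation it approaches f0^2 - the double exploitation of one
# free-energy difference that the DNA network emulates.

suppressMessages(library(kproof))
dir.create("results", recursive = TRUE, showWarnings = FALSE)

rows <- list()
for (f0 in c(5, 10, 20)) {
  for (drive in c(1, 1e2, 1e4, 1e8, 1e12)) {
    ss <- hopfield_steady_state(hopfield_cycle(f0, drive = drive))
    rows[[length(rows) + 1L]] <- data.frame(
      f0 = f0, drive = drive, enrichment = ss$enrichment,
      error_fraction = ss$error_fraction)
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/hopfield_enrichment.csv", row.names = FALSE)
print(tab, row.names = FALSE)
cat("\nEnrichment runs from f0 (drive = 1, detailed balance) to f0^2\n")
cat("(strong drive, slow product formation), for every f0 tested.\n")
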