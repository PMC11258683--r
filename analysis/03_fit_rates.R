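#!/usr/bin/env Rscript
# Staged rate-constant estimation on a synthetic study whose truth is known:
# stage 1 fits the blocker/template exchange rates on the binding wells;
# stage 2 fits the reporter rate once per candidate total-monomer
# concentration (8 candidates, 80%..115% of nominal); stage 3 fits the
# proofreading rates per candidate simultaneously on the template-recovery
# and full-discard wells and selects the candidate with the lowest total
# error.
#
# Finding: with the true reporter-well monomer concentration at 90% of
# nominal, the selection picks the 0.90 candidate, and the identifiable rates
# land within a few percent of truth; the reverse-proofreading rate is
# flagged as weakly constrained (its propensity is negligible at these
# designs), mirroring the study's own caveat about those constants.

suppressMessages(library(kproof))
dir.create("results", recursive = TRUE, showWarnings = FALSE)
seed <- 11

binding <- generate_study("fig2_binding", seed = seed, variants = "M1",
                          t_concs = c(2, 10), interval_scale = 2)
discard <- generate_study("fig3_discard", seed = seed + 1, variants = "M1",
                          interval_scale = 2, t_concs = c(2, 8),
                          reporter_monomer_scale = 0.90)
sf <- staged_fit(combine_studies(binding, discard), seed = seed)

truth <- c(k_bind = 2e5, k_unbind = 2e4, k_proof = 1e4, k_revproof = 1e2,
           k_rep = 5e4)
fitted <- sf$rates$values[names(truth)]
tab <- data.frame(rate = names(truth), truth = unname(truth),
                  fitted = unname(fitted),
                  rel_err_pct = 100 * abs(unname(fitted) - unname(truth)) /
                    unname(truth),
                  weakly_constrained = names(truth) %in%
                    sf$selection$fits[[sf$selection$index]]$weak)
write.csv(tab, "results/fitted_rates.csv", row.names = FALSE)
write.csv(sf$selection$errors, "results/reporter_selection.csv",
          row.names = FALSE)
write_rates(sf$rates, "results/final_rate_set.csv")

cat("Selected reporter candidate:", sf$selection$index,
    sprintf("(monomer fraction %.2f; truth 0.90)\n",
            sf$stage2$frac[sf$selection$index]))
cat("\nFitted vs true rate constants:\n")
print(tab, row.names = FALSE)
cat("\nStage-3 error table written to results/reporter_selection.csv\n")
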