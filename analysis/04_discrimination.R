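#!/usr/bin/env Rscript
# Specificity analysis of the proofread dimerization and SNP-detection
# networks: endpoint discrimination factors with and without proofreader,
# catalytic turnover of the discard pathway, the crude intermediate estimate
# by channel subtraction, and SNP initial-rate selectivity.
#
# Findings: without proofreader every monomer variant reaches essentially
# full dimer yield (D ~ 1); a discriminating proofreader suppresses the
# mismatched variants several-fold (improvement factor > 2). The discard
# pathway converts more monomer to waste than template added (turnover ~ 2
# at ML0/T0 = 2). Proofreading also multiplies the SNP initial-rate
# selectivity beyond the binding-only factor.

suppressMessages(library(kproof))
dir.create("results", recursive = TRUE, showWarnings = FALSE)

## dimerization: D with/without proofreader ----------------------------------
rep <- kp_enhancement_report()
write.csv(rep$yields, "results/dimer_yields.csv", row.names = FALSE)
dtab <- data.frame(comparison = names(rep$D),
                   D = vapply(rep$D, `[[`, 0, "D"))
write.csv(dtab, "results/discrimination_factors.csv", row.names = FALSE)
cat("Dimer endpoint yields and discrimination factors:\n")
print(rep)

## turnover of the discard pathway --------------------------------------------
fd <- build_network("full_discard")
tr <- integrate_network(fd, default_true_rates(fd, "M1"),
                        c(ML = 8, T = 4, P = 50, RQ = 20),
                        seq(0, 28800, length.out = 121))
tn <- turnover_number(sum(endpoint_yields(tr, c("MP", "MPR"))), 4)
cat(sprintf("\nDiscard-pathway turnover: %.3f waste per template (catalytic: %s)\n",
            tn$TN, tn$catalytic))

## intermediate estimation by channel subtraction ------------------------------
cal <- default_calibrations(fd)
unb <- signal_to_concentration(concentrations_to_signal(tr, cal$cy3_like),
                               cal$cy3_like, "MT")
was <- signal_to_concentration(concentrations_to_signal(tr, cal$af647_like),
                               cal$af647_like, "MPR")
est <- estimate_intermediate_by_subtraction(unb, was)
peak_true <- max(tr$conc[, "MT"])
peak_est <- max(est$conc)
cat(sprintf("MT intermediate: true peak %.3f nM, subtraction estimate %.3f nM\n",
            peak_true, peak_est))
cat("(the crude estimator overshoots when the waste reporter lags)\n")
write.csv(data.frame(time_s = est$times, mt_estimate_nM = est$conc,
                     mt_true_nM = tr$conc[tr$times %in% est$times, "MT"]),
          "results/intermediate_estimate.csv", row.names = FALSE)

## SNP initial-rate selectivity ------------------------------------------------
snp <- build_network("snp_detection")
times <- seq(0, 43200, length.out = 121)
rate_of <- function(v, p) {
  tt <- integrate_network(snp, default_true_rates(snp, v),
                          c(X = 15, RQ = 20, Sink = 20, Psnp = p, PL = 10),
                          times)
  initial_rate(times, tt$conc[, "XPR"])$rate
}
rows <- lapply(paste0("SNP", 1:6), function(v) {
  s0 <- rate_of("TS", 0) / rate_of(v, 0)
  s1 <- rate_of("TS", 20) / rate_of(v, 20)
  data.frame(candidate = v, selectivity_no_proof = s0,
             selectivity_with_proof = s1, gain = s1 / s0)
})
snp_tab <- do.call(rbind, rows)
write.csv(snp_tab, "results/snp_initial_rates.csv", row.names = FALSE)
cat("\nSNP initial-rate selectivity (TS rate / SNP rate):\n")
print(snp_tab, row.names = FALSE)
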