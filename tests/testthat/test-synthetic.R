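test_that("zero noise reproduces the noiseless observation exactly", {
  net <- build_network("template_binding")
  rates <- default_true_rates(net, "M1")
  design <- experiment_design("template_binding", c(ML = 8), c(T = 10),
                              duration = 3600, interval = 60)
  ds <- generate_traces(design, net, rates, default_calibrations(net),
                        noise_model(0, 0), seed = 1)
  keep <- ds$truth$times >= design$dead_time
  ref <- concentrations_to_signal(ds$truth, ds$calibrations$cy3_like)
  expect_identical(ds$traces$cy3_like$signal, ref$signal[keep])
  expect_identical(ds$traces$cy3_like$times, ref$times[keep])
  # dead-time samples are dropped, trigger included at t = 0
  expect_gte(min(ds$traces$cy3_like$times), design$dead_time)
  expect_equal(unname(ds$truth$conc[1, "T"]), 10)
})

test_that("datasets are bit-identical under the same seed", {
  net <- build_network("template_binding")
  rates <- default_true_rates(net, "M2")
  design <- experiment_design("template_binding", c(ML = 8), c(T = 5),
                              duration = 3600, interval = 60)
  a <- generate_traces(design, net, rates, default_calibrations(net),
                       noise_model(), seed = 77)
  b <- generate_traces(design, net, rates, default_calibrations(net),
                       noise_model(), seed = 77)
  expect_identical(a$traces, b$traces)
  c <- generate_traces(design, net, rates, default_calibrations(net),
                       noise_model(), seed = 78)
  expect_false(identical(a$traces$cy3_like$signal, c$traces$cy3_like$signal))

  s1 <- generate_study("fig2_binding", seed = 5, variants = "M1",
                       t_concs = 10)
  s2 <- generate_study("fig2_binding", seed = 5, variants = "M1",
                       t_concs = 10)
  expect_identical(s1$datasets[[1]]$traces, s2$datasets[[1]]$traces)
})

test_that("replicate noisy traces average to the noiseless signal", {
  net <- build_network("template_binding")
  rates <- default_true_rates(net, "M1")
  design <- experiment_design("template_binding", c(ML = 8), c(T = 10),
                              duration = 1200, interval = 120)
  noiseless <- generate_traces(design, net, rates, default_calibrations(net),
                               noise_model(0, 0), seed = 1)
  n_rep <- 200
  sigs <- vapply(seq_len(n_rep), function(s)
    generate_traces(design, net, rates, default_calibrations(net),
                    noise_model(), seed = 5000 + s)$traces$cy3_like$signal,
    numeric(length(noiseless$traces$cy3_like$signal)))
  for (i in seq_len(nrow(sigs))) {
    se <- stats::sd(sigs[i, ]) / sqrt(n_rep)
    expect_lt(abs(mean(sigs[i, ]) - noiseless$traces$cy3_like$signal[i]),
              3 * se)
  }
})

test_that("study presets encode the printed designs", {
  s2 <- generate_study("fig2_binding", noise_model(0, 0), seed = 1,
                       interval_scale = 10)
  expect_length(s2$datasets, 9)          # 3 variants x 3 template levels
  tcs <- vapply(s2$datasets, function(d) d$condition$T0, 0)
  expect_true(all(c(2, 5, 10) %in% tcs))
  expect_setequal(unique(vapply(s2$datasets, `[[`, "", "variant")),
                  c("M1", "M2", "M3"))

  s5 <- generate_study("fig5_snp", noise_model(0, 0), seed = 1,
                       interval_scale = 20)
  expect_length(s5$datasets, 14)         # 7 candidates x (0, 20 nM proofreader)
  expect_setequal(unique(vapply(s5$datasets, `[[`, "", "variant")),
                  c("TS", paste0("SNP", 1:6)))
  expect_setequal(unique(vapply(s5$datasets, function(d) d$condition$P0, 0)),
                  c(0, 20))

  s3 <- generate_study("fig3_discard", noise_model(0, 0), seed = 1,
                       variants = "M1", interval_scale = 10)
  expect_setequal(unique(vapply(s3$datasets, `[[`, "", "class")),
                  c("reporter", "template_recovery", "full_discard"))
  expect_error(generate_study("fig9_nope"), "unknown preset")
})

test_that("default rates reproduce the study's qualitative orderings", {
  # template binding: matched monomer forms MT fastest (Cy3 kinetics order)
  s <- generate_study("fig2_binding", noise_model(0, 0), seed = 1,
                      t_concs = 10, interval_scale = 5)
  at_1h <- vapply(s$datasets, function(d) {
    i <- which.min(abs(d$truth$times - 3600))
    d$truth$conc[i, "MT"]
  }, 0)
  names(at_1h) <- vapply(s$datasets, `[[`, "", "variant")
  expect_gt(at_1h[["M1"]], at_1h[["M2"]])
  expect_gt(at_1h[["M2"]], at_1h[["M3"]])

  # proofreading: mismatched monomers are stripped from the template faster
  rec <- build_network("template_recovery")
  waste_at <- vapply(c("M1", "M2", "M3"), function(v) {
    tr <- integrate_network(rec, default_true_rates(rec, v),
                            c(MT = 8, P = 50, RQ = 20),
                            seq(0, 3600, length.out = 31))
    sum(endpoint_yields(tr, c("MP", "MPR")))
  }, 0)
  expect_gt(waste_at[["M3"]], waste_at[["M2"]])
  expect_gt(waste_at[["M2"]], waste_at[["M1"]])
})
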