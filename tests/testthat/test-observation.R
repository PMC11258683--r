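make_flat_trajectory <- function(conc_named, times = seq(0, 100, 10)) {
  conc <- matrix(rep(conc_named, each = length(times)), nrow = length(times),
                 dimnames = list(NULL, names(conc_named)))
  structure(list(times = times, conc = conc, kind = "synthetic",
                 strands = list()),
            class = "kp_trajectory")
}

test_that("signal generation is linear with background offset", {
  tr <- make_flat_trajectory(c(A = 10, B = 3))
  cal <- calibration_curve("cy3_like", c(A = 100), background = 50)
  sig <- concentrations_to_signal(tr, cal)
  expect_equal(sig$signal, rep(1050, length(tr$times)))
  # zero slopes are rejected at construction, so "all slopes 0" is the
  # background-only case with a slope on an absent concentration
  tr0 <- make_flat_trajectory(c(A = 0, B = 3))
  expect_equal(concentrations_to_signal(tr0, cal)$signal,
               rep(50, length(tr0$times)))
  expect_error(
    concentrations_to_signal(tr, calibration_curve("cy3_like", c(Z = 10))),
    "unknown species")
})

test_that("calibration inverts exactly for a homogeneous group", {
  net <- build_network("full_discard")
  rates <- default_true_rates(net, "M1")
  traj <- integrate_network(net, rates, c(ML = 8, T = 4, P = 50, RQ = 20),
                            seq(0, 14400, 120))
  cal <- default_calibrations(net)$af647_like
  sig <- concentrations_to_signal(traj, cal)
  rec <- signal_to_concentration(sig, cal, "MPR")
  truth <- traj$conc[, "MPR"] + 0.05 * traj$conc[, "RQ"]
  expect_lt(max(abs(rec$conc - truth) / max(truth)), 1e-9)

  # background-only signal maps to zero concentration
  flat <- structure(list(well_id = "w", channel = "af647_like",
                         times = 0:5, signal = rep(cal$background, 6)),
                    class = "kp_signal_trace")
  expect_equal(signal_to_concentration(flat, cal, "MPR")$conc, rep(0, 6))

  # heterogeneous slopes in the requested group are a precondition error
  expect_error(signal_to_concentration(sig, cal, c("MPR", "RQ")),
               "heterogeneous")
})

test_that("noisy conversion is unbiased over replicates", {
  cal <- calibration_curve("cy3_like", c(A = 150), background = 50)
  tr <- make_flat_trajectory(c(A = 5), times = seq(0, 10, 1))
  noise <- noise_model(additive_sd = 7.5, proportional_sd = 0.02)
  net <- NULL
  n_rep <- 200
  set.seed(99)
  recovered <- replicate(n_rep, {
    sig <- concentrations_to_signal(tr, cal)
    sd <- sqrt(noise$additive_sd^2 + (noise$proportional_sd * sig$signal)^2)
    sig$signal <- sig$signal + stats::rnorm(length(sig$signal), 0, sd)
    mean(signal_to_concentration(sig, cal, "A")$conc)
  })
  se <- stats::sd(recovered) / sqrt(n_rep)
  expect_lt(abs(mean(recovered) - 5), 3 * se)
})

test_that("Cy3 signal tracks total unblocked monomer monotonically", {
  net <- build_network("full_discard")
  rates <- default_true_rates(net, "M1")
  traj <- integrate_network(net, rates, c(ML = 8, T = 4, P = 50, RQ = 20),
                            seq(0, 28800, 240))
  cal <- default_calibrations(net)$cy3_like
  sig <- concentrations_to_signal(traj, cal)
  unblocked <- rowSums(traj$conc[, c("MT", "MP", "MPR")])
  expect_true(all(diff(unblocked) >= -1e-9))
  expect_true(all(diff(sig$signal) >= -1e-6 * max(sig$signal)))
})

test_that("intermediate-by-subtraction behaves as the crude estimator", {
  # identical traces subtract to zero
  a <- structure(list(times = 0:10, conc = (0:10) / 2, species = "u"),
                 class = "kp_conc_trace")
  expect_true(all(estimate_intermediate_by_subtraction(a, a)$conc == 0))
  expect_true(isTRUE(attr(estimate_intermediate_by_subtraction(a, a), "crude")))

  # an instantaneously fast waste reporter makes the estimate track true MT
  net <- build_network("full_discard")
  rates <- update_rates(default_true_rates(net, "M1"), c(k_rep = 1e9))
  times <- seq(0, 28800, 120)
  traj <- integrate_network(net, rates, c(ML = 8, T = 4, P = 50, RQ = 20),
                            times)
  cal <- default_calibrations(net, quenched_frac = 0)
  unb <- signal_to_concentration(concentrations_to_signal(traj, cal$cy3_like),
                                 cal$cy3_like, "MT")
  was <- signal_to_concentration(concentrations_to_signal(traj, cal$af647_like),
                                 cal$af647_like, "MPR")
  est <- estimate_intermediate_by_subtraction(unb, was)
  truth <- traj$conc[, "MT"]
  sel <- truth > 0.05 * max(truth)
  expect_lt(max(abs(est$conc[sel] - truth[sel]) / truth[sel]), 0.02)

  # a slow reporter inflates the apparent intermediate (nonnegative bias)
  slow <- update_rates(default_true_rates(net, "M1"), c(k_rep = 5e3))
  traj2 <- integrate_network(net, slow, c(ML = 8, T = 4, P = 50, RQ = 20),
                             times)
  unb2 <- signal_to_concentration(
    concentrations_to_signal(traj2, cal$cy3_like), cal$cy3_like, "MT")
  was2 <- signal_to_concentration(
    concentrations_to_signal(traj2, cal$af647_like), cal$af647_like, "MPR")
  est2 <- estimate_intermediate_by_subtraction(unb2, was2)
  expect_true(all(est2$conc >= traj2$conc[, "MT"] - 1e-9))

  # non-overlapping time ranges are an error
  b <- structure(list(times = 100:110, conc = rep(1, 11), species = "w"),
                 class = "kp_conc_trace")
  expect_error(estimate_intermediate_by_subtraction(a, b), "overlap")
})
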