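## Synthetic plate-reader data at the study designs. Every dataset carries its
## ground truth (trajectory and true rates) so downstream stages are testable
## without the deposited raw data. Reproducibility contract: a dataset is a
## pure function of (design, network, rates, calibration, noise, seed).

#' Describe one well's experimental design
#'
#' @param kind Network kind the well runs.
#' @param initial Named nM concentrations present before triggering.
#' @param trigger Named nM concentrations injected at t = 0.
#' @param duration Run length, seconds (must exceed `dead_time`).
#' @param interval Sampling interval, seconds.
#' @param dead_time Mixing/shaking dead time before the first read, seconds
#'   (default 30 s: wells are shaken for 10-30 s before measurement starts).
#' @return A list of class `kp_design`.
#' @export
experiment_design <- function(kind, initial, trigger = numeric(0),
                              duration, interval, dead_time = 30) {
  stopifnot(all(initial >= 0), all(trigger >= 0), duration > dead_time,
            dead_time >= 0, interval > 0)
  structure(list(kind = kind, initial = initial, trigger = trigger,
                 duration = duration, interval = interval,
                 dead_time = dead_time),
            class = "kp_design")
}

#' Plate-reader noise model
#'
#' Additive plus proportional Gaussian noise:
#' sd(t) = sqrt(additive_sd^2 + (proportional_sd * signal(t))^2).
#' Defaults: additive 0.5% of a typical full-scale signal (150 units/nM x
#' 10 nM = 1500 units), proportional 2%.
#'
#' @param additive_sd Additive noise sd, signal units (>= 0).
#' @param proportional_sd Proportional noise fraction in [0, 1).
#' @return A list of class `kp_noise`.
#' @export
noise_model <- function(additive_sd = 7.5, proportional_sd = 0.02) {
  stopifnot(additive_sd >= 0, proportional_sd >= 0, proportional_sd < 1)
  structure(list(additive_sd = additive_sd, proportional_sd = proportional_sd),
            class = "kp_noise")
}

#' Generate noisy signal traces for one well
#'
#' Integrates the network from the post-injection state, drops samples before
#' the dead time, and emits one noisy trace per calibration channel, together
#' with the noiseless ground-truth trajectory (on the full grid, from t = 0).
#'
#' @param design A `kp_design`.
#' @param network A matching `kp_network`.
#' @param true_rates Ground-truth `kp_rates`.
#' @param calibrations Named list of `kp_calibration` (one per channel).
#' @param noise A `kp_noise`.
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @param well_id Well identifier.
#' @return A list of class `kp_dataset` with fields `design`, `traces` (named
#'   by channel), `truth` (a `kp_trajectory`), `calibrations`, `true_rates`,
#'   `seed`, `well_id`.
#' @export
generate_traces <- function(design, network, true_rates, calibrations,
                            noise = noise_model(), seed, well_id = "w1") {
  if (missing(seed)) stop("'seed' is required")
  init <- design$initial
  for (s in names(design$trigger))
    init[s] <- (if (s %in% names(init)) init[[s]] else 0) + design$trigger[[s]]
  times <- seq(0, design$duration, by = design$interval)
  truth <- integrate_network(network, true_rates, init, times)
  keep <- times >= design$dead_time
  set.seed(as.integer(seed))
  traces <- list()
  for (ch in names(calibrations)) {
    tr <- concentrations_to_signal(truth, calibrations[[ch]], well_id)
    tr$times <- tr$times[keep]
    tr$signal <- tr$signal[keep]
    sd <- sqrt(noise$additive_sd^2 + (noise$proportional_sd * tr$signal)^2)
    if (any(sd > 0))
      tr$signal <- tr$signal + stats::rnorm(length(tr$signal), 0, sd)
    traces[[ch]] <- tr
  }
  structure(list(design = design, traces = traces, truth = truth,
                 calibrations = calibrations, true_rates = true_rates,
                 seed = as.integer(seed), well_id = well_id),
            class = "kp_dataset")
}

well_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + 131 * i) %% 2147483629)
}

kp_presets <- c("fig2_binding", "fig3_discard", "fig4_dimerization", "fig5_snp")

#' Generate a multi-condition synthetic study
#'
#' Encodes the study's printed designs:
#' \describe{
#'   \item{fig2_binding}{8 nM blocked monomer per variant (M1, M2, M3), in
#'     separate wells, triggered by 2, 5 or 10 nM template.}
#'   \item{fig3_discard}{per variant: a template-recovery well (8 nM MT,
#'     50 nM P, 20 nM reporter) and a full-discard well (8 nM ML, 50 nM P,
#'     20 nM reporter, triggered by 4 nM T); plus reporter-triggering wells
#'     (pre-formed MP at `reporter_monomer_scale` times the 8 nM nominal,
#'     20 nM reporter) used by the staged fit.}
#'   \item{fig4_dimerization}{per variant, with and without 50 nM proofreader:
#'     8 nM blocked monomer, 10 nM N, 20 nM dimer reporter, triggered by 2 nM
#'     template; optionally the competitive pool (5 nM of each blocked
#'     monomer, 15 nM N, 2 nM template).}
#'   \item{fig5_snp}{candidates TS and SNP1..SNP6, each with 0 and 20 nM
#'     proofreader: 15 nM candidate, 20 nM reporter, 20 nM sink, triggered by
#'     10 nM Probe-Lock.}
#' }
#'
#' @param preset One of `"fig2_binding"`, `"fig3_discard"`,
#'   `"fig4_dimerization"`, `"fig5_snp"`.
#' @param noise A `kp_noise`.
#' @param seed Integer seed for the whole study; per-well seeds are derived
#'   from it.
#' @param variants Monomer variants (or SNP candidates) to include.
#' @param t_concs Template (trigger) concentration series where applicable.
#' @param mt_concs Pre-formed MT concentration series for the
#'   template-recovery wells (a range of MT levels makes the proofreading and
#'   reporter stages separately identifiable, since only the higher levels
#'   deplete the reporter appreciably).
#' @param reporter_monomer_scale True total-monomer scale (fraction of the
#'   8 nM nominal) in the reporter-triggering wells; the staged fit's
#'   candidate grid spans 0.80..1.15.
#' @param proof_concs Proofreader concentrations for the dimerization and
#'   SNP study arms.
#' @param include_competitive Include the competitive-pool wells in the
#'   dimerization preset.
#' @param interval_scale Multiplier on the preset sampling intervals (> 1
#'   thins the grids; used to keep refits cheap).
#' @return A list of class `kp_study`: `preset`, `seed`, `datasets` (each a
#'   `kp_dataset` plus `class`, `variant` and condition metadata).
#' @export
generate_study <- function(preset, noise = noise_model(), seed = 1,
                           variants = NULL, t_concs = NULL, mt_concs = NULL,
                           reporter_monomer_scale = 1.0,
                           proof_concs = NULL,
                           include_competitive = TRUE,
                           interval_scale = 1) {
  if (!preset %in% kp_presets)
    stop("unknown preset: ", preset, " (expected one of ",
         paste(kp_presets, collapse = ", "), ")")
  datasets <- list()
  i <- 0L
  add <- function(class, variant, design, network, rates, extra = list()) {
    i <<- i + 1L
    ds <- generate_traces(design, network, rates,
                          default_calibrations(network), noise,
                          seed = well_seed(seed, i),
                          well_id = sprintf("%s_w%02d", preset, i))
    ds$class <- class
    ds$variant <- variant
    ds$condition <- extra
    ds$network <- network
    datasets[[length(datasets) + 1L]] <<- ds
  }

  if (preset == "fig2_binding") {
    if (is.null(variants)) variants <- c("M1", "M2", "M3")
    if (is.null(t_concs)) t_concs <- c(2, 5, 10)
    net <- build_network("template_binding")
    for (v in variants) {
      rates <- default_true_rates(net, v)
      for (tc in t_concs)
        add("template_binding", v,
            experiment_design("template_binding", c(ML = 8),
                              c(T = tc), duration = 14400,
                              interval = 120 * interval_scale), net, rates,
            list(T0 = tc, ML0 = 8))
    }
  } else if (preset == "fig3_discard") {
    if (is.null(variants)) variants <- c("M1", "M2", "M3")
    if (is.null(t_concs)) t_concs <- 4
    if (is.null(mt_concs)) mt_concs <- c(2, 8)
    net_rec <- build_network("template_recovery")
    net_fd <- build_network("full_discard")
    rep_rates <- default_true_rates(net_rec, "M1")
    add("reporter", "M1",
        experiment_design("template_recovery",
                          c(MP = 8 * reporter_monomer_scale, RQ = 20),
                          duration = 7200, interval = 60 * interval_scale),
        net_rec, rep_rates,
        list(MP0_nominal = 8, scale = reporter_monomer_scale))
    for (v in variants) {
      rr <- default_true_rates(net_rec, v)
      for (mc in mt_concs)
        add("template_recovery", v,
            experiment_design("template_recovery",
                              c(MT = mc, P = 50, RQ = 20),
                              duration = 14400, interval = 120 * interval_scale),
            net_rec, rr, list(P0 = 50, MT0 = mc))
      fr <- default_true_rates(net_fd, v)
      for (tc in t_concs)
        add("full_discard", v,
            experiment_design("full_discard", c(ML = 8, P = 50, RQ = 20),
                              c(T = tc), duration = 28800,
                              interval = 240 * interval_scale),
            net_fd, fr, list(T0 = tc, P0 = 50))
    }
  } else if (preset == "fig4_dimerization") {
    if (is.null(variants)) variants <- c("M1", "M2", "M3")
    if (is.null(proof_concs)) proof_concs <- c(0, 50)
    net <- build_network("dimerization")
    for (v in variants) {
      rates <- default_true_rates(net, v)
      for (pc in proof_concs)
        add("dimerization", v,
            experiment_design("dimerization", c(ML = 8, N = 10, P = pc,
                                                RQ = 20),
                              c(T = 2), duration = 259200,
                              interval = 1800 * interval_scale), net, rates,
            list(P0 = pc, N0 = 10, T0 = 2, competitive = FALSE))
    }
    if (include_competitive && length(variants) > 1L) {
      cnet <- build_network("dimerization", variants = variants)
      crates <- default_true_rates(cnet)
      init <- c(stats::setNames(rep(5, length(variants)),
                                paste0(variants, "L")),
                N = 15, RQ = 20)
      for (pc in proof_concs)
        add("dimerization_competitive", paste(variants, collapse = "+"),
            experiment_design("dimerization", c(init, P = pc), c(T = 2),
                              duration = 259200,
                              interval = 1800 * interval_scale),
            cnet, crates,
            list(P0 = pc, N0 = 15, T0 = 2, competitive = TRUE))
    }
  } else if (preset == "fig5_snp") {
    if (is.null(variants)) variants <- c("TS", paste0("SNP", 1:6))
    if (is.null(proof_concs)) proof_concs <- c(0, 20)
    net <- build_network("snp_detection")
    for (v in variants) {
      rates <- default_true_rates(net, v)
      for (pc in proof_concs)
        add("snp", v,
            experiment_design("snp_detection", c(X = 15, RQ = 20, Sink = 20,
                                                 Psnp = pc),
                              c(PL = 10), duration = 172800,
                              interval = 1200 * interval_scale), net, rates,
            list(P0 = pc, X0 = 15, PL0 = 10))
    }
  }
  structure(list(preset = preset, seed = as.integer(seed),
                 datasets = datasets),
            class = "kp_study")
}

#' Concatenate studies (e.g. binding + discard for the staged fit)
#' @param ... `kp_study` objects.
#' @return A `kp_study` with the union of datasets.
#' @export
combine_studies <- function(...) {
  studies <- list(...)
  structure(list(preset = paste(vapply(studies, `[[`, "", "preset"),
                                collapse = "+"),
                 seed = studies[[1]]$seed,
                 datasets = do.call(c, lapply(studies, `[[`, "datasets"))),
            class = "kp_study")
}

#' Subset a study by dataset class
#' @param study A `kp_study`.
#' @param class Dataset class tag.
#' @return List of matching `kp_dataset`s.
#' @export
study_datasets <- function(study, class) {
  Filter(function(d) identical(d$class, class), study$datasets)
}

#' @export
print.kp_study <- function(x, ...) {
  cat("<kp_study>", x$preset, ":", length(x$datasets), "wells, seed",
      x$seed, "\n")
  cls <- table(vapply(x$datasets, `[[`, "", "class"))
  for (nm in names(cls)) cat("  ", nm, ":", cls[[nm]], "\n")
  invisible(x)
}
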