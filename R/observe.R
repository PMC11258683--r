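## Fluorescence observation layer. Two channels emulate the study's readout:
## a Cy3-like channel reporting monomer-strand species (quenched while the
## blocker is attached) and an AlexaFluor-647-like channel reporting opened
## reporter complexes. Signals are linear in concentration: one calibration
## slope per fluorophore is shared across complexes, because the fluorophore's
## local environment is the same in all of them; quenched complexes retain a
## small residual slope (default 5% of the unquenched slope).

#' Create a calibration curve
#'
#' @param channel `"cy3_like"` or `"af647_like"`.
#' @param slopes Named nonnegative numeric vector: signal units per nM for
#'   each fluorescent species; at least one slope must be positive.
#' @param background Nonnegative background signal.
#' @return A list of class `kp_calibration`.
#' @export
calibration_curve <- function(channel, slopes, background = 0) {
  channel <- match.arg(channel, c("cy3_like", "af647_like"))
  if (any(slopes < 0) || background < 0) stop("slopes and background must be >= 0")
  if (!any(slopes > 0)) stop("at least one species needs a positive slope")
  structure(list(channel = channel, slopes = slopes, background = background),
              class = "kp_calibration")
}

#' Default calibrations for a built-in network
#'
#' Cy3-like: every species containing the labeled monomer (or, for the SNP
#' network, the reporter strand) at the shared slope; complexes still carrying
#' a quencher-labeled blocker strand get `quenched_frac` of it.
#' AF647-like: opened reporter products at the shared slope; the intact
#' reporter complex (fluorophore still next to its quencher) at
#' `quenched_frac`.
#'
#' @param network A built-in `kp_network`.
#' @param slope Shared unquenched slope, signal units per nM.
#' @param background Background signal.
#' @param quenched_frac Residual slope fraction of quenched complexes.
#' @return Named list with elements `cy3_like` and `af647_like`.
#' @export
default_calibrations <- function(network, slope = 150, background = 50,
                                 quenched_frac = 0.05) {
  sm <- strand_map(network)
  sp <- names(sm)
  monomer_strands <- switch(network$kind,
    snp_detection = "X",
    dimerization = setdiff(unlist(lapply(network$species, function(s)
      if ("monomer" %in% s$roles) s$strands[1] else NULL)), character(0)),
    "M")
  quencher_strands <- switch(network$kind,
    snp_detection = c("Lock", "Q"),
    c("L", "Q"))
  cy3 <- numeric(0)
  for (s in sp) {
    if (any(sm[[s]] %in% monomer_strands)) {
      quenched <- any(sm[[s]] %in% quencher_strands)
      cy3[s] <- slope * if (quenched) quenched_frac else 1
    }
  }
  af <- numeric(0)
  if ("R" %in% unlist(sm)) {
    for (s in sp) {
      if ("R" %in% sm[[s]]) {
        quenched <- "Q" %in% sm[[s]]
        af[s] <- slope * if (quenched) quenched_frac else 1
      }
    }
  }
  out <- list(cy3_like = calibration_curve("cy3_like", cy3, background))
  if (length(af))
    out$af647_like <- calibration_curve("af647_like", af, background)
  out
}

#' Map a trajectory to a fluorescence signal trace
#'
#' signal(t) = background + sum over species of slope_s * [s](t).
#'
#' @param trajectory A `kp_trajectory`.
#' @param calibration A `kp_calibration`.
#' @param well_id Well identifier carried on the trace.
#' @return A list of class `kp_signal_trace`: `well_id`, `channel`, `times`,
#'   `signal`.
#' @export
concentrations_to_signal <- function(trajectory, calibration, well_id = "w1") {
  bad <- setdiff(names(calibration$slopes)[calibration$slopes > 0],
                 colnames(trajectory$conc))
  if (length(bad)) stop("calibration references unknown species: ",
                        paste(bad, collapse = ", "))
  common <- intersect(names(calibration$slopes), colnames(trajectory$conc))
  sig <- calibration$background +
    as.numeric(trajectory$conc[, common, drop = FALSE] %*%
                 calibration$slopes[common])
  structure(list(well_id = well_id, channel = calibration$channel,
                 times = trajectory$times, signal = sig),
            class = "kp_signal_trace")
}

#' Convert a signal trace back to a summed group concentration
#'
#' Inverse of [concentrations_to_signal()] for a single homogeneous species
#' group: all species in the group must share one slope within 1% (one
#' calibration per fluorophore).
#'
#' @param trace A `kp_signal_trace`.
#' @param calibration The `kp_calibration` of the trace's channel.
#' @param group Character vector of species whose summed concentration the
#'   signal reports.
#' @return A list of class `kp_conc_trace`: `times`, `conc` (nM), `species`.
#' @export
signal_to_concentration <- function(trace, calibration, group) {
  sl <- calibration$slopes[group]
  if (anyNA(sl)) stop("group species missing from calibration: ",
                      paste(group[is.na(sl)], collapse = ", "))
  if ((max(sl) - min(sl)) > 0.01 * max(sl))
    stop("heterogeneous slopes in group (differ by more than 1%): ",
         paste(group, collapse = ", "))
  conc <- (trace$signal - calibration$background) / mean(sl)
  structure(list(times = trace$times, conc = conc, species = group),
            class = "kp_conc_trace")
}

#' Estimate the template-bound intermediate by channel subtraction
#'
#' estimate(t) = unblocked(t) - waste(t), clipped at zero; the study's own
#' description of this estimator is that it is crude, and the returned object
#' is flagged accordingly. When the two traces live on different grids both
#' are linearly interpolated onto the coarser one.
#'
#' @param unblocked A `kp_conc_trace` of total unblocked monomer (Cy3-like).
#' @param waste A `kp_conc_trace` of reported waste (AF647-like).
#' @return A `kp_conc_trace` with attribute `crude = TRUE`.
#' @export
estimate_intermediate_by_subtraction <- function(unblocked, waste) {
  lo <- max(unblocked$times[1], waste$times[1])
  hi <- min(max(unblocked$times), max(waste$times))
  if (lo >= hi) stop("non-overlapping time ranges")
  grid <- if (length(unblocked$times) <= length(waste$times)) unblocked$times
          else waste$times
  grid <- grid[grid >= lo & grid <= hi]
  u <- stats::approx(unblocked$times, unblocked$conc, xout = grid)$y
  w <- stats::approx(waste$times, waste$conc, xout = grid)$y
  est <- structure(list(times = grid, conc = pmax(u - w, 0),
                        species = "intermediate_estimate"),
                   class = "kp_conc_trace")
  attr(est, "crude") <- TRUE
  est
}
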