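## Specificity statistics: discrimination factors on endpoint yields,
## catalytic turnover, and initial rates of product formation.

#' Discrimination factor between two variants
#'
#' D_x:y = endpoint yield of the correct variant's product over the incorrect
#' variant's, at matched input concentrations.
#'
#' @param yield_x,yield_y Endpoint product yields (nM), x the reference
#'   (correct) variant.
#' @param variant_x,variant_y Labels recorded on the result.
#' @param condition Metadata list (e.g. proofreader identity/concentration).
#' @return A list of class `kp_discrimination`: `D`, yields, labels,
#'   condition.
#' @export
discrimination_factor <- function(yield_x, yield_y, variant_x = "x",
                                  variant_y = "y", condition = list()) {
  if (!is.finite(yield_x) || !is.finite(yield_y) || yield_x < 0)
    stop("yields must be finite and nonnegative")
  if (yield_y <= 0)
    stop("discrimination factor undefined: zero yield for variant ", variant_y)
  structure(list(D = yield_x / yield_y, yield_x = yield_x, yield_y = yield_y,
                 variant_x = variant_x, variant_y = variant_y,
                 condition = condition),
            class = "kp_discrimination")
}

#' Catalytic turnover number
#'
#' TN = waste formed per unit of template added; TN > 1 is the signature of
#' repeated catalytic activity (each template molecule has driven more than
#' one monomer into waste).
#'
#' @param waste Endpoint waste concentration, nM.
#' @param template_initial Added template concentration, nM (> 0).
#' @return A list: `TN`, `catalytic` (TRUE when TN > 1).
#' @export
turnover_number <- function(waste, template_initial) {
  if (template_initial <= 0) stop("template_initial must be positive")
  TN <- waste / template_initial
  list(TN = TN, catalytic = TN > 1)
}

#' Initial rate of a concentration trace
#'
#' Least-squares slope over a time window (default: from the first point to
#' the time the trace reaches 10% of its final value).
#'
#' @param times,conc Trace vectors (nM vs seconds).
#' @param window `c(from, to)` in seconds; needs at least 3 points inside.
#' @return A list: `rate` (nM/s), `se` (standard error), `n`.
#' @export
initial_rate <- function(times, conc, window = NULL) {
  if (is.null(window)) {
    target <- conc[1] + 0.1 * (conc[length(conc)] - conc[1])
    hit <- which(conc >= target)
    window <- c(times[1], times[max(hit[1], 3)])
  }
  sel <- times >= window[1] & times <= window[2]
  if (sum(sel) < 3) stop("fewer than 3 points in the rate window")
  fit <- stats::lm(conc[sel] ~ times[sel])
  co <- summary(fit)$coefficients
  list(rate = unname(co[2, 1]), se = unname(co[2, 2]), n = sum(sel))
}

#' Proofreading enhancement report for the dimerization motif
#'
#' Runs matched dimerization simulations for each monomer variant with and
#' without the proofreader, tabulates endpoint dimer yields, the
#' discrimination factors D_1:x in both arms, their ratio (the improvement
#' factor the proofreader buys), time-to-half-yield, and an endpoint
#' convergence check (yield change below 1% over the final 10% of the run).
#'
#' @param variants Monomer variant profiles (first one is the reference).
#' @param proof_conc Proofreader concentration in the "with" arm, nM.
#' @param ml0,n0,t0,rq0 Initial concentrations, nM.
#' @param duration Run length, seconds.
#' @param n_points Output grid size.
#' @param rates_for Function `(network, variant) -> kp_rates` supplying each
#'   variant's rate constants; defaults to [default_true_rates()].
#' @return A list of class `kp_enhancement`: `yields` (per variant/arm table),
#'   `D` (per comparison/arm), `improvement` (named by comparison).
#' @export
kp_enhancement_report <- function(variants = c("M1", "M2", "M3"),
                                  proof_conc = 50, ml0 = 8, n0 = 10, t0 = 2,
                                  rq0 = 20, duration = 259200,
                                  n_points = 145,
                                  rates_for = default_true_rates) {
  net <- build_network("dimerization")
  times <- seq(0, duration, length.out = n_points)
  arms <- unique(c(0, proof_conc))
  rows <- list()
  for (v in variants) {
    rates <- rates_for(net, v)
    for (pc in arms) {
      traj <- integrate_network(net, rates,
                                c(ML = ml0, N = n0, P = pc, RQ = rq0, T = t0),
                                times)
      dimer <- traj$conc[, "MN"] + traj$conc[, "MNR"]
      yield <- dimer[length(dimer)]
      tail_start <- which(times >= 0.9 * duration)[1]
      converged <- (max(dimer[tail_start:length(dimer)]) -
                      min(dimer[tail_start:length(dimer)])) <= 0.01 * max(yield, 1e-12)
      half <- which(dimer >= 0.5 * yield)[1]
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, proofreader_nM = pc, dimer_yield_nM = yield,
        t_half_s = times[half], endpoint_converged = converged)
    }
  }
  yields <- do.call(rbind, rows)
  ref <- variants[1]
  D <- list(); improvement <- numeric(0)
  for (v in variants[-1]) {
    cmp <- paste0(sub("^M", "", ref), ":", sub("^M", "", v))
    for (pc in arms) {
      yx <- yields$dimer_yield_nM[yields$variant == ref &
                                    yields$proofreader_nM == pc]
      yy <- yields$dimer_yield_nM[yields$variant == v &
                                    yields$proofreader_nM == pc]
      D[[paste0("D", cmp, if (pc > 0) "_proof" else "_noproof")]] <-
        discrimination_factor(yx, yy, ref, v,
                              condition = list(proofreader_nM = pc))
    }
    if (length(arms) > 1L)
      improvement[cmp] <- D[[paste0("D", cmp, "_proof")]]$D /
        D[[paste0("D", cmp, "_noproof")]]$D
  }
  structure(list(yields = yields, D = D, improvement = improvement),
            class = "kp_enhancement")
}

#' @export
print.kp_enhancement <- function(x, ...) {
  print(x$yields, row.names = FALSE)
  for (nm in names(x$D))
    cat(" ", nm, "=", format(x$D[[nm]]$D, digits = 4), "\n")
  cat("  improvement factor:",
      paste(names(x$improvement), format(x$improvement, digits = 4),
            collapse = ", "), "\n")
  invisible(x)
}
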