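## Deterministic simulation. Internal units are nanomolar and seconds; the
## public rate interface is M^-1 s^-1 / s^-1 (see rates.R). Concentrations may
## undershoot zero by integrator tolerance during the solve; they are clipped
## to zero only on output.

new_trajectory <- function(times, conc, network) {
  structure(list(times = times, conc = conc, kind = network$kind,
                 strands = conservation_vectors(network)),
            class = "kp_trajectory")
}

#' Integrate a network's mass-action ODEs
#'
#' Solves d[c]/dt = S v(c) with mass-action propensities using a stiff-capable
#' integrator (deSolve lsoda), at relative tolerance 1e-8 and absolute
#' tolerance 1e-12 nM by default; rate constants span many orders of magnitude
#' in these networks, so the tolerances are deliberately tight.
#'
#' @param network A `kp_network`.
#' @param rates A `kp_rates` covering every reaction of the network.
#' @param initial Named vector of initial concentrations in nM; species not
#'   named start at 0.
#' @param times Numeric vector of output times in seconds, strictly
#'   increasing, starting at 0.
#' @param rtol,atol Integrator tolerances (relative; absolute, nM).
#' @return A `kp_trajectory`: `times` and a time-by-species concentration
#'   matrix `conc` (nM, clipped at 0).
#' @export
integrate_network <- function(network, rates, initial, times,
                              rtol = 1e-8, atol = 1e-12) {
  sp <- species_names(network)
  if (length(times) < 2L || any(diff(times) <= 0) || times[1] < 0)
    stop("'times' must be strictly increasing and start at >= 0")
  bad <- setdiff(names(initial), sp)
  if (length(bad)) stop("unknown species in 'initial': ",
                        paste(bad, collapse = ", "))
  y0 <- stats::setNames(numeric(length(sp)), sp)
  y0[names(initial)] <- initial
  if (any(y0 < 0)) stop("initial concentrations must be nonnegative")

  S <- stoichiometry(network)
  k <- internal_rate_vector(network, rates)
  i1 <- vapply(network$reactions, function(r) match(r$reactants[1], sp), 0L)
  # sentinel index n+1 holds the constant 1 for unimolecular steps
  i2 <- vapply(network$reactions, function(r)
    if (length(r$reactants) == 2L) match(r$reactants[2], sp)
    else length(sp) + 1L, 0L)

  rhs <- function(t, y, parms) {
    ya <- c(y, 1)
    v <- k * ya[i1] * ya[i2]
    list(as.vector(S %*% v))
  }
  t0 <- times
  prepend <- t0[1] > 0
  if (prepend) t0 <- c(0, t0)
  sol <- try(deSolve::ode(y = y0, times = t0, func = rhs, parms = NULL,
                          method = "lsoda", rtol = rtol, atol = atol),
             silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(t0)) {
    t_fail <- if (inherits(sol, "try-error")) NA_real_ else sol[nrow(sol), 1]
    stop("integration failed (kind=", network$kind, ") near t=", t_fail, " s")
  }
  conc <- unname(sol[, -1, drop = FALSE])
  if (prepend) conc <- conc[-1, , drop = FALSE]
  if (any(!is.finite(conc)))
    stop("integration produced non-finite concentrations (kind=",
         network$kind, ")")
  conc[conc < 0] <- 0
  colnames(conc) <- sp
  new_trajectory(times, conc, network)
}

#' Concentrations at the final time point
#'
#' @param trajectory A `kp_trajectory`.
#' @param species Character vector of species names; default all.
#' @return Named numeric vector of endpoint concentrations (nM).
#' @export
endpoint_yields <- function(trajectory, species = colnames(trajectory$conc)) {
  bad <- setdiff(species, colnames(trajectory$conc))
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  y <- trajectory$conc[nrow(trajectory$conc), species]
  stats::setNames(as.numeric(y), species)
}

#' Maximum relative drift of every strand conservation law
#'
#' For each strand, the conserved total is the conservation vector dotted with
#' the concentrations; the drift is the peak deviation from the initial total,
#' relative to that total (strands with zero total are skipped).
#'
#' @param trajectory A `kp_trajectory`.
#' @return Named numeric vector of relative drifts, one per strand.
#' @export
conservation_drift <- function(trajectory) {
  out <- numeric(0)
  for (st in names(trajectory$strands)) {
    v <- trajectory$strands[[st]][colnames(trajectory$conc)]
    tot <- as.numeric(trajectory$conc %*% v)
    if (tot[1] <= 0) next
    out[st] <- max(abs(tot - tot[1])) / tot[1]
  }
  out
}

#' Interpolate a trajectory column at arbitrary times
#' @keywords internal
traj_interp <- function(trajectory, species, at) {
  stats::approx(trajectory$times, trajectory$conc[, species], xout = at,
                rule = 2)$y
}

#' @export
print.kp_trajectory <- function(x, ...) {
  cat("<kp_trajectory>", x$kind, ":", length(x$times), "time points, ",
      ncol(x$conc), "species over [", x$times[1], ",",
      x$times[length(x$times)], "] s\n")
  invisible(x)
}
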