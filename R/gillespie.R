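## Exact stochastic simulation (direct method), the independent oracle for the
## deterministic engine. Bimolecular rate constants are converted to stochastic
## propensity constants through the reaction volume; at large copy number the
## replicate mean must agree with the ODE solution.

AVOGADRO <- 6.02214076e23

#' Exact stochastic simulation (direct-method SSA)
#'
#' @param network A `kp_network`.
#' @param rates A `kp_rates` (interface units).
#' @param initial_counts Named integer vector of initial molecule counts;
#'   species not named start at 0.
#' @param volume Reaction volume in liters (> 0); converts bimolecular rate
#'   constants to per-pair propensities (c = k / (N_A V) with k in
#'   M^-1 s^-1) and counts to concentrations.
#' @param t_end End time, seconds.
#' @param seed Integer random seed (mandatory: runs are reproducible).
#' @param record_times Optional increasing vector of times at which to record
#'   the state (default: 51 evenly spaced points over [0, t_end]).
#' @return A list of class `kp_ssa`: `times`, `counts` (time-by-species
#'   matrix, molecule numbers), `conc` (the same in nM), `n_events`, `seed`,
#'   `volume`.
#' @export
gillespie <- function(network, rates, initial_counts, volume, t_end, seed,
                      record_times = NULL) {
  if (missing(seed)) stop("'seed' is required")
  stopifnot(volume > 0, t_end > 0)
  sp <- species_names(network)
  bad <- setdiff(names(initial_counts), sp)
  if (length(bad)) stop("unknown species in 'initial_counts': ",
                        paste(bad, collapse = ", "))
  n <- stats::setNames(numeric(length(sp)), sp)
  n[names(initial_counts)] <- initial_counts
  if (any(n < 0) || any(n != round(n))) stop("counts must be nonnegative integers")

  if (is.null(record_times)) record_times <- seq(0, t_end, length.out = 51L)
  stopifnot(all(diff(record_times) > 0), record_times[1] >= 0,
            record_times[length(record_times)] <= t_end)

  S <- stoichiometry(network)
  rn <- vapply(network$reactions, `[[`, "", "rate")
  kM <- rates$values[rn]                       # interface units
  mol <- rates$molecularity[rn]
  cst <- ifelse(mol == 2L, kM / (AVOGADRO * volume), kM)
  i1 <- vapply(network$reactions, function(r) match(r$reactants[1], sp), 0L)
  i2 <- vapply(network$reactions, function(r)
    if (length(r$reactants) == 2L) match(r$reactants[2], sp) else NA_integer_, 0L)
  same <- !is.na(i2) & i2 == i1

  set.seed(as.integer(seed))
  rec <- matrix(0, nrow = length(record_times), ncol = length(sp),
                dimnames = list(NULL, sp))
  ptr <- 1L
  t <- 0
  n_events <- 0L
  nr <- length(cst)
  bi <- which(!is.na(i2))
  repeat {
    a <- cst * n[i1]
    a[bi] <- a[bi] * n[i2[bi]]
    a[same] <- cst[same] * n[i1[same]] * (n[i1[same]] - 1) / 2
    a0 <- sum(a)
    t_next <- if (a0 > 0) t + stats::rexp(1, a0) else Inf
    while (ptr <= length(record_times) && record_times[ptr] < t_next) {
      rec[ptr, ] <- n
      ptr <- ptr + 1L
    }
    if (!is.finite(t_next) || t_next > t_end) break
    t <- t_next
    j <- sample.int(nr, 1L, prob = a)
    n <- n + S[, j]
    n_events <- n_events + 1L
  }
  while (ptr <= length(record_times)) {
    rec[ptr, ] <- n
    ptr <- ptr + 1L
  }
  conc <- rec / (AVOGADRO * volume * 1e-9)
  structure(list(times = record_times, counts = rec, conc = conc,
                 n_events = n_events, seed = as.integer(seed),
                 volume = volume),
            class = "kp_ssa")
}

#' @export
print.kp_ssa <- function(x, ...) {
  cat("<kp_ssa>", x$n_events, "events, seed", x$seed, ", volume", x$volume,
      "L\n")
  invisible(x)
}
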