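## Idealized Hopfield recognition cycle, the analytic reference the
## strand-displacement motif is compared against. A single recognition site
## cycles through free -> bound -> activated states for either the correct
## ligand C or the incorrect ligand D; the incorrect ligand unbinds faster by
## the factor f0 at BOTH unbinding steps, and chemical drive (fuel-to-waste
## chemical-potential ratio) pushes the cycle clockwise so the factor can be
## exploited twice: enrichment runs from f0 (equilibrium) to f0^2 (strong
## drive, slow product formation).

#' Construct a Hopfield recognition cycle
#'
#' States: free site, ligand-bound (Xc), activated (Xc*) for X in {C, D}.
#' Transitions per ligand: binding (kon x concentration), unbinding
#' (koff x f), activation (kact, the fuel-coupled step), deactivation
#' (kdeact), release from the activated state (krel x f), direct rebinding
#' into the activated state (krebind x concentration), and product formation
#' (W, irreversible, regenerating the free site). Discrimination f is 1 for C
#' and `f0` for D, applied at the two unbinding steps only.
#'
#' The drive enters as an explicit dimensionless ratio, not as free energies
#' in physical units: `kdeact` is set so the clockwise/counterclockwise cycle
#' rate product equals `drive` (detailed balance at `drive = 1`).
#'
#' @param f0 Unbinding discrimination factor (> 0).
#' @param drive Fuel/waste chemical-potential ratio (1 = detailed balance).
#' @param kon,koff,kact,krel,krebind,W Base rate constants (see above).
#' @param conc_C,conc_D Ligand concentrations (arbitrary shared units).
#' @return A list of class `kp_hopfield`.
#' @export
hopfield_cycle <- function(f0, drive = 1, kon = 1, koff = 1, kact = 1e-3,
                           krel = 1, krebind = 1e-9, W = 1e-9,
                           conc_C = 1, conc_D = 1) {
  stopifnot(f0 > 0, drive > 0, kon > 0, koff > 0, kact > 0, krel > 0,
            krebind > 0, W >= 0, conc_C > 0, conc_D > 0)
  kdeact <- kon * kact * krel / (koff * krebind * drive)
  structure(list(f0 = f0, drive = drive, kon = kon, koff = koff,
                 kact = kact, kdeact = kdeact, krel = krel,
                 krebind = krebind, W = W, conc_C = conc_C, conc_D = conc_D),
            class = "kp_hopfield")
}

#' Generator matrix of the recognition-site master equation
#'
#' @param cycle A `kp_hopfield`.
#' @return 5x5 rate matrix Q (rows = from, columns = to) over states
#'   `free`, `C1`, `C2`, `D1`, `D2` (1 = bound, 2 = activated); diagonal
#'   holds minus the exit rates.
#' @export
hopfield_generator <- function(cycle) {
  st <- c("free", "C1", "C2", "D1", "D2")
  Q <- matrix(0, 5, 5, dimnames = list(st, st))
  add <- function(from, to, rate) Q[from, to] <<- Q[from, to] + rate
  for (X in c("C", "D")) {
    f <- if (X == "C") 1 else cycle$f0
    conc <- if (X == "C") cycle$conc_C else cycle$conc_D
    s1 <- paste0(X, "1"); s2 <- paste0(X, "2")
    add("free", s1, cycle$kon * conc)
    add(s1, "free", cycle$koff * f)
    add(s1, s2, cycle$kact)
    add(s2, s1, cycle$kdeact)
    add(s2, "free", cycle$krel * f)
    add("free", s2, cycle$krebind * conc)
    add(s2, "free", cycle$W)          # product formation regenerates the site
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Steady state of the Hopfield cycle
#'
#' Solves the stationary linear master equation exactly and reports the
#' correct:incorrect product-flux ratio (the enrichment, W pi(Cc*) / W
#' pi(Dc*)) and the error fraction of product formation.
#'
#' @param cycle A `kp_hopfield`.
#' @return A list: `pi` (stationary distribution over the five states),
#'   `enrichment`, `error_fraction`.
#' @export
hopfield_steady_state <- function(cycle) {
  Q <- hopfield_generator(cycle)
  A <- rbind(t(Q)[-1, ], rep(1, 5))
  b <- c(numeric(4), 1)
  pi <- try(solve(A, b), silent = TRUE)
  if (inherits(pi, "try-error") || any(!is.finite(pi)) || any(pi < -1e-12))
    stop("degenerate cycle: no stationary distribution")
  pi <- pmax(pi, 0); pi <- pi / sum(pi)
  names(pi) <- colnames(Q)
  if (pi[["D2"]] <= 0) stop("degenerate cycle: no incorrect-product flux")
  enrich <- pi[["C2"]] / pi[["D2"]]
  list(pi = pi, enrichment = unname(enrich),
       error_fraction = unname(pi[["D2"]] / (pi[["C2"]] + pi[["D2"]])))
}
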