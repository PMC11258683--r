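## Rate constants are held in interface units throughout the public API:
## M^-1 s^-1 for bimolecular steps, s^-1 for unimolecular steps. Conversion to
## the internal nM/seconds system (bimolecular x 1e-9) happens once, inside the
## simulators, driven by the molecularity each rate name has in the network.

#' Molecularity of every rate name in a network
#'
#' @param network A `kp_network`.
#' @return Named integer vector (1 or 2) over rate names. A rate name used by
#'   reactions of different molecularity is an error.
#' @export
molecularity <- function(network) {
  rn <- vapply(network$reactions, `[[`, "", "rate")
  nr <- vapply(network$reactions, function(r) length(r$reactants), 0L)
  out <- integer(0)
  for (nm in unique(rn)) {
    m <- unique(nr[rn == nm])
    if (length(m) != 1L)
      stop("rate '", nm, "' used at inconsistent molecularity")
    out[nm] <- m
  }
  out
}

#' Create a rate set for a network
#'
#' @param network The `kp_network` the rates belong to.
#' @param values Named numeric vector of rate-constant values in interface
#'   units (M^-1 s^-1 bimolecular, s^-1 unimolecular), covering every rate
#'   name the network references.
#' @param unknown Character vector of rate names to treat as unknown (the
#'   fit targets); the rest are known.
#' @param bounds Named list of `c(low, high)` search ranges (interface units)
#'   for the unknowns. Defaults to four decades either side of the value.
#' @return A list of class `kp_rates` with fields `values`, `known`,
#'   `unknown`, `bounds`, `molecularity`.
#' @export
rate_set <- function(network, values, unknown = character(), bounds = list()) {
  mol <- molecularity(network)
  missing <- setdiff(names(mol), names(values))
  if (length(missing))
    stop("rate values missing for: ", paste(missing, collapse = ", "))
  if (any(values < 0)) stop("rate values must be nonnegative")
  unknown <- as.character(unknown)
  bad <- setdiff(unknown, names(mol))
  if (length(bad)) stop("unknown rate names not in network: ",
                        paste(bad, collapse = ", "))
  b <- list()
  for (nm in unknown) {
    b[[nm]] <- if (!is.null(bounds[[nm]])) as.numeric(bounds[[nm]])
               else c(values[[nm]] / 1e4, values[[nm]] * 1e4)
    if (b[[nm]][1] <= 0 || b[[nm]][2] <= b[[nm]][1] || !all(is.finite(b[[nm]])))
      stop("invalid bounds for '", nm, "'")
    if (values[[nm]] < b[[nm]][1] || values[[nm]] > b[[nm]][2])
      stop("value of '", nm, "' outside its bounds")
  }
  structure(list(values = values[names(mol)],
                 known = setdiff(names(mol), unknown),
                 unknown = unknown, bounds = b, molecularity = mol),
            class = "kp_rates")
}

#' Replace some rate values
#' @param rates A `kp_rates`.
#' @param updates Named numeric vector of replacement values (interface units).
#' @return The updated `kp_rates`.
#' @export
update_rates <- function(rates, updates) {
  bad <- setdiff(names(updates), names(rates$values))
  if (length(bad)) stop("not rate names of this set: ", paste(bad, collapse = ", "))
  rates$values[names(updates)] <- updates
  rates
}

#' Mark rates as unknown fit targets
#' @param rates A `kp_rates`.
#' @param unknown Character vector of rate names.
#' @param bounds Optional named list of search ranges, as in [rate_set()].
#' @return The updated `kp_rates`.
#' @export
set_unknown <- function(rates, unknown, bounds = list()) {
  bad <- setdiff(unknown, names(rates$values))
  if (length(bad)) stop("not rate names of this set: ", paste(bad, collapse = ", "))
  rates$unknown <- as.character(unknown)
  rates$known <- setdiff(names(rates$values), rates$unknown)
  rates$bounds <- list()
  for (nm in rates$unknown) {
    rates$bounds[[nm]] <- if (!is.null(bounds[[nm]])) as.numeric(bounds[[nm]])
                          else c(rates$values[[nm]] / 1e4, rates$values[[nm]] * 1e4)
  }
  rates
}

## Internal nM-seconds values, ordered as network reactions.
internal_rate_vector <- function(network, rates) {
  rn <- vapply(network$reactions, `[[`, "", "rate")
  v <- rates$values[rn]
  if (anyNA(v)) stop("rates missing for: ",
                     paste(rn[is.na(v)], collapse = ", "))
  scale <- ifelse(rates$molecularity[rn] == 2L, 1e-9, 1)
  unname(v * scale)
}

## ---- study defaults --------------------------------------------------------

## Per-variant effective rate constants (M^-1 s^-1) encoding the qualitative
## orderings of the study: the matched monomer binds the template fastest,
## while proofreaders strip mismatched monomers 10-20x faster. Single-base
## discrimination enters only through these values, never structurally.
kp_variant_profiles <- list(
  M1 = c(k_bind = 2.0e5, k_unbind = 2.0e4, k_proof = 1.0e4, k_revproof = 1.0e2),
  M2 = c(k_bind = 2.0e4, k_unbind = 2.0e4, k_proof = 1.0e5, k_revproof = 1.0e2),
  M3 = c(k_bind = 1.0e4, k_unbind = 2.0e4, k_proof = 2.0e5, k_revproof = 1.0e2))

kp_snp_profiles <- list(
  TS   = c(k_bind = 2.0e5, k_proof = 1.0e4),
  SNP1 = c(k_bind = 1.3e5, k_proof = 5.0e4),
  SNP2 = c(k_bind = 1.1e5, k_proof = 7.0e4),
  SNP3 = c(k_bind = 9.0e4, k_proof = 9.0e4),
  SNP4 = c(k_bind = 8.0e4, k_proof = 1.2e5),
  SNP5 = c(k_bind = 1.2e5, k_proof = 6.0e4),
  SNP6 = c(k_bind = 1.0e5, k_proof = 8.0e4))

kp_shared_rates <- c(k_dimer = 3.5e5, k_rep = 5.0e4, k_leak = 2.0e1,
                     k_sink = 1.0e6, k_rep_snp = 1.0e4,
                     k_on = 1.0e6, k_off = 8.0e-2, k_disp = 2.0e-2,
                     k_redisp = 1.0e3)

#' Default ground-truth rate constants for a built-in network
#'
#' The study's fitted rate tables are not reproduced in the main text, so these
#' defaults are the package's own choices, fixed once: order-1e5 M^-1 s^-1
#' template binding for the matched variant with 10-20x slower binding for
#' mismatched variants, proofreading 10-20x faster for mismatched variants,
#' dimerization 3.5e5 M^-1 s^-1, and a deliberately slow SNP reporter.
#'
#' @param network A built-in `kp_network`.
#' @param variant Monomer variant profile ("M1", "M2", "M3") used for
#'   single-variant kinds, or candidate profile ("TS", "SNP1".."SNP6") for
#'   `snp_detection`.
#' @return A `kp_rates` with all rates known.
#' @export
default_true_rates <- function(network, variant = "M1") {
  mol <- molecularity(network)
  need <- names(mol)
  vals <- numeric(0)
  if (network$kind == "snp_detection") {
    prof <- kp_snp_profiles[[variant]]
    if (is.null(prof)) stop("unknown snp candidate profile: ", variant)
    base <- c(prof, k_unbind = 2.0e4, kp_shared_rates)
    base["k_rep"] <- kp_shared_rates[["k_rep_snp"]]
    vals <- base[need]
  } else if (network$kind == "dimerization" &&
             length(network$options$variants) > 1L) {
    for (v in network$options$variants) {
      prof <- kp_variant_profiles[[v]]
      if (is.null(prof)) stop("no profile for variant: ", v)
      pv <- c(prof, k_dimer = kp_shared_rates[["k_dimer"]],
              k_on = kp_shared_rates[["k_on"]], k_off = kp_shared_rates[["k_off"]],
              k_disp = kp_shared_rates[["k_disp"]],
              k_redisp = kp_shared_rates[["k_redisp"]])
      names(pv) <- paste0(names(pv), "_", v)
      vals <- c(vals, pv)
    }
    vals <- c(vals, kp_shared_rates)[need]
  } else {
    prof <- kp_variant_profiles[[variant]]
    if (is.null(prof)) stop("unknown variant profile: ", variant)
    vals <- c(prof, kp_shared_rates)[need]
  }
  if (anyNA(vals)) stop("no default for rates: ",
                        paste(need[is.na(vals)], collapse = ", "))
  names(vals) <- need
  rate_set(network, vals)
}

#' @export
print.kp_rates <- function(x, ...) {
  cat("<kp_rates>", length(x$values), "rates (",
      length(x$unknown), "unknown )\n")
  u <- ifelse(x$molecularity == 2L, "M^-1 s^-1", "s^-1")
  df <- data.frame(rate = names(x$values), value = unname(x$values),
                   unit = unname(u),
                   status = ifelse(names(x$values) %in% x$unknown,
                                   "unknown", "known"))
  print(df, row.names = FALSE)
  invisible(x)
}
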