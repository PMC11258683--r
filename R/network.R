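## Species names are complexes written by their constituent strands (ML = M + L).
## Reactions are elementary effective mass-action steps: uni- or bimolecular,
## with at most two products. Strand composition is the bookkeeping backbone:
## every reaction must conserve every strand, which yields one linear
## conservation law per strand and makes trajectory-level checks exact.

#' Create a species record
#'
#' A species is a strand complex: a unique name, the multiset of constituent
#' strands, and a set of role tags describing its function in the motif.
#'
#' @param name Species name, unique within a network.
#' @param strands Character vector of constituent strand identifiers (non-empty).
#' @param roles Character vector of role tags (e.g. "monomer", "template",
#'   "proofreader", "reporter", "waste", "product", "sink", "probe", "target",
#'   "blocker", "second_monomer", "quencher_product").
#' @return A list of class `kp_species`.
#' @export
kp_species <- function(name, strands, roles = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(strands) == 0L) stop("species '", name, "' has no constituent strands")
  structure(list(name = name, strands = as.character(strands),
                 roles = as.character(roles)),
            class = "kp_species")
}

#' Create a mass-action reaction
#'
#' @param reactants Character vector of 1 or 2 species names.
#' @param products Character vector of 1 or 2 species names.
#' @param rate Name of the rate constant in the accompanying rate set.
#' @param reverse Optional rate name of the reverse reaction (set on both
#'   members of a reversible pair by the builders).
#' @return A list of class `kp_reaction`.
#' @export
kp_reaction <- function(reactants, products, rate, reverse = NA_character_) {
  stopifnot(length(reactants) %in% 1:2, length(products) %in% 1:2,
            is.character(rate), length(rate) == 1L)
  structure(list(reactants = as.character(reactants),
                 products = as.character(products),
                 rate = rate, reverse = reverse),
            class = "kp_reaction")
}

new_network <- function(kind, species, reactions, options = list()) {
  nm <- vapply(species, function(s) s$name, "")
  if (anyDuplicated(nm)) stop("duplicate species names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  net <- structure(list(kind = kind, species = species, reactions = reactions,
                        options = options),
                   class = "kp_network")
  net
}

#' Species names of a network
#' @param network A `kp_network`.
#' @return Character vector of species names, in definition order.
#' @export
species_names <- function(network) {
  vapply(network$species, function(s) s$name, "")
}

#' Strand composition lookup
#' @param network A `kp_network`.
#' @return Named list mapping species name to its strand vector.
#' @export
strand_map <- function(network) {
  out <- lapply(network$species, function(s) s$strands)
  names(out) <- species_names(network)
  out
}

#' Net stoichiometry matrix
#'
#' @param network A `kp_network`.
#' @return Integer matrix, species (rows) by reactions (columns): products
#'   minus reactants.
#' @export
stoichiometry <- function(network) {
  sp <- species_names(network)
  S <- matrix(0L, nrow = length(sp), ncol = length(network$reactions),
              dimnames = list(sp, vapply(network$reactions, `[[`, "", "rate")))
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    for (x in r$reactants) S[x, j] <- S[x, j] - 1L
    for (x in r$products)  S[x, j] <- S[x, j] + 1L
  }
  S
}

#' Strand conservation vectors
#'
#' One vector per strand: the count of that strand in each species. Each is a
#' left null vector of the stoichiometry matrix for any strand-conserving
#' reaction set.
#'
#' @param network A `kp_network`.
#' @return Named list (by strand) of named integer vectors over species.
#' @export
conservation_vectors <- function(network) {
  sm <- strand_map(network)
  strands <- unique(unlist(sm))
  sp <- species_names(network)
  out <- lapply(strands, function(st) {
    v <- vapply(sp, function(s) sum(sm[[s]] == st), 0L)
    names(v) <- sp
    v
  })
  names(out) <- strands
  out
}

#' Validate a network
#'
#' Diagnostics, not exceptions: checks strand conservation of every reaction,
#' orphan species, and (when a rate set is supplied) unresolved rate names.
#'
#' @param network A `kp_network`.
#' @param rates Optional `kp_rates`; when given, every reaction's rate name
#'   must resolve in it.
#' @return A data frame with columns `type` and `detail`; zero rows when the
#'   network is clean.
#' @export
validate_network <- function(network, rates = NULL) {
  viol <- list()
  add <- function(type, detail) viol[[length(viol) + 1L]] <<- c(type, detail)
  sm <- strand_map(network)
  sp <- species_names(network)
  used <- character()
  for (r in network$reactions) {
    unknown <- setdiff(c(r$reactants, r$products), sp)
    if (length(unknown)) {
      add("unknown_species", paste0(r$rate, ": ", paste(unknown, collapse = ", ")))
      next
    }
    lhs <- sort(unname(unlist(sm[r$reactants])))
    rhs <- sort(unname(unlist(sm[r$products])))
    if (!identical(lhs, rhs))
      add("broken_conservation",
          paste0(r$rate, ": strands {", paste(lhs, collapse = ","),
                 "} -> {", paste(rhs, collapse = ","), "}"))
    used <- c(used, r$reactants, r$products)
  }
  orphan <- setdiff(sp, used)
  for (o in orphan) add("orphan_species", o)
  if (!is.null(rates)) {
    rn <- vapply(network$reactions, `[[`, "", "rate")
    missing <- setdiff(rn, names(rates$values))
    for (m in missing) add("unresolved_rate", m)
  }
  if (length(viol) == 0L)
    return(data.frame(type = character(), detail = character(),
                      stringsAsFactors = FALSE))
  m <- do.call(rbind, viol)
  data.frame(type = m[, 1], detail = m[, 2], stringsAsFactors = FALSE)
}

## ---- builders --------------------------------------------------------------

kp_kinds <- c("template_binding", "template_recovery", "full_discard",
              "dimerization", "snp_detection")

#' Build one of the study networks
#'
#' Builders for the five strand-displacement motifs: template binding
#' (ML + T <-> MT + L), template recovery (proofreading MT + P <-> MP + T with
#' a waste reporter), the full discard pathway (their union), templated
#' dimerization via HMSD (with optional proofreader and reporter leak), and the
#' SNP-detection probe network (probe + proofreader + sink).
#'
#' TMSD/HMSD steps are modeled as single effective bimolecular reactions;
#' `two_step = TRUE` replaces template binding with an explicit transient
#' MLT intermediate (ML + T <-> MLT <-> MT + L) for sensitivity analysis.
#'
#' @param kind One of `"template_binding"`, `"template_recovery"`,
#'   `"full_discard"`, `"dimerization"`, `"snp_detection"`.
#' @param reversible Keep the reverse of the template-binding (and probe
#'   binding) exchange. Proofreading is always reversible; reporter, HMSD
#'   dimerization and sink steps are always irreversible.
#' @param leak Add the direct monomer-reporter (or probe-reporter) leak
#'   reaction; only valid for kinds that contain a reporter.
#' @param two_step Use the explicit two-step template-binding variant.
#' @param variants For `kind = "dimerization"` only: character vector of
#'   monomer variant prefixes. The default `"M"` builds the single-variant
#'   network with plain names (ML, MT, ...); `c("M1","M2","M3")` builds the
#'   competitive-pool network sharing T, P, N and the reporter, with
#'   per-variant species (M1L, ...) and rate names (k_bind_M1, ...).
#' @return A validated `kp_network`.
#' @export
build_network <- function(kind, reversible = TRUE, leak = FALSE,
                          two_step = FALSE, variants = "M") {
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% kp_kinds))
    stop("unknown network kind: ", paste(kind, collapse = ","),
         " (expected one of ", paste(kp_kinds, collapse = ", "), ")")
  has_reporter <- kind %in% c("template_recovery", "full_discard",
                              "dimerization", "snp_detection")
  if (leak && !has_reporter)
    stop("option 'leak' requires a reporter in the network; kind '", kind,
         "' has none")
  if (two_step && !(kind %in% c("template_binding", "full_discard", "dimerization")))
    stop("option 'two_step' applies only to networks containing template binding; ",
         "kind '", kind, "' does not")
  if (!identical(variants, "M") && kind != "dimerization")
    stop("option 'variants' applies only to kind 'dimerization'")
  net <- switch(kind,
    template_binding  = net_template_binding(reversible, two_step),
    template_recovery = net_template_recovery(leak),
    full_discard      = net_full_discard(reversible, leak, two_step),
    dimerization      = net_dimerization(reversible, leak, two_step, variants),
    snp_detection     = net_snp_detection(reversible, leak))
  bad <- validate_network(net)
  if (nrow(bad)) stop("internal builder error: ", paste(bad$detail, collapse = "; "))
  net
}

binding_block <- function(reversible, two_step, prefix = "M",
                          suffix = "") {
  ML  <- paste0(prefix, "L"); MT <- paste0(prefix, "T")
  MLT <- paste0(prefix, "LT")
  rn <- function(b) paste0(b, suffix)
  if (!two_step) {
    rx <- list(kp_reaction(c(ML, "T"), c(MT, "L"), rn("k_bind"),
                           if (reversible) rn("k_unbind") else NA_character_))
    if (reversible)
      rx <- c(rx, list(kp_reaction(c(MT, "L"), c(ML, "T"), rn("k_unbind"),
                                   rn("k_bind"))))
    list(species = list(), reactions = rx)
  } else {
    rx <- list(
      kp_reaction(c(ML, "T"), MLT, rn("k_on"), rn("k_off")),
      kp_reaction(MLT, c(ML, "T"), rn("k_off"), rn("k_on")),
      kp_reaction(MLT, c(MT, "L"), rn("k_disp"),
                  if (reversible) rn("k_redisp") else NA_character_))
    if (reversible)
      rx <- c(rx, list(kp_reaction(c(MT, "L"), MLT, rn("k_redisp"), rn("k_disp"))))
    list(species = list(kp_species(MLT, c(prefix, "L", "T"), "monomer")),
         reactions = rx)
  }
}

net_template_binding <- function(reversible, two_step) {
  species <- list(
    kp_species("ML", c("M", "L"), c("monomer", "blocker")),
    kp_species("T",  "T", "template"),
    kp_species("MT", c("M", "T"), c("monomer", "template")),
    kp_species("L",  "L", "blocker"))
  blk <- binding_block(reversible, two_step)
  new_network("template_binding", c(species, blk$species), blk$reactions,
              list(reversible = reversible, two_step = two_step))
}

recovery_block <- function(prefix = "M", suffix = "") {
  MT <- paste0(prefix, "T"); MP <- paste0(prefix, "P")
  rn <- function(b) paste0(b, suffix)
  list(kp_reaction(c(MT, "P"), c(MP, "T"), rn("k_proof"), rn("k_revproof")),
       kp_reaction(c(MP, "T"), c(MT, "P"), rn("k_revproof"), rn("k_proof")))
}

net_template_recovery <- function(leak) {
  species <- list(
    kp_species("MT",  c("M", "T"), c("monomer", "template")),
    kp_species("P",   "P", "proofreader"),
    kp_species("MP",  c("M", "P"), c("monomer", "waste")),
    kp_species("T",   "T", "template"),
    kp_species("RQ",  c("R", "Q"), "reporter"),
    kp_species("MPR", c("M", "P", "R"), c("waste", "reporter")),
    kp_species("Q",   "Q", "quencher_product"))
  rx <- c(recovery_block(),
          list(kp_reaction(c("MP", "RQ"), c("MPR", "Q"), "k_rep")))
  if (leak)
    rx <- c(rx, list(kp_reaction(c("MT", "RQ"), c("MTR", "Q"), "k_leak")))
  if (leak)
    species <- c(species, list(kp_species("MTR", c("M", "T", "R"),
                                          c("monomer", "reporter"))))
  new_network("template_recovery", species, rx, list(leak = leak))
}

net_full_discard <- function(reversible, leak, two_step) {
  species <- list(
    kp_species("ML",  c("M", "L"), c("monomer", "blocker")),
    kp_species("T",   "T", "template"),
    kp_species("MT",  c("M", "T"), c("monomer", "template")),
    kp_species("L",   "L", "blocker"),
    kp_species("P",   "P", "proofreader"),
    kp_species("MP",  c("M", "P"), c("monomer", "waste")),
    kp_species("RQ",  c("R", "Q"), "reporter"),
    kp_species("MPR", c("M", "P", "R"), c("waste", "reporter")),
    kp_species("Q",   "Q", "quencher_product"))
  blk <- binding_block(reversible, two_step)
  rx <- c(blk$reactions, recovery_block(),
          list(kp_reaction(c("MP", "RQ"), c("MPR", "Q"), "k_rep")))
  if (leak) {
    species <- c(species, list(kp_species("MLR", c("M", "L", "R"),
                                          c("monomer", "reporter"))))
    rx <- c(rx, list(kp_reaction(c("ML", "RQ"), c("MLR", "Q"), "k_leak")))
  }
  new_network("full_discard", c(species, blk$species), rx,
              list(reversible = reversible, leak = leak, two_step = two_step))
}

net_dimerization <- function(reversible, leak, two_step, variants) {
  multi <- length(variants) > 1L
  sfx <- function(v) if (multi) paste0("_", v) else ""
  species <- list(
    kp_species("T", "T", "template"),
    kp_species("L", "L", "blocker"),
    kp_species("P", "P", "proofreader"),
    kp_species("N", "N", "second_monomer"),
    kp_species("RQ", c("R", "Q"), "reporter"),
    kp_species("Q", "Q", "quencher_product"))
  rx <- list()
  for (v in variants) {
    s <- sfx(v)
    species <- c(species, list(
      kp_species(paste0(v, "L"), c(v, "L"), c("monomer", "blocker")),
      kp_species(paste0(v, "T"), c(v, "T"), c("monomer", "template")),
      kp_species(paste0(v, "P"), c(v, "P"), c("monomer", "waste")),
      kp_species(paste0(v, "N"), c(v, "N"), "product"),
      kp_species(paste0(v, "NR"), c(v, "N", "R"), c("product", "reporter"))))
    blk <- binding_block(reversible, two_step, prefix = v, suffix = s)
    species <- c(species, blk$species)
    rx <- c(rx, blk$reactions, recovery_block(prefix = v, suffix = s),
            list(kp_reaction(c(paste0(v, "T"), "N"), c(paste0(v, "N"), "T"),
                             paste0("k_dimer", s)),
                 kp_reaction(c(paste0(v, "N"), "RQ"),
                             c(paste0(v, "NR"), "Q"), "k_rep")))
    if (leak) {
      species <- c(species, list(kp_species(paste0(v, "LR"), c(v, "L", "R"),
                                            c("monomer", "reporter"))))
      rx <- c(rx, list(kp_reaction(c(paste0(v, "L"), "RQ"),
                                   c(paste0(v, "LR"), "Q"), "k_leak")))
    }
  }
  new_network("dimerization", species, rx,
              list(reversible = reversible, leak = leak, two_step = two_step,
                   variants = variants))
}

net_snp_detection <- function(reversible, leak) {
  species <- list(
    kp_species("PL",   c("Probe", "Lock"), c("probe", "blocker")),
    kp_species("X",    "X", "target"),
    kp_species("XP",   c("X", "Probe"), c("target", "probe")),
    kp_species("Lock", "Lock", "blocker"),
    kp_species("RQ",   c("R", "Q"), "reporter"),
    kp_species("XPR",  c("X", "Probe", "R"), c("product", "reporter")),
    kp_species("Q",    "Q", "quencher_product"),
    kp_species("Psnp", "Psnp", "proofreader"),
    kp_species("W",    c("Probe", "Psnp"), "waste"),
    kp_species("Sink", "Sink", "sink"),
    kp_species("WS",   c("Probe", "Psnp", "Sink"), c("waste", "sink")))
  rx <- list(kp_reaction(c("PL", "X"), c("XP", "Lock"), "k_bind",
                         if (reversible) "k_unbind" else NA_character_))
  if (reversible)
    rx <- c(rx, list(kp_reaction(c("XP", "Lock"), c("PL", "X"), "k_unbind",
                                 "k_bind")))
  rx <- c(rx, list(
    kp_reaction(c("XP", "RQ"), c("XPR", "Q"), "k_rep"),
    kp_reaction(c("XP", "Psnp"), c("W", "X"), "k_proof"),
    kp_reaction(c("W", "Sink"), "WS", "k_sink")))
  if (leak) {
    species <- c(species, list(kp_species("PLR", c("Probe", "Lock", "R"),
                                          c("probe", "reporter"))))
    rx <- c(rx, list(kp_reaction(c("PL", "RQ"), c("PLR", "Q"), "k_leak")))
  }
  new_network("snp_detection", species, rx,
              list(reversible = reversible, leak = leak))
}

#' @export
print.kp_network <- function(x, ...) {
  cat("<kp_network> kind:", x$kind, "\n")
  cat(" ", length(x$species), "species:",
      paste(species_names(x), collapse = ", "), "\n")
  cat(" ", length(x$reactions), "reactions:\n")
  for (r in x$reactions)
    cat("   ", paste(r$reactants, collapse = " + "), "->",
        paste(r$products, collapse = " + "), " @", r$rate, "\n")
  invisible(x)
}
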