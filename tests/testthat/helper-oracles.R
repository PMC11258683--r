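# Independent oracles used across the suite.

# Stationary distribution of a finite CTMC via the Markov-chain tree theorem:
# pi(i) is proportional to the sum over spanning trees rooted at i of the
# product of edge rates directed toward the root. Brute-force enumeration;
# independent of the linear-algebra route in the package.
stationary_tree <- function(Q) {
  n <- nrow(Q)
  w <- numeric(n)
  for (root in seq_len(n)) {
    others <- setdiff(seq_len(n), root)
    choices <- lapply(others, function(i) which(Q[i, ] > 0 & seq_len(n) != i))
    if (any(vapply(choices, length, 0L) == 0L)) next
    grid <- as.matrix(expand.grid(choices))
    total <- 0
    for (g in seq_len(nrow(grid))) {
      parent <- rep(NA_integer_, n)
      parent[others] <- grid[g, ]
      ok <- TRUE
      for (i in others) {
        cur <- i
        steps <- 0L
        while (cur != root) {
          cur <- parent[cur]
          steps <- steps + 1L
          if (is.na(cur) || steps > n) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) total <- total + prod(Q[cbind(others, grid[g, ])])
    }
    w[root] <- total
  }
  if (sum(w) <= 0) stop("no spanning trees: chain not irreducible")
  w / sum(w)
}

# Exact solution of the irreversible bimolecular reaction A + B -> C
# (A0 != B0), in nM with k in nM^-1 s^-1.
bimolecular_closed_form <- function(A0, B0, k, t) {
  d <- B0 - A0
  A0 * d / (B0 * exp(d * k * t) - A0)
}

# Minimal single-reaction networks for engine tests.
make_ab_network <- function() {
  new_net <- kproof:::new_network
  new_net("template_binding",
          list(kp_species("A", "a"), kp_species("B", "b"),
               kp_species("C", c("a", "b"))),
          list(kp_reaction(c("A", "B"), "C", "k")))
}

make_decay_network <- function() {
  kproof:::new_network("template_binding",
                       list(kp_species("A", "a"), kp_species("B", "a")),
                       list(kp_reaction("A", "B", "k")))
}

# Preset simulation conditions for each built-in network, used by the
# conservation / convergence / SSA-equivalence loops.
network_conditions <- function() {
  list(
    template_binding = list(net = build_network("template_binding"),
                            variant = "M1",
                            init = c(ML = 8, T = 10), t_end = 7200),
    template_recovery = list(net = build_network("template_recovery"),
                             variant = "M1",
                             init = c(MT = 8, P = 50, RQ = 20), t_end = 14400),
    full_discard = list(net = build_network("full_discard"), variant = "M1",
                        init = c(ML = 8, T = 4, P = 50, RQ = 20),
                        t_end = 28800),
    dimerization = list(net = build_network("dimerization"), variant = "M1",
                        init = c(ML = 8, N = 10, P = 50, RQ = 20, T = 2),
                        t_end = 20000),
    snp_detection = list(net = build_network("snp_detection"), variant = "TS",
                         init = c(X = 15, RQ = 20, Sink = 20, Psnp = 20,
                                  PL = 10), t_end = 20000))
}
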