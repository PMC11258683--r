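test_that("every builder yields a conservation-clean, deterministic network", {
  builds <- list(
    build_network("template_binding"),
    build_network("template_binding", reversible = FALSE),
    build_network("template_binding", two_step = TRUE),
    build_network("template_recovery"),
    build_network("full_discard"),
    build_network("full_discard", leak = TRUE),
    build_network("dimerization"),
    build_network("dimerization", leak = TRUE),
    build_network("dimerization", variants = c("M1", "M2", "M3")),
    build_network("snp_detection"),
    build_network("snp_detection", leak = TRUE))
  for (net in builds) {
    expect_equal(nrow(validate_network(net)), 0)
    # exhaustive integer check: every strand vector is a left null vector of S
    S <- stoichiometry(net)
    for (v in conservation_vectors(net))
      expect_true(all(as.integer(v %*% S) == 0L))
    # no orphan species
    used <- unique(unlist(lapply(net$reactions,
                                 function(r) c(r$reactants, r$products))))
    expect_setequal(species_names(net), used)
  }
  expect_identical(build_network("full_discard"), build_network("full_discard"))
  expect_identical(build_network("snp_detection"), build_network("snp_detection"))
})

test_that("built networks have the expected reaction-group structure", {
  # one reversible pair; dropping reversibility leaves a single reaction
  tb <- build_network("template_binding")
  expect_length(tb$reactions, 2)
  expect_equal(tb$reactions[[1]]$reverse, "k_unbind")
  expect_length(build_network("template_binding", reversible = FALSE)$reactions, 1)

  # full discard: binding + proofreading reversible pairs plus the reporter
  fd <- build_network("full_discard")
  n_groups <- function(net) {
    rev_named <- vapply(net$reactions, function(r) !is.na(r$reverse), TRUE)
    length(net$reactions) - sum(rev_named) / 2
  }
  expect_equal(n_groups(fd), 3)
  expect_setequal(names(conservation_vectors(fd)),
                  c("M", "L", "T", "P", "R", "Q"))

  # snp network: binding, reporter, proofreading, sink
  expect_equal(n_groups(build_network("snp_detection")), 4)

  # two-step variant introduces the transient MLT intermediate
  ts <- build_network("template_binding", two_step = TRUE)
  expect_true("MLT" %in% species_names(ts))
})

test_that("option validation rejects inconsistent requests", {
  expect_error(build_network("nonsense"), "unknown network kind")
  expect_error(build_network("template_binding", leak = TRUE), "leak")
  expect_error(build_network("template_recovery", two_step = TRUE), "two_step")
  expect_error(build_network("snp_detection", variants = c("A", "B")),
               "variants")
})

test_that("validate_network reports violations as diagnostics", {
  # a reaction that deletes the blocker strand
  broken <- kproof:::new_network(
    "template_binding",
    list(kp_species("ML", c("M", "L")), kp_species("M", "M")),
    list(kp_reaction("ML", "M", "k_lose")))
  rep <- validate_network(broken)
  expect_true("broken_conservation" %in% rep$type)
  expect_match(rep$detail[rep$type == "broken_conservation"], "k_lose")

  # orphan species
  orphaned <- kproof:::new_network(
    "template_binding",
    list(kp_species("A", "a"), kp_species("B", "a"), kp_species("Z", "z")),
    list(kp_reaction("A", "B", "k")))
  expect_true("orphan_species" %in% validate_network(orphaned)$type)

  # unresolved rate name against a rate set missing an entry
  fd <- build_network("full_discard")
  rates <- default_true_rates(fd, "M1")
  rates$values <- rates$values[setdiff(names(rates$values), "k_rep")]
  rep2 <- validate_network(fd, rates)
  expect_true(any(rep2$type == "unresolved_rate" & rep2$detail == "k_rep"))
})

test_that("rate sets enforce units, bounds and the known/unknown partition", {
  net <- build_network("template_binding")
  expect_error(rate_set(net, c(k_bind = 1e5)), "k_unbind")
  r <- rate_set(net, c(k_bind = 2e5, k_unbind = 2e4))
  expect_setequal(r$known, c("k_bind", "k_unbind"))
  expect_equal(r$molecularity, c(k_bind = 2L, k_unbind = 2L))
  # internal conversion: bimolecular rates scaled to nM^-1 s^-1
  expect_equal(kproof:::internal_rate_vector(net, r), c(2e5, 2e4) * 1e-9)
  r2 <- set_unknown(r, "k_bind", list(k_bind = c(1e2, 1e8)))
  expect_equal(r2$unknown, "k_bind")
  expect_equal(r2$known, "k_unbind")
  expect_error(rate_set(net, c(k_bind = -1, k_unbind = 1)), "nonnegative")
  expect_error(set_unknown(r, "k_missing"), "not rate names")
})
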