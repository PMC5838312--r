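# network_core: data model, validation, S matrix, I/O round trips, and the
# packaged reduced network's structural invariants.

test_that("construction, validation and the stoichiometric matrix behave", {
  mets <- rbind(metabolite("A"), metabolite("B"), metabolite("C"))
  net <- metabolic_network(mets, list(
    reaction("R1", c(A = -1, B = 1)),
    reaction("R2", c(A = -1, B = -1, C = 2))), objective_id = "R2")
  S <- stoichiometric_matrix(net)
  expect_equal(unname(S[, "R1"]), c(-1, 1, 0))
  expect_equal(unname(S[, "R2"]), c(-1, -1, 2))
  expect_equal(dim(S), c(3L, 2L))

  # findings, not errors
  bad <- net
  bad$reactions[["R1"]]$lower_bound <- 2000
  f <- validate_network(bad)
  expect_true(any(grepl("lower_bound > upper_bound", f$message)))
  dup <- net
  dup$reactions[["R3"]] <- dup$reactions[["R1"]]
  dup$reactions[["R3"]]$id <- "R1"
  expect_true(any(grepl("duplicate reaction id", validate_network(dup)$message)))

  # dangling metabolite reference is a constructor error naming the offender
  expect_error(metabolic_network(mets, list(reaction("RX", c(X = 1))),
                                 objective_id = "RX"), "X")
  # default bounds
  expect_equal(reaction("r", c(A = 1))$lower_bound, 0)
  expect_equal(reaction("r", c(A = 1), reversible = TRUE)$lower_bound, -1000)
})

test_that("round trips are lossless in all three formats", {
  net <- load_reduced_oeni_model()
  # unicode survives too
  net$metabolites$name[net$metabolites$id == "mnl_e"] <- "D-mannitol (μmol·test)"
  for (fmt in c("json", "tsv", "sbml")) {
    path <- file.path(tempdir(), paste0("rt_", fmt,
                                        if (fmt == "tsv") "" else paste0(".", fmt)))
    write_network(net, path, fmt)
    n2 <- read_network(path, fmt)
    expect_identical(stoichiometric_matrix(net), stoichiometric_matrix(n2),
                     info = fmt)
    expect_equal(lapply(net$reactions, `[[`, "lower_bound"),
                 lapply(n2$reactions, `[[`, "lower_bound"), info = fmt)
    expect_equal(lapply(net$reactions, `[[`, "role_tags"),
                 lapply(n2$reactions, `[[`, "role_tags"), info = fmt)
    expect_identical(net$objective_id, n2$objective_id, info = fmt)
    expect_identical(net$metabolites$name, n2$metabolites$name, info = fmt)
  }
})

test_that("minimal JSON reads with defaulted bounds and errors name offenders", {
  p <- file.path(tempdir(), "mini.json")
  writeLines('{"name":"mini","objective_id":"R1",
    "metabolites":[{"id":"A"},{"id":"B"}],
    "reactions":[{"id":"R1","stoichiometry":{"A":-1,"B":1}}]}', p)
  net <- read_network(p, "json")
  expect_equal(length(net$reactions), 1L)
  expect_equal(net$reactions[["R1"]]$lower_bound, 0)
  expect_equal(net$reactions[["R1"]]$upper_bound, 1000)

  pbad <- file.path(tempdir(), "bad.json")
  writeLines('{"name":"x","objective_id":"R1",
    "metabolites":[{"id":"A"}],
    "reactions":[{"id":"R1","stoichiometry":{"X":-1}}]}', pbad)
  expect_error(read_network(pbad, "json"), "X")
  ppar <- file.path(tempdir(), "parse.json")
  writeLines('{"name": oops', ppar)
  expect_error(read_network(ppar, "json"), "parse")
})

test_that("the packaged reduced network satisfies its structural contract", {
  net <- load_reduced_oeni_model()
  expect_identical(validate_network(net)$message, character(0))
  subs <- unique(vapply(net$reactions, function(r) r$subsystem, character(1)))
  for (s in c("phosphoketolase", "MLF", "citrate_degradation",
              "fructose_reduction", "ATPase", "NGAM", "aa_degradation",
              "exchange", "transport"))
    expect_true(s %in% subs, info = s)

  # MLF: at least one reaction consuming L-malate and producing L-lactate
  mlf <- reactions_by_subsystem(net, "MLF")
  hit <- vapply(mlf, function(id) {
    st <- net$reactions[[id]]$stoichiometry
    isTRUE(st["mal_c"] < 0) && isTRUE(st["llac_c"] > 0)
  }, logical(1))
  expect_true(any(hit))

  # the three substrate-level kinases carry the PKP ATP tag, exactly
  expect_setequal(reactions_by_role(net, "atp_producer_pkp"),
                  c("ACK", "PYK", "PGK"))
  expect_setequal(reactions_by_role(net, "atp_producer_f0f1"), "ATPS")

  # S matrix: exchange columns have exactly one nonzero
  S <- stoichiometric_matrix(net)
  for (id in reactions_by_subsystem(net, "exchange"))
    expect_equal(sum(S[, id] != 0), 1L, info = id)

  # every internal (cytosolic) metabolite both produced and consumed
  lb <- vapply(net$reactions, function(r) r$lower_bound, numeric(1))
  cyto <- net$metabolites$id[net$metabolites$compartment == "c"]
  for (m in cyto) {
    row <- S[m, ]
    can_prod <- any(row > 0) || any(row < 0 & lb < 0)
    can_cons <- any(row < 0) || any(row > 0 & lb < 0)
    expect_true(can_prod && can_cons, info = m)
  }

  # carbon balance of all non-exchange, non-biomass reactions
  cmap <- setNames(vapply(net$metabolites$formula, carbon_count, numeric(1)),
                   net$metabolites$id)
  for (r in net$reactions) {
    if (r$subsystem %in% c("exchange", "biomass")) next
    if (length(r$stoichiometry) == 1) next   # boundary drains (demands)
    bal <- sum(r$stoichiometry * cmap[names(r$stoichiometry)])
    expect_equal(bal, 0, tolerance = 1e-9, info = r$id)
  }

  # closed system: zero flux everywhere
  closed <- net
  for (id in reactions_by_subsystem(net, "exchange"))
    closed <- set_bounds(closed, id, 0, 0)
  sol <- solve_fba(closed)
  expect_equal(sol$objective_value, 0, tolerance = 1e-9)
  expect_lt(max(abs(sol$fluxes)), 1e-9)

  # the shipped JSON copy is in sync with the constructor
  p <- system.file("extdata", "oeni_reduced.json", package = "oenoflux")
  expect_identical(stoichiometric_matrix(read_network(p)),
                   stoichiometric_matrix(load_reduced_oeni_model()))
})
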