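# efm: enumeration correctness against a support-subset oracle, and the
# substrate-product table's structure on the packaged network.

test_that("chains give one mode, diamonds two", {
  expect_length(enumerate_efms(toy_chain()), 1L)
  mets <- rbind(metabolite("Ae", "", "e"), metabolite("A"), metabolite("B"),
                metabolite("Be", "", "e"))
  diamond <- metabolic_network(mets, list(
    reaction("EX_A", c(Ae = -1), lower_bound = -10, upper_bound = 0,
             subsystem = "exchange"),
    reaction("T1", c(Ae = -1, A = 1)),
    reaction("R1", c(A = -1, B = 1)),
    reaction("R2", c(A = -1, B = 1)),
    reaction("T2", c(B = -1, Be = 1)),
    reaction("EX_B", c(Be = -1), subsystem = "exchange")),
    objective_id = "EX_B")
  m <- enumerate_efms(diamond)
  expect_length(m, 2L)
  expect_false(identical(m[[1]]$support, m[[2]]$support))
})

test_that("every returned mode is a steady-state, sign-feasible, support-minimal vector", {
  set.seed(23)
  for (i in 1:10) {
    net <- random_toy_network(n_met = sample(2:4, 1), n_rxn = sample(5:8, 1))
    modes <- enumerate_efms(net)
    if (!length(modes)) next
    pruned <- oenoflux:::prune_network(net)
    S <- stoichiometric_matrix(pruned)
    lb <- vapply(pruned$reactions, function(r) r$lower_bound, numeric(1))
    supports <- lapply(modes, function(m) m$support)
    for (m in modes) {
      v <- m$coefficients
      expect_lt(max(abs(S %*% v)), 1e-9 * max(1, max(abs(v))))
      expect_true(all(v[lb >= 0] >= -1e-9))
      expect_equal(min(abs(v[abs(v) > 1e-9])), 1, tolerance = 1e-9)
    }
    # pairwise support non-inclusion
    for (a in seq_along(supports)) for (b in seq_along(supports)) {
      if (a != b)
        expect_false(all(supports[[a]] %in% supports[[b]]) &&
                     length(supports[[a]]) < length(supports[[b]]))
    }
  }
})

test_that("enumeration agrees with the exhaustive support-subset oracle", {
  set.seed(101)
  n_checked <- 0
  while (n_checked < 20) {
    net <- random_toy_network(n_met = sample(2:3, 1), n_rxn = sample(4:7, 1))
    pruned <- oenoflux:::prune_network(net)
    if (length(pruned$reactions) < 2 || length(pruned$reactions) > 8) next
    got <- enumerate_efms(net)
    ref <- oracle_efms(pruned)
    lb <- vapply(pruned$reactions, function(r) r$lower_bound, numeric(1))
    got_keys <- sort(vapply(got, function(m)
      norm_mode(canon_orient(m$coefficients, lb)), character(1)))
    ref_keys <- sort(vapply(ref, function(v)
      norm_mode(canon_orient(v, lb)), character(1)))
    expect_identical(got_keys, ref_keys,
                     info = paste("network", n_checked + 1))
    n_checked <- n_checked + 1
  }
})

test_that("the packaged substrate-product table shows the published structure", {
  tab <- get_efm_table()
  # L-lactate only from L-malate
  expect_true(all(tab[setdiff(rownames(tab), "L-malate"), "L-lactate"] == 0))
  expect_gt(tab["L-malate", "L-lactate"], 0)
  # the malate row: D- and L-lactate only, two modes each
  expect_equal(unname(tab["L-malate", ]), c(0, 2, 2, 0, 0, 0, 0))
  # citrate: diacetyl and acetate, two modes each
  expect_equal(unname(tab["Citrate", c("Diacetyl", "Acetate")]), c(2, 2))
  expect_true(all(tab["Citrate", c("D-mannitol", "D-lactate", "L-lactate",
                                   "Ethanol", "Erythritol")] == 0))
  # amino acids: diacetyl, but never polyols (nor anything else)
  for (aa in c("L-cysteine", "L-serine", "L-threonine")) {
    expect_gt(tab[aa, "Diacetyl"], 0)
    expect_true(all(tab[aa, c("D-mannitol", "Erythritol", "D-lactate",
                              "L-lactate", "Ethanol", "Acetate")] == 0))
  }
  # sugars can make everything but L-lactate (and, in this reconstruction,
  # glucose cannot make mannitol: the mannitol-1P shunt is deliberately
  # absent — see the methods vignette)
  expect_true(all(tab["D-fructose", setdiff(colnames(tab), "L-lactate")] > 0))
  expect_true(all(tab["D-glucose",
                      setdiff(colnames(tab),
                              c("L-lactate", "D-mannitol"))] > 0))
  expect_equal(unname(tab["D-fructose", "L-lactate"]), 0)
  expect_equal(unname(tab["D-glucose", "L-lactate"]), 0)
  expect_equal(unname(tab["D-glucose", "D-mannitol"]), 0)
  # an unreachable product scores zero
  net <- toy_chain()
  t2 <- substrate_product_table(net, substrates = c(A = "EX_A"),
                                products = c(B = "EX_B"))
  expect_equal(unname(t2["A", "B"]), 1L)
})
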