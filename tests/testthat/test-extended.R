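# extended_model: Z-matrix construction, constraint application,
# accumulation FVA and phase splitting.

test_that("the dimension law d = n_phases*m + (n_phases-1)*c holds", {
  base <- get_base_model()
  n <- nrow(base$metabolites); m <- length(base$reactions)
  ext <- build_extended_model(base, 3)
  Z <- stoichiometric_matrix(ext$network)
  expect_equal(nrow(Z), 3 * n)
  expect_equal(ncol(Z), 3 * m + 2 * 6)

  # degenerate stacking: one phase is just S
  e1 <- build_extended_model(base, 1)
  expect_equal(dim(stoichiometric_matrix(e1$network)), c(n, m))
  expect_null(e1$accumulation)

  # random toy networks
  set.seed(11)
  for (i in 1:8) {
    toy <- random_toy_network(n_met = 3, n_rxn = 5)
    np <- sample(2:4, 1)
    comp <- c(x = "M1")
    ez <- build_extended_model(toy, np, comp)
    expect_equal(dim(stoichiometric_matrix(ez$network)),
                 c(np * 3, np * 5 + (np - 1) * 1))
  }
  expect_error(build_extended_model(base, 3, c(foo = "not_a_met")),
               "not_a_met")
})

test_that("a 2-phase toy Z matrix matches hand construction column by column", {
  mets <- rbind(metabolite("A"), metabolite("B"), metabolite("C"))
  toy <- metabolic_network(mets, list(
    reaction("U", c(A = 1)),
    reaction("R1", c(A = -1, B = 1)),
    reaction("R2", c(B = -1, C = 1)),
    reaction("D", c(C = -1))), objective_id = "D")
  ext <- build_extended_model(toy, 2, c(b = "B"))
  Z <- stoichiometric_matrix(ext$network)
  expect_equal(dim(Z), c(6L, 9L))
  S <- stoichiometric_matrix(toy)
  expect_equal(unname(Z[1:3, 1:4]), unname(S))       # phase-1 block
  expect_equal(unname(Z[4:6, 5:8]), unname(S))       # phase-2 block
  expect_true(all(Z[4:6, 1:4] == 0))
  expect_true(all(Z[1:3, 5:8] == 0))
  acc <- Z[, "ACC_b_1to2"]
  expect_equal(unname(acc[c("B_p1", "B_p2")]), c(-1, 1))
  expect_equal(sum(acc != 0), 2L)
})

test_that("constraints map to phase copies and zero constraints stay feasible", {
  base <- get_base_model()
  ext <- build_extended_model(base, 3)
  reg <- measured_metabolites()
  zero <- lapply(1:3, function(k)
    constraint_set(k, setNames(rep(0, nrow(reg)), reg$exchange_id),
                   biomass = 0))
  extc <- apply_experimental_constraints(ext, zero)
  expect_equal(extc$network$reactions[["EX_glc_p2"]]$upper_bound, 0)
  sol <- solve_fba(extc$network, "BIOMASS_p1", "max")
  expect_equal(sol$objective_value, 0, tolerance = 1e-9)
})

test_that("a contradictory rate produces an infeasibility report naming a culprit", {
  base <- get_base_model()
  ext <- build_extended_model(base, 3)
  reg <- measured_metabolites()
  ff <- setNames(rep(0, nrow(reg)), reg$exchange_id)
  ff1 <- ff; ff1[["EX_mnl"]] <- 5   # phase-1 product made from nothing
  bad <- c(list(constraint_set(1, ff1, biomass = 0)),
           lapply(2:3, function(k) constraint_set(k, ff, biomass = 0)))
  extb <- apply_experimental_constraints(ext, bad)
  hits <- diagnose_infeasibility(extb)
  expect_true(any(grepl("EX_mnl", hits)))
  expect_error(fva_accumulation(extb), "EX_mnl")
})

test_that("accumulation FVA spans contain the generator carry-over and tighten with tolerance", {
  w <- get_world(0)
  ab <- w$bounds
  truth <- w$sim$truth$accumulation
  for (i in seq_len(nrow(ab))) {
    a_star <- truth[ab$compound[i], ab$from_phase[i]]
    expect_gte(a_star, ab$min[i] - 1e-6)
    expect_lte(a_star, ab$max[i] + 1e-6)
  }
  # spans widen weakly as the tolerance on fixed fluxes grows
  base <- get_base_model()
  css_tol <- lapply(w$css, function(cs) { cs$tolerance <- 0.025; cs })
  ext2 <- apply_experimental_constraints(build_extended_model(base, 3), css_tol)
  ab2 <- fva_accumulation(ext2)
  expect_true(all(ab2$min <= ab$min + 1e-7))
  expect_true(all(ab2$max >= ab$max - 1e-7))
})

test_that("phase splitting adds the right boundary reactions and preserves feasibility", {
  w <- get_world(0)
  nets <- w$nets
  # phase II: 6 sinks + 6 demands
  ids2 <- reaction_ids(nets[[2]])
  expect_equal(sum(grepl("^ACCS_", ids2)), 6L)
  expect_equal(sum(grepl("^ACCD_", ids2)), 6L)
  expect_equal(sum(grepl("^ACCS_", reaction_ids(nets[[1]]))), 0L)
  expect_equal(sum(grepl("^ACCD_", reaction_ids(nets[[3]]))), 0L)
  # restriction soundness: the extended witness restricts to feasible blocks
  for (k in 1:3) {
    net <- apply_constraint_set(nets[[k]], w$css[[k]])
    sol <- solve_fba(net, "BIOMASS", "max")
    expect_identical(sol$solver_status, "optimal", info = paste("phase", k))
    expect_gte(sol$objective_value + 1e-9, w$rates[[k]]$mu)
  }
  # all-zero spans block the accumulation boundary entirely
  ab0 <- w$bounds
  ab0$min <- 0; ab0$max <- 0
  z <- split_into_phase_models(w$ext, ab0)
  expect_equal(z[[2]]$reactions[["ACCS_mannitol"]]$upper_bound, 0)
  expect_equal(z[[1]]$reactions[["ACCD_malate"]]$upper_bound, 0)
})
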