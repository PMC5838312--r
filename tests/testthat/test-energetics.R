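# energetics: ATP routes, redox and proton bookkeeping, conservation audits.

zero_flux <- function(net) {
  structure(list(fluxes = setNames(rep(0, length(net$reactions)),
                                   reaction_ids(net)),
                 objective_id = net$objective_id, objective_value = 0,
                 solver_status = "optimal"), class = "flux_distribution")
}

test_that("zero flux gives all-zero reports", {
  net <- get_base_model()
  f <- zero_flux(net)
  e <- atp_accounting(f, net)
  expect_equal(e$r_atp_total, 0)
  r <- redox_accounting(f, net)
  expect_equal(unname(r$totals["nadph_plus_nadh"]), 0)
  p <- proton_accounting(f, net)
  expect_equal(p$protons_in_f0f1, 0)
  expect_true(attr(e$audit, "balanced"))
})

test_that("route knockout forces the full ATP share onto substrate-level phosphorylation", {
  net <- get_base_model()
  net <- set_bounds(net, "ATPS", 0, 0)      # no F0F1 at all
  net <- set_bounds(net, "EX_glc", -1, -1)  # some glucose in
  sol <- solve_fba(net, "BIOMASS", "max")
  expect_identical(sol$solver_status, "optimal")
  e <- atp_accounting(sol, net)
  expect_equal(e$fraction_f0f1, 0)
  expect_gt(e$r_atp_pkp, 0)
})

test_that("a proton-driven phase-I scenario has a determined F0F1 majority share", {
  w <- get_world(0)
  ngb <- get_world_ngam(0)[[1]]
  cs <- w$css[[1]]; cs$ngam <- ngb$result$ngam; cs$tolerance <- 1e-4
  fnet <- apply_constraint_set(ngb$network, cs)
  sol <- solve_fba(fnet, "BIOMASS", "max")
  e <- atp_accounting(sol, fnet)
  expect_gt(e$fraction_f0f1, 0.5)
  # FVA of the F0F1 term under the same constraints: the share is determined
  span <- fva_linear_combination(fnet, "ATPS", 1)
  expect_lt(span$max - span$min, 0.05 * e$r_atp_total)
})

test_that("steady-state cofactor balances close to 1e-6 and role tags agree with the audit", {
  w <- get_world(0)
  for (k in 1:3) {
    net <- apply_constraint_set(w$sim$truth$networks[[k]], w$css[[k]])
    sol <- solve_fba(net, "BIOMASS", "max")
    aud <- audit_conservation(sol, net)
    expect_true(attr(aud, "balanced"), info = paste("phase", k))
    e <- atp_accounting(sol, net)
    expect_equal(e$r_atp_total, aud$production[aud$species == "atp"],
                 tolerance = 1e-6)
    r <- redox_accounting(sol, net)
    expect_equal(unname(r$totals["nadh"]),
                 aud$production[aud$species == "nadh"], tolerance = 1e-6)
    expect_equal(unname(r$totals["nadph"]),
                 aud$production[aud$species == "nadph"], tolerance = 1e-6)
  }
})

test_that("fraction_f0f1 is invariant under uniform flux rescaling", {
  w <- get_world(0)
  net <- apply_constraint_set(w$sim$truth$networks[[1]], w$css[[1]])
  sol <- solve_fba(net, "BIOMASS", "max")
  e1 <- atp_accounting(sol, net)
  sol2 <- sol
  sol2$fluxes <- sol$fluxes * 3.7
  e2 <- suppressWarnings(atp_accounting(sol2, net))
  expect_equal(e1$fraction_f0f1, e2$fraction_f0f1, tolerance = 1e-12)
})

test_that("all-fructose-to-mannitol limit: polyols account for all NAD(P)H reoxidation", {
  net <- get_base_model()
  net <- set_bounds(net, "EX_fru", -1, -1)
  net <- set_bounds(net, "EX_mal", -1, -1)   # NADH source via MDH route
  net <- set_bounds(net, "EX_mnl", 1, 1)         # all fructose reduced
  net <- set_bounds(net, "EX_etoh", 0, 0)
  net <- set_bounds(net, "EX_dlac", 0, 0)
  sol <- solve_fba(net, "EX_diact", "max")
  expect_identical(sol$solver_status, "optimal")
  r <- redox_accounting(sol, net)
  expect_equal(r$regeneration_share, 1, tolerance = 1e-6)
})

test_that("MLF as sole proton consumer yields fraction one; opening diacetyl raises its share", {
  net <- get_base_model()
  net <- set_bounds(net, "EX_mal", -2, -2)
  net <- set_bounds(net, "EX_llac", 0, 1000)
  net <- set_bounds(net, "EX_dlac", 0, 0)     # no other proton extruder route
  net <- set_bounds(net, "EX_ac", 0, 0)
  net <- set_bounds(net, "EX_diact", 0, 0)
  net <- set_bounds(net, "ATPM", 0.5, 0.5)
  sol <- solve_fba(net, "EX_llac", "max")
  expect_identical(sol$solver_status, "optimal")
  p1 <- proton_accounting(sol, net)
  expect_gt(p1$protons_in_f0f1, 0)
  expect_equal(unname(p1$consumption_shares[["mlf_lactate"]]), 1,
               tolerance = 1e-6)
  expect_equal(p1$fraction_diacetyl, 0, tolerance = 1e-9)
  # paired run with the diacetyl route opened
  net2 <- set_bounds(net, "EX_diact", 0.2, 1000)
  sol2 <- solve_fba(net2, "EX_llac", "max")
  p2 <- proton_accounting(sol2, net2)
  expect_gt(p2$fraction_diacetyl, p1$fraction_diacetyl)
})
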