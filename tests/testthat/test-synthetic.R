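# synthetic_data: stated-world defaults, generator/estimator closure, and
# mass sanity of the witness fluxes.

test_that("defaults encode the stated world", {
  cfg <- default_config()
  expect_equal(cfg$ethanol_levels, c(0, 3, 6, 9, 12))
  expect_equal(cfg$phase_boundaries, c(0, 48, 104, 168, 264))
  expect_equal(unname(cfg$mu_phase1),
               c(0.021, 0.018, 0.016, 0.014, 0.013))
  expect_equal(unname(cfg$initial_medium["glucose"]), 12.5 / 180.16 * 1000,
               tolerance = 1e-6)
  # NGAM truths monotone non-decreasing in ethanol, inside the 0-4 grid
  for (k in 1:3) {
    expect_true(all(diff(cfg$true_ngam[k, ]) >= 0))
    expect_true(all(cfg$true_ngam[k, ] >= 0 & cfg$true_ngam[k, ] <= 4))
  }
  # fructose consumed twice as fast as glucose in phase I
  expect_equal(unname(cfg$base_uptake[[1]]["fructose"] /
                      cfg$base_uptake[[1]]["glucose"]), 2)
})

test_that("the witness world realizes the stated phenomenology", {
  w <- get_world(0)
  tr <- w$sim$truth
  q1 <- tr$q[[1]]
  # fructose ~2x glucose, phase-I depletion of malate and citrate
  expect_equal(unname(q1[["fructose"]] / q1[["glucose"]]), 2, tolerance = 0.01)
  tc <- tr$timecourse
  i48 <- which(tc$times == 48)
  expect_lt(tc$concentrations$malate[i48],
            0.1 * tc$concentrations$malate[1])
  expect_lt(tc$concentrations$citrate[i48],
            0.1 * tc$concentrations$citrate[1])
  # biomass grows at the anchored rate and OD inverts the calibration
  expect_equal(tr$mu[1], 0.021, tolerance = 1e-9)
  expect_equal(od_to_dcw(tc$od600), tc$biomass, tolerance = 1e-9)
  # accumulation strictly positive for every compound and transition
  expect_true(all(tr$accumulation > 0))
})

test_that("witness fluxes satisfy the phase networks and carbon balance", {
  w <- get_world(0)
  tr <- w$sim$truth
  cmap <- setNames(vapply(get_base_model()$metabolites$formula, carbon_count,
                          numeric(1)), get_base_model()$metabolites$id)
  reg <- measured_metabolites()
  carbon_of <- setNames(cmap[c("glc_e", "fru_e", "cit_e", "mal_e", "cys_e",
                               "ser_e", "thr_e", "val_e", "phe_e", "mnl_e",
                               "eol_e", "llac_e", "dlac_e", "ac_e")],
                        reg$name)
  for (k in 1:3) {
    p <- oenoflux:::net_lp_parts(tr$networks[[k]])
    v <- tr$flux[[k]][p$ids]
    expect_lt(max(abs(p$S %*% v)), 1e-6)
    q <- tr$q[[k]]
    c_in <- -sum(q[q < 0] * carbon_of[names(q[q < 0])])
    c_out <- sum(q[q > 0] * carbon_of[names(q[q > 0])])
    biomass_c <- 33 * tr$mu[k]   # ~33 mmol C per gDCW in the lumped biomass
    expect_lt(c_out + biomass_c, c_in + 1e-9)
  }
})

test_that("zero carry-over worlds have accumulation spans containing zero", {
  # the no-accumulation limit: a zero-carry-over phase-I witness repeated in
  # every phase (without stored malate, later phases lose their oxaloacetate
  # source entirely, so a full three-phase zero-carry-over culture does not
  # exist — accumulation is what links the phases)
  cfg <- default_config()
  cfg$accumulation[] <- 0
  ph1 <- oenoflux:::witness_phase(get_base_model(), cfg, 0, 1,
                                  od_to_dcw(cfg$od600_init),
                                  cfg$initial_medium)
  reg <- measured_metabolites()
  css <- lapply(1:3, function(k)
    constraint_set(k, setNames(ph1$q, reg$exchange_id), biomass = ph1$mu))
  ext <- apply_experimental_constraints(
    build_extended_model(get_base_model(), 3), css)
  ab <- fva_accumulation(ext)
  expect_true(all(ab$min <= 1e-6))
})

test_that("noise is seed-reproducible", {
  cfg <- default_config()
  cfg$accumulation <- get_world(0)$sim$truth$accumulation
  s1 <- simulate_culture(cfg, 0, seed = 9, noise_cv = 0.02, refine = 0)
  s2 <- simulate_culture(cfg, 0, seed = 9, noise_cv = 0.02, refine = 0)
  s3 <- simulate_culture(cfg, 0, seed = 10, noise_cv = 0.02, refine = 0)
  expect_identical(s1$timecourse$biomass, s2$timecourse$biomass)
  expect_false(identical(s1$timecourse$biomass, s3$timecourse$biomass))
})
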