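# Techno-economic model: dosing, K co-input, costs, LCA, CDR algebra,
# equivalent rock rate, cost per tonne, moisture propagation.

test_that("dose follows target x water volume x molar mass", {
  sc <- econ_scenario()
  # hand oracle: 750e-6 mol/L x (1008 t x 0.20 x 1000 L/t) x 512.7 g/mol
  water_L <- 1008 * 0.20 * 1000
  expect_equal(eddha_dose(sc), 750e-6 * water_L * 512.7 / 1000)
  # linearity in the target concentration (homogeneity degree 1)
  sc2 <- econ_scenario(target_eddha_uM = 1500)
  expect_equal(eddha_dose(sc2), 2 * eddha_dose(sc))
  # linearity in moisture
  expect_equal(eddha_dose(sc, moisture = 0.10),
               eddha_dose(sc) / 2)
  expect_error(eddha_dose(sc, moisture = 0), "> 0")
})

test_that("K co-input is the salt's K mass fraction times the dose", {
  sc <- econ_scenario()
  expect_equal(k_coinput(100, sc), 100 * 4 * 39.098 / 512.7)
  expect_equal(k_coinput(0, sc), 0)
  # one K per molecule quarters the co-input
  sc1 <- econ_scenario(k_atoms_per_molecule = 1)
  expect_equal(k_coinput(100, sc1), k_coinput(100, sc) / 4)
})

test_that("cost identities hold and respond monotonically to prices", {
  sc <- econ_scenario()
  cst <- chelator_costs(77.5, 23.5, sc)
  expect_equal(cst$net, cst$gross - cst$offset)
  expect_equal(cst$gross, 77.5 * sc$eddha_price_per_kg)
  expect_equal(cst$offset, 23.5 * sc$k_fertilizer_value_per_kg_K)
  # doubling the chelator price doubles the gross cost only
  sc2 <- econ_scenario(eddha_price_per_kg = 2 * sc$eddha_price_per_kg)
  cst2 <- chelator_costs(77.5, 23.5, sc2)
  expect_equal(cst2$gross, 2 * cst$gross)
  expect_equal(cst2$offset, cst$offset)
})

test_that("LCA emissions convert kg-dose to tonnes CO2", {
  sc <- econ_scenario(lca_kgCO2_per_kg_eddha = 12.0)
  expect_equal(lca_emissions(100, sc), 1.2)
  expect_equal(lca_emissions(0, sc), 0)
})

test_that("CDR enhancement algebra: fold 1 costs exactly the LCA", {
  sc <- econ_scenario()
  expect_equal(cdr_enhancement(sc, fold = 1, lca_t = 0.7), -0.7)
  # net additional = baseline x (fold - 1) - LCA, checked directly
  expect_equal(cdr_enhancement(sc, fold = 2, lca_t = 0.5),
               3.8 * 1 - 0.5)
  # round trip: the default fold was chosen so that net additional CDR
  # equals baseline x (fold - 1) - LCA; invert it back out
  lca <- lca_emissions(eddha_dose(sc), sc)
  add <- cdr_enhancement(sc)
  fold_back <- (add + lca) / sc$baseline_cdr_t_per_ha + 1
  expect_equal(fold_back, sc$cdr_fold_at_target)
})

test_that("equivalent rock rate solves rate x eff x fold = target + LCA", {
  sc <- econ_scenario()
  eff <- sc$baseline_cdr_t_per_ha / sc$reference_rock_rate_t_per_ha
  rate <- equivalent_rock_rate(sc, target_net_cdr = 3.8, fold = 2,
                               lca_t = 1.0)
  # identity check: plug the rate back into the forward model
  expect_equal(rate * eff * 2 - 1.0, 3.8)
  # without chelator (fold 1, no LCA) the rate is the reference rate
  expect_equal(equivalent_rock_rate(sc, target_net_cdr = 3.8, fold = 1,
                                    lca_t = 0),
               sc$reference_rock_rate_t_per_ha)
  # higher fold -> less rock, strictly
  r1 <- equivalent_rock_rate(sc, fold = 1.5, lca_t = 1.0)
  r2 <- equivalent_rock_rate(sc, fold = 2.5, lca_t = 1.0)
  expect_lt(r2, r1)
  expect_error(equivalent_rock_rate(sc, target_net_cdr = -10, fold = 2,
                                    lca_t = 1.0), "infeasible")
})

test_that("cost per tonne matches a hand-built oracle over swept baselines", {
  for (base in c(80, 150, 300)) {
    sc <- econ_scenario(baseline_ew_cost_per_tCO2 = base)
    res <- cost_per_tonne(sc)
    dose <- eddha_dose(sc)
    net_cost <- chelator_costs(dose, k_coinput(dose, sc), sc)$net
    add <- cdr_enhancement(sc)
    oracle <- (base * 3.8 + net_cost) / (3.8 + add)
    expect_equal(res$with_eddha, oracle)
    expect_equal(res$reduction, base - oracle)
  }
  expect_error(cost_per_tonne(econ_scenario()), "required user input")
})

test_that("moisture propagation brackets the central value", {
  sc <- econ_scenario(baseline_ew_cost_per_tCO2 = 150)
  bounds <- propagate_moisture_uncertainty(sc)
  # central moisture 0.20 lies inside the 0.10-0.25 range, so every
  # monotone output's central value sits between its min and max
  expect_true(all(bounds$central >= bounds$min - 1e-12))
  expect_true(all(bounds$central <= bounds$max + 1e-12))
  # dose endpoints are exactly the dose at the range endpoints
  expect_equal(bounds$min[bounds$output == "dose_kg_ha"],
               eddha_dose(sc, 0.10))
  expect_equal(bounds$max[bounds$output == "dose_kg_ha"],
               eddha_dose(sc, 0.25))
  # grid SD matches a brute-force recomputation
  grid <- seq(0.10, 0.25, length.out = 31)
  expect_equal(bounds$sd[bounds$output == "dose_kg_ha"],
               sd(vapply(grid, function(m) eddha_dose(sc, m), 0)))
  # collapsed range: min = max = central at that moisture, sd = 0
  sc0 <- econ_scenario(moisture_range = c(0.20, 0.20))
  b0 <- propagate_moisture_uncertainty(sc0)
  expect_equal(b0$min, b0$max)
  expect_equal(b0$sd, rep(0, nrow(b0)))
})

test_that("scenario validation rejects non-physical inputs", {
  expect_error(econ_scenario(soil_moisture_frac = 0), "\\(0, 1\\)")
  expect_error(econ_scenario(soil_moisture_frac = 1.2), "\\(0, 1\\)")
  expect_error(econ_scenario(target_eddha_uM = -1), "target_eddha_uM")
  expect_error(econ_scenario(cdr_fold_at_target = 0.5), ">= 1")
  expect_error(econ_scenario(moisture_range = c(0.3, 0.1)), "increasing")
  expect_error(econ_scenario(k_atoms_per_molecule = 0), ">= 1")
})

test_that("the full report is internally consistent", {
  sc <- econ_scenario(baseline_ew_cost_per_tCO2 = 150)
  rep <- econ_report(sc)
  ctr <- rep$central
  expect_equal(ctr$net_usd_ha, ctr$gross_usd_ha - ctr$offset_usd_ha)
  expect_equal(ctr$net_additional_cdr_t_ha,
               ctr$gross_additional_cdr_t_ha - ctr$lca_tCO2_ha)
  expect_equal(ctr$k_kg_ha, k_coinput(ctr$dose_kg_ha, sc))
  # printing does not error and returns invisibly
  expect_output(print(rep), "techno-economic report")
})
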