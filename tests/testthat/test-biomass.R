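test_that("protein-vs-YAN curve has the right limits and monotonicity", {
  pc <- list(p_min = 0.05, p_max = 0.45, k_p = 50)
  expect_equal(protein_fraction_of_yan(0, pc), 0.05)
  expect_equal(protein_fraction_of_yan(1e9, pc), 0.45, tolerance = 1e-6)
  yan <- seq(0, 500, by = 10)
  p <- protein_fraction_of_yan(yan, pc)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p >= 0.05 & p <= 0.45))
  expect_error(protein_fraction_of_yan(10, list(p_min = 0.5, p_max = 0.4,
                                                k_p = 50)),
               "p_min")
})

test_that("preset curves are calibrated to the initial-must protein contents", {
  for (cs in list(list(name = "cold_12C", p0 = 0.66),
                  list(name = "standard_25C", p0 = 0.41))) {
    pr <- scenario_preset(cs$name)
    p <- protein_fraction_of_yan(pr$yan0, pr$params$protein_curve)
    expect_equal(p, cs$p0, tolerance = 1e-9)
  }
})

test_that("biomass composition closes to one with carbohydrate as buffer", {
  comp <- compose_biomass(0.41, rho = 0.05, dna_fraction = 0.01,
                          lipid_fraction = 0.05)
  expect_equal(comp$carb_fraction, 1 - 0.41 - 0.0205 - 0.06)   # 0.5095
  expect_equal(comp$rna_fraction, 0.05 * 0.41)
  z <- compose_biomass(0, dna_fraction = 0.01, lipid_fraction = 0.05)
  expect_equal(z$carb_fraction, 1 - 0.01 - 0.05)
  expect_error(compose_biomass(0.95), "protein fraction too high")
  # closure along a YAN trajectory
  pc <- list(p_min = 0.05, p_max = 0.66, k_p = 50)
  for (yan in c(0, 5, 50, 235, 1000)) {
    cc <- compose_biomass(protein_fraction_of_yan(yan, pc))
    expect_equal(cc$protein_fraction + cc$rna_fraction + cc$carb_fraction +
                   cc$dna_fraction + cc$lipid_fraction, 1, tolerance = 1e-9)
  }
})

test_that("GAM decomposition is additive, linear in gam_f, and matches the fitted totals", {
  comp25 <- compose_biomass(0.41)
  g0 <- total_gam(comp25, 0)
  expect_equal(g0$total, g0$gam_prot + g0$gam_rna + g0$gam_carb + g0$gam_dna)
  g1 <- total_gam(comp25, 40)
  expect_equal(g1$total, g0$total + 40)
  expect_error(total_gam(comp25, -1))

  # the two conditions' fitted GAM_F values give totals of about 137 and
  # 99.8 mmol ATP/gDW at their respective protein contents
  expect_equal(total_gam(compose_biomass(0.66), 108.5)$total, 137,
               tolerance = 0.001)
  expect_equal(total_gam(comp25, 77.5)$total, 99.8, tolerance = 0.001)
})

test_that("biomass reaction rewrite closes monomer mass and carries GAM", {
  m <- build_toy_model()
  comp <- compose_biomass(0.5)
  gam <- total_gam(comp, 60)
  pm <- toy_precursor_map()
  m2 <- update_biomass_reaction(m, comp, gam, pm)
  st <- m2$stoichiometry[["biomass"]]
  # each metabolite coefficient aggregates its polymers; total mass = 1 g
  total_mass <- -sum(vapply(unique(pm$metabolite), function(met) {
    st[[met]] * pm$molar_mass[match(met, pm$metabolite)]
  }, numeric(1)))
  expect_equal(total_mass, 1, tolerance = 0.02)
  expect_equal(unname(-st[["atp_c"]]), gam$total)
  expect_equal(unname(st[["adp_c"]]), gam$total)

  # zero protein -> no glutamate coefficient
  m3 <- update_biomass_reaction(m, compose_biomass(0), total_gam(compose_biomass(0), 60), pm)
  expect_false("glu_c" %in% names(m3$stoichiometry[["biomass"]]))

  expect_error(update_biomass_reaction(
    m, comp, gam, data.frame(polymer = "protein", metabolite = "ghost",
                             molar_mass = 0.1, weight = 1)),
    "precursor absent")
})

test_that("biomass yield per hexose is nonincreasing in gam_f", {
  m <- build_toy_model()
  pm <- toy_precursor_map()
  comp <- compose_biomass(0.41)
  yields <- vapply(seq(0, 120, by = 20), function(gf) {
    m2 <- update_biomass_reaction(m, comp, total_gam(comp, gf), pm)
    solve_fba(m2, c(biomass = 1), lb = c(EX_glc_e = -5, EX_nh4_e = -10),
              pfba = FALSE)$objective_value
  }, numeric(1))
  expect_true(all(diff(yields) <= 1e-9))
  expect_lt(yields[7], yields[1])   # strictly lower at high maintenance
})
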