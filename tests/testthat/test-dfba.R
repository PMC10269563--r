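test_that("phase assignment uses half-open intervals with left-closed boundaries", {
  sc <- phase_schedule(8, 40, 70, 250, 300)
  expect_equal(phase_of(0, sc), "lag")
  expect_equal(phase_of(8, sc), "exponential")
  expect_equal(phase_of(69.999, sc), "n_limited")
  expect_equal(phase_of(70, sc), "stationary")
  expect_equal(phase_of(250, sc), "decay")
  expect_equal(phase_of(300, sc), "decay")
  expect_error(phase_of(-1, sc), "outside")
  expect_error(phase_of(301, sc), "outside")
  expect_error(phase_schedule(10, 5, 70, 250, 300), "T_L < T_E")
})

test_that("phase objectives follow the five-phase program", {
  expect_equal(build_objective("lag"), c(atpm = 1))
  expect_equal(build_objective("exponential"), c(biomass = 1))
  expect_equal(build_objective("n_limited"), c(biomass_carb = 1))
  m <- build_toy_model()
  w <- build_objective("stationary", m, lb = c(EX_glc_e = -5))
  expect_named(w, c("atpm", "protein_synth"))
  expect_true(all(w > 0))
  # weights are reciprocals of the standalone optima
  opt_atp <- solve_fba(m, c(atpm = 1), lb = c(EX_glc_e = -5),
                       pfba = FALSE)$objective_value
  expect_equal(unname(w[["atpm"]]), 1 / opt_atp)
  # the combined optimum is at least each weighted standalone optimum
  s <- solve_fba(m, w, lb = c(EX_glc_e = -5), pfba = FALSE)
  expect_gte(s$objective_value + 1e-9, 1)  # each term alone can reach 1
})

test_that("solve_fba is bound-limited on a linear chain and pFBA picks the short route", {
  ch <- chain_model(cap = 10)
  s <- solve_fba(ch, c(EX_C = 1), ub = c(EX_C = 1000))
  expect_equal(s$objective_value, 10)

  dg <- degenerate_model(cap = 10)
  s2 <- solve_fba(dg, c(EX_C = 1), ub = c(EX_C = 1000), pfba = TRUE)
  expect_equal(s2$objective_value, 10)
  expect_equal(unname(s2$v[["s1"]]), 10)   # 2-reaction route carries all flux
  expect_equal(unname(s2$v[["l1"]]), 0)    # 3-reaction route unused
  # without the parsimonious stage the optimum is degenerate; with it the
  # total flux is minimal
  expect_equal(s2$total_flux, sum(abs(s2$v)))
})

test_that("right-hand side derivatives equal exchange flux times biomass", {
  m <- build_toy_model()
  pr <- scenario_preset("standard_25C")
  ctx <- fermdfba:::dfba_context(m, attr(m, "exchange_map"),
                                 toy_precursor_map())
  st <- pr$initial_state
  dy <- fermdfba:::dfba_rhs(ctx, pr$params, 0, st, "exponential")
  sol <- fermdfba:::fba_at_state(ctx, pr$params, st, "exponential")
  vhex <- hexose_uptake_bounds(st, pr$params)
  DW <- st[["biomass"]]
  expect_equal(dy[["glucose"]], unname(vhex[["glucose"]]) * DW)
  prods <- product_constraints(vhex, pr$params, "exponential", state = st)
  expect_equal(dy[["ethanol"]], unname(prods[["ethanol"]]) * DW)
  expect_lte(dy[["glucose"]], 0)
  expect_equal(dy[["biomass"]], unname(sol$mu) * DW)
  # all-zero fluxes give all-zero derivatives
  st0 <- st; st0[] <- 0
  dy0 <- fermdfba:::dfba_rhs(ctx, pr$params, 0, st0, "lag")
  expect_true(all(dy0 == 0))
})

test_that("simulated fermentations conserve mass and stay feasible", {
  traj <- preset_trajectory("standard_25C")
  glc <- traj$states[, "glucose"]
  expect_true(all(diff(glc) <= 1e-9))              # monotone nonincreasing
  hex0 <- sum(traj$states[1, c("glucose", "fructose")])
  hex_end <- sum(traj$states[nrow(traj$states), c("glucose", "fructose")])
  expect_lte(hex0 - hex_end, hex0 + 1e-9)
  expect_equal(unique(traj$phases),
               c("lag", "exponential", "n_limited", "stationary", "decay"))
  # steady-state conservation at every accepted sample
  expect_lt(max(traj$sv_residual), 1e-8)
  # times strictly increasing (phase-boundary samples appear exactly once;
  # the integrator hands the final state of a phase to the next, so the
  # state is continuous by construction)
  expect_true(all(diff(traj$times) > 0))
})

test_that("carbon taken up covers carbon in products, CO2 and biomass within 1%", {
  traj <- preset_trajectory("standard_25C")
  m <- traj$model
  pr <- scenario_preset("standard_25C")
  carbons <- setNames(m$metabolites$carbons, m$metabolites$id)
  exch <- grep("^EX_", colnames(traj$fluxes), value = TRUE)
  DW <- traj$states[, "biomass"]
  n <- length(traj$times)
  cflux_ex <- numeric(n)    # net extracellular carbon rate, mmol C/L/h
  cflux_up <- numeric(n)    # uptake part only (substrate carbon in)
  for (r in exch) {
    met <- names(m$stoichiometry[[r]])
    f <- traj$fluxes[, r] * carbons[[met]] * DW
    cflux_ex <- cflux_ex + f
    cflux_up <- cflux_up + pmin(f, 0)
  }
  # carbon drained into cells: biomass pseudoreactions (composition at the
  # sample's YAN) plus the protein-polymerization drain (5 C per glutamate)
  pm <- toy_precursor_map()
  ctx <- fermdfba:::dfba_context(m, attr(m, "exchange_map"),
                                 toy_precursor_map())
  cdrain <- numeric(n)
  for (i in seq_len(n)) {
    yan <- yan_of_state(traj$states[i, ], ctx$n_per_mmol)
    p <- protein_fraction_of_yan(yan, pr$params$protein_curve)
    comp <- compose_biomass(p)
    comp2 <- carb_enriched_composition(comp)
    c_per_flux <- function(cc) {
      fr <- c(protein = cc$protein_fraction, rna = cc$rna_fraction,
              dna = cc$dna_fraction, carb = cc$carb_fraction,
              lipid = cc$lipid_fraction)
      sum(fr[pm$polymer] * pm$weight / pm$molar_mass * carbons[pm$metabolite])
    }
    cdrain[i] <- DW[i] *
      (traj$fluxes[i, "biomass"] * c_per_flux(comp) +
       traj$fluxes[i, "biomass_carb"] * c_per_flux(comp2) +
       traj$fluxes[i, "DM_protein"] * carbons[["protein_c"]])
  }
  # instantaneous closure: net exchange carbon + cellular drain = 0
  expect_lt(max(abs(cflux_ex + cdrain)) / max(abs(cflux_up)), 1e-8)
  # integrated bookkeeping: substrate carbon in >= carbon out + biomass,
  # with the trapezoidal gap below 1%
  tt <- traj$times; dup <- duplicated(tt)
  Cin <- -pracma::trapz(tt[!dup], cflux_up[!dup])
  Cout <- pracma::trapz(tt[!dup], (cflux_ex - cflux_up)[!dup])
  Cbio <- pracma::trapz(tt[!dup], cdrain[!dup])
  expect_gte(Cin + 0.01 * Cin, Cout + Cbio)
  expect_lt(abs(Cin - Cout - Cbio) / Cin, 0.01)
})

test_that("adaptive integration is self-convergent and deterministic", {
  # compressed scenario keeps the adaptive runs cheap
  pr <- scenario_preset("standard_25C")
  sc <- phase_schedule(2, 10, 18, 40, 50)
  m <- build_toy_model()
  o1 <- dfba_options(method = "adams", rtol = 1e-6, atol = 1e-9, n_out = 10,
                     compute_fluxes = FALSE)
  o2 <- dfba_options(method = "adams", rtol = 5e-7, atol = 5e-10, n_out = 10,
                     compute_fluxes = FALSE)
  t1 <- simulate_dfba(m, pr$params, sc, pr$initial_state, options = o1)
  t1b <- simulate_dfba(m, pr$params, sc, pr$initial_state, options = o1)
  expect_identical(t1$states, t1b$states)   # determinism
  t2 <- simulate_dfba(m, pr$params, sc, pr$initial_state, options = o2)
  f1 <- t1$states[nrow(t1$states), ]
  f2 <- t2$states[nrow(t2$states), ]
  big <- f1 > 1   # compare states of appreciable magnitude
  expect_lt(max(abs(f1[big] - f2[big]) / f1[big]), 1e-3)
})
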