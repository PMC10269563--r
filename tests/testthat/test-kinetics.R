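state0 <- c(glucose = 100, fructose = 50, ethanol = 0, NH4 = 2, O2 = 0.25,
            aa1 = 1, aa2 = 0.5, aa3 = 0, arginine = 5)

test_that("hexose uptake shows half-saturation and ethanol inhibition halving", {
  p <- kinetic_parameters(vmax_G = 6, k_G = 100, vmax_F = 4, k_F = 50,
                          K_Ei = 300)
  v <- hexose_uptake_bounds(state0, p)
  expect_equal(unname(v[["glucose"]]), -3)   # Glx = k_G -> vmax/2
  expect_equal(unname(v[["fructose"]]), -2)  # F = k_F
  # saturating glucose, E = K_Ei -> -vmax/2
  st <- state0; st["glucose"] <- 1e8; st["ethanol"] <- 300
  v2 <- hexose_uptake_bounds(st, p)
  expect_equal(unname(v2[["glucose"]]), -3, tolerance = 1e-6)
  # no substrate -> no flux, even with k = 0
  st0 <- state0; st0["glucose"] <- 0
  expect_equal(unname(hexose_uptake_bounds(st0, p)[["glucose"]]), 0)
  p0 <- kinetic_parameters(vmax_G = 6, k_G = 0)
  expect_equal(unname(hexose_uptake_bounds(st0, p0)[["glucose"]]), 0)
  # strictly decreasing magnitude in ethanol
  mags <- vapply(c(0, 100, 300, 900), function(e) {
    st <- state0; st["ethanol"] <- e
    -hexose_uptake_bounds(st, p)[["glucose"]]
  }, numeric(1))
  expect_true(all(diff(mags) < 0))
})

test_that("nitrogen bounds: Michaelis-Menten ammonium, mass-action amino acids, gated arginine", {
  p <- kinetic_parameters(vmax_NH4 = 0.4, k_NH4 = 2,
                          k_AA = c(aa1 = 0.1, aa2 = 0.2, aa3 = 0.3),
                          k_Arg = 0.05)
  b <- nitrogen_uptake_bounds(state0, p, "exponential")
  expect_equal(unname(b[["NH4"]]), -0.2)      # NH4 = k_NH4
  expect_equal(unname(b[["aa1"]]), -0.1)
  expect_equal(unname(b[["aa3"]]), 0)         # depleted amino acid
  expect_equal(unname(b[["arginine"]]), -0.25)
  # arginine uptake is shut from the stationary phase onward
  for (ph in c("stationary", "decay"))
    expect_equal(unname(nitrogen_uptake_bounds(state0, p, ph)[["arginine"]]), 0)
  expect_true(all(b <= 0))
})

test_that("product constraints are proportional to hexose transport with the right sign", {
  p <- kinetic_parameters(k_P = c(prodA = 0.5, prodB = 0.1), X_A = 1)
  v <- product_constraints(c(glucose = -6, fructose = -4), p, "exponential")
  expect_equal(unname(v[["prodA"]]), 5)       # -1 * 0.5 * (-10)
  expect_equal(unname(v[["prodB"]]), 1)
  expect_true(all(product_constraints(c(glucose = 0, fructose = 0), p,
                                      "exponential") == 0))
  p0 <- kinetic_parameters(k_P = c(prodA = 0.5), X_A = 0)
  expect_equal(unname(product_constraints(c(glucose = -6, fructose = -4), p0,
                                          "exponential")[["prodA"]]), 0)
  # phase override can flip a product to uptake...
  pp <- kinetic_parameters(k_P = c(acet = 0.01),
                           k_P_phase = list(stationary = c(acet = -0.05)))
  v2 <- product_constraints(c(glucose = -10, fructose = 0), pp, "stationary",
                            state = c(acet = 3))
  expect_equal(unname(v2[["acet"]]), -0.5)
  # ...but never imports from an exhausted pool
  v3 <- product_constraints(c(glucose = -10, fructose = 0), pp, "stationary",
                            state = c(acet = 0))
  expect_equal(unname(v3[["acet"]]), 0)
})

test_that("oxygen bound is first order and vanishes with oxygen", {
  p <- kinetic_parameters(k_O2 = 0.2)
  st <- state0
  expect_equal(oxygen_bound(st, p), -0.05)
  st["O2"] <- 0.125
  expect_equal(oxygen_bound(st, p), -0.025)   # halving linearity
  st["O2"] <- 0
  expect_equal(oxygen_bound(st, p), 0)
})
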