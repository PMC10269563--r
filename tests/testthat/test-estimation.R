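test_that("the least-squares objective matches hand arithmetic and is invariant to unit rescaling", {
  # two variables, three times, hand-set residuals against a fake trajectory
  times <- c(0, 1, 2)
  traj <- structure(list(
    times = times,
    states = cbind(a = c(1, 2, 3), b = c(10, 20, 30)),
    phases = rep("lag", 3)), class = "dfba_trajectory")
  obs <- data.frame(variable = rep(c("a", "b"), each = 3),
                    time_h = rep(times, 2),
                    value = c(1.5, 2, 2, 10, 25, 35))
  ms <- measurement_set(obs)
  # residuals a: (-0.5, 0, 1) with q_a = mean(1.5, 2, 2); b: (0, -5, -5), q_b = 70/3
  qa <- mean(c(1.5, 2, 2)); qb <- mean(c(10, 25, 35))
  J_hand <- (0.25 + 0 + 1) / qa^2 + (0 + 25 + 25) / qb^2
  expect_equal(fermdfba:::measurement_loss(traj, ms), J_hand, tolerance = 1e-12)

  # rescaling variable b's unit (values and predictions together) leaves J unchanged
  obs2 <- obs; obs2$value[obs2$variable == "b"] <- obs2$value[obs2$variable == "b"] * 1000
  traj2 <- traj; traj2$states[, "b"] <- traj2$states[, "b"] * 1000
  expect_equal(fermdfba:::measurement_loss(traj2, measurement_set(obs2)), J_hand,
               tolerance = 1e-12)

  # J is invariant to row ordering of the measurements
  shuf <- obs[sample(nrow(obs)), ]
  expect_equal(fermdfba:::measurement_loss(traj, measurement_set(shuf)), J_hand,
               tolerance = 1e-12)
})

test_that("noise-free self-generated data give J = 0 at the true parameters", {
  pr <- scenario_preset("standard_25C")
  ds0 <- generate_dataset(pr, noise_cv = 0, seed = 3,
                          options = fit_sim_options(8))
  th <- c(vmax_G = pr$params$vmax_G, T_S = pr$schedule$T_S)
  expect_equal(lsq_objective(th, ds0$measurements, pr,
                             options = fit_sim_options(8)), 0,
               tolerance = 1e-16)
  # a wrong parameter raises J
  th2 <- th; th2["vmax_G"] <- 6
  expect_gt(lsq_objective(th2, ds0$measurements, pr,
                          options = fit_sim_options(8)), 1)
})

test_that("apply_theta maps names onto parameters and rejects misordered phases", {
  pr <- scenario_preset("cold_12C")
  ap <- apply_theta(pr, c(vmax_G = 5, "k_P.ethanol" = 1.5, T_S = 200,
                          p_max = 0.7))
  expect_equal(ap$params$vmax_G, 5)
  expect_equal(unname(ap$params$k_P[["ethanol"]]), 1.5)
  expect_equal(ap$schedule$T_S, 200)
  expect_equal(ap$params$protein_curve$p_max, 0.7)
  expect_null(apply_theta(pr, c(T_S = 10)))     # T_S < T_E
  expect_equal(lsq_objective(c(T_S = 10), NULL, pr), 1e8)  # penalty path
})

test_that("R-squared matches its definition on hand cases", {
  mk <- function(v) data.frame(variable = "x", time_h = seq_along(v), value = v)
  expect_equal(unname(r_squared(mk(c(1, 2, 3)), mk(c(1, 2, 3)))), 1)
  expect_equal(unname(r_squared(mk(c(2, 2, 2)), mk(c(1, 2, 3)))), 0)
  expect_equal(unname(r_squared(mk(c(1, 2, 4)), mk(c(1, 2, 3)))), 0.5)
  expect_true(is.na(unname(r_squared(mk(c(1, 2, 3)), mk(c(2, 2, 2))))))
  expect_error(r_squared(mk(1), mk(1)), ">= 2 observations")
})

test_that("the global fit is seed-deterministic, bound-respecting and never worse than its start", {
  pr <- scenario_preset("standard_25C")
  ds <- generate_dataset(pr, noise_cv = 0.05, seed = 5,
                         options = fit_sim_options(5))
  free <- list(vmax_G = c(4, 12))
  f1 <- fit_dfba(ds$measurements, pr, free, seed = 11, budget = 12,
                 options = fit_sim_options(5))
  f2 <- fit_dfba(ds$measurements, pr, free, seed = 11, budget = 12,
                 options = fit_sim_options(5))
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$J, f2$J)
  expect_lte(f1$J, f1$best_initial + 1e-12)
  expect_gte(coef(f1)[["vmax_G"]], 4)
  expect_lte(coef(f1)[["vmax_G"]], 12)

  # degenerate budget: a single evaluation still returns a finite result
  f3 <- fit_dfba(ds$measurements, pr, free, seed = 2, budget = 1,
                 options = fit_sim_options(5))
  expect_true(is.finite(f3$J))
})

test_that("fit objects expose the standard modelling methods", {
  pr <- scenario_preset("standard_25C")
  ds <- generate_dataset(pr, noise_cv = 0.02, seed = 9,
                         options = fit_sim_options(5))
  f <- fit_dfba(ds$measurements, pr, list(vmax_G = c(4, 12)), seed = 3,
                budget = 8, options = fit_sim_options(5))
  expect_named(coef(f), "vmax_G")
  expect_s3_class(predict(f), "dfba_trajectory")
  res <- residuals(f)
  expect_equal(length(res), nrow(ds$measurements$data))
  expect_output(print(f), "Fitted dynamic FBA model")
  expect_output(summary(f), "R\\^2")
  sims <- simulate(f, nsim = 2, seed = 4, noise_cv = 0.05)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "measurement_set")
})
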