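# Flux-ratio windows on the helper schedule: growth [1,3], stationary [3,4],
# decay [4,5] (whole run [0,5]).

test_that("constant-flux ratios equal the closed form independent of interval length", {
  for (np in c(6, 23)) {
    times <- seq(0, 5, length.out = np)
    tr <- analytic_trajectory(times,
                              v_i = function(t) 0.3,
                              v_glx = function(t) -4,
                              v_frc = function(t) -2,
                              DW = function(t) 1.7)
    for (ph in c("growth", "stationary", "decay")) {
      s <- phase_flux_ratio(tr, "target", ph)
      expect_equal(s, 100 * 0.3 / 6, tolerance = 1e-12)   # production sign
    }
    # literal printed orientation: signed hexose denominator
    s2 <- phase_flux_ratio(tr, "target", "stationary",
                           orientation = "consumption")
    expect_equal(s2, -100 * 0.3 / 6, tolerance = 1e-12)
  }
})

test_that("flux ratios are linear in the flux and self-normalizing for hexoses", {
  times <- seq(0, 5, length.out = 11)
  mk <- function(alpha) analytic_trajectory(times,
    v_i = function(t) alpha * (0.1 + 0.02 * t),
    v_glx = function(t) -3 - 0.1 * t, v_frc = function(t) -1,
    DW = function(t) 1 + 0.2 * t)
  s1 <- phase_flux_ratio(mk(1), "target", "stationary")
  s3 <- phase_flux_ratio(mk(3), "target", "stationary")
  expect_equal(s3, 3 * s1, tolerance = 1e-12)

  # glucose + fructose exchange ratios sum to 100 in the printed orientation
  tr <- mk(1)
  sg <- phase_flux_ratio(tr, "EX_glc_e", "growth", orientation = "consumption")
  sf <- phase_flux_ratio(tr, "EX_frc_e", "growth", orientation = "consumption")
  expect_equal(sg + sf, 100, tolerance = 1e-12)
  # fructose absent: glucose is the whole denominator
  tr0 <- analytic_trajectory(times, v_i = function(t) 0.1,
                             v_glx = function(t) -2, v_frc = function(t) 0,
                             DW = function(t) 1)
  expect_equal(phase_flux_ratio(tr0, "EX_glc_e", "growth",
                                orientation = "consumption"), 100,
               tolerance = 1e-12)
  # zero flux -> zero ratio; zero hexose -> undefined
  expect_equal(phase_flux_ratio(analytic_trajectory(times,
    v_i = function(t) 0, v_glx = function(t) -1, v_frc = function(t) 0,
    DW = function(t) 1), "target", "growth"), 0)
  expect_true(is.na(phase_flux_ratio(analytic_trajectory(times,
    v_i = function(t) 1, v_glx = function(t) 0, v_frc = function(t) 0,
    DW = function(t) 1), "target", "growth")))
})

test_that("trapezoidal error falls about fourfold when step spacing halves", {
  # smooth flux v(t) = sin(t), DW = 1, hexose constant: closed-form integral
  closed <- function(a, b) (cos(a) - cos(b))            # int sin dt
  err <- vapply(c(21, 41), function(np) {
    times <- seq(0, 5, length.out = np)
    tr <- analytic_trajectory(times, v_i = function(t) sin(t),
                              v_glx = function(t) -2, v_frc = function(t) 0,
                              DW = function(t) 1)
    s <- phase_flux_ratio(tr, "target", "stationary")
    truth <- 100 * closed(3, 4) / (2 * 1)
    abs(s - truth)
  }, numeric(1))
  expect_gt(err[1] / err[2], 3)
  expect_lt(err[1] / err[2], 5)
})

test_that("whole-run option reproduces the literal decay formula window", {
  times <- seq(0, 5, length.out = 26)
  tr <- analytic_trajectory(times, v_i = function(t) ifelse(t < 4, 1, 0),
                            v_glx = function(t) -1, v_frc = function(t) 0,
                            DW = function(t) 1)
  s_decay <- phase_flux_ratio(tr, "target", "decay")            # [4, 5]
  s_whole <- phase_flux_ratio(tr, "target", "decay", whole_run = TRUE)  # [0, 5]
  expect_lt(s_decay, 10)
  expect_equal(s_whole, 100 * 4 / 5, tolerance = 0.5)  # step function, trapz
})

test_that("log2 folds reproduce the printed temperature comparisons", {
  # glutamate decarboxylase: ratios 0.94 (25C) vs 0.19 (12C), printed 2.309
  expect_lt(abs(log2_fold(0.94, 0.19) - 2.309), 0.01)
  # mitochondrial ethanol: 2.25 vs 0.14 is the printed 16-fold
  expect_equal(round(2.25 / 0.14), 16)
  # mevalonate route: log2(1.31 / 0.04) rounds to the printed 5
  expect_equal(round(log2_fold(1.31, 0.04)), 5)
  expect_equal(log2_fold(0.5, 0.5), 0)
  expect_error(log2_fold(-0.2, 0.1), "sign")
})

test_that("differential selection applies magnitude and fold thresholds", {
  tab <- function(vals) {
    d <- data.frame(reaction = paste0("r", seq_along(vals)),
                    S_growth = vals, S_stationary = vals, S_decay = vals,
                    name = NA_character_, stringsAsFactors = FALSE)
    class(d) <- c("flux_ratio_table", "data.frame"); d
  }
  A <- tab(c(0.94, 0.05, 0.30, -0.5))
  B <- tab(c(0.19, 0.01, 0.28, 0.5))
  expect_equal(nrow(select_differential(A, A)), 0)     # identical -> empty
  sel <- select_differential(A, B)
  expect_true("r1" %in% sel$reaction)                   # 0.94 vs 0.19 passes
  expect_false("r2" %in% sel$reaction)                  # magnitude fails
  expect_false("r3" %in% sel$reaction)                  # fold fails
  expect_true("r4" %in% attr(sel, "sign_changes"))      # direction reversal
  expect_equal(sel$log2_fold[1], log2(0.94 / 0.19))
  # sorted by |fold| descending
  expect_true(all(diff(abs(sel$log2_fold)) <= 0))
})
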