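#' Two-temperature fermentation scenario presets
#'
#' Complete study conditions for the bundled toy network: kinetic
#' parameters, phase schedule and initial must composition for a standard
#' (25 degrees C) and a cold (12 degrees C) batch fermentation. The cold
#' preset has longer phases, slower uptake kinetics, a higher fitted
#' maintenance `gam_f`, a higher initial protein content, higher erythritol
#' and lower succinate yields, and much weaker stationary-phase acetate
#' uptake — the sign pattern of the temperature contrast this class of
#' models is used to study. Stationary-phase product-yield values are
#' calibrated so the presets' per-hexose stationary flux ratios fall in the
#' reported ranges for cold-tolerant yeasts (succinate about 0.94 vs 0.19,
#' acetate uptake about 4.1 vs 0.1, erythritol about 0.25 vs 0.69 mmol per
#' 100 mmol hexose at 25 vs 12 degrees C).
#'
#' The initial protein contents of newly formed biomass are 0.41 (25 C) and
#' 0.66 (12 C) g/gDW; each preset's protein-vs-YAN curve is calibrated to
#' hit that value at the initial must YAN. Arginine rate constants are
#' calibrated so that arginine consumption — which stops at the onset of the
#' stationary phase — leaves an unconsumed residual on the reported scale
#' (roughly 100 and 80 mg per 470-mL bioreactor, i.e. about 210 and
#' 170 mg/L, at 12 and 25 degrees C).
#'
#' @param name `"standard_25C"` or `"cold_12C"`.
#' @return object of class `scenario_preset`: list with `name`, `params`
#'   (a [kinetic_parameters()]), `schedule` (a [phase_schedule()]) and
#'   `initial_state` (named vector, mM and gDW/L).
#' @export
scenario_preset <- function(name = c("standard_25C", "cold_12C")) {
  name <- match.arg(name)
  initial_state <- c(glucose = 555, fructose = 555, NH4 = 4.3, O2 = 0.25,
                     aa1 = 1.5, aa2 = 1.5, aa3 = 1.5, arginine = 2.0,
                     ethanol = 0, glycerol = 0, erythritol = 0, succinate = 0,
                     acetate = 0, malate = 0, butanediol = 0, acetoin = 0,
                     isoamyl_alcohol = 0, isobutanol = 0, phenylethanol = 0,
                     mevalonate = 0, biomass = 0.02)
  yan0 <- 14.007 * (4.3 + 3 * 1.5 + 4 * 2.0)   # ~235 mg N/L

  calibrate_curve <- function(p0, p_min = 0.05, k_p = 50) {
    list(p_min = p_min, k_p = k_p,
         p_max = p_min + (p0 - p_min) * (yan0 + k_p) / yan0)
  }

  if (name == "standard_25C") {
    params <- kinetic_parameters(
      vmax_G = 8.0, k_G = 20, vmax_F = 6.5, k_F = 25, K_Ei = 700,
      vmax_NH4 = 0.5, k_NH4 = 0.5,
      k_AA = c(aa1 = 0.05, aa2 = 0.05, aa3 = 0.04),
      k_Arg = 0.010, k_O2 = 0.4,
      k_P = c(ethanol = 1.80, glycerol = 0.085, erythritol = 0.0025,
              succinate = 0.0094, acetate = 0.012,
              isoamyl_alcohol = 0.0015, isobutanol = 0.0006,
              phenylethanol = 0.0005),
      k_P_phase = list(stationary = c(acetate = -0.0413),
                       decay = c(acetate = -0.0413)),
      gam_f = 77.5,
      protein_curve = calibrate_curve(0.41),
      k_d = 0.002)
    schedule <- phase_schedule(T_L = 8, T_E = 40, T_S = 70, T_D = 250,
                               t_end = 300)
  } else {
    params <- kinetic_parameters(
      vmax_G = 4.0, k_G = 20, vmax_F = 3.2, k_F = 25, K_Ei = 600,
      vmax_NH4 = 0.3, k_NH4 = 0.5,
      k_AA = c(aa1 = 0.025, aa2 = 0.025, aa3 = 0.02),
      k_Arg = 0.0045, k_O2 = 0.25,
      k_P = c(ethanol = 1.78, glycerol = 0.10, erythritol = 0.0069,
              succinate = 0.0019, acetate = 0.012,
              isoamyl_alcohol = 0.002, isobutanol = 0.0008,
              phenylethanol = 0.0005),
      k_P_phase = list(stationary = c(acetate = -0.001),
                       decay = c(acetate = -0.001)),
      gam_f = 108.5,
      protein_curve = calibrate_curve(0.66),
      k_d = 0.0012)
    schedule <- phase_schedule(T_L = 24, T_E = 150, T_S = 260, T_D = 550,
                               t_end = 650)
  }
  structure(list(name = name, params = params, schedule = schedule,
                 initial_state = initial_state, yan0 = yan0),
            class = "scenario_preset")
}

#' @export
print.scenario_preset <- function(x, ...) {
  cat("Scenario preset:", x$name, "\n")
  cat("  phases end at:", paste(unlist(x$schedule[1:4]), collapse = ", "),
      "h; t_end =", x$schedule$t_end, "h\n")
  cat("  initial hexoses:", x$initial_state[["glucose"]], "+",
      x$initial_state[["fructose"]], "mM; YAN:", round(x$yan0), "mg N/L\n")
  cat("  gam_f:", x$params$gam_f, "mmol ATP/gDW\n")
  invisible(x)
}
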