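#' Kinetic parameters of the exchange-flux constraints
#'
#' Bundles every constant of the kinetic layer that couples extracellular
#' concentrations to the FBA problem: saturating hexose uptake with
#' noncompetitive ethanol inhibition, Michaelis-Menten ammonium uptake,
#' first-order (mass-action) amino-acid and arginine uptake, first-order
#' oxygen consumption, hexose-proportional product formation, the
#' phase-dependent activity coefficient `X_A`, the fitted maintenance
#' `gam_f`, the protein-vs-YAN curve, and the decay rate.
#'
#' Units: concentrations mM; fluxes mmol/(gDW h); first-order constants
#' L/(gDW h); `k_P` mmol product per mmol hexose; `gam_f` mmol ATP/gDW.
#'
#' @param vmax_G,k_G glucose uptake Vmax and half-saturation (mM).
#' @param vmax_F,k_F fructose analogues.
#' @param K_Ei ethanol noncompetitive-inhibition constant (mM).
#' @param vmax_NH4,k_NH4 ammonium Michaelis-Menten constants.
#' @param k_AA named vector of first-order amino-acid rate constants.
#' @param k_Arg arginine first-order rate constant.
#' @param k_O2 oxygen first-order rate constant.
#' @param k_P named vector of product yield coefficients (mmol/mmol hexose).
#' @param k_P_phase optional list of per-phase overrides of `k_P` entries
#'   (e.g. a negative stationary-phase acetate coefficient models acetate
#'   re-consumption proportional to hexose uptake).
#' @param X_A activity coefficient in `[0, 1]`; either a scalar or a named
#'   vector per phase (`lag`, `exponential`, `n_limited`, `stationary`,
#'   `decay`). Defaults to 1 in the growth phases.
#' @param gam_f fitted non-polymerization maintenance, mmol ATP/gDW.
#' @param protein_curve list with `p_min`, `p_max`, `k_p` for
#'   [protein_fraction_of_yan()].
#' @param rho,dna_fraction,lipid_fraction biomass composition constants.
#' @param carb_boost extra carbohydrate mass fraction (percentage points /
#'   100) of the carbohydrate-enriched biomass variant used under nitrogen
#'   limitation.
#' @param k_d first-order biomass decay rate (1/h), decay phase only.
#' @return object of class `kinetic_parameters`.
#' @export
kinetic_parameters <- function(vmax_G = 2.5, k_G = 10, vmax_F = 2.0, k_F = 12,
                               K_Ei = 600,
                               vmax_NH4 = 0.4, k_NH4 = 0.5,
                               k_AA = c(aa1 = 0.02, aa2 = 0.02, aa3 = 0.02),
                               k_Arg = 0.02, k_O2 = 0.5,
                               k_P = c(ethanol = 1.8, glycerol = 0.08,
                                       erythritol = 0.003, succinate = 0.004,
                                       acetate = 0.01, isoamyl_alcohol = 0.002,
                                       isobutanol = 0.001,
                                       phenylethanol = 0.0008),
                               k_P_phase = list(),
                               X_A = c(lag = 1, exponential = 1, n_limited = 1,
                                       stationary = 1, decay = 1),
                               gam_f = 77.5,
                               protein_curve = list(p_min = 0.05, p_max = 0.45,
                                                    k_p = 50),
                               rho = 0.05, dna_fraction = 0.01,
                               lipid_fraction = 0.05,
                               carb_boost = 0.20, k_d = 0.002) {
  p <- list(vmax_G = vmax_G, k_G = k_G, vmax_F = vmax_F, k_F = k_F,
            K_Ei = K_Ei, vmax_NH4 = vmax_NH4, k_NH4 = k_NH4, k_AA = k_AA,
            k_Arg = k_Arg, k_O2 = k_O2, k_P = k_P, k_P_phase = k_P_phase,
            X_A = X_A, gam_f = gam_f, protein_curve = protein_curve,
            rho = rho, dna_fraction = dna_fraction,
            lipid_fraction = lipid_fraction, carb_boost = carb_boost,
            k_d = k_d)
  rates <- c(vmax_G, k_G, vmax_F, k_F, K_Ei, vmax_NH4, k_NH4, k_AA, k_Arg,
             k_O2, k_d)
  if (any(rates < 0)) stop("rate constants must be nonnegative")
  xa <- if (length(X_A) == 1L) X_A else unname(X_A)
  if (any(xa < 0 | xa > 1)) stop("X_A must lie in [0, 1]")
  structure(p, class = "kinetic_parameters")
}

phase_value <- function(x, phase) {
  if (length(x) == 1L && is.null(names(x))) return(unname(x))
  if (phase %in% names(x)) unname(x[[phase]]) else unname(x[[1]])
}

#' Hexose uptake equality constraints
#'
#' Saturating (Michaelis-Menten-type) uptake with noncompetitive ethanol
#' inhibition, applied to both hexoses:
#' `v = -vmax * C / (C + k) * 1 / (1 + E / K_Ei)`, always <= 0.
#' Imposed on the FBA problem as equalities.
#'
#' @param state named numeric state vector with entries `glucose`,
#'   `fructose`, `ethanol` (mM).
#' @param params a `kinetic_parameters`.
#' @return named vector `c(glucose = v_Glx, fructose = v_F)`, mmol/(gDW h).
#' @export
hexose_uptake_bounds <- function(state, params) {
  inhib <- 1 / (1 + max(state[["ethanol"]], 0) / params$K_Ei)
  mm <- function(conc, vmax, k) {
    conc <- max(conc, 0)
    if (conc + k <= 0) return(0)        # k = 0 with zero substrate: limit 0
    -vmax * conc / (conc + k) * inhib
  }
  c(glucose = mm(state[["glucose"]], params$vmax_G, params$k_G),
    fructose = mm(state[["fructose"]], params$vmax_F, params$k_F))
}

#' Nitrogen uptake lower bounds
#'
#' Ammonium follows Michaelis-Menten uptake; each amino acid is first-order
#' (mass action); arginine is first-order during lag through nitrogen-limited
#' growth and exactly zero from the stationary phase onward (the species
#' cannot consume it to completion). These are one-sided lower bounds — the
#' FBA problem may take less.
#'
#' @param state named state vector with `NH4`, `arginine` and the amino-acid
#'   entries named as in `params$k_AA` (mM).
#' @param params a `kinetic_parameters`.
#' @param phase phase id.
#' @return named vector of lower bounds (<= 0), mmol/(gDW h), with entries
#'   `NH4`, the amino acids, and `arginine`.
#' @export
nitrogen_uptake_bounds <- function(state, params, phase) {
  nh4 <- max(state[["NH4"]], 0)
  b <- c(NH4 = if (nh4 + params$k_NH4 > 0)
    -params$vmax_NH4 * nh4 / (nh4 + params$k_NH4) else 0)
  for (aa in names(params$k_AA))
    b[aa] <- -params$k_AA[[aa]] * max(state[[aa]], 0)
  b["arginine"] <- if (phase %in% c("lag", "exponential", "n_limited"))
    -params$k_Arg * max(state[["arginine"]], 0) else 0
  b
}

#' Product formation equality constraints
#'
#' Products (ethanol, higher alcohols, carboxylic acids, esters, ...) are
#' formed in proportion to total hexose transport:
#' `v_Pj = -X_A * k_Pj * (v_Glx + v_F)`, nonnegative for positive `k_P`.
#' Phase-specific `k_P` overrides permit sign changes such as
#' stationary-phase acetate re-consumption.
#'
#' @param v_hexose named vector from [hexose_uptake_bounds()] (both <= 0).
#' @param params a `kinetic_parameters`.
#' @param phase phase id.
#' @param state optional named state vector; when given, an uptake-direction
#'   constraint (negative `k_P`, e.g. stationary acetate re-consumption) is
#'   zeroed once the corresponding extracellular pool is exhausted, so the
#'   FBA problem never imports mass that is not there.
#' @return named vector of product exchange fluxes (equality constraints).
#' @export
product_constraints <- function(v_hexose, params, phase, state = NULL) {
  stopifnot(all(v_hexose <= 1e-12))
  kp <- params$k_P
  if (!is.null(params$k_P_phase[[phase]])) {
    ov <- params$k_P_phase[[phase]]
    kp[names(ov)] <- ov
  }
  xa <- phase_value(params$X_A, phase)
  v <- -xa * kp * sum(v_hexose)
  if (!is.null(state)) {
    gone <- names(v)[v < 0 & unlist(state[names(v)]) <= 1e-9]
    v[gone] <- 0
  }
  v
}

#' Oxygen uptake bound
#'
#' First-order in dissolved oxygen, `v_O2 = -k_O2 * O2`; zero once oxygen is
#' exhausted (oxygen is present only at the start of fermentation).
#'
#' @param state named state vector with entry `O2` (mM).
#' @param params a `kinetic_parameters`.
#' @return scalar flux bound, mmol/(gDW h).
#' @export
oxygen_bound <- function(state, params) {
  -params$k_O2 * max(state[["O2"]], 0)
}
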