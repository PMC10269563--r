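# Shared in-code fixtures: tiny networks with known LP answers, and
# hand-built trajectories with closed-form flux integrals.

# linear chain  A_e -> A -> B -> C -> C_e, uptake capped at `cap`
chain_model <- function(cap = 10) {
  mets <- data.frame(id = c("A_e", "A", "B", "C", "C_e"),
                     name = c("A_e", "A", "B", "C", "C_e"),
                     compartment = c("e", "c", "c", "c", "e"),
                     carbons = 1, nitrogens = 0, stringsAsFactors = FALSE)
  rx <- list(EX_A = c(A_e = -1), t_A = c(A_e = -1, A = 1),
             r1 = c(A = -1, B = 1), r2 = c(B = -1, C = 1),
             t_C = c(C = -1, C_e = 1), EX_C = c(C_e = -1),
             biomass = c(C = -1))
  reactions <- data.frame(
    id = names(rx), name = names(rx),
    lower_bound = c(-cap, 0, 0, 0, 0, 0, 0),
    upper_bound = c(0, 1000, 1000, 1000, 1000, 1000, 0),
    subsystem = c("exchange", "", "", "", "", "exchange", "pseudo"),
    stringsAsFactors = FALSE)
  metabolic_model(mets, reactions, rx, biomass_reaction_id = "biomass")
}

# two alternate optimal routes from A to C: short (2 reactions) and long
# (3 reactions through X, Y); pFBA must choose the short one
degenerate_model <- function(cap = 10) {
  ids <- c("A_e", "A", "B", "X", "Y", "C", "C_e")
  mets <- data.frame(id = ids, name = ids,
                     compartment = c("e", rep("c", 5), "e"),
                     carbons = 1, nitrogens = 0, stringsAsFactors = FALSE)
  rx <- list(EX_A = c(A_e = -1), t_A = c(A_e = -1, A = 1),
             s1 = c(A = -1, B = 1), s2 = c(B = -1, C = 1),
             l1 = c(A = -1, X = 1), l2 = c(X = -1, Y = 1), l3 = c(Y = -1, C = 1),
             t_C = c(C = -1, C_e = 1), EX_C = c(C_e = -1),
             biomass = c(C = -1))
  reactions <- data.frame(
    id = names(rx), name = names(rx),
    lower_bound = c(-cap, rep(0, 9)),
    upper_bound = c(0, rep(1000, 8), 0),
    subsystem = "", stringsAsFactors = FALSE)
  metabolic_model(mets, reactions, rx, biomass_reaction_id = "biomass")
}

# trajectory-shaped list with analytic fluxes: v_i(t), hexose fluxes and DW
# supplied as functions of time, evaluated on `times`
analytic_trajectory <- function(times, v_i, v_glx, v_frc, DW,
                                schedule = phase_schedule(1, 2, 3, 4, 5)) {
  fx <- cbind(target = vapply(times, v_i, numeric(1)),
              EX_glc_e = vapply(times, v_glx, numeric(1)),
              EX_frc_e = vapply(times, v_frc, numeric(1)))
  states <- cbind(biomass = vapply(times, DW, numeric(1)))
  structure(list(times = times, states = states,
                 phases = rep("stationary", length(times)), fluxes = fx,
                 model = NULL, schedule = schedule,
                 exchange_map = c(glucose = "EX_glc_e", fructose = "EX_frc_e")),
            class = "dfba_trajectory")
}

# memoised preset simulations shared across test files (cheap fixed-step
# configuration with the parsimonious flux pass)
.sim_cache <- new.env()
preset_trajectory <- function(name) {
  if (is.null(.sim_cache[[name]])) {
    pr <- scenario_preset(name)
    .sim_cache[[name]] <- simulate_dfba(
      build_toy_model(), pr$params, pr$schedule, pr$initial_state,
      options = dfba_options(method = "heun", steps_per_phase = 10,
                             compute_fluxes = TRUE, pfba_rhs = FALSE,
                             normalize_each_step = FALSE))
  }
  .sim_cache[[name]]
}
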