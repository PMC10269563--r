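#' Integrator options for the dynamic FBA engine
#'
#' @param method `"adams"` for the variable-step, variable-order
#'   predictor-corrector (nonstiff Adams-Bashforth-Moulton via
#'   [deSolve::ode()]), or `"heun"` for a fixed-step second-order
#'   Runge-Kutta used where thousands of simulations must run cheaply
#'   (parameter estimation).
#' @param rtol,atol integration tolerances (adams).
#' @param n_out output samples per phase (adams).
#' @param steps_per_phase fixed steps per phase (heun).
#' @param compute_fluxes run the parsimonious FBA pass at every accepted
#'   sample and return the full flux matrix.
#' @param pfba_rhs use the parsimonious solution inside the right-hand side
#'   (the pFBA-at-every-step contract); stage-one FBA only if `FALSE`.
#' @param normalize_each_step recompute the stationary/decay objective
#'   normalization (each term weighted by the reciprocal of its standalone
#'   optimum) at every step; `FALSE` computes it once at phase entry and
#'   reuses it, halving the LP count of those phases (used during fitting).
#' @param stationary_excretion extracellular species whose excretion is
#'   unconstrained during the stationary and decay phases (the lipid-family
#'   proxy; mevalonate by default).
#' @return list of options.
#' @export
dfba_options <- function(method = c("adams", "heun"), rtol = 1e-6, atol = 1e-9,
                         n_out = 25, steps_per_phase = 12,
                         compute_fluxes = TRUE, pfba_rhs = TRUE,
                         normalize_each_step = TRUE,
                         stationary_excretion = "mev_e") {
  list(method = match.arg(method), rtol = rtol, atol = atol, n_out = n_out,
       steps_per_phase = steps_per_phase, compute_fluxes = compute_fluxes,
       pfba_rhs = pfba_rhs, normalize_each_step = normalize_each_step,
       stationary_excretion = stationary_excretion)
}

# Precomputed engine context: matrices, index maps, biomass column machinery.
dfba_context <- function(model, exchange_map, precursor_map) {
  S <- stoichiometric_matrix(model)
  rids <- colnames(S); mids <- rownames(S)
  ex_idx <- setNames(match(exchange_map, rids), names(exchange_map))
  if (anyNA(ex_idx))
    stop("exchange_map names reactions absent from the model: ",
         paste(exchange_map[is.na(ex_idx)], collapse = ", "))
  ex_met <- vapply(exchange_map, function(r) names(model$stoichiometry[[r]]),
                   character(1))
  nitrogens <- setNames(model$metabolites$nitrogens, model$metabolites$id)[ex_met]
  nitrogens[is.na(nitrogens)] <- 0
  n_sources <- names(exchange_map)[nitrogens > 0]
  list(model = model, S = S, rids = rids, mids = mids,
       L0 = setNames(model$reactions$lower_bound, rids),
       U0 = setNames(model$reactions$upper_bound, rids),
       ex_idx = ex_idx, n_sources = n_sources,
       n_per_mmol = setNames(nitrogens, names(exchange_map)),
       i_bio = match("biomass", rids), i_bioc = match("biomass_carb", rids),
       i_atpm = match("atpm", rids), i_prot = match("protein_synth", rids),
       precursor_map = precursor_map,
       vars = names(exchange_map))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# biomass pseudoreaction column (dense, over the model's metabolite order)
biomass_column <- function(ctx, comp, gam) {
  pm <- ctx$precursor_map
  col <- numeric(length(ctx$mids)); names(col) <- ctx$mids
  fr <- c(protein = comp$protein_fraction, rna = comp$rna_fraction,
          dna = comp$dna_fraction, carb = comp$carb_fraction,
          lipid = comp$lipid_fraction)
  for (k in seq_len(nrow(pm)))
    col[pm$metabolite[k]] <- col[pm$metabolite[k]] -
      fr[[pm$polymer[k]]] * pm$weight[k] / pm$molar_mass[k]
  col["atp_c"] <- col["atp_c"] - gam$total
  col["h2o_c"] <- col["h2o_c"] - gam$total
  col["adp_c"] <- col["adp_c"] + gam$total
  col["pi_c"] <- col["pi_c"] + gam$total
  col
}

#' Yeast assimilable nitrogen of a state
#'
#' YAN in mg N/L: 14.007 times the millimolar nitrogen carried by ammonium
#' and the free amino acids (arginine contributes its four nitrogens).
#'
#' @param state named state vector (mM).
#' @param n_per_mmol named vector of nitrogen atoms per mmol of each state
#'   variable (only nitrogen sources count).
#' @return YAN, mg N/L.
#' @export
yan_of_state <- function(state, n_per_mmol) {
  vars <- names(n_per_mmol)[n_per_mmol > 0]
  14.007 * sum(pmax(state[vars], 0) * n_per_mmol[vars])
}

# Assemble phase-specific bounds and the patched S, solve the phase FBA.
# Returns list(v, mu, objective_value, weights).
fba_at_state <- function(ctx, params, state, phase, pfba = TRUE,
                         weight_cache = NULL) {
  conc <- pmax(state, 0)
  L <- ctx$L0; U <- ctx$U0; S <- ctx$S
  ex <- ctx$ex_idx

  vhex <- hexose_uptake_bounds(conc, params)
  L[ex[["glucose"]]] <- U[ex[["glucose"]]] <- vhex[["glucose"]]
  L[ex[["fructose"]]] <- U[ex[["fructose"]]] <- vhex[["fructose"]]

  nb <- nitrogen_uptake_bounds(conc, params, phase)
  for (v in names(nb)) {
    L[ex[[v]]] <- nb[[v]]; U[ex[[v]]] <- 0
  }
  vo2 <- oxygen_bound(conc, params)
  L[ex[["O2"]]] <- U[ex[["O2"]]] <- vo2

  prods <- product_constraints(vhex, params, phase, state = conc)
  for (v in names(prods)) {
    L[ex[[v]]] <- U[ex[[v]]] <- prods[[v]]
  }

  # stationary/decay: lipid-family excretion unconstrained
  iex <- ex[["mevalonate"]]
  if (phase %in% c("stationary", "decay")) {
    L[iex] <- 0; U[iex] <- default_bound()
  } else {
    L[iex] <- U[iex] <- 0
  }

  # dynamic biomass equation
  yan <- yan_of_state(conc, ctx$n_per_mmol)
  p <- protein_fraction_of_yan(yan, params$protein_curve)
  comp <- compose_biomass(p, rho = params$rho,
                          dna_fraction = params$dna_fraction,
                          lipid_fraction = params$lipid_fraction)
  S[, ctx$i_bio] <- biomass_column(ctx, comp, total_gam(comp, params$gam_f))
  comp2 <- carb_enriched_composition(comp, boost = params$carb_boost,
                                     rho = params$rho)
  S[, ctx$i_bioc] <- biomass_column(ctx, comp2, total_gam(comp2, params$gam_f))
  U[ctx$i_bio] <- if (phase == "exponential") default_bound() else 0
  U[ctx$i_bioc] <- if (phase == "n_limited") default_bound() else 0

  # phase objective (stationary/decay weights normalized per step)
  weights <- NULL
  if (phase %in% c("stationary", "decay")) {
    ids <- c(ctx$i_atpm, ctx$i_prot)
    if (!is.null(weight_cache) && !is.null(weight_cache[[phase]])) {
      w <- weight_cache[[phase]]
    } else {
      w <- c(1, 1)
      for (k in 1:2) {
        cv <- numeric(length(ctx$rids)); cv[ids[k]] <- 1
        s <- fba_lp(S, L, U, cv, pfba = FALSE)
        opt <- if (s$status == "optimal") s$objective_value else 0
        w[k] <- if (opt > 1e-9) 1 / opt else 1
      }
      if (!is.null(weight_cache)) weight_cache[[phase]] <- w
    }
    cvec <- numeric(length(ctx$rids)); cvec[ids] <- w
    weights <- setNames(w, c("atpm", "protein_synth"))
  } else {
    cvec <- numeric(length(ctx$rids))
    cvec[switch(phase, lag = ctx$i_atpm, exponential = ctx$i_bio,
                n_limited = ctx$i_bioc)] <- 1
  }

  sol <- fba_lp(S, L, U, cvec, pfba = pfba)
  if (sol$status != "optimal")
    stop("FBA ", sol$status, " in phase '", phase, "' (glucose = ",
         signif(conc[["glucose"]], 4), " mM, ethanol = ",
         signif(conc[["ethanol"]], 4), " mM); active equality bounds: ",
         paste(ctx$rids[abs(L - U) < 1e-12 & abs(L) > 1e-12], collapse = ", "))
  v <- setNames(sol$v, ctx$rids)
  list(v = v, mu = v[[ctx$i_bio]] + v[[ctx$i_bioc]],
       objective_value = sol$objective_value, weights = weights,
       sv_residual = max(abs(S %*% v)))
}

# time-derivatives of the extracellular state (the dFBA right-hand side)
dfba_rhs <- function(ctx, params, t, y, phase, pfba = TRUE,
                     weight_cache = NULL) {
  sol <- fba_at_state(ctx, params, y, phase, pfba = pfba,
                      weight_cache = weight_cache)
  DW <- max(y[["biomass"]], 0)
  dy <- numeric(length(y)); names(dy) <- names(y)
  for (v in ctx$vars) {
    d <- sol$v[[ctx$ex_idx[[v]]]] * DW
    if (y[[v]] <= 0 && d < 0) d <- 0   # clamp: nothing left to take up
    dy[v] <- d
  }
  kd <- if (phase == "decay") params$k_d else 0
  dy["biomass"] <- (sol$mu - kd) * DW
  dy
}

#' Simulate a five-phase batch fermentation by dynamic FBA
#'
#' Integrates the extracellular mass balances `dC/dt = v_ex(C) * DW`,
#' `dDW/dt = mu * DW`, where the exchange fluxes `v_ex` and the growth rate
#' `mu` come from the phase's (parsimonious) FBA problem solved under the
#' kinetic bounds at every integration step. The integrator restarts at each
#' phase boundary because objectives and constraints switch discontinuously;
#' state is continuous across boundaries, fluxes need not be.
#'
#' @param model a `metabolic_model` (typically [build_toy_model()] output).
#' @param params a `kinetic_parameters`.
#' @param schedule a `phase_schedule`.
#' @param initial_state named nonnegative vector: one entry per exchange-map
#'   variable (mM) plus `biomass` (gDW/L).
#' @param exchange_map state-variable to exchange-reaction map; defaults to
#'   the model's `exchange_map` attribute.
#' @param precursor_map biomass precursor map (see [toy_precursor_map()]).
#' @param options a [dfba_options()] list.
#' @return object of class `dfba_trajectory`: `times` (h), `states`
#'   (matrix, one row per accepted sample), `phases` (labels), `fluxes`
#'   (matrix time x reaction, pFBA solutions; `NULL` when
#'   `compute_fluxes = FALSE`), plus the inputs.
#' @export
simulate_dfba <- function(model, params, schedule, initial_state,
                          exchange_map = attr(model, "exchange_map"),
                          precursor_map = toy_precursor_map(),
                          options = dfba_options()) {
  if (is.null(exchange_map)) stop("exchange_map is required")
  if (any(initial_state < 0)) stop("initial state must be nonnegative")
  ctx <- dfba_context(model, exchange_map, precursor_map)
  need <- c(ctx$vars, "biomass")
  missing_vars <- setdiff(need, names(initial_state))
  if (length(missing_vars))
    stop("initial_state lacks: ", paste(missing_vars, collapse = ", "))
  y <- initial_state[need]

  bnds <- c(0, schedule$T_L, schedule$T_E, schedule$T_S, schedule$T_D,
            schedule$t_end)
  phases <- phase_levels()
  all_t <- numeric(0); all_y <- NULL; all_ph <- character(0)

  wcache <- if (isTRUE(options$normalize_each_step)) NULL else new.env()
  for (k in seq_len(5)) {
    t0 <- bnds[k]; t1 <- bnds[k + 1]; ph <- phases[k]
    if (options$method == "adams") {
      times <- seq(t0, t1, length.out = options$n_out + 1)
      fn <- function(t, y, parms) {
        names(y) <- need
        list(unname(dfba_rhs(ctx, params, t, y, ph, pfba = options$pfba_rhs,
                             weight_cache = wcache)))
      }
      out <- deSolve::ode(y = unname(y), times = times, func = fn, parms = NULL,
                          method = "adams", rtol = options$rtol,
                          atol = options$atol)
      seg_t <- out[, 1]; seg_y <- pmax(out[, -1, drop = FALSE], 0)
    } else {
      nst <- options$steps_per_phase
      h <- (t1 - t0) / nst
      seg_t <- t0 + h * (0:nst)
      seg_y <- matrix(NA_real_, nst + 1, length(y))
      seg_y[1, ] <- y
      yy <- y
      for (s in seq_len(nst)) {
        tt <- seg_t[s]
        f1 <- dfba_rhs(ctx, params, tt, yy, ph, pfba = options$pfba_rhs,
                       weight_cache = wcache)
        y1 <- pmax(yy + h * f1, 0)
        f2 <- dfba_rhs(ctx, params, tt + h, y1, ph, pfba = options$pfba_rhs,
                       weight_cache = wcache)
        yy <- pmax(yy + h / 2 * (f1 + f2), 0)
        seg_y[s + 1, ] <- yy
      }
    }
    colnames(seg_y) <- need
    keep <- if (k < 5) seq_len(nrow(seg_y) - 1L) else seq_len(nrow(seg_y))
    all_t <- c(all_t, seg_t[keep])
    all_y <- rbind(all_y, seg_y[keep, , drop = FALSE])
    all_ph <- c(all_ph, rep(ph, length(keep)))
    y <- setNames(seg_y[nrow(seg_y), ], need)
  }

  fluxes <- NULL; sv_residual <- NULL
  if (options$compute_fluxes) {
    fluxes <- matrix(NA_real_, length(all_t), length(ctx$rids),
                     dimnames = list(NULL, ctx$rids))
    sv_residual <- numeric(length(all_t))
    for (i in seq_along(all_t)) {
      sol <- fba_at_state(ctx, params, setNames(all_y[i, ], need), all_ph[i],
                          pfba = TRUE)
      fluxes[i, ] <- sol$v
      sv_residual[i] <- sol$sv_residual
    }
  }

  structure(list(times = all_t, states = all_y, phases = all_ph,
                 fluxes = fluxes, sv_residual = sv_residual, model = model,
                 params = params, schedule = schedule,
                 exchange_map = exchange_map, options = options),
            class = "dfba_trajectory")
}

#' @export
print.dfba_trajectory <- function(x, ...) {
  cat("dFBA trajectory:", length(x$times), "samples over",
      format(max(x$times)), "h\n")
  cat("  phases:", paste(rle(x$phases)$values, collapse = " -> "), "\n")
  fin <- x$states[nrow(x$states), ]
  cat("  final biomass:", signif(fin[["biomass"]], 4), "gDW/L;",
      "glucose:", signif(fin[["glucose"]], 4), "mM;",
      "ethanol:", signif(fin[["ethanol"]], 4), "mM\n")
  invisible(x)
}

#' @export
plot.dfba_trajectory <- function(x, vars = c("glucose", "fructose", "ethanol",
                                             "biomass"), ...) {
  y <- x$states[, vars, drop = FALSE]
  matplot(x$times, y, type = "l", lty = 1, xlab = "time (h)",
          ylab = "concentration", ...)
  abline(v = unlist(x$schedule[c("T_L", "T_E", "T_S", "T_D")]), lty = 3,
         col = "grey")
  legend("topright", legend = vars, col = seq_along(vars), lty = 1, bty = "n")
  invisible(x)
}

#' @export
as.data.frame.dfba_trajectory <- function(x, ...) {
  data.frame(time_h = x$times, phase = x$phases, x$states,
             check.names = FALSE)
}
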