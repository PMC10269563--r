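#' Phase schedule of a batch fermentation
#'
#' The five phases — lag, exponential growth, growth under nitrogen
#' limitation, stationary, decay — are delimited by the (estimated) boundary
#' times `T_L < T_E < T_S < T_D <= t_end` (hours).
#'
#' @param T_L,T_E,T_S,T_D phase end times (h).
#' @param t_end end of simulation (h).
#' @return object of class `phase_schedule`.
#' @export
phase_schedule <- function(T_L, T_E, T_S, T_D, t_end) {
  if (!(0 < T_L && T_L < T_E && T_E < T_S && T_S < T_D && T_D <= t_end))
    stop("phase times must satisfy 0 < T_L < T_E < T_S < T_D <= t_end")
  structure(list(T_L = T_L, T_E = T_E, T_S = T_S, T_D = T_D, t_end = t_end),
            class = "phase_schedule")
}

#' Phase containing a time point
#'
#' Half-open assignment: `[0, T_L)` lag, `[T_L, T_E)` exponential,
#' `[T_E, T_S)` nitrogen-limited, `[T_S, T_D)` stationary, `[T_D, t_end]`
#' decay. Boundaries belong to the phase they start.
#'
#' @param t time (h) within `[0, t_end]`.
#' @param schedule a `phase_schedule`.
#' @return one of `"lag"`, `"exponential"`, `"n_limited"`, `"stationary"`,
#'   `"decay"`.
#' @export
phase_of <- function(t, schedule) {
  if (t < 0 || t > schedule$t_end)
    stop("t = ", t, " outside [0, ", schedule$t_end, "]")
  if (t < schedule$T_L) "lag"
  else if (t < schedule$T_E) "exponential"
  else if (t < schedule$T_S) "n_limited"
  else if (t < schedule$T_D) "stationary"
  else "decay"
}

phase_levels <- function() c("lag", "exponential", "n_limited", "stationary", "decay")

#' Cellular objective of a fermentation phase
#'
#' Lag: maximize ATPase expenditure (maintenance ATP hydrolysis).
#' Exponential growth: maximize the growth rate (biomass pseudoreaction).
#' Nitrogen-limited growth: maximize growth through the
#' carbohydrate-enriched biomass variant. Stationary and decay: maximize the
#' production of both ATP and protein — scalarized as a weighted sum in
#' which each flux is weighted by the reciprocal of its standalone optimum
#' under the current bounds, so neither term dominates on units.
#'
#' @param phase phase id.
#' @param model a `metabolic_model` (needed for the stationary/decay
#'   normalization; optional otherwise).
#' @param lb,ub optional bound overrides forwarded to the normalization LPs.
#' @param atpm_id,protein_id,biomass_id,biomass_carb_id reaction ids.
#' @return named numeric vector of nonnegative objective weights.
#' @export
build_objective <- function(phase, model = NULL, lb = NULL, ub = NULL,
                            atpm_id = "atpm", protein_id = "protein_synth",
                            biomass_id = "biomass",
                            biomass_carb_id = "biomass_carb") {
  switch(phase,
    lag = setNames(1, atpm_id),
    exponential = setNames(1, biomass_id),
    n_limited = setNames(1, biomass_carb_id),
    stationary = ,
    decay = {
      w <- c(1, 1)
      if (!is.null(model)) {
        for (k in 1:2) {
          id <- c(atpm_id, protein_id)[k]
          s <- solve_fba(model, setNames(1, id), lb = lb, ub = ub, pfba = FALSE)
          opt <- if (s$status == "optimal") s$objective_value else 0
          w[k] <- if (opt > 1e-9) 1 / opt else 1
        }
      }
      setNames(w, c(atpm_id, protein_id))
    },
    stop("unknown phase: ", phase))
}
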