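#' Maximum stoichiometric yield of a product from a substrate
#'
#' Answers "how many millimoles of product can the network make per millimole
#' of substrate, and what does that cost in a tracked cofactor?" — the desk
#' check behind claims such as "three acetyl-CoA and two NADPH per mevalonate
#' made from acetate" or "one NADPH produced per succinate via the GABA
#' shunt".
#'
#' All exchange reactions are closed. A temporary source injects the
#' substrate at exactly 1 mmol, a temporary drain exports the product freely,
#' and the caller declares which inorganic/cofactor pools may be balanced
#' externally (`sinks`). The LP maximizes product export under `S v = 0`; the
#' parsimonious refinement then makes the reported route and cofactor
#' bookkeeping unique. If a cofactor pair is tracked, a regeneration
#' pseudo-reaction converting its oxidized into its reduced form is added and
#' its flux at the optimum is the net cofactor consumption (negative = the
#' pathway produces the cofactor).
#'
#' @param model a `metabolic_model`.
#' @param substrate metabolite id injected at 1 mmol.
#' @param product metabolite id whose export is maximized.
#' @param tracked_cofactor `NULL`, or a character vector
#'   `c(from = <oxidized id>, to = <reduced id>)` (e.g.
#'   `c(from = "nadp_c", to = "nadph_c")`), or a single metabolite id for an
#'   unpaired pool.
#' @param sinks list of balancing pseudo-reactions the caller allows: each
#'   element either a metabolite id (free drain) or a named stoichiometry
#'   vector (free interconversion, e.g. ATP regeneration).
#' @return list with `yield` (mmol product per mmol substrate),
#'   `substrate_per_product` (its reciprocal, `Inf` when the yield is 0),
#'   `cofactor_per_product` (net tracked-cofactor consumption per mmol
#'   product, `NA` when untracked or yield 0), `status`, and `v` (the full
#'   pFBA flux vector of the yield optimum).
#' @export
pathway_yield <- function(model, substrate, product, tracked_cofactor = NULL,
                          sinks = list()) {
  stopifnot(substrate %in% model$metabolites$id)
  if (!product %in% model$metabolites$id) stop("unknown product: ", product)

  # close every exchange
  for (rid in model$reactions$id)
    if (is_exchange(model, rid)) {
      i <- match(rid, model$reactions$id)
      model$reactions$lower_bound[i] <- 0
      model$reactions$upper_bound[i] <- 0
    }
  # shut the biomass drain too
  ib <- match(model$biomass_reaction_id, model$reactions$id)
  model$reactions$lower_bound[ib] <- 0; model$reactions$upper_bound[ib] <- 0

  # caller-declared balancing sinks
  snames <- names(sinks); if (is.null(snames)) snames <- rep("", length(sinks))
  for (k in seq_along(sinks)) {
    s <- sinks[[k]]
    id <- if (nzchar(snames[k])) paste0("SINK_", snames[k]) else paste0("SINK_", k)
    st <- if (is.character(s)) setNames(-1, s) else s
    model <- add_reaction(model, id, st, name = id, subsystem = "pseudo")
  }

  # tracked cofactor regeneration
  track_id <- NULL
  if (!is.null(tracked_cofactor)) {
    track_id <- "REGEN_tracked"
    st <- if (length(tracked_cofactor) == 2L)
      setNames(c(-1, 1), c(tracked_cofactor[["from"]], tracked_cofactor[["to"]]))
    else setNames(1, tracked_cofactor)
    model <- add_reaction(model, track_id, st, name = "tracked cofactor regeneration",
                          subsystem = "pseudo")
  }

  model <- add_reaction(model, "SRC_substrate", setNames(1, substrate),
                        lb = 1, ub = 1, subsystem = "pseudo")
  model <- add_reaction(model, "PRD_product", setNames(-1, product),
                        lb = 0, ub = Inf, subsystem = "pseudo")

  sol <- solve_fba(model, c(PRD_product = 1), pfba = TRUE)
  if (sol$status == "unbounded")
    stop("pathway yield unbounded: the model leaks ", product)
  if (sol$status != "optimal")
    return(list(yield = 0, substrate_per_product = Inf,
                cofactor_per_product = NA_real_, status = sol$status,
                v = NULL))
  y <- sol$objective_value
  cof <- NA_real_
  if (!is.null(track_id) && y > 1e-12) cof <- sol$v[[track_id]] / y
  list(yield = y,
       substrate_per_product = if (y > 1e-12) 1 / y else Inf,
       cofactor_per_product = cof,
       status = "optimal", v = sol$v)
}
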