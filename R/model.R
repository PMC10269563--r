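#' Compartmental stoichiometric models
#'
#' A `metabolic_model` holds metabolites, reactions with bounds, and the id of
#' the biomass pseudoreaction. Stoichiometry is stored per reaction as a named
#' numeric vector of metabolite coefficients (negative = consumed). Exchange
#' reactions touch exactly one extracellular metabolite with coefficient -1,
#' so negative exchange flux means uptake and positive flux means export —
#' the usual constraint-based-modelling convention.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment` and
#'   optionally `carbons`, `nitrogens` (simplified elemental bookkeeping).
#' @param reactions data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound` and optionally `subsystem` (reactions in subsystem
#'   `"pseudo"` and exchanges are exempt from elemental balance checks).
#' @param stoichiometry named list (by reaction id) of named numeric vectors
#'   (by metabolite id).
#' @param biomass_reaction_id id of the biomass pseudoreaction.
#' @param compartments character vector of compartment ids; defaults to the
#'   set used by the metabolites.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            biomass_reaction_id, compartments = NULL) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$carbons)) metabolites$carbons <- NA_real_
  if (is.null(metabolites$nitrogens)) metabolites$nitrogens <- NA_real_
  if (is.null(reactions$subsystem)) reactions$subsystem <- ""
  if (is.null(compartments)) compartments <- unique(metabolites$compartment)
  m <- structure(list(metabolites = metabolites, reactions = reactions,
                      stoichiometry = stoichiometry,
                      biomass_reaction_id = biomass_reaction_id,
                      compartments = compartments),
                 class = "metabolic_model")
  validate_model(m)
  m
}

#' Validate a metabolic model's structural invariants
#'
#' Checks id uniqueness, that every stoichiometry key resolves to a metabolite,
#' bound consistency, non-empty reactions, and that exchange reactions touch
#' exactly one extracellular metabolite.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; errors describe the offending element.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites; rxns <- model$reactions
  if (anyDuplicated(mets$id)) stop("duplicate metabolite id: ",
                                   mets$id[duplicated(mets$id)][1])
  if (anyDuplicated(rxns$id)) stop("duplicate reaction id: ",
                                   rxns$id[duplicated(rxns$id)][1])
  if (nrow(rxns) == 0L) stop("no reactions")
  if (!all(mets$compartment %in% model$compartments))
    stop("metabolite compartment outside the declared compartment set")
  if (!setequal(names(model$stoichiometry), rxns$id))
    stop("stoichiometry entries do not match reaction ids")
  for (rid in rxns$id) {
    st <- model$stoichiometry[[rid]]
    if (length(st) == 0L || all(st == 0)) stop("reaction without nonzero coefficients: ", rid)
    unknown <- setdiff(names(st), mets$id)
    if (length(unknown))
      stop("reaction ", rid, " references unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
  }
  bad <- rxns$id[rxns$lower_bound > rxns$upper_bound]
  if (length(bad)) stop("lower_bound > upper_bound for: ", paste(bad, collapse = ", "))
  if (!model$biomass_reaction_id %in% rxns$id)
    stop("biomass reaction '", model$biomass_reaction_id, "' not present")
  invisible(model)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return dense numeric matrix, one row per metabolite, one column per
#'   reaction, in the model's declared order.
#' @export
stoichiometric_matrix <- function(model) {
  mids <- model$metabolites$id; rids <- model$reactions$id
  S <- matrix(0, length(mids), length(rids), dimnames = list(mids, rids))
  for (k in seq_along(rids)) {
    st <- model$stoichiometry[[rids[k]]]
    S[names(st), k] <- st
  }
  S
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model:", nrow(x$metabolites), "metabolites,",
      nrow(x$reactions), "reactions\n")
  cat("  compartments:", paste(x$compartments, collapse = ", "), "\n")
  cat("  biomass reaction:", x$biomass_reaction_id, "\n")
  nex <- sum(vapply(x$reactions$id, function(r) is_exchange(x, r), logical(1)))
  cat("  exchange reactions:", nex, "\n")
  invisible(x)
}

#' Test whether a reaction is an exchange reaction
#'
#' @param model a `metabolic_model`.
#' @param rid reaction id.
#' @param extracellular compartment id treated as the boundary side.
#' @return logical.
#' @export
is_exchange <- function(model, rid, extracellular = "e") {
  st <- model$stoichiometry[[rid]]
  if (length(st) != 1L) return(FALSE)
  comp <- model$metabolites$compartment[match(names(st), model$metabolites$id)]
  identical(comp, extracellular)
}

#' Find the exchange reaction of an extracellular species
#' @param model a `metabolic_model`.
#' @param species_id extracellular metabolite id.
#' @return reaction id, or `NA_character_` if none exists.
#' @export
find_exchange <- function(model, species_id) {
  for (rid in model$reactions$id) {
    st <- model$stoichiometry[[rid]]
    if (length(st) == 1L && names(st) == species_id) return(rid)
  }
  NA_character_
}

#' Remove reactions from a model
#'
#' Metabolites left orphaned (no longer referenced by any reaction) are
#' retained, not pruned, so the stoichiometric-matrix row indexing is stable
#' across curation steps; orphans are reported in a message.
#'
#' @param model a `metabolic_model`.
#' @param ids reaction ids to remove; duplicates are deduplicated; an empty
#'   vector returns the model unchanged.
#' @return the curated `metabolic_model`.
#' @export
remove_reactions <- function(model, ids) {
  ids <- unique(as.character(ids))
  if (length(ids) == 0L) return(model)
  unknown <- setdiff(ids, model$reactions$id)
  if (length(unknown))
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  if (model$biomass_reaction_id %in% ids)
    stop("cannot remove the biomass pseudoreaction")
  keep <- !(model$reactions$id %in% ids)
  model$reactions <- model$reactions[keep, , drop = FALSE]
  model$stoichiometry <- model$stoichiometry[model$reactions$id]
  used <- unique(unlist(lapply(model$stoichiometry, names)))
  orphans <- setdiff(model$metabolites$id, used)
  if (length(orphans))
    message("orphaned metabolites retained: ", paste(orphans, collapse = ", "))
  validate_model(model)
  model
}

#' Add a reaction to a model
#'
#' @param model a `metabolic_model`.
#' @param id,name reaction id and display name.
#' @param stoich named numeric vector of metabolite coefficients.
#' @param lb,ub flux bounds, mmol/(gDW h).
#' @param subsystem optional subsystem tag.
#' @return the extended model.
#' @export
add_reaction <- function(model, id, stoich, name = id,
                         lb = -default_bound(), ub = default_bound(),
                         subsystem = "") {
  if (id %in% model$reactions$id) stop("reaction id already present: ", id)
  missing_met <- setdiff(names(stoich), model$metabolites$id)
  if (length(missing_met))
    stop("missing metabolite ", paste(missing_met, collapse = ", "))
  model$reactions <- rbind(model$reactions,
                           data.frame(id = id, name = name, lower_bound = lb,
                                      upper_bound = ub, subsystem = subsystem,
                                      stringsAsFactors = FALSE))
  model$stoichiometry[[id]] <- stoich
  model
}

#' Conventional "large" flux bound
#'
#' 1000 mmol/(gDW h), the constraint-based-modelling convention for an
#' effectively unbounded flux.
#' @return numeric scalar.
#' @export
default_bound <- function() 1000

#' Add the erythritol production branch
#'
#' Appends the two-step erythritol pathway — dephosphorylation of
#' erythrose-4-phosphate to erythrose, then NADPH-dependent reduction of
#' erythrose to erythritol — plus an exchange reaction exporting erythritol
#' to the extracellular compartment. Reaction ids are fixed (`ery1`, `ery2`,
#' `EX_erythritol_e`) so that flux-ratio reports are reproducible across
#' models. Applying the operation to a model that already carries the branch
#' is an idempotent no-op (with a warning).
#'
#' @param model a `metabolic_model` containing cytoplasmic
#'   erythrose-4-phosphate (`e4p_c`), phosphate (`pi_c`), NADPH (`nadph_c`),
#'   NADP+ (`nadp_c`) and H+ (`h_c`).
#' @param ids optional list overriding the metabolite ids used above.
#' @return the extended model.
#' @export
add_erythritol_pathway <- function(model,
                                   ids = list(e4p = "e4p_c", pi = "pi_c",
                                              nadph = "nadph_c", nadp = "nadp_c",
                                              h = "h_c")) {
  if (all(c("ery1", "ery2", "EX_erythritol_e") %in% model$reactions$id)) {
    warning("erythritol pathway already present; model returned unchanged")
    return(model)
  }
  for (need in c("e4p", "pi", "nadph", "nadp", "h"))
    if (!ids[[need]] %in% model$metabolites$id)
      stop("missing metabolite ", ids[[need]])
  if (!"erythrose_c" %in% model$metabolites$id)
    model$metabolites <- rbind(model$metabolites,
      data.frame(id = "erythrose_c", name = "erythrose", compartment = "c",
                 carbons = 4, nitrogens = 0, stringsAsFactors = FALSE))
  if (!"erythritol_c" %in% model$metabolites$id)
    model$metabolites <- rbind(model$metabolites,
      data.frame(id = "erythritol_c", name = "erythritol", compartment = "c",
                 carbons = 4, nitrogens = 0, stringsAsFactors = FALSE))
  if (!"erythritol_e" %in% model$metabolites$id)
    model$metabolites <- rbind(model$metabolites,
      data.frame(id = "erythritol_e", name = "erythritol", compartment = "e",
                 carbons = 4, nitrogens = 0, stringsAsFactors = FALSE))
  st1 <- setNames(c(-1, 1, 1), c(ids$e4p, "erythrose_c", ids$pi))
  st2 <- setNames(c(-1, -1, -1, 1, 1),
                  c("erythrose_c", ids$nadph, ids$h, "erythritol_c", ids$nadp))
  model <- add_reaction(model, "ery1", st1,
                        name = "erythrose-4-phosphate phosphatase",
                        lb = 0, subsystem = "erythritol")
  model <- add_reaction(model, "ery2", st2, name = "erythrose reductase (NADPH)",
                        lb = 0, subsystem = "erythritol")
  model <- add_reaction(model, "ERYTt", setNames(c(-1, 1), c("erythritol_c", "erythritol_e")),
                        name = "erythritol export", lb = 0, subsystem = "erythritol")
  model <- add_reaction(model, "EX_erythritol_e", c(erythritol_e = -1),
                        name = "erythritol exchange", lb = 0, subsystem = "exchange")
  validate_model(model)
  model
}

#' Open unconstrained excretion for a set of species
#'
#' Ensures each species has an exchange reaction with export unbounded (upper
#' bound = the conventional large bound) and import closed (lower bound 0).
#' Used by the dynamic FBA engine to free lipid-family excretion during the
#' stationary phase. Already-open exchanges are left unchanged, so the
#' operation is idempotent.
#'
#' @param model a `metabolic_model`.
#' @param species_ids extracellular metabolite ids; empty vector = identity.
#' @return the model with the requested exchanges open.
#' @export
open_excretion <- function(model, species_ids) {
  if (length(species_ids) == 0L) return(model)
  unknown <- setdiff(species_ids, model$metabolites$id)
  if (length(unknown)) stop("unknown species: ", paste(unknown, collapse = ", "))
  for (sp in species_ids) {
    ex <- find_exchange(model, sp)
    if (is.na(ex)) {
      model <- add_reaction(model, paste0("EX_", sp), setNames(-1, sp),
                            name = paste("exchange", sp), lb = 0,
                            ub = default_bound(), subsystem = "exchange")
    } else {
      i <- match(ex, model$reactions$id)
      if (model$reactions$upper_bound[i] < default_bound())
        model$reactions$upper_bound[i] <- default_bound()
      if (model$reactions$lower_bound[i] < 0)
        model$reactions$lower_bound[i] <- 0
    }
  }
  model
}

#' Check simplified elemental balance of a model
#'
#' Verifies carbon and nitrogen conservation for every internal reaction with
#' complete elemental annotation. Exchange reactions, transport of a single
#' species between compartments and pseudoreactions (subsystem `"pseudo"`)
#' are exempt. For models lacking annotation the check is advisory (warning);
#' with `strict = TRUE` imbalances are errors.
#'
#' @param model a `metabolic_model`.
#' @param strict error on imbalance instead of warning.
#' @param tol allowed absolute imbalance per element.
#' @return data.frame of per-reaction carbon/nitrogen imbalances, invisibly.
#' @export
check_elemental_balance <- function(model, strict = FALSE, tol = 1e-9) {
  mets <- model$metabolites
  out <- data.frame(id = character(), carbon = numeric(), nitrogen = numeric(),
                    stringsAsFactors = FALSE)
  for (rid in model$reactions$id) {
    sub <- model$reactions$subsystem[match(rid, model$reactions$id)]
    if (identical(sub, "pseudo") || identical(sub, "exchange")) next
    if (is_exchange(model, rid)) next
    st <- model$stoichiometry[[rid]]
    idx <- match(names(st), mets$id)
    if (anyNA(mets$carbons[idx])) next   # unannotated: skip
    cimb <- sum(st * mets$carbons[idx])
    nimb <- sum(st * mets$nitrogens[idx])
    if (abs(cimb) > tol || abs(nimb) > tol)
      out <- rbind(out, data.frame(id = rid, carbon = cimb, nitrogen = nimb,
                                   stringsAsFactors = FALSE))
  }
  if (nrow(out)) {
    msg <- paste0("elementally unbalanced reaction(s): ",
                  paste(out$id, collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  invisible(out)
}

#' Summarize a model as a plain list (JSON-ready)
#'
#' @param model a `metabolic_model`.
#' @return list with counts, compartments and bound extrema.
#' @export
model_summary <- function(model) {
  list(n_metabolites = nrow(model$metabolites),
       n_reactions = nrow(model$reactions),
       compartments = model$compartments,
       biomass_reaction = model$biomass_reaction_id,
       min_lower_bound = min(model$reactions$lower_bound),
       max_upper_bound = max(model$reactions$upper_bound))
}
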