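#' Protein mass fraction of biomass as a function of assimilable nitrogen
#'
#' The protein content of newly formed cell mass rises with yeast assimilable
#' nitrogen (YAN). The dependence is modelled as a two-parameter saturating
#' curve with a floor:
#' `p(yan) = p_min + (p_max - p_min) * yan / (yan + k_p)` —
#' smooth, monotone nondecreasing, and calibrated per condition from the
#' initial-must protein content.
#'
#' @param yan yeast assimilable nitrogen, mg N/L (>= 0).
#' @param params list with `p_min`, `p_max` (mass fractions) and `k_p`
#'   (half-saturation, mg N/L).
#' @return protein mass fraction in `[p_min, p_max]`.
#' @export
protein_fraction_of_yan <- function(yan, params) {
  if (params$p_min > params$p_max) stop("p_min must not exceed p_max")
  yan <- pmax(yan, 0)
  params$p_min + (params$p_max - params$p_min) * yan / (yan + params$k_p)
}

#' Compose the macromolecular biomass fractions
#'
#' RNA is proportional to protein (`rna = rho * protein`); DNA and lipid are
#' fixed; carbohydrates absorb all remaining mass so the fractions close to 1.
#'
#' @param protein_fraction protein mass fraction (g/gDW).
#' @param rho mRNA:protein mass ratio (default 0.05 g/g).
#' @param dna_fraction,lipid_fraction fixed mass fractions.
#' @return object of class `biomass_composition`: list of the five fractions.
#' @export
compose_biomass <- function(protein_fraction, rho = 0.05,
                            dna_fraction = 0.01, lipid_fraction = 0.05) {
  rna <- rho * protein_fraction
  carb <- 1 - protein_fraction - rna - dna_fraction - lipid_fraction
  if (carb < -1e-12)
    stop("composition error: protein fraction too high, carbohydrate remainder ",
         format(carb), " is negative")
  comp <- list(protein_fraction = protein_fraction, rna_fraction = rna,
               carb_fraction = max(carb, 0), dna_fraction = dna_fraction,
               lipid_fraction = lipid_fraction)
  stopifnot(abs(do.call(sum, comp) - 1) < 1e-9)
  structure(comp, class = "biomass_composition")
}

#' Default polymerization ATP costs
#'
#' Literature polymerization costs per gram of polymer formed
#' (mmol ATP/g): peptide-bond formation dominates, nucleic-acid and
#' glycogen-type polymerization are cheaper. Overridable wherever a
#' `unit_costs` argument is accepted.
#'
#' @return named numeric vector (protein, rna, dna, carb), mmol ATP per g.
#' @export
gam_unit_costs <- function() {
  c(protein = 37.7, rna = 10.0, dna = 10.0, carb = 12.8)
}

#' Growth-associated maintenance (GAM) decomposition
#'
#' Total GAM is the sum of a species/strain-dependent fitted component
#' `gam_f` (maintenance not attributable to polymerization: turnover, leakage
#' repair) and the polymerization costs of each macromolecular class,
#' `fraction x unit cost`:
#' `GAM = GAM_F + GAM_prot + GAM_RNA + GAM_carb + GAM_DNA`.
#'
#' @param comp a `biomass_composition`.
#' @param gam_f fitted non-polymerization maintenance, mmol ATP/gDW (>= 0).
#' @param unit_costs per-polymer ATP costs, mmol ATP per g (see
#'   [gam_unit_costs()]).
#' @return object of class `gam_breakdown`: components and `total`, mmol
#'   ATP per gDW of biomass formed.
#' @export
total_gam <- function(comp, gam_f, unit_costs = gam_unit_costs()) {
  stopifnot(gam_f >= 0)
  g <- list(gam_f = gam_f,
            gam_prot = comp$protein_fraction * unit_costs[["protein"]],
            gam_rna = comp$rna_fraction * unit_costs[["rna"]],
            gam_carb = comp$carb_fraction * unit_costs[["carb"]],
            gam_dna = comp$dna_fraction * unit_costs[["dna"]])
  g$total <- g$gam_f + g$gam_prot + g$gam_rna + g$gam_carb + g$gam_dna
  structure(g, class = "gam_breakdown")
}

#' @export
print.gam_breakdown <- function(x, ...) {
  cat("GAM decomposition (mmol ATP/gDW):\n")
  cat(sprintf("  fitted (GAM_F): %8.2f\n", x$gam_f))
  cat(sprintf("  protein:        %8.2f\n", x$gam_prot))
  cat(sprintf("  RNA:            %8.2f\n", x$gam_rna))
  cat(sprintf("  carbohydrate:   %8.2f\n", x$gam_carb))
  cat(sprintf("  DNA:            %8.2f\n", x$gam_dna))
  cat(sprintf("  total:          %8.2f\n", x$total))
  invisible(x)
}

#' Rewrite a biomass pseudoreaction for a given composition and GAM
#'
#' Rescales the monomer coefficients of the biomass pseudoreaction so that
#' the monomer mass consumed per unit biomass flux equals 1 g per gDW at the
#' requested macromolecular composition, and sets the ATP-hydrolysis
#' stoichiometry (ATP + H2O -> ADP + Pi) to the total GAM — the convention of
#' the consensus yeast models, where maintenance ATP lives inside the biomass
#' equation.
#'
#' @param model a `metabolic_model`.
#' @param comp a `biomass_composition`.
#' @param gam a `gam_breakdown`.
#' @param precursor_map data.frame with columns `polymer` (one of protein,
#'   rna, dna, carb, lipid), `metabolite` (model id), `molar_mass` (g/mmol),
#'   `weight` (within-polymer mass weight; weights of a polymer sum to 1).
#' @param reaction_id biomass reaction to (re)write; defaults to the model's
#'   declared biomass pseudoreaction. A new id is added as an extra
#'   pseudoreaction (used for the carbohydrate-enriched biomass variant).
#' @param energy_ids ids for the ATP hydrolysis quartet.
#' @return the model with the updated pseudoreaction.
#' @export
update_biomass_reaction <- function(model, comp, gam, precursor_map,
                                    reaction_id = model$biomass_reaction_id,
                                    energy_ids = c(atp = "atp_c", adp = "adp_c",
                                                   pi = "pi_c", h2o = "h2o_c")) {
  missing_met <- setdiff(unique(precursor_map$metabolite), model$metabolites$id)
  if (length(missing_met))
    stop("precursor absent from model: ", paste(missing_met, collapse = ", "))
  fr <- c(protein = comp$protein_fraction, rna = comp$rna_fraction,
          dna = comp$dna_fraction, carb = comp$carb_fraction,
          lipid = comp$lipid_fraction)
  st <- numeric(0)
  for (k in seq_len(nrow(precursor_map))) {
    p <- precursor_map$polymer[k]
    coef <- fr[[p]] * precursor_map$weight[k] / precursor_map$molar_mass[k]
    met <- precursor_map$metabolite[k]
    st[met] <- (if (met %in% names(st)) st[[met]] else 0) - coef
  }
  for (m in c("atp", "h2o"))
    st[energy_ids[[m]]] <- (if (energy_ids[[m]] %in% names(st)) st[[energy_ids[[m]]]] else 0) - gam$total
  for (m in c("adp", "pi"))
    st[energy_ids[[m]]] <- (if (energy_ids[[m]] %in% names(st)) st[[energy_ids[[m]]]] else 0) + gam$total
  st <- st[abs(st) > 0]
  if (reaction_id %in% model$reactions$id) {
    model$stoichiometry[[reaction_id]] <- st
  } else {
    model <- add_reaction(model, reaction_id, st, name = reaction_id,
                          lb = 0, ub = default_bound(), subsystem = "pseudo")
  }
  model
}
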