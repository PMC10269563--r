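#' Build the bundled toy yeast network
#'
#' A hand-curated three-compartment (extracellular, cytoplasm, mitochondrion)
#' stoichiometric model of fermentative yeast metabolism, small enough for
#' desk-scale linear programs yet realizing the pathways that matter for
#' batch wine fermentation: lumped glycolysis, the oxidative and
#' non-oxidative pentose phosphate pathway with the erythritol branch,
#' pyruvate fermentation to ethanol, acetate formation and its activation to
#' acetyl-CoA (AMP-producing, serviced by adenylate kinase), the mevalonate
#' route, the oxidative TCA branch to 2-oxoglutarate and the cytosolic
#' reductive branch to succinate, the malate/2-oxoglutarate antiporter, the
#' GABA shunt, Ehrlich routes to isoamyl alcohol, isobutanol and
#' 2-phenylethanol with parallel NADH/NADPH reductions, the
#' ethanol-acetaldehyde mitochondrial shuttle, the glycerol branch,
#' 2,3-butanediol and malate as redox overflow valves, respiration while
#' dissolved oxygen lasts, ATP maintenance, nitrogen assimilation (ammonium,
#' three generic amino acids, arginine) and a nitrogen-dependent biomass
#' pseudoreaction (plus its carbohydrate-enriched variant).
#'
#' Every internal reaction is carbon- and nitrogen-balanced under the model's
#' simplified elemental annotation (cofactor carriers are treated as
#' carbon-free; acyl groups carry only their transferable carbons).
#'
#' @param composition optional `biomass_composition` used to seed the biomass
#'   pseudoreaction (default: composition at 0.41 protein).
#' @param gam_f fitted maintenance used to seed the biomass reaction.
#' @return a `metabolic_model` with attributes `exchange_map` (state
#'   variable -> exchange reaction id) and `molar_mass` (g/mmol per state
#'   variable).
#' @export
build_toy_model <- function(composition = compose_biomass(0.41),
                            gam_f = 77.5) {
  met <- function(id, comp, C = 0, N = 0, name = id)
    data.frame(id = id, name = name, compartment = comp, carbons = C,
               nitrogens = N, stringsAsFactors = FALSE)
  mets <- rbind(
    # extracellular
    met("glc_e", "e", 6), met("frc_e", "e", 6), met("o2_e", "e"),
    met("nh4_e", "e", 0, 1), met("aa1_e", "e", 3, 1), met("aa2_e", "e", 5, 1),
    met("aa3_e", "e", 9, 1), met("arg_e", "e", 6, 4),
    met("etoh_e", "e", 2), met("glyc_e", "e", 3), met("succ_e", "e", 4),
    met("ac_e", "e", 2), met("mal_e", "e", 4), met("btd_e", "e", 4),
    met("iamoh_e", "e", 5), met("ibutoh_e", "e", 4), met("peth_e", "e", 8),
    met("mev_e", "e", 6), met("actn_e", "e", 4), met("co2_e", "e", 1),
    # cytosol
    met("glc_c", "c", 6), met("frc_c", "c", 6), met("g6p_c", "c", 6),
    met("t3p_c", "c", 3), met("pyr_c", "c", 3), met("acald_c", "c", 2),
    met("etoh_c", "c", 2), met("ac_c", "c", 2), met("accoa_c", "c", 2),
    met("aacoa_c", "c", 4), met("hmgcoa_c", "c", 6), met("mev_c", "c", 6),
    met("p5p_c", "c", 5), met("e4p_c", "c", 4), met("glyc3p_c", "c", 3),
    met("glyc_c", "c", 3), met("oaa_c", "c", 4), met("mal_c", "c", 4),
    met("fum_c", "c", 4), met("succ_c", "c", 4), met("akg_c", "c", 5),
    met("glu_c", "c", 5, 1), met("gaba_c", "c", 4, 1), met("ssa_c", "c", 4),
    met("aa1_c", "c", 3, 1), met("aa3_c", "c", 9, 1), met("arg_c", "c", 6, 4),
    met("phepyr_c", "c", 9), met("pacald_c", "c", 8), met("peth_c", "c", 8),
    met("tmob_c", "c", 5), met("ketoleu_c", "c", 6), met("mbald_c", "c", 5),
    met("iamoh_c", "c", 5), met("ibutal_c", "c", 4), met("ibutoh_c", "c", 4),
    met("btd_c", "c", 4), met("actn_c", "c", 4), met("nh4_c", "c", 0, 1),
    met("co2_c", "c", 1),
    met("o2_c", "c"), met("atp_c", "c"), met("adp_c", "c"), met("amp_c", "c"),
    met("pi_c", "c"), met("h2o_c", "c"), met("h_c", "c"),
    met("nad_c", "c"), met("nadh_c", "c"), met("nadp_c", "c"),
    met("nadph_c", "c"), met("nucmono_c", "c", 9, 4),
    met("protein_c", "c", 5, 1),
    # mitochondrion
    met("pyr_m", "m", 3), met("accoa_m", "m", 2), met("oaa_m", "m", 4),
    met("akg_m", "m", 5), met("mal_m", "m", 4), met("acald_m", "m", 2),
    met("etoh_m", "m", 2), met("tmob_m", "m", 5),
    met("nad_m", "m"), met("nadh_m", "m"))

  rx <- list(); rb <- list()
  R <- function(id, stoich, lb = 0, ub = 1000, name = id, sub = "") {
    rx[[id]] <<- stoich
    rb[[id]] <<- data.frame(id = id, name = name, lower_bound = lb,
                            upper_bound = ub, subsystem = sub,
                            stringsAsFactors = FALSE)
    invisible(NULL)
  }
  EX <- function(sp, lb = 0, ub = 1000)
    R(paste0("EX_", sp), setNames(-1, sp), lb, ub, sub = "exchange")

  # exchanges (uptake bounds here are static defaults; the dFBA engine
  # overrides them from the kinetic layer at every step)
  EX("glc_e", -10, 0); EX("frc_e", -10, 0); EX("o2_e", -10, 0)
  EX("nh4_e", -10, 0); EX("aa1_e", -10, 0); EX("aa2_e", -10, 0)
  EX("aa3_e", -10, 0); EX("arg_e", -10, 0)
  EX("etoh_e"); EX("glyc_e"); EX("succ_e"); EX("ac_e"); EX("mal_e")
  EX("btd_e"); EX("actn_e"); EX("iamoh_e"); EX("ibutoh_e"); EX("peth_e")
  EX("co2_e")
  EX("mev_e", 0, 0)   # closed; opened for the stationary phase

  # transport
  R("t_glc", c(glc_e = -1, glc_c = 1)); R("t_frc", c(frc_e = -1, frc_c = 1))
  R("t_o2", c(o2_e = -1, o2_c = 1)); R("t_nh4", c(nh4_e = -1, nh4_c = 1))
  R("t_aa1", c(aa1_e = -1, aa1_c = 1)); R("t_aa2", c(aa2_e = -1, glu_c = 1))
  R("t_aa3", c(aa3_e = -1, aa3_c = 1)); R("t_arg", c(arg_e = -1, arg_c = 1))
  R("t_etoh", c(etoh_c = -1, etoh_e = 1), lb = -1000)
  R("t_glyc", c(glyc_c = -1, glyc_e = 1))
  R("t_succ", c(succ_c = -1, succ_e = 1))
  R("t_ac", c(ac_c = -1, ac_e = 1), lb = -1000)
  R("t_mal", c(mal_c = -1, mal_e = 1))
  R("t_btd", c(btd_c = -1, btd_e = 1))
  R("t_actn", c(actn_c = -1, actn_e = 1))
  R("t_iamoh", c(iamoh_c = -1, iamoh_e = 1))
  R("t_ibutoh", c(ibutoh_c = -1, ibutoh_e = 1))
  R("t_peth", c(peth_c = -1, peth_e = 1))
  R("t_mev", c(mev_c = -1, mev_e = 1))
  R("t_co2", c(co2_c = -1, co2_e = 1))
  R("t_pyr_m", c(pyr_c = -1, pyr_m = 1))
  R("t_acald_m", c(acald_c = -1, acald_m = 1), lb = -1000)
  R("t_etoh_m", c(etoh_m = -1, etoh_c = 1), lb = -1000)
  R("t_mal_akg", c(mal_c = -1, akg_m = -1, mal_m = 1, akg_c = 1),
    name = "malate/2-oxoglutarate antiporter")
  R("t_oaa_m", c(oaa_c = -1, oaa_m = 1), name = "oxaloacetate carrier")
  R("t_tmob", c(tmob_m = -1, tmob_c = 1))

  # glycolysis (lumped) and hexose entry
  R("glk", c(glc_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1))
  R("frk", c(frc_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1))
  R("pfk_ald", c(g6p_c = -1, atp_c = -1, t3p_c = 2, adp_c = 1))
  R("gapdh_pyk", c(t3p_c = -1, adp_c = -2, pi_c = -1, nad_c = -1,
                   pyr_c = 1, atp_c = 2, nadh_c = 1, h2o_c = 1, h_c = 1))

  # pentose phosphate pathway
  R("zwf", c(g6p_c = -1, nadp_c = -2, h2o_c = -1, p5p_c = 1, nadph_c = 2,
             co2_c = 1, h_c = 2), name = "oxidative PPP (lumped)")
  R("tkt", c(p5p_c = -2, e4p_c = 1, g6p_c = 1), name = "non-oxidative PPP (lumped)")
  R("tkt2", c(g6p_c = -1, t3p_c = -1, p5p_c = 1, e4p_c = 1), lb = -1000,
    name = "transketolase 2 (lumped)")

  # fermentation
  R("pdc", c(pyr_c = -1, acald_c = 1, co2_c = 1))
  R("adh1", c(acald_c = -1, nadh_c = -1, h_c = -1, etoh_c = 1, nad_c = 1))
  R("ald6", c(acald_c = -1, nadp_c = -1, h2o_c = -1, ac_c = 1, nadph_c = 1,
              h_c = 1), name = "acetaldehyde dehydrogenase (NADP)")
  R("ald4", c(acald_c = -1, nad_c = -1, h2o_c = -1, ac_c = 1, nadh_c = 1,
              h_c = 1), name = "acetaldehyde dehydrogenase (NAD)")
  R("acs", c(ac_c = -1, atp_c = -1, accoa_c = 1, amp_c = 1, pi_c = 1),
    name = "acetyl-CoA synthetase (AMP-producing)")
  R("adk", c(amp_c = -1, atp_c = -1, adp_c = 2), lb = -1000,
    name = "adenylate kinase")
  R("actn_synth", c(acald_c = -2, actn_c = 1),
    name = "acetoin synthesis (lumped condensation)")
  R("btd_synth", c(actn_c = -1, nadh_c = -1, h_c = -1, btd_c = 1, nad_c = 1),
    name = "butanediol dehydrogenase")

  # mevalonate route
  R("mva1", c(accoa_c = -2, aacoa_c = 1), name = "thiolase")
  R("mva2", c(aacoa_c = -1, accoa_c = -1, h2o_c = -1, hmgcoa_c = 1),
    name = "HMG-CoA synthase")
  R("hmgr", c(hmgcoa_c = -1, nadph_c = -2, h_c = -2, mev_c = 1, nadp_c = 2),
    name = "HMG-CoA reductase")

  # anaplerosis, reductive branch, antiporter partners
  R("pyc", c(pyr_c = -1, co2_c = -1, atp_c = -1, oaa_c = 1, adp_c = 1, pi_c = 1))
  R("mdh_c", c(oaa_c = -1, nadh_c = -1, h_c = -1, mal_c = 1, nad_c = 1))
  R("fum_r", c(mal_c = -1, fum_c = 1, h2o_c = 1))
  R("frd", c(fum_c = -1, nadh_c = -1, h_c = -1, succ_c = 1, nad_c = 1),
    name = "fumarate reductase")

  # mitochondrion: PDH, oxidative TCA branch, shuttle, respiration
  R("pdh", c(pyr_m = -1, nad_m = -1, accoa_m = 1, co2_c = 1, nadh_m = 1))
  R("cs_icdh", c(accoa_m = -1, oaa_m = -1, nad_m = -1, h2o_c = -1, akg_m = 1,
                 co2_c = 1, nadh_m = 1), name = "oxidative TCA to 2-oxoglutarate")
  R("mdh_m", c(mal_m = -1, nad_m = -1, oaa_m = 1, nadh_m = 1, h_c = 1),
    lb = -1000)
  R("adh3_m", c(acald_m = -1, nadh_m = -1, h_c = -1, etoh_m = 1, nad_m = 1),
    name = "mitochondrial alcohol dehydrogenase")
  R("resp", c(nadh_m = -1, o2_c = -0.5, adp_c = -1.5, pi_c = -1.5, nad_m = 1,
              atp_c = 1.5, h2o_c = 1), name = "respiration (lumped)")

  # nitrogen assimilation and the GABA shunt
  R("gdh", c(akg_c = -1, nh4_c = -1, nadph_c = -1, h_c = -1, glu_c = 1,
             nadp_c = 1, h2o_c = 1), name = "glutamate dehydrogenase (NADPH)")
  R("gad", c(glu_c = -1, h_c = -1, gaba_c = 1, co2_c = 1),
    name = "glutamate decarboxylase")
  R("gabat", c(gaba_c = -1, akg_c = -1, ssa_c = 1, glu_c = 1),
    name = "GABA transaminase")
  R("ssadh", c(ssa_c = -1, nadp_c = -1, h2o_c = -1, succ_c = 1, nadph_c = 1,
               h_c = 1), name = "succinate-semialdehyde dehydrogenase (NADP)")
  R("ta_aa1", c(aa1_c = -1, akg_c = -1, pyr_c = 1, glu_c = 1), lb = -1000,
    name = "alanine-type transaminase")
  R("ta_aa3", c(aa3_c = -1, akg_c = -1, phepyr_c = 1, glu_c = 1), lb = -1000,
    name = "aromatic transaminase")
  R("arg_cat", c(arg_c = -1, akg_c = -3, glu_c = 4, co2_c = 1),
    name = "arginine catabolism (lumped)")

  # Ehrlich / higher-alcohol routes
  R("arom_synth", c(e4p_c = -1, pyr_c = -2, nadph_c = -1, atp_c = -1,
                    phepyr_c = 1, co2_c = 1, nadp_c = 1, adp_c = 1, pi_c = 1),
    name = "aromatic synthesis (lumped shikimate)")
  R("kdc_phe", c(phepyr_c = -1, pacald_c = 1, co2_c = 1))
  R("adh_peth_nadh", c(pacald_c = -1, nadh_c = -1, h_c = -1, peth_c = 1,
                       nad_c = 1))
  R("adh_peth_nadph", c(pacald_c = -1, nadph_c = -1, h_c = -1, peth_c = 1,
                        nadp_c = 1))
  R("als_kari", c(pyr_m = -2, nadph_c = -1, h_c = -1, tmob_m = 1, co2_c = 1,
                  nadp_c = 1), name = "valine-precursor synthesis (lumped)")
  R("leu_synth", c(tmob_c = -1, accoa_c = -1, nad_c = -1, ketoleu_c = 1,
                   co2_c = 1, nadh_c = 1, h_c = 1),
    name = "isopropylmalate route to ketoleucine (lumped)")
  R("kdc_leu", c(ketoleu_c = -1, mbald_c = 1, co2_c = 1))
  R("adh_iam_nadh", c(mbald_c = -1, nadh_c = -1, h_c = -1, iamoh_c = 1,
                      nad_c = 1))
  R("adh_iam_nadph", c(mbald_c = -1, nadph_c = -1, h_c = -1, iamoh_c = 1,
                       nadp_c = 1))
  R("kdc_val", c(tmob_c = -1, ibutal_c = 1, co2_c = 1))
  R("adh_ibu_nadh", c(ibutal_c = -1, nadh_c = -1, h_c = -1, ibutoh_c = 1,
                      nad_c = 1))
  R("adh_ibu_nadph", c(ibutal_c = -1, nadph_c = -1, h_c = -1, ibutoh_c = 1,
                       nadp_c = 1))

  # glycerol branch
  R("gpd", c(t3p_c = -1, nadh_c = -1, h_c = -1, glyc3p_c = 1, nad_c = 1))
  R("gpp", c(glyc3p_c = -1, h2o_c = -1, glyc_c = 1, pi_c = 1))

  # maintenance, polymerization pseudo-fluxes, nucleotide synthesis
  R("atpm", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
    name = "non-growth ATP maintenance (ATPase)", sub = "pseudo")
  R("nuc_synth", c(p5p_c = -1, glu_c = -1, nh4_c = -3, atp_c = -4,
                   nucmono_c = 1, co2_c = 1, adp_c = 4, pi_c = 4),
    name = "nucleotide synthesis (lumped)")
  R("protein_synth", c(glu_c = -1, atp_c = -5.5, h2o_c = -5.5, protein_c = 1,
                       adp_c = 5.5, pi_c = 5.5),
    name = "protein polymerization pseudo-flux", sub = "pseudo")
  R("DM_protein", c(protein_c = -1), sub = "pseudo")

  # free pools: water, protons, inorganic phosphate (hydrogen, oxygen and
  # phosphorus bookkeeping is not modelled; adenylates are still conserved)
  R("h2o_pool", c(h2o_c = 1), lb = -1000, sub = "pseudo")
  R("h_pool", c(h_c = 1), lb = -1000, sub = "pseudo")
  R("pi_pool", c(pi_c = 1), lb = -1000, sub = "pseudo")

  # biomass pseudoreactions (seeded; the engine rewrites them dynamically)
  R("biomass", c(g6p_c = -1), sub = "pseudo")       # placeholder, rewritten below
  R("biomass_carb", c(g6p_c = -1), sub = "pseudo")

  reactions <- do.call(rbind, rb)
  model <- metabolic_model(mets, reactions, rx, biomass_reaction_id = "biomass",
                           compartments = c("e", "c", "m"))
  model <- add_erythritol_pathway(model)

  gam <- total_gam(composition, gam_f)
  pm <- toy_precursor_map()
  model <- update_biomass_reaction(model, composition, gam, pm)
  comp2 <- carb_enriched_composition(composition)
  model <- update_biomass_reaction(model, comp2, total_gam(comp2, gam_f), pm,
                                   reaction_id = "biomass_carb")

  attr(model, "exchange_map") <- toy_exchange_map()
  attr(model, "molar_mass") <- toy_molar_mass()
  check_elemental_balance(model, strict = TRUE)
  model
}

#' Carbohydrate-enriched biomass composition
#'
#' The nitrogen-limited growth phase accumulates storage carbohydrates. The
#' variant composition shifts mass from protein (and its proportional mRNA)
#' into carbohydrate by `boost` mass fraction, with a floor on protein.
#'
#' @param comp a `biomass_composition`.
#' @param boost carbohydrate mass-fraction increase (default +0.20).
#' @param rho mRNA:protein ratio used by the composition.
#' @return a `biomass_composition`.
#' @export
carb_enriched_composition <- function(comp, boost = 0.20, rho = NULL) {
  if (is.null(rho))
    rho <- if (comp$protein_fraction > 0)
      comp$rna_fraction / comp$protein_fraction else 0.05
  p2 <- max(comp$protein_fraction - boost / (1 + rho), 0.02)
  compose_biomass(p2, rho = rho, dna_fraction = comp$dna_fraction,
                  lipid_fraction = comp$lipid_fraction)
}

#' Precursor map of the toy network's biomass equation
#'
#' Assigns each macromolecular class to its monomer metabolite with molar
#' mass (g/mmol): protein draws on the glutamate pool, RNA and DNA on a
#' lumped nucleotide, carbohydrate on glucose-6-phosphate (anhydroglucose
#' incorporated), lipid on mevalonate (proxy precursor of the lipid family).
#'
#' @return data.frame with columns polymer, metabolite, molar_mass, weight.
#' @export
toy_precursor_map <- function() {
  data.frame(
    polymer = c("protein", "rna", "dna", "carb", "lipid"),
    metabolite = c("glu_c", "nucmono_c", "nucmono_c", "g6p_c", "mev_c"),
    molar_mass = c(0.14713, 0.345, 0.345, 0.16216, 0.14816),
    weight = 1, stringsAsFactors = FALSE)
}

#' State-variable to exchange-reaction map of the toy network
#' @return named character vector (state variable -> reaction id).
#' @export
toy_exchange_map <- function() {
  c(glucose = "EX_glc_e", fructose = "EX_frc_e", NH4 = "EX_nh4_e",
    O2 = "EX_o2_e", aa1 = "EX_aa1_e", aa2 = "EX_aa2_e", aa3 = "EX_aa3_e",
    arginine = "EX_arg_e", ethanol = "EX_etoh_e", glycerol = "EX_glyc_e",
    erythritol = "EX_erythritol_e", succinate = "EX_succ_e",
    acetate = "EX_ac_e", malate = "EX_mal_e", butanediol = "EX_btd_e",
    acetoin = "EX_actn_e",
    isoamyl_alcohol = "EX_iamoh_e", isobutanol = "EX_ibutoh_e",
    phenylethanol = "EX_peth_e", mevalonate = "EX_mev_e")
}

#' Molar masses of the tracked extracellular species
#' @return named numeric vector, g/mmol.
#' @export
toy_molar_mass <- function() {
  c(glucose = 0.18016, fructose = 0.18016, NH4 = 0.01804, O2 = 0.032,
    aa1 = 0.08909, aa2 = 0.14713, aa3 = 0.16519, arginine = 0.17420,
    ethanol = 0.04607, glycerol = 0.09209, erythritol = 0.12212,
    succinate = 0.11809, acetate = 0.06005, malate = 0.13409,
    butanediol = 0.09012, acetoin = 0.08811,
    isoamyl_alcohol = 0.08815, isobutanol = 0.07412,
    phenylethanol = 0.12216, mevalonate = 0.14816, biomass = NA_real_)
}

#' Default balancing sinks for stoichiometric yield queries on the toy model
#'
#' ATP regeneration, free water/proton pools and a CO2 drain — the
#' inorganic/cofactor pools a yield query may balance externally. NAD(H) and
#' NADP(H) are deliberately not included: redox closure is what the yield
#' questions probe.
#'
#' @return named list accepted by [pathway_yield()]'s `sinks` argument.
#' @export
toy_yield_sinks <- function() {
  list(atp = c(atp_c = 1, adp_c = -1, pi_c = -1),
       co2 = "co2_c", h2o = "h2o_c", h = "h_c", pi = "pi_c")
}
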