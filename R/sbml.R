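#' Write a model as SBML Level 3 (FBC version 2)
#'
#' Serializes compartments, species (with a simplified C/N chemical formula
#' when annotated), reactions with explicit flux-bound parameters, and an
#' active maximization objective on the biomass pseudoreaction. The subset
#' written is exactly the subset [read_sbml()] consumes, and a write-read
#' round trip preserves stoichiometry bit-exactly.
#'
#' @param model a `metabolic_model`.
#' @param path output file.
#' @param model_id SBML model id.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path, model_id = "model") {
  num <- function(x) sprintf("%.17g", x)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
    'level="3" version="1" fbc:required="false">')
  w('<model id="', esc(model_id), '" fbc:strict="true">')
  w('<listOfCompartments>')
  for (cp in model$compartments)
    w('<compartment id="', esc(cp), '" constant="true"/>')
  w('</listOfCompartments>')
  w('<listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    formula <- if (!is.na(m$carbons))
      paste0(' fbc:chemicalFormula="C', m$carbons,
             if (!is.na(m$nitrogens) && m$nitrogens > 0)
               paste0("N", m$nitrogens) else "", '"')
    else ""
    nm_attr <- if (identical(m$name, m$id)) "" else
      paste0(' name="', esc(m$name), '"')
    w('<species id="', esc(m$id), '"', nm_attr,
      ' compartment="', esc(m$compartment),
      '" hasOnlySubstanceUnits="false" boundaryCondition="false" ',
      'constant="false"', formula, '/>')
  }
  w('</listOfSpecies>')
  # shared flux-bound parameters: one per distinct bound value
  vals <- sort(unique(c(model$reactions$lower_bound,
                        model$reactions$upper_bound)))
  par_id <- setNames(paste0("fb_", seq_along(vals)), num(vals))
  w('<listOfParameters>')
  for (v in vals)
    w('<parameter id="', par_id[[num(v)]], '" value="', num(v),
      '" constant="true"/>')
  w('</listOfParameters>')
  w('<listOfReactions>')
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    st <- model$stoichiometry[[r$id]]
    nm_attr <- if (identical(r$name, r$id)) "" else
      paste0(' name="', esc(r$name), '"')
    w('<reaction id="', esc(r$id), '"', nm_attr,
      ' reversible="', tolower(r$lower_bound < 0), '" fast="false" ',
      'fbc:lowerFluxBound="', par_id[[num(r$lower_bound)]],
      '" fbc:upperFluxBound="', par_id[[num(r$upper_bound)]], '">')
    reac <- st[st < 0]; prod <- st[st > 0]
    if (length(reac)) {
      w('<listOfReactants>')
      for (s in names(reac))
        w('<speciesReference species="', esc(s), '" stoichiometry="',
          num(-reac[[s]]), '" constant="true"/>')
      w('</listOfReactants>')
    }
    if (length(prod)) {
      w('<listOfProducts>')
      for (s in names(prod))
        w('<speciesReference species="', esc(s), '" stoichiometry="',
          num(prod[[s]]), '" constant="true"/>')
      w('</listOfProducts>')
    }
    w('</reaction>')
  }
  w('    </listOfReactions>')
  w('<fbc:listOfObjectives fbc:activeObjective="obj">')
  w('<fbc:objective fbc:id="obj" fbc:type="maximize">')
  w('<fbc:listOfFluxObjectives>')
  w('<fbc:fluxObjective fbc:reaction="',
    esc(model$biomass_reaction_id), '" fbc:coefficient="1"/>')
  w('</fbc:listOfFluxObjectives>')
  w('</fbc:objective>')
  w('</fbc:listOfObjectives>')
  w('</model>')
  w('</sbml>')
  invisible(path)
}

#' Read a model from SBML Level 3 with the FBC package
#'
#' Parses species, compartments, reactions and FBC flux bounds; the active
#' FBC objective designates the biomass pseudoreaction (falling back to a
#' reaction whose id contains "biomass" when no objective is declared).
#' Simplified C/N elemental annotation is recovered from
#' `fbc:chemicalFormula` when present.
#'
#' @param path SBML file.
#' @return a `metabolic_model`.
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("SBML file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML in '", path, "': ",
                                           conditionMessage(e)))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  a <- function(node, at) xml2::xml_attr(node, at)

  comp_nodes <- xml2::xml_find_all(doc, ".//s:listOfCompartments/s:compartment", ns)
  compartments <- xml2::xml_attr(comp_nodes, "id")

  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  formula <- xml2::xml_attr(sp, "chemicalFormula")
  parse_el <- function(f, el) {
    out <- rep(NA_real_, length(f))
    has <- !is.na(f)
    m <- regmatches(f[has], regexec(paste0(el, "([0-9]*)"), f[has]))
    out[has] <- vapply(m, function(g) {
      if (length(g) < 2 || is.na(g[1])) return(0)
      if (g[2] == "") 1 else as.numeric(g[2])
    }, numeric(1))
    out
  }
  mets <- data.frame(id = xml2::xml_attr(sp, "id"),
                     name = xml2::xml_attr(sp, "name"),
                     compartment = xml2::xml_attr(sp, "compartment"),
                     carbons = parse_el(formula, "C"),
                     nitrogens = parse_el(formula, "N"),
                     stringsAsFactors = FALSE)
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]

  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  parval <- setNames(as.numeric(xml2::xml_attr(pars, "value")),
                     xml2::xml_attr(pars, "id"))

  rnodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (length(rnodes) == 0L) stop("no reactions in '", path, "'")
  ids <- xml2::xml_attr(rnodes, "id")
  lb_ref <- xml2::xml_attr(rnodes, "lowerFluxBound")
  ub_ref <- xml2::xml_attr(rnodes, "upperFluxBound")
  unbounded <- ids[is.na(lb_ref) | is.na(ub_ref) |
                     !(lb_ref %in% names(parval)) |
                     !(ub_ref %in% names(parval))]
  if (length(unbounded))
    stop("missing FBC flux bounds for reaction(s): ",
         paste(unbounded, collapse = ", "))
  stoich <- list()
  nm <- character(length(ids))
  for (k in seq_along(rnodes)) {
    node <- rnodes[[k]]
    nm[k] <- if (is.na(a(node, "name"))) ids[k] else a(node, "name")
    rs <- xml2::xml_find_all(node, "./s:listOfReactants/s:speciesReference", ns)
    ps <- xml2::xml_find_all(node, "./s:listOfProducts/s:speciesReference", ns)
    st <- c(setNames(-as.numeric(xml2::xml_attr(rs, "stoichiometry")),
                     xml2::xml_attr(rs, "species")),
            setNames(as.numeric(xml2::xml_attr(ps, "stoichiometry")),
                     xml2::xml_attr(ps, "species")))
    if (length(st) == 0L)
      stop("reaction '", ids[k], "' has no participants")
    stoich[[ids[k]]] <- tapply(st, names(st), sum)[unique(names(st))]
  }
  reactions <- data.frame(id = ids, name = nm,
                          lower_bound = unname(parval[lb_ref]),
                          upper_bound = unname(parval[ub_ref]),
                          subsystem = "", stringsAsFactors = FALSE)

  fo <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  biomass <- if (!inherits(fo, "xml_missing"))
    xml2::xml_attr(fo, "reaction")
  else grep("biomass", ids, value = TRUE)[1]
  if (is.na(biomass) || is.null(biomass))
    stop("no objective and no reaction id containing 'biomass' in '", path, "'")

  metabolic_model(mets, reactions, stoich, biomass_reaction_id = biomass,
                  compartments = compartments)
}
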