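# Model input/output.
#
# Two formats: SBML Level 3 with the fbc package (flux bounds, objectives,
# gene-product associations), and a JSON dialect mirroring the widespread
# COBRA JSON schema one-to-one (so synthetic models avoid SBML overhead in
# tests and can be read by other constraint-based toolkits). Package-
# specific metadata (role tags, metabolite roles, biomass spec) travels
# under a dedicated top-level JSON key and in an SBML annotation-free
# fashion is dropped on SBML round-trips.

sbml_sanitize <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

#' Write a model to SBML or JSON
#'
#' @param model A `metabolic_model`.
#' @param path Output file.
#' @param format `"sbml"` or `"json"`; guessed from the extension when
#'   missing.
#' @export
write_model <- function(model, path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml"
              else "json"
  if (format == "json") write_model_json(model, path)
  else write_model_sbml(model, path)
  invisible(path)
}

#' Read a model from SBML or JSON
#'
#' @param path Model file (SBML Level 3 + fbc, SBML Level 2 with
#'   notes-encoded GPRs, or the JSON dialect).
#' @param format As in [write_model()].
#' @return A `metabolic_model`.
#' @export
read_model <- function(path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml"
              else "json"
  if (format == "json") read_model_json(path) else read_sbml(path)
}

write_model_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment)
    if (!is.na(m$formula)) out$formula <- m$formula
    if (!is.na(m$charge)) out$charge <- m$charge
    out
  })
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    st <- model$stoichiometry[[r$id]]
    list(id = r$id, name = r$name,
         metabolites = as.list(st),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         gene_reaction_rule = gpr_to_string(model$gpr[[r$id]]),
         subsystem = r$subsystem,
         objective_coefficient = as.numeric(r$id == model$objective))
  })
  obj <- list(id = model$id,
              metabolites = mets, reactions = rxns,
              genes = lapply(model$genes, function(g) list(id = g, name = g)),
              compartments = as.list(model$compartments),
              robustfba = list(roles = model$roles,
                               met_roles = model$met_roles,
                               exchanges = model$reactions$id[model$reactions$is_exchange]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

read_model_json <- function(path) {
  obj <- jsonlite::read_json(path)
  mets <- do.call(rbind, lapply(obj$metabolites, function(m)
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment,
               formula = m$formula %||% NA_character_,
               charge = m$charge %||% NA_integer_,
               stringsAsFactors = FALSE)))
  st <- list(); gpr <- list(); objective <- NULL
  rxns <- do.call(rbind, lapply(obj$reactions, function(r) {
    st[[r$id]] <<- unlist(r$metabolites)
    rule <- r$gene_reaction_rule %||% ""
    if (nzchar(rule)) gpr[[r$id]] <<- rule
    if (!is.null(r$objective_coefficient) && r$objective_coefficient != 0)
      objective <<- r$id
    data.frame(id = r$id, name = r$name %||% r$id,
               lower_bound = r$lower_bound, upper_bound = r$upper_bound,
               subsystem = r$subsystem %||% "", stringsAsFactors = FALSE)
  }))
  if (is.null(objective)) stop("model file declares no objective reaction")
  extra <- obj$robustfba
  if (!is.null(extra$exchanges))
    rxns$is_exchange <- rxns$id %in% unlist(extra$exchanges)
  genes <- vapply(obj$genes, function(g) g$id, character(1))
  model <- metabolic_model(
    mets, rxns, st, gpr = gpr,
    genes = if (length(genes)) genes else NULL,
    compartments = unlist(obj$compartments),
    objective = objective,
    roles = lapply(extra$roles %||% list(), function(x) unlist(x)),
    met_roles = lapply(extra$met_roles %||% list(), function(x) unlist(x)),
    id = obj$id %||% "model")
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- SBML ----------------------------------------------------------------

FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"

write_model_sbml <- function(model, path) {
  param_id <- function(v)
    vapply(v, function(x)
      paste0("par_", sbml_sanitize(format(x, digits = 15,
                                          scientific = FALSE))),
      character(1))
  bounds <- sort(unique(c(model$reactions$lower_bound,
                          model$reactions$upper_bound)))
  gpr_xml <- function(rule) {
    if (is.null(rule)) return("")
    node <- function(r) {
      if (is.character(r))
        return(sprintf('<fbc:geneProductRef fbc:geneProduct="G_%s"/>',
                       sbml_sanitize(r)))
      tag <- if (r$op == "and") "fbc:and" else "fbc:or"
      paste0("<", tag, ">", paste(vapply(r$args, node, character(1)),
                                  collapse = ""), "</", tag, ">")
    }
    paste0("<fbc:geneProductAssociation>", node(rule),
           "</fbc:geneProductAssociation>")
  }
  met_xml <- vapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    sprintf(paste0('<species id="M_%s" name="%s" compartment="%s" ',
                   'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
                   'constant="false"%s/>'),
            sbml_sanitize(m$id), m$name, m$compartment,
            if (!is.na(m$formula) && nzchar(m$formula))
              sprintf(' fbc:chemicalFormula="%s"', gsub("\\.", "", m$formula))
            else "")
  }, character(1))
  rxn_xml <- vapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    st <- model$stoichiometry[[r$id]]
    side <- function(sel, tag) {
      if (!any(sel)) return("")
      refs <- sprintf('<speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
                      sbml_sanitize(names(st)[sel]),
                      format(abs(st[sel]), digits = 15))
      paste0("<", tag, ">", paste(refs, collapse = ""), "</", tag, ">")
    }
    sprintf(paste0('<reaction id="R_%s" name="%s" reversible="%s" fast="false" ',
                   'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">%s%s%s</reaction>'),
            sbml_sanitize(r$id), r$name,
            tolower(r$lower_bound < 0),
            param_id(r$lower_bound), param_id(r$upper_bound),
            gpr_xml(model$gpr[[r$id]]),
            side(st < 0, "listOfReactants"), side(st > 0, "listOfProducts"))
  }, character(1))
  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">\n',
            SBML_NS, FBC_NS),
    sprintf('<model id="%s" fbc:strict="true">\n', sbml_sanitize(model$id)),
    "<listOfCompartments>",
    paste(sprintf('<compartment id="%s" name="%s" constant="true"/>',
                  names(model$compartments), model$compartments),
          collapse = ""),
    "</listOfCompartments>\n",
    "<listOfSpecies>", paste(met_xml, collapse = "\n"), "</listOfSpecies>\n",
    "<listOfParameters>",
    paste(sprintf('<parameter id="%s" value="%s" constant="true"/>',
                  param_id(bounds), format(bounds, digits = 15)),
          collapse = ""),
    "</listOfParameters>\n",
    "<listOfReactions>", paste(rxn_xml, collapse = "\n"), "</listOfReactions>\n",
    '<fbc:listOfObjectives fbc:activeObjective="obj">',
    '<fbc:objective fbc:id="obj" fbc:type="maximize"><fbc:listOfFluxObjectives>',
    sprintf('<fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="1"/>',
            sbml_sanitize(model$objective)),
    "</fbc:listOfFluxObjectives></fbc:objective></fbc:listOfObjectives>\n",
    "<fbc:listOfGeneProducts>",
    paste(sprintf('<fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
                  sbml_sanitize(model$genes), model$genes),
          collapse = ""),
    "</fbc:listOfGeneProducts>\n",
    "</model></sbml>\n")
  writeLines(doc, path)
  invisible(path)
}

#' Read an SBML model
#'
#' Supports SBML Level 3 with the fbc package (flux-bound parameters,
#' gene-product associations, objectives) and falls back on notes-encoded
#' `GENE_ASSOCIATION:` strings and bounds in kinetic-law parameters for
#' Level 2 files. Exchange reactions are flagged as single-metabolite
#' boundary reactions.
#'
#' @param path SBML file.
#' @return A `metabolic_model`.
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed SBML: ", conditionMessage(e)))
  ns <- c(s = xml2::xml_ns(doc)[[1]], fbc = FBC_NS)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (is.na(mdl)) stop("malformed SBML: no <model> element")

  comp_nodes <- xml2::xml_find_all(mdl, ".//s:listOfCompartments/s:compartment", ns)
  compartments <- setNames(
    vapply(comp_nodes, function(n)
      xml2::xml_attr(n, "name") %||% xml2::xml_attr(n, "id"), character(1)),
    xml2::xml_attr(comp_nodes, "id"))
  compartments[is.na(compartments)] <- names(compartments)[is.na(compartments)]

  par_nodes <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  par_vals <- setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                       xml2::xml_attr(par_nodes, "id"))

  sp_nodes <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  strip_m <- function(x) sub("^M_", "", x)
  mets <- data.frame(
    id = strip_m(xml2::xml_attr(sp_nodes, "id")),
    name = ifelse(is.na(xml2::xml_attr(sp_nodes, "name")),
                  strip_m(xml2::xml_attr(sp_nodes, "id")),
                  xml2::xml_attr(sp_nodes, "name")),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    formula = xml2::xml_attr(sp_nodes, "chemicalFormula"),
    stringsAsFactors = FALSE)
  boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true"
  boundary_ids <- mets$id[boundary]

  parse_assoc <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef")
      return(sub("^G_", "", xml2::xml_attr(node, "geneProduct")))
    kids <- xml2::xml_children(node)
    if (nm %in% c("and", "or"))
      return(list(op = nm, args = lapply(kids, parse_assoc)))
    if (length(kids)) parse_assoc(kids[[1]]) else NULL
  }

  rx_nodes <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  strip_r <- function(x) sub("^R_", "", x)
  st <- list(); gpr <- list()
  rx_rows <- lapply(rx_nodes, function(n) {
    rid <- strip_r(xml2::xml_attr(n, "id"))
    reac <- xml2::xml_find_all(n, "./s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(n, "./s:listOfProducts/s:speciesReference", ns)
    coef <- function(nodes, sign) {
      v <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
      v[is.na(v)] <- 1
      setNames(sign * v, strip_m(xml2::xml_attr(nodes, "species")))
    }
    sti <- c(coef(reac, -1), coef(prod, 1))
    sti <- sti[!(names(sti) %in% boundary_ids)]
    st[[rid]] <<- sti
    ga <- xml2::xml_find_first(n, "./fbc:geneProductAssociation", ns)
    if (!is.na(ga)) {
      rule <- parse_assoc(xml2::xml_children(ga)[[1]])
      if (!is.null(rule)) gpr[[rid]] <<- rule
    } else {
      notes <- xml2::xml_text(xml2::xml_find_first(n, "./s:notes", ns))
      if (!is.na(notes) && grepl("GENE_ASSOCIATION", notes)) {
        rule <- sub(".*GENE_ASSOCIATION:\\s*([^\n<]*).*", "\\1", notes)
        if (nzchar(trimws(rule))) gpr[[rid]] <<- parse_gpr(trimws(rule))
      }
    }
    lbp <- xml2::xml_attr(n, "lowerFluxBound")
    ubp <- xml2::xml_attr(n, "upperFluxBound")
    lb <- if (!is.na(lbp)) par_vals[[lbp]] else
      if (xml2::xml_attr(n, "reversible") %in% "true") -1000 else 0
    ub <- if (!is.na(ubp)) par_vals[[ubp]] else 1000
    data.frame(id = rid,
               name = xml2::xml_attr(n, "name") %||% rid,
               lower_bound = lb, upper_bound = ub, stringsAsFactors = FALSE)
  })
  rxns <- do.call(rbind, rx_rows)
  rxns$name[is.na(rxns$name)] <- rxns$id[is.na(rxns$name)]

  gp_nodes <- xml2::xml_find_all(mdl, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  genes <- sub("^G_", "", xml2::xml_attr(gp_nodes, "id"))

  obj_node <- xml2::xml_find_first(
    mdl, ".//fbc:listOfObjectives//fbc:fluxObjective", ns)
  objective <- if (!is.na(obj_node))
    strip_r(xml2::xml_attr(obj_node, "reaction"))
  else {
    hit <- grep("biomass|growth", rxns$id, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) stop("SBML file declares no objective and no reaction ",
                           "id matches 'biomass'")
    hit[1]
  }
  rule_genes <- unique(unlist(lapply(gpr, gpr_genes)))
  metabolic_model(mets, rxns, st, gpr = gpr,
                  genes = union(genes[!is.na(genes)], rule_genes),
                  compartments = compartments, objective = objective,
                  id = xml2::xml_attr(mdl, "id") %||% "model")
}

## ---- tables --------------------------------------------------------------

#' Read an allele pair table
#'
#' @param path TSV with header columns `gene_id` and `allele_id`.
#' @return data.frame with the two columns.
#' @export
read_allele_table <- function(path) {
  tb <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "allele_id") %in% names(tb)))
    stop("allele table must have columns 'gene_id' and 'allele_id'")
  tb[, c("gene_id", "allele_id")]
}

#' Write flux solution as TSV (and optionally JSON)
#'
#' @param solution A `flux_solution`.
#' @param path Output TSV path (`reaction_id`, `flux`); a `.json` path
#'   writes status and growth as well.
#' @export
write_fluxes <- function(solution, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(status = solution$status,
                              method = solution$method,
                              growth = solution$objective_value,
                              growth_per_day = solution$growth_rate_per_day,
                              fluxes = as.list(solution$fluxes)),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    write.table(data.frame(reaction_id = names(solution$fluxes),
                           flux = as.numeric(solution$fluxes)),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
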