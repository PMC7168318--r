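# The metabolic_model container: a compartmentalised stoichiometric network
# with flux bounds, GPR rules, an objective (biomass) reaction, and optional
# role tags naming reactions/metabolites the analyses need (photon uptake,
# ATP maintenance, cyclic PSI, ...).

#' Construct a genome-scale metabolic model
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`
#'   and optionally `formula` (elemental formula string) and `charge`.
#' @param reactions data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound` (mmol gDW^-1 h^-1; the biomass reaction in h^-1), and
#'   optionally `subsystem` and `is_exchange`.
#' @param stoichiometry named list (one entry per reaction id) of named
#'   numeric vectors: metabolite id -> signed coefficient (negative =
#'   substrate, positive = product).
#' @param gpr named list of GPR rule trees or strings (see [parse_gpr()]);
#'   missing entries mean the empty rule.
#' @param genes character vector of gene ids; derived from the GPR rules
#'   when omitted.
#' @param compartments named character vector (id -> display name) of
#'   declared compartments.
#' @param objective id of the objective (biomass) reaction.
#' @param roles named list tagging reactions by function, e.g.
#'   `list(photon_uptake = "EX_photon", atp_maintenance = "ATPM")`; values
#'   may name several reactions.
#' @param met_roles named list tagging metabolites (e.g. `atp`, `nadph`,
#'   `nadp`, `h`), used by the quality-control routines.
#' @param id model identifier.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            gpr = list(), genes = NULL, compartments,
                            objective, roles = list(), met_roles = list(),
                            id = "model") {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  nm <- nrow(metabolites); nr <- nrow(reactions)
  if (is.null(metabolites$formula))
    metabolites$formula <- rep(NA_character_, nm)
  if (is.null(metabolites$charge)) metabolites$charge <- rep(NA_integer_, nm)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$subsystem)) reactions$subsystem <- rep("", nr)
  if (is.null(names(compartments)))
    compartments <- stats::setNames(compartments, compartments)

  gpr <- lapply(gpr, function(g) if (is.character(g)) parse_gpr(g) else g)
  full_gpr <- stats::setNames(vector("list", nrow(reactions)), reactions$id)
  full_gpr[names(gpr)] <- gpr
  if (is.null(genes))
    genes <- sort(unique(unlist(lapply(full_gpr, gpr_genes))))

  if (is.null(reactions$is_exchange))
    reactions$is_exchange <- vapply(reactions$id, function(r) {
      st <- stoichiometry[[r]]
      length(st) == 1L &&
        metabolites$compartment[match(names(st), metabolites$id)] %in%
          guess_boundary_compartment(compartments)
    }, logical(1))

  model <- structure(list(
    id = id,
    metabolites = metabolites,
    reactions = reactions,
    stoichiometry = stoichiometry[reactions$id],
    gpr = full_gpr,
    genes = genes,
    compartments = compartments,
    objective = objective,
    roles = roles,
    met_roles = met_roles,
    biomass_spec = NULL
  ), class = "metabolic_model")
  validate_model(model)
  model
}

guess_boundary_compartment <- function(compartments) {
  hit <- grepl("extracell|medium|external|^e$", c(names(compartments), compartments),
               ignore.case = TRUE)
  if (any(hit)) unique(c(names(compartments), compartments)[hit]) else names(compartments)[1]
}

#' Validate the internal consistency of a model
#'
#' Checks id uniqueness, declared compartments, bound ordering, that every
#' stoichiometry entry references a known metabolite, that non-exchange
#' reactions have nonempty stoichiometry, and that every GPR leaf is a
#' declared gene. Errors list all offenders.
#'
#' @param model A `metabolic_model`.
#' @return The model, invisibly.
#' @export
validate_model <- function(model) {
  m <- model$metabolites; r <- model$reactions
  if (anyDuplicated(m$id)) stop("duplicate metabolite ids: ",
                                paste(unique(m$id[duplicated(m$id)]), collapse = ", "))
  if (anyDuplicated(r$id)) stop("duplicate reaction ids: ",
                                paste(unique(r$id[duplicated(r$id)]), collapse = ", "))
  bad <- setdiff(m$compartment, names(model$compartments))
  if (length(bad)) stop("undeclared compartments: ", paste(bad, collapse = ", "))
  if (any(r$lower_bound > r$upper_bound))
    stop("lower_bound > upper_bound for: ",
         paste(r$id[r$lower_bound > r$upper_bound], collapse = ", "))
  if (!all(r$id %in% names(model$stoichiometry)))
    stop("missing stoichiometry for: ",
         paste(setdiff(r$id, names(model$stoichiometry)), collapse = ", "))
  for (rid in r$id) {
    st <- model$stoichiometry[[rid]]
    unk <- setdiff(names(st), m$id)
    if (length(unk)) stop("reaction ", rid, " references unknown metabolites: ",
                          paste(unk, collapse = ", "))
    if (length(st) == 0L && !r$is_exchange[match(rid, r$id)])
      stop("reaction ", rid, " has empty stoichiometry")
  }
  gpr_g <- unique(unlist(lapply(model$gpr, gpr_genes)))
  unk <- setdiff(gpr_g, model$genes)
  if (length(unk)) stop("GPR rules reference unknown genes: ",
                        paste(unk, collapse = ", "))
  if (!model$objective %in% r$id)
    stop("objective reaction '", model$objective, "' not in model")
  invisible(model)
}

#' Stoichiometric matrix of a model
#'
#' @param model A `metabolic_model`.
#' @return Dense numeric matrix, metabolites x reactions, with dimnames.
#' @export
stoich_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  for (rid in model$reactions$id) {
    st <- model$stoichiometry[[rid]]
    if (length(st)) S[names(st), rid] <- st
  }
  S
}

#' Set flux bounds on reactions
#'
#' @param model A `metabolic_model`.
#' @param rxns Reaction ids.
#' @param lower,upper New bounds, recycled along `rxns`; `NULL` leaves the
#'   corresponding bound unchanged.
#' @return The modified model.
#' @export
set_bounds <- function(model, rxns, lower = NULL, upper = NULL) {
  idx <- match(rxns, model$reactions$id)
  if (anyNA(idx)) stop("unknown reactions: ",
                       paste(rxns[is.na(idx)], collapse = ", "))
  if (!is.null(lower)) model$reactions$lower_bound[idx] <- rep_len(lower, length(idx))
  if (!is.null(upper)) model$reactions$upper_bound[idx] <- rep_len(upper, length(idx))
  model
}

#' Disable (knock out) reactions
#'
#' @param model A `metabolic_model`.
#' @param rxns Reaction ids whose bounds are set to `[0, 0]`.
#' @return The modified model.
#' @export
knockout_reactions <- function(model, rxns) set_bounds(model, rxns, 0, 0)

#' Reactions disabled by a gene knockout
#'
#' Evaluates every GPR under the knockout and returns the reactions whose
#' rule becomes false.
#'
#' @param model A `metabolic_model`.
#' @param genes Character vector of knocked-out gene ids.
#' @return Character vector of reaction ids losing catalytic support.
#' @export
reactions_disabled_by <- function(model, genes) {
  unk <- setdiff(genes, model$genes)
  if (length(unk)) stop("unknown genes: ", paste(unk, collapse = ", "))
  affected <- vapply(model$gpr, function(g)
    !is.null(g) && any(genes %in% gpr_genes(g)) && !gpr_eval_tree(g, genes),
    logical(1))
  names(affected)[affected]
}

#' Augment GPR rules with divergent allelic variants
#'
#' Each leaf occurrence of a paired gene `g` becomes `(g OR allele)`, making
#' the allele a redundant catalytic copy in deletion analyses. Re-applying
#' the same table is a no-op (no duplicate OR leaves).
#'
#' @param model A `metabolic_model`.
#' @param allele_table data.frame with columns `gene_id`, `allele_id`.
#' @return The augmented model; the input model is unmodified.
#' @export
augment_with_alleles <- function(model, allele_table) {
  stopifnot(all(c("gene_id", "allele_id") %in% names(allele_table)))
  unk <- setdiff(allele_table$gene_id, model$genes)
  if (length(unk)) stop("allele table references unknown genes: ",
                        paste(unk, collapse = ", "))
  clash <- intersect(allele_table$allele_id, model$genes)
  already <- vapply(seq_len(nrow(allele_table)), function(i)
    any(vapply(model$gpr, gpr_has_or_pair, logical(1),
               gene = allele_table$gene_id[i], allele = allele_table$allele_id[i])),
    logical(1))
  clash <- setdiff(clash, allele_table$allele_id[already])
  if (length(clash)) stop("allele ids collide with existing genes: ",
                          paste(clash, collapse = ", "))
  for (i in seq_len(nrow(allele_table))) {
    if (already[i]) next
    g <- allele_table$gene_id[i]; a <- allele_table$allele_id[i]
    model$gpr <- lapply(model$gpr, gpr_augment_tree, gene = g, allele = a)
  }
  model$genes <- union(model$genes, allele_table$allele_id)
  model
}

#' Summary counts for a model
#'
#' Counts reactions, metabolites, genes, gene-reaction association pairs
#' (one gene appearing in one reaction's GPR counts once), compartments and
#' subsystems.
#'
#' @param model A `metabolic_model`.
#' @return A named list of counts.
#' @export
model_stats <- function(model) {
  assoc <- sum(vapply(model$gpr, function(g) length(gpr_genes(g)), integer(1)))
  list(n_reactions = nrow(model$reactions),
       n_metabolites = nrow(model$metabolites),
       n_genes = length(model$genes),
       n_gene_associations = assoc,
       n_compartments = length(model$compartments),
       n_subsystems = length(unique(model$reactions$subsystem[
         nzchar(model$reactions$subsystem)])))
}

role_rxns <- function(model, role, required = TRUE) {
  r <- model$roles[[role]]
  if (is.null(r) || !length(r)) {
    if (required) stop("model lacks required role tag '", role, "'")
    return(character(0))
  }
  unk <- setdiff(r, model$reactions$id)
  if (length(unk)) stop("role '", role, "' names unknown reactions: ",
                        paste(unk, collapse = ", "))
  r
}

#' @export
print.metabolic_model <- function(x, ...) {
  s <- model_stats(x)
  cat("metabolic model '", x$id, "'\n", sep = "")
  cat(sprintf("  %d reactions, %d metabolites, %d genes, %d gene-reaction associations\n",
              s$n_reactions, s$n_metabolites, s$n_genes, s$n_gene_associations))
  cat(sprintf("  %d compartments: %s\n", s$n_compartments,
              paste(names(x$compartments), collapse = ", ")))
  cat("  objective:", x$objective, "\n")
  if (length(x$roles)) cat("  role tags:", paste(names(x$roles), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.metabolic_model <- function(object, ...) {
  s <- model_stats(object)
  s$n_exchange <- sum(object$reactions$is_exchange)
  s$n_reversible <- sum(object$reactions$lower_bound < 0)
  s$n_no_gpr <- sum(vapply(object$gpr, is.null, logical(1)))
  class(s) <- "summary.metabolic_model"
  s
}

#' @export
print.summary.metabolic_model <- function(x, ...) {
  cat("reactions:              ", x$n_reactions, "\n")
  cat("  exchange:             ", x$n_exchange, "\n")
  cat("  reversible:           ", x$n_reversible, "\n")
  cat("  without gene rule:    ", x$n_no_gpr, "\n")
  cat("metabolites:            ", x$n_metabolites, "\n")
  cat("genes:                  ", x$n_genes, "\n")
  cat("gene-reaction pairs:    ", x$n_gene_associations, "\n")
  cat("compartments:           ", x$n_compartments, "\n")
  cat("subsystems:             ", x$n_subsystems, "\n")
  invisible(x)
}
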