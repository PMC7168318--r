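# Single reaction / single gene deletion analysis.
#
# Deleting a target produces a model with modified structure (MMS) which is
# compared to the intact model (IM): growth is recomputed either by
# re-optimised parsimonious FBA (long-term acclimation) or by MOMA
# (short-term metabolic adjustment). Targets are classified by the growth
# ratio MMS/IM: "robust" when growth changes by at most 1%, "essential"
# when growth falls below the detection limit, "intermediate" otherwise
# (with inhibition >= 99% but detectable growth flagged `near_essential`
# and merged with essential in headline summaries).

classify_growth <- function(growth_wt, growth_del, settings = solver_settings()) {
  ratio <- growth_del / growth_wt
  if (growth_del <= settings$objective_zero_tolerance)
    return(list(class = "essential", near_essential = FALSE, ratio = ratio))
  if (abs(1 - ratio) <= 0.01)
    return(list(class = "robust", near_essential = FALSE, ratio = ratio))
  list(class = "intermediate", near_essential = (1 - ratio) >= 0.99,
       ratio = ratio)
}

#' Constrain photon uptake around a reference solution
#'
#' Deletions can otherwise be compensated by unrealistically large
#' increases in light harvesting; the photon uptake flux is therefore
#' limited to a window allowing a 1.5-fold increase or decrease relative to
#' its flux `w` in the intact-model reference: bounds `[w/1.5, 1.5 w]`.
#'
#' @param model A `metabolic_model` with a `photon_uptake` role tag.
#' @param reference An optimal `flux_solution` of the intact model.
#' @return The constrained model.
#' @export
constrain_photons <- function(model, reference) {
  rxn <- role_rxns(model, "photon_uptake")[1]
  if (reference$status != "optimal") stop("reference solution is not optimal")
  w <- abs(unname(reference$fluxes[rxn]))
  dir <- sign(sum(model$stoichiometry[[rxn]]))
  if (dir >= 0) set_bounds(model, rxn, w / 1.5, 1.5 * w)
  else set_bounds(model, rxn, -1.5 * w, -w / 1.5)
}

delete_one <- function(base, rxns_off, method, ref, settings, roles_present) {
  mod <- knockout_reactions(base, rxns_off)
  sol <- if (method == "fba") solve_pfba(mod, settings)
         else solve_moma(mod, ref, settings)
  growth <- if (sol$status == "optimal") sol$objective_value else 0
  comp <- if (sol$status == "optimal")
    compensatory_response(ref, sol, settings, roles = roles_present,
                          model = base)
  else list(n_activated = NA_integer_, n_inactivated = NA_integer_,
            pathway = NULL)
  list(sol = sol, growth = growth, comp = comp)
}

scan_result_row <- function(target, kind, method, ref, growth, cls, comp,
                            roles_present) {
  row <- data.frame(target = target, kind = kind, method = method,
                    growth_wt = ref$objective_value, growth_del = growth,
                    growth_ratio = growth / ref$objective_value,
                    robustness_class = cls$class,
                    near_essential = cls$near_essential,
                    n_activated = comp$n_activated,
                    n_inactivated = comp$n_inactivated,
                    stringsAsFactors = FALSE)
  for (role in roles_present) {
    pw <- comp$pathway
    row[[paste0(role, "_activated")]] <-
      if (is.null(pw)) NA else pw$activated[pw$role == role]
    row[[paste0(role, "_increased")]] <-
      if (is.null(pw)) NA else pw$increased[pw$role == role]
  }
  row
}

pathway_flag_roles <- function(model) {
  intersect(c("photorespiration", "mehler", "ptox", "cyclic_psi", "mito_atp",
              "photon_uptake", "chloro_atp"), names(model$roles))
}

#' Single reaction deletion scan
#'
#' Deletes each target reaction in turn (bounds set to `[0, 0]`), applies
#' the photon-uptake window of [constrain_photons()], recomputes growth by
#' parsimonious FBA or MOMA against the intact-model reference, classifies
#' the target and counts the compensatory response (reactions activated /
#' inactivated in the MMS relative to the IM, plus per-pathway flags).
#' Deletions of reactions that carry no flux in the reference leave the
#' optimum unchanged and are reported as trivially robust without
#' re-solving. Infeasible deletion problems are assigned growth 0.
#'
#' @param model A `metabolic_model`.
#' @param method `"fba"` (re-optimised pFBA) or `"moma"`.
#' @param settings A [solver_settings()] object.
#' @param reference Optional precomputed intact-model pFBA solution.
#' @param targets Reaction ids to delete; defaults to the active set of the
#'   reference (inactive reactions are appended as trivially robust rows).
#' @param photon_constraint Apply the photon window (default `TRUE`).
#' @return A `deletion_scan` data.frame, one row per target.
#' @export
single_reaction_deletion <- function(model, method = c("fba", "moma"),
                                     settings = solver_settings(),
                                     reference = NULL, targets = NULL,
                                     photon_constraint = TRUE) {
  method <- match.arg(method)
  ref <- if (is.null(reference)) solve_pfba(model, settings) else reference
  if (ref$status != "optimal") stop("intact model is not solvable")
  act <- active_set(ref, settings)
  roles_present <- pathway_flag_roles(model)
  base <- if (photon_constraint &&
              length(role_rxns(model, "photon_uptake", required = FALSE)))
    constrain_photons(model, ref) else model
  if (is.null(targets)) targets <- model$reactions$id
  unk <- setdiff(targets, model$reactions$id)
  if (length(unk)) stop("unknown reactions: ", paste(unk, collapse = ", "))

  rows <- lapply(targets, function(tg) {
    if (!(tg %in% act)) {
      cls <- list(class = "robust", near_essential = FALSE)
      comp <- list(n_activated = 0L, n_inactivated = 0L,
                   pathway = if (length(roles_present))
                     data.frame(role = roles_present, activated = FALSE,
                                increased = FALSE) else NULL)
      return(scan_result_row(tg, "reaction", method, ref,
                             ref$objective_value, cls, comp, roles_present))
    }
    res <- delete_one(base, tg, method, ref, settings, roles_present)
    cls <- classify_growth(ref$objective_value, res$growth, settings)
    scan_result_row(tg, "reaction", method, ref, res$growth, cls, res$comp,
                    roles_present)
  })
  out <- do.call(rbind, rows)
  attr(out, "active_targets") <- intersect(targets, act)
  attr(out, "reference") <- ref
  class(out) <- c("deletion_scan", class(out))
  out
}

#' Single gene deletion scan
#'
#' Knocks out each gene in turn: every reaction whose GPR rule evaluates
#' false under the knockout has its bounds set to `[0, 0]`, and the
#' resulting MMS is solved as in [single_reaction_deletion()]. "Active
#' genes" are genes appearing in the GPR of at least one active reaction of
#' the reference solution; knockouts that disable no reaction (or only
#' inactive ones) are trivially robust.
#'
#' @inheritParams single_reaction_deletion
#' @param allele_table Optional divergent allele pair table applied with
#'   [augment_with_alleles()] before the scan; the scan still iterates over
#'   the original gene list so robustness with and without alleles is
#'   comparable.
#' @param genes Genes to knock out; defaults to all model genes.
#' @return A `deletion_scan` data.frame, one row per gene, with an
#'   `active_gene` column.
#' @export
single_gene_deletion <- function(model, method = c("fba", "moma"),
                                 settings = solver_settings(),
                                 allele_table = NULL, reference = NULL,
                                 genes = NULL, photon_constraint = TRUE) {
  method <- match.arg(method)
  scan_genes <- if (is.null(genes)) model$genes else genes
  unk <- setdiff(scan_genes, model$genes)
  if (length(unk)) stop("unknown genes: ", paste(unk, collapse = ", "))
  if (length(scan_genes) == 0L) {
    out <- data.frame(target = character(0), kind = character(0),
                      method = character(0), growth_wt = numeric(0),
                      growth_del = numeric(0), growth_ratio = numeric(0),
                      robustness_class = character(0),
                      near_essential = logical(0),
                      n_activated = integer(0), n_inactivated = integer(0),
                      active_gene = logical(0), stringsAsFactors = FALSE)
    attr(out, "active_targets") <- character(0)
    class(out) <- c("deletion_scan", class(out))
    return(out)
  }
  if (!is.null(allele_table) && nrow(allele_table) > 0)
    model <- augment_with_alleles(model, allele_table)
  ref <- if (is.null(reference)) solve_pfba(model, settings) else reference
  if (ref$status != "optimal") stop("intact model is not solvable")
  act <- active_set(ref, settings)
  active_genes <- unique(unlist(lapply(model$gpr[act], gpr_genes)))
  roles_present <- pathway_flag_roles(model)
  base <- if (photon_constraint &&
              length(role_rxns(model, "photon_uptake", required = FALSE)))
    constrain_photons(model, ref) else model

  rows <- lapply(scan_genes, function(g) {
    off <- reactions_disabled_by(model, g)
    off_active <- intersect(off, act)
    if (length(off_active) == 0L) {
      cls <- list(class = "robust", near_essential = FALSE)
      comp <- list(n_activated = 0L, n_inactivated = 0L,
                   pathway = if (length(roles_present))
                     data.frame(role = roles_present, activated = FALSE,
                                increased = FALSE) else NULL)
      row <- scan_result_row(g, "gene", method, ref, ref$objective_value,
                             cls, comp, roles_present)
    } else {
      res <- delete_one(base, off, method, ref, settings, roles_present)
      cls <- classify_growth(ref$objective_value, res$growth, settings)
      row <- scan_result_row(g, "gene", method, ref, res$growth, cls,
                             res$comp, roles_present)
    }
    row$active_gene <- g %in% active_genes
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "active_targets") <- intersect(scan_genes, active_genes)
  attr(out, "reference") <- ref
  class(out) <- c("deletion_scan", class(out))
  out
}

#' Compensatory response between two flux solutions
#'
#' Compares the active sets of an intact-model solution and a
#' modified-model solution: counts reactions activated (inactive in the IM,
#' active in the MMS) and inactivated, and flags, for each tagged pathway,
#' whether its summed absolute flux was activated (zero to nonzero) or
#' strictly increased.
#'
#' @param solution_im,solution_mms Optimal `flux_solution` objects.
#' @param settings A [solver_settings()] object.
#' @param roles Role tags to flag; defaults to the pathway tags present in
#'   the scan functions.
#' @param model Optional model supplying role definitions when `roles` is
#'   a character vector of tag names.
#' @return A list with `n_activated`, `n_inactivated` and a data.frame
#'   `pathway` (role, flux_im, flux_mms, activated, increased).
#' @export
compensatory_response <- function(solution_im, solution_mms,
                                  settings = solver_settings(),
                                  roles = character(0), model = NULL) {
  if (solution_im$status != "optimal" || solution_mms$status != "optimal")
    stop("both solutions must be optimal")
  act_im <- active_set(solution_im, settings)
  act_mms <- active_set(solution_mms, settings)
  role_map <- attr(roles, "role_map")
  if (!is.null(model)) role_map <- model$roles
  if (is.null(role_map)) role_map <- attr(solution_im, "roles")
  pathway <- NULL
  if (length(roles)) {
    role_flux <- function(sol, rxns) {
      rxns <- intersect(rxns, names(sol$fluxes))
      sum(abs(sol$fluxes[rxns]))
    }
    rows <- lapply(roles, function(role) {
      rxns <- if (!is.null(role_map[[role]])) role_map[[role]] else role
      fi <- role_flux(solution_im, rxns)
      fm <- role_flux(solution_mms, rxns)
      data.frame(role = role, flux_im = fi, flux_mms = fm,
                 activated = fi <= settings$flux_zero_tolerance &&
                             fm > settings$flux_zero_tolerance,
                 increased = fm > fi + settings$flux_zero_tolerance,
                 stringsAsFactors = FALSE)
    })
    pathway <- do.call(rbind, rows)
  }
  list(n_activated = length(setdiff(act_mms, act_im)),
       n_inactivated = length(setdiff(act_im, act_mms)),
       pathway = pathway)
}

#' Summarise a deletion scan
#'
#' Tallies the robustness classes over the active targets and builds the
#' cumulative growth-inhibition curve: the percentage of targets whose
#' deletion inhibits growth by at most a given amount.
#'
#' @param results A `deletion_scan` data.frame.
#' @param active_only Restrict tallies to active targets (default `TRUE`).
#' @return An object of class `robustness_summary`.
#' @export
summarize_robustness <- function(results, active_only = TRUE) {
  act <- attr(results, "active_targets")
  df <- as.data.frame(results)
  if (active_only && !is.null(act)) df <- df[df$target %in% act, ]
  n <- nrow(df)
  if (n == 0L) stop("no (active) targets to summarise")
  counts <- c(robust = sum(df$robustness_class == "robust"),
              intermediate = sum(df$robustness_class == "intermediate"),
              essential = sum(df$robustness_class == "essential"))
  headline <- counts
  headline["essential"] <- headline["essential"] + sum(df$near_essential)
  headline["intermediate"] <- headline["intermediate"] - sum(df$near_essential)
  inhibition <- pmax(0, pmin(100, 100 * (1 - df$growth_ratio)))
  ord <- order(inhibition)
  curve <- data.frame(pct_targets = 100 * seq_len(n) / n,
                      inhibition_pct = inhibition[ord])
  structure(list(n_targets = n, counts = counts,
                 counts_headline = headline,
                 percentages = 100 * counts / n,
                 percentages_headline = 100 * headline / n,
                 n_near_essential = sum(df$near_essential),
                 method = df$method[1], kind = df$kind[1], curve = curve),
            class = "robustness_summary")
}

#' @export
print.robustness_summary <- function(x, ...) {
  cat(sprintf("%s deletion scan (%s): %d active targets\n", x$kind, x$method,
              x$n_targets))
  for (cl in names(x$counts))
    cat(sprintf("  %-13s %4d  (%.1f%%)\n", cl, x$counts[[cl]],
                x$percentages[[cl]]))
  if (x$n_near_essential > 0)
    cat(sprintf("  (%d intermediate targets inhibit growth by >= 99%% and are\n",
                x$n_near_essential),
        "  merged with essential in headline counts)\n")
  invisible(x)
}

#' @export
print.deletion_scan <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("deletion scan: %d %s targets (%s)\n", nrow(df), df$kind[1],
              df$method[1]))
  tab <- table(df$robustness_class)
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.deletion_scan <- function(object, ...) summarize_robustness(object, ...)

#' Plot the cumulative growth-inhibition curve
#'
#' @param x A `robustness_summary` (or `deletion_scan`, summarised first).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.robustness_summary <- function(x, ...) {
  graphics::plot(x$curve$pct_targets, x$curve$inhibition_pct, type = "s",
                 xlab = "% of active targets",
                 ylab = "growth inhibition (%)",
                 main = sprintf("cumulative inhibition (%s, %s)", x$kind,
                                x$method), ...)
  invisible(x)
}

#' @export
plot.deletion_scan <- function(x, ...) plot(summarize_robustness(x), ...)
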