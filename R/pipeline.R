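# End-to-end orchestration: quality control, parsimonious FBA, sensitivity
# analyses, deletion scans (with and without divergent alleles), and
# network metrics, with all module outputs written to an output directory
# together with a JSON manifest recording versions, seed and tolerances.

#' Run configuration for the full analysis
#'
#' @param model Path to a model file (SBML/JSON), a `metabolic_model`, or
#'   `NULL` to generate a synthetic model from `synth`.
#' @param synth A [synth_config()] used when `model` is `NULL`.
#' @param params A [composition_params()] set, a parameter file path, or
#'   `NULL` for nominal values.
#' @param allele_table Allele pair table (data.frame or TSV path), or
#'   `NULL`.
#' @param methods Deletion methods to run, subset of `c("fba", "moma")`.
#' @param scenario Bioenergetic scenario passed to
#'   [bioenergetics_scenario()] when the model carries the required roles.
#' @param sensitivity List of settings: `factor`, `n_random`, `morris_r`,
#'   `levels`; any may be `NULL` to skip that analysis.
#' @param seed Integer seed used for every stochastic stage.
#' @param out_dir Output directory (created); `NULL` writes nothing.
#' @param settings A [solver_settings()] object.
#' @return A `run_config` list.
#' @export
run_config <- function(model = NULL, synth = synth_config(), params = NULL,
                       allele_table = NULL, methods = c("fba", "moma"),
                       scenario = NULL,
                       sensitivity = list(factor = 0.4, n_random = 1000,
                                          morris_r = 10, levels = 4),
                       seed = 1L, out_dir = NULL,
                       settings = solver_settings()) {
  stopifnot(all(methods %in% c("fba", "moma")))
  structure(list(model = model, synth = synth, params = params,
                 allele_table = allele_table, methods = methods,
                 scenario = scenario, sensitivity = sensitivity,
                 seed = as.integer(seed), out_dir = out_dir,
                 settings = settings),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognised keys mirror the arguments of [run_config()]; `synth` keys are
#' passed to [synth_config()].
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- do.call(synth_config, c(y$synth %||% list(),
                                 if (!is.null(y$seed) && is.null(y$synth$seed))
                                   list(seed = y$seed)))
  run_config(model = y$model, synth = syn, params = y$params,
             allele_table = y$allele_table,
             methods = y$methods %||% c("fba", "moma"),
             scenario = y$scenario,
             sensitivity = y$sensitivity %||%
               list(factor = 0.4, n_random = 1000, morris_r = 10, levels = 4),
             seed = y$seed %||% 1L, out_dir = y$out_dir)
}

#' Run the full robustness analysis pipeline
#'
#' Stages: model loading or generation, quality control (blocking unless
#' `force = TRUE`), parsimonious FBA of the intact model, local sensitivity
#' analysis, random-combination analysis, Morris screening, single
#' reaction deletions, single gene deletions with and without divergent
#' alleles, and bipartite network metrics comparing the metabolites of
#' robust versus sensitive reactions. Results are returned as a list and,
#' when `out_dir` is set, written as TSV/JSON files plus a manifest.
#'
#' @param config A [run_config()] (or a YAML path accepted by
#'   [read_run_config()]).
#' @param force Continue past a failing quality control.
#' @param quiet Suppress per-stage messages.
#' @return A list of stage results, invisibly when writing to disk.
#' @export
run_pipeline <- function(config = run_config(), force = FALSE, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  settings <- config$settings
  say <- function(...) if (!quiet) message("[robustfba] ", ...)
  t0 <- Sys.time()
  res <- list(seed = config$seed, settings = settings)

  # -- model -----------------------------------------------------------
  params <- config$params
  if (is.character(params)) params <- read_composition_params(params)
  allele_table <- config$allele_table
  if (is.character(allele_table)) allele_table <- read_allele_table(allele_table)
  if (is.null(config$model)) {
    say("generating synthetic model (seed ", config$synth$seed, ")")
    gen <- generate_model(config$synth, qc = FALSE, settings = settings)
    model <- gen$model
    if (is.null(params)) params <- gen$params
    if (is.null(allele_table)) allele_table <- gen$allele_table
  } else if (is.character(config$model)) {
    say("reading model from ", config$model)
    model <- read_model(config$model)
  } else model <- config$model
  if (is.null(params)) params <- composition_params()
  if (!is.null(model$biomass_spec)) model <- update_model_params(model, params)
  if (!is.null(config$scenario)) {
    say("applying bioenergetic scenario: ", config$scenario)
    model <- bioenergetics_scenario(model, config$scenario)
  }
  res$model_stats <- model_stats(model)

  # -- qc --------------------------------------------------------------
  say("quality control")
  qc <- list(leak = qc_leak_test(model, settings))
  if (length(role_rxns(model, "atp_maintenance", required = FALSE)))
    qc$energy <- qc_energy_from_nothing(model, settings)
  res$qc <- qc
  qc_pass <- qc$leak$pass && (is.null(qc$energy) || qc$energy$pass)
  if (!qc_pass && !force)
    stop("stage 'qc' failed: model leaks or generates energy from nothing; ",
         "re-run with force = TRUE to continue")

  # -- pFBA ------------------------------------------------------------
  say("parsimonious FBA of the intact model")
  ref <- solve_pfba(model, settings)
  if (ref$status != "optimal") stop("stage 'fba' failed: status ", ref$status)
  act <- active_set(ref, settings)
  res$pfba <- list(solution = ref, growth = ref$objective_value,
                   growth_per_day = ref$growth_rate_per_day,
                   n_active = length(act),
                   n_inactive = nrow(model$reactions) - length(act))

  # -- sensitivity -----------------------------------------------------
  sens <- config$sensitivity
  can_sa <- !is.null(model$biomass_spec)
  if (can_sa && !is.null(sens$factor)) {
    say("local sensitivity analysis")
    res$local_sa <- local_sa(model, params, factor = sens$factor,
                             settings = settings)
  }
  if (can_sa && !is.null(sens$n_random) && sens$n_random > 0) {
    say("random-combination sensitivity (n = ", sens$n_random, ")")
    res$random_sa <- random_combo_sa(model, params, n = sens$n_random,
                                     factor = sens$factor %||% 0.4,
                                     seed = config$seed, settings = settings)
  }
  if (can_sa && !is.null(sens$morris_r) && sens$morris_r >= 2) {
    say("Morris screening (r = ", sens$morris_r, ")")
    res$morris <- morris_sa(model, params, r = sens$morris_r,
                            levels = sens$levels %||% 4,
                            factor = sens$factor %||% 0.4,
                            seed = config$seed, settings = settings)
  }

  # -- deletions -------------------------------------------------------
  res$reaction_deletion <- list(); res$gene_deletion <- list()
  for (m in config$methods) {
    say("single reaction deletions (", m, ")")
    scan <- single_reaction_deletion(model, method = m, settings = settings,
                                     reference = ref)
    res$reaction_deletion[[m]] <-
      list(scan = scan, summary = summarize_robustness(scan))
    out_g <- list()
    if (length(model$genes)) {
      say("single gene deletions (", m, ")")
      gscan <- single_gene_deletion(model, method = m, settings = settings,
                                    reference = ref)
      out_g <- list(scan = gscan, summary = summarize_robustness(gscan))
    }
    if (length(model$genes) &&
        !is.null(allele_table) && nrow(allele_table) > 0) {
      say("single gene deletions with divergent alleles (", m, ")")
      ascan <- single_gene_deletion(model, method = m, settings = settings,
                                    allele_table = allele_table)
      out_g$scan_alleles <- ascan
      out_g$summary_alleles <- summarize_robustness(ascan)
    }
    res$gene_deletion[[m]] <- out_g
  }

  # -- network ---------------------------------------------------------
  say("bipartite network metrics")
  graph <- build_active_bipartite(model, ref, settings)
  metrics <- bipartite_centralities(graph)
  res$network <- list(graph = graph, metrics = metrics,
                      n_nodes = igraph::vcount(graph),
                      n_metabolites = sum(igraph::V(graph)$kind == "metabolite"),
                      n_reactions = sum(igraph::V(graph)$kind == "reaction"))
  m1 <- config$methods[1]
  rscan <- res$reaction_deletion[[m1]]$scan
  rsub <- rscan[rscan$target %in% act, ]
  robust <- rsub$target[rsub$robustness_class == "robust"]
  sensitive <- rsub$target[rsub$robustness_class == "essential" |
                             rsub$near_essential]
  if (length(robust) && length(sensitive))
    res$network$comparison <- compare_metabolite_sets(graph, robust, sensitive,
                                                      metrics = metrics)

  res$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(res, model, params, config)
    return(invisible(res))
  }
  res
}

write_pipeline_outputs <- function(res, model, params, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(config$out_dir, ...)
  write_model(model, fp("model.json"))
  write_composition_params(params, fp("parameters.tsv"))
  write_fluxes(res$pfba$solution, fp("fluxes.tsv"))
  if (!is.null(res$local_sa))
    write.table(as.data.frame(res$local_sa), fp("local_sa.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(res$morris))
    write.table(res$morris$indices, fp("morris.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  for (m in names(res$reaction_deletion)) {
    write.table(as.data.frame(res$reaction_deletion[[m]]$scan),
                fp(paste0("reaction_deletions_", m, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(res$reaction_deletion[[m]]$summary$curve,
                fp(paste0("inhibition_curve_reactions_", m, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (m in names(res$gene_deletion)) {
    write.table(as.data.frame(res$gene_deletion[[m]]$scan),
                fp(paste0("gene_deletions_", m, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(res$gene_deletion[[m]]$scan_alleles))
      write.table(as.data.frame(res$gene_deletion[[m]]$scan_alleles),
                  fp(paste0("gene_deletions_alleles_", m, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$network)) {
    write_bipartite(res$network$graph, fp("bipartite_edges.tsv"))
    write.table(res$network$metrics, fp("node_metrics.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  qc_out <- list(leak = list(pass = res$qc$leak$pass,
                             leaky = res$qc$leak$leaky),
                 energy = if (!is.null(res$qc$energy))
                   list(pass = res$qc$energy$pass,
                        maxima = as.list(res$qc$energy$maxima)))
  jsonlite::write_json(qc_out, fp("qc_report.json"), auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(
    package = "robustfba",
    version = as.character(utils::packageVersion("robustfba")),
    seed = config$seed,
    tolerances = unclass(config$settings),
    growth_per_day = res$pfba$growth_per_day,
    n_active_reactions = res$pfba$n_active,
    elapsed_s = res$elapsed_s,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(config$out_dir)
}
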