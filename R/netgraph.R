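# Directed bipartite metabolite-reaction network of the active subnetwork.
#
# Substrates point to the reactions consuming them, reactions point to
# their products. Only reactions carrying flux in the intact-model
# solution are included; reversible reactions carried with negative flux
# have substrate and product roles swapped before edges are created, so
# edge orientation follows the realised flux direction.

#' Build the active-subnetwork bipartite graph
#'
#' @param model A `metabolic_model`.
#' @param solution An optimal `flux_solution` of the model.
#' @param settings A [solver_settings()] object (flux detection limits
#'   defining the active set).
#' @return An `igraph` directed graph with vertex attributes `kind`
#'   (`"metabolite"` or `"reaction"`) and `type` (logical, for igraph's
#'   bipartite helpers).
#' @export
build_active_bipartite <- function(model, solution,
                                   settings = solver_settings()) {
  act <- active_set(solution, settings)
  edges <- list()
  mets_used <- character(0)
  for (rid in act) {
    st <- model$stoichiometry[[rid]]
    if (solution$fluxes[[rid]] < 0) st <- -st
    subs <- names(st)[st < 0]
    prods <- names(st)[st > 0]
    mets_used <- c(mets_used, subs, prods)
    if (length(subs))
      edges[[length(edges) + 1L]] <- data.frame(from = subs, to = rid,
                                                stringsAsFactors = FALSE)
    if (length(prods))
      edges[[length(edges) + 1L]] <- data.frame(from = rid, to = prods,
                                                stringsAsFactors = FALSE)
  }
  mets_used <- unique(mets_used)
  vertices <- data.frame(
    name = c(mets_used, act),
    kind = c(rep("metabolite", length(mets_used)),
             rep("reaction", length(act))),
    stringsAsFactors = FALSE)
  vertices$type <- vertices$kind == "reaction"
  g <- igraph::graph_from_data_frame(
    if (length(edges)) do.call(rbind, edges)
    else data.frame(from = character(0), to = character(0)),
    directed = TRUE, vertices = vertices)
  g
}

#' Degree metrics of the metabolite nodes
#'
#' For each metabolite: `out_degree` counts reactions consuming it as a
#' substrate, `in_degree` counts reactions producing it, and
#' `total_degree = in_degree + out_degree`.
#'
#' @param graph A bipartite graph from [build_active_bipartite()].
#' @param metabolites_only Restrict rows to metabolite nodes (default).
#' @return data.frame with `node`, `kind` and the three degree columns.
#' @export
bipartite_degrees <- function(graph, metabolites_only = TRUE) {
  kind <- igraph::V(graph)$kind
  out <- data.frame(node = igraph::V(graph)$name, kind = kind,
                    in_degree = igraph::degree(graph, mode = "in"),
                    out_degree = igraph::degree(graph, mode = "out"),
                    stringsAsFactors = FALSE)
  out$total_degree <- out$in_degree + out$out_degree
  rownames(out) <- NULL
  if (metabolites_only) out <- out[out$kind == "metabolite", ]
  out
}

#' Centrality metrics of the bipartite graph
#'
#' Betweenness is the raw (unnormalised) count of directed shortest paths
#' crossing a node (paths may run through metabolite and reaction nodes
#' alike; metabolite rows are reported by default). Closeness is the
#' reciprocal of the sum of directed shortest-path lengths from the node
#' to every node it can reach (0 for nodes reaching nothing).
#'
#' @inheritParams bipartite_degrees
#' @return data.frame with degree and centrality columns per node.
#' @export
bipartite_centralities <- function(graph, metabolites_only = TRUE) {
  deg <- bipartite_degrees(graph, metabolites_only = FALSE)
  btw <- igraph::betweenness(graph, directed = TRUE, normalized = FALSE)
  D <- igraph::distances(graph, mode = "out")
  clo <- apply(D, 1, function(d) {
    d <- d[is.finite(d) & d > 0]
    if (length(d) == 0L) 0 else 1 / sum(d)
  })
  deg$betweenness <- unname(btw[deg$node])
  deg$closeness <- unname(clo[deg$node])
  if (metabolites_only) deg <- deg[deg$kind == "metabolite", ]
  deg
}

#' Compare metabolites of robust versus sensitive reactions
#'
#' The "robust metabolites" are the metabolites incident to at least one
#' reaction of the robust set, the "sensitive metabolites" those incident
#' to the sensitive set; a metabolite (e.g. a currency metabolite) may
#' belong to both. For every metric the mean and median within each set
#' are reported together with their ratios, plus relative-frequency degree
#' histograms (bins 1..20 and 20+).
#'
#' @param graph A bipartite graph from [build_active_bipartite()].
#' @param robust_rxns,sensitive_rxns Reaction-id sets (from a deletion
#'   scan).
#' @param metrics Optional precomputed [bipartite_centralities()] table.
#' @return A list with per-set statistics, ratios and histograms.
#' @export
compare_metabolite_sets <- function(graph, robust_rxns, sensitive_rxns,
                                    metrics = NULL) {
  if (length(robust_rxns) == 0L || length(sensitive_rxns) == 0L)
    stop("both reaction sets must be nonempty")
  if (is.null(metrics)) metrics <- bipartite_centralities(graph)
  nodes <- igraph::V(graph)$name
  met_set <- function(rxns) {
    rxns <- intersect(rxns, nodes)
    if (length(rxns) == 0L) stop("reaction set absent from the graph")
    nb <- unique(unlist(igraph::adjacent_vertices(
      graph, rxns, mode = "all")))
    intersect(nodes[nb], metrics$node)
  }
  sets <- list(robust = met_set(robust_rxns),
               sensitive = met_set(sensitive_rxns))
  cols <- c("total_degree", "in_degree", "out_degree", "betweenness",
            "closeness")
  stat <- function(members) {
    sub <- metrics[metrics$node %in% members, cols]
    rbind(mean = colMeans(sub), median = apply(sub, 2, median))
  }
  stats <- lapply(sets, stat)
  ratios <- stats$robust / stats$sensitive
  hist_deg <- function(members, col) {
    v <- metrics[[col]][metrics$node %in% members]
    v <- pmin(v, 21)                      # 21 == "more than 20"
    tab <- tabulate(v, nbins = 21)
    tab / length(v)
  }
  histograms <- lapply(c(total_degree = "total_degree",
                         in_degree = "in_degree", out_degree = "out_degree"),
                       function(col)
                         data.frame(bin = c(as.character(1:20), "20+"),
                                    robust = hist_deg(sets$robust, col),
                                    sensitive = hist_deg(sets$sensitive, col)))
  list(sets = sets,
       n = vapply(sets, length, integer(1)),
       stats = stats, ratios = ratios, histograms = histograms)
}

#' Export a bipartite graph
#'
#' @param graph A bipartite graph.
#' @param path Output path; `.graphml` writes GraphML, anything else an
#'   edge-list TSV with node kinds.
#' @export
write_bipartite <- function(graph, path) {
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(graph, what = "edges")
    kind <- setNames(igraph::V(graph)$kind, igraph::V(graph)$name)
    el$from_kind <- kind[el$from]
    el$to_kind <- kind[el$to]
    write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
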