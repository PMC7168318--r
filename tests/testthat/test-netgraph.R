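settings <- solver_settings()

chain_graph <- function() {
  # A -> R1 -> B -> R2 -> C with unit fluxes
  mets <- data.frame(id = c("A", "B", "C"), compartment = "c")
  rx <- data.frame(id = c("R1", "R2"), lower_bound = -10, upper_bound = 10,
                   is_exchange = FALSE)
  st <- list(R1 = c(A = -1, B = 1), R2 = c(B = -1, C = 1))
  model <- metabolic_model(mets, rx, st, compartments = c(c = "cytosol"),
                           objective = "R1")
  sol <- robustfba:::new_flux_solution(c(R1 = 1, R2 = 1), "optimal", "R1",
                                       "fba", settings)
  build_active_bipartite(model, sol, settings)
}

test_that("the bipartite graph of a chain has the expected shape", {
  g <- chain_graph()
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 4)
  expect_setequal(igraph::V(g)$name[igraph::V(g)$kind == "metabolite"],
                  c("A", "B", "C"))
  deg <- bipartite_degrees(g)
  b <- deg[deg$node == "B", ]
  expect_equal(c(b$in_degree, b$out_degree, b$total_degree), c(1, 1, 2))
  # two-mode: every edge connects a metabolite with a reaction
  el <- igraph::as_data_frame(g)
  kind <- setNames(igraph::V(g)$kind, igraph::V(g)$name)
  expect_true(all(kind[el$from] != kind[el$to]))
})

test_that("zero-flux solutions give an empty graph and orientation follows flux sign", {
  mets <- data.frame(id = c("A", "B"), compartment = "c")
  rx <- data.frame(id = "R1", lower_bound = -10, upper_bound = 10,
                   is_exchange = FALSE)
  model <- metabolic_model(mets, rx, list(R1 = c(A = -1, B = 1)),
                           compartments = c(c = "cytosol"), objective = "R1")
  z <- robustfba:::new_flux_solution(c(R1 = 0), "optimal", "R1", "fba",
                                     settings)
  expect_equal(igraph::vcount(build_active_bipartite(model, z, settings)), 0)
  # negative flux: B is the substrate, A the product
  neg <- robustfba:::new_flux_solution(c(R1 = -2), "optimal", "R1", "fba",
                                       settings)
  gneg <- build_active_bipartite(model, neg, settings)
  el <- igraph::as_data_frame(gneg)
  expect_true(any(el$from == "B" & el$to == "R1"))
  expect_true(any(el$from == "R1" & el$to == "A"))
})

test_that("degrees match a brute-force adjacency count on a synthetic model", {
  g <- generate_model(synth_config(seed = 3, composition = "compact"),
                      qc = FALSE)
  sol <- solve_pfba(g$model, settings)
  bg <- build_active_bipartite(g$model, sol, settings)
  deg <- bipartite_degrees(bg)
  act <- active_set(sol, settings)
  for (met in sample(deg$node, 10)) {
    prod <- sum(vapply(act, function(r) {
      st <- g$model$stoichiometry[[r]]
      if (sol$fluxes[[r]] < 0) st <- -st
      isTRUE(st[met] > 0)
    }, logical(1)))
    cons <- sum(vapply(act, function(r) {
      st <- g$model$stoichiometry[[r]]
      if (sol$fluxes[[r]] < 0) st <- -st
      isTRUE(st[met] < 0)
    }, logical(1)))
    row <- deg[deg$node == met, ]
    expect_equal(c(row$in_degree, row$out_degree), c(prod, cons), info = met)
  }
  # sum of metabolite in-degrees equals the number of reaction->metabolite edges
  el <- igraph::as_data_frame(bg)
  kind <- setNames(igraph::V(bg)$kind, igraph::V(bg)$name)
  expect_equal(sum(deg$in_degree), sum(kind[el$from] == "reaction"))
})

test_that("centralities agree with an all-pairs BFS oracle on small graphs", {
  g5 <- chain_graph()
  met <- bipartite_centralities(g5)
  # middle metabolite of the chain has the strictly greatest betweenness
  expect_equal(met$node[which.max(met$betweenness)], "B")
  # oracle comparison on the full 5-node graph plus random bipartite graphs
  graphs <- list(g5)
  set.seed(21)
  for (rep in 1:4) {
    nm <- 4; nr <- 3
    mets <- data.frame(id = paste0("m", 1:nm), compartment = "c")
    rx <- data.frame(id = paste0("r", 1:nr), lower_bound = 0,
                     upper_bound = 10, is_exchange = FALSE)
    st <- lapply(setNames(rx$id, rx$id), function(r) {
      k <- sample(2:3, 1)
      picks <- sample(mets$id, k)
      setNames(c(-1, rep(1, k - 1)), picks)
    })
    model <- metabolic_model(mets, rx, st, compartments = c(c = "cytosol"),
                             objective = "r1")
    sol <- robustfba:::new_flux_solution(setNames(rep(1, nr), rx$id),
                                         "optimal", "r1", "fba", settings)
    graphs[[length(graphs) + 1]] <- build_active_bipartite(model, sol,
                                                           settings)
  }
  for (bg in graphs) {
    nodes <- igraph::V(bg)$name
    oracle <- bfs_centralities(igraph::as_data_frame(bg), nodes)
    got <- bipartite_centralities(bg, metabolites_only = FALSE)
    expect_equal(got$betweenness, oracle$betweenness[match(got$node,
                                                           oracle$node)],
                 tolerance = 1e-9)
    expect_equal(got$closeness, oracle$closeness[match(got$node,
                                                       oracle$node)],
                 tolerance = 1e-9)
  }
})

test_that("complete bipartite toys have symmetric metabolite betweenness", {
  mets <- data.frame(id = c("m1", "m2"), compartment = "c")
  rx <- data.frame(id = c("r1", "r2"), lower_bound = 0, upper_bound = 10,
                   is_exchange = FALSE)
  st <- list(r1 = c(m1 = -1, m2 = 1), r2 = c(m2 = -1, m1 = 1))
  model <- metabolic_model(mets, rx, st, compartments = c(c = "cytosol"),
                           objective = "r1")
  sol <- robustfba:::new_flux_solution(c(r1 = 1, r2 = 1), "optimal", "r1",
                                       "fba", settings)
  cg <- bipartite_centralities(build_active_bipartite(model, sol, settings))
  expect_equal(cg$betweenness[1], cg$betweenness[2])
})

test_that("robust/sensitive metabolite sets compare as designed", {
  h <- hub_toy_graph()
  bg <- build_active_bipartite(h$model, h$solution, settings)
  # identical sets: every ratio is 1
  same <- compare_metabolite_sets(bg, c("RHUB", "R1"), c("RHUB", "R1"))
  expect_equal(same$stats$robust, same$stats$sensitive)
  ok <- is.finite(same$ratios)            # 0/0 metrics are NaN by design
  expect_true(all(abs(same$ratios[ok] - 1) < 1e-12))
  # hub-backed set vs chain-end set: higher mean degree for the hub set
  cmpr <- compare_metabolite_sets(bg, c("RHUB", "R1", "R2", "R3"), "REND")
  expect_gt(cmpr$stats$robust["mean", "total_degree"],
            cmpr$stats$sensitive["mean", "total_degree"])
  expect_error(compare_metabolite_sets(bg, character(0), "REND"), "nonempty")
  # histogram masses sum to one
  expect_equal(sum(cmpr$histograms$total_degree$robust), 1, tolerance = 1e-12)
})

test_that("graph export writes edge lists and GraphML", {
  bg <- chain_graph()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_bipartite(bg, tsv)
  el <- read.delim(tsv)
  expect_equal(nrow(el), 4)
  expect_true(all(el$from_kind != el$to_kind))
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_bipartite(bg, gml)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g2), 5)
})
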