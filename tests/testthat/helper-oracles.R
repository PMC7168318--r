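# Independent brute-force oracles, deliberately naive implementations.

# enumerate the vertices of {v : S v = 0, lb <= v <= ub} by fixing every
# choice of n - rank(S) variables at a bound and solving for the rest
enumerate_vertices <- function(S, lb, ub) {
  n <- ncol(S)
  r <- qr(S)$rank
  nfix <- n - r
  verts <- list()
  add_vertex <- function(v) {
    if (any(v < lb - 1e-8) || any(v > ub + 1e-8)) return()
    if (max(abs(S %*% v)) > 1e-8) return()
    verts[[length(verts) + 1L]] <<- pmin(pmax(v, lb), ub)
  }
  if (nfix == 0L) {
    add_vertex(qr.solve(S, numeric(nrow(S))))
  } else {
    combos <- combn(n, nfix)
    for (ci in seq_len(ncol(combos))) {
      fixed <- combos[, ci]
      freev <- setdiff(seq_len(n), fixed)
      Sf <- S[, freev, drop = FALSE]
      if (qr(Sf)$rank < length(freev)) next
      sides <- as.matrix(expand.grid(rep(list(c(1, 2)), nfix)))
      for (si in seq_len(nrow(sides))) {
        vfix <- ifelse(sides[si, ] == 1, lb[fixed], ub[fixed])
        if (any(!is.finite(vfix))) next
        rhs <- -S[, fixed, drop = FALSE] %*% vfix
        sol <- tryCatch(qr.coef(qr(Sf), rhs), error = function(e) NULL)
        if (is.null(sol) || anyNA(sol)) next
        if (max(abs(Sf %*% sol - rhs)) > 1e-8) next
        v <- numeric(n); v[fixed] <- vfix; v[freev] <- sol
        add_vertex(v)
      }
    }
  }
  if (length(verts) == 0L) return(NULL)
  V <- do.call(rbind, verts)
  V[!duplicated(round(V, 6)), , drop = FALSE]
}

# maximal growth over the vertex enumeration of a model's flux polytope
vertex_max_growth <- function(model) {
  S <- stoich_matrix(model)
  V <- enumerate_vertices(S, model$reactions$lower_bound,
                          model$reactions$upper_bound)
  if (is.null(V)) return(NA_real_)
  max(V[, match(model$objective, colnames(S))])
}

# minimal L1 norm among vertices attaining growth mu (within tol)
vertex_min_l1_at <- function(model, mu, tol = 1e-6) {
  S <- stoich_matrix(model)
  obj <- match(model$objective, colnames(S))
  # split fluxes so that L1-optimal points are vertices of the lifted polytope
  n <- ncol(S)
  A <- cbind(S, -S)
  lb <- c(pmax(model$reactions$lower_bound, 0),
          pmax(-model$reactions$upper_bound, 0))
  ub <- c(pmax(model$reactions$upper_bound, 0),
          pmax(-model$reactions$lower_bound, 0))
  lb[obj] <- mu; ub[obj] <- mu; lb[n + obj] <- 0; ub[n + obj] <- 0
  V <- enumerate_vertices(A, lb, ub)
  if (is.null(V)) return(NA_real_)
  min(rowSums(V))
}

# all-pairs BFS shortest-path betweenness (fractional geodesic counts) and
# closeness on a directed edge list
bfs_centralities <- function(edges, nodes) {
  adj <- lapply(setNames(nodes, nodes), function(v)
    edges$to[edges$from == v])
  btw <- setNames(numeric(length(nodes)), nodes)
  clo <- setNames(numeric(length(nodes)), nodes)
  for (s in nodes) {
    # BFS from s with geodesic counting (Brandes-style, naive)
    dist <- setNames(rep(Inf, length(nodes)), nodes)
    sigma <- setNames(numeric(length(nodes)), nodes)
    preds <- lapply(setNames(nodes, nodes), function(x) character(0))
    dist[s] <- 0; sigma[s] <- 1
    frontier <- s; order_visited <- character(0)
    while (length(frontier)) {
      nxt <- character(0)
      for (v in frontier) {
        order_visited <- c(order_visited, v)
        for (w in adj[[v]]) {
          if (!is.finite(dist[w])) { dist[w] <- dist[v] + 1; nxt <- union(nxt, w) }
          if (dist[w] == dist[v] + 1) {
            sigma[w] <- sigma[w] + sigma[v]
            preds[[w]] <- c(preds[[w]], v)
          }
        }
      }
      frontier <- nxt
    }
    d <- dist[names(dist) != s]
    d <- d[is.finite(d)]
    clo[s] <- if (length(d)) 1 / sum(d) else 0
    delta <- setNames(numeric(length(nodes)), nodes)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) btw[w] <- btw[w] + delta[w]
    }
  }
  data.frame(node = nodes, betweenness = unname(btw),
             closeness = unname(clo), stringsAsFactors = FALSE)
}

# independent GPR evaluation: translate the rule text to an R boolean
# expression and evaluate it with knocked-out genes bound to FALSE
eval_gpr_via_expression <- function(rule_text, genes, knocked_out) {
  if (!nzchar(rule_text)) return(TRUE)
  expr <- gsub("\\bor\\b", "||", gsub("\\band\\b", "&&", rule_text,
                                      ignore.case = TRUE), ignore.case = TRUE)
  env <- new.env()
  for (g in genes) assign(g, !(g %in% knocked_out), envir = env)
  isTRUE(eval(parse(text = expr), envir = env))
}

# random GPR tree with at most `max_leaves` leaves over the given genes
random_gpr_tree <- function(genes, max_leaves = 12) {
  build <- function(budget) {
    if (budget <= 1 || runif(1) < 0.35) return(sample(genes, 1))
    k <- sample(2:min(3, budget), 1)
    split <- rep(floor(budget / k), k)
    list(op = sample(c("and", "or"), 1),
         args = lapply(split, build))
  }
  build(max_leaves)
}
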