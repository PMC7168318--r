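# Flux computations: plain FBA, lexicographic parsimonious FBA (maximise
# growth, then minimise the Manhattan norm of the flux vector at fixed
# optimal growth), MOMA (nearest feasible flux vector to a reference, in the
# Euclidean sense), and the model quality controls.

new_flux_solution <- function(fluxes, status, objective_id, method, settings,
                              moma_distance = NULL) {
  growth <- if (status == "optimal") unname(fluxes[objective_id]) else NA_real_
  structure(list(fluxes = fluxes,
                 objective_value = growth,
                 growth_rate_per_day = if (is.na(growth)) NA_real_ else 24 * growth,
                 status = status,
                 objective_id = objective_id,
                 method = method,
                 moma_distance = moma_distance,
                 settings = settings),
            class = "flux_solution")
}

lp_parts <- function(model) {
  S <- stoich_matrix(model)
  obj <- as.numeric(model$reactions$id == model$objective)
  list(S = S, b = numeric(nrow(S)), obj = obj,
       lb = model$reactions$lower_bound, ub = model$reactions$upper_bound)
}

#' Flux balance analysis (growth maximisation only)
#'
#' Maximises the objective (biomass) flux over the steady-state polytope
#' `S v = 0`, `lb <= v <= ub`. The flux vector returned is one optimal
#' vertex and is generally not unique; use [solve_pfba()] when individual
#' fluxes matter.
#'
#' @param model A `metabolic_model`.
#' @param settings A [solver_settings()] object.
#' @return A `flux_solution`.
#' @export
solve_fba <- function(model, settings = solver_settings()) {
  p <- lp_parts(model)
  r <- solve_lp(p$S, p$b, p$obj, p$lb, p$ub, maximize = TRUE,
                tol = settings$feasibility_tolerance)
  if (r$status != "optimal")
    return(new_flux_solution(setNames(rep(NA_real_, ncol(p$S)), colnames(p$S)),
                             r$status, model$objective, "fba", settings))
  new_flux_solution(setNames(r$x, colnames(p$S)), "optimal", model$objective,
                    "fba", settings)
}

#' Parsimonious flux balance analysis
#'
#' Lexicographic two-step optimisation: first the biomass flux is maximised;
#' then, holding the biomass flux at its optimum (as an equality), the
#' Manhattan norm `sum(|v|)` of the flux vector is minimised by splitting
#' each flux into nonnegative forward and reverse parts. The secondary
#' objective models minimal total enzyme usage and selects a single flux
#' distribution among alternative growth optima (up to solver determinism on
#' degenerate networks).
#'
#' @inheritParams solve_fba
#' @return A `flux_solution`; `$l1_norm` carries the minimised Manhattan norm.
#' @export
solve_pfba <- function(model, settings = solver_settings()) {
  p <- lp_parts(model)
  r1 <- solve_lp(p$S, p$b, p$obj, p$lb, p$ub, maximize = TRUE,
                 tol = settings$feasibility_tolerance)
  if (r1$status != "optimal")
    return(new_flux_solution(setNames(rep(NA_real_, ncol(p$S)), colnames(p$S)),
                             r1$status, model$objective, "pfba", settings))
  mu <- r1$objective
  n <- ncol(p$S)
  A2 <- cbind(p$S, -p$S)
  lbf <- pmax(p$lb, 0); ubf <- pmax(p$ub, 0)
  lbr <- pmax(-p$ub, 0); ubr <- pmax(-p$lb, 0)
  iobj <- which(p$obj == 1)
  lbf[iobj] <- mu; ubf[iobj] <- mu            # growth pinned at its optimum
  lbr[iobj] <- 0; ubr[iobj] <- 0
  r2 <- solve_lp(A2, p$b, rep(1, 2 * n), c(lbf, lbr), c(ubf, ubr),
                 maximize = FALSE, tol = settings$feasibility_tolerance)
  if (r2$status != "optimal") {
    # fall back on the step-1 vertex (pinning can fail only by round-off)
    sol <- new_flux_solution(setNames(r1$x, colnames(p$S)), "optimal",
                             model$objective, "pfba", settings)
    sol$l1_norm <- sum(abs(r1$x))
    return(sol)
  }
  v <- r2$x[seq_len(n)] - r2$x[n + seq_len(n)]
  sol <- new_flux_solution(setNames(v, colnames(p$S)), "optimal",
                           model$objective, "pfba", settings)
  sol$l1_norm <- r2$objective
  sol
}

#' Minimisation of metabolic adjustment (MOMA)
#'
#' Finds the flux vector of the modified model (deletion strain) closest in
#' squared Euclidean distance to a reference flux distribution of the intact
#' model, subject to steady state and the modified bounds. Growth is read
#' off the biomass flux of the minimiser; it is not itself optimised, which
#' models short-term acclimation rather than re-optimised growth. The
#' distance is taken over all reactions, exchanges included.
#'
#' @param model_modified The perturbed `metabolic_model`.
#' @param reference A `flux_solution` for the intact model.
#' @param settings A [solver_settings()] object.
#' @return A `flux_solution` with `$moma_distance` set.
#' @export
solve_moma <- function(model_modified, reference, settings = solver_settings()) {
  stopifnot(inherits(reference, "flux_solution"))
  if (reference$status != "optimal")
    stop("MOMA reference solution is not optimal")
  p <- lp_parts(model_modified)
  w <- reference$fluxes[colnames(p$S)]
  if (anyNA(w)) stop("reference solution does not cover all reactions")
  r <- solve_qp_nearest(p$S, p$b, as.numeric(w), p$lb, p$ub)
  if (r$status != "optimal")
    return(new_flux_solution(setNames(rep(NA_real_, ncol(p$S)), colnames(p$S)),
                             "infeasible", model_modified$objective, "moma",
                             settings))
  v <- setNames(r$x, colnames(p$S))
  new_flux_solution(v, "optimal", model_modified$objective, "moma", settings,
                    moma_distance = sum((v - w)^2))
}

#' Reactions carrying flux in an optimal solution
#'
#' A reaction is active when its absolute flux exceeds the detection limit:
#' the objective reaction is compared against the objective tolerance, all
#' others against the (tighter) flux tolerance.
#'
#' @param solution An optimal `flux_solution`.
#' @param settings A [solver_settings()] object.
#' @return Character vector of active reaction ids.
#' @export
active_set <- function(solution, settings = solver_settings()) {
  if (solution$status != "optimal")
    stop("active_set() requires an optimal solution (status: ",
         solution$status, ")")
  tolv <- rep(settings$flux_zero_tolerance, length(solution$fluxes))
  tolv[names(solution$fluxes) == solution$objective_id] <-
    settings$objective_zero_tolerance
  names(solution$fluxes)[abs(solution$fluxes) > tolv]
}

close_exchanges <- function(model) {
  ex <- model$reactions$id[model$reactions$is_exchange]
  set_bounds(model, ex, 0, 0)
}

add_reaction <- function(model, id, stoich, lower = 0, upper = 1000,
                         is_exchange = FALSE) {
  model$reactions <- rbind(model$reactions,
    data.frame(id = id, name = id, lower_bound = lower, upper_bound = upper,
               subsystem = "", is_exchange = is_exchange,
               stringsAsFactors = FALSE))
  model$stoichiometry[[id]] <- stoich
  model$gpr[[id]] <- NULL
  model$gpr[id] <- list(NULL)
  model
}

#' Quality control: energy generation from nothing
#'
#' With every exchange reaction closed (and, as a second check, with only
#' the carbon and light inputs closed), maximises the flux through the ATP
#' maintenance reaction and through a temporary artificial reaction
#' `NADPH -> NADP + H+`. The model passes when each maximum is below the
#' objective detection limit or the problem is infeasible: neither ATP nor
#' reducing power can be generated without an external energy source.
#'
#' @param model A `metabolic_model` with an `atp_maintenance` role tag (and
#'   `nadph`/`nadp`/`h` metabolite role tags for the redox check).
#' @param settings A [solver_settings()] object.
#' @return A list with `pass`, per-check maxima, and for failing checks the
#'   reactions carrying flux in the offending solution.
#' @export
qc_energy_from_nothing <- function(model, settings = solver_settings()) {
  atpm <- role_rxns(model, "atp_maintenance")[1]
  tol <- settings$objective_zero_tolerance
  checks <- list()

  run_max <- function(mod, rxn) {
    mod$reactions$upper_bound[match(rxn, mod$reactions$id)] <- 1000
    p <- lp_parts(mod)
    obj <- as.numeric(colnames(p$S) == rxn)
    r <- solve_lp(p$S, p$b, obj, p$lb, p$ub, maximize = TRUE,
                  tol = settings$feasibility_tolerance)
    if (r$status != "optimal") return(list(max = 0, carriers = character(0)))
    carriers <- colnames(p$S)[abs(r$x) > settings$flux_zero_tolerance]
    list(max = r$objective, carriers = carriers)
  }

  closed <- close_exchanges(model)
  checks$atp_closed <- run_max(closed, atpm)

  dark <- model
  for (role in c("carbon_uptake", "photon_uptake")) {
    rr <- role_rxns(model, role, required = FALSE)
    if (length(rr)) dark <- set_bounds(dark, rr, 0, 0)
  }
  checks$atp_dark <- run_max(dark, atpm)

  mr <- model$met_roles
  if (!is.null(mr$nadph) && !is.null(mr$nadp)) {
    st <- setNames(c(-1, 1), c(mr$nadph, mr$nadp))
    if (!is.null(mr$h)) st <- c(st, setNames(1, mr$h))
    tmp <- add_reaction(closed, ".qc_nadph_drain", st, 0, 1000)
    checks$nadph_closed <- run_max(tmp, ".qc_nadph_drain")
  }

  maxima <- vapply(checks, `[[`, numeric(1), "max")
  fails <- names(checks)[maxima > tol]
  list(pass = length(fails) == 0L,
       maxima = maxima,
       failed_checks = fails,
       carriers = lapply(checks[fails], `[[`, "carriers"))
}

#' Quality control: metabolite leak test
#'
#' With all exchange reactions closed, checks that no metabolite can be net
#' produced: a temporary demand reaction is added for each metabolite and
#' its maximal flux must stay below the flux detection limit. A single
#' aggregate LP (maximising the sum of all bounded demands) certifies a
#' clean model in one solve; offenders, if any, are then isolated with
#' per-metabolite solves.
#'
#' @param model A `metabolic_model`.
#' @param settings A [solver_settings()] object.
#' @return A list with `pass` and a data.frame `leaky` naming metabolites
#'   that can be produced from nothing with their maximal production flux.
#' @export
qc_leak_test <- function(model, settings = solver_settings()) {
  closed <- close_exchanges(model)
  S <- stoich_matrix(closed)
  m <- nrow(S); n <- ncol(S)
  A <- cbind(S, -diag(m))
  lb <- c(closed$reactions$lower_bound, rep(0, m))
  ub <- c(closed$reactions$upper_bound, rep(1, m))
  r <- solve_lp(A, numeric(m), c(rep(0, n), rep(1, m)), lb, ub,
                maximize = TRUE, tol = settings$feasibility_tolerance)
  tol <- settings$flux_zero_tolerance
  clean <- data.frame(metabolite = character(0), max_production = numeric(0))
  # an infeasible closed model (e.g. a forced maintenance flux with no
  # energy source) can produce nothing at all
  if (r$status == "infeasible") return(list(pass = TRUE, leaky = clean))
  if (r$status == "optimal" && r$objective <= tol)
    return(list(pass = TRUE, leaky = clean))
  leaky <- clean
  suspects <- if (r$status == "optimal")
    rownames(S)[r$x[n + seq_len(m)] > tol] else rownames(S)
  for (met in suspects) {
    Ai <- cbind(S, -as.numeric(rownames(S) == met))
    ri <- solve_lp(Ai, numeric(m),
                   c(rep(0, n), 1), c(closed$reactions$lower_bound, 0),
                   c(closed$reactions$upper_bound, 1000),
                   maximize = TRUE, tol = settings$feasibility_tolerance)
    mx <- if (ri$status == "infeasible") 0
          else if (ri$status == "optimal") ri$objective else Inf
    if (mx > tol)
      leaky <- rbind(leaky, data.frame(metabolite = met, max_production = mx))
  }
  list(pass = nrow(leaky) == 0L, leaky = leaky)
}

#' Apply a bioenergetic scenario
#'
#' Two alternative wirings of the chloroplast-mitochondria energy balance:
#' `"no_redox_exchange"` closes the organelle redox shuttle reactions (role
#' `redox_shuttle`), forcing any extra ATP demand onto the cyclic
#' electron flow around photosystem I; `"psi_coupled"` opens the shuttle
#' and closes both the mitochondrial alternative oxidase (role `aox`, which
#' would otherwise short-circuit the electron transport chain) and the
#' cyclic flow itself (role `cyclic_psi`), so that photosystem I electron
#' transfer is coupled to mitochondrial ATP generation; `"control"`
#' restores the bounds saved when a scenario was first applied.
#'
#' @param model A `metabolic_model` with `redox_shuttle`, `aox` and
#'   `cyclic_psi` roles.
#' @param scenario One of `"control"`, `"no_redox_exchange"`, `"psi_coupled"`.
#' @return The modified model.
#' @export
bioenergetics_scenario <- function(model,
                                   scenario = c("control", "no_redox_exchange",
                                                "psi_coupled")) {
  scenario <- match.arg(scenario)
  shuttle <- role_rxns(model, "redox_shuttle")
  aox <- role_rxns(model, "aox")
  cyclic <- role_rxns(model, "cyclic_psi")
  touched <- Reduce(union, list(shuttle, aox, cyclic))
  if (is.null(model$scenario_saved_bounds)) {
    idx <- match(touched, model$reactions$id)
    model$scenario_saved_bounds <- data.frame(
      id = touched,
      lower_bound = model$reactions$lower_bound[idx],
      upper_bound = model$reactions$upper_bound[idx],
      stringsAsFactors = FALSE)
  }
  sv <- model$scenario_saved_bounds
  model <- set_bounds(model, sv$id, sv$lower_bound, sv$upper_bound)
  if (scenario == "no_redox_exchange") model <- set_bounds(model, shuttle, 0, 0)
  if (scenario == "psi_coupled")
    model <- set_bounds(model, union(aox, cyclic), 0, 0)
  model$scenario <- scenario
  model
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("flux solution (", x$method, "), status: ", x$status, "\n", sep = "")
  if (x$status == "optimal") {
    cat(sprintf("  growth: %.6g h^-1 (%.4g d^-1)\n",
                x$objective_value, x$growth_rate_per_day))
    if (!is.null(x$l1_norm))
      cat(sprintf("  Manhattan norm of fluxes: %.6g\n", x$l1_norm))
    if (!is.null(x$moma_distance))
      cat(sprintf("  MOMA distance to reference: %.6g\n", x$moma_distance))
    nact <- sum(abs(x$fluxes) > 1e-9)
    cat(sprintf("  %d of %d reactions carry flux\n", nact, length(x$fluxes)))
  }
  invisible(x)
}

#' @export
coef.flux_solution <- function(object, ...) object$fluxes

#' @export
summary.flux_solution <- function(object, ...) {
  act <- if (object$status == "optimal") sum(abs(object$fluxes) > 1e-9) else NA
  structure(list(status = object$status, method = object$method,
                 growth = object$objective_value,
                 growth_per_day = object$growth_rate_per_day,
                 n_reactions = length(object$fluxes), n_active = act,
                 l1_norm = object$l1_norm, moma_distance = object$moma_distance),
            class = "summary.flux_solution")
}

#' @export
print.summary.flux_solution <- function(x, ...) {
  cat("method:", x$method, " status:", x$status, "\n")
  if (x$status == "optimal") {
    cat(sprintf("growth %.6g h^-1 = %.4g d^-1; %d/%d reactions active\n",
                x$growth, x$growth_per_day, x$n_active, x$n_reactions))
  }
  invisible(x)
}
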