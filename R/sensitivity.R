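# Sensitivity of growth (and component production fluxes) to the 69
# composition parameters: local one-at-a-time scans, random and exhaustive
# multiplier combinations, and Morris elementary-effects screening.
#
# "Change by 40%" is implemented multiplicatively: the up-multiplier is
# 1 + factor and the down-multiplier its reciprocal 1/(1 + factor), so a
# growth rate proportional to a parameter responds with +40% / -29% to a
# 40% change of that parameter. The additive reading (down = 1 - factor)
# is available via `symmetric = TRUE`.

sa_multipliers <- function(factor, symmetric = FALSE) {
  c(up = 1 + factor, down = if (symmetric) 1 - factor else 1 / (1 + factor))
}

# growth (h^-1) and optional component production fluxes for a parameter set
sa_outputs <- function(model, params, settings, outputs = "growth") {
  mod <- update_model_params(model, params)
  if (identical(outputs, "growth")) {
    sol <- solve_fba(mod, settings)
    if (sol$status != "optimal") return(c(growth = NA_real_))
    return(c(growth = sol$objective_value))
  }
  sol <- solve_pfba(mod, settings)
  if (sol$status != "optimal")
    return(setNames(rep(NA_real_, length(outputs)), outputs))
  spec <- model$biomass_spec
  comp_flux <- sol$fluxes[spec$component_rxns]
  names(comp_flux) <- names(spec$component_rxns)
  bs <- if (spec$mode == "full") build_biomass(params, spec$monomer_masses) else NULL
  vals <- c(growth = sol$objective_value, comp_flux,
            storage = if (!is.null(bs))
              unname(bs$storage[["glucan"]] * comp_flux[["carbohydrate"]] +
                     bs$storage[["tag"]] * comp_flux[["lipid"]])
            else unname(0.3 * comp_flux[["carbohydrate"]] +
                        0.2 * comp_flux[["lipid"]]))
  vals[outputs]
}

#' Local one-at-a-time sensitivity analysis
#'
#' Perturbs each composition parameter independently by the up- and
#' down-multipliers, rebuilds the biomass and uptake constraints, re-solves,
#' and records the percent change of each output relative to nominal.
#' Perturbations yielding an infeasible model are recorded as -100% with a
#' flag.
#'
#' @param model A `metabolic_model` with a `biomass_spec`.
#' @param params Nominal [composition_params()].
#' @param factor Perturbation magnitude (default 0.4 = 40%).
#' @param outputs `"growth"` or a vector of outputs among `"growth"`, the
#'   six component production fluxes (`"protein"`, ..., `"pigment"`) and
#'   `"storage"`.
#' @param parameters Parameter names to scan; defaults to all 69.
#' @param symmetric Use `1 - factor` for the decrease instead of the
#'   reciprocal.
#' @param settings A [solver_settings()] object.
#' @return An object of class `local_sa`: data.frame with percent changes
#'   per parameter and direction.
#' @export
local_sa <- function(model, params, factor = 0.4, outputs = "growth",
                     parameters = names(params), symmetric = FALSE,
                     settings = solver_settings()) {
  mult <- sa_multipliers(factor, symmetric)
  nominal <- sa_outputs(model, params, settings, outputs)
  if (anyNA(nominal)) stop("nominal model is not solvable")
  rows <- lapply(parameters, function(pn) {
    one <- lapply(names(mult), function(dir) {
      p2 <- perturb_params(params, setNames(mult[[dir]], pn))
      out <- sa_outputs(model, p2, settings, outputs)
      infeasible <- anyNA(out)
      ch <- if (infeasible) setNames(rep(-100, length(nominal)), names(nominal))
            else 100 * (out - nominal) / nominal
      cbind(data.frame(parameter = pn, direction = dir,
                       multiplier = unname(mult[[dir]]),
                       infeasible = infeasible, stringsAsFactors = FALSE),
            as.data.frame(as.list(setNames(ch, paste0("change_", names(nominal))))))
    })
    do.call(rbind, one)
  })
  out <- do.call(rbind, rows)
  attr(out, "nominal") <- nominal
  attr(out, "factor") <- factor
  class(out) <- c("local_sa", class(out))
  out
}

#' @export
print.local_sa <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("local sensitivity analysis: %d parameters, factor %.0f%%\n",
              length(unique(df$parameter)), 100 * attr(x, "factor")))
  g <- df$change_growth
  top <- df[order(-abs(g)), ][1:min(5, nrow(df)), c("parameter", "direction",
                                                    "change_growth")]
  cat("  largest growth responses:\n")
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %-12s %-5s %+8.2f%%\n", top$parameter[i],
                top$direction[i], top$change_growth[i]))
  invisible(x)
}

#' Random-combination sensitivity analysis
#'
#' Draws `n` random parameter combinations, each parameter independently
#' taking the up- or the down-multiplier (or, with `uniform = TRUE`, a
#' uniform multiplier between the two), and records the growth change of
#' every draw. Reports the maximal relative increase and decrease.
#'
#' @inheritParams local_sa
#' @param n Number of random combinations.
#' @param seed Integer seed; results are reproducible bit-for-bit.
#' @param uniform Sample multipliers uniformly from the interval instead of
#'   the two-point set.
#' @return List with `max_increase_pct`, `max_decrease_pct` (both positive
#'   magnitudes) and the vector of growth changes (%).
#' @export
random_combo_sa <- function(model, params, n = 1000, factor = 0.4, seed = 1L,
                            uniform = FALSE, symmetric = FALSE,
                            settings = solver_settings()) {
  stopifnot(n >= 1)
  mult <- sa_multipliers(factor, symmetric)
  nominal <- sa_outputs(model, params, settings)[["growth"]]
  if (is.na(nominal)) stop("nominal model is not solvable")
  k <- length(params)
  changes <- with_seed(seed, {
    vapply(seq_len(n), function(i) {
      mm <- if (uniform) runif(k, min(mult), max(mult))
            else ifelse(runif(k) < 0.5, mult[["down"]], mult[["up"]])
      p2 <- perturb_params(params, setNames(mm, names(params)))
      g <- sa_outputs(model, p2, settings)[["growth"]]
      if (is.na(g)) -100 else 100 * (g - nominal) / nominal
    }, numeric(1))
  })
  list(max_increase_pct = max(c(changes, 0)),
       max_decrease_pct = -min(c(changes, 0)),
       changes = changes, n = n, seed = seed)
}

#' Exhaustive-combination sensitivity analysis
#'
#' Evaluates growth for every up/down multiplier combination of a parameter
#' subset (2^k solves) and reports the extrema of the growth change.
#'
#' @inheritParams local_sa
#' @param subset Parameter names (at most 12).
#' @return List with `max_increase_pct`, `max_decrease_pct` and the per-
#'   combination changes.
#' @export
exhaustive_combo_sa <- function(model, params, subset, factor = 0.4,
                                symmetric = FALSE,
                                settings = solver_settings()) {
  k <- length(subset)
  if (k > 12) stop("subset too large: ", k, " parameters (max 12)")
  unk <- setdiff(subset, names(params))
  if (length(unk)) stop("unknown parameters: ", paste(unk, collapse = ", "))
  mult <- sa_multipliers(factor, symmetric)
  nominal <- sa_outputs(model, params, settings)[["growth"]]
  if (is.na(nominal)) stop("nominal model is not solvable")
  if (k == 0)
    return(list(max_increase_pct = 0, max_decrease_pct = 0, changes = 0))
  grid <- as.matrix(expand.grid(rep(list(c(mult[["down"]], mult[["up"]])), k)))
  changes <- apply(grid, 1, function(mm) {
    p2 <- perturb_params(params, setNames(mm, subset))
    g <- sa_outputs(model, p2, settings)[["growth"]]
    if (is.na(g)) -100 else 100 * (g - nominal) / nominal
  })
  list(max_increase_pct = max(c(changes, 0)),
       max_decrease_pct = -min(c(changes, 0)),
       changes = changes)
}

#' Morris elementary-effects screening (generic core)
#'
#' Trajectory (one-at-a-time) design on the unit hypercube with `p` levels
#' and step `delta = p / (2 (p - 1))`, latin-hypercube-sampled starting
#' points, and `r` trajectories of `k + 1` evaluations each. The elementary
#' effect of parameter i along a trajectory is the scaled finite difference
#' `(f(x + delta e_i) - f(x)) / (+-delta)`.
#'
#' @param f Function taking a numeric vector in `[0, 1]^k`, returning a
#'   scalar.
#' @param k Number of parameters.
#' @param r Number of trajectories (>= 2).
#' @param levels Number of grid levels `p` (even).
#' @param seed Integer seed.
#' @param names Optional parameter names.
#' @return An object of class `morris_result`: per-parameter mean EE, mean
#'   |EE|, and SD of the EEs, plus sampling metadata.
#' @export
morris_screen <- function(f, k, r = 10, levels = 4, seed = 1L, names = NULL) {
  stopifnot(r >= 2, levels %% 2 == 0, levels >= 2)
  p <- levels
  delta <- p / (2 * (p - 1))
  starts_grid <- (seq_len(p / 2) - 1) / (p - 1)   # levels with room for +delta
  ee <- matrix(NA_real_, r, k)
  n_eval <- 0L
  with_seed(seed, {
    lh <- lhs::randomLHS(r, k)
    for (t in seq_len(r)) {
      x <- starts_grid[pmin(length(starts_grid),
                            1L + floor(lh[t, ] * length(starts_grid)))]
      fx <- f(x); n_eval <- n_eval + 1L
      for (i in sample(k)) {
        step <- if (x[i] + delta <= 1 + 1e-12) delta else -delta
        x2 <- x; x2[i] <- x[i] + step
        fx2 <- f(x2); n_eval <- n_eval + 1L
        ee[t, i] <- (fx2 - fx) / step
        x <- x2; fx <- fx2
      }
    }
  })
  res <- data.frame(parameter = if (is.null(names)) paste0("x", seq_len(k))
                                else names,
                    mean_ee = colMeans(ee),
                    mean_abs_ee = colMeans(abs(ee)),
                    sd_ee = apply(ee, 2, sd),
                    stringsAsFactors = FALSE)
  structure(list(indices = res, ee = ee, r = r, levels = levels,
                 delta = delta, seed = seed, n_evaluations = n_eval),
            class = "morris_result")
}

#' Morris screening of growth over the composition parameters
#'
#' Maps the unit cube onto per-parameter multiplier ranges
#' `[1/(1 + factor), 1 + factor]` (the same range the local analysis
#' spans), evaluates growth by FBA at each design point, and computes
#' elementary effects on the unit-scaled cube so that indices are
#' comparable across parameters with different units. Infeasible points are
#' assigned growth 0 and flagged.
#'
#' @inheritParams local_sa
#' @param r Number of trajectories; when `NULL`, chosen as
#'   `floor(budget / (k + 1))`.
#' @param levels Number of grid levels (even).
#' @param seed Integer seed.
#' @param budget Total model-evaluation budget used when `r` is `NULL`.
#' @return A `morris_result`; growth is in h^-1, effects in growth units
#'   per unit cube coordinate.
#' @export
morris_sa <- function(model, params, r = NULL, levels = 4, factor = 0.4,
                      seed = 1L, budget = 6500,
                      settings = solver_settings()) {
  k <- length(params)
  if (is.null(r)) r <- max(2L, floor(budget / (k + 1)))
  lo <- 1 / (1 + factor); hi <- 1 + factor
  n_infeasible <- 0L
  f <- function(x) {
    mm <- lo + x * (hi - lo)
    p2 <- perturb_params(params, setNames(mm, names(params)))
    g <- sa_outputs(model, p2, settings)[["growth"]]
    if (is.na(g)) { n_infeasible <<- n_infeasible + 1L; return(0) }
    g
  }
  out <- morris_screen(f, k, r = r, levels = levels, seed = seed,
                       names = names(params))
  out$factor <- factor
  out$n_infeasible <- n_infeasible
  out
}

#' @export
print.morris_result <- function(x, ...) {
  cat(sprintf("Morris screening: %d trajectories, %d levels, delta %.3f, %d evaluations\n",
              x$r, x$levels, x$delta, x$n_evaluations))
  top <- x$indices[order(-abs(x$indices$mean_ee)), ][1:min(5, nrow(x$indices)), ]
  cat("  most influential parameters (by |mean EE|):\n")
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %-12s mean EE %+.3e  SD EE %.3e\n", top$parameter[i],
                top$mean_ee[i], top$sd_ee[i]))
  invisible(x)
}

#' @export
plot.morris_result <- function(x, ...) {
  graphics::plot(x$indices$mean_ee, x$indices$sd_ee,
                 xlab = "mean of elementary effects",
                 ylab = "SD of elementary effects",
                 main = "Morris screening", ...)
  graphics::text(x$indices$mean_ee, x$indices$sd_ee,
                 labels = seq_len(nrow(x$indices)), pos = 3, cex = 0.6)
  invisible(x)
}
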