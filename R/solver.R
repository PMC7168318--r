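#' Solver settings for flux computations
#'
#' Numerical tolerances used throughout the package. The flux detection
#' limits mirror common practice in constraint-based modelling: a looser
#' limit for the objective (growth) flux and a tighter one for all other
#' reactions, below which a flux is treated as zero.
#'
#' @param objective_zero_tolerance Detection limit for the objective
#'   (biomass) flux, in h^-1. Default `1e-6`.
#' @param flux_zero_tolerance Detection limit for all other fluxes, in
#'   mmol gDW^-1 h^-1. Default `1e-9`.
#' @param feasibility_tolerance Tolerance used by the LP/QP solvers when
#'   checking constraint satisfaction. Default `1e-9`.
#' @return An object of class `solver_settings`.
#' @export
#' @examples
#' solver_settings()
solver_settings <- function(objective_zero_tolerance = 1e-6,
                            flux_zero_tolerance = 1e-9,
                            feasibility_tolerance = 1e-9) {
  stopifnot(objective_zero_tolerance > 0, flux_zero_tolerance > 0,
            feasibility_tolerance > 0)
  structure(list(objective_zero_tolerance = objective_zero_tolerance,
                 flux_zero_tolerance = flux_zero_tolerance,
                 feasibility_tolerance = feasibility_tolerance),
            class = "solver_settings")
}

#' @export
print.solver_settings <- function(x, ...) {
  cat("solver settings:\n")
  cat("  objective flux detection limit:", x$objective_zero_tolerance, "\n")
  cat("  flux detection limit:          ", x$flux_zero_tolerance, "\n")
  cat("  feasibility tolerance:         ", x$feasibility_tolerance, "\n")
  invisible(x)
}

# Dense LP:  optimise c'x  s.t.  A x = b,  lb <= x <= ub.
# Returns list(status = "optimal"|"infeasible"|"unbounded"|"failed",
#              x, objective).
solve_lp <- function(A, b, obj, lb, ub, maximize = FALSE, tol = 1e-9) {
  stopifnot(is.matrix(A), length(b) == nrow(A), length(obj) == ncol(A),
            length(lb) == ncol(A), length(ub) == ncol(A))
  lb2 <- ifelse(is.finite(lb), lb, -1e30)
  ub2 <- ifelse(is.finite(ub), ub, 1e30)
  r <- .simplex_core(A, as.numeric(b), as.numeric(obj), lb2, ub2,
                     maximize = maximize, tol = tol)
  status <- switch(as.character(r$status),
                   "0" = "optimal", "1" = "infeasible", "2" = "unbounded",
                   "failed")
  if (status == "optimal") {
    resid <- max(abs(A %*% r$x - b))
    if (resid > 1e-6) status <- "failed"
  }
  list(status = status,
       x = if (status == "optimal") as.numeric(r$x) else NULL,
       objective = if (status == "optimal") r$objective else NA_real_)
}

# Equality-constrained bound QP:  min ||x - w||^2  s.t.  A x = b, lb <= x <= ub.
# Fixed variables (lb == ub) are eliminated; linearly dependent rows of A are
# dropped by rank-revealing QR so quadprog sees an independent equality set.
solve_qp_nearest <- function(A, b, w, lb, ub) {
  n <- ncol(A)
  free <- (ub - lb) > 1e-12
  x <- numeric(n)
  x[!free] <- lb[!free]
  bb <- as.numeric(b - A[, !free, drop = FALSE] %*% x[!free])
  Af <- A[, free, drop = FALSE]
  nf <- sum(free)
  if (nf == 0L) {
    feas <- max(abs(bb)) <= 1e-6
    return(list(status = if (feas) "optimal" else "infeasible", x = x))
  }
  qrA <- qr(t(Af))
  keep <- qrA$pivot[seq_len(qrA$rank)]
  # rows dropped as dependent must still be consistent with the kept ones
  if (qrA$rank < nrow(Af)) {
    sol <- qr.coef(qr(t(Af[keep, , drop = FALSE])), t(Af[-keep, , drop = FALSE]))
    sol[is.na(sol)] <- 0
    if (max(abs(crossprod(sol, bb[keep]) - bb[-keep])) > 1e-6)
      return(list(status = "infeasible", x = NULL))
  }
  Aeq <- Af[keep, , drop = FALSE]
  beq <- bb[keep]
  ineqA <- NULL; ineqb <- NULL
  fin_lb <- is.finite(lb[free]); fin_ub <- is.finite(ub[free])
  if (any(fin_lb)) {
    ineqA <- rbind(ineqA, diag(nf)[fin_lb, , drop = FALSE])
    ineqb <- c(ineqb, lb[free][fin_lb])
  }
  if (any(fin_ub)) {
    ineqA <- rbind(ineqA, -diag(nf)[fin_ub, , drop = FALSE])
    ineqb <- c(ineqb, -ub[free][fin_ub])
  }
  Amat <- t(rbind(Aeq, ineqA))
  bvec <- c(beq, ineqb)
  fit <- tryCatch(
    quadprog::solve.QP(Dmat = diag(nf), dvec = w[free], Amat = Amat,
                       bvec = bvec, meq = nrow(Aeq)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    if (grepl("inconsistent|no solution", conditionMessage(fit)))
      return(list(status = "infeasible", x = NULL))
    return(list(status = "failed", x = NULL))
  }
  x[free] <- fit$solution
  list(status = "optimal", x = x)
}
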