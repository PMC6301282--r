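# Linear-programming core: plain FBA, flux variability analysis, and the
# geometric-FBA centring algorithm that picks a unique representative point
# of the optimal-flux polytope.

#' Solve a bounded linear program
#'
#' Thin interface over the package's built-in dense two-phase simplex:
#' optimise `obj' x` subject to `A x = b` and `lb <= x <= ub`. Any LP engine
#' honouring this contract could be substituted.
#'
#' @param obj objective coefficients.
#' @param A equality-constraint matrix.
#' @param b right-hand side.
#' @param lb,ub variable bounds (finite values recommended; the flux-bound
#'   sentinel is ±1000).
#' @param maximize maximise (default) or minimise.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"maxit"`),
#'   `x` and `objective`.
#' @export
solve_lp <- function(obj, A, b, lb, ub, maximize = TRUE) {
  res <- .simplex_lp(as.matrix(A), as.numeric(b), as.numeric(obj),
                     as.numeric(lb), as.numeric(ub), isTRUE(maximize))
  status <- c("optimal", "infeasible", "maxit", "unbounded")[res$status + 1]
  list(status = status, x = res$x, objective = res$objective)
}

lp_data <- function(model) {
  list(S = stoichiometric_matrix(model, sparse = FALSE),
       lb = model$reactions$lower_bound,
       ub = model$reactions$upper_bound,
       c = objective_vector(model),
       rids = model$reactions$id)
}

objective_vector <- function(model) {
  cvec <- numeric(n_reactions(model))
  names(cvec) <- model$reactions$id
  cvec[names(model$objective)] <- model$objective
  unname(cvec)
}

flux_solution <- function(fluxes, objective_value, status,
                          method = "fba", converged = TRUE) {
  structure(list(fluxes = fluxes, objective_value = objective_value,
                 status = status, method = method, converged = converged),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("flux_solution (", x$method, "): status ", x$status, sep = "")
  if (x$status == "optimal")
    cat(", objective ", format(x$objective_value), sep = "")
  if (!isTRUE(x$converged)) cat(" [not converged]")
  cat("\n")
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximises the model objective `c'v` over the steady-state flux cone
#' `S v = 0`, `V_min <= v <= V_max`.
#'
#' @param model a `metabolic_model` with a non-zero objective.
#' @return a `flux_solution`.
#' @export
fba <- function(model) {
  if (!length(model$objective) || all(model$objective == 0))
    stop("model has no objective; call set_objective() first", call. = FALSE)
  d <- lp_data(model)
  res <- solve_lp(d$c, d$S, rep(0, nrow(d$S)), d$lb, d$ub, maximize = TRUE)
  if (res$status != "optimal")
    return(flux_solution(NULL, NA_real_, res$status))
  flux_solution(setNames(res$x, d$rids), res$objective, "optimal")
}

# Shared scaffolding for FVA-type problems: S with an extra row fixing the
# objective at (fraction x optimum), solved per reaction for min and max.
fva_core <- function(S, cvec, lb, ub, target, idx) {
  Sfix <- rbind(S, cvec)
  b <- c(rep(0, nrow(S)), target)
  n <- ncol(S)
  out <- matrix(NA_real_, length(idx), 2)
  for (k in seq_along(idx)) {
    e <- numeric(n); e[idx[k]] <- 1
    lo <- solve_lp(e, Sfix, b, lb, ub, maximize = FALSE)
    hi <- solve_lp(e, Sfix, b, lb, ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem infeasible for reaction index ", idx[k],
           call. = FALSE)
    out[k, ] <- c(lo$objective, hi$objective)
  }
  out
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to the objective being at
#' least `fraction_of_optimum` times the FBA optimum.
#'
#' @param model a `metabolic_model` with an objective.
#' @param fraction_of_optimum fraction in `[0, 1]` (default 1).
#' @param reactions optional character vector restricting the analysis.
#' @return data.frame with columns `reaction`, `min`, `max`.
#' @export
fva <- function(model, fraction_of_optimum = 1, reactions = NULL) {
  base <- fba(model)
  if (base$status != "optimal")
    stop("FVA requires a solvable model (status: ", base$status, ")",
         call. = FALSE)
  d <- lp_data(model)
  idx <- if (is.null(reactions)) seq_along(d$rids)
         else match(reactions, d$rids)
  if (anyNA(idx)) stop("unknown reaction in FVA subset", call. = FALSE)
  # keep c'v >= fraction * opt via an explicit surplus variable
  n <- length(d$rids)
  target <- fraction_of_optimum * base$objective_value
  Saug <- cbind(rbind(d$S, d$c), c(rep(0, nrow(d$S)), -1))
  lb <- c(d$lb, 0); ub <- c(d$ub, 1e9)
  rng <- matrix(NA_real_, length(idx), 2)
  b <- c(rep(0, nrow(d$S)), target)
  for (k in seq_along(idx)) {
    e <- numeric(n + 1); e[idx[k]] <- 1
    lo <- solve_lp(e, Saug, b, lb, ub, maximize = FALSE)
    hi <- solve_lp(e, Saug, b, lb, ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem not optimal for reaction '", d$rids[idx[k]], "'",
           call. = FALSE)
    rng[k, ] <- c(lo$objective, hi$objective)
  }
  data.frame(reaction = d$rids[idx], min = rng[, 1], max = rng[, 2],
             stringsAsFactors = FALSE)
}

#' Geometric flux balance analysis
#'
#' Selects a unique, representative flux distribution from the optimal-flux
#' polytope by iterated centring: fix the objective at its FBA optimum,
#' compute FVA ranges, take per-reaction midpoints, find the feasible flux
#' vector minimising the L1 distance to the midpoint vector, then shrink
#' each range to the interval between that vector and the midpoint and
#' repeat until the widest range falls below `tolerance`. The limit point is
#' independent of simplex vertex choice, and fluxes around internal
#' reversible cycles - free to take any value at the optimum - are driven to
#' the centre of their (symmetric) range, i.e. zero.
#'
#' @param model a `metabolic_model` with an objective.
#' @param tolerance convergence threshold on range width (flux units),
#'   default 1e-6.
#' @param max_iterations iteration cap; range widths at least halve per
#'   iteration, so the default 200 is generous.
#' @return a `flux_solution` with `method = "geometric"`; `converged` is
#'   `FALSE` (with a warning) if the cap was hit.
#' @export
geometric_fba <- function(model, tolerance = 1e-6, max_iterations = 200) {
  base <- fba(model)
  if (base$status != "optimal")
    stop("geometric FBA requires an optimal base problem (status: ",
         base$status, ")", call. = FALSE)
  d <- lp_data(model)
  n <- length(d$rids)
  m <- nrow(d$S)
  Sfix <- rbind(d$S, d$c)           # objective fixed by an equality row
  bfix <- c(rep(0, m), base$objective_value)
  lbw <- d$lb; ubw <- d$ub
  v <- base$fluxes
  converged <- FALSE
  for (it in seq_len(max_iterations)) {
    active <- which(ubw - lbw > tolerance)
    if (length(active)) {
      rng <- fva_core(d$S, d$c, lbw, ubw, base$objective_value, active)
      lbw[active] <- rng[, 1]
      ubw[active] <- rng[, 2]
      active <- which(ubw - lbw > tolerance)
    }
    mid <- (lbw + ubw) / 2
    # L1 projection onto the midpoints of the still-degenerate directions
    k <- length(active)
    if (k == 0) {
      sol <- solve_lp(numeric(n), Sfix, bfix, lbw, ubw, maximize = FALSE)
      if (sol$status != "optimal")
        stop("geometric FBA: final feasibility problem not optimal",
             call. = FALSE)
      v <- setNames(sol$x, d$rids)
      converged <- TRUE
      break
    }
    Al1 <- cbind(Sfix, matrix(0, m + 1, 2 * k))
    rows <- matrix(0, k, n + 2 * k)
    for (j in seq_len(k)) {
      rows[j, active[j]] <- 1
      rows[j, n + j] <- -1         # t+
      rows[j, n + k + j] <- 1      # t-
    }
    Al1 <- rbind(Al1, rows)
    bl1 <- c(bfix, mid[active])
    obj <- c(numeric(n), rep(1, 2 * k))
    lo <- c(lbw, rep(0, 2 * k))
    hi <- c(ubw, rep(1e7, 2 * k))
    sol <- solve_lp(obj, Al1, bl1, lo, hi, maximize = FALSE)
    if (sol$status != "optimal")
      stop("geometric FBA: centring LP not optimal (", sol$status, ")",
           call. = FALSE)
    v <- setNames(sol$x[seq_len(n)], d$rids)
    # shrink to the hull between projection and midpoint (width halves)
    lbw[active] <- pmin(v[active], mid[active])
    ubw[active] <- pmax(v[active], mid[active])
    if (max(ubw - lbw) <= tolerance) { converged <- TRUE; break }
  }
  if (!converged)
    warning("geometric FBA did not converge in ", max_iterations,
            " iterations (max range width ",
            format(max(ubw - lbw)), ")")
  flux_solution(v, base$objective_value, "optimal", method = "geometric",
                converged = converged)
}
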