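# Simulation experiments over growth media: single-carbon-source scans,
# uptake-rate sweeps with a linearity diagnostic, mixed substrates, flux
# attribution between precursor pathways, and two-model comparison.

solve_by_method <- function(model, method = c("geometric", "fba"),
                            tolerance = 1e-6) {
  method <- match.arg(method)
  if (method == "geometric") geometric_fba(model, tolerance = tolerance)
  else fba(model)
}

#' Single-carbon-source scan
#'
#' For each source, builds a single-source medium (the source at `rate`,
#' every other listed source closed; all toy carbon exchanges are closed by
#' default anyway) and records the production flux of the objective under
#' geometric FBA.
#'
#' @param model a `metabolic_model`.
#' @param sources character vector of carbon-source names (resolved to
#'   exchange reactions).
#' @param rate uptake rate in mmol/gDW/h (default 10).
#' @param objective optional objective reaction id to set first.
#' @param method `"geometric"` (default) or `"fba"`.
#' @return a `scan_result` data.frame (`source`, `rate`, `objective`,
#'   `flux`); the full flux solutions are in the `"solutions"` attribute.
#' @export
carbon_source_scan <- function(model, sources, rate = 10, objective = NULL,
                               method = "geometric") {
  if (!is.null(objective)) model <- set_objective(model, objective)
  objname <- names(model$objective)[1]
  rows <- list(); sols <- list()
  for (src in sources) {
    m <- set_medium(model, medium_spec(setNames(rate, src),
                                       closed_sources = setdiff(sources, src)))
    sol <- solve_by_method(m, method)
    rows[[src]] <- data.frame(source = src, rate = rate,
                              objective = objname,
                              flux = sol$objective_value,
                              stringsAsFactors = FALSE)
    sols[[src]] <- sol
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(source = character(), rate = numeric(),
                         objective = character(), flux = numeric(),
                         stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "solutions") <- sols
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Uptake-rate sweep with linearity diagnostic
#'
#' One geometric FBA per uptake rate of a single source, plus a check of
#' the proportionality `production = slope x rate` expected from LP
#' homogeneity.
#'
#' @param model a `metabolic_model`.
#' @param source carbon-source name.
#' @param rates non-negative uptake rates.
#' @param objective optional objective reaction id.
#' @param method `"geometric"` or `"fba"`.
#' @return list with `scan` (a `scan_result`), `slope` (production per
#'   unit uptake) and `max_rel_deviation` from proportionality.
#' @export
uptake_sweep <- function(model, source, rates, objective = NULL,
                         method = "geometric") {
  if (any(rates < 0)) stop("rates must be >= 0", call. = FALSE)
  if (!is.null(objective)) model <- set_objective(model, objective)
  objname <- names(model$objective)[1]
  rows <- lapply(rates, function(r) {
    m <- set_medium(model, medium_spec(setNames(r, source)))
    sol <- solve_by_method(m, method)
    data.frame(source = source, rate = r, objective = objname,
               flux = sol$objective_value, stringsAsFactors = FALSE)
  })
  scan <- do.call(rbind, rows)
  class(scan) <- c("scan_result", "data.frame")
  pos <- scan$rate > 0
  if (any(pos)) {
    imax <- which.max(scan$rate)
    slope <- scan$flux[imax] / scan$rate[imax]
    pred <- slope * scan$rate[pos]
    denom <- pmax(abs(pred), .Machine$double.eps)
    dev <- max(abs(scan$flux[pos] - pred) / denom)
  } else {
    slope <- NA_real_; dev <- NA_real_
  }
  list(scan = scan, slope = slope, max_rel_deviation = dev)
}

#' Production under a mixed-substrate medium
#'
#' @param model a `metabolic_model`.
#' @param uptakes a [medium_spec()] or named numeric vector of simultaneous
#'   uptake rates (default convention: the control rate for every source).
#' @param objective optional objective reaction id.
#' @return the production flux (objective value); the full solution is the
#'   `"solution"` attribute.
#' @export
mixed_substrate <- function(model, uptakes, objective = NULL) {
  if (!is.null(objective)) model <- set_objective(model, objective)
  m <- set_medium(model, uptakes)
  sol <- geometric_fba(m)
  structure(sol$objective_value, solution = sol)
}

#' Attribute a reporter's precursor supply to pathway sets
#'
#' The reporter's direct substrates (ignoring ubiquitous protons/water)
#' define the precursor pools. Each named set of reactions is credited with
#' the flux it delivers into the pools it feeds, normalised by the total
#' production into those same pools, giving a share in `[0, 1]`. Sets
#' feeding the same pool therefore sum to at most 1 (residual =
#' unattributed routes); sets feeding different pools are each normalised
#' within their own pool.
#'
#' @param model the `metabolic_model` the solution came from.
#' @param solution a `flux_solution` with positive reporter flux.
#' @param sets named list of reaction-id vectors (e.g.
#'   [toy_pathway_sets()]).
#' @param reporter reaction id whose precursor supply is attributed
#'   (typically the rhamnolipid synthase).
#' @param tol flux tolerance.
#' @return named numeric vector of shares.
#' @export
pathway_attribution <- function(model, solution, sets, reporter,
                                tol = 1e-9) {
  if (!length(sets)) return(setNames(numeric(), character()))
  v <- solution$fluxes
  if (is.null(v) || !reporter %in% names(v))
    stop("solution carries no flux for reporter '", reporter, "'",
         call. = FALSE)
  if (abs(v[[reporter]]) <= tol)
    stop("reporter '", reporter,
         "' carries no flux; attribution undefined", call. = FALSE)
  sto_rep <- model$stoichiometry[[reporter]]
  pools <- setdiff(names(sto_rep)[sto_rep < 0], UBIQUITOUS_METS)
  production <- function(rids, met) {
    tot <- 0
    for (rid in rids) {
      sto <- model$stoichiometry[[rid]]
      if (met %in% names(sto)) tot <- tot + max(0, sto[[met]] * v[[rid]])
    }
    tot
  }
  all_ids <- setdiff(model$reactions$id, reporter)
  shares <- vapply(sets, function(ids) {
    ids <- setdiff(ids, reporter)
    feeds <- Filter(function(m)
      any(vapply(ids, function(rid)
        m %in% names(model$stoichiometry[[rid]]) &&
          model$stoichiometry[[rid]][[m]] > 0, TRUE)), pools)
    if (!length(feeds)) return(0)
    num <- sum(vapply(feeds, function(m) production(ids, m), 0))
    den <- sum(vapply(feeds, function(m) production(all_ids, m), 0))
    if (den <= tol) 0 else num / den
  }, 0)
  shares
}

#' Compare rhamnolipid production of two models across carbon sources
#'
#' Runs [carbon_source_scan()] on each model and aligns the results by
#' source. Per-model scan failures are recorded in status columns rather
#' than aborting the whole table.
#'
#' @param modelA,modelB engineered `metabolic_model`s with a production
#'   objective (or pass `objective`).
#' @param sources carbon sources to scan.
#' @param rate uptake rate (default 10).
#' @param objective optional objective reaction id applied to both models.
#' @return data.frame `source`, `flux_A`, `flux_B`, `status_A`, `status_B`.
#' @export
compare_models <- function(modelA, modelB, sources, rate = 10,
                           objective = NULL) {
  one <- function(model, src) {
    tryCatch({
      s <- carbon_source_scan(model, src, rate = rate,
                              objective = objective)
      list(flux = s$flux[1], status = "ok")
    }, error = function(e) list(flux = NA_real_,
                                status = conditionMessage(e)))
  }
  rows <- lapply(sources, function(src) {
    a <- one(modelA, src); b <- one(modelB, src)
    data.frame(source = src, flux_A = a$flux, flux_B = b$flux,
               status_A = a$status, status_B = b$status,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(source = character(), flux_A = numeric(),
                         flux_B = numeric(), status_A = character(),
                         status_B = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
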