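# Grafting the rhamnolipid biosynthesis machinery (rhamnosyltransferases
# RhlA/RhlB/RhlC plus the PHA-synthase-associated steps) onto a host model,
# and the curation checks run afterwards: elemental/charge balance and
# flux-carrying capability of the added reactions.

UBIQUITOUS_METS <- c("h_c", "h_e", "h2o_c", "h2o_e")

#' Load reaction specifications from a TSV
#'
#' Columns: `code`, `formula` (equation over metabolite ids), `reversibility`
#' (`reversible`/`irreversible`), `role`, optional `gpr`.
#'
#' @param path TSV file.
#' @return a `reaction_spec` data.frame.
#' @export
load_reaction_specs <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("code", "formula", "reversibility", "role")
  if (!all(need %in% names(tab)))
    stop("reaction spec TSV must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (is.null(tab$gpr)) tab$gpr <- NA_character_
  bad <- !tab$reversibility %in% c("reversible", "irreversible")
  if (any(bad))
    stop("bad reversibility for spec '", tab$code[bad][1], "'", call. = FALSE)
  class(tab) <- c("reaction_spec", "data.frame")
  tab
}

#' The rhamnolipid biosynthesis reaction set
#'
#' Returns the five core biosynthetic steps (RHLA, RHLB, RHLC, 3H3H, PHAC,
#' all irreversible, stoichiometry exactly as printed in the source reaction
#' table) plus a mono-rhamnolipid transport (cytosol to extracellular) and
#' exchange reaction. The di-rhamnolipid product of RHLC gets its own
#' transport/exchange only when `include_di = TRUE`; by default it is a dead
#' end, reflecting a mono-rhamnolipid-centred objective.
#'
#' Note that PHAC (1 hydroxyacyl-CoA to 2 dimer-CoA units) is
#' carbon-imbalanced as printed; [check_mass_balance()] reports this when
#' the participating metabolites carry formulas.
#'
#' @param include_di also return the di-rhamnolipid transport/exchange pair.
#' @return a `reaction_spec` data.frame (7 rows, or 9 with `include_di`).
#' @export
rhamnolipid_reaction_set <- function(include_di = FALSE) {
  path <- system.file("extdata", "rhamnolipid_reactions.tsv",
                      package = "rlflux", mustWork = TRUE)
  specs <- load_reaction_specs(path)
  if (!include_di)
    specs <- specs[!specs$role %in% c("transport_di", "exchange_di"), ]
  rownames(specs) <- NULL
  specs
}

rhamnolipid_metabolite_table <- function() {
  read.delim(system.file("extdata", "rhamnolipid_metabolites.tsv",
                         package = "rlflux", mustWork = TRUE),
             stringsAsFactors = FALSE)
}

#' Graft a reaction set onto a host model
#'
#' Adds one reaction per spec; metabolites absent from the host are created
#' (names taken from the package's rhamnolipid metabolite table when known,
#' compartment from the `_c`/`_e` id suffix, no formula). The objective is
#' untouched. All-or-nothing: a duplicate reaction id aborts before any
#' change is applied.
#'
#' @param model host `metabolic_model`.
#' @param specs a `reaction_spec` data.frame, e.g.
#'   [rhamnolipid_reaction_set()].
#' @return the engineered model, with the added reaction ids recorded in
#'   `model$engineered`.
#' @export
engineer_model <- function(model, specs) {
  if (!nrow(specs)) return(model)
  clash <- intersect(specs$code, model$reactions$id)
  if (length(clash))
    stop("reaction id '", clash[1], "' already present in model '",
         model$id, "'; model unchanged", call. = FALSE)
  if (anyDuplicated(specs$code))
    stop("duplicate spec code '", specs$code[duplicated(specs$code)][1], "'",
         call. = FALSE)
  known <- rhamnolipid_metabolite_table()
  mets <- model$metabolites
  rxns <- model$reactions
  sto <- model$stoichiometry
  for (i in seq_len(nrow(specs))) {
    parsed <- parse_equation(specs$formula[i])
    rev <- specs$reversibility[i] == "reversible"
    for (mid in names(parsed$stoichiometry)) {
      if (!mid %in% mets$id) {
        k <- match(mid, known$id)
        mets <- rbind(mets, data.frame(
          id = mid,
          name = if (!is.na(k)) known$name[k] else mid,
          compartment = if (!is.na(k)) known$compartment[k]
                        else if (grepl("_e$", mid)) "e" else "c",
          formula = NA_character_, charge = NA_real_,
          stringsAsFactors = FALSE))
      }
    }
    rxns <- rbind(rxns, data.frame(
      id = specs$code[i], name = specs$code[i],
      lower_bound = if (rev) DEFAULT_LB else 0,
      upper_bound = DEFAULT_UB,
      gpr = specs$gpr[i],
      subsystem = "rhamnolipid biosynthesis",
      is_exchange = NA,
      stringsAsFactors = FALSE))
    sto[[specs$code[i]]] <- parsed$stoichiometry
  }
  out <- metabolic_model(model$id, mets,
                         rxns[setdiff(names(rxns), "is_exchange")],
                         sto, model$objective)
  out$engineered <- union(model$engineered, specs$code)
  out
}

#' Elemental and charge balance report
#'
#' Checks every non-boundary reaction whose metabolites all carry elemental
#' formulas; element or charge imbalances are reported per reaction.
#' Reactions touching a metabolite without a formula are reported as
#' `"unchecked"`. Boundary (exchange/sink) reactions are exempt by
#' definition. A fully balanced model yields a zero-row report.
#'
#' @param model a `metabolic_model`.
#' @param tol numeric tolerance on element/charge sums.
#' @return data.frame with columns `reaction`, `status`
#'   (`imbalanced`/`unchecked`) and `detail`.
#' @export
check_mass_balance <- function(model, tol = 1e-6) {
  mets <- model$metabolites
  out <- list()
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    if (r$is_exchange) next
    sto <- model$stoichiometry[[i]]
    rows <- mets[match(names(sto), mets$id), ]
    if (anyNA(rows$formula)) {
      out[[r$id]] <- data.frame(reaction = r$id, status = "unchecked",
                                detail = "missing formula",
                                stringsAsFactors = FALSE)
      next
    }
    bal <- numeric(0)
    for (k in seq_along(sto)) {
      f <- parse_formula(rows$formula[k])
      for (el in names(f)) {
        prev <- if (el %in% names(bal)) bal[[el]] else 0
        bal[el] <- prev + sto[[k]] * f[[el]]
      }
    }
    if (!anyNA(rows$charge))
      bal["charge"] <- sum(sto * rows$charge)
    bad <- bal[abs(bal) > tol]
    if (length(bad))
      out[[r$id]] <- data.frame(
        reaction = r$id, status = "imbalanced",
        detail = paste(names(bad), format(unname(bad), trim = TRUE),
                       sep = ":", collapse = ", "),
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(reaction = character(), status = character(),
                      detail = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Blocked reactions among an engineered set
#'
#' Runs flux variability analysis over the added reactions under the model's
#' current medium and reports those unable to carry any flux (maximum
#' absolute flux below `tolerance`). Pure proton/water reactions are
#' excluded from the report (ubiquitous species).
#'
#' @param model an engineered `metabolic_model` (medium already applied).
#' @param objective_id reaction to use as the objective for solvability.
#' @param reactions ids to test; defaults to `model$engineered`.
#' @param tolerance flux threshold, default 1e-6.
#' @param fraction_of_optimum objective fraction the variability analysis
#'   must respect; 0 (default) tests raw capability.
#' @return character vector of blocked reaction ids.
#' @export
check_flux_carrying <- function(model, objective_id,
                                reactions = model$engineered,
                                tolerance = 1e-6,
                                fraction_of_optimum = 0) {
  if (is.null(reactions) || !length(reactions))
    stop("no engineered reactions recorded; pass `reactions=`", call. = FALSE)
  model <- set_objective(model, objective_id)
  keep <- vapply(reactions, function(rid) {
    sto <- model$stoichiometry[[rid]]
    !all(names(sto) %in% UBIQUITOUS_METS)
  }, TRUE)
  reactions <- reactions[keep]
  rng <- fva(model, fraction_of_optimum = fraction_of_optimum,
             reactions = reactions)
  blocked <- rng$reaction[pmax(abs(rng$min), abs(rng$max)) < tolerance]
  blocked
}
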