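#' @useDynLib rlflux, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats p.adjust sd setNames wilcox.test rnorm
#' @importFrom utils read.delim write.table head modifyList
NULL

DEFAULT_UB <- 1000
DEFAULT_LB <- -1000

#' Construct a constraint-based metabolic model
#'
#' A `metabolic_model` bundles the stoichiometric matrix S (m metabolites x
#' n reactions), flux bounds in mmol/gDW/h, an objective weight vector and
#' gene-protein-reaction (GPR) rules. Steady state `S v = 0` is imposed on
#' every metabolite; boundary (exchange/sink) reactions, which touch exactly
#' one metabolite, are the only route by which mass enters or leaves.
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   `formula`, `charge` (formula/charge may be `NA`).
#' @param reactions data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `gpr`, `subsystem` (gpr/subsystem may be `NA`).
#' @param stoichiometry named list (one entry per reaction id) of named
#'   numeric vectors `c(metabolite_id = signed_coefficient, ...)`; negative
#'   for consumption, positive for production.
#' @param objective named numeric vector of reaction weights (vector c).
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, stoichiometry,
                            objective = numeric()) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  for (col in c("formula", "charge")) {
    if (is.null(metabolites[[col]])) metabolites[[col]] <- NA
  }
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  for (col in c("gpr", "subsystem")) {
    if (is.null(reactions[[col]])) reactions[[col]] <- NA_character_
  }
  if (is.null(reactions$name)) reactions$name <- reactions$id
  reactions$lower_bound <- as.numeric(reactions$lower_bound)
  reactions$upper_bound <- as.numeric(reactions$upper_bound)
  if (!is.null(metabolites$charge))
    metabolites$charge <- as.numeric(metabolites$charge)
  stoichiometry <- stoichiometry[reactions$id]
  reactions$is_exchange <- vapply(stoichiometry, length, 1L) == 1L
  rownames(metabolites) <- NULL
  rownames(reactions) <- NULL
  model <- structure(list(id = id,
                          metabolites = metabolites,
                          reactions = reactions,
                          stoichiometry = stoichiometry,
                          objective = objective),
                     class = "metabolic_model")
  validate_model(model)
}

#' Validate a metabolic model's structural invariants
#'
#' Checks id uniqueness, bound ordering, compartment presence, resolvability
#' of stoichiometry entries, GPR parsability and objective references.
#' Called by every constructor and reader; errors name the offending record.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly usable in pipelines.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  rxns <- model$reactions
  if (anyDuplicated(mets$id))
    stop("duplicate metabolite id: ",
         mets$id[duplicated(mets$id)][1], call. = FALSE)
  if (anyDuplicated(rxns$id))
    stop("duplicate reaction id: ", rxns$id[duplicated(rxns$id)][1],
         call. = FALSE)
  if (any(is.na(mets$compartment) | !nzchar(mets$compartment)))
    stop("metabolite with empty compartment: ",
         mets$id[which(is.na(mets$compartment) | !nzchar(mets$compartment))[1]],
         call. = FALSE)
  bad <- which(rxns$lower_bound > rxns$upper_bound)
  if (length(bad))
    stop("reaction '", rxns$id[bad[1]],
         "': lower_bound exceeds upper_bound", call. = FALSE)
  for (rid in rxns$id) {
    sto <- model$stoichiometry[[rid]]
    if (is.null(sto) || !length(sto))
      stop("reaction '", rid, "' has no stoichiometry", call. = FALSE)
    unknown <- setdiff(names(sto), mets$id)
    if (length(unknown))
      stop("reaction '", rid, "' references unknown metabolite '",
           unknown[1], "'", call. = FALSE)
  }
  for (i in seq_len(nrow(rxns))) {
    g <- rxns$gpr[i]
    if (!is.na(g) && nzchar(g)) parse_gpr(g) # errors if malformed
  }
  unknown <- setdiff(names(model$objective), rxns$id)
  if (length(unknown))
    stop("objective references unknown reaction '", unknown[1], "'",
         call. = FALSE)
  invisible(model)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @param sparse return a `Matrix::sparseMatrix` (default) or a dense matrix.
#' @return the m x n matrix S with metabolite ids as rownames and reaction
#'   ids as colnames.
#' @export
stoichiometric_matrix <- function(model, sparse = TRUE) {
  mids <- model$metabolites$id
  rids <- model$reactions$id
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_along(rids)) {
    sto <- model$stoichiometry[[k]]
    i <- c(i, match(names(sto), mids))
    j <- c(j, rep.int(k, length(sto)))
    x <- c(x, unname(sto))
  }
  S <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(length(mids), length(rids)),
                            dimnames = list(mids, rids))
  if (sparse) S else as.matrix(S)
}

n_reactions <- function(model) nrow(model$reactions)
n_metabolites <- function(model) nrow(model$metabolites)

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model '", x$id, "': ", n_metabolites(x), " metabolites x ",
      n_reactions(x), " reactions\n", sep = "")
  if (length(x$objective))
    cat("objective:", paste(names(x$objective), x$objective,
                            sep = " * ", collapse = " + "), "\n")
  invisible(x)
}

# --- reaction equation strings ------------------------------------------------

#' Parse a reaction equation string
#'
#' Understands `"2 a_c + b_c --> c_c"` (irreversible) and `"a_c <=> b_c"`
#' (reversible); the unicode arrow in printed reaction tables is also
#' accepted. An empty side denotes a boundary reaction.
#'
#' @param equation the equation string.
#' @return list with `stoichiometry` (named numeric) and `reversible`.
#' @export
parse_equation <- function(equation) {
  eq <- equation
  rev <- grepl("<=>|<-->", eq)
  parts <- strsplit(eq, if (rev) "<=>|<-->" else "⇒|=>|-+>")[[1]]
  if (length(parts) > 2 || length(parts) < 1)
    stop("cannot parse reaction equation: '", equation, "'", call. = FALSE)
  side <- function(txt, sign) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(numeric())
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      if (!nzchar(tm)) next
      m <- regmatches(tm, regexec("^([0-9.]+)\\s+(.+)$", tm))[[1]]
      if (length(m)) {
        coef <- as.numeric(m[2]); met <- m[3]
      } else {
        coef <- 1; met <- tm
      }
      prev <- if (met %in% names(out)) out[[met]] else 0
      out[met] <- prev + sign * coef
    }
    out
  }
  lhs <- side(parts[1], -1)
  rhs <- if (length(parts) == 2) side(parts[2], +1) else numeric()
  sto <- lhs
  for (m in names(rhs)) sto[m] <- (if (m %in% names(sto)) sto[m] else 0) + rhs[m]
  sto <- sto[sto != 0]
  if (!length(sto))
    stop("reaction equation has empty stoichiometry: '", equation, "'",
         call. = FALSE)
  list(stoichiometry = sto, reversible = rev)
}

format_equation <- function(sto, reversible) {
  one <- function(v) paste(ifelse(abs(v) == 1, names(v),
                                  paste(abs(v), names(v))), collapse = " + ")
  lhs <- sto[sto < 0]; rhs <- sto[sto > 0]
  paste(one(lhs), if (reversible) "<=>" else "-->", one(rhs))
}

# --- elemental formulas -------------------------------------------------------

#' Parse an elemental formula into element counts
#'
#' Accepts standard Hill-style formulas (`"C6H12O6"`); single-letter
#' pseudo-elements used by the toy network's carbon-skeleton bookkeeping
#' parse the same way.
#'
#' @param formula formula string.
#' @return named numeric vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(numeric())
  mm <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula)
  toks <- regmatches(formula, mm)[[1]]
  if (sum(attr(mm[[1]], "match.length")) != nchar(formula))
    stop("cannot parse formula '", formula, "'", call. = FALSE)
  out <- numeric(0)
  for (tk in toks) {
    el <- sub("^([A-Z][a-z]?).*$", "\\1", tk)
    ct <- sub("^[A-Z][a-z]?", "", tk)
    n <- if (nzchar(ct)) as.numeric(ct) else 1
    out[el] <- (if (el %in% names(out)) out[el] else 0) + n
  }
  out
}
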