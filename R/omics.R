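# Transcriptome-constrained condition-specific models: the continuous
# bound-scaling rule phi(theta) = [1 + gamma*|log theta|]^sgn(theta - 1)
# multiplies both flux bounds of every enzyme-associated reaction, so
# over-expressed enzymes widen and under-expressed enzymes tighten the
# admissible flux range, symmetrically on the log scale.

#' Expression-to-bound scaling coefficient
#'
#' `phi(theta) = (1 + gamma * |log theta|)^sgn(theta - 1)` with natural log
#' and `sgn(0) = 0`, so `phi(1) = 1`, `phi(e) = 1 + gamma`, and
#' `phi(theta) * phi(1/theta) = 1` for all theta > 0.
#'
#' @param theta positive expression level(s), reference level 1.
#' @param gamma non-negative weight of expression on the bounds (default 1).
#' @return the scaling coefficient(s), always positive.
#' @export
phi <- function(theta, gamma = 1) {
  if (any(!is.finite(theta)) || any(theta <= 0))
    stop("theta must be positive and finite", call. = FALSE)
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  (1 + gamma * abs(log(theta)))^sign(theta - 1)
}

#' Two-group expression matrix container
#'
#' @param values genes x samples numeric matrix of expression levels
#'   (positive), with gene ids as rownames and sample ids as colnames.
#' @param groups character vector of group labels, either named by sample
#'   id or aligned with the columns.
#' @return an `expression_matrix`.
#' @export
expression_matrix <- function(values, groups) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("expression matrix needs unique gene ids as rownames",
         call. = FALSE)
  if (is.null(colnames(values)) && ncol(values) > 0)
    stop("expression matrix needs sample ids as colnames", call. = FALSE)
  if (any(values <= 0))
    stop("expression levels must be positive", call. = FALSE)
  if (!is.null(names(groups))) {
    missing <- setdiff(colnames(values), names(groups))
    if (length(missing))
      stop("no group label for sample '", missing[1], "'", call. = FALSE)
    groups <- groups[colnames(values)]
  } else if (length(groups) != ncol(values)) {
    stop("groups must have one label per sample", call. = FALSE)
  } else {
    names(groups) <- colnames(values)
  }
  structure(list(values = values, groups = groups),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (groups: ",
      paste(names(table(x$groups)), table(x$groups), sep = "=",
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Normalise expression to reference level 1
#'
#' Divides each gene by its mean across all samples, so theta = 1 is the
#' cohort average for that gene.
#'
#' @param expr an [expression_matrix()] or positive matrix.
#' @return object of the same type with normalised values.
#' @export
normalize_expression <- function(expr) {
  if (inherits(expr, "expression_matrix")) {
    expr$values <- expr$values / rowMeans(expr$values)
    return(expr)
  }
  expr / rowMeans(expr)
}

#' Build a condition-specific model from one expression profile
#'
#' Every reaction with a GPR rule gets both flux bounds multiplied by
#' `phi(theta_reaction, gamma)`, where `theta_reaction` aggregates the
#' profile through the rule (AND = min, OR = max). Reactions without a GPR
#' rule - and the model structure otherwise - are untouched.
#'
#' @param model a `metabolic_model`.
#' @param profile named numeric vector of normalised theta (reference 1).
#' @param gamma weight of expression on the bounds (default 1).
#' @param missing_theta theta for genes absent from the profile (default 1).
#' @return the constrained model.
#' @export
condition_specific_model <- function(model, profile, gamma = 1,
                                     missing_theta = 1) {
  for (i in seq_len(nrow(model$reactions))) {
    g <- model$reactions$gpr[i]
    if (is.na(g) || !nzchar(g)) next
    th <- tryCatch(reaction_expression(g, profile, missing_theta),
                   error = function(e)
                     stop("reaction '", model$reactions$id[i], "': ",
                          conditionMessage(e), call. = FALSE))
    f <- phi(th, gamma)
    model$reactions$lower_bound[i] <- model$reactions$lower_bound[i] * f
    model$reactions$upper_bound[i] <- model$reactions$upper_bound[i] * f
  }
  model
}

#' Batch geometric FBA over condition-specific models
#'
#' Builds one condition-specific model per sample (after per-gene
#' normalisation unless `normalize = FALSE`) and solves each with geometric
#' FBA. Failed samples are flagged in `status`, never silently dropped.
#'
#' @param model a `metabolic_model` with medium and objective configured
#'   (or pass `objective`).
#' @param expr an [expression_matrix()].
#' @param gamma bound-scaling weight (default 1).
#' @param objective optional objective reaction id to set first.
#' @param normalize divide each gene by its cross-sample mean first
#'   (default TRUE).
#' @param tolerance geometric FBA tolerance.
#' @return list with `fluxes` (reactions x samples matrix), `objective`
#'   (named numeric per sample), `status`, `groups`.
#' @export
batch_condition_fba <- function(model, expr, gamma = 1, objective = NULL,
                                normalize = TRUE, tolerance = 1e-6) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (!is.null(objective)) model <- set_objective(model, objective)
  if (normalize) expr <- normalize_expression(expr)
  samples <- colnames(expr$values)
  n <- n_reactions(model)
  fluxes <- matrix(NA_real_, n, length(samples),
                   dimnames = list(model$reactions$id, samples))
  objv <- setNames(rep(NA_real_, length(samples)), samples)
  status <- setNames(rep("optimal", length(samples)), samples)
  for (s in samples) {
    csm <- condition_specific_model(model, expr$values[, s], gamma)
    sol <- tryCatch(geometric_fba(csm, tolerance = tolerance),
                    error = function(e) e)
    if (inherits(sol, "error") || sol$status != "optimal") {
      status[s] <- if (inherits(sol, "error")) conditionMessage(sol)
                   else sol$status
      next
    }
    fluxes[, s] <- sol$fluxes
    objv[s] <- sol$objective_value
  }
  list(fluxes = fluxes, objective = objv, status = status,
       groups = expr$groups)
}

#' Read an expression TSV (genes x samples, header row of sample ids)
#' @param path TSV file; first column gene ids.
#' @param groups optional named group vector; see [expression_matrix()].
#' @return matrix, or an `expression_matrix` when `groups` is given.
#' @export
read_expression <- function(path, groups = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab[[1]]
  if (is.null(groups)) return(values)
  expression_matrix(values, groups)
}

#' Write an expression matrix to TSV
#' @param expr an [expression_matrix()] or matrix.
#' @param path output TSV.
#' @export
write_expression <- function(expr, path) {
  values <- if (inherits(expr, "expression_matrix")) expr$values else expr
  out <- data.frame(gene = rownames(values), values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a sample-to-group mapping TSV (`sample<TAB>group`, no header)
#' @param path TSV file.
#' @return named character vector of group labels.
#' @export
read_groups <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("sample", "group"))
  setNames(tab$group, tab$sample)
}
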