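# Downstream statistics on predicted flux matrices: differentially active
# reactions (two-group rank tests with FDR control), elastic-net ranking of
# the genes driving each disrupted reaction, and PCA of flux rates with the
# contribution / squared-cosine decomposition used for factor maps.

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, order-preserving and capped at
#' 1 (delegates to [stats::p.adjust()]).
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values, same order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvalues, method = "BH")
}

#' Differentially active reactions between two sample groups
#'
#' Per reaction, a two-sided Wilcoxon rank-sum test on the predicted flux
#' values of the two groups, followed by Benjamini-Hochberg adjustment
#' across all tested reactions. Reactions with (numerically) identical flux
#' in every sample carry no information and are excluded from testing; they
#' are reported in the `"constant"` attribute.
#'
#' @param flux_matrix reactions x samples matrix (e.g. from
#'   [batch_condition_fba()]).
#' @param groups group label per sample (two levels, each with >= 2
#'   samples).
#' @param alpha_threshold adjusted-p cutoff defining a DAR (default 0.05).
#' @param model optional `metabolic_model` supplying reaction names and
#'   pathway (subsystem) annotation.
#' @return a `dar_table` data.frame of reactions with adjusted p below the
#'   threshold, sorted by adjusted p; the full test table is in the
#'   `"all_tests"` attribute and untestable constant reactions in
#'   `"constant"`.
#' @export
identify_dars <- function(flux_matrix, groups, alpha_threshold = 0.05,
                          model = NULL) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2)
    stop("exactly two groups are required (got ", length(lev), ")",
         call. = FALSE)
  if (any(table(groups) < 2))
    stop("each group needs at least 2 samples", call. = FALSE)
  if (ncol(flux_matrix) != length(groups))
    stop("groups must have one label per sample column", call. = FALSE)
  ok <- !apply(flux_matrix, 1, anyNA)
  rng <- apply(flux_matrix[ok, , drop = FALSE], 1,
               function(x) diff(range(x)))
  constant <- rownames(flux_matrix)[ok][rng <= 1e-9]
  test_ids <- setdiff(rownames(flux_matrix)[ok], constant)
  g1 <- groups == lev[1]
  rows <- lapply(test_ids, function(rid) {
    x <- flux_matrix[rid, g1]
    y <- flux_matrix[rid, !g1]
    p <- suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
    data.frame(reaction = rid,
               mean_group1 = mean(x), mean_group2 = mean(y),
               p_value = p, stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows)
         else data.frame(reaction = character(), mean_group1 = numeric(),
                         mean_group2 = numeric(), p_value = numeric(),
                         stringsAsFactors = FALSE)
  tab$p_adjusted <- if (nrow(tab)) bh_adjust(tab$p_value) else numeric()
  if (!is.null(model)) {
    i <- match(tab$reaction, model$reactions$id)
    tab$name <- model$reactions$name[i]
    tab$pathway <- model$reactions$subsystem[i]
  }
  tab <- tab[order(tab$p_adjusted, tab$reaction), , drop = FALSE]
  rownames(tab) <- NULL
  dars <- tab[!is.na(tab$p_adjusted) & tab$p_adjusted < alpha_threshold, ,
              drop = FALSE]
  rownames(dars) <- NULL
  attr(dars, "all_tests") <- tab
  attr(dars, "constant") <- constant
  attr(dars, "groups") <- lev
  class(dars) <- c("dar_table", "data.frame")
  dars
}

#' Elastic-net selection of genes predicting a reaction's flux
#'
#' Fits the elastic net via glmnet with 10-fold cross-validation, choosing
#' lambda at the CV-error minimum. `alpha` follows the convention
#' `alpha = lambda2 / (lambda1 + lambda2)` (weight of the ridge term);
#' glmnet's mixing parameter is therefore `1 - alpha`. At the default
#' `alpha = 0.5` the two conventions coincide. Predictors are standardised
#' internally.
#'
#' @param X samples x genes matrix (column names = gene ids).
#' @param y response: the flux of one differentially active reaction per
#'   sample.
#' @param alpha ridge weight in `[0, 1]` (default 0.5).
#' @param folds number of CV folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param lambda optional user lambda grid passed to glmnet.
#' @return an `elastic_net_result`: `beta` (named coefficients at the
#'   chosen lambda), `intercept`, `lambda_grid`, `cv_error`, `lambda_min`,
#'   `alpha`, `lambda1`, `lambda2`, `seed`, and the underlying `fit`.
#' @export
elastic_net_select <- function(X, y, alpha = 0.5, folds = 10, seed = 1,
                               lambda = NULL) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop("NA in regression inputs", call. = FALSE)
  if (nrow(X) != length(y))
    stop("rows of X must align with y", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  genes <- colnames(X)
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(X)))
  if (sd(y) == 0) {
    warning("response has zero variance; returning all-zero coefficients")
    return(structure(list(beta = setNames(numeric(ncol(X)), genes),
                          intercept = mean(y), lambda_grid = NA_real_,
                          cv_error = NA_real_, lambda_min = NA_real_,
                          alpha = alpha, lambda1 = NA_real_,
                          lambda2 = NA_real_, seed = seed, fit = NULL),
                     class = "elastic_net_result"))
  }
  with_seed(seed, {
    foldid <- sample(rep(seq_len(folds), length.out = nrow(X)))
    cv <- glmnet::cv.glmnet(X, y, alpha = 1 - alpha, foldid = foldid,
                            lambda = lambda, standardize = TRUE)
  })
  co <- as.matrix(stats::coef(cv, s = "lambda.min"))
  beta <- setNames(co[-1, 1], genes)
  lmin <- cv$lambda.min
  structure(list(beta = beta, intercept = co[1, 1],
                 lambda_grid = cv$lambda, cv_error = cv$cvm,
                 cv_sd = cv$cvsd, lambda_min = lmin, alpha = alpha,
                 lambda1 = lmin * (1 - alpha), lambda2 = lmin * alpha,
                 seed = seed, fit = cv),
            class = "elastic_net_result")
}

#' @export
print.elastic_net_result <- function(x, ...) {
  nz <- sum(x$beta != 0)
  cat("elastic_net_result: alpha ", x$alpha, ", lambda_min ",
      format(x$lambda_min), ", ", nz, " non-zero of ", length(x$beta),
      " coefficients\n", sep = "")
  invisible(x)
}

#' Top genes by absolute elastic-net coefficient
#'
#' @param result an [elastic_net_select()] result.
#' @param k number of genes (default 10). If fewer than `k` coefficients
#'   are non-zero, all non-zero genes are returned and the result carries
#'   `attr(,"truncated") = TRUE`.
#' @return data.frame with columns `gene`, `beta`, ranked by `|beta|`
#'   descending, ties broken by gene id.
#' @export
top_genes <- function(result, k = 10) {
  beta <- result$beta[result$beta != 0]
  ord <- order(-abs(beta), names(beta))
  beta <- beta[ord]
  truncated <- length(beta) < k
  beta <- head(beta, k)
  out <- data.frame(gene = names(beta), beta = unname(beta),
                    stringsAsFactors = FALSE)
  attr(out, "truncated") <- truncated
  out
}

#' PCA of a flux matrix with contributions and squared cosines
#'
#' Singular-value decomposition of the column-centred (and, by default,
#' unit-scaled) flux matrix, individuals = reactions (rows), variables =
#' growth conditions (columns). Follows the standard factor-map
#' decomposition: variable coordinates are correlations with the
#' components (under scaling), contributions are percentage shares of each
#' component's inertia, and cos2 measures representation quality.
#' Constant columns are dropped with a warning.
#'
#' @param flux_matrix reactions x conditions numeric matrix.
#' @param scale unit-scale columns (correlation PCA, default TRUE).
#' @return a `flux_pca` list: `eigenvalues`, `variance_fraction`,
#'   `var_coord`, `var_contrib`, `var_cos2`, `ind_coord`, `ind_contrib`,
#'   `ind_cos2`, plus the decomposition (`u`, `d`, `v`) and the centring/
#'   scaling vectors for reconstruction.
#' @export
pca_flux <- function(flux_matrix, scale = TRUE) {
  X <- as.matrix(flux_matrix)
  if (ncol(X) < 2) stop("need at least 2 conditions", call. = FALSE)
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warning("dropping constant condition column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) < 2)
    stop("fewer than 2 non-constant condition columns", call. = FALSE)
  ctr <- colMeans(X)
  scl <- if (scale) apply(X, 2, sd) else rep(1, ncol(X))
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  n <- nrow(Z)
  sv <- svd(Z)
  eig <- sv$d^2 / (n - 1)
  ncomp <- length(eig)
  comp <- paste0("PC", seq_len(ncomp))
  ind_coord <- sv$u %*% diag(sv$d, ncomp)
  dimnames(ind_coord) <- list(rownames(X), comp)
  var_coord <- sv$v %*% diag(sqrt(eig), ncomp)
  dimnames(var_coord) <- list(colnames(X), comp)
  var_contrib <- 100 * sv$v^2
  dimnames(var_contrib) <- dimnames(var_coord)
  ind_contrib <- 100 * sv$u^2
  dimnames(ind_contrib) <- dimnames(ind_coord)
  row_norm2 <- rowSums(Z^2)
  ind_cos2 <- ind_coord^2 / ifelse(row_norm2 > 0, row_norm2, NA)
  ind_cos2[row_norm2 == 0, ] <- 0
  var_cos2 <- var_coord^2 / rowSums(var_coord^2)
  structure(list(eigenvalues = setNames(eig, comp),
                 variance_fraction = setNames(eig / sum(eig), comp),
                 var_coord = var_coord, var_contrib = var_contrib,
                 var_cos2 = var_cos2, ind_coord = ind_coord,
                 ind_contrib = ind_contrib, ind_cos2 = ind_cos2,
                 u = sv$u, d = sv$d, v = sv$v,
                 center = ctr, scale = scl),
            class = "flux_pca")
}

#' @export
print.flux_pca <- function(x, ...) {
  vf <- round(100 * x$variance_fraction, 1)
  cat("flux_pca: ", length(x$eigenvalues), " components; variance % = ",
      paste(vf, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Reconstruct the input matrix from a flux PCA
#'
#' Uses all components; the result equals the (non-constant columns of
#' the) original matrix up to numerical error.
#'
#' @param p a `flux_pca`.
#' @return the reconstructed matrix.
#' @export
pca_reconstruct <- function(p) {
  Z <- p$u %*% diag(p$d, length(p$d)) %*% t(p$v)
  sweep(sweep(Z, 2, p$scale, "*"), 2, p$center, "+")
}
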