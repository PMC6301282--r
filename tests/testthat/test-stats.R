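# Downstream statistics: BH adjustment against a literal step-up oracle,
# DAR detection, elastic-net behaviour in its analytic limits, and the PCA
# contribution/cos2 decomposition against a dense eigendecomposition.

test_that("BH adjustment matches the step-up oracle", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_adjust(p), rep(0.04, 4))
  expect_equal(bh_adjust(p), oracle_bh(p))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(3)
  q <- runif(50)
  expect_equal(bh_adjust(q), oracle_bh(q))
  expect_true(all(bh_adjust(q) >= q))       # adjusted >= raw
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(-0.1)), "0, 1")
})

test_that("identical groups yield no DARs; separation yields exactly one", {
  half <- matrix(rep(c(1, 2, 3), 10), 3, 10,
                 dimnames = list(c("r1", "r2", "r3"), paste0("s", 1:10)))
  flux <- cbind(half, half)
  colnames(flux) <- paste0("s", 1:20)
  groups <- rep(c("a", "b"), each = 10)
  d <- identify_dars(flux, groups)
  expect_equal(nrow(d), 0)
  expect_setequal(attr(d, "constant"), c("r1", "r2", "r3"))
  # one reaction at 1.0 in group a (n=40), 2.0 in group b (n=40)
  flux2 <- matrix(5, 4, 80, dimnames = list(paste0("r", 1:4),
                                            paste0("s", 1:80)))
  flux2["r2", ] <- rep(c(1, 2), each = 40)
  d2 <- identify_dars(flux2, rep(c("a", "b"), each = 40))
  expect_equal(d2$reaction, "r2")
  expect_lt(d2$p_adjusted, 1e-10)
  expect_error(identify_dars(flux2, rep("a", 80)), "two groups")
  expect_error(identify_dars(flux2, c("a", rep("b", 79))), "at least 2")
})

test_that("DAR false-positive proportion on null data stays at the nominal level", {
  # 200 reactions, 40 vs 40, no effect; BH controls the chance of any
  # discovery at alpha under the global null
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    flux <- matrix(rnorm(200 * 80), 200, 80,
                   dimnames = list(sprintf("r%03d", 1:200), NULL))
    colnames(flux) <- paste0("s", 1:80)
    nrow(identify_dars(flux, rep(c("a", "b"), each = 40))) > 0
  }, TRUE)
  fpp <- mean(hits)
  expect_lte(fpp, 0.05 + 2 * sqrt(0.05 * 0.95 / 100))
})

test_that("elastic net recovers the OLS limit and zeroes at lambda_max", {
  set.seed(21)
  n <- 200
  x1 <- scale(rnorm(n))[, 1]
  x2 <- scale(rnorm(n))[, 1]
  X <- cbind(g1 = x1, g2 = x2)
  y <- 2 * x1
  fit <- elastic_net_select(X, y, alpha = 0.5, seed = 4,
                            lambda = 10^seq(1, -7, length.out = 60))
  expect_equal(unname(fit$beta["g1"]), 2, tolerance = 1e-3)
  expect_equal(unname(fit$beta["g2"]), 0, tolerance = 1e-3)
  # lambda >= lambda_max (closed form from |X'y|) zeroes every coefficient
  y2 <- 2 * x1 + rnorm(n, 0, 0.5)
  alpha_l1 <- 0.5 # glmnet mixing parameter at ridge weight alpha = 0.5
  lambda_max <- max(abs(crossprod(scale(X), y2 - mean(y2)))) / (n * alpha_l1)
  g <- glmnet::glmnet(X, y2, alpha = alpha_l1,
                      lambda = c(lambda_max * 1.01, lambda_max * 2))
  expect_true(all(as.matrix(g$beta) == 0))
  # and our wrapper's own largest grid lambda likewise
  fit2 <- elastic_net_select(X, y2, alpha = 0.5, seed = 4)
  co <- as.matrix(stats::coef(fit2$fit$glmnet.fit,
                              s = max(fit2$lambda_grid)))
  expect_true(all(co[-1, ] == 0))
  # lambda1/lambda2 decomposition is consistent
  expect_equal(fit2$lambda1 + fit2$lambda2, fit2$lambda_min)
})

test_that("degenerate responses and inputs are rejected or zeroed", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  expect_warning(fit <- elastic_net_select(X, rep(3, 20)), "zero variance")
  expect_true(all(fit$beta == 0))
  expect_error(elastic_net_select(X, c(rep(1, 19), NA)), "NA")
  expect_error(elastic_net_select(X, rnorm(19)), "align")
})

test_that("coefficients move continuously along the lambda path", {
  set.seed(8)
  X <- matrix(rnorm(100 * 5), 100, 5,
              dimnames = list(NULL, paste0("g", 1:5)))
  y <- X %*% c(2, -1, 0.5, 0, 0) + rnorm(100, 0, 0.2)
  fit <- elastic_net_select(X, y[, 1], seed = 2)
  B <- as.matrix(fit$fit$glmnet.fit$beta)
  steps <- abs(t(diff(t(B))))
  expect_lt(max(steps), 0.5) # no jumps along the fitted path
})

test_that("top_genes ranks by |beta| with deterministic ties", {
  fake <- structure(list(beta = c(gB = -3, gA = 3, gC = 0.5, gD = 0)),
                    class = "elastic_net_result")
  tg <- top_genes(fake, 2)
  expect_equal(tg$gene, c("gA", "gB")) # tie on |3| broken by gene id
  expect_equal(top_genes(fake, 0)$gene, character(0))
  tg_all <- top_genes(fake, 10)
  expect_equal(nrow(tg_all), 3) # zeros never returned
  expect_true(attr(tg_all, "truncated"))
})

test_that("PCA decomposition satisfies its normalisations and oracle", {
  set.seed(14)
  X <- matrix(rnorm(60), 20, 3,
              dimnames = list(paste0("r", 1:20), c("c1", "c2", "c3")))
  p <- pca_flux(X, scale = TRUE)
  expect_equal(sum(p$variance_fraction), 1)
  expect_equal(unname(colSums(p$var_contrib)),
               rep(100, 3), tolerance = 1e-9)
  expect_equal(unname(colSums(p$ind_contrib)),
               rep(100, 3), tolerance = 1e-9)
  expect_equal(unname(rowSums(p$var_cos2)), rep(1, 3), tolerance = 1e-9)
  expect_true(all(rowSums(p$ind_cos2) <= 1 + 1e-9))
  expect_equal(unname(rowSums(p$ind_cos2)), rep(1, 20), tolerance = 1e-9)
  # dense eigendecomposition of the correlation matrix as oracle
  eg <- eigen(cor(X))
  expect_equal(unname(p$eigenvalues), eg$values, tolerance = 1e-9)
  expect_equal(abs(unname(p$var_coord)),
               abs(eg$vectors %*% diag(sqrt(eg$values))), tolerance = 1e-9)
  # reconstruction from all components
  expect_lt(max(abs(pca_reconstruct(p) - X)), 1e-8)
})

test_that("perfectly correlated variables load one component 50/50", {
  x <- rnorm(30)
  X <- cbind(a = x, b = 2 * x + 1)
  rownames(X) <- paste0("r", 1:30)
  p <- pca_flux(X, scale = TRUE)
  expect_equal(unname(p$variance_fraction["PC1"]), 1, tolerance = 1e-9)
  expect_equal(unname(p$var_contrib[, "PC1"]), c(50, 50), tolerance = 1e-9)
})

test_that("constant columns are dropped with a warning", {
  X <- cbind(a = rnorm(10), b = rnorm(10), c = rep(2, 10))
  rownames(X) <- paste0("r", 1:10)
  expect_warning(p <- pca_flux(X), "constant")
  expect_equal(ncol(p$var_coord), 2)
  expect_error(suppressWarnings(pca_flux(X[, c(1, 3)])), "non-constant")
  expect_error(pca_flux(X[, 1, drop = FALSE]), "at least 2")
})
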