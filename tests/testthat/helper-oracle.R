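# Independent oracles used to freeze expected values:
#  - exhaustive vertex enumeration for small LPs (checks the simplex core)
#  - a literal step-up implementation of Benjamini-Hochberg

# max c'v s.t. S v = 0, lb <= v <= ub, by enumerating all candidate
# vertices: every choice of (n - rank) variables fixed at a bound.
oracle_vertex_max <- function(model) {
  S <- stoichiometric_matrix(model, sparse = FALSE)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  cvec <- rlflux:::objective_vector(model)
  n <- ncol(S)
  r <- qr(S)$rank
  d <- n - r
  stopifnot(d >= 1)
  best <- -Inf
  combos <- utils::combn(n, d)
  pat <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), d)))
  for (ci in seq_len(ncol(combos))) {
    free <- combos[, ci]
    Sb <- S[, -free, drop = FALSE]
    qrS <- qr(Sb)
    if (qrS$rank < n - d) next
    for (pi in seq_len(nrow(pat))) {
      xf <- ifelse(pat[pi, ], ub[free], lb[free])
      xb <- qr.coef(qrS, -S[, free, drop = FALSE] %*% xf)
      if (anyNA(xb)) next
      x <- numeric(n)
      x[free] <- xf
      x[-free] <- xb
      if (max(abs(S %*% x)) > 1e-6) next
      if (any(x < lb - 1e-7) || any(x > ub + 1e-7)) next
      best <- max(best, sum(cvec * x))
    }
  }
  best
}

# literal BH step-up: adj p_(i) = min_{j >= i} min(1, n/j * p_(j))
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- pmin(rev(cummin(rev(ranked))), 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# glucose-fed toy with medium applied, memoised per test file
glc_toy <- function(rate = 10, ...) {
  set_medium(toy_model(...), c(glucose = rate))
}
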