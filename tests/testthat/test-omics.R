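# Expression integration: the phi bound-scaling rule, condition-specific
# models, and batch geometric FBA.

test_that("phi closed-form identities hold", {
  expect_equal(phi(1, 1), 1)
  expect_equal(phi(exp(1), 1), 2)
  expect_equal(phi(exp(-1), 1), 0.5)
  expect_equal(phi(exp(1), 2), 3)
  expect_error(phi(0), "positive")
  expect_error(phi(-2), "positive")
  expect_error(phi(2, gamma = -1), "gamma")
})

test_that("phi is multiplicatively symmetric and monotone", {
  set.seed(11)
  for (gamma in c(0, 0.5, 1, 2)) {
    theta <- exp(rnorm(50))
    expect_equal(phi(theta, gamma) * phi(1 / theta, gamma),
                 rep(1, 50), tolerance = 1e-12)
  }
  up <- sort(exp(seq(0.01, 2, length.out = 20)))
  expect_true(all(diff(phi(up, 1)) > 0))           # increasing for theta>1
  expect_true(all(diff(phi(rev(1 / up), 1)) > 0))  # decreasing toward 0
  expect_true(all(phi(up, 2) >= phi(up, 1)))       # gamma amplifies
})

test_that("condition-specific models scale only GPR-bearing bounds", {
  m <- toy_model()
  # all theta at the reference level: model unchanged
  ones <- setNames(rep(1, length(model_genes(m))), model_genes(m))
  expect_identical(condition_specific_model(m, ones), m)
  # single-gene reaction (0, 1000), theta = e, gamma = 1 -> (0, 2000)
  pro <- c(hex = exp(1))
  m2 <- condition_specific_model(m, pro)
  i <- match("HEX", m2$reactions$id)
  expect_equal(m2$reactions$upper_bound[i], 2000)
  expect_equal(m2$reactions$lower_bound[i], 0)
  # reversible bounds shrink symmetrically under theta = 1/e
  m3 <- toy_model()
  i <- match("Ht", m3$reactions$id)
  m3$reactions$gpr[i] <- "htA"
  m3$reactions$lower_bound[i] <- -10
  m3$reactions$upper_bound[i] <- 10
  m4 <- condition_specific_model(m3, c(htA = exp(-1)))
  expect_equal(m4$reactions$lower_bound[i], -5)
  expect_equal(m4$reactions$upper_bound[i], 5)
  # GPR-free reactions untouched
  expect_identical(m2$reactions$upper_bound[m2$reactions$id == "GLCt2"],
                   1000)
})

test_that("bound nesting: uniform under/over-expression moves the optimum", {
  m <- set_medium(toy_model(parallel_transport = FALSE,
                            vmax_override = c(GLCt1 = 10)),
                  c(glucose = 10))
  base <- fba(m)$objective_value
  genes <- model_genes(m)
  lo <- condition_specific_model(m, setNames(rep(exp(-0.5), length(genes)),
                                             genes))
  hi <- condition_specific_model(m, setNames(rep(exp(0.5), length(genes)),
                                             genes))
  expect_lt(fba(lo)$objective_value, base)
  expect_gte(fba(hi)$objective_value, base)
})

test_that("under-expressing the transport gene halves the optimum", {
  # the glucose transporter's cap binds at the optimum; theta = 1/e on its
  # gene scales the cap (and hence the optimum) by exactly 1/2
  m <- set_medium(toy_model(parallel_transport = FALSE,
                            vmax_override = c(GLCt1 = 10)),
                  c(glucose = 10))
  base <- fba(m)$objective_value
  csm <- condition_specific_model(m, c(glcT1 = exp(-1)))
  expect_equal(fba(csm)$objective_value, base / 2, tolerance = 1e-9)
})

test_that("batch condition FBA returns aligned columns and flags failures", {
  m <- set_medium(toy_model(parallel_transport = FALSE,
                            vmax_override = c(GLCt1 = 10)),
                  c(glucose = 10))
  genes <- model_genes(m)
  values <- matrix(1, length(genes) + 2, 3,
                   dimnames = list(c(genes, "zz1", "zz2"),
                                   c("s1", "s2", "s3")))
  expr <- expression_matrix(values, c(s1 = "a", s2 = "a", s3 = "b"))
  b <- batch_condition_fba(m, expr, objective = "EX_rl")
  expect_equal(colnames(b$fluxes), c("s1", "s2", "s3"))
  ref <- geometric_fba(set_objective(m, "EX_rl"))$fluxes
  for (s in colnames(b$fluxes))
    expect_equal(unname(b$fluxes[, s]), unname(ref), tolerance = 1e-6)
  # under-expression on the binding transporter halves one column
  values[, "s3"] <- 1
  values["glcT1", "s3"] <- exp(-1) * mean(c(1, 1, exp(-1)))^0 # raw theta
  expr2 <- expression_matrix(values, c(s1 = "a", s2 = "a", s3 = "b"))
  b2 <- batch_condition_fba(m, expr2, objective = "EX_rl",
                            normalize = FALSE)
  expect_equal(unname(b2$objective["s3"]),
               unname(b2$objective["s1"]) / 2, tolerance = 1e-6)
  # empty sample set
  e0 <- expression_matrix(values[, 0, drop = FALSE], character())
  b0 <- batch_condition_fba(m, e0, objective = "EX_rl")
  expect_equal(ncol(b0$fluxes), 0)
})

test_that("expression TSV and group files round-trip", {
  syn <- synth_expression(n_per_group = 3, genes = 20, seed = 5)
  path <- tempfile(fileext = ".tsv")
  write_expression(syn$expression, path)
  values <- read_expression(path)
  expect_equal(values, syn$expression$values, tolerance = 1e-12)
  gpath <- tempfile(fileext = ".tsv")
  write.table(data.frame(names(syn$expression$groups),
                         syn$expression$groups),
              gpath, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  expect_equal(read_groups(gpath), syn$expression$groups)
})

test_that("normalisation centres every gene at reference level 1", {
  syn <- synth_expression(n_per_group = 5, genes = 30, seed = 9)
  nm <- normalize_expression(syn$expression)
  expect_equal(unname(rowMeans(nm$values)), rep(1, 30), tolerance = 1e-12)
})
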