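# Joint pmf of the factor tree copula models: quadrature rule,
# normalization, exact reductions and the discretized-MVN specialization.

test_that("Gauss-Legendre rule on (0,1) has exact low-order moments", {
  r1 <- gauss_legendre_01(1)
  expect_equal(r1$nodes, 0.5)
  expect_equal(r1$weights, 1)
  for (nq in c(5, 25)) {
    r <- gauss_legendre_01(nq)
    expect_equal(sum(r$weights), 1, tolerance = 1e-13)
    expect_equal(sum(r$weights * r$nodes^3), 0.25, tolerance = 1e-12)
    expect_equal(r$nodes, 1 - rev(r$nodes), tolerance = 1e-12)
  }
  expect_error(gauss_legendre_01(0), "positive")
})

test_that("pmf sums to one over all outcomes for every model class", {
  cp <- cutpoints(rep(list(c(0.3, 0.7)), 4))
  grid <- as.matrix(expand.grid(0:2, 0:2, 0:2, 0:2))
  models <- list(
    p1 = factor_tree_model(1, cp, "gumbel", c(2.5, 2, 1.7, 1.4),
                           edges = cbind(1:3, 2:4), vine_family = "frank",
                           vine_theta = c(3, -2, 1)),
    p2 = factor_tree_model(2, cp, "gumbel", c(2, 1.8, 1.5, 1.3),
                           tree2_family = "t", tree2_theta = rep(0.5, 4),
                           tree2_nu = 5, edges = cbind(1:3, 2:4),
                           vine_family = "bvn",
                           vine_theta = c(0.4, -0.3, 0.2)),
    p0 = factor_tree_model(0, cp, edges = cbind(1:3, 2:4),
                           vine_family = "gumbel",
                           vine_theta = c(2, 1.5, 1.2)),
    p1_novine = factor_tree_model(1, cp, "sgumbel", c(2, 1.8, 1.5, 1.2))
  )
  for (nm in names(models))
    expect_equal(sum(model_pmf(grid, models[[nm]])), 1,
                 tolerance = 1e-6, label = nm)
})

test_that("exact reductions: independence, no-vine, no-factor nesting", {
  cp <- toy_cutpoints3()
  g <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  marg <- apply(g, 1, function(y) prod(c(0.2, 0.3, 0.5)[y + 1]))
  # everything-independence equals the product of margins
  mi <- factor_tree_model(1, cp, "bvn", rep(0, 3))
  expect_equal(model_pmf(g, mi), marg, tolerance = 1e-12)
  # p = 0 with an edge set equals the Markov-tree pmf; with d = 2 the
  # single-edge model is exactly the bivariate rectangle probability
  cp2 <- cutpoints(list(c(0.3, 0.6), c(0.4, 0.8)))
  sp <- bicop_spec("frank", 4)
  m2 <- factor_tree_model(0, cp2, edges = cbind(1L, 2L),
                          vine_family = "frank", vine_theta = 4)
  a1 <- c(0, 0.3, 0.6, 1); a2 <- c(0, 0.4, 0.8, 1)
  for (y1 in 0:2) for (y2 in 0:2) {
    rect <- pbicop(a1[y1 + 2], a2[y2 + 2], sp) -
      pbicop(a1[y1 + 1], a2[y2 + 2], sp) -
      pbicop(a1[y1 + 2], a2[y2 + 1], sp) +
      pbicop(a1[y1 + 1], a2[y2 + 1], sp)
    expect_equal(model_pmf(c(y1, y2), m2), rect, tolerance = 1e-12)
  }
  # independence edge copulas reduce the tree model to the factor model
  mt <- factor_tree_model(1, cp, "gumbel", c(2, 1.7, 1.4),
                          edges = cbind(1:2, 2:3), vine_family = "indep")
  mf <- factor_tree_model(1, cp, "gumbel", c(2, 1.7, 1.4))
  expect_equal(model_pmf(g, mt), model_pmf(g, mf), tolerance = 1e-13)
  # a two-factor model with independence second tree reduces to one factor
  m21 <- factor_tree_model(2, cp, "gumbel", c(2, 1.7, 1.4),
                           tree2_family = "indep")
  expect_equal(model_pmf(g, m21), model_pmf(g, mf), tolerance = 1e-12)
})

test_that("all-BVN factor model reproduces discretized-MVN rectangles", {
  skip_if_not_installed("mvtnorm")
  cp <- toy_cutpoints3()
  th <- c(0.8, 0.6, 0.4)
  mb <- factor_tree_model(1, cp, "bvn", th)
  R <- diag(3)
  for (j in 1:2) for (k in (j + 1):3) R[j, k] <- R[k, j] <- th[j] * th[k]
  al <- qnorm(c(0.2, 0.5))
  g <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  oracle <- apply(g, 1, function(y) {
    lo <- sapply(y, function(v) c(-Inf, al)[v + 1])
    hi <- sapply(y, function(v) c(al, Inf)[v + 1])
    suppressWarnings(
      mvtnorm::pmvnorm(lower = lo, upper = hi, corr = R,
                       algorithm = mvtnorm::Miwa(steps = 4097))[1])
  })
  expect_lt(max(abs(model_pmf(g, mb, nq = 150) - oracle)), 1e-5)
})

test_that("pmf is stable in the quadrature size", {
  cp <- toy_cutpoints5(4)
  set.seed(3)
  m <- factor_tree_model(1, cp, "gumbel",
                         vapply(runif(4, 0.2, 0.5),
                                function(t) tau_to_par("gumbel", t)$theta, 0),
                         edges = cbind(1:3, 2:4), vine_family = "frank",
                         vine_theta = runif(3, -2, 2))
  g <- as.matrix(expand.grid(0:4, 0:4, 0:4, 0:4))[sample(625, 60), ]
  expect_lt(max(abs(model_pmf(g, m, nq = 25) - model_pmf(g, m, nq = 50))),
            1e-5)
})

test_that("conditional item cdfs and ICCs follow the h-function chain", {
  cp <- toy_cutpoints3()
  m <- factor_tree_model(1, cp, "bvn", c(0.6, 0.5, 0.4))
  # numerical derivative oracle: d/dx C_bvn(x, a)
  a <- 0.2; x <- 0.3; eps <- 1e-6
  sp <- bicop_spec("bvn", 0.6)
  fd <- (pbicop(x + eps, a, sp) - pbicop(x - eps, a, sp)) / (2 * eps)
  expect_equal(item_cond_cdf(m, 1, 0, x), fd, tolerance = 1e-5)
  # boundaries and monotonicity
  expect_equal(item_cond_cdf(m, 1, -1, 0.4), 0)
  expect_equal(item_cond_cdf(m, 1, 2, 0.4), 1)
  # independence link returns the cutpoint regardless of x
  mi <- factor_tree_model(1, cp, "indep", rep(NA, 3))
  expect_equal(item_cond_cdf(mi, 2, 0, 0.77), 0.2)
  # ICC normalization at several latent values
  for (x in c(0.1, 0.5, 0.9))
    expect_equal(sum(item_icc(m, 1, 0:2, rep(x, 3))), 1, tolerance = 1e-12)
  # two-factor chain with independence second link reduces to one factor
  m2 <- factor_tree_model(2, cp, "bvn", c(0.6, 0.5, 0.4),
                          tree2_family = "indep")
  expect_equal(item_cond_cdf(m2, 1, 1, 0.3, 0.8),
               item_cond_cdf(m, 1, 1, 0.3), tolerance = 1e-12)
  m2t <- factor_tree_model(2, cp, "gumbel", c(2, 1.5, 1.3),
                           tree2_family = "t", tree2_theta = rep(0.4, 3),
                           tree2_nu = 5)
  for (x2 in c(0.2, 0.7))
    expect_equal(sum(item_icc(m2t, 2, 0:2, rep(0.4, 3), rep(x2, 3))), 1,
                 tolerance = 1e-12)
})

test_that("conditional pair pmf is a nonnegative normalized rectangle", {
  cp <- toy_cutpoints3()
  m <- factor_tree_model(1, cp, "gumbel", c(2, 1.7, 1.4),
                         edges = cbind(1:2, 2:3), vine_family = "frank",
                         vine_theta = c(3, -2))
  tot <- 0
  for (y1 in 0:2) for (y2 in 0:2) {
    p <- pair_pmf_cond(m, c(1, 2), y1, y2, 0.35)
    expect_gte(p, 0)
    tot <- tot + p
  }
  expect_equal(tot, 1, tolerance = 1e-10)
  expect_error(pair_pmf_cond(m, c(1, 3), 0, 0, 0.5), "not an edge")
  # independence edge factorizes into the two ICCs
  mi <- factor_tree_model(1, cp, "gumbel", c(2, 1.7, 1.4),
                          edges = cbind(1:2, 2:3), vine_family = "indep")
  expect_equal(pair_pmf_cond(mi, c(1, 2), 1, 2, 0.35),
               item_icc(mi, 1, 1, 0.35) * item_icc(mi, 2, 2, 0.35),
               tolerance = 1e-12)
})

test_that("log-likelihood is additive over rows", {
  cp <- toy_cutpoints3()
  m <- factor_tree_model(1, cp, "bvn", c(0.6, 0.5, 0.4))
  y1 <- c(0, 1, 2)
  expect_equal(loglik(matrix(y1, 1), m), log(model_pmf(y1, m)))
  y <- rbind(y1, c(1, 1, 0))
  expect_equal(loglik(rbind(y, y1), m),
               loglik(y, m) + log(model_pmf(y1, m)), tolerance = 1e-12)
})

test_that("model constructor validates structure", {
  cp <- toy_cutpoints3()
  expect_error(factor_tree_model(1, cp, "gumbel", rep(2, 3),
                                 edges = cbind(1:2, c(2, 1)),
                                 vine_family = "bvn",
                                 vine_theta = c(0.1, 0.2)),
               "cycle")
  expect_error(factor_tree_model(1, cp, "gumbel", rep(2, 3),
                                 edges = cbind(1, 2), vine_family = "bvn",
                                 vine_theta = 0.1),
               "d - 1 edges")
  expect_error(factor_tree_model(1, cp, "gumbel", rep(0.5, 3)),
               "domain")
})
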