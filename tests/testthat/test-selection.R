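# Polychoric machinery, spanning-tree selection, discrepancies, implied
# correlations, sequential family selection and Vuong comparison.

test_that("polychoric ML recovers a latent normal correlation", {
  set.seed(31)
  n <- 3e4
  rho <- 0.6
  z <- matrix(rnorm(2 * n), ncol = 2)
  z[, 2] <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
  cuts <- qnorm(c(0.2, 0.4, 0.6, 0.8))
  y <- cbind(findInterval(z[, 1], cuts), findInterval(z[, 2], cuts))
  expect_equal(polychoric(y[, 1], y[, 2]), rho, tolerance = 0.02)
  # independent items
  y0 <- cbind(sample(0:4, n, TRUE), sample(0:4, n, TRUE))
  expect_lt(abs(polychoric(y0[, 1], y0[, 2])), 0.02)
  # comonotone pair clips at the boundary
  expect_warning(r <- polychoric(y[, 1], y[, 1]), "boundary")
  expect_equal(r, 0.999)
})

test_that("partial correlations match a Gaussian precision-matrix oracle", {
  expect_equal(partial_corr_matrix(matrix(c(1, 0.5, 0.5, 1), 2),
                                   c(0.5, 0.5))[1, 2], 1 / 3)
  expect_equal(partial_corr_matrix(matrix(c(1, 0.35, 0.35, 1), 2),
                                   c(0.7, 0.5))[1, 2], 0)
  # two latent factors: compare against the partial correlation computed
  # from the inverse of the full (items + factors) covariance matrix
  set.seed(12)
  d <- 4
  l1 <- runif(d, 0.3, 0.7); l2 <- runif(d, 0.2, 0.5)
  P <- diag(d)
  P[1, 2] <- P[2, 1] <- 0.4; P[3, 4] <- P[4, 3] <- -0.3
  # build item correlations from the 2-factor + residual structure
  s1 <- sqrt(1 - l1^2); s2 <- sqrt(1 - l2^2)
  R <- outer(l1, l1) + outer(l2, l2) * outer(s1, s1) +
    P * outer(s1, s1) * outer(s2, s2)
  diag(R) <- 1
  # full covariance of (items, F1, F2): items = l1 F1 + s1 l2 F2 + resid
  S <- matrix(0, d + 2, d + 2)
  S[1:d, 1:d] <- R
  S[1:d, d + 1] <- S[d + 1, 1:d] <- l1
  S[1:d, d + 2] <- S[d + 2, 1:d] <- l2 * s1
  S[d + 1, d + 1] <- S[d + 2, d + 2] <- 1
  Q <- solve(S)
  oracle <- -Q[1:d, 1:d] / sqrt(outer(diag(Q)[1:d], diag(Q)[1:d]))
  diag(oracle) <- 1
  got <- partial_corr_matrix(R, l1, l2)
  expect_equal(got[upper.tri(got)], oracle[upper.tri(oracle)],
               tolerance = 1e-10)
})

test_that("Prim spanning tree equals brute force over Pruefer trees", {
  # dominance example
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.9; R[1, 3] <- R[3, 1] <- 0.5
  R[2, 3] <- R[3, 2] <- 0.1
  expect_equal(max_spanning_tree(R), rbind(c(1L, 2L), c(1L, 3L)))
  trees5 <- all_spanning_trees(5)
  expect_length(trees5, 125)
  set.seed(99)
  for (rep in 1:30) {
    r <- runif(10, -0.9, 0.9)
    R <- diag(5); R[upper.tri(R)] <- r; R <- pmax(R, t(R))
    R[lower.tri(R)] <- t(R)[lower.tri(R)]
    got <- max_spanning_tree(R)
    expect_equal(nrow(got), 4)
    best <- min(vapply(trees5, tree_weight, 0, R = R))
    expect_equal(tree_weight(got, R), best, tolerance = 1e-12)
  }
})

test_that("implied correlation matrix follows the normal-ogive formulas", {
  cp2 <- cutpoints(rep(list(c(0.3, 0.7)), 2))
  m <- factor_tree_model(1, cp2, "bvn", c(0.8, 0.6))
  expect_equal(implied_corr_matrix(m)[1, 2], 0.48)
  # non-adjacent pair: product of edge partials along the path, then
  # back-transformed through the factor loadings
  cp3 <- toy_cutpoints3()
  m3 <- factor_tree_model(1, cp3, "bvn", c(0.5, 0.6, 0.7),
                          edges = rbind(c(1L, 2L), c(2L, 3L)),
                          vine_family = "bvn", vine_theta = c(0.5, 0.4))
  R <- implied_corr_matrix(m3)
  pcond <- 0.5 * 0.4
  expect_equal(R[1, 3],
               0.5 * 0.7 + pcond * sqrt((1 - 0.25) * (1 - 0.49)))
  # simulation oracle for an adjacent pair
  y <- simulate(m3, nsim = 4e4, seed = 3)
  expect_equal(polychoric_matrix(y)[1, 2], R[1, 2], tolerance = 0.02)
  expect_error(implied_corr_matrix(
    factor_tree_model(1, cp2, "gumbel", c(2, 2))), "BVN")
})

test_that("discrepancy measures are zero at equality and positive off it", {
  R <- diag(4); R[upper.tri(R)] <- 0.3; R[lower.tri(R)] <- 0.3
  expect_equal(unname(discrepancies(R, R)), c(0, 0, 0))
  expect_equal(unname(discrepancies(diag(4), diag(4))), c(0, 0, 0))
  set.seed(4)
  for (i in 1:10) {
    A <- cov2cor(crossprod(matrix(rnorm(25), 5)))
    B <- cov2cor(crossprod(matrix(rnorm(25), 5)))
    expect_gt(discrepancies(A, B)[["D3"]], 0)
  }
})

test_that("Vuong interval matches hand-computed statistics", {
  Di <- c(0.1, -0.1, 0.3, -0.3)
  s <- sqrt(sum((Di - mean(Di))^2) / 3)
  v <- ftcopula:::vuong_stats(Di, npar_diff = 0)
  expect_equal(v$dbar, 0)
  expect_equal(v$s, s)
  expect_equal(v$ci, c(-1.96, 1.96) * s / 2)
  v2 <- ftcopula:::vuong_stats(Di, npar_diff = 4)
  expect_equal(v2$ci, -1 + c(-1.96, 1.96) * s / 2)
  expect_equal(v2$favored, 1L)
})

test_that("identical models give a Vuong interval centred on the penalty", {
  cp <- toy_cutpoints3()
  m <- factor_tree_model(1, cp, "gumbel", rep(1.8, 3))
  y <- simulate(m, nsim = 300, seed = 8)
  skel <- m; skel$th1[] <- NA
  f <- fit_ifm(y, skel, se = FALSE)
  v <- vuong_interval(f, f, y)
  expect_equal(v$dbar, 0)
  expect_equal(mean(v$ci), 0)
  expect_equal(v$favored, 0L)
})

test_that("family selection picks the only candidate and logs a trace", {
  fx <- generate_fixture("table3-d8", n = 300, seed = 17)
  sel <- select_families(fx$data, p = 1, candidates_factor = "bvn",
                         candidates_vine = c("bvn", "frank"),
                         tree_alg = "polychoric")
  expect_equal(unname(sel$families["factor1"]), "bvn")
  expect_equal(nrow(sel$edges), 7)
  expect_true(all(c("stage", "family", "loglik", "aic") %in%
                    colnames(sel$trace)))
  # the winner of each stage attains the stage's maximum log-likelihood
  for (st in unique(sel$trace$stage)) {
    rows <- sel$trace[sel$trace$stage == st, ]
    expect_true(any(rows$loglik == max(rows$loglik)))
  }
  # log-likelihood never decreases across stages at the winners
  win <- tapply(sel$trace$loglik, sel$trace$stage, max)
  expect_true(all(diff(win[c("factor1", "vine")]) >= -1e-6))
})

test_that("semi-correlations detect reflection asymmetry in the data", {
  cp <- toy_cutpoints5(6)
  th <- vapply(seq(0.6, 0.45, length.out = 6),
               function(t) tau_to_par("gumbel", t)$theta, 0)
  mg <- factor_tree_model(1, cp, "gumbel", th)
  yg <- simulate(mg, nsim = 3000, seed = 14)
  sg <- semicorrelations(yg)
  expect_gt(sg$average[["rho_plus"]], sg$average[["rho_minus"]])
  mb <- factor_tree_model(1, cp, "bvn",
                          vapply(seq(0.6, 0.45, length.out = 6),
                                 function(t) tau_to_par("bvn", t)$theta, 0))
  yb <- simulate(mb, nsim = 3000, seed = 15)
  sb <- semicorrelations(yb)
  expect_lt(abs(sb$average[["rho_plus"]] - sb$average[["rho_minus"]]), 0.12)
})
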