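# Bivariate copula families: bounds, h-functions, reflection, tau maps,
# normal-scores summaries.

fam_grid <- list(
  list(f = "bvn", th = c(-0.9, -0.5, 0, 0.5, 0.9)),
  list(f = "t", th = c(-0.9, -0.3, 0.2, 0.6, 0.95), nu = 5),
  list(f = "t", th = c(-0.8, 0.5), nu = 2),
  list(f = "gumbel", th = c(1, 1.3, 2, 4, 8)),
  list(f = "sgumbel", th = c(1, 1.5, 2.5, 5, 10)),
  list(f = "frank", th = c(-10, -3, 0.5, 4, 12))
)

spec_of <- function(fg, th) bicop_spec(fg$f, theta = th, nu = fg$nu)

test_that("cdfs respect Frechet bounds and uniform-margin boundaries", {
  u <- seq(0, 1, length.out = 21)
  g <- expand.grid(u = u, v = u)
  for (fg in fam_grid) for (th in fg$th) {
    sp <- spec_of(fg, th)
    C <- pbicop(g$u, g$v, sp)
    expect_true(all(C >= pmax(g$u + g$v - 1, 0) - 1e-9), label = fg$f)
    expect_true(all(C <= pmin(g$u, g$v) + 1e-9), label = fg$f)
    expect_equal(pbicop(u, rep(1, 21), sp), u, tolerance = 1e-8)
    expect_equal(pbicop(rep(1, 21), u, sp), u, tolerance = 1e-8)
    expect_equal(pbicop(u, rep(0, 21), sp), rep(0, 21))
  }
})

test_that("h-functions match the numerical derivative of the cdf", {
  set.seed(42)
  u <- runif(40, 0.02, 0.98); v <- runif(40, 0.02, 0.98)
  eps <- 1e-6
  for (fg in fam_grid) for (th in fg$th) {
    sp <- spec_of(fg, th)
    fd <- (pbicop(u + eps, v, sp) - pbicop(u - eps, v, sp)) / (2 * eps)
    expect_equal(hbicop(v, u, sp), fd, tolerance = 1e-5,
                 label = paste(fg$f, th))
  }
  # boundary values
  sp <- bicop_spec("gumbel", 2)
  expect_equal(hbicop(1, 0.4, sp), 1)
  expect_equal(hbicop(0, 0.4, sp), 0)
  expect_equal(hbicop(0.7, 0.4, bicop_spec("indep")), 0.7)
})

test_that("densities match the numerical derivative of the h-function", {
  set.seed(7)
  u <- runif(25, 0.05, 0.95); v <- runif(25, 0.05, 0.95)
  eps <- 1e-6
  for (fg in fam_grid) for (th in fg$th[c(2, length(fg$th))]) {
    sp <- spec_of(fg, th)
    fd <- (hbicop(v + eps, u, sp) - hbicop(v - eps, u, sp)) / (2 * eps)
    expect_equal(dbicop(u, v, sp), fd, tolerance = 1e-4,
                 label = paste(fg$f, th))
  }
})

test_that("Monte Carlo samplers agree with cdf and tau (Gumbel, Frank)", {
  set.seed(11)
  x <- r_gumbel_pairs(2e5, 2)
  # exact value of C(0.5, 0.5) for theta = 2 is 2^(-sqrt(2)) ~ 0.375
  expect_lt(abs(mean(x[, 1] <= 0.5 & x[, 2] <= 0.5) -
                  pbicop(0.5, 0.5, bicop_spec("gumbel", 2))), 0.005)
  expect_equal(pbicop(0.5, 0.5, bicop_spec("gumbel", 2)), 2^(-sqrt(2)),
               tolerance = 1e-10)
  xf <- r_frank_pairs(2e5, 5)
  expect_lt(abs(mean(xf[, 1] <= 0.3 & xf[, 2] <= 0.6) -
                  pbicop(0.3, 0.6, bicop_spec("frank", 5))), 0.005)
  # concordance-based Kendall tau oracle on a subsample
  sub <- xf[sample(nrow(xf), 4000), ]
  tau_mc <- cor(sub[, 1], sub[, 2], method = "kendall")
  expect_lt(abs(par_to_tau(bicop_spec("frank", 5)) - tau_mc), 0.04)
})

test_that("reflection satisfies the survival-copula identity", {
  u <- seq(0.05, 0.95, by = 0.15)
  g <- expand.grid(u = u, v = u)
  sp <- bicop_spec("gumbel", 2.5)
  rsp <- reflect_bicop(sp)
  expect_identical(rsp$family, "sgumbel")
  expect_equal(pbicop(g$u, g$v, rsp),
               g$u + g$v - 1 + pbicop(1 - g$u, 1 - g$v, sp),
               tolerance = 1e-12)
  # reflection-symmetric families are fixed points; reflection is an
  # involution
  for (lab in list(c("bvn", 0.5), c("frank", 4))) {
    sp <- bicop_spec(lab[1], as.numeric(lab[2]))
    expect_equal(pbicop(g$u, g$v, reflect_bicop(sp)),
                 g$u + g$v - 1 + pbicop(1 - g$u, 1 - g$v, sp),
                 tolerance = 1e-10)
  }
  expect_equal(pbicop(g$u, g$v, reflect_bicop(reflect_bicop(sp))),
               pbicop(g$u, g$v, sp))
})

test_that("tau maps have the stated closed forms and round trip", {
  expect_equal(par_to_tau(bicop_spec("gumbel", 2)), 0.5)
  expect_equal(par_to_tau(bicop_spec("bvn", 0.5)), 1 / 3)
  expect_equal(tau_to_par("gumbel", 0.7)$theta, 10 / 3)
  expect_equal(tau_to_par("t", 0, nu = 3)$theta, 0)
  for (fam in c("bvn", "t", "frank")) {
    for (tau in c(-0.8, -0.3, 0.2, 0.6, 0.9)) {
      sp <- tau_to_par(fam, tau, nu = 3)
      tol <- if (fam == "frank") 1e-7 else 1e-10
      expect_equal(par_to_tau(sp), tau, tolerance = tol,
                   label = paste(fam, tau))
    }
  }
  for (tau in c(0.05, 0.4, 0.9))
    expect_equal(par_to_tau(tau_to_par("gumbel", tau)), tau,
                 tolerance = 1e-12)
  expect_error(tau_to_par("gumbel", -0.2), "tau")
})

test_that("parameter domains are enforced with informative errors", {
  expect_error(bicop_spec("bvn", 1.5), "\\[-1, 1\\]")
  expect_error(bicop_spec("gumbel", 0.8), ">= 1")
  expect_error(bicop_spec("frank", 0), "indep")
  expect_error(bicop_spec("t", 0.5, nu = -1), "nu")
  expect_error(parse_family("clayton"), "unknown")
})

test_that("normal-scores correlation and semi-correlations behave", {
  expect_equal(unname(normal_scores_corr(bicop_spec("indep"))),
               c(0, 0, 0))
  # BVN normal scores are exactly BVN
  ns <- normal_scores_corr(bicop_spec("bvn", 0.35))
  expect_equal(ns[["rho"]], 0.35, tolerance = 1e-4)
  # reflection symmetry => equal semi-correlations
  for (sp in list(bicop_spec("bvn", 0.5), bicop_spec("t", 0.5, nu = 5),
                  bicop_spec("frank", 4))) {
    ns <- normal_scores_corr(sp)
    expect_equal(ns[["rho_minus"]], ns[["rho_plus"]], tolerance = 1e-4)
  }
  nsg <- normal_scores_corr(bicop_spec("gumbel", 1.7))
  expect_lt(nsg[["rho_minus"]], nsg[["rho_plus"]])
  nss <- normal_scores_corr(bicop_spec("sgumbel", 1.7))
  expect_gt(nss[["rho_minus"]], nss[["rho_plus"]])
  # reflection swaps the semi-correlations
  expect_equal(nsg[["rho_minus"]], nss[["rho_plus"]], tolerance = 1e-6)
})

test_that("calibration hits a target normal-scores correlation", {
  expect_equal(calibrate_rhoN("bvn", 0.35)$theta, 0.35)
  expect_equal(calibrate_rhoN("gumbel", 0)$theta, 1)
  for (fam in c("t5", "gumbel", "frank")) {
    sp <- calibrate_rhoN(fam, 0.35)
    expect_equal(normal_scores_corr(sp)[["rho"]], 0.35,
                 tolerance = 1e-4, label = fam)
  }
  expect_error(calibrate_rhoN("gumbel", -0.3), "nonnegative")
})
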