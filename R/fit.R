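# Two-step IFM estimation: cutpoints from univariate proportions, then
# quasi-Newton maximisation of the joint log-likelihood over the
# dependence parameters on unconstrained transforms.

# per-family unconstrained transform eta = g(theta) and inverse
par_transform <- function(family) {
  switch(family,
    bvn = ,
    t = list(to = function(th) atanh(pmin(pmax(th, -0.9985), 0.9985)),
             from = function(e) tanh(e)),
    gumbel = ,
    sgumbel = list(to = function(th) log(pmax(th, 1 + 1e-8) - 1),
                   from = function(e) 1 + exp(pmin(e, 3.9))),
    frank = list(to = function(th) th,
                 from = function(e) pmin(pmax(e, -35), 35)),
    stop("no free parameter for family ", family, call. = FALSE))
}

default_start_tau <- function(family, tree) {
  tau <- if (tree == "vine") 0.1 else 0.3
  if (family %in% c("bvn", "t", "frank", "gumbel", "sgumbel")) tau else 0
}

start_theta <- function(f, th, tree, len) {
  if (!length(th)) th <- rep(NA_real_, len)
  nas <- is.na(th)
  if (any(nas)) {
    tau0 <- default_start_tau(f$family, tree)
    th[nas] <- tau_to_par(f$family, tau0, nu = f$nu)$theta
  }
  th
}

# data-driven starting values for the residual-tree parameters: partial
# polychoric correlations given the fitted factor(s), mapped to the edge
# family through Kendall's tau (arcsine relation on the Gaussian scale)
vine_start_theta <- function(y, model, pre_fit) {
  taus <- model_taus(pre_fit$model)
  load1 <- sin(pi / 2 * taus$tree1)
  load2 <- if (model$p == 2) sin(pi / 2 * taus$tree2)
  P <- tryCatch(
    partial_corr_matrix(polychoric_matrix(y), load1, load2),
    error = function(e) NULL)
  fam <- model$fv$family
  fallback <- tau_to_par(fam, 0.1, nu = model$fv$nu)$theta
  if (is.null(P)) return(rep(fallback, nrow(model$edges)))
  vapply(seq_len(nrow(model$edges)), function(e) {
    r <- P[model$edges[e, 1], model$edges[e, 2]]
    tau <- 2 / pi * asin(max(min(r, 0.95), -0.95))
    tau <- switch(fam,
                  gumbel = , sgumbel = max(min(tau, 0.9), 0.01),
                  frank = if (abs(tau) < 0.01) 0.01 else
                    max(min(tau, 0.9), -0.9),
                  max(min(tau, 0.9), -0.9))
    tau_to_par(fam, tau, nu = model$fv$nu)$theta
  }, 0)
}

# number of free dependence parameters; the all-BVN two-factor model
# fixes one factor-2 parameter at zero for identifiability
n_dependence_params <- function(model) {
  np <- 0L
  if (model$p >= 1) np <- np + model$d
  if (model$p == 2) {
    np <- np + model$d
    if (model$f1$family == "bvn" && model$f2$family == "bvn") np <- np - 1L
  }
  np + nrow(model$edges)
}

# pack/unpack free parameters <-> model; returns closures over the layout
param_layout <- function(model) {
  d <- model$d; m <- nrow(model$edges)
  fix21 <- model$p == 2 && model$f1$family == "bvn" &&
    model$f2$family == "bvn"
  t1 <- if (model$p >= 1) par_transform(model$f1$family)
  t2 <- if (model$p == 2) par_transform(model$f2$family)
  tv <- if (m > 0 && model$fv$family != "indep")
    par_transform(model$fv$family)
  pack <- function(mod) {
    eta <- numeric(0)
    if (mod$p >= 1) eta <- c(eta, t1$to(mod$th1))
    if (mod$p == 2) {
      th2 <- mod$th2
      if (fix21) th2 <- th2[-1]
      eta <- c(eta, t2$to(th2))
    }
    if (!is.null(tv)) eta <- c(eta, tv$to(mod$thv))
    eta
  }
  unpack <- function(eta, mod) {
    i <- 0L
    if (mod$p >= 1) { mod$th1 <- t1$from(eta[i + seq_len(d)]); i <- i + d }
    if (mod$p == 2) {
      k <- d - fix21
      th2 <- t2$from(eta[i + seq_len(k)]); i <- i + k
      mod$th2 <- if (fix21) c(0, th2) else th2
    }
    if (!is.null(tv)) mod$thv <- tv$from(eta[i + seq_len(m)])
    mod
  }
  list(pack = pack, unpack = unpack, fix21 = fix21)
}

#' Fit a factor tree copula model by the two-step IFM method
#'
#' Step 1 estimates the cutpoints by univariate cumulative sample
#' proportions ([estimate_cutpoints()]); step 2 maximises the joint
#' log-likelihood over the dependence parameters with the cutpoints held
#' fixed, using BFGS on unconstrained transforms (`atanh` for BVN/t,
#' `log(theta - 1)` for Gumbel-type, identity for Frank).  Start values
#' default to Kendall's tau 0.3 for factor trees and 0.1 for residual
#' edges.  For the all-BVN two-factor model one factor-2 parameter is
#' fixed at zero for identifiability, as in the bidimensional normal
#' ogive model.
#'
#' @param data an [ordinal_data()] object or integer matrix.
#' @param skeleton a [factor_tree_model()] fixing factors, families and
#'   edge set; `NA` parameters are replaced by default starts, finite
#'   values are used as starting points.
#' @param nq quadrature size per latent dimension.
#' @param se compute standard errors from the inverse observed Hessian
#'   (delta-method transformed to the tau scale)?  These ignore step-1
#'   cutpoint uncertainty and are therefore approximate.
#' @param control passed to [stats::optim()] (`maxit` defaults to 500).
#' @param warm_start when the model has both a factor part and a
#'   residual tree and no starting values were supplied, first fit the
#'   factor-only model and start the joint optimisation from its
#'   estimates.  The joint likelihood has a ridge between strong factor
#'   dependence and the first residual edges on which a cold mid-range
#'   start can be trapped in a local optimum; the warm start avoids it.
#' @return object of class `"ftc_fit"` with elements `model` (estimated),
#'   `loglik`, `npar`, `aic`, `tau` (estimates on the tau scale),
#'   `se_tau`, `converged`, `counts`.
#' @export
fit_ifm <- function(data, skeleton, nq = 25, se = TRUE,
                    control = list(), warm_start = TRUE) {
  y <- ordinal_data(data)
  stopifnot(inherits(skeleton, "factor_tree_model"),
            ncol(y) == skeleton$d)
  model <- skeleton
  model$cutpoints <- estimate_cutpoints(y)
  d <- model$d; m <- nrow(model$edges)
  if (warm_start && model$p >= 1 && m > 0 &&
      !is.null(model$fv) && model$fv$family != "indep" &&
      all(is.na(model$th1))) {
    pre <- model
    pre$edges <- matrix(integer(0), 0, 2)
    pre$fv <- NULL; pre$thv <- numeric(0)
    pre_fit <- fit_ifm(y, pre, nq = nq, se = FALSE, control = control,
                       warm_start = FALSE)
    model$th1 <- pre_fit$model$th1
    if (model$p == 2 && all(is.na(model$th2)))
      model$th2 <- pre_fit$model$th2
    if (all(is.na(model$thv)))
      model$thv <- vine_start_theta(y, model, pre_fit)
  }
  if (model$p >= 1)
    model$th1 <- start_theta(model$f1, model$th1, "factor", d)
  if (model$p == 2) {
    model$th2 <- start_theta(model$f2, model$th2, "factor", d)
    if (model$p == 2 && model$f1$family == "bvn" &&
        model$f2$family == "bvn") model$th2[1] <- 0
  }
  pure_vine_free <- m > 0 && !is.null(model$fv) &&
    model$fv$family != "indep"
  if (pure_vine_free)
    model$thv <- start_theta(model$fv, model$thv, "vine", m)
  lay <- param_layout(model)
  eta0 <- lay$pack(model)
  a0 <- model_cpp_args(model, nq)
  ym <- matrix(as.integer(unclass(y)), ncol = d)
  negll <- function(eta) {
    mod <- lay$unpack(eta, model)
    a <- a0
    a$th1 <- if (length(mod$th1)) mod$th1 else a0$th1
    a$th2 <- if (length(mod$th2)) mod$th2 else a0$th2
    a$thv <- mod$thv
    -sum(cpp_logpmf_rows(ym, a$K, a$acuts, a$p, a$fam1, a$th1, a$nu1,
                         a$fam2, a$th2, a$nu2, a$edges, a$famv, a$thv,
                         a$nuv, a$xq, a$wq))
  }
  if (!length(eta0)) {
    # no free dependence parameters (independence-only model)
    ll <- -negll(eta0)
    fit_model <- model
    return(new_ftc_fit(fit_model, ll, 0L, numeric(0), numeric(0), TRUE,
                       c(`function` = 1, gradient = 0), nq))
  }
  ctl <- modifyList(list(maxit = 500, reltol = 1e-10), control)
  opt <- optim(eta0, negll, method = "BFGS", control = ctl)
  fit_model <- lay$unpack(opt$par, model)
  ll <- -opt$value
  npar <- n_dependence_params(fit_model)
  se_tau <- rep(NA_real_, length(opt$par))
  if (se) se_tau <- tau_scale_se(opt$par, negll, lay, fit_model)
  new_ftc_fit(fit_model, ll, npar, opt$par, se_tau,
              opt$convergence == 0, opt$counts, nq)
}

new_ftc_fit <- function(model, ll, npar, eta, se_tau, converged, counts,
                        nq) {
  structure(list(model = model, loglik = ll, npar = npar,
                 aic = -2 * ll + 2 * npar,
                 tau = fit_tau_table(model, se_tau),
                 eta = eta, converged = converged, counts = counts,
                 nq = nq),
            class = "ftc_fit")
}

# numerical Hessian of f at x (central differences)
num_hessian <- function(f, x, h = 1e-4) {
  n <- length(x)
  H <- matrix(NA_real_, n, n)
  f0 <- f(x)
  for (i in seq_len(n)) for (j in i:n) {
    if (i == j) {
      xp <- x; xp[i] <- x[i] + h
      xm <- x; xm[i] <- x[i] - h
      H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h^2
    } else {
      xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + h
      xpm <- x; xpm[i] <- x[i] + h; xpm[j] <- x[j] - h
      xmp <- x; xmp[i] <- x[i] - h; xmp[j] <- x[j] + h
      xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - h
      H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h^2)
    }
  }
  H
}

# delta-method SEs on the Kendall-tau scale from the observed information
# of the transformed parameters
tau_scale_se <- function(eta, negll, lay, model) {
  H <- num_hessian(negll, eta)
  V <- tryCatch(solve(H), error = function(e) NULL)
  n_eta <- length(eta)
  if (is.null(V) || any(!is.finite(diag(V))) || any(diag(V) <= 0))
    return(rep(NA_real_, n_eta))
  # d tau / d eta by central differences through the full map
  taus <- function(ee) unlist(model_taus(lay$unpack(ee, model)))
  h <- 1e-5
  grad <- vapply(seq_len(n_eta), function(i) {
    ep <- eta; ep[i] <- eta[i] + h
    em <- eta; em[i] <- eta[i] - h
    (taus(ep) - taus(em))[free_tau_index(lay, model)][i] / (2 * h)
  }, 0)
  sqrt(diag(V)) * abs(grad)
}

# indices of the free parameters inside the full tau vector
free_tau_index <- function(lay, model) {
  d <- model$d; m <- nrow(model$edges)
  idx <- integer(0)
  off <- 0L
  if (model$p >= 1) { idx <- c(idx, off + seq_len(d)); off <- off + d }
  if (model$p == 2) {
    i2 <- off + seq_len(d)
    if (lay$fix21) i2 <- i2[-1]
    idx <- c(idx, i2); off <- off + d
  }
  if (m > 0 && model$fv$family != "indep") idx <- c(idx, off + seq_len(m))
  idx
}

model_taus <- function(model) {
  out <- list()
  if (model$p >= 1)
    out$tree1 <- vapply(model$th1, function(th)
      par_to_tau(bicop_spec(model$f1$family, th, model$f1$nu)), 0)
  if (model$p == 2)
    out$tree2 <- vapply(model$th2, function(th)
      if (th == 0 && model$f2$family == "bvn") 0 else
        par_to_tau(bicop_spec(model$f2$family, th, model$f2$nu)), 0)
  if (nrow(model$edges) > 0 && model$fv$family != "indep")
    out$vine <- vapply(model$thv, function(th)
      par_to_tau(bicop_spec(model$fv$family, th, model$fv$nu)), 0)
  out
}

fit_tau_table <- function(model, se_tau) {
  taus <- model_taus(model)
  rows <- list()
  if (!is.null(taus$tree1))
    rows$t1 <- data.frame(tree = "factor1",
                          item = seq_len(model$d), edge = NA_character_,
                          family = model$f1$family, theta = model$th1,
                          tau = taus$tree1)
  if (!is.null(taus$tree2))
    rows$t2 <- data.frame(tree = "factor2",
                          item = seq_len(model$d), edge = NA_character_,
                          family = model$f2$family, theta = model$th2,
                          tau = taus$tree2)
  if (!is.null(taus$vine))
    rows$tv <- data.frame(tree = "vine", item = NA_integer_,
                          edge = paste(model$edges[, 1], model$edges[, 2],
                                       sep = "-"),
                          family = model$fv$family, theta = model$thv,
                          tau = taus$vine)
  tab <- do.call(rbind, rows)
  if (is.null(tab)) return(NULL)
  rownames(tab) <- NULL
  tab$se_tau <- NA_real_
  # free-parameter SEs align with the packed order; the fixed factor-2
  # parameter (all-BVN identification) keeps NA
  free <- rep(TRUE, nrow(tab))
  if (!is.null(taus$tree2) && model$f1$family == "bvn" &&
      model$f2$family == "bvn")
    free[model$d + 1L] <- FALSE
  if (!is.null(taus$vine) && model$fv$family == "indep")
    free[tab$tree == "vine"] <- FALSE
  if (length(se_tau) == sum(free)) tab$se_tau[free] <- se_tau
  tab
}

#' @export
print.ftc_fit <- function(x, digits = 3, ...) {
  print(x$model)
  cat(sprintf("loglik = %.2f on %d dependence parameters; AIC = %.1f\n",
              x$loglik, x$npar, x$aic))
  if (!x$converged) cat("WARNING: optimiser did not report convergence\n")
  if (!is.null(x$tau)) {
    tab <- x$tau
    tab$theta <- round(tab$theta, digits)
    tab$tau <- round(tab$tau, digits)
    tab$se_tau <- round(tab$se_tau, digits)
    print(tab)
  }
  invisible(x)
}

#' @export
logLik.ftc_fit <- function(object, ...) {
  structure(object$loglik, df = object$npar, class = "logLik")
}

#' Akaike information criterion of a fitted factor tree copula model
#'
#' `-2 loglik + 2 npar`, where `npar` counts only dependence parameters:
#' d per factor tree (minus one for the all-BVN two-factor model, whose
#' extra parameter is fixed at zero), plus one per residual-tree edge;
#' the t degrees of freedom come from a fixed grid and are not counted.
#'
#' @param fit an `"ftc_fit"` object.
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "ftc_fit"))
  fit$aic
}
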