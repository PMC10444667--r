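# Factor tree copula model objects and their probability mass function.

#' Gauss-Legendre quadrature on (0, 1)
#'
#' Standard Gauss-Legendre nodes and weights affinely mapped from
#' (-1, 1) to (0, 1); weights sum to one and the rule integrates
#' polynomials of degree up to `2 nq - 1` exactly.  Used to integrate
#' out the standard-uniform latent factors.
#'
#' @param nq number of quadrature points (default 25, which is accurate
#'   to well below 1e-5 for the models considered here).
#' @return list with `nodes` and `weights`.
#' @export
gauss_legendre_01 <- function(nq = 25) {
  if (!is.numeric(nq) || nq < 1) stop("nq must be a positive integer",
                                      call. = FALSE)
  nq <- as.integer(nq)
  if (nq == 1L) return(list(nodes = 0.5, weights = 1))
  g <- pracma::gaussLegendre(nq, 0, 1)
  list(nodes = g$x, weights = g$w)
}

tree_spec <- function(family, nu = NULL) {
  if (is.null(family)) return(NULL)
  pf <- parse_family(family)
  if (is.null(nu) && !is.na(pf$nu)) nu <- pf$nu
  if (pf$family == "t" && is.null(nu))
    stop("t family requires degrees of freedom", call. = FALSE)
  list(family = pf$family, code = fam_code(pf$family),
       nu = if (pf$family == "t") nu else NA_real_)
}

#' Factor tree copula model
#'
#' Specifies a combined factor/truncated-vine copula model for ordinal
#' items: `p` in \{0, 1, 2\} standard-uniform latent factors linked to the
#' items by one bivariate copula family per factor tree, plus an optional
#' Markov tree (1-truncated vine) of conditional bivariate copulas on
#' `d - 1` item pairs capturing residual dependence given the factors.
#' With `p = 0` and a nonempty edge set the model is a plain Markov-tree
#' (1-truncated vine) model; with an empty edge set it is the ordinary
#' 1- or 2-factor copula model.  One family is used per tree (families
#' are not mixed within a tree, which keeps the trees interpretable).
#'
#' @param p number of latent factors (0, 1 or 2).
#' @param cutpoints a [cutpoints()] object (or `NULL` for a skeleton to
#'   be completed by [fit_ifm()]).
#' @param tree1_family,tree1_theta family label and length-d parameter
#'   vector for the item-factor1 copulas (p >= 1).
#' @param tree2_family,tree2_theta same for factor 2 (p = 2).
#' @param edges integer matrix (m x 2, 1-based item indices) of Markov
#'   tree edges, or `NULL`/0-row for no residual tree.  A nonempty edge
#'   set must be a spanning tree on the d items.
#' @param vine_family,vine_theta family label and length-m parameter
#'   vector for the conditional edge copulas.
#' @param tree1_nu,tree2_nu,vine_nu degrees of freedom when the
#'   respective family is Student-t (labels like "t5" set them directly).
#' @param d number of items (required when `cutpoints` is `NULL`).
#' @return object of class `"factor_tree_model"`.
#' @examples
#' cp <- cutpoints(rep(list(c(0.2, 0.4, 0.6, 0.8)), 4))
#' m <- factor_tree_model(1, cp, "gumbel", rep(2, 4),
#'                        edges = cbind(1:3, 2:4),
#'                        vine_family = "frank", vine_theta = rep(2, 3))
#' @export
factor_tree_model <- function(p, cutpoints = NULL,
                              tree1_family = NULL, tree1_theta = NULL,
                              tree2_family = NULL, tree2_theta = NULL,
                              edges = NULL,
                              vine_family = NULL, vine_theta = NULL,
                              tree1_nu = NULL, tree2_nu = NULL,
                              vine_nu = NULL, d = NULL) {
  stopifnot(p %in% 0:2)
  if (!is.null(cutpoints)) {
    stopifnot(inherits(cutpoints, "cutpoints"))
    d <- length(cutpoints$a)
  } else if (is.null(d)) {
    stop("supply either cutpoints or the item count d", call. = FALSE)
  }
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(integer(0), 0, 2)
  } else {
    edges <- matrix(as.integer(edges), ncol = 2)
    check_spanning_tree(edges, d)
  }
  m <- nrow(edges)
  if (p == 0 && m == 0)
    message("p = 0 with no edges: model degenerates to independent items")
  f1 <- f2 <- fv <- NULL
  if (p >= 1) {
    f1 <- tree_spec(tree1_family, tree1_nu)
    if (is.null(f1)) stop("p >= 1 requires tree1_family", call. = FALSE)
    if (is.null(tree1_theta)) tree1_theta <- rep(NA_real_, d)
    stopifnot(length(tree1_theta) == d)
  }
  if (p == 2) {
    f2 <- tree_spec(tree2_family, tree2_nu)
    if (is.null(f2)) stop("p = 2 requires tree2_family", call. = FALSE)
    if (is.null(tree2_theta)) tree2_theta <- rep(NA_real_, d)
    stopifnot(length(tree2_theta) == d)
  }
  if (m > 0) {
    fv <- tree_spec(vine_family, vine_nu)
    if (is.null(fv)) stop("edges supplied but no vine_family", call. = FALSE)
    if (is.null(vine_theta)) vine_theta <- rep(NA_real_, m)
    stopifnot(length(vine_theta) == m)
  }
  check_theta <- function(fam, th, what) {
    th <- th[!is.na(th)]
    if (!length(th)) return(invisible())
    ok <- switch(fam,
      indep = TRUE,
      bvn = , t = all(abs(th) <= 1),
      gumbel = , sgumbel = all(th >= 1),
      frank = all(th != 0))
    if (!ok) stop("parameters of ", what, " (", fam,
                  ") outside the family domain", call. = FALSE)
  }
  if (!is.null(f1)) check_theta(f1$family, tree1_theta, "factor tree 1")
  if (!is.null(f2)) check_theta(f2$family, tree2_theta, "factor tree 2")
  if (!is.null(fv) && fv$family != "indep")
    check_theta(fv$family, vine_theta, "the residual tree")
  structure(list(p = p, d = d, cutpoints = cutpoints,
                 f1 = f1, th1 = as.numeric(tree1_theta %||% numeric(0)),
                 f2 = f2, th2 = as.numeric(tree2_theta %||% numeric(0)),
                 edges = edges, fv = fv,
                 thv = as.numeric(vine_theta %||% numeric(0))),
            class = "factor_tree_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_spanning_tree <- function(edges, d) {
  if (any(edges < 1L | edges > d))
    stop("edge indices must lie in 1..d", call. = FALSE)
  if (any(edges[, 1] == edges[, 2]))
    stop("self-loop in edge set", call. = FALSE)
  if (nrow(edges) != d - 1L)
    stop("a nonempty residual tree needs exactly d - 1 edges",
         call. = FALSE)
  # union-find acyclicity/connectivity check
  parent <- seq_len(d)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    if (a == b) stop("edge set contains a cycle", call. = FALSE)
    parent[a] <- b
  }
  invisible(TRUE)
}

#' @export
print.factor_tree_model <- function(x, ...) {
  fam_lab <- function(f) {
    if (is.null(f)) return("-")
    if (f$family == "t") sprintf("t%g", f$nu) else f$family
  }
  cat(sprintf("factor tree copula model: d = %d items, p = %d factor(s)\n",
              x$d, x$p))
  if (x$p >= 1) cat("  factor tree 1:", fam_lab(x$f1), "\n")
  if (x$p == 2) cat("  factor tree 2:", fam_lab(x$f2), "\n")
  if (nrow(x$edges))
    cat(sprintf("  residual Markov tree: %d edges, %s copulas\n",
                nrow(x$edges), fam_lab(x$fv)))
  else cat("  no residual tree (pure factor model)\n")
  invisible(x)
}

model_cpp_args <- function(model, nq) {
  if (is.null(model$cutpoints))
    stop("model has no cutpoints; fit or attach them first", call. = FALSE)
  rule <- gauss_legendre_01(nq)
  list(K = as.integer(model$cutpoints$K),
       acuts = model$cutpoints$a,
       p = as.integer(model$p),
       fam1 = if (is.null(model$f1)) 0L else model$f1$code,
       th1 = if (length(model$th1)) model$th1 else rep(0, model$d),
       nu1 = if (!is.null(model$f1) && !is.na(model$f1$nu)) model$f1$nu else 5,
       fam2 = if (is.null(model$f2)) 0L else model$f2$code,
       th2 = if (length(model$th2)) model$th2 else rep(0, model$d),
       nu2 = if (!is.null(model$f2) && !is.na(model$f2$nu)) model$f2$nu else 5,
       edges = matrix(as.integer(model$edges - 1L), ncol = 2),
       famv = if (is.null(model$fv)) 0L else model$fv$code,
       thv = if (length(model$thv)) model$thv else numeric(0),
       nuv = rep(if (!is.null(model$fv) && !is.na(model$fv$nu))
                   model$fv$nu else 5,
                 nrow(model$edges)),
       xq = rule$nodes, wq = rule$weights)
}

#' Log probability mass per response row
#'
#' Evaluates the model's joint pmf at each row of `y` on the log scale.
#' The latent factors are integrated out by Gauss-Legendre quadrature
#' with `nq` points per factor (a double sum for two factors); with no
#' factors the Markov-tree pmf is evaluated directly.
#'
#' @param y response matrix/vector with categories in 0..K_j - 1.
#' @param model a [factor_tree_model()].
#' @param nq quadrature size per latent dimension.
#' @return numeric vector of log pmf values.
#' @export
logpmf_rows <- function(y, model, nq = 25) {
  stopifnot(inherits(model, "factor_tree_model"))
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  y <- matrix(as.integer(y), ncol = model$d)
  K <- model$cutpoints$K
  for (j in seq_len(model$d))
    if (any(y[, j] < 0L | y[, j] >= K[j]))
      stop("responses of item ", j, " outside 0..", K[j] - 1, call. = FALSE)
  a <- model_cpp_args(model, nq)
  cpp_logpmf_rows(y, a$K, a$acuts, a$p, a$fam1, a$th1, a$nu1,
                  a$fam2, a$th2, a$nu2, a$edges, a$famv, a$thv, a$nuv,
                  a$xq, a$wq)
}

#' Joint probability mass function of a factor tree copula model
#'
#' @inheritParams logpmf_rows
#' @return vector of pmf values, one per row of `y`.
#' @export
model_pmf <- function(y, model, nq = 25) exp(logpmf_rows(y, model, nq))

#' Joint log-likelihood of ordinal data under a factor tree copula model
#'
#' The sum over rows of the log joint pmf, the objective maximised in the
#' second IFM step.
#'
#' @param data an [ordinal_data()] object or integer matrix.
#' @param model a [factor_tree_model()].
#' @param nq quadrature size per latent dimension.
#' @export
loglik <- function(data, model, nq = 25) {
  y <- if (inherits(data, "ordinal_data")) unclass(data) else
    as.matrix(data)
  ll <- logpmf_rows(y, model, nq)
  if (any(!is.finite(ll)))
    stop("non-finite log pmf at row ", which(!is.finite(ll))[1],
         call. = FALSE)
  sum(ll)
}

# ---- single-item / single-pair conditional quantities ------------------

item_spec <- function(model, j, tree = 1) {
  f <- if (tree == 1) model$f1 else model$f2
  th <- if (tree == 1) model$th1[j] else model$th2[j]
  if (f$family == "indep") bicop_spec("indep")
  else bicop_spec(f$family, theta = th, nu = f$nu)
}

#' Conditional cdf of an item given the latent factor(s)
#'
#' With one factor this is the h-function of the item-factor copula
#' evaluated at the cutpoint, `Pr(Y_j <= y | X1 = x1)`; with two factors
#' the factor-2 h-function is applied on top,
#' `Pr(Y_j <= y | X1 = x1, X2 = x2)`.  `y = -1` returns 0 and the top
#' category returns 1.
#'
#' @param model a [factor_tree_model()].
#' @param j item index (1-based).
#' @param y category (vectorised), -1..K_j - 1.
#' @param x1,x2 latent values in (0, 1); `x2` only for p = 2.
#' @export
item_cond_cdf <- function(model, j, y, x1, x2 = NULL) {
  stopifnot(j >= 1, j <= model$d, model$p >= 1)
  a <- model$cutpoints$a[[j]]
  F1 <- hbicop(a[y + 2L], x1, item_spec(model, j, 1))
  F1[y + 2L == 1L] <- 0; F1[y + 2L == length(a)] <- 1
  if (model$p == 1) {
    if (!is.null(x2)) stop("x2 supplied but the model has one factor",
                           call. = FALSE)
    return(F1)
  }
  if (is.null(x2)) stop("two-factor model requires x2", call. = FALSE)
  F2 <- hbicop(F1, x2, item_spec(model, j, 2))
  F2[y + 2L == 1L] <- 0; F2[y + 2L == length(a)] <- 1
  F2
}

#' Item characteristic curve of a factor (tree) copula model
#'
#' The conditional probability of each category given the latent
#' factor(s): the difference of [item_cond_cdf()] at `y` and `y - 1`.
#'
#' @inheritParams item_cond_cdf
#' @export
item_icc <- function(model, j, y, x1, x2 = NULL) {
  pmax(item_cond_cdf(model, j, y, x1, x2) -
         item_cond_cdf(model, j, y - 1L, x1, x2), 0)
}

#' Conditional pair pmf on a Markov-tree edge
#'
#' The rectangle probability of the edge copula applied to the items'
#' conditional cdfs given the factor(s),
#' `Pr(Y_j = y_j, Y_k = y_k | X = x)`.  Tiny negative values arising from
#' floating-point cancellation are clipped to zero.
#'
#' @param model a [factor_tree_model()] with a nonempty edge set.
#' @param edge length-2 vector (j, k); must be an edge of the tree.
#' @param yj,yk categories.
#' @param x1,x2 latent values.
#' @export
pair_pmf_cond <- function(model, edge, yj, yk, x1, x2 = NULL) {
  e <- which(model$edges[, 1] == edge[1] & model$edges[, 2] == edge[2] |
               model$edges[, 1] == edge[2] & model$edges[, 2] == edge[1])
  if (!length(e)) stop("pair (", edge[1], ", ", edge[2],
                       ") is not an edge of the residual tree",
                       call. = FALSE)
  e <- e[1]
  j <- model$edges[e, 1]; k <- model$edges[e, 2]
  if (all(edge == c(model$edges[e, 2], model$edges[e, 1]))) {
    tmp <- yj; yj <- yk; yk <- tmp
  }
  sp <- bicop_spec(model$fv$family, theta = model$thv[e], nu = model$fv$nu)
  if (model$p == 0) {
    Fj <- function(y) model$cutpoints$a[[j]][y + 2L]
    Fk <- function(y) model$cutpoints$a[[k]][y + 2L]
  } else {
    Fj <- function(y) item_cond_cdf(model, j, y, x1, x2)
    Fk <- function(y) item_cond_cdf(model, k, y, x1, x2)
  }
  rect <- pbicop(Fj(yj), Fk(yk), sp) - pbicop(Fj(yj - 1L), Fk(yk), sp) -
    pbicop(Fj(yj), Fk(yk - 1L), sp) + pbicop(Fj(yj - 1L), Fk(yk - 1L), sp)
  pmax(rect, 0)
}
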