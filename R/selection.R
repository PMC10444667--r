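# Polychoric machinery, spanning-tree structure selection, sequential
# copula-family selection, discrepancy measures and Vuong comparison.

# two-stage polychoric ML on a contingency table: cutpoints fixed at the
# table's cumulative margins, then scalar maximisation over rho
polychoric_table <- function(tab) {
  tab <- as.matrix(tab)
  keep_r <- rowSums(tab) > 0; keep_c <- colSums(tab) > 0
  tab <- tab[keep_r, keep_c, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(NA_real_)
  n <- sum(tab)
  aj <- qnorm(c(0, cumsum(rowSums(tab)) / n))
  ak <- qnorm(c(0, cumsum(colSums(tab)) / n))
  aj[1] <- -Inf; ak[1] <- -Inf
  aj[length(aj)] <- Inf; ak[length(ak)] <- Inf
  Kj <- nrow(tab); Kk <- ncol(tab)
  hh <- rep(aj, times = Kk + 1L); kk <- rep(ak, each = Kj + 1L)
  negll <- function(rho) {
    G <- matrix(cpp_pbvn(hh, kk, rho), Kj + 1L, Kk + 1L)
    P <- G[-1, -1] - G[-(Kj + 1L), -1] - G[-1, -(Kk + 1L)] +
      G[-(Kj + 1L), -(Kk + 1L)]
    -sum(tab * log(pmax(P, 1e-12)))
  }
  opt <- optimize(negll, c(-0.999, 0.999), tol = 1e-7)
  rho <- opt$minimum
  if (abs(rho) > 0.998) {
    warning("polychoric correlation at boundary; clipped to ",
            sign(rho) * 0.999, call. = FALSE)
    rho <- sign(rho) * 0.999
  }
  rho
}

#' Polychoric correlation of two ordinal items
#'
#' Two-stage maximum likelihood: the normal-scale cutpoints are fixed at
#' the univariate cumulative proportions and the latent bivariate-normal
#' correlation maximises the likelihood of the two-way table of rectangle
#' probabilities.
#'
#' @param yj,yk integer vectors of ordinal responses (0-based).
#' @return the polychoric correlation estimate.
#' @export
polychoric <- function(yj, yk) {
  stopifnot(length(yj) == length(yk))
  polychoric_table(table(factor(yj, levels = 0:max(yj)),
                         factor(yk, levels = 0:max(yk))))
}

#' Polychoric correlation matrix
#'
#' @param data an [ordinal_data()] object or matrix.
#' @return d x d symmetric matrix of pairwise polychoric correlations.
#' @export
polychoric_matrix <- function(data) {
  y <- ordinal_data(data)
  d <- ncol(y)
  R <- diag(d)
  for (j in seq_len(d - 1)) for (k in (j + 1):d)
    R[j, k] <- R[k, j] <- polychoric(y[, j], y[, k])
  dimnames(R) <- list(attr(y, "labels"), attr(y, "labels"))
  R
}

#' Average polychoric correlation and semi-correlations
#'
#' For every pair of items computes the polychoric correlation, and the
#' lower/upper polychoric semi-correlations: each item is dichotomised at
#' the cutpoint whose normal-scale image is closest to zero, and the
#' polychoric correlation is recomputed on the joint-lower (both items
#' below) and joint-upper sub-tables with cutpoints renormalised to the
#' sub-sample.  Pairs with a degenerate sub-table are skipped with a
#' warning.  An excess of `rho_plus` over `rho_minus` indicates more
#' dependence in the joint upper tail than a discretised multivariate
#' normal would give.
#'
#' @param data an [ordinal_data()] object or matrix.
#' @return list with `average` (named vector rho, rho_minus, rho_plus)
#'   and the per-pair matrices `rho`, `rho_minus`, `rho_plus`.
#' @export
semicorrelations <- function(data) {
  y <- ordinal_data(data)
  cp <- estimate_cutpoints(y)
  d <- ncol(y)
  # dichotomisation category: cutpoint closest to 0 on the normal scale
  split <- vapply(seq_len(d), function(j) {
    al <- cp$alpha[[j]]
    which.min(abs(al[-c(1, length(al))]))
  }, 1L)
  R <- Rlo <- Rhi <- matrix(NA_real_, d, d)
  diag(R) <- diag(Rlo) <- diag(Rhi) <- 1
  skipped <- 0L
  for (j in seq_len(d - 1)) for (k in (j + 1):d) {
    R[j, k] <- R[k, j] <- polychoric(y[, j], y[, k])
    lo <- y[, j] < split[j] & y[, k] < split[k]
    hi <- y[, j] >= split[j] & y[, k] >= split[k]
    rlo <- if (sum(lo) >= 10)
      polychoric_table(table(y[lo, j], y[lo, k])) else NA_real_
    rhi <- if (sum(hi) >= 10)
      polychoric_table(table(y[hi, j], y[hi, k])) else NA_real_
    if (is.na(rlo) || is.na(rhi)) skipped <- skipped + 1L
    Rlo[j, k] <- Rlo[k, j] <- rlo
    Rhi[j, k] <- Rhi[k, j] <- rhi
  }
  if (skipped > 0)
    warning(skipped, " pair(s) with a degenerate tail sub-table were ",
            "excluded from the semi-correlation averages", call. = FALSE)
  up <- upper.tri(R)
  list(average = c(rho = mean(R[up], na.rm = TRUE),
                   rho_minus = mean(Rlo[up], na.rm = TRUE),
                   rho_plus = mean(Rhi[up], na.rm = TRUE)),
       rho = R, rho_minus = Rlo, rho_plus = Rhi)
}

#' Partial correlations given one or two latent factors
#'
#' Removes the factor contribution(s) from a correlation matrix using the
#' normal-ogive loadings: level 1 computes
#' `(r_jk - t1_j t1_k) / sqrt((1 - t1_j^2)(1 - t1_k^2))`; level 2 applies
#' the same recursion again with the factor-2 loadings.
#'
#' @param R correlation matrix (e.g. polychoric).
#' @param loadings1 factor-1 loadings (BVN thetas of the 1- or 2-factor
#'   all-BVN model).
#' @param loadings2 factor-2 loadings for level 2, or `NULL`.
#' @return matrix of partial correlations (unit diagonal).
#' @export
partial_corr_matrix <- function(R, loadings1, loadings2 = NULL) {
  d <- nrow(R)
  stopifnot(length(loadings1) == d)
  if (any(abs(loadings1) >= 1) ||
      (!is.null(loadings2) && any(abs(loadings2) >= 1)))
    stop("loadings must satisfy |theta| < 1", call. = FALSE)
  P <- (R - outer(loadings1, loadings1)) /
    sqrt(outer(1 - loadings1^2, 1 - loadings1^2))
  diag(P) <- 1
  if (!is.null(loadings2)) {
    P <- (P - outer(loadings2, loadings2)) /
      sqrt(outer(1 - loadings2^2, 1 - loadings2^2))
    diag(P) <- 1
  }
  P
}

#' Maximum spanning tree of pairwise dependence
#'
#' Finds the spanning tree on the d items minimising
#' `sum(log(1 - r^2))` over tree edges (equivalently maximising the
#' dependence carried by the tree) with Prim's algorithm.  Ties are
#' broken by the lexicographically smallest pair, so the result is
#' deterministic.  A pair with `|r| = 1` gets weight `-Inf` and is
#' forced into the tree with a warning.
#'
#' @param R symmetric matrix of pairwise dependence measures in \[-1, 1\].
#' @return integer matrix (d-1 x 2) of edges, 1-based, j < k per row.
#' @export
max_spanning_tree <- function(R) {
  d <- nrow(R)
  stopifnot(d >= 2, isTRUE(all.equal(R, t(R), tolerance = 1e-8)))
  W <- log(1 - pmin(R^2, 1))
  if (any(is.infinite(W[upper.tri(W)])))
    warning("|r| = 1 for some pair; the edge is forced into the tree",
            call. = FALSE)
  in_tree <- c(TRUE, rep(FALSE, d - 1))
  edges <- matrix(0L, d - 1, 2)
  for (step in seq_len(d - 1)) {
    best <- NULL; best_w <- Inf
    for (j in which(in_tree)) for (k in which(!in_tree)) {
      w <- W[j, k]
      cand <- c(min(j, k), max(j, k))
      if (w < best_w ||
          (w == best_w && (cand[1] < best[1] ||
                           (cand[1] == best[1] && cand[2] < best[2])))) {
        best_w <- w; best <- cand; newk <- k
      }
    }
    edges[step, ] <- best
    in_tree[newk] <- TRUE
  }
  edges
}

#' Correlation matrix implied by an all-BVN factor tree copula model
#'
#' The factor part follows the normal-ogive formulas
#' (`r_jk = t1_j t1_k` for one factor, plus
#' `t2_j t2_k sqrt((1 - t1_j^2)(1 - t1_k^2))` for two).  On the residual
#' Markov tree, the partial correlation of a pair given the factors
#' equals the product of edge parameters along the unique tree path, and
#' is transformed back to the marginal scale through the same recursions.
#'
#' @param model an all-BVN [factor_tree_model()].
#' @return d x d implied correlation matrix.
#' @export
implied_corr_matrix <- function(model) {
  stopifnot(inherits(model, "factor_tree_model"))
  ok <- function(f) is.null(f) || f$family %in% c("bvn", "indep")
  if (!ok(model$f1) || !ok(model$f2) || !ok(model$fv))
    stop("implied correlation matrix is defined for all-BVN models only",
         call. = FALSE)
  d <- model$d
  # conditional (given factors) correlations from tree paths
  Pcond <- diag(d)
  if (nrow(model$edges) > 0 && model$fv$family == "bvn") {
    g <- lapply(seq_len(d), function(j) integer(0))
    wt <- list()
    for (e in seq_len(nrow(model$edges))) {
      j <- model$edges[e, 1]; k <- model$edges[e, 2]
      g[[j]] <- c(g[[j]], k); g[[k]] <- c(g[[k]], j)
      wt[[paste(j, k)]] <- model$thv[e]; wt[[paste(k, j)]] <- model$thv[e]
    }
    for (s in seq_len(d)) {  # BFS products from each source
      prod_to <- rep(NA_real_, d); prod_to[s] <- 1
      queue <- s
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        for (nb in g[[v]]) if (is.na(prod_to[nb])) {
          prod_to[nb] <- prod_to[v] * wt[[paste(v, nb)]]
          queue <- c(queue, nb)
        }
      }
      Pcond[s, ] <- ifelse(is.na(prod_to), 0, prod_to)
    }
    diag(Pcond) <- 1
  }
  t1 <- if (model$p >= 1) model$th1 else rep(0, d)
  t2 <- if (model$p == 2) model$th2 else rep(0, d)
  # undo the partial-correlation recursions: factors last-in first-out
  R <- Pcond
  R <- R * sqrt(outer(1 - t2^2, 1 - t2^2)) + outer(t2, t2)
  R <- R * sqrt(outer(1 - t1^2, 1 - t1^2)) + outer(t1, t1)
  diag(R) <- 1
  R
}

#' Discrepancies between model-implied and observed correlation matrices
#'
#' `D1` is the maximum and `D2` the average absolute off-diagonal
#' difference; `D3 = log det(R_model) - log det(R_obs) +
#' tr(R_model^{-1} R_obs) - d` is the Gaussian Kullback-Leibler-type
#' discrepancy, nonnegative for positive-definite inputs and zero only
#' at equality.
#'
#' @param R_model,R_observed d x d correlation matrices.
#' @return named vector `c(D1, D2, D3)`.
#' @export
discrepancies <- function(R_model, R_observed) {
  stopifnot(all(dim(R_model) == dim(R_observed)))
  d <- nrow(R_model)
  det_m <- determinant(R_model, logarithm = TRUE)
  if (det_m$sign <= 0) stop("R_model is singular or not positive definite",
                            call. = FALSE)
  off <- abs(R_model - R_observed)[upper.tri(R_model)]
  D3 <- as.numeric(det_m$modulus) -
    as.numeric(determinant(R_observed, logarithm = TRUE)$modulus) +
    sum(diag(solve(R_model, R_observed))) - d
  c(D1 = max(off), D2 = mean(off), D3 = D3)
}

#' Vuong comparison of two fitted factor tree copula models
#'
#' Computes the per-row log ratios `D_i = log(pmf2_i / pmf1_i)`, their
#' mean and standard deviation, and the AIC-adjusted 95% interval
#' `mean(D) - (npar2 - npar1)/n +- 1.96 sd(D)/sqrt(n)`.  An interval
#' entirely above zero favours model 2; one containing zero indicates no
#' significant difference.
#'
#' @param fit1,fit2 `"ftc_fit"` objects fitted to the same data.
#' @param data the common data.
#' @param nq quadrature size.
#' @return object of class `"vuong_interval"`: list with `dbar`, `s`,
#'   `ci` (length 2), `npar` (difference), `favored`.
#' @export
vuong_interval <- function(fit1, fit2, data, nq = 25) {
  y <- ordinal_data(data)
  l1 <- logpmf_rows(unclass(y), fit1$model, nq)
  l2 <- logpmf_rows(unclass(y), fit2$model, nq)
  if (any(!is.finite(l1)) || any(!is.finite(l2)))
    stop("zero pmf value at row ",
         which(!is.finite(l1) | !is.finite(l2))[1], call. = FALSE)
  vuong_stats(l2 - l1, fit2$npar - fit1$npar)
}

# core Vuong statistics from the per-row log ratios
vuong_stats <- function(Di, npar_diff) {
  n <- length(Di)
  dbar <- mean(Di)
  s <- sqrt(sum((Di - dbar)^2) / (n - 1))
  ci <- dbar - npar_diff / n + c(-1, 1) * 1.96 * s / sqrt(n)
  structure(list(dbar = dbar, s = s, ci = ci, npar_diff = npar_diff,
                 favored = if (ci[1] > 0) 2L else if (ci[2] < 0) 1L else 0L),
            class = "vuong_interval")
}

#' @export
print.vuong_interval <- function(x, ...) {
  cat(sprintf("Vuong 95%% CI (AIC-adjusted): (%.3f, %.3f)\n",
              x$ci[1], x$ci[2]))
  cat(switch(as.character(x$favored),
             "2" = "model 2 fits significantly better\n",
             "1" = "model 1 fits significantly better\n",
             "models are not significantly different\n"))
  invisible(x)
}

# ---- sequential copula family selection --------------------------------

default_factor_candidates <- c("bvn", "t2", "t3", "t5", "t7", "gumbel",
                               "sgumbel")
default_vine_candidates <- c(default_factor_candidates, "frank")

fit_candidate <- function(y, p, fam1, fam2, edges, famv, nq, control) {
  d <- ncol(y)
  skel <- factor_tree_model(
    p, estimate_cutpoints(y),
    tree1_family = if (p >= 1) fam1,
    tree2_family = if (p == 2) fam2,
    edges = edges,
    vine_family = if (!is.null(edges) && nrow(edges) > 0) famv)
  fit_ifm(y, skel, nq = nq, se = FALSE, control = control)
}

#' Sequential copula-family selection for factor tree copula models
#'
#' Implements the sequential heuristic: starting from BVN factor trees
#' and an independence residual tree, (1) refit with each candidate
#' family on factor tree 1 and keep the log-likelihood maximiser; (2) for
#' two-factor models, repeat for factor tree 2 with tree 1 fixed; (3)
#' select the residual tree structure by a maximum spanning tree on
#' either partial correlations given the factors (from the all-BVN
#' normal-ogive fit) or raw polychoric correlations, then iterate the
#' vine candidates and keep the maximiser.  One family is used per tree
#' (no mixing within a tree).
#'
#' @param data ordinal responses.
#' @param p number of factors (1 or 2).
#' @param tree_alg `"partial"` or `"polychoric"` structure selection;
#'   ignored when `edges` is supplied.
#' @param candidates_factor,candidates_vine candidate family labels.
#' @param edges optional fixed residual-tree edge matrix.
#' @param stages run only the first `stages` stages (1 = factor tree 1,
#'   2 = + factor tree 2, 3 = + residual tree); defaults to all.
#' @param allow_no_vine if `TRUE`, the no-vine model is retained when it
#'   beats the best vine model on AIC.
#' @param nq quadrature size.
#' @param control optimiser control for the candidate fits.
#' @return list with `fit` (final `"ftc_fit"`), `families` (selected
#'   labels per tree), `edges`, and `trace` (per-stage candidate
#'   log-likelihood table).
#' @export
select_families <- function(data, p = 1,
                            tree_alg = c("partial", "polychoric"),
                            candidates_factor = default_factor_candidates,
                            candidates_vine = default_vine_candidates,
                            edges = NULL, stages = 3,
                            allow_no_vine = FALSE, nq = 25,
                            control = list(reltol = 1e-8)) {
  y <- ordinal_data(data)
  tree_alg <- match.arg(tree_alg)
  stopifnot(p %in% 1:2)
  trace <- list()
  note <- function(stage, family, fit)
    data.frame(stage = stage, family = family, loglik = fit$loglik,
               npar = fit$npar, aic = fit$aic, stringsAsFactors = FALSE)
  run_stage <- function(stage, cands, fitter) {
    fits <- lapply(cands, function(f) {
      fit <- tryCatch(fitter(f), error = function(e) NULL)
      fit
    })
    keep <- !vapply(fits, is.null, TRUE)
    if (!any(keep)) stop("all candidate fits failed at stage ", stage,
                         call. = FALSE)
    fits <- fits[keep]; cands <- cands[keep]
    trace[[length(trace) + 1L]] <<- do.call(rbind, Map(note, stage,
                                                       cands, fits))
    best <- which.max(vapply(fits, function(f) f$loglik, 0))
    list(family = cands[best], fit = fits[[best]])
  }
  # stage 1: factor tree 1 (factor tree 2, if any, stays BVN; vine stays
  # independence)
  s1 <- run_stage("factor1", candidates_factor, function(f)
    fit_candidate(y, p, f, "bvn", NULL, NULL, nq, control))
  fam1 <- s1$family; best_fit <- s1$fit
  fam2 <- if (p == 2) "bvn" else NULL
  if (p == 2 && stages >= 2) {
    s2 <- run_stage("factor2", candidates_factor, function(f)
      fit_candidate(y, p, fam1, f, NULL, NULL, nq, control))
    fam2 <- s2$family; best_fit <- s2$fit
  }
  famv <- NULL
  if (stages >= 3) {
    if (is.null(edges)) {
      Rpoly <- polychoric_matrix(y)
      if (tree_alg == "polychoric") {
        edges <- max_spanning_tree(Rpoly)
      } else {
        og <- fit_candidate(y, p, "bvn", "bvn", NULL, NULL, nq, control)
        P <- if (p == 1) partial_corr_matrix(Rpoly, og$model$th1)
             else partial_corr_matrix(Rpoly, og$model$th1, og$model$th2)
        edges <- max_spanning_tree(P)
      }
    } else {
      edges <- matrix(as.integer(edges), ncol = 2)
    }
    s3 <- run_stage("vine", candidates_vine, function(f)
      fit_candidate(y, p, fam1, fam2, edges, f, nq, control))
    famv <- s3$family
    if (allow_no_vine && best_fit$aic < s3$fit$aic) {
      famv <- "indep"
    } else {
      best_fit <- s3$fit
    }
  }
  list(fit = best_fit,
       families = c(factor1 = fam1, factor2 = fam2 %||% NA_character_,
                    vine = famv %||% NA_character_),
       edges = if (stages >= 3) edges else NULL,
       trace = do.call(rbind, trace))
}
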