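# Exact sampling from factor tree copula models.

# conditional cdf grids per item: n x (K_j + 1) matrices, column m holding
# Pr(Y_j <= m - 2 | latent) (0 in column 1, 1 in the last column)
cond_cdf_grids <- function(model, x1, x2) {
  n <- length(x1)
  lapply(seq_len(model$d), function(j) {
    a <- model$cutpoints$a[[j]]
    K <- length(a) - 1L
    G <- matrix(0, n, K + 1L)
    G[, K + 1L] <- 1
    if (model$p == 0) {
      for (k in 2:K) G[, k] <- a[k]
      return(G)
    }
    sp1 <- item_spec(model, j, 1)
    for (k in 2:K) G[, k] <- hbicop(rep(a[k], n), x1, sp1)
    if (model$p == 2) {
      sp2 <- item_spec(model, j, 2)
      for (k in 2:K) G[, k] <- hbicop(G[, k], x2, sp2)
    }
    G
  })
}

# breadth-first traversal order of the residual tree from the
# lowest-index node; returns list of (child, parent) in visiting order
bfs_order <- function(edges, d) {
  adj <- lapply(seq_len(d), function(j) integer(0))
  for (e in seq_len(nrow(edges))) {
    j <- edges[e, 1]; k <- edges[e, 2]
    adj[[j]] <- c(adj[[j]], k); adj[[k]] <- c(adj[[k]], j)
  }
  root <- 1L
  seen <- rep(FALSE, d); seen[root] <- TRUE
  queue <- root
  out <- list()
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (nb in sort(adj[[v]])) if (!seen[nb]) {
      seen[nb] <- TRUE
      out[[length(out) + 1L]] <- c(nb, v)
      queue <- c(queue, nb)
    }
  }
  out
}

sample_from_grid <- function(G, u) {
  K <- ncol(G) - 1L
  as.integer(rowSums(u > G[, 2:K, drop = FALSE]))
}

#' Simulate ordinal responses from a factor tree copula model
#'
#' Draws the latent factor(s) uniformly, samples the lowest-index item
#' from its item characteristic curve by inverse cdf, and traverses the
#' residual Markov tree breadth-first, sampling each new item from its
#' conditional pmf given the already-sampled neighbour and the latent
#' point (any traversal order gives the same law on a Markov tree; the
#' breadth-first order is fixed for reproducibility).  With an empty
#' edge set the items are conditionally independent given the factors.
#'
#' @param object a fully parameterised [factor_tree_model()].
#' @param nsim number of response rows to draw.
#' @param seed optional integer seed (`set.seed`).
#' @param ... unused.
#' @return an [ordinal_data()] matrix with `nsim` rows.
#' @export
simulate.factor_tree_model <- function(object, nsim = 1, seed = NULL,
                                       ...) {
  model <- object
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(nsim)
  d <- model$d
  x1 <- runif(n)
  x2 <- if (model$p == 2) runif(n) else NULL
  G <- cond_cdf_grids(model, x1, x2)
  y <- matrix(0L, n, d)
  if (nrow(model$edges) == 0) {
    for (j in seq_len(d)) y[, j] <- sample_from_grid(G[[j]], runif(n))
    return(ordinal_data(y))
  }
  ord <- bfs_order(model$edges, d)
  y[, 1] <- sample_from_grid(G[[1]], runif(n))
  sampled <- rep(FALSE, d); sampled[1] <- TRUE
  edge_spec <- function(e)
    bicop_spec(model$fv$family, theta = model$thv[e], nu = model$fv$nu)
  for (step in ord) {
    child <- step[1]; parent <- step[2]
    e <- which((model$edges[, 1] == child & model$edges[, 2] == parent) |
                 (model$edges[, 1] == parent & model$edges[, 2] == child))
    sp <- edge_spec(e[1])
    Gp <- G[[parent]]; Gc <- G[[child]]
    idx <- cbind(seq_len(n), y[, parent] + 2L)
    Fp_hi <- Gp[idx]
    Fp_lo <- Gp[cbind(seq_len(n), y[, parent] + 1L)]
    icc_p <- pmax(Fp_hi - Fp_lo, 1e-300)
    K <- ncol(Gc) - 1L
    # conditional cdf of the child given the parent's category
    Gcond <- matrix(0, n, K + 1L)
    Gcond[, K + 1L] <- 1
    for (k in 2:K) {
      num <- pbicop(Gc[, k], Fp_hi, sp) - pbicop(Gc[, k], Fp_lo, sp)
      Gcond[, k] <- pmin(pmax(num / icc_p, 0), 1)
    }
    y[, child] <- sample_from_grid(Gcond, runif(n))
    sampled[child] <- TRUE
  }
  ordinal_data(y)
}
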