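# Independent sampling and enumeration oracles used by the tests.
# These deliberately avoid the package's own cdf/h-function code paths.

# Gumbel copula sampler via the Archimedean positive-stable frailty
# (Chambers-Mallows-Stuck for the stable variate).
r_gumbel_pairs <- function(n, theta) {
  alpha <- 1 / theta
  u <- runif(n, 0, pi)
  w <- rexp(n)
  s <- (sin(alpha * u) / sin(u)^(1 / alpha)) *
    (sin((1 - alpha) * u) / w)^((1 - alpha) / alpha)
  e1 <- rexp(n); e2 <- rexp(n)
  cbind(exp(-(e1 / s)^alpha), exp(-(e2 / s)^alpha))
}

# Frank copula sampler via the closed-form conditional inverse.
r_frank_pairs <- function(n, theta) {
  u <- runif(n); q <- runif(n)
  A <- exp(-theta * u); E <- exp(-theta)
  # solve q = A (1 - B) / (A + B - A B - E) for B = exp(-theta v)
  B <- (A + q * (E - A)) / (A + q * (1 - A))
  cbind(u, -log(B) / theta)
}

# all labelled spanning trees on d nodes via Pruefer sequences
all_spanning_trees <- function(d) {
  decode <- function(pr) {
    deg <- rep(1L, d)
    for (x in pr) deg[x] <- deg[x] + 1L
    edges <- matrix(0L, d - 1, 2)
    avail <- rep(TRUE, d)
    for (i in seq_along(pr)) {
      leaf <- min(which(deg == 1L & avail))
      edges[i, ] <- sort(c(leaf, pr[i]))
      avail[leaf] <- FALSE
      deg[pr[i]] <- deg[pr[i]] - 1L
    }
    edges[d - 1, ] <- sort(which(avail))
    edges
  }
  prufer <- as.matrix(expand.grid(rep(list(seq_len(d)), d - 2)))
  lapply(seq_len(nrow(prufer)), function(i) decode(as.integer(prufer[i, ])))
}

# tree weight used by the structure-selection objective
tree_weight <- function(edges, R)
  sum(apply(edges, 1, function(e) log(1 - R[e[1], e[2]]^2)))

# small helper models shared across test files
toy_cutpoints3 <- function(d = 3) cutpoints(rep(list(c(0.2, 0.5)), d))
toy_cutpoints5 <- function(d = 4) cutpoints(rep(list(c(0.2, 0.4, 0.6, 0.8)), d))
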