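# Simulation-study harness: n-scaled bias/SD/RMSE of the IFM estimates
# and copula-family selection frequencies.

#' Repeated-simulation study of IFM estimation accuracy
#'
#' Simulates `reps` datasets of `n` rows from `model`, refits the model
#' skeleton (same factors, families and edge set; parameters free) by
#' [fit_ifm()], and summarises each dependence parameter on the Kendall
#' tau scale by the n-scaled bias, standard deviation (denominator
#' `reps - 1`) and root mean square error.  Replicates whose optimiser
#' fails to converge are dropped and counted.
#'
#' @param model generating [factor_tree_model()] (fully parameterised).
#' @param n sample size per replicate.
#' @param reps number of replicates (>= 2).
#' @param seed master seed; per-replicate seeds are drawn from it so
#'   replicates are individually reproducible.
#' @param nq quadrature size.
#' @return data frame with one row per dependence parameter: `tree`,
#'   `label`, `true_tau`, `n_bias`, `n_sd`, `n_rmse`; attributes `reps`
#'   (used) and `dropped`.
#' @export
sim_study <- function(model, n = 500, reps = 100, seed = 1, nq = 25) {
  stopifnot(reps >= 2)
  set.seed(seed)
  rep_seeds <- sample.int(2^31 - 2, reps)
  true <- unlist(model_taus(model))
  skel <- model
  skel$th1 <- rep(NA_real_, length(skel$th1))
  skel$th2 <- rep(NA_real_, length(skel$th2))
  skel$thv <- rep(NA_real_, length(skel$thv))
  est <- matrix(NA_real_, reps, length(true))
  ok <- logical(reps)
  for (r in seq_len(reps)) {
    y <- simulate(model, nsim = n, seed = rep_seeds[r])
    fit <- tryCatch(fit_ifm(y, skel, nq = nq, se = FALSE),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    est[r, ] <- unlist(model_taus(fit$model))
    ok[r] <- TRUE
  }
  est <- est[ok, , drop = FALSE]
  reps_used <- nrow(est)
  if (reps_used < 2) stop("fewer than 2 converged replicates",
                          call. = FALSE)
  bias <- colMeans(est) - true
  sdv <- apply(est, 2, stats::sd)
  rmse <- sqrt(colMeans((est - matrix(true, reps_used, length(true),
                                      byrow = TRUE))^2))
  tab <- fit_tau_table(model, numeric(0))
  out <- data.frame(tree = tab$tree,
                    label = ifelse(is.na(tab$item), tab$edge, tab$item),
                    true_tau = true,
                    n_bias = n * bias, n_sd = n * sdv, n_rmse = n * rmse)
  rownames(out) <- NULL
  attr(out, "reps") <- reps_used
  attr(out, "dropped") <- reps - reps_used
  out
}

#' Copula-family selection frequency study
#'
#' Simulates replicates from a 1-factor tree model with Gumbel
#' item-factor copulas (Kendall tau descending 0.70 to 0.40) and a
#' serially connected (D-vine) residual tree of t3 copulas (tau 0.40 to
#' 0.10), runs the sequential family-selection heuristic, and counts how
#' often each candidate family is chosen.  By default only the factor
#' tree-1 stage is run, which is the stage of the heuristic that decides
#' the tree-1 family (the residual tree is still the independence copula
#' at that point); `trees = "both"` continues to the residual-tree stage
#' with the true D-vine edges replaced by the structure-selection step.
#'
#' @param reps number of replicates.
#' @param n sample size per replicate.
#' @param d number of items.
#' @param K number of (equally weighted) categories per item.
#' @param seed master seed.
#' @param candidates candidate families for the factor tree.
#' @param trees `"factor1"` or `"both"`.
#' @param nq quadrature size.
#' @return list with `counts` (per-tree tables of selection counts) and
#'   the generating `model`.
#' @export
family_selection_study <- function(reps = 100, n = 500, d = 8, K = 5,
                                   seed = 1,
                                   candidates = default_factor_candidates,
                                   trees = c("factor1", "both"),
                                   nq = 25) {
  trees <- match.arg(trees)
  set.seed(seed)
  rep_seeds <- sample.int(2^31 - 2, reps)
  model <- selection_design_model(d, K)
  pick1 <- character(reps)
  pickv <- character(reps)
  for (r in seq_len(reps)) {
    y <- simulate(model, nsim = n, seed = rep_seeds[r])
    sel <- select_families(y, p = 1, tree_alg = "partial",
                           candidates_factor = candidates,
                           stages = if (trees == "factor1") 1 else 3,
                           nq = nq)
    pick1[r] <- sel$families[["factor1"]]
    pickv[r] <- if (trees == "both") sel$families[["vine"]]
                else NA_character_
  }
  counts <- list(factor1 = table(factor(pick1, levels = candidates)))
  if (trees == "both")
    counts$vine <- table(factor(pickv, levels = default_vine_candidates))
  list(counts = counts, model = model)
}

# the generating design of the family-selection study
selection_design_model <- function(d = 8, K = 5) {
  cp <- cutpoints(rep(list(seq_len(K - 1) / K), d))
  tau1 <- seq(0.70, 0.40, length.out = d)
  tauv <- seq(0.40, 0.10, length.out = d - 1)
  factor_tree_model(
    1, cp,
    tree1_family = "gumbel",
    tree1_theta = vapply(tau1, function(t) tau_to_par("gumbel", t)$theta, 0),
    edges = cbind(seq_len(d - 1), seq_len(d - 1) + 1L),
    vine_family = "t3",
    vine_theta = vapply(tauv, function(t) tau_to_par("t", t, 3)$theta, 0))
}
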