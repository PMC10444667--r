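# Synthetic data generator: named study presets and a PTSD-like fixture.

# Kendall taus of the selected 2-factor tree model reported for the
# 20-item PTSD symptom checklist (t2 first factor, Gumbel second factor,
# t5 residual tree); used to parameterise the synthetic emulation.
.PTSD_TAU1 <- c(-0.17, -0.08, -0.12, -0.34, -0.21, -0.13, -0.09, 0.04,
                0.24, -0.12, -0.07, 0.28, 0.34, 0.35, 0.11, 0.10, 0.04,
                0.12, 0.28, 0.13)
.PTSD_TAU2 <- c(0.50, 0.45, 0.52, 0.57, 0.56, 0.26, 0.39, 0.19, 0.33,
                0.30, 0.48, 0.50, 0.49, 0.36, 0.44, 0.28, 0.33, 0.46,
                0.43, 0.40)
.PTSD_EDGES <- matrix(c(1, 18,  18, 17,  18, 14,  18, 10,  10, 11,
                        11, 9,   9, 2,   2, 3,   3, 20,   2, 16,
                        16, 15,  9, 4,  20, 5,  14, 13,   5, 6,
                        6, 7,   7, 19,  16, 8,  19, 12),
                      ncol = 2, byrow = TRUE)
.PTSD_TAUV <- c(-0.18, 0.22, -0.20, -0.10, 0.36, 0.29, -0.18, 0.26,
                0.05, 0.13, 0.17, 0.29, 0.05, 0.27, 0.12, 0.23, -0.21,
                0.12, 0.08)

equal_cutpoints <- function(d, K) cutpoints(rep(list(seq_len(K - 1) / K), d))

theta_of <- function(family, taus, nu = NULL)
  vapply(taus, function(t)
    if (abs(t) < 1e-12) tau_to_par(family, 1e-8, nu)$theta
    else tau_to_par(family, t, nu)$theta, 0)

#' Generate a synthetic ordinal dataset with its true model
#'
#' Named presets reproduce the package's study designs:
#' \describe{
#'   \item{`table1-d8`, `table1-d16`, `table1-d24`}{1-factor tree model,
#'     Gumbel copulas everywhere, d items with K = 5 equally weighted
#'     categories; factor taus equally spaced 0.70 to 0.40, residual
#'     D-vine (serial edges) taus 0.40 to 0.10; default n = 500.}
#'   \item{`table2-d24`}{2-factor tree Gumbel model, d = 24; factor-1
#'     taus 0.70 to 0.40, factor-2 taus 0.55 to 0.25, D-vine taus 0.40
#'     to 0.10; default n = 500.}
#'   \item{`table3-d8`}{the family-selection design: Gumbel factor tree
#'     (taus 0.70 to 0.40) with a t3 D-vine residual tree (taus 0.40 to
#'     0.10); default n = 500.}
#'   \item{`ptsd-like`}{a synthetic emulation of the 20-item PTSD symptom
#'     checklist (n = 221, K = 5): a 2-factor tree model with t2 copulas
#'     on factor 1, Gumbel on factor 2 and t5 on the residual tree, with
#'     Kendall taus and edge set taken from the fitted values reported
#'     for that application.  The Gumbel second factor gives the data
#'     more probability in the joint upper tail, so the upper
#'     semi-correlations exceed the lower ones on average.  The
#'     thresholds are a fixed mildly skewed choice (0.3, 0.5, 0.7, 0.85);
#'     the real item thresholds are not reproduced.}
#'   \item{`custom`}{simulate from a user-supplied `model`.}
#' }
#'
#' @param kind preset name.
#' @param n rows to simulate (defaults per preset).
#' @param seed integer seed for reproducibility.
#' @param model a [factor_tree_model()] for `kind = "custom"`.
#' @return list with `data` (an [ordinal_data()]) and `model` (the
#'   generating model, for parameter-recovery checks).
#' @export
generate_fixture <- function(kind = c("ptsd-like", "table1-d8",
                                      "table1-d16", "table1-d24",
                                      "table2-d24", "table3-d8",
                                      "custom"),
                             n = NULL, seed = 1, model = NULL) {
  kind <- match.arg(kind)
  if (kind == "custom") {
    if (is.null(model)) stop("kind = 'custom' requires a model",
                             call. = FALSE)
    n <- n %||% 500
  } else if (kind == "ptsd-like") {
    n <- n %||% 221
    cp <- cutpoints(rep(list(c(0.3, 0.5, 0.7, 0.85)), 20))
    model <- factor_tree_model(
      2, cp,
      tree1_family = "t2", tree1_theta = theta_of("t", .PTSD_TAU1, 2),
      tree2_family = "gumbel", tree2_theta = theta_of("gumbel", .PTSD_TAU2),
      edges = .PTSD_EDGES,
      vine_family = "t5", vine_theta = theta_of("t", .PTSD_TAUV, 5))
  } else if (kind == "table3-d8") {
    n <- n %||% 500
    model <- selection_design_model(8, 5)
  } else if (kind == "table2-d24") {
    n <- n %||% 500
    d <- 24
    model <- factor_tree_model(
      2, equal_cutpoints(d, 5),
      tree1_family = "gumbel",
      tree1_theta = theta_of("gumbel", seq(0.70, 0.40, length.out = d)),
      tree2_family = "gumbel",
      tree2_theta = theta_of("gumbel", seq(0.55, 0.25, length.out = d)),
      edges = cbind(seq_len(d - 1), seq_len(d - 1) + 1L),
      vine_family = "gumbel",
      vine_theta = theta_of("gumbel", seq(0.40, 0.10, length.out = d - 1)))
  } else {
    d <- as.integer(sub("table1-d", "", kind))
    n <- n %||% 500
    model <- factor_tree_model(
      1, equal_cutpoints(d, 5),
      tree1_family = "gumbel",
      tree1_theta = theta_of("gumbel", seq(0.70, 0.40, length.out = d)),
      edges = cbind(seq_len(d - 1), seq_len(d - 1) + 1L),
      vine_family = "gumbel",
      vine_theta = theta_of("gumbel", seq(0.40, 0.10, length.out = d - 1)))
  }
  list(data = simulate(model, nsim = n, seed = seed), model = model)
}
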