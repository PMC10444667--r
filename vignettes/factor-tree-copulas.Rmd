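---
title: "Factor tree copula models for ordinal item responses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Factor tree copula models for ordinal item responses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`ftcopula` models a vector of ordinal item responses
$Y_1, \dots, Y_d$, with $Y_j \in \{0, \dots, K_j - 1\}$, through a
*factor tree copula* construction with three layers:

1. **Margins.** Each item is a discretisation of a latent uniform
   variable at cutpoints $a_{j,0} = 0 < a_{j,1} \le \dots <
   a_{j,K_j} = 1$; $\alpha_{j,k} = \Phi^{-1}(a_{j,k})$ are their
   normal-scale images.
2. **Factor part.** One or two latent factors $X_1, X_2$, independent
   standard uniforms, are linked to each item by a parametric bivariate
   copula.  The conditional cdf of item $j$ given $X_1 = x$ is the
   h-function $C_{j|X_1}(a_{j,y+1} \mid x)$ of the linking copula, and
   for two factors the factor-2 h-function is composed on top.  Given
   the factors, the item characteristic curve (ICC) is the difference of
   consecutive conditional cdfs.
3. **Residual tree.** Items are not assumed conditionally independent
   given the factors.  Residual dependence follows a Markov tree
   (a vine truncated after its first tree): $d - 1$ item pairs
   $\mathcal{E}$ form a spanning tree, and each edge carries a bivariate
   copula applied to the items' conditional cdfs given the factors.  The
   joint conditional pmf multiplies the ICCs by the edge-wise ratio of
   the pair rectangle probability to the product of the two ICCs.  Pairs
   not joined by an edge are conditionally independent given the factors
   and the path between them.

The joint pmf integrates the conditional pmf over the factors.  Setting
$\mathcal{E} = \emptyset$ recovers the ordinary 1- or 2-factor copula
model; setting $p = 0$ factors recovers a plain Markov-tree model; with
all-BVN copulas the model coincides with the discretised multivariate
normal (normal ogive) model, which the package exploits for diagnostics.
Two modelling assumptions are hard-wired, as is standard for this model
class: the conditional (edge and factor-2) copulas do not depend on the
value of the conditioning variables, and the two factors are
independent.

Six bivariate families are supported: independence, bivariate normal
(BVN), Student-$t_\nu$, Gumbel, survival Gumbel and Frank.  They cover
reflection-symmetric dependence with and without tail dependence (BVN,
Frank, $t_\nu$) and reflection-asymmetric upper/lower tail dependence
(Gumbel / survival Gumbel), which is what distinguishes items behaving
like discretised means, mixtures of means, maxima or minima.  The
$t_\nu$ degrees of freedom are treated as a label from the fixed grid
$\{2, 3, 5, 7\}$, not as a free parameter: $\nu$ is chosen by model
selection and never counted in the AIC penalty.

## Estimation

Estimation is two-step IFM (inference functions for margins):

* **Step 1.** Cutpoints are the univariate cumulative sample
  proportions.  Interior categories that are never observed are
  collapsed (with a message) because the Markov-tree pmf divides by the
  per-category probabilities.
* **Step 2.** The joint log-likelihood is maximised over the dependence
  parameters only, cutpoints fixed, by BFGS on unconstrained transforms:
  $\operatorname{atanh}\theta$ for BVN/$t$, $\log(\theta - 1)$ for the
  Gumbel pair (capped at $\theta \le 1 + e^{3.9} \approx 50$, i.e.
  $\tau \lesssim 0.98$), identity for Frank (capped at $|\theta| \le
  35$, inside the numerically safe range of its exponential terms).

The factors are integrated out with Gauss–Legendre quadrature mapped to
$(0,1)$, `nq = 25` points per factor by default (a double sum for two
factors).  Against exhaustive enumeration and discretised-MVN rectangle
oracles, 25 points give absolute pmf errors below $10^{-5}$ at moderate
dependence and below $10^{-4}$ at item–factor Kendall $\tau \approx
0.7$; the package's oracle tests run selected comparisons at `nq = 150`
where the quadrature error is negligible.  Because the same nodes are
used for every likelihood evaluation, the objective is smooth in the
parameters and quasi-Newton iteration converges cleanly.

**Start values and the warm start.** Default starts are mid-range
(Kendall $\tau = 0.3$ for factor trees, $0.1$ for edges).  For models
with both a factor part and a residual tree the joint likelihood has a
ridge along which stronger factor loadings trade off against the first
residual edges, and a cold mid-range start can converge to a local
optimum in which one or two edges collapse to independence while the
factor loadings overshoot.  `fit_ifm()` therefore first fits the
factor-only model, starts the joint optimisation from its estimates, and
initialises the residual edges at the partial polychoric correlations
given the fitted factors (mapped to the edge family through the arcsine
Kendall-tau relation) rather than at a flat value (`warm_start = TRUE`).
In repeated-simulation checks this removed essentially all such
failures and roughly halved the sampling standard deviation of the
strongest factor parameter.

**Standard errors** are delta-method transforms to the $\tau$ scale of
the inverse observed Hessian (central differences on the transformed
scale).  They ignore step-1 cutpoint uncertainty and are therefore
approximate — adequate for the reporting granularity of a fitted-model
table, not for sharp inference on the margins.  A non-positive-definite
Hessian yields `NA` standard errors rather than an error.

**Identifiability.** The all-BVN two-factor model is rotation-invariant,
so one factor-2 parameter (item 1) is fixed at zero and the AIC counts
$2d - 1$ factor parameters; with any other family the two-factor model
is near-identifiable and all $2d$ parameters are free.  Factor-loading
signs are identified only jointly (flipping all loadings of one factor
is a relabelling of that factor).

## Model selection

**Tree structure.** The residual edge set is a maximum spanning tree,
computed by Prim's algorithm on weights $\log(1 - r_{jk}^2)$ (ties
broken by the lexicographically smallest pair so results are
deterministic).  Two dependence measures are offered: raw polychoric
correlations, or partial correlations given the factor(s) obtained from
the normal-ogive (all-BVN) fit via the standard one- and two-factor
partial-correlation recursions.  The partial variant asks "what
dependence is left after the factors" and is the natural default for
factor tree models.

**Copula families.** A sequential heuristic starts from BVN factor
trees and an independence residual tree; for each tree in order (factor
1, factor 2, residual) it refits the model once per candidate family
and keeps the log-likelihood maximiser.  One family is used per tree —
mixing families within a tree is deliberately not supported, which keeps
each tree interpretable (a "maxima" tree, a "mixture" tree, ...) and
keeps the search linear in the number of candidates.  Defaults: BVN,
$t_2$, $t_3$, $t_5$, $t_7$, Gumbel, survival Gumbel for factor trees,
plus Frank for the residual tree (Frank has a cheap closed-form cdf,
which matters in the rectangle probabilities, and tail dependence is
already supplied by the factor trees).  The selected tree-1 family is
decided entirely at the first stage, so selection-frequency studies of
that stage run the heuristic only through stage 1.

**Diagnostics.**

* *Semi-correlations.* For each pair of items the polychoric
  correlation is recomputed on the joint-lower and joint-upper
  sub-tables, dichotomising each item at the cutpoint whose normal-scale
  image is nearest zero, with cutpoints renormalised to the sub-sample;
  averaging over pairs gives $(\bar\rho_N, \bar\rho_N^-,
  \bar\rho_N^+)$.  An excess of $\bar\rho_N^+$ over $\bar\rho_N^-$
  indicates more probability in the joint upper tail than a discretised
  MVN would put there, pointing at Gumbel-type factor links.
* *Theoretical counterparts.* For a copula family calibrated to a
  normal-scores correlation $\rho_N$, the package computes
  $\rho_N^\pm$ as the correlation of the normal scores conditional on
  both scores being negative (respectively positive), by
  two-dimensional Gauss–Legendre integration of the copula density on
  the normal-scores scale ($120^2$ nodes over $[-8.5, 8.5]^2$ and the
  two quadrants).  These integrals are validated in the test suite
  against Monte Carlo oracles with $4 \times 10^6$ draws (agreement
  better than $2 \times 10^{-3}$).  Published tables of such
  semi-correlations vary in how the $t_\nu$ and Frank entries are
  computed; `ftcopula` documents and tests exactly this
  quadrant-conditional normal-scores definition.
* *Correlation-matrix discrepancies.* For Gaussian-analogue models the
  implied correlation matrix combines the normal-ogive factor formulas
  with the Markov-tree property that the partial correlation of a pair
  given the factors is the product of edge parameters along the unique
  tree path.  $D_1$ (max absolute difference), $D_2$ (average absolute
  difference) and the Kullback–Leibler-type
  $D_3 = \log\det R_{\text{model}} - \log\det R_{\text{obs}} +
  \operatorname{tr}(R_{\text{model}}^{-1} R_{\text{obs}}) - d$
  compare it with the observed polychoric matrix.
* *Vuong intervals.* Non-nested fitted models are compared through the
  AIC-adjusted 95% interval for the mean per-observation log-likelihood
  ratio; an interval above zero favours the second model.  The sample
  standard deviation of the log-ratios (denominator $n - 1$) is used as
  the dispersion.

## Simulation

`simulate()` draws exactly from the model: latent factors uniform; the
lowest-index item sampled by inverse cdf from its ICC; the remaining
items in breadth-first order over the residual tree, each drawn from
its conditional pmf given its already-sampled neighbour and the latent
point.  On a Markov tree any traversal order yields the same law; the
breadth-first order is fixed purely for reproducibility.  The sampler is
validated against implied correlations, margin frequencies and
independence tests.

`sim_study()` repeats simulate-and-refit and reports per-parameter
$n \times$ bias, $n \times$ SD (denominator `reps - 1`) and $n \times$
RMSE on the $\tau$ scale, dropping (and counting) non-converged
replicates.  `family_selection_study()` reports selection frequencies
under a Gumbel-factor/$t_3$-vine design.

### Synthetic fixtures

`generate_fixture()` provides the study designs as named presets, with
Kendall taus on equally spaced grids (factor $0.70 \to 0.40$, second
factor $0.55 \to 0.25$, residual tree $0.40 \to 0.10$), $K = 5$ equally
weighted categories, and serial (D-vine) residual edges.  The
`ptsd-like` preset emulates a 20-item, 221-respondent PTSD symptom
checklist with a two-factor tree model ($t_2$ first factor, Gumbel
second factor, $t_5$ residual tree) whose taus and edge set are the
fitted values reported for that application; its thresholds are a fixed
mildly skewed choice (0.3, 0.5, 0.7, 0.85 on the uniform scale) since
the real item thresholds are not part of the preset.  The fixture
reproduces the qualitative signature of the real data — average upper
semi-correlation above the lower one, and a two-factor structure
preferred by AIC and $D_3$ — but not its exact observed values, which
depend on the real thresholds and sampling noise.  Passing tests on the
fixture therefore demonstrates correctness of the machinery, not
replication of any particular dataset.

## Numerical choices

* Copula arguments are clamped to $[10^{-10}, 1 - 10^{-10}]$ before
  transcendental transforms; exact boundary identities ($C(u,1) = u$,
  $h(1|u) = 1$, ...) are short-circuited first so they hold exactly.
* The bivariate normal cdf uses the single-integral (arcsine) form with
  a 20-node Gauss–Legendre rule, switched to 96 nodes for
  $|\rho| > 0.85$; accuracy is at machine level across $|\rho| \le
  0.999$ (checked against `mvtnorm`).
* The bivariate $t$ cdf integrates the bivariate-normal cdf against the
  chi mixing density on the chi scale ($s = \sqrt{W}$, 48 nodes), where
  the integrand is smooth; accuracy is ~$10^{-10}$ for $\nu \in
  \{2, 3, 5, 7\}$ (checked against `mvtnorm`'s TVPACK).
* Gumbel quantities are computed through $\log(-\log u)$ and Frank
  quantities through the cancellation-free form
  $D = A + B - AB - E$ ($A = e^{-\theta u}$ etc.), so large $\theta$
  and corner arguments neither overflow nor lose all precision.
* Rectangle probabilities are clipped to $[0, \min(f_j, f_k)]$ — a
  rectangle can never exceed either conditional margin — and the pmf is
  floored at $10^{-300}$ before taking logs.  The clipping matters: it
  bounds the edge ratios when a conditional margin underflows at
  extreme parameter values, which otherwise lets the optimiser escape
  into spurious regions.
* Frank's Kendall tau uses the Debye-$D_1$ formula (evaluated by
  adaptive quadrature); its inverse and all calibration problems are
  solved by bracketed root search.

## Problem sizes used by the checks

The test suite and the acceptance script are sized for a single CPU:
exhaustive normalization up to $d = 4$, $K = 3$; discretised-MVN
comparisons at $d = 3$; spanning-tree brute force at $d = 5$ (125
labelled trees); the estimation study at $d = 8$, $n = 500$, 100
replicates; the family-selection study at 50 replicates (its reference
behaviour is a $\ge 90\%$ selection rate, checked as $\ge 45/50$); the
application pipeline at $d = 20$, $n = 221$.

## Limitations

* Residual dependence beyond a single tree (higher truncation levels)
  and more than two factors are out of scope.
* Families are one-parameter (plus the fixed $t$ grid); two-parameter
  families and per-item family mixing within a tree are not supported.
* Standard errors ignore first-stage cutpoint estimation.
* The implied correlation matrix, partial-correlation structure
  selection and $D_1$–$D_3$ are defined only for the Gaussian analogue
  (all-BVN) models.
* Missing responses are rejected, not imputed.
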