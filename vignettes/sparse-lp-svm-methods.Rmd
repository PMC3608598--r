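---
title: "Sparse LP-SVMs for metagenomic count data: models, parameters and design notes"
author: "metalinprog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse LP-SVMs for metagenomic count data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalinprog)
```

## The problem

Given a metagenomic count table $X \in \mathbb{N}^{n \times m}$ (rows =
samples, columns = OTUs, taxa or pathway features) and a clinical phenotype
$y$ with $c \ge 2$ categories, we want to (i) predict the phenotype of new
samples and (ii) identify the small subset of features whose abundance
differs between the phenotype groups — *simultaneously*, with one model,
rather than testing features one at a time and then training a separate
classifier.

## Preprocessing

Counts carry two nuisance structures: sequencing depth varies per sample,
and count variance grows with the mean (Poisson / negative-binomial
behaviour). The pipeline therefore

1. converts each sample to relative abundances
   $p_{ij} = x_{ij} / \sum_j x_{ij}$, and
2. applies a variance-stabilizing transform: $\sqrt{p}$ or the angular
   transform $\tilde{x} = \arcsin\sqrt{p}$ (radians, mapping $[0,1]$ to
   $[0, \pi/2]$).

`choose_transform()` implements the advisory rule: if Bartlett's test (each
sample is one group, its $m$ feature values the observations) does not
reject variance homogeneity at $\alpha = 0.05$, no transform is needed;
under heterogeneity, $\sqrt{p}$ suffices when the proportions occupy only
one of the bands $[0, 0.3]$ or $[0.7, 1]$, otherwise the arcsine transform
is used. Zeros are allowed alongside the high band since they are
structural in metagenomic tables. The default pipeline applies the arcsine
transform unconditionally — it is the safe choice for proportion data, and
keeping one fixed transform makes the repeated-split protocol comparable
across repeats. The fitted model records its transform and re-applies it
to new samples, computing relative abundance from the new sample's own row
sum (there is no training-set coupling in the preprocessing).

Two points about the Bartlett grouping are deliberate design choices: the
groups are *samples* (not phenotype classes), matching the advisory role of
the test in the preprocessing step, and the test may be run on the
proportion matrix (default) or on a transformed matrix to check how much
stabilization was achieved.

## The binary model

With labels $y_i \in \{-1, +1\}$ and transformed features $\tilde{x}_i$,
the classifier is linear, $f(\tilde{x}) = \beta_0 + \beta^\top \tilde{x}$,
fitted by minimizing the soft-margin hinge loss with an L1 penalty:

$$ \min_{\beta_0, \beta} \;\; \sum_{i=1}^n \max\!\big(0,\, 1 - y_i
f(\tilde{x}_i)\big) \; + \; \lambda \lVert \beta \rVert_1 . $$

The intercept is not penalized. The L1 penalty drives coefficients to
exactly zero, so the fitted support *is* the feature selection; $\lambda$
trades training fit against sparsity. Splitting $\beta = u - v$ and
$\beta_0 = b^+ - b^-$ with $u, v, b^\pm \ge 0$ and introducing hinge slacks
$\xi_i \ge 0$ turns the problem into a linear program with $2m + 2 + n$
variables and $n$ constraints, so the global optimum is found exactly —
there is no local-minimum or step-size issue.

## The multiclass model

For $c > 2$ classes the labels are encoded one-against-rest into
$Y \in \{\pm 1\}^{n \times (c-1)}$; the last class (configurable) is the
*reference* and its parameters are pinned at zero, which the softmax
normalization makes redundant anyway. Fitting the $c - 1$ binary problems
separately would let every classifier pick its own features. Instead the
joint objective

$$ \min_{B, \beta_0} \;\; \sum_{i,k} \xi_{ik} \; + \; \lambda \sum_{j=1}^m
\max_k \lvert \beta_{jk} \rvert $$

charges each feature once, for its largest coefficient across subproblems
(the $L_{\infty,1}$ mixed norm). A feature either enters *all* classifiers
for free once its largest coefficient is paid for, or stays at zero in all
of them — the classifiers are forced to agree on one small feature set.
With auxiliary row bounds $t_j \ge \lvert \beta_{jk} \rvert$ this is again
an LP ($2m(c-1) + 2(c-1) + n(c-1) + m$ variables,
$n(c-1) + 2m(c-1)$ constraints), and $t_j = \max_k \lvert \beta_{jk}
\rvert$ holds automatically at the optimum.

Class probabilities use the multinomial-logit form with the reference
score pinned at zero, $p_k = e^{f_k} / \sum_{l=1}^{c} e^{f_l}$ (with
$f_c = 0$), and the predicted class is the argmax; ties break to the
earliest class in the recorded class order, and a binary score of exactly
zero predicts the positive class. Binary problems are fitted by the
dedicated binary path rather than as $c = 2$ multiclass; the two
formulations attain the same optimum, which the test suite enforces.

## The interior-point solver

No linear-programming backend is assumed; the package ships its own
infeasible primal-dual Mehrotra predictor–corrector method, in two
flavours behind the `solve_lp()` contract:

* a dense backend for explicitly assembled programs (the binary SVM's
  normal matrix is only $n \times n$), and
* a structure-exploiting backend for the multiclass program, which
  eliminates the $2m(c-1)$ box rows feature-by-feature in closed form
  (each per-feature block is a rank-one update of $2 \times 2$ blocks,
  inverted by Sherman–Morrison with all-positive intermediates) and
  factorizes only an $n(c-1) \times n(c-1)$ Schur complement.

Numerical choices that matter:

* **Tolerances.** Iterations stop when the relative primal and dual
  residuals and the complementarity gap all fall below $10^{-9}$; the best
  iterate is tracked and certified optimal below $10^{-7}$. Solutions are
  re-checked for feasibility at $10^{-6}$ independently of the backend.
* **Split-column degeneracy.** The $\pm$ splits of free parameters give
  the dual no strict interior (the split columns are exact negatives); a
  cost perturbation of $10^{-9} \max(1, \lVert c \rVert_\infty)$ on
  zero-cost columns restores the central path, a per-iteration shrink of
  the common split component stops the primal from drifting along the
  exact null direction, and the reported objective is always that of the
  unperturbed program. Rarely — essentially only when the optimum is the
  all-zero model under a dominating penalty — the default perturbation
  still stalls; the fit paths then retry with a stronger ($10^{-6}$)
  perturbation and, failing that, a relaxed certification.
* **Approximate sparsity.** Interior-point optima are approximately, not
  exactly, sparse; `selected_features()` snaps coefficients below
  `1e-6 * max(1, max |coef|)` to zero. Only the objective value and the
  induced selected set are treated as canonical; coefficient values may
  differ between backends under degeneracy.

`pracma::linprog` (a big-M simplex) is wired in as an independent second
backend for small programs, and the test suite compares the two.

## Choosing the sparsity weight

`cv_lambda()` performs stratified $k$-fold cross-validation (default 10;
$k = n$ gives leave-one-out) over a candidate grid (default
$\{0.5, 1, \dots, 10, 15, 20\}$), scoring by misclassification error; AUC
is reported alongside but never drives selection. Ties break to the
*largest* error-minimizing $\lambda$ — when several models predict equally
well, prefer the sparsest. `repeated_split_eval()` wraps the full
evaluation protocol: repeated stratified train/test splits, $\lambda$
re-selected per repeat *on the training part only* (both a fixed and a
re-selected mode are supported; re-selection is the default because each
repeat is an independent rehearsal of the whole procedure), and
per-feature relevance counts — the number of repeats in which a feature
received a nonzero coefficient — as the stability measure of the
selection.

## The simulator and the study conditions

`simulate_counts()` draws each cell as Poisson with a Gamma-distributed
rate (mean 100, variance 1000; shape 10, scale 10), i.e. negative-binomial
counts with marginal mean 100 and variance 1100. Two designs, available
via `default_sim_specs()`, define the study conditions: 2 or 4 classes of
50 samples each, 1000 features, and the first 5 features planted as
class-discriminative by multiplying their Gamma scale with a class-specific
effect.

The effect sizes are the one genuinely open design choice, and they are
deliberately strong. On the arcsine-proportion scale a feature's typical
value is $\arcsin\sqrt{1/m} \approx 0.03$, and the all-zero coefficient
vector becomes LP-optimal once $\lambda$ exceeds roughly
$(n_{\text{train}}/2) \cdot \Delta\tilde{x}$, where $\Delta\tilde{x}$ is
the between-class separation of a planted feature after the transform.
For the grid $1..10$ to resolve informative models, the planted separation
must be large: the binary default multiplies the planted features' rates
100-fold in the second class (a rare 0.1%-abundance organism becoming a
dominant ~7% one — the magnitude of shift seen in strong dysbiosis), and
the four-class default assigns the abundance levels $(1, 12, 40, 100)$ —
equally spaced on the transformed scale — cyclically across the five
planted features, so every planted feature takes every level and every
class is linearly separable one-against-rest. A rank-one profile (all
planted features elevated the same way per class) would leave the middle
classes inseparable from both sides and is exactly the failure mode the
cyclic design avoids. The effect parameter accepts either a per-class
vector or a full feature-by-class matrix, so users can weaken or reshape
the signal.

What the simulator does *not* emulate: compositional correlation beyond
the shared row sum, zero inflation, phylogenetic structure between
features, and uneven sequencing depth beyond Poisson–Gamma noise. Passing
the simulation study therefore shows that the estimator and protocol work
as designed under clean planted signal; it does not certify performance on
real dysbiosis data, where the repeated-split protocol with relevance
counts (the same code path) is the appropriate instrument.

## Study sizes

`simulation_study()` runs the full design — fresh dataset per repeat,
stratified 50/50 split, training-only CV, held-out scoring. The packaged
configuration uses 20 repeats per design with 2-fold CV over
$\lambda \in \{1,\dots,10\}$ inside each training half. Two folds rather
than more is a deliberate choice beyond run time: with the error-tie rule
preferring the largest $\lambda$, $k$-fold CV selects $\lambda$ near the
critical value of an inner training set of size $(k-1)/k$ times the outer
one, so large $k$ pushes the final fit right up against the sparsity edge
where redundant planted features start dropping out; $k = 2$ keeps the
selected $\lambda$ at about half the outer critical value, comfortably in
the regime where the support is stable. These sizes keep a full two-design
study to a few minutes on one core while leaving the Monte-Carlo error of
the reported means well inside the tolerances the tests assert. The test suite and `scripts/acceptance.R` run exactly this
configuration.

## Known limitations

* The hinge scale is $\sum_i \xi_i$ (not the mean), so useful $\lambda$
  ranges grow with the training size and with the scale of the transformed
  features; grids should be chosen per dataset (the CV report makes the
  error profile visible).
* One-against-rest with linear scores cannot represent classes that are
  intermediate along a single abundance direction; the joint penalty
  shares features but does not fix that geometry.
* Interior-point solutions on degenerate optimal faces converge to the
  analytic center, which can spread weight across equivalent features;
  relevance counts over repeated splits are the intended remedy.
* No kernels, class weights, elastic-net variants, or probability
  calibration beyond the softmax link.
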