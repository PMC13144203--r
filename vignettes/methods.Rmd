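---
title: "Fitting topic models by Poisson NMF: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting topic models by Poisson NMF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmftopics)
```

## The two models and why we fit one through the other

The data are a sparse non-negative integer matrix $X$ with $n$ rows
(documents, cells) and $m$ columns (terms, genes). Two classical models
describe such counts:

* **Multinomial topic model.** Each row is multinomial,
  $x_{i\cdot} \sim \mathrm{Multin}(t_i;\, \pi_{i\cdot})$ with
  $\Pi = LF^T$, where the $n \times K$ matrix $L$ of topic proportions is
  row-stochastic and the $m \times K$ matrix $F$ of topic distributions is
  column-stochastic, and $t_i$ is the observed row total.

* **Poisson NMF.** Each count is independently Poisson,
  $x_{ij} \sim \mathrm{Pois}(\lambda_{ij})$ with $\Lambda = HW^T$ and
  $H, W \ge 0$ unconstrained beyond non-negativity.

The two are the same matrix factorization in different clothing. Writing
$u_k$ for the column sums of $W$ and $s_i$ for the row sums of
$H\,\mathrm{diag}(u)$, the change of variables

$$F = W\,\mathrm{diag}(u)^{-1}, \qquad
  L = \mathrm{diag}(s)^{-1} H\,\mathrm{diag}(u), $$

(implemented by `pnmf_to_mtm()`, with inverse `mtm_to_pnmf()`) satisfies
$\lambda_{ij} = s_i \pi_{ij}$ *exactly*, and the likelihoods factorize as

$$p_{\mathrm{PNMF}}(X \mid H, W) = p_{\mathrm{MTM}}(X \mid L, F)
  \prod_{i=1}^n \mathrm{Pois}(t_i; s_i).$$

`lemma_identity_gap()` evaluates the numerical residual of this identity;
the test suite verifies it at $10^{-8}$ relative tolerance across hundreds
of random instances. The practical consequence: a maximum-likelihood
Poisson NMF fit, pushed through the change of variables, is a
maximum-likelihood topic-model fit (the scale term
$\psi(s) = \sum_i s_i - t_i \log s_i$ is uniquely minimized at $s = t$
when all row totals are positive). The Poisson side has only bound
constraints — no sum-to-one coupling — which is what makes fast
coordinate-wise optimization possible. So the package always optimizes the
Poisson objective

$$\ell(X; H, W) = \sum_{ij} \lambda_{ij} - x_{ij} \log \lambda_{ij},$$

and converts at the end. Zero counts contribute only their $\lambda_{ij}$,
which aggregates in closed form to
$(\mathrm{colsums}\,H)\cdot(\mathrm{colsums}\,W)$; logs are taken only at
stored nonzeros, so every objective evaluation costs
$O(\mathrm{nnz}(X) + (n+m)K)$.

## The alternating driver and its two inner solvers

With $W$ fixed, $\ell$ separates over the columns of $X$ into $m$
independent $K$-dimensional *additive Poisson regressions*
($y \sim \mathrm{Pois}(Ab)$, $b \ge 0$); with $H$ fixed, symmetrically over
rows. Each outer iteration of `fit_poisson_nmf()` updates the loadings
block, then the factors block, solving each subproblem from its current
value with `inner_iter` updates (default 4) of one of:

* **EM** (`em_step()`): the multiplicative fixed-point update
  $b_k \leftarrow b_k \frac{\sum_i y_i a_{ik}/\mu_i}{\sum_i a_{ik}}$.
  It never increases the objective. Applied block-wise with
  `inner_iter = 1`, one outer iteration is *exactly* one round of the
  classic multiplicative updates for Poisson NMF — the package keeps an
  independent dense implementation (`multiplicative_update()`) and the
  tests pin the equivalence at $10^{-13}$ elementwise.

* **CD** (`cd_sweep()`): cyclic coordinate descent with a full feasible
  Newton step per coordinate,
  $b_k \leftarrow \max\{0,\, b_k - g_k/q_k\}$ using the exact first and
  second partial derivatives, updating $\mu$ incrementally. There is no
  line search: an individual sweep may occasionally increase the
  objective, and the driver's best-iterate bookkeeping (below) absorbs
  this. Coordinates are visited in fixed ascending order for determinism.

Both solvers floor every parameter at $10^{-15}$ after each update. This
prevents $\log 0$ and division by zero while perturbing objectives at the
$10^{-15}$ level; it also keeps the parameterization map defined
everywhere. When the curvature $q_k$ vanishes (a response that is all
zeros, or a topic with no support in the design) the likelihood is
maximized at the boundary whenever $g_k \ge 0$, so the coordinate is
parked at the floor; a flat direction with negative gradient is left in
place with a warning. EM has the analogous guard for a zero denominator.

The subproblems within a block are independent, so the block update is
vectorized across them (and would parallelize); the result is identical
under any execution order, which the tests assert against a per-subproblem
reference loop.

First-order optimality is certified by a KKT residual: at interior
entries the gradient must vanish, at floored entries it must be
non-negative. The threshold separating "interior" from "at the bound" is
$10^{-8}$, comfortably above the $10^{-15}$ floor and below any
statistically meaningful loading.

## Extrapolation

The optional acceleration (`extrapolate = TRUE`) maintains an accepted
sequence and a momentum-shifted sequence: updates are computed from the
shifted point $\max(10^{-15},\, \theta + \beta(\theta - \theta^{-}))$, and
the result is accepted only when it improves on the best objective so far.
On acceptance the step size grows ($\beta \leftarrow \min(\bar\beta,
1.05\,\beta)$); on failure the scheme restarts from the best iterate,
shrinks $\beta$ by $1.5$, and caps $\bar\beta$ at the failed value.
Defaults: $\beta_0 = 0.5$, $\bar\beta_0 = 1$, activation at outer
iteration 50 (`extrapolate_start`), all configurable via `control`. These
constants follow the published acceptance-based extrapolation scheme for
block-coordinate NMF; since acceptance is gated on objective improvement,
the returned accelerated fit can never be worse than the best
unaccelerated iterate it branched from, and in practice it converges
substantially faster.

Because the returned fit is always the best iterate visited, the sequence
of returned objectives is non-increasing in `numiter` for every
configuration — EM's monotonicity is a theorem, CD's and the extrapolated
variants' a construction.

## Initialization and stopping

Random starts are elementwise uniform on $(0, 1]$, jointly rescaled so the
mean of $HW^T$ matches the mean of $X$ (scale-matched starts avoid early
over/underflow), then polished by `init_em` plain EM outer updates
(default 10). The prefit always uses EM with `inner_iter = 1`, so solver
comparisons (`compare_fits()`) branch from a shared, method-independent
point — differences in the traces then reflect the solvers, not their
starting points. Stopping is primarily the iteration cap `numiter`;
a relative objective-change tolerance (`tol`, default $10^{-8}$) can end
the loop early and can be disabled with `tol = 0`, which the comparison
functions do.

## MAP estimation

Dirichlet priors on the columns of $F$ (shapes $a_{jk} \ge 1$) and gamma
rate terms $b_k$ on $W$ preserve the equivalence between the two problems.
The penalized objectives (`penalized_pnmf_objective()`,
`penalized_mtm_objective()`) differ, along the change of variables, by
$-\sum_{jk}(a_{jk}-1)\log u_k + \sum_k b_k u_k$ — a function of the topic
scales $u$ alone, independent of $L$, $F$ and $s$. That is precisely why
MAP estimates transfer across the map, and it is the form in which the
package tests the equivalence (constant gap across parameter points
sharing the same $u$). The penalty applies only to the factors block
(uniform prior on loadings); setting $a = 1$, $b = 0$ recovers the
unpenalized objectives exactly, which is asserted as an identity.

## The synthetic-data generators

`simulate_topic_data(n, m, K, doc_size, separation, seed)` draws each
topic distribution as a mixture of a Dirichlet(1) draw over all $m$ terms
and a Dirichlet(1) draw over the topic's disjoint *anchor set* of
$\lceil \mathrm{separation} \cdot m/K \rceil$ terms, with mixture weight
`separation` on the anchors; topic proportions are Dirichlet(1); counts
are multinomial with the given document sizes. `separation = 0` gives
unstructured topics, `separation = 1` disjoint supports; the default 0.8
produces well-separated, identifiability-friendly truth for which
maximum-likelihood recovery is meaningful. `simulate_pnmf_data()` draws
$H$ and $W$ elementwise from a standard exponential, rescaled so the mean
Poisson rate equals `scale`, and samples Poisson counts.

What these generators deliberately do **not** emulate: the burstiness,
heavy-tailed word frequencies, and strong document-length heterogeneity of
real corpora, or the overdispersion and technical dropout of single-cell
data. Passing recovery tests on this synthetic ground truth demonstrates
the optimizer finds the MLE and the MLE finds planted structure; it does
not certify that $K$ topics describe any particular real data set.

Generated sizes used by the tests and the acceptance script (chosen as
comfortable desk-scale problems on which every property is already
informative): identity and reparameterization checks on
$30 \times 40$, $K = 5$ instances; EM monotonicity on
$100 \times 200$, $K = 4$; recovery on $400 \times 100$, $K = 3$ with
document size 1000; solver comparisons on $100 \times 200$, $K = 3$ from a
shared 10-update EM prefit, 100 outer iterations per method.

## Numerical conventions and degenerate input

* All-zero rows or columns of $X$ make document scales or term loadings
  unidentifiable; `fit_poisson_nmf()` refuses such input and
  `validate_counts()` reports exactly which margins to filter. An all-zero
  *count matrix* is rejected outright.
* Real-valued input entries are accepted only within $10^{-9}$ of an
  integer (text formats routinely produce `2.0`), and are rounded.
* Objectives are reported without likelihood constants; the full
  log-likelihoods (`pnmf_loglik()`, `mtm_loglik()`) include every
  constant via log-gamma so the likelihood identity can be tested with
  constants in place.
* Fit serialization writes matrices as CSV with 17 significant digits,
  which round-trips IEEE doubles exactly; `read_fit()` therefore restores
  a fit bit-identically.
* Topic order is arbitrary (the likelihood is invariant to consistent
  column permutations); `match_topics()` resolves it for evaluation by
  exhaustive assignment up to $K = 8$ and greedily beyond.

## Known limitations

Everything runs in-memory on a single thread; the block updates are
schedule-independent by design, so a parallel backend would be a drop-in
change but is not provided. There is no held-out likelihood, no automatic
selection of $K$, and no online/streaming variant. EM-specific
accelerations (quasi-Newton, Anderson-style) are deliberately out of
scope: the coordinate-descent solver with extrapolation is the
recommended configuration.
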