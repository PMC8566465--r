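---
title: "Models and methods for reconstructing first-year molt evolution"
author: "moltevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for reconstructing first-year molt evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moltevol)
```

This vignette is the package's account of the statistical machinery:
the models, their assumptions, the numerical choices, and the places
where the design was genuinely open. The scientific setting is the
evolution of wing flight-feather molt during a bird's first year of
life — a 3-state character (`absent`, `partial`, `complete`, fixed in
that order everywhere in the package) observed at the tips of a
time-calibrated phylogeny with branch lengths in millions of years
(Myr).

## Discrete character evolution: the Mk model

The character evolves along each branch as a continuous-time Markov
chain with generator $Q$ ($k \times k$, off-diagonals $\ge 0$, rows
summing to zero). Transition probabilities over a branch of length $t$
are $P(t) = e^{Qt}$, computed by eigen-decomposition with a
scaling-and-squaring series fallback when the eigenvector matrix is
ill-conditioned (relevant for near-defective ARD generators); entries
are clamped to $[0,1]$ and rows renormalized against round-off.
Zero-length branches get the identity, so polytomies and consensus
trees with collapsed edges are handled without special cases.

Three nested parameterizations are fitted: ER (one rate), SYM
(symmetric, $k(k-1)/2$ rates) and ARD (all rates different, $k(k-1)$
rates), with free rates ordered row-major over the off-diagonal cells.
The likelihood is the pruning (post-order dynamic programming)
algorithm with per-node rescaling; multifurcating nodes take products
over all children. The implementation processes edges in topological
"rounds" so each round is a single vectorized matrix operation — on
bird-sized trees (depth $\sim$ 40 edges) a likelihood evaluation is a
few milliseconds, which keeps the full ER/SYM/ARD comparison on 1,808
tips around a minute.

**Fitting.** Rates are optimized on the log scale with a
box-constrained quasi-Newton method, bounds $[10^{-8}, 10^3]$
Myr$^{-1}$, from a data-informed start (1/tree height) plus 5 random
restarts by default; ARD likelihood surfaces can be multimodal and the
restarts are derived deterministically from the user seed. Monomorphic
tip data are flagged non-identifiable and returned as a boundary fit
rather than an error, so degenerate subsets (e.g. a family tree whose
members all share one strategy) propagate visibly instead of crashing.

**Root prior.** The default is flat (1/3, 1/3, 1/3), matching the
common default of marginal reconstruction software; `stationary` and
`fitzjohn` (root prior proportional to the root conditional
likelihoods) are provided. The choice matters mostly when the chain is
far from stationarity at the root.

**Model choice.** Models are compared by AICc with $n$ = number of
tips — the conventional (if imperfect) effective sample size for Mk
fits. A model is *decisively* selected only when its AICc advantage
over the runner-up exceeds 2.0 (strict); otherwise the
fewest-parameter model within the threshold is returned with
`decisive = FALSE`, so an indecisive comparison is visible in the
output rather than silently resolved.

## Marginal ancestral states

Ancestral posteriors are empirical Bayes: the generator is fixed at
its ML estimate and, for every node $v$,
$P(\text{state}(v) = s \mid \text{data})$ is computed exactly by one
post-order pass (conditional likelihoods of the subtree below each
node) and one pre-order pass (the likelihood of the rest of the tree),
multiplied and normalized. This up-down sweep is mathematically
identical to re-rooting the tree at every node — an equality the test
suite checks against an independent re-rooting implementation — at a
single O(n) cost. Rate uncertainty is *not* propagated; posteriors are
conditional on the point estimate of $Q$, as is standard for this kind
of reconstruction.

## Continuous character: Brownian motion

Body mass is modeled as Brownian motion with rate $\sigma^2$
((trait units)$^2$ Myr$^{-1}$). The tip covariance is
$V_{ij} = \sigma^2 \cdot$ (shared root-to-MRCA path length). The root
estimate is the GLS mean and $\sigma^2$ the ML estimator (1/n
denominator, matching the usual ancestral-state routine rather than
REML); both are computed by a contrast (pruning) recursion —
polytomies are merged pairwise, which leaves the invariants
(log-determinant, residual quadratic form, root estimate) unchanged —
and verified in tests against dense-matrix GLS to $10^{-8}$. Node
estimates come from Gaussian message passing with a flat root prior,
whose per-node means equal the classic re-rooted GLS estimates;
reported node variances are conditional variances scaled by
$\hat\sigma^2$.

Mass is analyzed in raw grams by default — the package reports the
ancestral mass on the scale the descriptive results use — with a
`log10` option recorded in the output, since BM on raw mass allows
negative excursions and is biologically questionable for a strictly
positive, right-skewed trait. Users comparing rate estimates across
studies should prefer the log scale.

## Phylogenetic logistic regression

The binary contrast (complete = 1 vs absent = 0; partial-molt species
are excluded because their molt extent cannot be assigned to either
category) is modeled as a two-state Markov switching process on the
tree with total switching rate $\alpha$ (Myr$^{-1}$): the stationary
probability at tip $i$ is $p_i = \mathrm{logit}^{-1}(x_i'\beta)$, and
the correlation between tips decays as $e^{-\alpha d_{ij}}$ with
patristic distance. Covariates (mass in grams, absolute
mid-distribution latitude in degrees) enter untransformed, so slopes
are per-gram and per-degree.

Two modeling details are worth spelling out:

- **Mean structure.** Covariates exist only at tips, so internal
  branches evolve toward the average stationary probability $\bar p$
  and the pendant branch toward $p_i$. The marginal tip mean is
  therefore $\mu_i = p_i + (\bar p - p_i) e^{-\alpha t_i}$ with $t_i$
  the pendant branch length. The package fits exactly this mean — the
  generative model's true expectation — rather than $p_i$; ignoring
  the equilibration attenuates slopes noticeably when
  $\alpha t_i \lesssim 1$. In the no-signal limit (large $\alpha$, or
  a star tree) $\mu_i \to p_i$ and the estimator collapses to ordinary
  logistic regression, which the acceptance tests verify against
  glm's IRLS to $10^{-3}$.
- **Estimation.** $\beta$ solves the quasi-Fisher scoring equations
  $D'V^{-1}(y-\mu)=0$ with working covariance
  $V = A^{1/2} R(\alpha) A^{1/2}$, $A = \mathrm{diag}(\mu(1-\mu))$,
  with step-halving and explicit refusal of divergent (separated)
  fits; a Firth-type adjusted-residual option exists but is off by
  default, because the penalty would break the exact no-signal
  equivalence with the IRLS MLE. $\alpha$ is profiled on a 12-point
  log grid over $[10^{-6}, 10^3]$ and refined locally against the
  Gaussian working likelihood of the residuals; boundary estimates are
  flagged. Per $\alpha$ the correlation factor is Cholesky-factored
  once, so profiling costs one factorization per grid point.

**Inference.** Every coefficient gets a Wald column
($z = \hat\beta/\mathrm{se}$, two-tailed normal $p$) — the shape of
the classic results table. But under strong phylogenetic correlation
the Wald test breaks down: the effective sample size
$n_\mathrm{eff} = \mathbf 1' R^{-1} \mathbf 1$ can be an order of
magnitude below the tip count (median $\approx 10$ at $\alpha = 0.02$
on 300-tip trees of bird-like depth), and the Wald statistic saturates
because large estimates inflate their own standard errors
(Hauck–Donner effect) — in simulation its null rejection rate falls
to $\sim$0–1% at nominal 5%. The package therefore also reports, per
slope, an efficient-score (Rao) test computed at the constrained fit,
referred to a $t$ distribution with $n_\mathrm{eff} - p$ degrees of
freedom — a standard small-sample correction in the GEE literature.
In 400-replicate null simulations under the generative model this
test rejects at 3–4%; it is the package's recommended slope test, and
the one its own acceptance suite holds to the 3–8% calibration band.

## Synthetic data: what it emulates and what it does not

Every stage has a seeded generative twin, so closing the loop
(simulate, fit, compare to truth) is the core of the test suite:

- `simulate_tree` — constant-rate birth–death conditioned on the tip
  count (via `ape::rphylo`), default speciation 0.075 Myr$^{-1}$
  chosen so a 1,808-tip pure-birth tree has a bird-like crown age
  (the study-like generator rescales depth to exactly 90 Myr).
- `simulate_mk` / `simulate_bm` — exact path simulation of the CTMC
  (exponential waiting times) and of BM increments, both returning the
  latent node truth for recovery tests.
- `simulate_binary_ig10` — the switching process above, sampled from
  the exact endpoint distribution per branch.
- `make_study_like_dataset` — a 1,808-species dataset with the study's
  structure: exact strategy counts 532/217/1,059 (so the regression
  subset is exactly 1,591), 27 orders and 146 families as nested
  clade-ordered blocks with one passerine-like order of 1,130 species,
  exactly 179 species flagged as placed without genetic data, and
  group-specific trait distributions frozen to the empirical
  descriptive statistics — complete-molt mass
  lognormal(2.40, 1.71) truncated to [2.5, 1250] g (mean ≈ 50 g),
  partial+absent mass lognormal(3.90, 2.20) on [4.5, 11000] g
  (mean ≈ 390 g), latitudes from truncated normals on [0, 50]° and
  [0, 90]° with means ≈ 17.5° and 26.7°. Strategies are simulated
  under a Markov chain whose stationary distribution equals the target
  frequencies, then minimally relabeled to the exact counts; masses
  and latitudes are iid draws from the group distributions,
  order-matched to BM latents within strategy groups so they carry
  phylogenetic ordering while sampling the target distributions.

What the generator does **not** emulate: tree-topology uncertainty (a
single tree, not a posterior sample), the joint mass–latitude–strategy
dependence beyond group-wise distributions, non-monophyletic taxonomy
noise, and any BDPR-style placement structure (the flag is assigned at
random). Passing tests on synthetic data therefore demonstrate the
correctness and calibration of the algorithms under the stated models,
not the robustness of empirical conclusions to tree error or trait
measurement error.

## Determinism, problem sizes, and degenerate inputs

All randomness flows from one integer seed through a local RNG helper
that restores the caller's RNG state; reruns of the full pipeline are
byte-identical, which the test suite checks by hashing the report
bundle. The shipped test suite uses brute-force enumeration oracles on
trees of up to 6 tips (exhaustive sums over all internal state
assignments), dense-matrix GLS oracles up to 20 tips, 400-replicate
calibration and 200-replicate recovery simulations at 300–500 tips,
and full-pipeline runs at 1,808 tips — sizes chosen so the whole suite
completes in well under half an hour on one CPU while still exercising
the study-scale path.

Degenerate inputs are handled explicitly rather than by numerical
accident: duplicate or missing species names error with the offending
labels; negative or non-finite branch lengths error at parse time;
monomorphic characters flag non-identifiability; constant continuous
traits return $\sigma^2 = 0$ with an undefined log-likelihood;
separation in the logistic model refuses boundary estimates; ties in
family-state assignment are flagged and broken toward the lowest state
index; and AICc refuses $n \le k+1$.

## Known limitations

- Rate uncertainty is not propagated into ancestral posteriors (no
  integration over $Q$), and tree uncertainty is out of scope: the
  input tree is taken as given.
- The latitude index is the absolute mid-point of the full annual
  range; a molt-period-weighted index for long-distance migrants is
  not formalized — users can supply their own override column.
- AICc uses tip count as $n$; for strongly correlated characters the
  effective sample size is smaller, so decisiveness thresholds should
  be read qualitatively.
- The working-likelihood profile for $\alpha$ is a quasi-likelihood
  device, not a true likelihood; $\alpha$ point estimates are
  well-centered in simulation but their uncertainty is not reported.
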