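---
title: "Inferring microbial association networks with zero-inflated log-normal models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring microbial association networks with zero-inflated log-normal models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zilnet)
```

## The problem

Shotgun metagenomic count tables are difficult raw material for network
inference. Counts are *compositional* — sequencing depth is arbitrary, so
only relative abundances carry information; they are *zero-rich* — at the
species level, well over half of all cells can be zero; and they are
*overdispersed* relative to Poisson sampling. Correlation-style analyses
applied directly to such data confound true ecological associations with
compositional artifacts and zero-handling choices.

zilnet models a sample's taxa jointly through a latent Gaussian vector
$z \sim N(\mu, \Sigma)$. The (unobserved) absolute abundance of taxon $j$ is

$$a_j = \mathbb{1}\{z_j > \delta_j\} \, e^{z_j},$$

so a taxon is truly absent — a *structural* (biological) zero — whenever its
latent coordinate falls below a per-taxon threshold $\delta_j$. Observed
counts are multinomial draws of the sample's library size $N$ on the
relative abundances $\pi_j = a_j / \sum_k a_k$; small $N\pi_j$ additionally
produces *sampling* zeros. The association network is the support of the
precision matrix $\Sigma^{-1}$: a zero partial covariance means conditional
independence given all other taxa.

## The inference pipeline

`ziln()` runs four steps.

**1. Zero-preserving clr transform.** The classical centered log-ratio,
$y^{clr}_{j} = \log y_j - \tfrac1p \sum_k \log y_k$, is undefined at zero,
and the common pseudocount workaround destroys scale invariance — two
samples with identical composition but different depths no longer transform
identically. `zclr()` instead centers each nonzero log count by the mean log
over the *nonzero* entries of its row and maps zeros to exactly zero. This
keeps scale invariance exactly (a property the test suite checks to
$10^{-12}$), at the price of treating zeros as a separate censored class —
which is precisely how the model interprets them.

**2. Marginal fits.** Assuming a diagonal working covariance, each taxon's
transformed values follow a univariate zero-inflated normal. The threshold
MLE is the minimum nonzero transformed value, $\hat\delta_j = \min_{i:
y_{ij}\neq 0} \tilde y_{ij}$. Given $\hat\delta_j$, `fit_marginals()`
maximizes the mixed likelihood — $\log\Phi_{\mu,\sigma^2}(\hat\delta_j)$ per
zero, the normal log density per nonzero value — by BFGS over $(\mu,
\log\sigma^2)$, starting from moment estimates of the nonzero entries.
Optimizing $\log\sigma^2$ enforces positivity; the gradient-free fallback on
optimizer failure is the moment pair with `converged = FALSE`. Taxa without
zeros reduce exactly to the Gaussian MLE; taxa with a single nonzero value
have $\hat\sigma^2$ floored at $10^{-4}$.

**3. Posterior-mean reconstruction.** The latent layer is estimated by the
expectation step of a one-step EM: observed entries are taken as-is, and
each structural zero is replaced by the truncated-normal mean
$E[z \mid z \le \hat\delta_j] = \hat\mu_j - \hat\sigma_j
\phi(\alpha)/\Phi(\alpha)$ with $\alpha = (\hat\delta_j -
\hat\mu_j)/\hat\sigma_j$. The Mills ratio is evaluated on the log scale, so
thresholds far in the lower tail ($\alpha \ll 0$) remain accurate instead of
collapsing to $0/0$; the closed form agrees with adaptive quadrature to
$10^{-8}$ across a wide $(\mu,\sigma,\delta)$ grid in the tests. We do not
rescale the reconstructed matrix's diagonal second moments: increasing the
per-variable variance shifts covariance information out of the off-diagonals
and empirically weakens support recovery, so the plain posterior-mean
reconstruction is used.

**4. Sparse structure estimation.** Two standard estimators run on the
reconstructed matrix: the graphical lasso (blockwise coordinate descent on
the empirical correlation matrix, warm-started along the penalty grid) and
Meinshausen–Bühlmann neighborhood selection (per-node lasso regressions,
equivalent to a penalized pseudo-likelihood maximization — the tests verify
the fixed-penalty support against brute-force minimization of the per-node
objective on a coefficient mesh). Rather than selecting a single graph, the
pipeline retains the whole solution path: an edge that first enters the
support at a large penalty is more reliable than one appearing only under
weak regularization, so `rank_edges()` orders all candidate pairs by
first-entry penalty, breaking ties by edge weight (absolute partial
correlation for glasso, largest absolute regression coefficient for MB) and
then pair index so the order is total and reproducible.

### Numerical and design choices

* **Penalty grid**: 50 log-spaced values from $\lambda_{\max}$ (the largest
  absolute off-diagonal correlation) down to $10^{-2}\lambda_{\max}$. The
  endpoints bracket the empty and the (near-)complete graph on all problems
  we simulate.
* **Column standardization**: latent columns are standardized to zero mean
  and unit *population* (1/n) variance before neighborhood selection, making
  the penalty comparable across taxa and the estimated support invariant to
  column scaling. With unit response variance, glmnet's objective is exactly
  $\frac{1}{2n}\|y - X\beta\|^2 + \lambda\|\beta\|_1$, which is what the
  brute-force equivalence check assumes.
* **MB symmetrization**: union ("or") by default — an edge is kept if either
  of its two regressions selects it — with an "and" flag. The union rule is
  the common default for the MB estimator.
* **Path nesting**: glasso supports along a decreasing grid are only
  approximately nested in floating point. Ranking by *first-entry* penalty
  keeps the edge ordering well-defined even when an edge later drops out.
* **Graphical lasso convergence**: outer sweeps stop when the maximum change
  in the working covariance falls below `tol` times the mean absolute
  off-diagonal of the input (default `tol = 1e-4`); solutions satisfy the
  KKT conditions of the penalized likelihood to the same order (checked in
  the tests). Non-converged grid points are skipped with a warning.
* **All-zero taxa** carry no information and are excluded from inference;
  their pairs are appended to the end of the ranking with score 0 so that
  evaluation still runs over all $\binom{p}{2}$ candidate pairs.
* **Degenerate samples**: a simulated sample whose abundances are all zero
  is redrawn once, then the generator fails loudly — silently dropping
  samples would bias $n$.

## What the synthetic-data generator emulates

The generator reproduces the model's own data-generating process, with
parameters chosen to mimic population-scale shotgun gut metagenomes:

* **Graph**: band, Erdős–Rényi or scale-free topology with the number of
  edges equal to the number of taxa ($e = p$), encoding the assumption that
  associations scale linearly with taxa. Scale-free graphs use preferential
  attachment with one edge per node ($p-1$ edges) plus uniformly random
  extras up to $e$ — an approximation, since exact-$e$ scale-free sampling
  is not uniquely defined.
* **Precision**: each edge receives a weight of magnitude uniform on
  $[0.3, 0.7]$ with random sign; the diagonal is then shifted by the unique
  constant putting the condition number at $\kappa$ (default 100), solved in
  closed form from the extreme eigenvalues. The matrix is *not* rescaled to
  correlation afterwards — rescaling would alter the condition number, which
  is the controlled difficulty knob. The weight distribution is our choice;
  only its support pattern and $\kappa$ are pinned down by the protocol.
* **Marginals**: latent means $\mu_j \sim \mathrm{unif}(0, 3)$; per-taxon
  zero probabilities either $s_j \sim \mathrm{unif}(0, 0.9)$ (the first
  protocol; overall ≈45% zero cells) or the deterministic profile
  $s_j = (j/p)^t$ with $t$ solved so the mean hits a global target
  (the sparsity-sweep protocol). The profile is capped at $s_j \le 0.99$:
  the last taxon would otherwise be deterministically absent for every
  exponent. Thresholds follow as normal quantiles,
  $\delta_j = \Phi^{-1}_{\mu_j,\sigma_{jj}}(s_j)$.
* **Library sizes**: negative binomial with mean $1.5\times 10^6$ and size
  5 — heavy-tailed sequencing depths typical of shotgun data.
* **Comparator generator**: a NorTA (Normal-to-Anything) construction with
  Gaussian copula and zero-inflated negative binomial marginals (means
  $e^{\mu_j}$, size 10, zero mass $s_j$). Unlike the log-normal generator it
  has no multinomial step, hence no compositional constraint.

What it does **not** emulate: real taxonomic correlation structure (truth
graphs are synthetic), taxon-specific overdispersion fitted to a cohort,
sequencing batch effects, or technical zeros from bioinformatic filtering.
Passing tests therefore demonstrate correct recovery *under the model and
its comparator*, not performance guarantees on any particular real cohort.

## Seeding

Every stochastic entry point takes one integer seed. Multi-stage procedures
derive child seeds with `split_seed()` (a seeded draw of 31-bit integers),
so each benchmark cell has an independent, replayable stream and a failure
in one cell cannot shift another cell's data.

## Problem sizes in the shipped checks

The package's own test battery runs the full generate–infer–score loop at
$p = 100$ taxa with $n = 300$ samples (10 replicates, paired transforms) and
a sparsity sweep at $p = 100$, $n = 100$ — sizes at which the qualitative
behavior (posterior-mean reconstruction beats the raw transform;
90%-zero data defeats every method relative to 10%) is already
unambiguous. Larger protocol cells ($p = 500$, $n = 2000$) are reachable
through `run_benchmark()` flags. Marginal-recovery checks use $n = 5000$
with 50 replicates; distribution-level checks use $10^4$–$10^5$ draws.

## Known limitations

* The marginal model is fitted per taxon with a diagonal working
  covariance; the posterior mean therefore ignores cross-taxon information
  when imputing censored entries. A full-covariance E-step is possible but
  much more expensive and is not implemented.
* The fit object ranks edges; it deliberately stops short of selecting one
  graph (no stability selection). Consumers choose a cutoff, e.g.
  `top_edges(fit, k)`.
* Because only diagonal marginals plus a support ranking are estimated, the
  fitted object cannot simulate or predict counts; there are therefore no
  `simulate()`/`predict()` methods for it.
* `zclr()` centers over nonzero entries only; under extreme sparsity few
  entries remain, and the transform (like every clr variant) becomes noisy —
  visible in the sparsity-sweep benchmarks as the universal collapse at 90%
  zeros.

## A worked example

```{r example}
sim <- simulate_dataset(p = 30, n = 200, topology = "erdos_renyi", seed = 3)
mean(sim$data$counts == 0) # overall zero fraction

fit <- ziln(sim$data, method = "mb")
summary(fit)

pr_metrics(fit$edges, sim$graph)
```

```{r plot, fig.width = 5, fig.height = 4}
plot(fit)
```
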