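---
title: "Permutation-invariant multi-output GPs for drug-combination dose-response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation-invariant multi-output GPs for drug-combination dose-response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piicm)
```

## The problem

High-throughput combination screens measure post-treatment cell viability
for pairs of drugs on panels of cancer cell lines, typically on a small
grid of concentrations with a few replicates. The quantity of scientific
interest is the dose-response surface $f(\mathbf{x}) \in [0,1]$ of each
(cell line, drug A, drug B) experiment, and in particular its departure
from a non-interaction reference: synergy (viability below the reference)
or antagonism (above). Because coverage of the cell-line $\times$
combination space is always incomplete, one wants to *predict* the surface
of untested experiments from tested ones, while propagating the
substantial, heteroskedastic measurement error of viability assays.

`piicm` implements a two-stage pipeline for exactly this.

## Stage 1: a Bayesian model per experiment

Each experiment is fit independently with

$$f(\mathbf{x}) = p_0(\mathbf{x}) + \Delta(\mathbf{x}), \qquad
  y_i \sim \mathcal{N}\!\left(f(\mathbf{x}_i),\ \sigma_i^2\right),$$

where the non-interaction surface is the Bliss product
$p_0(\mathbf{x}) = h_1(x_1)\,h_2(x_2)$ of two log-logistic monotherapy
curves

$$h(x) = l + \frac{u - l}{1 + 10^{\,s (x - m)}},$$

with $x$ the log10 concentration, lower asymptote $l \in [0,1]$, upper
asymptote fixed at $u = 1$ (no drug is assumed to promote growth), slope
$s > 0$, and EC50 $m$. The interaction term is a latent zero-mean GP $z$
with a Matérn-3/2 kernel pushed through the bounding transform

$$\Delta = g(z) = \frac{-p_0}{1 + e^{\,b_1 z + \mathrm{logit}(p_0)}}
  + \frac{1 - p_0}{1 + e^{\,-b_2 z - \mathrm{logit}(p_0)}},$$

which maps $\mathbb{R}$ to $(-p_0,\ 1 - p_0)$ so that $f \in (0,1)$
always, is strictly increasing, and satisfies $g(0) = 0$: with no evidence
the model falls back to the Bliss surface. Noise is heteroskedastic,
$\sigma_i^2 = \sigma_0^2 (c_0 + f(\mathbf{x}_i))$, encoding the empirical
fact that viability estimates are far noisier near full viability
(negative-control-like wells) than near full kill.

### Priors and sampler

The priors are weakly-informative choices of this package, kept together
in `stage1_priors()` so they can be swapped wholesale: $l \sim \mathrm{Beta}(1, 1.25)$,
$s \sim \mathrm{LogNormal}(0,1)$, $m \sim \mathcal{N}(0.5, 1)$ on the
unit-box scale, $b_1, b_2 \sim \mathrm{LogNormal}(0, 0.5)$, GP amplitude
$\sim$ HalfNormal(1), GP lengthscale $\sim \mathrm{LogNormal}(0, 0.5)$,
and $\sigma_0, c_0 \sim$ HalfNormal(0.1). The stage-1 kernel is
Matérn with $\nu = 3/2$, the standard rougher-than-squared-exponential
default for interaction surfaces that can change quickly.

No gradient-based MCMC infrastructure (Stan, HMC) is available in the
supported environment, so `fit_single_experiment()` uses a sampler built
from two exact components: elliptical slice sampling of the *whitened*
latent field ($z = L u$, $u \sim \mathcal{N}(0, I)$, $L$ the Cholesky
factor of the GP covariance at the observed combination locations), and
adaptive per-coordinate random-walk Metropolis on the remaining
parameters, with proposal scales tuned during warmup only. Defaults are 4
chains $\times$ 1000 post-warmup draws (4000 total), with a split-$\hat R
< 1.05$ convergence gate reported in the fit's diagnostics — never
silently.

Each experiment's concentrations are rescaled per drug to $[0,1]$ (min
observed log-concentration to 0, max to 1), and the latent GP is sampled
from its posterior predictive on a common equispaced $k \times k$ grid
(default $k = 10$). The posterior mean vector $\bar z$ and variance vector
$\sigma^2$ per experiment are the only quantities stage 2 consumes;
variances are floored at $10^{-6}$ so the stage-2 noise matrix stays
invertible. The unit box is what lets a single input lengthscale serve all
experiments.

## Stage 2: a permutation-invariant multi-output GP

Stage 2 treats each experiment's $\bar z$ as a noisy observation of one
output of a multi-output GP $\zeta$ with intrinsic-coregionalization
structure: covariance across experiments factorizes into a cell-line
kernel times a drug-combination kernel times an input (concentration)
kernel. Both output kernels are "free-form" low-rank matrices
$K = L L^\top + \mathrm{diag}(v)$ learned entry-wise from data; the input
kernel is squared-exponential on the unit box. A shared noise variance
$\sigma^2$ is added to every per-point stage-1 variance — without it a
noiseless multi-output GP degenerates into independent outputs
(autokrigability).

A dose-response surface must not depend on the arbitrary order in which
the two drugs are written: $f(c, A, B, (x_1, x_2)) = f(c, B, A, (x_2,
x_1))$. The model enforces this *in the prior* by symmetrization: with
$\tilde\zeta$ the plain ICM field over the *extended* pair list (canonical
pairs followed by their element-wise mirrors),

$$\zeta(c, A, B, \mathbf{x}) = \tilde\zeta(c, A, B, \mathbf{x})
  + \tilde\zeta(c, B, A, \tilde{\mathbf{x}}).$$

On a reflection-closed grid the induced covariance is, in matrix form,

$$K = K_c \otimes \left[(K_d + P K_d P) \otimes K_x
  + (P K_d + K_d P) \otimes \tilde P K_x\right],$$

with $P$ the pair-block swap and $\tilde P$ the grid reflection. Every row
of $K$ is duplicated under the joint swap, which is exactly why trained
predictions are swap-equivariant to machine precision (a property the test
suite asserts). The plain Kronecker product $K_c \otimes K_d \otimes K_x$
is retained as the `non_invariant` ablation.

### Inference with incomplete data

Experiments never cover all (cell line, pair) combinations, and the
reversed-order copies are *never* observed. Missing columns of the
response matrix are filled with a dummy value $z_0 = -999$ and a dummy
noise $1/\epsilon$ with $\epsilon = 10^{-12}$. Solving the preconditioned
system with $C = \Sigma^{-1/2}$ makes conjugate gradients reproduce the
reduced observed-data solve exactly (asserted at $10^{-6}$ relative
against dense oracles), while only ever touching $K$ through structured
matrix-vector products — two triple-Kronecker products, $O(N_c^2 + (2
N_d)^2 + n^2)$ memory.

The marginal-likelihood log-determinant uses the spectrum of $K$, which is
computable exactly: the positive eigenvalues of $K$ are twice the positive
eigenvalues of $K_c \otimes (P K_d + K_d P) \otimes \tilde P K_x$, and all
three factors are symmetric ($\tilde P K_x$ because the grid kernel is
reflection-invariant), so the spectrum is a cross-product of three small
symmetric eigenproblems. The identity is not taken on faith: the test
suite checks the full eigenvalue multiset against dense eigendecompositions
on 20+ randomized instances. For partial observation the $N$ eigenvalues
are scaled by $M/N$, the top $M$ kept, and paired with the sorted observed
noise entries (largest eigenvalue with smallest noise) inside
$\sum \log(\lambda_k + s_k)$ — a Weyl-type approximation. Several pairing
conventions are defensible; ours is chosen so that the fully observed
homoskedastic case is *exact* (also asserted), and it is validated by
closeness to dense log-determinants on small heteroskedastic instances.

### Optimization

All positive parameters are softplus-reparameterized; $\ell$ and $\sigma$
start at $\mathrm{softplus}(0) = \log 2$, factor entries at
$\mathcal{N}(0, 0.1^2)$, so both output covariances start near-diagonal.
Training maximizes the marginal likelihood with Adam (learning rate 0.1),
stopping after 50 stalled steps at relative tolerance $10^{-5}$.

Autodiff frameworks differentiate straight through the CG solve; R has no
automatic differentiation, so gradients are assembled from the
identity $\partial_\theta\, z^\top A^{-1} z = -\alpha^\top (\partial_\theta
A) \alpha$ (one CG solve per step, operator differences by central finite
differences) plus finite differences of the CG-free log-determinant term.
Two numerical consequences are worth recording. First, the conventional
CG tolerance $0.1\,M/N$ (scaled by the observed fraction) is far too loose
to difference across — it is only consistent when the solver itself is
differentiated — so training internally tightens the tolerance to
$\le 10^{-6}$; the loose scaled default remains the documented behaviour
for plain likelihood evaluation. Second,
the FD step (default $10^{-3}$) is kept two orders of magnitude above that
tolerance. Both points were found the hard way: with the loose tolerance
the invariant variant reproducibly stalled at parameters far below the
likelihood of the generating truth.

### Prediction and evaluation

Held-out experiments are predicted by GP imputation,
$\widehat{\mathrm{vec}(Z)} = K (K + \Sigma)^{-1} \mathrm{vec}(Z)$ — one CG
solve for all targets; per-point predictive variances are opt-in ($n$
extra solves per target). A predicted surface is reconstructed as
$\hat f = \hat p_0 + g(\bar\zeta_*)$ where $\hat p_0$ comes from
monotherapy data alone and $(b_1, b_2)$ — not estimable without the
held-out combination data — are aggregated as the unweighted mean of
per-experiment posterior means across training fits (a per-pair option
exists; the aggregation rule is a genuinely open design choice).

The headline metric is the inverse-variance-weighted RMSE with normalized
weights; Pearson correlation is secondary. Train/test splits sample
experiments (floor rounding), and rank selection for $(r_c, r_d)$ uses
k-fold cross-validation over experiments with ties broken toward smaller
$r_d$ then $r_c$.

## The synthetic world

Two generators make the package testable without any external data.

`simulate_stage2_dataset()` draws latent fields directly from the stage-2
generative model (dense sampling, hence capped at $N \le 5000$),
symmetrizes them so the swap identity holds to machine precision, and
observes them with per-entry log-normal variances (median 0.05) plus a
shared $\sigma^2 = 0.01$. Its defaults — $N_c = 3$, $N_d = 4$, $k = 4$ —
are the desk-scale world used throughout the tests. The
`synergy_in_block` setting gives a subset of pairs a strong shared latent
factor (loading 1.2 in the first column of $L_d$, both orderings),
mimicking a screen where a few mechanistically related combinations are
jointly synergistic; `independent` draws generic low-rank structure;
`none` collapses the latent field to (numerically) zero. Bliss surfaces
from random monotherapy parameters ($l \in [0, 0.6]$, $s \in [0.5, 3]$,
EC50 inside the box — realistic sigmoid coverage, not taken from any
source) turn latent truths into dose-response truths, and "stage-1-style"
observed surfaces are produced by pushing the noisy latent through the
transform with delta-method variances.

`simulate_viability_screen()` generates replicate-level raw viability from
the full stage-1 chain on the standard design (4 $\times$ 4 combination
grid in 4 replicates, 8-point monotherapies in 4 replicates), with noise
$\mathrm{sd} = \sigma_0 \sqrt{c_0 + f}$, $\sigma_0 = 0.08$, $c_0 = 0.3$ —
residual sd $\approx 0.05$ at full kill and $\approx 0.09$ at full
viability, typical of normalized ATP-based assays.

What the generators deliberately do *not* emulate: plate and edge effects,
control-well normalization artifacts, non-Gaussian outliers, and drug- or
cell-line-specific covariate structure. A green end-to-end test therefore
establishes that the pipeline recovers structure *its own model class
generated*, under realistic noise and masking — not that it would match
any particular published screen.

## Numerical choices and degenerate inputs

* Eigenvalues with $|\lambda| \le 10^{-10} \lambda_{\max}$ are treated as
  zero in the positive-part operation; factor matrices failing PSD by more
  than $10^{-8}$ relative are rejected.
* Dense materialization of $K$ is refused above $N = 5000$.
* $p_0$ at 0 or 1 makes the transform's log-odds undefined: stage-1 code
  clamps to $[10^{-12}, 1 - 10^{-12}]$ internally; the user-facing
  reconstruction clamps to $[10^{-6}, 1 - 10^{-6}]$ with a warning.
* Stage-1 variance floor $10^{-6}$; CG refuses non-positive noise.
* A screen with zero cell lines or pairs is rejected at assembly; with all
  data masked the likelihood is constant (and the gradient exactly zero).
* Duplicate concentration pairs within an experiment are kept as replicates
  at the same latent location; stage-2 summaries live on the snap-free
  common grid, so no tie-breaking is needed there.
* Seeds: stage-1 chains derive per-experiment seeds by hashing the
  experiment key with the global seed, so screen-level fits are
  reproducible and order-independent.

## Known limitations

* Cold-start prediction (new drugs, pairs, or cell lines) is structurally
  impossible with free-form output kernels — there are no covariates to
  extend the covariance with; the code refuses rather than extrapolates.
* The finite-difference/one-solve gradient scheme is tuned for desk-scale
  problems (tens of parameters, $N$ in the thousands); the published scale
  (hundreds of thousands of parameters) would need an autodiff backend,
  which the operator-level design permits but this package does not ship.
* The stage-1 random-walk sampler mixes more slowly than gradient-based
  MCMC; the default draw budget compensates at the cost of wall time
  (seconds to tens of seconds per experiment at $k = 10$).
* Eigen-pairing in the log-determinant approximation is exact only in the
  homoskedastic fully observed case; elsewhere it is an approximation
  controlled by the test-suite comparisons, not a bound.
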