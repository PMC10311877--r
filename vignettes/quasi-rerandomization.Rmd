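---
title: "Quasi-rerandomization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-rerandomization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In an observational study the treated and control groups differ
systematically on observed covariates, so the raw difference in mean
outcomes confounds the treatment effect with covariate imbalance. The
classical design-stage remedy is to reweight (or match) units so the
reweighted data resemble a randomized experiment — but most balancing
weights leave unstated *which* randomized experiment they emulate.

`qrer` makes that target explicit: the emulated experiment is
**rerandomization**, the accept/reject scheme that redraws a complete
randomization until the Mahalanobis distance between arm covariate means

$$D(X, \tilde T) = \frac{N_1 N_0}{N}\,
  \Delta(\tilde T)^\top\, \widehat{\mathrm{cov}}(X)^{-1}\, \Delta(\tilde T),
  \qquad \Delta(\tilde T) = \bar X_1 - \bar X_0,$$

falls below a threshold $a$ solving $P(\chi^2_d \le a) = p_a$. Because
rerandomization needs only covariates, it can be run on observational
data: the accepted allocations provide an *anchor distribution* of
covariate mean differences that well-balanced data should exhibit.

## The method

Sample weights $W = (W_1, W_0)$ live on two simplices (each arm's block
sums to one). Raw weights are drawn from flat Dirichlet distributions and
pushed through a learned transformation $G(W \mid \theta)$ — a
multilayer perceptron with two ReLU hidden layers of width 512, dropout
0.5 after each, and two separate softmax heads of sizes $N_1$ and $N_0$,
so outputs are valid simplex pairs by construction. Training aligns the
distribution of weighted mean differences $\Delta(\tilde W)$ with the
anchor distribution $\Delta(\tilde T)$ by minimizing a radial-basis-kernel
maximum mean discrepancy (the biased V-statistic form, square-rooted),
plus two regularizers:

* $\mathcal R_1$: squared distances of each weighted arm mean from the
  pooled covariate mean — the balance identities a rerandomized
  allocation satisfies approximately;
* $\mathcal R_2$: squared distances of the weight blocks from the uniform
  weights $1/N_1$, $1/N_0$ — a guard against extreme weights.

The objective is $\mathcal L_{\mathrm{MMD}} + \lambda_1 \mathcal R_1 +
\lambda_2 \mathcal R_2$ with $\lambda_1 = \lambda_2 = 1$ by default. The
kernel bandwidth $\gamma$ is adversarial: after each Adam step on
$\theta$, one Adam ascent step is taken on $\log\gamma$ to *maximize* the
MMD, using the pairwise-distance matrices already computed for the
$\theta$ step (recomputing them after the update would double the cost of
every iteration without changing the alternating-optimization character).
$\gamma$ is initialized by the median heuristic — the reciprocal of the
median pairwise squared distance among a first batch of anchor deltas — a
standard scale-aware choice.

Training follows three phases:

1. **Identity initialization** — `n_init = 500` full-batch Adam steps
   minimizing the mean squared error between $\log W$ and $\log G(W)$
   over a fixed pool of `b_init = 1000` Dirichlet draws, nudging $G$
   toward the identity map before the distributional objective takes
   over. The optimizer state is reset afterwards.
2. **Minibatch training** — up to `n_train = 5000` iterations; each uses
   `batch = 512` allocations resampled *with replacement* from a
   pre-generated pool of `b_loss = 10000` accepted allocations, and 512
   fresh Dirichlet draws.
3. **Early stopping** — every `eval_every = 100` iterations the
   Kolmogorov–Smirnov statistic between weighted Mahalanobis distances
   $\{D(X, \tilde W^{(b)})\}$ and anchor distances
   $\{D(X, \tilde T^{(b)})\}$ is computed on fixed pools of
   `b_stop = 1000` vectors; training stops after `n_stop = 15`
   evaluations without an improvement of at least `1e-4`, and the
   parameters achieving the best metric are kept (`keep_best = FALSE`
   returns the final iterate instead, useful when a strong regularizer
   deliberately sacrifices the balance metric). Per-iteration
   evaluation would make a 15-step patience window hypersensitive to SGD
   noise, hence the 100-iteration cadence (exposed in the
   configuration).

The weighted Mahalanobis distance plugs weighted moments into the
allocation formula, with pooled weights
$W^*_i = \{N_1 T_i + N_0 (1 - T_i)\} W_i / N$ and the covariance
normalizer $1/(1 - \sum_i W^{*2}_i)$; under uniform weights it reduces
exactly to $D(X, T)$, a property the test suite checks.

## Why dropout stays active at generation time

The identity initialization is deliberately gentle (Adam at learning rate
$10^{-3}$ for 500 steps cannot drive a 512-wide network all the way to
the identity on a 500-dimensional simplex), so after training, much of
the generator's output diversity is carried by the dropout noise rather
than by the Dirichlet input. Concretely, on a fitted scenario-1 dataset
the spread of $\Delta(\tilde W)$ with dropout active matches the anchor
spread almost exactly, while a dropout-free forward pass collapses the
spread by a factor of five and pushes the distance distribution far below
the anchor's. We therefore keep dropout **active** during weight
generation and in the stopping metric — the same stochastic forward pass
used in training, and the default behavior of the deep-learning
frameworks this architecture originates from, where inference-time
deactivation is an explicit opt-in. The `dropout_active` flag exposes the
deterministic variant for users who want a pure function of the Dirichlet
draw.

## Estimation

For outcomes $Y$ observed under the actual allocation, the single-vector
estimator is the weighted difference in means
$\hat\tau(\tilde W) = \sum_i \tilde W_i T_i Y_i -
\sum_i \tilde W_i (1 - T_i) Y_i$; the ensemble estimator averages $M$
generated vectors, which — by linearity — equals the single-vector
estimator applied to the averaged weight vector. `estimate_effect()`
obtains the same point estimate from a weighted linear regression of the
outcome on the treatment indicator with case weights proportional to
$W^*$, and reports a heteroskedasticity-robust (HC1 by default) sandwich
standard error with normal-quantile confidence limits; with uniform
weights this degenerates to ordinary least squares. Normal rather than
$t$ quantiles are used, consistent with the sandwich asymptotics at the
sample sizes involved.

## The synthetic benchmark

`simulate_qrer_study()` generates the study conditions the package is
evaluated under: $N_1 = 250$ treated and $N_0 = r \cdot 250$ controls
($r \in \{1, 2\}$), four Gaussian covariates distributed
$N(\mu, \Sigma)$ among treated and standard normal among controls, with
three scenarios — homogeneous variance ($\mu = (0.2, 0.2, 0.5, 0.5)$,
$\Sigma = I$), heterogeneous variance ($\mu$ scaled by $\sqrt{1.5}$,
$\Sigma = 2I$), and correlated treated covariates
($\Sigma = 1.5 I + 0.5\,\mathbf 1 \mathbf 1^\top$) — plus two Bernoulli
pairs with rates $0.1 + 0.068\,T$ and $0.4 + 0.242\,T$. Every covariate
has a true standardized mean difference of 0.2 or 0.5, i.e. meaningful
imbalance. Outcomes follow $Y = g(X) + \tau T + \varepsilon$ with
$\tau = 1$, standard normal noise shared across three response surfaces
(linear, interaction, polynomial) computed from the **raw** covariates;
covariates are standardized afterwards and only the standardized copies
feed the balancing methods. This ordering matters: generating responses
from standardized covariates would change every RMSE magnitude. The
$r = 2$ control pool is generated in full and the $r = 1$ dataset keeps
its first 250 controls, so paired datasets are nested row-for-row.

What the generator does **not** emulate: real covariate measurement
error, heavy-tailed or discrete-mixed outcomes, treatment-effect
heterogeneity, unobserved confounding beyond what the response surfaces
leave out of the covariate set, and any clustering or temporal structure.
Passing benchmarks on these conditions therefore demonstrates correctness
of the machinery under the stated generative model, not robustness on
arbitrary real data.

## Numerical choices

* The sample covariance uses the $N-1$ denominator everywhere, which
  makes the uniform-weight reduction of the weighted distance exact.
* A singular covariate covariance is an error, never a silent
  pseudo-inverse (that would change the null distribution of $D$); an
  explicit `ridge` argument adds $\varepsilon I$ on request.
* The dense network algebra runs in single precision (it is GEMM-bound;
  a full fit is about 2.5 minutes on one CPU core), but the three MMD
  kernel sums are accumulated in double precision — the loss is a small
  difference of large sums and float accumulation cannot resolve it —
  and the softmax outputs are renormalized in double precision so weight
  blocks sum to one within `1e-12`.
* All randomness (parameter initialization, Dirichlet draws, dropout
  masks, allocation subsampling) is drawn from R's RNG on the R side and
  passed into the compiled core, so a single `set.seed()` makes training
  bit-reproducible on one thread.
* Softmax outputs are floored at `1e-12` inside the logarithmic
  initialization loss as a defensive measure.
* Accept/reject sampling is guarded by a probe-based acceptance-rate
  floor (`1e-4`) so a pathological covariate geometry cannot loop
  forever.
* `sign(0) = 0` in the interaction surface (a measure-zero event).

## Problem sizes used in the shipped checks

The test suite and the acceptance script reproduce the rerandomization
RMSE cells at the full 200 replicates (no training involved; seconds per
cell). For the trained quasi-rerandomization cells we use
`n_train = 2000` with the default early-stopping rule and a small number
of replicates (5 in the acceptance script, 5 in the test suite), which is
the package's chosen trade-off between Monte-Carlo precision and a test
run that completes in minutes; the tolerance applied to those cells
scales with the Monte-Carlo standard error of the reduced run. A full
200-replicate training benchmark is an overnight job
(`run_qrer_benchmark()` with `n_reps = 200`) and reproduces the reported
cells with the printed Monte-Carlo standard errors.

## Known limitations

* The generator input dimension is tied to the sample size $N$, so a
  fitted model applies only to the dataset it was trained on — by
  design, as the weights are a property of the design stage of that
  study.
* With very small acceptance probabilities the anchor pool generation
  dominates runtime; `p_a` below about $10^{-3}$ is impractical without
  replacing the accept/reject engine.
* The PATE standard error treats the (averaged) weight vector as fixed;
  variability of the generator itself is not propagated. The ensemble
  over $M = 1000$ draws makes this a second-order effect for the point
  estimate, but coverage for single-vector estimates is conservative in
  some cells and anticonservative in others, as for most weighting
  estimators.
* Binary covariates are treated as numeric in the Mahalanobis metric,
  exactly as in the rerandomization literature the method targets.
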