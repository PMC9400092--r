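---
title: "Inferring energy landscapes from noisy trajectories: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring energy landscapes from noisy trajectories: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skipper)
```

## The generative model

`skipper` infers a potential-energy landscape $U(\cdot)$, a friction
coefficient $\zeta$, a measurement-noise variance $\sigma^2$, and the latent
path $x_{1:N}$ jointly from a recorded trajectory $y_{1:N}$. The model has
three layers.

**Dynamics.** The particle is overdamped: inertia is negligible on the
sampling time scale, so velocity is force over friction plus thermal noise.
Discretized by forward Euler at the sampling interval $\Delta t$,

$$x_{n+1} \mid x_n \sim \mathcal N\!\left(x_n + \tfrac{\Delta t}{\zeta}
f(x_n),\; \gamma^2 I\right), \qquad
f(x) = -\nabla U(x), \qquad
\gamma^2 = \frac{2\,kT\,\Delta t}{\zeta}.$$

The per-step variance $\gamma^2$ follows from the fluctuation–dissipation
relation: the diffusion coefficient is $kT/\zeta$. The first position gets
the zero-mean prior $\mathcal N(0,\, 2\Delta t\, kT/\zeta)$ — the same
$\zeta$-dependent variance as a single dynamical step — so that the friction
conditional keeps a single closed multiplicative form. (A fixed-variance
alternative $\Theta^2$ exists in the configuration for completeness but is
not used by the sampler; with any realistic $N$ the first-point prior is
irrelevant to the posterior.)

**Measurement.** Each recorded point is the true position plus independent
Gaussian noise, $y_n \sim \mathcal N(x_n, \sigma^2 I)$. Noise is assumed
white (no lag correlation) and stationary; `noise_from_difference()`
implements the standard dual-detector calibration check of exactly these
assumptions (Gaussianity of the difference trace, additivity of the two
variances, flat autocorrelation beyond lag zero).

**Potential prior.** $U$ is nonparametric: values $u_{1:M}$ at a fixed grid
of inducing points carry a Gaussian-process prior $\mathcal N(0, K)$ with a
squared-exponential kernel $k(x,x') = h^2 \exp(-|x-x'|^2/2\ell^2)$.
Everywhere else the potential and the force are kernel interpolants,

$$U(x) = K^\dagger K^{-1} u_{1:M}, \qquad
f_k(x) = K^{*k} K^{-1} u_{1:M}, \qquad
K^{*k}_{im} = \frac{h^2}{\ell^2}\,(x_i^k - x_m^{u,k})
\exp\!\left(-\tfrac12 \frac{|x_i - x^u_m|^2}{\ell^2}\right),$$

with $K^{*} = -\,\mathrm d K^\dagger/\mathrm d x$ the derivative
cross-covariance. Because the inducing grid never moves, $K$ is factorized
once per run; only the cross-covariances are rebuilt as the latent path
moves. That asymmetry is the package's central performance contract and the
reason inference scales to $5\times10^4$-point trajectories: cost per sweep
is $O(N M)$ for kernel work plus $O(N M^2)$ BLAS, never $O(N^3)$.

We compute the cross-covariances exactly from the formulas above rather
than through sparse local-interpolation weights; at the grid sizes used here
(tens of points per dimension) the exact form is both cheap and simpler to
verify against finite differences.

## The Gibbs sweep

One sweep updates, in order:

1. **Positions** — sequential single-site Gaussian random-walk
   Metropolis–Hastings over $n = 1..N$ (compiled). The site conditional is
   the product of at most three terms: the transition into $x_n$, the
   transition out of it, and the measurement density. It is not Gaussian
   (the force depends on $x_n$), hence MH rather than an exact draw.
2. **Potential** — the transition likelihood, rewritten in force space, is
   linear-Gaussian in $u_{1:M}$, so the conditional is an exact multivariate
   normal: precision $K^{-1} + \Lambda$ with
   $\Lambda = \frac{\tau}{2\zeta kT} K^{-1} K^{*T} K^* K^{-1}$ and
   information vector $b = \frac{\tau}{2kT} K^{-1} K^{*T} v$, where
   $v_n = (x_{n+1}-x_n)/\tau$. One Cholesky of the $M \times M$ precision
   per sweep gives both the mean and the draw.
3. **Friction** — the conditional (Gamma prior times the first-point prior
   times all transitions) is a generalized-inverse-Gaussian-shaped density
   with no standard sampler in base R; we use log-scale random-walk MH. The
   sufficient statistics ($\sum|\Delta x|^2 + |x_1|^2$, $\sum|f|^2$, count)
   make each MH step O(1).
4. **Noise variance** — conjugate: an exact
   $\mathrm{InvGamma}(\alpha_{\sigma^2} + ND/2,\; \beta_{\sigma^2} +
   \tfrac12\sum|x_n - y_n|^2)$ draw, the shape counting every scalar
   residual across dimensions and trajectories.

**Multiple trajectories** share $u$, $\zeta$, $\sigma^2$; each keeps its own
latent path. Their likelihoods contribute additively to $b$, $\Lambda$, and
the friction and noise statistics. This is what makes ensembles of short
non-equilibrium traces (all launched from a barrier top) informative about
the full landscape: each trace sees one basin, the pool sees both.

**Multi-dimensional trajectories** are handled by flattening per-time,
per-dimension arrays with dimension running fastest (row $(n-1)D + d$), and
assembling the force cross-covariance rows in the same order, after which
the one-dimensional algebra applies verbatim. The packing is checked
against a dense per-dimension construction of the product likelihood in the
test suite; the round trip `flatten_multidim()` /
`unflatten_multidim()` is exact by construction.

**Initialization** is $x^{(0)} = y$, $u^{(0)} = 0$, and prior means for
$\zeta$ and $\sigma^2$. Overdispersed starts are available by varying the
seed. Proposal scales (positions and log-friction) adapt toward a 0.35
acceptance rate during burn-in only, preserving detailed balance afterwards;
position updates sweep sequentially.

## Tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| `dt` | ms | 0.01 | 100 kHz sampling, typical of quadrant-photodiode detection |
| `zeta` | kT·ms/nm² | 2e-3 | gives D = kT/ζ = 500 nm²/ms, a desk-scale bead in water; relaxation time ζ/k ≈ 0.4 ms in the default well |
| `h2` | kT² | 25 | prior sd 5 kT: permissive for landscapes up to ~10–15 kT of relief |
| `ell` | nm | 10 | resolves features at the 10 nm scale of the benchmark wells without chasing noise |
| `m` | – | 50 (1D), 30×30 (2D) | grid spacing well below `ell` over the data range ± 3`ell` |
| `alpha_zeta, beta_zeta` | – | 2, 1000 | weak Gamma prior, mean 2e-3, relative sd 71% |
| `alpha_sigma2, beta_sigma2` | – | 2, 25 | inverse-gamma with mean 25 nm² (σ = 5 nm) and infinite variance — nanometre-scale detector noise |
| `sweeps / burnin / thin` | – | 5000 / 2000 / 5 | conservative defaults; the benchmarks below state what they actually used |

Kernel hyperparameters are fixed per run, not sampled: there is no
hyperprior in the model, and profiles over `h2`, `ell` are cheap to explore
by rerunning. All of the above live in `skipper_config()` and are
overridable from the CLI.

## What the synthetic generator emulates — and what it does not

`simulate_trajectory()` + `add_measurement_noise()` generate exactly the
model above: forward-Euler Langevin dynamics plus white Gaussian
measurement noise. The shipped scenario families mirror the benchmark
landscape classes: a harmonic well (stiffness 0.005 kT/nm²), a symmetric
quartic double well (10 kT barrier, minima at ±75 nm — the barrier height is
a stated design value; the quartic form and minima locations are this
package's choice, matching the length scale of nm-axis figures), a 13×13
pixel-grid "winky face" of Gaussian wells (10 nm pixels, features ~2 kT
deep, ≥20 kT walls; the pixel layout itself is illustrative), and
"roll-off" ensembles of 100 × 500-point traces launched at a barrier top
with modest (2 nm) noise.

Because the generator *is* the inference model, passing benchmarks
demonstrates correctness of the implementation and identifiability under
realistic sizes — not robustness to model misspecification. Real detectors
have drift, slightly non-Gaussian tails, and feedback-trap potentials
deviate from their design; none of that is emulated. The dual-detector
calibration statistics and the Boltzmann baseline are the tools the package
offers for checking a real dataset against the model's assumptions.

The simulator warns when `dt * stiffness / zeta > 0.1` (forward Euler
becoming inaccurate) and aborts, naming the step, if a trajectory leaves a
configurable bound — the symptom of a time step too coarse for the local
curvature.

## Numerical choices

* **Jitter.** `1e-8 * h2` is added to the diagonal of $K$ before
  factorization, escalating tenfold to at most `1e-4 * h2`, after which the
  run aborts with advice (larger `ell`, fewer inducing points). SE kernels
  on fine grids are near-singular by nature; interpolation error at the
  inducing points stays at jitter level.
* **Conditional precision factorization** retries with escalating jitter on
  the same schedule, relative to the diagonal scale.
* **Offset identifiability.** The dynamics see only potential differences,
  so the absolute level of $U$ is fixed by the prior mean (0) and reverts
  to it away from data. Summaries therefore offer `align = "min"` (each
  retained curve shifted so its minimum is 0, then the mean curve pinned at
  0), matching the usual display convention; the Boltzmann baseline pins its
  minimum occupied bin to 0 kT the same way.
* **Barrier heights** are read off the posterior-mean curve on its
  evaluation grid: the two deepest local minima, the largest interior
  maximum between them, ties broken leftmost; the estimate is the interior
  maximum minus the mean of the two minima. No smoothing is applied before
  extremum-finding.
* **Empty bins** in the Boltzmann estimator get `NA` energy and are carried
  with an `occupied` flag rather than dropped, so 2D displays can mask
  never-visited cells (and cells more than 5 kT above the minimum) exactly.
* **Determinism.** Every random step flows through R's RNG, including the
  compiled position sweep, so a single seed fixes simulation and chain
  exactly; storage thinning does not consume RNG and therefore cannot
  perturb the chain.

## Benchmark problem sizes

The test suite and `scripts/acceptance.R` run scaled-down versions of the
benchmark designs, chosen once for single-CPU desk runtimes:

* noise recovery: 10,000 points, 500–800 sweeps;
* barrier recovery: the full 100 × 500 roll-off design, 300–400 sweeps;
* curvature-under-noise comparison: 20,000 points at σ = 10 nm, 800 sweeps,
  curvature fitted over ±30 nm (≈ two position standard deviations, the
  region the particle actually samples);
* calibration: 50 replicate fits of 500 points, 1,200 sweeps each;
* conditional-vs-oracle checks: toys of N ≤ 4, M ≤ 6 against dense grid
  quadrature and completing-the-square algebra;
* a joint-consistency (Geweke-style) run alternating conditional updates
  with data regeneration on an N = 10 toy, whose stationary marginals for
  $\zeta$ and $\sigma^2$ are their priors.

## Known limitations

* The potential must be time-independent and the noise Gaussian and white;
  both are model assumptions, not options.
* Kernel hyperparameters are not learned; a badly mismatched `ell` will
  oversmooth or overfit, and the only remedy is rerunning.
* Single-site position updates mix slowly when `sigma^2` is much larger
  than the per-step dynamical variance; the friction chain inherits that
  autocorrelation. Budget sweeps accordingly (the calibration benchmark is
  the guide).
* The absolute energy scale is prior-anchored; only differences are data.
* 2D inference is limited by the inducing-grid size ($M^3$ factorization
  once, $M^2$ per sweep); 30×30 is comfortable, much beyond that is not the
  intended regime.
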