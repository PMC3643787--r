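---
title: "Ball-and-stick modelling of diffusion MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ball-and-stick modelling of diffusion MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ballstick)
```

## The model

Diffusion-weighted MRI sensitises the image contrast to water diffusion along
an applied gradient direction. In white matter diffusion is anisotropic —
water moves preferentially along axons — so the directional signal profile in
a voxel carries information about the local fibre orientations. The
ball-and-stick model explains the voxel signal with one isotropic compartment
(the *ball*) and $L$ perfectly anisotropic compartments (the *sticks*):

$$
S_i = S_0\left[\Big(1-\sum_{j=1}^{L} f_j\Big)\,e^{-b_i d}
      + \sum_{j=1}^{L} f_j\, e^{-b_i d\, (\mathbf{r}_i\cdot\mathbf{x}_j)^2}\right],
\qquad
\mathbf{x}_j = (\sin\theta_j\cos\phi_j,\ \sin\theta_j\sin\phi_j,\ \cos\theta_j),
$$

where $S_0$ is the unweighted baseline signal, $d$ the diffusivity (mm²/s),
$b_i$ the $i$-th measurement's b-value (s/mm²), $\mathbf{r}_i$ its unit
gradient direction, and $f_j \in [0,1]$ (with $\sum_j f_j \le 1$) the volume
fraction of stick $j$. The model has $R = 3L+2$ free parameters. The stick
orientations enter only through $(\mathbf{r}\cdot\mathbf{x})^2$, so each
orientation is *axial*: $\mathbf{x}$ and $-\mathbf{x}$ are indistinguishable,
and all orientation summaries in this package are therefore dyadic
(sign-free). Angles are stored unconstrained and mapped onto the sphere; no
canonical hemisphere is enforced inside the model, only in summaries.

Internally the compartment sum is accumulated as
$e^{-b d} + \sum_j f_j\,(e^{-b d (\mathbf r\cdot\mathbf x_j)^2} - e^{-b d})$,
which is algebraically identical but returns exactly $S_0$ at $b=0$ in
floating point, so the "no diffusion weighting" limit holds to the last bit.

## Two-stage inference

Inference follows the classic two-stage pipeline used for voxelwise
ball-and-stick inversion:

1. **Levenberg–Marquardt (LM)** minimises the sum of squared residuals and
   provides the starting point. Constraints are enforced by optimising in a
   transformed space: $S_0 = u^2$ and $d = u^2$ (non-negativity),
   $f_j = \sin^2 u$ (unit interval), with $\sum f_j \le 1$ restored by
   rescaling after each accepted step. The damped normal equations use
   Marquardt scaling ($\lambda\,\mathrm{diag}(J^\top J)$), with
   $\lambda_0 = 10^{-3}$, up-factor 10, down-factor 0.1 — the classic
   schedule. Iteration stops when the relative sum-of-squares improvement of
   an accepted step falls below `ftol` ($10^{-9}$ by default), when `max_iter`
   (200) is reached, or when the damping has grown past $10^{12}$ without an
   improving direction (a stationary point). The accepted sum-of-squares
   sequence is non-increasing by construction and is returned as a trace. How
   the LM stage itself is seeded is an open design choice; this package uses a
   log-linear diffusion-tensor fit (mean eigenvalue for $d$, principal
   eigenvector for the first stick, fractional anisotropy clipped to
   $[0.01, 0.95]$ for $f_1$, remaining eigenvectors with $f_j = f_1/(j+1)$ for
   further sticks), falling back to an isotropic initialisation when the
   tensor system is singular.

2. **Random-walk Metropolis MCMC** estimates the posterior of all $R$
   parameters. Each iteration updates the parameters one at a time in a fixed
   order — $S_0$, $d$, then per stick $f$, $\theta$, $\phi$ — with Normal
   proposals. The measurement-noise variance is marginalised analytically
   under a noninformative prior, giving the log-likelihood
   $-\tfrac{K}{2}\log \mathrm{SSR}$ (floored at $\mathrm{SSR} = 10^{-12}$ so a
   perfect fit cannot diverge). Priors are minimal and noninformative: flat on
   $S_0 \ge 0$, flat on $d \ge 0$, flat on the volume-fraction simplex, and
   uniform-on-sphere for each orientation, implemented as
   $\log\lvert\sin\theta_j\rvert$ (the absolute value extends the density
   periodically, since angles are unconstrained; on $[0,\pi]$ it is the usual
   $\sin\theta$ density). These forms are stated assumptions, not a reproduction
   of any particular toolbox's prior file.

Defaults follow the standard whole-brain settings: burn-in 3000 iterations,
1250 post-burn-in jumps, thinning 25 — hence $\lfloor 1250/25\rfloor = 50$
retained samples per parameter. Burn-in and thinning are conventional printed
settings; the jump count is a tool default chosen to match the conventional
overall iteration budget.

**Proposal adaptation.** During burn-in only, every 40 iterations each
proposal standard deviation is multiplied by (acceptance fraction / 0.5),
clipped to $[0.5, 2]$; it is frozen afterwards, so the post-burn-in kernel is
a fixed, valid Metropolis kernel targeting the exact posterior. Initial
proposal widths are scale-aware: $0.05\,S_0$, $0.2\,d$, $0.05$ for fractions
and $0.1$ rad for angles.

## Two engines, one random stream

All Normal and Uniform draws a chain will consume are pre-generated into
buffers indexed by (iteration, parameter) — `generate_stream()` — before the
chain runs. Two engines consume these buffers in exactly the same order:

* `engine = "serial"`: a plain-R reference implementation;
* `engine = "batched"`: compiled code in which the per-voxel chain logic
  (propose, accept/reject, adapt) is scalar and the $K$ per-gradient signal
  evaluations and the residual reduction are tight array loops — the
  data-parallel decomposition used by GPU implementations of this pipeline,
  where a thread block serves one voxel and distributes the $K$ likelihood
  terms across threads.

Because the sum-of-squares reduction order is fixed (sequential over the
canonical measurement order, with an extended-precision accumulator matching
R's `sum()`) and floating-point contraction is disabled in the compiled code,
the two engines perform the same IEEE operations in the same order, and in
practice produce **bitwise-identical** chains from the same stream. The test
suite asserts a maximum relative difference of $10^{-9}$ across all retained
samples on a 20-voxel phantom; the observed difference is 0. A distributional
check complements this: `repeat_validation()` runs each engine many times
with independent seeds and compares the per-parameter distributions of
posterior means by two-sample Kolmogorov–Smirnov tests (by default the two
engines get disjoint seed lists — shared lists would make the equivalent
engines bitwise-equal and the comparison vacuous). A deliberately corrupted
sampler (`engine = "broken"`, prior support widened beyond $[0,1]$ on the
fractions) serves as the negative control; it is flagged most strongly on
isotropic voxels, where the $f \ge 0$ boundary is active.

At volume level, `fit_volume()` processes every masked voxel independently:
each voxel derives its own stream seed from `base_seed` plus its linear
index, so results are invariant to `batch_size` (a throughput knob, default
64 to mirror the thread-block size reported as fastest for this
decomposition), to the number of `workers`, and to voxel ordering. Slices
(third axis) are the distribution unit across workers, assigned greedily
largest-first; workers never communicate because voxels are independent.

## The synthetic generator

`make_scheme()` emulates a whole-brain acquisition: $K$ approximately evenly
spaced directions from a deterministic spherical Fibonacci lattice
(hemisphere-folded; the model is axial), plus $n_{b0}$ unweighted
measurements — by default $K = 64$ at $b = 2500$ s/mm² with one $b=0$, the
kind of single-shell protocol used in whole-brain fibre-orientation studies.
A Fibonacci lattice was chosen over electrostatic-repulsion optimisation
because it is deterministic and dependency-free; its minimum pairwise axial
separation at $K=64$ (about 2.3°) is adequate for testing, though slightly
less uniform than optimised point sets.

`simulate_voxel()` adds Gaussian noise of standard deviation $S_0/\mathrm{SNR}$
(SNR defined at $b=0$ relative to $S_0$, the standard convention) or Rician
noise (magnitude of a complex Gaussian perturbation — what magnitude MR
images actually follow). The canonical phantom has three regions with
typical white-matter values ($S_0 = 1000$, $d = 10^{-3}$ mm²/s): isotropic
($f = 0$), single fibre ($f = 0.7$) and a 90° crossing
($f_1 = f_2 = 0.35$). What the generator does **not** emulate: spatial noise
correlation, eddy-current and motion artefacts, EPI distortion, partial
voluming, susceptibility dropout and multi-shell protocols. Passing tests
demonstrate correctness of the inference machinery under the stated noise
model, not robustness to real-scanner artefacts.

## Numerical choices

* Sum-of-squares floor $10^{-12}$ in the marginalised likelihood: prevents
  $-\infty \cdot 0$ pathologies on exactly model-generated data.
* $b < 50$ s/mm² is treated as $b=0$ (scanner tables rarely contain exact
  zeros); non-unit gradient directions are renormalised with a warning.
* Gradient tables are taken in the image coordinate frame **as given**: no
  gradient reorientation is applied. Users of scanner data must reorient
  upstream if needed.
* The LM start is nudged strictly inside the prior support before MCMC
  ($f \in [10^{-4}, 1-10^{-4}]$ etc.), since LM may legitimately sit on a
  boundary where the prior is degenerate.
* Dyads are canonicalised to the $z \ge 0$ hemisphere in outputs; dispersion
  is the largest eigenvalue of the mean dyadic tensor ($1$ = perfectly
  concentrated, $1/3$ = isotropic).
* Phantom volumes are written as float64 so a write/read round trip is exact;
  result maps are written as float32, the conventional output precision.

## Test problem sizes and recovery thresholds

The equivalence fixture uses 20 voxels at full default chain settings; the
repeated-execution validation uses 50 repeats per engine on one voxel of
each phantom region; recovery checks use 50 voxels per configuration.
Recovery thresholds were established **before** the acceptance checks were
wired up, from reference chains ten times longer (12500 jumps) on the same
phantom conditions, with a fixed rule: single-fibre thresholds are 1.5× the
reference-chain medians (angular error 0.93°, $|\hat f - f|$ 0.031), and the
crossing threshold is 1.5× the reference-chain 90th percentile of the
worst-dyad assignment error (5.25°), with recovery required in at least 80%
of voxels. The multiplier absorbs the extra Monte-Carlo noise of 50 retained
samples relative to 500 without tracking any particular test outcome.

## Known limitations

* Gaussian (marginalised) likelihood only; at low SNR magnitude data are
  Rician and the ball fraction absorbs part of the noise floor.
* Single b-value model: no multi-shell support, no tensor compartment, no
  automatic relevance determination on the fractions — fitting $L$ larger
  than the data support will overfit.
* Convergence diagnostics are limited to acceptance rates; the defaults are
  well-tested for the phantom regimes above, but unusual data may need longer
  burn-in.
* The sampler updates one parameter at a time; strongly correlated posteriors
  (e.g. $S_0$ with $d$ at few $b=0$ measurements) mix more slowly than a
  blocked sampler would.
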