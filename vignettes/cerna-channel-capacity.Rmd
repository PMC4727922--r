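---
title: "Methods: the ceRNA titration model and its channel capacities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ceRNA titration model and its channel capacities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernacap)
```

## The circuit

`cernacap` models the minimal competing-endogenous-RNA (ceRNA) circuit:
two RNA species `m1` (the competitor) and `m2` (the target), one shared
miRNA species `mu`, and the two miRNA-RNA complexes `c1`, `c2`. Each
transcription unit is activated by its own transcription factor through a
cooperative promoter. Throughout the package all levels are molecule
counts and all rates are per minute; no concentration conversion is
performed anywhere.

Two regulatory routes to the target are compared as information channels:

* the **miRNA channel** — the competitor's TF level `f1` is the input;
  raising it raises `m1`, which sequesters miRNA and derepresses `m2`;
* the **TF channel** — the target's own TF level `f2` is the input.

The output of both channels is the stationary target level `m2`.

### Assumptions

1. **Fast promoter equilibration.** TF-DNA binding/unbinding is much
   faster than transcription, so each occupancy is frozen at its Hill
   equilibrium `n(f) = f^h / (f^h + k_out/k_in)`. Only the ratio
   `k_out/k_in` matters and is what the parameter container stores.
   A consequence is that promoter switching noise is excluded by
   construction: transcription propensities in the stochastic model are
   constants.
2. **Well-mixed mass action.** RISC loading and other intermediates of
   miRNA-target binding are absorbed into effective association rates.
3. **Stationarity.** All quantities are computed at steady state;
   transient cross-talk is out of scope.
4. **External inputs.** TF levels are parameters, not dynamical species.

## Parameters

| field | meaning | units |
|---|---|---|
| `b1`, `b2`, `beta` | transcription rates of ceRNA1, ceRNA2, miRNA | molecules/min |
| `d1`, `d2`, `delta` | spontaneous degradation rates | 1/min |
| `kplus1`, `kplus2` | complex association rates | 1/(molecule·min) |
| `kminus1`, `kminus2` | complex dissociation rates | 1/min |
| `kappa1`, `kappa2` | catalytic complex decay (miRNA recycled) | 1/min |
| `sigma1`, `sigma2` | stoichiometric complex decay (miRNA lost) | 1/min |
| `kratio` | `k_out/k_in` of the promoters | molecules^h |
| `h` | Hill cooperativity | – |

The packaged presets (`cerna_preset("fig2")` … `"fig9"`) transcribe the
published parameter table for each scan protocol, with miRNA-/TF-channel
variants where the table distinguishes them. Axes that the corresponding
protocol sweeps are stored at the geometric midpoint of their tabulated
range, with the range itself in `$sweep`.

Two tabulated conventions for the input maximum disagree slightly: the
table lists `f^max = 30` while the occupancy convention `n(f^max) = 0.99`
gives `f = 22.87` (direct evaluation gives `n(30) = 0.9974`). Presets
store both; every input grid in the package is driven by the *occupancy*
range, which is the convention the channel definitions use. The
discrepancy is documented rather than resolved.

The distinction between stoichiometric (`sigma`) and catalytic (`kappa`)
complex decay is central: recycling returns the miRNA to the free pool,
so a heavily recycled (catalytically degraded) target cannot titrate
miRNAs, while a stoichiometrically degraded competitor can.

## Deterministic layer

At fixed occupancies the stationary state solves three coupled balance
conditions. Given the free-miRNA level, both free ceRNA levels are
explicit through the sigmoidal gain

$$\bar m_i = \frac{b_i \bar n_i}{d_i}\,
  \frac{\mu_{0,i}}{\mu_{0,i} + \bar\mu},\qquad
  \mu_{0,i} = \frac{d_i}{k_i^+}\Big(1 + \frac{k_i^-}{\sigma_i+\kappa_i}\Big),$$

and the complexes follow from their own balance, so the problem reduces
to a scalar fixed point in $\bar\mu$. `steady_state()` runs a damped
Picard iteration (damping 0.5) on that scalar map and falls back to a
bracketing root-finder on $[0, \beta\bar n_\mu/\delta]$ if the iteration
has not converged after `max_iter` steps. The convergence tolerance
(relative residual `1e-10`, default) is far below the one-molecule
resolution of any quantity reported; every solution is verified by
substituting back into all five stationary conditions.

`mu0` acts as a soft threshold: `classify_regime()` labels a ceRNA
*free* below `mu0/band`, *repressed* above `band·mu0` and *susceptible*
in between. The published description uses only qualitative symbols
(`<<`, `~`, `>>`); the default band of one decade (`ratio_band = 10`) is
this package's choice and is configurable.

### Locating the susceptibility point

`susceptibility_crossover()` supports two operational definitions. The
`"threshold"` method solves $\bar\mu(f_1) = \mu_{0,i}$ directly. This
equation can genuinely lack a root: as the competitor saturates, the
free-miRNA level plateaus, and at the `fig2` preset the plateau
(≈ 51.6 molecules) sits just above $\mu_{0,1} = 50.05$, so ceRNA1 never
crosses its threshold although it clearly passes through a susceptible
window. The default `"fano"` method therefore uses the observable
signature instead: the input at which the ceRNA's stationary Fano factor
(from the linear noise approximation) peaks. Both methods agree for
ceRNA2 at `fig2`; the Fano-peak definition is the one the package's
acceptance checks use.

### The omega rescaling

`rescale_omega()` applies $\delta \to \omega\delta$,
$k_i^+ \to \omega k_i^+$. When the dissociation and recycling return
fluxes are negligible against transcription, this leaves every mean
response unchanged while scaling the free-miRNA pool like $1/\omega$:
small $\omega$ is the limit of a large population of weakly interacting
miRNAs. The property tests verify the two smallness conditions
numerically before asserting invariance rather than assuming them.

## Stochastic layer

The simulator is a direct-method Gillespie algorithm over the 14
elementary reactions, implemented in C++ (Rcpp) and driven by R's RNG so
that `set.seed()`/`seed` arguments give bit-reproducible paths. Two entry
points exist: `simulate_ssa()` records the full event path (for
diagnostics and structural tests), while the internal moment accumulator
streams time-weighted first and second moments over the averaging window
without storing the path, which is what `moment_scan()` and the
GA-backed response curves use.

Choices the published description leaves open, fixed here:

* **Burn-in**: default one order of magnitude above the slowest
  relaxation time `1/min(d1, d2, delta)`; the sampling window is two
  orders of magnitude above it. Exposed as arguments everywhere.
* **Initial state**: the deterministic steady state rounded to integers —
  unbiased at stationarity and the cheapest way to shorten the
  transient.
* **Seeding**: per-grid-point, per-replicate seeds are derived
  deterministically from one master seed (`derive_seeds()`), and every
  output table records the seed used.

## Linear noise approximation

Writing the state as $x = (m_1, m_2, \mu, c_1, c_2)$ with drift $g(x)$,
fluctuations around the steady state relax as
$\dot{\delta x} = A\,\delta x + \eta$ with $A = \partial g/\partial x$
(analytic entries, validated against numerical differentiation) and
$\langle\eta_a(t)\eta_b(t')\rangle = \Gamma_{ab}\,\delta(t-t')$.

The published noise description lists the autocorrelation amplitude of
each independent Poisson channel but not the full cross-species structure
of $\Gamma$. The package reconstructs it by standard chemical-Langevin
bookkeeping: each of the 14 reactions contributes its stationary
propensity times the outer product of its stoichiometry vector,
$\Gamma = \sum_r a_r(\bar x)\, s_r s_r^\top$. This reproduces each listed
amplitude on the diagonal and fixes the off-diagonal terms (for example
the association and dissociation channels give
$\Gamma_{m_1 c_1} = -k_1^+\bar m_1\bar\mu - k_1^-\bar c_1$); the
reconstruction is validated against simulated cross-covariances rather
than assumed.

The stationary covariance is computed two independent ways:

* `covariance_lyapunov()` solves $AC + CA^\top = -\Gamma$ by Kronecker
  vectorisation — numerically robust, the default, and the ground truth;
* `covariance_spectral()` evaluates the eigendecomposition formula
  $C_{ab} = -\sum B_{ap}B_{br}\,\tilde\Gamma_{pr}/(\lambda_p+\lambda_r)$
  with $\tilde\Gamma = B^{-1}\Gamma B^{-\top}$. The index placement was
  fixed by requiring agreement with the Lyapunov solution; the two
  routes cross-validate to $10^{-8}$ on randomized stable systems in the
  test suite. Complex intermediate arithmetic is allowed; the imaginary
  residue is asserted below $10^{-8}$ before being discarded, and a
  near-defective eigenvector matrix (checked by SVD condition number)
  triggers a warning and the Lyapunov fallback.

Every covariance the package computes is required to satisfy the
fluctuation-dissipation identity $AC + CA^\top + \Gamma = 0$ to
$10^{-8}$.

## Capacity machinery

A channel is summarised by its response curve: mean and variance of `m2`
along an input grid. Estimators: `"deterministic"` (means only), `"lna"`
(Gaussian variance; deterministic, fast) and `"ga"` (simulated moments
pooled over replicates). In the small-noise Gaussian approximation the
optimal input density is

$$p_{\rm opt}(f) = \frac{1}{Z}
 \left[\frac{(d\bar m_2/df)^2}{2\pi e\,\sigma^2_{m_2}(f)}\right]^{1/2},
 \qquad I_{\rm opt} = \log_2 Z .$$

Numerical choices:

* **Input grid.** Half the points log-spaced in `f` (the scans' natural
  axis), half uniform in occupancy (which concentrates points where the
  Hill response actually moves), plus the `f = 0` endpoint when the range
  starts at zero occupancy. Default 50 points, at which doubling the grid
  moves `Z` by about 0.2% for the presets shipped.
* **Derivative.** Monotone samples get a monotonicity-preserving cubic
  interpolant (`monoH.FC`), so the squared derivative cannot pick up
  spline overshoot; genuinely non-monotone curves fall back to a natural
  spline and `optimal_input()` warns, because `Z` then counts levels
  along both branches and overestimates distinguishability.
  Gillespie-estimated curves use a smoothing spline instead — the
  derivative enters squared, which would amplify sampling jitter.
* **Variance interpolation** is done on the log scale, keeping the
  interpolant strictly positive between grid points.
* **Zero-variance points.** A grid point with zero variance can only be
  an empty output (`m2 = 0`, e.g. the `f = 0` endpoint of a direct
  channel); the Gaussian channel is undefined there and the point is
  excluded from the quadrature.
* **Clamping.** `Z < 1` means fewer than one distinguishable output
  level; the capacity is reported as 0 bits.
* **Quadrature**: trapezoid rule on a 2000-point refinement.

`mutual_information()` provides two cross-checks: a semi-analytic
estimate (Gaussian conditional integrated against a given input density)
and a 2-D histogram plug-in with Freedman-Diaconis bins for sampled
pairs. $\log_2 Z$ is the small-noise *approximation* of the capacity:
the semi-analytic MI under $p_{\rm opt}$ sits slightly above it at finite
noise and converges to it as the noise shrinks, which is exactly what the
tests assert. The headline values reported by the package are always
$\log_2 Z$.

### Matched-output comparison

Two protocols (presets `fig8`, `fig9`) compare the channels at a fixed
output range. The direct channel's occupancy window is then
reconstructed so that `b2·n2/d2` spans the miRNA channel's output range
(`match_tf_input_range()`). With the tabulated `fig9` TF-channel
transcription rate (`b2 = 22`) the upper target level (≈ 220.6
molecules) would require an occupancy slightly above 1; the
reconstruction clamps the occupancy just below promoter saturation
(default cap 0.9999), which reproduces the published amplitude within
its stated one-molecule uncertainty. The cap is an argument, not a
constant.

### The occupancy-plane protocol

The tabulated occupancy scan varies the two fixed occupancies
`(n1, n2)` on a plane. A channel's capacity needs its *own* input swept,
so the plane is interpreted as: at a grid point, `I_TF` is computed with
the competitor promoter frozen at `n1` (input `f2` swept over the full
range) and `I_miRNA` with the target promoter frozen at `n2` (input `f1`
swept); their difference is reported per grid point. The two axes
therefore act on different channels, which the test suite checks
explicitly.

## What the simulator emulates — and what it does not

The synthetic data produced by the Gillespie layer are exact samples of
the chemical master equation for the 14-reaction network at frozen
promoter occupancies. They therefore carry intrinsic birth-death noise,
titration (association/dissociation) noise and complex-processing noise,
with the correct stationary correlations — this is what the LNA and
capacity layers are validated against. They do *not* contain promoter
switching noise, extrinsic (cell-to-cell) variability, transcriptional
bursting, delays, or RISC-loading intermediates. Passing tests
demonstrate internal consistency of the model chain (deterministic ↔
stochastic ↔ Gaussian approximation ↔ capacity), not agreement with any
particular experimental system.

## Problem sizes and defaults used by the shipped tests

The test suite and the acceptance script run at desk scale, chosen so the
whole suite completes in a few minutes on one CPU: 5×5 grids for the
two-dimensional scans, 8-point grids for one-dimensional ones, 30-50
input points per capacity evaluation, and simulated moment scans of
6000 min per replicate with 8 replicates per grid point (a few million
reaction events per run). Sweep drivers accept larger grids and replicate
counts through their configuration. The capacity values quoted in sweep
tests use the LNA estimator, which is deterministic — its capacity
standard error is identically zero — with the Gillespie estimator
available behind the `estimator` flag for spot checks.

## Known limitations

* The capacity is only meaningful in the small-noise Gaussian regime; no
  discrete (Blahut-Arimoto) capacity computation is attempted, and for
  strongly non-Gaussian response distributions (e.g. near-empty outputs)
  $\log_2 Z$ is a rough guide only.
* One miRNA species and two ceRNAs; no network generalisation.
* Stationary analysis only; no transient information transfer.
* The LNA is stressed exactly where the biology is most interesting —
  at the susceptibility peak — and the tests correspondingly allow it a
  wider (25%) deviation band from simulation there, versus 10%
  elsewhere.

## Package shape

The package follows the base-R S3 idiom of the classic modelling stack —
constructor functions returning classed objects (`cerna_params`,
`cerna_steady_state`, `cerna_lna`, `cerna_response`, `cerna_capacity`,
`cerna_sweep`) with `print`/`plot` methods, base-graphics plots and no
tidyverse dependency. There is deliberately no formula/data fitting
interface: nothing in the package is estimated from data, so `simulate`
-style generation and deterministic solvers are the natural verbs, and a
thin command-line front end (`inst/cli/cernacap`) wraps the exported
functions for shell use.
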