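---
title: "From network structure to phase and directionality: methods"
author: "netphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From network structure to phase and directionality: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netphase)
```

## The model

`netphase` studies how the *structure* of a coupling network shapes the
*dynamics* and *directionality* of oscillatory activity on it. The dynamical
substrate is a Kuramoto-type phase-oscillator model on a weighted network
$A$ (with $A_{jk}$ the coupling from node $k$ to node $j$, zero diagonal):

$$\dot\theta_j \;=\; \omega_j \;+\; S \sum_k A_{jk}
  \sin\!\big(\theta_k(t-\tau_{jk}) - \theta_j(t) - \beta\big) \;+\; \xi_j(t),$$

where $\omega_j$ is the natural frequency (default $2\pi \cdot 10$ rad/s, an
alpha-band oscillation), $S$ a global coupling strength, $\xi_j$ Gaussian
white noise, and the frustration $\beta$ a constant phase offset that stands
in for a short transmission delay via the short-delay approximation
$\beta = \omega\tau$ (default $\tau = 4$ ms, so $\beta \approx 0.251$ rad at
10 Hz). Explicit uniform or distance-proportional delays are also supported
in the integrator; for the analytic solvers delays are always converted to
the equivalent offset first.

The central quantity is each node's *relative phase*
$\phi_j = \theta_j - \Omega t$ in the frame rotating at the collective
frequency $\Omega$, with the gauge fixed so the population mean phase
$\Phi$ is zero. Writing $\Delta_j = \omega_j - \Omega$, a node with strong
enough coupling locks at a stationary phase; the two solvers differ in the
field the node is assumed to feel.

**Mean-field approximation (MFA).** Every node feels the global mean field
$R e^{i\Phi}$, $R = |\langle e^{i\phi_k}\rangle_k|$. A node locks iff
$S n_j R > |\Delta_j|$, where $n_j = \sum_k A_{jk}$ is its (weighted)
degree, and then

$$\phi_j^* = \sin^{-1}\!\Big(\frac{\Delta_j}{S\,n_j R}\Big) - \beta ,$$

on the principal arcsin branch (the stable fixed point of the one-node phase
equation). Since $\sin^{-1}$ is increasing and $\Delta_j > 0$ under
frustration, $\phi_j^*$ **decreases with degree**: hubs lag, peripheral
nodes lead. $(R, \Omega)$ are determined jointly by self-consistency
($R$ reproduces itself) and the gauge (the population mean phasor is real
and positive; `solveMFA` finds $\Omega$ by root-finding the imaginary part,
scanning a bracket $[\min\omega - S n_{max} R,\ \max\omega + S n_{max} R]$
wide enough for the un-normalised coupling used here, and among multiple
gauge roots keeps the most coherent, i.e. largest-$R$, branch).

**Local order parameter (LOP).** The MFA erases local structure; the LOP
replaces the global field with each node's own field
$r_j e^{i\Theta_j} = \tfrac{1}{n_j}\sum_k A_{jk} e^{i\theta_k}$, which makes
the model equation exact. Locked nodes ($S n_j r_j > |\Delta_j|$) satisfy

$$\phi_j^* = \Phi_j^* - \beta +
   \sin^{-1}\!\Big(\frac{\Delta_j}{S\,n_j r_j}\Big),$$

with $\Phi_j^*$ the local mean-field phase in the rotating frame.
`solveLOP` iterates this map with damped updates
($\phi \leftarrow \phi + \lambda\,\mathrm{wrap}(\phi_{new}-\phi)$,
$\lambda = 0.3$ by default), re-solving $\Omega$ every sweep to preserve the
gauge, warm-started from the MFA solution (`init = "mfa"`); undamped
iteration can two-cycle on hub-dominated graphs, and the warm start matters
because the basins of the fixed points are not characterised.

**Drifting nodes.** A node that fails its locking condition never settles;
its phase has the stationary density of the deterministic drift
$\dot\phi = \Delta_j + S n_j r_j \sin(\Phi_j - \phi - \beta)$,

$$P(\phi) \propto \frac{1}{|\dot\phi|},$$

which concentrates near the would-be locked phase as the locking boundary is
approached. Inside both solvers a drifting node contributes the *circular
mean of this density* to the fields it participates in (rather than being
excluded), and `phiStar` reports that circular mean; `driftDistribution()`
exposes the full density. The density is evaluated on a uniform grid
(default 512-1024 points) — accurate because the integrand is smooth except
at near-tangencies, where the normalisation is still finite.

**When no fixed point exists.** On some networks — typically scale-free
realizations whose periphery contains chains of low-degree nodes — the
noise-free dynamics never fully lock: a loosely attached cluster drifts
*collectively*, the per-node locking criterion is satisfied yet the local
fields rotate, and the damped iteration cycles at any damping. This is a
property of the system, not of the numerics. `solveLOP` then (fallback
`"relax"`) integrates the exact noise-free dynamics from the warm start for
40 s of model time and reports each node's time-averaged rotating-frame
phasor: genuinely locked nodes recover their fixed point to high accuracy,
drifting nodes their drift mean. The returned `residual` honestly reports
the non-stationarity in that case instead of a `tol`-level value.

## Directionality

The directed phase lag index between two phase series is
$\mathrm{dPLI}_{ij} = \langle \mathrm{sign}(\Delta\theta_{ij}(t))\rangle_t$
with $\Delta\theta_{ij}$ wrapped to $(-\pi, \pi]$ *before* the sign — raw
unwrapped differences would make the measure depend on winding history.
Exact zeros count as 0. $\mathrm{PLI} = |\mathrm{dPLI}|$. Node-level dPLI is
the mean over all partners; by antisymmetry the node values sum to zero.
Because phase decreases with degree and dPLI is a monotone function of the
phase differences, degree, phase, and node dPLI form a tightly correlated
chain: hubs are directional *targets* (negative dPLI), peripheral nodes
*sources*. `analyticDpli()` predicts node dPLI from solver phases by the
zero-noise sign rule, optionally attenuated by a wrapped-normal phase-jitter
model.

## Coupling normalisation

Degrees are plain row sums ($n_j = \sum_k A_{jk}$, no $1/N$), the drift
prefactor is $S$ (not $S/N$), and the locking conditions are
$S n_j R > |\Delta_j|$ and $S n_j r_j > |\Delta_j|$ — one convention used
consistently across the simulator, both solvers, and the locking flags. This
convention is the one under which the framework's stated behaviour is
reproduced quantitatively: with unit-SD noise the degree-phase pattern is
stable for couplings above roughly $S \approx 0.2$, and at the comparison
coupling $S = 5$ the restoring rate $S n_j r_j$ (tens of rad/s) dominates
the noise.

## Simulation choices

* **Integrator**: Euler-Maruyama with $dt = 1$ ms ($\ge$ 100 steps per
  10 Hz cycle); phase models are non-stiff, and the noise term is scaled by
  $\sqrt{dt}$. Explicit delays use per-edge history buffers, initialised
  backwards at the natural frequency, $\theta_j(t<0)=\theta_j(0)-\omega_j|t|$.
* **Noise**: SD 1 by default. The mean of the noise only shifts $\Omega$
  uniformly and cancels in relative phases, so the default mean is 0, with
  `noiseMean` available.
* **Burn-in**: the first half of each run is discarded (no transient
  criterion is imposed; at $S = 5$ locking completes within a few seconds).
* **Analysis sampling**: the integrator advances at 1 ms but stores every
  5th step (`storeEveryN = 5`, a 200 Hz analysis rate — 20 samples per
  cycle), which leaves phase averages and dPLI statistically unchanged while
  keeping memory and dPLI cost proportionate.
* **Problem sizes**: the package's default protocol is 100-node networks,
  60 s runs (30 s analysed) averaged over `nRuns = 20` with fresh initial
  phases and noise per run, all drawn from one seeded RNG stream
  (`splitSeed` derives independent sub-seeds for network generation and
  simulation). Run-averaging tightens the phase estimates with variance
  shrinking inversely in the number of runs; larger run counts sharpen the
  comparison but do not change any conclusion.

## Model networks

* `gilbertRandom(n, epsilon)`: $G(N, p)$ with
  $p = (1+\epsilon)\log N / N$, $\epsilon = 0.1$ by default — just above the
  connectivity threshold, approximately Poisson degrees (a homogeneous
  family).
* `scaleFree(n, gamma, minDegree)`: degrees drawn from
  $P(k) \propto k^{-\gamma}$ ($\gamma = 2.5$ by default, endpoints 2 and 3
  accepted) truncated at the structural cutoff $\sqrt{\langle k\rangle N}$
  (which suppresses degree-degree correlations), wired by configuration-model
  stub matching that rejects self-loops and multi-edges. `minDegree = 3` by
  default: degree-2 peripheries frequently produce the collectively drifting
  clusters described above, outside the fully locked regime the analytic
  framework targets; a minimum degree of 3 keeps generated ensembles inside
  it. Generators do not enforce connectedness; experiments run on
  `largestComponent()`.

## The signal pipeline

For multichannel recordings the same measures are computed from data: Welch
PSD (2 s Hann windows, 50% overlap) averaged over channels selects the band
around the highest spectral peak (±2 Hz); a fifth-order Butterworth
band-pass is applied forward and backward (zero phase); instantaneous phases
come from the analytic (Hilbert) signal, with a fixed 1 s margin trimmed at
each end to remove filter and Hilbert edge artifacts; the trajectory is cut
into 5 s epochs (pseudo-stationary windows); per-epoch dPLI matrices are
averaged; the PLI matrix forms the weighted functional network, and a binary
network keeps the top fraction (default 0.30) of edges — explicit
proportional thresholding, with `thresholdSweep()` reporting stability
across fractions 0.1-0.5, rather than any data-fitted cutoff. Ties at the
cutoff are broken by stable edge order.

`generateSyntheticEEG()` makes this chain testable without recordings: each
channel is a narrow-band sinusoid carrying a prescribed phase lag plus an
independent random-walk phase jitter and white noise. It emulates the
band-limited, phase-locked aspect of real recordings but **not** volume
conduction, common reference effects, 1/f background, artifacts, or
non-stationarity — so a passing recovery test demonstrates the pipeline's
correctness, not robustness to those confounds. A NaN/flat-channel validator
stands in for the visual artifact rejection used with real data.

## Numerical details and degenerate inputs

* Gauge root-finding brackets $\Omega$ as above and falls back to a global
  grid scan (400 points) with refinement by `uniroot`; among several gauge
  roots the largest-$R$ branch is kept.
* Solver tolerances: `tol = 1e-8` on the residual/update, `maxIter = 10000`.
* An incoherent regime (no $R > 0$ solution, e.g. $S = 0$) is reported as
  $R = 0$ with all nodes unlocked — not an error.
* Isolated nodes ($n_j = 0$) are never locked; their `phiStar` is `NaN` and
  they are excluded from correlations.
* The wrap convention everywhere is the half-open interval $(-\pi, \pi]$.
* Proportional thresholding keeps `round(fraction * N(N-1)/2)` edges, at
  least one.

## Limitations

Phase-only dynamics (no amplitudes), a single dominant frequency band, and
dPLI as the directionality measure (a lead/lag asymmetry, not a causal
estimate) bound what the package can say about real recordings. The
analytic solvers assume a stationary locked core; systems deep in the
drifting regime are described only through their stationary phase
distributions.
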