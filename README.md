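# netphase

**Network structure, oscillator phase, and directionality in brain-like
networks.**

Across very different brain networks, hub regions (densely connected nodes)
show slower, phase-*lagging* activity and act as targets of directed
functional connectivity, while sparsely connected peripheral regions
phase-*lead* and act as sources. `netphase` implements the coupled-oscillator
framework behind that observation, for anyone who wants to predict phase and
directionality patterns from a structural network — computational
neuroscientists working with connectomes, and more generally anyone studying
Kuramoto-type dynamics on heterogeneous networks.

## What it computes

The dynamics are Kuramoto phase oscillators with frustration on a weighted
network (coupling `A[j, k]` from node k to j, degree `n_j = Σ_k A[j, k]`):

    dθ_j/dt = ω_j + S Σ_k A_jk sin(θ_k − θ_j − β) + ξ_j(t)

where the phase offset β ≈ ω·τ stands in for a short transmission delay and
ξ is Gaussian white noise. In the frame rotating at the collective frequency
Ω (gauge: population mean phase 0), the package predicts each node's
stationary relative phase φ\*_j **from structure alone**, two ways:

* **MFA** (mean-field approximation): every node feels the global order
  parameter R; a node with `S·n_j·R > |Δ_j|` (Δ_j = ω_j − Ω) locks at
  `φ*_j = asin(Δ_j / (S n_j R)) − β` — a monotonically *decreasing* function
  of degree: hubs lag, periphery leads.
* **LOP** (local order parameter): each node feels its own field
  `r_j e^{iΘ_j} = (1/n_j) Σ_k A_jk e^{iθ_k}`, making the equation exact;
  locked nodes satisfy `φ*_j = Φ*_j − β + asin(Δ_j / (S n_j r_j))`, solved
  as a damped fixed point. Nodes too weakly coupled to lock drift with
  stationary density `P(φ) ∝ 1/|dφ/dt|`.

Directionality is quantified by the **directed phase lag index**,
`dPLI_ij = ⟨sign(wrap(θ_i − θ_j))⟩_t` (+1 = i consistently leads), and
`PLI = |dPLI|`. A signal pipeline applies the same measures to multichannel
recordings: spectral-peak band selection, zero-phase Butterworth filtering,
Hilbert phases, 5 s epochs, PLI-weighted functional networks with
proportional thresholding.

## Worked example

Predict and verify the degree → phase → directionality chain on a random
network:

```r
library(netphase)

net <- largestComponent(gilbertRandom(100, epsilon = 0.1, seed = 7))
cfg <- simConfig(couplingS = 5, durationS = 20, transientS = 10, nRuns = 5)

ens <- simulateEnsemble(net, cfg, seed = 7)  # run-averaged simulation
mfa <- solveMFA(net, cfg)                    # structure-only predictions
lop <- solveLOP(net, cfg)
lop
#> AnalyticSolution (LOP): 100 nodes, 97 locked
#>   Omega = 56.1218 rad/s (8.932 Hz), R = 0.9570, residual = 2.56e-07

correlationReport(degrees(net), ens$phiMean, ens$nodeDpli)
#>          pair    rho        p
#> 1  degree~phi -0.825 4.83e-26
#> 2 degree~dPLI -0.823 8.68e-26
#> 3    phi~dPLI  0.995 8.24e-99
```

Reading the output: the population oscillates slightly below the 10 Hz
natural frequency (Ω ≈ 8.9 Hz — frustration slows the ensemble), 97 of 100
nodes are phase-locked, and the three per-node indices are tightly chained:
degree anticorrelates with relative phase (hubs lag) and with node dPLI
(hubs are directional targets), while phase and dPLI are nearly
interchangeable (ρ ≈ 0.99). Comparing the analytic phases with the
simulated ones:

```r
cor(mfa@phiStar, ens$phiMean, method = "spearman")  # 0.83 — MFA is coarse
cor(lop@phiStar, ens$phiMean, method = "spearman")  # 0.998 — LOP is sharp
```

Experiment drivers (`runModelNetworks`, `runConnectome`, `runEEG`) chain the
stages and write CSV reports; `inst/cli/netphase.R` is a thin command-line
wrapper over them (`simulate | analyze | compare | eeg-analyze`).

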