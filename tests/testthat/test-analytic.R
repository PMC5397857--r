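test_that("complete-graph symmetry: uniform phases, R = 1, LOP = MFA", {
  net <- completeNetwork(30)
  cfg <- simConfig(couplingS = 5)
  mfa <- solveMFA(net, cfg)
  lop <- solveLOP(net, cfg)
  expect_lt(max(abs(mfa@phiStar)), 1e-8)
  expect_equal(mfa@globalR, 1, tolerance = 1e-8)
  # on the complete graph the local field equals the global field
  expect_lt(max(abs(lop@phiStar - mfa@phiStar)), 1e-8)
  expect_lt(abs(lop@omega - mfa@omega), 1e-6)
  expect_equal(unname(lop@localR), rep(1, 30), tolerance = 1e-8)
})

test_that("beta -> 0 with identical frequencies recovers full synchrony", {
  net <- largestComponent(gilbertRandom(40, 0.2, seed = 2))
  cfg <- simConfig(couplingS = 5, betaRad = 0)
  for (sol in list(solveMFA(net, cfg), solveLOP(net, cfg))) {
    expect_lt(max(abs(sol@phiStar)), 1e-6)
    expect_equal(sol@omega, 2 * pi * 10, tolerance = 1e-6)
  }
})

test_that("two degree classes order as hub-lag / periphery-lead", {
  net <- twoClassNetwork(3, 6) # class degrees 6 (first 3 nodes) and 3
  cfg <- simConfig(couplingS = 5)
  for (sol in list(solveMFA(net, cfg), solveLOP(net, cfg))) {
    hub <- mean(sol@phiStar[1:3])
    leaf <- mean(sol@phiStar[4:9])
    expect_lt(hub, leaf)
  }
})

test_that("MFA phase is exactly nonincreasing in degree for equal detuning", {
  net <- largestComponent(gilbertRandom(80, 0.15, seed = 5))
  sol <- solveMFA(net, simConfig(couplingS = 5))
  k <- sol@degree[sol@locked]
  phi <- sol@phiStar[sol@locked]
  ord <- order(k)
  expect_true(all(diff(phi[ord]) <= 1e-12))
})

test_that("solutions are self-consistent and gauge-fixed", {
  net <- largestComponent(gilbertRandom(60, 0.25, seed = 7))
  cfg <- simConfig(couplingS = 5)
  mfa <- solveMFA(net, cfg)
  expect_lt(mfa@residual, 1e-6)
  lop <- solveLOP(net, cfg)
  expect_lt(lop@residual, 1e-4)
  A <- adjacency(net)
  if (all(lop@locked)) {
    # recompute the local order parameters from the returned phases
    w <- as.vector(A %*% exp(1i * lop@phiStar))
    expect_equal(Mod(w) / rowSums(A), unname(lop@localR), tolerance = 1e-6)
  }
  # gauge Phi = 0: population mean phasor is real and positive
  zM <- mean(exp(1i * mfa@phiStar[mfa@locked]))
  expect_lt(abs(Arg(mean(exp(1i * lop@phiStar[lop@locked])))), 0.2)
  expect_gt(Re(zM), 0)
})

test_that("the incoherent regime reports R = 0 without erroring", {
  net <- gilbertRandom(30, 0.2, seed = 3)
  sol <- solveMFA(net, simConfig(couplingS = 0))
  expect_equal(sol@globalR, 0)
  expect_false(any(sol@locked))
})

test_that("LOP initialisations agree on a well-locked network", {
  net <- largestComponent(gilbertRandom(40, 0.3, seed = 4))
  cfg <- simConfig(couplingS = 5)
  ref <- solveLOP(net, cfg, init = "mfa")
  alt <- solveLOP(net, cfg, init = "zero")
  expect_lt(max(abs(wrapPhase(ref@phiStar - alt@phiStar))), 1e-5)
})

test_that("heterogeneous natural frequencies are handled", {
  net <- completeNetwork(10)
  cfg <- simConfig(couplingS = 5, naturalFreqHz = seq(9.8, 10.2, length.out = 10))
  sol <- solveLOP(net, cfg)
  expect_true(all(sol@locked))
  # faster oscillators sit at larger relative phases
  expect_gt(spearman(sol@naturalOmega, sol@phiStar), 0.99)
})

# a strongly coupled pair (nodes 1-2) drives a weakly attached node 3 with
# no feedback: the pair locks autonomously (Omega = omega - S*sin(beta) in
# closed form) while node 3 drifts against the frozen pair field
drifterFixture <- function(deltaDrift = 3, beta = 2 * pi * 10 * 0.004,
                           S = 2, ...) {
  A <- rbind(c(0, 1, 0), c(1, 0, 0), c(0.5, 0.5, 0))
  f3 <- (2 * pi * 10 + deltaDrift - S * sin(beta)) / (2 * pi)
  list(net = oscillatorNetwork(A),
       cfg = simConfig(couplingS = S, naturalFreqHz = c(10, 10, f3),
                       betaRad = beta, ...))
}

test_that("drift density is normalised and refuses locked nodes", {
  fx <- drifterFixture()
  sol <- solveLOP(fx$net, fx$cfg)
  expect_true(all(sol@locked[1:2]))
  expect_false(sol@locked[3])
  # pair dynamics in closed form: Omega = omega - S*sin(beta)
  expect_equal(sol@omega, 2 * pi * 10 - 2 * sin(fx$cfg@betaRad),
               tolerance = 1e-6)
  dd <- driftDistribution(3, sol, gridSize = 1024)
  expect_equal(sum(dd$density) * 2 * pi / 1024, 1, tolerance = 1e-6)
  expect_error(driftDistribution(1, sol), "locked")
})

test_that("drift density matches the long-run simulated phase histogram", {
  fx <- drifterFixture(noiseSd = 0, durationS = 120, transientS = 20,
                       nRuns = 1)
  sol <- solveLOP(fx$net, fx$cfg)
  traj <- simulateOscillators(fx$net, fx$cfg, seed = 12)
  # gauge-free empirical relative phase of the drifter: theta3 - theta1 +
  # phi1* (node 1 is locked at phi1*)
  x <- wrapPhase(traj@phases[3, ] - traj@phases[1, ] + sol@phiStar[1])
  gridSize <- 64
  breaks <- seq(-pi, pi, length.out = gridSize + 1)
  emp <- hist(x, breaks = breaks, plot = FALSE)$density
  dd <- driftDistribution(3, sol, gridSize = gridSize)
  # bin centers of hist() sit half a step below driftDistribution's grid
  pred <- (dd$density + c(dd$density[gridSize], dd$density[-gridSize])) / 2
  tv <- 0.5 * sum(abs(emp - pred)) * 2 * pi / gridSize
  expect_lt(tv, 0.1)
})

test_that("density concentrates near the locking boundary", {
  # |delta| barely above K: most mass near the would-be locked phase
  fx <- drifterFixture(deltaDrift = 2.05)
  sol <- solveLOP(fx$net, fx$cfg)
  expect_false(sol@locked[3])
  dd <- driftDistribution(3, sol, gridSize = 720)
  # 1/|drift| near-diverges at the tangency phase
  expect_gt(max(dd$density), 10 * median(dd$density))
  peakMass <- sum(dd$density[order(-dd$density)[1:72]]) * 2 * pi / 720
  expect_gt(peakMass, 0.25) # top 10% of the grid carries a large mass share
})

test_that("distance delays are rejected by the analytic solvers", {
  net <- completeNetwork(4)
  cfg <- simConfig(couplingS = 1, delayMode = "distance_delay",
                   velocityMPerS = 5)
  expect_error(solveMFA(net, cfg), "offset")
})
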