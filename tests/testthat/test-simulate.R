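test_that("identical seeds give bit-identical trajectories", {
  net <- gilbertRandom(20, 0.3, seed = 1)
  cfg <- quickConfig(durationS = 2, transientS = 1)
  t1 <- simulateOscillators(net, cfg, seed = 9)
  t2 <- simulateOscillators(net, cfg, seed = 9)
  expect_identical(t1@phases, t2@phases)
})

test_that("identical oscillators on a complete graph fully synchronise", {
  net <- completeNetwork(20)
  cfg <- simConfig(couplingS = 1, betaRad = 0, noiseSd = 0, durationS = 4,
                   transientS = 2, nRuns = 1)
  traj <- simulateOscillators(net, cfg, seed = 4)
  Rend <- Mod(mean(exp(1i * traj@phases[, ncol(traj@phases)])))
  expect_gt(Rend, 0.9999)
  # gauge: all relative phases collapse to 0
  rel <- relativePhases(traj)
  expect_lt(max(abs(rel$phiMean)), 1e-3)
})

test_that("collective frequency is exact for uncoupled noise-free nodes", {
  net <- completeNetwork(5)
  cfg <- simConfig(couplingS = 0, noiseSd = 0, durationS = 2, transientS = 1,
                   nRuns = 1)
  traj <- simulateOscillators(net, cfg, seed = 2)
  expect_equal(collectiveFrequency(traj), 2 * pi * 10, tolerance = 1e-9)
})

test_that("frustration slows the population below the natural frequency", {
  net <- gilbertRandom(50, 0.2, seed = 3)
  cfg <- quickConfig(nRuns = 1, noiseSd = 0)
  traj <- simulateOscillators(net, cfg, seed = 5)
  expect_lt(collectiveFrequency(traj), 2 * pi * 10)
})

test_that("with zero frequency, a node drifts at the noise mean", {
  # one node: the circular-mean phase is the node's own random walk, whose
  # fitted slope has SD sigma * sqrt(12 / T^3)
  net <- oscillatorNetwork(matrix(0, 1, 1))
  cfg <- simConfig(couplingS = 0, naturalFreqHz = 1e-9, noiseSd = 0.2,
                   noiseMean = 4, durationS = 5, transientS = 0, nRuns = 1)
  traj <- simulateOscillators(net, cfg, seed = 6)
  se <- 0.2 * sqrt(12 / 5^3)
  expect_lt(abs(collectiveFrequency(traj) - 4), 3 * se)
})

test_that("relative phases have zero circular mean at every sample", {
  net <- gilbertRandom(25, 0.3, seed = 8)
  traj <- simulateOscillators(net, quickConfig(nRuns = 1), seed = 8)
  rel <- relativePhases(traj)
  resid <- Arg(colMeans(exp(1i * rel$phi)))
  expect_lt(max(abs(resid)), 1e-10)
})

test_that("hubs phase-lag: degree and relative phase anticorrelate at S = 5", {
  net <- largestComponent(gilbertRandom(100, 0.1, seed = 1))
  cfg <- simConfig(couplingS = 5, durationS = 15, transientS = 7.5,
                   nRuns = 10)
  ens <- simulateEnsemble(net, cfg, seed = 2, computeDpli = FALSE)
  # the attainable |rho| is capped by degree ties in a Poisson-degree network
  expect_lt(spearman(degrees(net), ens$phiMean), -0.75)
})

test_that("the degree-phase sign pattern holds across coupling strengths", {
  net <- largestComponent(gilbertRandom(60, 0.2, seed = 4))
  for (S in c(0.3, 1, 3, 5)) {
    cfg <- simConfig(couplingS = S, durationS = 10, transientS = 5,
                     nRuns = 3)
    ens <- simulateEnsemble(net, cfg, seed = 10, computeDpli = FALSE)
    expect_lt(spearman(degrees(net), ens$phiMean), 0,
              label = paste0("degree-phase rho at S = ", S))
  }
})

test_that("a small uniform delay is equivalent to the offset beta = omega*tau", {
  net <- largestComponent(gilbertRandom(40, 0.2, seed = 6))
  tau <- 0.004
  cfgDelay <- simConfig(couplingS = 5, delayMode = "uniform_delay",
                        tauS = tau, noiseSd = 0, durationS = 6,
                        transientS = 3, nRuns = 1)
  cfgOffset <- simConfig(couplingS = 5, betaRad = 2 * pi * 10 * tau,
                         noiseSd = 0, durationS = 6, transientS = 3,
                         nRuns = 1)
  phiD <- relativePhases(simulateOscillators(net, cfgDelay, seed = 3))$phiMean
  phiO <- relativePhases(simulateOscillators(net, cfgOffset, seed = 3))$phiMean
  expect_gt(spearman(phiD, phiO), 0.95)
})

test_that("distance-proportional delays require and use coordinates", {
  A <- adjacency(completeNetwork(5))
  cfg <- simConfig(couplingS = 1, delayMode = "distance_delay",
                   velocityMPerS = 6, durationS = 2, transientS = 1,
                   nRuns = 1)
  bare <- oscillatorNetwork(A)
  expect_error(simulateOscillators(bare, cfg, seed = 1), "coordinates")
  withCoords <- oscillatorNetwork(A, coordinates = matrix(rnorm(15, sd = 20), 5, 3))
  traj <- simulateOscillators(withCoords, cfg, seed = 1)
  expect_equal(nNodes(traj), 5)
})

test_that("unit-SD noise does not flip the degree-phase sign", {
  net <- largestComponent(gilbertRandom(60, 0.2, seed = 9))
  for (sd in c(0, 1)) {
    cfg <- simConfig(couplingS = 5, noiseSd = sd, durationS = 10,
                     transientS = 5, nRuns = 3)
    ens <- simulateEnsemble(net, cfg, seed = 11, computeDpli = FALSE)
    expect_lt(spearman(degrees(net), ens$phiMean), -0.5,
              label = paste0("degree-phase rho at noise sd ", sd))
  }
})

test_that("wrapped view stays in (-pi, pi]", {
  net <- completeNetwork(4)
  traj <- simulateOscillators(net, quickConfig(durationS = 2, transientS = 1,
                                               nRuns = 1), seed = 1)
  w <- wrappedPhases(traj)
  expect_true(all(w > -pi & w <= pi))
})

test_that("run-averaging tightens the phase estimate", {
  net <- largestComponent(gilbertRandom(40, 0.2, seed = 13))
  cfg <- simConfig(couplingS = 5, durationS = 6, transientS = 3, nRuns = 12)
  ens <- simulateEnsemble(net, cfg, seed = 14, computeDpli = FALSE)
  # dispersion of single-run estimates vs means of 4 disjoint triples
  node <- which.min(degrees(net))[1] # peripheral node: noisiest phase
  single <- ens$phiRuns[, node]
  grouped <- vapply(split(single, rep(1:4, each = 3)), mean, numeric(1))
  expect_lt(var(grouped), var(single))
})
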