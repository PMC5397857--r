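alphaBand <- bandSpec(8, 12)

test_that("synthetic signals carry the prescribed deterministic lead", {
  sig <- generateSyntheticEEG(2, fsHz = 250, durationS = 12, baseFreqHz = 10,
                              phaseLagsRad = c(0, -0.5),
                              couplingJitterSd = 0, noiseSd = 0, seed = 1)
  traj <- bandpassPhase(sig, alphaBand)
  expect_equal(dpli(traj@phases[1, ], traj@phases[2, ]), 1)
})

test_that("pure noise shows no phase locking", {
  withr::with_seed(5, {
    sig <- multichannelSignal(matrix(rnorm(6 * 250 * 20), 6), fsHz = 250)
  })
  tab <- directionalityTable(bandpassPhase(sig, alphaBand))
  offdiag <- tab@pliMatrix[upper.tri(tab@pliMatrix)]
  expect_lt(max(offdiag), 0.35)
})

test_that("peakBand finds the spectral peak and applies the half-width", {
  tt <- seq(0, 20, by = 1 / 500)[-1]
  mk <- function(f, amp = 1) amp * sin(2 * pi * f * tt)
  withr::with_seed(2, {
    x1 <- rbind(mk(10.5) + rnorm(length(tt), 0, 0.3),
                mk(10.5) + rnorm(length(tt), 0, 0.3))
  })
  b1 <- peakBand(multichannelSignal(x1, 500))
  expect_equal(c(b1@lowHz, b1@highHz), c(8.5, 12.5), tolerance = 0.26)
  b2 <- peakBand(multichannelSignal(rbind(mk(7.5)), 500))
  expect_equal(c(b2@lowHz, b2@highHz), c(5.5, 9.5), tolerance = 0.26)
  # stronger of two tones wins
  b3 <- peakBand(multichannelSignal(rbind(mk(10) + mk(20, 0.3)), 500))
  expect_equal((b3@lowHz + b3@highHz) / 2, 10, tolerance = 0.26)
})

test_that("a flat spectrum is rejected", {
  withr::with_seed(3, {
    sig <- multichannelSignal(matrix(rnorm(4 * 500 * 10), 4), 500)
  })
  expect_error(peakBand(sig), "flat spectrum")
})

test_that("band-passed Hilbert phases recover tone frequency and offsets", {
  fs <- 500
  tt <- seq(0, 12, by = 1 / fs)[-1]
  sig <- multichannelSignal(rbind(sin(2 * pi * 10 * tt + 0.5),
                                  sin(2 * pi * 10 * tt)), fs)
  traj <- bandpassPhase(sig, alphaBand)
  instFreq <- colMeans(apply(traj@phases, 1, diff)) * fs / (2 * pi)
  expect_equal(unname(instFreq), c(10, 10), tolerance = 0.01)
  d <- wrapPhase(traj@phases[1, ] - traj@phases[2, ])
  expect_equal(mean(d), 0.5, tolerance = 0.02)
})

test_that("forward-backward filtering has zero group delay", {
  fs <- 250
  tt <- seq(0, 8, by = 1 / fs)[-1]
  x <- sin(2 * pi * 10 * tt)
  bf <- signal::butter(5, c(8, 12) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  mid <- 500:1500
  xc <- sapply(-5:5, function(l) cor(x[mid], y[mid + l]))
  expect_equal(which.max(xc), 6) # peak at lag 0
})

test_that("epoching yields the expected segment counts", {
  sig <- generateSyntheticEEG(2, fsHz = 100, durationS = 30, seed = 1)
  expect_length(epochSignal(sig, 5), 6)
  sigLong <- generateSyntheticEEG(2, fsHz = 100, durationS = 180, seed = 1)
  expect_length(epochSignal(sigLong, 5), 36)
  short <- generateSyntheticEEG(2, fsHz = 100, durationS = 4, seed = 1)
  expect_error(epochSignal(short, 5), "shorter than one epoch")
})

test_that("proportional thresholding keeps the strongest edges", {
  t <- seq(0, 10, by = 1e-2)
  withr::with_seed(8, {
    phases <- rbind(2 * pi * 10 * t + 0.3,
                    2 * pi * 10 * t,
                    cumsum(rnorm(length(t), 0, 0.5)))
  })
  fn <- functionalNetwork(phases, thresholdFraction = 1 / 3)
  B <- adjacency(fn$binary)
  expect_equal(sum(B) / 2, 1)          # a single surviving edge
  expect_equal(B[1, 2], 1)             # the locked pair
  fnAll <- functionalNetwork(phases, thresholdFraction = 1)
  expect_true(all(degrees(fnAll$binary, "binary") == 2))
})

test_that("the pipeline on a simulated trajectory matches nodeDpli directly", {
  net <- largestComponent(gilbertRandom(20, 0.4, seed = 6))
  traj <- simulateOscillators(net, quickConfig(nRuns = 1), seed = 6)
  fn <- functionalNetwork(traj, 0.3)
  expect_identical(fn$table@nodeDpli, nodeDpli(traj))
})

test_that("the full chain recovers a prescribed lag gradient", {
  lags <- seq(0.8, -0.8, length.out = 10)
  sig <- generateSyntheticEEG(10, fsHz = 250, durationS = 30, baseFreqHz = 10,
                              phaseLagsRad = lags, couplingJitterSd = 0.05,
                              noiseSd = 0.5, seed = 9)
  res <- analyzeSignalNetwork(sig)
  # leading channels (larger prescribed lag) have larger node dPLI
  expect_gte(spearman(lags, res$nodeDpli), 0.9)
  expect_equal(res$nEpochs, 5) # 28 s after trimming -> 5 epochs
})

test_that("epoch averaging reduces the variance of node dPLI", {
  single <- c(); averaged <- c()
  for (s in 1:8) {
    sig <- generateSyntheticEEG(2, fsHz = 125, durationS = 22,
                                baseFreqHz = 10,
                                phaseLagsRad = c(0.2, -0.2),
                                couplingJitterSd = 0.4, noiseSd = 1, seed = s)
    traj <- bandpassPhase(sig, alphaBand)
    eps <- epochSignal(traj, 5)
    per <- vapply(eps, function(e) nodeDpli(e)[1], numeric(1))
    single <- c(single, per[1])
    averaged <- c(averaged, mean(per))
  }
  expect_lt(var(averaged), var(single))
})

test_that("threshold sweep reports stability across fractions", {
  sig <- generateSyntheticEEG(6, fsHz = 250, durationS = 15, seed = 4)
  traj <- bandpassPhase(sig, alphaBand)
  sw <- thresholdSweep(traj)
  expect_equal(sw$fraction, seq(0.1, 0.5, by = 0.1))
  expect_true(all(is.finite(sw$degreeDpliRho)))
})
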