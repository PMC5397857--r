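# Experiment drivers orchestrating the full chains (network generation or
# loading -> simulation -> analytic solvers -> directionality -> correlation
# report). These functions, together with the thin command-line wrapper in
# inst/cli/netphase.R, are the package's batch interface. One seed governs
# network generation, initial phases, and noise through a documented
# seed-splitting scheme (splitSeed).

# simulate + solve + correlate one network at the comparison coupling
compareOnNetwork <- function(network, config, seed) {
  ens <- simulateEnsemble(network, config, seed = seed)
  mfa <- solveMFA(network, config)
  lop <- solveLOP(network, config)
  deg <- degrees(network, "weighted")
  list(
    network = network, ensemble = ens, mfa = mfa, lop = lop,
    rhoMfaSim = spearman(mfa@phiStar, ens$phiMean),
    rhoLopSim = spearman(lop@phiStar, ens$phiMean),
    rhoPhiDpli = spearman(ens$phiMean, ens$nodeDpli),
    rhoDegPhi = spearman(deg, ens$phiMean),
    rhoDegDpli = spearman(deg, ens$nodeDpli),
    lopAbsError = mean(abs(wrapPhase(lop@phiStar - ens$phiMean)),
                       na.rm = TRUE),
    report = correlationReport(deg, ens$phiMean, ens$nodeDpli))
}

writeReportFiles <- function(res, outDir, stem) {
  if (is.null(outDir)) return(invisible(NULL))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(node_id = nodeIds(res$network),
                   degree = degrees(res$network, "weighted"),
                   phi_sim = res$ensemble$phiMean,
                   phi_mfa = res$mfa@phiStar,
                   phi_lop = res$lop@phiStar,
                   node_dpli = res$ensemble$nodeDpli)
  utils::write.csv(df, file.path(outDir, paste0(stem, "_nodes.csv")),
                   row.names = FALSE)
  utils::write.csv(res$report, file.path(outDir, paste0(stem, "_report.csv")),
                   row.names = FALSE)
  invisible(NULL)
}

#' Model-network experiment: random and scale-free families
#'
#' Generates one Gilbert random and one scale-free network (largest
#' components), sweeps the coupling strength over a grid to confirm the
#' degree-phase sign pattern, and at the comparison coupling `compareS`
#' runs the full run-averaged simulation, both analytic solvers (MFA and
#' LOP), and the directionality analysis, reporting the three-way Spearman
#' correlation table for each family.
#'
#' @param nNodes nodes per network (default 100).
#' @param epsilon Gilbert connectivity margin.
#' @param gamma scale-free degree exponent magnitude.
#' @param sGrid coupling strengths swept (quick, un-averaged runs).
#' @param compareS coupling used for the full comparison (default 5).
#' @param config base [SimConfig-class]; its `couplingS` is overridden per
#'   sweep point.
#' @param seed master seed (split across network generation and simulation).
#' @param outDir optional directory for CSV artifacts.
#' @return a list with `sweep` (data.frame S x family -> degree-phase rho)
#'   and per-family results (`random`, `scaleFree`), each as returned by the
#'   internal comparison: simulated ensemble, MFA/LOP solutions, and the
#'   Spearman correlations (`rhoMfaSim`, `rhoLopSim`, `rhoPhiDpli`, ...).
#' @export
runModelNetworks <- function(nNodes = 100, epsilon = 0.1, gamma = 2.5,
                             sGrid = c(0, 0.3, 1, 3, 5, 6), compareS = 5,
                             config = simConfig(), seed = 1, outDir = NULL) {
  seeds <- splitSeed(seed, 4)
  nets <- list(random = largestComponent(gilbertRandom(nNodes, epsilon,
                                                       seed = seeds[1])),
               scaleFree = largestComponent(scaleFree(nNodes, gamma,
                                                      seed = seeds[2])))
  # coupling sweep: single short runs, sign pattern only
  sweepCfg <- simConfig(couplingS = compareS,
                        naturalFreqHz = config@naturalFreqHz,
                        betaRad = config@betaRad, noiseSd = config@noiseSd,
                        dtS = config@dtS, durationS = 10, transientS = 5,
                        nRuns = 1)
  sweep <- do.call(rbind, lapply(names(nets), function(fam) {
    do.call(rbind, lapply(sGrid, function(S) {
      cfg <- sweepCfg; cfg@couplingS <- S
      ens <- simulateEnsemble(nets[[fam]], cfg, seed = seeds[3],
                              computeDpli = FALSE)
      data.frame(family = fam, S = S,
                 rhoDegPhi = spearman(degrees(nets[[fam]]), ens$phiMean))
    }))
  }))
  cfg <- config; cfg@couplingS <- compareS
  validObject(cfg)
  results <- lapply(names(nets), function(fam)
    compareOnNetwork(nets[[fam]], cfg, seed = seeds[4]))
  names(results) <- names(nets)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(sweep, file.path(outDir, "coupling_sweep.csv"),
                     row.names = FALSE)
    for (fam in names(results)) writeReportFiles(results[[fam]], outDir, fam)
  }
  c(list(sweep = sweep, compareS = compareS, seed = seed), results)
}

#' Connectome experiment: analysis of a supplied structural network
#'
#' Runs the simulation + MFA/LOP + directionality chain on a user-supplied
#' connectome-style weighted adjacency matrix (e.g. a DTI-derived structural
#' network), restricted to its largest component. Oscillator frequencies
#' default to 10 Hz, inside the 6-12 Hz band where brain recordings show
#' their dominant spectral peak. Reports the correlation table, the mean
#' absolute LOP prediction error, and the hub-phase-lag sign structure
#' (negative degree-phase and degree-dPLI correlations).
#'
#' @param network an [OscillatorNetwork-class] or a path accepted by
#'   [loadNetwork()].
#' @param mode `"weighted"` (as supplied) or `"binary"` (binarised couplings).
#' @param config a [SimConfig-class].
#' @param seed master seed.
#' @param outDir optional directory for CSV artifacts.
#' @return the comparison list (see [runModelNetworks()]) plus
#'   `signStructure`, a named logical vector checking hub phase-lag
#'   (`degPhiNegative`, `degDpliNegative`).
#' @export
runConnectome <- function(network, mode = c("weighted", "binary"),
                          config = simConfig(), seed = 1, outDir = NULL) {
  mode <- match.arg(mode)
  if (is.character(network)) network <- loadNetwork(network)
  stopifnot(is(network, "OscillatorNetwork"))
  if (mode == "binary")
    network <- oscillatorNetwork((network@adjacency > 0) * 1,
                                 nodeIds = network@nodeIds,
                                 coordinates = network@coordinates)
  network <- largestComponent(network)
  res <- compareOnNetwork(network, config, seed = seed)
  res$signStructure <- c(degPhiNegative = res$rhoDegPhi < 0,
                         degDpliNegative = res$rhoDegDpli < 0)
  writeReportFiles(res, outDir, "connectome")
  res
}

#' Signal experiment: functional-network analysis of a recording
#'
#' Applies [analyzeSignalNetwork()] to a multichannel signal (loaded from a
#' channels x samples CSV, or generated synthetically when `signal` is
#' `NULL`), and reports the degree-dPLI correlation and epoch count.
#'
#' @param signal a [MultichannelSignal-class], a CSV path (channels x
#'   samples; requires `fsHz`), or `NULL` to analyse a synthetic signal.
#' @param fsHz sampling rate for CSV input.
#' @param nChannels,durationS,baseFreqHz,phaseLagsRad,couplingJitterSd,noiseSd
#'   passed to [generateSyntheticEEG()] when `signal` is `NULL`.
#' @param band,epochS,thresholdFraction passed to [analyzeSignalNetwork()].
#' @param seed seed for the synthetic generator.
#' @param outDir optional directory for CSV artifacts.
#' @return the [analyzeSignalNetwork()] result plus `nChannels` and `seed`.
#' @export
runEEG <- function(signal = NULL, fsHz = 500, nChannels = 10,
                   durationS = 30, baseFreqHz = 10, phaseLagsRad = NULL,
                   couplingJitterSd = 0.1, noiseSd = 0.5, band = "auto",
                   epochS = 5, thresholdFraction = 0.30, seed = 1,
                   outDir = NULL) {
  if (is.null(signal)) {
    signal <- generateSyntheticEEG(nChannels, fsHz, durationS, baseFreqHz,
                                   phaseLagsRad, couplingJitterSd, noiseSd,
                                   seed = seed)
  } else if (is.character(signal)) {
    M <- as.matrix(utils::read.csv(signal, header = FALSE))
    signal <- multichannelSignal(M, fsHz)
  }
  res <- analyzeSignalNetwork(signal, band = band, epochS = epochS,
                              thresholdFraction = thresholdFraction)
  res$nChannels <- nNodes(signal)
  res$seed <- seed
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(data.frame(channel = names(res$degree),
                                degree = res$degree, phi = res$phiMean,
                                node_dpli = res$nodeDpli),
                     file.path(outDir, "eeg_nodes.csv"), row.names = FALSE)
    utils::write.csv(res$dpli, file.path(outDir, "eeg_dpli.csv"))
  }
  res
}
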