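#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' OscillatorNetwork: a structural coupling network
#'
#' Container for a weighted (or binary) coupling matrix. Entry `A[j, k]` is
#' the coupling *from* node `k` *to* node `j`, so the in-strength of node `j`
#' (its degree \eqn{n_j}) is the row sum \eqn{\sum_k A_{jk}}. Optional node
#' coordinates (in mm) support distance-proportional transmission delays.
#'
#' @slot adjacency numeric square matrix, nonnegative, zero diagonal.
#' @slot nodeIds character vector of node labels (row/column order).
#' @slot coordinates `NULL` or a numeric matrix (one row per node, columns
#'   x/y/z in mm) used by the distance-delay simulation mode.
#' @slot undirected logical; if `TRUE` the adjacency must be symmetric.
#'
#' @seealso [oscillatorNetwork()], [gilbertRandom()], [scaleFree()],
#'   [loadNetwork()]
#' @export
setClass("OscillatorNetwork",
  representation(
    adjacency   = "matrix",
    nodeIds     = "character",
    coordinates = "matrixOrNULL",
    undirected  = "logical"
  )
)

setValidity("OscillatorNetwork", function(object) {
  A <- object@adjacency
  msg <- character()
  if (!is.numeric(A)) msg <- c(msg, "adjacency must be numeric")
  if (nrow(A) != ncol(A))
    msg <- c(msg, sprintf("adjacency must be square (got %d x %d)",
                          nrow(A), ncol(A)))
  if (anyNA(A)) msg <- c(msg, "adjacency contains NA")
  else {
    if (any(A < 0)) msg <- c(msg, "adjacency entries must be >= 0")
    if (nrow(A) == ncol(A) && any(diag(A) != 0))
      msg <- c(msg, "diagonal must be zero (no self-coupling)")
    if (isTRUE(object@undirected) && nrow(A) == ncol(A) &&
        !isTRUE(all.equal(A, t(A), tolerance = 1e-12)))
      msg <- c(msg, "network declared undirected but adjacency != t(adjacency)")
  }
  if (length(object@nodeIds) != nrow(A))
    msg <- c(msg, "nodeIds length must equal the number of nodes")
  if (!is.null(object@coordinates)) {
    if (nrow(object@coordinates) != nrow(A))
      msg <- c(msg, "coordinates must have one row per node")
    if (!ncol(object@coordinates) %in% 2:3)
      msg <- c(msg, "coordinates must have 2 or 3 columns")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OscillatorNetwork
#'
#' @param adjacency nonnegative square numeric matrix; `adjacency[j, k]` is
#'   the coupling from node `k` to node `j`. The diagonal must be zero.
#' @param nodeIds optional character labels; defaults to the matrix dimnames
#'   or `"n1" ... "nN"`.
#' @param coordinates optional numeric matrix of node positions (mm), one row
#'   per node, 2 or 3 columns.
#' @param undirected logical; defaults to `TRUE` when the matrix is symmetric.
#' @return an [OscillatorNetwork-class] object.
#' @examples
#' net <- oscillatorNetwork(rbind(c(0, 1, 1), c(1, 0, 0), c(1, 0, 0)))
#' degrees(net)
#' @export
oscillatorNetwork <- function(adjacency, nodeIds = NULL, coordinates = NULL,
                              undirected = NULL) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "double"
  if (is.null(nodeIds)) {
    nodeIds <- if (!is.null(rownames(adjacency))) rownames(adjacency)
               else paste0("n", seq_len(nrow(adjacency)))
  }
  nodeIds <- as.character(nodeIds)
  dimnames(adjacency) <- list(nodeIds, nodeIds)
  if (is.null(undirected))
    undirected <- isTRUE(all.equal(adjacency, t(adjacency), tolerance = 1e-12))
  if (!is.null(coordinates)) {
    coordinates <- as.matrix(coordinates)
    storage.mode(coordinates) <- "double"
    rownames(coordinates) <- nodeIds
  }
  new("OscillatorNetwork", adjacency = adjacency, nodeIds = nodeIds,
      coordinates = coordinates, undirected = undirected)
}

#' SimConfig: simulation and solver parameters
#'
#' Holds all dynamical parameters of the coupled-oscillator model: global
#' coupling strength S, natural frequencies (Hz), the delay specification
#' (constant phase offset beta, a uniform time delay, or
#' distance-proportional delays), Gaussian white-noise level, integration
#' step, duration, burn-in, and the number of runs for run-averaging.
#'
#' @slot couplingS scalar coupling strength S (>= 0).
#' @slot naturalFreqHz natural frequency f in Hz, scalar or per node.
#' @slot delayMode one of `"offset"`, `"uniform_delay"`, `"distance_delay"`.
#' @slot betaRad phase offset beta in radians (offset mode).
#' @slot tauS uniform transmission delay in seconds (uniform_delay mode).
#' @slot velocityMPerS conduction velocity in m/s (distance_delay mode).
#' @slot noiseSd white-noise standard deviation (rad/sqrt(s)).
#' @slot noiseMean white-noise mean (rad/s); a nonzero mean only shifts the
#'   collective frequency and cancels in relative phases.
#' @slot dtS integration step in seconds.
#' @slot durationS total simulated time in seconds.
#' @slot transientS discarded burn-in in seconds.
#' @slot storeEveryN store every N-th integration step for analysis (the
#'   integrator always advances at `dtS`); the trajectory's sampling
#'   interval is `dtS * storeEveryN`.
#' @slot nRuns number of independent runs for run-averaging.
#' @seealso [simConfig()], [simulateOscillators()]
#' @export
setClass("SimConfig",
  representation(
    couplingS     = "numeric",
    naturalFreqHz = "numeric",
    delayMode     = "character",
    betaRad       = "numeric",
    tauS          = "numeric",
    velocityMPerS = "numeric",
    noiseSd       = "numeric",
    noiseMean     = "numeric",
    dtS           = "numeric",
    durationS     = "numeric",
    transientS    = "numeric",
    storeEveryN   = "integer",
    nRuns         = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@couplingS < 0) msg <- c(msg, "couplingS must be >= 0")
  if (any(object@naturalFreqHz <= 0)) msg <- c(msg, "naturalFreqHz must be > 0")
  if (!object@delayMode %in% c("offset", "uniform_delay", "distance_delay"))
    msg <- c(msg, "delayMode must be offset, uniform_delay or distance_delay")
  if (object@delayMode == "offset" && !length(object@betaRad))
    msg <- c(msg, "offset mode requires betaRad")
  if (object@delayMode == "uniform_delay" &&
      (!length(object@tauS) || object@tauS < 0))
    msg <- c(msg, "uniform_delay mode requires tauS >= 0")
  if (object@delayMode == "distance_delay" &&
      (!length(object@velocityMPerS) || object@velocityMPerS <= 0))
    msg <- c(msg, "distance_delay mode requires velocityMPerS > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@dtS <= 0) msg <- c(msg, "dtS must be > 0")
  if (!(object@durationS > object@transientS && object@transientS >= 0))
    msg <- c(msg, "need durationS > transientS >= 0")
  if (object@storeEveryN < 1L) msg <- c(msg, "storeEveryN must be >= 1")
  if (object@nRuns < 1L) msg <- c(msg, "nRuns must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' Defaults reflect the canonical study conditions of the package: 10 Hz
#' oscillators, phase offset beta = omega * 4 ms (~0.251 rad at 10 Hz,
#' the short-delay approximation of a 4 ms transmission delay), unit-SD
#' Gaussian white noise, 1 ms Euler-Maruyama step, 60 s runs with the first
#' half discarded as burn-in, and 20-run averaging.
#'
#' @param couplingS coupling strength S.
#' @param naturalFreqHz natural frequency in Hz (scalar or per node).
#' @param delayMode `"offset"` (default), `"uniform_delay"`, or
#'   `"distance_delay"`.
#' @param betaRad phase offset in radians; default `2*pi*mean(f)*0.004`.
#' @param tauS uniform delay in seconds (uniform_delay mode); default 0.004.
#' @param velocityMPerS conduction velocity in m/s (distance_delay mode).
#' @param noiseSd,noiseMean Gaussian white-noise SD and mean.
#' @param dtS integration step (s).
#' @param durationS total duration (s).
#' @param transientS burn-in discarded before analysis (s); default half the
#'   duration.
#' @param storeEveryN keep every N-th integration step for analysis
#'   (default 5: a 200 Hz analysis rate at the 1 ms default step, 20
#'   samples per cycle of a 10 Hz oscillation).
#' @param nRuns number of runs for averaging.
#' @return a [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(couplingS = 5)
#' cfg
#' @export
simConfig <- function(couplingS = 5, naturalFreqHz = 10, delayMode = "offset",
                      betaRad = NULL, tauS = 0.004, velocityMPerS = numeric(),
                      noiseSd = 1, noiseMean = 0, dtS = 0.001, durationS = 60,
                      transientS = NULL, storeEveryN = 5, nRuns = 20) {
  if (is.null(betaRad))
    betaRad <- 2 * pi * mean(naturalFreqHz) * 0.004
  if (is.null(transientS)) transientS <- durationS / 2
  new("SimConfig", couplingS = couplingS, naturalFreqHz = naturalFreqHz,
      delayMode = delayMode, betaRad = betaRad, tauS = tauS,
      velocityMPerS = velocityMPerS, noiseSd = noiseSd, noiseMean = noiseMean,
      dtS = dtS, durationS = durationS, transientS = transientS,
      storeEveryN = as.integer(storeEveryN), nRuns = as.integer(nRuns))
}

#' PhaseTrajectory: phase time series
#'
#' Phases are stored *unwrapped* (cumulative radians), one row per node, one
#' column per time sample; use [wrappedPhases()] for the (-pi, pi] view.
#' Trajectories returned by [simulateOscillators()] start after the burn-in.
#'
#' @slot phases numeric matrix, nodes x samples, unwrapped radians.
#' @slot dtS sampling interval in seconds.
#' @slot nodeIds character node labels.
#' @export
setClass("PhaseTrajectory",
  representation(phases = "matrix", dtS = "numeric", nodeIds = "character")
)

setValidity("PhaseTrajectory", function(object) {
  msg <- character()
  if (object@dtS <= 0) msg <- c(msg, "dtS must be > 0")
  if (length(object@nodeIds) != nrow(object@phases))
    msg <- c(msg, "nodeIds length must match the number of rows")
  if (length(msg)) msg else TRUE
})

#' Construct a PhaseTrajectory
#' @param phases nodes x samples numeric matrix of unwrapped phases (rad).
#' @param dtS sampling interval (s).
#' @param nodeIds optional node labels.
#' @return a [PhaseTrajectory-class] object.
#' @export
phaseTrajectory <- function(phases, dtS, nodeIds = NULL) {
  phases <- as.matrix(phases)
  if (is.null(nodeIds)) {
    nodeIds <- if (!is.null(rownames(phases))) rownames(phases)
               else paste0("n", seq_len(nrow(phases)))
  }
  rownames(phases) <- nodeIds
  new("PhaseTrajectory", phases = phases, dtS = dtS,
      nodeIds = as.character(nodeIds))
}

#' AnalyticSolution: structure-predicted stationary phases
#'
#' Result of [solveMFA()] or [solveLOP()]: the per-node stationary relative
#' phase \eqn{\phi_j^*} in the rotating frame (gauge: population mean phase
#' = 0), per-node locking flags, the collective frequency Omega, and the
#' order parameters (global R for MFA; local r_j and local mean-field phases
#' Theta_j for LOP). For drifting (unlocked) nodes `phiStar` holds the
#' circular mean of the stationary drift distribution; see
#' [driftDistribution()].
#'
#' @slot method `"MFA"` or `"LOP"`.
#' @slot phiStar per-node stationary relative phase, radians in (-pi, pi].
#' @slot locked per-node logical: does the locking condition hold
#'   (MFA: \eqn{S n_j R > |\Delta_j|}; LOP: \eqn{S n_j r_j > |\Delta_j|})?
#' @slot omega collective frequency Omega (rad/s).
#' @slot globalR global order parameter R in `[0, 1]`.
#' @slot localR per-node local order parameter r_j (LOP; empty for MFA).
#' @slot localTheta per-node local mean-field phase in the rotating frame
#'   (LOP; empty for MFA).
#' @slot residual maximum stationarity residual (rad/s) over locked nodes.
#' @slot degree per-node weighted degree n_j used by the solver.
#' @slot couplingS,betaRad,naturalOmega solver inputs retained for
#'   [driftDistribution()] and export.
#' @slot nodeIds character node labels.
#' @export
setClass("AnalyticSolution",
  representation(
    method       = "character",
    phiStar      = "numeric",
    locked       = "logical",
    omega        = "numeric",
    globalR      = "numeric",
    localR       = "numeric",
    localTheta   = "numeric",
    residual     = "numeric",
    degree       = "numeric",
    couplingS    = "numeric",
    betaRad      = "numeric",
    naturalOmega = "numeric",
    nodeIds      = "character"
  )
)

#' DirectionalityTable: pairwise and node-level dPLI/PLI
#'
#' @slot dpliMatrix N x N antisymmetric matrix in `[-1, 1]`; entry (i, j) is
#'   positive when node i consistently phase-leads node j.
#' @slot pliMatrix elementwise absolute value of `dpliMatrix`.
#' @slot nodeDpli per-node mean dPLI over all partners.
#' @slot nodeIds character node labels.
#' @seealso [directionalityTable()], [dpli()], [nodeDpli()]
#' @export
setClass("DirectionalityTable",
  representation(dpliMatrix = "matrix", pliMatrix = "matrix",
                 nodeDpli = "numeric", nodeIds = "character")
)

setValidity("DirectionalityTable", function(object) {
  D <- object@dpliMatrix
  msg <- character()
  if (any(abs(D + t(D)) > 1e-12)) msg <- c(msg, "dpliMatrix must be antisymmetric")
  if (any(abs(object@pliMatrix - abs(D)) > 1e-12))
    msg <- c(msg, "pliMatrix must equal |dpliMatrix|")
  if (length(msg)) msg else TRUE
})

#' MultichannelSignal: a multichannel oscillatory recording
#'
#' @slot samples channels x samples numeric matrix (arbitrary units).
#' @slot fsHz sampling rate in Hz.
#' @slot channelIds character channel labels.
#' @seealso [multichannelSignal()], [generateSyntheticEEG()]
#' @export
setClass("MultichannelSignal",
  representation(samples = "matrix", fsHz = "numeric", channelIds = "character")
)

setValidity("MultichannelSignal", function(object) {
  msg <- character()
  if (object@fsHz <= 0) msg <- c(msg, "fsHz must be > 0")
  if (anyNA(object@samples)) msg <- c(msg, "samples contain NA/NaN")
  if (length(object@channelIds) != nrow(object@samples))
    msg <- c(msg, "channelIds length must match the number of rows")
  if (length(msg)) msg else TRUE
})

#' Construct a MultichannelSignal
#' @param samples channels x samples numeric matrix.
#' @param fsHz sampling rate (Hz).
#' @param channelIds optional channel labels.
#' @return a [MultichannelSignal-class] object.
#' @export
multichannelSignal <- function(samples, fsHz, channelIds = NULL) {
  samples <- as.matrix(samples)
  if (is.null(channelIds)) {
    channelIds <- if (!is.null(rownames(samples))) rownames(samples)
                  else paste0("ch", seq_len(nrow(samples)))
  }
  rownames(samples) <- channelIds
  new("MultichannelSignal", samples = samples, fsHz = fsHz,
      channelIds = as.character(channelIds))
}

#' BandSpec: a frequency band
#'
#' @slot lowHz,highHz band edges in Hz (0 < low < high).
#' @slot provenance `"fixed"` or `"peak±2"` (selected around a spectral peak).
#' @export
setClass("BandSpec",
  representation(lowHz = "numeric", highHz = "numeric", provenance = "character")
)

setValidity("BandSpec", function(object) {
  if (!(object@lowHz > 0 && object@highHz > object@lowHz))
    "need 0 < lowHz < highHz" else TRUE
})

#' Construct a BandSpec
#' @param lowHz,highHz band edges in Hz.
#' @param provenance how the band was chosen (`"fixed"` by default).
#' @return a [BandSpec-class] object.
#' @export
bandSpec <- function(lowHz, highHz, provenance = "fixed") {
  new("BandSpec", lowHz = lowHz, highHz = highHz, provenance = provenance)
}
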