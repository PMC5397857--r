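#' Simulate coupled phase oscillators on a network
#'
#' Integrates the Kuramoto-type model
#' \deqn{\dot\theta_j = \omega_j + S \sum_k A_{jk} \sin(\theta_k(t-\tau_{jk})
#'   - \theta_j(t) - \beta) + \xi_j(t)}
#' by Euler-Maruyama (noise scaled by sqrt(dt)). In `"offset"` mode all
#' \eqn{\tau_{jk} = 0} and the constant frustration \eqn{\beta} stands in for
#' a short transmission delay (\eqn{\beta = \omega\tau}); in the delay modes
#' \eqn{\beta = 0} and phases are read from per-edge history (initialised by
#' backward extrapolation at the natural frequency). Initial phases are
#' uniform on (-pi, pi]. The burn-in (`transientS`) is discarded; the
#' returned trajectory covers only the stationary window.
#'
#' @param network an [OscillatorNetwork-class].
#' @param config a [SimConfig-class]; `"distance_delay"` mode requires node
#'   coordinates on the network.
#' @param seed optional integer seed (caller RNG untouched). With no seed the
#'   current RNG stream is consumed, which is what [simulateEnsemble()] uses.
#' @param initPhases optional initial phases (radians, length N).
#' @return a [PhaseTrajectory-class] of unwrapped phases after burn-in.
#' @examples
#' net <- gilbertRandom(30, seed = 1)
#' cfg <- simConfig(couplingS = 5, durationS = 4, transientS = 2, nRuns = 1)
#' traj <- simulateOscillators(net, cfg, seed = 1)
#' collectiveFrequency(traj) / (2 * pi) # close to, but below, 10 Hz
#' @export
simulateOscillators <- function(network, config, seed = NULL,
                                initPhases = NULL) {
  stopifnot(is(network, "OscillatorNetwork"), is(config, "SimConfig"))
  validObject(config)
  A <- network@adjacency
  N <- nrow(A)
  omega <- 2 * pi * rep_len(config@naturalFreqHz, N)
  dt <- config@dtS
  stride <- config@storeEveryN
  nsteps <- round(config@durationS / dt)
  nsteps <- (nsteps %/% stride) * stride
  withSeed(seed, {
    th0 <- if (is.null(initPhases)) stats::runif(N, -pi, pi)
           else rep_len(initPhases, N)
    phases <- switch(config@delayMode,
      offset = kuramoto_offset_cpp(A, omega, config@couplingS, config@betaRad,
                                   config@noiseSd, config@noiseMean, dt,
                                   nsteps, th0, stride),
      uniform_delay = {
        # the delay kernel keeps full-resolution history; thin afterwards
        D <- matrix(as.integer(round(config@tauS / dt)), N, N)
        full <- kuramoto_delay_cpp(A, D, omega, config@couplingS,
                                   config@noiseSd, config@noiseMean, dt,
                                   nsteps, th0)
        full[, seq(1, nsteps + 1, by = stride), drop = FALSE]
      },
      distance_delay = {
        if (is.null(network@coordinates))
          stop("distance_delay mode requires node coordinates on the network")
        dist <- as.matrix(stats::dist(network@coordinates)) # mm
        tau <- dist / (config@velocityMPerS * 1000)         # mm / (mm/s) = s
        D <- matrix(as.integer(round(tau / dt)), N, N)
        full <- kuramoto_delay_cpp(A, D, omega, config@couplingS,
                                   config@noiseSd, config@noiseMean, dt,
                                   nsteps, th0)
        full[, seq(1, nsteps + 1, by = stride), drop = FALSE]
      })
    keep <- (floor(config@transientS / (dt * stride)) + 1L):ncol(phases)
    phaseTrajectory(phases[, keep, drop = FALSE], dtS = dt * stride,
                    nodeIds = network@nodeIds)
  })
}

#' Collective frequency of a trajectory
#'
#' Omega is the frequency of the population oscillation in the stationary
#' state: the least-squares slope of the unwrapped circular-mean phase
#' versus time.
#'
#' @param traj a [PhaseTrajectory-class] (already past burn-in).
#' @return Omega in rad/s.
#' @export
collectiveFrequency <- function(traj) {
  stopifnot(is(traj, "PhaseTrajectory"))
  Tn <- ncol(traj@phases)
  if (Tn < 2) stop("trajectory must contain at least 2 samples")
  psi <- unwrapPhase(Arg(colMeans(exp(1i * traj@phases))))
  tt <- (seq_len(Tn) - 1) * traj@dtS
  unname(stats::coef(stats::lm.fit(cbind(1, tt), psi))[2])
}

#' Relative phases in the rotating frame
#'
#' Transforms phases into the frame rotating at the collective frequency,
#' \eqn{\phi_j(t) = \mathrm{wrap}(\theta_j(t) - \Omega t - \Phi(t))}, where
#' \eqn{\Phi(t)} is the instantaneous circular-mean phase. Subtracting
#' \eqn{\Phi(t)} enforces the gauge used throughout the package: the
#' population mean phase is 0, so \eqn{\phi_j} measures each node's lead
#' (positive) or lag (negative) relative to the collective oscillation.
#'
#' @param traj a [PhaseTrajectory-class].
#' @param omega collective frequency (rad/s); computed with
#'   [collectiveFrequency()] when `NULL`.
#' @return a list with `phi` (nodes x samples matrix of wrapped relative
#'   phases), `phiMean` (per-node circular mean over the window), and
#'   `omega`.
#' @export
relativePhases <- function(traj, omega = NULL) {
  stopifnot(is(traj, "PhaseTrajectory"))
  if (is.null(omega)) omega <- collectiveFrequency(traj)
  tt <- (seq_len(ncol(traj@phases)) - 1) * traj@dtS
  phi0 <- traj@phases - rep(omega * tt, each = nrow(traj@phases))
  z <- exp(1i * phi0)
  Phi <- Arg(colMeans(z))
  phi <- wrapPhase(phi0 - rep(Phi, each = nrow(phi0)))
  phiMean <- Arg(rowMeans(exp(1i * phi)))
  names(phiMean) <- traj@nodeIds
  rownames(phi) <- traj@nodeIds
  list(phi = phi, phiMean = phiMean, omega = omega)
}

#' Run-averaged simulation of a network
#'
#' Repeats [simulateOscillators()] `config@nRuns` times (fresh initial phases
#' and noise per run; all runs drawn from one seeded RNG stream), and
#' averages the per-node time-averaged relative phases (circular mean across
#' runs) and the pairwise dPLI matrix across runs. This mirrors the
#' run-averaging used for all quantitative comparisons between simulation
#' and the analytic solvers.
#'
#' @param network an [OscillatorNetwork-class].
#' @param config a [SimConfig-class].
#' @param seed integer seed governing every run.
#' @param computeDpli compute the run-averaged dPLI matrix (default TRUE).
#' @return a list: `phiMean` (run-averaged per-node relative phase),
#'   `phiRuns` (runs x nodes matrix), `omega` (mean collective frequency),
#'   `dpli` (run-averaged antisymmetric matrix or NULL), `nodeDpli`,
#'   `nRuns`.
#' @export
simulateEnsemble <- function(network, config, seed = 1, computeDpli = TRUE) {
  N <- nNodes(network)
  phiRuns <- matrix(NA_real_, config@nRuns, N,
                    dimnames = list(NULL, network@nodeIds))
  zAcc <- complex(real = numeric(N))
  dpliAcc <- if (computeDpli) matrix(0, N, N) else NULL
  omegaAcc <- 0
  withSeed(seed, {
    for (r in seq_len(config@nRuns)) {
      traj <- simulateOscillators(network, config, seed = NULL)
      rel <- relativePhases(traj)
      phiRuns[r, ] <- rel$phiMean
      zAcc <- zAcc + exp(1i * rel$phiMean)
      omegaAcc <- omegaAcc + rel$omega
      if (computeDpli) dpliAcc <- dpliAcc + dpli_matrix_cpp(traj@phases)
    }
  })
  phiMean <- Arg(zAcc / config@nRuns)
  names(phiMean) <- network@nodeIds
  out <- list(phiMean = phiMean, phiRuns = phiRuns,
              omega = omegaAcc / config@nRuns, dpli = NULL, nodeDpli = NULL,
              nRuns = config@nRuns)
  if (computeDpli) {
    D <- dpliAcc / config@nRuns
    dimnames(D) <- list(network@nodeIds, network@nodeIds)
    out$dpli <- D
    out$nodeDpli <- rowSums(D) / (N - 1)
  }
  out
}

#' @describeIn wrappedPhases phases of a PhaseTrajectory wrapped to (-pi, pi].
#' @export
setMethod("wrappedPhases", "PhaseTrajectory",
          function(object) wrapPhase(object@phases))

#' @describeIn nNodes nodes in a PhaseTrajectory.
#' @export
setMethod("nNodes", "PhaseTrajectory", function(object) nrow(object@phases))

#' @describeIn nodeIds labels of a PhaseTrajectory.
#' @export
setMethod("nodeIds", "PhaseTrajectory", function(object) object@nodeIds)

setMethod("show", "PhaseTrajectory", function(object) {
  cat(sprintf("PhaseTrajectory: %d nodes x %d samples (dt = %g s, %.3g s)\n",
              nrow(object@phases), ncol(object@phases), object@dtS,
              (ncol(object@phases) - 1) * object@dtS))
  invisible(object)
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: S = %g, f = %s Hz, mode = %s\n",
              object@couplingS,
              paste(signif(unique(object@naturalFreqHz), 4), collapse = "/"),
              object@delayMode))
  extra <- switch(object@delayMode,
    offset = sprintf("beta = %.4g rad", object@betaRad),
    uniform_delay = sprintf("tau = %g ms", 1000 * object@tauS),
    distance_delay = sprintf("velocity = %g m/s", object@velocityMPerS))
  cat(sprintf("  %s; noise sd %g; dt %g s; duration %g s (burn-in %g s); %d runs\n",
              extra, object@noiseSd, object@dtS, object@durationS,
              object@transientS, object@nRuns))
  invisible(object)
})

#' Export a trajectory as CSV plus a JSON sidecar
#'
#' @param traj a [PhaseTrajectory-class].
#' @param dir output directory (created if needed).
#' @param stem file stem; writes `<stem>.csv` (channels x samples) and
#'   `<stem>.json` (dt, node ids).
#' @param meta optional named list merged into the sidecar.
#' @return invisibly, the CSV path.
#' @export
exportTrajectory <- function(traj, dir, stem = "trajectory", meta = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(stem, ".csv"))
  utils::write.table(traj@phases, csv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  side <- c(list(dt_s = traj@dtS, node_ids = traj@nodeIds), meta)
  jsonlite::write_json(side, file.path(dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(csv)
}
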