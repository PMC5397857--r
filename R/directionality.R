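#' Directed phase lag index (dPLI) between two phase series
#'
#' The dPLI is the time-average of the sign of the instantaneous phase
#' difference, wrapped to (-pi, pi] before taking the sign:
#' \deqn{dPLI_{ij} = \langle \mathrm{sign}(\Delta\theta_{ij}(t)) \rangle_t.}
#' A constant lead of i over j gives +1, a constant lag -1, and random
#' alternation ~0. Exact zero differences contribute 0. The measure is
#' invariant to adding any common time-varying phase to both inputs.
#'
#' @param phasesI,phasesJ numeric phase series in radians, equal length.
#' @return scalar in `[-1, 1]`.
#' @examples
#' t <- seq(0, 1, by = 0.01)
#' dpli(2 * pi * 10 * t + 0.3, 2 * pi * 10 * t) # 1: constant lead
#' @export
dpli <- function(phasesI, phasesJ) {
  if (length(phasesI) != length(phasesJ))
    stop(sprintf("phase series lengths differ: %d vs %d",
                 length(phasesI), length(phasesJ)))
  mean(sign(wrapPhase(phasesI - phasesJ)))
}

#' Phase lag index (PLI) between two phase series
#'
#' `pli = |dpli|`: 1 for a consistent lead *or* lag (phase locking), ~0 when
#' the pair randomly alternates between leading and lagging.
#'
#' @inheritParams dpli
#' @return scalar in `[0, 1]`.
#' @export
pli <- function(phasesI, phasesJ) abs(dpli(phasesI, phasesJ))

#' Pairwise and node-level dPLI/PLI of a trajectory
#'
#' Computes the full antisymmetric dPLI matrix, the PLI matrix (its absolute
#' value), and per-node dPLI (mean over all partners; positive = the node
#' leads the network on balance and acts as a directional source, negative =
#' it lags and acts as a target).
#'
#' @param traj a [PhaseTrajectory-class] or a nodes x samples phase matrix.
#' @return a [DirectionalityTable-class].
#' @export
directionalityTable <- function(traj) {
  phases <- if (is(traj, "PhaseTrajectory")) traj@phases else as.matrix(traj)
  ids <- if (is(traj, "PhaseTrajectory")) traj@nodeIds
         else paste0("n", seq_len(nrow(phases)))
  if (nrow(phases) < 2) stop("need at least 2 nodes")
  D <- dpli_matrix_cpp(phases)
  dimnames(D) <- list(ids, ids)
  nd <- rowSums(D) / (nrow(D) - 1)
  new("DirectionalityTable", dpliMatrix = D, pliMatrix = abs(D),
      nodeDpli = nd, nodeIds = ids)
}

#' Node-level dPLI
#'
#' Row means of the pairwise dPLI matrix excluding the diagonal. By
#' antisymmetry the node values always sum to zero.
#'
#' @param x a [PhaseTrajectory-class], phase matrix, or
#'   [DirectionalityTable-class].
#' @return named numeric vector of per-node dPLI.
#' @export
nodeDpli <- function(x) {
  if (is(x, "DirectionalityTable")) return(x@nodeDpli)
  directionalityTable(x)@nodeDpli
}

# P(wrapped difference > 0) - P(< 0) for a wrapped-normal difference centred
# at d with SD s; summed over enough wraps for machine accuracy
wrappedSignExpectation <- function(d, s, nWrap = 4) {
  if (s <= 0) return(sign(wrapPhase(d)))
  m <- (-nWrap):nWrap
  pPos <- sum(stats::pnorm((pi + 2 * pi * m - d) / s) -
              stats::pnorm((2 * pi * m - d) / s))
  2 * pPos - 1
}

#' Analytic node dPLI from stationary phases
#'
#' Predicts the node-level dPLI implied by an analytic solution: each pair
#' contributes the expected sign of the wrapped difference of the two
#' stationary phases under independent Gaussian phase jitter of SD
#' `noiseSd` per node (zero-noise limit: the plain sign of
#' \eqn{\phi_i^* - \phi_j^*}). Because phase is monotone decreasing in
#' degree, the predicted node dPLI inherits the hub-lag/periphery-lead
#' ordering.
#'
#' @param solution a converged [AnalyticSolution-class].
#' @param noiseSd stationary phase-jitter SD (radians) per node; default 0.
#' @return named numeric vector of predicted per-node dPLI (NaN entries of
#'   `phiStar` propagate).
#' @export
analyticDpli <- function(solution, noiseSd = 0) {
  stopifnot(is(solution, "AnalyticSolution"))
  phi <- solution@phiStar
  N <- length(phi)
  if (N < 2) stop("need at least 2 nodes")
  s <- noiseSd * sqrt(2) # SD of the difference of two jittered phases
  D <- matrix(0, N, N)
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    v <- wrappedSignExpectation(wrapPhase(phi[i] - phi[j]), s)
    D[i, j] <- v; D[j, i] <- -v
  }
  out <- rowSums(D) / (N - 1)
  names(out) <- solution@nodeIds
  out
}

#' Spearman correlation report for degree, phase, and dPLI
#'
#' Pairwise Spearman rank correlations (average-rank ties) with two-sided
#' asymptotic p-values among the three per-node indices of the
#' degree -> phase -> directionality chain. A constant vector yields NA for
#' its pairs (rho undefined).
#'
#' @param degree,phi,nodeDpli equal-length per-node vectors (N >= 3).
#' @return data.frame with columns `pair`, `rho`, `p`.
#' @examples
#' net <- gilbertRandom(40, seed = 3)
#' sol <- solveMFA(net, simConfig())
#' correlationReport(degrees(net), sol@phiStar, analyticDpli(sol))
#' @export
correlationReport <- function(degree, phi, nodeDpli) {
  n <- length(degree)
  stopifnot(length(phi) == n, length(nodeDpli) == n, n >= 3)
  vars <- list(degree = degree, phi = phi, dPLI = nodeDpli)
  combos <- utils::combn(names(vars), 2)
  rows <- apply(combos, 2, function(pr) {
    x <- vars[[pr[1]]]; y <- vars[[pr[2]]]
    ok <- is.finite(x) & is.finite(y)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(data.frame(pair = paste(pr, collapse = "~"),
                        rho = NA_real_, p = NA_real_))
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    data.frame(pair = paste(pr, collapse = "~"),
               rho = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, rows)
}

# Spearman rho alone (average-rank ties), tolerating NaN entries
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  stats::cor(x[ok], y[ok], method = "spearman")
}

#' @describeIn nodeIds labels of a DirectionalityTable.
#' @export
setMethod("nodeIds", "DirectionalityTable", function(object) object@nodeIds)

setMethod("show", "DirectionalityTable", function(object) {
  cat(sprintf("DirectionalityTable: %d nodes; node dPLI in [%.3f, %.3f]\n",
              length(object@nodeDpli), min(object@nodeDpli),
              max(object@nodeDpli)))
  invisible(object)
})
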