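# Both solvers work in the rotating frame at the collective frequency Omega,
# with the gauge Phi = 0 (population mean phase zero). A locked node j sits at
#   phi_j* = Phi_j - beta + asin(Delta_j / (S n_j r_j))       (LOP)
#   phi_j* =       - beta + asin(Delta_j / (S n_j R))          (MFA, Phi_j = Phi = 0)
# on the principal (stable) arcsin branch, where Delta_j = omega_j - Omega.
# An unlocked (drifting) node contributes the circular mean of its stationary
# drift distribution P(phi) ~ 1/|dphi/dt| to the mean fields.

# resolve the phase offset actually used by the solvers: delays are converted
# via the short-delay approximation beta = omega * tau
effectiveBeta <- function(config) {
  switch(config@delayMode,
    offset = config@betaRad,
    uniform_delay = 2 * pi * mean(config@naturalFreqHz) * config@tauS,
    distance_delay = stop(
      "distance_delay has no single phase offset; re-express the config in offset mode first"))
}

# circular means of the stationary densities of
# dphi/dt = delta + K sin(Phi - phi - beta), vectorised over nodes; valid for
# |delta| > K (drifting nodes). K = 0 gives a uniform density (mean 0).
driftPhasor <- function(delta, K, Phi, beta, grid = 512) {
  m <- length(delta)
  if (!m) return(complex(0))
  phi <- seq(-pi, pi, length.out = grid + 1)[-1]
  v <- abs(delta + K * sin(outer(Phi - beta, phi, "-")))
  p <- 1 / v
  z <- as.vector((p %*% exp(1i * phi)) / rowSums(p))
  z[K <= 0] <- complex(real = 0, imaginary = 0)
  z
}

# per-node phasors given candidate Omega and frozen fields (rvec, Phivec):
# locked nodes as unit phasors at the arcsin solution, drifting nodes as
# their drift-distribution circular mean
nodePhasors <- function(Omega, omega, S, nj, rvec, Phivec, beta) {
  delta <- omega - Omega
  K <- S * nj * rvec
  locked <- K > abs(delta)
  z <- complex(length(nj))
  if (any(locked))
    z[locked] <- exp(1i * (Phivec[locked] - beta +
                           asin(delta[locked] / K[locked])))
  if (any(!locked))
    z[!locked] <- driftPhasor(delta[!locked], K[!locked], Phivec[!locked],
                              beta)
  list(z = z, locked = locked, delta = delta, K = K)
}

# root of Im(mean(z))(Omega) = 0 with Re > 0: grid scan for sign changes over
# the bracket, refine each by uniroot, keep the most coherent (largest Re) root
solveOmega <- function(omega, S, nj, rvec, Phivec, beta, lower, upper,
                       nGrid = 400) {
  f <- function(Om) {
    Z <- mean(nodePhasors(Om, omega, S, nj, rvec, Phivec, beta)$z)
    c(Im(Z), Re(Z))
  }
  grid <- seq(lower, upper, length.out = nGrid)
  vals <- vapply(grid, f, numeric(2))
  im <- vals[1, ]
  sc <- which(im[-1] * im[-nGrid] <= 0 & !(im[-1] == 0 & im[-nGrid] == 0))
  if (!length(sc)) return(NULL)
  best <- NULL
  for (i in sc) {
    root <- tryCatch(
      stats::uniroot(function(Om) f(Om)[1], c(grid[i], grid[i + 1]),
                     tol = 1e-12 * max(1, abs(upper)))$root,
      error = function(e) NULL)
    if (is.null(root)) next
    re <- f(root)[2]
    if (re > 0 && (is.null(best) || re > best$re))
      best <- list(Omega = root, re = re)
  }
  if (is.null(best)) NULL else best$Omega
}

# fast path: expanding bracket around a previous Omega, uniroot on the gauge
# residual; falls back to the global grid scan when no sign change is found
gaugeOmega <- function(omega, S, nj, rvec, Phivec, beta, OmegaPrev,
                       loBound, hiBound) {
  g <- function(Om)
    Im(mean(nodePhasors(Om, omega, S, nj, rvec, Phivec, beta)$z))
  if (!is.null(OmegaPrev)) {
    half <- max(0.5, 0.02 * S * max(nj))
    lo <- max(loBound, OmegaPrev - half)
    hi <- min(hiBound, OmegaPrev + half)
    glo <- g(lo); ghi <- g(hi)
    while (glo * ghi > 0 && (lo > loBound || hi < hiBound)) {
      half <- 2 * half
      lo <- max(loBound, OmegaPrev - half)
      hi <- min(hiBound, OmegaPrev + half)
      glo <- g(lo); ghi <- g(hi)
    }
    if (glo * ghi <= 0)
      return(stats::uniroot(g, c(lo, hi),
                            tol = 1e-12 * max(1, abs(hiBound)))$root)
  }
  solveOmega(omega, S, nj, rvec, Phivec, beta, loBound, hiBound)
}

#' Mean-field approximation (MFA) phase solver
#'
#' Predicts each node's stationary relative phase from network structure
#' alone by solving the mean-field self-consistency for the global order
#' parameter R and the collective frequency Omega. Under the MFA the field a
#' node feels is the population mean field, so a locked node (one with
#' \eqn{S n_j R > |\Delta_j|}) satisfies
#' \eqn{\Delta_j = S n_j R \sin(\phi_j^* + \beta)} and
#' \eqn{\phi_j^* = \sin^{-1}\{\Delta_j/(S n_j R)\} - \beta} on the principal
#' branch; with equal positive \eqn{\Delta_j} this is strictly decreasing in
#' the degree \eqn{n_j} — hubs phase-lag, peripheral nodes phase-lead.
#' Drifting nodes enter R through the circular mean of their stationary
#' drift density. Omega is fixed by the gauge Phi = 0 (the population mean
#' phasor is real and positive), and R by self-consistency
#' \eqn{R = |\langle e^{i\phi}\rangle|}.
#'
#' @param network an [OscillatorNetwork-class].
#' @param config a [SimConfig-class]; delay modes are converted to an
#'   equivalent phase offset beta = omega*tau.
#' @param tol convergence tolerance on R and the gauge residual.
#' @param maxIter maximum self-consistency iterations.
#' @return an [AnalyticSolution-class] with `method = "MFA"`. An incoherent
#'   regime (no R > 0 solution) is reported as R = 0 with all nodes
#'   unlocked, not as an error.
#' @examples
#' net <- gilbertRandom(50, seed = 1)
#' sol <- solveMFA(net, simConfig(couplingS = 5))
#' cor(degrees(net), sol@phiStar, method = "spearman") # strongly negative
#' @export
solveMFA <- function(network, config, tol = 1e-8, maxIter = 10000) {
  stopifnot(is(network, "OscillatorNetwork"), is(config, "SimConfig"))
  A <- network@adjacency
  N <- nrow(A)
  nj <- rowSums(A)
  omega <- 2 * pi * rep_len(config@naturalFreqHz, N)
  S <- config@couplingS
  beta <- effectiveBeta(config)
  nmax <- max(nj)

  incoherent <- function() {
    new("AnalyticSolution", method = "MFA", phiStar = rep(NaN, N),
        locked = rep(FALSE, N), omega = mean(omega), globalR = 0,
        localR = numeric(0), localTheta = numeric(0), residual = NA_real_,
        degree = nj, couplingS = S, betaRad = beta, naturalOmega = omega,
        nodeIds = network@nodeIds)
  }
  if (S == 0 || nmax == 0) return(incoherent())

  R <- 0.9
  Omega <- NULL
  zeroPhi <- rep(0, N)
  converged <- FALSE
  for (iter in seq_len(maxIter)) {
    lower <- min(omega) - S * nmax * R - 1
    upper <- max(omega) + S * nmax * R + 1
    OmegaNew <- gaugeOmega(omega, S, nj, rep(R, N), zeroPhi, beta, Omega,
                           lower, upper)
    if (is.null(OmegaNew)) return(incoherent())
    Omega <- OmegaNew
    np <- nodePhasors(Omega, omega, S, nj, rep(R, N), zeroPhi, beta)
    Rnew <- Re(mean(np$z))
    if (Rnew < 1e-6) return(incoherent())
    dR <- Rnew - R
    R <- R + 0.5 * dR
    if (abs(dR) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("MFA self-consistency did not converge in %d iterations (last |dR| = %.3g)",
                 maxIter, abs(dR)))
  np <- nodePhasors(Omega, omega, S, nj, rep(R, N), zeroPhi, beta)
  phi <- ifelse(Mod(np$z) > 0, Arg(np$z), NaN)
  resid <- if (any(np$locked)) {
    max(abs(np$delta[np$locked] -
            np$K[np$locked] * sin(phi[np$locked] + beta)))
  } else NA_real_
  new("AnalyticSolution", method = "MFA", phiStar = phi, locked = np$locked,
      omega = Omega, globalR = R, localR = numeric(0),
      localTheta = numeric(0), residual = resid, degree = nj, couplingS = S,
      betaRad = beta, naturalOmega = omega, nodeIds = network@nodeIds)
}

#' Local order parameter (LOP) phase solver
#'
#' Refines the mean-field picture by giving every node its own field: the
#' local order parameter \eqn{r_j e^{i\Theta_j} = (1/n_j)\sum_k A_{jk}
#' e^{i\theta_k}} measures the synchrony and mean phase of the nodes coupled
#' to j. The stationary phases solve the coupled fixed point
#' \eqn{\phi_j^* = \Phi_j^* - \beta + \sin^{-1}\{\Delta_j/(S n_j r_j)\}}
#' for locked nodes (\eqn{S n_j r_j > |\Delta_j|}), with drifting nodes
#' entering the local fields through their drift-distribution circular mean.
#' The solver iterates damped updates of the phase vector, re-solving Omega
#' each sweep so the gauge Phi = 0 is preserved, and verifies stationarity of
#' the returned state (max residual reported).
#'
#' @param network an [OscillatorNetwork-class].
#' @param config a [SimConfig-class] (delays converted to offset beta).
#' @param tol convergence tolerance on the maximum phase update (rad).
#' @param maxIter maximum fixed-point sweeps.
#' @param init `"mfa"` (warm start from [solveMFA()], default), `"zero"`, or
#'   `"random"`.
#' @param damping update fraction lambda in (0, 1]; on non-convergence the
#'   solver retries once with lambda/3.
#' @param fallback what to do when the fixed-point iteration does not
#'   converge. Not every network admits a fully phase-locked state: a loosely
#'   attached peripheral cluster can drift collectively, in which case the
#'   fixed point does not exist and the damped iteration cycles. With
#'   `"relax"` (default) the solver then integrates the exact noise-free
#'   rotating-frame dynamics from the warm start (a deterministic
#'   continuation; no randomness) and reports each node's time-averaged
#'   phasor: locked nodes recover their fixed point, drifting nodes their
#'   drift-distribution circular mean. `"error"` errors instead.
#' @return an [AnalyticSolution-class] with `method = "LOP"` (slots `localR`,
#'   `localTheta` filled; `globalR` recomputed from the solution phasors).
#'   The stationarity `residual` is ~`tol` for a converged fixed point, and
#'   reports the genuine non-stationarity of the relaxed state otherwise.
#' @examples
#' net <- scaleFree(60, seed = 2)
#' cfg <- simConfig(couplingS = 5)
#' sol <- solveLOP(net, cfg)
#' sol@residual # stationarity of the returned state
#' @export
solveLOP <- function(network, config, tol = 1e-8, maxIter = 10000,
                     init = c("mfa", "zero", "random"), damping = 0.3,
                     fallback = c("relax", "error")) {
  stopifnot(is(network, "OscillatorNetwork"), is(config, "SimConfig"))
  init <- match.arg(init)
  fallback <- match.arg(fallback)
  A <- network@adjacency
  N <- nrow(A)
  nj <- rowSums(A)
  omega <- 2 * pi * rep_len(config@naturalFreqHz, N)
  S <- config@couplingS
  beta <- effectiveBeta(config)
  nmax <- max(nj)

  startState <- function() {
    if (init == "mfa") {
      s0 <- solveMFA(network, config, tol = tol, maxIter = maxIter)
      phi <- ifelse(is.nan(s0@phiStar), 0, s0@phiStar)
      list(phi = phi, Omega = s0@omega, z = exp(1i * phi))
    } else if (init == "zero") {
      list(phi = rep(0, N), Omega = mean(omega), z = rep(1 + 0i, N))
    } else {
      phi <- stats::runif(N, -pi, pi)
      list(phi = phi, Omega = mean(omega), z = exp(1i * phi))
    }
  }

  runFixedPoint <- function(lambda) {
    st <- startState()
    phi <- st$phi; Omega <- st$Omega; zvec <- st$z
    loBound <- min(omega) - S * nmax - 1
    hiBound <- max(omega) + S * nmax + 1
    for (iter in seq_len(maxIter)) {
      w <- as.vector(A %*% zvec)
      rvec <- ifelse(nj > 0, Mod(w) / nj, 0)
      Phivec <- ifelse(nj > 0, Arg(w), 0)
      # gauge: pick Omega so the population mean phasor is real-positive
      OmegaNew <- gaugeOmega(omega, S, nj, rvec, Phivec, beta, Omega,
                             loBound, hiBound)
      if (is.null(OmegaNew)) return(list(ok = FALSE, resid = Inf))
      Omega <- OmegaNew
      np <- nodePhasors(Omega, omega, S, nj, rvec, Phivec, beta)
      phiNew <- ifelse(Mod(np$z) > 0, Arg(np$z), phi)
      dphi <- wrapPhase(phiNew - phi)
      phi <- wrapPhase(phi + lambda * dphi)
      zvec <- ifelse(Mod(np$z) > 0, Mod(np$z) * exp(1i * phi), np$z)
      if (max(abs(dphi)) < tol)
        return(list(ok = TRUE, phi = phi, Omega = Omega, zvec = zvec,
                    iter = iter))
    }
    list(ok = FALSE, resid = max(abs(dphi)))
  }

  # deterministic continuation for networks without a fully locked state:
  # integrate the exact noise-free dynamics from the warm start and read off
  # the time-averaged phasor of each node in the rotating frame
  runRelaxation <- function(relaxS = 40, dt = 0.001) {
    st <- startState()
    nsteps <- round(relaxS / dt)
    tr <- kuramoto_offset_cpp(A, omega, S, beta, 0, 0, dt, nsteps, st$phi)
    traj <- phaseTrajectory(tr[, (nsteps / 2 + 1):(nsteps + 1), drop = FALSE],
                            dtS = dt)
    rel <- relativePhases(traj)
    zvec <- rowMeans(exp(1i * rel$phi))
    list(ok = TRUE, phi = Arg(zvec), Omega = rel$omega, zvec = zvec)
  }

  res <- runFixedPoint(damping)
  if (!res$ok) res <- runFixedPoint(damping / 3)
  if (!res$ok && fallback == "relax") res <- runRelaxation()
  if (!res$ok)
    stop(sprintf("LOP fixed point did not converge in %d iterations (last max |dphi| = %.3g rad)",
                 maxIter, res$resid))
  phi <- res$phi; Omega <- res$Omega; zvec <- res$zvec
  w <- as.vector(A %*% zvec)
  rvec <- ifelse(nj > 0, Mod(w) / nj, 0)
  Phivec <- ifelse(nj > 0, Arg(w), 0)
  delta <- omega - Omega
  K <- S * nj * rvec
  locked <- K > abs(delta)
  phi[nj == 0] <- NaN
  resid <- if (any(locked)) {
    max(abs(delta[locked] +
            K[locked] * sin(Phivec[locked] - phi[locked] - beta)))
  } else NA_real_
  new("AnalyticSolution", method = "LOP", phiStar = phi, locked = locked,
      omega = Omega, globalR = Mod(mean(zvec)), localR = rvec,
      localTheta = Phivec, residual = resid, degree = nj, couplingS = S,
      betaRad = beta, naturalOmega = omega, nodeIds = network@nodeIds)
}

#' Stationary phase distribution of a drifting node
#'
#' A node whose coupling is too weak to lock (\eqn{S n_j r_j \le |\Delta_j|})
#' never settles; its relative phase drifts with deterministic velocity
#' \eqn{d\phi/dt = \Delta_j + S n_j r_j \sin(\Phi_j - \phi - \beta)} under
#' the frozen local field, and spends time at each phase in inverse
#' proportion to its speed there: \eqn{P(\phi) \propto 1/|d\phi/dt|}. As the
#' locking boundary is approached from outside the density concentrates near
#' the would-be locked phase.
#'
#' @param node node index (or id) in the solution.
#' @param solution a converged [AnalyticSolution-class].
#' @param gridSize number of uniform grid points over (-pi, pi].
#' @return a list: `phi` (grid), `density` (normalised to integrate to 1),
#'   and `circMean` (circular mean phase).
#' @export
driftDistribution <- function(node, solution, gridSize = 512) {
  stopifnot(is(solution, "AnalyticSolution"))
  if (is.character(node)) node <- match(node, solution@nodeIds)
  if (is.na(node) || node < 1 || node > length(solution@phiStar))
    stop("unknown node")
  if (solution@locked[node])
    stop("node is phase-locked; its stationary phase is phiStar[node]")
  nj <- solution@degree[node]
  rj <- if (solution@method == "LOP") solution@localR[node] else solution@globalR
  Phij <- if (solution@method == "LOP") solution@localTheta[node] else 0
  K <- solution@couplingS * nj * rj
  delta <- solution@naturalOmega[node] - solution@omega
  phi <- seq(-pi, pi, length.out = gridSize + 1)[-1]
  dphi <- 2 * pi / gridSize
  p <- if (K <= 0 && delta == 0) rep(1, gridSize)
       else 1 / abs(delta + K * sin(Phij - phi - solution@betaRad))
  p <- p / (sum(p) * dphi)
  z <- sum(p * exp(1i * phi)) * dphi
  list(phi = phi, density = p,
       circMean = if (Mod(z) < 1e-12) NaN else Arg(z))
}

#' @describeIn nNodes nodes in an AnalyticSolution.
#' @export
setMethod("nNodes", "AnalyticSolution",
          function(object) length(object@phiStar))

#' @describeIn nodeIds labels of an AnalyticSolution.
#' @export
setMethod("nodeIds", "AnalyticSolution", function(object) object@nodeIds)

setMethod("show", "AnalyticSolution", function(object) {
  cat(sprintf("AnalyticSolution (%s): %d nodes, %d locked\n", object@method,
              nNodes(object), sum(object@locked)))
  cat(sprintf("  Omega = %.4f rad/s (%.3f Hz), R = %.4f, residual = %.3g\n",
              object@omega, object@omega / (2 * pi), object@globalR,
              object@residual))
  invisible(object)
})

#' Export an analytic solution as CSV plus JSON header
#'
#' Writes a per-node table (node_id, degree, phi_star, locked, r_local) and a
#' JSON header (method, omega, R, residual).
#'
#' @param solution an [AnalyticSolution-class].
#' @param dir output directory.
#' @param stem file stem.
#' @return invisibly, the CSV path.
#' @export
exportSolution <- function(solution, dir, stem = "solution") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(node_id = solution@nodeIds, degree = solution@degree,
                   phi_star = solution@phiStar, locked = solution@locked,
                   r_local = if (length(solution@localR)) solution@localR
                             else rep(solution@globalR, nNodes(solution)))
  csv <- file.path(dir, paste0(stem, ".csv"))
  utils::write.csv(df, csv, row.names = FALSE)
  jsonlite::write_json(
    list(method = solution@method, omega = solution@omega,
         R = solution@globalR, residual = solution@residual),
    file.path(dir, paste0(stem, ".json")), auto_unbox = TRUE, digits = NA)
  invisible(csv)
}
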