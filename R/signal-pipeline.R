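# Welch PSD, averaged over channels: Hann-windowed segments with 50%
# overlap. Returns freq (Hz) and power density. (Textbook construction; no
# installed package in the stack exposes a Welch estimator.)
welchPsd <- function(samples, fsHz, windowS = 2, overlap = 0.5) {
  samples <- rbind(samples)
  L <- min(ncol(samples), max(16, round(windowS * fsHz)))
  step <- max(1, round(L * (1 - overlap)))
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1)) # Hann
  U <- sum(win^2)
  starts <- seq(1, ncol(samples) - L + 1, by = step)
  nf <- floor(L / 2) + 1
  acc <- numeric(nf)
  cnt <- 0
  for (ch in seq_len(nrow(samples))) {
    x <- samples[ch, ]
    for (s0 in starts) {
      seg <- x[s0:(s0 + L - 1)]
      seg <- (seg - mean(seg)) * win
      P <- Mod(stats::fft(seg))^2 / (U * fsHz)
      acc <- acc + P[seq_len(nf)]
      cnt <- cnt + 1
    }
  }
  list(freqHz = (seq_len(nf) - 1) * fsHz / L, psd = acc / cnt)
}

#' Generate a synthetic multichannel oscillatory signal
#'
#' Emulates narrow-band (e.g. 6-12 Hz) multichannel recordings with a known,
#' prescribed inter-channel phase structure: each channel is a sinusoid at
#' `baseFreqHz` carrying its prescribed phase lag, a slow common-to-nothing
#' random-walk phase jitter (SD `couplingJitterSd` rad/sqrt(s), independent
#' per channel), and additive white noise. The prescribed lag ordering is
#' recoverable by the analysis pipeline, which makes the full chain testable
#' without recorded data.
#'
#' @param nChannels number of channels.
#' @param fsHz sampling rate (Hz), default 500.
#' @param durationS duration (s).
#' @param baseFreqHz carrier frequency in Hz (within the analysed 0.5-55 Hz
#'   range).
#' @param phaseLagsRad per-channel phase lags in (-pi, pi]; default a linear
#'   gradient from +0.8 to -0.8 rad (channel 1 leads). For the ordering to
#'   be recoverable, inter-channel lag separations should exceed the typical
#'   jitter excursion within an epoch.
#' @param couplingJitterSd random-walk phase jitter SD (rad/sqrt(s)).
#' @param noiseSd additive white-noise SD (signal units; the sinusoid has
#'   amplitude 1).
#' @param seed optional integer seed.
#' @return a [MultichannelSignal-class].
#' @examples
#' sig <- generateSyntheticEEG(4, durationS = 10, seed = 1)
#' sig
#' @export
generateSyntheticEEG <- function(nChannels, fsHz = 500, durationS = 30,
                                 baseFreqHz = 10, phaseLagsRad = NULL,
                                 couplingJitterSd = 0.05, noiseSd = 0.5,
                                 seed = NULL) {
  stopifnot(baseFreqHz > 0.5, baseFreqHz < 55)
  if (is.null(phaseLagsRad))
    phaseLagsRad <- seq(0.8, -0.8, length.out = nChannels)
  stopifnot(length(phaseLagsRad) == nChannels,
            all(phaseLagsRad > -pi & phaseLagsRad <= pi))
  nT <- round(durationS * fsHz)
  tt <- (seq_len(nT) - 1) / fsHz
  withSeed(seed, {
    X <- matrix(0, nChannels, nT)
    for (ch in seq_len(nChannels)) {
      jitter <- cumsum(stats::rnorm(nT, 0, couplingJitterSd / sqrt(fsHz)))
      X[ch, ] <- sin(2 * pi * baseFreqHz * tt + phaseLagsRad[ch] + jitter) +
        stats::rnorm(nT, 0, noiseSd)
    }
    multichannelSignal(X, fsHz)
  })
}

#' Select the frequency band around the spectral peak
#'
#' Estimates the channel-averaged Welch power spectral density, finds the
#' highest peak inside the search range, and returns the band
#' `peak +/- halfWidthHz` — the band in which phase relationships are most
#' reliable. Errors when the spectrum is flat (no peak rising above twice
#' the in-range median).
#'
#' @param signal a [MultichannelSignal-class].
#' @param searchLowHz,searchHighHz search range (default 0.5-55 Hz, clipped
#'   to Nyquist).
#' @param halfWidthHz half-width of the returned band (default 2 Hz).
#' @return a [BandSpec-class] with provenance `"peak±2"`.
#' @export
peakBand <- function(signal, searchLowHz = 0.5, searchHighHz = 55,
                     halfWidthHz = 2) {
  stopifnot(is(signal, "MultichannelSignal"))
  nyq <- signal@fsHz / 2
  searchHighHz <- min(searchHighHz, 0.98 * nyq)
  stopifnot(searchLowHz > 0, searchHighHz > searchLowHz)
  ps <- welchPsd(signal@samples, signal@fsHz)
  inRange <- ps$freqHz >= searchLowHz & ps$freqHz <= searchHighHz
  if (!any(inRange)) stop("search range contains no frequency bins")
  p <- ps$psd[inRange]; f <- ps$freqHz[inRange]
  if (max(p) < 2 * stats::median(p))
    stop("flat spectrum: no peak above twice the median power in the search range")
  peak <- f[which.max(p)]
  low <- max(peak - halfWidthHz, 0.1)
  bandSpec(low, min(peak + halfWidthHz, 0.99 * nyq), provenance = "peak±2")
}

# analytic-signal (Hilbert) phase of one real series via FFT
analyticPhase <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Arg(stats::fft(X * h, inverse = TRUE) / n)
}

#' Band-pass filter a signal and extract instantaneous phases
#'
#' Applies a fifth-order Butterworth band-pass forward and backward
#' (zero-phase `filtfilt`, no group delay), extracts each channel's
#' instantaneous phase from the analytic (Hilbert) signal, unwraps it, and
#' trims an edge margin to remove filter/Hilbert edge artifacts.
#'
#' @param signal a [MultichannelSignal-class].
#' @param band a [BandSpec-class] (below Nyquist).
#' @param trimS margin trimmed from each end, seconds (default 1).
#' @return a [PhaseTrajectory-class] of unwrapped absolute phases, sampled at
#'   the signal rate. Relative phases in the population gauge are obtained
#'   with [relativePhases()]; dPLI/PLI are gauge-invariant and can be
#'   computed directly.
#' @export
bandpassPhase <- function(signal, band, trimS = 1) {
  stopifnot(is(signal, "MultichannelSignal"), is(band, "BandSpec"))
  nyq <- signal@fsHz / 2
  if (band@highHz >= nyq)
    stop(sprintf("band edge %.3g Hz is not below Nyquist (%.3g Hz)",
                 band@highHz, nyq))
  nT <- ncol(signal@samples)
  trimN <- round(trimS * signal@fsHz)
  if (nT - 2 * trimN < 4 ||
      nT <= 3 * 2 * 5) # filtfilt padding for a 5th-order section
    stop("signal too short for filtering and edge trimming")
  bf <- signal::butter(5, c(band@lowHz, band@highHz) / nyq, type = "pass")
  keep <- (trimN + 1):(nT - trimN)
  phases <- t(apply(signal@samples, 1, function(x) {
    unwrapPhase(analyticPhase(signal::filtfilt(bf, x)))[keep]
  }))
  phaseTrajectory(phases, dtS = 1 / signal@fsHz,
                  nodeIds = signal@channelIds)
}

#' Split a signal or trajectory into epochs
#'
#' Non-overlapping consecutive segments of `epochS` seconds (pseudo-
#' stationary analysis windows); the trailing remainder is dropped.
#' Per-epoch metrics are typically averaged over epochs.
#'
#' @param x a [MultichannelSignal-class] or [PhaseTrajectory-class].
#' @param epochS epoch length in seconds (must not exceed the duration).
#' @return list of objects of the same class as `x`.
#' @examples
#' sig <- generateSyntheticEEG(2, durationS = 30, seed = 1)
#' length(epochSignal(sig, 5)) # 6 epochs
#' @export
epochSignal <- function(x, epochS) {
  if (is(x, "MultichannelSignal")) {
    fs <- x@fsHz; M <- x@samples
    make <- function(cols) multichannelSignal(M[, cols, drop = FALSE], fs,
                                              x@channelIds)
  } else if (is(x, "PhaseTrajectory")) {
    fs <- 1 / x@dtS; M <- x@phases
    make <- function(cols) phaseTrajectory(M[, cols, drop = FALSE], x@dtS,
                                           x@nodeIds)
  } else stop("x must be a MultichannelSignal or PhaseTrajectory")
  perEpoch <- round(epochS * fs)
  nEpoch <- floor(ncol(M) / perEpoch)
  if (nEpoch < 1)
    stop(sprintf("signal (%.3g s) is shorter than one epoch (%g s)",
                 ncol(M) / fs, epochS))
  lapply(seq_len(nEpoch), function(e)
    make(((e - 1) * perEpoch + 1):(e * perEpoch)))
}

#' PLI-weighted functional network with proportional thresholding
#'
#' Builds the functional (statistical) counterpart of a structural network:
#' pairwise PLI values are the weighted edges; the binary network keeps the
#' top `thresholdFraction` strongest of all possible edges (proportional
#' thresholding, ties broken by stable edge order), and binary node degree
#' counts each channel's surviving links.
#'
#' @param x a [PhaseTrajectory-class], phase matrix, or a precomputed
#'   [DirectionalityTable-class].
#' @param thresholdFraction fraction of edges kept, in (0, 1]; default 0.30.
#' @return list: `weighted` (PLI matrix), `binary` (an
#'   [OscillatorNetwork-class]), `degree` (binary degrees), `table` (the
#'   [DirectionalityTable-class] used).
#' @export
functionalNetwork <- function(x, thresholdFraction = 0.30) {
  stopifnot(thresholdFraction > 0, thresholdFraction <= 1)
  tab <- if (is(x, "DirectionalityTable")) x else directionalityTable(x)
  P <- tab@pliMatrix
  N <- nrow(P)
  ut <- which(upper.tri(P))
  ord <- ut[order(-P[ut], ut)] # stable tie order: matrix index breaks ties
  nKeep <- max(1L, round(thresholdFraction * length(ut)))
  B <- matrix(0, N, N, dimnames = dimnames(P))
  B[ord[seq_len(nKeep)]] <- 1
  B <- B + t(B)
  bin <- oscillatorNetwork(B, nodeIds = tab@nodeIds, undirected = TRUE)
  list(weighted = P, binary = bin, degree = degrees(bin, "binary"),
       table = tab)
}

#' Full signal-analysis chain
#'
#' The complete pipeline for multichannel oscillatory recordings: band
#' selection at the spectral peak (or a fixed band), zero-phase band-pass
#' filtering and Hilbert phases, 5 s epoching, per-epoch dPLI/PLI,
#' epoch-averaged PLI functional network with proportional thresholding, and
#' the degree/phase/dPLI correlation report.
#'
#' @param signal a [MultichannelSignal-class].
#' @param band a [BandSpec-class] or `"auto"` (peak +/- 2 Hz).
#' @param epochS epoch length in seconds (default 5).
#' @param thresholdFraction fraction of edges kept in the binary network.
#' @param trimS edge margin trimmed after filtering (s).
#' @return a list: `band`, `nEpochs`, `dpli` and `pli` (epoch-averaged
#'   matrices), `nodeDpli`, `degree` (binary), `phiMean` (epoch-averaged
#'   relative phase per channel), `degreeDpliRho` (Spearman), `report`
#'   (three-way correlation table).
#' @examples
#' sig <- generateSyntheticEEG(8, durationS = 20, seed = 1)
#' res <- analyzeSignalNetwork(sig)
#' res$degreeDpliRho
#' @export
analyzeSignalNetwork <- function(signal, band = "auto", epochS = 5,
                                 thresholdFraction = 0.30, trimS = 1) {
  stopifnot(is(signal, "MultichannelSignal"))
  if (identical(band, "auto")) band <- peakBand(signal)
  traj <- bandpassPhase(signal, band, trimS = trimS)
  epochs <- epochSignal(traj, epochS)
  N <- nNodes(traj)
  dpliAcc <- matrix(0, N, N)
  zAcc <- complex(real = numeric(N))
  for (ep in epochs) {
    dpliAcc <- dpliAcc + dpli_matrix_cpp(ep@phases)
    zAcc <- zAcc + exp(1i * relativePhases(ep)$phiMean)
  }
  D <- dpliAcc / length(epochs)
  dimnames(D) <- list(traj@nodeIds, traj@nodeIds)
  tab <- new("DirectionalityTable", dpliMatrix = D, pliMatrix = abs(D),
             nodeDpli = rowSums(D) / (N - 1), nodeIds = traj@nodeIds)
  fn <- functionalNetwork(tab, thresholdFraction)
  phiMean <- Arg(zAcc / length(epochs))
  names(phiMean) <- traj@nodeIds
  list(band = band, nEpochs = length(epochs), dpli = D, pli = abs(D),
       nodeDpli = tab@nodeDpli, degree = fn$degree, phiMean = phiMean,
       degreeDpliRho = spearman(fn$degree, tab@nodeDpli),
       report = correlationReport(fn$degree, phiMean, tab@nodeDpli))
}

#' Threshold-stability sweep
#'
#' Recomputes binary degree and the degree-dPLI Spearman correlation across
#' a grid of proportional-threshold fractions, to check that conclusions do
#' not hinge on one threshold.
#'
#' @param x input accepted by [functionalNetwork()].
#' @param fractions numeric grid in (0, 1]; default 0.1 to 0.5.
#' @return data.frame with columns `fraction`, `degreeDpliRho`.
#' @export
thresholdSweep <- function(x, fractions = seq(0.1, 0.5, by = 0.1)) {
  tab <- if (is(x, "DirectionalityTable")) x else directionalityTable(x)
  do.call(rbind, lapply(fractions, function(fr) {
    fn <- functionalNetwork(tab, fr)
    data.frame(fraction = fr,
               degreeDpliRho = spearman(fn$degree, tab@nodeDpli))
  }))
}

#' @describeIn nNodes channels in a MultichannelSignal.
#' @export
setMethod("nNodes", "MultichannelSignal", function(object) nrow(object@samples))

#' @describeIn nodeIds channel labels of a MultichannelSignal.
#' @export
setMethod("nodeIds", "MultichannelSignal", function(object) object@channelIds)

setMethod("show", "MultichannelSignal", function(object) {
  cat(sprintf("MultichannelSignal: %d channels x %d samples @ %g Hz (%.3g s)\n",
              nrow(object@samples), ncol(object@samples), object@fsHz,
              ncol(object@samples) / object@fsHz))
  invisible(object)
})

setMethod("show", "BandSpec", function(object) {
  cat(sprintf("BandSpec: %.3g-%.3g Hz (%s)\n", object@lowHz, object@highHz,
              object@provenance))
  invisible(object)
})
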