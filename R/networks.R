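#' Gilbert (Erdos-Renyi G(N, p)) random network
#'
#' Generates an undirected binary network in which every pair of nodes is
#' connected independently with probability
#' \eqn{p = (1 + \epsilon) \log(N) / N}, slightly above the connectivity
#' threshold. The resulting degree distribution is approximately Poisson
#' (a homogeneous network).
#'
#' @param nNodes number of nodes N (>= 2).
#' @param epsilon small positive margin above the connectivity threshold;
#'   default 0.1.
#' @param seed optional integer seed; the caller's RNG state is untouched.
#' @return an [OscillatorNetwork-class] (binary, undirected).
#' @examples
#' net <- gilbertRandom(100, seed = 1)
#' mean(degrees(net, "binary"))
#' @export
gilbertRandom <- function(nNodes, epsilon = 0.1, seed = NULL) {
  stopifnot(nNodes >= 2, epsilon > 0)
  p <- (1 + epsilon) * log(nNodes) / nNodes
  if (p > 1)
    stop(sprintf(
      "edge probability (1+epsilon)*log(N)/N = %.3f exceeds 1; use a larger N or smaller epsilon",
      p))
  g <- withSeed(seed, igraph::sample_gnp(nNodes, p, directed = FALSE))
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  oscillatorNetwork(A, undirected = TRUE)
}

# expected degree of the truncated power law P(k) ~ k^-gamma on [kmin, kmax]
powerLawMeanDegree <- function(gamma, kmin, kmax) {
  k <- kmin:kmax
  p <- k^(-gamma)
  sum(k * p) / sum(p)
}

#' Scale-free network via the uncorrelated configuration model
#'
#' Draws a degree sequence from a truncated power law
#' \eqn{P(k) \propto k^{-\gamma}} with a structural cutoff
#' \eqn{k_{max} = \sqrt{\langle k \rangle N}} (which guarantees the absence
#' of degree-degree correlations), then wires a simple undirected graph with
#' exactly that degree sequence by configuration-model stub matching that
#' rejects self-loops and multi-edges, restarting when stuck
#' (Catanzaro-style).
#'
#' @param nNodes number of nodes.
#' @param gamma magnitude of the degree-distribution exponent; values in
#'   `[2, 3]` are the intended regime (a warning, not an error, outside it).
#' @param minDegree smallest allowed degree (default 3, which keeps the
#'   generated networks inside the fully phase-locked regime the analytic
#'   framework describes; degree-2 peripheries can form collectively
#'   drifting clusters).
#' @param seed optional integer seed.
#' @param maxAttempts resampling attempts for a graphical, wireable sequence.
#' @return an [OscillatorNetwork-class] (binary, undirected, simple).
#' @examples
#' net <- scaleFree(100, gamma = 2.5, seed = 1)
#' range(degrees(net, "binary"))
#' @export
scaleFree <- function(nNodes, gamma = 2.5, minDegree = 3, seed = NULL,
                      maxAttempts = 100) {
  stopifnot(nNodes >= 4, minDegree >= 1)
  if (gamma < 2 || gamma > 3)
    warning("gamma outside [2, 3]; the intended scale-free regime is 2..3")
  kmeanFull <- powerLawMeanDegree(gamma, minDegree, nNodes - 1)
  kmax <- max(minDegree + 1, min(nNodes - 1, floor(sqrt(kmeanFull * nNodes))))
  kGrid <- minDegree:kmax
  pGrid <- kGrid^(-gamma)
  pGrid <- pGrid / sum(pGrid)
  withSeed(seed, {
    for (att in seq_len(maxAttempts)) {
      deg <- sample(kGrid, nNodes, replace = TRUE, prob = pGrid)
      if (sum(deg) %% 2 == 1) { # parity fix: resample one stub
        i <- sample.int(nNodes, 1)
        deg[i] <- sample(kGrid, 1, prob = pGrid)
        if (sum(deg) %% 2 == 1) next
      }
      if (!igraph::is_graphical(deg)) next
      # Catanzaro-style uncorrelated matching: pair stubs at random,
      # rejecting self-loops and multi-edges, restarting when stuck
      g <- tryCatch(
        igraph::sample_degseq(deg, method = "fast.heur.simple"),
        error = function(e) NULL)
      if (!is.null(g)) {
        A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
        return(oscillatorNetwork(A, undirected = TRUE))
      }
    }
    stop(sprintf(
      "no graphical/wireable degree sequence found in %d attempts (n=%d, gamma=%.2f, minDegree=%d)",
      maxAttempts, nNodes, gamma, minDegree))
  })
}

#' Largest connected component
#'
#' Network generators do not enforce connectedness; experiments are typically
#' run on the largest component returned here.
#'
#' @param network an [OscillatorNetwork-class].
#' @return the induced subnetwork on the largest (weakly) connected component,
#'   node order preserved.
#' @export
largestComponent <- function(network) {
  A <- network@adjacency
  g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "max")
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  if (length(keep) == nrow(A)) return(network)
  oscillatorNetwork(A[keep, keep, drop = FALSE],
                    nodeIds = network@nodeIds[keep],
                    coordinates = if (is.null(network@coordinates)) NULL
                                  else network@coordinates[keep, , drop = FALSE],
                    undirected = network@undirected)
}

#' Load a network from a text file
#'
#' Two plain-text formats are supported: `"dense"` (a delimited numeric
#' square matrix, whitespace- or comma-separated, one row per node) and
#' `"edgelist"` (TSV rows of `source_id  target_id  [weight]`; a missing
#' weight column defaults to 1). `format = "auto"` picks edge-list for
#' 2-3 column files whose first column is non-numeric or whose shape is not
#' square, dense otherwise.
#'
#' @param path file path.
#' @param format `"auto"`, `"dense"`, or `"edgelist"`.
#' @param coordinatesPath optional 4-column TSV (id, x, y, z in mm) of node
#'   positions.
#' @return an [OscillatorNetwork-class].
#' @seealso [saveNetwork()]
#' @export
loadNetwork <- function(path, format = c("auto", "dense", "edgelist"),
                        coordinatesPath = NULL) {
  format <- match.arg(format)
  firstLine <- readLines(path, n = 1)
  sep <- if (grepl(",", firstLine)) "," else ""
  df <- utils::read.table(path, sep = sep, header = FALSE,
                          stringsAsFactors = FALSE)
  if (format == "auto") {
    looksEdge <- ncol(df) %in% 2:3 &&
      (is.character(df[[1]]) || nrow(df) != ncol(df))
    format <- if (looksEdge) "edgelist" else "dense"
  }
  net <- if (format == "dense") {
    M <- as.matrix(df)
    if (nrow(M) != ncol(M))
      stop(sprintf("dense matrix in '%s' is not square: %d rows x %d columns",
                   path, nrow(M), ncol(M)))
    storage.mode(M) <- "double"
    bad <- which(M < 0, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("negative weight at row %d, column %d of '%s'",
                   bad[1, 1], bad[1, 2], path))
    dimnames(M) <- NULL
    oscillatorNetwork(M)
  } else {
    if (!ncol(df) %in% 2:3)
      stop(sprintf("edge list in '%s' must have 2 or 3 columns, found %d",
                   path, ncol(df)))
    src <- as.character(df[[1]]); tgt <- as.character(df[[2]])
    w <- if (ncol(df) == 3) as.numeric(df[[3]]) else rep(1, nrow(df))
    if (anyNA(w) || any(w < 0)) {
      row <- which(is.na(w) | w < 0)[1]
      stop(sprintf("bad weight on row %d of '%s'", row, path))
    }
    ids <- unique(c(src, tgt))
    A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    for (r in seq_along(src)) {
      # edge direction: source -> target, stored as A[target, source]
      A[tgt[r], src[r]] <- w[r]
    }
    oscillatorNetwork(A, nodeIds = ids)
  }
  if (!is.null(coordinatesPath)) {
    cdf <- utils::read.table(coordinatesPath, header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(cdf) != 4)
      stop("coordinates file must have 4 columns: id, x, y, z")
    idx <- match(net@nodeIds, as.character(cdf[[1]]))
    if (anyNA(idx)) stop("coordinates file is missing some node ids")
    net@coordinates <- as.matrix(cdf[idx, 2:4])
    rownames(net@coordinates) <- net@nodeIds
    validObject(net)
  }
  net
}

#' Save a network to a text file
#'
#' Writes either the full dense matrix (15 significant digits; load/save
#' round-trips are lossless) or a 3-column TSV edge list of all nonzero
#' couplings.
#'
#' @param network an [OscillatorNetwork-class].
#' @param path output file path.
#' @param format `"dense"` or `"edgelist"`.
#' @return invisibly, `path`.
#' @export
saveNetwork <- function(network, path, format = c("dense", "edgelist")) {
  format <- match.arg(format)
  A <- network@adjacency
  if (format == "dense") {
    utils::write.table(format(A, digits = 15, scientific = TRUE, trim = TRUE),
                       path, sep = " ", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else {
    nz <- which(A != 0, arr.ind = TRUE)
    # A[j, k] is coupling k -> j, so source = column, target = row
    df <- data.frame(source = network@nodeIds[nz[, 2]],
                     target = network@nodeIds[nz[, 1]],
                     weight = format(A[nz], digits = 15))
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @describeIn degrees weighted row sums or binary counts of couplings.
#' @export
setMethod("degrees", "OscillatorNetwork", function(object,
    mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  A <- object@adjacency
  d <- if (mode == "weighted") rowSums(A) else rowSums(A != 0)
  names(d) <- object@nodeIds
  d
})

#' @describeIn adjacency coupling matrix of an OscillatorNetwork.
#' @export
setMethod("adjacency", "OscillatorNetwork", function(object) object@adjacency)

#' @describeIn nodeIds labels of an OscillatorNetwork.
#' @export
setMethod("nodeIds", "OscillatorNetwork", function(object) object@nodeIds)

#' @describeIn coordinates positions of an OscillatorNetwork.
#' @export
setMethod("coordinates", "OscillatorNetwork", function(object) object@coordinates)

#' @describeIn nNodes nodes in an OscillatorNetwork.
#' @export
setMethod("nNodes", "OscillatorNetwork", function(object) nrow(object@adjacency))

setMethod("show", "OscillatorNetwork", function(object) {
  d <- degrees(object, "binary")
  cat(sprintf("OscillatorNetwork: %d nodes, %s, %s\n",
              nNodes(object),
              if (object@undirected) "undirected" else "directed",
              if (all(object@adjacency %in% c(0, 1))) "binary" else "weighted"))
  cat(sprintf("  degree (binary): min %d, median %g, max %d\n",
              min(d), stats::median(d), max(d)))
  if (!is.null(object@coordinates)) cat("  with node coordinates\n")
  invisible(object)
})
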