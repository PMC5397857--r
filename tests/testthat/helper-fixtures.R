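# shared fixtures, built in code

# complete unweighted graph on n nodes
completeNetwork <- function(n) {
  A <- matrix(1, n, n) - diag(n)
  oscillatorNetwork(A)
}

# star: one hub coupled to `leaves` leaf nodes
starNetwork <- function(leaves = 4) {
  A <- matrix(0, leaves + 1, leaves + 1)
  A[1, -1] <- 1
  A[-1, 1] <- 1
  oscillatorNetwork(A)
}

# complete bipartite K_{a,b}: two exact degree classes (degree b and a)
twoClassNetwork <- function(a = 3, b = 6) {
  A <- matrix(0, a + b, a + b)
  A[seq_len(a), a + seq_len(b)] <- 1
  A[a + seq_len(b), seq_len(a)] <- 1
  oscillatorNetwork(A)
}

# short desk-scale config for unit tests
quickConfig <- function(couplingS = 5, durationS = 8, transientS = 4,
                        nRuns = 2, noiseSd = 1, ...) {
  simConfig(couplingS = couplingS, durationS = durationS,
            transientS = transientS, nRuns = nRuns, noiseSd = noiseSd, ...)
}

spearman <- netphase:::spearman
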