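#' Node degrees of a network
#'
#' The degree \eqn{n_j} of node j is the total coupling it receives,
#' \eqn{n_j = \sum_k A_{jk}} (row sums). `mode = "binary"` counts nonzero
#' couplings instead. No 1/N normalisation is applied here; the coupling
#' prefactor lives in the simulator and solvers.
#'
#' @param object an [OscillatorNetwork-class].
#' @param mode `"weighted"` (sum of couplings) or `"binary"` (count).
#' @return named numeric vector of length N.
#' @examples
#' star <- oscillatorNetwork(rbind(c(0, 1, 1, 1, 1), cbind(1, matrix(0, 4, 4))))
#' degrees(star, mode = "binary")
#' @export
setGeneric("degrees", function(object, mode = c("weighted", "binary"))
  standardGeneric("degrees"))

#' Adjacency matrix accessor
#' @param object an [OscillatorNetwork-class].
#' @return the numeric coupling matrix.
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))

#' Node/channel identifier accessor
#' @param object a netphase object carrying node or channel labels.
#' @return character vector of labels.
#' @export
setGeneric("nodeIds", function(object) standardGeneric("nodeIds"))

#' Node coordinate accessor
#' @param object an [OscillatorNetwork-class].
#' @return numeric matrix of positions (mm) or `NULL`.
#' @export
setGeneric("coordinates", function(object) standardGeneric("coordinates"))

#' Number of nodes
#' @param object a netphase object.
#' @return integer count.
#' @export
setGeneric("nNodes", function(object) standardGeneric("nNodes"))

#' Wrapped phase view
#' @param object a [PhaseTrajectory-class].
#' @return matrix of phases wrapped to (-pi, pi].
#' @export
setGeneric("wrappedPhases", function(object) standardGeneric("wrappedPhases"))
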