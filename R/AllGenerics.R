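#' @include AllClasses.R
NULL

#' Number of hidden states
#' @param object a chain or HMM object.
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))

#' Transition probability matrix
#' @param object a chain or HMM object.
#' @export
setGeneric("transitionMatrix", function(object) standardGeneric("transitionMatrix"))

#' Initial state distribution
#' @param object a chain or HMM object.
#' @export
setGeneric("initialProbs", function(object) standardGeneric("initialProbs"))

#' Per-state emission parameters
#' @param object a \linkS4class{GaussianHMM}.
#' @export
setGeneric("emissions", function(object) standardGeneric("emissions"))

#' Observation dimension
#' @param object a model or sequence object.
#' @export
setGeneric("obsDim", function(object) standardGeneric("obsDim"))

#' Log emission density matrix
#'
#' Entry (i, k) is the log mixture emission density of sample i under hidden
#' state k: \code{log sum_j w_kj N(x_i; mu_kj, Sigma_kj)}.
#'
#' @param model a \linkS4class{GaussianHMM}.
#' @param seq an \linkS4class{ObservationSequence} (or bare numeric matrix).
#' @return n x K matrix of finite log densities.
#' @export
setGeneric("logEmissionMatrix", function(model, seq) standardGeneric("logEmissionMatrix"))

#' Sequence log-likelihood by the scaled forward algorithm
#'
#' Computes \code{log p(X | lambda)}, the total observation probability summed
#' over all hidden state paths, using the forward recursion with per-step
#' rescaling (never raw probability products), so the result is finite for
#' arbitrarily long sequences.
#'
#' @param model a \linkS4class{GaussianHMM} or \linkS4class{DiscreteHMM}.
#' @param seq an \linkS4class{ObservationSequence} for the Gaussian case; an
#'   integer symbol vector (values in 1..M) for the discrete case.
#' @param ... further arguments; \code{method = c("scaling", "logspace")}
#'   selects the scaled recursion (default) or the pure log-space reference
#'   path, which agree to near machine precision.
#' @return the log-likelihood, a single finite number.
#' @export
setGeneric("forwardLogLik", function(model, seq, ...) standardGeneric("forwardLogLik"))

#' Forward-backward posteriors
#'
#' Runs the scaled forward-backward recursions and returns the EM sufficient
#' statistics: state posteriors tau, state-component posteriors, expected
#' transition counts, and the sequence log-likelihood.
#'
#' @param model a \linkS4class{GaussianHMM}.
#' @param seq an \linkS4class{ObservationSequence}.
#' @return a \linkS4class{PosteriorSet}.
#' @export
setGeneric("forwardBackward", function(model, seq) standardGeneric("forwardBackward"))

#' Viterbi decoding
#'
#' Finds the single most probable hidden state path. Ties are broken toward
#' the lower state index.
#'
#' @param model a \linkS4class{GaussianHMM}.
#' @param seq an \linkS4class{ObservationSequence}.
#' @return list with \code{path} (integer states, 1-based) and
#'   \code{logJoint} = log p(X, Z* | lambda), which never exceeds
#'   \code{forwardLogLik}.
#' @export
setGeneric("viterbiDecode", function(model, seq) standardGeneric("viterbiDecode"))

#' Sample a sequence from a Gaussian HMM
#'
#' Draws a hidden state path from the chain and observations from each
#' state's mixture; reproducible given \code{seed}.
#'
#' @param model a \linkS4class{GaussianHMM}.
#' @param n sequence length.
#' @param seed RNG seed.
#' @param samplingRate,channels,subjectId,label metadata for the returned
#'   sequence.
#' @return list with \code{seq} (an \linkS4class{ObservationSequence}) and
#'   \code{states} (the hidden path, for test assertions).
#' @export
setGeneric("sampleSequence", function(model, n, seed, ...) standardGeneric("sampleSequence"))

#' Brute-force log-likelihood by path enumeration (test oracle)
#'
#' Sums the complete-data likelihood
#' \code{p(z_1; pi) p(x_1|z_1) prod p(z_i|z_(i-1)) p(x_i|z_i)} over every one
#' of the K^n hidden state paths, accumulating in log space. Exponential in
#' n; guarded at K^n <= 1e6. Exists purely as an independent oracle for the
#' dynamic-programming recursions.
#'
#' @param model a \linkS4class{GaussianHMM} or \linkS4class{DiscreteHMM}.
#' @param seq sequence as in \code{\link{forwardLogLik}}.
#' @return the exact log-likelihood.
#' @export
setGeneric("bruteForceLogLik", function(model, seq) standardGeneric("bruteForceLogLik"))
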