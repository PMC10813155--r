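#' @include AllGenerics.R
NULL

#' @describeIn MarkovChain-class number of states.
#' @export
setMethod("nStates", "MarkovChain", function(object) length(object@pi))
#' @describeIn GaussianHMM-class number of hidden states.
#' @export
setMethod("nStates", "GaussianHMM", function(object) length(object@chain@pi))
#' @describeIn DiscreteHMM-class number of hidden states.
#' @export
setMethod("nStates", "DiscreteHMM", function(object) length(object@chain@pi))

#' @describeIn MarkovChain-class transition matrix.
#' @export
setMethod("transitionMatrix", "MarkovChain", function(object) object@A)
#' @describeIn GaussianHMM-class transition matrix.
#' @export
setMethod("transitionMatrix", "GaussianHMM", function(object) object@chain@A)
#' @describeIn DiscreteHMM-class transition matrix.
#' @export
setMethod("transitionMatrix", "DiscreteHMM", function(object) object@chain@A)

#' @describeIn MarkovChain-class initial distribution.
#' @export
setMethod("initialProbs", "MarkovChain", function(object) object@pi)
#' @describeIn GaussianHMM-class initial distribution.
#' @export
setMethod("initialProbs", "GaussianHMM", function(object) object@chain@pi)
#' @describeIn DiscreteHMM-class initial distribution.
#' @export
setMethod("initialProbs", "DiscreteHMM", function(object) object@chain@pi)

#' @describeIn GaussianHMM-class list of per-state emission objects.
#' @export
setMethod("emissions", "GaussianHMM", function(object) object@emissions)

#' @describeIn GaussianHMM-class observation dimension.
#' @export
setMethod("obsDim", "GaussianHMM", function(object) object@d)
#' @describeIn ObservationSequence-class number of channels.
#' @export
setMethod("obsDim", "ObservationSequence", function(object) ncol(object@values))

#' Displacement values of a recording
#' @param seq an \linkS4class{ObservationSequence}.
#' @return n x d numeric matrix.
#' @export
copValues <- function(seq) seq@values

#' Sampling rate of a recording (Hz)
#' @param seq an \linkS4class{ObservationSequence}.
#' @export
samplingRate <- function(seq) seq@samplingRate

#' Channel labels of a recording
#' @param seq an \linkS4class{ObservationSequence}.
#' @export
channels <- function(seq) seq@channels

#' Subject identifier of a recording
#' @param seq an \linkS4class{ObservationSequence}.
#' @export
subjectId <- function(seq) seq@subjectId

#' Class label of a recording
#' @param seq an \linkS4class{ObservationSequence}.
#' @return \code{"healthy"}, \code{"pd"} or \code{NA}.
#' @export
seqLabel <- function(seq) seq@label

#' State posteriors from a forward-backward pass
#' @param ps a \linkS4class{PosteriorSet}.
#' @export
statePosteriors <- function(ps) ps@gamma

#' Expected transition counts from a forward-backward pass
#' @param ps a \linkS4class{PosteriorSet}.
#' @export
transitionCounts <- function(ps) ps@xiSum

#' State-component posteriors from a forward-backward pass
#' @param ps a \linkS4class{PosteriorSet}.
#' @export
componentPosteriors <- function(ps) ps@compGamma

#' @describeIn PosteriorSet-class sequence log-likelihood.
#' @param object a \linkS4class{PosteriorSet}.
#' @importFrom stats logLik
#' @export
setMethod("logLik", "PosteriorSet", function(object) object@loglik)

#' Per-iteration log-likelihood trajectory of an EM fit
#' @param report a \linkS4class{FitReport}.
#' @export
loglikTrajectory <- function(report) report@loglikTrajectory

#' Pooled confusion counts of a cross-validation run
#' @param cv a \linkS4class{CVResult}.
#' @export
pooledConfusion <- function(cv) cv@pooled

#' Fold assignment of a cross-validation run
#' @param cv a \linkS4class{CVResult}.
#' @return named integer vector, subject id to fold.
#' @export
foldAssignments <- function(cv) cv@foldAssignments

#' Pooled cross-validation metrics
#' @param cv a \linkS4class{CVResult}.
#' @return named vector: sensitivity, specificity, accuracy (percent) and
#'   accuracy_spread (pp across folds).
#' @export
cvMetrics <- function(cv) {
  c(sensitivity = cv@sensitivity, specificity = cv@specificity,
    accuracy = cv@accuracy, accuracy_spread = cv@accuracySpread)
}

#' Manifest records
#' @param manifest a \linkS4class{CohortManifest}.
#' @return data.frame of subject records.
#' @export
manifestRecords <- function(manifest) manifest@records
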