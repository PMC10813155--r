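#' @import methods
NULL

.SIMPLEX_TOL <- 1e-12

.checkSimplex <- function(x, what) {
  if (any(!is.finite(x)) || any(x < -.SIMPLEX_TOL) || any(x > 1 + .SIMPLEX_TOL))
    return(sprintf("%s has entries outside [0, 1]", what))
  if (abs(sum(x) - 1) > 1e-8)
    return(sprintf("%s sums to %.15g, not 1", what, sum(x)))
  NULL
}

#' Markov chain parameters
#'
#' A finite-state Markov chain: initial distribution \code{pi}, row-stochastic
#' transition matrix \code{A}, and the chain \code{order}. Only first-order
#' chains are operated on by the inference and learning code; the order slot
#' exists so higher-order chains are representable, and any inference call on
#' \code{order > 1} fails with a clear error.
#'
#' @slot A K x K transition probability matrix, rows summing to 1.
#' @slot pi length-K initial state distribution.
#' @slot order chain order; only 1 is supported by inference.
#' @exportClass MarkovChain
setClass("MarkovChain",
  representation(A = "matrix", pi = "numeric", order = "integer"),
  prototype(order = 1L))

setValidity("MarkovChain", function(object) {
  K <- length(object@pi)
  if (K < 1L) return("pi must have length >= 1")
  if (!all(dim(object@A) == c(K, K)))
    return(sprintf("A must be %d x %d to match pi", K, K))
  msg <- .checkSimplex(object@pi, "pi")
  if (!is.null(msg)) return(msg)
  for (k in seq_len(K)) {
    msg <- .checkSimplex(object@A[k, ], sprintf("row %d of A", k))
    if (!is.null(msg)) return(msg)
  }
  if (object@order < 1L) return("order must be a positive integer")
  TRUE
})

#' @param A transition matrix.
#' @param pi initial distribution.
#' @param order chain order (default 1).
#' @rdname MarkovChain-class
#' @export
markovChain <- function(A, pi, order = 1L) {
  new("MarkovChain", A = as.matrix(A), pi = as.numeric(pi),
      order = as.integer(order))
}

#' Discrete-emission hidden Markov model
#'
#' A hidden Markov model over a finite alphabet of M symbols: a
#' \linkS4class{MarkovChain} over K hidden states plus a K x M emission
#' probability matrix B, with \code{B[l, m] = p(x = m | state l)}. Likelihood
#' evaluation is supported; Baum-Welch learning is implemented only for the
#' Gaussian case.
#'
#' @slot chain the hidden-state \linkS4class{MarkovChain}.
#' @slot B K x M row-stochastic emission matrix.
#' @exportClass DiscreteHMM
setClass("DiscreteHMM",
  representation(chain = "MarkovChain", B = "matrix"))

setValidity("DiscreteHMM", function(object) {
  K <- length(object@chain@pi)
  if (nrow(object@B) != K)
    return(sprintf("B has %d rows but the chain has %d states", nrow(object@B), K))
  if (ncol(object@B) < 1L) return("alphabet size M must be >= 1")
  for (l in seq_len(K)) {
    msg <- .checkSimplex(object@B[l, ], sprintf("row %d of B", l))
    if (!is.null(msg)) return(msg)
  }
  TRUE
})

#' @param chain a \linkS4class{MarkovChain}.
#' @param B emission probability matrix.
#' @rdname DiscreteHMM-class
#' @export
discreteHMM <- function(chain, B) new("DiscreteHMM", chain = chain, B = as.matrix(B))

#' Gaussian-mixture emission for one hidden state
#'
#' The emission density of one hidden state: a mixture of multivariate
#' Gaussians with simplex \code{weights}, component \code{means} (rows) and a
#' d x d x n_components array of \code{covariances}. A single component is the
#' plain Gaussian state density.
#'
#' @slot weights length-J mixture weights.
#' @slot means J x d matrix of component means (signal units, mm for COP).
#' @slot covariances d x d x J array of symmetric positive-definite matrices.
#' @exportClass GaussMixEmission
setClass("GaussMixEmission",
  representation(weights = "numeric", means = "matrix", covariances = "array"))

setValidity("GaussMixEmission", function(object) {
  J <- length(object@weights)
  d <- ncol(object@means)
  if (nrow(object@means) != J)
    return("means must have one row per mixture component")
  dm <- dim(object@covariances)
  if (length(dm) != 3L || !all(dm == c(d, d, J)))
    return(sprintf("covariances must be %d x %d x %d", d, d, J))
  msg <- .checkSimplex(object@weights, "mixture weights")
  if (!is.null(msg)) return(msg)
  for (j in seq_len(J)) {
    S <- object@covariances[, , j, drop = TRUE]
    S <- matrix(S, d, d)
    if (max(abs(S - t(S))) > 1e-8) return(sprintf("covariance %d is not symmetric", j))
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) return(sprintf("covariance %d is not positive definite", j))
  }
  TRUE
})

#' @param weights mixture weights.
#' @param means component means, J x d (a vector is taken as J x 1).
#' @param covariances d x d x J array; for d = 1 a vector of variances works.
#' @rdname GaussMixEmission-class
#' @export
gaussMixEmission <- function(weights, means, covariances) {
  if (is.null(dim(means))) means <- matrix(means, ncol = 1L)
  d <- ncol(means); J <- nrow(means)
  if (is.null(dim(covariances))) covariances <- array(covariances, c(d, d, J))
  new("GaussMixEmission", weights = as.numeric(weights),
      means = as.matrix(means), covariances = covariances)
}

#' Hidden Markov model with Gaussian-mixture emissions
#'
#' The full model lambda = (pi, A, emissions): a \linkS4class{MarkovChain}
#' over K hidden states, each emitting d-dimensional observations from its
#' own \linkS4class{GaussMixEmission}. d = 1 models a single COP channel
#' (ML or AP); d = 2 models the two channels jointly with full covariances.
#'
#' @slot chain the hidden-state \linkS4class{MarkovChain}.
#' @slot d observation dimension.
#' @slot emissions list of K \linkS4class{GaussMixEmission} objects, all
#'   sharing \code{d} and the component count.
#' @exportClass GaussianHMM
setClass("GaussianHMM",
  representation(chain = "MarkovChain", d = "integer", emissions = "list"))

setValidity("GaussianHMM", function(object) {
  K <- length(object@chain@pi)
  if (length(object@emissions) != K)
    return(sprintf("need %d emissions, one per state; got %d", K, length(object@emissions)))
  if (!all(vapply(object@emissions, is, logical(1), "GaussMixEmission")))
    return("emissions must be GaussMixEmission objects")
  ds <- vapply(object@emissions, function(e) ncol(e@means), integer(1))
  Js <- vapply(object@emissions, function(e) length(e@weights), integer(1))
  if (any(ds != object@d))
    return(sprintf("emission dimension %d does not match model d = %d", ds[ds != object@d][1], object@d))
  if (length(unique(Js)) != 1L)
    return("all states must share the same number of mixture components")
  if (object@chain@order != 1L)
    return("only first-order chains are supported for Gaussian HMMs")
  TRUE
})

#' @param chain a \linkS4class{MarkovChain}.
#' @param emissions list of per-state \linkS4class{GaussMixEmission}.
#' @rdname GaussianHMM-class
#' @export
gaussianHMM <- function(chain, emissions) {
  d <- ncol(emissions[[1]]@means)
  new("GaussianHMM", chain = chain, d = as.integer(d), emissions = emissions)
}

#' One subject's center-of-pressure recording
#'
#' An n x d matrix of COP displacements (mm), one column per channel
#' (ML and/or AP), with sampling metadata, a subject identifier and an
#' optional class label (\code{"healthy"} or \code{"pd"}; \code{NA} when
#' unlabeled).
#'
#' @slot values n x d numeric matrix of displacements.
#' @slot samplingRate sampling rate in Hz.
#' @slot channels ordered channel labels, a subset of \code{c("ML", "AP")}.
#' @slot subjectId opaque subject identifier.
#' @slot label \code{"healthy"}, \code{"pd"} or \code{NA}.
#' @exportClass ObservationSequence
setClass("ObservationSequence",
  representation(values = "matrix", samplingRate = "numeric",
                 channels = "character", subjectId = "character",
                 label = "character"),
  prototype(subjectId = NA_character_, label = NA_character_))

setValidity("ObservationSequence", function(object) {
  if (nrow(object@values) < 1L) return("sequence must contain at least one sample")
  if (ncol(object@values) != length(object@channels))
    return(sprintf("%d value columns but %d channel labels",
                   ncol(object@values), length(object@channels)))
  if (!all(object@channels %in% c("ML", "AP")))
    return("channels must be a subset of {ML, AP}")
  if (anyDuplicated(object@channels)) return("duplicate channel labels")
  if (!all(is.finite(object@values))) return("values contain non-finite entries")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    return("samplingRate must be a single positive number")
  if (!is.na(object@label) && !object@label %in% c("healthy", "pd"))
    return(sprintf("label must be 'healthy' or 'pd', got '%s'", object@label))
  TRUE
})

#' @param values displacement matrix (a vector is taken as one channel).
#' @param samplingRate sampling rate in Hz.
#' @param channels channel labels matching the columns of \code{values}.
#' @param subjectId subject identifier.
#' @param label optional class label.
#' @rdname ObservationSequence-class
#' @export
observationSequence <- function(values, samplingRate, channels,
                                subjectId = NA_character_,
                                label = NA_character_) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  values <- as.matrix(values)
  dimnames(values) <- NULL
  new("ObservationSequence", values = values,
      samplingRate = as.numeric(samplingRate), channels = as.character(channels),
      subjectId = as.character(subjectId), label = as.character(label))
}

#' Forward-backward sufficient statistics
#'
#' Per-sample state posteriors \code{gamma} (tau in the EM update equations),
#' per-sample state-component posteriors \code{compGamma}, expected transition
#' counts summed over time \code{xiSum}, and the sequence log-likelihood.
#' These are exactly the sufficient statistics the Baum-Welch M-step consumes.
#'
#' @slot gamma n x K state posterior matrix, rows summing to 1.
#' @slot xiSum K x K expected transition counts, totalling n - 1.
#' @slot compGamma n x K x J state-component posteriors, summing over
#'   components to \code{gamma}.
#' @slot loglik log p(X | lambda).
#' @exportClass PosteriorSet
setClass("PosteriorSet",
  representation(gamma = "matrix", xiSum = "matrix", compGamma = "array",
                 loglik = "numeric"))

setValidity("PosteriorSet", function(object) {
  n <- nrow(object@gamma)
  if (max(abs(rowSums(object@gamma) - 1)) > 1e-10)
    return("gamma rows must sum to 1")
  if (any(object@xiSum < -1e-12)) return("xiSum entries must be nonnegative")
  if (n > 1L && abs(sum(object@xiSum) - (n - 1)) > 1e-8)
    return("xiSum must total n - 1")
  cg <- 0
  for (j in seq_len(dim(object@compGamma)[3]))
    cg <- cg + object@compGamma[, , j]
  if (max(abs(cg - object@gamma)) > 1e-10)
    return("compGamma must sum over components to gamma")
  TRUE
})

#' Baum-Welch fit configuration
#'
#' Hyperparameters of K-means initialisation and Baum-Welch EM. Defaults are
#' the settings the classifier uses throughout: 3 hidden states, 2 Gaussian
#' mixture components per state, 15 EM iterations with no tolerance-based
#' early stop (\code{tol = 0} runs all iterations).
#'
#' @slot nStates number of hidden states.
#' @slot nComponents Gaussian mixture components per state.
#' @slot nIter EM iteration cap.
#' @slot tol log-likelihood convergence tolerance; 0 disables early stopping.
#' @slot covFloorScale covariance eigenvalue floor as a fraction of the pooled
#'   data variance.
#' @slot seed RNG seed for K-means and any re-seeding.
#' @slot kmeansRestarts K-means restarts; the best inertia wins.
#' @exportClass FitConfig
setClass("FitConfig",
  representation(nStates = "integer", nComponents = "integer",
                 nIter = "integer", tol = "numeric",
                 covFloorScale = "numeric", seed = "integer",
                 kmeansRestarts = "integer"))

setValidity("FitConfig", function(object) {
  if (object@nStates < 1L) return("nStates must be positive")
  if (object@nComponents < 1L) return("nComponents must be positive")
  if (object@nIter < 1L) return("nIter must be positive")
  if (object@tol < 0) return("tol must be nonnegative")
  if (object@covFloorScale <= 0) return("covFloorScale must be positive")
  if (object@kmeansRestarts < 1L) return("kmeansRestarts must be positive")
  TRUE
})

#' @param nStates,nComponents,nIter,tol,covFloorScale,seed,kmeansRestarts see slots.
#' @rdname FitConfig-class
#' @export
fitConfig <- function(nStates = 3L, nComponents = 2L, nIter = 15L, tol = 0,
                      covFloorScale = 1e-6, seed = 1L, kmeansRestarts = 5L) {
  new("FitConfig", nStates = as.integer(nStates),
      nComponents = as.integer(nComponents), nIter = as.integer(nIter),
      tol = as.numeric(tol), covFloorScale = as.numeric(covFloorScale),
      seed = as.integer(seed), kmeansRestarts = as.integer(kmeansRestarts))
}

#' EM fit report
#'
#' @slot loglikTrajectory total training log-likelihood at the start of each
#'   EM iteration (the quantity the M-step then improves).
#' @slot nIterRun iterations actually run.
#' @slot convergedByTol whether a positive tolerance stopped the fit early.
#' @exportClass FitReport
setClass("FitReport",
  representation(loglikTrajectory = "numeric", nIterRun = "integer",
                 convergedByTol = "logical"))

setValidity("FitReport", function(object) {
  if (length(object@loglikTrajectory) != object@nIterRun)
    return("trajectory length must equal nIterRun")
  TRUE
})

#' Trained two-model classifier
#'
#' A trained healthy-model / PD-model pair plus the preprocessing and channel
#' configuration needed to apply it. A subject is classified by evaluating the
#' observation log-likelihood under both models and taking the larger
#' (exact ties go to PD). For \code{channelMode = "MLAP"} the default fusion
#' is a single bivariate model per class; \code{fusion = "loglik_sum"} instead
#' trains one model per channel per class and sums the channel
#' log-likelihoods.
#'
#' @slot hModels list of \linkS4class{GaussianHMM} trained on healthy subjects
#'   (one model, or one per channel under \code{loglik_sum} fusion).
#' @slot pdModels matching list trained on PD subjects.
#' @slot channelMode \code{"ML"}, \code{"AP"} or \code{"MLAP"}.
#' @slot fusion \code{"bivariate"} or \code{"loglik_sum"}.
#' @slot decimate decimation factor applied before training/classification.
#' @slot center whether per-channel means are removed.
#' @slot fitConfig the \linkS4class{FitConfig} used for both classes.
#' @exportClass ClassifierModel
setClass("ClassifierModel",
  representation(hModels = "list", pdModels = "list", channelMode = "character",
                 fusion = "character", decimate = "integer", center = "logical",
                 fitConfig = "FitConfig"))

setValidity("ClassifierModel", function(object) {
  if (!object@channelMode %in% c("ML", "AP", "MLAP"))
    return("channelMode must be ML, AP or MLAP")
  if (!object@fusion %in% c("bivariate", "loglik_sum"))
    return("fusion must be 'bivariate' or 'loglik_sum'")
  if (length(object@hModels) != length(object@pdModels))
    return("hModels and pdModels must have equal length")
  dH <- vapply(object@hModels, function(m) m@d, integer(1))
  dP <- vapply(object@pdModels, function(m) m@d, integer(1))
  if (!identical(dH, dP)) return("healthy and PD models must share dimensions")
  expected_d <- if (object@channelMode == "MLAP" && object@fusion == "bivariate") 2L else 1L
  if (any(dH != expected_d))
    return(sprintf("model dimension %d inconsistent with channel mode %s",
                   dH[1], object@channelMode))
  TRUE
})

#' Confusion counts in the two-class layout
#'
#' Pooled confusion counts for the healthy / PD classification task, in the
#' layout Subjects / Predicted H / Predicted PD.
#'
#' @slot nHealthy,nPd class sizes.
#' @slot hPredH,hPredPd healthy subjects predicted healthy / PD.
#' @slot pdPredH,pdPredPd PD subjects predicted healthy / PD.
#' @exportClass ConfusionCounts
setClass("ConfusionCounts",
  representation(nHealthy = "integer", nPd = "integer", hPredH = "integer",
                 hPredPd = "integer", pdPredH = "integer", pdPredPd = "integer"))

setValidity("ConfusionCounts", function(object) {
  cnt <- c(object@hPredH, object@hPredPd, object@pdPredH, object@pdPredPd)
  if (any(cnt < 0L)) return("counts must be nonnegative")
  if (object@hPredH + object@hPredPd != object@nHealthy)
    return("healthy predictions must total nHealthy")
  if (object@pdPredH + object@pdPredPd != object@nPd)
    return("PD predictions must total nPd")
  TRUE
})

#' @param hPredH,hPredPd,pdPredH,pdPredPd cell counts.
#' @rdname ConfusionCounts-class
#' @export
confusionCounts <- function(hPredH, hPredPd, pdPredH, pdPredPd) {
  new("ConfusionCounts",
      nHealthy = as.integer(hPredH + hPredPd), nPd = as.integer(pdPredH + pdPredPd),
      hPredH = as.integer(hPredH), hPredPd = as.integer(hPredPd),
      pdPredH = as.integer(pdPredH), pdPredPd = as.integer(pdPredPd))
}

#' Cross-validation result
#'
#' @slot k number of folds.
#' @slot foldAssignments named integer vector mapping subject id to fold.
#' @slot pooled pooled \linkS4class{ConfusionCounts} over all held-out folds.
#' @slot sensitivity,specificity,accuracy percentages computed from the pooled
#'   counts (healthy is the "positive" class: sensitivity is the percentage of
#'   healthy subjects classified healthy, specificity the percentage of PD
#'   subjects classified PD).
#' @slot accuracySpread sample standard deviation of per-fold accuracies (pp).
#' @slot perFoldAccuracy per-fold accuracies (percent).
#' @slot seed fold-shuffle seed.
#' @exportClass CVResult
setClass("CVResult",
  representation(k = "integer", foldAssignments = "integer",
                 pooled = "ConfusionCounts", sensitivity = "numeric",
                 specificity = "numeric", accuracy = "numeric",
                 accuracySpread = "numeric", perFoldAccuracy = "numeric",
                 seed = "integer"))

setValidity("CVResult", function(object) {
  m <- computeMetrics(object@pooled)
  if (abs(m[["sensitivity"]] - object@sensitivity) > 1e-9 ||
      abs(m[["specificity"]] - object@specificity) > 1e-9 ||
      abs(m[["accuracy"]] - object@accuracy) > 1e-9)
    return("stored metrics inconsistent with pooled confusion counts")
  TRUE
})

#' Cohort manifest
#'
#' The index of a cohort on disk: one record per subject (id, file path,
#' class label, optional group tag) plus nominal sampling metadata. Sampling
#' rate and duration may be \code{NA} when unknown, e.g. for a manifest read
#' from disk before the recordings are loaded.
#'
#' @slot records data.frame with columns subject_id, path, label, group.
#' @slot samplingRate nominal sampling rate in Hz (may be \code{NA}).
#' @slot duration nominal recording duration in seconds (may be \code{NA}).
#' @exportClass CohortManifest
setClass("CohortManifest",
  representation(records = "data.frame", samplingRate = "numeric",
                 duration = "numeric"),
  prototype(samplingRate = NA_real_, duration = NA_real_))

setValidity("CohortManifest", function(object) {
  req <- c("subject_id", "path", "label", "group")
  if (!all(req %in% names(object@records)))
    return(sprintf("records must have columns %s", paste(req, collapse = ", ")))
  if (nrow(object@records) == 0L) return("manifest is empty")
  dup <- object@records$subject_id[duplicated(object@records$subject_id)]
  if (length(dup) > 0L)
    return(sprintf("duplicate subject_id: %s", paste(unique(dup), collapse = ", ")))
  bad <- setdiff(unique(object@records$label), c("healthy", "pd"))
  if (length(bad) > 0L)
    return(sprintf("unknown label(s): %s (must be healthy or pd)",
                   paste(bad, collapse = ", ")))
  TRUE
})

#' @param records manifest data.frame (column \code{group} optional).
#' @param samplingRate,duration nominal sampling metadata.
#' @rdname CohortManifest-class
#' @export
cohortManifest <- function(records, samplingRate = NA_real_, duration = NA_real_) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (is.null(records$group)) records$group <- NA_character_
  new("CohortManifest", records = records,
      samplingRate = as.numeric(samplingRate), duration = as.numeric(duration))
}

#' Synthetic cohort configuration
#'
#' Study-condition defaults mirror the cohort geometry the classifier is
#' evaluated on: 28 healthy and 32 PD subjects, 60 s of quiet standing per
#' subject. The default simulated rate is 100 Hz so a full
#' train/cross-validate cycle runs in minutes; 1000 Hz remains available.
#'
#' @slot nHealthy,nPd class sizes.
#' @slot duration recording duration in seconds.
#' @slot samplingRate sampling rate in Hz.
#' @slot mode \code{"hmm"} (regime-switching ground truth) or \code{"ar2"}
#'   (stable second-order autoregressive sway).
#' @slot separation nonnegative scale of the healthy/PD generator difference;
#'   0 makes the class generators identical.
#' @slot seed master seed.
#' @exportClass CohortSimConfig
setClass("CohortSimConfig",
  representation(nHealthy = "integer", nPd = "integer", duration = "numeric",
                 samplingRate = "numeric", mode = "character",
                 separation = "numeric", seed = "integer"))

setValidity("CohortSimConfig", function(object) {
  if (object@nHealthy < 0L || object@nPd < 0L) return("class sizes must be >= 0")
  if (object@separation < 0) return("separation must be nonnegative")
  if (!object@mode %in% c("hmm", "ar2")) return("mode must be 'hmm' or 'ar2'")
  if (object@duration <= 0 || object@samplingRate <= 0)
    return("duration and samplingRate must be positive")
  TRUE
})

#' @param nHealthy,nPd,duration,samplingRate,mode,separation,seed see slots.
#' @rdname CohortSimConfig-class
#' @export
cohortSimConfig <- function(nHealthy = 28L, nPd = 32L, duration = 60,
                            samplingRate = 100, mode = "hmm",
                            separation = 1, seed = 1L) {
  new("CohortSimConfig", nHealthy = as.integer(nHealthy), nPd = as.integer(nPd),
      duration = as.numeric(duration), samplingRate = as.numeric(samplingRate),
      mode = mode, separation = as.numeric(separation), seed = as.integer(seed))
}
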