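#' @include accessors.R
NULL

setMethod("show", "MarkovChain", function(object) {
  cat(sprintf("MarkovChain: %d states, order %d\n", nStates(object), object@order))
  cat("pi:", format(round(object@pi, 4)), "\n")
  cat("A:\n"); print(round(object@A, 4))
})

setMethod("show", "GaussianHMM", function(object) {
  K <- nStates(object)
  J <- length(object@emissions[[1]]@weights)
  cat(sprintf("GaussianHMM: %d states, %d mixture component(s)/state, d = %d\n",
              K, J, object@d))
  cat("pi:", format(round(object@chain@pi, 4)), "\n")
  cat("A:\n"); print(round(object@chain@A, 4))
  for (k in seq_len(K)) {
    em <- object@emissions[[k]]
    cat(sprintf("state %d: weights = %s; means:\n", k,
                paste(round(em@weights, 3), collapse = ", ")))
    print(round(em@means, 3))
  }
})

setMethod("show", "ObservationSequence", function(object) {
  cat(sprintf("ObservationSequence '%s': %d samples x %d channel(s) [%s] at %g Hz (%.1f s)%s\n",
              object@subjectId, nrow(object@values), ncol(object@values),
              paste(object@channels, collapse = ","), object@samplingRate,
              nrow(object@values) / object@samplingRate,
              if (is.na(object@label)) "" else sprintf(", label = %s", object@label)))
})

setMethod("show", "PosteriorSet", function(object) {
  cat(sprintf("PosteriorSet: n = %d, K = %d, J = %d, loglik = %.4f\n",
              nrow(object@gamma), ncol(object@gamma), dim(object@compGamma)[3],
              object@loglik))
})

setMethod("show", "FitConfig", function(object) {
  cat(sprintf("FitConfig: %d states, %d mixtures, %d iterations (tol = %g), cov floor %g, seed %d, %d k-means restarts\n",
              object@nStates, object@nComponents, object@nIter, object@tol,
              object@covFloorScale, object@seed, object@kmeansRestarts))
})

setMethod("show", "FitReport", function(object) {
  cat(sprintf("FitReport: %d iteration(s)%s; log-likelihood %.4f -> %.4f\n",
              object@nIterRun,
              if (object@convergedByTol) " (stopped by tol)" else "",
              object@loglikTrajectory[1],
              object@loglikTrajectory[object@nIterRun]))
})

setMethod("show", "ClassifierModel", function(object) {
  cat(sprintf("ClassifierModel: channels %s (%s fusion), decimate %d, center %s\n",
              object@channelMode, object@fusion, object@decimate, object@center))
  show(object@fitConfig)
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("%-9s %-12s %-12s\n", "Subjects", "Predicted H", "Predicted PD"))
  cat(sprintf("%-9s %-12d %-12d\n", "Healthy", object@hPredH, object@hPredPd))
  cat(sprintf("%-9s %-12d %-12d\n", "PD", object@pdPredH, object@pdPredPd))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", object@k, object@seed))
  writeLines(formatConfusionTable(object))
})

setMethod("show", "CohortManifest", function(object) {
  rec <- object@records
  cat(sprintf("CohortManifest: %d subjects (%d healthy, %d pd)",
              nrow(rec), sum(rec$label == "healthy"), sum(rec$label == "pd")))
  if (!is.na(object@samplingRate))
    cat(sprintf(", %g Hz x %g s", object@samplingRate, object@duration))
  cat("\n")
})
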