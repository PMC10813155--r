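#' @include classifier.R
NULL

.MODEL_SCHEMA_VERSION <- "1"

.hmmToList <- function(m) {
  list(pi = m@chain@pi, A = m@chain@A, d = m@d,
       emissions = lapply(m@emissions, function(e)
         list(weights = e@weights, means = e@means,
              covariances = lapply(seq_along(e@weights), function(j)
                matrix(e@covariances[, , j], m@d, m@d)))))
}

# JSON stores matrices as lists of rows; rebuild row-wise.
.jsonMatrix <- function(x) {
  if (is.matrix(x)) return(x)
  do.call(rbind, lapply(x, function(r) as.numeric(unlist(r))))
}

.hmmFromList <- function(l) {
  d <- as.integer(l$d)
  ems <- lapply(l$emissions, function(e) {
    w <- as.numeric(unlist(e$weights))
    J <- length(w)
    covs <- array(0, c(d, d, J))
    for (j in seq_len(J)) covs[, , j] <- .jsonMatrix(e$covariances[[j]])
    means <- .jsonMatrix(e$means)
    if (d == 1L) means <- matrix(as.numeric(unlist(e$means)), J, 1L)
    gaussMixEmission(w, means, covs)
  })
  pi <- as.numeric(unlist(l$pi))
  A <- .jsonMatrix(l$A)
  if (length(pi) == 1L) A <- matrix(as.numeric(unlist(l$A)), 1L, 1L)
  gaussianHMM(markovChain(A, pi), ems)
}

#' Serialize a trained classifier to versioned JSON
#'
#' Writes every parameter (initial distributions, transition matrices,
#' mixture weights, means, covariances) together with the fit configuration
#' in a human-readable, versioned JSON schema, so trained models are
#' auditable and a write/read round trip reproduces the classifier exactly.
#'
#' @param model a \linkS4class{ClassifierModel}.
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
writeClassifierModel <- function(model, path) {
  validObject(model)
  cfg <- model@fitConfig
  obj <- list(
    schema = "copHMM-classifier", version = .MODEL_SCHEMA_VERSION,
    channel_mode = model@channelMode, fusion = model@fusion,
    decimate = model@decimate, center = model@center,
    fit_config = list(n_states = cfg@nStates, n_components = cfg@nComponents,
                      n_iter = cfg@nIter, tol = cfg@tol,
                      cov_floor_scale = cfg@covFloorScale, seed = cfg@seed,
                      kmeans_restarts = cfg@kmeansRestarts),
    h_models = lapply(model@hModels, .hmmToList),
    pd_models = lapply(model@pdModels, .hmmToList))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a classifier serialized by \code{writeClassifierModel}
#' @param path JSON file path.
#' @return a \linkS4class{ClassifierModel}.
#' @export
readClassifierModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$schema, "copHMM-classifier"))
    stop("not a copHMM classifier file: ", path, call. = FALSE)
  if (!identical(as.character(obj$version), .MODEL_SCHEMA_VERSION))
    stop("unsupported classifier schema version: ", obj$version, call. = FALSE)
  fc <- obj$fit_config
  cfg <- fitConfig(fc$n_states, fc$n_components, fc$n_iter, fc$tol,
                   fc$cov_floor_scale, fc$seed, fc$kmeans_restarts)
  new("ClassifierModel",
      hModels = lapply(obj$h_models, .hmmFromList),
      pdModels = lapply(obj$pd_models, .hmmFromList),
      channelMode = obj$channel_mode, fusion = obj$fusion,
      decimate = as.integer(obj$decimate), center = as.logical(obj$center),
      fitConfig = cfg)
}
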