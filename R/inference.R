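#' @include emissions.R
NULL

# Pure log-space forward recursion (reference path for the scaled C++ code).
.forwardLogspace <- function(logB, pi, A) {
  n <- nrow(logB); K <- ncol(logB)
  logA <- log(A)
  a <- log(pi) + logB[1L, ]
  if (n > 1L) for (i in 2:n) {
    a <- vapply(seq_len(K), function(l) .logSumExp(a + logA[, l]), numeric(1)) +
      logB[i, ]
  }
  .logSumExp(a)
}

.forwardGaussian <- function(model, seq, method = c("scaling", "logspace")) {
  method <- match.arg(method)
  .assertFirstOrder(model@chain)
  logB <- logEmissionMatrix(model, seq)
  if (method == "scaling")
    cpp_forward_loglik(logB, model@chain@pi, model@chain@A)
  else
    .forwardLogspace(logB, model@chain@pi, model@chain@A)
}

#' @describeIn forwardLogLik Gaussian HMM on an observation sequence.
#' @export
setMethod("forwardLogLik", signature("GaussianHMM", "ANY"),
  function(model, seq, ...) .forwardGaussian(model, seq, ...))

# Discrete emissions: logB[i, k] = log B[k, x_i] for symbols x_i in 1..M.
.discreteLogB <- function(model, seq) {
  x <- as.integer(seq)
  if (length(x) == 0L) stop("empty observation sequence", call. = FALSE)
  if (anyNA(x)) stop("observation sequence contains NA symbols", call. = FALSE)
  M <- ncol(model@B)
  if (any(x < 1L | x > M))
    stop(sprintf("symbols must lie in 1..%d", M), call. = FALSE)
  t(log(model@B)[, x, drop = FALSE])
}

#' @describeIn forwardLogLik discrete HMM on an integer symbol vector.
#' @export
setMethod("forwardLogLik", signature("DiscreteHMM", "ANY"),
  function(model, seq, ...) {
    method <- match.arg(list(...)$method %||% "scaling", c("scaling", "logspace"))
    .assertFirstOrder(model@chain)
    logB <- .discreteLogB(model, seq)
    if (method == "scaling")
      cpp_forward_loglik(logB, model@chain@pi, model@chain@A)
    else
      .forwardLogspace(logB, model@chain@pi, model@chain@A)
  })

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn forwardBackward Gaussian HMM posteriors.
#' @export
setMethod("forwardBackward", signature("GaussianHMM", "ObservationSequence"),
  function(model, seq) {
    .assertFirstOrder(model@chain)
    x <- .asValuesMatrix(seq)
    .checkSeqValues(x)
    logComp <- .logComponentDensities(model, x)
    logB <- .collapseLogB(logComp)
    if (!all(is.finite(logB)))
      stop("non-finite log emission density; check model covariances", call. = FALSE)
    fb <- cpp_forward_backward(logB, model@chain@pi, model@chain@A)
    n <- nrow(x); K <- ncol(logB); J <- dim(logComp)[3]
    compGamma <- array(0, c(n, K, J))
    for (j in seq_len(J))
      compGamma[, , j] <- fb$gamma * exp(matrix(logComp[, , j], n, K) - logB)
    # exact component-sum consistency with gamma
    tot <- 0
    for (j in seq_len(J)) tot <- tot + compGamma[, , j]
    scale <- ifelse(tot > 0, fb$gamma / pmax(tot, .Machine$double.xmin), 0)
    for (j in seq_len(J)) compGamma[, , j] <- compGamma[, , j] * scale
    new("PosteriorSet", gamma = fb$gamma, xiSum = fb$xi_sum,
        compGamma = compGamma, loglik = fb$loglik)
  })

#' @describeIn viterbiDecode Gaussian HMM decoding.
#' @export
setMethod("viterbiDecode", signature("GaussianHMM", "ANY"),
  function(model, seq) {
    .assertFirstOrder(model@chain)
    logB <- logEmissionMatrix(model, seq)
    vt <- cpp_viterbi(logB, log(model@chain@pi), log(model@chain@A))
    list(path = as.integer(vt$path), logJoint = vt$logjoint)
  })

#' @describeIn sampleSequence draw from a Gaussian HMM.
#' @param ... unused.
#' @export
setMethod("sampleSequence", signature("GaussianHMM"),
  function(model, n, seed, samplingRate = 100, channels = NULL,
           subjectId = NA_character_, label = NA_character_, ...) {
    n <- as.integer(n)
    if (is.na(n) || n < 1L) stop("n must be a positive integer", call. = FALSE)
    K <- length(model@chain@pi); d <- model@d
    if (is.null(channels)) channels <- c("ML", "AP")[seq_len(d)]
    .withSeed(seed, {
      states <- integer(n)
      states[1L] <- sample.int(K, 1L, prob = model@chain@pi)
      if (n > 1L) for (i in 2:n)
        states[i] <- sample.int(K, 1L, prob = model@chain@A[states[i - 1L], ])
      J <- length(model@emissions[[1]]@weights)
      comp <- integer(n)
      for (i in seq_len(n))
        comp[i] <- if (J == 1L) 1L else
          sample.int(J, 1L, prob = model@emissions[[states[i]]]@weights)
      x <- matrix(NA_real_, n, d)
      # draw standard normals once, colour per (state, component) group
      for (k in seq_len(K)) for (j in seq_len(J)) {
        idx <- which(states == k & comp == j)
        if (length(idx) == 0L) next
        em <- model@emissions[[k]]
        R <- chol(matrix(em@covariances[, , j], d, d))
        z <- matrix(stats::rnorm(length(idx) * d), ncol = d)
        x[idx, ] <- sweep(z %*% R, 2L, em@means[j, ], "+")
      }
      list(seq = observationSequence(x, samplingRate, channels, subjectId, label),
           states = states)
    })
  })

.enumeratePaths <- function(K, n) {
  if (K^n > 1e6)
    stop("path enumeration guard: K^n = ", K^n,
         " exceeds 1e6; use a smaller instance", call. = FALSE)
  as.matrix(expand.grid(rep(list(seq_len(K)), n)))
}

# Log joint of every path: vector over the K^n enumerated paths.
.pathLogJoints <- function(logB, pi, A, paths) {
  n <- ncol(paths)
  lp <- log(pi)[paths[, 1L]] + logB[cbind(1L, paths[, 1L])]
  if (n > 1L) {
    logA <- log(A)
    for (i in 2:n)
      lp <- lp + logA[cbind(paths[, i - 1L], paths[, i])] +
        logB[cbind(i, paths[, i])]
  }
  lp
}

.bruteForce <- function(logB, pi, A) {
  paths <- .enumeratePaths(length(pi), nrow(logB))
  .logSumExp(.pathLogJoints(logB, pi, A, paths))
}

#' @describeIn bruteForceLogLik Gaussian HMM oracle.
#' @export
setMethod("bruteForceLogLik", signature("GaussianHMM", "ANY"),
  function(model, seq) {
    .assertFirstOrder(model@chain)
    .bruteForce(logEmissionMatrix(model, seq), model@chain@pi, model@chain@A)
  })

#' @describeIn bruteForceLogLik discrete HMM oracle.
#' @export
setMethod("bruteForceLogLik", signature("DiscreteHMM", "ANY"),
  function(model, seq) {
    .assertFirstOrder(model@chain)
    .bruteForce(.discreteLogB(model, seq), model@chain@pi, model@chain@A)
  })
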