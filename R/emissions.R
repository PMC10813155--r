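#' @include AllGenerics.R
NULL

# Log density of n points under one multivariate Gaussian, via Cholesky.
# x: n x d matrix. Errors if Sigma is not positive definite.
.logMvnorm <- function(x, mu, Sigma) {
  d <- ncol(x)
  R <- tryCatch(chol(Sigma), error = function(e)
    stop("covariance matrix is not positive definite", call. = FALSE))
  xc <- sweep(x, 2L, mu)
  z <- backsolve(R, t(xc), transpose = TRUE)   # solves t(R) z = t(xc)
  -0.5 * d * log(2 * pi) - sum(log(diag(R))) - 0.5 * colSums(z * z)
}

# n x K x J array of log(w_kj) + log N(x_i; mu_kj, Sigma_kj).
.logComponentDensities <- function(model, x) {
  n <- nrow(x); K <- length(model@emissions)
  J <- length(model@emissions[[1]]@weights)
  out <- array(NA_real_, c(n, K, J))
  for (k in seq_len(K)) {
    em <- model@emissions[[k]]
    for (j in seq_len(J)) {
      Sigma <- matrix(em@covariances[, , j], model@d, model@d)
      out[, k, j] <- log(em@weights[j]) + .logMvnorm(x, em@means[j, ], Sigma)
    }
  }
  out
}

# Collapse component log densities to the n x K state log density matrix.
.collapseLogB <- function(logComp) {
  n <- dim(logComp)[1]; K <- dim(logComp)[2]; J <- dim(logComp)[3]
  if (J == 1L) return(matrix(logComp[, , 1L], n, K))
  m <- matrix(logComp[, , 1L], n, K)
  for (j in 2:J) m <- pmax(m, matrix(logComp[, , j], n, K))
  s <- matrix(0, n, K)
  for (j in seq_len(J)) s <- s + exp(matrix(logComp[, , j], n, K) - m)
  m + log(s)
}

#' @describeIn logEmissionMatrix mixture log densities for a Gaussian HMM.
#' @export
setMethod("logEmissionMatrix", signature("GaussianHMM", "ANY"),
  function(model, seq) {
    x <- .asValuesMatrix(seq)
    .checkSeqValues(x)
    if (ncol(x) != model@d)
      stop(sprintf("sequence dimension %d does not match model dimension %d",
                   ncol(x), model@d), call. = FALSE)
    logB <- .collapseLogB(.logComponentDensities(model, x))
    if (!all(is.finite(logB)))
      stop("non-finite log emission density; check model covariances", call. = FALSE)
    logB
  })
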