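.logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Clamp the eigenvalues of a symmetric matrix at `floor` and symmetrise.
.floorCovariance <- function(S, floor) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  S <- e$vectors %*% (vals * t(e$vectors))
  (S + t(S)) / 2
}

# Stationary distribution of a row-stochastic matrix via eigen-decomposition.
.stationaryDistribution <- function(A) {
  e <- eigen(t(A))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' Symmetric KL divergence between two multivariate Gaussians
#'
#' Closed-form Jeffreys divergence
#' \code{0.5 * (KL(N1 || N2) + KL(N2 || N1))}; used to quantify how far apart
#' two state emission densities are.
#'
#' @param mu1,Sigma1,mu2,Sigma2 means and covariances of the two Gaussians.
#' @return a nonnegative number, 0 iff the Gaussians coincide.
#' @export
gaussSymKL <- function(mu1, Sigma1, mu2, Sigma2) {
  mu1 <- as.numeric(mu1); mu2 <- as.numeric(mu2)
  d <- length(mu1)
  Sigma1 <- matrix(Sigma1, d, d); Sigma2 <- matrix(Sigma2, d, d)
  i1 <- solve(Sigma1); i2 <- solve(Sigma2)
  dm <- mu1 - mu2
  kl12 <- 0.5 * (sum(diag(i2 %*% Sigma1)) + drop(t(dm) %*% i2 %*% dm) - d +
                   determinant(Sigma2)$modulus - determinant(Sigma1)$modulus)
  kl21 <- 0.5 * (sum(diag(i1 %*% Sigma2)) + drop(t(dm) %*% i1 %*% dm) - d +
                   determinant(Sigma1)$modulus - determinant(Sigma2)$modulus)
  as.numeric(kl12 + kl21) / 2
}

.assertFirstOrder <- function(chain) {
  if (chain@order != 1L)
    stop("inference supports first-order chains only; got order ", chain@order,
         call. = FALSE)
}

.asValuesMatrix <- function(seq) {
  if (is(seq, "ObservationSequence")) seq@values
  else if (is.matrix(seq)) seq
  else matrix(as.numeric(seq), ncol = 1L)
}

.checkSeqValues <- function(x) {
  if (length(x) == 0L || nrow(x) < 1L) stop("empty observation sequence", call. = FALSE)
  if (anyNA(x) || !all(is.finite(x)))
    stop("observation sequence contains NaN or non-finite values", call. = FALSE)
  invisible(x)
}
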