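#' @include inference.R
NULL

.pooledSamples <- function(sequences) {
  do.call(rbind, lapply(sequences, .asValuesMatrix))
}

# Floor value for covariance eigenvalues: a fraction of the pooled per-channel
# variance of the training data, guarded away from exactly zero.
.covFloorValue <- function(X, scale) {
  v <- mean(apply(X, 2L, stats::var))
  max(scale * v, .Machine$double.eps * 100)
}

.checkSharedGeometry <- function(sequences) {
  if (length(sequences) == 0L) stop("need at least one training sequence", call. = FALSE)
  ch <- lapply(sequences, function(s) s@channels)
  if (length(unique(ch)) != 1L)
    stop("all training sequences must share the same channels", call. = FALSE)
  invisible(sequences)
}

#' K-means initialisation of a Gaussian-mixture HMM
#'
#' Pools the samples of all training sequences, clusters them into
#' \code{nStates * nComponents} centroids with \code{\link[stats]{kmeans}}
#' (best of \code{kmeansRestarts} restarts by within-cluster sum of squares,
#' seeded), and assigns centroids to states in contiguous blocks of
#' \code{nComponents}. Component means are the centroids, covariances the
#' within-cluster covariances (1/n normalisation, eigenvalue-floored), mixture
#' weights proportional to cluster sizes within each state; the initial
#' distribution and transition matrix start uniform. Deterministic given the
#' seed in \code{config}.
#'
#' @param sequences list of \linkS4class{ObservationSequence}.
#' @param config a \linkS4class{FitConfig}.
#' @return a \linkS4class{GaussianHMM}.
#' @export
kmeansInit <- function(sequences, config = fitConfig()) {
  .checkSharedGeometry(sequences)
  X <- .pooledSamples(sequences)
  K <- config@nStates; J <- config@nComponents
  nc <- K * J
  if (nrow(X) < nc)
    stop(sprintf("too few samples (%d) for %d x %d clusters; need at least %d",
                 nrow(X), K, J, nc), call. = FALSE)
  floorVal <- .covFloorValue(X, config@covFloorScale)
  km <- .withSeed(config@seed, {
    if (nc == 1L) list(centers = matrix(colMeans(X), 1L), cluster = rep(1L, nrow(X)))
    else stats::kmeans(X, centers = nc, nstart = config@kmeansRestarts,
                       iter.max = 500L, algorithm = "Lloyd")
  })
  # deterministic centroid order: lexicographic on the centre coordinates
  ord <- do.call(order, as.data.frame(km$centers))
  relabel <- match(seq_len(nc), ord)
  cluster <- relabel[km$cluster]
  centers <- km$centers[ord, , drop = FALSE]

  d <- ncol(X)
  emissions <- vector("list", K)
  for (k in seq_len(K)) {
    idx_comp <- (k - 1L) * J + seq_len(J)
    means <- centers[idx_comp, , drop = FALSE]
    covs <- array(0, c(d, d, J))
    sizes <- numeric(J)
    for (j in seq_len(J)) {
      pts <- X[cluster == idx_comp[j], , drop = FALSE]
      sizes[j] <- nrow(pts)
      S <- if (nrow(pts) > 0L) crossprod(sweep(pts, 2L, means[j, ])) / nrow(pts)
           else diag(floorVal, d)
      covs[, , j] <- .floorCovariance(S, floorVal)
    }
    w <- if (sum(sizes) > 0) sizes / sum(sizes) else rep(1 / J, J)
    emissions[[k]] <- gaussMixEmission(w, means, covs)
  }
  chain <- markovChain(matrix(1 / K, K, K), rep(1 / K, K))
  gaussianHMM(chain, emissions)
}

#' Single-Gaussian M-step for one state
#'
#' The weighted mean and covariance updates with the state posteriors tau as
#' weights:
#' \code{mu_k = sum_i tau_ik x_i / sum_i tau_ik} and
#' \code{Sigma_k = sum_i tau_ik (x_i - mu_k)(x_i - mu_k)' / sum_i tau_ik},
#' optionally eigenvalue-floored. Exposed on its own so the update can be
#' checked against hand-computed values; \code{\link{baumWelchFit}} applies
#' the component-responsibility generalisation of the same update.
#'
#' @param posteriors a \linkS4class{PosteriorSet} computed from \code{seq}.
#' @param seq the \linkS4class{ObservationSequence} the posteriors refer to.
#' @param k state index.
#' @param floor covariance eigenvalue floor (default 0: no flooring).
#' @return list with \code{mu} and \code{Sigma}.
#' @export
mStepSingleGaussian <- function(posteriors, seq, k, floor = 0) {
  x <- .asValuesMatrix(seq)
  tau <- posteriors@gamma[, k]
  W <- sum(tau)
  if (W < 1e-10)
    stop(sprintf("state %d is starved: posterior mass %.3g below 1e-10", k, W),
         call. = FALSE)
  mu <- colSums(tau * x) / W
  xc <- sweep(x, 2L, mu)
  Sigma <- crossprod(xc, tau * xc) / W
  if (floor > 0) Sigma <- .floorCovariance(Sigma, floor)
  list(mu = mu, Sigma = Sigma)
}

# One E-step accumulation pass over all sequences. Returns the pooled
# sufficient statistics and the total log-likelihood at the current params.
.accumulateEStep <- function(model, sequences) {
  K <- length(model@chain@pi); d <- model@d
  J <- length(model@emissions[[1]]@weights)
  piAcc <- numeric(K)
  xiAcc <- matrix(0, K, K)
  W <- matrix(0, K, J)
  Sx <- array(0, c(K, J, d))
  Sxx <- array(0, c(K, J, d, d))
  total <- 0
  worst <- list(val = Inf, x = NULL)
  for (s in sequences) {
    ps <- forwardBackward(model, s)
    x <- s@values
    total <- total + ps@loglik
    piAcc <- piAcc + ps@gamma[1L, ]
    xiAcc <- xiAcc + ps@xiSum
    for (k in seq_len(K)) for (j in seq_len(J)) {
      tau <- ps@compGamma[, k, j]
      W[k, j] <- W[k, j] + sum(tau)
      Sx[k, j, ] <- Sx[k, j, ] + colSums(tau * x)
      Sxx[k, j, , ] <- Sxx[k, j, , ] + crossprod(x, tau * x)
    }
    # track the sample least covered by any state, for starvation re-seeding
    peak <- apply(ps@gamma, 1L, max)
    i <- which.min(peak)
    if (peak[i] < worst$val) worst <- list(val = peak[i], x = x[i, ])
  }
  list(piAcc = piAcc, xiAcc = xiAcc, W = W, Sx = Sx, Sxx = Sxx,
       loglik = total, worst = worst)
}

#' Baum-Welch EM for Gaussian-mixture HMMs over multiple sequences
#'
#' Expectation-maximisation from a given starting model. Each iteration runs
#' the scaled forward-backward pass on every training sequence, pools the
#' sufficient statistics (sequence boundaries are respected; sequences are
#' never concatenated), and re-estimates the initial distribution (average of
#' per-sequence initial posteriors), the transition matrix (row-normalised
#' pooled expected transition counts), and the per-state mixture weights,
#' means and covariances via the posterior-weighted updates. Covariance
#' eigenvalues are floored at \code{covFloorScale} times the pooled data
#' variance after every M-step. With \code{tol = 0} (the default) exactly
#' \code{nIter} iterations run; a positive \code{tol} stops early once the
#' log-likelihood improvement falls below it.
#'
#' A mixture component whose pooled posterior mass falls below 1e-10 is
#' re-seeded (with a warning) at the training sample least covered by any
#' state, with the floored pooled covariance.
#'
#' @param init starting \linkS4class{GaussianHMM}, typically from
#'   \code{\link{kmeansInit}}.
#' @param sequences list of \linkS4class{ObservationSequence} sharing
#'   channels.
#' @param config a \linkS4class{FitConfig}.
#' @return list with \code{model} (the fitted \linkS4class{GaussianHMM}) and
#'   \code{report} (a \linkS4class{FitReport} holding the per-iteration
#'   log-likelihood trajectory).
#' @export
baumWelchFit <- function(init, sequences, config = fitConfig()) {
  .checkSharedGeometry(sequences)
  if (any(vapply(sequences, function(s) ncol(s@values), integer(1)) != init@d))
    stop("sequence dimension does not match the model", call. = FALSE)
  X <- .pooledSamples(sequences)
  floorVal <- .covFloorValue(X, config@covFloorScale)
  pooledCov <- .floorCovariance(crossprod(sweep(X, 2L, colMeans(X))) / nrow(X),
                                floorVal)
  K <- length(init@chain@pi); J <- length(init@emissions[[1]]@weights)
  d <- init@d
  model <- init
  traj <- numeric(0)
  converged <- FALSE
  nRun <- 0L

  for (iter in seq_len(config@nIter)) {
    acc <- .accumulateEStep(model, sequences)
    if (!is.finite(acc$loglik))
      stop(sprintf("log-likelihood became non-finite at EM iteration %d", iter),
           call. = FALSE)
    traj <- c(traj, acc$loglik)
    nRun <- iter
    if (config@tol > 0 && iter > 1L &&
        (acc$loglik - traj[iter - 1L]) < config@tol) {
      converged <- TRUE
      break
    }

    # --- M-step ---
    pi_new <- acc$piAcc / length(sequences)
    pi_new <- pi_new / sum(pi_new)
    A_new <- model@chain@A
    rs <- rowSums(acc$xiAcc)
    for (k in seq_len(K)) if (rs[k] > 0) A_new[k, ] <- acc$xiAcc[k, ] / rs[k]

    emissions <- vector("list", K)
    for (k in seq_len(K)) {
      means <- matrix(NA_real_, J, d)
      covs <- array(0, c(d, d, J))
      Wk <- acc$W[k, ]
      for (j in seq_len(J)) {
        if (Wk[j] < 1e-10) {
          warning(sprintf(
            "component %d of state %d starved at iteration %d; re-seeding",
            j, k, iter), call. = FALSE)
          means[j, ] <- acc$worst$x
          covs[, , j] <- pooledCov
          Wk[j] <- 1e-3 * sum(Wk)
        } else {
          mu <- acc$Sx[k, j, ] / Wk[j]
          S <- matrix(acc$Sxx[k, j, , ], d, d) / Wk[j] - tcrossprod(mu)
          means[j, ] <- mu
          covs[, , j] <- .floorCovariance(S, floorVal)
        }
      }
      w <- Wk / sum(Wk)
      emissions[[k]] <- gaussMixEmission(w, means, covs)
    }
    if (anyNA(pi_new) || anyNA(A_new) ||
        any(vapply(emissions, function(e) anyNA(e@means), logical(1))))
      stop(sprintf("NaN parameter at EM iteration %d", iter), call. = FALSE)
    model <- gaussianHMM(markovChain(A_new, pi_new), emissions)
  }

  report <- new("FitReport", loglikTrajectory = traj, nIterRun = nRun,
                convergedByTol = converged)
  list(model = model, report = report)
}
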