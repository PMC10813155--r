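# Builders for small random models and sequences used across test files.

randomSimplex <- function(n) {
  x <- stats::runif(n, 0.1, 1)
  x / sum(x)
}

randomChain <- function(K) {
  A <- t(vapply(seq_len(K), function(i) randomSimplex(K), numeric(K)))
  markovChain(matrix(A, K, K), randomSimplex(K))
}

randomGaussianHMM <- function(K = 2L, J = 1L, d = 1L) {
  ems <- lapply(seq_len(K), function(k) {
    means <- matrix(stats::rnorm(J * d, sd = 3), J, d)
    covs <- array(0, c(d, d, J))
    for (j in seq_len(J)) {
      L <- matrix(stats::rnorm(d * d, sd = 0.5), d, d)
      covs[, , j] <- crossprod(L) + diag(0.5, d)
    }
    gaussMixEmission(randomSimplex(J), means, covs)
  })
  gaussianHMM(randomChain(K), ems)
}

randomSeq <- function(n, d = 1L, rate = 100) {
  observationSequence(matrix(stats::rnorm(n * d), n, d), rate,
                      c("ML", "AP")[seq_len(d)])
}

stdNormalModel <- function() {
  gaussianHMM(markovChain(matrix(1, 1, 1), 1),
              list(gaussMixEmission(1, 0, 1)))
}

# Enumeration-based state posterior oracle: P(z_i = k | X) by summing
# normalized path joints over all paths through (i, k).
enumGamma <- function(model, seq) {
  logB <- logEmissionMatrix(model, seq)
  K <- nStates(model); n <- nrow(logB)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  lp <- copHMM:::.pathLogJoints(logB, initialProbs(model),
                                transitionMatrix(model), paths)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  g <- matrix(0, n, K)
  for (i in seq_len(n)) for (k in seq_len(K))
    g[i, k] <- sum(w[paths[, i] == k])
  g
}

# Enumeration-based Viterbi oracle: best path and its log joint.
enumViterbi <- function(model, seq) {
  logB <- logEmissionMatrix(model, seq)
  K <- nStates(model); n <- nrow(logB)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  lp <- copHMM:::.pathLogJoints(logB, initialProbs(model),
                                transitionMatrix(model), paths)
  best <- which(lp == max(lp))
  list(paths = paths[best, , drop = FALSE], logJoint = max(lp))
}

# Tiny labeled cohort for classifier tests.
tinyCohort <- function(nH = 4L, nP = 4L, n = 300L, separation = 2, seed = 7L) {
  simulateCohort(cohortSimConfig(nHealthy = nH, nPd = nP,
                                 duration = n / 50, samplingRate = 50,
                                 separation = separation, seed = seed))
}
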