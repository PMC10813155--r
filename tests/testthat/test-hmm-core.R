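test_that("log emission density matches the Gaussian density and collapses degenerate mixtures", {
  m <- stdNormalModel()
  s <- observationSequence(0, 100, "ML")
  expect_equal(logEmissionMatrix(m, s)[1, 1], -0.5 * log(2 * pi), tolerance = 1e-12)

  # two identical components with equal weights = single component
  m2 <- gaussianHMM(markovChain(matrix(1, 1, 1), 1),
                    list(gaussMixEmission(c(0.5, 0.5), matrix(0, 2, 1),
                                          array(1, c(1, 1, 2)))))
  x <- observationSequence(c(-1.3, 0, 2.2), 100, "ML")
  expect_equal(logEmissionMatrix(m2, x), logEmissionMatrix(m, x), tolerance = 1e-12)

  # term-by-term brute-force mixture summation, d = 2, 2 states, 2 components
  set.seed(11)
  m3 <- randomGaussianHMM(K = 2L, J = 2L, d = 2L)
  s3 <- randomSeq(5, d = 2L)
  logB <- logEmissionMatrix(m3, s3)
  for (k in 1:2) {
    em <- emissions(m3)[[k]]
    for (i in 1:5) {
      dens <- 0
      for (j in 1:2) {
        S <- matrix(em@covariances[, , j], 2, 2)
        xc <- copValues(s3)[i, ] - em@means[j, ]
        dens <- dens + em@weights[j] *
          exp(-0.5 * drop(t(xc) %*% solve(S) %*% xc)) /
          (2 * pi * sqrt(det(S)))
      }
      expect_equal(logB[i, k], log(dens), tolerance = 1e-12)
    }
  }
})

test_that("emission evaluation rejects dimension mismatches and bad covariances", {
  m <- randomGaussianHMM(K = 2L, J = 1L, d = 2L)
  expect_error(logEmissionMatrix(m, randomSeq(5, d = 1L)), "dimension 1.*dimension 2")
  # a non-positive-definite covariance is rejected at model construction
  expect_error(gaussMixEmission(1, matrix(0, 1, 2),
                                array(c(1, 2, 2, 1), c(2, 2, 1))),
               "positive definite")
  # and by the density evaluator itself when validity is bypassed
  bad <- stdNormalModel()
  bad@emissions[[1]]@covariances[1, 1, 1] <- -1
  expect_error(logEmissionMatrix(bad, randomSeq(4)), "positive definite")
})

test_that("forward log-likelihood reduces to i.i.d. forms in degenerate models", {
  m <- stdNormalModel()
  s <- observationSequence(c(0, 0), 100, "ML")
  expect_equal(forwardLogLik(m, s), -log(2 * pi), tolerance = 1e-12)

  # shared emissions across states make the transition matrix irrelevant
  set.seed(21)
  em <- gaussMixEmission(1, 0.7, 1.3)
  x <- randomSeq(12)
  iid <- sum(stats::dnorm(copValues(x), 0.7, sqrt(1.3), log = TRUE))
  for (r in 1:20) {
    K <- sample(2:3, 1)
    mshared <- gaussianHMM(randomChain(K), rep(list(em), K))
    expect_equal(forwardLogLik(mshared, x), iid, tolerance = 1e-10)
  }
})

test_that("forward recursion agrees with path enumeration on random instances", {
  set.seed(31)
  for (r in 1:50) {
    K <- sample(1:3, 1); n <- sample(2:8, 1); d <- sample(1:2, 1)
    m <- randomGaussianHMM(K, J = sample(1:2, 1), d = d)
    s <- randomSeq(n, d)
    bf <- bruteForceLogLik(m, s)
    expect_equal(forwardLogLik(m, s), bf, tolerance = 1e-8)
    expect_equal(forwardLogLik(m, s, method = "logspace"), bf, tolerance = 1e-10)
  }
})

test_that("forward evaluation rejects empty and NaN input", {
  m <- stdNormalModel()
  expect_error(forwardLogLik(m, numeric(0)), "empty")
  expect_error(forwardLogLik(m, c(0, NaN)), "NaN|non-finite")
})

test_that("discrete-HMM forward matches enumeration and handles symbol contracts", {
  set.seed(41)
  for (r in 1:10) {
    K <- sample(1:3, 1); M <- sample(2:4, 1); n <- sample(2:6, 1)
    B <- t(vapply(seq_len(K), function(i) randomSimplex(M), numeric(M)))
    dm <- discreteHMM(randomChain(K), matrix(B, K, M))
    x <- sample.int(M, n, replace = TRUE)
    expect_equal(forwardLogLik(dm, x), bruteForceLogLik(dm, x), tolerance = 1e-10)
  }
  dm <- discreteHMM(randomChain(2), matrix(0.5, 2, 2))
  expect_error(forwardLogLik(dm, c(1L, 3L)), "symbols must lie in 1..2")
})

test_that("forward-backward posteriors satisfy normalization and match enumeration", {
  # single state: gamma identically one
  ps <- forwardBackward(stdNormalModel(), randomSeq(10))
  expect_equal(statePosteriors(ps), matrix(1, 10, 1))

  # symmetric two-state model: gamma = 0.5 everywhere
  em <- gaussMixEmission(1, 0, 1)
  sym <- gaussianHMM(markovChain(matrix(0.5, 2, 2), c(0.5, 0.5)),
                     list(em, em))
  ps <- forwardBackward(sym, randomSeq(8))
  expect_equal(statePosteriors(ps), matrix(0.5, 8, 2), tolerance = 1e-12)

  set.seed(51)
  for (r in 1:20) {
    K <- sample(2:3, 1); n <- sample(3:7, 1); J <- sample(1:2, 1)
    m <- randomGaussianHMM(K, J, d = 1L)
    s <- randomSeq(n)
    ps <- forwardBackward(m, s)
    expect_true(validObject(ps))
    expect_equal(logLik(ps), forwardLogLik(m, s), tolerance = 1e-10)
    expect_equal(max(abs(rowSums(statePosteriors(ps)) - 1)), 0, tolerance = 1e-10)
    expect_equal(sum(transitionCounts(ps)), n - 1, tolerance = 1e-8)
    expect_equal(statePosteriors(ps), enumGamma(m, s), tolerance = 1e-8)
  }
})

test_that("Viterbi decoding is optimal, tie-broken to the lower state, and bounded by the likelihood", {
  # deterministic chain pinned to state 1
  m <- gaussianHMM(markovChain(diag(2), c(1, 0)),
                   list(gaussMixEmission(1, -5, 1), gaussMixEmission(1, 5, 1)))
  s <- observationSequence(c(5, 5, 5), 100, "ML")  # emissions favor state 2
  v <- viterbiDecode(m, s)
  expect_equal(v$path, rep(1L, 3))

  set.seed(61)
  for (r in 1:50) {
    K <- sample(1:2, 1); n <- sample(2:6, 1)
    m <- randomGaussianHMM(K, J = 1L, d = 1L)
    s <- randomSeq(n)
    v <- viterbiDecode(m, s)
    o <- enumViterbi(m, s)
    expect_equal(v$logJoint, o$logJoint, tolerance = 1e-9)
    expect_true(v$logJoint <= forwardLogLik(m, s) + 1e-10)
    # the returned path must be among the enumerated argmax paths
    hit <- any(apply(o$paths, 1L, function(p) all(p == v$path)))
    expect_true(hit)
  }

  # exact tie: identical emissions and symmetric chain; lower state must win
  em <- gaussMixEmission(1, 0, 1)
  sym <- gaussianHMM(markovChain(matrix(0.5, 2, 2), c(0.5, 0.5)), list(em, em))
  expect_equal(viterbiDecode(sym, randomSeq(5))$path, rep(1L, 5))
})

test_that("sampled sequences are reproducible and match model statistics", {
  m <- stdNormalModel()
  a <- sampleSequence(m, 50, seed = 9L)
  b <- sampleSequence(m, 50, seed = 9L)
  expect_identical(copValues(a$seq), copValues(b$seq))
  expect_identical(a$states, b$states)
  expect_error(sampleSequence(m, 0, seed = 1L), "positive")

  big <- sampleSequence(m, 10000, seed = 10L)
  expect_lt(abs(mean(copValues(big$seq))), 4 / sqrt(10000))

  # 3-state occupancy vs stationary distribution of A (eigen-decomposition)
  set.seed(71)
  m3 <- randomGaussianHMM(K = 3L, J = 1L, d = 1L)
  draw <- sampleSequence(m3, 50000, seed = 12L)
  occ <- tabulate(draw$states, 3L) / 50000
  stat <- copHMM:::.stationaryDistribution(transitionMatrix(m3))
  expect_lt(max(abs(occ - stat)), 0.02)
})

test_that("brute-force oracle guards exponential instances and handles n = 1", {
  m <- randomGaussianHMM(K = 3L, J = 1L, d = 1L)
  expect_error(bruteForceLogLik(m, randomSeq(20)), "guard")
  s1 <- randomSeq(1)
  closed <- log(sum(initialProbs(m) * exp(logEmissionMatrix(m, s1)[1, ])))
  expect_equal(bruteForceLogLik(m, s1), closed, tolerance = 1e-12)
  expect_equal(forwardLogLik(m, s1), closed, tolerance = 1e-12)
})

test_that("likelihood of a 60,000-sample recording is finite (no underflow)", {
  m <- makeGroundTruthModels(1, seed = 3L)$healthy
  s <- sampleSequence(m, 60000, seed = 4L)$seq
  ll <- forwardLogLik(m, s)
  expect_true(is.finite(ll))
  ps <- forwardBackward(m, s)
  expect_true(is.finite(logLik(ps)))
  expect_equal(logLik(ps), ll, tolerance = 1e-10)
})

test_that("higher-order chains are representable but rejected by inference", {
  ch <- markovChain(matrix(1, 1, 1), 1, order = 2L)
  m <- new("GaussianHMM", chain = markovChain(matrix(1, 1, 1), 1),
           d = 1L, emissions = list(gaussMixEmission(1, 0, 1)))
  m@chain@order <- 2L
  expect_error(forwardLogLik(m, randomSeq(3)), "first-order")
  expect_error(viterbiDecode(m, randomSeq(3)), "first-order")
  expect_equal(ch@order, 2L)
})
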