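test_that("K-means initialisation recovers pooled moments and separated clusters", {
  set.seed(101)
  seqs <- list(randomSeq(200), randomSeq(150))
  X <- rbind(copValues(seqs[[1]]), copValues(seqs[[2]]))

  # one state, one component: pooled mean and 1/n covariance
  cfg <- fitConfig(nStates = 1L, nComponents = 1L)
  m <- kmeansInit(seqs, cfg)
  em <- emissions(m)[[1]]
  expect_equal(as.numeric(em@means), mean(X), tolerance = 1e-12)
  expect_equal(as.numeric(em@covariances),
               mean((X - mean(X))^2), tolerance = 1e-10)

  # two well-separated clusters at 0 and 100
  set.seed(102)
  x <- c(rnorm(500, 0), rnorm(500, 100))
  s <- observationSequence(sample(x), 100, "ML")
  m2 <- kmeansInit(list(s), fitConfig(nStates = 2L, nComponents = 1L))
  mus <- sort(vapply(emissions(m2), function(e) e@means[1, 1], numeric(1)))
  expect_lt(abs(mus[1] - 0), 0.5)
  expect_lt(abs(mus[2] - 100), 0.5)

  # determinism and uniform chain initialisation
  m3 <- kmeansInit(seqs, fitConfig(seed = 5L))
  m4 <- kmeansInit(seqs, fitConfig(seed = 5L))
  expect_equal(m3, m4)
  expect_equal(initialProbs(m3), rep(1 / 3, 3))
  expect_equal(transitionMatrix(m3), matrix(1 / 3, 3, 3))

  expect_error(kmeansInit(list(randomSeq(4)), fitConfig(nStates = 3L, nComponents = 2L)),
               "at least 6")
})

test_that("single-Gaussian M-step reproduces the weighted closed forms", {
  s <- observationSequence(c(0, 2), 100, "ML")
  ps <- new("PosteriorSet", gamma = matrix(0.5, 2, 2),
            xiSum = matrix(0.25, 2, 2),
            compGamma = array(0.5, c(2, 2, 1)), loglik = 0)
  up <- mStepSingleGaussian(ps, s, 1L)
  expect_equal(as.numeric(up$mu), 1)
  expect_equal(as.numeric(up$Sigma), 1)

  # unit weights give the plain MLE (1/n covariance)
  x <- randomSeq(50)
  ps1 <- forwardBackward(stdNormalModel(), x)
  up1 <- mStepSingleGaussian(ps1, x, 1L)
  v <- copValues(x)
  expect_equal(as.numeric(up1$mu), mean(v), tolerance = 1e-12)
  expect_equal(as.numeric(up1$Sigma), mean((v - mean(v))^2), tolerance = 1e-12)

  # degenerate weighting picks out one observation exactly
  g <- matrix(c(1, 0, 0, 1), 2, 2)
  ps2 <- new("PosteriorSet", gamma = g, xiSum = matrix(c(0,0,1,0),2,2),
             compGamma = array(g, c(2, 2, 1)), loglik = 0)
  up2 <- mStepSingleGaussian(ps2, s, 1L)
  expect_equal(as.numeric(up2$mu), 0)

  # starved state errors
  g3 <- cbind(rep(1, 2), rep(0, 2))
  ps3 <- new("PosteriorSet", gamma = g3, xiSum = matrix(c(1,0,0,0),2,2),
             compGamma = array(g3, c(2, 2, 1)), loglik = 0)
  expect_error(mStepSingleGaussian(ps3, s, 2L), "starved")
})

test_that("single-state EM reproduces the closed-form Gaussian MLE in one iteration", {
  set.seed(111)
  s <- randomSeq(400)
  cfg <- fitConfig(nStates = 1L, nComponents = 1L, nIter = 1L)
  fit <- baumWelchFit(kmeansInit(list(s), cfg), list(s), cfg)
  em <- emissions(fit$model)[[1]]
  v <- copValues(s)
  expect_equal(as.numeric(em@means), mean(v), tolerance = 1e-10)
  expect_equal(as.numeric(em@covariances), mean((v - mean(v))^2),
               tolerance = 1e-8)
})

test_that("EM runs the configured number of iterations and stays near a fixed point on model data", {
  set.seed(121)
  truth <- randomGaussianHMM(K = 2L, J = 1L, d = 1L)
  s <- sampleSequence(truth, 5000, seed = 13L)$seq
  cfg <- fitConfig(nStates = 2L, nComponents = 1L)
  fit <- baumWelchFit(truth, list(s), cfg)
  traj <- loglikTrajectory(fit$report)
  expect_length(traj, 15L)                 # tol = 0 runs all iterations
  expect_identical(fit$report@nIterRun, 15L)
  expect_false(fit$report@convergedByTol)
  expect_true(all(diff(traj) >= -1e-6 * abs(traj[-length(traj)])))
  # starting at the generator, the total gain is small relative to |loglik|
  expect_lt((traj[15] - traj[1]) / abs(traj[1]), 0.01)

  # a positive tolerance stops early near the fixed point
  fit2 <- baumWelchFit(truth, list(s), fitConfig(nStates = 2L, nComponents = 1L,
                                                 nIter = 15L, tol = 1))
  expect_true(fit2$report@convergedByTol)
  expect_lt(fit2$report@nIterRun, 15L)
})

test_that("EM log-likelihood is monotone and parameters stay stochastic across random seeds", {
  for (seed in 1:20) {
    set.seed(seed)
    truth <- randomGaussianHMM(K = 2L, J = 1L, d = 1L)
    seqs <- lapply(1:2, function(i)
      sampleSequence(truth, 150, seed = 100L * seed + i)$seq)
    cfg <- fitConfig(nStates = 2L, nComponents = 2L, nIter = 8L, seed = seed)
    fit <- baumWelchFit(kmeansInit(seqs, cfg), seqs, cfg)
    traj <- loglikTrajectory(fit$report)
    expect_true(all(diff(traj) >= -1e-6 * abs(traj[-length(traj)])),
                info = sprintf("seed %d", seed))
    m <- fit$model
    expect_equal(sum(initialProbs(m)), 1, tolerance = 1e-10)
    expect_equal(rowSums(transitionMatrix(m)), rep(1, 2), tolerance = 1e-10)
    floorVal <- copHMM:::.covFloorValue(
      do.call(rbind, lapply(seqs, copValues)), cfg@covFloorScale)
    for (em in emissions(m)) {
      expect_equal(sum(em@weights), 1, tolerance = 1e-10)
      for (j in seq_along(em@weights)) {
        S <- matrix(em@covariances[, , j], 1, 1)
        expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
                   floorVal * (1 - 1e-8))
      }
    }
  }
})

test_that("EM recovers a well-separated 3-state bivariate generator up to permutation", {
  trueMeans <- rbind(c(10, 0), c(-8, 8), c(0, -10))
  A <- matrix(c(0.90, 0.05, 0.05,
                0.08, 0.90, 0.02,
                0.05, 0.05, 0.90), 3, 3, byrow = TRUE)
  ems <- lapply(1:3, function(k)
    gaussMixEmission(1, matrix(trueMeans[k, ], 1), array(diag(2), c(2, 2, 1))))
  truth <- gaussianHMM(markovChain(A, rep(1 / 3, 3)), ems)
  seqs <- lapply(1:20, function(i) sampleSequence(truth, 2000, seed = 200L + i)$seq)
  cfg <- fitConfig(nStates = 3L, nComponents = 1L, nIter = 15L, seed = 2L)
  fit <- baumWelchFit(kmeansInit(seqs, cfg), seqs, cfg)

  estMeans <- t(vapply(emissions(fit$model), function(e) e@means[1, ], numeric(2)))
  perms <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  cost <- apply(perms, 1L, function(p) sum((estMeans[p, ] - trueMeans)^2))
  p <- perms[which.min(cost), ]
  for (k in 1:3) {
    relErr <- sqrt(sum((estMeans[p[k], ] - trueMeans[k, ])^2)) /
      sqrt(sum(trueMeans[k, ]^2))
    expect_lt(relErr, 0.10)
  }
  estA <- transitionMatrix(fit$model)[p, p]
  expect_lt(max(abs(estA - A)), 0.1)
})
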