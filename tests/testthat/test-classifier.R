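test_that("channel selection returns the named columns in fixed order", {
  x <- matrix(rnorm(20), 10, 2)
  s <- observationSequence(x, 100, c("AP", "ML"))  # reversed on purpose
  ml <- selectChannels(s, "ML")
  expect_equal(channels(ml), "ML")
  expect_equal(copValues(ml), x[, 2, drop = FALSE])
  both <- selectChannels(s, "MLAP")
  expect_equal(channels(both), c("ML", "AP"))
  expect_equal(copValues(both), x[, c(2, 1)])

  mlOnly <- observationSequence(x[, 1], 100, "ML")
  expect_error(selectChannels(mlOnly, "AP"), "available: ML")
})

test_that("metrics follow the healthy-positive convention and reproduce the worked confusion table", {
  # 28 healthy all correct; 1 of 32 PD misclassified
  cc <- confusionCounts(hPredH = 28L, hPredPd = 0L, pdPredH = 1L, pdPredPd = 31L)
  m <- computeMetrics(cc)
  expect_equal(m[["sensitivity"]], 100)
  expect_equal(m[["specificity"]], 100 * 31 / 32)   # 96.875
  expect_equal(m[["accuracy"]], 100 * 59 / 60)      # 98.333...

  expect_equal(unname(computeMetrics(confusionCounts(10L, 0L, 0L, 12L))),
               c(100, 100, 100))
  expect_equal(unname(computeMetrics(confusionCounts(0L, 10L, 12L, 0L))),
               c(0, 0, 0))
  expect_error(computeMetrics(confusionCounts(0L, 0L, 3L, 4L)), "nonempty")
})

test_that("confusion counts enforce their marginals", {
  expect_error(new("ConfusionCounts", nHealthy = 3L, nPd = 2L, hPredH = 1L,
                   hPredPd = 1L, pdPredH = 1L, pdPredPd = 1L),
               "total nHealthy")
})

test_that("training is deterministic and symmetric given identical inputs", {
  sim <- tinyCohort()
  cfg <- fitConfig(nStates = 2L, nComponents = 1L, nIter = 3L, seed = 3L)
  same <- trainClassifier(sim$healthy, sim$healthy, config = cfg)
  expect_equal(same@hModels, same@pdModels)

  a <- trainClassifier(sim$healthy, sim$pd, config = cfg)
  b <- trainClassifier(sim$healthy, sim$pd, config = cfg)
  expect_equal(a@hModels, b@hModels)
  expect_equal(a@pdModels, b@pdModels)
  expect_identical(a@fitConfig@nStates, 2L)
  expect_error(trainClassifier(list(), sim$pd, config = cfg), "nonempty")
})

test_that("default classifier settings are 3 states, 2 mixtures, 15 iterations, k = 10", {
  cfg <- fitConfig()
  expect_identical(cfg@nStates, 3L)
  expect_identical(cfg@nComponents, 2L)
  expect_identical(cfg@nIter, 15L)
  expect_identical(cfg@tol, 0)
  expect_identical(formals(kfoldCrossValidate)$k, 10L)
})

test_that("held-out sequences score higher under their own class model", {
  sim <- tinyCohort(nH = 5L, nP = 5L, n = 400L, separation = 2)
  cfg <- fitConfig(nStates = 2L, nComponents = 1L, nIter = 5L)
  cls <- trainClassifier(sim$healthy[1:4], sim$pd[1:4], config = cfg)
  rH <- classifySubject(cls, sim$healthy[[5]])
  rP <- classifySubject(cls, sim$pd[[5]])
  expect_gt(rH$loglikH, rH$loglikPD)
  expect_equal(rH$label, "healthy")
  expect_gt(rP$loglikPD, rP$loglikH)
  expect_equal(rP$label, "pd")

  # generator-identity check: a sequence sampled from the H-HMM itself
  own <- sampleSequence(cls@hModels[[1]], 400, seed = 44L)$seq
  expect_equal(classifySubject(cls, own)$label, "healthy")
})

test_that("exact likelihood ties are resolved to PD", {
  sim <- tinyCohort(nH = 3L, nP = 3L)
  cfg <- fitConfig(nStates = 1L, nComponents = 1L, nIter = 1L)
  cls <- trainClassifier(sim$healthy, sim$healthy, config = cfg)  # identical models
  r <- classifySubject(cls, sim$healthy[[1]])
  expect_equal(r$loglikH, r$loglikPD)
  expect_equal(r$label, "pd")
})

test_that("loglik-sum fusion trains per-channel models and classifies", {
  sim <- tinyCohort(nH = 3L, nP = 3L, n = 200L)
  cfg <- fitConfig(nStates = 2L, nComponents = 1L, nIter = 2L)
  cls <- trainClassifier(sim$healthy, sim$pd, config = cfg, fusion = "loglik_sum")
  expect_length(cls@hModels, 2L)
  expect_equal(obsDim(cls@hModels[[1]]), 1L)
  r <- classifySubject(cls, sim$pd[[1]])
  expect_true(r$label %in% c("healthy", "pd"))
})

test_that("stratified k-fold CV is deterministic, stratified, and supports leave-one-out", {
  sim <- tinyCohort(nH = 6L, nP = 6L, n = 250L, separation = 2)
  cfg <- fitConfig(nStates = 2L, nComponents = 1L, nIter = 3L)
  cv1 <- kfoldCrossValidate(sim, k = 3L, config = cfg, seed = 11L)
  cv2 <- kfoldCrossValidate(sim, k = 3L, config = cfg, seed = 11L)
  expect_identical(foldAssignments(cv1), foldAssignments(cv2))
  expect_equal(cvMetrics(cv1), cvMetrics(cv2))

  # stratification: each fold holds 2 healthy + 2 pd
  f <- foldAssignments(cv1)
  ids <- names(f)
  isH <- seq_along(f) <= 6
  expect_true(all(table(f[isH]) == 2))
  expect_true(all(table(f[!isH]) == 2))
  expect_true(validObject(cv1))

  # leave-one-out: every fold holds exactly one subject
  loo <- kfoldCrossValidate(sim, k = 12L, config = cfg, seed = 11L)
  expect_true(all(table(foldAssignments(loo)) == 1))

  expect_error(kfoldCrossValidate(sim, k = 13L, config = cfg), "exceeds")
})

test_that("a fold that would empty a training class is rejected with advice", {
  sim <- tinyCohort(nH = 1L, nP = 5L, n = 150L)
  expect_error(kfoldCrossValidate(sim, k = 2L,
                                  config = fitConfig(nStates = 1L, nComponents = 1L, nIter = 1L)),
               "smaller k")
})

test_that("metrics identity: CVResult fields always match its pooled counts", {
  sim <- tinyCohort(nH = 4L, nP = 4L, n = 200L, separation = 1)
  cv <- kfoldCrossValidate(sim, k = 2L,
                           config = fitConfig(nStates = 2L, nComponents = 1L, nIter = 2L))
  m <- computeMetrics(pooledConfusion(cv))
  expect_equal(cv@sensitivity, m[["sensitivity"]])
  expect_equal(cv@specificity, m[["specificity"]])
  expect_equal(cv@accuracy, m[["accuracy"]])
  p <- pooledConfusion(cv)
  expect_identical(p@nHealthy, 4L)
  expect_identical(p@nPd, 4L)
})

test_that("the sweep shares folds with a direct CV call and reports the grid shape", {
  sim <- tinyCohort(nH = 4L, nP = 4L, n = 200L, separation = 2)
  cfg <- fitConfig(nStates = 2L, nComponents = 1L, nIter = 2L)
  tab <- hyperparameterSweep(sim, states = 2L, mixtures = 1L, k = 2L,
                             config = cfg, seed = 6L)
  expect_equal(nrow(tab), 1L)
  direct <- kfoldCrossValidate(sim, k = 2L, config = cfg, seed = 6L)
  expect_equal(tab$accuracy, direct@accuracy)
  expect_equal(tab$sensitivity, direct@sensitivity)

  tab2 <- hyperparameterSweep(sim, states = 2:3, mixtures = 1:2, k = 2L,
                              config = fitConfig(nIter = 2L), seed = 6L)
  expect_equal(nrow(tab2), 4L)
  expect_equal(sort(unique(tab2$n_states)), 2:3)

  # failing cells (more clusters than training samples) yield NA; sweep continues
  tab3 <- suppressWarnings(
    hyperparameterSweep(sim, states = c(2000L, 2L), mixtures = 1L, k = 2L,
                        config = fitConfig(nIter = 2L), seed = 6L))
  expect_true(is.na(tab3$accuracy[1]))
  expect_false(is.na(tab3$accuracy[2]))
})

test_that("confusion rendering follows the report layout", {
  sim <- tinyCohort(nH = 4L, nP = 4L, n = 200L, separation = 2)
  cv <- kfoldCrossValidate(sim, k = 2L,
                           config = fitConfig(nStates = 2L, nComponents = 1L, nIter = 2L))
  lines <- formatConfusionTable(cv)
  expect_length(lines, 3L)
  expect_match(lines[1], "Subjects\\s+Predicted H\\s+Predicted PD")
  expect_match(lines[2], "^Healthy")
  expect_match(lines[3], "^PD")
})
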