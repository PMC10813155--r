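#' @include classifier.R
NULL

#' Ground-truth generator pair for a synthetic cohort
#'
#' Builds two 3-state bivariate Gaussian HMMs with identical topology that
#' play the role of the healthy and PD sway generators. The PD model differs
#' from the healthy one by an amount proportional to \code{separation}:
#' its state means are displaced, its per-state sway variance inflated, and
#' its state dwell times shortened (faster regime switching), qualitatively
#' mirroring the larger, faster sway of impaired postural control.
#' \code{separation = 0} returns two identical models. The seed jitters the
#' displacement directions so different seeds give different (but equally
#' separated) cohorts.
#'
#' @param separation nonnegative scale of the class difference.
#' @param seed RNG seed.
#' @return list with \code{healthy} and \code{pd}, both
#'   \linkS4class{GaussianHMM}.
#' @export
makeGroundTruthModels <- function(separation = 1, seed = 1L) {
  if (separation < 0) stop("separation must be nonnegative", call. = FALSE)
  baseMeans <- rbind(c(0, 0), c(2.5, 1.5), c(-2, 2.5))   # mm, per state
  baseVar <- c(1.0, 1.4, 1.8)                            # mm^2 sway variance
  baseCor <- 0.2
  stay <- 0.98                                           # ~0.5 s dwell at 100 Hz

  mkChain <- function(stayProb) {
    K <- 3L
    A <- matrix((1 - stayProb) / (K - 1), K, K)
    diag(A) <- stayProb
    markovChain(A, rep(1 / K, K))
  }
  mkModel <- function(means, vars, corr, stayProb) {
    ems <- lapply(seq_len(3L), function(k) {
      S <- vars[k] * matrix(c(1, corr, corr, 1), 2, 2)
      gaussMixEmission(1, matrix(means[k, ], 1L), array(S, c(2, 2, 1)))
    })
    gaussianHMM(mkChain(stayProb), ems)
  }

  dir <- .withSeed(seed, {
    ang <- stats::runif(3L, 0, 2 * pi)
    cbind(cos(ang), sin(ang))
  })
  healthy <- mkModel(baseMeans, baseVar, baseCor, stay)
  pdMeans <- baseMeans + separation * 3 * dir            # mm displacement
  pdVar <- baseVar * (1 + 0.8 * separation)              # larger sway
  pdStay <- 1 - min((1 - stay) * (1 + 1.5 * separation), 0.5)  # faster switching
  pd <- mkModel(pdMeans, pdVar, baseCor, pdStay)
  list(healthy = healthy, pd = pd)
}

.ar2Stable <- function(phi1, phi2) {
  # stationarity triangle for AR(2)
  (phi2 > -1) && (phi1 + phi2 < 1) && (phi2 - phi1 < 1)
}

.simulateAR2 <- function(n, phi1, phi2, sdNoise) {
  if (!.ar2Stable(phi1, phi2))
    stop(sprintf("unstable AR(2) coefficients (phi1=%.3f, phi2=%.3f)",
                 phi1, phi2), call. = FALSE)
  as.numeric(stats::arima.sim(list(ar = c(phi1, phi2)), n = n,
                              sd = sdNoise))
}

#' Simulate a synthetic COP cohort with known ground truth
#'
#' Generates \code{nHealthy + nPd} two-channel quiet-standing recordings.
#' In \code{"hmm"} mode each subject is sampled from the class's
#' ground-truth HMM (\code{\link{makeGroundTruthModels}}); the hidden state
#' paths are returned for recovery tests. In \code{"ar2"} mode each channel
#' is a stable AR(2) process whose coefficients and innovation variance are
#' displaced between classes in proportion to \code{separation} (PD: less
#' damped, noisier sway). Everything is reproducible from the config seed.
#'
#' @param config a \linkS4class{CohortSimConfig}.
#' @return list with \code{manifest} (a \linkS4class{CohortManifest} with
#'   \code{NA} paths until written), \code{healthy} and \code{pd} (lists of
#'   labeled \linkS4class{ObservationSequence}), \code{truth} (the generator
#'   models for hmm mode, AR coefficients for ar2 mode) and \code{states}
#'   (per-subject hidden paths, hmm mode only).
#' @export
simulateCohort <- function(config = cohortSimConfig()) {
  validObject(config)
  n <- as.integer(round(config@duration * config@samplingRate))
  nTot <- config@nHealthy + config@nPd
  labels <- rep(c("healthy", "pd"), c(config@nHealthy, config@nPd))
  ids <- sprintf("S%03d", seq_len(nTot))

  truth <- NULL
  states <- NULL
  seqs <- vector("list", nTot)
  # per-subject seed stream; modulus keeps the products inside integer range
  subSeed <- function(i) (config@seed %% 1000000L) * 1000L + i
  if (config@mode == "hmm") {
    truth <- makeGroundTruthModels(config@separation, config@seed)
    states <- vector("list", nTot)
    for (i in seq_len(nTot)) {
      gen <- truth[[labels[i]]]
      draw <- sampleSequence(gen, n, seed = subSeed(i),
                             samplingRate = config@samplingRate,
                             subjectId = ids[i], label = labels[i])
      seqs[[i]] <- draw$seq
      states[[i]] <- draw$states
    }
  } else {
    s <- config@separation
    truth <- list(
      healthy = list(phi1 = 1.6, phi2 = -0.65, sd = c(ML = 0.30, AP = 0.40)),
      pd = list(phi1 = 1.6 + 0.15 * s, phi2 = -0.65 - 0.14 * s,
                sd = c(ML = 0.30 * (1 + 0.6 * s), AP = 0.40 * (1 + 0.6 * s))))
    for (cls in c("healthy", "pd")) {
      p <- truth[[cls]]
      if (!.ar2Stable(p$phi1, p$phi2))
        stop(sprintf("separation %.3g yields unstable AR(2) coefficients for the %s class",
                     s, cls), call. = FALSE)
    }
    for (i in seq_len(nTot)) {
      p <- truth[[labels[i]]]
      x <- .withSeed(subSeed(i),
                     cbind(ML = .simulateAR2(n, p$phi1, p$phi2, p$sd[["ML"]]),
                           AP = .simulateAR2(n, p$phi1, p$phi2, p$sd[["AP"]])))
      seqs[[i]] <- observationSequence(x, config@samplingRate, c("ML", "AP"),
                                       ids[i], labels[i])
    }
  }

  manifest <- cohortManifest(
    data.frame(subject_id = ids, path = NA_character_, label = labels,
               group = NA_character_, stringsAsFactors = FALSE),
    samplingRate = config@samplingRate, duration = config@duration)
  list(manifest = manifest,
       healthy = seqs[labels == "healthy"], pd = seqs[labels == "pd"],
       truth = truth, states = states)
}

#' Write a simulated cohort to disk
#'
#' Writes one COP CSV per subject plus \code{manifest.csv} into \code{dir}.
#'
#' @param sim result of \code{\link{simulateCohort}}.
#' @param dir output directory (created if needed).
#' @return path of the written manifest, invisibly.
#' @export
writeCohort <- function(sim, dir) {
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", dir, call. = FALSE)
  rec <- sim$manifest@records
  seqs <- c(sim$healthy, sim$pd)
  ids <- vapply(seqs, function(s) s@subjectId, character(1))
  for (i in seq_len(nrow(rec))) {
    s <- seqs[[match(rec$subject_id[i], ids)]]
    fname <- paste0(rec$subject_id[i], ".csv")
    writeCopFile(s, file.path(dir, fname))
    rec$path[i] <- fname
  }
  manifest <- cohortManifest(rec, sim$manifest@samplingRate,
                             sim$manifest@duration)
  writeManifest(manifest, file.path(dir, "manifest.csv"))
  invisible(file.path(dir, "manifest.csv"))
}
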