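#' @include learn.R cop-io.R
NULL

#' Select COP channels
#'
#' Restricts a recording to the requested channel(s): \code{"ML"} or
#' \code{"AP"} give a single-channel sequence, \code{"MLAP"} gives both
#' channels in the fixed order (ML, AP).
#'
#' @param seq an \linkS4class{ObservationSequence}.
#' @param mode \code{"ML"}, \code{"AP"} or \code{"MLAP"}.
#' @return an \linkS4class{ObservationSequence} with the selected columns.
#' @export
selectChannels <- function(seq, mode = c("MLAP", "ML", "AP")) {
  mode <- match.arg(mode)
  want <- switch(mode, ML = "ML", AP = "AP", MLAP = c("ML", "AP"))
  miss <- setdiff(want, seq@channels)
  if (length(miss) > 0L)
    stop(sprintf("channel(s) %s not present; available: %s",
                 paste(miss, collapse = ", "),
                 paste(seq@channels, collapse = ", ")), call. = FALSE)
  idx <- match(want, seq@channels)
  observationSequence(seq@values[, idx, drop = FALSE], seq@samplingRate,
                      want, seq@subjectId, seq@label)
}

# Channel views used for training/scoring: one d-dim view for bivariate or
# single-channel modes, one view per channel for log-likelihood-sum fusion.
.channelViews <- function(seq, channelMode, fusion, decimate, center) {
  modes <- if (channelMode == "MLAP" && fusion == "loglik_sum") c("ML", "AP")
           else channelMode
  lapply(modes, function(m)
    preprocessCop(selectChannels(seq, m), decimate, center))
}

#' Train the two-model healthy/PD classifier
#'
#' Trains one Gaussian-mixture HMM per class on the channel-selected,
#' preprocessed training recordings: a K-means initialisation followed by
#' Baum-Welch EM, run independently for the healthy and PD training sets with
#' the same configuration and seed. Under \code{channelMode = "MLAP"} the
#' default is a single bivariate model per class (full covariances capture
#' ML/AP correlation); \code{fusion = "loglik_sum"} instead trains one
#' single-channel model per channel per class and sums channel
#' log-likelihoods at classification time.
#'
#' @param healthy,pd lists of \linkS4class{ObservationSequence} for the two
#'   training classes.
#' @param channelMode \code{"ML"}, \code{"AP"} or \code{"MLAP"}.
#' @param config a \linkS4class{FitConfig}; the defaults (3 states, 2 mixture
#'   components, 15 iterations) are the classifier's standard settings.
#' @param fusion MLAP fusion strategy, see above.
#' @param decimate,center preprocessing applied before training and, later,
#'   classification (defaults: none).
#' @return a \linkS4class{ClassifierModel}.
#' @export
trainClassifier <- function(healthy, pd, channelMode = c("MLAP", "ML", "AP"),
                            config = fitConfig(),
                            fusion = c("bivariate", "loglik_sum"),
                            decimate = 1L, center = FALSE) {
  channelMode <- match.arg(channelMode)
  fusion <- match.arg(fusion)
  if (length(healthy) == 0L || length(pd) == 0L)
    stop("both training classes must be nonempty", call. = FALSE)
  fitClass <- function(seqs, what) {
    views <- lapply(seqs, .channelViews, channelMode = channelMode,
                    fusion = fusion, decimate = decimate, center = center)
    nviews <- length(views[[1L]])
    lapply(seq_len(nviews), function(v) {
      tr <- lapply(views, `[[`, v)
      tryCatch({
        init <- kmeansInit(tr, config)
        baumWelchFit(init, tr, config)$model
      }, error = function(e)
        stop(sprintf("fitting the %s model failed: %s", what,
                     conditionMessage(e)), call. = FALSE))
    })
  }
  hModels <- fitClass(healthy, "healthy (H-HMM)")
  pdModels <- fitClass(pd, "PD (PD-HMM)")
  new("ClassifierModel", hModels = hModels, pdModels = pdModels,
      channelMode = channelMode, fusion = fusion,
      decimate = as.integer(decimate), center = center, fitConfig = config)
}

#' Classify one subject by maximum model likelihood
#'
#' Evaluates the total observation log-likelihood of the recording under the
#' healthy and the PD model and assigns the class whose model scores
#' strictly higher; an exact tie is resolved to PD (the clinically
#' conservative call). Both log-likelihoods are returned for audit.
#'
#' @param model a trained \linkS4class{ClassifierModel}.
#' @param seq an \linkS4class{ObservationSequence} containing the channels
#'   the classifier was trained on.
#' @return list with \code{label} (\code{"healthy"} or \code{"pd"}),
#'   \code{loglikH} and \code{loglikPD}.
#' @export
classifySubject <- function(model, seq) {
  views <- .channelViews(seq, model@channelMode, model@fusion,
                         model@decimate, model@center)
  llH <- sum(mapply(function(m, v) forwardLogLik(m, v), model@hModels, views))
  llPD <- sum(mapply(function(m, v) forwardLogLik(m, v), model@pdModels, views))
  list(label = if (llH > llPD) "healthy" else "pd",
       loglikH = llH, loglikPD = llPD)
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' Healthy is the "positive" class: sensitivity is the percentage of healthy
#' subjects classified healthy, specificity the percentage of PD subjects
#' classified PD, accuracy the percentage of all subjects classified
#' correctly. (Note this is the reverse of the common clinical convention,
#' where the disease class is positive.)
#'
#' @param counts a \linkS4class{ConfusionCounts}.
#' @return named numeric vector \code{sensitivity}, \code{specificity},
#'   \code{accuracy}, in percent.
#' @export
computeMetrics <- function(counts) {
  validObject(counts)
  if (counts@nHealthy == 0L || counts@nPd == 0L)
    stop("both classes must be nonempty to compute metrics", call. = FALSE)
  c(sensitivity = 100 * counts@hPredH / counts@nHealthy,
    specificity = 100 * counts@pdPredPd / counts@nPd,
    accuracy = 100 * (counts@hPredH + counts@pdPredPd) /
      (counts@nHealthy + counts@nPd))
}

# Accept either list(healthy=, pd=) or a flat list of labeled sequences.
.splitCohort <- function(cohort) {
  if (is.list(cohort) && !is.null(cohort$healthy) && !is.null(cohort$pd))
    return(cohort[c("healthy", "pd")])
  labels <- vapply(cohort, function(s) s@label, character(1))
  if (anyNA(labels))
    stop("all sequences must carry a class label for cross-validation",
         call. = FALSE)
  list(healthy = cohort[labels == "healthy"], pd = cohort[labels == "pd"])
}

.subjectIds <- function(seqs, prefix) {
  ids <- vapply(seqs, function(s) s@subjectId, character(1))
  miss <- is.na(ids) | ids == "NA"
  ids[miss] <- paste0(prefix, which(miss))
  ids
}

#' Stratified k-fold cross-validation of the two-model classifier
#'
#' Assigns subjects to \code{k} folds stratified by class (seeded shuffle,
#' round-robin within class so class proportions are preserved per fold),
#' then for each fold trains the classifier on the remaining folds and
#' classifies the held-out subjects. The confusion counts are pooled over all
#' folds; \code{accuracySpread} is the sample standard deviation of the
#' per-fold accuracies.
#'
#' @param cohort either \code{list(healthy = ..., pd = ...)} or a flat list of
#'   labeled \linkS4class{ObservationSequence}.
#' @param k number of folds (default 10). \code{k} equal to the cohort size
#'   gives leave-one-out.
#' @param channelMode,config,fusion,decimate,center passed to
#'   \code{\link{trainClassifier}}.
#' @param seed fold-shuffle seed (defaults to the seed in \code{config}).
#' @return a \linkS4class{CVResult}.
#' @export
kfoldCrossValidate <- function(cohort, k = 10L,
                               channelMode = c("MLAP", "ML", "AP"),
                               config = fitConfig(),
                               fusion = c("bivariate", "loglik_sum"),
                               decimate = 1L, center = FALSE,
                               seed = config@seed) {
  channelMode <- match.arg(channelMode)
  fusion <- match.arg(fusion)
  k <- as.integer(k)
  parts <- .splitCohort(cohort)
  nH <- length(parts$healthy); nP <- length(parts$pd)
  if (nH == 0L || nP == 0L)
    stop("cohort must contain both classes", call. = FALSE)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (k > nH + nP) stop("k exceeds the cohort size", call. = FALSE)

  idsH <- .subjectIds(parts$healthy, "H")
  idsP <- .subjectIds(parts$pd, "PD")
  # stratified, seeded: shuffle within class, then deal fold labels round-robin
  # across the whole cohort (healthy first) so folds stay globally balanced
  deal <- rep_len(seq_len(k), nH + nP)
  foldsH <- .withSeed(seed, { f <- integer(nH); f[sample(nH)] <- deal[seq_len(nH)]; f })
  foldsP <- .withSeed(seed + 1L, { f <- integer(nP); f[sample(nP)] <- deal[nH + seq_len(nP)]; f })

  for (f in seq_len(k)) {
    if (sum(foldsH != f) == 0L || sum(foldsP != f) == 0L)
      stop(sprintf("fold %d leaves a training class empty; use a smaller k", f),
           call. = FALSE)
  }

  predH <- character(nH); predP <- character(nP)
  perFoldAcc <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    holdH <- which(foldsH == f); holdP <- which(foldsP == f)
    if (length(holdH) + length(holdP) == 0L) next
    cls <- trainClassifier(parts$healthy[foldsH != f], parts$pd[foldsP != f],
                           channelMode = channelMode, config = config,
                           fusion = fusion, decimate = decimate, center = center)
    for (i in holdH) predH[i] <- classifySubject(cls, parts$healthy[[i]])$label
    for (i in holdP) predP[i] <- classifySubject(cls, parts$pd[[i]])$label
    correct <- sum(predH[holdH] == "healthy") + sum(predP[holdP] == "pd")
    perFoldAcc[f] <- 100 * correct / (length(holdH) + length(holdP))
  }
  perFoldAcc <- perFoldAcc[!is.na(perFoldAcc)]

  pooled <- confusionCounts(hPredH = sum(predH == "healthy"),
                            hPredPd = sum(predH == "pd"),
                            pdPredH = sum(predP == "healthy"),
                            pdPredPd = sum(predP == "pd"))
  m <- computeMetrics(pooled)
  folds <- c(foldsH, foldsP)
  names(folds) <- c(idsH, idsP)
  new("CVResult", k = k, foldAssignments = folds, pooled = pooled,
      sensitivity = m[["sensitivity"]], specificity = m[["specificity"]],
      accuracy = m[["accuracy"]],
      accuracySpread = if (length(perFoldAcc) > 1L) stats::sd(perFoldAcc) else NA_real_,
      perFoldAccuracy = perFoldAcc, seed = as.integer(seed))
}

#' Cross-validated accuracy over a (states x mixtures) grid
#'
#' Runs \code{\link{kfoldCrossValidate}} for every combination of state and
#' mixture-component counts, holding the fold assignment fixed (same seed)
#' so rows are comparable. A failing grid point is recorded as \code{NA}
#' with a warning and the sweep continues.
#'
#' @param cohort as in \code{\link{kfoldCrossValidate}}.
#' @param states integer vector of state counts.
#' @param mixtures integer vector of mixture-component counts.
#' @param k,channelMode,config,fusion,decimate,center,seed as in
#'   \code{\link{kfoldCrossValidate}}; \code{config} supplies everything but
#'   the swept fields.
#' @return data.frame with columns \code{n_states}, \code{n_components},
#'   \code{accuracy}, \code{sensitivity}, \code{specificity},
#'   \code{accuracy_spread}.
#' @export
hyperparameterSweep <- function(cohort, states = 3L, mixtures = 2L, k = 10L,
                                channelMode = c("MLAP", "ML", "AP"),
                                config = fitConfig(),
                                fusion = c("bivariate", "loglik_sum"),
                                decimate = 1L, center = FALSE,
                                seed = config@seed) {
  channelMode <- match.arg(channelMode)
  fusion <- match.arg(fusion)
  if (length(states) == 0L || length(mixtures) == 0L)
    stop("states and mixtures grids must be nonempty", call. = FALSE)
  grid <- expand.grid(n_states = as.integer(states),
                      n_components = as.integer(mixtures))
  out <- cbind(grid, accuracy = NA_real_, sensitivity = NA_real_,
               specificity = NA_real_, accuracy_spread = NA_real_)
  for (i in seq_len(nrow(grid))) {
    cfg <- fitConfig(nStates = grid$n_states[i],
                     nComponents = grid$n_components[i],
                     nIter = config@nIter, tol = config@tol,
                     covFloorScale = config@covFloorScale, seed = config@seed,
                     kmeansRestarts = config@kmeansRestarts)
    res <- tryCatch(
      kfoldCrossValidate(cohort, k = k, channelMode = channelMode,
                         config = cfg, fusion = fusion, decimate = decimate,
                         center = center, seed = seed),
      error = function(e) {
        warning(sprintf("sweep cell (states=%d, mixtures=%d) failed: %s",
                        grid$n_states[i], grid$n_components[i],
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (!is.null(res)) {
      out$accuracy[i] <- res@accuracy
      out$sensitivity[i] <- res@sensitivity
      out$specificity[i] <- res@specificity
      out$accuracy_spread[i] <- res@accuracySpread
    }
  }
  out
}

#' Write a sweep or CV table as TSV
#' @param x a data.frame (e.g. from \code{\link{hyperparameterSweep}}).
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render pooled confusion counts in the standard report layout
#'
#' @param cv a \linkS4class{CVResult}.
#' @return character vector of table lines
#'   (Subjects / Predicted H / Predicted PD / Sensitivity-Specificity /
#'   Overall Accuracy).
#' @export
formatConfusionTable <- function(cv) {
  p <- cv@pooled
  spread <- if (is.na(cv@accuracySpread)) "" else
    sprintf(" ± %.1f%%", cv@accuracySpread)
  c(sprintf("%-9s %-9s %-12s %-13s %-24s %s",
            "", "Subjects", "Predicted H", "Predicted PD",
            "Sensitivity/Specificity", "Overall Accuracy"),
    sprintf("%-9s %-9d %-12d %-13d %-24s %s",
            "Healthy", p@nHealthy, p@hPredH, p@hPredPd,
            sprintf("%.1f%%", cv@sensitivity),
            sprintf("%.2f%%%s", cv@accuracy, spread)),
    sprintf("%-9s %-9d %-12d %-13d %-24s",
            "PD", p@nPd, p@pdPredH, p@pdPredPd,
            sprintf("%.1f%%", cv@specificity)))
}
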