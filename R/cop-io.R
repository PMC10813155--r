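#' @include AllClasses.R
NULL

# COP file dialect: comma-delimited with header, columns `time` (seconds)
# then channel columns (ML, AP; mm). Written with 17 significant digits so
# a write/read round trip is bit-exact for doubles.

#' Read a COP recording from delimited text
#'
#' Expects a comma-separated file with a header row naming a \code{time}
#' column (seconds) and at least one of \code{ML}, \code{AP} (displacement in
#' mm). Time must be strictly increasing; the sampling rate is inferred from
#' the median time step and, when \code{expectedRate} is given, must match it
#' within 1 percent.
#'
#' @param path file path.
#' @param expectedRate expected sampling rate in Hz, or \code{NA} to skip the
#'   check.
#' @param subjectId,label metadata attached to the returned sequence.
#' @return an \linkS4class{ObservationSequence}.
#' @export
readCopFile <- function(path, expectedRate = NA_real_,
                        subjectId = NA_character_, label = NA_character_) {
  if (!file.exists(path)) stop("COP file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df))
    stop("COP file ", path, " is missing the required 'time' column", call. = FALSE)
  chans <- intersect(c("ML", "AP"), names(df))
  if (length(chans) == 0L)
    stop("COP file ", path, " has no ML or AP channel column; found: ",
         paste(setdiff(names(df), "time"), collapse = ", "), call. = FALSE)
  tm <- as.numeric(df$time)
  if (anyNA(tm) || (length(tm) > 1L && any(diff(tm) <= 0)))
    stop("time column of ", path, " is not strictly increasing", call. = FALSE)
  vals <- as.matrix(df[chans])
  if (anyNA(vals) || !all(is.finite(vals)))
    stop("COP file ", path, " contains NaN or non-finite values", call. = FALSE)
  rate <- if (length(tm) > 1L) 1 / stats::median(diff(tm)) else
    (if (is.na(expectedRate)) 1 else expectedRate)
  if (!is.na(expectedRate) && abs(rate - expectedRate) / expectedRate > 0.01)
    stop(sprintf("inferred sampling rate %.6g Hz differs from expected %.6g Hz by more than 1%%",
                 rate, expectedRate), call. = FALSE)
  observationSequence(vals, rate, chans, subjectId, label)
}

#' Write a COP recording as delimited text
#'
#' Writes the header \code{time,<channels>} and one row per sample, with the
#' time axis reconstructed from the sampling rate. Full double precision, so
#' \code{readCopFile} round-trips exactly.
#'
#' @param seq an \linkS4class{ObservationSequence}.
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
writeCopFile <- function(seq, path) {
  stopifnot(is(seq, "ObservationSequence"))
  validObject(seq)
  n <- nrow(seq@values)
  tm <- (seq_len(n) - 1) / seq@samplingRate
  cols <- cbind(tm, seq@values)
  lines <- c(paste(c("time", seq@channels), collapse = ","),
             apply(cols, 1L, function(r) paste(sprintf("%.17g", r), collapse = ",")))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) stop("cannot write COP file ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a cohort manifest
#'
#' Comma-separated manifest with header columns \code{subject_id},
#' \code{path}, \code{label} and optionally \code{group}. Relative recording
#' paths are resolved against the manifest's directory.
#'
#' @param path manifest file path.
#' @return a \linkS4class{CohortManifest}.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  req <- c("subject_id", "path", "label")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L)
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) stop("manifest ", path, " is empty", call. = FALSE)
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  cohortManifest(df)
}

#' Write a cohort manifest
#' @param manifest a \linkS4class{CohortManifest}.
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  validObject(manifest)
  utils::write.csv(manifest@records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load all recordings referenced by a manifest
#'
#' Reads every referenced COP file, checks its sampling rate against the
#' manifest's nominal rate (when present), attaches ids and labels, and
#' splits the cohort by class.
#'
#' @param manifest a \linkS4class{CohortManifest}.
#' @param expectedRate overrides the manifest's nominal sampling rate.
#' @return list with elements \code{healthy} and \code{pd}, each a list of
#'   labeled \linkS4class{ObservationSequence}.
#' @export
loadCohort <- function(manifest, expectedRate = NULL) {
  validObject(manifest)
  rate <- if (!is.null(expectedRate)) expectedRate else manifest@samplingRate
  rec <- manifest@records
  seqs <- vector("list", nrow(rec))
  for (i in seq_len(nrow(rec))) {
    if (!file.exists(rec$path[i]))
      stop(sprintf("row %d (subject %s): recording file missing: %s",
                   i, rec$subject_id[i], rec$path[i]), call. = FALSE)
    seqs[[i]] <- readCopFile(rec$path[i], expectedRate = rate,
                             subjectId = rec$subject_id[i],
                             label = rec$label[i])
  }
  list(healthy = seqs[rec$label == "healthy"],
       pd = seqs[rec$label == "pd"])
}

#' Decimate and/or centre a COP recording
#'
#' Keeps every \code{decimate}-th sample (dividing the sampling rate
#' accordingly) and optionally removes each channel's mean. The defaults
#' (factor 1, centring off) return the input unchanged, so by default the
#' classifier consumes raw signals.
#'
#' @param seq an \linkS4class{ObservationSequence}.
#' @param decimate integer decimation factor, >= 1.
#' @param center remove per-channel means?
#' @return an \linkS4class{ObservationSequence}.
#' @export
preprocessCop <- function(seq, decimate = 1L, center = FALSE) {
  if (length(decimate) != 1L || is.na(decimate) || decimate != round(decimate) ||
      decimate < 1)
    stop("decimate must be a single integer >= 1", call. = FALSE)
  decimate <- as.integer(decimate)
  if (decimate == 1L && !center) return(seq)
  vals <- seq@values
  if (decimate > 1L)
    vals <- vals[seq(1L, nrow(vals), by = decimate), , drop = FALSE]
  if (center) vals <- sweep(vals, 2L, colMeans(vals))
  observationSequence(vals, seq@samplingRate / decimate, seq@channels,
                      seq@subjectId, seq@label)
}
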