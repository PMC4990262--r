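# Ground-truth scoring: greedy one-to-one spike-time matching and
# detection-corrected error rates, plus the overlapping-spike audit.

#' Match a sorted spike train against ground truth
#'
#' Greedy nearest-first one-to-one matching: candidate pairs within
#' +/-`windowSamples` are matched in order of increasing time difference,
#' each sorted and each truth spike at most once. `FNd` is the number of
#' truth spikes never detected in the extracellular trace (supplied by
#' the detection stage); the detection-corrected rates exclude them:
#' `FP_rate = FP / (FN - FNd + TP)`, `FN_rate = (FN - FNd) / (FN - FNd +
#' TP)`, while the percentage-style rates are `%FP = FP / (FP + TP)` and
#' `%FN = FN / (FP + TP)`.
#'
#' @param sortedTimes ascending spike times (samples) of one sorted unit.
#' @param truthTimes ascending ground-truth spike times (samples).
#' @param windowSamples matching half-window in samples.
#' @param FNd undetected truth spikes (default 0).
#' @return list with counts `TP`, `FP`, `FN`, `FNd`, rates `FPrate`,
#'   `FNrate`, `pctFP`, `pctFN`, and `truthMatched` (logical per truth
#'   spike).
#' @export
matchUnit <- function(sortedTimes, truthTimes, windowSamples, FNd = 0L) {
  if (!length(truthTimes)) stop("empty ground truth")
  stopifnot(!is.unsorted(sortedTimes), !is.unsorted(truthTimes))
  ns <- length(sortedTimes); nt <- length(truthTimes)
  pairs <- NULL
  if (ns > 0L) {
    lo <- findInterval(sortedTimes - windowSamples - 1, truthTimes) + 1L
    hi <- findInterval(sortedTimes + windowSamples, truthTimes)
    idx <- which(hi >= lo)
    pairs <- do.call(rbind, lapply(idx, function(i)
      cbind(s = i, g = lo[i]:hi[i])))
  }
  sMatched <- logical(ns); gMatched <- logical(nt)
  if (!is.null(pairs) && nrow(pairs)) {
    dt <- abs(sortedTimes[pairs[, 1]] - truthTimes[pairs[, 2]])
    pairs <- pairs[order(dt), , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      s <- pairs[r, 1]; g <- pairs[r, 2]
      if (!sMatched[s] && !gMatched[g]) {
        sMatched[s] <- TRUE; gMatched[g] <- TRUE
      }
    }
  }
  TP <- sum(sMatched); FP <- ns - TP; FN <- nt - TP
  FNd <- min(FNd, FN)
  denom <- FN - FNd + TP
  list(TP = TP, FP = FP, FN = FN, FNd = FNd,
       FPrate = if (denom > 0) FP / denom else NA_real_,
       FNrate = if (denom > 0) (FN - FNd) / denom else NA_real_,
       pctFP = if (FP + TP > 0) FP / (FP + TP) else NA_real_,
       pctFN = if (FP + TP > 0) FN / (FP + TP) else NA_real_,
       truthMatched = gMatched)
}

#' Find the sorted unit matching a ground-truth train
#'
#' Scores every sorted unit against the truth train and returns the unit
#' with the highest true-positive count.
#'
#' @param sortedList list of ascending spike-time vectors, one per unit.
#' @param truthTimes ascending ground-truth times.
#' @param windowSamples matching half-window in samples.
#' @param FNd undetected truth spikes (default 0).
#' @return the [matchUnit()] result of the best unit, plus `matchedUnit`.
#' @export
bestMatchUnit <- function(sortedList, truthTimes, windowSamples, FNd = 0L) {
  if (!length(sortedList)) stop("no sorted units")
  res <- lapply(sortedList, matchUnit, truthTimes = truthTimes,
                windowSamples = windowSamples, FNd = FNd)
  best <- which.max(vapply(res, function(r) r$TP, numeric(1)))
  out <- res[[best]]
  out$matchedUnit <- best
  out
}

#' Audit recovery of temporally overlapping truth spikes
#'
#' Enumerates all cross-unit ground-truth spike pairs closer than the
#' censored period — the detector necessarily lumped those events — and
#' reports how many of the involved truth spikes the sorter recovered.
#'
#' @param truthTimes list of per-unit truth time vectors (samples).
#' @param recovered list of logical vectors parallel to `truthTimes`
#'   (e.g. `truthMatched` from [matchUnit()] per unit).
#' @param tauCSamples censored period in samples.
#' @return list with `n` (truth spikes involved in close pairs),
#'   `nRecovered`, and `fraction` (NA when n = 0).
#' @export
overlapAudit <- function(truthTimes, recovered, tauCSamples) {
  stopifnot(length(truthTimes) >= 2L,
            length(truthTimes) == length(recovered))
  nU <- length(truthTimes)
  involved <- lapply(truthTimes, function(t) logical(length(t)))
  for (i in seq_len(nU - 1L)) for (j in (i + 1L):nU) {
    ti <- truthTimes[[i]]; tj <- truthTimes[[j]]
    if (!length(ti) || !length(tj)) next
    for (a in seq_along(ti)) {
      close <- abs(tj - ti[a]) < tauCSamples
      if (any(close)) {
        involved[[i]][a] <- TRUE
        involved[[j]][close] <- TRUE
      }
    }
  }
  n <- sum(unlist(involved))
  nRec <- sum(unlist(involved) & unlist(recovered))
  list(n = n, nRecovered = nRec,
       fraction = if (n > 0) nRec / n else NA_real_)
}
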