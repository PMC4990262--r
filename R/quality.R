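# Per-unit quality: stability-based false-positive / false-negative
# estimates, template SNR, refractory violations, burst-split flags, and
# the isolation distance for comparison with covariance-based metrics.

#' Stability-based per-unit error estimates
#'
#' For each final unit, counts how often its spikes were co-clustered
#' with outside spikes across the clustering ensemble: per iteration and
#' ensemble cluster k, if the unit's intersection with k is strictly
#' smaller than the outsiders' the unit-side spikes count as false
#' positives; if strictly larger, the outsider-side spikes count as false
#' negatives. Counts are averaged over iterations and normalized by the
#' unit size.
#'
#' @param model a [ConsensusModel-class].
#' @param ensemble the [LabelEnsemble-class] the model was built from.
#' @return data.frame with `unit`, `n`, `PFP`, `PFN` and `lowConfidence`
#'   (TRUE for singleton units).
#' @export
unitErrorEstimates <- function(model, ensemble) {
  kept <- model@keptIdx
  L <- ensemble@labels[kept, , drop = FALSE]
  assign <- model@finalAssign
  units <- sort(unique(assign[!is.na(assign)]))
  Nite <- ncol(L)
  Kmax <- max(L)
  FP <- FN <- setNames(numeric(length(units)), units)
  for (n in seq_len(Nite)) {
    tot <- tabulate(L[, n], Kmax)
    for (ui in seq_along(units)) {
      inUnit <- !is.na(assign) & assign == units[ui]
      u <- tabulate(L[inUnit, n], Kmax)
      o <- tot - u
      FP[ui] <- FP[ui] + sum(u[u < o])
      FN[ui] <- FN[ui] + sum(o[o < u & o > 0])
    }
  }
  nU <- vapply(units, function(x) sum(assign == x, na.rm = TRUE), 1L)
  data.frame(unit = units, n = nU,
             PFP = as.numeric(FP) / (nU * Nite),
             PFN = as.numeric(FN) / (nU * Nite),
             lowConfidence = nU < 2L)
}

#' Template signal-to-noise ratio
#'
#' The maximum over space-time of the squared template (mean waveform)
#' divided by the across-spike variance at the same space-time point.
#'
#' @param unitWf waveform array of the unit's spikes (n x ch x s), n >= 2.
#' @return the SNR; an all-zero template yields 0, and a zero variance at
#'   the maximizing point yields `Inf` with a warning.
#' @export
unitSnr <- function(unitWf) {
  stopifnot(length(dim(unitWf)) == 3L, dim(unitWf)[1] >= 2L)
  tpl <- apply(unitWf, c(2L, 3L), mean)
  if (all(tpl == 0)) return(0)
  v <- apply(unitWf, c(2L, 3L), function(x) sum((x - mean(x))^2) /
               (length(x) - 1L))
  ratio <- tpl^2 / v
  if (any(!is.finite(ratio) & tpl != 0)) {
    warning("zero across-spike variance at the template maximum")
    return(Inf)
  }
  max(ratio[is.finite(ratio)], 0)
}

#' Refractory-period violation rate
#'
#' Fraction of inter-spike intervals in `[0, windowMs)`.
#'
#' @param timesSamples spike times in samples, ascending.
#' @param rateHz sample rate of those times.
#' @param windowMs violation window (default 2 ms).
#' @return fraction in [0, 1]; 0 for fewer than 2 spikes.
#' @export
isiViolationRate <- function(timesSamples, rateHz, windowMs = 2) {
  if (length(timesSamples) < 2L) return(0)
  isiMs <- diff(sort(timesSamples)) / rateHz * 1000
  mean(isiMs < windowMs)
}

# Maximum over time lags of the Pearson correlation between two
# spatiotemporal templates (channels x samples).
templateCorrelation <- function(a, b) {
  ns <- ncol(a)
  lags <- seq(-(ns %/% 2L), ns %/% 2L)
  best <- -1
  va <- as.numeric(a)
  if (sd(va) == 0) return(0)
  for (tau in lags) {
    vb <- as.numeric(shiftTemplate(b, tau))
    if (sd(vb) == 0) next
    best <- max(best, cor(va, vb))
  }
  best
}

#' Flag putative burst splits
#'
#' Bursting cells produce systematically varying spike shapes that the
#' clustering may split; pairs of units whose templates correlate above
#' `corThreshold` (maximum over time lags) and whose pairwise
#' misclassification probability exceeds `pmisThreshold` are listed for
#' manual review (never auto-merged).
#'
#' @param templates list of final-unit templates (channels x samples).
#' @param Pmis final misclassification matrix.
#' @param corThreshold correlation threshold (default 0.70).
#' @param pmisThreshold misclassification threshold (default 0.05).
#' @return data.frame with `unitA`, `unitB`, `correlation`, `Pmis`.
#' @export
flagBurstMerges <- function(templates, Pmis, corThreshold = 0.70,
                            pmisThreshold = 0.05) {
  out <- list()
  nU <- length(templates)
  for (i in seq_len(nU)) for (j in seq_len(nU)) {
    if (j <= i) next
    cc <- templateCorrelation(templates[[i]], templates[[j]])
    if (cc > corThreshold && Pmis[i, j] > pmisThreshold)
      out[[length(out) + 1L]] <-
        data.frame(unitA = i, unitB = j, correlation = cc,
                   Pmis = Pmis[i, j])
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(unitA = integer(), unitB = integer(),
                  correlation = numeric(), Pmis = numeric())
}

#' Isolation distance
#'
#' The Mahalanobis distance (under the unit's own covariance) of the
#' N-th closest outside spike, with N the unit size, in the given feature
#' space (conventionally the first 12 principal components).
#'
#' @param unitFeatures n_unit x P feature rows of the unit's spikes.
#' @param outsideFeatures rows of all other spikes.
#' @return the (squared-convention) isolation distance, or `NA` when
#'   there are fewer outside spikes than unit spikes or the unit
#'   covariance is singular.
#' @export
isolationDistance <- function(unitFeatures, outsideFeatures) {
  nU <- nrow(unitFeatures)
  if (nrow(outsideFeatures) < nU) return(NA_real_)
  C <- cov(unitFeatures)
  d2 <- tryCatch(
    mahalanobis(outsideFeatures, colMeans(unitFeatures), C),
    error = function(e) NULL)
  if (is.null(d2)) return(NA_real_)
  sort(d2, partial = nU)[nU]
}
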