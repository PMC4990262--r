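# Feature extraction: PCA of the concatenated spatiotemporal waveforms,
# keeping the components whose projections reject Gaussianity.

#' Extract non-Gaussian principal-component features
#'
#' Waveforms are cropped to `tauWinMs` around the trough, concatenated
#' across channels into one vector per spike, and PCA-decomposed
#' (mean-centred, unscaled: whitening has already equalized the noise).
#' Components whose projection distribution rejects normality (Lilliefors
#' test at `pThreshold`) are retained, in variance order. When no
#' component rejects, the top 3 variance components are used instead (with
#' a warning): in that case the ensemble is indistinguishable from one
#' Gaussian blob and any low-dimensional summary is as good as another.
#'
#' Component signs follow a deterministic convention (largest-magnitude
#' loading positive).
#'
#' @param ensemble a whitened [SpikeEnsemble-class].
#' @param tauWinMs feature window in ms (default 2.5).
#' @param pThreshold Lilliefors significance level (default 0.01).
#' @return a [FeatureMatrix-class].
#' @export
extractFeatures <- function(ensemble, tauWinMs = 2.5, pThreshold = 0.01) {
  stopifnot(is(ensemble, "SpikeEnsemble"))
  if (nSpikes(ensemble) < 50L)
    warning("fewer than 50 spikes: the normality test has little power")
  if (tauWinMs > ensemble@tauWfMs)
    stop("tauWinMs must not exceed the stored waveform length")
  wf <- cropWaveforms(ensemble@waveforms, ensemble@waveRateHz, tauWinMs)
  X <- flattenWaveforms(wf)
  featureProjection(X, pThreshold)
}

# Shared PCA + Lilliefors selection over an n x d matrix.
featureProjection <- function(X, pThreshold = 0.01) {
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  nComp <- max(1L, sum(pc$sdev > max(pc$sdev, .Machine$double.eps) * 1e-8))
  rot <- pc$rotation[, seq_len(nComp), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(rot))) {
    jm <- which.max(abs(rot[, j]))
    if (rot[jm, j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- sweep(X, 2L, pc$center) %*% rot
  pv <- vapply(seq_len(ncol(scores)), function(j) {
    s <- scores[, j]
    if (sd(s) == 0) return(1)
    nortest::lillie.test(s)$p.value
  }, numeric(1))
  keep <- which(pv < pThreshold)
  fallback <- FALSE
  if (!length(keep)) {
    warning("no principal component rejected Gaussianity; ",
            "falling back to the top 3 variance components")
    keep <- seq_len(min(3L, ncol(scores)))
    fallback <- TRUE
  }
  new("FeatureMatrix",
      values = scores[, keep, drop = FALSE],
      components = rot[, keep, drop = FALSE],
      center = pc$center,
      pValues = pv[keep],
      fallback = fallback)
}

#' Project features back into waveform space
#'
#' Back-projection with the retained components; with all components this
#' reconstructs the input losslessly (up to numerical tolerance).
#'
#' @param fm a [FeatureMatrix-class].
#' @return n x d matrix in the original concatenated-waveform space.
#' @export
backProject <- function(fm) {
  sweep(fm@values %*% t(fm@components), 2L, fm@center, "+")
}
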