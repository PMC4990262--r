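#' @import methods
#' @importFrom stats median quantile sd cor cov rnorm runif rexp rpois
#'   prcomp kmeans hclust cutree as.dist mahalanobis setNames aggregate
#' @importFrom utils head tail read.csv write.csv
#' @useDynLib consensusSort, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Multichannel extracellular recording
#'
#' Container for a channels x samples voltage matrix together with its
#' sampling rate, the 2-D electrode positions (micrometres) and the
#' band-pass band the signal is (or will be) filtered to.
#'
#' @slot signal numeric matrix, channels x samples, in microvolts.
#' @slot rateHz sampling rate in Hz.
#' @slot positionsUm channels x 2 matrix of electrode coordinates in
#'   micrometres; rows must be unique.
#' @slot band length-2 numeric, low/high band edge in Hz.
#' @export
setClass("Recording",
  representation(
    signal = "matrix",
    rateHz = "numeric",
    positionsUm = "matrix",
    band = "numeric"
  )
)

setValidity("Recording", function(object) {
  msg <- character()
  if (length(object@rateHz) != 1L || object@rateHz <= 0)
    msg <- c(msg, "rateHz must be a single positive number")
  if (nrow(object@positionsUm) != nrow(object@signal))
    msg <- c(msg, "positionsUm must have one row per channel")
  if (ncol(object@positionsUm) != 2L)
    msg <- c(msg, "positionsUm must have 2 columns")
  if (anyDuplicated(object@positionsUm))
    msg <- c(msg, "channel positions must be unique")
  if (length(object@band) != 2L || any(object@band <= 0) ||
      object@band[1] >= object@band[2])
    msg <- c(msg, "band must be (low, high) with 0 < low < high")
  if (length(object@rateHz) == 1L && length(object@band) == 2L &&
      object@rateHz <= 2 * object@band[2])
    msg <- c(msg, "rateHz must exceed twice the upper band edge")
  if (length(msg)) msg else TRUE
})

#' Detected spike waveform ensemble
#'
#' Spike times (trough-aligned, 1-based sample indices at the recording
#' rate), cut-out spatiotemporal waveforms resampled at the waveform rate,
#' and per-spike spatial windows (contiguous channel ranges from detection
#' lumping).
#'
#' @slot times numeric vector of trough sample indices, strictly increasing.
#' @slot waveforms 3-D array, n_spikes x channels x samples.
#' @slot windows integer matrix, n_spikes x 2 (first and last channel of the
#'   spike's spatial window).
#' @slot waveRateHz sample rate of the stored waveforms (Hz).
#' @slot recRateHz sample rate the times refer to (Hz).
#' @slot tauWfMs full stored waveform length in ms.
#' @slot whitened logical, TRUE once spatial whitening has been applied.
#' @slot nDropped number of detections discarded at the recording edges.
#' @export
setClass("SpikeEnsemble",
  representation(
    times = "numeric",
    waveforms = "array",
    windows = "matrix",
    waveRateHz = "numeric",
    recRateHz = "numeric",
    tauWfMs = "numeric",
    whitened = "logical",
    nDropped = "integer"
  )
)

setValidity("SpikeEnsemble", function(object) {
  msg <- character()
  n <- length(object@times)
  if (n > 0L) {
    if (is.unsorted(object@times, strictly = TRUE))
      msg <- c(msg, "times must be strictly increasing")
    if (length(dim(object@waveforms)) != 3L ||
        dim(object@waveforms)[1] != n)
      msg <- c(msg, "waveforms must be n_spikes x channels x samples")
    if (nrow(object@windows) != n || ncol(object@windows) != 2L)
      msg <- c(msg, "windows must be n_spikes x 2")
  }
  if (length(msg)) msg else TRUE
})

#' Feature matrix from non-Gaussian principal components
#'
#' @slot values n_spikes x P projection matrix.
#' @slot components feature-dimension x P orthonormal loading matrix.
#' @slot center feature-dimension mean vector removed before projection.
#' @slot pValues Lilliefors p-value per retained component.
#' @slot fallback TRUE when no component rejected Gaussianity and the top
#'   variance components were used instead.
#' @export
setClass("FeatureMatrix",
  representation(
    values = "matrix",
    components = "matrix",
    center = "numeric",
    pValues = "numeric",
    fallback = "logical"
  )
)

setValidity("FeatureMatrix", function(object) {
  if (ncol(object@values) < 1L) return("at least one component is required")
  cp <- crossprod(object@components)
  if (max(abs(cp - diag(ncol(cp)))) > 1e-6)
    return("components must be orthonormal")
  TRUE
})

#' Ensemble of clustering solutions
#'
#' One column per template-matching iteration: the cluster label each spike
#' was assigned to (K_si) and the mean-squared residual (chi^2) of its best
#' template fit.
#'
#' @slot labels integer matrix, n_spikes x Nite.
#' @slot chi2 numeric matrix, n_spikes x Nite, all values >= 0.
#' @slot K number of K-means clusters requested per iteration.
#' @slot seeds integer vector of per-iteration RNG seeds.
#' @export
setClass("LabelEnsemble",
  representation(
    labels = "matrix",
    chi2 = "matrix",
    K = "integer",
    seeds = "integer"
  )
)

setValidity("LabelEnsemble", function(object) {
  msg <- character()
  if (!all(dim(object@labels) == dim(object@chi2)))
    msg <- c(msg, "labels and chi2 must have identical dimensions")
  if (any(object@chi2 < 0)) msg <- c(msg, "chi2 must be non-negative")
  if (ncol(object@labels) < 1L) msg <- c(msg, "at least one iteration required")
  if (length(msg)) msg else TRUE
})

#' Consensus clustering result
#'
#' Core-cluster and final-cluster assignments together with the
#' co-assignment matrix (over label signatures), the misclassification
#' matrix between final clusters, and the single-link tree that was cut at
#' 1 - P_th.
#'
#' @slot keptIdx indices (into the label ensemble) of the spikes used for
#'   consensus clustering (the chi^2-gated set).
#' @slot signatureId integer per kept spike: which distinct label signature
#'   it carries.
#' @slot P0 symmetric co-assignment matrix over signatures, values in [0,1].
#' @slot coreAssign integer per kept spike: core cluster id, NA = excluded.
#' @slot finalAssign integer per kept spike: final cluster id, NA = excluded.
#' @slot Pmis symmetric misclassification matrix between final clusters.
#' @slot linkage the hclust tree over core clusters (distance 1 - Pmis).
#' @slot minCsize the core-cluster size threshold retained by the sweep.
#' @slot sweep data.frame: minCsize, n_final, frac_excluded per sweep value.
#' @slot Pth dendrogram cut level used.
#' @export
setClass("ConsensusModel",
  representation(
    keptIdx = "integer",
    signatureId = "integer",
    P0 = "matrix",
    coreAssign = "integer",
    finalAssign = "integer",
    Pmis = "matrix",
    linkage = "ANY",
    minCsize = "integer",
    sweep = "data.frame",
    Pth = "numeric"
  )
)

setValidity("ConsensusModel", function(object) {
  msg <- character()
  if (length(object@P0)) {
    if (any(object@P0 < -1e-9 | object@P0 > 1 + 1e-9))
      msg <- c(msg, "P0 must lie in [0,1]")
    if (max(abs(object@P0 - t(object@P0))) > 1e-9)
      msg <- c(msg, "P0 must be symmetric")
  }
  if (length(object@Pmis)) {
    if (any(object@Pmis < -1e-9 | object@Pmis > 1 + 1e-9))
      msg <- c(msg, "Pmis must lie in [0,1]")
    if (max(abs(object@Pmis - t(object@Pmis))) > 1e-9)
      msg <- c(msg, "Pmis must be symmetric")
  }
  if (length(msg)) msg else TRUE
})

#' Per-unit quality report
#'
#' @slot units data.frame with one row per final unit: unit id, spike count,
#'   PFP_total, PFN_total, SNR, ISI violation rate, isolation distance (NA
#'   when undefined) and the validated flag.
#' @slot mergeFlags data.frame of unit pairs flagged as putative burst
#'   splits (template correlation > 0.70 and Pmis > 0.05).
#' @export
setClass("QualityReport",
  representation(
    units = "data.frame",
    mergeFlags = "data.frame"
  )
)

#' Ground-truth synthetic recording
#'
#' A Recording plus the per-unit true spike times and templates used to
#' build it.
#'
#' @slot recording the synthetic [Recording-class].
#' @slot trueTimes list of numeric vectors, one per unit, trough sample
#'   indices (1-based, recording rate).
#' @slot trueTemplates list of channels x samples template matrices (uV).
#' @slot jitterSd amplitude jitter SD (fraction of unity).
#' @slot noiseCov channels x channels spatial noise covariance.
#' @slot refractoryMs refractory period enforced in the generated trains.
#' @export
setClass("GroundTruthRecording",
  representation(
    recording = "Recording",
    trueTimes = "list",
    trueTemplates = "list",
    jitterSd = "numeric",
    noiseCov = "matrix",
    refractoryMs = "numeric"
  )
)

setValidity("GroundTruthRecording", function(object) {
  msg <- character()
  ns <- ncol(object@recording@signal)
  for (u in seq_along(object@trueTimes)) {
    tt <- object@trueTimes[[u]]
    if (length(tt) && (min(tt) < 1 || max(tt) > ns))
      msg <- c(msg, sprintf("unit %d has spike times outside the recording", u))
    if (length(tt) > 1L) {
      isiMs <- diff(tt) / object@recording@rateHz * 1000
      if (any(isiMs < object@refractoryMs - 1e-9))
        msg <- c(msg, sprintf("unit %d violates the refractory period", u))
    }
  }
  if (length(object@noiseCov)) {
    if (max(abs(object@noiseCov - t(object@noiseCov))) > 1e-9)
      msg <- c(msg, "noiseCov must be symmetric")
    else if (any(eigen(object@noiseCov, symmetric = TRUE,
                       only.values = TRUE)$values < -1e-9))
      msg <- c(msg, "noiseCov must be positive semi-definite")
  }
  if (length(msg)) msg else TRUE
})
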