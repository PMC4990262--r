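# Accessors and show methods for the core containers.

#' Number of channels
#' @param x a Recording or SpikeEnsemble
#' @return integer channel count
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Number of detected spikes
#' @param x a SpikeEnsemble or LabelEnsemble
#' @return integer spike count
#' @export
setGeneric("nSpikes", function(x) standardGeneric("nSpikes"))

#' Spike times
#' @param x a SpikeEnsemble
#' @return numeric vector of trough sample indices (1-based)
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))

#' Spike waveform array
#' @param x a SpikeEnsemble
#' @return n_spikes x channels x samples array
#' @export
setGeneric("waveforms", function(x) standardGeneric("waveforms"))

#' Sampling rate in Hz
#' @param x a Recording
#' @return numeric rate
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' Final cluster assignment over kept spikes
#' @param x a ConsensusModel
#' @return integer vector (NA = excluded)
#' @export
setGeneric("finalAssign", function(x) standardGeneric("finalAssign"))

#' Core cluster assignment over kept spikes
#' @param x a ConsensusModel
#' @return integer vector (NA = excluded)
#' @export
setGeneric("coreAssign", function(x) standardGeneric("coreAssign"))

#' @rdname nChannels
#' @export
setMethod("nChannels", "Recording", function(x) nrow(x@signal))

#' @rdname nChannels
#' @export
setMethod("nChannels", "SpikeEnsemble", function(x) dim(x@waveforms)[2])

#' @rdname nSpikes
#' @export
setMethod("nSpikes", "SpikeEnsemble", function(x) length(x@times))

#' @rdname nSpikes
#' @export
setMethod("nSpikes", "LabelEnsemble", function(x) nrow(x@labels))

#' @rdname spikeTimes
#' @export
setMethod("spikeTimes", "SpikeEnsemble", function(x) x@times)

#' @rdname waveforms
#' @export
setMethod("waveforms", "SpikeEnsemble", function(x) x@waveforms)

#' @rdname sampleRate
#' @export
setMethod("sampleRate", "Recording", function(x) x@rateHz)

#' @rdname finalAssign
#' @export
setMethod("finalAssign", "ConsensusModel", function(x) x@finalAssign)

#' @rdname coreAssign
#' @export
setMethod("coreAssign", "ConsensusModel", function(x) x@coreAssign)

setMethod("show", "Recording", function(object) {
  cat(sprintf(
    "Recording: %d channels x %d samples @ %g Hz (%.1f s), band %g-%g Hz\n",
    nrow(object@signal), ncol(object@signal), object@rateHz,
    ncol(object@signal) / object@rateHz, object@band[1], object@band[2]))
})

setMethod("show", "SpikeEnsemble", function(object) {
  cat(sprintf(
    "SpikeEnsemble: %d spikes, %d channels, %d waveform samples @ %g Hz%s\n",
    length(object@times), dim(object@waveforms)[2],
    dim(object@waveforms)[3], object@waveRateHz,
    if (isTRUE(object@whitened)) " (whitened)" else ""))
  if (object@nDropped > 0L)
    cat(sprintf("  %d edge detections dropped\n", object@nDropped))
})

setMethod("show", "LabelEnsemble", function(object) {
  cat(sprintf("LabelEnsemble: %d spikes x %d iterations, K = %d\n",
              nrow(object@labels), ncol(object@labels), object@K))
})

setMethod("show", "ConsensusModel", function(object) {
  nf <- length(unique(object@finalAssign[!is.na(object@finalAssign)]))
  cat(sprintf(
    "ConsensusModel: %d kept spikes, %d signatures, %d core clusters, %d final clusters\n",
    length(object@keptIdx), nrow(object@P0),
    length(unique(object@coreAssign[!is.na(object@coreAssign)])), nf))
  cat(sprintf("  minCsize = %d, P_th = %g, excluded = %d\n",
              object@minCsize, object@Pth, sum(is.na(object@finalAssign))))
})

setMethod("show", "QualityReport", function(object) {
  cat(sprintf("QualityReport: %d units, %d validated, %d merge flags\n",
              nrow(object@units), sum(object@units$validated),
              nrow(object@mergeFlags)))
})

setMethod("show", "GroundTruthRecording", function(object) {
  cat(sprintf("GroundTruthRecording: %d units, %d total true spikes\n",
              length(object@trueTimes),
              sum(lengths(object@trueTimes))))
  show(object@recording)
})
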