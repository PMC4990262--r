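# Synthetic multichannel recordings with ground truth: parametric
# spatiotemporal templates, Poisson-with-refractoriness spike trains,
# amplitude jitter, and band-limited spatially correlated noise.

#' Electrode geometries
#'
#' `linearGeometry` lays `n` sites on a line with the given pitch;
#' `tetrodeGeometry` returns the canonical 4-site square bundle.
#'
#' @param n number of sites.
#' @param pitchUm inter-site spacing in micrometres.
#' @return n x 2 matrix of site coordinates (um).
#' @export
linearGeometry <- function(n, pitchUm = 20) {
  cbind(x = rep(0, n), y = seq(0, by = pitchUm, length.out = n))
}

#' @rdname linearGeometry
#' @param sideUm tetrode bundle side length in micrometres.
#' @export
tetrodeGeometry <- function(sideUm = 25) {
  cbind(x = c(0, sideUm, 0, sideUm), y = c(0, 0, sideUm, sideUm))
}

# Canonical single-channel time courses, unit negative peak, sampled at
# rateHz over durMs. Trough at the centre sample.
templateTimeCourse <- function(shape = c("biphasic", "triphasic", "bursty"),
                               rateHz, durMs = 4) {
  shape <- match.arg(shape)
  n <- round(durMs / 1000 * rateHz)
  if (n %% 2L == 0L) n <- n + 1L
  t <- (seq_len(n) - (n %/% 2L + 1L)) / rateHz * 1000  # ms around trough
  g <- function(mu, sdv) exp(-(t - mu)^2 / (2 * sdv^2))
  v <- switch(shape,
    biphasic  = -g(0, 0.18) + 0.45 * g(0.55, 0.35),
    triphasic = 0.25 * g(-0.45, 0.22) - g(0, 0.16) + 0.55 * g(0.5, 0.3),
    bursty    = -g(0, 0.24) + 0.35 * g(0.95, 0.55)
  )
  v / abs(min(v))
}

#' Build a spatiotemporal template
#'
#' Combines a canonical time course with a Gaussian spatial amplitude decay
#' around a source position, producing a channels x samples matrix whose
#' footprint spans the few sites nearest the source.
#'
#' @param shape one of "biphasic", "triphasic", "bursty".
#' @param positionsUm channel geometry (n x 2, um).
#' @param sourceUm length-2 source position (um).
#' @param amplitudeUv negative peak amplitude on the closest channel (uV).
#' @param decayUm spatial decay constant of the Gaussian amplitude profile.
#' @param rateHz sampling rate of the template.
#' @param durMs template duration in ms (trough at the centre sample).
#' @return channels x samples matrix (uV).
#' @export
makeTemplate <- function(shape, positionsUm, sourceUm, amplitudeUv = 100,
                         decayUm = 25, rateHz = 10000, durMs = 4) {
  tc <- templateTimeCourse(shape, rateHz, durMs)
  d <- sqrt(rowSums((positionsUm -
                       matrix(sourceUm, nrow(positionsUm), 2,
                              byrow = TRUE))^2))
  amp <- amplitudeUv * exp(-d^2 / (2 * decayUm^2))
  amp[amp < 1e-3 * amplitudeUv] <- 0  # hard footprint edge
  outer(amp, tc)
}

# Power gain of the zero-phase (forward-backward) band-pass used for noise
# shaping: mean over frequency of |H|^4 for white input.
bandpassPowerGain <- function(band, rateHz, order = 4L) {
  bf <- signal::butter(order, band / (rateHz / 2), type = "pass")
  w <- seq(0, pi, length.out = 4096)
  h <- signal::freqz(bf, w)$h
  mean(Mod(h)^4)
}

# Band-limited, spatially correlated Gaussian noise with stationary spatial
# covariance approximately noiseCov. Uses the current RNG stream.
makeNoise <- function(noiseCov, nSamples, rateHz, band = c(200, 4000)) {
  nch <- nrow(noiseCov)
  white <- matrix(rnorm(nch * nSamples), nch, nSamples)
  L <- t(chol(noiseCov + diag(1e-12, nch)))
  x <- L %*% white
  bf <- signal::butter(4, band / (rateHz / 2), type = "pass")
  gain <- bandpassPowerGain(band, rateHz)
  for (ch in seq_len(nch))
    x[ch, ] <- signal::filtfilt(bf, x[ch, ]) / sqrt(gain)
  x
}

# Poisson spike train with an absolute refractory period: inter-spike gaps
# are refractory + Exp(rate). Returns trough sample indices in
# [margin+1, nSamples-margin].
poissonTrain <- function(rateHz, durationS, sampleRateHz, refractoryMs,
                         marginSamples) {
  gaps <- numeric(0)
  tMax <- durationS
  t <- rexp(1, rateHz)
  times <- numeric(0)
  while (t < tMax) {
    times <- c(times, t)
    t <- t + refractoryMs / 1000 + rexp(1, rateHz)
  }
  s <- round(times * sampleRateHz)
  s <- s[s > marginSamples & s <= durationS * sampleRateHz - marginSamples]
  s
}

# Add one scaled template at each time (trough sample index), in place.
addTemplateAt <- function(signal, template, times, scales) {
  L <- ncol(template)
  trough <- which.min(template[which.max(-apply(template, 1, min)), ])
  ns <- ncol(signal)
  for (i in seq_along(times)) {
    lo <- times[i] - (trough - 1L)
    hi <- lo + L - 1L
    if (lo < 1L || hi > ns) next
    signal[, lo:hi] <- signal[, lo:hi] + scales[i] * template
  }
  signal
}

#' Generate a ground-truth synthetic recording
#'
#' Sums per-unit spike trains of jittered templates with band-limited,
#' spatially correlated Gaussian noise. Units are assigned the built-in
#' template shapes in rotation and positioned evenly along the array.
#'
#' @param units number of units.
#' @param durationS recording duration (s).
#' @param rateHz per-unit mean firing rate (Hz); scalar or per-unit vector.
#' @param geometry channels x 2 electrode positions (um), e.g.
#'   [linearGeometry()] or [tetrodeGeometry()].
#' @param jitterSd per-spike amplitude jitter SD as a fraction of the
#'   template amplitude (default 0.10); scales are drawn from
#'   Normal(1, jitterSd) truncated at zero.
#' @param noiseCov channels x channels spatial noise covariance (uV^2); the
#'   default is exponential spatial correlation `exp(-d/50um)` at
#'   `noiseSdUv^2` variance. Pass a zero matrix for a noiseless recording.
#' @param noiseSdUv noise SD used to build the default covariance.
#' @param amplitudesUv per-unit negative peak amplitudes (uV); default 100
#'   for every unit.
#' @param sampleRateHz sampling rate (default 10 kHz).
#' @param refractoryMs absolute refractory period enforced in the generated
#'   trains (default 2 ms, matching the refractory-violation criterion).
#' @param seed integer RNG seed.
#' @param templates optional list of channels x samples template matrices
#'   overriding the built-in shapes.
#' @return a [GroundTruthRecording-class].
#' @export
makeRecording <- function(units, durationS, rateHz, geometry,
                          jitterSd = 0.10, noiseCov = NULL,
                          noiseSdUv = 10, amplitudesUv = rep(100, units),
                          sampleRateHz = 10000, refractoryMs = 2,
                          seed = 1L, templates = NULL) {
  stopifnot(units >= 1, durationS > 0)
  nch <- nrow(geometry)
  if (anyDuplicated(geometry)) stop("channel geometry entries overlap")
  rateHz <- rep_len(rateHz, units)
  amplitudesUv <- rep_len(amplitudesUv, units)
  if (any(durationS * rateHz < 1))
    stop("duration x rate must produce at least one spike per unit")
  if (is.null(noiseCov)) {
    d <- as.matrix(stats::dist(geometry))
    noiseCov <- noiseSdUv^2 * exp(-d / 50)
  }
  ns <- round(durationS * sampleRateHz)
  shapes <- c("biphasic", "triphasic", "bursty")
  if (is.null(templates)) {
    # sources spread along the array, offset sideways so no site sits
    # exactly on a source
    yr <- range(geometry[, 2])
    ys <- seq(yr[1], yr[2], length.out = units + 2L)[-c(1L, units + 2L)]
    templates <- lapply(seq_len(units), function(u) {
      makeTemplate(shapes[(u - 1L) %% 3L + 1L], geometry,
                   sourceUm = c(mean(geometry[, 1]) + 8, ys[u]),
                   amplitudeUv = amplitudesUv[u],
                   rateHz = sampleRateHz)
    })
  }
  stopifnot(length(templates) == units,
            all(vapply(templates, nrow, 1L) == nch))
  margin <- max(vapply(templates, ncol, 1L))
  withSeed(seed, {
    noiseless <- all(noiseCov == 0)
    sigNoise <- if (noiseless) matrix(0, nch, ns)
                else makeNoise(noiseCov, ns, sampleRateHz)
    trueTimes <- vector("list", units)
    signal <- sigNoise
    for (u in seq_len(units)) {
      tt <- poissonTrain(rateHz[u], durationS, sampleRateHz,
                         refractoryMs, margin)
      scales <- rnorm(length(tt), 1, jitterSd)
      scales[scales < 0] <- 0
      signal <- addTemplateAt(signal, templates[[u]], tt, scales)
      trueTimes[[u]] <- tt
    }
    rec <- new("Recording", signal = signal, rateHz = sampleRateHz,
               positionsUm = geometry, band = c(200, 4000))
    new("GroundTruthRecording", recording = rec, trueTimes = trueTimes,
        trueTemplates = templates, jitterSd = jitterSd,
        noiseCov = noiseCov, refractoryMs = refractoryMs)
  })
}

#' Replicate a recording into a larger virtual array
#'
#' Stacks `copies` time-shifted copies of the signal as consecutive channel
#' blocks (block i delayed by i x shift), emulating the construction of
#' virtual 32-channel recordings from tetrode data. Ground-truth lists are
#' replicated with matching offsets, and the geometry becomes a linear
#' array with 20-um spacing.
#'
#' @param gt a [GroundTruthRecording-class].
#' @param copies number of channel-block copies.
#' @param shiftS time shift between consecutive blocks (s), ~0.1 by
#'   convention.
#' @return a [GroundTruthRecording-class] with `copies * nChannels`
#'   channels and `copies * nUnits` truth lists.
#' @export
replicateRecording <- function(gt, copies, shiftS = 0.1) {
  stopifnot(is(gt, "GroundTruthRecording"), copies >= 1)
  rec <- gt@recording
  ns <- ncol(rec@signal)
  shiftSamples <- round(shiftS * rec@rateHz)
  if (shiftSamples * (copies - 1L) >= ns)
    stop("total shift exceeds the recording duration")
  nch <- nrow(rec@signal)
  out <- matrix(0, nch * copies, ns)
  newTimes <- list()
  newTemplates <- list()
  for (i in seq_len(copies)) {
    off <- (i - 1L) * shiftSamples
    rows <- (i - 1L) * nch + seq_len(nch)
    if (off == 0L) out[rows, ] <- rec@signal
    else out[rows, (off + 1L):ns] <- rec@signal[, 1:(ns - off)]
    for (u in seq_along(gt@trueTimes)) {
      tt <- gt@trueTimes[[u]] + off
      newTimes[[length(newTimes) + 1L]] <- tt[tt <= ns]
      tpl <- matrix(0, nch * copies, ncol(gt@trueTemplates[[u]]))
      tpl[rows, ] <- gt@trueTemplates[[u]]
      newTemplates[[length(newTemplates) + 1L]] <- tpl
    }
  }
  geom <- linearGeometry(nch * copies, 20)
  cov2 <- matrix(0, nch * copies, nch * copies)
  for (i in seq_len(copies)) {
    rows <- (i - 1L) * nch + seq_len(nch)
    cov2[rows, rows] <- gt@noiseCov
  }
  rec2 <- new("Recording", signal = out, rateHz = rec@rateHz,
              positionsUm = geom, band = rec@band)
  new("GroundTruthRecording", recording = rec2, trueTimes = newTimes,
      trueTemplates = newTemplates, jitterSd = gt@jitterSd,
      noiseCov = cov2, refractoryMs = gt@refractoryMs)
}

#' Inject scaled template trains into an existing recording
#'
#' Adds amplitude-jittered copies of the given templates at the given
#' times, turning any recording into a ground-truth recording (the
#' artificial-spike protocol).
#'
#' @param rec a [Recording-class].
#' @param templates list of channels x samples template matrices.
#' @param times list of trough sample-index vectors, one per template.
#' @param jitterSd amplitude jitter SD (fraction); scales ~ Normal(1,
#'   jitterSd) truncated at zero.
#' @param seed integer RNG seed.
#' @param refractoryMs refractory period the supplied trains respect.
#' @return a [GroundTruthRecording-class].
#' @export
injectSpikes <- function(rec, templates, times, jitterSd = 0.10, seed = 1L,
                         refractoryMs = 2) {
  stopifnot(is(rec, "Recording"), length(templates) == length(times))
  nch <- nrow(rec@signal)
  ns <- ncol(rec@signal)
  for (tpl in templates)
    if (nrow(tpl) != nch)
      stop("template channel count does not match the recording")
  for (tt in times)
    if (length(tt) && (min(tt) < 1 || max(tt) > ns))
      stop("injection times fall outside the recording")
  withSeed(seed, {
    signal <- rec@signal
    for (u in seq_along(templates)) {
      scales <- rnorm(length(times[[u]]), 1, jitterSd)
      scales[scales < 0] <- 0
      signal <- addTemplateAt(signal, templates[[u]], times[[u]], scales)
    }
    rec2 <- new("Recording", signal = signal, rateHz = rec@rateHz,
                positionsUm = rec@positionsUm, band = rec@band)
    new("GroundTruthRecording", recording = rec2, trueTimes = times,
        trueTemplates = templates, jitterSd = jitterSd,
        noiseCov = matrix(0, nch, nch), refractoryMs = refractoryMs)
  })
}
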