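# Detection and preprocessing: zero-phase band-pass, robust negative
# threshold, cross-channel lumping within the censored period, waveform
# extraction and resampling, spatial noise whitening, spatial windowing.

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward-backward (zero phase) to every
#' channel.
#'
#' @param rec a [Recording-class].
#' @param band length-2 numeric band edges (Hz); defaults to the
#'   recording's band.
#' @return the filtered [Recording-class] with its band slot set.
#' @export
bandpassFilter <- function(rec, band = rec@band) {
  stopifnot(is(rec, "Recording"))
  if (band[2] >= rec@rateHz / 2)
    stop("upper band edge must be below the Nyquist frequency")
  bf <- signal::butter(4, band / (rec@rateHz / 2), type = "pass")
  sig <- rec@signal
  for (ch in seq_len(nrow(sig)))
    sig[ch, ] <- signal::filtfilt(bf, sig[ch, ])
  new("Recording", signal = sig, rateHz = rec@rateHz,
      positionsUm = rec@positionsUm, band = band)
}

#' Robust detection threshold
#'
#' `T = -zTh * median(|V|) / 0.6745`: the median absolute deviation scaled
#' to estimate the noise SD under Gaussianity, times the threshold
#' multiplier, with a negative sign (spikes are negative deflections).
#'
#' @param channelSignal numeric vector of one channel's samples.
#' @param zTh threshold multiplier (default 5).
#' @return the threshold in the signal's units (<= 0). An all-zero channel
#'   yields 0 with a warning (degenerate).
#' @export
detectionThreshold <- function(channelSignal, zTh = 5) {
  stopifnot(length(channelSignal) > 0)
  m <- median(abs(channelSignal))
  if (m == 0) {
    warning("degenerate channel: median absolute signal is zero")
    return(0)
  }
  -zTh * m / 0.6745
}

# Per-channel negative-threshold crossings; each crossing is resolved to
# the trough within the next `troughBoundMs`. Returns a data.frame
# (time, channel, amp).
channelDetections <- function(signal, rateHz, zTh, troughBoundMs = 1) {
  bound <- max(1L, round(troughBoundMs / 1000 * rateHz))
  out <- vector("list", nrow(signal))
  globalMin <- min(signal)
  for (ch in seq_len(nrow(signal))) {
    v <- signal[ch, ]
    th <- suppressWarnings(detectionThreshold(v, zTh))
    # on (near-)noiseless recordings the robust noise estimate collapses
    # to the filter-ringing floor; keep the threshold at no less than 5%
    # of the array-wide largest deflection so ringing is never detected
    if (globalMin < 0) th <- min(th, 0.05 * globalMin)
    if (th == 0) next
    below <- v < th
    cross <- which(below & !c(FALSE, below[-length(below)]))
    if (!length(cross)) next
    tt <- integer(length(cross))
    aa <- numeric(length(cross))
    for (i in seq_along(cross)) {
      hi <- min(length(v), cross[i] + bound)
      seg <- v[cross[i]:hi]
      tt[i] <- cross[i] + which.min(seg) - 1L
      aa[i] <- min(seg)
    }
    keep <- !duplicated(tt)
    out[[ch]] <- data.frame(time = tt[keep], channel = ch, amp = aa[keep])
  }
  det <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(det)) det <- data.frame(time = integer(), channel = integer(),
                                      amp = numeric())
  det[order(det$time, det$channel), , drop = FALSE]
}

# Greedy lumping of detections: events within tauC samples of the lump's
# latest event and on channels within lumpRadiusUm of any lumped channel
# belong to the same spike. Returns per-lump: time of the largest
# deflection and the contiguous channel range covering the lump.
lumpDetections <- function(det, positionsUm, tauCSamples, lumpRadiusUm) {
  n <- nrow(det)
  if (n == 0L)
    return(data.frame(time = integer(), amp = numeric(),
                      chLo = integer(), chHi = integer()))
  D <- as.matrix(stats::dist(positionsUm))
  lumpId <- integer(n)
  lumps <- list()  # each: list(lastTime, channels, bestIdx)
  openLumps <- integer(0)
  for (i in seq_len(n)) {
    t <- det$time[i]; ch <- det$channel[i]
    # retire lumps too old to accept this (time-sorted) event
    if (length(openLumps))
      openLumps <- openLumps[vapply(openLumps, function(l)
        t - lumps[[l]]$lastTime <= tauCSamples, TRUE)]
    joined <- 0L
    for (l in openLumps) {
      if (min(D[ch, lumps[[l]]$channels]) < lumpRadiusUm) { joined <- l; break }
    }
    if (joined) {
      lumps[[joined]]$lastTime <- t
      lumps[[joined]]$channels <- union(lumps[[joined]]$channels, ch)
      if (det$amp[i] < det$amp[lumps[[joined]]$bestIdx])
        lumps[[joined]]$bestIdx <- i
      lumpId[i] <- joined
    } else {
      lumps[[length(lumps) + 1L]] <- list(lastTime = t, channels = ch,
                                          bestIdx = i)
      openLumps <- c(openLumps, length(lumps))
      lumpId[i] <- length(lumps)
    }
  }
  res <- lapply(lumps, function(l)
    data.frame(time = det$time[l$bestIdx], amp = det$amp[l$bestIdx],
               chLo = min(l$channels), chHi = max(l$channels)))
  res <- do.call(rbind, res)
  res[order(res$time), , drop = FALSE]
}

# Linear resampling operator taking a length-nIn window to the target rate.
resampleMatrix <- function(nIn, rateIn, rateOut) {
  if (rateIn == rateOut) return(diag(nIn))
  basis <- diag(nIn)
  cols <- lapply(seq_len(nIn), function(j)
    as.numeric(signal::resample(basis[, j], rateOut, rateIn)))
  do.call(cbind, cols)  # nOut x nIn
}

#' Detect spikes and extract waveforms
#'
#' Negative-threshold crossings are found independently per channel; spike
#' times are the troughs following the crossings (bounded to 1 ms).
#' Detections closer in time than the censored period and on channels
#' closer than the lumping radius are merged, keeping the time of the
#' largest deflection; the smallest contiguous channel range covering the
#' lumped detections becomes the spike's spatial window. Waveforms are cut
#' over `windowMs` centred on the trough across all channels and resampled
#' at the Nyquist rate of the band (2 x upper edge). Spikes whose window
#' would extend past the recording are dropped (counted in `nDropped`).
#'
#' @param rec a band-pass filtered [Recording-class].
#' @param zTh threshold multiplier (default 5).
#' @param tauCMs censored period in ms (default 0.6).
#' @param lumpRadiusUm lumping distance in um (default 60).
#' @param windowMs waveform window in ms (default 6).
#' @param alignUpsample integer upsampling factor for sub-sample trough
#'   alignment (default 4); waveforms are cut on an upsampled grid
#'   re-centred on the interpolated trough, which stops detection-noise
#'   jitter of +/-1 raw sample from splitting a unit into shifted-copy
#'   clusters. Set to 1 to disable.
#' @return a [SpikeEnsemble-class] (not yet whitened).
#' @export
detectSpikes <- function(rec, zTh = 5, tauCMs = 0.6, lumpRadiusUm = 60,
                         windowMs = 6, alignUpsample = 4L) {
  stopifnot(is(rec, "Recording"))
  sig <- rec@signal
  det <- channelDetections(sig, rec@rateHz, zTh)
  lum <- lumpDetections(det, rec@positionsUm,
                        tauCSamples = round(tauCMs / 1000 * rec@rateHz),
                        lumpRadiusUm = lumpRadiusUm)
  # distinct lumps can in principle share a trough sample on distant
  # channels; keep the larger deflection so times stay strictly increasing
  if (anyDuplicated(lum$time)) {
    lum <- lum[order(lum$time, lum$amp), ]
    lum <- lum[!duplicated(lum$time), ]
  }
  waveRate <- 2 * rec@band[2]
  # upsampled grid on which the trough is localized; the output grid must
  # decimate it by an integer step
  up <- as.integer(alignUpsample)
  while (up <= 16L && (rec@rateHz * up) %% waveRate != 0) up <- up + 1L
  if ((rec@rateHz * up) %% waveRate != 0) up <- 1L
  upRate <- rec@rateHz * up
  step <- if ((upRate %% waveRate) == 0) as.integer(upRate / waveRate) else NA
  marginMs <- 1.5  # extra input so the aligned window stays in range
  halfIn <- round((windowMs / 2 + marginMs) / 1000 * rec@rateHz)
  halfOut <- round(windowMs / 2 / 1000 * waveRate)
  nIn <- 2L * halfIn + 1L
  ns <- ncol(sig)
  inRange <- lum$time - halfIn >= 1 & lum$time + halfIn <= ns
  nDropped <- sum(!inRange)
  lum <- lum[inRange, , drop = FALSE]
  n <- nrow(lum)
  wf <- array(0, c(n, nrow(sig), 2L * halfOut + 1L))
  if (n > 0L) {
    Rup <- resampleMatrix(nIn, rec@rateHz, upRate)  # nUp x nIn
    nUp <- nrow(Rup)
    centreUp <- round((halfIn) / rec@rateHz * upRate) + 1L
    searchUp <- round(1.2e-3 * upRate)  # trough search span around centre
    # Gaussian matched-smoothing kernel (sigma 0.12 ms): the argmin of the
    # raw trace wanders with noise on flat trough bottoms; smoothing makes
    # the alignment a matched-filter peak estimate
    ks <- 0.12e-3 * upRate
    khw <- ceiling(3 * ks)
    kern <- exp(-(seq(-khw, khw))^2 / (2 * ks^2))
    kern <- kern / sum(kern)
    for (i in seq_len(n)) {
      seg <- sig[, (lum$time[i] - halfIn):(lum$time[i] + halfIn),
                 drop = FALSE]
      segUp <- seg %*% t(Rup)                     # ch x nUp
      peakCh <- which.min(seg[, halfIn + 1L])     # deepest channel at trough
      lo <- max(1L, centreUp - searchUp)
      hi <- min(nUp, centreUp + searchUp)
      sm <- stats::filter(segUp[peakCh, ], kern, sides = 2)
      sm[is.na(sm)] <- 0
      tr <- lo + which.min(sm[lo:hi]) - 1L
      idx <- tr + (seq_len(2L * halfOut + 1L) - halfOut - 1L) * step
      if (idx[1] < 1L || idx[length(idx)] > nUp) {
        shift <- max(1L - idx[1], 0L) + min(nUp - idx[length(idx)], 0L)
        idx <- idx + shift
      }
      wf[i, , ] <- segUp[, idx, drop = FALSE]
    }
  }
  new("SpikeEnsemble", times = as.numeric(lum$time), waveforms = wf,
      windows = cbind(lum$chLo, lum$chHi), waveRateHz = waveRate,
      recRateHz = rec@rateHz, tauWfMs = windowMs, whitened = FALSE,
      nDropped = as.integer(nDropped))
}

#' Estimate the spatial noise covariance from spike-free snippets
#'
#' Scans the recording in steps of the snippet length and keeps windows in
#' which no channel exceeds 4 x the robust noise SD
#' (`median(|V|)/0.6745`), up to `maxSnippets` windows; the channels x
#' channels covariance is estimated over all retained samples.
#'
#' @param rec a filtered [Recording-class].
#' @param snippetSamples snippet length in samples (default: 6 ms worth).
#' @param maxSnippets cap on the number of snippets (default 5000).
#' @return channels x channels covariance matrix.
#' @export
noiseCovariance <- function(rec, snippetSamples = NULL, maxSnippets = 5000L) {
  sig <- rec@signal
  if (is.null(snippetSamples))
    snippetSamples <- round(6 / 1000 * rec@rateHz)
  th <- apply(sig, 1L, function(v) 4 * median(abs(v)) / 0.6745)
  quiet <- colSums(abs(sig) > th) == 0L
  starts <- seq(1L, ncol(sig) - snippetSamples + 1L, by = snippetSamples)
  ok <- vapply(starts, function(s)
    all(quiet[s:(s + snippetSamples - 1L)]), TRUE)
  starts <- head(starts[ok], maxSnippets)
  if (length(starts) < 2L)
    stop("not enough spike-free snippets to estimate the noise covariance")
  idx <- as.vector(outer(0:(snippetSamples - 1L), starts, "+"))
  X <- sig[, idx, drop = FALSE]
  cov(t(X))
}

# Symmetric (ZCA) inverse square root with ridge regularization when the
# conditioning exceeds 1e8.
zcaWhitener <- function(C) {
  if (sum(diag(C)) < .Machine$double.eps * nrow(C))
    return(diag(nrow(C)))  # no measurable noise: nothing to whiten
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) <= 0 || max(e$values) / min(e$values) > 1e8) {
    warning("near-singular noise covariance; adding ridge regularization")
    lam <- 1e-6 * sum(diag(C)) / nrow(C)
    C <- C + diag(lam, nrow(C))
    e <- eigen(C, symmetric = TRUE)
  }
  e$vectors %*% diag(1 / sqrt(e$values), nrow(C)) %*% t(e$vectors)
}

#' Spatially whiten a spike ensemble
#'
#' Premultiplies every waveform (channel dimension) by the inverse
#' symmetric square root of the spatial noise covariance, so that
#' background noise becomes approximately unit-variance and uncorrelated
#' across channels.
#'
#' @param ensemble a [SpikeEnsemble-class].
#' @param rec the filtered [Recording-class] the spikes came from.
#' @param noiseCov optional pre-computed covariance (else estimated with
#'   [noiseCovariance()]).
#' @return the whitened [SpikeEnsemble-class].
#' @export
whitenWaveforms <- function(ensemble, rec, noiseCov = NULL) {
  stopifnot(is(ensemble, "SpikeEnsemble"))
  if (is.null(noiseCov)) {
    snip <- dim(ensemble@waveforms)[3]
    snipOrig <- round(snip * rec@rateHz / ensemble@waveRateHz)
    noiseCov <- noiseCovariance(rec, snippetSamples = snipOrig)
  }
  W <- zcaWhitener(noiseCov)
  wf <- ensemble@waveforms
  for (i in seq_len(dim(wf)[1]))
    wf[i, , ] <- W %*% wf[i, , ]
  initialize(ensemble, waveforms = wf, whitened = TRUE)
}

#' Spatially window whitened waveforms
#'
#' Channels farther than `marginUm` from every channel of a spike's
#' spatial window are replaced by unit-variance Gaussian noise (the
#' whitened noise floor), suppressing uninformative distant channels on
#' large arrays. Tetrode-sized arrays (<= 4 channels) pass through
#' unchanged.
#'
#' @param ensemble a whitened [SpikeEnsemble-class].
#' @param positionsUm channel geometry.
#' @param marginUm margin in micrometres (default 40, i.e. 2 sites at
#'   20-um pitch).
#' @param seed RNG seed for the replacement noise.
#' @return the windowed [SpikeEnsemble-class].
#' @export
spatialWindow <- function(ensemble, positionsUm, marginUm = 40, seed = 1L) {
  stopifnot(is(ensemble, "SpikeEnsemble"))
  nch <- dim(ensemble@waveforms)[2]
  if (nch <= 4L) return(ensemble)
  D <- as.matrix(stats::dist(positionsUm))
  wf <- ensemble@waveforms
  ns <- dim(wf)[3]
  withSeed(seed, {
    for (i in seq_len(dim(wf)[1])) {
      win <- ensemble@windows[i, 1]:ensemble@windows[i, 2]
      dmin <- apply(D[, win, drop = FALSE], 1L, min)
      far <- which(dmin > marginUm)
      if (length(far))
        wf[i, far, ] <- matrix(rnorm(length(far) * ns), length(far), ns)
    }
  })
  initialize(ensemble, waveforms = wf)
}
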