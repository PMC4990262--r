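# Assignment of the chi^2-gated leftovers: direct template fit when a
# single final template explains the waveform, greedy matching pursuit
# over shifted templates when it looks like an overlap of several spikes.

# Shift a channels x samples template right by tau samples (zero padded).
shiftTemplate <- function(tpl, tau) {
  ns <- ncol(tpl)
  out <- matrix(0, nrow(tpl), ns)
  if (tau >= 0) {
    if (tau < ns) out[, (tau + 1L):ns] <- tpl[, 1:(ns - tau)]
  } else {
    if (-tau < ns) out[, 1:(ns + tau)] <- tpl[, (1L - tau):ns]
  }
  out
}

#' Assign leftover spikes by template matching and matching pursuit
#'
#' Each waveform is first fitted against every final template with the
#' bounded amplitude scale; if the best residual chi^2 is at or below the
#' gate threshold the spike is assigned outright. Otherwise the spike is
#' treated as a putative overlap: the residual of the best fit is
#' iteratively explained by the best (cluster, delay, amplitude) over all
#' integer delays within +/- half the waveform length, for up to
#' `maxRounds` rounds, accepting the decomposition once the residual
#' drops below threshold. Overlap components with |delay| >= the censored
#' period correspond to events the detector has already seen separately
#' and are not re-emitted; components with smaller delays are recorded.
#' Spikes whose residual never passes the gate are left unclassified.
#'
#' @param wf leftover waveform array (n x channels x samples).
#' @param templates list of channels x samples final-cluster templates.
#' @param chi2Th the chi^2 gate threshold.
#' @param tauCMs censored period (ms).
#' @param waveRateHz waveform sample rate (Hz).
#' @param maxRounds pursuit rounds (default 3).
#' @return list with `labels` (integer per spike, -1 = unclassified) and
#'   `components` (data.frame spike, cluster, tauSamples, a).
#' @export
assignRemainder <- function(wf, templates, chi2Th, tauCMs, waveRateHz,
                            maxRounds = 3L) {
  n <- dim(wf)[1]
  if (n == 0L || length(templates) == 0L)
    return(list(labels = rep(-1L, n),
                components = data.frame(spike = integer(),
                                        cluster = integer(),
                                        tauSamples = integer(),
                                        a = numeric())))
  ns <- dim(wf)[3]
  tauC <- round(tauCMs / 1000 * waveRateHz)
  Tflat <- do.call(rbind, lapply(templates, function(t) as.numeric(t(t))))
  # bank of all (cluster, delay) shifted templates for the pursuit
  delays <- seq(-floor((ns - 1) / 2), floor((ns - 1) / 2))
  bank <- do.call(rbind, lapply(seq_along(templates), function(u)
    do.call(rbind, lapply(delays, function(tau)
      as.numeric(t(shiftTemplate(templates[[u]], tau)))))))
  bankCluster <- rep(seq_along(templates), each = length(delays))
  bankTau <- rep(delays, length(templates))
  S <- flattenWaveforms(wf)
  fit0 <- templateFitAll(S, Tflat)
  best0 <- max.col(-fit0$chi2, ties.method = "first")
  chi0 <- fit0$chi2[cbind(seq_len(n), best0)]
  # the gate threshold can collapse to numerical dust on noiseless data;
  # never demand a fit better than the spike's own energy resolution
  thFor <- pmax(chi2Th, 1e-9 * rowMeans(S^2))
  labels <- rep(-1L, n)
  comps <- list()
  for (i in seq_len(n)) {
    if (chi0[i] <= thFor[i]) {
      labels[i] <- best0[i]
      comps[[length(comps) + 1L]] <-
        data.frame(spike = i, cluster = best0[i], tauSamples = 0L,
                   a = fit0$a[i, best0[i]])
      next
    }
    # putative overlap: greedy pursuit over (cluster, delay) from the raw
    # waveform — a lumped event's trough is not the alignment of either
    # component, so even the first component is fit over all delays
    r <- S[i, ]
    found <- list()
    accepted <- FALSE
    for (round in seq_len(maxRounds)) {
      fr <- templateFitAll(matrix(r, 1L), bank)
      j <- which.min(fr$chi2[1L, ])
      r <- r - fr$a[1L, j] * bank[j, ]
      found[[length(found) + 1L]] <-
        data.frame(spike = i, cluster = bankCluster[j],
                   tauSamples = bankTau[j], a = fr$a[1L, j])
      if (mean(r^2) <= thFor[i]) { accepted <- TRUE; break }
    }
    if (accepted) {
      labels[i] <- found[[1L]]$cluster
      keep <- vapply(found, function(f) abs(f$tauSamples) < tauC, TRUE)
      comps <- c(comps, found[keep])
    }
  }
  components <- if (length(comps)) do.call(rbind, comps)
                else data.frame(spike = integer(), cluster = integer(),
                                tauSamples = integer(), a = numeric())
  list(labels = labels, components = components)
}
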