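# Pipeline orchestration: filter -> detect -> whiten -> window ->
# features -> label ensemble -> chi^2 gate -> consensus -> overlap
# pursuit -> quality report.

#' Sort a recording
#'
#' Runs the full consensus-sorting pipeline with the given configuration
#' and returns every intermediate product plus the per-unit quality
#' report. All randomness derives from `config$masterSeed`; identical
#' input and config reproduce the output exactly.
#'
#' @param rec a [Recording-class] (raw or filtered).
#' @param config a `SortConfig` from [sortConfig()].
#' @param verbose log per-stage counts with `message()` (default TRUE).
#' @return a list of class `SortResult`: `ensemble` (windowed
#'   [SpikeEnsemble-class]), `features`, `labelEnsemble`, `gate`,
#'   `model` ([ConsensusModel-class]), `templates` (final full-window
#'   templates), `times`, `labels` (per detected spike; -1 = unclassified
#'   or excluded), `unitTrains` (per-unit output spike trains including
#'   accepted overlap components), `overlapComponents`, `quality`
#'   ([QualityReport-class]), `K`, and `config`.
#' @export
sortSpikes <- function(rec, config = sortConfig(), verbose = TRUE) {
  stopifnot(is(rec, "Recording"))
  say <- function(...) if (verbose) message(sprintf(...))
  seeds <- deriveSeeds(config$masterSeed, 4L)

  filt <- bandpassFilter(rec, config$band)
  ens <- detectSpikes(filt, zTh = config$zTh, tauCMs = config$tauCMs,
                      lumpRadiusUm = config$lumpRadiusUm,
                      windowMs = config$windowMs)
  say("detected %d spikes (%d dropped at edges)", nSpikes(ens),
      ens@nDropped)
  if (nSpikes(ens) < 10L) stop("sort failed at detection: too few spikes")
  ens <- whitenWaveforms(ens, filt)
  ens <- spatialWindow(ens, filt@positionsUm, seed = seeds[1])

  feat <- extractFeatures(ens, tauWinMs = config$tauWinMs,
                          pThreshold = config$pLillie)
  say("retained %d non-Gaussian components", ncol(feat@values))

  S <- flattenWaveforms(
    cropWaveforms(ens@waveforms, ens@waveRateHz, config$tauWinMs))
  n <- nSpikes(ens)
  K <- config$K
  if (identical(K, "auto")) {
    cand <- 2^(1:12)
    cand <- cand[cand < sqrt(n)]
    if (length(cand) < 2L) cand <- unique(c(2L, max(2L, floor(sqrt(n)) - 1L)))
    K0 <- chooseK(feat@values, S, cand, seed = seeds[2])
    # the plateau onset over-counts waveform modes when amplitude jitter
    # splits a unit into scaled copies of one template; count the modes
    # that remain distinct under scale-invariant template comparison
    nModes <- countTemplateModes(
      oneIteration(feat@values, S, K0, seeds[2], iterMax = 300L)$templates)
    # the ensemble wants K comfortably above the mode count so successive
    # K-means runs carve the modes differently (diversity), but not the
    # very large K that freezes each spike into a stable micro-cell
    K <- min(max(4L * nModes, 2L), max(2L, floor(sqrt(n)) - 1L))
    say("chi^2 plateau at K = %d, %d distinct modes; using K = %d",
        K0, nModes, K)
  }
  le <- runEnsemble(feat@values, S, K, Nite = config$Nite,
                    masterSeed = seeds[3])
  gate <- chi2Gate(le, config$chi2Percentile)
  say("chi^2 gate kept %d / %d spikes (threshold %.4g)",
      length(gate$kept), n, gate$threshold)

  model <- consensusPartition(le, kept = gate$kept,
                              minCsize = config$minCsizeRange,
                              Pth = config$Pth, coreMode = config$coreMode)
  say("consensus: %d signatures, minCsize = %d, %d final clusters, %d excluded",
      nrow(model@P0), model@minCsize,
      length(unique(model@finalAssign[!is.na(model@finalAssign)])),
      sum(is.na(model@finalAssign)))

  # final full-window templates from the consensus-labelled spikes
  finals <- sort(unique(model@finalAssign[!is.na(model@finalAssign)]))
  templates <- lapply(finals, function(u) {
    idx <- model@keptIdx[!is.na(model@finalAssign) & model@finalAssign == u]
    apply(ens@waveforms[idx, , , drop = FALSE], c(2L, 3L), mean)
  })

  labels <- rep(-1L, n)
  keptLab <- model@finalAssign
  labels[model@keptIdx[!is.na(keptLab)]] <-
    match(keptLab[!is.na(keptLab)], finals)
  leftover <- setdiff(seq_len(n), model@keptIdx)
  pursuit <- assignRemainder(
    ens@waveforms[leftover, , , drop = FALSE], templates,
    chi2Th = gate$threshold, tauCMs = config$tauCMs,
    waveRateHz = ens@waveRateHz)
  labels[leftover] <- pursuit$labels
  if (nrow(pursuit$components))
    pursuit$components$spike <- leftover[pursuit$components$spike]
  say("pursuit assigned %d / %d leftover spikes; %d unclassified overall",
      sum(pursuit$labels > 0), length(leftover), sum(labels == -1L))

  quality <- buildQualityReport(model, le, ens, labels, templates, config)
  say("%d / %d units validated", sum(quality@units$validated),
      nrow(quality@units))

  # per-unit output trains: consensus-labelled spikes plus every accepted
  # matching-pursuit component (overlaps contribute one event per
  # component, at the component's delay)
  comp <- pursuit$components
  primDf <- data.frame(
    time = ens@times[labels > 0 & !(seq_len(n) %in% comp$spike)],
    unit = labels[labels > 0 & !(seq_len(n) %in% comp$spike)])
  compDf <- if (nrow(comp)) {
    data.frame(time = ens@times[comp$spike] +
                 round(comp$tauSamples * ens@recRateHz / ens@waveRateHz),
               unit = comp$cluster)
  } else primDf[0, ]
  tauCSamp <- round(config$tauCMs / 1000 * ens@recRateHz)
  unitTrains <- lapply(seq_along(templates), function(u) {
    base <- sort(primDf$time[primDf$unit == u])
    # add pursuit components unless they duplicate an event of this unit
    # that the detector already saw (within the censored period)
    extra <- sort(compDf$time[compDf$unit == u])
    for (t in extra) {
      if (!length(base) || min(abs(base - t)) >= tauCSamp)
        base <- sort(c(base, t))
    }
    base
  })

  structure(list(ensemble = ens, features = feat, labelEnsemble = le,
                 gate = gate, model = model, templates = templates,
                 times = ens@times, labels = labels,
                 unitTrains = unitTrains,
                 overlapComponents = pursuit$components,
                 quality = quality, K = K, config = config),
            class = "SortResult")
}

# Count waveform modes among templates, treating templates that are
# scaled copies of one another (relative residual under unconstrained
# 1-D scaling below relTol) as the same mode.
countTemplateModes <- function(templates, relTol = 0.25) {
  modes <- list()
  for (i in seq_len(nrow(templates))) {
    ti <- templates[i, ]
    ei <- mean(ti^2)
    if (ei == 0) next
    dup <- FALSE
    for (mo in modes) {
      a <- sum(ti * mo) / sum(mo^2)
      if (mean((ti - a * mo)^2) / ei < relTol) { dup <- TRUE; break }
    }
    if (!dup) modes[[length(modes) + 1L]] <- ti
  }
  max(1L, length(modes))
}

# Assemble the per-unit quality table and burst-split flags.
buildQualityReport <- function(model, le, ens, labels, templates, config) {
  err <- unitErrorEstimates(model, le)
  finalsOrig <- sort(unique(model@finalAssign[!is.na(model@finalAssign)]))
  err <- err[match(finalsOrig, err$unit), ]
  nU <- length(finalsOrig)
  # isolation distance in the 12-first-PC space of the full waveforms
  X <- flattenWaveforms(ens@waveforms)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  p12 <- pc$x[, seq_len(min(12L, ncol(pc$x))), drop = FALSE]
  rows <- lapply(seq_len(nU), function(ui) {
    idx <- which(labels == ui)
    snr <- if (length(idx) >= 2L)
      unitSnr(ens@waveforms[idx, , , drop = FALSE]) else 0
    isoD <- if (length(idx) >= 2L && length(idx) * 2L <= nrow(p12))
      isolationDistance(p12[idx, , drop = FALSE],
                        p12[-idx, , drop = FALSE]) else NA_real_
    isiV <- isiViolationRate(ens@times[idx], ens@recRateHz)
    data.frame(unit = ui, n = length(idx),
               PFP = err$PFP[ui], PFN = err$PFN[ui],
               SNR = snr, isiViolation = isiV, isolationDistance = isoD)
  })
  units <- do.call(rbind, rows)
  units$validated <- (units$PFP + units$PFN) < config$misclassGate &
    units$SNR > config$snrGate & units$isiViolation < config$isiGate
  Pmis <- model@Pmis
  flags <- if (nU >= 2L && all(dim(Pmis) == nU))
    flagBurstMerges(templates, Pmis) else
    data.frame(unitA = integer(), unitB = integer(),
               correlation = numeric(), Pmis = numeric())
  new("QualityReport", units = units, mergeFlags = flags)
}

#' Apply the flag-guided curation merges
#'
#' Sub-clustering of one cell's spikes (amplitude variability, bursting)
#' is a documented behaviour of the consensus cut at `Pth = 0.15`; such
#' splits are detected by the burst-merge flags (template correlation
#' above 0.70 and misclassification probability above 0.05) and resolved
#' by merging the flagged pair — the curation the flags exist to guide.
#' This function applies those merges deterministically (transitively,
#' re-flagging after each pass up to `maxPasses`). It is an explicit
#' post-processing step: [sortSpikes()] never applies it on its own.
#'
#' @param result a `SortResult` from [sortSpikes()].
#' @param maxPasses re-flagging passes (default 3).
#' @return the curated `SortResult` (labels, unit trains, templates,
#'   quality and the model's final assignment updated).
#' @export
curateFlaggedMerges <- function(result, maxPasses = 3L) {
  le <- result$labelEnsemble
  model <- result$model
  ens <- result$ensemble
  # signature-level view for recomputing Pmis after merging
  G <- max(model@signatureId)
  first <- match(seq_len(G), model@signatureId)
  Lg <- le@labels[model@keptIdx[first], , drop = FALSE]
  sizes <- tabulate(model@signatureId, G)
  keptAssign <- result$labels[model@keptIdx]  # 1..nU over kept spikes
  sigAssign <- keptAssign[first]
  sigAssign[sigAssign < 1L] <- NA_integer_
  labels <- result$labels
  templates <- result$templates
  unitTrains <- result$unitTrains
  for (pass in seq_len(maxPasses)) {
    nU <- length(templates)
    if (nU < 2L) break
    Pmis <- pmisMatrix(Lg, sizes, sigAssign)
    flags <- flagBurstMerges(templates, Pmis)
    if (!nrow(flags)) break
    map <- seq_len(nU)
    find <- function(x) { while (map[x] != x) x <- map[x]; x }
    for (r in seq_len(nrow(flags)))
      map[find(flags$unitB[r])] <- find(flags$unitA[r])
    roots <- vapply(seq_len(nU), find, 1L)
    newId <- match(roots, sort(unique(roots)))
    labels[labels > 0] <- newId[labels[labels > 0]]
    sigAssign[!is.na(sigAssign)] <- newId[sigAssign[!is.na(sigAssign)]]
    counts <- vapply(seq_len(nU), function(u) sum(result$labels == u), 1)
    templates <- lapply(seq_len(max(newId)), function(u) {
      members <- which(newId == u)
      Reduce(`+`, lapply(members, function(m)
        templates[[m]] * counts[m])) / sum(counts[members])
    })
    unitTrains <- lapply(seq_len(max(newId)), function(u)
      sort(unique(unlist(unitTrains[newId == u]))))
  }
  finalAssign <- model@finalAssign
  finalAssign[] <- sigAssign[model@signatureId]
  model2 <- initialize(model, finalAssign = as.integer(finalAssign),
                       Pmis = pmisMatrix(Lg, sizes, sigAssign))
  quality <- buildQualityReport(model2, le, ens, labels, templates,
                                result$config)
  out <- result
  out$model <- model2
  out$labels <- labels
  out$templates <- templates
  out$unitTrains <- unitTrains
  out$quality <- quality
  out
}

#' Consensus clustering of a plain point set
#'
#' The point-cloud pipeline: repeated K-means partitions combined by
#' consensus, as used to recover distorted 2-D clusters that a single
#' K-means run cannot. No chi^2 gate is applied (every point is kept).
#'
#' @param points n x d point matrix.
#' @param K clusters per K-means run (default `floor(sqrt(n))`).
#' @param Nite number of runs (default 200).
#' @param minCsize core-size threshold (single value or range).
#' @param Pth misclassification cut level (default 0.05 for point data).
#' @param masterSeed RNG seed.
#' @return list with `labels` (final cluster per point, NA = excluded)
#'   and `model` (the [ConsensusModel-class]).
#' @export
consensusClusterPoints <- function(points, K = floor(sqrt(nrow(points))),
                                   Nite = 200L, minCsize = 8L,
                                   Pth = 0.05, masterSeed = 1L) {
  le <- kmeansEnsemble(points, K = K, Nite = Nite, masterSeed = masterSeed)
  model <- consensusPartition(le, minCsize = minCsize, Pth = Pth)
  labels <- rep(NA_integer_, nrow(points))
  labels[model@keptIdx] <- model@finalAssign
  list(labels = labels, model = model)
}

#' Score a sort result against its ground truth
#'
#' Matches every truth unit to the sorted unit with the most hits within
#' the window, corrects for truth spikes the detector never saw (FNd),
#' and reports the detection-corrected and percentage error rates.
#'
#' @param result a `SortResult` from [sortSpikes()].
#' @param gt the [GroundTruthRecording-class] that was sorted.
#' @param windowMs matching half-window in ms (default 2).
#' @return data.frame, one row per truth unit: matched unit, TP, FP, FN,
#'   FNd, FPrate, FNrate, pctFP, pctFN.
#' @export
evaluateSorting <- function(result, gt, windowMs = 2) {
  rateHz <- gt@recording@rateHz
  win <- round(windowMs / 1000 * rateHz)
  sortedList <- result$unitTrains
  units <- seq_along(sortedList)
  rows <- lapply(seq_along(gt@trueTimes), function(tu) {
    truth <- sort(gt@trueTimes[[tu]])
    # truth spikes with no detected event at all, regardless of label
    FNd <- sum(vapply(truth, function(t)
      !any(abs(result$times - t) <= win), TRUE))
    m <- bestMatchUnit(sortedList, truth, win, FNd = FNd)
    data.frame(truthUnit = tu, matchedUnit = units[m$matchedUnit],
               TP = m$TP, FP = m$FP, FN = m$FN, FNd = m$FNd,
               FPrate = m$FPrate, FNrate = m$FNrate,
               pctFP = m$pctFP, pctFN = m$pctFN)
  })
  do.call(rbind, rows)
}
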