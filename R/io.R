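# File interfaces: recordings as flat float32 binary + JSON sidecar,
# ground-truth and final labels as CSV, linkage as a JSON merge list,
# configs as YAML.

#' Write / read a recording as flat binary + JSON sidecar
#'
#' The signal is stored column-major (sample-major: all channels of sample
#' 1, then sample 2, ...) as little-endian float32 in `<path>.bin`, with a
#' JSON sidecar `<path>.json` holding `rate_hz`, `n_channels`, `band_hz`
#' and `positions_um`.
#'
#' @param rec a [Recording-class].
#' @param path file stem (no extension).
#' @return `writeRecording` returns `path` invisibly; `readRecording`
#'   returns a [Recording-class].
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "Recording"))
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(rec@signal), con, size = 4L, endian = "little")
  side <- list(rate_hz = rec@rateHz,
               n_channels = nrow(rec@signal),
               band_hz = rec@band,
               positions_um = unname(rec@positionsUm))
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRecording
#' @export
readRecording <- function(path) {
  sidecarPath <- paste0(path, ".json")
  if (!file.exists(sidecarPath))
    stop("missing sidecar file: ", sidecarPath)
  side <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
  for (key in c("rate_hz", "n_channels", "positions_um"))
    if (is.null(side[[key]]))
      stop("sidecar is missing required key '", key, "'")
  nch <- as.integer(side$n_channels)
  binPath <- paste0(path, ".bin")
  nVals <- file.size(binPath) / 4L
  con <- file(binPath, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = nVals, size = 4L, endian = "little")
  band <- if (!is.null(side$band_hz)) as.numeric(side$band_hz)
          else c(200, 4000)
  new("Recording", signal = matrix(x, nrow = nch),
      rateHz = as.numeric(side$rate_hz),
      positionsUm = as.matrix(side$positions_um),
      band = band)
}

#' Write / read ground-truth spike times as CSV
#'
#' Columns `unit_id` (1-based) and `time_sample` (1-based trough sample).
#'
#' @param trueTimes list of per-unit sample-index vectors, or a
#'   [GroundTruthRecording-class].
#' @param path CSV file path.
#' @export
writeTruthCsv <- function(trueTimes, path) {
  if (is(trueTimes, "GroundTruthRecording"))
    trueTimes <- trueTimes@trueTimes
  df <- data.frame(
    unit_id = rep(seq_along(trueTimes), lengths(trueTimes)),
    time_sample = unlist(trueTimes, use.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTruthCsv
#' @export
readTruthCsv <- function(path) {
  df <- read.csv(path)
  split(df$time_sample, factor(df$unit_id, levels = sort(unique(df$unit_id))))
}

#' Export final labels
#'
#' `writeLabelsCsv` writes (time_sample, unit_id) pairs, unclassified and
#' excluded spikes carrying unit_id -1. `writePhy` writes the flat binary
#' pair `spike_times` (int64... stored as float64 sample indices) and
#' `spike_clusters` (int32) understood by phy-style viewers.
#'
#' @param times spike times (sample indices).
#' @param labels integer labels, -1 for unclassified.
#' @param path CSV path (`writeLabelsCsv`) or directory (`writePhy`).
#' @export
writeLabelsCsv <- function(times, labels, path) {
  stopifnot(length(times) == length(labels))
  write.csv(data.frame(time_sample = times, unit_id = labels), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname writeLabelsCsv
#' @export
writePhy <- function(times, labels, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(path, "spike_times.npy.bin"), "wb")
  writeBin(as.double(times), con, size = 8L, endian = "little")
  close(con)
  con <- file(file.path(path, "spike_clusters.npy.bin"), "wb")
  writeBin(as.integer(labels), con, size = 4L, endian = "little")
  close(con)
  invisible(path)
}

#' Export a single-link tree as a JSON merge list
#'
#' @param tree an `hclust` object.
#' @param path JSON file path.
#' @export
writeLinkageJson <- function(tree, path) {
  merges <- lapply(seq_len(nrow(tree$merge)), function(i) {
    list(left = tree$merge[i, 1], right = tree$merge[i, 2],
         height = tree$height[i])
  })
  jsonlite::write_json(list(merge = merges, order = tree$order),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Sorting configuration
#'
#' Bundles every tunable of the pipeline with the method's default values:
#' detection threshold multiplier `zTh = 5`, censored period 0.6 ms,
#' lumping radius 60 um, 6-ms waveform window, 2.5-ms feature window,
#' Lilliefors level 0.01, automatic K, `Nite = 100` iterations, 95 percent
#' chi-square gate, core-size threshold 8, `Pth = 0.15`, and validation
#' gates SNR > 4, PFP+PFN < 0.20, ISI violations < 0.01.
#'
#' @param band band-pass edges (Hz).
#' @param zTh detection threshold multiplier.
#' @param tauCMs censored period (ms).
#' @param lumpRadiusUm cross-channel lumping distance (um).
#' @param windowMs full waveform window (ms).
#' @param tauWinMs feature/template window (ms).
#' @param pLillie Lilliefors significance level.
#' @param K clusters per iteration, or "auto".
#' @param Nite number of template-matching iterations.
#' @param chi2Percentile chi-square gate percentile.
#' @param minCsizeRange core-cluster size threshold: a single value (the
#'   default, 8) or a range `c(lo, hi)` to sweep with the max-final-count
#'   selection rule (suited to data where small-core chaining merges
#'   units).
#' @param Pth dendrogram cut level (misclassification probability).
#' @param snrGate,misclassGate,isiGate unit-validation thresholds.
#' @param coreMode "tree" (inconsistency cut of the co-assignment tree) or
#'   "best_iteration" (clusters of the lowest-mean-chi2 iteration).
#' @param masterSeed master RNG seed.
#' @return a classed list (`SortConfig`).
#' @export
sortConfig <- function(band = c(200, 4000), zTh = 5, tauCMs = 0.6,
                       lumpRadiusUm = 60, windowMs = 6, tauWinMs = 2.5,
                       pLillie = 0.01, K = "auto", Nite = 100L,
                       chi2Percentile = 95, minCsizeRange = 8L,
                       Pth = 0.15, snrGate = 4, misclassGate = 0.20,
                       isiGate = 0.01, coreMode = c("tree", "best_iteration"),
                       masterSeed = 1L) {
  coreMode <- match.arg(coreMode)
  stopifnot(zTh > 0, tauCMs > 0, windowMs > 0, Nite >= 1,
            chi2Percentile > 0, chi2Percentile <= 100,
            Pth > 0, Pth < 1)
  structure(list(
    band = band, zTh = zTh, tauCMs = tauCMs, lumpRadiusUm = lumpRadiusUm,
    windowMs = windowMs, tauWinMs = tauWinMs, pLillie = pLillie, K = K,
    Nite = as.integer(Nite), chi2Percentile = chi2Percentile,
    minCsizeRange = as.integer(minCsizeRange), Pth = Pth,
    snrGate = snrGate, misclassGate = misclassGate, isiGate = isiGate,
    coreMode = coreMode, masterSeed = as.integer(masterSeed)),
    class = "SortConfig")
}

#' Read / write a SortConfig as YAML
#'
#' Round-trips losslessly: unspecified keys take the defaults of
#' [sortConfig()].
#'
#' @param config a `SortConfig`.
#' @param path YAML file path.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sortConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(sortConfig, vals)
}
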