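# Internal helpers: seeded RNG scoping and k-means++ seeding.

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library calls never perturb user randomness.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive n child seeds from a master seed, all < 2^31.
deriveSeeds <- function(masterSeed, n) {
  withSeed(masterSeed, sample.int(.Machine$integer.max - 1L, n))
}

# Lloyd K-means initialized from a uniform random sample of K distinct
# points; single run, no restarts, and deliberately truncated Lloyd
# updates. The consensus method *feeds* on the run-to-run diversity of
# local optima: spread-out seeding or fully converged updates make
# successive runs nearly identical, which starves the co-assignment and
# misclassification estimates of the variability they measure (fully
# converged runs reproducibly freeze each cluster's interior partition and
# split units into artificially stable sub-clusters). Clusters emptied by
# Lloyd updates are tolerated.
kmeansOnce <- function(x, K, iterMax = 10L) {
  n <- nrow(x)
  stopifnot(K >= 1L, K <= n)
  centers <- unique(x[sample.int(n, K), , drop = FALSE])
  suppressWarnings(
    stats::kmeans(x, centers = centers, iter.max = iterMax,
                  algorithm = "Lloyd"))
}

# Flatten the tau_win crop of a waveform array (n x ch x s) into n x (ch*s),
# channel-major (channel 1's samples, then channel 2's, ...).
flattenWaveforms <- function(wf) {
  n <- dim(wf)[1]
  matrix(aperm(wf, c(1L, 3L, 2L)), nrow = n)
}

# Crop a waveform array to tauWin ms around its centre sample.
cropWaveforms <- function(wf, waveRateHz, tauWinMs) {
  ns <- dim(wf)[3]
  half <- floor(tauWinMs / 1000 * waveRateHz / 2)
  centre <- floor(ns / 2) + 1L
  lo <- max(1L, centre - half)
  hi <- min(ns, centre + half)
  wf[, , lo:hi, drop = FALSE]
}
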