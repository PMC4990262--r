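# The label-ensemble engine: K-means partitions seed spatiotemporal
# templates; every spike is re-assigned to its best-fitting template under
# a bounded amplitude scale, and the residual chi^2 is recorded. Repeating
# with fresh K-means seeds yields the clustering ensemble that consensus
# clustering consumes.

#' Bounded-amplitude least-squares template fit
#'
#' Fits `s = a * T + e` with the scale clamped to `[0.8, 1.2]` (a +/-20
#' percent amplitude tolerance): `a = clamp(<s,T>/<T,T>)`, and the error
#' is the mean squared residual over all space-time points.
#'
#' @param s numeric vector (or matrix) spike waveform.
#' @param template numeric vector (or matrix) of the same shape.
#' @param lo,hi scale bounds.
#' @return list with `a` and `chi2`. A zero template yields `a = 1`,
#'   `chi2 = mean(s^2)` with a warning.
#' @export
fitAmplitude <- function(s, template, lo = 0.8, hi = 1.2) {
  s <- as.numeric(s); template <- as.numeric(template)
  stopifnot(length(s) == length(template))
  tt <- sum(template^2)
  if (tt == 0) {
    warning("zero template: amplitude undefined, returning a = 1")
    return(list(a = 1, chi2 = mean(s^2)))
  }
  a <- min(max(sum(s * template) / tt, lo), hi)
  list(a = a, chi2 = mean((s - a * template)^2))
}

# Vectorized fit of all spikes (rows of S, n x d) against all templates
# (rows of Tm, K x d): returns list(a, chi2) of n x K matrices.
templateFitAll <- function(S, Tm, lo = 0.8, hi = 1.2) {
  d <- ncol(S)
  dot <- S %*% t(Tm)                      # n x K
  tt <- rowSums(Tm^2)                     # K
  ss <- rowSums(S^2)                      # n
  a <- sweep(dot, 2L, pmax(tt, .Machine$double.eps), "/")
  a[] <- pmin(pmax(a, lo), hi)
  zero <- tt == 0
  if (any(zero)) a[, zero] <- 1
  chi2 <- (matrix(ss, nrow(S), length(tt)) - 2 * a * dot +
             sweep(a^2, 2L, tt, "*")) / d
  chi2[chi2 < 0] <- 0  # numerical guard
  list(a = a, chi2 = chi2)
}

#' One template-matching iteration
#'
#' K-means (k-means++ seeding, Lloyd updates, single run) partitions the
#' feature vectors; the spatiotemporal mean waveform of each K-means
#' cluster becomes a template; every spike is then assigned to the
#' template minimizing its bounded-amplitude chi^2 (ties to the lowest
#' cluster index). Clusters emptied by Lloyd updates are dropped for the
#' iteration.
#'
#' @param featValues n x P feature matrix.
#' @param S n x d flattened waveform matrix (the template window).
#' @param K number of K-means clusters.
#' @param seed iteration RNG seed.
#' @param iterMax Lloyd update rounds (default 10, deliberately truncated
#'   for ensemble diversity; see the package vignette).
#' @return list with `labels` (integer n, in 1..K'), `chi2` (numeric n)
#'   and `templates` (K' x d matrix).
#' @export
oneIteration <- function(featValues, S, K, seed, iterMax = 10L) {
  km <- withSeed(seed, kmeansOnce(featValues, K, iterMax))
  cl <- km$cluster
  counts <- tabulate(cl)
  keep <- which(counts > 0L)
  Tm <- rowsum(S, cl) / counts[keep]      # K' x d mean templates
  fit <- templateFitAll(S, Tm)
  # argmin with ties to the lowest cluster index; "tie" is relative to the
  # spike's energy so that exact fits (noiseless data) do not break on
  # floating-point dust
  best <- do.call(pmin, lapply(seq_len(ncol(fit$chi2)),
                               function(j) fit$chi2[, j]))
  tol <- 1e-9 * (rowMeans(S^2) + best)
  labels <- max.col(fit$chi2 <= best + tol, ties.method = "first")
  chi2 <- fit$chi2[cbind(seq_len(nrow(S)), labels)]
  list(labels = labels, chi2 = chi2, templates = Tm)
}

#' Run the full clustering ensemble
#'
#' Repeats [oneIteration()] `Nite` times with per-iteration seeds derived
#' deterministically from the master seed.
#'
#' @param featValues n x P feature matrix.
#' @param S n x d flattened waveform matrix.
#' @param K clusters per iteration.
#' @param Nite number of iterations (default 100).
#' @param masterSeed master RNG seed.
#' @return a [LabelEnsemble-class].
#' @export
runEnsemble <- function(featValues, S, K, Nite = 100L, masterSeed = 1L) {
  stopifnot(Nite >= 1L)
  seeds <- deriveSeeds(masterSeed, Nite)
  n <- nrow(S)
  labels <- matrix(NA_integer_, n, Nite)
  chi2 <- matrix(NA_real_, n, Nite)
  for (it in seq_len(Nite)) {
    one <- oneIteration(featValues, S, K, seeds[it])
    labels[, it] <- one$labels
    chi2[, it] <- one$chi2
  }
  new("LabelEnsemble", labels = labels, chi2 = chi2, K = as.integer(K),
      seeds = as.integer(seeds))
}

#' Choose the number of K-means clusters
#'
#' Runs matching passes per candidate K (at full Lloyd convergence) and
#' tracks the mean chi^2 over all spikes, which decreases towards a
#' plateau as K grows. Returns the smallest candidate already on the
#' plateau: the smallest K whose mean chi^2 lies within `plateauTol`
#' (relative) of the best value attained over all candidates. Anchoring to
#' the asymptote rather than to consecutive step improvements keeps the
#' choice stable when one step straddles a tolerance. All candidates must
#' stay below sqrt(n_spikes).
#'
#' @param featValues n x P feature matrix.
#' @param S n x d flattened waveform matrix.
#' @param candidates ascending candidate values of K.
#' @param plateauTol relative excess over the asymptotic chi^2 regarded
#'   as on-plateau (default 0.15).
#' @param seed RNG seed for the probe iterations.
#' @param nProbes matching passes averaged per candidate (default 5; the
#'   single-run chi^2 is a noisy local optimum).
#' @return the chosen K (integer).
#' @export
chooseK <- function(featValues, S, candidates, plateauTol = 0.15,
                    seed = 1L, nProbes = 5L) {
  n <- nrow(S)
  stopifnot(!is.unsorted(candidates, strictly = TRUE))
  if (any(candidates >= sqrt(n)))
    stop("all candidate K must be below sqrt(n_spikes)")
  seeds <- deriveSeeds(seed, length(candidates) * nProbes)
  # probe at full Lloyd convergence: the chi^2(K) fit-quality curve is a
  # property of the best attainable partition at each K, independent of
  # the truncation used for ensemble diversity
  m <- vapply(seq_along(candidates), function(i) {
    mean(vapply(seq_len(nProbes), function(p)
      mean(oneIteration(featValues, S, candidates[i],
                        seeds[(i - 1L) * nProbes + p],
                        iterMax = 300L)$chi2),
      numeric(1)))
  }, numeric(1))
  if (m[1] <= .Machine$double.eps) return(as.integer(candidates[1]))
  onPlateau <- m <= (1 + plateauTol) * min(m)
  as.integer(candidates[which(onPlateau)[1]])
}

#' Chi-square gate
#'
#' Computes the per-spike mean chi^2 across iterations and the threshold
#' at the requested percentile of its cumulative distribution; spikes at
#' or below the threshold are kept for consensus clustering.
#'
#' @param ensemble a [LabelEnsemble-class].
#' @param percentile percentile in (0, 100] (default 95).
#' @return list with `kept` (indices), `threshold` (chi^2_th) and
#'   `meanChi2` (per spike).
#' @export
chi2Gate <- function(ensemble, percentile = 95) {
  stopifnot(percentile > 0, percentile <= 100)
  meanChi2 <- rowMeans(ensemble@chi2)
  n <- length(meanChi2)
  kth <- ceiling(percentile / 100 * n)
  threshold <- sort(meanChi2, partial = kth)[kth]
  list(kept = which(meanChi2 <= threshold), threshold = threshold,
       meanChi2 = meanChi2)
}

#' K-means label ensemble over plain points
#'
#' The point-cloud variant of [runEnsemble()]: repeated K-means partitions
#' of a point set (no templates), as used to demonstrate consensus
#' clustering on 2-D data. The chi^2 column holds the squared distance of
#' each point to its assigned centroid.
#'
#' @param points n x d point matrix.
#' @param K clusters per run (default `floor(sqrt(n))`).
#' @param Nite number of runs.
#' @param masterSeed master RNG seed.
#' @return a [LabelEnsemble-class].
#' @export
kmeansEnsemble <- function(points, K = floor(sqrt(nrow(points))),
                           Nite = 200L, masterSeed = 1L) {
  seeds <- deriveSeeds(masterSeed, Nite)
  n <- nrow(points)
  labels <- matrix(NA_integer_, n, Nite)
  chi2 <- matrix(NA_real_, n, Nite)
  for (it in seq_len(Nite)) {
    km <- withSeed(seeds[it], kmeansOnce(points, K))
    labels[, it] <- km$cluster
    chi2[, it] <- rowSums((points - km$centers[km$cluster, , drop = FALSE])^2)
  }
  new("LabelEnsemble", labels = labels, chi2 = chi2, K = as.integer(K),
      seeds = as.integer(seeds))
}
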