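# Brute-force reference implementations used to cross-check the package's
# vectorized / compiled code paths, plus small fixture builders. These
# oracles deliberately use naive loops and set algebra.

# Co-assignment probability at spike level: fraction of iterations two
# spikes share a label. O(n^2 * Nite) double loop.
bruteP0 <- function(L) {
  n <- nrow(L)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    P[i, j] <- mean(L[i, ] == L[j, ])
  }
  P
}

# Misclassification probability between two spike sets by direct set
# enumeration of the FP/FN ensembles (strict inequalities, ties neither).
brutePmis <- function(L, setA, setB) {
  Nite <- ncol(L)
  total <- 0
  for (it in seq_len(Nite)) {
    mis <- integer(0)
    for (k in unique(L[, it])) {
      inK <- which(L[, it] == k)
      aK <- intersect(setA, inK)
      bK <- intersect(setB, inK)
      if (length(aK) < length(bK)) mis <- union(mis, aK)
      if (length(bK) < length(aK)) mis <- union(mis, bK)
    }
    total <- total + length(mis)
  }
  total / Nite / (length(setA) + length(setB))
}

# Per-unit stability error estimates by direct enumeration of the
# co-clustered outsider sets.
bruteUnitErr <- function(L, unitIdx) {
  Nite <- ncol(L)
  n <- nrow(L)
  outIdx <- setdiff(seq_len(n), unitIdx)
  FP <- FN <- 0
  for (it in seq_len(Nite)) {
    fpSet <- integer(0); fnSet <- integer(0)
    for (k in unique(L[, it])) {
      inK <- which(L[, it] == k)
      u <- intersect(unitIdx, inK)
      o <- intersect(outIdx, inK)
      if (length(u) < length(o)) fpSet <- union(fpSet, u)
      if (length(o) < length(u) && length(o) > 0) fnSet <- union(fnSet, o)
    }
    FP <- FP + length(fpSet)
    FN <- FN + length(fnSet)
  }
  list(PFP = FP / Nite / length(unitIdx), PFN = FN / Nite / length(unitIdx))
}

# Single-link agglomeration by exhaustive minimum search; returns the
# merge heights and the flat clusters at cut height h.
bruteSingleLink <- function(D, h) {
  n <- nrow(D)
  groups <- as.list(seq_len(n))
  heights <- numeric(0)
  repeat {
    if (length(groups) == 1L) break
    best <- c(NA, NA); bestD <- Inf
    for (a in seq_along(groups)) for (b in seq_along(groups)) {
      if (b <= a) next
      d <- min(D[groups[[a]], groups[[b]]])
      if (d < bestD) { bestD <- d; best <- c(a, b) }
    }
    if (bestD > h) break
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
    heights <- c(heights, bestD)
  }
  lab <- integer(n)
  for (g in seq_along(groups)) lab[groups[[g]]] <- g
  list(labels = lab, heights = heights)
}

# Best template per spike by looping fitAmplitude over all pairs.
bruteAssign <- function(S, Tm) {
  n <- nrow(S); K <- nrow(Tm)
  lab <- integer(n); chi <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf; bj <- 1L
    for (j in seq_len(K)) {
      f <- suppressWarnings(fitAmplitude(S[i, ], Tm[j, ]))
      if (f$chi2 < best - 1e-12) { best <- f$chi2; bj <- j }
    }
    lab[i] <- bj; chi[i] <- best
  }
  list(labels = lab, chi2 = chi)
}

# Random label-ensemble fixture: n spikes x Nite iterations with K labels.
randomLabels <- function(n, Nite, K, seed) {
  withr::with_seed(seed, matrix(sample.int(K, n * Nite, replace = TRUE),
                                n, Nite))
}

# Wrap a label matrix as a LabelEnsemble with zero chi^2.
asEnsemble <- function(L) {
  storage.mode(L) <- "integer"
  new("LabelEnsemble", labels = L, chi2 = matrix(0, nrow(L), ncol(L)),
      K = as.integer(max(L)), seeds = seq_len(ncol(L)))
}

# Small ground-truth recording used by several module tests.
smallRecording <- function(units = 2, durationS = 20, seed = 5,
                           channels = 8, rateHz = 5) {
  makeRecording(units = units, durationS = durationS, rateHz = rateHz,
                geometry = linearGeometry(channels, 20), seed = seed)
}

# The criterion-style overlap fixture: two units on disjoint regions of a
# 16-channel array, isolated spikes plus nPairs constructed cross-unit
# pairs closer than the censored period.
overlapFixture <- function(seed, durationS = 60, nPairs = 24,
                           jitterSd = 0.10) {
  geom <- linearGeometry(16, 20)
  tplA <- makeTemplate("biphasic", geom, c(8, 60), 100, rateHz = 10000)
  tplB <- makeTemplate("triphasic", geom, c(8, 240), 100, rateHz = 10000)
  ns <- durationS * 10000
  noise <- consensusSort:::withSeed(seed, {
    d <- as.matrix(dist(geom))
    consensusSort:::makeNoise(100 * exp(-d / 50), ns, 10000)
  })
  rec <- new("Recording", signal = noise, rateHz = 10000,
             positionsUm = geom, band = c(200, 4000))
  isoA <- seq(5000, ns - 50000, by = 1200)
  isoB <- isoA + 600
  pairA <- seq(ns - 45000, ns - 5000, by = 1500)[seq_len(nPairs)]
  pairB <- pairA + rep_len(c(2, 3, 4, 5), nPairs)
  injectSpikes(rec, list(tplA, tplB),
               list(sort(c(isoA, pairA)), sort(c(isoB, pairB))),
               jitterSd = jitterSd, seed = seed + 1L)
}
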