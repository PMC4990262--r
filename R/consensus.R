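# Consensus clustering by evidence accumulation: co-assignment
# probabilities over label signatures, core clusters from an
# inconsistency-coefficient cut of the single-link tree, misclassification
# probabilities between clusters, and the final single-link merge cut at
# 1 - P_th.

#' Pairwise co-assignment probabilities
#'
#' Spikes are first compressed to distinct label signatures (groups of
#' spikes with identical label vectors across all iterations: such spikes
#' are interchangeable for every downstream step). `P0` between two
#' signatures is the fraction of iterations in which they share a label.
#'
#' @param ensemble a [LabelEnsemble-class].
#' @param kept indices of the spikes to use (default all), e.g. from
#'   [chi2Gate()].
#' @param maxSignatures memory guard: error out beyond this many distinct
#'   signatures (use the best-iteration core mode for such data).
#' @return list with `P0` (G x G symmetric, unit diagonal), `sizes`
#'   (spikes per signature), `signatureId` (per kept spike) and
#'   `signatureLabels` (G x Nite label matrix).
#' @export
computeP0 <- function(ensemble, kept = seq_len(nSpikes(ensemble)),
                      maxSignatures = 20000L) {
  L <- ensemble@labels[kept, , drop = FALSE]
  key <- do.call(paste, c(as.data.frame(L), sep = ","))
  sigId <- match(key, unique(key))
  G <- max(sigId)
  if (G > maxSignatures)
    stop("more than ", maxSignatures, " distinct label signatures; ",
         "use coreMode = 'best_iteration' to bound memory")
  first <- match(seq_len(G), sigId)
  Lg <- L[first, , drop = FALSE]
  sizes <- tabulate(sigId, G)
  acc <- matrix(0, G, G)
  for (it in seq_len(ncol(Lg))) {
    li <- Lg[, it]
    acc <- acc + (outer(li, li, "==") * 1)
  }
  P0 <- acc / ncol(Lg)
  list(P0 = P0, sizes = sizes, signatureId = sigId, signatureLabels = Lg)
}

#' Inconsistency coefficients of a linkage tree
#'
#' For every merge, compares its height with the heights of the links up
#' to `depth` levels below it (the link itself and, at the default depth
#' 2, its direct child links): `(h - mean) / sd`, with 0 where the sd
#' vanishes.
#'
#' @param tree an `hclust` object.
#' @param depth comparison depth (default 2).
#' @return numeric vector, one coefficient per merge.
#' @export
inconsistencyCoefficient <- function(tree, depth = 2L) {
  m <- tree$merge
  h <- tree$height
  n <- nrow(m)
  inc <- numeric(n)
  for (i in seq_len(n)) {
    set <- i
    frontier <- i
    for (d in seq_len(depth - 1L)) {
      kids <- m[frontier, , drop = FALSE]
      kids <- kids[kids > 0]
      if (!length(kids)) break
      set <- c(set, kids)
      frontier <- kids
    }
    hh <- h[set]
    s <- sd(hh)
    inc[i] <- if (length(hh) < 2L || s == 0 || is.na(s)) 0
              else (h[i] - mean(hh)) / s
  }
  inc
}

# Flat clusters from an inconsistency cutoff: a merge is applied only if
# its coefficient is below the cutoff and all its descendant merges were
# applied; leaves under unapplied merges stay separate.
cutInconsistent <- function(tree, inc, cutoff) {
  m <- tree$merge
  n <- nrow(m)
  nLeaves <- n + 1L
  consistent <- logical(n)
  for (i in seq_len(n)) {
    kids <- m[i, ][m[i, ] > 0]
    consistent[i] <- inc[i] < cutoff && all(consistent[kids])
  }
  # union-find over applied merges
  parent <- seq_len(nLeaves)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  rep1 <- integer(n)  # a leaf representative per merge node
  for (i in seq_len(n)) {
    l <- m[i, 1]; r <- m[i, 2]
    lRep <- if (l < 0) -l else rep1[l]
    rRep <- if (r < 0) -r else rep1[r]
    rep1[i] <- lRep
    if (consistent[i]) parent[find(rRep)] <- find(lRep)
  }
  roots <- vapply(seq_len(nLeaves), find, 1L)
  match(roots, unique(roots))
}

#' Core-cluster partition of the co-assignment tree
#'
#' Builds the single-link tree over `1 - P0` and cuts it at the largest
#' inconsistency-coefficient value that still yields more than one
#' cluster (immediately above it, all spikes lump into a single cluster).
#'
#' @param P0 co-assignment matrix over signatures (from [computeP0()]).
#' @param depth inconsistency depth (default 2).
#' @param tol coefficients closer than this are one threshold band: the
#'   depth-2 coefficient has hard algebraic ceilings (e.g. 2/sqrt(3) when
#'   both child heights tie) that many links attain up to float noise, and
#'   the cut must sever the whole band, not one arbitrary member.
#' @return integer cluster id per signature.
#' @export
corePartition <- function(P0, depth = 2L, tol = 1e-6) {
  G <- nrow(P0)
  if (G == 1L) return(1L)
  tree <- hclust(as.dist(1 - P0), method = "single")
  inc <- inconsistencyCoefficient(tree, depth)
  cutInconsistent(tree, inc, max(inc) - tol)
}

# Size-weighted mean co-assignment probability between all cluster pairs:
# (A' P0 A) / outer(n, n) with A the size-weighted membership matrix.
clusterMeanP0 <- function(P0, sizes, part) {
  M <- max(part)
  A <- matrix(0, length(part), M)
  A[cbind(seq_along(part), part)] <- sizes
  num <- crossprod(A, P0 %*% A)
  tot <- colSums(A)
  num / outer(tot, tot)
}

#' Enforce the minimum core-cluster size
#'
#' Clusters at or below `minCsize` spikes are reassigned to the closest
#' cluster strictly above the threshold — closeness being the
#' size-weighted mean `P0` between member signatures (ties to the larger
#' cluster) — provided that probability exceeds `1/Nite`; otherwise their
#' spikes are excluded from consensus clustering.
#'
#' @param part integer cluster id per signature (from [corePartition()]).
#' @param P0,sizes from [computeP0()].
#' @param minCsize minimum spikes per core cluster.
#' @param Nite number of ensemble iterations.
#' @return integer vector: core id per signature (re-packed 1..C), NA for
#'   excluded signatures.
#' @export
reassignSmallClusters <- function(part, P0, sizes, minCsize, Nite) {
  part <- match(part, sort(unique(part)))
  nSpk <- vapply(seq_len(max(part)), function(m) sum(sizes[part == m]),
                 numeric(1))
  big <- which(nSpk > minCsize)
  small <- which(nSpk <= minCsize)
  if (!length(big)) return(rep(NA_integer_, length(part)))
  out <- part
  if (length(small)) {
    meanP0 <- clusterMeanP0(P0, sizes, part)
    for (cs in small) {
      p <- meanP0[cs, big]
      # ties go to the larger cluster
      best <- big[order(-p, -nSpk[big])][1]
      out[part == cs] <- if (meanP0[cs, best] > 1 / Nite) best
                         else NA_integer_
    }
  }
  ok <- !is.na(out)
  out[ok] <- match(out[ok], sort(unique(out[ok])))
  out
}

#' Misclassification probability matrix
#'
#' Implements the size-normalized misclassification estimate between
#' clusters: per iteration and per ensemble cluster k, the side of a
#' cluster pair with the strictly smaller nonzero intersection with k
#' counts as misclassified (ties count neither); counts are summed over
#' k, averaged over iterations, and normalized by the summed pair sizes.
#'
#' @param signatureLabels G x Nite signature label matrix.
#' @param sizes spikes per signature.
#' @param assign cluster id per signature (NA = excluded).
#' @return C x C symmetric matrix with zero diagonal, values in [0, 1].
#' @export
pmisMatrix <- function(signatureLabels, sizes, assign) {
  ok <- !is.na(assign)
  C <- if (any(ok)) max(assign[ok]) else 0L
  if (C == 0L) return(matrix(0, 0, 0))
  a <- assign
  a[is.na(a)] <- 0L
  counts <- pmisCounts(signatureLabels, as.integer(sizes),
                       as.integer(a), as.integer(C))
  nC <- vapply(seq_len(C), function(ci) sum(sizes[ok & assign == ci]),
               numeric(1))
  denom <- outer(nC, nC, "+") * ncol(signatureLabels)
  P <- counts / denom
  diag(P) <- 0
  P
}

#' Merge core clusters into final clusters
#'
#' Single-link tree over `1 - Pmis`, cut so that clusters with a mutual
#' misclassification probability strictly above `Pth` merge; the
#' misclassification matrix is then recomputed once between the final
#' clusters with their new sizes.
#'
#' @param coreAssign core id per signature (NA = excluded).
#' @param signatureLabels,sizes from [computeP0()].
#' @param Pth misclassification threshold (default 0.15).
#' @return list with `finalAssign` (per signature, NA = excluded),
#'   `tree` (`hclust` over cores, NULL if < 2 cores), `coreToFinal`,
#'   and `Pmis` (updated, between final clusters).
#' @export
mergeFinal <- function(coreAssign, signatureLabels, sizes, Pth = 0.15) {
  ok <- !is.na(coreAssign)
  C <- if (any(ok)) max(coreAssign[ok]) else 0L
  if (C == 0L)
    return(list(finalAssign = coreAssign, tree = NULL,
                coreToFinal = integer(0), Pmis = matrix(0, 0, 0)))
  PmisCore <- pmisMatrix(signatureLabels, sizes, coreAssign)
  if (C == 1L) {
    coreToFinal <- 1L
    tree <- NULL
  } else {
    tree <- hclust(as.dist(1 - PmisCore), method = "single")
    coreToFinal <- cutree(tree, h = 1 - Pth - 1e-9)
  }
  finalAssign <- coreAssign
  finalAssign[ok] <- coreToFinal[coreAssign[ok]]
  PmisFinal <- pmisMatrix(signatureLabels, sizes, finalAssign)
  list(finalAssign = finalAssign, tree = tree, coreToFinal = coreToFinal,
       Pmis = PmisFinal)
}

#' Consensus partition of a label ensemble
#'
#' The full consensus stage: co-assignment probabilities over signatures,
#' core partition (inconsistency cut, or the lowest-chi^2 iteration's
#' clusters in `"best_iteration"` mode), a sweep of the core-size
#' threshold that keeps the value maximizing the number of final clusters
#' while excluding at most 0.1 percent of spikes, and the final
#' single-link merge at `1 - Pth`.
#'
#' @param ensemble a [LabelEnsemble-class].
#' @param kept spike indices to cluster (default all).
#' @param minCsize sweep range `c(lo, hi)` (default `c(4, 19)`, the
#'   paper-range interior), or a single fixed value.
#' @param Pth misclassification cut level (default 0.15).
#' @param coreMode `"tree"` or `"best_iteration"`.
#' @param maxExcluded largest tolerated excluded-spike fraction during the
#'   sweep (default 0.001).
#' @return a [ConsensusModel-class].
#' @export
consensusPartition <- function(ensemble, kept = seq_len(nSpikes(ensemble)),
                               minCsize = c(4L, 19L), Pth = 0.15,
                               coreMode = c("tree", "best_iteration"),
                               maxExcluded = 0.001) {
  coreMode <- match.arg(coreMode)
  p0 <- computeP0(ensemble, kept)
  G <- nrow(p0$P0)
  nKept <- length(kept)
  if (coreMode == "tree") {
    part <- corePartition(p0$P0)
  } else {
    bestIt <- which.min(colMeans(ensemble@chi2[kept, , drop = FALSE]))
    part <- match(p0$signatureLabels[, bestIt],
                  sort(unique(p0$signatureLabels[, bestIt])))
  }
  if (max(part) == 1L && G > 1L)
    warning("no structure: every signature fell into one core cluster")
  sweepVals <- if (length(minCsize) == 1L) minCsize
               else seq(minCsize[1], minCsize[2])
  rows <- list()
  results <- list()
  for (mc in sweepVals) {
    assign <- reassignSmallClusters(part, p0$P0, p0$sizes, mc,
                                    ncol(p0$signatureLabels))
    excl <- sum(p0$sizes[is.na(assign)]) / nKept
    if (all(is.na(assign))) {
      rows[[length(rows) + 1L]] <- data.frame(minCsize = mc, n_final = NA,
                                              frac_excluded = 1)
      next
    }
    mf <- mergeFinal(assign, p0$signatureLabels, p0$sizes, Pth)
    nFinal <- length(unique(mf$finalAssign[!is.na(mf$finalAssign)]))
    rows[[length(rows) + 1L]] <-
      data.frame(minCsize = mc, n_final = nFinal, frac_excluded = excl)
    results[[as.character(mc)]] <- list(assign = assign, mf = mf)
    if (excl > maxExcluded) break
  }
  sweepDf <- do.call(rbind, rows)
  valid <- !is.na(sweepDf$n_final) & sweepDf$frac_excluded <= maxExcluded
  if (!any(valid)) {
    # the excluded-fraction cap is the sweep's stop rule; when every
    # evaluated threshold exceeds it (common for short recordings, where
    # a handful of outlier spikes is already > 0.1%), fall back to the
    # threshold excluding the fewest spikes rather than failing
    valid <- !is.na(sweepDf$n_final) &
      sweepDf$frac_excluded <= min(sweepDf$frac_excluded[!is.na(sweepDf$n_final)])
    if (!any(valid)) stop("no structure: consensus excluded every spike")
    warning("every core-size threshold excluded more than ",
            maxExcluded * 100, "% of spikes; using the least-exclusion one")
  }
  bestRow <- which(valid)[which.max(sweepDf$n_final[valid])]
  mcBest <- sweepDf$minCsize[bestRow]
  chosen <- results[[as.character(mcBest)]]
  sigId <- p0$signatureId
  new("ConsensusModel",
      keptIdx = as.integer(kept),
      signatureId = as.integer(sigId),
      P0 = p0$P0,
      coreAssign = as.integer(chosen$assign[sigId]),
      finalAssign = as.integer(chosen$mf$finalAssign[sigId]),
      Pmis = chosen$mf$Pmis,
      linkage = chosen$mf$tree,
      minCsize = as.integer(mcBest),
      sweep = sweepDf,
      Pth = Pth)
}
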