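# Consensus stage: co-assignment, core extraction, misclassification
# probabilities, final merging, overlap pursuit.

test_that("P0 matches the brute-force double loop and compresses exactly", {
  for (trial in 1:15) {
    L <- randomLabels(20, 5, 4, seed = 300 + trial)
    p0 <- computeP0(asEnsemble(L))
    # expand back to spike level and compare with the naive matrix
    full <- p0$P0[p0$signatureId, p0$signatureId]
    expect_equal(full, bruteP0(L), tolerance = 1e-12, ignore_attr = TRUE)
  }
  # trivial pairs
  L <- rbind(c(1, 2, 1), c(1, 2, 1), c(2, 2, 1))
  p0 <- computeP0(asEnsemble(L))
  expect_equal(p0$P0[p0$signatureId[1], p0$signatureId[2]], 1)
  expect_equal(p0$P0[p0$signatureId[1], p0$signatureId[3]], 2 / 3)
  expect_true(all(diag(p0$P0) == 1))
  expect_error(computeP0(asEnsemble(randomLabels(30, 6, 20, 1)),
                         maxSignatures = 5), "best_iteration")
})

test_that("Pmis reproduces the hand-enumerated example and the oracle", {
  # one iteration; A = spikes 1:3, B = spikes 4:5; cell 1 holds one A and
  # both B spikes: |mis| = 1, Pmis = 1/5
  L <- matrix(c(1, 2, 2, 1, 1), ncol = 1)
  P <- pmisMatrix(L, sizes = rep(1L, 5),
                  assign = c(1L, 1L, 1L, 2L, 2L))
  expect_equal(P[1, 2], 0.2)

  # never co-located: zero
  L2 <- matrix(c(1, 1, 2, 2), ncol = 1)
  P2 <- pmisMatrix(L2, rep(1L, 4), c(1L, 1L, 2L, 2L))
  expect_equal(P2[1, 2], 0)

  # random matrices against the set-enumeration oracle, with symmetry
  for (trial in 1:15) {
    L <- randomLabels(24, 6, 5, seed = 400 + trial)
    assign <- withr::with_seed(500 + trial,
                               sample(1:3, 24, replace = TRUE))
    P <- pmisMatrix(L, rep(1L, 24), as.integer(assign))
    expect_equal(P, t(P))
    for (a in 1:2) for (b in (a + 1):3) {
      expect_equal(P[a, b],
                   brutePmis(L, which(assign == a), which(assign == b)),
                   tolerance = 1e-12,
                   info = sprintf("trial %d pair %d-%d", trial, a, b))
    }
  }
})

test_that("signature-weighted Pmis equals its spike-level expansion", {
  L <- randomLabels(30, 4, 3, seed = 77)
  p0 <- computeP0(asEnsemble(L))
  assignSig <- withr::with_seed(78, sample(1:2, nrow(p0$P0), TRUE))
  Pw <- pmisMatrix(p0$signatureLabels, p0$sizes, as.integer(assignSig))
  assignSpike <- assignSig[p0$signatureId]
  Ps <- pmisMatrix(L, rep(1L, 30), as.integer(assignSpike))
  expect_equal(Pw, Ps, tolerance = 1e-12)
})

test_that("single-link merging at the cut equals brute-force agglomeration", {
  # two cores with Pmis above the threshold merge
  Lg <- matrix(c(1, 1, 2, 2), ncol = 1)
  pm <- matrix(c(0, 0.2, 0.2, 0), 2)
  tree <- hclust(as.dist(1 - pm), method = "single")
  expect_equal(unname(cutree(tree, h = 1 - 0.15 - 1e-9)), c(1, 1))

  # all-zero Pmis: no merges, finals = cores
  mf0 <- mergeFinal(c(1L, 1L, 2L, 2L), randomLabels(4, 3, 2, 1),
                    rep(1L, 4), Pth = 0.15)
  # (random labels give nonzero Pmis sometimes; force orthogonal labels)
  Lsep <- cbind(c(1L, 1L, 2L, 2L), c(3L, 3L, 4L, 4L))
  mfSep <- mergeFinal(c(1L, 1L, 2L, 2L), Lsep, rep(1L, 4), Pth = 0.15)
  expect_equal(length(unique(na.omit(mfSep$finalAssign))), 2)

  # hand-set 4-core distance structure vs exhaustive single link
  for (trial in 1:25) {
    Pm <- withr::with_seed(600 + trial, {
      M <- matrix(runif(16, 0, 0.4), 4)
      M <- (M + t(M)) / 2
      diag(M) <- 0
      M
    })
    tree <- hclust(as.dist(1 - Pm), method = "single")
    got <- cutree(tree, h = 1 - 0.15 - 1e-9)
    want <- bruteSingleLink(1 - Pm, 1 - 0.15 - 1e-9)$labels
    expect_equal(length(unique(got)), length(unique(want)))
    expect_equal(unname(got[want == want[1]]),
                 rep(got[1], sum(want == want[1])))
  }
})

test_that("core extraction handles the degenerate one-signature case", {
  L <- matrix(rep(c(1L, 2L), each = 6), nrow = 6)  # all spikes identical
  model <- consensusPartition(asEnsemble(L), minCsize = 3)
  expect_equal(unique(model@finalAssign), 1L)
  expect_equal(nrow(model@P0), 1)
})

test_that("the minCsize sweep reports its curve and applies the cap", {
  gt <- smallRecording(units = 2, durationS = 25, seed = 61)
  res <- sortSpikes(gt@recording,
                    sortConfig(masterSeed = 62, Nite = 40, K = 8L,
                               minCsizeRange = c(4L, 19L)),
                    verbose = FALSE)
  sw <- res$model@sweep
  expect_true(all(c("minCsize", "n_final", "frac_excluded") %in%
                    colnames(sw)))
  expect_true(all(diff(sw$minCsize) == 1))
  valid <- !is.na(sw$n_final) & sw$frac_excluded <= 0.001
  expect_equal(res$model@minCsize,
               sw$minCsize[which(valid)[which.max(sw$n_final[valid])]])
})

test_that("small clusters are reassigned by co-assignment or excluded", {
  # signatures: two big groups (never co-assigned) and one singleton that
  # co-clusters with group 1 in most iterations
  Lg <- rbind(c(1, 1, 1), c(2, 2, 2), c(1, 1, 3))
  sizes <- c(10L, 10L, 1L)
  part <- c(1L, 2L, 3L)
  out <- reassignSmallClusters(part, bruteP0(Lg), sizes,
                               minCsize = 5, Nite = 3)
  expect_equal(out[3], out[1])   # absorbed into the co-assigned big core
  # a singleton that never co-clusters with anything is excluded
  Lg2 <- rbind(c(1, 1, 1), c(2, 2, 2), c(3, 3, 4))
  out2 <- reassignSmallClusters(c(1L, 2L, 3L), bruteP0(Lg2), sizes,
                                minCsize = 5, Nite = 3)
  expect_true(is.na(out2[3]))
})

test_that("matching pursuit resolves constructed overlaps", {
  geom <- linearGeometry(8, 20)
  tplA <- makeTemplate("biphasic", geom, c(8, 45), 100, rateHz = 8000,
                       durMs = 6)
  tplB <- makeTemplate("triphasic", geom, c(8, 95), 100, rateHz = 8000,
                       durMs = 6)
  nsmp <- ncol(tplA)
  templates <- list(tplA, tplB)

  # leftover equal to a final template: assigned without pursuit
  wf <- array(0, c(3, 8, nsmp))
  wf[1, , ] <- tplA
  # overlap: A + B delayed by 0.4 ms (3.2 samples at 8 kHz -> 3)
  wf[2, , ] <- tplA + consensusSort:::shiftTemplate(tplB, 3L)
  # structureless noise burst
  wf[3, , ] <- withr::with_seed(3, matrix(rnorm(8 * nsmp, sd = 30), 8))

  out <- assignRemainder(wf, templates, chi2Th = 1, tauCMs = 0.6,
                         waveRateHz = 8000)
  expect_equal(out$labels[1], 1L)
  expect_equal(nrow(out$components[out$components$spike == 1, ]), 1)

  cmp2 <- out$components[out$components$spike == 2, ]
  expect_setequal(cmp2$cluster, c(1, 2))
  expect_equal(cmp2$tauSamples[cmp2$cluster == 1], 0L)
  expect_equal(cmp2$tauSamples[cmp2$cluster == 2], 3L)
  # grid-search oracle: the pursuit delay minimizes the residual
  r <- as.numeric(t(wf[2, , ])) -
    cmp2$a[cmp2$cluster == 1] * as.numeric(t(tplA))
  resid <- vapply(-5:5, function(tau)
    suppressWarnings(fitAmplitude(
      r, as.numeric(t(consensusSort:::shiftTemplate(tplB, tau)))))$chi2,
    numeric(1))
  expect_equal((-5:5)[which.min(resid)], 3)

  expect_equal(out$labels[3], -1L)  # rejected after three rounds
})

test_that("P0 and Pmis are proper probabilities on random ensembles", {
  for (trial in 1:10) {
    L <- randomLabels(30, 8, 6, seed = 800 + trial)
    p0 <- computeP0(asEnsemble(L))
    expect_true(all(p0$P0 >= 0 & p0$P0 <= 1))
    expect_equal(p0$P0, t(p0$P0))
    assign <- withr::with_seed(trial, sample(1:3, nrow(p0$P0), TRUE))
    P <- pmisMatrix(p0$signatureLabels, p0$sizes, as.integer(assign))
    expect_true(all(P >= 0 & P <= 1))
    expect_true(all(diag(P) == 0))
  }
})
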