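# Bounded-amplitude template fitting and the clustering ensemble.

test_that("the amplitude fit is exact in, and clamped outside, its bounds", {
  T0 <- c(1, -3, 2, 0.5)
  f1 <- fitAmplitude(T0, T0)
  expect_equal(f1$a, 1)
  expect_equal(f1$chi2, 0)

  f2 <- fitAmplitude(1.1 * T0, T0)
  expect_equal(f2$a, 1.1)
  expect_equal(f2$chi2, 0, tolerance = 1e-12)

  f3 <- fitAmplitude(1.5 * T0, T0)
  expect_equal(f3$a, 1.2)
  expect_equal(f3$chi2, 0.09 * mean(T0^2))  # (1.5 - 1.2)^2 <T^2>

  expect_warning(f0 <- fitAmplitude(T0, rep(0, 4)), "zero template")
  expect_equal(f0$a, 1)
  expect_equal(f0$chi2, mean(T0^2))
})

test_that("vectorized fits agree with the scalar fit on random cases", {
  for (trial in 1:20) {
    S <- withr::with_seed(trial, matrix(rnorm(8 * 12), 8, 12))
    Tm <- withr::with_seed(trial + 100, matrix(rnorm(3 * 12), 3, 12))
    all <- consensusSort:::templateFitAll(S, Tm)
    for (i in 1:8) for (j in 1:3) {
      f <- fitAmplitude(S[i, ], Tm[j, ])
      expect_equal(all$a[i, j], f$a, tolerance = 1e-12)
      expect_equal(all$chi2[i, j], f$chi2, tolerance = 1e-12)
    }
  }
})

test_that("iteration assignment equals the brute-force argmin oracle", {
  feat <- withr::with_seed(9, matrix(rnorm(60 * 3), 60, 3))
  S <- withr::with_seed(10, matrix(rnorm(60 * 24), 60, 24))
  one <- oneIteration(feat, S, K = 5, seed = 77)
  oracle <- bruteAssign(S, one$templates)
  expect_equal(one$labels, oracle$labels)
  expect_equal(one$chi2, oracle$chi2, tolerance = 1e-10)
  # determinism
  expect_identical(oneIteration(feat, S, K = 5, seed = 77)$labels,
                   one$labels)
})

test_that("two spikes matching two orthogonal templates fit exactly", {
  S <- rbind(c(1, 0, 0, 0), c(0, 0, 1, 0))
  feat <- S
  one <- oneIteration(feat, S, K = 2, seed = 1)
  expect_equal(sort(unique(one$labels)), c(1, 2))
  expect_equal(one$chi2, c(0, 0), tolerance = 1e-12)
})

test_that("the ensemble is seed-reproducible and column-consistent", {
  feat <- withr::with_seed(3, matrix(rnorm(80 * 2), 80, 2))
  S <- withr::with_seed(4, matrix(rnorm(80 * 10), 80, 10))
  le1 <- runEnsemble(feat, S, K = 4, Nite = 6, masterSeed = 11)
  le2 <- runEnsemble(feat, S, K = 4, Nite = 6, masterSeed = 11)
  expect_identical(le1@labels, le2@labels)
  expect_identical(le1@chi2, le2@chi2)

  one <- oneIteration(feat, S, K = 4, seed = le1@seeds[1])
  expect_identical(le1@labels[, 1], one$labels)

  # assignment optimality on every column
  for (it in 1:6) {
    oneIt <- oneIteration(feat, S, K = 4, seed = le1@seeds[it])
    oracle <- bruteAssign(S, oneIt$templates)
    expect_equal(oneIt$labels, oracle$labels)
  }
  expect_true(all(le1@chi2 >= 0))
})

test_that("ensemble columns mostly agree and their consensus is exact", {
  # three well-separated Gaussian blobs in feature space; single runs are
  # deliberately diverse (un-optimized K-means), so not every column is a
  # perfect partition, but the consensus over columns is
  feat <- withr::with_seed(20, rbind(
    matrix(rnorm(60 * 2, 0), 60, 2),
    matrix(rnorm(60 * 2, 8), 60, 2),
    matrix(rnorm(60 * 2, -8), 60, 2)))
  S <- cbind(feat, feat)  # waveforms carry the same separation
  le <- runEnsemble(feat, S, K = 4, Nite = 40, masterSeed = 5)
  truth <- rep(1:3, each = 60)
  agree <- vapply(seq_len(40), function(it) {
    tab <- table(truth, le@labels[, it])
    sum(apply(tab, 2, max)) / 180  # best-permutation agreement
  }, numeric(1))
  expect_gte(mean(agree >= 0.95), 0.7)
  model <- consensusPartition(le, minCsize = 8)
  expect_equal(mclust::adjustedRandIndex(truth, model@finalAssign), 1)
})

test_that("chooseK lands on the chi^2 plateau and respects sqrt(n)", {
  feat <- withr::with_seed(20, rbind(
    matrix(rnorm(100 * 2, 0, 0.5), 100, 2),
    matrix(rnorm(100 * 2, 8, 0.5), 100, 2),
    matrix(rnorm(100 * 2, -8, 0.5), 100, 2)))
  # realistic waveforms carry an irreducible high-dimensional noise floor
  S <- cbind(feat, withr::with_seed(22, matrix(rnorm(300 * 38), 300, 38)))
  K <- chooseK(feat, S, candidates = c(2, 4, 8, 16), seed = 3)
  expect_true(K %in% c(4, 8))
  expect_error(chooseK(feat, S, candidates = c(2, 20)), "sqrt")

  # single unit with no residual structure: smallest candidate wins
  feat1 <- matrix(0, 100, 2)
  S1 <- matrix(0, 100, 4)
  expect_equal(chooseK(feat1, S1, candidates = c(2, 4, 8)), 2L)
})

test_that("the chi^2 gate keeps the documented fraction", {
  chi2 <- withr::with_seed(6, matrix(rexp(200 * 5), 200, 5))
  le <- new("LabelEnsemble", labels = matrix(1L, 200, 5), chi2 = chi2,
            K = 1L, seeds = 1:5)
  gAll <- chi2Gate(le, 100)
  expect_length(gAll$kept, 200)

  g95 <- chi2Gate(le, 95)
  expect_length(g95$kept, ceiling(0.95 * 200))
  m <- rowMeans(chi2)
  expect_equal(g95$threshold, sort(m)[ceiling(0.95 * 200)])  # sort oracle
  expect_true(all(m[g95$kept] <= g95$threshold))
})
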