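# The ground-truth generators: clouds, recordings, replication, injection.

test_that("cloud generation is labelled, reproducible, and validated", {
  spec1 <- cloudSpec(list(list(list(mean = c(0, 0), cov = diag(2),
                                    weight = 1))),
                     pointsPerCloud = 100, seed = 3)
  d1 <- makeClouds(spec1)
  expect_equal(nrow(d1$points), 100)
  expect_true(all(d1$labels == 1))
  expect_identical(makeClouds(spec1), d1)  # seed determinism

  badCov <- matrix(c(1, 2, 2, 1), 2)  # indefinite
  expect_error(cloudSpec(list(list(list(mean = c(0, 0), cov = badCov,
                                        weight = 1)))),
               "positive-definite")
})

test_that("cloud sample means match the analytic mixture means", {
  spec <- defaultCloudSpec(pointsPerCloud = 400, seed = 11)
  d <- makeClouds(spec)
  for (ci in seq_along(spec$clouds)) {
    comps <- spec$clouds[[ci]]
    w <- vapply(comps, function(cp) cp$weight, numeric(1))
    mixMean <- Reduce(`+`, Map(function(cp, wi) wi * cp$mean, comps, w))
    pts <- d$points[d$labels == ci, ]
    # SE of the mixture mean along each axis
    secMom <- Reduce(`+`, Map(function(cp, wi)
      wi * (diag(cp$cov) + cp$mean^2), comps, w))
    se <- sqrt((secMom - mixMean^2) / nrow(pts))
    expect_true(all(abs(colMeans(pts) - mixMean) < 3.5 * se),
                info = sprintf("cloud %d mean", ci))
  }
})

test_that("noiseless single-spike recording reproduces the template", {
  geom <- linearGeometry(4, 20)
  gt <- makeRecording(units = 1, durationS = 5, rateHz = 2,
                      geometry = geom, jitterSd = 0,
                      noiseCov = matrix(0, 4, 4), seed = 2)
  expect_gte(length(gt@trueTimes[[1]]), 1)
  tpl <- gt@trueTemplates[[1]]
  t0 <- gt@trueTimes[[1]][1]
  trough <- which.min(tpl[which.min(apply(tpl, 1, min)), ])
  lo <- t0 - (trough - 1)
  seg <- gt@recording@signal[, lo:(lo + ncol(tpl) - 1)]
  expect_equal(seg, tpl, tolerance = 1e-12, ignore_attr = TRUE)

})

test_that("zero jitter leaves every realized amplitude at the template's", {
  geom <- linearGeometry(4, 20)
  gt <- makeRecording(units = 1, durationS = 10, rateHz = 5,
                      geometry = geom, jitterSd = 0,
                      noiseCov = matrix(0, 4, 4), seed = 7)
  tplMin <- min(gt@trueTemplates[[1]])
  troughs <- gt@recording@signal[cbind(
    which.min(apply(gt@trueTemplates[[1]], 1, min)), gt@trueTimes[[1]])]
  expect_true(all(abs(troughs - tplMin) < 1e-9))
})

test_that("spike-free spatial covariance approaches the requested one", {
  geom <- linearGeometry(4, 20)
  d <- as.matrix(dist(geom))
  C <- 64 * exp(-d / 50)
  errFor <- function(durationS) {
    gt <- makeRecording(units = 1, durationS = durationS, rateHz = 0.2,
                        geometry = geom, noiseCov = C, seed = 9)
    sig <- gt@recording@signal
    # exclude spike neighbourhoods
    mask <- rep(TRUE, ncol(sig))
    for (t in gt@trueTimes[[1]]) mask[max(1, t - 60):(t + 60)] <- FALSE
    Chat <- cov(t(sig[, mask]))
    norm(Chat - C, "F") / norm(C, "F")
  }
  eShort <- errFor(5)
  eLong <- errFor(40)
  expect_lt(eLong, 0.15)
  expect_lt(eLong, eShort + 0.02)  # error shrinks with duration
})

test_that("recording invariants hold: refractoriness and conservation", {
  gt <- smallRecording(units = 3, durationS = 15, seed = 21)
  expect_true(validObject(gt))
  for (tt in gt@trueTimes) {
    if (length(tt) > 1)
      expect_true(all(diff(tt) / 10000 * 1000 >= gt@refractoryMs - 1e-9))
  }
  expect_error(makeRecording(units = 1, durationS = 1, rateHz = 0.1,
                             geometry = linearGeometry(4, 20)),
               "at least one spike")
  expect_error(makeRecording(units = 1, durationS = 5, rateHz = 5,
                             geometry = rbind(c(0, 0), c(0, 0))),
               "overlap")
})

test_that("replication stacks shifted channel blocks with shifted truth", {
  gt <- makeRecording(units = 2, durationS = 5, rateHz = 4,
                      geometry = tetrodeGeometry(), seed = 3)
  r1 <- replicateRecording(gt, copies = 1, shiftS = 0)
  expect_equal(r1@recording@signal, gt@recording@signal,
               ignore_attr = TRUE)
  expect_equal(r1@trueTimes, gt@trueTimes)

  r8 <- replicateRecording(gt, copies = 8, shiftS = 0.1)
  expect_equal(nrow(r8@recording@signal), 32)
  expect_length(r8@trueTimes, 16)  # 8 copies x 2 units
  expect_equal(r8@recording@positionsUm,
               linearGeometry(32, 20), ignore_attr = TRUE)
  # truth offsets match the block shift
  expect_equal(r8@trueTimes[[3]][1] - r8@trueTimes[[1]][1], 1000)

  expect_error(replicateRecording(gt, copies = 60, shiftS = 0.1),
               "exceeds")
})

test_that("cross-correlation of replicated blocks peaks at the shift", {
  geom <- tetrodeGeometry()
  gt <- makeRecording(units = 1, durationS = 3, rateHz = 5,
                      geometry = geom, jitterSd = 0,
                      noiseCov = matrix(0, 4, 4), seed = 13)
  r2 <- replicateRecording(gt, copies = 2, shiftS = 0.05)
  a <- r2@recording@signal[1, ]
  b <- r2@recording@signal[5, ]
  cc <- ccf(b, a, lag.max = 800, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 500)
})

test_that("injection is additive, jitter-calibrated, and conserving", {
  geom <- linearGeometry(6, 20)
  zero <- new("Recording", signal = matrix(0, 6, 30000), rateHz = 10000,
              positionsUm = geom, band = c(200, 4000))
  tpl <- makeTemplate("biphasic", geom, c(8, 50), 80, rateHz = 10000)
  times <- list(seq(500, 29000, by = 150))
  gt0 <- injectSpikes(zero, list(tpl), times, jitterSd = 0, seed = 4)
  # jitter 0 on a zero recording: output is exactly the template train,
  # and subtracting it restores the input bit-exactly
  back <- gt0@recording@signal
  trough <- which.min(tpl[which.min(apply(tpl, 1, min)), ])
  for (t in times[[1]]) {
    lo <- t - (trough - 1)
    back[, lo:(lo + ncol(tpl) - 1)] <- back[, lo:(lo + ncol(tpl) - 1)] - tpl
  }
  expect_true(all(back == 0))
  expect_equal(sum(lengths(gt0@trueTimes)), length(times[[1]]))

  gt1 <- injectSpikes(zero, list(tpl), times, jitterSd = 0.10, seed = 4)
  peakCh <- which.min(apply(tpl, 1, min))
  scales <- gt1@recording@signal[peakCh, times[[1]]] / min(tpl)
  expect_lt(abs(sd(scales) - 0.10), 0.02)

  wide <- makeTemplate("biphasic", linearGeometry(8, 20), c(8, 50), 80,
                       rateHz = 10000)
  expect_error(injectSpikes(zero, list(wide), times), "channel count")
  expect_error(injectSpikes(zero, list(tpl), list(c(10, 40000))),
               "outside")
})

test_that("identical generator arguments give bit-identical output", {
  g1 <- smallRecording(seed = 42, durationS = 5)
  g2 <- smallRecording(seed = 42, durationS = 5)
  expect_identical(g1@recording@signal, g2@recording@signal)
  expect_identical(g1@trueTimes, g2@trueTimes)
})
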