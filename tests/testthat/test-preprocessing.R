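# Filtering, robust detection, lumping, whitening, spatial windowing.

mkRec <- function(sig, rateHz = 10000, geom = linearGeometry(nrow(sig), 20)) {
  new("Recording", signal = sig, rateHz = rateHz, positionsUm = geom,
      band = c(200, 4000))
}

test_that("band-pass keeps the passband, kills DC and low frequencies", {
  t <- seq(0, 1, by = 1e-4)[-1]
  s1k <- sin(2 * pi * 1000 * t)
  s10 <- sin(2 * pi * 10 * t)
  rec <- mkRec(rbind(s1k, s10 + 2))
  out <- bandpassFilter(rec)
  mid <- 3000:7000
  # forward-backward filtering squares the magnitude response, so the
  # 1-kHz amplitude sits just below unity
  expect_gt(max(abs(out@signal[1, mid])), 0.94)
  att <- max(abs(out@signal[2, mid]))  # 10 Hz + DC offset
  expect_lt(20 * log10(att / 1), -20)
  expect_lt(abs(mean(out@signal[2, ])), 0.02)
  expect_error(bandpassFilter(rec, c(200, 6000)), "Nyquist")
})

test_that("the detection threshold follows the robust-SD rule", {
  v <- c(-1, 1) * 0.6745  # median(|v|) = 0.6745
  expect_equal(detectionThreshold(rep(v, 50), zTh = 5), -5)
  expect_warning(th0 <- detectionThreshold(rep(0, 100)), "degenerate")
  expect_identical(th0, 0)
  x <- withr::with_seed(1, rnorm(1e6))
  expect_equal(detectionThreshold(x, zTh = 5), -5, tolerance = 0.01)
})

test_that("detection finds injected troughs and drops quiet signals", {
  geom <- linearGeometry(4, 20)
  noise <- withr::with_seed(3, matrix(rnorm(4 * 20000), 4))
  rec <- bandpassFilter(mkRec(noise))
  expect_equal(nSpikes(detectSpikes(rec, zTh = 12)), 0)  # nothing crosses

  tpl <- makeTemplate("biphasic", geom, c(8, 25), 60, rateHz = 10000)
  gt <- injectSpikes(mkRec(noise), list(tpl), list(c(5000, 12000)),
                     jitterSd = 0, seed = 1)
  ens <- detectSpikes(bandpassFilter(gt@recording))
  expect_equal(nSpikes(ens), 2)
  # brute-force trough: global minimum near the injection
  best <- which.min(gt@recording@signal[which.min(apply(tpl, 1, min)), ])
  expect_lte(min(abs(ens@times - best)), 1)
})

test_that("near-simultaneous detections on nearby channels are lumped", {
  geom <- linearGeometry(4, 20)
  sig <- withr::with_seed(5, matrix(rnorm(4 * 20000), 4)) * 0.3
  # two pulses 0.3 ms apart on adjacent channels, the second deeper
  sig[1, 8000 + 0:4] <- sig[1, 8000 + 0:4] - c(3, 6, 8, 6, 3)
  sig[2, 8003 + 0:4] <- sig[2, 8003 + 0:4] - c(4, 8, 10, 8, 4)
  rec <- mkRec(sig)
  ens <- detectSpikes(rec, zTh = 5, tauCMs = 0.6)
  expect_equal(nSpikes(ens), 1)
  expect_equal(ens@times[1], 8005)        # the larger trough wins
  expect_equal(unname(ens@windows[1, ]), c(1, 2))

  # idempotence: lumped output re-lumps to itself
  det <- data.frame(time = ens@times, channel = ens@windows[, 1],
                    amp = -10)
  lum2 <- consensusSort:::lumpDetections(det, geom, 6, 60)
  expect_equal(nrow(lum2), nSpikes(ens))
})

test_that("whitening normalizes correlated noise and is scale-equivariant", {
  geom <- linearGeometry(4, 20)
  d <- as.matrix(dist(geom))
  C <- 25 * exp(-d / 40)
  gt <- makeRecording(units = 1, durationS = 25, rateHz = 0.5,
                      geometry = geom, noiseCov = C, seed = 31)
  filt <- bandpassFilter(gt@recording)
  ens <- detectSpikes(filt)
  w <- whitenWaveforms(ens, filt)
  expect_true(w@whitened)

  # whitened spike-free snippets have ~identity covariance
  Chat <- noiseCovariance(filt)
  W <- consensusSort:::zcaWhitener(Chat)
  quiet <- W %*% filt@signal[, 5000:30000]
  expect_lt(norm(cov(t(quiet)) - diag(4), "F"), 0.1)

  # identity covariance leaves waveforms unchanged
  wId <- whitenWaveforms(ens, filt, noiseCov = diag(4))
  expect_equal(wId@waveforms, ens@waveforms, tolerance = 1e-10)

  # scaling all channels by 2 leaves the whitened output invariant
  ens2 <- ens
  ens2@waveforms <- ens@waveforms * 2
  w2 <- whitenWaveforms(ens2, filt, noiseCov = 4 * Chat)
  wA <- whitenWaveforms(ens, filt, noiseCov = Chat)
  expect_equal(w2@waveforms, wA@waveforms, tolerance = 1e-8)
})

test_that("spatial windowing replaces only channels far from the window", {
  # tetrode-sized arrays pass through unchanged
  wfT <- array(rnorm(5 * 4 * 16), c(5, 4, 16))
  ensT <- new("SpikeEnsemble", times = as.numeric(1:5) * 100,
              waveforms = wfT, windows = cbind(rep(1L, 5), rep(4L, 5)),
              waveRateHz = 8000, recRateHz = 10000, tauWfMs = 2,
              whitened = TRUE, nDropped = 0L)
  expect_identical(spatialWindow(ensT, tetrodeGeometry()), ensT)

  # 32-channel array, spike on channels 10-12, 40-um margin at 20-um pitch
  wf <- array(7, c(1, 32, 8))
  ens <- new("SpikeEnsemble", times = 100, waveforms = wf,
             windows = cbind(10L, 12L), waveRateHz = 8000,
             recRateHz = 10000, tauWfMs = 1, whitened = TRUE,
             nDropped = 0L)
  out <- spatialWindow(ens, linearGeometry(32, 20), marginUm = 40,
                       seed = 9)
  keptCh <- 8:14
  expect_identical(out@waveforms[1, keptCh, ], wf[1, keptCh, ])
  far <- setdiff(1:32, keptCh)
  expect_true(all(out@waveforms[1, far, ] != 7))
  expect_equal(sd(out@waveforms[1, far, ]), 1, tolerance = 0.2)

  # margin at least the array extent: identity
  outAll <- spatialWindow(ens, linearGeometry(32, 20), marginUm = 1000)
  expect_identical(outAll@waveforms, wf)
})

test_that("noiseless detection recalls every suprathreshold spike", {
  gt <- makeRecording(units = 2, durationS = 20, rateHz = 3,
                      geometry = linearGeometry(8, 20), jitterSd = 0,
                      noiseCov = matrix(0, 8, 8), seed = 17)
  ens <- detectSpikes(bandpassFilter(gt@recording))
  truth <- sort(unlist(gt@trueTimes))
  hit <- vapply(truth, function(t) any(abs(ens@times - t) <= 20), TRUE)
  expect_true(all(hit))
})
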