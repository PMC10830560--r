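test_that("bandpass removes DC, keeps the band, rejects 100 Hz", {
  fs <- 1000
  dc <- AnalogTrial(rep(2, 7000), fs, "LFP", OdorStimulus("hex", 2))
  expect_lt(max(abs(traceValues(bandpassFilter(dc)))), 2e-3)

  s20 <- fixtureSineTrial(20)
  out <- traceValues(bandpassFilter(s20))[2000:5000]
  expect_lt(abs(max(out) - 1), 0.05)

  s100 <- fixtureSineTrial(100)
  att <- max(abs(traceValues(bandpassFilter(s100))[2000:5000]))
  expect_lt(att, 10^(-20 / 20))  # >= 20 dB down

  slow <- AnalogTrial(rep(0, 700), 90, "LFP", OdorStimulus("hex", 2))
  expect_error(bandpassFilter(slow), "twice the upper band edge")
})

test_that("spectrogram geometry and content match the direct-DFT oracle", {
  z <- AnalogTrial(rep(0, 3000), 1000, "LFP", OdorStimulus("hex", 1))
  expect_true(all(specPower(computeSpectrogram(z)) == 0))

  s20 <- fixtureSineTrial(20)
  sp <- computeSpectrogram(s20)
  expect_equal(diff(specFreqs(sp)[1:2]), 2)       # 1 / 0.5 s window
  expect_equal(diff(specTimes(sp)[1:2]), 0.25)    # 50% overlap
  peakRow <- apply(specPower(sp), 1, function(p) specFreqs(sp)[which.max(p)])
  expect_true(all(peakRow == 20))

  # linear chirp: per-column argmax increases, and power equals direct sums
  fs <- 1000; tt <- (0:(4 * fs - 1)) / fs
  chirp <- AnalogTrial(sin(2 * pi * (10 * tt + 2.5 * tt^2)), fs, "LFP",
                       OdorStimulus("hex", 1))
  spc <- computeSpectrogram(chirp)
  am <- apply(specPower(spc), 1, which.max)
  expect_true(all(diff(am) >= 0))
  for (col in c(1L, 4L, 8L)) {
    start <- 1L + (col - 1L) * 250L
    expect_equal(specPower(spc)[col, ],
                 oracleStftColumn(traceValues(chirp), start, 500L),
                 tolerance = 1e-8)
  }

  tiny <- AnalogTrial(rep(0, 100), 1000, "LFP", OdorStimulus("hex", 0.01))
  expect_error(computeSpectrogram(tiny), "shorter than one")
})

test_that("total sinusoid power is invariant to phase", {
  p0 <- sum(specPower(computeSpectrogram(fixtureSineTrial(20, phase = 0))))
  p1 <- sum(specPower(computeSpectrogram(fixtureSineTrial(20, phase = 1.1))))
  expect_equal(p0, p1, tolerance = 1e-3)
})

test_that("trial averaging excludes trials 1-2 and reduces noise", {
  mk <- function(idx, amp) {
    tr <- fixtureSineTrial(20, amp = amp)
    tr@trial_index <- idx
    tr
  }
  clean <- lapply(3:10, mk, amp = 1)
  outliers <- lapply(1:2, mk, amp = 50)
  avg <- averageSpectrograms(c(outliers, clean))
  expect_equal(specPower(avg), specPower(computeSpectrogram(clean[[1]])),
               tolerance = 1e-9)

  # averaging noisy trials raises the peak-bin SNR above any single trial
  set.seed(19)
  noisy <- lapply(3:10, function(k) {
    tr <- genLFPTrials(25, n_trials = 1, seed = NULL)[[1]]
    tr@trial_index <- k
    bandpassFilter(tr)
  })
  # SNR: burst-bin power against the strongest pre-onset noise power
  snr <- function(sp) {
    band <- specFreqs(sp) >= 3 & specFreqs(sp) <= 50
    sig <- max(specPower(sp)[specTimes(sp) >= 2 & specTimes(sp) <= 4, band])
    noise <- max(specPower(sp)[specTimes(sp) < 2, band])
    sig / noise
  }
  snrAvg <- snr(averageSpectrograms(noisy))
  snrOne <- vapply(noisy, function(tr) snr(computeSpectrogram(tr)),
                   numeric(1))
  expect_gt(snrAvg, max(snrOne))

  short <- fixtureSineTrial(20, dur = 6)
  expect_error(averageSpectrograms(list(fixtureSineTrial(20), short),
                                   trial_range = NULL), "mismatched")
})

test_that("peak frequency honors the analysis window and the band", {
  # 15 Hz burst inside the window, 30 Hz outside
  fs <- 1000; tt <- (0:(7 * fs - 1)) / fs
  x <- ifelse(tt >= 2 & tt < 3, sin(2 * pi * 15 * tt), 0) +
    ifelse(tt >= 4.5 & tt < 5.5, 2 * sin(2 * pi * 30 * tt), 0)
  tr <- AnalogTrial(x, fs, "LFP", OdorStimulus("hex", 2))
  f <- peakFrequency(computeSpectrogram(tr), stimulus(tr))
  expect_equal(as.numeric(f), 15, tolerance = 1.01)

  # exact on the 2 Hz grid, within one bin off-grid
  for (fg in seq(6, 44, by = 4)) {
    sp <- computeSpectrogram(fixtureSineTrial(fg))
    expect_equal(as.numeric(peakFrequency(sp, OdorStimulus("hex", 2))), fg)
  }
  for (fo in c(11.3, 27.7)) {
    sp <- computeSpectrogram(fixtureSineTrial(fo))
    expect_lte(abs(as.numeric(peakFrequency(sp, OdorStimulus("hex", 2))) - fo),
               2)
  }

  # flat white noise: low-confidence flag
  set.seed(20)
  wn <- AnalogTrial(rnorm(7000, 0, 0.05), 1000, "LFP", OdorStimulus("hex", 2))
  fw <- peakFrequency(computeSpectrogram(wn), OdorStimulus("hex", 2))
  expect_true(attr(fw, "low_confidence"))
})

test_that("oscillation summaries recover generator ground truth", {
  s <- oscillationSummary(genLFPTrials(25, n_trials = 10, seed = 22))
  expect_equal(s$peak_frequency_hz, 20)
  expect_equal(s$amplitude_mV, 0.2, tolerance = 0.15)
  expect_gt(s$duration_s, 0.6); expect_lt(s$duration_s, 1.3)
  expect_gt(s$latency_s, 0.3); expect_lt(s$latency_s, 0.55)
  expect_false(s$low_confidence)

  # doubling the burst amplitude doubles amplitude, leaves the rest
  cfgA <- SynthConfig(lfp = list(noise_sd_mV = 0.004, white_sd_mV = 0.001))
  cfgB <- SynthConfig(lfp = list(noise_sd_mV = 0.004, white_sd_mV = 0.001,
                                 amplitude_mV = c(adult = 0.4)))
  sA <- oscillationSummary(genLFPTrials(25, cfg = cfgA, n_trials = 5,
                                        seed = 23))
  sB <- oscillationSummary(genLFPTrials(25, cfg = cfgB, n_trials = 5,
                                        seed = 23))
  expect_equal(sB$amplitude_mV / sA$amplitude_mV, 2, tolerance = 0.05)
  expect_equal(sB$peak_frequency_hz, sA$peak_frequency_hz)
  expect_equal(sB$duration_s, sA$duration_s, tolerance = 0.2)

  # zero-amplitude burst: no oscillation span
  cfg0 <- SynthConfig(lfp = list(amplitude_mV = c(adult = 0)))
  s0 <- oscillationSummary(genLFPTrials(25, cfg = cfg0, n_trials = 10,
                                        seed = 24))
  expect_identical(s0$duration_s, 0)
  expect_true(is.na(s0$latency_s))
})

test_that("recovered burst frequency is monotone in segment count", {
  for (seed in 1:20) {
    segs <- c(10, 15, 20, 25)
    f <- vapply(segs, function(ns) {
      trls <- genLFPTrials(ns, n_trials = 6, seed = seed * 100 + ns)
      bp <- lapply(trls, bandpassFilter)
      as.numeric(peakFrequency(averageSpectrograms(bp, trial_range = NULL),
                               stimulus(trls[[1]])))
    }, numeric(1))
    expect_true(all(diff(f) >= 0))
  }
})

test_that("the contralateral estimate ignores ipsilateral trials entirely", {
  ds <- genTrimExperiment(c(25, 21, 17), n_animals = 2, seed = 25)
  # few animals and no trend: the fit can be numerically exact
  full <- suppressWarnings(trimFrequencyRegression(ds, "contra"))
  keep <- vapply(trials(ds), function(tr) tr@side == "contra", logical(1))
  contraOnly <- EphysDataset(trials(ds)[keep], manifest(ds))
  stripped <- suppressWarnings(trimFrequencyRegression(contraOnly, "contra"))
  expect_identical(full$slope_hz_per_cut, stripped$slope_hz_per_cut)
  expect_identical(full$points, stripped$points)

  oneStage <- genTrimExperiment(25, n_animals = 1, seed = 26)
  expect_error(trimFrequencyRegression(oneStage, "ipsi"),
               "two distinct cut counts")
})
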