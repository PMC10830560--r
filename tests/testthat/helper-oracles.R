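# Independent oracles used by the unit and acceptance tests. Each one is a
# deliberately slow, literal evaluation of the rule it checks, sharing no
# code with the implementation.

# Per-sample inverse-ISI rule: for each time point, search the spike list
# directly for the bracketing interval sp[i] < t <= sp[i+1].
oracleIsiRate <- function(spikes, times) {
  vapply(times, function(t) {
    for (i in seq_len(length(spikes) - 1L)) {
      if (spikes[i] < t && t <= spikes[i + 1L])
        return(1 / (spikes[i + 1L] - spikes[i]))
    }
    0
  }, numeric(1))
}

# Direct O(n*k) convolution with a unit-sum truncated Gaussian and reflect
# padding; mirrors the smoothing contract sample by sample.
oracleGaussianSmooth <- function(x, dt, sigma, width) {
  half <- max(1L, round(width / 2 / dt))
  kern <- exp(-0.5 * ((-half:half) * dt / sigma)^2)
  kern <- kern / sum(kern)
  n <- length(x)
  reflect <- function(i) {
    # map index onto 1..n by mirroring (without repeating the edge sample)
    while (i < 1L || i > n) {
      if (i < 1L) i <- 2L - i
      if (i > n) i <- 2L * n - i
    }
    i
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in -half:half) s <- s + kern[j + half + 1L] * x[reflect(i + j)]
    out[i] <- s
  }
  out
}

# Literal scan of the lookahead/delta confirmation rule, written as an
# explicit two-state machine over every sample (state: which extremum is
# being sought). Candidates confirmed at the very first sample are dropped
# as initialization artifacts, as the contract specifies.
oraclePeakDetect <- function(y, t, lookahead, delta) {
  n <- length(y)
  peaks <- list(); valleys <- list()
  if (n <= lookahead) return(list(peaks = peaks, valleys = valleys))
  state <- "both"
  mx <- -Inf; mn <- Inf; mxi <- NA; mni <- NA
  i <- 1L
  while (i <= n - lookahead) {
    if (state %in% c("both", "max") && y[i] > mx) { mx <- y[i]; mxi <- i }
    if (state %in% c("both", "min") && y[i] < mn) { mn <- y[i]; mni <- i }
    confirmedMax <- state %in% c("both", "max") && is.finite(mx) &&
      y[i] < mx - delta && max(y[i:(i + lookahead - 1L)]) < mx
    if (confirmedMax) {
      if (mxi > 1L) peaks[[length(peaks) + 1L]] <- c(t[mxi], mx)
      state <- "min"; mn <- Inf; mni <- NA; mx <- Inf
      if (i + lookahead >= n) break
      i <- i + 1L
      next
    }
    confirmedMin <- state %in% c("both", "min") && is.finite(mn) &&
      y[i] > mn + delta && min(y[i:(i + lookahead - 1L)]) > mn
    if (confirmedMin) {
      if (mni > 1L) valleys[[length(valleys) + 1L]] <- c(t[mni], mn)
      state <- "max"; mx <- -Inf; mxi <- NA; mn <- -Inf
      if (i + lookahead >= n) break
    }
    i <- i + 1L
  }
  list(peaks = peaks, valleys = valleys)
}

# Brute-force ECDF supremum over a fine grid of both samples' values.
oracleKsStatistic <- function(a, b) {
  grid <- sort(c(a, b))
  best <- 0
  for (x in grid) {
    d <- abs(sum(a <= x) / length(a) - sum(b <= x) / length(b))
    if (d > best) best <- d
  }
  best
}

# Direct DFT sums for a Hann-windowed segment starting at sample `start`
# (1-based), window length nwin: P[f] = |sum_k x[k] w[k] e^{-2pi i f k}|^2.
oracleStftColumn <- function(x, start, nwin) {
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nwin - 1)) / (nwin - 1))
  seg <- x[start:(start + nwin - 1L)] * w
  nf <- floor(nwin / 2) + 1L
  vapply(seq_len(nf), function(fi) {
    k <- 0:(nwin - 1)
    re <- sum(seg * cos(-2 * pi * (fi - 1) * k / nwin))
    im <- sum(seg * sin(-2 * pi * (fi - 1) * k / nwin))
    re^2 + im^2
  }, numeric(1))
}

# Exhaustive (or near-exhaustive) permutation p-value for the two-sample
# t statistic.
oraclePermutationT <- function(a, b, variant = "pooled") {
  pool <- c(a, b)
  n <- length(a)
  idx <- utils::combn(length(pool), n)
  tobs <- abs(olfOntogeny::tTwoSample(a, b, variant)$statistic)
  ts <- apply(idx, 2L, function(ia) {
    abs(olfOntogeny::tTwoSample(pool[ia], pool[-ia], variant)$statistic)
  })
  mean(ts >= tobs - 1e-12)
}

# Closed-form normal-equation OLS solve.
oracleOlsSolve <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)
}

# Small deterministic fixture builders -------------------------------------

fixtureSpikeTrial <- function(spikes, dur = 8, onset = 2, odor = "hex",
                              trial = 1L, cell = "c1",
                              animal = AnimalMeta("a1", "adult")) {
  SpikeTrainTrial(spikes, dur, OdorStimulus(odor, onset),
                  trial_index = trial, cell_id = cell, animal = animal)
}

fixtureSineTrial <- function(freq_hz, fs = 1000, dur = 7, onset = 2,
                             amp = 1, phase = 0, modality = "LFP") {
  tt <- (seq_len(dur * fs) - 1) / fs
  AnalogTrial(amp * sin(2 * pi * freq_hz * tt + phase), fs, modality,
              OdorStimulus("hex", onset))
}

# Well-separated, low-noise demonstration profile for statistical recovery
# of the transition count: 0.5 s excitatory epochs at high transient rates,
# silenced inhibitory epochs, sparse baseline.
fixtureRecoveryProfile <- function(onset = 2) {
  RateProfile(onset + c(0.3, 0.8, 1.4, 1.9, 2.9),
              c(100, 0, 70, 0), baseline_hz = 2, onset_s = onset)
}
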