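# Odor-evoked LFP oscillation pipeline: zero-phase bandpass, Hann
# spectrograms, trial-averaged peak-frequency extraction, burst property
# summaries, and the antennal-trimming frequency regression.

#' Zero-phase 3-50 Hz bandpass filter
#'
#' Butterworth bandpass (order 4 per direction) applied forward-backward
#' with [signal::filtfilt()], so the filter is zero-phase and burst latency
#' estimates downstream are not shifted. The trace mean is removed and the
#' ends are padded by odd reflection before filtering, which suppresses the
#' start-up transients a step from zero initial conditions would inject;
#' the padding is trimmed from the result.
#'
#' @param trial an [AnalogTrial-class] sampled above 100 Hz.
#' @param low,high passband edges in Hz (defaults 3 and 50).
#' @param order Butterworth order per direction (default 4).
#' @return The trial with filtered `values_mV`.
#' @export
bandpassFilter <- function(trial, low = 3, high = 50, order = 4) {
  stopifnot(is(trial, "AnalogTrial"))
  fs <- trial@fs_hz
  if (fs <= 2 * high)
    stop("sampling rate must exceed twice the upper band edge (",
         2 * high, " Hz)")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  x <- trial@values_mV - mean(trial@values_mV)
  n <- length(x)
  npad <- min(n - 1L, round(3 * fs / low))
  pre <- 2 * x[1L] - x[(npad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - npad)]
  y <- as.numeric(signal::filtfilt(bf, c(pre, x, post)))
  trial@values_mV <- y[(npad + 1L):(npad + n)]
  trial
}

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

#' Short-time power spectrogram
#'
#' Hann-tapered short-time power spectra with a 0.5 s window and 50% overlap
#' between successive window positions (2 Hz frequency resolution); time
#' centers sit at window midpoints on the trial's own time axis. Power is
#' the squared magnitude of the one-sided DFT.
#'
#' @param trial an [AnalogTrial-class], already band-passed.
#' @param window_s analysis window in seconds (default 0.5).
#' @param overlap_fraction overlap between windows (default 0.5).
#' @return A [SpectrogramResult-class].
#' @export
computeSpectrogram <- function(trial, window_s = 0.5,
                               overlap_fraction = 0.5) {
  stopifnot(is(trial, "AnalogTrial"), overlap_fraction >= 0,
            overlap_fraction < 1)
  fs <- trial@fs_hz
  x <- trial@values_mV
  n <- round(window_s * fs)
  if (length(x) < n)
    stop("trace shorter than one analysis window")
  hop <- max(1L, round(n * (1 - overlap_fraction)))
  starts <- seq(1L, length(x) - n + 1L, by = hop)
  w <- .hann(n)
  segs <- vapply(starts, function(s) x[s:(s + n - 1L)] * w, numeric(n))
  ft <- stats::mvfft(matrix(segs, nrow = n))
  nf <- floor(n / 2) + 1L
  pow <- t(Mod(ft[seq_len(nf), , drop = FALSE])^2)
  new("SpectrogramResult",
      time_centers_s = (starts - 1 + (n - 1) / 2) / fs,
      freq_centers_hz = (seq_len(nf) - 1L) * fs / n,
      power = pow, window_s = window_s,
      overlap_fraction = overlap_fraction)
}

#' Trial-averaged spectrogram
#'
#' Computes per-trial spectrograms and averages their power element-wise.
#' Trials 3-10 are used by default: oscillations usually only develop after
#' the first two odor presentations, so those are excluded.
#'
#' @param trls list of band-passed [AnalogTrial-class] with identical
#'   sampling rate and length.
#' @param trial_range trial indices to include (default `3:10`).
#' @param ... passed to [computeSpectrogram()].
#' @return A [SpectrogramResult-class] holding the mean power.
#' @export
averageSpectrograms <- function(trls, trial_range = 3:10, ...) {
  stopifnot(length(trls) >= 1L)
  if (!is.null(trial_range)) {
    keep <- vapply(trls, trialIndex, integer(1)) %in% trial_range
    trls <- trls[keep]
  }
  if (!length(trls))
    stop("no trials fall in the requested trial range")
  specs <- lapply(trls, computeSpectrogram, ...)
  dims <- vapply(specs, function(s) dim(s@power), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("trials produce mismatched spectrogram shapes; sampling rate or ",
         "length differ")
  avg <- Reduce(`+`, lapply(specs, specPower)) / length(specs)
  out <- specs[[1L]]
  out@power <- avg
  out
}

#' Peak oscillation frequency after odor onset
#'
#' Frequency of the global power maximum over the spectrogram columns whose
#' time centers fall within one second after odor onset (configurable) and
#' the rows within the 3-50 Hz analysis band. The peak is flagged
#' low-confidence unless its power exceeds `prominence_factor` times the
#' strongest pre-stimulus power in the same band (falling back to the
#' in-window median when no pre-stimulus columns exist) — pure noise has no
#' meaningful spectral peak, and the flag gives that case a defined,
#' noise-level-referenced behavior.
#'
#' @param spec a [SpectrogramResult-class] (typically trial-averaged).
#' @param stim the [OdorStimulus-class] the window is keyed to.
#' @param window_s window length after onset (default 1 s).
#' @param window_abs_s optional absolute-time override `c(lo, hi)` in
#'   seconds; when given, `stim`/`window_s` are ignored.
#' @param band frequency band searched (default `c(3, 50)` Hz).
#' @param prominence_factor low-confidence threshold (default 3).
#' @return Peak frequency in Hz with attributes `low_confidence` (logical)
#'   and `power` (peak power).
#' @export
peakFrequency <- function(spec, stim, window_s = 1, window_abs_s = NULL,
                          band = c(3, 50), prominence_factor = 3) {
  stopifnot(is(spec, "SpectrogramResult"))
  win <- if (!is.null(window_abs_s)) window_abs_s
         else stim@onset_s + c(0, window_s)
  tsel <- spec@time_centers_s >= win[1] & spec@time_centers_s <= win[2]
  if (!any(tsel))
    stop("no spectrogram columns fall inside the analysis window")
  fsel <- spec@freq_centers_hz >= band[1] & spec@freq_centers_hz <= band[2]
  sub <- spec@power[tsel, fsel, drop = FALSE]
  ij <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
  f <- spec@freq_centers_hz[fsel][ij[2L]]
  preSel <- spec@time_centers_s < win[1]
  floorPow <- if (any(preSel)) {
    prominence_factor * max(spec@power[preSel, fsel, drop = FALSE])
  } else {
    prominence_factor * stats::median(sub)
  }
  attr(f, "low_confidence") <- max(sub) < floorPow
  attr(f, "power") <- max(sub)
  f
}

# Analytic signal via FFT; Mod() of the result is the envelope.
.analyticSignal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1L] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1L] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Oscillation burst properties of a set of LFP trials
#'
#' Operational definitions (conventions made explicit because figure-level
#' summaries rarely state them): frequency is the post-onset peak of the
#' trial-averaged spectrogram; the envelope is the magnitude of the analytic
#' signal (Hilbert transform) of the band-passed trial-averaged trace;
#' amplitude is the envelope maximum in the response window; duration is the
#' longest contiguous span with envelope above baseline mean + 2 baseline
#' SD; latency is the first such crossing after onset. Suprathreshold runs
#' shorter than `min_span_s` (default 0.1 s, far below any real burst but
#' above the envelope's correlation time) are discarded as chance noise
#' excursions. If no qualifying span exists, duration is 0 and latency is
#' reported missing.
#'
#' @param trls list of [AnalogTrial-class] (>= 1, same grid), raw or
#'   band-passed.
#' @param trial_range trial indices for the spectrogram average (`NULL` =
#'   all trials; default).
#' @param response_window_s response window after onset (default 4 s).
#' @param threshold_sd envelope threshold in baseline SDs (default 2).
#' @param min_span_s shortest suprathreshold run counted as oscillation
#'   (default 0.1 s).
#' @param bandpass apply [bandpassFilter()] first (default TRUE).
#' @return List with `peak_frequency_hz`, `amplitude_mV`, `duration_s`,
#'   `latency_s` (`NA` when no crossing), `low_confidence`.
#' @export
oscillationSummary <- function(trls, trial_range = NULL,
                               response_window_s = 4, threshold_sd = 2,
                               min_span_s = 0.1, bandpass = TRUE) {
  stopifnot(length(trls) >= 1L)
  if (bandpass) trls <- lapply(trls, bandpassFilter)
  stim <- stimulus(trls[[1L]])
  fs <- sampleRate(trls[[1L]])
  spec <- averageSpectrograms(trls, trial_range = trial_range)
  f <- peakFrequency(spec, stim)

  avg <- Reduce(`+`, lapply(trls, traceValues)) / length(trls)
  env <- Mod(.analyticSignal(avg))
  tt <- (seq_along(env) - 1L) / fs
  pre <- env[tt < stim@onset_s]
  if (!length(pre)) stop("no pre-onset samples: baseline envelope undefined")
  thr <- mean(pre) + threshold_sd * stats::sd(pre)
  inWin <- tt >= stim@onset_s & tt <= stim@onset_s + response_window_s
  above <- env > thr & inWin

  amplitude <- max(env[inWin])
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  qual <- runs$values & runs$lengths >= round(min_span_s * fs)
  if (any(qual)) {
    duration <- max(runs$lengths[qual]) / fs
    firstStart <- ends[which(qual)[1L]] - runs$lengths[which(qual)[1L]] + 1L
    latency <- tt[firstStart] - stim@onset_s
  } else {
    duration <- 0
    latency <- NA_real_
  }
  list(peak_frequency_hz = as.numeric(f), amplitude_mV = amplitude,
       duration_s = duration, latency_s = latency,
       low_confidence = attr(f, "low_confidence"))
}

#' Peak-frequency regression against the number of trimmed segments
#'
#' For each (animal, trimming stage) on the requested side, band-passes the
#' LFP trials, averages the spectrograms of trials 3-10 (oscillations only
#' develop after the first two presentations) and extracts the post-onset
#' peak frequency; then fits an ordinary least squares regression of those
#' per-stage frequencies on the cumulative number of cut segments. On the
#' trimmed (ipsilateral) side the slope estimates the frequency lost per
#' removed segment; the untrimmed contralateral side serves as the
#' within-animal control and should show no trend.
#'
#' @param ds an [EphysDataset-class] containing a trimming experiment.
#' @param side `"ipsi"` or `"contra"`.
#' @param trial_range trials entering the average (default `3:10`).
#' @return List with `side`, `slope_hz_per_cut`, `se`, `r_squared`, `p`,
#'   `n_points`, and `points` (data frame animal/stage/cuts/frequency).
#' @export
trimFrequencyRegression <- function(ds, side = c("ipsi", "contra"),
                                    trial_range = 3:10) {
  side <- match.arg(side)
  stopifnot(is(ds, "EphysDataset"))
  sel <- vapply(ds@trials, function(tr)
    is(tr, "AnalogTrial") && tr@modality == "LFP" && tr@side == side,
    logical(1))
  trls <- ds@trials[sel]
  if (!length(trls)) stop("no LFP trials for side '", side, "'")
  if (any(vapply(trls, function(tr) is.na(tr@cuts), logical(1))))
    stop("trim regression requires the per-trial cut count")
  key <- vapply(trls, function(tr)
    paste(tr@animal@animal_id, tr@stage, sep = "|"), character(1))
  groups <- split(trls, key)

  rows <- lapply(groups, function(g) {
    bp <- lapply(g, bandpassFilter)
    spec <- averageSpectrograms(bp, trial_range = trial_range)
    f <- peakFrequency(spec, stimulus(g[[1L]]))
    data.frame(animal = g[[1L]]@animal@animal_id, stage = g[[1L]]@stage,
               cuts = g[[1L]]@cuts, frequency_hz = as.numeric(f),
               stringsAsFactors = FALSE)
  })
  pts <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (length(unique(pts$cuts)) < 2L)
    stop("need at least two distinct cut counts for the regression")
  fit <- stats::lm(frequency_hz ~ cuts, data = pts)
  sm <- summary(fit)
  co <- sm$coefficients
  list(side = side,
       slope_hz_per_cut = co["cuts", "Estimate"],
       se = co["cuts", "Std. Error"],
       r_squared = sm$r.squared,
       p = co["cuts", "Pr(>|t|)"],
       n_points = nrow(pts),
       points = pts)
}
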