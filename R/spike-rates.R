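# Firing-rate estimation: histogram bin rates, the inverse-ISI instantaneous
# rate, and Gaussian smoothing of rate series.

#' Histogram firing rates in fixed-width bins
#'
#' Counts spikes in `[k*bin, (k+1)*bin)` over the whole record and divides by
#' the bin width. 400 ms bins are the convention used by the responsiveness
#' gate.
#'
#' @param trial a [SpikeTrainTrial-class].
#' @param bin_s bin width in seconds (default 0.4).
#' @return Numeric vector of per-bin rates in Hz; bin `k` covers
#'   `[(k-1)*bin_s, k*bin_s)`.
#' @examples
#' tr <- SpikeTrainTrial(c(0.1, 0.2, 0.3), 2, OdorStimulus("hex", 1))
#' binnedRates(tr)[1]   # 3 spikes / 0.4 s = 7.5 Hz
#' @export
binnedRates <- function(trial, bin_s = 0.4) {
  stopifnot(is(trial, "SpikeTrainTrial"), bin_s > 0)
  nb <- max(1L, ceiling(trial@record_duration_s / bin_s))
  breaks <- (0:nb) * bin_s
  # right-open bins: [k*bin, (k+1)*bin)
  counts <- tabulate(findInterval(trial@spikes_s, breaks,
                                  rightmost.closed = FALSE), nbins = nb)
  counts / bin_s
}

# Rates in equal right-open windows [breaks[i], breaks[i+1]) of width binw
# (passed explicitly so every bin rate shares the exact same divisor).
.windowRates <- function(spikes, breaks, binw) {
  counts <- tabulate(findInterval(spikes, breaks), nbins = length(breaks))
  counts <- counts[-length(counts)]
  counts / binw
}

#' Instantaneous firing rate as the inverse inter-spike interval
#'
#' For sample times t with `t_i < t <= t_{i+1}` (consecutive spikes) the rate
#' is `1 / (t_{i+1} - t_i)`; before the first and after the last spike the
#' rate is 0 (the inverse interval is undefined there, and zero matches "no
#' observed activity"). Trains with fewer than two spikes yield an all-zero
#' series.
#'
#' @param trial a [SpikeTrainTrial-class].
#' @param dt_s sample spacing in seconds (default 1 ms).
#' @return A [RateSeries-class] sampled on `[0, record_duration_s]`.
#' @export
isiRate <- function(trial, dt_s = 0.001) {
  stopifnot(is(trial, "SpikeTrainTrial"), dt_s > 0)
  n <- floor(trial@record_duration_s / dt_s) + 1L
  tt <- (seq_len(n) - 1L) * dt_s
  sp <- trial@spikes_s
  rates <- numeric(n)
  if (length(sp) >= 2L) {
    idx <- findInterval(tt, sp, left.open = TRUE)  # sp[i] < t <= sp[i+1]
    inside <- idx >= 1L & idx < length(sp)
    rates[inside] <- 1 / diff(sp)[idx[inside]]
  }
  RateSeries(0, dt_s, rates)
}

#' Gaussian smoothing of a rate series
#'
#' Convolution with a truncated, unit-sum Gaussian kernel (33.33 ms standard
#' deviation and 200 ms = 6 SD total width by default). Output length equals
#' input length; edges are handled by reflect padding, which avoids the
#' spurious edge valleys that zero padding would inject into the transition
#' counts.
#'
#' @param rs a [RateSeries-class].
#' @param sigma_s kernel standard deviation in seconds (default 0.03333).
#' @param width_s total kernel width in seconds (default 0.2, i.e. 6 SD).
#' @return A smoothed [RateSeries-class] on the same time grid.
#' @export
gaussianSmooth <- function(rs, sigma_s = 0.03333, width_s = 0.2) {
  stopifnot(is(rs, "RateSeries"))
  if (sigma_s <= 0) stop("sigma_s must be positive")
  half <- max(1L, round(width_s / 2 / rs@dt_s))
  off <- (-half):half
  kern <- exp(-0.5 * (off * rs@dt_s / sigma_s)^2)
  kern <- kern / sum(kern)
  x <- rs@rates_hz
  n <- length(x)
  if (n == 0L) return(rs)
  pad <- min(half, n - 1L)
  # reflect padding (without repeating the edge sample)
  left <- if (pad > 0L) x[(pad + 1L):2L] else numeric(0)
  right <- if (pad > 0L) x[(n - 1L):(n - pad)] else numeric(0)
  if (pad < half) {  # very short series: extend with edge values
    left <- c(rep(x[1L], half - pad), left)
    right <- c(right, rep(x[n], half - pad))
  }
  xp <- c(left, x, right)
  # direct (non-FFT) convolution: flat plateaus stay exactly flat, so a
  # zero-delta peak detector sees no numerical ripple
  sm <- stats::filter(xp, kern, method = "convolution", sides = 2L)
  sm <- as.numeric(sm[(half + 1L):(half + n)])
  RateSeries(rs@t0_s, rs@dt_s, pmax(sm, 0))
}
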