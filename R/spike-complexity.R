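# Projection-neuron response complexity: responsiveness gating, peak/valley
# detection on the smoothed inverse-ISI rate, epoch-transition counting, and
# the age-group comparison of transition-count distributions.

#' Responsiveness of one PN-odor pair
#'
#' A cell is considered responsive in a 400 ms bin if its firing rate within
#' the 4 s window from odor onset differs from the baseline by more than one
#' standard deviation; the pair is included for complexity analysis if some
#' bin is responsive in at least half of its trials. The baseline is the
#' pre-stimulus bin rate averaged across trials. The reference SD is, by
#' default, the SD of the pooled pre-stimulus bin rates across all trials of
#' the pair (the highest-powered reading); a per-trial SD variant is exposed
#' via `sd_mode` because either convention is defensible.
#'
#' @param trls list of [SpikeTrainTrial-class] for one PN-odor pair (>= 1
#'   trial, all with pre-onset data).
#' @param bin_s bin width (default 0.4 s).
#' @param baseline_window_s pre-onset span used for the baseline (default
#'   2 s, clipped to the available pre-onset data).
#' @param response_window_s response span after onset (default 4 s).
#' @param sd_mode `"pooled"` (default) or `"per_trial"`.
#' @return List with `baseline_hz`, `baseline_sd_hz`, `mask` (response-bin by
#'   trial logical matrix), `included`, `n_trials`.
#' @export
assessResponsiveness <- function(trls, bin_s = 0.4, baseline_window_s = 2,
                                 response_window_s = 4,
                                 sd_mode = c("pooled", "per_trial")) {
  sd_mode <- match.arg(sd_mode)
  stopifnot(length(trls) >= 1L)
  onsets <- vapply(trls, stimOnset, numeric(1))
  nbBase <- floor(min(onsets, baseline_window_s) / bin_s)
  if (nbBase < 1L)
    stop("no pre-onset data: baseline rates are undefined")
  nbResp <- round(response_window_s / bin_s)

  baseMat <- vapply(trls, function(tr) {
    on <- stimOnset(tr)
    .windowRates(spikes(tr), on - (nbBase:0) * bin_s, bin_s)
  }, numeric(nbBase))
  baseMat <- matrix(baseMat, nrow = nbBase)
  respMat <- vapply(trls, function(tr) {
    on <- stimOnset(tr)
    .windowRates(spikes(tr), on + (0:nbResp) * bin_s, bin_s)
  }, numeric(nbResp))
  respMat <- matrix(respMat, nrow = nbResp)

  baseline <- mean(baseMat)
  if (sd_mode == "pooled") {
    sdv <- stats::sd(as.vector(baseMat))
    if (is.na(sdv)) sdv <- 0
    mask <- abs(respMat - baseline) > sdv
  } else {
    sdv <- apply(baseMat, 2L, stats::sd)
    sdv[is.na(sdv)] <- 0
    mask <- sweep(abs(respMat - baseline), 2L, sdv, `>`)
  }
  nTr <- length(trls)
  included <- any(rowSums(mask) >= nTr / 2)
  list(baseline_hz = baseline, baseline_sd_hz = sdv, mask = mask,
       included = included, n_trials = nTr)
}

#' Lookahead/delta peak and valley detection
#'
#' Alternating-extrema detection on a rate series: the scan tracks the
#' running candidate maximum (minimum); a peak (valley) is confirmed when the
#' series falls below the candidate minus `delta_hz` (rises above the
#' candidate plus `delta_hz`) and no sample within the lookahead horizon
#' exceeds (undercuts) the candidate. Confirmed extrema strictly alternate.
#' A candidate sitting on the very first sample is an initialization
#' artifact — the series simply started below (above) its surroundings — and
#' is discarded, so monotone series yield no extrema while an interior bump
#' of height greater than `delta_hz` yields exactly one peak.
#'
#' @param rs a [RateSeries-class].
#' @param lookahead_s lookahead horizon in seconds (default 0.2, matching
#'   the smoothing support).
#' @param delta_hz minimum excursion for confirmation (Hz, `>= 0`).
#' @return An [EpochAnnotation-class] with peaks and valleys (transitions
#'   not yet counted). Series shorter than the lookahead yield an empty
#'   annotation.
#' @export
detectPeaksValleys <- function(rs, lookahead_s = 0.2, delta_hz = 0) {
  stopifnot(is(rs, "RateSeries"), delta_hz >= 0)
  la <- max(1L, round(lookahead_s / rs@dt_s))
  y <- rs@rates_hz
  tt <- rateTimes(rs)
  n <- length(y)
  if (n <= la) return(EpochAnnotation())

  pk <- list(); vl <- list()
  mx <- -Inf; mn <- Inf
  mxi <- NA_integer_; mni <- NA_integer_
  for (i in seq_len(n - la)) {
    if (y[i] > mx) { mx <- y[i]; mxi <- i }
    if (y[i] < mn) { mn <- y[i]; mni <- i }
    if (is.finite(mx) && y[i] < mx - delta_hz) {
      if (max(y[i:(i + la - 1L)]) < mx) {
        if (mxi > 1L) pk[[length(pk) + 1L]] <- c(tt[mxi], mx)
        mx <- Inf; mn <- Inf
        if (i + la >= n) break
        next
      }
    }
    if (is.finite(mn) && y[i] > mn + delta_hz) {
      if (min(y[i:(i + la - 1L)]) > mn) {
        if (mni > 1L) vl[[length(vl) + 1L]] <- c(tt[mni], mn)
        mn <- -Inf; mx <- -Inf
        if (i + la >= n) break
      }
    }
  }
  toMat <- function(lst) {
    if (!length(lst)) return(.emptyExtrema())
    m <- do.call(rbind, lst)
    dimnames(m) <- list(NULL, c("time_s", "rate_hz"))
    m
  }
  EpochAnnotation(peaks = toMat(pk), valleys = toMat(vl))
}

#' Count excitatory/inhibitory epoch transitions
#'
#' Peaks mark excitatory epochs and the valleys between them inhibitory
#' epochs, so every valley lying strictly between two in-window peaks counts
#' for two transitions (excitatory-to-inhibitory and back). A
#' spontaneous-to-excitatory transition is counted when the first in-window
#' peak appears more than 200 ms after odor onset, and an
#' excitatory-to-baseline transition when the last in-window peak lies more
#' than 200 ms after onset and before the end of the response window; a lone
#' peak within 200 ms of onset is treated as excitation already ongoing at
#' stimulus time and contributes no boundary transition.
#'
#' @param ann an [EpochAnnotation-class] from [detectPeaksValleys()].
#' @param onset_s odor onset (s).
#' @param window_s response window length (default 4 s).
#' @param guard_s boundary guard (default 0.2 s).
#' @return Integer transition count (`2 * interior valleys + boundary
#'   increments`, the latter in 0..2).
#' @export
countTransitions <- function(ann, onset_s, window_s = 4, guard_s = 0.2) {
  stopifnot(is(ann, "EpochAnnotation"))
  lo <- onset_s; hi <- onset_s + window_s
  pt <- ann@peaks[, 1L][ann@peaks[, 1L] >= lo & ann@peaks[, 1L] <= hi]
  if (!length(pt)) return(0L)
  vt <- ann@valleys[, 1L]
  vInterior <- sum(vt > min(pt) & vt < max(pt))
  b <- 0L
  if (min(pt) > lo + guard_s) b <- b + 1L
  if (max(pt) > lo + guard_s && max(pt) < hi) b <- b + 1L
  as.integer(2L * vInterior + b)
}

#' Per-trial epoch transitions of one spike train
#'
#' Convenience wrapper running the full single-trial pipeline: inverse-ISI
#' rate, Gaussian smoothing, lookahead/delta detection, transition counting.
#'
#' @param trial a [SpikeTrainTrial-class].
#' @param delta_hz detector excursion floor (Hz).
#' @param lookahead_s detector lookahead (s).
#' @param dt_s rate sampling step (s).
#' @param sigma_s,width_s smoothing kernel parameters.
#' @param window_s response window (s).
#' @return Integer transition count.
#' @export
epochTransitions <- function(trial, delta_hz, lookahead_s = 0.2,
                             dt_s = 0.001, sigma_s = 0.03333, width_s = 0.2,
                             window_s = 4) {
  rs <- gaussianSmooth(isiRate(trial, dt_s), sigma_s, width_s)
  ann <- detectPeaksValleys(rs, lookahead_s, delta_hz)
  countTransitions(ann, stimOnset(trial), window_s)
}

#' Transition-count distribution for an age group
#'
#' Applies the responsiveness gate to every PN-odor pair of the requested age
#' group, then computes one transition count per trial of each included pair
#' from the smoothed inverse-ISI rate. The detector's excursion floor
#' defaults to one standard deviation of the pooled pre-onset samples of the
#' smoothed rate series of the pair, tying the prominence floor to the
#' responsiveness criterion; pass `delta_hz` to fix it instead.
#'
#' @param ds an [EphysDataset-class].
#' @param age_group age group to analyze.
#' @param delta_hz fixed detector floor in Hz, or `NULL` (default) for one
#'   baseline SD of the smoothed series per pair.
#' @param lookahead_s detector lookahead (default 0.2 s).
#' @param sd_mode baseline SD convention for the responsiveness gate.
#' @param dt_s,sigma_s,width_s rate sampling and smoothing parameters.
#' @param window_s response window (default 4 s).
#' @return Integer vector of per-trial transition counts, with attribute
#'   `"pairs"`: a data frame describing every pair (cell, odor, included,
#'   n_trials). Empty (with a warning) when no pair passes the gate.
#' @export
complexityDistribution <- function(ds, age_group, delta_hz = NULL,
                                   lookahead_s = 0.2,
                                   sd_mode = c("pooled", "per_trial"),
                                   dt_s = 0.001, sigma_s = 0.03333,
                                   width_s = 0.2, window_s = 4) {
  sd_mode <- match.arg(sd_mode)
  stopifnot(is(ds, "EphysDataset"))
  isSpike <- vapply(ds@trials, is, logical(1), "SpikeTrainTrial")
  trls <- ds@trials[isSpike]
  trls <- trls[vapply(trls, ageGroup, character(1)) == age_group]
  if (!length(trls)) {
    warning("no spike trials for age group '", age_group, "'")
    out <- integer(0)
    attr(out, "pairs") <- data.frame(cell = character(), odor = character(),
                                     included = logical(),
                                     n_trials = integer())
    return(out)
  }
  key <- vapply(trls, function(tr) paste(tr@cell_id, odorLabel(tr), sep = "|"),
                character(1))
  groups <- split(trls, key)

  counts <- integer(0)
  pairs <- data.frame(cell = character(), odor = character(),
                      included = logical(), n_trials = integer())
  for (g in groups) {
    resp <- assessResponsiveness(g, sd_mode = sd_mode)
    pairs <- rbind(pairs, data.frame(
      cell = g[[1L]]@cell_id, odor = odorLabel(g[[1L]]),
      included = resp$included, n_trials = length(g)))
    if (!resp$included) next
    smoothed <- lapply(g, function(tr)
      gaussianSmooth(isiRate(tr, dt_s), sigma_s, width_s))
    delta <- delta_hz
    if (is.null(delta)) {
      pre <- unlist(lapply(seq_along(g), function(j) {
        rs <- smoothed[[j]]
        rs@rates_hz[rateTimes(rs) < stimOnset(g[[j]])]
      }))
      delta <- stats::sd(pre)
      if (!is.finite(delta)) delta <- 0
    }
    for (j in seq_along(g)) {
      ann <- detectPeaksValleys(smoothed[[j]], lookahead_s, delta)
      counts <- c(counts,
                  countTransitions(ann, stimOnset(g[[j]]), window_s))
    }
  }
  if (!length(counts)) warning("no responsive PN-odor pairs")
  attr(counts, "pairs") <- pairs
  counts
}

#' Compare two transition-count distributions
#'
#' Two-sample Kolmogorov-Smirnov test on the empirical distributions of
#' integer transition counts (asymptotic p, appropriate at the trial counts
#' these comparisons involve).
#'
#' @param a,b integer count vectors (non-empty).
#' @return [ksTwoSample()] result list.
#' @export
compareDistributions <- function(a, b) {
  if (!length(a) || !length(b)) stop("both count sets must be non-empty")
  ksTwoSample(a, b, exact = "never")
}

#' Two-way ANOVA of PN firing rates by age and odor
#'
#' Computes one mean firing rate per spike trial — spontaneous over the 2 s
#' before onset, or evoked over the 4 s from onset — and fits a two-way
#' ANOVA with factors age group and odor (Type II sums of squares by
#' default, see [anovaTwoWay()]).
#'
#' @param ds an [EphysDataset-class] with spike trials from >= 2 age groups.
#' @param phase `"evoked"` (default) or `"spontaneous"`.
#' @param response_window_s evoked window (default 4 s).
#' @param baseline_window_s spontaneous window (default 2 s).
#' @param type sums-of-squares type, see [anovaTwoWay()].
#' @return The [anovaTwoWay()] table plus attribute `"rates"` holding the
#'   per-trial rate table.
#' @export
firingRateAnova <- function(ds, phase = c("evoked", "spontaneous"),
                            response_window_s = 4, baseline_window_s = 2,
                            type = "II") {
  phase <- match.arg(phase)
  stopifnot(is(ds, "EphysDataset"))
  isSpike <- vapply(ds@trials, is, logical(1), "SpikeTrainTrial")
  trls <- ds@trials[isSpike]
  if (!length(trls)) stop("dataset contains no spike trials")
  rows <- lapply(trls, function(tr) {
    on <- stimOnset(tr)
    rate <- if (phase == "evoked") {
      sum(spikes(tr) >= on & spikes(tr) < on + response_window_s) /
        response_window_s
    } else {
      w <- min(on, baseline_window_s)
      if (w <= 0) stop("trial without pre-onset data: spontaneous rate ",
                       "undefined")
      sum(spikes(tr) >= on - w & spikes(tr) < on) / w
    }
    data.frame(rate = rate, age = ageGroup(tr), odor = odorLabel(tr),
               cell = tr@cell_id, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (length(unique(tab$age)) < 2L)
    stop("need at least two age groups for the age comparison")
  res <- anovaTwoWay(tab, "rate", "age", "odor", type = type)
  attr(res, "rates") <- tab
  res
}
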