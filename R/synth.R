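# Seeded synthetic-data generators emulating the statistical structure of
# each recording modality: inhomogeneous-Poisson spike trains with
# multiphasic excitation/inhibition epochs, LFP traces with odor-locked
# oscillation bursts riding on autoregressive background noise, and EAG
# traces with odor-specific difference-of-exponential deflections. Every
# generator is deterministic given (config, seed) and stores ground truth
# for parameter-recovery tests.

#' Enumerate the transitions implied by a piecewise-constant rate profile
#'
#' Rule-enumeration oracle for the transition count, independent of the
#' smoothing/detection code path: adjacent equal-rate segments (including
#' the flanking baseline) are merged, strict local maxima of the merged
#' level sequence are the excitatory epochs and strict interior minima the
#' inhibitory epochs, and the counting rules are applied with each epoch's
#' appearance time = its segment start. Used to stamp
#' `ground_truth_transitions` on every [RateProfile-class].
#'
#' @param breakpoints_s ascending segment boundaries (s).
#' @param rates_hz per-segment rates.
#' @param baseline_hz rate outside the breakpoint span.
#' @param onset_s odor onset (s).
#' @param window_s response window (default 4 s).
#' @param guard_s boundary guard (default 0.2 s).
#' @return Integer transition count.
#' @export
profileTransitions <- function(breakpoints_s, rates_hz, baseline_hz,
                               onset_s, window_s = 4, guard_s = 0.2) {
  lev <- c(baseline_hz, rates_hz, baseline_hz)
  starts <- c(-Inf, breakpoints_s)
  keep <- c(TRUE, diff(lev) != 0)
  lev <- lev[keep]; starts <- starts[keep]
  k <- length(lev)
  if (k < 3L) return(0L)
  idx <- 2:(k - 1L)
  isPeak <- lev[idx] > lev[idx - 1L] & lev[idx] > lev[idx + 1L]
  isValley <- lev[idx] < lev[idx - 1L] & lev[idx] < lev[idx + 1L]
  peakT <- starts[idx][isPeak]
  valleyT <- starts[idx][isValley]
  lo <- onset_s; hi <- onset_s + window_s
  peakT <- peakT[peakT >= lo & peakT <= hi]
  if (!length(peakT)) return(0L)
  vInterior <- sum(valleyT > min(peakT) & valleyT < max(peakT))
  b <- 0L
  if (min(peakT) > lo + guard_s) b <- b + 1L
  if (max(peakT) > lo + guard_s && max(peakT) < hi) b <- b + 1L
  as.integer(2L * vInterior + b)
}

#' @rdname RateProfile-class
#' @param breakpoints_s ascending segment boundaries (s).
#' @param rates_hz per-segment rates (one fewer than breakpoints).
#' @param baseline_hz rate outside the breakpoint span (default 0).
#' @param onset_s stimulus onset the ground truth is enumerated for.
#' @param window_s response window used for the enumeration (default 4 s).
#' @return A `RateProfile` with its ground-truth transition count stamped by
#'   [profileTransitions()].
#' @export
RateProfile <- function(breakpoints_s, rates_hz, baseline_hz = 0,
                        onset_s = 2, window_s = 4) {
  gt <- profileTransitions(breakpoints_s, rates_hz, baseline_hz, onset_s,
                           window_s)
  new("RateProfile", breakpoints_s = as.numeric(breakpoints_s),
      rates_hz = as.numeric(rates_hz), baseline_hz = as.numeric(baseline_hz),
      ground_truth_transitions = gt, onset_s = as.numeric(onset_s))
}

#' Evaluate a rate profile
#'
#' @param profile a [RateProfile-class].
#' @param t times (s).
#' @return Rate in Hz at each time.
#' @export
profileRate <- function(profile, t) {
  bp <- profile@breakpoints_s
  idx <- findInterval(t, bp)
  out <- rep(profile@baseline_hz, length(t))
  inside <- idx >= 1L & idx < length(bp)
  out[inside] <- profile@rates_hz[idx[inside]]
  out
}

#' Synthetic-data generator configuration
#'
#' All generator parameters with their defaults. Trial counts follow the
#' recording conventions (6 spike trials, 10 LFP trials per odor); per-age
#' defaults are chosen to reproduce the qualitative developmental ordering
#' only — lower firing rates and smaller/briefer/earlier oscillation bursts
#' in hatchlings — since no quantitative per-age values are claimed.
#'
#' @slot lfp list: `fs_hz` (1000), `onset_s` (2), `record_s` (7),
#'   `noise_sd_mV` (0.02), `ar_coef` (0.97), `white_sd_mV` (0.005),
#'   `animal_f_sd_hz` (0.5), and per-age `amplitude_mV`, `duration_s`,
#'   `latency_s`, `segments`.
#' @slot eag list: `fs_hz` (500), `onset_s` (1), `record_s` (4),
#'   `noise_sd_mV` (0.02), `peak_cv` (0.15), `gain_sd` (0.25),
#'   `tau_rise_s` (0.05), `tau_decay_s` (0.4), `peaks_mV` (per-odor means,
#'   hexanol largest).
#' @slot rates list of per-age `baseline_hz` and `peak_hz` used by
#'   [ageRateProfile()].
#' @slot n_spike_trials integer (6).
#' @slot n_lfp_trials integer (10).
#' @export
setClass("SynthConfig", representation(
  lfp = "list", eag = "list", rates = "list",
  n_spike_trials = "integer", n_lfp_trials = "integer"
))

#' @rdname SynthConfig-class
#' @param ... named overrides merged over the defaults; `lfp`, `eag` and
#'   `rates` overrides are merged element-wise.
#' @return A `SynthConfig` object.
#' @export
SynthConfig <- function(...) {
  lfp <- list(
    fs_hz = 1000, onset_s = 2, record_s = 7,
    noise_sd_mV = 0.02, ar_coef = 0.97, white_sd_mV = 0.005,
    animal_f_sd_hz = 1.0, stage_f_sd_hz = 0.3,
    amplitude_mV = c(hatchling = 0.05, d10 = 0.10, d20 = 0.15, adult = 0.20),
    duration_s = c(hatchling = 0.5, d10 = 0.8, d20 = 1.0, adult = 1.2),
    latency_s = c(hatchling = 0.10, d10 = 0.17, d20 = 0.24, adult = 0.30),
    segments = c(hatchling = 12, d10 = 16, d20 = 20, adult = 25))
  eag <- list(
    fs_hz = 500, onset_s = 1, record_s = 4,
    noise_sd_mV = 0.02, peak_cv = 0.15, gain_sd = 0.25,
    tau_rise_s = 0.05, tau_decay_s = 0.4,
    peaks_mV = c(hex = 2.0, cis = 1.7, wgj = 1.8, hxa = 1.2, pen = 0.8,
                 oct = 0.6, cit = 0.55, cyc = 0.5, fur = 0.65, eth = 0.6,
                 cam = 0.45))
  rates <- list(
    hatchling = c(baseline_hz = 1.5, peak_hz = 25),
    d10 = c(baseline_hz = 2.5, peak_hz = 35),
    d20 = c(baseline_hz = 3.0, peak_hz = 45),
    adult = c(baseline_hz = 4.0, peak_hz = 55))
  defaults <- list(lfp = lfp, eag = eag, rates = rates,
                   n_spike_trials = 6L, n_lfp_trials = 10L)
  over <- list(...)
  for (nm in names(over)) {
    if (nm %in% c("lfp", "eag", "rates") && is.list(over[[nm]])) {
      defaults[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      defaults[[nm]] <- over[[nm]]
    }
  }
  new("SynthConfig", lfp = defaults$lfp, eag = defaults$eag,
      rates = defaults$rates,
      n_spike_trials = as.integer(defaults$n_spike_trials),
      n_lfp_trials = as.integer(defaults$n_lfp_trials))
}

#' Default multiphasic rate profile for an age group
#'
#' A two-excitation/two-inhibition layout within the 4 s response window —
#' epochs wider than the 400 ms analysis bins, excursions large relative to
#' baseline — scaled by the per-age rate defaults (hatchling rates lowest).
#' Its ground-truth transition count is 4 (two boundary transitions plus an
#' interior valley).
#'
#' @param age_group age group label.
#' @param cfg a [SynthConfig-class].
#' @param onset_s stimulus onset (default 2 s, leaving a 2 s baseline).
#' @return A [RateProfile-class].
#' @export
ageRateProfile <- function(age_group, cfg = SynthConfig(), onset_s = 2) {
  r <- cfg@rates[[age_group]]
  if (is.null(r)) stop("no rate defaults for age group '", age_group, "'")
  base <- r[["baseline_hz"]]; pk <- r[["peak_hz"]]
  RateProfile(
    breakpoints_s = onset_s + c(0.3, 1.3, 2.1, 3.1, 4.2),
    rates_hz = c(pk, 0, 0.6 * pk, 0),
    baseline_hz = base, onset_s = onset_s)
}

.poissonThin <- function(profile, duration_s) {
  lmax <- max(profile@rates_hz, profile@baseline_hz)
  if (lmax <= 0) return(numeric(0))
  n <- stats::rpois(1L, lmax * duration_s)
  if (n == 0L) return(numeric(0))
  cand <- sort(stats::runif(n, 0, duration_s))
  keep <- stats::runif(n) < profileRate(profile, cand) / lmax
  cand[keep]
}

#' Generate spike-train trials from a rate profile
#'
#' Draws each trial from an inhomogeneous Poisson process with the profile
#' as intensity (thinning method). Records include at least 2 s of
#' pre-onset baseline. An all-zero profile is valid and yields empty
#' trains.
#'
#' @param profile a [RateProfile-class] (with `onset_s >= 2`).
#' @param n_trials number of trials (default 6).
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @param odor odor label for the stimulus (default `"hex"`).
#' @param cell_id,animal identity metadata.
#' @param record_duration_s record length; defaults to cover the profile
#'   and the 4 s response window.
#' @return List of [SpikeTrainTrial-class].
#' @export
genPNTrials <- function(profile, n_trials = 6L, seed = NULL, odor = "hex",
                        cell_id = "cell1",
                        animal = AnimalMeta("a1", "adult"),
                        record_duration_s = NULL) {
  stopifnot(is(profile, "RateProfile"), n_trials >= 1L)
  if (profile@onset_s < 2)
    stop("profile onset must leave at least 2 s of pre-onset baseline")
  if (!is.null(seed)) set.seed(seed)
  dur <- record_duration_s %||%
    max(profile@onset_s + 5, max(profile@breakpoints_s) + 0.5)
  stim <- OdorStimulus(odor, profile@onset_s, 1.0)
  lapply(seq_len(n_trials), function(k) {
    SpikeTrainTrial(.poissonThin(profile, dur), dur, stim,
                    trial_index = k, cell_id = cell_id, animal = animal)
  })
}

.arNoise <- function(n, sd, ar, white_sd) {
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - ar^2))
  as.numeric(stats::filter(innov, ar, method = "recursive")) +
    stats::rnorm(n, 0, white_sd)
}

#' Generate LFP trials with an odor-locked oscillation burst
#'
#' Each trial is first-order autoregressive background noise (approximating
#' a 1/f-like spectrum without band-edge artifacts) plus a stimulus-locked
#' sinusoidal burst at the [DriveMap-class] frequency for `n_segments`,
#' under a raised-cosine amplitude envelope with configured peak amplitude,
#' onset latency and duration. Burst amplitude scales linearly with the
#' fraction of intact segments, emulating the loss of afferent drive under
#' trimming.
#'
#' @param n_segments intact antennal segment count (>= 1).
#' @param drive a [DriveMap-class].
#' @param cfg a [SynthConfig-class]; `cfg@lfp$fs_hz` must exceed 100 Hz.
#' @param n_trials number of trials (default `cfg@n_lfp_trials`).
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @param age_group age group whose amplitude/duration/latency defaults
#'   apply (default `"adult"`).
#' @param amplitude_mV,duration_s,latency_s explicit burst parameter
#'   overrides.
#' @param odor,side,animal,stage,cuts trial metadata.
#' @return List of [AnalogTrial-class].
#' @export
genLFPTrials <- function(n_segments, drive = DriveMap(),
                         cfg = SynthConfig(),
                         n_trials = cfg@n_lfp_trials, seed = NULL,
                         age_group = "adult", amplitude_mV = NULL,
                         duration_s = NULL, latency_s = NULL,
                         odor = "hex", side = "none",
                         animal = NULL, stage = NA_integer_,
                         cuts = NA_integer_) {
  stopifnot(n_segments >= 1L)
  p <- cfg@lfp
  if (p$fs_hz <= 100)
    stop("configuration error: LFP sampling rate must exceed 100 Hz")
  if (!is.null(seed)) set.seed(seed)
  amp <- (amplitude_mV %||% unname(p$amplitude_mV[age_group])) *
    n_segments / drive@ref_segments
  bdur <- duration_s %||% unname(p$duration_s[age_group])
  blat <- latency_s %||% unname(p$latency_s[age_group])
  f <- driveFrequency(drive, n_segments)
  n <- round(p$record_s * p$fs_hz)
  tt <- (seq_len(n) - 1L) / p$fs_hz
  t0 <- p$onset_s + blat
  rel <- (tt - t0) / bdur
  env <- ifelse(rel >= 0 & rel <= 1, 0.5 - 0.5 * cos(2 * pi * rel), 0)
  burst <- amp * env * sin(2 * pi * f * (tt - t0))
  if (is.null(animal))
    animal <- AnimalMeta("a1", age_group, as.integer(n_segments))
  stim <- OdorStimulus(odor, p$onset_s, 1.0)
  lapply(seq_len(n_trials), function(k) {
    AnalogTrial(.arNoise(n, p$noise_sd_mV, p$ar_coef, p$white_sd_mV) + burst,
                p$fs_hz, "LFP", stim, trial_index = k, side = side,
                animal = animal, stage = stage, cuts = cuts)
  })
}

.eagKernel <- function(t, tau_rise, tau_decay) {
  tpk <- log(tau_decay / tau_rise) / (1 / tau_rise - 1 / tau_decay)
  gmax <- exp(-tpk / tau_decay) - exp(-tpk / tau_rise)
  ifelse(t >= 0, (exp(-t / tau_decay) - exp(-t / tau_rise)) / gmax, 0)
}

#' Generate EAG trials for one age group
#'
#' Per animal, per odor: a negative-going deflection modeled as a
#' difference of exponentials whose peak is the configured per-odor mean
#' (hexanol largest), scaled by a per-animal multiplicative gain (log-normal;
#' removed by within-animal normalization) and perturbed by between-trial
#' variability and additive trace noise. Per-age mean profiles are equal by
#' default, emulating peripheral tuning that does not change with age.
#'
#' @param age_group age group label stamped on the animals.
#' @param odor_panel odors to generate (default: all odors with configured
#'   peaks).
#' @param cfg a [SynthConfig-class].
#' @param n_animals number of animals (default 9).
#' @param n_trials trials per animal-odor (default 1; the peak summaries
#'   average within animal anyway).
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @param animal_prefix prefix for generated animal ids.
#' @return List of EAG [AnalogTrial-class].
#' @export
genEAGTrials <- function(age_group, odor_panel = NULL, cfg = SynthConfig(),
                         n_animals = 9L, n_trials = 1L, seed = NULL,
                         animal_prefix = age_group) {
  p <- cfg@eag
  odor_panel <- odor_panel %||% names(p$peaks_mV)
  stopifnot(length(odor_panel) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  n <- round(p$record_s * p$fs_hz)
  tt <- (seq_len(n) - 1L) / p$fs_hz
  kern <- .eagKernel(tt - p$onset_s, p$tau_rise_s, p$tau_decay_s)
  stimFor <- function(od) OdorStimulus(od, p$onset_s, 1.0)
  out <- list()
  for (a in seq_len(n_animals)) {
    animal <- AnimalMeta(sprintf("%s%02d", animal_prefix, a), age_group)
    gain <- exp(stats::rnorm(1L, 0, p$gain_sd))
    for (od in odor_panel) {
      mu <- unname(p$peaks_mV[od])
      if (is.na(mu)) stop("no configured EAG peak for odor '", od, "'")
      for (k in seq_len(n_trials)) {
        pk <- max(0.01, mu * gain * (1 + stats::rnorm(1L, 0, p$peak_cv)))
        v <- -pk * kern + stats::rnorm(n, 0, p$noise_sd_mV)
        out[[length(out) + 1L]] <- AnalogTrial(
          v, p$fs_hz, "EAG", stimFor(od), trial_index = k, side = "none",
          animal = animal)
      }
    }
  }
  out
}

#' Generate a full antennal-trimming experiment
#'
#' For each animal and each stage of the (non-increasing) cut schedule:
#' `n_lfp_trials` ipsilateral LFP trials at the trimmed segment count and
#' the same number of contralateral trials at the intact count, with the
#' per-animal reference frequency jittered to emulate biological
#' variability. The drive map's slope (the ground-truth frequency change
#' per cut) is stored in the manifest for recovery tests.
#'
#' @param cut_schedule non-increasing vector of remaining-segment counts,
#'   first entry = intact count.
#' @param drive a [DriveMap-class].
#' @param cfg a [SynthConfig-class].
#' @param n_animals number of trimmed antennae (default 7).
#' @param seed RNG seed.
#' @param odor odor label (default `"hex"`).
#' @return A validated [EphysDataset-class]; its manifest `ground_truth`
#'   holds the slope per cut and the schedule.
#' @export
genTrimExperiment <- function(cut_schedule = c(25, 23, 21, 19, 17, 15),
                              drive = DriveMap(), cfg = SynthConfig(),
                              n_animals = 7L, seed = NULL, odor = "hex") {
  if (!length(cut_schedule))
    stop("configuration error: empty cut schedule")
  if (is.unsorted(rev(cut_schedule)))
    stop("cut schedule must be non-increasing in remaining segments")
  if (!is.null(seed)) set.seed(seed)
  p <- cfg@lfp
  trialList <- list()
  for (a in seq_len(n_animals)) {
    aDrive <- DriveMap(
      f_ref_hz = drive@f_ref_hz + stats::rnorm(1L, 0, p$animal_f_sd_hz),
      ref_segments = drive@ref_segments,
      slope_hz_per_segment = drive@slope_hz_per_segment,
      f_floor_hz = drive@f_floor_hz)
    for (s in seq_along(cut_schedule)) {
      cuts <- as.integer(cut_schedule[1L] - cut_schedule[s])
      ipsiAnimal <- AnimalMeta(sprintf("trim%02d", a), "adult",
                               as.integer(cut_schedule[s]))
      contraAnimal <- AnimalMeta(sprintf("trim%02d", a), "adult",
                                 as.integer(cut_schedule[1L]))
      # slow within-animal state drift between stages, independent per side
      stageDrive <- function() {
        DriveMap(aDrive@f_ref_hz + stats::rnorm(1L, 0, p$stage_f_sd_hz),
                 aDrive@ref_segments, aDrive@slope_hz_per_segment,
                 aDrive@f_floor_hz)
      }
      trialList <- c(trialList,
        genLFPTrials(cut_schedule[s], stageDrive(), cfg, side = "ipsi",
                     animal = ipsiAnimal, stage = s, cuts = cuts,
                     odor = odor),
        genLFPTrials(cut_schedule[1L], stageDrive(), cfg, side = "contra",
                     animal = contraAnimal, stage = s, cuts = cuts,
                     odor = odor))
    }
  }
  EphysDataset(trialList, manifest = list(
    schema_version = .SCHEMA_VERSION,
    generator = list(kind = "trim_experiment", n_animals = n_animals,
                     seed = seed %||% NA),
    ground_truth = list(
      slope_hz_per_cut = -drive@slope_hz_per_segment,
      f_ref_hz = drive@f_ref_hz,
      cut_schedule = cut_schedule)))
}
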