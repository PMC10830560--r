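#' @import methods
NULL

.AGE_GROUPS <- c("hatchling", "d10", "d20", "adult")
.MODALITIES <- c("LFP", "EAG", "Vm")
.SIDES <- c("ipsi", "contra", "none")

#' Standard odor panel abbreviations
#'
#' The eleven-odor panel used throughout: 1-hexanol (hex), cis-3-hexen-1-ol
#' (cis), 1-hexanal (hxa), 1-octen-3-ol (oct), cyclohexanone (cyc), furfuryl
#' mercaptan (fur), ethyl mercaptan (eth), citral (cit), pentyl acetate (pen),
#' camphor (cam) and wheat grass juice (wgj). Free-text labels are also
#' accepted by [OdorStimulus()].
#'
#' @format Character vector of length 11.
#' @export
odorPanel <- c("hex", "cis", "hxa", "oct", "cyc", "fur",
               "eth", "cit", "pen", "cam", "wgj")

#' Odor stimulus metadata
#'
#' Describes one odor pulse: the odor label, its onset relative to the start
#' of the recording (t = 0 at trace start; the stimulus position is carried
#' as an onset, never re-zeroed, because pre-stimulus baseline windows are
#' needed by every downstream analysis) and its duration (1 s pulses by
#' convention).
#'
#' @slot odor single non-empty character label (see [odorPanel]).
#' @slot onset_s stimulus onset in seconds from trace start, `>= 0`.
#' @slot duration_s stimulus duration in seconds, `> 0`.
#' @export
setClass("OdorStimulus", representation(
  odor = "character",
  onset_s = "numeric",
  duration_s = "numeric"
))

setValidity("OdorStimulus", function(object) {
  msg <- character()
  if (length(object@odor) != 1L || is.na(object@odor))
    msg <- c(msg, "odor must be a single non-NA character label")
  if (length(object@onset_s) != 1L || length(object@duration_s) != 1L)
    msg <- c(msg, "onset_s and duration_s must be scalars")
  if (length(msg)) msg else TRUE
})

#' @rdname OdorStimulus-class
#' @param odor odor label.
#' @param onset_s onset in seconds from trace start.
#' @param duration_s pulse duration in seconds (default 1).
#' @return An `OdorStimulus` object.
#' @examples
#' OdorStimulus("hex", onset_s = 2)
#' @export
OdorStimulus <- function(odor, onset_s, duration_s = 1.0) {
  new("OdorStimulus", odor = as.character(odor),
      onset_s = as.numeric(onset_s), duration_s = as.numeric(duration_s))
}

#' Animal metadata
#'
#' Identity, age group and (optionally) the number of olfactory-sensillum
#' bearing antennal segments remaining on the recorded side. Locusts hatch
#' with roughly 11-13 segments and reach 24-26 as adults; trimming
#' experiments reduce the count stepwise.
#'
#' @slot animal_id single character token.
#' @slot age_group one of `"hatchling"`, `"d10"`, `"d20"`, `"adult"`.
#' @slot antennal_segments integer segment count, or `NA` when not recorded.
#' @export
setClass("AnimalMeta", representation(
  animal_id = "character",
  age_group = "character",
  antennal_segments = "integer"
))

setValidity("AnimalMeta", function(object) {
  msg <- character()
  if (length(object@animal_id) != 1L || is.na(object@animal_id) ||
      !nzchar(object@animal_id))
    msg <- c(msg, "animal_id must be a single non-empty token")
  if (length(object@age_group) != 1L)
    msg <- c(msg, "age_group must be a scalar")
  if (length(object@antennal_segments) != 1L)
    msg <- c(msg, "antennal_segments must be a scalar (NA allowed)")
  if (length(msg)) msg else TRUE
})

#' @rdname AnimalMeta-class
#' @param animal_id animal identifier token.
#' @param age_group age group label.
#' @param antennal_segments antennal segment count or `NA`.
#' @return An `AnimalMeta` object.
#' @export
AnimalMeta <- function(animal_id, age_group, antennal_segments = NA_integer_) {
  new("AnimalMeta", animal_id = as.character(animal_id),
      age_group = as.character(age_group),
      antennal_segments = as.integer(antennal_segments))
}

#' One spike-train trial
#'
#' Sorted spike times (seconds) for a single projection-neuron/odor/trial
#' combination, together with the stimulus and animal metadata. Units at the
#' API boundary are fixed: seconds, millivolts, hertz.
#'
#' @slot spikes_s ascending numeric spike times in seconds.
#' @slot record_duration_s total record length in seconds.
#' @slot stimulus an [OdorStimulus-class].
#' @slot trial_index 1-based trial number.
#' @slot cell_id cell identifier token.
#' @slot animal an [AnimalMeta-class].
#' @export
setClass("SpikeTrainTrial", representation(
  spikes_s = "numeric",
  record_duration_s = "numeric",
  stimulus = "OdorStimulus",
  trial_index = "integer",
  cell_id = "character",
  animal = "AnimalMeta"
))

setValidity("SpikeTrainTrial", function(object) {
  msg <- character()
  if (length(object@record_duration_s) != 1L ||
      !is.finite(object@record_duration_s))
    msg <- c(msg, "record_duration_s must be a finite scalar")
  if (length(object@trial_index) != 1L || is.na(object@trial_index) ||
      object@trial_index < 1L)
    msg <- c(msg, "trial_index must be a 1-based integer")
  if (length(object@cell_id) != 1L)
    msg <- c(msg, "cell_id must be a scalar token")
  if (anyNA(object@spikes_s))
    msg <- c(msg, "spike times must not contain NA")
  if (length(msg)) msg else TRUE
})

#' @rdname SpikeTrainTrial-class
#' @param spikes_s spike times in seconds, ascending.
#' @param record_duration_s record length in seconds.
#' @param stimulus an [OdorStimulus-class].
#' @param trial_index 1-based trial number.
#' @param cell_id cell identifier.
#' @param animal an [AnimalMeta-class].
#' @return A `SpikeTrainTrial` object.
#' @export
SpikeTrainTrial <- function(spikes_s, record_duration_s, stimulus,
                            trial_index = 1L, cell_id = "cell1",
                            animal = AnimalMeta("a1", "adult")) {
  new("SpikeTrainTrial", spikes_s = as.numeric(spikes_s),
      record_duration_s = as.numeric(record_duration_s),
      stimulus = stimulus, trial_index = as.integer(trial_index),
      cell_id = as.character(cell_id), animal = animal)
}

#' One analog trial (LFP, EAG or membrane potential)
#'
#' A uniformly sampled voltage trace in millivolts, with its sampling rate,
#' modality, recording side, and stimulus/animal metadata. For antennal
#' trimming experiments the trimming stage and the cumulative number of cut
#' segments are carried per trial (`NA` otherwise).
#'
#' @slot values_mV numeric samples in millivolts.
#' @slot fs_hz sampling rate in hertz.
#' @slot modality one of `"LFP"`, `"EAG"`, `"Vm"`.
#' @slot stimulus an [OdorStimulus-class].
#' @slot trial_index 1-based trial number.
#' @slot side recording side: `"ipsi"`, `"contra"` or `"none"`.
#' @slot animal an [AnimalMeta-class].
#' @slot stage 1-based trimming stage, `NA` outside trim experiments.
#' @slot cuts cumulative antennal segments removed at this stage, `NA`
#'   outside trim experiments.
#' @export
setClass("AnalogTrial", representation(
  values_mV = "numeric",
  fs_hz = "numeric",
  modality = "character",
  stimulus = "OdorStimulus",
  trial_index = "integer",
  side = "character",
  animal = "AnimalMeta",
  stage = "integer",
  cuts = "integer"
))

setValidity("AnalogTrial", function(object) {
  msg <- character()
  if (length(object@fs_hz) != 1L || !is.finite(object@fs_hz) ||
      object@fs_hz <= 0)
    msg <- c(msg, "fs_hz must be a positive finite scalar")
  if (length(object@modality) != 1L ||
      !object@modality %in% .MODALITIES)
    msg <- c(msg, sprintf("modality must be one of %s",
                          paste(.MODALITIES, collapse = ", ")))
  if (length(object@side) != 1L || !object@side %in% .SIDES)
    msg <- c(msg, sprintf("side must be one of %s",
                          paste(.SIDES, collapse = ", ")))
  if (length(object@trial_index) != 1L || is.na(object@trial_index) ||
      object@trial_index < 1L)
    msg <- c(msg, "trial_index must be a 1-based integer")
  if (length(msg)) msg else TRUE
})

#' @rdname AnalogTrial-class
#' @param values_mV samples in millivolts.
#' @param fs_hz sampling rate in hertz.
#' @param modality `"LFP"`, `"EAG"` or `"Vm"`.
#' @param stimulus an [OdorStimulus-class].
#' @param trial_index 1-based trial number.
#' @param side recording side.
#' @param animal an [AnimalMeta-class].
#' @param stage trimming stage or `NA`.
#' @param cuts cumulative segments removed or `NA`.
#' @return An `AnalogTrial` object.
#' @export
AnalogTrial <- function(values_mV, fs_hz, modality, stimulus,
                        trial_index = 1L, side = "none",
                        animal = AnimalMeta("a1", "adult"),
                        stage = NA_integer_, cuts = NA_integer_) {
  new("AnalogTrial", values_mV = as.numeric(values_mV),
      fs_hz = as.numeric(fs_hz), modality = as.character(modality),
      stimulus = stimulus, trial_index = as.integer(trial_index),
      side = as.character(side), animal = animal,
      stage = as.integer(stage), cuts = as.integer(cuts))
}

#' A collection of trials with a manifest
#'
#' The container every analysis consumes: a list of [SpikeTrainTrial-class]
#' and [AnalogTrial-class] objects plus a manifest block carrying the schema
#' version and, for synthetic data, generator provenance and ground truth.
#'
#' @slot trials list of trial objects.
#' @slot manifest named list: at least `schema_version`; synthetic datasets
#'   add `generator` and `ground_truth` blocks.
#' @export
setClass("EphysDataset", representation(
  trials = "list",
  manifest = "list"
))

setValidity("EphysDataset", function(object) {
  ok <- vapply(object@trials, function(tr)
    is(tr, "SpikeTrainTrial") || is(tr, "AnalogTrial"), logical(1))
  if (!all(ok))
    return("all trials must be SpikeTrainTrial or AnalogTrial objects")
  TRUE
})

#' @rdname EphysDataset-class
#' @param trials list of trial objects.
#' @param manifest named metadata list.
#' @return An `EphysDataset` object.
#' @export
EphysDataset <- function(trials = list(), manifest = list()) {
  if (is.null(manifest$schema_version)) manifest$schema_version <- "1.0"
  new("EphysDataset", trials = trials, manifest = manifest)
}

#' Uniformly sampled instantaneous firing-rate series
#'
#' @slot t0_s time of the first sample, seconds.
#' @slot dt_s sample spacing, seconds (default 1 ms in [isiRate()]).
#' @slot rates_hz non-negative rate samples.
#' @export
setClass("RateSeries", representation(
  t0_s = "numeric",
  dt_s = "numeric",
  rates_hz = "numeric"
))

setValidity("RateSeries", function(object) {
  if (length(object@dt_s) != 1L || object@dt_s <= 0)
    return("dt_s must be a positive scalar")
  TRUE
})

#' @rdname RateSeries-class
#' @param t0_s time of first sample (s).
#' @param dt_s sample spacing (s).
#' @param rates_hz rate samples (Hz).
#' @return A `RateSeries` object.
#' @export
RateSeries <- function(t0_s, dt_s, rates_hz) {
  new("RateSeries", t0_s = as.numeric(t0_s), dt_s = as.numeric(dt_s),
      rates_hz = as.numeric(rates_hz))
}

#' Detected excitatory/inhibitory epoch structure of a rate series
#'
#' Peaks mark excitatory epochs, the valleys between them inhibitory epochs.
#' `transitions` is `NA` until [countTransitions()] has been applied.
#'
#' @slot peaks two-column matrix `(time_s, rate_hz)` of confirmed peaks.
#' @slot valleys two-column matrix of confirmed valleys.
#' @slot transitions integer transition count or `NA`.
#' @slot window numeric length-2 `(onset, onset + window)` used for counting,
#'   or `NA` before counting.
#' @export
setClass("EpochAnnotation", representation(
  peaks = "matrix",
  valleys = "matrix",
  transitions = "integer",
  window = "numeric"
))

.emptyExtrema <- function() {
  matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("time_s", "rate_hz")))
}

#' @rdname EpochAnnotation-class
#' @param peaks peak matrix.
#' @param valleys valley matrix.
#' @param transitions transition count or `NA`.
#' @param window counting window or `NA`.
#' @return An `EpochAnnotation` object.
#' @export
EpochAnnotation <- function(peaks = .emptyExtrema(), valleys = .emptyExtrema(),
                            transitions = NA_integer_,
                            window = c(NA_real_, NA_real_)) {
  new("EpochAnnotation", peaks = peaks, valleys = valleys,
      transitions = as.integer(transitions), window = as.numeric(window))
}

#' Short-time spectral power of an analog trial
#'
#' Power in a time-frequency grid: rows are window positions (centers in
#' seconds), columns frequency bins. With the 0.5 s analysis window the
#' frequency resolution is 2 Hz before any zero padding.
#'
#' @slot time_centers_s window-center times (s).
#' @slot freq_centers_hz frequency bin centers (Hz).
#' @slot power time-by-frequency non-negative power matrix.
#' @slot window_s analysis window length (s).
#' @slot overlap_fraction overlap between successive windows.
#' @export
setClass("SpectrogramResult", representation(
  time_centers_s = "numeric",
  freq_centers_hz = "numeric",
  power = "matrix",
  window_s = "numeric",
  overlap_fraction = "numeric"
))

setValidity("SpectrogramResult", function(object) {
  msg <- character()
  if (nrow(object@power) != length(object@time_centers_s) ||
      ncol(object@power) != length(object@freq_centers_hz))
    msg <- c(msg, "power must be time x frequency")
  if (any(object@power < 0))
    msg <- c(msg, "power must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Piecewise-constant firing-rate profile with stored ground truth
#'
#' Defines the inhomogeneous Poisson intensity used by [genPNTrials()]:
#' `rates_hz[i]` applies on `[breakpoints_s[i], breakpoints_s[i+1])` and the
#' baseline rate everywhere else. The implied epoch-transition count is
#' computed by the rule-enumeration oracle ([profileTransitions()]) at
#' construction time, never hand-entered.
#'
#' @slot breakpoints_s ascending segment boundaries (s).
#' @slot rates_hz per-segment rates, `length(breakpoints_s) - 1`.
#' @slot baseline_hz rate outside the breakpoint span.
#' @slot ground_truth_transitions transition count implied by the profile
#'   under the counting rules (for a given stimulus window).
#' @slot onset_s the stimulus onset the ground truth was enumerated for.
#' @export
setClass("RateProfile", representation(
  breakpoints_s = "numeric",
  rates_hz = "numeric",
  baseline_hz = "numeric",
  ground_truth_transitions = "integer",
  onset_s = "numeric"
))

setValidity("RateProfile", function(object) {
  msg <- character()
  if (length(object@rates_hz) != length(object@breakpoints_s) - 1L)
    msg <- c(msg, "need one rate per segment between breakpoints")
  if (is.unsorted(object@breakpoints_s, strictly = TRUE))
    msg <- c(msg, "breakpoints_s must be strictly ascending")
  if (any(object@rates_hz < 0) || object@baseline_hz < 0)
    msg <- c(msg, "rates must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Afferent drive to oscillation-frequency map
#'
#' Phenomenological map from the number of intact antennal segments (a proxy
#' for the afferent olfactory-sensory-neuron count driving the antennal-lobe
#' oscillator) to the odor-evoked oscillation frequency:
#' `f(n) = max(f_floor, f_ref - slope * (ref_segments - n))`.
#' Defaults: 20 Hz at the adult reference of 25 segments, 0.52 Hz lost per
#' removed segment, 5 Hz floor.
#'
#' @slot f_ref_hz frequency at the reference segment count (Hz).
#' @slot ref_segments reference (intact adult) segment count.
#' @slot slope_hz_per_segment frequency change per segment (Hz/segment).
#' @slot f_floor_hz minimum frequency (Hz).
#' @export
setClass("DriveMap", representation(
  f_ref_hz = "numeric",
  ref_segments = "integer",
  slope_hz_per_segment = "numeric",
  f_floor_hz = "numeric"
))

#' @rdname DriveMap-class
#' @param f_ref_hz reference frequency (Hz).
#' @param ref_segments reference segment count.
#' @param slope_hz_per_segment Hz per segment.
#' @param f_floor_hz frequency floor (Hz).
#' @return A `DriveMap` object.
#' @examples
#' dm <- DriveMap()
#' driveFrequency(dm, 25)   # 20
#' driveFrequency(dm, 15)   # 20 - 10 * 0.52
#' @export
DriveMap <- function(f_ref_hz = 20, ref_segments = 25L,
                     slope_hz_per_segment = 0.52, f_floor_hz = 5) {
  new("DriveMap", f_ref_hz = as.numeric(f_ref_hz),
      ref_segments = as.integer(ref_segments),
      slope_hz_per_segment = as.numeric(slope_hz_per_segment),
      f_floor_hz = as.numeric(f_floor_hz))
}

#' Evaluate a drive map at a segment count
#'
#' @param drive a [DriveMap-class].
#' @param n_segments integer vector of intact segment counts.
#' @return Oscillation frequency in Hz (vectorized, monotone non-decreasing
#'   in `n_segments`).
#' @export
driveFrequency <- function(drive, n_segments) {
  pmax(drive@f_floor_hz,
       drive@f_ref_hz -
         drive@slope_hz_per_segment * (drive@ref_segments - n_segments))
}
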