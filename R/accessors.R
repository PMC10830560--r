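# Accessors and show methods. Slot access from user code is discouraged;
# these are the supported surface.

#' @name accessors
#' @title Accessors for trial and dataset objects
#' @description Small generic accessors used across the package instead of
#'   direct slot access.
#' @param x an object.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("spikes", function(x) standardGeneric("spikes"))
#' @rdname accessors
#' @export
setMethod("spikes", "SpikeTrainTrial", function(x) x@spikes_s)

#' @rdname accessors
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))
#' @rdname accessors
#' @export
setMethod("traceValues", "AnalogTrial", function(x) x@values_mV)

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setMethod("sampleRate", "AnalogTrial", function(x) x@fs_hz)

#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @rdname accessors
#' @export
setMethod("modality", "AnalogTrial", function(x) x@modality)

#' @rdname accessors
#' @export
setGeneric("stimulus", function(x) standardGeneric("stimulus"))
#' @rdname accessors
#' @export
setMethod("stimulus", "SpikeTrainTrial", function(x) x@stimulus)
#' @rdname accessors
#' @export
setMethod("stimulus", "AnalogTrial", function(x) x@stimulus)

#' @rdname accessors
#' @export
setGeneric("odorLabel", function(x) standardGeneric("odorLabel"))
#' @rdname accessors
#' @export
setMethod("odorLabel", "OdorStimulus", function(x) x@odor)
#' @rdname accessors
#' @export
setMethod("odorLabel", "SpikeTrainTrial", function(x) x@stimulus@odor)
#' @rdname accessors
#' @export
setMethod("odorLabel", "AnalogTrial", function(x) x@stimulus@odor)

#' @rdname accessors
#' @export
setGeneric("stimOnset", function(x) standardGeneric("stimOnset"))
#' @rdname accessors
#' @export
setMethod("stimOnset", "OdorStimulus", function(x) x@onset_s)
#' @rdname accessors
#' @export
setMethod("stimOnset", "SpikeTrainTrial", function(x) x@stimulus@onset_s)
#' @rdname accessors
#' @export
setMethod("stimOnset", "AnalogTrial", function(x) x@stimulus@onset_s)

#' @rdname accessors
#' @export
setGeneric("animalMeta", function(x) standardGeneric("animalMeta"))
#' @rdname accessors
#' @export
setMethod("animalMeta", "SpikeTrainTrial", function(x) x@animal)
#' @rdname accessors
#' @export
setMethod("animalMeta", "AnalogTrial", function(x) x@animal)

#' @rdname accessors
#' @export
setGeneric("ageGroup", function(x) standardGeneric("ageGroup"))
#' @rdname accessors
#' @export
setMethod("ageGroup", "AnimalMeta", function(x) x@age_group)
#' @rdname accessors
#' @export
setMethod("ageGroup", "SpikeTrainTrial", function(x) x@animal@age_group)
#' @rdname accessors
#' @export
setMethod("ageGroup", "AnalogTrial", function(x) x@animal@age_group)

#' @rdname accessors
#' @export
setGeneric("trialIndex", function(x) standardGeneric("trialIndex"))
#' @rdname accessors
#' @export
setMethod("trialIndex", "SpikeTrainTrial", function(x) x@trial_index)
#' @rdname accessors
#' @export
setMethod("trialIndex", "AnalogTrial", function(x) x@trial_index)

#' @rdname accessors
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))
#' @rdname accessors
#' @export
setMethod("trials", "EphysDataset", function(x) x@trials)

#' @rdname accessors
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))
#' @rdname accessors
#' @export
setMethod("manifest", "EphysDataset", function(x) x@manifest)

#' @rdname accessors
#' @param i index.
#' @export
setMethod("[[", "EphysDataset", function(x, i) x@trials[[i]])

#' @rdname accessors
#' @export
setMethod("length", "EphysDataset", function(x) length(x@trials))

#' @rdname accessors
#' @export
setGeneric("rateTimes", function(x) standardGeneric("rateTimes"))
#' @rdname accessors
#' @export
setMethod("rateTimes", "RateSeries",
          function(x) x@t0_s + (seq_along(x@rates_hz) - 1L) * x@dt_s)

#' @rdname accessors
#' @export
setGeneric("rateValues", function(x) standardGeneric("rateValues"))
#' @rdname accessors
#' @export
setMethod("rateValues", "RateSeries", function(x) x@rates_hz)

#' @rdname accessors
#' @export
setGeneric("epochPeaks", function(x) standardGeneric("epochPeaks"))
#' @rdname accessors
#' @export
setMethod("epochPeaks", "EpochAnnotation", function(x) x@peaks)

#' @rdname accessors
#' @export
setGeneric("epochValleys", function(x) standardGeneric("epochValleys"))
#' @rdname accessors
#' @export
setMethod("epochValleys", "EpochAnnotation", function(x) x@valleys)

#' @rdname accessors
#' @export
setGeneric("specPower", function(x) standardGeneric("specPower"))
#' @rdname accessors
#' @export
setMethod("specPower", "SpectrogramResult", function(x) x@power)

#' @rdname accessors
#' @export
setGeneric("specTimes", function(x) standardGeneric("specTimes"))
#' @rdname accessors
#' @export
setMethod("specTimes", "SpectrogramResult", function(x) x@time_centers_s)

#' @rdname accessors
#' @export
setGeneric("specFreqs", function(x) standardGeneric("specFreqs"))
#' @rdname accessors
#' @export
setMethod("specFreqs", "SpectrogramResult", function(x) x@freq_centers_hz)

#' @rdname accessors
#' @export
setGeneric("groundTruthTransitions",
           function(x) standardGeneric("groundTruthTransitions"))
#' @rdname accessors
#' @export
setMethod("groundTruthTransitions", "RateProfile",
          function(x) x@ground_truth_transitions)

setMethod("show", "OdorStimulus", function(object) {
  cat(sprintf("OdorStimulus '%s' onset %.3g s, duration %.3g s\n",
              object@odor, object@onset_s, object@duration_s))
})

setMethod("show", "SpikeTrainTrial", function(object) {
  cat(sprintf(
    "SpikeTrainTrial %s/%s trial %d: %d spikes over %.3g s (odor %s @ %.3g s)\n",
    object@animal@animal_id, object@cell_id, object@trial_index,
    length(object@spikes_s), object@record_duration_s,
    object@stimulus@odor, object@stimulus@onset_s))
})

setMethod("show", "AnalogTrial", function(object) {
  cat(sprintf(
    "AnalogTrial [%s] %s trial %d: %d samples @ %g Hz (%.3g s), odor %s, side %s\n",
    object@modality, object@animal@animal_id, object@trial_index,
    length(object@values_mV), object@fs_hz,
    length(object@values_mV) / object@fs_hz,
    object@stimulus@odor, object@side))
})

setMethod("show", "EphysDataset", function(object) {
  kinds <- vapply(object@trials, function(tr)
    if (is(tr, "SpikeTrainTrial")) "spike" else tr@modality, character(1))
  cat(sprintf("EphysDataset with %d trials", length(object@trials)))
  if (length(kinds))
    cat(" (", paste(sprintf("%s: %d", names(table(kinds)), table(kinds)),
                    collapse = ", "), ")", sep = "")
  cat(sprintf("\n  schema %s\n",
              as.character(object@manifest$schema_version %||% "?")))
})

setMethod("show", "SpectrogramResult", function(object) {
  cat(sprintf(
    "SpectrogramResult: %d windows x %d frequency bins (%.3g-%.3g Hz, %.3g Hz bins)\n",
    nrow(object@power), ncol(object@power),
    min(object@freq_centers_hz), max(object@freq_centers_hz),
    if (length(object@freq_centers_hz) > 1)
      diff(object@freq_centers_hz[1:2]) else NA_real_))
})

setMethod("show", "EpochAnnotation", function(object) {
  cat(sprintf("EpochAnnotation: %d peaks, %d valleys, transitions = %s\n",
              nrow(object@peaks), nrow(object@valleys),
              ifelse(is.na(object@transitions), "not counted",
                     object@transitions)))
})

setMethod("show", "RateProfile", function(object) {
  cat(sprintf(
    "RateProfile: %d segments on [%.3g, %.3g] s, baseline %.3g Hz, ground-truth transitions = %d\n",
    length(object@rates_hz), min(object@breakpoints_s),
    max(object@breakpoints_s), object@baseline_hz,
    object@ground_truth_transitions))
})

setMethod("show", "DriveMap", function(object) {
  cat(sprintf(
    "DriveMap: f(n) = max(%.3g, %.3g - %.3g * (%d - n)) Hz\n",
    object@f_floor_hz, object@f_ref_hz, object@slope_hz_per_segment,
    object@ref_segments))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
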