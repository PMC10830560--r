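# On-disk dataset format: one manifest.json plus one plain-text file per
# trial (spike files: one spike time per line; analog files: one sample per
# line, or two columns time,value of which the second is used). Chosen for
# diffability and zero binary dependencies. All values are converted to
# seconds / millivolts / hertz at the API boundary; files may declare "ms",
# "uV" or "V" and are converted on load.

.SCHEMA_VERSION <- "1.0"

.trialLabel <- function(tr, k) {
  if (is(tr, "SpikeTrainTrial"))
    sprintf("trial %d (spike, cell %s, odor %s, index %d)",
            k, tr@cell_id, tr@stimulus@odor, tr@trial_index)
  else
    sprintf("trial %d (%s, animal %s, odor %s, index %d, side %s)",
            k, tr@modality, tr@animal@animal_id, tr@stimulus@odor,
            tr@trial_index, tr@side)
}

.fmt <- function(x) sprintf("%.17g", x)

#' Save a dataset to a directory
#'
#' Writes `manifest.json` plus one delimited-text file per trial. The layout
#' round-trips through [loadDataset()] with all fields preserved (exactly for
#' integers and strings, to better than 1e-9 relative error for floats).
#'
#' @param ds an [EphysDataset-class].
#' @param path directory to create/write into.
#' @return Invisibly, the manifest path.
#' @seealso [loadDataset()], [validateDataset()]
#' @export
saveDataset <- function(ds, path) {
  stopifnot(is(ds, "EphysDataset"))
  if (!dir.exists(path) &&
      !dir.create(path, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create dataset directory: ", path)
  if (file.access(path, 2L) != 0L)
    stop("dataset directory is not writable: ", path)

  entries <- vector("list", length(ds@trials))
  for (k in seq_along(ds@trials)) {
    tr <- ds@trials[[k]]
    if (is(tr, "SpikeTrainTrial")) {
      fn <- sprintf("trial_%04d_spikes.txt", k)
      writeLines(.fmt(tr@spikes_s), file.path(path, fn))
      entries[[k]] <- list(
        kind = "spike", file = fn,
        record_duration_s = tr@record_duration_s,
        odor = tr@stimulus@odor, onset_s = tr@stimulus@onset_s,
        duration_s = tr@stimulus@duration_s,
        trial_index = tr@trial_index, cell_id = tr@cell_id,
        animal_id = tr@animal@animal_id, age_group = tr@animal@age_group,
        antennal_segments = tr@animal@antennal_segments)
    } else {
      fn <- sprintf("trial_%04d_%s.txt", k, tolower(tr@modality))
      writeLines(.fmt(tr@values_mV), file.path(path, fn))
      entries[[k]] <- list(
        kind = "analog", file = fn, fs_hz = tr@fs_hz,
        modality = tr@modality, side = tr@side,
        odor = tr@stimulus@odor, onset_s = tr@stimulus@onset_s,
        duration_s = tr@stimulus@duration_s,
        trial_index = tr@trial_index, stage = tr@stage, cuts = tr@cuts,
        animal_id = tr@animal@animal_id, age_group = tr@animal@age_group,
        antennal_segments = tr@animal@antennal_segments)
    }
  }
  man <- ds@manifest
  man$schema_version <- man$schema_version %||% .SCHEMA_VERSION
  man$trials <- entries
  jsonlite::write_json(man, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(file.path(path, "manifest.json"))
}

.asInt <- function(x) if (is.null(x) || is.na(x)) NA_integer_ else as.integer(x)

.readAnalogFile <- function(fp) {
  first <- readLines(fp, n = 1L)
  if (length(first) && grepl("[,\t ]", trimws(first))) {
    tab <- utils::read.table(fp, sep = "", header = FALSE,
                             comment.char = "#")
    if (ncol(tab) == 1L) tab[[1L]] else tab[[2L]]
  } else {
    scan(fp, what = double(), quiet = TRUE)
  }
}

.timeScale <- function(unit) {
  switch(unit %||% "s", s = 1, ms = 1e-3,
         stop("unsupported time unit: ", unit))
}
.voltScale <- function(unit) {
  switch(unit %||% "mV", mV = 1, uV = 1e-3, V = 1e3,
         stop("unsupported voltage unit: ", unit))
}

#' Load a dataset directory
#'
#' Reads `manifest.json` and the trial files it references, converts any
#' declared units to seconds/millivolts/hertz, and validates the result; any
#' violation (e.g. non-monotone spike times) raises an error naming the
#' offending trial.
#'
#' @param path dataset directory written by [saveDataset()] (or by hand in
#'   the same layout).
#' @return A validated [EphysDataset-class].
#' @export
loadDataset <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf))
    stop("format error: no manifest.json in ", path)
  man <- jsonlite::read_json(mf, simplifyVector = FALSE)
  entries <- man$trials %||% list()
  man$trials <- NULL

  trialList <- vector("list", length(entries))
  for (k in seq_along(entries)) {
    e <- entries[[k]]
    fp <- file.path(path, e$file)
    if (!file.exists(fp))
      stop("format error: trial file missing: ", e$file)
    stim <- OdorStimulus(e$odor, e$onset_s, e$duration_s %||% 1.0)
    animal <- AnimalMeta(e$animal_id %||% "unknown",
                         e$age_group %||% "adult",
                         .asInt(e$antennal_segments))
    if (identical(e$kind, "spike")) {
      sp <- scan(fp, what = double(), quiet = TRUE) *
        .timeScale(e$time_unit)
      trialList[[k]] <- SpikeTrainTrial(
        sp, e$record_duration_s, stim,
        trial_index = e$trial_index, cell_id = e$cell_id %||% "cell",
        animal = animal)
    } else if (identical(e$kind, "analog")) {
      v <- .readAnalogFile(fp) * .voltScale(e$value_unit)
      trialList[[k]] <- AnalogTrial(
        v, e$fs_hz, e$modality, stim,
        trial_index = e$trial_index, side = e$side %||% "none",
        animal = animal, stage = .asInt(e$stage), cuts = .asInt(e$cuts))
    } else {
      stop("format error: unknown trial kind '", e$kind, "'")
    }
  }
  ds <- EphysDataset(trialList, man)
  viol <- validateDataset(ds)
  if (length(viol))
    stop("validation error:\n  ", paste(viol, collapse = "\n  "))
  ds
}

#' Validate a dataset against the domain invariants
#'
#' Checks every rule of the trial data model and returns the violations as a
#' character vector (empty when the dataset is valid); nothing is raised, so
#' this can be used to audit partially broken data.
#'
#' Rules: stimulus onsets non-negative, durations positive, odor labels
#' non-empty; age groups from the known set; antennal segment counts in
#' 1..30 when present; spike times strictly ascending and inside
#' `[0, record_duration_s]`; stimulus fitting inside the record; LFP
#' sampling above 100 Hz (Nyquist for the 50 Hz analysis band edge) and LFP
#' records covering at least onset + 4 s; trial indices unique within
#' (cell or animal, odor, modality, side, stage).
#'
#' @param ds an [EphysDataset-class].
#' @return Character vector of violations, each naming the trial and rule.
#' @export
validateDataset <- function(ds) {
  stopifnot(is(ds, "EphysDataset"))
  v <- character()
  keys <- character(length(ds@trials))
  for (k in seq_along(ds@trials)) {
    tr <- ds@trials[[k]]
    lab <- .trialLabel(tr, k)
    st <- tr@stimulus
    if (!nzchar(st@odor))
      v <- c(v, paste0(lab, ": odor label must be non-empty"))
    if (st@onset_s < 0)
      v <- c(v, paste0(lab, ": stimulus onset must be non-negative"))
    if (st@duration_s <= 0)
      v <- c(v, paste0(lab, ": stimulus duration must be positive"))
    if (!tr@animal@age_group %in% .AGE_GROUPS)
      v <- c(v, paste0(lab, ": unknown age group '", tr@animal@age_group,
                       "'"))
    segs <- tr@animal@antennal_segments
    if (!is.na(segs) && (segs < 1L || segs > 30L))
      v <- c(v, paste0(lab, ": antennal_segments must be in [1, 30]"))

    if (is(tr, "SpikeTrainTrial")) {
      sp <- tr@spikes_s
      if (length(sp) > 1L && is.unsorted(sp, strictly = TRUE))
        v <- c(v, paste0(lab, ": spike times must be strictly ascending"))
      if (length(sp) && min(sp) < 0)
        v <- c(v, paste0(lab, ": spike times must be non-negative"))
      if (length(sp) && max(sp) > tr@record_duration_s)
        v <- c(v, paste0(lab, ": spike times must not exceed the record ",
                         "duration"))
      if (st@onset_s + st@duration_s > tr@record_duration_s)
        v <- c(v, paste0(lab, ": stimulus must end within the record"))
      keys[k] <- paste(tr@cell_id, st@odor, "spike", "none",
                       tr@trial_index, sep = "|")
    } else {
      n <- length(tr@values_mV)
      if (tr@modality == "LFP" && tr@fs_hz <= 100)
        v <- c(v, paste0(lab, ": LFP sampling rate must exceed 100 Hz ",
                         "(Nyquist for the 50 Hz band edge)"))
      if (tr@modality == "LFP" && n < tr@fs_hz * (st@onset_s + 4))
        v <- c(v, paste0(lab, ": LFP record must cover onset + 4 s"))
      keys[k] <- paste(tr@animal@animal_id, st@odor, tr@modality, tr@side,
                       tr@stage, tr@trial_index, sep = "|")
    }
  }
  dup <- duplicated(keys) & nzchar(keys)
  for (k in which(dup)) {
    v <- c(v, paste0(.trialLabel(ds@trials[[k]], k),
                     ": duplicate trial_index within its ",
                     "(recording, odor, modality, side) group"))
  }
  v
}
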