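# Electroantennogram analysis: peak extraction, within-animal normalization
# to the hexanol response, pairwise age comparisons with Bonferroni
# correction, and the amplitude ~ age + stimulus OLS.

#' EAG peak amplitude of one trial
#'
#' Peak = maximum absolute deviation from the pre-onset baseline within the
#' response window. The absolute deviation is used because EAG deflections
#' are conventionally negative-going; the baseline is the mean of all
#' pre-onset samples.
#'
#' @param trial an EAG [AnalogTrial-class] with pre-onset samples.
#' @param response_window_s window after onset searched for the peak
#'   (default 2 s).
#' @return Peak amplitude in mV (non-negative).
#' @export
eagPeakAmplitude <- function(trial, response_window_s = 2) {
  stopifnot(is(trial, "AnalogTrial"))
  if (trial@modality != "EAG")
    stop("eagPeakAmplitude expects an EAG trial")
  fs <- trial@fs_hz
  on <- stimOnset(trial)
  tt <- (seq_along(trial@values_mV) - 1L) / fs
  pre <- trial@values_mV[tt < on]
  if (!length(pre))
    stop("no pre-onset samples: baseline is undefined")
  win <- tt >= on & tt <= on + response_window_s
  if (!any(win))
    stop("response window lies outside the trace")
  max(abs(trial@values_mV[win] - mean(pre)))
}

#' Normalize an odor panel by the hexanol response
#'
#' Divides every peak in a per-animal odor-to-amplitude map by that animal's
#' hexanol peak, making hexanol's normalized value exactly 1 and leaving the
#' map invariant under any rescaling of the whole panel.
#'
#' @param peaks named numeric vector of raw peak amplitudes (mV); must
#'   contain a positive `hex` entry.
#' @param reference reference odor (default `"hex"`).
#' @return Named numeric vector of unitless normalized amplitudes.
#' @examples
#' normalizePanel(c(hex = 2, cis = 1))   # hex 1.0, cis 0.5
#' @export
normalizePanel <- function(peaks, reference = "hex") {
  if (!reference %in% names(peaks))
    stop("reference odor '", reference, "' missing from the panel")
  ref <- peaks[[reference]]
  if (!is.finite(ref) || ref <= 0)
    stop("reference ('", reference, "') peak must be positive")
  peaks / ref
}

#' Per-animal EAG summaries from a dataset
#'
#' Extracts the peak amplitude of every EAG trial, averages trials within
#' each (animal, odor) pair, and normalizes each animal's panel by its own
#' hexanol peak.
#'
#' @param ds an [EphysDataset-class].
#' @param response_window_s passed to [eagPeakAmplitude()].
#' @param reference reference odor for normalization.
#' @return Data frame with one row per (animal, odor): `animal_id`,
#'   `age_group`, `odor`, `peak_mV`, `normalized`.
#' @export
eagSummaries <- function(ds, response_window_s = 2, reference = "hex") {
  stopifnot(is(ds, "EphysDataset"))
  sel <- vapply(ds@trials, function(tr)
    is(tr, "AnalogTrial") && tr@modality == "EAG", logical(1))
  trls <- ds@trials[sel]
  if (!length(trls)) stop("dataset contains no EAG trials")
  tab <- do.call(rbind, lapply(trls, function(tr) data.frame(
    animal_id = tr@animal@animal_id, age_group = ageGroup(tr),
    odor = odorLabel(tr),
    peak_mV = eagPeakAmplitude(tr, response_window_s),
    stringsAsFactors = FALSE)))
  agg <- stats::aggregate(peak_mV ~ animal_id + age_group + odor, tab, mean)
  out <- do.call(rbind, lapply(split(agg, agg$animal_id), function(a) {
    pk <- stats::setNames(a$peak_mV, a$odor)
    a$normalized <- as.numeric(normalizePanel(pk, reference)[a$odor])
    a
  }))
  rownames(out) <- NULL
  out
}

#' Pairwise age-group comparison of normalized EAG amplitudes
#'
#' One two-sample t-test per odor between the two age groups, on the
#' normalized amplitudes, with a Bonferroni-corrected alpha. The reference
#' odor is excluded — its normalized value is 1 in every animal by
#' construction, so there is nothing to compare. Welch's test is the default
#' (group sizes differ); the pooled-variance Student variant is available.
#' An odor missing from one group is skipped with a warning.
#'
#' @param summaries data frame from [eagSummaries()] with exactly two age
#'   groups.
#' @param odors odors to test (default: all shared non-reference odors).
#' @param reference reference odor to exclude (default `"hex"`).
#' @param variant t-test variant, see [tTwoSample()].
#' @param m_comparisons Bonferroni divisor; defaults to the number of odors
#'   actually tested.
#' @param family_alpha family-wise error target (default 0.05).
#' @return Data frame (odor, t, df, p, significant) with attributes
#'   `corrected_alpha` and `m_comparisons`.
#' @export
compareAgeGroups <- function(summaries, odors = NULL, reference = "hex",
                             variant = c("welch", "pooled"),
                             m_comparisons = NULL, family_alpha = 0.05) {
  variant <- match.arg(variant)
  ages <- unique(summaries$age_group)
  if (length(ages) != 2L)
    stop("need exactly two age groups, got: ", paste(ages, collapse = ", "))
  if (is.null(odors))
    odors <- setdiff(sort(unique(summaries$odor)), reference)
  odors <- setdiff(odors, reference)

  rows <- list()
  for (od in odors) {
    a <- summaries$normalized[summaries$odor == od &
                                summaries$age_group == ages[1L]]
    b <- summaries$normalized[summaries$odor == od &
                                summaries$age_group == ages[2L]]
    if (length(a) < 2L || length(b) < 2L) {
      warning("odor '", od, "' missing (or < 2 animals) in one group; ",
              "skipped")
      next
    }
    tt <- tTwoSample(a, b, variant)
    rows[[od]] <- data.frame(odor = od, t = tt$statistic, df = tt$df,
                             p = tt$p_value, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no odor could be tested")
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  m <- m_comparisons %||% nrow(out)
  alpha <- bonferroniAlpha(m, family_alpha)
  out$significant <- out$p < alpha
  attr(out, "corrected_alpha") <- alpha
  attr(out, "m_comparisons") <- m
  out
}

#' OLS of EAG peak amplitude on age and stimulus
#'
#' Dummy-coded ordinary least squares of amplitude on the categorical
#' factors age group and odor: `amplitude ~ age + stimulus`. The age
#' coefficient (with its standard error and p) measures whether the odor
#' panel evokes systematically different amplitudes across ages once odor
#' identity is accounted for.
#'
#' @param long_table data frame with columns `amplitude`, `age_group`,
#'   `odor` (one row per (animal, odor) observation); >= 2 levels of each
#'   factor.
#' @return [olsCategorical()] result; the age coefficient rows are the
#'   entries of `coefficients` whose term starts with `age_group`.
#' @export
fitAmplitudeOLS <- function(long_table) {
  stopifnot(all(c("amplitude", "age_group", "odor") %in% names(long_table)))
  if (length(unique(long_table$age_group)) < 2L ||
      length(unique(long_table$odor)) < 2L)
    stop("need at least two age groups and two odors")
  olsCategorical(long_table, "amplitude", c("age_group", "odor"))
}
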