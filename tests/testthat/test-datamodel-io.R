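test_that("save/load round-trips every field", {
  prof <- ageRateProfile("adult")
  sp <- genPNTrials(prof, 1, seed = 7)[[1]]
  an <- genLFPTrials(25, n_trials = 1, seed = 8,
                     animal = AnimalMeta("a9", "adult", 25L))[[1]]
  ds <- EphysDataset(list(sp, an),
                     manifest = list(generator = list(kind = "demo")))
  d <- withr::local_tempdir()
  saveDataset(ds, d)
  ds2 <- loadDataset(d)

  expect_length(ds2, 2L)
  sp2 <- ds2[[1]]; an2 <- ds2[[2]]
  expect_equal(spikes(sp2), spikes(sp), tolerance = 1e-12)
  expect_identical(sp2@cell_id, sp@cell_id)
  expect_identical(trialIndex(sp2), trialIndex(sp))
  expect_identical(odorLabel(sp2), odorLabel(sp))
  expect_equal(stimOnset(sp2), stimOnset(sp))
  expect_equal(sp2@record_duration_s, sp@record_duration_s)
  expect_equal(traceValues(an2), traceValues(an), tolerance = 1e-12)
  expect_equal(sampleRate(an2), sampleRate(an))
  expect_identical(modality(an2), modality(an))
  expect_identical(an2@animal@antennal_segments, 25L)
  expect_identical(manifest(ds2)$generator$kind, "demo")
})

test_that("empty dataset saves as a manifest-only directory", {
  d <- withr::local_tempdir()
  saveDataset(EphysDataset(), d)
  expect_identical(list.files(d), "manifest.json")
  expect_length(loadDataset(d), 0L)
})

test_that("directory without a manifest is a format error", {
  d <- withr::local_tempdir()
  expect_error(loadDataset(d), "format error")
})

test_that("6 trials x 8 odors from the generator load back as 48 trials", {
  prof <- ageRateProfile("adult")
  odors <- odorPanel[1:8]
  trls <- list()
  set.seed(21)
  for (od in odors)
    trls <- c(trls, genPNTrials(prof, 6, odor = od))
  d <- withr::local_tempdir()
  saveDataset(EphysDataset(trls), d)
  ds <- loadDataset(d)
  expect_length(ds, 48L)
  isSpike <- vapply(trials(ds), is, logical(1), "SpikeTrainTrial")
  expect_identical(sum(isSpike), 48L)
})

test_that("trim experiment enumerates per-animal, per-stage trials", {
  ds <- genTrimExperiment(c(25, 20), n_animals = 2L, seed = 3)
  d <- withr::local_tempdir()
  saveDataset(ds, d)
  man <- jsonlite::read_json(file.path(d, "manifest.json"),
                             simplifyVector = TRUE)
  # 2 animals x 2 stages x 2 sides x 10 trials
  expect_identical(nrow(man$trials), 80L)
  expect_setequal(unique(man$trials$animal_id), c("trim01", "trim02"))
  expect_setequal(unique(man$trials$stage), c(1L, 2L))
  expect_setequal(unique(man$trials$cuts), c(0L, 5L))
  expect_equal(man$ground_truth$slope_hz_per_cut, -0.52)
})

test_that("declared file units are converted on load", {
  d <- withr::local_tempdir()
  writeLines(sprintf("%.10g", c(1500, 2500)), file.path(d, "sp.txt"))
  writeLines(sprintf("%.10g", c(0, -2000, 0, 0, 0, 0)),
             file.path(d, "eag.txt"))
  man <- list(schema_version = "1.0", trials = list(
    list(kind = "spike", file = "sp.txt", record_duration_s = 8,
         odor = "hex", onset_s = 2, duration_s = 1, trial_index = 1,
         cell_id = "c1", animal_id = "a1", age_group = "adult",
         time_unit = "ms"),
    list(kind = "analog", file = "eag.txt", fs_hz = 2, modality = "EAG",
         side = "none", odor = "hex", onset_s = 1, duration_s = 1,
         trial_index = 1, animal_id = "a1", age_group = "adult",
         value_unit = "uV")))
  jsonlite::write_json(man, file.path(d, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  ds <- loadDataset(d)
  expect_equal(spikes(ds[[1]]), c(1.5, 2.5))
  expect_equal(min(traceValues(ds[[2]])), -2)  # microvolts -> millivolts
})

test_that("validateDataset flags one violation per broken invariant", {
  ok <- fixtureSpikeTrial(c(0.5, 1.0))
  stim <- OdorStimulus("hex", 2)

  bad <- list(
    negative_spike = fixtureSpikeTrial(c(-1, 0.5)),
    non_monotone = fixtureSpikeTrial(c(1.0, 0.5)),
    spike_after_end = fixtureSpikeTrial(c(0.5, 9.5)),
    stim_outside = SpikeTrainTrial(c(0.5), 2.5, stim),
    neg_onset = fixtureSpikeTrial(0.5, onset = -1),
    zero_duration = SpikeTrainTrial(0.5, 8, OdorStimulus("hex", 2, 0)),
    empty_odor = fixtureSpikeTrial(0.5, odor = ""),
    bad_age = fixtureSpikeTrial(0.5, animal = AnimalMeta("a1", "larva")),
    bad_segments = fixtureSpikeTrial(
      0.5, animal = AnimalMeta("a1", "adult", 31L)),
    lfp_nyquist = AnalogTrial(rep(0, 600), 60, "LFP", stim),
    lfp_short = AnalogTrial(rep(0, 500), 500, "LFP", stim))

  expect_length(validateDataset(EphysDataset(list(ok))), 0L)
  msgs <- c(negative_spike = "non-negative", non_monotone = "ascending",
            spike_after_end = "record", stim_outside = "end within",
            neg_onset = "onset", zero_duration = "duration",
            empty_odor = "odor", bad_age = "age group",
            bad_segments = "1, 30", lfp_nyquist = "Nyquist",
            lfp_short = "onset \\+ 4")
  for (nm in names(bad)) {
    v <- validateDataset(EphysDataset(list(bad[[nm]])))
    expect_gte(length(v), 1L)
    expect_match(v, msgs[[nm]], all = FALSE, label = nm)
  }

  dup <- EphysDataset(list(ok, fixtureSpikeTrial(c(0.2))))
  expect_match(validateDataset(dup), "duplicate", all = FALSE)
})
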