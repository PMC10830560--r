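test_that("responsiveness gate follows the half-the-trials rule", {
  # perfectly regular trains, no stimulus modulation: nothing responsive
  flat <- lapply(1:6, function(k)
    fixtureSpikeTrial(seq(0.05, 7.95, by = 0.1), trial = k))
  expect_false(assessResponsiveness(flat)$included)

  # strong excitation in all trials: included, first response bin flagged
  burst <- lapply(1:6, function(k)
    fixtureSpikeTrial(c(seq(0.05, 1.95, by = 0.4),
                        seq(2.02, 2.38, by = 0.02)), trial = k))
  rb <- assessResponsiveness(burst)
  expect_true(rb$included)
  expect_gte(sum(rb$mask[1, ]), 3)

  # response in only 2 of 6 trials: excluded
  some <- lapply(1:6, function(k) {
    sp <- if (k <= 2) c(seq(0.05, 1.95, by = 0.4), seq(2.02, 2.38, by = 0.02))
          else seq(0.05, 7.95, by = 0.4)
    fixtureSpikeTrial(sp, trial = k)
  })
  expect_false(assessResponsiveness(some)$included)

  noBaseline <- list(fixtureSpikeTrial(c(0.5, 1), onset = 0.2))
  expect_error(assessResponsiveness(noBaseline), "pre-onset")
})

test_that("peak detection obeys the lookahead/delta confirmation contract", {
  mono <- RateSeries(0, 0.01, seq(0, 10, length.out = 300))
  annUp <- detectPeaksValleys(mono, 0.2, 0.5)
  expect_identical(nrow(epochPeaks(annUp)), 0L)
  expect_identical(nrow(epochValleys(annUp)), 0L)
  monoDown <- RateSeries(0, 0.01, seq(10, 0, length.out = 300))
  annDown <- detectPeaksValleys(monoDown, 0.2, 0.5)
  expect_identical(nrow(epochPeaks(annDown)), 0L)
  expect_identical(nrow(epochValleys(annDown)), 0L)

  tri <- RateSeries(0, 0.01, c(seq(0, 8, length.out = 150),
                               seq(8, 0, length.out = 150)))
  annTri <- detectPeaksValleys(tri, 0.2, 1)
  expect_identical(nrow(epochPeaks(annTri)), 1L)
  expect_identical(nrow(epochValleys(annTri)), 0L)

  short <- RateSeries(0, 0.01, c(1, 5, 1))
  expect_identical(nrow(epochPeaks(detectPeaksValleys(short, 0.2, 1))), 0L)
})

test_that("detected extrema equal the brute-force confirmation-rule oracle", {
  set.seed(8)
  for (rep in 1:12) {
    raw <- RateSeries(0, 0.01, pmax(0, cumsum(rnorm(400, 0, 2)) + 20))
    rs <- gaussianSmooth(raw, sigma_s = 0.05, width_s = 0.3)
    for (delta in c(0.5, 2)) {
      ann <- detectPeaksValleys(rs, lookahead_s = 0.2, delta_hz = delta)
      orc <- oraclePeakDetect(rateValues(rs), rateTimes(rs), 20L, delta)
      expect_equal(epochPeaks(ann)[, 1], vapply(orc$peaks, `[`, numeric(1), 1),
                   ignore_attr = TRUE)
      expect_equal(epochValleys(ann)[, 1],
                   vapply(orc$valleys, `[`, numeric(1), 1),
                   ignore_attr = TRUE)
    }
  }
})

test_that("transition counting implements the valley and boundary rules", {
  mkAnn <- function(peaks, valleys) {
    pm <- if (length(peaks)) cbind(peaks, 10) else
      matrix(numeric(0), ncol = 2)
    vm <- if (length(valleys)) cbind(valleys, 1) else
      matrix(numeric(0), ncol = 2)
    EpochAnnotation(peaks = pm, valleys = vm)
  }
  expect_identical(countTransitions(mkAnn(NULL, NULL), 2), 0L)
  # two peaks separated by one valley: 2 (valley) + 1 (late first peak)
  # + 1 (early last peak)
  expect_identical(countTransitions(mkAnn(c(2.5, 5.0), 3.5), 2), 4L)
  # single peak within the 200 ms guard, excitation continuing to the end
  expect_identical(countTransitions(mkAnn(2.1, NULL), 2), 0L)
  # single late peak: spontaneous->excitatory and excitatory->baseline
  expect_identical(countTransitions(mkAnn(3.0, NULL), 2), 2L)

  # parity/bounds property on random alternating annotations
  set.seed(9)
  for (rep in 1:50) {
    k <- sample(1:5, 1)
    ext <- sort(runif(2 * k - 1, 2, 6))
    pk <- ext[seq(1, length(ext), by = 2)]
    vl <- if (length(ext) > 1) ext[seq(2, length(ext), by = 2)] else NULL
    n <- countTransitions(mkAnn(pk, vl), 2)
    vIn <- if (is.null(vl)) 0 else sum(vl > min(pk) & vl < max(pk))
    b <- n - 2L * vIn
    expect_true(b %in% 0:2)
  }
})

test_that("noiseless profiles run through the pipeline hit the enumeration oracle", {
  profiles <- list(
    fixtureRecoveryProfile(),
    ageRateProfile("adult"),
    ageRateProfile("hatchling"),
    RateProfile(2 + c(0.3, 1.0), 50, baseline_hz = 3),          # single epoch
    RateProfile(2 + c(0.01, 3.99), 50, baseline_hz = 3),        # spans window
    RateProfile(2 + c(0.3, 0.9, 1.5, 2.1, 2.7, 3.3),
                c(60, 5, 45, 5, 30), baseline_hz = 3))          # three epochs
  for (prof in profiles) {
    tt <- seq(0, max(prof@breakpoints_s) + 2, by = 0.001)
    rs <- gaussianSmooth(RateSeries(0, 0.001, profileRate(prof, tt)))
    ann <- detectPeaksValleys(rs, 0.2, 0)
    expect_identical(countTransitions(ann, prof@onset_s),
                     groundTruthTransitions(prof))
  }
})

test_that("transition distributions concentrate at ground truth and compare via KS", {
  prof <- fixtureRecoveryProfile()
  set.seed(15)
  trls <- list()
  for (cell in 1:4)
    trls <- c(trls, genPNTrials(prof, 6, cell_id = paste0("c", cell)))
  ds <- EphysDataset(trls)
  cnt <- complexityDistribution(ds, "adult", delta_hz = 40)
  expect_length(cnt, 24L)
  gt <- groundTruthTransitions(prof)
  expect_identical(as.integer(names(which.max(table(cnt)))), gt)

  pairs <- attr(cnt, "pairs")
  expect_identical(nrow(pairs), 4L)
  expect_true(all(pairs$included))

  expect_identical(compareDistributions(cnt, cnt)$statistic, 0)
  expect_equal(compareDistributions(c(0, 0, 1), c(1, 1, 1))$statistic, 2 / 3)
  expect_error(compareDistributions(integer(0), 1), "non-empty")

  quiet <- EphysDataset(lapply(1:6, function(k)
    fixtureSpikeTrial(seq(0.05, 7.95, by = 0.1), trial = k)))
  expect_warning(empty <- complexityDistribution(quiet, "adult"),
                 "responsive")
  expect_length(empty, 0L)
})

test_that("firing-rate ANOVA detects an injected age effect", {
  buildAge <- function(age, peak, n_cells, seed) {
    set.seed(seed)
    trls <- list()
    for (cell in seq_len(n_cells)) {
      for (od in c("hex", "cis", "oct", "cyc")) {
        prof <- RateProfile(2 + c(0.3, 1.3), peak, baseline_hz = peak / 10)
        trls <- c(trls, genPNTrials(
          prof, 6, odor = od, cell_id = sprintf("%s_c%d", age, cell),
          animal = AnimalMeta(sprintf("%s_a%d", age, cell), age)))
      }
    }
    trls
  }
  ds <- EphysDataset(c(buildAge("adult", 40, 5, 16),
                       buildAge("hatchling", 20, 5, 17)))
  res <- firingRateAnova(ds)
  expect_equal(res$df[res$term == "age"], 1)
  expect_lt(res$p[res$term == "age"], 1e-6)
  expect_gt(res$F[res$term == "age"], res$F[res$term == "odor"])

  expect_error(firingRateAnova(EphysDataset(buildAge("adult", 40, 2, 18))),
               "two age groups")
})
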