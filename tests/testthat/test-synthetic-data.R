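test_that("risk labelling applies the strict 12.47 s threshold", {
  expect_identical(labelByTugTime(13.0), "at_risk")
  expect_identical(labelByTugTime(12.47), "no_risk")  # strictly greater-than
  expect_identical(labelByTugTime(10.0), "no_risk")
  expect_identical(labelByTugTime(12.47 + 1e-9), "at_risk")
  expect_error(labelByTugTime(0), "positive")
  expect_error(labelByTugTime(-3), "positive")
  expect_error(labelByTugTime(Inf), "finite")
  expect_error(labelByTugTime(NA_real_), "finite")
})

test_that("config validation rejects inconsistent generator settings", {
  expect_error(generatorConfig(nPerClass = 0L), "nPerClass")
  expect_error(generatorConfig(samplingRate = -45), "samplingRate")
  expect_error(generatorConfig(phaseFractionMeans = c(0.5, 0.2, 0.1, 0.1, 0.2)),
               "sum to 1")
  expect_error(generatorConfig(tugMeans = c(no_risk = 13, at_risk = 15.5)),
               "below")
})

test_that("zero walk amplitude and zero noise give piecewise-constant traces", {
  cfg <- generatorConfig(
    nPerClass = 1L, noiseSd = 0,
    walkAmplitude = rbind(at_risk = c(v = 0, ml = 0, ap = 0),
                          no_risk = c(v = 0, ml = 0, ap = 0)),
    transitionAmplitude = c(no_risk = 0, at_risk = 0),
    seed = 3L)
  s <- generateSubject(cfg, "no_risk", "S1", seed = 5L)
  pb <- s@phaseBoundaries
  for (ph in 1:5) {
    seg <- s@trace[, (pb[ph] + 1):pb[ph + 1], drop = FALSE]
    expect_equal(max(apply(seg, 1, function(r) diff(range(r)))), 0)
  }
  # offsets survive as the constant level
  expect_equal(unname(s@trace["ap", 1]), 2.0)
})

test_that("subject records satisfy their structural invariants", {
  co <- quietCohort(nPerClass = 4L, seed = 11L)
  for (i in seq_len(length(co))) {
    s <- co[[i]]
    expect_equal(ncol(s@trace), round(s@tugTime * s@samplingRate))
    expect_identical(s@phaseBoundaries[1], 0L)
    expect_identical(s@phaseBoundaries[6], ncol(s@trace))
    expect_true(all(diff(s@phaseBoundaries) > 0))
    expect_identical(s@label, labelByTugTime(s@tugTime))
  }
})

test_that("cohorts have the configured size and are seed-deterministic", {
  co <- generateCohort(generatorConfig(nPerClass = 2L, seed = 9L))
  expect_equal(length(co), 4L)
  expect_setequal(unique(riskLabels(co)), c("at_risk", "no_risk"))

  tiny <- generateCohort(generatorConfig(nPerClass = 1L, seed = 2L))
  expect_equal(length(tiny), 2L)
  expect_identical(sort(riskLabels(tiny)), c("at_risk", "no_risk"))

  a <- generateCohort(generatorConfig(nPerClass = 2L, seed = 13L))
  b <- generateCohort(generatorConfig(nPerClass = 2L, seed = 13L))
  for (i in 1:4) expect_identical(a[[i]]@trace, b[[i]]@trace)
  c2 <- generateCohort(generatorConfig(nPerClass = 2L, seed = 14L))
  expect_false(identical(a[[1]]@trace, c2[[1]]@trace))
})

test_that("all TUG times fall on the label-consistent side of the threshold", {
  co <- quietCohort(nPerClass = 10L, seed = 21L)
  tt <- tugTimes(co); lab <- riskLabels(co)
  expect_true(all(tt[lab == "at_risk"] > 12.47))
  expect_true(all(tt[lab == "no_risk"] <= 12.47))
})

test_that("no-risk walking segments carry more gait-band power than at-risk", {
  # paired by seed, walk-F segment, periodogram oracle on the gait band
  cfg <- generatorConfig(seed = 1L)
  sNo <- generateSubject(cfg, "no_risk", "N", seed = 77L)
  sAt <- generateSubject(cfg, "at_risk", "A", seed = 77L)
  for (ax in c("v", "ml", "ap")) {
    segNo <- sNo@trace[ax, (sNo@phaseBoundaries[2] + 1):sNo@phaseBoundaries[3]]
    segAt <- sAt@trace[ax, (sAt@phaseBoundaries[2] + 1):sAt@phaseBoundaries[3]]
    pNo <- oracleBandPower(segNo, 45, 1.5, 2.5)
    pAt <- oracleBandPower(segAt, 45, 1.5, 2.5)
    expect_gt(pNo, pAt)
  }
})

test_that("gait-band class separation holds on every axis across many cohorts", {
  nCoh <- 20L
  bp <- array(NA_real_, c(nCoh, 3, 2),
              dimnames = list(NULL, c("v", "ml", "ap"), c("no_risk", "at_risk")))
  for (k in seq_len(nCoh)) {
    co <- generateCohort(generatorConfig(nPerClass = 3L, seed = 3000L + k))
    lab <- riskLabels(co)
    pw <- sapply(seq_len(length(co)), function(i) {
      s <- co[[i]]
      idx <- (s@phaseBoundaries[2] + 1):s@phaseBoundaries[3]
      vapply(c("v", "ml", "ap"), function(ax)
        oracleBandPower(s@trace[ax, idx], s@samplingRate, 1.5, 2.5),
        numeric(1))
    })
    for (ax in c("v", "ml", "ap")) {
      bp[k, ax, "no_risk"] <- mean(pw[ax, lab == "no_risk"])
      bp[k, ax, "at_risk"] <- mean(pw[ax, lab == "at_risk"])
    }
  }
  for (ax in c("v", "ml", "ap"))
    expect_gt(mean(bp[, ax, "no_risk"]), mean(bp[, ax, "at_risk"]))
})

test_that("cohorts round-trip through CSV files", {
  co <- quietCohort(nPerClass = 2L, seed = 31L)
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(manifest), 4L)
  expect_identical(names(manifest),
                   c("subject_id", "label", "tug_time_s", "trace_file",
                     paste0("b", 0:5)))
  back <- readCohort(dir)
  expect_equal(length(back), length(co))
  for (i in seq_len(length(co))) {
    expect_identical(back[[i]]@subjectId, co[[i]]@subjectId)
    expect_identical(back[[i]]@label, co[[i]]@label)
    expect_equal(back[[i]]@tugTime, co[[i]]@tugTime)
    expect_identical(back[[i]]@phaseBoundaries, co[[i]]@phaseBoundaries)
    expect_equal(back[[i]]@trace, co[[i]]@trace, tolerance = 1e-6)
  }
})

test_that("reading a cohort from an empty directory fails with the file named", {
  dir <- withr::local_tempdir()
  expect_error(readCohort(dir), "manifest")
  # a missing trace file is reported by name
  co <- quietCohort(nPerClass = 1L, seed = 41L)
  writeCohort(co, dir)
  unlink(file.path(dir, "traces", paste0(co[[1]]@subjectId, ".csv")))
  expect_error(readCohort(dir), co[[1]]@subjectId)
})
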