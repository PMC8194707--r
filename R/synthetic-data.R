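#' Risk label from a TUG completion time
#'
#' Community-dwelling elderly are screened as at risk of falling when the
#' timed-up-and-go time exceeds 12.47 s; times at or below the threshold are
#' labelled no-risk.
#'
#' @param tugTime TUG completion time in seconds (single positive number).
#' @return "at_risk" if \code{tugTime > 12.47}, else "no_risk".
#' @examples
#' labelByTugTime(13.0)  # "at_risk"
#' labelByTugTime(12.47) # "no_risk": the threshold is a strict inequality
#' @export
labelByTugTime <- function(tugTime) {
  .assertScalar(tugTime, "tugTime", positive = TRUE)
  if (tugTime > .TUG_THRESHOLD) "at_risk" else "no_risk"
}

#' @rdname labelByTugTime
#' @export
tugRiskThreshold <- function() .TUG_THRESHOLD

#' Build a synthetic-cohort generator configuration
#'
#' Defaults mirror the study conditions the pipeline targets: 22 subjects
#' per class sampled at 45 Hz, walking (gait) oscillations in the
#' 1.5-2.5 Hz band whose amplitude is higher for no-risk subjects on every
#' axis, and sit/stand transition bursts on the AP axis that are likewise
#' stronger for no-risk subjects. TUG times are drawn from truncated
#' normals on either side of the 12.47 s threshold so labels are consistent
#' by construction.
#'
#' @param nPerClass subjects per class (default 22).
#' @param samplingRate sampling rate in Hz (default 45).
#' @param tugMeans,tugSds named numeric (no_risk, at_risk): per-class
#'   TUG-time normal parameters before truncation at 12.47 s.
#' @param phaseFractionMeans mean phase-duration fractions for sit-to-stand,
#'   walk-F, turning, walk-B, stand-to-sit; must sum to 1.
#' @param gaitFrequencyRange Hz band the per-subject gait frequency is
#'   drawn from.
#' @param walkAmplitude 2 x 3 matrix (rows at_risk, no_risk; columns v, ml,
#'   ap) of gait oscillation amplitudes.
#' @param transitionAmplitude named numeric of AP-axis burst amplitudes for
#'   the sit-to-stand and stand-to-sit phases.
#' @param axisOffsets per-axis constant offsets.
#' @param noiseSd additive Gaussian noise sd.
#' @param seed integer master seed.
#' @return A validated \linkS4class{GeneratorConfig}.
#' @export
generatorConfig <- function(nPerClass = 22L,
                            samplingRate = 45,
                            tugMeans = c(no_risk = 9.5, at_risk = 15.5),
                            tugSds = c(no_risk = 1.2, at_risk = 2.0),
                            phaseFractionMeans = c(sit_to_stand = 0.15,
                                                   walk_f = 0.30,
                                                   turning = 0.12,
                                                   walk_b = 0.30,
                                                   stand_to_sit = 0.13),
                            gaitFrequencyRange = c(1.5, 2.5),
                            walkAmplitude = rbind(
                              at_risk = c(v = 1.2, ml = 1.0, ap = 1.4),
                              no_risk = c(v = 3.0, ml = 2.0, ap = 2.5)),
                            transitionAmplitude = c(no_risk = 3.0,
                                                    at_risk = 1.5),
                            axisOffsets = c(v = 1.0, ml = 1.0, ap = 2.0),
                            noiseSd = 0.3,
                            seed = 1L) {
  walkAmplitude <- walkAmplitude[.LABELS, .AXES, drop = FALSE]
  new("GeneratorConfig",
      nPerClass = as.integer(nPerClass),
      samplingRate = samplingRate,
      tugMeans = tugMeans, tugSds = tugSds,
      phaseFractionMeans = phaseFractionMeans,
      gaitFrequencyRange = gaitFrequencyRange,
      walkAmplitude = walkAmplitude,
      transitionAmplitude = transitionAmplitude,
      axisOffsets = axisOffsets[.AXES],
      noiseSd = noiseSd,
      seed = as.integer(seed))
}

## Truncated-normal draw by inverse CDF: deterministic in the single
## uniform it consumes, and exact about which side of the threshold it
## falls on.
.rtruncnorm1 <- function(mean, sd, upper = NULL, lower = NULL) {
  u <- stats::runif(1)
  if (!is.null(upper)) {
    pHi <- stats::pnorm((upper - mean) / sd)
    q <- stats::qnorm(u * pHi)
  } else {
    pLo <- stats::pnorm((lower - mean) / sd)
    q <- stats::qnorm(pLo + u * (1 - pLo))
  }
  mean + sd * q
}

#' Generate one synthetic TUG subject
#'
#' The trace is built phase by phase: the two walking phases carry a
#' sinusoid at a gait frequency drawn from the configured band, with
#' class- and axis-dependent amplitude, plus two extra mediolateral
#' components (near 1-1.3 Hz for both classes and near 2.5-3.5 Hz mainly
#' for no-risk subjects, emulating arm-swing energy); the turning phase
#' carries an attenuated oscillation at 1.5-2 Hz; the sit-to-stand and
#' stand-to-sit phases carry a half-sine burst on the AP axis with
#' class-dependent amplitude. Constant per-axis offsets model the
#' gravity/posture component and Gaussian noise is added throughout.
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @param label "at_risk" or "no_risk".
#' @param subjectId identifier string.
#' @param seed integer seed for this subject's draws.
#' @return A \linkS4class{SubjectRecord}.
#' @export
generateSubject <- function(config, label, subjectId, seed) {
  stopifnot(is(config, "GeneratorConfig"))
  validObject(config)
  if (!label %in% .LABELS) stop("label must be 'at_risk' or 'no_risk'")
  fs <- config@samplingRate

  .withSeed(seed, {
    tugTime <- if (label == "no_risk") {
      .rtruncnorm1(config@tugMeans["no_risk"], config@tugSds["no_risk"],
                   upper = .TUG_THRESHOLD)
    } else {
      .rtruncnorm1(config@tugMeans["at_risk"], config@tugSds["at_risk"],
                   lower = .TUG_THRESHOLD)
    }
    tugTime <- unname(tugTime)
    T <- round(tugTime * fs)

    ## jittered phase fractions, renormalized; boundaries kept strictly
    ## increasing
    fr <- config@phaseFractionMeans * exp(stats::rnorm(5, 0, 0.08))
    fr <- fr / sum(fr)
    pb <- round(cumsum(c(0, fr)) * T)
    pb[6] <- T
    for (k in 2:6) if (pb[k] <= pb[k - 1]) pb[k] <- pb[k - 1] + 1L
    if (pb[6] > T) stop("trace too short for five phases")

    tSec <- (seq_len(T) - 1) / fs
    trace <- matrix(0, nrow = 3, ncol = T, dimnames = list(.AXES, NULL))

    fGait <- stats::runif(1, config@gaitFrequencyRange[1],
                          config@gaitFrequencyRange[2])
    phiWalk <- stats::runif(3, 0, 2 * pi)
    fMlLow <- stats::runif(1, 1.0, 1.3)
    fMlHigh <- stats::runif(1, 2.5, 3.5)
    phiMl <- stats::runif(2, 0, 2 * pi)
    fTurn <- stats::runif(1, 1.5, 2.0)
    phiTurn <- stats::runif(3, 0, 2 * pi)
    amp <- config@walkAmplitude[label, ]
    mlHighScale <- if (label == "no_risk") 0.9 else 0.25

    for (ph in c(2L, 4L)) {            # walk-F and walk-B
      idx <- (pb[ph] + 1):pb[ph + 1]
      tt <- tSec[idx]
      for (a in seq_along(.AXES))
        trace[a, idx] <- trace[a, idx] +
          amp[a] * sin(2 * pi * fGait * tt + phiWalk[a])
      trace["ml", idx] <- trace["ml", idx] +
        0.8 * amp["ml"] * sin(2 * pi * fMlLow * tt + phiMl[1]) +
        mlHighScale * amp["ml"] * sin(2 * pi * fMlHigh * tt + phiMl[2])
    }

    idx <- (pb[3] + 1):pb[4]           # turning
    tt <- tSec[idx]
    for (a in seq_along(.AXES))
      trace[a, idx] <- trace[a, idx] +
        0.6 * amp[a] * sin(2 * pi * fTurn * tt + phiTurn[a])

    aTrans <- config@transitionAmplitude[label]
    for (ph in c(1L, 5L)) {            # sit-to-stand, stand-to-sit
      idx <- (pb[ph] + 1):pb[ph + 1]
      w <- seq(0, 1, length.out = length(idx))
      trace["ap", idx] <- trace["ap", idx] + aTrans * sin(pi * w)
    }

    trace <- trace + config@axisOffsets
    if (config@noiseSd > 0)
      trace <- trace + matrix(stats::rnorm(3 * T, 0, config@noiseSd), nrow = 3)

    new("SubjectRecord",
        subjectId = subjectId, label = label, tugTime = tugTime,
        trace = trace, samplingRate = fs,
        phaseBoundaries = as.integer(pb), seedUsed = as.integer(seed))
  })
}

#' Generate a full synthetic cohort
#'
#' Produces exactly \code{nPerClass} subjects per class, each from a seed
#' derived deterministically from the config seed, so the whole cohort is a
#' pure function of its configuration.
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @return A \linkS4class{TugCohort}; at-risk subjects first.
#' @examples
#' cohort <- generateCohort(generatorConfig(nPerClass = 2L))
#' riskLabels(cohort)
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  validObject(config)
  subjects <- list()
  for (ci in seq_along(.LABELS)) {
    lab <- .LABELS[ci]
    prefix <- if (lab == "at_risk") "AR" else "NR"
    for (i in seq_len(config@nPerClass)) {
      sid <- sprintf("%s%02d", prefix, i)
      seed <- .deriveSeed(config@seed, ci, i)
      subjects[[length(subjects) + 1L]] <- generateSubject(config, lab, sid, seed)
    }
  }
  new("TugCohort", subjects = subjects, config = config)
}

#' @rdname accessors
#' @aliases riskLabels tugTimes subjectIds
#' @param x a \linkS4class{TugCohort}.
setMethod("riskLabels", "TugCohort", function(x)
  vapply(x@subjects, slot, character(1), name = "label"))

#' @rdname accessors
setMethod("tugTimes", "TugCohort", function(x)
  vapply(x@subjects, slot, numeric(1), name = "tugTime"))

#' @rdname accessors
setMethod("subjectIds", "TugCohort", function(x)
  vapply(x@subjects, slot, character(1), name = "subjectId"))

#' @describeIn generateCohort number of subjects
#' @param x a TugCohort
#' @export
setMethod("length", "TugCohort", function(x) length(x@subjects))

#' @describeIn generateCohort extract one SubjectRecord
#' @param i index
#' @export
setMethod("[[", "TugCohort", function(x, i) x@subjects[[i]])

setMethod("show", "TugCohort", function(object) {
  lab <- riskLabels(object)
  cat(sprintf("TugCohort with %d subjects (%d at risk / %d no risk)\n",
              length(lab), sum(lab == "at_risk"), sum(lab == "no_risk")))
  tt <- tugTimes(object)
  cat(sprintf("  TUG times: %.1f-%.1f s (threshold %.2f s)\n",
              min(tt), max(tt), .TUG_THRESHOLD))
})

setMethod("show", "SubjectRecord", function(object) {
  cat(sprintf("SubjectRecord %s [%s]: TUG %.2f s, %d samples @ %g Hz\n",
              object@subjectId, object@label, object@tugTime,
              ncol(object@trace), object@samplingRate))
})

#' Write / read a cohort as plain-text CSV files
#'
#' \code{writeCohort} writes a manifest (\code{manifest.csv} with columns
#' subject_id, label, tug_time_s, trace_file, b0..b5) and one trace CSV per
#' subject with columns t, v, ml, ap. \code{readCohort} reads them back;
#' labels, times and phase boundaries round-trip losslessly and traces
#' round-trip to numeric-text precision.
#'
#' @param cohort a \linkS4class{TugCohort}.
#' @param directory target/source directory.
#' @return \code{writeCohort} the directory invisibly; \code{readCohort} a
#'   \linkS4class{TugCohort}.
#' @export
writeCohort <- function(cohort, directory) {
  stopifnot(is(cohort, "TugCohort"))
  dir.create(file.path(directory, "traces"), recursive = TRUE,
             showWarnings = FALSE)
  rows <- lapply(cohort@subjects, function(s) {
    tf <- file.path("traces", paste0(s@subjectId, ".csv"))
    tSec <- (seq_len(ncol(s@trace)) - 1) / s@samplingRate
    df <- data.frame(t = tSec, v = s@trace["v", ], ml = s@trace["ml", ],
                     ap = s@trace["ap", ])
    utils::write.csv(df, file.path(directory, tf), row.names = FALSE)
    c(subject_id = s@subjectId, label = s@label,
      tug_time_s = format(s@tugTime, digits = 17), trace_file = tf,
      stats::setNames(as.character(s@phaseBoundaries), paste0("b", 0:5)))
  })
  manifest <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(directory, "manifest.csv"),
                   row.names = FALSE)
  srFile <- file.path(directory, "sampling_rate.txt")
  writeLines(format(cohort@subjects[[1]]@samplingRate, digits = 17), srFile)
  invisible(directory)
}

#' @rdname writeCohort
#' @export
readCohort <- function(directory) {
  mf <- file.path(directory, "manifest.csv")
  if (!file.exists(mf))
    stop(sprintf("cohort manifest not found: %s", mf), call. = FALSE)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  srFile <- file.path(directory, "sampling_rate.txt")
  if (!file.exists(srFile))
    stop(sprintf("sampling-rate file not found: %s", srFile), call. = FALSE)
  fs <- as.numeric(readLines(srFile)[1])
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    tf <- file.path(directory, row$trace_file)
    if (!file.exists(tf))
      stop(sprintf("trace file not found: %s", tf), call. = FALSE)
    tr <- utils::read.csv(tf)
    trace <- t(as.matrix(tr[, c("v", "ml", "ap")]))
    rownames(trace) <- .AXES
    new("SubjectRecord",
        subjectId = row$subject_id, label = row$label,
        tugTime = as.numeric(row$tug_time_s), trace = trace,
        samplingRate = fs,
        phaseBoundaries = as.integer(row[paste0("b", 0:5)]),
        seedUsed = NA_integer_)
  })
  new("TugCohort", subjects = subjects, config = NULL)
}
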