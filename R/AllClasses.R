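#' @import methods
NULL

## TUG time (s) above which a subject is considered at risk of falling,
## following the community-elderly screening threshold.
.TUG_THRESHOLD <- 12.47

## Axis labels, fixed order: vertical, mediolateral, anteroposterior.
.AXES <- c("v", "ml", "ap")

## Class labels; at_risk is the positive class throughout.
.LABELS <- c("at_risk", "no_risk")

#' Configuration for the synthetic TUG cohort generator
#'
#' Holds every parameter of the seeded synthetic cohort: per-class sample
#' sizes, sampling rate, per-class TUG-time distributions (truncated normals
#' on either side of the 12.47 s risk threshold), mean phase-duration
#' fractions for the five TUG phases, the gait-frequency band, class- and
#' axis-dependent walking amplitudes, class-dependent sit/stand transition
#' burst amplitudes on the AP axis, per-axis static offsets, additive noise
#' scale and the master seed.
#'
#' @slot nPerClass integer, subjects per class.
#' @slot samplingRate sampling rate in Hz.
#' @slot tugMeans,tugSds named numeric (no_risk, at_risk): mean and sd of the
#'   per-class TUG-time normal before truncation at the risk threshold.
#' @slot phaseFractionMeans numeric(5), mean fraction of the TUG duration
#'   spent in each phase (sit-to-stand, walk-F, turning, walk-B,
#'   stand-to-sit); must sum to 1.
#' @slot gaitFrequencyRange numeric(2), Hz band the gait frequency is drawn
#'   from.
#' @slot walkAmplitude 2 x 3 numeric matrix (rows no_risk, at_risk; columns
#'   v, ml, ap): amplitude of the gait oscillation in the walking phases.
#' @slot transitionAmplitude named numeric (no_risk, at_risk): amplitude of
#'   the sit-to-stand / stand-to-sit burst on the AP axis.
#' @slot axisOffsets named numeric(3): constant per-axis offsets modelling
#'   gravity/posture components.
#' @slot noiseSd sd of the additive Gaussian noise.
#' @slot seed integer master seed.
#' @exportClass GeneratorConfig
setClass("GeneratorConfig",
  representation(
    nPerClass = "integer",
    samplingRate = "numeric",
    tugMeans = "numeric",
    tugSds = "numeric",
    phaseFractionMeans = "numeric",
    gaitFrequencyRange = "numeric",
    walkAmplitude = "matrix",
    transitionAmplitude = "numeric",
    axisOffsets = "numeric",
    noiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  if (length(object@nPerClass) != 1L || is.na(object@nPerClass) ||
      object@nPerClass < 1L)
    msg <- c(msg, "nPerClass must be a single integer >= 1")
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  for (s in c("tugMeans", "tugSds", "transitionAmplitude")) {
    v <- slot(object, s)
    if (!identical(sort(names(v)), sort(.LABELS)))
      msg <- c(msg, sprintf("%s must be named with %s",
                            s, paste(.LABELS, collapse = ", ")))
  }
  pf <- object@phaseFractionMeans
  if (length(pf) != 5L || any(!is.finite(pf)) || any(pf <= 0))
    msg <- c(msg, "phaseFractionMeans must be 5 positive fractions")
  else if (abs(sum(pf) - 1) > 1e-8)
    msg <- c(msg, "phaseFractionMeans must sum to 1")
  gr <- object@gaitFrequencyRange
  if (length(gr) != 2L || any(!is.finite(gr)) || gr[1] <= 0 || gr[1] > gr[2])
    msg <- c(msg, "gaitFrequencyRange must be an increasing positive pair")
  wa <- object@walkAmplitude
  if (!all(dim(wa) == c(2L, 3L)) ||
      !identical(rownames(wa), .LABELS) || !identical(colnames(wa), .AXES))
    msg <- c(msg, "walkAmplitude must be a 2 x 3 matrix with rows at_risk/no_risk and columns v/ml/ap")
  if (length(object@noiseSd) != 1L || !is.finite(object@noiseSd) ||
      object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be a single non-negative number")
  if (all(is.finite(object@tugMeans)) &&
      object@tugMeans["no_risk"] >= .TUG_THRESHOLD)
    msg <- c(msg, "no-risk TUG mean must lie below the 12.47 s threshold")
  if (all(is.finite(object@tugMeans)) &&
      object@tugMeans["at_risk"] <= .TUG_THRESHOLD)
    msg <- c(msg, "at-risk TUG mean must lie above the 12.47 s threshold")
  if (length(msg)) msg else TRUE
})

#' One synthetic TUG subject
#'
#' @slot subjectId character identifier.
#' @slot label "at_risk" or "no_risk"; consistent with \code{tugTime} by
#'   construction (at risk iff the TUG time exceeds 12.47 s).
#' @slot tugTime total TUG duration in seconds.
#' @slot trace 3 x T acceleration matrix, rows v, ml, ap.
#' @slot samplingRate Hz.
#' @slot phaseBoundaries integer(6) sample indices delimiting the five
#'   phases; first is 0, last is T.
#' @slot seedUsed integer seed the subject was generated from (NA when read
#'   back from disk).
#' @exportClass SubjectRecord
setClass("SubjectRecord",
  representation(
    subjectId = "character",
    label = "character",
    tugTime = "numeric",
    trace = "matrix",
    samplingRate = "numeric",
    phaseBoundaries = "integer",
    seedUsed = "integer"
  )
)

setValidity("SubjectRecord", function(object) {
  msg <- character()
  if (!object@label %in% .LABELS)
    msg <- c(msg, "label must be 'at_risk' or 'no_risk'")
  if (!is.finite(object@tugTime) || object@tugTime <= 0)
    msg <- c(msg, "tugTime must be positive")
  tr <- object@trace
  if (nrow(tr) != 3L || !identical(rownames(tr), .AXES))
    msg <- c(msg, "trace must have 3 rows named v, ml, ap")
  pb <- object@phaseBoundaries
  if (length(pb) != 6L || pb[1] != 0L || pb[6] != ncol(tr) ||
      any(diff(pb) <= 0))
    msg <- c(msg, "phaseBoundaries must be 6 strictly increasing indices from 0 to T")
  expT <- round(object@tugTime * object@samplingRate)
  if (ncol(tr) != expT)
    msg <- c(msg, "trace length must equal round(tugTime * samplingRate)")
  lab <- if (object@tugTime > .TUG_THRESHOLD) "at_risk" else "no_risk"
  if (!identical(lab, object@label))
    msg <- c(msg, "label inconsistent with tugTime and the 12.47 s threshold")
  if (length(msg)) msg else TRUE
})

#' A synthetic TUG cohort
#'
#' An ordered collection of \linkS4class{SubjectRecord} objects together
#' with the \linkS4class{GeneratorConfig} they were generated from.
#'
#' @slot subjects list of SubjectRecord.
#' @slot config the GeneratorConfig used (may be NULL when read from disk).
#' @exportClass TugCohort
setClass("TugCohort",
  representation(subjects = "list", config = "ANY")
)

setValidity("TugCohort", function(object) {
  ok <- vapply(object@subjects, is, logical(1), class2 = "SubjectRecord")
  if (!all(ok)) "all elements must be SubjectRecord objects" else TRUE
})

#' Complex Morlet wavelet
#'
#' A complex sinusoid at central frequency \code{fc} under a Gaussian
#' envelope, sampled at the trace sampling rate over a finite symmetric
#' support. The frequency width is tied to the central frequency by the
#' constant ratio fc / sigmaF = 7, so that sigmaT * sigmaF = 1 / (2 pi) and
#' the amplitude A = (sigmaT * sqrt(pi))^(-1/2) gives unit energy.
#'
#' @slot fc central frequency, Hz.
#' @slot sigmaF Gaussian width in the frequency domain, Hz.
#' @slot sigmaT wavelet duration, s.
#' @slot A normalization factor.
#' @slot samples complex vector sampled at \code{samplingRate}.
#' @slot samplingRate Hz.
#' @exportClass MorletWavelet
setClass("MorletWavelet",
  representation(
    fc = "numeric", sigmaF = "numeric", sigmaT = "numeric",
    A = "numeric", samples = "complex", samplingRate = "numeric"
  )
)

setValidity("MorletWavelet", function(object) {
  msg <- character()
  if (object@fc <= 0) msg <- c(msg, "fc must be positive")
  if (abs(object@sigmaF - object@fc / 7) > 1e-12 * object@fc)
    msg <- c(msg, "sigmaF must equal fc / 7")
  if (abs(object@sigmaT * object@sigmaF - 1 / (2 * pi)) > 1e-12)
    msg <- c(msg, "sigmaT * sigmaF must equal 1 / (2 pi)")
  if (length(msg)) msg else TRUE
})

#' Frequency grid for time-frequency analysis
#'
#' @slot frequencies strictly increasing Hz values, linearly spaced with
#'   both endpoints included.
#' @exportClass FrequencyGrid
setClass("FrequencyGrid", representation(frequencies = "numeric"))

setValidity("FrequencyGrid", function(object) {
  f <- object@frequencies
  if (length(f) < 2L) return("need at least 2 frequencies")
  if (any(!is.finite(f)) || f[1] <= 0) return("frequencies must be positive")
  if (any(diff(f) <= 0)) return("frequencies must be strictly increasing")
  TRUE
})

#' Time-frequency representation of one axis of one trace
#'
#' The time-varying energy E(t, fc): squared modulus of the convolution of
#' the signal with complex Morlet wavelets, one row per grid frequency.
#'
#' @slot energy nBins x T non-negative matrix.
#' @slot timeAxis time points in seconds.
#' @slot grid the \linkS4class{FrequencyGrid}.
#' @exportClass TFRepresentation
setClass("TFRepresentation",
  representation(energy = "matrix", timeAxis = "numeric", grid = "FrequencyGrid")
)

setValidity("TFRepresentation", function(object) {
  msg <- character()
  if (nrow(object@energy) != length(object@grid@frequencies))
    msg <- c(msg, "energy must have one row per grid frequency")
  if (ncol(object@energy) != length(object@timeAxis))
    msg <- c(msg, "energy must have one column per time point")
  if (any(object@energy < 0))
    msg <- c(msg, "energy entries must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Fixed-size colormapped time-frequency image
#'
#' @slot pixels H x W x 3 array with values in [0, 1]; low frequencies at
#'   the bottom row, time along the width.
#' @slot sourceAxis which acceleration axis the image came from.
#' @exportClass TFImage
setClass("TFImage",
  representation(pixels = "array", sourceAxis = "character")
)

setValidity("TFImage", function(object) {
  p <- object@pixels
  if (length(dim(p)) != 3L || dim(p)[3] != 3L)
    return("pixels must be an H x W x 3 array")
  if (any(p < 0) || any(p > 1)) return("pixel values must lie in [0, 1]")
  TRUE
})

#' One sparse autoencoder layer
#'
#' Encoder z = sigmoid(W1 x + b1) and decoder xhat = sigmoid(W2 z + b2),
#' with L2 weight decay coefficient \code{lambda}, sparsity coefficient
#' \code{beta} and target mean activation (sparsity proportion) \code{rho}.
#'
#' @slot W1 dHidden x dIn encoder weights.
#' @slot b1 dHidden encoder biases.
#' @slot W2 dIn x dHidden decoder weights.
#' @slot b2 dIn decoder biases.
#' @slot lambda,beta,rho hyperparameters (lambda, beta >= 0; rho in (0,1)).
#' @exportClass AutoencoderLayer
setClass("AutoencoderLayer",
  representation(
    W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric",
    lambda = "numeric", beta = "numeric", rho = "numeric"
  )
)

setValidity("AutoencoderLayer", function(object) {
  msg <- character()
  dH <- nrow(object@W1); dI <- ncol(object@W1)
  if (length(object@b1) != dH) msg <- c(msg, "b1 length must match nrow(W1)")
  if (!all(dim(object@W2) == c(dI, dH)))
    msg <- c(msg, "W2 must be ncol(W1) x nrow(W1)")
  if (length(object@b2) != dI) msg <- c(msg, "b2 length must match ncol(W1)")
  if (object@lambda < 0 || object@beta < 0)
    msg <- c(msg, "lambda and beta must be non-negative")
  if (object@rho <= 0 || object@rho >= 1)
    msg <- c(msg, "rho must lie strictly in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Training configuration for autoencoder and classifier optimization
#'
#' @slot maxIterations iteration cap for each unsupervised layer fit.
#' @slot softmaxIterations iteration cap for the convex softmax-head fit.
#' @slot fineTuneIterations iteration cap for supervised fine-tuning of the
#'   whole encoder stack (0 disables fine-tuning).
#' @slot optimizer name of the stats::optim method (deterministic full-batch
#'   quasi-Newton by default).
#' @slot convergenceTol gradient-norm tolerance passed to the optimizer.
#' @slot fineTuneDecay L2 weight-decay coefficient applied to the encoder
#'   weight matrices during supervised fine-tuning (softmax weights stay
#'   unregularized); 0 disables it.
#' @slot validationFraction fraction of the training examples held out
#'   (stratified) to early-stop the supervised fine-tuning; 0 disables
#'   early stopping.
#' @slot patience number of consecutive non-improving validation checks
#'   tolerated before fine-tuning stops.
#' @slot seed integer seed for weight initialization.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(
    maxIterations = "integer",
    softmaxIterations = "integer",
    fineTuneIterations = "integer",
    optimizer = "character",
    convergenceTol = "numeric",
    fineTuneDecay = "numeric",
    validationFraction = "numeric",
    patience = "integer",
    seed = "integer"
  )
)

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@maxIterations < 1L) msg <- c(msg, "maxIterations must be >= 1")
  if (object@softmaxIterations < 1L)
    msg <- c(msg, "softmaxIterations must be >= 1")
  if (object@fineTuneIterations < 0L)
    msg <- c(msg, "fineTuneIterations must be >= 0")
  if (object@fineTuneDecay < 0)
    msg <- c(msg, "fineTuneDecay must be >= 0")
  if (object@validationFraction < 0 || object@validationFraction >= 0.5)
    msg <- c(msg, "validationFraction must lie in [0, 0.5)")
  if (object@patience < 1L) msg <- c(msg, "patience must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Stacked autoencoder classifier
#'
#' Two greedily pretrained encoder layers followed by a two-class softmax
#' head; after supervised training the decoders are unused for prediction.
#'
#' @slot encoder1 first \linkS4class{AutoencoderLayer} (input -> n1).
#' @slot encoder2 second layer (n1 -> n2).
#' @slot softmaxW 2 x n2 softmax weights.
#' @slot softmaxB numeric(2) softmax biases.
#' @slot classes class labels, positive class first.
#' @exportClass SAEClassifier
setClass("SAEClassifier",
  representation(
    encoder1 = "AutoencoderLayer",
    encoder2 = "AutoencoderLayer",
    softmaxW = "matrix",
    softmaxB = "numeric",
    classes = "character"
  )
)

setValidity("SAEClassifier", function(object) {
  msg <- character()
  n1 <- nrow(object@encoder1@W1)
  if (ncol(object@encoder2@W1) != n1)
    msg <- c(msg, "encoder2 input size must equal encoder1 hidden size")
  n2 <- nrow(object@encoder2@W1)
  if (!all(dim(object@softmaxW) == c(2L, n2)))
    msg <- c(msg, "softmaxW must be 2 x n2")
  if (length(object@softmaxB) != 2L) msg <- c(msg, "softmaxB must have length 2")
  if (length(object@classes) != 2L) msg <- c(msg, "classes must have length 2")
  if (length(msg)) msg else TRUE
})

#' Neuron-count grid-search result
#'
#' @slot mseTable matrix of mean stacked-reconstruction MSE, rows indexed by
#'   first-layer sizes, columns by second-layer sizes.
#' @slot bestPair named integer(2), the (n1, n2) attaining the minimum MSE
#'   (ties broken toward smaller n1, then smaller n2).
#' @slot runs number of independently seeded runs averaged per cell.
#' @exportClass GridSearchResult
setClass("GridSearchResult",
  representation(mseTable = "matrix", bestPair = "integer", runs = "integer")
)

setValidity("GridSearchResult", function(object) {
  b <- object@bestPair
  if (length(b) != 2L) return("bestPair must have length 2")
  m <- object@mseTable
  v <- m[as.character(b[1]), as.character(b[2])]
  if (abs(v - min(m)) > 0) return("bestPair must attain the minimum MSE")
  TRUE
})

#' Aggregate confusion matrix with derived rates
#'
#' Positive class is at_risk. Accuracy, sensitivity and specificity are
#' derived from the integer cell counts.
#'
#' @slot tp,fp,tn,fn integer counts.
#' @exportClass ConfusionSummary
setClass("ConfusionSummary",
  representation(tp = "integer", fp = "integer", tn = "integer", fn = "integer")
)

setValidity("ConfusionSummary", function(object) {
  cells <- c(object@tp, object@fp, object@tn, object@fn)
  if (any(cells < 0)) return("counts must be non-negative")
  if (sum(cells) == 0) return("at least one prediction is required")
  TRUE
})

#' Full-experiment configuration
#'
#' @slot generator \linkS4class{GeneratorConfig} for the cohort.
#' @slot fmin,fmax,nBins frequency sweep for the wavelet transform.
#' @slot imageHeight,imageWidth rendered image size.
#' @slot n1,n2 encoder layer sizes.
#' @slot hyper per-layer SAE hyperparameters (see \code{\link{saeHyper}}).
#' @slot train \linkS4class{TrainConfig}.
#' @slot alpha significance level for baseline feature screening.
#' @slot nRepeats repeated SAE LOOCV runs with distinct training seeds.
#' @slot outputDir directory for artifacts, or NA to keep in memory.
#' @exportClass ExperimentConfig
setClass("ExperimentConfig",
  representation(
    generator = "GeneratorConfig",
    fmin = "numeric", fmax = "numeric", nBins = "integer",
    imageHeight = "integer", imageWidth = "integer",
    n1 = "integer", n2 = "integer",
    hyper = "list",
    train = "TrainConfig",
    alpha = "numeric",
    nRepeats = "integer",
    outputDir = "character"
  )
)

setValidity("ExperimentConfig", function(object) {
  msg <- character()
  if (object@nRepeats < 1L) msg <- c(msg, "nRepeats must be >= 1")
  if (!(object@fmin > 0 && object@fmin < object@fmax))
    msg <- c(msg, "need 0 < fmin < fmax")
  if (length(msg)) msg else TRUE
})

#' Per-axis evaluation report for both pipelines
#'
#' Stores per-run confusion matrices and derived metrics for each axis and
#' method; summary tables recompute means and standard deviations from the
#' stored per-run values.
#'
#' @slot metrics data.frame with one row per run x axis x method, holding
#'   confusion cells and accuracy/sensitivity/specificity.
#' @slot config the \linkS4class{ExperimentConfig} used.
#' @slot provenance list: master seed, derived per-run seeds, config
#'   fingerprint, timestamp.
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(metrics = "data.frame", config = "ExperimentConfig",
                 provenance = "list")
)
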