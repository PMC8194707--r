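#' Statistical features of one axis of a trace
#'
#' The five summary features used by the feature-based pipeline: mean,
#' standard deviation (unbiased, divisor T - 1), maximum, minimum and the
#' mean crossing rate (MCR) -- the fraction of consecutive sample pairs
#' that strictly straddle the signal mean.
#'
#' @param x numeric vector, one axis of a trace (length >= 2).
#' @return Named numeric(5): mean, std, max, min, mcr.
#' @examples
#' extractFeatures(c(1, -1, 1, -1, 1))  # mcr = 1
#' @export
extractFeatures <- function(x) {
  if (length(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (any(!is.finite(x))) stop("signal contains non-finite values", call. = FALSE)
  m <- mean(x)
  d <- x - m
  crossings <- sum(d[-length(d)] * d[-1] < 0)
  c(mean = m, std = stats::sd(x), max = max(x), min = min(x),
    mcr = crossings / (length(x) - 1))
}

## Canonical 15-feature column order: 5 features x 3 axes.
.FEATURE_NAMES <- as.vector(t(outer(.AXES, c("mean", "std", "max", "min", "mcr"),
                                    function(a, f) paste(f, a, sep = "_"))))

#' Per-subject feature table for a cohort
#'
#' Computes the 15 features (5 per axis, full-trace) for every subject.
#'
#' @param cohort a \linkS4class{TugCohort}.
#' @return data.frame with subject_id, label and the 15 feature columns
#'   (mean_v, std_v, max_v, min_v, mcr_v, ..., mcr_ap).
#' @export
cohortFeatureTable <- function(cohort) {
  stopifnot(is(cohort, "TugCohort"))
  rows <- t(vapply(cohort@subjects, function(s) {
    unlist(lapply(.AXES, function(a) extractFeatures(s@trace[a, ])))
  }, numeric(15)))
  colnames(rows) <- .FEATURE_NAMES
  data.frame(subject_id = subjectIds(cohort), label = riskLabels(cohort),
             rows, check.names = FALSE)
}

#' Screen features by two-sample t-test significance
#'
#' Classic pooled-variance (Student) two-sample t-tests per feature, two
#' sided; a feature is selected when p <= alpha. Kolmogorov-Smirnov
#' normality p-values (against a normal with the class sample mean and sd)
#' are reported per feature and class for information only -- they do not
#' gate selection.
#'
#' @param featureTable numeric matrix or data.frame, subjects x features.
#' @param labels character/factor vector of class labels, both classes
#'   present.
#' @param alpha significance level (default 0.05).
#' @return list of class "SelectionResult": pValues, normalityP (features x
#'   classes matrix), selected (logical), alpha.
#' @export
selectFeatures <- function(featureTable, labels, alpha = 0.05) {
  X <- as.matrix(featureTable)
  labels <- as.character(labels)
  if (nrow(X) != length(labels)) stop("labels must match table rows")
  cls <- unique(labels)
  if (length(cls) != 2L)
    stop("both classes must be present", call. = FALSE)
  if (nrow(X) < 4L) stop("need at least 4 subjects", call. = FALSE)
  pValues <- apply(X, 2, function(col) {
    stats::t.test(col[labels == cls[1]], col[labels == cls[2]],
                  var.equal = TRUE)$p.value
  })
  normalityP <- t(apply(X, 2, function(col) {
    vapply(cls, function(cl) {
      v <- col[labels == cl]
      if (stats::sd(v) == 0) return(NA_real_)
      suppressWarnings(
        stats::ks.test(v, "pnorm", mean = mean(v), sd = stats::sd(v))$p.value)
    }, numeric(1))
  }))
  colnames(normalityP) <- cls
  structure(list(pValues = pValues, normalityP = normalityP,
                 selected = pValues <= alpha, alpha = alpha),
            class = "SelectionResult")
}

#' @export
print.SelectionResult <- function(x, ...) {
  cat(sprintf("SelectionResult: %d/%d features selected at alpha = %g\n",
              sum(x$selected), length(x$selected), x$alpha))
  invisible(x)
}

#' Build a ConfusionSummary from counts or predictions
#'
#' @param tp,fp,tn,fn integer cell counts (positive class = at_risk).
#' @return A \linkS4class{ConfusionSummary}.
#' @export
confusionSummary <- function(tp, fp, tn, fn) {
  new("ConfusionSummary", tp = as.integer(tp), fp = as.integer(fp),
      tn = as.integer(tn), fn = as.integer(fn))
}

## Aggregate predicted vs true labels into a ConfusionSummary.
.confusionFromPredictions <- function(predicted, truth) {
  confusionSummary(
    tp = sum(predicted == "at_risk" & truth == "at_risk"),
    fp = sum(predicted == "at_risk" & truth == "no_risk"),
    tn = sum(predicted == "no_risk" & truth == "no_risk"),
    fn = sum(predicted == "no_risk" & truth == "at_risk"))
}

#' @rdname confusion
#' @aliases accuracy sensitivity specificity
#' @param x a \linkS4class{ConfusionSummary}.
setMethod("accuracy", "ConfusionSummary", function(x)
  (x@tp + x@tn) / (x@tp + x@tn + x@fp + x@fn))

#' @rdname confusion
setMethod("sensitivity", "ConfusionSummary", function(x) x@tp / (x@tp + x@fn))

#' @rdname confusion
setMethod("specificity", "ConfusionSummary", function(x) x@tn / (x@tn + x@fp))

setMethod("show", "ConfusionSummary", function(object) {
  cat(sprintf("ConfusionSummary (positive = at_risk): TP %d FP %d TN %d FN %d\n",
              object@tp, object@fp, object@tn, object@fn))
  cat(sprintf("  accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
              accuracy(object), sensitivity(object), specificity(object)))
})

#' Leave-one-out cross-validated linear discriminant analysis
#'
#' For each subject, a two-class LDA (shared covariance, empirical class
#' priors) is fitted on all remaining subjects and the held-out subject
#' predicted; predictions are aggregated into a single confusion matrix.
#'
#' @param featureTable numeric matrix/data.frame, subjects x selected
#'   features (k >= 1).
#' @param labels class labels ("at_risk" / "no_risk"), both present.
#' @return A \linkS4class{ConfusionSummary} over all n held-out predictions.
#' @export
loocvLda <- function(featureTable, labels) {
  X <- as.matrix(featureTable)
  labels <- as.character(labels)
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 subjects", call. = FALSE)
  if (length(unique(labels)) != 2L)
    stop("both classes must be present", call. = FALSE)
  if (ncol(X) < 1L) stop("need at least one feature", call. = FALSE)
  preds <- character(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- labels[-i]
    ## guard against a singular pooled covariance before calling lda
    pooled <- 0
    for (cl in unique(ytr)) {
      Xc <- scale(Xtr[ytr == cl, , drop = FALSE], scale = FALSE)
      pooled <- pooled + crossprod(Xc)
    }
    pooled <- pooled / (nrow(Xtr) - 2L)
    if (ncol(X) > 1L && rcond(pooled) < 1e-12 ||
        ncol(X) == 1L && pooled[1] <= 0)
      stop("pooled covariance is singular; reduce or decorrelate features",
           call. = FALSE)
    fit <- suppressWarnings(MASS::lda(Xtr, grouping = factor(ytr)))
    preds[i] <- as.character(
      stats::predict(fit, X[i, , drop = FALSE])$class)
  }
  .confusionFromPredictions(preds, labels)
}
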