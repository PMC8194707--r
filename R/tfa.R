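#' Build a complex Morlet wavelet
#'
#' The wavelet is A * exp(-t^2 / (2 sigmaT^2)) * exp(i 2 pi fc t) with the
#' frequency width tied to the central frequency by the constant ratio
#' fc / sigmaF = 7, sigmaT = 1 / (2 pi sigmaF), and A = (sigmaT sqrt(pi))^(-1/2)
#' so the continuous wavelet has unit energy. Samples cover a symmetric
#' support truncated at +/- \code{nSigma} * sigmaT (Gaussian tail < 1e-8 at
#' the default 6) at the trace sampling rate.
#'
#' @param fc central frequency in Hz (> 0).
#' @param samplingRate sampling rate in Hz; a warning is issued when it is
#'   not above the Nyquist requirement 2 * fc.
#' @param nSigma truncation half-width in units of sigmaT.
#' @return A \linkS4class{MorletWavelet}.
#' @examples
#' w <- buildMorlet(7, 45)
#' w@sigmaF            # 1
#' w@sigmaT * w@sigmaF # 1 / (2 * pi)
#' @export
buildMorlet <- function(fc, samplingRate, nSigma = 6) {
  .assertScalar(fc, "fc", positive = TRUE)
  .assertScalar(samplingRate, "samplingRate", positive = TRUE)
  if (samplingRate <= 2 * fc)
    warning(sprintf("samplingRate %g Hz is not above 2*fc = %g Hz; the wavelet is undersampled",
                    samplingRate, 2 * fc))
  sigmaF <- fc / 7
  sigmaT <- 1 / (2 * pi * sigmaF)
  A <- 1 / sqrt(sigmaT * sqrt(pi))
  n <- floor(nSigma * sigmaT * samplingRate)
  t <- (-n:n) / samplingRate
  samples <- A * exp(-t^2 / (2 * sigmaT^2)) * exp(1i * 2 * pi * fc * t)
  new("MorletWavelet", fc = fc, sigmaF = sigmaF, sigmaT = sigmaT, A = A,
      samples = samples, samplingRate = samplingRate)
}

setMethod("show", "MorletWavelet", function(object) {
  cat(sprintf("MorletWavelet fc = %g Hz (sigmaF = %.4g Hz, sigmaT = %.4g s, %d samples @ %g Hz)\n",
              object@fc, object@sigmaF, object@sigmaT,
              length(object@samples), object@samplingRate))
})

#' Linearly spaced frequency grid
#'
#' The default sweep covers 0.05-5 Hz, the band holding postural, gait and
#' arm-swing energy in TUG accelerometry, in 100 linear bins.
#'
#' @param fmin,fmax sweep endpoints in Hz, 0 < fmin < fmax.
#' @param nBins number of bins (>= 2); endpoints are included.
#' @return A \linkS4class{FrequencyGrid}.
#' @export
makeFrequencyGrid <- function(fmin = 0.05, fmax = 5, nBins = 100L) {
  .assertScalar(fmin, "fmin", positive = TRUE)
  .assertScalar(fmax, "fmax")
  if (fmin >= fmax) stop("need fmin < fmax", call. = FALSE)
  if (nBins < 2L) stop("need nBins >= 2", call. = FALSE)
  new("FrequencyGrid", frequencies = seq(fmin, fmax, length.out = nBins))
}

setMethod("show", "FrequencyGrid", function(object) {
  f <- object@frequencies
  cat(sprintf("FrequencyGrid: %d bins, %g-%g Hz\n", length(f), f[1], f[length(f)]))
})

## Frequency-domain wavelet bank, memoised on (grid, sampling rate, pad
## length): trace lengths across a cohort round up to the same power-of-two
## pad, so the 100 wavelet FFTs are shared across subjects.
.waveletBankCache <- new.env(parent = emptyenv())

.waveletBank <- function(freqs, samplingRate, T) {
  keyW <- paste(samplingRate, length(freqs),
                freqs[1], freqs[length(freqs)], sep = "_")
  wav <- .waveletBankCache[[keyW]]
  if (is.null(wav)) {
    samples <- lapply(freqs, function(fc)
      buildMorlet(fc, samplingRate)@samples)
    wav <- list(samples = samples,
                lengths = vapply(samples, length, integer(1)))
    rm(list = ls(.waveletBankCache), envir = .waveletBankCache)
    .waveletBankCache[[keyW]] <- wav
  }
  padN <- stats::nextn(T + max(wav$lengths) - 1L)
  keyF <- paste(keyW, padN, sep = "_")
  ffts <- .waveletBankCache[[keyF]]
  if (is.null(ffts)) {
    ffts <- lapply(wav$samples, function(s)
      stats::fft(c(s, rep(0, padN - length(s)))))
    .waveletBankCache[[keyF]] <- ffts
  }
  list(padN = padN, lengths = wav$lengths, ffts = ffts)
}

#' Complex-Morlet time-frequency transform
#'
#' For each grid frequency the signal is convolved with the complex Morlet
#' wavelet at that frequency ("same"-length alignment, zero padding at the
#' edges) and the squared modulus taken, giving the time-varying energy
#' E(t, fc). Convolutions are evaluated by FFT.
#'
#' @param signal numeric vector, one axis of a trace (finite, length >= 2).
#' @param samplingRate sampling rate in Hz.
#' @param grid a \linkS4class{FrequencyGrid}.
#' @return A \linkS4class{TFRepresentation} with one energy row per grid
#'   frequency.
#' @export
setMethod("tfTransform", signature(signal = "numeric"),
  function(signal, samplingRate, grid) {
    if (length(signal) < 2L) stop("signal must have length >= 2", call. = FALSE)
    if (any(!is.finite(signal)))
      stop("signal contains non-finite values", call. = FALSE)
    stopifnot(is(grid, "FrequencyGrid"))
    T <- length(signal)
    freqs <- grid@frequencies

    bank <- .waveletBank(freqs, samplingRate, T)
    padN <- bank$padN
    fSig <- stats::fft(c(signal, rep(0, padN - T)))

    energy <- matrix(0, nrow = length(freqs), ncol = T)
    for (k in seq_along(freqs)) {
      L <- bank$lengths[k]
      conv <- stats::fft(fSig * bank$ffts[[k]], inverse = TRUE) / padN
      ## centre T samples of the full linear convolution (L is odd)
      ctr <- conv[((L - 1L) %/% 2L) + seq_len(T)]
      energy[k, ] <- Mod(ctr)^2
    }
    ## squared modulus: clamp tiny negative rounding artefacts
    energy[energy < 0] <- 0
    new("TFRepresentation", energy = energy,
        timeAxis = (seq_len(T) - 1) / samplingRate, grid = grid)
  })

setMethod("show", "TFRepresentation", function(object) {
  f <- object@grid@frequencies
  cat(sprintf("TFRepresentation: %d frequencies x %d time points (%g-%g Hz, %.2f s)\n",
              nrow(object@energy), ncol(object@energy),
              f[1], f[length(f)], max(object@timeAxis)))
})

## Fixed rainbow-style colormap anchors (positions 0..1, RGB in [0,1]),
## kept as a constant so rendered images are bit-reproducible.
.TF_COLORMAP <- cbind(
  r = c(0.0, 0.0, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5),
  g = c(0.0, 0.0, 0.5, 1.0, 1.0, 1.0, 0.0, 0.0),
  b = c(0.5, 1.0, 1.0, 0.5, 0.0, 0.0, 0.0, 0.0)
)

#' @rdname renderImage
#' @export
tfColormap <- function() .TF_COLORMAP

## Map values in [0,1] to RGB by piecewise-linear interpolation between
## the colormap anchors. Returns a matrix with 3 columns.
.applyColormap <- function(v) {
  pos <- seq(0, 1, length.out = nrow(.TF_COLORMAP))
  cbind(
    stats::approx(pos, .TF_COLORMAP[, "r"], xout = v)$y,
    stats::approx(pos, .TF_COLORMAP[, "g"], xout = v)$y,
    stats::approx(pos, .TF_COLORMAP[, "b"], xout = v)$y
  )
}

## Separable bilinear resampling of a matrix to nr x nc, endpoints mapped
## to endpoints, expressed as two interpolation-weight matmuls.
.bilinearWeights <- function(nSrc, nDst) {
  W <- matrix(0, nDst, nSrc)
  if (nSrc == 1L) { W[, 1] <- 1; return(W) }
  src <- seq(0, 1, length.out = nSrc)
  dst <- seq(0, 1, length.out = nDst)
  for (i in seq_len(nDst)) {
    j <- findInterval(dst[i], src, rightmost.closed = TRUE)
    j <- min(max(j, 1L), nSrc - 1L)
    a <- (dst[i] - src[j]) / (src[j + 1] - src[j])
    W[i, j] <- 1 - a
    W[i, j + 1] <- a
  }
  W
}

.resizeBilinear <- function(m, nr, nc) {
  .bilinearWeights(nrow(m), nr) %*% m %*% t(.bilinearWeights(ncol(m), nc))
}

#' Render a time-frequency representation as a fixed-size color image
#'
#' The energy matrix is min-max normalized to [0, 1] (per image by default,
#' or against a fixed global range), mapped through a fixed rainbow-style
#' colormap to three channels, and bilinearly resampled to
#' \code{height} x \code{width}: the time axis maps to the image width (so
#' traces of different TUG durations all yield images of the same size) and
#' the frequency axis to the height, with the lowest frequency at the
#' bottom row. An all-constant energy matrix maps to the colormap's lowest
#' color.
#'
#' @param tfr a \linkS4class{TFRepresentation}.
#' @param height,width output size in pixels (default 28 x 28, the
#'   2,352-value input the classifier consumes).
#' @param normalize "image" (per-image min-max) or "global" (use
#'   \code{globalRange}).
#' @param globalRange numeric(2) energy range used when
#'   \code{normalize = "global"}.
#' @param sourceAxis optional axis tag stored in the image.
#' @return A \linkS4class{TFImage}.
#' @export
setMethod("renderImage", "TFRepresentation",
  function(tfr, height = 28L, width = 28L, normalize = c("image", "global"),
           globalRange = NULL, sourceAxis = NA_character_) {
    normalize <- match.arg(normalize)
    E <- tfr@energy
    if (normalize == "image") {
      lo <- min(E); hi <- max(E)
    } else {
      if (is.null(globalRange) || length(globalRange) != 2L)
        stop("globalRange must be numeric(2) when normalize = 'global'")
      lo <- globalRange[1]; hi <- globalRange[2]
    }
    v <- if (hi > lo) (E - lo) / (hi - lo) else E * 0
    v[v < 0] <- 0; v[v > 1] <- 1
    ## colormap first, then resample: channel-wise bilinear reduction of
    ## the colormapped array
    rgb <- .applyColormap(as.vector(v))
    pix <- array(0, dim = c(height, width, 3L))
    for (ch in 1:3) {
      M <- matrix(rgb[, ch], nrow = nrow(E))
      M <- M[rev(seq_len(nrow(M))), , drop = FALSE]  # low freq -> bottom row
      pix[, , ch] <- .resizeBilinear(M, height, width)
    }
    pix[pix < 0] <- 0; pix[pix > 1] <- 1
    new("TFImage", pixels = pix, sourceAxis = as.character(sourceAxis))
  })

setMethod("show", "TFImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("TFImage %d x %d x 3 (axis %s), values in [%.3f, %.3f]\n",
              d[1], d[2], object@sourceAxis,
              min(object@pixels), max(object@pixels)))
})

#' Flatten a TFImage to the classifier's input vector
#'
#' Column-major flattening of the H x W x 3 array, length H*W*3 (2,352 at
#' the 28 x 28 default).
#'
#' @param image a \linkS4class{TFImage}.
#' @return numeric vector in [0, 1].
#' @export
flattenImage <- function(image) {
  stopifnot(is(image, "TFImage"))
  as.vector(image@pixels)
}

#' Transform every subject of a cohort on one axis into flattened images
#'
#' Convenience wrapper running \code{\link{tfTransform}} and
#' \code{\link{renderImage}} per subject and stacking the flattened pixel
#' vectors into a matrix with one row per subject.
#'
#' @param cohort a \linkS4class{TugCohort}.
#' @param axis "v", "ml" or "ap".
#' @param grid a \linkS4class{FrequencyGrid}.
#' @param height,width image size.
#' @return n x (height*width*3) numeric matrix, rownames = subject ids.
#' @export
cohortToImages <- function(cohort, axis = c("v", "ml", "ap"),
                           grid = makeFrequencyGrid(),
                           height = 28L, width = 28L) {
  axis <- match.arg(axis)
  stopifnot(is(cohort, "TugCohort"))
  imgs <- t(vapply(cohort@subjects, function(s) {
    tfr <- tfTransform(s@trace[axis, ], s@samplingRate, grid)
    flattenImage(renderImage(tfr, height, width, sourceAxis = axis))
  }, numeric(height * width * 3L)))
  rownames(imgs) <- subjectIds(cohort)
  imgs
}

#' Write a TFImage as an 8-bit PNG
#'
#' The numeric [0, 1] array remains the classifier input; the PNG is a
#' visualization artifact.
#'
#' @param image a \linkS4class{TFImage}.
#' @param path output file path.
#' @export
writeTFImagePNG <- function(image, path) {
  stopifnot(is(image, "TFImage"))
  png::writePNG(image@pixels, target = path)
  invisible(path)
}

#' Write a TFRepresentation as a CSV matrix
#'
#' One row per frequency (column \code{frequency_hz} first, then one column
#' per time point labelled with its time in seconds).
#'
#' @param tfr a \linkS4class{TFRepresentation}.
#' @param path output file path.
#' @export
writeTFRepresentation <- function(tfr, path) {
  stopifnot(is(tfr, "TFRepresentation"))
  df <- data.frame(frequency_hz = tfr@grid@frequencies, tfr@energy)
  names(df)[-1] <- sprintf("t%.6f", tfr@timeAxis)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
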