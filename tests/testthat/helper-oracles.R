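## Independent brute-force oracles used across tests. These deliberately
## avoid the package's own vectorized code paths.

## Feature oracle: plain loops over the definition of each statistic.
oracleFeatures <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  ss <- 0
  for (xi in x) ss <- ss + (xi - m)^2
  cross <- 0
  for (i in 1:(n - 1)) {
    if ((x[i] - m) * (x[i + 1] - m) < 0) cross <- cross + 1
  }
  c(mean = m, std = sqrt(ss / (n - 1)), max = max(x), min = min(x),
    mcr = cross / (n - 1))
}

## Direct O(T * L) time-domain convolution with 'same' alignment, zero
## padded: independent of the FFT path used by tfTransform.
oracleMorletEnergy <- function(signal, fc, fs) {
  sigmaF <- fc / 7
  sigmaT <- 1 / (2 * pi * sigmaF)
  A <- 1 / sqrt(sigmaT * sqrt(pi))
  n <- floor(6 * sigmaT * fs)
  tw <- (-n:n) / fs
  w <- A * exp(-tw^2 / (2 * sigmaT^2)) * exp(1i * 2 * pi * fc * tw)
  T <- length(signal)
  L <- length(w)
  out <- complex(T)
  half <- (L - 1) / 2
  for (t in 1:T) {
    acc <- 0 + 0i
    for (k in 1:L) {
      j <- t + half - k + 1   # full-convolution index shifted to 'same'
      if (j >= 1 && j <= T) acc <- acc + w[k] * signal[j]
    }
    out[t] <- acc
  }
  Mod(out)^2
}

## Periodogram band power via a plain DFT loop (no fft), mean over the
## requested frequency band.
oracleBandPower <- function(x, fs, flo, fhi) {
  T <- length(x)
  x <- x - mean(x)
  freqs <- (0:(T - 1)) * fs / T
  keep <- which(freqs >= flo & freqs <= fhi)
  p <- 0
  tt <- 0:(T - 1)
  for (k in keep) {
    ck <- sum(x * exp(-2i * pi * (k - 1) * tt / T))
    p <- p + Mod(ck)^2 / T
  }
  p / length(keep)
}

## Toy image set: smooth random low-rank patterns in [0,1], n x d.
toyImages <- function(n, d, seed) {
  set.seed(seed)
  U <- matrix(rnorm(n * 3), n, 3)
  V <- matrix(rnorm(3 * d), 3, d)
  M <- U %*% V
  (M - min(M)) / (max(M) - min(M))
}

## Two linearly separable "image" classes: class mean shift on half the
## pixels plus small noise, values kept inside [0,1].
separableImages <- function(nPerClass, d, shift = 0.4, noise = 0.03,
                            seed = 1) {
  set.seed(seed)
  n <- 2 * nPerClass
  base <- matrix(runif(n * d, 0.2, 0.4), n, d)
  lab <- rep(c("at_risk", "no_risk"), each = nPerClass)
  idx <- seq_len(d %/% 2)
  base[lab == "no_risk", idx] <- base[lab == "no_risk", idx] + shift
  base <- base + matrix(rnorm(n * d, 0, noise), n, d)
  base[base < 0] <- 0; base[base > 1] <- 1
  list(images = base, labels = lab)
}

## Hyperparameters proportionate to toy problem sizes: the defaults target
## 2,352-pixel images, where the pixel-summed reconstruction term dwarfs
## the sparsity term; on 20-40-dimensional toys that balance inverts.
toyHyper <- function() saeHyper(lambda1 = 1e-4, lambda2 = 1e-4, beta = 1,
                                rho1 = 0.1, rho2 = 0.1)

quietCohort <- function(nPerClass = 3L, seed = 7L, ...) {
  generateCohort(generatorConfig(nPerClass = as.integer(nPerClass),
                                 seed = as.integer(seed), ...))
}
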