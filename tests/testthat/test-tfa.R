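test_that("Morlet wavelet satisfies its resolution identities", {
  w <- buildMorlet(7, 45)
  expect_equal(w@sigmaF, 1)
  expect_equal(w@sigmaT, 1 / (2 * pi), tolerance = 1e-12)

  w2 <- buildMorlet(0.05, 45)
  expect_equal(w2@sigmaT * w2@sigmaF, 1 / (2 * pi), tolerance = 1e-12)

  expect_error(buildMorlet(0, 45), "positive")
  expect_warning(buildMorlet(30, 45), "undersampled")
})

test_that("normalization gives the sampled wavelet unit energy", {
  w <- buildMorlet(2, 45)
  # trapezoidal integration of |w|^2 over the +/- 6 sigmaT support
  y <- Mod(w@samples)^2
  dt <- 1 / w@samplingRate
  energy <- sum((y[-1] + y[-length(y)]) / 2) * dt
  expect_equal(energy, 1, tolerance = 0.01)
})

test_that("frequency grids are linear with included endpoints", {
  g <- makeFrequencyGrid(0.05, 5, 100L)
  f <- g@frequencies
  expect_length(f, 100L)
  expect_equal(f[1], 0.05)
  expect_equal(f[100], 5)
  expect_equal(diff(f), rep(diff(f)[1], 99))

  g2 <- makeFrequencyGrid(1, 1.0001, 2L)
  expect_length(g2@frequencies, 2L)

  expect_error(makeFrequencyGrid(5, 0.05, 10L), "fmin < fmax")
  expect_error(makeFrequencyGrid(0.05, 5, 1L), "nBins")
})

test_that("transform of the zero signal is the zero energy matrix", {
  g <- makeFrequencyGrid(nBins = 10L)
  tfr <- tfTransform(rep(0, 200), 45, g)
  expect_equal(dim(tfr@energy), c(10L, 200L))
  expect_true(all(tfr@energy == 0))
})

test_that("transform rejects degenerate input", {
  g <- makeFrequencyGrid(nBins = 5L)
  expect_error(tfTransform(c(1, NA, 2), 45, g), "finite")
  expect_error(tfTransform(1, 45, g), "length")
})

test_that("FFT-based transform matches direct time-domain convolution", {
  set.seed(5)
  fs <- 45
  sig <- sin(2 * pi * 2 * (0:199) / fs) + 0.1 * rnorm(200)
  g <- makeFrequencyGrid(1, 3, 5L)
  tfr <- tfTransform(sig, fs, g)
  for (k in c(1L, 3L, 5L)) {
    direct <- oracleMorletEnergy(sig, g@frequencies[k], fs)
    expect_equal(tfr@energy[k, ], direct, tolerance = 1e-8)
  }
})

test_that("a pure sinusoid is localized at the nearest grid bin", {
  fs <- 45
  tt <- (0:899) / fs                      # 20 s
  g <- makeFrequencyGrid(0.05, 5, 100L)
  sig <- sin(2 * pi * 2.0 * tt)
  tfr <- tfTransform(sig, fs, g)
  peak <- which.max(rowMeans(tfr@energy))
  expect_lte(abs(peak - which.min(abs(g@frequencies - 2.0))), 1L)
})

test_that("energy scales with the square of the signal amplitude", {
  set.seed(8)
  sig <- rnorm(150)
  g <- makeFrequencyGrid(nBins = 8L)
  e1 <- tfTransform(sig, 45, g)@energy
  e3 <- tfTransform(3 * sig, 45, g)@energy
  expect_equal(e3, 9 * e1, tolerance = 1e-10)
})

test_that("rendered images have the contracted geometry and range", {
  co <- quietCohort(nPerClass = 1L, seed = 17L)
  tfr <- tfTransform(co[[1]]@trace["v", ], 45, makeFrequencyGrid(nBins = 40L))
  img <- renderImage(tfr, sourceAxis = "v")
  expect_equal(dim(img@pixels), c(28L, 28L, 3L))
  expect_length(flattenImage(img), 2352L)
  expect_true(all(img@pixels >= 0 & img@pixels <= 1))
})

test_that("all-constant energy renders as the colormap's lowest color", {
  g <- makeFrequencyGrid(nBins = 6L)
  tfr <- tfTransform(rep(0, 100), 45, g)
  img <- renderImage(tfr, height = 5L, width = 5L)
  cm <- tfColormap()
  for (ch in 1:3)
    expect_true(all(abs(img@pixels[, , ch] - cm[1, ch]) < 1e-12))
})

test_that("rendering agrees with direct per-pixel colormap evaluation", {
  # energy already at target size: resampling is the identity, so the
  # image must equal the colormap applied pixel by pixel (rows flipped so
  # low frequency sits at the bottom)
  set.seed(2)
  H <- 9L; W <- 11L
  E <- matrix(runif(H * W), H, W)
  g <- new("FrequencyGrid", frequencies = seq(0.5, 3, length.out = H))
  tfr <- new("TFRepresentation", energy = E,
             timeAxis = (seq_len(W) - 1) / 45, grid = g)
  img <- renderImage(tfr, height = H, width = W)
  v <- (E - min(E)) / (max(E) - min(E))
  pos <- seq(0, 1, length.out = nrow(tfColormap()))
  for (ch in 1:3) {
    direct <- matrix(approx(pos, tfColormap()[, ch], xout = as.vector(v))$y, H, W)
    expect_equal(img@pixels[, , ch], direct[rev(seq_len(H)), ],
                 tolerance = 1e-12)
  }
})

test_that("low frequencies map to the bottom image rows", {
  # energy concentrated in the lowest-frequency row must light up the
  # bottom of the image, not the top
  H <- 8L; W <- 8L
  E <- matrix(0, H, W); E[1, ] <- 1    # row 1 = lowest frequency
  g <- new("FrequencyGrid", frequencies = seq(1, 2, length.out = H))
  tfr <- new("TFRepresentation", energy = E,
             timeAxis = (seq_len(W) - 1) / 45, grid = g)
  img <- renderImage(tfr, height = H, width = W)
  # red channel: colormap top color is warm, bottom color is cold
  expect_gt(mean(img@pixels[H, , 1]), mean(img@pixels[1, , 1]))
})

test_that("resolution identity holds across the default grid", {
  g <- makeFrequencyGrid()
  for (fc in g@frequencies[c(1, 25, 50, 100)]) {
    w <- suppressWarnings(buildMorlet(fc, 45))
    expect_equal(w@sigmaT * w@sigmaF, 1 / (2 * pi), tolerance = 1e-12)
  }
})
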