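test_that("encode and decode apply the logistic layer maps exactly", {
  l <- initAutoencoderLayer(6, 4, seed = 2L)
  zeroL <- initialize(l, W1 = matrix(0, 4, 6), b1 = rep(0, 4))
  expect_equal(encode(zeroL, runif(6)), rep(0.5, 4))    # sigmoid(0)

  set.seed(3)
  X <- matrix(runif(5 * 6), 5, 6)
  Z <- encode(l, X)
  # hand-rolled oracle: explicit matrix multiply + sigmoid
  for (i in 1:5) {
    want <- 1 / (1 + exp(-(l@W1 %*% X[i, ] + l@b1)))
    expect_equal(Z[i, ], as.vector(want), tolerance = 1e-12)
  }
  Xh <- decode(l, Z)
  expect_equal(dim(Xh), dim(X))
  expect_true(all(Z > 0 & Z < 1) && all(Xh > 0 & Xh < 1))
  expect_error(encode(l, runif(5)), "dimension")
})

test_that("mean activation is the example-wise mean of the codes", {
  l <- initAutoencoderLayer(4, 3, seed = 5L)
  x <- runif(4)
  expect_equal(meanActivation(l, matrix(x, 1)), encode(l, x))

  set.seed(6)
  X <- matrix(runif(7 * 4), 7, 4)
  got <- meanActivation(l, X)
  want <- rep(0, 3)
  for (j in 1:7) want <- want + encode(l, X[j, ])
  expect_equal(got, want / 7, tolerance = 1e-14)
})

test_that("KL sparsity penalty is zero at rho and positive elsewhere", {
  expect_equal(sparsityPenalty(rep(0.015, 10), 0.015), 0)
  # d = 1, rho = 0.5, pHat = 0.25: direct scalar arithmetic
  want <- 0.5 * log(0.5 / 0.25) + 0.5 * log(0.5 / 0.75)
  expect_equal(sparsityPenalty(0.25, 0.5), want, tolerance = 1e-14)
  expect_gt(sparsityPenalty(c(0.1, 0.3), 0.2), 0)
  expect_error(sparsityPenalty(c(0.2, 1), 0.2), "strictly")
  expect_error(sparsityPenalty(0, 0.2), "strictly")
})

test_that("KL penalty is locally convex in each mean activation", {
  rho <- 0.015
  for (p0 in c(0.01, 0.015, 0.05)) {
    h <- 1e-4
    d2 <- (sparsityPenalty(p0 + h, rho) - 2 * sparsityPenalty(p0, rho) +
           sparsityPenalty(p0 - h, rho)) / h^2
    expect_gt(d2, 0)
  }
})

test_that("L2 penalty is half the sum of squared weights", {
  l <- initAutoencoderLayer(5, 3, seed = 9L)
  z <- initialize(l, W1 = matrix(0, 3, 5), W2 = matrix(0, 5, 3))
  expect_equal(l2Penalty(z), 0)
  one <- initialize(z, W1 = matrix(c(2, rep(0, 14)), 3, 5))
  expect_equal(l2Penalty(one), 2)      # 0.5 * 2^2
  # loop oracle
  acc <- 0
  for (w in as.vector(l@W1)) acc <- acc + w * w
  for (w in as.vector(l@W2)) acc <- acc + w * w
  expect_equal(l2Penalty(l), acc / 2, tolerance = 1e-12)
})

test_that("cost reduces to reconstruction MSE when both penalties are off", {
  set.seed(11)
  l <- initAutoencoderLayer(6, 4, lambda = 0, beta = 0, seed = 12L)
  X <- matrix(runif(5 * 6), 5, 6)
  r <- aeCost(l, X)
  mse <- 0
  for (i in 1:5) mse <- mse + sum((X[i, ] - decode(l, encode(l, X[i, ])))^2)
  expect_equal(r$cost, mse / 5, tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  set.seed(13)
  l <- initAutoencoderLayer(6, 4, lambda = 0.01, beta = 3, rho = 0.2,
                            seed = 14L)
  X <- matrix(runif(5 * 6), 5, 6)
  r <- aeCost(l, X)
  ana <- c(as.vector(r$gradW1), r$gradB1, as.vector(r$gradW2), r$gradB2)
  par <- c(as.vector(l@W1), l@b1, as.vector(l@W2), l@b2)
  rebuild <- function(p) {
    W1 <- matrix(p[1:24], 4, 6); b1 <- p[25:28]
    W2 <- matrix(p[29:52], 6, 4); b2 <- p[53:58]
    initialize(l, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  }
  h <- 1e-6
  idx <- seq(1, length(par), by = 3)   # every third coordinate
  for (k in idx) {
    p1 <- par; p2 <- par
    p1[k] <- p1[k] - h; p2[k] <- p2[k] + h
    num <- (aeCost(rebuild(p2), X)$cost - aeCost(rebuild(p1), X)$cost) / (2 * h)
    expect_lt(abs(ana[k] - num) / max(abs(num), 1e-8), 1e-6)
  }
})

test_that("training decreases the cost and is seed-deterministic", {
  imgs <- toyImages(30, 40, seed = 21)
  cfg <- trainConfig(maxIterations = 60L, seed = 33L)
  l <- trainAutoencoder(imgs, 8L, lambda = 0.004, beta = 1, rho = 0.05,
                        config = cfg)
  init <- initAutoencoderLayer(40, 8, 0.004, 1, 0.05, seed = 33L)
  expect_lt(aeCost(l, imgs)$cost, aeCost(init, imgs)$cost)
  expect_lt(aeCost(l, imgs)$mse, aeCost(init, imgs)$mse)

  l2 <- trainAutoencoder(imgs, 8L, lambda = 0.004, beta = 1, rho = 0.05,
                         config = cfg)
  expect_identical(l@W1, l2@W1)
  expect_identical(l@b2, l2@b2)
})

test_that("large weight decay drives trained weights toward zero", {
  imgs <- toyImages(20, 20, seed = 25)
  small <- trainAutoencoder(imgs, 4L, lambda = 1e-4, beta = 0, rho = 0.05,
                            config = trainConfig(maxIterations = 50L, seed = 3L))
  big <- trainAutoencoder(imgs, 4L, lambda = 100, beta = 0, rho = 0.05,
                          config = trainConfig(maxIterations = 50L, seed = 3L))
  expect_lt(sum(big@W1^2) + sum(big@W2^2),
            0.1 * (sum(small@W1^2) + sum(small@W2^2)))
})

test_that("a one-unit autoencoder recovers a one-dimensional input family", {
  # inputs lie on a logistic curve parameterized by a single latent value,
  # so a 1-hidden-unit AE should reconstruct far below the data variance;
  # the oracle fits the best single-logistic reconstruction directly
  set.seed(41)
  n <- 30; d <- 12
  lat <- seq(-2, 2, length.out = n)
  W2true <- seq(-1, 1, length.out = d)
  X <- t(vapply(lat, function(z) 1 / (1 + exp(-(W2true * z))), numeric(d)))
  l <- trainAutoencoder(X, 1L, lambda = 0, beta = 0, rho = 0.5,
                        config = trainConfig(maxIterations = 300L, seed = 8L))
  mseTrained <- aeCost(l, X)$mse
  dataVar <- sum(scale(X, scale = FALSE)^2) / n
  expect_lt(mseTrained, 0.1 * dataVar)
})

test_that("sparsity pressure pulls mean activations toward the target", {
  imgs <- toyImages(25, 30, seed = 61)
  rho <- 0.05
  dev <- sapply(c(0, 4), function(b) {
    mean(sapply(1:5, function(s) {
      l <- trainAutoencoder(imgs, 6L, lambda = 0.002, beta = b, rho = rho,
                            config = trainConfig(maxIterations = 80L,
                                                 seed = 100L + s))
      mean(abs(meanActivation(l, imgs) - rho))
    }))
  })
  expect_lt(dev[2], dev[1])
})

test_that("the stacked classifier emits normalized probabilities and fits a separable set", {
  sep <- separableImages(8, 30, seed = 71)
  cfg <- trainConfig(maxIterations = 30L, softmaxIterations = 50L,
                     fineTuneIterations = 30L, seed = 5L)
  m <- buildAndTrainSae(sep$images, sep$labels, n1 = 10L, n2 = 4L,
                        hyper = toyHyper(), config = cfg)
  expect_equal(mean(predict(m, sep$images) == sep$labels), 1.0)

  set.seed(9)
  P <- predict(m, matrix(runif(100 * 30), 100, 30), type = "prob")
  expect_equal(rowSums(P), rep(1, 100), tolerance = 1e-12)
  expect_error(buildAndTrainSae(sep$images, rep("at_risk", 16)), "both classes")
})

test_that("supervised fine-tuning does not hurt the training fit", {
  sep <- separableImages(6, 25, shift = 0.25, noise = 0.08, seed = 81)
  base <- trainConfig(maxIterations = 20L, softmaxIterations = 40L,
                      fineTuneIterations = 0L, validationFraction = 0,
                      seed = 7L)
  tuned <- initialize(base, fineTuneIterations = 40L)
  mBase <- buildAndTrainSae(sep$images, sep$labels, n1 = 8L, n2 = 3L,
                            hyper = toyHyper(), config = base)
  mTuned <- buildAndTrainSae(sep$images, sep$labels, n1 = 8L, n2 = 3L,
                             hyper = toyHyper(), config = tuned)
  ce <- function(m) {
    P <- predict(m, sep$images, type = "prob")
    y <- cbind(sep$labels == "at_risk", sep$labels == "no_risk")
    -mean(log(P[y] + 1e-12))
  }
  expect_lte(ce(mTuned), ce(mBase) + 1e-8)
})

test_that("grid search averages seeded runs and reports the true argmin", {
  imgs <- toyImages(12, 25, seed = 91)
  cfg <- trainConfig(maxIterations = 15L, seed = 17L)
  gs <- gridSearch(imgs, n1Values = c(4L, 6L), n2Values = c(2L, 3L),
                   runs = 2L, hyper = toyHyper(), config = cfg)
  expect_equal(dim(gs@mseTable), c(2L, 2L))
  b <- gs@bestPair
  expect_equal(gs@mseTable[as.character(b["n1"]), as.character(b["n2"])],
               min(gs@mseTable))
  gs2 <- gridSearch(imgs, n1Values = c(4L, 6L), n2Values = c(2L, 3L),
                    runs = 2L, hyper = toyHyper(), config = cfg)
  expect_identical(gs@mseTable, gs2@mseTable)
})

test_that("SAE models round-trip through serialization", {
  sep <- separableImages(5, 20, seed = 95)
  cfg <- trainConfig(maxIterations = 10L, softmaxIterations = 20L,
                     fineTuneIterations = 10L, seed = 3L)
  m <- buildAndTrainSae(sep$images, sep$labels, n1 = 6L, n2 = 3L,
                        hyper = toyHyper(), config = cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  saveSAE(m, path)
  m2 <- loadSAE(path)
  expect_identical(predict(m, sep$images, type = "prob"),
                   predict(m2, sep$images, type = "prob"))
})
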