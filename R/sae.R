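## Sparse autoencoder: encoder z = sigmoid(W1 x + b1), decoder
## xhat = sigmoid(W2 z + b2), trained by minimizing
##   E = (1/N) sum_n sum_k (x_kn - xhat_kn)^2
##       + lambda * 0.5 * (||W1||^2 + ||W2||^2)
##       + beta * sum_i KL(rho || rhoHat_i)
## with rhoHat_i the mean activation of hidden neuron i over the batch.
## All training is deterministic full-batch quasi-Newton (L-BFGS-B).

## Mean activations are clipped away from 0/1 inside the KL term; logistic
## outputs can saturate in finite precision.
.RHO_CLIP <- 1e-6

#' Create an autoencoder layer with seeded random initialization
#'
#' Weights are drawn from a symmetric uniform scaled by fan-in/fan-out
#' (range +/- sqrt(6 / (dIn + dHidden))); biases start at zero.
#'
#' @param dIn input dimension.
#' @param dHidden hidden dimension.
#' @param lambda L2 weight-decay coefficient.
#' @param beta sparsity-penalty coefficient.
#' @param rho target mean activation (sparsity proportion), in (0, 1).
#' @param seed integer seed.
#' @return An \linkS4class{AutoencoderLayer}.
#' @export
initAutoencoderLayer <- function(dIn, dHidden, lambda = 0, beta = 0,
                                 rho = 0.05, seed = 1L) {
  r <- sqrt(6 / (dIn + dHidden))
  .withSeed(seed, {
    W1 <- matrix(stats::runif(dHidden * dIn, -r, r), dHidden, dIn)
    W2 <- matrix(stats::runif(dIn * dHidden, -r, r), dIn, dHidden)
    new("AutoencoderLayer", W1 = W1, b1 = numeric(dHidden),
        W2 = W2, b2 = numeric(dIn),
        lambda = lambda, beta = beta, rho = rho)
  })
}

setMethod("show", "AutoencoderLayer", function(object) {
  cat(sprintf("AutoencoderLayer %d -> %d (lambda = %g, beta = %g, rho = %g)\n",
              ncol(object@W1), nrow(object@W1),
              object@lambda, object@beta, object@rho))
})

## Accept examples as rows (n x d) and transpose to the internal d x n
## column layout; single vectors pass through as one column.
.asColumns <- function(x, d) {
  if (is.null(dim(x))) {
    if (length(x) != d) stop("input length does not match layer dimension",
                             call. = FALSE)
    return(matrix(x, ncol = 1))
  }
  if (ncol(x) != d) stop("input dimension does not match layer", call. = FALSE)
  t(x)
}

#' Encode / decode through one autoencoder layer
#'
#' \code{encode} applies z = sigmoid(W1 x + b1); \code{decode} applies
#' xhat = sigmoid(W2 z + b2). Inputs may be a single vector or a matrix
#' with one example per row; outputs match that shape.
#'
#' @param layer an \linkS4class{AutoencoderLayer}.
#' @param x input vector (length dIn) or n x dIn matrix.
#' @param z code vector (length dHidden) or n x dHidden matrix.
#' @return Activations in (0, 1), same orientation as the input.
#' @name encode
#' @export
setMethod("encode", "AutoencoderLayer", function(layer, x) {
  X <- .asColumns(x, ncol(layer@W1))
  Z <- .sigmoid(layer@W1 %*% X + layer@b1)
  if (is.null(dim(x))) as.vector(Z) else t(Z)
})

#' @rdname encode
#' @export
setMethod("decode", "AutoencoderLayer", function(layer, z) {
  Z <- .asColumns(z, nrow(layer@W1))
  Xh <- .sigmoid(layer@W2 %*% Z + layer@b2)
  if (is.null(dim(z))) as.vector(Xh) else t(Xh)
})

#' Mean hidden activation over a batch of examples
#'
#' rhoHat_i = (1/n) sum_j z_i(x_j), the average output activation of each
#' hidden neuron over the n examples.
#'
#' @param layer an \linkS4class{AutoencoderLayer}.
#' @param inputs n x dIn matrix (or a single input vector).
#' @return numeric(dHidden) with entries in (0, 1).
#' @export
meanActivation <- function(layer, inputs) {
  X <- .asColumns(inputs, ncol(layer@W1))
  if (ncol(X) < 1L) stop("need at least one example", call. = FALSE)
  rowMeans(.sigmoid(layer@W1 %*% X + layer@b1))
}

#' Kullback-Leibler sparsity penalty
#'
#' sum_i [ rho log(rho / rhoHat_i) + (1 - rho) log((1 - rho) / (1 - rhoHat_i)) ].
#' Non-negative, and zero exactly when every rhoHat_i equals rho.
#'
#' @param pHat mean activations, strictly inside (0, 1).
#' @param rho target sparsity proportion in (0, 1).
#' @return scalar penalty.
#' @export
sparsityPenalty <- function(pHat, rho) {
  if (any(pHat <= 0) || any(pHat >= 1))
    stop("mean activations must lie strictly in (0, 1)", call. = FALSE)
  if (rho <= 0 || rho >= 1) stop("rho must lie in (0, 1)", call. = FALSE)
  sum(rho * log(rho / pHat) + (1 - rho) * log((1 - rho) / (1 - pHat)))
}

#' L2 weight penalty of one layer
#'
#' Half the sum of squares over the encoder and decoder weight matrices;
#' biases are excluded.
#'
#' @param layer an \linkS4class{AutoencoderLayer}.
#' @return scalar penalty.
#' @export
l2Penalty <- function(layer) {
  0.5 * (sum(layer@W1^2) + sum(layer@W2^2))
}

## Flatten / unflatten layer parameters for the optimizer.
.layerToPar <- function(layer)
  c(as.vector(layer@W1), layer@b1, as.vector(layer@W2), layer@b2)

.parToLayer <- function(par, template) {
  dH <- nrow(template@W1); dI <- ncol(template@W1)
  i <- 0L
  W1 <- matrix(par[i + seq_len(dH * dI)], dH, dI); i <- i + dH * dI
  b1 <- par[i + seq_len(dH)]; i <- i + dH
  W2 <- matrix(par[i + seq_len(dI * dH)], dI, dH); i <- i + dI * dH
  b2 <- par[i + seq_len(dI)]
  initialize(template, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

## Core cost + gradient on the internal d x n layout, evaluated by the
## compiled kernel; par layout matches .layerToPar.
.aeFlat <- function(par, X, lambda, beta, rho, dH)
  aeCostGradCpp(par, X, lambda, beta, rho, dH)

#' Composite autoencoder cost and analytic gradients
#'
#' Evaluates the training cost -- reconstruction mean squared error (summed
#' over features, averaged over examples) plus L2 and KL-sparsity
#' penalties -- together with backpropagated gradients for all weights and
#' biases, including the sparsity term's dependence on the batch mean
#' activations.
#'
#' @param layer an \linkS4class{AutoencoderLayer}.
#' @param inputs n x dIn matrix of examples in [0, 1].
#' @return list: cost, mse, kl, and gradients (gradW1, gradB1, gradW2,
#'   gradB2).
#' @export
aeCost <- function(layer, inputs) {
  X <- .asColumns(inputs, ncol(layer@W1))
  dH <- nrow(layer@W1); dI <- ncol(layer@W1)
  r <- .aeFlat(.layerToPar(layer), X, layer@lambda, layer@beta, layer@rho, dH)
  g <- r$grad
  i <- 0L
  gW1 <- matrix(g[i + seq_len(dH * dI)], dH, dI); i <- i + dH * dI
  gb1 <- g[i + seq_len(dH)]; i <- i + dH
  gW2 <- matrix(g[i + seq_len(dI * dH)], dI, dH); i <- i + dI * dH
  gb2 <- g[i + seq_len(dI)]
  list(cost = r$cost, mse = r$mse, kl = r$kl,
       gradW1 = gW1, gradB1 = gb1, gradW2 = gW2, gradB2 = gb2)
}

#' Training configuration
#'
#' @param maxIterations unsupervised iteration cap per layer (default 400).
#' @param softmaxIterations iteration cap for the softmax-head fit.
#' @param fineTuneIterations iteration cap for supervised fine-tuning of
#'   the full encoder stack (default 100; 0 disables fine-tuning).
#' @param optimizer stats::optim method (default "L-BFGS-B").
#' @param convergenceTol projected-gradient tolerance.
#' @param fineTuneDecay L2 weight decay applied to the two encoder weight
#'   matrices during supervised fine-tuning (the softmax weights stay
#'   unregularized); 0 disables it.
#' @param validationFraction fraction of training examples held out
#'   (stratified by class, seeded) to early-stop fine-tuning on validation
#'   cross-entropy; 0 disables early stopping and fine-tunes on all
#'   examples for the full iteration budget.
#' @param patience consecutive non-improving validation checks tolerated
#'   before stopping (checks happen every few iterations).
#' @param seed integer seed for weight initialization.
#' @return A \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(maxIterations = 400L, softmaxIterations = 100L,
                        fineTuneIterations = 100L, optimizer = "L-BFGS-B",
                        convergenceTol = 1e-8, fineTuneDecay = 0,
                        validationFraction = 0, patience = 3L, seed = 1L) {
  new("TrainConfig", maxIterations = as.integer(maxIterations),
      softmaxIterations = as.integer(softmaxIterations),
      fineTuneIterations = as.integer(fineTuneIterations),
      optimizer = optimizer, convergenceTol = convergenceTol,
      fineTuneDecay = fineTuneDecay,
      validationFraction = validationFraction, patience = as.integer(patience),
      seed = as.integer(seed))
}

## Run optim with a shared fn/gr evaluation cache. The L-BFGS-B driver
## requests the gradient immediately after the cost at the same parameter
## vector, so fn stashes the gradient and gr returns it; three probe
## coordinates guard against a stale stash for any other call pattern.
.optimize <- function(par, fngr, maxit, config) {
  cache <- new.env(parent = emptyenv())
  n <- length(par)
  mid <- (n + 1L) %/% 2L
  fn <- function(p) {
    v <- fngr(p)
    cache$grad <- v$grad
    cache$probe <- c(p[1L], p[mid], p[n])
    v$cost
  }
  gr <- function(p) {
    if (!is.null(cache$probe) &&
        identical(cache$probe, c(p[1L], p[mid], p[n])))
      return(cache$grad)
    fngr(p)$grad
  }
  stats::optim(par, fn = fn, gr = gr,
               method = config@optimizer,
               control = list(maxit = maxit, lmm = 2,
                              pgtol = config@convergenceTol))
}

#' Train one sparse autoencoder layer
#'
#' Deterministic full-batch minimization of the composite cost from a
#' seeded random initialization; the returned layer never has higher cost
#' than the initial one.
#'
#' @param inputs n x dIn matrix of examples in [0, 1] (n >= 2).
#' @param dHidden hidden-layer size.
#' @param lambda,beta,rho hyperparameters.
#' @param config a \linkS4class{TrainConfig}; its seed drives the
#'   initialization.
#' @return A trained \linkS4class{AutoencoderLayer}.
#' @export
trainAutoencoder <- function(inputs, dHidden, lambda = 0.004, beta = 4,
                             rho = 0.015, config = trainConfig()) {
  X <- .asColumns(inputs, if (is.null(dim(inputs))) length(inputs)
                          else ncol(inputs))
  if (ncol(X) < 2L) stop("need at least 2 examples", call. = FALSE)
  dIn <- nrow(X)
  layer0 <- initAutoencoderLayer(dIn, dHidden, lambda, beta, rho,
                                 seed = config@seed)
  par0 <- .layerToPar(layer0)
  fngr <- function(p) .aeFlat(p, X, lambda, beta, rho, dHidden)
  res <- .optimize(par0, fngr, config@maxIterations, config)
  trained <- .parToLayer(res$par, layer0)
  ## guard the descent contract even if the optimizer stopped early
  c0 <- .aeFlat(par0, X, lambda, beta, rho, dHidden)$cost
  if (res$value > c0) trained <- layer0
  trained
}

#' Per-layer SAE hyperparameters
#'
#' Defaults follow the reference configuration: L2 coefficients 0.004 and
#' 0.002 for the first and second hidden layers, sparsity coefficient
#' beta = 4 for both, and sparsity proportions 0.015 and 0.01.
#'
#' @param lambda1,lambda2 L2 coefficients per layer.
#' @param beta sparsity coefficient (both layers).
#' @param rho1,rho2 sparsity proportions per layer.
#' @return Named list of hyperparameters.
#' @export
saeHyper <- function(lambda1 = 0.004, lambda2 = 0.002, beta = 4,
                     rho1 = 0.015, rho2 = 0.01) {
  list(lambda1 = lambda1, lambda2 = lambda2, beta = beta,
       rho1 = rho1, rho2 = rho2)
}

## Softmax probabilities for a 2 x N score matrix, numerically stable.
.softmax <- function(S) {
  S <- sweep(S, 2, apply(S, 2, max))
  E <- exp(S)
  sweep(E, 2, colSums(E), "/")
}

#' Build and train a stacked autoencoder classifier
#'
#' Greedy layer-wise pretraining: the first sparse autoencoder is trained
#' on the images, its codes become the training set of the second; the
#' decoders are then set aside and a two-neuron softmax head is attached to
#' the second encoder. The head is first fitted with the encoders frozen
#' (a convex problem), then the entire encoder + head stack is fine-tuned
#' by minimizing the cross-entropy (disable with
#' \code{fineTuneIterations = 0} in the config).
#'
#' @param images n x d matrix of flattened images in [0, 1] (d = 2,352 for
#'   28 x 28 x 3 inputs).
#' @param labels class labels ("at_risk" / "no_risk"), both present.
#' @param n1,n2 hidden sizes of the two encoder layers (defaults 300, 30).
#' @param hyper per-layer hyperparameters, see \code{\link{saeHyper}}.
#' @param config a \linkS4class{TrainConfig}.
#' @return A trained \linkS4class{SAEClassifier}.
#' @export
buildAndTrainSae <- function(images, labels, n1 = 300L, n2 = 30L,
                             hyper = saeHyper(), config = trainConfig()) {
  X <- as.matrix(images)
  labels <- as.character(labels)
  if (nrow(X) < 4L) stop("need at least 4 examples", call. = FALSE)
  if (length(unique(labels)) != 2L)
    stop("both classes must be present", call. = FALSE)

  ae1Cfg <- initialize(config, seed = .deriveSeed(config@seed, 1L))
  ae2Cfg <- initialize(config, seed = .deriveSeed(config@seed, 2L))
  enc1 <- trainAutoencoder(X, n1, hyper$lambda1, hyper$beta, hyper$rho1,
                           ae1Cfg)
  Z1 <- encode(enc1, X)                       # n x n1
  enc2 <- trainAutoencoder(Z1, n2, hyper$lambda2, hyper$beta, hyper$rho2,
                           ae2Cfg)
  Z2 <- t(encode(enc2, Z1))                   # n2 x n

  classes <- c("at_risk", "no_risk")
  Y <- rbind(as.numeric(labels == classes[1]),
             as.numeric(labels == classes[2]))

  ## convex softmax-head fit with frozen encoders
  headFngr <- function(p) {
    Ws <- matrix(p[seq_len(2 * n2)], 2, n2)
    bs <- p[2 * n2 + 1:2]
    P <- .softmax(Ws %*% Z2 + bs)
    Ds <- (P - Y) / ncol(Z2)
    list(cost = -sum(Y * log(P + 1e-12)) / ncol(Z2),
         grad = c(as.vector(Ds %*% t(Z2)), rowSums(Ds)))
  }
  headRes <- .optimize(numeric(2 * n2 + 2), headFngr,
                       config@softmaxIterations, config)
  Ws <- matrix(headRes$par[seq_len(2 * n2)], 2, n2)
  bs <- headRes$par[2 * n2 + 1:2]

  W1a <- enc1@W1; b1a <- enc1@b1
  W1b <- enc2@W1; b1b <- enc2@b1
  if (config@fineTuneIterations > 0L) {
    sizes <- c(length(W1a), length(b1a), length(W1b), length(b1b),
               length(Ws), length(bs))
    splitPar <- function(p) {
      out <- vector("list", 6)
      i <- 0L
      for (k in seq_along(sizes)) {
        out[[k]] <- p[i + seq_len(sizes[k])]
        i <- i + sizes[k]
      }
      out
    }
    ## stratified validation split for early stopping (reference-tooling
    ## style); empty when validationFraction = 0
    valIdx <- integer(0)
    if (config@validationFraction > 0) {
      valIdx <- .withSeed(.deriveSeed(config@seed, 9L), {
        unlist(lapply(classes, function(cl) {
          idx <- which(labels == cl)
          nVal <- max(1L, round(config@validationFraction * length(idx)))
          if (nVal >= length(idx)) nVal <- length(idx) - 1L
          sample(idx, nVal)
        }))
      })
    }
    trIdx <- setdiff(seq_len(nrow(X)), valIdx)
    Xtr <- t(X[trIdx, , drop = FALSE]); Ytr <- Y[, trIdx, drop = FALSE]
    ftFngr <- function(p)
      stackCostGradCpp(p, Xtr, Ytr, n1, n2, config@fineTuneDecay, TRUE)
    par <- c(as.vector(W1a), b1a, as.vector(W1b), b1b, as.vector(Ws), bs)
    if (length(valIdx) == 0L) {
      par <- .optimize(par, ftFngr, config@fineTuneIterations, config)$par
    } else {
      Xv <- t(X[valIdx, , drop = FALSE]); Yv <- Y[, valIdx, drop = FALSE]
      valCE <- function(p)
        stackCostGradCpp(p, Xv, Yv, n1, n2, 0, FALSE)$cost
      chunk <- 5L
      bestPar <- par
      bestCE <- valCE(par)
      bad <- 0L
      done <- 0L
      while (done < config@fineTuneIterations) {
        it <- min(chunk, config@fineTuneIterations - done)
        par <- .optimize(par, ftFngr, it, config)$par
        done <- done + it
        ce <- valCE(par)
        if (ce < bestCE - 1e-10) {
          bestCE <- ce; bestPar <- par; bad <- 0L
        } else {
          bad <- bad + 1L
          if (bad >= config@patience) break
        }
      }
      par <- bestPar
    }
    b <- splitPar(par)
    W1a <- matrix(b[[1]], n1); b1a <- b[[2]]
    W1b <- matrix(b[[3]], n2); b1b <- b[[4]]
    Ws <- matrix(b[[5]], 2); bs <- b[[6]]
  }

  new("SAEClassifier",
      encoder1 = initialize(enc1, W1 = W1a, b1 = b1a),
      encoder2 = initialize(enc2, W1 = W1b, b1 = b1b),
      softmaxW = Ws, softmaxB = bs, classes = classes)
}

setMethod("show", "SAEClassifier", function(object) {
  cat(sprintf("SAEClassifier: %d -> %d -> %d -> softmax(%s)\n",
              ncol(object@encoder1@W1), nrow(object@encoder1@W1),
              nrow(object@encoder2@W1),
              paste(object@classes, collapse = "/")))
})

#' Predict fall-risk classes or probabilities
#'
#' @param object a trained \linkS4class{SAEClassifier}.
#' @param newdata n x d matrix of flattened images (or a single vector).
#' @param type "class" for labels, "prob" for the n x 2 matrix of class
#'   probabilities (columns at_risk, no_risk; rows sum to 1).
#' @return character vector of labels or a probability matrix.
#' @export
setMethod("predict", "SAEClassifier",
  function(object, newdata, type = c("class", "prob")) {
    type <- match.arg(type)
    single <- is.null(dim(newdata))
    X <- if (single) matrix(newdata, nrow = 1) else as.matrix(newdata)
    Z1 <- encode(object@encoder1, X)
    Z2 <- encode(object@encoder2, Z1)
    P <- t(.softmax(object@softmaxW %*% t(Z2) + object@softmaxB))
    colnames(P) <- object@classes
    if (type == "prob") return(P)
    object@classes[max.col(P, ties.method = "first")]
  })

#' Stacked reconstruction mean squared error
#'
#' Encodes each image through both layers and decodes back
#' (x -> z1 -> z2 -> z1hat -> xhat); returns the reconstruction MSE summed
#' over pixels and averaged over examples, on the [0, 1] pixel scale.
#'
#' @param enc1,enc2 trained \linkS4class{AutoencoderLayer} objects.
#' @param images n x d matrix.
#' @return scalar MSE.
#' @export
stackedReconstructionMse <- function(enc1, enc2, images) {
  X <- as.matrix(images)
  Z1 <- encode(enc1, X)
  Z2 <- encode(enc2, Z1)
  Z1h <- decode(enc2, Z2)
  Xh <- decode(enc1, Z1h)
  sum((X - Xh)^2) / nrow(X)
}

#' Grid search over encoder layer sizes
#'
#' For every (n1, n2) pair the two-layer stack is trained \code{runs} times
#' from distinct derived seeds and the stacked reconstruction MSE on the
#' training images is averaged; the best pair minimizes the mean MSE with
#' ties broken toward the smaller n1, then the smaller n2. The default grid
#' spans 100-500 first-layer and 10-30 second-layer neurons.
#'
#' @param images n x d matrix of flattened images in [0, 1].
#' @param n1Values,n2Values candidate layer sizes.
#' @param runs independently seeded runs averaged per cell (default 10).
#' @param hyper per-layer hyperparameters (see \code{\link{saeHyper}}).
#' @param config a \linkS4class{TrainConfig}; the master seed determines
#'   every per-run seed.
#' @return A \linkS4class{GridSearchResult}.
#' @export
gridSearch <- function(images, n1Values = c(100L, 200L, 300L, 400L, 500L),
                       n2Values = c(10L, 15L, 20L, 25L, 30L),
                       runs = 10L, hyper = saeHyper(),
                       config = trainConfig()) {
  X <- as.matrix(images)
  if (nrow(X) < 1L) stop("need a non-empty image set", call. = FALSE)
  mse <- matrix(NA_real_, length(n1Values), length(n2Values),
                dimnames = list(as.character(n1Values),
                                as.character(n2Values)))
  for (i in seq_along(n1Values)) {
    for (j in seq_along(n2Values)) {
      vals <- numeric(runs)
      for (r in seq_len(runs)) {
        s1 <- .deriveSeed(config@seed, i, j, r, 1L)
        s2 <- .deriveSeed(config@seed, i, j, r, 2L)
        enc1 <- trainAutoencoder(X, n1Values[i], hyper$lambda1, hyper$beta,
                                 hyper$rho1, initialize(config, seed = s1))
        Z1 <- encode(enc1, X)
        enc2 <- trainAutoencoder(Z1, n2Values[j], hyper$lambda2, hyper$beta,
                                 hyper$rho2, initialize(config, seed = s2))
        vals[r] <- stackedReconstructionMse(enc1, enc2, X)
      }
      mse[i, j] <- mean(vals)
    }
  }
  ## argmin with deterministic tie-break: row-major scan, smaller n1 first
  best <- c(1L, 1L)
  for (i in seq_along(n1Values)) for (j in seq_along(n2Values))
    if (mse[i, j] < mse[best[1], best[2]]) best <- c(i, j)
  new("GridSearchResult", mseTable = mse,
      bestPair = c(n1 = as.integer(n1Values[best[1]]),
                   n2 = as.integer(n2Values[best[2]])),
      runs = as.integer(runs))
}

setMethod("show", "GridSearchResult", function(object) {
  cat(sprintf("GridSearchResult (%d runs/cell): best n1 = %d, n2 = %d, MSE %.4g\n",
              object@runs, object@bestPair["n1"], object@bestPair["n2"],
              min(object@mseTable)))
})

#' Save / load a trained SAE classifier
#'
#' Single-file serialization of all weights, biases, hyperparameters and
#' the class labels under a versioned schema.
#'
#' @param model a \linkS4class{SAEClassifier}.
#' @param path file path.
#' @return \code{loadSAE} returns the restored \linkS4class{SAEClassifier}.
#' @export
saveSAE <- function(model, path) {
  stopifnot(is(model, "SAEClassifier"))
  payload <- list(
    schema = "tugsae-sae-1",
    classes = model@classes,
    softmaxW = model@softmaxW, softmaxB = model@softmaxB,
    encoders = lapply(list(model@encoder1, model@encoder2), function(e)
      list(W1 = e@W1, b1 = e@b1, W2 = e@W2, b2 = e@b2,
           lambda = e@lambda, beta = e@beta, rho = e@rho)))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname saveSAE
#' @export
loadSAE <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$schema, "tugsae-sae-1"))
    stop("unrecognized SAE model schema", call. = FALSE)
  mk <- function(e) new("AutoencoderLayer", W1 = e$W1, b1 = e$b1, W2 = e$W2,
                        b2 = e$b2, lambda = e$lambda, beta = e$beta,
                        rho = e$rho)
  new("SAEClassifier",
      encoder1 = mk(payload$encoders[[1]]),
      encoder2 = mk(payload$encoders[[2]]),
      softmaxW = payload$softmaxW, softmaxB = payload$softmaxB,
      classes = payload$classes)
}
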