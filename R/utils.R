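## Internal helpers shared across modules.

## Derive a child seed from a master seed and a path of indices, staying
## below 2^31. Multiplicative hashing keeps distinct paths well separated.
.deriveSeed <- function(seed, ...) {
  idx <- c(...)
  h <- as.numeric(seed) %% 2147483647
  for (i in idx) {
    h <- (h * 48271 + as.numeric(i) * 16807 + 12345) %% 2147483647
  }
  as.integer(h)
}

## Evaluate expr with a locally-set RNG seed, restoring global RNG state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

.assertScalar <- function(x, name, positive = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}

## Logistic sigmoid, numerically stable at both tails.
.sigmoid <- function(x) 1 / (1 + exp(-x))

## Cheap deterministic fingerprint of an R object (provenance only).
.fingerprint <- function(x) {
  txt <- paste(deparse(x, control = "all"), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
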