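# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    stopf("`%s` must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x > max) {
    stopf("`%s` must be a single finite number in [%s, %s]", name, min, max)
  }
  as.numeric(x)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# derive a child seed that stays inside 32-bit integer range
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# labels (0-based integers) -> n x C one-hot matrix
one_hot <- function(labels, n_classes) {
  labels <- as.integer(labels)
  if (any(labels < 0L | labels >= n_classes)) {
    stopf("labels must lie in 0..%d", n_classes - 1L)
  }
  y <- matrix(0, nrow = length(labels), ncol = n_classes)
  y[cbind(seq_along(labels), labels + 1L)] <- 1
  y
}
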