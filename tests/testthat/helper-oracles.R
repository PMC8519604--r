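# Independent brute-force oracles: deliberately naive double/triple loops
# and closed forms, kept free of any package internals so they can verify
# the vectorised implementations.

oracle_kernel <- function(x, y, sigmas) {
  mean(exp(-sum((x - y)^2) / (2 * sigmas^2)))
}

oracle_mmd2 <- function(X, Y, sigmas = 1) {
  n <- nrow(X); m <- nrow(Y)
  t1 <- 0; t2 <- 0; t3 <- 0
  for (i in 1:n) for (j in 1:n) t1 <- t1 + oracle_kernel(X[i, ], X[j, ], sigmas)
  for (i in 1:m) for (j in 1:m) t2 <- t2 + oracle_kernel(Y[i, ], Y[j, ], sigmas)
  for (i in 1:n) for (j in 1:m) t3 <- t3 + oracle_kernel(X[i, ], Y[j, ], sigmas)
  t1 / n^2 + t2 / m^2 - 2 * t3 / (n * m)
}

# triple-loop weighted class-conditional MMD for one source-target pair,
# weighted mode (no 1/n^2 prefactors), averaged over C classes
oracle_pair_llmmd <- function(Xs, ys, Xt, probs, sigmas = 1, C = 2) {
  total <- 0
  for (c in 0:(C - 1)) {
    src <- which(ys == c)
    a <- rep(0, nrow(Xs)); a[src] <- 1 / length(src)
    colmass <- sum(probs[, c + 1])
    if (length(src) == 0 || colmass == 0) next
    b <- probs[, c + 1] / colmass
    s <- 0
    for (i in seq_len(nrow(Xs))) for (j in seq_len(nrow(Xs)))
      s <- s + a[i] * a[j] * oracle_kernel(Xs[i, ], Xs[j, ], sigmas)
    for (i in seq_len(nrow(Xt))) for (j in seq_len(nrow(Xt)))
      s <- s + b[i] * b[j] * oracle_kernel(Xt[i, ], Xt[j, ], sigmas)
    for (i in seq_len(nrow(Xs))) for (j in seq_len(nrow(Xt)))
      s <- s - 2 * a[i] * b[j] * oracle_kernel(Xs[i, ], Xt[j, ], sigmas)
    total <- total + s
  }
  total / C
}

oracle_global_loss <- function(probs_list) {
  N <- length(probs_list)
  d <- matrix(0, N, N)
  for (n in 1:N) for (m in 1:N) {
    d[n, m] <- mean(rowSums(abs(probs_list[[n]] - probs_list[[m]])))
  }
  total <- 0
  for (n in 1:(N - 1)) for (m in (n + 1):N) {
    omega_mn <- d[n, m] / sum(d[n, -n])
    total <- total + (1 - omega_mn) * d[n, m]
  }
  total * 2 / (N * (N - 1))
}

oracle_cross_entropy <- function(preds_list, labels_list) {
  total <- 0
  for (n in seq_along(preds_list)) {
    p <- preds_list[[n]]
    y <- labels_list[[n]]
    s <- 0
    for (i in seq_len(nrow(p))) s <- s - log(p[i, y[i] + 1])
    total <- total + s / nrow(p)
  }
  total
}

one_hot <- function(labels, C) {
  y <- matrix(0, length(labels), C)
  y[cbind(seq_along(labels), as.integer(labels) + 1L)] <- 1
  y
}

# random probability rows via normalised uniforms
random_probs <- function(n, C) {
  p <- matrix(stats::runif(n * C), n, C)
  p / rowSums(p)
}

# a small labeled cohort for pipeline tests
small_cohort_spec <- function(n_subjects = 3, seed = 42) {
  cohort_spec(n_subjects = n_subjects, n_channels = 5,
              segments_per_class = 30, seed = seed)
}
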