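test_that("Gaussian kernel matches its closed form and is symmetric", {
  expect_equal(kernel_matrix(matrix(0), matrix(sqrt(2)))[1, 1], exp(-1),
               tolerance = 1e-12)
  x <- matrix(rnorm(5), 1)
  expect_equal(kernel_matrix(x, x)[1, 1], 1)
  X <- matrix(rnorm(12), 4)
  K <- kernel_matrix(X, X, kernel_spec(c(0.5, 2)))
  expect_equal(K, t(K))
  expect_true(all(K > 0 & K <= 1))
  expect_error(kernel_matrix(matrix(0, 1, 2), matrix(0, 1, 3)), "dimension")
  expect_error(kernel_spec(c(1, -1)), "positive")
})

test_that("squared MMD matches closed forms and the brute-force oracle", {
  # two Dirac samples at distance sqrt(2), sigma 1
  expect_equal(mmd_squared(matrix(0), matrix(sqrt(2))), 2 - 2 * exp(-1),
               tolerance = 1e-12)
  X <- matrix(rnorm(15), 5)
  expect_equal(mmd_squared(X, X), 0, tolerance = 1e-12)
  set.seed(41)
  for (i in 1:100) {
    n <- sample(2:6, 1); m <- sample(2:6, 1); d <- sample(1:4, 1)
    A <- matrix(rnorm(n * d), n); B <- matrix(rnorm(m * d) + 0.5, m)
    s <- runif(1, 0.5, 2)
    expect_equal(mmd_squared(A, B, kernel_spec(s)), oracle_mmd2(A, B, s),
                 tolerance = 1e-10)
  }
  expect_error(mmd_squared(matrix(numeric(0), 0, 2), X), "empty")
})

test_that("source class weights implement the label-count normalisation", {
  w <- source_class_weights(one_hot(c(0, 0, 1, 1, 1), 2))
  expect_equal(w$weights[, 1], c(0.5, 0.5, 0, 0, 0))
  expect_equal(w$weights[, 2], c(0, 0, 1/3, 1/3, 1/3))
  single <- source_class_weights(one_hot(0L, 2))
  expect_equal(single$weights[1, 1], 1)
  expect_false(single$present[2])
  expect_error(source_class_weights(matrix(c(1, 1), 1)), "one 1 per row")
})

test_that("target class weights normalise probabilities per class column", {
  w <- target_class_weights(rbind(c(0.8, 0.2), c(0.2, 0.8)))
  expect_equal(w$weights[, 1], c(0.8, 0.2))
  expect_equal(w$weights[, 2], c(0.2, 0.8))
  # hard one-hot probabilities reduce to the source construction
  y <- c(0, 1, 1, 0, 1)
  expect_equal(target_class_weights(one_hot(y, 2))$weights,
               source_class_weights(one_hot(y, 2))$weights)
  expect_error(target_class_weights(matrix(c(-0.1, 1.1), 1)), "nonnegative")
})

test_that("class weight columns sum to one on randomised inputs", {
  set.seed(42)
  for (i in 1:1000) {
    n <- sample(1:20, 1)
    C <- sample(2:4, 1)
    ws <- source_class_weights(one_hot(sample(0:(C - 1), n, TRUE), C))
    sums <- colSums(ws$weights)
    expect_equal(unname(sums[ws$present]),
                 rep(1, sum(ws$present)), tolerance = 1e-12)
    wt <- target_class_weights(random_probs(n, C))
    expect_equal(unname(colSums(wt$weights)[wt$present]),
                 rep(1, sum(wt$present)), tolerance = 1e-12)
  }
})

test_that("llmmd reduces to plain MMD with one domain and one class", {
  set.seed(43)
  Xs <- matrix(rnorm(12), 4)
  Xt <- matrix(rnorm(15), 5)
  res <- llmmd(list(Xs), list(rep(0L, 4)), Xt,
               matrix(1, 5, 1), spec = kernel_spec(1), n_classes = 1)
  expect_equal(res$total, mmd_squared(Xs, Xt), tolerance = 1e-12)
})

test_that("llmmd vanishes when the target equals a source with true labels", {
  set.seed(44)
  X <- matrix(rnorm(20), 10)
  y <- rep(0:1, 5)
  res <- llmmd(list(X), list(y), X, one_hot(y, 2), spec = kernel_spec(1))
  expect_equal(res$total, 0, tolerance = 1e-10)
})

test_that("llmmd matches the triple-loop weighted oracle", {
  set.seed(45)
  for (i in 1:30) {
    ns <- sample(4:8, 1); nt <- sample(4:8, 1); d <- sample(1:3, 1)
    Xs <- matrix(rnorm(ns * d), ns)
    Xt <- matrix(rnorm(nt * d), nt)
    ys <- sample(0:1, ns, TRUE)
    pt <- random_probs(nt, 2)
    s <- runif(1, 0.5, 2)
    res <- llmmd(list(Xs), list(ys), Xt, pt, spec = kernel_spec(s))
    expect_equal(res$total, oracle_pair_llmmd(Xs, ys, Xt, pt, s),
                 tolerance = 1e-10)
  }
})

test_that("llmmd is invariant to sample order within a domain", {
  set.seed(46)
  Xs <- matrix(rnorm(24), 8)
  ys <- sample(0:1, 8, TRUE)
  Xt <- matrix(rnorm(18), 6)
  pt <- random_probs(6, 2)
  ref <- llmmd(list(Xs), list(ys), Xt, pt, spec = kernel_spec(1))$total
  perm <- sample(8)
  permt <- sample(6)
  out <- llmmd(list(Xs[perm, ]), list(ys[perm]), Xt[permt, ],
               pt[permt, ], spec = kernel_spec(1))$total
  expect_equal(out, ref, tolerance = 1e-12)
})

test_that("llmmd decreases as the target interpolates toward a source", {
  set.seed(47)
  n <- 150
  Xs <- rbind(matrix(rnorm(n, 0), n / 2, 2), matrix(rnorm(n, 3), n / 2, 2))
  ys <- rep(0:1, each = n / 2)
  shifted <- Xs + 4
  vals <- vapply(c(1, 0.5, 0), function(a) {
    Xt <- a * shifted + (1 - a) * Xs
    llmmd(list(Xs), list(ys), Xt, one_hot(ys, 2),
          spec = kernel_spec(2))$total
  }, numeric(1))
  expect_true(vals[1] > vals[2] && vals[2] > vals[3])
  expect_lt(vals[3], 1e-10)
})

test_that("literal mode reproduces the printed prefactor form", {
  set.seed(48)
  Xs <- matrix(rnorm(12), 4)
  Xt <- matrix(rnorm(9), 3)
  ys <- c(0L, 1L, 0L, 1L)
  pt <- random_probs(3, 2)
  lit <- llmmd(list(Xs), list(ys), Xt, pt, spec = kernel_spec(1),
               mode = "literal")$total
  # independently: weighted sums with explicit 1/n^2 prefactors
  manual <- 0
  for (c in 1:2) {
    a <- one_hot(ys, 2)[, c]; a <- a / sum(a)
    b <- pt[, c] / sum(pt[, c])
    K1 <- kernel_matrix(Xs, Xs); K2 <- kernel_matrix(Xt, Xt)
    K12 <- kernel_matrix(Xs, Xt)
    manual <- manual + drop(a %*% K1 %*% a) / 16 +
      drop(b %*% K2 %*% b) / 9 - 2 * drop(a %*% K12 %*% b) / 12
  }
  expect_equal(lit, manual / 2, tolerance = 1e-12)
})
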