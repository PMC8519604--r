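check_prob_matrix <- function(p, name = "probs") {
  if (is.vector(p)) p <- matrix(p, nrow = 1L)
  if (any(p < -1e-9)) stopf("`%s` must be nonnegative", name)
  p
}

#' Mean absolute output discrepancy between two classifiers
#'
#' `d_nm = 1/T sum_i sum_c |p_n(i, c) - p_m(i, c)|`, the mean L1 distance
#' between the two classifiers' probability rows on the same target
#' samples.  Lies in `[0, 2]`.
#'
#' @param probs_n,probs_m T x C probability matrices.
#' @return A nonnegative scalar.
#' @export
pairwise_discrepancy <- function(probs_n, probs_m) {
  probs_n <- check_prob_matrix(probs_n, "probs_n")
  probs_m <- check_prob_matrix(probs_m, "probs_m")
  if (!all(dim(probs_n) == dim(probs_m))) {
    stopf("probability matrices must have identical shapes")
  }
  sum(abs(probs_n - probs_m)) / nrow(probs_n)
}

discrepancy_matrix <- function(probs_list) {
  N <- length(probs_list)
  d <- matrix(0, N, N)
  for (n in seq_len(N - 1L)) {
    for (m in (n + 1L):N) {
      d[n, m] <- d[m, n] <- pairwise_discrepancy(probs_list[[n]],
                                                 probs_list[[m]])
    }
  }
  d
}

#' Unweighted global classifier discrepancy
#'
#' The mean of the pairwise discrepancies over the `N(N-1)/2` unordered
#' classifier pairs: `2/(N(N-1)) sum_{n<m} d_nm`.
#'
#' @param probs_list List of N (>= 2) T x C probability matrices, one per
#'   classifier, on the same target samples.
#' @return A nonnegative scalar.
#' @export
unweighted_global <- function(probs_list) {
  N <- length(probs_list)
  if (N < 2L) stopf("at least two classifiers are required")
  d <- discrepancy_matrix(probs_list)
  sum(d[upper.tri(d)]) * 2 / (N * (N - 1))
}

#' Similarity weights from a discrepancy matrix
#'
#' Row n holds `omega_mn = d_nm / sum_{j != n} d_nj`: each classifier's
#' discrepancies with the others, normalised so the row sums to one (the
#' diagonal is zero).  A row whose discrepancies are all zero gets the
#' uniform weights `1/(N-1)`.
#'
#' @param d Symmetric nonnegative N x N discrepancy matrix with zero
#'   diagonal, or a list of probability matrices from which it is computed.
#' @return An N x N weight matrix `w` with `w[n, m] = omega_mn`,
#'   `rowSums(w) = 1`.
#' @export
similarity_weights <- function(d) {
  if (is.list(d)) d <- discrepancy_matrix(d)
  if (any(d < 0)) stopf("discrepancies must be nonnegative")
  N <- nrow(d)
  if (N < 2L) stopf("at least two classifiers are required")
  w <- matrix(0, N, N)
  for (n in seq_len(N)) {
    tot <- sum(d[n, -n])
    w[n, -n] <- if (tot > 0) d[n, -n] / tot else 1 / (N - 1)
  }
  w
}

#' Discrepancy table: pairwise d and similarity weights
#'
#' @inheritParams unweighted_global
#' @return A list of class `discrepancy_table` with the symmetric `d`
#'   matrix and the row-normalised weight matrix `omega`.
#' @export
discrepancy_table <- function(probs_list) {
  d <- discrepancy_matrix(probs_list)
  structure(list(d = d, omega = similarity_weights(d)),
            class = "discrepancy_table")
}

#' Similarity-weighted global discrepancy loss
#'
#' `2/(N(N-1)) sum_{n<m} (1 - omega_mn) d_nm`: pairs whose classifiers
#' already agree closely (small `d_nm`, hence small `omega_mn` relative to
#' classifier n's other discrepancies) keep a large `1 - omega_mn` factor,
#' so agreement is reinforced while genuinely dissimilar pairs are
#' down-weighted.  With exactly two classifiers the weight construction
#' degenerates (`omega = 1`, loss identically zero), so the unweighted
#' discrepancy `d_12` is returned instead, with a warning.
#'
#' @inheritParams unweighted_global
#' @param symmetrize Use the symmetrised weights
#'   `(omega_mn + omega_nm)/2` instead of the row-n form (default FALSE).
#' @return A nonnegative scalar, at most [unweighted_global()].
#' @export
global_loss <- function(probs_list, symmetrize = FALSE) {
  N <- length(probs_list)
  if (N < 2L) stopf("at least two classifiers are required")
  d <- discrepancy_matrix(probs_list)
  if (N == 2L) {
    warning("two classifiers: similarity weights are degenerate, ",
            "returning the unweighted discrepancy")
    return(d[1, 2])
  }
  w <- similarity_weights(d)
  if (symmetrize) w <- (w + t(w)) / 2
  total <- 0
  for (n in seq_len(N - 1L)) {
    for (m in (n + 1L):N) {
      total <- total + (1 - w[n, m]) * d[n, m]
    }
  }
  total * 2 / (N * (N - 1))
}

# gradient of global_loss wrt each probability matrix, with the weights
# treated as constants (detached); subgradient sign(0) = 0 at ties.
# `omega` lets the caller supply pre-frozen weights.
global_loss_grads <- function(probs_list, symmetrize = FALSE, omega = NULL) {
  N <- length(probs_list)
  T_ <- nrow(probs_list[[1]])
  d <- discrepancy_matrix(probs_list)
  if (N == 2L) {
    s <- sign(probs_list[[1]] - probs_list[[2]]) / T_
    return(list(value = d[1, 2], grads = list(s, -s)))
  }
  w <- omega %||% similarity_weights(d)
  if (is.null(omega) && symmetrize) w <- (w + t(w)) / 2
  scale <- 2 / (N * (N - 1))
  grads <- lapply(probs_list, function(p) matrix(0, nrow(p), ncol(p)))
  value <- 0
  for (n in seq_len(N - 1L)) {
    for (m in (n + 1L):N) {
      coef <- scale * (1 - w[n, m])
      value <- value + coef * d[n, m]
      s <- sign(probs_list[[n]] - probs_list[[m]]) * (coef / T_)
      grads[[n]] <- grads[[n]] + s
      grads[[m]] <- grads[[m]] - s
    }
  }
  list(value = value, grads = grads)
}
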