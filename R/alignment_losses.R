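#' Gaussian kernel specification
#'
#' The kernel is `k(x, y) = exp(-||x - y||^2 / (2 sigma^2))`; with several
#' bandwidths the kernel is the mean over them, the usual multi-bandwidth
#' construction that removes the need to pick a single sigma.
#'
#' @param sigmas Positive bandwidths.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(sigmas = 1) {
  if (length(sigmas) < 1L || any(!is.finite(sigmas)) || any(sigmas <= 0)) {
    stopf("`sigmas` must be one or more positive numbers")
  }
  structure(list(family = "gaussian", sigmas = as.numeric(sigmas)),
            class = "kernel_spec")
}

#' Median-heuristic bandwidths
#'
#' Returns `{median pairwise distance x 2^k, k in -2..2}` computed on the
#' pooled rows of the inputs — the standard per-batch bandwidth family for
#' MMD losses.
#'
#' @param ... Numeric matrices pooled before computing pairwise distances.
#' @return A [kernel_spec()].
#' @export
median_heuristic <- function(...) {
  z <- do.call(rbind, list(...))
  if (nrow(z) > 256L) z <- z[seq_len(256L), , drop = FALSE]
  d <- stats::dist(z)
  med <- stats::median(d)
  if (!is.finite(med) || med <= 0) med <- 1
  kernel_spec(med * 2^(-2:2))
}

sq_dists <- function(X, Y) {
  xn <- rowSums(X^2)
  yn <- rowSums(Y^2)
  d2 <- outer(xn, yn, `+`) - 2 * X %*% t(Y)
  pmax(d2, 0)
}

#' Gaussian kernel matrix between two sample sets
#'
#' @param X,Y Numeric matrices with matching column dimension.
#' @param spec A [kernel_spec()]; with several bandwidths the mean kernel
#'   is returned.
#' @return An `nrow(X)` x `nrow(Y)` matrix with entries in (0, 1].
#' @export
kernel_matrix <- function(X, Y, spec = kernel_spec()) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  if (is.vector(Y)) Y <- matrix(Y, nrow = 1L)
  if (ncol(X) != ncol(Y)) stopf("X and Y must have the same dimension")
  if (anyNA(X) || anyNA(Y)) stopf("kernel inputs must be finite")
  d2 <- sq_dists(X, Y)
  K <- matrix(0, nrow(d2), ncol(d2))
  for (s in spec$sigmas) K <- K + exp(-d2 / (2 * s^2))
  K / length(spec$sigmas)
}

#' Squared maximum mean discrepancy between two sample sets
#'
#' The biased V-statistic estimate
#' `1/n^2 sum k(x_i, x_j) + 1/m^2 sum k(y_i, y_j) - 2/(nm) sum k(x_i, y_j)`.
#'
#' @inheritParams kernel_matrix
#' @return A nonnegative scalar (zero when `X` and `Y` are the same sample
#'   set).
#' @export
mmd_squared <- function(X, Y, spec = kernel_spec()) {
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  if (is.vector(Y)) Y <- matrix(Y, nrow = 1L)
  if (nrow(X) < 1L || nrow(Y) < 1L) stopf("empty sample set")
  mean(kernel_matrix(X, X, spec)) + mean(kernel_matrix(Y, Y, spec)) -
    2 * mean(kernel_matrix(X, Y, spec))
}

#' Per-class sample weights from source labels
#'
#' Each sample of class c receives weight `1 / (count of class c)` in that
#' class's weight vector, so every non-empty class's weights sum to one.
#'
#' @param labels_onehot An n x C one-hot label matrix.
#' @return An object of class `class_weights`: `weights` is an n x C matrix
#'   whose non-empty columns sum to 1, `present` flags classes with any
#'   mass.
#' @export
source_class_weights <- function(labels_onehot) {
  if (is.vector(labels_onehot)) labels_onehot <- matrix(labels_onehot, 1L)
  if (any(rowSums(labels_onehot) != 1) ||
      !all(labels_onehot %in% c(0, 1))) {
    stopf("`labels_onehot` must have exactly one 1 per row")
  }
  totals <- colSums(labels_onehot)
  w <- sweep(labels_onehot, 2L, pmax(totals, 1), `/`)
  structure(list(weights = w, present = totals > 0,
                 n = nrow(labels_onehot), C = ncol(labels_onehot)),
            class = "class_weights")
}

#' Per-class sample weights from classifier probabilities
#'
#' The target analogue of [source_class_weights()]: sample i's weight for
#' class c is its predicted probability of c normalised over the batch,
#' `p_ic / sum_j p_jc`, so each non-empty class's weights sum to one.
#'
#' @param probs An n x C matrix of probability rows (soft pseudo-labels).
#' @return A `class_weights` object; columns with zero total mass are
#'   flagged absent.
#' @export
target_class_weights <- function(probs) {
  if (is.vector(probs)) probs <- matrix(probs, 1L)
  if (any(probs < 0)) stopf("probabilities must be nonnegative")
  totals <- colSums(probs)
  w <- sweep(probs, 2L, ifelse(totals > 0, totals, 1), `/`)
  w[, totals == 0] <- 0
  structure(list(weights = w, present = totals > 0,
                 n = nrow(probs), C = ncol(probs)),
            class = "class_weights")
}

# per-class weighted MMD between one source's specific features and the
# target's, optionally with the literal 1/n^2 prefactors kept
pair_local_mmd <- function(Xs, ws, Xt, wt, spec, mode) {
  C <- ws$C
  Kss <- kernel_matrix(Xs, Xs, spec)
  Ktt <- kernel_matrix(Xt, Xt, spec)
  Kst <- kernel_matrix(Xs, Xt, spec)
  ns <- nrow(Xs)
  nt <- nrow(Xt)
  per_class <- numeric(C)
  skipped <- logical(C)
  for (c in seq_len(C)) {
    if (!ws$present[c] || !wt$present[c]) {
      skipped[c] <- TRUE
      next
    }
    a <- ws$weights[, c]
    b <- wt$weights[, c]
    if (mode == "literal") {
      a <- a / ns
      b <- b / nt
    }
    per_class[c] <- drop(a %*% Kss %*% a) + drop(b %*% Ktt %*% b) -
      2 * drop(a %*% Kst %*% b)
  }
  list(value = mean(per_class), per_class = per_class, skipped = skipped)
}

#' Label-conditional weighted MMD alignment loss
#'
#' For every pair (source n, target), the within-class discrepancy between
#' the source's specific features and the target's is measured with the
#' weighted kernel statistic
#' `sum_ij phi_i phi_j k(s_i, s_j) - 2 sum_ij phi_i phi_j k(s_i, t_j) +
#'  sum_ij phi_i phi_j k(t_i, t_j)`,
#' where the source weights phi come from the true labels
#' ([source_class_weights()]) and the target weights from classifier n's
#' soft pseudo-labels ([target_class_weights()]).  Class terms are averaged
#' over the C classes and the N source domains.  A class absent from either
#' side of a pair contributes zero and is flagged.
#'
#' @param source_feats List of N matrices: source n's specific features.
#' @param source_labels List of N label vectors (values 0..C-1).
#' @param target_feats_list Either one matrix (target features shared by
#'   all pairs) or a list of N matrices: the target batch mapped through
#'   subnet n.
#' @param target_probs List of N probability matrices (classifier n's
#'   output on the target batch), or a single matrix used for all pairs.
#' @param spec A [kernel_spec()], or `NULL` to use the per-pair
#'   [median_heuristic()].
#' @param mode `"weighted"` (default) uses the normalised phi weights with
#'   no additional prefactor; `"literal"` additionally divides the three
#'   kernel sums by `ns^2`, `ns*nt` and `nt^2` as in the printed loss.
#' @param n_classes Number of classes C (default: inferred from the
#'   probability matrices).
#' @return A list of class `llmmd_loss`: `total`, `per_domain`, and
#'   `skipped` (N x C logical: class terms absent from a pair).
#' @export
llmmd <- function(source_feats, source_labels, target_feats_list,
                  target_probs, spec = NULL,
                  mode = c("weighted", "literal"), n_classes = NULL) {
  mode <- match.arg(mode)
  N <- length(source_feats)
  if (N < 1L) stopf("at least one source domain is required")
  if (is.matrix(target_feats_list)) {
    target_feats_list <- rep(list(target_feats_list), N)
  }
  if (is.matrix(target_probs)) target_probs <- rep(list(target_probs), N)
  C <- n_classes %||% ncol(target_probs[[1]])
  per_domain <- numeric(N)
  skipped <- matrix(FALSE, N, C)
  for (n in seq_len(N)) {
    Xs <- source_feats[[n]]
    Xt <- target_feats_list[[n]]
    if (ncol(Xs) != ncol(Xt)) stopf("feature dimension mismatch in pair %d", n)
    ws <- source_class_weights(one_hot(source_labels[[n]], C))
    wt <- target_class_weights(target_probs[[n]])
    ks <- spec %||% median_heuristic(Xs, Xt)
    res <- pair_local_mmd(Xs, ws, Xt, wt, ks, mode)
    per_domain[n] <- res$value
    skipped[n, ] <- res$skipped
  }
  structure(list(total = mean(per_domain), per_domain = per_domain,
                 skipped = skipped, mode = mode),
            class = "llmmd_loss")
}

# ---- gradients -----------------------------------------------------------
# Gradient machinery for the weighted kernel statistic.  For the bilinear
# form  S(X, Y) = sum_ij A_ij k_sigma(x_i, y_j)  with A = outer(a, b) and a
# Gaussian kernel,  dS/dX = -(1/sigma^2) [diag(rowSums(A o K)) X - (A o K) Y]
# summed (averaged) over bandwidths; weights are treated as constants.

bilinear_grad <- function(X, Y, W, d2, spec) {
  gX <- matrix(0, nrow(X), ncol(X))
  gY <- matrix(0, nrow(Y), ncol(Y))
  value <- 0
  for (s in spec$sigmas) {
    K <- exp(-d2 / (2 * s^2))
    A <- W * K
    value <- value + sum(A)
    gX <- gX - (rowSums(A) * X - A %*% Y) / s^2
    gY <- gY - (colSums(A) * Y - crossprod(A, X)) / s^2
  }
  ns <- length(spec$sigmas)
  list(value = value / ns, gX = gX / ns, gY = gY / ns)
}

# Value and feature gradients of the per-pair local loss (weighted mode),
# averaged over classes.  The class sums are folded into weight matrices
# first (the statistic and its gradient are linear in them), so each
# kernel block is evaluated once regardless of C.
pair_local_mmd_grad <- function(Xs, ws, Xt, wt, spec) {
  C <- ws$C
  active <- ws$present & wt$present
  if (!any(active)) {
    return(list(value = 0,
                gXs = matrix(0, nrow(Xs), ncol(Xs)),
                gXt = matrix(0, nrow(Xt), ncol(Xt))))
  }
  A <- ws$weights[, active, drop = FALSE]
  B <- wt$weights[, active, drop = FALSE]
  Wss <- tcrossprod(A)
  Wtt <- tcrossprod(B)
  Wst <- tcrossprod(A, B)
  g_ss <- bilinear_grad(Xs, Xs, Wss, sq_dists(Xs, Xs), spec)
  g_tt <- bilinear_grad(Xt, Xt, Wtt, sq_dists(Xt, Xt), spec)
  g_st <- bilinear_grad(Xs, Xt, Wst, sq_dists(Xs, Xt), spec)
  list(value = (g_ss$value + g_tt$value - 2 * g_st$value) / C,
       gXs = (g_ss$gX + g_ss$gY - 2 * g_st$gX) / C,
       gXt = (g_tt$gX + g_tt$gY - 2 * g_st$gY) / C)
}
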