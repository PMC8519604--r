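#' Supervised multi-source classification loss
#'
#' Sum over source domains of the per-domain mean cross-entropy between
#' each head's predictions and the true labels; probabilities are clamped
#' away from zero so the loss stays finite.
#'
#' @param predictions_list List of N batch x C probability matrices.
#' @param labels_list List of N label vectors (0..C-1) or one-hot
#'   matrices.
#' @param clamp Lower probability bound before the logarithm.
#' @return A nonnegative scalar.
#' @export
supervised_loss <- function(predictions_list, labels_list, clamp = 1e-12) {
  if (length(predictions_list) != length(labels_list)) {
    stopf("predictions and labels must pair up per domain")
  }
  total <- 0
  for (n in seq_along(predictions_list)) {
    p <- predictions_list[[n]]
    y <- labels_list[[n]]
    if (!is.matrix(y)) y <- one_hot(y, ncol(p))
    if (!all(dim(p) == dim(y))) stopf("shape mismatch in domain %d", n)
    total <- total + mean(-rowSums(y * log(pmax(p, clamp))))
  }
  total
}

#' Total training objective
#'
#' `L_total = L_c + mu * L_local + gamma * L_global`.
#'
#' @param L_c,L_local,L_global Component losses.
#' @param mu,gamma Trade-off weights for the local alignment and global
#'   discrepancy terms.
#' @return The affine combination.
#' @export
total_loss <- function(L_c, L_local, L_global, mu, gamma) {
  stopifnot(is.finite(L_c), is.finite(L_local), is.finite(L_global))
  L_c + mu * L_local + gamma * L_global
}

#' Training configuration
#'
#' @param learning_rate Adam step size (default 0.001).
#' @param batch_size Samples drawn per domain per iteration (default 64).
#' @param max_iterations Optimisation steps (default 500).
#' @param mu Weight of the label-conditional alignment loss (default 0.5).
#' @param gamma Weight of the classifier-discrepancy loss (default 0.5).
#' @param ramp Ramp mu and gamma linearly from 0 to their targets over the
#'   first `ramp_frac` of iterations (default TRUE), a standard
#'   stabilisation while pseudo-labels are still noisy.
#' @param ramp_frac Fraction of iterations over which to ramp (default
#'   0.25).
#' @param aux_ratio Fraction lambda of the unlabeled target pool used as
#'   auxiliary training data for the alignment losses (default 1).
#' @param common_dim,specific_dim Backbone widths (see [model_config()]).
#' @param kernel A fixed [kernel_spec()], or `NULL` (default) for the
#'   per-batch [median_heuristic()].
#' @param llmmd_mode `"weighted"` or `"literal"` (see [llmmd()]).
#' @param symmetrize_omega Symmetrise the similarity weights in the global
#'   loss (default FALSE).
#' @param ensemble `"agreement"` (default) or `"uniform"` classifier
#'   weighting at prediction time (see [predict.msda_fit()]).
#' @param seed Integer seed controlling initialisation and batch sampling.
#' @param verbose Print progress every 100 iterations.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 64,
                         max_iterations = 500, mu = 0.5, gamma = 0.5,
                         ramp = TRUE, ramp_frac = 0.25, aux_ratio = 1,
                         common_dim = 64, specific_dim = 64,
                         kernel = NULL,
                         llmmd_mode = c("weighted", "literal"),
                         symmetrize_omega = FALSE,
                         ensemble = c("agreement", "uniform"),
                         seed = 1, verbose = FALSE) {
  structure(list(
    learning_rate = check_number(learning_rate, "learning_rate", min = 1e-12),
    batch_size = check_count(batch_size, "batch_size"),
    max_iterations = check_count(max_iterations, "max_iterations"),
    mu = check_number(mu, "mu", min = 0),
    gamma = check_number(gamma, "gamma", min = 0),
    ramp = isTRUE(ramp),
    ramp_frac = check_number(ramp_frac, "ramp_frac", min = 0, max = 1),
    aux_ratio = check_number(aux_ratio, "aux_ratio", min = 0, max = 1),
    common_dim = check_count(common_dim, "common_dim"),
    specific_dim = check_count(specific_dim, "specific_dim"),
    kernel = kernel,
    llmmd_mode = match.arg(llmmd_mode),
    symmetrize_omega = isTRUE(symmetrize_omega),
    ensemble = match.arg(ensemble),
    seed = check_count(seed, "seed", min = 0L),
    verbose = isTRUE(verbose)
  ), class = "train_config")
}

# normalise the accepted domain input forms to list(x, y)
as_domain <- function(d, need_labels = TRUE) {
  if (inherits(d, "feature_matrix")) {
    if (need_labels && is.null(d$labels)) {
      stopf("source feature matrix %s has no labels", d$subject_id)
    }
    return(list(x = d$features, y = d$labels))
  }
  if (is.list(d) && !is.null(d$x)) {
    return(list(x = d$x, y = d$y))
  }
  if (is.matrix(d)) return(list(x = d, y = NULL))
  stopf("cannot interpret domain input of class %s", class(d)[1])
}

# flat parameter list view used by the optimiser
param_names <- function(model) {
  N <- model$config$n_sources
  c("W1", "b1",
    paste0("V", seq_len(N)), paste0("cb", seq_len(N)),
    paste0("U", seq_len(N)), paste0("d", seq_len(N)))
}

get_param <- function(model, name) {
  if (name %in% c("W1", "b1")) return(model[[name]])
  slot <- sub("[0-9]+$", "", name)
  idx <- as.integer(sub("^[A-Za-z]+", "", name))
  model[[slot]][[idx]]
}

set_param <- function(model, name, value) {
  if (name %in% c("W1", "b1")) {
    model[[name]] <- value
  } else {
    slot <- sub("[0-9]+$", "", name)
    idx <- as.integer(sub("^[A-Za-z]+", "", name))
    model[[slot]][[idx]] <- value
  }
  model
}

softmax_backward <- function(p, dprob) {
  p * (dprob - rowSums(dprob * p))
}

# Loss and analytic parameter gradients for one step.  Batches must
# already be standardized.  Pseudo-label weights and the similarity
# weights omega are treated as constants (detached), as are the
# median-heuristic bandwidths.  `frozen` (list with `wt` per domain and
# `omega`) pins those detached quantities to externally supplied values,
# which makes the stop-gradient objective an ordinary function of the
# parameters — used by the finite-difference gradient checks.
msda_loss_grads <- function(model, source_x, source_y, target_x,
                            mu, gamma, kernel = NULL,
                            llmmd_mode = "weighted",
                            symmetrize_omega = FALSE, frozen = NULL) {
  N <- model$config$n_sources
  C <- model$config$n_classes
  grads <- list(W1 = matrix(0, nrow(model$W1), ncol(model$W1)),
                b1 = numeric(length(model$b1)))
  for (n in seq_len(N)) {
    grads[[paste0("V", n)]] <- matrix(0, nrow(model$V[[n]]),
                                      ncol(model$V[[n]]))
    grads[[paste0("cb", n)]] <- numeric(length(model$cb[[n]]))
    grads[[paste0("U", n)]] <- matrix(0, nrow(model$U[[n]]),
                                      ncol(model$U[[n]]))
    grads[[paste0("d", n)]] <- numeric(length(model$d[[n]]))
  }

  # forward: source branches
  caches <- lapply(seq_len(N), function(n)
    forward_branch(model, source_x[[n]], n))
  onehots <- lapply(seq_len(N), function(n) one_hot(source_y[[n]], C))
  L_c <- supervised_loss(lapply(caches, `[[`, "p"), onehots)

  # forward: target through the shared extractor and every branch
  need_target <- mu > 0 || gamma > 0
  L_local <- 0
  L_global <- 0
  if (need_target) {
    z1t <- sweep(target_x %*% t(model$W1), 2L, model$b1, `+`)
    ht <- relu(z1t)
    z2t <- lapply(seq_len(N), function(n)
      sweep(ht %*% t(model$V[[n]]), 2L, model$cb[[n]], `+`))
    tfeat <- lapply(z2t, relu)
    q <- lapply(seq_len(N), function(n)
      softmax_rows(sweep(tfeat[[n]] %*% t(model$U[[n]]), 2L,
                         model$d[[n]], `+`)))
    dtfeat <- lapply(tfeat, function(t_) matrix(0, nrow(t_), ncol(t_)))
    dq <- lapply(q, function(p) matrix(0, nrow(p), ncol(p)))
    ds_extra <- lapply(caches, function(cc)
      matrix(0, nrow(cc$s), ncol(cc$s)))

    if (mu > 0) {
      per_domain <- numeric(N)
      for (n in seq_len(N)) {
        ws <- source_class_weights(onehots[[n]])
        wt <- if (is.null(frozen)) target_class_weights(q[[n]])
              else frozen$wt[[n]]
        ks <- kernel %||% median_heuristic(caches[[n]]$s, tfeat[[n]])
        if (llmmd_mode == "literal") {
          # the literal 1/n^2 prefactors fold into the weights
          ws$weights <- ws$weights / nrow(caches[[n]]$s)
          wt$weights <- wt$weights / nrow(tfeat[[n]])
        }
        g <- pair_local_mmd_grad(caches[[n]]$s, ws, tfeat[[n]], wt, ks)
        per_domain[n] <- g$value
        ds_extra[[n]] <- ds_extra[[n]] + (mu / N) * g$gXs
        dtfeat[[n]] <- dtfeat[[n]] + (mu / N) * g$gXt
      }
      L_local <- mean(per_domain)
    }

    if (gamma > 0 && N >= 2) {
      gg <- global_loss_grads(q, symmetrize = symmetrize_omega,
                              omega = frozen$omega)
      L_global <- gg$value
      for (n in seq_len(N)) dq[[n]] <- dq[[n]] + gamma * gg$grads[[n]]
    }

    # backward: target path
    dht <- matrix(0, nrow(ht), ncol(ht))
    for (n in seq_len(N)) {
      dz3 <- softmax_backward(q[[n]], dq[[n]])
      grads[[paste0("U", n)]] <- grads[[paste0("U", n)]] +
        t(dz3) %*% tfeat[[n]]
      grads[[paste0("d", n)]] <- grads[[paste0("d", n)]] + colSums(dz3)
      dt <- dz3 %*% model$U[[n]] + dtfeat[[n]]
      dz2 <- dt * (z2t[[n]] > 0)
      grads[[paste0("V", n)]] <- grads[[paste0("V", n)]] + t(dz2) %*% ht
      grads[[paste0("cb", n)]] <- grads[[paste0("cb", n)]] + colSums(dz2)
      dht <- dht + dz2 %*% model$V[[n]]
    }
    dz1t <- dht * (z1t > 0)
    grads$W1 <- grads$W1 + t(dz1t) %*% target_x
    grads$b1 <- grads$b1 + colSums(dz1t)
  }

  # backward: source branches (cross-entropy + local-alignment pull)
  for (n in seq_len(N)) {
    cc <- caches[[n]]
    B <- nrow(cc$p)
    dz3 <- (cc$p - onehots[[n]]) / B
    grads[[paste0("U", n)]] <- grads[[paste0("U", n)]] + t(dz3) %*% cc$s
    grads[[paste0("d", n)]] <- grads[[paste0("d", n)]] + colSums(dz3)
    ds <- dz3 %*% model$U[[n]] + if (need_target) ds_extra[[n]] else 0
    dz2 <- ds * (cc$z2 > 0)
    grads[[paste0("V", n)]] <- grads[[paste0("V", n)]] + t(dz2) %*% cc$h
    grads[[paste0("cb", n)]] <- grads[[paste0("cb", n)]] + colSums(dz2)
    dh <- dz2 %*% model$V[[n]]
    dz1 <- dh * (cc$z1 > 0)
    grads$W1 <- grads$W1 + t(dz1) %*% cc$x
    grads$b1 <- grads$b1 + colSums(dz1)
  }

  list(losses = list(L_c = L_c, L_local = L_local, L_global = L_global,
                     L_total = total_loss(L_c, L_local, L_global, mu, gamma)),
       grads = grads)
}

adam_init <- function(model) {
  nm <- param_names(model)
  st <- list(t = 0L, m = list(), v = list())
  for (name in nm) {
    p <- get_param(model, name)
    st$m[[name]] <- p * 0
    st$v[[name]] <- p * 0
  }
  st
}

adam_step <- function(model, grads, opt, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (name in param_names(model)) {
    g <- grads[[name]]
    opt$m[[name]] <- beta1 * opt$m[[name]] + (1 - beta1) * g
    opt$v[[name]] <- beta2 * opt$v[[name]] + (1 - beta2) * g^2
    upd <- lr * (opt$m[[name]] / bc1) / (sqrt(opt$v[[name]] / bc2) + eps)
    model <- set_param(model, name, get_param(model, name) - upd)
  }
  list(model = model, opt = opt)
}

#' Train the multi-source adaptation model
#'
#' Optimises `L_total = L_c + mu L_local + gamma L_global` with Adam: the
#' supervised cross-entropy of every head on its own source, the
#' label-conditional weighted MMD between each source's specific features
#' and the target's, and the similarity-weighted discrepancy between the
#' heads' predictions on the target.  Each iteration samples `batch_size`
#' rows from every source and from the auxiliary target pool (`aux_ratio`
#' of the unlabeled target).  Target labels are never read: the target
#' input's labels, if any, are discarded on entry.
#'
#' @param sources List of N >= 2 labeled domains: [feature_matrix()]
#'   objects or `list(x, y)` with `y` in 0..C-1.
#' @param target Unlabeled target domain: a matrix or a
#'   [feature_matrix()] (labels ignored).
#' @param config A [train_config()].
#' @return An object of class `msda_fit`: the trained `model`, the
#'   per-iteration loss `history` (with the effective mu and gamma at each
#'   step), and the auxiliary-pool indices `aux_idx`.
#' @export
train <- function(sources, target, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  N <- length(sources)
  if (N < 2L) stopf("at least two source domains are required")
  doms <- lapply(sources, as_domain, need_labels = TRUE)
  tgt <- as_domain(target, need_labels = FALSE)$x  # labels dropped here
  dims <- vapply(doms, function(d) ncol(d$x), integer(1))
  if (length(unique(c(dims, ncol(tgt)))) != 1L) {
    stopf("feature dimension differs across domains")
  }
  D <- dims[[1]]
  C <- length(unique(unlist(lapply(doms, `[[`, "y"))))
  C <- max(2L, C)

  # per-feature standardization from the pooled sources
  n_tot <- sum(vapply(doms, function(d) nrow(d$x), integer(1)))
  mu_f <- Reduce(`+`, lapply(doms, function(d) colSums(d$x))) / n_tot
  ssq <- Reduce(`+`, lapply(doms, function(d)
    colSums(sweep(d$x, 2L, mu_f)^2))) / n_tot
  sd_f <- sqrt(pmax(ssq, 1e-12))

  mconf <- model_config(D, N, n_classes = C,
                        common_dim = config$common_dim,
                        specific_dim = config$specific_dim)
  model <- init_model(mconf, seed = config$seed)
  model$feature_center <- mu_f
  model$feature_scale <- sd_f
  opt <- adam_init(model)

  history <- data.frame(iteration = integer(0), L_c = numeric(0),
                        L_local = numeric(0), L_global = numeric(0),
                        L_total = numeric(0), mu = numeric(0),
                        gamma = numeric(0))
  ramp_end <- max(1, ceiling(config$ramp_frac * config$max_iterations))

  with_seed(child_seed(config$seed, 1L), {
    n_aux <- max(1L, floor(config$aux_ratio * nrow(tgt)))
    aux_idx <- sample.int(nrow(tgt), n_aux)
    aux <- tgt[aux_idx, , drop = FALSE]
    hist_rows <- vector("list", config$max_iterations)
    for (it in seq_len(config$max_iterations)) {
      r <- if (config$ramp) min(1, it / ramp_end) else 1
      mu_t <- config$mu * r
      gamma_t <- config$gamma * r
      bx <- vector("list", N)
      by <- vector("list", N)
      for (n in seq_len(N)) {
        ns <- nrow(doms[[n]]$x)
        idx <- sample.int(ns, min(config$batch_size, ns),
                          replace = ns < config$batch_size)
        bx[[n]] <- standardize_batch(model, doms[[n]]$x[idx, , drop = FALSE])
        by[[n]] <- doms[[n]]$y[idx]
      }
      tb_idx <- sample.int(nrow(aux), min(config$batch_size, nrow(aux)),
                           replace = nrow(aux) < config$batch_size)
      tb <- standardize_batch(model, aux[tb_idx, , drop = FALSE])

      res <- msda_loss_grads(model, bx, by, tb, mu_t, gamma_t,
                             kernel = config$kernel,
                             llmmd_mode = config$llmmd_mode,
                             symmetrize_omega = config$symmetrize_omega)
      st <- adam_step(model, res$grads, opt, config$learning_rate)
      model <- st$model
      opt <- st$opt
      model$step <- it
      hist_rows[[it]] <- data.frame(
        iteration = it, L_c = res$losses$L_c,
        L_local = res$losses$L_local, L_global = res$losses$L_global,
        L_total = res$losses$L_total, mu = mu_t, gamma = gamma_t)
      if (config$verbose && it %% 100 == 0) {
        message(sprintf("iter %4d  L_total %.4f (L_c %.4f)", it,
                        res$losses$L_total, res$losses$L_c))
      }
    }
    history <- do.call(rbind, hist_rows)
  })
  structure(list(model = model, history = history, aux_idx = aux_idx,
                 config = config),
            class = "msda_fit")
}

#' @export
print.msda_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<msda_fit> %d sources, %d iterations, final L_total %.4f\n",
              x$model$config$n_sources, nrow(x$history), last$L_total))
  invisible(x)
}

classifier_probs <- function(model, x, chunk = 4096L) {
  N <- model$config$n_sources
  n <- nrow(x)
  out <- lapply(seq_len(N), function(n_)
    matrix(0, n, model$config$n_classes))
  starts <- seq.int(1L, n, by = chunk)
  for (s in starts) {
    e <- min(s + chunk - 1L, n)
    h <- common_features(model, x[s:e, , drop = FALSE])
    for (n_ in seq_len(N)) {
      sf <- specific_features(model, h, n_)
      out[[n_]][s:e, ] <- classify(model, sf, n_)
    }
  }
  out
}

ensemble_weights <- function(probs_list, mode = "agreement") {
  N <- length(probs_list)
  if (mode == "uniform" || N < 3L) return(rep(1 / N, N))
  tab <- discrepancy_table(probs_list)
  if (all(tab$d == 0)) return(rep(1 / N, N))
  wbar <- (tab$omega + t(tab$omega)) / 2
  agree <- vapply(seq_len(N), function(n) sum(1 - wbar[n, -n]), numeric(1))
  agree <- pmax(agree, 0)
  if (sum(agree) <= 0) return(rep(1 / N, N))
  agree / sum(agree)
}

#' Predict target labels with the classifier ensemble
#'
#' Every head predicts the target batch; the final distribution is the
#' weighted average of the N heads.  With `ensemble = "agreement"` a
#' head's weight grows with how closely the other heads agree with it
#' (via the symmetrised similarity weights); `"uniform"` averages the
#' heads equally.  The predicted label is the arg-max, ties broken toward
#' the lower class index.
#'
#' @param object An `msda_fit` from [train()].
#' @param target Matrix or [feature_matrix()] of target samples.
#' @param ... Unused.
#' @return A list of class `msda_prediction`: integer `labels` (0-based),
#'   ensemble `probs`, `per_classifier` probability matrices and the
#'   ensemble `weights`.
#' @export
predict.msda_fit <- function(object, target, ...) {
  model <- object$model
  if (model$step < 1L) stopf("model has not been trained")
  x <- as_domain(target, need_labels = FALSE)$x
  probs_list <- classifier_probs(model, x)
  w <- ensemble_weights(probs_list, object$config$ensemble %||% "agreement")
  probs <- Reduce(`+`, Map(function(p, wi) p * wi, probs_list, w))
  labels <- max.col(probs, ties.method = "first") - 1L
  structure(list(labels = labels, probs = probs,
                 per_classifier = probs_list, weights = w),
            class = "msda_prediction")
}

#' Confusion-matrix metrics for binary fatigue classification
#'
#' Standard binary metrics with fatigue (label 1) as the positive class:
#' accuracy, precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and F1, all as
#' percentages, together with the confusion counts they derive from.
#'
#' @param truth True labels (0 awake / 1 fatigue).
#' @param predicted Predicted labels, or an `msda_prediction`.
#' @param positive The positive class (default 1, fatigue).
#' @param subject_id Optional identifier carried into the row.
#' @return A one-row data frame with `subject_id`, `accuracy`,
#'   `precision`, `recall`, `f1` (percent) and `tp`, `fp`, `fn`, `tn`.
#' @export
evaluate_predictions <- function(truth, predicted, positive = 1L,
                                 subject_id = NA_character_) {
  if (inherits(predicted, "msda_prediction")) predicted <- predicted$labels
  if (length(truth) != length(predicted)) {
    stopf("truth and predictions must have equal length")
  }
  if (length(truth) == 0L) stopf("cannot evaluate an empty prediction set")
  tp <- sum(truth == positive & predicted == positive)
  fp <- sum(truth != positive & predicted == positive)
  fn <- sum(truth == positive & predicted != positive)
  tn <- sum(truth != positive & predicted != positive)
  acc <- (tp + tn) / length(truth)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  data.frame(subject_id = subject_id, accuracy = 100 * acc,
             precision = 100 * prec, recall = 100 * rec, f1 = 100 * f1,
             tp = tp, fp = fp, fn = fn, tn = tn,
             stringsAsFactors = FALSE)
}

#' Leave-one-subject-out cross-subject evaluation
#'
#' Holds out each subject in turn as the unlabeled target, trains the
#' adaptation model on the remaining subjects (one source domain each),
#' predicts the held-out subject and scores the prediction.  The target's
#' labels are used only for scoring, never for training.  When
#' `config$aux_ratio < 1` the model trains on the auxiliary fraction of
#' the target and is evaluated on the remaining segments; otherwise it is
#' evaluated on the full target.
#'
#' @param features List of labeled [feature_matrix()] objects, one per
#'   subject (at least 3).
#' @param config A [train_config()]; each fold derives its own seed from
#'   `config$seed`.
#' @return A data frame of per-subject metric rows plus a final `"Avg"`
#'   row averaging the percentage metrics.
#' @export
loso_experiment <- function(features, config = train_config()) {
  if (length(features) < 3L) stopf("at least 3 subjects are required")
  rows <- vector("list", length(features))
  for (i in seq_along(features)) {
    tgt_fm <- features[[i]]
    truth <- tgt_fm$labels
    if (is.null(truth)) stopf("subject %d has no labels to score against", i)
    fold_cfg <- config
    fold_cfg$seed <- child_seed(config$seed, i)
    fit <- train(features[-i], tgt_fm$features, fold_cfg)
    eval_idx <- if (config$aux_ratio < 1) {
      setdiff(seq_len(nrow(tgt_fm$features)), fit$aux_idx)
    } else {
      seq_len(nrow(tgt_fm$features))
    }
    pred <- predict(fit, tgt_fm$features[eval_idx, , drop = FALSE])
    rows[[i]] <- evaluate_predictions(
      truth[eval_idx], pred,
      subject_id = tgt_fm$subject_id %||% sprintf("S%02d", i))
    if (config$verbose) {
      message(sprintf("fold %2d (%s): accuracy %.2f%%", i,
                      rows[[i]]$subject_id, rows[[i]]$accuracy))
    }
  }
  tab <- do.call(rbind, rows)
  avg <- data.frame(subject_id = "Avg",
                    accuracy = mean(tab$accuracy),
                    precision = mean(tab$precision),
                    recall = mean(tab$recall), f1 = mean(tab$f1),
                    tp = NA_integer_, fp = NA_integer_,
                    fn = NA_integer_, tn = NA_integer_,
                    stringsAsFactors = FALSE)
  rbind(tab, avg)
}
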