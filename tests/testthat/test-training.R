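test_that("supervised loss matches closed forms and the hand-rolled oracle", {
  y <- c(0L, 1L, 1L)
  perfect <- one_hot(y, 2)
  expect_equal(supervised_loss(list(perfect), list(y)), 0, tolerance = 1e-9)
  uniform <- matrix(0.5, 4, 2)
  expect_equal(supervised_loss(list(uniform), list(c(0L, 0L, 1L, 1L))),
               log(2), tolerance = 1e-12)
  expect_equal(supervised_loss(list(uniform, uniform),
                               list(c(0L, 1L, 0L, 1L), c(1L, 1L, 0L, 0L))),
               2 * log(2), tolerance = 1e-12)
  set.seed(61)
  for (i in 1:20) {
    N <- sample(1:3, 1)
    preds <- lapply(seq_len(N), function(j) random_probs(6, 2))
    labs <- lapply(seq_len(N), function(j) sample(0:1, 6, TRUE))
    expect_equal(supervised_loss(preds, labs),
                 oracle_cross_entropy(preds, labs), tolerance = 1e-10)
  }
  # zero probability at the true class stays finite
  expect_true(is.finite(supervised_loss(list(rbind(c(0, 1))), list(0L))))
})

test_that("total loss is the exact affine combination", {
  expect_equal(total_loss(1.0, 0.5, 0.2, 1, 1), 1.7)
  expect_equal(total_loss(3, 7, 11, 0, 0), 3)
  expect_equal(total_loss(1, 2, 3, 0.5, 0.25) - total_loss(1, 0, 3, 0.5, 0.25),
               0.5 * 2)
})

test_that("analytic gradients match finite differences of the objective", {
  set.seed(62)
  N <- 3; D <- 6
  m <- init_model(model_config(D, N, common_dim = 5, specific_dim = 4), 9)
  sx <- lapply(1:N, function(i) matrix(rnorm(8 * D), 8))
  sy <- lapply(1:N, function(i) sample(0:1, 8, TRUE))
  tx <- matrix(rnorm(7 * D), 7)
  ks <- kernel_spec(c(0.7, 1.3))
  base_q <- lapply(1:N, function(n) {
    h <- common_features(m, tx)
    classify(m, specific_features(m, h, n), n)
  })
  frozen <- list(wt = lapply(base_q, target_class_weights),
                 omega = similarity_weights(base_q))
  f <- function(model) {
    eegmsda:::msda_loss_grads(model, sx, sy, tx, mu = 0.6, gamma = 0.4,
                              kernel = ks, frozen = frozen)$losses$L_total
  }
  res <- eegmsda:::msda_loss_grads(m, sx, sy, tx, mu = 0.6, gamma = 0.4,
                                   kernel = ks, frozen = frozen)
  eps <- 1e-6
  for (nm in eegmsda:::param_names(m)) {
    p <- eegmsda:::get_param(m, nm)
    g <- res$grads[[nm]]
    idx <- if (length(p) > 5) sample(length(p), 5) else seq_along(p)
    for (i in idx) {
      p2 <- p
      p2[i] <- p[i] + eps
      up <- f(eegmsda:::set_param(m, nm, p2))
      p2[i] <- p[i] - eps
      dn <- f(eegmsda:::set_param(m, nm, p2))
      num <- (up - dn) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-4)
    }
  }
})

test_that("training is reproducible and decreases the objective", {
  blobs <- make_blob_domains(blob_spec(n_domains = 4, n_per_class = 60,
                                       dim = 6, domain_shift_scale = 0.5,
                                       seed = 71))
  cfg <- train_config(max_iterations = 200, batch_size = 32,
                      common_dim = 16, specific_dim = 16, seed = 5)
  fit1 <- train(blobs$sources, blobs$target_x, cfg)
  fit2 <- train(blobs$sources, blobs$target_x, cfg)
  expect_identical(fit1$model$W1, fit2$model$W1)
  expect_equal(fit1$history, fit2$history)
  expect_lt(fit1$history$L_total[200], fit1$history$L_total[1])
  expect_equal(fit1$history$L_total,
               fit1$history$L_c + fit1$history$mu * fit1$history$L_local +
                 fit1$history$gamma * fit1$history$L_global,
               tolerance = 1e-12)
  expect_error(train(blobs$sources[1], blobs$target_x, cfg), "at least two")
})

test_that("the ablation run optimises the supervised loss only", {
  blobs <- make_blob_domains(blob_spec(n_domains = 4, n_per_class = 40,
                                       dim = 6, seed = 72))
  cfg <- train_config(max_iterations = 50, batch_size = 16, mu = 0,
                      gamma = 0, common_dim = 8, specific_dim = 8, seed = 6)
  fit <- train(blobs$sources, blobs$target_x, cfg)
  expect_equal(fit$history$L_total, fit$history$L_c)
  expect_true(all(fit$history$L_local == 0))
  expect_true(all(fit$history$L_global == 0))
})

test_that("target labels are never read during training or prediction", {
  blobs <- make_blob_domains(blob_spec(n_domains = 4, n_per_class = 40,
                                       dim = 6, seed = 73))
  cfg <- train_config(max_iterations = 50, batch_size = 16,
                      common_dim = 8, specific_dim = 8, seed = 7)
  tgt_with_labels <- feature_matrix(blobs$target_x, blobs$target_labels,
                                    subject_id = "T")
  tgt_wrong <- feature_matrix(blobs$target_x, rev(blobs$target_labels),
                              subject_id = "T")
  fit1 <- train(blobs$sources, tgt_with_labels, cfg)
  fit2 <- train(blobs$sources, tgt_wrong, cfg)
  fit3 <- train(blobs$sources, blobs$target_x, cfg)
  expect_identical(fit1$model, fit2$model)
  expect_identical(fit1$model, fit3$model)
  expect_identical(predict(fit1, tgt_with_labels)$labels,
                   predict(fit3, blobs$target_x)$labels)
})

test_that("ensemble prediction averages heads and breaks ties downward", {
  blobs <- make_blob_domains(blob_spec(n_domains = 3, n_per_class = 30,
                                       dim = 4, seed = 74))
  cfg <- train_config(max_iterations = 30, batch_size = 16, common_dim = 8,
                      specific_dim = 8, seed = 8, ensemble = "uniform")
  fit <- train(blobs$sources, blobs$target_x, cfg)
  pred <- predict(fit, blobs$target_x)
  manual <- Reduce(`+`, pred$per_classifier) / length(pred$per_classifier)
  expect_equal(pred$probs, manual, tolerance = 1e-12)
  expect_equal(pred$labels, max.col(manual, ties.method = "first") - 1L)
  # hand arithmetic: equal-weight mean of [.9,.1] and [.7,.3] -> class 0
  mean_p <- (c(0.9, 0.1) + c(0.7, 0.3)) / 2
  expect_equal(mean_p, c(0.8, 0.2))
  expect_equal(which.max(mean_p) - 1L, 0L)
  # exact tie goes to the lower class index
  expect_equal(max.col(rbind(c(0.5, 0.5)), ties.method = "first") - 1L, 0L)
  untrained <- fit
  untrained$model$step <- 0L
  expect_error(predict(untrained, blobs$target_x), "not been trained")
})

test_that("confusion-matrix metrics follow the textbook formulas", {
  truth <- c(rep(1, 60), rep(0, 40))
  pred <- c(rep(1, 40), rep(0, 20), rep(1, 10), rep(0, 30))
  row <- evaluate_predictions(truth, pred)
  expect_equal(row$tp, 40); expect_equal(row$fp, 10)
  expect_equal(row$fn, 20); expect_equal(row$tn, 30)
  expect_equal(row$accuracy, 70)
  expect_equal(row$precision, 80)
  expect_equal(row$recall, 66.67, tolerance = 1e-3)
  expect_equal(row$f1, 72.73, tolerance = 1e-3)
  perm <- sample(100)
  expect_equal(evaluate_predictions(truth[perm], pred[perm])[, -1],
               row[, -1])
  all_right <- evaluate_predictions(c(0, 1, 1), c(0, 1, 1))
  expect_equal(all_right$accuracy, 100)
  expect_error(evaluate_predictions(integer(0), integer(0)), "empty")
})

test_that("the LOSO harness produces one row per subject plus an average", {
  sp <- cohort_spec(n_subjects = 3, n_channels = 4, segments_per_class = 40,
                    seed = 75)
  feats <- extract_features(simulate_cohort(sp))
  cfg <- train_config(max_iterations = 60, batch_size = 16, common_dim = 8,
                      specific_dim = 8, seed = 9)
  tab <- loso_experiment(feats, cfg)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$subject_id, c("S01", "S02", "S03", "Avg"))
  expect_equal(tab$accuracy[4], mean(tab$accuracy[1:3]))
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 100))
  expect_error(loso_experiment(feats[1:2], cfg), "at least 3")
})

test_that("the auxiliary ratio reserves target segments for evaluation", {
  blobs <- make_blob_domains(blob_spec(n_domains = 3, n_per_class = 40,
                                       dim = 4, seed = 76))
  cfg <- train_config(max_iterations = 20, batch_size = 16, common_dim = 8,
                      specific_dim = 8, aux_ratio = 0.6, seed = 10)
  fit <- train(blobs$sources, blobs$target_x, cfg)
  expect_length(fit$aux_idx, floor(0.6 * nrow(blobs$target_x)))
})
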