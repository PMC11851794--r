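test_that("fold planning is stratified, deterministic, and leak-free", {
  subjects <- c(sprintf("mdd%02d", 1:30), sprintf("hc%02d", 1:28))
  labels <- c(rep(1, 30), rep(0, 28))
  plan <- plan_folds(subjects, labels, k = 5, seed = 3)
  sizes <- sort(as.numeric(table(plan$fold)), decreasing = TRUE)
  expect_equal(sizes, c(12, 12, 12, 11, 11))
  # within-class fold sizes differ by at most one
  for (cl in 0:1) {
    t <- table(plan$fold[plan$label == cl])
    expect_lte(diff(range(t)), 1)
  }
  expect_identical(plan, plan_folds(subjects, labels, k = 5, seed = 3))
  expect_false(identical(plan$fold,
                         plan_folds(subjects, labels, k = 5, seed = 4)$fold))
  expect_true(assert_no_leakage(plan))
  # every subject in exactly one fold
  expect_equal(sort(plan$subject_id), sort(subjects))
  expect_error(plan_folds(c("a", "b", "c"), c(1, 1, 0), k = 2),
               "fewer subjects")
})

test_that("leakage assertion actually fires on a corrupted plan", {
  plan <- data.frame(subject_id = c("a", "b", "c", "a"),
                     label = c(0, 1, 0, 1), fold = c(1, 1, 2, 2))
  expect_error(assert_no_leakage(plan), "leakage")
})

test_that("classification metrics match hand-computed confusion tables", {
  m <- classification_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unlist(m[c("acc", "pre", "rec", "f1")]), rep(1, 4),
               ignore_attr = TRUE)
  m <- classification_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
  expect_equal(m$acc, 0.75)
  expect_equal(m$pre, 1)
  expect_equal(m$rec, 0.5)
  expect_equal(m$f1, 2 / 3)
  # all-positive predictor on a balanced set
  m <- classification_metrics(c(1, 1, 0, 0), c(1, 1, 1, 1))
  expect_equal(m$acc, 0.5)
  expect_equal(m$rec, 1)
  # zero-denominator metrics are 0 with a warning
  w <- capture_warnings(m <- classification_metrics(c(0, 0), c(0, 0)))
  expect_match(w, "undefined", all = FALSE)
  expect_equal(m$pre, 0)
})

make_toy_samples <- function(n_subj = 8, per_subj = 6, seed = 1,
                             effect = 3) {
  # separable toy: label-1 subjects get an amplitude boost on channel 1
  set.seed(seed)
  samples <- list()
  for (s in seq_len(n_subj)) {
    lab <- as.integer(s > n_subj / 2)
    for (k in seq_len(per_subj)) {
      x <- array(rnorm(2 * 32 * 5 * 5), c(2, 32, 5, 5))
      if (lab == 1) x[1, , 2, 2] <- x[1, , 2, 2] * effect
      samples[[length(samples) + 1L]] <-
        structure(list(tensor = x, subject_id = sprintf("s%02d", s),
                       label = lab, segment_index = k),
                  class = "tsf_sample")
    }
  }
  samples
}

test_that("training reduces the loss and early stopping respects patience", {
  samples <- make_toy_samples()
  cfg <- tiny_caps_config()
  ctl <- train_control(learning_rate = 1e-3, batch_size = 8,
                       max_epochs = 8, patience = 2, seed = 1)
  fit <- train_fold(samples, cfg, ctl)
  h <- fit$history
  expect_lt(h$train_loss[fit$best_epoch], h$train_loss[1])
  expect_lte(fit$best_epoch, fit$stopped_epoch)
  # stopping happens exactly `patience` non-improving epochs after the best
  if (fit$stopped_epoch < 8)
    expect_equal(fit$stopped_epoch, fit$best_epoch + 2)
  expect_error(train_fold(samples[1:6], cfg, ctl), "single class")
})

test_that("training is deterministic for a fixed seed", {
  samples <- make_toy_samples(n_subj = 6, per_subj = 4)
  cfg <- tiny_caps_config()
  ctl <- train_control(learning_rate = 1e-3, batch_size = 8,
                       max_epochs = 3, patience = 3, seed = 7)
  f1 <- train_fold(samples, cfg, ctl)
  f2 <- train_fold(samples, cfg, ctl)
  expect_identical(f1$history, f2$history)
  e1 <- evaluate_model(f1$model, samples)
  e2 <- evaluate_model(f2$model, samples)
  expect_identical(e1$metrics, e2$metrics)
})

test_that("evaluation reports per-sample predictions consistent with metrics", {
  samples <- make_toy_samples(n_subj = 6, per_subj = 4)
  cfg <- tiny_caps_config()
  m <- capsnet_init(cfg, seed = 2)
  res <- evaluate_model(m, samples)
  expect_equal(nrow(res$predictions), length(samples))
  recomputed <- classification_metrics(res$predictions$label,
                                       res$predictions$pred)
  expect_identical(res$metrics[c("acc", "pre", "rec", "f1")],
                   recomputed[c("acc", "pre", "rec", "f1")])
})

test_that("cross-validation refuses leaks and aggregates fold metrics", {
  samples <- make_toy_samples(n_subj = 8, per_subj = 4)
  subjects <- sprintf("s%02d", 1:8)
  labels <- as.integer(1:8 > 4)
  plan <- plan_folds(subjects, labels, k = 2, seed = 1)
  cfg <- tiny_caps_config()
  ctl <- train_control(learning_rate = 1e-3, batch_size = 8,
                       max_epochs = 2, patience = 2, seed = 1)
  cv <- cross_validate(samples, plan, cfg, ctl)
  expect_length(cv$folds, 2L)
  accs <- vapply(cv$folds, function(f) f$metrics$acc, 0)
  expect_equal(cv$summary$mean[cv$summary$metric == "acc"], mean(accs))
  # no test subject ever appears among its fold's training subjects
  for (f in cv$folds) {
    test_subj <- unique(f$predictions$subject_id)
    train_subj <- plan$subject_id[plan$fold != f$fold]
    expect_length(intersect(test_subj, train_subj), 0L)
  }
  # pooled predictions cover every sample exactly once
  expect_equal(nrow(cv$predictions), length(samples))
  # a plan that misses subjects is rejected
  expect_error(cross_validate(samples, plan[-1, ], cfg, ctl),
               "does not cover")
})

test_that("embedding export produces correctly shaped tables per stage", {
  samples <- make_toy_samples(n_subj = 4, per_subj = 3)
  cfg <- tiny_caps_config()
  m <- capsnet_init(cfg, seed = 3)
  emb_in <- export_embeddings(m, samples, "input")
  expect_equal(nrow(emb_in), 12L)
  expect_equal(ncol(emb_in) - 2L, 2L * 32L * 5L * 5L)
  emb_cb <- export_embeddings(m, samples, "conv_block")
  expect_equal(ncol(emb_cb) - 2L, cfg$conv2d_filters * cfg$h_out * cfg$w_out)
  emb_out <- export_embeddings(m, samples, "output")
  expect_equal(ncol(emb_out) - 2L, cfg$n_class * cfg$d_e)
  expect_equal(emb_out$label, vapply(samples, function(s) s$label, 0))
  expect_error(export_embeddings(m, samples, "bogus"))
})
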