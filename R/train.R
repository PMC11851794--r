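#' Subject-independent training and evaluation
#'
#' Cross-validation is planned at the *subject* level: every subject's
#' segments land in exactly one fold, so no identity information can leak
#' between training and test.  Training uses Adam on the margin loss
#' (cross-entropy for the `conv_fc` variant) with early stopping on a
#' subject-held-out tuning split, and evaluation reports accuracy,
#' precision, recall and F1 with the patient class (label 1) as positive.
#'
#' @name training
NULL

#' Training control parameters
#'
#' Defaults follow the reference protocol: Adam with learning rate 1e-4,
#' batch size 32, early stopping (patience 10 on the tuning loss, up to 100
#' epochs, best checkpoint restored), 20% of training *subjects* held out
#' for tuning.
#'
#' @param learning_rate,beta1,beta2,adam_eps Adam settings.
#' @param weight_decay decoupled (AdamW-style) weight decay applied to the
#'   weight matrices (not biases or BN parameters).  Default 0 -- the
#'   reference protocol states plain Adam; desk-scale runs on small cohorts
#'   overfit without it.
#' @param batch_size minibatch size.
#' @param max_epochs,patience early-stopping controls.
#' @param tuning_frac fraction of training subjects held out for the tuning
#'   split (subject-level, so the split itself cannot leak).
#' @param seed RNG seed for shuffling, initialization and the tuning split.
#' @param verbose print per-epoch losses.
#' @export
train_control <- function(learning_rate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                          adam_eps = 1e-8, weight_decay = 0,
                          batch_size = 32L,
                          max_epochs = 100L, patience = 10L,
                          tuning_frac = 0.2, seed = 1L, verbose = FALSE) {
  list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
       adam_eps = adam_eps, weight_decay = weight_decay,
       batch_size = batch_size,
       max_epochs = max_epochs, patience = patience,
       tuning_frac = tuning_frac, seed = seed, verbose = verbose)
}

adam_init <- function(params) {
  flat <- flatten_params(params)
  list(m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0), t = 0L)
}

flatten_params <- function(params) {
  out <- list()
  for (nm in names(params)) {
    if (nm %in% c("bn1", "bn2")) {
      out[[paste0(nm, ".gamma")]] <- params[[nm]]$gamma
      out[[paste0(nm, ".beta")]] <- params[[nm]]$beta
    } else out[[nm]] <- params[[nm]]
  }
  out
}

flatten_grads <- function(grads) {
  out <- list()
  for (nm in names(grads)) {
    if (nm %in% c("bn1", "bn2")) {
      out[[paste0(nm, ".gamma")]] <- grads[[nm]]$gamma
      out[[paste0(nm, ".beta")]] <- grads[[nm]]$beta
    } else out[[nm]] <- grads[[nm]]
  }
  out
}

unflatten_into <- function(params, flat) {
  for (nm in names(flat)) {
    if (grepl("^bn[12]\\.", nm)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      params[[parts[1]]][[parts[2]]] <- flat[[nm]]
    } else params[[nm]] <- flat[[nm]]
  }
  params
}

adam_step <- function(params, grads, state, ctl) {
  flat_p <- flatten_params(params)
  flat_g <- flatten_grads(grads)
  state$t <- state$t + 1L
  bc1 <- 1 - ctl$beta1^state$t
  bc2 <- 1 - ctl$beta2^state$t
  wd <- if (is.null(ctl$weight_decay)) 0 else ctl$weight_decay
  for (nm in names(flat_g)) {
    g <- flat_g[[nm]]
    state$m[[nm]] <- ctl$beta1 * state$m[[nm]] + (1 - ctl$beta1) * g
    state$v[[nm]] <- ctl$beta2 * state$v[[nm]] + (1 - ctl$beta2) * g^2
    flat_p[[nm]] <- flat_p[[nm]] - ctl$learning_rate *
      (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + ctl$adam_eps)
    if (wd > 0 && startsWith(nm, "w"))
      flat_p[[nm]] <- flat_p[[nm]] * (1 - ctl$learning_rate * wd)
  }
  list(params = unflatten_into(params, flat_p), state = state)
}

#' Plan a stratified, subject-independent K-fold split
#'
#' Subjects are shuffled within each class (seeded) and dealt round-robin to
#' the folds, so fold sizes within a class differ by at most one and every
#' subject sits in exactly one fold.
#'
#' @param subject_ids character vector, one entry per subject.
#' @param labels 0/1 vector aligned with `subject_ids`.
#' @param k number of folds (default 5).
#' @param seed shuffle seed.
#' @return data.frame (subject_id, label, fold) with folds in `1:k`.
#' @export
plan_folds <- function(subject_ids, labels, k = 5L, seed = 1L) {
  stopifnot(length(subject_ids) == length(labels),
            !anyDuplicated(subject_ids))
  for (cl in unique(labels)) {
    if (sum(labels == cl) < k)
      stop("class ", cl, " has fewer subjects (", sum(labels == cl),
           ") than folds (", k, ")")
  }
  set.seed(seed)
  plan <- data.frame(subject_id = subject_ids, label = labels,
                     fold = NA_integer_, stringsAsFactors = FALSE)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    plan$fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  plan
}

#' Assert that a fold plan leaks no subject
#'
#' Checks programmatically that, for every fold, no subject contributes
#' samples to both the train and the test side.
#'
#' @param plan from [plan_folds()].
#' @param sample_subjects subject id per sample (defaults to the plan's
#'   subjects, one sample each).
#' @return TRUE invisibly; stops on leakage.
#' @export
assert_no_leakage <- function(plan, sample_subjects = plan$subject_id) {
  for (f in sort(unique(plan$fold))) {
    test_subj <- plan$subject_id[plan$fold == f]
    train_subj <- plan$subject_id[plan$fold != f]
    overlap <- intersect(unique(sample_subjects[sample_subjects %in% test_subj]),
                         unique(sample_subjects[sample_subjects %in% train_subj]))
    both <- intersect(test_subj, train_subj)
    if (length(both) > 0L || length(overlap) > 0L)
      stop("subject leakage in fold ", f, ": ",
           paste(union(both, overlap), collapse = ", "))
  }
  invisible(TRUE)
}

sample_labels <- function(samples)
  vapply(samples, function(s) as.integer(s$label), integer(1))

sample_subjects <- function(samples)
  vapply(samples, function(s) as.character(s$subject_id), character(1))

eval_loss <- function(model, samples, labels, batch_size = 32L) {
  n <- length(samples)
  idx <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  tot <- 0
  for (ii in idx) {
    fwd <- capsnet_forward(model, samples[ii], training = FALSE)
    if (model$config$variant == "conv_fc") {
      onehot <- outer(seq_len(model$config$n_class) - 1L, labels[ii], "==") * 1
      tot <- tot + sum(-colSums(onehot * log(fwd$probs + 1e-12)))
    } else {
      tot <- tot + sum(margin_loss_batch(fwd$norms, labels[ii],
                                         model$config))
    }
  }
  tot / n
}

#' Train one fold's model
#'
#' Splits the training subjects into a fit set and a tuning set
#' (subject-level, stratified), minimizes the margin loss (cross-entropy for
#' `conv_fc`) with Adam, and early-stops when the tuning loss has not
#' improved for `patience` consecutive epochs, restoring the best
#' checkpoint.
#'
#' @param samples list of `tsf_sample` (training subjects only).
#' @param config a `capsnet_config`.
#' @param control from [train_control()].
#' @return List: `model` (best checkpoint), `history` (per-epoch data.frame
#'   of train/tuning loss), `stopped_epoch`, `best_epoch`.
#' @export
train_fold <- function(samples, config, control = train_control()) {
  labels <- sample_labels(samples)
  subjects <- sample_subjects(samples)
  if (length(unique(labels)) < 2L)
    stop("training set contains a single class")
  set.seed(control$seed)
  # subject-level stratified tuning split
  subj_tab <- unique(data.frame(subject_id = subjects, label = labels,
                                stringsAsFactors = FALSE))
  tune_subj <- character()
  for (cl in unique(subj_tab$label)) {
    ids <- subj_tab$subject_id[subj_tab$label == cl]
    n_tune <- max(1L, round(control$tuning_frac * length(ids)))
    n_tune <- min(n_tune, length(ids) - 1L)
    if (n_tune > 0L) tune_subj <- c(tune_subj, sample(ids, n_tune))
  }
  is_tune <- subjects %in% tune_subj
  fit_idx <- which(!is_tune)
  tune_idx <- which(is_tune)
  if (length(unique(labels[fit_idx])) < 2L)
    stop("fit split lost a class; too few subjects for the tuning fraction")

  model <- capsnet_init(config, seed = control$seed)
  state <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  wait <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        tuning_loss = numeric())
  for (epoch in seq_len(control$max_epochs)) {
    ord <- fit_idx[sample.int(length(fit_idx))]
    batches <- split(ord, ceiling(seq_along(ord) / control$batch_size))
    ep_loss <- 0
    for (bi in batches) {
      fwd <- capsnet_forward(model, samples[bi], training = TRUE)
      model <- fwd$model                    # BN running stats
      bwd <- capsnet_backward(model, fwd, labels[bi])
      upd <- adam_step(model$params, bwd$grads, state, control)
      model$params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + bwd$loss * length(bi)
    }
    ep_loss <- ep_loss / length(fit_idx)
    tune_loss <- if (length(tune_idx) > 0L)
      eval_loss(model, samples[tune_idx], labels[tune_idx],
                control$batch_size) else ep_loss
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss,
                                         tuning_loss = tune_loss))
    if (control$verbose)
      message(sprintf("epoch %3d  train %.5f  tune %.5f", epoch, ep_loss,
                      tune_loss))
    if (tune_loss < best$loss - 1e-9) {
      best <- list(loss = tune_loss, params = model$params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= control$patience) break
    }
  }
  model$params <- best$params
  list(model = model, history = history, stopped_epoch = nrow(history),
       best_epoch = best$epoch)
}

#' Binary classification metrics
#'
#' Accuracy, precision, recall and F1 with class 1 as positive.  Metrics
#' with a zero denominator are reported as 0 with a warning.
#'
#' @param labels true 0/1 labels.
#' @param preds predicted 0/1 labels.
#' @return Named list (acc, pre, rec, f1) plus the confusion counts.
#' @export
classification_metrics <- function(labels, preds) {
  stopifnot(length(labels) == length(preds))
  tp <- sum(labels == 1 & preds == 1)
  tn <- sum(labels == 0 & preds == 0)
  fp <- sum(labels == 0 & preds == 1)
  fn <- sum(labels == 1 & preds == 0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as 0")
      return(0)
    }
    num / den
  }
  acc <- (tp + tn) / length(labels)
  pre <- safe_div(tp, tp + fp, "precision")
  rec <- safe_div(tp, tp + fn, "recall")
  f1 <- if (pre + rec > 0) 2 * pre * rec / (pre + rec) else {
    warning("F1 undefined (precision + recall = 0); reported as 0")
    0
  }
  list(acc = acc, pre = pre, rec = rec, f1 = f1,
       tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Evaluate a trained model on held-out samples
#'
#' @param model a trained `capsnet_model`.
#' @param samples list of `tsf_sample`.
#' @param batch_size evaluation micro-batch size.
#' @return A `fold_result`: per-sample predictions/probabilities/labels/
#'   subjects and the metrics.
#' @export
evaluate_model <- function(model, samples, batch_size = 32L) {
  stopifnot(length(samples) > 0L)
  pred <- capsnet_predict(model, samples, batch_size)
  labels <- sample_labels(samples)
  metrics <- classification_metrics(labels, pred$pred)
  structure(list(predictions = cbind(data.frame(
    subject_id = sample_subjects(samples), label = labels), pred),
    metrics = metrics), class = "fold_result")
}

#' Subject-independent cross-validation
#'
#' Trains and evaluates one model per fold of `plan`; each fold's test set
#' is exactly the samples of that fold's subjects.  Leakage is asserted
#' programmatically for every fold.  The summary reports the unweighted
#' mean (and sd) of the fold metrics, plus metrics pooled over all
#' out-of-fold predictions.
#'
#' @param samples list of `tsf_sample` covering the planned subjects.
#' @param plan from [plan_folds()].
#' @param config a `capsnet_config`.
#' @param control from [train_control()]; each fold is seeded with
#'   `control$seed + fold`.
#' @return List with `folds` (per-fold `fold_result` + history), `summary`
#'   (mean/sd per metric) and `pooled` metrics.
#' @export
cross_validate <- function(samples, plan, config,
                           control = train_control()) {
  subjects <- sample_subjects(samples)
  missing <- setdiff(unique(subjects), plan$subject_id)
  if (length(missing) > 0L)
    stop("plan does not cover subject(s): ", paste(missing, collapse = ", "))
  assert_no_leakage(plan, subjects)
  folds <- sort(unique(plan$fold))
  results <- list()
  pooled_pred <- NULL
  for (f in folds) {
    test_subj <- plan$subject_id[plan$fold == f]
    test_idx <- which(subjects %in% test_subj)
    train_idx <- which(!subjects %in% test_subj)
    stopifnot(length(intersect(subjects[test_idx],
                               subjects[train_idx])) == 0L)
    ctl <- control
    ctl$seed <- control$seed + f
    fit <- train_fold(samples[train_idx], config, ctl)
    res <- evaluate_model(fit$model, samples[test_idx], ctl$batch_size)
    res$fold <- f
    res$history <- fit$history
    res$best_epoch <- fit$best_epoch
    res$model <- fit$model
    results[[as.character(f)]] <- res
    pooled_pred <- rbind(pooled_pred,
                         cbind(res$predictions, fold = f))
  }
  mtab <- t(vapply(results, function(r)
    unlist(r$metrics[c("acc", "pre", "rec", "f1")]), numeric(4)))
  summary <- data.frame(metric = colnames(mtab),
                        mean = colMeans(mtab),
                        sd = apply(mtab, 2L, stats::sd))
  pooled <- classification_metrics(pooled_pred$label, pooled_pred$pred)
  list(folds = results, summary = summary, pooled = pooled,
       predictions = pooled_pred)
}

#' Export per-sample feature vectors for 2D projection tools
#'
#' Flattened features at one of three stages: the raw input tensor, the
#' ConvBlock output, or the class capsules of the full model.  The returned
#' table (one row per sample, with subject and label columns) can be fed to
#' any embedding tool (e.g. t-SNE) -- the projection itself is out of scope.
#'
#' @param model a trained `capsnet_model`.
#' @param samples list of `tsf_sample`.
#' @param stage `"input"`, `"conv_block"` or `"output"`.
#' @param batch_size evaluation micro-batch size.
#' @return data.frame: subject_id, label, feature columns `V1..Vk`.
#' @export
export_embeddings <- function(model, samples, stage = c("input",
                                                        "conv_block",
                                                        "output"),
                              batch_size = 32L) {
  stage <- match.arg(stage)
  feats <- if (stage == "input") {
    do.call(rbind, lapply(samples, function(s) as.numeric(s$tensor)))
  } else {
    n <- length(samples)
    idx <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
    do.call(rbind, lapply(idx, function(ii) {
      fwd <- capsnet_forward(model, samples[ii], training = FALSE)
      if (stage == "conv_block") {
        d <- dim(fwd$conv_out)
        t(matrix(fwd$conv_out, prod(d[1:3]), d[4]))
      } else {
        d <- dim(fwd$v)
        t(matrix(fwd$v, d[1] * d[2], d[3]))
      }
    }))
  }
  colnames(feats) <- paste0("V", seq_len(ncol(feats)))
  cbind(data.frame(subject_id = sample_subjects(samples),
                   label = sample_labels(samples)), as.data.frame(feats))
}
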