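# K-fold class-weighted training protocol and five-metric evaluation.
#
# Folds are stratified by class within the unit of assignment: whole
# subjects for inter-patient splitting (train and validation never share
# a subject), individual episodes for intra-patient. Class weights are
# inverse-frequency, n_total / (n_classes * n_class), computed on each
# fold's training split. Training is mini-batch Adam on weighted
# cross-entropy, fixed epoch count, no early stopping.

#' Training hyperparameters
#'
#' Defaults: Adam, learning rate 1e-4, batch size 16, 100 epochs, k = 10
#' folds. All overridable.
#'
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size.
#' @param epochs training epochs (no early stopping).
#' @param k number of cross-validation folds.
#' @param class_weights optional named per-class weights; `NULL` means
#'   inverse-frequency weights computed per fold.
#' @param seed root seed for shuffling and initialization.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 16L,
                         epochs = 100L, k = 10L, class_weights = NULL,
                         seed = 1L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  stopifnot(is_scalar_num(learning_rate), learning_rate >= 0,
            is_count(batch_size), is_count(epochs, min = 0L), is_count(k))
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), k = as.integer(k),
                 class_weights = class_weights, seed = as.integer(seed),
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "train_config")
}

inverse_frequency_weights <- function(labels, classes) {
  n <- length(labels)
  w <- vapply(classes, function(cl) {
    nc <- sum(labels == cl)
    if (nc == 0) NA_real_ else n / (length(classes) * nc)
  }, numeric(1L))
  names(w) <- classes
  w
}

#' Build a k-fold cross-validation plan
#'
#' @param meta data.frame with at least `label` and `subject_id` columns
#'   (an episode store or a manifest).
#' @param k number of folds.
#' @param split_mode `"inter_patient"` (units are subjects; no subject in
#'   both train and validation of a fold) or `"intra_patient"` (units are
#'   episodes).
#' @param seed shuffling seed; the plan is deterministic given it.
#' @return an object of class `fold_plan`: `assignments` (fold id per
#'   row), per-fold inverse-frequency training `class_weights`, and the
#'   split mode.
#' @export
make_folds <- function(meta, k = 10L, split_mode = c("inter_patient",
                                                     "intra_patient"),
                       seed = 1L) {
  split_mode <- match.arg(split_mode)
  stopifnot(is.data.frame(meta), is_count(k),
            all(c("label", "subject_id") %in% names(meta)))
  n <- nrow(meta)
  classes <- intersect(rhythm_classes(), unique(meta$label))
  fold <- integer(n)
  if (split_mode == "inter_patient") {
    subjects <- unique(meta$subject_id)
    if (length(subjects) < k)
      abort("inter-patient %d-fold needs >= %d subjects, got %d",
            k, k, length(subjects))
    # a subject's stratum is its majority class
    subj_class <- vapply(subjects, function(s) {
      tab <- table(meta$label[meta$subject_id == s])
      names(tab)[which.max(tab)]
    }, character(1L))
    subj_fold <- integer(length(subjects))
    offset <- 0L
    with_seed(derive_seed(seed, "folds"), {
      for (cl in unique(subj_class)) {
        idx <- which(subj_class == cl)
        idx <- idx[sample.int(length(idx))]
        subj_fold[idx] <- (seq_along(idx) - 1L + offset) %% k + 1L
        offset <- offset + length(idx)
      }
    })
    fold <- subj_fold[match(meta$subject_id, subjects)]
  } else {
    with_seed(derive_seed(seed, "folds"), {
      offset <- 0L
      for (cl in unique(meta$label)) {
        idx <- which(meta$label == cl)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- (seq_along(idx) - 1L + offset) %% k + 1L
        offset <- offset + length(idx)
      }
    })
  }
  class_weights <- lapply(seq_len(k), function(f)
    inverse_frequency_weights(meta$label[fold != f], classes))
  structure(list(k = k, split_mode = split_mode, assignments = fold,
                 classes = classes, class_weights = class_weights,
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> k=%d, %s, %d units\n", x$k, x$split_mode,
              length(x$assignments)))
  print(table(fold = x$assignments))
  invisible(x)
}

# labels -> one-hot / 0-1 targets in canonical class order
encode_labels <- function(labels, n_classes) {
  if (n_classes == 2L) {
    bad <- setdiff(unique(labels), c("N", "AF"))
    if (length(bad)) abort("binary training saw label '%s'", bad[1L])
    matrix(as.numeric(labels == "AF"), ncol = 1L)
  } else {
    classes <- rhythm_classes()
    Y <- matrix(0, length(labels), 3L)
    Y[cbind(seq_along(labels), match(labels, classes))] <- 1
    Y
  }
}

adam_state <- function(weights) {
  lapply(weights, function(w)
    if (length(w)) list(mW = w$W * 0, vW = w$W * 0,
                        mb = w$b * 0, vb = w$b * 0) else list())
}

#' Train a network on one fold's training split
#'
#' Minimizes class-weighted cross-entropy (binary or categorical,
#' matching the head) with mini-batch Adam at the configured
#' hyperparameters. Epoch shuffling is seeded; the final-epoch model is
#' returned — no early stopping.
#'
#' @param net a [rhythm_cnn()]; the input handle is not modified.
#' @param X numeric matrix, episodes x input_length.
#' @param labels character vector of rhythm labels, one per row of `X`.
#' @param config a [train_config()].
#' @param class_weights named per-class weights; defaults to
#'   `config$class_weights`, else inverse-frequency on `labels`.
#' @return the trained `rhythm_cnn`, with the per-epoch mean weighted
#'   loss in `$loss_log`.
#' @export
train_fold <- function(net, X, labels, config = train_config(),
                       class_weights = NULL) {
  stopifnot(inherits(net, "rhythm_cnn"), is.matrix(X),
            nrow(X) == length(labels))
  if (ncol(X) != net$config$input_length)
    abort("episode length %d does not match model input length %d",
          ncol(X), net$config$input_length)
  n_classes <- net$config$n_classes
  need <- if (n_classes == 2L) c("N", "AF") else rhythm_classes()
  missing_cl <- setdiff(need, unique(labels))
  if (length(missing_cl))
    abort("class '%s' absent from the training split", missing_cl[1L])
  if (is.null(class_weights))
    class_weights <- config$class_weights %||%
      inverse_frequency_weights(labels, need)
  w_sample <- unname(class_weights[labels])
  Y <- encode_labels(labels, n_classes)
  if (is.null(net$weights))
    net$weights <- init_weights(net$config, net$seed)
  # deep-copy so in-place Adam updates never touch the caller's handle
  net$weights <- lapply(net$weights, function(w)
    if (length(w)) list(W = w$W + 0, b = w$b + 0) else list())
  st <- adam_state(net$weights)
  lr <- config$learning_rate
  b1 <- config$beta1; b2 <- config$beta2; eps <- config$eps
  tstep <- 0L
  n <- nrow(X)
  loss_log <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, sprintf("epoch%d", ep)),
                     sample.int(n))
    ep_loss <- 0
    ep_w <- 0
    for (s in seq.int(1L, n, by = config$batch_size)) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      B <- length(idx)
      fw <- cnn_forward(net, X[idx, , drop = FALSE], keep_cache = TRUE)
      P <- fw$probs
      Yb <- Y[idx, , drop = FALSE]
      wb <- w_sample[idx]
      Pc <- pmin(pmax(P, 1e-12), 1 - 1e-12)
      if (n_classes == 2L)
        loss <- -sum(wb * (Yb * log(Pc) + (1 - Yb) * log(1 - Pc)))
      else
        loss <- -sum(wb * rowSums(Yb * log(Pc)))
      ep_loss <- ep_loss + loss
      ep_w <- ep_w + sum(wb)
      dZ <- (P - Yb) * (wb / B)                    # sigmoid & softmax alike
      grads <- cnn_backward(net, fw$caches, dZ)
      tstep <- tstep + 1L
      corr <- sqrt(1 - b2^tstep) / (1 - b1^tstep)
      for (i in seq_along(grads)) {
        if (is.null(grads[[i]])) next
        g <- grads[[i]]
        adam_update_inplace(net$weights[[i]]$W, st[[i]]$mW, st[[i]]$vW,
                            g$dW, lr, b1, b2, eps, corr)
        adam_update_inplace(net$weights[[i]]$b, st[[i]]$mb, st[[i]]$vb,
                            g$db, lr, b1, b2, eps, corr)
      }
    }
    loss_log[ep] <- ep_loss / ep_w
  }
  net$loss_log <- loss_log
  net
}

# ---- metrics ---------------------------------------------------------------

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Five-metric evaluation report
#'
#' One-vs-rest confusion counts per class and the five derived metrics:
#' accuracy (TP+TN)/(TP+TN+FP+FN), sensitivity TP/(TP+FN), specificity
#' TN/(TN+FP), precision TP/(TP+FP), F1 = 2*precision*sensitivity /
#' (precision+sensitivity). Ratios with a zero denominator are reported
#' as `NA`, never as 0. `overall_accuracy` is the plain multi-class
#' accuracy; `macro` is the unweighted mean over classes.
#'
#' @param predicted,actual character vectors of class labels.
#' @param classes label set; defaults to the classes present in `actual`,
#'   in canonical order.
#' @return an object of class `metrics_report`.
#' @export
metrics_report <- function(predicted, actual,
                           classes = intersect(rhythm_classes(),
                                               unique(actual))) {
  if (length(predicted) == 0L || length(predicted) != length(actual))
    abort("predicted and actual must be equal-length, non-empty")
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(predicted == cl & actual == cl)
    fp <- sum(predicted == cl & actual != cl)
    fn <- sum(predicted != cl & actual == cl)
    tn <- sum(predicted != cl & actual != cl)
    sens <- safe_ratio(tp, tp + fn)
    prec <- safe_ratio(tp, tp + fp)
    f1 <- if (is.na(sens) || is.na(prec) || (prec + sens) == 0) NA_real_
          else 2 * prec * sens / (prec + sens)
    data.frame(class = cl, tp = tp, fp = fp, fn = fn, tn = tn,
               accuracy = safe_ratio(tp + tn, tp + tn + fp + fn),
               sensitivity = sens,
               specificity = safe_ratio(tn, tn + fp),
               precision = prec, f1 = f1, stringsAsFactors = FALSE)
  }))
  metric_cols <- c("accuracy", "sensitivity", "specificity", "precision",
                   "f1")
  macro <- colMeans(per_class[, metric_cols])
  structure(list(per_class = per_class, macro = macro,
                 overall_accuracy = mean(predicted == actual),
                 n = length(actual), classes = classes),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d, overall accuracy %.2f%%\n",
              x$n, 100 * x$overall_accuracy))
  df <- x$per_class
  df[, 6:10] <- round(100 * df[, 6:10], 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Evaluate a trained network
#'
#' @param net a trained [rhythm_cnn()].
#' @param X episode matrix, list, or episode store.
#' @param labels true labels, one per episode.
#' @return a [metrics_report()].
#' @export
evaluate_model <- function(net, X, labels) {
  if (length(labels) == 0L) abort("cannot evaluate on empty input")
  pred <- predict(net, X)
  classes <- if (net$config$n_classes == 2L) c("N", "AF") else rhythm_classes()
  metrics_report(pred$label, labels, classes = classes)
}

# arithmetic mean of per-fold metric data.frames (the "Average" row)
average_reports <- function(reports) {
  metric_cols <- c("accuracy", "sensitivity", "specificity", "precision",
                   "f1")
  per_class <- reports[[1L]]$per_class
  for (cl in metric_cols)
    per_class[[cl]] <- rowMeans(do.call(cbind, lapply(reports, function(r)
      r$per_class[[cl]])))
  per_class[, c("tp", "fp", "fn", "tn")] <- NA
  structure(list(per_class = per_class,
                 macro = rowMeans(do.call(cbind,
                                          lapply(reports, `[[`, "macro"))),
                 overall_accuracy = mean(vapply(reports, `[[`, numeric(1L),
                                                "overall_accuracy")),
                 n = sum(vapply(reports, `[[`, numeric(1L), "n")),
                 classes = reports[[1L]]$classes),
            class = "metrics_report")
}

# fold metrics as a percentage table, Table-5 layout: one row per fold
# plus an Average row, five metric columns, 2 decimals
metrics_table <- function(reports, avg, positive = "AF") {
  pick <- function(r) {
    row <- r$per_class[r$per_class$class == positive, ]
    if (nrow(row) == 0L) row <- r$per_class[1L, ]
    c(accuracy = r$overall_accuracy, sensitivity = row$sensitivity,
      specificity = row$specificity, f1 = row$f1, precision = row$precision)
  }
  tab <- do.call(rbind, lapply(reports, pick))
  tab <- rbind(tab, pick(avg))
  tab <- round(100 * tab, 2)
  data.frame(fold = c(seq_len(nrow(tab) - 1L), "Average"), tab,
             row.names = NULL, check.names = FALSE)
}

#' Run the full k-fold protocol
#'
#' Composes [make_folds()], [train_fold()] and [evaluate_model()] over
#' every fold of an episode store, and optionally persists per-fold
#' reports, the fold-averaged report (arithmetic mean over folds), loss
#' logs, the metrics table CSV and the resolved configuration under
#' `out_dir`. Deterministic given `train_config$seed`.
#'
#' @param episode_table episode store data.frame (see
#'   [episodes_to_table()]).
#' @param model_config a `rhythm_cnn_config`.
#' @param config a [train_config()].
#' @param split_mode forwarded to [make_folds()].
#' @param out_dir optional output directory for artifacts.
#' @param folds optional subset of fold indices to run (default all k).
#' @return list with `fold_reports`, `average` (a [metrics_report()]),
#'   `table` (percentage metrics, one row per fold plus Average),
#'   `fold_plan`, and `loss_logs`.
#' @export
run_protocol <- function(episode_table, model_config, config = train_config(),
                         split_mode = "intra_patient", out_dir = NULL,
                         folds = NULL) {
  stopifnot(is.data.frame(episode_table))
  plan <- make_folds(episode_table, k = config$k, split_mode = split_mode,
                     seed = config$seed)
  X <- episode_matrix(episode_table)
  labels <- episode_table$label
  folds <- folds %||% seq_len(config$k)
  reports <- list()
  loss_logs <- list()
  for (f in folds) {
    tr <- plan$assignments != f
    if (plan$split_mode == "inter_patient") {
      overlap <- intersect(unique(episode_table$subject_id[tr]),
                           unique(episode_table$subject_id[!tr]))
      if (length(overlap))
        abort("fold %d: subject leakage (%s)", f, overlap[1L])
    }
    net <- rhythm_cnn(model_config, seed = derive_seed(config$seed,
                                                       sprintf("fold%d", f)))
    trained <- tryCatch(
      train_fold(net, X[tr, , drop = FALSE], labels[tr], config,
                 class_weights = plan$class_weights[[f]]),
      error = function(e) abort("fold %d: %s", f, conditionMessage(e)))
    reports[[length(reports) + 1L]] <-
      evaluate_model(trained, X[!tr, , drop = FALSE], labels[!tr])
    loss_logs[[length(loss_logs) + 1L]] <- trained$loss_log
    log_stage("train", "fold %d/%d: val accuracy %.2f%%", f, config$k,
              100 * reports[[length(reports)]]$overall_accuracy)
  }
  avg <- average_reports(reports)
  tab <- metrics_table(reports, avg,
                       positive = if (model_config$n_classes == 2L) "AF"
                                  else plan$classes[1L])
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(out_dir, "metrics_by_fold.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(folds = lapply(reports, function(r) r$per_class),
           average = avg$per_class,
           overall_accuracy = vapply(reports, `[[`, numeric(1L),
                                     "overall_accuracy"),
           loss_logs = loss_logs,
           config = list(k = config$k, split_mode = split_mode,
                         learning_rate = config$learning_rate,
                         batch_size = config$batch_size,
                         epochs = config$epochs, seed = config$seed)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  list(fold_reports = reports, average = avg, table = tab, fold_plan = plan,
       loss_logs = loss_logs)
}
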