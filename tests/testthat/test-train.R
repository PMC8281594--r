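# Fold construction, class weights, the training loop, and the
# five-metric evaluation.

test_that("inter-patient folds partition subjects without leakage", {
  meta <- data.frame(label = rep(c("N", "AF"), each = 50),
                     subject_id = sprintf("S%03d", 1:100))
  plan <- make_folds(meta, k = 10, split_mode = "inter_patient", seed = 1)
  expect_equal(sort(unique(plan$assignments)), 1:10)
  expect_equal(unname(table(plan$assignments)), rep(10L, 10),
               ignore_attr = TRUE)
  for (f in 1:10) {
    val_subj <- meta$subject_id[plan$assignments == f]
    train_subj <- meta$subject_id[plan$assignments != f]
    expect_length(intersect(val_subj, train_subj), 0)
    expect_equal(length(val_subj), 10)
  }
  # validation sets cover all rows exactly once
  expect_equal(sum(table(plan$assignments)), 100)
})

test_that("no subject straddles a fold boundary over random layouts", {
  for (seed in 1:5) {
    set.seed(seed)
    n_subj <- sample(12:30, 1)
    meta <- data.frame(
      label = sample(c("N", "AF"), 200, replace = TRUE),
      subject_id = sample(sprintf("S%02d", 1:n_subj), 200, replace = TRUE))
    plan <- make_folds(meta, k = 10, split_mode = "inter_patient",
                       seed = seed)
    per_subj <- tapply(plan$assignments, meta$subject_id,
                       function(f) length(unique(f)))
    expect_true(all(per_subj == 1))
  }
})

test_that("80/20 intra-patient folds give 0.625/2.5 training class weights", {
  meta <- data.frame(label = rep(c("N", "AF"), c(80, 20)),
                     subject_id = sprintf("S%03d", 1:100))
  plan <- make_folds(meta, k = 10, split_mode = "intra_patient", seed = 2)
  for (f in 1:10) {
    w <- plan$class_weights[[f]]
    expect_equal(unname(w["N"]), 0.625, tolerance = 1e-12)
    expect_equal(unname(w["AF"]), 2.5, tolerance = 1e-12)
  }
})

test_that("fold plans are deterministic in the seed", {
  meta <- toy_episode_table(15)[, c("label", "subject_id")]
  p1 <- make_folds(meta, k = 5, split_mode = "intra_patient", seed = 7)
  p2 <- make_folds(meta, k = 5, split_mode = "intra_patient", seed = 7)
  expect_identical(p1, p2)
  expect_error(make_folds(meta[1:5, ], k = 10,
                          split_mode = "inter_patient"),
               "subjects")
})

test_that("training reduces loss; zero learning rate changes nothing", {
  tab <- toy_episode_table(20)
  X <- rhythmnet:::episode_matrix(tab)
  net <- rhythm_cnn(tiny_config(), seed = 4)
  trained <- train_fold(net, X, tab$label,
                        train_config(epochs = 10, batch_size = 8,
                                     learning_rate = 1e-3, seed = 4))
  expect_lt(trained$loss_log[10], trained$loss_log[1])

  frozen <- train_fold(net, X, tab$label,
                       train_config(epochs = 3, learning_rate = 0,
                                    seed = 4))
  expect_identical(frozen$weights, rhythm_cnn(tiny_config(), seed = 4)$weights)
  expect_equal(frozen$loss_log, rep(frozen$loss_log[1], 3))
})

test_that("a class missing from the training split is rejected up front", {
  tab <- toy_episode_table(5)
  X <- rhythmnet:::episode_matrix(tab)
  only_n <- tab$label == "N"
  net <- rhythm_cnn(tiny_config(), seed = 1)
  expect_error(train_fold(net, X[only_n, ], tab$label[only_n],
                          train_config(epochs = 1)),
               "absent")
})

test_that("the five metrics agree with hand-evaluated confusion counts", {
  # TP=90 FN=10 TN=95 FP=5 with AF positive
  actual <- rep(c("AF", "N"), c(100, 100))
  predicted <- c(rep("AF", 90), rep("N", 10), rep("N", 95), rep("AF", 5))
  rep_ <- metrics_report(predicted, actual)
  af <- rep_$per_class[rep_$per_class$class == "AF", ]
  expect_equal(af$sensitivity, 0.90)
  expect_equal(af$specificity, 0.95)
  expect_equal(af$accuracy, 0.925)
  expect_equal(af$precision, 90 / 95)
  expect_equal(af$f1, 2 * (90 / 95) * 0.9 / (90 / 95 + 0.9))
  expect_equal(rep_$overall_accuracy, 0.925)
})

test_that("perfect predictions score 100% on all five metrics", {
  labels <- rep(rhythm_classes(), each = 4)
  rep_ <- metrics_report(labels, labels)
  expect_true(all(rep_$per_class[, c("accuracy", "sensitivity",
                                     "specificity", "precision",
                                     "f1")] == 1))
  expect_equal(rep_$overall_accuracy, 1)
})

test_that("degenerate one-class predictions report NA, never zero, for undefined ratios", {
  actual <- rep(c("N", "AF"), c(6, 4))
  predicted <- rep("AF", 10)
  rep_ <- metrics_report(predicted, actual)
  af <- rep_$per_class[rep_$per_class$class == "AF", ]
  nn <- rep_$per_class[rep_$per_class$class == "N", ]
  expect_equal(af$sensitivity, 1)
  expect_equal(nn$sensitivity, 0)
  expect_true(is.na(nn$precision))     # N never predicted
  expect_error(metrics_report(character(0), character(0)), "non-empty")
})

test_that("metrics match a brute-force recount on random label pairs", {
  set.seed(19)
  classes <- rhythm_classes()
  for (rep_i in 1:20) {
    n <- sample(20:200, 1)
    actual <- sample(classes, n, replace = TRUE)
    predicted <- sample(classes, n, replace = TRUE)
    r <- metrics_report(predicted, actual, classes = classes)
    for (cl in classes) {
      tp <- 0; fp <- 0; fn <- 0; tn <- 0
      for (i in seq_len(n)) {
        if (predicted[i] == cl && actual[i] == cl) tp <- tp + 1
        else if (predicted[i] == cl) fp <- fp + 1
        else if (actual[i] == cl) fn <- fn + 1
        else tn <- tn + 1
      }
      row <- r$per_class[r$per_class$class == cl, ]
      expect_equal(unlist(row[, c("tp", "fp", "fn", "tn")]),
                   c(tp = tp, fp = fp, fn = fn, tn = tn))
      if (tp + fn > 0) expect_equal(row$sensitivity, tp / (tp + fn))
      if (tn + fp > 0) expect_equal(row$specificity, tn / (tn + fp))
    }
    # binary identity: accuracy = (sens*P + spec*N) / (P + N)
    act2 <- ifelse(actual == "AF", "AF", "N")
    pred2 <- ifelse(predicted == "AF", "AF", "N")
    r2 <- metrics_report(pred2, act2, classes = c("N", "AF"))
    af <- r2$per_class[r2$per_class$class == "AF", ]
    P <- sum(act2 == "AF"); Nn <- sum(act2 == "N")
    expect_equal(r2$overall_accuracy,
                 (af$sensitivity * P + af$specificity * Nn) / (P + Nn))
  }
})

test_that("the k-fold protocol emits k fold rows plus an average, reproducibly", {
  tab <- toy_episode_table(15)
  cfg <- train_config(epochs = 2, batch_size = 8, learning_rate = 1e-3,
                      k = 5, seed = 3)
  out <- withr::local_tempdir()
  res <- run_protocol(tab, tiny_config(), cfg,
                      split_mode = "intra_patient", out_dir = out)
  expect_length(res$fold_reports, 5)
  expect_equal(nrow(res$table), 6)
  expect_identical(res$table$fold[6], "Average")
  expect_true(file.exists(file.path(out, "metrics_by_fold.csv")))
  expect_true(file.exists(file.path(out, "report.json")))
  # fold averaging is the arithmetic mean of per-fold metrics
  expect_equal(res$average$overall_accuracy,
               mean(vapply(res$fold_reports, `[[`, 0, "overall_accuracy")))

  res2 <- run_protocol(tab, tiny_config(), cfg,
                       split_mode = "intra_patient")
  expect_equal(res2$table, res$table)
  expect_identical(res2$fold_plan, res$fold_plan)
})

test_that("the three-class protocol reports all three classes", {
  tab <- toy_episode_table(8, classes = rhythm_classes())
  cfg <- train_config(epochs = 1, batch_size = 8, k = 3, seed = 5)
  res <- run_protocol(tab, tiny_config(3), cfg,
                      split_mode = "intra_patient")
  expect_setequal(res$average$per_class$class, rhythm_classes())
})
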