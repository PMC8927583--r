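# Classifier construction, training, prediction, grid search, baselines.

test_that("model configurations are validated against the search ranges", {
  expect_error(model_config("recurrent", lstm_layers = 4), "1, 2 or 3")
  expect_error(model_config("feedforward", hidden_layers = 3), "between 4 and 8")
  expect_error(model_config("feedforward", dropout = 1), "dropout")
  expect_silent(model_config("recurrent", lstm_layers = 3,
                             bidirectional = FALSE, dropout = 0.45))
})

test_that("the recurrent model maps a (128 x L) sequence to one probability", {
  cfg <- model_config("recurrent", seed = 5, epochs = 2)
  m <- build_recurrent_model(cfg, L = 4)
  feats <- toy_band_features(n_epochs_per_trial = 10, n_trials = 4)
  seqs <- build_sequences(feats, L = 4, stride = 2)
  parts <- chronological_split(seqs)
  m <- train_workload_model(m, parts[parts$.split == "train", ],
                            parts[parts$.split == "validation", ])
  pred <- predict(m, parts[parts$.split == "test", ])
  expect_true(all(pred$.prob > 0 & pred$.prob < 1))
  expect_true(all(pred$.pred %in% 0:1))
  # repeated inference is identical (dropout disabled at prediction)
  expect_identical(pred$.prob, predict(m, parts[parts$.split == "test", ])$.prob)
  # degenerate one-epoch sequences still work
  s1 <- build_sequences(feats, L = 1, stride = 1)
  m1 <- build_recurrent_model(model_config("recurrent", seed = 5, epochs = 2),
                              L = 1)
  p1 <- chronological_split(s1)
  m1 <- train_workload_model(m1, p1[p1$.split == "train", ])
  expect_true(all(predict(m1, p1[p1$.split == "test", ])$.prob > 0))
})

test_that("the feed-forward model emits valid probabilities, even on zeros", {
  win <- separable_fused_windows(n_per_class = 20)
  parts <- chronological_split(win)
  m <- build_feedforward_model(model_config("feedforward", seed = 2,
                                            epochs = 30))
  m <- train_workload_model(m, parts[parts$.split == "train", ])
  zero <- win[1:3, ]
  zero[, fused_feature_names()] <- 0
  pz <- predict(m, zero)
  expect_true(all(pz$.prob > 0 & pz$.prob < 1))
  expect_identical(pz$.prob, predict(m, zero)$.prob)
})

test_that("training separates separable features and is seed-deterministic", {
  win <- separable_fused_windows(n_per_class = 30)
  parts <- chronological_split(win)
  train <- parts[parts$.split == "train", ]
  # dropout off isolates the optimizer: separable data must be fit exactly
  cfg <- model_config("feedforward", seed = 7, epochs = 40, dropout = 0)
  m1 <- train_workload_model(build_feedforward_model(cfg), train)
  expect_equal(model_accuracy(m1, train), 1.0)
  # loss decreases in trend: late-epoch mean well below early-epoch mean
  h <- tidy(m1)
  expect_lt(mean(tail(h$loss, 10)), mean(head(h$loss, 5)))
  # identical seed, identical final weights
  m2 <- train_workload_model(build_feedforward_model(cfg), train)
  expect_identical(m1$params, m2$params)
  # single-class training data is rejected
  expect_error(train_workload_model(build_feedforward_model(cfg),
                                    train[train$label == 0, ]),
               "single class")
})

test_that("normalization and imputation statistics come from the training split only", {
  win <- separable_fused_windows(n_per_class = 30)
  win$pd[3] <- NA
  parts <- chronological_split(win)
  train <- parts[parts$.split == "train", ]
  m <- train_workload_model(build_feedforward_model(
    model_config("feedforward", seed = 1, epochs = 2)), train)
  mat <- as.matrix(train[, fused_feature_names()])
  imputed <- mat
  for (r in which(!stats::complete.cases(imputed))) {
    s <- train$subject[r]
    fill <- m$impute$per_subject[[s]]
    imputed[r, is.na(imputed[r, ])] <- fill[is.na(imputed[r, ])]
  }
  expect_equal(m$norm$mean, colMeans(imputed))
  expect_equal(m$norm$sd, apply(imputed, 2, sd), tolerance = 1e-12)
})

test_that("baseline classifiers share the predict interface", {
  win <- separable_fused_windows(n_per_class = 30, gap = 4)
  parts <- chronological_split(win)
  train <- parts[parts$.split == "train", ]
  val <- parts[parts$.split == "validation", ]
  for (kind in c("knn", "random_forest", "svm")) {
    m <- train_workload_model(baseline_classifier(kind), train)
    pred <- predict(m, val)
    expect_true(all(pred$.prob >= 0 & pred$.prob <= 1))
    expect_gt(model_accuracy(m, val), 0.9)
  }
  # 1-NN reproduces its own training set exactly
  m1 <- train_workload_model(
    baseline_classifier("knn", model_config("knn", k = 1)), train)
  expect_equal(model_accuracy(m1, train), 1.0)
  expect_error(baseline_classifier("lda"), "arg")
})

test_that("grid search returns the validation-accuracy argmax", {
  win <- separable_fused_windows(n_per_class = 25, gap = 1.5)
  parts <- chronological_split(win)
  train <- parts[parts$.split == "train", ]
  val <- parts[parts$.split == "validation", ]

  single <- list(model_config("feedforward", seed = 3, epochs = 5))
  gs1 <- grid_search(single, train, val)
  expect_identical(gs1$best_config, single[[1]])

  expect_length(default_grid("recurrent"), 3 * 2 * 2)
  expect_length(default_grid("feedforward"), 5 * 2)

  grid <- default_grid("feedforward", seed = 3, epochs = 4)[c(1, 4, 8)]
  gs <- grid_search(grid, train, val)
  expect_equal(nrow(gs$results), 3)
  best_acc <- gs$results$val_accuracy[
    gs$results$config_id == which.max(gs$results$val_accuracy)]
  expect_true(all(model_accuracy(gs$best_model, val) >= gs$results$val_accuracy |
                    abs(model_accuracy(gs$best_model, val) -
                          gs$results$val_accuracy) < 1e-12))
  expect_error(grid_search(list(), train, val), "empty")
})

test_that("the cognitive index is the mean predicted probability", {
  win <- separable_fused_windows(n_per_class = 25)
  parts <- chronological_split(win)
  m <- train_workload_model(build_feedforward_model(
    model_config("feedforward", seed = 4, epochs = 20)),
    parts[parts$.split == "train", ])
  test <- parts[parts$.split == "test", ]
  idx <- cognitive_index(m, test)
  expect_equal(idx, mean(predict(m, test)$.prob))
  expect_gte(idx, 0)
  expect_lte(idx, 1)
  expect_error(cognitive_index(m, test[0, ]), "no windows")
})

test_that("tidy and glance summarize trained models", {
  win <- separable_fused_windows(n_per_class = 25)
  parts <- chronological_split(win)
  m <- build_feedforward_model(model_config("feedforward", seed = 4,
                                            epochs = 6))
  expect_error(predict(m, parts), "not trained")
  m <- train_workload_model(m, parts[parts$.split == "train", ],
                            parts[parts$.split == "validation", ])
  h <- tidy(m)
  expect_equal(nrow(h), 6)
  expect_named(h, c("epoch", "loss", "val_loss", "val_accuracy"))
  g <- glance(m)
  expect_equal(g$model_kind, "feedforward")
  expect_equal(g$epochs, 6L)
  expect_gt(g$n_parameters, 0)
})

test_that("evaluation tables have one row per model and length", {
  feats <- toy_band_features(n_epochs_per_trial = 20, n_trials = 4,
                             n_subjects = 2, shift = 0.12)
  cfg <- list(recurrent = model_config("recurrent", lstm_layers = 1,
                                       bidirectional = FALSE, epochs = 8,
                                       seed = 2))
  tab <- evaluate_vs_sequence_length(feats, lengths_s = c(10, 25),
                                     model_kinds = "recurrent",
                                     stride_s = 5, config = cfg)
  expect_s3_class(tab, "workload_eval")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$length_s, c(10, 25))
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
  # lengths that no trial can host are skipped with a warning
  expect_warning(
    short <- evaluate_vs_sequence_length(feats, lengths_s = c(10, 1000),
                                         model_kinds = "recurrent",
                                         stride_s = 5, config = cfg),
    "skipping"
  )
  expect_equal(nrow(short), 1)
  p <- autoplot(tab)
  expect_s3_class(p, "ggplot")
})

test_that("a majority-class dummy scores the class balance", {
  # analytic baseline for evaluation accuracies: a constant predictor can
  # never beat the class balance, which is 0.5 by protocol design
  feats <- toy_band_features(n_epochs_per_trial = 10, n_trials = 4)
  seqs <- build_sequences(feats, 2, 2)
  expect_equal(mean(seqs$label), 0.5)
})
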