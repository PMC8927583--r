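# Workload classifiers: the recurrent (LSTM) EEG-sequence model, the
# feed-forward fused-feature model, and classical baselines behind one
# train / predict surface. Both neural models minimize binary cross-entropy
# with Adam (100 epochs, batch size 10 by default); feature standardization
# and missing-feature imputation statistics always come from the training
# split only.

#' Names of the nine fused EEG + eye features
#'
#' Four channel-averaged band coefficients plus the five eye features.
#' @return Character vector of column names.
#' @export
fused_feature_names <- function() {
  c("eeg_delta", "eeg_theta", "eeg_alpha", "eeg_beta",
    "pd", "nf", "ft", "ssp", "nni")
}

#' Model configuration
#'
#' Hyperparameters for all classifier kinds, validated against the ranges
#' the grid search explores: 1-3 LSTM layers (uni- or bidirectional,
#' dropout 0.45 or 0.5 in the grid) for the recurrent model; 4-8 hidden
#' layers for the feed-forward model. Training runs 100 epochs of Adam
#' with batch size 10 unless overridden.
#'
#' @param model_kind One of `"recurrent"`, `"feedforward"`, `"knn"`,
#'   `"random_forest"`, `"svm"`.
#' @param lstm_layers Number of stacked LSTM layers (1-3).
#' @param bidirectional Logical; process sequences in both directions.
#' @param hidden_units LSTM hidden state width (default 32).
#' @param reduce_units Width of the per-timestep reducing dense layer
#'   (default 64).
#' @param dropout Dropout rate in `[0, 1)`.
#' @param hidden_layers Feed-forward depth (4-8).
#' @param hidden_width Width of every feed-forward hidden layer (default 64).
#' @param epochs,batch_size,learning_rate Adam training schedule.
#' @param k Neighbours for the KNN baseline.
#' @param seed Seed recorded with (and controlling) every trained model.
#' @return An object of class `model_config`.
#' @export
model_config <- function(model_kind = c("recurrent", "feedforward", "knn",
                                        "random_forest", "svm"),
                         lstm_layers = 2, bidirectional = TRUE,
                         hidden_units = 32, reduce_units = 64,
                         dropout = 0.5, hidden_layers = 5, hidden_width = 64,
                         epochs = 100, batch_size = 10, learning_rate = 1e-3,
                         k = 5, seed = 1) {
  model_kind <- match.arg(model_kind)
  if (model_kind == "recurrent" &&
      (!lstm_layers %in% 1:3)) {
    abort("`lstm_layers` must be 1, 2 or 3.")
  }
  if (model_kind == "feedforward" && !hidden_layers %in% 4:8) {
    abort("`hidden_layers` must be between 4 and 8.")
  }
  if (dropout < 0 || dropout >= 1) abort("`dropout` must be in [0, 1).")
  stopifnot_scalar_number(epochs, "epochs", min = 1)
  stopifnot_scalar_number(batch_size, "batch_size", min = 1)
  structure(
    list(model_kind = model_kind, lstm_layers = as.integer(lstm_layers),
         bidirectional = isTRUE(bidirectional),
         hidden_units = as.integer(hidden_units),
         reduce_units = as.integer(reduce_units), dropout = dropout,
         hidden_layers = as.integer(hidden_layers),
         hidden_width = as.integer(hidden_width),
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, k = as.integer(k),
         seed = as.integer(seed)),
    class = "model_config"
  )
}

ff_widths <- function(config) {
  rep(config$hidden_width, config$hidden_layers)
}

#' Build an untrained recurrent EEG-sequence classifier
#'
#' Stage 1 is a per-timestep dense layer reducing the 128-element
#' band-power vector; stage 2 stacks (bi)directional LSTM layers whose
#' final hidden state feeds a sigmoid output unit. Accepts input sequences
#' of shape `features x L` and emits one probability of high workload.
#'
#' @param config A [model_config()] with `model_kind = "recurrent"`.
#' @param L Sequence length in epochs.
#' @param input_dim Per-timestep feature dimension (default 128).
#' @return An untrained object of class `workload_model`.
#' @export
build_recurrent_model <- function(config, L, input_dim = 128) {
  if (config$model_kind != "recurrent") abort("config is not for a recurrent model.")
  params <- with_seed(config$seed,
                      init_recurrent(input_dim, config$reduce_units,
                                     config$hidden_units, config$lstm_layers,
                                     config$bidirectional))
  structure(list(kind = "recurrent", config = config, L = as.integer(L),
                 input_dim = input_dim, params = params, trained = FALSE),
            class = "workload_model")
}

#' Build an untrained feed-forward fused-feature classifier
#'
#' Dense-ReLU blocks with batch normalization and dropout, sigmoid output,
#' over the 9-element fused EEG + eye vector.
#'
#' @param config A [model_config()] with `model_kind = "feedforward"`.
#' @param input_dim Input dimension (default 9).
#' @return An untrained `workload_model`.
#' @export
build_feedforward_model <- function(config, input_dim = 9) {
  if (config$model_kind != "feedforward") abort("config is not for a feed-forward model.")
  widths <- ff_widths(config)
  params <- with_seed(config$seed, init_feedforward(input_dim, widths))
  structure(list(kind = "feedforward", config = config, widths = widths,
                 input_dim = input_dim, params = params,
                 bn_stats = init_bn_stats(widths), trained = FALSE),
            class = "workload_model")
}

#' Build an untrained baseline classifier
#'
#' KNN, random forest and SVM comparison baselines over fused feature
#' vectors, behind the same train / predict interface as the neural
#' models. These wrap standard implementations; they are reference points,
#' not the proposed models.
#'
#' @param kind `"knn"`, `"random_forest"` or `"svm"`.
#' @param config Optional [model_config()]; defaults to one of the given
#'   kind.
#' @return An untrained `workload_model`.
#' @export
baseline_classifier <- function(kind = c("knn", "random_forest", "svm"),
                                config = NULL) {
  kind <- match.arg(kind)
  config <- config %||% model_config(model_kind = kind)
  if (config$model_kind != kind) abort("config kind does not match `kind`.")
  structure(list(kind = kind, config = config, trained = FALSE),
            class = "workload_model")
}

#' @export
print.workload_model <- function(x, ...) {
  cat(sprintf("<workload_model: %s> %s", x$kind,
              if (x$trained) "trained" else "untrained"))
  if (x$kind == "recurrent") {
    cat(sprintf(" | %d%s LSTM layer(s) x %d units, L = %d",
                x$config$lstm_layers,
                if (x$config$bidirectional) " bidirectional" else "",
                x$config$hidden_units, x$L))
  }
  if (x$kind == "feedforward") {
    cat(sprintf(" | hidden widths %s", paste(x$widths, collapse = "-")))
  }
  if (!is.null(x$history)) {
    cat(sprintf(" | final loss %.4f", tail(x$history$loss, 1)))
  }
  cat("\n")
  invisible(x)
}

# ---- feature extraction from window tables ----------------------------------

# windows with a `features` list-column -> (B, d, L) array
sequence_tensor <- function(windows) {
  stack_windows(windows$features)
}

fused_matrix <- function(windows, feature_cols = fused_feature_names()) {
  missing_cols <- setdiff(feature_cols, names(windows))
  if (length(missing_cols)) {
    abort(sprintf("windows lack fused feature column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  as.matrix(windows[, feature_cols])
}

# per-subject imputation means from the training windows (NA features only)
impute_stats <- function(train_mat, subjects) {
  global <- colMeans(train_mat, na.rm = TRUE)
  global[!is.finite(global)] <- 0
  per_subject <- lapply(split(seq_len(nrow(train_mat)), subjects), function(i) {
    m <- colMeans(train_mat[i, , drop = FALSE], na.rm = TRUE)
    m[!is.finite(m)] <- global[!is.finite(m)]
    m
  })
  list(global = global, per_subject = per_subject)
}

apply_impute <- function(mat, subjects, stats) {
  for (r in which(!complete.cases(mat))) {
    fill <- stats$per_subject[[subjects[r]]] %||% stats$global
    nas <- is.na(mat[r, ])
    mat[r, nas] <- fill[nas]
  }
  mat
}

standardize_fit <- function(mat) {
  mu <- colMeans(mat)
  sdv <- apply(mat, 2, sd)
  sdv[sdv < 1e-12] <- 1
  list(mean = mu, sd = sdv)
}

standardize_apply <- function(mat, st) {
  sweep(sweep(mat, 2, st$mean), 2, st$sd, "/")
}

# ---- training ---------------------------------------------------------------

#' Train a workload classifier
#'
#' Neural kinds minimize binary cross-entropy with Adam over mini-batches;
#' baseline kinds fit their standard estimators. Feature standardization
#' and (for fused features) per-subject missing-value imputation are fitted
#' on the training windows only and stored with the model, so no statistic
#' ever leaks from validation or test data. Training is deterministic for
#' a fixed `config$seed`.
#'
#' @param model An untrained `workload_model`.
#' @param train Training window tibble: recurrent models need a `features`
#'   list-column (from [build_sequences()]); other kinds need the nine
#'   fused feature columns (from [fuse_features()]). A `label` column with
#'   both classes present is required.
#' @param validation Optional window tibble monitored during training
#'   (never used to fit anything).
#' @return The trained `workload_model` with a `history` tibble of
#'   per-epoch losses.
#' @export
train_workload_model <- function(model, train, validation = NULL) {
  stopifnot(inherits(model, "workload_model"))
  y <- train$label
  if (length(unique(y)) < 2) {
    abort("training windows contain a single class; both LCL and HCL are required.")
  }
  cfg <- model$config
  if (model$kind == "recurrent") {
    X <- sequence_tensor(train)
    d <- dim(X)[2]
    flat <- matrix(aperm(X, c(1, 3, 2)), ncol = d)
    norm <- standardize_fit(flat)
    model$norm <- norm
    Xs <- scale_tensor(X, norm)
    val <- if (!is.null(validation)) {
      list(X = scale_tensor(sequence_tensor(validation), norm),
           y = validation$label)
    }
    model <- train_nn_loop(model, Xs, y, val)
  } else if (model$kind == "feedforward") {
    mats <- prepare_fused(model, train)
    model <- mats$model
    val <- if (!is.null(validation)) {
      list(X = predict_prepare_fused(model, validation), y = validation$label)
    }
    model <- train_nn_loop(model, mats$X, y, val)
  } else {
    mats <- prepare_fused(model, train)
    model <- mats$model
    model$fit <- with_seed(cfg$seed, switch(
      model$kind,
      knn = list(X = mats$X, y = y),
      random_forest = randomForest::randomForest(
        mats$X, factor(y, levels = c(0, 1)), ntree = 200),
      svm = e1071::svm(mats$X, factor(y, levels = c(0, 1)),
                       probability = TRUE, kernel = "radial")
    ))
    model$trained <- TRUE
  }
  model
}

scale_tensor <- function(X, norm) {
  d <- dim(X)
  flat <- matrix(aperm(X, c(1, 3, 2)), ncol = d[2])
  flat <- standardize_apply(flat, norm)
  aperm(array(flat, c(d[1], d[3], d[2])), c(1, 3, 2))
}

prepare_fused <- function(model, train) {
  mat <- fused_matrix(train)
  model$impute <- impute_stats(mat, train$subject)
  mat <- apply_impute(mat, train$subject, model$impute)
  model$norm <- standardize_fit(mat)
  list(model = model, X = standardize_apply(mat, model$norm))
}

predict_prepare_fused <- function(model, windows) {
  mat <- fused_matrix(windows)
  mat <- apply_impute(mat, windows$subject, model$impute)
  standardize_apply(mat, model$norm)
}

# shared Adam mini-batch loop for both neural kinds
train_nn_loop <- function(model, X, y, val = NULL) {
  cfg <- model$config
  is_seq <- model$kind == "recurrent"
  n <- if (is_seq) dim(X)[1] else nrow(X)
  with_seed(cfg$seed, {
    state <- adam_init(model$params)
    history <- vector("list", cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = cfg$batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1, n)]
        if (is_seq) {
          Xb <- X[idx, , , drop = FALSE]
          fwd <- rnn_forward(model$params, Xb, cfg, training = TRUE)
          grads <- rnn_backward(model$params, fwd, y[idx], cfg)
        } else {
          Xb <- X[idx, , drop = FALSE]
          fwd <- ff_forward(model$params, Xb, model$widths, cfg$dropout,
                            training = TRUE, bn_stats = model$bn_stats)
          model$bn_stats <- fwd$bn_stats
          grads <- ff_backward(model$params, fwd, y[idx], model$widths)
        }
        upd <- adam_step(model$params, grads, state, lr = cfg$learning_rate)
        model$params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + bce_loss(y[idx], fwd$prob) * length(idx)
      }
      row <- tibble(epoch = ep, loss = ep_loss / n)
      if (!is.null(val)) {
        vp <- nn_predict_prob(model, val$X)
        row$val_loss <- bce_loss(val$y, vp)
        row$val_accuracy <- mean((vp > 0.5) == (val$y == 1))
      }
      history[[ep]] <- row
    }
    model$history <- dplyr::bind_rows(history)
  })
  model$trained <- TRUE
  model
}

nn_predict_prob <- function(model, X) {
  if (model$kind == "recurrent") {
    rnn_forward(model$params, X, model$config, training = FALSE)$prob
  } else {
    ff_forward(model$params, X, model$widths, training = FALSE,
               bn_stats = model$bn_stats)$prob
  }
}

#' Predict workload probabilities for labeled windows
#'
#' Dropout is disabled and batch normalization uses its running statistics,
#' so repeated calls are identical. Probabilities are of the high-load
#' class; hard labels use the 0.5 threshold.
#'
#' @param object A trained `workload_model`.
#' @param newdata Window tibble matching the model's input kind.
#' @param ... Unused.
#' @return `newdata` with `.prob` and `.pred` columns appended.
#' @export
predict.workload_model <- function(object, newdata, ...) {
  if (!object$trained) abort("model is not trained.")
  prob <- if (object$kind == "recurrent") {
    nn_predict_prob(object, scale_tensor(sequence_tensor(newdata), object$norm))
  } else if (object$kind == "feedforward") {
    nn_predict_prob(object, predict_prepare_fused(object, newdata))
  } else {
    X <- predict_prepare_fused(object, newdata)
    switch(object$kind,
           knn = {
             k <- min(object$config$k, nrow(object$fit$X))
             pr <- class::knn(object$fit$X, X,
                              factor(object$fit$y, levels = c(0, 1)),
                              k = k, prob = TRUE)
             win <- attr(pr, "prob")
             ifelse(pr == "1", win, 1 - win)
           },
           random_forest = predict(object$fit, X, type = "prob")[, "1"],
           svm = {
             pr <- predict(object$fit, X, probability = TRUE)
             attr(pr, "probabilities")[, "1"]
           })
  }
  out <- as_tibble(newdata)
  out$.prob <- as.numeric(prob)
  out$.pred <- as.integer(out$.prob > 0.5)
  out
}

#' Classification accuracy of a model on labeled windows
#'
#' @param model A trained `workload_model`.
#' @param windows Labeled window tibble.
#' @return Fraction of windows whose 0.5-thresholded prediction matches the
#'   label.
#' @export
model_accuracy <- function(model, windows) {
  pred <- predict(model, windows)
  mean(pred$.pred == pred$label)
}

# ---- grid search ------------------------------------------------------------

#' Hyperparameter grids explored for each neural model
#'
#' Recurrent: LSTM layers 1-3 x uni/bidirectional x dropout {0.45, 0.5}.
#' Feed-forward: hidden layers 4-8 x dropout {0.45, 0.5}.
#'
#' @param model_kind `"recurrent"` or `"feedforward"`.
#' @param seed,epochs Passed into every configuration.
#' @return A list of [model_config()] objects.
#' @export
default_grid <- function(model_kind = c("recurrent", "feedforward"), seed = 1,
                         epochs = 100) {
  model_kind <- match.arg(model_kind)
  if (model_kind == "recurrent") {
    grid <- tidyr::expand_grid(lstm_layers = 1:3,
                               bidirectional = c(FALSE, TRUE),
                               dropout = c(0.45, 0.5))
    purrr::pmap(grid, function(lstm_layers, bidirectional, dropout) {
      model_config("recurrent", lstm_layers = lstm_layers,
                   bidirectional = bidirectional, dropout = dropout,
                   seed = seed, epochs = epochs)
    })
  } else {
    grid <- tidyr::expand_grid(hidden_layers = 4:8, dropout = c(0.45, 0.5))
    purrr::pmap(grid, function(hidden_layers, dropout) {
      model_config("feedforward", hidden_layers = hidden_layers,
                   dropout = dropout, seed = seed, epochs = epochs)
    })
  }
}

build_from_config <- function(config, L = NULL, input_dim = NULL) {
  switch(config$model_kind,
         recurrent = build_recurrent_model(config, L = L,
                                           input_dim = input_dim %||% 128),
         feedforward = build_feedforward_model(config,
                                               input_dim = input_dim %||% 9),
         baseline_classifier(config$model_kind, config))
}

#' Grid search over model configurations
#'
#' Trains one model per configuration on the training windows and returns
#' the configuration maximizing validation accuracy; ties go to the
#' smaller model (fewer trainable parameters).
#'
#' @param config_grid A list of [model_config()] objects (e.g. from
#'   [default_grid()]).
#' @param train,validation Window tibbles.
#' @param L Sequence length, required for recurrent grids.
#' @return A list with `best_config`, `best_model` and a `results` tibble
#'   (one row per configuration with its validation accuracy).
#' @export
grid_search <- function(config_grid, train, validation, L = NULL) {
  if (length(config_grid) == 0) abort("`config_grid` is empty.")
  results <- purrr::map(config_grid, function(cfg) {
    model <- build_from_config(cfg, L = L)
    trained <- train_workload_model(model, train, validation)
    size <- if (!is.null(trained$params)) n_params(trained$params) else NA_integer_
    list(model = trained,
         row = tibble(model_kind = cfg$model_kind,
                      lstm_layers = cfg$lstm_layers,
                      bidirectional = cfg$bidirectional,
                      hidden_layers = cfg$hidden_layers,
                      dropout = cfg$dropout,
                      n_params = size,
                      val_accuracy = model_accuracy(trained, validation)))
  })
  tab <- dplyr::bind_rows(purrr::map(results, "row"))
  tab$config_id <- seq_len(nrow(tab))
  ord <- order(-tab$val_accuracy, tab$n_params)
  best <- ord[1]
  list(best_config = config_grid[[best]],
       best_model = results[[best]]$model,
       results = tab)
}

#' Session-level cognitive workload index
#'
#' Mean predicted probability of the high-load class over the
#' chronological windows of one task execution: 0 means the model saw only
#' low load, 1 only high load. (A pragmatic session summary built on the
#' classifier's probabilities; the underlying construct has no canonical
#' definition.)
#'
#' @param model A trained `workload_model`.
#' @param windows Window tibble covering one task execution.
#' @return Scalar in `[0, 1]`.
#' @export
cognitive_index <- function(model, windows) {
  if (nrow(windows) == 0) abort("no windows supplied.")
  mean(predict(model, windows)$.prob)
}

# ---- broom-style accessors --------------------------------------------------

#' @export
tidy.workload_model <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble(epoch = integer(), loss = numeric()))
  }
  x$history
}

#' @export
glance.workload_model <- function(x, ...) {
  tibble(
    model_kind = x$kind,
    trained = x$trained,
    n_parameters = if (!is.null(x$params)) n_params(x$params) else NA_integer_,
    epochs = if (!is.null(x$history)) nrow(x$history) else 0L,
    final_loss = if (!is.null(x$history)) tail(x$history$loss, 1) else NA_real_,
    val_accuracy = if (!is.null(x$history) && "val_accuracy" %in% names(x$history)) {
      tail(x$history$val_accuracy, 1)
    } else {
      NA_real_
    },
    seed = x$config$seed
  )
}
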