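# Accuracy-versus-sequence-length evaluation: the central computational
# experiment. For every requested input length, windows are built, split
# chronologically (or by session), one model per kind is trained, and
# per-subject test accuracies are averaged.

eval_model_kinds <- c("recurrent", "feedforward", "knn", "random_forest",
                      "svm")

#' Evaluate classifiers across input sequence lengths
#'
#' For the recurrent model, a length of `l` seconds means `l / 5` EEG
#' epochs per sequence (EEG-only). For the feed-forward model and the
#' baselines, it is the span of the fused window (requires eye features).
#' Windows are split 60-20-20 chronologically within subject (or by
#' session with `split = "session"`: last session tests, second-to-last
#' validates, the rest train), a model is trained on the pooled training
#' windows, and the mean over subjects of the per-subject test accuracy is
#' reported. Lengths exceeding the available epochs of a trial are skipped
#' with a warning.
#'
#' @param eeg_features Per-epoch band-power tibble.
#' @param eye_features Per-epoch eye feature tibble (required for fused
#'   model kinds).
#' @param lengths_s Numeric vector of window lengths in seconds (multiples
#'   of 5).
#' @param model_kinds Subset of `"recurrent"`, `"feedforward"`, `"knn"`,
#'   `"random_forest"`, `"svm"`.
#' @param split `"chronological"` or `"session"`.
#' @param stride_s Window stride in seconds; defaults to the window length
#'   (non-overlapping windows).
#' @param config Optional named list of [model_config()] overrides per
#'   model kind.
#' @param seed Seed applied to model configs lacking one.
#' @param epoch_s EEG epoch length (default 5).
#' @return A `workload_eval` tibble: one row per (model, length) with
#'   `accuracy` (mean over subjects), `n_train`/`n_test` window counts and
#'   the per-subject accuracies nested in `by_subject`.
#' @export
evaluate_vs_sequence_length <- function(eeg_features, eye_features = NULL,
                                        lengths_s, model_kinds = "recurrent",
                                        split = c("chronological", "session"),
                                        stride_s = NULL, config = NULL,
                                        seed = 1, epoch_s = 5) {
  split <- match.arg(split)
  bad <- setdiff(model_kinds, eval_model_kinds)
  if (length(bad)) {
    abort(sprintf("unknown model kind(s): %s.", paste(bad, collapse = ", ")))
  }
  fused_kinds <- setdiff(model_kinds, "recurrent")
  if (length(fused_kinds) && is.null(eye_features)) {
    abort("fused model kinds require `eye_features`.")
  }
  rows <- list()
  for (len in lengths_s) {
    L <- len / epoch_s
    if (abs(L - round(L)) > 1e-9) {
      warn(sprintf("skipping length %g s: not a whole number of epochs.", len))
      next
    }
    L <- as.integer(round(L))
    stride_epochs <- max(1L, as.integer(round((stride_s %||% len) / epoch_s)))
    for (kind in model_kinds) {
      windows <- if (kind == "recurrent") {
        build_sequences(eeg_features, L, stride_epochs)
      } else {
        fuse_features(eeg_features, eye_features, window_s = len,
                      stride_s = stride_s %||% len, epoch_s = epoch_s)
      }
      if (nrow(windows) == 0) {
        warn(sprintf("skipping length %g s for %s: no trial has %d epochs.",
                     len, kind, L))
        next
      }
      parts <- split_windows(windows, split)
      cfg <- config[[kind]] %||% model_config(model_kind = kind, seed = seed)
      model <- build_from_config(cfg, L = L)
      model <- train_workload_model(model, parts$train, parts$validation)
      test_pred <- predict(model, parts$test)
      by_subject <- dplyr::summarise(
        dplyr::group_by(test_pred, .data$subject),
        accuracy = mean(.data$.pred == .data$label), n = dplyr::n(),
        .groups = "drop"
      )
      rows[[length(rows) + 1L]] <- tibble(
        model = kind, length_s = len,
        accuracy = mean(by_subject$accuracy),
        n_train = nrow(parts$train), n_test = nrow(parts$test),
        by_subject = list(by_subject)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("workload_eval", class(out))
  out
}

split_windows <- function(windows, split) {
  if (split == "chronological") {
    marked <- chronological_split(windows)
    return(list(train = marked[marked$.split == "train", ],
                validation = marked[marked$.split == "validation", ],
                test = marked[marked$.split == "test", ]))
  }
  sessions <- sort(unique(windows$session))
  if (length(sessions) < 3) {
    abort("session-to-session evaluation needs at least 3 sessions.")
  }
  test_s <- sessions[length(sessions)]
  val_s <- sessions[length(sessions) - 1]
  list(train = windows[!windows$session %in% c(test_s, val_s), ],
       validation = windows[windows$session == val_s, ],
       test = windows[windows$session == test_s, ])
}

#' Plot accuracy against sequence length
#'
#' @param object A `workload_eval` tibble from
#'   [evaluate_vs_sequence_length()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.workload_eval <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$length_s, y = .data$accuracy,
                               colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "input sequence length (s)", y = "test accuracy",
                  colour = "model") +
    ggplot2::coord_cartesian(ylim = c(0.4, 1)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.workload_eval
#' @param eval_table A `workload_eval` tibble.
#' @export
plot_accuracy_curve <- function(eval_table) autoplot.workload_eval(eval_table)
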