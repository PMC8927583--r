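# Fusion of EEG band-power sequences with per-epoch eye features into the
# 9-element vectors consumed by the feed-forward model and the baselines.

#' Fuse EEG and eye features into multi-sensor windows
#'
#' EEG epochs are grouped into windows of `window_s` seconds and collapsed
#' (time average, then channel average per band) into 4 coefficients; the
#' 15 s eye-feature epochs whose span overlaps the window are averaged into
#' the 5 eye features. The result is one 9-element fused vector per
#' window. Windows never cross trial boundaries and are non-overlapping by
#' default (`stride_s = window_s`). Eye features still missing after
#' aggregation stay `NA`; they are imputed from training-split statistics
#' at model-fitting time.
#'
#' @param eeg_features Per-epoch band-power tibble from
#'   [band_power_features()].
#' @param eye_features Per-epoch eye feature tibble from
#'   [eye_feature_table()].
#' @param window_s Window length in seconds; must be a whole number of EEG
#'   epochs (default 25).
#' @param stride_s Window stride in seconds (default `window_s`).
#' @param epoch_s,eye_epoch_s Epoch lengths used to build the inputs.
#' @return A tibble with provenance columns, `label`, `duration_s` and the
#'   nine [fused_feature_names()] columns.
#' @export
fuse_features <- function(eeg_features, eye_features, window_s = 25,
                          stride_s = NULL, epoch_s = 5, eye_epoch_s = 15) {
  stride_s <- stride_s %||% window_s
  L <- window_s / epoch_s
  if (abs(L - round(L)) > 1e-9) {
    abort(sprintf("`window_s` (%g) must be a whole number of %g s epochs.",
                  window_s, epoch_s))
  }
  stride_epochs <- max(1L, as.integer(round(stride_s / epoch_s)))
  seqs <- build_sequences(eeg_features, as.integer(round(L)), stride_epochs)
  if (nrow(seqs) == 0) return(seqs)
  eeg_summary <- purrr::map(seqs$features, function(m) {
    collapse_sequence(m)$band_summary
  })
  eeg_mat <- do.call(rbind, eeg_summary)
  colnames(eeg_mat) <- paste0("eeg_", colnames(eeg_mat))

  eye_key <- paste(eye_features$subject, eye_features$session,
                   eye_features$trial)
  eye_groups <- split(eye_features, eye_key)
  window_key <- paste(seqs$subject, seqs$session, seqs$trial)
  eye_mat <- matrix(NA_real_, nrow(seqs), 5,
                    dimnames = list(NULL, c("pd", "nf", "ft", "ssp", "nni")))
  for (i in seq_len(nrow(seqs))) {
    grp <- eye_groups[[window_key[i]]]
    if (is.null(grp)) next
    ws <- seqs$t_start[i]
    we <- ws + window_s
    sel <- grp$t_start < we - 1e-9 & grp$t_start + eye_epoch_s > ws + 1e-9
    if (!any(sel)) next
    vals <- grp[sel, c("pd", "nf", "ft", "ssp", "nni")]
    eye_mat[i, ] <- vapply(vals, function(v) {
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
  }
  out <- dplyr::select(seqs, -"features")
  dplyr::bind_cols(out, as_tibble(eeg_mat), as_tibble(eye_mat))
}
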