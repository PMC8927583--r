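# Shared fixtures and independent oracles, all built in code.

# multichannel sinusoid recording: one frequency per channel
sine_recording <- function(freqs = c(10, 6), duration_s = 10, fs = 250,
                           amp = 10) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  samples <- t(vapply(freqs, function(f) amp * sin(2 * pi * f * t),
                      numeric(length(t))))
  eeg_recording(samples, sampling_rate = fs,
                channel_names = paste0("ch", seq_along(freqs)))
}

# gaze stream made of explicit stationary segments (for fixation tests):
# segments is a tibble-ish list with x, y, dur_s entries; samples are
# noise-free so dispersion is exactly zero within a segment.
segment_gaze <- function(segments, fs = 60, valid = NULL) {
  gx <- unlist(purrr::map(segments, function(s) {
    rep(s$x, round(s$dur_s * fs))
  }))
  gy <- unlist(purrr::map(segments, function(s) {
    rep(s$y, round(s$dur_s * fs))
  }))
  n <- length(gx)
  gaze_stream(
    timestamps = (seq_len(n) - 1) / fs, gaze_x = gx, gaze_y = gy,
    pupil_left = rep(3, n), pupil_right = rep(3.05, n),
    validity = valid %||% rep(1L, n), sampling_rate = fs
  )
}

# brute-force I-DT: for each candidate start, grow the window to the
# largest dispersion-compliant extent (recomputing dispersion from scratch)
# and keep it if it covers the minimum duration. Independent of the
# package's incremental implementation.
brute_force_fixations <- function(epoch, min_dur_ms = 85, dispersion = 0.02,
                                  fs = attr(epoch, "sampling_rate") %||% 60) {
  dt_ms <- 1000 / fs
  valid <- epoch$validity == 1L & !is.na(epoch$gaze_x) & !is.na(epoch$gaze_y)
  runs <- rle(valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (r in which(runs$values)) {
    x <- epoch$gaze_x[starts[r]:ends[r]]
    y <- epoch$gaze_y[starts[r]:ends[r]]
    ts <- epoch$timestamp[starts[r]:ends[r]]
    n <- length(x)
    min_samples <- ceiling(min_dur_ms / dt_ms)
    i <- 1L
    while (i <= n) {
      j_max <- i
      for (j in i:n) {
        disp <- (max(x[i:j]) - min(x[i:j])) + (max(y[i:j]) - min(y[i:j]))
        if (disp <= dispersion) j_max <- j else break
      }
      if (j_max - i + 1L >= min_samples) {
        out[[length(out) + 1L]] <- tibble::tibble(
          centroid_x = mean(x[i:j_max]), centroid_y = mean(y[i:j_max]),
          start_s = ts[i], duration_ms = (j_max - i + 1L) * dt_ms
        )
        i <- j_max + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (length(out)) dplyr::bind_rows(out) else {
    tibble::tibble(centroid_x = numeric(), centroid_y = numeric(),
                   start_s = numeric(), duration_ms = numeric())
  }
}

# trapezoidal band-power oracle from the raw (single-segment, untapered)
# periodogram of a whole epoch
periodogram_band_power <- function(epoch, fs, bands = band_edges()) {
  n <- ncol(epoch)
  f <- (seq_len(n %/% 2 + 1) - 1) * fs / n
  coefs <- lapply(seq_len(nrow(epoch)), function(ch) {
    x <- epoch[ch, ] - mean(epoch[ch, ])
    p <- (Mod(stats::fft(x))^2)[seq_along(f)] / (fs * n)
    p[-1] <- p[-1] * 2
    trap <- function(lo, hi) {
      sel <- which(f >= lo & f <= hi)
      sum(diff(f[sel]) * (p[sel][-1] + p[sel][-length(sel)]) / 2)
    }
    band <- mapply(trap, bands$low, bands$high)
    band / trap(min(bands$low), max(bands$high))
  })
  do.call(rbind, coefs)
}

# small fused-feature window table with linearly separable classes
separable_fused_windows <- function(n_per_class = 30, n_subjects = 2,
                                    gap = 3, seed = 42) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    labels <- rep(c(0L, 1L), each = n_per_class)
    base <- matrix(rnorm(n * 9), n, 9)
    base[labels == 1L, 1:4] <- base[labels == 1L, 1:4] + gap
    colnames(base) <- fused_feature_names()
    out <- tibble::as_tibble(base)
    out$subject <- rep(sprintf("S%02d", seq_len(n_subjects)), length.out = n)
    out$session <- 1L
    out$trial <- 1L
    out$label <- labels
    out$condition <- ifelse(labels == 1L, "HCL", "LCL")
    # interleave classes so chronological splits keep both classes
    out[order(rep(seq_len(n_per_class), 2)), ]
  })
}

# tiny labeled band-power feature table with a deterministic class shift on
# selected channel/band cells (for sequence models and topography)
toy_band_features <- function(n_epochs_per_trial = 12, n_trials = 4,
                              n_subjects = 2, shift = 0.1,
                              shift_cols = c("F7_theta", "FC5_theta"),
                              noise_sd = 0.01, seed = 99) {
  withr::with_seed(seed, {
    channels <- cap32_channels()
    fnames <- feature_names(channels)
    rows <- list()
    for (s in seq_len(n_subjects)) {
      for (tr in seq_len(n_trials)) {
        cond <- if (tr %% 2 == 1) "LCL" else "HCL"
        base <- matrix(0.25 + rnorm(n_epochs_per_trial * 128, 0, noise_sd),
                       n_epochs_per_trial, 128)
        colnames(base) <- fnames
        if (cond == "HCL") {
          base[, shift_cols] <- base[, shift_cols] + shift
        }
        # renormalize rows per channel block to keep coefficients summing to 1
        for (ch in channels) {
          cols <- paste(ch, band_edges()$band, sep = "_")
          base[, cols] <- base[, cols] / rowSums(base[, cols])
        }
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(
            subject = sprintf("S%02d", s), session = 1L, trial = tr,
            epoch_index = seq_len(n_epochs_per_trial), condition = cond,
            label = as.integer(cond == "HCL"),
            t_start = (tr - 1) * n_epochs_per_trial * 5 +
              (seq_len(n_epochs_per_trial) - 1) * 5
          ),
          tibble::as_tibble(base)
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}

# scaled-down protocols for fast smoke tests
small_protocol <- function(protocol = "dataset2", n_trials = 4,
                           trial_s = 30) {
  protocol_spec(protocol,
                trials = tibble::tibble(
                  duration_s = rep(trial_s, n_trials),
                  condition = rep_len(c("LCL", "HCL"), n_trials)
                ))
}
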