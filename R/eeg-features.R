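# EEG spectral band-power features.
#
# Continuous EEG -> non-overlapping 5 s epochs -> Welch PSD per channel ->
# normalized band-power coefficients (delta/theta/alpha/beta), assembled
# channel-major into a 128-element feature vector per epoch, then grouped
# into temporal sequences for the recurrent classifier.

#' Frequency band edges
#'
#' The four canonical bands partition the 0.5-30 Hz analysis passband:
#' delta 0.5-4, theta 4-8, alpha 8-12, beta 12-30 Hz. Bands are half-open
#' `[low, high)` except the last, which is closed, so no bin is counted
#' twice. The 12-30 Hz band is conventionally beta (it is occasionally
#' labeled gamma elsewhere; this package always calls it beta).
#'
#' @return A tibble with columns `band`, `low`, `high`.
#' @export
band_edges <- function() {
  tibble(band = c("delta", "theta", "alpha", "beta"),
         low = c(0.5, 4, 8, 12),
         high = c(4, 8, 12, 30))
}

#' Channel-major feature names
#'
#' @param channels Character vector of channel labels.
#' @param bands Band names, default the four canonical bands.
#' @return `"<channel>_<band>"` names, channel-major (all bands of channel 1,
#'   then channel 2, ...), matching the layout of the 128-element vector.
#' @export
feature_names <- function(channels, bands = band_edges()$band) {
  as.vector(t(outer(channels, bands, paste, sep = "_")))
}

#' Split a recording into non-overlapping epochs
#'
#' @param recording An [eeg_recording()].
#' @param epoch_s Epoch length in seconds (default 5).
#' @return A list of channels x samples epoch matrices, each carrying
#'   `epoch_index`, `t_start` and `sampling_rate` attributes. Trailing data
#'   shorter than one epoch is dropped; a recording shorter than `epoch_s`
#'   yields an empty list with a warning.
#' @export
epoch_eeg <- function(recording, epoch_s = 5) {
  stopifnot(inherits(recording, "eeg_recording"))
  stopifnot_scalar_number(epoch_s, "epoch_s", min = 1e-9)
  spe <- as.integer(round(epoch_s * recording$sampling_rate))
  n_epochs <- ncol(recording$samples) %/% spe
  if (n_epochs == 0) {
    warn(sprintf("recording (%.2f s) is shorter than one %g s epoch; no epochs produced.",
                 duration(recording), epoch_s))
    return(list())
  }
  lapply(seq_len(n_epochs), function(t) {
    idx <- ((t - 1) * spe + 1):(t * spe)
    m <- recording$samples[, idx, drop = FALSE]
    attr(m, "epoch_index") <- t
    attr(m, "t_start") <- recording$timestamps[idx[1]]
    attr(m, "sampling_rate") <- recording$sampling_rate
    m
  })
}

# Hann taper (periodic form, as used by standard Welch implementations).
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

# Segment start indices for Welch: 50% overlap, plus an end-anchored final
# segment so the trailing part of the epoch contributes too.
welch_starts <- function(n, nperseg) {
  step <- max(1L, nperseg %/% 2L)
  starts <- seq.int(1L, n - nperseg + 1L, by = step)
  if (tail(starts, 1) < n - nperseg + 1L) starts <- c(starts, n - nperseg + 1L)
  starts
}

# Core Welch periodogram on a columns-are-segments matrix. Each column is
# linearly detrended, Hann-tapered and transformed. Pairs of real columns
# are packed into one complex FFT column (hermitian unpacking), halving the
# transform work. Returns one-sided PSD (nperseg/2 + 1 rows), density-scaled.
welch_core <- function(segments, fs) {
  nperseg <- nrow(segments)
  ncols <- ncol(segments)
  w <- hann_window(nperseg)
  tt <- seq_len(nperseg) - (nperseg + 1) / 2
  means <- colMeans(segments)
  slopes <- colSums(segments * tt) / sum(tt^2)
  detrended <- (segments - rep(means, each = nperseg) - outer(tt, slopes)) * w
  half <- nperseg %/% 2 + 1L
  npairs <- (ncols + 1L) %/% 2L
  a_idx <- 2L * seq_len(npairs) - 1L
  b_idx <- pmin(2L * seq_len(npairs), ncols)  # last pair may duplicate
  X <- stats::mvfft(detrended[, a_idx, drop = FALSE] +
                      1i * detrended[, b_idx, drop = FALSE])
  Xk <- X[seq_len(half), , drop = FALSE]
  Xm <- X[c(1L, nperseg:(nperseg - half + 2L)), , drop = FALSE]
  scale <- 1 / (4 * fs * sum(w^2))
  pa <- Mod(Xk + Conj(Xm))^2 * scale
  pb <- Mod(Xk - Conj(Xm))^2 * scale
  p <- matrix(0, half, ncols)
  p[, a_idx] <- pa
  p[, b_idx] <- pb
  # one-sided: double everything except DC and (for even nperseg) Nyquist
  dbl <- rep(2, half)
  dbl[1] <- 1
  if (nperseg %% 2 == 0) dbl[half] <- 1
  p * dbl
}

#' Welch power spectral density of one epoch
#'
#' Per-channel PSD using Welch's method with 4 s Hann-tapered, linearly
#' detrended segments at 50% overlap (an end-anchored final segment is added
#' when the nominal step does not cover the epoch exactly, so all samples
#' contribute). Deterministic for fixed input.
#'
#' @param epoch A channels x samples matrix from [epoch_eeg()].
#' @param window_s Welch segment length in seconds (default 4).
#' @param sampling_rate Sampling rate in Hz; taken from the epoch attribute
#'   when present.
#' @return A `psd_matrix`: list with `psd` (channels x frequency bins, power
#'   density units) and `freqs` (Hz).
#' @export
welch_psd <- function(epoch, window_s = 4,
                      sampling_rate = attr(epoch, "sampling_rate")) {
  stopifnot(is.matrix(epoch), is.numeric(epoch))
  if (is.null(sampling_rate)) abort("`sampling_rate` is required.")
  nperseg <- as.integer(round(window_s * sampling_rate))
  n <- ncol(epoch)
  if (nperseg > n) {
    abort(sprintf("Welch window (%g s = %d samples) is longer than the epoch (%d samples).",
                  window_s, nperseg, n))
  }
  nch <- nrow(epoch)
  starts <- welch_starts(n, nperseg)
  nseg <- length(starts)
  # columns ordered segment-within-channel
  segs <- matrix(0, nperseg, nch * nseg)
  for (s in seq_len(nseg)) {
    segs[, (s - 1) * nch + seq_len(nch)] <-
      t(epoch[, starts[s]:(starts[s] + nperseg - 1), drop = FALSE])
  }
  p <- welch_core(segs, sampling_rate)
  half <- nrow(p)
  psd <- matrix(0, nch, half)
  for (s in seq_len(nseg)) {
    psd <- psd + t(p[, (s - 1) * nch + seq_len(nch), drop = FALSE])
  }
  psd <- psd / nseg
  rownames(psd) <- rownames(epoch)
  structure(list(psd = psd,
                 freqs = (seq_len(half) - 1) * sampling_rate / nperseg),
            class = "psd_matrix")
}

#' Normalized band-power coefficients of one epoch
#'
#' For each channel, the coefficient of band *b* is the PSD mass inside *b*
#' divided by the total PSD mass over the full analysis passband
#' (0.5-30 Hz by default, the union of the bands). Because the four bands
#' partition the passband, per-channel coefficients lie in `[0, 1]` and sum
#' to 1 up to floating-point error. The 128-element vector is assembled
#' channel-major (32 channels x 4 bands).
#'
#' @param psd A `psd_matrix` from [welch_psd()].
#' @param bands Band-edge tibble, default [band_edges()].
#' @return A named numeric vector of `channels x bands` coefficients with
#'   attributes `channels` and `bands`.
#' @export
band_power <- function(psd, bands = band_edges()) {
  stopifnot(inherits(psd, "psd_matrix"))
  f <- psd$freqs
  lo <- min(bands$low)
  hi <- max(bands$high)
  if (min(f) > lo || max(f) < hi) {
    abort("PSD frequency grid does not span the requested bands.")
  }
  in_pass <- f >= lo & f <= hi
  total <- rowSums(psd$psd[, in_pass, drop = FALSE])
  if (any(total <= 0)) {
    abort(sprintf("zero total energy in channel(s): %s.",
                  paste(rownames(psd$psd)[total <= 0], collapse = ", ")))
  }
  nb <- nrow(bands)
  coef <- matrix(0, nrow(psd$psd), nb)
  for (b in seq_len(nb)) {
    last <- b == nb
    sel <- f >= bands$low[b] & (if (last) f <= bands$high[b] else f < bands$high[b])
    coef[, b] <- rowSums(psd$psd[, sel, drop = FALSE]) / total
  }
  channels <- rownames(psd$psd) %||% paste0("ch", seq_len(nrow(psd$psd)))
  out <- as.vector(t(coef))
  names(out) <- feature_names(channels, bands$band)
  attr(out, "channels") <- channels
  attr(out, "bands") <- bands$band
  out
}

# Fast path: band-power coefficients for every epoch of one trial in a
# single FFT batch. Returns an n_epochs x (channels*bands) matrix identical
# (to floating point) to mapping welch_psd() + band_power() over epochs.
trial_band_power <- function(trial, sampling_rate, epoch_s = 5, window_s = 4,
                             bands = band_edges()) {
  nch <- nrow(trial)
  spe <- as.integer(round(epoch_s * sampling_rate))
  nperseg <- as.integer(round(window_s * sampling_rate))
  n_epochs <- ncol(trial) %/% spe
  if (n_epochs == 0) return(matrix(0, 0, nch * nrow(bands)))
  starts <- welch_starts(spe, nperseg)
  nseg <- length(starts)
  # row indices of every (epoch, segment) block in the time x channels view
  offs <- rep((seq_len(n_epochs) - 1L) * spe, each = nseg) +
    rep(starts, n_epochs)
  ridx <- rep(offs, each = nperseg) + rep(seq_len(nperseg) - 1L, length(offs))
  tv <- t(trial)                       # time x channels
  segs <- tv[ridx, , drop = FALSE]     # (nperseg * nes) x nch
  # columns ordered (epoch, segment) fastest, channel slowest
  dim(segs) <- c(nperseg, n_epochs * nseg * nch)
  p <- welch_core(segs, sampling_rate)
  f <- (seq_len(nrow(p)) - 1) * sampling_rate / nperseg
  nb <- nrow(bands)
  # per-band PSD mass for every column, then average segments per epoch
  band_mass <- vapply(seq_len(nb), function(b) {
    last <- b == nb
    sel <- f >= bands$low[b] & (if (last) f <= bands$high[b] else f < bands$high[b])
    colSums(p[sel, , drop = FALSE])
  }, numeric(ncol(p)))                 # (nes * nch) x nb
  dim(band_mass) <- c(nseg, n_epochs, nch, nb)
  per_epoch <- colMeans(band_mass)     # n_epochs x nch x nb
  total <- rowSums(per_epoch, dims = 2)  # n_epochs x nch
  if (any(total <= 0)) abort("zero total energy in a channel.")
  out <- matrix(0, n_epochs, nch * nb)
  for (b in seq_len(nb)) {
    out[, (seq_len(nch) - 1L) * nb + b] <- per_epoch[, , b] / total
  }
  colnames(out) <- feature_names(rownames(trial) %||% paste0("ch", seq_len(nch)),
                                 bands$band)
  out
}

#' Per-epoch band-power feature table for a session
#'
#' Runs the epoch / Welch / band-power pipeline over every annotated trial
#' of a synchronized session and returns one row per 5 s epoch: provenance
#' columns (`subject`, `session`, `trial`, `epoch_index`, `condition`,
#' `label`, `t_start`) followed by the 128 `<channel>_<band>` coefficients.
#' Epochs never straddle trial boundaries.
#'
#' @param session A `synced_session` from [synchronize()] or
#'   [generate_session()].
#' @param epoch_s,window_s Epoch and Welch segment lengths in seconds.
#' @param bands Band-edge tibble.
#' @return A tibble, one row per epoch.
#' @export
band_power_features <- function(session, epoch_s = 5, window_s = 4,
                                bands = band_edges()) {
  stopifnot(inherits(session, "synced_session"))
  eeg <- session$eeg
  ann <- session$annotations
  rows <- purrr::pmap(
    list(ann$start_s, ann$end_s, ann$trial_index, ann$condition,
         ann$subject, ann$session),
    function(start_s, end_s, trial_index, condition, subject, sess) {
      i1 <- findInterval(start_s - 1e-9, eeg$timestamps) + 1L
      i2 <- findInterval(end_s - 1e-9, eeg$timestamps)
      if (i2 < i1) return(NULL)
      idx <- i1:i2
      coefs <- trial_band_power(eeg$samples[, idx, drop = FALSE],
                                eeg$sampling_rate, epoch_s, window_s, bands)
      if (nrow(coefs) == 0) return(NULL)
      dplyr::bind_cols(
        tibble(subject = subject, session = sess, trial = trial_index,
               epoch_index = seq_len(nrow(coefs)),
               condition = condition,
               label = condition_to_label(condition),
               t_start = start_s + (seq_len(nrow(coefs)) - 1) * epoch_s),
        as_tibble(coefs)
      )
    }
  )
  dplyr::bind_rows(rows)
}

#' Group per-epoch feature vectors into temporal sequences
#'
#' A sliding window of `L` consecutive epochs (stride `stride`) within each
#' trial yields one `features x L` matrix per window; sequences never cross
#' trial boundaries. A window of `L` 5 s epochs spans `5 * L` seconds.
#'
#' @param features Per-epoch feature tibble from [band_power_features()].
#' @param L Sequence length in epochs (`L >= 1`).
#' @param stride Window stride in epochs (default 1).
#' @return A tibble with provenance columns and a `features` list-column of
#'   128 x L matrices; `duration_s` gives the window span in seconds.
#'   Trials with fewer than `L` epochs contribute no windows.
#' @export
build_sequences <- function(features, L, stride = 1) {
  stopifnot(is.data.frame(features))
  stopifnot_scalar_number(L, "L", min = 1)
  stopifnot_scalar_number(stride, "stride", min = 1)
  L <- as.integer(L)
  stride <- as.integer(stride)
  fcols <- setdiff(names(features),
                   c("subject", "session", "trial", "epoch_index", "condition",
                     "label", "t_start"))
  epoch_s <- if (nrow(features) > 1 && "t_start" %in% names(features)) {
    d <- diff(features$t_start[1:2])
    if (is.finite(d) && d > 0) d else 5
  } else 5
  groups <- dplyr::group_split(
    dplyr::group_by(features, .data$subject, .data$session, .data$trial)
  )
  out <- purrr::map(groups, function(g) {
    g <- dplyr::arrange(g, .data$epoch_index)
    n <- nrow(g)
    if (n < L) return(NULL)
    starts <- seq.int(1L, n - L + 1L, by = stride)
    mat <- t(as.matrix(g[, fcols]))
    tibble(
      subject = g$subject[1], session = g$session[1], trial = g$trial[1],
      window_index = seq_along(starts),
      start_epoch = g$epoch_index[starts],
      t_start = g$t_start[starts],
      condition = g$condition[1],
      label = condition_to_label(g$condition[1]),
      duration_s = L * epoch_s,
      features = lapply(starts, function(s) mat[, s:(s + L - 1), drop = FALSE])
    )
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) > 0) res <- dplyr::arrange(res, .data$subject, .data$session,
                                           .data$t_start)
  res
}

#' Collapse a feature sequence into a single EEG vector
#'
#' Time-averages the sequence into one 128-element vector (`per_channel`)
#' and further averages the band coefficients across all channels into a
#' 4-element summary (`band_summary`), the EEG half of the fused EEG + eye
#' feature vector. The channel average matches the brute-force mean over
#' all `channels x L` entries of each band.
#'
#' @param seq_matrix A features x L matrix from [build_sequences()].
#' @param n_bands Number of bands per channel in the channel-major layout.
#' @return A list with `per_channel` (named, length = features) and
#'   `band_summary` (named, length = `n_bands`).
#' @export
collapse_sequence <- function(seq_matrix, n_bands = 4) {
  stopifnot(is.matrix(seq_matrix), nrow(seq_matrix) %% n_bands == 0)
  per_channel <- rowMeans(seq_matrix)
  band_idx <- rep(seq_len(n_bands), times = nrow(seq_matrix) / n_bands)
  band_summary <- vapply(seq_len(n_bands),
                         function(b) mean(per_channel[band_idx == b]),
                         numeric(1))
  bn <- band_edges()$band
  names(band_summary) <- if (n_bands == length(bn)) bn else paste0("band", seq_len(n_bands))
  list(per_channel = per_channel, band_summary = band_summary)
}
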