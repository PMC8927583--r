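# Gaze workload features.
#
# A gaze stream is cut into non-overlapping 15 s epochs; each epoch yields
# five features: mean left-eye pupil diameter (PD, mm), number of fixations
# (NF), mean fixation time (FT, ms), scan-path length (SSP, scene units) and
# nearest-neighbour index (NNI, dimensionless). Fixations come from a
# dispersion-based (I-DT) detector; only fixations of at least 85 ms count.
# Blink gaps (validity 0) terminate candidate fixations and are excluded
# from every computation; missing features are marked NA, never imputed here.

#' Split a gaze stream into non-overlapping epochs
#'
#' @param stream A [gaze_stream()].
#' @param epoch_s Epoch length in seconds (default 15, the minimum epoch
#'   size for stable fixation statistics).
#' @return A list of per-epoch sample tibbles, each with `epoch_index`,
#'   `t_start` and `sampling_rate` attributes. The trailing remainder is
#'   dropped; a stream shorter than one epoch yields an empty list.
#' @export
epoch_gaze <- function(stream, epoch_s = 15) {
  stopifnot(inherits(stream, "gaze_stream"))
  stopifnot_scalar_number(epoch_s, "epoch_s", min = 1e-9)
  n_epochs <- floor(duration(stream) / epoch_s)
  if (n_epochs == 0) return(list())
  t0 <- stream$samples$timestamp[1]
  idx <- floor((stream$samples$timestamp - t0) / epoch_s) + 1
  lapply(seq_len(n_epochs), function(k) {
    ep <- stream$samples[idx == k, , drop = FALSE]
    attr(ep, "epoch_index") <- k
    attr(ep, "t_start") <- t0 + (k - 1) * epoch_s
    attr(ep, "sampling_rate") <- stream$sampling_rate
    ep
  })
}

#' Mean pupil diameter of one gaze epoch
#'
#' Arithmetic mean of the valid left-eye pupil samples (Tobii-style streams
#' report both eyes; the left eye is the one used for workload).
#'
#' @param epoch A per-epoch sample tibble from [epoch_gaze()].
#' @return Mean diameter in mm, or `NA` when no valid sample exists.
#' @export
mean_pupil <- function(epoch) {
  pd <- epoch$pupil_left[epoch$validity == 1L & !is.na(epoch$pupil_left)]
  if (length(pd) == 0) return(NA_real_)
  mean(pd)
}

# dispersion of a set of points: (max x - min x) + (max y - min y)
point_dispersion <- function(x, y) diff(range(x)) + diff(range(y))

#' Detect fixations with a dispersion-based (I-DT) scan
#'
#' Consecutive valid samples are grouped while their dispersion
#' (x-range + y-range) stays within `dispersion`; groups covering at least
#' `min_dur_ms` become fixations with centroid = mean of member samples.
#' Invalid (blink) samples break candidate groups. A fixation's duration
#' counts one sampling period per member sample.
#'
#' @param epoch A per-epoch sample tibble from [epoch_gaze()], or any tibble
#'   with `timestamp`, `gaze_x`, `gaze_y`, `validity` columns.
#' @param min_dur_ms Minimum fixation duration in ms (default 85; shorter
#'   gaze-stationary periods are discarded).
#' @param dispersion Dispersion threshold in scene units (default 0.02 for
#'   normalized coordinates). This is the detector's main free parameter.
#' @param sampling_rate Hz; taken from the epoch attribute when present.
#' @return A `fixation_set` tibble with columns `centroid_x`, `centroid_y`,
#'   `start_s`, `duration_ms`, in chronological order.
#' @export
detect_fixations <- function(epoch, min_dur_ms = 85, dispersion = 0.02,
                             sampling_rate = attr(epoch, "sampling_rate")) {
  if (is.null(sampling_rate)) sampling_rate <- 60
  dt_ms <- 1000 / sampling_rate
  out <- list()
  valid <- epoch$validity == 1L & !is.na(epoch$gaze_x) & !is.na(epoch$gaze_y)
  runs <- rle(valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (r in which(runs$values)) {
    x <- epoch$gaze_x[starts[r]:ends[r]]
    y <- epoch$gaze_y[starts[r]:ends[r]]
    ts <- epoch$timestamp[starts[r]:ends[r]]
    n <- length(x)
    min_samples <- ceiling(min_dur_ms / dt_ms)
    i <- 1L
    while (i + min_samples - 1L <= n) {
      j <- i + min_samples - 1L
      if (point_dispersion(x[i:j], y[i:j]) <= dispersion) {
        while (j < n &&
               point_dispersion(x[i:(j + 1L)], y[i:(j + 1L)]) <= dispersion) {
          j <- j + 1L
        }
        out[[length(out) + 1L]] <-
          c(mean(x[i:j]), mean(y[i:j]), ts[i], (j - i + 1L) * dt_ms)
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  fx <- if (length(out)) {
    m <- do.call(rbind, out)
    tibble(centroid_x = m[, 1], centroid_y = m[, 2],
           start_s = m[, 3], duration_ms = m[, 4])
  } else {
    tibble(centroid_x = numeric(), centroid_y = numeric(),
           start_s = numeric(), duration_ms = numeric())
  }
  class(fx) <- c("fixation_set", class(fx))
  fx
}

#' Fixation count and mean fixation time
#'
#' @param fixset A `fixation_set` from [detect_fixations()].
#' @return A list with `nf` (count) and `ft_ms` (mean duration in ms, `NA`
#'   when there are no fixations).
#' @export
fixation_stats <- function(fixset) {
  nf <- nrow(fixset)
  list(nf = nf, ft_ms = if (nf == 0) NA_real_ else mean(fixset$duration_ms))
}

#' Scan-path length
#'
#' Sum of Euclidean distances between chronologically consecutive fixation
#' centroids; 0 for fewer than two fixations. Units follow the scene
#' coordinates.
#'
#' @param fixset A `fixation_set`.
#' @return Non-negative scalar.
#' @export
scan_path_length <- function(fixset) {
  if (nrow(fixset) <= 1) return(0)
  sum(sqrt(diff(fixset$centroid_x)^2 + diff(fixset$centroid_y)^2))
}

# mean nearest-neighbour distance of a point set (self-pairs excluded)
mean_nn_distance <- function(x, y) {
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  mean(d[cbind(seq_len(nrow(d)), max.col(-d, ties.method = "first"))])
}

#' Nearest-neighbour index of a fixation set
#'
#' Ratio of the observed mean nearest-neighbour distance d(NN) to the same
#' statistic d(ran) averaged over `n_random_draws` uniformly random sets of
#' the same size in the scene rectangle. Values well below 1 indicate
#' spatial clustering of fixations. Scale-invariant when the scene bounds
#' scale with the coordinates.
#'
#' @param fixset A `fixation_set`.
#' @param n_random_draws Number of seeded uniform reference sets (default 100).
#' @param seed RNG seed for the reference draws; reproducible when set.
#' @param scene_bounds `c(width, height)` of the scene rectangle (default
#'   the unit square of normalized coordinates).
#' @return The NNI, or `NA` for fewer than two fixations.
#' @export
nearest_neighbor_index <- function(fixset, n_random_draws = 100, seed = NULL,
                                   scene_bounds = c(1, 1)) {
  nf <- nrow(fixset)
  if (nf < 2) return(NA_real_)
  dnn <- mean_nn_distance(fixset$centroid_x, fixset$centroid_y)
  dran <- with_seed(seed, {
    mean(vapply(seq_len(n_random_draws), function(i) {
      mean_nn_distance(runif(nf, 0, scene_bounds[1]),
                       runif(nf, 0, scene_bounds[2]))
    }, numeric(1)))
  })
  dnn / dran
}

#' Per-epoch eye workload features of a gaze stream
#'
#' Composes the five feature operations over each 15 s epoch. Features that
#' cannot be computed (no valid pupil samples, fewer than two fixations)
#' are `NA`; imputation is deferred to model training so only
#' training-split statistics are used.
#'
#' @inheritParams detect_fixations
#' @param stream A [gaze_stream()].
#' @param epoch_s Epoch length in seconds (default 15).
#' @param n_random_draws,seed Passed to [nearest_neighbor_index()]; with a
#'   seed the whole table is bit-reproducible.
#' @return A tibble with columns `epoch_index`, `t_start`, `pd`, `nf`, `ft`,
#'   `ssp`, `nni`.
#' @export
extract_eye_features <- function(stream, epoch_s = 15, min_dur_ms = 85,
                                 dispersion = 0.02, n_random_draws = 100,
                                 seed = NULL) {
  epochs <- epoch_gaze(stream, epoch_s)
  seeds <- if (is.null(seed)) {
    rep(list(NULL), length(epochs))
  } else {
    as.list(derive_seeds(seed, max(1L, length(epochs))))
  }
  rows <- purrr::map2(epochs, seeds[seq_along(epochs)], function(ep, s) {
    fx <- detect_fixations(ep, min_dur_ms, dispersion)
    st <- fixation_stats(fx)
    tibble(
      epoch_index = attr(ep, "epoch_index"),
      t_start = attr(ep, "t_start"),
      pd = mean_pupil(ep),
      nf = st$nf,
      ft = st$ft_ms,
      ssp = scan_path_length(fx),
      nni = nearest_neighbor_index(fx, n_random_draws, seed = s)
    )
  })
  dplyr::bind_rows(rows)
}

#' Per-epoch eye feature table for a session
#'
#' Like [band_power_features()] but for the gaze stream: eye features are
#' extracted trial by trial (epochs never straddle trial boundaries) with
#' provenance and condition labels attached.
#'
#' @inheritParams extract_eye_features
#' @param session A `synced_session` whose `gaze` element is non-`NULL`.
#' @return A tibble, one row per 15 s epoch.
#' @export
eye_feature_table <- function(session, epoch_s = 15, min_dur_ms = 85,
                              dispersion = 0.02, n_random_draws = 100,
                              seed = NULL) {
  stopifnot(inherits(session, "synced_session"))
  if (is.null(session$gaze)) abort("session has no gaze stream.")
  ann <- session$annotations
  g <- session$gaze
  trial_seeds <- if (is.null(seed)) {
    rep(list(NULL), nrow(ann))
  } else {
    as.list(derive_seeds(seed, max(1L, nrow(ann))))
  }
  rows <- purrr::pmap(
    list(ann$start_s, ann$end_s, ann$trial_index, ann$condition,
         ann$subject, ann$session, trial_seeds),
    function(start_s, end_s, trial_index, condition, subject, sess, ts) {
      keep <- g$samples$timestamp >= start_s - 1e-9 &
        g$samples$timestamp < end_s - 1e-9
      if (!any(keep)) return(NULL)
      gs <- g$samples[keep, ]
      sub <- gaze_stream(gs$timestamp, gs$gaze_x, gs$gaze_y, gs$pupil_left,
                         gs$pupil_right, gs$validity, g$sampling_rate)
      feats <- extract_eye_features(sub, epoch_s, min_dur_ms, dispersion,
                                    n_random_draws, seed = ts)
      if (nrow(feats) == 0) return(NULL)
      dplyr::bind_cols(
        tibble(subject = subject, session = sess, trial = trial_index,
               condition = condition,
               label = condition_to_label(condition)),
        feats
      )
    }
  )
  dplyr::bind_rows(rows)
}
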