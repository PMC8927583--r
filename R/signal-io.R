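# Data model and file I/O for synchronized EEG + gaze sessions.
#
# Two stream containers (eeg_recording, gaze_stream), a trial annotation
# table, and a synced_session bundling them on a shared clock. On-disk
# format is plain CSV: EEG as `timestamp,<ch1>,...,<chN>` in microvolts,
# gaze as `timestamp,gaze_x,gaze_y,pupil_left,pupil_right,validity`,
# annotations as `start_s,end_s,condition,trial_index[,subject,session,protocol]`.

#' Construct a continuous multichannel EEG recording
#'
#' @param samples Numeric matrix, channels x time, in microvolts.
#' @param sampling_rate Sampling rate in Hz (default 250).
#' @param channel_names Character vector of montage labels, one per row of
#'   `samples`. Defaults to `rownames(samples)`.
#' @param timestamps Optional numeric vector of per-sample times in seconds on
#'   the session clock; defaults to a regular grid starting at `t0`.
#' @param t0 Start time in seconds used when `timestamps` is not given.
#'
#' @details Invariants enforced: channel count equals `length(channel_names)`,
#'   no duplicated channel names, strictly increasing timestamps, no missing
#'   sample values (gaps must be handled upstream, they are never imputed
#'   silently).
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, sampling_rate = 250,
                          channel_names = rownames(samples),
                          timestamps = NULL, t0 = 0) {
  if (!is.matrix(samples) || !is.numeric(samples)) {
    abort("`samples` must be a numeric channels x time matrix.")
  }
  stopifnot_scalar_number(sampling_rate, "sampling_rate", min = 1e-9)
  if (is.null(channel_names)) {
    abort("`channel_names` is required (or set rownames on `samples`).")
  }
  channel_names <- as.character(channel_names)
  if (nrow(samples) != length(channel_names)) {
    abort(sprintf("channel count mismatch: %d rows but %d channel names.",
                  nrow(samples), length(channel_names)))
  }
  if (anyDuplicated(channel_names)) {
    abort(sprintf("duplicate channel names: %s.",
                  paste(unique(channel_names[duplicated(channel_names)]),
                        collapse = ", ")))
  }
  if (anyNA(samples) || !all(is.finite(samples))) {
    abort("`samples` contains missing or non-finite values.")
  }
  if (is.null(timestamps)) {
    timestamps <- t0 + seq_len(ncol(samples)) / sampling_rate - 1 / sampling_rate
  }
  if (length(timestamps) != ncol(samples)) {
    abort("`timestamps` length must equal the number of samples.")
  }
  if (ncol(samples) > 1 && any(diff(timestamps) <= 0)) {
    abort("`timestamps` must be strictly increasing.")
  }
  rownames(samples) <- channel_names
  new_eeg_recording(samples, sampling_rate, channel_names,
                    as.numeric(timestamps))
}

# trusted constructor: invariants already established by the caller
new_eeg_recording <- function(samples, sampling_rate, channel_names,
                              timestamps) {
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         channel_names = channel_names, timestamps = timestamps),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate, duration(x)))
  cat("  channels:", paste(head(x$channel_names, 8), collapse = " "),
      if (length(x$channel_names) > 8) "..." else "", "\n")
  invisible(x)
}

#' Duration of a stream in seconds
#'
#' Counts one sampling period per sample, so a 2500-sample recording at
#' 250 Hz has a duration of 10 s.
#'
#' @param x An `eeg_recording` or `gaze_stream`.
#' @return Duration in seconds.
#' @export
duration <- function(x) UseMethod("duration")

#' @export
duration.eeg_recording <- function(x) ncol(x$samples) / x$sampling_rate

#' @export
duration.gaze_stream <- function(x) nrow(x$samples) / x$sampling_rate

# Half-open time span [start, end) covered by a stream.
stream_span <- function(x) {
  ts <- if (inherits(x, "eeg_recording")) x$timestamps else x$samples$timestamp
  c(ts[1], ts[length(ts)] + 1 / x$sampling_rate)
}

#' Construct a gaze stream
#'
#' @param timestamps Seconds on the session clock, non-decreasing.
#' @param gaze_x,gaze_y 2D gaze position in normalized scene coordinates.
#' @param pupil_left,pupil_right Pupil diameters in millimetres; may be `NA`
#'   during blinks.
#' @param validity Integer/logical mask; samples with `validity == 0` (blink
#'   gaps) are excluded from all feature computations, never interpolated.
#' @param sampling_rate Sampling rate in Hz (default 60).
#'
#' @return An object of class `gaze_stream` holding a tibble of samples.
#' @export
gaze_stream <- function(timestamps, gaze_x, gaze_y, pupil_left, pupil_right,
                        validity = 1L, sampling_rate = 60) {
  stopifnot_scalar_number(sampling_rate, "sampling_rate", min = 1e-9)
  n <- length(timestamps)
  samples <- tibble(
    timestamp = as.numeric(timestamps),
    gaze_x = as.numeric(gaze_x),
    gaze_y = as.numeric(gaze_y),
    pupil_left = as.numeric(pupil_left),
    pupil_right = as.numeric(pupil_right),
    validity = as.integer(rep_len(validity, n))
  )
  if (n > 1 && any(diff(samples$timestamp) < 0)) {
    abort("gaze `timestamps` must be non-decreasing.")
  }
  if (!any(samples$validity == 1L)) {
    abort("gaze stream has no valid samples.")
  }
  valid <- samples$validity == 1L
  if (anyNA(samples$gaze_x[valid]) || anyNA(samples$gaze_y[valid])) {
    abort("valid gaze samples must have finite coordinates.")
  }
  new_gaze_stream(samples, sampling_rate)
}

new_gaze_stream <- function(samples, sampling_rate) {
  structure(list(samples = samples, sampling_rate = sampling_rate),
            class = "gaze_stream")
}

#' @export
print.gaze_stream <- function(x, ...) {
  cat(sprintf("<gaze_stream> %d samples @ %g Hz (%.1f s), %.1f%% valid\n",
              nrow(x$samples), x$sampling_rate, duration(x),
              100 * mean(x$samples$validity == 1L)))
  invisible(x)
}

#' Construct a trial annotation table
#'
#' One row per trial with its time span on the session clock and its
#' workload condition label (`"LCL"` low load, `"HCL"` high load).
#'
#' @param start_s,end_s Trial boundaries in seconds, `end_s > start_s`.
#' @param condition Character vector of `"LCL"`/`"HCL"`.
#' @param trial_index Integer trial indices; default sequential.
#' @param subject,session Optional provenance identifiers.
#' @param protocol Optional protocol tag (`"dataset1"` or `"dataset2"`).
#'
#' @return A tibble with one validated row per trial.
#' @export
trial_annotations <- function(start_s, end_s, condition,
                              trial_index = seq_along(start_s),
                              subject = NA_character_, session = NA_integer_,
                              protocol = NA_character_) {
  ann <- tibble(
    subject = as.character(subject), session = as.integer(session),
    trial_index = as.integer(trial_index),
    start_s = as.numeric(start_s), end_s = as.numeric(end_s),
    condition = as.character(condition), protocol = as.character(protocol)
  )
  check_condition(ann$condition)
  if (any(ann$end_s <= ann$start_s)) {
    abort("every trial must satisfy end_s > start_s.")
  }
  ann <- dplyr::arrange(ann, .data$subject, .data$session, .data$start_s)
  overlap <- dplyr::group_by(ann, .data$subject, .data$session)
  overlap <- dplyr::summarise(
    overlap,
    bad = dplyr::n() > 1 && any(utils::head(.data$end_s, -1) >
                                  utils::tail(.data$start_s, -1) + 1e-9),
    .groups = "drop"
  )
  if (any(overlap$bad)) abort("trials within a session must not overlap.")
  ann
}

# ---- file readers / writers -------------------------------------------------

read_csv_quiet <- function(path, ...) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE, ...)
}

# full-precision CSV writer: doubles are printed with 17 significant digits
# so that numeric streams round-trip bit-identically through disk
write_csv_full <- function(tab, path) {
  cols <- lapply(tab, function(col) {
    if (is.double(col)) {
      out <- sprintf("%.17g", col)
      out[is.na(col)] <- "NA"
      out
    } else {
      as.character(col)
    }
  })
  lines <- do.call(paste, c(cols, sep = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(tab), collapse = ","), con)
  writeLines(lines, con)
  invisible(path)
}

#' Read / write an EEG recording as CSV
#'
#' Tabular dialect: a header row, `timestamp` in seconds as first column and
#' one column per channel in microvolts. `write_eeg_csv()` preserves full
#' double precision so recordings round-trip exactly.
#'
#' @param path File path.
#' @param sampling_rate Sampling rate in Hz of the stored recording.
#' @return `read_eeg_csv()` returns an [eeg_recording()];
#'   `write_eeg_csv()` returns `path` invisibly.
#' @export
read_eeg_csv <- function(path, sampling_rate = 250) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (length(header) < 2 || header[1] != "timestamp") {
    abort("EEG file must have a `timestamp` first column plus channel columns.")
  }
  channels <- header[-1]
  if (anyDuplicated(channels)) {
    abort(sprintf("duplicate channel columns: %s.",
                  paste(unique(channels[duplicated(channels)]), collapse = ", ")))
  }
  # base reader: strtod parsing is correctly rounded, so full-precision
  # files round-trip bit-identically
  tab <- utils::read.csv(path, colClasses = "numeric", check.names = FALSE)
  if (anyNA(tab)) abort("EEG file contains missing values.")
  if (nrow(tab) > 1 && any(diff(tab$timestamp) <= 0)) {
    abort("EEG timestamps must be strictly increasing.")
  }
  rec <- eeg_recording(t(as.matrix(tab[, channels, drop = FALSE])),
                       sampling_rate = sampling_rate,
                       channel_names = channels,
                       timestamps = tab$timestamp)
  check_line_noise(rec)
  rec
}

#' @rdname read_eeg_csv
#' @param x An `eeg_recording`.
#' @export
write_eeg_csv <- function(x, path) {
  stopifnot(inherits(x, "eeg_recording"))
  tab <- as_tibble(t(x$samples))
  tab <- dplyr::bind_cols(tibble(timestamp = x$timestamps), tab)
  write_csv_full(tab, path)
}

#' Load an EEG recording
#'
#' Thin dialect dispatcher over the file readers. Only the tabular CSV
#' dialect is implemented; `"xdf"` is reserved and raises an unsupported
#' format error.
#'
#' @inheritParams read_eeg_csv
#' @param dialect `"tabular"` (CSV) or `"xdf"` (unsupported).
#' @return An [eeg_recording()].
#' @export
load_eeg <- function(path, dialect = c("tabular", "xdf"), sampling_rate = 250) {
  dialect <- match.arg(dialect)
  if (dialect == "xdf") {
    abort("XDF container support is not implemented; use the tabular dialect.")
  }
  read_eeg_csv(path, sampling_rate = sampling_rate)
}

#' Read / write a gaze stream as CSV
#'
#' Columns: `timestamp,gaze_x,gaze_y,pupil_left,pupil_right,validity`.
#' Blink gaps (validity 0) are kept as rows and flagged invalid; they are
#' never interpolated.
#'
#' @param path File path.
#' @param sampling_rate Sampling rate in Hz of the stored stream.
#' @return `read_gaze_csv()` / `load_gaze()` return a [gaze_stream()];
#'   `write_gaze_csv()` returns `path` invisibly.
#' @export
read_gaze_csv <- function(path, sampling_rate = 60) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  required <- c("timestamp", "gaze_x", "gaze_y", "pupil_left", "pupil_right",
                "validity")
  tab <- utils::read.csv(path, check.names = FALSE)
  if (!all(required %in% names(tab))) {
    abort(sprintf("gaze file must have columns: %s.",
                  paste(required, collapse = ", ")))
  }
  gaze_stream(tab$timestamp, tab$gaze_x, tab$gaze_y, tab$pupil_left,
              tab$pupil_right, tab$validity, sampling_rate = sampling_rate)
}

#' @rdname read_gaze_csv
#' @export
load_gaze <- read_gaze_csv

#' @rdname read_gaze_csv
#' @param x A `gaze_stream`.
#' @export
write_gaze_csv <- function(x, path) {
  stopifnot(inherits(x, "gaze_stream"))
  write_csv_full(x$samples, path)
}

#' Read / write trial annotations as CSV
#'
#' @param path File path.
#' @return `read_annotations_csv()` returns the validated annotation tibble;
#'   `write_annotations_csv()` returns `path` invisibly.
#' @export
read_annotations_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tab <- read_csv_quiet(path)
  required <- c("start_s", "end_s", "condition", "trial_index")
  if (!all(required %in% names(tab))) {
    abort(sprintf("annotation file must have columns: %s.",
                  paste(required, collapse = ", ")))
  }
  trial_annotations(
    tab$start_s, tab$end_s, tab$condition, tab$trial_index,
    subject = tab$subject %||% NA_character_,
    session = tab$session %||% NA_integer_,
    protocol = tab$protocol %||% NA_character_
  )
}

#' @rdname read_annotations_csv
#' @param x An annotation tibble from [trial_annotations()].
#' @export
write_annotations_csv <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

# Acquisition applies a 0.5-30 Hz band-pass and a 58-62 Hz notch upstream;
# loading only sanity-checks that mains frequency does not dominate.
check_line_noise <- function(rec) {
  n <- min(ncol(rec$samples), as.integer(rec$sampling_rate * 20))
  if (n < 64 || rec$sampling_rate < 130) return(invisible(rec))
  x <- rec$samples[1, seq_len(n)]
  p <- Mod(stats::fft(x - mean(x)))^2
  f <- (seq_len(n) - 1) * rec$sampling_rate / n
  mains <- mean(p[f >= 58 & f <= 62])
  pass <- mean(p[f >= 0.5 & f <= 30])
  if (is.finite(mains) && is.finite(pass) && pass > 0 && mains > pass) {
    warn("possible uncorrected 60 Hz line noise: mains band power exceeds the 0.5-30 Hz passband mean.")
  }
  invisible(rec)
}

# ---- synchronization --------------------------------------------------------

#' Synchronize EEG, gaze and trial annotations onto a common interval
#'
#' Both streams must carry timestamps on the same clock (file replay assumes
#' clock offsets were corrected at acquisition). Streams are trimmed to their
#' common time interval; annotations falling (partly) outside it are rejected
#' and reported via the `rejected_annotations` attribute and a warning.
#'
#' @param eeg An [eeg_recording()].
#' @param gaze Optional [gaze_stream()] (EEG-only sessions pass `NULL`).
#' @param annotations Annotation tibble from [trial_annotations()].
#' @return A `synced_session` with elements `eeg`, `gaze`, `annotations`.
#' @export
synchronize <- function(eeg, gaze = NULL, annotations) {
  stopifnot(inherits(eeg, "eeg_recording"))
  span <- stream_span(eeg)
  if (!is.null(gaze)) {
    stopifnot(inherits(gaze, "gaze_stream"))
    gspan <- stream_span(gaze)
    lo <- max(span[1], gspan[1])
    hi <- min(span[2], gspan[2])
    if (hi <= lo) abort("EEG and gaze time ranges are disjoint; cannot synchronize.")
    if (lo > span[1] + 1e-12 || hi < span[2] - 1e-12) {
      keep <- eeg$timestamps >= lo & eeg$timestamps < hi
      eeg <- new_eeg_recording(eeg$samples[, keep, drop = FALSE],
                               eeg$sampling_rate, eeg$channel_names,
                               eeg$timestamps[keep])
    }
    if (lo > gspan[1] + 1e-12 || hi < gspan[2] - 1e-12) {
      gkeep <- gaze$samples$timestamp >= lo & gaze$samples$timestamp < hi
      gaze <- new_gaze_stream(gaze$samples[gkeep, ], gaze$sampling_rate)
    }
    span <- c(lo, hi)
  }
  inside <- annotations$start_s >= span[1] - 1e-9 &
    annotations$end_s <= span[2] + 1e-9
  rejected <- annotations[!inside, ]
  if (nrow(rejected) > 0) {
    warn(sprintf("%d annotation(s) outside the synchronized interval [%.3f, %.3f] s were rejected.",
                 nrow(rejected), span[1], span[2]))
  }
  structure(
    list(eeg = eeg, gaze = gaze, annotations = annotations[inside, ],
         rejected_annotations = rejected),
    class = "synced_session"
  )
}

#' @export
print.synced_session <- function(x, ...) {
  cat(sprintf("<synced_session> %d trial(s), EEG %.1f s%s\n",
              nrow(x$annotations), duration(x$eeg),
              if (is.null(x$gaze)) "" else sprintf(", gaze %.1f s", duration(x$gaze))))
  invisible(x)
}

# ---- chronological splitting ------------------------------------------------

#' Chronological 60-20-20 split of labeled windows
#'
#' Within each subject, windows (assumed in chronological order) are
#' partitioned so the first 60% train the model, the next 20% tune it and
#' the last 20% test it. Train and validation sizes use `floor`; the
#' remainder goes to test, so partitions are disjoint and exhaustive.
#'
#' @param windows A tibble of labeled windows with a `subject` column,
#'   ordered by time within subject.
#' @param train_frac,validation_frac Split fractions (default 0.6 / 0.2).
#' @return `windows` with an added `.split` factor
#'   (`train`/`validation`/`test`).
#' @export
chronological_split <- function(windows, train_frac = 0.6,
                                validation_frac = 0.2) {
  stopifnot(is.data.frame(windows))
  if (!"subject" %in% names(windows)) abort("`windows` must have a `subject` column.")
  if (train_frac <= 0 || validation_frac <= 0 || train_frac + validation_frac >= 1) {
    abort("split fractions must be positive and sum to less than 1.")
  }
  windows <- as_tibble(windows)
  out <- dplyr::group_by(windows, .data$subject)
  out <- dplyr::mutate(out, .split = {
    n <- dplyr::n()
    if (n < 5) {
      abort(sprintf("subject %s has %d windows; at least 5 are required to split.",
                    .data$subject[1], n))
    }
    n_train <- floor(train_frac * n)
    n_val <- floor(validation_frac * n)
    factor(rep(c("train", "validation", "test"),
               c(n_train, n_val, n - n_train - n_val)),
           levels = c("train", "validation", "test"))
  })
  dplyr::ungroup(out)
}
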