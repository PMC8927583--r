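# Synthetic physiological-signal generator.
#
# Emulates the two acquisition protocols so the whole pipeline is testable
# without recorded human data: per-channel EEG as a sum of band-limited
# Gaussian oscillators (2 Hz wide, one per canonical band) over 1/f
# background noise, synthesized spectrally at 250 Hz; gaze as an
# alternating fixation/saccade process at 60 Hz with log-normal fixation
# durations, pupil drift and blink gaps. High-workload trials scale the
# theta/alpha oscillator amplitudes up (and delta down) on fronto-temporal
# channels, shift the mean pupil diameter and raise the fixation rate.

#' The 32-channel recording montage
#'
#' Channel labels of the 32-electrode gel cap used by both protocols
#' (10-10 names; AFZ is ground and the right earlobe is reference, so
#' neither appears as a data channel).
#'
#' @return Character vector of 32 channel labels.
#' @export
cap32_channels <- function() {
  c("FP1", "FP2", "AF3", "AF4", "F7", "F3", "FZ", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "T7", "C3", "CZ", "C4", "T8",
    "CP5", "CP1", "CP2", "CP6", "P7", "P3", "PZ", "P4", "P8",
    "PO7", "PO3", "PO4", "PO8", "OZ")
}

#' Effect specification for the synthetic generator
#'
#' Describes how the high-cognitive-load (HCL) condition differs from the
#' low-load (LCL) baseline, plus the LCL spectral composition itself. The
#' defaults realize the qualitative physiological signature of high
#' workload: elevated theta and alpha oscillations over fronto-temporal
#' electrodes, delta suppression on F7/FC5/T8, pupil dilation and a higher
#' fixation rate.
#'
#' @param hcl_theta_gain,hcl_alpha_gain Multiplicative amplitude factors
#'   applied to the theta / alpha oscillators on their affected channels
#'   under HCL (defaults 1.5 and 1.3).
#' @param hcl_delta_gain Amplitude factor (< 1 suppresses) for the delta
#'   oscillator on `delta_channels` under HCL (default 0.8).
#' @param theta_channels,alpha_channels,delta_channels Affected channel
#'   sets; defaults are the fronto-temporal sets where workload effects are
#'   expected.
#' @param pupil_shift_mm Additive HCL increase of mean pupil diameter in mm
#'   (default 0.4).
#' @param fixation_rate_factor Multiplicative HCL increase of the fixation
#'   rate (fixation durations are divided by it; default 1.3).
#' @param pupil_base_mm Baseline LCL mean pupil diameter (default 3.0 mm).
#' @param osc_rms_uv Named RMS amplitudes (microvolts) of the four band
#'   oscillators under LCL.
#' @param noise_rms_uv RMS amplitude of the 1/f background over the
#'   passband (default 3).
#' @param noise_exponent Spectral exponent of the background (default 1).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(hcl_theta_gain = 1.5,
                        hcl_alpha_gain = 1.3,
                        hcl_delta_gain = 0.8,
                        theta_channels = c("FP1", "AF3", "AF4", "F7", "F3",
                                           "F4", "F8", "FC5", "FC2", "FC6",
                                           "T7", "C3", "C4", "T8", "CP5"),
                        alpha_channels = c("F7", "F8", "FC5", "FC6", "T7",
                                           "C4", "T8", "CP5", "CP6"),
                        delta_channels = c("F7", "FC5", "T8"),
                        pupil_shift_mm = 0.4,
                        fixation_rate_factor = 1.3,
                        pupil_base_mm = 3.0,
                        osc_rms_uv = c(delta = 4, theta = 3, alpha = 3, beta = 2),
                        noise_rms_uv = 3,
                        noise_exponent = 1) {
  gains <- c(hcl_theta_gain, hcl_alpha_gain, hcl_delta_gain)
  if (any(!is.finite(gains)) || any(gains <= 0)) {
    abort("effect gains must be positive.")
  }
  chans <- unique(c(theta_channels, alpha_channels, delta_channels))
  unknown <- setdiff(chans, cap32_channels())
  if (length(unknown)) {
    abort(sprintf("affected channels not in the montage: %s.",
                  paste(unknown, collapse = ", ")))
  }
  if (!all(c("delta", "theta", "alpha", "beta") %in% names(osc_rms_uv))) {
    abort("`osc_rms_uv` must name delta, theta, alpha and beta amplitudes.")
  }
  if (fixation_rate_factor <= 0) abort("`fixation_rate_factor` must be positive.")
  structure(
    list(hcl_theta_gain = hcl_theta_gain, hcl_alpha_gain = hcl_alpha_gain,
         hcl_delta_gain = hcl_delta_gain,
         theta_channels = theta_channels, alpha_channels = alpha_channels,
         delta_channels = delta_channels,
         pupil_shift_mm = pupil_shift_mm,
         fixation_rate_factor = fixation_rate_factor,
         pupil_base_mm = pupil_base_mm,
         osc_rms_uv = osc_rms_uv, noise_rms_uv = noise_rms_uv,
         noise_exponent = noise_exponent),
    class = "effect_spec"
  )
}

#' Null effect specification
#'
#' All HCL gains at 1, no pupil shift, no fixation-rate change: both
#' conditions are generated from the same distribution. Used to calibrate
#' that the classifiers find nothing when there is nothing to find.
#'
#' @inheritParams effect_spec
#' @return An `effect_spec` with every condition effect switched off.
#' @export
null_effect_spec <- function(...) {
  effect_spec(hcl_theta_gain = 1, hcl_alpha_gain = 1, hcl_delta_gain = 1,
              pupil_shift_mm = 0, fixation_rate_factor = 1, ...)
}

#' Acquisition protocol specification
#'
#' `dataset1`: six 5-minute peg-transfer trials per session, three under
#' normal teleoperation (LCL) and three under inverted teleoperation (HCL),
#' EEG only, trial order randomized per session seed. `dataset2`: ten
#' 3-minute needle-pass trials alternating no-bleeding (LCL) and bleeding
#' (HCL), starting with LCL, EEG + gaze. Both total 30 minutes of signal.
#'
#' @param protocol `"dataset1"` or `"dataset2"`.
#' @param trials Optional custom trial table (columns `duration_s`,
#'   `condition`) replacing the standard protocol, e.g. for scaled-down
#'   smoke runs. Custom tables keep the protocol's gaze setting.
#' @param include_gaze Override whether sessions carry a gaze stream.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(protocol = c("dataset1", "dataset2"), trials = NULL,
                          include_gaze = NULL) {
  protocol <- match.arg(protocol)
  standard <- is.null(trials)
  if (standard) {
    trials <- if (protocol == "dataset1") {
      tibble(duration_s = rep(300, 6),
             condition = rep(c("LCL", "HCL"), each = 3))
    } else {
      tibble(duration_s = rep(180, 10),
             condition = rep(c("LCL", "HCL"), 5))
    }
  } else {
    trials <- as_tibble(trials)
    stopifnot(all(c("duration_s", "condition") %in% names(trials)))
    check_condition(trials$condition)
  }
  structure(
    list(protocol_id = protocol, trials = trials,
         include_gaze = include_gaze %||% (protocol == "dataset2"),
         randomize_order = standard && protocol == "dataset1"),
    class = "protocol_spec"
  )
}

# ---- EEG synthesis ----------------------------------------------------------

# Analytic per-band signal variance (uV^2) for one channel under a given
# condition: oscillator variance (with HCL gain applied) plus the share of
# the 1/f background falling in the band. Used by generate_eeg and, in
# reverse, by tests as the expected spectral composition.
band_variances <- function(effect, condition, channel) {
  bands <- band_edges()
  osc <- effect$osc_rms_uv[bands$band]^2
  if (condition == "HCL") {
    if (channel %in% effect$theta_channels) {
      osc["theta"] <- osc["theta"] * effect$hcl_theta_gain^2
    }
    if (channel %in% effect$alpha_channels) {
      osc["alpha"] <- osc["alpha"] * effect$hcl_alpha_gain^2
    }
    if (channel %in% effect$delta_channels) {
      osc["delta"] <- osc["delta"] * effect$hcl_delta_gain^2
    }
  }
  e <- effect$noise_exponent
  pink_int <- function(lo, hi) {
    if (abs(e - 1) < 1e-12) log(hi / lo) else (hi^(1 - e) - lo^(1 - e)) / (1 - e)
  }
  w <- mapply(pink_int, bands$low, bands$high)
  pink <- effect$noise_rms_uv^2 * w / pink_int(min(bands$low), max(bands$high))
  total <- osc + pink
  names(total) <- bands$band
  total
}

# 2 Hz wide oscillator support centered in each band
oscillator_bands <- function() {
  tibble(band = c("delta", "theta", "alpha", "beta"),
         lo = c(1, 5, 9, 20), hi = c(3, 7, 11, 22))
}

#' Generate a synthetic EEG recording
#'
#' Spectral synthesis: a hermitian complex-Gaussian spectrum is shaped so
#' each channel carries four 2 Hz wide band-limited oscillators plus a 1/f
#' background confined to 0.5-30 Hz, then inverse-transformed. Under HCL
#' the effect gains scale the oscillator amplitudes on the affected
#' channels. Deterministic for a fixed seed.
#'
#' @param condition `"LCL"` or `"HCL"`.
#' @param duration_s Duration in seconds (>= 5).
#' @param effect An [effect_spec()].
#' @param seed RNG seed.
#' @param channels Channel labels (default the 32-channel montage).
#' @param sampling_rate Hz (default 250).
#' @param t0 Start time on the session clock.
#' @param amp_scale Global amplitude multiplier (models day-to-day drift).
#' @return An [eeg_recording()].
#' @export
generate_eeg <- function(condition, duration_s, effect = effect_spec(),
                         seed = NULL, channels = cap32_channels(),
                         sampling_rate = 250, t0 = 0, amp_scale = 1) {
  condition <- match.arg(condition, condition_levels)
  stopifnot_scalar_number(duration_s, "duration_s", min = 5)
  n <- as.integer(round(duration_s * sampling_rate))
  nch <- length(channels)
  freqs <- (seq_len(n %/% 2)) * sampling_rate / n  # positive-frequency bins
  bands <- band_edges()
  osc <- oscillator_bands()
  e <- effect$noise_exponent

  # per-bin variance targets (positive freqs); scaling: a band of total
  # variance V spread over bins k with weights w_k (sum 1) needs
  # E|X_k|^2 = V * n^2 * w_k / 2 in the hermitian construction.
  vmat <- matrix(0, length(freqs), nch)
  for (b in seq_len(4)) {
    idx <- which(freqs >= osc$lo[b] & freqs <= osc$hi[b])
    base_var <- effect$osc_rms_uv[[osc$band[b]]]^2
    gains <- rep(1, nch)
    if (condition == "HCL") {
      g <- switch(osc$band[b], theta = effect$hcl_theta_gain,
                  alpha = effect$hcl_alpha_gain,
                  delta = effect$hcl_delta_gain, 1)
      affected <- switch(osc$band[b], theta = effect$theta_channels,
                         alpha = effect$alpha_channels,
                         delta = effect$delta_channels, character())
      gains[channels %in% affected] <- g
    }
    vmat[idx, ] <- vmat[idx, ] +
      outer(rep(base_var / length(idx), length(idx)), gains^2)
  }
  pass <- which(freqs >= min(bands$low) & freqs <= max(bands$high))
  w <- freqs[pass]^(-e)
  w <- w / sum(w)
  vmat[pass, ] <- vmat[pass, ] + effect$noise_rms_uv^2 * w
  vmat <- vmat * amp_scale^2

  occupied <- which(rowSums(vmat) > 0)
  x <- with_seed(seed, {
    m <- length(occupied)
    Z <- matrix(complex(real = rnorm(m * nch), imaginary = rnorm(m * nch)),
                m, nch) / sqrt(2)
    Xpos <- sqrt(vmat[occupied, , drop = FALSE] / 2) * Z * n
    # pack channel pairs (a + i b) into one hermitian-mirrored spectrum so a
    # single inverse FFT yields two real channels (Re -> a, Im -> b)
    npairs <- (nch + 1L) %/% 2L
    a_idx <- 2L * seq_len(npairs) - 1L
    b_idx <- pmin(2L * seq_len(npairs), nch)
    C <- matrix(0 + 0i, n, npairs)
    Xb <- Xpos[, b_idx, drop = FALSE]
    if (any(b_idx == a_idx)) Xb[, b_idx == a_idx] <- 0 + 0i
    C[occupied + 1L, ] <- Xpos[, a_idx, drop = FALSE] + 1i * Xb
    C[n + 1L - occupied, ] <- Conj(Xpos[, a_idx, drop = FALSE]) +
      1i * Conj(Xb)
    y <- stats::mvfft(C, inverse = TRUE) / n
    out <- matrix(0, n, nch)
    out[, a_idx] <- Re(y)
    out[, setdiff(b_idx, a_idx)] <- Im(y[, b_idx != a_idx, drop = FALSE])
    out
  })
  samples <- t(x)
  rownames(samples) <- channels
  new_eeg_recording(samples, sampling_rate, channels,
                    t0 + (seq_len(n) - 1) / sampling_rate)
}

# ---- gaze synthesis ---------------------------------------------------------

#' Generate a synthetic gaze stream
#'
#' Alternating fixation/saccade process at 60 Hz: fixation centers uniform
#' in the scene, durations log-normal (truncated at 120 ms under LCL),
#' within-fixation jitter well inside the detector's dispersion threshold,
#' short linear saccades, slow AR(1) pupil drift with measurement noise and
#' occasional blink gaps flagged invalid. Under HCL the mean pupil diameter
#' shifts by `pupil_shift_mm` and fixation durations shrink by
#' `fixation_rate_factor`.
#'
#' @inheritParams generate_eeg
#' @param duration_s Duration in seconds (>= 15).
#' @param sampling_rate Hz (default 60).
#' @param pupil_base_shift Additive session-level pupil offset in mm
#'   (models day-to-day drift).
#' @return A [gaze_stream()].
#' @export
generate_gaze <- function(condition, duration_s, effect = effect_spec(),
                          seed = NULL, sampling_rate = 60, t0 = 0,
                          pupil_base_shift = 0) {
  condition <- match.arg(condition, condition_levels)
  stopifnot_scalar_number(duration_s, "duration_s", min = 15)
  n <- as.integer(round(duration_s * sampling_rate))
  dt <- 1 / sampling_rate
  rate_factor <- if (condition == "HCL") effect$fixation_rate_factor else 1
  pupil_mean <- effect$pupil_base_mm + pupil_base_shift +
    if (condition == "HCL") effect$pupil_shift_mm else 0

  with_seed(seed, {
    gx <- numeric(n)
    gy <- numeric(n)
    i <- 1L
    prev <- runif(2, 0.3, 0.7)
    while (i <= n) {
      center <- runif(2, 0.05, 0.95)
      # saccade towards the new center (1-3 samples)
      ns_sac <- sample(1:3, 1)
      for (s in seq_len(ns_sac)) {
        if (i > n) break
        frac <- s / (ns_sac + 1)
        gx[i] <- prev[1] + frac * (center[1] - prev[1])
        gy[i] <- prev[2] + frac * (center[2] - prev[2])
        i <- i + 1L
      }
      dur <- max(stats::rlnorm(1, log(0.28), 0.35), 0.12) / rate_factor
      ns_fix <- max(1L, as.integer(round(dur / dt)))
      if (i > n) break
      idx <- i:min(n, i + ns_fix - 1L)
      gx[idx] <- center[1] + rnorm(length(idx), 0, 0.002)
      gy[idx] <- center[2] + rnorm(length(idx), 0, 0.002)
      i <- i + ns_fix
      prev <- center
    }
    # slow AR(1) pupil drift plus measurement noise
    drift <- numeric(n)
    innov <- rnorm(n, 0, 0.01)
    phi <- 0.995
    drift[1] <- rnorm(1, 0, 0.01 / sqrt(1 - phi^2))
    for (k in 2:n) drift[k] <- phi * drift[k - 1] + innov[k]
    pupil_l <- pupil_mean + drift + rnorm(n, 0, 0.02)
    pupil_r <- pupil_l + rnorm(n, 0.05, 0.02)
    # blink gaps: exponential inter-blink intervals, 150-300 ms long
    validity <- rep(1L, n)
    tpos <- stats::rexp(1, 1 / 8)
    while (tpos < duration_s) {
      blink <- tpos + c(0, runif(1, 0.15, 0.3))
      idx <- which(seq_len(n) * dt > blink[1] & seq_len(n) * dt <= blink[2])
      validity[idx] <- 0L
      tpos <- blink[2] + stats::rexp(1, 1 / 8)
    }
    pupil_l[validity == 0L] <- NA_real_
    pupil_r[validity == 0L] <- NA_real_
    gx[validity == 0L] <- NA_real_
    gy[validity == 0L] <- NA_real_
    gaze_stream(t0 + (seq_len(n) - 1) * dt, gx, gy, pupil_l, pupil_r,
                validity, sampling_rate = sampling_rate)
  })
}

# ---- session / study builders ----------------------------------------------

#' Generate one synthetic recording session
#'
#' Concatenates the protocol's trials into continuous EEG (and gaze, for
#' protocols that include it) with matching trial annotations, bundled as a
#' synchronized session.
#'
#' @param protocol A [protocol_spec()].
#' @param effect An [effect_spec()].
#' @param seed Session seed; trial-level seeds derive from it.
#' @param subject,session Provenance identifiers.
#' @param amp_scale,pupil_base_shift Session-level drift parameters (see
#'   [generate_study()]).
#' @return A `synced_session`.
#' @export
generate_session <- function(protocol, effect = effect_spec(), seed = NULL,
                             subject = "S01", session = 1L, amp_scale = 1,
                             pupil_base_shift = 0) {
  stopifnot(inherits(protocol, "protocol_spec"))
  trials <- protocol$trials
  n_trials <- nrow(trials)
  seeds <- derive_seeds(seed %||% sample.int(1e6, 1), n_trials + 1L)
  if (protocol$randomize_order) {
    ord <- with_seed(seeds[n_trials + 1L], sample.int(n_trials))
    trials <- trials[ord, ]
  }
  starts <- cumsum(c(0, trials$duration_s))[seq_len(n_trials)]
  eeg_parts <- vector("list", n_trials)
  gaze_parts <- if (protocol$include_gaze) vector("list", n_trials) else NULL
  for (k in seq_len(n_trials)) {
    trial_seeds <- derive_seeds(seeds[k], 2L)
    eeg_parts[[k]] <- generate_eeg(trials$condition[k], trials$duration_s[k],
                                   effect, seed = trial_seeds[1],
                                   t0 = starts[k], amp_scale = amp_scale)
    if (protocol$include_gaze) {
      gaze_parts[[k]] <- generate_gaze(trials$condition[k],
                                       trials$duration_s[k], effect,
                                       seed = trial_seeds[2], t0 = starts[k],
                                       pupil_base_shift = pupil_base_shift)
    }
  }
  eeg_samples <- do.call(cbind, lapply(eeg_parts, function(p) p$samples))
  eeg <- new_eeg_recording(
    eeg_samples, eeg_parts[[1]]$sampling_rate,
    eeg_parts[[1]]$channel_names,
    unlist(lapply(eeg_parts, function(p) p$timestamps))
  )
  gaze <- if (protocol$include_gaze) {
    all_samples <- dplyr::bind_rows(lapply(gaze_parts, function(p) p$samples))
    gaze_stream(all_samples$timestamp, all_samples$gaze_x, all_samples$gaze_y,
                all_samples$pupil_left, all_samples$pupil_right,
                all_samples$validity,
                sampling_rate = gaze_parts[[1]]$sampling_rate)
  } else {
    NULL
  }
  ann <- trial_annotations(starts, starts + trials$duration_s,
                           trials$condition,
                           trial_index = seq_len(n_trials),
                           subject = subject, session = session,
                           protocol = protocol$protocol_id)
  synchronize(eeg, gaze, ann)
}

# Per-subject / per-session simulation plan: derived seeds, jittered effect
# sizes (inter-subject variability) and session drift (day-to-day
# variability motivating session-to-session evaluation). Shared by
# generate_study() and study_features() so both produce identical signals.
study_plan <- function(protocol, n_subjects, n_sessions, effect, master_seed,
                       subject_jitter_sd = 0.15, session_drift_sd = 0.1) {
  total <- n_subjects * n_sessions
  with_seed(master_seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, total)
    jitter <- stats::rlnorm(n_subjects, 0, subject_jitter_sd)
    amp <- stats::rlnorm(total, 0, session_drift_sd)
    pupil_shift <- rnorm(total, 0, 0.05)
    plan <- tidyr::expand_grid(subject_i = seq_len(n_subjects),
                               session = seq_len(n_sessions))
    plan$subject <- sprintf("S%02d", plan$subject_i)
    plan$seed <- seeds
    plan$amp_scale <- amp
    plan$pupil_base_shift <- pupil_shift
    plan$effect <- lapply(seq_len(total), function(i) {
      j <- jitter[plan$subject_i[i]]
      scale_gain <- function(g) max(1 + (g - 1) * j, 0.05)
      effect_spec(
        hcl_theta_gain = scale_gain(effect$hcl_theta_gain),
        hcl_alpha_gain = scale_gain(effect$hcl_alpha_gain),
        hcl_delta_gain = scale_gain(effect$hcl_delta_gain),
        theta_channels = effect$theta_channels,
        alpha_channels = effect$alpha_channels,
        delta_channels = effect$delta_channels,
        pupil_shift_mm = effect$pupil_shift_mm * j,
        fixation_rate_factor = max(1 + (effect$fixation_rate_factor - 1) * j,
                                   0.05),
        pupil_base_mm = effect$pupil_base_mm,
        osc_rms_uv = effect$osc_rms_uv,
        noise_rms_uv = effect$noise_rms_uv,
        noise_exponent = effect$noise_exponent
      )
    })
    plan
  })
}

#' Generate a multi-subject synthetic study
#'
#' Applies per-subject random effect-size jitter (inter-subject
#' variability) and per-session amplitude / pupil drift (day-to-day
#' variability) around the nominal [effect_spec()], then generates one
#' session per subject x session cell. Deterministic under `master_seed`.
#'
#' @inheritParams generate_session
#' @param n_subjects,n_sessions Study dimensions (e.g. 8 subjects x 4
#'   sessions for the EEG-only protocol; 10 subjects x 1 session for the
#'   EEG + gaze protocol).
#' @param master_seed Single seed controlling all randomness.
#' @param subject_jitter_sd,session_drift_sd Log-normal SDs of the
#'   inter-subject effect jitter and the session amplitude drift.
#' @return A list of `synced_session` objects.
#' @export
generate_study <- function(protocol, n_subjects, n_sessions = 1,
                           effect = effect_spec(), master_seed = 1,
                           subject_jitter_sd = 0.15, session_drift_sd = 0.1) {
  plan <- study_plan(protocol, n_subjects, n_sessions, effect, master_seed,
                     subject_jitter_sd, session_drift_sd)
  purrr::pmap(
    list(plan$effect, plan$seed, plan$subject, plan$session, plan$amp_scale,
         plan$pupil_base_shift),
    function(eff, seed, subject, session, amp, ps) {
      generate_session(protocol, eff, seed = seed, subject = subject,
                       session = session, amp_scale = amp,
                       pupil_base_shift = ps)
    }
  )
}

#' Generate a study and extract its feature tables session by session
#'
#' Identical signals to [generate_study()] (same plan, same seeds) but each
#' session's raw streams are discarded as soon as its features are
#' extracted, keeping memory flat for full-scale studies.
#'
#' @inheritParams generate_study
#' @param epoch_s,window_s EEG epoching / Welch parameters.
#' @param eye_epoch_s Eye feature epoch length.
#' @return A list with `eeg` (per-epoch band-power tibble) and `eye`
#'   (per-epoch eye feature tibble, `NULL` for EEG-only protocols).
#' @export
study_features <- function(protocol, n_subjects, n_sessions = 1,
                           effect = effect_spec(), master_seed = 1,
                           subject_jitter_sd = 0.15, session_drift_sd = 0.1,
                           epoch_s = 5, window_s = 4, eye_epoch_s = 15) {
  plan <- study_plan(protocol, n_subjects, n_sessions, effect, master_seed,
                     subject_jitter_sd, session_drift_sd)
  eeg_tabs <- vector("list", nrow(plan))
  eye_tabs <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    sess <- generate_session(protocol, plan$effect[[i]], seed = plan$seed[i],
                             subject = plan$subject[i],
                             session = plan$session[i],
                             amp_scale = plan$amp_scale[i],
                             pupil_base_shift = plan$pupil_base_shift[i])
    eeg_tabs[[i]] <- band_power_features(sess, epoch_s, window_s)
    if (!is.null(sess$gaze)) {
      eye_tabs[[i]] <- eye_feature_table(sess, eye_epoch_s,
                                         seed = plan$seed[i])
    }
  }
  list(eeg = dplyr::bind_rows(eeg_tabs),
       eye = if (protocol$include_gaze) dplyr::bind_rows(eye_tabs) else NULL)
}

# ---- session persistence ----------------------------------------------------

session_file_prefix <- function(session) {
  ann <- session$annotations
  sprintf("%s_ses-%02d", ann$subject[1], ann$session[1])
}

#' Write / read a session as CSV files
#'
#' A session becomes `<subject>_ses-<k>_eeg.csv`, `..._gaze.csv` (when
#' present) and `..._annotations.csv` in `dir`. Round-trips exactly.
#'
#' @param session A `synced_session`.
#' @param dir Directory (created if missing).
#' @return `write_session()` returns the file prefix invisibly;
#'   `read_session()` returns a `synced_session`.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prefix <- session_file_prefix(session)
  write_eeg_csv(session$eeg, file.path(dir, paste0(prefix, "_eeg.csv")))
  if (!is.null(session$gaze)) {
    write_gaze_csv(session$gaze, file.path(dir, paste0(prefix, "_gaze.csv")))
  }
  write_annotations_csv(session$annotations,
                        file.path(dir, paste0(prefix, "_annotations.csv")))
  invisible(prefix)
}

#' @rdname write_session
#' @param prefix File prefix, e.g. `"S01_ses-01"`.
#' @param sampling_rate,gaze_sampling_rate Sampling rates of the stored
#'   streams.
#' @export
read_session <- function(dir, prefix, sampling_rate = 250,
                         gaze_sampling_rate = 60) {
  eeg <- read_eeg_csv(file.path(dir, paste0(prefix, "_eeg.csv")),
                      sampling_rate = sampling_rate)
  gaze_path <- file.path(dir, paste0(prefix, "_gaze.csv"))
  gaze <- if (file.exists(gaze_path)) {
    read_gaze_csv(gaze_path, sampling_rate = gaze_sampling_rate)
  } else {
    NULL
  }
  ann <- read_annotations_csv(file.path(dir, paste0(prefix, "_annotations.csv")))
  synchronize(eeg, gaze, ann)
}
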