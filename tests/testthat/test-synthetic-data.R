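# Generator: protocols, determinism, spectral and oculomotor calibration.

test_that("standard protocols reproduce the acquisition designs", {
  p1 <- protocol_spec("dataset1")
  expect_equal(nrow(p1$trials), 6)
  expect_equal(sum(p1$trials$duration_s), 1800)
  expect_equal(sum(p1$trials$condition == "LCL"), 3)
  expect_false(p1$include_gaze)

  p2 <- protocol_spec("dataset2")
  expect_equal(nrow(p2$trials), 10)
  expect_equal(sum(p2$trials$duration_s), 1800)
  expect_equal(p2$trials$condition, rep(c("LCL", "HCL"), 5))
  expect_true(p2$include_gaze)
})

test_that("effect specifications validate gains and channels", {
  expect_error(effect_spec(hcl_theta_gain = -1), "positive")
  expect_error(effect_spec(theta_channels = c("F7", "XX")), "not in the montage")
  null <- null_effect_spec()
  expect_equal(null$hcl_theta_gain, 1)
  expect_equal(null$pupil_shift_mm, 0)
  expect_equal(null$fixation_rate_factor, 1)
})

test_that("generation is seed-deterministic and distinct across conditions", {
  a <- generate_eeg("LCL", 10, seed = 5, channels = c("F7", "CZ"))
  b <- generate_eeg("LCL", 10, seed = 5, channels = c("F7", "CZ"))
  expect_identical(a$samples, b$samples)
  c <- generate_eeg("LCL", 10, seed = 6, channels = c("F7", "CZ"))
  expect_false(identical(a$samples, c$samples))

  g1 <- generate_gaze("HCL", 20, seed = 5)
  g2 <- generate_gaze("HCL", 20, seed = 5)
  expect_identical(g1$samples, g2$samples)
  expect_error(generate_eeg("LOW", 10, seed = 1), "arg")
})

test_that("a single noiseless oscillator concentrates its band power", {
  eff <- effect_spec(osc_rms_uv = c(delta = 0, theta = 0, alpha = 3, beta = 0),
                     noise_rms_uv = 0)
  rec <- generate_eeg("LCL", 5, eff, seed = 8, channels = c("FP1", "CZ"))
  v <- band_power(welch_psd(epoch_eeg(rec)[[1]]))
  expect_gte(v[["FP1_alpha"]], 0.9)
  expect_gte(v[["CZ_alpha"]], 0.9)
})

test_that("LCL band-power proportions match the configured spectral composition", {
  eff <- effect_spec()
  # expected proportions, derived independently from the generator recipe:
  # oscillator variances plus the 1/f share of each band
  osc <- eff$osc_rms_uv^2
  pink_share <- log(c(4, 8, 12, 30) / c(0.5, 4, 8, 12)) / log(30 / 0.5)
  expected <- osc + eff$noise_rms_uv^2 * pink_share
  expected <- expected / sum(expected)
  rec <- generate_eeg("LCL", 120, eff, seed = 13, channels = c("FP1", "PZ"))
  bp <- colMeans(do.call(rbind, lapply(epoch_eeg(rec), function(e) {
    band_power(welch_psd(e))
  })))
  measured <- bp[paste0("FP1_", band_edges()$band)]
  expect_equal(unname(measured), unname(expected), tolerance = 0.1)
})

test_that("HCL raises theta power on affected channels only", {
  eff <- effect_spec()
  diffs <- vapply(1:20, function(i) {
    lcl <- generate_eeg("LCL", 15, eff, seed = 100 + i,
                        channels = c("F7", "PZ"))
    hcl <- generate_eeg("HCL", 15, eff, seed = 200 + i,
                        channels = c("F7", "PZ"))
    bl <- colMeans(do.call(rbind, lapply(epoch_eeg(lcl), function(e) {
      band_power(welch_psd(e))
    })))
    bh <- colMeans(do.call(rbind, lapply(epoch_eeg(hcl), function(e) {
      band_power(welch_psd(e))
    })))
    c(bh[["F7_theta"]] - bl[["F7_theta"]], bh[["PZ_theta"]] - bl[["PZ_theta"]])
  }, numeric(2))
  expect_gt(mean(diffs[1, ]), 0.05)            # affected channel rises
  expect_lt(abs(mean(diffs[2, ])), 0.02)       # unaffected channel does not
})

test_that("detected fixation counts track the configured fixation rate", {
  eff <- effect_spec()
  # configured rate, from the generator's duration distribution
  withr::with_seed(1, {
    mean_fix <- mean(pmax(stats::rlnorm(1e5, log(0.28), 0.35), 0.12))
  })
  mean_sac <- 2 / 60
  expected_nf <- 15 / (mean_fix + mean_sac)
  nf <- vapply(1:20, function(i) {
    g <- generate_gaze("LCL", 30, eff, seed = 300 + i)
    mean(extract_eye_features(g, seed = i)$nf)
  }, numeric(1))
  expect_equal(mean(nf), expected_nf, tolerance = 0.2)
})

test_that("null effects leave pupil diameter indistinguishable", {
  eff <- null_effect_spec()
  pds <- purrr::map(1:4, function(i) {
    l <- extract_eye_features(generate_gaze("LCL", 400, eff, seed = 10 + i),
                              seed = 1)
    h <- extract_eye_features(generate_gaze("HCL", 400, eff, seed = 50 + i),
                              seed = 2)
    list(l = l$pd, h = h$pd)
  })
  lcl <- unlist(purrr::map(pds, "l"))
  hcl <- unlist(purrr::map(pds, "h"))
  expect_gte(length(lcl), 100)
  expect_gt(stats::t.test(lcl, hcl)$p.value, 0.01)
})

test_that("sessions assemble trials with continuous clocks and balanced labels", {
  sess <- generate_session(protocol_spec("dataset2"), seed = 3,
                           subject = "S05", session = 2L)
  expect_equal(nrow(sess$annotations), 10)
  expect_equal(duration(sess$eeg), 1800)
  expect_equal(duration(sess$gaze), 1800)
  expect_equal(mean(sess$annotations$condition == "HCL"), 0.5)
  expect_true(all(diff(sess$eeg$timestamps) > 0))
  expect_equal(sess$annotations$condition, rep(c("LCL", "HCL"), 5))

  d1 <- generate_session(small_protocol("dataset1", n_trials = 6,
                                        trial_s = 10), seed = 3)
  expect_null(d1$gaze)
  expect_equal(nrow(d1$annotations), 6)
})

test_that("studies have the right shape and distinct subjects differ", {
  proto <- small_protocol("dataset1", n_trials = 2, trial_s = 10)
  proto$include_gaze <- FALSE
  study <- generate_study(proto, n_subjects = 8, n_sessions = 4,
                          master_seed = 5)
  expect_length(study, 32)
  subjects <- vapply(study, function(s) s$annotations$subject[1], character(1))
  expect_equal(sort(unique(subjects)), sprintf("S%02d", 1:8))

  study2 <- generate_study(small_protocol(n_trials = 2, trial_s = 20),
                           n_subjects = 2, n_sessions = 1, master_seed = 5)
  expect_length(study2, 2)
  expect_false(identical(study2[[1]]$eeg$samples, study2[[2]]$eeg$samples))
  # deterministic under the master seed
  study3 <- generate_study(small_protocol(n_trials = 2, trial_s = 20),
                           n_subjects = 2, n_sessions = 1, master_seed = 5)
  expect_identical(study2[[1]]$eeg$samples, study3[[1]]$eeg$samples)
})

test_that("study_features matches feature extraction of generate_study", {
  proto <- small_protocol(n_trials = 2, trial_s = 20)
  direct <- study_features(proto, n_subjects = 2, master_seed = 9)
  study <- generate_study(proto, n_subjects = 2, master_seed = 9)
  via_sessions <- dplyr::bind_rows(lapply(study, band_power_features))
  expect_equal(direct$eeg, via_sessions, tolerance = 1e-12)
  expect_false(is.null(direct$eye))
  expect_equal(nrow(direct$eye), 2 * 2 * 1)  # one 15 s epoch per 20 s trial
})
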