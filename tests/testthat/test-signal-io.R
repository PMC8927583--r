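# Stream containers, file round-trips, synchronization, splitting.

test_that("eeg_recording validates its invariants", {
  m <- matrix(rnorm(4 * 500), 4, 500)
  rec <- eeg_recording(m, 250, paste0("ch", 1:4))
  expect_equal(duration(rec), 2)
  expect_equal(rec$timestamps[1], 0)

  expect_error(eeg_recording(m, 250, c("a", "a", "b", "c")), "duplicate")
  expect_error(eeg_recording(m, 250, c("a", "b")), "mismatch")
  m[1, 5] <- NA
  expect_error(eeg_recording(m, 250, paste0("ch", 1:4)), "missing")
  expect_error(eeg_recording(matrix(1, 1, 3), 250, "a",
                             timestamps = c(0, 2, 1)), "increasing")
})

test_that("a 2500-row recording at 250 Hz lasts 10 s and a 900-row gaze stream 15 s", {
  rec <- eeg_recording(matrix(0, 2, 2500), 250, c("a", "b"))
  expect_equal(duration(rec), 10)
  g <- gaze_stream((0:899) / 60, runif(900), runif(900), 3, 3)
  expect_equal(duration(g), 15)
})

test_that("EEG and gaze files round-trip exactly through CSV", {
  sess <- generate_session(small_protocol(n_trials = 2, trial_s = 20),
                           seed = 11, subject = "S01")
  dir <- withr::local_tempdir()
  prefix <- write_session(sess, dir)
  back <- suppressWarnings(read_session(dir, prefix))
  expect_identical(back$eeg$samples, sess$eeg$samples)
  expect_identical(back$eeg$timestamps, sess$eeg$timestamps)
  expect_identical(back$gaze$samples$pupil_left, sess$gaze$samples$pupil_left)
  expect_identical(back$gaze$samples$validity, sess$gaze$samples$validity)
  expect_equal(back$annotations$condition, sess$annotations$condition)
})

test_that("EEG file loading rejects malformed tables", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "eeg.csv")
  writeLines(c("timestamp,FP1,FP1", "0,1,2", "0.004,1,2"), path)
  expect_error(read_eeg_csv(path), "duplicate")
  writeLines(c("FP1,FP2", "1,2"), path)
  expect_error(read_eeg_csv(path), "timestamp")
  writeLines(c("timestamp,FP1", "0,1", "0,2"), path)
  expect_error(read_eeg_csv(path), "increasing")
  expect_error(load_eeg(path, dialect = "xdf"), "XDF")
  expect_error(read_eeg_csv(file.path(dir, "absent.csv")), "not found")
})

test_that("an all-invalid gaze stream is rejected", {
  expect_error(gaze_stream((0:9) / 60, runif(10), runif(10), 3, 3,
                           validity = 0L), "no valid samples")
})

test_that("loading flags 60 Hz dominated recordings", {
  t <- seq(0, 20 - 1 / 250, by = 1 / 250)
  bad <- eeg_recording(rbind(20 * sin(2 * pi * 60 * t) + rnorm(length(t), 0, 0.1),
                             rnorm(length(t))),
                       250, c("a", "b"))
  dir <- withr::local_tempdir()
  write_eeg_csv(bad, file.path(dir, "bad.csv"))
  expect_warning(read_eeg_csv(file.path(dir, "bad.csv")), "line noise")
})

test_that("synchronize trims to the common interval and rejects outside annotations", {
  eeg <- eeg_recording(matrix(rnorm(2 * 300 * 50), 2), 50, c("a", "b"))
  gn <- 305 * 30
  gaze <- gaze_stream(5 + (0:(gn - 1)) / 30, runif(gn), runif(gn), 3, 3,
                      sampling_rate = 30)
  ann <- trial_annotations(c(10, 290), c(100, 305), c("LCL", "HCL"))
  expect_warning(sess <- synchronize(eeg, gaze, ann), "rejected")
  expect_equal(min(sess$eeg$timestamps), 5)
  expect_lt(max(sess$eeg$timestamps), 300)
  expect_equal(nrow(sess$annotations), 1)
  expect_equal(nrow(sess$rejected_annotations), 1)
  expect_equal(sess$rejected_annotations$start_s, 290)

  # identical spans: nothing is trimmed
  g2 <- gaze_stream(eeg$timestamps[1] + (0:(300 * 30 - 1)) / 30,
                    runif(9000), runif(9000), 3, 3, sampling_rate = 30)
  ann2 <- trial_annotations(0, 300, "LCL")
  s2 <- synchronize(eeg, g2, ann2)
  expect_identical(s2$eeg$samples, eeg$samples)
  expect_equal(nrow(s2$gaze$samples), 9000)

  # disjoint ranges cannot synchronize
  g3 <- gaze_stream(400 + (0:99) / 30, runif(100), runif(100), 3, 3,
                    sampling_rate = 30)
  expect_error(synchronize(eeg, g3, ann2), "disjoint")
})

test_that("durations never grow under synchronization", {
  withr::with_seed(5, {
    for (i in 1:5) {
      e0 <- runif(1, 0, 10)
      eeg <- eeg_recording(matrix(rnorm(100 * 50), 2), 50, c("a", "b"),
                           t0 = e0)
      g0 <- runif(1, 0, 10)
      gaze <- gaze_stream(g0 + (0:200) / 30, runif(201), runif(201), 3, 3,
                          sampling_rate = 30)
      ann <- trial_annotations(max(e0, g0), max(e0, g0) + 0.5, "LCL")
      sess <- suppressWarnings(synchronize(eeg, gaze, ann))
      expect_lte(duration(sess$eeg), duration(eeg))
      expect_lte(duration(sess$gaze), duration(gaze))
    }
  })
})

test_that("chronological split is 60-20-20 with floor and remainder to test", {
  w10 <- tibble::tibble(subject = "S01", label = rep(0:1, 5))
  s10 <- chronological_split(w10)
  expect_equal(as.vector(table(s10$.split)), c(6, 2, 2))

  w100 <- tibble::tibble(subject = "S01", label = rep(0:1, 50))
  s100 <- chronological_split(w100)
  expect_equal(as.vector(table(s100$.split)), c(60, 20, 20))

  expect_error(chronological_split(tibble::tibble(subject = "S01",
                                                  label = c(0, 1, 0, 1))),
               "at least 5")
})

test_that("splits are disjoint, exhaustive, ordered and deterministic for any n", {
  for (n in 5:50) {
    w <- tibble::tibble(subject = "S01", idx = seq_len(n))
    s <- chronological_split(w)
    expect_equal(nrow(s), n)
    expect_equal(sort(s$idx), seq_len(n))
    counts <- table(s$.split)
    expect_equal(unname(counts[["train"]]), floor(0.6 * n))
    expect_equal(unname(counts[["validation"]]), floor(0.2 * n))
    # chronological: every train window precedes every validation window, etc.
    expect_true(max(s$idx[s$.split == "train"]) <
                  min(s$idx[s$.split == "validation"]))
    expect_true(max(s$idx[s$.split == "validation"]) <
                  min(s$idx[s$.split == "test"]))
    expect_identical(s, chronological_split(w))
  }
  # splitting is per subject
  w2 <- tibble::tibble(subject = rep(c("S01", "S02"), each = 10))
  s2 <- chronological_split(w2)
  expect_equal(as.vector(table(s2$.split, s2$subject)), c(6, 2, 2, 6, 2, 2))
})
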