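# Gaze epoching, fixation detection, eye workload features.

test_that("gaze epoching yields floor(duration / 15) aligned epochs", {
  g <- generate_gaze("LCL", 180, seed = 2)
  eps <- epoch_gaze(g)
  expect_length(eps, 12)
  expect_equal(vapply(eps, function(e) attr(e, "t_start"), numeric(1)),
               seq(0, 165, by = 15))

  g29 <- generate_gaze("LCL", 29, seed = 2)
  expect_length(epoch_gaze(g29), 1)

  # 3 EEG epochs of 5 s per eye epoch: boundaries align at multiples of 15
  expect_equal(attr(eps[[2]], "t_start") / 5, 3)
})

test_that("mean pupil diameter averages valid left-eye samples only", {
  n <- 60
  g <- gaze_stream((0:(n - 1)) / 60, runif(n), runif(n),
                   pupil_left = rep(3, n), pupil_right = rep(9, n))
  expect_equal(mean_pupil(g$samples), 3)

  pl <- rep(c(2, 4), n / 2)
  g2 <- gaze_stream((0:(n - 1)) / 60, runif(n), runif(n), pl, pl)
  expect_equal(mean_pupil(g2$samples), 3)

  # brute force with a validity mask
  withr::with_seed(8, {
    for (i in 1:10) {
      pl <- runif(n, 2, 5)
      valid <- rbinom(n, 1, 0.8)
      if (!any(valid == 1)) valid[1] <- 1L
      g3 <- gaze_stream((0:(n - 1)) / 60, runif(n), runif(n), pl, pl, valid)
      expect_equal(mean_pupil(g3$samples), mean(pl[valid == 1]))
    }
  })

  all_na <- g$samples
  all_na$pupil_left <- NA_real_
  expect_true(is.na(mean_pupil(all_na)))
})

test_that("fixation detection keeps stationary segments of at least 85 ms", {
  # one 200 ms stationary segment between long saccade-like sweeps
  segs <- list(list(x = 0.2, y = 0.2, dur_s = 0.2))
  sweep_x <- seq(0, 1, length.out = 30)
  g <- gaze_stream((0:(30 + 12 + 30 - 1)) / 60,
                   c(sweep_x, rep(0.2, 12), rev(sweep_x)),
                   c(sweep_x, rep(0.2, 12), rev(sweep_x)),
                   3, 3)
  fx <- detect_fixations(g$samples, sampling_rate = 60)
  expect_equal(nrow(fx), 1)
  expect_equal(fx$duration_ms, 200)
  expect_equal(fx$centroid_x, 0.2)

  # stationary segments of 50 and 84 ms only: nothing survives the filter
  jump <- function(k) seq(0, 1, length.out = 30) + k
  g2 <- segment_gaze(list(list(x = 0.1, y = 0.1, dur_s = 0.050),
                          list(x = 0.9, y = 0.9, dur_s = 0.084)), fs = 1000)
  fx2 <- detect_fixations(g2$samples, sampling_rate = 1000)
  expect_equal(nrow(fx2), 0)
})

test_that("fixation filter sweep admits nothing under 85 ms", {
  # 1 kHz synthetic stream: exact millisecond durations
  durs_ms <- c(30, 50, 84, 85, 90, 120, 200, 400)
  segs <- purrr::imap(durs_ms, function(d, i) {
    list(x = (i %% 2) * 0.8 + 0.05, y = ((i + 1) %% 2) * 0.8 + 0.05,
         dur_s = d / 1000)
  })
  g <- segment_gaze(segs, fs = 1000)
  fx <- detect_fixations(g$samples, sampling_rate = 1000)
  expect_equal(nrow(fx), sum(durs_ms >= 85))
  expect_true(all(fx$duration_ms >= 85))
  # raising the minimum duration can only reduce the count
  counts <- vapply(c(85, 100, 150, 250, 500), function(md) {
    nrow(detect_fixations(g$samples, min_dur_ms = md, sampling_rate = 1000))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("fixation detection matches the brute-force dispersion scan", {
  withr::with_seed(14, {
    for (i in 1:20) {
      n <- sample(200:1000, 1)
      # piecewise-stationary walk with jumps and noise
      centers <- matrix(runif(2 * 8), ncol = 2)
      x <- unlist(lapply(seq_len(8), function(k) {
        rep(centers[k, 1], n %/% 8) + rnorm(n %/% 8, 0, 0.004)
      }))
      y <- unlist(lapply(seq_len(8), function(k) {
        rep(centers[k, 2], n %/% 8) + rnorm(n %/% 8, 0, 0.004)
      }))
      valid <- rbinom(length(x), 1, 0.95)
      if (!any(valid == 1)) valid[1] <- 1L
      g <- gaze_stream((seq_along(x) - 1) / 60, x, y, 3, 3, valid)
      got <- detect_fixations(g$samples, sampling_rate = 60)
      want <- brute_force_fixations(g$samples, fs = 60)
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$centroid_x, want$centroid_x)
      expect_equal(got$duration_ms, want$duration_ms)
      expect_equal(got$start_s, want$start_s)
    }
  })
})

test_that("fixation stats, scan path and NNI follow their definitions", {
  fx <- tibble::tibble(centroid_x = c(0, 3, 6), centroid_y = c(0, 4, 8),
                       start_s = c(0, 1, 2), duration_ms = c(100, 300, 150))
  class(fx) <- c("fixation_set", class(fx))
  st <- fixation_stats(fx[1:2, ])
  expect_equal(st$nf, 2)
  expect_equal(st$ft_ms, 200)
  empty <- fx[0, ]
  expect_equal(fixation_stats(empty)$nf, 0)
  expect_true(is.na(fixation_stats(empty)$ft_ms))

  expect_equal(scan_path_length(fx), 10)
  expect_equal(scan_path_length(fx[1, ]), 0)
  # reversing the order leaves the path length unchanged
  expect_equal(scan_path_length(fx[3:1, ]), 10)
  # SSP is bounded below by the direct first-to-last distance
  withr::with_seed(3, {
    for (i in 1:10) {
      r <- tibble::tibble(centroid_x = runif(6), centroid_y = runif(6),
                          start_s = 1:6, duration_ms = 100)
      ssp <- scan_path_length(r)
      direct <- sqrt((r$centroid_x[6] - r$centroid_x[1])^2 +
                       (r$centroid_y[6] - r$centroid_y[1])^2)
      expect_gte(ssp + 1e-12, direct)
    }
  })

  # coincident fixations: d(NN) = 0 so NNI = 0
  co <- fx[c(1, 1), ]
  expect_equal(nearest_neighbor_index(co, seed = 1), 0)
  expect_true(is.na(nearest_neighbor_index(fx[1, ], seed = 1)))

  # a tight cluster in a large scene is strongly clustered
  cl <- tibble::tibble(centroid_x = 0.5 + runif(20, 0, 1e-3),
                       centroid_y = 0.5 + runif(20, 0, 1e-3),
                       start_s = 1:20, duration_ms = 100)
  expect_lt(nearest_neighbor_index(cl, seed = 2), 0.1)
})

test_that("NNI is invariant to uniform coordinate scaling", {
  withr::with_seed(21, {
    fx <- tibble::tibble(centroid_x = runif(15), centroid_y = runif(15),
                         start_s = 1:15, duration_ms = 100)
    a <- nearest_neighbor_index(fx, seed = 5)
    fx10 <- fx
    fx10$centroid_x <- fx10$centroid_x * 10
    fx10$centroid_y <- fx10$centroid_y * 10
    b <- nearest_neighbor_index(fx10, seed = 5, scene_bounds = c(10, 10))
    expect_equal(a, b, tolerance = 1e-12)
  })
})

test_that("eye feature extraction emits the five features per epoch", {
  g <- generate_gaze("LCL", 45, seed = 6)
  tab <- extract_eye_features(g, seed = 10)
  expect_equal(nrow(tab), 3)
  expect_named(tab, c("epoch_index", "t_start", "pd", "nf", "ft", "ssp", "nni"))
  expect_true(all(tab$nf > 0))
  expect_true(all(tab$ssp >= 0))
  expect_true(all(tab$pd > 0))

  # bit-identical reproducibility under a fixed seed
  expect_identical(tab, extract_eye_features(g, seed = 10))

  # an all-blink epoch is missing-marked
  s <- g$samples
  blink <- s$timestamp >= 15 & s$timestamp < 30
  s$validity[blink] <- 0L
  s$pupil_left[blink] <- NA
  s$gaze_x[blink] <- NA
  s$gaze_y[blink] <- NA
  g2 <- gaze_stream(s$timestamp, s$gaze_x, s$gaze_y, s$pupil_left,
                    s$pupil_right, s$validity)
  tab2 <- extract_eye_features(g2, seed = 10)
  expect_true(is.na(tab2$pd[2]))
  expect_true(is.na(tab2$ft[2]))
  expect_true(is.na(tab2$nni[2]))
  expect_equal(tab2$nf[2], 0)
  expect_equal(tab2$ssp[2], 0)
})

test_that("per-session eye tables attach provenance and never cross trials", {
  sess <- generate_session(small_protocol(n_trials = 2, trial_s = 30),
                           seed = 12, subject = "S03")
  tab <- eye_feature_table(sess, seed = 4)
  expect_equal(nrow(tab), 4)
  expect_equal(unique(tab$subject), "S03")
  expect_equal(tab$trial, c(1L, 1L, 2L, 2L))
  expect_equal(tab$label, as.integer(tab$condition == "HCL"))
})
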