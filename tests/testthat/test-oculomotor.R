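test_that("clock correction shifts by whole samples and round-trips", {
  tr <- flat_trace(1000)
  tr$x_deg <- tr$x_deg + sin(seq_len(1000) / 50)
  expect_identical(apply_clock_correction(tr, 0), tr)
  cor7 <- apply_clock_correction(tr, 0.007)
  expect_equal(nrow(cor7), 993)
  expect_equal(cor7$x_deg, tr$x_deg[8:1000])
  # shifting forward by the lag restores the original over common support
  expect_equal(cor7$x_deg[1:986], tr$x_deg[8:993])
  expect_error(apply_clock_correction(flat_trace(5), 0.007), "longer than")
})

test_that("constant gaze with tiny noise yields no saccades", {
  withr::with_seed(11, {
    tr <- flat_trace(2000, noise = 0.01)
    tr$x_deg <- as.numeric(stats::filter(tr$x_deg, rep(1 / 20, 20),
                                         sides = 2, circular = TRUE))
    tr$y_deg <- as.numeric(stats::filter(tr$y_deg, rep(1 / 20, 20),
                                         sides = 2, circular = TRUE))
  })
  expect_equal(nrow(detect_saccades(tr)), 0)
})

test_that("zero-variance traces raise a degenerate-input error", {
  expect_error(detect_saccades(flat_trace(100)), "zero velocity variance")
})

test_that("a synthetic 14 degree saccade is found at its true onset", {
  tm <- tibble::tibble(s1_onset = 1, saccade_latency = 0.226,
                       saccade_duration = 0.062)
  # low jitter keeps the velocity threshold small, so the crossing happens
  # right at movement onset
  tr <- synthesize_eye_trace(tm, amplitude_mean = 14, amplitude_sd = 0,
                             vertical_sd = 0, jitter_sd = 0.02, seed = 20)
  ev <- detect_saccades(tr, s1_onset = 1)
  expect_equal(nrow(ev), 1)
  truth <- attr(tr, "events")
  expect_lte(abs(ev$onset - truth$onset), 0.004 + 1e-9)
  expect_lt(abs(abs(ev$h_amplitude) - 14) / 14, 0.02)
})

test_that("detector recall and precision are 1 on seeded saccade trials", {
  hits <- 0
  fas <- 0
  for (s in 1:100) {
    amp <- 1 + (s %% 10) # 1 to 10 degrees
    tm <- tibble::tibble(s1_onset = 0.5, saccade_latency = 0.2,
                         saccade_duration = 0.027 + 0.0025 * amp)
    tr <- synthesize_eye_trace(tm, amplitude_mean = amp, amplitude_sd = 0,
                               vertical_sd = 0, duration = 1.2, seed = s)
    ev <- detect_saccades(tr)
    truth <- attr(tr, "events")
    # an event counts as the saccade when its window overlaps the truth
    matched <- any(ev$onset <= truth$offset[1] & ev$offset >= truth$onset[1])
    hits <- hits + matched
    fas <- fas + (nrow(ev) - matched)
  }
  expect_equal(hits, 100) # recall
  expect_equal(fas, 0)    # precision
})

test_that("bursts separated by less than the minimum fixation merge", {
  # two 15-sample velocity bursts with a 30 ms quiet gap, on low drift noise
  drifting <- function(seed) {
    tr <- flat_trace(1200, noise = 0)
    withr::with_seed(seed, {
      tr$x_deg <- tr$x_deg + cumsum(rnorm(1200, 0, 1e-4))
      tr$y_deg <- tr$y_deg + cumsum(rnorm(1200, 0, 1e-4))
    })
    tr
  }
  tr <- drifting(7)
  tr <- inject_burst(tr, 300, 315, 2)
  tr <- inject_burst(tr, 345, 360, 2)
  ev <- detect_saccades(tr)
  expect_equal(nrow(ev), 1)
  # the same bursts 80 ms apart stay separate
  tr2 <- drifting(7)
  tr2 <- inject_burst(tr2, 300, 315, 2)
  tr2 <- inject_burst(tr2, 395, 410, 2)
  ev2 <- detect_saccades(tr2)
  expect_equal(nrow(ev2), 2)
})

test_that("detection is invariant to a constant position offset", {
  tm <- tibble::tibble(s1_onset = 0.5, saccade_latency = 0.2,
                       saccade_duration = 0.06)
  tr <- synthesize_eye_trace(tm, duration = 1.2, seed = 30)
  shifted <- tr
  shifted$x_deg <- shifted$x_deg + 3.7
  shifted$y_deg <- shifted$y_deg - 1.2
  a <- detect_saccades(tr)
  b <- detect_saccades(shifted)
  expect_equal(a$onset, b$onset)
  expect_equal(a$duration, b$duration)
  expect_equal(a$h_amplitude, b$h_amplitude, tolerance = 1e-10)
})

test_that("photodiode ternarization counts exactly the level changes", {
  # clean square wave black <-> white with 3 flips
  lv <- c(rep(-1, 100), rep(1, 100), rep(-1, 100), rep(1, 100))
  expect_equal(length(ternarize_photodiode(lv, rate = 1000)), 3)
  # noise on a gray stretch stays sub-boundary: no events inside it
  withr::with_seed(3, {
    g <- c(rep(-1, 100), rnorm(300, 0, 0.02), rep(1, 100))
  })
  ev_g <- ternarize_photodiode(g, rate = 1000)
  expect_equal(length(ev_g), 2) # only the black->gray and gray->white steps
  expect_equal(ev_g, c(0.1, 0.4))
  # black -> gray -> white staircase: 2 events
  st <- c(rep(-1, 100), rep(0, 100), rep(1, 100))
  ev <- ternarize_photodiode(st, rate = 1000)
  expect_equal(length(ev), 2)
  expect_equal(ev, c(0.1, 0.2))
  expect_error(ternarize_photodiode(rep(1, 50), rate = 1000), "constant")
})

test_that("saccade summaries exclude out-of-window latencies", {
  ev <- tibble::tibble(condition = "Sac-LVF",
                       latency = c(0.100, 0.200, 0.300, 0.600),
                       h_amplitude = c(-10, -13, -14, -20))
  s <- saccade_summaries(ev, condition)
  expect_equal(s$median_latency, 0.250)
  expect_equal(s$mean_h_amplitude, -13.5)
  expect_equal(s$n_excluded, 2)
  # all inside: exclusion changes nothing
  ev2 <- tibble::tibble(condition = "x", latency = c(0.2, 0.3, 0.4),
                        h_amplitude = c(-1, -2, -3))
  expect_equal(saccade_summaries(ev2, condition)$median_latency, 0.3)
  # single survivor
  ev3 <- tibble::tibble(condition = "x", latency = c(0.05, 0.31),
                        h_amplitude = c(0, -5))
  expect_equal(saccade_summaries(ev3, condition)$median_latency, 0.31)
  # empty group errors
  ev4 <- tibble::tibble(condition = "x", latency = 0.9, h_amplitude = 1)
  expect_error(saccade_summaries(ev4, condition), "empty")
})

test_that("re-detection inside detected windows is stable (merge idempotent)", {
  tm <- tibble::tibble(s1_onset = 0.5, saccade_latency = 0.2,
                       saccade_duration = 0.06)
  tr <- synthesize_eye_trace(tm, duration = 1.2, seed = 31)
  ev <- detect_saccades(tr)
  ev2 <- detect_saccades(tr)
  expect_identical(ev, ev2)
})
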