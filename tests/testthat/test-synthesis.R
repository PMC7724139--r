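test_that("jitter-free trace without saccade is constant at fixation", {
  tm <- tibble::tibble(s1_onset = 1, saccade_latency = NA_real_)
  tr <- synthesize_eye_trace(tm, has_saccade = FALSE, jitter_sd = 0,
                             duration = 1.5, seed = 1)
  expect_true(all(tr$x_deg == 7))
  expect_true(all(tr$y_deg == 0))
})

test_that("generated saccade amplitude matches the request within 1%", {
  tm <- tibble::tibble(s1_onset = 1, saccade_latency = 0.2,
                       saccade_duration = 0.062)
  tr <- synthesize_eye_trace(tm, jitter_sd = 0, amplitude_sd = 0,
                             vertical_sd = 0, seed = 2)
  i0 <- which(tr$time_s >= 1.2)[1] - 1
  i1 <- which(tr$time_s >= 1.262)[1]
  amp <- abs(tr$x_deg[i1] - tr$x_deg[i0])
  expect_lt(abs(amp - 13.1) / 13.1, 0.01)
})

test_that("a 14 degree saccade exceeds 100 deg/s peak velocity", {
  tm <- tibble::tibble(s1_onset = 1, saccade_latency = 0.2,
                       saccade_duration = 0.062)
  tr <- synthesize_eye_trace(tm, jitter_sd = 0, amplitude_mean = 14,
                             amplitude_sd = 0, vertical_sd = 0, seed = 3)
  v <- abs(diff(tr$x_deg)) * attr(tr, "rate")
  expect_gt(max(v), 100)
})

test_that("saccade longer than the trace is rejected", {
  tm <- tibble::tibble(s1_onset = 1, saccade_latency = 0.45,
                       saccade_duration = 0.2)
  expect_error(synthesize_eye_trace(tm, duration = 1.5, seed = 1),
               "exceeds trace length")
})

test_that("photodiode traces flip polarity at display changes", {
  # no changes: constant gray
  pd0 <- synthesize_photodiode(changes = numeric(0), duration = 0.5,
                               noise_sd = 0)
  expect_true(all(pd0$level == 0))
  # S1 + S2 schedule: exactly two flips, three levels when noise-free
  pd <- synthesize_photodiode(changes = c(0.1, 0.3), duration = 0.5,
                              noise_sd = 0)
  expect_equal(sum(diff(pd$level) != 0), 2)
  expect_equal(sort(unique(pd$level)), c(-1, 0, 1))
})

test_that("zero-amplitude model produces pure noise", {
  m <- small_model(amplitude = 0)
  trial <- tibble::tibble(condition = "Fix-LVF", spatial_frequency = "high")
  tm <- sample_trial_timing(trial, seed = 5)
  rec <- synthesize_sensor_data(trial, tm, m, seed = 6)
  m0 <- small_model(amplitude = 0, noise_sd = 0)
  rec0 <- synthesize_sensor_data(trial, tm, m0, seed = 6)
  expect_true(all(rec0 == 0))
  expect_equal(dim(rec), dim(rec0))
})

test_that("zero persistence removes presaccadic energy after the tail", {
  m <- pattern_model(small_array(), t_persist = 0, noise_sd = 0,
                     saccade_gain = 0, seed = 7)
  trial <- tibble::tibble(condition = "Sac-LVF", spatial_frequency = "low")
  tm <- sample_trial_timing(trial, seed = 8)
  rec <- synthesize_sensor_data(trial, tm, m, seed = 9)
  t <- attr(rec, "time")
  offset <- tm$s1_onset + tm$saccade_latency + tm$saccade_duration
  pre <- get_topography(m, "low", "LVF")
  post <- get_topography(m, "low", "RVF")
  proj <- as.numeric(crossprod(pre, unclass(rec)))
  # beyond the envelope fall time only crosstalk with the (non-orthogonal)
  # postsaccadic pattern remains
  crosstalk <- abs(sum(pre * post)) * m$amplitude + 1e-9
  late <- t > offset + m$fall + 0.002
  expect_true(any(late))
  expect_true(all(abs(proj[late]) <= crosstalk))
  # while with the default persistence the presaccadic projection is still
  # strong shortly after saccade offset
  m2 <- pattern_model(small_array(), t_persist = 0.2, noise_sd = 0,
                      saccade_gain = 0, seed = 7)
  rec2 <- synthesize_sensor_data(trial, tm, m2, seed = 9)
  proj2 <- as.numeric(crossprod(pre, unclass(rec2)))
  mid <- t > offset + 0.05 & t < offset + 0.15
  expect_gt(mean(abs(proj2[mid])), 1)
})

test_that("projection of a noiseless trial recovers the envelope", {
  m <- pattern_model(small_array(), noise_sd = 0, seed = 10)
  trial <- tibble::tibble(condition = "Fix-LVF", spatial_frequency = "high")
  tm <- tibble::tibble(s1_onset = 1, s1_duration = 0.6,
                       blank_duration = 0.05, saccade_latency = NA_real_,
                       saccade_duration = NA_real_, s2_onset = 5,
                       s2_duration = 0.6) # S2 outside the trace
  rec <- synthesize_sensor_data(trial, tm, m, seed = 11)
  t <- attr(rec, "time")
  topo <- get_topography(m, "high", "LVF")
  proj <- as.numeric(crossprod(topo, unclass(rec)))
  env <- m$amplitude * response_envelope(t, tm$s1_onset + m$onset_latency,
                                         tm$s1_onset + tm$s1_duration, m)
  expect_equal(proj, env, tolerance = 1e-10)
  expect_true(all(env[t < tm$s1_onset + m$onset_latency] == 0))
})

test_that("evoked energy is contralateral for both spatial frequencies", {
  arr <- small_array(32)
  sites <- arr$sites
  for (sf in c("low", "high")) {
    m <- pattern_model(arr, noise_sd = 0, seed = 12)
    for (hemi in c("LVF", "RVF")) {
      topo <- get_topography(m, sf, hemi)
      ch <- arr$channels
      energy_right <- sum(topo[sites$x[ch$site] > 0]^2)
      energy_left <- sum(topo[sites$x[ch$site] < 0]^2)
      if (hemi == "LVF") expect_gt(energy_right, energy_left)
      else expect_gt(energy_left, energy_right)
    }
  }
})

test_that("sensor arrays enumerate channels site-major", {
  a4 <- make_sensor_array(4)
  expect_equal(nrow(a4$channels), 8)
  a4m <- make_sensor_array(4, magnetometers = TRUE)
  expect_equal(nrow(a4m$channels), 12)
  full <- make_sensor_array(102, magnetometers = TRUE)
  expect_equal(nrow(full$channels), 306)
  expect_error(make_sensor_array(3), ">= 4")
  ring <- make_sensor_array(12, layout = "ring")
  expect_equal(nrow(dplyr::distinct(ring$sites[, c("x", "y")])), 12)
})

test_that("full-chain session couples eye, photodiode and sensor clocks", {
  arr <- small_array()
  m <- small_model(arr)
  d <- build_design(1, 1, seed = 2)[c(1:3, 49:51), ]
  ses <- simulate_session(d, m, rate_sensor = 500, seed = 13)
  expect_s3_class(ses$epochs, "epoch_set")
  expect_equal(dim(ses$epochs)[1], 6)
  expect_equal(dim(ses$epochs)[3], 1000) # 2 s at 500 Hz
  # detected saccades on saccade trials only (fixation may hold microsaccades)
  sac_rows <- ses$trials$block_type == "saccade"
  expect_true(all(!is.na(ses$trials$det_latency[sac_rows])))
  # detected latency close to ground truth
  expect_true(all(abs(ses$trials$det_latency[sac_rows] -
                        ses$trials$saccade_latency[sac_rows]) < 0.02))
})
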