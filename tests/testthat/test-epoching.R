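make_recording <- function(n_ch = 2, rate = 1000, t0 = 0, dur = 3,
                           fill = 0) {
  n <- round(dur * rate)
  structure(matrix(fill, n_ch, n), time = t0 + (seq_len(n) - 1) / rate,
            rate = rate, class = "sensor_recording")
}

test_that("epoch cutting is half-open and includes the event sample", {
  rec <- make_recording()
  es <- cut_epochs(list(rec), 1.0, c(-0.5, 1.5))
  expect_equal(dim(es$data), c(1, 2, 2000))
  expect_equal(es$times[1], -0.5)
  expect_true(0 %in% es$times)
  expect_equal(max(es$times), 1.5 - 1 / 1000)
  expect_error(cut_epochs(list(rec), 1.0, c(0, 0)), "empty epoch window")
  expect_error(cut_epochs(list(rec), 0.2, c(-0.5, 1.5)), "edge")
})

test_that("downsampling decimates cleanly and keeps t = 0 and DC", {
  rec <- make_recording(fill = 2.5)
  es <- cut_epochs(list(rec), 1.0, c(-0.5, 1.5))
  expect_identical(downsample_epochs(es, 1000), es)
  ds <- downsample_epochs(es, 250)
  expect_equal(dim(ds$data)[3], 500)
  expect_true(0 %in% ds$times)
  expect_equal(ds$rate, 250)
  # a DC epoch passes through the anti-alias filter unchanged
  expect_equal(as.numeric(ds$data), rep(2.5, length(ds$data)),
               tolerance = 1e-6)
  expect_error(downsample_epochs(es, 300), "divide")
})

test_that("baseline standardization matches hand arithmetic", {
  # baseline samples have mean 2 and sd 0.5; post-event value is 3
  base_vals <- c(1.5, 2.5, 1.5, 2.5) # mean 2
  sd_b <- sd(base_vals)
  data <- array(0, c(1, 1, 8))
  data[1, 1, ] <- c(base_vals, 3, 3, 3, 3)
  es <- toy_epochs(data, rate = 1000, t0_index = 5)
  z <- standardize_to_baseline(es, c(-0.004, 0))
  expect_equal(z$data[1, 1, 5], (3 - 2) / sd_b)
  sub <- standardize_to_baseline(es, c(-0.004, 0), mode = "subtract")
  expect_equal(sub$data[1, 1, 5], 1)
  expect_error(standardize_to_baseline(es, c(-0.5, -0.4)), "empty baseline")
})

test_that("standardized baselines have mean 0 and sd 1", {
  withr::with_seed(8, {
    data <- array(rnorm(20 * 4 * 100, 5, 3), c(20, 4, 100))
  })
  es <- toy_epochs(data, rate = 250, t0_index = 51)
  z <- standardize_to_baseline(es, c(-0.2, 0))
  idx <- which(es$times >= -0.2 & es$times < 0)
  base <- z$data[, , idx, drop = FALSE]
  mu <- apply(base, c(1, 2), mean)
  sdv <- apply(base, c(1, 2), sd)
  expect_lt(max(abs(mu)), 1e-10)
  expect_equal(as.numeric(sdv), rep(1, length(sdv)))
})

saccade_toys <- function() {
  # trials x rules: construct one violating case per rule plus one keeper
  tibble::tribble(
    ~trial_index, ~n_sac, ~x_end, ~y_end, ~latency,
    0L, 1L, -6.8, -0.3, 0.23,  # kept
    1L, 2L, -6.8, -0.3, 0.23,  # two saccades
    2L, 1L, -3.0, -0.3, 0.23,  # did not cross midline by 4 deg
    3L, 1L, -6.8, -2.5, 0.23,  # too low
    4L, 1L, -6.8, -0.3, 0.14,  # latency too short
    5L, 1L, -6.8, -0.3, 0.55   # latency too long
  )
}

test_that("saccade epoch selection applies the four printed rules", {
  toys <- saccade_toys()
  n <- nrow(toys)
  es <- toy_epochs(array(0, c(n, 1, 10)), rate = 250, t0_index = 1,
                   trials = tibble::tibble(trial_index = toys$trial_index))
  events <- purrr::pmap_dfr(toys, function(trial_index, n_sac, x_end,
                                           y_end, latency) {
    tibble::tibble(trial_index = trial_index,
                   onset = latency + 0.01 * (seq_len(n_sac) - 1),
                   x_end = x_end, y_end = y_end, latency = latency)
  })
  kept <- select_saccade_epochs(es, events, s2_onset = 1.0)
  expect_equal(kept$trials$trial_index, 0L)
  # brute-force application of the printed rules agrees
  brute <- toys$n_sac == 1 & toys$x_end <= -4 & toys$y_end >= -2 &
    toys$latency >= 0.15 & toys$latency <= 0.50
  expect_equal(kept$trials$trial_index, toys$trial_index[brute])
  # every dropped trial is accounted for
  expect_setequal(unique(kept$rejection_log$trial_index),
                  toys$trial_index[!brute])
  expect_equal(nrow(kept$trials) + length(unique(kept$rejection_log$trial_index)),
               n)
  expect_setequal(
    kept$rejection_log$rule[kept$rejection_log$trial_index == 1L],
    "one_saccade")
  expect_setequal(
    kept$rejection_log$rule[kept$rejection_log$trial_index == 2L],
    "midline")
  expect_setequal(
    kept$rejection_log$rule[kept$rejection_log$trial_index == 3L],
    "vertical")
  expect_setequal(
    kept$rejection_log$rule[kept$rejection_log$trial_index == 4L],
    "latency")
})

test_that("fixation epoch selection enforces gaze bounds and microsaccades", {
  es <- toy_epochs(array(0, c(3, 1, 10)), rate = 250, t0_index = 3,
                   trials = tibble::tibble(trial_index = 0:2))
  steady <- flat_trace(200, x = 7, y = 0)
  steady$time_s <- steady$time_s - 0.05
  wander <- steady
  # excursion to 2.5 degrees from fixation, inside the epoch window
  wander$x_deg[wander$time_s >= 0 & wander$time_s <= 0.02] <- 9.5
  traces <- list(steady, steady, wander)
  ms <- tibble::tibble(trial_index = 1L, amplitude = 0.6)
  kept <- select_fixation_epochs(es, traces, ms,
                                 fixation_points = c(7, 0))
  expect_equal(kept$trials$trial_index, 0L)
  expect_setequal(kept$rejection_log$rule[kept$rejection_log$trial_index == 1L],
                  "microsaccade")
  expect_setequal(kept$rejection_log$rule[kept$rejection_log$trial_index == 2L],
                  "gaze_bounds")
  # sub-threshold microsaccades are tolerated
  ms_ok <- tibble::tibble(trial_index = 1L, amplitude = 0.4)
  kept2 <- select_fixation_epochs(es, traces, ms_ok,
                                  fixation_points = c(7, 0))
  expect_setequal(kept2$trials$trial_index, c(0L, 1L))
})

test_that("selection bookkeeping: kept + rejected = input", {
  withr::with_seed(21, {
    n <- 30
    toys <- tibble::tibble(
      trial_index = seq_len(n) - 1L,
      n_sac = sample(1:2, n, replace = TRUE, prob = c(0.8, 0.2)),
      x_end = rnorm(n, -6, 2),
      y_end = rnorm(n, -0.5, 1.2),
      latency = runif(n, 0.1, 0.6)
    )
  })
  es <- toy_epochs(array(0, c(nrow(toys), 1, 10)), rate = 250, t0_index = 1,
                   trials = tibble::tibble(trial_index = toys$trial_index))
  events <- purrr::pmap_dfr(toys, function(trial_index, n_sac, x_end,
                                           y_end, latency) {
    tibble::tibble(trial_index = trial_index,
                   onset = latency + 0.01 * (seq_len(n_sac) - 1),
                   x_end = x_end, y_end = y_end, latency = latency)
  })
  kept <- select_saccade_epochs(es, events, s2_onset = 1.0)
  brute <- toys$n_sac == 1 & toys$x_end <= -4 & toys$y_end >= -2 &
    toys$latency >= 0.15 & toys$latency <= 0.50
  expect_equal(kept$trials$trial_index, toys$trial_index[brute])
  expect_equal(nrow(kept$trials) +
                 length(unique(kept$rejection_log$trial_index)), nrow(toys))
  # selection is idempotent: re-applying the rules changes nothing
  again <- select_saccade_epochs(kept, events, s2_onset = 1.0)
  expect_equal(again$trials, kept$trials)
  expect_equal(dim(again$data), dim(kept$data))
})

test_that("realignment re-cuts around per-trial events and logs misfits", {
  rate <- 250
  n_t <- 500 # [-0.5, 1.5) at 250 Hz
  data <- array(0, c(2, 1, n_t))
  times <- (seq_len(n_t) - 126) / rate
  # encode absolute time in the signal to verify the re-cut
  data[1, 1, ] <- times
  data[2, 1, ] <- times
  es <- new_epoch_set(data, times, rate, "S1_onset",
                      tibble::tibble(trial_index = 0:1))
  # trial 1: offset at 0.30 fits [-0.6, 0.4); trial 2: offset at 1.2 does not
  re <- realign_epochs(es, c(0.30, 1.2), window = c(-0.6, 0.4),
                       baseline = NULL)
  expect_equal(dim(re$data)[1], 1)
  expect_equal(re$alignment, "saccade_offset")
  expect_equal(re$rejection_log$rule, "margin")
  expect_equal(re$rejection_log$trial_index, 1L)
  # the value at new time t equals old value at t + 0.30
  expect_equal(as.numeric(re$data[1, 1, ]), re$times + 0.30,
               tolerance = 1e-9)
  # realigning to the original event reproduces the window
  re0 <- realign_epochs(es, c(0, 0), window = c(-0.4, 0.4), baseline = NULL)
  sel <- which(times >= -0.4 & times < 0.4)
  expect_equal(re0$data[1, 1, ], data[1, 1, sel])
})

test_that("artifact thresholding flags only contaminated epochs", {
  withr::with_seed(31, data <- array(rnorm(10 * 2 * 50), c(10, 2, 50)))
  data[4, 1, 20] <- 60 # gross spike
  es <- toy_epochs(data, rate = 250, t0_index = 10)
  kept <- reject_artifact_epochs(es, k = 8)
  expect_equal(nrow(kept$trials), 9)
  expect_equal(kept$rejection_log$trial_index, 3L) # 0-based index of trial 4
  expect_equal(kept$rejection_log$rule, "artifact")
  # clean data pass untouched
  es2 <- toy_epochs(array(rnorm(5 * 2 * 50), c(5, 2, 50)), 250, 10)
  expect_equal(nrow(reject_artifact_epochs(es2)$trials), 5)
})
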