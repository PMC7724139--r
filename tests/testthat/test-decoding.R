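test_that("searchlight geometry: window sizes and boundary handling", {
  es <- toy_epochs(array(rnorm(5 * 64 * 20), c(5, 64, 20)), rate = 250,
                   t0_index = 5)
  expect_equal(ncol(searchlight_features(es, 10, radius = 0L)), 64)
  expect_equal(ncol(searchlight_features(es, 10, radius = 2L)), 320)
  expect_equal(searchlight_centers(es, 2L), 3:18)
  expect_error(searchlight_features(es, 2, radius = 2L), "exceeds")
  expect_error(searchlight_features(es, 10, radius = -1), "non-negative")
  # 8 ms at 250 Hz is exactly two samples
  expect_identical(radius_samples(0.008, 250), 2L)
  expect_error(radius_samples(0.008, 300), "whole number")
})

test_that("log-odds conversion maps chance to zero and stays finite", {
  expect_equal(to_log_odds(50, 100), 0)
  expect_equal(to_log_odds(62, 100), log(62.5 / 38.5))
  expect_equal(round(to_log_odds(62, 100), 4), 0.4845)
  expect_true(is.finite(to_log_odds(100, 100)))
  expect_true(is.finite(to_log_odds(0, 100)))
  expect_equal(to_log_odds(0, 10), -to_log_odds(10, 10))
  expect_error(to_log_odds(5, 0), "positive")
  expect_error(to_log_odds(11, 10), "0 <= k <= n")
  expect_equal(accuracy_to_log_odds(0.5, 200), 0)
})

test_that("the shifted diagonal origin is latency plus duration", {
  expect_equal(offset_diagonal_origin(0.226, 0.062), 0.288)
  expect_equal(offset_diagonal_origin(0, 0), 0)
  expect_equal(offset_diagonal_origin(c(0.2, 0.25), c(0.05, 0.06)),
               c(0.25, 0.31))
  expect_error(offset_diagonal_origin(NA_real_, 0.06), "medians")
})

test_that("diagonal-band extraction averages the right cells", {
  gm <- structure(list(
    value = matrix(7, 20, 20),
    train_times = (0:19) / 250, test_times = (0:19) / 250,
    statistic = "accuracy", n_test = 10,
    train_condition = "a", test_condition = "b",
    train_alignment = "S1_onset", test_alignment = "S1_onset"
  ), class = "generalization_matrix")
  # constant matrix: constant trace for any origin/width
  tr <- extract_diagonal_band(gm, 0, 0, width = 0.020)
  expect_true(all(tr$value == 7))
  tr2 <- extract_diagonal_band(gm, 0.02, 0, width = 0.040)
  expect_true(all(tr2$value == 7))
  # interior cells of a 20 ms band at 250 Hz cover five samples
  expect_equal(max(tr$n_cells), 5)
  expect_true(all(tr$n_cells[tr$time >= 0.008 &
                               tr$time <= max(tr$time) - 0.008] == 5))
  # identity-structured matrix with a single-sample band
  gm$value <- diag(20)
  tr3 <- extract_diagonal_band(gm, 0, 0, width = 1 / 250)
  expect_true(all(tr3$value == 1))
  # a shifted origin reads the shifted diagonal
  gm$value <- matrix(0, 20, 20)
  gm$value[cbind(6:20, 1:15)] <- 1 # train = test + 5 samples
  tr4 <- extract_diagonal_band(gm, train_origin = 5 / 250, test_origin = 0,
                               width = 1 / 250)
  expect_true(all(tr4$value[tr4$time <= 14 / 250] == 1))
})

test_that("cross-validated decoding separates a planted pattern", {
  es <- separable_epochs(n_trials = 60, gain = 4, seed = 2)
  tc <- crossval_timecourse(es, "label", k = 10, radius = 2, seed = 3)
  expect_true(all(tc$accuracy >= 0 & tc$accuracy <= 1))
  on <- tc$time > 0.06
  pre <- tc$time < 0
  expect_gt(mean(tc$accuracy[on]), 0.95)
  expect_lt(mean(tc$accuracy[pre]), 0.7)
  # label symmetry: swapping class labels leaves accuracy unchanged
  es_sw <- es
  es_sw$trials$label <- ifelse(es$trials$label == "low", "high", "low")
  tc_sw <- crossval_timecourse(es_sw, "label", k = 10, radius = 2, seed = 3)
  expect_equal(tc$accuracy, tc_sw$accuracy)
})

test_that("decoding shuffled labels stays at chance", {
  es <- separable_epochs(n_trials = 60, gain = 4, seed = 4)
  withr::with_seed(5, {
    es$trials$label <- sample(es$trials$label)
  })
  tc <- crossval_timecourse(es, "label", k = 10, radius = 2, seed = 6)
  # 3 Monte-Carlo SEs of a 60-trial binomial around 0.5
  expect_lt(abs(mean(tc$accuracy) - 0.5), 3 * sqrt(0.25 / 60))
})

test_that("decoding is deterministic under a fixed seed", {
  es <- separable_epochs(n_trials = 40, gain = 1, noise = 2, seed = 7)
  a <- crossval_timecourse(es, "label", k = 5, radius = 1, seed = 8)
  b <- crossval_timecourse(es, "label", k = 5, radius = 1, seed = 8)
  expect_identical(a, b)
  d <- crossval_timecourse(es, "label", k = 5, radius = 1, seed = 9)
  expect_false(identical(a$accuracy, d$accuracy))
})

test_that("cross-condition generalization transfers a shared pattern", {
  tr_es <- separable_epochs(n_trials = 50, gain = 4, seed = 10)
  te_es <- separable_epochs(n_trials = 50, gain = 4, seed = 10)
  withr::with_seed(11, {
    te_es$data <- te_es$data + array(rnorm(length(te_es$data), 0, 0.5),
                                     dim(te_es$data))
  })
  gm <- cross_condition_matrix(tr_es, te_es, "label", radius = 2, seed = 12)
  expect_equal(dim(gm$value), c(46, 46))
  expect_true(all(gm$value >= 0 & gm$value <= 1))
  late <- gm$train_times > 0.06
  expect_gt(mean(gm$value[late, gm$test_times > 0.06]), 0.9)
  expect_lt(mean(gm$value[!late, gm$test_times < 0]), 0.75)
})

test_that("unbalanced training sets are balanced by subsampling", {
  es <- separable_epochs(n_trials = 60, gain = 4, seed = 13)
  # drop 'high' trials to unbalance 2:1
  keep <- c(which(es$trials$label == "low"),
            which(es$trials$label == "high")[1:15])
  es2 <- new_epoch_set(es$data[keep, , , drop = FALSE], es$times, es$rate,
                       es$alignment, es$trials[keep, ])
  y <- factor(es2$trials$label)
  bal <- sacdec:::balanced_subsample(y, seed = 14)
  expect_equal(as.numeric(table(y[bal])), c(15, 15))
  # stratified balancing respects the strata proportions
  strata <- factor(rep(c("a", "b"), length.out = nrow(es2$trials)))
  bal2 <- sacdec:::balanced_subsample(y, strata = strata, seed = 15)
  expect_equal(as.numeric(table(y[bal2])), c(15, 15))
})

test_that("choice statistic reports the forced-choice proportion", {
  tr_es <- separable_epochs(n_trials = 40, gain = 5, seed = 16)
  # symmetric noise-only test trials: proportion-high stays near 0.5
  te_es <- toy_epochs(array(rnorm(60 * 8 * 50), c(60, 8, 50)), rate = 250,
                      t0_index = 13,
                      trials = tibble::tibble(trial_index = 0:59))
  gm <- classify_bias(tr_es, te_es, label = "label", choice_level = "high",
                      radius = 2, seed = 17)
  expect_equal(gm$statistic, "choice")
  expect_lt(abs(mean(gm$value) - 0.5), 3 * sqrt(0.25 / 60))
  # test data carrying the 'high' pattern are nearly always chosen as high
  te_hi <- separable_epochs(n_trials = 40, gain = 5, seed = 16)
  hi_idx <- which(te_hi$trials$label == "high")
  te_hi2 <- new_epoch_set(te_hi$data[hi_idx, , , drop = FALSE], te_hi$times,
                          te_hi$rate, te_hi$alignment,
                          te_hi$trials[hi_idx, ])
  gm_hi <- classify_bias(tr_es, te_hi2, label = "label",
                         choice_level = "high", radius = 2, seed = 18)
  late <- gm_hi$train_times > 0.06
  expect_gt(mean(gm_hi$value[late, te_hi2$times[
    sacdec::searchlight_centers(te_hi2, 2)] > 0.06]), 0.95)
})

test_that("tidiers and autoplot run on decoding objects", {
  tr_es <- separable_epochs(n_trials = 30, gain = 3, seed = 19)
  te_es <- separable_epochs(n_trials = 30, gain = 3, seed = 20)
  gm <- cross_condition_matrix(tr_es, te_es, "label", radius = 2, seed = 21)
  td <- tidy(gm)
  expect_equal(nrow(td), length(gm$value))
  g <- glance(gm)
  expect_equal(g$n_test, 30)
  expect_s3_class(autoplot(gm), "ggplot")
  tr <- extract_diagonal_band(gm, 0, 0)
  expect_s3_class(autoplot(tr), "ggplot")
})

test_that("diagonal inferences are robust to the band width", {
  # the pattern of inference (which test times decode above chance) must
  # not depend on the band width; the trace values themselves saturate on
  # synthetic handoff data, so the comparison is at the mask level
  arr <- make_sensor_array(16)
  m <- pattern_model(arr, t_persist = 0.2, seed = 22)
  train <- simulate_decoding_set("Fix-LVF", 160, m, seed = 23)
  test <- simulate_decoding_set("Sac-LVF", 160, m, align = "saccade_offset",
                                seed = 24)
  shift <- offset_diagonal_origin(median(test$trials$saccade_latency),
                                  median(test$trials$saccade_duration))
  gm <- cross_condition_matrix(train, test, "label", radius = 2,
                               train_window = c(shift - 0.6, shift + 0.45),
                               seed = 25)
  thr <- 0.5 + 3 * sqrt(0.25 / 160)
  trace_w <- lapply(c(0.008, 0.020, 0.040, 0.080), function(w) {
    tr <- extract_diagonal_band(gm, shift, 0, width = w)
    tr[tr$time >= -0.25 & tr$time <= 0.35, ]
  })
  ref_mask <- trace_w[[2]]$value > thr
  for (tr in trace_w) {
    expect_gt(mean((tr$value > thr) == ref_mask), 0.9)
  }
  # the persistence readout agrees between the 8 and 20 ms bands; wider
  # bands dilute the band mean with off-diagonal cells and shorten it,
  # so they are not held to the same mark
  lst <- vapply(trace_w[1:2], last_significant_time, numeric(1))
  expect_lt(abs(lst[1] - lst[2]), 0.02)
})
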