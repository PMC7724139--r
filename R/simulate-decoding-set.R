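#' Simulate analysis-ready epochs for one condition
#'
#' A lean generator path for decoding studies: balanced low/high
#' spatial-frequency labels, sampled trial timing, sensor synthesis with
#' ground-truth saccade times, epoch cutting, baseline standardization and
#' downsampling — skipping eye-trace measurement and event detection
#' (ground truth stands in for the detector). Use [simulate_session()] for
#' the full chain.
#'
#' @param condition `"Fix-LVF"`, `"Fix-RVF"`, `"Sac-LVF"` or `"Sac-noVF"`.
#' @param n_trials Number of trials (split evenly over the two spatial
#'   frequencies; no-stimulus trials get alternating dummy labels).
#' @param model A [pattern_model()].
#' @param params A [timing_params()].
#' @param align `"S1_onset"`, `"saccade_onset"` or `"saccade_offset"`.
#' @param rate_sensor Synthesis rate (Hz).
#' @param rate Analysis rate (Hz) after downsampling.
#' @param baseline S1-locked baseline window (s).
#' @param realign_window Window used when `align` is saccade-locked (s).
#' @param seed Integer seed.
#' @return An `epoch_set` whose trials carry `spatial_frequency`,
#'   `saccade_latency`, `saccade_duration`.
#' @export
simulate_decoding_set <- function(condition, n_trials, model,
                                  params = timing_params(),
                                  align = "S1_onset",
                                  rate_sensor = 500, rate = 250,
                                  baseline = c(-0.2, 0),
                                  realign_window = c(-0.6, 0.4),
                                  seed = 1L) {
  check_that(n_trials >= 2, "need at least two trials")
  sf <- rep(c("low", "high"), length.out = n_trials)
  sf_col <- if (identical(condition, "Sac-noVF")) rep("none", n_trials)
            else sf
  block_type <- if (startsWith(condition, "Sac")) "saccade" else "fixation"
  design <- tibble::tibble(
    trial_index = seq_len(n_trials) - 1L,
    condition = condition,
    spatial_frequency = sf_col,
    label = sf,
    change = rep(c(TRUE, FALSE), length.out = n_trials),
    block_type = block_type
  )
  recordings <- vector("list", n_trials)
  timings <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    s_i <- derive_seed(seed, 2000, i)
    timing <- sample_trial_timing(design[i, ], params,
                                  seed = derive_seed(s_i, 1))
    recordings[[i]] <- synthesize_sensor_data(
      design[i, ], timing, model, rate = rate_sensor,
      t_start = timing$s1_onset - 0.6, t_end = timing$s1_onset + 1.6,
      seed = derive_seed(s_i, 2))
    timings[[i]] <- timing
  }
  timing_tbl <- dplyr::bind_rows(timings)
  trials <- dplyr::bind_cols(design, timing_tbl)
  es <- cut_epochs(recordings, trials$s1_onset, c(-0.5, 1.5),
                   trials = trials, alignment = "S1_onset")
  es <- standardize_to_baseline(es, baseline)
  es <- downsample_epochs(es, rate)
  if (align != "S1_onset") {
    ev <- if (align == "saccade_onset") es$trials$saccade_latency
          else es$trials$saccade_latency + es$trials$saccade_duration
    es <- realign_epochs(es, ev, window = realign_window, baseline = NULL,
                         alignment = align)
  }
  es
}

#' Noise-only epochs with statistically independent labels
#'
#' Convenience for chance-level calibration: epochs are pure noise from
#' the model's noise process; labels are random coin flips independent of
#' the data.
#'
#' @param n_trials,n_channels Shape of the set.
#' @param n_times Number of time samples.
#' @param rate Sampling rate (Hz).
#' @param seed Integer seed.
#' @return An `epoch_set` with a random two-level `label` column.
#' @export
simulate_null_epochs <- function(n_trials, n_channels, n_times,
                                 rate = 250, seed = 1L) {
  data <- with_seed(derive_seed(seed, 3000), {
    array(rnorm(n_trials * n_channels * n_times),
          c(n_trials, n_channels, n_times))
  })
  labels <- with_seed(derive_seed(seed, 3001), {
    sample(c("low", "high"), n_trials, replace = TRUE)
  })
  # guard against a degenerate single-class draw
  if (length(unique(labels)) == 1) labels[1] <- setdiff(c("low", "high"),
                                                        labels[1])
  trials <- tibble::tibble(trial_index = seq_len(n_trials) - 1L,
                           label = labels)
  new_epoch_set(data, (seq_len(n_times) - 1) / rate, rate, "S1_onset",
                trials)
}
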