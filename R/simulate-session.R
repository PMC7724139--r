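# delay eye samples by `lag` relative to the sensor clock (emulates the
# analog-converter lag that apply_clock_correction removes)
delay_trace <- function(trace, lag) {
  rate <- attr(trace, "rate")
  k <- round(lag * rate)
  if (k == 0) return(trace)
  n <- nrow(trace)
  out <- trace
  out$x_deg <- c(rep(trace$x_deg[1], k), trace$x_deg[seq_len(n - k)])
  out$y_deg <- c(rep(trace$y_deg[1], k), trace$y_deg[seq_len(n - k)])
  ev <- attr(trace, "events")
  ev$onset <- ev$onset + lag
  ev$offset <- ev$offset + lag
  attr(out, "events") <- ev
  out
}

#' Simulate one subject's full recording session
#'
#' Runs the complete generator chain for every trial of a design: event
#' timing, a 1000 Hz eye trace (delayed by the converter lag that
#' [apply_clock_correction()] later removes), a photodiode trace, and the
#' multichannel sensor recording. It then runs the measurement side:
#' photodiode ternarization for S1 onset, clock correction, velocity-based
#' saccade detection, and epoch cutting around S1 onset.
#'
#' @param design Trial tibble from [build_design()].
#' @param model A [pattern_model()].
#' @param geometry A [scene_geometry()].
#' @param params A [timing_params()].
#' @param rate_sensor Sensor sampling rate (Hz).
#' @param rate_eye Eye-tracker sampling rate (Hz).
#' @param eye_lag Converter lag injected into the eye traces (s).
#' @param microsaccade_rate Microsaccade rate on fixation trials (1/s).
#' @param epoch_window S1-locked epoch window (s).
#' @param seed Integer seed; every per-trial seed derives from it.
#' @return A list of class `session`: `trials` (design + timing + detected
#'   saccade metrics), `epochs` (S1-aligned `epoch_set`), `events`
#'   (detected saccades, times relative to S1 onset), `eye_traces`
#'   (S1-locked, for fixation-epoch selection).
#' @export
simulate_session <- function(design, model,
                             geometry = scene_geometry(),
                             params = timing_params(),
                             rate_sensor = 500,
                             rate_eye = 1000,
                             eye_lag = 0.007,
                             microsaccade_rate = 0.3,
                             epoch_window = c(-0.5, 1.5),
                             seed = 1L) {
  n <- nrow(design)
  check_that(n > 0, "empty design")
  recordings <- vector("list", n)
  traces <- vector("list", n)
  timings <- vector("list", n)
  ev_list <- vector("list", n)
  s1_detected <- numeric(n)
  for (i in seq_len(n)) {
    trial <- design[i, ]
    s_i <- derive_seed(seed, 1000, i)
    timing <- sample_trial_timing(trial, params,
                                  saccade_amplitude =
                                    geometry$required_saccade_amplitude,
                                  seed = derive_seed(s_i, 1))
    has_sac <- trial$block_type == "saccade"
    fix_pt <- if (trial$fixation_side == "left") geometry$fixation_left
              else geometry$fixation_right
    eye <- synthesize_eye_trace(
      timing, geometry, fixation = fix_pt,
      has_saccade = has_sac, rate = rate_eye,
      duration = timing$s1_onset + epoch_window[2] + 0.2,
      microsaccade_rate = if (has_sac) 0 else microsaccade_rate,
      seed = derive_seed(s_i, 2))
    truth <- attr(eye, "events")
    eye_meas <- delay_trace(eye, eye_lag)
    changes <- if (trial$condition == "Sac-noVF") timing$s1_onset
    pd <- synthesize_photodiode(timing, changes = changes, rate = rate_eye,
                                duration = nrow(eye) / rate_eye,
                                seed = derive_seed(s_i, 3))
    s1 <- ternarize_photodiode(pd)[1]
    eye_corr <- apply_clock_correction(eye_meas, eye_lag)
    det <- detect_saccades(eye_corr, s1_onset = s1)
    main_sac <- truth[truth$kind == "saccade", ]
    recordings[[i]] <- synthesize_sensor_data(
      trial, timing, model,
      saccade_onset = if (nrow(main_sac)) main_sac$onset[1],
      saccade_offset = if (nrow(main_sac)) main_sac$offset[1],
      rate = rate_sensor,
      t_start = timing$s1_onset + epoch_window[1] - 0.1,
      t_end = timing$s1_onset + epoch_window[2] + 0.1,
      seed = derive_seed(s_i, 4))
    # S1-locked copies for selection / bookkeeping
    s1_detected[i] <- s1
    tr_rel <- eye_corr
    tr_rel$time_s <- tr_rel$time_s - s1
    traces[[i]] <- tr_rel
    if (nrow(det) > 0) {
      det$trial_index <- trial$trial_index
      det$onset <- det$onset - s1
      det$offset <- det$offset - s1
      ev_list[[i]] <- det
    }
    timings[[i]] <- timing
  }
  timing_tbl <- dplyr::bind_rows(timings)
  events <- if (length(purrr::compact(ev_list))) {
    dplyr::bind_rows(purrr::compact(ev_list))
  } else {
    tibble::tibble(trial_index = integer(0), onset = numeric(0),
                   offset = numeric(0), x_end = numeric(0),
                   y_end = numeric(0), latency = numeric(0))
  }
  trials <- dplyr::bind_cols(design, timing_tbl)
  trials$s2_rel <- trials$s2_onset - trials$s1_onset
  # detected main saccade per trial (largest event in the response window)
  main <- events |>
    dplyr::filter(.data$onset > 0) |>
    dplyr::group_by(.data$trial_index) |>
    dplyr::slice_max(.data$amplitude, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("trial_index", det_latency = "latency",
                  det_duration = "duration", det_h_amplitude = "h_amplitude")
  trials <- dplyr::left_join(trials, main, by = "trial_index")
  epochs <- cut_epochs(recordings, s1_detected, epoch_window,
                       trials = trials, alignment = "S1_onset")
  structure(list(trials = trials, epochs = epochs, events = events,
                 eye_traces = traces, geometry = geometry,
                 rate_sensor = rate_sensor, seed = seed),
            class = "session")
}

#' @export
print.session <- function(x, ...) {
  cat("<session> ", nrow(x$trials), " trials, ", sep = "")
  print(x$epochs)
  invisible(x)
}

#' Prepare one condition's analysis-ready epochs from a session
#'
#' Applies the condition's epoch-exclusion rules (saccade geometry/latency
#' rules or fixation gaze/microsaccade rules), baseline-standardizes on the
#' S1-locked grid, and downsamples for the multivariate analyses.
#'
#' @param session A [simulate_session()] result.
#' @param condition Condition name (`"Fix-LVF"`, `"Fix-RVF"`, `"Sac-LVF"`,
#'   `"Sac-noVF"`).
#' @param rate Analysis rate (Hz), default 250.
#' @param baseline S1-locked baseline window (s).
#' @param align `"S1_onset"`, `"saccade_onset"` or `"saccade_offset"`;
#'   realignment happens after standardization, re-using each trial's
#'   detected saccade.
#' @param realign_window Window for realigned epochs (s).
#' @return An `epoch_set`.
#' @export
condition_epochs <- function(session, condition, rate = 250,
                             baseline = c(-0.2, 0),
                             align = "S1_onset",
                             realign_window = c(-0.6, 0.4)) {
  sel <- which(session$trials$condition == condition)
  check_that(length(sel) > 0, paste0("no trials in condition ", condition))
  es <- session$epochs
  es <- new_epoch_set(es$data[sel, , , drop = FALSE], es$times, es$rate,
                      es$alignment, es$trials[sel, ])
  if (startsWith(condition, "Sac")) {
    s2 <- ifelse(is.na(es$trials$s2_rel), es$times[length(es$times)],
                 es$trials$s2_rel)
    es <- select_saccade_epochs(es, session$events, s2_onset = s2)
  } else {
    idx <- match(es$trials$trial_index, session$trials$trial_index)
    fix_side <- es$trials$fixation_side
    fp <- t(vapply(fix_side, function(s) {
      if (s == "left") session$geometry$fixation_left
      else session$geometry$fixation_right
    }, numeric(2)))
    ms <- session$events[session$events$onset >= es$times[1] &
                           session$events$onset <=
                             es$times[length(es$times)], ]
    es <- select_fixation_epochs(es, session$eye_traces[idx], ms, fp)
  }
  es <- standardize_to_baseline(es, baseline)
  es <- downsample_epochs(es, rate)
  if (align != "S1_onset") {
    ev <- if (align == "saccade_onset") es$trials$det_latency
          else es$trials$det_latency + es$trials$det_duration
    es <- realign_epochs(es, ev, window = realign_window, baseline = NULL,
                         alignment = align)
  }
  es
}
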