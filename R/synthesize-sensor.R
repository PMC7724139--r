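#' Synthesize one trial's multichannel sensor recording
#'
#' The recording is a sum of topography x envelope source contributions
#' plus stationary 1/f-weighted Gaussian noise. Fixation trials drive the
#' stimulated-hemifield topography at S1 (and S2) onset. Saccade trials
#' drive the presaccadic topography (stimulus in the left visual field,
#' right-hemisphere pattern) from S1 onset until `t_persist` after saccade
#' offset, and the postsaccadic topography (right visual field,
#' left-hemisphere pattern) from `onset_latency` after saccade offset; an
#' SF-independent saccade-locked component is added on every saccade trial.
#' No-stimulus saccade trials contain only noise plus that saccade-locked
#' component.
#'
#' @param trial One-row design tibble (see [build_design()]).
#' @param timing One-row timing tibble (see [sample_trial_timing()]).
#' @param model A [pattern_model()].
#' @param saccade_onset,saccade_offset Saccade times (s); taken from
#'   `timing` when omitted. Pass detected times to couple the recording to
#'   a generated eye trace.
#' @param rate Sensor sampling rate (Hz), default 500.
#' @param t_start,t_end Recording support (s); defaults to
#'   `s1_onset - 0.6` to `s1_onset + 1.6`.
#' @param seed Integer seed (noise only; topographies live in the model).
#' @return A `sensor_recording`: channels x time matrix with attributes
#'   `time` (s), `rate`, and `sources` (tibble of ground-truth source
#'   windows).
#' @export
synthesize_sensor_data <- function(trial, timing, model,
                                   saccade_onset = NULL,
                                   saccade_offset = NULL,
                                   rate = 500,
                                   t_start = NULL, t_end = NULL,
                                   seed = 1L) {
  check_that(inherits(model, "pattern_model"), "`model` must be a pattern_model")
  t_start <- t_start %||% (timing$s1_onset - 0.6)
  t_end <- t_end %||% (timing$s1_onset + 1.6)
  n <- round((t_end - t_start) * rate)
  t <- t_start + (seq_len(n) - 1) / rate
  n_ch <- nrow(model$array$channels)
  cond <- trial$condition[[1]]
  sf <- trial$spatial_frequency[[1]]
  lat <- model$onset_latency

  sources <- tibble::tibble(pattern = character(0), t_on = numeric(0),
                            t_off = numeric(0), gain = numeric(0))
  add_src <- function(sources, pattern, t_on, t_off, gain = 1) {
    dplyr::bind_rows(sources, tibble::tibble(
      pattern = pattern, t_on = t_on, t_off = t_off, gain = gain))
  }

  if (cond %in% c("Fix-LVF", "Fix-RVF")) {
    hemi <- if (cond == "Fix-LVF") "LVF" else "RVF"
    key <- paste(sf, hemi, sep = "_")
    sources <- add_src(sources, key, timing$s1_onset + lat,
                       timing$s1_onset + timing$s1_duration)
    if (!is.na(timing$s2_onset) && timing$s2_onset < t_end) {
      sources <- add_src(sources, key, timing$s2_onset + lat,
                         timing$s2_onset + timing$s2_duration)
    }
  } else {
    sac_on <- saccade_onset %||% (timing$s1_onset + timing$saccade_latency)
    sac_off <- saccade_offset %||% (sac_on + timing$saccade_duration)
    if (cond == "Sac-LVF") {
      sources <- add_src(sources, paste(sf, "LVF", sep = "_"),
                         timing$s1_onset + lat, sac_off + model$t_persist)
      sources <- add_src(sources, paste(sf, "RVF", sep = "_"),
                         sac_off + lat, timing$s2_onset + timing$s2_duration)
    }
    sources <- add_src(sources, "saccade", sac_on, sac_off + 0.05,
                       gain = model$saccade_gain)
    if (model$artifact_gain > 0) {
      sources <- add_src(sources, model$artifact_pattern, sac_on,
                         sac_on + 0.030, gain = model$artifact_gain)
    }
  }

  data <- matrix(0, n_ch, n)
  for (i in seq_len(nrow(sources))) {
    topo <- model$topographies[[sources$pattern[i]]]
    check_that(!is.null(topo),
               paste0("missing topography `", sources$pattern[i], "`"))
    env <- response_envelope(t, sources$t_on[i], sources$t_off[i], model)
    data <- data + model$amplitude * sources$gain[i] * tcrossprod(topo, env)
  }
  if (model$noise_sd > 0) {
    noise <- with_seed(seed, pink_noise(n, n_ch, model$noise_alpha))
    data <- data + model$noise_sd * t(noise)
  }
  structure(data, time = t, rate = rate, sources = sources,
            class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat("<sensor_recording> ", nrow(x), " channels x ", ncol(x),
      " samples at ", attr(x, "rate"), " Hz\n", sep = "")
  invisible(x)
}
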