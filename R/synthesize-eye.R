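#' Synthesize a monocular eye-position trace
#'
#' Gaze sits at the right fixation point with slow positional jitter
#' (white noise smoothed over 25 ms, SD `jitter_sd`). On saccade trials a
#' single saccade with a raised-cosine velocity profile moves gaze toward
#' the left fixation point at `s1_onset + saccade_latency`; the executed
#' amplitude is drawn around `amplitude_mean` (hypometric relative to the
#' required 14 degrees). Optional microsaccades are injected at a Poisson
#' rate during fixation. Ground-truth events are attached as the
#' `"events"` attribute.
#'
#' @param timing One-row timing tibble from [sample_trial_timing()].
#' @param geometry A [scene_geometry()].
#' @param fixation Fixation-point coordinates (degrees); defaults to the
#'   right fixation point (the starting point of saccade trials).
#' @param has_saccade Generate the main saccade?
#' @param rate Sampling rate (Hz), default 1000.
#' @param duration Trace length (s); defaults to `s1_onset + 1.6`.
#' @param jitter_sd Fixational jitter SD (degrees).
#' @param amplitude_mean,amplitude_sd Executed horizontal saccade amplitude
#'   distribution (degrees); the default mean emulates hypometric 13.1
#'   degree saccades.
#' @param vertical_sd SD of the saccade endpoint's vertical error (degrees).
#' @param microsaccade_rate Poisson rate (per second) of injected
#'   microsaccades during fixation.
#' @param microsaccade_amp Median microsaccade amplitude (degrees).
#' @param seed Integer seed.
#' @return A tibble (`time_s`, `x_deg`, `y_deg`) of class `eye_trace`, with
#'   attributes `rate` and `events` (tibble: `onset`, `offset`, `x_start`,
#'   `y_start`, `x_end`, `y_end`, `amplitude`, `kind`).
#' @export
synthesize_eye_trace <- function(timing, geometry = scene_geometry(),
                                 fixation = NULL,
                                 has_saccade = TRUE,
                                 rate = 1000,
                                 duration = NULL,
                                 jitter_sd = 0.05,
                                 amplitude_mean = 13.1,
                                 amplitude_sd = 0.5,
                                 vertical_sd = 0.4,
                                 microsaccade_rate = 0,
                                 microsaccade_amp = 0.2,
                                 seed = 1L) {
  duration <- duration %||% (timing$s1_onset + 1.6)
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  fix <- fixation %||% geometry$fixation_right
  with_seed(seed, {
    x <- rep(fix[1], n)
    y <- rep(fix[2], n)
    if (jitter_sd > 0) {
      x <- x + smooth_jitter(n, rate, jitter_sd)
      y <- y + smooth_jitter(n, rate, jitter_sd)
    }
    events <- tibble::tibble(
      onset = numeric(0), offset = numeric(0), x_start = numeric(0),
      y_start = numeric(0), x_end = numeric(0), y_end = numeric(0),
      amplitude = numeric(0), kind = character(0)
    )
    if (has_saccade) {
      check_that(!is.na(timing$saccade_latency),
                 "timing lacks a saccade latency")
      onset <- timing$s1_onset + timing$saccade_latency
      dur <- timing$saccade_duration
      amp <- if (amplitude_sd > 0) rnorm(1, amplitude_mean, amplitude_sd)
             else amplitude_mean
      dy <- if (vertical_sd > 0) rnorm(1, 0, vertical_sd) else 0
      res <- add_saccade(x, y, t, onset, dur, dx = -amp, dy = dy)
      x <- res$x; y <- res$y
      events <- dplyr::bind_rows(events, res$event)
    }
    if (microsaccade_rate > 0) {
      # only during the pre-saccadic fixation period (or the whole trace)
      fix_end <- if (has_saccade) timing$s1_onset + timing$saccade_latency -
                   0.05 else duration - 0.05
      n_ms <- stats::rpois(1, microsaccade_rate * max(fix_end - 0.05, 0))
      if (n_ms > 0) {
        onsets <- sort(runif(n_ms, 0.05, fix_end))
        for (o in onsets) {
          amp <- rlnorm(1, log(microsaccade_amp), 0.5)
          ang <- runif(1, 0, 2 * pi)
          dur_ms <- 0.027 + 0.0025 * amp
          res <- add_saccade(x, y, t, o, dur_ms,
                             dx = amp * cos(ang), dy = amp * sin(ang),
                             kind = "microsaccade")
          x <- res$x; y <- res$y
          events <- dplyr::bind_rows(events, res$event)
        }
      }
    }
  })
  out <- tibble::tibble(time_s = t, x_deg = x, y_deg = y)
  class(out) <- c("eye_trace", class(out))
  attr(out, "rate") <- rate
  attr(out, "events") <- dplyr::arrange(events, .data$onset)
  out
}

smooth_jitter <- function(n, rate, sd) {
  w <- max(round(0.025 * rate), 1)
  raw <- rnorm(n + 2 * w)
  sm <- stats::filter(raw, rep(1 / w, w), sides = 2)
  sm <- sm[(w + 1):(w + n)]
  as.numeric(sm) / sd(sm, na.rm = TRUE) * sd
}

# displace (x, y) by a raised-cosine-velocity step of (dx, dy) at `onset`
add_saccade <- function(x, y, t, onset, dur, dx, dy, kind = "saccade") {
  check_that(onset + dur <= t[length(t)],
             "saccade duration exceeds trace length")
  phase <- pmin(pmax((t - onset) / dur, 0), 1)
  # position profile with velocity (1 - cos(2*pi*p)) / dur: smooth, symmetric
  prof <- phase - sin(2 * pi * phase) / (2 * pi)
  i0 <- which(phase > 0)[1] - 1L
  i1 <- which(phase >= 1)[1]
  event <- tibble::tibble(
    onset = onset, offset = onset + dur,
    x_start = x[max(i0, 1)], y_start = y[max(i0, 1)],
    x_end = x[max(i0, 1)] + dx, y_end = y[max(i0, 1)] + dy,
    amplitude = sqrt(dx^2 + dy^2), kind = kind
  )
  list(x = x + dx * prof, y = y + dy * prof, event = event)
}

#' @export
print.eye_trace <- function(x, ...) {
  ev <- attr(x, "events")
  cat("<eye_trace> ", nrow(x), " samples at ", attr(x, "rate"), " Hz, ",
      nrow(ev), " ground-truth event(s)\n", sep = "")
  NextMethod()
}

#' Synthesize a photodiode trace
#'
#' The simulated photodiode patch shows one of three luminance levels
#' (black -1, gray 0, white +1) and flips polarity at every display change:
#' gray before S1, then alternating white/black at each scheduled change.
#'
#' @param timing One-row timing tibble; S1 onset and S2 onset (plus S2
#'   offset for fixation trials' blank) define the display-change schedule,
#'   or pass `changes` directly.
#' @param changes Optional explicit vector of display-change times (s),
#'   overriding the schedule derived from `timing`.
#' @param rate Sampling rate (Hz).
#' @param duration Trace length (s).
#' @param noise_sd Additive Gaussian noise SD (must stay below half the
#'   level separation, 0.5).
#' @param seed Integer seed.
#' @return A tibble (`time_s`, `level`) of class `photodiode_trace` with a
#'   `changes` attribute holding the ground-truth change times.
#' @export
synthesize_photodiode <- function(timing = NULL, changes = NULL, rate = 1000,
                                  duration = NULL, noise_sd = 0.05,
                                  seed = 1L) {
  if (is.null(changes)) {
    check_that(!is.null(timing), "provide `timing` or `changes`")
    changes <- c(timing$s1_onset, timing$s2_onset)
    if (!is.na(timing$blank_duration)) {
      # fixation trials blank S1 before S2: S1 off is its own display change
      changes <- c(timing$s1_onset, timing$s1_onset + timing$s1_duration,
                   timing$s2_onset)
    }
    changes <- changes[!is.na(changes)]
  }
  check_that(noise_sd < 0.5, "`noise_sd` must stay below half a level step")
  duration <- duration %||% (max(c(changes, 1)) + 0.5)
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  level <- numeric(n) # gray
  state <- 0
  for (ct in sort(changes)) {
    state <- if (state >= 0) -1 else 1 # polarity flip at every change
    if (state == -1 && all(level == 0)) state <- 1 # first change goes white
    level[t >= ct] <- state
  }
  if (noise_sd > 0) level <- level + with_seed(seed, rnorm(n, 0, noise_sd))
  out <- tibble::tibble(time_s = t, level = level)
  class(out) <- c("photodiode_trace", class(out))
  attr(out, "rate") <- rate
  attr(out, "changes") <- sort(changes)
  out
}
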