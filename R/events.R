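#' Shift an eye trace back in time to compensate converter lag
#'
#' Eye-position samples recorded through an analog converter arrive with a
#' fixed lag relative to the sensor clock; the correction shifts all samples
#' earlier by `lag` (rounded to a whole number of samples, documented
#' half-up rounding) and trims the trailing samples that no longer have
#' support.
#'
#' @param trace An `eye_trace` (tibble with `time_s`, `x_deg`, `y_deg`).
#' @param lag Lag to remove (s), default 0.007.
#' @return The corrected `eye_trace` (shorter by `round(lag * rate)`
#'   samples).
#' @export
apply_clock_correction <- function(trace, lag = 0.007) {
  check_that(lag >= 0, "`lag` must be non-negative")
  rate <- attr(trace, "rate") %||%
    (1 / median(diff(trace$time_s)))
  k <- round(lag * rate)
  n <- nrow(trace)
  check_that(k < n, "lag longer than trace")
  if (k == 0) return(trace)
  out <- trace[seq_len(n - k), ]
  out$x_deg <- trace$x_deg[(k + 1):n]
  out$y_deg <- trace$y_deg[(k + 1):n]
  for (a in c("rate", "events")) attr(out, a) <- attr(trace, a)
  class(out) <- class(trace)
  out
}

#' Saccade detector parameters
#'
#' @param lambda Velocity threshold scale factor (multiples of the robust
#'   velocity SD), default 6.
#' @param min_saccade Minimum saccade duration (s).
#' @param min_fixation Minimum fixation duration between saccades (s);
#'   events separated by shorter gaps are merged.
#' @return A list of class `detector_params`.
#' @export
detector_params <- function(lambda = 6, min_saccade = 0.010,
                            min_fixation = 0.040) {
  check_that(lambda > 0, "`lambda` must be positive")
  structure(list(lambda = lambda, min_saccade = min_saccade,
                 min_fixation = min_fixation), class = "detector_params")
}

#' Detect saccades with a median-based velocity threshold
#'
#' Velocity is the 5-point smoothed derivative
#' `v_n = (p_{n+2} + p_{n+1} - p_{n-1} - p_{n-2}) / (6 dt)` per axis. A
#' robust SD per axis, `sqrt(median(v^2) - median(v)^2)`, sets elliptic
#' thresholds at `lambda` multiples; contiguous supra-threshold runs form
#' candidate events, runs separated by gaps shorter than `min_fixation` are
#' merged, and events shorter than `min_saccade` are dropped. Events cannot
#' be detected within 2 samples of the trace boundary (the velocity
#' estimate is undefined there).
#'
#' @param trace An `eye_trace`.
#' @param params A [detector_params()].
#' @param s1_onset Optional S1 onset time (s) for latency computation.
#' @return A tibble of events: `onset`, `offset`, `duration`, `x_start`,
#'   `y_start`, `x_end`, `y_end`, `h_amplitude` (signed horizontal
#'   component), `amplitude`, `peak_velocity`, `latency`.
#' @export
detect_saccades <- function(trace, params = detector_params(),
                            s1_onset = NA_real_) {
  n <- nrow(trace)
  check_that(n >= 5, "trace must have at least 5 samples")
  rate <- attr(trace, "rate") %||% (1 / median(diff(trace$time_s)))
  dt <- 1 / rate
  v <- function(p) {
    idx <- 3:(n - 2)
    (p[idx + 2] + p[idx + 1] - p[idx - 1] - p[idx - 2]) / (6 * dt)
  }
  vx <- v(trace$x_deg)
  vy <- v(trace$y_deg)
  rsd <- function(vv) sqrt(median(vv^2) - median(vv)^2)
  sx <- rsd(vx)
  sy <- rsd(vy)
  check_that(is.finite(sx) && is.finite(sy) && sx > 0 && sy > 0,
             "degenerate trace: zero velocity variance")
  crit <- (vx / (params$lambda * sx))^2 + (vy / (params$lambda * sy))^2 > 1

  runs <- find_runs(crit)
  if (nrow(runs) > 1) {
    # merge events separated by gaps shorter than the minimum fixation
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap <- (runs$start[i] - merged$end[nrow(merged)] - 1) * dt
      if (gap < params$min_fixation) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  if (nrow(runs) > 0) {
    dur <- (runs$end - runs$start + 1) * dt
    runs <- runs[dur >= params$min_saccade, , drop = FALSE]
  }
  if (nrow(runs) == 0) {
    return(tibble::tibble(
      onset = numeric(0), offset = numeric(0), duration = numeric(0),
      x_start = numeric(0), y_start = numeric(0), x_end = numeric(0),
      y_end = numeric(0), h_amplitude = numeric(0), amplitude = numeric(0),
      peak_velocity = numeric(0), latency = numeric(0)
    ))
  }
  # indices in `crit` are offset by 2 samples relative to the trace
  i_on <- runs$start + 2L
  i_off <- runs$end + 2L
  speed <- sqrt(vx^2 + vy^2)
  out <- purrr::map_dfr(seq_len(nrow(runs)), function(i) {
    sel <- runs$start[i]:runs$end[i]
    tibble::tibble(
      onset = trace$time_s[i_on[i]],
      offset = trace$time_s[i_off[i]],
      duration = trace$time_s[i_off[i]] - trace$time_s[i_on[i]],
      x_start = trace$x_deg[i_on[i]], y_start = trace$y_deg[i_on[i]],
      x_end = trace$x_deg[i_off[i]], y_end = trace$y_deg[i_off[i]],
      h_amplitude = trace$x_deg[i_off[i]] - trace$x_deg[i_on[i]],
      amplitude = sqrt((trace$x_deg[i_off[i]] - trace$x_deg[i_on[i]])^2 +
                         (trace$y_deg[i_off[i]] - trace$y_deg[i_on[i]])^2),
      peak_velocity = max(speed[sel])
    )
  })
  out$latency <- out$onset - s1_onset
  out
}

find_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(start = starts[keep], end = ends[keep])
}

#' Extract display-change times from a photodiode trace
#'
#' The raw signal is reduced to a ternary code using four evenly spaced
#' boundary values spanning its range (inclusive of min and max): samples
#' below the second boundary are black (-1), between the second and third
#' gray (0), above the third white (+1). Event times are the first samples
#' where the ternary code changes.
#'
#' @param signal A `photodiode_trace` tibble (`time_s`, `level`) or a
#'   numeric vector (then `rate` is required).
#' @param rate Sampling rate (Hz) when `signal` is a bare vector.
#' @return Numeric vector of event times (s).
#' @export
ternarize_photodiode <- function(signal, rate = NULL) {
  if (is.numeric(signal)) {
    check_that(!is.null(rate), "`rate` required for a bare numeric signal")
    time_s <- (seq_along(signal) - 1) / rate
    level <- signal
  } else {
    time_s <- signal$time_s
    level <- signal$level
  }
  lo <- min(level)
  hi <- max(level)
  check_that(hi > lo, "degenerate photodiode signal: constant level")
  bounds <- seq(lo, hi, length.out = 4)
  tern <- ifelse(level < bounds[2], -1L, ifelse(level <= bounds[3], 0L, 1L))
  flips <- which(abs(diff(tern)) > 0) + 1L
  time_s[flips]
}

#' Per-condition saccade summaries
#'
#' Median latency and mean horizontal amplitude per group, after excluding
#' trials whose latency falls outside the inclusion window (0.15-0.50 s by
#' default).
#'
#' @param events Tibble with one detected saccade per trial: `latency`,
#'   `h_amplitude`, plus grouping columns.
#' @param ... Grouping columns (tidy-select), e.g. `condition`.
#' @param latency_bounds Inclusion window for latency (s).
#' @return A tibble per group: `n`, `n_excluded`, `median_latency`,
#'   `mean_h_amplitude`.
#' @export
saccade_summaries <- function(events, ..., latency_bounds = c(0.15, 0.50)) {
  grouped <- dplyr::group_by(events, ...)
  out <- dplyr::summarise(
    grouped,
    n = sum(.data$latency >= latency_bounds[1] &
              .data$latency <= latency_bounds[2]),
    n_excluded = dplyr::n() - .data$n,
    median_latency = median(
      .data$latency[.data$latency >= latency_bounds[1] &
                      .data$latency <= latency_bounds[2]]),
    mean_h_amplitude = mean(
      .data$h_amplitude[.data$latency >= latency_bounds[1] &
                          .data$latency <= latency_bounds[2]]),
    .groups = "drop"
  )
  check_that(all(out$n > 0), "a group is empty after latency exclusion")
  out
}
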