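#' Epoch container
#'
#' An `epoch_set` holds a trials x channels x time array plus alignment
#' metadata, the per-trial design rows, and a rejection log that accounts
#' for every dropped trial.
#'
#' @param data trials x channels x time numeric array.
#' @param times Time vector (s) relative to the alignment event.
#' @param rate Sampling rate (Hz).
#' @param alignment One of `"S1_onset"`, `"saccade_onset"`,
#'   `"saccade_offset"`.
#' @param trials Tibble with one row per trial (must include
#'   `trial_index`).
#' @param rejection_log Tibble (`trial_index`, `rule`, `detail`).
#' @return An object of class `epoch_set`.
#' @export
new_epoch_set <- function(data, times, rate,
                          alignment = c("S1_onset", "saccade_onset",
                                        "saccade_offset"),
                          trials = NULL, rejection_log = NULL) {
  alignment <- match.arg(alignment)
  check_that(length(dim(data)) == 3, "`data` must be a 3-D array")
  check_that(dim(data)[3] == length(times), "time vector length mismatch")
  trials <- trials %||% tibble::tibble(trial_index = seq_len(dim(data)[1]) - 1L)
  check_that(nrow(trials) == dim(data)[1], "trial metadata length mismatch")
  rejection_log <- rejection_log %||%
    tibble::tibble(trial_index = integer(0), rule = character(0),
                   detail = character(0))
  structure(list(data = data, times = times, rate = rate,
                 alignment = alignment, trials = trials,
                 rejection_log = rejection_log),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_set> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " samples at ", x$rate, " Hz, aligned to ", x$alignment,
      " (", nrow(x$rejection_log), " rejection(s) logged)\n", sep = "")
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

n_trials <- function(es) dim(es$data)[1]

# sample indices of the half-open window [w0, w1) on a time grid
window_index <- function(times, w0, w1) {
  eps <- 1e-9
  which(times >= w0 - eps & times < w1 - eps)
}

#' Cut epochs around per-trial events
#'
#' Samples are selected half-open, `[t_event + w0, t_event + w1)`, on the
#' recording grid; the sample at `t = 0` (the event) is always included.
#'
#' @param recordings List of `sensor_recording` objects (one per trial).
#' @param event_times Event time (s) per trial, on each recording's clock.
#' @param window Length-2 window (s), default `c(-0.5, 1.5)`.
#' @param trials Optional tibble of per-trial metadata.
#' @param alignment Alignment label stored in the result.
#' @return An `epoch_set`.
#' @export
cut_epochs <- function(recordings, event_times, window = c(-0.5, 1.5),
                       trials = NULL, alignment = "S1_onset") {
  check_that(length(recordings) == length(event_times),
             "one event time per recording required")
  check_that(window[2] > window[1], "empty epoch window")
  rate <- attr(recordings[[1]], "rate")
  o0 <- round(window[1] * rate)
  o1 <- round(window[2] * rate)
  times <- (o0:(o1 - 1)) / rate
  n_ch <- nrow(recordings[[1]])
  data <- array(NA_real_, c(length(recordings), n_ch, length(times)))
  for (i in seq_along(recordings)) {
    rec_t <- attr(recordings[[i]], "time")
    i_ev <- which.min(abs(rec_t - event_times[i]))
    idx <- i_ev + o0:(o1 - 1)
    check_that(idx[1] >= 1 && idx[length(idx)] <= ncol(recordings[[i]]),
               paste0("event in trial ", i, " too close to recording edge"))
    data[i, , ] <- recordings[[i]][, idx]
  }
  new_epoch_set(data, times, rate, alignment, trials)
}

#' Downsample an epoch set
#'
#' Anti-alias low-pass (zero-phase FIR at 80% of the new Nyquist) followed
#' by decimation with the phase chosen so the `t = 0` sample survives on
#' the new grid.
#'
#' @param es An `epoch_set`.
#' @param target Target rate (Hz); must divide the current rate.
#' @return The downsampled `epoch_set`.
#' @export
downsample_epochs <- function(es, target) {
  check_that(target > 0 && es$rate %% target == 0,
             "`target` must divide the sampling rate")
  q <- es$rate / target
  if (q == 1) return(es)
  i_t0 <- which.min(abs(es$times))
  keep <- which((seq_along(es$times) - i_t0) %% q == 0)
  d <- dim(es$data)
  # filter all trial-channel series in one pass (columns of a time x series
  # matrix), with reflection padding against filter edge transients
  b <- signal::fir1(63L, 0.8 / q)
  b <- b / sum(b)
  pad <- length(b)
  n <- d[3]
  check_that(n > pad, "epoch too short for the anti-alias filter")
  m <- matrix(aperm(es$data, c(3, 1, 2)), nrow = n)
  mp <- rbind(m[(pad + 1):2, , drop = FALSE], m,
              m[(n - 1):(n - pad), , drop = FALSE])
  mf <- stats::filter(mp, b, sides = 2)[pad + keep, , drop = FALSE]
  out <- aperm(array(as.numeric(mf), c(length(keep), d[1], d[2])),
               c(2, 3, 1))
  new_epoch_set(out, es$times[keep], target, es$alignment, es$trials,
                es$rejection_log)
}

#' Baseline-standardize epochs
#'
#' Per trial and channel, subtract the mean over the baseline window and
#' (in `"zscore"` mode) divide by the baseline SD, floored at `sd_floor`.
#' `"subtract"` mode (baseline correction only) is used for event-related
#' field averages.
#'
#' @param es An `epoch_set`.
#' @param baseline Length-2 half-open window (s), default `c(-0.2, 0)`.
#' @param mode `"zscore"` or `"subtract"`.
#' @param sd_floor Lower bound applied to the baseline SD.
#' @return The standardized `epoch_set`.
#' @export
standardize_to_baseline <- function(es, baseline = c(-0.2, 0),
                                    mode = c("zscore", "subtract"),
                                    sd_floor = 1e-8) {
  mode <- match.arg(mode)
  idx <- window_index(es$times, baseline[1], baseline[2])
  check_that(length(idx) > 0, "empty baseline window")
  d <- dim(es$data)
  base <- es$data[, , idx, drop = FALSE]
  mu <- apply(base, c(1, 2), mean)
  out <- es$data - array(rep(mu, d[3]), d)
  if (mode == "zscore") {
    sdv <- pmax(apply(base, c(1, 2), sd), sd_floor)
    out <- out / array(rep(sdv, d[3]), d)
  }
  new_epoch_set(out, es$times, es$rate, es$alignment, es$trials,
                es$rejection_log)
}

reject_trials <- function(es, log_new) {
  keep <- !(es$trials$trial_index %in% log_new$trial_index)
  new_epoch_set(es$data[keep, , , drop = FALSE], es$times, es$rate,
                es$alignment, es$trials[keep, ],
                dplyr::bind_rows(es$rejection_log, log_new))
}

#' Select valid saccade-condition epochs
#'
#' A trial is kept iff (1) exactly one saccade occurred between S1 onset
#' and S2 onset; (2) the saccade endpoint crossed the vertical screen
#' midline by at least 4 degrees in the saccade direction (leftward:
#' `x_end <= -4`), so the stimulus fully switched hemifields; (3) the
#' endpoint stayed above 2 degrees below the horizontal midline
#' (`y_end >= -2`), keeping the stimulus in the lower visual field; and
#' (4) saccade latency fell in `latency_bounds`. Every exclusion is logged
#' with its rule id.
#'
#' @param es An `epoch_set` aligned to S1 onset.
#' @param events Tibble of detected saccades with `trial_index`, `onset`
#'   (s relative to S1 onset), `x_end`, `y_end`, `latency`.
#' @param s2_onset S2 onset (s relative to S1 onset) per trial, recycled if
#'   length 1.
#' @param midline_margin Required midline crossing (degrees).
#' @param vertical_limit Lowest allowed endpoint y (degrees).
#' @param latency_bounds Saccade-latency inclusion window (s).
#' @return The filtered `epoch_set` with an updated rejection log.
#' @export
select_saccade_epochs <- function(es, events, s2_onset,
                                  midline_margin = 4,
                                  vertical_limit = -2,
                                  latency_bounds = c(0.15, 0.50)) {
  s2 <- rep_len(s2_onset, n_trials(es))
  logs <- list()
  for (i in seq_len(n_trials(es))) {
    ti <- es$trials$trial_index[i]
    ev <- events[events$trial_index == ti & events$onset > 0 &
                   events$onset < s2[i], , drop = FALSE]
    viol <- character(0)
    if (nrow(ev) != 1) {
      viol <- c(viol, paste0("one_saccade: ", nrow(ev), " saccades"))
    } else {
      if (ev$x_end > -midline_margin)
        viol <- c(viol, paste0("midline: x_end=", round(ev$x_end, 2)))
      if (ev$y_end < vertical_limit)
        viol <- c(viol, paste0("vertical: y_end=", round(ev$y_end, 2)))
      if (ev$latency < latency_bounds[1] || ev$latency > latency_bounds[2])
        viol <- c(viol, paste0("latency: ", round(ev$latency, 3), " s"))
    }
    if (length(viol) > 0) {
      logs[[length(logs) + 1]] <- tibble::tibble(
        trial_index = ti,
        rule = sub(":.*", "", viol),
        detail = sub("^[^:]+: ", "", viol)
      )
    }
  }
  log_new <- if (length(logs)) dplyr::bind_rows(logs) else
    tibble::tibble(trial_index = integer(0), rule = character(0),
                   detail = character(0))
  reject_trials(es, log_new)
}

#' Select valid fixation-condition epochs
#'
#' A trial is kept iff gaze stayed within `max_deviation` of the fixation
#' point for the whole epoch and no microsaccade with amplitude above
#' `max_microsaccade` occurred.
#'
#' @param es An `epoch_set` aligned to S1 onset.
#' @param traces Named (or positional) list of `eye_trace` objects, one per
#'   trial, on the S1-locked clock (`time_s = 0` at S1 onset).
#' @param microsaccades Tibble with `trial_index` and `amplitude` of
#'   microsaccades detected within the epoch.
#' @param fixation_points Two-column matrix (or length-2 vector) of
#'   fixation-point coordinates per trial.
#' @param max_deviation Allowed gaze distance from fixation (degrees).
#' @param max_microsaccade Largest tolerated microsaccade amplitude
#'   (degrees).
#' @return The filtered `epoch_set` with an updated rejection log.
#' @export
select_fixation_epochs <- function(es, traces, microsaccades,
                                   fixation_points,
                                   max_deviation = 2,
                                   max_microsaccade = 0.5) {
  check_that(length(traces) == n_trials(es), "one trace per trial required")
  if (is.null(dim(fixation_points))) {
    fixation_points <- matrix(fixation_points, n_trials(es), 2, byrow = TRUE)
  }
  w0 <- es$times[1]
  w1 <- es$times[length(es$times)] + 1 / es$rate
  logs <- list()
  for (i in seq_len(n_trials(es))) {
    ti <- es$trials$trial_index[i]
    tr <- traces[[i]]
    sel <- tr$time_s >= w0 - 1e-9 & tr$time_s < w1 - 1e-9
    check_that(any(sel), paste0("trace for trial ", ti,
                                " does not cover the epoch"))
    dist <- sqrt((tr$x_deg[sel] - fixation_points[i, 1])^2 +
                   (tr$y_deg[sel] - fixation_points[i, 2])^2)
    viol <- character(0)
    if (max(dist) > max_deviation)
      viol <- c(viol, paste0("gaze_bounds: max ", round(max(dist), 2), " deg"))
    ms <- microsaccades[microsaccades$trial_index == ti, , drop = FALSE]
    if (nrow(ms) > 0 && any(ms$amplitude > max_microsaccade))
      viol <- c(viol, paste0("microsaccade: ",
                             round(max(ms$amplitude), 2), " deg"))
    if (length(viol) > 0) {
      logs[[length(logs) + 1]] <- tibble::tibble(
        trial_index = ti, rule = sub(":.*", "", viol),
        detail = sub("^[^:]+: ", "", viol))
    }
  }
  log_new <- if (length(logs)) dplyr::bind_rows(logs) else
    tibble::tibble(trial_index = integer(0), rule = character(0),
                   detail = character(0))
  reject_trials(es, log_new)
}

#' Re-align epochs to a new per-trial event
#'
#' Cuts a new window around a per-trial event (typically saccade offset)
#' inside the existing epochs. Trials whose new window does not fit are
#' rejected and logged. An optional baseline is applied on the new grid.
#'
#' @param es An `epoch_set`.
#' @param new_events Event time per trial (s, relative to the current
#'   alignment zero).
#' @param window New half-open window (s), default `c(-0.6, 0.4)`.
#' @param baseline Baseline window on the new grid, default
#'   `c(-0.1, -0.004)`; `NULL` skips re-baselining (use this when epochs
#'   were already standardized on the original alignment).
#' @param baseline_mode Passed to [standardize_to_baseline()].
#' @param alignment New alignment label.
#' @return The re-aligned `epoch_set`.
#' @export
realign_epochs <- function(es, new_events, window = c(-0.6, 0.4),
                           baseline = c(-0.1, -0.004),
                           baseline_mode = "zscore",
                           alignment = "saccade_offset") {
  check_that(length(new_events) == n_trials(es),
             "one event per trial required")
  o0 <- round(window[1] * es$rate)
  o1 <- round(window[2] * es$rate)
  times <- (o0:(o1 - 1)) / es$rate
  i_zero <- which.min(abs(es$times))
  keep <- logical(n_trials(es))
  idx_list <- vector("list", n_trials(es))
  for (i in seq_len(n_trials(es))) {
    shift <- round(new_events[i] * es$rate)
    idx <- i_zero + shift + o0:(o1 - 1)
    ok <- !is.na(new_events[i]) && idx[1] >= 1 &&
      idx[length(idx)] <= length(es$times)
    keep[i] <- ok
    if (ok) idx_list[[i]] <- idx
  }
  log_new <- tibble::tibble(
    trial_index = es$trials$trial_index[!keep],
    rule = "margin",
    detail = "realignment window outside epoch"
  )
  d <- dim(es$data)
  out <- array(NA_real_, c(sum(keep), d[2], length(times)))
  j <- 0
  for (i in which(keep)) {
    j <- j + 1
    out[j, , ] <- es$data[i, , idx_list[[i]]]
  }
  res <- new_epoch_set(out, times, es$rate, alignment, es$trials[keep, ],
                       dplyr::bind_rows(es$rejection_log, log_new))
  if (!is.null(baseline)) {
    res <- standardize_to_baseline(res, baseline, mode = baseline_mode)
  }
  res
}

#' Flag epochs with extreme amplitudes
#'
#' A threshold stand-in for interactive artifact inspection: a trial is
#' flagged when any sample's magnitude exceeds `k` robust SDs (median
#' absolute deviation scaled to the normal) of the epoch set. Disabled by
#' default in the pipeline, since clean synthetic data carry no
#' artifacts.
#'
#' @param es An `epoch_set`.
#' @param k Threshold in robust SDs (default 8).
#' @return The filtered `epoch_set`; flagged trials are logged under rule
#'   `"artifact"`.
#' @export
reject_artifact_epochs <- function(es, k = 8) {
  rsd <- stats::mad(es$data)
  check_that(rsd > 0, "degenerate epoch set: zero spread")
  peak <- apply(abs(es$data), 1, max)
  bad <- peak > k * rsd
  log_new <- tibble::tibble(
    trial_index = es$trials$trial_index[bad],
    rule = "artifact",
    detail = paste0("peak ", round(peak[bad], 2), " > ", k, " robust SD")
  )
  reject_trials(es, log_new)
}
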