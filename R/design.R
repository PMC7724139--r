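#' Scene geometry of the saccade/fixation display
#'
#' Screen coordinates are in degrees of visual angle, origin at the screen
#' center, x positive rightward, y positive upward. Two fixation points sit
#' 7 degrees left and right of center; the grating is centered on the vertical
#' meridian, 6 degrees below the horizontal meridian. The required saccade
#' (right fixation point to left fixation point) therefore spans 14 degrees.
#'
#' @param fixation_x Horizontal eccentricity of the fixation points (degrees).
#' @param stimulus_center Numeric length-2, stimulus center (degrees).
#' @param stimulus_diameter Stimulus diameter (degrees).
#' @return A list of class `scene_geometry`.
#' @export
#' @examples
#' scene_geometry()
scene_geometry <- function(fixation_x = 7,
                           stimulus_center = c(0, -6),
                           stimulus_diameter = 8) {
  check_that(fixation_x > 0, "`fixation_x` must be positive")
  g <- list(
    fixation_right = c(fixation_x, 0),
    fixation_left = c(-fixation_x, 0),
    stimulus_center = stimulus_center,
    stimulus_diameter = stimulus_diameter,
    required_saccade_amplitude = 2 * fixation_x
  )
  structure(g, class = "scene_geometry")
}

sf_levels <- c(low = 0.33, high = 1.33)

#' Build a factorial trial design
#'
#' One saccade block crosses spatial frequency (low 0.33, high 1.33
#' cycles/degree, or none for the no-stimulus trials), base orientation
#' (-30/+30 degrees), grating phase (0/pi) and change presence, each cell
#' repeated twice: 48 trials. One fixation block crosses the two stimulus
#' spatial frequencies with orientation, phase, change and fixation side:
#' 32 trials. Trial order is shuffled independently within each block.
#'
#' @param n_saccade_blocks,n_fixation_blocks Number of blocks of each type.
#' @param seed Integer seed controlling the within-block shuffles.
#' @return A tibble with one row per trial: `condition` (Sac-LVF, Sac-noVF,
#'   Fix-LVF or Fix-RVF), `spatial_frequency` (low/high/none), `sf_cpd`
#'   (cycles per degree, `NA` for no-stimulus trials), `base_orientation`,
#'   `phase`, `change`, `fixation_side`, `block_type`, `block_index` and
#'   `trial_index` (0-based within the session).
#' @export
#' @examples
#' dplyr::count(build_design(13, 0, seed = 1), condition)
build_design <- function(n_saccade_blocks, n_fixation_blocks, seed = 1L) {
  check_that(is_count(n_saccade_blocks) && is_count(n_fixation_blocks),
             "block counts must be non-negative integers")

  sac_cells <- tidyr::expand_grid(
    spatial_frequency = c("low", "high", "none"),
    base_orientation = c(-30, 30),
    phase = c(0, pi),
    change = c(TRUE, FALSE),
    repetition = 1:2
  )
  sac_cells$condition <- ifelse(sac_cells$spatial_frequency == "none",
                                "Sac-noVF", "Sac-LVF")
  sac_cells$fixation_side <- "right" # saccade trials start at the right point

  fix_cells <- tidyr::expand_grid(
    spatial_frequency = c("low", "high"),
    base_orientation = c(-30, 30),
    phase = c(0, pi),
    change = c(TRUE, FALSE),
    fixation_side = c("left", "right")
  )
  # stimulus is at screen center: fixating right puts it in the left hemifield
  fix_cells$condition <- ifelse(fix_cells$fixation_side == "right",
                                "Fix-LVF", "Fix-RVF")
  fix_cells$repetition <- 1L

  one_block <- function(cells, type, index, block_seed) {
    cells <- cells[with_seed(block_seed, sample.int(nrow(cells))), ]
    cells$block_type <- type
    cells$block_index <- index
    cells
  }

  blocks <- c(
    purrr::map(seq_len(n_saccade_blocks),
               ~ one_block(sac_cells, "saccade", .x, derive_seed(seed, 1, .x))),
    purrr::map(seq_len(n_fixation_blocks),
               ~ one_block(fix_cells, "fixation", .x, derive_seed(seed, 2, .x)))
  )
  if (length(blocks) == 0) {
    out <- sac_cells[0, ]
    out$block_type <- character(0)
    out$block_index <- integer(0)
  } else {
    out <- dplyr::bind_rows(blocks)
  }
  out$sf_cpd <- unname(sf_levels[out$spatial_frequency])
  out$trial_index <- seq_len(nrow(out)) - 1L
  tibble::as_tibble(dplyr::select(
    out, "trial_index", "block_type", "block_index", "condition",
    "spatial_frequency", "sf_cpd", "base_orientation", "phase", "change",
    "fixation_side"
  ))
}

#' Default timing distribution settings
#'
#' @param saccade_latency_median Median saccade latency (s).
#' @param saccade_latency_sdlog Log-scale spread of the (lognormal) latency
#'   distribution; 0 collapses every draw onto the median.
#' @param latency_bounds Truncation bounds for saccade latency (s).
#' @param blank_mean,blank_sd Fixation-trial blank duration moments (s);
#'   draws are truncated to `blank_bounds` and quantized to the display
#'   refresh (`frame_rate`).
#' @param blank_bounds Truncation bounds for the blank duration (s).
#' @param frame_rate Display refresh rate (Hz) used for quantization.
#' @param main_sequence `c(intercept_s, slope_s_per_deg)` mapping saccade
#'   amplitude to duration; the default maps 14 degrees to 62 ms.
#' @param initial_fixation Range of the initial fixation period (s).
#' @param s1_duration_range S1 duration range for fixation trials (s).
#' @return A list of class `timing_params`.
#' @export
timing_params <- function(saccade_latency_median = 0.226,
                          saccade_latency_sdlog = 0.35,
                          latency_bounds = c(0.10, 1.0),
                          blank_mean = 0.055,
                          blank_sd = 0.006,
                          blank_bounds = c(0.042, 0.075),
                          frame_rate = 120,
                          main_sequence = c(0.027, 0.0025),
                          initial_fixation = c(1.0, 1.5),
                          s1_duration_range = c(0.5, 0.7)) {
  check_that(latency_bounds[1] < latency_bounds[2] &&
               blank_bounds[1] < blank_bounds[2],
             "truncation bounds must be increasing")
  structure(
    list(
      saccade_latency_median = saccade_latency_median,
      saccade_latency_sdlog = saccade_latency_sdlog,
      latency_bounds = latency_bounds,
      blank_mean = blank_mean, blank_sd = blank_sd,
      blank_bounds = blank_bounds, frame_rate = frame_rate,
      main_sequence = main_sequence,
      initial_fixation = initial_fixation,
      s1_duration_range = s1_duration_range
    ),
    class = "timing_params"
  )
}

rtrunc <- function(n, draw, lower, upper) {
  out <- draw(n)
  bad <- which(out < lower | out > upper)
  guard <- 0
  while (length(bad) > 0 && guard < 1000) {
    out[bad] <- draw(length(bad))
    bad <- which(out < lower | out > upper)
    guard <- guard + 1
  }
  pmin(pmax(out, lower), upper)
}

#' Sample per-trial event timing
#'
#' Fixation trials: S1 stays on for a uniform 0.5-0.7 s, is blanked for a
#' normally distributed 55 +/- 6 ms (truncated to 42-75 ms and quantized to
#' the 120 Hz display refresh), then S2 follows. Saccade trials: saccade
#' latency is drawn from a truncated lognormal (right-skewed, configurable
#' median), saccade duration follows the main-sequence rule
#' `duration = a + b * amplitude`, and S2 appears during the saccade.
#'
#' @param trial One-row tibble (or list) with at least `condition`.
#' @param params A [timing_params()] list.
#' @param saccade_amplitude Planned saccade amplitude (degrees) used by the
#'   main-sequence rule.
#' @param seed Integer seed.
#' @return A one-row tibble: `s1_onset`, `s1_duration`, `blank_duration`,
#'   `saccade_latency`, `saccade_duration`, `s2_onset`, `s2_duration`
#'   (seconds; `NA` where not applicable).
#' @export
sample_trial_timing <- function(trial, params = timing_params(),
                                saccade_amplitude = 14, seed = 1L) {
  cond <- trial$condition[[1]]
  with_seed(seed, {
    s1_onset <- runif(1, params$initial_fixation[1], params$initial_fixation[2])
    if (cond %in% c("Fix-LVF", "Fix-RVF")) {
      s1_dur <- runif(1, params$s1_duration_range[1], params$s1_duration_range[2])
      blank <- rtrunc(1, function(n) rnorm(n, params$blank_mean, params$blank_sd),
                      params$blank_bounds[1], params$blank_bounds[2])
      blank <- round(blank * params$frame_rate) / params$frame_rate
      blank <- pmin(pmax(blank, ceiling(params$blank_bounds[1] * params$frame_rate) /
                           params$frame_rate),
                    floor(params$blank_bounds[2] * params$frame_rate) /
                      params$frame_rate)
      tibble::tibble(
        s1_onset = s1_onset, s1_duration = s1_dur, blank_duration = blank,
        saccade_latency = NA_real_, saccade_duration = NA_real_,
        s2_onset = s1_onset + s1_dur + blank, s2_duration = s1_dur
      )
    } else {
      lat <- if (params$saccade_latency_sdlog <= 0) {
        params$saccade_latency_median
      } else {
        rtrunc(1, function(n) rlnorm(n, log(params$saccade_latency_median),
                                     params$saccade_latency_sdlog),
               params$latency_bounds[1], params$latency_bounds[2])
      }
      dur <- params$main_sequence[1] + params$main_sequence[2] * saccade_amplitude
      s1_dur <- lat + 0.020 # stimulus swapped once gaze leaves the fixation zone
      tibble::tibble(
        s1_onset = s1_onset, s1_duration = s1_dur, blank_duration = NA_real_,
        saccade_latency = lat, saccade_duration = dur,
        s2_onset = s1_onset + s1_dur, s2_duration = s1_dur
      )
    }
  })
}
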