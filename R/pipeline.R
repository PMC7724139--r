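#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis with defaults that
#' reproduce the printed analysis settings (250 Hz analysis rate, 8 ms
#' searchlight radius, 10 folds, 20 ms diagonal width, 10^4 permutations,
#' alpha 0.05, the S1-locked [-0.5, 1.5) epoch with [-0.2, 0) baseline and
#' the offset-locked [-0.6, 0.4) window) at a desk-scale array and trial
#' count. Use [validate_config()] to normalize and cross-check a config.
#'
#' @param n_subjects Number of simulated subjects.
#' @param n_saccade_blocks,n_fixation_blocks Blocks per subject.
#' @param n_sites Sensor sites (2 gradiometers each).
#' @param t_persist Planted presaccadic persistence (s).
#' @param amplitude,noise_sd Generator signal and noise scales.
#' @param rate_sensor,rate_analysis Synthesis and analysis rates (Hz).
#' @param searchlight_radius_s Searchlight radius (s).
#' @param k_folds Cross-validation folds.
#' @param diagonal_width Diagonal band width (s).
#' @param n_perm Sign-flip permutations.
#' @param alpha Two-tailed significance level.
#' @param tfce_e,tfce_h TFCE exponents.
#' @param epoch_window,baseline,realign_window,realign_baseline Analysis
#'   windows (s).
#' @param full_chain Use the full measurement chain
#'   ([simulate_session()]: eye traces, photodiode, detection, exclusion
#'   rules) rather than the lean generator path.
#' @param seed Master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_subjects = 4,
                       n_saccade_blocks = 4,
                       n_fixation_blocks = 7,
                       n_sites = 32,
                       t_persist = 0.2,
                       amplitude = 3,
                       noise_sd = 1,
                       rate_sensor = 500,
                       rate_analysis = 250,
                       searchlight_radius_s = 0.008,
                       k_folds = 10,
                       diagonal_width = 0.020,
                       n_perm = 1e4,
                       alpha = 0.05,
                       tfce_e = 0.5,
                       tfce_h = 2,
                       epoch_window = c(-0.5, 1.5),
                       baseline = c(-0.2, 0),
                       realign_window = c(-0.6, 0.4),
                       realign_baseline = c(-0.1, -0.004),
                       full_chain = TRUE,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  validate_config(cfg)
}

#' Validate and normalize a run configuration
#'
#' Fills defaults for missing fields and checks cross-field constraints:
#' the analysis rate must divide the sensor rate, the searchlight radius
#' must be a whole number of samples at the analysis rate, and baselines
#' must nest inside their windows. All violations are reported together.
#'
#' @param config A `run_config`, or a plain named list of overrides.
#' @return The normalized `run_config`.
#' @export
validate_config <- function(config = list()) {
  defaults <- formals(run_config)
  defaults <- lapply(defaults[setdiff(names(defaults), "")], eval)
  cfg <- utils::modifyList(defaults, unclass(config))
  problems <- character(0)
  if (cfg$rate_sensor %% cfg$rate_analysis != 0) {
    problems <- c(problems, paste0(
      "rate_analysis (", cfg$rate_analysis,
      ") does not divide rate_sensor (", cfg$rate_sensor, ")"))
  }
  r <- cfg$searchlight_radius_s * cfg$rate_analysis
  if (abs(r - round(r)) > 1e-9) {
    problems <- c(problems, paste0(
      "searchlight_radius_s (", cfg$searchlight_radius_s,
      ") is not a whole number of samples at rate_analysis (",
      cfg$rate_analysis, ")"))
  }
  if (cfg$baseline[1] < cfg$epoch_window[1] ||
      cfg$baseline[2] > cfg$epoch_window[2]) {
    problems <- c(problems, "baseline outside epoch_window")
  }
  if (cfg$realign_baseline[1] < cfg$realign_window[1] ||
      cfg$realign_baseline[2] > cfg$realign_window[2]) {
    problems <- c(problems, "realign_baseline outside realign_window")
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) {
    problems <- c(problems, "alpha must lie in (0, 1)")
  }
  if (cfg$n_perm < 1) problems <- c(problems, "n_perm must be >= 1")
  if (cfg$n_subjects < 2) {
    problems <- c(problems,
                  "n_subjects must be >= 2 (group statistics need them)")
  }
  check_that(length(problems) == 0,
             paste0("invalid configuration:\n  - ",
                    paste(problems, collapse = "\n  - ")))
  class(cfg) <- "run_config"
  cfg
}

#' Run the end-to-end pipeline
#'
#' For every simulated subject: generate the session, build
#' analysis-ready epochs for the four conditions, run within-condition
#' cross-validated decoding, the four cross-condition temporal
#' generalizations (train Fix-LVF / Fix-RVF by test Sac-LVF aligned to S1
#' onset / saccade offset), the three diagonal readouts, the
#' spatial-invariance transfer between the two fixation conditions, the
#' presaccadic-updating test (saccade-onset-aligned test data), the
#' no-stimulus bias analysis and the behavioral summaries. Subject
#' log-odds diagonals then enter group-level TFCE sign-flip permutation
#' tests.
#'
#' @param config A [run_config()].
#' @return A `results_bundle`: list with `subjects` (per-subject results),
#'   `group` (cluster results per diagonal), `behavior`, `saccades`, and
#'   `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  cfg <- validate_config(config)
  radius <- radius_samples(cfg$searchlight_radius_s, cfg$rate_analysis)
  array <- make_sensor_array(cfg$n_sites)
  subjects <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    subjects[[s]] <- run_subject(cfg, array, radius,
                                 seed = derive_seed(cfg$seed, 500, s))
  }
  names(subjects) <- paste0("S", seq_len(cfg$n_subjects))

  diag_names <- names(subjects[[1]]$diagonals)
  group <- list()
  for (dn in diag_names) {
    mat <- t(vapply(subjects, function(su) {
      tr <- su$diagonals[[dn]]
      accuracy_to_log_odds(tr$value, attr(tr, "n_test"))
    }, numeric(nrow(subjects[[1]]$diagonals[[dn]]))))
    adj <- sensor_time_adjacency(1, ncol(mat), time_radius = radius)
    group[[dn]] <- list(
      times = subjects[[1]]$diagonals[[dn]]$time,
      cluster = sign_flip_permutation(
        mat, adj, n_perm = cfg$n_perm, alpha = cfg$alpha,
        E = cfg$tfce_e, H = cfg$tfce_h,
        seed = derive_seed(cfg$seed, 600, match(dn, diag_names)))
    )
  }

  behavior <- dplyr::bind_rows(
    purrr::imap(subjects, ~ dplyr::mutate(.x$behavior, subject = .y)))
  saccades <- dplyr::bind_rows(
    purrr::imap(subjects, ~ dplyr::mutate(.x$saccades, subject = .y)))
  structure(list(subjects = subjects, group = group, behavior = behavior,
                 saccades = saccades, config = cfg),
            class = "results_bundle")
}

run_subject <- function(cfg, array, radius, seed) {
  model <- pattern_model(array, t_persist = cfg$t_persist,
                         amplitude = cfg$amplitude, noise_sd = cfg$noise_sd,
                         seed = derive_seed(seed, 1))
  if (cfg$full_chain) {
    design <- build_design(cfg$n_saccade_blocks, cfg$n_fixation_blocks,
                           seed = derive_seed(seed, 2))
    session <- simulate_session(design, model,
                                rate_sensor = cfg$rate_sensor,
                                epoch_window = cfg$epoch_window,
                                seed = derive_seed(seed, 3))
    eps <- list(
      fix_lvf = condition_epochs(session, "Fix-LVF", cfg$rate_analysis,
                                 cfg$baseline),
      fix_rvf = condition_epochs(session, "Fix-RVF", cfg$rate_analysis,
                                 cfg$baseline),
      sac_s1 = condition_epochs(session, "Sac-LVF", cfg$rate_analysis,
                                cfg$baseline),
      sac_off = condition_epochs(session, "Sac-LVF", cfg$rate_analysis,
                                 cfg$baseline, align = "saccade_offset",
                                 realign_window = cfg$realign_window),
      sac_on = condition_epochs(session, "Sac-LVF", cfg$rate_analysis,
                                cfg$baseline, align = "saccade_onset",
                                realign_window = cfg$realign_window),
      novf_off = condition_epochs(session, "Sac-noVF", cfg$rate_analysis,
                                  cfg$baseline, align = "saccade_offset",
                                  realign_window = cfg$realign_window)
    )
    lat <- eps$sac_s1$trials$det_latency
    dur <- eps$sac_s1$trials$det_duration
    responses <- simulate_responses(session$trials,
                                    seed = derive_seed(seed, 4))
    sac_metrics <- dplyr::filter(
      session$trials, .data$block_type == "saccade",
      !is.na(.data$det_latency)) |>
      dplyr::transmute(condition = .data$condition,
                       spatial_frequency = .data$spatial_frequency,
                       latency = .data$det_latency,
                       h_amplitude = .data$det_h_amplitude)
  } else {
    n_tr <- cfg$n_saccade_blocks * 32L # stimulus trials per saccade block
    n_fix <- cfg$n_fixation_blocks * 16L
    sim <- function(cond, n, align, k) {
      simulate_decoding_set(cond, n, model, align = align,
                            rate_sensor = cfg$rate_sensor,
                            rate = cfg$rate_analysis,
                            baseline = cfg$baseline,
                            realign_window = cfg$realign_window,
                            seed = derive_seed(seed, 10 + k))
    }
    eps <- list(
      fix_lvf = sim("Fix-LVF", n_fix, "S1_onset", 1),
      fix_rvf = sim("Fix-RVF", n_fix, "S1_onset", 2),
      sac_s1 = sim("Sac-LVF", n_tr, "S1_onset", 3),
      sac_off = sim("Sac-LVF", n_tr, "saccade_offset", 3),
      sac_on = sim("Sac-LVF", n_tr, "saccade_onset", 3),
      novf_off = sim("Sac-noVF", ceiling(n_tr / 2), "saccade_offset", 4)
    )
    lat <- eps$sac_s1$trials$saccade_latency
    dur <- eps$sac_s1$trials$saccade_duration
    responses <- NULL
    sac_metrics <- NULL
  }
  label <- if ("spatial_frequency" %in% names(eps$fix_lvf$trials) &&
               cfg$full_chain) "spatial_frequency" else "label"

  within <- list(
    fix_lvf = crossval_timecourse(eps$fix_lvf, label, k = cfg$k_folds,
                                  radius = radius,
                                  seed = derive_seed(seed, 20)),
    fix_rvf = crossval_timecourse(eps$fix_rvf, label, k = cfg$k_folds,
                                  radius = radius,
                                  seed = derive_seed(seed, 21))
  )

  xc <- list()
  for (tr_name in c("fix_lvf", "fix_rvf")) {
    for (te in c("sac_s1", "sac_off")) {
      xc[[paste(tr_name, te, sep = "_x_")]] <- cross_condition_matrix(
        eps[[tr_name]], eps[[te]], label, radius = radius,
        seed = derive_seed(seed, 30))
    }
  }

  med_lat <- median(lat, na.rm = TRUE)
  med_dur <- median(dur, na.rm = TRUE)
  shift <- offset_diagonal_origin(med_lat, med_dur)
  diagonals <- list(
    onset = extract_diagonal_band(xc$fix_lvf_x_sac_s1, 0, 0,
                                  cfg$diagonal_width),
    offset = extract_diagonal_band(xc$fix_lvf_x_sac_off, 0, 0,
                                   cfg$diagonal_width),
    offset_shifted = extract_diagonal_band(xc$fix_lvf_x_sac_off,
                                           train_origin = shift,
                                           test_origin = 0,
                                           width = cfg$diagonal_width),
    offset_post = extract_diagonal_band(xc$fix_rvf_x_sac_off, 0, 0,
                                        cfg$diagonal_width)
  )

  invariance <- list(
    lvf_on_rvf = cross_condition_matrix(eps$fix_lvf, eps$fix_rvf, label,
                                        radius = radius,
                                        seed = derive_seed(seed, 40)),
    rvf_on_lvf = cross_condition_matrix(eps$fix_rvf, eps$fix_lvf, label,
                                        radius = radius,
                                        seed = derive_seed(seed, 41))
  )
  presaccadic <- list(
    lvf = cross_condition_matrix(eps$fix_lvf, eps$sac_on, label,
                                 radius = radius,
                                 seed = derive_seed(seed, 50)),
    rvf = cross_condition_matrix(eps$fix_rvf, eps$sac_on, label,
                                 radius = radius,
                                 seed = derive_seed(seed, 51))
  )
  bias <- classify_bias(eps$fix_lvf, eps$novf_off, label,
                        radius = radius, seed = derive_seed(seed, 60))

  behavior <- if (!is.null(responses)) {
    summarize_behavior(responses)
  } else {
    tibble::tibble()
  }
  sac_sum <- if (!is.null(sac_metrics) && nrow(sac_metrics) > 0) {
    saccade_summaries(sac_metrics, .data$condition)
  } else {
    tibble::tibble(median_latency = med_lat)
  }

  list(epoch_counts = purrr::map_int(eps, n_trials),
       within = within, generalizations = xc, diagonals = diagonals,
       invariance = invariance, presaccadic = presaccadic, bias = bias,
       behavior = behavior, saccades = sac_sum,
       median_latency = med_lat, median_duration = med_dur,
       n_test_sac = n_trials(eps$sac_off), seed = seed)
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("<results_bundle> ", length(x$subjects), " subject(s); group tests: ",
      paste(names(x$group), collapse = ", "), "\n", sep = "")
  invisible(x)
}
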