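#' Signal-detection sensitivity (d-prime)
#'
#' `D' = qnorm(HR) - qnorm(FAR)` with Laplace-style rate correction
#' `HR = (n_hit + 0.5) / (n_hit + n_miss + 1)` (and likewise for the
#' false-alarm rate), which keeps perfect scores finite.
#'
#' @param n_hit,n_miss,n_fa,n_cr Trial counts: hits and misses on change
#'   trials, false alarms and correct rejections on no-change trials.
#' @return D-prime value.
#' @export
#' @examples
#' dprime(18, 2, 2, 18)
dprime <- function(n_hit, n_miss, n_fa, n_cr) {
  check_that(all(n_hit + n_miss > 0) && all(n_fa + n_cr > 0),
             "both trial-type margins must be non-empty")
  hr <- (n_hit + 0.5) / (n_hit + n_miss + 1)
  far <- (n_fa + 0.5) / (n_fa + n_cr + 1)
  qnorm(hr) - qnorm(far)
}

#' Simulate change-detection responses
#'
#' A simple equal-variance signal-detection observer: on each
#' stimulus-present trial the internal change evidence is
#' `N(d' * change, 1)` and the observer answers "different" when it
#' exceeds the criterion. Feeds the d-prime summaries with configurable
#' ground truth.
#'
#' @param design Trial tibble from [build_design()] (no-stimulus trials
#'   get no response).
#' @param sensitivity Named vector of true d' per condition (unmatched
#'   conditions fall back to the mean), or a single value.
#' @param criterion Decision criterion.
#' @param seed Integer seed.
#' @return The design with `response` ("same"/"different", `NA` for
#'   no-stimulus trials) and `correct` columns.
#' @export
simulate_responses <- function(design,
                               sensitivity = c("Sac-LVF" = 2.8,
                                               "Fix-LVF" = 3.5,
                                               "Fix-RVF" = 3.5),
                               criterion = NULL, seed = 1L) {
  task <- design$condition != "Sac-noVF"
  d_true <- if (length(sensitivity) == 1) rep(sensitivity, nrow(design))
            else {
              v <- sensitivity[as.character(design$condition)]
              v[is.na(v)] <- mean(sensitivity)
              v
            }
  criterion <- criterion %||% (d_true / 2)
  evidence <- with_seed(seed, rnorm(nrow(design), d_true * design$change, 1))
  resp <- ifelse(evidence > criterion, "different", "same")
  resp[!task] <- NA_character_
  out <- design
  out$response <- resp
  out$correct <- (out$response == "different") == out$change
  out
}

#' Behavioral and oculomotor summaries
#'
#' Per condition (and spatial frequency) d-prime from the response table,
#' joined with median saccade latency and mean horizontal amplitude where
#' saccade metrics are supplied; across-subject mean and SEM when a
#' `subject` column is present.
#'
#' @param responses Response tibble (see [simulate_responses()]): needs
#'   `condition`, `spatial_frequency`, `change`, `response`, optionally
#'   `subject`.
#' @param saccade_metrics Optional per-trial saccade tibble with
#'   `condition`, `spatial_frequency`, `latency`, `h_amplitude` (and
#'   `subject`), filtered and summarized via [saccade_summaries()].
#' @param latency_bounds Latency inclusion window (s) for the saccade
#'   summaries.
#' @return A tibble per group with `dprime`, `n_change`, `n_nochange`, and
#'   (when available) `median_latency`, `mean_h_amplitude`; with multiple
#'   subjects, `mean`/`sem` columns across subjects.
#' @export
summarize_behavior <- function(responses, saccade_metrics = NULL,
                               latency_bounds = c(0.15, 0.50)) {
  has_subj <- "subject" %in% names(responses)
  resp <- dplyr::filter(responses, !is.na(.data$response))
  check_that(nrow(resp) > 0, "no scoreable responses")
  grp <- c(if (has_subj) "subject", "condition", "spatial_frequency")
  tab <- dplyr::summarise(
    dplyr::group_by(resp, dplyr::across(dplyr::all_of(grp))),
    n_change = sum(.data$change),
    n_nochange = sum(!.data$change),
    dprime = dprime(
      sum(.data$change & .data$response == "different"),
      sum(.data$change & .data$response == "same"),
      sum(!.data$change & .data$response == "different"),
      sum(!.data$change & .data$response == "same")),
    .groups = "drop"
  )
  if (!is.null(saccade_metrics)) {
    sac_grp <- intersect(grp, names(saccade_metrics))
    sac <- saccade_summaries(
      saccade_metrics,
      dplyr::across(dplyr::all_of(sac_grp)),
      latency_bounds = latency_bounds
    )
    tab <- dplyr::left_join(tab, sac, by = sac_grp)
  }
  if (has_subj) {
    num <- setdiff(names(tab)[vapply(tab, is.numeric, logical(1))],
                   c("subject"))
    across_grp <- setdiff(grp, "subject")
    tab <- dplyr::summarise(
      dplyr::group_by(tab, dplyr::across(dplyr::all_of(across_grp))),
      dplyr::across(dplyr::all_of(num),
                    list(mean = mean,
                         sem = ~ sd(.x) / sqrt(dplyr::n()))),
      n_subjects = dplyr::n(),
      .groups = "drop"
    )
  }
  tab
}
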