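#' Evoked-pattern forward model for the synthetic generator
#'
#' Each (spatial frequency, stimulated hemifield) pair gets a fixed unit-norm
#' sensor topography whose spatial energy is concentrated over the hemisphere
#' contralateral to the stimulus. A stimulus (or the postsaccadic refixation
#' of one) drives its topography with a temporal envelope that is zero until
#' `onset_latency` after the event, rises to a transient peak about 30 ms
#' later (70 ms after the event), sustains at `plateau` while the source is
#' active, and ramps off after the source ends. On saccade trials the
#' presaccadic pattern keeps its source active until `t_persist` after
#' saccade offset (the handoff), while the postsaccadic pattern starts
#' `onset_latency` after saccade offset. A spatially broad, SF-independent
#' saccade-locked component is added on saccade trials, and an optional
#' artifact aligned with a chosen topography can be injected to probe
#' classifier bias.
#'
#' @param array A [make_sensor_array()] object.
#' @param onset_latency Response latency after a visual event (s).
#' @param t_persist Persistence of the presaccadic pattern after saccade
#'   offset (s).
#' @param amplitude Evoked amplitude in units of per-channel noise SD.
#' @param noise_sd Per-channel noise SD.
#' @param noise_alpha Spectral exponent of the 1/f^alpha noise power.
#' @param plateau Sustained envelope level relative to the transient peak.
#' @param rise,fall Envelope on/off ramp widths (s).
#' @param transient_peak Time-to-peak of the onset transient after the
#'   envelope starts (s).
#' @param saccade_gain Amplitude of the SF-independent saccade-locked
#'   component, relative to `amplitude`.
#' @param artifact_gain Amplitude of the optional saccade-onset artifact
#'   (0 disables it).
#' @param artifact_pattern Which topography the artifact projects onto
#'   (`"saccade"`, or e.g. `"high_RVF"` for an adversarial bias probe).
#' @param seed Seed fixing the topographies.
#' @return A list of class `pattern_model`.
#' @export
pattern_model <- function(array,
                          onset_latency = 0.040,
                          t_persist = 0.200,
                          amplitude = 3,
                          noise_sd = 1,
                          noise_alpha = 1,
                          plateau = 0.7,
                          rise = 0.020,
                          fall = 0.020,
                          transient_peak = 0.030,
                          saccade_gain = 0.8,
                          artifact_gain = 0,
                          artifact_pattern = "saccade",
                          seed = 1L) {
  check_that(inherits(array, "sensor_array"), "`array` must be a sensor_array")
  check_that(t_persist >= 0 && onset_latency >= 0,
             "latencies must be non-negative")
  centers <- list(
    low_LVF = c(0.5, -0.3), high_LVF = c(0.5, -0.3),   # LVF -> right sensors
    low_RVF = c(-0.5, -0.3), high_RVF = c(-0.5, -0.3), # RVF -> left sensors
    saccade = c(0, 0.2)
  )
  widths <- c(low_LVF = 0.35, high_LVF = 0.35, low_RVF = 0.35,
              high_RVF = 0.35, saccade = 0.9)
  topos <- purrr::imap(centers, function(ctr, nm) {
    make_topography(array, ctr, widths[[nm]],
                    seed = derive_seed(seed, match(nm, names(centers))))
  })
  structure(
    list(array = array, topographies = topos,
         onset_latency = onset_latency, t_persist = t_persist,
         amplitude = amplitude, noise_sd = noise_sd,
         noise_alpha = noise_alpha, plateau = plateau, rise = rise,
         fall = fall, transient_peak = transient_peak,
         saccade_gain = saccade_gain, artifact_gain = artifact_gain,
         artifact_pattern = artifact_pattern, seed = seed),
    class = "pattern_model"
  )
}

# unit-norm channel topography: Gaussian site profile times a seeded random
# per-channel modulation, so patterns sharing a hemisphere stay discriminable
make_topography <- function(array, center, width, seed) {
  sites <- array$sites
  w_site <- exp(-((sites$x - center[1])^2 + (sites$y - center[2])^2) /
                  (2 * width^2))
  ch <- array$channels
  with_seed(seed, {
    theta <- runif(nrow(sites), 0, 2 * pi)
    mod <- 1 + 0.6 * rnorm(nrow(ch))
  })
  base <- numeric(nrow(ch))
  g1 <- ch$type == "grad1"
  g2 <- ch$type == "grad2"
  mg <- ch$type == "mag"
  base[g1] <- w_site[ch$site[g1]] * cos(theta[ch$site[g1]])
  base[g2] <- w_site[ch$site[g2]] * sin(theta[ch$site[g2]])
  base[mg] <- 0.7 * w_site[ch$site[mg]]
  v <- base * mod
  v / sqrt(sum(v^2))
}

#' Retrieve a model topography
#'
#' @param model A [pattern_model()].
#' @param spatial_frequency `"low"`, `"high"`, or `"saccade"` for the
#'   SF-independent component.
#' @param hemifield `"LVF"` or `"RVF"` (ignored for `"saccade"`).
#' @return Unit-norm numeric vector over channels.
#' @export
get_topography <- function(model, spatial_frequency, hemifield = NULL) {
  key <- if (identical(spatial_frequency, "saccade")) "saccade"
         else paste(spatial_frequency, hemifield, sep = "_")
  topo <- model$topographies[[key]]
  check_that(!is.null(topo), paste0("no topography `", key, "` in model"))
  topo
}

#' Temporal response envelope
#'
#' Zero before `t_on`, raised-cosine rise, gamma-like transient peaking
#' `transient_peak` after `t_on`, sustained `plateau`, raised-cosine fall
#' after `t_off`. `t_on` should already include the response onset latency.
#'
#' @param t Time vector (s).
#' @param t_on,t_off Envelope start and source-off time (s).
#' @param model A [pattern_model()] (supplies shape parameters).
#' @return Nonnegative envelope values, peak approximately 1.
#' @export
response_envelope <- function(t, t_on, t_off, model) {
  tau <- t - t_on
  on <- cos_ramp(tau, model$rise)
  tp <- model$transient_peak
  bump <- ifelse(tau > 0, (tau / tp * exp(1 - tau / tp))^2, 0)
  off <- 1 - cos_ramp(t - t_off, model$fall)
  env <- on * (model$plateau + (1 - model$plateau) * bump) * off
  env[t < t_on] <- 0
  env
}
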