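# shared fixtures, built in code at test time

small_array <- function(n_sites = 16) make_sensor_array(n_sites)

small_model <- function(array = small_array(), ...) {
  pattern_model(array, seed = 42L, ...)
}

# a flat eye trace at the right fixation point with optional injected steps
flat_trace <- function(n = 1500, rate = 1000, x = 7, y = 0, noise = 0) {
  tr <- tibble::tibble(
    time_s = (seq_len(n) - 1) / rate,
    x_deg = rep(x, n) + if (noise > 0) rnorm(n, 0, noise) else 0,
    y_deg = rep(y, n) + if (noise > 0) rnorm(n, 0, noise) else 0
  )
  class(tr) <- c("eye_trace", class(tr))
  attr(tr, "rate") <- rate
  attr(tr, "events") <- tibble::tibble()
  tr
}

# inject a linear-ish burst of horizontal motion: `span` degrees over
# [i0, i1] samples (constant velocity, abrupt on/off)
inject_burst <- function(tr, i0, i1, span) {
  n <- nrow(tr)
  prof <- c(rep(0, i0 - 1), seq(0, 1, length.out = i1 - i0 + 1),
            rep(1, n - i1))
  tr$x_deg <- tr$x_deg + span * prof
  tr
}

# minimal epoch_set from an explicit array
toy_epochs <- function(data, rate = 250, t0_index = 1, trials = NULL) {
  d <- dim(data)
  times <- (seq_len(d[3]) - t0_index) / rate
  new_epoch_set(data, times, rate, "S1_onset", trials)
}

# epochs whose two classes differ by a fixed pattern from `t_on` onward
separable_epochs <- function(n_trials = 40, n_channels = 8, n_times = 50,
                             rate = 250, t_on = 0.04, gain = 5,
                             noise = 1, seed = 1) {
  withr::with_seed(seed, {
    pat <- rnorm(n_channels)
    pat <- pat / sqrt(sum(pat^2))
    lab <- rep(c("low", "high"), length.out = n_trials)
    times <- (seq_len(n_times) - round(n_times / 4)) / rate
    data <- array(rnorm(n_trials * n_channels * n_times, 0, noise),
                  c(n_trials, n_channels, n_times))
    on <- times >= t_on
    for (i in seq_len(n_trials)) {
      s <- if (lab[i] == "high") 1 else -1
      data[i, , on] <- data[i, , on] + s * gain * pat
    }
    toy_epochs(data, rate, t0_index = round(n_times / 4),
               trials = tibble::tibble(trial_index = seq_len(n_trials) - 1L,
                                       label = lab))
  })
}

grid_adjacency_1d <- function(n_times, radius = 1L) {
  sensor_time_adjacency(1, n_times, time_radius = radius)
}
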