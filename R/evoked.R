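#' Combine a planar-gradiometer pair
#'
#' Pointwise Euclidean norm of the two orthogonal gradients at a site,
#' `sqrt(g1^2 + g2^2)`; applied to trial-averaged channels.
#'
#' @param g1,g2 Numeric vectors on the same time grid.
#' @return Nonnegative combined site values.
#' @export
#' @examples
#' combine_planar_pair(3, 4)
combine_planar_pair <- function(g1, g2) {
  check_that(length(g1) == length(g2), "mismatched time grids")
  sqrt(g1^2 + g2^2)
}

#' Event-related average with planar-gradient combination
#'
#' The fixed order of operations is: average over trials per channel, then
#' combine each site's gradiometer pair (Euclidean norm), then subtract
#' each site's mean over the baseline window. A per-trial combination mode
#' exists for comparison but is not the default.
#'
#' @param es An `epoch_set`.
#' @param array The [make_sensor_array()] describing the channels.
#' @param baseline Baseline window (s) whose mean is subtracted after
#'   combination; `NULL` skips the subtraction.
#' @param per_trial Combine gradients per trial before averaging (not the
#'   default order).
#' @return An `evoked_map`: sites x time matrix with attributes `times`,
#'   `alignment`, `n_trials`, `sites`. Magnetometer channels are averaged
#'   but reported separately in the `"mag"` attribute.
#' @export
compute_evoked <- function(es, array, baseline = c(-0.2, 0),
                           per_trial = FALSE) {
  check_that(n_trials(es) >= 1, "empty epoch set")
  ch <- array$channels
  g1 <- ch$channel[ch$type == "grad1"]
  g2 <- ch$channel[ch$type == "grad2"]
  if (per_trial) {
    d <- dim(es$data)
    comb_tr <- array(NA_real_, c(d[1], length(g1), d[3]))
    for (i in seq_len(d[1])) {
      comb_tr[i, , ] <- sqrt(es$data[i, g1, , drop = FALSE]^2 +
                               es$data[i, g2, , drop = FALSE]^2)[1, , ]
    }
    comb <- apply(comb_tr, c(2, 3), mean)
  } else {
    avg <- apply(es$data, c(2, 3), mean) # channels x time
    comb <- sqrt(avg[g1, , drop = FALSE]^2 + avg[g2, , drop = FALSE]^2)
  }
  if (!is.null(baseline)) {
    idx <- window_index(es$times, baseline[1], baseline[2])
    check_that(length(idx) > 0, "empty baseline window")
    comb <- comb - rowMeans(comb[, idx, drop = FALSE])
  }
  mags <- ch$channel[ch$type == "mag"]
  mag_avg <- if (length(mags) > 0) {
    apply(es$data[, mags, , drop = FALSE], c(2, 3), mean)
  }
  structure(comb, times = es$times, alignment = es$alignment,
            n_trials = n_trials(es), sites = array$sites, mag = mag_avg,
            class = "evoked_map")
}

#' @export
print.evoked_map <- function(x, ...) {
  cat("<evoked_map> ", nrow(x), " sites x ", ncol(x), " samples, ",
      attr(x, "n_trials"), " trials, aligned to ", attr(x, "alignment"),
      "\n", sep = "")
  invisible(x)
}

#' Difference of two evoked maps
#'
#' Pointwise `a - b`, e.g. high minus low spatial frequency, or change
#' minus no-change.
#'
#' @param map_a,map_b `evoked_map` objects on the same grid.
#' @return An `evoked_map` of differences (may be negative).
#' @export
evoked_contrast <- function(map_a, map_b) {
  check_that(all(dim(map_a) == dim(map_b)) &&
               isTRUE(all.equal(attr(map_a, "times"), attr(map_b, "times"))),
             "evoked maps are on different grids")
  out <- unclass(map_a) - unclass(map_b)
  attributes(out) <- attributes(map_a)
  attr(out, "n_trials") <- min(attr(map_a, "n_trials"),
                               attr(map_b, "n_trials"))
  out
}
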