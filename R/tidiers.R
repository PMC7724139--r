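#' Tidy a generalization matrix into a long tibble
#'
#' @param x A `generalization_matrix`.
#' @param ... Unused.
#' @return A tibble with `train_time`, `test_time`, `value`.
#' @method tidy generalization_matrix
#' @export
tidy.generalization_matrix <- function(x, ...) {
  out <- tidyr::expand_grid(train_time = x$train_times,
                            test_time = x$test_times)
  out$value <- as.vector(t(x$value))
  out$statistic <- x$statistic
  out
}

#' @rdname tidy.generalization_matrix
#' @method glance generalization_matrix
#' @export
glance.generalization_matrix <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    train_condition = x$train_condition,
    test_condition = x$test_condition,
    test_alignment = x$test_alignment,
    n_train_times = length(x$train_times),
    n_test_times = length(x$test_times),
    n_test = x$n_test,
    peak = max(x$value),
    peak_train_time = x$train_times[which(x$value == max(x$value),
                                          arr.ind = TRUE)[1, 1]],
    peak_test_time = x$test_times[which(x$value == max(x$value),
                                        arr.ind = TRUE)[1, 2]]
  )
}

#' Tidy a cluster result
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return A tibble with one row per map point: `point`, `statistic`
#'   (t value), `tfce`, `p`, `significant`.
#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) {
  tibble::tibble(point = seq_along(x$p), statistic = x$stat_map,
                 tfce = x$tfce_map, p = x$p, significant = x$mask)
}

#' @rdname tidy.cluster_result
#' @method glance cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(n_points = length(x$p), n_perm = x$n_perm,
                 alpha = x$alpha, n_significant = sum(x$mask),
                 min_p = min(x$p, na.rm = TRUE))
}

#' Tidy an epoch set
#'
#' @param x An `epoch_set`.
#' @param ... Unused.
#' @return A long tibble: `trial_index`, `channel`, `time`, `value`.
#' @method tidy epoch_set
#' @export
tidy.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  out <- tidyr::expand_grid(trial_index = x$trials$trial_index,
                            channel = seq_len(d[2]),
                            time = x$times)
  # expand_grid varies time fastest, then channel, then trial; the aperm
  # below serializes the array in exactly that order
  out$value <- as.vector(aperm(x$data, c(3, 2, 1)))
  out
}

#' @rdname tidy.epoch_set
#' @method glance epoch_set
#' @export
glance.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  tibble::tibble(n_trials = d[1], n_channels = d[2], n_times = d[3],
                 rate = x$rate, alignment = x$alignment,
                 n_rejected = length(unique(x$rejection_log$trial_index)))
}

#' Tidy an evoked map
#'
#' @param x An `evoked_map`.
#' @param ... Unused.
#' @return A long tibble: `site`, `time`, `value`.
#' @method tidy evoked_map
#' @export
tidy.evoked_map <- function(x, ...) {
  out <- tidyr::expand_grid(site = seq_len(nrow(x)),
                            time = attr(x, "times"))
  out$value <- as.vector(t(unclass(x)))
  out
}
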