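#' Construct a planar sensor array
#'
#' Sites are laid out on a unit-scale 2-D grid or ring. Each site carries two
#' orthogonal planar-gradiometer channels and, optionally, one magnetometer;
#' channels are enumerated site-major, so a full 102-site array with
#' magnetometers yields 306 channels.
#'
#' @param n_sites Number of sensor sites (>= 4).
#' @param layout `"grid"` or `"ring"`.
#' @param magnetometers Include one magnetometer per site?
#' @return A list of class `sensor_array` with `sites` (tibble: `site`,
#'   `x`, `y`) and `channels` (tibble: `channel`, `site`, `type`, `pair`).
#' @export
#' @examples
#' nrow(make_sensor_array(102, magnetometers = TRUE)$channels)
make_sensor_array <- function(n_sites, layout = c("grid", "ring"),
                              magnetometers = FALSE) {
  layout <- match.arg(layout)
  check_that(is_count(n_sites) && n_sites >= 4, "`n_sites` must be >= 4")
  if (layout == "grid") {
    nc <- ceiling(sqrt(n_sites))
    nr <- ceiling(n_sites / nc)
    pos <- tidyr::expand_grid(row = seq_len(nr), col = seq_len(nc))
    pos <- pos[seq_len(n_sites), ]
    x <- (pos$col - (nc + 1) / 2) / ((nc - 1) / 2)
    y <- -(pos$row - (nr + 1) / 2) / ((nr - 1) / 2)
  } else {
    theta <- 2 * pi * (seq_len(n_sites) - 1) / n_sites
    x <- cos(theta)
    y <- sin(theta)
  }
  sites <- tibble::tibble(site = seq_len(n_sites), x = x, y = y)
  check_that(!anyDuplicated(round(cbind(x, y), 12)),
             "sensor sites must have distinct positions")
  types <- c("grad1", "grad2", if (magnetometers) "mag")
  channels <- tidyr::expand_grid(site = sites$site, type = types)
  channels$channel <- seq_len(nrow(channels))
  channels$pair <- ifelse(channels$type == "mag", NA_integer_, channels$site)
  structure(list(sites = sites,
                 channels = channels[, c("channel", "site", "type", "pair")]),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat("<sensor_array> ", nrow(x$sites), " sites, ",
      nrow(x$channels), " channels\n", sep = "")
  invisible(x)
}

#' Delaunay sensor adjacency
#'
#' Neighbor pairs from the Delaunay triangulation of the site layout, the
#' standard spatial-cluster neighborhood for sensor-level statistics.
#'
#' @param array A [make_sensor_array()] object, or a two-column matrix of
#'   positions.
#' @return A tibble of undirected neighbor pairs (`from` < `to`, site ids).
#' @export
sensor_adjacency <- function(array) {
  pos <- if (inherits(array, "sensor_array")) {
    cbind(array$sites$x, array$sites$y)
  } else {
    as.matrix(array)
  }
  check_that(nrow(pos) >= 3, "need at least 3 sites for a triangulation")
  dd <- deldir::deldir(pos[, 1], pos[, 2], suppressMsge = TRUE)
  e <- dd$delsgs[, c("ind1", "ind2")]
  from <- pmin(e$ind1, e$ind2)
  to <- pmax(e$ind1, e$ind2)
  dplyr::distinct(tibble::tibble(from = from, to = to))
}
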