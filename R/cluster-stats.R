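#' One-sample t map
#'
#' Per-point one-sample t statistic over subjects,
#' `t = (mean - mu0) / (sd / sqrt(n))`. Points with zero variance are
#' signalled and masked with `NA` rather than dividing by zero.
#'
#' @param maps Subjects x points numeric matrix (sensor-by-time maps are
#'   flattened sensor-major: point = (sensor - 1) * n_times + time).
#' @param mu0 Null value, default 0.
#' @return Numeric vector of t values (length = points).
#' @export
#' @examples
#' one_sample_t_map(matrix(c(1, 2, 3), ncol = 1))
one_sample_t_map <- function(maps, mu0 = 0) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  check_that(n >= 2, "need at least two subjects")
  m <- colMeans(maps) - mu0
  s <- apply(maps, 2, sd)
  zero <- s == 0
  if (any(zero)) {
    warn(paste0(sum(zero), " point(s) have zero variance; masked with NA"))
    s[zero] <- NA_real_
  }
  m / (s / sqrt(n))
}

#' Sensor-by-time cluster adjacency
#'
#' Two map points are neighbors iff they share a sensor and lie within
#' `time_radius` samples of each other, or they are Delaunay-adjacent
#' sensors at the identical time point. Points are flattened sensor-major
#' (`point = (sensor - 1) * n_times + time`). With `n_sensors = 1` this
#' reduces to the purely temporal neighborhood used for decoding
#' time courses.
#'
#' @param n_sensors,n_times Map dimensions.
#' @param sensor_edges Tibble of sensor neighbor pairs (`from`, `to`), e.g.
#'   from [sensor_adjacency()]; ignored when `n_sensors = 1`.
#' @param time_radius Temporal neighborhood radius in samples (default 2,
#'   i.e. 8 ms at 250 Hz).
#' @return 0-based integer edge matrix (two columns) for the C++ TFCE core.
#' @export
sensor_time_adjacency <- function(n_sensors, n_times, sensor_edges = NULL,
                                  time_radius = 2L) {
  edges <- list()
  if (time_radius > 0 && n_times > 1) {
    for (dlt in seq_len(min(time_radius, n_times - 1))) {
      t0 <- seq_len(n_times - dlt)
      for (s in seq_len(n_sensors)) {
        base <- (s - 1) * n_times
        edges[[length(edges) + 1]] <-
          cbind(base + t0 - 1L, base + t0 + dlt - 1L)
      }
    }
  }
  if (n_sensors > 1 && !is.null(sensor_edges) && nrow(sensor_edges) > 0) {
    tt <- seq_len(n_times) - 1L
    for (e in seq_len(nrow(sensor_edges))) {
      edges[[length(edges) + 1]] <-
        cbind((sensor_edges$from[e] - 1L) * n_times + tt,
              (sensor_edges$to[e] - 1L) * n_times + tt)
    }
  }
  if (length(edges) == 0) {
    return(matrix(integer(0), 0, 2))
  }
  out <- do.call(rbind, edges)
  storage.mode(out) <- "integer"
  out
}

#' Threshold-free cluster enhancement
#'
#' `TFCE(p) = sum over heights h in (0, t_p] (step dh) of
#' extent(h, p)^E * h^H * dh`, where `extent(h, p)` is the size of the
#' connected supra-threshold component containing `p` under the adjacency.
#' The negative tail is enhanced by applying the transform to the negated
#' map; the result is signed.
#'
#' @param stat Numeric statistic map (flattened; `NA` treated as 0).
#' @param adjacency 0-based edge matrix from [sensor_time_adjacency()].
#' @param E,H TFCE extent and height exponents (defaults 0.5 and 2).
#' @param n_steps Number of integration steps when `dh` is not given
#'   (`dh = max|stat| / n_steps`).
#' @param dh Explicit step height (optional).
#' @return Signed enhanced map, same length as `stat`.
#' @export
tfce_transform <- function(stat, adjacency, E = 0.5, H = 2,
                           n_steps = 100L, dh = NULL) {
  check_that(E >= 0 && H >= 0, "invalid TFCE exponents")
  check_that(is.null(dh) || dh > 0, "`dh` must be positive")
  tfce_enhance_cpp(as.numeric(stat), adjacency, E, H, as.integer(n_steps),
                   if (is.null(dh)) -1 else dh)
}

#' Group-level sign-flip permutation test with TFCE
#'
#' One-sample test of subject maps against `mu0` under the symmetric null:
#' whole-subject sign flips of the demeaned maps generate the null
#' distribution of the maximum absolute TFCE statistic, and each point's
#' corrected two-tailed p value is
#' `(1 + #\{perm max >= |observed|\}) / (n_perm + 1)`.
#'
#' @param maps Subjects x points matrix (log-odds maps for accuracy data).
#' @param adjacency 0-based edge matrix from [sensor_time_adjacency()].
#' @param n_perm Number of random sign assignments (default 10^4).
#' @param alpha Two-tailed significance level.
#' @param mu0 Null value subtracted before flipping.
#' @param E,H,n_steps TFCE settings (see [tfce_transform()]).
#' @param enumerate Enumerate all `2^n` sign patterns instead of sampling
#'   (exact test; requires `n_subjects <= 20`).
#' @param seed Integer seed for the random flips.
#' @return A `cluster_result`: list with `stat_map` (t values),
#'   `tfce_map`, `p` (corrected, per point), `mask` (p <= alpha),
#'   `null_max` (permutation maxima), `alpha`, `n_perm`.
#' @export
sign_flip_permutation <- function(maps, adjacency, n_perm = 1e4,
                                  alpha = 0.05, mu0 = 0, E = 0.5, H = 2,
                                  n_steps = 100L, enumerate = FALSE,
                                  seed = 1L) {
  check_that(n_perm >= 1, "`n_perm` must be at least 1")
  maps <- as.matrix(maps) - mu0
  n <- nrow(maps)
  p_pts <- ncol(maps)

  ssq <- colSums(maps^2)
  t_from_signs <- function(S) {
    # S: flips x subjects in {-1, +1}
    M <- (S %*% maps) / n
    V <- sweep(-n * M^2, 2, ssq, "+") / (n - 1)
    V[V < 0] <- 0
    Tm <- M / sqrt(V / n)
    Tm[!is.finite(Tm)] <- 0
    Tm
  }
  # the observed map goes through the same arithmetic as the permuted maps,
  # so sign patterns that reproduce the data tie with it exactly
  t_disp <- suppressWarnings(one_sample_t_map(maps, 0))
  t_obs <- t_from_signs(matrix(1, 1, n))[1, ]
  tfce_obs <- tfce_transform(t_obs, adjacency, E, H, n_steps)

  if (enumerate) {
    check_that(n <= 20, "enumeration limited to 20 subjects")
    n_perm <- 2^n
    grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null_max <- numeric(n_perm)
    chunk <- 512
    for (i0 in seq(1, n_perm, by = chunk)) {
      i1 <- min(i0 + chunk - 1, n_perm)
      Tm <- t_from_signs(grid[i0:i1, , drop = FALSE])
      null_max[i0:i1] <- tfce_max_batch_cpp(Tm, adjacency, E, H,
                                            as.integer(n_steps))
    }
  } else {
    null_max <- numeric(n_perm)
    chunk <- max(1, floor(2e6 / p_pts))
    done <- 0
    while (done < n_perm) {
      m <- min(chunk, n_perm - done)
      S <- with_seed(derive_seed(seed, 13, done), {
        matrix(sample(c(-1, 1), m * n, replace = TRUE), m, n)
      })
      Tm <- t_from_signs(S)
      null_max[done + seq_len(m)] <- tfce_max_batch_cpp(
        Tm, adjacency, E, H, as.integer(n_steps))
      done <- done + m
    }
  }

  abs_obs <- abs(tfce_obs)
  exceed <- vapply(abs_obs, function(v) sum(null_max >= v), numeric(1))
  p <- (1 + exceed) / (n_perm + 1)
  p[is.na(t_disp)] <- NA_real_
  structure(
    list(stat_map = t_disp, tfce_map = tfce_obs, p = p,
         mask = !is.na(p) & p <= alpha, null_max = null_max,
         alpha = alpha, n_perm = n_perm, E = E, H = H),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", length(x$p), " points, ", x$n_perm,
      " permutations, ", sum(x$mask), " significant at alpha = ",
      x$alpha, "\n", sep = "")
  invisible(x)
}
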