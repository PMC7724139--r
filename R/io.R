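#' Read and write eye and photodiode traces
#'
#' Traces travel as tab-separated text with a documented header:
#' eye traces as `time_s`, `x_deg`, `y_deg`; photodiode traces as
#' `time_s`, `level`.
#'
#' @param trace An `eye_trace` or `photodiode_trace` tibble.
#' @param path File path.
#' @return `write_*` returns `path` invisibly; `read_*` returns the tibble
#'   with its `rate` attribute restored from the time stamps.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(as.data.frame(trace), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_eye_trace <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  out <- tibble::as_tibble(df)
  class(out) <- c("eye_trace", class(out))
  attr(out, "rate") <- round(1 / median(diff(out$time_s)))
  attr(out, "events") <- tibble::tibble()
  out
}

#' @rdname write_trace
#' @export
read_photodiode_trace <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  out <- tibble::as_tibble(df)
  class(out) <- c("photodiode_trace", class(out))
  attr(out, "rate") <- round(1 / median(diff(out$time_s)))
  out
}

#' Serialize an epoch set to plain text
#'
#' Writes a directory with `data.csv` (one row per trial-channel, samples
#' in columns), `trials.csv`, `rejection_log.csv` and `meta.json`
#' (times, rate, alignment). The text layout keeps synthetic fixtures
#' diff-able and loadable without binary dependencies.
#'
#' @param es An `epoch_set`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_epoch_set <- function(es, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(es$data)
  flat <- t(matrix(aperm(es$data, c(3, 2, 1)), nrow = d[3]))
  idx <- tidyr::expand_grid(trial = seq_len(d[1]), channel = seq_len(d[2]))
  utils::write.csv(cbind(idx, as.data.frame(flat)),
                   file.path(dir, "data.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(es$trials), file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(es$rejection_log),
                   file.path(dir, "rejection_log.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(times = es$times, rate = es$rate, alignment = es$alignment,
         dims = d),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  df <- utils::read.csv(file.path(dir, "data.csv"))
  d <- meta$dims
  flat <- as.matrix(df[, -(1:2)])
  data <- aperm(array(t(flat), c(d[3], d[2], d[1])), c(3, 2, 1))
  trials <- tibble::as_tibble(utils::read.csv(file.path(dir, "trials.csv")))
  rej <- tibble::as_tibble(utils::read.csv(file.path(dir,
                                                     "rejection_log.csv")))
  if (nrow(rej) == 0) {
    rej <- tibble::tibble(trial_index = integer(0), rule = character(0),
                          detail = character(0))
  }
  new_epoch_set(data, meta$times, meta$rate, meta$alignment, trials, rej)
}

#' Export a generalization matrix as CSV plus JSON metadata
#'
#' @param gm A `generalization_matrix`.
#' @param path_csv CSV path for the value matrix (train times in rows).
#' @param path_json JSON path for the axis/provenance metadata.
#' @return `path_csv`, invisibly.
#' @export
write_generalization_matrix <- function(gm, path_csv, path_json) {
  utils::write.csv(as.data.frame(gm$value), path_csv, row.names = FALSE)
  jsonlite::write_json(
    gm[c("train_times", "test_times", "statistic", "label",
         "train_condition", "test_condition", "train_alignment",
         "test_alignment", "n_test")],
    path_json, auto_unbox = TRUE, digits = NA)
  invisible(path_csv)
}

#' Export detected saccade events as CSV
#'
#' @param events Event tibble from [detect_saccades()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}
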