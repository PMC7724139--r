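#' Temporal-searchlight feature extraction
#'
#' Features at time index `t_index` are all channels by the
#' `2 * radius + 1` samples centered on it, flattened channel-major. At
#' 250 Hz the default radius of 2 samples spans 8 ms on each side. Time
#' points whose window exceeds the epoch are not valid feature centers.
#'
#' @param es An `epoch_set`.
#' @param t_index Time index (1-based) of the searchlight center.
#' @param radius Searchlight radius in samples.
#' @return Trials x features numeric matrix.
#' @export
searchlight_features <- function(es, t_index, radius = 2L) {
  check_that(radius >= 0, "`radius` must be non-negative")
  n_t <- length(es$times)
  check_that(t_index - radius >= 1 && t_index + radius <= n_t,
             "searchlight window exceeds the epoch")
  idx <- (t_index - radius):(t_index + radius)
  d <- dim(es$data)
  matrix(es$data[, , idx], nrow = d[1])
}

#' Valid searchlight centers
#'
#' @param es An `epoch_set`.
#' @param radius Searchlight radius in samples.
#' @return Integer vector of valid time indices.
#' @export
searchlight_centers <- function(es, radius = 2L) {
  n_t <- length(es$times)
  check_that(n_t > 2 * radius, "epoch shorter than the searchlight")
  (radius + 1L):(n_t - radius)
}

#' Searchlight radius in samples for a given rate
#'
#' @param radius_s Radius in seconds (default 0.008).
#' @param rate Sampling rate (Hz).
#' @return Integer number of samples (`radius_s * rate`, must be whole).
#' @export
#' @examples
#' radius_samples(0.008, 250)
radius_samples <- function(radius_s = 0.008, rate = 250) {
  r <- radius_s * rate
  check_that(abs(r - round(r)) < 1e-9,
             "searchlight radius is not a whole number of samples at this rate")
  as.integer(round(r))
}

# subsample indices so both classes (optionally within strata) are balanced;
# each class's RNG stream is keyed by its member set (not its name), so the
# subsample is invariant under relabeling the classes
balanced_subsample <- function(y, strata = NULL, seed = 1L) {
  classes <- levels(y)
  check_that(length(classes) == 2, "need exactly two classes")
  n_target <- min(table(y))
  keep <- integer(0)
  for (cl in classes) {
    idx <- which(y == cl)
    keep <- c(keep, with_seed(derive_seed(seed, idx[1]), {
      if (length(idx) <= n_target) {
        idx
      } else if (is.null(strata)) {
        sample(idx, n_target)
      } else {
        # stratified draw: spread the kept trials over the strata
        st <- strata[idx]
        tab <- table(st)
        alloc <- floor(n_target * tab / sum(tab))
        rem <- n_target - sum(alloc)
        if (rem > 0) {
          extra <- sample(rep(names(tab), pmax(tab - alloc, 0)), rem)
          alloc <- alloc + table(factor(extra, levels = names(tab)))
        }
        out <- integer(0)
        for (s in names(tab)) {
          pool <- idx[st == s]
          out <- c(out, if (length(pool) <= alloc[[s]]) pool
                   else sample(pool, alloc[[s]]))
        }
        out
      }
    }))
  }
  sort(keep)
}

# linear SVC (cost fixed at 1, no feature rescaling); returns weights and the
# class that positive decision values map to; ties (decision exactly 0) go to
# the class with the lower label id
fit_linear_svc <- function(X, y) {
  fit <- e1071::svm(X, y, kernel = "linear", cost = 1, scale = FALSE)
  w <- as.numeric(crossprod(fit$coefs, fit$SV))
  # resolve the sign convention from the fitted training predictions
  dec_tr <- as.numeric(X %*% w) - fit$rho
  agree <- mean((dec_tr > 0) == (as.character(fit$fitted) == fit$levels[1]))
  positive <- if (agree >= 0.5) fit$levels[1] else fit$levels[2]
  list(w = w, rho = fit$rho, positive = positive,
       classes = sort(fit$levels))
}

predict_svc <- function(clf, X) {
  dec <- as.numeric(X %*% clf$w) - clf$rho
  negative <- setdiff(clf$classes, clf$positive)
  out <- ifelse(dec > 0, clf$positive, negative)
  out[dec == 0] <- clf$classes[1]
  out
}

get_labels <- function(es, label) {
  if (is.character(label) && length(label) == 1) {
    check_that(label %in% names(es$trials),
               paste0("no column `", label, "` in trial metadata"))
    y <- es$trials[[label]]
  } else {
    y <- label
  }
  factor(as.character(y))
}

#' Time-resolved cross-validated decoding
#'
#' Stratified k-fold cross-validation of linear support-vector classifiers
#' with a temporal searchlight. Within each fold's training partition the
#' classes are balanced by seeded subsampling (redrawn per fold), optionally
#' stratified on a second design factor. Accuracy is pooled over folds per
#' time point.
#'
#' @param es An `epoch_set` (typically 250 Hz, baseline-standardized).
#' @param label Column name in `es$trials` (or a vector) with two classes.
#' @param k Number of folds.
#' @param radius Searchlight radius in samples.
#' @param balance_within Optional column name used as a stratification
#'   constraint when balancing (e.g. `"change"`).
#' @param seed Integer seed for fold assignment and balancing.
#' @return An `accuracy_timecourse` tibble: `time`, `accuracy`, `n_test`.
#' @export
crossval_timecourse <- function(es, label, k = 10L, radius = 2L,
                                balance_within = NULL, seed = 1L) {
  y <- get_labels(es, label)
  strata <- if (!is.null(balance_within)) {
    factor(as.character(es$trials[[balance_within]]))
  }
  check_that(all(table(y) >= k), "each class needs at least k trials")
  # fold streams are keyed by each class's member set so the partition is
  # invariant under swapping the class labels
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    perm <- with_seed(derive_seed(seed, 101, idx[1]), sample(idx))
    folds[perm] <- rep_len(seq_len(k), length(perm))
  }
  centers <- searchlight_centers(es, radius)
  correct <- numeric(length(centers))
  total <- numeric(length(centers))
  d <- dim(es$data)
  bal_by_fold <- lapply(seq_len(k), function(f) {
    tr_idx <- which(folds != f)
    tr_idx[balanced_subsample(droplevels(y[tr_idx]),
                              strata = strata[tr_idx],
                              seed = derive_seed(seed, 7, f))]
  })
  y_chr <- as.character(y)
  for (j in seq_along(centers)) {
    sl <- (centers[j] - radius):(centers[j] + radius)
    Xall <- matrix(es$data[, , sl], nrow = d[1])
    for (f in seq_len(k)) {
      te_idx <- which(folds == f)
      bal <- bal_by_fold[[f]]
      clf <- fit_linear_svc(Xall[bal, , drop = FALSE], droplevels(y[bal]))
      pred <- predict_svc(clf, Xall[te_idx, , drop = FALSE])
      correct[j] <- correct[j] + sum(pred == y_chr[te_idx])
      total[j] <- total[j] + length(te_idx)
    }
  }
  out <- tibble::tibble(time = es$times[centers],
                        accuracy = correct / total, n_test = total)
  class(out) <- c("accuracy_timecourse", class(out))
  attr(out, "label") <- if (is.character(label)) label else "label"
  attr(out, "k") <- k
  out
}

#' Cross-condition temporal generalization
#'
#' For each training time point one linear classifier is trained on all
#' (class-balanced) training-condition trials and evaluated at every test
#' time point of an independent condition; train and test sets come from
#' different conditions, so no cross-validation is used. The recorded
#' statistic is either decoding accuracy or the proportion of test trials
#' assigned to `choice_level` (used for the no-stimulus bias analysis).
#'
#' @param train,test `epoch_set`s with identical channel sets and rates.
#' @param label Two-class label (column name in both trial tables; for the
#'   `"choice"` statistic only the training labels are needed).
#' @param radius Searchlight radius in samples.
#' @param balance_within Optional stratification column for balancing.
#' @param statistic `"accuracy"` or `"choice"`.
#' @param choice_level Class whose choice proportion is reported when
#'   `statistic = "choice"`.
#' @param train_window,test_window Optional length-2 time windows (s)
#'   restricting the train/test axes.
#' @param seed Integer seed for balancing.
#' @return A `generalization_matrix`: list with `value` (train x test),
#'   `train_times`, `test_times`, conditions, alignments and `n_test`.
#' @export
cross_condition_matrix <- function(train, test, label, radius = 2L,
                                   balance_within = NULL,
                                   statistic = c("accuracy", "choice"),
                                   choice_level = "high",
                                   train_window = NULL, test_window = NULL,
                                   seed = 1L) {
  statistic <- match.arg(statistic)
  check_that(dim(train$data)[2] == dim(test$data)[2],
             "train and test channel sets differ")
  check_that(isTRUE(all.equal(train$rate, test$rate)),
             "train and test rates differ")
  y_tr <- get_labels(train, label)
  strata <- if (!is.null(balance_within)) {
    factor(as.character(train$trials[[balance_within]]))
  }
  tr_centers <- restrict_centers(train, radius, train_window)
  te_centers <- restrict_centers(test, radius, test_window)
  bal <- balanced_subsample(y_tr, strata = strata,
                            seed = derive_seed(seed, 11))
  d_tr <- dim(train$data)
  d_te <- dim(test$data)
  n_feat <- d_tr[2] * (2 * radius + 1)
  W <- matrix(NA_real_, length(tr_centers), n_feat)
  rho <- numeric(length(tr_centers))
  pos <- character(length(tr_centers))
  classes <- NULL
  for (i in seq_along(tr_centers)) {
    sl <- (tr_centers[i] - radius):(tr_centers[i] + radius)
    X <- matrix(train$data[bal, , sl], nrow = length(bal))
    clf <- fit_linear_svc(X, droplevels(y_tr[bal]))
    W[i, ] <- clf$w
    rho[i] <- clf$rho
    pos[i] <- clf$positive
    classes <- clf$classes
  }
  value <- matrix(NA_real_, length(tr_centers), length(te_centers))
  # sign algebra instead of per-cell class bookkeeping: with columns flipped
  # so positive decisions always mean classes[1], a prediction is classes[1]
  # iff the flipped decision is >= 0 (ties go to the lower label id)
  s_vec <- ifelse(pos == classes[1], 1, -1)
  if (statistic == "accuracy") {
    is_cl1 <- as.character(get_labels(test, label)) == classes[1]
  }
  for (j in seq_along(te_centers)) {
    sl <- (te_centers[j] - radius):(te_centers[j] + radius)
    Xte <- matrix(test$data[, , sl], nrow = d_te[1])
    dec <- Xte %*% t(W) - matrix(rho, d_te[1], length(tr_centers),
                                 byrow = TRUE)
    pred1 <- sweep(dec, 2, s_vec, "*") >= 0
    if (statistic == "accuracy") {
      value[, j] <- colMeans(pred1 == is_cl1)
    } else if (choice_level == classes[1]) {
      value[, j] <- colMeans(pred1)
    } else {
      value[, j] <- 1 - colMeans(pred1)
    }
  }
  structure(
    list(value = value,
         train_times = train$times[tr_centers],
         test_times = test$times[te_centers],
         statistic = statistic,
         label = if (is.character(label)) label else "label",
         train_condition = condition_of(train),
         test_condition = condition_of(test),
         train_alignment = train$alignment,
         test_alignment = test$alignment,
         n_test = d_te[1]),
    class = "generalization_matrix"
  )
}

restrict_centers <- function(es, radius, window) {
  centers <- searchlight_centers(es, radius)
  if (!is.null(window)) {
    tt <- es$times[centers]
    centers <- centers[tt >= window[1] - 1e-9 & tt < window[2] - 1e-9]
    check_that(length(centers) > 0, "time window excludes every center")
  }
  centers
}

condition_of <- function(es) {
  if ("condition" %in% names(es$trials)) {
    paste(unique(as.character(es$trials$condition)), collapse = "+")
  } else {
    "unknown"
  }
}

#' @export
print.generalization_matrix <- function(x, ...) {
  cat("<generalization_matrix> ", nrow(x$value), " train x ",
      ncol(x$value), " test times; train ", x$train_condition,
      " (", x$train_alignment, "), test ", x$test_condition,
      " (", x$test_alignment, "); statistic: ", x$statistic,
      "\n", sep = "")
  invisible(x)
}

#' Extract a diagonal band from a generalization matrix
#'
#' For each test time, averages the matrix cells whose train time satisfies
#' `|(t_train - train_origin) - (t_test - test_origin)| <= width / 2`.
#' At 250 Hz the default 20 ms width covers five samples at interior
#' points.
#'
#' @param gm A `generalization_matrix`.
#' @param train_origin,test_origin Diagonal origins (s) on the train and
#'   test axes; a latency-plus-duration-shifted diagonal uses
#'   [offset_diagonal_origin()] as `train_origin`.
#' @param width Full band width (s), default 0.020.
#' @return A `diagonal_trace` tibble: `time` (test axis), `value`,
#'   `n_cells`; attributes record origins, width and provenance.
#' @export
extract_diagonal_band <- function(gm, train_origin = 0, test_origin = 0,
                                  width = 0.020) {
  tol <- width / 2 + 1e-9
  val <- numeric(length(gm$test_times))
  n_cells <- integer(length(gm$test_times))
  for (j in seq_along(gm$test_times)) {
    lagdiff <- (gm$train_times - train_origin) -
      (gm$test_times[j] - test_origin)
    sel <- abs(lagdiff) <= tol
    n_cells[j] <- sum(sel)
    val[j] <- if (any(sel)) mean(gm$value[sel, j]) else NA_real_
  }
  check_that(any(n_cells > 0), "diagonal band is empty at every test time")
  out <- tibble::tibble(time = gm$test_times, value = val, n_cells = n_cells)
  out <- out[out$n_cells > 0, ]
  class(out) <- c("diagonal_trace", class(out))
  attr(out, "train_origin") <- train_origin
  attr(out, "test_origin") <- test_origin
  attr(out, "width") <- width
  attr(out, "statistic") <- gm$statistic
  attr(out, "n_test") <- gm$n_test
  attr(out, "provenance") <- gm[c("train_condition", "test_condition",
                                  "train_alignment", "test_alignment")]
  out
}

#' Train-side origin of the saccade-shifted diagonal
#'
#' The offset-locked diagonal compares test times relative to saccade
#' offset with train times relative to S1 onset shifted by the subject's
#' median saccade latency plus median saccade duration.
#'
#' @param median_latency,median_duration Subject medians (s) over retained
#'   trials.
#' @return Train-side origin (s after S1 onset).
#' @export
#' @examples
#' offset_diagonal_origin(0.226, 0.062)
offset_diagonal_origin <- function(median_latency, median_duration) {
  check_that(length(median_latency) == length(median_duration) &&
               !any(is.na(median_latency)) && !any(is.na(median_duration)),
             "medians unavailable (no retained trials?)")
  median_latency + median_duration
}

#' Empirical-logit (log-odds) transform of a proportion correct
#'
#' `ln((k + 0.5) / (n - k + 0.5))`; the additive correction keeps perfect
#' scores finite, and a chance outcome `k = n/2` maps exactly to 0.
#'
#' @param k_correct Number of correct classifications (may be fractional
#'   when pooled).
#' @param n Number of classifications.
#' @return Log-odds value(s).
#' @export
#' @examples
#' to_log_odds(50, 100)
to_log_odds <- function(k_correct, n) {
  check_that(all(n > 0), "`n` must be positive")
  check_that(all(k_correct >= 0 & k_correct <= n), "need 0 <= k <= n")
  log((k_correct + 0.5) / (n - k_correct + 0.5))
}

#' Log-odds of an accuracy time course or matrix
#'
#' @param value Proportion(s) correct.
#' @param n Number of test classifications behind each proportion.
#' @return Log-odds on the same shape.
#' @export
accuracy_to_log_odds <- function(value, n) {
  to_log_odds(value * n, n)
}

#' Classifier-choice bias on no-stimulus trials
#'
#' Applies fixation-trained spatial-frequency classifiers to no-stimulus
#' saccade trials aligned to saccade offset and reports the proportion of
#' trials classified as the high spatial frequency per (train, test) time.
#' An unbiased pipeline stays at 0.5 throughout.
#'
#' @param train Fixation-condition `epoch_set`.
#' @param test No-stimulus saccade `epoch_set` aligned to saccade offset.
#' @param label Training label (default `"spatial_frequency"`).
#' @param choice_level Class whose choice proportion is reported.
#' @inheritParams cross_condition_matrix
#' @return A `generalization_matrix` with statistic `"choice"`.
#' @export
classify_bias <- function(train, test, label = "spatial_frequency",
                          choice_level = "high", radius = 2L,
                          train_window = NULL, test_window = NULL,
                          seed = 1L) {
  check_that(n_trials(test) > 0, "empty test set")
  cross_condition_matrix(train, test, label, radius = radius,
                         statistic = "choice", choice_level = choice_level,
                         train_window = train_window,
                         test_window = test_window, seed = seed)
}

#' Last significantly above-chance time of a diagonal trace
#'
#' A simple per-timepoint binomial criterion: a point is above chance when
#' its proportion correct exceeds `0.5 + z * sqrt(0.25 / n_test)`. Used to
#' read the persistence of the presaccadic pattern off the offset-locked
#' diagonal: the last supra-threshold test time estimates how long the
#' presaccadic representation stayed decodable after saccade offset.
#'
#' @param trace A `diagonal_trace` with an accuracy statistic.
#' @param n_test Number of test trials behind each proportion (defaults to
#'   the trace's provenance).
#' @param z Threshold in binomial standard errors (default 3).
#' @param from Only consider test times at or after this value (default 0,
#'   i.e. saccade offset for offset-locked traces).
#' @return Last supra-threshold time (s), or `NA` if none.
#' @export
last_significant_time <- function(trace, n_test = attr(trace, "n_test"),
                                  z = 3, from = 0) {
  check_that(!is.null(n_test) && n_test > 0, "`n_test` unknown")
  thr <- 0.5 + z * sqrt(0.25 / n_test)
  ok <- trace$value > thr & trace$time >= from
  if (!any(ok)) return(NA_real_)
  max(trace$time[ok])
}
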