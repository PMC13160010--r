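#' Cross-validate the error classifier across time
#'
#' Splits the window sequence into `n_folds` contiguous time blocks (so
#' temporally adjacent, correlated windows never straddle the train/test
#' split), trains on the remaining blocks and evaluates the held-out flags
#' (`probability >= tau`). Accuracy is the fraction of held-out windows
#' whose flag matches their (mapped) label; chance is the greedy
#' majority-class level on the same labels.
#'
#' @param windows A [window_features()] tibble, in time order.
#' @param n_folds Number of folds (default 8).
#' @param include_pre_error Label-mapping convention for training *and*
#'   evaluation (pre-error counts as error when `TRUE`).
#' @param tau Decision threshold (default 0.85).
#' @param pooled Passed to [train_error_classifier()].
#' @return An object of class `bci_cv`: `accuracy`, `chance`, `folds`
#'   (per-fold tibble), and per-window `probability` / `flag` vectors in
#'   input order.
#' @export
cross_validate_time <- function(windows, n_folds = 8,
                                include_pre_error = TRUE, tau = 0.85,
                                pooled = TRUE) {
  n <- nrow(windows)
  if (n < 2L * n_folds) abort("Too few windows for the requested folds.")
  fold <- as.integer(cut(seq_len(n), n_folds, labels = FALSE))
  cross_validate_folds(windows, fold, include_pre_error, tau, pooled,
                       scheme = "time")
}

#' Cross-validate the error classifier across target positions
#'
#' Each fold holds out all windows of trials whose reach target was at one
#' position, so the classifier is tested on a target it never saw (the
#' error signal must be target-agnostic). All `n_folds` target positions
#' must be present.
#'
#' @inheritParams cross_validate_time
#' @param n_folds Number of target positions (default 8).
#' @return A `bci_cv` object (see [cross_validate_time()]).
#' @export
cross_validate_targets <- function(windows, n_folds = 8,
                                   include_pre_error = TRUE, tau = 0.85,
                                   pooled = TRUE) {
  tg <- windows$target_index
  present <- sort(unique(tg[tg > 0L]))
  missing <- setdiff(seq_len(n_folds), present)
  if (length(missing) > 0) {
    abort(sprintf("Missing target position(s): %s",
                  paste(missing, collapse = ", ")))
  }
  fold <- match(tg, present)
  keep <- !is.na(fold)
  res <- cross_validate_folds(windows[keep, ], fold[keep], include_pre_error,
                              tau, pooled, scheme = "target")
  res
}

cross_validate_folds <- function(windows, fold, include_pre_error, tau,
                                 pooled, scheme) {
  y <- map_error_labels(windows$label, include_pre_error)
  prob <- rep(NA_real_, nrow(windows))
  for (f in sort(unique(fold))) {
    test <- fold == f
    model <- train_error_classifier(windows[!test, ], include_pre_error,
                                    tau = tau, pooled = pooled)
    prob[test] <- predict_error_probability(model, windows[test, ])
  }
  flag <- prob >= tau
  pred <- ifelse(flag, "error", "correct")
  folds <- tibble(
    fold = sort(unique(fold)),
    n = as.vector(table(fold)),
    accuracy = vapply(sort(unique(fold)),
                      function(f) mean(pred[fold == f] == y[fold == f]),
                      numeric(1))
  )
  structure(
    list(accuracy = mean(pred == y),
         chance = greedy_chance_level(y),
         folds = folds, probability = prob, flag = flag,
         label = windows$label, mapped_label = y,
         trial_id = windows$trial_id,
         include_pre_error = include_pre_error, tau = tau, scheme = scheme),
    class = "bci_cv"
  )
}

#' @export
print.bci_cv <- function(x, ...) {
  cat(sprintf("<bci_cv> %s CV, %d folds: accuracy %.3f (chance %.3f)\n",
              x$scheme, nrow(x$folds), x$accuracy, x$chance))
  invisible(x)
}

#' @rdname glance.error_classifier
#' @export
glance.bci_cv <- function(x, ...) {
  tibble(scheme = x$scheme, n_folds = nrow(x$folds), accuracy = x$accuracy,
         chance = x$chance, include_pre_error = x$include_pre_error,
         tau = x$tau)
}

#' @rdname tidy.error_classifier
#' @export
tidy.bci_cv <- function(x, ...) x$folds

#' Delay between kinematic error onset and classifier detection
#'
#' For each maximal run ("bout") of error-labeled windows, the delay is
#' `(first flagged window - onset window) * window_len`; flags are searched
#' from the end of the previous bout, so a flag raised on a pre-error
#' window gives a negative delay. Undetected bouts are excluded from the
#' mean and reported through `detected_fraction`.
#'
#' @param flags Logical per-window classifier flags.
#' @param labels Per-window kinematic labels (the `error` runs define the
#'   bouts).
#' @param window_len Window length in seconds (default 0.08).
#' @return List with `mean_delay` (s), `detected_fraction`, `n_bouts`, and
#'   the per-bout `delays`.
#' @examples
#' detection_delay(c(FALSE, FALSE, FALSE, TRUE), c("correct", "error",
#'   "error", "error"), window_len = 0.08)
#' @export
detection_delay <- function(flags, labels, window_len = 0.08) {
  stopifnot(length(flags) == length(labels))
  is_err <- labels == "error"
  if (!any(is_err)) {
    warn("No error bouts in the label stream.")
    return(list(mean_delay = NA_real_, detected_fraction = NA_real_,
                n_bouts = 0L, delays = numeric(0)))
  }
  onsets <- which(is_err & !c(FALSE, is_err[-length(is_err)]))
  ends <- which(is_err & !c(is_err[-1], FALSE))
  delays <- rep(NA_real_, length(onsets))
  prev_end <- 0L
  for (i in seq_along(onsets)) {
    search <- seq(prev_end + 1L, ends[i])
    hit <- search[flags[search]]
    if (length(hit) > 0) delays[i] <- (hit[1] - onsets[i]) * window_len
    prev_end <- ends[i]
  }
  det <- !is.na(delays)
  list(mean_delay = if (any(det)) mean(delays[det]) else NA_real_,
       detected_fraction = mean(det), n_bouts = length(onsets),
       delays = delays)
}

#' Detection delay of a cross-validated session
#'
#' Applies [detection_delay()] within each trial record of a `bci_cv`
#' result (bouts never straddle trials) and pools the per-bout delays.
#'
#' @param cv A [cross_validate_time()] result.
#' @param window_len Window length, seconds.
#' @return List with `mean_delay`, `detected_fraction`, `n_bouts`.
#' @export
session_detection_delay <- function(cv, window_len = 0.08) {
  delays <- numeric(0); n_bouts <- 0L; n_det <- 0L
  for (tr in unique(cv$trial_id)) {
    idx <- which(cv$trial_id == tr)
    if (!any(cv$label[idx] == "error")) next
    dd <- detection_delay(cv$flag[idx], cv$label[idx], window_len)
    delays <- c(delays, dd$delays[!is.na(dd$delays)])
    n_bouts <- n_bouts + dd$n_bouts
    n_det <- n_det + sum(!is.na(dd$delays))
  }
  list(mean_delay = if (length(delays)) mean(delays) else NA_real_,
       detected_fraction = if (n_bouts) n_det / n_bouts else NA_real_,
       n_bouts = n_bouts)
}
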