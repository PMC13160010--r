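#' Train the naive Bayes error classifier
#'
#' Gaussian naive Bayes on per-channel window features with
#' pooled (class-shared) per-feature variances, which makes the decision
#' function linear in the features. Pre-error windows are mapped to the
#' error class when `include_pre_error = TRUE` and to the correct class
#' otherwise; the mapping is the only thing the flag changes. Variances are
#' floored at `var_floor_rel` times the median feature variance.
#'
#' @param windows A [window_features()] tibble (or any tibble with a
#'   `features` matrix column and a `label` column).
#' @param include_pre_error Map pre-error windows to the error class
#'   (default TRUE).
#' @param tau Decision threshold on the error probability (default 0.85,
#'   applied inclusively).
#' @param pooled Use pooled per-feature variances (default TRUE, linear
#'   decision function). `FALSE` gives plain class-specific-variance
#'   Gaussian naive Bayes.
#' @param var_floor_rel Relative variance floor.
#' @param shrink Nearest-shrunken-centroid regularization for the pooled
#'   model: each feature's standardized class-mean difference is
#'   soft-thresholded at `shrink` times its standard error before entering
#'   the weights. The default `NULL` uses the universal threshold
#'   `sqrt(2 log n_features)`, which silences features whose apparent
#'   class difference is indistinguishable from noise (so a classifier
#'   trained on an uninformative population reduces to the prior); genuine
#'   error-signal features pass it untouched. Use `0` for the plain
#'   unregularized model.
#' @return An object of class `error_classifier` with the class means,
#'   (pooled) variances, log priors, threshold and, for the pooled model,
#'   the linear weights `w`, `b` such that the error posterior is
#'   `plogis(w . x + b)`.
#' @export
train_error_classifier <- function(windows, include_pre_error = TRUE,
                                   tau = 0.85, pooled = TRUE,
                                   var_floor_rel = 1e-6, shrink = NULL) {
  if (tau <= 0 || tau > 1) abort("`tau` must be in (0, 1].")
  x <- as.matrix(windows$features)
  y <- map_error_labels(windows$label, include_pre_error)
  if (length(unique(y)) < 2L) {
    abort("Both classes must be present after label mapping.")
  }
  n <- nrow(x)
  mu <- rbind(correct = colMeans(x[y == "correct", , drop = FALSE]),
              error = colMeans(x[y == "error", , drop = FALSE]))
  center <- x - mu[y, , drop = FALSE]
  if (pooled) {
    v <- colSums(center^2) / (n - 2L)
    v <- floor_variances(v, var_floor_rel)
    vars <- rbind(correct = v, error = v)
  } else {
    vars <- rbind(
      correct = apply(x[y == "correct", , drop = FALSE], 2, stats::var),
      error = apply(x[y == "error", , drop = FALSE], 2, stats::var)
    )
    vars <- t(apply(vars, 1, floor_variances, var_floor_rel))
  }
  priors <- c(correct = mean(y == "correct"), error = mean(y == "error"))
  obj <- structure(
    list(class_means = mu, variances = vars, log_priors = log(priors),
         tau = tau, include_pre_error = include_pre_error, pooled = pooled,
         n_features = ncol(x), n_train = n),
    class = "error_classifier"
  )
  if (pooled) {
    v <- vars[1, ]
    if (is.null(shrink)) shrink <- sqrt(2 * log(ncol(x)))
    d <- mu["error", ] - mu["correct", ]
    if (shrink > 0) {
      n_e <- sum(y == "error"); n_c <- sum(y == "correct")
      # windows are temporally autocorrelated (smoothed rates), which
      # deflates the nominal SE of a mean difference; correct it with the
      # average lag-1 autocorrelation (effective-sample-size factor)
      r1 <- mean(vapply(seq_len(ncol(x)), function(j) {
        xs <- x[, j]
        suppressWarnings(stats::cor(xs[-1], xs[-length(xs)]))
      }, numeric(1)), na.rm = TRUE)
      r1 <- min(max(r1, 0), 0.9)
      ess <- sqrt((1 + r1) / (1 - r1))
      se <- ess * sqrt(v * (1 / n_e + 1 / n_c))
      d <- sign(d) * pmax(0, abs(d) - shrink * se)
    }
    obj$shrink <- shrink
    obj$w <- d / v
    # midpoint rule on the (shrunken) difference plus the prior odds
    obj$b <- -sum(obj$w * (mu["error", ] + mu["correct", ]) / 2) +
      obj$log_priors["error"] - obj$log_priors["correct"]
    names(obj$b) <- NULL
  }
  obj
}

map_error_labels <- function(labels, include_pre_error) {
  ifelse(labels == "error" | (include_pre_error & labels == "pre_error"),
         "error", "correct")
}

floor_variances <- function(v, rel) {
  fl <- rel * stats::median(v[v > 0])
  if (!is.finite(fl) || fl <= 0) fl <- rel
  if (any(v < fl)) {
    warn(sprintf("%d feature variance(s) floored.", sum(v < fl)))
    v <- pmax(v, fl)
  }
  v
}

#' Posterior probability of erroneous control
#'
#' Evaluates the naive Bayes error posterior for one window or a matrix of
#' windows. The flag used for modulation and accuracy is
#' `probability >= tau` (threshold inclusive).
#'
#' @param model A trained [train_error_classifier()].
#' @param window Feature vector, feature matrix (rows = windows), or a
#'   tibble with a `features` column.
#' @return Numeric vector of error probabilities in \[0, 1\].
#' @export
predict_error_probability <- function(model, window) {
  x <- if (is.data.frame(window)) as.matrix(window$features)
       else if (is.matrix(window)) window
       else matrix(window, nrow = 1L)
  if (ncol(x) != model$n_features) {
    abort(sprintf("Window has %d features; model expects %d.",
                  ncol(x), model$n_features))
  }
  if (model$pooled) {
    return(as.vector(plogis(x %*% model$w + model$b)))
  }
  ll <- function(cls) {
    v <- model$variances[cls, ]
    -0.5 * colSums((t(x) - model$class_means[cls, ])^2 / v) -
      0.5 * sum(log(v)) + model$log_priors[cls]
  }
  as.vector(plogis(ll("error") - ll("correct")))
}

#' Greedy chance-level accuracy
#'
#' Accuracy of the classifier that always predicts the most populated
#' class: the maximum class frequency. Used as the chance baseline for the
#' unbalanced error/correct classification.
#'
#' @param labels Vector of class labels.
#' @return Scalar accuracy in \[0, 1\].
#' @examples
#' greedy_chance_level(c(rep("a", 7), rep("b", 3)))
#' @export
greedy_chance_level <- function(labels) {
  if (length(labels) == 0L) abort("`labels` must be non-empty.")
  max(table(labels)) / length(labels)
}

#' @export
print.error_classifier <- function(x, ...) {
  cat(sprintf(
    "<error_classifier> %d features, %s variances, tau = %.2f, pre-error %s\n",
    x$n_features, if (x$pooled) "pooled" else "class-specific", x$tau,
    if (x$include_pre_error) "included" else "excluded"))
  invisible(x)
}

#' Tidy an error classifier
#'
#' One row per feature with the class means, (pooled) variance and, for the
#' pooled model, the linear weight.
#'
#' @param x A trained [train_error_classifier()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.error_classifier <- function(x, ...) {
  out <- tibble(
    feature = seq_len(x$n_features),
    mean_correct = x$class_means["correct", ],
    mean_error = x$class_means["error", ],
    variance = x$variances[1, ]
  )
  if (x$pooled) out$weight <- x$w
  out
}

#' Glance at a fitted model
#'
#' One-row summaries of the fitted objects in the package.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.error_classifier <- function(x, ...) {
  tibble(n_features = x$n_features, n_train = x$n_train, tau = x$tau,
         include_pre_error = x$include_pre_error, pooled = x$pooled,
         prior_error = exp(x$log_priors["error"]))
}
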