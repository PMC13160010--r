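# Neural-population subspace comparisons across correct / pre-error /
# error epochs: alignment index with chance level, dimensionality,
# participation ratio, Gaussian mutual information, intent reconstruction,
# LDA projection.

center_cols <- function(x) sweep(as.matrix(x), 2, colMeans(x))

cov_of <- function(x) {
  xc <- center_cols(x)
  crossprod(xc) / (nrow(xc) - 1L)
}

#' Subspace alignment index between two datasets
#'
#' `H(A, B) = tr(V C V') / S`, where `V` is the top-`M` PCA basis of
#' dataset `A` (after mean-centering), `C` the covariance of `B`, and `S`
#' the sum of the first `M` singular values of `C`; the returned value is
#' the symmetrized index `(H(A, B) + H(B, A)) / 2`. It equals 1 when both
#' datasets span the same `M`-dimensional hyperplane and 0 when they live
#' in orthogonal hyperplanes.
#'
#' @param A,B Data matrices (samples x channels), same channel count.
#' @param M Subspace dimensionality (default 10).
#' @param symmetric Return the symmetrized index (default TRUE).
#' @return Scalar in \[0, 1\].
#' @examples
#' set.seed(1)
#' A <- matrix(rnorm(200), 100, 2) %*% matrix(rnorm(2 * 6), 2, 6)
#' alignment_index(A, A, M = 2)
#' @export
alignment_index <- function(A, B, M = 10, symmetric = TRUE) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) abort("`A` and `B` must share channels.")
  if (nrow(A) <= M || nrow(B) <= M) {
    abort("Both datasets need more than M samples.")
  }
  h <- function(X, Y, nameX) {
    eX <- eigen(cov_of(X), symmetric = TRUE)
    rnk <- sum(eX$values > max(eX$values[1], 0) * 1e-12)
    if (rnk < M) {
      abort(sprintf("Dataset %s has rank %d < M = %d.", nameX, rnk, M))
    }
    V <- eX$vectors[, seq_len(M), drop = FALSE]        # N x M
    C <- cov_of(Y)
    S <- sum(sort(eigen(C, symmetric = TRUE, only.values = TRUE)$values,
                  decreasing = TRUE)[seq_len(M)])
    if (S <= 0) abort(sprintf("Dataset %s has zero variance.",
                              if (nameX == "A") "B" else "A"))
    sum(diag(crossprod(V, C %*% V))) / S
  }
  hab <- h(A, B, "A")
  if (!symmetric) return(hab)
  (hab + h(B, A, "B")) / 2
}

#' Chance level for the alignment index
#'
#' The joined dataset `rbind(A, B)` is split into `n_chunks` contiguous
#' chunks of (near-)equal size; for each repeat a random half of the chunks
#' forms one sub-dataset and the other half the second, and their
#' (symmetrized) alignment index is collected. An observed index below this
#' chance distribution indicates that the two datasets are more misaligned
#' than sampling noise alone explains; the reported `p_below` is the
#' fraction of chance values at or below the observed index.
#'
#' @inheritParams alignment_index
#' @param n_chunks Number of contiguous chunks (even, default 40).
#' @param n_repeats Number of random half-splits (default 100).
#' @return List with `observed`, `chance` (vector), `p_below` and the
#'   chance quantiles `lo` / `hi` (2.5% / 97.5%).
#' @export
alignment_chance_level <- function(A, B, M = 10, n_chunks = 40,
                                   n_repeats = 100) {
  if (n_chunks %% 2L != 0L) abort("`n_chunks` must be even.")
  joined <- rbind(as.matrix(A), as.matrix(B))
  n <- nrow(joined)
  if (n < n_chunks) abort("Joined dataset shorter than `n_chunks`.")
  chunk <- as.integer(cut(seq_len(n), n_chunks, labels = FALSE))
  observed <- alignment_index(A, B, M)
  chance <- vapply(seq_len(n_repeats), function(r) {
    half <- sample.int(n_chunks, n_chunks / 2L)
    alignment_index(joined[chunk %in% half, , drop = FALSE],
                    joined[!(chunk %in% half), , drop = FALSE], M)
  }, numeric(1))
  list(observed = observed, chance = chance,
       p_below = mean(chance <= observed),
       lo = unname(quantile(chance, 0.025)),
       hi = unname(quantile(chance, 0.975)))
}

#' PCA dimensionality at a variance threshold
#'
#' The smallest number of principal components whose cumulative eigenvalue
#' fraction reaches `variance_threshold` (default 80%).
#'
#' @param data Data matrix (samples x channels), or `NULL` when
#'   `eigenvalues` are given directly.
#' @param variance_threshold Cumulative variance fraction (default 0.80).
#' @param eigenvalues Optional covariance eigenvalues (descending or not).
#' @return Integer dimensionality.
#' @examples
#' pca_dimensionality(eigenvalues = c(0.5, 0.3, 0.1, 0.1))
#' @export
pca_dimensionality <- function(data = NULL, variance_threshold = 0.80,
                               eigenvalues = NULL) {
  ev <- eigenvalues_of(data, eigenvalues)
  total <- sum(ev)
  if (total <= 0) abort("Zero total variance.")
  as.integer(which(cumsum(ev) / total >= variance_threshold - 1e-12)[1])
}

#' Participation ratio
#'
#' Effective dimensionality from the spread of the covariance eigenvalues,
#' `PR = (sum lambda)^2 / sum lambda^2`; equals 1 for rank-1 data and `N`
#' for isotropic `N`-dimensional data.
#'
#' @inheritParams pca_dimensionality
#' @return Scalar in \[1, N\].
#' @examples
#' participation_ratio(eigenvalues = c(3, 1))  # 16/10
#' @export
participation_ratio <- function(data = NULL, eigenvalues = NULL) {
  ev <- eigenvalues_of(data, eigenvalues)
  if (sum(ev) <= 0) abort("Zero total variance.")
  sum(ev)^2 / sum(ev^2)
}

eigenvalues_of <- function(data, eigenvalues) {
  if (!is.null(eigenvalues)) {
    ev <- sort(eigenvalues, decreasing = TRUE)
  } else {
    if (is.null(data)) abort("Provide `data` or `eigenvalues`.")
    if (nrow(data) < 2L) abort("Need at least 2 samples.")
    ev <- eigen(cov_of(data), symmetric = TRUE, only.values = TRUE)$values
  }
  pmax(ev, 0)
}

#' Gaussian mutual information between two variable blocks
#'
#' `I(X; Y) = H(X) + H(Y) - H(X, Y)` with the Gaussian entropy
#' `H = k/2 log(2 pi e) + 1/2 log det(Sigma)` evaluated on the empirical
#' covariances of `X`, `Y` and the joined block. Covariances are
#' regularized by adding `reg` times the mean diagonal to the diagonal, and
#' the reported MI is floored at 0.
#'
#' @param X Matrix (time x k), e.g. the motor intent.
#' @param Y Matrix (time x N), e.g. neural activity.
#' @param reg Relative diagonal regularization (default 1e-6).
#' @return Mutual information in nats (>= 0).
#' @export
gaussian_mi <- function(X, Y, reg = 1e-6) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) abort("`X` and `Y` lengths differ.")
  gaussian_mi_from_cov(cov_of(cbind(X, Y)), ncol(X), reg = reg)
}

#' Gaussian mutual information from a joint covariance
#'
#' Entropy-decomposition MI for a given joint covariance whose first `k`
#' rows/columns are the `X` block. With a block-diagonal joint covariance
#' the MI is exactly 0.
#'
#' @param joint_cov Joint covariance matrix of `(X, Y)`.
#' @param k Dimension of the `X` block.
#' @param reg Relative diagonal regularization (default 0: analytic
#'   covariances need none).
#' @param floor_zero Floor the reported value at 0 (default TRUE).
#' @return Mutual information in nats.
#' @examples
#' S <- diag(4)
#' gaussian_mi_from_cov(S, 2)  # independent blocks: 0
#' @export
gaussian_mi_from_cov <- function(joint_cov, k, reg = 0, floor_zero = TRUE) {
  S <- as.matrix(joint_cov)
  d <- ncol(S)
  if (k < 1 || k >= d) abort("`k` must split the joint covariance.")
  if (reg > 0) S <- S + diag(reg * mean(diag(S)), d)
  ldet <- function(m) {
    v <- determinant(m, logarithm = TRUE)
    if (v$sign <= 0) abort("Covariance not positive definite; increase `reg`.")
    as.numeric(v$modulus)
  }
  ix <- seq_len(k); iy <- (k + 1L):d
  mi <- 0.5 * (ldet(S[ix, ix, drop = FALSE]) + ldet(S[iy, iy, drop = FALSE]) -
                 ldet(S))
  if (floor_zero) max(mi, 0) else mi
}

#' Linear reconstruction of motor intent from neural activity
#'
#' Least-squares weights mapping the neural matrix `Y` (time x N) onto the
#' intent matrix `X` (time x 2): `W = (Y'Y)^-1 Y'X`, `Xhat = Y W` (both
#' blocks mean-centered). When `Y'Y` is ill-conditioned or there are fewer
#' samples than channels, a small ridge is applied and reported. The score
#' is the mean Pearson correlation between the actual and reconstructed x
#' and y intent components.
#'
#' @param X Intent matrix, time x 2.
#' @param Y Neural matrix, time x N.
#' @return An object of class `intent_regression`: `weights`, `fitted`,
#'   `score`, `r` (per-column correlations), `ridge`.
#' @export
reconstruct_intent <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) abort("`X` and `Y` lengths differ.")
  if (any(apply(X, 2, stats::sd) < .Machine$double.eps)) {
    abort("Constant intent column; correlation undefined.")
  }
  Xc <- center_cols(X); Yc <- center_cols(Y)
  G <- crossprod(Yc)
  ridge <- 0
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (nrow(Y) <= ncol(Y) || min(ev) < 1e-10 * max(ev)) {
    ridge <- 1e-6 * mean(diag(G))
  }
  W <- solve(G + diag(ridge, ncol(Y)), crossprod(Yc, Xc))
  fitted <- Yc %*% W
  r <- col_cor(Xc, fitted)
  structure(list(weights = W, fitted = fitted, score = mean(r), r = r,
                 ridge = ridge),
            class = "intent_regression")
}

#' @export
print.intent_regression <- function(x, ...) {
  cat(sprintf("<intent_regression> score %.3f (rx %.3f, ry %.3f)%s\n",
              x$score, x$r[1], x$r[2],
              if (x$ridge > 0) sprintf(", ridge %.2g", x$ridge) else ""))
  invisible(x)
}

#' @rdname glance.error_classifier
#' @export
glance.intent_regression <- function(x, ...) {
  tibble(score = x$score, r_x = x$r[1], r_y = x$r[2], ridge = x$ridge)
}

#' Two-component LDA projection of labeled activity
#'
#' Linear discriminant projection onto the two leading discriminant
#' directions, with the within-class scatter shrunk towards a scaled
#' identity (`(1 - shrinkage) W + shrinkage * tr(W)/p * I`) for stability
#' with many channels. Intended for visualizing the separability of the
#' correct / pre-error / error epochs.
#'
#' @param data Matrix (samples x channels).
#' @param labels Class label per sample; at least 3 classes with >= 2
#'   samples each.
#' @param shrinkage Within-class scatter shrinkage in \[0, 1\] (default
#'   0.1).
#' @return List with `projection` (samples x 2), `basis` (channels x 2),
#'   `class_means` (projected class means) and `labels`.
#' @export
lda_project <- function(data, labels, shrinkage = 0.1) {
  x <- as.matrix(data)
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) < 3L) abort("Need at least 3 classes.")
  if (any(table(labels) < 2L)) abort("Each class needs >= 2 samples.")
  p <- ncol(x)
  mu <- colMeans(x)
  Wm <- matrix(0, p, p); Bm <- matrix(0, p, p)
  for (c in cls) {
    xi <- x[labels == c, , drop = FALSE]
    mc <- colMeans(xi)
    Wm <- Wm + crossprod(sweep(xi, 2, mc))
    Bm <- Bm + nrow(xi) * tcrossprod(mc - mu)
  }
  Wm <- Wm / (nrow(x) - length(cls))
  Bm <- Bm / (length(cls) - 1L)
  Ws <- (1 - shrinkage) * Wm + shrinkage * (sum(diag(Wm)) / p) * diag(p)
  # generalized eigenproblem Bm v = lambda Ws v via whitening
  cw <- chol(Ws)
  iL <- backsolve(cw, diag(p))          # U^-1 with Ws = U'U
  Msym <- t(iL) %*% Bm %*% iL
  es <- eigen((Msym + t(Msym)) / 2, symmetric = TRUE)
  basis <- iL %*% es$vectors[, 1:2, drop = FALSE]
  basis <- sweep(basis, 2, sqrt(colSums(basis^2)), "/")
  proj <- sweep(x, 2, mu) %*% basis
  cm <- do.call(rbind, lapply(cls, function(c)
    colMeans(proj[labels == c, , drop = FALSE])))
  rownames(cm) <- cls
  list(projection = proj, basis = basis, class_means = cm, labels = labels)
}

#' Compare neural subspaces across control epochs
#'
#' Full per-session population comparison of the correct, pre-error and
#' error epochs from labeled feature windows: pairwise (symmetrized)
#' alignment indices with their chunk-shuffle chance levels, PCA
#' dimensionality and participation ratio per epoch, and Gaussian MI and
#' linear intent-reconstruction score per epoch. To remove
#' sample-size-dependent estimation bias from the across-epoch comparison,
#' all classes are subsampled to the smallest class count
#' (`balance = TRUE`); MI and reconstruction are computed after projecting
#' the features onto the top `mi_components` principal components of the
#' pooled data (one shared basis for all epochs).
#'
#' @param windows A [window_features()] tibble with `label`, `intent_x`,
#'   `intent_y` and the `features` matrix column.
#' @param M Alignment subspace dimensionality (default 10).
#' @param n_chunks Chunks for the chance level (default 40).
#' @param n_repeats Chance-level repeats (default 100).
#' @param variance_threshold PCA dimensionality threshold (default 0.80).
#' @param mi_components Pooled-PCA dimensionality for MI and intent
#'   reconstruction (default 20).
#' @param balance Subsample all classes to the smallest class (default
#'   TRUE).
#' @param seed Seed for the subsampling and chance shuffles.
#' @return A tibble with columns `statistic`, `epoch` (or `pair`), `value`,
#'   `chance_lo`, `chance_hi`, `p_below` (alignment rows only).
#' @export
compare_epochs <- function(windows, M = 10, n_chunks = 40, n_repeats = 100,
                           variance_threshold = 0.80, mi_components = 20,
                           balance = TRUE, seed = 1L) {
  cls <- c("correct", "pre_error", "error")
  missing <- setdiff(cls, unique(windows$label))
  if (length(missing) > 0) {
    warn(sprintf("Missing epoch class(es): %s; partial report.",
                 paste(missing, collapse = ", ")))
    cls <- setdiff(cls, missing)
  }
  set.seed(seed)
  feats <- as.matrix(windows$features)
  intent <- cbind(windows$intent_x, windows$intent_y)
  idx_by <- lapply(cls, function(c) which(windows$label == c))
  names(idx_by) <- cls
  if (balance) {
    # equalize the correct / error sample counts (the headline comparison)
    # so estimation bias is shared; the scarcer pre-error class keeps its
    # own count rather than crippling every estimate
    main <- intersect(c("correct", "error"), cls)
    if (length(main) == 2L) {
      n_min <- min(lengths(idx_by[main]))
      idx_by[main] <- lapply(idx_by[main], function(i) sort(sample(i, n_min)))
    }
  }
  # shared low-d basis for MI / reconstruction
  pooled <- feats[unlist(idx_by), , drop = FALSE]
  pc <- prcomp(pooled, center = TRUE, scale. = FALSE)
  kc <- min(mi_components, ncol(pc$rotation))
  proj <- function(x) sweep(x, 2, pc$center) %*% pc$rotation[, seq_len(kc)]

  rows <- list()
  for (c in cls) {
    Fi <- feats[idx_by[[c]], , drop = FALSE]
    Xi <- intent[idx_by[[c]], , drop = FALSE]
    rows[[length(rows) + 1L]] <- tibble(
      statistic = c("pca_dimensionality", "participation_ratio",
                    "mutual_information", "intent_score"),
      epoch = c, pair = NA_character_,
      value = c(pca_dimensionality(Fi, variance_threshold),
                participation_ratio(Fi),
                gaussian_mi(Xi, proj(Fi)),
                reconstruct_intent(Xi, proj(Fi))$score),
      chance_lo = NA_real_, chance_hi = NA_real_, p_below = NA_real_
    )
  }
  if (length(cls) > 1L) {
    for (pr in utils::combn(cls, 2, simplify = FALSE)) {
      A <- feats[idx_by[[pr[1]]], , drop = FALSE]
      B <- feats[idx_by[[pr[2]]], , drop = FALSE]
      # short sessions: drop to the largest even chunk count the data allow
      nc <- min(n_chunks, 2L * floor((nrow(A) + nrow(B)) / 4L))
      if (nc < n_chunks) {
        warn(sprintf("Pair %s: reducing chance-level chunks to %d.",
                     paste(pr, collapse = " vs "), nc))
      }
      al <- alignment_chance_level(A, B, M = M, n_chunks = nc,
                                   n_repeats = n_repeats)
      rows[[length(rows) + 1L]] <- tibble(
        statistic = "alignment_index", epoch = NA_character_,
        pair = paste(pr, collapse = " vs "),
        value = al$observed, chance_lo = al$lo, chance_hi = al$hi,
        p_below = al$p_below
      )
    }
  }
  dplyr::bind_rows(rows)
}
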