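test_that("alignment index hits its analytic limits", {
  set.seed(1)
  basis <- qr.Q(qr(matrix(rnorm(50 * 10), 50, 10)))
  A <- matrix(rnorm(400 * 10), 400, 10) %*% t(basis)
  B <- matrix(rnorm(400 * 10), 400, 10) %*% t(basis)
  expect_equal(alignment_index(A, B, M = 10), 1, tolerance = 1e-9)
  # orthogonal subspaces in a 20-dim ambient space
  A2 <- cbind(matrix(rnorm(300 * 10), 300, 10), matrix(0, 300, 10))
  B2 <- cbind(matrix(0, 300, 10), matrix(rnorm(300 * 10), 300, 10))
  expect_equal(alignment_index(A2, B2, M = 10), 0, tolerance = 1e-12)
})

test_that("alignment index matches an independent SVD oracle", {
  set.seed(2)
  for (i in 1:5) {
    A <- matrix(rnorm(200 * 50), 200, 50)
    B <- matrix(rnorm(200 * 50), 200, 50)
    got <- alignment_index(A, B, M = 10)
    expect_gt(got, 0); expect_lt(got, 1)
    expect_equal(got, alignment_oracle(A, B, 10), tolerance = 1e-10)
  }
})

test_that("alignment index is symmetric, bounded and validates rank", {
  set.seed(3)
  A <- matrix(rnorm(150 * 12), 150, 12)
  B <- matrix(rnorm(150 * 12), 150, 12)
  expect_equal(alignment_index(A, B, M = 5), alignment_index(B, A, M = 5))
  low_rank <- matrix(rnorm(100 * 3), 100, 3) %*% matrix(rnorm(3 * 12), 3, 12)
  expect_error(alignment_index(low_rank, B, M = 5), "rank")
})

test_that("chance level uses contiguous equal chunks and flags misalignment", {
  set.seed(4)
  # one stationary process: observed alignment within the central chance mass
  base <- matrix(rnorm(8 * 30), 8, 30)
  A <- matrix(rnorm(400 * 8), 400, 8) %*% base +
    matrix(rnorm(400 * 30, sd = 0.5), 400, 30)
  B <- matrix(rnorm(400 * 8), 400, 8) %*% base +
    matrix(rnorm(400 * 30, sd = 0.5), 400, 30)
  cl <- alignment_chance_level(A, B, M = 5, n_chunks = 40, n_repeats = 60)
  expect_gt(cl$p_below, 0.02)
  # orthogonal subspaces: observed below every chance value
  A2 <- cbind(matrix(rnorm(200 * 5), 200, 5), matrix(0, 200, 5))
  B2 <- cbind(matrix(0, 200, 5), matrix(rnorm(200 * 5), 200, 5))
  cl2 <- alignment_chance_level(A2, B2, M = 3, n_chunks = 20, n_repeats = 40)
  expect_equal(cl2$p_below, 0)
  expect_true(all(cl2$chance > cl2$observed))
  expect_error(alignment_chance_level(A, B, M = 5, n_chunks = 39), "even")
  # chunk sizes differ by at most one sample
  chunk <- as.integer(cut(seq_len(803), 40, labels = FALSE))
  expect_lte(diff(range(table(chunk))), 1)
})

test_that("PCA dimensionality counts components to the variance threshold", {
  expect_equal(pca_dimensionality(eigenvalues = c(0.5, 0.3, 0.1, 0.1)), 2L)
  expect_equal(pca_dimensionality(eigenvalues = rep(1, 10)), 8L)
  set.seed(5)
  rank1 <- matrix(rnorm(100), 100, 1) %*% t(rep(1, 6))
  expect_equal(pca_dimensionality(rank1), 1L)
  expect_error(pca_dimensionality(eigenvalues = rep(0, 3)), "variance")
})

test_that("participation ratio measures eigenvalue spread", {
  expect_equal(participation_ratio(eigenvalues = c(3, 1)), 1.6)
  expect_equal(participation_ratio(eigenvalues = rep(2, 7)), 7)
  set.seed(6)
  iso <- exact_cov_data(rep(1, 9), n = 60)
  expect_equal(participation_ratio(iso), 9, tolerance = 1e-8)
  rank1 <- matrix(rnorm(80), 80, 1) %*% t(c(1, 2, 3))
  expect_equal(participation_ratio(rank1), 1, tolerance = 1e-10)
  # bounds on arbitrary data
  x <- matrix(rnorm(200 * 12), 200, 12)
  pr <- participation_ratio(x)
  expect_gte(pr, 1); expect_lte(pr, 12)
})

test_that("Gaussian MI reproduces the analytic closed forms", {
  # block-diagonal joint covariance: exactly zero
  S <- diag(c(1, 2, rep(1.5, 10)))
  expect_equal(gaussian_mi_from_cov(S, 2), 0)
  # bivariate correlation rho: -log(1 - rho^2) / 2
  rho <- 0.8
  S2 <- matrix(c(1, rho, rho, 1), 2)
  expect_equal(gaussian_mi_from_cov(S2, 1), -0.5 * log(1 - rho^2),
               tolerance = 1e-6)
  expect_equal(gaussian_mi_from_cov(S2, 1), 0.5108256, tolerance = 1e-6)
  # invariance under invertible linear maps of X
  set.seed(7)
  A <- matrix(rnorm(9), 3, 3)
  Sx <- crossprod(matrix(rnorm(25), 5, 5))[1:3, 1:3]
  Sxy <- matrix(rnorm(6, sd = 0.1), 3, 2)
  Sy <- diag(2)
  J <- rbind(cbind(Sx, Sxy), cbind(t(Sxy), Sy))
  Jt <- rbind(cbind(A %*% Sx %*% t(A), A %*% Sxy),
              cbind(t(Sxy) %*% t(A), Sy))
  expect_equal(gaussian_mi_from_cov(J, 3), gaussian_mi_from_cov(Jt, 3),
               tolerance = 1e-9)
  # data interface is non-negative and near zero for independent samples
  X <- matrix(rnorm(2000), 1000, 2)
  Y <- matrix(rnorm(3000), 1000, 3)
  expect_gte(gaussian_mi(X, Y), 0)
  expect_lt(gaussian_mi(X, Y), 0.02)
})

test_that("intent reconstruction scores behave as a regression should", {
  set.seed(8)
  X <- matrix(rnorm(600), 300, 2)
  G <- matrix(rnorm(2 * 20), 2, 20)
  Y <- X %*% G
  fit <- reconstruct_intent(X, Y)
  expect_equal(fit$score, 1, tolerance = 1e-8)
  # independent neural data: score near 0 within sampling noise
  Y2 <- matrix(rnorm(300 * 20), 300, 20)
  expect_lt(abs(reconstruct_intent(X, Y2)$score), 3 / sqrt(300) + 0.25)
  # additive noise decreases the expected score monotonically
  scores <- vapply(c(0.5, 2, 8), function(s) {
    mean(vapply(1:5, function(i) {
      Yn <- Y + matrix(rnorm(length(Y), sd = s), nrow(Y), ncol(Y))
      reconstruct_intent(X, Yn)$score
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
  expect_error(reconstruct_intent(cbind(rep(1, 10), rnorm(10)),
                                  matrix(rnorm(50), 10, 5)), "Constant")
})

test_that("LDA projection separates separable classes in 2 components", {
  set.seed(9)
  mk <- function(mu, n = 60) sweep(matrix(rnorm(n * 10), n, 10), 2, mu, "+")
  x <- rbind(mk(rep(0, 10)), mk(rep(4, 10)), mk(c(rep(0, 5), rep(4, 5))))
  lab <- rep(c("correct", "error", "pre_error"), each = 60)
  out <- lda_project(x, lab)
  expect_equal(ncol(out$projection), 2L)
  within <- mean(vapply(unique(lab), function(c)
    mean(apply(out$projection[lab == c, ], 2, sd)), numeric(1)))
  between <- mean(dist(out$class_means))
  expect_gt(between / within, 3)
  # identical distributions: near-zero separation
  x0 <- matrix(rnorm(180 * 10), 180, 10)
  out0 <- lda_project(x0, lab)
  between0 <- mean(dist(out0$class_means))
  expect_lt(between0, between / 5)
  expect_error(lda_project(x[1:120, ], lab[1:120]), "3 classes")
})

test_that("cross-check: our LDA agrees with the reference on easy data", {
  skip_if_not_installed("MASS")
  set.seed(10)
  mk <- function(mu, n = 80) sweep(matrix(rnorm(n * 6), n, 6), 2, mu, "+")
  x <- rbind(mk(c(3, 0, 0, 0, 0, 0)), mk(c(0, 3, 0, 0, 0, 0)),
             mk(c(0, 0, 3, 0, 0, 0)))
  lab <- rep(c("a", "b", "c"), each = 80)
  ours <- lda_project(x, lab, shrinkage = 0.01)
  ref <- MASS::lda(x, grouping = lab)
  q1 <- qr.Q(qr(ours$basis))
  q2 <- qr.Q(qr(ref$scaling[, 1:2]))
  expect_gt(min(svd(crossprod(q1, q2))$d), 0.98)
})

test_that("epoch comparison reports the full per-session statistics table", {
  w <- small_windows()
  rep <- suppressWarnings(compare_epochs(w, M = 5, n_chunks = 20,
                                         n_repeats = 20, mi_components = 10))
  expect_setequal(unique(rep$statistic),
                  c("pca_dimensionality", "participation_ratio",
                    "mutual_information", "intent_score", "alignment_index"))
  expect_equal(sum(rep$statistic == "alignment_index"), 3L)
  al <- rep[rep$statistic == "alignment_index", ]
  expect_true(all(al$value >= 0 & al$value <= 1))
  expect_true(all(al$chance_lo <= al$chance_hi))
  # missing class yields a partial report with a warning
  w2 <- w[w$label != "pre_error", ]
  expect_warning(rep2 <- compare_epochs(w2, M = 5, n_chunks = 20,
                                        n_repeats = 10, mi_components = 10),
                 "pre_error")
  expect_equal(sum(rep2$statistic == "alignment_index"), 1L)
})

test_that("alignment orderings are stable across subspace dimensionalities", {
  w <- small_windows()
  f <- as.matrix(w$features)
  A <- f[w$label == "correct", ]
  B <- f[w$label == "error", ]
  C <- f[w$label == "pre_error", ]
  ord <- vapply(c(5, 10, 15), function(M) {
    vals <- c(alignment_index(A, B, M), alignment_index(A, C, M),
              alignment_index(B, C, M))
    order(vals)[3]  # index of the most aligned pair
  }, numeric(1))
  # the most aligned pair does not change with M
  expect_equal(length(unique(ord)), 1L)
})
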