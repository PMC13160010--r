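#' Maximum-likelihood factor analysis by EM
#'
#' Fits the linear-Gaussian factor model `x = mu + L z + eps`,
#' `eps ~ N(0, diag(psi))`, by expectation-maximization on the sample
#' covariance. Constant (zero-variance) channels are excluded with a
#' warning and their indices reported in the fitted object. The
#' log-likelihood trace is stored and is non-decreasing.
#'
#' @param rates Data matrix, time x channels (smoothed firing rates).
#' @param n_factors Number of latent factors (default 20).
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood convergence tolerance.
#' @return An object of class `fa_model`: `loading` (channels x factors),
#'   `psi` (uniquenesses), `mean`, `beta` (projection matrix,
#'   factors x channels, for `E[z | x] = beta (x - mean)`), `loglik`
#'   (per-iteration trace), `excluded` (indices of constant channels).
#' @examples
#' set.seed(1)
#' z <- matrix(rnorm(500 * 3), 500, 3)
#' x <- z %*% matrix(rnorm(3 * 10), 3, 10) + matrix(rnorm(5000, sd = .3), 500, 10)
#' fit <- fit_factor_analysis(x, n_factors = 3)
#' all(diff(fit$loglik) > -1e-8)
#' @export
fit_factor_analysis <- function(rates, n_factors = 20, max_iter = 100,
                                tol = 1e-6) {
  rates <- as.matrix(rates)
  n <- nrow(rates); p_all <- ncol(rates)
  if (n_factors > p_all) abort("`n_factors` cannot exceed the channel count.")
  if (n <= n_factors) abort("Need more time samples than factors.")
  v <- apply(rates, 2, stats::var)
  excluded <- which(v < .Machine$double.eps)
  if (length(excluded) > 0) {
    warn(sprintf("Excluding %d constant channel(s): %s",
                 length(excluded),
                 paste(utils::head(excluded, 10), collapse = ", ")))
  }
  keep <- setdiff(seq_len(p_all), excluded)
  if (length(keep) < n_factors) {
    abort("`n_factors` exceeds the number of non-degenerate channels.")
  }
  x <- rates[, keep, drop = FALSE]
  p <- ncol(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  S <- crossprod(xc) / n
  # init from PCA
  es <- eigen(S, symmetric = TRUE)
  lam0 <- pmax(es$values[seq_len(n_factors)], 1e-8)
  L <- es$vectors[, seq_len(n_factors), drop = FALSE] %*% diag(sqrt(lam0), n_factors)
  psi <- pmax(diag(S) - rowSums(L^2), 1e-6 * mean(diag(S)))
  loglik <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    # E-step via Woodbury: beta = (I + L' Psi^-1 L)^-1 L' Psi^-1
    LtPi <- t(L) / rep(psi, each = n_factors)          # k x p
    G <- diag(n_factors) + LtPi %*% L                  # k x k
    cG <- chol(G)
    beta <- backsolve(cG, forwardsolve(t(cG), LtPi))   # k x p
    SbT <- S %*% t(beta)                               # p x k
    Ezz <- diag(n_factors) - beta %*% L + beta %*% SbT # k x k
    # M-step
    L_new <- SbT %*% solve(Ezz)
    psi_new <- pmax(diag(S) - rowSums(L_new * SbT), 1e-8 * mean(diag(S)))
    # log-likelihood of the *current* (pre-update) parameters
    # logdet(LL' + Psi) = logdet(G) + sum(log psi)
    logdet <- 2 * sum(log(diag(cG))) + sum(log(psi))
    # tr(Sigma^-1 S) with Sigma^-1 = Psi^-1 - Psi^-1 L beta
    tr_term <- sum(diag(S) / psi) - sum(t(beta) * (S %*% (L / psi)))
    ll <- -n / 2 * (p * log(2 * pi) + logdet + tr_term)
    loglik <- c(loglik, ll)
    L <- L_new; psi <- psi_new
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll_old)) break
    ll_old <- ll
  }
  LtPi <- t(L) / rep(psi, each = n_factors)
  G <- diag(n_factors) + LtPi %*% L
  beta <- solve(G, LtPi)
  structure(
    list(loading = L, psi = psi, mean = mu, beta = beta,
         n_factors = n_factors, loglik = loglik, excluded = excluded,
         kept = keep, n_channels = p_all),
    class = "fa_model"
  )
}

#' Project data onto factor-analysis latents
#'
#' Posterior mean of the latent factors, `E[z | x] = beta (x - mean)`,
#' applied row-wise.
#'
#' @param fa A fitted [fit_factor_analysis()] model.
#' @param rates Matrix (time x channels) or a single bin vector.
#' @return Matrix of factor scores (time x n_factors).
#' @export
fa_project <- function(fa, rates) {
  if (is.vector(rates)) rates <- matrix(rates, nrow = 1L)
  x <- rates[, fa$kept, drop = FALSE]
  sweep(x, 2, fa$mean) %*% t(fa$beta)
}
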