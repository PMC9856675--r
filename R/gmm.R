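# Univariate Gaussian mixture fitting by expectation-maximization.
#
# Two variance structures are distinguished: "component" (one variance per
# component; in one dimension the spherical, diagonal and full covariance
# parameterizations all reduce to this) and "tied" (a single shared
# variance). Restarts use random data points as initial means; the best
# log-likelihood fit is kept. Callers manage the RNG state.

row_max <- function(m) {
  out <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) out <- pmax(out, m[, j])
  out
}

gmm1d_fit <- function(x, k, variance = c("component", "tied"),
                      restarts = 10, max_iter = 300, tol = 1e-7) {
  variance <- match.arg(variance)
  n <- length(x)
  stopifnot(n >= k, k >= 1)
  vfloor <- max(1e-6 * stats::var(x), 1e-12)
  if (!is.finite(vfloor) || vfloor == 0) stop("degenerate input: zero variance")

  best <- NULL
  for (r in seq_len(restarts)) {
    mu <- sort(sample(x, k))
    sig2 <- rep(stats::var(x) / k, k)
    w <- rep(1 / k, k)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      # E-step in log space
      lg <- vapply(seq_len(k), function(j) {
        log(w[j]) + stats::dnorm(x, mu[j], sqrt(sig2[j]), log = TRUE)
      }, numeric(n))
      if (k == 1) dim(lg) <- c(n, 1)
      m <- row_max(lg)
      lse <- m + log(rowSums(exp(lg - m)))
      ll <- sum(lse)
      resp <- exp(lg - lse)
      # M-step
      nk <- colSums(resp)
      if (any(nk < 1e-10)) { ll <- -Inf; break }
      w <- nk / n
      mu <- colSums(resp * x) / nk
      if (variance == "component") {
        sig2 <- pmax(colSums(resp * (x - rep(mu, each = n))^2) / nk, vfloor)
      } else {
        sig2 <- rep(max(sum(resp * (x - rep(mu, each = n))^2) / n, vfloor), k)
      }
      if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
      ll_old <- ll
    }
    if (is.finite(ll)) {
      # the loop's ll predates the last M-step; report it at the final params
      lg <- vapply(seq_len(k), function(j) {
        log(w[j]) + stats::dnorm(x, mu[j], sqrt(sig2[j]), log = TRUE)
      }, numeric(n))
      if (k == 1) dim(lg) <- c(n, 1)
      m <- row_max(lg)
      ll <- sum(m + log(rowSums(exp(lg - m))))
    }
    if (is.finite(ll) && (is.null(best) || ll > best$loglik)) {
      ord <- order(mu)
      best <- list(means = mu[ord], variances = sig2[ord], weights = w[ord],
                   loglik = ll, n_iter = it)
    }
  }
  if (is.null(best)) stop("EM failed to converge for any restart")
  best$variance <- variance
  best$k <- k
  best
}

gmm1d_n_params <- function(k, variance) {
  # means + variances + free weights
  if (variance == "tied") k + 1 + (k - 1) else 2 * k + (k - 1)
}

gmm1d_bic <- function(fit, n) {
  gmm1d_n_params(fit$k, fit$variance) * log(n) - 2 * fit$loglik
}

gmm1d_responsibilities <- function(means, variances, weights, x) {
  k <- length(means)
  lg <- vapply(seq_len(k), function(j) {
    log(weights[j]) + stats::dnorm(x, means[j], sqrt(variances[j]), log = TRUE)
  }, numeric(length(x)))
  lg <- matrix(lg, length(x), k)
  m <- row_max(lg)
  exp(lg - (m + log(rowSums(exp(lg - m)))))
}
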