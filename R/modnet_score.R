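#' Normal-gamma score prior
#'
#' Conjugate normal-gamma hyperparameters for the Bayesian module score:
#' expression values in a leaf are modelled as exchangeable
#' `N(mu, 1/tau)` draws with `(mu, tau) ~ NormalGamma(mu0, lambda0, alpha0,
#' beta0)`. Defaults are tuned for per-probe-centered log2 tumor/normal
#' ratios (mean 0, unit-scale spread).
#'
#' @param mu0 prior mean.
#' @param lambda0 prior precision-scaling pseudo-count (> 0).
#' @param alpha0,beta0 gamma shape/rate on the precision (> 0).
#' @return a `score_prior` object.
#' @export
score_prior <- function(mu0 = 0, lambda0 = 1, alpha0 = 1, beta0 = 0.1) {
  stopifnot(lambda0 > 0, alpha0 > 0, beta0 > 0)
  structure(list(mu0 = mu0, lambda0 = lambda0, alpha0 = alpha0,
                 beta0 = beta0), class = "score_prior")
}

## Vectorized log marginal from sufficient statistics (n, sum, sum of
## squares). Empty leaves score 0.
leaf_log_marginal_ss <- function(n, s1, s2, prior) {
  out <- numeric(length(n))
  pos <- n > 0
  if (!any(pos)) return(out)
  n <- n[pos]; s1 <- s1[pos]; s2 <- s2[pos]
  xbar <- s1 / n
  ss <- pmax(s2 - s1^2 / n, 0)
  lambda_n <- prior$lambda0 + n
  alpha_n <- prior$alpha0 + n / 2
  beta_n <- prior$beta0 + ss / 2 +
    prior$lambda0 * n * (xbar - prior$mu0)^2 / (2 * lambda_n)
  out[pos] <- -(n / 2) * log(2 * pi) +
    0.5 * (log(prior$lambda0) - log(lambda_n)) +
    prior$alpha0 * log(prior$beta0) - alpha_n * log(beta_n) +
    lgamma(alpha_n) - lgamma(prior$alpha0)
  out
}

#' Leaf log marginal likelihood
#'
#' Closed-form log marginal likelihood of a set of exchangeable
#' observations under the normal-gamma model: with `lambda_n = lambda0 + n`,
#' `alpha_n = alpha0 + n/2` and
#' `beta_n = beta0 + SS/2 + lambda0 n (xbar - mu0)^2 / (2 lambda_n)`,
#' `log p(x) = -(n/2) log 2 pi + (log lambda0 - log lambda_n)/2 +
#' alpha0 log beta0 - alpha_n log beta_n + log Gamma(alpha_n) -
#' log Gamma(alpha0)`. The empty set scores 0.
#'
#' @param values numeric vector of observations (finite).
#' @param prior a [score_prior()].
#' @return scalar log marginal likelihood.
#' @export
leaf_log_marginal <- function(values, prior = score_prior()) {
  stopifnot(all(is.finite(values)))
  leaf_log_marginal_ss(length(values), sum(values), sum(values^2), prior)
}
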