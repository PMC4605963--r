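# Three-level hierarchical AR(1) model for net migration rates, and the
# closed-form full conditionals the Gibbs sampler sweeps over.
#
# Level 1:  (r[c,t] - mu_c) = phi_c (r[c,t-1] - mu_c) + eps[c,t],
#           eps[c,t] ~ N(0, sigma2_c), independent.
# Level 2:  phi_c ~ U(0,1);  mu_c ~ N(lambda, tau^2);  sigma2_c ~ IG(a, b).
# Level 3:  a ~ U(1,10);  b|a ~ U(0, 100(a-1));
#           lambda ~ U(-100,100);  tau ~ U(0,100).
#
# The likelihood conditions on each country's first observation (transition
# terms only; no stationary-distribution term for t = 1).

#' Construct a model parameter state
#'
#' Country-level parameters (long-term mean rate `mu`, autoregression `phi`,
#' innovation variance `sigma2`, one entry per country) together with the
#' hyperparameters (`lam`, `tau` for the mean hierarchy; `a`, `b` for the
#' variance hierarchy).
#'
#' @param mu,phi,sigma2 numeric vectors of equal length C.
#' @param lam,tau,a,b scalar hyperparameters.
#' @param country_ids optional country codes (names for the vectors).
#' @param validate check the printed supports (default TRUE).
#' @return object of class `model_params`.
#' @export
model_params <- function(mu, phi, sigma2, lam, tau, a, b,
                         country_ids = NULL, validate = TRUE) {
  C <- length(mu)
  stopifnot(length(phi) == C, length(sigma2) == C)
  if (!is.null(country_ids)) {
    stopifnot(length(country_ids) == C)
    names(mu) <- names(phi) <- names(sigma2) <- country_ids
  }
  x <- structure(list(mu = as.numeric(mu), phi = as.numeric(phi),
                      sigma2 = as.numeric(sigma2),
                      lam = as.numeric(lam), tau = as.numeric(tau),
                      a = as.numeric(a), b = as.numeric(b)),
                 class = "model_params")
  if (validate) validate_model_params(x)
  x
}

#' Validate a model parameter state against the printed supports
#'
#' phi in (0,1), sigma2 > 0, mu finite, lambda in (-100,100), tau in (0,100),
#' a in (1,10), b in (0, 100(a-1)).
#'
#' @param x a `model_params` object.
#' @return `x`, invisibly; error outside any support.
#' @export
validate_model_params <- function(x) {
  stopifnot(inherits(x, "model_params"))
  if (!all(is.finite(x$mu))) stop("mu must be finite")
  if (!all(x$phi > 0 & x$phi < 1)) stop("phi must lie in (0, 1)")
  if (!all(x$sigma2 > 0)) stop("sigma2 must be positive")
  if (!(x$lam > -100 && x$lam < 100)) stop("lambda must lie in (-100, 100)")
  if (!(x$tau > 0 && x$tau < 100)) stop("tau must lie in (0, 100)")
  if (!(x$a > 1 && x$a < 10)) stop("a must lie in (1, 10)")
  if (!(x$b > 0 && x$b < 100 * (x$a - 1)))
    stop("b must lie in (0, 100(a-1))")
  invisible(x)
}

# Transition arrays for the AR(1) likelihood: lagged and current rates per
# country with missing cells masked to zero, plus the per-country transition
# count. Masking to zero makes every masked residual contribute exactly 0 to
# the sufficient statistics, so row sums need no NA handling.
dataset_transitions <- function(data) {
  r <- data$rates
  T_ <- ncol(r)
  if (T_ < 2L)
    return(list(prev = matrix(0, nrow(r), 0), curr = matrix(0, nrow(r), 0),
                valid = matrix(FALSE, nrow(r), 0),
                n_trans = rep(0L, nrow(r))))
  prev <- r[, -T_, drop = FALSE]
  curr <- r[, -1L, drop = FALSE]
  valid <- !is.na(prev) & !is.na(curr)
  prev[!valid] <- 0
  curr[!valid] <- 0
  list(prev = prev, curr = curr, valid = valid,
       n_trans = as.integer(rowSums(valid)))
}

#' AR(1) log likelihood
#'
#' Sum over countries and transitions t = 2..T of the normal log density of
#' the residual `eps = (r_t - mu) - phi (r_{t-1} - mu)` with variance
#' `sigma2`. The first observation of each country is conditioned on.
#' Countries with fewer than two observations contribute zero and are listed
#' in the `"skipped_countries"` attribute.
#'
#' @param params a [model_params()] state (one entry per dataset country, in
#'   dataset order).
#' @param data a [migration_dataset()].
#' @return scalar log likelihood.
#' @export
log_likelihood <- function(params, data) {
  tr <- dataset_transitions(data)
  C <- length(data$country_ids)
  stopifnot(length(params$mu) == C)
  mu <- params$mu; phi <- params$phi; s2 <- params$sigma2
  # residuals; masked cells have prev = curr = 0, subtract their spurious
  # contribution (1 - phi)^2 mu^2 via the valid mask
  eps <- (tr$curr - mu) - phi * (tr$prev - mu)
  eps <- eps * tr$valid
  ss <- rowSums(eps^2)
  ll <- sum(-tr$n_trans / 2 * log(2 * pi * s2) - ss / (2 * s2))
  structure(ll, skipped_countries = data$country_ids[tr$n_trans == 0L])
}

#' Log prior density of a model parameter state
#'
#' Sum of the Level 2 and Level 3 log densities; `-Inf` outside any support.
#'
#' @param params a [model_params()] state (built with `validate = FALSE` if it
#'   may lie outside the supports).
#' @return scalar log prior density (`-Inf` out of support).
#' @export
log_prior <- function(params) {
  p <- params
  if (!all(is.finite(p$mu))) return(-Inf)
  if (!all(p$phi > 0 & p$phi < 1)) return(-Inf)
  if (!all(p$sigma2 > 0)) return(-Inf)
  if (!(p$a > 1 && p$a < 10)) return(-Inf)
  if (!(p$b > 0 && p$b < 100 * (p$a - 1))) return(-Inf)
  if (!(p$lam > -100 && p$lam < 100)) return(-Inf)
  if (!(p$tau > 0 && p$tau < 100)) return(-Inf)
  C <- length(p$mu)
  # Level 2: phi ~ U(0,1) contributes 0 inside the support
  lp <- sum(stats::dnorm(p$mu, p$lam, p$tau, log = TRUE)) +
    sum(dinvgamma_log(p$sigma2, p$a, p$b))
  # Level 3: a ~ U(1,10); b|a ~ U(0,100(a-1)); lam ~ U(-100,100); tau ~ U(0,100)
  lp + -log(9) - log(100 * (p$a - 1)) - log(200) - log(100)
}

# inverse-gamma log density: f(x) = b^a / Gamma(a) x^{-a-1} exp(-b/x)
dinvgamma_log <- function(x, a, b) {
  a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
}

# per-country sufficient statistics used by several conditionals
country_stats <- function(c_idx, state, data) {
  tr <- dataset_transitions(data)
  list(prev = tr$prev[c_idx, ], curr = tr$curr[c_idx, ],
       valid = tr$valid[c_idx, ], n = tr$n_trans[c_idx])
}

#' Full conditional of a country mean `mu_c`
#'
#' Conjugate normal update. With `k = 1 - phi_c` and
#' `d_t = r_t - phi_c r_{t-1}`:
#' `precision = (T_c - 1) k^2 / sigma2_c + 1 / tau^2`,
#' `mean = (k sum(d_t) / sigma2_c + lam / tau^2) / precision`.
#' With fewer than two observations the prior `N(lam, tau^2)` is returned.
#'
#' @param c_idx country index into the dataset.
#' @param state current [model_params()].
#' @param data a [migration_dataset()].
#' @return `list(mean, var)` of the conditional normal.
#' @export
cond_mu <- function(c_idx, state, data) {
  st <- country_stats(c_idx, state, data)
  phi <- state$phi[c_idx]; s2 <- state$sigma2[c_idx]
  if (st$n == 0L)
    return(list(mean = state$lam, var = state$tau^2))
  k <- 1 - phi
  d <- (st$curr - phi * st$prev)[st$valid]
  prec <- st$n * k^2 / s2 + 1 / state$tau^2
  m <- (k * sum(d) / s2 + state$lam / state$tau^2) / prec
  list(mean = m, var = 1 / prec)
}

#' Full conditional of a country innovation variance `sigma2_c`
#'
#' Conjugate inverse-gamma update: `shape = a + (T_c - 1)/2`,
#' `rate = b + sum(eps_t^2)/2`. With fewer than two observations the prior
#' `IG(a, b)` is returned.
#'
#' @inheritParams cond_mu
#' @return `list(shape, rate)` of the conditional inverse gamma.
#' @export
cond_sigma2 <- function(c_idx, state, data) {
  st <- country_stats(c_idx, state, data)
  mu <- state$mu[c_idx]; phi <- state$phi[c_idx]
  if (st$n == 0L) return(list(shape = state$a, rate = state$b))
  eps <- ((st$curr - mu) - phi * (st$prev - mu))[st$valid]
  list(shape = state$a + st$n / 2, rate = state$b + sum(eps^2) / 2)
}

#' Full conditional of a country autoregression `phi_c`
#'
#' Truncated-normal update on (0, 1). With `x_t = r_{t-1} - mu_c` and
#' `z_t = r_t - mu_c`: untruncated `mean = sum(x z) / sum(x^2)`,
#' `var = sigma2_c / sum(x^2)`. A degenerate design (`sum(x^2) = 0`, or fewer
#' than two observations) returns the U(0,1) prior (`uniform = TRUE`).
#'
#' @inheritParams cond_mu
#' @return `list(mean, var, lower = 0, upper = 1, uniform)`.
#' @export
cond_phi <- function(c_idx, state, data) {
  st <- country_stats(c_idx, state, data)
  mu <- state$mu[c_idx]; s2 <- state$sigma2[c_idx]
  x <- (st$prev - mu)[st$valid]
  z <- (st$curr - mu)[st$valid]
  sxx <- sum(x^2)
  if (st$n == 0L || sxx == 0)
    return(list(mean = NA_real_, var = NA_real_, lower = 0, upper = 1,
                uniform = TRUE))
  list(mean = sum(x * z) / sxx, var = s2 / sxx, lower = 0, upper = 1,
       uniform = FALSE)
}

#' Full conditional of the inverse-gamma rate hyperparameter `b`
#'
#' `p(b | .) \propto b^{C a} exp(-b sum_c 1/sigma2_c)` on `(0, 100(a-1))`:
#' a Gamma(shape = C a + 1, rate = sum_c 1/sigma2_c) truncated above at
#' `100(a-1)`.
#'
#' @param state current [model_params()].
#' @return `list(shape, rate, upper)` of the truncated gamma.
#' @export
cond_b <- function(state) {
  C <- length(state$sigma2)
  list(shape = C * state$a + 1, rate = sum(1 / state$sigma2),
       upper = 100 * (state$a - 1))
}

#' Full conditional of the mean hyperparameter `lambda`
#'
#' `N(mean(mu_c), tau^2 / C)` truncated to (-100, 100). With zero countries
#' the U(-100, 100) prior is returned (`uniform = TRUE`).
#'
#' @param state current [model_params()].
#' @return `list(mean, var, lower = -100, upper = 100, uniform)`.
#' @export
cond_lambda <- function(state) {
  C <- length(state$mu)
  if (C == 0L)
    return(list(mean = NA_real_, var = NA_real_, lower = -100, upper = 100,
                uniform = TRUE))
  list(mean = mean(state$mu), var = state$tau^2 / C,
       lower = -100, upper = 100, uniform = FALSE)
}

#' Log full conditional of the scale hyperparameter `tau`
#'
#' `-C log(tau) - sum_c (mu_c - lam)^2 / (2 tau^2)` on (0, 100); `-Inf`
#' outside. Sampled by slice sampling.
#'
#' @param tau candidate value.
#' @param state current [model_params()].
#' @return scalar log kernel.
#' @export
log_cond_tau <- function(tau, state) {
  if (tau <= 0 || tau >= 100) return(-Inf)
  C <- length(state$mu)
  -C * log(tau) - sum((state$mu - state$lam)^2) / (2 * tau^2)
}

#' Log full conditional of the inverse-gamma shape hyperparameter `a`
#'
#' `C [a log(b) - log Gamma(a)] - (a + 1) sum_c log(sigma2_c)
#'  - log(100(a-1))` on `(1, 10)` intersected with `b < 100(a-1)`; `-Inf`
#' outside. The `-log(100(a-1))` term is the `b | a` prior's dependence on
#' `a`. Sampled by slice sampling.
#'
#' @param a candidate value.
#' @param state current [model_params()].
#' @return scalar log kernel.
#' @export
log_cond_a <- function(a, state) {
  if (a <= 1 || a >= 10) return(-Inf)
  if (state$b >= 100 * (a - 1)) return(-Inf)
  C <- length(state$sigma2)
  C * (a * log(state$b) - lgamma(a)) -
    (a + 1) * sum(log(state$sigma2)) - log(100 * (a - 1))
}
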