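# Independent oracles used across the suite.
#
# The grid oracle never touches the closed-form conditionals: it normalizes
# exp(log_likelihood + log_prior) over a fine grid in one coordinate (all
# other coordinates held fixed) by Simpson's rule and reads off the mean and
# variance. Closed forms are only used to pick a grid range wide enough to
# hold essentially all of the mass, which does not bias the integral.

# Simpson weights; n must be odd
simpson_weights <- function(n) {
  stopifnot(n %% 2L == 1L, n >= 3L)
  w <- rep(c(2, 4), length.out = n)
  w[1L] <- 1; w[n] <- 1
  w
}

# normalized moments of exp(logf) tabulated on an equally spaced grid
grid_moments <- function(x, logf_vals) {
  stopifnot(length(x) == length(logf_vals))
  w <- simpson_weights(length(x))
  p <- exp(logf_vals - max(logf_vals[is.finite(logf_vals)])) * w
  z <- sum(p)
  m <- sum(p * x) / z
  v <- sum(p * (x - m)^2) / z
  list(mean = m, var = v)
}

# log posterior kernel as a function of a single coordinate
logpost_fn <- function(state, data, param, c_idx = NULL) {
  function(v) {
    st <- state
    if (param %in% c("mu", "phi", "sigma2")) st[[param]][c_idx] <- v
    else st[[param]] <- v
    lp <- log_prior(st)
    if (!is.finite(lp)) return(-Inf)
    lp + as.numeric(log_likelihood(st, data))
  }
}

# grid oracle for one coordinate: range [lo, hi], n odd points
grid_oracle <- function(state, data, param, c_idx, lo, hi, n = 8001L) {
  if (n %% 2L == 0L) n <- n + 1L
  x <- seq(lo, hi, length.out = n)
  f <- logpost_fn(state, data, param, c_idx)
  grid_moments(x, vapply(x, f, numeric(1)))
}

# oracle on a log-scale grid (for the positive, heavy-tailed sigma2)
grid_oracle_log <- function(state, data, param, c_idx, lo, hi, n = 8001L) {
  if (n %% 2L == 0L) n <- n + 1L
  u <- seq(log(lo), log(hi), length.out = n)
  x <- exp(u)
  f <- logpost_fn(state, data, param, c_idx)
  lv <- vapply(x, f, numeric(1)) + u  # jacobian of x = exp(u)
  grid_moments_x(x, u, lv)
}

# moments in x when the density is tabulated on an equally spaced u-grid
grid_moments_x <- function(x, u, logf_vals) {
  w <- simpson_weights(length(u))
  p <- exp(logf_vals - max(logf_vals[is.finite(logf_vals)])) * w
  z <- sum(p)
  m <- sum(p * x) / z
  list(mean = m, var = sum(p * (x - m)^2) / z)
}

# closed-form moments of a truncated normal on (lo, hi)
tnorm_moments <- function(mean, var, lo, hi) {
  s <- sqrt(var)
  a <- (lo - mean) / s
  b <- (hi - mean) / s
  Z <- pnorm(b) - pnorm(a)
  dm <- (dnorm(a) - dnorm(b)) / Z
  m <- mean + s * dm
  v <- var * (1 + (a * dnorm(a) - b * dnorm(b)) / Z - dm^2)
  list(mean = m, var = v)
}

# closed-form moments of a Gamma(shape, rate) truncated to (0, upper)
tgamma_moments <- function(shape, rate, upper) {
  z0 <- pgamma(upper, shape, rate)
  m1 <- shape / rate * pgamma(upper, shape + 1, rate) / z0
  m2 <- shape * (shape + 1) / rate^2 * pgamma(upper, shape + 2, rate) / z0
  list(mean = m1, var = m2 - m1^2)
}

# closed-form moments of an inverse gamma (shape > 2)
invgamma_moments <- function(shape, rate) {
  list(mean = rate / (shape - 1),
       var = rate^2 / ((shape - 1)^2 * (shape - 2)))
}

# a random interior model state plus a matching random small dataset
random_state_and_data <- function(seed, C = 2L, T_ = 4L) {
  set.seed(seed)
  lam <- runif(1, -3, 3)
  tau <- runif(1, 0.5, 3)
  a <- runif(1, 2.5, 5)
  b <- runif(1, 5, min(60, 100 * (a - 1) * 0.9))
  st <- model_params(mu = rnorm(C, lam, tau),
                     phi = runif(C, 0.1, 0.9),
                     sigma2 = runif(C, 0.5, 4),
                     lam = lam, tau = tau, a = a, b = b)
  rates <- matrix(rnorm(C * T_, 0, 3), C, T_)
  pops <- matrix(exp(runif(C * T_, log(1e6), log(1e8))), C, T_)
  data <- migration_dataset(sprintf("X%02d", seq_len(C)),
                            seq(1950, by = 5, length.out = T_),
                            rates = rates, populations = pops)
  list(state = st, data = data)
}

# degenerate posterior concentrated at a single parameter point
make_point_posterior <- function(mu, phi, sigma2, lam = 0, tau = 1,
                                 a = 2, b = 1, n = 1L) {
  C <- length(mu)
  structure(list(mu = matrix(mu, n, C, byrow = TRUE,
                             dimnames = list(NULL, names(mu))),
                 phi = matrix(phi, n, C, byrow = TRUE),
                 sigma2 = matrix(sigma2, n, C, byrow = TRUE),
                 lam = rep(lam, n), tau = rep(tau, n), a = rep(a, n),
                 b = rep(b, n), chain_id = rep(1L, n),
                 country_ids = names(mu) %||%
                   sprintf("A%02d", seq_len(C)),
                 config = NULL),
            class = "posterior_sample")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-assembled trajectory set (K x C x H arrays)
make_traj_set <- function(rates, rates_uncorrected = NULL, pops = NULL,
                          levels = c(0.025, 0.1, 0.5, 0.9, 0.975)) {
  d <- dim(rates)
  pops <- pops %||% matrix(1e6, d[2L], d[3L])
  structure(list(rates = rates,
                 rates_uncorrected = rates_uncorrected %||% rates,
                 counts = rates / 1000 * 5 *
                   aperm(array(pops, c(d[2L], d[3L], d[1L])), c(3, 1, 2)),
                 counts_age_sex = NULL, populations = pops,
                 country_ids = sprintf("A%02d", seq_len(d[2L])),
                 period_starts = seq(2010, by = 5, length.out = d[3L]),
                 cell_names = "total",
                 config = list(levels = levels)),
            class = "trajectory_set")
}

# quick dataset builder for unit tests
make_dataset <- function(rates, pops = NULL, start = 1950, by = 5) {
  rates <- as.matrix(rates)
  if (is.null(pops)) pops <- matrix(1e6, nrow(rates), ncol(rates))
  migration_dataset(sprintf("A%02d", seq_len(nrow(rates))),
                    seq(start, by = by, length.out = ncol(rates)),
                    rates = rates, populations = pops)
}
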