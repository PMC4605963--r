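# Synthetic WPP-like datasets with known ground truth, generated from the
# hierarchical AR(1) model itself: country parameters drawn from the Level 2
# distributions, rate series iterated forward from a stationary start,
# log-uniform populations with constant per-country growth, and smooth
# young-adult-peaked age x sex schedules.
#
# Default generator hyperparameters (lambda = 0, tau = 3, a = 3, b = 20, all
# inside the printed supports) give rate magnitudes of a few per thousand,
# the scale of observed five-year net migration rates.

#' Synthetic-data specification
#'
#' @param C number of countries (>= 1).
#' @param T_ number of observed periods (>= 2).
#' @param hyper generator-truth hyperparameters: list with `lam`, `tau`,
#'   `a`, `b`, all inside the printed supports.
#' @param pop_range range for log-uniform initial populations (persons).
#' @param growth_range range for the uniform per-period population growth
#'   factor (constant per country).
#' @param seed integer RNG seed.
#' @param n_age number of five-year age groups for schedules (default 17).
#' @param horizon_periods future periods of projected populations to emit
#'   (default 18: five-year steps, roughly 2010 to 2100).
#' @param start_year first period start year (default 1950).
#' @param period_length years per period (default 5).
#' @param sigma2_override optional per-country vector overriding the drawn
#'   innovation variances (hook for noise-free limits; may be ~0).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(C, T_, hyper = list(lam = 0, tau = 3, a = 3,
                                               b = 20),
                           pop_range = c(5e5, 5e8),
                           growth_range = c(0.95, 1.15),
                           seed = 1, n_age = 17, horizon_periods = 18,
                           start_year = 1950, period_length = 5,
                           sigma2_override = NULL) {
  stopifnot(C >= 1, T_ >= 2, pop_range[1L] > 0, pop_range[2L] >= pop_range[1L])
  stopifnot(hyper$lam > -100, hyper$lam < 100, hyper$tau > 0,
            hyper$tau < 100, hyper$a > 1, hyper$a < 10, hyper$b > 0,
            hyper$b < 100 * (hyper$a - 1))
  if (!is.null(sigma2_override))
    stopifnot(length(sigma2_override) == C, all(sigma2_override >= 0))
  structure(list(C = as.integer(C), T_ = as.integer(T_), hyper = hyper,
                 pop_range = pop_range, growth_range = growth_range,
                 seed = as.integer(seed), n_age = as.integer(n_age),
                 horizon_periods = as.integer(horizon_periods),
                 start_year = start_year, period_length = period_length,
                 sigma2_override = sigma2_override),
            class = "synthetic_spec")
}

# smooth young-adult-peaked age profile over five-year groups: principal
# peak near ages 20-29 plus a smaller childhood bump, equal sex split
young_adult_schedule <- function(country_id, n_age = 17) {
  mid <- seq(2.5, by = 5, length.out = n_age)
  shape <- 0.75 * stats::dnorm(mid, 24, 8) + 0.25 * stats::dnorm(mid, 7, 5)
  w <- cbind(F = shape / 2, M = shape / 2) / sum(shape)
  rownames(w) <- if (n_age == 17) default_age_groups()
                 else paste0("ag", seq_len(n_age))
  migration_schedule(country_id, w)
}

#' Generate a synthetic dataset with known ground truth
#'
#' Draws `phi_c ~ U(0,1)`, `mu_c ~ N(lam, tau^2)`, `sigma2_c ~ IG(a, b)`,
#' initializes each rate series from the AR(1) stationary distribution
#' `N(mu_c, sigma2_c / (1 - phi_c^2))`, and iterates the recursion forward.
#' Populations are log-uniform over `pop_range` with a constant per-country
#' per-period growth factor, continued over the projection horizon.
#' Deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `dataset` (a [migration_dataset()]), `truth`
#'   (a [model_params()] with the generating values, plus attributes
#'   `"innovations"` — the injected noise matrix for t >= 2 — and
#'   `"growth"`), `schedules` (named list), `future_pops` (countries x
#'   horizon matrix, colnames future period starts).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  C <- spec$C; T_ <- spec$T_; hy <- spec$hyper
  ids <- sprintf("C%03d", seq_len(C))
  phi <- stats::runif(C)
  mu <- stats::rnorm(C, hy$lam, hy$tau)
  sigma2 <- 1 / stats::rgamma(C, shape = hy$a, rate = hy$b)
  if (!is.null(spec$sigma2_override)) sigma2 <- spec$sigma2_override
  r <- matrix(NA_real_, C, T_)
  r[, 1L] <- stats::rnorm(C, mu, sqrt(sigma2 / (1 - phi^2)))
  eps <- matrix(stats::rnorm(C * (T_ - 1L)), C, T_ - 1L) * sqrt(sigma2)
  for (t_ in 2:T_)
    r[, t_] <- mu + phi * (r[, t_ - 1L] - mu) + eps[, t_ - 1L]
  pop0 <- exp(stats::runif(C, log(spec$pop_range[1L]),
                           log(spec$pop_range[2L])))
  growth <- stats::runif(C, spec$growth_range[1L], spec$growth_range[2L])
  H <- spec$horizon_periods
  pops_all <- pop0 * t(sapply(growth, function(g) g^(0:(T_ + H - 1L))))
  if (C == 1L) pops_all <- matrix(pops_all, 1L)
  periods <- spec$start_year + spec$period_length * (0:(T_ - 1L))
  future_periods <- spec$start_year + spec$period_length *
    (T_:(T_ + H - 1L))
  dataset <- migration_dataset(ids, periods, rates = r,
                               populations = pops_all[, seq_len(T_),
                                                      drop = FALSE],
                               period_length = spec$period_length)
  sig2_truth <- pmax(sigma2, .Machine$double.xmin)  # keep state valid
  truth <- model_params(mu = mu, phi = phi, sigma2 = sig2_truth,
                        lam = hy$lam, tau = hy$tau, a = hy$a, b = hy$b,
                        country_ids = ids, validate = FALSE)
  attr(truth, "innovations") <- eps
  attr(truth, "growth") <- growth
  schedules <- stats::setNames(
    lapply(ids, young_adult_schedule, n_age = spec$n_age), ids)
  future_pops <- pops_all[, T_ + seq_len(H), drop = FALSE]
  colnames(future_pops) <- future_periods
  rownames(future_pops) <- ids
  list(dataset = dataset, truth = truth, schedules = schedules,
       future_pops = future_pops)
}

#' Split the most recent periods off for holdout evaluation
#'
#' Returns the training dataset (first `T - m` periods) and the withheld
#' truths; concatenating the two restores the original exactly.
#'
#' @param dataset a [migration_dataset()].
#' @param m number of most recent periods to withhold (1 <= m <= T - 2).
#' @return list `train` (a [migration_dataset()]) and `withheld` (list with
#'   `period_starts`, `rates`, `counts`, `populations`).
#' @export
split_holdout <- function(dataset, m) {
  stopifnot(inherits(dataset, "migration_dataset"))
  T_ <- length(dataset$period_starts)
  if (!(is.numeric(m) && length(m) == 1L && m >= 1))
    stop("m must be a positive integer")
  if (T_ - m < 2L) stop("at least two training periods are required")
  keep <- seq_len(T_ - m)
  drop_ <- (T_ - m + 1L):T_
  train <- migration_dataset(dataset$country_ids,
                             dataset$period_starts[keep],
                             rates = dataset$rates[, keep, drop = FALSE],
                             populations = dataset$populations[, keep,
                                                               drop = FALSE],
                             period_length = dataset$period_length)
  list(train = train,
       withheld = list(period_starts = dataset$period_starts[drop_],
                       rates = dataset$rates[, drop_, drop = FALSE],
                       counts = dataset$counts[, drop_, drop = FALSE],
                       populations = dataset$populations[, drop_,
                                                         drop = FALSE]))
}
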