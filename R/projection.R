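# Posterior-predictive trajectory simulation with the zero-global-net-
# migration correction. For each trajectory one posterior draw is held fixed
# over the whole horizon; within a period, rates are stepped forward by the
# AR(1) recursion, converted to counts, split by age and sex, corrected so
# world net migration is zero in every (age, sex) cell, and converted back
# to rates. The corrected rate is the lag fed into the next period.
#
# Because every schedule's weights sum to 1, the country-total corrected
# count equals the total-level correction y_c - share_c * sum_j y_j; the
# per-cell corrected counts are therefore only materialized when requested.

#' Projection configuration
#'
#' @param horizon_periods number of future periods to simulate (>= 1).
#' @param n_trajectories number of joint trajectories (default 4000).
#' @param period_length years per period (default 5).
#' @param seed integer RNG seed.
#' @param levels quantile levels for summaries (strictly increasing in (0,1);
#'   default gives the median with 80 % and 95 % intervals).
#' @return object of class `projection_config`.
#' @export
projection_config <- function(horizon_periods, n_trajectories = 4000,
                              period_length = 5, seed = 1,
                              levels = c(0.025, 0.1, 0.5, 0.9, 0.975)) {
  stopifnot(horizon_periods >= 1, n_trajectories >= 1,
            all(diff(levels) > 0), all(levels > 0 & levels < 1))
  structure(list(horizon_periods = as.integer(horizon_periods),
                 n_trajectories = as.integer(n_trajectories),
                 period_length = period_length, seed = as.integer(seed),
                 levels = levels),
            class = "projection_config")
}

#' One AR(1) step of the rate process
#'
#' `r' = mu + phi (prev - mu) + eps`, `eps ~ N(0, sigma2)` independently per
#' country. Draws come from the current RNG stream (seed it upstream).
#'
#' @param params a [model_params()] draw.
#' @param prev_rates numeric vector of lag rates, one per country.
#' @return numeric vector of uncorrected next-period rates.
#' @export
simulate_rate_step <- function(params, prev_rates) {
  stopifnot(length(prev_rates) == length(params$mu))
  params$mu + params$phi * (prev_rates - params$mu) +
    stats::rnorm(length(prev_rates), 0, sqrt(params$sigma2))
}

#' Disaggregate country net counts by age and sex
#'
#' `y[c, a, s] = y[c] * weight_c(a, s)`; summing over cells recovers the
#' input exactly (weights sum to 1). Countries without a schedule use
#' `default` if supplied, otherwise an error is raised.
#'
#' @param counts named numeric vector of per-country net counts.
#' @param schedules named list of [migration_schedule()] objects.
#' @param default optional fallback schedule (e.g. [uniform_schedule()]).
#' @return 3-d array countries x age groups x sexes.
#' @export
disaggregate_counts <- function(counts, schedules, default = NULL) {
  ids <- names(counts)
  if (is.null(ids)) stop("counts must be a named vector of country ids")
  first <- schedules[[1L]] %||% default
  if (is.null(first)) stop("no schedules available")
  dims <- dim(first$weights)
  out <- array(NA_real_, c(length(ids), dims[1L], dims[2L]),
               dimnames = c(list(ids), dimnames(first$weights)))
  for (i in seq_along(ids)) {
    sch <- schedules[[ids[i]]]
    if (is.null(sch)) {
      if (is.null(default))
        stop("no schedule for country ", ids[i], " and no default supplied")
      sch <- default
    }
    if (!all(dim(sch$weights) == dims))
      stop("schedule grid mismatch for country ", ids[i])
    out[i, , ] <- counts[i] * sch$weights
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Zero-global-net-migration correction
#'
#' Redistributes the world's total net count to all countries in proportion
#' to their projected populations:
#' `y*_c = y_c - (n_c / sum_j n_j) * sum_j y_j`.
#' The output sums to zero (up to floating point); an input already summing
#' to zero is returned unchanged.
#'
#' @param counts numeric vector of per-country net counts for one
#'   (period, age, sex) cell.
#' @param populations matching vector of projected populations (> 0, not all
#'   zero).
#' @return corrected counts, same length.
#' @export
zero_sum_correct <- function(counts, populations) {
  stopifnot(length(counts) == length(populations))
  if (all(populations == 0)) stop("populations must not be all zero")
  if (any(populations < 0)) stop("populations must be non-negative")
  total <- sum(counts)
  counts - populations / sum(populations) * total
}

#' Simulate corrected joint trajectories
#'
#' Repeats the per-period cycle (AR(1) rate step, rate-to-count conversion,
#' age/sex disaggregation, zero-sum correction, count-to-rate conversion)
#' out to the horizon, feeding each period's corrected rate back in as the
#' next lag. Each trajectory uses a single posterior draw held fixed over
#' the whole horizon; if `n_trajectories` exceeds the posterior size, draws
#' are resampled with replacement (seeded), otherwise a deterministic
#' evenly-spaced subsequence of draws is used.
#'
#' @param posterior a `posterior_sample` from [run_mcmc()] (non-empty).
#' @param data the fitted [migration_dataset()] (provides the last observed
#'   rate per country, the AR(1) lag for the first future period).
#' @param future_pops countries x horizon matrix of projected period-average
#'   populations (column names = future period start years; countries in
#'   dataset order).
#' @param schedules optional named list of [migration_schedule()] objects;
#'   when `NULL` the correction operates on country totals (a single cell).
#' @param config a [projection_config()].
#' @param default_schedule fallback schedule for countries missing from
#'   `schedules` (default [uniform_schedule()] on the first schedule's grid).
#' @param store_age_sex keep the per-cell corrected counts (array
#'   trajectories x countries x periods x age x sex); off by default, as the
#'   array is large.
#' @return object of class `trajectory_set`: arrays `rates` (corrected) and
#'   `rates_uncorrected` of dimension trajectories x countries x periods,
#'   `counts` (corrected country totals), `populations`, period/country
#'   labels, and optionally `counts_age_sex`.
#' @export
project_migration <- function(posterior, data, future_pops, schedules = NULL,
                              config, default_schedule = NULL,
                              store_age_sex = FALSE) {
  stopifnot(inherits(posterior, "posterior_sample"),
            inherits(data, "migration_dataset"),
            inherits(config, "projection_config"))
  C <- length(data$country_ids)
  H <- config$horizon_periods
  K <- config$n_trajectories
  future_pops <- as.matrix(future_pops)
  if (nrow(future_pops) != C)
    stop("future_pops must have one row per country")
  if (ncol(future_pops) < H)
    stop("horizon (", H, " periods) exceeds future_pops (",
         ncol(future_pops), " periods)")
  if (any(future_pops[, seq_len(H)] <= 0))
    stop("future populations must be strictly positive")
  N <- n_draws(posterior)
  if (N < 1L) stop("posterior is empty")

  set.seed(config$seed)
  idx <- if (K <= N) as.integer(round(seq(1, N, length.out = K)))
         else sample.int(N, K, replace = TRUE)

  mu <- posterior$mu[idx, , drop = FALSE]
  phi <- posterior$phi[idx, , drop = FALSE]
  sig <- sqrt(posterior$sigma2[idx, , drop = FALSE])

  # schedule weight matrix countries x cells (single unit cell when absent)
  if (!is.null(schedules)) {
    grid <- (schedules[[1L]] %||% default_schedule)$weights
    if (is.null(default_schedule))
      default_schedule <- uniform_schedule("default", rownames(grid),
                                           colnames(grid))
    W <- t(vapply(data$country_ids, function(cid) {
      sch <- schedules[[cid]] %||% default_schedule
      if (!all(dim(sch$weights) == dim(grid)))
        stop("schedule grid mismatch for country ", cid)
      as.vector(sch$weights)
    }, numeric(length(grid))))
    cell_names <- outer(rownames(grid), colnames(grid), paste, sep = ".")
  } else {
    W <- matrix(1, C, 1L)
    cell_names <- "total"
    grid <- matrix(1, 1, 1)
  }
  n_cells <- ncol(W)

  periods <- as.numeric(colnames(future_pops)[seq_len(H)])
  if (any(is.na(periods)))
    periods <- max(data$period_starts) + config$period_length * seq_len(H)

  last_obs <- apply(data$rates, 1L, function(x) x[max(which(!is.na(x)))])
  dn <- list(NULL, data$country_ids, periods)
  rates_c <- array(NA_real_, c(K, C, H), dimnames = dn)
  rates_u <- array(NA_real_, c(K, C, H), dimnames = dn)
  counts_c <- array(NA_real_, c(K, C, H), dimnames = dn)
  counts_as <- if (store_age_sex)
    array(NA_real_, c(K, C, H, n_cells),
          dimnames = c(dn, list(as.vector(cell_names)))) else NULL

  L <- config$period_length
  prev <- matrix(rep(last_obs, each = K), K, C)
  for (h in seq_len(H)) {
    eps <- matrix(stats::rnorm(K * C), K, C) * sig
    R <- mu + phi * (prev - mu) + eps
    pop <- future_pops[, h]
    share <- pop / sum(pop)
    Y <- R / 1000 * matrix(rep(pop, each = K), K, C) * L
    tot <- rowSums(Y)
    Ystar <- Y - tot %o% share
    Rstar <- Ystar * 1000 / (matrix(rep(pop, each = K), K, C) * L)
    rates_u[, , h] <- R
    rates_c[, , h] <- Rstar
    counts_c[, , h] <- Ystar
    if (store_age_sex) {
      for (cell in seq_len(n_cells)) {
        Ycell <- Y * matrix(rep(W[, cell], each = K), K, C)
        counts_as[, , h, cell] <-
          Ycell - rowSums(Ycell) %o% share
      }
    }
    prev <- Rstar
  }
  structure(list(rates = rates_c, rates_uncorrected = rates_u,
                 counts = counts_c, counts_age_sex = counts_as,
                 populations = future_pops[, seq_len(H), drop = FALSE],
                 country_ids = data$country_ids, period_starts = periods,
                 cell_names = as.vector(cell_names),
                 schedule_grid = dimnames(grid), config = config),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  d <- dim(x$rates)
  cat("<trajectory_set> ", d[1L], " trajectories x ", d[2L], " countries x ",
      d[3L], " periods\n", sep = "")
  invisible(x)
}

#' Pointwise quantiles of corrected trajectory rates
#'
#' @param trajectories a `trajectory_set`.
#' @param levels quantile levels (default the set's configured levels).
#' @param what `"rates"` (default) or `"counts"`.
#' @return data.frame `country_id`, `period_start`, one `q<level>` column per
#'   level (median = `q0.5`).
#' @export
summarize_trajectories <- function(trajectories, levels = NULL,
                                   what = c("rates", "counts")) {
  what <- match.arg(what)
  stopifnot(inherits(trajectories, "trajectory_set"))
  levels <- levels %||% trajectories$config$levels
  arr <- trajectories[[what]]
  C <- dim(arr)[2L]; H <- dim(arr)[3L]
  rows <- vector("list", C * H)
  n <- 0L
  for (i in seq_len(C)) for (h in seq_len(H)) {
    q <- stats::quantile(arr[, i, h], levels, names = FALSE)
    n <- n + 1L
    rows[[n]] <- c(q)
  }
  qm <- do.call(rbind, rows)
  colnames(qm) <- paste0("q", levels)
  out <- data.frame(
    country_id = rep(trajectories$country_ids, each = H),
    period_start = rep(trajectories$period_starts, times = C),
    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(qm))
}

#' Size of the zero-sum correction on the rate scale
#'
#' `|r* - r|` per (trajectory, country, period): the quantity behind the
#' claim that corrections are typically small on the net rate scale. The
#' summary attribute reports quantiles and the fraction below `threshold`.
#'
#' @param trajectories a `trajectory_set`.
#' @param threshold rate-change threshold for the reported fraction
#'   (default 0.2 net annual migrants per thousand).
#' @return array of absolute rate changes (trajectories x countries x
#'   periods) with a `"summary"` attribute.
#' @export
correction_sensitivity <- function(trajectories, threshold = 0.2) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  d <- abs(trajectories$rates - trajectories$rates_uncorrected)
  structure(d, summary = list(
    quantiles = stats::quantile(d, c(0.5, 0.9, 0.95, 0.99)),
    fraction_below = mean(d < threshold),
    threshold = threshold))
}

#' Write trajectories to CSV (long format)
#'
#' Columns `country_id`, `period_start`, `trajectory_index`, `rate`, `count`
#' (corrected values).
#'
#' @param trajectories a `trajectory_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories_csv <- function(trajectories, path) {
  d <- dim(trajectories$rates)
  df <- data.frame(
    country_id = rep(trajectories$country_ids, each = d[1L], times = d[3L]),
    period_start = rep(trajectories$period_starts, each = d[1L] * d[2L]),
    trajectory_index = rep(seq_len(d[1L]), times = d[2L] * d[3L]),
    rate = as.vector(trajectories$rates),
    count = as.vector(trajectories$counts),
    stringsAsFactors = FALSE)
  write_csv_full_precision(df, path)
  invisible(path)
}

#' Write a quantile summary to CSV
#'
#' @param summary data.frame from [summarize_trajectories()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_quantiles_csv <- function(summary, path) {
  write_csv_full_precision(summary, path)
  invisible(path)
}
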