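# Out-of-sample holdout evaluation (MAE and interval coverage by lead time,
# on the rate scale) and global migration-trend statistics: the unweighted
# and population-weighted means of absolute net migration rates, u(t) and
# w(t), and migration-parity-change fractions.

#' Holdout specification
#'
#' @param m number of most recent periods withheld (1 <= m < T).
#' @return object of class `holdout_spec`.
#' @export
holdout_spec <- function(m) {
  stopifnot(is.numeric(m), length(m) == 1L, m >= 1)
  structure(list(m = as.integer(m)), class = "holdout_spec")
}

#' Out-of-sample holdout evaluation
#'
#' Withholds the `m` most recent periods, refits the chosen forecaster on
#' the truncated data only, and scores forecasts against the withheld truths
#' on the rate scale. MAE per lead is the mean over countries of
#' `|point forecast - truth|`; coverage (Bayesian forecaster only) is the
#' percentage of countries whose truth lies inside the pointwise interval
#' (closed at the endpoints). Projected populations for the withheld periods
#' are the dataset's own observed populations.
#'
#' @param data a [migration_dataset()] with `T - m >= 2` periods.
#' @param spec a [holdout_spec()].
#' @param forecaster `"bayesian"`, `"persistence_rates"`,
#'   `"persistence_counts"`, `"gravity"`, or a function
#'   `function(train, m, future_pops)` returning either a countries x m
#'   matrix of point forecasts or a list with elements `median` and
#'   optionally `lower80`/`upper80`/`lower95`/`upper95` (all countries x m
#'   matrices).
#' @param mcmc_config an [mcmc_config()] (Bayesian forecaster).
#' @param projection_config a [projection_config()] or NULL for defaults
#'   (Bayesian forecaster; its horizon is forced to `m`).
#' @param exponents a [gravity_exponents()] (gravity forecaster).
#' @return object of class `eval_report`: data.frame with one row per lead
#'   (`lead_years`, `mae`, `cov80`, `cov95`, `n_countries`) plus an
#'   all-leads aggregate row (`lead_years = NA`).
#' @export
holdout_evaluate <- function(data, spec, forecaster = "bayesian",
                             mcmc_config = NULL, projection_config = NULL,
                             exponents = NULL) {
  stopifnot(inherits(data, "migration_dataset"), inherits(spec, "holdout_spec"))
  T_ <- length(data$period_starts)
  m <- spec$m
  if (T_ - m < 2L) stop("T - m must be at least 2")
  split <- split_holdout(data, m)
  train <- split$train
  truth <- split$withheld$rates              # C x m
  held_pops <- split$withheld$populations    # C x m, the "projected" pops
  colnames(held_pops) <- split$withheld$period_starts
  C <- length(data$country_ids)

  lower80 <- upper80 <- lower95 <- upper95 <- NULL
  if (is.function(forecaster)) {
    fc <- forecaster(train, m, held_pops)
    if (is.list(fc)) {
      med <- fc$median
      lower80 <- fc$lower80; upper80 <- fc$upper80
      lower95 <- fc$lower95; upper95 <- fc$upper95
    } else med <- fc
  } else if (forecaster == "bayesian") {
    mcmc_config <- mcmc_config %||% mcmc_config()
    pc <- projection_config %||% projection_config(horizon_periods = m)
    pc$horizon_periods <- m
    post <- run_mcmc(train, mcmc_config)
    traj <- project_migration(post, train, held_pops, schedules = NULL,
                              config = pc)
    qs <- apply(traj$rates, c(2L, 3L), stats::quantile,
                probs = c(0.025, 0.1, 0.5, 0.9, 0.975))
    med <- qs[3L, , , drop = TRUE]
    if (m == 1L) med <- matrix(med, C, 1L)
    lower95 <- matrix(qs[1L, , ], C, m); lower80 <- matrix(qs[2L, , ], C, m)
    upper80 <- matrix(qs[4L, , ], C, m); upper95 <- matrix(qs[5L, , ], C, m)
  } else if (forecaster == "persistence_rates") {
    med <- persistence_forecast(train, "rates", m)
  } else if (forecaster == "persistence_counts") {
    med <- persistence_forecast(train, "counts", m, held_pops)
  } else if (forecaster == "gravity") {
    if (is.null(exponents))
      stop("gravity forecaster requires exponents")
    med <- gravity_forecast_all(train, exponents, m, held_pops)
  } else {
    stop("unknown forecaster: ", forecaster)
  }
  med <- as.matrix(med)
  stopifnot(all(dim(med) == c(C, m)))

  lead_years <- seq_len(m) * data$period_length
  rows <- lapply(seq_len(m), function(j) {
    ok <- !is.na(truth[, j]) & !is.na(med[, j])
    mae <- mean(abs(med[ok, j] - truth[ok, j]))
    cov80 <- if (!is.null(lower80))
      100 * mean(truth[ok, j] >= lower80[ok, j] &
                 truth[ok, j] <= upper80[ok, j]) else NA_real_
    cov95 <- if (!is.null(lower95))
      100 * mean(truth[ok, j] >= lower95[ok, j] &
                 truth[ok, j] <= upper95[ok, j]) else NA_real_
    data.frame(lead_years = lead_years[j], mae = mae, cov80 = cov80,
               cov95 = cov95, n_countries = sum(ok))
  })
  ok <- !is.na(truth) & !is.na(med)
  agg <- data.frame(
    lead_years = NA_real_,
    mae = mean(abs(med[ok] - truth[ok])),
    cov80 = if (!is.null(lower80))
      100 * mean(truth[ok] >= lower80[ok] & truth[ok] <= upper80[ok])
      else NA_real_,
    cov95 = if (!is.null(lower95))
      100 * mean(truth[ok] >= lower95[ok] & truth[ok] <= upper95[ok])
      else NA_real_,
    n_countries = sum(ok))
  structure(rbind(do.call(rbind, rows), agg), class = c("eval_report",
                                                        "data.frame"))
}

#' Unweighted mean absolute net migration rate, u(t)
#'
#' `u(t) = sum_c |r_c| / C`: whether the typical country experiences much
#' population change through migration.
#'
#' @param rates per-country net migration rates at one period.
#' @return scalar.
#' @export
u_stat <- function(rates) {
  rates <- rates[!is.na(rates)]
  if (!length(rates)) return(NA_real_)
  mean(abs(rates))
}

#' Population-weighted mean absolute net migration rate, w(t)
#'
#' `w(t) = sum_c |r_c| n_c / sum_j n_j`: what the typical person, rather
#' than the typical country, experiences.
#'
#' @param rates per-country net migration rates at one period.
#' @param populations matching populations (> 0).
#' @return scalar.
#' @export
w_stat <- function(rates, populations) {
  stopifnot(length(rates) == length(populations))
  ok <- !is.na(rates) & !is.na(populations)
  if (!any(ok)) return(NA_real_)
  if (any(populations[ok] <= 0)) stop("populations must be positive")
  sum(abs(rates[ok]) * populations[ok]) / sum(populations[ok])
}

#' Fraction of countries changing migration parity
#'
#' Observed mode (`target` a vector of rates): fraction of countries whose
#' rate sign at the target period differs from the sign at the base period.
#' Projected mode (`target` a `trajectory_set` plus `period`): mean over
#' trajectories of the per-trajectory switch fraction — a posterior
#' predictive probability of a parity change, averaged over countries.
#' A rate of exactly zero carries no parity and never counts as a switch.
#'
#' @param base_rates per-country rates at the base period.
#' @param target per-country rates at the comparison period, or a
#'   `trajectory_set`.
#' @param period for the projected mode, the index (or period start year) of
#'   the trajectory period to compare against.
#' @param method projected mode only: `"mean"` (default; average the switch
#'   fraction over trajectories) or `"median_trajectory"` (compare against
#'   the pointwise median path).
#' @return scalar fraction in [0, 1].
#' @export
parity_change_fraction <- function(base_rates, target, period = NULL,
                                   method = c("mean", "median_trajectory")) {
  method <- match.arg(method)
  s0 <- sign(base_rates)
  switch_frac <- function(r1) mean(s0 * sign(r1) < 0, na.rm = TRUE)
  if (inherits(target, "trajectory_set")) {
    if (is.null(period)) stop("period is required for the projected mode")
    h <- if (period %in% target$period_starts)
      match(period, target$period_starts) else as.integer(period)
    if (is.na(h) || h < 1L || h > dim(target$rates)[3L])
      stop("period out of range")
    R <- target$rates[, , h, drop = TRUE]
    if (is.null(dim(R))) R <- matrix(R, nrow = dim(target$rates)[1L])
    if (method == "mean")
      mean(apply(R, 1L, switch_frac))
    else
      switch_frac(apply(R, 2L, stats::median))
  } else {
    stopifnot(length(target) == length(base_rates))
    switch_frac(target)
  }
}

#' Projected quantiles of the trend statistics u(t) and w(t)
#'
#' Computes u and w within each (trajectory, period), then pointwise
#' quantiles across trajectories.
#'
#' @param trajectories a `trajectory_set`.
#' @param populations countries x periods population matrix (default: the
#'   set's projected populations, the w(t) weights).
#' @param levels quantile levels (default the set's configured levels).
#' @return data.frame `period_start`, `stat` (`"u"`/`"w"`), one `q<level>`
#'   column per level.
#' @export
trend_projection <- function(trajectories, populations = NULL,
                             levels = NULL) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  populations <- populations %||% trajectories$populations
  levels <- levels %||% trajectories$config$levels
  K <- dim(trajectories$rates)[1L]
  H <- dim(trajectories$rates)[3L]
  rows <- vector("list", 2L * H)
  for (h in seq_len(H)) {
    R <- abs(trajectories$rates[, , h, drop = TRUE])
    if (is.null(dim(R))) R <- matrix(R, nrow = K)
    u <- rowMeans(R)
    wgt <- populations[, h] / sum(populations[, h])
    w <- as.vector(R %*% wgt)
    rows[[2L * h - 1L]] <- data.frame(
      period_start = trajectories$period_starts[h], stat = "u",
      t(stats::quantile(u, levels, names = FALSE)))
    rows[[2L * h]] <- data.frame(
      period_start = trajectories$period_starts[h], stat = "w",
      t(stats::quantile(w, levels, names = FALSE)))
  }
  out <- do.call(rbind, rows)
  names(out)[-(1:2)] <- paste0("q", levels)
  out
}

#' Write an evaluation report to CSV
#'
#' One row per lead time and an aggregate row; columns `lead_years`, `mae`,
#' `cov80`, `cov95`, `n_countries`.
#'
#' @param report an `eval_report` from [holdout_evaluate()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  write_csv_full_precision(as.data.frame(report), path)
  invisible(path)
}
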