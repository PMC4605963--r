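# Point-forecast comparison models: persistence (of rates or of counts) and
# the gravity model, in which net migration is the difference of two
# power-law flows in the country's own population L(t) and the rest-of-world
# population M(t), with per-country proportionality constants fit by least
# squares.

#' Gravity-model exponents
#'
#' The four power-law exponents: `alpha`/`beta` for in-migration
#' `a * L(t)^alpha * M(t)^beta`, `gamma`/`delta` for out-migration
#' `b * L(t)^gamma * M(t)^delta`. Externally estimated values are required
#' inputs — there are no defaults.
#'
#' @param alpha,beta,gamma,delta finite real exponents.
#' @return object of class `gravity_exponents`.
#' @export
gravity_exponents <- function(alpha, beta, gamma, delta) {
  v <- c(alpha = alpha, beta = beta, gamma = gamma, delta = delta)
  if (!all(is.finite(v))) stop("gravity exponents must be finite")
  structure(as.list(v), class = "gravity_exponents")
}

#' Persistence point forecasts
#'
#' `kind = "rates"`: each country's last observed rate repeated over the
#' horizon. `kind = "counts"`: the last observed per-period count repeated,
#' then converted to rates with the projected populations — so the implied
#' rate drifts as populations change.
#'
#' @param data a [migration_dataset()].
#' @param kind `"rates"` or `"counts"`.
#' @param horizon number of future periods.
#' @param future_pops countries x horizon population matrix (required for
#'   `kind = "counts"`).
#' @return countries x horizon matrix of forecast rates (per thousand,
#'   annual).
#' @export
persistence_forecast <- function(data, kind = c("rates", "counts"), horizon,
                                 future_pops = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(data, "migration_dataset"), horizon >= 1)
  C <- length(data$country_ids)
  last_idx <- apply(data$rates, 1L, function(x) max(which(!is.na(x))))
  if (kind == "rates") {
    last_rate <- data$rates[cbind(seq_len(C), last_idx)]
    out <- matrix(last_rate, C, horizon)
  } else {
    if (is.null(future_pops))
      stop("future_pops is required for persistence of counts")
    future_pops <- as.matrix(future_pops)
    if (nrow(future_pops) != C || ncol(future_pops) < horizon)
      stop("future_pops must be countries x horizon")
    last_count <- data$counts[cbind(seq_len(C), last_idx)]
    out <- counts_to_rates(matrix(last_count, C, horizon),
                           future_pops[, seq_len(horizon), drop = FALSE],
                           data$period_length)
  }
  dimnames(out) <- list(data$country_ids, NULL)
  out
}

#' Fit gravity-model proportionality constants for one country
#'
#' Minimizes `sum_t (y_t - [a L_t^alpha M_t^beta - b L_t^gamma M_t^delta])^2`
#' over `a, b >= 0`. The objective is linear in `(a, b)`, so the constrained
#' minimum is the unconstrained least-squares solution when that is already
#' non-negative, and otherwise the best of the boundary fits. Proportional
#' regressor columns (e.g. all exponents zero) leave only `a - b`
#' identifiable: a collinearity warning is raised and the minimum-norm
#' non-negative solution is returned.
#'
#' @param y numeric vector of historical net migration counts (length >= 2).
#' @param L country population at the same time points (> 0).
#' @param M rest-of-world population at the same time points (> 0).
#' @param exponents a [gravity_exponents()].
#' @return object of class `gravity_fit`: `a_grav`, `b_grav`, `rss`,
#'   `unconstrained` (the unconstrained pair), `collinear` flag.
#' @export
fit_gravity <- function(y, L, M, exponents) {
  stopifnot(inherits(exponents, "gravity_exponents"),
            length(y) >= 2, length(L) == length(y), length(M) == length(y))
  if (any(L <= 0) || any(M <= 0)) stop("populations must be positive")
  u <- L^exponents$alpha * M^exponents$beta   # in-flow regressor
  v <- L^exponents$gamma * M^exponents$delta  # out-flow regressor
  X <- cbind(u, -v)
  XtX <- crossprod(X)
  collinear <- rcond_2x2(XtX) < 1e-12
  if (collinear) {
    warning("gravity regressors are collinear; only a - b is identifiable; ",
            "returning the minimum-norm non-negative solution")
    # v = s * u with s > 0; best net coefficient m for y ~ m * u
    s <- sum(u * v) / sum(u * u)
    m <- sum(u * y) / sum(u * u)
    ab <- if (m >= 0) c(m, 0) else c(0, -m / s)
    fit <- c(a_grav = ab[1L], b_grav = ab[2L])
    unconstrained <- c(a = NA_real_, b = NA_real_)
  } else {
    unconstrained <- drop(solve(XtX, crossprod(X, y)))
    names(unconstrained) <- c("a", "b")
    if (all(unconstrained >= 0)) {
      fit <- c(a_grav = unconstrained[[1L]], b_grav = unconstrained[[2L]])
    } else {
      # best boundary candidates
      cand <- list(
        c(max(0, sum(u * y) / sum(u * u)), 0),
        c(0, max(0, -sum(v * y) / sum(v * v))),
        c(0, 0))
      rss_of <- function(ab) sum((y - (ab[1L] * u - ab[2L] * v))^2)
      best <- cand[[which.min(vapply(cand, rss_of, numeric(1)))]]
      fit <- c(a_grav = best[1L], b_grav = best[2L])
    }
  }
  rss <- sum((y - (fit[["a_grav"]] * u - fit[["b_grav"]] * v))^2)
  structure(list(a_grav = fit[["a_grav"]], b_grav = fit[["b_grav"]],
                 rss = rss, unconstrained = unconstrained,
                 collinear = collinear, exponents = exponents),
            class = "gravity_fit")
}

# reciprocal condition number of a 2x2 symmetric PSD matrix
rcond_2x2 <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  max(min(ev), 0) / max(ev)
}

#' Gravity-model net migration forecast
#'
#' Plugs projected populations into the fitted form
#' `a L^alpha M^beta - b L^gamma M^delta`.
#'
#' @param fit a [gravity_fit] from [fit_gravity()].
#' @param L_future,M_future projected own and rest-of-world populations.
#' @return numeric vector of projected net migration counts per period.
#' @export
gravity_forecast <- function(fit, L_future, M_future) {
  stopifnot(inherits(fit, "gravity_fit"),
            length(L_future) == length(M_future))
  e <- fit$exponents
  fit$a_grav * L_future^e$alpha * M_future^e$beta -
    fit$b_grav * L_future^e$gamma * M_future^e$delta
}

#' Gravity point forecasts for every country, on the rate scale
#'
#' Fits [fit_gravity()] per country on the historical counts (with `L` the
#' country's own population and `M` world minus `L`, both from the dataset's
#' population table) and forecasts with projected populations.
#'
#' @param data a [migration_dataset()] (complete series; countries with
#'   fewer than 2 observations are forecast as `NA`).
#' @param exponents a [gravity_exponents()].
#' @param horizon number of future periods.
#' @param future_pops countries x horizon population matrix.
#' @return countries x horizon matrix of forecast rates.
#' @export
gravity_forecast_all <- function(data, exponents, horizon, future_pops) {
  stopifnot(inherits(data, "migration_dataset"))
  future_pops <- as.matrix(future_pops)
  C <- length(data$country_ids)
  if (nrow(future_pops) != C || ncol(future_pops) < horizon)
    stop("future_pops must be countries x horizon")
  world <- colSums(data$populations, na.rm = TRUE)
  world_f <- colSums(future_pops[, seq_len(horizon), drop = FALSE])
  out <- matrix(NA_real_, C, horizon,
                dimnames = list(data$country_ids, NULL))
  for (i in seq_len(C)) {
    obs <- which(!is.na(data$counts[i, ]))
    if (length(obs) < 2L) next
    Lh <- data$populations[i, obs]
    fit <- suppressWarnings(
      fit_gravity(data$counts[i, obs], Lh, world[obs] - Lh, exponents))
    Lf <- future_pops[i, seq_len(horizon)]
    counts_f <- gravity_forecast(fit, Lf, world_f - Lf)
    out[i, ] <- counts_to_rates(matrix(counts_f, 1L), matrix(Lf, 1L),
                                data$period_length)
  }
  out
}
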