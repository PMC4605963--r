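# Dataset container and CSV plumbing for WPP-style net migration inputs.
#
# Conventions (declared, configurable):
#   * rates r[c, t] are ANNUAL net migrants per thousand population,
#   * counts y[c, t] are net migrants over the WHOLE period,
#   * populations n[c, t] are period-average persons,
#   * count = rate / 1000 * population * period_length   (period_length in years,
#     default 5, equal to the spacing of the period grid).
# A period labelled by its start year covers [start, start + period_length).

#' Construct a net-migration dataset
#'
#' Bundles per-country five-year net migration rates, counts and period-average
#' populations on a common (country x period) grid. Exactly one of `rates` or
#' `counts` may be omitted; the missing one is derived through the package's
#' rate/count convention (see [rates_to_counts()]).
#'
#' Leading `NA` periods are allowed per country (a country may enter the sample
#' late); interior gaps are rejected rather than imputed. Countries with
#' leading gaps are recorded in the `"late_entry"` attribute.
#'
#' @param country_ids character vector of country codes (unique, length C).
#' @param period_starts integer start years of the periods (strictly
#'   increasing, constant spacing; length T).
#' @param rates C x T matrix of annual net migration rates per thousand.
#' @param counts C x T matrix of per-period net migrant counts.
#' @param populations C x T matrix of period-average populations (persons,
#'   strictly positive where observed).
#' @param period_length period length in years; default the grid spacing.
#' @return an object of class `migration_dataset`: a list with elements
#'   `country_ids`, `period_starts`, `rates`, `counts`, `populations`,
#'   `period_length`.
#' @export
migration_dataset <- function(country_ids, period_starts, rates = NULL,
                              counts = NULL, populations,
                              period_length = NULL) {
  country_ids <- as.character(country_ids)
  period_starts <- as.numeric(period_starts)
  if (anyDuplicated(country_ids))
    stop("duplicate country ids: ",
         paste(unique(country_ids[duplicated(country_ids)]), collapse = ", "))
  if (length(period_starts) < 1L) stop("at least one period is required")
  if (length(period_starts) > 1L) {
    sp <- diff(period_starts)
    if (any(sp <= 0)) stop("period_starts must be strictly increasing")
    if (max(sp) - min(sp) > 1e-9)
      stop("period grid must have constant spacing; got spacings ",
           paste(unique(sp), collapse = ", "))
    if (is.null(period_length)) period_length <- sp[1L]
  } else if (is.null(period_length)) {
    period_length <- 5
  }
  populations <- as_cxt_matrix(populations, country_ids, period_starts,
                               "populations")
  if (is.null(rates) && is.null(counts))
    stop("one of rates or counts must be supplied")
  if (!is.null(rates))
    rates <- as_cxt_matrix(rates, country_ids, period_starts, "rates")
  if (!is.null(counts))
    counts <- as_cxt_matrix(counts, country_ids, period_starts, "counts")
  if (is.null(counts))
    counts <- rates_to_counts(rates, populations, period_length)
  if (is.null(rates))
    rates <- counts_to_rates(counts, populations, period_length)
  out <- structure(
    list(country_ids = country_ids, period_starts = period_starts,
         rates = rates, counts = counts, populations = populations,
         period_length = period_length),
    class = "migration_dataset")
  validate_migration_dataset(out)
}

# coerce to a C x T matrix with dimnames country x period
as_cxt_matrix <- function(x, country_ids, period_starts, what) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop(what, " must be numeric")
  if (nrow(x) != length(country_ids) || ncol(x) != length(period_starts))
    stop(what, " must be ", length(country_ids), " x ", length(period_starts),
         " (countries x periods); got ", nrow(x), " x ", ncol(x))
  dimnames(x) <- list(country_ids, period_starts)
  x
}

#' Validate a migration dataset
#'
#' Checks the container invariants: matching dimensions, a strictly increasing
#' constant-spacing period grid, strictly positive populations, finite rates,
#' no interior missing values, and rate/count consistency under the conversion
#' convention (relative tolerance 1e-9).
#'
#' @param x a `migration_dataset`.
#' @return `x`, invisibly, with the `"late_entry"` attribute set to the ids of
#'   countries whose series start after the first period.
#' @export
validate_migration_dataset <- function(x) {
  stopifnot(inherits(x, "migration_dataset"))
  C <- length(x$country_ids); T_ <- length(x$period_starts)
  for (f in c("rates", "counts", "populations"))
    if (!all(dim(x[[f]]) == c(C, T_)))
      stop(f, " has wrong dimensions")
  late <- character(0)
  for (i in seq_len(C)) {
    obs <- !is.na(x$rates[i, ])
    if (!any(obs))
      stop("country ", x$country_ids[i], " has no observed periods")
    first <- which(obs)[1L]
    if (any(!obs[first:T_]))
      stop("country ", x$country_ids[i],
           " has interior missing periods (ragged grid); ",
           "only leading gaps are allowed")
    if (first > 1L) late <- c(late, x$country_ids[i])
    if (any(!is.finite(x$rates[i, obs])))
      stop("non-finite rate for country ", x$country_ids[i])
    pop <- x$populations[i, obs]
    if (any(is.na(pop)) || any(pop <= 0))
      stop("non-positive or missing population for country ",
           x$country_ids[i])
  }
  expected <- rates_to_counts(x$rates, x$populations, x$period_length)
  obs <- !is.na(expected) & !is.na(x$counts)
  if (any(obs)) {
    rel <- abs(x$counts[obs] - expected[obs]) /
      pmax(abs(expected[obs]), 1e-300)
    bad <- rel > 1e-9 & abs(x$counts[obs] - expected[obs]) > 1e-9
    if (any(bad))
      stop("counts inconsistent with rates x populations x period_length/1000")
  }
  attr(x, "late_entry") <- late
  invisible(x)
}

#' @export
print.migration_dataset <- function(x, ...) {
  cat("<migration_dataset> ", length(x$country_ids), " countries x ",
      length(x$period_starts), " periods (",
      min(x$period_starts), "-", max(x$period_starts), ", length ",
      x$period_length, "y)\n", sep = "")
  invisible(x)
}

#' Convert net migration rates to counts
#'
#' `count = rate / 1000 * population * period_length`. Rates are annual per
#' thousand; counts cover the whole period. Exact inverse of
#' [counts_to_rates()].
#'
#' @param rates matrix (or vector) of annual rates per thousand.
#' @param populations matching matrix of period-average populations (> 0).
#' @param period_length period length in years (default 5).
#' @return matrix of per-period net migrant counts.
#' @export
rates_to_counts <- function(rates, populations, period_length = 5) {
  check_conversion_args(rates, populations, period_length)
  rates / 1000 * populations * period_length
}

#' Convert net migration counts to rates
#'
#' Inverse of [rates_to_counts()]: `rate = count * 1000 / (population *
#' period_length)`.
#'
#' @inheritParams rates_to_counts
#' @param counts matrix of per-period net migrant counts.
#' @return matrix of annual rates per thousand.
#' @export
counts_to_rates <- function(counts, populations, period_length = 5) {
  check_conversion_args(counts, populations, period_length)
  counts * 1000 / (populations * period_length)
}

check_conversion_args <- function(x, populations, period_length) {
  if (length(dim(x)) != length(dim(populations)) ||
      !all(dim(x) == dim(populations)) || length(x) != length(populations))
    stop("shape mismatch between values and populations")
  if (any(populations <= 0, na.rm = TRUE))
    stop("populations must be strictly positive")
  if (!is.numeric(period_length) || length(period_length) != 1L ||
      period_length <= 0)
    stop("period_length must be a positive scalar")
  invisible(TRUE)
}

#' Read a migration dataset from CSV
#'
#' Expects columns `country_id`, `period_start`, `value`, `population` (an
#' optional `country_name` is carried through untouched), one row per
#' (country, period). `kind` says whether `value` holds rates or counts; the
#' other is derived.
#'
#' @param path CSV file path.
#' @param kind `"rates"` or `"counts"`: interpretation of the `value` column.
#' @return a validated [migration_dataset()].
#' @export
read_migration_dataset <- function(path, kind = c("rates", "counts")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("country_id", "period_start", "value", "population")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  key <- paste(df$country_id, df$period_start)
  if (anyDuplicated(key))
    stop("duplicate (country, period) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  bad_pop <- which(!is.na(df$population) & df$population <= 0)
  if (length(bad_pop))
    stop("non-positive population in row ", bad_pop[1L], " (country ",
         df$country_id[bad_pop[1L]], ", period ",
         df$period_start[bad_pop[1L]], ")")
  periods <- sort(unique(df$period_start))
  countries <- unique(df$country_id)
  C <- length(countries); T_ <- length(periods)
  val <- pop <- matrix(NA_real_, C, T_, dimnames = list(countries, periods))
  i <- match(df$country_id, countries)
  j <- match(df$period_start, periods)
  val[cbind(i, j)] <- df$value
  pop[cbind(i, j)] <- df$population
  if (kind == "rates")
    migration_dataset(countries, periods, rates = val, populations = pop)
  else
    migration_dataset(countries, periods, counts = val, populations = pop)
}

#' Write a migration dataset to CSV
#'
#' Writes the reader's column layout (`country_id`, `period_start`, `value`,
#' `population`) at full double precision, so a read-back reproduces the value
#' columns bit-comparably. Rows with unobserved (leading-gap) periods are
#' omitted.
#'
#' @param x a `migration_dataset`.
#' @param path output CSV path.
#' @param kind which quantity to place in the `value` column.
#' @return `path`, invisibly.
#' @export
write_migration_dataset <- function(x, path, kind = c("rates", "counts")) {
  kind <- match.arg(kind)
  stopifnot(inherits(x, "migration_dataset"))
  value <- if (kind == "rates") x$rates else x$counts
  df <- data.frame(
    country_id = rep(x$country_ids, times = length(x$period_starts)),
    period_start = rep(x$period_starts, each = length(x$country_ids)),
    value = as.vector(value),
    population = as.vector(x$populations),
    stringsAsFactors = FALSE)
  df <- df[!is.na(df$value), , drop = FALSE]
  df <- df[order(df$country_id, df$period_start), , drop = FALSE]
  write_csv_full_precision(df, path)
  invisible(path)
}

# full-precision CSV writer: doubles via %.17g survive a read.csv round trip
write_csv_full_precision <- function(df, path) {
  for (nm in names(df))
    if (is.double(df[[nm]]))
      df[[nm]] <- ifelse(is.na(df[[nm]]), "NA",
                         sprintf("%.17g", df[[nm]]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

## ---- migration schedules ----------------------------------------------

#' Default five-year age groups
#'
#' Seventeen five-year age groups, `0-4` through `80+`.
#' @return character vector of age-group labels.
#' @export
default_age_groups <- function() {
  c(paste(seq(0, 75, 5), seq(4, 79, 5), sep = "-"), "80+")
}

#' Construct a migration schedule
#'
#' Age x sex weights distributing a country's net migration count across
#' demographic cells. Weights must sum to 1 within `tol` (they are then
#' renormalized to sum to 1 exactly); negative entries are permitted, since
#' net age schedules can change sign by age.
#'
#' @param country_id country code.
#' @param weights numeric matrix, ages in rows, sexes in columns.
#' @param tol tolerance on `sum(weights) - 1` (default 1e-6).
#' @return object of class `migration_schedule`.
#' @export
migration_schedule <- function(country_id, weights, tol = 1e-6) {
  weights <- as.matrix(weights)
  if (!all(is.finite(weights))) stop("schedule weights must be finite")
  s <- sum(weights)
  if (abs(s - 1) > tol)
    stop("schedule weights for country ", country_id, " sum to ",
         format(s), ", not 1")
  structure(list(country_id = as.character(country_id),
                 weights = weights / s),
            class = "migration_schedule")
}

#' Uniform migration schedule
#'
#' Equal weight on every age x sex cell; the default attached to countries
#' with no schedule on file.
#'
#' @param country_id country code.
#' @param age_groups age-group labels (default [default_age_groups()]).
#' @param sexes sex labels (default `c("F", "M")`).
#' @return a [migration_schedule()].
#' @export
uniform_schedule <- function(country_id, age_groups = default_age_groups(),
                             sexes = c("F", "M")) {
  w <- matrix(1 / (length(age_groups) * length(sexes)),
              length(age_groups), length(sexes),
              dimnames = list(age_groups, sexes))
  migration_schedule(country_id, w)
}

#' Read migration schedules from CSV
#'
#' Expects columns `country_id`, `age_group`, `sex`, `weight`; sex labels must
#' be `F` or `M` (case-insensitive). Per-country weights must sum to 1 within
#' 1e-6.
#'
#' @param path CSV file path.
#' @return named list of [migration_schedule()] objects, one per country.
#' @export
read_migration_schedules <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("country_id", "age_group", "sex", "weight")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  sex <- toupper(as.character(df$sex))
  bad <- setdiff(unique(sex), c("F", "M"))
  if (length(bad))
    stop("unknown sex label(s): ", paste(bad, collapse = ", "),
         " (expected F or M)")
  df$sex <- sex
  out <- list()
  for (cid in unique(df$country_id)) {
    sub <- df[df$country_id == cid, , drop = FALSE]
    ages <- unique(sub$age_group)
    sexes <- sort(unique(sub$sex))
    w <- matrix(0, length(ages), length(sexes),
                dimnames = list(ages, sexes))
    w[cbind(match(sub$age_group, ages), match(sub$sex, sexes))] <- sub$weight
    out[[as.character(cid)]] <- migration_schedule(cid, w)
  }
  out
}

#' Write migration schedules to CSV
#'
#' @param schedules named list of [migration_schedule()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_migration_schedules <- function(schedules, path) {
  rows <- lapply(schedules, function(s) {
    w <- s$weights
    data.frame(country_id = s$country_id,
               age_group = rep(rownames(w), times = ncol(w)),
               sex = rep(colnames(w), each = nrow(w)),
               weight = as.vector(w), stringsAsFactors = FALSE)
  })
  write_csv_full_precision(do.call(rbind, rows), path)
  invisible(path)
}
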