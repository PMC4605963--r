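# MCMC over the hierarchical AR(1) model: conjugate Gibbs updates for mu_c,
# phi_c, sigma2_c, lambda and b; slice sampling (stepping-out + shrinkage)
# for tau and a. Truncated conditionals are sampled by inverse CDF with
# quantile arguments clamped away from 0/1 by 1e-12.

#' MCMC configuration
#'
#' @param n_iterations total sweeps per chain (default 12000).
#' @param burn_in sweeps discarded per chain (default 2000).
#' @param thin keep every `thin`-th sweep after burn-in (default 10);
#'   `(n_iterations - burn_in)` must be divisible by `thin`.
#' @param n_chains number of independent chains (default 3).
#' @param seed integer RNG seed; all chain seeds derive from it.
#' @param slice_width named initial slice widths for the two slice-sampled
#'   hyperparameters, `c(tau = ..., a = ...)`.
#' @param init_strategy `"data"` (moment-based starting values) or `"prior"`
#'   (drawn from the priors).
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iterations = 12000, burn_in = 2000, thin = 10,
                        n_chains = 3, seed = 1,
                        slice_width = c(tau = 1, a = 0.5),
                        init_strategy = c("data", "prior")) {
  init_strategy <- match.arg(init_strategy)
  stopifnot(n_iterations > burn_in, burn_in >= 0, thin >= 1, n_chains >= 1)
  if ((n_iterations - burn_in) %% thin != 0)
    stop("(n_iterations - burn_in) must be divisible by thin")
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 n_chains = as.integer(n_chains), seed = as.integer(seed),
                 slice_width = slice_width,
                 init_strategy = init_strategy),
            class = "mcmc_config")
}

# inverse-CDF truncated normal; u clamped to [1e-12, 1 - 1e-12]
rtruncnorm_icdf <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi_ <- stats::pnorm(upper, mean, sd)
  u <- plo + stats::runif(n) * (phi_ - plo)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  x <- stats::qnorm(u, mean, sd)
  pmin(pmax(x, lower), upper)
}

# inverse-CDF gamma truncated to (0, upper)
rtruncgamma_icdf <- function(n, shape, rate, upper) {
  phi_ <- stats::pgamma(upper, shape, rate)
  u <- stats::runif(n) * phi_
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  pmin(stats::qgamma(u, shape, rate), upper)
}

# univariate slice sampler, stepping-out + shrinkage (Neal 2003). logf must
# return -Inf outside the support; bounds cap the stepping-out.
slice_sample_1d <- function(x0, logf, w, lower = -Inf, upper = Inf,
                            max_steps = 100L) {
  f0 <- logf(x0)
  if (!is.finite(f0))
    stop("slice sampler started outside the support (logf = ", f0, ")")
  y <- f0 - stats::rexp(1)
  u <- stats::runif(1)
  L <- x0 - w * u
  R <- L + w
  j <- max_steps
  while (j > 0L && L > lower && logf(L) > y) { L <- L - w; j <- j - 1L }
  j <- max_steps
  while (j > 0L && R < upper && logf(R) > y) { R <- R + w; j <- j - 1L }
  L <- max(L, lower); R <- min(R, upper)
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) >= y) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

# moment-based initial state (all values inside the printed supports)
init_state_data <- function(data) {
  r <- data$rates
  mu <- rowMeans(r, na.rm = TRUE)
  s2 <- apply(r, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(1)
    stats::var(x)
  })
  s2 <- pmax(s2, 1e-4)
  lam <- mean(mu)
  lam <- min(max(lam, -99), 99)
  tau <- stats::sd(mu)
  if (!is.finite(tau)) tau <- 1
  tau <- min(max(tau, 0.01), 99)
  a <- 2
  b <- min(max((a - 1) * stats::median(s2), 1e-3), 100 * (a - 1) * 0.99)
  model_params(mu = mu, phi = rep(0.5, nrow(r)), sigma2 = s2,
               lam = lam, tau = tau, a = a, b = b,
               country_ids = data$country_ids)
}

init_state_prior <- function(data) {
  C <- length(data$country_ids)
  a <- stats::runif(1, 1.5, 5)
  b <- stats::runif(1, 0.5, 50)
  b <- min(b, 100 * (a - 1) * 0.99)
  lam <- stats::runif(1, -5, 5)
  tau <- stats::runif(1, 0.5, 5)
  model_params(mu = stats::rnorm(C, lam, tau),
               phi = stats::runif(C), sigma2 = 1 / stats::rgamma(C, a, b),
               lam = lam, tau = tau, a = a, b = b,
               country_ids = data$country_ids)
}

#' Run the Gibbs/slice sampler
#'
#' One sweep updates, in fixed order: every `mu_c` (Gibbs, [cond_mu()]),
#' every `phi_c` (Gibbs, truncated normal from [cond_phi()]), every
#' `sigma2_c` (Gibbs, [cond_sigma2()]), `lambda` (Gibbs, truncated normal),
#' `tau` (slice on [log_cond_tau()]), `a` (slice on [log_cond_a()]), `b`
#' (Gibbs, truncated gamma from [cond_b()]). Identical seed, config and data
#' give bitwise-identical draws.
#'
#' @param data a [migration_dataset()] with at least one country having two
#'   or more observed periods.
#' @param config an [mcmc_config()].
#' @param freeze character vector of parameter blocks NOT to update (any of
#'   `"mu"`, `"phi"`, `"sigma2"`, `"lam"`, `"tau"`, `"a"`, `"b"`); intended
#'   for sampler validation.
#' @param init optional [model_params()] starting state (overrides
#'   `init_strategy`; required to be meaningful when blocks are frozen).
#' @return object of class `posterior_sample`: matrices `mu`, `phi`, `sigma2`
#'   (draws x countries), vectors `lam`, `tau`, `a`, `b`, `chain_id`, plus
#'   `country_ids` and the `config` echo.
#' @export
run_mcmc <- function(data, config = mcmc_config(), freeze = character(0),
                     init = NULL) {
  stopifnot(inherits(data, "migration_dataset"))
  tr <- dataset_transitions(data)
  if (!any(tr$n_trans >= 1L))
    stop("no country has two or more observed periods")
  C <- length(data$country_ids)
  bad <- setdiff(freeze, c("mu", "phi", "sigma2", "lam", "tau", "a", "b"))
  if (length(bad)) stop("unknown freeze block(s): ", paste(bad, collapse = ", "))
  upd <- !(c(mu = "mu", phi = "phi", sigma2 = "sigma2", lam = "lam",
             tau = "tau", a = "a", b = "b") %in% freeze)
  names(upd) <- c("mu", "phi", "sigma2", "lam", "tau", "a", "b")

  n_keep <- (config$n_iterations - config$burn_in) %/% config$thin
  N <- n_keep * config$n_chains
  out <- list(mu = matrix(NA_real_, N, C, dimnames = list(NULL, data$country_ids)),
              phi = matrix(NA_real_, N, C, dimnames = list(NULL, data$country_ids)),
              sigma2 = matrix(NA_real_, N, C, dimnames = list(NULL, data$country_ids)),
              lam = numeric(N), tau = numeric(N), a = numeric(N),
              b = numeric(N), chain_id = integer(N))

  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, config$n_chains)
  w_tau <- config$slice_width[["tau"]]
  w_a <- config$slice_width[["a"]]
  prev <- tr$prev; curr <- tr$curr; valid <- tr$valid
  n_trans <- tr$n_trans

  row <- 0L
  for (chain in seq_len(config$n_chains)) {
    set.seed(chain_seeds[chain])
    st <- if (!is.null(init)) init
          else if (config$init_strategy == "data") init_state_data(data)
          else init_state_prior(data)
    mu <- st$mu; phi <- st$phi; s2 <- st$sigma2
    lam <- st$lam; tau <- st$tau; a <- st$a; b <- st$b
    for (it in seq_len(config$n_iterations)) {
      if (upd[["mu"]]) {
        k <- 1 - phi
        d_sum <- rowSums((curr - phi * prev) * valid)
        prec <- n_trans * k^2 / s2 + 1 / tau^2
        m <- (k * d_sum / s2 + lam / tau^2) / prec
        mu <- stats::rnorm(C, m, sqrt(1 / prec))
      }
      if (upd[["phi"]]) {
        x <- (prev - mu) * valid
        z <- (curr - mu) * valid
        sxx <- rowSums(x * x)
        sxz <- rowSums(x * z)
        deg <- sxx == 0
        sxx_safe <- ifelse(deg, 1, sxx)
        phi <- rtruncnorm_icdf(C, sxz / sxx_safe, sqrt(s2 / sxx_safe), 0, 1)
        if (any(deg)) phi[deg] <- stats::runif(sum(deg))
      }
      if (upd[["sigma2"]]) {
        eps <- ((curr - mu) - phi * (prev - mu)) * valid
        shape <- a + n_trans / 2
        rate <- b + rowSums(eps^2) / 2
        s2 <- 1 / stats::rgamma(C, shape = shape, rate = rate)
      }
      if (upd[["lam"]])
        lam <- rtruncnorm_icdf(1, mean(mu), tau / sqrt(C), -100, 100)
      st_hyper <- list(mu = mu, sigma2 = s2, lam = lam, b = b)
      if (upd[["tau"]])
        tau <- slice_sample_1d(tau, function(t_) log_cond_tau(t_, st_hyper),
                               w = w_tau, lower = 0, upper = 100)
      if (upd[["a"]])
        a <- slice_sample_1d(a, function(a_) log_cond_a(a_, st_hyper),
                             w = w_a, lower = 1, upper = 10)
      if (upd[["b"]]) {
        cb <- cond_b(list(sigma2 = s2, a = a))
        b <- rtruncgamma_icdf(1, cb$shape, cb$rate, cb$upper)
      }
      state_vec <- c(mu, phi, s2, lam, tau, a, b)
      if (any(!is.finite(state_vec))) {
        nm <- c(paste0("mu[", seq_len(C), "]"), paste0("phi[", seq_len(C), "]"),
                paste0("sigma2[", seq_len(C), "]"), "lam", "tau", "a", "b")
        stop("non-finite state at iteration ", it, " (chain ", chain,
             "): ", nm[which(!is.finite(state_vec))[1L]])
      }
      if (it > config$burn_in &&
          (it - config$burn_in) %% config$thin == 0L) {
        row <- row + 1L
        out$mu[row, ] <- mu; out$phi[row, ] <- phi; out$sigma2[row, ] <- s2
        out$lam[row] <- lam; out$tau[row] <- tau
        out$a[row] <- a; out$b[row] <- b
        out$chain_id[row] <- chain
      }
    }
  }
  structure(c(out, list(country_ids = data$country_ids, config = config)),
            class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat("<posterior_sample> ", length(x$lam), " draws (",
      x$config$n_chains, " chain(s)) x ", ncol(x$mu),
      " countries\n", sep = "")
  invisible(x)
}

# number of draws in a posterior sample
n_draws <- function(sample) length(sample$lam)

# extract draw k as a model_params state
posterior_draw <- function(sample, k) {
  model_params(mu = sample$mu[k, ], phi = sample$phi[k, ],
               sigma2 = sample$sigma2[k, ], lam = sample$lam[k],
               tau = sample$tau[k], a = sample$a[k], b = sample$b[k],
               country_ids = sample$country_ids, validate = FALSE)
}

## ---- diagnostics -------------------------------------------------------

# split-Rhat: each chain halved, then the usual between/within variance ratio
split_rhat <- function(x, chain_id) {
  halves <- list()
  for (ch in unique(chain_id)) {
    xc <- x[chain_id == ch]
    n <- length(xc)
    if (n < 4L) return(NA_real_)
    h <- n %/% 2L
    halves <- c(halves, list(xc[1:h]), list(xc[(h + 1L):(2L * h)]))
  }
  m <- length(halves)
  n <- length(halves[[1L]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size: Geyer initial-positive-sequence estimate per chain,
# summed over chains; a zero-variance chain contributes 1.
# ESS = n / (-1 + 2 sum_m Gamma_m), Gamma_m = rho_{2m} + rho_{2m+1},
# summed while positive (rho_0 = 1).
ess_chain <- function(x) {
  n <- length(x)
  v <- stats::var(x)
  if (!is.finite(v) || v == 0) return(1)
  rho <- stats::acf(x, lag.max = min(n - 2L, 1000L), plot = FALSE,
                    demean = TRUE)$acf[, 1L, 1L]
  s <- 0
  m <- 1L
  while (m + 1L <= length(rho)) {
    pair <- rho[m] + rho[m + 1L]
    if (pair <= 0) break
    s <- s + pair
    m <- m + 2L
  }
  tau_int <- max(-1 + 2 * s, 1e-12)
  max(1, min(n, n / tau_int))
}

ess <- function(x, chain_id) {
  sum(vapply(unique(chain_id), function(ch) ess_chain(x[chain_id == ch]),
             numeric(1)))
}

#' Posterior summary and convergence diagnostics
#'
#' Per scalar parameter: posterior mean, sd, quantiles (2.5/50/97.5 %),
#' split-Rhat and effective sample size. Parameters with Rhat above
#' `rhat_warn` are flagged; single-chain Rhat is computed on split halves.
#'
#' @param sample a `posterior_sample` from [run_mcmc()].
#' @param rhat_warn flag threshold (default 1.05).
#' @return data.frame with one row per scalar parameter; the flagged subset
#'   is attached as attribute `"warnings"`.
#' @export
mcmc_diagnostics <- function(sample, rhat_warn = 1.05) {
  stopifnot(inherits(sample, "posterior_sample"))
  cid <- sample$chain_id
  cols <- list()
  for (blk in c("mu", "phi", "sigma2"))
    for (j in seq_len(ncol(sample[[blk]])))
      cols[[paste0(blk, "[", sample$country_ids[j], "]")]] <- sample[[blk]][, j]
  for (blk in c("lam", "tau", "a", "b")) cols[[blk]] <- sample[[blk]]
  res <- do.call(rbind, lapply(names(cols), function(nm) {
    x <- cols[[nm]]
    q <- stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(parameter = nm, mean = mean(x), sd = stats::sd(x),
               q2.5 = q[1L], q50 = q[2L], q97.5 = q[3L],
               rhat = split_rhat(x, cid), ess = ess(x, cid),
               stringsAsFactors = FALSE)
  }))
  res$flagged <- !is.na(res$rhat) & res$rhat > rhat_warn
  attr(res, "warnings") <- res$parameter[res$flagged]
  res
}

## ---- posterior CSV I/O -------------------------------------------------

#' Write posterior draws to CSV (long format)
#'
#' Columns `chain`, `iteration` (index of the stored draw within its chain),
#' `parameter`, `value`.
#'
#' @param sample a `posterior_sample`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_posterior_csv <- function(sample, path) {
  cid <- sample$chain_id
  iter <- stats::ave(seq_along(cid), cid, FUN = seq_along)
  blocks <- list()
  for (blk in c("mu", "phi", "sigma2")) {
    m <- sample[[blk]]
    blocks[[blk]] <- data.frame(
      chain = rep(cid, times = ncol(m)),
      iteration = rep(iter, times = ncol(m)),
      parameter = rep(paste0(blk, "[", sample$country_ids, "]"),
                      each = nrow(m)),
      value = as.vector(m), stringsAsFactors = FALSE)
  }
  for (blk in c("lam", "tau", "a", "b"))
    blocks[[blk]] <- data.frame(chain = cid, iteration = iter,
                                parameter = blk, value = sample[[blk]],
                                stringsAsFactors = FALSE)
  write_csv_full_precision(do.call(rbind, blocks), path)
  invisible(path)
}

#' Read posterior draws from a long-format CSV
#'
#' Inverse of [write_posterior_csv()].
#'
#' @param path CSV path.
#' @return a `posterior_sample` (without a config echo).
#' @export
read_posterior_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  key <- paste(df$chain, df$iteration)
  draws <- unique(key)
  N <- length(draws)
  row_of <- match(key, draws)
  is_vec <- grepl("^(mu|phi|sigma2)\\[", df$parameter)
  cids <- unique(sub("^mu\\[(.*)\\]$", "\\1",
                     df$parameter[grepl("^mu\\[", df$parameter)]))
  out <- list(mu = matrix(NA_real_, N, length(cids), dimnames = list(NULL, cids)),
              phi = matrix(NA_real_, N, length(cids), dimnames = list(NULL, cids)),
              sigma2 = matrix(NA_real_, N, length(cids), dimnames = list(NULL, cids)),
              lam = numeric(N), tau = numeric(N), a = numeric(N), b = numeric(N),
              chain_id = as.integer(vapply(strsplit(draws, " "), `[`,
                                           character(1), 1L)))
  vec_rows <- which(is_vec)
  blk <- sub("^([a-z0-9]+)\\[.*$", "\\1", df$parameter[vec_rows])
  cc <- sub("^[a-z0-9]+\\[(.*)\\]$", "\\1", df$parameter[vec_rows])
  for (b_ in c("mu", "phi", "sigma2")) {
    sel <- vec_rows[blk == b_]
    out[[b_]][cbind(row_of[sel], match(cc[blk == b_], cids))] <- df$value[sel]
  }
  for (b_ in c("lam", "tau", "a", "b")) {
    sel <- which(df$parameter == b_)
    out[[b_]][row_of[sel]] <- df$value[sel]
  }
  structure(c(out, list(country_ids = cids, config = NULL)),
            class = "posterior_sample")
}
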