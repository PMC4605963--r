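# trajectory simulation: AR(1) step, disaggregation, zero-sum correction,
# composed projection, quantile summaries, correction sensitivity

test_that("zero_sum_correct: worked example, fixed point, degenerate case", {
  # overflow 40 redistributed by population shares 0.25 / 0.75
  expect_equal(zero_sum_correct(c(100, -60), c(1000, 3000)), c(90, -90))
  # already balanced input is unchanged
  expect_equal(zero_sum_correct(c(70, -70), c(1000, 3000)), c(70, -70))
  # single country: the whole overflow is removed
  expect_equal(zero_sum_correct(7, 1000), 0)
  expect_error(zero_sum_correct(c(1, 2), c(0, 0)), "all zero")
})

test_that("zero_sum_correct: conservation and idempotence on random cases", {
  set.seed(31)
  for (C in c(1, 2, 5, 50)) {
    y <- rnorm(C, 0, 1e5) * sample(c(-1, 1), C, replace = TRUE)
    n <- exp(runif(C, log(1e3), log(1e9)))  # extreme population ratios
    y1 <- zero_sum_correct(y, n)
    expect_lt(abs(sum(y1)), 1e-6)
    expect_equal(zero_sum_correct(y1, n), y1, tolerance = 1e-12)
  }
})

test_that("disaggregate_counts splits proportionally and conserves totals", {
  sch <- list(AA = migration_schedule("AA", matrix(c(0.7, 0.3), 2, 1,
                                                   dimnames = list(c("X", "Y"),
                                                                   "F"))),
              BB = migration_schedule("BB", matrix(c(0.5, 0.5), 2, 1,
                                                   dimnames = list(c("X", "Y"),
                                                                   "F"))))
  out <- disaggregate_counts(c(AA = 100, BB = -50), sch)
  expect_equal(out["AA", , "F"], c(X = 70, Y = 30))
  expect_equal(out["BB", , "F"], c(X = -25, Y = -25))

  # mixed-sign weights still conserve the total
  schm <- list(AA = migration_schedule("AA", matrix(c(1.2, -0.2), 2, 1,
                                                    dimnames = list(c("X", "Y"),
                                                                    "F"))))
  outm <- disaggregate_counts(c(AA = 10), schm)
  expect_equal(outm["AA", , "F"], c(X = 12, Y = -2))
  expect_equal(sum(outm), 10)

  expect_error(disaggregate_counts(c(AA = 1, CC = 2), sch),
               "no schedule for country CC")
  # ... unless a default is supplied
  out2 <- disaggregate_counts(c(AA = 1, CC = 2), sch,
                              default = sch$BB)
  expect_equal(sum(out2["CC", , ]), 2)
})

test_that("simulate_rate_step: noise-free limits and Monte-Carlo mean", {
  p <- model_params(mu = c(1, -2), phi = c(0.5, 0.8),
                    sigma2 = c(1e-300, 1e-300), lam = 0, tau = 1, a = 2,
                    b = 1, validate = FALSE)
  expect_equal(simulate_rate_step(p, c(3, 0)),
               c(1 + 0.5 * 2, -2 + 0.8 * 2))
  p0 <- model_params(mu = 4, phi = 1e-300, sigma2 = 1e-300, 0, 1, 2, 1,
                     validate = FALSE)
  expect_equal(simulate_rate_step(p0, 123), 4)

  pn <- model_params(mu = 2, phi = 0.6, sigma2 = 4, 0, 1, 2, 1)
  set.seed(55)
  draws <- replicate(10000, simulate_rate_step(pn, 5))
  analytic <- 2 + 0.6 * 3
  se <- 2 / sqrt(10000)
  expect_lt(abs(mean(draws) - analytic), 3 * se)
})

test_that("project: deterministic composition at sigma2 -> 0", {
  # symmetric two-country world: counts cancel, correction is a no-op,
  # so the output is exactly the AR(1) mean step
  d <- make_dataset(matrix(c(2, -2, 2, -2), 2, 2),
                    pops = matrix(1e6, 2, 2))
  post <- make_point_posterior(mu = c(1, -1), phi = c(0.5, 0.5),
                               sigma2 = c(1e-300, 1e-300))
  fp <- matrix(1e6, 2, 1, dimnames = list(NULL, 2010))
  traj <- project_migration(post, d, fp,
                            config = projection_config(1, 3, seed = 1))
  expect_equal(traj$rates[1, , 1], c(A01 = 1.5, A02 = -1.5))
  expect_equal(traj$rates, traj$rates_uncorrected)
})

test_that("project: world total is zero per (trajectory, period, cell)", {
  gen <- generate_synthetic(synthetic_spec(C = 5, T_ = 6, seed = 21,
                                           n_age = 4, horizon_periods = 3))
  post <- run_mcmc(gen$dataset, mcmc_config(300, 100, 2, 1, seed = 12))
  traj <- project_migration(post, gen$dataset, gen$future_pops,
                            gen$schedules,
                            projection_config(3, 50, seed = 9),
                            store_age_sex = TRUE)
  sums <- apply(traj$counts_age_sex, c(1, 3, 4), sum)
  expect_lt(max(abs(sums)), 1e-6)
  tot <- apply(traj$counts, c(1, 3), sum)
  expect_lt(max(abs(tot)), 1e-6)
  # rates and counts mutually consistent under the conversion convention
  pops_arr <- aperm(array(traj$populations, c(5, 3, 50)), c(3, 1, 2))
  expect_equal(traj$counts, traj$rates / 1000 * pops_arr * 5,
               tolerance = 1e-12)
})

test_that("project: determinism and lead-1 predictive median", {
  gen <- generate_synthetic(synthetic_spec(C = 5, T_ = 6, seed = 22))
  post <- make_point_posterior(mu = gen$truth$mu, phi = gen$truth$phi,
                               sigma2 = gen$truth$sigma2)
  cfg <- projection_config(2, 4000, seed = 77)
  t1 <- project_migration(post, gen$dataset, gen$future_pops, config = cfg)
  t2 <- project_migration(post, gen$dataset, gen$future_pops, config = cfg)
  expect_identical(t1$rates, t2$rates)

  # uncorrected lead-1 median vs analytic AR(1) median, 3 SE of the median
  last <- gen$dataset$rates[, 6]
  analytic <- gen$truth$mu + gen$truth$phi * (last - gen$truth$mu)
  sdv <- sqrt(gen$truth$sigma2)
  med <- apply(t1$rates_uncorrected[, , 1], 2, median)
  se_med <- 1.2533 * sdv / sqrt(4000)  # asymptotic SE of a normal median
  expect_true(all(abs(med - analytic) < 3 * 1.2533 * sdv / sqrt(4000) +
                    1e-12))
  expect_lt(max(abs(med - analytic) / sdv), 0.1)
})

test_that("project input validation", {
  gen <- generate_synthetic(synthetic_spec(C = 3, T_ = 5, seed = 2,
                                           horizon_periods = 2))
  post <- make_point_posterior(mu = gen$truth$mu, phi = gen$truth$phi,
                               sigma2 = gen$truth$sigma2)
  expect_error(project_migration(post, gen$dataset, gen$future_pops,
                                 config = projection_config(5, 3, seed = 1)),
               "exceeds")
})

test_that("summarize_trajectories: quantiles behave", {
  # all trajectories identical -> every quantile equals the path
  arr <- array(rep(c(1, 2, 3, 4, 5, 6), each = 10), c(10, 2, 3))
  ts <- make_traj_set(arr)
  s <- summarize_trajectories(ts)
  expect_equal(s$q0.025, s$q0.975)
  expect_equal(s$q0.5[s$country_id == "A01"], c(1, 3, 5))

  # standard-normal fake trajectories: q97.5 near 1.96
  set.seed(12)
  arr2 <- array(rnorm(4000), c(4000, 1, 1))
  s2 <- summarize_trajectories(make_traj_set(arr2))
  expect_lt(abs(s2$q0.975 - qnorm(0.975)), 0.08)
  # monotonicity across levels at every (country, period)
  qcols <- as.matrix(s2[grep("^q", names(s2))])
  expect_true(all(apply(qcols, 1, function(x) all(diff(x) >= 0))))
})

test_that("correction_sensitivity: zero-overflow and hand-computed cases", {
  arr <- array(rnorm(24), c(4, 2, 3))
  ts0 <- make_traj_set(arr, rates_uncorrected = arr)
  d0 <- correction_sensitivity(ts0)
  expect_true(all(d0 == 0))

  # (+100, -60) counts at populations (1000, 3000): corrected counts
  # (90, -90); rate changes 10*1000/(1000*5) = 2 and 30*1000/(3000*5) = 2
  d <- make_dataset(matrix(c(20, -4, 20, -4), 2, 2),
                    pops = matrix(c(1000, 3000), 2, 2))
  post <- make_point_posterior(mu = c(20, -4), phi = c(0.5, 0.5),
                               sigma2 = c(1e-300, 1e-300))
  fp <- matrix(c(1000, 3000), 2, 1, dimnames = list(NULL, 1960))
  traj <- project_migration(post, d, fp,
                            config = projection_config(1, 2, seed = 1))
  expect_equal(unname(traj$counts[1, , 1]), c(90, -90))
  sens <- correction_sensitivity(traj)
  expect_equal(unname(sens[1, , 1]), c(2, 2))
  expect_true(all(sens >= 0))
  expect_equal(attr(sens, "summary")$fraction_below, 0)  # threshold 0.2
})
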