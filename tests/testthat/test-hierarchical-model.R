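# likelihood, prior, and the closed-form full conditionals, checked against
# hand evaluations and the grid-integration oracle

state1 <- function(mu = 0, phi = 0.5, sigma2 = 1) {
  model_params(mu = mu, phi = phi, sigma2 = sigma2,
               lam = 0, tau = 1, a = 2, b = 1, validate = FALSE)
}

test_that("log_likelihood matches direct normal density evaluation", {
  d <- make_dataset(matrix(c(0, 1), 1, 2))
  ll <- log_likelihood(state1(), d)
  # single transition: eps = (1 - 0) - 0.5 * (0 - 0) = 1, var 1
  expect_equal(as.numeric(ll), dnorm(1, 0, 1, log = TRUE))
  expect_equal(as.numeric(ll), -0.5 * log(2 * pi) - 0.5)

  # phi -> 0 degenerates to iid N(mu, sigma2) on r[2..T]
  set.seed(1)
  r <- matrix(rnorm(6), 1, 6)
  d2 <- make_dataset(r)
  st <- state1(mu = 0.3, phi = 1e-300, sigma2 = 2)
  expect_equal(as.numeric(log_likelihood(st, d2)),
               sum(dnorm(r[1, -1], 0.3, sqrt(2), log = TRUE)))

  # additivity across countries
  ra <- matrix(rnorm(4), 1, 4); rb <- matrix(rnorm(4), 1, 4)
  st2 <- model_params(mu = c(0.1, -0.2), phi = c(0.4, 0.7),
                      sigma2 = c(1, 2), lam = 0, tau = 1, a = 2, b = 1)
  both <- make_dataset(rbind(ra, rb))
  sa <- model_params(0.1, 0.4, 1, 0, 1, 2, 1)
  sb <- model_params(-0.2, 0.7, 2, 0, 1, 2, 1)
  expect_equal(as.numeric(log_likelihood(st2, both)),
               as.numeric(log_likelihood(sa, make_dataset(ra))) +
                 as.numeric(log_likelihood(sb, make_dataset(rb))))
})

test_that("log_likelihood is invariant under permutation of countries", {
  set.seed(42)
  r <- matrix(rnorm(12), 3, 4)
  st <- model_params(mu = rnorm(3), phi = runif(3), sigma2 = runif(3, 0.5, 2),
                     lam = 0, tau = 2, a = 2, b = 5)
  perm <- c(3, 1, 2)
  stp <- model_params(st$mu[perm], st$phi[perm], st$sigma2[perm],
                      0, 2, 2, 5)
  expect_equal(as.numeric(log_likelihood(st, make_dataset(r))) +
                 log_prior(st),
               as.numeric(log_likelihood(stp, make_dataset(r[perm, ]))) +
                 log_prior(stp))
})

test_that("log_prior: supports and termwise sum", {
  st <- model_params(mu = c(1, -2), phi = c(0.3, 0.6), sigma2 = c(1, 2),
                     lam = 0.5, tau = 2, a = 3, b = 10)
  # independent recomputation term by term
  expected <- sum(dnorm(c(1, -2), 0.5, 2, log = TRUE)) +
    sum(3 * log(10) - lgamma(3) - (3 + 1) * log(c(1, 2)) - 10 / c(1, 2)) +
    log(1 / 9) + log(1 / (100 * (3 - 1))) + log(1 / 200) + log(1 / 100)
  expect_equal(log_prior(st), expected)

  bad <- function(...) {
    st2 <- st; mod <- list(...)
    for (nm in names(mod)) st2[[nm]] <- mod[[nm]]
    log_prior(st2)
  }
  expect_identical(bad(a = 0.5), -Inf)            # outside U(1,10)
  expect_identical(bad(phi = c(1.2, 0.6)), -Inf)  # outside U(0,1)
  expect_identical(bad(b = 100 * (3 - 1) + 1), -Inf)
  expect_identical(bad(tau = 101), -Inf)
  expect_identical(bad(lam = -150), -Inf)
})

test_that("cond_mu: limits and hand case", {
  # tau^2 -> large with phi ~ 0: mean -> sample mean of r[2..T]
  r <- matrix(c(0, 1, 2, 4), 1, 4)
  d <- make_dataset(r)
  st <- model_params(0, 1e-12, 1, 0, 99, 2, 1, validate = FALSE)
  cm <- cond_mu(1, st, d)
  expect_equal(cm$mean, mean(r[1, -1]), tolerance = 1e-4)

  # phi -> 1: k = 0, data uninformative, conditional -> prior
  st2 <- model_params(0, 1 - 1e-14, 1, 0.7, 1.3, 2, 1, validate = FALSE)
  cm2 <- cond_mu(1, st2, d)
  expect_equal(cm2$mean, 0.7, tolerance = 1e-6)
  expect_equal(cm2$var, 1.3^2, tolerance = 1e-6)

  # spec hand case: r = (0,1,2), phi = 0.5, sigma2 = 1, lam = 0, tau = 1
  d3 <- make_dataset(matrix(c(0, 1, 2), 1, 3))
  st3 <- model_params(0, 0.5, 1, 0, 1, 2, 1)
  cm3 <- cond_mu(1, st3, d3)
  expect_equal(cm3$mean, (0.5 * 2.5) / 1.5)
  expect_equal(cm3$var, 1 / 1.5)
})

test_that("cond_sigma2: hand cases", {
  # zero residuals -> IG(a + (T-1)/2, b)
  r <- matrix(c(1, 1, 1), 1, 3)  # mu = 1, phi arbitrary -> eps = 0
  st <- model_params(1, 0.5, 1, 0, 1, 2, 3)
  cs <- cond_sigma2(1, st, make_dataset(r))
  expect_equal(cs$shape, 2 + 1)
  expect_equal(cs$rate, 3)

  # r = (0,1), mu = 0, phi ~ 0 -> eps = 1: IG(a + 0.5, b + 0.5)
  st2 <- model_params(0, 1e-300, 1, 0, 1, 2, 3, validate = FALSE)
  cs2 <- cond_sigma2(1, st2, make_dataset(matrix(c(0, 1), 1, 2)))
  expect_equal(cs2$shape, 2.5)
  expect_equal(cs2$rate, 3.5)

  # no data (single observation): prior IG(a, b), mean b/(a-1)
  d1 <- migration_dataset("A01", 1950, rates = matrix(0.5),
                          populations = matrix(1e6))
  cs3 <- cond_sigma2(1, st, d1)
  expect_equal(invgamma_moments(cs3$shape, cs3$rate)$mean, 3 / (2 - 1))
})

test_that("cond_phi: noise-free regression, hand case, degenerate design", {
  # z = 0.5 x exactly -> untruncated mean 0.5
  r <- matrix(c(4, 2, 1, 0.5), 1, 4)  # deviations halve each step (mu = 0)
  st <- model_params(0, 0.3, 1, 0, 1, 2, 1)
  cp <- cond_phi(1, st, make_dataset(r))
  expect_equal(cp$mean, 0.5)

  # single transition x = 2, z = 1, sigma2 = 4 -> mean 0.5, var 1
  cp2 <- cond_phi(1, model_params(0, 0.3, 4, 0, 1, 2, 1),
                  make_dataset(matrix(c(2, 1), 1, 2)))
  expect_equal(cp2$mean, 0.5)
  expect_equal(cp2$var, 1)
  expect_equal(c(cp2$lower, cp2$upper), c(0, 1))

  # all x = 0 -> U(0,1)
  cp3 <- cond_phi(1, st, make_dataset(matrix(c(0, 1), 1, 2)))
  expect_true(cp3$uniform)
})

test_that("cond_b and cond_lambda: closed forms", {
  # C = 1, sigma2 = 1, a = 2 -> Gamma(3, 1) truncated to (0, 100)
  st <- model_params(0, 0.5, 1, 0, 1, 2, 1)
  cb <- cond_b(st)
  expect_equal(cb$shape, 3)
  expect_equal(cb$rate, 1)
  expect_equal(cb$upper, 100)                       # 100(a-1) exactly
  expect_equal((cb$shape - 1) / cb$rate, 2)         # untruncated mode Ca/sum

  # mu = (-1, 1), tau = 1, C = 2 -> N(0, 0.5) truncated to (-100, 100)
  st2 <- model_params(c(-1, 1), c(0.5, 0.5), c(1, 1), 0, 1, 2, 1)
  cl <- cond_lambda(st2)
  expect_equal(cl$mean, 0)
  expect_equal(cl$var, 0.5)
  expect_equal(c(cl$lower, cl$upper), c(-100, 100))
})

test_that("log_cond_tau / log_cond_a: supports and termwise recomputation", {
  expect_identical(log_cond_tau(-1, state1()), -Inf)
  expect_identical(log_cond_tau(100.5, state1()), -Inf)
  st <- model_params(c(0.5, -0.5), c(0.3, 0.6), c(1, 2), 0.1, 1.5, 3, 40)
  # a with b >= 100(a-1) is outside the joint support
  expect_identical(log_cond_a(1.2, st), -Inf)   # 100 * 0.2 = 20 < 40
  expect_identical(log_cond_a(0.9, st), -Inf)
  expect_identical(log_cond_a(10.1, st), -Inf)

  # termwise recomputation from the Level 2/3 densities on random states:
  # both kernels must differ from the full conditional log density only by
  # an additive constant in the target coordinate
  for (seed in 1:5) {
    sd_ <- random_state_and_data(seed, C = 3L, T_ = 4L)
    st_r <- sd_$state
    f_tau <- function(tau) sum(dnorm(st_r$mu, st_r$lam, tau, log = TRUE))
    taus <- c(0.8, 1.7, 2.9)
    k1 <- vapply(taus, function(t_) log_cond_tau(t_, st_r), numeric(1))
    k2 <- vapply(taus, f_tau, numeric(1))
    expect_equal(diff(k1), diff(k2), tolerance = 1e-10)

    f_a <- function(a)
      sum(a * log(st_r$b) - lgamma(a) - (a + 1) * log(st_r$sigma2)) -
        log(100 * (a - 1))
    as_ <- 1 + st_r$b / 100 + c(0.5, 1.5, 3)
    as_ <- as_[as_ < 10]
    k3 <- vapply(as_, function(a_) log_cond_a(a_, st_r), numeric(1))
    k4 <- vapply(as_, f_a, numeric(1))
    expect_equal(diff(k3), diff(k4), tolerance = 1e-10)
  }
})

test_that("countries with fewer than 2 observations are shrunk to the prior", {
  # country 2 enters at the last period only
  r <- matrix(c(1, NA, 2, NA, 3, 0.5), 2, 3)
  d <- make_dataset(r)
  st <- model_params(c(0, 0), c(0.5, 0.5), c(1, 1), 0.3, 1.1, 2.5, 8)
  cm <- cond_mu(2, st, d)
  expect_equal(cm$mean, 0.3)
  expect_equal(cm$var, 1.1^2)
  cs <- cond_sigma2(2, st, d)
  expect_equal(c(cs$shape, cs$rate), c(2.5, 8))
  expect_true(cond_phi(2, st, d)$uniform)
  ll <- log_likelihood(st, d)
  expect_equal(attr(ll, "skipped_countries"), "A02")
})
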