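test_that("censored log-likelihood matches term-wise recomputation", {
  theta <- c(1.2, 0.8, 1.5, 0.9)
  set.seed(21)
  d <- raw_emergence_sim(theta, c(0, 0.25, 0.5, 1), c(5, 5, 5, 5), 30)
  clt <- log(30)
  # independent term-by-term oracle from normal pdf/cdf
  mu <- theta[1] + theta[2] * d$level + theta[3] * d$level^2
  ll <- 0
  for (i in seq_len(nrow(d))) {
    ll <- ll + if (d$observed[i] == 1)
      log(dnorm(d$log_time[i], mu[i], theta[4]))
    else log(1 - pnorm((clt - mu[i]) / theta[4]))
  }
  expect_equal(loglik_censored(theta, d, clt), ll, tolerance = 1e-10)

  # fully observed data reduce to the plain normal log-likelihood
  d2 <- raw_emergence_sim(theta, c(0, 0.5, 1), c(4, 4, 4))
  mu2 <- theta[1] + theta[2] * d2$level + theta[3] * d2$level^2
  expect_equal(loglik_censored(theta, d2),
               sum(dnorm(d2$log_time, mu2, theta[4], log = TRUE)))

  # a censored unit whose mean sits at the horizon contributes log(1/2)
  d3 <- censored_data(0, NA, 0L)
  expect_equal(loglik_censored(c(log(30), 1, 1, 1), d3, log(30)), log(0.5))

  # the fast sufficient-statistic path agrees with the record-wise one
  st <- adaptdesign:::aggregate_censored(d)
  expect_equal(adaptdesign:::loglik_stats(theta[1], theta[2], theta[3],
                                          theta[4], st, clt),
               loglik_censored(theta, d, clt), tolerance = 1e-10)
})

test_that("expected information: closed form, additivity, censoring limits", {
  # hand-evaluated closed form at sigma = 1, grid (0, 1), one unit each
  info <- expected_information(c(0, 1, 1, 1), c(0, 1), c(1, 1))
  expect_equal(unname(info[1:3, 1:3]),
               matrix(c(2, 1, 1, 1, 1, 1, 1, 1, 1), 3))
  expect_equal(info[4, 4], 1)
  expect_true(all(info[1:3, 4] == 0))

  theta <- c(1, 0.5, 2, 0.8)
  lv <- c(0, 0.25, 0.5, 1); cnt <- c(3, 4, 5, 6)
  # doubling every count doubles the matrix (censored and uncensored)
  for (clt in list(NULL, log(20))) {
    I1 <- expected_information(theta, lv, cnt, clt)
    I2 <- expected_information(theta, lv, 2 * cnt, clt)
    expect_equal(I2, 2 * I1, tolerance = 1e-12)
    expect_equal(I1, t(I1))
    expect_true(all(eigen(I1, only.values = TRUE)$values > -1e-10))
  }

  # a distant horizon converges to the uncensored closed form
  I_unc <- expected_information(theta, lv, cnt)
  I_far <- expected_information(theta, lv, cnt, censor_log_time = 30)
  expect_lt(max(abs(I_far - I_unc) / (abs(I_unc) + 1e-12)), 1e-4)
})

test_that("censored per-unit information matches quadrature of its defining integrals", {
  # observed-region second-derivative integrals plus the censored-mass term,
  # evaluated by adaptive quadrature, against the closed forms
  for (case in list(c(3, 1.2, log(30)), c(2.5, 0.6, log(30)),
                    c(3.8, 2.1, log(15)))) {
    mu <- case[1]; sig <- case[2]; clt <- case[3]
    v <- sig^2; z <- (clt - mu) / sig
    S <- pnorm(z, lower.tail = FALSE); lam <- dnorm(z) / S
    a_q <- integrate(function(y) dnorm(y, mu, sig) / v, -Inf, clt,
                     rel.tol = 1e-10)$value + S * lam * (lam - z) / v
    b_q <- integrate(function(y) dnorm(y, mu, sig) * (y - mu) / v^2, -Inf,
                     clt, rel.tol = 1e-10)$value +
      S * (lam * (lam - z) * z + lam) / (2 * v^1.5)
    c_q <- integrate(function(y)
      dnorm(y, mu, sig) * ((y - mu)^2 / v^3 - 1 / (2 * v^2)), -Inf, clt,
      rel.tol = 1e-10)$value +
      S * (lam * (lam - z) * z^2 + 3 * lam * z) / (4 * v^2)
    info <- expected_information(c(mu, 0, 0, sig), 0, 1, clt)
    expect_equal(info[1, 1], a_q, tolerance = 1e-8)
    expect_equal(info[1, 4], b_q, tolerance = 1e-8)
    expect_equal(info[4, 4], c_q, tolerance = 1e-8)
  }
})

test_that("censored expected information matches the Monte-Carlo observed information", {
  # E[-hessian of the log-likelihood] estimated from one large simulated
  # sample, with the hessian taken by finite differences of the
  # independently verified log-likelihood
  theta <- c(2.5, 0.07, 3, 1)
  lv <- c(0, 0.5, 1); n_per <- 80000
  set.seed(77)
  d <- raw_emergence_sim(theta, lv, rep(n_per, 3), 30)
  f <- function(p) loglik_censored(c(p[1:3], sqrt(p[4])), d, log(30))
  H <- fd_hessian(f, c(theta[1:3], theta[4]^2), eps = 2e-4)
  I_mc <- -H / n_per
  I_th <- expected_information(theta, lv, c(1, 1, 1), log(30))
  expect_lt(max(abs(I_mc - I_th) / (abs(I_th) + 0.02 * max(abs(I_th)))), 0.02)
})

test_that("delta-method variance scales with information and ignores empty levels", {
  theta <- c(1, 0.5, 2, 1)
  lv <- c(0, 0.125, 0.25, 0.5, 1)
  cnt <- c(10, 5, 5, 20, 10)
  v1 <- asymptotic_variance_delta(theta, lv, cnt)
  expect_equal(asymptotic_variance_delta(theta, lv, 3 * cnt), v1 / 3,
               tolerance = 1e-10)
  v2 <- asymptotic_variance_delta(theta, c(lv, 0.7), c(cnt, 0))
  expect_equal(v2, v1, tolerance = 1e-12)
  # undefined target propagates as NA
  expect_true(is.na(asymptotic_variance_delta(c(1, 0.1, -5, 1), lv, cnt)))
  # matches a direct solve of the full system
  h <- delta_gradient(theta)
  info <- expected_information(theta, lv, cnt, log(30))
  expect_equal(asymptotic_variance_delta(theta, lv, cnt, log(30)),
               drop(t(h) %*% solve(info) %*% h), tolerance = 1e-8)
})

test_that("small-grid designs: optimizer agrees with an exhaustive grid search", {
  # every split of n units over a three-point grid (including two-point
  # support candidates) evaluated directly with the delta-method variance
  theta <- c(1, 1, 1, 1)
  lv <- c(0, 0.5, 1)
  n <- 30
  grid_best <- NULL; grid_val <- Inf
  for (m1 in 0:n) for (m2 in 0:(n - m1)) {
    v <- asymptotic_variance_delta(theta, lv, c(m1, m2, n - m1 - m2))
    if (is.na(v) || !is.null(attr(v, "singular"))) next
    if (v < grid_val) { grid_val <- as.numeric(v); grid_best <- c(m1, m2, n - m1 - m2) }
  }
  pr <- design_problem(lv, n, matrix(theta, 1), "c_delta")
  res <- optimize_allocation(pr)
  expect_true(res$exact)
  expect_equal(res$counts, grid_best)
  expect_equal(res$value, grid_val, tolerance = 1e-10)
})
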