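# Independent oracles used across the test files.  These deliberately avoid
# the package's own code paths.

# central finite-difference gradient of a scalar function
fd_gradient <- function(f, x, eps = 1e-6) {
  sapply(seq_along(x), function(i) {
    h <- numeric(length(x)); h[i] <- eps
    (f(x + h) - f(x - h)) / (2 * eps)
  })
}

# numerical Hessian of a scalar function (central differences)
fd_hessian <- function(f, x, eps = 1e-4) {
  k <- length(x)
  H <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(i)) {
    ei <- numeric(k); ei[i] <- eps
    ej <- numeric(k); ej[j] <- eps
    H[i, j] <- H[j, i] <-
      (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
      (4 * eps^2)
  }
  H
}

# brute-force best phase-2 split of the estimated-SE objective
brute_allocate_phase2 <- function(s1, s2, n1, n2, budget) {
  obj <- sapply(0:budget, function(a) s1 / (n1 + a) + s2 / (n2 + budget - a))
  a <- (0:budget)[which.min(obj)]
  c(a, budget - a)
}

# Newton-Raphson logistic regression (aggregated binomial), an oracle for
# fit_logistic which delegates to glm
newton_logistic <- function(X, successes, trials, maxit = 50) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    p <- plogis(drop(X %*% beta))
    W <- trials * p * (1 - p)
    score <- drop(crossprod(X, successes - trials * p))
    H <- crossprod(X, X * W)
    step <- solve(H, score)
    beta <- beta + step
    if (max(abs(step)) < 1e-12) break
  }
  beta
}

# simulate one emergence dataset without the package generator
raw_emergence_sim <- function(theta, levels, counts, censor_days = NULL) {
  x <- rep(levels, counts)
  y <- rnorm(length(x), theta[1] + theta[2] * x + theta[3] * x^2, theta[4])
  if (is.null(censor_days)) return(censored_data(x, y, 1L))
  obs <- y <= log(censor_days)
  censored_data(x, ifelse(obs, y, NA_real_), as.integer(obs))
}
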