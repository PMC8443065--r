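# Quadratic log-normal time-to-emergence model.
#
# ln(T) ~ N(mu_x, sigma^2) with mu_x = beta0 + beta1*x + beta2*x^2 on a
# concentration scale x in [0, 1].  The target parameter Delta is the
# concentration at which the median emergence time is `fold` times the
# control median, i.e. the smallest positive root of
#   beta2 * Delta^2 + beta1 * Delta - log(fold) = 0.

#' Effective concentration for a fold increase of the median emergence time
#'
#' Solves \code{beta2 * Delta^2 + beta1 * Delta = log(fold)} for the smallest
#' positive root.  Under the log-normal model the median time to emergence at
#' concentration \code{Delta} is \code{fold} times the control median.
#'
#' @param beta1,beta2 linear and quadratic coefficients of the concentration
#'   curve on the log-day scale.  Vectors are recycled to a common length.
#' @param fold median multiplier, a constant greater than 1 (default 2,
#'   i.e. a doubled median waiting time).
#' @return Numeric vector of concentrations; \code{NA} where no positive real
#'   root exists (possible when \code{beta2 < 0}).
#' @examples
#' delta_from_theta(0.5, 2)    # 0.477
#' delta_from_theta(log(2), 0) # 1
#' @export
delta_from_theta <- function(beta1, beta2, fold = 2) {
  if (!is.numeric(fold) || length(fold) != 1L || !is.finite(fold) || fold <= 1)
    stop("`fold` must be a single number greater than 1", call. = FALSE)
  L <- log(fold)
  n <- max(length(beta1), length(beta2))
  beta1 <- rep_len(as.numeric(beta1), n)
  beta2 <- rep_len(as.numeric(beta2), n)
  delta <- rep(NA_real_, n)
  disc <- beta1^2 + 4 * L * beta2
  quad <- beta2 != 0 & disc >= 0
  delta[quad] <- (-beta1[quad] + sqrt(disc[quad])) / (2 * beta2[quad])
  lin <- beta2 == 0 & beta1 > 0
  delta[lin] <- L / beta1[lin]
  delta[!is.na(delta) & delta <= 0] <- NA_real_
  delta
}

#' Gradient of the effective concentration
#'
#' Gradient of \code{Delta} with respect to the model parameter vector
#' \code{(beta0, beta1, beta2, sigma^2)}.  The first and last components are
#' identically zero because \code{Delta} depends only on the two slope
#' coefficients.
#'
#' @param theta numeric vector \code{(beta0, beta1, beta2, sigma)}.
#' @inheritParams delta_from_theta
#' @return Numeric 4-vector.
#' @export
delta_gradient <- function(theta, fold = 2) {
  theta <- as_theta(theta)
  b1 <- theta[["beta1"]]; b2 <- theta[["beta2"]]
  L <- log(fold)
  delta <- delta_from_theta(b1, b2, fold)
  if (is.na(delta))
    stop("Delta is undefined at `theta`; gradient does not exist", call. = FALSE)
  s <- sqrt(b1^2 + 4 * L * b2)
  # d Delta / d beta2 = -(Delta - L/s) / beta2, rationalised to avoid the
  # beta2 -> 0 cancellation: the conjugate form is exact for all beta2 and
  # reduces to the analytic limit -L^2 / beta1^3 at beta2 = 0
  g2 <- -2 * L^2 / (s * (b1^2 + 2 * L * b2 + b1 * s))
  c(0, -delta / s, g2, 0)
}

#' Mean log emergence time at given concentrations
#'
#' @param theta numeric vector \code{(beta0, beta1, beta2, sigma)}.
#' @param x concentrations in \code{[0, 1]}.
#' @return \code{beta0 + beta1 * x + beta2 * x^2}.
#' @export
emergence_mu <- function(theta, x) {
  theta <- as_theta(theta)
  theta[["beta0"]] + theta[["beta1"]] * x + theta[["beta2"]] * x^2
}

# Coerce/validate a theta vector (beta0, beta1, beta2, sigma).
as_theta <- function(theta) {
  theta <- as.numeric(theta)
  if (length(theta) != 4L || any(!is.finite(theta)))
    stop("`theta` must be a finite numeric 4-vector (beta0, beta1, beta2, sigma)",
         call. = FALSE)
  if (theta[4] <= 0) stop("`sigma` must be positive", call. = FALSE)
  names(theta) <- c("beta0", "beta1", "beta2", "sigma")
  theta
}

#' Censored emergence records
#'
#' Builds the per-unit record set used throughout the package: one row per
#' experimental unit with its concentration, the log emergence time when the
#' event was observed within the horizon, and an observation indicator.
#'
#' @param level concentration per unit, in \code{[0, 1]}.
#' @param log_time log emergence time (log days); \code{NA} for censored units.
#' @param observed 1 if emergence was observed within the horizon, 0 if the
#'   unit was right-censored.
#' @return A data frame of class \code{"censored_data"} with columns
#'   \code{level}, \code{log_time}, \code{observed}.
#' @export
censored_data <- function(level, log_time, observed) {
  level <- as.numeric(level); log_time <- as.numeric(log_time)
  observed <- as.integer(observed)
  n <- length(level)
  if (length(log_time) == 1L) log_time <- rep(log_time, n)
  if (length(observed) == 1L) observed <- rep(observed, n)
  if (length(log_time) != n || length(observed) != n)
    stop("`level`, `log_time` and `observed` must have equal length", call. = FALSE)
  if (any(level < 0 | level > 1, na.rm = TRUE))
    stop("concentrations must lie in [0, 1]", call. = FALSE)
  if (!all(observed %in% c(0L, 1L)))
    stop("`observed` must be 0/1", call. = FALSE)
  if (any(observed == 1L & !is.finite(log_time)))
    stop("observed units must carry a finite log_time", call. = FALSE)
  log_time[observed == 0L] <- NA_real_
  out <- data.frame(level = level, log_time = log_time, observed = observed)
  class(out) <- c("censored_data", "data.frame")
  out
}

#' Censored log-likelihood of the emergence model
#'
#' Observed units contribute the log-normal density of their log time;
#' censored units contribute the log survival probability at the censoring
#' horizon, computed on the log scale for numerical stability.
#'
#' @param theta numeric vector \code{(beta0, beta1, beta2, sigma)}.
#' @param data a \code{\link{censored_data}} frame.
#' @param censor_log_time censoring horizon on the log-day scale
#'   (default \code{log(30)}); ignored for fully observed data.
#' @return Scalar log-likelihood.
#' @export
loglik_censored <- function(theta, data, censor_log_time = log(30)) {
  theta <- as_theta(theta)
  if (nrow(data) == 0L) return(0)
  mu <- emergence_mu(theta, data$level)
  sigma <- theta[["sigma"]]
  obs <- data$observed == 1L
  ll <- 0
  if (any(obs))
    ll <- ll + sum(dnorm(data$log_time[obs], mu[obs], sigma, log = TRUE))
  if (any(!obs)) {
    z <- (censor_log_time - mu[!obs]) / sigma
    ll <- ll + sum(pnorm(z, lower.tail = FALSE, log.p = TRUE))
  }
  ll
}

# Per-level sufficient statistics for fast repeated likelihood evaluation
# (the censored normal likelihood depends on the data only through these).
aggregate_censored <- function(data) {
  lv <- sort(unique(data$level))
  obs <- data$observed == 1L
  n_obs <- n_cen <- sum_y <- sum_y2 <- numeric(length(lv))
  for (i in seq_along(lv)) {
    at <- data$level == lv[i]
    y <- data$log_time[at & obs]
    n_obs[i] <- length(y)
    n_cen[i] <- sum(at & !obs)
    sum_y[i] <- sum(y)
    sum_y2[i] <- sum(y^2)
  }
  list(level = lv, n_obs = n_obs, n_cen = n_cen, sum_y = sum_y, sum_y2 = sum_y2)
}

# Log-likelihood from aggregated statistics; identical to loglik_censored.
loglik_stats <- function(beta0, beta1, beta2, sigma, st, censor_log_time) {
  mu <- beta0 + beta1 * st$level + beta2 * st$level^2
  v <- sigma^2
  ll <- sum(-0.5 * st$n_obs * log(2 * pi * v) -
              (st$sum_y2 - 2 * mu * st$sum_y + st$n_obs * mu^2) / (2 * v))
  cen <- st$n_cen > 0
  if (any(cen)) {
    z <- (censor_log_time - mu[cen]) / sigma
    ll <- ll + sum(st$n_cen[cen] * pnorm(z, lower.tail = FALSE, log.p = TRUE))
  }
  ll
}

# Scalar building blocks of the per-unit expected information under Type-I
# right censoring at log-time `clt`, with respect to (mu, sigma^2):
#   a = E[-d2 l / d mu2], b = E[-d2 l / d mu d sigma2], c = E[-d2 l / d(sigma2)2].
# Exact expressions in terms of Phi, phi and the normal hazard; they reduce to
# the textbook uncensored values (1/v, 0, 1/(2 v^2)) as clt -> Inf.
censored_abc <- function(mu, sigma, censor_log_time = NULL) {
  v <- sigma^2
  k <- max(length(mu), length(sigma))
  if (is.null(censor_log_time))
    return(list(a = rep_len(1 / v, k), b = rep(0, k),
                c = rep_len(1 / (2 * v^2), k)))
  z <- (censor_log_time - mu) / sigma
  Phi <- pnorm(z)
  phi <- dnorm(z)
  # hazard phi/S computed on the log scale; stable far into the upper tail
  lam <- exp(dnorm(z, log = TRUE) - pnorm(z, lower.tail = FALSE, log.p = TRUE))
  d <- lam - z
  a <- (Phi + phi * d) / v
  b <- phi * (d * z - 1) / (2 * v^1.5)
  cc <- (2 * Phi + phi * (d * z^2 - z)) / (4 * v^2)
  # numerically uncensored region (survival underflows): exact limit
  far <- z > 37
  if (any(far)) {
    a[far] <- 1 / v; b[far] <- 0; cc[far] <- 1 / (2 * v^2)
  }
  list(a = a, b = b, c = cc)
}

#' Expected Fisher information of the emergence model
#'
#' Expected information for \code{(beta0, beta1, beta2, sigma^2)} of an
#' experiment that allocates \code{counts} units to the concentrations
#' \code{levels}, optionally right-censored at a fixed horizon.  Without
#' censoring this is the closed form \code{(1/sigma^2) sum m_i v_i v_i'} for
#' the beta block (with \code{v_i = (1, x_i, x_i^2)}), \code{n/(2 sigma^4)}
#' for the variance entry and zero cross terms; censoring introduces
#' information loss and a non-zero mean-variance cross term.
#'
#' @inheritParams loglik_censored
#' @param levels concentrations of the design grid.
#' @param counts units allocated per level (non-negative, recycled checked).
#' @param censor_log_time censoring horizon on the log-day scale, or
#'   \code{NULL} for no censoring.
#' @return Symmetric positive semi-definite 4x4 matrix.
#' @export
expected_information <- function(theta, levels, counts, censor_log_time = NULL) {
  theta <- as_theta(theta)
  levels <- as.numeric(levels); counts <- as.numeric(counts)
  if (length(levels) != length(counts))
    stop("`levels` and `counts` must have equal length", call. = FALSE)
  if (any(counts < 0)) stop("`counts` must be non-negative", call. = FALSE)
  mu <- emergence_mu(theta, levels)
  abc <- censored_abc(mu, theta[["sigma"]], censor_log_time)
  V <- rbind(1, levels, levels^2)
  info <- matrix(0, 4, 4)
  wa <- counts * abc$a
  info[1:3, 1:3] <- V %*% (t(V) * wa)
  bv <- V %*% (counts * abc$b)
  info[1:3, 4] <- bv
  info[4, 1:3] <- bv
  info[4, 4] <- sum(counts * abc$c)
  dimnames(info) <- list(c("beta0", "beta1", "beta2", "sigma2"),
                         c("beta0", "beta1", "beta2", "sigma2"))
  (info + t(info)) / 2
}

#' Delta-method asymptotic variance of the effective concentration estimator
#'
#' \code{h' I(theta)^{-1} h} where \code{h} is \code{\link{delta_gradient}}
#' and \code{I} is \code{\link{expected_information}} for the given design.
#'
#' @inheritParams expected_information
#' @inheritParams delta_from_theta
#' @return Positive scalar; \code{NA} when \code{Delta} is undefined at
#'   \code{theta}.  When the information matrix is numerically singular a
#'   Moore-Penrose pseudo-inverse is used and the result carries the
#'   attribute \code{singular = TRUE}.
#' @export
asymptotic_variance_delta <- function(theta, levels, counts,
                                      censor_log_time = NULL, fold = 2) {
  theta <- as_theta(theta)
  if (is.na(delta_from_theta(theta[["beta1"]], theta[["beta2"]], fold)))
    return(NA_real_)
  h <- delta_gradient(theta, fold)
  info <- expected_information(theta, levels, counts, censor_log_time)
  sol <- tryCatch(solve(info, h), error = function(e) NULL)
  if (is.null(sol) || any(!is.finite(sol))) {
    sol <- MASS::ginv(info) %*% h
    out <- drop(crossprod(h, sol))
    attr(out, "singular") <- TRUE
    return(out)
  }
  drop(crossprod(h, sol))
}
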