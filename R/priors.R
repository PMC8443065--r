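# Prior elicitation and posterior sampling for the emergence model.

#' Elicit the informative prior for the emergence model
#'
#' The prior is specified on interpretable quantities: the control-group
#' median emergence time \code{exp(beta0)} gets a log-normal prior centred at
#' \code{median_control_days} with \code{upper_days} as an upper bound of
#' probability \code{upper_prob}; the slope coefficients \code{beta1, beta2}
#' get independent exponential priors with rates \code{d1, d2} (mean
#' \code{1/d}); the residual sd \code{sigma} gets a flat prior on a bounded
#' positive interval.  With the defaults \code{a0 = log(7) = 1.95} and
#' \code{b0 = 0.5 log(30/7) = 0.73}: the 30-day bound is treated as a
#' two-standard-deviation bound (\code{upper_prob = pnorm(2)}, about 0.977).
#'
#' The default rates \code{d1 = d2 = 0.2} concentrate the induced prior of
#' the effective concentration so that \code{P(Delta < 0.5)} is about 0.95
#' and \code{P(Delta < 1)} is about 1.
#'
#' @param median_control_days prior median of the control emergence time (days).
#' @param upper_days prior upper bound for the control median (days).
#' @param upper_prob probability attached to \code{upper_days}; must lie in
#'   (0.5, 1).
#' @param d1,d2 exponential rates for \code{beta1} and \code{beta2}.
#' @param sigma_range support of the flat prior on \code{sigma}.
#' @param fold median multiplier defining \code{Delta} (default 2).
#' @return An object of class \code{"emergence_prior"}.
#' @examples
#' p <- elicit_prior()
#' round(c(p$a0, p$b0), 2) # 1.95 0.73
#' @export
elicit_prior <- function(median_control_days = 7, upper_days = 30,
                         upper_prob = pnorm(2), d1 = 0.2, d2 = 0.2,
                         sigma_range = c(0.05, 5), fold = 2) {
  if (!(median_control_days > 0 && median_control_days < upper_days))
    stop("need 0 < median_control_days < upper_days", call. = FALSE)
  if (!(upper_prob > 0.5 && upper_prob < 1))
    stop("`upper_prob` must lie in (0.5, 1)", call. = FALSE)
  if (d1 <= 0 || d2 <= 0) stop("exponential rates must be positive", call. = FALSE)
  if (length(sigma_range) != 2L || sigma_range[1] <= 0 ||
      sigma_range[2] <= sigma_range[1])
    stop("`sigma_range` must be an increasing positive interval", call. = FALSE)
  structure(list(a0 = log(median_control_days),
                 b0 = log(upper_days / median_control_days) / qnorm(upper_prob),
                 d1 = d1, d2 = d2, sigma_range = as.numeric(sigma_range),
                 fold = fold),
            class = "emergence_prior")
}

#' @export
print.emergence_prior <- function(x, ...) {
  cat("Emergence-model prior\n")
  cat(sprintf("  beta0 ~ Normal(%.3f, %.3f)   [control median %.3g days]\n",
              x$a0, x$b0, exp(x$a0)))
  cat(sprintf("  beta1 ~ Exponential(rate %.3g), beta2 ~ Exponential(rate %.3g)\n",
              x$d1, x$d2))
  cat(sprintf("  sigma ~ Uniform(%.3g, %.3g)\n", x$sigma_range[1], x$sigma_range[2]))
  invisible(x)
}

#' Flat (vague) prior for the emergence model
#'
#' Uniform prior over a wide box for the regression coefficients and a
#' bounded interval for \code{sigma}.  Used for the unconstrained posterior
#' mean of \code{Delta} in the design comparisons; the box is configuration,
#' wide enough that the likelihood dominates at the sample sizes studied.
#'
#' @param beta_lower,beta_upper bounds for each of \code{beta0, beta1, beta2}.
#' @param sigma_range support of the flat prior on \code{sigma}.
#' @param fold median multiplier defining \code{Delta}.
#' @return An object of class \code{"flat_prior"}.
#' @export
flat_prior <- function(beta_lower = c(-20, -20, -20),
                       beta_upper = c(20, 20, 20),
                       sigma_range = c(0.05, 5), fold = 2) {
  stopifnot(length(beta_lower) == 3L, length(beta_upper) == 3L,
            all(beta_upper > beta_lower), sigma_range[1] > 0,
            sigma_range[2] > sigma_range[1])
  structure(list(beta_lower = as.numeric(beta_lower),
                 beta_upper = as.numeric(beta_upper),
                 sigma_range = as.numeric(sigma_range), fold = fold),
            class = "flat_prior")
}

#' Draw model parameters from the emergence prior
#'
#' @param prior an \code{\link{elicit_prior}} object.
#' @param n_draws number of independent draws.
#' @param seed optional integer seed for reproducibility.
#' @return Matrix with \code{n_draws} rows and columns
#'   \code{beta0, beta1, beta2, sigma}.
#' @export
sample_prior <- function(prior, n_draws, seed = NULL) {
  stopifnot(inherits(prior, "emergence_prior"), n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  cbind(beta0 = rnorm(n_draws, prior$a0, prior$b0),
        beta1 = rexp(n_draws, prior$d1),
        beta2 = rexp(n_draws, prior$d2),
        sigma = runif(n_draws, prior$sigma_range[1], prior$sigma_range[2]))
}

# log prior density in the sampling parameterisation.
#  - emergence_prior: p = (beta0, log beta1, log beta2, log sigma)
#  - flat_prior:      p = (beta0, beta1, beta2, log sigma)
log_prior_transformed <- function(p, prior) {
  ls <- p[4]
  sigma <- exp(ls)
  if (sigma < prior$sigma_range[1] || sigma > prior$sigma_range[2]) return(-Inf)
  if (inherits(prior, "emergence_prior")) {
    b1 <- exp(p[2]); b2 <- exp(p[3])
    dnorm(p[1], prior$a0, prior$b0, log = TRUE) +
      dexp(b1, prior$d1, log = TRUE) + p[2] +
      dexp(b2, prior$d2, log = TRUE) + p[3] +
      ls                                    # Jacobian of log sigma
  } else if (inherits(prior, "flat_prior")) {
    if (any(p[1:3] < prior$beta_lower) || any(p[1:3] > prior$beta_upper))
      return(-Inf)
    ls
  } else stop("unknown prior class", call. = FALSE)
}

transform_to_theta <- function(p, prior) {
  if (inherits(prior, "emergence_prior"))
    c(p[1], exp(p[2]), exp(p[3]), exp(p[4]))
  else c(p[1:3], exp(p[4]))
}

theta_to_transform <- function(theta, prior) {
  if (inherits(prior, "emergence_prior"))
    c(theta[1], log(max(theta[2], 1e-6)), log(max(theta[3], 1e-6)),
      log(theta[4]))
  else c(theta[1:3], log(theta[4]))
}

# crude starting value: least squares on the observed records, clipped into
# the prior support (the mode search below refines it).
posterior_start <- function(data, prior) {
  sig_mid <- sqrt(prod(prior$sigma_range))
  beta <- if (inherits(prior, "emergence_prior"))
    c(prior$a0, log(2) / prior$d1 / 2, log(2) / prior$d2 / 2)
  else pmin(pmax(c(log(14), 1, 1), prior$beta_lower + 0.1),
            prior$beta_upper - 0.1)
  obs <- data$observed == 1L
  if (sum(obs) >= 4L && length(unique(data$level[obs])) >= 3L) {
    fit <- tryCatch(lm(log_time ~ level + I(level^2), data = data[obs, ]),
                    error = function(e) NULL)
    if (!is.null(fit) && all(is.finite(coef(fit)))) {
      beta <- coef(fit)
      s <- summary(fit)$sigma
      if (is.finite(s) && s > 0) sig_mid <- s
    }
  }
  if (inherits(prior, "emergence_prior")) beta[2:3] <- pmax(beta[2:3], 0.05)
  else beta <- pmin(pmax(beta, prior$beta_lower + 1e-3),
                    prior$beta_upper - 1e-3)
  sig_mid <- min(max(sig_mid, prior$sigma_range[1] * 1.05),
                 prior$sigma_range[2] * 0.95)
  c(beta, sig_mid)
}

#' Posterior sampling for the emergence model
#'
#' Random-walk Metropolis sampling of the posterior proportional to
#' prior x censored likelihood.  The chain runs in an unconstrained
#' parameterisation (log transforms for positive parameters), is initialised
#' at the posterior mode found by \code{\link[stats]{optim}}, and uses a
#' multivariate normal proposal scaled from the mode Hessian with scale
#' adaptation during burn-in.
#'
#' @param data a \code{\link{censored_data}} frame (may have zero rows, in
#'   which case the posterior equals the prior).
#' @param prior an \code{\link{elicit_prior}} or \code{\link{flat_prior}}
#'   object.
#' @param censor_log_time censoring horizon on the log-day scale.
#' @param iters total Metropolis iterations (default 6000).
#' @param burn burn-in iterations discarded (default 1000).
#' @param thin keep every \code{thin}-th draw after burn-in.
#' @param seed optional integer seed.
#' @param ess_warn warn (and flag) when the effective sample size of the
#'   \code{Delta} chain falls below this threshold.
#' @return Object of class \code{"emergence_posterior"}: \code{draws}
#'   (matrix of \code{beta0, beta1, beta2, sigma}), \code{delta} (per-draw
#'   effective concentration, \code{NA} when undefined),
#'   \code{delta_undefined_frac}, \code{accept_rate}, \code{ess_delta},
#'   \code{converged}, and a \code{delta_summary} (posterior mean and
#'   equal-tail 95\% credible interval over the defined draws).
#' @export
sample_posterior <- function(data, prior = elicit_prior(),
                             censor_log_time = log(30),
                             iters = 6000, burn = 1000, thin = 1,
                             seed = NULL, ess_warn = 100) {
  stopifnot(iters > burn, thin >= 1)
  if (!is.null(seed)) set.seed(seed)
  st <- if (nrow(data) > 0L) aggregate_censored(data) else NULL
  ll <- function(p) {
    if (is.null(st)) return(0)
    th <- transform_to_theta(p, prior)
    loglik_stats(th[1], th[2], th[3], th[4], st, censor_log_time)
  }
  lpost <- function(p) {
    lp <- log_prior_transformed(p, prior)
    if (!is.finite(lp)) return(-Inf)
    lp + ll(p)
  }
  p0 <- theta_to_transform(posterior_start(data, prior), prior)

  # posterior mode and curvature for the proposal
  opt <- tryCatch(
    optim(p0, function(p) -lpost(p), method = "Nelder-Mead",
          control = list(maxit = 500)),
    error = function(e) NULL)
  if (!is.null(opt) && is.finite(opt$value)) p0 <- opt$par
  Hc <- tryCatch({
    H <- optimHess(p0, function(p) -lpost(p))
    t(chol(solve((H + t(H)) / 2)))
  }, error = function(e) NULL)
  if (is.null(Hc)) Hc <- diag(c(0.2, 0.3, 0.3, 0.15))

  n_keep <- floor((iters - burn) / thin)
  draws_t <- matrix(NA_real_, n_keep, 4)
  scale <- 2.4 / sqrt(4)
  cur <- p0
  cur_lp <- lpost(cur)
  if (!is.finite(cur_lp)) {  # mode landed outside the support: nudge inside
    cur <- theta_to_transform(posterior_start(censored_data(numeric(0),
                                                            numeric(0),
                                                            integer(0)),
                                              prior), prior)
    cur_lp <- lpost(cur)
  }
  acc <- 0L; acc_win <- 0L; kept <- 0L
  for (it in seq_len(iters)) {
    prop <- cur + scale * drop(Hc %*% rnorm(4))
    prop_lp <- lpost(prop)
    if (is.finite(prop_lp) && log(runif(1)) < prop_lp - cur_lp) {
      cur <- prop; cur_lp <- prop_lp
      acc <- acc + 1L; acc_win <- acc_win + 1L
    }
    if (it <= burn && it %% 100L == 0L) {      # Robbins-Monro scale adaptation
      rate <- acc_win / 100
      scale <- scale * exp(rate - 0.3)
      acc_win <- 0L
    }
    if (it > burn && (it - burn) %% thin == 0L) {
      kept <- kept + 1L
      draws_t[kept, ] <- cur
    }
  }
  draws <- t(apply(draws_t, 1, transform_to_theta, prior = prior))
  colnames(draws) <- c("beta0", "beta1", "beta2", "sigma")
  fold <- if (is.null(prior$fold)) 2 else prior$fold
  delta <- delta_from_theta(draws[, "beta1"], draws[, "beta2"], fold)
  undef <- mean(is.na(delta))
  ess <- ess_univariate(if (undef < 1) delta[!is.na(delta)] else draws[, 1])
  converged <- ess >= ess_warn
  if (!converged)
    warning(sprintf("posterior chain may not have converged (ESS %.0f < %d)",
                    ess, ess_warn), call. = FALSE)
  ds <- if (all(is.na(delta))) c(mean = NA_real_, lower = NA_real_, upper = NA_real_)
  else c(mean = mean(delta, na.rm = TRUE),
         lower = unname(quantile(delta, 0.025, na.rm = TRUE)),
         upper = unname(quantile(delta, 0.975, na.rm = TRUE)))
  structure(list(draws = draws, delta = delta, delta_undefined_frac = undef,
                 delta_summary = ds, accept_rate = acc / iters,
                 ess_delta = ess, converged = converged, prior = prior,
                 censor_log_time = censor_log_time),
            class = "emergence_posterior")
}

#' @export
print.emergence_posterior <- function(x, ...) {
  cat(sprintf("Emergence-model posterior: %d draws (acceptance %.2f, ESS %.0f%s)\n",
              nrow(x$draws), x$accept_rate, x$ess_delta,
              if (x$converged) "" else ", NOT CONVERGED"))
  cat(sprintf("  posterior mean Delta = %.3f, 95%% CrI (%.3f, %.3f)\n",
              x$delta_summary["mean"], x$delta_summary["lower"],
              x$delta_summary["upper"]))
  if (x$delta_undefined_frac > 0)
    cat(sprintf("  Delta undefined for %.1f%% of draws (excluded)\n",
                100 * x$delta_undefined_frac))
  invisible(x)
}

# Effective sample size from the initial positive autocorrelations.
ess_univariate <- function(x) {
  n <- length(x)
  if (n < 10L || sd(x) == 0) return(n)
  r <- drop(acf(x, lag.max = min(500L, n - 1L), plot = FALSE)$acf)[-1]
  cut <- which(r < 0.05)[1]
  if (is.na(cut)) cut <- length(r)
  n / (1 + 2 * sum(r[seq_len(cut)]))
}
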