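# Logistic model for the joint effect of two treatments:
#   logit P(Y=1 | x, z) = beta0 + beta1 x + beta2 z + beta3 x z
# with concentrations x, z in [0, 1].  beta3 measures synergy (positive) or
# antagonism (negative); the design goal is to test beta3 = 0 with maximal
# power, or to learn all four coefficients (d-optimality).

#' Conditional-mean-prior transform: corner probabilities to coefficients
#'
#' Maps success probabilities at the four corner concentrations
#' \code{(0,0), (1,0), (0,1), (1,1)} to the logistic coefficients; this is
#' the exact inverse of evaluating the model at the corners.
#'
#' @param pi00,pi10,pi01,pi11 success probabilities, strictly in (0, 1).
#'   Vectors of equal length are mapped row-wise.
#' @return Numeric 4-vector \code{(beta0, beta1, beta2, beta3)}, or a matrix
#'   with those columns for vector input.
#' @export
corner_probs_to_beta <- function(pi00, pi10, pi01, pi11) {
  p <- cbind(pi00, pi10, pi01, pi11)
  if (any(p <= 0 | p >= 1))
    stop("corner probabilities must lie strictly in (0, 1)", call. = FALSE)
  l <- qlogis(p)
  out <- cbind(beta0 = l[, 1],
               beta1 = l[, 2] - l[, 1],
               beta2 = l[, 3] - l[, 1],
               beta3 = l[, 4] - l[, 3] - l[, 2] + l[, 1])
  if (nrow(out) == 1L) drop(out) else out
}

#' Independent beta priors on the corner success probabilities
#'
#' @param shape1,shape2 length-4 vectors of beta shape parameters for the
#'   corners \code{(0,0), (1,0), (0,1), (1,1)}.
#' @return Object of class \code{"synergy_prior"}.
#' @seealso \code{\link{synergy_prior_vague}} (all Beta(1,1)) and
#'   \code{\link{synergy_prior_informative}} (Beta(2,8), Beta(5,5),
#'   Beta(5,5), Beta(8,2)).
#' @export
synergy_prior <- function(shape1, shape2) {
  stopifnot(length(shape1) == 4L, length(shape2) == 4L,
            all(shape1 > 0), all(shape2 > 0))
  structure(list(shape1 = as.numeric(shape1), shape2 = as.numeric(shape2)),
            class = "synergy_prior")
}

#' @rdname synergy_prior
#' @export
synergy_prior_vague <- function() synergy_prior(rep(1, 4), rep(1, 4))

#' @rdname synergy_prior
#' @export
synergy_prior_informative <- function()
  synergy_prior(c(2, 5, 5, 8), c(8, 5, 5, 2))

#' Draw logistic coefficients from a corner-probability prior
#'
#' @param prior a \code{\link{synergy_prior}}.
#' @param n_draws number of independent draws.
#' @param seed optional integer seed.
#' @return Matrix with columns \code{beta0..beta3}.
#' @export
sample_synergy_prior <- function(prior, n_draws, seed = NULL) {
  stopifnot(inherits(prior, "synergy_prior"), n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- sapply(1:4, function(i) rbeta(n_draws, prior$shape1[i], prior$shape2[i]))
  p <- matrix(p, ncol = 4)
  out <- corner_probs_to_beta(p[, 1], p[, 2], p[, 3], p[, 4])
  if (is.null(dim(out))) out <- matrix(out, 1, dimnames = list(NULL, names(out)))
  out
}

#' Expected Fisher information of the logistic synergy model
#'
#' \code{sum_i m_i pi_i (1 - pi_i) v_i v_i'} with
#' \code{v_i = (1, x_i, z_i, x_i z_i)} over the design points.
#'
#' @param beta numeric 4-vector of logistic coefficients.
#' @param grid two-column matrix or data frame of \code{(x, z)} design
#'   points.
#' @param counts units allocated per design point.
#' @return Symmetric positive semi-definite 4x4 matrix.
#' @export
logistic_fei <- function(beta, grid, counts) {
  grid <- as.matrix(grid)
  stopifnot(ncol(grid) == 2L, length(counts) == nrow(grid),
            all(counts >= 0), length(beta) == 4L)
  V <- cbind(1, grid[, 1], grid[, 2], grid[, 1] * grid[, 2])
  p <- plogis(drop(V %*% beta))
  w <- counts * p * (1 - p)
  info <- crossprod(V, V * w)
  dimnames(info) <- list(c("beta0", "beta1", "beta2", "beta3"),
                         c("beta0", "beta1", "beta2", "beta3"))
  info
}

#' Maximum-likelihood fit of the synergy model
#'
#' Iteratively-reweighted least squares via \code{\link[stats]{glm}}.  The
#' \code{converged} flag is false when IRLS failed to converge or the data
#' show (quasi-)separation, detected from runaway coefficients or standard
#' errors.
#'
#' @param data data frame with columns \code{x}, \code{z} and either
#'   \code{successes} + \code{trials} (aggregated) or a 0/1 column \code{y}.
#' @param penalized fit by Firth-penalized likelihood (Jeffreys-prior score
#'   adjustment) instead of plain maximum likelihood; estimates then remain
#'   finite under separation.  Off by default so that power simulations
#'   count separated fits conservatively.
#' @return List with \code{coef} (named 4-vector), \code{vcov} (4x4 inverse
#'   observed information), \code{converged}, \code{separated}.
#' @export
fit_logistic <- function(data, penalized = FALSE) {
  data <- as.data.frame(data)
  if (!all(c("x", "z") %in% names(data)))
    stop("`data` needs columns x and z", call. = FALSE)
  if (all(c("successes", "trials") %in% names(data))) {
    if (any(data$successes < 0 | data$successes > data$trials))
      stop("need 0 <= successes <= trials", call. = FALSE)
    resp <- cbind(data$successes, data$trials - data$successes)
  } else if ("y" %in% names(data)) {
    if (!all(data$y %in% 0:1)) stop("`y` must be 0/1", call. = FALSE)
    resp <- data$y
  } else stop("`data` needs successes/trials or y", call. = FALSE)
  X <- cbind(1, data$x, data$z, data$x * data$z)
  if (qr(X)$rank < 4L)
    stop("design is rank-deficient: need at least 4 affinely independent (x, z) points",
         call. = FALSE)
  if (penalized) {
    if (is.matrix(resp)) {
      succ <- resp[, 1]; tri <- rowSums(resp)
    } else { succ <- resp; tri <- rep(1, length(resp)) }
    return(firth_logistic(X, succ, tri))
  }
  fit <- suppressWarnings(
    glm(resp ~ x + z + x:z, family = binomial(), data = data))
  cf <- coef(fit)
  vc <- suppressWarnings(vcov(fit))
  separated <- any(abs(cf) > 15) || any(sqrt(diag(vc)) > 50)
  names(cf) <- c("beta0", "beta1", "beta2", "beta3")
  dimnames(vc) <- list(names(cf), names(cf))
  list(coef = cf, vcov = vc,
       converged = isTRUE(fit$converged) && !separated,
       separated = separated)
}

#' Wald test for the synergy coefficient
#'
#' Two-sided Wald test of \code{beta3 = 0} from a \code{\link{fit_logistic}}
#' result.  A non-converged or separated fit yields a conservative
#' non-rejection (p-value 1) with a warning.
#'
#' @param fit result of \code{\link{fit_logistic}}.
#' @param alpha significance level.
#' @return List with \code{statistic} (z), \code{p_value}, \code{reject}.
#' @export
test_beta3 <- function(fit, alpha = 0.05) {
  if (!isTRUE(fit$converged)) {
    warning("fit did not converge; returning non-rejection", call. = FALSE)
    return(list(statistic = NA_real_, p_value = 1, reject = FALSE))
  }
  se <- sqrt(fit$vcov["beta3", "beta3"])
  z <- fit$coef[["beta3"]] / se
  p <- 2 * pnorm(-abs(z))
  list(statistic = z, p_value = p, reject = p < alpha)
}

#' Simulate grouped binary outcomes from the synergy model
#'
#' @param beta numeric 4-vector of logistic coefficients.
#' @param grid two-column matrix or data frame of \code{(x, z)} design points.
#' @param counts trials per design point.
#' @return Data frame with columns \code{x}, \code{z}, \code{successes},
#'   \code{trials} (rows with zero trials dropped).
#' @export
generate_synergy_data <- function(beta, grid, counts) {
  grid <- as.matrix(grid)
  keep <- counts > 0
  V <- cbind(1, grid[, 1], grid[, 2], grid[, 1] * grid[, 2])
  p <- plogis(drop(V %*% beta))
  data.frame(x = grid[keep, 1], z = grid[keep, 2],
             successes = rbinom(sum(keep), counts[keep], p[keep]),
             trials = counts[keep])
}

# Firth-penalized logistic IRLS: score adjusted by half the trace term of
# the Jeffreys prior, i.e. successes shifted by h/2 with h the hat values.
# Estimates stay finite under (quasi-)separation.
firth_logistic <- function(X, successes, trials, maxit = 200, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (it in seq_len(maxit)) {
    p <- plogis(drop(X %*% beta))
    w <- trials * p * (1 - p)
    info <- crossprod(X, X * w)
    Iinv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(Iinv)) break
    h <- rowSums((X %*% Iinv) * X) * w       # hat values of the weighted LS
    score <- drop(crossprod(X, successes - trials * p + h * (0.5 - p)))
    step <- drop(Iinv %*% score)
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  p <- plogis(drop(X %*% beta))
  info <- crossprod(X, X * (trials * p * (1 - p)))
  vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, 4, 4))
  nm <- c("beta0", "beta1", "beta2", "beta3")
  names(beta) <- nm; dimnames(vc) <- list(nm, nm)
  list(coef = beta, vcov = vc, converged = converged, separated = FALSE)
}

# log posterior kernel for the conditional-mean prior: the beta densities on
# the corner probabilities plus the Jacobian of the corner-logit transform
# reduce to shape1*log(pi_c) + shape2*log(1-pi_c) summed over corners
log_posterior_synergy <- function(beta, data_resp, X, prior) {
  eta <- drop(X %*% beta)
  ll <- sum(data_resp[, 1] * plogis(eta, log.p = TRUE) +
              data_resp[, 2] * plogis(-eta, log.p = TRUE))
  corners <- rbind(c(1, 0, 0, 0), c(1, 1, 0, 0), c(1, 0, 1, 0), c(1, 1, 1, 1))
  etac <- drop(corners %*% beta)
  lp <- sum(prior$shape1 * plogis(etac, log.p = TRUE) +
              prior$shape2 * plogis(-etac, log.p = TRUE))
  ll + lp
}

#' Posterior sampling for the synergy model
#'
#' Random-walk Metropolis on the four logistic coefficients under the
#' conditional-mean prior, initialised at the posterior mode with proposal
#' covariance from the mode Hessian.
#'
#' @param data data frame with columns \code{x}, \code{z}, \code{successes},
#'   \code{trials}.
#' @param prior a \code{\link{synergy_prior}}.
#' @param iters,burn,thin Metropolis settings.
#' @param seed optional integer seed.
#' @return Matrix of posterior draws with columns \code{beta0..beta3},
#'   with attribute \code{accept_rate}.
#' @export
sample_synergy_posterior <- function(data, prior, iters = 4000, burn = 1000,
                                     thin = 1, seed = NULL) {
  stopifnot(inherits(prior, "synergy_prior"), iters > burn)
  if (!is.null(seed)) set.seed(seed)
  data <- as.data.frame(data)
  resp <- if (all(c("successes", "trials") %in% names(data)))
    cbind(data$successes, data$trials - data$successes)
  else cbind(data$y, 1 - data$y)
  X <- cbind(1, data$x, data$z, data$x * data$z)
  lpost <- function(b) log_posterior_synergy(b, resp, X, prior)
  opt <- tryCatch(optim(rep(0, 4), function(b) -lpost(b), method = "BFGS"),
                  error = function(e) NULL)
  p0 <- if (!is.null(opt)) opt$par else rep(0, 4)
  Hc <- tryCatch({
    H <- optimHess(p0, function(b) -lpost(b))
    t(chol(solve((H + t(H)) / 2)))
  }, error = function(e) diag(0.3, 4))
  n_keep <- floor((iters - burn) / thin)
  draws <- matrix(NA_real_, n_keep, 4,
                  dimnames = list(NULL, c("beta0", "beta1", "beta2", "beta3")))
  cur <- p0; cur_lp <- lpost(cur)
  scale <- 2.4 / 2; acc <- 0L; acc_win <- 0L; kept <- 0L
  for (it in seq_len(iters)) {
    prop <- cur + scale * drop(Hc %*% rnorm(4))
    prop_lp <- lpost(prop)
    if (is.finite(prop_lp) && log(runif(1)) < prop_lp - cur_lp) {
      cur <- prop; cur_lp <- prop_lp; acc <- acc + 1L; acc_win <- acc_win + 1L
    }
    if (it <= burn && it %% 100L == 0L) {
      scale <- scale * exp(acc_win / 100 - 0.3); acc_win <- 0L
    }
    if (it > burn && (it - burn) %% thin == 0L) {
      kept <- kept + 1L; draws[kept, ] <- cur
    }
  }
  attr(draws, "accept_rate") <- acc / iters
  draws
}
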