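# Optimality criteria and integer allocation search.
#
# A design problem fixes a grid of treatment levels, a budget of new units,
# possibly an already-spent allocation, and a set of parameter draws
# representing prior or posterior knowledge.  Criteria are Monte-Carlo
# averages over the draws; lower is better for every criterion by convention
# (the d-criterion is the negative mean log-determinant of the information).

#' Define an allocation-optimization problem
#'
#' @param levels design space: a numeric vector of concentrations for the
#'   emergence model, or a two-column data frame / matrix of \code{(x, z)}
#'   concentration pairs for the synergy model.
#' @param total_n number of new units to allocate (>= 0).
#' @param theta_draws matrix of parameter draws, one row per draw:
#'   columns \code{beta0, beta1, beta2, sigma} for the emergence model or
#'   \code{beta0..beta3} for the synergy model.
#' @param criterion \code{"c_delta"} (mean delta-method variance of the
#'   effective concentration), \code{"c_beta3"} (mean asymptotic variance of
#'   the interaction coefficient) or \code{"d"} (negative mean
#'   log-determinant of the expected information).
#' @param fixed_counts units already spent at each level (default none);
#'   their information is added to every candidate's.
#' @param censor_log_time censoring horizon (log days) for the emergence
#'   model, or \code{NULL} for no censoring.
#' @param fold median multiplier defining the effective concentration.
#' @param penalty_factor draws whose criterion is undefined or singular
#'   contribute \code{penalty_factor} times the largest finite draw value.
#' @return Object of class \code{"design_problem"} with precomputed per-draw,
#'   per-level unit information.
#' @export
design_problem <- function(levels, total_n, theta_draws,
                           criterion = c("c_delta", "c_beta3", "d"),
                           fixed_counts = NULL, censor_log_time = NULL,
                           fold = 2, penalty_factor = 10) {
  criterion <- match.arg(criterion)
  theta_draws <- as.matrix(theta_draws)
  if (nrow(theta_draws) < 1L) stop("`theta_draws` must be non-empty", call. = FALSE)
  if (total_n < 0) stop("`total_n` must be >= 0", call. = FALSE)
  model <- if (is.numeric(levels) && is.null(dim(levels))) "emergence" else "synergy"
  D <- nrow(theta_draws)
  if (model == "emergence") {
    stopifnot(ncol(theta_draws) == 4L)
    x <- as.numeric(levels)
    k <- length(x)
    # per-draw, per-level unit information, stacked as a (16 D) x k matrix so
    # that candidate information is a single matrix-vector product
    V <- rbind(1, x, x^2)
    U <- matrix(0, 16 * D, k)
    mu_all <- outer(theta_draws[, 1], rep(1, k)) +
      outer(theta_draws[, 2], x) + outer(theta_draws[, 3], x^2)
    for (i in seq_len(k)) {
      abc <- censored_abc(mu_all[, i], theta_draws[, 4], censor_log_time)
      vi <- V[, i]
      P1 <- as.numeric(rbind(cbind(tcrossprod(vi), 0), 0))  # a-pattern
      P2 <- numeric(16); P2[c(13:15, 4, 8, 12)] <- rep(vi, 2)  # b-pattern
      P3 <- numeric(16); P3[16] <- 1
      block <- tcrossprod(abc$a, P1) + tcrossprod(abc$b, P2) +
        tcrossprod(abc$c, P3)                                # D x 16
      U[, i] <- as.numeric(t(block))
    }
    h <- matrix(NA_real_, D, 4)
    deltas <- delta_from_theta(theta_draws[, 2], theta_draws[, 3], fold)
    for (d in which(!is.na(deltas)))
      h[d, ] <- delta_gradient(theta_draws[d, ], fold)
    geom <- list(x = x, k = k, U = U, h = h, defined = !is.na(deltas))
  } else {
    stopifnot(ncol(theta_draws) == 4L)
    grid <- as.matrix(levels)
    if (ncol(grid) != 2L) stop("synergy `levels` needs two columns (x, z)", call. = FALSE)
    k <- nrow(grid)
    U <- matrix(0, 16 * D, k)
    for (i in seq_len(k)) {
      v <- c(1, grid[i, 1], grid[i, 2], grid[i, 1] * grid[i, 2])
      eta <- theta_draws %*% v
      w <- as.numeric(plogis(eta) * (1 - plogis(eta)))
      U[, i] <- as.numeric(t(tcrossprod(w, as.numeric(tcrossprod(v)))))
    }
    geom <- list(grid = grid, k = k, U = U, h = NULL, defined = rep(TRUE, D))
  }
  if (is.null(fixed_counts)) fixed_counts <- rep(0, geom$k)
  if (length(fixed_counts) != geom$k)
    stop("`fixed_counts` must have one entry per level", call. = FALSE)
  structure(list(model = model, levels = levels, total_n = as.integer(total_n),
                 criterion = criterion, theta_draws = theta_draws,
                 fixed_counts = as.numeric(fixed_counts),
                 censor_log_time = censor_log_time, fold = fold,
                 penalty_factor = penalty_factor, D = D, geom = geom),
            class = "design_problem")
}

# Per-draw criterion values at a candidate allocation (new units only;
# fixed_counts are added internally).  Returns a vector of length D with NA
# for undefined/singular draws.  The c-criteria are evaluated with
# vectorized closed-form block elimination of the 4x4 systems (the search
# evaluates thousands of candidates, so per-draw solve() calls dominate
# otherwise).
criterion_draws <- function(problem, counts) {
  drop(criterion_draws_mat(problem, matrix(counts, ncol = 1)))
}

# Batched per-draw criterion over C candidate allocations (columns of Cmat):
# one (16 D) x C matrix product gives every candidate's information, and the
# closed-form eliminations are elementwise over the D x C layout.
criterion_draws_mat <- function(problem, Cmat) {
  g <- problem$geom
  D <- problem$D
  C <- ncol(Cmat)
  Mflat <- g$U %*% (problem$fixed_counts + Cmat)   # (16 D) x C
  # entry (i, j) of the information, as a D x C matrix (draw-major rows)
  M <- function(i, j)
    Mflat[(seq_len(D) - 1L) * 16L + (j - 1L) * 4L + i, , drop = FALSE]
  vals <- matrix(NA_real_, D, C)
  if (problem$criterion %in% c("d", "c_beta3")) {
    # (M^-1)[4,4] = 1 / (m44 - w' M33^-1 w) via the 3x3 cofactor inverse
    a <- M(1, 1); b <- M(1, 2); cc <- M(1, 3)
    d3 <- M(2, 2); e <- M(2, 3); f <- M(3, 3)
    w1 <- M(1, 4); w2 <- M(2, 4); w3 <- M(3, 4); m44 <- M(4, 4)
    det3 <- a * (d3 * f - e^2) - b * (b * f - cc * e) + cc * (b * e - cc * d3)
    q <- (w1^2 * (d3 * f - e^2) + w2^2 * (a * f - cc^2) +
            w3^2 * (a * d3 - b^2) + 2 * w1 * w2 * (cc * e - b * f) +
            2 * w1 * w3 * (b * e - cc * d3) + 2 * w2 * w3 * (b * cc - a * e))
    schur <- m44 - q / det3
    # positive definiteness by Sylvester's criterion on leading minors
    det2 <- a * d3 - b^2
    pd <- is.finite(schur) & a > 0 & det2 > 0 & det3 > 0 & schur > 0
    if (problem$criterion == "d") {
      v <- -(log(det3) + log(schur))        # negative log-determinant
      vals[pd & is.finite(v)] <- v[pd & is.finite(v)]
    } else {
      v <- 1 / schur
      vals[pd & is.finite(v) & v > 0] <- v[pd & is.finite(v) & v > 0]
    }
  } else {
    # h = (0, h2, h3, 0): reduce to the {2,3} block of M^-1 by eliminating
    # the {1,4} block
    m11 <- M(1, 1); m14 <- M(1, 4); m44 <- M(4, 4)
    e11 <- M(1, 2); e12 <- M(1, 3); e21 <- M(4, 2); e22 <- M(4, 3)
    det11 <- m11 * m44 - m14^2
    t11 <- (m44 * e11 - m14 * e21) / det11
    t12 <- (m44 * e12 - m14 * e22) / det11
    t21 <- (m11 * e21 - m14 * e11) / det11
    t22 <- (m11 * e22 - m14 * e12) / det11
    s11 <- M(2, 2) - (e11 * t11 + e21 * t21)
    s12 <- M(2, 3) - (e11 * t12 + e21 * t22)
    s22 <- M(3, 3) - (e12 * t12 + e22 * t22)
    dets <- s11 * s22 - s12^2
    h2 <- g$h[, 2]; h3 <- g$h[, 3]
    v <- (h2^2 * s22 - 2 * h2 * h3 * s12 + h3^2 * s11) / dets
    ok <- g$defined & is.finite(v) & v > 0 & is.finite(det11) & det11 > 0 &
      is.finite(dets) & dets > 0
    vals[ok] <- v[ok]
  }
  vals
}

#' Evaluate a design criterion at a candidate allocation
#'
#' Monte-Carlo average of the per-draw criterion over the problem's parameter
#' draws, evaluated at \code{fixed_counts + counts}.  Draws with an undefined
#' target or a singular information matrix contribute a large finite penalty;
#' the penalized fraction is attached as an attribute.
#'
#' @param problem a \code{\link{design_problem}}.
#' @param counts candidate allocation of the new units (must sum to
#'   \code{problem$total_n}).
#' @return Scalar criterion value (lower is better), with attribute
#'   \code{penalized_frac}.
#' @export
criterion_value <- function(problem, counts) {
  counts <- as.numeric(counts)
  if (length(counts) != problem$geom$k)
    stop("`counts` must have one entry per level", call. = FALSE)
  if (any(counts < 0)) stop("`counts` must be non-negative", call. = FALSE)
  if (abs(sum(counts) - problem$total_n) > 1e-8)
    stop("`counts` must sum to the problem budget", call. = FALSE)
  vals <- criterion_draws(problem, counts)
  bad <- !is.finite(vals)
  if (all(bad))
    stop("criterion undefined or singular for every parameter draw", call. = FALSE)
  if (any(bad)) {
    mx <- max(vals[!bad])
    vals[bad] <- mx + problem$penalty_factor * abs(mx) + 1
  }
  structure(mean(vals), penalized_frac = mean(bad))
}

# fully degenerate candidates (every draw singular) score +Inf in searches
criterion_value_or_inf <- function(problem, counts) {
  tryCatch(as.numeric(criterion_value(problem, counts)),
           error = function(e) Inf)
}

# batched penalized criterion over candidate columns; +Inf for fully
# degenerate candidates
criterion_values_batch <- function(problem, Cmat) {
  vals <- criterion_draws_mat(problem, Cmat)
  out <- numeric(ncol(Cmat))
  for (cc in seq_len(ncol(Cmat))) {
    v <- vals[, cc]
    bad <- !is.finite(v)
    if (all(bad)) { out[cc] <- Inf; next }
    if (any(bad)) {
      mx <- max(v[!bad])
      v[bad] <- mx + problem$penalty_factor * abs(mx) + 1
    }
    out[cc] <- mean(v)
  }
  out
}

# enumerate all k-part compositions of n (columns), for exact optimization
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1, 1))
  out <- vector("list", n + 1L)
  for (i in 0:n) {
    sub <- compositions(n - i, k - 1L)
    out[[i + 1L]] <- rbind(rep(i, ncol(sub)), sub)
  }
  do.call(cbind, out)
}

n_compositions <- function(n, k) choose(n + k - 1, k - 1)

# largest-remainder rounding of weights to integer counts summing to n
round_allocation <- function(w, n) {
  w <- pmax(w, 0); w <- w / sum(w)
  raw <- w * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  base
}

# one-unit coordinate exchange until a full pass yields no improvement
coordinate_exchange <- function(problem, counts, max_passes = 60) {
  val <- criterion_value_or_inf(problem, counts)
  k <- problem$geom$k
  trace <- val
  for (pass in seq_len(max_passes)) {
    # all one-unit moves evaluated in one batched criterion call
    moves <- list()
    for (i in seq_len(k)) {
      if (counts[i] == 0) next
      for (j in seq_len(k)) {
        if (j == i) next
        cand <- counts
        cand[i] <- cand[i] - 1; cand[j] <- cand[j] + 1
        moves[[length(moves) + 1L]] <- cand
      }
    }
    if (!length(moves)) break
    Cmat <- do.call(cbind, moves)
    vs <- criterion_values_batch(problem, Cmat)
    best <- which.min(vs)
    if (!length(best) || !is.finite(vs[best]) || vs[best] >= val) break
    counts <- Cmat[, best]
    val <- vs[best]
    trace <- c(trace, val)
  }
  list(counts = counts, value = val, trace = trace)
}

#' Optimize an integer allocation
#'
#' For problems with few candidate allocations the search is exhaustive and
#' the result exactly optimal.  Otherwise the search combines a continuous
#' relaxation over design weights (Nelder-Mead on a softmax parameterisation,
#' rounded by largest remainder) with multi-started one-unit coordinate
#' exchange.
#'
#' @param problem a \code{\link{design_problem}}.
#' @param n_starts number of exchange starts (rounded continuous solution,
#'   balanced, and random roundings of Dirichlet weights).
#' @param seed optional integer seed (random starts only).
#' @param enumerate_limit use exhaustive enumeration when the number of
#'   candidate allocations does not exceed this.
#' @param warm_start run the continuous relaxation before the exchange
#'   (disable for speed in tight inner loops; the exchange then starts from
#'   the balanced and random allocations only).
#' @return Object of class \code{"design_result"}: \code{counts},
#'   \code{value}, \code{exact} (logical: enumeration used),
#'   \code{penalized_frac}, \code{trace}.
#' @export
optimize_allocation <- function(problem, n_starts = 8, seed = NULL,
                                enumerate_limit = 50000, warm_start = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  k <- problem$geom$k
  n <- problem$total_n
  if (n == 0L) {
    counts <- rep(0, k)
    val <- criterion_value(problem, counts)
    return(structure(list(counts = counts, value = as.numeric(val),
                          exact = TRUE,
                          penalized_frac = attr(val, "penalized_frac"),
                          trace = as.numeric(val)),
                     class = "design_result"))
  }
  if (n_compositions(n, k) <= enumerate_limit) {
    cand <- compositions(n, k)
    vals <- numeric(ncol(cand))
    for (lo in seq(1, ncol(cand), by = 512)) {   # chunked batch evaluation
      hi <- min(lo + 511, ncol(cand))
      vals[lo:hi] <- criterion_values_batch(problem, cand[, lo:hi, drop = FALSE])
    }
    if (all(!is.finite(vals)))
      stop("criterion degenerate at every candidate allocation", call. = FALSE)
    best <- which.min(vals)
    counts <- cand[, best]
    val <- criterion_value(problem, counts)
    return(structure(list(counts = counts, value = as.numeric(val),
                          exact = TRUE,
                          penalized_frac = attr(val, "penalized_frac"),
                          trace = as.numeric(val)),
                     class = "design_result"))
  }
  # continuous warm start on softmax weights
  obj_w <- function(p) {
    w <- exp(c(0, p)); w <- w / sum(w)
    criterion_value_or_inf(problem, w * n)
  }
  opt <- if (!warm_start) NULL else tryCatch(
    optim(rep(0, k - 1), obj_w, method = "Nelder-Mead",
          control = list(maxit = 300)),
    error = function(e) NULL)
  starts <- list()
  if (!is.null(opt)) {
    w <- exp(c(0, opt$par)); w <- w / sum(w)
    starts <- c(starts, list(round_allocation(w, n)))
  }
  starts <- c(starts, list(round_allocation(rep(1, k), n)))
  while (length(starts) < n_starts)
    starts <- c(starts, list(round_allocation(rgamma(k, 1), n)))
  best <- NULL
  for (s in starts) {
    res <- tryCatch(coordinate_exchange(problem, s), error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("criterion degenerate at every start", call. = FALSE)
  val <- criterion_value(problem, best$counts)
  structure(list(counts = best$counts, value = best$value, exact = FALSE,
                 penalized_frac = attr(val, "penalized_frac"),
                 trace = best$trace),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("Allocation (%s): %s\n",
              if (x$exact) "exhaustive, exact" else "exchange heuristic",
              paste(x$counts, collapse = ", ")))
  cat(sprintf("  criterion value %.6g", x$value))
  if (isTRUE(x$penalized_frac > 0))
    cat(sprintf(" (%.1f%% of draws penalized)", 100 * x$penalized_frac))
  cat("\n")
  invisible(x)
}

#' Posterior-updated allocation for the next experimental phase
#'
#' Samples the posterior given the data already observed, then allocates the
#' phase budget by minimizing the posterior-averaged criterion, accounting
#' for the information already bought by the spent allocation.
#'
#' @param levels design grid (concentrations).
#' @param fixed_counts units already spent per level.
#' @param data observed \code{\link{censored_data}} for the spent units.
#' @param prior prior used for the posterior update.
#' @param phase_budget number of new units to allocate.
#' @param censor_log_time per-phase censoring horizon (log days), used in
#'   the posterior update.
#' @param n_draws number of (thinned) posterior draws used in the
#'   Monte-Carlo criterion.
#' @param mcmc list of \code{\link{sample_posterior}} settings
#'   (\code{iters}, \code{burn}).
#' @param criterion_censor_log_time horizon used inside the design
#'   criterion's information matrix.  The default \code{NULL} evaluates the
#'   uncensored expected information (the delta-method variance as derived
#'   for the uncensored model): censoring then informs the design only
#'   through the posterior, which reproduces the applied experiment's
#'   allocations and keeps the prior-averaged integrand stable.
#' @param n_starts,warm_start,seed passed to
#'   \code{\link{optimize_allocation}}.
#' @return List with elements \code{design} (a design result) and
#'   \code{posterior}.
#' @export
run_adaptive_phase <- function(levels, fixed_counts, data, prior,
                               phase_budget, censor_log_time = log(30),
                               n_draws = 400,
                               mcmc = list(iters = 6000, burn = 1000),
                               criterion_censor_log_time = NULL,
                               n_starts = 8, warm_start = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  post <- sample_posterior(data, prior, censor_log_time,
                           iters = mcmc$iters, burn = mcmc$burn)
  draws <- post$draws
  if (nrow(draws) > n_draws)
    draws <- draws[round(seq(1, nrow(draws), length.out = n_draws)), , drop = FALSE]
  problem <- design_problem(levels, phase_budget, draws, "c_delta",
                            fixed_counts = fixed_counts,
                            censor_log_time = criterion_censor_log_time,
                            fold = if (is.null(prior$fold)) 2 else prior$fold)
  design <- optimize_allocation(problem, n_starts = n_starts,
                                warm_start = warm_start)
  list(design = design, posterior = post)
}
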