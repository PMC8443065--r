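# Seeded simulation harnesses for the four headline studies:
#   - two-sample power grid (balanced vs adaptive Welch designs),
#   - uncensored dose-response MSE comparison (balanced vs c-optimal),
#   - retrospective censored comparison (one-shot vs two-phase c-optimal),
#   - synergy power curves across designs.
# Every harness is reproducible from (config, seed); per-replicate seeds are
# derived from the base seed so results do not depend on evaluation order.

#' Simulate censored emergence data
#'
#' Draws log emergence times from the quadratic log-normal model for an
#' allocation over a concentration grid, right-censoring at a fixed horizon.
#'
#' @param theta numeric vector \code{(beta0, beta1, beta2, sigma)}.
#' @param levels concentration grid.
#' @param counts units per level.
#' @param censor_days censoring horizon in days, or \code{NULL} for none.
#' @param seed optional integer seed.
#' @return A \code{\link{censored_data}} frame.
#' @export
generate_emergence_data <- function(theta, levels, counts, censor_days = NULL,
                                    seed = NULL) {
  theta <- as_theta(theta)
  if (!is.null(seed)) set.seed(seed)
  x <- rep(levels, counts)
  y <- rnorm(length(x), emergence_mu(theta, x), theta[["sigma"]])
  if (is.null(censor_days)) return(censored_data(x, y, 1L))
  obs <- y <= log(censor_days)
  censored_data(x, ifelse(obs, y, NA_real_), as.integer(obs))
}

# bias / variance / MSE summary with exact mse = bias^2 + variance
sim_report_row <- function(est, truth) {
  est <- est[is.finite(est)]
  reps <- length(est)
  bias <- mean(est) - truth
  variance <- mean((est - mean(est))^2)
  mse <- mean((est - truth)^2)
  data.frame(reps = reps, bias = bias, variance = variance, mse = mse,
             mc_se_mse = sd((est - truth)^2) / sqrt(reps))
}

#' Scenario table for the uncensored dose-response study
#'
#' Four quadratic-curve scenarios with \code{sigma = 1} on the five-level
#' grid \code{(0, 1/8, 1/4, 1/2, 1)} and \code{n = 100}.
#'
#' @return Data frame of scenario parameters and the analytic \code{Delta}.
#' @export
uncensored_study_scenarios <- function() {
  s <- data.frame(scenario = 1:4,
                  beta0 = 1, beta1 = c(0.5, 3, 3, 3),
                  beta2 = c(2, 2, -0.5, -1.5), sigma = 1)
  s$delta <- delta_from_theta(s$beta1, s$beta2)
  s
}

#' Scenario table for the retrospective censored study
#'
#' Six scenarios around the applied experiment's posterior:
#' \code{beta0 = 2.5}, \code{beta1} in \code{{0.07, 0.7, 1.7}},
#' \code{beta2} in \code{{1, 3}}, \code{sigma = 1}.
#'
#' @return Data frame of scenario parameters and the analytic \code{Delta}.
#' @export
retrospective_scenarios <- function() {
  g <- expand.grid(beta2 = c(1, 3), beta1 = c(0.07, 0.7, 1.7))
  s <- data.frame(scenario = 1:6, beta0 = 2.5, beta1 = g$beta1,
                  beta2 = g$beta2, sigma = 1)
  s$delta <- delta_from_theta(s$beta1, s$beta2)
  s
}

#' Dose-response design comparison on uncensored data
#'
#' For each scenario and design, repeatedly simulates an uncensored
#' experiment, computes the posterior mean of the effective concentration
#' under a flat prior, and reports bias, variance and MSE against the
#' analytic value.  Replicates whose posterior leaves the target undefined
#' for every draw are excluded and counted.
#'
#' @param reps replicates per scenario/design.
#' @param designs named list of allocations over the five-level grid.
#' @param scenarios scenario table as from \code{\link{uncensored_study_scenarios}}.
#' @param mcmc list of posterior settings (\code{iters}, \code{burn}).
#' @param seed base seed; per-replicate seeds are derived from it.
#' @return Data frame with one row per scenario x design.
#' @export
run_uncensored_design_study <- function(reps = 1000,
                             designs = list(balanced = c(20, 20, 20, 20, 20),
                                            c_optimal = c(42, 0, 0, 50, 8)),
                             scenarios = uncensored_study_scenarios(),
                             mcmc = list(iters = 4000, burn = 1000),
                             seed = 1) {
  levels <- c(0, 0.125, 0.25, 0.5, 1)
  prior <- flat_prior()
  out <- list()
  for (s in seq_len(nrow(scenarios))) {
    theta <- c(scenarios$beta0[s], scenarios$beta1[s], scenarios$beta2[s],
               scenarios$sigma[s])
    for (d in names(designs)) {
      est <- rep(NA_real_, reps)
      for (r in seq_len(reps)) {
        set.seed(seed + 7919L * s + 104729L * match(d, names(designs)) + r)
        dat <- generate_emergence_data(theta, levels, designs[[d]])
        post <- suppressWarnings(
          sample_posterior(dat, prior, iters = mcmc$iters, burn = mcmc$burn))
        est[r] <- post$delta_summary[["mean"]]
      }
      row <- sim_report_row(est, scenarios$delta[s])
      row$scenario <- scenarios$scenario[s]; row$design <- d
      row$excluded <- reps - row$reps; row$seed <- seed
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' Retrospective comparison of one-shot and two-phase c-optimal designs
#'
#' The one-shot arm allocates all \code{n} units by the prior c-optimal
#' design; the adaptive arm spends half by the prior design, updates the
#' posterior on the censored phase-1 data, and allocates the second half by
#' the posterior c-optimal design.  Both arms use a 30-day horizon per
#' phase and are summarised by the bias/variance/MSE of the final posterior
#' mean of the effective concentration under the elicited prior.
#'
#' @param reps replicates per scenario and arm.
#' @param scenarios scenario table as from \code{\link{retrospective_scenarios}}.
#' @param n total sample size (split in half for the adaptive arm).
#' @param censor_days per-phase censoring horizon in days.
#' @param prior elicited prior used for design and estimation.
#' @param design_draws prior draws used to derive the two fixed designs.
#' @param mcmc posterior settings for the final estimate.
#' @param phase_mcmc posterior settings for the interim update.
#' @param phase_design_draws posterior draws used in the per-replicate
#'   phase-2 allocation search.
#' @param seed base seed.
#' @return Data frame with one row per scenario x arm, plus the derived
#'   designs as attributes \code{fixed_design} and \code{phase1_design}.
#' @export
run_adaptive_design_study <- function(reps = 1000, scenarios = retrospective_scenarios(),
                             n = 100, censor_days = 30,
                             prior = elicit_prior(), design_draws = 2000,
                             mcmc = list(iters = 4000, burn = 1000),
                             phase_mcmc = list(iters = 3000, burn = 800),
                             phase_design_draws = 150, seed = 1) {
  levels <- c(0, 0.125, 0.25, 0.5, 1)
  clt <- log(censor_days)
  draws <- sample_prior(prior, design_draws, seed = seed + 17L)
  fixed_design <- optimize_allocation(
    design_problem(levels, n, draws, "c_delta", fold = prior$fold),
    seed = seed + 19L)$counts
  phase1_design <- optimize_allocation(
    design_problem(levels, n %/% 2L, draws, "c_delta", fold = prior$fold),
    seed = seed + 23L)$counts
  out <- list()
  for (s in seq_len(nrow(scenarios))) {
    theta <- c(scenarios$beta0[s], scenarios$beta1[s], scenarios$beta2[s],
               scenarios$sigma[s])
    est_fixed <- est_adapt <- rep(NA_real_, reps)
    for (r in seq_len(reps)) {
      set.seed(seed + 7919L * s + r)
      dat <- generate_emergence_data(theta, levels, fixed_design, censor_days)
      post <- suppressWarnings(
        sample_posterior(dat, prior, clt, iters = mcmc$iters, burn = mcmc$burn))
      est_fixed[r] <- post$delta_summary[["mean"]]

      set.seed(seed + 7919L * s + 15485863L + r)
      d1 <- generate_emergence_data(theta, levels, phase1_design, censor_days)
      ph <- suppressWarnings(
        run_adaptive_phase(levels, phase1_design, d1, prior,
                           phase_budget = n - sum(phase1_design),
                           censor_log_time = clt,
                           n_draws = phase_design_draws,
                           mcmc = phase_mcmc, n_starts = 2,
                           warm_start = FALSE))
      d2 <- generate_emergence_data(theta, levels, ph$design$counts,
                                    censor_days)
      pooled <- rbind(d1, d2)
      class(pooled) <- class(d1)
      post2 <- suppressWarnings(
        sample_posterior(pooled, prior, clt, iters = mcmc$iters,
                         burn = mcmc$burn))
      est_adapt[r] <- post2$delta_summary[["mean"]]
    }
    for (arm in c("fixed", "adaptive")) {
      row <- sim_report_row(if (arm == "fixed") est_fixed else est_adapt,
                            scenarios$delta[s])
      row$scenario <- scenarios$scenario[s]; row$design <- arm
      row$excluded <- reps - row$reps; row$seed <- seed
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  attr(res, "fixed_design") <- fixed_design
  attr(res, "phase1_design") <- phase1_design
  res
}

#' Two-sample power grid for balanced and adaptive Welch designs
#'
#' Rejection rates over a grid of second-group means and standard
#' deviations, for both the balanced fixed design and the two-phase
#' adaptive design, under a chosen noise family.
#'
#' @param mu2,sigma2 grids for the second group (first group fixed at
#'   \code{mu1}, \code{sigma1}).
#' @param mu1,sigma1 first-group mean and sd.
#' @param family noise family (see \code{\link{two_sample_scenario}}).
#' @param total_n,phase1_per_group design sizes.
#' @param reps replicates per cell.
#' @param alpha significance level.
#' @param seed base seed.
#' @return Data frame with one row per (design, mu2, sigma2) cell.
#' @export
run_two_sample_power_study <- function(mu2 = seq(10, 100, by = 10),
                           sigma2 = c(10, 20, 50, 100),
                           mu1 = 10, sigma1 = 10, family = "normal",
                           total_n = 40, phase1_per_group = 10,
                           reps = 10000, alpha = 0.05, seed = 1) {
  cells <- expand.grid(design = c("balanced", "adaptive"), mu2 = mu2,
                       sigma2 = sigma2, stringsAsFactors = FALSE)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sc <- two_sample_scenario(mu1, cells$mu2[i], sigma1, cells$sigma2[i],
                              family)
    r <- simulate_rejection_rate(cells$design[i], sc, total_n,
                                 phase1_per_group, reps, alpha,
                                 seed = seed + i)
    out[[i]] <- data.frame(design = cells$design[i], mu1 = mu1,
                           mu2 = cells$mu2[i], sigma1 = sigma1,
                           sigma2 = cells$sigma2[i], family = family,
                           power = r$rate, mc_se = r$mc_se, reps = reps,
                           seed = seed)
  }
  do.call(rbind, out)
}

#' Synergy power curves across designs
#'
#' Simulated power for testing the interaction coefficient over a grid of
#' true values, for the balanced, d-optimal and c-optimal (vague and
#' informative prior) allocations of \code{n} units over the 4 x 4
#' concentration grid, optionally adding the two-phase adaptive c-optimal
#' design under the informative prior.
#'
#' @param beta3_grid true interaction values.
#' @param beta012 true \code{(beta0, beta1, beta2)}.
#' @param n total units (split in half for the adaptive design).
#' @param reps replicates per design and \code{beta3}.
#' @param designs optional named list of fixed allocations over the grid;
#'   when \code{NULL} the four reference designs are derived.
#' @param include_adaptive also run the two-phase adaptive arm (slower).
#' @param design_draws prior draws for deriving the fixed designs.
#' @param alpha significance level.
#' @param seed base seed.
#' @return Data frame with one row per design x beta3: power, Monte-Carlo
#'   standard error, and the count of separated/non-converged fits.  The
#'   derived allocations are attached as attribute \code{designs}.
#' @export
run_synergy_power_study <- function(beta3_grid = c(0, 0.5, 1, 3, 5, 10, 15),
                           beta012 = c(-1.5, 0.75, 1.5), n = 160,
                           reps = 1000, designs = NULL,
                           include_adaptive = FALSE, design_draws = 400,
                           alpha = 0.05, seed = 1) {
  grid <- synergy_grid()
  if (is.null(designs)) {
    p1 <- sample_synergy_prior(synergy_prior_vague(), design_draws,
                               seed = seed + 101L)
    p2 <- sample_synergy_prior(synergy_prior_informative(), design_draws,
                               seed = seed + 102L)
    designs <- list(
      balanced = rep(n / 16, 16),
      d_optimal = optimize_allocation(
        design_problem(grid, n, p1, "d"), seed = seed + 1L)$counts,
      c_optimal_vague = optimize_allocation(
        design_problem(grid, n, p1, "c_beta3"), seed = seed + 2L)$counts,
      c_optimal_informative = optimize_allocation(
        design_problem(grid, n, p2, "c_beta3"), seed = seed + 3L)$counts)
  }
  out <- list()
  for (d in names(designs)) {
    for (b3 in beta3_grid) {
      beta <- c(beta012, b3)
      rej <- logical(reps); nsep <- 0L
      for (r in seq_len(reps)) {
        set.seed(seed + 104729L * match(d, names(designs)) +
                   7919L * match(b3, beta3_grid) + r)
        dat <- generate_synergy_data(beta, grid, designs[[d]])
        fit <- fit_logistic(dat)
        if (!fit$converged) nsep <- nsep + 1L
        rej[r] <- suppressWarnings(test_beta3(fit, alpha)$reject)
      }
      out[[length(out) + 1L]] <- data.frame(
        design = d, beta3 = b3, power = mean(rej),
        mc_se = sqrt(mean(rej) * (1 - mean(rej)) / reps),
        separated = nsep, reps = reps, seed = seed)
    }
  }
  if (include_adaptive) {
    p2 <- sample_synergy_prior(synergy_prior_informative(), design_draws,
                               seed = seed + 102L)
    phase1 <- optimize_allocation(
      design_problem(grid, n / 2, p2, "c_beta3"), seed = seed + 4L)$counts
    for (b3 in beta3_grid) {
      beta <- c(beta012, b3)
      rej <- logical(reps); nsep <- 0L
      for (r in seq_len(reps)) {
        set.seed(seed + 32452843L + 7919L * match(b3, beta3_grid) + r)
        d1 <- generate_synergy_data(beta, grid, phase1)
        post <- sample_synergy_posterior(d1, synergy_prior_informative(),
                                         iters = 2500, burn = 700)
        pd <- post[round(seq(1, nrow(post), length.out = 150)), , drop = FALSE]
        ph2 <- optimize_allocation(
          design_problem(grid, n / 2, pd, "c_beta3", fixed_counts = phase1),
          n_starts = 2)$counts
        d2 <- generate_synergy_data(beta, grid, ph2)
        fit <- fit_logistic(rbind(d1, d2))
        if (!fit$converged) nsep <- nsep + 1L
        rej[r] <- suppressWarnings(test_beta3(fit, alpha)$reject)
      }
      out[[length(out) + 1L]] <- data.frame(
        design = "adaptive_c_informative", beta3 = b3, power = mean(rej),
        mc_se = sqrt(mean(rej) * (1 - mean(rej)) / reps),
        separated = nsep, reps = reps, seed = seed)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "designs") <- designs
  res
}

#' The 4 x 4 concentration grid of the synergy study
#'
#' @return 16 x 2 matrix of \code{(x, z)} combinations of
#'   \code{0, 0.25, 0.5, 1}.
#' @export
synergy_grid <- function() {
  g <- as.matrix(expand.grid(x = c(0, 0.25, 0.5, 1), z = c(0, 0.25, 0.5, 1)))
  dimnames(g) <- list(NULL, c("x", "z"))
  g
}
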