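# Two-phase adaptive two-sample design with the Welch t-test.
#
# Phase 1 samples both groups equally; the phase-2 budget is then split to
# minimize the estimated standard error sqrt(S1^2/n1 + S2^2/n2), and the
# pooled data are analysed with the ordinary Welch test (the test does not
# adjust for the adaptive sampling; under skewed noise this inflates the
# type-I error mildly).

#' Two-phase two-sample design
#'
#' @param total_n total number of units across both groups and phases.
#' @param phase1_per_group units sampled per group in phase 1; the phase-2
#'   budget is \code{total_n - 2 * phase1_per_group} (zero gives the balanced
#'   fixed design).
#' @param alpha two-sided significance level.
#' @return Object of class \code{"two_sample_design"}.
#' @export
two_sample_design <- function(total_n = 40, phase1_per_group = 10,
                              alpha = 0.05) {
  stopifnot(total_n >= 4, phase1_per_group >= 2,
            2 * phase1_per_group <= total_n, alpha > 0, alpha < 1)
  structure(list(total_n = as.integer(total_n),
                 phase1_per_group = as.integer(phase1_per_group),
                 phase2_budget = as.integer(total_n - 2 * phase1_per_group),
                 alpha = alpha),
            class = "two_sample_design")
}

#' Two-group response scenario
#'
#' Group responses are generated as \code{mu + sigma * e} where \code{e} is a
#' standardized (mean 0, sd 1) draw from the noise family: normal, scaled
#' t(10) or t(5), Beta(5,10) or Beta(10,5), or chi-square(3), each
#' standardized by its analytic mean and standard deviation.
#'
#' @param mu1,mu2 group means.
#' @param sigma1,sigma2 positive group standard deviations.
#' @param family noise family.
#' @return Object of class \code{"two_sample_scenario"}.
#' @export
two_sample_scenario <- function(mu1, mu2, sigma1, sigma2,
                                family = c("normal", "t10", "t5",
                                           "beta_5_10", "beta_10_5",
                                           "chisq3")) {
  family <- match.arg(family)
  stopifnot(sigma1 > 0, sigma2 > 0)
  structure(list(mu1 = mu1, mu2 = mu2, sigma1 = sigma1, sigma2 = sigma2,
                 family = family),
            class = "two_sample_scenario")
}

# standardized noise draw (mean 0, sd 1 analytically)
draw_noise <- function(n, family) {
  switch(family,
         normal = rnorm(n),
         t10 = rt(n, 10) / sqrt(10 / 8),
         t5 = rt(n, 5) / sqrt(5 / 3),
         beta_5_10 = (rbeta(n, 5, 10) - 1 / 3) /
           sqrt(50 / (15^2 * 16)),
         beta_10_5 = (rbeta(n, 10, 5) - 2 / 3) /
           sqrt(50 / (15^2 * 16)),
         chisq3 = (rchisq(n, 3) - 3) / sqrt(6),
         stop("unknown noise family", call. = FALSE))
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom.  When
#' both sample variances are zero the p-value is 1 for equal means and 0
#' otherwise, by convention.
#'
#' @param group1_values,group2_values numeric response vectors (>= 2 values
#'   each).
#' @return List with \code{statistic}, \code{df}, \code{p_value}.
#' @export
welch_t_test <- function(group1_values, group2_values) {
  n1 <- length(group1_values); n2 <- length(group2_values)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  s1 <- var(group1_values); s2 <- var(group2_values)
  diff <- mean(group1_values) - mean(group2_values)
  se2 <- s1 / n1 + s2 / n2
  if (se2 == 0) {
    return(list(statistic = if (diff == 0) 0 else sign(diff) * Inf,
                df = n1 + n2 - 2,
                p_value = if (diff == 0) 1 else 0))
  }
  tstat <- diff / sqrt(se2)
  df <- se2^2 / ((s1 / n1)^2 / (n1 - 1) + (s2 / n2)^2 / (n2 - 1))
  list(statistic = tstat, df = df,
       p_value = 2 * pt(-abs(tstat), df))
}

#' Split the phase-2 budget to minimize the estimated standard error
#'
#' Returns the integer split \code{(n1_add, n2_add)} of the phase-2 budget
#' minimizing \code{sqrt(s1_sq/(n1 + n1_add) + s2_sq/(n2 + n2_add))} over all
#' \code{n1_add = 0..budget}.  Ties are broken toward the smaller
#' \code{n1_add}; when both variances are zero the objective is flat and the
#' budget is split evenly.
#'
#' @param s1_sq,s2_sq phase-1 sample variances (n-1 denominator).
#' @param n1_phase1,n2_phase1 phase-1 group sizes.
#' @param phase2_budget number of phase-2 units to split.
#' @return Integer vector \code{c(n1_add, n2_add)}.
#' @export
allocate_phase2 <- function(s1_sq, s2_sq, n1_phase1, n2_phase1,
                            phase2_budget) {
  stopifnot(s1_sq >= 0, s2_sq >= 0, phase2_budget >= 0,
            n1_phase1 >= 1, n2_phase1 >= 1)
  if (phase2_budget == 0L) return(c(0L, 0L))
  if (s1_sq == 0 && s2_sq == 0) {
    n1 <- phase2_budget %/% 2L
    return(c(n1, phase2_budget - n1))
  }
  n1_add <- 0:phase2_budget
  se2 <- s1_sq / (n1_phase1 + n1_add) +
    s2_sq / (n2_phase1 + phase2_budget - n1_add)
  best <- which.min(se2)  # first minimum: smallest n1_add on ties
  c(n1_add[best], phase2_budget - n1_add[best])
}

#' Run one adaptive (or balanced) two-sample trial
#'
#' Draws phase-1 samples of \code{phase1_per_group} per group, splits the
#' phase-2 budget with \code{\link{allocate_phase2}} using the phase-1 sample
#' variances, draws phase 2, and applies the Welch test to the pooled data.
#' With a zero phase-2 budget this is exactly the balanced fixed design.
#'
#' @param design a \code{\link{two_sample_design}}.
#' @param scenario a \code{\link{two_sample_scenario}}.
#' @param seed optional integer seed.
#' @return List with \code{group1}, \code{group2} (values), \code{phase1_n},
#'   \code{phase2_n} (per-group sizes), \code{statistic}, \code{df},
#'   \code{p_value}, \code{reject}.
#' @export
run_adaptive_trial <- function(design, scenario, seed = NULL) {
  stopifnot(inherits(design, "two_sample_design"),
            inherits(scenario, "two_sample_scenario"))
  if (!is.null(seed)) set.seed(seed)
  m <- design$phase1_per_group
  g1 <- scenario$mu1 + scenario$sigma1 * draw_noise(m, scenario$family)
  g2 <- scenario$mu2 + scenario$sigma2 * draw_noise(m, scenario$family)
  add <- allocate_phase2(var(g1), var(g2), m, m, design$phase2_budget)
  if (add[1] > 0)
    g1 <- c(g1, scenario$mu1 + scenario$sigma1 * draw_noise(add[1], scenario$family))
  if (add[2] > 0)
    g2 <- c(g2, scenario$mu2 + scenario$sigma2 * draw_noise(add[2], scenario$family))
  tst <- welch_t_test(g1, g2)
  list(group1 = g1, group2 = g2,
       phase1_n = c(m, m), phase2_n = c(add[1], add[2]),
       statistic = tst$statistic, df = tst$df, p_value = tst$p_value,
       reject = tst$p_value < design$alpha)
}

#' Monte-Carlo rejection rate of a two-sample design
#'
#' @param design \code{"adaptive"} (two-phase reallocation) or
#'   \code{"balanced"} (equal fixed allocation of the same total).
#' @param scenario a \code{\link{two_sample_scenario}}.
#' @param total_n total sample size.
#' @param phase1_per_group phase-1 size per group for the adaptive design.
#' @param reps Monte-Carlo replicates.
#' @param alpha significance level.
#' @param seed optional integer seed.
#' @return List with \code{rate}, \code{mc_se}, \code{reps}.
#' @export
simulate_rejection_rate <- function(design = c("adaptive", "balanced"),
                                    scenario, total_n = 40,
                                    phase1_per_group = 10, reps = 10000,
                                    alpha = 0.05, seed = NULL) {
  design <- match.arg(design)
  if (!is.null(seed)) set.seed(seed)
  des <- if (design == "adaptive")
    two_sample_design(total_n, phase1_per_group, alpha)
  else two_sample_design(total_n, total_n %/% 2L, alpha)
  rej <- logical(reps)
  for (r in seq_len(reps))
    rej[r] <- run_adaptive_trial(des, scenario)$reject
  rate <- mean(rej)
  list(rate = rate, mc_se = sqrt(rate * (1 - rate) / reps), reps = reps)
}
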