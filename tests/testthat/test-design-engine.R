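test_that("criterion with one draw equals the delta-method variance directly", {
  th <- c(1, 0.5, 2, 1)
  lv <- c(0, 0.125, 0.25, 0.5, 1)
  pr <- design_problem(lv, 100, matrix(th, 1), "c_delta")
  cnt <- c(20, 20, 20, 20, 20)
  expect_equal(as.numeric(criterion_value(pr, cnt)),
               asymptotic_variance_delta(th, lv, cnt), tolerance = 1e-10)
  # the published unbalanced allocation beats balanced at this parameter
  expect_lt(as.numeric(criterion_value(pr, c(42, 0, 0, 50, 8))),
            as.numeric(criterion_value(pr, cnt)))
})

test_that("criterion is invariant to draw order and level relabeling", {
  lv <- c(0, 0.25, 0.5, 1)
  draws <- sample_prior(elicit_prior(), 50, seed = 5)
  cnt <- c(10, 5, 20, 15)
  v1 <- as.numeric(criterion_value(
    design_problem(lv, 50, draws, "c_delta"), cnt))
  v2 <- as.numeric(criterion_value(
    design_problem(lv, 50, draws[sample(50), ], "c_delta"), cnt))
  expect_equal(v1, v2, tolerance = 1e-12)
  perm <- c(3, 1, 4, 2)
  v3 <- as.numeric(criterion_value(
    design_problem(lv[perm], 50, draws, "c_delta"), cnt[perm]))
  expect_equal(v1, v3, tolerance = 1e-10)
})

test_that("criterion validates the candidate and reports penalized draws", {
  lv <- c(0, 0.5, 1)
  pr <- design_problem(lv, 9, matrix(c(1, 1, 1, 1), 1), "c_delta")
  expect_error(criterion_value(pr, c(3, 3, 2)), "sum")
  expect_error(criterion_value(pr, c(-1, 5, 5)), "non-negative")
  # one defined and one undefined draw: penalty fraction 1/2
  draws <- rbind(c(1, 1, 1, 1), c(1, 0.1, -5, 1))
  pr2 <- design_problem(lv, 9, draws, "c_delta")
  v <- criterion_value(pr2, c(3, 3, 3))
  expect_equal(attr(v, "penalized_frac"), 0.5)
  # all draws undefined: degenerate criterion
  pr3 <- design_problem(lv, 9, rbind(c(1, 0.1, -5, 1)), "c_delta")
  expect_error(criterion_value(pr3, c(3, 3, 3)), "every parameter draw")
})

test_that("optimizer equals brute force on small instances", {
  # fixed tiny instance
  th <- c(1, 0.5, 2, 1)
  pr <- design_problem(c(0, 0.5, 1), 6, matrix(th, 1), "c_delta")
  res <- optimize_allocation(pr)
  cand <- adaptdesign:::compositions(6, 3)
  vals <- apply(cand, 2, function(cc)
    tryCatch(as.numeric(criterion_value(pr, cc)), error = function(e) Inf))
  expect_true(res$exact)
  expect_equal(res$value, min(vals), tolerance = 1e-12)

  # randomized small instances, heuristic forced, against enumeration
  set.seed(9)
  for (i in 1:6) {
    k <- sample(3:4, 1); n <- sample(6:10, 1)
    lv <- sort(c(0, runif(k - 1)))
    draws <- sample_prior(elicit_prior(), 12)
    prb <- design_problem(lv, n, draws, "c_delta")
    exact <- optimize_allocation(prb)
    heur <- optimize_allocation(prb, enumerate_limit = 0, seed = i,
                                n_starts = 6)
    expect_true(exact$exact)
    expect_false(heur$exact)
    expect_lte(heur$value, exact$value + 1e-8)
    expect_gte(heur$value, exact$value - 1e-8)
  }
})

test_that("optimizer never does worse than the balanced allocation", {
  set.seed(15)
  lv <- c(0, 0.125, 0.25, 0.5, 1)
  draws <- sample_prior(elicit_prior(), 100)
  pr <- design_problem(lv, 60, draws, "c_delta")
  res <- optimize_allocation(pr, seed = 2, n_starts = 3)
  expect_lte(res$value,
             as.numeric(criterion_value(pr, rep(12, 5))) + 1e-8)
  expect_equal(sum(res$counts), 60)
})

test_that("zero budget returns the empty allocation against fixed counts", {
  th <- c(1, 0.5, 2, 1)
  lv <- c(0, 0.5, 1)
  pr <- design_problem(lv, 0, matrix(th, 1), "c_delta",
                       fixed_counts = c(5, 5, 5))
  res <- optimize_allocation(pr)
  expect_equal(res$counts, c(0, 0, 0))
  expect_equal(res$value, asymptotic_variance_delta(th, lv, c(5, 5, 5)),
               tolerance = 1e-10)
})

test_that("information accounting across phases is additive at each draw", {
  th <- c(2, 1, 1.5, 1)
  lv <- c(0, 0.5, 1)
  pr <- design_problem(lv, 10, matrix(th, 1), "c_delta",
                       fixed_counts = c(4, 3, 3))
  v <- as.numeric(criterion_value(pr, c(2, 4, 4)))
  expect_equal(v, asymptotic_variance_delta(th, lv, c(6, 7, 7)),
               tolerance = 1e-10)
})

test_that("adaptive phase with no data reduces to the prior design", {
  lv <- c(0, 0.125, 0.25, 0.5, 1)
  prior <- elicit_prior()
  empty <- censored_data(numeric(0), numeric(0), integer(0))
  set.seed(6)
  ph <- suppressWarnings(
    run_adaptive_phase(lv, rep(0, 5), empty, prior, 50,
                       n_draws = 4000, mcmc = list(iters = 30000, burn = 4000),
                       n_starts = 4, seed = 60))
  # the posterior equals the prior, so the design follows the prior pattern:
  # support on {0, 0.5, 1} with the bulk in the middle
  expect_equal(sum(ph$design$counts), 50)
  expect_equal(sum(ph$design$counts[2:3]), 0)
  expect_gt(ph$design$counts[4], 15)
})
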