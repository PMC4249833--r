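make_obs <- function(df) observation_set(df)

two_state_obs <- function(f_t6, cond = "sorted_Y") {
  # one condition started pure-Y, observed at day 6
  make_obs(data.frame(
    condition = cond,
    time_days = rep(c(0, 6), each = 2),
    phenotype = rep(c("X", "Y"), 2),
    fraction = c(0, 1, f_t6, 1 - f_t6)
  ))
}

test_that("objective: exact match gives zero, mismatch gives the hand-worked sum", {
  m <- gt_model(c("X", "Y"), c(X = 0.7, Y = 0.5),
                c("X->Y" = 0.1, "Y->X" = 0.05))
  # simulate the true day-6 composition from a pure-Y start
  tr <- simulate_population(m, c(0, 100), c(0, 6))
  f6 <- unname(tr$fractions[2, 1])
  expect_equal(fit_objective(m, two_state_obs(f6)), 0, tolerance = 1e-15)

  # hand-worked sum of squares against a deliberately wrong observation
  wrong <- two_state_obs(0.9)
  manual <- (f6 - 0.9)^2 + ((1 - f6) - 0.1)^2
  expect_equal(fit_objective(m, wrong), manual, tolerance = 1e-10)
  expect_equal(fit_objective(m, wrong, kind = "l1"),
               abs(f6 - 0.9) + abs(1 - f6 - 0.1), tolerance = 1e-10)

  # orthogonal unit compositions differ by squared distance 2
  expect_equal(sum((c(1, 0, 0) - c(0, 1, 0))^2), 2)
})

test_that("observation sets validate the simplex and the day-0 anchor", {
  bad <- data.frame(condition = "a", time_days = c(0, 0, 6, 6),
                    phenotype = c("X", "Y", "X", "Y"),
                    fraction = c(0, 1, 0.5, 0.4))
  expect_error(observation_set(bad), regexp = "simplex", class = "pp_validation_error")
  no_day0 <- data.frame(condition = "a", time_days = c(6, 6),
                        phenotype = c("X", "Y"), fraction = c(0.5, 0.5))
  expect_error(observation_set(no_day0), regexp = "day-0", class = "pp_validation_error")
})

test_that("grid scan recovers a planted on-grid optimum exactly", {
  m <- grid_truth_model()
  obs <- generate_observations(m, sorting_design(c(0, 6)),
                               noise_model(Inf, seed = 1))
  # truth transitions are multiples of 0.1; use the 0.1 grid restricted to [0, 0.4]
  spec <- scan_spec(
    growth = list(A = 0.8, B = 0.9, C = 0.9),
    transitions = list("A->B" = c(0, 0.4, 0.1), "A->C" = c(0, 0.4, 0.1),
                       "B->A" = c(0, 0.4, 0.1), "B->C" = c(0, 0.4, 0.1),
                       "C->A" = c(0, 0.4, 0.1), "C->B" = c(0, 0.4, 0.1))
  )
  fit <- grid_scan(spec, obs, quiet = TRUE)
  expect_equal(unname(fit$best_params),
               c(0.2, 0.1, 0.1, 0.2, 0.3, 0.2), tolerance = 1e-12)
  expect_equal(fit$objective, 0, tolerance = 1e-12)
  expect_true(all(Re(fit$diagnostics$eigenvalues) > 0))
  # the shortlist is ranked and bounded below by the best objective
  expect_true(all(diff(fit$shortlist$objective) >= 0))
  expect_gte(fit$shortlist$objective[1], 0)
})

test_that("ties break to the lexicographically smallest parameter tuple", {
  # a condition already at the symmetric fixed point: every symmetric (k, k)
  # candidate reproduces it exactly, so the scan faces a deliberate tie
  obs <- make_obs(data.frame(
    condition = "steady", time_days = rep(c(0, 6), each = 2),
    phenotype = rep(c("X", "Y"), 2), fraction = rep(0.5, 4)
  ))
  spec <- scan_spec(growth = list(X = 0.5, Y = 0.5),
                    transitions = list("X->Y" = c(0, 0.2, 0.1),
                                       "Y->X" = c(0, 0.2, 0.1)))
  fit <- grid_scan(spec, obs, quiet = TRUE)
  expect_equal(unname(fit$best_params), c(0, 0))
  expect_equal(fit$objective, 0, tolerance = 1e-14)
})

test_that("worker count does not change the result", {
  m <- grid_truth_model()
  obs <- generate_observations(m, sorting_design(c(0, 6)),
                               noise_model(500, seed = 7))
  spec <- scan_spec(
    growth = list(A = 0.8, B = 0.9, C = 0.9),
    transitions = list("A->B" = c(0, 0.4, 0.1), "A->C" = c(0, 0.4, 0.1),
                       "B->A" = c(0, 0.4, 0.1), "B->C" = c(0, 0.4, 0.1),
                       "C->A" = c(0, 0.4, 0.1), "C->B" = c(0, 0.4, 0.1))
  )
  f1 <- grid_scan(spec, obs, jobs = 1, quiet = TRUE)
  f2 <- grid_scan(spec, obs, jobs = 3, quiet = TRUE)
  expect_identical(f1$best_params, f2$best_params)
  expect_identical(f1$objective, f2$objective)
  expect_equal(f1$shortlist, f2$shortlist, tolerance = 1e-15)
})

test_that("fraction-only objectives cannot see a uniform growth shift", {
  m <- grid_truth_model()
  obs <- generate_observations(m, sorting_design(c(0, 6)),
                               noise_model(500, seed = 3))
  shifted <- gt_model(m$labels, m$g + 0.3,
                      setNames(m$k[m$k > 0],
                               paste0(m$labels[which(m$k > 0, arr.ind = TRUE)[, 1]],
                                      "->",
                                      m$labels[which(m$k > 0, arr.ind = TRUE)[, 2]])))
  expect_equal(fit_objective(m, obs), fit_objective(shifted, obs),
               tolerance = 1e-10)
})

test_that("feasibility filter: sign criteria and the empty-feasible-set error", {
  grow <- gt_model(c("X", "Y"), c(X = 0.7, Y = 0.5),
                   c("X->Y" = 0.01, "Y->X" = 0.01))
  die <- gt_model(c("X", "Y"), c(X = -0.2, Y = -0.3),
                  c("X->Y" = 0.01, "Y->X" = 0.01))
  mixed <- gt_model(c("X", "Y"), c(X = 0.5, Y = 0.1),
                    c("X->Y" = 0.01, "Y->X" = 0.4))
  expect_true(feasibility_filter(grow, list(sign = "positive")))
  expect_false(feasibility_filter(mixed, list(sign = "positive")))
  expect_true(feasibility_filter(die, list(sign = "negative")))
  expect_false(feasibility_filter(die, list(sign = "positive")))
  expect_true(feasibility_filter(mixed, list(sign = "any")))
  expect_false(feasibility_filter(mixed, list(sign = "any", survivable = TRUE)))

  # a scan whose whole grid is infeasible reports the violation counts
  obs <- two_state_obs(0.5)
  spec <- scan_spec(growth = list(X = -1, Y = -1),
                    transitions = list("X->Y" = c(0, 0.2, 0.1),
                                       "Y->X" = c(0, 0.2, 0.1)),
                    feasibility = "coexistent_growth")
  expect_error(grid_scan(spec, obs, quiet = TRUE), regexp = "eigenvalue-sign",
               class = "pp_numeric_error")
})
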