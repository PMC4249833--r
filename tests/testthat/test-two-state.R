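p_ref <- two_state_params(0.7, 0.5, 0.1, 0.05)
T_ref <- matrix(c(0.6, 0.1, 0.05, 0.45), 2, 2)  # system matrix of p_ref

test_that("ratio rate: backflow at zero, zero at the fixed point, symmetry", {
  expect_equal(ratio_rate(0, p_ref), 0.05)
  expect_equal(ratio_rate(steady_ratio(p_ref), p_ref), 0, tolerance = 1e-14)
  psym <- two_state_params(0.4, 0.4, 0.2, 0.2)
  expect_equal(ratio_rate(1, psym), 0)
  expect_error(ratio_rate(-0.1, p_ref), class = "pp_validation_error")
})

test_that("steady ratio equals the leading-eigenvector component ratio", {
  # oracle: dense eigensolve of the 2x2 system matrix
  e <- eigen(T_ref)
  v <- e$vectors[, which.max(Re(e$values))]
  expect_equal(steady_ratio(p_ref), v[1] / v[2], tolerance = 1e-12)

  expect_equal(steady_ratio(two_state_params(0.4, 0.4, 0.2, 0.2)), 1)
  # zero growth: Markov-chain ratio k_YX / k_XY
  expect_equal(steady_ratio(two_state_params(0, 0, 0.2, 0.1)), 0.5)

  expect_error(steady_ratio(two_state_params(0.7, 0.5, 0, 0.05)),
               class = "pp_validation_error")
  expect_equal(steady_ratio(two_state_params(0.7, 0.5, 0, 0.05),
                            allow_degenerate = TRUE), Inf)
  # k_XY = 0 but X at a growth disadvantage: finite linear-drift answer
  expect_equal(steady_ratio(two_state_params(0.1, 0.8, 0, 0.2),
                            allow_degenerate = TRUE), 0.2 / 0.5)
})

test_that("eigen-ratio and growth-rate identities hold over random draws", {
  with_seed(61, {
    for (i in 1:300) {
      p <- random_two_state()
      sm <- system_matrix(as_gt_model(p))
      e <- eigen(sm$T)
      lead <- which.max(Re(e$values))
      v <- Re(e$vectors[, lead])
      expect_equal(steady_ratio(p), v[1] / v[2], tolerance = 1e-8)
      expect_equal(population_growth_rate(p), max(Re(e$values)),
                   tolerance = 1e-10)
    }
  })
})

test_that("population growth rate: symmetric and decoupled special cases", {
  expect_equal(population_growth_rate(two_state_params(0.3, 0.3, 0.2, 0.1)), 0.3)
  expect_equal(population_growth_rate(two_state_params(0.7, 0.5, 0, 0)), 0.7)
})

test_that("closed-form time course agrees with adaptive integration", {
  # oracle: integrate dr/dt = k_YX + Delta r - k_XY r^2 at tight tolerance
  rs <- steady_ratio(p_ref)
  target <- 0.9 * rs
  t_closed <- time_of_ratio(0, target, p_ref)
  # raw Riccati polynomial, written out by hand: Delta = (0.7-0.5)-(0.1-0.05)
  out <- deSolve::lsoda(y = c(r = 0), times = seq(0, 2 * t_closed, length.out = 4001),
                        func = function(t, y, parms) list(0.05 + 0.15 * y - 0.1 * y^2),
                        rtol = 1e-10, atol = 1e-12)
  r_at_closed <- stats::approx(out[, 1], out[, 2], xout = t_closed)$y
  expect_equal(r_at_closed, target, tolerance = 1e-6)

  expect_equal(time_of_ratio(0.3, 0.3, p_ref), 0)
  expect_error(time_of_ratio(0.5 * rs, 1.5 * rs, p_ref),
               class = "pp_validation_error")
})

test_that("trajectory inversion: ratio_at_time is the inverse of time_of_ratio", {
  with_seed(71, {
    for (i in 1:100) {
      p <- random_two_state()
      rs <- steady_ratio(p)
      # below the fixed point
      t1 <- stats::runif(1, 0.1, 5)
      r1 <- ratio_at_time(0, t1, p)
      expect_lt(r1, rs)
      expect_equal(time_of_ratio(0, r1, p), t1, tolerance = 1e-8)
      # above the fixed point
      r0 <- 2 * rs + 0.5
      r2 <- ratio_at_time(r0, t1, p)
      expect_gt(r2, rs)
      expect_equal(time_of_ratio(r0, r2, p), t1, tolerance = 1e-8)
    }
  })
})

test_that("re-equilibration timescale is of order 1/S", {
  # the residual distance to r* decays asymptotically at rate S: the
  # incremental e-folding time between the (1 - e^-1)- and (1 - e^-2)-fold
  # approach points is within a factor 2 of 1/S
  with_seed(81, {
    for (i in 1:100) {
      p <- random_two_state()
      rs <- steady_ratio(p)
      S <- kinetic_shape(p)$S
      t1 <- time_of_ratio(0, rs * (1 - exp(-1)), p)
      t2 <- time_of_ratio(0, rs * (1 - exp(-2)), p)
      expect_gt((t2 - t1) * S, 0.5)
      expect_lt((t2 - t1) * S, 2)
      # and the total approach time is itself at least 1/S
      expect_gt(t1 * S, 0.5)
    }
  })
})

test_that("monotone approach: trajectories never overshoot the steady ratio", {
  with_seed(91, {
    for (i in 1:50) {
      p <- random_two_state()
      rs <- steady_ratio(p)
      for (r0 in c(0, 2 * rs + 0.1)) {
        tt <- seq(0, 20 / kinetic_shape(p)$S, length.out = 200)
        r <- ratio_at_time(r0, tt, p)
        expect_true(all(diff(r) * sign(rs - r0) >= -1e-12))
        expect_true(all((r - rs) * (r0 - rs) >= -1e-10))
      }
    }
  })
})

test_that("kinetic shape: peak location, peak rate and the regime dichotomy", {
  ks1 <- kinetic_shape(two_state_params(0.9, 0.3, 0.05, 0.05))  # Delta = 0.6
  expect_equal(ks1$shape, "sigmoidal")
  expect_equal(ks1$r_peak, 6.0)
  expect_equal(ks1$max_rate, 0.05 + 0.6^2 / (4 * 0.05))

  ks2 <- kinetic_shape(two_state_params(0.5, 0.5, 0.3, 0.05))  # Delta = -0.25
  expect_equal(ks2$shape, "saturating")
  expect_equal(ks2$r_peak, 0)
  expect_equal(ks2$max_rate, 0.05)

  ks3 <- kinetic_shape(two_state_params(0.5, 0.5, 0.1, 0.1))   # Delta = 0
  expect_equal(ks3$shape, "saturating")
  expect_equal(ks3$r_peak, 0)
  expect_equal(ks3$max_rate, 0.1)
})

test_that("sigmoidal versus saturating matches numerical inflection detection", {
  with_seed(101, {
    n_sig <- 0; n_sat <- 0
    while (n_sig < 25 || n_sat < 25) {
      p <- random_two_state(k_range = c(0.05, 1))
      ks <- kinetic_shape(p)
      # the dichotomy is continuous at Delta = 0; grid-based detection is
      # resolution-limited there, so test clear-cut draws
      if (abs(ks$delta) < 0.05) next
      tt <- seq(0, 12 / ks$S, length.out = 2001)
      r <- ratio_at_time(0, tt, p)
      rate <- diff(r) / diff(tt)           # numerical dr/dt on the grid
      interior_max <- which.max(rate) > 2  # rate rises before it falls
      if (ks$shape == "sigmoidal") {
        n_sig <- n_sig + 1
        expect_true(interior_max)
        expect_true(any(diff(sign(diff(rate))) != 0))  # inflection in r(t)
      } else {
        n_sat <- n_sat + 1
        expect_false(interior_max)
        expect_true(all(diff(rate) <= 1e-10))
      }
    }
  })
})
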