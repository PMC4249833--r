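test_that("system matrix bookkeeping: diagonal growth minus outflow, transposed inflow", {
  m <- gt_model(c("X", "Y"), c(X = 0.7, Y = 0.5),
                c("X->Y" = 0.1, "Y->X" = 0.05))
  sm <- system_matrix(m)
  expect_equal(unname(sm$T), matrix(c(0.6, 0.1, 0.05, 0.45), 2, 2))
  expect_equal(sm$T, sm$G + sm$K)

  # no transitions: T is the bare growth diagonal
  m0 <- gt_model(c("X", "Y", "Z"), c(X = 0.7, Y = 0.5, Z = -0.1))
  expect_equal(unname(system_matrix(m0)$T), diag(c(0.7, 0.5, -0.1)))
})

test_that("flux conservation: columns of K sum to zero for random models", {
  with_seed(11, {
    for (i in 1:50) {
      sm <- system_matrix(random_model(4))
      expect_lt(max(abs(colSums(sm$K))), 1e-12)
      expect_true(all(sm$T[row(sm$T) != col(sm$T)] >= 0))
    }
  })
})

test_that("model validation names the offending entry", {
  expect_error(gt_model("X", c(X = 1)), class = "pp_validation_error")
  expect_error(gt_model(c("X", "Y"), c(X = 1, Y = NA_real_)),
               regexp = "Y", class = "pp_validation_error")
  expect_error(gt_model(c("X", "Y"), c(X = 1, Y = 1), c("X->Y" = -0.1)),
               regexp = "X->Y", class = "pp_validation_error")
  expect_error(gt_model(c("X", "Y"), c(X = 1, Y = 1), c("X->Z" = 0.1)),
               regexp = "Z", class = "pp_validation_error")
  expect_error(gt_model(c("X", "Y"), c(X = 1, Y = 1), c("X->X" = 0.1)),
               regexp = "self", class = "pp_validation_error")
  expect_error(gt_model(c("X", "Y"), c(X = 1, Y = 1), c("XY" = 0.1)),
               regexp = "malformed|A->B", class = "pp_validation_error")
})

test_that("spectral summary matches the 2x2 characteristic quadratic", {
  # oracle: eigenvalues of [[a, b], [c, d]] from trace/determinant by hand
  T <- matrix(c(0.6, 0.1, 0.05, 0.45), 2, 2)
  tr <- sum(diag(T)); dt <- T[1, 1] * T[2, 2] - T[1, 2] * T[2, 1]
  lam_hand <- sort((tr + c(1, -1) * sqrt(tr^2 - 4 * dt)) / 2, decreasing = TRUE)

  ss <- spectral_summary(gt_model(c("X", "Y"), c(X = 0.7, Y = 0.5),
                                  c("X->Y" = 0.1, "Y->X" = 0.05)))
  expect_equal(Re(ss$eigenvalues), lam_hand, tolerance = 1e-12)
  expect_equal(ss$lambda_max, lam_hand[1], tolerance = 1e-12)
  expect_equal(sum(ss$leading_composition), 1, tolerance = 1e-10)
  expect_true(ss$irreducible)
  expect_false(ss$degenerate)

  # decoupled diagonal case
  ssd <- spectral_summary(gt_model(c("X", "Y"), c(X = 0.6, Y = 0.45)))
  expect_equal(Re(ssd$eigenvalues), c(0.6, 0.45))
  expect_equal(unname(ssd$leading_composition), c(1, 0))
  expect_false(ssd$irreducible)
})

test_that("SUM159 phenotypes co-exist: all eigenvalue real parts positive", {
  ss <- spectral_summary(sum159_model())
  expect_true(all(Re(ss$eigenvalues) > 0))
  expect_equal(classify_regime(sum159_model())$regime, "coexistent_growth")
})

test_that("Perron-Frobenius structure holds on random models", {
  with_seed(21, {
    for (i in 1:300) {
      m <- random_model(sample(2:5, 1))
      ss <- spectral_summary(m)
      expect_false(ss$degenerate)
      expect_true(ss$irreducible)
      # leading eigenvalue real and strictly dominant
      expect_lt(abs(Im(ss$eigenvalues[1])), 1e-10)
      expect_gt(ss$spectral_gap, 0)
      expect_true(all(ss$leading_composition > 0))
      # fixed point: applying the (shifted, positivity-preserving) flow and
      # renormalizing reproduces the composition
      sm <- system_matrix(m)
      shift <- max(0, -min(Re(ss$eigenvalues))) + 1
      y <- (sm$T + shift * diag(nrow(sm$T))) %*% ss$leading_composition
      expect_equal(as.numeric(y / sum(y)),
                   unname(ss$leading_composition), tolerance = 1e-10)
    }
  })
})

test_that("stationary composition: symmetry, Markov limit, integration oracle", {
  # symmetric two-state: equal split
  msym <- gt_model(c("X", "Y"), c(X = 0.4, Y = 0.4),
                   c("X->Y" = 0.2, "Y->X" = 0.2))
  expect_equal(unname(stationary_composition(msym)), c(0.5, 0.5), tolerance = 1e-12)

  # zero growth: stationary distribution of the chain, ratio k_YX : k_XY
  mm <- gt_model(c("X", "Y"), c(X = 0, Y = 0), c("X->Y" = 0.2, "Y->X" = 0.1))
  expect_equal(unname(stationary_composition(mm)), c(1, 2) / 3, tolerance = 1e-12)

  # random irreducible 3-state vs long-time adaptive integration
  with_seed(31, {
    for (i in 1:20) {
      m <- random_model(3)
      sm <- system_matrix(m)
      ss <- spectral_summary(sm)
      horizon <- 200 / ss$spectral_gap
      N <- integrate_counts_oracle(sm$T - diag(ss$lambda_max, 3), rep(1, 3),
                                   c(0, horizon))[2, ]
      expect_equal(unname(stationary_composition(m)), N / sum(N),
                   tolerance = 1e-7)
    }
  })
})

test_that("growth-shift invariance: eigenvalues translate, composition fixed", {
  with_seed(41, {
    m <- random_model(4)
    shifted <- gt_model(m$labels, m$g + 0.37,
                        setNames(m$k[m$k > 0],
                                 paste0(m$labels[which(m$k > 0, arr.ind = TRUE)[, 1]],
                                        "->",
                                        m$labels[which(m$k > 0, arr.ind = TRUE)[, 2]])))
    s1 <- spectral_summary(m); s2 <- spectral_summary(shifted)
    expect_equal(sort(Re(s2$eigenvalues)), sort(Re(s1$eigenvalues)) + 0.37,
                 tolerance = 1e-10)
    expect_equal(s2$leading_composition, s1$leading_composition, tolerance = 1e-10)
  })
})

test_that("regime classification follows eigenvalue signs and det T for m = 2", {
  expect_equal(classify_regime(gt_model(c("X", "Y"), c(X = 0.7, Y = 0.5),
                                        c("X->Y" = 0.01, "Y->X" = 0.01)))$regime,
               "coexistent_growth")
  expect_equal(classify_regime(gt_model(c("X", "Y"), c(X = -0.2, Y = -0.3),
                                        c("X->Y" = 0.01, "Y->X" = 0.01)))$regime,
               "coexistent_extinction")
  rd <- classify_regime(gt_model(c("X", "Y"), c(X = 0.5, Y = 0.1),
                                 c("X->Y" = 0.01, "Y->X" = 0.4)))
  expect_equal(rd$regime, "derived_survival")
  expect_false(rd$survivability$independent[2])  # Y persists only via backflow

  # transitions dominating growth for every phenotype: blurred single type
  bl <- classify_regime(gt_model(c("X", "Y"), c(X = 0.01, Y = 0.02),
                                 c("X->Y" = 1, "Y->X" = 1.2)))
  expect_equal(bl$regime, "blurred_single_type")

  # same-sign eigenvalues iff det T > 0 (two-state determinant condition)
  with_seed(51, {
    for (i in 1:200) {
      p <- random_two_state()
      m2 <- as_gt_model(p)
      rep2 <- classify_regime(m2)
      if (rep2$marginal) next
      re <- Re(rep2$eigenvalues)
      expect_identical(all(re > 0) || all(re < 0), rep2$det_T > 0)
    }
  })

  # an eigenvalue at zero: marginal, no hard classification
  mz <- gt_model(c("X", "Y"), c(X = 0, Y = 0), c("X->Y" = 0.2, "Y->X" = 0.1))
  expect_true(classify_regime(mz)$marginal)
  expect_true(is.na(classify_regime(mz)$regime))
})

test_that("survivability: growth versus conversion outflow", {
  s159 <- survivability(sum159_model())
  expect_true(all(s159$independent))
  s149 <- survivability(sum149_model())
  expect_true(all(s149$independent))

  # no transitions: everyone independent
  expect_true(all(survivability(gt_model(c("X", "Y"), c(X = 0.1, Y = 0.2)))$independent))

  sv <- survivability(gt_model(c("X", "Y"), c(X = 0.5, Y = 0.1),
                               c("Y->X" = 0.4, "X->Y" = 0.01)))
  expect_true(sv$independent[sv$phenotype == "X"])
  expect_false(sv$independent[sv$phenotype == "Y"])
  expect_error(survivability(sum159_model(), dominance_factor = -1),
               class = "pp_validation_error")
})
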