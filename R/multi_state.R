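#' Fraction dynamics on the simplex
#'
#' Normalizing the linear count dynamics `dN/dt = T N` by the total
#' population, the fractions `x = N / sum(N)` obey the replicator-like
#' nonlinear system
#' \deqn{dx_i/dt = (T x)_i - x_i \sum_j (T x)_j,}
#' whose quadratic coupling term is the instantaneous mean growth rate.  The
#' right-hand side is tangent to the simplex (components sum to zero) and
#' vanishes exactly at the stationary composition.
#'
#' @param x simplex vector of fractions (entries `>= 0`, summing to 1 within
#'   `1e-9`).
#' @param model a [gt_model()] (or system matrix).
#' @return Named vector `dx/dt` in 1/day, summing to zero.
#' @export
fraction_rhs <- function(x, model) {
  sm <- as_system_matrix(model)
  m <- nrow(sm$T)
  if (length(x) != m || any(!is.finite(x))) {
    pp_stop_validation("'x' must be a finite vector of length ", m)
  }
  if (abs(sum(x) - 1) > 1e-9 || any(x < -1e-9)) {
    pp_stop_validation("'x' is off the simplex (sum = ", format(sum(x), digits = 12),
                       ", min = ", format(min(x), digits = 6), ")")
  }
  Tx <- as.numeric(sm$T %*% x)
  setNames(Tx - x * sum(Tx), sm$labels)
}

#' Stationary fractions by root finding on the simplex
#'
#' Solves `fraction_rhs(x) = 0` numerically: the fixed-point condition is a
#' coupled quadratic system with no general closed form, so a damped Newton
#' iteration is run in the `m - 1` free coordinates (the last fraction is
#' eliminated by the simplex constraint), with step halving whenever a step
#' would leave the simplex or fail to reduce the residual.  The result
#' coincides with the leading-eigenvector composition of
#' [stationary_composition()]; the two routes serve as mutual cross-checks.
#'
#' @param model a [gt_model()] (irreducible for a unique interior root).
#' @param x0 starting composition; default uniform.
#' @param max_iter iteration cap (default 500).
#' @param tol residual infinity-norm tolerance (default 1e-12).
#' @return Named simplex vector.
#' @export
stationary_fractions_numeric <- function(model, x0 = NULL,
                                         max_iter = 500, tol = 1e-12) {
  sm <- as_system_matrix(model)
  T <- sm$T
  m <- nrow(T)
  if (is.null(x0)) x0 <- rep(1 / m, m)
  if (length(x0) != m || abs(sum(x0) - 1) > 1e-9 || any(x0 < 0)) {
    pp_stop_validation("'x0' must be a simplex vector of length ", m)
  }

  full_x <- function(z) c(z, 1 - sum(z))
  resid <- function(x) {
    Tx <- as.numeric(T %*% x)
    Tx - x * sum(Tx)
  }
  # Jacobian of the first m-1 components of the rhs wrt the free coordinates,
  # with x_m = 1 - sum(z) substituted.
  jac <- function(x) {
    s <- sum(T %*% x)
    cs <- colSums(T)
    J <- matrix(0, m - 1, m - 1)
    for (j in seq_len(m - 1)) {
      dx <- numeric(m); dx[j] <- 1; dx[m] <- -1
      dTx <- as.numeric(T %*% dx)
      ds <- sum(cs * dx)
      J[, j] <- dTx[seq_len(m - 1)] - dx[seq_len(m - 1)] * s -
        x[seq_len(m - 1)] * ds
    }
    J
  }

  # globalization when a Newton step stalls: a few steps of the shifted,
  # positivity-preserving discrete flow x <- normalize((T + cI) x), which
  # contracts toward the attracting fixed point from anywhere on the simplex
  advance_flow <- function(x, n_steps = 25L) {
    c_shift <- 1 + max(0, -min(diag(T)))
    M <- T + diag(c_shift, m)
    for (s in seq_len(n_steps)) {
      y <- pmax(as.numeric(M %*% x), 0)
      if (sum(y) <= 0) return(x)
      x <- y / sum(y)
    }
    x
  }

  z <- x0[seq_len(m - 1)]
  x <- full_x(z)
  f <- resid(x)
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) <= tol) break
    J <- jac(x)
    step <- tryCatch(solve(J, -f[seq_len(m - 1)]),
                     error = function(e) NULL)
    improved <- FALSE
    if (!is.null(step)) {
      lambda <- 1
      for (h in 1:40) {
        z_new <- z + lambda * step
        x_new <- full_x(z_new)
        if (all(x_new >= -1e-14)) {
          xc <- pmax(x_new, 0) / sum(pmax(x_new, 0))
          f_new <- resid(xc)
          if (max(abs(f_new)) < max(abs(f))) {
            x <- xc
            z <- x[seq_len(m - 1)]
            f <- f_new
            improved <- TRUE
            break
          }
        }
        lambda <- lambda / 2
      }
    }
    if (!improved) {
      x <- advance_flow(x)
      z <- x[seq_len(m - 1)]
      f_new <- resid(x)
      if (max(abs(f_new)) >= max(abs(f)) && max(abs(f)) <= 1e-12) break
      f <- f_new
    }
  }
  if (max(abs(f)) > max(tol, 1e-10)) {
    pp_stop_numeric("stationary-fraction iteration did not converge: residual ",
                    format(max(abs(f)), digits = 4), " after ", max_iter,
                    " iterations")
  }
  setNames(x, sm$labels)
}

#' Convert simplex fractions to ratios relative to a reference phenotype
#'
#' The fixed-point analysis can equivalently be phrased in terms of ratios
#' `N_i / N_ref`; these views interconvert exactly.
#'
#' @param x simplex vector of fractions.
#' @param ref index or label of the reference phenotype (must have `x[ref] > 0`).
#' @return Vector of ratios with the reference entry equal to 1.
#' @export
fractions_to_ratios <- function(x, ref = 1L) {
  if (is.character(ref)) ref <- match(ref, names(x))
  if (is.na(ref) || ref < 1 || ref > length(x)) {
    pp_stop_validation("unknown reference phenotype")
  }
  if (x[ref] <= 0) pp_stop_validation("reference fraction must be positive")
  x / x[ref]
}

#' @rdname fractions_to_ratios
#' @param r vector of ratios to the reference phenotype.
#' @export
ratios_to_fractions <- function(r) {
  if (any(r < 0) || sum(r) <= 0) pp_stop_validation("ratios must be nonnegative")
  r / sum(r)
}

#' Spectral mode decomposition of a trajectory
#'
#' Writes the solution of `dN/dt = T N` as a sum of exponential modes,
#' `N(t) = sum_i A_i v_i exp(lambda_i t)`, with the coefficients `A`
#' determined from the initial counts by solving `V A = N0` in the
#' eigenbasis `V`.  For `m = 2` this is exactly the classical two-term
#' general solution.  Each subpopulation count is thus a linear combination
#' of exponentials; no nontrivial steady state in absolute numbers exists
#' unless an eigenvalue vanishes.
#'
#' @param model a [gt_model()] with a numerically diagonalizable system
#'   matrix.
#' @param N0 initial count vector (length m).
#' @return Object of class `mode_decomposition`: `eigenvalues`,
#'   `eigenvectors` (columns `v_i`), `coefficients` (`A_i`), `labels`.  Use
#'   [reconstruct_counts()] to evaluate the sum at given times.
#' @export
mode_decomposition <- function(model, N0) {
  sm <- as_system_matrix(model)
  m <- nrow(sm$T)
  if (length(N0) != m || any(!is.finite(N0))) {
    pp_stop_validation("'N0' must be a finite vector of length ", m)
  }
  e <- eigen(sm$T)
  kap <- tryCatch(kappa(e$vectors, exact = TRUE), error = function(err) Inf)
  if (!is.finite(kap) || kap > 1e10) {
    pp_stop_numeric("system matrix is numerically defective (eigenbasis condition ",
                    format(kap, digits = 3), "); use the integrator instead")
  }
  A <- solve(e$vectors, N0)
  structure(list(eigenvalues = e$values, eigenvectors = e$vectors,
                 coefficients = A, labels = sm$labels),
            class = "mode_decomposition")
}

#' Evaluate a mode decomposition at given times
#'
#' @param md a [mode_decomposition()].
#' @param times numeric vector of times (days).
#' @return `length(times) x m` matrix of counts (real part; imaginary parts
#'   cancel for real initial data).
#' @export
reconstruct_counts <- function(md, times) {
  stopifnot(inherits(md, "mode_decomposition"))
  out <- vapply(times, function(t) {
    Re(md$eigenvectors %*% (md$coefficients * exp(md$eigenvalues * t)))
  }, numeric(length(md$labels)))
  out <- t(matrix(out, nrow = length(md$labels)))
  colnames(out) <- md$labels
  out
}
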