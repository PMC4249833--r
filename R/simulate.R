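#' Simulate the linear count dynamics
#'
#' Propagates `dN/dt = T N` on a time grid.  The system is linear, so the
#' primary propagator is exact: eigendecomposition of `T` (equivalently the
#' matrix exponential).  When the eigenbasis is ill-conditioned the solver
#' falls back to a stiff adaptive integrator (`deSolve::lsoda`, rtol 1e-10).
#' Transitions conserve total cell number, so the total-count derivative is
#' always `sum_i g_i N_i`.
#'
#' @param model a [gt_model()].
#' @param N0 nonnegative initial counts (cells), not all zero; named or in
#'   label order.
#' @param times increasing grid of times in days (must include or start at
#'   the earliest requested time; typically starts at 0).
#' @return Object of class `pp_trajectory`: `times`, `counts`
#'   (`length(times) x m` matrix), `fractions` (row-wise simplex), `labels`.
#'   `as.data.frame()` gives the tidy long form with columns `time_days`,
#'   `phenotype`, `count`, `fraction`.
#' @examples
#' m <- gt_model(c("X", "Y"), c(X = 0.7, Y = 0.5),
#'               c("X->Y" = 0.1, "Y->X" = 0.05))
#' tr <- simulate_population(m, c(100, 0), times = seq(0, 20, by = 0.5))
#' head(as.data.frame(tr))
#' @export
simulate_population <- function(model, N0, times) {
  sm <- as_system_matrix(model)
  m <- nrow(sm$T)
  if (length(times) == 0) pp_stop_validation("'times' must be a non-empty grid")
  if (any(!is.finite(times)) || is.unsorted(times, strictly = TRUE)) {
    pp_stop_validation("'times' must be a strictly increasing finite grid")
  }
  if (length(N0) != m || any(!is.finite(N0)) || any(N0 < 0) || sum(N0) == 0) {
    pp_stop_validation("'N0' must be nonnegative, finite, not all zero, length ", m)
  }
  if (!is.null(names(N0))) N0 <- N0[sm$labels]

  e <- eigen(sm$T)
  kap <- tryCatch(kappa(e$vectors, exact = FALSE), error = function(err) Inf)
  if (is.finite(kap) && kap < 1e8) {
    A <- solve(e$vectors, N0)
    counts <- t(vapply(times, function(t) {
      pmax(Re(e$vectors %*% (A * exp(e$values * t))), 0)
    }, numeric(m)))
  } else {
    out <- deSolve::lsoda(y = as.numeric(N0), times = unique(c(min(times, 0), times)),
                          func = function(tt, y, p) list(sm$T %*% y),
                          rtol = 1e-10, atol = 1e-12)
    counts <- pmax(out[match(times, out[, 1L]), -1L, drop = FALSE], 0)
  }
  colnames(counts) <- sm$labels
  totals <- rowSums(counts)
  if (any(totals <= 0)) {
    pp_stop_numeric("population died out numerically (total count reached 0)")
  }
  structure(list(times = times, counts = counts,
                 fractions = counts / totals, labels = sm$labels),
            class = "pp_trajectory")
}

#' @export
print.pp_trajectory <- function(x, ...) {
  cat("Phenotype trajectory:", length(x$times), "timepoints x",
      length(x$labels), "phenotypes (", paste(x$labels, collapse = ", "), ")\n")
  cat("  t in [", min(x$times), ",", max(x$times), "] days\n")
  cat("  final fractions:", paste(sprintf("%s=%.4f", x$labels,
                                          x$fractions[nrow(x$fractions), ]),
                                  collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.pp_trajectory <- function(x, ...) {
  m <- length(x$labels)
  data.frame(
    time_days = rep(x$times, each = m),
    phenotype = rep(x$labels, times = length(x$times)),
    count = as.vector(t(x$counts)),
    fraction = as.vector(t(x$fractions)),
    stringsAsFactors = FALSE
  )
}

#' Simulated FACS-sorting re-equilibration panel
#'
#' Emulates the classical cell-sorting experiment: each phenotype is isolated
#' into a (near-)pure culture and regrown; all cultures drift back to the
#' same stationary composition.  One trajectory is produced per phenotype,
#' started from `purity` on its own phenotype with the remainder split evenly
#' over the others.
#'
#' @param model an irreducible [gt_model()].
#' @param times time grid in days.
#' @param purity initial own-phenotype fraction, in `(0.5, 1]`; default 1
#'   (perfectly pure sort).
#' @param N_total initial total cell count per culture (default 1e4).
#' @return Object of class `sorting_panel`: named list of `pp_trajectory`
#'   (one per sorted phenotype) plus the `purity` used.
#' @export
sorting_panel <- function(model, times, purity = 1, N_total = 1e4) {
  stopifnot(inherits(model, "gt_model"))
  if (!is.numeric(purity) || length(purity) != 1 || purity <= 0.5 || purity > 1) {
    pp_stop_validation("'purity' must lie in (0.5, 1]")
  }
  m <- n_states(model)
  trajs <- lapply(seq_len(m), function(i) {
    x0 <- rep((1 - purity) / (m - 1), m)
    x0[i] <- purity
    simulate_population(model, N_total * x0, times)
  })
  names(trajs) <- model$labels
  structure(list(trajectories = trajs, purity = purity), class = "sorting_panel")
}

#' @export
print.sorting_panel <- function(x, ...) {
  cat("Sorting panel:", length(x$trajectories), "pure-sorted cultures (purity ",
      x$purity, ")\n", sep = "")
  for (nm in names(x$trajectories)) {
    tr <- x$trajectories[[nm]]
    cat(sprintf("  sorted %s -> final fractions %s\n", nm,
                paste(sprintf("%.4f", tr$fractions[nrow(tr$fractions), ]),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Time for the composition to re-equilibrate
#'
#' The smallest time after which the fraction vector comes and *stays*
#' within `tol` (L-infinity) of the stationary composition.  "Stays" is
#' checked over a horizon of five times the candidate answer: the distance
#' need not be monotone, so a transient dip below `tol` does not count.
#' Times are reported on a 0.1-day grid.
#'
#' @param model an irreducible [gt_model()].
#' @param N0 initial counts (or fractions; only the composition matters).
#' @param tol L-infinity tolerance on fractions (default 0.01, well below
#'   typical flow-cytometry composition resolution).
#' @param dt reporting grid step in days (default 0.1).
#' @param max_horizon give up beyond this many days (default 2000).
#' @return Time in days (0 when already within tolerance).
#' @export
time_to_equilibrium <- function(model, N0, tol = 0.01, dt = 0.1,
                                max_horizon = 2000) {
  if (!is.numeric(tol) || tol <= 0) pp_stop_validation("'tol' must be positive")
  sm <- as_system_matrix(model)
  target <- stationary_composition(sm)
  # propagate the growth-shifted system: identical fractions, but counts stay
  # bounded over long horizons instead of overflowing at rate lambda_max
  lam <- spectral_summary(sm)$lambda_max
  T_shifted <- sm$T - diag(lam, nrow(sm$T))
  dimnames(T_shifted) <- dimnames(sm$T)
  horizon <- 50
  repeat {
    times <- seq(0, horizon, by = dt)
    tr <- simulate_population(T_shifted, N0, times)
    d <- apply(abs(tr$fractions - matrix(target, nrow(tr$fractions),
                                         length(target), byrow = TRUE)),
               1, max)
    ok <- d <= tol
    stays <- rev(cumprod(rev(ok))) == 1  # TRUE where ok from here to horizon
    idx <- which(stays)
    if (length(idx)) {
      t_eq <- times[idx[1L]]
      # require the sustained window to cover 5x the answer (or the cap)
      if (horizon >= min(5 * max(t_eq, dt), max_horizon)) return(t_eq)
    }
    if (horizon >= max_horizon) {
      pp_stop_numeric("no sustained convergence within ", max_horizon,
                      " days (final distance ", format(d[length(d)], digits = 4), ")")
    }
    horizon <- min(horizon * 4, max_horizon)
  }
}
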