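#' Two-phenotype model parameters
#'
#' Parameter set for the two-phenotype population: net growth rates `g_X`,
#' `g_Y` and directed transition rates `k_XY` (X to Y) and `k_YX` (Y to X),
#' all in 1/day.  The ratio `N_X / N_Y` obeys the Riccati equation
#' \deqn{dr/dt = k_{YX} + \Delta r - k_{XY} r^2,}
#' where \eqn{\Delta = (g_X - g_Y) - (k_{XY} - k_{YX})} is the drift: the
#' growth-rate difference minus the transition-rate difference.  The sign of
#' \eqn{\Delta} separates sigmoidal from saturating re-equilibration, and
#' the discriminant \eqn{S = \sqrt{\Delta^2 + 4 k_{XY} k_{YX}}} sets the
#' re-equilibration timescale \eqn{1/S}.
#'
#' @param g_X,g_Y net growth rates (1/day); may be negative.
#' @param k_XY,k_YX nonnegative transition rates (1/day).
#' @return Object of class `two_state_params`.
#' @examples
#' p <- two_state_params(0.7, 0.5, 0.1, 0.05)
#' steady_ratio(p)
#' kinetic_shape(p)
#' @export
two_state_params <- function(g_X, g_Y, k_XY, k_YX) {
  vals <- c(g_X = g_X, g_Y = g_Y, k_XY = k_XY, k_YX = k_YX)
  if (!all(is.finite(vals))) {
    pp_stop_validation("non-finite two-state parameter(s): ",
                       paste(names(vals)[!is.finite(vals)], collapse = ", "))
  }
  if (k_XY < 0 || k_YX < 0) {
    pp_stop_validation("transition rates must be nonnegative")
  }
  structure(list(g_X = g_X, g_Y = g_Y, k_XY = k_XY, k_YX = k_YX),
            class = "two_state_params")
}

#' @export
print.two_state_params <- function(x, ...) {
  cat(sprintf("Two-state parameters: g_X=%g g_Y=%g k_XY=%g k_YX=%g (1/day)\n",
              x$g_X, x$g_Y, x$k_XY, x$k_YX))
  invisible(x)
}

#' Convert two-state parameters to a full growth-transition model
#' @param p a [two_state_params()].
#' @param labels two phenotype names, default `c("X", "Y")`.
#' @return A [gt_model()].
#' @export
as_gt_model <- function(p, labels = c("X", "Y")) {
  stopifnot(inherits(p, "two_state_params"), length(labels) == 2)
  tr <- c(p$k_XY, p$k_YX)
  names(tr) <- c(paste0(labels[1], "->", labels[2]),
                 paste0(labels[2], "->", labels[1]))
  gt_model(labels, growth = setNames(c(p$g_X, p$g_Y), labels), transitions = tr)
}

ts_delta <- function(p) (p$g_X - p$g_Y) - (p$k_XY - p$k_YX)
ts_S <- function(p) sqrt(ts_delta(p)^2 + 4 * p$k_XY * p$k_YX)

# Roots of the Riccati right-hand side k_YX + Delta*r - k_XY*r^2.
# r_plus is the stable nonnegative fixed point, r_minus the negative root.
ts_roots <- function(p) {
  d <- ts_delta(p)
  S <- ts_S(p)
  c(minus = (d - S) / (2 * p$k_XY), plus = (d + S) / (2 * p$k_XY))
}

#' Instantaneous rate of change of the population ratio
#'
#' Evaluates `dr/dt = k_YX + Delta * r - k_XY * r^2` for the ratio
#' `N_X / N_Y`.  At a ratio of zero (a pure Y population) the rate is
#' `k_YX`: re-equilibration
#' starts purely by backflow.  The rate vanishes exactly at the steady ratio.
#'
#' @param r nonnegative ratio(s) `N_X / N_Y`.
#' @param p a [two_state_params()].
#' @return Rate(s) in 1/day.
#' @export
ratio_rate <- function(r, p) {
  stopifnot(inherits(p, "two_state_params"))
  if (any(!is.finite(r)) || any(r < 0)) {
    pp_stop_validation("'r' must be nonnegative and finite")
  }
  p$k_YX + ts_delta(p) * r - p$k_XY * r^2
}

#' Steady-state population ratio
#'
#' The nonnegative root of the Riccati right-hand side,
#' \eqn{r^* = (\Delta + S) / (2 k_{XY})}; it equals the component ratio of
#' the leading eigenvector of the 2x2 system matrix.  In the zero-growth
#' limit it reduces to the Markov-chain answer `k_YX / k_XY`.
#'
#' @param p a [two_state_params()] with `k_XY > 0`.
#' @param allow_degenerate if `TRUE`, the absorbing case `k_XY = 0` returns
#'   the decoupled answer instead of erroring: the drift is then linear,
#'   `dr/dt = k_YX + Delta r`, so the ratio settles at `-k_YX / Delta` when
#'   `Delta < 0` and diverges (`Inf`, X takes over) otherwise.
#' @return Nonnegative steady ratio (dimensionless), possibly `Inf` in the
#'   opt-in degenerate case.
#' @export
steady_ratio <- function(p, allow_degenerate = FALSE) {
  stopifnot(inherits(p, "two_state_params"))
  if (p$k_XY == 0) {
    if (!allow_degenerate) {
      pp_stop_validation("k_XY = 0: the ratio N_X/N_Y has no finite steady state ",
                         "in general; set allow_degenerate = TRUE for the ",
                         "absorbing/decoupled answer")
    }
    d <- ts_delta(p)
    if (d < 0) return(-p$k_YX / d)  # linear drift with stable finite ratio
    return(Inf)                     # X takes over (or fully decoupled)
  }
  unname(ts_roots(p)["plus"])
}

#' Asymptotic growth rate of the total two-state population
#'
#' Once the ratio settles at `r*`, the total population `N_X + N_Y` grows
#' exponentially at the composition-weighted mean growth rate
#' `(g_X r* + g_Y) / (r* + 1)` (transitions conserve total mass).  This
#' equals the leading eigenvalue of the 2x2 system matrix.
#'
#' @inheritParams steady_ratio
#' @return Growth rate in 1/day.
#' @export
population_growth_rate <- function(p) {
  stopifnot(inherits(p, "two_state_params"))
  if (p$k_XY == 0 && p$k_YX == 0) {
    return(max(p$g_X, p$g_Y))  # decoupled clones: the faster one dominates
  }
  if (p$k_XY == 0) {
    # X is absorbing for the ratio; lambda_max from the 2x2 matrix directly
    sm <- system_matrix(as_gt_model(p))
    return(max(Re(eigen(sm$T, only.values = TRUE)$values)))
  }
  r_star <- steady_ratio(p)
  (p$g_X * r_star + p$g_Y) / (r_star + 1)
}

#' Closed-form time for the ratio to travel from r0 to r
#'
#' Integrating the Riccati ratio equation by partial fractions gives
#' \deqn{t = \frac{1}{S} \log\left[\frac{(r - r_-)(r_0 - r_+)}
#'   {(r - r_+)(r_0 - r_-)}\right]}
#' with the two Riccati roots \eqn{r_\pm = (\Delta \pm S)/(2 k_{XY})}.  The
#' expression is valid piecewise on `(0, r*)` and `(r*, Inf)`: a trajectory
#' cannot cross its fixed point, so `r0` and `r` straddling `r*` is a domain
#' error.  The `1/S` prefactor is why the re-equilibration time is of order
#' `1/S`.
#'
#' @param r0 starting ratio (nonnegative).
#' @param r target ratio (nonnegative, same side of the steady ratio as `r0`).
#' @param p a [two_state_params()] with `k_XY > 0` and `S > 0`.
#' @return Time in days (nonnegative when `r` lies between `r0` and `r*`).
#' @seealso [ratio_at_time()] for the inverse map.
#' @export
time_of_ratio <- function(r0, r, p) {
  stopifnot(inherits(p, "two_state_params"))
  if (p$k_XY == 0) {
    pp_stop_validation("k_XY = 0: no finite fixed point; use the simulator instead")
  }
  if (!is.finite(r0) || !is.finite(r) || r0 < 0 || r < 0) {
    pp_stop_validation("'r0' and 'r' must be nonnegative and finite")
  }
  S <- ts_S(p)
  if (S == 0) {
    pp_stop_validation("degenerate kinetics (S = 0): both Riccati roots coincide")
  }
  roots <- ts_roots(p)
  rp <- roots["plus"]; rm <- roots["minus"]
  side0 <- sign(r0 - rp); side1 <- sign(r - rp)
  if (side0 != 0 && side1 != 0 && side0 != side1) {
    pp_stop_validation("'r0' and 'r' straddle the steady ratio r* = ", signif(rp, 6),
                       ": the trajectory cannot cross its fixed point")
  }
  if (r == r0) return(0)
  unname(log(((r - rm) * (r0 - rp)) / ((r - rp) * (r0 - rm))) / S)
}

#' Ratio reached after a given time
#'
#' Inverse of [time_of_ratio()]: solving the closed-form time course for `r`
#' gives a Moebius map of `exp(S t)`,
#' `r(t) = (r_- + c(t) r_+) / (1 + c(t))` with
#' `c(t) = exp(S t) (r0 - r_-) / (r_+ - r0)`.
#'
#' @param r0 starting ratio (nonnegative).
#' @param t time(s) in days, `>= 0`.
#' @inheritParams time_of_ratio
#' @return Ratio(s) at the requested times.
#' @export
ratio_at_time <- function(r0, t, p) {
  stopifnot(inherits(p, "two_state_params"))
  if (p$k_XY == 0) {
    pp_stop_validation("k_XY = 0: no finite fixed point; use the simulator instead")
  }
  if (!is.finite(r0) || r0 < 0) pp_stop_validation("'r0' must be nonnegative and finite")
  if (any(t < 0)) pp_stop_validation("'t' must be nonnegative")
  S <- ts_S(p)
  roots <- ts_roots(p)
  rp <- unname(roots["plus"]); rm <- unname(roots["minus"])
  if (r0 == rp) return(rep(rp, length(t)))
  cc <- exp(S * t) * (r0 - rm) / (rp - r0)
  r <- (rm + cc * rp) / (1 + cc)
  # starting above r*: cc < 0 and |cc| grows, the map stays on (r*, Inf)
  r[is.infinite(cc)] <- rp
  r
}

#' Re-equilibration kinetics and the sigmoidal/saturating dichotomy
#'
#' The Riccati rate `dr/dt` is a downward parabola in `r`, maximal at
#' `r_peak = Delta / (2 k_XY)` where it attains
#' `max_rate = k_YX + Delta^2 / (4 k_XY)`.  Starting from a pure Y
#' population (`r0 = 0`):
#' * `Delta > 0` (growth-rate difference exceeds the transition-rate
#'   difference, the Darwinian-dominated side): the rate first rises until
#'   the trajectory passes `r_peak`, then falls -- a **sigmoidal** time
#'   course.
#' * `Delta <= 0` (transition-dominated, Lamarckian side): the rate is
#'   monotone decreasing from `k_YX` -- **saturating** (exponential
#'   approach) kinetics.  `r_peak` is clipped to 0 and the maximal observed
#'   rate from `r0 = 0` is the initial backflow `k_YX`.
#'
#' @param p a [two_state_params()] with `k_XY > 0`.
#' @return Object of class `ratio_kinetics`: `r_star`, `delta`, `S`
#'   (discriminant, 1/day), `timescale` (`1/S`, days), `r_peak`, `max_rate`,
#'   `shape` (`"sigmoidal"` or `"saturating"`).
#' @export
kinetic_shape <- function(p) {
  stopifnot(inherits(p, "two_state_params"))
  if (p$k_XY == 0) {
    pp_stop_validation("k_XY = 0: kinetics are degenerate (no finite steady ratio)")
  }
  d <- ts_delta(p)
  S <- ts_S(p)
  sigmoidal <- d > 0
  structure(list(
    r_star = steady_ratio(p),
    delta = d,
    S = S,
    timescale = if (S > 0) 1 / S else Inf,
    r_peak = if (sigmoidal) d / (2 * p$k_XY) else 0,
    max_rate = if (sigmoidal) p$k_YX + d^2 / (4 * p$k_XY) else p$k_YX,
    shape = if (sigmoidal) "sigmoidal" else "saturating"
  ), class = "ratio_kinetics")
}

#' @export
print.ratio_kinetics <- function(x, ...) {
  cat("Two-state re-equilibration kinetics\n")
  cat(sprintf("  steady ratio r* : %g\n", x$r_star))
  cat(sprintf("  drift Delta     : %g 1/day\n", x$delta))
  cat(sprintf("  discriminant S  : %g 1/day  (timescale %g days)\n", x$S, x$timescale))
  cat(sprintf("  shape           : %s (r_peak = %g, max rate = %g 1/day)\n",
              x$shape, x$r_peak, x$max_rate))
  invisible(x)
}
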