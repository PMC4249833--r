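#' @useDynLib phenopop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rgamma rlnorm runif setNames
#' @importFrom utils modifyList write.csv read.csv
NULL

# Error helpers: validation problems (bad user input) and numerical failures
# (non-convergence) are distinguishable by condition class so callers -- in
# particular the command-line wrapper -- can map them to exit codes.
pp_stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("pp_validation_error", "error")))
}

pp_stop_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("pp_numeric_error", "error")))
}

#' Growth-transition model of interconverting cell phenotypes
#'
#' Defines a population of `m >= 2` discrete cell phenotypes, each with its
#' own net growth rate (birth minus death, the only growth quantity that can
#' be measured reliably in culture) and first-order directed transition rates
#' between phenotypes.  The counts \eqn{N_i(t)} then obey the linear system
#' \eqn{dN/dt = T N} with \eqn{T = G + K} (see [system_matrix()]).
#'
#' @param labels character vector of phenotype names (length `m >= 2`).
#' @param growth named numeric vector of net growth rates in 1/day, one per
#'   label; values may be negative (net dying subpopulations).
#' @param transitions named numeric vector of directed transition rates in
#'   1/day.  Names use the form `"A->B"` meaning conversion of an `A` cell
#'   into a `B` cell at that rate.  Omitted pairs default to 0; rates must be
#'   nonnegative and finite; self-transitions `"A->A"` are invalid.
#'
#' @return An object of class `gt_model` with elements `labels`, `g` (named
#'   growth vector) and `k` (an `m x m` matrix whose `[i, j]` entry is the
#'   rate of conversion from phenotype `i` to phenotype `j`; zero diagonal).
#'
#' @examples
#' m <- gt_model(c("X", "Y"), growth = c(X = 0.7, Y = 0.5),
#'               transitions = c("X->Y" = 0.1, "Y->X" = 0.05))
#' system_matrix(m)$T
#' @seealso [system_matrix()], [spectral_summary()], [stationary_composition()]
#' @export
gt_model <- function(labels, growth, transitions = numeric()) {
  labels <- as.character(labels)
  m <- length(labels)
  if (m < 2) {
    pp_stop_validation("a growth-transition model needs at least 2 phenotypes, got ", m)
  }
  if (anyDuplicated(labels)) {
    pp_stop_validation("duplicated phenotype labels: ",
                       paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  growth <- unlist(growth)
  if (is.null(names(growth)) || !setequal(names(growth), labels)) {
    if (length(growth) == m && is.null(names(growth))) {
      names(growth) <- labels
    } else {
      pp_stop_validation("'growth' must name every phenotype exactly once")
    }
  }
  growth <- growth[labels]
  if (!all(is.finite(growth))) {
    pp_stop_validation("non-finite growth rate for phenotype(s): ",
                       paste(labels[!is.finite(growth)], collapse = ", "))
  }

  k <- matrix(0, m, m, dimnames = list(from = labels, to = labels))
  transitions <- unlist(transitions)
  if (length(transitions)) {
    if (is.null(names(transitions))) {
      pp_stop_validation("'transitions' must be named \"A->B\" = rate")
    }
    for (nm in names(transitions)) {
      pair <- parse_transition_key(nm, labels)
      rate <- transitions[[nm]]
      if (!is.finite(rate)) {
        pp_stop_validation("non-finite transition rate for '", nm, "'")
      }
      if (rate < 0) {
        pp_stop_validation("negative transition rate ", rate, " for '", nm, "'")
      }
      k[pair[1L], pair[2L]] <- rate
    }
  }
  structure(list(labels = labels, g = growth, k = k), class = "gt_model")
}

parse_transition_key <- function(key, labels) {
  parts <- strsplit(key, "->", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) {
    pp_stop_validation("malformed transition key '", key, "': expected \"A->B\"")
  }
  parts <- trimws(parts)
  unknown <- setdiff(parts, labels)
  if (length(unknown)) {
    pp_stop_validation("unknown phenotype label(s) in transition '", key, "': ",
                       paste(unknown, collapse = ", "))
  }
  if (parts[1L] == parts[2L]) {
    pp_stop_validation("self-transition '", key, "' is not allowed")
  }
  parts
}

#' @export
print.gt_model <- function(x, ...) {
  cat("Growth-transition model with", length(x$labels), "phenotypes:",
      paste(x$labels, collapse = ", "), "\n")
  cat("Net growth rates (1/day):\n")
  print(x$g)
  nz <- which(x$k > 0, arr.ind = TRUE)
  if (nrow(nz)) {
    cat("Transition rates (1/day):\n")
    for (r in seq_len(nrow(nz))) {
      cat(sprintf("  %s -> %s : %g\n", x$labels[nz[r, 1]], x$labels[nz[r, 2]],
                  x$k[nz[r, 1], nz[r, 2]]))
    }
  } else {
    cat("No transitions (decoupled clones).\n")
  }
  invisible(x)
}

n_states <- function(model) length(model$labels)

# named "A->B" vector of the nonzero transition rates of a gt_model
model_transitions <- function(model) {
  nz <- which(model$k > 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) return(numeric())
  setNames(model$k[nz], paste0(model$labels[nz[, 1L]], "->", model$labels[nz[, 2L]]))
}

# shift every growth rate by a constant (leaves the composition unchanged)
shift_growth <- function(model, shift) {
  gt_model(model$labels, model$g + shift, model_transitions(model))
}

#' Build the system matrix T = G + K
#'
#' Assembles the matrix governing `dN/dt = T N`.  `G` is the diagonal matrix
#' of net growth rates.  `K` is the transition part: column `i` carries the
#' outflow of phenotype `i`, with `K[j, i] = k(i -> j)` and
#' `K[i, i] = -sum_j k(i -> j)`, so every column of `K` sums to zero (flux
#' conservation: conversions move cells between states without creating or
#' destroying them).  `K` is therefore a Markov generator and `T` a Metzler
#' matrix (nonnegative off-diagonals), which is what makes Perron-Frobenius
#' spectral analysis applicable.
#'
#' @param model a [gt_model()].
#' @return An object of class `system_matrix`: list with the `m x m` matrices
#'   `T`, `G`, `K` and the `labels` ordering.
#' @examples
#' m <- gt_model(c("X", "Y"), c(X = 0.7, Y = 0.5),
#'               c("X->Y" = 0.1, "Y->X" = 0.05))
#' system_matrix(m)$T  # [[0.6, 0.05], [0.1, 0.45]]
#' @export
system_matrix <- function(model) {
  stopifnot(inherits(model, "gt_model"))
  m <- n_states(model)
  G <- diag(model$g, m)
  outflow <- rowSums(model$k)
  K <- t(model$k) - diag(outflow, m)
  dimnames(G) <- dimnames(K) <- list(model$labels, model$labels)
  structure(list(T = G + K, G = G, K = K, labels = model$labels),
            class = "system_matrix")
}

as_system_matrix <- function(x) {
  if (inherits(x, "system_matrix")) return(x)
  if (inherits(x, "gt_model")) return(system_matrix(x))
  if (is.matrix(x)) {
    if (nrow(x) != ncol(x) || !all(is.finite(x))) {
      pp_stop_validation("system matrix must be square with finite entries")
    }
    labels <- rownames(x)
    if (is.null(labels)) labels <- paste0("S", seq_len(nrow(x)))
    K <- x
    diag(K) <- diag(K) - colSums(x)  # split so that K columns sum to zero
    return(structure(list(T = x, G = diag(colSums(x), nrow(x)), K = K,
                          labels = labels), class = "system_matrix"))
  }
  pp_stop_validation("cannot interpret object of class ",
                     paste(class(x), collapse = "/"), " as a system matrix")
}

# Strong connectivity of the directed graph of off-diagonal support of T;
# for the small m used here boolean reachability by repeated squaring is fine.
is_irreducible <- function(T, tol = 0) {
  m <- nrow(T)
  A <- (abs(T) > tol)
  diag(A) <- TRUE
  R <- A
  for (i in seq_len(ceiling(log2(max(m, 2))))) {
    R <- (R %*% R) > 0
  }
  all(R)
}

#' Spectral summary of the growth-transition system
#'
#' Eigen-decomposes the system matrix.  For an irreducible model the leading
#' eigenvalue is real and simple (Perron-Frobenius for Metzler matrices): it
#' is the asymptotic exponential growth rate of the total population, and its
#' right eigenvector, rescaled to the probability simplex, is the stationary
#' phenotype composition.
#'
#' @param x a [gt_model()], a [system_matrix()] or a plain square matrix.
#' @return Object of class `spectral_summary`: `eigenvalues` (complex, sorted
#'   by decreasing real part), `lambda_max` (real part of the leading
#'   eigenvalue), `leading_composition` (simplex vector, or `NA`s when the
#'   leading mode is degenerate/non-real), `spectral_gap` (difference of the
#'   two largest real parts), `irreducible`, and `degenerate` (fallback flag:
#'   `TRUE` when the leading eigenvalue is non-real or numerically
#'   non-simple, or the leading eigenvector leaves the simplex).
#' @examples
#' spectral_summary(gt_model(c("X", "Y"), c(X = 0.7, Y = 0.5),
#'                           c("X->Y" = 0.1, "Y->X" = 0.05)))
#' @export
spectral_summary <- function(x) {
  sm <- as_system_matrix(x)
  T <- sm$T
  m <- nrow(T)
  e <- eigen(T)
  ord <- order(-Re(e$values), -Im(e$values))
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]

  tol <- 1e-10 * max(1, norm(T, "1"))
  lead <- values[1L]
  degenerate <- abs(Im(lead)) > tol
  if (m >= 2 && abs(values[2L] - lead) <= tol) degenerate <- TRUE

  comp <- rep(NA_real_, m)
  if (!degenerate) {
    v <- Re(vectors[, 1L])
    s <- sum(v)
    if (abs(s) <= tol) {
      degenerate <- TRUE
    } else {
      v <- v / s
      if (any(v < -1e-8)) {
        degenerate <- TRUE  # leading mode points out of the positive cone
      } else {
        comp <- pmax(v, 0)
        comp <- comp / sum(comp)
      }
    }
  }
  names(comp) <- sm$labels

  structure(list(
    eigenvalues = values,
    lambda_max = Re(lead),
    leading_composition = comp,
    spectral_gap = if (m >= 2) Re(values[1L]) - Re(values[2L]) else NA_real_,
    irreducible = is_irreducible(T),
    degenerate = degenerate,
    labels = sm$labels
  ), class = "spectral_summary")
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat("Spectral summary (", length(x$eigenvalues), " phenotypes)\n", sep = "")
  cat("  eigenvalues:", paste(format(x$eigenvalues, digits = 6), collapse = ", "), "\n")
  cat("  lambda_max :", format(x$lambda_max, digits = 6), "(1/day)\n")
  cat("  spectral gap:", format(x$spectral_gap, digits = 6), "\n")
  cat("  irreducible:", x$irreducible, " degenerate:", x$degenerate, "\n")
  if (!anyNA(x$leading_composition)) {
    cat("  stationary composition:\n")
    print(round(x$leading_composition, 6))
  }
  invisible(x)
}

#' Stationary phenotype composition
#'
#' The simplex vector of subpopulation fractions to which the population
#' converges from any strictly positive initial condition; it is the leading
#' right eigenvector of `T` normalized to sum one.  When growth and
#' transitions are both present only the *fractions* become stationary --
#' absolute counts keep growing (or dying) exponentially at `lambda_max`.
#' In the zero-growth limit the result is the stationary distribution of the
#' transition Markov chain; for two states this is the ratio
#' `k(Y->X) : k(X->Y)`.
#'
#' @param x model, system matrix or plain matrix.
#' @param fallback if `TRUE` (default), a degenerate or non-real leading mode
#'   or a reducible matrix falls back to long-time integration of the
#'   fraction dynamics (horizon `200 / spectral_gap`, or a fixed 1000-day
#'   horizon when the gap vanishes), with a warning.
#' @return Named simplex vector of fractions.
#' @examples
#' stationary_composition(gt_model(c("X", "Y"), c(X = 0, Y = 0),
#'                                 c("X->Y" = 0.2, "Y->X" = 0.1)))  # (1/3, 2/3)
#' @export
stationary_composition <- function(x, fallback = TRUE) {
  sm <- as_system_matrix(x)
  ss <- spectral_summary(sm)
  if (!ss$degenerate && ss$irreducible) {
    return(ss$leading_composition)
  }
  if (!fallback) {
    pp_stop_numeric("leading eigenmode is degenerate or the model is reducible; ",
                    "re-run with fallback = TRUE to use the integration fallback")
  }
  warning("degenerate or reducible leading mode: stationary composition ",
          "obtained by long-time integration", call. = FALSE)
  gap <- ss$spectral_gap
  horizon <- if (is.finite(gap) && gap > 1e-8) 200 / gap else 1000
  m <- nrow(sm$T)
  N0 <- rep(1, m)
  N <- propagate_counts(sm$T, N0, horizon)
  comp <- N / sum(N)
  names(comp) <- sm$labels
  comp
}

# exp(T t) %*% N0 without forming the full matrix exponential when the
# eigenbasis is well conditioned; renormalizes against overflow by factoring
# out the leading rate.
propagate_counts <- function(T, N0, t) {
  e <- eigen(T)
  kappa <- tryCatch(kappa(e$vectors, exact = FALSE), error = function(e) Inf)
  shift <- max(Re(e$values))
  if (is.finite(kappa) && kappa < 1e8) {
    A <- solve(e$vectors, N0)
    N <- Re(e$vectors %*% (A * exp((e$values - shift) * t)))
  } else {
    # near-defective: fall back to a stiff integrator on the shifted system
    out <- deSolve::lsoda(
      y = N0, times = c(0, t),
      func = function(tt, y, p) list((T - diag(shift, nrow(T))) %*% y),
      rtol = 1e-10, atol = 1e-12
    )
    N <- as.numeric(out[nrow(out), -1L])
  }
  pmax(N, 0)
}

#' Phenotype survivability: independent versus derived subpopulations
#'
#' A phenotype can persist on its own when its net growth rate exceeds its
#' total conversion outflow; otherwise it only persists as a "derivative" of
#' the others, sustained by backflow from them.  For the qualitative
#' "much larger" judgement a dominance factor is reported: growth exceeding
#' `dominance_factor` times the outflow counts as clear-cut dominance.
#'
#' @param model a [gt_model()].
#' @param dominance_factor positive multiplier operationalizing "much
#'   larger"; default 10.
#' @return data.frame with one row per phenotype: `growth`, `outflow`,
#'   `independent` (strict `growth > outflow`), `dominant`
#'   (`growth > dominance_factor * outflow`).
#' @export
survivability <- function(model, dominance_factor = 10) {
  stopifnot(inherits(model, "gt_model"))
  if (!is.numeric(dominance_factor) || dominance_factor <= 0) {
    pp_stop_validation("'dominance_factor' must be a positive number")
  }
  outflow <- rowSums(model$k)
  data.frame(
    phenotype = model$labels,
    growth = unname(model$g),
    outflow = unname(outflow),
    independent = unname(model$g > outflow),
    dominant = unname(model$g > dominance_factor * outflow),
    row.names = NULL
  )
}

#' Classify the long-term population regime
#'
#' The signs of the eigenvalues of `T` decide the fate of the subpopulations:
#' all positive real parts means the phenotypes co-exist and the whole
#' population grows (`coexistent_growth`); all negative means joint
#' extinction (`coexistent_extinction`); mixed signs mean that modes decay
#' and some phenotypes persist only as derivatives of the survivors
#' (`derived_survival`).  When every phenotype's conversion outflow exceeds
#' `dominance_factor` times its net growth rate, transitions dominate so
#' strongly that the discrete phenotypes blur into a single effective
#' population with a mean growth rate (`blurred_single_type`).  For `m = 2`
#' the same-sign condition is equivalent to `det(T) > 0`.
#'
#' @inheritParams survivability
#' @return Object of class `regime_report`: `regime`, `blurred` (the
#'   transition-dominance condition on its own), `marginal` (TRUE when
#'   an eigenvalue real part sits within tolerance of zero, in which case no
#'   hard sign classification is made), per-phenotype `survivability` table,
#'   `det_T` (reported for m = 2), `eigenvalues`, `dominance_factor`.
#' @examples
#' classify_regime(gt_model(c("X", "Y"), c(X = 0.7, Y = 0.5),
#'                          c("X->Y" = 0.01, "Y->X" = 0.01)))
#' @export
classify_regime <- function(model, dominance_factor = 10) {
  stopifnot(inherits(model, "gt_model"))
  sm <- system_matrix(model)
  ss <- spectral_summary(sm)
  surv <- survivability(model, dominance_factor)
  tol <- 1e-12 * max(1, norm(sm$T, "1"))
  re <- Re(ss$eigenvalues)

  marginal <- any(abs(re) <= tol)
  outflow <- rowSums(model$k)
  # transitions dominate when every phenotype's conversion outflow dwarfs the
  # magnitude of its net growth rate
  blurred <- all(outflow > dominance_factor * abs(model$g))

  regime <- if (marginal) {
    NA_character_
  } else if (blurred) {
    "blurred_single_type"
  } else if (all(re > tol)) {
    "coexistent_growth"
  } else if (all(re < -tol)) {
    "coexistent_extinction"
  } else {
    "derived_survival"
  }

  structure(list(
    regime = regime,
    blurred = blurred,
    marginal = marginal,
    survivability = surv,
    det_T = if (n_states(model) == 2) det(sm$T) else NA_real_,
    eigenvalues = ss$eigenvalues,
    dominance_factor = dominance_factor
  ), class = "regime_report")
}

#' @export
print.regime_report <- function(x, ...) {
  cat("Population regime:", if (is.na(x$regime)) "(marginal, unclassified)" else x$regime, "\n")
  if (x$marginal) cat("  an eigenvalue real part is within tolerance of zero\n")
  cat("  eigenvalues:", paste(format(x$eigenvalues, digits = 6), collapse = ", "), "\n")
  if (!is.na(x$det_T)) cat("  det(T):", format(x$det_T, digits = 6), "\n")
  cat("  per-phenotype survivability:\n")
  print(x$survivability)
  invisible(x)
}
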