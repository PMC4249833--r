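#' Observation set for fitting
#'
#' Observed subpopulation-fraction time courses from one or more culture
#' conditions (typically one per sorted phenotype).  Day-0 rows define the
#' initial composition of each condition and are *not* fitted; rows at
#' positive times are the fit targets.
#'
#' @param data data.frame with columns `condition`, `time_days`, `phenotype`,
#'   `fraction`.  Every (condition, time) block must cover all phenotypes
#'   and sum to 1 within `1e-6`; every condition needs a `time_days == 0`
#'   block (its initial composition) and at least one later block.
#' @param labels optional phenotype ordering; default: order of first
#'   appearance.
#' @return Object of class `observation_set`.
#' @export
observation_set <- function(data, labels = NULL) {
  req <- c("condition", "time_days", "phenotype", "fraction")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    pp_stop_validation("observations lack column(s): ",
                       paste(missing_cols, collapse = ", "))
  }
  if (is.null(labels)) labels <- unique(as.character(data$phenotype))
  if (!setequal(unique(as.character(data$phenotype)), labels)) {
    pp_stop_validation("observation phenotypes do not match the given labels")
  }
  data$condition <- as.character(data$condition)
  data$phenotype <- as.character(data$phenotype)

  conditions <- unique(data$condition)
  parsed <- lapply(conditions, function(cond) {
    d <- data[data$condition == cond, ]
    times <- sort(unique(d$time_days))
    frac <- vapply(times, function(t) {
      block <- d[d$time_days == t, ]
      if (!setequal(block$phenotype, labels) || nrow(block) != length(labels)) {
        pp_stop_validation("condition '", cond, "' at t=", t,
                           ": needs exactly one fraction per phenotype")
      }
      f <- block$fraction[match(labels, block$phenotype)]
      if (any(f < -1e-9) || abs(sum(f) - 1) > 1e-6) {
        pp_stop_validation("condition '", cond, "' at t=", t,
                           ": fractions are off the simplex (sum = ",
                           format(sum(f), digits = 8), ")")
      }
      pmax(f, 0)
    }, numeric(length(labels)))
    if (!(0 %in% times)) {
      pp_stop_validation("condition '", cond,
                         "' has no day-0 block (needed as initial composition)")
    }
    if (all(times == 0)) {
      pp_stop_validation("condition '", cond, "' has no post-baseline timepoint")
    }
    x0 <- frac[, times == 0, drop = TRUE]
    list(x0 = x0 / sum(x0), times = times[times > 0],
         fractions = frac[, times > 0, drop = FALSE])
  })
  names(parsed) <- conditions
  structure(list(labels = labels, conditions = parsed, data = data),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat("Observation set:", length(x$conditions), "conditions,",
      length(x$labels), "phenotypes (", paste(x$labels, collapse = ", "), ")\n")
  for (nm in names(x$conditions)) {
    cat(sprintf("  %s: fitted timepoints %s days\n", nm,
                paste(x$conditions[[nm]]$times, collapse = ", ")))
  }
  invisible(x)
}

#' Fit objective: composition mismatch of a candidate model
#'
#' Simulates each condition from its observed day-0 composition and sums,
#' over conditions and post-baseline timepoints, the squared (or absolute)
#' differences between simulated and observed fraction vectors.  Zero if and
#' only if the model reproduces every observed composition exactly.  Note
#' that a fraction-only objective is invariant under adding a constant to
#' all growth rates (only fold-change data break that degeneracy).
#'
#' @param model a [gt_model()] whose labels match the observations.
#' @param obs an [observation_set()].
#' @param kind `"sse"` (default) or `"l1"`.
#' @return Nonnegative scalar.
#' @export
fit_objective <- function(model, obs, kind = c("sse", "l1")) {
  kind <- match.arg(kind)
  stopifnot(inherits(model, "gt_model"), inherits(obs, "observation_set"))
  if (!identical(model$labels, obs$labels)) {
    pp_stop_validation("model labels and observation labels differ")
  }
  sm <- system_matrix(model)
  acc <- 0
  for (cond in obs$conditions) {
    for (ti in seq_along(cond$times)) {
      N <- propagate_counts(sm$T, cond$x0, cond$times[ti])
      if (sum(N) <= 0) pp_stop_numeric("simulated population vanished during fit")
      d <- N / sum(N) - cond$fractions[, ti]
      acc <- acc + if (kind == "sse") sum(d^2) else sum(abs(d))
    }
  }
  acc
}

#' Grid-scan specification
#'
#' Ranges and fixed values for an exhaustive scan.  Each growth entry is
#' named by phenotype, each transition entry by `"A->B"`; an entry is either
#' a single number (held fixed) or `c(min, max, step)` (scanned).
#' Transitions not mentioned are fixed at 0.
#'
#' @param growth named list/vector: one entry per phenotype.
#' @param transitions named list: directed transition entries.
#' @param feasibility `"coexistent_growth"` (all eigenvalue real parts must
#'   be positive; default), `"coexistent_extinction"` (all negative) or
#'   `"none"`.
#' @param require_survivable additionally require every phenotype's growth
#'   to exceed its conversion outflow (default `FALSE`).
#' @param objective `"sse"` or `"l1"`.
#' @return Object of class `scan_spec`.
#' @examples
#' scan_spec(growth = list(X = 0.7, Y = 0.5),
#'           transitions = list("X->Y" = c(0, 1, 0.1), "Y->X" = c(0, 1, 0.1)))
#' @export
scan_spec <- function(growth, transitions,
                      feasibility = c("coexistent_growth",
                                      "coexistent_extinction", "none"),
                      require_survivable = FALSE,
                      objective = c("sse", "l1")) {
  feasibility <- match.arg(feasibility)
  objective <- match.arg(objective)
  check_entry <- function(v, nm) {
    if (!is.numeric(v) || !(length(v) %in% c(1L, 3L)) || any(!is.finite(v))) {
      pp_stop_validation("scan entry '", nm, "' must be a fixed value or c(min, max, step)")
    }
    if (length(v) == 3L && (v[1] > v[2] || v[3] <= 0)) {
      pp_stop_validation("scan entry '", nm, "' needs min <= max and step > 0")
    }
    v
  }
  growth <- lapply(seq_along(growth), function(i) {
    check_entry(growth[[i]], names(growth)[i])
  }) |> setNames(names(growth))
  transitions <- lapply(seq_along(transitions), function(i) {
    check_entry(transitions[[i]], names(transitions)[i])
  }) |> setNames(names(transitions))
  structure(list(growth = growth, transitions = transitions,
                 feasibility = feasibility,
                 require_survivable = require_survivable,
                 objective = objective),
            class = "scan_spec")
}

grid_values <- function(entry) {
  if (length(entry) == 1L) return(entry)
  seq(entry[1], entry[2], by = entry[3])
}

#' Feasibility of a candidate model
#'
#' Coexistence (or co-extinction) of all phenotypes requires all eigenvalue
#' real parts of the system matrix to share one sign; optionally every
#' phenotype must also be independently survivable (growth exceeding
#' conversion outflow).  Used by [grid_scan()] to discard structurally
#' implausible candidates before comparing objectives.
#'
#' @param model a [gt_model()].
#' @param criteria list with `sign` in `"positive"`/`"negative"`/`"any"` and
#'   logical `survivable`.
#' @return `TRUE`/`FALSE`.
#' @export
feasibility_filter <- function(model,
                               criteria = list(sign = "positive",
                                               survivable = FALSE)) {
  stopifnot(inherits(model, "gt_model"))
  re <- Re(spectral_summary(model)$eigenvalues)
  ok <- switch(criteria$sign %||% "positive",
               positive = all(re > 0),
               negative = all(re < 0),
               any = TRUE,
               pp_stop_validation("unknown feasibility sign criterion"))
  if (ok && isTRUE(criteria$survivable)) {
    ok <- all(survivability(model)$independent)
  }
  ok
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exhaustive grid-search fit
#'
#' Evaluates [fit_objective()] on the full Cartesian grid defined by a
#' [scan_spec()], after discarding candidates failing the feasibility
#' criteria.  The result is deterministic and independent of `jobs`:
#' evaluation follows lexicographic order of the free-parameter tuple
#' (growth parameters in label order, then transitions in from/to label
#' order) and ties keep the lexicographically smallest tuple.
#'
#' @param spec a [scan_spec()].
#' @param obs an [observation_set()]; its labels define the phenotypes.
#' @param shortlist how many top candidates to return (default 10).
#' @param jobs number of worker processes (forked); must not and does not
#'   affect the result, only wall time.
#' @param quiet suppress the grid-size message.
#' @return Object of class `fit_result`: `best_model`, `best_params` (named
#'   vector of the free parameters), `objective`, `shortlist` (data.frame of
#'   top parameter tuples and objectives), `diagnostics` (eigenvalues and
#'   survivability of the best model, feasibility failure counts), `n_grid`,
#'   `n_feasible`.
#' @export
grid_scan <- function(spec, obs, shortlist = 10, jobs = 1, quiet = FALSE) {
  stopifnot(inherits(spec, "scan_spec"), inherits(obs, "observation_set"))
  labels <- obs$labels
  m <- length(labels)
  if (!setequal(names(spec$growth), labels)) {
    pp_stop_validation("scan spec growth entries must name every observed phenotype")
  }

  # canonical parameter order: growth by label order, then transitions by
  # (from, to) label order -- this order defines the tie-break
  base_g <- numeric(m)
  base_k <- matrix(0, m, m)
  free <- list()
  for (i in seq_len(m)) {
    e <- grid_values(spec$growth[[labels[i]]])
    if (length(e) == 1L) base_g[i] <- e
    else free[[length(free) + 1L]] <- list(type = 0L, i = i, j = 0L,
                                           values = e, name = paste0("g_", labels[i]))
  }
  tr_names <- names(spec$transitions)
  tr_pairs <- lapply(tr_names, parse_transition_key, labels = labels)
  ord <- order(match(vapply(tr_pairs, `[`, "", 1L), labels),
               match(vapply(tr_pairs, `[`, "", 2L), labels))
  for (t_idx in ord) {
    pair <- tr_pairs[[t_idx]]
    i <- match(pair[1L], labels); j <- match(pair[2L], labels)
    e <- grid_values(spec$transitions[[tr_names[t_idx]]])
    if (length(e) == 1L) base_k[i, j] <- e
    else free[[length(free) + 1L]] <- list(type = 1L, i = i, j = j, values = e,
                                           name = paste0("k_", pair[1L], "->", pair[2L]))
  }
  if (!length(free)) pp_stop_validation("scan spec fixes every parameter; nothing to scan")

  n_grid <- prod(vapply(free, function(f) length(f$values), 0))
  if (!quiet) {
    message("grid scan: ", length(free), " free parameter(s), ",
            format(n_grid, big.mark = ","), " grid points")
  }

  feas_sign <- switch(spec$feasibility,
                      coexistent_growth = 1L, coexistent_extinction = -1L, none = 0L)
  x0 <- vapply(obs$conditions, function(cond) cond$x0, numeric(m))
  obs_times <- lapply(obs$conditions, function(cond) cond$times)
  obs_frac <- lapply(obs$conditions, function(cond) cond$fractions)
  obj_kind <- if (spec$objective == "sse") 0L else 1L

  run_chunk <- function(v1) {
    grids <- lapply(free, `[[`, "values")
    grids[[1L]] <- v1
    .scan_core(base_g, base_k,
               vapply(free, `[[`, 0L, "type"),
               vapply(free, function(f) f$i - 1L, 0L),
               vapply(free, function(f) max(f$j - 1L, 0L), 0L),
               grids, x0, obs_times, obs_frac,
               feas_sign, isTRUE(spec$require_survivable), obj_kind,
               as.integer(shortlist))
  }

  v1 <- free[[1L]]$values
  if (jobs > 1 && length(v1) > 1 && .Platform$OS.type == "unix") {
    chunks <- split(v1, cut(seq_along(v1), min(jobs, length(v1)), labels = FALSE))
    results <- parallel::mclapply(chunks, run_chunk, mc.cores = jobs)
    offsets <- c(0, cumsum(vapply(chunks, length, 0L)))[seq_along(chunks)]
  } else {
    results <- list(run_chunk(v1))
    offsets <- 0L
  }

  # deterministic merge: strict improvement only, so the earliest chunk
  # (smallest first-parameter values) wins ties
  best_val <- Inf
  best_idx <- NULL
  sl_idx <- NULL
  sl_val <- numeric()
  n_feasible <- 0; n_sign_fail <- 0; n_surv_fail <- 0
  for (ci in seq_along(results)) {
    res <- results[[ci]]
    n_feasible <- n_feasible + res$n_feasible
    n_sign_fail <- n_sign_fail + res$n_sign_fail
    n_surv_fail <- n_surv_fail + res$n_surv_fail
    if (is.finite(res$best_value) && res$best_value < best_val) {
      best_val <- res$best_value
      best_idx <- res$best_idx
      best_idx[1L] <- best_idx[1L] + offsets[ci]
    }
    if (nrow(res$shortlist_idx)) {
      adj <- res$shortlist_idx
      adj[, 1L] <- adj[, 1L] + offsets[ci]
      sl_idx <- rbind(sl_idx, adj)
      sl_val <- c(sl_val, res$shortlist_value)
    }
  }
  if (n_feasible == 0 || is.null(best_idx)) {
    pp_stop_numeric("no feasible grid point: ", n_sign_fail,
                    " failed the eigenvalue-sign criterion, ", n_surv_fail,
                    " the survivability criterion")
  }
  if (is.null(sl_idx)) sl_idx <- matrix(0L, 0L, length(free))
  keep <- order(sl_val)[seq_len(min(shortlist, length(sl_val)))]
  sl_idx <- sl_idx[keep, , drop = FALSE]
  sl_val <- sl_val[keep]

  idx_to_params <- function(idx) {
    vapply(seq_along(free), function(p) free[[p]]$values[idx[p]], 0)
  }
  par_names <- vapply(free, `[[`, "", "name")
  best_params <- setNames(idx_to_params(best_idx), par_names)
  best_model <- params_to_model(labels, base_g, base_k, free, best_idx)

  sl_df <- if (nrow(sl_idx)) {
    as.data.frame(t(apply(sl_idx, 1L, idx_to_params)))
  } else {
    as.data.frame(matrix(numeric(), 0L, length(free)))
  }
  names(sl_df) <- par_names
  sl_df$objective <- sl_val

  structure(list(
    best_model = best_model,
    best_params = best_params,
    objective = best_val,
    shortlist = sl_df,
    diagnostics = list(
      eigenvalues = spectral_summary(best_model)$eigenvalues,
      survivability = survivability(best_model),
      n_sign_fail = n_sign_fail,
      n_surv_fail = n_surv_fail
    ),
    n_grid = n_grid,
    n_feasible = n_feasible
  ), class = "fit_result")
}

params_to_model <- function(labels, base_g, base_k, free, idx) {
  g <- base_g
  k <- base_k
  for (p in seq_along(free)) {
    v <- free[[p]]$values[idx[p]]
    if (free[[p]]$type == 0L) g[free[[p]]$i] <- v
    else k[free[[p]]$i, free[[p]]$j] <- v
  }
  nz <- which(k > 0, arr.ind = TRUE)
  tr <- if (nrow(nz)) {
    setNames(k[nz], paste0(labels[nz[, 1L]], "->", labels[nz[, 2L]]))
  } else {
    numeric()
  }
  gt_model(labels, setNames(g, labels), tr)
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Grid-scan fit over", format(x$n_grid, big.mark = ","), "candidates (",
      format(x$n_feasible, big.mark = ","), "feasible )\n")
  cat("  best objective:", format(x$objective, digits = 6), "\n")
  cat("  best parameters:\n")
  print(round(x$best_params, 6))
  cat("  eigenvalues of best model:",
      paste(format(x$diagnostics$eigenvalues, digits = 5), collapse = ", "), "\n")
  invisible(x)
}
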