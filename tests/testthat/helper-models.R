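# Random model generators used across the suite.  All draws are local to a
# caller-provided seed so tests are reproducible and order-independent.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# irreducible m-state model: every directed rate strictly positive
random_model <- function(m, g_range = c(-0.5, 1), k_range = c(0.01, 0.5)) {
  labels <- LETTERS[seq_len(m)]
  g <- stats::runif(m, g_range[1], g_range[2])
  pairs <- expand.grid(from = labels, to = labels, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  tr <- stats::runif(nrow(pairs), k_range[1], k_range[2])
  names(tr) <- paste0(pairs$from, "->", pairs$to)
  gt_model(labels, stats::setNames(g, labels), tr)
}

random_two_state <- function(g_range = c(-0.5, 1), k_range = c(0.01, 1)) {
  two_state_params(stats::runif(1, g_range[1], g_range[2]),
                   stats::runif(1, g_range[1], g_range[2]),
                   stats::runif(1, k_range[1], k_range[2]),
                   stats::runif(1, k_range[1], k_range[2]))
}

# independent trajectory oracle: adaptive stiff integration of dN/dt = T N
integrate_counts_oracle <- function(T, N0, times, rtol = 1e-11) {
  out <- deSolve::lsoda(y = N0, times = times,
                        func = function(t, y, p) list(T %*% y),
                        rtol = rtol, atol = 1e-13)
  unname(as.matrix(out[, -1, drop = FALSE]))
}

# ground-truth model used by the fit/synthetic tests: all rates on the 0.1 grid,
# all eigenvalues positive (coexistent growth)
grid_truth_model <- function() {
  gt_model(c("A", "B", "C"),
           c(A = 0.8, B = 0.9, C = 0.9),
           c("A->B" = 0.2, "A->C" = 0.1, "B->A" = 0.1,
             "B->C" = 0.2, "C->A" = 0.3, "C->B" = 0.2))
}

grid_truth_spec <- function(step = 0.1) {
  scan_spec(
    growth = list(A = 0.8, B = 0.9, C = 0.9),
    transitions = list("A->B" = c(0, 1, step), "A->C" = c(0, 1, step),
                       "B->A" = c(0, 1, step), "B->C" = c(0, 1, step),
                       "C->A" = c(0, 1, step), "C->B" = c(0, 1, step))
  )
}
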