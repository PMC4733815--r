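# Shared helpers for the test suite.

# Vectorized mean-field right-hand side on grids, independent of
# wc_rhs's internals; used as the brute-force fixed-point oracle.
grid_rhs <- function(p, E, I) {
  sE <- p$w_EE * E - p$w_EI * I + p$h_E
  sI <- p$w_IE * E - p$w_II * I + p$h_I
  list(dE = (-E + (1 - p$r * E) * eval_rate(p$f_E, sE)) / p$tau,
       dI = (-I + (1 - p$r * I) * eval_rate(p$f_I, sI)) / p$tau)
}

# Count sign-change cells of the two nullcline fields on an n x n grid:
# cells where both dE and dI change sign contain a fixed point of the
# continuous system (up to grid resolution).
brute_force_fixed_points <- function(p, n = 1000) {
  g <- seq(0, 1, length.out = n)
  E <- matrix(g, n, n)                 # rows: E, cols: I
  I <- matrix(g, n, n, byrow = TRUE)
  d <- grid_rhs(p, E, I)
  sE <- d$dE >= 0         # >= so fixed points on grid lines register
  sI <- d$dI >= 0
  cell_change <- function(s) {
    (s[-n, -n] != s[-1, -n]) | (s[-n, -n] != s[-n, -1]) |
      (s[-n, -n] != s[-1, -1])
  }
  hits <- which(cell_change(sE) & cell_change(sI), arr.ind = TRUE)
  if (!nrow(hits)) return(matrix(numeric(0), 0, 2))
  pts <- cbind(g[hits[, 1]], g[hits[, 2]])
  # cluster contiguous hit cells into distinct fixed-point locations
  keep <- list()
  for (k in seq_len(nrow(pts))) {
    if (!length(keep) ||
        min(vapply(keep, function(q) max(abs(q - pts[k, ])),
                   numeric(1))) > 5 / n) {
      keep[[length(keep) + 1L]] <- pts[k, ]
    }
  }
  do.call(rbind, keep)
}

# deterministic RNG scope
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  force(code)
}
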