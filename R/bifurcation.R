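#' Test a 2x2 matrix for Bogdanov-Takens degeneracy
#'
#' A Bogdanov-Takens point carries a double zero eigenvalue, i.e. both
#' the trace and the determinant of the Jacobian vanish.
#'
#' @param m A 2x2 real matrix.
#' @param tol Tolerance on |trace| and |det|.
#' @return TRUE if both degeneracy conditions hold within \code{tol}.
#' @examples
#' bt_degenerate(matrix(c(0, 0, 1, 0), 2, 2))   # normal-form signature
#' @export
bt_degenerate <- function(m, tol = 1e-6) {
  stopifnot(is.matrix(m), all(dim(m) == c(2, 2)))
  tr <- m[1, 1] + m[2, 2]
  dt <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  abs(tr) < tol && abs(dt) < tol
}

#' Default (a, b) -> weights family for bifurcation scans
#'
#' Maps the control parameters \eqn{a = w_{EE} w_{II}} and \eqn{b =
#' w_{IE} w_{EI}} back to a full weight set by the symmetric square-root
#' convention \eqn{w_{EE} = w_{II} = \sqrt a}, \eqn{w_{IE} = w_{EI} =
#' \sqrt b}; the inverse map is not unique, so scans accept any
#' user-supplied family.
#'
#' @param base A [wc_params()] object providing tau, r, inputs and rate
#'   functions.
#' @return A function \code{(a, b) -> wc_params}.
#' @export
sqrt_weight_family <- function(base = wc_params()) {
  stopifnot(inherits(base, "wc_params"))
  function(a, b) {
    stopifnot(a >= 0, b >= 0)
    p <- base
    p$w_EE <- sqrt(a); p$w_II <- sqrt(a)
    p$w_IE <- sqrt(b); p$w_EI <- sqrt(b)
    p
  }
}

#' Scan the (a, b) control plane for bifurcations
#'
#' For every grid cell the fixed points of the parametrized family are
#' located and, for the fixed point continued from the neighboring cell,
#' saddle-node (SN) crossings are flagged where the Jacobian determinant
#' changes sign, Andronov-Hopf (AH) crossings where the trace changes
#' sign while the eigenvalues are complex (negative discriminant, det >
#' 0), and Bogdanov-Takens (BT) cells where both degeneracies hold
#' within tolerance.
#'
#' @param family A function \code{(a, b) -> wc_params}, e.g.
#'   [sqrt_weight_family()].
#' @param a_range,b_range Numeric ranges \code{c(lo, hi)}.
#' @param n_a,n_b Grid resolution.
#' @param n_starts Multi-start resolution for the per-cell fixed-point
#'   search.
#' @param degeneracy_tol Tolerance for per-cell BT flags on |trace| and
#'   |det| (1/ms and 1/ms^2).
#' @return Object of class \code{"bifurcation_scan"}: a data.frame with
#'   one row per (cell, fixed point) holding location, trace, det,
#'   discriminant, classification and logical flags \code{SN}, \code{AH},
#'   \code{BT}.
#' @export
scan_bifurcations <- function(family, a_range, b_range,
                              n_a = 11, n_b = 11, n_starts = 8,
                              degeneracy_tol = 1e-3) {
  stopifnot(is.function(family))
  a_grid <- seq(a_range[[1]], a_range[[2]], length.out = n_a)
  b_grid <- seq(b_range[[1]], b_range[[2]], length.out = n_b)
  rows <- list()
  prev_col <- vector("list", n_b)
  for (ia in seq_along(a_grid)) {
    for (ib in seq_along(b_grid)) {
      p <- family(a_grid[[ia]], b_grid[[ib]])
      fps <- tryCatch(wc_fixed_points(p, n_starts = n_starts),
                      error = function(e) list())
      cell <- lapply(fps, function(fp) {
        J <- fp$jacobian
        tr <- J[1, 1] + J[2, 2]
        dt <- det(J)
        list(loc = fp$location, tr = tr, det = dt,
             disc = tr^2 - 4 * dt, class = fp$classification)
      })
      # continuation against the same cell index in the previous a-column
      neigh <- prev_col[[ib]]
      # a change in the number of fixed points between neighboring
      # cells is a fold (saddle-node) crossing even when no tracked
      # point's determinant changes sign
      count_changed <- !is.null(neigh) && length(neigh) != length(cell)
      for (fp in cell) {
        SN <- count_changed; AH <- FALSE
        if (!is.null(neigh) && length(neigh)) {
          d <- vapply(neigh, function(q) max(abs(q$loc - fp$loc)),
                      numeric(1))
          q <- neigh[[which.min(d)]]
          if (min(d) < 0.25) {
            SN <- SN || sign(q$det) != sign(fp$det)
            AH <- sign(q$tr) != sign(fp$tr) &&
              fp$disc < 0 && fp$det > 0
          }
        }
        BT <- abs(fp$tr) < degeneracy_tol &&
          abs(fp$det) < degeneracy_tol
        rows[[length(rows) + 1L]] <- data.frame(
          a = a_grid[[ia]], b = b_grid[[ib]],
          E = fp$loc[["E"]], I = fp$loc[["I"]],
          trace = fp$tr, det = fp$det, disc = fp$disc,
          classification = fp$class,
          SN = SN, AH = AH, BT = BT,
          stringsAsFactors = FALSE)
      }
      prev_col[[ib]] <- cell
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("bifurcation_scan", class(out))
  out
}
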