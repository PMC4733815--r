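#' Right-hand side of the mean-field Wilson-Cowan equations
#'
#' @param state Numeric vector \code{c(E, I)}, active fractions in [0, 1].
#' @param p A [wc_params()] object.
#' @return Numeric vector \code{c(dE, dI)} in 1/ms.
#' @export
wc_rhs <- function(state, p) {
  stopifnot(inherits(p, "wc_params"), length(state) >= 2L)
  E <- state[[1]]; I <- state[[2]]
  sE <- p$w_EE * E - p$w_EI * I + p$h_E
  sI <- p$w_IE * E - p$w_II * I + p$h_I
  c(E = (-E + (1 - p$r * E) * eval_rate(p$f_E, sE)) / p$tau,
    I = (-I + (1 - p$r * I) * eval_rate(p$f_I, sI)) / p$tau)
}

#' Integrate the mean-field equations (fixed-step RK4)
#'
#' Deterministic classical Runge-Kutta integration at a fixed step; a
#' fixed step is preferred over adaptive control so that trajectories are
#' exactly reproducible.  States are checked to remain in
#' \eqn{[-\epsilon, 1+\epsilon]}.
#'
#' @param p A [wc_params()] object.
#' @param init Initial state \code{c(E, I)}.
#' @param T Total time, ms.
#' @param dt Step, ms; default \code{0.01 * tau}.
#' @param bound_eps Tolerated excursion outside [0, 1] before erroring.
#' @return A data.frame with columns \code{t}, \code{E}, \code{I}.
#' @export
wc_integrate <- function(p, init, T, dt = 0.01 * p$tau, bound_eps = 1e-6) {
  stopifnot(inherits(p, "wc_params"), T > 0, dt > 0)
  deriv <- function(t, y, parms) list(wc_rhs(y, p))
  times <- seq(0, T, by = dt)
  out <- deSolve::ode(y = c(E = init[[1]], I = init[[2]]), times = times,
                      func = deriv, parms = NULL, method = "rk4")
  out <- as.data.frame(out)
  names(out) <- c("t", "E", "I")
  bad <- !is.finite(out$E) | !is.finite(out$I)
  if (any(bad)) {
    stop("non-finite state at t = ", out$t[which(bad)[1]], " ms")
  }
  oob <- out$E < -bound_eps | out$E > 1 + bound_eps |
    out$I < -bound_eps | out$I > 1 + bound_eps
  if (any(oob)) {
    stop("state left [0,1] at t = ", out$t[which(oob)[1]], " ms")
  }
  out
}

#' Analytic Jacobian of the mean-field equations
#'
#' Closed-form partial derivatives of [wc_rhs()], including the
#' \eqn{-r f[\cdot]} contribution from the refractory factor
#' \eqn{(1 - rE)}.
#'
#' @param p A [wc_params()] object.
#' @param point Numeric \code{c(E, I)}.
#' @return A 2x2 matrix in 1/ms.
#' @export
wc_jacobian <- function(p, point) {
  stopifnot(inherits(p, "wc_params"))
  E <- point[[1]]; I <- point[[2]]
  sE <- p$w_EE * E - p$w_EI * I + p$h_E
  sI <- p$w_IE * E - p$w_II * I + p$h_I
  fE <- eval_rate(p$f_E, sE); dfE <- eval_rate_deriv(p$f_E, sE)
  fI <- eval_rate(p$f_I, sI); dfI <- eval_rate_deriv(p$f_I, sI)
  m <- matrix(0, 2, 2, dimnames = list(c("E", "I"), c("E", "I")))
  m[1, 1] <- (-1 - p$r * fE + (1 - p$r * E) * dfE * p$w_EE) / p$tau
  m[1, 2] <- (-(1 - p$r * E) * dfE * p$w_EI) / p$tau
  m[2, 1] <- ((1 - p$r * I) * dfI * p$w_IE) / p$tau
  m[2, 2] <- (-1 - p$r * fI - (1 - p$r * I) * dfI * p$w_II) / p$tau
  m
}

#' Nullclines of the mean-field equations
#'
#' For each grid value of one population the other population's
#' stationarity condition is solved by a bracketed scalar root search on
#' [0, 1].  Grid points where no root exists in [0, 1] are omitted.
#'
#' @param p A [wc_params()] object.
#' @param grid Numeric vector of grid values for the swept variable.
#' @return List with data.frames \code{E_nullcline} (columns E, I solving
#'   dE/dt = 0 at each E) and \code{I_nullcline} (dI/dt = 0 at each I).
#' @export
wc_nullclines <- function(p, grid = seq(0, 1, length.out = 201)) {
  stopifnot(inherits(p, "wc_params"))
  solve_curve <- function(which_eq) {
    pts <- lapply(grid, function(v) {
      g <- if (which_eq == "E") {
        function(other) wc_rhs(c(v, other), p)[[1]]
      } else {
        function(other) wc_rhs(c(other, v), p)[[2]]
      }
      lo <- g(0); hi <- g(1)
      if (!is.finite(lo) || !is.finite(hi) || sign(lo) == sign(hi)) {
        return(NULL)
      }
      root <- stats::uniroot(g, c(0, 1), tol = 1e-12)$root
      if (which_eq == "E") c(E = v, I = root) else c(E = root, I = v)
    })
    do.call(rbind.data.frame, c(Filter(Negate(is.null), pts),
                                stringsAsFactors = FALSE))
  }
  en <- solve_curve("E"); inl <- solve_curve("I")
  if (nrow(en)) names(en) <- c("E", "I")
  if (nrow(inl)) names(inl) <- c("E", "I")
  list(E_nullcline = en, I_nullcline = inl)
}

#' Classify a fixed point from its Jacobian eigenvalues
#'
#' @param eig Complex eigenvalue pair.
#' @param tol Nonhyperbolicity tolerance on |Re(lambda)|, 1/ms.
#' @return One of "stable_node", "stable_focus", "unstable_node",
#'   "unstable_focus", "saddle", "nonhyperbolic".
#' @export
classify_eigenvalues <- function(eig, tol = 1e-6) {
  re <- Re(eig); im <- Im(eig)
  if (any(abs(re) < tol)) return("nonhyperbolic")
  complex_pair <- any(abs(im) > tol)
  if (all(re < 0)) {
    if (complex_pair) "stable_focus" else "stable_node"
  } else if (all(re > 0)) {
    if (complex_pair) "unstable_focus" else "unstable_node"
  } else {
    "saddle"
  }
}

#' Find the fixed points of the mean-field equations
#'
#' Damped-Newton iterations (analytic Jacobian) launched from a dense grid
#' of starting points over the unit square, deduplicated by distance, and
#' classified by Jacobian eigenvalues.
#'
#' @param p A [wc_params()] object.
#' @param n_starts Grid resolution per axis for the multi-start search.
#' @param dedup_tol State-space deduplication tolerance.
#' @param class_tol Eigenvalue-zero tolerance, in units of 1/tau.
#' @return A list of fixed points, each a list with \code{location} (c(E, I)),
#'   \code{jacobian}, \code{eigenvalues} and \code{classification};
#'   class \code{"wc_fixed_points"}.
#' @export
wc_fixed_points <- function(p, n_starts = 15, dedup_tol = 1e-6,
                            class_tol = 1e-6 / p$tau) {
  stopifnot(inherits(p, "wc_params"))
  starts <- as.matrix(expand.grid(
    E = seq(0, 1, length.out = n_starts),
    I = seq(0, 1, length.out = n_starts)))
  roots <- list()
  for (k in seq_len(nrow(starts))) {
    x <- starts[k, ]
    ok <- FALSE
    for (it in 1:60) {
      fx <- wc_rhs(x, p)
      if (!all(is.finite(fx))) break
      if (max(abs(fx)) < 1e-12) { ok <- TRUE; break }
      J <- wc_jacobian(p, x)
      step <- tryCatch(solve(J, fx), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) break
      # damp steps so iterates stay near the unit square
      sc <- min(1, 0.25 / max(abs(step)))
      x_new <- pmin(1.2, pmax(-0.2, x - sc * step))
      if (max(abs(x_new - x)) < 1e-14 && max(abs(fx)) < 1e-10) {
        x <- x_new; ok <- TRUE; break
      }
      x <- x_new
    }
    if (ok && all(x > -1e-9) && all(x < 1 + 1e-9) &&
        max(abs(wc_rhs(x, p))) < 1e-10) {
      roots[[length(roots) + 1L]] <- pmin(1, pmax(0, x))
    }
  }
  if (!length(roots)) {
    stop("no fixed point found; increase n_starts")
  }
  uniq <- list()
  for (r in roots) {
    if (!length(uniq) ||
        min(vapply(uniq, function(u) max(abs(u - r)), numeric(1))) >
          dedup_tol) {
      uniq[[length(uniq) + 1L]] <- r
    }
  }
  uniq <- uniq[order(vapply(uniq, `[[`, numeric(1), 1L),
                     vapply(uniq, `[[`, numeric(1), 2L))]
  fps <- lapply(uniq, function(loc) {
    J <- wc_jacobian(p, loc)
    eig <- eigen(J, only.values = TRUE)$values
    list(location = c(E = unname(loc[[1]]), I = unname(loc[[2]])),
         jacobian = J, eigenvalues = eig,
         classification = classify_eigenvalues(eig, class_tol))
  })
  structure(fps, class = "wc_fixed_points")
}

#' @export
print.wc_fixed_points <- function(x, ...) {
  cat("<wc_fixed_points>", length(x), "fixed point(s)\n")
  for (fp in x) {
    cat(sprintf("  (E*=%.6f, I*=%.6f)  %s  Re(lambda)=(%.4g, %.4g)\n",
                fp$location[["E"]], fp$location[["I"]],
                fp$classification,
                Re(fp$eigenvalues)[1], Re(fp$eigenvalues)[2]))
  }
  invisible(x)
}
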