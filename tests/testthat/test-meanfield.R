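test_that("quiescence is a fixed point when f[0] = 0 and inputs vanish", {
  p <- wc_params(tau = 10, r = 1, w_EE = 5, w_EI = 3, w_IE = 4, w_II = 2)
  expect_equal(unname(wc_rhs(c(0, 0), p)), c(0, 0))
})

test_that("uncoupled populations relax exponentially to f[h]", {
  p <- wc_params(tau = 8, r = 0, h_E = 1.5, h_I = 0.5,
                 f_E = firing_rate("logistic_shifted", gain = 1.2,
                                   threshold = 0.3),
                 f_I = firing_rate("logistic_shifted", gain = 0.8,
                                   threshold = 0.1))
  tr <- wc_integrate(p, c(0, 0), T = 60, dt = 0.05)
  target_E <- eval_rate(p$f_E, 1.5)
  target_I <- eval_rate(p$f_I, 0.5)
  expect_equal(tr$E, target_E * (1 - exp(-tr$t / 8)), tolerance = 1e-7)
  expect_equal(tr$I, target_I * (1 - exp(-tr$t / 8)), tolerance = 1e-7)
})

test_that("fixed-step integration has fourth-order convergence", {
  p <- wc_preset("fig10_limit_cycle")
  end <- function(dt) {
    tr <- wc_integrate(p, c(0.25, 0.35), T = 16, dt = dt)
    unlist(tr[nrow(tr), c("E", "I")])
  }
  e1 <- max(abs(end(0.4) - end(0.2)))
  e2 <- max(abs(end(0.2) - end(0.1)))
  expect_gt(e1 / e2, 8)     # ~16 for a 4th-order scheme
  expect_lt(e1 / e2, 40)
})

test_that("a trajectory started at a stable fixed point stays put", {
  p <- wc_preset("fig10_nodes")
  fps <- wc_fixed_points(p)
  stable <- Filter(function(fp) startsWith(fp$classification, "stable"),
                   fps)
  fp <- stable[[length(stable)]]
  tr <- wc_integrate(p, fp$location, T = 100, dt = 0.1)
  expect_lt(max(abs(tr$E - fp$location[["E"]])), 1e-6)
  expect_lt(max(abs(tr$I - fp$location[["I"]])), 1e-6)
})

test_that("multi-node regime: trajectories settle onto point attractors", {
  p <- wc_preset("fig10_nodes")
  fps <- wc_fixed_points(p)
  stable_locs <- t(vapply(
    Filter(function(fp) startsWith(fp$classification, "stable"), fps),
    function(fp) fp$location, numeric(2)))
  expect_gte(nrow(stable_locs), 2)
  with_seed(21, {
    for (k in 1:5) {
      tr <- wc_integrate(p, runif(2), T = 400, dt = 0.1)
      late <- tr[tr$t > 350, ]
      # no sustained oscillation ...
      expect_lt(diff(range(late$E)), 1e-4)
      # ... and the endpoint is one of the computed stable nodes
      d <- sqrt((stable_locs[, 1] - late$E[nrow(late)])^2 +
                  (stable_locs[, 2] - late$I[nrow(late)])^2)
      expect_lt(min(d), 1e-3)
    }
  })
})

test_that("limit-cycle regime: long-time trajectory is periodic, not constant", {
  p <- wc_preset("fig10_limit_cycle")
  tr <- wc_integrate(p, c(0.3, 0.3), T = 800, dt = 0.1)
  late <- tr[tr$t > 500, ]
  expect_gt(diff(range(late$E)), 0.05)         # sustained oscillation
  # oscillation does not decay: amplitude similar in two late windows
  a1 <- diff(range(late$E[late$t < 650]))
  a2 <- diff(range(late$E[late$t >= 650]))
  expect_equal(a1, a2, tolerance = 0.05)
  # the unique interior fixed point is unstable (focus)
  fps <- wc_fixed_points(p)
  expect_true(any(vapply(fps, function(f)
    f$classification == "unstable_focus", logical(1))))
})

test_that("nullcline points satisfy their stationarity condition", {
  p <- wc_preset("fig10_nodes")
  nc <- wc_nullclines(p, grid = seq(0, 1, length.out = 101))
  for (k in seq_len(nrow(nc$E_nullcline))) {
    expect_lt(abs(wc_rhs(unlist(nc$E_nullcline[k, ]), p)[[1]]), 1e-8)
  }
  for (k in seq_len(nrow(nc$I_nullcline))) {
    expect_lt(abs(wc_rhs(unlist(nc$I_nullcline[k, ]), p)[[2]]), 1e-8)
  }
})

test_that("nullcline intersections coincide with the fixed points", {
  p <- wc_preset("fig10_nodes")
  grid <- seq(0, 1, length.out = 401)
  nc <- wc_nullclines(p, grid = grid)
  fps <- wc_fixed_points(p)
  for (fp in fps) {
    dE <- sqrt((nc$E_nullcline$E - fp$location[["E"]])^2 +
                 (nc$E_nullcline$I - fp$location[["I"]])^2)
    dI <- sqrt((nc$I_nullcline$E - fp$location[["E"]])^2 +
                 (nc$I_nullcline$I - fp$location[["I"]])^2)
    expect_lt(min(dE), 0.01)
    expect_lt(min(dI), 0.01)
  }
})

test_that("symmetric parameters put the diagonal point on both nullclines", {
  sym <- wc_preset("benayoun_low")
  S0 <- symmetric_fixed_point(sym)
  d <- symmetric_rhs(c(S0, S0), sym)
  expect_equal(unname(d), c(0, 0), tolerance = 1e-12)
})

test_that("analytic Jacobian matches central finite differences", {
  p <- wc_preset("fig10_limit_cycle")
  h <- 1e-6
  with_seed(31, {
    for (k in 1:6) {
      x <- runif(2)
      J <- wc_jacobian(p, x)
      for (j in 1:2) {
        xp <- x; xm <- x
        xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
        fd <- (wc_rhs(xp, p) - wc_rhs(xm, p)) / (2 * h)
        expect_equal(unname(J[, j]), unname(fd), tolerance = 1e-5)
      }
    }
  })
})

test_that("zero-weight Jacobian is diagonal -1/tau when r = 0", {
  p <- wc_params(tau = 7, r = 0)
  J <- wc_jacobian(p, c(0.4, 0.6))
  expect_equal(unname(J), diag(c(-1 / 7, -1 / 7)), tolerance = 1e-12)
})

test_that("fixed-point census matches a brute-force grid scan", {
  p <- wc_preset("fig10_nodes")
  fps <- wc_fixed_points(p)
  brute <- brute_force_fixed_points(p, n = 1000)
  expect_equal(length(fps), nrow(brute))
  for (fp in fps) {
    d <- sqrt((brute[, 1] - fp$location[["E"]])^2 +
                (brute[, 2] - fp$location[["I"]])^2)
    expect_lt(min(d), 5e-3)
  }
})

test_that("classification agrees with an independent eigenvalue computation", {
  for (nm in c("fig10_nodes", "fig10_limit_cycle")) {
    p <- wc_preset(nm)
    for (fp in wc_fixed_points(p)) {
      ev <- eigen(wc_jacobian(p, fp$location), only.values = TRUE)$values
      expect_equal(sort(Re(ev)), sort(Re(fp$eigenvalues)),
                   tolerance = 1e-9)
      expect_identical(fp$classification, classify_eigenvalues(ev))
    }
  }
})

test_that("symmetric preset has a unique stable diagonal fixed point", {
  sym <- wc_preset("benayoun_low")
  p <- as_wc_params(sym)
  # structural expansion is exact
  expect_identical(p$w_EE, sym$w_E)
  expect_identical(p$w_IE, sym$w_E)
  expect_identical(p$w_EI, sym$w_I)
  expect_identical(p$w_II, sym$w_I)
  S0 <- symmetric_fixed_point(sym)
  ev <- eigen(symmetric_jacobian(sym, c(S0, S0)),
              only.values = TRUE)$values
  expect_true(all(Re(ev) < 0))
  # unique in [0,1]: the scalar stationarity condition crosses once
  g <- function(S) -sym$alpha * S +
    (1 - S) * eval_rate(sym$f, sym$w_0 * S + sym$h)
  S <- seq(0, 1, length.out = 2001)
  expect_equal(sum(diff(sign(g(S))) != 0), 1)
})
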