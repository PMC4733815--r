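make_lat <- function(n = 64, dx = 25, boundary = "periodic") {
  wc_lattice(dim = 1, n = n, dx = dx, boundary = boundary)
}

test_that("discretized kernels reproduce the continuum integrals", {
  k <- wc_kernel(b = 0.7, sigma = 100)
  lat <- make_lat(dx = 10)
  st <- discretize_kernel(k, lat)
  expect_equal(max(st$values), 0.7)                 # beta(0) = b
  expect_equal(sum(st$values) * lat$dx, 2 * 0.7 * 100,
               tolerance = 0.01)                    # 1-D integral 2 b sigma
  # under-resolved lattice is refused
  expect_error(discretize_kernel(k, make_lat(dx = 50)),
               "under-resolve")
})

test_that("2-D radial stencil matches planar quadrature of the kernel", {
  k <- wc_kernel(b = 0.4, sigma = 100)
  lat <- wc_lattice(dim = 2, n = c(24, 24), dx = 25)
  st <- discretize_kernel(k, lat)
  num <- sum(st$values) * lat$dx^2
  # integral of b exp(-r/sigma) over the plane, by radial quadrature
  quad <- stats::integrate(function(r) 2 * pi * r * 0.4 * exp(-r / 100),
                           0, 6 * 100)$value
  expect_equal(num, quad, tolerance = 0.02)
})

test_that("uniform fields reduce the spatial operator to the mean-field one", {
  lat <- make_lat()
  base <- wc_params(tau = 10, r = 0, h_E = 0.1, h_I = 0.05,
                    f_E = firing_rate("logistic_shifted"),
                    f_I = firing_rate("logistic_shifted"))
  sp <- wc_spatial_params(base,
                          beta_EE = kernel_from_weight(3, 100),
                          beta_EI = kernel_from_weight(2, 100),
                          beta_IE = kernel_from_weight(2.5, 100),
                          beta_II = kernel_from_weight(1, 100),
                          lattice = lat)
  E0 <- 0.31; I0 <- 0.12
  d <- spatial_rhs(rep(E0, 64), rep(I0, 64), sp)
  # discrete integrated weights (exact row sums of the coupling)
  wEE <- sum(sp$W_EE[1, ]); wEI <- sum(sp$W_EI[1, ])
  wIE <- sum(sp$W_IE[1, ]); wII <- sum(sp$W_II[1, ])
  pm <- wc_params(tau = 10, r = 0, w_EE = wEE, w_EI = wEI,
                  w_IE = wIE, w_II = wII, h_E = 0.1, h_I = 0.05,
                  f_E = base$f_E, f_I = base$f_I)
  ref <- wc_rhs(c(E0, I0), pm)
  expect_equal(unique(round(d$dE, 14)), round(ref[[1]], 14))
  expect_equal(unique(round(d$dI, 14)), round(ref[[2]], 14))
  # quiescent state with f[0] = 0 and no input stays quiescent
  base0 <- wc_params(tau = 10, r = 0)
  sp0 <- wc_spatial_params(base0,
                           beta_EE = kernel_from_weight(3, 100),
                           beta_EI = kernel_from_weight(2, 100),
                           beta_IE = kernel_from_weight(2.5, 100),
                           beta_II = kernel_from_weight(1, 100),
                           lattice = lat)
  d0 <- spatial_rhs(rep(0, 64), rep(0, 64), sp0)
  expect_true(all(d0$dE == 0) && all(d0$dI == 0))
})

test_that("periodic convolution preserves the spatial mean", {
  lat <- make_lat()
  sp <- wc_spatial_params(wc_params(tau = 10, r = 0),
                          beta_EE = kernel_from_weight(3, 100),
                          beta_EI = kernel_from_weight(2, 100),
                          beta_IE = kernel_from_weight(2.5, 100),
                          beta_II = kernel_from_weight(1, 100),
                          lattice = lat)
  with_seed(51, {
    x <- runif(64)
    conv <- as.numeric(sp$W_EE %*% x)
    expect_equal(mean(conv), sum(sp$W_EE[1, ]) * mean(x),
                 tolerance = 1e-12)
  })
})

test_that("uniform initial data track the homogeneous ODE to high accuracy", {
  lat <- make_lat(n = 64)
  base <- wc_params(tau = 10, r = 0, h_E = 0.2, h_I = 0.2,
                    f_E = firing_rate("logistic_shifted"),
                    f_I = firing_rate("logistic_shifted"))
  sp <- wc_spatial_params(base,
                          beta_EE = kernel_from_weight(3, 100),
                          beta_EI = kernel_from_weight(2, 100),
                          beta_IE = kernel_from_weight(2.5, 100),
                          beta_II = kernel_from_weight(1, 100),
                          lattice = lat)
  h <- simulate_field(sp, NULL, T = 40, dt = 0.1,
                      init = list(E = 0.05, I = 0.05), stride = 10)
  pm <- wc_params(tau = 10, r = 0,
                  w_EE = sum(sp$W_EE[1, ]), w_EI = sum(sp$W_EI[1, ]),
                  w_IE = sum(sp$W_IE[1, ]), w_II = sum(sp$W_II[1, ]),
                  h_E = 0.2, h_I = 0.2, f_E = base$f_E, f_I = base$f_I)
  tr <- wc_integrate(pm, c(0.05, 0.05), T = 40, dt = 0.1)
  ref <- tr$E[match(h$times, tr$t)]
  expect_lt(max(abs(h$E - ref)), 1e-8)
  # and a uniform fixed point stays constant with zero stimulus
  fps <- wc_fixed_points(pm)
  st <- Filter(function(f) startsWith(f$classification, "stable"), fps)
  fp <- st[[1]]$location
  h2 <- simulate_field(sp, NULL, T = 20, dt = 0.1,
                       init = list(E = fp[["E"]], I = fp[["I"]]),
                       stride = 10)
  expect_lt(max(abs(sweep(h2$E, 2, h2$E[1, ]))), 1e-9)
})

test_that("doubling the periodic extent leaves the central response unchanged early", {
  sc <- wc_preset("fig21_weak")
  build <- function(n) {
    lat <- wc_lattice(1, n, 375, "periodic")
    base <- sc$params$base
    sp <- wc_spatial_params(base,
                            beta_EE = sc$params$beta_EE,
                            beta_EI = sc$params$beta_EI,
                            beta_IE = sc$params$beta_IE,
                            beta_II = sc$params$beta_II,
                            lattice = lat)
    stim <- wc_stimulus(center = (n / 2) * 375, halfwidth = 750,
                        amplitude = 0.25, onset = 1, duration = 2,
                        population = "E")
    simulate_field(sp, stim, T = 25, dt = 0.2, stride = 5)
  }
  h1 <- build(64); h2 <- build(128)
  # compare a central window of +/- 16 sites around the stimulus
  w1 <- h1$E[, 32 + (-16:16)]
  w2 <- h2$E[, 64 + (-16:16)]
  # identical until wrap-around contributions (exponentially small in
  # the extent) arrive; response scale here is ~1e-2
  expect_lt(max(abs(w1 - w2)), 1e-5)
})

test_that("weak-stimulus response scales linearly with amplitude", {
  sc <- wc_preset("fig21_weak")
  resp <- function(amp) {
    stim <- sc$stimulus; stim$amplitude <- amp
    h <- simulate_field(sc$params, stim, T = 30, dt = 0.2, stride = 5)
    max(abs(sweep(h$E, 2, h$E[1, ])))
  }
  r1 <- resp(0.01); r2 <- resp(0.02)
  expect_equal(r2 / r1, 2, tolerance = 0.02)
})

test_that("exponential coarse-graining has unit DC gain and one-pole rolloff", {
  expect_equal(coarse_grain(rep(3.7, 100), tau = 5, dt = 0.1),
               rep(3.7, 100))
  dt <- 0.01; tau <- 2
  t <- seq(0, 3000, by = dt)
  atten <- function(f_hz) {
    f <- f_hz / 1000                       # cycles per ms
    x <- sin(2 * pi * f * t)
    y <- coarse_grain(x, tau, dt)
    keep <- t > 100                        # discard filter transient
    # leakage-free amplitude via quadrature regression
    co <- stats::coef(stats::lm(
      y[keep] ~ sin(2 * pi * f * t[keep]) + cos(2 * pi * f * t[keep])))
    unname(sqrt(co[2]^2 + co[3]^2))
  }
  one_pole <- function(f_hz) 1 / sqrt(1 + (2 * pi * f_hz / 1000 * tau)^2)
  expect_equal(atten(100), one_pole(100), tolerance = 0.02)
  expect_equal(atten(1), one_pole(1), tolerance = 0.02)
  # strictly decreasing magnitude response
  a <- vapply(c(1, 5, 20, 50, 100, 200), atten, numeric(1))
  expect_true(all(diff(a) < 0))
})

test_that("wave metrology recovers a planted decaying wave", {
  h <- planted_wave_history(lambda0_mm = 3, v0_mm_ms = 0.3)
  wm <- measure_wave(h, sigma = 1000, rel_floor = 1e-4)
  expect_identical(wm$classification, "propagating")
  expect_equal(wm$speed, 0.3, tolerance = 0.02)
  expect_equal(wm$decay_length, 3, tolerance = 0.02)
  # time reversal: same decay length and |speed|
  hr <- h
  hr$E <- h$E[rev(seq_len(nrow(h$E))), ]
  wr <- measure_wave(hr, origin = h$stimulus$center, sigma = 1000,
                     rel_floor = 1e-4)
  expect_equal(wr$speed, wm$speed, tolerance = 1e-6)
  expect_equal(wr$decay_length, wm$decay_length, tolerance = 1e-6)
})
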