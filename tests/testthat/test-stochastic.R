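test_that("excitatory channel rates match direct arithmetic", {
  sym <- wc_preset("benayoun_high")
  p <- stoch_params_from_symmetric(sym, 800, 800)
  # absorbing state: no events possible without input
  p0 <- stoch_params(N_E = 50, w_EE = 1, h_E = 0)
  expect_equal(unname(rates_excitatory(0, p0)), c(0, 0))
  # full population: no activation channel left
  expect_equal(rates_excitatory(p0$N_E, p0)[["activation"]], 0)
  # hand-computed values at n_E = n_I = 400
  r <- rates_ei(400, 400, p)
  s <- sym$w_E * 0.5 - sym$w_I * 0.5 + sym$h     # = w_0/2 + h
  expect_equal(r[["E_deact"]], 0.1 * 400)
  expect_equal(r[["E_act"]], 400 * tanh(s))
  expect_equal(r[["I_act"]], r[["E_act"]])        # symmetric weights
  # equal fractions imply equal currents even with unequal sizes
  p2 <- stoch_params_from_symmetric(sym, 400, 800)
  r2 <- rates_ei(200, 400, p2)
  expect_equal(r2[["E_act"]] / (p2$N_E - 200),
               r2[["I_act"]] / (p2$N_I - 400))
})

test_that("the all-quiescent state with zero input is absorbing for the SSA", {
  p <- stoch_params(N_E = 30, N_I = 30, w_EE = 2, w_EI = 1,
                    w_IE = 2, w_II = 1, h_E = 0, h_I = 0)
  r <- gillespie(p, T = 10, init = c(0, 0), seed = 5)
  expect_true(r$absorbed)
  expect_identical(nrow(r$events), 0L)
})

test_that("SSA events preserve state bounds and strictly increase in time", {
  sym <- wc_preset("benayoun_low")
  p <- stoch_params_from_symmetric(sym, 60, 60)
  r <- gillespie(p, T = 300, init = c(30, 30), seed = 7,
                 record_ids = TRUE)
  tr <- count_trajectory(r)
  expect_true(all(tr$n_E >= 0 & tr$n_E <= 60))
  expect_true(all(tr$n_I >= 0 & tr$n_I <= 60))
  expect_true(all(diff(r$events$time) > 0))
  # neuron ids stay within the population
  expect_true(all(r$events$neuron_id >= 1 & r$events$neuron_id <= 60))
  # identical seed reproduces the run exactly
  r2 <- gillespie(p, T = 300, init = c(30, 30), seed = 7,
                  record_ids = TRUE)
  expect_identical(r$events, r2$events)
})

test_that("seed-averaged SSA activity matches the rate-equation fixed point", {
  sym <- wc_preset("benayoun_low")
  p <- stoch_params_from_symmetric(sym, 800, 800)
  S0 <- symmetric_fixed_point(sym)
  means <- vapply(1:12, function(s) {
    r <- gillespie(p, T = 400, init = c(round(800 * S0), round(800 * S0)),
                   seed = s)
    occ <- occupancy_histogram(r, burn_in = 100)
    sum(occ * (0:800)) / 800
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  # the stationary mean carries a finite-size correction of order 1/N
  # (the rate nonlinearity rectifies the large balanced fluctuations);
  # allow for it explicitly on top of the sampling error
  expect_lt(abs(mean(means) - S0), 3 * se + 16 / 800)
})

test_that("small-system SSA occupancy matches the master equation (TV < 0.02)", {
  p <- stoch_params(N_E = 20, alpha_E = 0.1, w_EE = 0.4, h_E = 0.1)
  pi_exact <- master_stationary(p)
  r <- gillespie(p, T = 30000, init = c(5, 0), seed = 11)
  occ <- occupancy_histogram(r, burn_in = 200)
  tv <- 0.5 * sum(abs(occ - pi_exact))
  expect_lt(tv, 0.02)
  # long-time master integration agrees with the stationary solution
  P <- integrate_master(p, T = 2000)
  expect_lt(0.5 * sum(abs(P[nrow(P), ] - pi_exact)), 1e-6)
})

test_that("master equation conserves probability and matches pure-death decay", {
  p <- stoch_params(N_E = 30, alpha_E = 0.2, w_EE = 0, h_E = 0)
  # f[0] = 0 with zero input: pure death from n = N, binomial marginals
  P0 <- c(rep(0, 30), 1)
  out <- integrate_master(p, T = 12, P0 = P0, times = c(0, 3, 6, 12))
  expect_true(all(abs(rowSums(out) - 1) < 1e-9))
  for (tt in c(3, 6, 12)) {
    q <- exp(-0.2 * tt)
    expect_equal(unname(out[as.character(tt), ]),
                 stats::dbinom(0:30, 30, q), tolerance = 1e-6)
  }
  # first moment obeys the mean-field equation when f is linearized:
  # with f = 0 the mean is exactly N exp(-alpha t)
  means <- out %*% (0:30)
  expect_equal(as.numeric(means),
               30 * exp(-0.2 * c(0, 3, 6, 12)), tolerance = 1e-6)
})

test_that("system-size convergence: SSA fraction approaches the ODE as N grows", {
  sym <- wc_preset("benayoun_low")
  S0 <- symmetric_fixed_point(sym)
  grid <- seq(20, 200, by = 5)
  deriv <- function(t, y, parms) list(symmetric_rhs(y, sym))
  ode <- deSolve::ode(c(0.25, 0.25), c(0, grid), deriv, NULL,
                      method = "rk4")
  ref <- ode[-1, 2]
  dev_for <- function(N) {
    acc <- 0
    for (s in 1:8) {
      r <- gillespie(stoch_params_from_symmetric(sym, N, N),
                     T = 200, init = c(round(0.25 * N), round(0.25 * N)),
                     seed = 100 + s)
      tr <- count_trajectory(r)
      idx <- findInterval(grid, tr$t)
      acc <- acc + tr$n_E[idx] / N
    }
    max(abs(acc / 8 - ref))
  }
  devs <- vapply(c(100, 400, 1600), dev_for, numeric(1))
  expect_true(all(diff(devs) < 0))
})

test_that("linear-noise trajectories decay without noise and match OU variance", {
  p <- stoch_params(N_E = 200, alpha_E = 0.1, w_EE = 0.4, h_E = 0.1)
  tr0 <- langevin_lna(p, T = 200, dt = 0.05, seed = 1, mode = "single",
                      noise_scale = 0, xi0 = 2)
  expect_lt(abs(tr0$xi[nrow(tr0$xi), 1]), 1e-4)
  expect_true(all(diff(abs(tr0$xi[, 1])) <= 0))
  tr <- langevin_lna(p, T = 120000, dt = 0.05, seed = 2,
                     mode = "single")
  A <- tr$A[1, 1]; D <- tr$noise_sd
  v_theory <- D^2 / (2 * abs(A))
  v_emp <- stats::var(tr$xi[-(1:2000), 1])
  expect_equal(v_emp, v_theory, tolerance = 0.05)
})

test_that("sigma/delta fluctuations are feed-forward: Delta never hears Sigma", {
  sym <- wc_preset("benayoun_high")
  ej <- effective_jacobian(sym)
  # a pure Sigma perturbation leaves Delta at zero forever
  tr <- langevin_lna(sym, T = 50, dt = 0.02, seed = 3,
                     mode = "sigma_delta", noise_scale = 0,
                     xi0 = c(1, 0))
  expect_true(all(tr$xi[, "xi_Delta"] == 0))
  # a pure Delta perturbation decays at exactly lambda_2 while
  # feeding Sigma through w_ff
  tr2 <- langevin_lna(sym, T = 50, dt = 0.02, seed = 3,
                      mode = "sigma_delta", noise_scale = 0,
                      xi0 = c(0, 1e-3))
  expect_equal(tr2$xi[, "xi_Delta"],
               1e-3 * exp(-ej$lambda2 * tr2$times), tolerance = 1e-3)
  expect_gt(max(abs(tr2$xi[, "xi_Sigma"])), 1e-4)
})

test_that("kernel-coupled input current matches a brute-force convolution", {
  lat <- wc_lattice(1, 48, 25, "periodic")
  k <- kernel_from_weight(2, 100)
  W <- wcdyn:::kernel_matrix(k, lat)
  with_seed(61, {
    n <- runif(48)
    cur <- spatial_input_current(n, W, h = 0.05)
    # O(n^2) double loop with explicit wrap-around distances
    st <- discretize_kernel(k, lat)
    brute <- vapply(1:48, function(i) {
      acc <- 0
      for (m in seq_len(nrow(st$offsets))) {
        j <- ((i - 1 + st$offsets[m, 1]) %% 48) + 1
        acc <- acc + st$values[m] * 25 * n[j]
      }
      acc + 0.05
    }, numeric(1))
    expect_equal(cur, brute, tolerance = 1e-10)
    # delta field reproduces the kernel profile; uniform field the
    # mean-field current
    delta <- replace(rep(0, 48), 10, 1)
    prof <- spatial_input_current(delta, W)
    expect_equal(max(prof), max(st$values) * 25, tolerance = 1e-12)
    unif <- spatial_input_current(rep(0.3, 48), W)
    expect_equal(unif, rep(sum(W[1, ]) * 0.3, 48), tolerance = 1e-12)
  })
})

test_that("lattice SSA: uncoupled sites are independent, coupled sites correlate", {
  sym0 <- wc_symmetric(w_0 = 0, w_sum = 0, h = 0.5, alpha = 0.1)
  lat <- wc_lattice(1, 8, 100, "periodic")
  lp0 <- stoch_lattice_params(sym0, lat, N_site = 30, sigma = 400)
  run0 <- gillespie_lattice(lp0, T = 400, seed = 21, sample_dt = 1)
  C0 <- stats::cor(run0$n_E[-(1:50), ])
  off0 <- C0[upper.tri(C0)]
  expect_lt(max(abs(off0)), 0.2)
  expect_lt(abs(mean(off0)), 0.05)
  # strong shared coupling induces strong pair correlation
  sym1 <- wc_symmetric(w_0 = 0.2, w_sum = 6, h = 0.05, alpha = 0.1)
  lp1 <- stoch_lattice_params(sym1, lat, N_site = 30, sigma = 400)
  run1 <- gillespie_lattice(lp1, T = 400, seed = 22, sample_dt = 1)
  A <- run1$n_E + run1$n_I
  C1 <- stats::cor(A[-(1:50), ])
  expect_gt(mean(C1[upper.tri(C1)]), 0.5)
})

test_that("additive-noise field reduces exactly to the deterministic solver", {
  sc <- wc_preset("fig21_weak")
  h0 <- simulate_field(sc$params, sc$stimulus, T = 20, dt = 0.2,
                       stride = 5)
  h1 <- additive_noise_field(sc$params, noise_sd = 0, sc$stimulus,
                             T = 20, dt = 0.2, seed = 9, stride = 5)
  expect_identical(h0$E, h1$E)
  expect_identical(h0$I, h1$I)
})

test_that("additive-noise fluctuations saturate to stationarity", {
  sc <- correlation_scenario("additive")
  h <- additive_noise_field(sc$params, noise_sd = sc$noise_sd,
                            T = 400, dt = 0.1, seed = 13,
                            init = sc$init, stride = 10)
  dev <- sweep(h$E, 2, colMeans(h$E[-(1:100), ]))
  v_early <- mean(dev[h$times > 5 & h$times <= 15, ]^2)
  v_mid <- mean(dev[h$times > 150 & h$times <= 250, ]^2)
  v_late <- mean(dev[h$times > 300, ]^2)
  expect_lt(v_early, v_mid)                # variance still growing early
  expect_equal(v_late / v_mid, 1, tolerance = 0.5)  # then saturated
})
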