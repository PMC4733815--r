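#' Stochastic (master-equation) model parameters
#'
#' Two-state neurons (quiescent/active) in excitatory and inhibitory
#' pools: active neurons deactivate at rate \eqn{\alpha}; each quiescent
#' neuron activates at rate \eqn{f[s]}, where the net input
#' \eqn{s_E = w_{EE} n_E/N_E - w_{EI} n_I/N_I + h_E} (and the I
#' analogue) uses population \emph{fractions}, so the mean-field rate
#' equations are the exact large-N limit.
#'
#' @param N_E,N_I Population sizes (N_I = 0 gives the single-population
#'   model).
#' @param alpha_E,alpha_I Deactivation rates, 1/ms.
#' @param w_EE,w_EI,w_IE,w_II Nonnegative weights.
#' @param h_E,h_I External inputs.
#' @param f_E,f_I [firing_rate()] objects (activation-rate form).
#' @return Object of class \code{"stoch_params"}.
#' @export
stoch_params <- function(N_E, N_I = 0, alpha_E = 0.1, alpha_I = alpha_E,
                         w_EE = 0, w_EI = 0, w_IE = 0, w_II = 0,
                         h_E = 0, h_I = 0,
                         f_E = firing_rate("rectified_saturating",
                                           rate_scale = 1, I_TH = 1),
                         f_I = f_E) {
  stopifnot(N_E >= 0, N_I >= 0, N_E + N_I > 0,
            alpha_E >= 0, alpha_I >= 0,
            w_EE >= 0, w_EI >= 0, w_IE >= 0, w_II >= 0,
            inherits(f_E, "firing_rate"), inherits(f_I, "firing_rate"))
  structure(list(N_E = as.integer(N_E), N_I = as.integer(N_I),
                 alpha_E = alpha_E, alpha_I = alpha_I,
                 w_EE = w_EE, w_EI = w_EI, w_IE = w_IE, w_II = w_II,
                 h_E = h_E, h_I = h_I, f_E = f_E, f_I = f_I),
            class = "stoch_params")
}

#' Stochastic parameters from the symmetric family
#'
#' @param p A [wc_symmetric()] object.
#' @param N_E,N_I Population sizes.
#' @return A [stoch_params()] object with \code{w_IE = w_EE = w_E},
#'   \code{w_EI = w_II = w_I} and the shared rate function.
#' @export
stoch_params_from_symmetric <- function(p, N_E = 800, N_I = N_E) {
  stopifnot(inherits(p, "wc_symmetric"))
  stoch_params(N_E = N_E, N_I = N_I, alpha_E = p$alpha, alpha_I = p$alpha,
               w_EE = p$w_E, w_EI = p$w_I, w_IE = p$w_E, w_II = p$w_I,
               h_E = p$h, h_I = p$h, f_E = p$f, f_I = p$f)
}

# net input currents given counts
stoch_inputs <- function(p, n_E, n_I) {
  fE <- if (p$N_E > 0) n_E / p$N_E else 0
  fI <- if (p$N_I > 0) n_I / p$N_I else 0
  c(s_E = p$w_EE * fE - p$w_EI * fI + p$h_E,
    s_I = p$w_IE * fE - p$w_II * fI + p$h_I)
}

#' Transition rates of the single-population master equation
#'
#' @param n_E Number of active excitatory neurons.
#' @param p A [stoch_params()] object.
#' @param n_I Number of active inhibitory neurons (enters the input
#'   current only).
#' @return Named vector \code{c(deactivation, activation)} in 1/ms:
#'   \eqn{\alpha n_E} and \eqn{(N_E - n_E) f_E[s_E]}.
#' @export
rates_excitatory <- function(n_E, p, n_I = 0) {
  stopifnot(inherits(p, "stoch_params"),
            n_E >= 0, n_E <= p$N_E)
  s <- stoch_inputs(p, n_E, n_I)
  c(deactivation = p$alpha_E * n_E,
    activation = (p$N_E - n_E) * eval_rate(p$f_E, s[["s_E"]]))
}

#' The four channel rates of the E/I master equation
#'
#' @param n_E,n_I Active counts.
#' @param p A [stoch_params()] object.
#' @return Named vector with \code{E_deact}, \code{E_act},
#'   \code{I_deact}, \code{I_act} in 1/ms.
#' @export
rates_ei <- function(n_E, n_I, p) {
  stopifnot(inherits(p, "stoch_params"),
            n_E >= 0, n_E <= p$N_E, n_I >= 0, n_I <= p$N_I)
  s <- stoch_inputs(p, n_E, n_I)
  c(E_deact = p$alpha_E * n_E,
    E_act = (p$N_E - n_E) * eval_rate(p$f_E, s[["s_E"]]),
    I_deact = p$alpha_I * n_I,
    I_act = if (p$N_I > 0) {
      (p$N_I - n_I) * eval_rate(p$f_I, s[["s_I"]])
    } else 0)
}

# fast scalar evaluator for a firing_rate, used inside event loops
rate_closure <- function(fr) {
  a <- fr$gain; th <- fr$threshold; rs <- fr$rate_scale; ith <- fr$I_TH
  switch(fr$form,
    logistic = function(x) 1 / (1 + exp(-a * (x - th))),
    logistic_shifted = {
      off <- 1 / (1 + exp(a * th))
      function(x) 1 / (1 + exp(-a * (x - th))) - off
    },
    rectified_saturating = function(x) if (x > 0) rs * tanh(x / ith) else 0)
}

#' Exact stochastic simulation of the E/I master equation (Gillespie)
#'
#' Event-driven exact sampling: the waiting time is exponential with the
#' total rate, the channel is chosen proportionally to its rate, and the
#' state is updated by one neuron.  When \code{record_ids} is TRUE each
#' activation is assigned a uniformly random quiescent neuron id (and
#' each deactivation a uniformly random active id), which matters only
#' for raster realism -- the master equation is exchangeable.
#'
#' @param p A [stoch_params()] object.
#' @param T End time, ms.
#' @param init Initial counts \code{c(n_E, n_I)}.
#' @param seed Integer RNG seed (recorded in the output).
#' @param record_ids Assign neuron ids to events.
#' @param max_events Safety cap on the number of events.
#' @return Object of class \code{"wc_raster"}: data.frame \code{events}
#'   with columns \code{time}, \code{neuron_id}, \code{population},
#'   \code{transition}; plus \code{N_E}, \code{N_I}, \code{duration},
#'   \code{seed}, \code{init} and the logical \code{absorbed} (TRUE if
#'   the total rate hit zero before \code{T}).
#' @export
gillespie <- function(p, T, init = c(0, 0), seed = 1L,
                      record_ids = FALSE, max_events = 5e6) {
  stopifnot(inherits(p, "stoch_params"), T > 0)
  set.seed(seed)
  nE <- as.integer(init[[1]]); nI <- as.integer(init[[2]])
  stopifnot(nE >= 0, nE <= p$N_E, nI >= 0, nI <= p$N_I)
  fE <- rate_closure(p$f_E); fI <- rate_closure(p$f_I)
  NE <- p$N_E; NI <- p$N_I
  aE <- p$alpha_E; aI <- p$alpha_I
  wEE <- p$w_EE; wEI <- p$w_EI; wIE <- p$w_IE; wII <- p$w_II
  hE <- p$h_E; hI <- p$h_I
  invNE <- if (NE > 0) 1 / NE else 0
  invNI <- if (NI > 0) 1 / NI else 0
  cap <- 4096L
  ev_t <- numeric(cap); ev_pop <- integer(cap)
  ev_tr <- integer(cap); ev_id <- integer(cap)
  if (record_ids) {
    idsE <- seq_len(max(NE, 1L)); idsI <- seq_len(max(NI, 1L))
    # invariant: the first nE/nI entries are the active ids
  }
  t <- 0; k <- 0L; absorbed <- FALSE
  while (t < T && k < max_events) {
    frE <- nE * invNE; frI <- nI * invNI
    r1 <- aE * nE
    r2 <- (NE - nE) * fE(wEE * frE - wEI * frI + hE)
    r3 <- aI * nI
    r4 <- if (NI > 0) (NI - nI) * fI(wIE * frE - wII * frI + hI) else 0
    rtot <- r1 + r2 + r3 + r4
    if (rtot <= 0) { absorbed <- TRUE; break }
    t <- t + stats::rexp(1L, rtot)
    if (t >= T) break
    u <- stats::runif(1L) * rtot
    if (k == cap) {                     # grow storage
      cap <- cap * 2L
      length(ev_t) <- cap; length(ev_pop) <- cap
      length(ev_tr) <- cap; length(ev_id) <- cap
    }
    k <- k + 1L
    if (u < r1) {                       # E deactivation
      id <- NA_integer_
      if (record_ids) {
        j <- sample.int(nE, 1L); id <- idsE[j]
        idsE[j] <- idsE[nE]; idsE[nE] <- id
      }
      nE <- nE - 1L
      ev_t[k] <- t; ev_pop[k] <- 1L; ev_tr[k] <- 0L; ev_id[k] <- id
    } else if (u < r1 + r2) {           # E activation
      id <- NA_integer_
      if (record_ids) {
        j <- nE + sample.int(NE - nE, 1L); id <- idsE[j]
        idsE[j] <- idsE[nE + 1L]; idsE[nE + 1L] <- id
      }
      nE <- nE + 1L
      ev_t[k] <- t; ev_pop[k] <- 1L; ev_tr[k] <- 1L; ev_id[k] <- id
    } else if (u < r1 + r2 + r3) {      # I deactivation
      id <- NA_integer_
      if (record_ids) {
        j <- sample.int(nI, 1L); id <- idsI[j]
        idsI[j] <- idsI[nI]; idsI[nI] <- id
      }
      nI <- nI - 1L
      ev_t[k] <- t; ev_pop[k] <- 2L; ev_tr[k] <- 0L; ev_id[k] <- id
    } else {                            # I activation
      id <- NA_integer_
      if (record_ids) {
        j <- nI + sample.int(NI - nI, 1L); id <- idsI[j]
        idsI[j] <- idsI[nI + 1L]; idsI[nI + 1L] <- id
      }
      nI <- nI + 1L
      ev_t[k] <- t; ev_pop[k] <- 2L; ev_tr[k] <- 1L; ev_id[k] <- id
    }
  }
  if (k >= max_events) {
    warning("event cap reached at t = ", signif(t, 6), " ms")
  }
  events <- data.frame(
    time = ev_t[seq_len(k)],
    neuron_id = ev_id[seq_len(k)],
    population = c("E", "I")[ev_pop[seq_len(k)]],
    transition = c("deactivation", "activation")[ev_tr[seq_len(k)] + 1L],
    stringsAsFactors = FALSE)
  structure(list(events = events, N_E = NE, N_I = NI,
                 duration = T, seed = seed,
                 init = c(n_E = as.integer(init[[1]]),
                          n_I = as.integer(init[[2]])),
                 absorbed = absorbed),
            class = "wc_raster")
}

#' @export
print.wc_raster <- function(x, ...) {
  cat(sprintf("<wc_raster> N_E=%d N_I=%d, %d events over %g ms (seed %d)%s\n",
              x$N_E, x$N_I, nrow(x$events), x$duration, x$seed,
              if (x$absorbed) " [absorbed]" else ""))
  invisible(x)
}

#' Count trajectory of a raster
#'
#' Reconstructs \code{(n_E(t), n_I(t))} from the event log, starting at
#' the recorded initial state.
#'
#' @param r A [gillespie()] raster.
#' @return data.frame with columns \code{t}, \code{n_E}, \code{n_I}
#'   (state immediately after each event; first row is the initial
#'   state at t = 0).
#' @export
count_trajectory <- function(r) {
  stopifnot(inherits(r, "wc_raster"))
  ev <- r$events
  dE <- ifelse(ev$population == "E",
               ifelse(ev$transition == "activation", 1L, -1L), 0L)
  dI <- ifelse(ev$population == "I",
               ifelse(ev$transition == "activation", 1L, -1L), 0L)
  data.frame(t = c(0, ev$time),
             n_E = cumsum(c(r$init[["n_E"]], dE)),
             n_I = cumsum(c(r$init[["n_I"]], dI)))
}

#' Time-weighted occupancy distribution of the excitatory count
#'
#' Fraction of simulated time spent in each state \code{n_E = 0..N_E},
#' the quantity directly comparable with the master-equation
#' probability vector.
#'
#' @param r A [gillespie()] raster.
#' @param burn_in Time discarded from the start, ms.
#' @return Numeric vector of length \code{N_E + 1} summing to 1.
#' @export
occupancy_histogram <- function(r, burn_in = 0) {
  tr <- count_trajectory(r)
  t_end <- r$duration
  t_next <- c(tr$t[-1], t_end)
  dwell <- pmax(0, pmin(t_next, t_end) - pmax(tr$t, burn_in))
  w <- tapply(dwell, factor(tr$n_E, levels = 0:r$N_E), sum,
              default = 0)
  as.numeric(w) / sum(dwell)
}

#' Integrate the single-population master equation
#'
#' Direct numerical integration of the \code{N_E + 1} coupled linear
#' ODEs for the probabilities \eqn{P_n(t)}: gain/loss of one active
#' neuron with deactivation rate \eqn{\alpha n} and activation rate
#' \eqn{(N - n) f[s_E(n)]}.  This is the exact small-system oracle for
#' the stochastic simulator.
#'
#' @param p A [stoch_params()] object with \code{N_I == 0} and
#'   \code{N_E <= 200}.
#' @param T End time, ms.
#' @param P0 Initial distribution over \code{n = 0..N_E}; default a
#'   point mass at 0.
#' @param times Output times; default \code{c(0, T)}.
#' @return Matrix with one row per output time (rownames = time),
#'   columns \code{n = 0..N_E}; each row sums to 1 within 1e-6 (checked).
#' @export
integrate_master <- function(p, T, P0 = NULL, times = c(0, T)) {
  stopifnot(inherits(p, "stoch_params"), p$N_I == 0, p$N_E <= 200, T > 0)
  N <- p$N_E
  n <- 0:N
  act <- (N - n) * eval_rate(p$f_E, p$w_EE * n / N + p$h_E)
  deact <- p$alpha_E * n
  # generator: from n, up at act[n], down at deact[n]
  if (is.null(P0)) P0 <- c(1, rep(0, N))
  stopifnot(length(P0) == N + 1, abs(sum(P0) - 1) < 1e-8)
  deriv <- function(t, P, parms) {
    up_in <- c(0, act[-(N + 1)] * P[-(N + 1)])    # from n-1
    down_in <- c(deact[-1] * P[-1], 0)            # from n+1
    list(up_in + down_in - (act + deact) * P)
  }
  out <- deSolve::ode(y = P0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-9, atol = 1e-12)
  P <- out[, -1, drop = FALSE]
  mass_err <- abs(rowSums(P) - 1)
  if (any(mass_err > 1e-6)) {
    stop("probability mass deviates from 1 by ", max(mass_err))
  }
  rownames(P) <- out[, 1]
  colnames(P) <- n
  P
}

#' Stationary distribution of the single-population master equation
#'
#' Solves the global balance equations directly (birth-death detailed
#' balance), providing an independent long-time reference for
#' [integrate_master()] and [occupancy_histogram()].
#'
#' @param p A [stoch_params()] object with \code{N_I == 0}.
#' @return Probability vector over \code{n = 0..N_E}.
#' @export
master_stationary <- function(p) {
  stopifnot(inherits(p, "stoch_params"), p$N_I == 0)
  N <- p$N_E
  n <- 0:N
  act <- (N - n) * eval_rate(p$f_E, p$w_EE * n / N + p$h_E)
  deact <- p$alpha_E * n
  # birth-death chain: pi_{n+1}/pi_n = act_n / deact_{n+1}
  logpi <- c(0, cumsum(log(act[-(N + 1)]) - log(deact[-1])))
  logpi[is.nan(logpi) | logpi == -Inf] <- -Inf
  pim <- exp(logpi - max(logpi[is.finite(logpi)]))
  pim[!is.finite(pim)] <- 0
  pim / sum(pim)
}

#' Linear-noise (system-size) Langevin trajectory
#'
#' Euler-Maruyama integration of the Gaussian fluctuation equation from
#' the van Kampen expansion about a stable fixed point.
#'
#' For \code{mode = "single"} (one excitatory population of size N):
#' \deqn{\dot\xi = A\xi + \sqrt{\alpha n_0 + (1 - n_0) f[s_0]}\ \eta,}
#' with \eqn{A} the mean-field Jacobian at the fixed point \eqn{n_0};
#' the reconstructed count is \eqn{k = N n_0 + \sqrt N \xi}.
#'
#' For \code{mode = "sigma_delta"} (symmetric E/I family): the
#' two-component equation with the upper-triangular effective
#' feed-forward matrix and noise amplitude \eqn{\sqrt{\alpha\Sigma_0}}
#' in each component (see [effective_jacobian()]).
#'
#' @param p A [stoch_params()] (mode "single") or [wc_symmetric()]
#'   (mode "sigma_delta") object.
#' @param T,dt Duration and step, ms.
#' @param seed RNG seed.
#' @param N System size used for count reconstruction.
#' @param mode "single" or "sigma_delta".
#' @param noise_scale Multiplier on the noise amplitude (0 gives the
#'   deterministic linearization).
#' @param xi0 Initial fluctuation (vector for sigma_delta).
#' @return Object of class \code{"langevin_trajectory"}: \code{times},
#'   matrix \code{xi} (columns \code{xi_Sigma}, \code{xi_Delta} or
#'   \code{xi_E}), \code{fixed_point}, \code{counts} (reconstructed
#'   \eqn{k}), \code{A}, \code{noise_sd}, \code{seed}.
#' @export
langevin_lna <- function(p, T, dt = 0.05, seed = 1L, N = 800,
                         mode = c("sigma_delta", "single"),
                         noise_scale = 1, xi0 = NULL) {
  mode <- match.arg(mode)
  set.seed(seed)
  nstep <- ceiling(T / dt)
  times <- seq(0, nstep) * dt
  if (mode == "single") {
    stopifnot(inherits(p, "stoch_params"), p$N_I == 0)
    g <- function(x) -p$alpha_E * x +
      (1 - x) * eval_rate(p$f_E, p$w_EE * x + p$h_E)
    lo <- if (g(0) > 0) 0 else 1e-9
    if (g(lo) <= 0 || g(1) >= 0) stop("no interior stable fixed point")
    n0 <- stats::uniroot(g, c(lo, 1), tol = 1e-14)$root
    s0 <- p$w_EE * n0 + p$h_E
    A <- -p$alpha_E - eval_rate(p$f_E, s0) +
      (1 - n0) * p$w_EE * eval_rate_deriv(p$f_E, s0)
    if (A >= 0) stop("fixed point is not stable (A >= 0)")
    D <- noise_scale * sqrt(p$alpha_E * n0 +
                              (1 - n0) * eval_rate(p$f_E, s0))
    x1 <- if (is.null(xi0)) 0 else xi0[[1]]
    # Euler-Maruyama as a linear recursion xi_{k+1} = (1+A dt) xi_k + D sqrt(dt) z_k
    incr <- D * sqrt(dt) * stats::rnorm(nstep)
    incr[1] <- incr[1] + (1 + A * dt) * x1
    xi <- c(x1, as.numeric(stats::filter(incr, 1 + A * dt,
                                         method = "recursive")))
    ximat <- cbind(xi_E = xi)
    fp <- c(n_E = n0)
    counts <- N * n0 + sqrt(N) * xi
    Amat <- matrix(A, 1, 1)
    noise_sd <- D
  } else {
    stopifnot(inherits(p, "wc_symmetric"))
    ej <- effective_jacobian(p)
    if (max(Re(eigen(ej$matrix, only.values = TRUE)$values)) >= 0) {
      stop("symmetric fixed point is not stable")
    }
    Amat <- ej$matrix
    noise_sd <- noise_scale * ej$noise_amplitude
    ximat <- matrix(0, nstep + 1, 2,
                    dimnames = list(NULL, c("xi_Sigma", "xi_Delta")))
    if (!is.null(xi0)) ximat[1, ] <- xi0
    z <- matrix(stats::rnorm(2 * nstep), nstep, 2)
    for (k in seq_len(nstep)) {
      ximat[k + 1, ] <- ximat[k, ] + (Amat %*% ximat[k, ]) * dt +
        noise_sd * sqrt(dt) * z[k, ]
    }
    fp <- c(Sigma = ej$Sigma0, Delta = 0)
    # reconstructed excitatory count: n_E = Sigma + Delta
    counts <- N * ej$Sigma0 + sqrt(N) * (ximat[, 1] + ximat[, 2])
  }
  structure(list(times = times, xi = ximat, fixed_point = fp,
                 counts = counts, A = Amat, noise_sd = noise_sd,
                 seed = seed, dt = dt),
            class = "langevin_trajectory")
}
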