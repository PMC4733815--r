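#' Kernel-coupled input current on a lattice of counts
#'
#' The spatial extension of the master-equation input: the current
#' density at site x is the discrete convolution of the connectivity
#' kernel with the active fraction field plus the external input,
#' \eqn{I(x) = \sum_{x'} w(x - x')\, n(x') + h(x)}.
#'
#' @param n Numeric vector of active fractions (or counts) per site.
#' @param W Coupling matrix as built by the spatial machinery (sparse,
#'   includes quadrature and density factors), or a [wc_kernel()] with
#'   \code{lattice} supplied.
#' @param h External input per site (scalar recycled).
#' @param lattice Required when \code{W} is a kernel.
#' @return Numeric vector of currents per site.
#' @export
spatial_input_current <- function(n, W, h = 0, lattice = NULL) {
  if (inherits(W, "wc_kernel")) {
    stopifnot(inherits(lattice, "wc_lattice"))
    W <- kernel_matrix(W, lattice)
  }
  as.numeric(W %*% n) + h
}

#' Lattice of local stochastic populations
#'
#' Describes a chain (or sheet) of local E/I pools of \code{N_site}
#' neurons each, coupled through exponential kernels; used by
#' [gillespie_lattice()].
#'
#' @param p A [wc_symmetric()] object giving rates, weights and input;
#'   the kernel distributes each weight over space with unit integral.
#' @param lattice A [wc_lattice()] object.
#' @param N_site Neurons per population per site.
#' @param sigma Kernel space constant, micrometres.
#' @return Object of class \code{"stoch_lattice_params"} with dense
#'   coupling matrices \code{W_E} (excitatory kernel scaled by
#'   \code{w_E}) and \code{W_I}.
#' @export
stoch_lattice_params <- function(p, lattice, N_site = 32, sigma = 100) {
  stopifnot(inherits(p, "wc_symmetric"), inherits(lattice, "wc_lattice"),
            N_site >= 1)
  ns <- prod(lattice$n)
  wmat <- function(w) {
    if (w > 0) {
      as.matrix(kernel_matrix(
        kernel_from_weight(w, sigma = sigma, dim = lattice$dim),
        lattice))
    } else {
      matrix(0, ns, ns)                 # uncoupled limit
    }
  }
  structure(list(sym = p, lattice = lattice,
                 N_site = as.integer(N_site), sigma = sigma,
                 W_E = wmat(p$w_E), W_I = wmat(p$w_I)),
            class = "stoch_lattice_params")
}

#' Gillespie simulation of the spatial master equation
#'
#' Exact SSA over all sites' channels: each site holds local E and I
#' pools whose activation rates depend on kernel-weighted input from
#' every site, \eqn{s_E(x) = (W_E * n_E/N) (x) - (W_I * n_I/N)(x) + h}.
#' Site states are snapshotted at regular sample times for downstream
#' correlation analysis.
#'
#' @param lp A [stoch_lattice_params()] object.
#' @param T Duration, ms.
#' @param seed RNG seed.
#' @param sample_dt Snapshot interval, ms.
#' @param h_drive Additional uniform external drive added to both
#'   populations' inputs (used for "driven" runs).
#' @param init Initial active count per site (scalar), default half of
#'   \code{N_site}.
#' @param max_events Safety cap.
#' @return List of class \code{"lattice_ssa"}: \code{times}, matrices
#'   \code{n_E}, \code{n_I} (time x site, counts), \code{lattice},
#'   \code{N_site}, \code{seed}, \code{absorbed}, \code{n_events}.
#' @export
gillespie_lattice <- function(lp, T, seed = 1L, sample_dt = 1,
                              h_drive = 0, init = NULL,
                              max_events = 5e6) {
  stopifnot(inherits(lp, "stoch_lattice_params"), T > 0)
  set.seed(seed)
  sym <- lp$sym
  ns <- prod(lp$lattice$n)
  N <- lp$N_site
  f <- rate_closure(sym$f)
  fvec <- function(s) vapply(s, f, numeric(1))
  n_E <- rep(if (is.null(init)) N %/% 2L else as.integer(init), ns)
  n_I <- n_E
  WE <- lp$W_E / N                      # per-count current increments
  WI <- lp$W_I / N
  s_E <- as.numeric(WE %*% n_E) - as.numeric(WI %*% n_I) +
    sym$h + h_drive
  s_I <- s_E                            # symmetric weights: same current
  tsamp <- seq(0, T, by = sample_dt)
  snapE <- matrix(NA_integer_, length(tsamp), ns)
  snapI <- matrix(NA_integer_, length(tsamp), ns)
  snapE[1, ] <- n_E; snapI[1, ] <- n_I
  si <- 2L
  t <- 0; k <- 0L; absorbed <- FALSE
  alpha <- sym$alpha
  while (t < T && k < max_events) {
    rEd <- alpha * n_E
    rEa <- (N - n_E) * fvec(s_E)
    rId <- alpha * n_I
    rIa <- (N - n_I) * fvec(s_I)
    rtot <- sum(rEd) + sum(rEa) + sum(rId) + sum(rIa)
    if (rtot <= 0) { absorbed <- TRUE; break }
    t_new <- t + stats::rexp(1L, rtot)
    while (si <= length(tsamp) && tsamp[si] < min(t_new, T)) {
      snapE[si, ] <- n_E; snapI[si, ] <- n_I
      si <- si + 1L
    }
    t <- t_new
    if (t >= T) break
    k <- k + 1L
    u <- stats::runif(1L) * rtot
    cs <- cumsum(c(sum(rEd), sum(rEa), sum(rId), sum(rIa)))
    if (u < cs[1]) {
      j <- sample.int(ns, 1L, prob = rEd)
      n_E[j] <- n_E[j] - 1L
      s_E <- s_E - WE[, j]; s_I <- s_I - WE[, j]
    } else if (u < cs[2]) {
      j <- sample.int(ns, 1L, prob = rEa)
      n_E[j] <- n_E[j] + 1L
      s_E <- s_E + WE[, j]; s_I <- s_I + WE[, j]
    } else if (u < cs[3]) {
      j <- sample.int(ns, 1L, prob = rId)
      n_I[j] <- n_I[j] - 1L
      s_E <- s_E + WI[, j]; s_I <- s_I + WI[, j]
    } else {
      j <- sample.int(ns, 1L, prob = rIa)
      n_I[j] <- n_I[j] + 1L
      s_E <- s_E - WI[, j]; s_I <- s_I - WI[, j]
    }
  }
  while (si <= length(tsamp)) {         # fill trailing samples
    snapE[si, ] <- n_E; snapI[si, ] <- n_I
    si <- si + 1L
  }
  if (k >= max_events) warning("event cap reached at t = ", signif(t, 6))
  structure(list(times = tsamp, n_E = snapE, n_I = snapI,
                 lattice = lp$lattice, N_site = N, seed = seed,
                 absorbed = absorbed, n_events = k),
            class = "lattice_ssa")
}

#' Spatial field simulation with additive Gaussian noise
#'
#' Stochastic time stepping of the spatial mean-field equations with
#' independent delta-correlated Gaussian noise added per site: the
#' drift is advanced with the same fixed-step RK4 stages as
#' [simulate_field()], and each step then adds an additive increment
#' \code{noise_sd * sqrt(dt) * z} to both fields.  With
#' \code{noise_sd = 0} the scheme reduces exactly to
#' [simulate_field()].
#'
#' @param p A [wc_spatial_params()] object.
#' @param noise_sd Noise amplitude (field units per sqrt(ms)).
#' @param stimulus A [wc_stimulus()] or NULL; a persistent uniform
#'   drive can instead be supplied via \code{h_drive}.
#' @param T,dt Duration and step, ms.
#' @param seed RNG seed.
#' @param h_drive Constant uniform extra input to both populations.
#' @param init Initial fields, list(E =, I =).
#' @param stride Record every stride-th step.
#' @return A \code{"field_history"} object (see [simulate_field()]).
#' @export
additive_noise_field <- function(p, noise_sd = 0, stimulus = NULL,
                                 T, dt = 0.1, seed = 1L, h_drive = 0,
                                 init = list(E = 0, I = 0),
                                 stride = 5L) {
  stopifnot(inherits(p, "wc_spatial_params"), T > 0, dt > 0)
  set.seed(seed)
  nsite <- prod(p$lattice$n)
  E <- rep_len(init$E, nsite); I <- rep_len(init$I, nsite)
  prof <- stimulus_profile(stimulus, p$lattice)
  nstep <- ceiling(T / dt)
  rec_idx <- seq(0L, nstep, by = stride)
  Eh <- matrix(NA_real_, length(rec_idx), nsite)
  Ih <- matrix(NA_real_, length(rec_idx), nsite)
  Eh[1, ] <- E; Ih[1, ] <- I
  ri <- 2L
  sq <- noise_sd * sqrt(dt)
  stim_at <- function(t) {
    on <- !is.null(stimulus) && t >= stimulus$onset &&
      t < stimulus$onset + stimulus$duration
    h <- if (on) prof else 0
    if (is.null(stimulus) || stimulus$population == "both") {
      list(hE = h + h_drive, hI = h + h_drive)
    } else if (stimulus$population == "E") {
      list(hE = h + h_drive, hI = h_drive)
    } else {
      list(hE = h_drive, hI = h + h_drive)
    }
  }
  for (k in seq_len(nstep)) {
    t0 <- (k - 1) * dt
    h1 <- stim_at(t0); h2 <- stim_at(t0 + dt / 2); h4 <- stim_at(t0 + dt)
    k1 <- spatial_rhs(E, I, p, h1$hE, h1$hI)
    k2 <- spatial_rhs(E + dt / 2 * k1$dE, I + dt / 2 * k1$dI, p,
                      h2$hE, h2$hI)
    k3 <- spatial_rhs(E + dt / 2 * k2$dE, I + dt / 2 * k2$dI, p,
                      h2$hE, h2$hI)
    k4 <- spatial_rhs(E + dt * k3$dE, I + dt * k3$dI, p, h4$hE, h4$hI)
    E <- E + dt / 6 * (k1$dE + 2 * k2$dE + 2 * k3$dE + k4$dE)
    I <- I + dt / 6 * (k1$dI + 2 * k2$dI + 2 * k3$dI + k4$dI)
    if (noise_sd > 0) {
      E <- E + sq * stats::rnorm(nsite)
      I <- I + sq * stats::rnorm(nsite)
    }
    if (!all(is.finite(E))) stop("field non-finite at t = ", k * dt)
    if (ri <= length(rec_idx) && k == rec_idx[ri]) {
      Eh[ri, ] <- E; Ih[ri, ] <- I
      ri <- ri + 1L
    }
  }
  structure(list(times = rec_idx * dt, E = Eh, I = Ih,
                 lattice = p$lattice, stimulus = stimulus, dt = dt,
                 stride = stride, seed = seed, noise_sd = noise_sd),
            class = "field_history")
}
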