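#' Exponential connectivity kernel
#'
#' Spatio-temporal kernel of the continuum model: temporal impulse
#' response \eqn{\alpha(t) = \alpha_0 e^{-t/\tau}} and spatial weighting
#' \eqn{\beta(x) = b\, e^{-|x|/\sigma}}.  The 1-D spatial integral is
#' \eqn{\int\beta = 2 b \sigma}; in 2-D (radial) it is \eqn{2\pi b
#' \sigma^2}.
#'
#' @param b Spatial amplitude (> 0).
#' @param sigma Space constant, micrometres (> 0). Default 100.
#' @param tau Membrane time constant, ms (> 0). Default 10.
#' @param alpha0 Temporal amplitude, 1/ms. Default \code{1/tau} (unit DC
#'   gain).
#' @return Object of class \code{"wc_kernel"}.
#' @export
wc_kernel <- function(b = 1, sigma = 100, tau = 10, alpha0 = 1 / tau) {
  stopifnot(b > 0, sigma > 0, tau > 0, alpha0 > 0)
  structure(list(b = b, sigma = sigma, tau = tau, alpha0 = alpha0),
            class = "wc_kernel")
}

#' Kernel with a prescribed integrated weight
#'
#' Convenience constructor choosing the amplitude \code{b} so that the
#' continuum integral of \eqn{\beta} equals \code{w}: \code{b = w /
#' (2 sigma)} in 1-D, \code{b = w / (2 pi sigma^2)} in 2-D.  A spatially
#' uniform field then feels exactly the mean-field weight \code{w}
#' (with unit packing density).
#'
#' @param w Target integrated weight (dimensionless).
#' @param sigma Space constant, micrometres.
#' @param dim Lattice dimension, 1 or 2.
#' @param ... Passed to [wc_kernel()].
#' @return A [wc_kernel()] object.
#' @export
kernel_from_weight <- function(w, sigma = 100, dim = 1, ...) {
  stopifnot(w > 0, dim %in% c(1, 2))
  b <- if (dim == 1) w / (2 * sigma) else w / (2 * pi * sigma^2)
  wc_kernel(b = b, sigma = sigma, ...)
}

#' Lattice descriptor
#'
#' @param dim 1 or 2.
#' @param n Number of sites per axis (scalar for 1-D, length-2 for 2-D).
#' @param dx Spacing, micrometres.
#' @param boundary "periodic" or "zero_flux" (reflecting).
#' @return List of class \code{"wc_lattice"} with an \code{extent} field
#'   (micrometres per axis).  Site i sits at physical position
#'   \code{(i - 1) * dx} from the left/lower edge.
#' @export
wc_lattice <- function(dim = 1, n = 200, dx = 25,
                       boundary = c("periodic", "zero_flux")) {
  boundary <- match.arg(boundary)
  stopifnot(dim %in% c(1, 2), all(n >= 4), dx > 0)
  if (dim == 2 && length(n) == 1L) n <- c(n, n)
  structure(list(dim = dim, n = n, dx = dx, boundary = boundary,
                 extent = n * dx),
            class = "wc_lattice")
}

#' Discretize a spatial kernel on a lattice
#'
#' Samples \eqn{\beta} at lattice offsets, truncated at \eqn{6\sigma}.
#' The lattice must resolve the kernel (\code{dx <= sigma / 4}), in which
#' case the Riemann sum \code{sum(values) * dx^dim} matches the continuum
#' integral to within 1 percent.
#'
#' @param k A [wc_kernel()] object.
#' @param lattice A [wc_lattice()] object.
#' @return List with \code{offsets} (integer matrix, one row per stencil
#'   point) and \code{values} (kernel amplitudes \eqn{\beta} at those
#'   offsets, before the \code{dx^dim} quadrature factor).
#' @export
discretize_kernel <- function(k, lattice) {
  stopifnot(inherits(k, "wc_kernel"), inherits(lattice, "wc_lattice"))
  if (lattice$dx > k$sigma / 4) {
    stop("lattice under-resolves the kernel: need dx <= sigma/4 (dx = ",
         lattice$dx, ", sigma = ", k$sigma, ")")
  }
  K <- ceiling(6 * k$sigma / lattice$dx)
  if (lattice$dim == 1) {
    off <- matrix(-K:K, ncol = 1)
    r <- abs(off[, 1]) * lattice$dx
  } else {
    g <- expand.grid(i = -K:K, j = -K:K)
    r <- sqrt(g$i^2 + g$j^2) * lattice$dx
    keep <- r <= 6 * k$sigma
    off <- as.matrix(g[keep, , drop = FALSE])
    r <- r[keep]
  }
  list(offsets = off, values = k$b * exp(-r / k$sigma))
}

# Sparse site-to-site weight matrix for a discretized kernel.
# Includes the quadrature factor dx^dim; boundary handled by wrapping
# (periodic) or mirror reflection (zero_flux).
kernel_matrix <- function(k, lattice) {
  st <- discretize_kernel(k, lattice)
  dxp <- lattice$dx^lattice$dim
  if (lattice$dim == 1) {
    n <- lattice$n[[1]]
    i_idx <- rep(seq_len(n), each = nrow(st$offsets))
    j_raw <- i_idx + rep(st$offsets[, 1], times = n)
    vals <- rep(st$values, times = n) * dxp
    j_idx <- map_boundary(j_raw, n, lattice$boundary)
    keep <- !is.na(j_idx)
    m <- Matrix::sparseMatrix(i = i_idx[keep], j = j_idx[keep],
                              x = vals[keep], dims = c(n, n))
  } else {
    nx <- lattice$n[[1]]; ny <- lattice$n[[2]]
    n <- nx * ny
    nk <- nrow(st$offsets)
    site <- seq_len(n)
    ix <- ((site - 1) %% nx) + 1L
    iy <- ((site - 1) %/% nx) + 1L
    i_idx <- rep(site, each = nk)
    jx_raw <- rep(ix, each = nk) + rep(st$offsets[, 1], times = n)
    jy_raw <- rep(iy, each = nk) + rep(st$offsets[, 2], times = n)
    jx <- map_boundary(jx_raw, nx, lattice$boundary)
    jy <- map_boundary(jy_raw, ny, lattice$boundary)
    keep <- !is.na(jx) & !is.na(jy)
    j_idx <- (jy[keep] - 1L) * nx + jx[keep]
    vals <- rep(st$values, times = n)[keep] * dxp
    m <- Matrix::sparseMatrix(i = i_idx[keep], j = j_idx, x = vals,
                              dims = c(n, n))
  }
  m
}

# Map raw (possibly out-of-range) indices onto 1..n for a boundary rule.
map_boundary <- function(idx, n, boundary) {
  if (boundary == "periodic") {
    ((idx - 1L) %% n) + 1L
  } else {
    # mirror reflection about the edges (period 2n - 2)
    m <- (idx - 1L) %% (2L * n - 2L)
    ifelse(m < n, m + 1L, 2L * n - 1L - m)
  }
}

#' Spatially extended Wilson-Cowan parameters
#'
#' The continuum field equations on a lattice:
#' \deqn{\tau \partial_t E = -E + (1 - rE)\, f_E[\rho_E(\beta_{EE} * E)
#'   - \rho_I(\beta_{EI} * I) + h_E(x, t)],}
#' and the analogous inhibitory equation, with discrete convolutions
#' over the truncated kernel stencils.
#'
#' @param base A [wc_params()] object; its scalar weights are ignored in
#'   favor of the kernels, but tau, r, inputs and rate functions are
#'   used.
#' @param beta_EE,beta_EI,beta_IE,beta_II [wc_kernel()] objects.
#' @param rho_E,rho_I Packing densities (cells per unit length or area);
#'   default 1, i.e. densities folded into the kernel amplitudes.
#' @param lattice A [wc_lattice()]; its extent must be at least
#'   \code{10 * sigma} of the widest kernel.
#' @return Object of class \code{"wc_spatial_params"} carrying
#'   precomputed sparse coupling matrices \code{W_EE}, ..., which include
#'   the density and quadrature factors.
#' @export
wc_spatial_params <- function(base, beta_EE, beta_EI, beta_IE, beta_II,
                              rho_E = 1, rho_I = 1,
                              lattice = wc_lattice()) {
  stopifnot(inherits(base, "wc_params"), inherits(lattice, "wc_lattice"))
  sig_max <- max(beta_EE$sigma, beta_EI$sigma, beta_IE$sigma,
                 beta_II$sigma)
  if (min(lattice$extent) < 10 * sig_max) {
    stop("lattice extent must be >= 10 * sigma of the widest kernel")
  }
  structure(list(
    base = base, lattice = lattice, rho_E = rho_E, rho_I = rho_I,
    beta_EE = beta_EE, beta_EI = beta_EI,
    beta_IE = beta_IE, beta_II = beta_II,
    W_EE = rho_E * kernel_matrix(beta_EE, lattice),
    W_EI = rho_I * kernel_matrix(beta_EI, lattice),
    W_IE = rho_E * kernel_matrix(beta_IE, lattice),
    W_II = rho_I * kernel_matrix(beta_II, lattice)),
    class = "wc_spatial_params")
}

#' Field derivatives of the spatial model
#'
#' @param E,I Numeric vectors of activity per site (2-D lattices are
#'   stored in site order, x fastest).
#' @param p A [wc_spatial_params()] object.
#' @param h_E,h_I External input per site (recycled scalars allowed),
#'   added to the base inputs.
#' @return List with vectors \code{dE}, \code{dI} in 1/ms.
#' @export
spatial_rhs <- function(E, I, p, h_E = 0, h_I = 0) {
  stopifnot(inherits(p, "wc_spatial_params"))
  b <- p$base
  sE <- as.numeric(p$W_EE %*% E) - as.numeric(p$W_EI %*% I) +
    b$h_E + h_E
  sI <- as.numeric(p$W_IE %*% E) - as.numeric(p$W_II %*% I) +
    b$h_I + h_I
  list(dE = (-E + (1 - b$r * E) * eval_rate(b$f_E, sE)) / b$tau,
       dI = (-I + (1 - b$r * I) * eval_rate(b$f_I, sI)) / b$tau)
}

#' Localized stimulus specification
#'
#' Gaussian bump in space, rectangular in time:
#' \eqn{h(x, t) = A \exp(-(x - c)^2 / (2 w^2))} for \eqn{t \in
#' [t_0, t_0 + d)}, 0 otherwise.
#'
#' @param center Center position, micrometres (2-D: length-2).
#' @param halfwidth Gaussian width parameter w, micrometres.
#' @param amplitude Peak amplitude A (input-current units).
#' @param onset Onset time, ms.
#' @param duration Duration, ms.
#' @param population "E", "I" or "both".
#' @return List of class \code{"wc_stimulus"}.
#' @export
wc_stimulus <- function(center, halfwidth, amplitude,
                        onset = 0, duration = 1,
                        population = c("E", "both", "I")) {
  population <- match.arg(population)
  structure(list(center = center, halfwidth = halfwidth,
                 amplitude = amplitude, onset = onset,
                 duration = duration, population = population),
            class = "wc_stimulus")
}

# spatial profile of a stimulus on the lattice (vector over sites)
stimulus_profile <- function(stim, lattice) {
  if (is.null(stim)) return(0)
  pos <- site_positions(lattice)
  if (lattice$dim == 1) {
    d2 <- (pos[, 1] - stim$center[[1]])^2
  } else {
    d2 <- (pos[, 1] - stim$center[[1]])^2 + (pos[, 2] - stim$center[[2]])^2
  }
  stim$amplitude * exp(-d2 / (2 * stim$halfwidth^2))
}

#' Physical positions of lattice sites (micrometres)
#'
#' @param lattice A [wc_lattice()] object.
#' @return Matrix with one row per site and \code{dim} columns.
#' @export
site_positions <- function(lattice) {
  stopifnot(inherits(lattice, "wc_lattice"))
  if (lattice$dim == 1) {
    matrix((seq_len(lattice$n[[1]]) - 1) * lattice$dx, ncol = 1)
  } else {
    nx <- lattice$n[[1]]; ny <- lattice$n[[2]]
    site <- seq_len(nx * ny)
    cbind(((site - 1) %% nx) * lattice$dx,
          ((site - 1) %/% nx) * lattice$dx)
  }
}

#' Simulate the spatial field equations
#'
#' Deterministic fixed-step RK4 time stepping; the history is
#' sub-sampled at a stated stride.
#'
#' @param p A [wc_spatial_params()] object.
#' @param stimulus A [wc_stimulus()] or NULL.
#' @param T Total time, ms.
#' @param dt Step, ms.
#' @param init Initial fields, list(E =, I =) or scalars (default 0).
#' @param stride Record every \code{stride}-th step.
#' @return Object of class \code{"field_history"}: \code{times} (ms),
#'   matrices \code{E}, \code{I} (time x site), the lattice, and the
#'   stimulus record.
#' @export
simulate_field <- function(p, stimulus = NULL, T, dt = 0.1,
                           init = list(E = 0, I = 0), stride = 5L) {
  stopifnot(inherits(p, "wc_spatial_params"), T > 0, dt > 0)
  nsite <- prod(p$lattice$n)
  E <- rep_len(init$E, nsite); I <- rep_len(init$I, nsite)
  prof <- stimulus_profile(stimulus, p$lattice)
  stim_h <- function(t) {
    if (is.null(stimulus)) return(list(hE = 0, hI = 0))
    on <- t >= stimulus$onset && t < stimulus$onset + stimulus$duration
    h <- if (on) prof else 0
    switch(stimulus$population,
           E = list(hE = h, hI = 0),
           I = list(hE = 0, hI = h),
           both = list(hE = h, hI = h))
  }
  nstep <- ceiling(T / dt)
  rec_idx <- seq(0L, nstep, by = stride)
  times <- rec_idx * dt
  Eh <- matrix(NA_real_, length(rec_idx), nsite)
  Ih <- matrix(NA_real_, length(rec_idx), nsite)
  Eh[1, ] <- E; Ih[1, ] <- I
  ri <- 2L
  for (k in seq_len(nstep)) {
    t0 <- (k - 1) * dt
    h1 <- stim_h(t0); h2 <- stim_h(t0 + dt / 2); h4 <- stim_h(t0 + dt)
    k1 <- spatial_rhs(E, I, p, h1$hE, h1$hI)
    k2 <- spatial_rhs(E + dt / 2 * k1$dE, I + dt / 2 * k1$dI, p,
                      h2$hE, h2$hI)
    k3 <- spatial_rhs(E + dt / 2 * k2$dE, I + dt / 2 * k2$dI, p,
                      h2$hE, h2$hI)
    k4 <- spatial_rhs(E + dt * k3$dE, I + dt * k3$dI, p, h4$hE, h4$hI)
    E <- E + dt / 6 * (k1$dE + 2 * k2$dE + 2 * k3$dE + k4$dE)
    I <- I + dt / 6 * (k1$dI + 2 * k2$dI + 2 * k3$dI + k4$dI)
    if (!all(is.finite(E)) || !all(is.finite(I))) {
      stop("field became non-finite at t = ", k * dt, " ms")
    }
    if (ri <= length(rec_idx) && k == rec_idx[ri]) {
      Eh[ri, ] <- E; Ih[ri, ] <- I
      ri <- ri + 1L
    }
  }
  structure(list(times = times, E = Eh, I = Ih, lattice = p$lattice,
                 stimulus = stimulus, dt = dt, stride = stride),
            class = "field_history")
}

#' Causal exponential (one-pole low-pass) temporal coarse-graining
#'
#' Filters a uniformly sampled series with the kernel
#' \eqn{\alpha(t) = \alpha_0 e^{-t/\tau}}, \eqn{\alpha_0 = 1/\tau}, i.e.
#' unit DC gain: a constant input passes unchanged while components
#' faster than \eqn{1/(2\pi\tau)} are attenuated by the one-pole
#' response \eqn{1/\sqrt{1 + (2\pi f \tau)^2}}.
#'
#' @param series Numeric vector (or matrix, filtered column-wise).
#' @param tau Filter time constant, ms.
#' @param dt Sampling interval, ms.
#' @return Filtered series of the same shape.
#' @export
coarse_grain <- function(series, tau, dt) {
  stopifnot(tau > 0, dt > 0)
  lam <- exp(-dt / tau)
  filt1 <- function(x) {
    as.numeric(stats::filter((1 - lam) * x, lam, method = "recursive",
                             init = x[[1]]))
  }
  if (is.matrix(series)) apply(series, 2, filt1) else filt1(series)
}

#' Wave metrology on a field history
#'
#' From a pulse response, computes per-distance peak amplitudes and
#' peak times (relative to stimulus onset), then
#' \itemize{
#'   \item speed = slope of the least-squares line of distance against
#'     peak time (mm/ms, numerically equal to m/s),
#'   \item decay length \eqn{\lambda} = -1/slope of log peak amplitude
#'     against distance (mm),
#'   \item classification: \code{"propagating"} iff the peak-time
#'     regression over distances in \code{[2 sigma, 10 sigma]} has
#'     R-squared > 0.9 and positive slope, else \code{"localized"}.
#' }
#' Peaks with amplitude below \code{rel_floor} times the maximum
#' response are treated as undetectable.  If fewer than \code{min_bins}
#' detectable distances remain beyond \eqn{2\sigma}, the response is
#' localized with speed reported as 0 and \code{no_peaks = TRUE}.
#'
#' @param h A [simulate_field()] history (or compatible list).
#' @param origin Origin position in micrometres; defaults to the
#'   stimulus center.
#' @param sigma Reference space constant, micrometres, defining the fit
#'   window; defaults to 4x the lattice spacing times 4 (i.e. use
#'   \code{fit_range} directly if given).
#' @param fit_range Distance window \code{c(lo, hi)} in micrometres;
#'   default \code{c(2, 10) * sigma}.
#' @param rel_floor Relative detectability floor.
#' @param min_bins Minimum usable distance bins.
#' @param field "E" or "I".
#' @return Object of class \code{"wave_metrics"}.
#' @export
measure_wave <- function(h, origin = NULL, sigma = NULL,
                         fit_range = NULL, rel_floor = 1e-3,
                         min_bins = 4L, field = "E") {
  lattice <- h$lattice
  if (is.null(origin)) {
    if (!is.null(h$stimulus)) {
      origin <- h$stimulus$center
    } else {
      stop("origin required when the history has no stimulus record")
    }
  }
  if (is.null(sigma)) sigma <- 4 * lattice$dx
  if (is.null(fit_range)) fit_range <- c(2, 10) * sigma
  M <- h[[field]]
  resp <- sweep(M, 2, M[1, ])          # deviation from initial field
  pos <- site_positions(lattice)
  d <- if (lattice$dim == 1) {
    abs(pos[, 1] - origin[[1]])
  } else {
    sqrt((pos[, 1] - origin[[1]])^2 + (pos[, 2] - origin[[2]])^2)
  }
  dbin <- round(d / lattice$dx) * lattice$dx
  t0 <- if (!is.null(h$stimulus)) h$stimulus$onset else 0
  ub <- sort(unique(dbin))
  peak_amp <- peak_time <- numeric(length(ub))
  for (i in seq_along(ub)) {
    sites <- which(dbin == ub[i])
    prof <- if (length(sites) == 1L) resp[, sites] else
      apply(resp[, sites, drop = FALSE], 1, max)
    j <- which.max(prof)
    peak_amp[i] <- prof[j]
    peak_time[i] <- h$times[j] - t0
  }
  tab <- data.frame(distance_mm = ub / 1000, peak_amp = peak_amp,
                    peak_time = peak_time)
  floor_amp <- rel_floor * max(peak_amp)
  use <- ub >= fit_range[[1]] & ub <= fit_range[[2]] &
    peak_amp >= floor_amp
  no_peaks <- sum(use) < min_bins
  speed <- 0; lambda <- NA_real_; slope_t <- NA_real_
  r2_time <- NA_real_; r2_amp <- NA_real_
  classification <- "localized"
  if (!no_peaks) {
    ft <- stats::lm(distance_mm ~ peak_time, data = tab[use, ])
    r2_time <- summary(ft)$r.squared
    slope_t <- stats::coef(ft)[["peak_time"]]
    fa <- stats::lm(log(peak_amp) ~ distance_mm, data = tab[use, ])
    r2_amp <- summary(fa)$r.squared
    slope_a <- stats::coef(fa)[["distance_mm"]]
    if (is.finite(slope_a) && slope_a < 0) lambda <- -1 / slope_a
    # unsigned regression speed; classification additionally demands
    # that peaks move outward (positive slope)
    if (is.finite(slope_t)) speed <- abs(slope_t)
    if (is.finite(r2_time) && r2_time > 0.9 && slope_t > 0) {
      classification <- "propagating"
    }
  }
  structure(list(speed = speed, time_slope = slope_t,
                 decay_length = lambda,
                 classification = classification,
                 r2_time = r2_time, r2_amp = r2_amp,
                 no_peaks = no_peaks, table = tab,
                 fit_range = fit_range),
            class = "wave_metrics")
}

#' @export
print.wave_metrics <- function(x, ...) {
  cat("<wave_metrics>", x$classification, "\n")
  cat(sprintf("  speed: %.4g mm/ms (R2 time fit %.3f)\n",
              x$speed, x$r2_time))
  cat(sprintf("  decay length: %.4g mm (R2 amp fit %.3f)\n",
              x$decay_length, x$r2_amp))
  invisible(x)
}
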