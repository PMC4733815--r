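#' Named parameter presets
#'
#' Ready-made parameter sets for the scenarios the package ships:
#' \describe{
#'   \item{fig10_nodes}{Classical two-population phase plane with
#'     multiple stable nodes: weights w_EE=12, w_EI=4, w_IE=13,
#'     w_II=11, no external input.  The sigmoid constants are the
#'     classical Wilson-Cowan presets (excitatory gain 1.2 / threshold
#'     2.8, inhibitory gain 1 / threshold 4); they are presets of this
#'     package, not values fixed by the phase-plane weights.}
#'   \item{fig10_limit_cycle}{Oscillatory regime: weights w_EE=16,
#'     w_EI=12, w_IE=15, w_II=3 with excitatory drive h_E = 1.25
#'     (classical limit-cycle sigmoids: gains 1.3/2, thresholds
#'     4/3.7).}
#'   \item{benayoun_low}{Symmetric stochastic family at
#'     h_E=h_I=0.001, w_0=0.2, w_E+w_I=0.8, alpha=0.1/ms, f =
#'     tanh rectified at unit rate scale; population size N=800 per
#'     pool. Small, Poisson-like fluctuations about the fixed point.}
#'   \item{benayoun_high}{Same but w_E+w_I=13.8: the balanced
#'     (avalanche) regime with random bursts.}
#'   \item{fig21_weak / fig21_strong}{Calibrated 1-D neural-field
#'     scenario for pulse-response wave metrology: a weak pulse
#'     launches a propagating, exponentially decaying wave; a strong
#'     pulse recruits inhibition (high inhibitory threshold) and stays
#'     localized.  These spatial parameters are calibrations of this
#'     package chosen to put the weak-pulse speed in the
#'     0.1-1 mm/ms decade; they are not printed model constants.}
#'   \item{branching_critical}{Critical Galton-Watson reference:
#'     Poisson offspring with mean 1, 1e5 trials, truncation at 1e5.}
#' }
#'
#' @param name Preset name.
#' @return The preset object: a [wc_params()], [wc_symmetric()] (with
#'   attribute \code{N}), a list for the spatial scenarios (fields
#'   \code{params}, \code{stimulus}, \code{sigma}), or a plain list for
#'   \code{branching_critical}.
#' @export
wc_preset <- function(name) {
  switch(name,
    fig10_nodes = wc_params(
      tau = 10, r = 1,
      w_EE = 12, w_EI = 4, w_IE = 13, w_II = 11,
      h_E = 0, h_I = 0,
      f_E = firing_rate("logistic_shifted", gain = 1.2, threshold = 2.8),
      f_I = firing_rate("logistic_shifted", gain = 1, threshold = 4)),
    fig10_limit_cycle = wc_params(
      tau = 10, r = 1,
      w_EE = 16, w_EI = 12, w_IE = 15, w_II = 3,
      h_E = 1.25, h_I = 0,
      f_E = firing_rate("logistic_shifted", gain = 1.3, threshold = 4),
      f_I = firing_rate("logistic_shifted", gain = 2, threshold = 3.7)),
    benayoun_low = structure(
      wc_symmetric(w_0 = 0.2, w_sum = 0.8, h = 0.001, alpha = 0.1,
                   f = firing_rate("rectified_saturating",
                                   rate_scale = 1, I_TH = 1)),
      N = 800L),
    benayoun_high = structure(
      wc_symmetric(w_0 = 0.2, w_sum = 13.8, h = 0.001, alpha = 0.1,
                   f = firing_rate("rectified_saturating",
                                   rate_scale = 1, I_TH = 1)),
      N = 800L),
    fig21_weak = fig21_scenario("weak"),
    fig21_strong = fig21_scenario("strong"),
    branching_critical = list(m = 1, n_trials = 1e5, max_size = 1e5),
    stop("unknown preset: ", name)
  )
}

#' Catalog of shipped presets
#'
#' @return data.frame with columns \code{name}, \code{kind},
#'   \code{note}.
#' @export
list_presets <- function() {
  data.frame(
    name = c("fig10_nodes", "fig10_limit_cycle", "benayoun_low",
             "benayoun_high", "fig21_weak", "fig21_strong",
             "branching_critical"),
    kind = c("wc_params", "wc_params", "wc_symmetric", "wc_symmetric",
             "spatial_scenario", "spatial_scenario", "branching"),
    note = c(
      "multiple stable nodes; classical sigmoid presets",
      "limit cycle, h_E = 1.25; classical sigmoid presets",
      "symmetric E/I family, w_0=0.2, w_E+w_I=0.8, h=0.001, N=800",
      "balanced avalanche regime, w_0=0.2, w_E+w_I=13.8, h=0.001, N=800",
      "weak pulse -> propagating decaying wave (calibrated)",
      "strong pulse -> localized response (calibrated)",
      "critical Galton-Watson, Poisson(1) offspring, 1e5 trials"),
    stringsAsFactors = FALSE)
}

#' Resting vs driven pair-correlation scenario
#'
#' Calibrated 1-D setups for comparing spatial pair correlations at
#' rest and under a uniform external drive, for the two noise routes:
#' \describe{
#'   \item{additive}{mean-field spatial equations plus delta-correlated
#'     Gaussian noise per site (linear fluctuation regime).  At rest
#'     the recurrent gain is high (f' large near threshold) and noise
#'     is spatially smoothed over an amplified length; the drive pushes
#'     the sigmoid toward saturation, cutting f', so correlations both
#'     weaken and shorten.}
#'   \item{intrinsic}{a chain of local E/I pools simulated exactly with
#'     the Gillespie algorithm; the multiplicative demographic noise is
#'     spatially shared through the coupling kernel, and a drive
#'     saturates the activation rate with the same decorrelating
#'     effect.}
#' }
#' All values are calibrations of this package (the comparison is
#' qualitative in the source material).
#'
#' @param noise "additive" or "intrinsic".
#' @return List with the simulation pieces: for additive,
#'   \code{params}, \code{init}, \code{noise_sd}, \code{h_drive},
#'   \code{T}, \code{dt}, \code{stride}, \code{transient},
#'   \code{max_distance}; for intrinsic, \code{params} (a
#'   [stoch_lattice_params()]), \code{h_drive}, \code{T},
#'   \code{sample_dt}, \code{transient}, \code{max_distance}.
#' @export
correlation_scenario <- function(noise = c("additive", "intrinsic")) {
  noise <- match.arg(noise)
  if (noise == "additive") {
    sigma <- 100
    lat <- wc_lattice(dim = 1, n = 64, dx = 25, boundary = "periodic")
    base <- wc_params(
      tau = 10, r = 0, h_E = 0.05, h_I = 0.05,
      f_E = firing_rate("logistic_shifted", gain = 1, threshold = 0),
      f_I = firing_rate("logistic_shifted", gain = 1, threshold = 0))
    sp <- wc_spatial_params(
      base,
      beta_EE = kernel_from_weight(6.5, sigma = sigma),
      beta_EI = kernel_from_weight(3.5, sigma = sigma),
      beta_IE = kernel_from_weight(6.5, sigma = sigma),
      beta_II = kernel_from_weight(3.5, sigma = sigma),
      lattice = lat)
    # uniform resting state of the homogeneous reduction
    fp <- wc_fixed_points(wc_params(
      tau = 10, r = 0, w_EE = 6.5, w_EI = 3.5, w_IE = 6.5, w_II = 3.5,
      h_E = 0.05, h_I = 0.05, f_E = base$f_E,
      f_I = base$f_I))[[1]]$location
    list(params = sp, init = list(E = fp[["E"]], I = fp[["I"]]),
         noise_sd = 0.02, h_drive = 0.7, T = 600, dt = 0.1,
         stride = 10L, transient = 100L, max_distance = 500)
  } else {
    sym <- wc_symmetric(w_0 = 0.2, w_sum = 1.6, h = 0.05, alpha = 0.1)
    lat <- wc_lattice(dim = 1, n = 32, dx = 50, boundary = "periodic")
    list(params = stoch_lattice_params(sym, lat, N_site = 24,
                                       sigma = 200),
         h_drive = 0.1, T = 500, sample_dt = 1, transient = 50L,
         max_distance = 500)
  }
}

# Calibrated 1-D field scenario used by the wave-metrology presets.
# Excitatory kernel integral 3.2 with f_E'(0) = 0.25 gives a linear
# recurrent gain of 0.8: sub-critical, so a weak pulse launches a
# decaying wave transported by repeated kernel convolutions (measured
# speed ~0.16 mm/ms, decay length ~2.7 mm on this lattice).  The
# inhibitory threshold (0.3) sits well above the weak response, so
# only the strong pulse recruits inhibition, which clamps the source
# before it radiates: the response then stays localized.  The domain
# is large (96 mm periodic) so no wrap-around or boundary reflection
# reaches the measurement window.
fig21_scenario <- function(which = c("weak", "strong")) {
  which <- match.arg(which)
  sigma <- 1500                         # micrometres
  lat <- wc_lattice(dim = 1, n = 256, dx = sigma / 4,
                    boundary = "periodic")
  base <- wc_params(
    tau = 10, r = 0, h_E = 0, h_I = 0,
    f_E = firing_rate("logistic_shifted", gain = 1, threshold = 0),
    f_I = firing_rate("logistic_shifted", gain = 40, threshold = 0.3))
  sp <- wc_spatial_params(
    base,
    beta_EE = kernel_from_weight(3.2, sigma = sigma, tau = base$tau),
    beta_EI = kernel_from_weight(8.0, sigma = sigma, tau = base$tau),
    beta_IE = kernel_from_weight(3.2, sigma = sigma, tau = base$tau),
    beta_II = kernel_from_weight(1.0, sigma = sigma, tau = base$tau),
    lattice = lat)
  center <- (lat$n[[1]] / 2) * lat$dx
  stim <- wc_stimulus(center = center, halfwidth = 750,
                      amplitude = if (which == "weak") 0.25 else 10,
                      onset = 1,
                      duration = if (which == "weak") 2 else 4,
                      population = "E")
  list(params = sp, stimulus = stim, sigma = sigma,
       T = 120, dt = 0.2, stride = 2L)
}
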