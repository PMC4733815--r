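#' Mean-field Wilson-Cowan parameters
#'
#' Container for the spatially homogeneous two-population model
#' \deqn{\tau \dot E = -E + (1 - rE) f_E[w_{EE}E - w_{EI}I + h_E],}
#' \deqn{\tau \dot I = -I + (1 - rI) f_I[w_{IE}E - w_{II}I + h_I].}
#' All weights are stored nonnegative; the inhibitory sign is applied
#' inside the equations.
#'
#' The derived control parameters \eqn{a = w_{EE} w_{II}} and
#' \eqn{b = w_{IE} w_{EI}} (used by the bifurcation scan) are always
#' recomputed from the weights, never stored; see [control_parameters()].
#'
#' @param tau Population time constant, ms (> 0).
#' @param r Absolute refractory period, ms (>= 0).
#' @param w_EE,w_EI,w_IE,w_II Nonnegative synaptic weights (dimensionless).
#' @param h_E,h_I External inputs (input-current units).
#' @param f_E,f_I [firing_rate()] objects for the two populations.
#' @return An object of class \code{"wc_params"}.
#' @export
wc_params <- function(tau = 10, r = 0,
                      w_EE = 0, w_EI = 0, w_IE = 0, w_II = 0,
                      h_E = 0, h_I = 0,
                      f_E = firing_rate("logistic_shifted"),
                      f_I = firing_rate("logistic_shifted")) {
  stopifnot(is.numeric(tau), tau > 0, is.numeric(r), r >= 0,
            w_EE >= 0, w_EI >= 0, w_IE >= 0, w_II >= 0,
            inherits(f_E, "firing_rate"), inherits(f_I, "firing_rate"))
  structure(list(tau = tau, r = r,
                 w_EE = w_EE, w_EI = w_EI, w_IE = w_IE, w_II = w_II,
                 h_E = h_E, h_I = h_I, f_E = f_E, f_I = f_I),
            class = "wc_params")
}

#' @export
print.wc_params <- function(x, ...) {
  cat("<wc_params> tau =", x$tau, "ms, r =", x$r, "ms\n")
  cat(sprintf("  weights: w_EE=%g w_EI=%g w_IE=%g w_II=%g\n",
              x$w_EE, x$w_EI, x$w_IE, x$w_II))
  cat(sprintf("  inputs:  h_E=%g h_I=%g\n", x$h_E, x$h_I))
  ab <- control_parameters(x)
  cat(sprintf("  control: a=%g b=%g\n", ab[["a"]], ab[["b"]]))
  invisible(x)
}

#' Bifurcation control parameters a and b
#'
#' Returns \code{c(a = w_EE * w_II, b = w_IE * w_EI)}, the two products of
#' synaptic weights that organize the bifurcation structure of the
#' mean-field equations around the Bogdanov-Takens point.
#'
#' @param p A [wc_params()] object.
#' @return Named numeric vector with elements \code{a} and \code{b}.
#' @export
control_parameters <- function(p) {
  stopifnot(inherits(p, "wc_params"))
  c(a = p$w_EE * p$w_II, b = p$w_IE * p$w_EI)
}

#' Symmetric (balanced-family) parameters
#'
#' The symmetry conditions \eqn{w_{IE} = w_{EE} = w_E}, \eqn{w_{EI} =
#' w_{II} = w_I} make both populations feel the same net current
#' \eqn{s = w_E n_E - w_I n_I + h}.  The family is parametrized by the
#' difference \eqn{w_0 = w_E - w_I} (held fixed) and the sum
#' \eqn{w_E + w_I} (the free "balance" coordinate): increasing the sum at
#' fixed \eqn{w_0} leaves the fixed point unchanged while amplifying
#' fluctuations.
#'
#' The rate form of the symmetric dynamics,
#' \deqn{\dot n = -\alpha n + (1 - n) f[s],}
#' uses an activation decay rate \eqn{\alpha} (1/ms) and no refractory
#' factor; it is the exact large-N limit of the stochastic master
#' equation.
#'
#' @param w_0 Difference \eqn{w_E - w_I} (dimensionless).
#' @param w_sum Sum \eqn{w_E + w_I} (>= |w_0|).
#' @param h External input, same to both populations.
#' @param alpha Activation decay rate, 1/ms.
#' @param f A [firing_rate()] object shared by both populations.
#' @return Object of class \code{"wc_symmetric"} with fields \code{w_E},
#'   \code{w_I}, \code{w_0}, \code{w_sum}, \code{h}, \code{alpha}, \code{f}.
#' @export
wc_symmetric <- function(w_0 = 0.2, w_sum = 0.8, h = 0.001, alpha = 0.1,
                         f = firing_rate("rectified_saturating",
                                         rate_scale = 1, I_TH = 1)) {
  stopifnot(w_sum >= abs(w_0), alpha > 0, inherits(f, "firing_rate"))
  w_E <- (w_sum + w_0) / 2
  w_I <- (w_sum - w_0) / 2
  structure(list(w_E = w_E, w_I = w_I, w_0 = w_0, w_sum = w_sum,
                 h = h, alpha = alpha, f = f),
            class = "wc_symmetric")
}

#' @export
print.wc_symmetric <- function(x, ...) {
  cat(sprintf("<wc_symmetric> w_0=%g w_E+w_I=%g (w_E=%g, w_I=%g)\n",
              x$w_0, x$w_sum, x$w_E, x$w_I))
  cat(sprintf("  h=%g alpha=%g ms^-1\n", x$h, x$alpha))
  invisible(x)
}

#' Expand symmetric parameters to the full four-weight container
#'
#' Sets \code{w_IE = w_EE = w_E} and \code{w_EI = w_II = w_I} exactly.
#' The rate form carries \code{tau = 1/alpha} and \code{r = 0} so that
#' \code{wc_rhs} on the expanded parameters reproduces the symmetric rate
#' equations up to the overall \eqn{1/\tau} vs \eqn{\alpha} convention
#' (see [sigma_delta_rhs()] for the native rate form).
#'
#' @param p A [wc_symmetric()] object.
#' @return A [wc_params()] object.
#' @export
as_wc_params <- function(p) {
  stopifnot(inherits(p, "wc_symmetric"))
  wc_params(tau = 1 / p$alpha, r = 0,
            w_EE = p$w_E, w_EI = p$w_I, w_IE = p$w_E, w_II = p$w_I,
            h_E = p$h, h_I = p$h, f_E = p$f, f_I = p$f)
}

#' Number of binary network configurations (base-ten exponent)
#'
#' A network of \code{n} binary (quiescent/activated) neurons has
#' \eqn{2^n} configurations, i.e. \eqn{10^{n \log_{10} 2}}.  For the
#' human cortex (about 5e10 neurons) the exponent itself is about
#' 1.5e10 -- the reason statistical methods are unavoidable.
#'
#' @param n_neurons Number of binary neurons.
#' @return The base-ten exponent \code{n_neurons * log10(2)}.
#' @examples
#' state_count_exponent(5e10)   # ~1.5e10
#' @export
state_count_exponent <- function(n_neurons) {
  stopifnot(is.numeric(n_neurons), n_neurons >= 0)
  n_neurons * log10(2)
}
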