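#' Logistic (sigmoid) activation function
#'
#' The classical population response function \eqn{f[n] = [1 + \exp(-n)]^{-1}
#' = \frac{1}{2}[1 + \tanh(n/2)]}, the smooth analogue of the Heaviside
#' threshold of a binary (McCulloch--Pitts) neuron when thresholds are
#' randomly distributed across the population.
#'
#' @param n Numeric vector of (dimensionless) net inputs.
#' @return Values in (0, 1); \code{logistic(0) == 0.5}.
#' @examples
#' logistic(0)          # 0.5
#' logistic(log(3))     # 0.75
#' @export
logistic <- function(n) {
  # plogis is the same function and saturates without overflow
  stats::plogis(n)
}

#' Construct a firing-rate function
#'
#' A parametrized monotone response function mapping summed synaptic input
#' to either a probability of firing (mean-field forms, bounded by 1) or a
#' transition rate in 1/ms (stochastic form, bounded by \code{rate_scale}).
#'
#' Three forms are supported:
#' \describe{
#'   \item{\code{"logistic"}}{\eqn{f(x) = 1/(1 + e^{-a(x-\theta)})}.}
#'   \item{\code{"logistic_shifted"}}{the logistic form shifted so that
#'     \eqn{f(0) = 0} exactly: \eqn{f(x) = 1/(1+e^{-a(x-\theta)}) -
#'     1/(1+e^{a\theta})}.  This is the form used inside the mean-field
#'     equations, which require a quiescent network to stay quiescent.}
#'   \item{\code{"rectified_saturating"}}{a rheobase-rectified saturating
#'     rate \eqn{f(s) = \alpha_{max}\tanh(x / I_{TH})} for \eqn{x > 0} and 0
#'     otherwise, where \eqn{x/I_{TH}} is the input current normalized by
#'     the threshold (rheobase) current.  This low-noise form is the
#'     per-neuron activation rate of the stochastic (master-equation)
#'     model.}
#' }
#'
#' @param form One of \code{"logistic"}, \code{"logistic_shifted"},
#'   \code{"rectified_saturating"}.
#' @param gain Dimensionless slope parameter \code{a > 0} (logistic forms).
#' @param threshold Input-current threshold \eqn{\theta} (logistic forms).
#' @param rate_scale Maximum transition rate in 1/ms (stochastic form).
#'   Default 1/3, i.e. a 3 ms membrane time constant.
#' @param I_TH Rheobase (threshold) current normalizer, > 0. Default 1, so
#'   the argument is the raw summed input.
#' @return An object of class \code{"firing_rate"}.
#' @seealso [eval_rate()], [eval_rate_deriv()]
#' @export
firing_rate <- function(form = c("logistic", "logistic_shifted",
                                 "rectified_saturating"),
                        gain = 1, threshold = 0,
                        rate_scale = 1 / 3, I_TH = 1) {
  form <- match.arg(form)
  stopifnot(is.numeric(gain), length(gain) == 1L, gain > 0,
            is.numeric(threshold), length(threshold) == 1L,
            is.numeric(rate_scale), length(rate_scale) == 1L, rate_scale > 0,
            is.numeric(I_TH), length(I_TH) == 1L, I_TH > 0)
  structure(list(form = form, gain = gain, threshold = threshold,
                 rate_scale = rate_scale, I_TH = I_TH),
            class = "firing_rate")
}

#' @export
print.firing_rate <- function(x, ...) {
  cat("<firing_rate>", x$form, "\n")
  if (x$form == "rectified_saturating") {
    cat("  rate_scale:", x$rate_scale, "ms^-1  I_TH:", x$I_TH, "\n")
  } else {
    cat("  gain:", x$gain, " threshold:", x$threshold, "\n")
  }
  invisible(x)
}

#' Evaluate a firing-rate function
#'
#' @param fr A [firing_rate()] object.
#' @param x Numeric vector of summed inputs (input-current units).
#' @return Probability (mean-field forms) or transition rate in 1/ms
#'   (stochastic form); monotone nondecreasing in \code{x}.
#' @examples
#' f <- firing_rate("logistic_shifted", gain = 1.2, threshold = 2.8)
#' eval_rate(f, 0)   # exactly 0
#' @export
eval_rate <- function(fr, x) {
  stopifnot(inherits(fr, "firing_rate"))
  switch(fr$form,
    logistic = logistic(fr$gain * (x - fr$threshold)),
    logistic_shifted =
      logistic(fr$gain * (x - fr$threshold)) -
        logistic(-fr$gain * fr$threshold),
    rectified_saturating =
      ifelse(x > 0, fr$rate_scale * tanh(x / fr$I_TH), 0),
    stop("unknown firing-rate form: ", fr$form)
  )
}

#' Derivative of a firing-rate function
#'
#' Closed-form derivative \eqn{f'(x)}, used by the analytic Jacobians and
#' the effective feed-forward linearization.  For the rectified form the
#' derivative is taken as 0 on the rectified branch (\eqn{x \le 0}).
#'
#' @inheritParams eval_rate
#' @return Numeric vector of derivatives, units 1/(input current) (times
#'   1/ms for the stochastic form).
#' @export
eval_rate_deriv <- function(fr, x) {
  stopifnot(inherits(fr, "firing_rate"))
  switch(fr$form,
    logistic = {
      p <- logistic(fr$gain * (x - fr$threshold))
      fr$gain * p * (1 - p)
    },
    logistic_shifted = {
      p <- logistic(fr$gain * (x - fr$threshold))
      fr$gain * p * (1 - p)
    },
    rectified_saturating =
      ifelse(x > 0,
             fr$rate_scale / fr$I_TH * (1 - tanh(x / fr$I_TH)^2), 0),
    stop("unknown firing-rate form: ", fr$form)
  )
}
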