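#' Sum/difference (sigma/delta) change of variables
#'
#' \eqn{\Sigma = (n_E + n_I)/2}, \eqn{\Delta = (n_E - n_I)/2}.  Under the
#' symmetric weight conditions this transform decouples the mean activity
#' from the E-I imbalance and exposes the effective feed-forward
#' structure of the balanced network.
#'
#' @param n_E,n_I Active fractions.
#' @return Named vector \code{c(Sigma, Delta)}.
#' @seealso [sigma_delta_inverse()]
#' @export
sigma_delta <- function(n_E, n_I) {
  c(Sigma = (n_E + n_I) / 2, Delta = (n_E - n_I) / 2)
}

#' Invert the sigma/delta transform
#'
#' @param Sigma,Delta Transformed coordinates.
#' @return Named vector \code{c(n_E, n_I)}; exact inverse of
#'   [sigma_delta()].
#' @export
sigma_delta_inverse <- function(Sigma, Delta) {
  c(n_E = Sigma + Delta, n_I = Sigma - Delta)
}

#' Right-hand side of the symmetric dynamics in sigma/delta coordinates
#'
#' \deqn{\dot\Sigma = -\alpha\Sigma + (1 - \Sigma) f[s], \qquad
#'       \dot\Delta = -\Delta(\alpha + f[s]),}
#' with the net current \eqn{s = w_0\Sigma + (w_E + w_I)\Delta + h}.
#' The \eqn{\Delta} equation has no source term: \eqn{\Delta = 0} is an
#' invariant manifold and \eqn{|\Delta|} can only shrink, which is the
#' deterministic face of the excitation-inhibition balance.
#'
#' @param state Numeric \code{c(Sigma, Delta)}.
#' @param p A [wc_symmetric()] object.
#' @return Numeric \code{c(dSigma, dDelta)} in 1/ms.
#' @export
sigma_delta_rhs <- function(state, p) {
  stopifnot(inherits(p, "wc_symmetric"))
  Sigma <- state[[1]]; Delta <- state[[2]]
  s <- p$w_0 * Sigma + p$w_sum * Delta + p$h
  fs <- eval_rate(p$f, s)
  c(Sigma = -p$alpha * Sigma + (1 - Sigma) * fs,
    Delta = -Delta * (p$alpha + fs))
}

#' Symmetric rate equations in the original (n_E, n_I) coordinates
#'
#' \deqn{\dot n_E = -\alpha n_E + (1 - n_E) f[s], \qquad
#'       \dot n_I = -\alpha n_I + (1 - n_I) f[s],}
#' with the common current \eqn{s = w_E n_E - w_I n_I + h}.  The
#' sigma/delta form ([sigma_delta_rhs()]) is this system after the
#' half-sum/half-difference change of variables.
#'
#' @param state Numeric \code{c(n_E, n_I)}.
#' @param p A [wc_symmetric()] object.
#' @return Numeric \code{c(dn_E, dn_I)} in 1/ms.
#' @export
symmetric_rhs <- function(state, p) {
  stopifnot(inherits(p, "wc_symmetric"))
  nE <- state[[1]]; nI <- state[[2]]
  s <- p$w_E * nE - p$w_I * nI + p$h
  fs <- eval_rate(p$f, s)
  c(n_E = -p$alpha * nE + (1 - nE) * fs,
    n_I = -p$alpha * nI + (1 - nI) * fs)
}

#' Analytic Jacobian of the symmetric rate equations
#'
#' @param p A [wc_symmetric()] object.
#' @param point Numeric \code{c(n_E, n_I)}.
#' @return 2x2 matrix in 1/ms; at the symmetric fixed point
#'   \eqn{(\Sigma_0, \Sigma_0)} its eigenvalues are the
#'   \eqn{-\lambda_1, -\lambda_2} of [effective_jacobian()].
#' @export
symmetric_jacobian <- function(p, point) {
  stopifnot(inherits(p, "wc_symmetric"))
  nE <- point[[1]]; nI <- point[[2]]
  s <- p$w_E * nE - p$w_I * nI + p$h
  fs <- eval_rate(p$f, s)
  dfs <- eval_rate_deriv(p$f, s)
  matrix(c(-p$alpha - fs + (1 - nE) * dfs * p$w_E,
           (1 - nI) * dfs * p$w_E,
           -(1 - nE) * dfs * p$w_I,
           -p$alpha - fs - (1 - nI) * dfs * p$w_I),
         2, 2, dimnames = list(c("n_E", "n_I"), c("n_E", "n_I")))
}

#' Stable symmetric fixed point Sigma_0
#'
#' Solves the self-consistency \eqn{\alpha\Sigma_0 = (1 - \Sigma_0)
#' f[w_0\Sigma_0 + h]} on [0, 1] by a bracketed root search.  The fixed
#' point \eqn{(\Sigma_0, 0)} (equivalently \eqn{n_E = n_I = \Sigma_0}) is
#' independent of the balance coordinate \eqn{w_E + w_I}.
#'
#' @param p A [wc_symmetric()] object.
#' @return Scalar \eqn{\Sigma_0} in [0, 1].
#' @export
symmetric_fixed_point <- function(p) {
  stopifnot(inherits(p, "wc_symmetric"))
  g <- function(S) -p$alpha * S + (1 - S) * eval_rate(p$f, p$w_0 * S + p$h)
  g0 <- g(0); g1 <- g(1)
  if (g0 == 0) return(0)
  if (sign(g0) == sign(g1)) stop("no symmetric fixed point bracketed on [0,1]")
  stats::uniroot(g, c(0, 1), tol = 1e-14)$root
}

#' Effective feed-forward Jacobian of the balanced network
#'
#' Linearization of the sigma/delta dynamics at the stable fixed point
#' \eqn{(\Sigma_0, 0)}:
#' \deqn{A = \begin{pmatrix} -\lambda_1 & w_{ff} \\ 0 & -\lambda_2
#' \end{pmatrix},}
#' with \eqn{\lambda_1 = (\alpha + f[s_0]) - (1-\Sigma_0) w_0 f'[s_0]},
#' \eqn{\lambda_2 = \alpha + f[s_0]},
#' \eqn{w_{ff} = (1-\Sigma_0)(w_E + w_I) f'[s_0]} and
#' \eqn{s_0 = w_0 \Sigma_0 + h}.  The \eqn{\lambda_1} expression is the
#' exact derivative of the \eqn{\Sigma} flow: the net-excitatory
#' recurrent feedback (\eqn{w_0 > 0}) weakens the damping of the mean
#' activity, so \eqn{\lambda_1 \le \lambda_2}, with equality at
#' \eqn{w_0 = 0}.  The matrix is upper triangular: the imbalance
#' \eqn{\Delta} drives the mean activity \eqn{\Sigma} through the
#' feed-forward weight \eqn{w_{ff}} but receives no feedback.  As
#' \eqn{w_0 \to 0} (with weak input) the eigenvalue gap closes while
#' \eqn{w_{ff}} survives and grows with \eqn{w_E + w_I} -- the
#' structure of the Bogdanov-Takens normal form, which is why the
#' balanced state is weakly stable with strongly amplified
#' fluctuations.
#'
#' The associated linear-noise amplitude is \eqn{\sqrt{\alpha\Sigma_0}}
#' per component.
#'
#' @param p A [wc_symmetric()] object.
#' @return List with \code{lambda1}, \code{lambda2}, \code{w_ff} (1/ms),
#'   \code{Sigma0}, \code{s0}, \code{noise_amplitude}
#'   (\eqn{\sqrt{\alpha\Sigma_0}}, 1/sqrt(ms)) and the 2x2 \code{matrix};
#'   class \code{"effective_jacobian"}.
#' @export
effective_jacobian <- function(p) {
  stopifnot(inherits(p, "wc_symmetric"))
  Sigma0 <- symmetric_fixed_point(p)
  s0 <- p$w_0 * Sigma0 + p$h
  fs <- eval_rate(p$f, s0)
  dfs <- eval_rate_deriv(p$f, s0)
  lambda2 <- p$alpha + fs
  lambda1 <- lambda2 - (1 - Sigma0) * p$w_0 * dfs
  w_ff <- (1 - Sigma0) * p$w_sum * dfs
  A <- matrix(c(-lambda1, 0, w_ff, -lambda2), 2, 2,
              dimnames = list(c("Sigma", "Delta"), c("Sigma", "Delta")))
  structure(list(lambda1 = lambda1, lambda2 = lambda2, w_ff = w_ff,
                 Sigma0 = Sigma0, s0 = s0,
                 noise_amplitude = sqrt(p$alpha * Sigma0),
                 matrix = A),
            class = "effective_jacobian")
}

#' @export
print.effective_jacobian <- function(x, ...) {
  cat(sprintf("<effective_jacobian> Sigma0=%.6f s0=%.6f\n", x$Sigma0, x$s0))
  cat(sprintf("  lambda1=%.6g lambda2=%.6g w_ff=%.6g (1/ms)\n",
              x$lambda1, x$lambda2, x$w_ff))
  cat(sprintf("  noise amplitude sqrt(alpha*Sigma0)=%.6g\n",
              x$noise_amplitude))
  invisible(x)
}
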