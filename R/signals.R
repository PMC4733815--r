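#' Segment-averaged power spectral density
#'
#' Welch-style estimator: the series is split into overlapping
#' segments, each mean-detrended, Hann-tapered and Fourier transformed;
#' the one-sided periodograms are averaged.  The density scaling is
#' such that the integral of the spectrum over frequency approximates
#' the series variance (Parseval).
#'
#' @param x Numeric series, uniformly sampled, length >= 256.
#' @param fs Sampling frequency, Hz.
#' @param segment_length Samples per segment (default 256).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return data.frame with columns \code{frequency} (Hz, excluding DC)
#'   and \code{power} (units^2 / Hz).
#' @export
power_spectrum <- function(x, fs, segment_length = 256, overlap = 0.5) {
  stopifnot(is.numeric(x), fs > 0,
            segment_length >= 16, overlap >= 0, overlap < 1)
  if (length(x) < 256) stop("series too short: need >= 256 samples")
  L <- min(segment_length, length(x))
  step <- max(1L, floor(L * (1 - overlap)))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))   # Hann
  U <- sum(w^2)
  acc <- numeric(L)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  acc <- acc / length(starts)
  nf <- floor(L / 2)
  psd <- acc[2:(nf + 1)] * 2 / (fs * U)   # one-sided, density scaling
  if (L %% 2 == 0) psd[nf] <- psd[nf] / 2 # Nyquist bin is not doubled
  data.frame(frequency = (1:nf) * fs / L, power = psd)
}

#' Fit a Lorentzian (Brownian-motion) spectrum
#'
#' Nonlinear least squares for \eqn{S(f) = a / (b + f^2)}, the power
#' spectrum of a random walk with decay (Ornstein-Uhlenbeck process).
#' Starting values come from a two-point method: the half-power
#' frequency gives \code{b}, the low-frequency plateau times \code{b}
#' gives \code{a}.  Narrow oscillatory peaks (e.g. alpha/beta bands)
#' should be masked out with \code{exclude} before fitting.
#'
#' @param frequency,power Spectrum samples (Hz, power units).
#' @param f_range Fit window \code{c(lo, hi)} in Hz; default all.
#' @param exclude List of \code{c(lo, hi)} bands to mask out.
#' @return Object of class \code{"lorentzian_fit"} with \code{a},
#'   \code{b}, \code{residual_norm}, \code{n}.
#' @export
fit_lorentzian <- function(frequency, power, f_range = NULL,
                           exclude = NULL) {
  stopifnot(length(frequency) == length(power))
  keep <- rep(TRUE, length(frequency))
  if (!is.null(f_range)) {
    keep <- keep & frequency >= f_range[[1]] & frequency <= f_range[[2]]
  }
  if (!is.null(exclude)) {
    for (band in exclude) {
      keep <- keep & !(frequency >= band[[1]] & frequency <= band[[2]])
    }
  }
  f <- frequency[keep]; S <- power[keep]
  if (length(f) < 10) stop("need at least 10 spectrum points in range")
  S0 <- max(S)
  f_half <- f[which.min(abs(S - S0 / 2))]
  b0 <- max(f_half^2, 1e-6)
  a0 <- S0 * b0
  fit <- minpack.lm::nlsLM(S ~ a / (b + f^2),
                           start = list(a = a0, b = b0),
                           lower = c(1e-12, 1e-12),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200))
  if (!fit$convInfo$isConv) {
    stop("Lorentzian fit did not converge; residual norm ",
         signif(sqrt(sum(stats::residuals(fit)^2)), 4))
  }
  co <- stats::coef(fit)
  structure(list(a = unname(co[["a"]]), b = unname(co[["b"]]),
                 residual_norm = sqrt(sum(stats::residuals(fit)^2)),
                 n = length(f)),
            class = "lorentzian_fit")
}

#' @export
print.lorentzian_fit <- function(x, ...) {
  cat(sprintf("<lorentzian_fit> S(f) = %.6g / (%.6g + f^2)  [n=%d, resid %.3g]\n",
              x$a, x$b, x$n, x$residual_norm))
  invisible(x)
}

#' Zero-lag pair correlation against distance
#'
#' Pearson correlation at lag zero for every pair of lattice sites,
#' averaged within distance bins.  Sites with (numerically) constant
#' series are excluded.
#'
#' @param series Matrix, time x site.
#' @param lattice A [wc_lattice()] describing site geometry, or a
#'   numeric matrix/vector of site positions in micrometres.
#' @param max_distance Largest separation retained, micrometres
#'   (default all).
#' @param bin Distance bin width, micrometres; defaults to the lattice
#'   spacing.
#' @param transient Number of leading samples discarded.
#' @return Object of class \code{"correlation_profile"}: data.frame
#'   \code{profile} with \code{distance_mm}, \code{correlation},
#'   \code{n_pairs}; and \code{excluded_sites}.
#' @export
pair_correlation <- function(series, lattice, max_distance = Inf,
                             bin = NULL, transient = 0L) {
  stopifnot(is.matrix(series))
  pos <- if (inherits(lattice, "wc_lattice")) {
    site_positions(lattice)
  } else {
    as.matrix(lattice)
  }
  stopifnot(nrow(pos) == ncol(series))
  if (is.null(bin)) {
    bin <- if (inherits(lattice, "wc_lattice")) lattice$dx else
      min(stats::dist(pos))
  }
  if (transient > 0L) series <- series[-seq_len(transient), , drop = FALSE]
  sds <- apply(series, 2, stats::sd)
  ok <- is.finite(sds) & sds > 1e-12
  excluded <- which(!ok)
  series <- series[, ok, drop = FALSE]
  pos <- pos[ok, , drop = FALSE]
  if (ncol(series) < 2L) stop("need at least 2 non-constant sites")
  C <- stats::cor(series)
  if (inherits(lattice, "wc_lattice") && lattice$boundary == "periodic") {
    # shortest wrap-around separation per axis
    D2 <- 0
    for (ax in seq_len(ncol(pos))) {
      dd <- abs(outer(pos[, ax], pos[, ax], "-"))
      ext <- lattice$extent[[ax]]
      dd <- pmin(dd, ext - dd)
      D2 <- D2 + dd^2
    }
    D <- sqrt(D2)
  } else {
    D <- as.matrix(stats::dist(pos))
  }
  iu <- upper.tri(D, diag = TRUE)
  d <- D[iu]; cc <- C[iu]
  keep <- d <= max_distance
  d <- d[keep]; cc <- cc[keep]
  db <- round(d / bin) * bin
  agg <- tapply(cc, db, mean)
  npair <- tapply(cc, db, length)
  prof <- data.frame(distance_mm = as.numeric(names(agg)) / 1000,
                     correlation = as.numeric(agg),
                     n_pairs = as.integer(npair))
  prof <- prof[order(prof$distance_mm), ]
  rownames(prof) <- NULL
  structure(list(profile = prof, excluded_sites = excluded),
            class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat("<correlation_profile>", nrow(x$profile), "distance bins\n")
  print(utils::head(x$profile, 8))
  invisible(x)
}

#' Correlation length from a decaying profile
#'
#' Exponential fit \eqn{c(d) = c_0 e^{-d/\ell}} to a pair-correlation
#' profile; returns the length scale \eqn{\ell} in mm.
#'
#' @param profile A [pair_correlation()] result or a data.frame with
#'   \code{distance_mm} and \code{correlation} columns.
#' @param min_correlation Points below this value are dropped before
#'   the log-linear fit (correlations near or below zero carry no
#'   length information).
#' @return Correlation length, mm.
#' @export
correlation_length <- function(profile, min_correlation = 1e-3) {
  prof <- if (inherits(profile, "correlation_profile")) {
    profile$profile
  } else {
    profile
  }
  prof <- prof[is.finite(prof$correlation) &
                 prof$correlation > min_correlation, , drop = FALSE]
  if (nrow(prof) < 3L) stop("too few positive-correlation points")
  fit <- stats::lm(log(correlation) ~ distance_mm, data = prof)
  slope <- stats::coef(fit)[["distance_mm"]]
  if (!is.finite(slope) || slope >= -1e-9) {
    stop("profile does not decay; no correlation length")
  }
  -1 / slope
}
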