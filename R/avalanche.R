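#' Mean inter-spike interval of a raster
#'
#' Mean difference of consecutive activation times, both populations
#' pooled; deactivation events are ignored.  This is the natural bin
#' width for avalanche extraction: at this resolution the average frame
#' holds one spike, so blank frames delimit bursts.
#'
#' @param r A [gillespie()] raster (or any list with an \code{events}
#'   data.frame).
#' @return Mean ISI, ms.
#' @export
mean_isi <- function(r) {
  tt <- activation_times(r)
  if (length(tt) < 2L) stop("need at least 2 activation events")
  mean(diff(tt))
}

# pooled, sorted activation times of a raster
activation_times <- function(r) {
  ev <- r$events
  sort(ev$time[ev$transition == "activation"])
}

#' Bin activation events into frames
#'
#' Half-open bins \eqn{[k\Delta t, (k+1)\Delta t)}: an event exactly on
#' a boundary belongs to the right bin.
#'
#' @param r A raster (see [mean_isi()]).
#' @param dt Bin width \eqn{\Delta t}, ms; \code{"auto"} uses the mean
#'   inter-spike interval.
#' @param t_end Record end; defaults to the raster duration.
#' @return Integer vector of spike counts per frame.
#' @export
bin_raster <- function(r, dt = "auto", t_end = NULL) {
  if (identical(dt, "auto")) dt <- mean_isi(r)
  stopifnot(is.numeric(dt), dt > 0)
  tt <- activation_times(r)
  if (is.null(t_end)) t_end <- r$duration
  nb <- max(1L, ceiling(t_end / dt))
  idx <- floor(tt / dt) + 1L
  idx <- idx[idx >= 1L & idx <= nb]
  tabulate(idx, nbins = nb)
}

#' Extract avalanches from frame counts
#'
#' An avalanche is a maximal run of nonzero frames preceded and
#' followed by blank frames; its size is the summed spike count of the
#' run.  Runs touching the record edges have no bounding blank frame
#' and are discarded (their spike count is reported separately).
#'
#' @param frames Integer vector of per-frame spike counts.
#' @param dt Bin width used, ms (metadata only).
#' @return Object of class \code{"avalanche_dist"}: \code{sizes}
#'   (integer vector), \code{n_avalanches}, \code{dt},
#'   \code{edge_discarded} (spikes in discarded edge runs),
#'   \code{total_spikes}.
#' @export
extract_avalanches <- function(frames, dt = NA_real_) {
  stopifnot(is.numeric(frames), all(frames >= 0))
  active <- frames > 0
  sizes <- integer(0)
  edge <- 0L
  if (any(active)) {
    rl <- rle(active)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    for (j in seq_along(rl$values)) {
      if (!rl$values[j]) next
      run_sum <- sum(frames[starts[j]:ends[j]])
      if (starts[j] == 1L || ends[j] == length(frames)) {
        edge <- edge + run_sum      # not preceded AND followed by blanks
      } else {
        sizes <- c(sizes, run_sum)
      }
    }
  }
  structure(list(sizes = as.integer(sizes),
                 n_avalanches = length(sizes),
                 dt = dt, edge_discarded = as.integer(edge),
                 total_spikes = as.integer(sum(frames))),
            class = "avalanche_dist")
}

#' @export
print.avalanche_dist <- function(x, ...) {
  cat(sprintf("<avalanche_dist> %d avalanches (dt = %s ms)\n",
              x$n_avalanches, format(x$dt)))
  if (x$n_avalanches) {
    cat(sprintf("  sizes: min %d, median %g, max %d; %d edge spikes discarded\n",
                min(x$sizes), stats::median(x$sizes), max(x$sizes),
                x$edge_discarded))
  }
  invisible(x)
}

#' Avalanches straight from a raster
#'
#' Convenience wrapper: bin at the mean inter-spike interval (or a
#' given dt) and extract blank-frame-delimited avalanches.
#'
#' @inheritParams bin_raster
#' @return An \code{"avalanche_dist"} object.
#' @export
avalanches_from_raster <- function(r, dt = "auto") {
  if (identical(dt, "auto")) dt <- mean_isi(r)
  extract_avalanches(bin_raster(r, dt), dt = dt)
}

# logarithmic bins over the integer support [x_min, x_max]
log_bins <- function(x_min, x_max, ratio) {
  edges <- x_min * ratio^(0:ceiling(log(x_max / x_min + 1e-12) /
                                      log(ratio) + 1))
  edges <- edges[edges / ratio <= x_max]
  if (length(edges) < 2L) edges <- c(x_min, x_min * ratio)
  lo <- edges[-length(edges)]
  hi <- pmin(edges[-1], x_max + 1)      # clamp the last (partial) bin
  supp <- lapply(seq_along(lo), function(i) {
    s <- ceiling(lo[i]):(ceiling(hi[i]) - 1)
    s[s >= lo[i] & s < hi[i]]
  })
  supp[vapply(supp, length, integer(1)) > 0L]
}

#' Least-squares power-law fit to an avalanche size distribution
#'
#' Fits a straight line to log10(PMF) against log10(size): the PMF is
#' estimated on logarithmically spaced bins (count / (n * integer bin
#' support)), each bin is placed at the representative size where a
#' power law equals its bin average (computed by a short fixed-point
#' iteration on the exponent -- with the plain geometric-mean abscissa
#' the small discrete bins bow the line and bias the slope), and the
#' regression is weighted by bin counts so that sparse tail bins,
#' whose log is biased downward, do not tilt the fit.  Only bins
#' holding at least \code{min_count} sizes enter.  The slope is the
#' avalanche exponent (negative for a decaying distribution).
#'
#' @param d An \code{"avalanche_dist"} or a numeric vector of sizes.
#' @param x_min,x_max Fit range; \code{x_max = NULL} extends to the
#'   last bin with at least \code{min_count} sizes.
#' @param ratio Log-bin ratio (default octaves).
#' @param min_count Minimum sizes per usable bin (default 5).
#' @return Object of class \code{"power_law_fit"}: \code{exponent},
#'   \code{se}, \code{r_squared}, \code{x_min}, \code{x_max},
#'   \code{bins}, \code{n}.
#' @export
fit_power_law <- function(d, x_min = 1, x_max = NULL, ratio = 2,
                          min_count = 5) {
  sizes <- if (inherits(d, "avalanche_dist")) d$sizes else d
  stopifnot(length(sizes) > 0, all(sizes >= 1))
  if (length(sizes) < 100) {
    warning("fewer than 100 sizes; exponent estimate will be noisy")
  }
  upper <- if (is.null(x_max)) max(sizes) else x_max
  sizes_in <- sizes[sizes >= x_min & sizes <= upper]
  supp <- log_bins(x_min, upper, ratio)
  count <- vapply(supp, function(s) sum(sizes_in %in% s), numeric(1))
  if (is.null(x_max)) {
    # default range ends at the last bin still holding min_count sizes
    ok <- count >= min_count
    last <- if (any(!ok)) which(!ok)[1] - 1L else length(count)
  } else {
    last <- max(which(count >= min_count), 0L)
  }
  if (last < 2L) stop("fewer than 2 usable bins")
  supp <- supp[seq_len(last)]; count <- count[seq_len(last)]
  use <- count >= min_count
  supp <- supp[use]; count <- count[use]
  if (length(supp) < 2L) stop("fewer than 2 usable bins")
  width <- vapply(supp, length, numeric(1))
  pmf <- count / (length(sizes_in) * width)
  g <- -1.5
  for (it in 1:6) {
    x <- vapply(supp, function(s) mean(s^g)^(1 / g), numeric(1))
    fit <- stats::lm(log10(pmf) ~ log10(x), weights = count)
    g_new <- unname(stats::coef(fit)[2])
    if (abs(g_new - g) < 1e-10) { g <- g_new; break }
    g <- g_new
  }
  sm <- summary(fit)
  bins <- data.frame(
    x = x,
    lo = vapply(supp, min, numeric(1)),
    hi = vapply(supp, max, numeric(1)),
    count = count, width = width, pmf = pmf)
  structure(list(exponent = g,
                 se = sm$coefficients[2, 2],
                 r_squared = sm$r.squared,
                 x_min = x_min, x_max = max(bins$hi),
                 bins = bins, n = length(sizes_in)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> exponent %.3f (se %.3f, R2 %.3f) over [%g, %g], n = %d\n",
              x$exponent, x$se, x$r_squared, x$x_min, x$x_max, x$n))
  invisible(x)
}

#' Maximum-likelihood discrete power-law exponent (cross-check)
#'
#' ML estimate of gamma for \eqn{P(n) \propto n^{-\gamma}} on the
#' truncated integer support \code{[x_min, x_max]}, by direct
#' optimization of the log likelihood with the finite normalizing sum.
#' Provided as an independent check on the least-squares slope, which
#' is the headline estimator here.
#'
#' @inheritParams fit_power_law
#' @return List with \code{exponent} (reported negative, as a slope)
#'   and \code{loglik}.
#' @export
fit_power_law_ml <- function(d, x_min = 1, x_max = NULL) {
  sizes <- if (inherits(d, "avalanche_dist")) d$sizes else d
  if (is.null(x_max)) x_max <- max(sizes)
  sizes <- sizes[sizes >= x_min & sizes <= x_max]
  stopifnot(length(sizes) > 1)
  supp <- x_min:x_max
  nll <- function(g) {
    logZ <- log(sum(supp^(-g)))
    -(-g * sum(log(sizes)) - length(sizes) * logZ)
  }
  opt <- stats::optimize(nll, c(0.01, 6))
  list(exponent = -opt$minimum, loglik = -opt$objective)
}

#' Geometric fit to avalanche sizes
#'
#' Maximum-likelihood geometric distribution on support 1, 2, ...:
#' \eqn{P(n) = p(1-p)^{n-1}} with \eqn{\hat p = 1/\bar n}.
#'
#' @param d An \code{"avalanche_dist"} or numeric sizes.
#' @return Object of class \code{"geometric_fit"} with \code{p} and
#'   \code{loglik}.
#' @export
fit_geometric <- function(d) {
  sizes <- if (inherits(d, "avalanche_dist")) d$sizes else d
  stopifnot(length(sizes) > 0, all(sizes >= 1))
  p <- 1 / mean(sizes)
  ll <- sum(log(p) + (sizes - 1) * log1p(-p))
  structure(list(p = p, loglik = ll), class = "geometric_fit")
}

#' @export
print.geometric_fit <- function(x, ...) {
  cat(sprintf("<geometric_fit> p = %.4f (loglik %.2f)\n", x$p, x$loglik))
  invisible(x)
}

#' Compare power-law and geometric models by likelihood
#'
#' Both models are evaluated as proper discrete likelihoods on the same
#' truncated support \code{[1, max(size)]}; the log-likelihood ratio
#' (power law minus geometric) decides the preferred model.
#'
#' @param d An \code{"avalanche_dist"} or numeric sizes.
#' @return List with \code{preferred} ("power_law" or "geometric"),
#'   \code{log_likelihood_ratio}, and both fits.
#' @export
compare_fits <- function(d) {
  sizes <- if (inherits(d, "avalanche_dist")) d$sizes else d
  geo <- fit_geometric(sizes)
  supp <- 1:max(sizes)
  # geometric likelihood renormalized on the truncated support
  geo_p <- geo$p * (1 - geo$p)^(supp - 1)
  geo_ll <- sum(log(geo_p[sizes] / sum(geo_p)))
  pl <- fit_power_law_ml(sizes)
  lr <- pl$loglik - geo_ll
  list(preferred = if (lr > 0) "power_law" else "geometric",
       log_likelihood_ratio = lr,
       power_law = pl, geometric = geo)
}

#' Critical branching-process avalanche sizes (Galton-Watson)
#'
#' Total progeny of independent Galton-Watson trees with Poisson(m)
#' offspring.  At the critical mean m = 1 the size distribution follows
#' the mean-field avalanche law \eqn{P(n) \sim n^{-3/2}}.  Trees are
#' truncated at \code{max_size} nodes; truncated trials are flagged so
#' they can be excluded from fits.
#'
#' @param m Mean offspring number (>= 0).
#' @param n_trials Number of independent trees.
#' @param max_size Truncation cap on total progeny.
#' @param seed RNG seed.
#' @return List with \code{sizes} (total progeny per completed tree)
#'   and \code{truncated} (logical per trial).
#' @export
branching_avalanches <- function(m, n_trials, max_size = 1e5,
                                 seed = 1L) {
  stopifnot(m >= 0, n_trials >= 1, max_size >= 1)
  set.seed(seed)
  total <- rep(1L, n_trials)
  z <- rep(1L, n_trials)                 # current generation sizes
  repeat {
    alive <- which(z > 0L & total < max_size)
    if (!length(alive)) break
    z_new <- stats::rpois(length(alive), m * z[alive])
    z[alive] <- z_new
    total[alive] <- total[alive] + z_new
  }
  truncated <- total >= max_size
  list(sizes = total[!truncated], truncated = truncated)
}
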