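#' Read a flat key = value configuration file
#'
#' Line-oriented TOML-like format: one \code{key = value} pair per
#' line, \code{#} comments, blank lines ignored.  Values that parse as
#' numbers become numeric; quoted or bare words stay character.
#' Unknown keys are rejected so typos fail loudly.
#'
#' @param path File path.
#' @return Named list of class \code{"wc_config"}.
#' @seealso [write_wc_config()], [config_to_params()]
#' @export
read_wc_config <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("malformed config line: ", ln)
    key <- m[2]
    val <- trimws(m[3])
    val <- gsub('^"|"$', "", val)
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  validate_config(cfg)
  structure(cfg, class = "wc_config")
}

# known configuration keys and simple range checks
config_keys <- function() {
  c("model", "preset", "T", "dt", "seed", "out",
    "N_E", "N_I", "N", "tau", "r", "alpha",
    "w_0", "w_sum", "w_EE", "w_EI", "w_IE", "w_II",
    "h", "h_E", "h_I",
    "f_E_form", "f_E_gain", "f_E_threshold", "f_E_rate_scale",
    "f_E_I_TH",
    "f_I_form", "f_I_gain", "f_I_threshold", "f_I_rate_scale",
    "f_I_I_TH")
}

validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), config_keys())
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  positive <- c("T", "dt", "tau", "alpha", "N_E", "N_I", "N")
  for (k in intersect(names(cfg), positive)) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0) {
      stop("config key '", k, "' must be a positive number")
    }
  }
  nonneg <- c("r", "w_EE", "w_EI", "w_IE", "w_II", "w_sum")
  for (k in intersect(names(cfg), nonneg)) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0) {
      stop("config key '", k, "' must be a nonnegative number")
    }
  }
  invisible(cfg)
}

#' Write a configuration file
#'
#' @param cfg Named list (validated against the known key set).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_wc_config <- function(cfg, path) {
  validate_config(cfg)
  fmt <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    if (is.numeric(v)) {
      sprintf("%s = %s", k, format(v, digits = 15))
    } else {
      sprintf('%s = "%s"', k, v)
    }
  }, character(1))
  writeLines(fmt, path)
  invisible(path)
}

# build a firing_rate from config keys with a prefix ("f_E" / "f_I")
config_firing_rate <- function(cfg, prefix, default) {
  form <- cfg[[paste0(prefix, "_form")]]
  if (is.null(form)) return(default)
  firing_rate(form,
              gain = cfg[[paste0(prefix, "_gain")]] %||% 1,
              threshold = cfg[[paste0(prefix, "_threshold")]] %||% 0,
              rate_scale = cfg[[paste0(prefix, "_rate_scale")]] %||% (1 / 3),
              I_TH = cfg[[paste0(prefix, "_I_TH")]] %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve a configuration into model parameters
#'
#' A \code{preset} key expands to the named preset (explicit keys are
#' not allowed alongside it); otherwise the parameter keys are
#' assembled into the container selected by \code{model}
#' ("ode" -> [wc_params()], "sigma_delta" -> [wc_symmetric()],
#' "ssa" -> [stoch_params()]).
#'
#' @param cfg A [read_wc_config()] result (or compatible list).
#' @return A parameter object.
#' @export
config_to_params <- function(cfg) {
  if (!is.null(cfg$preset)) {
    return(wc_preset(cfg$preset))
  }
  model <- cfg$model %||% "ode"
  if (model == "ode") {
    wc_params(tau = cfg$tau %||% 10, r = cfg$r %||% 0,
              w_EE = cfg$w_EE %||% 0, w_EI = cfg$w_EI %||% 0,
              w_IE = cfg$w_IE %||% 0, w_II = cfg$w_II %||% 0,
              h_E = cfg$h_E %||% 0, h_I = cfg$h_I %||% 0,
              f_E = config_firing_rate(cfg, "f_E",
                                       firing_rate("logistic_shifted")),
              f_I = config_firing_rate(cfg, "f_I",
                                       firing_rate("logistic_shifted")))
  } else if (model == "sigma_delta") {
    wc_symmetric(w_0 = cfg$w_0 %||% 0.2, w_sum = cfg$w_sum %||% 0.8,
                 h = cfg$h %||% 0.001, alpha = cfg$alpha %||% 0.1,
                 f = config_firing_rate(
                   cfg, "f_E",
                   firing_rate("rectified_saturating",
                               rate_scale = 1, I_TH = 1)))
  } else if (model == "ssa") {
    sym <- wc_symmetric(w_0 = cfg$w_0 %||% 0.2,
                        w_sum = cfg$w_sum %||% 0.8,
                        h = cfg$h %||% 0.001, alpha = cfg$alpha %||% 0.1,
                        f = config_firing_rate(
                          cfg, "f_E",
                          firing_rate("rectified_saturating",
                                      rate_scale = 1, I_TH = 1)))
    stoch_params_from_symmetric(sym, N_E = cfg$N_E %||% cfg$N %||% 800,
                                N_I = cfg$N_I %||% cfg$N %||% 800)
  } else {
    stop("unknown model: ", model)
  }
}

#' Write an event raster to a tab-separated file
#'
#' Header lines prefixed \code{#} record the population sizes, the
#' duration and the seed; then one line per event:
#' \code{time_ms  neuron_id  population  transition}.
#'
#' @param r A [gillespie()] raster.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_raster <- function(r, path) {
  stopifnot(inherits(r, "wc_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# wcdyn raster",
    sprintf("# N_E=%d", r$N_E),
    sprintf("# N_I=%d", r$N_I),
    sprintf("# duration_ms=%.10g", r$duration),
    sprintf("# seed=%d", r$seed),
    sprintf("# init_n_E=%d", r$init[["n_E"]]),
    sprintf("# init_n_I=%d", r$init[["n_I"]]),
    "time_ms\tneuron_id\tpopulation\ttransition"), con)
  ev <- r$events
  writeLines(sprintf("%.10g\t%s\t%s\t%s", ev$time,
                     ifelse(is.na(ev$neuron_id), "NA", ev$neuron_id),
                     ev$population, ev$transition), con)
  invisible(path)
}

#' Read an event raster written by [write_raster()]
#'
#' @param path File path.
#' @return A \code{"wc_raster"} object.
#' @export
read_raster <- function(path) {
  stopifnot(file.exists(path))
  hdr <- readLines(path, n = 64)
  hdr <- hdr[startsWith(hdr, "#")]
  get <- function(key, default = NA) {
    m <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(m)) return(default)
    as.numeric(sub(paste0("^# ", key, "="), "", m[[1]]))
  }
  ev <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  names(ev) <- c("time", "neuron_id", "population", "transition")
  structure(list(events = ev,
                 N_E = as.integer(get("N_E", 0)),
                 N_I = as.integer(get("N_I", 0)),
                 duration = get("duration_ms"),
                 seed = as.integer(get("seed", NA)),
                 init = c(n_E = as.integer(get("init_n_E", 0)),
                          n_I = as.integer(get("init_n_I", 0))),
                 absorbed = FALSE),
            class = "wc_raster")
}

#' Sample from a truncated discrete power law
#'
#' Inverse-CDF sampling of \eqn{P(n) \propto n^{exponent}} on the
#' integer support \code{[x_min, x_max]} (exponent negative).  Used to
#' plant ground-truth distributions for estimator checks.
#'
#' @param n Number of draws.
#' @param exponent Power-law exponent (e.g. -1.5).
#' @param x_min,x_max Integer support bounds.
#' @param seed Optional RNG seed.
#' @return Integer vector of draws.
#' @export
sample_power_law <- function(n, exponent, x_min = 1, x_max = 1e4,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  supp <- x_min:x_max
  cdf <- cumsum(supp^exponent)
  cdf <- cdf / cdf[length(cdf)]
  supp[findInterval(stats::runif(n), cdf) + 1L]
}

#' Build a planted decaying-wave field history
#'
#' Synthetic history \eqn{A e^{-d/\lambda_0}\, g(t - d/v_0)} with a
#' Gaussian temporal pulse g, used as the ground-truth input for wave
#' metrology checks (recovery of \eqn{\lambda_0} and \eqn{v_0}).
#'
#' @param lambda0_mm Planted decay length, mm.
#' @param v0_mm_ms Planted speed, mm/ms.
#' @param n,dx Lattice size and spacing (micrometres).
#' @param T,dt Duration and sampling step, ms.
#' @param A Peak amplitude.
#' @param pulse_sd Temporal width of the pulse, ms.
#' @return A \code{"field_history"}-compatible object (E field only;
#'   I is zero).
#' @export
planted_wave_history <- function(lambda0_mm = 3, v0_mm_ms = 0.3,
                                 n = 81, dx = 250, T = 60, dt = 0.25,
                                 A = 1, pulse_sd = 1.5) {
  lat <- wc_lattice(dim = 1, n = n, dx = dx, boundary = "periodic")
  center <- ((n - 1) %/% 2) * dx
  pos <- site_positions(lat)[, 1]
  d_mm <- abs(pos - center) / 1000
  times <- seq(0, T, by = dt)
  onset <- 3
  E <- outer(times, d_mm, function(t, d) {
    A * exp(-d / lambda0_mm) *
      exp(-((t - onset - d / v0_mm_ms)^2) / (2 * pulse_sd^2))
  })
  structure(list(times = times, E = E, I = 0 * E, lattice = lat,
                 stimulus = wc_stimulus(center = center,
                                        halfwidth = dx,
                                        amplitude = A,
                                        onset = onset, duration = 1,
                                        population = "E"),
                 dt = dt, stride = 1L),
            class = "field_history")
}

#' Generate deterministic test fixtures
#'
#' Writes small plain-text inputs with a JSON manifest of the planted
#' ground truth: an event raster from a short stochastic run, a
#' planted power-law size sample, a planted Lorentzian spectrum, and a
#' planted decaying-wave field history.  Regenerating with the same
#' seed reproduces the files byte for byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, the manifest list.
#' @export
generate_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed)

  sym <- wc_symmetric(w_0 = 0.2, w_sum = 0.8, h = 0.05, alpha = 0.1)
  sp <- stoch_params_from_symmetric(sym, N_E = 40, N_I = 40)
  r <- gillespie(sp, T = 40, init = c(10, 10), seed = seed,
                 record_ids = TRUE)
  write_raster(r, file.path(out_dir, "raster.tsv"))
  manifest$raster <- list(file = "raster.tsv", N_E = 40, N_I = 40,
                          n_events = nrow(r$events))

  sizes <- sample_power_law(2000, -1.5, 1, 1000, seed = seed)
  utils::write.csv(data.frame(size = sizes),
                   file.path(out_dir, "power_law_sizes.csv"),
                   row.names = FALSE)
  manifest$power_law <- list(file = "power_law_sizes.csv",
                             exponent = -1.5, x_min = 1, x_max = 1000,
                             n = 2000)

  f <- seq(0.5, 100, by = 0.5)
  spec <- data.frame(frequency = f, power = 75 / (3 + f^2))
  utils::write.csv(spec, file.path(out_dir, "lorentzian_spectrum.csv"),
                   row.names = FALSE)
  manifest$lorentzian <- list(file = "lorentzian_spectrum.csv",
                              a = 75, b = 3)

  h <- planted_wave_history(lambda0_mm = 3, v0_mm_ms = 0.3,
                            n = 41, dx = 500, T = 50, dt = 0.5)
  wave <- data.frame(
    t = rep(h$times, times = ncol(h$E)),
    site = rep(seq_len(ncol(h$E)), each = nrow(h$E)),
    value = as.vector(h$E))
  utils::write.csv(wave, file.path(out_dir, "wave_history.csv"),
                   row.names = FALSE)
  manifest$wave <- list(file = "wave_history.csv", lambda0_mm = 3,
                        v0_mm_ms = 0.3, n = 41, dx = 500,
                        T = 50, dt = 0.5)

  jsonlite::write_json(manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
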