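#' Band kinetic description for the synthetic generator
#'
#' One vibrational band with a per-day amplitude trajectory. Together with the
#' background model these define the noiseless "true" spectrum of each culture
#' day, against which recovery of kinetics by the analysis chain is judged.
#'
#' @param center Band center (cm^-1), within [300, 3100].
#' @param width Full width at half maximum (cm^-1), > 0.
#' @param amplitude_by_day Non-negative amplitudes, one per simulated day.
#' @param shape `"gaussian"` (default) or `"lorentzian"` peak profile.
#' @param label Optional band label (e.g. `"1524"`).
#' @return A `band_kinetic` list.
#' @export
band_kinetic <- function(center, width, amplitude_by_day,
                         shape = c("gaussian", "lorentzian"), label = NULL) {
  shape <- match.arg(shape)
  if (center < 300 || center > 3100)
    stop("band center must lie within [300, 3100] cm^-1", call. = FALSE)
  if (width <= 0) stop("band width must be positive", call. = FALSE)
  if (any(amplitude_by_day < 0))
    stop("band amplitudes must be non-negative", call. = FALSE)
  structure(list(center = center, width = width,
                 amplitude_by_day = as.numeric(amplitude_by_day),
                 shape = shape,
                 label = if (is.null(label)) as.character(round(center)) else label),
            class = "band_kinetic")
}

# Piecewise-linear day trajectory through (day, amplitude) nodes,
# held constant beyond the outermost nodes.
trajectory_nodes <- function(days, node_days, node_amps)
  stats::approx(node_days, node_amps, xout = seq_len(days) - 1, rule = 2)$y

#' Full generative description of a synthetic culture run
#'
#' @param days Number of culture days (>= 1).
#' @param sessions_per_day Acquisition sessions per day (>= 1).
#' @param spectra_per_session Spectra per session (>= 1).
#' @param bands List of [band_kinetic()] objects; each `amplitude_by_day`
#'   must have length `days`.
#' @param axis_min,axis_max,axis_step Wavenumber axis (cm^-1).
#' @param baseline_coeffs Polynomial coefficients (intensity units) of the
#'   broad fluorescence background, in the scaled coordinate
#'   u = (x - axis_min) / (axis_max - axis_min): baseline = sum c_k u^k.
#' @param baseline_decay Optional decay constant (per cm^-1) of an additional
#'   exponentially decaying background term.
#' @param baseline_exp_amp Amplitude (intensity units) of the exponential
#'   background term; 0 disables it.
#' @param noise_sd Additive white-noise standard deviation (intensity units).
#' @param replicate_jitter_sd Standard deviation of the multiplicative
#'   per-spectrum scale jitter applied to the band component (dimensionless).
#' @param nitrogen_depletion_day Day index at which pigment bands switch from
#'   rising to declining and storage-lipid bands from flat to rising.
#' @param seed Integer RNG seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(days, sessions_per_day, spectra_per_session,
                              bands,
                              axis_min = 300, axis_max = 3100, axis_step = 2,
                              baseline_coeffs = c(0, 0, 0),
                              baseline_decay = NULL, baseline_exp_amp = 0,
                              noise_sd = 0, replicate_jitter_sd = 0,
                              nitrogen_depletion_day = 0, seed = 1L) {
  cfg <- structure(list(
    days = as.integer(days), sessions_per_day = as.integer(sessions_per_day),
    spectra_per_session = as.integer(spectra_per_session),
    axis_min = axis_min, axis_max = axis_max, axis_step = axis_step,
    bands = bands, baseline_coeffs = as.numeric(baseline_coeffs),
    baseline_decay = baseline_decay, baseline_exp_amp = baseline_exp_amp,
    noise_sd = noise_sd, replicate_jitter_sd = replicate_jitter_sd,
    nitrogen_depletion_day = as.integer(nitrogen_depletion_day),
    seed = as.integer(seed)), class = "simulation_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot_msg <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  stopifnot_msg(cfg$days >= 1, "days must be >= 1")
  stopifnot_msg(cfg$sessions_per_day >= 1, "sessions_per_day must be >= 1")
  stopifnot_msg(cfg$spectra_per_session >= 1, "spectra_per_session must be >= 1")
  stopifnot_msg(cfg$axis_min < cfg$axis_max, "axis_min must be < axis_max")
  stopifnot_msg(cfg$axis_step > 0, "axis_step must be > 0")
  stopifnot_msg(cfg$noise_sd >= 0, "noise_sd must be >= 0")
  stopifnot_msg(cfg$replicate_jitter_sd >= 0, "replicate_jitter_sd must be >= 0")
  stopifnot_msg(cfg$nitrogen_depletion_day >= 0 &&
                cfg$nitrogen_depletion_day <= cfg$days,
                "nitrogen_depletion_day must lie in [0, days]")
  for (b in cfg$bands) {
    stopifnot_msg(inherits(b, "band_kinetic"), "bands must be band_kinetic objects")
    stopifnot_msg(length(b$amplitude_by_day) == cfg$days,
                  sprintf("band %s: amplitude_by_day length must equal days", b$label))
  }
  invisible(cfg)
}

#' Default synthetic culture scenarios
#'
#' Two acquisition schedules are built in. `"lab"` emulates a bench
#' photobioreactor campaign: 50 spectra acquired once daily for 36 days.
#' `"pilot"` emulates an automated sampling loop on a pilot reactor: four
#' sessions per day, six hours apart, of 50 spectra each, for 14 days.
#' Both carry the full set of assigned vibrational bands (479, 865, 988,
#' 1157, 1444, 1524, 1660, 1750, 2850, 2885, 2940, 2970, 3008 cm^-1) with
#' two-phase amplitude kinetics: pigment bands (chlorophyll 988; carotenoids
#' 1157, 1524) rise during the first days, plateau, then fall steeply once
#' nitrogen runs out, while storage-lipid and unsaturation bands (1660,
#' 1750, 2940, 3008, and more weakly the other C-H bands) stay flat then
#' rise, as nitrogen starvation redirects metabolism from pigments to
#' reserve lipids. The two regimes give the score space its two-cluster
#' (pigment-rich vs lipid-rich) structure.
#'
#' @param scenario `"lab"` or `"pilot"`.
#' @param seed Integer RNG seed stored in the config.
#' @return A [simulation_config()].
#' @export
default_config <- function(scenario = c("lab", "pilot"), seed = 1L) {
  if (length(scenario) == 1 && !scenario %in% c("lab", "pilot"))
    stop(sprintf("unknown scenario '%s'; valid scenarios are 'lab' and 'pilot'",
                 scenario), call. = FALSE)
  scenario <- match.arg(scenario)
  if (scenario == "lab") {
    days <- 36L; sessions <- 1L; reps <- 50L; depletion <- 6L
  } else {
    days <- 14L; sessions <- 4L; reps <- 50L; depletion <- 8L
  }
  last <- days - 1L
  tn <- function(node_days, node_amps) trajectory_nodes(days, node_days, node_amps)
  # pigments: moderate start (inoculated from a grown pre-culture), rise to
  # an early plateau, steep chlorosis over ~2 days after nitrogen depletion;
  # the lab campaign ends with the slight late carotenoid re-rise seen in
  # long starvations
  pigment <- function(a0, apk, alow) {
    if (scenario == "pilot")
      tn(c(0, 3, depletion, depletion + 2, last), c(a0, apk, apk, alow, alow))
    else
      tn(c(0, depletion, 28, 32, last), c(a0, apk, alow, alow, 1.35 * alow))
  }
  # storage lipids: flat until depletion, then linear accumulation
  lipid <- function(a0, aend) tn(c(0, depletion, last), c(a0, a0, aend))
  bands <- list(
    # carbohydrate reserve, slow monotone accumulation
    band_kinetic(479, 24, tn(c(0, depletion, last), c(0.8, 1.1, 2.0)), label = "479"),
    # phospholipid head group, weak and nearly flat
    band_kinetic(865, 22, tn(c(0, depletion, last), c(0.5, 0.55, 0.45)), label = "865"),
    # chlorophyll CH3 deformation
    band_kinetic(988, 22, pigment(3.0, 4.0, 1.0), label = "988"),
    # carotenoid C-C stretch
    band_kinetic(1157, 22, pigment(3.75, 5.0, 1.5), label = "1157"),
    # CH2 scissoring, total acyl pool: nearly constant
    band_kinetic(1444, 26, tn(c(0, last), c(2.0, 2.2)), label = "1444"),
    # carotenoid C=C stretch (resonance enhanced, the strongest band)
    band_kinetic(1524, 26, pigment(6.0, 8.0, 2.0), label = "1524"),
    # cis C=C stretch, unsaturation: flat then rising
    band_kinetic(1660, 26, lipid(1.5, 4.0), label = "1660"),
    # ester C=O, triacylglycerols: flat then rising
    band_kinetic(1750, 24, lipid(0.3, 1.5), label = "1750"),
    # C-H stretch region
    band_kinetic(2850, 24, lipid(2.0, 3.5), label = "2850"),
    band_kinetic(2885, 24, lipid(1.5, 2.5), label = "2885"),
    band_kinetic(2940, 24, lipid(3.0, 6.0), label = "2940"),
    band_kinetic(2970, 24, lipid(1.2, 2.0), label = "2970"),
    # =C-H stretch, unsaturation: flat then rising
    band_kinetic(3008, 22, lipid(0.4, 1.6), label = "3008"))
  simulation_config(
    days = days, sessions_per_day = sessions, spectra_per_session = reps,
    bands = bands, axis_min = 300, axis_max = 3100, axis_step = 2,
    baseline_coeffs = c(8, 6, -5), baseline_decay = 1 / 800,
    baseline_exp_amp = 30, noise_sd = 0.16, replicate_jitter_sd = 0.05,
    nitrogen_depletion_day = depletion, seed = seed)
}

#' Monotone-kinetics validation scenario
#'
#' A pilot-schedule config in which the carotenoid 1524 band declines
#' linearly over the whole run, the unsaturation 1660 band rises linearly,
#' the 1444 reference band stays constant, and every other band is frozen at
#' its day-0 level. Used to validate that the analysis chain recovers
#' programmed band kinetics (rank correlation of day means against the
#' programmed amplitudes, strictly increasing unsaturation index).
#'
#' @param spectra_per_session Spectra per session (default 10).
#' @param noise_sd,replicate_jitter_sd Noise model overrides (default 0:
#'   noiseless ground-truth run).
#' @param seed Integer RNG seed.
#' @return A [simulation_config()].
#' @export
monotone_kinetics_config <- function(spectra_per_session = 10, noise_sd = 0,
                                     replicate_jitter_sd = 0, seed = 1L) {
  cfg <- default_config("pilot", seed = seed)
  cfg$spectra_per_session <- as.integer(spectra_per_session)
  cfg$noise_sd <- noise_sd
  cfg$replicate_jitter_sd <- replicate_jitter_sd
  d <- cfg$days
  lin <- function(a0, a1) trajectory_nodes(d, c(0, d - 1), c(a0, a1))
  for (i in seq_along(cfg$bands)) {
    b <- cfg$bands[[i]]
    cfg$bands[[i]]$amplitude_by_day <- switch(b$label,
      "1524" = lin(8, 2),
      "1660" = lin(1.5, 4),
      "1444" = rep(2, d),
      rep(b$amplitude_by_day[1], d))
  }
  validate_config(cfg)
  cfg
}

config_axis <- function(cfg) seq(cfg$axis_min, cfg$axis_max, by = cfg$axis_step)

peak_profile <- function(x, center, fwhm, shape) {
  if (shape == "gaussian") {
    s <- fwhm / (2 * sqrt(2 * log(2)))
    exp(-((x - center)^2) / (2 * s^2))
  } else {
    g <- fwhm / 2
    g^2 / ((x - center)^2 + g^2)
  }
}

baseline_model <- function(cfg, x) {
  u <- (x - cfg$axis_min) / (cfg$axis_max - cfg$axis_min)
  b <- numeric(length(x))
  for (k in seq_along(cfg$baseline_coeffs))
    b <- b + cfg$baseline_coeffs[k] * u^(k - 1)
  if (!is.null(cfg$baseline_decay) && cfg$baseline_exp_amp != 0)
    b <- b + cfg$baseline_exp_amp * exp(-cfg$baseline_decay * (x - cfg$axis_min))
  b
}

band_sum_model <- function(cfg, x, day) {
  y <- numeric(length(x))
  for (b in cfg$bands)
    y <- y + b$amplitude_by_day[day + 1] * peak_profile(x, b$center, b$width, b$shape)
  y
}

#' Noiseless model spectrum for one culture day
#'
#' Evaluates the generative model (band sum plus background) without jitter
#' or noise: the ground truth used in recovery tests of the baseline
#' correction and the band kinetics.
#'
#' @param config A [simulation_config()].
#' @param day 0-based day index, `0 <= day < config$days`.
#' @return A `spectrum` with id `"model_d<day>"`.
#' @export
evaluate_model <- function(config, day) {
  validate_config(config)
  if (day < 0 || day >= config$days)
    stop(sprintf("day %d out of range [0, %d]", day, config$days - 1),
         call. = FALSE)
  x <- config_axis(config)
  new_spectrum(x, band_sum_model(config, x, day) + baseline_model(config, x),
               spectrum_id = sprintf("model_d%02d", day), day = day)
}

#' Simulate a Raman spectra time series
#'
#' Draws `days x sessions_per_day x spectra_per_session` spectra. Each
#' spectrum is the day's band sum scaled by `(1 + jitter)` (one multiplicative
#' scatter factor per spectrum, emulating focus/turbidity variation that SNV
#' later removes), plus the fluorescence background, plus additive white
#' noise. Identical config and seed yield bit-identical output; the caller's
#' RNG state is left untouched.
#'
#' @param config A [simulation_config()].
#' @return A `spectra_set` with metadata recording day/session/replicate.
#' @export
simulate_spectra <- function(config) {
  validate_config(config)
  x <- config_axis(config)
  npt <- length(x)
  n <- config$days * config$sessions_per_day * config$spectra_per_session
  base <- baseline_model(config, x)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  jitter <- if (config$replicate_jitter_sd > 0)
    stats::rnorm(n, 0, config$replicate_jitter_sd) else numeric(n)
  noise <- if (config$noise_sd > 0)
    matrix(stats::rnorm(n * npt, 0, config$noise_sd), nrow = n) else
    matrix(0, nrow = n, ncol = npt)

  mat <- matrix(0, nrow = n, ncol = npt)
  meta <- data.frame(spectrum_id = character(n), day = integer(n),
                     session = integer(n), replicate = integer(n),
                     stringsAsFactors = FALSE)
  i <- 0L
  for (d in seq_len(config$days) - 1L) {
    bands_d <- band_sum_model(config, x, d)
    for (s in seq_len(config$sessions_per_day) - 1L) {
      for (r in seq_len(config$spectra_per_session) - 1L) {
        i <- i + 1L
        mat[i, ] <- bands_d * (1 + jitter[i]) + base + noise[i, ]
        meta$spectrum_id[i] <- sprintf("d%02ds%dr%02d", d, s, r)
        meta$day[i] <- d; meta$session[i] <- s; meta$replicate[i] <- r
      }
    }
  }
  new_spectra_set(x, mat, meta)
}
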