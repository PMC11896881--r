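# Synthetic-data generator emulating the study's measurement design:
# chill-then-radiant-lamp heat-up traces on two channels, thermal-gradient
# occupancy tracks with missing sightings, and replicate reflectance spectra
# with the spectrometer's 654-659 nm artefact.
#
# The heat-up backbone is lumped-capacitance Newton heating,
#   T(t) = T_eq - (T_eq - T0) * exp(-k t),  k = k0 * (m / m_ref)^beta,
# with beta = -1/3 by default (surface-to-volume scaling), so heavier
# individuals heat more slowly and sex differences emerge through mass.

#' Construct an individual record
#'
#' @param id Opaque identifier string.
#' @param species One of `"ungarica"`, `"sibiricus"`, `"parallelus"`.
#' @param sex `"F"` or `"M"`.
#' @param morph Colour morph; `"dorsal-green"`/`"lateral-green"` are only
#'   valid for `parallelus`.
#' @param mass Body mass in grams (> 0).
#' @param brightness Mean reflectance in %, or `NA` before spectra processing.
#' @return A one-row data.frame of class `individual`.
#' @export
individual <- function(id, species, sex, morph, mass, brightness = NA_real_) {
  species <- match.arg(species, SPECIES_LEVELS)
  sex <- match.arg(sex, SEX_LEVELS)
  if (!morph %in% valid_morphs(species))
    stopf("morph '%s' is not valid for species '%s'", morph, species)
  if (!is.numeric(mass) || length(mass) != 1L || !is.finite(mass) || mass <= 0)
    stopf("mass must be a positive number")
  structure(
    data.frame(id = as.character(id), species = species, sex = sex,
               morph = morph, mass = mass, brightness = brightness,
               stringsAsFactors = FALSE),
    class = c("individual", "data.frame")
  )
}

# Green-weight of a morph: green 1, brown 0, intermediates 1/2. Used to apply
# additive morph effects (green relative to brown) in the generator's
# non-null configurations.
morph_weight <- function(morph) {
  c(green = 1, brown = 0, `dorsal-green` = 0.5, `lateral-green` = 0.5)[morph]
}

# Species x sex row of the physiology table
physio_row <- function(cfg, species, sex) {
  p <- cfg$physiology
  r <- p[p$species == species & p$sex == sex, , drop = FALSE]
  if (nrow(r) != 1L) stopf("no physiology entry for %s %s", species, sex)
  r
}

# True Newton parameters of an individual under a config
true_heatup_params <- function(ind, cfg) {
  pr <- physio_row(cfg, ind$species, ind$sex)
  w <- unname(morph_weight(ind$morph))
  k <- cfg$k0 * (ind$mass / cfg$m_ref)^cfg$beta * pr$k_scale *
    (1 + cfg$morph_effect_k * w)
  list(t_eq = pr$t_eq + cfg$morph_effect_teq * w, k = k)
}

newton_backbone <- function(t, t0, t_eq, k) t_eq - (t_eq - t0) * exp(-k * t)

#' Simulate one heat-up trace
#'
#' Samples the Newton backbone on the channel's grid, adds Gaussian
#' observation noise, and — with probability `dip_prob` — replaces the first
#' `dip_duration` seconds by a linear segment from `T0 + dip_depth` toward
#' the backbone, emulating the haemolymph-homogenisation dip seen at the
#' start of real traces (those samples are truncated before analysis).
#'
#' @param ind An [individual()] (or one-row data.frame with the same fields).
#' @param cfg A [sim_config()].
#' @param channel `"internal"` (5 s grid) or `"external"` (20 s grid).
#' @param seed Integer seed; defaults to a stream derived from the cohort
#'   seed and the individual's id.
#' @param t0 Optional fixed start temperature (degC); drawn from the chill
#'   distribution when `NULL`.
#' @return A `thermal_trace`: list with `individual_id`, `channel`,
#'   `interval`, `time_s`, `temperature_c`.
#' @export
simulate_heatup_trace <- function(ind, cfg, channel = c("internal", "external"),
                                  seed = NULL, t0 = NULL) {
  channel <- match.arg(channel)
  if (ind$mass <= 0) stopf("mass must be positive")
  if (cfg$k0 <= 0) stopf("k0 must be positive")
  if (is.null(seed))
    seed <- child_seed(child_seed(cfg$seed, ind$id), paste0("trace_", channel))
  pars <- true_heatup_params(ind, cfg)
  grid <- trace_grid(cfg, channel)
  noise_sd <- if (channel == "internal") cfg$noise_internal else cfg$noise_external
  with_seed(seed, {
    if (is.null(t0)) t0 <- rnorm(1, cfg$t0_mean, cfg$t0_sd)
    temp <- newton_backbone(grid, t0, pars$t_eq, pars$k)
    if (runif(1) < cfg$dip_prob && cfg$dip_duration > 0) {
      pre <- grid < cfg$dip_duration
      anchor <- newton_backbone(cfg$dip_duration, t0, pars$t_eq, pars$k)
      temp[pre] <- (t0 + cfg$dip_depth) +
        (anchor - (t0 + cfg$dip_depth)) * grid[pre] / cfg$dip_duration
    }
    temp <- temp + rnorm(length(grid), 0, noise_sd)
    thermal_trace(ind$id, channel, grid, temp)
  })
}

#' Simulate a thermal-gradient occupancy track
#'
#' The individual is released at `release_pos` and relaxes exponentially
#' (time constant `track_tau` minutes) toward the runway position whose
#' calibrated temperature equals its preferred temperature, with Gaussian
#' positional noise; positions are clamped to the runway and each sighting
#' is independently missing with probability `missing_prob`.
#'
#' @param ind An [individual()].
#' @param calibration A fitted [gradient_calibration].
#' @param cfg A [sim_config()].
#' @param pref_temp Preferred temperature (degC); drawn from the group
#'   distribution when `NULL`.
#' @param seed Integer seed (defaults to the individual's track stream).
#' @return A `gradient_track` (see [gradient_track()]); carries attribute
#'   `clamped = TRUE` when the preferred temperature fell outside the
#'   calibrated range.
#' @export
simulate_gradient_track <- function(ind, calibration, cfg, pref_temp = NULL,
                                    seed = NULL) {
  stopifnot(inherits(calibration, "gradient_calibration"))
  if (is.null(seed)) seed <- child_seed(child_seed(cfg$seed, ind$id), "track")
  pr <- physio_row(cfg, ind$species, ind$sex)
  with_seed(seed, {
    if (is.null(pref_temp))
      pref_temp <- rnorm(1, pr$pref_mean, pr$pref_sd) +
        cfg$morph_effect_pref * unname(morph_weight(ind$morph))
    inv <- invert_calibration(calibration, pref_temp,
                              length = cfg$runway_length)
    times <- seq(cfg$sighting_interval, by = cfg$sighting_interval,
                 length.out = cfg$n_sightings)
    pos <- inv$position +
      (cfg$release_pos - inv$position) * exp(-times / cfg$track_tau) +
      rnorm(length(times), 0, cfg$track_noise_sd)
    pos <- pmin(pmax(pos, 0), cfg$runway_length)
    miss <- runif(length(times)) < cfg$missing_prob
    pos[miss] <- NA_real_
    out <- gradient_track(ind$id, calibration$runway_id, times, pos)
    attr(out, "clamped") <- inv$clamped
    out
  })
}

# Spectral shapes (arbitrary positive units, later scaled to a brightness
# target): green cuticle shows a reflectance peak near 550 nm plus the NIR
# rise common to foliage-matching colours; brown is a gently rising,
# featureless curve.
shape_green <- function(wl) {
  0.35 + 0.85 * exp(-((wl - 550)^2) / (2 * 45^2)) +
    0.9 / (1 + exp(-(wl - 750) / 60))
}
shape_brown <- function(wl) 0.45 + 1.1 * (wl - 300) / 700

# Body-part shape for a morph: intermediates are green on one body part only.
part_shape <- function(morph, body_part, wl) {
  green_part <- switch(morph,
    green = c(TRUE, TRUE), brown = c(FALSE, FALSE),
    `dorsal-green` = c(TRUE, FALSE), `lateral-green` = c(FALSE, TRUE)
  )[match(body_part, BODY_PARTS)]
  if (green_part) shape_green(wl) else shape_brown(wl)
}

#' Simulate the ten raw reflectance spectra of one individual
#'
#' Five replicates per body part (dorsal pronotum, lateral pronotum lobe) on
#' the 1 nm 300-1000 nm grid, scaled so the expected mean brightness of the
#' 10-replicate average equals the individual's target, with mean-one
#' lognormal multiplicative jitter per replicate and a positive instrument
#' spike added at 654-659 nm.
#'
#' @param ind An [individual()].
#' @param cfg A [sim_config()].
#' @param target Brightness target (% reflectance); drawn from the group
#'   distribution when `NULL`.
#' @param seed Integer seed (defaults to the individual's spectra stream).
#' @return List of 10 [reflectance_spectrum] objects.
#' @export
simulate_reflectance <- function(ind, cfg, target = NULL, seed = NULL) {
  if (is.null(seed)) seed <- child_seed(child_seed(cfg$seed, ind$id), "spectra")
  g <- cfg$groups
  row <- g[g$species == ind$species & g$sex == ind$sex & g$morph == ind$morph, ]
  if (is.null(target)) {
    if (nrow(row) != 1L) stopf("no brightness target for this group")
  }
  wl <- WL_GRID
  flat <- isTRUE(cfg$flat_spectra)
  shapes <- lapply(BODY_PARTS, function(bp)
    if (flat) rep(1, length(wl)) else part_shape(ind$morph, bp, wl))
  norm <- mean(unlist(shapes))  # so the 10-replicate average has mean = target
  with_seed(seed, {
    if (is.null(target))
      target <- max(0.5, rnorm(1, row$brightness_mean, row$brightness_sd))
    spikes <- wl >= 654 & wl <= 659
    out <- vector("list", 10L)
    idx <- 0L
    for (p in seq_along(BODY_PARTS)) for (rep_i in 1:5) {
      jit <- if (cfg$jitter_sd > 0)
        exp(rnorm(1, -cfg$jitter_sd^2 / 2, cfg$jitter_sd)) else 1
      refl <- shapes[[p]] / norm * target * jit
      refl[spikes] <- refl[spikes] + cfg$spike_mag
      idx <- idx + 1L
      out[[idx]] <- reflectance_spectrum(ind$id, BODY_PARTS[p], rep_i, refl)
    }
    out
  })
}

#' Generate a full synthetic cohort
#'
#' Produces, for every configured individual, one internal and one external
#' heat-up trace, one gradient track bound to one of `n_runways` runway
#' calibrations, and ten raw reflectance spectra. Draws are split
#' hierarchically from the cohort seed by individual id, so enlarging the
#' config does not perturb previously generated individuals.
#'
#' @param cfg A [sim_config()].
#' @return A `cohort`: list with `individuals` (data.frame, one row per
#'   individual incl. true generator parameters), `calibrations` (list of
#'   [gradient_calibration]), `traces` (per id: `$internal`, `$external`),
#'   `tracks` (per id), `spectra` (per id: list of 10 spectra), and `config`.
#' @examples
#' co <- generate_cohort(sim_config(seed = 42))
#' nrow(co$individuals)  # 432
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  g <- cfg$groups
  inds <- list()
  for (r in seq_len(nrow(g))) {
    n <- g$n[r]
    if (n == 0) next
    for (i in seq_len(n)) {
      id <- sprintf("%s_%s_%s_%03d", g$species[r], g$sex[r],
                    gsub("-", "", g$morph[r]), i)
      iseed <- child_seed(cfg$seed, id)
      mass <- with_seed(child_seed(iseed, "mass"),
                        max(0.01, rnorm(1, g$mass_mean[r], g$mass_sd[r])))
      inds[[length(inds) + 1L]] <-
        individual(id, g$species[r], g$sex[r], g$morph[r], mass)
    }
  }
  if (!length(inds)) {
    return(structure(list(
      individuals = data.frame(id = character(), species = character(),
                               sex = character(), morph = character(),
                               mass = numeric(), brightness = numeric(),
                               runway_id = character(),
                               stringsAsFactors = FALSE),
      calibrations = list(), traces = list(), tracks = list(),
      spectra = list(), config = cfg), class = "cohort"))
  }
  individuals <- do.call(rbind, lapply(inds, as.data.frame))
  individuals$runway_id <-
    paste0("runway", (seq_len(nrow(individuals)) - 1L) %% cfg$n_runways + 1L)

  calibrations <- lapply(seq_len(cfg$n_runways), function(r)
    simulate_calibration(cfg, paste0("runway", r),
                         seed = child_seed(cfg$seed, paste0("runway", r))))
  names(calibrations) <- paste0("runway", seq_len(cfg$n_runways))

  traces <- list(); tracks <- list(); spectra <- list()
  truth <- data.frame(id = individuals$id, t_eq = NA_real_, k = NA_real_)
  for (i in seq_len(nrow(individuals))) {
    ind <- individuals[i, ]
    traces[[ind$id]] <- list(
      internal = simulate_heatup_trace(ind, cfg, "internal"),
      external = simulate_heatup_trace(ind, cfg, "external")
    )
    tracks[[ind$id]] <-
      simulate_gradient_track(ind, calibrations[[ind$runway_id]], cfg)
    spectra[[ind$id]] <- simulate_reflectance(ind, cfg)
    tp <- true_heatup_params(ind, cfg)
    truth$t_eq[i] <- tp$t_eq; truth$k[i] <- tp$k
  }
  individuals$true_t_eq <- truth$t_eq
  individuals$true_k <- truth$k
  structure(list(individuals = individuals, calibrations = calibrations,
                 traces = traces, tracks = tracks, spectra = spectra,
                 config = cfg),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$individuals), " individuals\n", sep = "")
  if (nrow(x$individuals))
    print(table(x$individuals$species, x$individuals$sex))
  invisible(x)
}

#' Simulate one runway's five-point temperature calibration
#'
#' Base profile interpolates the configured endpoints (10.0 and 51.0 degC by
#' default) with mild cubic curvature pinned to a 27.1 degC mid-runway
#' release temperature, plus per-position measurement noise; a cubic is then
#' least-squares fitted via [fit_calibration()].
#'
#' @param cfg A [sim_config()].
#' @param runway_id Runway identifier string.
#' @param seed Integer seed.
#' @return A [gradient_calibration].
#' @export
simulate_calibration <- function(cfg, runway_id = "runway1", seed = 1L) {
  pos <- seq(0, cfg$runway_length, length.out = 5L)
  base <- c(10.0, 17.8, 27.1, 38.3, 51.0)        # degC at 0,20,...,80 cm
  shape <- (base - base[1]) / (base[5] - base[1])
  temps_true <- cfg$grad_cold + shape * (cfg$grad_hot - cfg$grad_cold)
  sds <- c(1.1, 1.4, 1.3, 1.8, 2.3)              # endpoint SDs as printed
  temps <- with_seed(seed, temps_true + rnorm(5, 0, sds))
  temps <- sort(temps)  # keep the profile monotone for invertibility
  fit_calibration(pos, temps, runway_id = runway_id)
}
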