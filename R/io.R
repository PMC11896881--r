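# Tidy long-format CSV interfaces between pipeline stages (UTF-8, "."
# decimal, empty cell = missing), plus schema validation with
# machine-readable reports.

#' Write a cohort's input CSVs
#'
#' Writes `individuals.csv`, `traces.csv`, `calibrations.csv`, `tracks.csv`
#' and (optionally, it is large) `spectra.csv`, plus a `config.json`
#' sidecar of the true generator parameters.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param raw_spectra Also write the long-format raw spectra CSV.
#' @return Named character vector of the files written (invisibly).
#' @export
write_cohort_csv <- function(cohort, dir, raw_spectra = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c()
  p <- function(f) file.path(dir, f)

  ind <- cohort$individuals
  write.csv(data.frame(individual_id = ind$id, species = ind$species,
                       sex = ind$sex, morph = ind$morph, mass_g = ind$mass,
                       runway_id = ind$runway_id),
            p("individuals.csv"), row.names = FALSE)
  files["individuals"] <- p("individuals.csv")

  tr <- do.call(rbind, lapply(unname(cohort$traces), function(ch)
    do.call(rbind, lapply(unname(ch), function(t)
      data.frame(individual_id = t$individual_id, channel = t$channel,
                 time_s = t$time_s, temperature_c = t$temperature_c)))))
  if (is.null(tr))
    tr <- data.frame(individual_id = character(), channel = character(),
                     time_s = numeric(), temperature_c = numeric())
  write.csv(tr, p("traces.csv"), row.names = FALSE)
  files["traces"] <- p("traces.csv")

  cal <- do.call(rbind, lapply(unname(cohort$calibrations), function(cl)
    data.frame(runway_id = cl$runway_id, position_cm = cl$positions,
               temperature_c = cl$temperatures)))
  if (is.null(cal))
    cal <- data.frame(runway_id = character(), position_cm = numeric(),
                      temperature_c = numeric())
  write.csv(cal, p("calibrations.csv"), row.names = FALSE)
  files["calibrations"] <- p("calibrations.csv")

  tk <- do.call(rbind, lapply(unname(cohort$tracks), function(t)
    data.frame(individual_id = t$individual_id, runway_id = t$runway_id,
               time_min = t$time_min, position_cm = t$position_cm)))
  if (is.null(tk))
    tk <- data.frame(individual_id = character(), runway_id = character(),
                     time_min = numeric(), position_cm = numeric())
  write.csv(tk, p("tracks.csv"), row.names = FALSE, na = "")
  files["tracks"] <- p("tracks.csv")

  if (raw_spectra) {
    sp <- do.call(rbind, lapply(unname(cohort$spectra), function(sl)
      do.call(rbind, lapply(sl, function(s)
        data.frame(individual_id = s$individual_id, body_part = s$body_part,
                   replicate = s$replicate, wavelength_nm = s$wavelength,
                   reflectance_pct = s$reflectance)))))
    if (is.null(sp))
      sp <- data.frame(individual_id = character(), body_part = character(),
                       replicate = integer(), wavelength_nm = numeric(),
                       reflectance_pct = numeric())
    write.csv(sp, p("spectra.csv"), row.names = FALSE)
    files["spectra"] <- p("spectra.csv")
  }

  write_sim_config(cohort$config, p("config.json"))
  files["config"] <- p("config.json")
  invisible(files)
}

#' Read pipeline input CSVs back into a cohort-like object
#'
#' @param dir Directory containing the CSVs written by [write_cohort_csv()]
#'   (spectra optional).
#' @return A `cohort` (without true generator parameters; `config` is read
#'   from `config.json` when present).
#' @export
read_cohort_csv <- function(dir) {
  ind <- read.csv(file.path(dir, "individuals.csv"),
                  stringsAsFactors = FALSE)
  individuals <- data.frame(id = ind$individual_id, species = ind$species,
                            sex = ind$sex, morph = ind$morph,
                            mass = ind$mass_g, brightness = NA_real_,
                            runway_id = ind$runway_id,
                            stringsAsFactors = FALSE)
  tr <- read.csv(file.path(dir, "traces.csv"), stringsAsFactors = FALSE)
  traces <- list()
  if (nrow(tr)) {
    for (key in unique(paste(tr$individual_id, tr$channel))) {
      sel <- paste(tr$individual_id, tr$channel) == key
      d <- tr[sel, ]
      traces[[d$individual_id[1]]][[d$channel[1]]] <-
        thermal_trace(d$individual_id[1], d$channel[1], d$time_s,
                      d$temperature_c)
    }
  }
  cal <- read.csv(file.path(dir, "calibrations.csv"),
                  stringsAsFactors = FALSE)
  calibrations <- lapply(split(cal, cal$runway_id), function(d)
    fit_calibration(d$position_cm, d$temperature_c,
                    runway_id = d$runway_id[1]))
  tk <- read.csv(file.path(dir, "tracks.csv"), stringsAsFactors = FALSE)
  tracks <- lapply(split(tk, tk$individual_id), function(d)
    gradient_track(d$individual_id[1], d$runway_id[1], d$time_min,
                   d$position_cm))
  spectra <- list()
  spath <- file.path(dir, "spectra.csv")
  if (file.exists(spath)) {
    sp <- read.csv(spath, stringsAsFactors = FALSE)
    for (id in unique(sp$individual_id)) {
      d <- sp[sp$individual_id == id, ]
      spectra[[id]] <- lapply(split(d, paste(d$body_part, d$replicate)),
                              function(g)
        reflectance_spectrum(id, g$body_part[1], g$replicate[1],
                             g$reflectance_pct[order(g$wavelength_nm)]))
      names(spectra[[id]]) <- NULL
    }
  }
  cpath <- file.path(dir, "config.json")
  cfg <- if (file.exists(cpath)) read_sim_config(cpath) else NULL
  structure(list(individuals = individuals, calibrations = calibrations,
                 traces = traces, tracks = tracks, spectra = spectra,
                 config = cfg),
            class = "cohort")
}

#' Validate pipeline input files
#'
#' Checks schemas and cross-file consistency: required columns, duplicate
#' ids, valid species/morph combinations, positive masses, uniform trace
#' sampling, positions within the runway, runway-id linkage, and complete
#' 300-1000 nm spectral grids. Failures are collected, not thrown.
#'
#' @param dir Directory with the input CSVs.
#' @return Data.frame report (`file`, `rule`, `detail`), zero rows when
#'   everything passes.
#' @export
validate_inputs <- function(dir) {
  report <- list()
  note <- function(file, rule, detail)
    report[[length(report) + 1L]] <<- data.frame(
      file = file, rule = rule, detail = detail, stringsAsFactors = FALSE)

  ipath <- file.path(dir, "individuals.csv")
  if (!file.exists(ipath)) {
    note("individuals.csv", "missing_file", ipath)
    ind <- NULL
  } else {
    ind <- read.csv(ipath, stringsAsFactors = FALSE)
    if (anyDuplicated(ind$individual_id))
      note("individuals.csv", "duplicate_id",
           paste(unique(ind$individual_id[duplicated(ind$individual_id)]),
                 collapse = ", "))
    bad <- !ind$species %in% SPECIES_LEVELS
    if (any(bad))
      note("individuals.csv", "unknown_species",
           paste(unique(ind$species[bad]), collapse = ", "))
    badm <- !mapply(function(sp, m)
      sp %in% SPECIES_LEVELS && m %in% valid_morphs(sp),
      ind$species, ind$morph)
    if (any(badm))
      note("individuals.csv", "invalid_morph_for_species",
           paste(unique(ind$individual_id[badm]), collapse = ", "))
    if (any(!is.finite(ind$mass_g) | ind$mass_g <= 0))
      note("individuals.csv", "nonpositive_mass",
           paste(ind$individual_id[!is.finite(ind$mass_g) | ind$mass_g <= 0],
                 collapse = ", "))
  }

  tpath <- file.path(dir, "traces.csv")
  if (file.exists(tpath)) {
    tr <- read.csv(tpath, stringsAsFactors = FALSE)
    if (nrow(tr)) {
      if (!all(tr$channel %in% c("internal", "external")))
        note("traces.csv", "unknown_channel",
             paste(setdiff(unique(tr$channel), c("internal", "external")),
                   collapse = ", "))
      for (key in unique(paste(tr$individual_id, tr$channel, sep = "/"))) {
        sel <- paste(tr$individual_id, tr$channel, sep = "/") == key
        dt <- diff(sort(tr$time_s[sel]))
        if (length(dt) && any(abs(dt - dt[1]) > 1e-9))
          note("traces.csv", "nonuniform_sampling", key)
      }
      if (!is.null(ind) &&
          length(miss <- setdiff(unique(tr$individual_id),
                                 ind$individual_id)))
        note("traces.csv", "unknown_individual", paste(miss, collapse = ", "))
    }
  }

  cpath <- file.path(dir, "calibrations.csv")
  runways <- character()
  if (file.exists(cpath)) {
    cal <- read.csv(cpath, stringsAsFactors = FALSE)
    runways <- unique(cal$runway_id)
    for (r in runways) {
      d <- cal[cal$runway_id == r, ]
      if (length(unique(d$position_cm)) < 4L)
        note("calibrations.csv", "too_few_positions", r)
    }
  }

  kpath <- file.path(dir, "tracks.csv")
  if (file.exists(kpath)) {
    tk <- read.csv(kpath, stringsAsFactors = FALSE)
    obs <- !is.na(tk$position_cm)
    if (any(tk$position_cm[obs] < 0 | tk$position_cm[obs] > 80))
      note("tracks.csv", "position_out_of_range",
           paste(unique(tk$individual_id[obs & (tk$position_cm < 0 |
                                                  tk$position_cm > 80)]),
                 collapse = ", "))
    if (length(runways) &&
        length(miss <- setdiff(unique(tk$runway_id), runways)))
      note("tracks.csv", "unknown_runway", paste(miss, collapse = ", "))
  }

  spath <- file.path(dir, "spectra.csv")
  if (file.exists(spath)) {
    sp <- read.csv(spath, stringsAsFactors = FALSE)
    if (nrow(sp)) {
      cnt <- table(paste(sp$individual_id, sp$body_part, sp$replicate))
      if (any(cnt != length(WL_GRID)))
        note("spectra.csv", "incomplete_grid",
             paste(names(cnt)[cnt != length(WL_GRID)], collapse = ", "))
      if (any(sp$reflectance_pct < 0, na.rm = TRUE))
        note("spectra.csv", "negative_reflectance", "values < 0 present")
    }
  }

  if (!length(report))
    return(data.frame(file = character(), rule = character(),
                      detail = character(), stringsAsFactors = FALSE))
  do.call(rbind, report)
}
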