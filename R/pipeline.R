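# Orchestration: generate (or load) -> process spectra -> gradient ->
# physiology -> constrained bootstrap -> classical tests, with a JSON run
# manifest and tidy CSV outputs per species-x-sex subset.

#' Assemble the six species-x-sex analysis subsets
#'
#' Joins brightness, physiology and preferred-temperature summaries onto the
#' individual table and builds, per subset, the truncated internal/external
#' trace matrices and the substrate-temperature matrix.
#'
#' @param cohort A `cohort` (generated or read from CSV).
#' @param brightness Data.frame from [process_spectra()] (`$brightness`), or
#'   `NULL` to skip.
#' @param physiology Data.frame from [summarise_physiology()], or `NULL`.
#' @param preferred Data.frame (`individual_id`, `preferred_temp`), or
#'   `NULL`.
#' @return Named list of [analysis_subset()] objects ("species.sex"),
#'   only for non-empty subsets.
#' @export
build_subsets <- function(cohort, brightness = NULL, physiology = NULL,
                          preferred = NULL) {
  ind <- cohort$individuals
  if (!nrow(ind)) return(list())
  if (!is.null(brightness))
    ind$brightness <-
      brightness$brightness_pct[match(ind$id, brightness$individual_id)]
  if (!is.null(physiology)) {
    for (ch in unique(physiology$channel)) {
      d <- physiology[physiology$channel == ch, ]
      ind[[paste0("heatup_", ch)]] <-
        d$heatup_speed_c_per_min[match(ind$id, d$individual_id)]
      ind[[paste0("equilibrium_", ch)]] <-
        d$equilibrium_c[match(ind$id, d$individual_id)]
    }
  }
  if (!is.null(preferred))
    ind$preferred_temp <-
      preferred$preferred_temp[match(ind$id, preferred$individual_id)]

  trace_mat <- function(ids, channel) {
    if (!length(cohort$traces)) return(NULL)
    tl <- lapply(ids, function(id)
      truncate_trace(cohort$traces[[id]][[channel]]))
    m <- do.call(rbind, lapply(tl, `[[`, "temperature_c"))
    rownames(m) <- ids
    attr(m, "time") <- tl[[1L]]$time_s
    m
  }
  substrate_mat <- function(ids) {
    if (!length(cohort$tracks)) return(NULL)
    m <- do.call(rbind, lapply(ids, function(id) {
      tk <- cohort$tracks[[id]]
      track_temperatures(tk, cohort$calibrations[[tk$runway_id]])
    }))
    rownames(m) <- ids
    attr(m, "time") <- cohort$tracks[[ids[1L]]]$time_min
    m
  }

  out <- list()
  for (sp in unique(ind$species)) for (sx in unique(ind$sex)) {
    rows <- ind[ind$species == sp & ind$sex == sx, , drop = FALSE]
    if (!nrow(rows)) next
    traces <- list()
    if (length(cohort$traces)) {
      traces$internal <- trace_mat(rows$id, "internal")
      traces$external <- trace_mat(rows$id, "external")
    }
    if (length(cohort$tracks)) traces$substrate <- substrate_mat(rows$id)
    out[[paste(sp, sx, sep = ".")]] <-
      analysis_subset(rows, traces, species = sp, sex = sx)
  }
  out
}

# Morph contrasts analysed for a subset: green-brown headline, all six
# pairs for the four-morph species.
subset_contrasts <- function(morphs, all_pairs = TRUE) {
  present <- intersect(MORPH_LEVELS, unique(morphs))
  if (length(present) < 2L) return(NULL)
  if (!all_pairs) {
    if (all(c("green", "brown") %in% present))
      return(list(c("green", "brown")))
    return(NULL)
  }
  cmb <- utils::combn(present, 2L)
  lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
}

#' Run the full analysis pipeline
#'
#' Synthetic mode (`config` given): generates a cohort; input mode
#' (`input_dir` given): reads the four CSVs. Then processes spectra to
#' brightness, derives physiology summaries and preferred temperatures,
#' and, per species-x-sex subset, computes morph-constrained bootstrap CIs
#' for all summary-statistic morph contrasts and brightness/mass Spearman
#' correlations (plus optional time-resolved curves), and the classical
#' test table. Equilibrium analyses are skipped for groups flagged as never
#' reaching the plateau.
#'
#' @param config A [sim_config()] (or path to a JSON config) for synthetic
#'   mode; ignored when `input_dir` is given.
#' @param input_dir Directory of input CSVs (see [read_cohort_csv()]).
#' @param out_dir Optional output directory for tidy CSVs and the manifest.
#' @param B Bootstrap iterations (default 1000).
#' @param level CI level (default 0.95).
#' @param seed Analysis seed (bootstrap streams); defaults to the config
#'   seed + 1.
#' @param curves Character subset of `c("difference", "brightness", "mass")`
#'   selecting which time-resolved curves to compute (on `curve_channel`);
#'   empty to skip.
#' @param curve_channel Channel for the curves (default `"internal"`).
#' @return List: `cohort`, `subsets`, `brightness`, `physiology`,
#'   `preferred`, `results` (tidy data.frame), `tests` (data.frame),
#'   `curves` (nested list), `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), input_dir = NULL,
                         out_dir = NULL, B = 1000L, level = 0.95,
                         seed = NULL, curves = character(),
                         curve_channel = "internal") {
  if (is.character(config)) config <- read_sim_config(config)
  if (is.null(input_dir)) {
    cohort <- generate_cohort(config)
  } else {
    rep_ <- validate_inputs(input_dir)
    if (nrow(rep_))
      stopf("input validation failed: %s",
            paste(sprintf("%s[%s: %s]", rep_$file, rep_$rule, rep_$detail),
                  collapse = "; "))
    cohort <- read_cohort_csv(input_dir)
    if (is.null(cohort$config)) cohort$config <- config
  }
  cfg <- cohort$config
  if (is.null(seed)) seed <- (cfg$seed + 1L) %% MAXSEED

  spec_res <- if (length(cohort$spectra)) process_spectra(cohort$spectra)
  brightness <- if (!is.null(spec_res)) spec_res$brightness
  physiology <- if (length(cohort$traces)) summarise_physiology(cohort)
  preferred <- if (length(cohort$tracks)) {
    d <- do.call(rbind, lapply(names(cohort$tracks), function(id) {
      tk <- cohort$tracks[[id]]
      pt <- preferred_temperature(tk, cohort$calibrations[[tk$runway_id]])
      data.frame(individual_id = id, preferred_temp = pt$preferred_temp,
                 n_used = pt$n_used, stringsAsFactors = FALSE)
    }))
    d
  }

  subsets <- build_subsets(cohort, brightness, physiology, preferred)

  responses <- intersect(
    c("heatup_internal", "heatup_external", "equilibrium_internal",
      "equilibrium_external", "preferred_temp"),
    if (length(subsets)) names(subsets[[1L]]$individuals) else character())

  results <- list(); tests <- list(); curve_out <- list()
  add_result <- function(subset_name, kind, contrast, response, br)
    results[[length(results) + 1L]] <<- data.frame(
      subset = subset_name, kind = kind, contrast = contrast,
      response = response, time = "summary", estimate = br$estimate,
      ci_low = br$ci_low, ci_high = br$ci_high,
      excludes_zero = br$excludes_zero, valid = br$valid,
      stringsAsFactors = FALSE)

  for (sn in names(subsets)) {
    s <- subsets[[sn]]
    d <- s$individuals
    for (resp in responses) {
      v <- d[[resp]]
      if (all(is.na(v))) next  # e.g. equilibrium never reached in this group
      # morph contrasts
      ctr <- subset_contrasts(d$morph)
      for (cc in ctr) {
        if (all(is.na(v[d$morph == cc[1]])) ||
            all(is.na(v[d$morph == cc[2]]))) next
        br <- bootstrap_ci(s, stat_diff_means(resp, cc[1], cc[2]), B = B,
                           level = level,
                           seed = child_seed(seed, paste(sn, resp, cc[1],
                                                         cc[2])),
                           label = sprintf("%s %s-%s %s", sn, cc[1], cc[2],
                                           resp))
        add_result(sn, "contrast", paste(cc, collapse = "-"), resp, br)
      }
      # covariate correlations
      for (cov in intersect(c("brightness", "mass"), names(d))) {
        if (all(is.na(d[[cov]]))) next
        br <- bootstrap_ci(s, stat_spearman(cov, resp), B = B, level = level,
                           seed = child_seed(seed, paste(sn, resp, cov)),
                           label = sprintf("%s %s~%s", sn, resp, cov))
        add_result(sn, "correlation", cov, resp, br)
      }
      # classical tests: morph effect
      groups <- split(v[!is.na(v)], d$morph[!is.na(v)])
      groups <- groups[lengths(groups) >= 3L]
      if (length(groups) >= 2L) {
        tr <- tryCatch(
          if (length(groups) == 2L) two_group_test(groups)
          else multi_group_test(groups),
          error = function(e) NULL)
        if (!is.null(tr))
          tests[[length(tests) + 1L]] <- data.frame(
            subset = sn, response = resp, factor = "morph", test = tr$test,
            statistic = tr$statistic,
            df = if (all(is.na(tr$df))) NA_real_ else tr$df[1],
            p = tr$p, transform = tr$transform, stringsAsFactors = FALSE)
      }
      # classical tests: covariate correlations
      for (cov in intersect(c("brightness", "mass"), names(d))) {
        ok <- !is.na(v) & !is.na(d[[cov]])
        if (sum(ok) < 4L) next
        bvn <- shapiro.test(v[ok])$p.value > 0.05 &&
          shapiro.test(d[[cov]][ok])$p.value > 0.05
        tr <- correlation_test(d[[cov]][ok], v[ok], bivariate_normal = bvn)
        tests[[length(tests) + 1L]] <- data.frame(
          subset = sn, response = resp, factor = cov, test = tr$test,
          statistic = tr$statistic,
          df = if (all(is.na(tr$df))) NA_real_ else tr$df[1],
          p = tr$p, transform = tr$transform, stringsAsFactors = FALSE)
      }
    }
    # time-resolved curves
    if (length(curves) && !is.null(s$traces[[curve_channel]])) {
      cl <- list()
      if ("difference" %in% curves &&
          all(c("green", "brown") %in% d$morph))
        cl$difference <- difference_curve(
          s, "green", "brown", channel = curve_channel, B = B, level = level,
          seed = child_seed(seed, paste(sn, "diffcurve")))
      for (cov in intersect(curves, c("brightness", "mass")))
        if (!is.null(d[[cov]]) && !any(is.na(d[[cov]])))
          cl[[cov]] <- correlation_curve(
            s, cov, channel = curve_channel, B = B, level = level,
            seed = child_seed(seed, paste(sn, "corrcurve", cov)))
      curve_out[[sn]] <- cl
    }
  }

  # sex effect per species (pooled over morphs), t vs Mann-Whitney
  for (sp in unique(cohort$individuals$species)) {
    pair <- subsets[paste(sp, c("F", "M"), sep = ".")]
    if (any(vapply(pair, is.null, TRUE))) next
    for (resp in responses) {
      g <- lapply(pair, function(s) {
        x <- s$individuals[[resp]]
        x[!is.na(x)]
      })
      if (any(lengths(g) < 3L)) next
      normal <- all(vapply(g, function(x) shapiro.test(x)$p.value, 0) > 0.05)
      tr <- if (normal) {
        hom <- var.test(g[[1]], g[[2]])$p.value > 0.05
        two_group_test(g, list(normal = TRUE, homoscedastic = hom))
      } else mann_whitney(g[[1]], g[[2]])
      tests[[length(tests) + 1L]] <- data.frame(
        subset = sp, response = resp, factor = "sex", test = tr$test,
        statistic = tr$statistic,
        df = if (all(is.na(tr$df))) NA_real_ else tr$df[1],
        p = tr$p, transform = tr$transform, stringsAsFactors = FALSE)
    }
  }

  results <- if (length(results)) do.call(rbind, results) else
    data.frame(subset = character(), kind = character(),
               contrast = character(), response = character(),
               time = character(), estimate = numeric(),
               ci_low = numeric(), ci_high = numeric(),
               excludes_zero = logical(), valid = logical(),
               stringsAsFactors = FALSE)
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(subset = character(), response = character(),
               factor = character(), test = character(),
               statistic = numeric(), df = numeric(), p = numeric(),
               transform = character(), stringsAsFactors = FALSE)

  missing_sightings <- if (length(cohort$tracks)) {
    pos <- unlist(lapply(cohort$tracks, `[[`, "position_cm"))
    mean(is.na(pos))
  } else NA_real_

  manifest <- list(
    config_hash = str_hash(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                                            digits = NA)),
    cohort_seed = cfg$seed, analysis_seed = seed, B = B, level = level,
    n_individuals = nrow(cohort$individuals),
    subset_sizes = lapply(subsets, function(s) nrow(s$individuals)),
    missing_sighting_rate = missing_sightings,
    timestamp = format(Sys.time(), tz = "UTC"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(results, file.path(out_dir, "bootstrap_results.csv"),
              row.names = FALSE, na = "")
    write.csv(tests, file.path(out_dir, "classical_tests.csv"),
              row.names = FALSE, na = "")
    if (!is.null(brightness))
      write.csv(brightness, file.path(out_dir, "brightness.csv"),
                row.names = FALSE, na = "")
    if (!is.null(physiology))
      write.csv(physiology, file.path(out_dir, "physiology.csv"),
                row.names = FALSE, na = "")
    if (!is.null(preferred))
      write.csv(preferred, file.path(out_dir, "preferred_temperature.csv"),
                row.names = FALSE, na = "")
    for (sn in names(curve_out)) for (cn in names(curve_out[[sn]]))
      write.csv(curve_out[[sn]][[cn]],
                file.path(out_dir, sprintf("curve_%s_%s.csv", sn, cn)),
                row.names = FALSE, na = "")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(cohort = cohort, subsets = subsets,
                 brightness = brightness, physiology = physiology,
                 preferred = preferred, results = results, tests = tests,
                 curves = curve_out, manifest = manifest))
}
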