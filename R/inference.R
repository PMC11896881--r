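# Morph-constrained nonparametric bootstrap over whole individuals.
#
# Resamples draw individuals with replacement within each colour-morph
# stratum, keeping every stratum at its original size; an individual's
# complete record (summaries and full time series) moves as one unit. 95%
# percentile confidence intervals are read off the replicate distribution,
# and an effect is called when the CI excludes zero. Curve bands reuse one
# set of resamples across all time points (coherent bands).

#' Build one species-x-sex analysis subset
#'
#' @param individuals Data.frame with at least `id` and `morph` plus any
#'   summary columns (e.g. `mass`, `brightness`, `heatup_speed`,
#'   `equilibrium`, `preferred_temp`); all rows must share species and sex.
#' @param traces Optional named list of time-series matrices (individuals in
#'   rows, time points in columns, `attr(.., "time")` giving the grid), e.g.
#'   `internal`, `external`, `substrate`.
#' @param species,sex Labels carried on the subset.
#' @return An `analysis_subset`.
#' @export
analysis_subset <- function(individuals, traces = list(),
                            species = NA_character_, sex = NA_character_) {
  stopifnot(is.data.frame(individuals), "morph" %in% names(individuals))
  for (m in traces) {
    if (nrow(m) != nrow(individuals))
      stopf("trace matrix rows must match individuals")
  }
  structure(list(individuals = individuals, traces = traces,
                 species = species, sex = sex),
            class = "analysis_subset")
}

#' @export
print.analysis_subset <- function(x, ...) {
  cat("<analysis_subset> ", x$species, " ", x$sex, ": ",
      nrow(x$individuals), " individuals (",
      paste(sprintf("%s=%d", names(table(x$individuals$morph)),
                    as.integer(table(x$individuals$morph))), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

# Stratified index draw: within each morph, sample that morph's indices with
# replacement at the original count. Assumes the caller seeded the RNG.
resample_indices <- function(morph) {
  idx <- integer(length(morph))
  for (m in unique(morph)) {
    i <- which(morph == m)
    idx[i] <- i[sample.int(length(i), length(i), replace = TRUE)]
  }
  idx
}

# Take rows idx of a subset, moving each individual's full record as a unit.
take_rows <- function(subset, idx) {
  subset$individuals <- subset$individuals[idx, , drop = FALSE]
  subset$traces <- lapply(subset$traces, function(m) {
    out <- m[idx, , drop = FALSE]
    attr(out, "time") <- attr(m, "time")
    out
  })
  subset
}

#' One morph-constrained resample of a subset
#'
#' @param subset An [analysis_subset()]; every morph stratum must be
#'   non-empty.
#' @param seed Integer seed.
#' @return A resampled `analysis_subset` of identical size and morph
#'   composition.
#' @export
constrained_resample <- function(subset, seed = 1L) {
  stopifnot(inherits(subset, "analysis_subset"))
  morph <- subset$individuals$morph
  if (!length(morph)) stopf("cannot resample an empty subset")
  with_seed(seed, take_rows(subset, resample_indices(morph)))
}

#' Percentile-bootstrap confidence interval for a subset statistic
#'
#' Draws `B` morph-constrained resamples, evaluates `statistic_fn` on each,
#' and reads the CI off the empirical replicate quantiles. The point
#' estimate is computed on the original subset and is never altered by
#' resampling. Replicates on which the statistic is undefined (error or
#' `NA`, e.g. zero rank variance in a correlation) are recorded as missing;
#' if more than half are missing the result is flagged invalid.
#'
#' @param subset An [analysis_subset()].
#' @param statistic_fn Function `(subset, idx) -> scalar`, where `idx`
#'   indexes the (re)sampled individuals; see [stat_diff_means()] and
#'   [stat_spearman()].
#' @param B Number of bootstrap iterations (default 1000).
#' @param level CI level (default 0.95).
#' @param seed Integer seed.
#' @param label Statistic label carried on the result.
#' @param quantile_type Quantile convention for the percentile method
#'   (default type 7, linear interpolation of order statistics).
#' @return A `bootstrap_result`: `label`, `estimate`, `replicates`,
#'   `ci_low`, `ci_high`, `level`, `excludes_zero`, `n_missing`, `valid`,
#'   `seed`.
#' @examples
#' s <- analysis_subset(data.frame(
#'   morph = rep(c("green", "brown"), each = 4),
#'   y = c(5, 6, 7, 8, 1, 2, 3, 4)))
#' bootstrap_ci(s, stat_diff_means("y"), B = 200, seed = 1)
#' @export
bootstrap_ci <- function(subset, statistic_fn, B = 1000L, level = 0.95,
                         seed = 1L, label = "statistic", quantile_type = 7L) {
  stopifnot(inherits(subset, "analysis_subset"))
  morph <- subset$individuals$morph
  if (any(table(morph) == 0L)) stopf("empty morph stratum")
  n <- length(morph)
  est <- statistic_fn(subset, seq_len(n))
  reps <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- resample_indices(morph)
      tryCatch(as.numeric(statistic_fn(subset, idx)),
               error = function(e) NA_real_)
    }, numeric(1))
  })
  n_missing <- sum(is.na(reps))
  ci <- percentile_ci(reps, level = level, type = quantile_type)
  structure(list(label = label, estimate = est, replicates = reps,
                 ci_low = ci[1], ci_high = ci[2], level = level,
                 excludes_zero = is.finite(ci[1]) && is.finite(ci[2]) &&
                   (ci[1] > 0 || ci[2] < 0),
                 n_missing = n_missing, valid = n_missing <= B / 2,
                 seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %s: %.4g [%.4g, %.4g] (%d%% percentile, B=%d)%s\n",
              x$label, x$estimate, x$ci_low, x$ci_high,
              round(100 * x$level), length(x$replicates),
              if (x$excludes_zero) " *excludes zero*" else ""))
  if (!x$valid) cat("  INVALID: ", x$n_missing, " missing replicates\n")
  invisible(x)
}

#' Statistic factories for [bootstrap_ci()]
#'
#' `stat_diff_means(column, a, b)` gives the available-case difference of
#' group means `mean(a) - mean(b)` (positive = first group larger; for
#' morph contrasts, green minus brown = green hotter). `stat_spearman(x, y)`
#' gives [spearman_rho()] between two summary columns on complete pairs.
#'
#' @param column,x,y Column names in `subset$individuals`.
#' @param a,b Morph labels contrasted (defaults `"green"`, `"brown"`).
#' @return A function `(subset, idx) -> scalar`.
#' @export
stat_diff_means <- function(column, a = "green", b = "brown") {
  function(subset, idx) {
    d <- subset$individuals
    v <- d[[column]][idx]
    m <- d$morph[idx]
    mean(v[m == a], na.rm = TRUE) - mean(v[m == b], na.rm = TRUE)
  }
}

#' @rdname stat_diff_means
#' @export
stat_spearman <- function(x, y) {
  function(subset, idx) {
    d <- subset$individuals
    spearman_rho(d[[x]][idx], d[[y]][idx])
  }
}

#' Spearman rank correlation
#'
#' Mid-ranks for ties, then the Pearson correlation of the ranks. Undefined
#' (returns `NA`) when either rank vector has zero variance; incomplete
#' pairs are dropped.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return The correlation in \[-1, 1\], or `NA`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stopf("need >= 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0) return(NA_real_)
  cor(rx, ry)
}

# Shared engine for the two curve operations: one set of constrained
# resamples, statistic evaluated at every time point of the chosen channel.
curve_bootstrap <- function(subset, channel, col_stat, B, level, seed,
                            quantile_type) {
  m <- subset$traces[[channel]]
  if (is.null(m)) stopf("subset has no '%s' time-series matrix", channel)
  tgrid <- attr(m, "time")
  morph <- subset$individuals$morph
  est <- col_stat(m, seq_len(nrow(m)))
  reps <- with_seed(seed, {
    t(vapply(seq_len(B), function(b) col_stat(m, resample_indices(morph)),
             numeric(ncol(m))))
  })
  a <- (1 - level) / 2
  lo <- apply(reps, 2, quantile, probs = a, type = quantile_type, na.rm = TRUE)
  hi <- apply(reps, 2, quantile, probs = 1 - a, type = quantile_type,
              na.rm = TRUE)
  data.frame(time = tgrid, estimate = est, ci_low = unname(lo),
             ci_high = unname(hi),
             excludes_zero = unname(lo > 0 | hi < 0))
}

#' Time-resolved group-difference curve with bootstrap band
#'
#' At every time point, mean temperature of `group_a` minus `group_b`
#' (positive = first group hotter), with a pointwise percentile band from
#' `B` morph-constrained resamples of whole time series — resampled once and
#' evaluated at all time points, not independently per point. All pairwise
#' morph contrasts are supported for the four-morph species.
#'
#' @param subset An [analysis_subset()] whose `traces` contain `channel`.
#' @param group_a,group_b Morph labels to contrast.
#' @param channel `"internal"`, `"external"` or `"substrate"`.
#' @param B,level,seed,quantile_type As in [bootstrap_ci()].
#' @return Data.frame `time`, `estimate`, `ci_low`, `ci_high`,
#'   `excludes_zero`; attribute `convention` documents the sign.
#' @export
difference_curve <- function(subset, group_a = "green", group_b = "brown",
                             channel = "internal", B = 1000L, level = 0.95,
                             seed = 1L, quantile_type = 7L) {
  stopifnot(inherits(subset, "analysis_subset"))
  morph <- subset$individuals$morph
  if (!any(morph == group_a) || !any(morph == group_b))
    stopf("both contrast groups must be present")
  col_stat <- function(m, idx) {
    mi <- morph[idx]
    colMeans(m[idx[mi == group_a], , drop = FALSE], na.rm = TRUE) -
      colMeans(m[idx[mi == group_b], , drop = FALSE], na.rm = TRUE)
  }
  out <- curve_bootstrap(subset, channel, col_stat, B, level, seed,
                         quantile_type)
  attr(out, "convention") <-
    sprintf("positive = %s hotter than %s", group_a, group_b)
  out
}

#' Time-resolved covariate-correlation curve with bootstrap band
#'
#' At every time point, the Spearman correlation between a per-individual
#' covariate (brightness or mass) and temperature, with percentile bands
#' from `B` morph-constrained resamples (strata preserved as for the morph
#' contrasts).
#'
#' @param subset An [analysis_subset()]; `covariate` must be a column of
#'   `subset$individuals` with no missing values.
#' @param covariate Column name, e.g. `"brightness"` or `"mass"`.
#' @inheritParams difference_curve
#' @return As [difference_curve()]; positive = higher covariate, hotter.
#' @export
correlation_curve <- function(subset, covariate = "brightness",
                              channel = "internal", B = 1000L, level = 0.95,
                              seed = 1L, quantile_type = 7L) {
  stopifnot(inherits(subset, "analysis_subset"))
  v <- subset$individuals[[covariate]]
  if (is.null(v) || any(!is.finite(v)))
    stopf("covariate '%s' must be present and complete", covariate)
  col_stat <- function(m, idx) {
    rv <- rank(v[idx])
    if (var(rv) == 0) return(rep(NA_real_, ncol(m)))
    rm_ <- apply(m[idx, , drop = FALSE], 2, rank)
    drop(cor(rv, rm_))
  }
  out <- curve_bootstrap(subset, channel, col_stat, B, level, seed,
                         quantile_type)
  attr(out, "convention") <-
    sprintf("positive = higher %s, hotter", covariate)
  out
}
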