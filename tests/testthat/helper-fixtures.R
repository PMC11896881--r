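# Shared fixtures and independent oracles. Oracles here are deliberately
# written from first principles (counting, enumeration, closed forms) and
# never call the package code paths they check.

# -- fixtures ---------------------------------------------------------------

flat_spectrum <- function(value = 10, id = "ind1",
                          body_part = "dorsal_pronotum", replicate = 1L) {
  reflectance_spectrum(id, body_part, replicate, rep(value, 701))
}

# one-species, two-morph group table for small simulations
small_groups <- function(n_green = 5, n_brown = 5, species = "sibiricus",
                         sex = "F", mass_mean = 0.36, mass_sd = 0.07,
                         brightness_mean = 5.1, brightness_sd = 1.3) {
  data.frame(species = species, sex = sex,
             morph = rep(c("green", "brown"), c(1, 1)),
             n = c(n_green, n_brown),
             mass_mean = mass_mean, mass_sd = mass_sd,
             brightness_mean = brightness_mean,
             brightness_sd = brightness_sd,
             stringsAsFactors = FALSE)
}

small_config <- function(n_green = 5, n_brown = 5, seed = 1L, ...) {
  sim_config(groups = small_groups(n_green, n_brown), seed = seed, ...)
}

# deterministic Newton-backbone trace via an explicit closed form
backbone_trace <- function(t0 = 5, t_eq = 40, k = 0.01, dt = 5,
                           duration = 790, id = "ind1",
                           channel = "internal") {
  tt <- seq(0, duration, by = dt)
  thermal_trace(id, channel, tt, t_eq - (t_eq - t0) * exp(-k * tt))
}

# -- oracles ----------------------------------------------------------------

# mid-ranks by direct counting (no rank())
midranks_bf <- function(x) {
  vapply(seq_along(x), function(i)
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2, numeric(1))
}

# Spearman rho from the definition: Pearson product-moment of mid-ranks,
# computed with explicit sums
spearman_bf <- function(x, y) {
  rx <- midranks_bf(x); ry <- midranks_bf(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (den == 0) NA_real_ else num / den
}

# Mann-Whitney U for the first sample: count pairwise wins + half ties
mw_u_bf <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# Population quantile of a discrete equal-mass distribution: smallest atom
# whose CDF reaches p (what a large-B sample quantile converges to when p
# falls strictly inside an atom's mass)
pop_quantile <- function(vals, p) {
  v <- sort(vals)
  v[which(seq_along(v) / length(v) >= p - 1e-12)[1]]
}

# All morph-constrained resamples of tiny strata, as a list of index
# vectors (ordered draws with replacement within each stratum)
enumerate_resamples <- function(morph) {
  per_stratum <- lapply(unique(morph), function(m) {
    i <- which(morph == m)
    as.matrix(do.call(expand.grid, rep(list(i), length(i))))
  })
  combos <- do.call(expand.grid,
                    lapply(per_stratum, function(m) seq_len(nrow(m))))
  lapply(seq_len(nrow(combos)), function(r) {
    idx <- integer(length(morph))
    for (s in seq_along(per_stratum)) {
      rows <- per_stratum[[s]][combos[r, s], ]
      idx[which(morph == unique(morph)[s])] <- as.integer(rows)
    }
    idx
  })
}
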