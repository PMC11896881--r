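# Synthetic-data generator: cohort structure, determinism, heat-up model,
# gradient tracks and reflectance construction.

test_that("cohort sizes match the configured counts exactly", {
  co <- generate_cohort(sim_config(seed = 3))
  expect_equal(nrow(co$individuals), 432L)
  tab <- aggregate(rep(1L, nrow(co$individuals)),
                   co$individuals[c("species", "sex", "morph")], sum)
  cfg <- sim_config()
  for (r in seq_len(nrow(cfg$groups))) {
    g <- cfg$groups[r, ]
    got <- tab$x[tab$species == g$species & tab$sex == g$sex &
                   tab$morph == g$morph]
    expect_equal(got, g$n)
  }
  # per individual: two traces, one track, ten spectra
  expect_length(co$traces, 432L)
  expect_named(co$traces[[1]], c("internal", "external"))
  expect_length(co$tracks, 432L)
  expect_true(all(vapply(co$spectra, length, 0L) == 10L))
})

test_that("zero counts give an empty cohort, not an error", {
  g <- small_groups(0, 0)
  co <- generate_cohort(sim_config(groups = g))
  expect_equal(nrow(co$individuals), 0L)
  expect_length(co$traces, 0L)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- small_config(3, 3, seed = 11)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  # and differs under another seed
  co2 <- generate_cohort(small_config(3, 3, seed = 12))
  expect_false(identical(generate_cohort(cfg)$individuals$mass,
                         co2$individuals$mass))
})

test_that("adding individuals does not perturb earlier ones", {
  co3 <- generate_cohort(small_config(3, 3, seed = 5))
  co6 <- generate_cohort(small_config(6, 6, seed = 5))
  shared <- intersect(co3$individuals$id, co6$individuals$id)
  expect_length(shared, 6L)
  for (id in shared) {
    expect_identical(co3$traces[[id]], co6$traces[[id]])
    expect_identical(co3$spectra[[id]], co6$spectra[[id]])
  }
})

test_that("invalid morph/species combinations are rejected", {
  expect_error(individual("x", "sibiricus", "F", "dorsal-green", 0.3),
               "not valid")
  g <- small_groups(); g$morph[1] <- "dorsal-green"
  expect_error(sim_config(groups = g), "invalid species/morph")
  expect_error(individual("x", "sibiricus", "F", "green", -1), "positive")
})

test_that("config validation enforces the stated invariants", {
  expect_error(sim_config(t0_sd = -1), "SDs")
  expect_error(sim_config(dip_prob = 1.2), "dip_prob")
  expect_error(sim_config(missing_prob = -0.1), "missing_prob")
  expect_error(sim_config(k0 = 0), "k0")
  expect_error(sim_config(nonsense_field = 1), "unknown")
  g <- small_groups(); g$n[1] <- 2.5
  expect_error(sim_config(groups = g), "integers")
  g2 <- small_groups(); g2$mass_mean[1] <- -0.2
  expect_error(sim_config(groups = g2), "positive")
})

test_that("heat-up backbone matches the Newton closed form", {
  # config pinned so k = k0 (m/m_ref)^beta = 0.01 exactly
  phys <- default_physiology_table()
  cfg <- sim_config(k0 = 0.01, m_ref = 0.36, noise_internal = 0,
                    dip_prob = 0, groups = small_groups(),
                    physiology = phys)
  ind <- individual("i1", "sibiricus", "F", "green", 0.36)
  tr <- simulate_heatup_trace(ind, cfg, "internal", seed = 1, t0 = 5)
  expect_equal(tr$temperature_c[tr$time_s == 0], 5)
  # closed-form oracle at t = 100 s, >= 10 significant digits
  expect_equal(tr$temperature_c[tr$time_s == 100], 40 - 35 * exp(-1),
               tolerance = 1e-12)
  # asymptote: T -> T_eq (at 10 time constants)
  long <- sim_config(k0 = 0.01, m_ref = 0.36, noise_internal = 0,
                     dip_prob = 0, duration = 5000,
                     groups = small_groups(), physiology = phys)
  tl <- simulate_heatup_trace(ind, long, "internal", seed = 1, t0 = 5)
  expect_equal(tail(tl$temperature_c, 1), 40, tolerance = 1e-4)
  # strictly increasing backbone when T_eq > T0
  expect_true(all(diff(tr$temperature_c) > 0))
})

test_that("heavier individuals sit strictly below lighter ones at all t > 0", {
  cfg <- sim_config(noise_internal = 0, dip_prob = 0,
                    groups = small_groups())
  light <- simulate_heatup_trace(individual("a", "sibiricus", "F", "green",
                                            0.2), cfg, seed = 1, t0 = 5)
  heavy <- simulate_heatup_trace(individual("b", "sibiricus", "F", "green",
                                            0.6), cfg, seed = 1, t0 = 5)
  sel <- light$time_s > 0
  expect_true(all(heavy$temperature_c[sel] < light$temperature_c[sel]))
})

test_that("trace length and grids follow floor(duration/dt) + 1", {
  cfg <- small_config()
  co <- generate_cohort(small_config(1, 0))
  tr <- co$traces[[1]]
  expect_length(tr$internal$time_s, 159L)   # 0..790 s by 5
  expect_length(tr$external$time_s, 40L)    # 0..780 s by 20
  expect_equal(tr$internal$interval, 5)
  expect_equal(tr$external$interval, 20)
})

test_that("initial dip declines from T0 + depth and meets the backbone", {
  cfg <- sim_config(noise_internal = 0, dip_prob = 1, dip_depth = 6,
                    k0 = 0.002, groups = small_groups())
  ind <- individual("i1", "sibiricus", "F", "green", 0.36)
  tr <- simulate_heatup_trace(ind, cfg, seed = 2, t0 = 5)
  expect_equal(tr$temperature_c[1], 5 + 6)
  # continuous at the 20 s anchor: sample at 20 s is on the backbone
  k <- 0.002 * (0.36 / cfg$m_ref)^cfg$beta
  expect_equal(tr$temperature_c[tr$time_s == 20],
               40 - 35 * exp(-20 * k), tolerance = 1e-10)
  # and the pre-20 s segment declines (slow heater)
  expect_true(all(diff(tr$temperature_c[tr$time_s < 20]) < 0))
})

test_that("gradient track relaxes to the preferred position", {
  cfg <- sim_config(track_noise_sd = 0, missing_prob = 0,
                    groups = small_groups())
  cal <- simulate_calibration(cfg, "runway1", seed = 4)
  target_temp <- position_to_temperature(cal, 60)
  ind <- individual("i1", "sibiricus", "F", "green", 0.36)
  tk <- simulate_gradient_track(ind, cal, cfg, pref_temp = target_temp,
                                seed = 9)
  expect_equal(tail(tk$position_cm, 1), 60, tolerance = 1e-6)
  expect_false(attr(tk, "clamped"))
  # out-of-range preference clamps and flags
  tk2 <- simulate_gradient_track(ind, cal, cfg, pref_temp = 99, seed = 9)
  expect_true(attr(tk2, "clamped"))
  expect_true(all(tk2$position_cm <= cfg$runway_length))
})

test_that("missing sightings follow the configured Bernoulli rate", {
  cfg1 <- sim_config(missing_prob = 1, groups = small_groups())
  cal <- simulate_calibration(cfg1, "runway1", seed = 4)
  ind <- individual("i1", "sibiricus", "F", "green", 0.36)
  tk <- simulate_gradient_track(ind, cal, cfg1, seed = 1)
  expect_true(all(is.na(tk$position_cm)))

  # ~10,000 sightings at p = 0.016: empirical fraction within 3 binomial SE
  cfg <- sim_config(missing_prob = 0.016, groups = small_groups())
  n_tracks <- 1700  # x 6 sightings = 10,200
  miss <- vapply(seq_len(n_tracks), function(i)
    sum(is.na(simulate_gradient_track(ind, cal, cfg, pref_temp = 30,
                                      seed = i)$position_cm)), 0)
  frac <- sum(miss) / (6 * n_tracks)
  se <- sqrt(0.016 * 0.984 / (6 * n_tracks))
  expect_lt(abs(frac - 0.016), 3 * se)
})

test_that("reflectance construction: flat target, spike, morph shapes", {
  cfg <- sim_config(jitter_sd = 0, spike_mag = 0, flat_spectra = TRUE,
                    groups = small_groups())
  ind <- individual("i1", "sibiricus", "F", "green", 0.36)
  sp <- simulate_reflectance(ind, cfg, target = 10, seed = 1)
  expect_length(sp, 10L)
  for (s in sp) expect_true(all(s$reflectance == 10))

  # spike +15 exceeds both flanking windows (654-659 nm)
  cfg2 <- sim_config(jitter_sd = 0, spike_mag = 15, groups = small_groups())
  s <- simulate_reflectance(ind, cfg2, target = 10, seed = 1)[[1]]
  wl <- s$wavelength
  spike_vals <- s$reflectance[wl >= 654 & wl <= 659]
  expect_gt(min(spike_vals), max(s$reflectance[wl >= 648 & wl <= 653]))
  expect_gt(min(spike_vals), max(s$reflectance[wl >= 660 & wl <= 665]))

  # green morph peaks near 550 nm relative to its red trough; brown rises
  cfg3 <- sim_config(jitter_sd = 0, spike_mag = 0, groups = small_groups())
  gr <- simulate_reflectance(ind, cfg3, target = 10, seed = 1)[[1]]
  expect_gt(mean(gr$reflectance[wl >= 540 & wl <= 560]),
            mean(gr$reflectance[wl >= 640 & wl <= 660]))
  br_ind <- individual("i2", "sibiricus", "F", "brown", 0.36)
  br <- simulate_reflectance(br_ind, cfg3, target = 10, seed = 1)[[1]]
  expect_gt(mean(br$reflectance[wl > 900]), mean(br$reflectance[wl < 400]))
})

test_that("config sidecar round-trips through JSON", {
  cfg <- small_config(2, 3, seed = 42)
  path <- withr::local_tempfile(fileext = ".json")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$groups, cfg$groups)
  expect_equal(cfg2$k0, cfg$k0)
  # JSON decimal round-trip is exact to ~1 ulp (beta = -1/3), not bitwise
  co_a <- generate_cohort(cfg2)$individuals
  co_b <- generate_cohort(cfg)$individuals
  expect_identical(co_a$id, co_b$id)
  expect_identical(co_a$mass, co_b$mass)
  expect_equal(co_a$true_k, co_b$true_k, tolerance = 1e-12)
})
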