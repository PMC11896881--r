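# Constrained bootstrap, percentile CIs, curves and Spearman's rho.

subset_fixture <- function(green, brown, traces = list()) {
  analysis_subset(data.frame(
    id = paste0("i", seq_len(length(green) + length(brown))),
    morph = rep(c("green", "brown"), c(length(green), length(brown))),
    y = c(green, brown), stringsAsFactors = FALSE), traces)
}

test_that("constrained resamples conserve stratum sizes, always", {
  s <- subset_fixture(rnorm(3), rnorm(5))
  for (seed in 1:200) {
    r <- constrained_resample(s, seed)
    expect_equal(as.integer(table(r$individuals$morph)[c("brown", "green")]),
                 c(5L, 3L))
  }
})

test_that("singleton strata make resampling the identity", {
  s <- subset_fixture(1.5, -2.5)
  for (seed in 1:25)
    expect_identical(constrained_resample(s, seed)$individuals$y,
                     s$individuals$y)
})

test_that("inclusion probability matches the binomial computation", {
  # stratum {a,b,c}: P(a drawn >= once) = 1 - (2/3)^3
  morph <- rep("green", 3)
  p_true <- 1 - (2 / 3)^3
  hits <- 0L
  set.seed(2024)
  n_rep <- 30000L
  for (i in seq_len(n_rep))
    hits <- hits + (1L %in% thermomorph:::resample_indices(morph))
  se <- sqrt(p_true * (1 - p_true) / n_rep)
  expect_lt(abs(hits / n_rep - p_true), 3 * se)
})

test_that("bootstrap_ci degenerates correctly and never moves the estimate", {
  s <- subset_fixture(c(1, 2, 3), c(4, 5))
  bc <- bootstrap_ci(s, function(su, idx) 7, B = 50, seed = 1)
  expect_equal(c(bc$ci_low, bc$ci_high), c(7, 7))
  expect_true(bc$excludes_zero)
  bz <- bootstrap_ci(s, function(su, idx) 0, B = 50, seed = 1)
  expect_false(bz$excludes_zero)

  # two singleton strata: degenerate CI at the observed difference
  s1 <- subset_fixture(3, 1)
  b1 <- bootstrap_ci(s1, stat_diff_means("y"), B = 100, seed = 2)
  expect_equal(b1$estimate, 2)
  expect_equal(c(b1$ci_low, b1$ci_high), c(2, 2))

  # the point estimate is computed on the original subset, whatever the seed
  ests <- vapply(1:5, function(sd)
    bootstrap_ci(s, stat_diff_means("y"), B = 20, seed = sd)$estimate, 0)
  expect_true(all(ests == ests[1]))

  # undefined replicates (here: any repeated draw) are recorded as missing
  # and can invalidate the result; the point estimate is unaffected
  fragile <- function(su, idx) if (anyDuplicated(idx)) stop("no") else 0
  bad <- bootstrap_ci(s, fragile, B = 60, seed = 1)
  expect_equal(bad$estimate, 0)
  expect_gt(bad$n_missing, 30L)  # P(duplicate) = 1 - (3!/3^3)(2/2^2) = 8/9
  expect_false(bad$valid)
})

test_that("small-strata bootstrap matches exhaustive enumeration", {
  s <- subset_fixture(c(1, 3), c(0, 10))
  stat <- stat_diff_means("y")
  idx_all <- enumerate_resamples(s$individuals$morph)
  expect_length(idx_all, 16L)
  vals <- vapply(idx_all, function(idx) stat(s, idx), 0)

  bc <- bootstrap_ci(s, stat, B = 20000, seed = 7)
  # large-B percentile CI converges to the population quantiles of the
  # equally likely enumeration atoms
  expect_equal(c(bc$ci_low, bc$ci_high),
               c(pop_quantile(vals, 0.025), pop_quantile(vals, 0.975)))
  # replicate distribution matches enumeration probabilities within 4 SE
  for (v in unique(vals)) {
    p <- mean(vals == v)
    phat <- mean(bc$replicates == v)
    expect_lt(abs(phat - p), 4 * sqrt(p * (1 - p) / 20000) + 1e-12)
  }

  # strata of sizes 3 and 2: 27 x 4 = 108 enumeration atoms
  s3 <- subset_fixture(c(1, 3, 6), c(0, 10))
  idx3 <- enumerate_resamples(s3$individuals$morph)
  expect_length(idx3, 108L)
  vals3 <- vapply(idx3, function(idx) stat(s3, idx), 0)
  bc3 <- bootstrap_ci(s3, stat, B = 20000, seed = 8)
  expect_equal(c(bc3$ci_low, bc3$ci_high),
               c(pop_quantile(vals3, 0.025), pop_quantile(vals3, 0.975)))
})

test_that("spearman_rho matches hand values and handles ties/degeneracy", {
  expect_equal(spearman_rho(1:6, (1:6)^3), 1)
  expect_equal(spearman_rho(1:6, -(1:6)^3), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_true(is.na(spearman_rho(c(1, 1, 1), c(1, 2, 3))))
  expect_error(spearman_rho(1:4, 1:3), "equal length")
})

test_that("spearman_rho equals the brute-force definition on all n <= 5", {
  x <- c(2, 5, 1, 4, 3)
  for (p in 1:60) {
    set.seed(p)
    y <- sample(5)
    expect_equal(spearman_rho(x, y), spearman_bf(x, y), tolerance = 1e-12)
    # with ties
    xt <- sample(c(1, 1, 2, 3, 3), 5)
    yt <- sample(c(2, 2, 2, 5, 7), 5)
    expect_equal(spearman_rho(xt, yt), spearman_bf(xt, yt),
                 tolerance = 1e-12)
  }
  for (n in 3:5) {
    set.seed(n)
    x2 <- rnorm(n); y2 <- rnorm(n)
    expect_equal(spearman_rho(x2, y2), spearman_bf(x2, y2),
                 tolerance = 1e-12)
  }
})

test_that("difference curves: identity, constant offset, coherent bands", {
  tgrid <- seq(20, 100, 5)
  base <- outer(rep(1, 2), sin(tgrid / 30))
  m <- rbind(base[1, ], base[1, ])  # one green, one brown, identical rows
  attr(m, "time") <- tgrid
  s <- analysis_subset(data.frame(morph = c("green", "brown")),
                       list(internal = m))
  dc <- difference_curve(s, B = 50, seed = 1)
  expect_true(all(dc$estimate == 0 & dc$ci_low == 0 & dc$ci_high == 0))
  expect_false(any(dc$excludes_zero))

  # constant offset delta on the traces reappears in the curve
  delta <- 1.7
  m2 <- rbind(base[1, ] + delta, base[1, ] + delta, base[1, ], base[1, ])
  attr(m2, "time") <- tgrid
  s2 <- analysis_subset(data.frame(morph = rep(c("green", "brown"), each = 2)),
                        list(internal = m2))
  dc2 <- difference_curve(s2, B = 50, seed = 1)
  expect_equal(dc2$estimate, rep(delta, length(tgrid)))
  expect_true(all(dc2$excludes_zero))

  expect_error(difference_curve(s, channel = "external"), "no 'external'")
})

test_that("correlation curves hit +/-1 in the deterministic cases", {
  tgrid <- c(20, 40, 60)
  # covariate equal to T(40): rho = 1 at that time point
  m <- matrix(rnorm(15), nrow = 5)
  attr(m, "time") <- tgrid
  d <- data.frame(morph = rep("green", 5), covar = m[, 2])
  s <- analysis_subset(d, list(internal = m))
  cc <- correlation_curve(s, covariate = "covar", B = 30, seed = 1)
  expect_equal(cc$estimate[2], 1)

  # mass ladder, noiseless Newton: rho = -1 early in the heat-up phase
  cfg <- sim_config(noise_internal = 0, dip_prob = 0,
                    groups = small_groups())
  masses <- c(0.1, 0.2, 0.4, 0.7, 1.1)
  tl <- lapply(masses, function(mm)
    truncate_trace(simulate_heatup_trace(
      individual("x", "sibiricus", "F", "green", mm), cfg, seed = 1,
      t0 = 5.8)))
  mm <- do.call(rbind, lapply(tl, `[[`, "temperature_c"))
  attr(mm, "time") <- tl[[1]]$time_s
  s2 <- analysis_subset(data.frame(morph = rep("green", 5), mass = masses),
                        list(internal = mm))
  cc2 <- correlation_curve(s2, covariate = "mass", B = 30, seed = 1)
  early <- attr(mm, "time") <= 240
  expect_equal(cc2$estimate[early], rep(-1, sum(early)), tolerance = 1e-12)
})
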