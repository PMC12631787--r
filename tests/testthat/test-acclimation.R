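# Antecedent-temperature window, trait regressions, acclimation functions,
# and the trait ANOVA stage.

test_that("antecedent mean handles constant, alternating and ramped series", {
  met <- fixture_met_constant(t = 20, n_days = 20)
  at <- met$timestamp[1] + 15 * 86400
  expect_equal(antecedent_mean_tair(met, at), 20, tolerance = 1e-12)

  # whole days alternating 10/30 over an even 14-day window
  met2 <- met
  day_idx <- floor(as.numeric(met2$timestamp - met2$timestamp[1]) / 86400)
  met2$tair_C <- ifelse(day_idx %% 2 == 0, 10, 30)
  expect_equal(antecedent_mean_tair(met2, at), 20, tolerance = 1e-12)

  # linear ramp 10 -> 24 across the window: mean 17 (closed form), checked
  # against direct summation
  met3 <- met
  n <- nrow(met3)
  met3$tair_C <- seq(10, 24, length.out = n)
  at3 <- met3$timestamp[n] + 1800 # window = last 14 days
  sel <- met3$timestamp >= at3 - 14 * 86400
  expect_equal(antecedent_mean_tair(met3, at3), mean(met3$tair_C[sel]),
               tolerance = 1e-12)
  ramp <- fixture_met_constant(t = 0, n_days = 14)
  ramp$tair_C <- seq(10, 24, length.out = nrow(ramp))
  expect_equal(antecedent_mean_tair(ramp, ramp$timestamp[nrow(ramp)] + 1800),
               17, tolerance = 1e-3)
})

test_that("the window is the exact closed-open k-step slice", {
  met <- fixture_met(n_days = 20)
  at <- met$timestamp[1] + 16 * 86400
  k <- 14 * 48
  sel <- met$timestamp >= at - 14 * 86400 & met$timestamp < at
  expect_equal(sum(sel), k)
  expect_equal(antecedent_mean_tair(met, at), sum(met$tair_C[sel]) / k,
               tolerance = 1e-12)
})

test_that("coverage gaps in the antecedent window are rejected with the span", {
  met <- fixture_met(n_days = 20)
  expect_error(antecedent_mean_tair(met, met$timestamp[1] + 5 * 86400),
               "does not cover")
  holey <- met[-(100:105), ]
  expect_error(antecedent_mean_tair(holey, met$timestamp[1] + 15 * 86400),
               "irregular|cover")
})

test_that("a perfectly collinear trait line is recovered exactly", {
  x <- seq(8, 25, length.out = 10)
  m <- suppressWarnings(regress_trait(2 + 0.6 * x, x, "t_opt"))
  expect_equal(m$slope, 0.6, tolerance = 1e-12)
  expect_equal(m$intercept, 2, tolerance = 1e-12)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
  expect_error(regress_trait(c(1, 2, 3), rep(5, 3)), "zero variance")
  expect_error(regress_trait(c(1, 2), c(1, 2)), ">= 3")
})

test_that("the palm T_opt acclimation slope is recovered within 2 SE", {
  met <- fixture_met(mat = 16.5, n_days = 240, noise = 2, seasonal = 6)
  truth <- species_truth("T.fortunei")
  design <- campaign_design(n_campaigns = 30, n_individuals = 1)
  obs <- generate_response_observations(truth, design, met, "light", seed = 21)
  fits <- fit_curves(obs)
  ok <- fits$flags == ""
  m <- regress_trait(fits$t_opt[ok], fits$t_antecedent[ok], "t_opt")
  expect_lt(abs(m$slope - truth$topt[["slope"]]), 2 * m$se_slope)
})

test_that("shuffled pairings rarely produce spuriously significant slopes", {
  met <- fixture_met(mat = 16.5, n_days = 240, noise = 2)
  truth <- species_truth("T.fortunei")
  design <- campaign_design(n_campaigns = 30, n_individuals = 1)
  obs <- generate_response_observations(truth, design, met, "light", seed = 22)
  fits <- fit_curves(obs)
  ok <- fits$flags == ""
  y <- fits$t_opt[ok]; x <- fits$t_antecedent[ok]
  set.seed(99)
  p_vals <- replicate(100, regress_trait(sample(y), x, "t_opt")$p_value)
  expect_gte(mean(p_vals > 0.05), 0.9)
})

test_that("acclimated R_25 evaluates the printed species lines", {
  # palm line at antecedent 0 C returns its intercept
  expect_equal(acclimated_r25("T.fortunei", 0), 0.50, tolerance = 1e-12)
  # linden line at 20 C: 1.36 - 0.0317 * 20
  expect_equal(acclimated_r25("T.cordata", 20), 1.36 - 0.0317 * 20,
               tolerance = 1e-12)
  expect_equal(acclimated_r25("T.cordata", 20), 0.726, tolerance = 1e-12)
  # zero slope: output independent of temperature
  expect_equal(acclimated_r25("x", 5, coefficients = c(0.8, 0)),
               acclimated_r25("x", 35, coefficients = c(0.8, 0)))
  expect_error(acclimated_r25("nope", 10), "unknown species")
  # positive floor when extrapolated to very hot antecedents
  expect_equal(acclimated_r25("T.cordata", 60), 0.01)
})

test_that("Q_10 acclimation is palm-specific by default", {
  expect_lt(acclimated_q10("T.fortunei", 25), acclimated_q10("T.fortunei", 10))
  expect_equal(acclimated_q10("I.aquifolium", 25),
               acclimated_q10("I.aquifolium", 10))
})

test_that("two-way trait ANOVA matches a from-scratch sums-of-squares oracle", {
  set.seed(7)
  d <- expand.grid(species = c("a", "b", "c"), site = c("s1", "s2"),
                   rep = 1:4)
  d$t_opt <- 20 + 2 * (d$species == "b") + 1.5 * (d$site == "s2") +
    rnorm(nrow(d), 0, 0.5)
  res <- trait_anova(d, "t_opt")
  an <- res$anova
  # textbook balanced two-way decomposition
  y <- d$t_opt
  mu <- mean(y)
  mi <- tapply(y, d$species, mean); mj <- tapply(y, d$site, mean)
  mij <- tapply(y, interaction(d$species, d$site), mean)
  n_rep <- 4
  ss_a <- n_rep * 2 * sum((mi - mu)^2)
  ss_b <- n_rep * 3 * sum((mj - mu)^2)
  cell <- interaction(d$species, d$site)
  ss_ab <- n_rep * sum((mij - rep(mi, 2) -
                          mj[rep(c(1, 2), each = 3)] + mu)^2)
  ss_res <- sum((y - mij[cell])^2)
  expect_equal(an[an$term == "species", "Sum Sq"], ss_a, tolerance = 1e-8)
  expect_equal(an[an$term == "site", "Sum Sq"], ss_b, tolerance = 1e-8)
  expect_equal(an[an$term == "species:site", "Sum Sq"], ss_ab, tolerance = 1e-8)
  expect_equal(an[an$term == "Residuals", "Sum Sq"], ss_res, tolerance = 1e-8)
  f_a <- (ss_a / 2) / (ss_res / (nrow(d) - 6))
  expect_equal(an[an$term == "species", "F value"], f_a, tolerance = 1e-8)
})

test_that("a strongly shifted species separates at p < 0.001", {
  set.seed(8)
  d <- expand.grid(species = c("a", "b"), site = c("s1", "s2"), rep = 1:5)
  d$r25 <- rnorm(nrow(d), 0.8, 0.05) + 10 * (d$species == "b")
  res <- trait_anova(d, "r25")
  expect_lt(res$anova[res$anova$term == "species", "Pr(>F)"], 0.001)
})

test_that("identical observations and empty cells are handled explicitly", {
  d <- expand.grid(species = c("a", "b"), site = c("s1", "s2"), rep = 1:3)
  d$q10 <- 2
  res <- trait_anova(d, "q10")
  expect_true(all(res$anova[res$anova$term != "Residuals", "Sum Sq"] < 1e-12))
  expect_identical(res$tukey$note, "zero residual variance")
  d2 <- d[!(d$species == "a" & d$site == "s2"), ]
  expect_error(trait_anova(d2, "q10"), "empty design cell")
})

test_that("acclimation-slope recovery is unbiased across seeded replicates", {
  # mean recovered slope across replicates within 5% of the generating slope
  met <- fixture_met(mat = 16.5, n_days = 200, noise = 2)
  truth <- species_truth("I.aquifolium")
  design <- campaign_design(n_campaigns = 6, n_individuals = 8)
  slopes <- vapply(1:25, function(s) {
    obs <- generate_response_observations(truth, design, met, "dark", seed = s)
    fits <- fit_curves(obs)
    ok <- fits$flags == "" & is.finite(fits$r25)
    regress_trait(fits$r25[ok], fits$t_antecedent[ok], "r25")$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - truth$r25[["slope"]]),
            0.05 * abs(truth$r25[["slope"]]))
})
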