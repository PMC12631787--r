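# Coupled leaf model primitives and the nested solver.

test_that("peaked Arrhenius is normalised at 25 C and peaks at the closed form", {
  for (ds in c(630, 650, 668)) {
    expect_equal(peaked_arrhenius(37.5, 25, 71.513, 200, ds), 37.5,
                 tolerance = 1e-12)
    # argmax on a fine grid vs closed form
    tt <- seq(0, 60, by = 0.001)
    v <- peaked_arrhenius(1, tt, 71.513, 200, ds)
    expect_equal(tt[which.max(v)], peak_temperature(71.513, 200, ds),
                 tolerance = 0.001)
  }
  expect_error(peaked_arrhenius(1, 25, 200, 100, 640), "no peak")
})

test_that("entropy acclimation shifts the response peak with growth temperature", {
  expect_equal(acclimate_entropy(10, "vcmax", coefficients = c(650, 0)),
               acclimate_entropy(35, "vcmax", coefficients = c(650, 0)))
  tg <- seq(10, 35, by = 1)
  ds <- acclimate_entropy(tg, "vcmax")
  expect_true(all(diff(ds) < 0)) # negative default slope
  tp <- peak_temperature(71.513, 200, ds)
  expect_true(all(diff(tp) > 0)) # warmer growth -> higher peak
  expect_error(acclimate_entropy(20, "jmax", coefficients = NA), "missing")
})

test_that("the limiting rate switches regimes and is continuous at the crossover", {
  p <- fixture_params()
  dark <- limiting_rate(280, 25, 0, p)
  expect_equal(dark$b, 0)
  expect_identical(dark$which, "rubp")
  lowci <- limiting_rate(60, 25, 1500, p)
  expect_identical(lowci$which, "rubisco")
  # find the crossover ci and check continuity of the minimum there
  f <- function(ci) {
    l <- limiting_rate(ci, 25, 600, p)
    wc <- l$vcmax * (ci - l$gamma_star) / (ci + l$km)
    wj <- (l$j / 4) * (ci - l$gamma_star) / (ci + 2 * l$gamma_star)
    wc - wj
  }
  if (sign(f(50)) != sign(f(1500))) {
    cx <- oracle_bisect(f, 50, 1500)
    b_lo <- limiting_rate(cx - 1e-7, 25, 600, p)$b
    b_hi <- limiting_rate(cx + 1e-7, 25, 600, p)$b
    expect_lt(abs(b_hi - b_lo), 1e-6)
  }
  expect_error(limiting_rate(-5, 25, 500, p), "ci must")
})

test_that("the stomatal-optimum expression matches an independent evaluation", {
  # zero numerator: B (ci - gamma) == R (D ci + E)
  ci <- 300; gamma <- 45; d_c <- 1; e_m <- 700; f_c <- 280; ca <- 400
  b <- 2; r <- b * (ci - gamma) / (d_c * ci + e_m)
  expect_equal(gs_max_optimal(ci, ca, gamma, b, r, d_c, e_m, f_c), 0)
  # homogeneity: doubling both numerator terms doubles the output
  g1 <- gs_max_optimal(250, 400, 45, 6, 0.5, d_c, e_m, f_c)
  g2 <- gs_max_optimal(250, 400, 45, 12, 1.0, d_c, e_m, f_c)
  expect_equal(g2, 2 * g1, tolerance = 1e-12)
  # randomized admissible inputs vs a duplicate of the printed formula
  set.seed(31)
  for (i in 1:50) {
    ci <- runif(1, 60, 390); ca <- 400; gamma <- runif(1, 30, 60)
    b <- runif(1, 1, 30); r <- runif(1, 0.1, 1.5)
    e_m <- runif(1, 80, 900); f_c <- runif(1, 0, 400); d_c <- runif(1, 0.5, 2)
    ref <- max(0, (b * (ci - gamma) - r * (d_c * ci + e_m)) /
                 ((e_m + f_c) * (ci - ca)))
    expect_equal(gs_max_optimal(ci, ca, gamma, b, r, d_c, e_m, f_c), ref,
                 tolerance = 1e-12)
  }
  expect_error(gs_max_optimal(400, 400, 45, 5, 0.5, 1, 700, 280), "singularity")
})

test_that("hydraulic down-regulation has the right limits and matches a scan oracle", {
  p <- fixture_params()
  # zero demand: psi_leaf = psi_soil, gs = gs_max * cost(psi_soil)
  h0 <- hydraulic_gs(0.2, -0.5, 0, p)
  expect_equal(h0$psi_leaf, -0.5, tolerance = 1e-9)
  cost <- 1 / (1 + (-0.5 / p$psi50)^p$shape)
  expect_equal(h0$gs, max(p$gmin, 0.2 * cost), tolerance = 1e-9)
  # well-watered saturation
  hw <- hydraulic_gs(0.2, 0, 0.1, p)
  expect_gt(hw$gs, 0.195)
  # the coupled system E = 1.6 gs vpd / P, psi = psi_soil - E / K(psi),
  # gs = max(gmin, gs_max cost(psi)) reduces to one unknown psi: scan it
  # densely and compare the implied conductance
  for (case in list(c(0.15, -0.8, 2.5), c(0.02, -0.1, 3.5),
                    c(0.001, 0, 1))) {
    gs_max <- case[1]; psi_soil <- case[2]; vpd <- case[3]
    h <- hydraulic_gs(gs_max, psi_soil, vpd, p)
    cost_fun <- function(psi) 1 / (1 + (pmin(psi, 0) / p$psi50)^p$shape)
    psi_grid <- seq(5 * p$psi50, psi_soil, by = 1e-3)
    gs_of <- pmax(p$gmin, gs_max * cost_fun(psi_grid))
    resid <- abs(psi_grid - psi_soil +
                   1.6 * gs_of * vpd / (101.325 * p$kmax_plant *
                                          cost_fun(psi_grid)))
    psi_star <- psi_grid[which.min(resid)]
    expect_lt(abs(h$psi_leaf - psi_star), 2e-3)
    expect_lt(abs(h$gs - max(p$gmin, gs_max * cost_fun(psi_star))), 1e-4)
  }
  expect_error(hydraulic_gs(0.1, 0.5, 1, p), "psi_soil")
  expect_error(hydraulic_gs(0.1, 0, -1, p), "vpd")
})

test_that("respiration at leaf temperature follows the Q10 law", {
  expect_equal(respiration_at_tl(25, 0.4, 2), 0.4, tolerance = 1e-15)
  expect_equal(respiration_at_tl(35, 0.4, 2), 0.8, tolerance = 1e-12)
  expect_equal(respiration_at_tl(30, 0.4, 2), 0.4 * sqrt(2), tolerance = 1e-12)
  expect_equal(respiration_at_tl(30, 0.4, 2), 0.5657, tolerance = 1e-4)
  expect_error(respiration_at_tl(25, -0.1, 2), "r25")
})

test_that("the energy balance has exact no-forcing and heating limits", {
  p <- fixture_params(absorptance = 1)
  # no absorbed radiation, closed stomata: t_leaf = t_air exactly
  eb0 <- leaf_energy_balance(20, 0, 60, 1, 0, p)
  expect_equal(eb0$t_leaf, 20, tolerance = 1e-9)
  # radiation load with closed stomata heats the leaf
  eb1 <- leaf_energy_balance(20, 1000, 60, 1, 0, p)
  expect_gt(eb1$t_leaf, 20)
  expect_true(eb1$converged)
  expect_error(leaf_energy_balance(20, 0, 0, 1, 0, p), "rh")
})

test_that("the energy balance agrees with a dense grid root search", {
  p <- fixture_params()
  eb <- leaf_energy_balance(28, 800, 50, 1.5, 0.12, p)
  grid <- seq(20, 40, by = 0.001)
  res <- vapply(grid, function(tl)
    thermacclim:::.eb_residual(tl, 28, 800, 50, 1.5, 0.12, p, 101.325),
    numeric(1))
  expect_equal(eb$t_leaf, grid[which.min(abs(res))], tolerance = 0.01)
  expect_lt(abs(eb$residual), 0.01)
})

test_that("the nocturnal leaf state closes on dark respiration", {
  p <- fixture_params()
  rec <- fixture_midday(ppfd = 0)
  st <- solve_leaf_state(rec, p)
  expect_equal(st$a_net, -st$rd, tolerance = 1e-7)
  expect_equal(st$a_gross, 0, tolerance = 1e-9)
  expect_equal(st$gs, p$gmin, tolerance = 1e-12)
})

test_that("every solved step closes carbon and energy budgets", {
  p <- fixture_params()
  met <- fixture_met(n_days = 4, seed = 3)
  st <- solve_leaf_states(met, p)
  expect_true(all(abs(st$a_gross - st$rd - st$a_net) < 1e-9))
  expect_true(all(st$gs >= p$gmin - 1e-15))
  conv <- st$converged
  expect_gt(mean(conv), 0.99)
  expect_true(all(abs(st$eb_residual[conv]) < 0.01))
  # diffusion-biochemistry consistency at convergence
  a_diff <- st$gs * (met$co2_ppm - st$ci)
  expect_true(all(abs(a_diff[conv] - st$a_net[conv]) < 1e-6))
  # determinism: no internal randomness
  expect_identical(st, solve_leaf_states(met, p))
})

test_that("gs never rises with VPD and A_gross never falls with PPFD", {
  p <- fixture_params()
  # holding everything else (including leaf temperature) fixed, the
  # stomatal chain is strictly non-increasing in VPD
  gs_h <- vapply(seq(0, 4, by = 0.25), function(v)
    hydraulic_gs(0.06, -0.3, v, p)$gs, numeric(1))
  expect_true(all(diff(gs_h) <= 1e-12))
  # in the fully coupled model (leaf temperature responding too), drier air
  # still closes stomata overall
  gs_v <- vapply(c(90, 50, 15), function(rh) {
    solve_leaf_state(fixture_midday(rh = rh), p)$gs
  }, numeric(1)) # falling rh = rising vpd
  expect_lt(gs_v[3], gs_v[1])
  # PPFD response with the radiative load decoupled (tiny absorptance), so
  # light acts through electron transport alone; leaf heating is exercised
  # by the energy-balance tests
  p_cool <- fixture_params(absorptance = 1e-6)
  ag <- vapply(c(0, 100, 300, 600, 1000, 1500), function(q)
    solve_leaf_state(fixture_midday(ppfd = q), p_cool)$a_gross, numeric(1))
  expect_true(all(diff(ag) >= -1e-10))
})

test_that("the coupled solution matches an independent 2-D scan over (ci, t_leaf)", {
  p <- fixture_params()
  rec <- fixture_midday(tair = 24, rh = 55, ppfd = 450)
  st <- solve_leaf_state(rec, p)
  # scan each residual on a fine grid around the solution: the diffusion/
  # biochemistry balance pins ci at 0.1 ppm resolution and the energy
  # balance pins t_leaf at 0.01 C resolution
  ci_grid <- seq(150, 395, by = 0.1)
  scan <- expand.grid(tl = seq(st$t_leaf - 1, st$t_leaf + 1, by = 0.01))
  a_diff <- st$gs * (rec$co2_ppm - ci_grid)
  lim <- limiting_rate(ci_grid, st$t_leaf, rec$ppfd_umol_m2_s, p)
  a_bio <- lim$b - st$rd
  ci_best <- ci_grid[which.min(abs(a_diff - a_bio))]
  expect_lt(abs(st$ci - ci_best), 0.1)
  eb_res <- vapply(scan$tl, function(tl)
    abs(thermacclim:::.eb_residual(tl, rec$tair_C, rec$ppfd_umol_m2_s,
                                   rec$rh_pct, rec$wind_m_s, st$gs, p,
                                   101.325)), numeric(1))
  expect_lt(abs(st$t_leaf - scan$tl[which.min(eb_res)]), 0.01)
})

test_that("acclimation at the reference configuration is a no-op", {
  sp <- "T.fortunei"
  tg_ref <- 17
  p_on <- species_params(sp)
  p_off <- species_params(sp)
  p_off$r25 <- acclimated_r25(sp, tg_ref)
  p_off$q10 <- acclimated_q10(sp, tg_ref)
  p_off$t_growth_ref <- tg_ref
  met <- fixture_met(n_days = 2, seed = 5)
  on <- solve_leaf_states(met, p_on, acclimation = "on", t_growth = tg_ref)
  off <- solve_leaf_states(met, p_off, acclimation = "off")
  expect_equal(on$a_net, off$a_net, tolerance = 1e-12)
  expect_equal(on$t_leaf, off$t_leaf, tolerance = 1e-12)
})

test_that("the printed net-uptake reading is available behind the audit switch", {
  p <- fixture_params()
  rec <- fixture_midday()
  st_ph <- solve_leaf_state(rec, p)
  st_pr <- solve_leaf_state(rec, p, uptake_convention = "printed")
  # printed reading shifts the diffusion constraint by Rd
  expect_false(isTRUE(all.equal(st_ph$ci, st_pr$ci)))
  a_diff_printed <- st_pr$gs * (rec$co2_ppm - st_pr$ci) + st_pr$rd
  expect_equal(a_diff_printed, st_pr$a_net, tolerance = 1e-6)
})
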