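# Shared fixtures, built in code at test time.

# short met series with known structure
fixture_met <- function(mat = 15, n_days = 30, step_minutes = 30, seed = 1,
                        noise = 1.5, seasonal = 8, diurnal = 8, ...) {
  site <- site_config("fixture", mat, seasonal_amplitude = seasonal,
                      diurnal_amplitude = diurnal, noise_sd_tair = noise, ...)
  generate_met_series(site, "2023-04-01", n_days, step_minutes, seed)
}

# constant-temperature met series (no seasonality, diurnal cycle or noise)
fixture_met_constant <- function(t = 20, n_days = 20, step_minutes = 30,
                                 rh = 70) {
  site <- site_config("const", t, seasonal_amplitude = 0,
                      diurnal_amplitude = 0, noise_sd_tair = 0, rh_mean = rh)
  generate_met_series(site, "2023-04-01", n_days, step_minutes, seed = 1)
}

# one standard mid-day met record
fixture_midday <- function(tair = 25, rh = 60, ppfd = 500, wind = 1,
                           co2 = 400) {
  data.frame(timestamp = as.POSIXct("2023-06-01 12:00:00", tz = "UTC"),
             tair_C = tair, rh_pct = rh, ppfd_umol_m2_s = ppfd,
             wind_m_s = wind, co2_ppm = co2, pressure_kPa = 101.325)
}

fixture_params <- function(species = "I.aquifolium", ...) {
  species_params(species, ...)
}

# bisection root-finder used as an independent oracle in several tests
oracle_bisect <- function(f, lo, hi, tol = 1e-9, maxit = 200) {
  flo <- f(lo)
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(flo)) { lo <- mid; flo <- f(mid) } else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}
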