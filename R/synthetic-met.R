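# Synthetic meteorological drivers: seasonal + diurnal sinusoids with
# additive Gaussian noise, understory shading of light, and relative humidity
# derived from a fixed site dew point so that RH is anti-correlated with
# air temperature.

#' Configure a synthetic site climate
#'
#' @param site_id Character label.
#' @param mean_annual_tair Mean annual air temperature, deg C.
#' @param seasonal_amplitude Half-range of the seasonal temperature cycle, deg C.
#' @param diurnal_amplitude Peak-to-trough diurnal range, deg C.
#' @param noise_sd_tair Gaussian noise sd added per step, deg C.
#' @param shading_fraction Fraction of sunlight obstructed by the shading
#'   infrastructure, at least 0 and below 1 (the experiment obstructed 70
#'   percent).
#' @param daylength_hours Day length used for the light window, hours.
#' @param rh_mean Mean relative humidity at the mean temperature, percent.
#' @param co2_ambient Ambient CO2, ppm.
#' @param ppfd_max Open-sky midday PPFD before shading, umol m-2 s-1.
#' @param wind Constant wind speed, m s-1.
#' @param pressure_kpa Atmospheric pressure, kPa.
#' @return A `site_config` list.
#' @export
site_config <- function(site_id, mean_annual_tair,
                        seasonal_amplitude = 8, diurnal_amplitude = 8,
                        noise_sd_tair = 1.5, shading_fraction = 0.7,
                        daylength_hours = 13, rh_mean = 70,
                        co2_ambient = 400, ppfd_max = 1800, wind = 1,
                        pressure_kpa = 101.325) {
  if (shading_fraction < 0 || shading_fraction >= 1)
    .fail("shading_fraction must be in [0, 1), got %g", shading_fraction)
  if (seasonal_amplitude < 0 || diurnal_amplitude < 0)
    .fail("amplitudes must be >= 0")
  if (rh_mean <= 0 || rh_mean > 100)
    .fail("rh_mean must be in (0, 100], got %g", rh_mean)
  structure(list(
    site_id = site_id, mean_annual_tair = mean_annual_tair,
    seasonal_amplitude = seasonal_amplitude,
    diurnal_amplitude = diurnal_amplitude,
    noise_sd_tair = noise_sd_tair, shading_fraction = shading_fraction,
    daylength_hours = daylength_hours, rh_mean = rh_mean,
    co2_ambient = co2_ambient, ppfd_max = ppfd_max, wind = wind,
    pressure_kpa = pressure_kpa
  ), class = "site_config")
}

#' Generate a half-hourly (or other step) meteorological driver series
#'
#' Air temperature is the sum of the site mean, a seasonal cosine peaking in
#' mid-July (day of year 197), a diurnal cosine peaking at 15:00, and iid
#' Gaussian noise. PPFD follows a half-sine over the daylight window scaled by
#' `(1 - shading_fraction)` and is exactly zero at night. RH is computed from
#' a fixed site dew point (set so RH equals `rh_mean` at the site mean
#' temperature) and clamped to (5, 100].
#'
#' @param site A [site_config()].
#' @param start_date Start date (`Date` or ISO string), first step at 00:00 UTC.
#' @param n_days Number of days to generate (>= 1).
#' @param step_minutes Step length in minutes; must divide 1440.
#' @param seed Integer seed; the series is bit-reproducible for a given seed.
#' @return A `data.frame` with columns `timestamp` (POSIXct UTC), `tair_C`,
#'   `rh_pct`, `ppfd_umol_m2_s`, `wind_m_s`, `co2_ppm`, `pressure_kPa`.
#' @export
generate_met_series <- function(site, start_date, n_days, step_minutes = 30,
                                seed = 1) {
  stopifnot(inherits(site, "site_config"))
  if (n_days < 1) .fail("n_days must be >= 1, got %g", n_days)
  if (1440 %% step_minutes != 0)
    .fail("step_minutes (%g) must divide 1440", step_minutes)
  start <- as.POSIXct(paste(as.Date(start_date), "00:00:00"), tz = "UTC")
  n <- n_days * (1440 %/% step_minutes)
  ts <- start + seq_len(n) * (step_minutes * 60) - step_minutes * 60

  doy <- as.numeric(strftime(ts, "%j", tz = "UTC")) +
    (as.numeric(ts) %% 86400) / 86400
  hour <- (as.numeric(ts) %% 86400) / 3600

  seasonal <- site$seasonal_amplitude * cos(2 * pi * (doy - 197) / 365.25)
  diurnal <- (site$diurnal_amplitude / 2) * cos(2 * pi * (hour - 15) / 24)
  noise <- if (site$noise_sd_tair > 0)
    with_seed(seed_stream(seed, 1L), stats::rnorm(n, 0, site$noise_sd_tair))
  else rep(0, n)
  tair <- site$mean_annual_tair + seasonal + diurnal + noise

  # light: half-sine across the daylight window, understory-shaded
  dl <- site$daylength_hours
  dawn <- 12 - dl / 2
  frac <- (hour - dawn) / dl
  ppfd <- ifelse(frac > 0 & frac < 1,
                 site$ppfd_max * sin(pi * pmin(pmax(frac, 0), 1)), 0) *
    (1 - site$shading_fraction)

  # fixed dew point -> RH anti-correlated with T
  ea <- site$rh_mean / 100 * esat_kpa(site$mean_annual_tair)
  rh <- pmin(100, pmax(5, 100 * ea / esat_kpa(tair)))

  data.frame(
    timestamp = ts, tair_C = tair, rh_pct = rh, ppfd_umol_m2_s = ppfd,
    wind_m_s = rep(site$wind, n), co2_ppm = rep(site$co2_ambient, n),
    pressure_kPa = rep(site$pressure_kpa, n)
  )
}

# step length (seconds) of a met series, with a gap check
.met_step_seconds <- function(met) {
  d <- diff(as.numeric(met$timestamp))
  if (length(d) == 0) return(NA_real_)
  step <- d[1]
  if (any(d != step))
    .fail("met series has irregular steps (first gap after %s)",
          format(met$timestamp[which(d != step)[1]], tz = "UTC"))
  step
}
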