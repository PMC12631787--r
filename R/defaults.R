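# Versioned defaults: species acclimation lines, site climates, and the
# photosynthesis-model constants used throughout the package.
#
# Trait acclimation lines are of the form trait = intercept + slope * T_ant,
# where T_ant is the mean air temperature of the 14 days preceding a
# measurement. Slopes are the species-specific field estimates; intercepts are
# anchored so each line passes through the species mean trait value at the
# mid-gradient antecedent temperature of 16.5 C (the field reports slopes and
# species means, not intercepts).

.TMID <- 16.5 # deg C, anchor for trait-line intercepts

#' Species defaults: acclimation lines and physiology
#'
#' Returns the per-species defaults used by the synthetic-data generator and
#' by [acclimated_r25()] / [acclimated_q10()]. The three species are the
#' invasive windmill palm (`T.fortunei`, evergreen), European holly
#' (`I.aquifolium`, evergreen) and small-leaved linden (`T.cordata`,
#' deciduous).
#'
#' Elements per species:
#' * `topt`, `aopt`, `t80`: `c(intercept, slope)` of the trait line on
#'   antecedent air temperature (deg C resp. umol m-2 s-1 per deg C).
#' * `r25`: `c(intercept, slope)` of the R_25 acclimation line,
#'   umol m-2 s-1 (per deg C).
#' * `q10`: `c(intercept, slope)`; the slope is non-zero only for the palm,
#'   where Q_10 declines with antecedent temperature (the magnitude of that
#'   decline is a documented placeholder, configurable by the caller).
#' * `aopt_per_topt`: field coupling of A_opt to T_opt (umol m-2 s-1 per C).
#' * `deciduous`: logical phenology flag.
#'
#' @return Named list of per-species default lists.
#' @export
species_defaults <- function() {
  line <- function(mean, slope) c(intercept = mean - slope * .TMID, slope = slope)
  list(
    T.fortunei = list(
      topt = line(21.3, 0.60),
      aopt = line(2.86, 0.16),
      t80  = line(11.1, 0.19),
      r25  = c(intercept = 0.50, slope = -0.0037),
      q10  = line(2.0, -0.02),  # placeholder slope; relation exists, value unpublished
      aopt_per_topt = 0.12,
      obs_noise_sd_a = 0.2,
      obs_noise_sd_r = 0.03,
      deciduous = FALSE
    ),
    I.aquifolium = list(
      topt = line(22.7, 0.55),
      aopt = line(5.50, 0.19),
      t80  = line(13.9, 0.00),
      r25  = c(intercept = 1.42, slope = -0.0293),
      q10  = c(intercept = 2.2, slope = 0),
      aopt_per_topt = 0.23,
      obs_noise_sd_a = 0.2,
      obs_noise_sd_r = 0.03,
      deciduous = FALSE
    ),
    T.cordata = list(
      topt = line(23.9, 0.33),
      aopt = line(6.96, 0.00),
      t80  = line(15.2, 0.00),
      r25  = c(intercept = 1.36, slope = -0.0317),
      q10  = c(intercept = 2.1, slope = 0),
      aopt_per_topt = 0.27,
      obs_noise_sd_a = 0.2,
      obs_noise_sd_r = 0.03,
      deciduous = TRUE
    )
  )
}

#' Default experimental-site climates
#'
#' Five sites spanning the measured-period mean annual air temperatures of the
#' transplant gradient (8.4 to 21.8 C), coldest to warmest. The
#' sub-Mediterranean site is the reference. Each element is a [site_config()].
#'
#' @return Named list of site configurations.
#' @export
site_defaults <- function() {
  mk <- function(id, mat) site_config(site_id = id, mean_annual_tair = mat)
  list(
    cold              = mk("cold", 8.4),
    temperate         = mk("temperate", 13.3),
    sub_mediterranean = mk("sub_mediterranean", 15.2),
    mediterranean     = mk("mediterranean", 17.7),
    semi_arid         = mk("semi_arid", 21.8)
  )
}

# Peaked-Arrhenius acclimation coefficients for Vcmax/Jmax
# (Kattge & Knorr 2007 "general coefficients"):
#   Ha_V = 71.513 kJ mol-1, Ha_J = 49.884 kJ mol-1, Hd = 200 kJ mol-1
#   dS_V = 668.39 - 1.07 * T_growth   [J mol-1 K-1, T_growth in deg C]
#   dS_J = 659.70 - 0.75 * T_growth
#' Entropy-acclimation coefficients for the peaked-Arrhenius response
#'
#' @return List with `vcmax` and `jmax` components, each
#'   `c(intercept, slope)` in J mol-1 K-1 (per deg C growth temperature),
#'   plus activation/deactivation energies `ha_v`, `ha_j`, `hd` in kJ mol-1.
#' @export
entropy_coefficients <- function() {
  list(
    vcmax = c(intercept = 668.39, slope = -1.07),
    jmax  = c(intercept = 659.70, slope = -0.75),
    ha_v = 71.513, ha_j = 49.884, hd = 200
  )
}

# Michaelis-Menten / compensation-point kinetics (Bernacchi et al. 2001),
# rates in umol mol-1 (Ko in mmol mol-1), activation energies kJ mol-1.
.KINETICS <- list(
  gamma_star25 = 42.75, ha_gamma = 37.83,
  kc25 = 404.9, ha_kc = 79.43,
  ko25 = 278.4, ha_ko = 36.38,
  o2 = 210 # mmol mol-1
)

#' Constants of the stomatal-optimum expression
#'
#' The D and F constants of the g_s,max expression (the E metric is the
#' temperature-adjusted Michaelis term of the active limitation and is
#' computed at run time). F is a calibratable offset (ppm) standing in for
#' the C_i dependence of the exact Fickian denominator; its default equals
#' the operating intercellular concentration at ambient CO2 (0.7 x 400 ppm),
#' at which the expression reproduces the Fickian conductance.
#'
#' @return List with elements `d` (unitless) and `f` (ppm).
#' @export
stomatal_constants <- function() list(d = 1, f = 280)
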