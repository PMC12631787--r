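# Species parameter container for the coupled SPAC leaf model.

#' Build a species parameter set for the SPAC leaf model
#'
#' Returns a validated parameter list. When `species` is one of the three
#' focal species, field-plausible defaults are filled in (photosynthetic
#' capacities, minimum conductance, hydraulics, leaf geometry) together with
#' the species acclimation coefficient lines from [species_defaults()];
#' any element can be overridden through `...`.
#'
#' @param species Species label (free-form; defaults exist for
#'   `"T.fortunei"`, `"I.aquifolium"`, `"T.cordata"`).
#' @param ... Named overrides of any parameter listed below.
#' @return A `species_params` list with elements: `vcmax25`, `jmax25`
#'   (umol m-2 s-1), `r25` (umol m-2 s-1), `q10`, `gmin` (mol CO2 m-2 s-1),
#'   `ha_v`, `ha_j`, `hd` (kJ mol-1), `ds_v`, `ds_j` (J mol-1 K-1 or `NULL`
#'   to derive from growth temperature), `gamma_star25`, `kc25` (umol mol-1),
#'   `ko25`, `o2` (mmol mol-1) with activation energies, `alpha`, `theta`
#'   (electron-transport light response), `kmax_plant`
#'   (mol m-2 s-1 MPa-1), `psi50` (MPa, < 0), `shape` (vulnerability-curve
#'   exponent), `leaf_area_total` (m2), `lrr`, `leaf_width` (m),
#'   `absorptance` (0-1, total shortwave), `t_growth_ref` (deg C),
#'   `r25_acclim`, `q10_acclim` (`c(intercept, slope)` acclimation lines),
#'   `d_const`, `f_const` (stomatal-optimum constants), `gs_cap`
#'   (mol CO2 m-2 s-1).
#' @export
species_params <- function(species = "T.fortunei", ...) {
  sd_all <- species_defaults()
  sp <- sd_all[[species]]
  base <- list(
    species = species,
    vcmax25 = 55, jmax25 = 95,
    r25 = 0.6, q10 = 2,
    gmin = 0.01,
    ha_v = entropy_coefficients()$ha_v,
    ha_j = entropy_coefficients()$ha_j,
    hd = entropy_coefficients()$hd,
    ds_v = NULL, ds_j = NULL,
    gamma_star25 = .KINETICS$gamma_star25, ha_gamma = .KINETICS$ha_gamma,
    kc25 = .KINETICS$kc25, ha_kc = .KINETICS$ha_kc,
    ko25 = .KINETICS$ko25, ha_ko = .KINETICS$ha_ko,
    o2 = .KINETICS$o2,
    alpha = 0.24, theta = 0.85,
    kmax_plant = 0.002, psi50 = -2.5, shape = 2,
    leaf_area_total = 0.4, lrr = 8, leaf_width = 0.05,
    absorptance = 0.5,
    t_growth_ref = 17,
    r25_acclim = NULL, q10_acclim = NULL, entropy_coef = NULL,
    d_const = stomatal_constants()$d, f_const = stomatal_constants()$f,
    ci_ratio = 0.7, gs_cap = 1
  )
  if (!is.null(sp)) {
    per_species <- switch(species,
      T.fortunei = list(vcmax25 = 14, jmax25 = 28, r25 = 0.40, q10 = 2.0,
                        gmin = 0.010, psi50 = -2.5, leaf_area_total = 0.35,
                        leaf_width = 0.04),
      I.aquifolium = list(vcmax25 = 25, jmax25 = 48, r25 = 0.85, q10 = 2.2,
                          gmin = 0.008, psi50 = -3.5, leaf_area_total = 0.40,
                          leaf_width = 0.05),
      T.cordata = list(vcmax25 = 32, jmax25 = 60, r25 = 0.75, q10 = 2.1,
                       gmin = 0.012, psi50 = -2.0, leaf_area_total = 0.60,
                       leaf_width = 0.06)
    )
    base[names(per_species)] <- per_species
    base$r25_acclim <- sp$r25
    base$q10_acclim <- sp$q10
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(base))
  if (length(unknown)) .fail("unknown parameter(s): %s",
                             paste(unknown, collapse = ", "))
  base[names(dots)] <- dots
  p <- base
  if (any(c(p$vcmax25, p$jmax25, p$r25, p$q10, p$gmin, p$kmax_plant) <= 0))
    .fail("rates and conductances must be > 0")
  if (p$hd <= p$ha_v || p$hd <= p$ha_j)
    .fail("deactivation energy hd must exceed activation energies")
  if (p$absorptance <= 0 || p$absorptance > 1)
    .fail("absorptance must be in (0, 1]")
  if (p$psi50 >= 0) .fail("psi50 must be negative (MPa)")
  structure(p, class = "species_params")
}
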