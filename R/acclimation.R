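# Antecedent temperature, trait-on-temperature regressions, and the
# species-specific acclimation functions consumed by the simulator.

#' Mean air temperature of the preceding window
#'
#' Arithmetic mean of `tair_C` over the closed-open interval
#' `[at - window_days, at)`. The window must be fully covered by the met
#' series (no gap larger than one step).
#'
#' @param met Met driver `data.frame` (see [generate_met_series()]).
#' @param at Timestamp (POSIXct or coercible) the window ends at (excluded).
#' @param window_days Window length in days (default 14, the two-week
#'   acclimation window).
#' @return Mean temperature, deg C.
#' @export
antecedent_mean_tair <- function(met, at, window_days = 14) {
  at <- as.POSIXct(at, tz = "UTC")
  step <- .met_step_seconds(met)
  from <- at - window_days * 86400
  sel <- met$timestamp >= from & met$timestamp < at
  k_expected <- round(window_days * 86400 / step)
  if (sum(sel) < k_expected)
    .fail("met series does not cover [%s, %s): %d of %d steps present",
          format(from, tz = "UTC"), format(at, tz = "UTC"),
          sum(sel), k_expected)
  mean(met$tair_C[sel])
}

#' Regress a fitted trait on antecedent air temperature
#'
#' Ordinary least squares of campaign-level trait values on the 2-week
#' antecedent mean air temperature, as used for the acclimation relationships.
#'
#' @param trait_values Numeric trait values (one per campaign mean).
#' @param antecedent_temps Matching antecedent temperatures, deg C.
#' @param trait Trait label (`"t_opt"`, `"a_opt"`, `"t80"`, `"r25"`, `"q10"`, ...).
#' @param species Optional species label carried into the result.
#' @return An `acclimation_model` list: `trait`, `species`, `intercept`,
#'   `slope`, `se_intercept`, `se_slope`, `r_squared`, `p_value`, `n`.
#' @export
regress_trait <- function(trait_values, antecedent_temps, trait = "trait",
                          species = NA_character_) {
  ok <- is.finite(trait_values) & is.finite(antecedent_temps)
  y <- trait_values[ok]; x <- antecedent_temps[ok]
  if (length(y) < 3) .fail("need >= 3 paired finite values, got %d", length(y))
  if (stats::sd(x) == 0) .fail("zero variance in antecedent temperatures")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  co <- sm$coefficients
  structure(list(
    trait = trait, species = species,
    intercept = unname(co[1, 1]), slope = unname(co[2, 1]),
    se_intercept = unname(co[1, 2]), se_slope = unname(co[2, 2]),
    r_squared = sm$r.squared,
    p_value = unname(co[2, 4]),
    n = length(y)
  ), class = "acclimation_model")
}

#' Acclimated dark respiration at 25 C
#'
#' Evaluates the species-specific linear acclimation of R_25 on the 2-week
#' antecedent air temperature, `R_25 = intercept + slope * T_ant`, clamped at
#' a positive floor so extrapolation to hot sites never yields non-positive
#' respiration. Default coefficients per species:
#' `T.fortunei` 0.50 - 0.0037 T, `I.aquifolium` 1.42 - 0.0293 T,
#' `T.cordata` 1.36 - 0.0317 T (umol m-2 s-1).
#'
#' @param species Species label, one of `names(species_defaults())` unless
#'   `coefficients` is supplied.
#' @param antecedent_tair Antecedent mean air temperature, deg C.
#' @param coefficients Optional `c(intercept, slope)` override.
#' @param floor Lower clamp, umol m-2 s-1 (default 0.01).
#' @return R_25 in umol m-2 s-1.
#' @export
acclimated_r25 <- function(species, antecedent_tair, coefficients = NULL,
                           floor = 0.01) {
  if (is.null(coefficients)) {
    sp <- species_defaults()[[species]]
    if (is.null(sp)) .fail("unknown species '%s'", species)
    coefficients <- sp$r25
  }
  pmax(floor, coefficients[[1]] + coefficients[[2]] * antecedent_tair)
}

#' Acclimated Q_10 of dark respiration
#'
#' Linear-in-temperature Q_10 acclimation, enabled by default only for the
#' palm (the other species carry zero slopes). Clamped below at `floor` so the
#' respiration curve keeps a positive temperature sensitivity.
#'
#' @inheritParams acclimated_r25
#' @param floor Lower clamp on Q_10 (default 1.1).
#' @return Q_10, unitless.
#' @export
acclimated_q10 <- function(species, antecedent_tair, coefficients = NULL,
                           floor = 1.1) {
  if (is.null(coefficients)) {
    sp <- species_defaults()[[species]]
    if (is.null(sp)) .fail("unknown species '%s'", species)
    coefficients <- sp$q10
  }
  pmax(floor, coefficients[[1]] + coefficients[[2]] * antecedent_tair)
}

#' Two-way ANOVA with Tukey HSD for a fitted trait
#'
#' Species x climate analysis of variance on a fits table, followed by Tukey
#' HSD pairwise comparisons within each factor. Requires every species x site
#' cell to be populated.
#'
#' @param fits `data.frame` with columns `species`, `site`, and the trait.
#' @param trait Name of the trait column to analyse.
#' @return List with `anova` (the two-way ANOVA table as a `data.frame`) and
#'   `tukey` (list of pairwise tables for species and site).
#' @export
trait_anova <- function(fits, trait) {
  for (col in c("species", "site", trait))
    if (!col %in% names(fits)) .fail("fits table lacks column '%s'", col)
  d <- fits[is.finite(fits[[trait]]), , drop = FALSE]
  tab <- table(d$species, d$site)
  if (any(tab == 0)) {
    idx <- which(tab == 0, arr.ind = TRUE)[1, ]
    .fail("empty design cell: species '%s' at site '%s'",
          rownames(tab)[idx[1]], colnames(tab)[idx[2]])
  }
  if (nrow(tab) < 2 || ncol(tab) < 2)
    .fail("need >= 2 species and >= 2 sites")
  d$species <- factor(d$species); d$site <- factor(d$site)
  d$.y <- d[[trait]]
  fit <- stats::aov(.y ~ species * site, data = d)
  an <- as.data.frame(summary(fit)[[1]])
  an$term <- trimws(rownames(an))
  rownames(an) <- NULL
  resid_ms <- an[an$term == "Residuals", "Mean Sq"]
  ms_floor <- .Machine$double.eps * max(1, sum(d$.y^2))
  tukey <- if (is.finite(resid_ms) && resid_ms > ms_floor) {
    tk <- stats::TukeyHSD(fit, which = c("species", "site"))
    lapply(tk, as.data.frame)
  } else {
    # zero residual variance: pairwise contrasts undefined, reported as such
    list(species = NULL, site = NULL, note = "zero residual variance")
  }
  list(anova = an, tukey = tukey)
}
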