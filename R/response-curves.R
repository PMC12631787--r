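# Temperature-response curve fitting: parabolic assimilation curves
# A_i = A_opt - b (T_i - T_opt)^2, exponential respiration curves
# R_i = R_25 * Q_10^((T_i - 25)/10), and the thermal breadth T_80.

#' Fit the parabolic assimilation-temperature response
#'
#' Least-squares fit of `A = A_opt - b (T - T_opt)^2` to light-mode gas
#' exchange points. The parabola is a reparameterised quadratic, so the
#' global least-squares optimum is obtained exactly from the linear fit of
#' `A ~ T + T^2`; parameter standard errors come from the delta method.
#' Thermal breadth `t80` is filled in via [thermal_breadth()].
#'
#' A fit with non-positive curvature (`b <= 0`) or with too few points is
#' returned as a flagged failure record rather than dropped silently.
#'
#' @param temperature Measurement temperatures, deg C (cuvette set to ambient).
#' @param flux Net assimilation, umol m-2 s-1. Points below the compensation
#'   point (negative flux) are retained.
#' @return A `photo_temp_fit` list: `a_opt`, `t_opt`, `b`, `t80`,
#'   `r_squared`, `n_points`, `std_errors` (named), `flags` (character).
#' @export
fit_parabolic <- function(temperature, flux) {
  fail <- function(flag) structure(list(
    a_opt = NA_real_, t_opt = NA_real_, b = NA_real_, t80 = NA_real_,
    r_squared = NA_real_, n_points = length(flux),
    std_errors = c(a_opt = NA_real_, t_opt = NA_real_, b = NA_real_),
    flags = flag), class = "photo_temp_fit")
  if (length(temperature) != length(flux)) .fail("length mismatch")
  if (length(flux) < 4) return(fail("too_few_points"))
  if (length(unique(temperature)) < 3) return(fail("degenerate_temperatures"))
  fit <- stats::lm(flux ~ temperature + I(temperature^2))
  cf <- stats::coef(fit)
  b <- -cf[[3]]
  if (!is.finite(b) || b <= 0) return(fail("nonpositive_curvature"))
  t_opt <- cf[[2]] / (2 * b)
  a_opt <- cf[[1]] + b * t_opt^2
  # delta method on (c0, c1, c2) -> (a_opt, t_opt, b)
  V <- stats::vcov(fit)
  g_topt <- c(0, 1 / (2 * b), cf[[2]] / (2 * b^2))
  # a_opt = c0 + c1^2/(4b), b = -c2
  g_aopt <- c(1, cf[[2]] / (2 * b), cf[[2]]^2 / (4 * b^2))
  g_b <- c(0, 0, -1)
  se <- sqrt(c(
    a_opt = drop(t(g_aopt) %*% V %*% g_aopt),
    t_opt = drop(t(g_topt) %*% V %*% g_topt),
    b = drop(t(g_b) %*% V %*% g_b)
  ))
  r2 <- summary(fit)$r.squared
  t80 <- if (a_opt > 0) thermal_breadth(a_opt, b) else NA_real_
  flags <- character(0)
  if (a_opt <= 0) flags <- c(flags, "nonpositive_a_opt")
  # an optimum outside the sampled range cannot be located reliably
  if (t_opt < min(temperature) || t_opt > max(temperature))
    flags <- c(flags, "t_opt_out_of_range")
  structure(list(
    a_opt = a_opt, t_opt = t_opt, b = b, t80 = t80,
    r_squared = r2, n_points = length(flux), std_errors = se,
    flags = paste(flags, collapse = ";")
  ), class = "photo_temp_fit")
}

#' Thermal breadth of photosynthesis (T_80)
#'
#' Width of the temperature interval over which assimilation exceeds 80% of
#' its optimum, obtained by solving the parabola `A(T) = 0.8 A_opt`:
#' `T_80 = 2 sqrt(0.2 A_opt / b)`.
#'
#' @param a_opt Assimilation at the optimum, umol m-2 s-1 (> 0).
#' @param b Curve width parameter, umol m-2 s-1 C-2 (> 0).
#' @return T_80 in deg C.
#' @export
thermal_breadth <- function(a_opt, b) {
  if (any(a_opt <= 0)) .fail("a_opt must be > 0")
  if (any(b <= 0)) .fail("b must be > 0")
  2 * sqrt(0.2 * a_opt / b)
}

#' Predict assimilation from a parabolic fit
#'
#' @param object A `photo_temp_fit`.
#' @param temperature Temperatures, deg C.
#' @param ... Unused.
#' @return Predicted net assimilation, umol m-2 s-1.
#' @export
predict.photo_temp_fit <- function(object, temperature, ...) {
  object$a_opt - object$b * (temperature - object$t_opt)^2
}

#' Fit the exponential respiration-temperature response
#'
#' Nonlinear least squares for `R = R_25 * Q_10^((T - 25)/10)` on dark-mode
#' points, started from the exact log-linear regression of `ln R` on
#' `(T - 25)/10`.
#'
#' @param temperature Measurement temperatures, deg C.
#' @param flux Dark respiration rates, umol m-2 s-1; must all be positive.
#' @return A `resp_temp_fit` list: `r25`, `q10`, `r_squared`, `n_points`,
#'   `std_errors`, `flags` (`"low_q10"` when the fitted Q_10 <= 1, which
#'   downstream regressions exclude).
#' @export
fit_exponential <- function(temperature, flux) {
  if (length(temperature) != length(flux)) .fail("length mismatch")
  if (any(flux <= 0)) .fail("dark respiration fluxes must be positive")
  if (length(flux) < 3) .fail("need >= 3 dark-mode points, got %d", length(flux))
  if (length(unique(temperature)) < 2)
    return(structure(list(
      r25 = NA_real_, q10 = NA_real_, r_squared = NA_real_,
      n_points = length(flux),
      std_errors = c(r25 = NA_real_, q10 = NA_real_),
      flags = "degenerate_temperatures"), class = "resp_temp_fit"))
  x <- (temperature - 25) / 10
  lin <- stats::lm(log(flux) ~ x)
  start <- list(r25 = exp(stats::coef(lin)[[1]]), q10 = exp(stats::coef(lin)[[2]]))
  fit <- minpack.lm::nlsLM(flux ~ r25 * q10^x,
                           start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  se <- summary(fit)$coefficients[, 2]
  pred <- stats::predict(fit)
  ss_res <- sum((flux - pred)^2)
  ss_tot <- sum((flux - mean(flux))^2)
  structure(list(
    r25 = unname(cf["r25"]), q10 = unname(cf["q10"]),
    r_squared = 1 - ss_res / ss_tot, n_points = length(flux),
    std_errors = c(r25 = unname(se["r25"]), q10 = unname(se["q10"])),
    flags = if (cf["q10"] <= 1) "low_q10" else ""
  ), class = "resp_temp_fit")
}

#' Predict respiration from an exponential fit
#'
#' @param object A `resp_temp_fit`.
#' @param temperature Temperatures, deg C.
#' @param ... Unused.
#' @return Predicted dark respiration, umol m-2 s-1. At 25 C this returns
#'   exactly `r25` for any `q10`.
#' @export
predict.resp_temp_fit <- function(object, temperature, ...) {
  object$r25 * object$q10^((temperature - 25) / 10)
}

#' Fit response curves for every individual x campaign group
#'
#' Applies [fit_parabolic()] to the light-mode points and [fit_exponential()]
#' to the dark-mode points of each `site x species x individual x campaign`
#' group of a gas-exchange observation table, returning one row per group.
#' Fits flagged as failures keep their row with NA estimates and a non-empty
#' `flags` value.
#'
#' @param obs Observation table in the gas-exchange CSV dialect (columns
#'   `site`, `species`, `individual`, `campaign`, `mode`, `tleaf_C`,
#'   `anet_umol_m2_s`, optionally `t_antecedent`).
#' @param pool_individuals If `TRUE`, pool individuals and fit one curve per
#'   `site x species x campaign` (the per-site pooled variant); default fits
#'   per individual.
#' @return `data.frame` with columns `site`, `species`, `individual`,
#'   `campaign`, `t_antecedent`, `a_opt`, `t_opt`, `b`, `t80`, `r25`, `q10`,
#'   `r2_light`, `r2_dark`, `n_light`, `n_dark`, `flags`.
#' @export
fit_curves <- function(obs, pool_individuals = FALSE) {
  need <- c("site", "species", "individual", "campaign", "mode",
            "tleaf_C", "anet_umol_m2_s")
  for (col in need) if (!col %in% names(obs)) .fail("missing column '%s'", col)
  keys <- if (pool_individuals) c("site", "species", "campaign")
  else c("site", "species", "individual", "campaign")
  grp <- interaction(obs[keys], drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(obs, grp), function(g) {
    light <- g[g$mode == "light", ]
    dark <- g[g$mode == "dark", ]
    pf <- if (nrow(light) > 0) fit_parabolic(light$tleaf_C, light$anet_umol_m2_s)
    else NULL
    rf <- if (nrow(dark) >= 3 && all(dark$anet_umol_m2_s > 0))
      fit_exponential(dark$tleaf_C, dark$anet_umol_m2_s) else NULL
    flags <- paste(c(if (!is.null(pf) && nzchar(pf$flags)) pf$flags,
                     if (!is.null(rf) && nzchar(rf$flags)) rf$flags),
                   collapse = ";")
    data.frame(
      site = g$site[1], species = g$species[1],
      individual = if (pool_individuals) NA else g$individual[1],
      campaign = g$campaign[1],
      t_antecedent = if ("t_antecedent" %in% names(g)) g$t_antecedent[1] else NA,
      a_opt = if (is.null(pf)) NA else pf$a_opt,
      t_opt = if (is.null(pf)) NA else pf$t_opt,
      b = if (is.null(pf)) NA else pf$b,
      t80 = if (is.null(pf)) NA else pf$t80,
      r25 = if (is.null(rf)) NA else rf$r25,
      q10 = if (is.null(rf)) NA else rf$q10,
      r2_light = if (is.null(pf)) NA else pf$r_squared,
      r2_dark = if (is.null(rf)) NA else rf$r_squared,
      n_light = nrow(light), n_dark = nrow(dark),
      flags = flags,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
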