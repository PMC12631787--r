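# Coupled leaf gas-exchange model: Farquhar-type limitation, stomatal optimum
# with hydraulic down-regulation, peaked-Arrhenius thermal response with
# entropy acclimation, Q10 respiration on leaf temperature, closed by a leaf
# energy balance through nested iteration. All solvers are vectorized over
# time steps; every function is deterministic.

# Stefan-Boltzmann (W m-2 K-4), leaf emissivity, molar heat capacity of air
.SIGMA <- 5.670374e-8
.EMISS <- 0.97
.CP_MOL <- 29.3 # J mol-1 K-1
# latent heat of vaporisation, J mol-1, weak linear T dependence
.lambda_mol <- function(t_c) 45064.3 - 42.9 * t_c
# PAR energy content: 1 W m-2 PAR ~ 4.57 umol m-2 s-1; total shortwave ~ 2x PAR
.PAR_UMOL_PER_J <- 4.57

#' Peaked Arrhenius temperature response, normalised at 25 C
#'
#' Scales a rate known at 25 C with the peaked (deactivating) Arrhenius
#' factor, which rises with activation energy `ha` and declines past a peak
#' set by the deactivation energy `hd` and entropy `ds`. Returns exactly
#' `k25` at 25 C for any parameter combination.
#'
#' @param k25 Rate at 25 C.
#' @param t_leaf Leaf temperature, deg C (vectorised).
#' @param ha Activation energy, kJ mol-1 (0 < ha < hd).
#' @param hd Deactivation energy, kJ mol-1.
#' @param ds Entropy factor, J mol-1 K-1.
#' @return Scaled rate.
#' @seealso [peak_temperature()] for the closed-form peak location.
#' @export
peaked_arrhenius <- function(k25, t_leaf, ha, hd, ds) {
  if (hd <= ha) .fail("hd (%g) must exceed ha (%g): no peak exists", hd, ha)
  tk <- .c_to_k(t_leaf)
  ha_j <- ha * 1000; hd_j <- hd * 1000
  num <- 1 + exp((298.15 * ds - hd_j) / (.RGAS * 298.15))
  den <- 1 + exp((tk * ds - hd_j) / (.RGAS * tk))
  k25 * exp(ha_j * (tk - 298.15) / (.RGAS * 298.15 * tk)) * num / den
}

#' Closed-form peak temperature of the peaked Arrhenius response
#'
#' @inheritParams peaked_arrhenius
#' @return Temperature of the response maximum, deg C:
#'   `Hd / (dS - R ln(Ha / (Hd - Ha))) - 273.15`.
#' @export
peak_temperature <- function(ha, hd, ds) {
  if (hd <= ha) .fail("hd must exceed ha")
  hd * 1000 / (ds - .RGAS * log(ha / (hd - ha))) - 273.15
}

#' Growth-temperature acclimation of the entropy factor
#'
#' Linear function of growth temperature with the published general
#' coefficients recorded in [entropy_coefficients()] (Kattge & Knorr 2007):
#' dS_V = 668.39 - 1.07 T_growth, dS_J = 659.70 - 0.75 T_growth.
#'
#' @param t_growth Growth temperature (2-week antecedent mean), deg C.
#' @param process `"vcmax"` or `"jmax"`.
#' @param coefficients `c(intercept, slope)` override; defaults come from
#'   [entropy_coefficients()].
#' @return Entropy factor, J mol-1 K-1.
#' @export
acclimate_entropy <- function(t_growth, process = c("vcmax", "jmax"),
                              coefficients = NULL) {
  process <- match.arg(process)
  if (is.null(coefficients)) coefficients <- entropy_coefficients()[[process]]
  if (length(coefficients) < 2 || any(!is.finite(coefficients[1:2])))
    .fail("entropy coefficients missing for process '%s'", process)
  coefficients[[1]] + coefficients[[2]] * t_growth
}

# electron transport from a non-rectangular hyperbola of PPFD
.j_rate <- function(ppfd, jmax, alpha, theta) {
  q <- alpha * ppfd
  (q + jmax - sqrt((q + jmax)^2 - 4 * theta * q * jmax)) / (2 * theta)
}

#' CO2-uptake limiting rate
#'
#' Computes the Rubisco-limited and electron-transport-limited carboxylation
#' terms at temperature-adjusted V_cmax and J_max (J from a non-rectangular
#' hyperbola of PPFD) and returns their minimum `b` together with which
#' limitation is active. The matching capacity (`V_cmax` or `J/4`) and
#' Michaelis metric (`K_m = Kc (1 + O/Ko)` or `2 Gamma*`) of the active
#' limitation are reported for use in [gs_max_optimal()].
#'
#' @param ci Intercellular CO2, ppm (> 0); vectorised.
#' @param t_leaf Leaf temperature, deg C.
#' @param ppfd Photosynthetic photon flux, umol m-2 s-1.
#' @param params A [species_params()].
#' @param ds_v,ds_j Entropy factors (J mol-1 K-1); default from
#'   [acclimate_entropy()] at `params$t_growth_ref`.
#' @return List: `b` (limiting rate, umol m-2 s-1), `which` (`"rubisco"` or
#'   `"rubp"`), `capacity`, `e_metric`, `gamma_star`, `km`, `rd` is not
#'   included (respiration is handled separately).
#' @export
limiting_rate <- function(ci, t_leaf, ppfd, params, ds_v = NULL, ds_j = NULL) {
  if (any(ci <= 0)) .fail("ci must be > 0")
  if (is.null(ds_v)) ds_v <- params$ds_v %||% acclimate_entropy(params$t_growth_ref, "vcmax")
  if (is.null(ds_j)) ds_j <- params$ds_j %||% acclimate_entropy(params$t_growth_ref, "jmax")
  gamma <- arrhenius(params$gamma_star25, params$ha_gamma, t_leaf)
  kc <- arrhenius(params$kc25, params$ha_kc, t_leaf)
  ko <- arrhenius(params$ko25, params$ha_ko, t_leaf)
  km <- kc * (1 + params$o2 / ko)
  vc <- peaked_arrhenius(params$vcmax25, t_leaf, params$ha_v, params$hd, ds_v)
  jm <- peaked_arrhenius(params$jmax25, t_leaf, params$ha_j, params$hd, ds_j)
  jr <- .j_rate(ppfd, jm, params$alpha, params$theta)
  wc <- vc * (ci - gamma) / (ci + km)
  wj <- (jr / 4) * (ci - gamma) / (ci + 2 * gamma)
  rubisco <- wc <= wj
  list(
    b = pmin(wc, wj),
    which = ifelse(rubisco, "rubisco", "rubp"),
    capacity = ifelse(rubisco, vc, jr / 4),
    e_metric = ifelse(rubisco, km, 2 * gamma),
    gamma_star = gamma, km = km, vcmax = vc, jmax = jm, j = jr
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Maximum stomatal conductance from the optimisation expression
#'
#' Evaluates the printed stomatal-optimum expression
#' `g_s,max = (B (C_i - Gamma) - R (D C_i + E)) / ((E + F) (C_i - C_a))`,
#' floored at zero. `B` is the CO2-uptake limiting rate, `R` dark
#' respiration, `E` the Michaelis metric of the active limitation, and `D`,
#' `F` constants (see [stomatal_constants()]).
#'
#' @param ci Intercellular CO2, ppm.
#' @param ca Ambient CO2, ppm (`ci != ca`).
#' @param gamma CO2 compensation point, ppm.
#' @param b_rate Limiting rate B, umol m-2 s-1.
#' @param rd Dark respiration, umol m-2 s-1.
#' @param d_const,f_const Constants D (unitless) and F (ppm).
#' @param e_metric Carboxylation/oxygenation metric E, ppm.
#' @return g_s,max in mol CO2 m-2 s-1, >= 0.
#' @export
gs_max_optimal <- function(ci, ca, gamma, b_rate, rd, d_const, e_metric, f_const) {
  if (any(ci == ca)) .fail("ci = ca is a singularity of the expression")
  num <- b_rate * (ci - gamma) - rd * (d_const * ci + e_metric)
  pmax(0, num / ((e_metric + f_const) * (ci - ca)))
}

# Working orientation used inside the solver: same numerator, denominator
# read atmosphere-ward as (E + F)(Ca - Ci); zero above ambient Ci, capped.
.gs_max_oriented <- function(ci, ca, gamma, b_rate, rd, d_const, e_metric,
                             f_const, cap) {
  num <- b_rate * (ci - gamma) - rd * (d_const * ci + e_metric)
  gs <- ifelse(ci < ca - 1e-9,
               num / ((e_metric + f_const) * (ca - ci)), 0)
  pmin(pmax(gs, 0), cap)
}

# sigmoidal hydraulic cost in [0, 1]; 1 at psi = 0, 0.5 at psi50
.hydraulic_cost <- function(psi, psi50, shape) {
  1 / (1 + (pmin(psi, 0) / psi50)^shape)
}

#' Hydraulic down-regulation of stomatal conductance
#'
#' Solves the self-consistent system E = 1.6 g_s VPD_leaf / P_atm,
#' psi_leaf = psi_soil - E / K(psi), g_s = g_s,max * cost(psi_leaf) with a
#' sigmoidal vulnerability cost. Because the plant conductance K and the
#' stomatal down-regulation share the vulnerability sigmoid, the
#' unconstrained solution is closed-form; only the `gmin`-floored branch
#' needs a bisection. The result is never below `gmin`.
#'
#' @param gs_max Unregulated conductance, mol CO2 m-2 s-1 (vectorised).
#' @param psi_soil Soil water potential, MPa (<= 0).
#' @param vpd_leaf Leaf-to-air vapour pressure deficit, kPa (>= 0).
#' @param params A [species_params()] (uses `kmax_plant`, `psi50`, `shape`,
#'   `gmin`).
#' @param patm Atmospheric pressure, kPa.
#' @param max_iter,tol Fixed-point controls.
#' @return List with `gs` (mol CO2 m-2 s-1), `psi_leaf` (MPa),
#'   `converged` (logical).
#' @export
hydraulic_gs <- function(gs_max, psi_soil, vpd_leaf, params,
                         patm = 101.325, max_iter = 30, tol = 1e-6) {
  if (any(vpd_leaf < 0)) .fail("vpd_leaf must be >= 0")
  if (any(psi_soil > 0)) .fail("psi_soil must be <= 0")
  n <- max(length(gs_max), length(vpd_leaf), length(psi_soil))
  gs_max <- rep_len(gs_max, n); vpd <- rep_len(vpd_leaf, n)
  psi_s <- rep_len(psi_soil, n)
  psi_min <- 5 * params$psi50
  # Because conductance loss and stomatal down-regulation share the same
  # vulnerability sigmoid, the cost factor cancels between transpiration
  # demand E = 1.6 gs vpd / P and supply K(psi) (psi_s - psi), giving the
  # unconstrained leaf water potential in closed form.
  psi_unc <- pmax(psi_min, psi_s - 1.6 * gs_max * vpd / (patm * params$kmax_plant))
  gs_unc <- gs_max * .hydraulic_cost(psi_unc, params$psi50, params$shape)
  bind <- gs_unc < params$gmin
  # gmin-bound leaves: psi solves psi = psi_s - 1.6 gmin vpd / (P K(psi))
  cc <- 1.6 * params$gmin * vpd / (patm * params$kmax_plant)
  lo <- rep(psi_min, n); hi <- psi_s
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    h <- mid - psi_s + cc / .hydraulic_cost(mid, params$psi50, params$shape)
    pos <- h > 0 # root lies below
    hi <- ifelse(pos, mid, hi)
    lo <- ifelse(pos, lo, mid)
  }
  psi_bind <- (lo + hi) / 2
  psi <- ifelse(bind, psi_bind, psi_unc)
  gs <- ifelse(bind, params$gmin, gs_unc)
  list(gs = gs, psi_leaf = psi, converged = TRUE)
}

#' Dark respiration at leaf temperature
#'
#' Exponential Q10 response evaluated at leaf temperature:
#' `R_d = R_25 Q_10^((T_L - 25)/10)`.
#'
#' @param t_leaf Leaf temperature, deg C.
#' @param r25 Respiration at 25 C, umol m-2 s-1 (> 0).
#' @param q10 Temperature sensitivity (> 0).
#' @return R_d, umol m-2 s-1.
#' @export
respiration_at_tl <- function(t_leaf, r25, q10) {
  if (any(r25 <= 0) || any(q10 <= 0)) .fail("r25 and q10 must be > 0")
  r25 * q10^((t_leaf - 25) / 10)
}

# energy-balance residual (W m-2) at leaf temperature tl, vectorised
.eb_residual <- function(tl, t_air, ppfd, rh, wind, gs, params, patm) {
  sw_abs <- params$absorptance * 2 * ppfd / .PAR_UMOL_PER_J
  ta_k <- .c_to_k(t_air); tl_k <- .c_to_k(tl)
  gbh <- 1.4 * 0.135 * sqrt(wind / params$leaf_width)
  gbw <- 1.4 * 0.147 * sqrt(wind / params$leaf_width)
  gsw <- 1.6 * gs # water-vapour stomatal conductance
  gtw <- ifelse(gsw > 0, 1 / (1 / gsw + 1 / gbw), 0)
  ea <- rh / 100 * esat_kpa(t_air)
  e_mol <- gtw * pmax(esat_kpa(tl) - ea, 0) / patm
  sw_abs + .EMISS * .SIGMA * ta_k^4 - .EMISS * .SIGMA * tl_k^4 -
    .CP_MOL * gbh * (tl - t_air) - .lambda_mol(tl) * e_mol
}

#' Leaf temperature from the energy balance
#'
#' Finds the leaf temperature at which absorbed shortwave plus incoming
#' longwave balances emitted longwave, sensible and latent heat. Boundary-
#' layer conductances follow the flat-leaf forced-convection forms
#' `g_bH = 1.4 * 0.135 sqrt(u/d)` (and 0.147 for vapour). Solved by damped
#' Newton iteration; converged solutions have residual < 0.01 W m-2.
#'
#' @param t_air Air temperature, deg C (vectorised).
#' @param ppfd PPFD, umol m-2 s-1.
#' @param rh Relative humidity, percent in (0, 100].
#' @param wind Wind speed, m s-1 (> 0).
#' @param gs Stomatal conductance to CO2, mol m-2 s-1 (>= 0).
#' @param params A [species_params()].
#' @param patm Atmospheric pressure, kPa.
#' @param max_iter Newton iterations.
#' @return List with `t_leaf` (deg C), `residual` (W m-2), `converged`.
#' @export
leaf_energy_balance <- function(t_air, ppfd, rh, wind, gs, params,
                                patm = 101.325, max_iter = 10) {
  if (any(rh <= 0 | rh > 100)) .fail("rh must be in (0, 100]")
  if (any(gs < 0)) .fail("gs must be >= 0")
  tl <- t_air
  for (i in seq_len(max_iter)) {
    f0 <- .eb_residual(tl, t_air, ppfd, rh, wind, gs, params, patm)
    fp <- (.eb_residual(tl + 5e-4, t_air, ppfd, rh, wind, gs, params, patm) -
           .eb_residual(tl - 5e-4, t_air, ppfd, rh, wind, gs, params, patm)) / 1e-3
    step <- f0 / fp
    tl <- pmin(pmax(tl - step, t_air - 25), t_air + 25)
  }
  res <- .eb_residual(tl, t_air, ppfd, rh, wind, gs, params, patm)
  list(t_leaf = tl, residual = res, converged = abs(res) < 0.01)
}

#' Solve the coupled leaf state for a series of met records
#'
#' Nested solution of the full leaf model at every time step: an outer damped
#' fixed point on leaf temperature encloses an inner bisection on C_i that
#' makes the diffusion constraint `A_net = g_s (C_a - C_i)` (g_s in CO2
#' units) consistent with the biochemical rate `A_net = min(W_c, W_j) - R_d`,
#' with stomatal conductance from the optimisation expression down-regulated
#' hydraulically, respiration at leaf temperature, and leaf temperature from
#' the energy balance. All steps are solved simultaneously (vectorised).
#'
#' With `acclimation = "on"`, the entropy factors follow `t_growth` through
#' [acclimate_entropy()] and R_25 / Q_10 follow the species acclimation lines
#' (`params$r25_acclim`, `params$q10_acclim`); with `"off"`, all four are held
#' at the values in `params` (entropy at `params$t_growth_ref`).
#'
#' @param met Met driver `data.frame` (see [generate_met_series()]).
#' @param params A [species_params()].
#' @param psi_soil Soil water potential, MPa (scalar or per-step).
#' @param acclimation `"off"` or `"on"`.
#' @param t_growth Growth temperature (2-week antecedent mean air
#'   temperature), deg C; scalar or per-step vector. Required when
#'   `acclimation = "on"`.
#' @param uptake_convention `"physical"` (default; diffusion constraint with
#'   R_d subtracted in the biochemical rate) or `"printed"` (net uptake read
#'   as `g_s (C_a - C_i) + R_d`), kept as an audit switch.
#' @param control List of solver controls: `outer_max` (50), `tol_tl`
#'   (0.01 C), `damping` (0.5), `inner_iter` (32 bisection steps).
#' @return `data.frame` with one row per met step: `t_leaf`, `gs`
#'   (mol CO2 m-2 s-1), `ci` (ppm), `a_net`, `a_gross`, `rd`
#'   (umol m-2 s-1), `transpiration` (mmol m-2 s-1), `psi_leaf` (MPa),
#'   `eb_residual` (W m-2), `converged`, `iterations`.
#' @export
solve_leaf_states <- function(met, params, psi_soil = 0,
                              acclimation = c("off", "on"), t_growth = NULL,
                              uptake_convention = c("physical", "printed"),
                              control = list()) {
  acclimation <- match.arg(acclimation)
  uptake_convention <- match.arg(uptake_convention)
  ctl <- utils::modifyList(
    list(outer_max = 50, tol_tl = 0.01, damping = 0.5, inner_iter = 32),
    control)
  n <- nrow(met)
  tair <- met$tair_C; rh <- met$rh_pct; ppfd <- met$ppfd_umol_m2_s
  wind <- met$wind_m_s %||% rep(1, n)
  ca <- met$co2_ppm %||% rep(400, n)
  patm <- (met$pressure_kPa %||% rep(101.325, n))[1]

  if (acclimation == "on") {
    if (is.null(t_growth)) .fail("t_growth is required when acclimation is on")
    tg <- rep_len(t_growth, n)
    ds_v <- acclimate_entropy(tg, "vcmax",
                              coefficients = params$entropy_coef$vcmax)
    ds_j <- acclimate_entropy(tg, "jmax",
                              coefficients = params$entropy_coef$jmax)
    r25_t <- if (!is.null(params$r25_acclim))
      acclimated_r25(params$species, tg, coefficients = params$r25_acclim)
    else rep(params$r25, n)
    q10_t <- if (!is.null(params$q10_acclim))
      acclimated_q10(params$species, tg, coefficients = params$q10_acclim)
    else rep(params$q10, n)
  } else {
    ds_v <- params$ds_v %||% acclimate_entropy(params$t_growth_ref, "vcmax")
    ds_j <- params$ds_j %||% acclimate_entropy(params$t_growth_ref, "jmax")
    r25_t <- params$r25
    q10_t <- params$q10
  }

  tl <- tair
  iterations <- 0L
  outer_converged <- FALSE
  gs <- rep(params$gmin, n); ci <- ca; psi_leaf <- rep(psi_soil, n)
  lim <- NULL

  inner_solve <- function(tl) {
    # temperature-adjusted biochemistry at current leaf temperature
    gamma <- arrhenius(params$gamma_star25, params$ha_gamma, tl)
    kc <- arrhenius(params$kc25, params$ha_kc, tl)
    ko <- arrhenius(params$ko25, params$ha_ko, tl)
    km <- kc * (1 + params$o2 / ko)
    vc <- peaked_arrhenius(params$vcmax25, tl, params$ha_v, params$hd, ds_v)
    jm <- peaked_arrhenius(params$jmax25, tl, params$ha_j, params$hd, ds_j)
    jr <- .j_rate(ppfd, jm, params$alpha, params$theta)
    rd <- r25_t * q10_t^((tl - 25) / 10)
    vpd_leaf <- pmax(esat_kpa(tl) - rh / 100 * esat_kpa(tair), 0)

    # stomatal optimum evaluated at the operating point ci_ratio * Ca, with
    # B the capacity of the active limitation (Vcmax or J/4) and E its
    # Michaelis metric, then hydraulically down-regulated
    ci_op <- params$ci_ratio * ca
    wc_op <- vc * (ci_op - gamma) / (ci_op + km)
    wj_op <- (jr / 4) * (ci_op - gamma) / (ci_op + 2 * gamma)
    rubisco <- wc_op <= wj_op
    bcap <- ifelse(rubisco, vc, jr / 4)
    emet <- ifelse(rubisco, km, 2 * gamma)
    gsm <- .gs_max_oriented(ci_op, ca, gamma, bcap, rd,
                            params$d_const, emet, params$f_const,
                            params$gs_cap)
    hyd <- hydraulic_gs(gsm, psi_soil, vpd_leaf, params, patm)
    gs <- hyd$gs

    # inner solution: ci making the diffusion constraint consistent with the
    # biochemical rate at this gs (unique root; supply decreasing in ci,
    # demand increasing)
    a_bio <- function(ci) {
      wc <- vc * (ci - gamma) / (ci + km)
      wj <- (jr / 4) * (ci - gamma) / (ci + 2 * gamma)
      pmin(wc, wj) - rd
    }
    a_diff <- function(ci) {
      if (uptake_convention == "physical") gs * (ca - ci)
      else gs * (ca - ci) + rd
    }
    lo <- rep(1e-3, n); hi <- 2 * ca
    for (k in seq_len(ctl$inner_iter)) {
      mid <- (lo + hi) / 2
      pos <- a_diff(mid) - a_bio(mid) > 0
      lo <- ifelse(pos, mid, lo)
      hi <- ifelse(pos, hi, mid)
    }
    ci <- (lo + hi) / 2
    wc <- vc * (ci - gamma) / (ci + km)
    wj <- (jr / 4) * (ci - gamma) / (ci + 2 * gamma)
    a_gross <- pmin(wc, wj)
    list(ci = ci, gs = gs, psi_leaf = hyd$psi_leaf, rd = rd,
         a_gross = a_gross, a_net = a_gross - rd, vpd_leaf = vpd_leaf,
         diff_resid = a_diff(ci) - a_bio(ci))
  }

  for (it in seq_len(ctl$outer_max)) {
    sol <- inner_solve(tl)
    eb <- leaf_energy_balance(tair, ppfd, rh, wind, sol$gs, params, patm)
    delta <- eb$t_leaf - tl
    tl <- tl + ctl$damping * delta
    iterations <- it
    if (max(abs(delta)) < ctl$tol_tl) { outer_converged <- TRUE; break }
  }
  # polish: settle leaf temperature on the energy-balance root at the
  # converged conductance (damped, since gs feeds back on t_leaf), then
  # recompute the gas-exchange state there
  for (pp in 1:8) {
    eb <- leaf_energy_balance(tair, ppfd, rh, wind, sol$gs, params, patm)
    tl <- tl + 0.7 * (eb$t_leaf - tl)
    sol <- inner_solve(tl)
    res <- .eb_residual(tl, tair, ppfd, rh, wind, sol$gs, params, patm)
    if (max(abs(res)) < 0.005) break
  }
  eb_res <- .eb_residual(tl, tair, ppfd, rh, wind, sol$gs, params, patm)

  gbw <- 1.4 * 0.147 * sqrt(wind / params$leaf_width)
  gsw <- 1.6 * sol$gs
  gtw <- ifelse(gsw > 0, 1 / (1 / gsw + 1 / gbw), 0)
  transp <- 1000 * gtw * sol$vpd_leaf / patm

  data.frame(
    timestamp = met$timestamp, t_leaf = tl, gs = sol$gs, ci = sol$ci,
    a_net = sol$a_net, a_gross = sol$a_gross, rd = sol$rd,
    transpiration = transp, psi_leaf = sol$psi_leaf,
    eb_residual = eb_res,
    converged = outer_converged & abs(eb_res) < 0.01,
    iterations = iterations
  )
}

#' Solve the coupled leaf state for a single met record
#'
#' Scalar convenience wrapper around [solve_leaf_states()].
#'
#' @inheritParams solve_leaf_states
#' @param met_record One-row met `data.frame` or a named list with `tair_C`,
#'   `rh_pct`, `ppfd_umol_m2_s`, and optionally `wind_m_s`, `co2_ppm`,
#'   `pressure_kPa`.
#' @return A one-element list of class `leaf_state` with the fields of the
#'   corresponding [solve_leaf_states()] row.
#' @export
solve_leaf_state <- function(met_record, params, psi_soil = 0,
                             acclimation = c("off", "on"), t_growth = NULL,
                             uptake_convention = c("physical", "printed"),
                             control = list()) {
  md <- as.data.frame(met_record)
  if (!"timestamp" %in% names(md)) md$timestamp <- as.POSIXct(0, tz = "UTC")
  out <- solve_leaf_states(md, params, psi_soil, acclimation, t_growth,
                           uptake_convention, control)
  structure(as.list(out[1, ]), class = "leaf_state")
}
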