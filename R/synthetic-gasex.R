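# Synthetic gas-exchange observations: per-campaign generating curves whose
# parameters are linear in the 2-week antecedent air temperature, plus
# Gaussian measurement noise. The generating truth is retained as an
# attribute so recovery tests can compare fitted against generating values.

#' Describe the generating truth for one species
#'
#' Each trait line is `c(intercept, slope)` on the 2-week antecedent mean air
#' temperature. Defaults come from [species_defaults()]; any line can be
#' overridden. The parabola width is derived per campaign from the A_opt and
#' T_80 lines (`b = 0.8 A_opt / T_80^2`) so that generating T_80 is exactly
#' linear in antecedent temperature.
#'
#' @param species_id Species label (defaults exist for the three focal
#'   species; other labels require explicit lines).
#' @param topt,aopt,t80,r25,q10 Optional `c(intercept, slope)` overrides.
#' @param obs_noise_sd_a,obs_noise_sd_r Gaussian observation noise sd for
#'   light / dark mode, umol m-2 s-1.
#' @return A `species_truth` list.
#' @export
species_truth <- function(species_id, topt = NULL, aopt = NULL, t80 = NULL,
                          r25 = NULL, q10 = NULL,
                          obs_noise_sd_a = NULL, obs_noise_sd_r = NULL) {
  base <- species_defaults()[[species_id]]
  pick <- function(x, d) if (!is.null(x)) x else d
  if (is.null(base) && (is.null(topt) || is.null(aopt) || is.null(t80) ||
                        is.null(r25) || is.null(q10)))
    .fail("no defaults for species '%s': supply all trait lines", species_id)
  tr <- structure(list(
    species_id = species_id,
    topt = pick(topt, base$topt), aopt = pick(aopt, base$aopt),
    t80 = pick(t80, base$t80), r25 = pick(r25, base$r25),
    q10 = pick(q10, base$q10),
    obs_noise_sd_a = pick(obs_noise_sd_a, base$obs_noise_sd_a %||% 0.2),
    obs_noise_sd_r = pick(obs_noise_sd_r, base$obs_noise_sd_r %||% 0.03)
  ), class = "species_truth")
  tr
}

#' Describe a measurement-campaign design
#'
#' @param n_campaigns Number of campaigns.
#' @param n_individuals Individuals measured per species and campaign.
#' @param n_timepoints_per_day Measurement time points per diurnal curve
#'   (5 or 6).
#' @param tair_range Range of measurement temperatures, `c(min, max)` deg C.
#' @param months Optional month indices to centre campaigns on; by default
#'   campaigns are spread evenly over the met series (after a 14-day spin-up).
#' @param track_ambient If `TRUE`, each campaign's measurement window keeps
#'   the width of `tair_range` but is recentred on that campaign's antecedent
#'   temperature, mirroring a cuvette set to track ambient air temperature;
#'   if `FALSE` (default) all campaigns sample within the fixed `tair_range`.
#' @return A `campaign_design` list.
#' @export
campaign_design <- function(n_campaigns = 6, n_individuals = 10,
                            n_timepoints_per_day = 6,
                            tair_range = c(12, 35), months = NULL,
                            track_ambient = FALSE) {
  if (!n_timepoints_per_day %in% c(5, 6))
    .fail("n_timepoints_per_day must be 5 or 6")
  if (tair_range[1] >= tair_range[2]) .fail("tair_range min must be < max")
  structure(list(
    n_campaigns = n_campaigns, n_individuals = n_individuals,
    n_timepoints_per_day = n_timepoints_per_day,
    tair_range = tair_range, months = months,
    track_ambient = isTRUE(track_ambient)
  ), class = "campaign_design")
}

# campaign dates: mid-month if months given, else evenly spread after spin-up
.campaign_dates <- function(design, met) {
  t0 <- met$timestamp[1]; t1 <- met$timestamp[nrow(met)]
  if (!is.null(design$months)) {
    yrs <- unique(as.integer(strftime(met$timestamp, "%Y", tz = "UTC")))
    cand <- as.POSIXct(outer(yrs, design$months,
                             function(y, m) sprintf("%04d-%02d-15", y, m)),
                       tz = "UTC")
    cand <- sort(cand[cand >= t0 + 14 * 86400 & cand <= t1])
    if (length(cand) < design$n_campaigns)
      .fail("met series holds only %d of %d requested campaign months",
            length(cand), design$n_campaigns)
    cand[seq_len(design$n_campaigns)]
  } else {
    if (as.numeric(t1) - as.numeric(t0) < 15 * 86400)
      .fail("met series shorter than the 14-day antecedent window")
    seq(t0 + 14 * 86400, t1, length.out = design$n_campaigns)
  }
}

#' Generating curve parameters per campaign
#'
#' Evaluates the species truth lines at the antecedent temperature of each
#' campaign date (noise-free).
#'
#' @param truth A [species_truth()].
#' @param design A [campaign_design()].
#' @param met Met driver covering 14 days before each campaign.
#' @return `data.frame` with one row per campaign: `campaign`, `date`,
#'   `t_antecedent`, `t_opt`, `a_opt`, `t80`, `b`, `r25`, `q10`.
#' @export
generating_parameters <- function(truth, design, met) {
  dates <- .campaign_dates(design, met)
  t_ant <- vapply(dates, function(d) antecedent_mean_tair(met, d), numeric(1))
  lin <- function(co) co[[1]] + co[[2]] * t_ant
  a_opt <- lin(truth$aopt)
  t80 <- lin(truth$t80)
  if (any(a_opt <= 0) || any(t80 <= 0))
    .fail("generating A_opt/T_80 non-positive over the antecedent range")
  data.frame(
    campaign = seq_along(dates), date = dates, t_antecedent = t_ant,
    t_opt = lin(truth$topt), a_opt = a_opt, t80 = t80,
    b = 0.8 * a_opt / t80^2,
    r25 = pmax(0.01, lin(truth$r25)),
    q10 = pmax(1.1, lin(truth$q10))
  )
}

#' Generate synthetic gas-exchange observations
#'
#' For each campaign, the generating curve parameters are the species truth
#' lines evaluated at the 2-week antecedent mean air temperature; observed
#' fluxes are the generating curve plus iid Gaussian noise. Light mode draws
#' parabolic assimilation points at saturating PPFD; dark mode draws
#' exponential respiration points at PPFD 0. Measurement temperatures are
#' sampled uniformly within `design$tair_range` per individual.
#'
#' @param truth A [species_truth()].
#' @param design A [campaign_design()].
#' @param met Met driver covering 14 days before each campaign.
#' @param mode `"light"` or `"dark"`.
#' @param seed Integer seed (per-individual sub-streams derive from it).
#' @param site Site label recorded in the table.
#' @return Observation `data.frame` in the gas-exchange dialect (`site`,
#'   `species`, `individual`, `campaign`, `timestamp`, `mode`, `tleaf_C`,
#'   `anet_umol_m2_s`, `ppfd`, `vpd_kPa`, `co2_ppm`, `t_antecedent`), with
#'   the generating truth attached as `attr(, "generating")`.
#' @export
generate_response_observations <- function(truth, design, met,
                                           mode = c("light", "dark"),
                                           seed = 1, site = "synthetic") {
  mode <- match.arg(mode)
  gen <- generating_parameters(truth, design, met)
  noise_sd <- if (mode == "light") truth$obs_noise_sd_a else truth$obs_noise_sd_r
  rows <- vector("list", nrow(gen) * design$n_individuals)
  k <- 0
  for (ci in seq_len(nrow(gen))) {
    g <- gen[ci, ]
    for (ind in seq_len(design$n_individuals)) {
      k <- k + 1
      sub <- seed_stream(seed, ci * 1000L + ind)
      rows[[k]] <- with_seed(sub, {
        # one temperature per stratum of the diurnal range, mirroring the
        # sunrise-to-afternoon measurement sequence; with track_ambient the
        # window follows the campaign's prevailing conditions (cuvette set
        # to ambient, extended to bracket the optimum), so light-mode
        # windows centre on the campaign optimum and dark-mode windows on
        # the antecedent temperature
        rng <- design$tair_range
        if (design$track_ambient) {
          centre <- if (mode == "light") g$t_opt else g$t_antecedent
          rng <- centre + rng - mean(rng)
        }
        brk <- seq(rng[1], rng[2],
                   length.out = design$n_timepoints_per_day + 1)
        tt <- stats::runif(design$n_timepoints_per_day,
                           brk[-length(brk)], brk[-1])
        mu <- if (mode == "light") g$a_opt - g$b * (tt - g$t_opt)^2
        else g$r25 * g$q10^((tt - 25) / 10)
        flux <- mu + if (noise_sd > 0)
          stats::rnorm(length(tt), 0, noise_sd) else 0
        data.frame(
          site = site, species = truth$species_id,
          individual = sprintf("ind%02d", ind), campaign = g$campaign,
          timestamp = g$date, mode = mode, tleaf_C = tt,
          anet_umol_m2_s = flux,
          ppfd = if (mode == "light") 1500 else 0,
          vpd_kPa = 1, co2_ppm = 400,
          t_antecedent = g$t_antecedent,
          stringsAsFactors = FALSE
        )
      })
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "generating") <- gen
  out
}

#' Generate synthetic diurnal net-assimilation observations
#'
#' Runs the coupled leaf model forward over a met series and adds Gaussian
#' observation noise, producing the calibration fixtures used by the DE-MC
#' calibrator.
#'
#' @param params A [species_params()] (the known truth).
#' @param met Met driver rows at which A_net is "measured".
#' @param noise_sd Gaussian observation noise sd, umol m-2 s-1.
#' @param seed Integer seed.
#' @param ... Passed to [solve_leaf_states()].
#' @return `data.frame` of the met rows plus `anet_obs` and `anet_true`;
#'   non-convergent steps propagate as an error.
#' @export
generate_diurnal_anet <- function(params, met, noise_sd = 0.5, seed = 1, ...) {
  states <- solve_leaf_states(met, params, ...)
  if (any(!states$converged))
    .fail("forward model failed to converge at %d of %d steps",
          sum(!states$converged), nrow(states))
  noise <- if (noise_sd > 0)
    with_seed(seed_stream(seed, 77L), stats::rnorm(nrow(met), 0, noise_sd))
  else 0
  out <- met
  out$anet_true <- states$a_net
  out$anet_obs <- states$a_net + noise
  out
}
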