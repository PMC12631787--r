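# Season integration of leaf states into carbon budgets, whole-plant
# scaling, and acclimated vs non-acclimated scenario runs.

.GC_PER_UMOL <- 12.011e-6 # gC per umol CO2

#' Integrate leaf states over a growing season
#'
#' Sums net assimilation, gross assimilation and respiration over the steps
#' inside `[flush_date, senescence_date]`, converting umol CO2 m-2 s-1 to
#' gC m-2 (molar mass 12.011). Steps outside the phenology window contribute
#' exactly zero; negative instantaneous A_net (night, heat) is retained, so
#' `c_leaf` is a true net budget and `c_leaf = a_gross_total - r_total`.
#'
#' @param states Per-step `data.frame` from [solve_leaf_states()] (needs
#'   `timestamp`, `a_net`, `a_gross`, `rd`).
#' @param step_seconds Step length, s (default inferred from timestamps).
#' @param flush_date,senescence_date Season bounds (default: full series).
#' @param scenario Label stored in the result.
#' @return A `carbon_budget` list: `c_leaf`, `a_gross_total`, `r_total`
#'   (gC m-2), `season_start`, `season_end`, `n_steps`, `scenario`,
#'   `pct_nonconverged`.
#' @export
integrate_season <- function(states, step_seconds = NULL,
                             flush_date = NULL, senescence_date = NULL,
                             scenario = "acclimated") {
  if (is.null(step_seconds)) {
    d <- diff(as.numeric(states$timestamp))
    if (length(d)) {
      step_seconds <- d[1]
      if (any(d != step_seconds))
        .fail("state series has a gap after %s",
              format(states$timestamp[which(d != step_seconds)[1]], tz = "UTC"))
    } else .fail("cannot infer step length from a single state")
  }
  sel <- rep(TRUE, nrow(states))
  if (!is.null(flush_date))
    sel <- sel & states$timestamp >= as.POSIXct(flush_date, tz = "UTC")
  if (!is.null(senescence_date))
    sel <- sel & states$timestamp <= as.POSIXct(senescence_date, tz = "UTC")
  s <- states[sel, , drop = FALSE]
  if (nrow(s) == 0) .fail("no steps inside [flush, senescence]")
  f <- step_seconds * .GC_PER_UMOL
  structure(list(
    c_leaf = sum(s$a_net) * f,
    a_gross_total = sum(s$a_gross) * f,
    r_total = sum(s$rd) * f,
    season_start = s$timestamp[1], season_end = s$timestamp[nrow(s)],
    n_steps = nrow(s), scenario = scenario,
    pct_nonconverged = if ("converged" %in% names(s))
      100 * mean(!s$converged) else 0
  ), class = "carbon_budget")
}

#' Whole-plant carbon uptake
#'
#' @param budget A [integrate_season()] result.
#' @param leaf_area_total Total plant leaf area, m2 (> 0).
#' @return C_tot in gC: `c_leaf * leaf_area_total`.
#' @export
total_uptake <- function(budget, leaf_area_total) {
  if (leaf_area_total <= 0) .fail("leaf_area_total must be > 0")
  budget$c_leaf * leaf_area_total
}

#' Differences in annual leaf-level uptake relative to a reference site
#'
#' For each site and scenario, computes `delta_c_leaf = c_leaf(site) -
#' c_leaf(reference, same scenario)`; reference rows are zero in their own
#' scenario.
#'
#' @param budgets `data.frame` with columns `site`, `scenario`,
#'   `c_leaf_gC_m2` (and optionally `species`, handled per species).
#' @param reference_site Reference site label; must be present in every
#'   scenario (and species).
#' @return The input with an added `delta_c_leaf_gC_m2` column.
#' @export
delta_vs_reference <- function(budgets, reference_site) {
  key_cols <- intersect(c("species", "scenario"), names(budgets))
  grp <- if (length(key_cols))
    interaction(budgets[key_cols], drop = TRUE) else factor(rep(1, nrow(budgets)))
  out <- lapply(split(budgets, grp), function(g) {
    ref <- g$c_leaf_gC_m2[g$site == reference_site]
    if (length(ref) != 1)
      .fail("reference site '%s' missing (or duplicated) in scenario '%s'",
            reference_site, paste(unique(g$scenario), collapse = ","))
    g$delta_c_leaf_gC_m2 <- g$c_leaf_gC_m2 - ref
    g
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# rolling 14-day antecedent mean of air temperature, one value per step
.antecedent_series <- function(met, window_days = 14) {
  step <- .met_step_seconds(met)
  k <- round(window_days * 86400 / step)
  x <- met$tair_C
  cs <- cumsum(x)
  n <- length(x)
  out <- numeric(n)
  idx <- seq_len(n)
  lo <- pmax(idx - k, 0)
  out <- (cs - c(0, cs)[lo + 1]) / (idx - lo)
  out
}

#' Run acclimated and non-acclimated carbon-budget scenarios
#'
#' For each site, generates (or takes) a met driver, computes the per-step
#' 2-week antecedent temperature, and runs the coupled leaf model twice per
#' species: once with acclimating physiology (entropy factors, R_25 and Q_10
#' follow the antecedent temperature) and once with all four frozen at the
#' reference-site configuration (the energy balance and stomata still respond
#' to weather). Both scenarios share identical drivers and phenology.
#'
#' @param sites Named list of [site_config()]s (default [site_defaults()]).
#' @param species Character vector of species labels (defaults to the three
#'   focal species).
#' @param reference_site Name of the reference site in `sites`.
#' @param start_date Season start (default the mid-October reporting window).
#' @param n_days Days to simulate (a 14-day spin-up is generated on top).
#' @param step_minutes Met step, minutes.
#' @param seed Integer seed for the met generator.
#' @param met_by_site Optional named list of pre-built met drivers (must
#'   include 14 days of spin-up before `start_date`).
#' @param phenology Named list per species of `c(flush_month, senescence_month)`
#'   used for deciduous species; evergreens integrate the full window.
#' @param params_by_species Optional named list of [species_params()].
#' @param max_nonconverged_pct A run with more non-converged steps than this
#'   fails loudly.
#' @return `data.frame` with one row per site x species x scenario:
#'   `site`, `species`, `scenario`, `c_leaf_gC_m2`, `a_gross_gC_m2`,
#'   `r_gC_m2`, `c_tot_gC`, `season_start`, `season_end`, `pct_nonconverged`.
#' @export
run_scenarios <- function(sites = site_defaults(),
                          species = names(species_defaults()),
                          reference_site = "sub_mediterranean",
                          start_date = "2022-10-15", n_days = 365,
                          step_minutes = 30, seed = 1,
                          met_by_site = NULL,
                          phenology = list(T.cordata = c(4, 10)),
                          params_by_species = NULL,
                          max_nonconverged_pct = 1) {
  if (!reference_site %in% names(sites))
    .fail("reference_site '%s' not in sites", reference_site)
  spin <- 14
  start_spin <- as.Date(start_date) - spin
  mets <- met_by_site %||% lapply(sites, function(s)
    generate_met_series(s, start_spin, n_days + spin, step_minutes, seed))
  season0 <- as.POSIXct(paste(as.Date(start_date), "00:00:00"), tz = "UTC")

  # frozen reference configuration: growing-season mean antecedent temperature
  ref_met <- mets[[reference_site]]
  ref_tg_series <- .antecedent_series(ref_met)
  in_season <- ref_met$timestamp >= season0
  tg_ref <- mean(ref_tg_series[in_season])

  sp_defaults <- species_defaults()
  rows <- list()
  for (site_name in names(sites)) {
    met <- mets[[site_name]]
    tg <- .antecedent_series(met)
    keep <- met$timestamp >= season0
    met_s <- met[keep, , drop = FALSE]
    tg_s <- tg[keep]
    for (sp in species) {
      p <- if (!is.null(params_by_species)) params_by_species[[sp]]
      else species_params(sp)
      deciduous <- isTRUE(sp_defaults[[sp]]$deciduous)
      bounds <- if (deciduous && !is.null(phenology[[sp]])) {
        yrs <- unique(as.integer(strftime(met_s$timestamp, "%Y", tz = "UTC")))
        mo <- as.integer(strftime(met_s$timestamp, "%m", tz = "UTC"))
        met_s$timestamp[mo >= phenology[[sp]][1] & mo <= phenology[[sp]][2]]
      } else met_s$timestamp
      if (length(bounds) == 0) .fail("empty phenology window for %s", sp)
      sel <- met_s$timestamp %in% bounds
      msel <- met_s[sel, , drop = FALSE]

      # acclimated: traits track local antecedent temperature
      acc <- solve_leaf_states(msel, p, acclimation = "on",
                               t_growth = tg_s[sel])
      # non-acclimated: Vcmax/Jmax temperature response, R25 and Q10 frozen
      # at the reference-site configuration
      p_ref <- p
      p_ref$r25 <- acclimated_r25(sp, tg_ref,
                                  coefficients = p$r25_acclim %||% c(p$r25, 0))
      p_ref$q10 <- acclimated_q10(sp, tg_ref,
                                  coefficients = p$q10_acclim %||% c(p$q10, 0))
      p_ref$t_growth_ref <- tg_ref
      non <- solve_leaf_states(msel, p_ref, acclimation = "off")

      for (sc in c("acclimated", "nonacclimated")) {
        st <- if (sc == "acclimated") acc else non
        bud <- integrate_season(st, step_seconds = step_minutes * 60,
                                scenario = sc)
        if (bud$pct_nonconverged > max_nonconverged_pct)
          .fail("%s/%s/%s: %.1f%% non-converged steps",
                site_name, sp, sc, bud$pct_nonconverged)
        rows[[length(rows) + 1]] <- data.frame(
          site = site_name, species = sp, scenario = sc,
          c_leaf_gC_m2 = bud$c_leaf, a_gross_gC_m2 = bud$a_gross_total,
          r_gC_m2 = bud$r_total,
          c_tot_gC = total_uptake(bud, p$leaf_area_total),
          season_start = bud$season_start, season_end = bud$season_end,
          pct_nonconverged = bud$pct_nonconverged,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
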