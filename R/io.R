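# CSV dialects, configuration, and the pipeline driver tying the stages
# together. All artifacts are plain text; CSV files carry a leading
# '# units:' comment so each artifact self-describes its units, and readers
# are header-keyed (column order does not matter).

.MET_COLS <- c("timestamp", "tair_C", "rh_pct", "ppfd_umol_m2_s",
               "wind_m_s", "co2_ppm", "pressure_kPa")
.MET_UNITS <- "ISO-8601 UTC, degC, percent, umol m-2 s-1, m s-1, ppm, kPa"
.GASEX_COLS <- c("site", "species", "individual", "campaign", "timestamp",
                 "mode", "tleaf_C", "anet_umol_m2_s", "ppfd", "vpd_kPa",
                 "co2_ppm")
.GASEX_UNITS <- "labels, ISO-8601 UTC, degC, umol m-2 s-1, umol m-2 s-1, kPa, ppm"

.read_csv_checked <- function(path, required, units_line) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing))
    .fail("%s: missing column(s) %s", path, paste(missing, collapse = ", "))
  d
}

.parse_timestamps <- function(x, path) {
  ts <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")) {
    todo <- is.na(ts)
    if (!any(todo)) break
    ts[todo] <- as.POSIXct(strptime(x[todo], fmt, tz = "UTC"), tz = "UTC")
  }
  bad <- which(is.na(ts))
  if (length(bad))
    .fail("%s: unparseable timestamp at data row %d ('%s')",
          path, bad[1], x[bad[1]])
  ts
}

#' Read / write meteorological driver CSV
#'
#' The met dialect has columns `timestamp` (ISO-8601, UTC), `tair_C`,
#' `rh_pct`, `ppfd_umol_m2_s`, `wind_m_s`, `co2_ppm`, `pressure_kPa`;
#' columns are header-keyed, a leading `# units:` comment is written and
#' skipped on read, and timestamps must be strictly increasing.
#'
#' @param path File path.
#' @return `read_met_csv`: the met `data.frame`.
#' @export
read_met_csv <- function(path) {
  d <- .read_csv_checked(path, .MET_COLS, .MET_UNITS)
  d$timestamp <- .parse_timestamps(d$timestamp, path)
  if (any(diff(as.numeric(d$timestamp)) <= 0))
    .fail("%s: timestamps not strictly increasing at data row %d", path,
          which(diff(as.numeric(d$timestamp)) <= 0)[1] + 1)
  d[.MET_COLS]
}

#' @rdname read_met_csv
#' @param met Met `data.frame` to write.
#' @return `write_met_csv`: the path, invisibly.
#' @export
write_met_csv <- function(met, path) {
  out <- met[.MET_COLS]
  out$timestamp <- strftime(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: %s", .MET_UNITS), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write gas-exchange observation CSV
#'
#' Dialect: `site`, `species`, `individual`, `campaign`, `timestamp`,
#' `mode` (`light`|`dark`), `tleaf_C`, `anet_umol_m2_s`, `ppfd`, `vpd_kPa`,
#' `co2_ppm` (plus any extra columns, which round-trip unchanged).
#' Dark-mode rows must carry `ppfd = 0`.
#'
#' @param path File path.
#' @return `read_gasex_csv`: the observation `data.frame`.
#' @export
read_gasex_csv <- function(path) {
  d <- .read_csv_checked(path, .GASEX_COLS, .GASEX_UNITS)
  d$timestamp <- .parse_timestamps(d$timestamp, path)
  bad <- which(d$mode == "dark" & d$ppfd > 0)
  if (length(bad))
    .fail("%s: dark-mode row %d has ppfd > 0", path, bad[1])
  d
}

#' @rdname read_gasex_csv
#' @param obs Observation `data.frame` to write.
#' @return `write_gasex_csv`: the path, invisibly.
#' @export
write_gasex_csv <- function(obs, path) {
  out <- obs
  out$timestamp <- strftime(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: %s", .GASEX_UNITS), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML (or JSON) configuration mirroring the [run_pipeline()] arguments.
#'
#' @param path Path to a YAML/JSON config file.
#' @return Named list of configuration values.
#' @export
read_pipeline_config <- function(path) {
  if (grepl("[.]json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

#' Run the full analysis pipeline
#'
#' Executes generate -> fit-curves -> regress -> (optional calibrate) ->
#' simulate -> budget on synthetic drivers, writing CSV/JSON artifacts when
#' `out_dir` is given. Reruns with the same configuration are byte-identical.
#'
#' @param config Named list (or path read by [read_pipeline_config()]) with
#'   elements `seed`, `sites` (named MAT values or site_configs),
#'   `reference_site`, `species`, `n_days`, `step_minutes`,
#'   `calibrate` (logical), `scenarios` (logical).
#' @param out_dir Optional output directory for artifacts.
#' @return List with `met` (per site), `observations`, `fits`,
#'   `acclimation_models`, `budgets` (when scenarios are on), and the
#'   `config` used (seed included).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- utils::modifyList(list(
    seed = 1, reference_site = "sub_mediterranean",
    species = names(species_defaults()),
    n_days = 120, step_minutes = 30, start_date = "2023-04-01",
    n_campaigns = 6, n_individuals = 4,
    calibrate = FALSE, scenarios = FALSE
  ), config)
  sites <- cfg$sites %||% site_defaults()
  sites <- Map(function(id, s) {
    if (inherits(s, "site_config")) s else site_config(id, as.numeric(s))
  }, names(sites), sites)

  mets <- lapply(sites, generate_met_series, start_date = cfg$start_date,
                 n_days = cfg$n_days, step_minutes = cfg$step_minutes,
                 seed = cfg$seed)

  design <- campaign_design(n_campaigns = cfg$n_campaigns,
                            n_individuals = cfg$n_individuals)
  obs <- list(); fits <- list()
  for (site in names(sites)) {
    for (sp in cfg$species) {
      truth <- species_truth(sp)
      for (mode in c("light", "dark")) {
        o <- generate_response_observations(
          truth, design, mets[[site]], mode = mode,
          seed = seed_stream(cfg$seed, match(site, names(sites)) * 100L +
                               match(sp, cfg$species) * 10L +
                               (mode == "dark")),
          site = site)
        obs[[length(obs) + 1]] <- o
      }
    }
  }
  obs <- do.call(rbind, obs)
  fits <- fit_curves(obs)

  models <- list()
  for (sp in unique(fits$species)) {
    f <- fits[fits$species == sp & fits$flags == "", ]
    for (trait in c("t_opt", "a_opt", "t80", "r25", "q10")) {
      ok <- is.finite(f[[trait]])
      if (sum(ok) >= 3)
        models[[length(models) + 1]] <-
          as.data.frame(unclass(regress_trait(f[[trait]][ok],
                                              f$t_antecedent[ok],
                                              trait, sp)))
    }
  }
  models <- do.call(rbind, models)

  budgets <- if (isTRUE(cfg$scenarios))
    run_scenarios(sites, cfg$species, cfg$reference_site,
                  start_date = cfg$start_date, n_days = cfg$n_days,
                  step_minutes = cfg$step_minutes, seed = cfg$seed)
  else NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (site in names(mets))
      write_met_csv(mets[[site]], file.path(out_dir, paste0("met_", site, ".csv")))
    write_gasex_csv(obs, file.path(out_dir, "observations.csv"))
    utils::write.csv(fits, file.path(out_dir, "fits.csv"), row.names = FALSE)
    utils::write.csv(models, file.path(out_dir, "acclimation_models.csv"),
                     row.names = FALSE)
    if (!is.null(budgets))
      utils::write.csv(budgets, file.path(out_dir, "budgets.csv"),
                       row.names = FALSE)
    stamp <- cfg
    stamp$sites <- lapply(sites, unclass)
    jsonlite::write_json(stamp[order(names(stamp))],
                         file.path(out_dir, "run_config.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(met = mets, observations = obs, fits = fits,
       acclimation_models = models, budgets = budgets, config = cfg)
}
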