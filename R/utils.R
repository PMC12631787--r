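# Shared physical helpers and small utilities.

#' Saturation vapour pressure (Tetens)
#'
#' @param t_c Temperature in degrees Celsius.
#' @return Saturation vapour pressure in kPa.
#' @export
esat_kpa <- function(t_c) {
  0.61078 * exp(17.27 * t_c / (t_c + 237.3))
}

#' Vapour pressure deficit of the air
#'
#' @param t_c Air temperature (degrees C).
#' @param rh_pct Relative humidity in percent, in (0, 100].
#' @return VPD in kPa.
#' @export
vpd_kpa <- function(t_c, rh_pct) {
  stopifnot(all(rh_pct > 0 & rh_pct <= 100))
  esat_kpa(t_c) * (1 - rh_pct / 100)
}

# Universal gas constant, J mol-1 K-1
.RGAS <- 8.314

.c_to_k <- function(t_c) t_c + 273.15

#' Arrhenius temperature scaling normalised to 25 degrees C
#'
#' Scales a rate known at 25 C to another temperature using the standard
#' (non-peaked) Arrhenius form.
#'
#' @param k25 Rate at 25 C.
#' @param ha_kj Activation energy, kJ mol-1.
#' @param t_c Target temperature, degrees C.
#' @return Scaled rate, same units as `k25`.
#' @export
arrhenius <- function(k25, ha_kj, t_c) {
  tk <- .c_to_k(t_c)
  k25 * exp(ha_kj * 1000 * (tk - 298.15) / (.RGAS * 298.15 * tk))
}

# Derive a reproducible sub-stream seed from a base seed and a stream index.
# Kept below 2^31 - 1 so set.seed() always accepts it.
seed_stream <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + as.double(stream) * 104729) %% 2147483647)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# consistent stop() with call. = FALSE
.fail <- function(...) stop(sprintf(...), call. = FALSE)
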