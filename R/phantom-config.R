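#' Phantom configuration
#'
#' Describes a synthetic recruitable-lung phantom: a population of threshold
#' lung units distributed over a CT voxel grid. Defaults are desk-scale
#' (roughly a 1/20-scale injured lung that fits the default 32x64x64 grid at
#' the standard voxel geometry of 0.35 mm^2 pixel area x 5 mm slice
#' thickness) so that a full phantom renders in well under a second.
#'
#' @param n_units number of lung units.
#' @param opening_mu,opening_sd mean and sd (cmH2O) of the Gaussian opening
#'   pressures; draws are clamped at 0.
#' @param closing_offset closing pressure deficit (cmH2O): each unit closes at
#'   `opening_pressure - closing_offset`, clamped at 0 (airway hysteresis).
#' @param weight_total total tissue mass (g) shared by the units.
#' @param specific_compliance ml gas per cmH2O per gram of open tissue.
#' @param resting_gas ml gas per gram retained by an open unit at zero
#'   distending pressure.
#' @param grid_shape integer vector (slices, rows, cols) of the CT grid.
#' @param pixel_area in-plane pixel area, mm^2.
#' @param slice_thickness slice thickness, mm.
#' @param hu_noise_sd additive Gaussian CT noise, HU.
#' @param aop_pressure airway opening pressure (cmH2O) to build into the
#'   low-flow inflation, or `NULL` for no airway closure.
#' @param seed integer seed controlling unit draws and CT noise.
#' @return an object of class `phantom_config` (a validated list).
#' @export
phantom_config <- function(n_units = 256L,
                           opening_mu = 8,
                           opening_sd = 6,
                           closing_offset = 4,
                           weight_total = 50,
                           specific_compliance = 0.06,
                           resting_gas = 0.8,
                           grid_shape = c(32L, 64L, 64L),
                           pixel_area = 0.35,
                           slice_thickness = 5,
                           hu_noise_sd = 30,
                           aop_pressure = NULL,
                           seed = 1L) {
  cfg <- list(
    n_units = as.integer(n_units), opening_mu = opening_mu,
    opening_sd = opening_sd, closing_offset = closing_offset,
    weight_total = weight_total, specific_compliance = specific_compliance,
    resting_gas = resting_gas, grid_shape = as.integer(grid_shape),
    pixel_area = pixel_area, slice_thickness = slice_thickness,
    hu_noise_sd = hu_noise_sd, aop_pressure = aop_pressure,
    seed = as.integer(seed)
  )
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
}

validate_phantom_config <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  if (!is.finite(cfg$n_units) || cfg$n_units <= 0L)
    stop("invalid phantom config: n_units must be a positive integer", call. = FALSE)
  if (!is.finite(cfg$weight_total) || cfg$weight_total <= 0)
    stop("invalid phantom config: weight_total must be positive", call. = FALSE)
  for (f in c("opening_sd", "closing_offset", "specific_compliance",
              "resting_gas", "pixel_area", "slice_thickness", "hu_noise_sd")) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0)
      stop("invalid phantom config: ", f, " must be non-negative", call. = FALSE)
  }
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape <= 0L))
    stop("invalid phantom config: grid_shape must be 3 positive integers", call. = FALSE)
  if (prod(cfg$grid_shape) < cfg$n_units)
    stop("invalid phantom config: grid voxel count must be >= n_units", call. = FALSE)
  if (!is.null(cfg$aop_pressure) &&
      (!is.finite(cfg$aop_pressure) || cfg$aop_pressure <= 0))
    stop("invalid phantom config: aop_pressure must be positive or NULL", call. = FALSE)
  cfg
}

#' Ventilation protocol
#'
#' Settings of the constant-flow volume-control protocol simulated for a
#' phantom: tidal breathing with end-inspiratory and end-expiratory
#' occlusions at the low and the high PEEP, a low-flow inflation for airway
#' opening pressure (AOP) detection at the low PEEP, and one one-breath
#' derecruitment maneuver from high to low PEEP. Defaults are desk-scale to
#' match [phantom_config()]: VT 16 ml against a ~50 g phantom gives the
#' tidal strain of a protectively ventilated injured lung.
#'
#' @param vt tidal volume, ml.
#' @param rr respiratory rate, breaths/min.
#' @param ie_ratio inspiratory:expiratory time ratio (ti/te).
#' @param peep_low,peep_high set PEEP at the two steps, cmH2O.
#' @param resistance airway resistance, cmH2O/(L/s).
#' @param sample_rate sampling rate of flow/pressure, Hz.
#' @param derecruit_rr respiratory rate (breaths/min) during the one-breath
#'   derecruitment maneuver; 6/min with i:e 1:2 gives the nominal 6.6 s
#'   prolonged expiration.
#' @param aop_flow inspiratory flow of the low-flow AOP breath, L/min. The
#'   bedside maneuver uses 5 L/min against a ~400 ml tidal volume; the
#'   desk-scale default keeps the same flow-to-volume proportion (and stays
#'   above the zero-flow threshold) for the default 16 ml phantom VT.
#' @param maneuvers character vector of maneuvers to simulate.
#' @return an object of class `vent_protocol`.
#' @export
vent_protocol <- function(vt = 16,
                          rr = 25,
                          ie_ratio = 0.5,
                          peep_low = 5,
                          peep_high = 15,
                          resistance = 10,
                          sample_rate = 200,
                          derecruit_rr = 6,
                          aop_flow = 0.5,
                          maneuvers = c("occlusions", "derecruitment", "aop_breath")) {
  p <- list(vt = vt, rr = rr, ie_ratio = ie_ratio, peep_low = peep_low,
            peep_high = peep_high, resistance = resistance,
            sample_rate = sample_rate, derecruit_rr = derecruit_rr,
            aop_flow = aop_flow, maneuvers = maneuvers)
  class(p) <- "vent_protocol"
  validate_vent_protocol(p)
}

validate_vent_protocol <- function(p) {
  stopifnot(inherits(p, "vent_protocol"))
  if (!is.finite(p$vt) || p$vt <= 0)
    stop("invalid protocol: vt must be positive", call. = FALSE)
  if (!is.finite(p$sample_rate) || p$sample_rate <= 0)
    stop("invalid protocol: sample_rate must be positive", call. = FALSE)
  if (!is.finite(p$peep_low) || p$peep_low < 0 || p$peep_high < p$peep_low)
    stop("invalid protocol: need peep_high >= peep_low >= 0", call. = FALSE)
  if (p$rr <= 0 || p$ie_ratio <= 0 || p$resistance < 0 || p$derecruit_rr <= 0)
    stop("invalid protocol: rr, ie_ratio, derecruit_rr must be positive", call. = FALSE)
  if (length(p$maneuvers) == 0L)
    stop("invalid protocol: maneuver list is empty", call. = FALSE)
  p
}

# Evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
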