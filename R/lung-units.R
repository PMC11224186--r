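#' Generate threshold lung units
#'
#' Draws the unit population of a recruitable-lung phantom. Each unit is a
#' parcel of tissue with a threshold opening pressure (Gaussian across units,
#' clamped at 0), a closing pressure offset below it (hysteresis), a specific
#' compliance and a resting gas content. A unit is aerated at end-inspiration
#' when the plateau pressure has reached its opening pressure, and stays
#' aerated at end-expiration when PEEP is at or above its closing pressure;
#' an aerated unit at pressure P holds
#' `weight * (resting_gas + specific_compliance * P)` ml of gas.
#'
#' @param config a [phantom_config()].
#' @return a `data.frame` of class `lung_units` with columns `weight` (g),
#'   `opening_pressure`, `closing_pressure` (cmH2O), `specific_compliance`
#'   (ml/(cmH2O*g)) and `resting_gas` (ml/g). Weights sum to
#'   `config$weight_total`.
#' @export
generate_units <- function(config) {
  config <- validate_phantom_config(config)
  with_seed(config$seed, {
    opening <- pmax(stats::rnorm(config$n_units, config$opening_mu,
                                 config$opening_sd), 0)
    closing <- pmax(opening - config$closing_offset, 0)
    # mild lognormal size heterogeneity, renormalised to the total mass
    w <- stats::rlnorm(config$n_units, meanlog = 0, sdlog = 0.3)
    w <- w * (config$weight_total / sum(w))
    units <- data.frame(
      weight = w,
      opening_pressure = opening,
      closing_pressure = closing,
      specific_compliance = config$specific_compliance,
      resting_gas = config$resting_gas
    )
    class(units) <- c("lung_units", "data.frame")
    units
  })
}

# Aggregate compliance (ml/cmH2O) of units aerated at end-inspiration for a
# given plateau pressure.
units_compliance <- function(units, plateau) {
  open <- units$opening_pressure <= plateau
  sum(units$weight[open] * units$specific_compliance[open])
}

# Self-consistent plateau pressure: P = peep + vt / C(P), where C(P) counts
# units whose opening pressure has been reached. C(P) is a non-decreasing
# step function, so peep + vt/C(P) - P is decreasing across each step and the
# crossing is found by bisection.
solve_plateau <- function(units, peep, vt, p_max = 200) {
  f <- function(p) {
    C <- units_compliance(units, p)
    if (C <= 0) return(Inf)
    peep + vt / C - p
  }
  lo <- peep
  hi <- p_max
  if (f(hi) > 0) stop("phantom cannot accept the tidal volume: no plateau below ",
                      p_max, " cmH2O", call. = FALSE)
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  hi
}

# Open/closed state and per-unit gas volume (ml) at one phase of one PEEP
# step. phase: "exp" (pressure = peep, unit must also have stayed open, i.e.
# closing <= peep) or "insp" (pressure = plateau).
unit_state <- function(units, peep, plateau, phase = c("exp", "insp")) {
  phase <- match.arg(phase)
  open_insp <- units$opening_pressure <= plateau
  if (phase == "insp") {
    open <- open_insp
    pressure <- plateau
  } else {
    open <- open_insp & (units$closing_pressure <= peep)
    pressure <- peep
  }
  gas <- ifelse(open,
                units$weight * (units$resting_gas +
                                  units$specific_compliance * pressure),
                0)
  list(open = open, gas = gas, pressure = pressure)
}
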