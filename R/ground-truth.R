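#' Analytic ground truth of a phantom
#'
#' Computes, from the unit model alone, every quantity the measurement chain
#' later estimates from CT volumes and ventilator traces: tissue recruitment
#' (mass of units aerated at end-expiration at PEEP_HIGH but not at
#' PEEP_LOW), gas recruitment (gas held by those units at PEEP_HIGH), the
#' end-expiratory lung volumes and their difference, the low-PEEP
#' respiratory-system compliance (aggregate compliance of units reached by
#' the low-PEEP plateau), the recruited-compliance chain and R/I, and the
#' dynamic/static lung strains.
#'
#' @param units a `lung_units` data frame.
#' @param protocol a [vent_protocol()].
#' @param config the [phantom_config()] that produced `units`.
#' @return object of class `ground_truth`: a list of named scalars plus
#'   `flags` (character vector; `"ri_undefined"` when the PEEP step is
#'   degenerate, `"fully_open"` when nothing is recruitable).
#' @export
export_ground_truth <- function(units, protocol, config) {
  protocol <- validate_vent_protocol(protocol)
  pl <- protocol$peep_low
  ph <- protocol$peep_high
  vt <- protocol$vt
  plateau_low <- solve_plateau(units, pl, vt)
  plateau_high <- solve_plateau(units, ph, vt)

  exp_low <- unit_state(units, pl, plateau_low, "exp")
  exp_high <- unit_state(units, ph, plateau_high, "exp")

  recruited <- exp_high$open & !exp_low$open
  true_t_rec <- sum(units$weight[recruited])
  true_gas_rec <- sum(exp_high$gas[recruited])
  eelv_low <- sum(exp_low$gas)
  eelv_high <- sum(exp_high$gas)
  delta_eelv <- eelv_high - eelv_low
  c_rs_low <- units_compliance(units, plateau_low)

  flags <- character(0)
  if (ph <= pl) {
    flags <- c(flags, "ri_undefined")
    inflation <- v_rec <- c_rec <- ri <- NA_real_
  } else {
    inflation <- c_rs_low * (ph - pl)
    v_rec <- delta_eelv - inflation
    c_rec <- v_rec / (ph - pl)
    ri <- c_rec / c_rs_low
  }
  if (true_t_rec == 0) flags <- c(flags, "fully_open")

  dyn_low <- vt / eelv_low
  dyn_high <- vt / (eelv_low + true_gas_rec)
  static_high <- (delta_eelv - true_gas_rec) / (eelv_low + true_gas_rec)

  structure(list(
    true_t_rec = true_t_rec,
    true_gas_rec = true_gas_rec,
    true_delta_eelv = delta_eelv,
    true_eelv_low = eelv_low,
    true_eelv_high = eelv_high,
    true_c_rs_low = c_rs_low,
    true_c_rec = c_rec,
    true_v_rec = v_rec,
    true_inflation_volume = inflation,
    true_ri = ri,
    true_dynamic_low = dyn_low,
    true_dynamic_high = dyn_high,
    true_static_high = static_high,
    true_global_low = dyn_low,
    true_global_high = dyn_high + static_high,
    plateau_low = plateau_low,
    plateau_high = plateau_high,
    flags = flags
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  cat(sprintf("  T_REC %.2f g   GAS_REC %.1f ml   dEELV %.1f ml\n",
              x$true_t_rec, x$true_gas_rec, x$true_delta_eelv))
  cat(sprintf("  EELV_low %.1f ml   C_RS,low %.2f ml/cmH2O   R/I %s\n",
              x$true_eelv_low, x$true_c_rs_low,
              ifelse(is.na(x$true_ri), "NA", sprintf("%.3f", x$true_ri))))
  cat(sprintf("  strain dyn %.3f -> %.3f, static_high %.3f\n",
              x$true_dynamic_low, x$true_dynamic_high, x$true_static_high))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Configurations for a synthetic cohort
#'
#' Builds `n` phantom configurations spanning a range of recruitability by
#' varying the mean opening pressure (low mean: lung mostly open at low PEEP,
#' little to recruit; high mean: widespread collapse reversible by the PEEP
#' step) and jittering the total mass, mirroring the between-animal spread of
#' a lavage/endotoxin injury cohort.
#'
#' @param n cohort size.
#' @param seed integer seed; subject seeds are derived from it.
#' @param opening_mu_range range of mean opening pressures across subjects.
#' @param weight_mean,weight_sd total-mass distribution across subjects (g).
#' @param ... further arguments passed to every [phantom_config()].
#' @return list of `n` `phantom_config` objects.
#' @export
cohort_configs <- function(n = 14, seed = 1L, opening_mu_range = c(2, 11),
                           weight_mean = 50, weight_sd = 4, ...) {
  stopifnot(n >= 1)
  mus <- seq(opening_mu_range[1], opening_mu_range[2], length.out = n)
  with_seed(seed, {
    mus <- sample(mus)  # decouple subject index from recruitability
    ws <- pmax(stats::rnorm(n, weight_mean, weight_sd), weight_mean / 2)
    lapply(seq_len(n), function(i) {
      phantom_config(opening_mu = mus[i], weight_total = ws[i],
                     seed = seed + i, ...)
    })
  })
}
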