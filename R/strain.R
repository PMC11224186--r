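# CT-based lung strain. The low PEEP is the baseline condition: its
# end-expiratory gas volume is the functional residual capacity surrogate
# and static strain there is 0 by definition.

#' Dynamic, static and global lung strain at both PEEPs
#'
#' With `EELV_LOW` the total end-expiratory gas volume at the low PEEP (the
#' FRC surrogate) and `GAS_REC` the gas recruitment:
#' dynamic strain = `VT / EELV_LOW` at the low PEEP and
#' `VT / (EELV_LOW + GAS_REC)` at the high PEEP; static strain is 0 at the
#' low PEEP and `(dEELV - GAS_REC) / (EELV_LOW + GAS_REC)` at the high PEEP,
#' where `dEELV - GAS_REC` is the PEEP volume (inflation of already aerated
#' regions); global strain = static + dynamic at each PEEP. `dEELV` is by
#' default the CT gas-volume difference between the two end-expiratory
#' scans; set `delta_eelv_source = "maneuver"` (and supply
#' `delta_eelv_maneuver`) to use the derecruitment-maneuver value instead
#' for sensitivity analysis.
#'
#' @param vt tidal volume, ml.
#' @param summary_low_exp,summary_high_exp end-expiratory
#'   [summarize_compartments()] results at the two PEEPs.
#' @param recruitment a [compute_recruitment()] result (its `gas_rec` is
#'   propagated, not recomputed).
#' @param delta_eelv_source `"ct"` (default) or `"maneuver"`.
#' @param delta_eelv_maneuver maneuver-derived dEELV, ml (required when
#'   `delta_eelv_source = "maneuver"`).
#' @return object of class `strain_result` with fields `eelv_low`,
#'   `delta_eelv_ct`, `peep_volume` (ml), `dynamic_low`, `dynamic_high`,
#'   `static_low`, `static_high`, `global_low`, `global_high`,
#'   `delta_dynamic`, `delta_static`, `delta_global`, `flags`.
#' @export
compute_strains <- function(vt, summary_low_exp, summary_high_exp,
                            recruitment,
                            delta_eelv_source = c("ct", "maneuver"),
                            delta_eelv_maneuver = NULL) {
  delta_eelv_source <- match.arg(delta_eelv_source)
  if (vt <= 0) stop("vt must be positive", call. = FALSE)
  for (s in list(summary_low_exp, summary_high_exp))
    if (s$phase != "end_expiration")
      stop("strain uses end-expiratory summaries", call. = FALSE)
  eelv_low <- summary_low_exp$total_gas_ml
  if (eelv_low <= 0) stop("EELV at PEEP_LOW must be positive", call. = FALSE)
  delta_eelv <- if (delta_eelv_source == "ct") {
    summary_high_exp$total_gas_ml - eelv_low
  } else {
    if (is.null(delta_eelv_maneuver))
      stop("delta_eelv_maneuver required for the maneuver source", call. = FALSE)
    delta_eelv_maneuver
  }
  gas_rec <- recruitment$gas_rec
  denom <- eelv_low + gas_rec
  if (denom <= 0) stop("EELV_LOW + GAS_REC must be positive", call. = FALSE)
  dynamic_low <- vt / eelv_low
  dynamic_high <- vt / denom
  static_low <- 0
  static_high <- (delta_eelv - gas_rec) / denom
  flags <- character(0)
  if (static_high < 0) flags <- c(flags, "negative_static_high")
  structure(list(
    eelv_low = eelv_low,
    delta_eelv_ct = delta_eelv,
    delta_eelv_source = delta_eelv_source,
    peep_volume = delta_eelv - gas_rec,
    gas_rec = gas_rec,
    dynamic_low = dynamic_low, dynamic_high = dynamic_high,
    static_low = static_low, static_high = static_high,
    global_low = dynamic_low + static_low,
    global_high = dynamic_high + static_high,
    delta_dynamic = dynamic_high - dynamic_low,
    delta_static = static_high - static_low,
    delta_global = (dynamic_high + static_high) - (dynamic_low + static_low),
    flags = flags
  ), class = "strain_result")
}

#' @export
print.strain_result <- function(x, ...) {
  cat("<strain_result>\n")
  cat(sprintf("  EELV_LOW %.1f ml, dEELV(%s) %.1f ml, PEEP volume %.1f ml\n",
              x$eelv_low, x$delta_eelv_source, x$delta_eelv_ct, x$peep_volume))
  cat(sprintf("  dynamic %.3f -> %.3f (d %.3f)\n",
              x$dynamic_low, x$dynamic_high, x$delta_dynamic))
  cat(sprintf("  static  %.3f -> %.3f;  global %.3f -> %.3f\n",
              x$static_low, x$static_high, x$global_low, x$global_high))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Per-subject table for the cohort statistics
#'
#' Assembles the paired per-subject rows feeding the correlation analysis:
#' R/I against the PEEP-induced strain changes and normalised recruitment.
#' Subject identity is checked: the strain results, recruitment results and
#' R/I values must carry the same ids in the same order.
#'
#' @param strains named list of [compute_strains()] results.
#' @param ri named numeric vector of R/I values (same names, same order).
#' @param recruitment named list of [compute_recruitment()] results (same
#'   names, same order).
#' @return data frame with one row per subject: `id`, `ri`, `delta_dynamic`,
#'   `delta_static`, `delta_global`, `t_rec`, `gas_rec`,
#'   `normalized_t_rec`, `normalized_gas_rec`, `dynamic_low`,
#'   `dynamic_high`, `static_high`, `global_low`, `global_high`.
#' @export
strain_ratio_table <- function(strains, ri, recruitment) {
  if (length(strains) != length(ri) || length(strains) != length(recruitment))
    stop("strains, ri and recruitment must have equal length", call. = FALSE)
  ids <- names(strains)
  if (is.null(ids) || is.null(names(ri)) || is.null(names(recruitment)))
    stop("strains, ri and recruitment must be named by subject", call. = FALSE)
  if (!identical(ids, names(ri)) || !identical(ids, names(recruitment)))
    stop("subject ids do not match across inputs", call. = FALSE)
  rows <- lapply(seq_along(ids), function(i) {
    s <- strains[[i]]
    r <- recruitment[[i]]
    data.frame(id = ids[i], ri = unname(ri[i]),
               delta_dynamic = s$delta_dynamic,
               delta_static = s$delta_static,
               delta_global = s$delta_global,
               t_rec = r$t_rec, gas_rec = r$gas_rec,
               normalized_t_rec = r$normalized_t_rec,
               normalized_gas_rec = r$normalized_gas_rec,
               dynamic_low = s$dynamic_low, dynamic_high = s$dynamic_high,
               static_high = s$static_high,
               global_low = s$global_low, global_high = s$global_high)
  })
  do.call(rbind, rows)
}
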