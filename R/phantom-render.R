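#' Construct a CT volume object
#'
#' Container for one reconstructed CT volume: an integer-HU 3D array in
#' (slice, row, col) order plus voxel geometry and acquisition labels.
#'
#' @param hu integer 3D array of Hounsfield units.
#' @param pixel_area pixel area, mm^2.
#' @param slice_thickness slice thickness, mm.
#' @param phase `"end_expiration"` or `"end_inspiration"`.
#' @param peep_label `"low"` or `"high"`.
#' @return object of class `ct_volume`.
#' @export
ct_volume <- function(hu, pixel_area = 0.35, slice_thickness = 5,
                      phase = c("end_expiration", "end_inspiration"),
                      peep_label = c("low", "high")) {
  phase <- match.arg(phase)
  peep_label <- match.arg(peep_label)
  if (length(dim(hu)) != 3L) stop("hu must be a 3D array", call. = FALSE)
  if (pixel_area <= 0 || slice_thickness <= 0)
    stop("voxel geometry must be positive", call. = FALSE)
  structure(list(hu = hu, pixel_area = pixel_area,
                 slice_thickness = slice_thickness,
                 phase = phase, peep_label = peep_label),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$hu), collapse = "x"),
      " voxels, ", x$phase, " @ PEEP_", toupper(x$peep_label),
      ", voxel ", x$pixel_area, " mm^2 x ", x$slice_thickness, " mm\n",
      sep = "")
  invisible(x)
}

# HU of the unmasked (extra-pulmonary) background: soft tissue.
.BACKGROUND_HU <- 60L

#' Render the end-expiratory / end-inspiratory CT pair at one PEEP
#'
#' Rasterises the unit population onto the phantom's voxel grid at
#' end-expiration and end-inspiration of one PEEP step. Each unit occupies a
#' run of `round(total volume / voxel volume)` consecutive voxels; within a
#' unit every voxel carries the unit's gas fraction, so voxel
#' HU = round(-1000 * gasfraction) + N(0, hu_noise_sd), clipped to
#' [-1000, +100]. Tissue density is 1 g/ml, so a closed unit renders at
#' ~0 HU. Voxels outside all units are extra-pulmonary background (+60 HU)
#' and excluded from the returned mask.
#'
#' @param units a `lung_units` data frame from [generate_units()].
#' @param config the [phantom_config()] (grid and noise).
#' @param peep end-expiratory pressure of this step, cmH2O.
#' @param plateau end-inspiratory plateau pressure, cmH2O; if `NULL` it is
#'   solved self-consistently for tidal volume `vt`.
#' @param vt tidal volume (ml) used only when `plateau` is `NULL`.
#' @param peep_label `"low"` or `"high"` acquisition label.
#' @return a list with elements `exp` and `insp` (each a list of `volume`,
#'   a [ct_volume()], and `mask`, a logical array), plus `plateau`.
#' @export
render_ct_pair <- function(units, config, peep, plateau = NULL, vt = NULL,
                           peep_label = "low") {
  config <- validate_phantom_config(config)
  if (is.null(plateau)) {
    if (is.null(vt)) stop("provide either plateau or vt", call. = FALSE)
    plateau <- solve_plateau(units, peep, vt)
  }
  if (plateau < peep) stop("plateau must be >= peep", call. = FALSE)
  out <- list(
    exp = render_phase(units, config, peep, plateau, "exp", peep_label),
    insp = render_phase(units, config, peep, plateau, "insp", peep_label),
    plateau = plateau
  )
  out
}

render_phase <- function(units, config, peep, plateau, phase, peep_label) {
  st <- unit_state(units, peep, plateau, phase)
  voxvol_ml <- config$pixel_area * config$slice_thickness / 1000  # mm^3 -> ml
  vol_ml <- units$weight + st$gas                  # tissue density 1 g/ml
  n_vox <- pmax(1L, as.integer(round(vol_ml / voxvol_ml)))
  n_total <- prod(config$grid_shape)
  if (sum(n_vox) > n_total)
    stop("phantom geometry error: units need ", sum(n_vox),
         " voxels but the grid holds ", n_total, call. = FALSE)
  gasfrac <- st$gas / vol_ml
  hu_clean <- -1000 * rep(gasfrac, times = n_vox)
  hu <- rep(.BACKGROUND_HU, n_total)
  hu[seq_along(hu_clean)] <- hu_clean
  if (config$hu_noise_sd > 0)
    hu[seq_along(hu_clean)] <- hu[seq_along(hu_clean)] +
      stats::rnorm(length(hu_clean), 0, config$hu_noise_sd)
  hu <- pmin(pmax(round(hu), -1000), 100)
  mask <- rep(FALSE, n_total)
  mask[seq_along(hu_clean)] <- TRUE
  dim(hu) <- config$grid_shape
  dim(mask) <- config$grid_shape
  ph <- if (phase == "exp") "end_expiration" else "end_inspiration"
  list(volume = ct_volume(storage_int(hu), config$pixel_area,
                          config$slice_thickness, ph, peep_label),
       mask = mask,
       unit_voxels = n_vox)
}

storage_int <- function(x) {
  storage.mode(x) <- "integer"
  x
}

#' Simulate the full phantom acquisition at both PEEP steps
#'
#' Convenience wrapper running the whole synthetic acquisition for one
#' subject: unit generation, the four CT volumes (end-expiration and
#' end-inspiration at PEEP_LOW and PEEP_HIGH), the ventilator trace and the
#' analytic ground truth, all from one seed.
#'
#' @param config a [phantom_config()].
#' @param protocol a [vent_protocol()].
#' @return list with `units`, `ct` (list `low`, `high` of render pairs),
#'   `trace` (a `vent_trace`), `truth` (a `ground_truth`), `config`,
#'   `protocol`.
#' @export
simulate_phantom <- function(config, protocol) {
  config <- validate_phantom_config(config)
  protocol <- validate_vent_protocol(protocol)
  units <- generate_units(config)
  truth <- export_ground_truth(units, protocol, config)
  ct <- with_seed(config$seed + 1L, list(
    low = render_ct_pair(units, config, protocol$peep_low,
                         plateau = truth$plateau_low, peep_label = "low"),
    high = render_ct_pair(units, config, protocol$peep_high,
                          plateau = truth$plateau_high, peep_label = "high")
  ))
  trace <- simulate_traces(units, protocol, aop_pressure = config$aop_pressure)
  list(units = units, ct = ct, trace = trace, truth = truth,
       config = config, protocol = protocol)
}
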