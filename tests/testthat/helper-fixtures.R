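# Shared fixtures: small phantoms for speed, hand-built traces and
# compartment summaries with known values.

# Desk-scale-squared: a 16x32x32 grid holds ~28.7 ml, so the small phantom
# is ~6 g with a 2 ml tidal volume (same dimensionless strains).
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_units = 64L, grid_shape = c(16L, 32L, 32L), hu_noise_sd = 0,
         weight_total = 6),
    list(...))
  do.call(phantom_config, args)
}

# VT 6 ml keeps the inspiratory flow above the zero-flow threshold
small_protocol <- function(...) {
  args <- utils::modifyList(list(vt = 6), list(...))
  do.call(vent_protocol, args)
}

# A ct_volume directly from an HU vector (1 x 1 x n), voxel 1.75 mm^3.
hu_volume <- function(hu, phase = "end_expiration", peep_label = "low") {
  arr <- array(as.integer(hu), dim = c(1L, 1L, length(hu)))
  ct_volume(arr, pixel_area = 0.35, slice_thickness = 5,
            phase = phase, peep_label = peep_label)
}

full_mask <- function(volume) array(TRUE, dim = dim(volume$hu))

comp_weight <- function(s, comp) s$table$weight_g[s$table$compartment == comp]

# Fabricated compartment summary with prescribed per-compartment weights and
# gas volumes (vectors in the order hyperinflated, normally, poorly,
# nonaerated).
fake_summary <- function(weights, gas, phase = "end_expiration",
                         peep_label = "low") {
  comps <- c("hyperinflated", "normally", "poorly", "nonaerated")
  structure(list(
    table = data.frame(compartment = c(comps, "total"),
                       weight_g = c(weights, sum(weights)),
                       gas_ml = c(gas, sum(gas))),
    total_weight_g = sum(weights),
    total_gas_ml = sum(gas),
    total_volume_ml = sum(weights) + sum(gas),
    n_voxels = NA_integer_,
    phase = phase, peep_label = peep_label
  ), class = "compartment_summary")
}

fake_recruitment <- function(gas_rec, t_rec = NA_real_) {
  structure(list(t_rec = t_rec, gas_rec = gas_rec,
                 gt_median_high = NA_real_, flags = character(0)),
            class = "recruitment_result")
}

# Hand-built single-breath trace: constant-flow inspiration then quiescence,
# with optional occlusion events and power-law pressure rise.
flat_trace <- function(flow_plateau = 0.3, ti = 1.0, peep = 5, dp = 9,
                       b = 1, fs = 200, noise_sd = 0, n_breaths = 1,
                       occlusions = FALSE, p_plat = peep + dp,
                       peep_tot = peep) {
  n_i <- round(ti * fs)
  one <- function() {
    t <- (0:n_i) / fs
    flow <- c(rep(0, fs), rep(flow_plateau, n_i + 1L), rep(0, fs))
    paw <- c(rep(peep, fs),
             peep + 1 + dp * (t / ti)^b + stats::rnorm(n_i + 1L, 0, noise_sd),
             rep(peep, fs))
    ev <- rep("none", length(flow))
    if (occlusions) {
      # 0.6 s end-inspiratory occlusion at p_plat, terminal hold as
      # end-expiratory occlusion at peep_tot
      occ_i <- fs + n_i + 1L + seq_len(round(0.6 * fs))
      paw[occ_i] <- p_plat
      flow[occ_i] <- 0
      ev[occ_i] <- "insp_occlusion"
      occ_e <- (length(flow) - round(0.6 * fs) + 1L):length(flow)
      paw[occ_e] <- peep_tot
      ev[occ_e] <- "exp_occlusion"
    }
    list(flow = flow, paw = paw, ev = ev)
  }
  parts <- replicate(n_breaths, one(), simplify = FALSE)
  flow <- unlist(lapply(parts, `[[`, "flow"))
  paw <- unlist(lapply(parts, `[[`, "paw"))
  ev <- unlist(lapply(parts, `[[`, "ev"))
  tr <- data.frame(time_s = (seq_along(flow) - 1L) / fs, flow_lps = flow,
                   paw_cmh2o = paw, event = ev, phase = NA_character_)
  attr(tr, "sample_rate") <- fs
  class(tr) <- c("vent_trace", "data.frame")
  tr
}

# Independent per-voxel reference implementation of the compartment summary:
# an explicit loop with if/else per voxel, no vectorisation shared with the
# package code.
loop_compartments <- function(volume, mask) {
  voxvol <- volume$pixel_area * volume$slice_thickness / 1000
  comps <- c("hyperinflated", "normally", "poorly", "nonaerated")
  w <- stats::setNames(numeric(4), comps)
  g <- stats::setNames(numeric(4), comps)
  hu_all <- as.vector(volume$hu)
  m_all <- as.vector(mask)
  for (i in seq_along(hu_all)) {
    if (!m_all[i]) next
    hu <- round(hu_all[i])
    if (hu > 100) hu <- 100
    if (hu < -1000) hu <- -1000
    if (hu >= -1000 && hu <= -901) comp <- "hyperinflated"
    else if (hu <= -501) comp <- "normally"
    else if (hu <= -101) comp <- "poorly"
    else comp <- "nonaerated"
    if (hu <= 0) {
      g[comp] <- g[comp] + voxvol * (-hu / 1000)
      w[comp] <- w[comp] + voxvol * (1 + hu / 1000)
    } else {
      w[comp] <- w[comp] + voxvol * (1 + hu / 1000)
    }
  }
  list(weight = w, gas = g)
}
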