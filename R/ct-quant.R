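# Quantitative CT densitometry: Hounsfield-unit gas/tissue decomposition,
# aeration compartments, tissue and gas recruitment.

check_mask <- function(volume, mask) {
  if (!inherits(volume, "ct_volume")) stop("volume must be a ct_volume", call. = FALSE)
  if (is.null(dim(mask)) || !identical(dim(mask), dim(volume$hu)))
    stop("mask shape must match the CT volume", call. = FALSE)
  storage.mode(mask) <- "logical"
  if (!any(mask)) stop("lung mask is empty", call. = FALSE)
  mask
}

#' Voxel gas/tissue decomposition
#'
#' Decomposes every masked voxel into its gas volume and tissue weight from
#' its Hounsfield number, under the linear gas/tissue mixture model
#' (-1000 HU = pure gas, 0 HU = pure tissue at density 1 g/ml). For HU in
#' \[-1000, 0\]: gas = voxel_volume * (-HU/1000) and
#' tissue = voxel_volume * (1 + HU/1000) grams, so gas and tissue volume sum
#' to the voxel volume exactly. For HU in (0, +100\] the voxel holds no gas
#' and its density extrapolates to 1 + HU/1000 g/ml. Masked voxels above
#' +100 HU are counted as nonaerated at the +100 density with a warning
#' (they are not dropped, so mask totals are conserved); values below
#' -1000 are clamped to -1000.
#'
#' @param volume a [ct_volume()].
#' @param mask logical array of the lung region, same shape as `volume$hu`.
#' @return list with vectors `gas_ml` and `tissue_g` over the masked voxels
#'   (in array order), plus the scalar `voxel_volume_ml`.
#' @export
decompose_voxels <- function(volume, mask) {
  mask <- check_mask(volume, mask)
  voxvol <- volume$pixel_area * volume$slice_thickness / 1000  # ml
  hu <- as.numeric(volume$hu[mask])
  n_over <- sum(hu > 100)
  if (n_over > 0) {
    warning(n_over, " masked voxel(s) above +100 HU counted as nonaerated ",
            "at density 1.1 g/ml", call. = FALSE)
    hu[hu > 100] <- 100
  }
  hu[hu < -1000] <- -1000
  hu_mix <- pmin(hu, 0)                       # mixture part, [-1000, 0]
  gas <- voxvol * (-hu_mix / 1000)
  tissue <- voxvol * (1 + hu_mix / 1000)
  dense <- hu > 0                             # (0, 100]: gasless, density > 1
  tissue[dense] <- voxvol * (1 + hu[dense] / 1000)
  gas[dense] <- 0
  list(gas_ml = gas, tissue_g = tissue, voxel_volume_ml = voxvol)
}

# Aeration compartments on integer HU, exactly as conventionally printed.
.COMPARTMENTS <- data.frame(
  compartment = c("hyperinflated", "normally", "poorly", "nonaerated"),
  hu_min = c(-1000L, -900L, -500L, -100L),
  hu_max = c(-901L, -501L, -101L, 100L)
)

#' Aeration compartment summary of one CT volume
#'
#' Assigns every masked voxel to exactly one aeration compartment by its
#' integer Hounsfield number — hyperinflated \[-1000, -901\], normally
#' aerated \[-900, -501\], poorly aerated \[-500, -101\], nonaerated
#' \[-100, +100\] — and accumulates tissue weight and gas volume per
#' compartment. Non-integer HU (e.g. after resampling) are rounded to the
#' nearest integer before binning; masked voxels above +100 HU fall in the
#' nonaerated bin (see [decompose_voxels()]).
#'
#' @inheritParams decompose_voxels
#' @return object of class `compartment_summary`: a list with `table` (a
#'   data frame of weight_g and gas_ml per compartment plus a total row),
#'   scalars `total_weight_g`, `total_gas_ml`, `total_volume_ml`, `n_voxels`,
#'   and the `phase`/`peep_label` of the volume.
#' @export
summarize_compartments <- function(volume, mask) {
  mask <- check_mask(volume, mask)
  dec <- decompose_voxels(volume, mask)
  hu <- round(as.numeric(volume$hu[mask]))
  hu[hu < -1000] <- -1000
  hu[hu > 100] <- 100
  bin <- cut(hu, breaks = c(-1000.5, -900.5, -500.5, -100.5, 100.5),
             labels = c("hyperinflated", "normally", "poorly", "nonaerated"))
  w <- vapply(levels(bin), function(l) sum(dec$tissue_g[bin == l]), 0.0)
  g <- vapply(levels(bin), function(l) sum(dec$gas_ml[bin == l]), 0.0)
  tab <- data.frame(compartment = c(levels(bin), "total"),
                    weight_g = c(w, sum(w)),
                    gas_ml = c(g, sum(g)),
                    row.names = NULL)
  structure(list(table = tab,
                 total_weight_g = sum(w),
                 total_gas_ml = sum(g),
                 total_volume_ml = sum(dec$gas_ml) + sum(dec$tissue_g),
                 n_voxels = sum(mask),
                 phase = volume$phase,
                 peep_label = volume$peep_label),
            class = "compartment_summary")
}

#' @export
print.compartment_summary <- function(x, ...) {
  cat("<compartment_summary> ", x$phase, " @ PEEP_", toupper(x$peep_label),
      " (", x$n_voxels, " voxels)\n", sep = "")
  print(transform(x$table, weight_g = round(weight_g, 2),
                  gas_ml = round(gas_ml, 2)), row.names = FALSE)
  invisible(x)
}

comp_value <- function(summary, compartment, what = c("weight_g", "gas_ml")) {
  what <- match.arg(what)
  summary$table[[what]][summary$table$compartment == compartment]
}

#' PEEP-induced tissue and gas recruitment from CT
#'
#' Tissue recruitment `T_REC` is the fall in nonaerated tissue weight from
#' the low to the high PEEP at end-expiration; the alternative estimate
#' `t_rec_alt` uses nonaerated plus poorly aerated tissue. Gas recruitment
#' `GAS_REC` is `T_REC` times the gas-to-tissue ratio at the high PEEP:
#' either the median of voxelwise gas/tissue ratios over the masked
#' end-expiratory PEEP_HIGH voxels (`gt_mode = "voxel_median"`, the default;
#' voxels with under 1e-9 g of tissue are excluded) or the whole-lung
#' gas/tissue ratio (`gt_mode = "whole_lung_ratio"`). Both quantities are
#' normalised to the PEEP_LOW end-expiratory totals. Negative values
#' (derecruitment) propagate with a flag and are never clamped.
#'
#' @param summary_low_exp,summary_high_exp end-expiratory
#'   [summarize_compartments()] results at the two PEEPs.
#' @param volume_high_exp the end-expiratory PEEP_HIGH [ct_volume()].
#' @param mask lung mask of `volume_high_exp`.
#' @param gt_mode how to read "the g/t at PEEP_HIGH"; see above.
#' @return object of class `recruitment_result` with fields `t_rec` (g),
#'   `t_rec_alt` (g), `gt_median_high`, `gas_rec` (ml), `normalized_t_rec`,
#'   `normalized_gas_rec`, `delta_hyperinflated_gas` (ml) and `flags`.
#' @export
compute_recruitment <- function(summary_low_exp, summary_high_exp,
                                volume_high_exp, mask,
                                gt_mode = c("voxel_median", "whole_lung_ratio")) {
  gt_mode <- match.arg(gt_mode)
  for (s in list(summary_low_exp, summary_high_exp)) {
    if (!inherits(s, "compartment_summary"))
      stop("summaries must be compartment_summary objects", call. = FALSE)
    if (s$phase != "end_expiration")
      stop("recruitment uses end-expiratory summaries, got ", s$phase,
           call. = FALSE)
  }
  t_rec <- comp_value(summary_low_exp, "nonaerated") -
    comp_value(summary_high_exp, "nonaerated")
  t_rec_alt <- (comp_value(summary_low_exp, "nonaerated") +
                  comp_value(summary_low_exp, "poorly")) -
    (comp_value(summary_high_exp, "nonaerated") +
       comp_value(summary_high_exp, "poorly"))
  dec <- decompose_voxels(volume_high_exp, mask)
  if (gt_mode == "voxel_median") {
    keep <- dec$tissue_g > 1e-9
    gt <- stats::median(dec$gas_ml[keep] / dec$tissue_g[keep])
  } else {
    gt <- sum(dec$gas_ml) / sum(dec$tissue_g)
  }
  gas_rec <- t_rec * gt
  tot_w_low <- summary_low_exp$total_weight_g
  tot_g_low <- summary_low_exp$total_gas_ml
  if (tot_g_low <= 0)
    stop("cannot normalise: total gas volume at PEEP_LOW is zero", call. = FALSE)
  flags <- character(0)
  if (t_rec < 0) flags <- c(flags, "derecruitment_negative")
  structure(list(
    t_rec = t_rec,
    t_rec_alt = t_rec_alt,
    gt_median_high = gt,
    gt_mode = gt_mode,
    gas_rec = gas_rec,
    normalized_t_rec = t_rec / tot_w_low,
    normalized_gas_rec = gas_rec / tot_g_low,
    delta_hyperinflated_gas = comp_value(summary_high_exp, "hyperinflated", "gas_ml") -
      comp_value(summary_low_exp, "hyperinflated", "gas_ml"),
    flags = flags
  ), class = "recruitment_result")
}

#' @export
print.recruitment_result <- function(x, ...) {
  cat("<recruitment_result>\n")
  cat(sprintf("  T_REC %.2f g (alt %.2f g), g/t@high %.3f [%s]\n",
              x$t_rec, x$t_rec_alt, x$gt_median_high, x$gt_mode))
  cat(sprintf("  GAS_REC %.1f ml; normalized T_REC %.3f, GAS_REC %.3f\n",
              x$gas_rec, x$normalized_t_rec, x$normalized_gas_rec))
  cat(sprintf("  delta hyperinflated gas %.2f ml\n", x$delta_hyperinflated_gas))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
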