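# Pipeline orchestration: simulate -> ct-quant -> ri -> strain -> stats,
# file-based between stages so every stage is independently re-runnable,
# with a run manifest (config hash, checksums, warnings).

.PIPELINE_KEYS <- c("phantom", "protocol", "gt_mode", "delta_eelv_source",
                    "seed", "cohort_size", "opening_mu_range", "weight_mean",
                    "weight_sd")

#' Default pipeline configuration
#'
#' @return a named list of documented defaults: a 14-subject synthetic
#'   cohort spanning low-to-high recruitability, analysed with the
#'   voxel-median gas/tissue ratio and the CT-derived dEELV.
#' @export
default_config <- function() {
  ph <- phantom_config()
  pr <- vent_protocol()
  list(phantom = unclass(ph)[setdiff(names(ph), "seed")],
       protocol = unclass(pr),
       gt_mode = "voxel_median",
       delta_eelv_source = "ct",
       seed = 1L,
       cohort_size = 14L,
       opening_mu_range = c(2, 11),
       weight_mean = 50,
       weight_sd = 4)
}

#' Validate a pipeline configuration
#'
#' Reads a JSON configuration (or takes a list), fills documented defaults,
#' range-checks every field through the underlying constructors and rejects
#' unknown keys.
#'
#' @param config path to a JSON file, or a list.
#' @return object of class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stop("config must be a list or a JSON path", call. = FALSE)
  unknown <- setdiff(names(config), .PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  def <- default_config()
  cfg <- utils::modifyList(def, config)
  for (k in c("phantom", "protocol")) {
    bad <- setdiff(names(cfg[[k]]), names(def[[k]]))
    bad <- setdiff(bad, "seed")
    if (length(bad))
      stop("unknown ", k, " key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg$phantom$seed <- NULL
  if (!("aop_pressure" %in% names(cfg$phantom)))
    cfg$phantom["aop_pressure"] <- list(NULL)   # JSON null round-trips to NULL
  do.call(phantom_config, c(cfg$phantom, list(seed = cfg$seed)))  # range check
  cfg$protocol <- unclass(do.call(vent_protocol, cfg$protocol))
  cfg$gt_mode <- match.arg(cfg$gt_mode, c("voxel_median", "whole_lung_ratio"))
  cfg$delta_eelv_source <- match.arg(cfg$delta_eelv_source, c("ct", "maneuver"))
  if (cfg$cohort_size < 1) stop("cohort_size must be >= 1", call. = FALSE)
  if (cfg$seed < 0 || cfg$seed > 2^31 - 10^6)
    stop("seed out of range", call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write a pipeline configuration as JSON
#'
#' @param config a `pipeline_config` (or plain list).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

write_result_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes the whole measurement chain for a synthetic cohort: phantom
#' simulation (CT volumes written as NIfTI, traces as CSV, ground truth as
#' JSON), quantitative CT analysis, waveform mechanics and R/I, lung
#' strain, and the cohort statistics, writing every stage product under
#' `out_dir` together with a run manifest. Stages communicate through files
#' only; rerunning with the same config and seed reproduces identical
#' artifact checksums.
#'
#' @param config a `pipeline_config` from [validate_config()] (or a list /
#'   JSON path accepted by it).
#' @param out_dir output directory, created if missing.
#' @return the run manifest (class `run_manifest`), invisibly; all stage
#'   outputs are on disk.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, paste0(...))
  t0 <- Sys.time()

  # ---- stage 1: simulate ---------------------------------------------------
  protocol <- do.call(vent_protocol, cfg$protocol)
  configs <- do.call(cohort_configs, c(
    list(n = cfg$cohort_size, seed = cfg$seed,
         opening_mu_range = cfg$opening_mu_range,
         weight_mean = cfg$weight_mean, weight_sd = cfg$weight_sd),
    cfg$phantom[setdiff(names(cfg$phantom),
                        c("opening_mu", "weight_total"))]))
  sim_dir <- file.path(out_dir, "simulate")
  dir.create(sim_dir, showWarnings = FALSE)
  ids <- sprintf("subj%02d", seq_len(cfg$cohort_size))
  for (i in seq_len(cfg$cohort_size)) {
    ph <- simulate_phantom(configs[[i]], protocol)
    d <- file.path(sim_dir, ids[i])
    dir.create(d, showWarnings = FALSE)
    for (pl in c("low", "high")) for (phz in c("exp", "insp")) {
      v <- ph$ct[[pl]][[phz]]
      write_nifti(v$volume, file.path(d, sprintf("ct_%s_%s.nii.gz", pl, phz)))
      write_nifti(v$mask, file.path(d, sprintf("mask_%s_%s.nii.gz", pl, phz)))
    }
    write_trace_csv(ph$trace, file.path(d, "trace.csv"))
    write_result_json(ph$truth, file.path(d, "ground_truth.json"))
    write_result_json(list(id = ids[i],
                           phantom = unclass(configs[[i]]),
                           protocol = unclass(protocol)),
                      file.path(d, "manifest.json"))
  }

  # ---- stage 2-4: per-subject measurement chain ----------------------------
  res_dir <- file.path(out_dir, "analysis")
  dir.create(res_dir, showWarnings = FALSE)
  strains <- list(); recs <- list(); ris <- numeric(0)
  for (i in seq_len(cfg$cohort_size)) {
    d <- file.path(sim_dir, ids[i])
    geom <- list(pixel_area = cfg$phantom$pixel_area,
                 slice_thickness = cfg$phantom$slice_thickness)
    read_pair <- function(pl, phz) {
      v <- read_ct_nifti(file.path(d, sprintf("ct_%s_%s.nii.gz", pl, phz)),
                         pixel_area = geom$pixel_area,
                         slice_thickness = geom$slice_thickness,
                         phase = if (phz == "exp") "end_expiration"
                         else "end_inspiration",
                         peep_label = pl)
      m <- read_nifti(file.path(d, sprintf("mask_%s_%s.nii.gz", pl, phz)))
      list(volume = v, mask = array(m$data > 0, dim = m$dim))
    }
    low_exp <- read_pair("low", "exp")
    high_exp <- read_pair("high", "exp")
    sum_low <- summarize_compartments(low_exp$volume, low_exp$mask)
    sum_high <- summarize_compartments(high_exp$volume, high_exp$mask)
    rec <- withCallingHandlers(
      compute_recruitment(sum_low, sum_high, high_exp$volume, high_exp$mask,
                          gt_mode = cfg$gt_mode),
      warning = function(w) { note(ids[i], ": ", conditionMessage(w))
        invokeRestart("muffleWarning") })

    trace <- read_trace_csv(file.path(d, "trace.csv"))
    seg <- segment_breaths(trace)
    mech_low <- compute_mechanics(trace, seg, protocol$peep_low)
    mech_high <- compute_mechanics(trace, seg, protocol$peep_high)
    aop <- tryCatch(detect_aop(trace, seg, protocol$peep_low),
                    error = function(e) NULL)
    dr <- derecruitment_ri(trace, seg, mech_low, protocol$peep_high,
                           protocol$peep_low, aop)
    if (length(dr$flags)) note(ids[i], ": ", paste(dr$flags, collapse = ", "))

    st <- compute_strains(mech_low$vt, sum_low, sum_high, rec,
                          delta_eelv_source = cfg$delta_eelv_source,
                          delta_eelv_maneuver = dr$delta_eelv)
    strains[[ids[i]]] <- st
    recs[[ids[i]]] <- rec
    ris[ids[i]] <- dr$ri
    write_result_json(list(mechanics_low = unclass(mech_low),
                           mechanics_high = unclass(mech_high),
                           aop = if (is.null(aop)) NULL else unclass(aop),
                           derecruitment = unclass(dr),
                           recruitment = unclass(rec),
                           strain = unclass(st)),
                      file.path(res_dir, paste0(ids[i], ".json")))
  }

  cohort <- strain_ratio_table(strains, ris, recs)
  cohort_csv <- file.path(res_dir, "cohort.csv")
  utils::write.csv(cohort, cohort_csv, row.names = FALSE)

  # ---- stage 5: cohort statistics ------------------------------------------
  stats_out <- cohort_statistics(cohort)
  write_result_json(stats_out, file.path(res_dir, "statistics.json"))
  writeLines(format_report(stats_out, cohort),
             file.path(res_dir, "report.txt"))

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  sums <- tools::md5sum(files)
  manifest <- structure(list(
    config_hash = config_hash(cfg),
    version = as.character(utils::packageVersion("recruitquant")),
    seed = cfg$seed,
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    checksums = data.frame(file = substring(names(sums), nchar(out_dir) + 2L),
                           md5 = unname(sums)),
    warnings = warnings_log
  ), class = "run_manifest")
  write_result_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> seed ", x$seed, ", config ", x$config_hash, "\n",
      "  ", nrow(x$checksums), " artifacts, ", length(x$warnings),
      " warning(s)\n", sep = "")
  invisible(x)
}

#' Cohort statistics stage
#'
#' Runs the cohort analysis plan on a per-subject table: median \[IQR\]
#' summaries, the paired low-vs-high comparison of dynamic strain, Pearson
#' correlations (with Fisher-z 95% CI) of R/I against the strain changes
#' and normalised recruitment, the regression of the dynamic-strain change
#' on R/I with influence diagnostics, and the coefficient of variation of
#' the dynamic-strain reduction.
#'
#' @param cohort data frame from [strain_ratio_table()] (or the cohort CSV).
#' @return a list of named results (correlations, comparison, regression,
#'   summaries).
#' @export
cohort_statistics <- function(cohort) {
  if (is.character(cohort)) cohort <- utils::read.csv(cohort)
  list(
    n = nrow(cohort),
    ri_summary = cohort_summary(cohort$ri),
    dynamic_comparison = unclass(
      paired_compare(cohort$dynamic_low, cohort$dynamic_high)),
    cv_dynamic_reduction_pct = cohort_summary(
      cohort$dynamic_low - cohort$dynamic_high)$cv,
    cor_ri_delta_dynamic = unclass(pearson_ci(cohort$ri, cohort$delta_dynamic)),
    cor_ri_delta_static = unclass(pearson_ci(cohort$ri, cohort$delta_static)),
    cor_ri_delta_global = unclass(pearson_ci(cohort$ri, cohort$delta_global)),
    cor_ri_norm_gas_rec = unclass(pearson_ci(cohort$ri, cohort$normalized_gas_rec)),
    cor_ri_norm_t_rec = unclass(pearson_ci(cohort$ri, cohort$normalized_t_rec)),
    regression_ri_delta_dynamic = unclass(
      linreg_diagnostics(cohort$ri, cohort$delta_dynamic))[
        c("slope", "intercept", "slope_ci", "intercept_ci",
          "residual_normality_p", "n")]
  )
}

format_report <- function(stats_out, cohort) {
  f <- function(s) sprintf("%.3g [%.3g-%.3g]", s$median, s$q25, s$q75)
  cor_line <- function(name, cr)
    sprintf("  %-28s r = %+.3f [95%% CI %+.3f to %+.3f], p = %.3g",
            name, cr$r, cr$ci_low, cr$ci_high, cr$p)
  c(sprintf("Synthetic cohort report (n = %d)", stats_out$n),
    sprintf("  R/I median [IQR]: %s", f(stats_out$ri_summary)),
    sprintf("  dynamic strain low -> high: %.3g -> %.3g (p = %.3g, %s)",
            stats_out$dynamic_comparison$median[1],
            stats_out$dynamic_comparison$median[2],
            stats_out$dynamic_comparison$p, stats_out$dynamic_comparison$test),
    sprintf("  CV of dynamic strain reduction: %.1f%%",
            stats_out$cv_dynamic_reduction_pct),
    "Correlations with R/I:",
    cor_line("delta dynamic strain", stats_out$cor_ri_delta_dynamic),
    cor_line("delta static strain", stats_out$cor_ri_delta_static),
    cor_line("delta global strain", stats_out$cor_ri_delta_global),
    cor_line("normalized GAS_REC", stats_out$cor_ri_norm_gas_rec),
    cor_line("normalized T_REC", stats_out$cor_ri_norm_t_rec),
    sprintf("Regression d(dynamic) ~ R/I: slope %.3f [%.3f, %.3f], intercept %.3f",
            stats_out$regression_ri_delta_dynamic$slope,
            stats_out$regression_ri_delta_dynamic$slope_ci[1],
            stats_out$regression_ri_delta_dynamic$slope_ci[2],
            stats_out$regression_ri_delta_dynamic$intercept))
}
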