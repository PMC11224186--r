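# Respiratory mechanics from ventilator waveforms: breath segmentation,
# occlusion-based plateau/PEEP readings, stress index, ventilatory ratio,
# airway opening pressure detection and the one-breath derecruitment chain
# yielding the recruitment-to-inflation ratio.
#
# Units discipline throughout: pressures cmH2O, volumes ml, flows L/s,
# compliances ml/cmH2O.

# discrete trapezoidal integral of y sampled at rate fs
trapz <- function(y, fs) (sum(y) - (y[1] + y[length(y)]) / 2) / fs

.FLOW_THRESHOLD <- 0.005  # L/s; below this the airway is considered at rest

#' Segment a ventilator trace into breaths
#'
#' Delimits breaths at inspiratory flow onsets (flow rising above the
#' threshold after at least 50 ms below it), locates end-inspiratory and
#' end-expiratory occlusion windows, and identifies the maneuver breaths.
#' Event labels, when present in the trace, take precedence; otherwise
#' occlusions are zero-flow holds (>= 0.3 s after inspiration for the
#' end-inspiratory one, a long terminal hold for the end-expiratory one),
#' the derecruitment breath is the one whose expiration lasts more than
#' twice the median, and the low-flow breath the one whose inspiration does.
#'
#' @param trace a `vent_trace` (see [read_trace_csv()]).
#' @param flow_threshold zero-flow threshold, L/s.
#' @return object of class `breath_segmentation`: list with `breaths` (data
#'   frame of sample indices `onset`, `insp_end`, `end`, `baseline_paw`,
#'   `type`) and `occlusions` (data frame `start`, `end`, `type`, `breath`).
#' @export
segment_breaths <- function(trace, flow_threshold = .FLOW_THRESHOLD) {
  fs <- attr(trace, "sample_rate")
  flow <- trace$flow_lps
  if (!any(flow > flow_threshold))
    stop("no breaths: flow never exceeds the threshold", call. = FALSE)
  above <- flow > flow_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_gap <- max(1L, round(0.05 * fs))
  onsets <- integer(0)
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    if (i == 1L || r$lengths[i - 1L] >= min_gap)
      onsets <- c(onsets, starts[i])
  }
  if (length(onsets) == 0L)
    stop("no breaths: no inspiratory onset found", call. = FALSE)
  breath_end <- c(onsets[-1L] - 1L, length(flow))
  insp_end <- vapply(seq_along(onsets), function(i) {
    j <- which(starts >= onsets[i] & r$values)[1]
    ends[j]
  }, 1L)
  baseline <- vapply(onsets, function(o) {
    pre <- max(1L, o - round(0.25 * fs)):(max(1L, o - 1L))
    stats::median(trace$paw_cmh2o[pre])
  }, 0.0)

  ev <- trace$event
  occl <- data.frame(start = integer(0), end = integer(0),
                     type = character(0), breath = integer(0))
  add_occl <- function(s, e, type) {
    b <- findInterval(s, onsets)
    rbind(occl, data.frame(start = s, end = e, type = type,
                           breath = max(b, 1L)))
  }
  if (any(ev %in% c("insp_occlusion", "exp_occlusion"))) {
    for (type in c("insp_occlusion", "exp_occlusion")) {
      rr <- rle(ev == type)
      re <- cumsum(rr$lengths)
      rs <- re - rr$lengths + 1L
      for (i in which(rr$values)) occl <- add_occl(rs[i], re[i], type)
    }
  } else {
    still <- abs(flow) < flow_threshold
    rr <- rle(still)
    re <- cumsum(rr$lengths)
    rs <- re - rr$lengths + 1L
    for (i in which(rr$values & rr$lengths >= round(0.3 * fs))) {
      b <- findInterval(rs[i], onsets)
      if (b < 1L) next
      # right after inspiration -> end-inspiratory occlusion
      if (rs[i] - insp_end[b] <= round(0.1 * fs) &&
          rs[i] > insp_end[b])
        occl <- add_occl(rs[i], re[i], "insp_occlusion")
      else if (rr$lengths[i] >= round(1.5 * fs) &&
               re[i] >= breath_end[b] - round(0.25 * fs))
        occl <- add_occl(rs[i], re[i], "exp_occlusion")
    }
  }

  type <- rep("tidal", length(onsets))
  labelled <- FALSE
  for (i in seq_along(onsets)) {
    win <- onsets[i]:breath_end[i]
    if (any(ev[win] == "derecruitment")) { type[i] <- "derecruitment"; labelled <- TRUE }
    else if (any(ev[win] == "aop_breath")) { type[i] <- "aop"; labelled <- TRUE }
  }
  if (!labelled && length(onsets) >= 3L) {
    te <- breath_end - insp_end
    ti <- insp_end - onsets
    type[te > 2 * stats::median(te)] <- "derecruitment"
    type[ti > 2 * stats::median(ti) & type == "tidal"] <- "aop"
  }

  structure(list(
    breaths = data.frame(onset = onsets, insp_end = insp_end,
                         end = breath_end, baseline_paw = baseline,
                         type = type),
    occlusions = occl,
    sample_rate = fs
  ), class = "breath_segmentation")
}

#' @export
print.breath_segmentation <- function(x, ...) {
  cat("<breath_segmentation> ", nrow(x$breaths), " breaths (",
      paste(names(table(x$breaths$type)), table(x$breaths$type),
            sep = ":", collapse = ", "),
      "), ", nrow(x$occlusions), " occlusion window(s)\n", sep = "")
  invisible(x)
}

occl_reading <- function(trace, occl, fs, window_s = 0.5) {
  keep <- max(occl$start, occl$end - round(window_s * fs) + 1L):occl$end
  mean(trace$paw_cmh2o[keep])
}

#' Respiratory mechanics at one PEEP step
#'
#' Reads tidal volume (trapezoidal integration of inspiratory flow), peak
#' and plateau pressure, total PEEP, intrinsic PEEP, driving pressure and
#' respiratory-system compliance from the tidal breaths and occlusion
#' windows belonging to one PEEP step. Plateau and total PEEP are the mean
#' airway pressure over the last 0.5 s of the end-inspiratory and
#' end-expiratory occlusion, respectively.
#'
#' @param trace a `vent_trace`.
#' @param segmentation a [segment_breaths()] result.
#' @param peep_set the set PEEP (cmH2O) of the step to analyse; breaths are
#'   matched by their pre-inspiratory baseline pressure.
#' @param match_tol baseline-matching tolerance, cmH2O.
#' @return object of class `resp_mechanics` with fields `vt` (ml),
#'   `peep_set`, `peep_i`, `peep_tot`, `p_plat`, `p_peak`,
#'   `driving_pressure` (cmH2O), `c_rs` (ml/cmH2O), and `stress_index` /
#'   `ventilatory_ratio` slots (NA until filled by [stress_index()] /
#'   [ventilatory_ratio()]).
#' @export
compute_mechanics <- function(trace, segmentation, peep_set, match_tol = 2) {
  seg <- segmentation
  fs <- seg$sample_rate
  b <- seg$breaths
  sel <- which(abs(b$baseline_paw - peep_set) <= match_tol & b$type == "tidal")
  if (length(sel) == 0L)
    stop("no tidal breaths found at set PEEP ", peep_set, call. = FALSE)
  vts <- vapply(sel, function(i) {
    1000 * trapz(trace$flow_lps[b$onset[i]:b$insp_end[i]], fs)
  }, 0.0)
  vt <- stats::median(vts)
  occ <- seg$occlusions[seg$occlusions$breath %in% sel, , drop = FALSE]
  io <- occ[occ$type == "insp_occlusion", , drop = FALSE]
  eo <- occ[occ$type == "exp_occlusion", , drop = FALSE]
  if (nrow(io) == 0L)
    stop("mechanics unavailable: no end-inspiratory occlusion at set PEEP ",
         peep_set, call. = FALSE)
  if (nrow(eo) == 0L)
    stop("mechanics unavailable: no end-expiratory occlusion at set PEEP ",
         peep_set, call. = FALSE)
  p_plat <- mean(vapply(seq_len(nrow(io)),
                        function(i) occl_reading(trace, io[i, ], fs), 0.0))
  peep_tot <- mean(vapply(seq_len(nrow(eo)),
                          function(i) occl_reading(trace, eo[i, ], fs), 0.0))
  p_peak <- max(vapply(sel, function(i)
    max(trace$paw_cmh2o[b$onset[i]:b$insp_end[i]]), 0.0))
  peep_i <- max(peep_tot - peep_set, 0)
  dp <- p_plat - peep_tot
  if (dp <= 0) stop("driving pressure is not positive; check occlusions",
                    call. = FALSE)
  structure(list(vt = vt, peep_set = peep_set, peep_i = peep_i,
                 peep_tot = peep_tot, p_plat = p_plat, p_peak = p_peak,
                 driving_pressure = dp, c_rs = vt / dp,
                 stress_index = NA_real_, ventilatory_ratio = NA_real_),
            class = "resp_mechanics")
}

#' @export
print.resp_mechanics <- function(x, ...) {
  cat("<resp_mechanics> @ set PEEP", x$peep_set, "cmH2O\n")
  cat(sprintf("  VT %.1f ml  Pplat %.2f  PEEPtot %.2f  dP %.2f cmH2O  Crs %.2f ml/cmH2O\n",
              x$vt, x$p_plat, x$peep_tot, x$driving_pressure, x$c_rs))
  if (!is.na(x$stress_index))
    cat(sprintf("  stress index %.3f\n", x$stress_index))
  if (!is.na(x$ventilatory_ratio))
    cat(sprintf("  ventilatory ratio %.2f\n", x$ventilatory_ratio))
  invisible(x)
}

#' Stress index of a constant-flow inspiration
#'
#' Fits `paw(t) = a * t^b + c` over the constant-flow portion of an
#' inspiration (samples whose flow is within 5% of the inspiratory plateau
#' median, excluding the first 50 ms of circuit transients) and returns the
#' exponent b: above 1 the pressure profile is convex (overdistension
#' accumulating), below 1 concave (tidal recruitment). The fit profiles b:
#' at each candidate b, (a, c) solve a linear least-squares problem; b is
#' then optimised on \[0.2, 3\].
#'
#' @inheritParams compute_mechanics
#' @param breath index of the breath to fit; default the first tidal breath.
#' @return the stress index (dimensionless scalar).
#' @export
stress_index <- function(trace, segmentation, breath = NULL) {
  seg <- segmentation
  fs <- seg$sample_rate
  b <- seg$breaths
  if (is.null(breath)) breath <- which(b$type == "tidal")[1]
  if (is.na(breath)) stop("stress index unavailable: no tidal breath", call. = FALSE)
  win <- b$onset[breath]:b$insp_end[breath]
  skip <- round(0.05 * fs)
  if (length(win) > skip) win <- win[-seq_len(skip)]
  fl <- trace$flow_lps[win]
  plateau <- stats::median(fl)
  keep <- abs(fl - plateau) <= 0.05 * abs(plateau)
  win <- win[keep]
  if (length(win) < 20L)
    stop("stress index unavailable: constant-flow window under 20 samples",
         call. = FALSE)
  # time is zeroed at the inspiratory onset: the power-law pressure profile
  # originates where flow starts, and an offset origin would bias b
  t <- trace$time_s[win] - trace$time_s[b$onset[breath]]
  p <- trace$paw_cmh2o[win]
  sse <- function(bb) {
    X <- cbind(t^bb, 1)
    fit <- stats::lm.fit(X, p)
    sum(fit$residuals^2)
  }
  opt <- stats::optimize(sse, interval = c(0.2, 3), tol = 1e-7)
  opt$minimum
}

#' Ventilatory ratio
#'
#' `Vr = (VT (ml) * RR * PaCO2) / (PBW * 100 * 37.5)`: measured minute
#' ventilation times measured PaCO2, scaled to the predicted minute
#' ventilation (100 ml/kg/min of predicted body weight) at the ideal PaCO2
#' of 37.5 mmHg. A dead-space surrogate: 1 is normal.
#'
#' @param mech a [compute_mechanics()] result (or any list with `vt` in ml).
#' @param rr respiratory rate, breaths/min.
#' @param gas a list with `paco2` (mmHg); see [blood_gas()].
#' @param subject a list with `pbw` (kg); see [subject_info()].
#' @return the dimensionless ventilatory ratio.
#' @export
ventilatory_ratio <- function(mech, rr, gas, subject) {
  if (is.null(gas$paco2) || !is.finite(gas$paco2) || gas$paco2 <= 0)
    stop("PaCO2 must be positive", call. = FALSE)
  if (is.null(subject$pbw) || subject$pbw <= 0)
    stop("predicted body weight must be positive", call. = FALSE)
  if (rr <= 0 || mech$vt <= 0)
    stop("rr and vt must be positive", call. = FALSE)
  (mech$vt * rr * gas$paco2) / (subject$pbw * 100 * 37.5)
}

#' Subject scalars
#'
#' @param pbw predicted body weight, kg.
#' @param id subject label.
#' @return list of class `subject_info`.
#' @export
subject_info <- function(pbw, id = "subject") {
  if (pbw <= 0) stop("pbw must be positive", call. = FALSE)
  structure(list(pbw = pbw, id = id), class = "subject_info")
}

#' Blood-gas scalars
#'
#' @param paco2,pao2 arterial CO2 / O2 tensions, mmHg.
#' @param fio2 inspired oxygen fraction (0, 1].
#' @param ph arterial pH.
#' @return list of class `blood_gas`.
#' @export
blood_gas <- function(paco2, pao2 = NA_real_, fio2 = 1, ph = NA_real_) {
  if (paco2 <= 0) stop("paco2 must be positive", call. = FALSE)
  if (fio2 <= 0 || fio2 > 1) stop("fio2 must be in (0, 1]", call. = FALSE)
  structure(list(paco2 = paco2, pao2 = pao2, fio2 = fio2, ph = ph),
            class = "blood_gas")
}

#' Airway opening pressure from the low-flow inflation
#'
#' Regresses airway pressure against delivered volume over the low-flow
#' breath and searches exhaustively for the best two-segment piecewise-linear
#' (hinge) fit. An AOP is declared when the pre-breakpoint slope is at least
#' `slope_ratio_min` times the post-breakpoint slope, the breakpoint lies in
#' the first `max_break_frac` of the delivered volume, and the breakpoint
#' pressure exceeds the low PEEP; the AOP is the fitted pressure at the
#' breakpoint.
#'
#' @inheritParams compute_mechanics
#' @param peep_low the set low PEEP, cmH2O.
#' @param slope_ratio_min,max_break_frac detection gates (see above).
#' @return object of class `aop_result`: `present`, `aop` (cmH2O or NA),
#'   `breakpoint_volume` (ml), `slope_ratio`.
#' @export
detect_aop <- function(trace, segmentation, peep_low,
                       slope_ratio_min = 3, max_break_frac = 0.2) {
  seg <- segmentation
  fs <- seg$sample_rate
  b <- seg$breaths
  i <- which(b$type == "aop")[1]
  if (is.na(i)) stop("AOP unavailable: no low-flow breath", call. = FALSE)
  win <- b$onset[i]:b$insp_end[i]
  skip <- round(0.05 * fs)
  if (length(win) > skip + 10L) win <- win[-seq_len(skip)]
  fl <- trace$flow_lps[win]
  p <- trace$paw_cmh2o[win]
  v <- 1000 * (cumsum(fl) - fl / 2 - (fl[1] / 2)) / fs  # cumulative trapezoid, ml
  vt_b <- v[length(v)]
  cand <- seq(5L, length(v) - 5L)
  if (length(cand) > 200L) cand <- unique(round(seq(5L, length(v) - 5L,
                                                    length.out = 200L)))
  best <- NULL
  for (k in cand) {
    X <- cbind(1, v, pmax(v - v[k], 0))
    fit <- stats::lm.fit(X, p)
    sse <- sum(fit$residuals^2)
    if (is.null(best) || sse < best$sse)
      best <- list(sse = sse, k = k, coef = fit$coefficients)
  }
  slope1 <- best$coef[2]
  slope2 <- best$coef[2] + best$coef[3]
  ratio <- if (slope2 <= 0) Inf else slope1 / slope2
  vb <- v[best$k]
  p_break <- best$coef[1] + slope1 * vb
  present <- is.finite(ratio) && ratio >= slope_ratio_min &&
    vb < max_break_frac * vt_b && p_break > peep_low
  structure(list(present = present,
                 aop = if (present) unname(p_break) else NA_real_,
                 breakpoint_volume = unname(vb),
                 slope_ratio = unname(ratio)),
            class = "aop_result")
}

#' @export
print.aop_result <- function(x, ...) {
  if (x$present)
    cat(sprintf("<aop_result> AOP present at %.2f cmH2O (breakpoint %.1f ml, slope ratio %.1f)\n",
                x$aop, x$breakpoint_volume, x$slope_ratio))
  else cat("<aop_result> no airway opening pressure detected\n")
  invisible(x)
}

#' One-breath derecruitment maneuver and recruitment-to-inflation ratio
#'
#' Applies the R/I equation chain to the prolonged expiration recorded when
#' PEEP is dropped from high to low within one breath:
#' `dEELV = exhaled volume - VT`;
#' `inflation volume = C_RS,low * (PEEP_high - effective low pressure)`;
#' `V_REC = dEELV - inflation volume`;
#' `C_REC = V_REC / (PEEP_high - effective low pressure)`;
#' `R/I = C_REC / C_RS,low`.
#' The effective low pressure is the airway opening pressure when one is
#' present, the low PEEP otherwise. A negative `V_REC` (non-recruiter) is
#' reported with the flag `non_recruiter_negative`, never clamped.
#'
#' @inheritParams compute_mechanics
#' @param mech_low [compute_mechanics()] result at the low PEEP (for
#'   `c_rs` and the fallback tidal volume).
#' @param peep_high,peep_low the PEEP step, cmH2O.
#' @param aop optional [detect_aop()] result.
#' @return object of class `derecruit_result` with `exhaled_volume`,
#'   `delta_eelv`, `inflation_volume`, `v_rec` (ml), `c_rec` (ml/cmH2O),
#'   `ri`, `effective_low_pressure`, `vt`, `c_rs_low`, `flags`.
#' @export
derecruitment_ri <- function(trace, segmentation, mech_low,
                             peep_high, peep_low, aop = NULL) {
  seg <- segmentation
  fs <- seg$sample_rate
  b <- seg$breaths
  i <- which(b$type == "derecruitment")[1]
  if (is.na(i)) stop("no derecruitment breath identified", call. = FALSE)
  eff_low <- if (!is.null(aop) && isTRUE(aop$present)) aop$aop else peep_low
  if (peep_high <= eff_low)
    stop("peep_high must exceed the effective low pressure", call. = FALSE)
  lab <- which(trace$event == "derecruitment")
  lab <- lab[lab >= b$onset[i] & lab <= b$end[i]]
  win <- if (length(lab)) lab else (b$insp_end[i] + 1L):b$end[i]
  exhaled <- 1000 * abs(trapz(trace$flow_lps[win], fs))
  insp <- b$onset[i]:b$insp_end[i]
  vt <- if (any(trace$flow_lps[insp] > .FLOW_THRESHOLD))
    1000 * trapz(trace$flow_lps[insp], fs) else mech_low$vt
  c_rs_low <- mech_low$c_rs
  delta_eelv <- exhaled - vt
  inflation <- c_rs_low * (peep_high - eff_low)
  v_rec <- delta_eelv - inflation
  c_rec <- v_rec / (peep_high - eff_low)
  ri <- c_rec / c_rs_low
  flags <- if (v_rec < 0) "non_recruiter_negative" else character(0)
  structure(list(exhaled_volume = exhaled, delta_eelv = delta_eelv,
                 inflation_volume = inflation, v_rec = v_rec, c_rec = c_rec,
                 ri = ri, effective_low_pressure = eff_low, vt = vt,
                 c_rs_low = c_rs_low, flags = flags),
            class = "derecruit_result")
}

#' @export
print.derecruit_result <- function(x, ...) {
  cat("<derecruit_result>\n")
  cat(sprintf("  exhaled %.1f ml, VT %.1f ml -> dEELV %.1f ml\n",
              x$exhaled_volume, x$vt, x$delta_eelv))
  cat(sprintf("  inflation %.1f ml, V_REC %.1f ml, C_REC %.2f ml/cmH2O\n",
              x$inflation_volume, x$v_rec, x$c_rec))
  cat(sprintf("  R/I = %.3f (effective low pressure %.1f cmH2O)\n",
              x$ri, x$effective_low_pressure))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
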