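# Ventilator waveform synthesis.
#
# Breaths are constant-flow volume-control: inspiratory flow VT/Ti with
# airway pressure PEEP + R*flow + (VT/C)*(t/Ti)^b (b = stress-index
# exponent), passive single-exponential expiration with time constant R*C.
# The derecruitment maneuver imposes its exhaled volume exactly by scaling
# the expiratory flow so that its discrete trapezoidal integral equals the
# target: the measurement chain, not an ODE solver, is under test.

new_trace <- function(time, flow, paw, event, phase, sample_rate) {
  tr <- data.frame(time_s = time, flow_lps = flow, paw_cmh2o = paw,
                   event = event, phase = phase,
                   stringsAsFactors = FALSE)
  attr(tr, "sample_rate") <- sample_rate
  class(tr) <- c("vent_trace", "data.frame")
  tr
}

#' @export
print.vent_trace <- function(x, ...) {
  cat("<vent_trace> ", nrow(x), " samples @ ", attr(x, "sample_rate"),
      " Hz (", sprintf("%.1f", nrow(x) / attr(x, "sample_rate")), " s), events: ",
      paste(setdiff(unique(x$event), "none"), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# -- segment builders (flow L/s, paw cmH2O, durations s) ---------------------

seg_hold <- function(fs, duration, paw, event = "none") {
  n <- max(1L, round(duration * fs))
  list(flow = rep(0, n), paw = rep(paw, n), event = rep(event, n))
}

# Constant-flow inspiration delivering vt ml in ti s; n_i + 1 samples carry
# the plateau flow so the trapezoidal integral from onset to the last
# above-threshold sample is exactly vt.
seg_inspiration <- function(fs, vt, ti, peep, C, R, b = 1, event = "none") {
  n_i <- max(2L, round(ti * fs))
  Fl <- (vt / 1000) / (n_i / fs)          # L/s, using the realised ti
  k <- 0:n_i
  paw <- peep + R * Fl + (vt / C) * (k / n_i)^b
  list(flow = rep(Fl, n_i + 1L), paw = paw, event = rep(event, n_i + 1L))
}

seg_expiration <- function(fs, vt, te, peep, C, R, event = "none",
                           target_ml = NULL, tau = NULL) {
  n_e <- max(2L, round(te * fs))
  t <- (1:n_e) / fs
  if (is.null(tau)) tau <- max(R * (C / 1000), 2 / fs)
  shape <- exp(-t / tau)
  flow <- -(vt / 1000) / tau * shape
  if (!is.null(target_ml)) {
    # impose the exhaled volume exactly on the discrete trapezoid
    w <- sum(abs(flow)) - (abs(flow[1]) + abs(flow[n_e])) / 2
    flow <- flow * (target_ml / 1000) / (w / fs)
  }
  list(flow = flow, paw = rep(peep, n_e), event = rep(event, n_e))
}

seg_insp_occlusion <- function(fs, duration, peep, vt, C, R, Fl) {
  n <- round(duration * fs)
  t <- (1:n) / fs
  plat <- peep + vt / C
  paw <- plat + (R * Fl) * exp(-t / 0.05)  # resistive component washes out
  list(flow = rep(0, n), paw = paw, event = rep("insp_occlusion", n))
}

seg_aop_breath <- function(fs, vt, peep, C, R, aop_flow_lpm, aop_pressure) {
  Fl <- aop_flow_lpm / 60
  ti <- (vt / 1000) / Fl
  n <- max(20L, round(ti * fs))
  v <- (0:n) / fs * Fl * 1000              # delivered volume, ml
  if (is.null(aop_pressure)) {
    paw_el <- peep + v / C
  } else {
    C_pre <- C / 5                          # closed-airway pseudo-compliance
    v_break <- C_pre * (aop_pressure - peep)
    paw_el <- ifelse(v <= v_break,
                     peep + v / C_pre,
                     aop_pressure + (v - v_break) / C)
  }
  list(flow = rep(Fl, n + 1L), paw = paw_el + R * Fl,
       event = rep("aop_breath", n + 1L))
}

cat_segs <- function(...) {
  segs <- list(...)
  list(flow = unlist(lapply(segs, `[[`, "flow")),
       paw = unlist(lapply(segs, `[[`, "paw")),
       event = unlist(lapply(segs, `[[`, "event")))
}

# One ventilation phase: tidal breaths, one end-inspiratory occlusion, one
# end-expiratory occlusion, optional AOP breath.
build_phase <- function(fs, vt, rr, ie, peep, C, R, b = 1,
                        occlusions = TRUE, aop = FALSE, aop_flow = 5,
                        aop_pressure = NULL) {
  Tt <- 60 / rr
  ti <- Tt * ie / (1 + ie)
  te <- Tt - ti
  tidal <- function() cat_segs(
    seg_inspiration(fs, vt, ti, peep, C, R, b),
    seg_expiration(fs, vt, te, peep, C, R))
  Fl <- (vt / 1000) / ti
  parts <- list(seg_hold(fs, 1.0, peep), tidal(), tidal())
  if (occlusions) {
    parts <- c(parts, list(
      cat_segs(seg_inspiration(fs, vt, ti, peep, C, R, b),
               seg_insp_occlusion(fs, 2.0, peep, vt, C, R, Fl),
               seg_expiration(fs, vt, te, peep, C, R)),
      tidal(),
      seg_hold(fs, 2.0, peep, "exp_occlusion"),
      seg_hold(fs, 0.3, peep)))
  }
  if (aop) {
    parts <- c(parts, list(
      cat_segs(seg_aop_breath(fs, vt, peep, C, R, aop_flow, aop_pressure),
               seg_expiration(fs, vt, te, peep, C, R)),
      seg_hold(fs, 0.5, peep)))
  }
  do.call(cat_segs, parts)
}

build_derecruitment <- function(fs, vt, rr, derecruit_rr, ie, peep_high,
                                peep_low, C_high, R, exhaled_ml) {
  # inspiration keeps the tidal timing (and thus a resolvable flow); the
  # slow-rate setting only serves to prolong the expiration (6.6 s nominal)
  ti <- (60 / rr) * ie / (1 + ie)
  te <- (60 / derecruit_rr) * (1 - ie / (1 + ie))
  cat_segs(
    seg_inspiration(fs, vt, ti, peep_high, C_high, R),
    seg_expiration(fs, vt, te, peep_low, C_high, R,
                   event = "derecruitment", target_ml = exhaled_ml,
                   tau = 0.8),
    seg_hold(fs, 1.0, peep_low))
}

#' Simulate the ventilator trace of a phantom
#'
#' Produces the full waveform record of the experimental sequence for one
#' phantom: ventilation at PEEP_LOW with end-inspiratory/end-expiratory
#' occlusions and a low-flow airway-opening-pressure (AOP) breath,
#' ventilation at PEEP_HIGH with occlusions, and the one-breath
#' derecruitment maneuver whose exhaled volume is `VT + true ΔEELV` of the
#' unit model.
#'
#' @param units a `lung_units` data frame.
#' @param protocol a [vent_protocol()].
#' @param aop_pressure optional airway opening pressure (cmH2O) to embed in
#'   the low-flow breath; `NULL` for an open airway.
#' @return a `vent_trace` data frame (`time_s`, `flow_lps`, `paw_cmh2o`,
#'   `event`, `phase`) sampled at `protocol$sample_rate`.
#' @export
simulate_traces <- function(units, protocol, aop_pressure = NULL) {
  protocol <- validate_vent_protocol(protocol)
  fs <- protocol$sample_rate
  truth <- export_ground_truth(units, protocol, config = NULL)
  C_low <- truth$true_c_rs_low
  C_high <- units_compliance(units, truth$plateau_high)
  if (C_low <= 0 || C_high <= 0)
    stop("phantom has no aerated units; cannot ventilate", call. = FALSE)
  R <- protocol$resistance
  lowp <- build_phase(fs, protocol$vt, protocol$rr, protocol$ie_ratio,
                      protocol$peep_low, C_low, R,
                      occlusions = "occlusions" %in% protocol$maneuvers,
                      aop = "aop_breath" %in% protocol$maneuvers,
                      aop_flow = protocol$aop_flow,
                      aop_pressure = aop_pressure)
  highp <- build_phase(fs, protocol$vt, protocol$rr, protocol$ie_ratio,
                       protocol$peep_high, C_high, R,
                       occlusions = "occlusions" %in% protocol$maneuvers)
  segs <- list(low = lowp, high = highp)
  if ("derecruitment" %in% protocol$maneuvers) {
    exhaled <- protocol$vt + truth$true_delta_eelv
    segs$maneuver <- build_derecruitment(
      fs, protocol$vt, protocol$rr, protocol$derecruit_rr, protocol$ie_ratio,
      protocol$peep_high, protocol$peep_low, C_high, R, exhaled)
  }
  flow <- unlist(lapply(segs, `[[`, "flow"), use.names = FALSE)
  paw <- unlist(lapply(segs, `[[`, "paw"), use.names = FALSE)
  event <- unlist(lapply(segs, `[[`, "event"), use.names = FALSE)
  phase <- rep(names(segs), vapply(segs, function(s) length(s$flow), 1L))
  n <- length(flow)
  new_trace((seq_len(n) - 1L) / fs, flow, paw, event, phase, fs)
}

#' Construct a fully specified one-breath derecruitment record
#'
#' Builds a synthetic trace encoding a worked R/I example directly: tidal
#' ventilation with occlusions at the low PEEP such that the measured
#' respiratory-system compliance equals `c_rs_low`, followed by a one-breath
#' derecruitment maneuver from `peep_high` to `peep_low` with the stated
#' total exhaled volume. Running [segment_breaths()], [compute_mechanics()]
#' and [derecruitment_ri()] on the result reproduces the R/I equation chain
#' from first principles.
#'
#' @param vt tidal volume, ml.
#' @param peep_low,peep_high the PEEP step, cmH2O.
#' @param c_rs_low respiratory-system compliance at the low PEEP, ml/cmH2O.
#' @param exhaled_volume total exhaled volume of the maneuver, ml.
#' @param resistance airway resistance, cmH2O/(L/s).
#' @param sample_rate sampling rate, Hz.
#' @return a `vent_trace`.
#' @export
one_breath_maneuver_trace <- function(vt, peep_low, peep_high, c_rs_low,
                                      exhaled_volume, resistance = 10,
                                      sample_rate = 200) {
  fs <- sample_rate
  lowp <- build_phase(fs, vt, 25, 0.5, peep_low, c_rs_low, resistance)
  # inflate at the high PEEP assuming an unchanged compliance, then the
  # prolonged expiration back at the low PEEP
  man <- build_derecruitment(fs, vt, 25, 6, 0.5, peep_high, peep_low,
                             c_rs_low, resistance, exhaled_volume)
  segs <- list(low = lowp, maneuver = man)
  flow <- unlist(lapply(segs, `[[`, "flow"), use.names = FALSE)
  paw <- unlist(lapply(segs, `[[`, "paw"), use.names = FALSE)
  event <- unlist(lapply(segs, `[[`, "event"), use.names = FALSE)
  phase <- rep(names(segs), vapply(segs, function(s) length(s$flow), 1L))
  new_trace((seq_along(flow) - 1L) / fs, flow, paw, event, phase, fs)
}

#' Read / write ventilator traces as CSV
#'
#' The on-disk schema is `time_s,flow_lps,paw_cmh2o,event` with
#' `event` one of `none`, `insp_occlusion`, `exp_occlusion`,
#' `derecruitment`, `aop_breath`. Real waveform exports with the same
#' columns are accepted.
#'
#' @param trace a `vent_trace`.
#' @param path CSV file path.
#' @return `read_trace_csv` returns a `vent_trace`; `write_trace_csv`
#'   returns `path` invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace[, c("time_s", "flow_lps", "paw_cmh2o", "event")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "flow_lps", "paw_cmh2o")
  if (!all(need %in% names(d)))
    stop("trace CSV must have columns time_s, flow_lps, paw_cmh2o", call. = FALSE)
  if (is.null(d$event)) d$event <- "none"
  dt <- diff(d$time_s)
  if (any(dt <= 0)) stop("trace time must be strictly increasing", call. = FALSE)
  fs <- 1 / stats::median(dt)
  new_trace(d$time_s, d$flow_lps, d$paw_cmh2o, d$event,
            if (is.null(d$phase)) rep(NA_character_, nrow(d)) else d$phase,
            fs)
}
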