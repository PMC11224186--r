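# Waveform processing: segmentation, mechanics, stress index, ventilatory
# ratio, AOP detection, derecruitment R/I chain.

test_that("breath segmentation finds constructed onsets and rejects silence", {
  tr <- flat_trace(n_breaths = 3)
  seg <- segment_breaths(tr)
  expect_equal(nrow(seg$breaths), 3L)
  n_one <- nrow(tr) / 3
  expect_equal(seg$breaths$onset, 200 + 1 + n_one * 0:2)

  silent <- flat_trace(flow_plateau = 0)
  expect_error(segment_breaths(silent), "no breaths")
})

test_that("a labelled derecruitment breath is flagged regardless of duration", {
  tr <- flat_trace(n_breaths = 3)
  i <- which(tr$flow_lps == 0 & tr$time_s > 2.0)[1:50]
  tr$event[i] <- "derecruitment"
  seg <- segment_breaths(tr)
  expect_equal(sum(seg$breaths$type == "derecruitment"), 1L)
})

test_that("mechanics reads VT, plateau, total PEEP and derived quantities", {
  # square flow 0.5 L/s for 1.0 s -> VT 500 ml
  tr <- flat_trace(flow_plateau = 0.5, ti = 1.0, occlusions = TRUE,
                   peep = 5, p_plat = 14, peep_tot = 5)
  mech <- compute_mechanics(tr, segment_breaths(tr), peep_set = 5)
  expect_equal(mech$vt, 500, tolerance = 1e-9)
  expect_equal(mech$p_plat, 14)
  expect_equal(mech$peep_tot, 5)
  expect_equal(mech$peep_i, 0)
  expect_equal(mech$driving_pressure, 9)
  expect_equal(mech$c_rs, 500 / 9)

  # p_plat 29, peep_tot 20, vt 320 -> dP 9 and C_RS 35.6 ml/cmH2O
  tr2 <- flat_trace(flow_plateau = 0.4, ti = 0.8, occlusions = TRUE,
                    peep = 20, p_plat = 29, peep_tot = 20)
  m2 <- compute_mechanics(tr2, segment_breaths(tr2), peep_set = 20)
  expect_equal(m2$vt, 320, tolerance = 1e-9)
  expect_equal(m2$driving_pressure, 9)
  expect_equal(m2$c_rs, 35.6, tolerance = 0.01)

  # intrinsic PEEP: set 5, occluded end-expiratory pressure 7 -> PEEPi 2
  tr3 <- flat_trace(occlusions = TRUE, peep = 5, p_plat = 16, peep_tot = 7)
  m3 <- compute_mechanics(tr3, segment_breaths(tr3), peep_set = 5)
  expect_equal(m3$peep_i, 2)
  expect_equal(m3$peep_tot, 7)

  # no occlusions -> mechanics unavailable
  expect_error(compute_mechanics(flat_trace(), segment_breaths(flat_trace()), 5),
               "occlusion")
})

test_that("stress index recovers the power-law exponent", {
  tr1 <- flat_trace(b = 1)
  expect_equal(stress_index(tr1, segment_breaths(tr1)), 1.0, tolerance = 1e-3)

  tr13 <- flat_trace(b = 1.3)
  expect_equal(stress_index(tr13, segment_breaths(tr13)), 1.3, tolerance = 0.01)

  set.seed(2)
  tr09 <- flat_trace(b = 0.9, noise_sd = 0.2)
  expect_equal(stress_index(tr09, segment_breaths(tr09)), 0.9, tolerance = 0.05)

  short <- flat_trace(ti = 0.08)
  expect_error(stress_index(short, segment_breaths(short)), "20 samples")
})

test_that("ventilatory ratio follows the standard normalisation", {
  mech <- list(vt = 470)  # pbw 47 kg -> minute ventilation 4700 = pbw*100
  vr <- ventilatory_ratio(mech, rr = 10, gas = blood_gas(paco2 = 37.5),
                          subject = subject_info(pbw = 47))
  expect_equal(vr, 1.0)
  vr2 <- ventilatory_ratio(list(vt = 320), rr = 25,
                           gas = blood_gas(paco2 = 57),
                           subject = subject_info(pbw = 47))
  expect_equal(vr2, 456000 / 176250, tolerance = 1e-12)
  expect_equal(vr2, 2.59, tolerance = 0.005)
  expect_error(blood_gas(paco2 = 0), "paco2")
  expect_error(ventilatory_ratio(list(vt = 320), 25,
                                 list(paco2 = -1), subject_info(47)),
               "PaCO2")
})

aop_pv_trace <- function(v_break_frac, aop = 8, peep = 5, vt = 16,
                         slope2 = 1 / 2, fs = 200, flow = 0.008) {
  # hand-built low-flow inflation: slope break at v_break_frac of VT
  n <- round((vt / 1000) / flow * fs)
  v <- (0:n) / fs * flow * 1000
  vb <- v_break_frac * vt
  slope1 <- (aop - peep) / vb
  paw <- ifelse(v <= vb, peep + slope1 * v, aop + slope2 * (v - vb))
  fl <- c(rep(0, fs), rep(flow, n + 1L), rep(0, fs))
  p <- c(rep(peep, fs), paw, rep(peep, fs))
  ev <- c(rep("none", fs), rep("aop_breath", n + 1L), rep("none", fs))
  tr <- data.frame(time_s = (seq_along(fl) - 1) / fs, flow_lps = fl,
                   paw_cmh2o = p, event = ev, phase = NA_character_)
  attr(tr, "sample_rate") <- fs
  class(tr) <- c("vent_trace", "data.frame")
  tr
}

test_that("AOP detection recovers constructed breakpoints and applies gates", {
  # closure at 8 cmH2O at 10% of VT with slope ratio 5
  tr <- aop_pv_trace(v_break_frac = 0.10, aop = 8, slope2 = (8 - 5) / 1.6 / 5)
  res <- detect_aop(tr, segment_breaths(tr), peep_low = 5)
  expect_true(res$present)
  expect_equal(res$aop, 8, tolerance = 0.5)
  expect_gte(res$slope_ratio, 3)

  # single-slope curve: no breakpoint
  tr1 <- aop_pv_trace(v_break_frac = 1e-9, aop = 5 + 1e-9)
  res1 <- detect_aop(tr1, segment_breaths(tr1), peep_low = 5)
  expect_false(res1$present)

  # breakpoint at 40% of VT: rejected by the early-volume rule
  tr40 <- aop_pv_trace(v_break_frac = 0.40, aop = 8, slope2 = 0.1)
  res40 <- detect_aop(tr40, segment_breaths(tr40), peep_low = 5)
  expect_false(res40$present)

  # no low-flow breath at all
  trn <- flat_trace()
  expect_error(detect_aop(trn, segment_breaths(trn), 5), "low-flow")
})

test_that("the derecruitment equation chain reproduces worked examples", {
  # exhaled 950, VT 350, C_RS,low 30, PEEP 15 -> 5
  tr <- one_breath_maneuver_trace(vt = 350, peep_low = 5, peep_high = 15,
                                  c_rs_low = 30, exhaled_volume = 950)
  seg <- segment_breaths(tr)
  mech <- compute_mechanics(tr, seg, 5)
  expect_equal(mech$c_rs, 30, tolerance = 0.01)
  dr <- derecruitment_ri(tr, seg, mech, 15, 5)
  expect_equal(dr$delta_eelv, 600, tolerance = 1e-3)
  expect_equal(dr$inflation_volume, 300, tolerance = 1e-3)
  expect_equal(dr$v_rec, 300, tolerance = 1e-2)
  expect_equal(dr$c_rec, 30, tolerance = 1e-2)
  expect_equal(dr$ri, 1.0, tolerance = 0.005)

  # exhaled equals VT: zero volume change, R/I = -1, flagged non-recruiter
  tr0 <- one_breath_maneuver_trace(vt = 350, peep_low = 5, peep_high = 15,
                                   c_rs_low = 30, exhaled_volume = 350)
  seg0 <- segment_breaths(tr0)
  dr0 <- derecruitment_ri(tr0, seg0, compute_mechanics(tr0, seg0, 5), 15, 5)
  expect_equal(dr0$delta_eelv, 0, tolerance = 0.5)
  expect_equal(dr0$v_rec, -dr0$inflation_volume, tolerance = 1e-2)
  expect_equal(dr0$ri, -1.0, tolerance = 0.005)
  expect_true("non_recruiter_negative" %in% dr0$flags)

  # an AOP shrinks both denominators to (PEEP_high - AOP)
  aop <- structure(list(present = TRUE, aop = 8, breakpoint_volume = 1,
                        slope_ratio = 5), class = "aop_result")
  dra <- derecruitment_ri(tr, seg, mech, 15, 5, aop = aop)
  expect_equal(dra$effective_low_pressure, 8)
  expect_equal(dra$inflation_volume, mech$c_rs * 7, tolerance = 0.1)
  expect_equal(dra$c_rec, dra$v_rec / 7, tolerance = 1e-9)
  expect_error(derecruitment_ri(tr, seg, mech, 15, 15), "exceed")
})

test_that("the R/I identity chain holds to machine precision", {
  for (ex in list(c(850, 400), c(950, 350), c(350, 350), c(600, 400))) {
    tr <- one_breath_maneuver_trace(vt = ex[2], peep_low = 5, peep_high = 15,
                                    c_rs_low = 30, exhaled_volume = ex[1])
    seg <- segment_breaths(tr)
    mech <- compute_mechanics(tr, seg, 5)
    dr <- derecruitment_ri(tr, seg, mech, 15, 5)
    lhs <- dr$ri * dr$c_rs_low * (15 - dr$effective_low_pressure) +
      dr$inflation_volume + dr$vt
    expect_equal(lhs, dr$exhaled_volume, tolerance = 1e-9)
  }
})
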