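# Phantom generator: unit model, CT rendering, trace synthesis, ground truth.

test_that("unit generation is deterministic and obeys the threshold model", {
  cfg <- phantom_config(seed = 42L, closing_offset = 4)
  u1 <- generate_units(cfg)
  u2 <- generate_units(cfg)
  expect_identical(u1, u2)
  expect_equal(sum(u1$weight), cfg$weight_total)
  expect_true(all(u1$weight > 0))
  expect_true(all(u1$opening_pressure >= 0))
  expect_equal(u1$closing_pressure, pmax(u1$opening_pressure - 4, 0))

  # law of large numbers on the opening-pressure mean at n = 10000
  big <- phantom_config(n_units = 10000L, opening_mu = 15, opening_sd = 5,
                        grid_shape = c(32L, 64L, 64L), seed = 7L)
  ub <- generate_units(big)
  expect_lt(abs(mean(ub$opening_pressure) - 15), 0.2)

  expect_error(phantom_config(n_units = 0), "n_units")
  expect_error(phantom_config(weight_total = -1), "weight_total")
  expect_error(phantom_config(n_units = 100, grid_shape = c(2, 2, 2)),
               "grid voxel count")
})

test_that("rendering maps gas fraction linearly to HU", {
  # two units: one closed (pure tissue, HU 0), one open at gas fraction 0.5
  units <- data.frame(
    weight = c(0.5, 0.5),
    opening_pressure = c(100, 0),   # first never opens
    closing_pressure = c(96, 0),
    specific_compliance = c(0, 0),
    resting_gas = c(0, 1))          # open unit: 1 ml/g gas = gas fraction 0.5
  class(units) <- c("lung_units", "data.frame")
  cfg <- small_config(n_units = 2L, weight_total = 1)
  ph <- render_ct_pair(units, cfg, peep = 5, plateau = 10)
  hu <- ph$exp$volume$hu[ph$exp$mask]
  n1 <- ph$exp$unit_voxels[1]
  expect_true(all(hu[seq_len(n1)] == 0))              # closed unit: tissue
  expect_true(all(hu[(n1 + 1):length(hu)] == -500))   # gas fraction 0.5
})

test_that("phantom mass is conserved across PEEP and EELV is monotone", {
  cfg <- small_config(seed = 5L)
  units <- generate_units(cfg)
  masses <- c()
  eelv <- c()
  for (peep in c(0, 5, 10, 15)) {
    r <- render_ct_pair(units, cfg, peep = peep, plateau = 30)
    s <- summarize_compartments(r$exp$volume, r$exp$mask)
    masses <- c(masses, s$total_weight_g)
    eelv <- c(eelv, s$total_gas_ml)
  }
  expect_true(all(abs(masses - cfg$weight_total) / cfg$weight_total < 0.002))
  expect_true(all(diff(eelv) >= 0))
})

test_that("noiseless round-trip recovers generator totals within quantisation", {
  cfg <- small_config(seed = 9L)
  units <- generate_units(cfg)
  truth <- export_ground_truth(units, small_protocol(), cfg)
  r <- render_ct_pair(units, cfg, peep = 5, plateau = truth$plateau_low)
  s <- summarize_compartments(r$exp$volume, r$exp$mask)
  expect_lt(abs(s$total_weight_g - cfg$weight_total) / cfg$weight_total, 0.002)
  expect_lt(abs(s$total_gas_ml - truth$true_eelv_low) /
              max(truth$true_eelv_low, 1), 0.005)
})

test_that("ground truth flags degenerate and fully open lungs", {
  cfg <- small_config(seed = 3L)
  units <- generate_units(cfg)
  pr_eq <- small_protocol(peep_low = 5, peep_high = 5)
  tr <- export_ground_truth(units, pr_eq, cfg)
  expect_equal(tr$true_t_rec, 0)
  expect_equal(tr$true_gas_rec, 0)
  expect_true("ri_undefined" %in% tr$flags)
  expect_true(is.na(tr$true_ri))

  # everything already open below the low PEEP: nothing to recruit
  open_cfg <- small_config(opening_mu = 0, opening_sd = 0,
                           closing_offset = 0, seed = 3L)
  uo <- generate_units(open_cfg)
  tro <- export_ground_truth(uo, small_protocol(), open_cfg)
  expect_equal(tro$true_t_rec, 0)
  expect_true("fully_open" %in% tro$flags)
  expect_lte(tro$true_ri, 0 + 1e-9)
})

test_that("trace simulation is deterministic and encodes the maneuvers", {
  cfg <- small_config(seed = 21L)
  units <- generate_units(cfg)
  pr <- vent_protocol()
  t1 <- simulate_traces(units, pr)
  t2 <- simulate_traces(units, pr)
  expect_identical(t1, t2)
  expect_setequal(setdiff(unique(t1$event), "none"),
                  c("insp_occlusion", "exp_occlusion", "derecruitment",
                    "aop_breath"))
  expect_error(simulate_traces(units, vent_protocol(maneuvers = character(0))),
               "maneuver")
})

test_that("single-compartment occluded plateau equals PEEP + VT/C", {
  # one always-open unit with aggregate compliance 30 ml/cmH2O, VT 300 ml:
  # elastic pressure 10 cmH2O above PEEP
  units <- data.frame(weight = 100, opening_pressure = 0,
                      closing_pressure = 0, specific_compliance = 0.3,
                      resting_gas = 1)
  class(units) <- c("lung_units", "data.frame")
  pr <- vent_protocol(vt = 300, peep_low = 5, peep_high = 15,
                      resistance = 10,
                      maneuvers = c("occlusions", "derecruitment"))
  trc <- simulate_traces(units, pr)
  seg <- segment_breaths(trc)
  mech <- compute_mechanics(trc, seg, 5)
  expect_equal(mech$p_plat, 5 + 300 / 30, tolerance = 0.01)
  expect_equal(mech$c_rs, 30, tolerance = 0.01)

  # no recruitment: derecruitment exhaled volume is VT + C * dPEEP
  dr <- derecruitment_ri(trc, seg, mech, 15, 5)
  expect_equal(dr$exhaled_volume, 300 + 30 * 10, tolerance = 0.01)
  expect_equal(dr$ri, 0, tolerance = 0.01)
})

test_that("measured R/I recovers the ground truth on the default phantom", {
  cfg <- phantom_config(hu_noise_sd = 0, seed = 17L)
  pr <- vent_protocol()
  ph <- simulate_phantom(cfg, pr)
  seg <- segment_breaths(ph$trace)
  mech <- compute_mechanics(ph$trace, seg, pr$peep_low)
  dr <- derecruitment_ri(ph$trace, seg, mech, pr$peep_high, pr$peep_low)
  expect_equal(dr$ri, ph$truth$true_ri, tolerance = 0.1)
})

test_that("simulated phantoms are reproducible end to end", {
  cfg <- small_config(seed = 31L, hu_noise_sd = 30)
  pr <- small_protocol()
  a <- simulate_phantom(cfg, pr)
  b <- simulate_phantom(cfg, pr)
  expect_identical(a$ct$low$exp$volume$hu, b$ct$low$exp$volume$hu)
  expect_identical(a$trace, b$trace)
  expect_identical(unclass(a$truth), unclass(b$truth))
})
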