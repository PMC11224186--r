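# Quantitative CT: gas/tissue decomposition, compartments, recruitment.

test_that("voxel decomposition follows the linear mixture rule", {
  # voxel volume 0.35 mm^2 * 5 mm = 1.75 mm^3 = 0.00175 ml
  v <- hu_volume(c(-1000, 0, -500, 100))
  d <- decompose_voxels(v, full_mask(v))
  expect_equal(d$voxel_volume_ml, 0.00175)
  expect_equal(d$gas_ml, c(0.00175, 0, 0.000875, 0))
  expect_equal(d$tissue_g, c(0, 0.00175, 0.000875, 0.001925))
})

test_that("gas and tissue volume sum to the voxel volume for mixture voxels", {
  set.seed(1)
  hu <- sample(-1000:0, 500, replace = TRUE)
  v <- hu_volume(hu)
  d <- decompose_voxels(v, full_mask(v))
  expect_equal(d$gas_ml + d$tissue_g, rep(0.00175, 500), tolerance = 1e-12)
})

test_that("masked voxels above +100 HU are kept as nonaerated with a warning", {
  v <- hu_volume(c(-500, 300))
  expect_warning(d <- decompose_voxels(v, full_mask(v)), "\\+100 HU")
  expect_equal(d$tissue_g[2], 0.00175 * 1.1)
  s <- suppressWarnings(summarize_compartments(v, full_mask(v)))
  expect_equal(s$total_weight_g, 0.000875 + 0.001925)
  expect_equal(comp_weight(s, "nonaerated"), 0.001925)
})

test_that("compartment bin edges match the printed HU ranges", {
  edges <- c(-1000, -950, -901, -900, -501, -500, -101, -100, 0, 100)
  expected <- c("hyperinflated", "hyperinflated", "hyperinflated",
                "normally", "normally", "poorly", "poorly",
                "nonaerated", "nonaerated", "nonaerated")
  v <- hu_volume(edges)
  s <- summarize_compartments(v, full_mask(v))
  for (comp in unique(expected)) {
    idx <- expected == comp
    # tissue weight per voxel is voxvol * (1 + HU/1000) over the whole
    # [-1000, +100] range (mixture below 0, dense extrapolation above)
    expect_equal(comp_weight(s, comp),
                 sum(0.00175 * (1 + edges[idx] / 1000)),
                 tolerance = 1e-12, label = comp)
  }
})

test_that("single-bin volume puts all weight and gas in that compartment", {
  v <- hu_volume(rep(-950, 64))
  s <- summarize_compartments(v, full_mask(v))
  expect_equal(comp_weight(s, "hyperinflated"), s$total_weight_g)
  expect_equal(s$table$gas_ml[s$table$compartment == "hyperinflated"],
               s$total_gas_ml)
})

test_that("vectorised summaries equal the per-voxel reference loop", {
  set.seed(11)
  arr <- array(sample(-1024:150, 20 * 20 * 5, replace = TRUE), c(20L, 20L, 5L))
  vol <- ct_volume(arr, pixel_area = 0.35, slice_thickness = 5)
  mask <- array(stats::runif(prod(dim(arr))) < 0.8, dim = dim(arr))
  ref <- loop_compartments(vol, mask)
  s <- suppressWarnings(summarize_compartments(vol, mask))
  for (comp in names(ref$weight)) {
    expect_equal(comp_weight(s, comp), unname(ref$weight[comp]),
                 tolerance = 1e-12, label = paste(comp, "weight"))
    expect_equal(s$table$gas_ml[s$table$compartment == comp],
                 unname(ref$gas[comp]), tolerance = 1e-12,
                 label = paste(comp, "gas"))
  }
  # additivity: compartments sum to the whole-lung totals
  expect_equal(sum(ref$weight), s$total_weight_g, tolerance = 1e-12)
  expect_equal(sum(ref$gas), s$total_gas_ml, tolerance = 1e-12)
})

test_that("mask handling errors are explicit", {
  v <- hu_volume(c(-500, -500))
  expect_error(summarize_compartments(v, array(FALSE, dim(v$hu))), "empty")
  expect_error(summarize_compartments(v, array(TRUE, c(1, 1, 3))), "shape")
})

test_that("recruitment arithmetic follows the subtraction/product chain", {
  low <- fake_summary(weights = c(2, 300, 298, 400), gas = c(5, 500, 150, 21),
                      peep_label = "low")
  high <- fake_summary(weights = c(3, 552, 295, 150), gas = c(14, 1400, 160, 5),
                       peep_label = "high")
  # end-expiratory PEEP_HIGH volume with a known voxelwise g/t structure
  vol_high <- hu_volume(rep(-615, 100), peep_label = "high")  # g/t 615/385
  rec <- compute_recruitment(low, high, vol_high, full_mask(vol_high))
  expect_equal(rec$t_rec, 250)
  expect_equal(rec$t_rec_alt, (400 + 298) - (150 + 295))
  expect_equal(rec$gt_median_high, 615 / 385, tolerance = 1e-12)
  expect_equal(rec$gas_rec, rec$t_rec * rec$gt_median_high)  # exact identity
  expect_equal(rec$gas_rec, 400, tolerance = 0.03 * 400)     # ~1.6 * 250
  expect_equal(rec$normalized_t_rec, 250 / 1000)
  expect_equal(rec$normalized_gas_rec, rec$gas_rec / 676)
  expect_equal(rec$delta_hyperinflated_gas, 14 - 5)
  expect_length(rec$flags, 0)
})

test_that("identical volumes give zero recruitment; negatives propagate flagged", {
  s <- fake_summary(weights = c(1, 300, 300, 400), gas = c(3, 500, 150, 20))
  vol <- hu_volume(rep(-500, 50), peep_label = "high")
  rec <- compute_recruitment(s, s, vol, full_mask(vol))
  expect_equal(rec$t_rec, 0)
  expect_equal(rec$gas_rec, 0)
  expect_equal(rec$delta_hyperinflated_gas, 0)

  worse <- fake_summary(weights = c(1, 250, 300, 450), gas = c(3, 400, 150, 25),
                        peep_label = "high")
  rec2 <- compute_recruitment(s, worse, vol, full_mask(vol))
  expect_lt(rec2$t_rec, 0)
  expect_lt(rec2$gas_rec, 0)
  expect_true("derecruitment_negative" %in% rec2$flags)
})

test_that("phase guards and gt_mode variants behave", {
  s_exp <- fake_summary(weights = c(1, 2, 3, 4), gas = c(1, 2, 3, 4))
  s_insp <- fake_summary(weights = c(1, 2, 3, 4), gas = c(1, 2, 3, 4),
                         phase = "end_inspiration")
  vol <- hu_volume(rep(-500, 10))
  expect_error(compute_recruitment(s_exp, s_insp, vol, full_mask(vol)),
               "end-expir")
  # whole-lung ratio: total gas / total tissue of the high volume
  set.seed(4)
  hu <- sample(seq(-900, -100, by = 50), 64, replace = TRUE)
  volh <- hu_volume(hu, peep_label = "high")
  d <- decompose_voxels(volh, full_mask(volh))
  rec <- compute_recruitment(s_exp, s_exp, volh, full_mask(volh),
                             gt_mode = "whole_lung_ratio")
  expect_equal(rec$gt_median_high, sum(d$gas_ml) / sum(d$tissue_g),
               tolerance = 1e-12)
})

test_that("noiseless phantom recruitment matches truth within 2%", {
  cfg <- small_config(seed = 13L, opening_mu = 8)
  pr <- small_protocol()
  ph <- simulate_phantom(cfg, pr)
  sl <- summarize_compartments(ph$ct$low$exp$volume, ph$ct$low$exp$mask)
  sh <- summarize_compartments(ph$ct$high$exp$volume, ph$ct$high$exp$mask)
  rec <- compute_recruitment(sl, sh, ph$ct$high$exp$volume, ph$ct$high$exp$mask)
  expect_equal(rec$t_rec, ph$truth$true_t_rec,
               tolerance = 0.02 * ph$truth$true_t_rec)
})
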