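test_that("cohort generation is deterministic in the seed", {
  cfg <- synthetic_config(n_patients = 8, seed = 77)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  other <- generate_cohort(synthetic_config(n_patients = 8, seed = 78))
  expect_false(identical(generate_cohort(cfg)$mean_adc, other$mean_adc))
})

test_that("config validation rejects impossible settings", {
  expect_error(synthetic_config(), "seed")
  expect_error(synthetic_config(motion_fraction = 1.5, seed = 1), "motion_fraction")
  expect_error(synthetic_config(adc_range = c(100, 50), seed = 1), "adc_range")
  expect_error(synthetic_config(n_voxel_range = c(0, 10), seed = 1),
               "n_voxel_range")
})

test_that("zero-noise cohorts have exactly zero repeatability", {
  cfg <- synthetic_config(n_patients = 6, beta = 0, sigma_fix = 0,
                          epsilon_sys = 0, motion_fraction = 0,
                          vol_jitter = 0, seed = 9)
  recs <- make_records(cfg)
  expect_equal(recs$r12, rep(0, nrow(recs)))
  expect_equal(recs$delta_vol_pct, rep(0, nrow(recs)))
})

test_that("systematic-error-only cohorts reproduce the configured spread", {
  # beta irrelevant with w_bio = 0; sigma_fix = 0: SD(R12) ~ epsilon_sys
  cfg <- synthetic_config(n_patients = 5000, roi_kinds = "whole_3d",
                          w_bio_range = c(0, 0), sigma_fix = 0, beta = 0,
                          epsilon_sys = 5, motion_fraction = 0, seed = 13)
  recs <- make_records(cfg)
  expect_gt(nrow(recs), 4999)
  expect_lt(abs(sd(recs$r12) - 5) / 5, 0.05)
})

test_that("cohort marginals match the configuration", {
  cfg <- synthetic_config(n_patients = 300, seed = 17)
  cohort <- generate_cohort(cfg)
  tum <- cohort[cohort$roi_kind != "parenchyma", ]
  expect_true(all(tum$n_voxels >= 50 & tum$n_voxels <= 20000))
  expect_true(mean(tum$n_voxels < 1000) > 0.3)   # log-uniform, not uniform
  expect_true(all(cohort$mean_adc > 0))
  par <- cohort[cohort$roi_kind == "parenchyma", ]
  expect_true(all(par$n_voxels == cfg$parenchyma_voxels))
  # motion fraction within binomial error of 25% of patients
  pairs <- pair_sessions(cohort, quiet = TRUE)
  frac <- mean(tapply(pairs$motion, pairs$patient_id, any))
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / 300))
})

test_that("standardising with the true parameters gives normal residuals", {
  cfg <- no_motion_config(seed = 23, n_patients = 300)
  std <- standardise(make_records(cfg), study_params())
  expect_gt(stats::ks.test(std$z, "pnorm")$p.value, 0.01)
})

test_that("noiseless phantoms recover per-voxel ADC exactly end to end", {
  ph <- generate_dwi_phantom(noise_sigma = 0, seed = 3)
  m <- adc_map(ph$signals, ph$b_values)
  expect_true(all(m$valid))
  expect_equal(m$adc, ph$adc_true, tolerance = 1e-8)
  s <- summarise_roi(m, ph$mask)
  expect_equal(s$n_voxels, sum(ph$mask))
  expect_equal(s$mean_adc, mean(ph$adc_true[ph$mask]), tolerance = 1e-8)
})

test_that("noisy phantom ROI mean lands within sampling error of truth", {
  ph <- generate_dwi_phantom(dims = c(40, 40, 16), lesion_radius = c(12, 12, 6),
                             lesion_mean = 109, lesion_sd = 20,
                             noise_sigma = 5, seed = 29)
  m <- adc_map(ph$signals, ph$b_values, noise_sigma = ph$noise_sigma)
  s <- summarise_roi(m, ph$mask)
  expect_gt(s$n_voxels, 2000)
  expect_lt(abs(s$mean_adc - 109), 3 * s$adc_sd / sqrt(s$n_voxels) + 1)
})

test_that("phantom geometry is validated", {
  expect_error(generate_dwi_phantom(dims = c(10, 10, 4),
                                    lesion_radius = c(8, 8, 3)), "fit")
  expect_error(generate_dwi_phantom(s0 = -1), "s0")
  expect_error(generate_dwi_phantom(noise_sigma = -1), "noise_sigma")
})

test_that("recovery studies summarise per-replicate fits against truth", {
  cfg <- no_motion_config(seed = 37, n_patients = 10)
  rs <- recovery_study(cfg, n_replicates = 2, n_starts = 4)
  expect_equal(nrow(rs), 2L)
  expect_false(any(rs$failed))
  smry <- attr(rs, "summary")
  expect_equal(smry$term, c("beta", "sigma_fix", "epsilon_sys"))
  expect_equal(smry$truth, c(4.87, 69.35, 2.65))
  rs1 <- recovery_study(cfg, n_replicates = 1, n_starts = 2)
  expect_equal(nrow(rs1), 1L)
})
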