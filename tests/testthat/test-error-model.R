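test_that("error propagation matches its closed forms", {
  expect_equal(propagate_error(100, 120, 0, 0), 0)
  # symmetric case: 100*sqrt(2)*sigma/D
  expect_equal(propagate_error(100, 100, 1, 1), 100 * sqrt(2) / 100,
               tolerance = 1e-12)
  expect_equal(propagate_error(109, 109, 2.5, 2.5),
               100 * sqrt(2) * 2.5 / 109, tolerance = 1e-12)
  # homogeneity of degree zero
  set.seed(3)
  for (i in 1:20) {
    d1 <- runif(1, 50, 200); d2 <- runif(1, 50, 200)
    s1 <- runif(1, 0, 5); s2 <- runif(1, 0, 5); c_ <- runif(1, 0.1, 10)
    expect_equal(propagate_error(c_ * d1, c_ * d2, c_ * s1, c_ * s2),
                 propagate_error(d1, d2, s1, s2), tolerance = 1e-12)
  }
  expect_error(propagate_error(0, 0, 1, 1), "d1 \\+ d2")
  expect_error(propagate_error(100, 100, -1, 0), ">= 0")
})

test_that("parameter container enforces variant consistency", {
  p <- error_model_params(4.87, 69.35, 2.65)
  expect_s3_class(p, "error_model_params")
  expect_equal(tidy(p)$estimate, c(4.87, 69.35, 2.65))
  expect_error(error_model_params(1, 0, 2, variant = "sys_only"), "sys_only")
  expect_error(error_model_params(1, 5, 2, variant = "two_param"), "two_param")
  expect_error(error_model_params(-1, 0, 0), "beta")
})

test_that("total uncertainty combines the three terms in quadrature", {
  params <- study_params()
  pair <- symmetric_pair(d = 109, w = 50, n = 2000)
  eps <- total_uncertainty(pair, params)
  # independent hand evaluation via the symmetric-case closed form
  d <- 109; w <- 50; n <- 2000
  t_width <- params$beta * 100 * sqrt(2) * (w / sqrt(n)) / d
  t_fix <- 100 * sqrt(2) * (params$sigma_fix / sqrt(n)) / d
  expect_equal(eps, sqrt(t_width^2 + t_fix^2 + params$epsilon_sys^2),
               tolerance = 1e-12)
  # quadrature identity against the single-term models
  e_sys <- total_uncertainty(pair, error_model_params(0, 0, 2.65,
                                                      variant = "sys_only"))
  e_width <- total_uncertainty(pair, error_model_params(4.87, 0, 1e-12))
  e_fix <- total_uncertainty(pair, error_model_params(1e-12, 69.35, 1e-12))
  expect_equal(eps^2, e_width^2 + e_fix^2 + e_sys^2, tolerance = 1e-6)
})

test_that("limits and monotonicity of the uncertainty model hold", {
  params <- study_params()
  # sigma terms vanish -> epsilon_sys
  pair0 <- symmetric_pair(w = 0, n = 10000000)
  eps0 <- total_uncertainty(pair0, error_model_params(4.87, 0, 2.65))
  expect_equal(eps0, 2.65, tolerance = 1e-12)
  # with beta = 1, sigma_fix = 0, esys ~ 0, reduces to propagate_error on SEMs
  pair <- pair_sessions(tiny_roi_table())
  reduced <- total_uncertainty(pair, error_model_params(1, 0, 1e-15))
  direct <- propagate_error(pair$mean_adc_1, pair$mean_adc_2,
                            pair$sem_1, pair$sem_2)
  expect_equal(reduced, direct, tolerance = 1e-9)
  # decreasing in N at fixed everything else
  ns <- c(50, 200, 1000, 5000, 20000)
  eps_n <- vapply(ns, function(n)
    total_uncertainty(symmetric_pair(n = n), params), numeric(1))
  expect_true(all(diff(eps_n) < 0))
  # non-decreasing in each parameter and in w
  base <- total_uncertainty(symmetric_pair(), params)
  expect_gt(total_uncertainty(symmetric_pair(),
                              error_model_params(5.87, 69.35, 2.65)), base)
  expect_gt(total_uncertainty(symmetric_pair(),
                              error_model_params(4.87, 89.35, 2.65)), base)
  expect_gt(total_uncertainty(symmetric_pair(),
                              error_model_params(4.87, 69.35, 3.65)), base)
  expect_gt(total_uncertainty(symmetric_pair(w = 60), params), base)
  # all-zero model is rejected
  expect_error(total_uncertainty(symmetric_pair(w = 0),
                                 error_model_params(0, 0, 0)), "zero")
})

test_that("look-up grid agrees with direct evaluation and orders correctly", {
  params <- study_params()
  grid <- build_lookup(params, n_grid = c(100, 889, 1778, 2000, 10000),
                       sd_grid = c(10, 50), d_nominal = 109)
  # every cell equals a direct call
  expect_equal(grid$epsilon_pct,
               roi_uncertainty(grid$n_voxels, grid$adc_sd, params, 109))
  # wider histograms always mean more uncertainty (10-20 cm^3 band)
  band <- grid[grid$n_voxels %in% c(889, 1778), ]
  wide <- band$epsilon_pct[band$adc_sd == 50]
  narrow <- band$epsilon_pct[band$adc_sd == 10]
  expect_true(all(wide > narrow))
  # cells strictly decrease along N at fixed SD
  for (s in c(10, 50)) {
    col <- grid$epsilon_pct[grid$adc_sd == s][order(grid$n_voxels[grid$adc_sd == s])]
    expect_true(all(diff(col) < 0))
  }
  # huge N, tiny SD -> epsilon_sys
  lim <- build_lookup(params, n_grid = 1e8, sd_grid = 1e-6)
  expect_equal(lim$epsilon_pct, params$epsilon_sys, tolerance = 1e-4)
  expect_equal(grid$volume_cm3,
               voxels_to_volume(grid$n_voxels, units = "cm3"))
})

test_that("look-up grid exports wide CSV with metadata", {
  grid <- build_lookup(study_params(), n_grid = c(100, 1000),
                       sd_grid = c(10, 50))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_lookup(grid, csv, meta_path = js)
  wide <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(nrow(wide), 2L)
  expect_named(wide, c("n_voxels", "sd_10", "sd_50"))
  expect_equal(wide$sd_50[wide$n_voxels == 1000],
               roi_uncertainty(1000, 50, study_params()))
  meta <- jsonlite::read_json(js)
  expect_equal(meta$beta, 4.87)
  expect_equal(meta$d_nominal, 109)
})
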