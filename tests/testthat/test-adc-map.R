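test_that("noise-floor correction has the right identity/clamp behaviour", {
  expect_equal(correct_noise_floor(c(0, 5, 100), 0), c(0, 5, 100))
  # degenerate branch: signal^2 <= 2 sigma^2 clamps to the noise scale
  expect_equal(correct_noise_floor(12, 10), 10)
  # ... or to the signal itself when even that is smaller
  expect_equal(correct_noise_floor(5, 10), 5)
  expect_equal(correct_noise_floor(0, 10), 0)
  # never increases the signal, never negative; monotone in signal
  s <- seq(0, 50, by = 0.5)
  corr <- correct_noise_floor(s, 7)
  expect_true(all(corr <= s + 1e-15))
  expect_true(all(corr >= 0))
  expect_true(all(diff(corr) >= 0))
})

test_that("corrected magnitude is closer to the true amplitude (Rician MC)", {
  set.seed(101)
  sigma <- 10
  n <- 1e5
  for (a in c(1.5 * sigma, 5 * sigma)) {
    m <- sqrt((a + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
    corr <- correct_noise_floor(m, sigma)
    expect_lt(abs(mean(corr) - a), abs(mean(m) - a))
    # second-moment consistency: corrected power recovers the amplitude
    expect_lt(abs(sqrt(mean(corr^2)) - a), abs(sqrt(mean(m^2)) - a))
  }
})

test_that("mono-exponential fit is exact on noiseless decays", {
  b <- c(100, 500, 900)
  expect_equal(fit_adc(1000 * exp(-b * 109e-5), b), 109, tolerance = 1e-10)
  # any D >= 0 and any >= 2 distinct b-values
  set.seed(7)
  for (i in 1:20) {
    d <- runif(1, 0, 300)
    bs <- sort(sample(0:1200, sample(2:5, 1)))
    expect_equal(fit_adc(500 * exp(-bs * d * 1e-5), bs), d, tolerance = 1e-8)
  }
  expect_equal(fit_adc(c(800, 800, 800), b), 0, tolerance = 1e-12)
})

test_that("degenerate voxels are marked invalid, not errors", {
  b <- c(100, 500, 900)
  expect_true(is.na(fit_adc(c(0, 0, 0), b)))
  m <- adc_map(rbind(1000 * exp(-b * 100e-5), c(0, 0, 0)), b)
  expect_equal(m$valid, c(TRUE, FALSE))
  expect_true(is.na(m$adc[2]))
  expect_error(adc_map(matrix(1, 1, 2), c(500, 500)), "distinct")
})

test_that("noise-floor correction reduces ADC bias at low SNR", {
  # phantom in the noise-floor-dominated regime: SNR ~ 1.5 at b = 900
  # (at SNR >= 3 the log-linear fit is already nearly unbiased and the
  # correction has nothing to repair)
  set.seed(202)
  b <- c(100, 500, 900)
  d_true <- 109
  s0 <- 1000
  true_900 <- s0 * exp(-900 * d_true * 1e-5)   # ~ 375
  sigma <- true_900 / 1.5
  n <- 1e4
  clean <- matrix(s0 * exp(-rep(b, each = n) * d_true * 1e-5), nrow = n)
  noisy <- sqrt((clean + rnorm(3 * n, 0, sigma))^2 +
                  matrix(rnorm(3 * n, 0, sigma), nrow = n)^2)
  with_corr <- adc_map(noisy, b, noise_sigma = sigma)
  without <- adc_map(noisy, b, noise_sigma = 0)
  bias_with <- abs(mean(with_corr$adc[with_corr$valid]) - d_true)
  bias_without <- abs(mean(without$adc[without$valid]) - d_true)
  expect_lt(bias_with, bias_without)
})

test_that("ROI summaries match hand values and ignore voxel order", {
  map <- list(adc = c(100, 102, 120, NA), valid = c(TRUE, TRUE, TRUE, FALSE))
  s <- summarise_roi(map, mask = c(1L, 2L))
  expect_equal(s$mean_adc, 101)
  expect_equal(s$adc_sd, sqrt(2))
  expect_equal(s$n_voxels, 2L)
  # identical voxels: zero width
  s1 <- summarise_roi(list(adc = rep(7, 5), valid = rep(TRUE, 5)), mask = 1:5)
  expect_equal(s1$mean_adc, 7)
  expect_equal(s1$adc_sd, 0)
  # invalid voxels excluded; empty ROI is an explicit error
  s2 <- summarise_roi(map, mask = c(3L, 4L))
  expect_equal(s2$n_voxels, 1L)
  expect_error(summarise_roi(map, mask = 4L), "Empty ROI")
  # order invariance
  set.seed(11)
  vals <- rnorm(50, 109, 20)
  m1 <- list(adc = vals, valid = rep(TRUE, 50))
  m2 <- list(adc = rev(vals), valid = rep(TRUE, 50))
  expect_equal(summarise_roi(m1, 1:50)[, c("mean_adc", "adc_sd")],
               summarise_roi(m2, 1:50)[, c("mean_adc", "adc_sd")],
               ignore_attr = TRUE)
})

test_that("large-sample ROI mean is within sampling error of truth", {
  set.seed(33)
  vals <- rnorm(1e4, 109, 20)
  s <- summarise_roi(list(adc = vals, valid = rep(TRUE, 1e4)), mask = 1:1e4)
  expect_lt(abs(s$mean_adc - 109), 3 * 20 / sqrt(1e4))
})

test_that("voxel-to-volume conversion follows the acquisition geometry", {
  expect_equal(voxels_to_volume(1), 11.25)
  expect_equal(voxels_to_volume(2000, units = "cm3"), 22.5)
  expect_equal(voxels_to_volume(0), 0)
  expect_equal(voxels_to_volume(10, voxel_dims = c(1, 1, 1)), 10)
  expect_error(voxels_to_volume(-1), "non-negative")
})
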