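test_that("negative log-likelihood matches hand evaluation and is additive", {
  params <- error_model_params(0, 0, 5, variant = "sys_only")
  rec1 <- symmetric_pair(); rec1$r12 <- 0
  expect_equal(error_model_nll(rec1, params), log(5))
  rec2 <- symmetric_pair(); rec2$r12 <- 4
  # two records, closed-form hand evaluation: sum of log(5) + r^2/(2*25)
  both <- dplyr::bind_rows(rec1, rec2)
  expect_equal(error_model_nll(both, params),
               log(5) + (log(5) + 16 / 50), tolerance = 1e-12)
  # additivity
  expect_equal(error_model_nll(both, params),
               error_model_nll(rec1, params) + error_model_nll(rec2, params))
})

test_that("sys_only MLE equals the closed form sqrt(mean(r12^2))", {
  records <- make_records(no_motion_config(seed = 21))
  fit <- fit_error_model(records, variant = "sys_only", seed = 21)
  closed <- sqrt(mean(records$r12^2))
  expect_equal(fit$params$epsilon_sys, closed, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_equal(fit$params$beta, 0)
  expect_equal(fit$params$sigma_fix, 0)
})

test_that("fits are reproducible and respect motion exclusion counts", {
  cfg <- synthetic_config(n_patients = 12,
                          roi_kinds = roi_kinds(tumour_only = TRUE),
                          seed = 31)
  records <- make_records(cfg)
  f1 <- fit_error_model(records, seed = 5)
  f2 <- fit_error_model(records, seed = 5)
  expect_equal(tidy(f1), tidy(f2))
  expect_equal(f1$neg_log_likelihood, f2$neg_log_likelihood)
  expect_equal(f1$n_records_used + f1$n_excluded_motion, nrow(records))
  expect_equal(f1$n_excluded_motion, sum(records$motion))
  # all-motion input with exclusion is an insufficient-data error
  allm <- dplyr::mutate(records, motion = TRUE)
  expect_error(fit_error_model(allm), "Too few")
})

test_that("nested variants have ordered optimal likelihoods", {
  records <- make_records(no_motion_config(seed = 41))
  nll3 <- fit_error_model(records, "three_param", seed = 1)$neg_log_likelihood
  nll2 <- fit_error_model(records, "two_param", seed = 1)$neg_log_likelihood
  nll1 <- fit_error_model(records, "sys_only", seed = 1)$neg_log_likelihood
  expect_lte(nll3, nll2 + 1e-6)
  expect_lte(nll2, nll1 + 1e-6)
})

test_that("chi-squared statistic, dof and tail probability behave", {
  params <- error_model_params(0, 0, 5, variant = "sys_only")
  recs <- dplyr::bind_rows(lapply(1:6, function(i) symmetric_pair()))
  recs$r12 <- 0
  g0 <- chi_squared_gof(recs, params)
  expect_equal(g0$chi2, 0)
  expect_equal(g0$p_value, 1)
  expect_equal(g0$dof, 6L)
  # r12 = epsilon for every record -> chi2 = n
  recs$r12 <- 5
  gn <- chi_squared_gof(recs, params)
  expect_equal(gn$chi2, 6)
  expect_equal(gn$p_value, pchisq(6, 6, lower.tail = FALSE))
  expect_true(gn$accepted)
  # subset selection
  recs$roi_kind <- rep(c("whole_3d", "parenchyma"), 3)
  gsub <- chi_squared_gof(recs, params, roi_kind = "whole_3d")
  expect_equal(gsub$dof, 3L)
  expect_error(chi_squared_gof(recs, params, roi_kind = "slice_solid"),
               "No records")
})

test_that("standardisation divides by predicted uncertainty and keeps motion", {
  params <- study_params()
  records <- make_records(synthetic_config(n_patients = 10, seed = 51))
  std <- standardise(records, params)
  expect_equal(std$z, std$r12 / std$epsilon_r12)
  expect_true(all(std$epsilon_r12 > 0))
  expect_equal(sum(std$motion), sum(records$motion))   # flagged, not dropped
  # r12 = epsilon -> z = 1
  one <- symmetric_pair()
  one$r12 <- total_uncertainty(one, params)
  expect_equal(standardise(one, params)$z, 1)
  zs <- attr(std, "z_summary")
  expect_equal(zs$ci_width_95, 1.96 * group_summary(std$z)$sd)
})

test_that("standardised residuals of well-specified data are ~ N(0,1)", {
  set.seed(61)
  truth <- study_params()
  # big no-motion cohort, standardised with the true parameters
  records <- make_records(no_motion_config(seed = 61, n_patients = 400))
  std <- standardise(records, truth)
  expect_lt(abs(mean(std$z)), 0.1)
  expect_lt(abs(sd(std$z) - 1), 0.1)
  expect_gt(stats::ks.test(std$z, "pnorm")$p.value, 0.01)
})
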