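#' Negative log-likelihood of the error model
#'
#' Likelihood used for fitting: each repeatability value `r12` is an
#' independent zero-mean Gaussian whose standard deviation is the
#' model-predicted uncertainty of that pair,
#' \deqn{-\log L = \sum_i \left[\log \varepsilon_i +
#'   r_i^2 / (2 \varepsilon_i^2)\right]} (additive constants dropped).
#' Heteroscedastic by construction: small or heterogeneous ROIs are allowed
#' a larger spread than large homogeneous ones.
#'
#' @param records Repeatability records (see [repeatability()]) with an
#'   `r12` column.
#' @param params [error_model_params()] or fitted model.
#' @return Scalar negative log-likelihood.
#' @export
error_model_nll <- function(records, params) {
  check_pairs(records, require = c("r12"))
  eps <- total_uncertainty(records, params)
  sum(log(eps) + records$r12^2 / (2 * eps^2))
}

variant_free_params <- function(variant) {
  switch(variant,
         sys_only = "epsilon_sys",
         two_param = c("beta", "epsilon_sys"),
         three_param = c("beta", "sigma_fix", "epsilon_sys"),
         abort(sprintf("Unknown variant '%s'.", variant)))
}

params_from_vector <- function(theta, variant) {
  full <- c(beta = 0, sigma_fix = 0, epsilon_sys = 0)
  full[variant_free_params(variant)] <- theta
  error_model_params(full[["beta"]], full[["sigma_fix"]], full[["epsilon_sys"]],
                     variant = variant)
}

#' Fit the measurement-error model by maximum likelihood
#'
#' Minimises [error_model_nll()] over the free parameters of the requested
#' variant.  Positivity is enforced by optimising in log-parameter space.
#' The optimiser is a derivative-free Nelder-Mead search (Brent line search
#' for the one-parameter `sys_only` variant) launched from multiple seeded
#' starting points; the best optimum is kept, with ties (NLL within 1e-8)
#' broken by the smallest parameter-vector norm.  Pairs flagged as
#' motion-affected are excluded from fitting by default, because motion
#' corrupts the ADC map in a way the model cannot represent as a fixed
#' error; they can still be standardised against the fitted model
#' afterwards (see [standardise()]).
#'
#' @param records Repeatability records from [repeatability()].
#' @param variant `"three_param"` (default), `"two_param"` or `"sys_only"`.
#' @param exclude_motion Exclude motion-flagged pairs from the fit
#'   (default `TRUE`).
#' @param n_starts Number of optimiser starts, >= 1; default 8.
#' @param seed Integer seed controlling the random starts; the fit is
#'   reproducible given `(records, seed)`.
#' @return An object of class `adc_error_fit`: fitted `params`,
#'   `neg_log_likelihood`, `n_records_used`, `n_excluded_motion`,
#'   `converged`, a per-start `trace` tibble, and the input `records`.
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(seed = 7, motion_fraction = 0))
#' records <- repeatability(pair_sessions(cohort))
#' fit <- fit_error_model(records, seed = 7)
#' tidy(fit)
fit_error_model <- function(records, variant = c("three_param", "two_param", "sys_only"),
                            exclude_motion = TRUE, n_starts = 8, seed = 1L) {
  variant <- match.arg(variant)
  check_pairs(records, require = c("r12", "motion"))
  used <- if (exclude_motion) records[!records$motion, ] else records
  n_excluded <- nrow(records) - nrow(used)
  free <- variant_free_params(variant)
  if (nrow(used) < length(free) + 1) {
    abort(sprintf(
      "Too few records to fit '%s': %d available, need at least %d.",
      variant, nrow(used), length(free) + 1))
  }
  if (n_starts < 1) abort("`n_starts` must be >= 1.")

  objective <- function(log_theta) {
    p <- params_from_vector(exp(log_theta), variant)
    v <- tryCatch(error_model_nll(used, p), error = function(e) Inf)
    if (!is.finite(v)) Inf else v
  }

  rms <- sqrt(mean(used$r12^2))
  heuristic <- c(beta = 1, sigma_fix = 50, epsilon_sys = max(rms / 2, 0.1))
  starts <- with_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      if (i == 1) return(log(heuristic[free]))
      log(c(beta = exp(runif(1, log(0.2), log(20))),
            sigma_fix = exp(runif(1, log(1), log(500))),
            epsilon_sys = exp(runif(1, log(0.2), log(max(2 * rms, 1)))))[free])
    })
  })

  run_start <- function(st) {
    if (length(st) == 1) {
      o <- optim(st, objective, method = "Brent",
                 lower = log(1e-6), upper = log(1e4),
                 control = list(maxit = 1000))
    } else {
      o <- optim(st, objective, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-10))
    }
    list(par = o$par, value = o$value, convergence = o$convergence)
  }
  results <- lapply(starts, function(st) {
    tryCatch(run_start(st), error = function(e)
      list(par = st, value = Inf, convergence = 99L))
  })

  values <- vapply(results, `[[`, numeric(1), "value")
  if (all(!is.finite(values))) {
    abort("All optimiser starts failed to produce a finite likelihood.")
  }
  best_val <- min(values)
  tied <- which(values <= best_val + 1e-8)
  norms <- vapply(results[tied], function(r) sqrt(sum(exp(r$par)^2)), numeric(1))
  best <- results[[tied[which.min(norms)]]]

  trace <- tibble::tibble(
    start = seq_len(n_starts),
    nll = values,
    convergence = vapply(results, `[[`, numeric(1), "convergence"))
  est <- stats::setNames(exp(best$par), free)
  params <- params_from_vector(est, variant)

  structure(list(
    params = params,
    neg_log_likelihood = best$value,
    n_records_used = nrow(used),
    n_excluded_motion = n_excluded,
    converged = best$convergence == 0,
    trace = trace,
    seed = seed,
    variant = variant,
    records = records
  ), class = "adc_error_fit")
}

#' @export
print.adc_error_fit <- function(x, ...) {
  cat(sprintf("Error-model fit (%s), NLL = %.4f\n", x$variant,
              x$neg_log_likelihood))
  cat(sprintf("  records used: %d (motion excluded: %d); converged: %s\n",
              x$n_records_used, x$n_excluded_motion, x$converged))
  print(x$params)
  invisible(x)
}

#' Tidy / glance methods for fitted error models
#'
#' @param x An `adc_error_fit` object.
#' @param ... Unused.
#' @return `tidy()` returns one row per parameter (including fixed-at-zero
#'   parameters of nested variants); `glance()` a one-row model summary.
#' @export
tidy.adc_error_fit <- function(x, ...) {
  out <- tidy(x$params)
  out$free <- out$term %in% variant_free_params(x$variant)
  out
}

#' @rdname tidy.adc_error_fit
#' @export
glance.adc_error_fit <- function(x, ...) {
  tibble::tibble(variant = x$variant,
                 neg_log_likelihood = x$neg_log_likelihood,
                 n_records_used = x$n_records_used,
                 n_excluded_motion = x$n_excluded_motion,
                 converged = x$converged)
}

#' Chi-squared goodness of fit of the error model
#'
#' Tests whether the model-predicted uncertainties describe the observed
#' repeatability spread: \eqn{\chi^2 = \sum_i (r_i / \varepsilon_i)^2}
#' over the selected records, with degrees of freedom equal to the number
#' of records evaluated (the convention used when quoting the fit quality
#' per ROI subset) and an upper-tail p-value.  The model is reported as
#' accepted when p > 0.05.
#'
#' @param records Repeatability records.
#' @param params [error_model_params()] or fitted model.
#' @param roi_kind Optional ROI kind(s) to restrict to (see [roi_kinds()]).
#' @param include_motion Include motion-flagged records (default `TRUE`);
#'   motion typically inflates the statistic because it is not part of the
#'   model.
#' @return A one-row tibble: `chi2`, `dof`, `p_value`, `accepted`, `n_motion`.
#' @export
chi_squared_gof <- function(records, params, roi_kind = NULL,
                            include_motion = TRUE) {
  check_pairs(records, require = c("r12", "motion"))
  sel <- records
  if (!is.null(roi_kind)) sel <- sel[sel$roi_kind %in% roi_kind, ]
  if (!include_motion) sel <- sel[!sel$motion, ]
  if (nrow(sel) == 0) abort("No records in the requested subset.")
  z <- sel$r12 / total_uncertainty(sel, params)
  chi2 <- sum(z^2)
  dof <- nrow(sel)
  p <- pchisq(chi2, df = dof, lower.tail = FALSE)
  tibble::tibble(chi2 = chi2, dof = dof, p_value = p,
                 accepted = p > 0.05, n_motion = sum(sel$motion))
}

#' Standardise repeatability against its predicted uncertainty
#'
#' Divides each observed repeatability value by its model-predicted
#' uncertainty, `z = r12 / epsilon_r12`.  If the model is well specified,
#' z is approximately standard normal, so the group 95% width of z
#' (`1.96 * SD(z)`, same convention as [group_summary()]) tends to 1.96 --
#' enabling a before/after comparison with the raw percent-change width.
#' Motion-flagged records are standardised too (they typically surface as
#' outliers in z, whatever their size) and remain flagged in the output.
#'
#' @param records Repeatability records from [repeatability()].
#' @param params [error_model_params()] or fitted model.
#' @return `records` with `epsilon_r12` and `z` columns appended; attribute
#'   `"z_summary"` holds the [group_summary()] of z.
#' @export
standardise <- function(records, params) {
  check_pairs(records, require = c("r12", "motion"))
  out <- tibble::as_tibble(records)
  out$epsilon_r12 <- total_uncertainty(out, params)
  out$z <- out$r12 / out$epsilon_r12
  if (nrow(out) >= 2) attr(out, "z_summary") <- group_summary(out$z)
  out
}

#' Standardised group width
#'
#' Shortcut for the `1.96 * SD(z)` width of standardised records.
#'
#' @param standardised Output of [standardise()].
#' @param motion_only_excluded If `TRUE`, compute the width over
#'   non-motion records only.
#' @return Scalar width (dimensionless).
#' @export
z_width <- function(standardised, motion_only_excluded = FALSE) {
  z <- if (motion_only_excluded) standardised$z[!standardised$motion]
       else standardised$z
  group_summary(z)$ci_width_95
}

#' Plot standardised residuals of a fitted error model
#'
#' Standardised repeatability (z) against ROI size on a log axis, with
#' motion-affected pairs highlighted; the well-specified band (|z| < 1.96)
#' is shaded.
#'
#' @param object An `adc_error_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adc_error_fit <- function(object, ...) {
  std <- standardise(object$records, object$params)
  std$avg_n <- (std$n_1 + std$n_2) / 2
  ggplot2::ggplot(std, ggplot2::aes(x = .data$avg_n, y = .data$z)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = -1.96,
                      ymax = 1.96, alpha = 0.1) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$motion,
                                     shape = .data$roi_kind)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "black"),
                                 name = "motion") +
    ggplot2::labs(x = "ROI size (voxels, log scale)",
                  y = "standardised repeatability z",
                  title = "Repeatability standardised to predicted uncertainty") +
    ggplot2::theme_minimal()
}
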