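#' Run the full repeatability-analysis pipeline
#'
#' Orchestrates every stage on a cohort of ROI session summaries:
#' pair sessions, compute repeatability, fit the error model by maximum
#' likelihood (motion-flagged pairs excluded from fitting), chi-squared
#' goodness of fit per subset, standardise all records (motion included)
#' against the fitted uncertainty, build a look-up grid, write figures, and
#' record a manifest sufficient to re-execute the run.
#'
#' The raw versus standardised 95% width comparison -- the headline payoff
#' of standardisation -- is reported in `summary.json` and in the returned
#' object.
#'
#' @param input One of: a [synthetic_config()] (a cohort is generated from
#'   its seed), a path to an ROI table readable by [read_roi_table()], or a
#'   data frame passing [validate_roi_table()].
#' @param out_dir Output directory; created if needed.
#' @param variant Error-model variant to fit.
#' @param exclude_motion Exclude motion-flagged pairs from the fit
#'   (default `TRUE`).
#' @param fit_kinds ROI kinds entering the fit; default the three tumour
#'   kinds (parenchyma ROIs are standardised and reported but do not drive
#'   the fit).
#' @param d_nominal Nominal ADC for the look-up grid; default the cohort's
#'   rounded mean session ADC.
#' @param seed Seed for the optimiser starts (default 1).
#' @param make_plots Write figure files (default `TRUE`).
#' @return Invisibly, a list of class `adc_pipeline` with elements
#'   `records` (standardised), `fit`, `gof`, `widths`, `lookup`, `files`,
#'   `manifest`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(synthetic_config(n_patients = 6, seed = 3),
#'                     out_dir = tempfile())
#' res$widths
#' }
run_pipeline <- function(input, out_dir,
                         variant = c("three_param", "two_param", "sys_only"),
                         exclude_motion = TRUE,
                         fit_kinds = roi_kinds(tumour_only = TRUE),
                         d_nominal = NULL, seed = 1L, make_plots = TRUE) {
  variant <- match.arg(variant)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  input_desc <- stage("load", {
    if (inherits(input, "synthetic_config")) {
      measurements <- generate_cohort(input)
      list(type = "synthetic", seed = input$seed, measurements = measurements)
    } else if (is.character(input) && length(input) == 1) {
      list(type = "file", path = normalizePath(input),
           measurements = read_roi_table(input))
    } else if (is.data.frame(input)) {
      list(type = "data.frame", measurements = validate_roi_table(input))
    } else {
      abort("`input` must be a synthetic_config, a file path, or a data frame.")
    }
  })
  measurements <- input_desc$measurements

  pairs <- stage("pair", pair_sessions(measurements, quiet = TRUE))
  records <- stage("repeatability", repeatability(pairs))

  fit_records <- records[records$roi_kind %in% fit_kinds, ]
  fit <- stage("fit", fit_error_model(fit_records, variant = variant,
                                      exclude_motion = exclude_motion,
                                      seed = seed))

  gof <- stage("gof", {
    subsets <- list(
      list(label = "whole_3d_no_motion", kind = "whole_3d", motion = FALSE),
      list(label = "tumour_no_motion", kind = fit_kinds, motion = FALSE),
      list(label = "tumour_all", kind = fit_kinds, motion = TRUE))
    purrr::map_dfr(subsets, function(s) {
      g <- tryCatch(
        chi_squared_gof(records, fit, roi_kind = s$kind,
                        include_motion = s$motion),
        error = function(e) NULL)
      if (is.null(g)) return(NULL)
      dplyr::bind_cols(tibble::tibble(subset = s$label), g)
    })
  })

  standardised <- stage("standardise", standardise(records, fit))
  widths <- stage("widths", tibble::tibble(
    raw_width_pct = group_summary(standardised$r12)$ci_width_95,
    standardised_width = group_summary(standardised$z)$ci_width_95,
    standardised_width_no_motion = z_width(standardised,
                                           motion_only_excluded = TRUE)))

  if (is.null(d_nominal)) {
    d_nominal <- round(mean(c(records$mean_adc_1, records$mean_adc_2)))
  }
  lookup <- stage("lookup", build_lookup(fit, d_nominal = d_nominal))

  files <- stage("write", {
    f <- list(
      records = file.path(out_dir, "records.csv"),
      params = file.path(out_dir, "params.json"),
      gof = file.path(out_dir, "gof.json"),
      summary = file.path(out_dir, "summary.json"),
      lookup = file.path(out_dir, "lookup.csv"),
      manifest = file.path(out_dir, "manifest.json"))
    readr::write_csv(standardised, f$records)
    p <- fit$params
    jsonlite::write_json(
      list(beta = p$beta, sigma_fix = p$sigma_fix, epsilon_sys = p$epsilon_sys,
           variant = p$variant, neg_log_likelihood = fit$neg_log_likelihood,
           n_records_used = fit$n_records_used,
           n_excluded_motion = fit$n_excluded_motion,
           converged = fit$converged, seed = fit$seed),
      f$params, auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(gof, f$gof, digits = NA)
    jsonlite::write_json(as.list(widths[1, ]), f$summary,
                         auto_unbox = TRUE, digits = NA)
    write_lookup(lookup, f$lookup)
    f
  })

  if (make_plots) {
    fig_files <- stage("figures", make_figures(standardised, fit, out_dir,
                                               d_nominal = d_nominal))
    files <- c(files, fig_files)
  }

  manifest <- stage("manifest", {
    existing <- unlist(files)
    existing <- existing[file.exists(existing)]
    m <- list(
      package_version = as.character(packageVersion("adcrepeat")),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
      input = input_desc[c("type", "seed", "path")[c("type", "seed", "path") %in%
                                                     names(input_desc)]],
      fit_seed = seed, variant = variant, exclude_motion = exclude_motion,
      fit_kinds = fit_kinds, d_nominal = d_nominal,
      counts = list(measurements = nrow(measurements), pairs = nrow(pairs),
                    unpaired = nrow(attr(pairs, "unpaired")),
                    motion_pairs = sum(pairs$motion)),
      file_md5 = as.list(tools::md5sum(existing)))
    jsonlite::write_json(m, files$manifest, auto_unbox = TRUE, digits = NA)
    m
  })

  invisible(structure(
    list(records = standardised, fit = fit, gof = gof, widths = widths,
         lookup = lookup, files = files, manifest = manifest),
    class = "adc_pipeline"))
}

#' @export
print.adc_pipeline <- function(x, ...) {
  cat("ADC repeatability pipeline\n")
  cat(sprintf("  pairs: %d (motion: %d)\n", nrow(x$records),
              sum(x$records$motion)))
  print(x$fit$params)
  cat(sprintf("  95%% width: raw %.1f%% -> standardised %.2f (z units)\n",
              x$widths$raw_width_pct, x$widths$standardised_width))
  invisible(x)
}

#' Scatter of repeatability against ROI size
#'
#' Percent ADC change (raw, or standardised if `standardised = TRUE` and a
#' `z` column is present) against the session-average voxel count on a log
#' axis; 2D/3D ROI kinds by shape, motion-affected pairs in black.
#'
#' @param records Repeatability records (optionally standardised).
#' @param standardised Plot `z` instead of `r12`.
#' @return A ggplot object.
#' @export
plot_repeatability <- function(records, standardised = FALSE) {
  check_pairs(records, require = c("r12", "motion"))
  yvar <- if (standardised) "z" else "r12"
  if (standardised && !"z" %in% names(records)) {
    abort("Standardised plot needs a `z` column; run standardise() first.")
  }
  df <- tibble::as_tibble(records)
  df$avg_n <- (df$n_1 + df$n_2) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg_n, y = .data[[yvar]])) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$motion,
                                     shape = .data$roi_kind), size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "black"),
                                 name = "motion") +
    ggplot2::labs(x = "ROI size (voxels, log scale)",
                  y = if (standardised) "standardised repeatability z"
                      else expression(Delta * "ADC (%)")) +
    ggplot2::theme_minimal()
}

#' Predicted uncertainty against ROI size
#'
#' Per-record model-predicted uncertainty against ROI size, with the
#' plateau threshold annotated (default 2000 voxels, i.e. 22.5 cm^3 at the
#' reference geometry): above it the gain from further size is marginal.
#'
#' @param records Standardised records (with `epsilon_r12`).
#' @param threshold_voxels Vertical annotation position (default 2000).
#' @return A ggplot object.
#' @export
plot_uncertainty_vs_size <- function(records, threshold_voxels = 2000) {
  if (!"epsilon_r12" %in% names(records)) {
    abort("Needs `epsilon_r12`; run standardise() first.")
  }
  df <- tibble::as_tibble(records)
  df$avg_n <- (df$n_1 + df$n_2) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg_n, y = .data$epsilon_r12)) +
    ggplot2::geom_vline(xintercept = threshold_voxels, linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$motion,
                                     shape = .data$roi_kind), size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "black"),
                                 name = "motion") +
    ggplot2::annotate("text", x = threshold_voxels, y = Inf,
                      label = sprintf("%d voxels (%.1f cm³)", threshold_voxels,
                                      voxels_to_volume(threshold_voxels,
                                                       units = "cm3")),
                      vjust = 1.5, hjust = -0.05, size = 3) +
    ggplot2::labs(x = "ROI size (voxels, log scale)",
                  y = "predicted uncertainty (%)") +
    ggplot2::theme_minimal()
}

#' Write the figure set for a cohort
#'
#' Produces the four standard figures -- repeatability vs size, predicted
#' uncertainty vs size (with the 2000-voxel threshold), standardised
#' repeatability vs size, and the look-up heat map -- as PDF files, and
#' exports the exact numbers behind each plot as CSV so every figure is
#' regenerable from data alone.
#'
#' @param records Standardised repeatability records (see [standardise()]);
#'   if `epsilon_r12`/`z` are absent they are computed from `params`.
#' @param params [error_model_params()] or fitted model.
#' @param dir Output directory.
#' @param d_nominal Nominal ADC for the look-up chart.
#' @param threshold_voxels Plateau annotation (default 2000).
#' @return Named list of created file paths, invisibly.
#' @export
make_figures <- function(records, params, dir, d_nominal = 109,
                         threshold_voxels = 2000) {
  if (nrow(records) == 0) abort("No records to plot.")
  if (!all(c("epsilon_r12", "z") %in% names(records))) {
    records <- standardise(records, params)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- tibble::as_tibble(records)
  df$avg_n <- (df$n_1 + df$n_2) / 2
  lookup <- build_lookup(params, d_nominal = d_nominal)
  files <- list(
    fig_repeatability = file.path(dir, "fig_repeatability.pdf"),
    fig_repeatability_csv = file.path(dir, "fig_repeatability.csv"),
    fig_uncertainty = file.path(dir, "fig_uncertainty_vs_size.pdf"),
    fig_uncertainty_csv = file.path(dir, "fig_uncertainty_vs_size.csv"),
    fig_standardised = file.path(dir, "fig_standardised.pdf"),
    fig_standardised_csv = file.path(dir, "fig_standardised.csv"),
    fig_lookup = file.path(dir, "fig_lookup.pdf"),
    fig_lookup_csv = file.path(dir, "fig_lookup.csv"))
  save_quiet <- function(plot, path) {
    suppressMessages(ggplot2::ggsave(path, plot, width = 6, height = 4.5,
                                     device = grDevices::pdf))
  }
  save_quiet(plot_repeatability(df), files$fig_repeatability)
  readr::write_csv(df[, c("patient_id", "roi_kind", "avg_n", "r12", "motion")],
                   files$fig_repeatability_csv)
  save_quiet(plot_uncertainty_vs_size(df, threshold_voxels),
             files$fig_uncertainty)
  readr::write_csv(df[, c("patient_id", "roi_kind", "avg_n", "epsilon_r12",
                          "motion")], files$fig_uncertainty_csv)
  save_quiet(plot_repeatability(df, standardised = TRUE),
             files$fig_standardised)
  readr::write_csv(df[, c("patient_id", "roi_kind", "avg_n", "z", "motion")],
                   files$fig_standardised_csv)
  save_quiet(autoplot(lookup), files$fig_lookup)
  readr::write_csv(tibble::as_tibble(lookup), files$fig_lookup_csv)
  invisible(files)
}
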