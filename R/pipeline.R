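#' Pipeline configuration
#'
#' Aggregates the constants of the screening pipeline. The defaults are
#' the reference values: Cy3 saturation threshold 65000, QC exclusion when
#' more than 50% of z-layers are incorrect, EC levels 10 and 50, and
#' alpha 0.05 for the control comparison.
#'
#' @param segmentation A [segmentation_params].
#' @param saturation_threshold Cy3 saturation threshold.
#' @param exclude_fitc_saturation Also exclude FITC-saturated pixels.
#' @param max_incorrect_z_fraction QC threshold on the incorrect-z fraction.
#' @param ec_levels Percent effect levels reported.
#' @param alpha Significance level for the control comparison.
#' @param ci_method Confidence-interval method for ECx, see [ec_x].
#' @param immobilization_fit `"binomial_ml"` or `"least_squares"`.
#' @param jc1_floor Optional explicit lower limit for the JC-1 LL4 fit;
#'   when `NULL` it is estimated from dead controls.
#' @param seed Optional integer seed for stochastic steps.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(segmentation = segmentation_params(),
                            saturation_threshold = 65000,
                            exclude_fitc_saturation = FALSE,
                            max_incorrect_z_fraction = 0.5,
                            ec_levels = c(10, 50),
                            alpha = 0.05,
                            ci_method = c("delta_original", "delta_log",
                                          "bootstrap"),
                            immobilization_fit = c("binomial_ml",
                                                   "least_squares"),
                            jc1_floor = NULL,
                            seed = NULL) {
  structure(
    list(segmentation = segmentation,
         saturation_threshold = saturation_threshold,
         exclude_fitc_saturation = isTRUE(exclude_fitc_saturation),
         max_incorrect_z_fraction = max_incorrect_z_fraction,
         ec_levels = ec_levels, alpha = alpha,
         ci_method = match.arg(ci_method),
         immobilization_fit = match.arg(immobilization_fit),
         jc1_floor = jc1_floor, seed = seed),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the arguments of [pipeline_config]; the
#' `segmentation` key takes a nested map of [segmentation_params]
#' arguments. Unknown keys raise an error.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path), class = "jc1_io_error")
  }
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "jc1_configuration_error")
  }
  if (!is.null(raw$segmentation)) {
    raw$segmentation <- do.call(segmentation_params, raw$segmentation)
  }
  do.call(pipeline_config, raw)
}

#' Write a pipeline configuration to YAML
#'
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  out <- unclass(config)
  out$segmentation <- unclass(out$segmentation)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Analyze a plate of well stacks
#'
#' Runs segmentation and masked quantification over every stack found in
#' an image directory (or supplied in memory), aggregates per-individual
#' results under the QC rules, and reports every exclusion with its
#' reason (no organism found, more than one segment, or too many
#' incorrect z-layers).
#'
#' @param source Either a directory containing TIFFs in the
#'   `<well>_z<k>_<channel>.tif` convention, or a list of [well_stack]
#'   objects.
#' @param layout Optional [plate_layout]; when supplied, wells are checked
#'   against it.
#' @param config A [pipeline_config].
#' @param verbose Report QC exclusions via messages. Default `TRUE`.
#' @return List with `z_levels` (per-z measurements) and `individuals`
#'   (per-organism results, QC applied).
#' @export
analyze_plate <- function(source, layout = NULL, config = pipeline_config(),
                          verbose = TRUE) {
  if (is.character(source)) {
    stacks <- discover_well_stacks(source)
    if (length(stacks) == 0) {
      abort(paste0("No well stacks found in ", source, "."),
            class = "jc1_io_error")
    }
    z_levels <- purrr::map_dfr(names(stacks), function(w) {
      stack <- read_well_stack(stacks[[w]], well_id = w)
      measure_well_stack(stack, config$segmentation,
                         config$saturation_threshold,
                         config$exclude_fitc_saturation)
    })
  } else {
    z_levels <- purrr::map_dfr(source, function(stack) {
      measure_well_stack(stack, config$segmentation,
                         config$saturation_threshold,
                         config$exclude_fitc_saturation)
    })
  }
  individuals <- z_levels |>
    dplyr::group_by(.data$well_id) |>
    dplyr::group_map(~ aggregate_individual(
      dplyr::mutate(.x, well_id = .y$well_id),
      config$max_incorrect_z_fraction)) |>
    dplyr::bind_rows()
  if (!is.null(layout)) {
    unknown <- setdiff(individuals$well_id, layout$well_id)
    if (length(unknown) > 0) {
      warn(paste0("Well(s) not present in the layout: ",
                  paste(head(unknown, 5), collapse = ", ")))
    }
  }
  excl <- individuals[!individuals$qc_pass, , drop = FALSE]
  if (verbose) {
    inform(paste0(nrow(individuals), " individual(s) measured, ",
                  nrow(excl), " excluded by QC."))
    for (i in seq_len(nrow(excl))) {
      inform(paste0("  QC exclusion: well ", excl$well_id[i], " (",
                    excl$qc_reason[i], "; ", excl$n_z_correct[i], "/",
                    excl$n_z_total[i], " z-layers correct)"))
    }
  }
  list(z_levels = z_levels, individuals = individuals)
}

#' Fit concentration-response models and report effect concentrations
#'
#' For each compound and timepoint: normalizes JC-1 ratios to the medium
#' control, aggregates replicate means, fixes the LL4 lower limit to the
#' dead-control floor (or a configured value) and fits the constrained
#' LL4 model; pools immobilization counts and fits the LL2 model by
#' binomial maximum likelihood. EC10/EC50 with 95% confidence intervals
#' are reported per endpoint along with a CI-overlap flag between the two
#' endpoints' EC50 intervals.
#'
#' @param individuals Per-individual results from [analyze_plate].
#' @param immobilization Tibble of immobilization records (or `NULL`).
#' @param layout A [plate_layout].
#' @param config A [pipeline_config].
#' @return List with `fits` (one row per compound x endpoint x timepoint),
#'   `ec` (long ECx table), `control_comparison` (tibble or `NULL`) and
#'   `fit_objects` (named list of `ll_fit`).
#' @export
fit_report <- function(individuals, immobilization = NULL, layout,
                       config = pipeline_config()) {
  norm <- normalize_to_control(individuals, layout)
  floor_val <- config$jc1_floor %||% dead_control_floor(norm)
  points <- aggregate_replicate_means(norm, layout)

  fits <- list(); rows <- list(); ec_rows <- list()
  jc1_groups <- dplyr::distinct(points, .data$compound, .data$timepoint_h)
  for (i in seq_len(nrow(jc1_groups))) {
    g <- jc1_groups[i, ]
    pts <- dplyr::semi_join(points, g, by = c("compound", "timepoint_h"))
    key <- paste0(g$compound, "_jc1_", g$timepoint_h, "h")
    fit <- tryCatch(fit_ll4(pts, c_fixed = floor_val),
                    error = function(e) e)
    rows[[key]] <- report_row(fit, g$compound, "jc1", g$timepoint_h,
                              config)
    if (inherits(fit, "ll_fit")) {
      fits[[key]] <- fit
      ec_rows[[key]] <- dplyr::mutate(
        ec_x(fit, config$ec_levels, config$ci_method),
        compound = g$compound, endpoint = "jc1",
        timepoint_h = g$timepoint_h)
    }
  }

  if (!is.null(immobilization) && nrow(immobilization) > 0) {
    imm <- as_tibble(immobilization)
    if (!"compound" %in% names(imm)) {
      imm$compound <- unique(layout$compound[layout$role == "treatment"])[1]
    }
    imm_groups <- dplyr::distinct(imm, .data$compound, .data$timepoint_h)
    for (i in seq_len(nrow(imm_groups))) {
      g <- imm_groups[i, ]
      rec <- dplyr::semi_join(imm, g, by = c("compound", "timepoint_h"))
      key <- paste0(g$compound, "_immobilization_", g$timepoint_h, "h")
      fit <- tryCatch(fit_ll2(rec, method = config$immobilization_fit),
                      error = function(e) e)
      rows[[key]] <- report_row(fit, g$compound, "immobilization",
                                g$timepoint_h, config)
      if (inherits(fit, "ll_fit")) {
        fits[[key]] <- fit
        ec_rows[[key]] <- dplyr::mutate(
          ec_x(fit, config$ec_levels, config$ci_method),
          compound = g$compound, endpoint = "immobilization",
          timepoint_h = g$timepoint_h)
      }
    }
  }

  report <- dplyr::bind_rows(rows)
  # CI-overlap flag between the two endpoints' EC50 intervals
  report$ci_overlap_ec50 <- NA
  for (i in seq_len(nrow(report))) {
    other <- report[report$compound == report$compound[i] &
                      report$timepoint_h == report$timepoint_h[i] &
                      report$endpoint != report$endpoint[i], ]
    if (nrow(other) == 1 && is.finite(report$ec50_lo[i]) &&
        is.finite(other$ec50_lo)) {
      report$ci_overlap_ec50[i] <-
        report$ec50_lo[i] <= other$ec50_hi && other$ec50_lo <= report$ec50_hi[i]
    }
  }

  ctrl_cmp <- NULL
  m7 <- norm$normalized_ratio[norm$role == "control" & norm$qc_pass]
  dmso <- norm$normalized_ratio[norm$role == "solvent_control" & norm$qc_pass]
  if (sum(is.finite(m7)) >= 3 && sum(is.finite(dmso)) >= 3) {
    ctrl_cmp <- compare_controls(m7, dmso, config$alpha)
  }

  list(fits = report, ec = dplyr::bind_rows(ec_rows),
       control_comparison = ctrl_cmp, fit_objects = fits)
}

report_row <- function(fit, compound, endpoint, timepoint_h, config) {
  if (!inherits(fit, "ll_fit")) {
    return(tibble(
      compound = compound, endpoint = endpoint, timepoint_h = timepoint_h,
      family = NA_character_, b = NA_real_, c = NA_real_, d = NA_real_,
      e = NA_real_, ec10 = NA_real_, ec10_lo = NA_real_, ec10_hi = NA_real_,
      ec50 = NA_real_, ec50_lo = NA_real_, ec50_hi = NA_real_,
      converged = FALSE, n_points = NA_integer_,
      note = conditionMessage(fit)
    ))
  }
  ec <- ec_x(fit, c(10, 50), config$ci_method)
  tibble(
    compound = compound, endpoint = endpoint, timepoint_h = timepoint_h,
    family = fit$family,
    b = fit$coef[["b"]], c = fit$coef[["c"]], d = fit$coef[["d"]],
    e = fit$coef[["e"]],
    ec10 = ec$value[ec$p == 10], ec10_lo = ec$ci_low[ec$p == 10],
    ec10_hi = ec$ci_high[ec$p == 10],
    ec50 = ec$value[ec$p == 50], ec50_lo = ec$ci_low[ec$p == 50],
    ec50_hi = ec$ci_high[ec$p == 50],
    converged = fit$converged, n_points = fit$n_points,
    note = NA_character_
  )
}

#' Write a fit report to CSV
#'
#' @param report The `fits` tibble from [fit_report].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(report, path) {
  readr::write_csv(report, path)
  invisible(path)
}
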