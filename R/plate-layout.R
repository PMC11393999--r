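#' Well roles recognised in a plate layout
#'
#' `control` is the M7 medium control used for normalization,
#' `solvent_control` the DMSO vehicle control, `treatment` an exposed group,
#' and `dead_control` the non-viable reference group whose mean normalized
#' ratio fixes the lower asymptote of the JC-1 concentration-response model.
#'
#' @export
plate_roles <- c("control", "solvent_control", "treatment", "dead_control")

layout_columns <- c(
  "well_id", "compound", "concentration", "unit", "role",
  "experiment_id", "timepoint_h", "n_individuals"
)

immobilization_columns <- c(
  "well_group", "concentration", "unit", "n_exposed", "n_immobile",
  "experiment_id", "timepoint_h"
)

#' Construct and validate a plate layout
#'
#' A plate layout maps each well (or well group) to its compound,
#' concentration, role, experiment and timepoint. Validation enforces the
#' layout invariants: well ids unique within an experiment and timepoint,
#' zero concentration for all control roles, and known role labels.
#'
#' @param x A data frame with columns `well_id`, `compound`, `concentration`,
#'   `unit`, `role`, `experiment_id`, `timepoint_h`, `n_individuals`.
#' @return A validated tibble with class `plate_layout`.
#' @export
plate_layout <- function(x) {
  x <- as_tibble(x)
  missing <- setdiff(layout_columns, names(x))
  if (length(missing) > 0) {
    abort(
      paste0("Plate layout is missing column(s): ",
             paste(missing, collapse = ", ")),
      class = "jc1_schema_error"
    )
  }
  x <- x[layout_columns]
  bad_role <- !x$role %in% plate_roles
  if (any(bad_role)) {
    warn(paste0(
      "Rejecting ", sum(bad_role), " layout row(s) with unknown role: ",
      paste(unique(x$role[bad_role]), collapse = ", ")
    ))
    x <- x[!bad_role, , drop = FALSE]
  }
  dup <- duplicated(x[c("well_id", "experiment_id", "timepoint_h")])
  if (any(dup)) {
    abort(
      paste0("Duplicate well id(s) within an experiment/timepoint: ",
             paste(unique(x$well_id[dup]), collapse = ", ")),
      class = "jc1_validation_error"
    )
  }
  if (any(x$concentration < 0, na.rm = TRUE)) {
    abort("Concentrations must be non-negative.",
          class = "jc1_validation_error")
  }
  ctrl <- x$role %in% c("control", "solvent_control", "dead_control")
  if (any(x$concentration[ctrl] != 0)) {
    abort("Control, solvent-control and dead-control wells must have concentration 0.",
          class = "jc1_validation_error")
  }
  zero_trt <- x$role == "treatment" & x$concentration == 0
  if (any(zero_trt)) {
    # tolerated so that layout edits never silently reclassify a well; such
    # rows are never pooled into the control group
    warn(paste0(sum(zero_trt),
                " treatment row(s) have concentration 0; accepted as-is."))
  }
  if (any(x$n_individuals < 1)) {
    abort("n_individuals must be a positive integer.",
          class = "jc1_validation_error")
  }
  class(x) <- c("plate_layout", class(x))
  x
}

#' Read a plate layout from CSV
#'
#' The file must carry the header
#' `well_id,compound,concentration,unit,role,experiment_id,timepoint_h,n_individuals`.
#'
#' @param path Path to the layout CSV.
#' @return A validated [plate_layout] tibble (possibly with zero rows).
#' @export
read_plate_layout <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Layout file not found: ", path), class = "jc1_io_error")
  }
  x <- readr::read_csv(path, col_types = readr::cols(
    well_id = readr::col_character(),
    compound = readr::col_character(),
    concentration = readr::col_double(),
    unit = readr::col_character(),
    role = readr::col_character(),
    experiment_id = readr::col_character(),
    timepoint_h = readr::col_double(),
    n_individuals = readr::col_integer()
  ))
  plate_layout(x)
}

#' Write a plate layout to CSV
#'
#' @param layout A [plate_layout].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_layout <- function(layout, path) {
  readr::write_csv(as_tibble(layout)[layout_columns], path)
  invisible(path)
}

#' Read immobilization observations from CSV
#'
#' Immobilization is the apical acute-toxicity endpoint: the number of
#' animals unable to swim out of the number exposed, per well group. The
#' file must carry the header
#' `well_group,concentration,unit,n_exposed,n_immobile,experiment_id,timepoint_h`.
#'
#' @param path Path to the immobilization CSV.
#' @return A tibble of immobilization records.
#' @export
read_immobilization <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Immobilization file not found: ", path),
          class = "jc1_io_error")
  }
  x <- readr::read_csv(path, col_types = readr::cols(
    well_group = readr::col_character(),
    concentration = readr::col_double(),
    unit = readr::col_character(),
    n_exposed = readr::col_integer(),
    n_immobile = readr::col_integer(),
    experiment_id = readr::col_character(),
    timepoint_h = readr::col_double()
  ))
  missing <- setdiff(immobilization_columns, names(x))
  if (length(missing) > 0) {
    abort(paste0("Immobilization table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "jc1_schema_error")
  }
  validate_immobilization(x)
}

validate_immobilization <- function(x) {
  x <- as_tibble(x)
  if (any(x$n_exposed < 1)) {
    abort("n_exposed must be positive.", class = "jc1_validation_error")
  }
  if (any(x$n_immobile < 0 | x$n_immobile > x$n_exposed)) {
    abort("n_immobile must lie in [0, n_exposed].",
          class = "jc1_validation_error")
  }
  x
}

#' Write immobilization observations to CSV
#'
#' @param records A tibble of immobilization records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_immobilization <- function(records, path) {
  readr::write_csv(validate_immobilization(records)[immobilization_columns],
                   path)
  invisible(path)
}

z_measurement_columns <- c(
  "well_id", "z", "area_px", "mean_cy3", "mean_fitc", "n_saturated_px",
  "segment_count", "z_correct", "ratio"
)

individual_columns <- c(
  "well_id", "ratio", "n_z_total", "n_z_correct", "n_z_segment0",
  "n_z_multi", "qc_pass", "qc_reason", "normalized_ratio"
)

#' Write per-z-level and per-individual measurements
#'
#' Writes two plain CSV files: `<stem>_zlevels.csv` with one row per well
#' per z-level, and `<stem>_individuals.csv` with one summary row per
#' organism. CSV keeps full double precision, so a read-back round-trips
#' every numeric field.
#'
#' @param z_levels Tibble of z-level measurements (see [masked_channel_means]).
#' @param individuals Tibble of individual results (see [aggregate_individual]).
#' @param dir Output directory (created if absent).
#' @param stem File-name stem, default `"measurements"`.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_measurements <- function(z_levels, individuals, dir,
                               stem = "measurements") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  zp <- file.path(dir, paste0(stem, "_zlevels.csv"))
  ip <- file.path(dir, paste0(stem, "_individuals.csv"))
  z_levels <- as_tibble(z_levels)
  individuals <- as_tibble(individuals)
  for (col in setdiff(z_measurement_columns, names(z_levels))) {
    abort(paste0("z-level table is missing column: ", col),
          class = "jc1_schema_error")
  }
  for (col in setdiff(individual_columns, names(individuals))) {
    abort(paste0("individual table is missing column: ", col),
          class = "jc1_schema_error")
  }
  readr::write_csv(z_levels[z_measurement_columns], zp)
  readr::write_csv(individuals[individual_columns], ip)
  invisible(c(z_levels = zp, individuals = ip))
}

#' Read measurements written by [write_measurements]
#'
#' @param dir Directory containing the files.
#' @param stem File-name stem used when writing.
#' @return List with elements `z_levels` and `individuals`.
#' @export
read_measurements <- function(dir, stem = "measurements") {
  zp <- file.path(dir, paste0(stem, "_zlevels.csv"))
  ip <- file.path(dir, paste0(stem, "_individuals.csv"))
  for (p in c(zp, ip)) {
    if (!file.exists(p)) {
      abort(paste0("Measurement file not found: ", p), class = "jc1_io_error")
    }
  }
  z <- readr::read_csv(zp, col_types = readr::cols(
    well_id = readr::col_character(),
    z = readr::col_integer(),
    area_px = readr::col_integer(),
    mean_cy3 = readr::col_double(),
    mean_fitc = readr::col_double(),
    n_saturated_px = readr::col_integer(),
    segment_count = readr::col_integer(),
    z_correct = readr::col_logical(),
    ratio = readr::col_double()
  ))
  ind <- readr::read_csv(ip, col_types = readr::cols(
    well_id = readr::col_character(),
    ratio = readr::col_double(),
    n_z_total = readr::col_integer(),
    n_z_correct = readr::col_integer(),
    n_z_segment0 = readr::col_integer(),
    n_z_multi = readr::col_integer(),
    qc_pass = readr::col_logical(),
    qc_reason = readr::col_character(),
    normalized_ratio = readr::col_double()
  ))
  list(z_levels = z, individuals = ind)
}
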