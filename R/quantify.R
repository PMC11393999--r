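#' Masked channel means with paired saturation exclusion
#'
#' Measures the mean Cy3 and FITC intensity inside the organism mask.
#' Mask pixels whose Cy3 intensity reaches the saturation threshold
#' (default 65000 on the 16-bit scale) are excluded from BOTH channel
#' means — pixel-level paired exclusion preserves the red/green ratio's
#' pairing, and whole-image exclusion is recovered automatically when every
#' mask pixel saturates.
#'
#' @param mask An [organism_mask] for this z-level.
#' @param cy3,fitc Numeric matrices with the same dimensions as the mask.
#' @param saturation_threshold Cy3 intensity at or above which a pixel is
#'   treated as overexposed. Default 65000.
#' @param exclude_fitc_saturation Also exclude pixels saturated in FITC.
#'   Default `FALSE`: only the Cy3 channel is thresholded.
#' @param well_id Well identifier carried into the output row.
#' @return A one-row tibble (a z-level measurement): `well_id`, `z`,
#'   `area_px`, `mean_cy3`, `mean_fitc`, `n_saturated_px`, `segment_count`,
#'   `z_correct`, `ratio`. The ratio is defined only when the layer is
#'   correct (`segment_count == 1`, usable area after exclusion > 0,
#'   `mean_fitc > 0`); otherwise it is `NA` and the layer counts as
#'   incorrect.
#' @export
masked_channel_means <- function(mask, cy3, fitc,
                                 saturation_threshold = 65000,
                                 exclude_fitc_saturation = FALSE,
                                 well_id = NA_character_) {
  stopifnot(inherits(mask, "organism_mask"))
  if (!identical(dim(cy3), dim(mask$mask)) ||
      !identical(dim(fitc), dim(mask$mask))) {
    abort("Fluorescence images must match the mask dimensions.",
          class = "jc1_measurement_error")
  }
  if (saturation_threshold <= 0 || saturation_threshold > 65535) {
    abort("saturation_threshold must lie in (0, 65535].",
          class = "jc1_measurement_error")
  }
  m <- mask$mask
  saturated <- m & (cy3 >= saturation_threshold)
  if (exclude_fitc_saturation) {
    saturated <- saturated | (m & fitc >= saturation_threshold)
  }
  usable <- m & !saturated
  n_usable <- sum(usable)
  if (n_usable > 0) {
    mean_cy3 <- mean(cy3[usable])
    mean_fitc <- mean(fitc[usable])
  } else {
    mean_cy3 <- NA_real_
    mean_fitc <- NA_real_
  }
  z_correct <- mask$segment_count == 1L && n_usable > 0 &&
    !is.na(mean_fitc) && mean_fitc > 0
  ratio <- if (z_correct) mean_cy3 / mean_fitc else NA_real_
  tibble(
    well_id = well_id,
    z = mask$z_index,
    area_px = mask$area_px,
    mean_cy3 = mean_cy3,
    mean_fitc = mean_fitc,
    n_saturated_px = as.integer(sum(saturated)),
    segment_count = mask$segment_count,
    z_correct = z_correct,
    ratio = ratio
  )
}

#' Red/green fluorescence ratio of a z-level measurement
#'
#' The red (Cy3, J-aggregate) to green (FITC, monomer) ratio indexes
#' mitochondrial membrane potential.
#'
#' @param meas A one-row z-level measurement from [masked_channel_means].
#' @return `mean_cy3 / mean_fitc`, or `NA` with a warning when the FITC
#'   mean is zero or undefined (the layer is then treated as incorrect).
#' @export
red_green_ratio <- function(meas) {
  stopifnot(is.data.frame(meas), nrow(meas) == 1)
  if (is.na(meas$mean_fitc) || meas$mean_fitc == 0) {
    warn("FITC mean is zero or undefined; ratio is undefined.")
    return(NA_real_)
  }
  meas$mean_cy3 / meas$mean_fitc
}

#' Aggregate z-level measurements into a per-individual result
#'
#' The per-organism red/green ratio is the arithmetic mean over correct
#' z-levels. An individual passes QC when at most 50% of its z-layers are
#' incorrect (the exclusion rule is strictly "more than 50%") and at least
#' one layer is correct. A layer is incorrect when its segment count is not
#' 1 or its ratio is undefined for any reason.
#'
#' @param z_measurements Tibble of z-level measurements for one well.
#' @param max_incorrect_z_fraction QC threshold: the individual is excluded
#'   when the fraction of incorrect layers exceeds this value (default 0.5).
#' @return A one-row tibble: `well_id`, `ratio`, `n_z_total`, `n_z_correct`,
#'   `n_z_segment0`, `n_z_multi`, `qc_pass`, `qc_reason`,
#'   `normalized_ratio` (`NA` until normalization).
#' @export
aggregate_individual <- function(z_measurements,
                                 max_incorrect_z_fraction = 0.5) {
  z <- as_tibble(z_measurements)
  stopifnot(nrow(z) > 0)
  if (length(unique(z$well_id)) != 1) {
    abort("aggregate_individual expects measurements from a single well.",
          class = "jc1_measurement_error")
  }
  ok <- z$z_correct & !is.na(z$ratio)
  n_total <- nrow(z)
  n_correct <- sum(ok)
  frac_incorrect <- (n_total - n_correct) / n_total
  qc_pass <- frac_incorrect <= max_incorrect_z_fraction && n_correct >= 1
  n_seg0 <- sum(z$segment_count == 0L)
  n_multi <- sum(z$segment_count > 1L)
  reason <- if (qc_pass) {
    NA_character_
  } else if (n_multi >= n_seg0 && n_multi > 0) {
    "segment_count > 1"
  } else if (n_seg0 > 0) {
    "segment_count == 0"
  } else {
    "undefined ratio"
  }
  tibble(
    well_id = z$well_id[1],
    ratio = if (qc_pass) mean(z$ratio[ok]) else NA_real_,
    n_z_total = as.integer(n_total),
    n_z_correct = as.integer(n_correct),
    n_z_segment0 = as.integer(n_seg0),
    n_z_multi = as.integer(n_multi),
    qc_pass = qc_pass,
    qc_reason = reason,
    normalized_ratio = NA_real_
  )
}

#' Measure one well stack
#'
#' Segments every z-level of the transmitted-light channel and measures the
#' masked Cy3/FITC means with saturation exclusion.
#'
#' @param stack A [well_stack].
#' @param params A [segmentation_params].
#' @param saturation_threshold Cy3 saturation threshold, default 65000.
#' @param exclude_fitc_saturation See [masked_channel_means].
#' @return Tibble of z-level measurements, one row per z-level.
#' @export
measure_well_stack <- function(stack, params = segmentation_params(),
                               saturation_threshold = 65000,
                               exclude_fitc_saturation = FALSE) {
  stopifnot(inherits(stack, "well_stack"))
  purrr::map_dfr(seq_along(stack$z_levels), function(k) {
    lev <- stack$z_levels[[k]]
    mask <- segment_organism(lev$tl, params, z_index = k)
    masked_channel_means(mask, lev$cy3, lev$fitc,
                         saturation_threshold = saturation_threshold,
                         exclude_fitc_saturation = exclude_fitc_saturation,
                         well_id = stack$well_id)
  })
}
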