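#' Simulation ground truth
#'
#' Defines the generating concentration-response curves and the plate
#' design of a synthetic study. Defaults mirror the reference design:
#' the seven CCCP concentrations (0.5-2500 ug/L), five individuals per
#' concentration, three independent experiments, and a normalized JC-1
#' curve falling from 1 toward a dead-control floor of 0.2.
#'
#' @param ll4 Named vector `(b, c, d, e)` of the JC-1 ratio curve on the
#'   normalized scale.
#' @param ll2 Named vector `(b, e)` of the immobilization curve.
#' @param concentrations Distinct non-negative exposure concentrations.
#' @param unit Concentration unit label.
#' @param n_individuals_per_conc Individuals imaged per concentration per
#'   experiment (default 5).
#' @param n_exposed_per_conc Animals per concentration per experiment in
#'   the immobilization count (defaults to `n_individuals_per_conc`).
#' @param n_experiments Independent experiments (default 3).
#' @param noise_sd Per-individual Gaussian noise on the normalized ratio;
#'   replicate means receive noise `noise_sd / sqrt(n_individuals)`.
#' @param timepoint_h Exposure duration label in hours.
#' @param seed Integer seed making every simulated table reproducible.
#' @return A list of class `simulation_truth`.
#' @export
simulation_truth <- function(ll4 = c(b = 2, c = 0.2, d = 1, e = 100),
                             ll2 = c(b = -4, e = 500),
                             concentrations = c(0.5, 5, 25, 50, 250, 500, 2500),
                             unit = "ug/L",
                             n_individuals_per_conc = 5,
                             n_exposed_per_conc = NULL,
                             n_experiments = 3,
                             noise_sd = 0.05,
                             timepoint_h = 24,
                             seed = 1L) {
  stopifnot(all(c("b", "c", "d", "e") %in% names(ll4)),
            all(c("b", "e") %in% names(ll2)),
            ll4[["e"]] > 0, ll2[["e"]] > 0,
            ll4[["d"]] >= ll4[["c"]],
            noise_sd >= 0, n_individuals_per_conc >= 1, n_experiments >= 1)
  concentrations <- sort(unique(concentrations))
  if (any(concentrations < 0)) {
    abort("Concentrations must be non-negative.", class = "jc1_domain_error")
  }
  structure(
    list(ll4 = ll4, ll2 = ll2, concentrations = concentrations, unit = unit,
         n_individuals_per_conc = as.integer(n_individuals_per_conc),
         n_exposed_per_conc =
           as.integer(n_exposed_per_conc %||% n_individuals_per_conc),
         n_experiments = as.integer(n_experiments),
         noise_sd = noise_sd, timepoint_h = timepoint_h,
         seed = as.integer(seed)),
    class = "simulation_truth"
  )
}

#' Simulate tabular dose-response data
#'
#' Generates replicate-mean JC-1 response points and immobilization counts
#' directly from the ground-truth curves, bypassing the imaging stages.
#' JC-1 points are `ll4_response(conc) + N(0, noise_sd / sqrt(n))` per
#' experiment and concentration; immobilized counts are
#' `Binomial(n_exposed, ll2_response(conc))`. Identical seeds give
#' identical tables.
#'
#' @param truth A [simulation_truth].
#' @param compound Compound label used in the tables.
#' @return List with `jc1` (response-point tibble) and `immobilization`
#'   (immobilization-record tibble).
#' @export
simulate_response_tables <- function(truth, compound = "synthetic") {
  stopifnot(inherits(truth, "simulation_truth"))
  set.seed(truth$seed)
  grid <- tidyr::expand_grid(
    experiment_id = sprintf("E%d", seq_len(truth$n_experiments)),
    concentration = truth$concentrations
  )
  mu <- ll4_response(grid$concentration, truth$ll4[["b"]], truth$ll4[["c"]],
                     truth$ll4[["d"]], truth$ll4[["e"]])
  sd_mean <- truth$noise_sd / sqrt(truth$n_individuals_per_conc)
  jc1 <- tibble(
    compound = compound,
    concentration = grid$concentration,
    unit = truth$unit,
    experiment_id = grid$experiment_id,
    timepoint_h = truth$timepoint_h,
    response = mu + rnorm(nrow(grid), 0, sd_mean),
    n_individuals = truth$n_individuals_per_conc,
    endpoint = "jc1"
  )
  p <- ll2_response(grid$concentration, truth$ll2[["b"]], truth$ll2[["e"]])
  immobilization <- tibble(
    well_group = paste0(grid$experiment_id, "_",
                        format(grid$concentration, trim = TRUE)),
    concentration = grid$concentration,
    unit = truth$unit,
    n_exposed = truth$n_exposed_per_conc,
    n_immobile = rbinom(nrow(grid), truth$n_exposed_per_conc, p),
    experiment_id = grid$experiment_id,
    timepoint_h = truth$timepoint_h
  )
  list(jc1 = jc1, immobilization = immobilization)
}

#' Phantom image parameters
#'
#' Geometry, intensity and artifact settings of the synthetic well images.
#' The organism phantom is a two-ellipse body-and-head composite with
#' optional antenna strokes on a brighter transmitted-light background;
#' FITC carries a diffuse signal on the silhouette and Cy3 a punctate
#' signal whose silhouette mean is scaled so that the red/green ratio
#' equals the generating curve at the well's dose. Intensity defaults are
#' chosen for contrast on the 16-bit scale, not instrument realism.
#'
#' @param image_size_px Image height and width in pixels.
#' @param body_axes_px Semi-axes of the body ellipse in pixels. The default
#'   geometry gives a whole-organism footprint of about 3000 px.
#' @param head_radius_px Radius of the head disc.
#' @param antennae Draw two thin antenna strokes. Default `TRUE`.
#' @param tl_background,tl_contrast Transmitted-light background level and
#'   the amount by which the organism is darker.
#' @param tl_noise_sd Gaussian noise on the TL channel.
#' @param cy3_puncta_density Expected puncta per organism pixel.
#' @param cy3_puncta_sigma_px Gaussian width of a punctum.
#' @param cy3_base_frac Fraction of the Cy3 silhouette mean contributed by
#'   a diffuse base rather than puncta.
#' @param fitc_diffuse_intensity Diffuse FITC level on the silhouette.
#' @param channel_background Fluorescence background outside the organism.
#' @param control_ratio Raw red/green ratio of a healthy (control)
#'   organism; raw ratios are `control_ratio` times the normalized curve.
#' @param read_noise_sd Gaussian read noise on the fluorescence channels
#'   (0 disables).
#' @param shot_noise Add shot noise (Gaussian approximation of Poisson,
#'   sd = sqrt(intensity)). Default `TRUE`.
#' @param attenuation Fractional intensity attenuation of Cy3 puncta
#'   toward the body center, mimicking tissue translucency loss.
#' @param artifact_rates Named list of per-well probabilities:
#'   `saturated_patch`, `external_aggregate`, `empty_well`,
#'   `double_occupancy`.
#' @param saturated_patch_frac Fraction of the organism covered by an
#'   injected saturated patch.
#' @param z_levels Number of z-levels per well (default 10).
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(image_size_px = c(160, 160),
                           body_axes_px = c(39, 22),
                           head_radius_px = 11,
                           antennae = TRUE,
                           tl_background = 30000,
                           tl_contrast = 12000,
                           tl_noise_sd = 150,
                           cy3_puncta_density = 0.03,
                           cy3_puncta_sigma_px = 2,
                           cy3_base_frac = 0.3,
                           fitc_diffuse_intensity = 6000,
                           channel_background = 200,
                           control_ratio = 2,
                           read_noise_sd = 100,
                           shot_noise = TRUE,
                           attenuation = 0.4,
                           artifact_rates = list(saturated_patch = 0,
                                                 external_aggregate = 0,
                                                 empty_well = 0,
                                                 double_occupancy = 0),
                           saturated_patch_frac = 0.3,
                           z_levels = 10) {
  rates <- modifyList(list(saturated_patch = 0, external_aggregate = 0,
                           empty_well = 0, double_occupancy = 0),
                      artifact_rates)
  stopifnot(all(unlist(rates) >= 0), all(unlist(rates) <= 1), z_levels >= 1)
  structure(
    list(image_size_px = as.integer(image_size_px),
         body_axes_px = body_axes_px, head_radius_px = head_radius_px,
         antennae = isTRUE(antennae), tl_background = tl_background,
         tl_contrast = tl_contrast, tl_noise_sd = tl_noise_sd,
         cy3_puncta_density = cy3_puncta_density,
         cy3_puncta_sigma_px = cy3_puncta_sigma_px,
         cy3_base_frac = cy3_base_frac,
         fitc_diffuse_intensity = fitc_diffuse_intensity,
         channel_background = channel_background,
         control_ratio = control_ratio,
         read_noise_sd = read_noise_sd, shot_noise = isTRUE(shot_noise),
         attenuation = attenuation, artifact_rates = rates,
         saturated_patch_frac = saturated_patch_frac,
         z_levels = as.integer(z_levels)),
    class = "phantom_params"
  )
}

phantom_silhouette <- function(phantom, center, angle) {
  nr <- phantom$image_size_px[1]; nc <- phantom$image_size_px[2]
  a <- phantom$body_axes_px[1]; bb <- phantom$body_axes_px[2]
  if (2 * (a + phantom$head_radius_px) > min(nr, nc)) {
    abort("Organism phantom larger than the image.",
          class = "jc1_parameter_error")
  }
  xs <- matrix(rep(seq_len(nr), nc), nr, nc) - center[1]
  ys <- matrix(rep(seq_len(nc), each = nr), nr, nc) - center[2]
  u <- cos(angle) * xs + sin(angle) * ys
  v <- -sin(angle) * xs + cos(angle) * ys
  body <- (u / a)^2 + (v / bb)^2 <= 1
  hr <- phantom$head_radius_px
  hc <- c(a + 0.4 * hr, 0)  # head center on the major axis, mostly outside
  head <- (u - hc[1])^2 + (v - hc[2])^2 <= hr^2
  sil <- body | head
  if (phantom$antennae) {
    # two thin strokes leaving the head at +-40 degrees
    for (sgn in c(-1, 1)) {
      du <- u - (hc[1] + 0.6 * hr)
      dv <- v - sgn * 0.5 * hr
      dir <- c(cos(sgn * 0.7), sin(sgn * 0.7))
      proj <- du * dir[1] + dv * dir[2]
      perp <- abs(-du * dir[2] + dv * dir[1])
      sil <- sil | (proj >= 0 & proj <= 22 & perp <= 1.2)
    }
  }
  sil
}

disc_mask <- function(nr, nc, center, radius) {
  xs <- matrix(rep(seq_len(nr), nc), nr, nc) - center[1]
  ys <- matrix(rep(seq_len(nc), each = nr), nr, nc) - center[2]
  xs^2 + ys^2 <= radius^2
}

add_channel_noise <- function(img, phantom) {
  if (phantom$shot_noise) {
    img <- img + rnorm(length(img), 0, sqrt(pmax(img, 0)))
  }
  if (phantom$read_noise_sd > 0) {
    img <- img + rnorm(length(img), 0, phantom$read_noise_sd)
  }
  matrix(pmin(pmax(img, 0), 65535), nrow(img), ncol(img))
}

cy3_puncta_field <- function(sil, phantom, body_center) {
  nr <- nrow(sil); nc <- ncol(sil)
  idx <- which(sil)
  n_puncta <- rpois(1, phantom$cy3_puncta_density * length(idx))
  field <- matrix(0, nr, nc)
  if (n_puncta > 0) {
    centers <- sample(idx, n_puncta, replace = TRUE)
    ci <- (centers - 1) %% nr + 1
    cj <- (centers - 1) %/% nr + 1
    s <- phantom$cy3_puncta_sigma_px
    w <- ceiling(3 * s)
    for (k in seq_len(n_puncta)) {
      ii <- max(1, ci[k] - w):min(nr, ci[k] + w)
      jj <- max(1, cj[k] - w):min(nc, cj[k] + w)
      gx <- exp(-(ii - ci[k])^2 / (2 * s^2))
      gy <- exp(-(jj - cj[k])^2 / (2 * s^2))
      field[ii, jj] <- field[ii, jj] + outer(gx, gy)
    }
  }
  # attenuate toward the body center (deeper tissue is dimmer)
  xs <- matrix(rep(seq_len(nr), nc), nr, nc) - body_center[1]
  ys <- matrix(rep(seq_len(nc), each = nr), nr, nc) - body_center[2]
  dist <- sqrt(xs^2 + ys^2)
  dmax <- max(dist[sil], 1)
  atten <- 1 - phantom$attenuation * (1 - dist / dmax)
  field * atten
}

#' Generate one synthetic well stack
#'
#' Composes the TL/Cy3/FITC z-stack of a single well so that, in the
#' artifact-free and noise-free limit, the masked red/green ratio of every
#' z-level equals the generating curve at the well's dose. Artifacts are
#' injected per `phantom$artifact_rates`. Uses the current RNG state; seed
#' the session (or [generate_plate]) for reproducibility.
#'
#' @param dose Exposure concentration of this well.
#' @param truth A [simulation_truth] providing the JC-1 curve.
#' @param phantom A [phantom_params].
#' @param well_id Identifier for the stack.
#' @param normalized_ratio Optional override of the intended normalized
#'   ratio (used for dead-control wells); default is the LL4 curve value
#'   at `dose`.
#' @return List with `stack` (a [well_stack]) and `truth` (list with the
#'   ground-truth silhouette mask, occupancy, intended raw and normalized
#'   ratios).
#' @export
generate_well_stack <- function(dose, truth, phantom = phantom_params(),
                                well_id = "W01", normalized_ratio = NULL) {
  stopifnot(inherits(truth, "simulation_truth"),
            inherits(phantom, "phantom_params"))
  nr <- phantom$image_size_px[1]; nc <- phantom$image_size_px[2]
  rates <- phantom$artifact_rates
  occupancy <- 1L
  if (runif(1) < rates$empty_well) {
    occupancy <- 0L
  } else if (runif(1) < rates$double_occupancy) {
    occupancy <- 2L
  }
  r_norm <- normalized_ratio %||%
    ll4_response(dose, truth$ll4[["b"]], truth$ll4[["c"]], truth$ll4[["d"]],
                 truth$ll4[["e"]])
  # raw red/green target; control wells sit at control_ratio exactly
  r_raw <- phantom$control_ratio * r_norm / truth$ll4[["d"]]

  centers <- list(); angles <- list()
  if (occupancy >= 1) {
    jit <- runif(2, -6, 6)
    angle1 <- runif(1, 0, pi)
    if (occupancy == 1) {
      centers[[1]] <- c(nr / 2 + jit[1], nc / 2 + jit[2])
      angles[[1]] <- angle1
    } else {
      # two parallel organisms separated perpendicular to the body axis so
      # the silhouettes stay disjoint and inside the frame
      sep <- 1.3 * phantom$body_axes_px[2] + phantom$head_radius_px + 3
      perp <- c(-sin(angle1), cos(angle1)) * sep
      base <- c(nr / 2 + jit[1] / 2, nc / 2 + jit[2] / 2)
      centers[[1]] <- base - perp
      centers[[2]] <- base + perp
      angles[[1]] <- angle1
      angles[[2]] <- angle1
    }
  }
  sils <- purrr::map2(centers, angles, function(ctr, ang)
    phantom_silhouette(phantom, ctr, ang))
  sil_all <- Reduce(`|`, sils, matrix(FALSE, nr, nc))

  with_patch <- runif(1) < rates$saturated_patch && occupancy >= 1
  patch <- matrix(FALSE, nr, nc)
  if (with_patch) {
    r_patch <- sqrt(phantom$saturated_patch_frac * sum(sils[[1]]) / pi)
    patch <- disc_mask(nr, nc, centers[[1]], r_patch) & sil_all
  }
  with_agg <- runif(1) < rates$external_aggregate
  agg <- matrix(FALSE, nr, nc)
  if (with_agg) {
    for (try in 1:20) {
      ctr <- c(runif(1, 10, nr - 10), runif(1, 10, nc - 10))
      cand <- disc_mask(nr, nc, ctr, 6)
      if (!any(cand & sil_all)) { agg <- cand; break }
    }
  }

  z_levels <- vector("list", phantom$z_levels)
  for (k in seq_len(phantom$z_levels)) {
    tl <- matrix(phantom$tl_background, nr, nc)
    tl[sil_all] <- phantom$tl_background - phantom$tl_contrast
    tl[agg] <- phantom$tl_background - phantom$tl_contrast
    if (phantom$tl_noise_sd > 0) {
      tl <- tl + rnorm(length(tl), 0, phantom$tl_noise_sd)
    }
    tl <- matrix(pmin(pmax(tl, 0), 65535), nr, nc)

    fitc <- matrix(phantom$channel_background, nr, nc)
    fitc[sil_all] <- phantom$fitc_diffuse_intensity
    fitc[agg] <- 3000

    cy3 <- matrix(phantom$channel_background, nr, nc)
    if (occupancy >= 1) {
      target_mean <- r_raw * phantom$fitc_diffuse_intensity
      base <- phantom$cy3_base_frac * target_mean
      for (i in seq_along(sils)) {
        sil <- sils[[i]]
        punct <- cy3_puncta_field(sil, phantom, centers[[i]])
        raw <- base + punct[sil]
        # exact per-z scaling: silhouette mean hits the intended ratio
        cy3[sil] <- raw * target_mean / mean(raw)
      }
    }
    cy3[agg] <- 40000
    cy3 <- add_channel_noise(cy3, phantom)
    fitc <- add_channel_noise(fitc, phantom)
    cy3[patch] <- 65535
    z_levels[[k]] <- list(tl = tl, cy3 = cy3, fitc = fitc)
  }
  list(
    stack = well_stack(well_id, z_levels),
    truth = list(
      well_id = well_id, dose = dose, occupancy = occupancy,
      mask = sil_all,
      area_px = if (occupancy >= 1) sum(sils[[1]]) else 0L,
      intended_ratio_raw = if (occupancy >= 1) r_raw else NA_real_,
      intended_ratio_normalized = if (occupancy >= 1) r_norm else NA_real_,
      saturated_patch = with_patch, external_aggregate = with_agg
    )
  )
}

#' Generate a full synthetic plate
#'
#' One stack per layout row, using each well's concentration (dose 0 for
#' controls; the dead-control intended normalized ratio is the LL4 floor
#' `c`). Optionally writes TIFFs in the `<well>_z<k>_<channel>.tif` naming
#' convention together with `layout.csv`, `immobilization.csv` and a
#' `truth.json` manifest, or streams stacks to a callback for in-memory
#' analysis.
#'
#' @param layout A [plate_layout]; one stack is generated per row.
#' @param truth A [simulation_truth].
#' @param phantom A [phantom_params].
#' @param dir Output directory; required when `write = TRUE`.
#' @param seed Integer seed; when given, the RNG is seeded so regeneration
#'   is identical.
#' @param write Write TIFFs and metadata files (default `TRUE`).
#' @param force Overwrite a non-empty output directory.
#' @param on_stack Optional callback `function(stack, truth_row)` invoked
#'   per generated stack (stacks are not retained in memory).
#' @return Invisibly, a list with `manifest` (per-well truth tibble),
#'   `immobilization` (simulated counts for treatment series) and `dir`.
#' @export
generate_plate <- function(layout, truth, phantom = phantom_params(),
                           dir = NULL, seed = NULL, write = TRUE,
                           force = FALSE, on_stack = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  lay <- as_tibble(layout)
  if (write) {
    if (is.null(dir)) {
      abort("An output directory is required when write = TRUE.",
            class = "jc1_io_error")
    }
    if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
      abort(paste0("Output directory is not empty: ", dir,
                   " (use force = TRUE to overwrite)."),
            class = "jc1_io_error")
    }
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", nrow(lay))
  for (i in seq_len(nrow(lay))) {
    row <- lay[i, ]
    r_norm <- if (row$role == "dead_control") truth$ll4[["c"]] else NULL
    gen <- generate_well_stack(row$concentration, truth, phantom,
                               well_id = row$well_id,
                               normalized_ratio = r_norm)
    if (write) write_well_stack(gen$stack, dir)
    if (!is.null(on_stack)) on_stack(gen$stack, gen$truth)
    tr <- gen$truth
    rows[[i]] <- tibble(
      well_id = tr$well_id, dose = tr$dose, role = row$role,
      experiment_id = row$experiment_id, timepoint_h = row$timepoint_h,
      occupancy = tr$occupancy, area_px = tr$area_px,
      intended_ratio_raw = tr$intended_ratio_raw,
      intended_ratio_normalized = tr$intended_ratio_normalized,
      saturated_patch = tr$saturated_patch,
      external_aggregate = tr$external_aggregate
    )
  }
  manifest <- dplyr::bind_rows(rows)

  trt <- lay[lay$role %in% c("treatment", "control", "solvent_control"), ]
  cells <- dplyr::summarise(
    dplyr::group_by(trt, .data$experiment_id, .data$timepoint_h,
                    .data$concentration, .data$unit),
    n_exposed = sum(.data$n_individuals), .groups = "drop"
  )
  p <- ll2_response(cells$concentration, truth$ll2[["b"]], truth$ll2[["e"]])
  immobilization <- tibble(
    well_group = paste0(cells$experiment_id, "_",
                        format(cells$concentration, trim = TRUE)),
    concentration = cells$concentration,
    unit = cells$unit,
    n_exposed = as.integer(cells$n_exposed),
    n_immobile = rbinom(nrow(cells), cells$n_exposed, p),
    experiment_id = cells$experiment_id,
    timepoint_h = cells$timepoint_h
  )

  if (write) {
    write_plate_layout(plate_layout(lay), file.path(dir, "layout.csv"))
    write_immobilization(immobilization, file.path(dir, "immobilization.csv"))
    manifest_json <- list(
      seed = seed, ll4 = as.list(truth$ll4), ll2 = as.list(truth$ll2),
      unit = truth$unit,
      wells = manifest[setdiff(names(manifest), "mask")]
    )
    jsonlite::write_json(manifest_json, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(manifest = manifest, immobilization = immobilization,
                 dir = dir))
}

#' Build a per-individual plate layout for a simulated study
#'
#' Expands a design (one compound, a concentration series, controls and
#' dead controls, several experiments) into one layout row per imaging
#' well, i.e. one organism per row, following the one-individual-per-well
#' imaging format.
#'
#' @param compound Compound label.
#' @param concentrations Positive treatment concentrations.
#' @param unit Concentration unit.
#' @param n_per_group Individuals per concentration per experiment.
#' @param n_experiments Number of independent experiments.
#' @param timepoint_h Exposure duration in hours.
#' @param n_control,n_solvent,n_dead Individuals per control group per
#'   experiment.
#' @return A [plate_layout] with one row per imaging well.
#' @export
design_layout <- function(compound, concentrations, unit = "ug/L",
                          n_per_group = 5, n_experiments = 3,
                          timepoint_h = 24, n_control = 5, n_solvent = 5,
                          n_dead = 5) {
  rows <- list()
  for (ex in seq_len(n_experiments)) {
    eid <- sprintf("E%d", ex)
    groups <- list(
      list(role = "control", conc = 0, n = n_control, tag = "CTRL"),
      list(role = "solvent_control", conc = 0, n = n_solvent, tag = "SOLV"),
      list(role = "dead_control", conc = 0, n = n_dead, tag = "DEAD")
    )
    for (ci in seq_along(concentrations)) {
      groups[[length(groups) + 1]] <- list(role = "treatment",
                                           conc = concentrations[ci],
                                           n = n_per_group,
                                           tag = sprintf("T%02d", ci))
    }
    for (g in groups) {
      if (g$n < 1) next
      for (k in seq_len(g$n)) {
        rows[[length(rows) + 1]] <- tibble(
          well_id = sprintf("%s_%s_i%d", eid, g$tag, k),
          compound = compound, concentration = g$conc, unit = unit,
          role = g$role, experiment_id = eid, timepoint_h = timepoint_h,
          n_individuals = 1L
        )
      }
    }
  }
  plate_layout(dplyr::bind_rows(rows))
}
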