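#' Channels acquired per z-level
#' @keywords internal
stack_channels <- c("TL", "CY3", "FITC")

stack_file_regex <- "^(.+)_z([0-9]+)_(TL|CY3|FITC)\\.tiff?$"

#' Build a well stack from in-memory images
#'
#' A well stack is the ordered z-series of co-registered transmitted-light
#' (TL), Cy3 (J-aggregate, red) and FITC (monomer, green) images for one
#' imaging well containing one organism.
#'
#' @param well_id Well identifier.
#' @param z_levels List, one element per z-level, each a list with numeric
#'   matrices `tl`, `cy3`, `fitc` of identical dimensions, intensities in
#'   `[0, 65535]`.
#' @param z_spacing_um Spacing between z-levels in micrometres (default 15).
#' @param pixel_size_um Pixel size in micrometres (default 3.25, the 4x
#'   objective geometry).
#' @return An object of class `well_stack`.
#' @export
well_stack <- function(well_id, z_levels, z_spacing_um = 15,
                       pixel_size_um = 3.25) {
  if (length(z_levels) < 1) {
    abort("A well stack needs at least one z-level.", class = "jc1_stack_error")
  }
  dims <- NULL
  for (k in seq_along(z_levels)) {
    lev <- z_levels[[k]]
    if (!all(c("tl", "cy3", "fitc") %in% names(lev))) {
      abort(paste0("z-level ", k, " lacks a tl/cy3/fitc image."),
            class = "jc1_stack_error")
    }
    for (ch in c("tl", "cy3", "fitc")) {
      img <- lev[[ch]]
      if (!is.matrix(img)) {
        abort(paste0("z-level ", k, " channel ", ch, " is not a matrix."),
              class = "jc1_stack_error")
      }
      if (is.null(dims)) dims <- dim(img)
      if (!identical(dim(img), dims)) {
        abort(paste0("Dimension mismatch at z-level ", k, " channel ", ch,
                     " of well ", well_id, "."),
              class = "jc1_stack_error")
      }
      rng <- range(img, na.rm = TRUE)
      if (rng[1] < 0 || rng[2] > 65535) {
        abort(paste0("Intensities outside [0, 65535] at z-level ", k,
                     " channel ", ch, "."), class = "jc1_stack_error")
      }
    }
  }
  structure(
    list(well_id = well_id, z_levels = z_levels,
         z_spacing_um = z_spacing_um, pixel_size_um = pixel_size_um),
    class = "well_stack"
  )
}

#' @export
print.well_stack <- function(x, ...) {
  d <- dim(x$z_levels[[1]]$tl)
  cat("<well_stack> ", x$well_id, ": ", length(x$z_levels),
      " z-level(s) of ", d[1], "x", d[2], " px, dz = ",
      x$z_spacing_um, " um\n", sep = "")
  invisible(x)
}

#' Discover well stacks in an image directory
#'
#' Files are expected to follow the convention `<well>_z<k>_<channel>.tif`
#' with channel in `TL`, `CY3`, `FITC` and 1-based z index, mirroring the
#' per-site/per-channel export style of high-content screening instruments.
#'
#' @param directory Directory to scan (not recursive).
#' @return A named list, one element per well, each a tibble with columns
#'   `z`, `tl`, `cy3`, `fitc` (file paths), ordered by ascending z.
#' @export
discover_well_stacks <- function(directory) {
  if (!dir.exists(directory)) {
    abort(paste0("Image directory not found: ", directory),
          class = "jc1_io_error")
  }
  files <- list.files(directory, pattern = stack_file_regex)
  if (length(files) == 0) return(list())
  m <- regmatches(files, regexec(stack_file_regex, files))
  tab <- tibble(
    path = file.path(directory, files),
    well_id = vapply(m, `[[`, "", 2),
    z = as.integer(vapply(m, `[[`, "", 3)),
    channel = vapply(m, `[[`, "", 4)
  )
  out <- list()
  for (w in sort(unique(tab$well_id))) {
    sub <- tab[tab$well_id == w, , drop = FALSE]
    wide <- tidyr::pivot_wider(sub, id_cols = "z", names_from = "channel",
                               values_from = "path")
    for (ch in stack_channels) {
      if (!ch %in% names(wide) || anyNA(wide[[ch]])) {
        abort(paste0("Incomplete stack for well ", w,
                     ": missing ", ch, " file(s)."),
              class = "jc1_incomplete_stack_error")
      }
    }
    wide <- wide[order(wide$z), ]
    out[[w]] <- tibble(z = wide$z, tl = wide$TL, cy3 = wide$CY3,
                       fitc = wide$FITC)
  }
  out
}

read_tiff_16 <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  bits <- attr(img, "bits.per.sample") %||% 16L
  if (length(dim(img)) == 3) {
    # grayscale stored with a singleton channel dimension
    img <- img[, , 1]
  }
  img <- matrix(as.numeric(img), nrow(img), ncol(img))
  if (bits == 8) {
    warn(paste0("8-bit image rescaled to the 16-bit range: ", basename(path)))
    img <- img * 257  # 255 * 257 = 65535
  } else if (bits != 16) {
    abort(paste0("Unsupported bit depth (", bits, "): ", path),
          class = "jc1_io_error")
  }
  img
}

#' Read one well stack from disk
#'
#' @param files A per-well tibble as returned by [discover_well_stacks]
#'   (columns `z`, `tl`, `cy3`, `fitc`), or a character vector of paths
#'   following the naming convention.
#' @param well_id Optional well id; inferred from file names if omitted.
#' @inheritParams well_stack
#' @return A [well_stack].
#' @export
read_well_stack <- function(files, well_id = NULL, z_spacing_um = 15,
                            pixel_size_um = 3.25) {
  if (is.character(files)) {
    dirpath <- unique(dirname(files))
    base <- basename(files)
    m <- regmatches(base, regexec(stack_file_regex, base))
    ok <- lengths(m) == 4
    if (!all(ok)) {
      abort("Some file names do not follow <well>_z<k>_<channel>.tif.",
            class = "jc1_io_error")
    }
    tab <- tibble(
      path = files,
      well_id = vapply(m, `[[`, "", 2),
      z = as.integer(vapply(m, `[[`, "", 3)),
      channel = vapply(m, `[[`, "", 4)
    )
    if (length(unique(tab$well_id)) != 1) {
      abort("Files belong to more than one well.", class = "jc1_io_error")
    }
    well_id <- well_id %||% tab$well_id[1]
    files <- tidyr::pivot_wider(tab, id_cols = "z", names_from = "channel",
                                values_from = "path")
    for (ch in stack_channels) {
      if (!ch %in% names(files) || anyNA(files[[ch]])) {
        abort(paste0("Incomplete stack for well ", well_id, "."),
              class = "jc1_incomplete_stack_error")
      }
    }
    files <- tibble(z = files$z, tl = files$TL, cy3 = files$CY3,
                    fitc = files$FITC)
  }
  files <- files[order(files$z), ]
  if (is.null(well_id)) {
    base <- basename(files$tl[1])
    well_id <- sub(stack_file_regex, "\\1", base)
  }
  z_levels <- purrr::pmap(files, function(z, tl, cy3, fitc) {
    list(tl = read_tiff_16(tl), cy3 = read_tiff_16(cy3),
         fitc = read_tiff_16(fitc))
  })
  well_stack(well_id, z_levels, z_spacing_um = z_spacing_um,
             pixel_size_um = pixel_size_um)
}

#' Write a well stack as single-plane 16-bit TIFF files
#'
#' @param stack A [well_stack].
#' @param directory Output directory (created if absent).
#' @return Character vector of written paths, invisibly.
#' @export
write_well_stack <- function(stack, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  paths <- character(0)
  for (k in seq_along(stack$z_levels)) {
    lev <- stack$z_levels[[k]]
    for (ch in c("tl", "cy3", "fitc")) {
      p <- file.path(directory, sprintf("%s_z%d_%s.tif", stack$well_id, k,
                                        toupper(ch)))
      img <- pmin(pmax(round(lev[[ch]]), 0), 65535)
      tiff::writeTIFF(img / 65535, p, bits.per.sample = 16L,
                      compression = "none")
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
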