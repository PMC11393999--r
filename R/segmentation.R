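#' Segmentation parameters
#'
#' Controls the brightness-difference organism segmentation applied to each
#' transmitted-light (TL) image. The organism appears as a contiguous region
#' whose brightness deviates from the well background; the background level
#' is estimated as the median of a border band of the image, and pixels are
#' classified by an Otsu threshold on the absolute deviation image.
#'
#' @param smoothing_sigma_px Gaussian smoothing applied to the TL image
#'   before thresholding, in pixels (0 disables smoothing). Default 2.
#' @param min_object_area_px Connected components smaller than this many
#'   pixels are discarded; rejects small extra-organismal dye aggregates.
#'   Default 500 at the 4x geometry.
#' @param closing_radius_px Radius of the disc structuring element used for
#'   morphological closing (0 disables). Default 3.
#' @param fill_holes Fill enclosed holes in each component. Default `TRUE`.
#' @param polarity `"dark_object"` if the organism is darker than the well
#'   background (the usual transmitted-light appearance), `"bright_object"`
#'   otherwise. The deviation is thresholded in absolute value, so polarity
#'   only restricts which side of the background qualifies.
#' @param border_band_px Width of the image border band used for the
#'   background median. Default 8.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(smoothing_sigma_px = 2,
                                min_object_area_px = 500,
                                closing_radius_px = 3,
                                fill_holes = TRUE,
                                polarity = c("dark_object", "bright_object"),
                                border_band_px = 8) {
  polarity <- match.arg(polarity)
  stopifnot(smoothing_sigma_px >= 0, min_object_area_px >= 0,
            closing_radius_px >= 0, border_band_px >= 1)
  structure(
    list(smoothing_sigma_px = smoothing_sigma_px,
         min_object_area_px = as.integer(min_object_area_px),
         closing_radius_px = as.integer(closing_radius_px),
         fill_holes = isTRUE(fill_holes),
         polarity = polarity,
         border_band_px = as.integer(border_band_px)),
    class = "segmentation_params"
  )
}

label_components <- function(mask) {
  mask[is.na(mask)] <- FALSE
  .label_components8(mask)
}

#' Segment the organism from a transmitted-light image
#'
#' Implements the brightness-difference rule: the TL image is Gaussian
#' smoothed, the well background is estimated as the median of the image
#' border band, and pixels whose deviation from the background exceeds an
#' Otsu-derived threshold on the absolute deviation image are classified as
#' organism. Morphological closing, optional hole filling and a minimum
#' component area filter then clean the mask. Components are labelled with
#' 8-connectivity; `segment_count` is reported before any component
#' selection and the returned mask is the union of all surviving
#' components — a count other than 1 flags the z-layer as incorrect rather
#' than being repaired.
#'
#' @param tl Numeric matrix of transmitted-light intensities.
#' @param params A [segmentation_params] object.
#' @param z_index Optional z-index stored in the result.
#' @return An object of class `organism_mask`: list with `mask` (logical
#'   matrix), `segment_count`, `area_px` and `z_index`. A constant
#'   (zero-contrast) image yields an empty mask with `segment_count` 0.
#' @export
segment_organism <- function(tl, params = segmentation_params(),
                             z_index = NA_integer_) {
  stopifnot(is.matrix(tl))
  if (!all(is.finite(tl))) {
    abort("TL image contains non-finite values.", class = "jc1_segmentation_error")
  }
  img <- tl
  if (params$smoothing_sigma_px > 0) {
    # gblur needs the kernel to fit inside the image
    ksize <- 2 * ceiling(3 * params$smoothing_sigma_px) + 1
    if (ksize <= min(dim(img))) {
      img <- EBImage::gblur(img, sigma = params$smoothing_sigma_px)
      img <- img[seq_len(nrow(tl)), seq_len(ncol(tl)), drop = FALSE]
      img <- matrix(as.numeric(img), nrow(tl), ncol(tl))
    }
  }
  nr <- nrow(img); nc <- ncol(img)
  band <- min(params$border_band_px, floor(min(nr, nc) / 2))
  border_sel <- matrix(FALSE, nr, nc)
  border_sel[c(seq_len(band), nr - seq_len(band) + 1), ] <- TRUE
  border_sel[, c(seq_len(band), nc - seq_len(band) + 1)] <- TRUE
  bg <- median(img[border_sel])
  dev_img <- abs(img - bg)
  if (max(dev_img) <= 0) {
    return(organism_mask(matrix(FALSE, nrow(tl), ncol(tl)), 0L, z_index))
  }
  thr <- EBImage::otsu(EBImage::Image(dev_img / max(dev_img)),
                       range = c(0, 1)) * max(dev_img)
  # an object must stand out from the background noise: if the Otsu split
  # lies within the noise floor of the border band, the well is empty
  noise_floor <- 5 * stats::mad(img[border_sel], center = bg)
  if (thr <= noise_floor) {
    return(organism_mask(matrix(FALSE, nrow(tl), ncol(tl)), 0L, z_index))
  }
  cand <- dev_img > thr
  if (params$polarity == "dark_object") {
    cand <- cand & (img < bg)
  } else {
    cand <- cand & (img > bg)
  }
  if (params$closing_radius_px > 0) {
    brush <- EBImage::makeBrush(2 * params$closing_radius_px + 1,
                                shape = "disc")
    cand <- EBImage::closing(cand * 1, brush) > 0
  }
  if (params$fill_holes) {
    cand <- EBImage::fillHull(cand * 1) > 0
  }
  lab <- label_components(cand)
  keep <- matrix(FALSE, nrow(tl), ncol(tl))
  n_keep <- 0L
  if (max(lab) > 0) {
    sizes <- tabulate(lab, nbins = max(lab))
    surviving <- which(sizes >= params$min_object_area_px)
    n_keep <- length(surviving)
    if (n_keep > 0) keep <- matrix(lab %in% surviving, nrow(tl), ncol(tl))
  }
  organism_mask(keep, n_keep, z_index)
}

#' Construct an organism mask
#'
#' @param mask Logical matrix, `TRUE` on the organism.
#' @param segment_count Number of connected components surviving the size
#'   filter (before any selection).
#' @param z_index z-level the mask belongs to.
#' @return An object of class `organism_mask`.
#' @export
organism_mask <- function(mask, segment_count, z_index = NA_integer_) {
  stopifnot(is.matrix(mask), is.logical(mask))
  structure(
    list(mask = mask, segment_count = as.integer(segment_count),
         area_px = as.integer(sum(mask)), z_index = as.integer(z_index)),
    class = "organism_mask"
  )
}

#' @export
print.organism_mask <- function(x, ...) {
  cat("<organism_mask> ", x$segment_count, " segment(s), area ",
      x$area_px, " px\n", sep = "")
  invisible(x)
}

#' Is a z-level's segmentation correct?
#'
#' One organism is placed per imaging well, so only a segment count of
#' exactly 1 is correct: 0 means the outline was not found, more than 1
#' means extra organisms or artifacts were segmented.
#'
#' @param mask An [organism_mask].
#' @return `TRUE` iff `segment_count == 1`.
#' @export
z_level_correct <- function(mask) {
  stopifnot(inherits(mask, "organism_mask"))
  mask$segment_count == 1L
}

#' Write a boolean mask as a TIFF for debugging
#'
#' @param mask An [organism_mask].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(mask$mask * 1, path, bits.per.sample = 8L)
  invisible(path)
}
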