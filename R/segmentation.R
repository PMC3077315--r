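# Static ROI workflow: min-max normalize the magnitude image, threshold,
# pick the 4-connected component under a seed, extract the perimeter for QC.
# Pixel-center membership only; no sub-pixel boundary refinement, consistent
# with the flow-rate estimator.

#' Min-max normalize an image to \[0, 1\]
#'
#' Applied before thresholding so the printed 0.60 threshold transfers
#' between acquisitions.
#'
#' @param image numeric matrix.
#' @return matrix rescaled to \[0, 1\]; a constant image maps to all zeros.
#' @export
normalize_image <- function(image) {
  rng <- range(image)
  if (diff(rng) == 0) return(image * 0)
  (image - rng[1]) / diff(rng)
}

#' Threshold a magnitude image
#'
#' @param magnitude numeric matrix (finite values).
#' @param threshold fraction in the normalized intensity scale.
#' @param normalize min-max normalize first (default TRUE).
#' @return logical matrix, TRUE where intensity > threshold.
#' @export
threshold_image <- function(magnitude, threshold, normalize = TRUE) {
  if (any(!is.finite(magnitude)))
    stop("magnitude image must be finite", call. = FALSE)
  if (normalize) magnitude <- normalize_image(magnitude)
  magnitude > threshold
}

# 4-connected flood fill by iterative frontier dilation
flood_fill4 <- function(binary, seed_pixel) {
  n <- dim(binary)
  comp <- matrix(FALSE, n[1], n[2])
  comp[seed_pixel[1], seed_pixel[2]] <- TRUE
  repeat {
    grown <- comp
    grown[-1, ] <- grown[-1, ] | comp[-n[1], ]
    grown[-n[1], ] <- grown[-n[1], ] | comp[-1, ]
    grown[, -1] <- grown[, -1] | comp[, -n[2]]
    grown[, -n[2]] <- grown[, -n[2]] | comp[, -1]
    grown <- grown & binary
    if (identical(grown, comp)) break
    comp <- grown
  }
  comp
}

# perimeter: TRUE pixels with at least one FALSE 4-neighbor (image border
# counts as FALSE)
perimeter_pixels <- function(mask) {
  n <- dim(mask)
  pad <- matrix(FALSE, n[1] + 2, n[2] + 2)
  pad[2:(n[1] + 1), 2:(n[2] + 1)] <- mask
  core <- pad[2:(n[1] + 1), 2:(n[2] + 1)]
  nb_all <- pad[1:n[1], 2:(n[2] + 1)] & pad[3:(n[1] + 2), 2:(n[2] + 1)] &
    pad[2:(n[1] + 1), 1:n[2]] & pad[2:(n[1] + 1), 3:(n[2] + 2)]
  core & !nb_all
}

#' Region-of-interest mask
#'
#' A single 4-connected set of pixels representing the flow-crossing portion
#' of the control surface, with its pixel count, physical area and perimeter.
#'
#' @param mask logical matrix, a single 4-connected component.
#' @param pixel_spacing pixel spacing, cm.
#' @param threshold_used threshold that produced the mask (NA if n/a).
#' @return object of class `roi_mask` with fields `mask`, `pixel_count`,
#'   `area` (= count * spacing^2, cm^2), `perimeter_pixels` (n x 2 matrix of
#'   row/col indices), `pixel_spacing`, `threshold_used`.
#' @export
roi_mask <- function(mask, pixel_spacing, threshold_used = NA_real_) {
  if (!is.logical(mask) || is.null(dim(mask)))
    stop("mask must be a logical matrix", call. = FALSE)
  if (!any(mask)) stop("empty-ROI error: mask has no pixels", call. = FALSE)
  per <- which(perimeter_pixels(mask), arr.ind = TRUE)
  structure(
    list(mask = mask,
         pixel_count = sum(mask),
         area = sum(mask) * pixel_spacing^2,
         perimeter_pixels = per,
         pixel_spacing = pixel_spacing,
         threshold_used = threshold_used),
    class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask: N = %d pixels, area %.4g cm^2, %d perimeter pixels>\n",
              x$pixel_count, x$area, nrow(x$perimeter_pixels)))
  invisible(x)
}

#' Select the connected region under a seed pixel
#'
#' Returns the 4-connected component of a thresholded image containing the
#' seed pixel -- the programmatic analogue of the operator clicking on the
#' bright lumen region.
#'
#' @param binary logical matrix from [threshold_image()].
#' @param seed_pixel length-2 integer `c(row, col)` inside the grid.
#' @param pixel_spacing pixel spacing, cm.
#' @param threshold_used recorded for provenance.
#' @return an [roi_mask()].
#' @export
select_region <- function(binary, seed_pixel, pixel_spacing,
                          threshold_used = NA_real_) {
  n <- dim(binary)
  if (length(seed_pixel) != 2 || any(seed_pixel < 1) ||
      seed_pixel[1] > n[1] || seed_pixel[2] > n[2])
    stop("invalid parameter: seed_pixel outside the grid", call. = FALSE)
  if (!binary[seed_pixel[1], seed_pixel[2]])
    stop("no-component error: seed pixel is not foreground", call. = FALSE)
  roi_mask(flood_fill4(binary, seed_pixel), pixel_spacing, threshold_used)
}

#' Overlay the ROI perimeter on a magnitude image
#'
#' QC image mirroring the final segmentation check: the magnitude image with
#' the ROI perimeter pixels replaced by a sentinel intensity.
#'
#' @param mask an [roi_mask()].
#' @param magnitude numeric matrix, same shape as the mask.
#' @param sentinel value marking perimeter pixels; defaults to
#'   `max(magnitude) + 1`.
#' @return numeric matrix.
#' @export
perimeter_overlay <- function(mask, magnitude, sentinel = NULL) {
  stopifnot(inherits(mask, "roi_mask"))
  if (!identical(dim(mask$mask), dim(magnitude)))
    stop("configuration error: mask and magnitude shapes differ", call. = FALSE)
  if (is.null(sentinel)) sentinel <- max(magnitude) + 1
  magnitude[mask$perimeter_pixels] <- sentinel
  magnitude
}

#' Segment a static ROI from a velocity series
#'
#' Convenience wrapper chaining the workflow on a gated series: build a
#' single magnitude frame (temporal mean by default, more robust under
#' noise; or one chosen frame), normalize, threshold, and select the
#' component under the seed (defaults to the grid center, where the lumen
#' sits in the synthetic phantom).
#'
#' @param series a [velocity_series()].
#' @param threshold normalized intensity threshold (default 0.60).
#' @param seed_pixel `c(row, col)`; default grid center.
#' @param frame "mean" (default) or an integer phase index for the
#'   single-frame, best-contrast variant.
#' @return an [roi_mask()].
#' @export
segment_series <- function(series, threshold = 0.60, seed_pixel = NULL,
                           frame = "mean") {
  stopifnot(inherits(series, "velocity_series"))
  mag <- if (identical(frame, "mean")) {
    apply(series$magnitude, c(1, 2), mean)
  } else {
    series$magnitude[, , as.integer(frame)]
  }
  if (is.null(seed_pixel)) {
    n <- dim(mag)
    seed_pixel <- c(floor(n[1] / 2) + 1, floor(n[2] / 2) + 1)
  }
  bin <- threshold_image(mag, threshold)
  select_region(bin, seed_pixel, series$acquisition$pixel_spacing,
                threshold_used = threshold)
}
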