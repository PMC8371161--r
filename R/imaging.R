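#' Machine-vision measurement of egg axes
#'
#' The image path from raster to metric axes: median denoising and
#' grayscale conversion, Otsu segmentation with largest-component and
#' hole-fill cleanup, principal-axis Feret extents in pixels, and the
#' pixel-to-millimetre conversion. Designed for the high-contrast regime of
#' a top-down camera over a matte dark enclosure: a single bright convex
#' egg on a darker background.
#'
#' All rasters are numeric matrices with intensities in [0, 1]
#' (the EBImage convention); pixel coordinates are 0-based (row, col) and
#' extents are inclusive pixel counts, so a blob spanning columns 10..19
#' has extent 10 px.
#'
#' @name imaging
NULL

#' Convert an image to a clean grayscale raster
#'
#' Collapses colour channels to luminance if needed, clips intensities to
#' [0, 1] and applies a square median filter (default 3x3) to suppress
#' shot noise without moving the contour. On a pure-noise background the
#' filter never increases the intensity standard deviation; a uniform
#' image passes through unchanged.
#'
#' @param raster An `EBImage::Image` (colour or grayscale), a numeric
#'   matrix, or a rows x cols x channels array with values in [0, 1].
#' @param median_radius Median filter radius in pixels; 1 gives the default
#'   3x3 window, 0 disables filtering.
#' @return A numeric matrix in [0, 1] with the input's spatial dimensions.
#' @export
preprocess <- function(raster, median_radius = 1) {
  if (inherits(raster, "Image")) {
    if (EBImage::colorMode(raster) == EBImage::Color) {
      raster <- EBImage::channel(raster, "gray")
    }
    raster <- EBImage::imageData(raster)
  }
  if (is.array(raster) && length(dim(raster)) == 3) {
    # average remaining channels to luminance-like gray
    raster <- apply(raster, c(1, 2), mean)
  }
  if (!is.matrix(raster) || !is.numeric(raster) || any(dim(raster) < 1)) {
    stop("`raster` must be a non-empty 2-D numeric image", call. = FALSE)
  }
  gray <- pmin(pmax(raster, 0), 1)
  # a constant image is its own median; skipping avoids the filter's
  # 16-bit requantisation of the uniform level
  if (median_radius > 0 && diff(range(gray)) > 0) {
    gray <- EBImage::imageData(
      EBImage::medianFilter(EBImage::Image(gray), as.integer(median_radius)))
  }
  gray
}

#' Segment the egg from a grayscale raster
#'
#' Global Otsu threshold, then keep the largest connected foreground
#' component and fill its interior holes. Fails with a "no egg detected"
#' error when thresholding yields no foreground (e.g. a blank frame);
#' warns when the foreground touches the image border, which usually means
#' the egg is truncated.
#'
#' @param gray Numeric matrix in [0, 1], typically from [preprocess()].
#' @return A list of class `egg_segmentation`: `mask` (logical matrix),
#'   `length_px`, `breadth_px`, `orientation` (degrees), `centroid`
#'   (0-based row, col), `area` (pixels), `threshold` (Otsu level).
#' @export
segment_egg <- function(gray) {
  if (!is.matrix(gray) || !is.numeric(gray) || any(dim(gray) < 2)) {
    stop("`gray` must be a numeric matrix with at least 2x2 pixels",
         call. = FALSE)
  }
  if (diff(range(gray)) == 0) {
    stop("no egg detected: image has no contrast", call. = FALSE)
  }
  thr <- EBImage::otsu(EBImage::Image(gray))
  mask <- gray > thr
  if (!any(mask)) stop("no egg detected: empty foreground after thresholding",
                       call. = FALSE)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  mask <- EBImage::imageData(lab) == which.max(sizes)
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
  if (any(mask[1, ]) || any(mask[nrow(mask), ]) ||
      any(mask[, 1]) || any(mask[, ncol(mask)])) {
    warning("foreground touches the image border: egg may be truncated",
            call. = FALSE)
  }
  ax <- measure_axes(mask)
  structure(list(mask = mask,
                 length_px = ax$length_px, breadth_px = ax$breadth_px,
                 orientation = ax$orientation, centroid = ax$centroid,
                 area = sum(mask), threshold = thr),
            class = "egg_segmentation")
}

#' @export
print.egg_segmentation <- function(x, ...) {
  cat(sprintf("<egg_segmentation> %.1f x %.1f px at %.1f deg, area %d px\n",
              x$length_px, x$breadth_px, x$orientation, x$area))
  invisible(x)
}

#' Principal-axis extents of a binary mask
#'
#' Orientation is taken from the second central moments of the foreground
#' pixel coordinates; the length is the Feret (maximal) extent of pixel
#' centres along that axis and the breadth the maximal extent along the
#' perpendicular, both as inclusive pixel counts. Axes are swapped if
#' needed so that length >= breadth, making the result rotation-invariant
#' to within about a pixel.
#'
#' @param mask Logical (or 0/1 numeric) matrix with at least one foreground
#'   pixel.
#' @return List with `length_px`, `breadth_px`, `orientation` (degrees of
#'   the major axis, measured from the column direction in (col, row)
#'   space), `centroid` (0-based row, col of the foreground mean).
#' @export
measure_axes <- function(mask) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("`mask` has no foreground pixels", call. = FALSE)
  y <- idx[, 1] - 1   # row
  x <- idx[, 2] - 1   # col
  cx <- mean(x); cy <- mean(y)
  dx <- x - cx; dy <- y - cy
  mu20 <- mean(dx^2); mu02 <- mean(dy^2); mu11 <- mean(dx * dy)
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  pu <- dx * cos(theta) + dy * sin(theta)
  pv <- -dx * sin(theta) + dy * cos(theta)
  len <- diff(range(pu)) + 1
  brd <- diff(range(pv)) + 1
  if (brd > len) {
    tmp <- len; len <- brd; brd <- tmp
    theta <- theta + pi / 2
  }
  list(length_px = len, breadth_px = brd,
       orientation = (theta * 180 / pi) %% 180,
       centroid = c(row = cy, col = cx))
}

#' Measure an egg image in millimetres
#'
#' Full composition of the vision path: [preprocess()], [segment_egg()],
#' [measure_axes()] and the calibration scale, returning an
#' [egg_measurement()] ready for grading. The segmentation is attached as
#' attribute `"segmentation"`.
#'
#' @param raster Image as accepted by [preprocess()], or a file path to a
#'   PNG/TIFF read via `EBImage::readImage`.
#' @param profile A `calibration_profile`.
#' @param weight Egg weight in grams (from the scale; images carry no mass).
#' @param median_radius Passed to [preprocess()].
#' @return An [egg_measurement()] with length and breadth in mm.
#' @export
measure_image <- function(raster, profile, weight, median_radius = 1) {
  stopifnot(inherits(profile, "calibration_profile"))
  if (is.character(raster)) {
    raster <- EBImage::readImage(raster)
  }
  seg <- segment_egg(preprocess(raster, median_radius = median_radius))
  meas <- egg_measurement(weight = weight,
                          length = seg$length_px * profile$mm_per_px,
                          breadth = seg$breadth_px * profile$mm_per_px)
  attr(meas, "segmentation") <- seg
  meas
}
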