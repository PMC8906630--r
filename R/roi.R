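# Skin images and circular region-of-interest reduction.

.breast_levels <- c("irradiated", "unirradiated")
.site_levels <- c("upper", "lower", "inner", "outer")
.time_levels <- c("RT_before", "RT_7days", "RT_14days", "RT_after")

#' Closed vocabularies of the longitudinal design
#'
#' Breast (irradiated vs unirradiated control), measurement site around the
#' nipple, and longitudinal time point (baseline, ~7 and ~14 days after the
#' first fraction, and ~10 days after completing radiotherapy).
#' @return Named list of character vectors.
#' @export
study_levels <- function() {
  list(breast = .breast_levels, site = .site_levels, time_point = .time_levels)
}

#' Construct a skin image
#'
#' An 8-bit RGB raster with its acquisition metadata. Channel values are
#' stored as doubles on the 0--255 scale; the synthetic renderer may keep
#' fractional intensities (quantization is optional there), while images
#' read from disk are integer valued.
#'
#' @param pixels H x W x 3 array, channels on \[0, 255\].
#' @param patient_id Patient identifier.
#' @param breast `"irradiated"` or `"unirradiated"`.
#' @param site `"upper"`, `"lower"`, `"inner"` or `"outer"`.
#' @param time_point One of `"RT_before"`, `"RT_7days"`, `"RT_14days"`,
#'   `"RT_after"`.
#' @return An object of class `skin_image`.
#' @export
skin_image <- function(pixels, patient_id = NA_character_,
                       breast = NA_character_, site = NA_character_,
                       time_point = NA_character_) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3L] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  if (dim(pixels)[1L] < 1L || dim(pixels)[2L] < 1L)
    stop("image must have at least one pixel")
  if (!all(is.finite(pixels)) || any(pixels < 0) || any(pixels > 255))
    stop("pixel channels must lie in [0, 255]")
  if (!is.na(breast)) breast <- match.arg(breast, .breast_levels)
  if (!is.na(site)) site <- match.arg(site, .site_levels)
  if (!is.na(time_point)) time_point <- match.arg(time_point, .time_levels)
  structure(
    list(pixels = pixels, patient_id = as.character(patient_id),
         breast = breast, site = site, time_point = time_point),
    class = "skin_image")
}

#' @export
print.skin_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<skin_image> %d x %d px | patient %s | %s / %s / %s\n",
              d[2L], d[1L], x$patient_id, x$breast, x$site, x$time_point))
  invisible(x)
}

#' Read a skin image from PNG or TIFF
#'
#' Accepts 8-bit RGB rasters. Greyscale images are rejected; an alpha
#' channel is rejected unless `strip_alpha = TRUE`. Metadata can be given
#' explicitly or recovered from a `patient/breast/site/timepoint.png`
#' directory convention with `from_path = TRUE`.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @param patient_id,breast,site,time_point Acquisition metadata.
#' @param strip_alpha Drop an alpha channel instead of erroring.
#' @param from_path Parse metadata from the last four path components.
#' @return A [skin_image()].
#' @export
read_skin_image <- function(path, patient_id = NA_character_,
                            breast = NA_character_, site = NA_character_,
                            time_point = NA_character_,
                            strip_alpha = FALSE, from_path = FALSE) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext))
  if (length(dim(raw)) != 3L)
    stop("expected an RGB image, got a single-channel raster: ", path)
  if (dim(raw)[3L] == 4L) {
    if (!strip_alpha)
      stop("image has an alpha channel; pass strip_alpha = TRUE to drop it: ",
           path)
    raw <- raw[, , 1:3, drop = FALSE]
  }
  if (dim(raw)[3L] != 3L)
    stop("expected 3 colour channels, found ", dim(raw)[3L], ": ", path)
  if (from_path) {
    parts <- rev(strsplit(path, "/", fixed = TRUE)[[1L]])
    time_point <- tools::file_path_sans_ext(parts[1L])
    site <- parts[2L]; breast <- parts[3L]; patient_id <- parts[4L]
  }
  skin_image(round(raw * 255), patient_id = patient_id, breast = breast,
             site = site, time_point = time_point)
}

#' Write a skin image to PNG
#'
#' Channels are quantized to 8 bits on write.
#' @param image A [skin_image()].
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_skin_image <- function(image, path) {
  stopifnot(inherits(image, "skin_image"))
  png::writePNG(round(image$pixels) / 255, target = path)
  invisible(path)
}

#' Construct a circular region of interest
#'
#' @param center_x,center_y Centre in 0-based pixel coordinates (a pixel's
#'   location is its integer index; centres may be fractional).
#' @param radius Radius in pixels, > 0.
#' @return An object of class `circular_roi`.
#' @export
circular_roi <- function(center_x, center_y, radius) {
  if (!is.finite(radius) || radius <= 0) stop("`radius` must be > 0")
  structure(list(center_x = center_x, center_y = center_y, radius = radius),
            class = "circular_roi")
}

#' Default centred ROI for an image
#'
#' The design ROI is a disc of radius 300 px centred at the image centre
#' (the acquisition device delivers 1624 x 1212 px over 1 x 1 cm). For even
#' dimensions the centre is fractional, `(W-1)/2`, keeping the pixel mask
#' symmetric. Images too small to hold the design radius get the largest
#' fully inscribed disc instead, unless `strict = TRUE`.
#'
#' @param image A [skin_image()].
#' @param radius Design radius in pixels (default 300).
#' @param strict Error, rather than shrink, when the disc does not fit.
#' @return A [circular_roi()].
#' @export
default_roi <- function(image, radius = 300, strict = FALSE) {
  d <- dim(image$pixels)
  h <- d[1L]; w <- d[2L]
  fit <- (min(w, h) - 1) / 2
  if (fit <= 0) stop("image is too small for a circular ROI")
  if (radius > fit) {
    if (strict)
      stop(sprintf("design radius %.1f px does not fit a %d x %d image",
                   radius, w, h))
    radius <- fit
  }
  circular_roi((w - 1) / 2, (h - 1) / 2, radius)
}

#' Pixel membership mask of a circular ROI
#'
#' A pixel belongs to the ROI iff the Euclidean distance from its 0-based
#' integer coordinate to the ROI centre is at most the radius.
#'
#' @param image A [skin_image()].
#' @param roi A [circular_roi()].
#' @return H x W logical matrix with at least one `TRUE` entry.
#' @export
roi_mask <- function(image, roi) {
  stopifnot(inherits(roi, "circular_roi"))
  d <- dim(image$pixels)
  h <- d[1L]; w <- d[2L]
  dx2 <- ((seq_len(w) - 1) - roi$center_x)^2
  dy2 <- ((seq_len(h) - 1) - roi$center_y)^2
  mask <- outer(dy2, dx2, `+`) <= roi$radius^2
  if (!any(mask))
    stop("degenerate ROI: no pixel centre falls inside the disc")
  mask
}

#' Reduce an ROI to the twelve-parameter colour vector
#'
#' Every member pixel is converted to all four colour models first and the
#' twelve per-pixel parameters are then averaged arithmetically
#' (convert-then-average; because HSV and L*a*b* are nonlinear in RGB this
#' is not the same as converting the mean colour, and the per-pixel order
#' is what the representative value is defined to be). Hue is averaged
#' arithmetically like the other parameters.
#'
#' @param image A [skin_image()].
#' @param roi A [circular_roi()]; defaults to [default_roi()] of the image.
#' @return Named numeric vector of length 12 ([color_parameter_names()]).
#' @export
extract_parameters <- function(image, roi = default_roi(image)) {
  mask <- roi_mask(image, roi)
  px <- cbind(image$pixels[, , 1L][mask],
              image$pixels[, , 2L][mask],
              image$pixels[, , 3L][mask])
  colMeans(pixel_to_vector12(px))
}
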