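# Colour-space conversions used to parameterize skin erythema.
#
# All four transforms are authored here (not delegated to a graphics
# library) because their exact dialect is part of the method:
#   * HSV      : hexcone model, H stored in [0,1) with 1 wrapped to 0
#   * L*a*b*   : sRGB gamma, D65 white point (the white is taken as the
#                row sums of the sRGB->XYZ matrix so RGB white maps to
#                L*=100, a*=b*=0 exactly)
#   * YCbCr    : ITU-R BT.601 *studio swing* (Y in 16-235, Cb/Cr in 16-240);
#                full-swing JPEG YCbCr is deliberately not used
# Conversions run in double precision end to end; Y/Cb/Cr are never
# re-quantized to bytes before averaging.

# sRGB -> XYZ (D65) matrix; reference white = row sums.
.srgb_to_xyz <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)
.xyz_white <- rowSums(.srgb_to_xyz)
.xyz_to_srgb <- solve(.srgb_to_xyz)

# CIE f(t) threshold: (6/29)^3
.lab_eps <- (6 / 29)^3
.lab_kap <- 1 / (3 * (6 / 29)^2)

.as_triple_matrix <- function(x, arg = "x") {
  if (is.null(dim(x))) {
    if (length(x) %% 3L != 0L)
      stop(sprintf("`%s` must be a length-3 vector or an n x 3 matrix", arg))
    x <- matrix(x, ncol = 3L, byrow = length(x) == 3L)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L)
    stop(sprintf("`%s` must have 3 columns (one per channel)", arg))
  if (!all(is.finite(x)))
    stop(sprintf("`%s` contains non-finite values", arg))
  storage.mode(x) <- "double"
  x
}

.maybe_drop <- function(m, input) {
  if (is.null(dim(input)) && length(input) == 3L) drop(m) else m
}

#' Normalize 8-bit RGB channels to the unit interval
#'
#' Divides each channel by 255. Channels may be fractional (e.g. rendered
#' intensities before quantization) but must lie in \[0, 255\].
#'
#' @param rgb A length-3 vector `c(r, g, b)` or an n x 3 matrix of channel
#'   intensities on the 0--255 scale.
#' @return Values on \[0, 1\], same shape as the input.
#' @examples
#' normalize_rgb(c(51, 102, 204))
#' @export
normalize_rgb <- function(rgb) {
  m <- .as_triple_matrix(rgb, "rgb")
  if (any(m < 0 | m > 255))
    stop("RGB channels must lie in [0, 255]")
  .maybe_drop(m / 255, rgb)
}

#' Convert unit RGB to HSV
#'
#' Hexcone model: V is the channel maximum, S is the chroma relative to V
#' (0 for black), and H is the hue angle scaled to \[0, 1) with the
#' wraparound at pure red. Achromatic pixels (S = 0) report H = 0 so that
#' downstream averaging is deterministic.
#'
#' @param rgb Unit RGB, length-3 vector or n x 3 matrix, values in \[0, 1\].
#' @return Columns/components `H`, `S`, `V`, all in \[0, 1\].
#' @export
rgb_to_hsv <- function(rgb) {
  m <- .as_triple_matrix(rgb, "rgb")
  if (any(m < 0 | m > 1))
    stop("unit RGB components must lie in [0, 1]")
  r <- m[, 1L]; g <- m[, 2L]; b <- m[, 3L]
  v <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  c_ <- v - mn
  s <- ifelse(v > 0, c_ / v, 0)
  h <- numeric(length(v))
  nz <- c_ > 0
  if (any(nz)) {
    hr <- nz & v == r
    hg <- nz & !hr & v == g
    hb <- nz & !hr & !hg
    h[hr] <- ((g[hr] - b[hr]) / c_[hr]) %% 6
    h[hg] <- (b[hg] - r[hg]) / c_[hg] + 2
    h[hb] <- (r[hb] - g[hb]) / c_[hb] + 4
    h <- (h / 6) %% 1
  }
  out <- cbind(H = h, S = s, V = v)
  .maybe_drop(out, rgb)
}

#' Convert HSV back to unit RGB
#'
#' Exact inverse of [rgb_to_hsv()] on its image; used for round-trip
#' verification and by the synthetic renderer.
#'
#' @param hsv Length-3 vector `c(h, s, v)` or n x 3 matrix, components in
#'   \[0, 1\].
#' @return Unit RGB, same shape as the input.
#' @export
hsv_to_rgb <- function(hsv) {
  m <- .as_triple_matrix(hsv, "hsv")
  if (any(m < 0 | m > 1))
    stop("HSV components must lie in [0, 1]")
  h6 <- (m[, 1L] %% 1) * 6
  s <- m[, 2L]; v <- m[, 3L]
  c_ <- v * s
  x <- c_ * (1 - abs(h6 %% 2 - 1))
  i <- floor(h6) %% 6
  r <- ifelse(i == 0 | i == 5, c_, ifelse(i == 1 | i == 4, x, 0))
  g <- ifelse(i == 0 | i == 3, x, ifelse(i == 1 | i == 2, c_, 0))
  b <- ifelse(i == 2 | i == 5, x, ifelse(i == 3 | i == 4, c_, 0))
  out <- cbind(R = r + (v - c_), G = g + (v - c_), B = b + (v - c_))
  .maybe_drop(out, hsv)
}

.srgb_linearize <- function(c) {
  out <- c / 12.92
  hi <- c > 0.04045
  out[hi] <- ((c[hi] + 0.055) / 1.055)^2.4
  out
}

.srgb_delinearize <- function(c) {
  out <- 12.92 * c
  hi <- c > 0.0031308
  out[hi] <- 1.055 * c[hi]^(1 / 2.4) - 0.055
  out
}

.lab_f <- function(t) {
  out <- .lab_kap * t + 4 / 29
  hi <- t > .lab_eps
  out[hi] <- t[hi]^(1 / 3)
  out
}

.lab_finv <- function(ft) {
  out <- (ft - 4 / 29) / .lab_kap
  hi <- ft > 6 / 29
  out[hi] <- ft[hi]^3
  out
}

#' Convert unit RGB to CIE L*a*b*
#'
#' Pipeline: sRGB inverse gamma (linearization), linear RGB -> XYZ under
#' the D65 illuminant, white-point normalization, then the CIE cube-root
#' function with its linear segment below (6/29)^3. L* spans 0 (black) to
#' 100 (white); a* is the red(+)/green(-) axis and b* the
#' yellow(+)/blue(-) axis.
#'
#' @param rgb Unit RGB, length-3 vector or n x 3 matrix, values in \[0, 1\].
#' @param white Reference white XYZ; defaults to the D65 white of the sRGB
#'   primaries.
#' @return Columns/components `Lstar`, `astar`, `bstar`.
#' @export
rgb_to_lab <- function(rgb, white = .xyz_white) {
  m <- .as_triple_matrix(rgb, "rgb")
  if (any(m < 0 | m > 1))
    stop("unit RGB components must lie in [0, 1]")
  xyz <- .srgb_linearize(m) %*% t(.srgb_to_xyz)
  fx <- .lab_f(xyz[, 1L] / white[1L])
  fy <- .lab_f(xyz[, 2L] / white[2L])
  fz <- .lab_f(xyz[, 3L] / white[3L])
  out <- cbind(Lstar = 116 * fy - 16,
               astar = 500 * (fx - fy),
               bstar = 200 * (fy - fz))
  .maybe_drop(out, rgb)
}

#' Convert CIE L*a*b* to unit RGB
#'
#' Inverse of [rgb_to_lab()]. Colours outside the sRGB gamut are clipped
#' to \[0, 1\] with a warning (optional), which the synthetic renderer uses
#' to keep extreme erythema shifts displayable.
#'
#' @param lab Length-3 vector `c(L, a, b)` or n x 3 matrix.
#' @param white Reference white XYZ (D65 default, as in [rgb_to_lab()]).
#' @param warn_clip Warn if any channel had to be clipped into gamut.
#' @return Unit RGB, same shape as the input.
#' @export
lab_to_rgb <- function(lab, white = .xyz_white, warn_clip = TRUE) {
  m <- .as_triple_matrix(lab, "lab")
  fy <- (m[, 1L] + 16) / 116
  fx <- fy + m[, 2L] / 500
  fz <- fy - m[, 3L] / 200
  xyz <- cbind(.lab_finv(fx) * white[1L],
               .lab_finv(fy) * white[2L],
               .lab_finv(fz) * white[3L])
  lin <- xyz %*% t(.xyz_to_srgb)
  clipped <- lin < 0 | lin > 1
  if (any(clipped)) {
    if (warn_clip)
      warning(sprintf("%d channel value(s) outside the sRGB gamut were clipped",
                      sum(clipped)))
    lin[lin < 0] <- 0
    lin[lin > 1] <- 1
  }
  out <- .srgb_delinearize(lin)
  colnames(out) <- c("R", "G", "B")
  .maybe_drop(out, lab)
}

#' Convert unit RGB to BT.601 studio-swing YCbCr
#'
#' Affine transform fixed by the nominal digital ranges Y in 16 (black) to
#' 235 (white) and Cb/Cr in 16--240 with the achromatic axis at 128:
#' \deqn{Y = 16 + 65.481 r + 128.553 g + 24.966 b}
#' \deqn{Cb = 128 - 37.797 r - 74.203 g + 112 b}
#' \deqn{Cr = 128 + 112 r - 93.786 g - 18.214 b}
#'
#' @param rgb Unit RGB, length-3 vector or n x 3 matrix, values in \[0, 1\].
#' @return Columns/components `Y`, `Cb`, `Cr` on the digital 16--240 scale
#'   (not re-quantized to integers).
#' @export
rgb_to_ycbcr <- function(rgb) {
  m <- .as_triple_matrix(rgb, "rgb")
  if (any(m < 0 | m > 1))
    stop("unit RGB components must lie in [0, 1]")
  out <- cbind(
    Y  =  16 + 65.481 * m[, 1L] + 128.553 * m[, 2L] + 24.966 * m[, 3L],
    Cb = 128 - 37.797 * m[, 1L] -  74.203 * m[, 2L] + 112    * m[, 3L],
    Cr = 128 + 112    * m[, 1L] -  93.786 * m[, 2L] - 18.214 * m[, 3L])
  .maybe_drop(out, rgb)
}

#' Names of the twelve colour-space parameters
#'
#' Order: RGB on the 0--255 scale, HSV on \[0, 1\], CIE L*a*b*, and
#' studio-swing YCbCr on the 16--240 digital scale.
#' @return Character vector of length 12.
#' @export
color_parameter_names <- function() {
  c("R", "G", "B", "H", "S", "V",
    "Lstar", "astar", "bstar", "Y", "Cb", "Cr")
}

#' Compute all twelve colour parameters for 8-bit RGB pixels
#'
#' Bundles the four colour models: R, G, B are passed through on the 0--255
#' scale, the remaining nine come from [rgb_to_hsv()], [rgb_to_lab()] and
#' [rgb_to_ycbcr()] applied to the normalized pixel.
#'
#' @param rgb255 A length-3 vector or n x 3 matrix of channel intensities
#'   on the 0--255 scale.
#' @return Named vector (or n x 12 matrix) in [color_parameter_names()]
#'   order.
#' @examples
#' pixel_to_vector12(c(255, 0, 0))
#' @export
pixel_to_vector12 <- function(rgb255) {
  m <- .as_triple_matrix(rgb255, "rgb255")
  u <- normalize_rgb(m)
  out <- cbind(m, rgb_to_hsv(u), rgb_to_lab(u), rgb_to_ycbcr(u))
  colnames(out) <- color_parameter_names()
  .maybe_drop(out, rgb255)
}
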