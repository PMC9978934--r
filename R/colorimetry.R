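# Colorimetry: sRGB <-> CIELAB conversion and dyeing-intensity scoring.
#
# Dyeing intensity is defined as the Euclidean norm sqrt(L*^2 + a*^2 + b*^2)
# of the mean CIELAB colour of the dyed swatch. Deep indigo dyeing drives b*
# strongly negative (blue) and L* down, so the norm tracks visual depth of
# shade. All conversions assume the scanner-standard sRGB encoding
# (IEC 61966-2-1 piecewise gamma), D65 white point, 2 degree observer.

# D65 reference white (2 deg observer), XYZ scaled to Y = 100.
.white_d65 <- c(X = 95.047, Y = 100, Z = 108.883)

.srgb_to_xyz_mat <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)

.lab_f <- function(t) {
  delta <- 6 / 29
  ifelse(t > delta^3, t^(1 / 3), t / (3 * delta^2) + 4 / 29)
}

.lab_f_inv <- function(t) {
  delta <- 6 / 29
  ifelse(t > delta, t^3, 3 * delta^2 * (t - 4 / 29))
}

#' Convert sRGB channel values to CIELAB
#'
#' Standard sRGB decoding (IEC 61966-2-1 piecewise gamma) to linear RGB,
#' linear RGB to XYZ (D65, 2 degree observer), then XYZ to CIELAB with the
#' D65 white point. Vectorised over rows.
#'
#' @param rgb A numeric vector of length 3, or an n x 3 matrix/data frame,
#'   of sRGB channel values in `[0, 255]`.
#' @return A tibble with columns `L`, `a`, `b`.
#' @examples
#' srgb_to_lab(c(0, 0, 255))
#' @export
srgb_to_lab <- function(rgb) {
  m <- to_rgb_matrix(rgb)
  if (any(!is.finite(m)) || any(m < 0) || any(m > 255)) {
    abort("sRGB channel values must lie in [0, 255]")
  }
  v <- m / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.srgb_to_xyz_mat) * 100
  fx <- .lab_f(xyz[, 1] / .white_d65[["X"]])
  fy <- .lab_f(xyz[, 2] / .white_d65[["Y"]])
  fz <- .lab_f(xyz[, 3] / .white_d65[["Z"]])
  tibble(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

#' Convert CIELAB to sRGB
#'
#' Inverse of [srgb_to_lab()]. Colours outside the sRGB gamut are clamped to
#' the nearest representable channel values and flagged.
#'
#' @param lab A numeric vector `c(L, a, b)` or an n x 3 matrix/data frame.
#' @return A tibble with integer columns `r`, `g`, `b` in `[0, 255]` and a
#'   logical `clamped` column marking out-of-gamut inputs.
#' @export
lab_to_srgb <- function(lab) {
  m <- to_lab_matrix(lab)
  fy <- (m[, 1] + 16) / 116
  fx <- fy + m[, 2] / 500
  fz <- fy - m[, 3] / 200
  xyz <- cbind(
    .lab_f_inv(fx) * .white_d65[["X"]],
    .lab_f_inv(fy) * .white_d65[["Y"]],
    .lab_f_inv(fz) * .white_d65[["Z"]]
  ) / 100
  lin <- xyz %*% t(solve(.srgb_to_xyz_mat))
  v <- ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
  clamped <- rowSums(v < -1e-9 | v > 1 + 1e-9) > 0
  v <- pmin(pmax(v, 0), 1)
  out <- round(v * 255)
  tibble(r = out[, 1], g = out[, 2], b = out[, 3], clamped = clamped)
}

#' Dyeing intensity of a CIELAB colour
#'
#' The phenotype score: `sqrt(L^2 + a^2 + b^2)`. Zero if and only if the
#' colour is the CIELAB origin; invariant under sign flips of `a` and `b`.
#'
#' @param lab A numeric vector `c(L, a, b)`, an n x 3 matrix, or a data frame
#'   with columns `L`, `a`, `b`.
#' @return A numeric vector of intensities (one per row).
#' @examples
#' dye_intensity(c(3, 4, 0)) # 5
#' @export
dye_intensity <- function(lab) {
  m <- to_lab_matrix(lab)
  sqrt(rowSums(m^2))
}

#' Central-crop mask for a swatch image
#'
#' Scanned swatches carry an undyed margin; the default scoring strategy
#' crops a central region and averages only interior pixels.
#'
#' @param image A swatch image as returned by [render_swatch()] (H x W x 3
#'   array of sRGB values) or any H x W x 3 array.
#' @param border_fraction Fraction of each edge to drop, in `[0, 0.5)`.
#' @return A logical H x W matrix, `TRUE` for pixels inside the crop.
#' @export
extract_swatch_mask <- function(image, border_fraction = 0.15) {
  dims <- dim(image)
  assert_that(length(dims) == 3 && dims[3] == 3, "image must be an H x W x 3 array")
  assert_that(
    is.numeric(border_fraction) && border_fraction >= 0 && border_fraction < 0.5,
    "border_fraction must lie in [0, 0.5)"
  )
  h <- dims[1]
  w <- dims[2]
  rb <- floor(h * border_fraction)
  cb <- floor(w * border_fraction)
  rows <- seq.int(rb + 1, h - rb)
  cols <- seq.int(cb + 1, w - cb)
  if (length(rows) < 1 || length(cols) < 1) abort("mask is empty: border_fraction leaves no interior pixels")
  mask <- matrix(FALSE, h, w)
  mask[rows, cols] <- TRUE
  mask
}

#' Score a dyed-swatch image
#'
#' Converts the masked pixels to CIELAB, averages in Lab space (the score is
#' defined on L*, a*, b* values, so averaging happens after conversion, not
#' on raw sRGB), and returns the Euclidean norm of the mean colour.
#'
#' @inheritParams extract_swatch_mask
#' @param average One of `"lab"` (default) or `"srgb"`: whether pixel
#'   averaging happens in CIELAB or in sRGB space before conversion.
#' @return A one-row tibble: `L`, `a`, `b` (mean colour), `intensity`,
#'   `n_pixels_used`, `mask_fraction`.
#' @export
score_image <- function(image, border_fraction = 0.15, average = c("lab", "srgb")) {
  average <- match.arg(average)
  mask <- extract_swatch_mask(image, border_fraction)
  idx <- which(mask)
  px <- cbind(image[, , 1][idx], image[, , 2][idx], image[, , 3][idx])
  if (average == "lab") {
    lab <- srgb_to_lab(px)
    mean_lab <- c(mean(lab$L), mean(lab$a), mean(lab$b))
  } else {
    mean_lab <- unlist(srgb_to_lab(colMeans(px)))
  }
  tibble(
    L = mean_lab[1], a = mean_lab[2], b = mean_lab[3],
    intensity = sqrt(sum(mean_lab^2)),
    n_pixels_used = length(idx),
    mask_fraction = length(idx) / (dim(image)[1] * dim(image)[2])
  )
}

#' Score a table of CIELAB measurements
#'
#' Convenience wrapper: takes per-sample L, a, b readings and appends the
#' dyeing-intensity column.
#'
#' @param data A data frame with columns `L`, `a`, `b`.
#' @return `data` as a tibble with an `intensity` column appended.
#' @export
score_lab <- function(data) {
  assert_that(all(c("L", "a", "b") %in% names(data)), "data must have columns L, a, b")
  dplyr::mutate(as_tibble(data), intensity = dye_intensity(cbind(.data$L, .data$a, .data$b)))
}

# CIE76 colour difference, used by tests and the swatch round-trip contract.
delta_e <- function(lab1, lab2) {
  sqrt(sum((unlist(lab1) - unlist(lab2))^2))
}

to_rgb_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, 1:3])
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = TRUE)
  storage.mode(x) <- "double"
  assert_that(ncol(x) == 3, "expected 3 colour channels")
  x
}

to_lab_matrix <- function(x) {
  if (is.data.frame(x)) {
    cols <- if (all(c("L", "a", "b") %in% names(x))) c("L", "a", "b") else 1:3
    x <- as.matrix(x[, cols])
  }
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = TRUE)
  storage.mode(x) <- "double"
  assert_that(ncol(x) == 3 && all(is.finite(x)), "expected finite L, a, b values")
  # small slack absorbs round-trip arithmetic on the gamut boundary
  assert_that(all(x[, 1] >= -1e-3 & x[, 1] <= 100 + 1e-3), "L must lie in [0, 100]")
  x[, 1] <- pmin(pmax(x[, 1], 0), 100)
  x
}
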