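# Colorimetric foundation: CIE xyY <-> XYZ <-> linear display RGB,
# opponent-pair construction, and an isoluminant circular palette.

# sRGB primaries, D65 white, 2-degree observer (IEC 61966-2-1).
# Linear RGB in [0,1] maps to XYZ relative to a white of Y = 1.
.M_RGB2XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)

.M_XYZ2RGB <- solve(.M_RGB2XYZ)

#' Validate CIE xy chromaticity coordinates
#'
#' A valid chromaticity satisfies `0 < x < 1`, `0 < y < 1` and `x + y < 1`.
#'
#' @param x,y Numeric vectors of CIE 1931 chromaticity coordinates.
#' @return Invisibly `TRUE`; aborts with class
#'   `"contourfill_invalid_chromaticity"` otherwise.
#' @export
validate_chromaticity <- function(x, y) {
  bad <- !is.finite(x) | !is.finite(y) | x <= 0 | y <= 0 | x >= 1 | y >= 1 |
    (x + y) >= 1
  if (any(bad)) {
    rlang::abort(
      sprintf("invalid chromaticity at %d position(s), e.g. (x = %.4f, y = %.4f)",
              sum(bad), x[which(bad)[1]], y[which(bad)[1]]),
      class = "contourfill_invalid_chromaticity"
    )
  }
  invisible(TRUE)
}

#' Convert CIE xyY to XYZ tristimulus values
#'
#' `Y` carries absolute luminance in cd/m^2; the returned `Y` component is
#' unchanged, so the tristimulus triple carries luminance too.
#'
#' @param x,y CIE 1931 chromaticity coordinates.
#' @param Y Luminance in cd/m^2 (or any linear photometric unit).
#' @return A tibble with columns `X`, `Y`, `Z`.
#' @examples
#' xyY_to_XYZ(1 / 3, 1 / 3, 1)   # equal-energy point: (1, 1, 1)
#' xyY_to_XYZ(0.329, 0.412, 126) # the green used in the plaid stimuli
#' @export
xyY_to_XYZ <- function(x, y, Y) {
  validate_chromaticity(x, y)
  tibble::tibble(X = x * Y / y, Y = Y, Z = (1 - x - y) * Y / y)
}

#' Convert XYZ tristimulus values to CIE xyY
#'
#' @param X,Y,Z CIE 1931 tristimulus values; `Y` in cd/m^2.
#' @return A tibble with columns `x`, `y`, `Y`.
#' @export
XYZ_to_xyY <- function(X, Y, Z) {
  s <- X + Y + Z
  if (any(s <= 0)) {
    rlang::abort("tristimulus sum X + Y + Z must be positive",
                 class = "contourfill_invalid_chromaticity")
  }
  tibble::tibble(x = X / s, y = Y / s, Y = Y)
}

# internal: n x 3 XYZ matrix (absolute, cd/m^2) -> n x 3 linear RGB
xyz_mat_to_linrgb <- function(m, white_Y) {
  stopifnot(white_Y > 0)
  (m / white_Y) %*% t(.M_XYZ2RGB)
}

linrgb_mat_to_xyz <- function(m, white_Y) {
  stopifnot(white_Y > 0)
  (m %*% t(.M_RGB2XYZ)) * white_Y
}

#' Convert absolute XYZ to linear display RGB
#'
#' The display model is sRGB primaries with a D65 white point scaled so that
#' the display white at luminance `white_Y` maps to the maximal
#' equal-component triple (1, 1, 1). Values are linear light; gamma encoding
#' is applied only on PNG export.
#'
#' Out-of-gamut colors are clipped per channel when `clip = TRUE`; the result
#' then carries an attribute `clipped` with the per-row logical flag and
#' `max_overshoot` with the largest excursion outside `[0, 1]`.
#'
#' @param X,Y,Z Tristimulus values (`Y` in cd/m^2).
#' @param white_Y Display white luminance in cd/m^2.
#' @param clip Clip out-of-gamut channels to `[0, 1]`? If `FALSE`, channels
#'   are returned untouched (possibly outside `[0, 1]`).
#' @return A tibble with columns `R`, `G`, `B` (linear, nominally in
#'   `[0, 1]`) and logical `clipped`.
#' @export
XYZ_to_display <- function(X, Y, Z, white_Y, clip = TRUE) {
  m <- xyz_mat_to_linrgb(cbind(X, Y, Z), white_Y)
  over <- pmax(m - 1, -m, 0)
  clipped <- rowSums(over > 1e-12) > 0
  if (clip) m <- pmin(pmax(m, 0), 1)
  out <- tibble::tibble(R = m[, 1], G = m[, 2], B = m[, 3], clipped = clipped)
  attr(out, "max_overshoot") <- max(over)
  out
}

#' Convert linear display RGB back to absolute XYZ
#'
#' Inverse of [XYZ_to_display()] for in-gamut colors.
#'
#' @param R,G,B Linear RGB channels in `[0, 1]`.
#' @param white_Y Display white luminance in cd/m^2.
#' @return A tibble with columns `X`, `Y`, `Z` (`Y` in cd/m^2).
#' @export
display_to_XYZ <- function(R, G, B, white_Y) {
  m <- linrgb_mat_to_xyz(cbind(R, G, B), white_Y)
  tibble::tibble(X = m[, 1], Y = m[, 2], Z = m[, 3])
}

# luminance (cd/m^2) of linear RGB values
linrgb_luminance <- function(R, G, B, white_Y) {
  white_Y * (.M_RGB2XYZ[2, 1] * R + .M_RGB2XYZ[2, 2] * G + .M_RGB2XYZ[2, 3] * B)
}

#' Construct an opponent color pair about a gray point
#'
#' The partner of chromaticity `c` is its point reflection `2 g - c` through
#' the gray point, so the two chromaticities average to gray exactly and both
#' share luminance `Y`.
#'
#' @param x,y Chromaticity of one pair member.
#' @param gray_x,gray_y Chromaticity of the gray point (default equal-energy
#'   (1/3, 1/3)).
#' @param Y Shared luminance in cd/m^2.
#' @return A two-row tibble (`member`, `x`, `y`, `X`, `Y`, `Z`): the input
#'   color and its opponent partner.
#' @export
opponent_pair <- function(x, y, gray_x = 1 / 3, gray_y = 1 / 3, Y = 126) {
  stopifnot(length(x) == 1, length(y) == 1)
  validate_chromaticity(x, y)
  validate_chromaticity(gray_x, gray_y)
  px <- 2 * gray_x - x
  py <- 2 * gray_y - y
  ok <- tryCatch(validate_chromaticity(px, py), error = function(e) FALSE)
  if (isFALSE(ok)) {
    rlang::abort("reflected chromaticity falls outside the valid domain",
                 class = "contourfill_out_of_range")
  }
  xs <- c(x, px)
  ys <- c(y, py)
  xyz <- xyY_to_XYZ(xs, ys, c(Y, Y))
  tibble::tibble(member = 1:2, x = xs, y = ys,
                 X = xyz$X, Y = xyz$Y, Z = xyz$Z)
}

#' Isoluminant circular palette in CIE xy
#'
#' Approximates a set of colors that are isoluminant, equally detectable and
#' perceptually equidistant by `n` points at equal angular spacing on a
#' circle of radius `radius` about a gray point in the chromaticity plane.
#' Entries `i` and `i + n/2` (mod `n`) are opponent pairs; entries `i` and
#' `i + n/4` are orthogonal pairs.
#'
#' @param n Number of entries (default 16).
#' @param gray_x,gray_y Gray point chromaticity.
#' @param radius Circle radius in xy distance.
#' @param Y Shared luminance, cd/m^2.
#' @param white_Y Display white luminance used for the gamut check.
#' @param start_angle First entry's angle in degrees, CCW from +x.
#' @return A tibble (class `teufel_palette`) with columns `index`, `angle`,
#'   `x`, `y`, `X`, `Y`, `Z`; attributes `gray`, `radius`, `luminance`.
#' @export
teufel_palette <- function(n = 16, gray_x = 1 / 3, gray_y = 1 / 3,
                           radius = 0.08, Y = 126, white_Y = 340,
                           start_angle = 0) {
  stopifnot(n >= 2, radius > 0, Y > 0)
  ang <- start_angle + 360 * (seq_len(n) - 1) / n
  x <- gray_x + radius * cospi(ang / 180)
  y <- gray_y + radius * sinpi(ang / 180)
  validate_chromaticity(x, y)
  xyz <- xyY_to_XYZ(x, y, rep(Y, n))
  rgb <- XYZ_to_display(xyz$X, xyz$Y, xyz$Z, white_Y, clip = FALSE)
  out_of_gamut <- rgb$R < 0 | rgb$R > 1 | rgb$G < 0 | rgb$G > 1 |
    rgb$B < 0 | rgb$B > 1
  if (any(out_of_gamut)) {
    rlang::abort(
      paste0("palette leaves the display gamut at entries: ",
             paste(which(out_of_gamut), collapse = ", ")),
      class = "contourfill_out_of_gamut"
    )
  }
  out <- tibble::tibble(index = seq_len(n), angle = ang %% 360,
                        x = x, y = y, X = xyz$X, Y = xyz$Y, Z = xyz$Z)
  attr(out, "gray") <- c(x = gray_x, y = gray_y)
  attr(out, "radius") <- radius
  attr(out, "luminance") <- Y
  class(out) <- c("teufel_palette", class(out))
  out
}

#' Extract an opponent pair from a palette
#'
#' @param palette A [teufel_palette()].
#' @param i 1-based index of the first member; the partner is entry
#'   `i + n/2` (mod n).
#' @return A two-row tibble like [opponent_pair()].
#' @export
palette_pair <- function(palette, i) {
  n <- nrow(palette)
  j <- ((i - 1 + n / 2) %% n) + 1
  rows <- palette[c(i, j), ]
  tibble::tibble(member = 1:2, x = rows$x, y = rows$y,
                 X = rows$X, Y = rows$Y, Z = rows$Z)
}

#' Euclidean distance in the CIE xy plane
#'
#' @param x1,y1,x2,y2 Chromaticity coordinates.
#' @return Numeric vector of distances.
#' @export
xy_distance <- function(x1, y1, x2, y2) {
  sqrt((x1 - x2)^2 + (y1 - y2)^2)
}

#' Write a palette to CSV
#'
#' Columns `index`, `x`, `y`, `Y` as a plain-text interchange format.
#'
#' @param palette A [teufel_palette()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_palette_csv <- function(palette, path) {
  utils::write.csv(palette[, c("index", "x", "y", "Y")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a palette CSV written by [write_palette_csv()]
#'
#' @param path Input file path.
#' @return A tibble with columns `index`, `x`, `y`, `Y`, `X`, `Z`.
#' @export
read_palette_csv <- function(path) {
  d <- utils::read.csv(path)
  xyz <- xyY_to_XYZ(d$x, d$y, d$Y)
  tibble::tibble(index = d$index, x = d$x, y = d$y,
                 X = xyz$X, Y = xyz$Y, Z = xyz$Z)
}
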