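# Raster container: a pixel grid of linear display RGB with a
# degrees <-> pixels scale. Row-major, origin top-left, 1-based indices;
# radii are measured from the geometric center.

new_raster <- function(rgb, ppd, white_Y, center = NULL, inside = NULL) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3, ppd > 0, white_Y > 0)
  if (is.null(center)) {
    center <- c((dim(rgb)[1] + 1) / 2, (dim(rgb)[2] + 1) / 2)
  }
  structure(
    list(rgb = rgb, ppd = ppd, white_Y = white_Y,
         center = center, inside = inside),
    class = "raster_stim"
  )
}

#' @export
print.raster_stim <- function(x, ...) {
  d <- dim(x$rgb)
  cat(sprintf(
    "<raster_stim> %d x %d px (%.2f x %.2f deg at %g px/deg), white %g cd/m^2\n",
    d[2], d[1], d[2] / x$ppd, d[1] / x$ppd, x$ppd, x$white_Y))
  if (!is.null(x$inside)) {
    cat(sprintf("  stimulus area: %d px (%.1f%%)\n", sum(x$inside),
                100 * mean(x$inside)))
  }
  invisible(x)
}

#' @export
dim.raster_stim <- function(x) dim(x$rgb)[1:2]

# matrices of pixel-center coordinates in degrees relative to the center
raster_coords_deg <- function(r) {
  d <- dim(r$rgb)
  row_deg <- (seq_len(d[1]) - r$center[1]) / r$ppd
  col_deg <- (seq_len(d[2]) - r$center[2]) / r$ppd
  list(
    y = matrix(row_deg, d[1], d[2]),
    x = matrix(col_deg, d[1], d[2], byrow = TRUE)
  )
}

raster_radius_deg <- function(r) {
  co <- raster_coords_deg(r)
  sqrt(co$x^2 + co$y^2)
}

#' Per-pixel luminance of a raster
#'
#' @param r A raster.
#' @return A matrix of luminances in cd/m^2.
#' @export
raster_luminance <- function(r) {
  linrgb_luminance(r$rgb[, , 1], r$rgb[, , 2], r$rgb[, , 3], r$white_Y)
}

# n x 3 matrix of XYZ (absolute) for all pixels, pixel order = column-major
raster_xyz_matrix <- function(r) {
  d <- dim(r$rgb)
  m <- matrix(r$rgb, d[1] * d[2], 3)
  linrgb_mat_to_xyz(m, r$white_Y)
}

#' Convert a raster to a long tibble
#'
#' One row per pixel with pixel indices, visual-degree coordinates, linear
#' RGB, and CIE xyY.
#'
#' @param x A raster.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `x_deg`, `y_deg`, `R`, `G`,
#'   `B`, `x`, `y`, `Y`.
#' @method as_tibble raster_stim
#' @export
as_tibble.raster_stim <- function(x, ...) {
  d <- dim(x$rgb)
  co <- raster_coords_deg(x)
  xyz <- raster_xyz_matrix(x)
  s <- rowSums(xyz)
  tibble::tibble(
    row = rep(seq_len(d[1]), d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    x_deg = as.vector(co$x), y_deg = as.vector(co$y),
    R = as.vector(x$rgb[, , 1]), G = as.vector(x$rgb[, , 2]),
    B = as.vector(x$rgb[, , 3]),
    x = xyz[, 1] / s, y = xyz[, 2] / s, Y = xyz[, 2]
  )
}

# build a raster from an n x 3 XYZ pixel matrix (column-major pixel order)
raster_from_xyz <- function(xyz, nrow, ncol, ppd, white_Y,
                            center = NULL, inside = NULL, clip = TRUE) {
  m <- xyz_mat_to_linrgb(xyz, white_Y)
  if (clip) m <- pmin(pmax(m, 0), 1)
  new_raster(array(m, c(nrow, ncol, 3)), ppd, white_Y, center, inside)
}

# sRGB transfer function (gamma encoding) for export / display only
srgb_encode <- function(u) {
  ifelse(u <= 0.0031308, 12.92 * u, 1.055 * u^(1 / 2.4) - 0.055)
}

#' Export a raster as an sRGB-encoded PNG
#'
#' Linear channel values are gamma-encoded with the sRGB transfer function
#' at write time; all internal computation stays in linear light.
#'
#' @param r A raster.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_raster_png <- function(r, path) {
  img <- srgb_encode(pmin(pmax(r$rgb, 0), 1))
  png::writePNG(img, path)
  invisible(path)
}

#' Gaussian blur of a raster in linear light
#'
#' Separable Gaussian convolution applied per channel with replicated
#' borders. `sigma_deg = 0` returns the input unchanged.
#'
#' @param r A raster.
#' @param sigma_deg Blur standard deviation in visual degrees.
#' @return A blurred raster with the same geometry.
#' @export
raster_blur <- function(r, sigma_deg) {
  stopifnot(sigma_deg >= 0)
  if (sigma_deg == 0) return(r)
  sigma_px <- sigma_deg * r$ppd
  out <- r$rgb
  for (ch in 1:3) {
    out[, , ch] <- EBImage::gblur(r$rgb[, , ch], sigma = sigma_px,
                                  boundary = "replicate")
  }
  out <- pmin(pmax(out, 0), 1)
  new_raster(out, r$ppd, r$white_Y, r$center, r$inside)
}
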