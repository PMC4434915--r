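# Stimulus synthesis: concentric square-wave grating disks, octagon plaids,
# anchored radial gradients, and achromatic contour overlays.

#' Declarative stimulus description
#'
#' Geometry is expressed in visual degrees and converted to pixels through
#' `ppd` (pixels per degree). `blur_sigma_deg` defaults to one sixth of the
#' relevant period (grating period for disks, tile period for plaids, none
#' for the already-smooth gradient).
#'
#' @param kind One of `"disk_gratings"`, `"octagon_plaid"`,
#'   `"anchored_gradient"`.
#' @param diameter_deg Stimulus diameter (disk) or side length (plaid) in
#'   visual degrees.
#' @param ppd Pixels per degree.
#' @param period_deg Grating period in degrees (disk and gradient kinds).
#' @param cycles_per_image Tile repetitions across the image (plaid kind).
#' @param blur_sigma_deg Gaussian blur SD in degrees; `NULL` picks the
#'   kind-specific default.
#' @param background_Y Background (display white) luminance, cd/m^2.
#' @param white_Y Display white luminance used for RGB scaling, cd/m^2.
#' @return A list of class `stimulus_spec`.
#' @export
stimulus_spec <- function(kind = c("disk_gratings", "octagon_plaid",
                                   "anchored_gradient"),
                          diameter_deg = 10.8, ppd = 32,
                          period_deg = 2.4, cycles_per_image = 9.5,
                          blur_sigma_deg = NULL,
                          background_Y = 340, white_Y = 340) {
  kind <- match.arg(kind)
  stopifnot(diameter_deg > 0, ppd > 0, period_deg > 0, cycles_per_image > 0,
            background_Y > 0, white_Y > 0)
  if (is.null(blur_sigma_deg)) {
    blur_sigma_deg <- switch(kind,
      disk_gratings = period_deg / 6,
      octagon_plaid = (diameter_deg / cycles_per_image) / 6,
      anchored_gradient = 0)
  }
  stopifnot(blur_sigma_deg >= 0)
  structure(
    list(kind = kind, diameter_deg = diameter_deg, ppd = ppd,
         period_deg = period_deg, cycles_per_image = cycles_per_image,
         blur_sigma_deg = blur_sigma_deg,
         background_Y = background_Y, white_Y = white_Y),
    class = "stimulus_spec")
}

# background linear RGB (display white scaled to background_Y)
spec_background_rgb <- function(spec) {
  rep(spec$background_Y / spec$white_Y, 3)
}

spec_raster_shell <- function(spec) {
  n <- round(spec$diameter_deg * spec$ppd)
  rgb <- array(0, c(n, n, 3))
  new_raster(rgb, spec$ppd, spec$white_Y)
}

# linear RGB rows (2 x 3) for an opponent-pair tibble
pair_linrgb <- function(pair, white_Y, clip = TRUE) {
  m <- xyz_mat_to_linrgb(cbind(pair$X, pair$Y, pair$Z), white_Y)
  if (clip) m <- pmin(pmax(m, 0), 1)
  m
}

# 0/1 square-wave ring index; one cycle (period_deg) holds both members,
# so each ring is half a period wide and phase is measured in cycles
ring_index <- function(r_deg, period_deg, phase) {
  floor(2 * (r_deg / period_deg + phase)) %% 2
}

#' Concentric square-wave grating disk
#'
#' Alternating rings of the two members of an opponent pair. One cycle
#' (`period_deg`) holds both members, so ring membership at radius `r` is
#' `floor(2 (r / period + phase)) mod 2` with `phase` in cycles. Pixels
#' outside the disk take the background color.
#'
#' @param spec A [stimulus_spec()] of kind `"disk_gratings"`.
#' @param pair A two-row opponent-pair tibble (see [opponent_pair()]).
#' @param phase Phase as a fraction of a cycle.
#' @return A raster.
#' @export
radial_square_grating <- function(spec, pair, phase = 0) {
  stopifnot(inherits(spec, "stimulus_spec"), spec$kind == "disk_gratings",
            nrow(pair) == 2)
  shell <- spec_raster_shell(spec)
  r <- raster_radius_deg(shell)
  idx <- ring_index(r, spec$period_deg, phase)
  cols <- pair_linrgb(pair, spec$white_Y)
  bg <- spec_background_rgb(spec)
  inside <- r <= spec$diameter_deg / 2
  out <- shell$rgb
  for (ch in 1:3) {
    plane <- ifelse(idx == 0, cols[1, ch], cols[2, ch])
    plane[!inside] <- bg[ch]
    out[, , ch] <- plane
  }
  new_raster(out, spec$ppd, spec$white_Y, shell$center, inside)
}

# unmasked full-plane ring raster used by compose_disk
ring_plane_rgb <- function(spec, shell, pair, phase) {
  r <- raster_radius_deg(shell)
  idx <- ring_index(r, spec$period_deg, phase)
  cols <- pair_linrgb(pair, spec$white_Y)
  out <- shell$rgb
  for (ch in 1:3) out[, , ch] <- ifelse(idx == 0, cols[1, ch], cols[2, ch])
  out
}

#' Compose the colored gradient disk from three phase-shifted gratings
#'
#' Three concentric square-wave gratings built from three opponent pairs and
#' phase-shifted by thirds of a cycle are averaged per pixel in linear light
#' and Gaussian-blurred; the result is masked to the disk over the white
#' background.
#'
#' @param spec A [stimulus_spec()] of kind `"disk_gratings"`.
#' @param pairs List of exactly three opponent-pair tibbles.
#' @param phases Three phases in cycle fractions, spaced by 1/3.
#' @return A raster with an `inside` disk mask.
#' @export
compose_disk <- function(spec, pairs, phases = c(0, 1 / 3, 2 / 3)) {
  stopifnot(inherits(spec, "stimulus_spec"), spec$kind == "disk_gratings")
  if (length(pairs) != 3 || length(phases) != 3) {
    rlang::abort("compose_disk needs exactly three pairs and three phases",
                 class = "contourfill_spec_error")
  }
  shell <- spec_raster_shell(spec)
  acc <- shell$rgb
  for (i in 1:3) {
    acc <- acc + ring_plane_rgb(spec, shell, pairs[[i]], phases[i])
  }
  acc <- acc / 3
  full <- new_raster(acc, spec$ppd, spec$white_Y, shell$center)
  full <- raster_blur(full, spec$blur_sigma_deg)
  r <- raster_radius_deg(full)
  inside <- r <= spec$diameter_deg / 2
  bg <- spec_background_rgb(spec)
  out <- full$rgb
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[!inside] <- bg[ch]
    out[, , ch] <- plane
  }
  new_raster(out, spec$ppd, spec$white_Y, full$center, inside)
}

# truncated-square (4.8.8) tiling classification in unit cell coordinates:
# TRUE = octagon interior, FALSE = corner diamond ("star") interior
.octagon_cut <- 1 / (2 + sqrt(2))

octagon_cell_class <- function(u, v) {
  du <- pmin(u, 1 - u)
  dv <- pmin(v, 1 - v)
  (du + dv) >= .octagon_cut
}

# cell coordinates of pixel centers for a tiling with period p and phase
# shift (both axes) of `phase` cycles
tile_cell_coords <- function(r, period_deg, phase) {
  co <- raster_coords_deg(r)
  list(u = (co$x / period_deg - phase) %% 1,
       v = (co$y / period_deg - phase) %% 1)
}

#' Octagon-grid plaid from two superimposed counter-phase images
#'
#' Two octagon-tiling images, one per opponent pair and in spatial counter
#' phase (half-period shift both horizontally and vertically), are mixed per
#' pixel as `alpha * A + (1 - alpha) * B` in linear light and then
#' Gaussian-blurred.
#'
#' @param spec A [stimulus_spec()] of kind `"octagon_plaid"`.
#' @param pairA,pairB Two-row color tibbles (octagon color first, interstitial
#'   color second). The pairs are expected to be orthogonal color axes;
#'   a deviation beyond 15 degrees raises a warning, not an error.
#' @param alpha Mixing weight of image A in `[0, 1]`.
#' @param phase_a,phase_b Tile phases of the two images in cycle fractions
#'   (applied to both axes); the defaults place them in counter phase.
#' @param blur Apply the spec's Gaussian blur? `FALSE` gives the raw mixture.
#' @return A raster (no inside mask; the plaid fills the image).
#' @export
octagon_plaid <- function(spec, pairA, pairB, alpha = 0.5,
                          phase_a = 0, phase_b = 0.5, blur = TRUE) {
  stopifnot(inherits(spec, "stimulus_spec"), spec$kind == "octagon_plaid",
            alpha >= 0, alpha <= 1)
  # orthogonality is assessed in the (isoluminant) tristimulus plane
  dA <- c(pairA$X[1] - pairA$X[2], pairA$Y[1] - pairA$Y[2],
          pairA$Z[1] - pairA$Z[2])
  dB <- c(pairB$X[1] - pairB$X[2], pairB$Y[1] - pairB$Y[2],
          pairB$Z[1] - pairB$Z[2])
  cosang <- sum(dA * dB) / sqrt(sum(dA^2) * sum(dB^2))
  if (abs(cosang) > cospi(75 / 180)) {
    rlang::warn(sprintf(
      "pairA and pairB deviate from orthogonality (angle %.1f deg)",
      acos(abs(cosang)) * 180 / pi))
  }
  shell <- spec_raster_shell(spec)
  p <- spec$diameter_deg / spec$cycles_per_image
  ccA <- tile_cell_coords(shell, p, phase_a)
  ccB <- tile_cell_coords(shell, p, phase_b)
  octA <- octagon_cell_class(ccA$u, ccA$v)
  octB <- octagon_cell_class(ccB$u, ccB$v)
  # mix in linear light BEFORE gamut clipping: the component images may use
  # virtual (out-of-gamut) lights as long as every rendered mixture is
  # displayable
  colsA <- pair_linrgb(pairA, spec$white_Y, clip = FALSE)
  colsB <- pair_linrgb(pairB, spec$white_Y, clip = FALSE)
  out <- shell$rgb
  for (ch in 1:3) {
    a <- ifelse(octA, colsA[1, ch], colsA[2, ch])
    b <- ifelse(octB, colsB[1, ch], colsB[2, ch])
    out[, , ch] <- pmin(pmax(alpha * a + (1 - alpha) * b, 0), 1)
  }
  res <- new_raster(out, spec$ppd, spec$white_Y, shell$center)
  if (blur) res <- raster_blur(res, spec$blur_sigma_deg)
  res
}

#' Radial color profile through six anchors
#'
#' Periodic cosine interpolation of tristimulus values between consecutive
#' anchors: at radius `r0_deg + k * spacing_deg` the profile equals anchor
#' `(k mod 6) + 1` exactly, with zero radial slope; the period is six
#' inter-anchor spacings.
#'
#' @param anchors A six-row tibble with columns `x`, `y`, `Y` (CIE xyY).
#' @param r_deg Vector of radii (degrees) at which to evaluate.
#' @param r0_deg Radius of the first anchor, degrees.
#' @param spacing_deg Radial distance between consecutive anchors, degrees.
#' @return A `length(r_deg)` x 3 matrix of XYZ values.
#' @export
gradient_profile <- function(anchors, r_deg, r0_deg, spacing_deg) {
  stopifnot(nrow(anchors) == 6, spacing_deg > 0)
  axyz <- as.matrix(xyY_to_XYZ(anchors$x, anchors$y, anchors$Y))
  t <- (r_deg - r0_deg) / spacing_deg
  i <- floor(t)
  s <- t - i
  k1 <- ((i %% 6) + 6) %% 6 + 1          # anchor at or below
  k2 <- (k1 %% 6) + 1                    # next anchor
  w <- (1 - cospi(s)) / 2
  (1 - w) * axyz[k1, , drop = FALSE] + w * axyz[k2, , drop = FALSE]
}

#' Anchored periodic radial gradient
#'
#' A smooth radial color profile that passes exactly through six anchor
#' colors at equally spaced radii and repeats with period
#' `6 * spacing_deg`. Between consecutive anchors the tristimulus values are
#' cosine-interpolated (zero slope at each anchor). Pixels outside the disk
#' take the background color.
#'
#' @param anchors A six-row tibble with columns `x`, `y`, `Y` (CIE xyY).
#' @param spec A [stimulus_spec()] of kind `"anchored_gradient"`.
#' @param r0_deg Radius of the first anchor, degrees.
#' @param spacing_deg Radial distance between consecutive anchors, degrees.
#' @return A raster with an `inside` disk mask; attributes `anchor_radii_deg`
#'   and `anchor_spacing_deg` record the geometry.
#' @export
anchored_gradient <- function(anchors, spec, r0_deg = 1.8,
                              spacing_deg = 1.2) {
  stopifnot(inherits(spec, "stimulus_spec"),
            spec$kind == "anchored_gradient", nrow(anchors) == 6,
            r0_deg > 0, spacing_deg > 0)
  shell <- spec_raster_shell(spec)
  r <- raster_radius_deg(shell)
  inside <- r <= spec$diameter_deg / 2
  bg <- spec_background_rgb(spec)
  xyz <- gradient_profile(anchors, as.vector(r), r0_deg, spacing_deg)
  out <- raster_from_xyz(xyz, nrow(r), ncol(r), spec$ppd, spec$white_Y,
                         shell$center, inside)
  rgbm <- out$rgb
  for (ch in 1:3) {
    plane <- rgbm[, , ch]
    plane[!inside] <- bg[ch]
    rgbm[, , ch] <- plane
  }
  res <- new_raster(rgbm, spec$ppd, spec$white_Y, shell$center, inside)
  attr(res, "anchor_radii_deg") <- r0_deg + spacing_deg * (0:5)
  attr(res, "anchor_spacing_deg") <- spacing_deg
  res
}

#' Achromatic contour overlay description
#'
#' @param family Contour family: concentric circles for disk stimuli;
#'   octagon/square/diamond/circle grids for plaids; `"none"` is a no-op.
#' @param phase Contour phase. For circles, a fraction of `spacing_deg`; for
#'   grids, a fraction of the tile period applied to both axes (0.5 gives
#'   the counter-phase placement).
#' @param line_width_arcmin Line width in arcminutes of visual angle.
#' @param spacing_deg Radial spacing of concentric circles, degrees.
#' @param period_deg Tile period for grid families, degrees.
#' @param radius_frac Circle radius as a fraction of the tile period
#'   (`circle_grid_small` / `circle_grid_large` only).
#' @param line_Y Line luminance in cd/m^2 (near-black default, below any
#'   stimulus luminance).
#' @return A list of class `contour_spec`.
#' @export
contour_spec <- function(family = c("none", "concentric_circles",
                                    "octagon_grid", "square_grid",
                                    "diamond_grid", "circle_grid_small",
                                    "circle_grid_large"),
                         phase = 0, line_width_arcmin = 2.15,
                         spacing_deg = 1.2, period_deg = NULL,
                         radius_frac = NULL, line_Y = 0.5) {
  family <- match.arg(family)
  stopifnot(phase >= 0, phase < 1, line_Y > 0)
  if (family != "none") stopifnot(line_width_arcmin > 0)
  if (is.null(radius_frac)) {
    radius_frac <- switch(family, circle_grid_small = 0.30,
                          circle_grid_large = 0.48, NA_real_)
  }
  structure(
    list(family = family, phase = phase,
         line_width_arcmin = line_width_arcmin,
         spacing_deg = spacing_deg, period_deg = period_deg,
         radius_frac = radius_frac, line_Y = line_Y),
    class = "contour_spec")
}

#' Rendered line width in pixels for a contour spec
#'
#' `ceil(line_width_arcmin / 60 * ppd)`, at least 1 pixel so that barriers
#' always separate regions.
#'
#' @param cspec A [contour_spec()].
#' @param ppd Pixels per degree.
#' @return Integer pixel width.
#' @export
contour_width_px <- function(cspec, ppd) {
  max(1L, as.integer(ceiling(cspec$line_width_arcmin / 60 * ppd)))
}

# logical matrix: which pixels belong to the contour lines
contour_mask_for <- function(r, cspec) {
  if (cspec$family == "none") {
    return(matrix(FALSE, dim(r)[1], dim(r)[2]))
  }
  w_deg <- contour_width_px(cspec, r$ppd) / r$ppd
  hw <- w_deg / 2
  if (cspec$family == "concentric_circles") {
    rad <- raster_radius_deg(r)
    rmax <- if (!is.null(r$inside)) max(rad[r$inside]) else max(rad)
    radii <- (seq_len(ceiling(rmax / cspec$spacing_deg) + 1) - 1 +
                cspec$phase) * cspec$spacing_deg
    radii <- radii[radii > hw & radii <= rmax - hw]
    m <- matrix(FALSE, nrow(rad), ncol(rad))
    for (rk in radii) m <- m | (abs(rad - rk) <= hw)
    return(m)
  }
  p <- cspec$period_deg
  if (is.null(p)) {
    rlang::abort("grid contour families need period_deg",
                 class = "contourfill_spec_error")
  }
  if (cspec$family == "diamond_grid") {
    # a diamond lattice is invariant under a joint half-period shift of
    # both axes; its counter-phase placement shifts one axis only
    co <- raster_coords_deg(r)
    cc <- list(u = (co$x / p - cspec$phase) %% 1, v = (co$y / p) %% 1)
  } else {
    cc <- tile_cell_coords(r, p, cspec$phase)
  }
  u <- cc$u
  v <- cc$v
  hwc <- hw / p  # half width in cell units
  du <- pmin(u, 1 - u)
  dv <- pmin(v, 1 - v)
  switch(cspec$family,
    square_grid = (du <= hwc) | (dv <= hwc),
    diamond_grid = {
      a <- (u + v) %% 1
      b <- (u - v) %% 1
      (pmin(a, 1 - a) / sqrt(2) <= hwc) | (pmin(b, 1 - b) / sqrt(2) <= hwc)
    },
    octagon_grid = {
      d <- du + dv  # L1 distance to nearest cell corner
      grid_part <- ((du <= hwc) | (dv <= hwc)) & (d >= .octagon_cut)
      diag_part <- abs(d - .octagon_cut) / sqrt(2) <= hwc
      grid_part | diag_part
    },
    circle_grid_small = ,
    circle_grid_large = {
      dc <- sqrt((u - 0.5)^2 + (v - 0.5)^2)
      abs(dc - cspec$radius_frac) <= hwc
    })
}

#' Overlay achromatic contours on a raster
#'
#' Contour pixels are replaced by the line color (a near-black display gray
#' of luminance `line_Y`); every other pixel is bit-identical to the input.
#' `family = "none"` returns the input unchanged.
#'
#' @param r A raster.
#' @param cspec A [contour_spec()].
#' @return A raster; attribute `contour_mask` holds the logical line mask
#'   and `contour_px` its pixel count.
#' @export
overlay_contours <- function(r, cspec) {
  stopifnot(inherits(r, "raster_stim"), inherits(cspec, "contour_spec"))
  if (cspec$family == "none") return(r)
  m <- contour_mask_for(r, cspec)
  line_rgb <- rep(cspec$line_Y / r$white_Y, 3)
  out <- r$rgb
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[m] <- line_rgb[ch]
    out[, , ch] <- plane
  }
  res <- new_raster(out, r$ppd, r$white_Y, r$center, r$inside)
  attr(res, "contour_mask") <- m
  attr(res, "contour_px") <- sum(m)
  res
}

# ---------------------------------------------------------------------------
# Convenience builders with the study's stimulus parameters

#' Printed colors at the six dot locations of the matching experiment
#'
#' @return A six-row tibble with columns `location`, `x`, `y`, `Y`.
#' @export
exp2_anchor_colors <- function() {
  tibble::tibble(
    location = 1:6,
    x = c(0.364, 0.370, 0.325, 0.285, 0.275, 0.312),
    y = c(0.390, 0.373, 0.326, 0.303, 0.318, 0.371),
    Y = c(96.1, 93.4, 97.7, 90.2, 97.4, 95.3))
}

#' Construction pairs for the green/purple plaid
#'
#' Derives two opponent color pairs, symmetric about the mean of the two
#' target extremes in tristimulus space and mutually orthogonal in the
#' isoluminant plane, such that the 50/50 counter-phase mixture of the two
#' octagon images attains exactly the printed green (octagons of image A
#' over interstices of image B) and purple (the reverse overlap) at its
#' extremes. The component colors may sit slightly outside the display
#' gamut; only their mixtures are rendered.
#'
#' @param x1,y1,x2,y2 Chromaticities of the two target extreme colors
#'   (defaults: the printed plaid green and purple).
#' @param Y Shared luminance, cd/m^2.
#' @param ortho_scale Length of the shared orthogonal component relative to
#'   the green-purple half-difference; 1 makes the two pairs exactly
#'   orthogonal and equally long.
#' @return A list with elements `pairA` and `pairB` (two-row color tibbles).
#' @export
plaid_pairs_from_extremes <- function(x1 = 0.329, y1 = 0.412,
                                      x2 = 0.310, y2 = 0.306, Y = 126,
                                      ortho_scale = 1) {
  e <- as.matrix(xyY_to_XYZ(c(x1, x2), c(y1, y2), c(Y, Y)))
  g0 <- colMeans(e)
  w <- (e[1, ] - e[2, ]) / 2                  # isoluminant: w[2] == 0
  wp <- c(-w[3], 0, w[1]) * ortho_scale       # orthogonal, still isoluminant
  mk <- function(m) {
    xy <- XYZ_to_xyY(m[, 1], m[, 2], m[, 3])
    tibble::tibble(member = 1:2, x = xy$x, y = xy$y,
                   X = m[, 1], Y = m[, 2], Z = m[, 3])
  }
  # mixture identities: (A1 + B2) / 2 = g0 + w (green),
  #                     (A2 + B1) / 2 = g0 - w (purple)
  list(pairA = mk(rbind(g0 + w + wp, g0 - w - wp)),
       pairB = mk(rbind(g0 - w + wp, g0 + w - wp)))
}

#' The comparison-battery disk stimulus
#'
#' The 10.8-degree gradient disk composed from three palette opponent pairs
#' at phases 0, 1/3 and 2/3 of the grating cycle.
#'
#' @param ppd Pixels per degree.
#' @param period_deg Grating period, degrees.
#' @param palette Palette supplying the opponent pairs (entries 1, 3, 5 and
#'   their opposites of a 16-entry palette).
#' @return A raster.
#' @export
exp1_disk_raster <- function(ppd = 32, period_deg = 2.4,
                             palette = teufel_palette()) {
  spec <- stimulus_spec("disk_gratings", diameter_deg = 10.8, ppd = ppd,
                        period_deg = period_deg)
  pairs <- lapply(c(1, 3, 5), function(i) palette_pair(palette, i))
  compose_disk(spec, pairs)
}

#' The comparison-battery plaid stimulus
#'
#' The 10.8 x 10.8-degree green/purple octagon plaid with 9.5 cycles per
#' image, anchored to the printed extreme chromaticities.
#'
#' @param ppd Pixels per degree.
#' @param blur Apply the construction blur?
#' @return A raster.
#' @export
exp1_plaid_raster <- function(ppd = 32, blur = TRUE) {
  spec <- stimulus_spec("octagon_plaid", diameter_deg = 10.8, ppd = ppd)
  pr <- plaid_pairs_from_extremes()
  octagon_plaid(spec, pr$pairA, pr$pairB, alpha = 0.5, blur = blur)
}

#' The matching-experiment gradient disk
#'
#' The 19.8-degree disk carrying the anchored periodic radial gradient
#' through the six printed dot-location colors. The anchors sit at radii
#' 2.4 to 6.9 degrees at 0.9-degree spacing (one 5.4-degree period), so
#' that under every contour setting each dot location falls inside a
#' complete inter-contour annulus (never the truncated central disk).
#'
#' @param ppd Pixels per degree.
#' @return A raster with anchor geometry attributes.
#' @export
exp2_gradient_raster <- function(ppd = 32) {
  spec <- stimulus_spec("anchored_gradient", diameter_deg = 19.8, ppd = ppd,
                        period_deg = 5.4)
  anchored_gradient(exp2_anchor_colors(), spec, r0_deg = 2.4,
                    spacing_deg = 0.9)
}

#' Concentric-circle contours for the matching experiment
#'
#' Circles spaced half a gradient period (2.7 degrees) apart. Setting `s`
#' places them so that dot locations fall into consecutive triplets
#' (wrapping around the period): setting 1 separates locations 1-3 from
#' 4-6, and each further setting shifts the circles outward by one sixth
#' of the period (one inter-location spacing).
#'
#' @param setting Contour setting 1, 2 or 3, or `"none"`.
#' @param line_width_arcmin Line width, arcminutes.
#' @return A [contour_spec()].
#' @export
exp2_contours <- function(setting, line_width_arcmin = 2.15) {
  if (identical(setting, "none")) return(contour_spec("none"))
  setting <- as.integer(setting)
  stopifnot(setting %in% 1:3)
  spacing <- 2.7
  offset <- 2.4 + 0.9 * (2.5 + (setting - 1))
  contour_spec("concentric_circles", phase = (offset / spacing) %% 1,
               spacing_deg = spacing, line_width_arcmin = line_width_arcmin)
}
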