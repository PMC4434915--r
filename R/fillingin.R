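# The perceptual mechanism as computation: predicted percept =
# within-region color average. A conservative diffusion iterator provides
# the mechanistic variant whose steady state agrees with the region means.

#' Region-mean percept prediction
#'
#' Each contour-bounded region is painted with the arithmetic mean of its
#' pixels' tristimulus values (averaging in linear light / XYZ, the
#' physical-light average; chromaticities are derived afterwards for
#' reporting). Barrier pixels keep their line color.
#'
#' @param r A raster (with contours overlaid).
#' @param labels A `region_map` consistent with `r`; computed via
#'   [segment_regions()] when missing.
#' @param threshold Luminance threshold used when `labels` is missing.
#' @return A list of class `percept_map`: `region_colors` (tibble with
#'   `label`, `pixel_count`, `X`, `Y`, `Z`, `x`, `y`, `is_background`),
#'   `raster` (the painted raster), `labels`, and `mode = "region_mean"`.
#' @export
region_mean_percept <- function(r, labels = NULL, threshold = 5) {
  if (is.null(labels)) labels <- segment_regions(r, threshold)
  stopifnot(all(dim(labels) == dim(r)))
  d <- dim(r$rgb)
  lab <- as.vector(labels)
  keep <- lab != 0
  m <- matrix(r$rgb, d[1] * d[2], 3)
  sums <- rowsum(m[keep, , drop = FALSE], lab[keep])
  counts <- as.vector(table(lab[keep]))
  means <- sums / counts
  # paint each region with its mean color
  out <- m
  out[keep, ] <- means[lab[keep], ]
  xyz <- linrgb_mat_to_xyz(means, r$white_Y)
  s <- rowSums(xyz)
  bg <- attr(labels, "background_label")
  region_colors <- tibble::tibble(
    label = as.integer(rownames(sums)),
    pixel_count = counts,
    X = xyz[, 1], Y = xyz[, 2], Z = xyz[, 3],
    x = xyz[, 1] / s, y = xyz[, 2] / s,
    is_background = as.integer(rownames(sums)) == bg)
  structure(
    list(region_colors = region_colors,
         raster = new_raster(array(out, d), r$ppd, r$white_Y, r$center,
                             r$inside),
         labels = labels, mode = "region_mean"),
    class = "percept_map")
}

#' @export
print.percept_map <- function(x, ...) {
  cat(sprintf("<percept_map> mode %s, %d region(s)\n", x$mode,
              nrow(x$region_colors)))
  print(x$region_colors, n = 8)
  invisible(x)
}

#' Contour-gated color diffusion to steady state
#'
#' Iterative 4-neighbor averaging in which color spreads equally in all
#' directions except across barrier pixels and image edges (no-flux
#' boundaries). Each step moves a fraction `lambda` of every open
#' neighbor-pair difference, which conserves the total tristimulus over
#' non-barrier pixels exactly at every iteration; the steady state within
#' each region is therefore the region mean. Iteration stops when the
#' largest per-channel per-pixel update falls below `tol`.
#'
#' @param r A raster.
#' @param mask Logical barrier matrix; computed via [barrier_mask()] when
#'   missing. The area outside the stimulus (if the raster has one) is also
#'   treated as blocked.
#' @param tol Convergence tolerance as a linear channel fraction.
#' @param max_iter Iteration budget; exceeding it raises an error of class
#'   `contourfill_no_convergence` carrying the last residual.
#' @param lambda Per-edge transfer fraction in (0, 0.25]; values below 1/4
#'   leave every pixel a positive self-weight, which prevents the
#'   checkerboard oscillation of pure neighbor averaging.
#' @return A raster of class `raster_stim` with attributes `iterations` and
#'   `residual`.
#' @export
diffuse_fill <- function(r, mask = NULL, tol = 1e-6, max_iter = 100000,
                         lambda = 0.2) {
  stopifnot(tol > 0, lambda > 0, lambda <= 0.25)
  if (is.null(mask)) mask <- barrier_mask(r)
  blocked <- mask
  if (!is.null(r$inside)) blocked <- blocked | !r$inside
  free <- !blocked
  h <- nrow(free); w <- ncol(free)
  up <- function(m) rbind(m[1, , drop = FALSE], m[-h, , drop = FALSE])
  dn <- function(m) rbind(m[-1, , drop = FALSE], m[h, , drop = FALSE])
  lf <- function(m) cbind(m[, 1, drop = FALSE], m[, -w, drop = FALSE])
  rt <- function(m) cbind(m[, -1, drop = FALSE], m[, w, drop = FALSE])
  # edge validity: both endpoints free; image border edges are cut by the
  # replicate shift mapping a border pixel onto itself (difference 0)
  vu <- (free & up(free)) + 0; vu[1, ] <- 0
  vd <- (free & dn(free)) + 0; vd[h, ] <- 0
  vl <- (free & lf(free)) + 0; vl[, 1] <- 0
  vr <- (free & rt(free)) + 0; vr[, w] <- 0
  deg <- vu + vd + vl + vr
  chans <- lapply(1:3, function(ch) r$rgb[, , ch])
  iter <- 0L
  repeat {
    iter <- iter + 1L
    residual <- 0
    for (ch in 1:3) {
      x <- chans[[ch]]
      delta <- vu * up(x) + vd * dn(x) + vl * lf(x) + vr * rt(x) - deg * x
      step <- lambda * delta
      residual <- max(residual, max(abs(step)))
      chans[[ch]] <- x + step
    }
    if (residual < tol) break
    if (iter >= max_iter) {
      rlang::abort(
        sprintf("diffusion did not converge in %d iterations (residual %.3g)",
                max_iter, residual),
        class = "contourfill_no_convergence", residual = residual,
        iterations = iter)
    }
  }
  out <- array(0, dim(r$rgb))
  for (ch in 1:3) out[, , ch] <- chans[[ch]]
  res <- new_raster(out, r$ppd, r$white_Y, r$center, r$inside)
  attr(res, "iterations") <- iter
  attr(res, "residual") <- residual
  res
}

#' Diffusion-mode percept prediction
#'
#' Runs [diffuse_fill()] and wraps the steady raster as a `percept_map`
#' whose per-region colors are the means of the diffused raster (equal to
#' the region means of the input up to the convergence tolerance).
#'
#' @inheritParams diffuse_fill
#' @param threshold Luminance threshold for segmentation.
#' @return A `percept_map` with `mode = "diffusion"`.
#' @export
diffusion_percept <- function(r, threshold = 5, tol = 1e-6,
                              max_iter = 100000) {
  labels <- segment_regions(r, threshold)
  steady <- diffuse_fill(r, mask = barrier_mask(r, threshold),
                         tol = tol, max_iter = max_iter)
  pm <- region_mean_percept(steady, labels)
  pm$mode <- "diffusion"
  pm$raster <- steady
  pm
}

# pixel (row, col) of a location given in degrees relative to center
location_to_pixel <- function(r, x_deg, y_deg) {
  c(round(r$center[1] + y_deg * r$ppd), round(r$center[2] + x_deg * r$ppd))
}

#' Predict the matched color at a probe location
#'
#' With contours, the prediction is the mean color of the contour-bounded
#' region containing the location (a probe falling on a barrier pixel falls
#' back to the nearest region pixel, flagged in the result). Without
#' contours, it is the mean color over an annulus around the location --
#' the local color immediately around a small probe dot.
#'
#' @param r A raster (contours overlaid for `"with_contours"`).
#' @param x_deg,y_deg Probe location in degrees from the stimulus center.
#' @param mode `"with_contours"` or `"no_contours"`.
#' @param labels Optional precomputed `region_map` (with-contours mode).
#' @param percept Optional precomputed `percept_map` (with-contours mode).
#' @param inner_deg,outer_deg Annulus radii in degrees (no-contours mode);
#'   the inner radius is the probe-dot radius analog, the outer radius
#'   keeps the sample local relative to the gradient's anchor spacing.
#' @param threshold Luminance threshold for segmentation.
#' @return A one-row tibble with `X`, `Y`, `Z`, `x`, `y`, plus `label` and
#'   `on_barrier` in with-contours mode.
#' @export
predict_match <- function(r, x_deg, y_deg = 0,
                          mode = c("with_contours", "no_contours"),
                          labels = NULL, percept = NULL,
                          inner_deg = 0.05, outer_deg = 0.15,
                          threshold = 5) {
  mode <- match.arg(mode)
  if (mode == "no_contours") {
    co <- raster_coords_deg(r)
    dist <- sqrt((co$x - x_deg)^2 + (co$y - y_deg)^2)
    sel <- dist >= inner_deg & dist <= outer_deg
    if (!is.null(r$inside)) sel <- sel & r$inside
    if (!any(sel)) {
      rlang::abort("annulus contains no stimulus pixels",
                   class = "contourfill_spec_error")
    }
    m <- matrix(r$rgb, length(sel), 3)
    mean_rgb <- unname(colMeans(m[as.vector(sel), , drop = FALSE]))
    xyz <- as.vector(linrgb_mat_to_xyz(matrix(mean_rgb, 1), r$white_Y))
    s <- sum(xyz)
    return(tibble::tibble(X = xyz[1], Y = xyz[2], Z = xyz[3],
                          x = xyz[1] / s, y = xyz[2] / s))
  }
  if (is.null(percept)) percept <- region_mean_percept(r, labels, threshold)
  labels <- percept$labels
  px <- location_to_pixel(r, x_deg, y_deg)
  if (px[1] < 1 || px[1] > nrow(labels) || px[2] < 1 ||
      px[2] > ncol(labels)) {
    rlang::abort("probe location outside the raster",
                 class = "contourfill_spec_error")
  }
  lab <- labels[px[1], px[2]]
  on_barrier <- lab == 0
  if (on_barrier) {
    # nearest non-barrier pixel, raster-scan tie-break
    free_idx <- which(labels != 0)
    rows <- (free_idx - 1) %% nrow(labels) + 1
    cols <- (free_idx - 1) %/% nrow(labels) + 1
    nearest <- which.min((rows - px[1])^2 + (cols - px[2])^2)
    lab <- labels[free_idx[nearest]]
  }
  row <- percept$region_colors[percept$region_colors$label == lab, ]
  tibble::tibble(X = row$X, Y = row$Y, Z = row$Z, x = row$x, y = row$y,
                 label = lab, on_barrier = on_barrier)
}
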