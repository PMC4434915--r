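# Stimulus synthesis: gratings, disk composition, plaid, gradient, overlays.

disk_spec <- function(ppd = 8, period = 2.4, blur = NULL) {
  stimulus_spec("disk_gratings", diameter_deg = 10.8, ppd = ppd,
                period_deg = period, blur_sigma_deg = blur)
}

test_that("radial square-wave grating follows the ring formula", {
  spec <- disk_spec(ppd = 8)
  pal <- teufel_palette()
  pair <- palette_pair(pal, 1)
  g <- radial_square_grating(spec, pair, phase = 0.2)

  # raster size: round(diameter * ppd)
  expect_equal(dim(g), c(round(10.8 * 8), round(10.8 * 8)))
  # at the study scale of 32 px/deg the disk is 346 px wide
  expect_equal(round(10.8 * 32), 346)

  # brute-force per-pixel oracle
  rgbcols <- XYZ_to_display(pair$X, pair$Y, pair$Z, 340)
  n <- dim(g)[1]
  ctr <- (n + 1) / 2
  bg <- 1 # background = display white
  for (i in seq(1, n, by = 7)) for (j in seq(1, n, by = 7)) {
    r <- sqrt((i - ctr)^2 + (j - ctr)^2) / 8
    want <- if (r > 5.4) c(bg, bg, bg) else {
      k <- floor(2 * (r / 2.4 + 0.2)) %% 2
      unlist(rgbcols[k + 1, c("R", "G", "B")])
    }
    expect_equal(unname(g$rgb[i, j, ]), unname(want), tolerance = 1e-12)
  }

  # periodicity: phase p and p + 1 give identical rasters
  g2 <- radial_square_grating(spec, pair, phase = 1.2)
  expect_identical(g$rgb, g2$rgb)
})

test_that("disk composition averages three gratings and blurs", {
  pal <- teufel_palette()
  pair <- palette_pair(pal, 1)
  spec0 <- disk_spec(ppd = 8, blur = 0)

  # identical pairs and phases with zero blur equal the single grating
  same <- compose_disk(spec0, list(pair, pair, pair), phases = rep(0.1, 3))
  single <- radial_square_grating(spec0, pair, phase = 0.1)
  expect_equal(same$rgb, single$rgb, tolerance = 1e-12)

  # averaging commutes: permuting the gratings changes nothing
  pairs <- lapply(c(1, 3, 5), function(i) palette_pair(pal, i))
  a <- compose_disk(spec0, pairs, phases = c(0, 1 / 3, 2 / 3))
  b <- compose_disk(spec0, pairs[c(3, 1, 2)],
                    phases = c(2 / 3, 0, 1 / 3))
  expect_equal(a$rgb, b$rgb, tolerance = 1e-12)

  # pair count is enforced
  expect_error(compose_disk(spec0, pairs[1:2], phases = c(0, 1 / 3, 2 / 3)),
               class = "contourfill_spec_error")

  # rotational symmetry: the blurred disk depends on radius only
  ab <- compose_disk(disk_spec(ppd = 8), pairs)
  n <- dim(ab)[1]; ctr <- (n + 1) / 2
  k <- round(1.5 * 8)
  expect_equal(ab$rgb[ctr + k, ctr, ], ab$rgb[ctr, ctr + k, ],
               tolerance = 1e-6)
  expect_equal(ab$rgb[ctr - k, ctr, ], ab$rgb[ctr, ctr - k, ],
               tolerance = 1e-6)
})

test_that("radial mean of the composite over one period is the six-color mean", {
  # numerical oracle: sample the unblurred composite along a radial line
  # across exactly one period; the square waves each spend half the length
  # in each member, so the tristimulus mean is the mean of all six colors
  # (exactly, because mixing and averaging are both linear in XYZ)
  pal <- teufel_palette()
  pairs <- lapply(c(1, 3, 5), function(i) palette_pair(pal, i))
  spec <- disk_spec(ppd = 20, blur = 0)
  d <- compose_disk(spec, pairs)
  n <- dim(d)[1]
  tb <- as_tibble(d)
  # one full period (48 px) along the row just below the geometric center
  row <- tb[tb$row == n / 2 + 1 & tb$x_deg >= 0.2 - 1e-9 &
              tb$x_deg < 2.6 - 1e-9, ]
  expect_equal(nrow(row), 48)
  got <- colMeans(as.matrix(xyY_to_XYZ(row$x, row$y, row$Y)))
  six <- do.call(rbind, pairs)
  want <- colMeans(six[, c("X", "Y", "Z")])
  expect_equal(unname(got), unname(unlist(want)), tolerance = 1e-6)
  # the xy mean sits near the palette gray (not exactly: chromaticity
  # averages are weighted by the tristimulus sum, which varies with hue)
  expect_lt(abs(mean(row$x) - mean(six$x)), 0.02)
  expect_lt(abs(mean(row$y) - mean(six$y)), 0.02)
})

test_that("octagon plaid mixes counter-phase images in linear light", {
  spec <- stimulus_spec("octagon_plaid", diameter_deg = 8, ppd = 16,
                        cycles_per_image = 8)
  pr <- plaid_pairs_from_extremes()
  pl <- octagon_plaid(spec, pr$pairA, pr$pairB, alpha = 0.5, blur = FALSE)

  # tile period: diameter / cycles = 1 deg = 16 px; the raster repeats
  expect_equal(pl$rgb[1:32, 1:32, ], pl$rgb[17:48, 17:48, ],
               tolerance = 1e-12)

  # swapping the two layers (pairs with their phases) at alpha = 0.5
  # leaves the output unchanged
  pl2 <- octagon_plaid(spec, pr$pairB, pr$pairA, alpha = 0.5,
                       phase_a = 0.5, phase_b = 0, blur = FALSE)
  expect_equal(pl$rgb, pl2$rgb, tolerance = 1e-12)

  # direct per-pixel oracle: unblurred mixed color = alpha-weighted mean of
  # the two local tile colors, classified independently
  cut <- 1 / (2 + sqrt(2))
  n <- dim(pl)[1]; ctr <- (n + 1) / 2
  linA <- as.matrix(XYZ_to_display(pr$pairA$X, pr$pairA$Y, pr$pairA$Z, 340,
                                   clip = FALSE)[, 1:3])
  linB <- as.matrix(XYZ_to_display(pr$pairB$X, pr$pairB$Y, pr$pairB$Z, 340,
                                   clip = FALSE)[, 1:3])
  cls <- function(u, v) {
    (min(u, 1 - u) + min(v, 1 - v)) >= cut
  }
  for (i in seq(3, n, by = 13)) for (j in seq(5, n, by = 13)) {
    u <- ((j - ctr) / 16) %% 1; v <- ((i - ctr) / 16) %% 1
    ub <- (u - 0.5) %% 1; vb <- (v - 0.5) %% 1
    a <- linA[if (cls(u, v)) 1 else 2, ]
    b <- linB[if (cls(ub, vb)) 1 else 2, ]
    want <- pmin(pmax(0.5 * a + 0.5 * b, 0), 1)
    expect_equal(unname(pl$rgb[i, j, ]), unname(want), tolerance = 1e-9)
  }

  # non-orthogonal pairs warn but still render
  pal <- teufel_palette()
  expect_warning(
    octagon_plaid(spec, palette_pair(pal, 1), palette_pair(pal, 2),
                  blur = FALSE),
    "orthogonality")
})

test_that("the study plaid attains the printed extremes at full luminance", {
  pl <- exp1_plaid_raster(ppd = 16, blur = FALSE)
  tb <- as_tibble(pl)
  gdir <- c(0.329 - 0.310, 0.412 - 0.306)
  gdir <- gdir / sqrt(sum(gdir^2))
  proj <- (tb$x - mean(tb$x)) * gdir[1] + (tb$y - mean(tb$y)) * gdir[2]
  g <- tb[which.max(proj), ]
  p <- tb[which.min(proj), ]
  expect_equal(c(g$x, g$y, g$Y), c(0.329, 0.412, 126), tolerance = 1e-9)
  expect_equal(c(p$x, p$y, p$Y), c(0.310, 0.306, 126), tolerance = 1e-9)
})

test_that("the anchored gradient passes through its anchors", {
  anchors <- exp2_anchor_colors()
  radii <- 2.4 + 0.9 * (0:5)

  # the profile hits every anchor exactly, in xyY
  prof <- gradient_profile(anchors, radii, 2.4, 0.9)
  xy <- XYZ_to_xyY(prof[, 1], prof[, 2], prof[, 3])
  expect_equal(xy$x, anchors$x, tolerance = 1e-12)
  expect_equal(xy$y, anchors$y, tolerance = 1e-12)
  expect_equal(xy$Y, anchors$Y, tolerance = 1e-12)
  # printed anchor 1
  expect_equal(c(xy$x[1], xy$y[1], xy$Y[1]), c(0.364, 0.390, 96.1))

  # periodicity: one full period later the profile repeats
  prof2 <- gradient_profile(anchors, radii + 5.4, 2.4, 0.9)
  expect_equal(prof, prof2, tolerance = 1e-12)

  # midpoints are the half-cosine mix, i.e. the plain XYZ mean
  mid <- gradient_profile(anchors, radii[1] + 0.45, 2.4, 0.9)
  axyz <- as.matrix(xyY_to_XYZ(anchors$x, anchors$y, anchors$Y))
  expect_equal(as.vector(mid), unname((axyz[1, ] + axyz[2, ]) / 2),
               tolerance = 1e-12)

  # the rendered raster carries the profile at pixel radii
  g <- exp2_gradient_raster(ppd = 10)
  tb <- as_tibble(g)
  px <- tb[abs(tb$y_deg) < 1e-9 & abs(tb$x_deg - 3.0) < 0.051, ]
  want <- gradient_profile(anchors, px$x_deg, 2.4, 0.9)
  wxy <- XYZ_to_xyY(want[, 1], want[, 2], want[, 3])
  expect_equal(px$x, wxy$x, tolerance = 1e-6)
  expect_equal(px$Y, wxy$Y, tolerance = 1e-6)

  # six anchors are required
  spec <- stimulus_spec("anchored_gradient", diameter_deg = 19.8, ppd = 4,
                        period_deg = 5.4)
  expect_error(anchored_gradient(anchors[1:5, ], spec))
})

test_that("contour overlays replace exactly the line pixels", {
  base <- exp1_disk_raster(ppd = 8)
  none <- overlay_contours(base, contour_spec("none"))
  expect_identical(none$rgb, base$rgb)

  cs <- contour_spec("concentric_circles", phase = 0, spacing_deg = 1.2,
                     line_width_arcmin = 2.15)
  ov <- overlay_contours(base, cs)
  m <- attr(ov, "contour_mask")
  expect_true(any(m))
  # non-contour pixels are bit-identical to the input
  for (ch in 1:3) {
    plane_in <- base$rgb[, , ch]
    plane_out <- ov$rgb[, , ch]
    expect_identical(plane_out[!m], plane_in[!m])
    expect_true(all(plane_out[m] == 0.5 / 340))
  }
  # determinism: the same spec overlays identically
  ov2 <- overlay_contours(base, cs)
  expect_identical(ov$rgb, ov2$rgb)

  # line width in pixels: ceil(arcmin / 60 * ppd), at least 1
  expect_equal(contour_width_px(cs, 32), 2L)
  expect_equal(contour_width_px(contour_spec("octagon_grid",
                                             line_width_arcmin = 0.86,
                                             period_deg = 1), 32), 1L)
  expect_equal(contour_width_px(cs, 4), 1L)
})

test_that("blur preserves channel convexity and uniform fields", {
  u <- uniform_raster(n = 24)
  bu <- raster_blur(u, 0.3)
  expect_equal(bu$rgb, u$rgb, tolerance = 1e-9)

  withr::with_seed(7, {
    r <- random_smooth_raster(n = 24)
  })
  br <- raster_blur(r, 0.2)
  for (ch in 1:3) {
    expect_true(min(br$rgb[, , ch]) >= min(r$rgb[, , ch]) - 1e-9)
    expect_true(max(br$rgb[, , ch]) <= max(r$rgb[, , ch]) + 1e-9)
  }
})
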