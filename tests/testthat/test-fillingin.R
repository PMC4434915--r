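# Region-mean percepts, contour-gated diffusion, match prediction.

test_that("region means reproduce hand-computed averages on a toy raster", {
  # 4 x 4 raster, vertical barrier in column 3 splits left from right
  vals <- array(0, c(4, 4, 3))
  vals[, , 1] <- matrix(c(
    0.10, 0.20, 0.001, 0.70,
    0.30, 0.40, 0.001, 0.80,
    0.10, 0.20, 0.001, 0.60,
    0.30, 0.40, 0.001, 0.50), 4, 4, byrow = TRUE)
  vals[, , 2] <- 0.5
  vals[, , 3] <- 0.25
  vals[, 3, 2] <- 0.001
  vals[, 3, 3] <- 0.001
  r <- structure(list(rgb = vals, ppd = 4, white_Y = 340,
                      center = c(2.5, 2.5), inside = NULL),
                 class = "raster_stim")
  mask <- matrix(FALSE, 4, 4); mask[, 3] <- TRUE
  labels <- label_regions(mask)
  pm <- region_mean_percept(r, labels)
  expect_equal(attr(labels, "n_regions"), 2)
  left <- pm$region_colors[pm$region_colors$label == labels[1, 1], ]
  right <- pm$region_colors[pm$region_colors$label == labels[1, 4], ]
  left_want <- colMeans(matrix(vals[, 1:2, ], ncol = 3)) # hand average
  expect_equal(left_want[1], mean(c(0.10, 0.20, 0.30, 0.40)))
  got_left <- display_to_XYZ(left_want[1], left_want[2], left_want[3], 340)
  expect_equal(unname(c(left$X, left$Y, left$Z)),
               c(got_left$X, got_left$Y, got_left$Z), tolerance = 1e-12)
  right_want <- colMeans(matrix(vals[, 4, ], ncol = 3))
  got_right <- display_to_XYZ(right_want[1], right_want[2], right_want[3], 340)
  expect_equal(left$pixel_count, 8)
  expect_equal(right$pixel_count, 4)
  expect_equal(unname(c(right$X, right$Y, right$Z)),
               c(got_right$X, got_right$Y, got_right$Z), tolerance = 1e-12)
  # painted raster is constant within each region, barrier untouched
  expect_equal(pm$raster$rgb[1, 1, 1], pm$raster$rgb[4, 2, 1])
  expect_equal(pm$raster$rgb[2, 3, 1], 0.001)
})

test_that("uniform rasters are fixed points of averaging and diffusion", {
  u <- uniform_raster(n = 16)
  pm <- region_mean_percept(u)
  expect_equal(pm$raster$rgb, u$rgb, tolerance = 1e-12)
  df <- diffuse_fill(u, tol = 1e-6)
  expect_equal(attr(df, "iterations"), 1)
  expect_equal(df$rgb, u$rgb, tolerance = 1e-12)
})

test_that("diffusion conserves total tristimulus and reaches region means", {
  withr::with_seed(21, {
    r <- random_smooth_raster(n = 26)
    mask <- random_barrier_mask(26)
  })
  rr <- r
  for (ch in 1:3) {
    plane <- rr$rgb[, , ch]
    plane[mask] <- 0.5 / 340
    rr$rgb[, , ch] <- plane
  }
  # conservation: free-pixel channel sums are invariant (checked after a
  # few steps and at the steady state)
  free <- !mask
  sums0 <- sapply(1:3, function(ch) sum(rr$rgb[, , ch][free]))
  part <- diffuse_fill(rr, mask, tol = 1e-12, max_iter = 7,
                       lambda = 0.2) |> try(silent = TRUE)
  expect_s3_class(attr(part, "condition"), "contourfill_no_convergence")
  steady <- diffuse_fill(rr, mask, tol = 1e-9)
  sums1 <- sapply(1:3, function(ch) sum(steady$rgb[, , ch][free]))
  expect_equal(sums1, sums0, tolerance = 1e-9)

  # oracle equivalence: the steady state is the region-mean painting
  labels <- label_regions(mask)
  pm <- region_mean_percept(rr, labels)
  expect_lt(max(abs(steady$rgb - pm$raster$rgb)), 1e-4)
})

test_that("a barrier-free image diffuses to its global mean", {
  withr::with_seed(22, {
    r <- random_smooth_raster(n = 20)
  })
  steady <- diffuse_fill(r, matrix(FALSE, 20, 20), tol = 1e-9)
  for (ch in 1:3) {
    expect_equal(as.vector(steady$rgb[, , ch]),
                 rep(mean(r$rgb[, , ch]), 400), tolerance = 1e-4)
  }
})

test_that("diffusion percept agrees with the region-mean percept", {
  u <- uniform_raster(n = 40, x = 0.35, y = 0.35, Y = 110, ppd = 8)
  withr::with_seed(23, {
    g <- random_smooth_raster(n = 40, ppd = 8)
  })
  cs <- contour_spec("concentric_circles", spacing_deg = 1.2,
                     line_width_arcmin = 10)
  ov <- overlay_contours(g, cs)
  dp <- diffusion_percept(ov, tol = 1e-8)
  rm <- region_mean_percept(ov)
  expect_equal(dp$mode, "diffusion")
  expect_equal(dp$region_colors$x, rm$region_colors$x, tolerance = 1e-5)
  expect_lt(max(abs(dp$raster$rgb - rm$raster$rgb)), 1e-3)
})

test_that("match prediction returns region colors and local annulus means", {
  g <- exp2_gradient_raster(ppd = 16)
  cs <- contoured_stimulus(g, exp2_contours(1))

  # two locations in the same annulus share one predicted color
  p2 <- predict_match(cs$overlaid, 3.3, 0, "with_contours",
                      percept = cs$percept)
  p3 <- predict_match(cs$overlaid, 4.2, 0, "with_contours",
                      percept = cs$percept)
  expect_equal(p2$x, p3$x, tolerance = 1e-12)
  expect_equal(p2$label, p3$label)

  # the prediction is exactly the region-mean oracle for that region
  want <- cs$percept$region_colors
  want <- want[want$label == p2$label, ]
  expect_equal(c(p2$X, p2$Y, p2$Z), c(want$X, want$Y, want$Z))

  # a probe on a barrier pixel falls back to the nearest region, flagged
  circ_r <- 2.4 + 0.9 * 2.5 # a contour circle radius for setting 1
  pb <- predict_match(cs$overlaid, circ_r, 0, "with_contours",
                      percept = cs$percept)
  expect_true(pb$on_barrier)
  expect_true(pb$label %in% cs$percept$region_colors$label)

  # no-contour annulus sampling tracks the local gradient color
  loc <- predict_match(g, 2.4, 0, "no_contours")
  expect_equal(loc$x, 0.364, tolerance = 2e-3)
  expect_error(predict_match(g, 30, 0, "no_contours"),
               class = "contourfill_spec_error")
})

test_that("percepts respond to contour phase but not contour styling", {
  g <- exp2_gradient_raster(ppd = 16)
  tol <- 1e-6
  s1 <- contoured_stimulus(g, exp2_contours(1))
  s2 <- contoured_stimulus(g, exp2_contours(2))
  # phase shift by one sixth period moves at least one region mean by far
  # more than the diffusion tolerance
  m1 <- predict_match(s1$overlaid, 3.3, 0, "with_contours",
                      percept = s1$percept)
  m2 <- predict_match(s2$overlaid, 3.3, 0, "with_contours",
                      percept = s2$percept)
  expect_gt(xy_distance(m1$x, m1$y, m2$x, m2$y), 10 * tol)

  # predictions depend on the partition, not line width or darkness
  for (variant in list(c(2.15, 0.5), c(4.3, 0.5), c(2.15, 2))) {
    cs <- contour_spec("concentric_circles", phase = attr(exp2_contours(1), "phase"),
                       spacing_deg = 2.7, line_width_arcmin = variant[1],
                       line_Y = variant[2])
    cs$phase <- exp2_contours(1)$phase
    sv <- contoured_stimulus(g, cs)
    mv <- predict_match(sv$overlaid, 3.3, 0, "with_contours",
                        percept = sv$percept)
    expect_equal(mv$x, m1$x, tolerance = 5e-3)
    expect_equal(mv$y, m1$y, tolerance = 5e-3)
  }
})
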