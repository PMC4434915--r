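# Shared fixtures and independent oracles, all generated in code.

# independent 4-connected flood-fill labeling (stack-based), used as the
# oracle for label_regions
flood_fill_labels <- function(blocked) {
  h <- nrow(blocked); w <- ncol(blocked)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (jj in seq_len(w)) for (ii in seq_len(h)) {
    if (blocked[ii, jj] || lab[ii, jj] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(ii, jj))
    lab[ii, jj] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= h && q[2] >= 1 && q[2] <= w &&
            !blocked[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- nxt
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# two labelings describe the same partition (up to label permutation)
same_partition <- function(a, b) {
  if (!all(dim(a) == dim(b))) return(FALSE)
  if (!all((a == 0) == (b == 0))) return(FALSE)
  keep <- a != 0
  key <- paste(a[keep], b[keep])
  length(unique(key)) == length(unique(a[keep])) &&
    length(unique(key)) == length(unique(b[keep]))
}

# small raster of a given uniform xyY color
uniform_raster <- function(n = 20, x = 1 / 3, y = 1 / 3, Y = 126,
                           ppd = 10, white_Y = 340) {
  xyz <- contourfill::xyY_to_XYZ(x, y, Y)
  rgb <- contourfill::XYZ_to_display(xyz$X, xyz$Y, xyz$Z, white_Y)
  arr <- array(0, c(n, n, 3))
  arr[, , 1] <- rgb$R; arr[, , 2] <- rgb$G; arr[, , 3] <- rgb$B
  structure(list(rgb = arr, ppd = ppd, white_Y = white_Y,
                 center = c((n + 1) / 2, (n + 1) / 2), inside = NULL),
            class = "raster_stim")
}

# random smooth in-gamut raster: mixture of a few palette colors with a
# smooth spatial weight field
random_smooth_raster <- function(n = 28, ppd = 10, white_Y = 340) {
  pal <- contourfill::teufel_palette(radius = 0.06)
  idx <- sample(nrow(pal), 3)
  cols <- contourfill::XYZ_to_display(pal$X[idx], pal$Y[idx], pal$Z[idx],
                                      white_Y)
  cm <- cbind(cols$R, cols$G, cols$B)
  xs <- matrix(seq(0, 1, length.out = n), n, n)
  ys <- t(xs)
  f1 <- runif(1, 0.5, 2); f2 <- runif(1, 0.5, 2)
  w1 <- (1 + sinpi(2 * f1 * xs + runif(1))) / 2
  w2 <- (1 + cospi(2 * f2 * ys + runif(1))) / 2
  w3 <- 1
  tot <- w1 + w2 + w3
  arr <- array(0, c(n, n, 3))
  for (ch in 1:3) {
    arr[, , ch] <- (w1 * cm[1, ch] + w2 * cm[2, ch] + w3 * cm[3, ch]) / tot
  }
  structure(list(rgb = arr, ppd = ppd, white_Y = white_Y,
                 center = c((n + 1) / 2, (n + 1) / 2), inside = NULL),
            class = "raster_stim")
}

# a random closed-curve barrier mask on an n x n grid (circle or rectangle
# outline), guaranteed closed
random_barrier_mask <- function(n = 28) {
  m <- matrix(FALSE, n, n)
  if (runif(1) < 0.5) {
    cx <- runif(1, 0.4, 0.6) * n; cy <- runif(1, 0.4, 0.6) * n
    rad <- runif(1, 0.2, 0.32) * n
    co <- expand.grid(r = seq_len(n), c = seq_len(n))
    d <- sqrt((co$r - cy)^2 + (co$c - cx)^2)
    m[cbind(co$r, co$c)] <- abs(d - rad) <= 0.75
  } else {
    r1 <- sample(4:8, 1); r2 <- sample((n - 8):(n - 4), 1)
    c1 <- sample(4:8, 1); c2 <- sample((n - 8):(n - 4), 1)
    m[r1:r2, c(c1, c2)] <- TRUE
    m[c(r1, r2), c1:c2] <- TRUE
  }
  m
}

# per-location mean matches of one condition, as a plain data frame
location_means <- function(records, cond) {
  sub <- records[records$condition == cond, ]
  aggregate(cbind(x, y) ~ location, data = as.data.frame(sub), FUN = mean)
}
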