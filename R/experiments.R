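# In-silico replications: the same/different comparison battery and the
# six-location color-matching experiment with chromaticity clustering.

#' Bundle a base raster with a contour overlay and its percept
#'
#' Renders the overlay, segments the result and computes the region-mean
#' percept once, so that comparison batteries can reuse them.
#'
#' @param base The underlying colored raster.
#' @param cspec A [contour_spec()].
#' @param threshold Luminance threshold for segmentation, cd/m^2.
#' @return A list of class `contoured_stim` with elements `base`, `cspec`,
#'   `overlaid`, `labels`, `percept`.
#' @export
contoured_stimulus <- function(base, cspec, threshold = 5) {
  overlaid <- overlay_contours(base, cspec)
  labels <- segment_regions(overlaid, threshold)
  percept <- region_mean_percept(overlaid, labels)
  structure(list(base = base, cspec = cspec, overlaid = overlaid,
                 labels = labels, percept = percept),
            class = "contoured_stim")
}

# per-pixel chromaticity planes of a percept raster
percept_xy_planes <- function(r) {
  d <- dim(r$rgb)
  xyz <- raster_xyz_matrix(r)
  s <- rowSums(xyz)
  list(x = matrix(xyz[, 1] / s, d[1], d[2]),
       y = matrix(xyz[, 2] / s, d[1], d[2]))
}

#' Ideal-observer same/different decision
#'
#' Compares the predicted percepts of two contour arrangements of the same
#' underlying colored image. Every region of the finer partition (the
#' partition induced by both contour sets together) is probed through its
#' pixels; the verdict is "same" iff the largest chromaticity difference
#' across probes is at most `tol_xy`.
#'
#' @param stim_a,stim_b Two [contoured_stimulus()] objects sharing the same
#'   base raster.
#' @param tol_xy Chromaticity (xy distance) tolerance.
#' @return A one-row tibble with `verdict` ("same"/"different"), `max_dxy`
#'   and `n_probe_px`.
#' @export
exp1_decide <- function(stim_a, stim_b, tol_xy = 0.005) {
  stopifnot(inherits(stim_a, "contoured_stim"),
            inherits(stim_b, "contoured_stim"))
  if (!identical(dim(stim_a$base$rgb), dim(stim_b$base$rgb)) ||
      max(abs(stim_a$base$rgb - stim_b$base$rgb)) > 1e-12) {
    rlang::abort("stimuli do not share the same underlying colored image",
                 class = "contourfill_comparison_error")
  }
  bg_a <- attr(stim_a$labels, "background_label")
  bg_b <- attr(stim_b$labels, "background_label")
  valid <- stim_a$labels != 0 & stim_b$labels != 0
  if (bg_a > 0) valid <- valid & stim_a$labels != bg_a
  if (bg_b > 0) valid <- valid & stim_b$labels != bg_b
  pa <- percept_xy_planes(stim_a$percept$raster)
  pb <- percept_xy_planes(stim_b$percept$raster)
  d <- sqrt((pa$x - pb$x)^2 + (pa$y - pb$y)^2)
  max_dxy <- max(d[valid])
  tibble::tibble(
    verdict = if (max_dxy <= tol_xy) "same" else "different",
    max_dxy = max_dxy, n_probe_px = sum(valid))
}

# the thirteen contoured versions used in the comparison battery
exp1_battery_stimuli <- function(ppd = 32, period_deg = 2.4,
                                 threshold = 5) {
  disk <- exp1_disk_raster(ppd = ppd, period_deg = period_deg)
  plaid <- exp1_plaid_raster(ppd = ppd)
  tile <- 10.8 / 9.5
  disk_contour <- function(phase) {
    contour_spec("concentric_circles", phase = phase,
                 spacing_deg = period_deg / 2, line_width_arcmin = 2.15)
  }
  plaid_contour <- function(family, phase) {
    contour_spec(family, phase = phase, period_deg = tile,
                 line_width_arcmin = 0.86)
  }
  stims <- list(
    disk_B = contoured_stimulus(disk, disk_contour(0), threshold),
    disk_C = contoured_stimulus(disk, disk_contour(1 / 3), threshold),
    disk_D = contoured_stimulus(disk, disk_contour(2 / 3), threshold))
  fams <- c("octagon_grid", "square_grid", "diamond_grid",
            "circle_grid_small", "circle_grid_large")
  for (f in fams) {
    for (ph in c(0, 0.5)) {
      stims[[paste0(f, "_", ph)]] <-
        contoured_stimulus(plaid, plaid_contour(f, ph), threshold)
    }
  }
  stims
}

#' Run the full same/different comparison battery
#'
#' Same-contour trials pair each contoured stimulus with an identically
#' contoured copy; different-contour trials run the three pairings of the
#' disk's contour phases and the five counter-phase plaid pairings. Each
#' comparison is repeated `n_repeats` times (the ideal observer is
#' deterministic, so repeats replicate the design, not the noise).
#'
#' @param tol_xy Chromaticity tolerance for [exp1_decide()].
#' @param ppd Pixels per degree used for rendering.
#' @param n_repeats Repeats per comparison.
#' @param period_deg Disk grating period, degrees.
#' @return A tibble with one row per trial: `stimulus`, `pair`,
#'   `trial_type`, `repeat_id`, `verdict`, `max_dxy`.
#' @export
run_exp1_battery <- function(tol_xy = 0.005, ppd = 32, n_repeats = 4,
                             period_deg = 2.4) {
  stims <- exp1_battery_stimuli(ppd = ppd, period_deg = period_deg)
  fams <- c("octagon_grid", "square_grid", "diamond_grid",
            "circle_grid_small", "circle_grid_large")
  diff_pairs <- c(
    list(c("disk_B", "disk_C"), c("disk_B", "disk_D"),
         c("disk_C", "disk_D")),
    lapply(fams, function(f) paste0(f, c("_0", "_0.5"))))
  same_pairs <- lapply(names(stims), function(nm) c(nm, nm))
  run_pairs <- function(pairs, type) {
    purrr::map_dfr(pairs, function(p) {
      dec <- exp1_decide(stims[[p[1]]], stims[[p[2]]], tol_xy)
      tibble::tibble(
        stimulus = if (grepl("^disk", p[1])) "disk" else "plaid",
        pair = paste(p[1], p[2], sep = " vs "),
        trial_type = type,
        repeat_id = seq_len(n_repeats),
        verdict = dec$verdict, max_dxy = dec$max_dxy)
    })
  }
  dplyr::bind_rows(run_pairs(same_pairs, "same_contour"),
                   run_pairs(diff_pairs, "different_contour"))
}

#' Summarise a comparison battery
#'
#' @param trials Trial table from [run_exp1_battery()].
#' @return A tibble with one row per trial type: number of trials, number
#'   of expected verdicts ("same" on same-contour trials, "different" on
#'   different-contour trials) and the percentage.
#' @export
summarise_exp1 <- function(trials) {
  expected <- c(same_contour = "same", different_contour = "different")
  dplyr::summarise(
    dplyr::group_by(trials, .data$trial_type),
    n_trials = dplyr::n(),
    n_expected = sum(.data$verdict == expected[.data$trial_type[1]]),
    pct_expected = 100 * .data$n_expected / .data$n_trials,
    .groups = "drop")
}

#' Dot-location probe positions for the matching experiment
#'
#' @return A tibble with `location`, `x_deg`, `y_deg` (along the +x radius).
#' @export
exp2_locations <- function() {
  tibble::tibble(location = 1:6, x_deg = 2.4 + 0.9 * (0:5), y_deg = 0)
}

#' Model-predicted matches of the six-location matching experiment
#'
#' For each contour condition (none / 1 / 2 / 3) and each of the six dot
#' locations on the anchored-gradient disk, the predicted match is computed
#' with [predict_match()]: annulus-sampled local color without contours,
#' region-mean color otherwise.
#'
#' @param ppd Pixels per degree for rendering the gradient disk.
#' @param conditions Subset of `c("none", "1", "2", "3")`.
#' @param threshold Luminance threshold for segmentation.
#' @return A `MatchRecord` tibble: `condition`, `location`, `source`,
#'   `observer_id`, `repeat_id`, `X`, `Y`, `Z`, `x`, `y`.
#' @export
run_exp2 <- function(ppd = 32, conditions = c("none", "1", "2", "3"),
                     threshold = 5) {
  base <- exp2_gradient_raster(ppd = ppd)
  locs <- exp2_locations()
  rows <- purrr::map_dfr(conditions, function(cond) {
    if (cond == "none") {
      preds <- purrr::map_dfr(seq_len(6), function(k) {
        predict_match(base, locs$x_deg[k], locs$y_deg[k],
                      mode = "no_contours")
      })
    } else {
      cs <- contoured_stimulus(base, exp2_contours(cond), threshold)
      preds <- purrr::map_dfr(seq_len(6), function(k) {
        predict_match(cs$overlaid, locs$x_deg[k], locs$y_deg[k],
                      mode = "with_contours", percept = cs$percept)
      })
      preds <- preds[, c("X", "Y", "Z", "x", "y")]
    }
    dplyr::bind_cols(
      tibble::tibble(condition = cond, location = locs$location,
                     source = "model", observer_id = NA_integer_,
                     repeat_id = NA_integer_),
      preds)
  })
  rows
}

#' Cluster matches in chromaticity space
#'
#' Single-linkage agglomeration on pairwise CIE xy distances between the
#' per-location (mean) matches of one condition, cut at `cutoff`. Cluster
#' ids are renumbered by their lowest location index.
#'
#' @param records MatchRecord tibble for a single condition (records from
#'   several observers/repeats are averaged per location first).
#' @param cutoff Merge distance in xy units.
#' @return An object of class `match_clusters`: `assignments` (tibble of
#'   `location`, `x`, `y`, `cluster`), `k`, `sizes`, `within_dispersion`,
#'   `between_dispersion`, `cutoff`.
#' @export
cluster_matches <- function(records, cutoff = 0.02) {
  stopifnot(nrow(records) >= 2)
  if (length(unique(records$condition)) > 1) {
    rlang::abort("cluster_matches expects records from a single condition",
                 class = "contourfill_spec_error")
  }
  pts <- dplyr::summarise(dplyr::group_by(records, .data$location),
                          x = mean(.data$x), y = mean(.data$y),
                          .groups = "drop")
  pts <- pts[order(pts$location), ]
  dd <- stats::dist(cbind(pts$x, pts$y))
  if (max(dd) <= cutoff || nrow(pts) == 1) {
    cl <- rep(1L, nrow(pts))
  } else {
    hc <- stats::hclust(dd, method = "single")
    cl <- stats::cutree(hc, h = cutoff)
  }
  # renumber clusters by lowest member location
  first_loc <- tapply(pts$location, cl, min)
  remap <- integer(length(first_loc))
  remap[order(first_loc)] <- seq_along(first_loc)
  cl <- remap[cl]
  pts$cluster <- cl
  dmat <- as.matrix(dd)
  same <- outer(cl, cl, "==") & upper.tri(dmat)
  diffm <- outer(cl, cl, "!=") & upper.tri(dmat)
  structure(
    list(assignments = pts, k = max(cl),
         sizes = as.integer(table(cl)),
         within_dispersion = if (any(same)) mean(dmat[same]) else 0,
         between_dispersion = if (any(diffm)) mean(dmat[diffm]) else NA_real_,
         cutoff = cutoff),
    class = "match_clusters")
}

#' @export
print.match_clusters <- function(x, ...) {
  cat(sprintf(
    "<match_clusters> k = %d (sizes %s), within %.4f, between %s, cutoff %g\n",
    x$k, paste(x$sizes, collapse = ","), x$within_dispersion,
    ifelse(is.na(x$between_dispersion), "NA",
           sprintf("%.4f", x$between_dispersion)), x$cutoff))
  invisible(x)
}

#' Within-cluster vs no-contour dispersion, per contour setting
#'
#' For each contour setting, the six locations are clustered and the mean
#' pairwise xy distance within clusters is compared with the mean pairwise
#' xy distance of the same location groups in the no-contour records: if
#' contours make the percepts within each bounded surface collapse
#' together, the former is smaller.
#'
#' @param records MatchRecord tibble containing a `"none"` condition and at
#'   least one contour setting.
#' @param cutoff Clustering cutoff passed to [cluster_matches()].
#' @return A tibble with `condition`, `k`, `within_dispersion`,
#'   `nocontour_dispersion`, `contour_tightens`.
#' @export
dispersion_report <- function(records, cutoff = 0.02) {
  stopifnot("none" %in% records$condition)
  none_pts <- dplyr::summarise(
    dplyr::group_by(records[records$condition == "none", ], .data$location),
    x = mean(.data$x), y = mean(.data$y), .groups = "drop")
  settings <- setdiff(unique(records$condition), "none")
  purrr::map_dfr(settings, function(s) {
    cl <- cluster_matches(records[records$condition == s, ], cutoff)
    per_cluster <- function(pts) {
      vals <- vapply(unique(cl$assignments$cluster), function(g) {
        locs <- cl$assignments$location[cl$assignments$cluster == g]
        if (length(locs) < 2) return(NA_real_)
        sub <- pts[match(locs, pts$location), ]
        mean(stats::dist(cbind(sub$x, sub$y)))
      }, numeric(1))
      mean(vals, na.rm = TRUE)
    }
    within <- per_cluster(cl$assignments)
    nocontour <- per_cluster(none_pts)
    tibble::tibble(condition = s, k = cl$k,
                   within_dispersion = within,
                   nocontour_dispersion = nocontour,
                   contour_tightens = within < nocontour)
  })
}
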