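# Synthetic observers: noisy matches around model-predicted percepts with
# the matching experiment's 5-observer x 3-repeat design, for end-to-end
# testing and parameter recovery without human data.

#' Synthetic observer noise model
#'
#' Matches are the model prediction plus a per-observer chromaticity bias
#' (drawn once per observer) and independent Gaussian noise per trial:
#' isotropic in CIE xy with SD `sigma_xy` per axis, and in luminance with
#' SD `sigma_Y`.
#'
#' @param sigma_xy Chromaticity noise SD per axis (xy units).
#' @param sigma_Y Luminance noise SD, cd/m^2.
#' @param bias_sd SD of the per-observer chromaticity bias; 0 disables it.
#' @param seed RNG seed for reproducible tables (`NULL` leaves the RNG
#'   state alone).
#' @return A list of class `observer_model`.
#' @export
observer_model <- function(sigma_xy = 0.005, sigma_Y = 2, bias_sd = 0.002,
                           seed = NULL) {
  stopifnot(sigma_xy >= 0, sigma_Y >= 0, bias_sd >= 0)
  structure(list(sigma_xy = sigma_xy, sigma_Y = sigma_Y, bias_sd = bias_sd,
                 seed = seed),
            class = "observer_model")
}

#' Simulate observer matches around model predictions
#'
#' One record per truth row x observer x repeat. Noisy chromaticities are
#' clipped to the valid domain (`x, y >= 0.001`, `x + y <= 0.999`) and
#' luminance to at least 0.1 cd/m^2; the number of clipped draws is stored
#' in the `n_clipped` attribute.
#'
#' @param truth MatchRecord tibble from [run_exp2()] (the model's
#'   predictions).
#' @param model An [observer_model()].
#' @param n_observers,n_repeats Design size (defaults: 5 observers, 3
#'   repeats, the matching experiment's design).
#' @return A MatchRecord tibble with `source = "synthetic_observer"`.
#' @export
simulate_matches <- function(truth, model = observer_model(),
                             n_observers = 5, n_repeats = 3) {
  stopifnot(inherits(model, "observer_model"),
            n_observers >= 1, n_repeats >= 1)
  if (!is.null(model$seed)) set.seed(model$seed)
  bias <- matrix(stats::rnorm(2 * n_observers, 0, model$bias_sd),
                 n_observers, 2)
  design <- tidyr::expand_grid(truth_row = seq_len(nrow(truth)),
                               observer_id = seq_len(n_observers),
                               repeat_id = seq_len(n_repeats))
  n <- nrow(design)
  tr <- truth[design$truth_row, ]
  x <- tr$x + bias[design$observer_id, 1] +
    stats::rnorm(n, 0, model$sigma_xy)
  y <- tr$y + bias[design$observer_id, 2] +
    stats::rnorm(n, 0, model$sigma_xy)
  Yl <- tr$Y + stats::rnorm(n, 0, model$sigma_Y)
  xc <- pmin(pmax(x, 0.001), 0.998)
  yc <- pmin(pmax(y, 0.001), 0.998)
  s <- xc + yc
  shrink <- s > 0.999
  xc[shrink] <- xc[shrink] * 0.999 / s[shrink]
  yc[shrink] <- yc[shrink] * 0.999 / s[shrink]
  Yc <- pmax(Yl, 0.1)
  n_clipped <- sum(xc != x | yc != y | Yc != Yl)
  xyz <- xyY_to_XYZ(xc, yc, Yc)
  out <- tibble::tibble(
    condition = tr$condition, location = tr$location,
    source = "synthetic_observer",
    observer_id = design$observer_id, repeat_id = design$repeat_id,
    X = xyz$X, Y = xyz$Y, Z = xyz$Z, x = xc, y = yc)
  attr(out, "n_clipped") <- n_clipped
  attr(out, "model") <- model
  out
}

#' Recover per-location colors from simulated matches
#'
#' Per condition/location mean chromaticity with standard errors; when the
#' truth table is supplied, the recovery error (xy distance from truth) is
#' attached.
#'
#' @param simulated MatchRecord tibble from [simulate_matches()].
#' @param truth Optional model-prediction table the simulation was built
#'   from.
#' @return A tibble with `condition`, `location`, `n`, `x_hat`, `y_hat`,
#'   `Y_hat`, `se_x`, `se_y`, and (given truth) `x_true`, `y_true`,
#'   `err_xy`.
#' @export
recover_region_colors <- function(simulated, truth = NULL) {
  counts <- table(paste(simulated$condition, simulated$location))
  if (any(counts < 2)) {
    rlang::abort("need at least 2 records per condition/location",
                 class = "contourfill_estimation_error")
  }
  est <- dplyr::summarise(
    dplyr::group_by(simulated, .data$condition, .data$location),
    n = dplyr::n(),
    x_hat = mean(.data$x), y_hat = mean(.data$y), Y_hat = mean(.data$Y),
    se_x = stats::sd(.data$x) / sqrt(dplyr::n()),
    se_y = stats::sd(.data$y) / sqrt(dplyr::n()),
    .groups = "drop")
  if (!is.null(truth)) {
    tr <- truth[, c("condition", "location", "x", "y")]
    names(tr)[3:4] <- c("x_true", "y_true")
    est <- dplyr::left_join(est, tr, by = c("condition", "location"))
    est$err_xy <- xy_distance(est$x_hat, est$y_hat, est$x_true, est$y_true)
  }
  est
}

#' Write a match-record table to CSV
#'
#' The seed and noise parameters (when the table carries an observer model)
#' are recorded in `#`-prefixed header lines.
#'
#' @param records A MatchRecord tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matches_csv <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  model <- attr(records, "model")
  if (!is.null(model)) {
    writeLines(sprintf(
      "# observer_model: sigma_xy=%g sigma_Y=%g bias_sd=%g seed=%s",
      model$sigma_xy, model$sigma_Y, model$bias_sd,
      ifelse(is.null(model$seed), "NULL", model$seed)), con)
  }
  utils::write.csv(as.data.frame(records), con, row.names = FALSE)
  invisible(path)
}
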