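# Ordinary kriging of axial angles and the permutation randomness map.
#
# Axial angles cannot be kriged directly (0 and 180 are the same
# orientation), so angles are doubled, mapped to unit-vector components,
# the components are kriged with shared weights (weights depend only on
# geometry and the variogram model), and the prediction is back-
# transformed to [0, 180).

# collapse co-located samples (exactly duplicated coordinates) to their
# axial mean so the kriging system is non-singular
dedupe_field <- function(field) {
  key <- paste(field$x_um, field$y_um)
  if (!anyDuplicated(key)) return(field)
  message("kriging: averaged co-located samples")
  field |>
    group_by(.data$x_um, .data$y_um) |>
    summarise(angle_deg = axial_mean(.data$angle_deg), .groups = "drop")
}

# ordinary kriging weight matrix for a set of targets.
# returns (n+1) x m matrix: n weights per target plus the Lagrange row.
# a model with (numerically) zero total sill carries no spatial
# information: prediction falls back to the equal-weight mean.
kriging_weights <- function(xs, ys, fit, tx, ty) {
  n <- length(xs)
  if (fit$nugget + sum(fit$sills) < 1e-12) {
    return(rbind(matrix(1 / n, n, length(tx)), rep(0, length(tx))))
  }
  D <- sqrt(outer(xs, xs, "-")^2 + outer(ys, ys, "-")^2)
  A <- rbind(cbind(predict_variogram(fit, D), rep(1, n)),
             c(rep(1, n), 0))
  Dt <- sqrt(outer(xs, tx, "-")^2 + outer(ys, ty, "-")^2)
  Bm <- rbind(predict_variogram(fit, Dt), rep(1, length(tx)))
  solve(A, Bm)
}

#' Ordinary kriging of axial angles
#'
#' Predicts axial angles at target locations by ordinary kriging with the
#' supplied variogram model. Weights sum to 1 at every target (the
#' unbiasedness constraint, asserted on every solve); with a zero nugget
#' the predictor interpolates the samples exactly. Co-located samples are
#' averaged before solving.
#'
#' @param field a data frame with `x_um`, `y_um`, `angle_deg`.
#' @param fit a `dd_variogram_fit` (see [fit_variogram_model()]).
#' @param targets a data frame with `x_um`, `y_um`.
#' @param return_weights if `TRUE`, attach the n x m weight matrix as the
#'   `"weights"` attribute.
#' @return A tibble `x_um, y_um, angle_deg` of predictions.
#' @export
krige_angles <- function(field, fit, targets, return_weights = FALSE) {
  check_angle_field(field)
  field <- dedupe_field(field)
  W <- kriging_weights(field$x_um, field$y_um, fit,
                       targets$x_um, targets$y_um)
  n <- nrow(field)
  wsum <- colSums(W[seq_len(n), , drop = FALSE])
  if (any(abs(wsum - 1) > 1e-8)) {
    stop_dd("kriging weights failed the unbiasedness constraint",
            class = "dermadisp_numeric_error")
  }
  phi <- 2 * field$angle_deg * pi / 180
  Z <- cbind(cos(phi), sin(phi))
  P <- crossprod(W[seq_len(n), , drop = FALSE], Z)
  pred <- axial_mod(atan2(P[, 2], P[, 1]) * 180 / pi / 2)
  out <- tibble(x_um = targets$x_um, y_um = targets$y_um, angle_deg = pred)
  if (return_weights) attr(out, "weights") <- W[seq_len(n), , drop = FALSE]
  out
}

#' Local randomness map of an orientation field
#'
#' Compares the kriged experimental orientation field against the fields
#' obtained by permuting the orientations across the fixed sample
#' locations (the variogram model is kept unchanged). Kriging is carried
#' out on doubled-angle unit-vector components; for each pixel of a
#' `grid_n` x `grid_n` prediction grid, the experimental kriged component
#' pair is compared with the permutation distribution of kriged component
#' pairs: a pixel is "random" when the experimental pair lies inside the
#' permutation cloud's (1 - alpha) radius around its centre. (Comparing
#' components rather than back-transformed angles keeps power where a
#' permuted mixture of orientations averages to a near-zero resultant,
#' whose angle is uninformative.) The randomness ratio is the fraction of
#' random pixels; 1 minus it is the spatially correlated area fraction.
#' The test is conditional on the pooled set of orientations, so it flags
#' local coherence that differs from the field-wide mixture; a perfectly
#' homogeneous field is exchangeable and correctly reads as random.
#'
#' @param field a data frame with `x_um`, `y_um`, `angle_deg`.
#' @param fit a `dd_variogram_fit`; by default fitted here from the
#'   classic (pairwise) angular variogram of `field` with one structure.
#' @param n_perm permutations (default 100; at least 50 so the interval is
#'   resolvable at alpha = 0.01).
#' @param grid_n grid resolution per side (default 100).
#' @param alpha significance level (default 0.01).
#' @param seed integer seed for the permutations.
#' @param extent optional `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   sample bounding box.
#' @return A `dd_randomness_map`: list with `grid` (tibble `x_um, y_um,
#'   angle_deg, random`), `randomness_ratio`, `correlated_fraction`,
#'   `alpha`, `n_perm`. Has `glance()` and `autoplot()` methods.
#' @export
local_randomness_map <- function(field, fit = NULL, n_perm = 100,
                                 grid_n = 100, alpha = 0.01, seed = 1,
                                 extent = NULL) {
  if (n_perm < 50) {
    stop_dd("n_perm must be at least 50 for a resolvable interval",
            class = "dermadisp_validation_error")
  }
  check_angle_field(field)
  field <- dedupe_field(field)
  if (is.null(fit)) {
    vg <- suppressMessages(angular_variogram(field, centre = NULL))
    fit <- fit_variogram_model(vg, n_structures = 1, weights = "cressie")
  }
  extent <- extent %||% c(range(field$x_um), range(field$y_um))
  gx <- seq(extent[1], extent[2], length.out = grid_n)
  gy <- seq(extent[3], extent[4], length.out = grid_n)
  targets <- expand.grid(x_um = gx, y_um = gy)

  n <- nrow(field)
  W <- kriging_weights(field$x_um, field$y_um, fit,
                       targets$x_um, targets$y_um)[seq_len(n), , drop = FALSE]
  wsum <- colSums(W)
  if (any(abs(wsum - 1) > 1e-8)) {
    stop_dd("kriging weights failed the unbiasedness constraint",
            class = "dermadisp_numeric_error")
  }

  phi <- 2 * field$angle_deg * pi / 180
  obs_c <- as.numeric(crossprod(W, cos(phi)))
  obs_s <- as.numeric(crossprod(W, sin(phi)))
  obs_angle <- axial_mod(atan2(obs_s, obs_c) * 180 / pi / 2)

  set.seed(seed)
  m <- nrow(targets)
  perm_c <- matrix(NA_real_, n_perm, m)
  perm_s <- matrix(NA_real_, n_perm, m)
  for (r in seq_len(n_perm)) {
    p <- sample.int(n)
    perm_c[r, ] <- as.numeric(crossprod(W, cos(phi)[p]))
    perm_s[r, ] <- as.numeric(crossprod(W, sin(phi)[p]))
  }
  centre_c <- colMeans(perm_c)
  centre_s <- colMeans(perm_s)
  dev_perm <- sqrt(sweep(perm_c, 2, centre_c)^2 +
                     sweep(perm_s, 2, centre_s)^2)
  dev_obs <- sqrt((obs_c - centre_c)^2 + (obs_s - centre_s)^2)
  qcrit <- apply(dev_perm, 2, quantile, probs = 1 - alpha, names = FALSE)
  random_px <- dev_obs <= qcrit

  grid <- tibble(x_um = targets$x_um, y_um = targets$y_um,
                 angle_deg = obs_angle, random = random_px)
  structure(
    list(grid = grid,
         randomness_ratio = mean(random_px),
         correlated_fraction = 1 - mean(random_px),
         alpha = alpha, n_perm = n_perm, grid_n = grid_n,
         extent = extent, fit = fit),
    class = "dd_randomness_map"
  )
}

#' @export
print.dd_randomness_map <- function(x, ...) {
  cat(sprintf(
    "Randomness map: %d x %d grid, %d permutations, alpha = %g\n",
    x$grid_n, x$grid_n, x$n_perm, x$alpha))
  cat(sprintf("  randomness ratio: %.3f (correlated area: %.3f)\n",
              x$randomness_ratio, x$correlated_fraction))
  invisible(x)
}

#' @rdname dermadisp-generics
#' @export
glance.dd_randomness_map <- function(x, ...) {
  tibble(randomness_ratio = x$randomness_ratio,
         correlated_fraction = x$correlated_fraction,
         alpha = x$alpha, n_perm = x$n_perm, grid_n = x$grid_n)
}
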