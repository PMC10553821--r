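# Seeded synthetic-data generators with known ground truth: tracking
# tables with the dividing/non-dividing structure of the explant movies,
# spatially structured mitosis-angle fields, and stained fibre images.
# Every generator is deterministic given its seed and returns the ground
# truth alongside the data for recovery tests.

#' Generate a synthetic tracking table
#'
#' Non-dividing cells perform a planar Gaussian walk whose step scale is
#' set so the mean step speed equals `interphase_speed` (Rayleigh mean
#' relation). Each dividing lineage has a diffusive mother up to a random
#' division time, a diametric separation of `jump_length_um` at an axial
#' angle drawn uniformly, an optional pause, a fast persistent phase of
#' `fast_duration_min` at `fast_multiplier` times the interphase mean
#' speed (wrapped-normal turning about the previous heading, first heading
#' along the separation direction), and then reverts to the diffusive
#' walk. Defaults mirror the measured study conditions: 10-min frames,
#' 25 h duration, 0.02 μm/min interphase speed, 180-min fast phase at
#' three times the interphase speed.
#'
#' @param n_nondividing number of non-dividing tracks.
#' @param n_lineages number of dividing lineages (one mother, two
#'   daughters each).
#' @param frame_dt frame interval (minutes).
#' @param duration_min total tracking duration (minutes); must exceed
#'   `fast_duration_min`.
#' @param interphase_speed target mean step speed (μm/min).
#' @param fast_multiplier daughter fast-phase speed ratio (>= 1).
#' @param fast_duration_min fast-phase duration (minutes).
#' @param pause_frames zero-displacement frames after the mitotic jump.
#' @param phi_sd_deg wrapped-normal s.d. of fast-phase turning (degrees).
#' @param jump_length_um diametric separation at cytokinesis (μm).
#' @param field_um field extent `c(width, height)` (μm).
#' @param condensates optional condensate tibble, recorded in the truth.
#' @param seed integer seed.
#' @return A list: `tracks` (validated track tibble), `condensates`,
#'   `truth` (list of the generating parameters, including the implied
#'   diffusion coefficient and MSD slope).
#' @export
gen_trackset <- function(n_nondividing = 50, n_lineages = 45,
                         frame_dt = 10, duration_min = 1500,
                         interphase_speed = 0.02, fast_multiplier = 3,
                         fast_duration_min = 180, pause_frames = 0,
                         phi_sd_deg = 40, jump_length_um = 8,
                         field_um = c(400, 400), condensates = NULL,
                         seed = 1) {
  if (duration_min <= fast_duration_min) {
    stop_dd("duration_min must exceed fast_duration_min",
            class = "dermadisp_config_error")
  }
  if (fast_multiplier < 1) {
    stop_dd("fast_multiplier must be >= 1", class = "dermadisp_config_error")
  }
  set.seed(seed)
  sigma <- interphase_speed * frame_dt / sqrt(pi / 2)
  fast_scale <- fast_multiplier * interphase_speed * frame_dt / sqrt(pi / 2)
  n_frames <- floor(duration_min / frame_dt) + 1L
  tgrid <- (seq_len(n_frames) - 1L) * frame_dt
  fast_steps <- round(fast_duration_min / frame_dt)

  margin <- min(field_um) * 0.1
  rand_start <- function() c(runif(1, margin, field_um[1] - margin),
                             runif(1, margin, field_um[2] - margin))

  rows <- vector("list", n_nondividing + 3L * n_lineages)
  k <- 0L

  walk_xy <- function(x0, y0, n_pts) {
    dx <- c(0, rnorm(n_pts - 1, 0, sigma))
    dy <- c(0, rnorm(n_pts - 1, 0, sigma))
    cbind(x0 + cumsum(dx), y0 + cumsum(dy))
  }

  for (i in seq_len(n_nondividing)) {
    p0 <- rand_start()
    xy <- walk_xy(p0[1], p0[2], n_frames)
    k <- k + 1L
    rows[[k]] <- tibble(track_id = sprintf("nd%03d", i),
                        lineage_id = sprintf("nd%03d", i),
                        role = "non_dividing", t_min = tgrid,
                        x_um = xy[, 1], y_um = xy[, 2])
  }

  # division times leave room for a 180-min mother window and two
  # daughter windows
  lead_min <- fast_duration_min
  tail_min <- 2 * fast_duration_min
  div_frames <- sample(
    seq(ceiling(lead_min / frame_dt), floor((duration_min - tail_min) /
                                              frame_dt)),
    n_lineages, replace = TRUE)

  fast_walk <- function(x0, y0, heading0, n_fast, n_after) {
    xs <- x0; ys <- y0
    h <- heading0
    x <- x0; y <- y0
    if (pause_frames > 0) {
      xs <- c(xs, rep(x0, pause_frames)); ys <- c(ys, rep(y0, pause_frames))
    }
    for (s in seq_len(n_fast)) {
      len <- fast_scale * sqrt(-2 * log(runif(1)))
      x <- x + len * cos(h * pi / 180)
      y <- y + len * sin(h * pi / 180)
      xs <- c(xs, x); ys <- c(ys, y)
      h <- h + rnorm(1, 0, phi_sd_deg)
    }
    if (n_after > 0) {
      dx <- rnorm(n_after, 0, sigma); dy <- rnorm(n_after, 0, sigma)
      xs <- c(xs, x + cumsum(dx)); ys <- c(ys, y + cumsum(dy))
    }
    cbind(xs, ys)
  }

  for (i in seq_len(n_lineages)) {
    lin <- sprintf("lin%03d", i)
    f_div <- div_frames[i]
    t_div <- tgrid[f_div + 1L]
    p0 <- rand_start()
    mo <- walk_xy(p0[1], p0[2], f_div + 1L)
    k <- k + 1L
    rows[[k]] <- tibble(track_id = paste0(lin, "_mo"), lineage_id = lin,
                        role = "mother", t_min = tgrid[seq_len(f_div + 1L)],
                        x_um = mo[, 1], y_um = mo[, 2])
    theta <- runif(1, 0, 180)
    half <- jump_length_um / 2
    n_after_frames <- n_frames - (f_div + 1L)
    for (d in 1:2) {
      h0 <- if (d == 1) theta else theta + 180
      x0 <- mo[f_div + 1L, 1] + half * cos(h0 * pi / 180)
      y0 <- mo[f_div + 1L, 2] + half * sin(h0 * pi / 180)
      n_fast <- min(fast_steps, max(n_after_frames - pause_frames, 0))
      n_after <- max(n_after_frames - pause_frames - n_fast, 0)
      xy <- fast_walk(x0, y0, h0, n_fast, n_after)
      tt <- tgrid[(f_div + 1L):n_frames]
      k <- k + 1L
      rows[[k]] <- tibble(track_id = paste0(lin, "_d", d), lineage_id = lin,
                          role = "daughter", t_min = tt[seq_len(nrow(xy))],
                          x_um = xy[, 1], y_um = xy[, 2])
    }
  }

  tracks <- as_tracks(list_rbind(rows[seq_len(k)]), frame_dt = frame_dt)
  truth <- list(
    interphase_speed = interphase_speed,
    sigma_um = sigma, D_um2_min = sigma^2 / (2 * frame_dt),
    msd_slope_um2_min = 2 * sigma^2 / frame_dt,
    fast_multiplier = fast_multiplier,
    fast_duration_min = fast_duration_min,
    fast_speed = fast_multiplier * interphase_speed,
    jump_length_um = jump_length_um, phi_sd_deg = phi_sd_deg,
    frame_dt = frame_dt, duration_min = duration_min,
    pause_frames = pause_frames, seed = seed
  )
  list(tracks = tracks, condensates = condensates, truth = truth)
}

#' Generate a synthetic mitosis-angle field
#'
#' Sample positions are uniform on the extent. Near a condensate centre,
#' angles are tangential (perpendicular to the radius) plus Gaussian noise
#' whose variance follows the nested exponential profile
#' `nugget + sum_k sills[k] (1 - exp(-r / ranges_a[k]))`, so the ground
#' truth of a variogram fit is explicit. Alternatively, a globally aligned
#' field (`global_axis` ± noise) or a patchwork of aligned zones on a
#' uniform background can be generated for randomness-map tests.
#'
#' @param n_samples number of mitoses.
#' @param extent `c(xmin, xmax, ymin, ymax)` (μm).
#' @param centre optional condensate centre `c(x, y)`.
#' @param sills partial sills of the variance profile (deg²).
#' @param ranges_a range parameters a_k (μm); effective ranges are 3 a_k.
#' @param nugget nugget variance (deg²).
#' @param global_axis,global_sd_deg globally aligned field: axial mean and
#'   wrapped-normal s.d. (used when `centre` is `NULL`).
#' @param patches optional list of lists `(xmin, xmax, ymin, ymax, axis,
#'   sd_deg)`; samples outside all patches get uniform axial angles.
#' @param seed integer seed.
#' @return A list: `field` (tibble `x_um, y_um, angle_deg`), `truth`.
#' @export
gen_mitosis_field <- function(n_samples = 600,
                              extent = c(0, 400, 0, 400),
                              centre = NULL,
                              sills = c(500, 214), ranges_a = c(20, 59),
                              nugget = 0,
                              global_axis = NULL, global_sd_deg = 10,
                              patches = NULL, seed = 1) {
  if (n_samples < 1) {
    stop_dd("n_samples must be positive", class = "dermadisp_config_error")
  }
  set.seed(seed)
  x <- runif(n_samples, extent[1], extent[2])
  y <- runif(n_samples, extent[3], extent[4])

  if (!is.null(centre)) {
    r <- sqrt((x - centre[1])^2 + (y - centre[2])^2)
    v <- exp_vg_value(r, nugget, sills, ranges_a)
    tangent <- axial_mod(atan2(centre[2] - y, centre[1] - x) * 180 / pi + 90)
    angle <- axial_mod(tangent + rnorm(n_samples, 0, sqrt(v)))
  } else if (!is.null(patches)) {
    angle <- runif(n_samples, 0, 180)
    for (p in patches) {
      inside <- x >= p$xmin & x <= p$xmax & y >= p$ymin & y <= p$ymax
      angle[inside] <- axial_mod(p$axis +
                                   rnorm(sum(inside), 0, p$sd_deg))
    }
  } else if (!is.null(global_axis)) {
    angle <- axial_mod(global_axis + rnorm(n_samples, 0, global_sd_deg))
  } else {
    angle <- runif(n_samples, 0, 180)
  }

  list(field = tibble(x_um = x, y_um = y, angle_deg = angle),
       truth = list(centre = centre, sills = sills, ranges_a = ranges_a,
                    effective_ranges = 3 * ranges_a, nugget = nugget,
                    variance_fraction = sills / sum(sills),
                    global_axis = global_axis, global_sd_deg = global_sd_deg,
                    patches = patches, extent = extent, seed = seed))
}

#' Generate a synthetic stained-fibre image
#'
#' Renders anti-aliased fibre segments whose axial orientations are drawn
#' about `orientation_deg` with wrapped-normal s.d. `orientation_sd_deg`
#' (0 = parallel fibres; `Inf` = isotropic), coloured magenta so the
#' signal lands in the a* channel and the negative b* region, over a dark
#' background with additive pixel noise.
#'
#' @param orientation_deg target axial orientation (degrees).
#' @param orientation_sd_deg orientation spread (0 = parallel, `Inf` =
#'   isotropic).
#' @param size image side in pixels (>= 64).
#' @param n_fibres number of fibre segments (0 gives a noise-only image).
#' @param noise additive uniform noise amplitude in \[0, 1\].
#' @param seed integer seed.
#' @return An `size x size x 3` sRGB array in \[0, 1\].
#' @export
gen_fibre_image <- function(orientation_deg = 30, orientation_sd_deg = 0,
                            size = 192, n_fibres = 140, noise = 0.05,
                            seed = 1) {
  if (size < 64) {
    stop_dd("size must be at least 64", class = "dermadisp_config_error")
  }
  set.seed(seed)
  canvas <- matrix(0, size, size)
  # ideal isotropy: stratified orientations with jitter (an i.i.d. draw of
  # a few hundred fibres carries sampling anisotropy of order 1/sqrt(n))
  iso_angles <- if (n_fibres > 0) {
    sample(seq(0, 180, length.out = n_fibres + 1)[-1] +
             runif(n_fibres, -90, 90) / n_fibres)
  }
  for (i in seq_len(n_fibres)) {
    ang <- if (is.infinite(orientation_sd_deg)) {
      iso_angles[i]
    } else {
      axial_mod(orientation_deg + rnorm(1, 0, orientation_sd_deg))
    }
    len <- runif(1, size / 4, size / 3)
    # keep the whole segment inside the canvas so every fibre deposits its
    # full energy (border-cropped fibres would skew the orientation power)
    cx <- runif(1, 1 + len / 2, size - 1 - len / 2)
    cy <- runif(1, 1 + len / 2, size - 1 - len / 2)
    # dense points along the segment, splatted bilinearly (y = rows)
    tpar <- seq(-len / 2, len / 2, by = 0.35)
    px <- cx + tpar * cos(ang * pi / 180)
    py <- cy + tpar * sin(ang * pi / 180)
    keep <- px >= 1 & px <= size - 1 & py >= 1 & py <= size - 1
    px <- px[keep]; py <- py[keep]
    if (length(px) == 0) next
    r0 <- floor(py); c0 <- floor(px)
    fr <- py - r0; fc <- px - c0
    amp <- runif(1, 0.85, 1)
    for (dd in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
      wgt <- (if (dd[1] == 0) 1 - fr else fr) *
        (if (dd[2] == 0) 1 - fc else fc)
      idx <- cbind(r0 + dd[1], c0 + dd[2])
      canvas[idx] <- canvas[idx] + amp * wgt
    }
  }
  # normalise additively accumulated strokes without hard clipping
  if (any(canvas > 0)) {
    canvas <- canvas / max(quantile(canvas[canvas > 0], 0.98), 1)
  }
  canvas <- pmin(canvas, 1)
  img <- array(0, dim = c(size, size, 3))
  # magenta fibres (strong a*, negative b*) over a dark background
  img[, , 1] <- 0.05 + 0.85 * canvas
  img[, , 2] <- 0.05
  img[, , 3] <- 0.05 + 0.75 * canvas
  img <- img + array(runif(size * size * 3, 0, noise),
                     dim = c(size, size, 3))
  pmin(pmax(img, 0), 1)
}
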