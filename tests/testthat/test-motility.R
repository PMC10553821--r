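test_that("instantaneous speeds follow the step/interval definition", {
  still <- make_tracks(list(id = "s", role = "non_dividing",
                            t = seq(0, 40, 10), x = rep(1, 5),
                            y = rep(2, 5)))
  expect_true(all(track_speeds(still)$speed_um_min == 0))

  straight <- make_tracks(list(id = "r", role = "non_dividing",
                               t = seq(0, 40, 10), x = seq(0, 4), y = rep(0, 5)))
  expect_equal(track_speeds(straight)$speed_um_min, rep(0.1, 4))

  single <- make_tracks(list(id = "p", role = "non_dividing", t = 0,
                             x = 0, y = 0))
  expect_warning(out <- track_speeds(single),
                 class = "dermadisp_single_point")
  expect_equal(nrow(out), 0)
})

test_that("displacement metrics: straight, out-and-back, Pythagorean", {
  tr <- make_tracks(
    list(id = "straight", role = "non_dividing", t = c(0, 10, 20),
         x = c(0, 1, 2), y = c(0, 0, 0)),
    list(id = "back", role = "non_dividing", t = c(0, 10, 20),
         x = c(0, 1, 0), y = c(0, 0, 0)),
    list(id = "pyth", role = "non_dividing", t = c(0, 10, 20),
         x = c(0, 3, 3), y = c(0, 0, 4))
  )
  dm <- displacement_metrics(tr)
  dm <- dm[match(c("straight", "back", "pyth"), dm$track_id), ]
  expect_equal(dm$persistence[1], 1)
  expect_equal(dm$euclidean_um[2], 0)
  expect_equal(dm$persistence[2], 0)
  expect_equal(dm$euclidean_um[3], 5)
  expect_equal(dm$accumulated_um[3], 7)
  expect_equal(dm$persistence[3], 5 / 7)
})

test_that("phase windows follow the 180-min construction", {
  tr <- make_tracks(
    list(id = "m", lineage = "L", role = "mother", t = seq(120, 300, 10),
         x = seq_len(19), y = rep(0, 19)),
    list(id = "d1", lineage = "L", role = "daughter", t = seq(300, 660, 10),
         x = seq_len(37), y = rep(0, 37)),
    list(id = "nd", role = "non_dividing", t = seq(0, 100, 10),
         x = seq_len(11), y = rep(0, 11))
  )
  w <- assign_phase_windows(tr)
  mo <- w[w$window == "mother_pre180", ]
  expect_equal(c(mo$t_start, mo$t_end), c(120, 300))
  d1 <- w[w$window == "daughter_0_180", ]
  expect_equal(c(d1$t_start, d1$t_end), c(300, 480))
  d2 <- w[w$window == "daughter_180_360", ]
  expect_equal(c(d2$t_start, d2$t_end), c(480, 660))
  nd <- w[w$window == "non_dividing", ]
  expect_equal(c(nd$t_start, nd$t_end), c(0, 100))
})

test_that("division at the first tracked frame warns of an empty mother window", {
  tr <- make_tracks(
    list(id = "m", lineage = "L", role = "mother", t = 0, x = 0, y = 0),
    list(id = "d1", lineage = "L", role = "daughter", t = c(0, 10),
         x = c(1, 2), y = c(0, 0))
  )
  expect_warning(assign_phase_windows(tr), class = "dermadisp_empty_window")
})

test_that("time-ensemble MSD matches closed forms", {
  still <- make_tracks(list(id = "s", role = "non_dividing",
                            t = seq(0, 90, 10), x = rep(0, 10),
                            y = rep(0, 10)))
  expect_true(all(msd_time_ensemble(still)$msd_um2 == 0))

  # ballistic track at 0.1 um/min: msd(tau) = (0.1 tau)^2 exactly
  bal <- make_tracks(list(id = "b", role = "non_dividing",
                          t = seq(0, 190, 10), x = seq(0, 19), y = rep(0, 20)))
  curve <- msd_time_ensemble(bal, max_lag_min = 90)
  expect_equal(curve$msd_um2, (0.1 * curve$lag_min)^2, tolerance = 1e-12)

  # at the largest lag with a single pair, msd equals that pair's squared
  # displacement exactly
  curve_all <- msd_time_ensemble(bal, max_lag_min = 190)
  top <- curve_all[curve_all$n_pairs == 1, ]
  expect_equal(top$msd_um2, (0.1 * top$lag_min)^2, tolerance = 1e-12)
})

test_that("diffusion fit recovers exact lines and flags degenerate windows", {
  curve <- structure(
    tibble::tibble(lag_min = seq(10, 100, 10),
                   msd_um2 = 0.2 * seq(10, 100, 10), n_pairs = 10L),
    class = c("msd_curve", class(tibble::tibble())))
  fit <- diffusion_coefficient(curve, fit_window = c(10, 100))
  expect_equal(fit$slope, 0.2, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(fit$D, 0.05, tolerance = 1e-12)

  flat <- curve
  flat$msd_um2 <- 0
  expect_equal(diffusion_coefficient(flat, c(10, 100))$slope, 0)

  expect_error(diffusion_coefficient(curve, fit_window = c(10, 10)),
               class = "dermadisp_validation_error")
})

test_that("speed and MSD are invariant to rotation and translation", {
  gen <- gen_trackset(n_nondividing = 10, n_lineages = 0,
                      duration_min = 400, seed = 11)
  tr <- gen$tracks
  th <- 37 * pi / 180
  rot <- dplyr::mutate(tr,
    x_new = cos(th) * x_um - sin(th) * y_um + 55,
    y_new = sin(th) * x_um + cos(th) * y_um - 20)
  rot$x_um <- rot$x_new; rot$y_um <- rot$y_new
  rot <- rot[names(tr)]
  expect_equal(track_speeds(rot)$speed_um_min,
               track_speeds(tr)$speed_um_min, tolerance = 1e-10)
  expect_equal(msd_time_ensemble(rot)$msd_um2,
               msd_time_ensemble(tr)$msd_um2, tolerance = 1e-10)
})

test_that("Brownian tracks recover the configured diffusion scale", {
  # 500 tracks, 100 frames, per-axis step variance 2 D dt with D = 0.05:
  # the fitted MSD slope must be within 10% of 4D = 0.2
  set.seed(401)
  D <- 0.05; dt <- 10; n_frames <- 100
  sigma <- sqrt(2 * D * dt)
  rows <- lapply(seq_len(500), function(i) {
    tibble::tibble(track_id = paste0("b", i), lineage_id = paste0("b", i),
                   role = "non_dividing",
                   t_min = seq(0, by = dt, length.out = n_frames),
                   x_um = cumsum(c(0, rnorm(n_frames - 1, 0, sigma))),
                   y_um = cumsum(c(0, rnorm(n_frames - 1, 0, sigma))))
  })
  tr <- as_tracks(dplyr::bind_rows(rows), frame_dt = dt)
  fit <- diffusion_coefficient(msd_time_ensemble(tr))
  expect_lt(abs(fit$slope - 4 * D) / (4 * D), 0.10)
})

test_that("fast-phase daughters have a larger MSD slope than non-dividing cells", {
  gen <- gen_trackset(n_nondividing = 60, n_lineages = 60,
                      duration_min = 900, seed = 21)
  msd <- msd_by_phase(gen$tracks, max_lag_min = 120)
  slope_of <- function(wname) {
    sub <- msd[msd$window == wname, c("lag_min", "msd_um2", "n_pairs")]
    class(sub) <- c("msd_curve", class(sub))
    diffusion_coefficient(sub, fit_window = range(sub$lag_min))$slope
  }
  expect_gt(slope_of("daughter_0_180"), slope_of("non_dividing"))
})
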