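test_that("mitosis axis angles are axial and order-free", {
  expect_equal(mitosis_axis_angle(0, 0, 1, 0), 0)
  expect_equal(mitosis_axis_angle(0, 0, 0, 1), 90)
  a1 <- mitosis_axis_angle(2, 3, 5, 9)
  a2 <- mitosis_axis_angle(5, 9, 2, 3)
  expect_equal(a1, a2)
  expect_error(mitosis_axis_angle(1, 1, 1, 1),
               class = "dermadisp_validation_error")
})

test_that("angles relative to the condensate span radial to tangential", {
  # event at (0,0), centre at (10,0): radial line along +x
  expect_equal(angle_relative_to_condensate(0, 0, 0, 10, 0), 0)
  expect_equal(angle_relative_to_condensate(0, 0, 90, 10, 0), 90)
  expect_equal(angle_relative_to_condensate(0, 0, 45, 10, 0), 45)
  expect_error(angle_relative_to_condensate(10, 0, 30, 10, 0),
               class = "dermadisp_validation_error")
})

test_that("variograms vanish on constant fields and match brute force", {
  const <- tibble::tibble(x_um = runif(40, 0, 100), y_um = runif(40, 0, 100),
                          angle_deg = 57)
  vg <- suppressMessages(angular_variogram(const, centre = c(50, 50),
                                           relative = FALSE))
  expect_true(all(vg$gamma_deg2 == 0))
  fit <- fit_variogram_model(vg, 1)
  expect_lt(fit$nugget + sum(fit$sills), 1e-8)

  # four hand-placed samples in one bin: brute-force pairwise oracle
  f4 <- tibble::tibble(x_um = c(10, 10.5, 11, 11.5), y_um = 0,
                       angle_deg = c(0, 30, 60, 90))
  vg4 <- suppressMessages(
    angular_variogram(f4, centre = c(0, 0), n_bins = 1, min_pairs = 1,
                      relative = FALSE))
  expect_equal(vg4$gamma_deg2, semivariance_oracle(c(0, 30, 60, 90)),
               tolerance = 1e-12)
  expect_equal(vg4$n_pairs, 6)
})

test_that("iid uniform axial fields give a flat variogram at the uniform sill", {
  # E[d_ax^2]/2 for independent uniform axial angles: d_ax ~ U(0, 90),
  # so the sill is 90^2/3/2 = 1350 exactly
  set.seed(33)
  f <- tibble::tibble(x_um = runif(4000, 0, 200), y_um = runif(4000, 0, 200),
                      angle_deg = runif(4000, 0, 180))
  vg <- suppressMessages(angular_variogram(f, centre = c(100, 100),
                                           relative = FALSE, n_bins = 10))
  expect_true(all(abs(vg$gamma_deg2 - 1350) / 1350 < 0.10))
})

test_that("nested exponential fits recover noiseless parameters within 5%", {
  h <- seq(5, 300, length.out = 15)
  vg <- tibble::tibble(
    lag_um = h,
    gamma_deg2 = 70 * (1 - exp(-h / 20)) + 30 * (1 - exp(-h / 59)),
    n_pairs = round(seq(20, 400, length.out = 15)))
  fit <- fit_variogram_model(vg, n_structures = 2)
  o <- order(fit$ranges_a)
  expect_lt(abs(fit$ranges_a[o][1] - 20) / 20, 0.05)
  expect_lt(abs(fit$ranges_a[o][2] - 59) / 59, 0.05)
  expect_lt(abs(fit$sills[o][1] - 70) / 70, 0.05)
  expect_lt(abs(fit$sills[o][2] - 30) / 30, 0.05)
  expect_lt(fit$nugget, 1)
  g <- glance(fit)
  expect_equal(g$short_effective_range_um, 60, tolerance = 0.05)
  expect_equal(g$long_effective_range_um, 177, tolerance = 0.05)
  expect_equal(g$short_variance_fraction, 0.7, tolerance = 0.05)
})

test_that("flat variograms fit as pure nugget", {
  vg <- tibble::tibble(lag_um = seq(10, 150, 10), gamma_deg2 = 200,
                       n_pairs = 50)
  fit <- fit_variogram_model(vg, 1)
  expect_true(fit$degenerate)
  expect_equal(fit$nugget_to_sill, 1, tolerance = 1e-6)
})

test_that("ordinary kriging interpolates exactly and matches the 3x3 solve", {
  f <- tibble::tibble(x_um = c(0, 100, 30, 70), y_um = c(0, 0, 80, 40),
                      angle_deg = c(10, 60, 120, 90))
  fit <- fit_variogram_model(
    tibble::tibble(lag_um = seq(10, 150, 15),
                   gamma_deg2 = 400 * (1 - exp(-seq(10, 150, 15) / 30)),
                   n_pairs = 50), 1)
  expect_lt(fit$nugget, 1e-6)
  # zero nugget: prediction at a sample location returns its angle
  pred <- krige_angles(f, fit, f[2, c("x_um", "y_um")])
  expect_equal(pred$angle_deg, 60, tolerance = 1e-6)

  # constant field: constant prediction, weights sum to one
  fc <- dplyr::mutate(f, angle_deg = 42)
  targets <- tibble::tibble(x_um = runif(20, 0, 100), y_um = runif(20, 0, 80))
  pc <- krige_angles(fc, fit, targets, return_weights = TRUE)
  expect_true(all(abs(pc$angle_deg - 42) < 1e-8))
  expect_true(all(abs(colSums(attr(pc, "weights")) - 1) < 1e-8))

  # two-sample weights against the direct linear solve
  f2 <- f[1:2, ]
  t2 <- tibble::tibble(x_um = 20, y_um = 15)
  p2 <- krige_angles(f2, fit, t2, return_weights = TRUE)
  w <- as.numeric(attr(p2, "weights"))
  w_oracle <- kriging_2pt_oracle(0, 0, 100, 0, fit, 20, 15)
  expect_equal(w, w_oracle, tolerance = 1e-10)
})

test_that("co-located samples are averaged before kriging", {
  f <- tibble::tibble(x_um = c(0, 0, 50), y_um = c(0, 0, 50),
                      angle_deg = c(10, 20, 100))
  fit <- fit_variogram_model(
    tibble::tibble(lag_um = seq(10, 100, 10),
                   gamma_deg2 = 300 * (1 - exp(-seq(10, 100, 10) / 25)),
                   n_pairs = 30), 1)
  expect_message(p <- krige_angles(f, fit, tibble::tibble(x_um = 0, y_um = 0)),
                 "co-located")
  expect_equal(p$angle_deg, 15, tolerance = 1e-6)
})

test_that("permutation test rejects strongly structured fields", {
  gen <- gen_mitosis_field(n_samples = 600, extent = c(0, 200, 0, 200),
                           centre = c(100, 100), seed = 11)
  pt <- permutation_range_test(gen$field, c(100, 100), n_perm = 199,
                               seed = 4)
  expect_lt(pt$p_value, 0.005)  # level statistic: no permutation as ordered
  expect_true(is.finite(pt$observed_range_a))
  expect_true(all(pt$perm_levels > pt$observed_level))
})

test_that("permutation test refuses constant fields", {
  f <- tibble::tibble(x_um = runif(30, 0, 100), y_um = runif(30, 0, 100),
                      angle_deg = 45)
  expect_error(permutation_range_test(f, c(50, 50)),
               class = "dermadisp_degenerate_field")
})

test_that("randomness maps separate coherent patches from uniform fields", {
  field <- patch_field(n = 500, sd_deg = 20, seed = 6)
  rmap <- suppressMessages(
    local_randomness_map(field, n_perm = 100, grid_n = 60, seed = 2))
  expect_lt(rmap$randomness_ratio, 0.25)
  expect_equal(rmap$correlated_fraction, 1 - rmap$randomness_ratio)

  unif <- gen_mitosis_field(n_samples = 200, centre = NULL, seed = 8)$field
  rmap_u <- suppressMessages(
    local_randomness_map(unif, n_perm = 100, grid_n = 40, seed = 2))
  expect_gt(rmap_u$randomness_ratio, 0.9)

  expect_error(local_randomness_map(unif, n_perm = 20),
               class = "dermadisp_validation_error")
})
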