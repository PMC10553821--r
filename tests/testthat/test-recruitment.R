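cond1 <- tibble::tibble(id = "c1", cx_um = 100, cy_um = 0, radius_um = 10)

test_that("first entries are detected with absorbing censoring", {
  tr <- make_tracks(
    # passes through the disc at t = 20, stays in afterwards
    list(id = "hit", role = "non_dividing", t = seq(0, 40, 10),
         x = c(0, 50, 95, 100, 120), y = rep(0, 5)),
    # never within the radius
    list(id = "miss", role = "non_dividing", t = seq(0, 20, 10),
         x = c(0, 10, 20), y = rep(50, 3)),
    # starts inside the disc
    list(id = "inside", role = "non_dividing", t = c(0, 10),
         x = c(100, 130), y = c(0, 0))
  )
  ev <- detect_entries(tr, cond1)
  expect_setequal(ev$track_id, c("hit", "inside"))
  hit <- ev[ev$track_id == "hit", ]
  expect_equal(hit$entry_time_min, 20)
  expect_false(hit$started_inside)
  expect_equal(hit$start_distance_um, 100)
  expect_true(ev$started_inside[ev$track_id == "inside"])

  props <- entry_proportions(ev, tr)
  nd <- props[props$group == "non_dividing", ]
  expect_equal(nd$n_tracked, 2)  # started-inside track excluded
  expect_equal(nd$fraction, 0.5)
})

test_that("dividing start distances are referenced to the division position", {
  tr <- make_tracks(
    list(id = "m", lineage = "L", role = "mother", t = c(0, 10),
         x = c(0, 40), y = c(0, 0)),
    list(id = "d1", lineage = "L", role = "daughter", t = c(10, 20, 30),
         x = c(44, 70, 100), y = c(0, 0, 0)),
    list(id = "d2", lineage = "L", role = "daughter", t = c(10, 20),
         x = c(36, 20), y = c(0, 0))
  )
  ev <- detect_entries(tr, cond1)
  expect_equal(ev$track_id, "d1")
  expect_equal(ev$group, "dividing")
  expect_equal(ev$rel_entry_min, 20)
  # distance measured from the mother's position at division (40, 0)
  expect_equal(ev$start_distance_um, 60)
})

test_that("fisher_exact_2x2 matches printed anchors and handles margins", {
  expect_equal(fisher_exact_2x2(c(5, 5, 5, 5))$p_value, 1)
  # full enumeration: two extreme tables of probability 1/20 each
  expect_equal(fisher_exact_2x2(c(3, 0, 0, 3))$p_value, 0.1,
               tolerance = 1e-12)
  z <- fisher_exact_2x2(c(0, 0, 3, 4))
  expect_equal(z$p_value, 1)
  expect_true(z$degenerate)
  expect_error(fisher_exact_2x2(c(-1, 1, 1, 1)),
               class = "dermadisp_validation_error")
})

test_that("fisher_exact_2x2 equals enumeration and stats::fisher.test", {
  set.seed(7)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 4), 2, 2)
    p <- fisher_exact_2x2(tab)$p_value
    expect_equal(p, fisher_enum_oracle(tab[1, 1], tab[1, 2],
                                       tab[2, 1], tab[2, 2]),
                 tolerance = 1e-10)
    if (sum(tab) > 0 && all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-6)
    }
  }
})

test_that("windowed rates: equal prompt entry in both groups gives p = 1", {
  tr <- make_tracks(
    list(id = "m", lineage = "L", role = "mother", t = c(0, 10),
         x = c(0, 40), y = c(0, 0)),
    list(id = "d1", lineage = "L", role = "daughter", t = c(10, 20),
         x = c(85, 95), y = c(0, 0)),
    list(id = "d2", lineage = "L", role = "daughter", t = c(10, 20),
         x = c(75, 92), y = c(0, 0)),
    list(id = "n1", role = "non_dividing", t = c(0, 10, 20),
         x = c(80, 95, 100), y = c(0, 0, 0)),
    list(id = "n2", role = "non_dividing", t = c(0, 10, 20),
         x = c(70, 93, 100), y = c(0, 0, 0))
  )
  ev <- detect_entries(tr, cond1)
  wr <- windowed_entry_rates(ev, tr, window_min = 20)
  w0 <- wr[wr$window_idx == 0, ]
  expect_equal(unique(w0$p_value), 1)
  expect_equal(w0$rate, c(1, 1))
})

test_that("cumulative entry curves are monotone and end at the proportions", {
  gen <- gen_trackset(n_nondividing = 80, n_lineages = 40,
                      duration_min = 900, seed = 5)
  cond <- tibble::tibble(id = paste0("c", 1:9),
                         cx_um = rep(c(100, 200, 300), 3),
                         cy_um = rep(c(100, 200, 300), each = 3),
                         radius_um = 35)
  ev <- detect_entries(gen$tracks, cond)
  expect_gt(nrow(ev), 0)
  # censoring: one event per track at most
  expect_false(any(duplicated(ev$track_id)))
  cc <- cumulative_entry_curve(ev, gen$tracks)
  props <- entry_proportions(ev, gen$tracks)
  for (g in unique(cc$group)) {
    cg <- cc[cc$group == g, ]
    expect_true(all(diff(cg$cum_fraction) >= 0))
    expect_lte(max(cg$cum_fraction), 1)
    expect_equal(max(cg$cum_fraction),
                 props$fraction[props$group == g], tolerance = 1e-12)
  }
})

test_that("entry-distance densities integrate to one", {
  ev <- tibble::tibble(
    track_id = paste0("t", 1:40), lineage_id = paste0("t", 1:40),
    role = "non_dividing", group = "non_dividing",
    condensate_id = "c1", entry_time_min = 10, rel_entry_min = NA_real_,
    start_distance_um = c(rep(50, 10), runif(30, 10, 120)),
    started_inside = FALSE)
  dens <- entry_distance_density(ev, bin_um = 10)
  hist_part <- dens[dens$type == "histogram", ]
  expect_equal(sum(hist_part$density) * 10, 1, tolerance = 1e-9)
  smooth <- dens[dens$type == "smooth", ]
  area <- sum(diff(smooth$distance_um) *
                (head(smooth$density, -1) + tail(smooth$density, -1)) / 2)
  expect_equal(area, 1, tolerance = 0.05)

  # unit mass when all events share one distance
  one <- ev[1:10, ]
  d1 <- entry_distance_density(one, bin_um = 10)
  h1 <- d1[d1$type == "histogram", ]
  expect_equal(sum(h1$density[h1$distance_um > 40 & h1$distance_um < 60]) * 10,
               1, tolerance = 1e-9)
})

test_that("fast-phase daughters out-enter non-dividing cells in window one", {
  gen <- gen_trackset(n_nondividing = 200, n_lineages = 120,
                      duration_min = 900, seed = 9)
  cond <- tibble::tibble(id = paste0("c", 1:9),
                         cx_um = rep(c(100, 200, 300), 3),
                         cy_um = rep(c(100, 200, 300), each = 3),
                         radius_um = 35)
  ev <- detect_entries(gen$tracks, cond)
  wr <- windowed_entry_rates(ev, gen$tracks, window_min = 180)
  w0 <- wr[wr$window_idx == 0, ]
  expect_gt(w0$rate[w0$group == "dividing"],
            w0$rate[w0$group == "non_dividing"])
})
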