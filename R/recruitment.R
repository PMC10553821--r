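# Condensate entry detection and recruitment-rate statistics: first-entry
# detection with absorbing censoring, per-group entry proportions,
# windowed Fisher exact comparisons, and entry-distance densities.

role_group <- function(role) {
  ifelse(role == "non_dividing", "non_dividing", "dividing")
}

#' Detect first condensate entries
#'
#' A track enters a condensate at the first frame whose planar position
#' lies within a condensate disc (nucleus-centroid containment); from that
#' frame on the track is censored, so no track contributes more than one
#' entry. When a position lies inside several discs the nearest centre
#' wins. Tracks whose first observed point is already inside a disc are
#' flagged `started_inside` and must be excluded from rate analyses.
#'
#' The starting distance is measured from the group's reference position:
#' for dividing lineages, the lineage position at division (mother's last
#' frame if tracked, otherwise the daughter's first frame); for
#' non-dividing cells, the first tracked position.
#'
#' @param tracks a track tibble.
#' @param condensates a condensate tibble (see [as_condensates()]).
#' @return A tibble of entry events: `track_id, lineage_id, role, group,
#'   condensate_id, entry_time_min, rel_entry_min` (relative to division;
#'   `NA` for non-dividing), `start_distance_um, started_inside`.
#' @export
detect_entries <- function(tracks, condensates) {
  condensates <- as_condensates(condensates)
  if (nrow(condensates) == 0) {
    stop_dd("condensate map is empty", class = "dermadisp_validation_error")
  }
  div <- division_times(tracks)
  refs <- reference_positions(tracks, div)

  by_track <- split(tracks, tracks$track_id)
  events <- lapply(by_track, function(d) {
    dist_mat <- outer(d$x_um, condensates$cx_um, "-")^2 +
      outer(d$y_um, condensates$cy_um, "-")^2
    dist_mat <- sqrt(dist_mat)
    inside <- sweep(dist_mat, 2, condensates$radius_um, "<=")
    hit_rows <- which(rowSums(inside) > 0)
    if (length(hit_rows) == 0) return(NULL)
    i <- hit_rows[1]
    cand <- which(inside[i, ])
    j <- cand[which.min(dist_mat[i, cand])]
    tibble(
      track_id = d$track_id[1], lineage_id = d$lineage_id[1],
      role = d$role[1], group = role_group(d$role[1]),
      condensate_id = condensates$id[j],
      entry_time_min = d$t_min[i],
      started_inside = i == 1L
    )
  })
  out <- list_rbind(Filter(Negate(is.null), events))
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(track_id = character(), lineage_id = character(),
                  role = character(), group = character(),
                  condensate_id = character(), entry_time_min = numeric(),
                  rel_entry_min = numeric(), start_distance_um = numeric(),
                  started_inside = logical()))
  }
  out <- out |>
    left_join(div, by = "lineage_id") |>
    left_join(refs, by = "track_id") |>
    mutate(
      rel_entry_min = ifelse(.data$group == "dividing",
                             .data$entry_time_min - .data$division_time_min,
                             NA_real_),
      start_distance_um = sqrt(
        (.data$ref_x - condensates$cx_um[match(.data$condensate_id,
                                               condensates$id)])^2 +
        (.data$ref_y - condensates$cy_um[match(.data$condensate_id,
                                               condensates$id)])^2)
    ) |>
    select("track_id", "lineage_id", "role", "group", "condensate_id",
           "entry_time_min", "rel_entry_min", "start_distance_um",
           "started_inside")
  out
}

# reference position per track: lineage position at division for dividing
# lineages (mother's frame at/nearest division, else daughter's first
# frame), first tracked position for non-dividing cells
reference_positions <- function(tracks, div = division_times(tracks)) {
  firsts <- tracks |>
    group_by(.data$track_id) |>
    summarise(lineage_id = first(.data$lineage_id), role = first(.data$role),
              ref_x = first(.data$x_um), ref_y = first(.data$y_um),
              .groups = "drop")
  mother_at_div <- tracks |>
    filter(.data$role == "mother") |>
    group_by(.data$lineage_id) |>
    summarise(div_x = last(.data$x_um), div_y = last(.data$y_um),
              .groups = "drop")
  firsts |>
    left_join(mother_at_div, by = "lineage_id") |>
    mutate(
      use_div = .data$role %in% c("mother", "daughter") & !is.na(.data$div_x),
      ref_x = ifelse(.data$use_div, .data$div_x, .data$ref_x),
      ref_y = ifelse(.data$use_div, .data$div_y, .data$ref_y)
    ) |>
    select("track_id", "ref_x", "ref_y")
}

#' Per-group condensate entry proportions
#'
#' Fraction of tracked cells entering a condensate, for dividing-lineage
#' cells (mothers and daughters, each daughter counted separately) versus
#' non-dividing cells. Tracks that started inside a condensate are
#' excluded from both numerator and denominator.
#'
#' @param events entry events from [detect_entries()].
#' @param tracks the track tibble the events came from.
#' @return A tibble `group, n_tracked, n_entered, fraction`.
#' @export
entry_proportions <- function(events, tracks) {
  excluded <- events$track_id[events$started_inside]
  denom <- tracks |>
    distinct(.data$track_id, .data$role) |>
    filter(!(.data$track_id %in% excluded)) |>
    mutate(group = role_group(.data$role)) |>
    dplyr::count(.data$group, name = "n_tracked")
  num <- events |>
    filter(!.data$started_inside) |>
    dplyr::count(.data$group, name = "n_entered")
  out <- left_join(denom, num, by = "group") |>
    mutate(n_entered = dplyr::coalesce(.data$n_entered, 0L),
           fraction = ifelse(.data$n_tracked > 0,
                             .data$n_entered / .data$n_tracked, NA_real_))
  out
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value obtained by summing, over the hypergeometric
#' distribution induced by the table margins, the probabilities of all
#' tables no more probable than the observed one (probability-mass
#' summation, not tail doubling). A table with a zero margin carries no
#' information; by convention p = 1, flagged `degenerate`.
#'
#' @param table a 2x2 matrix of non-negative integer counts, or a numeric
#'   vector of length 4 in row-major order (a, b, c, d).
#' @return A list with `p_value`, `odds_ratio` (sample odds ratio) and
#'   `degenerate`; `tidy()` returns the same as a one-row tibble.
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as_2x2(table)
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  degenerate <- (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
  if (degenerate) {
    p <- 1
  } else {
    k <- max(0, c1 - r2):min(r1, c1)
    probs <- dhyper(k, r1, r2, c1)
    p_obs <- dhyper(a, r1, r2, c1)
    p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }
  or <- if (b * c_ > 0) (a * d) / (b * c_) else NA_real_
  structure(list(p_value = p, odds_ratio = or, table = m,
                 degenerate = degenerate),
            class = "dd_fisher_2x2")
}

as_2x2 <- function(table) {
  if (is.matrix(table)) {
    m <- table
  } else if (length(table) == 4) {
    m <- matrix(as.numeric(table), 2, 2, byrow = TRUE)
  } else {
    stop_dd("expected a 2x2 matrix or 4 counts",
            class = "dermadisp_validation_error")
  }
  if (any(m < 0) || any(m != round(m)) || any(!is.finite(m))) {
    stop_dd("counts must be non-negative integers",
            class = "dermadisp_validation_error")
  }
  storage.mode(m) <- "double"
  m
}

#' @export
print.dd_fisher_2x2 <- function(x, ...) {
  cat(sprintf("Fisher exact 2x2: p = %.6g%s\n", x$p_value,
              if (x$degenerate) " (zero margin; p = 1 by convention)" else ""))
  invisible(x)
}

#' @rdname dermadisp-generics
#' @export
tidy.dd_fisher_2x2 <- function(x, ...) {
  tibble(p_value = x$p_value, odds_ratio = x$odds_ratio,
         degenerate = x$degenerate)
}

#' Windowed condensate entry rates with Fisher exact comparisons
#'
#' Entry rates in consecutive windows of `window_min` minutes, aligned to
#' division for dividing-lineage cells (window 0 = 0-180 min post-mitosis)
#' and to the first tracked frame for non-dividing cells (matching
#' exposure). The risk set of a window contains cells under observation
#' at the window start that have not yet entered (entered cells are
#' censored; cells that started inside a disc are excluded throughout).
#' Each window is summarised by a 2x2 table (entered, not entered) x
#' (dividing, non-dividing) and a two-sided Fisher exact p-value.
#'
#' @param events entry events from [detect_entries()].
#' @param tracks the track tibble the events came from.
#' @param window_min window length in minutes (default 180).
#' @return A tibble with one row per window and group: `window_idx,
#'   window_label, group, n_at_risk, n_entered, rate, p_value` (the p for
#'   a window is repeated on both of its rows).
#' @export
windowed_entry_rates <- function(events, tracks, window_min = 180) {
  frame_dt <- frame_interval(tracks)
  if (is.finite(frame_dt) && window_min < 2 * frame_dt) {
    stop_dd("window_min must cover at least two frames",
            class = "dermadisp_validation_error")
  }
  excluded <- events$track_id[events$started_inside]
  ev <- filter(events, !.data$started_inside)
  div <- division_times(tracks)

  info <- tracks |>
    group_by(.data$track_id) |>
    summarise(lineage_id = first(.data$lineage_id), role = first(.data$role),
              t_first = min(.data$t_min), t_last = max(.data$t_min),
              .groups = "drop") |>
    filter(!(.data$track_id %in% excluded)) |>
    left_join(div, by = "lineage_id") |>
    mutate(
      group = role_group(.data$role),
      anchor = ifelse(.data$group == "dividing",
                      .data$division_time_min, .data$t_first),
      rel_start = .data$t_first - .data$anchor,
      rel_end = .data$t_last - .data$anchor
    ) |>
    left_join(ev |> select("track_id", "entry_time_min"), by = "track_id") |>
    mutate(rel_entry = .data$entry_time_min - .data$anchor)

  max_rel <- max(info$rel_end, na.rm = TRUE)
  n_win <- max(1L, ceiling(max_rel / window_min))
  rows <- list()
  for (w in seq_len(n_win) - 1L) {
    lo <- w * window_min; hi <- lo + window_min
    counts <- info |>
      mutate(
        at_risk = .data$rel_start <= lo & .data$rel_end > lo &
          (is.na(.data$rel_entry) | .data$rel_entry >= lo),
        entered = .data$at_risk & !is.na(.data$rel_entry) &
          .data$rel_entry < hi
      ) |>
      group_by(.data$group) |>
      summarise(n_at_risk = sum(.data$at_risk),
                n_entered = sum(.data$entered), .groups = "drop")
    counts <- tibble(group = c("dividing", "non_dividing")) |>
      left_join(counts, by = "group") |>
      mutate(across(c("n_at_risk", "n_entered"),
                    ~ dplyr::coalesce(.x, 0L)))
    tab <- matrix(c(counts$n_entered[1],
                    counts$n_at_risk[1] - counts$n_entered[1],
                    counts$n_entered[2],
                    counts$n_at_risk[2] - counts$n_entered[2]),
                  2, 2, byrow = TRUE)
    p <- fisher_exact_2x2(tab)$p_value
    rows[[w + 1L]] <- counts |>
      mutate(window_idx = w,
             window_label = sprintf("%g-%g min", lo, hi),
             rate = ifelse(.data$n_at_risk > 0,
                           .data$n_entered / .data$n_at_risk, NA_real_),
             p_value = p)
  }
  list_rbind(rows) |>
    select("window_idx", "window_label", "group", "n_at_risk",
           "n_entered", "rate", "p_value")
}

#' Cumulative entry curves
#'
#' Per-group cumulative fraction of cells that have entered a condensate
#' by a given time (relative to division for dividing lineages, to the
#' first tracked frame for non-dividing cells). Non-decreasing by
#' construction and ending at the [entry_proportions()] fraction.
#'
#' @inheritParams windowed_entry_rates
#' @return A tibble `group, rel_time_min, cum_fraction`.
#' @export
cumulative_entry_curve <- function(events, tracks) {
  props <- entry_proportions(events, tracks)
  ev <- filter(events, !.data$started_inside)
  firsts <- tracks |>
    group_by(.data$track_id) |>
    summarise(t_first = min(.data$t_min), .groups = "drop")
  ev <- ev |>
    left_join(firsts, by = "track_id") |>
    mutate(rel_time_min = ifelse(.data$group == "dividing",
                                 .data$rel_entry_min,
                                 .data$entry_time_min - .data$t_first))
  ev |>
    arrange(.data$group, .data$rel_time_min) |>
    group_by(.data$group) |>
    mutate(cum_entered = seq_len(dplyr::n())) |>
    ungroup() |>
    left_join(props |> select("group", "n_tracked"), by = "group") |>
    mutate(cum_fraction = .data$cum_entered / .data$n_tracked) |>
    select("group", "rel_time_min", "cum_fraction")
}

#' Entry-distance probability density
#'
#' Distribution of the starting distance from the entered condensate's
#' centre, for cells that entered: a normalised histogram (default 10-μm
#' bins) and a Gaussian-kernel smoothed density, each integrating to 1.
#'
#' @param events entry events from [detect_entries()] (or simulated
#'   absorptions with a `start_distance_um` and `group` column).
#' @param group optional group label to restrict to.
#' @param bin_um histogram bin width in micrometres.
#' @return A tibble `group, distance_um, density, type` where `type` is
#'   `"histogram"` (bin midpoints) or `"smooth"`.
#' @export
entry_distance_density <- function(events, group = NULL, bin_um = 10) {
  ev <- filter(events, !.data$started_inside)
  if (!is.null(group)) ev <- ev[ev$group %in% group, , drop = FALSE]
  if (nrow(ev) == 0) {
    warn_dd("no entry events; empty density", class = "dermadisp_empty_result")
    return(tibble(group = character(), distance_um = numeric(),
                  density = numeric(), type = character()))
  }
  ev |>
    dplyr::group_split(.data$group) |>
    map(function(d) {
      x <- d$start_distance_um
      breaks <- seq(0, max(x) + bin_um, by = bin_um)
      h <- graphics::hist(x, breaks = breaks, plot = FALSE)
      hist_tbl <- tibble(group = d$group[1], distance_um = h$mids,
                         density = h$density, type = "histogram")
      if (length(x) >= 2 && sd(x) > 0) {
        dn <- density(x, from = 0, to = max(x) + bin_um)
        sm <- tibble(group = d$group[1], distance_um = dn$x,
                     density = dn$y, type = "smooth")
        bind_rows(hist_tbl, sm)
      } else {
        hist_tbl
      }
    }) |>
    list_rbind()
}
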