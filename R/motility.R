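# Per-track and per-population motility statistics: speed, displacement,
# persistence, time-ensemble MSD and its fitted slope (the "diffusion
# coefficient" in the sense used for tracked nuclei: the raw MSD slope,
# with the physically normalised D = slope/4 reported alongside).

#' Instantaneous speeds along tracks
#'
#' Speed between consecutive frames is the planar step length divided by
#' the actual time difference (gaps contribute one step over the longer
#' interval; nothing is interpolated). Each value is timestamped at the
#' later frame.
#'
#' @param tracks a track tibble (see [as_tracks()]).
#' @return A tibble `track_id, lineage_id, role, t_min, speed_um_min`.
#'   Single-point tracks contribute no rows (with a warning).
#' @export
track_speeds <- function(tracks) {
  singletons <- tracks |>
    group_by(.data$track_id) |>
    summarise(n = dplyr::n(), .groups = "drop") |>
    filter(.data$n < 2)
  if (nrow(singletons) > 0) {
    warn_dd("track(s) with a single point produce no speeds: ",
            paste(singletons$track_id, collapse = ", "),
            class = "dermadisp_single_point")
  }
  tracks |>
    group_by(.data$track_id) |>
    mutate(
      speed_um_min = c(NA_real_,
                       step_lengths(.data$x_um, .data$y_um) /
                         diff(.data$t_min))
    ) |>
    ungroup() |>
    filter(!is.na(.data$speed_um_min)) |>
    select("track_id", "lineage_id", "role", "t_min", "speed_um_min")
}

#' Cell-cycle phase windows for a track table
#'
#' Builds the standard analysis windows relative to division: the mother's
#' final `window_min` minutes before division, the daughters' first and
#' second `window_min`-minute intervals after division, and one window
#' spanning the whole track for non-dividing cells. Division time is the
#' daughters' first observed frame (see [division_times()]).
#'
#' @param tracks a track tibble.
#' @param window_min window length in minutes (180 by default).
#' @return A tibble `track_id, lineage_id, role, window, t_start, t_end`;
#'   windows are half-open `[t_start, t_end)` except `non_dividing`, which
#'   covers the full observed span.
#' @export
assign_phase_windows <- function(tracks, window_min = 180) {
  div <- division_times(tracks)
  ids <- tracks |>
    distinct(.data$track_id, .data$lineage_id, .data$role)
  spans <- tracks |>
    group_by(.data$track_id) |>
    summarise(t_first = min(.data$t_min), t_last = max(.data$t_min),
              .groups = "drop")
  ids <- left_join(ids, spans, by = "track_id") |>
    left_join(div, by = "lineage_id")

  miss <- ids$role == "daughter" & is.na(ids$division_time_min)
  if (any(miss)) {
    stop_dd("daughter track(s) without a division time: ",
            paste(ids$track_id[miss], collapse = ", "),
            class = "dermadisp_validation_error")
  }

  rows <- list()
  mo <- filter(ids, .data$role == "mother", !is.na(.data$division_time_min))
  if (nrow(mo) > 0) {
    rows$mother <- tibble(
      track_id = mo$track_id, lineage_id = mo$lineage_id, role = mo$role,
      window = "mother_pre180",
      t_start = mo$division_time_min - window_min,
      t_end = mo$division_time_min
    )
  }
  da <- filter(ids, .data$role == "daughter")
  if (nrow(da) > 0) {
    rows$d1 <- tibble(
      track_id = da$track_id, lineage_id = da$lineage_id, role = da$role,
      window = "daughter_0_180",
      t_start = da$division_time_min,
      t_end = da$division_time_min + window_min
    )
    rows$d2 <- tibble(
      track_id = da$track_id, lineage_id = da$lineage_id, role = da$role,
      window = "daughter_180_360",
      t_start = da$division_time_min + window_min,
      t_end = da$division_time_min + 2 * window_min
    )
  }
  nd <- filter(ids, .data$role == "non_dividing")
  if (nrow(nd) > 0) {
    rows$nd <- tibble(
      track_id = nd$track_id, lineage_id = nd$lineage_id, role = nd$role,
      window = "non_dividing",
      t_start = nd$t_first, t_end = nd$t_last
    )
  }
  out <- bind_rows(rows)
  empty_mother <- out$window == "mother_pre180" &
    out$t_end <= (left_join(out, spans, by = "track_id")$t_first)
  if (any(empty_mother)) {
    warn_dd("mother window(s) empty (division at or before first frame)",
            class = "dermadisp_empty_window")
  }
  out
}

# points of each track that fall in each window ([start, end) for lineage
# windows, [start, end] for the non_dividing whole-track window)
phase_points <- function(tracks, windows) {
  out <- left_join(windows, tracks,
                   by = c("track_id", "lineage_id", "role"),
                   relationship = "many-to-many")
  keep <- ifelse(out$window == "non_dividing",
                 out$t_min >= out$t_start & out$t_min <= out$t_end,
                 out$t_min >= out$t_start & out$t_min < out$t_end)
  out[keep, , drop = FALSE]
}

#' Displacement metrics per track and phase window
#'
#' For each track and window: the Euclidean (straight-line) distance
#' between the first and last in-window points, the accumulated path
#' length over in-window steps, and persistence = Euclidean / accumulated
#' (1 for a perfectly straight, same-directed path; undefined when the
#' accumulated length is zero).
#'
#' @param tracks a track tibble.
#' @param windows phase windows, defaulting to [assign_phase_windows()].
#' @return A tibble with `track_id, lineage_id, role, window, n_points,
#'   euclidean_um, accumulated_um, persistence, no_data`; rows with fewer
#'   than two in-window points are flagged `no_data = TRUE`.
#' @export
displacement_metrics <- function(tracks, windows = NULL) {
  windows <- windows %||% assign_phase_windows(tracks)
  pts <- phase_points(tracks, windows)
  base <- windows |> select("track_id", "lineage_id", "role", "window")
  mets <- pts |>
    group_by(.data$track_id, .data$lineage_id, .data$role, .data$window) |>
    summarise(
      n_points = dplyr::n(),
      euclidean_um = sqrt((last(.data$x_um) - first(.data$x_um))^2 +
                          (last(.data$y_um) - first(.data$y_um))^2),
      accumulated_um = sum(step_lengths(.data$x_um, .data$y_um)),
      .groups = "drop"
    )
  out <- left_join(base, mets,
                   by = c("track_id", "lineage_id", "role", "window")) |>
    mutate(
      n_points = dplyr::coalesce(.data$n_points, 0L),
      no_data = .data$n_points < 2,
      euclidean_um = ifelse(.data$no_data, NA_real_, .data$euclidean_um),
      accumulated_um = ifelse(.data$no_data, NA_real_, .data$accumulated_um),
      persistence = ifelse(!.data$no_data & .data$accumulated_um > 0,
                           .data$euclidean_um / .data$accumulated_um,
                           NA_real_)
    ) |>
    select("track_id", "lineage_id", "role", "window", "n_points",
           "euclidean_um", "accumulated_um", "persistence", "no_data")
  out
}

#' Time-ensemble mean squared displacement
#'
#' For each lag (multiples of the frame interval up to `max_lag_min`), the
#' squared planar displacement is averaged over every track and every
#' start time at which both endpoints were observed; gapped frames simply
#' contribute no pair at the affected lags. Tracks acquired at different
#' frame intervals must not be pooled in one curve.
#'
#' @param tracks a track tibble (all at one frame interval).
#' @param max_lag_min largest lag in minutes; defaults to half the longest
#'   track duration.
#' @param frame_dt frame interval in minutes; inferred when `NULL`.
#' @return An `msd_curve` tibble `lag_min, msd_um2, n_pairs` (lags with no
#'   pairs are dropped), with attributes `frame_dt` and
#'   `shortest_track_min` (shortest contributing track duration, used for
#'   the default fit window of [diffusion_coefficient()]).
#' @export
msd_time_ensemble <- function(tracks, max_lag_min = NULL, frame_dt = NULL) {
  frame_dt <- frame_dt %||% frame_interval(tracks)
  if (!is.finite(frame_dt) || frame_dt <= 0) {
    stop_dd("cannot infer a positive frame interval",
            class = "dermadisp_validation_error")
  }
  by_track <- split(tracks[, c("t_min", "x_um", "y_um")], tracks$track_id)
  by_track <- Filter(function(d) nrow(d) >= 2, by_track)
  if (length(by_track) == 0) {
    warn_dd("no track with two or more points; empty MSD curve",
            class = "dermadisp_empty_result")
    out <- tibble(lag_min = numeric(), msd_um2 = numeric(),
                  n_pairs = integer())
    class(out) <- c("msd_curve", class(out))
    return(out)
  }
  durations <- vapply(by_track, function(d) diff(range(d$t_min)), numeric(1))
  max_lag_min <- max_lag_min %||% (max(durations) / 2)
  n_lags <- max(1L, floor(max_lag_min / frame_dt + 1e-9))

  sums <- numeric(n_lags)
  counts <- integer(n_lags)
  for (d in by_track) {
    idx <- as.integer(round(d$t_min / frame_dt))
    pos <- rep(NA_real_, max(idx) - min(idx) + 1L)
    off <- min(idx) - 1L
    xs <- pos; ys <- pos
    xs[idx - off] <- d$x_um
    ys[idx - off] <- d$y_um
    L <- length(xs)
    for (k in seq_len(min(n_lags, L - 1L))) {
      dx <- xs[(1L + k):L] - xs[1L:(L - k)]
      dy <- ys[(1L + k):L] - ys[1L:(L - k)]
      sq <- dx^2 + dy^2
      ok <- !is.na(sq)
      sums[k] <- sums[k] + sum(sq[ok])
      counts[k] <- counts[k] + sum(ok)
    }
  }
  out <- tibble(
    lag_min = seq_len(n_lags) * frame_dt,
    msd_um2 = ifelse(counts > 0, sums / counts, NA_real_),
    n_pairs = counts
  ) |> filter(.data$n_pairs > 0)
  attr(out, "frame_dt") <- frame_dt
  attr(out, "shortest_track_min") <- min(durations)
  class(out) <- c("msd_curve", class(out))
  out
}

#' MSD curves per cell-cycle phase window
#'
#' Convenience wrapper computing one time-ensemble MSD per phase window
#' (mother pre-division, daughters 0-180 and 180-360 min post-division,
#' non-dividing).
#'
#' @inheritParams msd_time_ensemble
#' @param windows phase windows, defaulting to [assign_phase_windows()].
#' @return A tibble with columns `window, lag_min, msd_um2, n_pairs`.
#' @export
msd_by_phase <- function(tracks, windows = NULL, max_lag_min = NULL,
                         frame_dt = NULL) {
  windows <- windows %||% assign_phase_windows(tracks)
  frame_dt <- frame_dt %||% frame_interval(tracks)
  pts <- phase_points(tracks, windows)
  pts |>
    dplyr::group_split(.data$window) |>
    map(function(d) {
      curve <- msd_time_ensemble(as_tibble(d), max_lag_min = max_lag_min,
                                 frame_dt = frame_dt)
      mutate(as_tibble(curve), window = d$window[1], .before = 1)
    }) |>
    list_rbind()
}

#' Fit the MSD slope ("diffusion coefficient")
#'
#' Ordinary least squares through the (lag, MSD) points of the fit window.
#' The slope itself is reported as the diffusion coefficient, matching how
#' tracked-nucleus MSD slopes are usually quoted; the physically
#' normalised planar coefficient `D = slope / 4` is reported alongside.
#'
#' @param curve an `msd_curve` from [msd_time_ensemble()].
#' @param fit_window numeric length-2 lag range in minutes; the default
#'   spans one frame interval to a quarter of the shortest contributing
#'   track duration (a standard guard against noisy large-lag estimates).
#' @return A `dd_diffusion_fit` object with elements `slope` (μm²/min),
#'   `intercept`, `D` (= slope/4), `r_squared`, `fit_window`, `n_lags`.
#'   Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
diffusion_coefficient <- function(curve, fit_window = NULL) {
  if (is.null(fit_window)) {
    hi <- attr(curve, "shortest_track_min")
    hi <- if (is.null(hi)) max(curve$lag_min) else hi / 4
    fit_window <- c(min(curve$lag_min), max(min(curve$lag_min), hi))
  }
  pts <- filter(curve, .data$lag_min >= fit_window[1],
                .data$lag_min <= fit_window[2])
  if (nrow(pts) < 2) {
    stop_dd("fit window contains fewer than two lags",
            class = "dermadisp_validation_error")
  }
  fit <- lm(msd_um2 ~ lag_min, data = pts)
  r2 <- summary(fit)$r.squared
  structure(
    list(slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         D = unname(coef(fit)[2]) / 4,
         r_squared = r2,
         fit_window = fit_window,
         n_lags = nrow(pts),
         curve = curve,
         model = fit),
    class = "dd_diffusion_fit"
  )
}

#' @export
print.dd_diffusion_fit <- function(x, ...) {
  cat("MSD linear fit\n")
  cat(sprintf("  slope (MSD/lag): %.6g um^2/min   D = slope/4: %.6g um^2/min\n",
              x$slope, x$D))
  cat(sprintf("  intercept: %.6g um^2   R^2: %.4f   lags: %d in [%g, %g] min\n",
              x$intercept, x$r_squared, x$n_lags,
              x$fit_window[1], x$fit_window[2]))
  invisible(x)
}

#' @rdname dermadisp-generics
#' @export
tidy.dd_diffusion_fit <- function(x, ...) {
  tibble(term = c("slope", "intercept"),
         estimate = c(x$slope, x$intercept),
         std.error = summary(x$model)$coefficients[c(2, 1), 2])
}

#' @rdname dermadisp-generics
#' @export
glance.dd_diffusion_fit <- function(x, ...) {
  tibble(slope_um2_min = x$slope, D_um2_min = x$D,
         intercept_um2 = x$intercept, r_squared = x$r_squared,
         n_lags = x$n_lags,
         fit_lo_min = x$fit_window[1], fit_hi_min = x$fit_window[2])
}
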