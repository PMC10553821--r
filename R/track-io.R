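# Trajectory / condensate table model and readers.
#
# Standard track schema (long format, one row per cell per frame):
#   track_id, lineage_id, role, t_min, x_um, y_um [, z_um]
# role is one of "mother", "daughter", "non_dividing". Division time is
# implicit in the table: a daughter's first frame is the first frame after
# cytokinesis, a mother's last frame is at (or before) division.
# Condensate schema: id, cx_um, cy_um, radius_um.

TRACK_ROLES <- c("mother", "daughter", "non_dividing")
TRACK_COLS <- c("track_id", "lineage_id", "role", "t_min", "x_um", "y_um")

#' Validate and normalise a track table
#'
#' Checks the standard track schema and its invariants: required columns,
#' finite non-negative times, finite planar coordinates, known roles,
#' strictly increasing times within each track, and a single role and
#' lineage per track. Rows are sorted by track and time. Time gaps
#' (missing frames) are retained and flagged, never interpolated.
#'
#' @param tracks a data frame in the standard track schema.
#' @param frame_dt acquisition interval in minutes; inferred as the modal
#'   consecutive time difference when `NULL`.
#' @return A tibble sorted by `track_id`, `t_min`, with attributes
#'   `frame_dt` (minutes) and `n_gaps` (count of consecutive-frame gaps
#'   larger than `frame_dt`).
#' @export
as_tracks <- function(tracks, frame_dt = NULL) {
  missing_cols <- setdiff(TRACK_COLS, names(tracks))
  if (length(missing_cols) > 0) {
    stop_dd("track table is missing column(s): ",
            paste(missing_cols, collapse = ", "),
            class = "dermadisp_schema_error")
  }
  out <- as_tibble(tracks)
  out$track_id <- as.character(out$track_id)
  out$lineage_id <- as.character(out$lineage_id)
  out$role <- as.character(out$role)

  bad_role <- setdiff(unique(out$role), TRACK_ROLES)
  if (length(bad_role) > 0) {
    stop_dd("unknown role(s): ", paste(bad_role, collapse = ", "),
            class = "dermadisp_validation_error")
  }
  if (nrow(out) > 0) {
    if (any(!is.finite(out$t_min)) || any(out$t_min < 0)) {
      stop_dd("t_min must be finite and non-negative",
              class = "dermadisp_validation_error")
    }
    if (any(!is.finite(out$x_um)) || any(!is.finite(out$y_um))) {
      stop_dd("x_um / y_um must be finite",
              class = "dermadisp_validation_error")
    }
  }
  out <- dplyr::arrange(out, .data$track_id, .data$t_min)

  n_gaps <- 0L
  if (nrow(out) > 0) {
    by_track <- split(out$t_min, out$track_id)
    for (id in names(by_track)) {
      tt <- by_track[[id]]
      if (length(tt) > 1 && any(diff(tt) <= 0)) {
        stop_dd("non-monotone times within track '", id, "'",
                class = "dermadisp_validation_error")
      }
    }
    multi <- vapply(split(out$role, out$track_id),
                    function(r) length(unique(r)), integer(1))
    if (any(multi > 1)) {
      stop_dd("track(s) with more than one role: ",
              paste(names(multi)[multi > 1], collapse = ", "),
              class = "dermadisp_validation_error")
    }
    dts <- unlist(lapply(by_track, diff), use.names = FALSE)
    if (is.null(frame_dt)) {
      frame_dt <- if (length(dts) == 0) NA_real_ else modal_value(dts)
    }
    if (length(dts) > 0 && is.finite(frame_dt)) {
      n_gaps <- sum(dts > frame_dt * 1.5)
    }
  }
  attr(out, "frame_dt") <- frame_dt
  attr(out, "n_gaps") <- n_gaps
  out
}

modal_value <- function(x) {
  ux <- sort(unique(x))
  ux[which.max(tabulate(match(x, ux)))]
}

#' Acquisition frame interval of a track table
#'
#' Returns the `frame_dt` attribute when present, otherwise the modal
#' consecutive time difference across tracks (10 min for the mouse
#' explant movies, 15 min for chicken).
#'
#' @param tracks a track table.
#' @return Frame interval in minutes.
#' @export
frame_interval <- function(tracks) {
  fd <- attr(tracks, "frame_dt")
  if (!is.null(fd) && is.finite(fd)) return(fd)
  dts <- unlist(lapply(split(tracks$t_min, tracks$track_id), diff),
                use.names = FALSE)
  if (length(dts) == 0) return(NA_real_)
  modal_value(dts)
}

#' Read a track table from CSV/TSV or a workbook sheet
#'
#' Tracking tables exported from manual-tracking tools arrive as CSV/TSV
#' files or multi-sheet workbooks; `dialect` maps either onto the standard
#' schema.
#'
#' @param path file path.
#' @param dialect optional list: `format` ("csv", "tsv" or "xlsx",
#'   inferred from the extension when missing), `sheet` (workbook sheet
#'   name or index) and `columns` (named character vector mapping standard
#'   column names to the file's column names).
#' @param frame_dt optional frame interval in minutes; inferred if `NULL`.
#' @return A validated track tibble (see [as_tracks()]).
#' @export
read_track_table <- function(path, dialect = NULL, frame_dt = NULL) {
  raw <- read_table_any(path, dialect)
  cols <- dialect$columns
  if (!is.null(cols)) {
    for (std in names(cols)) {
      if (!cols[[std]] %in% names(raw)) {
        stop_dd("dialect column '", cols[[std]], "' not found in ", path,
                class = "dermadisp_schema_error")
      }
      names(raw)[names(raw) == cols[[std]]] <- std
    }
  }
  as_tracks(raw, frame_dt = frame_dt)
}

read_table_any <- function(path, dialect = NULL) {
  if (!file.exists(path)) {
    stop_dd("file not found: ", path, class = "dermadisp_io_error")
  }
  fmt <- dialect$format %||% switch(tolower(tools::file_ext(path)),
                                    tsv = "tsv", txt = "tsv",
                                    xlsx = "xlsx", xls = "xlsx",
                                    "csv")
  switch(fmt,
    csv = readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    tsv = readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop_dd("readxl is required to read workbooks",
                class = "dermadisp_io_error")
      }
      readxl::read_excel(path, sheet = dialect$sheet %||% 1)
    },
    stop_dd("unknown table format: ", fmt, class = "dermadisp_io_error")
  )
}

#' Read a condensate map
#'
#' @param path CSV with columns `id`, `cx_um`, `cy_um`, `radius_um`.
#' @return A condensate tibble (one disc per row).
#' @export
read_condensate_map <- function(path) {
  as_condensates(read_table_any(path))
}

#' Validate a condensate table
#'
#' @param condensates a data frame with columns `id`, `cx_um`, `cy_um`,
#'   `radius_um`; radii must be positive and ids unique.
#' @return A condensate tibble.
#' @export
as_condensates <- function(condensates) {
  need <- c("id", "cx_um", "cy_um", "radius_um")
  missing_cols <- setdiff(need, names(condensates))
  if (length(missing_cols) > 0) {
    stop_dd("condensate table is missing column(s): ",
            paste(missing_cols, collapse = ", "),
            class = "dermadisp_schema_error")
  }
  out <- as_tibble(condensates)[, need]
  out$id <- as.character(out$id)
  if (nrow(out) > 0) {
    if (any(!is.finite(out$radius_um)) || any(out$radius_um <= 0)) {
      stop_dd("condensate radius_um must be positive",
              class = "dermadisp_validation_error")
    }
    if (anyDuplicated(out$id)) {
      stop_dd("duplicate condensate id(s): ",
              paste(unique(out$id[duplicated(out$id)]), collapse = ", "),
              class = "dermadisp_validation_error")
    }
  }
  out
}

#' Write a results table as CSV
#'
#' Writes with a stable column order and full precision so that numeric
#' round-trips agree to at least 12 significant digits.
#'
#' @param records a data frame.
#' @param path output path.
#' @return `records`, invisibly.
#' @export
write_results_table <- function(records, path) {
  readr::write_csv(as_tibble(records), path, progress = FALSE)
  invisible(records)
}

#' Write a track table in the standard schema
#'
#' @param tracks a track tibble.
#' @param path output path (CSV).
#' @return `tracks`, invisibly.
#' @export
write_track_table <- function(tracks, path) {
  keep <- intersect(c(TRACK_COLS, "z_um"), names(tracks))
  readr::write_csv(tracks[, keep], path, progress = FALSE)
  invisible(tracks)
}

#' Division times per lineage
#'
#' The division time of a lineage is the first frame after cytokinesis,
#' i.e. the earliest time at which a daughter of that lineage is observed.
#' Lineages whose daughters were not tracked fall back to the mother's
#' last frame.
#'
#' @param tracks a track tibble.
#' @return A tibble with `lineage_id` and `division_time_min`.
#' @export
division_times <- function(tracks) {
  daughters <- filter(tracks, .data$role == "daughter")
  div <- if (nrow(daughters) == 0) {
    tibble(lineage_id = character(), division_time_min = numeric())
  } else {
    daughters |>
      group_by(.data$lineage_id) |>
      summarise(division_time_min = min(.data$t_min), .groups = "drop")
  }
  mothers <- tracks |>
    filter(.data$role == "mother",
           !(.data$lineage_id %in% div$lineage_id))
  mothers <- if (nrow(mothers) == 0) {
    tibble(lineage_id = character(), division_time_min = numeric())
  } else {
    mothers |>
      group_by(.data$lineage_id) |>
      summarise(division_time_min = max(.data$t_min), .groups = "drop")
  }
  bind_rows(div, mothers) |> arrange(.data$lineage_id)
}
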