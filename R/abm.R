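# Agent-based model of mitotic dispersal: off-lattice diffusive walkers on
# a periodic square domain, division events with a diametric mitotic jump
# (angle theta from the horizontal) followed by a persistent random walk
# (per-step distance d_pers, turning angle Phi about the previous heading,
# first heading along the jump direction), and fully absorbing condensate
# discs. Per-step draw order: movement, then division, then absorption.

#' Convert a target mean step speed to a diffusion coefficient
#'
#' For a planar Gaussian walk with per-axis step variance `2 D dt`, step
#' lengths are Rayleigh with mean `sigma sqrt(pi/2)`; matching a target
#' mean speed fixes `D = (speed dt / sqrt(pi/2))^2 / (2 dt)`.
#'
#' @param speed_um_min target mean step speed (μm/min).
#' @param frame_dt frame interval (minutes).
#' @return Diffusion coefficient D (μm²/min).
#' @export
speed_to_D <- function(speed_um_min, frame_dt) {
  sigma <- speed_um_min * frame_dt / sqrt(pi / 2)
  sigma^2 / (2 * frame_dt)
}

#' Simulation configuration
#'
#' Defaults reproduce the measured scales of the explant movies: 10-min
#' frames, interphase diffusion at the MSD-slope scale of the tracked
#' non-dividing population (D = 0.05 μm²/min), a
#' 180-min fast phase at three times the interphase mean speed with
#' wrapped-normal turning, an 8 μm diametric mitotic separation, and four
#' absorbing condensate discs of 35 μm radius on a square lattice in a
#' 400 μm periodic domain.
#'
#' @param domain_um square domain side (μm).
#' @param frame_dt step length (minutes).
#' @param duration_min run length (minutes).
#' @param n_cells initial cell count.
#' @param interphase_speed mean interphase step speed (μm/min); sets `D`
#'   when given. By default derived from `D`.
#' @param D interphase diffusion coefficient (μm²/min); default 0.05, the
#'   MSD-slope scale of the tracked non-dividing population.
#' @param division_rate per-cell probability of dividing per step
#'   (fast-phase daughters are excluded).
#' @param n_divisions optional fixed division schedule (overrides
#'   `division_rate`): this many of the initial cells are designated as
#'   dividers at t = 0, each with a division time uniform over the run, as
#'   when dividing cells are identified by observing the whole movie. A
#'   designated cell absorbed before its division time still belongs to
#'   the dividing group in the entry statistics. Only designated cells
#'   divide in this mode.
#' @param jump_length_um diametric mitotic separation (μm); each daughter
#'   is displaced half of it.
#' @param theta_mean_deg,theta_sd_deg mitotic jump angle distribution:
#'   uniform axial when `theta_mean_deg` is `NULL` (default), otherwise
#'   wrapped normal about the mean (a point mass when `theta_sd_deg = 0`).
#' @param persist_steps fast-phase steps (default 180 min / `frame_dt`).
#' @param fast_multiplier fast-phase mean speed as a multiple of the
#'   interphase mean speed; sets the Rayleigh scale of `d_pers`.
#' @param phi_sd_deg wrapped-normal s.d. of the per-step turning angle
#'   about the previous heading (degrees).
#' @param pause_steps zero-displacement steps inserted between the mitotic
#'   jump and the fast phase (default 0).
#' @param condensates condensate tibble (see [as_condensates()]); must lie
#'   inside the domain.
#' @param init_positions optional `n_cells x 2` matrix of initial positions
#'   (μm); uniform random placement when `NULL`.
#' @return A `dd_sim_config` list.
#' @export
sim_config <- function(domain_um = 400, frame_dt = 10, duration_min = 1500,
                       n_cells = 1000, interphase_speed = NULL, D = NULL,
                       division_rate = 0.0015, n_divisions = NULL,
                       jump_length_um = 8, theta_mean_deg = NULL,
                       theta_sd_deg = 20,
                       persist_steps = NULL, fast_multiplier = 3,
                       phi_sd_deg = 40, pause_steps = 0,
                       condensates = NULL, init_positions = NULL) {
  if (domain_um <= 0 || frame_dt <= 0 || duration_min <= 0 || n_cells < 1) {
    stop_dd("domain_um, frame_dt, duration_min must be positive",
            class = "dermadisp_config_error")
  }
  if (is.null(D) && is.null(interphase_speed)) D <- 0.05
  D <- D %||% speed_to_D(interphase_speed, frame_dt)
  # mean step speed implied by D (Rayleigh mean of Gaussian steps); the
  # fast-phase step scale is fast_multiplier times this
  interphase_speed <- interphase_speed %||%
    (sqrt(2 * D * frame_dt) * sqrt(pi / 2) / frame_dt)
  if (D < 0 || division_rate < 0 || jump_length_um < 0 ||
      fast_multiplier < 0) {
    stop_dd("rates, lengths and multipliers must be non-negative",
            class = "dermadisp_config_error")
  }
  persist_steps <- persist_steps %||% round(180 / frame_dt)
  # default layout: four discs on a half-spaced square lattice, the
  # nascent-follicle pattern of the imaged fields, 35 μm radius each
  condensates <- as_condensates(
    condensates %||% tibble(id = paste0("c", 1:4),
                            cx_um = domain_um * c(0.25, 0.75, 0.25, 0.75),
                            cy_um = domain_um * c(0.25, 0.25, 0.75, 0.75),
                            radius_um = 35)
  )
  structure(
    list(domain_um = domain_um, frame_dt = frame_dt,
         duration_min = duration_min, n_cells = n_cells,
         interphase_speed = interphase_speed, D = D,
         division_rate = division_rate, n_divisions = n_divisions,
         jump_length_um = jump_length_um,
         theta_mean_deg = theta_mean_deg, theta_sd_deg = theta_sd_deg,
         persist_steps = persist_steps, fast_multiplier = fast_multiplier,
         phi_sd_deg = phi_sd_deg, pause_steps = pause_steps,
         condensates = condensates, init_positions = init_positions),
    class = "dd_sim_config"
  )
}

# minimal-image displacement on the torus
torus_delta <- function(d, L) {
  d - L * round(d / L)
}

#' Minimal-image distance on the periodic domain
#'
#' @param x1,y1,x2,y2 coordinates (μm).
#' @param L domain side (μm).
#' @return Distances under the minimal-image convention.
#' @export
torus_distance <- function(x1, y1, x2, y2, L) {
  sqrt(torus_delta(x1 - x2, L)^2 + torus_delta(y1 - y2, L)^2)
}

#' Run the mitotic-dispersal agent-based model
#'
#' Cells are placed uniformly at random and, per step, move (diffusive
#' interphase steps, or persistent fast-phase steps for newly born
#' daughters), may divide (a dividing cell is replaced by two daughters
#' displaced `jump_length_um / 2` each in diametrically opposite
#' directions at angle theta), and are absorbed when their position falls
#' inside a condensate disc. Positions wrap periodically. Daughters cannot
#' divide during their fast phase; afterwards they revert to the
#' interphase walk and may divide.
#'
#' @param config a `dd_sim_config` (see [sim_config()]).
#' @param seed integer seed.
#' @param replicate_id label recorded in the outputs.
#' @param record_tracks if `FALSE`, per-frame trajectories are not stored
#'   (absorptions and divisions still are).
#' @return A `dd_sim_result` list: `tracks` (standard track schema),
#'   `absorptions` (`track_id, group, t_min, condensate_id, start_x,
#'   start_y, start_distance_um, started_inside`), `divisions`
#'   (`lineage_id, t_min, x_um, y_um, angle_deg`), `counts` (per-step
#'   `t_min, alive, absorbed, divisions_cum`), `group_sizes`, `config`,
#'   `replicate_id`.
#' @export
simulate_dispersal <- function(config, seed = 1, replicate_id = 1L,
                               record_tracks = TRUE) {
  stopifnot(inherits(config, "dd_sim_config"))
  L <- config$domain_um
  dt <- config$frame_dt
  n_steps <- floor(config$duration_min / dt)
  cond <- config$condensates
  if (any(cond$cx_um < 0 | cond$cx_um > L | cond$cy_um < 0 |
          cond$cy_um > L)) {
    stop_dd("condensates must lie within the domain",
            class = "dermadisp_config_error")
  }
  set.seed(seed)

  sigma <- sqrt(2 * config$D * dt)
  d_pers_scale <- config$fast_multiplier * config$interphase_speed * dt /
    sqrt(pi / 2)

  n0 <- config$n_cells
  cap <- n0 * 4 + 64
  x <- numeric(cap); y <- numeric(cap)
  alive <- logical(cap)
  fast_left <- integer(cap); pause_left <- integer(cap)
  heading <- numeric(cap)
  divided <- logical(cap)   # underwent division (removed as a cell)
  born <- logical(cap)      # arose from a division
  designated <- logical(cap) # scheduled to divide (fixed-schedule mode)
  start_x <- numeric(cap); start_y <- numeric(cap)
  lineage <- character(cap)

  idx <- seq_len(n0)
  x[idx] <- runif(n0, 0, L); y[idx] <- runif(n0, 0, L)
  alive[idx] <- TRUE
  lineage[idx] <- paste0("L", idx)
  start_x[idx] <- x[idx]; start_y[idx] <- y[idx]
  n_total <- n0
  next_lineage <- n0 + 1L

  div_step <- rep(NA_integer_, cap)
  if (!is.null(config$init_positions)) {
    stopifnot(nrow(config$init_positions) == n0)
    x[idx] <- config$init_positions[, 1] %% L
    y[idx] <- config$init_positions[, 2] %% L
    start_x[idx] <- x[idx]; start_y[idx] <- y[idx]
  }
  if (!is.null(config$n_divisions)) {
    k <- min(config$n_divisions, n0)
    chosen <- sample.int(n0, k)
    designated[chosen] <- TRUE
    div_step[chosen] <- sample.int(n_steps, k, replace = TRUE)
  }

  absorptions <- list(); divisions <- list()
  track_rows <- list()
  counts <- matrix(NA_real_, n_steps + 1, 4)
  n_absorbed <- 0L; n_divisions <- 0L

  absorb <- function(ids, t_now, at_start = FALSE) {
    if (length(ids) == 0) return(invisible(NULL))
    dmat <- vapply(seq_len(nrow(cond)), function(j) {
      torus_distance(x[ids], y[ids], cond$cx_um[j], cond$cy_um[j], L)
    }, numeric(length(ids)))
    dmat <- matrix(dmat, nrow = length(ids))
    inside <- sweep(dmat, 2, cond$radius_um, "<=")
    hit <- which(rowSums(inside) > 0)
    if (length(hit) == 0) return(invisible(NULL))
    for (ii in hit) {
      i <- ids[ii]
      js <- which(inside[ii, ])
      j <- js[which.min(dmat[ii, js])]
      sx <- start_x[i]; sy <- start_y[i]
      sd_um <- torus_distance(sx, sy, cond$cx_um[j], cond$cy_um[j], L)
      absorptions[[length(absorptions) + 1L]] <<- tibble(
        track_id = paste0("T", i),
        group = if (born[i] || divided[i] || designated[i]) "dividing" else
          "non_dividing",
        t_min = t_now, condensate_id = cond$id[j],
        start_x = sx, start_y = sy,
        start_distance_um = sd_um,
        started_inside = at_start
      )
      alive[i] <<- FALSE
    }
    n_absorbed <<- n_absorbed + length(hit)
    invisible(NULL)
  }

  record <- function(t_now) {
    if (!record_tracks) return(invisible(NULL))
    ids <- which(alive)
    if (length(ids) == 0) return(invisible(NULL))
    track_rows[[length(track_rows) + 1L]] <<- tibble(
      cell = ids, t_min = t_now, x_um = x[ids], y_um = y[ids],
      fast = fast_left[ids] > 0 | pause_left[ids] > 0
    )
    invisible(NULL)
  }

  # initial placement; cells landing inside a disc are absorbed at t = 0
  absorb(which(alive), 0, at_start = TRUE)
  if (!any(alive)) {
    warn_dd("all cells absorbed at t = 0 (condensates cover the domain)",
            class = "dermadisp_degenerate_run")
  }
  record(0)
  counts[1, ] <- c(0, sum(alive), n_absorbed, n_divisions)

  for (s in seq_len(n_steps)) {
    t_now <- s * dt
    ids <- which(alive)
    if (length(ids) > 0) {
      paused <- ids[pause_left[ids] > 0]
      fasts <- ids[pause_left[ids] == 0 & fast_left[ids] > 0]
      diff_ids <- ids[pause_left[ids] == 0 & fast_left[ids] == 0]
      if (length(diff_ids) > 0) {
        x[diff_ids] <- (x[diff_ids] + rnorm(length(diff_ids), 0, sigma)) %% L
        y[diff_ids] <- (y[diff_ids] + rnorm(length(diff_ids), 0, sigma)) %% L
      }
      if (length(fasts) > 0) {
        step_len <- d_pers_scale * sqrt(-2 * log(runif(length(fasts))))
        x[fasts] <- (x[fasts] + step_len * cos(heading[fasts] * pi / 180)) %% L
        y[fasts] <- (y[fasts] + step_len * sin(heading[fasts] * pi / 180)) %% L
        heading[fasts] <- (heading[fasts] +
                             rnorm(length(fasts), 0, config$phi_sd_deg)) %% 360
        fast_left[fasts] <- fast_left[fasts] - 1L
      }
      if (length(paused) > 0) pause_left[paused] <- pause_left[paused] - 1L
    }

    # division: interphase cells only
    ids <- which(alive)
    eligible <- ids[pause_left[ids] == 0 & fast_left[ids] == 0]
    if (length(eligible) > 0) {
      if (!is.null(config$n_divisions)) {
        movers <- eligible[!is.na(div_step[eligible]) &
                             div_step[eligible] == s]
      } else {
        movers <- eligible[runif(length(eligible)) < config$division_rate]
      }
      for (i in movers) {
        theta <- if (is.null(config$theta_mean_deg)) {
          runif(1, 0, 180)
        } else {
          axial_mod(config$theta_mean_deg +
                      rnorm(1, 0, config$theta_sd_deg))
        }
        lin <- paste0("L", next_lineage); next_lineage <- next_lineage + 1L
        if (n_total + 2L > cap) {
          grow <- cap
          x <- c(x, numeric(grow)); y <- c(y, numeric(grow))
          alive <- c(alive, logical(grow))
          fast_left <- c(fast_left, integer(grow))
          pause_left <- c(pause_left, integer(grow))
          heading <- c(heading, numeric(grow))
          divided <- c(divided, logical(grow))
          born <- c(born, logical(grow))
          designated <- c(designated, logical(grow))
          div_step <- c(div_step, rep(NA_integer_, grow))
          start_x <- c(start_x, numeric(grow))
          start_y <- c(start_y, numeric(grow))
          lineage <- c(lineage, character(grow))
          cap <- cap + grow
        }
        d1 <- n_total + 1L; d2 <- n_total + 2L; n_total <- n_total + 2L
        half <- config$jump_length_um / 2
        dxj <- half * cos(theta * pi / 180)
        dyj <- half * sin(theta * pi / 180)
        x[d1] <- (x[i] + dxj) %% L; y[d1] <- (y[i] + dyj) %% L
        x[d2] <- (x[i] - dxj) %% L; y[d2] <- (y[i] - dyj) %% L
        alive[c(d1, d2)] <- TRUE
        born[c(d1, d2)] <- TRUE
        fast_left[c(d1, d2)] <- config$persist_steps
        pause_left[c(d1, d2)] <- config$pause_steps
        heading[d1] <- theta
        heading[d2] <- (theta + 180) %% 360
        start_x[c(d1, d2)] <- x[i]; start_y[c(d1, d2)] <- y[i]
        lineage[c(d1, d2)] <- lin
        divided[i] <- TRUE
        alive[i] <- FALSE
        divisions[[length(divisions) + 1L]] <- tibble(
          lineage_id = lin, t_min = t_now, x_um = x[i], y_um = y[i],
          angle_deg = axial_mod(theta),
          daughter_ids = paste0("T", d1, "+T", d2),
          mother_id = paste0("T", i)
        )
        n_divisions <- n_divisions + 1L
      }
    }

    absorb(which(alive), t_now)
    record(t_now)
    counts[s + 1, ] <- c(t_now, sum(alive), n_absorbed, n_divisions)
  }

  divisions <- if (length(divisions)) list_rbind(divisions) else
    tibble(lineage_id = character(), t_min = numeric(), x_um = numeric(),
           y_um = numeric(), angle_deg = numeric(),
           daughter_ids = character(), mother_id = character())
  absorptions <- if (length(absorptions)) list_rbind(absorptions) else
    tibble(track_id = character(), group = character(), t_min = numeric(),
           condensate_id = character(), start_x = numeric(),
           start_y = numeric(), start_distance_um = numeric(),
           started_inside = logical())

  tracks <- NULL
  if (record_tracks && length(track_rows) > 0) {
    raw <- list_rbind(track_rows)
    role_of <- function(i) {
      if (born[i]) "daughter" else if (divided[i]) "mother" else
        "non_dividing"
    }
    roles <- vapply(seq_len(n_total), role_of, character(1))
    tracks <- raw |>
      mutate(track_id = paste0("T", .data$cell),
             lineage_id = lineage[.data$cell],
             role = roles[.data$cell]) |>
      select("track_id", "lineage_id", "role", "t_min", "x_um", "y_um") |>
      arrange(.data$track_id, .data$t_min)
  }

  structure(
    list(tracks = tracks, absorptions = absorptions, divisions = divisions,
         counts = tibble(t_min = counts[, 1], alive = counts[, 2],
                         absorbed = counts[, 3],
                         divisions_cum = counts[, 4]),
         group_sizes = {
           idx_all <- seq_len(n_total)
           n_div <- sum(born[idx_all] | divided[idx_all] |
                          designated[idx_all])
           tibble(group = c("dividing", "non_dividing"),
                  n = c(n_div, n_total - n_div))
         },
         config = config, replicate_id = replicate_id, seed = seed),
    class = "dd_sim_result"
  )
}

#' Run seeded replicate simulations
#'
#' @param config a `dd_sim_config`.
#' @param n_replicates number of replicates (default 8).
#' @param seed master seed; per-replicate seeds are derived substreams.
#' @param record_tracks passed to [simulate_dispersal()].
#' @return A list of `dd_sim_result`.
#' @export
simulate_replicates <- function(config, n_replicates = 8, seed = 1,
                                record_tracks = FALSE) {
  lapply(seq_len(n_replicates), function(r) {
    simulate_dispersal(config, seed = child_seed(seed, paste0("rep", r)),
                       replicate_id = r, record_tracks = record_tracks)
  })
}

#' Entry statistics across simulation replicates
#'
#' Per-replicate condensate-entry fractions by group (dividing = cells
#' that underwent or arose from a division; cells absorbed at t = 0 are
#' excluded), their mean and standard error, and pooled entry-distance
#' densities (minimal-image starting distances).
#'
#' @param results a list of `dd_sim_result`.
#' @param bin_um histogram bin width for the densities (μm).
#' @return A list: `fractions` (per replicate and group), `summary`
#'   (per-group mean, SEM, n), `densities` (see
#'   [entry_distance_density()]), `initial_locations` (start positions of
#'   eventual enterers).
#' @export
entry_statistics <- function(results, bin_um = 10) {
  fracs <- map(results, function(res) {
    abs_ok <- filter(res$absorptions, !.data$started_inside)
    ns <- setNames(res$group_sizes$n, res$group_sizes$group)
    started_inside_groups <- table(
      res$absorptions$group[res$absorptions$started_inside])
    for (g in names(started_inside_groups)) {
      ns[g] <- ns[g] - started_inside_groups[[g]]
    }
    tibble(replicate_id = res$replicate_id,
           group = c("dividing", "non_dividing"),
           n_group = as.numeric(ns[c("dividing", "non_dividing")]),
           n_entered = c(sum(abs_ok$group == "dividing"),
                         sum(abs_ok$group == "non_dividing"))) |>
      mutate(fraction = ifelse(.data$n_group > 0,
                               .data$n_entered / .data$n_group, NA_real_))
  }) |> list_rbind()

  summ <- fracs |>
    group_by(.data$group) |>
    summarise(mean_fraction = mean(.data$fraction, na.rm = TRUE),
              sem = sd(.data$fraction, na.rm = TRUE) /
                sqrt(sum(!is.na(.data$fraction))),
              n_replicates = dplyr::n(), .groups = "drop")

  pooled <- map(results, function(res) {
    filter(res$absorptions, !.data$started_inside)
  }) |> list_rbind()
  densities <- if (nrow(pooled) > 0) {
    suppressWarnings(entry_distance_density(pooled, bin_um = bin_um))
  } else {
    tibble(group = character(), distance_um = numeric(),
           density = numeric(), type = character())
  }
  list(fractions = fracs, summary = summ, densities = densities,
       initial_locations = pooled |>
         select("group", "start_x", "start_y", "start_distance_um"))
}
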