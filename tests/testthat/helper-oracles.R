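# Independent oracles and small fixture builders used across tests.

# build a track tibble from per-track point lists
make_tracks <- function(..., frame_dt = NULL) {
  specs <- list(...)
  rows <- lapply(specs, function(s) {
    tibble::tibble(track_id = s$id, lineage_id = s$lineage %||% s$id,
                   role = s$role, t_min = s$t, x_um = s$x, y_um = s$y)
  })
  as_tracks(dplyr::bind_rows(rows), frame_dt = frame_dt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force two-sided Fisher p by full enumeration of tables sharing the
# observed margins, using exact factorial probabilities
fisher_enum_oracle <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  prob_of <- function(k) {
    # hypergeometric probability from factorials (independent of dhyper)
    exp(lgamma(r1 + 1) - lgamma(k + 1) - lgamma(r1 - k + 1) +
          lgamma(r2 + 1) - lgamma(c1 - k + 1) - lgamma(r2 - c1 + k + 1) -
          (lgamma(r1 + r2 + 1) - lgamma(c1 + 1) - lgamma(r1 + r2 - c1 + 1)))
  }
  probs <- vapply(ks, prob_of, numeric(1))
  p_obs <- probs[ks == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force semivariance of a set of axial angles sharing one lag bin
semivariance_oracle <- function(angles) {
  n <- length(angles)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- abs(angles[i] - angles[j]) %% 180
      d <- min(d, 180 - d)
      s <- s + d^2
    }
  }
  s / (2 * (n * (n - 1) / 2))
}

# direct solve of the 2-sample ordinary kriging system (3x3)
kriging_2pt_oracle <- function(x1, y1, x2, y2, fit, tx, ty) {
  g <- function(p, q) predict_variogram(fit, sqrt(sum((p - q)^2)))
  s1 <- c(x1, y1); s2 <- c(x2, y2); t <- c(tx, ty)
  A <- rbind(c(g(s1, s1), g(s1, s2), 1),
             c(g(s2, s1), g(s2, s2), 1),
             c(1, 1, 0))
  solve(A, c(g(s1, t), g(s2, t), 1))[1:2]
}

# minimal-image step differences for unwrapping periodic trajectories
torus_delta_steps <- function(d, L) {
  d - L * round(d / L)
}

# two-patch orientation field used for randomness-map tests
patch_field <- function(n = 500, sd_deg = 20, seed = 1) {
  patches <- list(
    list(xmin = 0, xmax = 400, ymin = 0, ymax = 190, axis = 30,
         sd_deg = sd_deg),
    list(xmin = 0, xmax = 400, ymin = 210, ymax = 400, axis = 120,
         sd_deg = sd_deg)
  )
  gen_mitosis_field(n_samples = n, centre = NULL, patches = patches,
                    seed = seed)$field
}
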