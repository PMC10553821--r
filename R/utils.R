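# Shared helpers: axial-angle arithmetic and small numeric utilities.

#' Acute difference between axial angles
#'
#' Axial (undirected) angles live on \[0, 180); the distance between two of
#' them is the acute angle between the corresponding lines,
#' `min(|a - b| mod 180, 180 - |a - b| mod 180)`, which lies in \[0, 90\].
#'
#' @param a,b axial angles in degrees (recycled).
#' @return Numeric vector of acute differences in degrees, in \[0, 90\].
#' @examples
#' axial_diff(10, 170)  # 20, not 160
#' @export
axial_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Reduce angles to the axial range \[0, 180)
#'
#' @param a angles in degrees.
#' @return Angles folded into \[0, 180).
#' @export
axial_mod <- function(a) {
  a %% 180
}

#' Circular mean of axial angles
#'
#' Angles are doubled, averaged as unit vectors, and halved back, the
#' standard construction for orientations defined modulo 180 degrees.
#'
#' @param a axial angles in degrees.
#' @param w optional non-negative weights.
#' @return The mean orientation in \[0, 180), or `NA` if the resultant is
#'   numerically zero (perfectly balanced orientations).
#' @export
axial_mean <- function(a, w = NULL) {
  if (length(a) == 0L) return(NA_real_)
  if (is.null(w)) w <- rep(1, length(a))
  phi <- 2 * a * pi / 180
  c2 <- sum(w * cos(phi)) / sum(w)
  s2 <- sum(w * sin(phi)) / sum(w)
  if (sqrt(c2^2 + s2^2) < 1e-12) return(NA_real_)
  axial_mod(atan2(s2, c2) * 180 / pi / 2)
}

# planar step lengths between consecutive rows of (x, y)
step_lengths <- function(x, y) {
  sqrt(diff(x)^2 + diff(y)^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic child seed derived from a master seed and a label;
# kept below 2^31 so it is a valid R integer seed
child_seed <- function(seed, label) {
  bytes <- utf8ToInt(paste0(label, ":", seed))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  as.integer(h)
}

stop_dd <- function(..., class) {
  rlang::abort(paste0(...), class = c(class, "dermadisp_error"))
}

warn_dd <- function(..., class) {
  rlang::warn(paste0(...), class = c(class, "dermadisp_warning"))
}
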