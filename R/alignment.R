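# Pairwise alignment coefficient for directed vectors and axial
# orientations. The coefficient is the mean dot product over all n^2
# ordered pairs of unit vectors, which equals the squared length of the
# mean (resultant) unit vector: 1 when every vector shares one
# orientation, approaching 0 for isotropy (with a 1/n positive bias for
# finite samples of random angles).

#' Pairwise alignment coefficient
#'
#' Maps each angle to a unit vector (doubling the angle first in axial
#' mode so that orientations 180 degrees apart coincide) and returns the
#' mean dot product over all ordered pairs, i.e. the squared resultant
#' length. Optionally weighted (e.g. by a fibre orientation histogram).
#'
#' @param angles_deg angles in degrees.
#' @param mode `"axial"` for undirected orientations (mitosis axes,
#'   nuclei, fibres), `"directed"` for migration vectors.
#' @param weights optional non-negative weights (normalised internally).
#' @return A `dd_alignment` list: `d` in \[0, 1\], `n`, `mode`.
#' @examples
#' alignment_coefficient(rep(45, 50))$d        # exactly 1
#' alignment_coefficient(c(0, 90))$d           # 0: orthogonal axes cancel
#' @export
alignment_coefficient <- function(angles_deg,
                                  mode = c("axial", "directed"),
                                  weights = NULL) {
  mode <- match.arg(mode)
  n <- length(angles_deg)
  if (n < 2) {
    stop_dd("need at least two vectors", class = "dermadisp_validation_error")
  }
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0)) {
    stop_dd("weights must be non-negative",
            class = "dermadisp_validation_error")
  }
  w <- weights / sum(weights)
  phi <- (if (mode == "axial") 2 else 1) * angles_deg * pi / 180
  d <- sum(w * cos(phi))^2 + sum(w * sin(phi))^2
  structure(list(d = d, n = n, mode = mode), class = "dd_alignment")
}

#' Angles of planar vectors
#'
#' @param dx,dy vector components (y-down image convention).
#' @return Directed angles in degrees in \[0, 360).
#' @export
vectors_to_angles <- function(dx, dy) {
  if (any(dx == 0 & dy == 0)) {
    stop_dd("zero-length vector has no direction",
            class = "dermadisp_validation_error")
  }
  (atan2(dy, dx) * 180 / pi) %% 360
}

#' @export
print.dd_alignment <- function(x, ...) {
  cat(sprintf("Alignment coefficient (%s): d = %.6f (n = %d)\n",
              x$mode, x$d, x$n))
  invisible(x)
}

#' @rdname dermadisp-generics
#' @export
glance.dd_alignment <- function(x, ...) {
  tibble(d = x$d, n = x$n, mode = x$mode)
}
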