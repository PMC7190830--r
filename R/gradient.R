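#' Linear NaCl gradient specification
#'
#' Describes a linear salt gradient on an assay plate as an affine map from
#' arena position (mm) to NaCl concentration (mM). The standard assay pours a
#' 0--100 mM gradient across a 120 mm square plate; animals are released at the
#' gradient midpoint, which corresponds to approximately 50 mM NaCl.
#'
#' @param origin_mm numeric(2); arena point where the axis coordinate is zero.
#' @param axis numeric(2); direction of increasing concentration. Normalized
#'   to unit length. Default is the plate's +y axis.
#' @param c_min,c_max concentrations (mM) at the low and high edge.
#' @param length_mm extent of the gradient along `axis`.
#' @param release_mm axis coordinate where animals are released (defaults to
#'   the midpoint).
#' @return An object of class `gradient_spec`.
#' @export
gradient_spec <- function(origin_mm = c(0, 0), axis = c(0, 1),
                          c_min = 0, c_max = 100, length_mm = 120,
                          release_mm = length_mm / 2) {
  stopifnot(length(origin_mm) == 2, length(axis) == 2, is.finite(axis))
  nrm <- sqrt(sum(axis^2))
  if (nrm <= 0) stop("gradient axis must be a non-zero vector")
  if (c_max < c_min) stop("c_max must be >= c_min")
  if (length_mm <= 0) stop("length_mm must be positive")
  structure(list(origin_mm = as.numeric(origin_mm),
                 axis = as.numeric(axis) / nrm,
                 c_min = c_min, c_max = c_max,
                 length_mm = length_mm, release_mm = release_mm),
            class = "gradient_spec")
}

#' Axis coordinate of arena positions
#'
#' Signed coordinate (mm) of positions along the gradient axis, relative to
#' the gradient origin. Positive values point up-gradient.
#'
#' @param g a [gradient_spec()].
#' @param xy numeric(2) or an n x 2 matrix of positions in mm.
#' @return numeric vector of axis coordinates.
#' @export
axis_coord <- function(g, xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  (xy[, 1] - g$origin_mm[1]) * g$axis[1] + (xy[, 2] - g$origin_mm[2]) * g$axis[2]
}

#' NaCl concentration at arena positions
#'
#' Affine in the axis coordinate and clamped to `[c_min, c_max]` outside the
#' gradient extent.
#'
#' @inheritParams axis_coord
#' @return concentrations in mM.
#' @export
concentration_at <- function(g, xy) {
  s <- axis_coord(g, xy)
  frac <- pmin(pmax(s / g$length_mm, 0), 1)
  g$c_min + (g$c_max - g$c_min) * frac
}

#' Reverse the direction of a gradient
#'
#' Flips the gradient axis in place (origin kept); "up" becomes "down".
#' Useful for antisymmetry checks on navigation indices.
#'
#' @param g a [gradient_spec()].
#' @return a `gradient_spec` with negated axis.
#' @export
reverse_gradient <- function(g) {
  g$axis <- -g$axis
  g
}
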