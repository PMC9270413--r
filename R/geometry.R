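#' Survey-buffer geometry
#'
#' Closed-form geometry of the circular buffers used to extract land-cover
#' composition around survey routes. Snow-track mammal routes are equilateral
#' triangles; the habitat buffer is the circle through the three vertices
#' (the circumcircle), optionally extended outward by a fixed margin. Bird
#' line transects use a rectangular buffer of half-width `buffer` whose area
#' is converted to an equivalent circular radius.
#'
#' @name survey-geometry
NULL

round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Circumradius of an equilateral triangle survey route
#'
#' For an equilateral triangle of side `side` metres the circle through the
#' three vertices has radius `side / sqrt(3)`. For the standard 4-km wildlife
#' triangle this is 2309 m.
#'
#' @param side Triangle side length in metres (positive).
#' @param digits Rounding digits (round-half-up). Use `NULL` for no rounding.
#' @return Radius in metres.
#' @examples
#' triangle_circumradius(4000) # 2309
#' @export
triangle_circumradius <- function(side, digits = 0) {
  stopifnot(is.numeric(side))
  if (any(side <= 0)) stop("`side` must be positive", call. = FALSE)
  r <- side / sqrt(3)
  if (is.null(digits)) r else round_half_up(r, digits)
}

#' Extended survey radius around a triangle route
#'
#' Circumradius of the triangle plus a fixed outward extension; with a 4-km
#' side and a 500-m extension this is the 2809-m buffer used for habitat
#' extraction around mammal routes.
#'
#' @param side Triangle side length in metres (positive).
#' @param extension Outward extension in metres (non-negative).
#' @inheritParams triangle_circumradius
#' @return Radius in metres.
#' @examples
#' extended_survey_radius(4000, 500) # 2809
#' @export
extended_survey_radius <- function(side, extension, digits = 0) {
  stopifnot(is.numeric(extension))
  if (any(extension < 0)) stop("`extension` must be non-negative", call. = FALSE)
  r <- side / sqrt(3) + extension
  if (any(side <= 0)) stop("`side` must be positive", call. = FALSE)
  if (is.null(digits)) r else round_half_up(r, digits)
}

#' Equivalent circular radius of a line-transect buffer
#'
#' A buffer of radius `buffer` around a straight transect of length
#' `transect_length` covers `2 L b + pi b^2` (rectangle plus two half-disks,
#' standard round-cap GIS buffer). The function returns the radius of the
#' circle of equal area, used to place a comparable circular buffer around
#' survey units reported only as points.
#'
#' @param transect_length Transect length L in metres (positive).
#' @param buffer Buffer half-width b in metres (positive).
#' @inheritParams triangle_circumradius
#' @return Radius in metres such that `pi r^2 = 2 L b + pi b^2`.
#' @examples
#' line_buffer_equivalent_radius(5000, 500) # 1357
#' @export
line_buffer_equivalent_radius <- function(transect_length, buffer, digits = 0) {
  stopifnot(is.numeric(transect_length), is.numeric(buffer))
  if (any(transect_length <= 0)) stop("`transect_length` must be positive", call. = FALSE)
  if (any(buffer <= 0)) stop("`buffer` must be positive", call. = FALSE)
  r <- sqrt((2 * transect_length * buffer + pi * buffer^2) / pi)
  if (is.null(digits)) r else round_half_up(r, digits)
}
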