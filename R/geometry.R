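# Stimulus geometry: fragmented isosceles triangles and their exact
# (noise-free Euclidean) completion.
#
# Coordinate convention: base endpoints at (-b/2, 0) and (+b/2, 0), apex in
# the open upper half plane, so "bias toward the base" is a signed negative
# y-deviation. The rotated presentation (base on the vertical axis) maps all
# geometry through a +90 degree rotation. Angles are stored in radians
# internally and exposed in degrees at every interface.

#' Define a fragmented isosceles triangle stimulus
#'
#' A stimulus is an isosceles triangle shown only by its two base corners;
#' the apex is missing and must be inferred. `base_length` is in normalized
#' units (the pixel scale is carried separately); `base_angle_deg` is the
#' interior angle at each base vertex.
#'
#' @param base_length Base length, in normalized units (> 0).
#' @param base_angle_deg Base angle in degrees, strictly between 0 and 90.
#' @param orientation `"x"` (base on the horizontal axis, the default) or
#'   `"y"` (base on the vertical axis, the rotated presentation).
#' @param pixel_scale Pixels per normalized unit (> 0). Purely metadata for
#'   converting to screen coordinates.
#' @return An object of class `tc_triangle_spec`.
#' @export
#' @examples
#' spec <- triangle_spec(base_length = 2, base_angle_deg = 45)
#' true_apex(spec)
#' side_length(spec)
triangle_spec <- function(base_length, base_angle_deg, orientation = c("x", "y"),
                          pixel_scale = 1) {
  check_number(base_length, "base_length", lower = 0)
  check_number(base_angle_deg, "base_angle_deg", lower = 0, upper = 90)
  check_number(pixel_scale, "pixel_scale", lower = 0)
  orientation <- match.arg(orientation)
  structure(
    list(
      base_length = as.double(base_length),
      base_angle_deg = as.double(base_angle_deg),
      theta0 = deg2rad(base_angle_deg),
      orientation = orientation,
      pixel_scale = as.double(pixel_scale)
    ),
    class = "tc_triangle_spec"
  )
}

#' @export
print.tc_triangle_spec <- function(x, ...) {
  cat(sprintf(
    "<tc_triangle_spec> base %g, angle %g deg, side %g, base on %s-axis, %g px/unit\n",
    x$base_length, x$base_angle_deg, side_length(x), x$orientation, x$pixel_scale
  ))
  invisible(x)
}

is_triangle_spec <- function(x) inherits(x, "tc_triangle_spec")

stop_if_not_spec <- function(spec) {
  if (!is_triangle_spec(spec)) abort("`spec` must be created by `triangle_spec()`.")
  invisible(spec)
}

#' Side length of the implied triangle
#'
#' The distance from a base vertex to the true apex,
#' `L = base_length / (2 cos(theta0))`. Side length (not base length) is the
#' canonical size variable of every model in this package.
#'
#' @param spec A [triangle_spec()].
#' @return A single number.
#' @export
side_length <- function(spec) {
  stop_if_not_spec(spec)
  spec$base_length / (2 * cos(spec$theta0))
}

# rotate (x, y) by +90 degrees: (x, y) -> (-y, x)
rotate90 <- function(x, y) list(x = -y, y = x)

# apply the spec's orientation to base-on-x coordinates
orient_xy <- function(spec, x, y) {
  if (spec$orientation == "y") rotate90(x, y) else list(x = x, y = y)
}

#' True (Euclidean) apex of the stimulus
#'
#' Exact completion: with the base centered at the origin, the apex sits at
#' `(0, L sin(theta0))`, i.e. at height `(base_length / 2) tan(theta0)`.
#' For the rotated presentation the point is mapped by a +90 degree rotation.
#'
#' @param spec A [triangle_spec()].
#' @return A one-row tibble with columns `x`, `y`.
#' @export
true_apex <- function(spec) {
  stop_if_not_spec(spec)
  p <- orient_xy(spec, 0, side_length(spec) * sin(spec$theta0))
  tibble::tibble(x = p$x, y = p$y)
}

#' Rotate a stimulus between the two presentations
#'
#' Flips the orientation flag; all downstream geometry is mapped by a +90
#' degree rotation (or its inverse), so model statistics are invariant.
#'
#' @param spec A [triangle_spec()].
#' @return The equivalent `tc_triangle_spec` with the other orientation.
#' @export
rotate_stimulus <- function(spec) {
  stop_if_not_spec(spec)
  spec$orientation <- if (spec$orientation == "x") "y" else "x"
  spec
}

#' Read or write a stimulus definition
#'
#' Stimuli serialize to a small YAML or JSON mapping with keys
#' `base_length`, `base_angle_deg`, `orientation`, `pixel_scale`.
#'
#' @param spec A [triangle_spec()].
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or `.json`).
#' @return `read_triangle_spec()` returns a `tc_triangle_spec`;
#'   `write_triangle_spec()` returns `path` invisibly.
#' @export
write_triangle_spec <- function(spec, path) {
  stop_if_not_spec(spec)
  fields <- spec[c("base_length", "base_angle_deg", "orientation", "pixel_scale")]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(fields, path)
  }
  invisible(path)
}

#' @rdname write_triangle_spec
#' @export
read_triangle_spec <- function(path) {
  fields <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  needed <- c("base_length", "base_angle_deg")
  if (!all(needed %in% names(fields))) {
    abort("Stimulus file must define `base_length` and `base_angle_deg`.")
  }
  triangle_spec(
    base_length = fields$base_length,
    base_angle_deg = fields$base_angle_deg,
    orientation = fields$orientation %||% "x",
    pixel_scale = fields$pixel_scale %||% 1
  )
}

# Interior angles at the base vertices of the triangle formed with an apex
# sample (x, y), base-on-x frame. Vectorized over x, y.
effective_base_angles <- function(x, y, base_length) {
  b2 <- base_length / 2
  list(left = atan2(y, x + b2), right = atan2(y, b2 - x))
}
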