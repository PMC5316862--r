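#' Acquisition geometry of a well's focal-plane stack
#'
#' Describes how a well was imaged: number of focal planes, their spacing
#' along the z axis, lateral image size and the physical size of a pixel.
#' Defaults correspond to the acquisition protocol the pipeline was built
#' for: 28 planes 150 micrometres apart, 2448 x 1920 px frames.
#'
#' @param n_planes Number of focal planes (>= 1).
#' @param plane_spacing Distance between consecutive planes, micrometres (> 0).
#' @param width,height Frame size in pixels (each >= 16).
#' @param pixel_size Lateral size of one pixel, micrometres per pixel (> 0).
#' @param depth_of_first_plane Depth of plane 1, micrometres. Plane \code{i}
#'   sits at \code{depth_of_first_plane + (i - 1) * plane_spacing}, increasing
#'   down into the well.
#'
#' @return An object of class \code{stack_geometry}.
#' @seealso [plane_depths()], [generate_stack()]
#' @export
#' @examples
#' geom <- stack_geometry(n_planes = 5, width = 256, height = 256)
#' plane_depths(geom)
stack_geometry <- function(n_planes = 28, plane_spacing = 150,
                           width = 2448, height = 1920,
                           pixel_size = 1.5, depth_of_first_plane = 0) {
  stopifnot(length(n_planes) == 1, length(plane_spacing) == 1,
            length(width) == 1, length(height) == 1, length(pixel_size) == 1)
  if (n_planes < 1) stop("n_planes must be >= 1")
  if (plane_spacing <= 0) stop("plane_spacing must be > 0")
  if (width < 16 || height < 16) stop("width and height must be >= 16 px")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(n_planes = as.integer(n_planes),
                 plane_spacing = plane_spacing,
                 width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size,
                 depth_of_first_plane = depth_of_first_plane),
            class = "stack_geometry")
}

#' Depths of all focal planes
#'
#' @param geometry A [stack_geometry()].
#' @return Numeric vector of plane depths in micrometres, one per plane.
#' @export
plane_depths <- function(geometry) {
  stopifnot(inherits(geometry, "stack_geometry"))
  geometry$depth_of_first_plane +
    (seq_len(geometry$n_planes) - 1) * geometry$plane_spacing
}

#' @export
print.stack_geometry <- function(x, ...) {
  cat(sprintf("stack_geometry: %d planes, %g um apart, %d x %d px (%g um/px)\n",
              x$n_planes, x$plane_spacing, x$width, x$height, x$pixel_size))
  invisible(x)
}
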