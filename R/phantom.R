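#' Specify one object of a synthetic scene
#'
#' An object is either a hollow sphere (\code{kind = "cyst"}) or one of five
#' planar distractors, each designed to trip one of the exclusion rules
#' applied by [filter_objects()]:
#' \describe{
#'   \item{\code{debris}}{small disc, mean radius at or below the 15 px cut;}
#'   \item{\code{oversize_blob}}{disc with radius above the 200 px cut;}
#'   \item{\code{elongated}}{ellipse with a 2:1 axis ratio, eccentricity
#'     \eqn{\sqrt{1 - 0.25} = 0.866 > 0.75};}
#'   \item{\code{irregular}}{five-lobed shape whose boundary radius varies by
#'     +/- 40 percent, radius CV well above 0.2;}
#'   \item{\code{border_artifact}}{disc crossing the image border, imaged as an
#'     open arc.}
#' }
#' All coordinates and radii are physical (micrometres); \code{x} runs along
#' image columns, \code{y} along rows, \code{z} down into the well.
#'
#' @param center_x,center_y Lateral position, micrometres.
#' @param center_z Depth, micrometres.
#' @param radius Radius, micrometres (> 0). For \code{kind = "cyst"} the
#'   radius in pixels (\code{radius / pixel_size}) must lie in the keep band
#'   (> 15 and <= 200 px) at the widest cross-section; this is checked by
#'   [generate_stack()].
#' @param rim_contrast Fractional darkening of the object's contour relative
#'   to the background, in (0, 1].
#' @param kind One of \code{"cyst"}, \code{"debris"}, \code{"oversize_blob"},
#'   \code{"elongated"}, \code{"irregular"}, \code{"border_artifact"}.
#'
#' @return An object of class \code{sphere_spec}.
#' @export
#' @examples
#' sphere_spec(450, 300, 1500, radius = 60)
sphere_spec <- function(center_x, center_y, center_z, radius,
                        rim_contrast = 0.7,
                        kind = c("cyst", "debris", "oversize_blob",
                                 "elongated", "irregular", "border_artifact")) {
  kind <- match.arg(kind)
  if (radius <= 0) stop("radius must be > 0")
  if (rim_contrast <= 0 || rim_contrast > 1)
    stop("rim_contrast must be in (0, 1]")
  structure(list(center_x = center_x, center_y = center_y,
                 center_z = center_z, radius = radius,
                 rim_contrast = rim_contrast, kind = kind),
            class = "sphere_spec")
}

.as_object_frame <- function(objects) {
  if (length(objects) == 0)
    return(data.frame(center_x = numeric(0), center_y = numeric(0),
                      center_z = numeric(0), radius = numeric(0),
                      rim_contrast = numeric(0), kind = character(0)))
  do.call(rbind, lapply(objects, function(o) {
    stopifnot(inherits(o, "sphere_spec"))
    data.frame(center_x = o$center_x, center_y = o$center_y,
               center_z = o$center_z, radius = o$radius,
               rim_contrast = o$rim_contrast, kind = o$kind)
  }))
}

# Render one object's cross-section into a plane image (in place).
# All rendering is contour-based: brightfield presents object boundaries as
# dark bands; cysts additionally have a lumen brighter than the background.
.render_object <- function(img, row, col, r_px, kind, rim_value,
                           lumen_value, rim_w) {
  nr <- nrow(img); nc <- ncol(img)
  ext <- r_px * switch(kind, elongated = 2, irregular = 1.4, 1)
  r0 <- max(1L, floor(row - ext - rim_w)); r1 <- min(nr, ceiling(row + ext + rim_w))
  c0 <- max(1L, floor(col - ext - rim_w)); c1 <- min(nc, ceiling(col + ext + rim_w))
  if (r0 > r1 || c0 > c1) return(img)
  dy <- outer((r0:r1) - row, rep(1, c1 - c0 + 1))
  dx <- outer(rep(1, r1 - r0 + 1), (c0:c1) - col)
  d <- sqrt(dy^2 + dx^2)
  # effective radial coordinate: contour is the set {reff == r_px}
  reff <- switch(kind,
    elongated = sqrt((dy / 2)^2 + dx^2),
    irregular = d / (1 + 0.4 * cos(5 * atan2(dx, dy))),
    d)
  sub <- img[r0:r1, c0:c1, drop = FALSE]
  if (kind == "cyst") sub[reff < r_px - rim_w / 2] <- lumen_value
  sub[abs(reff - r_px) <= rim_w / 2] <- rim_value
  img[r0:r1, c0:c1] <- sub
  img
}

#' Render a synthetic focal-plane stack with known ground truth
#'
#' Renders spheres and planar distractors into the focal planes of a well and
#' returns both the images and the scene description needed to score recovery.
#' A sphere of radius \eqn{R} centred at depth \eqn{z_0} appears in every
#' plane at depth \eqn{z} with \eqn{|z - z_0| < R}, as a dark ring of
#' cross-section radius \eqn{\sqrt{R^2 - (z - z_0)^2}} (the chord of the
#' sphere at that depth). Distractor kinds model planar junk (dust, bubbles,
#' fibres) and are rendered only in the plane nearest their depth.
#'
#' Appearance model: mid-grey background (128), object contours darkened by
#' \code{rim_contrast}, cyst lumen slightly brighter (160) than background,
#' contour band 3 px wide, Gaussian optical blur, additive Gaussian noise,
#' quantized to 8-bit.
#'
#' @param geometry A [stack_geometry()].
#' @param objects List of [sphere_spec()] objects (possibly empty).
#' @param noise_sd Additive Gaussian noise standard deviation, 8-bit intensity
#'   units (>= 0).
#' @param blur_sigma Gaussian blur sigma in pixels (>= 0).
#' @param seed Integer seed; identical seeds and parameters give bit-identical
#'   output.
#' @param rim_width Contour band width, pixels.
#'
#' @return A list with components \code{stack} (class \code{image_stack}:
#'   \code{planes}, a list of integer-valued matrices in 0..255, and
#'   \code{geometry}) and \code{truth} (class \code{ground_truth}: the
#'   geometry, the object table, \code{expected_cyst_count},
#'   \code{expected_volumes} in cubic micrometres, and the seed).
#' @seealso [generate_distractor_suite()], [quantify_stack()]
#' @export
#' @examples
#' geom <- stack_geometry(n_planes = 3, width = 256, height = 256,
#'                        plane_spacing = 150)
#' sph <- sphere_spec(192, 192, 150, radius = 60)
#' sim <- generate_stack(geom, list(sph), noise_sd = 0, blur_sigma = 0, seed = 1)
#' sim$truth$expected_cyst_count
generate_stack <- function(geometry, objects, noise_sd = 1, blur_sigma = 1.5,
                           seed = 1L, rim_width = 3) {
  stopifnot(inherits(geometry, "stack_geometry"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (blur_sigma < 0) stop("blur_sigma must be >= 0")
  obj <- .as_object_frame(objects)
  w_um <- geometry$width * geometry$pixel_size
  h_um <- geometry$height * geometry$pixel_size
  out_of_bounds <- which(obj$center_x < 0 | obj$center_x > w_um |
                         obj$center_y < 0 | obj$center_y > h_um)
  if (length(out_of_bounds) > 0)
    stop("object(s) outside lateral bounds: index ",
         paste(out_of_bounds, collapse = ", "))
  bad_band <- which(obj$kind == "cyst" &
                    (obj$radius / geometry$pixel_size <= 15 |
                     obj$radius / geometry$pixel_size > 200))
  if (length(bad_band) > 0)
    stop("cyst radius outside keep band (>15, <=200 px): index ",
         paste(bad_band, collapse = ", "))

  bg <- 128; lumen <- 160
  depths <- plane_depths(geometry)
  # planar distractors occupy the single nearest plane (ties -> lower index)
  nearest_plane <- vapply(obj$center_z, function(z)
    which.min(abs(depths - z)), integer(1))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  planes <- vector("list", geometry$n_planes)
  for (p in seq_len(geometry$n_planes)) {
    img <- matrix(bg, geometry$height, geometry$width)
    if (nrow(obj) > 0) {
      for (i in seq_len(nrow(obj))) {
        dz <- depths[p] - obj$center_z[i]
        if (obj$kind[i] == "cyst") {
          if (abs(dz) >= obj$radius[i]) next
          r_px <- sqrt(obj$radius[i]^2 - dz^2) / geometry$pixel_size
        } else {
          if (nearest_plane[i] != p) next
          r_px <- obj$radius[i] / geometry$pixel_size
        }
        img <- .render_object(img,
                              row = obj$center_y[i] / geometry$pixel_size,
                              col = obj$center_x[i] / geometry$pixel_size,
                              r_px = r_px, kind = obj$kind[i],
                              rim_value = round(bg * (1 - obj$rim_contrast[i])),
                              lumen_value = lumen, rim_w = rim_width)
      }
    }
    if (blur_sigma > 0)
      img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                               sigma = blur_sigma))
    if (noise_sd > 0)
      img <- img + rnorm(length(img), 0, noise_sd)
    planes[[p]] <- round(pmin(pmax(img, 0), 255))
  }

  is_cyst <- obj$kind == "cyst"
  truth <- structure(list(geometry = geometry, objects = obj,
                          expected_cyst_count = sum(is_cyst),
                          expected_volumes = (4 / 3) * pi * obj$radius[is_cyst]^3,
                          seed = seed),
                     class = "ground_truth")
  stack <- structure(list(planes = planes, geometry = geometry),
                     class = "image_stack")
  list(stack = stack, truth = truth)
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("image_stack: %d planes of %d x %d px\n",
              length(x$planes), nrow(x$planes[[1]]), ncol(x$planes[[1]])))
  invisible(x)
}

#' Largest rendered cross-section radius of each true cyst, in pixels
#'
#' For a sphere rendered at discrete plane depths, the widest visible
#' cross-section is the chord at the plane nearest the sphere's centre --
#' equal to the true radius only when the centre depth coincides with a
#' plane depth.
#'
#' @param truth A \code{ground_truth} object from [generate_stack()].
#' @return Numeric vector, one value per true cyst (object order).
#' @export
true_cross_section_radii <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  obj <- truth$objects[truth$objects$kind == "cyst", , drop = FALSE]
  depths <- plane_depths(truth$geometry)
  vapply(seq_len(nrow(obj)), function(i) {
    dz <- depths - obj$center_z[i]
    vis <- abs(dz) < obj$radius[i]
    if (!any(vis)) return(NA_real_)
    max(sqrt(obj$radius[i]^2 - dz[vis]^2)) / truth$geometry$pixel_size
  }, numeric(1))
}

#' Generate one distractor per exclusion rule
#'
#' Builds a suite of planar distractors that should all be rejected by the
#' four exclusion rules: a 10 px debris disc, a 210 px oversize blob, a 2:1
#' ellipse (eccentricity 0.866), a five-lobed irregular shape (radius CV
#' about 0.28) and a disc crossing the image border. The oversize blob is
#' placed on the deepest plane by itself (it covers most of a small frame);
#' the remaining four share the plane above. Positions are jittered slightly
#' by \code{seed}.
#'
#' @param geometry A [stack_geometry()]; the frame must be at least 448 px in
#'   both dimensions so the oversize blob fits.
#' @param seed Integer seed for the position jitter.
#' @return List of [sphere_spec()] objects.
#' @export
generate_distractor_suite <- function(geometry, seed = 1L) {
  stopifnot(inherits(geometry, "stack_geometry"))
  px <- geometry$pixel_size
  if (min(geometry$width, geometry$height) < 448)
    stop("geometry too small for distractor suite (need >= 448 px frames)")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  jit <- function() round(rnorm(1, 0, 3))
  depths <- plane_depths(geometry)
  z_blob <- depths[geometry$n_planes]
  z_rest <- depths[max(1L, geometry$n_planes - 1L)]
  w <- geometry$width; h <- geometry$height
  list(
    sphere_spec((0.5 * w + jit()) * px, (0.5 * h + jit()) * px, z_blob,
                radius = 210 * px, kind = "oversize_blob"),
    sphere_spec((0.15 * w + jit()) * px, (0.15 * h + jit()) * px, z_rest,
                radius = 10 * px, kind = "debris"),
    sphere_spec((0.82 * w + jit()) * px, (0.22 * h + jit()) * px, z_rest,
                radius = 40 * px, kind = "elongated"),
    sphere_spec((0.2 * w + jit()) * px, (0.78 * h + jit()) * px, z_rest,
                radius = 40 * px, kind = "irregular"),
    sphere_spec((0.85 * w + jit()) * px, 2 * px, z_rest,
                radius = 40 * px, kind = "border_artifact"))
}
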