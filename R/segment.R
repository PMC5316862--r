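#' Parameters of the per-plane segmentation chain
#'
#' Controls the operator chain applied to each focal plane: artifact masking,
#' Laplacian high-pass, adaptive local-mean threshold, then dilation, hole
#' filling and erosion. The threshold offset default (10 intensity units) is
#' calibrated so that, on 8-bit images with about one grey level of sensor
#' noise, it sits a few standard deviations above the noise floor of the
#' absolute Laplacian response while remaining well below the response of a
#' dark object contour; see the package vignette.
#'
#' @param laplacian_kernel_size Odd kernel size, >= 3. Size 3 is the discrete
#'   Laplacian (centre -4, edge neighbours +1); larger sizes use a
#'   Laplacian-of-Gaussian with sigma = size / 6.
#' @param threshold_window Odd side length of the local-mean window, >= 3.
#' @param threshold_offset Amount by which the response must exceed the local
#'   mean to become foreground (>= 0).
#' @param se_radius Radius of the disc structuring element for dilation and
#'   erosion, pixels.
#' @param dilation_iters,erosion_iters Iterations of each morphological step.
#' @param connectivity Pixel connectivity for labeling, 4 or 8.
#' @param signed_laplacian If FALSE (default) the absolute Laplacian response
#'   is used, so both dark-on-light and light-on-dark edges respond.
#' @param threshold_on Whether the adaptive threshold operates on the
#'   high-pass \code{"response"} (default) or the \code{"raw"} image.
#'
#' @return An object of class \code{segmentation_params}.
#' @export
segmentation_params <- function(laplacian_kernel_size = 3,
                                threshold_window = 51,
                                threshold_offset = 10,
                                se_radius = 3,
                                dilation_iters = 1, erosion_iters = 1,
                                connectivity = 8,
                                signed_laplacian = FALSE,
                                threshold_on = c("response", "raw")) {
  threshold_on <- match.arg(threshold_on)
  if (laplacian_kernel_size < 3 || laplacian_kernel_size %% 2 == 0)
    stop("laplacian_kernel_size must be odd and >= 3")
  if (threshold_window < 3 || threshold_window %% 2 == 0)
    stop("threshold_window must be odd and >= 3")
  if (threshold_offset < 0) stop("threshold_offset must be >= 0")
  if (!(connectivity %in% c(4, 8))) stop("connectivity must be 4 or 8")
  if (se_radius < 1) stop("se_radius must be >= 1")
  structure(list(laplacian_kernel_size = as.integer(laplacian_kernel_size),
                 threshold_window = as.integer(threshold_window),
                 threshold_offset = threshold_offset,
                 se_radius = as.integer(se_radius),
                 dilation_iters = as.integer(dilation_iters),
                 erosion_iters = as.integer(erosion_iters),
                 connectivity = as.integer(connectivity),
                 signed_laplacian = signed_laplacian,
                 threshold_on = threshold_on),
            class = "segmentation_params")
}

#' Convert an RGB plane to grayscale
#'
#' Applies the fixed luminance weights 0.299, 0.587, 0.114 and rounds to
#' integer grey levels. Grayscale input (a plain matrix) is returned
#' unchanged.
#'
#' @param plane A numeric matrix (grayscale) or an H x W x 3 array (RGB).
#' @return A numeric matrix.
#' @export
to_grayscale <- function(plane) {
  if (is.matrix(plane)) return(plane)
  if (length(dim(plane)) == 3 && dim(plane)[3] == 3)
    return(round(0.299 * plane[, , 1] + 0.587 * plane[, , 2] +
                 0.114 * plane[, , 3]))
  stop("unsupported channel count: expected a matrix or an H x W x 3 array")
}

#' Replace artifact pixels by the median of the rest of the plane
#'
#' Pixels under the mask are replaced by the median intensity of the
#' unmasked pixels, so they can never seed foreground downstream. With no
#' mask the plane is returned unchanged. The operation is idempotent.
#'
#' @param plane A numeric matrix.
#' @param artifact_mask A logical or 0/1 matrix of the same dimensions, or
#'   NULL.
#' @return A numeric matrix.
#' @export
mask_artifacts <- function(plane, artifact_mask = NULL) {
  if (is.null(artifact_mask)) return(plane)
  if (!all(dim(artifact_mask) == dim(plane)))
    stop("artifact mask dimensions must match the plane")
  m <- artifact_mask > 0
  if (all(m)) stop("artifact mask covers all pixels; no intensities left")
  plane[m] <- median(plane[!m])
  plane
}

# pad a matrix by symmetric reflection (edge pixel repeated) by h on each side
.pad_symmetric <- function(x, h) {
  nr <- nrow(x); nc <- ncol(x)
  if (h >= nr || h >= nc) stop("padding exceeds image size")
  x[c(h:1, 1:nr, nr:(nr - h + 1)), c(h:1, 1:nc, nc:(nc - h + 1))]
}

.log_kernel <- function(size) {
  sigma <- size / 6
  half <- (size - 1) / 2
  g <- outer((-half):half, (-half):half, function(x, y) {
    (x^2 + y^2 - 2 * sigma^2) / sigma^4 * exp(-(x^2 + y^2) / (2 * sigma^2))
  })
  g - mean(g)  # zero net response to constants
}

#' High-pass Laplacian response of a plane
#'
#' Convolves the plane with a discrete Laplacian (3 x 3: centre -4, edge
#' neighbours +1, corners 0) or, for larger odd kernel sizes, a
#' Laplacian-of-Gaussian. Borders are handled by symmetric reflection. By
#' default the absolute response is returned, so the result is >= 0
#' everywhere and both polarities of edge respond.
#'
#' @param plane A grayscale numeric matrix.
#' @param params A [segmentation_params()].
#' @return A numeric matrix of the same dimensions.
#' @export
laplacian_highpass <- function(plane, params = segmentation_params()) {
  stopifnot(is.matrix(plane), inherits(params, "segmentation_params"))
  k <- params$laplacian_kernel_size
  if (k == 3) {
    nr <- nrow(plane); nc <- ncol(plane)
    up <- plane[c(1, seq_len(nr - 1)), , drop = FALSE]
    dn <- plane[c(seq_len(nr)[-1], nr), , drop = FALSE]
    lf <- plane[, c(1, seq_len(nc - 1)), drop = FALSE]
    rt <- plane[, c(seq_len(nc)[-1], nc), drop = FALSE]
    resp <- up + dn + lf + rt - 4 * plane
  } else {
    h <- (k - 1) / 2
    padded <- .pad_symmetric(plane, h)
    conv <- EBImage::imageData(EBImage::filter2(EBImage::Image(padded),
                                                .log_kernel(k)))
    resp <- conv[(h + 1):(h + nrow(plane)), (h + 1):(h + ncol(plane))]
  }
  if (params$signed_laplacian) resp else abs(resp)
}

# exact local mean over a w x w window with symmetric reflection, via an
# integral image on the padded matrix
.local_mean <- function(x, w) {
  h <- (w - 1) / 2
  nr <- nrow(x); nc <- ncol(x)
  p <- .pad_symmetric(x, h)
  cs <- apply(p, 2, cumsum)
  cs <- rbind(0, cs)
  row_sums <- cs[seq_len(nr) + w, , drop = FALSE] -
    cs[seq_len(nr), , drop = FALSE]
  cs2 <- t(apply(row_sums, 1, cumsum))
  cs2 <- cbind(0, cs2)
  (cs2[, seq_len(nc) + w, drop = FALSE] -
     cs2[, seq_len(nc), drop = FALSE]) / (w * w)
}

#' Adaptive local-mean threshold
#'
#' A pixel becomes foreground iff its response exceeds the mean response over
#' the surrounding \code{threshold_window} x \code{threshold_window} window
#' (borders reflected) by more than \code{threshold_offset}.
#'
#' @param response A numeric matrix (typically from [laplacian_highpass()]).
#' @param params A [segmentation_params()].
#' @return A logical matrix with attribute \code{provenance = "thresholded"}.
#' @export
adaptive_threshold <- function(response, params = segmentation_params()) {
  stopifnot(is.matrix(response), inherits(params, "segmentation_params"))
  w <- params$threshold_window
  if (w > nrow(response) || w > ncol(response))
    stop("threshold_window must not exceed the image dimensions")
  mask <- response > .local_mean(response, w) + params$threshold_offset
  attr(mask, "provenance") <- "thresholded"
  mask
}

#' Fill holes in a binary mask
#'
#' Background components not connected to the image border become foreground.
#' Background connectivity is complementary to the foreground connectivity
#' (8-connected objects have 4-connected holes, and vice versa).
#'
#' @param mask A logical matrix.
#' @param connectivity Foreground connectivity, 4 or 8.
#' @return A logical matrix.
#' @export
fill_holes <- function(mask, connectivity = 8) {
  bg_conn <- if (connectivity == 8) 4 else 8
  bg_labels <- .label_components(!mask, bg_conn)
  if (attr(bg_labels, "n_objects") == 0) return(mask)
  border_labels <- unique(c(bg_labels[1, ], bg_labels[nrow(bg_labels), ],
                            bg_labels[, 1], bg_labels[, ncol(bg_labels)]))
  hole <- !mask & !(bg_labels %in% setdiff(border_labels, 0L))
  out <- mask | matrix(hole, nrow(mask), ncol(mask))
  out
}

#' Morphological refinement of a thresholded mask
#'
#' Applies, in order: dilation with a disc structuring element of radius
#' \code{se_radius} (\code{dilation_iters} times), hole filling, and erosion
#' with the same element (\code{erosion_iters} times). Dilation bridges small
#' gaps in an object's contour so that hole filling can recover its full
#' cross-section; erosion restores the outline to approximately its original
#' extent.
#'
#' @param mask A logical matrix (thresholded stage).
#' @param params A [segmentation_params()].
#' @return A logical matrix with attribute \code{provenance = "refined"}.
#' @export
refine <- function(mask, params = segmentation_params()) {
  stopifnot(is.matrix(mask), inherits(params, "segmentation_params"))
  brush <- EBImage::makeBrush(2 * params$se_radius + 1, shape = "disc")
  m <- EBImage::Image(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  for (i in seq_len(params$dilation_iters)) m <- EBImage::dilate(m, brush)
  m <- EBImage::imageData(m) > 0
  m <- fill_holes(m, params$connectivity)
  m <- EBImage::Image(matrix(as.numeric(m), nrow(m), ncol(m)))
  for (i in seq_len(params$erosion_iters)) m <- EBImage::erode(m, brush)
  out <- EBImage::imageData(m) > 0
  attr(out, "provenance") <- "refined"
  out
}

# Run-based connected-component labeling. Scans rows of the matrix, encodes
# maximal horizontal runs of foreground, and unions runs of consecutive rows
# whose column ranges overlap (with one column of slack under
# 8-connectivity). Labels are assigned 1..n in raster (row-major) order of
# each component's first pixel.
.label_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  v <- t(mask)  # row-major traversal: column j of v is row j of mask
  runs_row <- integer(0); runs_s <- integer(0); runs_e <- integer(0)
  run_list <- vector("list", nr)
  for (i in seq_len(nr)) {
    r <- rle(as.logical(v[, i]))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    run_list[[i]] <- cbind(starts[keep], ends[keep])
  }
  n_runs_per_row <- vapply(run_list, nrow, integer(1))
  total <- sum(n_runs_per_row)
  out <- matrix(0L, nr, nc)
  attr(out, "n_objects") <- 0L
  if (total == 0) return(out)
  run_row <- rep.int(seq_len(nr), n_runs_per_row)
  run_mat <- do.call(rbind, run_list)
  run_s <- run_mat[, 1]; run_e <- run_mat[, 2]

  parent <- seq_len(total)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  slack <- if (connectivity == 8) 1L else 0L
  row_offset <- c(0L, cumsum(n_runs_per_row))
  for (i in seq_len(nr)[-1]) {
    cur <- seq.int(row_offset[i] + 1L, length.out = n_runs_per_row[i])
    prev <- seq.int(row_offset[i - 1L] + 1L, length.out = n_runs_per_row[i - 1L])
    if (length(cur) == 0 || length(prev) == 0) next
    for (a in cur) {
      hits <- prev[run_s[prev] <= run_e[a] + slack &
                   run_e[prev] >= run_s[a] - slack]
      for (b in hits) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(total), find, integer(1))
  # raster order of each component's first pixel = order of its first run
  first_run <- !duplicated(roots)
  labels <- integer(total)
  labels[match(roots, roots[first_run])] <- 0L  # placeholder
  labels <- match(roots, unique(roots))
  for (k in seq_len(total))
    out[run_row[k], run_s[k]:run_e[k]] <- labels[k]
  attr(out, "n_objects") <- max(labels)
  out
}

#' Label connected foreground components
#'
#' Connected components under the configured connectivity, labeled 1..n in
#' raster (row-major) order of each component's first pixel; 0 is background.
#'
#' @param mask A logical matrix (refined stage).
#' @param params A [segmentation_params()].
#' @return An integer matrix of labels with attribute \code{n_objects}.
#' @export
label_objects <- function(mask, params = segmentation_params()) {
  stopifnot(is.matrix(mask), inherits(params, "segmentation_params"))
  .label_components(mask > 0, params$connectivity)
}

#' Segment one focal plane into labeled candidate objects
#'
#' The full per-plane chain: grayscale conversion, artifact masking,
#' Laplacian high-pass, adaptive threshold, morphological refinement,
#' labeling.
#'
#' @param plane A numeric matrix or H x W x 3 RGB array.
#' @param params A [segmentation_params()].
#' @param artifact_mask Optional logical matrix of pixels to neutralize.
#' @return An integer label matrix with attribute \code{n_objects}.
#' @export
segment_plane <- function(plane, params = segmentation_params(),
                          artifact_mask = NULL) {
  g <- mask_artifacts(to_grayscale(plane), artifact_mask)
  x <- if (params$threshold_on == "raw") g else laplacian_highpass(g, params)
  label_objects(refine(adaptive_threshold(x, params), params), params)
}
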