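#' Write an image stack as TIFF
#'
#' Either one multi-page 8-bit grayscale TIFF per well (default) or one
#' single-page file per plane, named \code{well_<id>_z<index>.tif}.
#'
#' @param stack An \code{image_stack}.
#' @param path Output file (multipage) or directory (per_plane).
#' @param layout \code{"multipage"} or \code{"per_plane"}.
#' @param well_id Used in per-plane file names.
#' @return Invisibly, the file path(s) written.
#' @export
write_stack <- function(stack, path, layout = c("multipage", "per_plane"),
                        well_id = "well") {
  layout <- match.arg(layout)
  stopifnot(inherits(stack, "image_stack"))
  scaled <- lapply(stack$planes, function(p) p / 255)
  if (layout == "multipage") {
    tiff::writeTIFF(scaled, path, bits.per.sample = 8)
    invisible(path)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    files <- vapply(seq_along(scaled), function(i) {
      f <- file.path(path, sprintf("well_%s_z%02d.tif", well_id, i))
      tiff::writeTIFF(scaled[[i]], f, bits.per.sample = 8)
      f
    }, character(1))
    invisible(files)
  }
}

#' Read an image stack from TIFF
#'
#' Reads a multi-page TIFF (or a vector of single-page files, in z order)
#' into an \code{image_stack}. RGB pages are converted to grayscale with
#' [to_grayscale()]; intensities are returned on the 0..255 scale.
#'
#' @param path One multi-page TIFF, or a character vector of per-plane
#'   files.
#' @param geometry Optional [stack_geometry()]; when omitted, a geometry is
#'   derived from the images with default spacing and pixel size.
#' @return An \code{image_stack}.
#' @export
read_stack <- function(path, geometry = NULL) {
  pages <- if (length(path) == 1) {
    p <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(p)) list(p) else p
  } else {
    lapply(path, tiff::readTIFF)
  }
  planes <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1:3] * 255 else p <- p * 255
    round(to_grayscale(p))
  })
  if (is.null(geometry))
    geometry <- stack_geometry(n_planes = length(planes),
                               width = ncol(planes[[1]]),
                               height = nrow(planes[[1]]))
  structure(list(planes = planes, geometry = geometry),
            class = "image_stack")
}

#' Write a table as tab-separated values
#'
#' List columns (member tables, footprints, per-well volume vectors) are
#' flattened to comma-separated strings so the output is a plain text table.
#'
#' @param x A data.frame.
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
write_tsv <- function(x, path) {
  flat <- x
  for (nm in names(flat)) {
    if (is.list(flat[[nm]]))
      flat[[nm]] <- vapply(flat[[nm]], function(v) {
        if (is.data.frame(v)) v <- do.call(paste, c(v, sep = ":"))
        paste(format(v, trim = TRUE), collapse = ",")
      }, character(1))
  }
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the ground truth of a synthetic scene
#'
#' @param truth A \code{ground_truth} from [generate_stack()].
#' @param path Output TSV file.
#' @return Invisibly, \code{path}.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  write_tsv(truth$objects, path)
}
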