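#' Per-object shape statistics
#'
#' Computes, for every labeled object in a plane: the centroid (unweighted
#' mean of pixel coordinates), area, the distribution of centroid-to-boundary
#' distances (boundary = object pixels with at least one background
#' 4-neighbour; pixels on the image edge count as boundary), summarized as
#' \code{mean_radius} and its coefficient of variation \code{radius_cv}, and
#' the eccentricity of the second-central-moments equivalent ellipse,
#' \eqn{\sqrt{1 - \lambda_2/\lambda_1}} (0 for a circle). Single-pixel
#' objects get mean_radius, radius_cv and eccentricity 0 by convention.
#'
#' @param labels An integer label matrix (from [label_objects()]).
#' @param plane_index Ordinal of the plane within its stack (recorded in the
#'   output for cross-plane linking).
#' @return A data.frame with one row per object: \code{plane_index},
#'   \code{label}, \code{centroid_row}, \code{centroid_col}, \code{area},
#'   \code{mean_radius}, \code{radius_cv}, \code{eccentricity},
#'   \code{min_row}, \code{min_col}, \code{max_row}, \code{max_col}
#'   (inclusive bounding box) and a list-column \code{footprint} of linear
#'   pixel indices into the label matrix. The matrix dimensions are attached
#'   as attribute \code{dim_image}. An empty mask gives an empty data.frame.
#' @export
compute_features <- function(labels, plane_index = 1L) {
  stopifnot(is.matrix(labels))
  nr <- nrow(labels); nc <- ncol(labels)
  px <- which(labels > 0)
  empty <- data.frame(plane_index = integer(0), label = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      area = integer(0), mean_radius = numeric(0),
                      radius_cv = numeric(0), eccentricity = numeric(0),
                      min_row = integer(0), min_col = integer(0),
                      max_row = integer(0), max_col = integer(0))
  if (length(px) == 0) {
    empty$footprint <- list()
    attr(empty, "dim_image") <- c(nr, nc)
    return(empty)
  }
  lab <- labels[px]
  groups <- split(px, lab)

  rows <- lapply(names(groups), function(lb) {
    p <- groups[[lb]]
    r <- (p - 1L) %% nr + 1L
    cc <- (p - 1L) %/% nr + 1L
    cy <- mean(r); cx <- mean(cc)
    # boundary within the object's bounding box; outside the image counts
    # as background
    r0 <- min(r); r1 <- max(r); c0 <- min(cc); c1 <- max(cc)
    bnr <- r1 - r0 + 3L; bnc <- c1 - c0 + 3L   # 1-px pad
    m <- matrix(FALSE, bnr, bnc)
    m[cbind(r - r0 + 2L, cc - c0 + 2L)] <- TRUE
    ctr <- m[2:(bnr - 1), 2:(bnc - 1), drop = FALSE]
    up <- m[1:(bnr - 2), 2:(bnc - 1), drop = FALSE]
    dn <- m[3:bnr, 2:(bnc - 1), drop = FALSE]
    lf <- m[2:(bnr - 1), 1:(bnc - 2), drop = FALSE]
    rt <- m[2:(bnr - 1), 3:bnc, drop = FALSE]
    bd <- ctr & !(up & dn & lf & rt)
    bp <- which(bd)
    br <- (bp - 1L) %% (bnr - 2L) + r0
    bc <- (bp - 1L) %/% (bnr - 2L) + c0
    rad <- sqrt((br - cy)^2 + (bc - cx)^2)
    mr <- mean(rad)
    cv <- if (mr > 0 && length(rad) > 1) sd(rad) / mr else 0
    mu20 <- mean((r - cy)^2); mu02 <- mean((cc - cx)^2)
    mu11 <- mean((r - cy) * (cc - cx))
    tr2 <- (mu20 + mu02) / 2
    det <- mu20 * mu02 - mu11^2
    disc <- sqrt(max(0, tr2^2 - det))
    l1 <- tr2 + disc; l2 <- tr2 - disc
    ecc <- if (l1 <= 0) 0 else sqrt(max(0, 1 - l2 / l1))
    out <- data.frame(plane_index = as.integer(plane_index),
                      label = as.integer(lb),
                      centroid_row = cy, centroid_col = cx,
                      area = length(p), mean_radius = mr, radius_cv = cv,
                      eccentricity = ecc,
                      min_row = r0, min_col = c0, max_row = r1, max_col = c1)
    out$footprint <- list(p)
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$label), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dim_image") <- c(nr, nc)
  out
}

#' Exclusion thresholds for candidate objects
#'
#' Defaults implement the four rules used to discard debris and artifacts:
#' objects are removed if the mean radius is at or below 15 px, above 200 px,
#' if the radius coefficient of variation exceeds 0.2, or if the eccentricity
#' exceeds 0.75. Note the asymmetry of the radius bounds: exactly 15 px is
#' excluded, exactly 200 px is kept; CV exactly 0.2 and eccentricity exactly
#' 0.75 are kept.
#'
#' @param min_mean_radius Exclusive lower bound on mean radius, pixels.
#' @param max_mean_radius Inclusive upper bound on mean radius, pixels.
#' @param max_radius_cv Inclusive upper bound on the radius CV.
#' @param max_eccentricity Inclusive upper bound on eccentricity.
#' @return An object of class \code{filter_thresholds}.
#' @export
filter_thresholds <- function(min_mean_radius = 15, max_mean_radius = 200,
                              max_radius_cv = 0.2, max_eccentricity = 0.75) {
  if (!(min_mean_radius > 0 && min_mean_radius < max_mean_radius))
    stop("need 0 < min_mean_radius < max_mean_radius")
  structure(list(min_mean_radius = min_mean_radius,
                 max_mean_radius = max_mean_radius,
                 max_radius_cv = max_radius_cv,
                 max_eccentricity = max_eccentricity),
            class = "filter_thresholds")
}

#' Apply the four exclusion rules
#'
#' An object is kept iff \code{mean_radius > min_mean_radius},
#' \code{mean_radius <= max_mean_radius}, \code{radius_cv <= max_radius_cv}
#' and \code{eccentricity <= max_eccentricity}. Rejected objects carry the
#' first violated rule (checked in the order radius-min, radius-max, CV,
#' eccentricity) as \code{reject_reason}; the outcome itself does not depend
#' on that order. Kept and rejected partition the input.
#'
#' @param objects A data.frame of object features (from [compute_features()]).
#' @param thresholds A [filter_thresholds()].
#' @return A list with data.frames \code{kept} and \code{rejected} (the
#'   latter with an extra \code{reject_reason} column, one of
#'   \code{"radius_min"}, \code{"radius_max"}, \code{"radius_cv"},
#'   \code{"eccentricity"}).
#' @export
filter_objects <- function(objects, thresholds = filter_thresholds()) {
  stopifnot(is.data.frame(objects), inherits(thresholds, "filter_thresholds"))
  if (nrow(objects) == 0) {
    rejected <- objects
    rejected$reject_reason <- character(0)
    return(list(kept = objects, rejected = rejected))
  }
  too_small <- objects$mean_radius <= thresholds$min_mean_radius
  too_big <- objects$mean_radius > thresholds$max_mean_radius
  too_variable <- objects$radius_cv > thresholds$max_radius_cv
  too_eccentric <- objects$eccentricity > thresholds$max_eccentricity
  keep <- !(too_small | too_big | too_variable | too_eccentric)
  reason <- rep(NA_character_, nrow(objects))
  reason[too_eccentric] <- "eccentricity"
  reason[too_variable] <- "radius_cv"
  reason[too_big] <- "radius_max"
  reason[too_small] <- "radius_min"
  rejected <- objects[!keep, , drop = FALSE]
  rejected$reject_reason <- reason[!keep]
  dim_image <- attr(objects, "dim_image")
  kept <- objects[keep, , drop = FALSE]
  rownames(kept) <- rownames(rejected) <- NULL
  attr(kept, "dim_image") <- dim_image
  attr(rejected, "dim_image") <- dim_image
  list(kept = kept, rejected = rejected)
}
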