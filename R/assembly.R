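#' Deduplicate objects across the z axis into cysts
#'
#' A cyst larger than the plane spacing appears in several consecutive focal
#' planes; to count it once, objects in adjacent planes that occupy the same
#' x/y position are treated as the same cyst. Two objects in adjacent planes
#' are linked when their pixel footprints overlap by at least one pixel
#' (\code{mode = "overlap"}, default) or when either centroid falls inside
#' the other's footprint (\code{mode = "centroid"}). Cysts are the connected
#' components of this adjacent-plane graph; objects in non-adjacent planes
#' are never linked directly, so a one-plane gap splits a cyst in two.
#'
#' @param kept A data.frame of filtered object features (the \code{kept}
#'   element of [filter_objects()]), with \code{plane_index}, \code{label}
#'   and \code{footprint} columns and a \code{dim_image} attribute. Footprints
#'   of distinct labels within one plane are disjoint, as produced by a label
#'   mask.
#' @param mode Link test, \code{"overlap"} or \code{"centroid"}.
#' @return A data.frame with one row per cyst: \code{cyst_id},
#'   \code{n_members}, \code{representative_radius} (mean radius of the
#'   largest-area member; ties broken by lowest plane index),
#'   \code{centroid_row}, \code{centroid_col} (of that member),
#'   \code{first_plane}, \code{last_plane}, and a list-column \code{members}
#'   holding each cyst's member feature rows.
#' @export
link_across_planes <- function(kept, mode = c("overlap", "centroid")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(kept))
  n <- nrow(kept)
  if (n == 0) {
    out <- data.frame(cyst_id = integer(0), n_members = integer(0),
                      representative_radius = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      first_plane = integer(0), last_plane = integer(0))
    out$members <- list()
    return(out)
  }
  if (anyDuplicated(kept[, c("plane_index", "label")]))
    stop("duplicate (plane_index, label) keys")
  dims <- attr(kept, "dim_image")
  if (is.null(dims))
    dims <- c(max(kept$max_row), max(kept$max_col))
  npx <- prod(dims)

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union2 <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }

  planes <- sort(unique(kept$plane_index))
  idx_by_plane <- split(seq_len(n), kept$plane_index)
  for (p in planes) {
    q <- as.character(p + 1L)
    if (is.null(idx_by_plane[[q]])) next
    a_idx <- idx_by_plane[[as.character(p)]]
    b_idx <- idx_by_plane[[q]]
    if (mode == "overlap") {
      va <- integer(npx); vb <- integer(npx)
      for (i in a_idx) va[kept$footprint[[i]]] <- i
      for (j in b_idx) vb[kept$footprint[[j]]] <- j
      both <- va > 0L & vb > 0L
      if (any(both)) {
        pairs <- unique(cbind(va[both], vb[both]))
        for (r in seq_len(nrow(pairs))) union2(pairs[r, 1], pairs[r, 2])
      }
    } else {
      for (i in a_idx) for (j in b_idx) {
        ci <- (round(kept$centroid_col[i]) - 1L) * dims[1] +
          round(kept$centroid_row[i])
        cj <- (round(kept$centroid_col[j]) - 1L) * dims[1] +
          round(kept$centroid_row[j])
        if (ci %in% kept$footprint[[j]] || cj %in% kept$footprint[[i]])
          union2(i, j)
      }
    }
  }

  roots <- vapply(seq_len(n), find, integer(1))
  ord <- order(kept$plane_index, kept$label)
  comp_ids <- unique(roots[ord])
  rows <- lapply(seq_along(comp_ids), function(k) {
    members_idx <- which(roots == comp_ids[k])
    mem <- kept[members_idx, , drop = FALSE]
    mem <- mem[order(mem$plane_index, mem$label), , drop = FALSE]
    big <- which(mem$area == max(mem$area))[1]  # ties: lowest plane first
    out <- data.frame(cyst_id = k, n_members = nrow(mem),
                      representative_radius = mem$mean_radius[big],
                      centroid_row = mem$centroid_row[big],
                      centroid_col = mem$centroid_col[big],
                      first_plane = min(mem$plane_index),
                      last_plane = max(mem$plane_index))
    out$members <- list(mem[, setdiff(names(mem), "footprint")])
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Estimate spherical cyst volumes
#'
#' Each cyst is assumed spherical; its volume is \eqn{\frac{4}{3}\pi r^3}
#' with \eqn{r} the mean radius of the largest (largest-area) member object.
#' Volumes are reported both in cubic pixels and, via
#' \code{pixel_size^3}, in cubic micrometres.
#'
#' @param cysts A data.frame from [link_across_planes()].
#' @param pixel_size Micrometres per pixel (> 0).
#' @return The input with columns \code{volume_px3} and \code{volume_um3}
#'   added.
#' @export
#' @examples
#' # a 1 px radius gives 4*pi/3 cubic pixels
#' cyst <- data.frame(cyst_id = 1, representative_radius = 1)
#' estimate_volume(cyst, pixel_size = 1)$volume_px3
estimate_volume <- function(cysts, pixel_size) {
  stopifnot(is.data.frame(cysts))
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  r <- cysts$representative_radius
  cysts$volume_px3 <- (4 / 3) * pi * r^3
  cysts$volume_um3 <- cysts$volume_px3 * pixel_size^3
  cysts
}

# stable fingerprint of segmentation + filter settings, so summaries record
# which parameterization produced them
.params_fingerprint <- function(params, thresholds) {
  fmt <- function(x) paste(names(x), vapply(x, format, character(1)),
                           sep = "=", collapse = ";")
  paste0(if (!is.null(params)) fmt(unclass(params)) else "",
         "|", if (!is.null(thresholds)) fmt(unclass(thresholds)) else "")
}

#' Summarize the cysts of one well
#'
#' @param cysts A data.frame from [estimate_volume()] (volumes populated),
#'   possibly with zero rows.
#' @param well_id Well identifier.
#' @param params,thresholds The [segmentation_params()] and
#'   [filter_thresholds()] used, recorded as a parameter fingerprint.
#' @return A one-row data.frame: \code{well_id}, \code{cyst_count},
#'   \code{total_volume_um3}, \code{mean_volume_um3} (NA when the well has
#'   no cysts), \code{params_fingerprint}, plus a list-column
#'   \code{volumes_um3}.
#' @export
summarize_well <- function(cysts, well_id, params = NULL, thresholds = NULL) {
  stopifnot(is.data.frame(cysts))
  vols <- if (nrow(cysts) > 0) cysts$volume_um3 else numeric(0)
  out <- data.frame(well_id = well_id, cyst_count = length(vols),
                    total_volume_um3 = sum(vols),
                    mean_volume_um3 = if (length(vols) > 0) mean(vols)
                                      else NA_real_,
                    params_fingerprint = .params_fingerprint(params,
                                                             thresholds))
  out$volumes_um3 <- list(vols)
  out
}

#' Summarize wells by treatment group
#'
#' Per-group mean and standard error (s.e.m. = sd / sqrt(n), NA for
#' single-well groups) of cyst count and total volume, plus each group's
#' mean cyst count as a percentage of the control group's.
#'
#' @param wells A data.frame of well summaries (rows from
#'   [summarize_well()]).
#' @param design A data.frame mapping \code{well_id} to \code{group_id};
#'   every well must be assigned.
#' @param control_group The \code{group_id} serving as the 100 percent
#'   reference.
#' @return A data.frame with one row per group: \code{group_id},
#'   \code{n_wells}, \code{mean_count}, \code{sem_count},
#'   \code{mean_total_volume_um3}, \code{sem_total_volume_um3},
#'   \code{percent_of_control}.
#' @export
summarize_groups <- function(wells, design, control_group) {
  stopifnot(is.data.frame(wells), is.data.frame(design),
            all(c("well_id", "group_id") %in% names(design)))
  grp <- design$group_id[match(wells$well_id, design$well_id)]
  if (anyNA(grp)) stop("every well must be assigned to a group")
  if (!(control_group %in% grp)) stop("control group empty")
  groups <- unique(grp)
  sem <- function(x) if (length(x) >= 2) sd(x) / sqrt(length(x)) else NA_real_
  out <- do.call(rbind, lapply(groups, function(g) {
    sel <- grp == g
    data.frame(group_id = g, n_wells = sum(sel),
               mean_count = mean(wells$cyst_count[sel]),
               sem_count = sem(wells$cyst_count[sel]),
               mean_total_volume_um3 = mean(wells$total_volume_um3[sel]),
               sem_total_volume_um3 = sem(wells$total_volume_um3[sel]))
  }))
  ctrl_mean <- out$mean_count[out$group_id == control_group]
  out$percent_of_control <- 100 * out$mean_count / ctrl_mean
  rownames(out) <- NULL
  out
}

#' Quantify one well's image stack end to end
#'
#' Runs the full pipeline on every plane of a stack -- segmentation, feature
#' extraction, exclusion filtering, z-axis deduplication, spherical volume
#' estimation -- and summarizes the well.
#'
#' @param stack An \code{image_stack} (from [generate_stack()] or
#'   [read_stack()]).
#' @param params A [segmentation_params()].
#' @param thresholds A [filter_thresholds()].
#' @param well_id Well identifier for the summary.
#' @param link_mode Passed to [link_across_planes()].
#' @param artifact_masks Optional list of per-plane artifact masks.
#' @return A list: \code{features} (all objects), \code{kept},
#'   \code{rejected}, \code{cysts} (with volumes) and \code{well} (one-row
#'   summary).
#' @export
#' @examples
#' geom <- stack_geometry(n_planes = 3, width = 480, height = 480,
#'                        pixel_size = 1.5)
#' sim <- generate_stack(geom, list(sphere_spec(360, 360, 150, radius = 60)),
#'                       seed = 7)
#' res <- quantify_stack(sim$stack, well_id = "demo")
#' res$well$cyst_count
quantify_stack <- function(stack, params = segmentation_params(),
                           thresholds = filter_thresholds(),
                           well_id = "well", link_mode = "overlap",
                           artifact_masks = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  feats <- lapply(seq_along(stack$planes), function(p) {
    labels <- segment_plane(stack$planes[[p]], params,
                            if (!is.null(artifact_masks))
                              artifact_masks[[p]] else NULL)
    compute_features(labels, plane_index = p)
  })
  all_feats <- do.call(rbind, feats)
  attr(all_feats, "dim_image") <- attr(feats[[1]], "dim_image")
  split_feats <- filter_objects(all_feats, thresholds)
  cysts <- link_across_planes(split_feats$kept, mode = link_mode)
  cysts <- estimate_volume(cysts, stack$geometry$pixel_size)
  well <- summarize_well(cysts, well_id, params, thresholds)
  list(features = all_feats, kept = split_feats$kept,
       rejected = split_feats$rejected, cysts = cysts, well = well)
}
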