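# strip non-dim attributes so masks can be compared bit-for-bit
bare <- function(m) matrix(as.vector(m), nrow(m), ncol(m))

# Independent reference implementations and fixture builders. These are
# deliberately naive (per-pixel loops, BFS) so they share no code path with
# the package.

# brute-force adaptive threshold: per-pixel window mean over a symmetric
# reflection padding
oracle_adaptive_threshold <- function(response, window, offset) {
  h <- (window - 1) / 2
  nr <- nrow(response); nc <- ncol(response)
  p <- response[c(h:1, 1:nr, nr:(nr - h + 1)), c(h:1, 1:nc, nc:(nc - h + 1))]
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    out[i, j] <- response[i, j] >
      mean(p[i:(i + window - 1), j:(j + window - 1)]) + offset
  }
  out
}

# BFS connected-component labeling, labels in raster (row-major) order
oracle_label_bfs <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbr <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  next_label <- 0L
  for (i0 in seq_len(nr)) for (j0 in seq_len(nc)) {   # raster scan
    if (!mask[i0, j0] || lab[i0, j0] > 0) next
    next_label <- next_label + 1L
    queue <- list(c(i0, j0)); lab[i0, j0] <- next_label
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbr))) {
        i <- cur[1] + nbr[k, 1]; j <- cur[2] + nbr[k, 2]
        if (i >= 1 && i <= nr && j >= 1 && j <= nc &&
            mask[i, j] && lab[i, j] == 0) {
          lab[i, j] <- next_label
          queue[[length(queue) + 1]] <- c(i, j)
        }
      }
    }
  }
  attr(lab, "n_objects") <- next_label
  lab
}

# flood fill background from the border; unreached background pixels are holes
oracle_fill_holes <- function(mask, connectivity = 8) {
  bg_conn <- if (connectivity == 8) 4 else 8
  bg <- oracle_label_bfs(!mask, bg_conn)
  border <- setdiff(unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)])),
                    0L)
  mask | (!mask & !(matrix(bg %in% border, nrow(mask), ncol(mask))))
}

# independently written four-predicate exclusion check
oracle_keep <- function(mean_radius, radius_cv, eccentricity,
                        rmin = 15, rmax = 200, cvmax = 0.2, emax = 0.75) {
  if (mean_radius <= rmin) return(FALSE)
  if (mean_radius > rmax) return(FALSE)
  if (radius_cv > cvmax) return(FALSE)
  if (eccentricity > emax) return(FALSE)
  TRUE
}

# brute-force cyst assembly: build the explicit adjacent-plane overlap graph
# and take its connected components by repeated expansion
oracle_link_components <- function(kept) {
  n <- nrow(kept)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(kept$plane_index[i] - kept$plane_index[j]) == 1 &&
        length(intersect(kept$footprint[[i]], kept$footprint[[j]])) >= 1)
      adj[i, j] <- TRUE
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        new <- min(comp[i], comp[j])
        comp[comp == comp[i] | comp == comp[j]] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # normalize to partition sizes for comparison
  sort(as.integer(table(comp)))
}

# rasterized shapes on a background matrix
raster_disc <- function(r, pad = 5) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  d <- sqrt(outer(seq_len(n) - ctr, seq_len(n) - ctr, function(a, b) a^2 + b^2))
  d <= r
}

raster_ellipse <- function(a, b, pad = 5) {
  # semi-axis a along rows, b along columns
  nr <- 2 * (a + pad) + 1; nc <- 2 * (b + pad) + 1
  cy <- a + pad + 1; cx <- b + pad + 1
  outer(seq_len(nr) - cy, seq_len(nc) - cx,
        function(y, x) (y / a)^2 + (x / b)^2) <= 1
}

# features of a plain logical mask, via the package's own labeling
mask_features <- function(mask, params = segmentation_params()) {
  compute_features(label_objects(mask, params), plane_index = 1L)
}

# a small well-separated multi-sphere scene used by several tests
demo_scene <- function(n_planes = 6, width = 612, height = 480,
                       radii_um = c(60, 90), seed = 3) {
  geom <- stack_geometry(n_planes = n_planes, width = width, height = height,
                         pixel_size = 1.5)
  depths <- plane_depths(geom)
  pos <- list(c(400, 300), c(150, 150), c(480, 120), c(160, 430),
              c(700, 500))[seq_along(radii_um)]
  objs <- mapply(function(r, p, z) sphere_spec(p[1], p[2], z, radius = r),
                 radii_um, pos,
                 depths[1 + (seq_along(radii_um) %% (n_planes - 1))],
                 SIMPLIFY = FALSE)
  generate_stack(geom, objs, seed = seed)
}

# build a feature row with an explicit footprint on a dims[1] x dims[2] grid
fake_obj <- function(plane, label, footprint, dims = c(20, 20),
                     area = length(footprint), mean_radius = 20,
                     centroid = c(5, 5)) {
  out <- data.frame(plane_index = as.integer(plane), label = as.integer(label),
                    centroid_row = centroid[1], centroid_col = centroid[2],
                    area = as.integer(area), mean_radius = mean_radius,
                    radius_cv = 0.05, eccentricity = 0.1,
                    min_row = 1L, min_col = 1L,
                    max_row = dims[1], max_col = dims[2])
  out$footprint <- list(as.integer(footprint))
  out
}

bind_objs <- function(..., dims = c(20, 20)) {
  out <- do.call(rbind, list(...))
  attr(out, "dim_image") <- dims
  out
}
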