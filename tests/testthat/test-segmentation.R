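test_that("grayscale conversion uses fixed luminance weights", {
  grey <- array(77 / 1, dim = c(4, 5, 3))
  expect_equal(to_grayscale(grey), matrix(77, 4, 5))
  red <- array(0, dim = c(4, 5, 3)); red[, , 1] <- 255
  expect_equal(to_grayscale(red), matrix(76, 4, 5))  # round(0.299 * 255)
  m <- matrix(1:20, 4, 5)
  expect_identical(to_grayscale(m), m)
  expect_error(to_grayscale(array(0, dim = c(4, 5, 2))), "channel")
})

test_that("artifact masking replaces masked pixels by the unmasked median", {
  plane <- matrix(50, 10, 10)
  plane[3, 3:6] <- 240  # bright scratch
  mask <- matrix(FALSE, 10, 10); mask[3, 3:6] <- TRUE
  out <- mask_artifacts(plane, mask)
  expect_true(all(out == 50))
  expect_identical(mask_artifacts(plane, NULL), plane)
  expect_error(mask_artifacts(plane, matrix(FALSE, 5, 5)), "dimensions")
  expect_error(mask_artifacts(plane, matrix(TRUE, 10, 10)), "all pixels")
  # idempotence
  expect_identical(mask_artifacts(out, mask), out)
})

test_that("Laplacian response annihilates constants and affine ramps", {
  p <- segmentation_params()
  expect_true(all(laplacian_highpass(matrix(77, 12, 12), p) == 0))
  ramp <- outer(1:12, 1:12, function(i, j) 3 * i + 5 * j)
  resp <- laplacian_highpass(ramp, p)
  expect_true(all(resp[2:11, 2:11] == 0))  # interior of an affine image
})

test_that("Laplacian of an impulse matches direct convolution", {
  img <- matrix(0, 11, 11); img[6, 6] <- 10
  resp <- laplacian_highpass(img, segmentation_params())
  expect_equal(resp[6, 6], 40)   # |-4h|
  expect_equal(resp[5, 6], 10)   # |+h| at the 4-neighbours
  expect_equal(resp[6, 7], 10)
  expect_equal(resp[5, 5], 0)    # corners are not in the stencil
  expect_error(segmentation_params(laplacian_kernel_size = 4), "odd")
})

test_that("signed mode keeps the response sign", {
  img <- matrix(0, 7, 7); img[4, 4] <- 10
  resp <- laplacian_highpass(img,
    segmentation_params(signed_laplacian = TRUE))
  expect_equal(resp[4, 4], -40)
})

test_that("larger kernels (Laplacian of Gaussian) still annihilate constants", {
  p <- segmentation_params(laplacian_kernel_size = 9)
  resp <- laplacian_highpass(matrix(100, 32, 32), p)
  expect_true(all(abs(resp) < 1e-8))
})

test_that("adaptive threshold marks pixels above local mean plus offset", {
  p <- segmentation_params(threshold_window = 9, threshold_offset = 2)
  expect_true(all(!adaptive_threshold(matrix(5, 20, 20), p)))
  # offset 0 on a block image: exactly the pixels above their local mean
  resp <- matrix(0, 9, 9); resp[4:6, 4:6] <- 100
  p0 <- segmentation_params(threshold_window = 9, threshold_offset = 0)
  got <- adaptive_threshold(resp, p0)
  expect_identical(bare(got), bare(oracle_adaptive_threshold(resp, 9, 0)))
  expect_error(adaptive_threshold(matrix(0, 8, 8),
    segmentation_params(threshold_window = 9)), "exceed")
})

test_that("adaptive threshold agrees bit-exactly with the brute-force oracle", {
  set.seed(11)
  for (i in 1:20) {
    nr <- sample(12:40, 1); nc <- sample(12:40, 1)
    img <- matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc)
    w <- sample(c(3, 5, 7, 9, 11), 1)
    off <- sample(c(0, 1, 2, 5, 10), 1)
    p <- segmentation_params(threshold_window = w, threshold_offset = off)
    expect_identical(bare(adaptive_threshold(img, p)),
                     bare(oracle_adaptive_threshold(img, w, off)))
  }
})

test_that("increasing the offset never grows the foreground", {
  set.seed(12)
  img <- matrix(sample(0:255, 40 * 40, replace = TRUE), 40, 40)
  resp <- laplacian_highpass(img, segmentation_params())
  counts <- vapply(c(0, 2, 5, 10, 20, 50), function(off)
    sum(adaptive_threshold(resp,
      segmentation_params(threshold_window = 9, threshold_offset = off))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("hole filling fills enclosed background only", {
  ring <- raster_disc(8) & !raster_disc(4, pad = 9)
  filled <- fill_holes(ring, connectivity = 8)
  expect_identical(bare(filled), bare(raster_disc(8)))
  expect_identical(bare(fill_holes(ring, 8)), bare(oracle_fill_holes(ring, 8)))
  # EBImage's fillHull agrees on this fixture (independent cross-check)
  eb <- EBImage::imageData(EBImage::fillHull(
    EBImage::Image(matrix(as.numeric(ring), nrow(ring), ncol(ring))))) > 0
  expect_identical(bare(filled), bare(eb))
  # open shapes are untouched
  arc <- ring; arc[1:nrow(arc), 9] <- FALSE
  expect_lt(sum(fill_holes(arc, 8)), sum(filled))
})

test_that("refinement closes a ring into a disc and preserves a solid disc", {
  p <- segmentation_params()
  expect_true(all(!refine(matrix(FALSE, 30, 30), p)))
  ring <- raster_disc(10, pad = 8) & !raster_disc(7, pad = 11)
  out <- refine(ring, p)
  # hole filled: centre pixel is foreground
  ctr <- (nrow(ring) + 1) / 2
  expect_true(out[ctr, ctr])
  # outer radius preserved within +/- se_radius
  f <- mask_features(out)
  expect_lt(abs(f$mean_radius - 10), p$se_radius + 0.5)
  # closing (dilate then erode) of a convex disc is the disc itself
  disc <- raster_disc(9, pad = 8)
  expect_identical(bare(refine(disc, p)), bare(disc))
})

test_that("labeling matches the BFS oracle, including connectivity semantics", {
  diag2 <- matrix(FALSE, 6, 6); diag2[2, 2] <- TRUE; diag2[3, 3] <- TRUE
  p8 <- segmentation_params(connectivity = 8)
  p4 <- segmentation_params(connectivity = 4)
  expect_identical(attr(label_objects(diag2, p8), "n_objects"), 1L)
  expect_identical(attr(label_objects(diag2, p4), "n_objects"), 2L)
  expect_identical(attr(label_objects(matrix(FALSE, 5, 5), p8), "n_objects"),
                   0L)
  two <- matrix(FALSE, 12, 24)
  two[3:6, 3:6] <- TRUE; two[3:6, 12:15] <- TRUE
  expect_identical(attr(label_objects(two, p8), "n_objects"), 2L)
  set.seed(13)
  for (i in 1:15) {
    m <- matrix(runif(30 * 30) < 0.4, 30, 30)
    for (conn in c(4, 8)) {
      p <- segmentation_params(connectivity = conn)
      got <- label_objects(m, p)
      ref <- oracle_label_bfs(m, conn)
      expect_identical(bare(got), bare(ref))
    }
    # EBImage bwlabel is 4-connected: cross-check object counts
    eb <- EBImage::bwlabel(matrix(as.numeric(m), 30, 30))
    expect_identical(attr(label_objects(m, segmentation_params(connectivity = 4)),
                          "n_objects"), as.integer(max(eb)))
  }
})

test_that("labels come in raster order of each component's first pixel", {
  m <- matrix(FALSE, 10, 10)
  m[8, 2] <- TRUE          # later in raster order
  m[2, 5:6] <- TRUE        # first
  m[5, 9] <- TRUE          # second
  lab <- label_objects(m, segmentation_params())
  expect_identical(lab[2, 5], 1L)
  expect_identical(lab[5, 9], 2L)
  expect_identical(lab[8, 2], 3L)
})

test_that("segmentation is equivariant to translation away from borders", {
  geom_img <- matrix(0, 64, 64)
  geom_img[20:28, 20:28] <- 100
  shifted <- matrix(0, 64, 64)
  shifted[25:33, 30:38] <- 100
  p <- segmentation_params(threshold_window = 9, threshold_offset = 2)
  seg1 <- segment_plane(geom_img, p)
  seg2 <- segment_plane(shifted, p)
  expect_identical(bare(seg1[15:33, 15:33]), bare(seg2[20:38, 25:43]))
})
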