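test_that("one object gives one single-member cyst", {
  k <- bind_objs(fake_obj(1, 1, 1:10))
  cysts <- link_across_planes(k)
  expect_equal(nrow(cysts), 1)
  expect_equal(cysts$n_members, 1)
})

test_that("co-located objects two planes apart are NOT linked (gap case)", {
  k <- bind_objs(fake_obj(3, 1, 50:80), fake_obj(5, 1, 50:80))
  cysts <- link_across_planes(k)
  expect_equal(nrow(cysts), 2)
})

test_that("a chain of co-located objects in planes 1-4 is one cyst", {
  k <- bind_objs(fake_obj(1, 1, 50:80), fake_obj(2, 1, 60:90),
                 fake_obj(3, 1, 55:85), fake_obj(4, 1, 50:70))
  cysts <- link_across_planes(k)
  expect_equal(nrow(cysts), 1)
  expect_equal(cysts$n_members, 4)
})

test_that("adjacent planes require >= 1 px footprint overlap", {
  k <- bind_objs(fake_obj(1, 1, 1:20), fake_obj(2, 1, 21:40))
  expect_equal(nrow(link_across_planes(k)), 2)   # disjoint -> two cysts
  k2 <- bind_objs(fake_obj(1, 1, 1:20), fake_obj(2, 1, 20:40))
  expect_equal(nrow(link_across_planes(k2)), 1)  # single shared pixel links
})

test_that("one object overlapping two in the next plane merges all three", {
  k <- bind_objs(fake_obj(1, 1, 1:100), fake_obj(2, 1, 10:20),
                 fake_obj(2, 2, 80:90))
  cysts <- link_across_planes(k)
  expect_equal(nrow(cysts), 1)
  expect_equal(cysts$n_members, 3)
})

test_that("duplicate (plane, label) keys are rejected", {
  k <- bind_objs(fake_obj(1, 1, 1:10), fake_obj(1, 1, 20:30))
  expect_error(link_across_planes(k), "duplicate")
})

test_that("linking is invariant to plane processing order", {
  k_fwd <- bind_objs(fake_obj(1, 1, 50:80), fake_obj(2, 1, 60:90),
                     fake_obj(4, 1, 10:30), fake_obj(5, 1, 10:30))
  k_rev <- k_fwd[rev(seq_len(nrow(k_fwd))), ]
  attr(k_rev, "dim_image") <- attr(k_fwd, "dim_image")
  a <- link_across_planes(k_fwd)
  b <- link_across_planes(k_rev)
  expect_equal(nrow(a), nrow(b))
  expect_setequal(a$n_members, b$n_members)
})

test_that("every kept object belongs to exactly one cyst (conservation)", {
  set.seed(31)
  for (rep in 1:10) {
    objs <- list()
    id <- 0
    for (p in 1:5) {
      for (l in seq_len(sample(0:3, 1))) {
        id <- id + 1
        # footprints of labels within one plane are disjoint (they come from
        # one label mask); give each label its own column band
        start <- (l - 1) * 130 + sample(1:80, 1)
        objs[[id]] <- fake_obj(p, l, start:(start + sample(5:40, 1)))
      }
    }
    if (length(objs) == 0) next
    k <- do.call(bind_objs, objs)
    cysts <- link_across_planes(k)
    expect_equal(sum(cysts$n_members), nrow(k))
    # component sizes agree with the brute-force overlap-graph oracle
    expect_identical(sort(cysts$n_members), oracle_link_components(k))
  }
})

test_that("centroid mode links when a centroid falls in the other footprint", {
  m <- matrix(FALSE, 20, 20); m[4:8, 4:8] <- TRUE
  k <- bind_objs(fake_obj(1, 1, which(m), centroid = c(6, 6)),
                 fake_obj(2, 1, which(m), centroid = c(6, 6)))
  expect_equal(nrow(link_across_planes(k, mode = "centroid")), 1)
})

test_that("representative radius comes from the largest-area member", {
  k <- bind_objs(fake_obj(1, 1, 1:100, area = 100, mean_radius = 5.6),
                 fake_obj(2, 1, 1:100, area = 400, mean_radius = 11.3))
  cysts <- link_across_planes(k)
  expect_equal(cysts$representative_radius, 11.3)
  v <- estimate_volume(cysts, pixel_size = 1)
  expect_equal(v$volume_px3, (4 / 3) * pi * 11.3^3, tolerance = 1e-10)
  expect_equal(round(v$volume_px3, 1), 6044.0)
})

test_that("area ties break to the lowest plane", {
  k <- bind_objs(fake_obj(2, 1, 1:100, area = 100, mean_radius = 7),
                 fake_obj(1, 1, 1:100, area = 100, mean_radius = 9))
  expect_equal(link_across_planes(k)$representative_radius, 9)
})

test_that("volume formula and unit conversion are exact", {
  one <- data.frame(cyst_id = 1L, representative_radius = 1)
  expect_equal(estimate_volume(one, 1)$volume_px3, 4 * pi / 3)
  ten <- data.frame(cyst_id = 1L, representative_radius = 10)
  v <- estimate_volume(ten, pixel_size = 2)
  expect_equal(v$volume_um3, (4 / 3) * pi * 1000 * 8)
  expect_equal(round(v$volume_um3, 1), 33510.3)
  expect_error(estimate_volume(ten, 0), "pixel_size")
})

test_that("well summaries aggregate counts and volumes", {
  cysts <- data.frame(cyst_id = 1:3, representative_radius = c(1, 2, 3))
  cysts <- estimate_volume(cysts, 1)
  cysts$volume_um3 <- c(10, 20, 30)
  w <- summarize_well(cysts, "w1")
  expect_equal(w$cyst_count, 3)
  expect_equal(w$total_volume_um3, 60)
  expect_equal(w$mean_volume_um3, 20)
  empty <- summarize_well(estimate_volume(
    data.frame(cyst_id = integer(0), representative_radius = numeric(0)), 1),
    "w0")
  expect_equal(empty$cyst_count, 0)
  expect_equal(empty$total_volume_um3, 0)
  expect_true(is.na(empty$mean_volume_um3))
})

test_that("the parameter fingerprint changes when any threshold changes", {
  cysts <- estimate_volume(data.frame(cyst_id = 1L,
                                      representative_radius = 2), 1)
  a <- summarize_well(cysts, "w", segmentation_params(), filter_thresholds())
  b <- summarize_well(cysts, "w", segmentation_params(threshold_offset = 11),
                      filter_thresholds())
  c <- summarize_well(cysts, "w", segmentation_params(),
                      filter_thresholds(max_radius_cv = 0.3))
  expect_false(a$params_fingerprint == b$params_fingerprint)
  expect_false(a$params_fingerprint == c$params_fingerprint)
})

test_that("group summaries compute mean, s.e.m. and percent of control", {
  wells <- do.call(rbind, lapply(1:6, function(i) {
    cysts <- estimate_volume(
      data.frame(cyst_id = seq_len(if (i <= 3) 10 else 5),
                 representative_radius = 2), 1)
    summarize_well(cysts, paste0("w", i))
  }))
  design <- data.frame(well_id = paste0("w", 1:6),
                       group_id = rep(c("vehicle", "antimir"), each = 3))
  g <- summarize_groups(wells, design, control_group = "vehicle")
  expect_equal(g$mean_count[g$group_id == "vehicle"], 10)
  expect_equal(g$percent_of_control[g$group_id == "antimir"], 50)
  expect_equal(g$sem_count, c(0, 0))
  expect_equal(g$percent_of_control[g$group_id == "vehicle"], 100)
  # single-well group: s.e.m. undefined
  g1 <- summarize_groups(wells[c(1, 4), ],
                         design[c(1, 4), ], control_group = "vehicle")
  expect_true(all(is.na(g1$sem_count)))
  expect_error(summarize_groups(wells, design, control_group = "nope"),
               "control")
  expect_error(summarize_groups(wells, design[1:5, ], "vehicle"), "assigned")
})
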