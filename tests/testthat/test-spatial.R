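test_that("component extraction matches a brute-force labelling", {
  set.seed(61)
  for (i in 1:10) {
    m <- random_mask(32, 32, 0.08)
    tab <- extract_components(list(X = m), pixel_size = 0.5)
    lab <- oracle_label(m)
    expect_equal(nrow(tab), max(lab))
    expect_setequal(tab$area_px, tabulate(lab[lab > 0]))
  }
  # empty mask set gives an empty table
  expect_equal(nrow(extract_components(list(X = matrix(FALSE, 8, 8)))), 0L)
  # two disjoint blobs in one class give two rows
  m2 <- matrix(FALSE, 16, 16); m2[2:4, 2:4] <- TRUE; m2[10:12, 10:12] <- TRUE
  expect_equal(nrow(extract_components(list(X = m2))), 2L)
})

test_that("mask counts and areas convert to square microns", {
  m <- matrix(FALSE, 20, 20)
  m[2:4, 2:4] <- TRUE; m[10:11, 10:12] <- TRUE; m[16, 16] <- TRUE
  tab <- extract_components(list(K17 = m), pixel_size = 0.175)
  cm <- count_masks(tab)
  expect_equal(cm$n, 3L)
  expect_equal(cm$area_px, 9 + 6 + 1)
  expect_equal(cm$area_um2, 16 * 0.175^2)
  expect_equal(nrow(count_masks(extract_components(
    list(K17 = matrix(FALSE, 4, 4))))), 0L)
})

test_that("nearest-neighbour distance is exact edge-to-edge", {
  # single pixels at (0,0) and (3,4): a 3-4-5 triangle, 5 px = 0.875 um
  m <- matrix(FALSE, 10, 10); m[1, 1] <- TRUE
  t <- matrix(FALSE, 10, 10); t[4, 5] <- TRUE
  tab <- extract_components(list(src = m, tgt = t), pixel_size = 0.175)
  rec <- nearest_neighbor(tab, "src", "tgt")
  expect_equal(rec$distance_um, 5 * 0.175)
  # overlap means zero distance
  ov <- extract_components(list(src = m, tgt = m), pixel_size = 0.175)
  expect_equal(nearest_neighbor(ov, "src", "tgt")$distance_um, 0)
  # unreachable targets are flagged
  un <- extract_components(list(src = m, tgt = matrix(FALSE, 10, 10)))
  r <- nearest_neighbor(un, "src", "tgt")
  expect_true(r$unreachable)
  expect_true(is.na(r$distance_um))
})

test_that("nearest-neighbour equals the all-pairs brute force on random layouts", {
  set.seed(62)
  for (i in 1:20) {
    src <- random_mask(48, 48, 0.03)
    tgt <- random_mask(48, 48, 0.03)
    if (!any(src) || !any(tgt)) next
    tab <- extract_components(list(a = src, b = tgt), pixel_size = 1)
    got <- nearest_neighbor(tab, "a", "b")$distance_um
    want <- oracle_nn_px(src, tgt)
    expect_equal(sort(got), sort(want), tolerance = 1e-12)
  }
})

test_that("adding target components never increases a source's distance", {
  set.seed(63)
  src <- matrix(FALSE, 32, 32); src[5:7, 5:7] <- TRUE
  t1 <- matrix(FALSE, 32, 32); t1[25:27, 25:27] <- TRUE
  t2 <- t1; t2[5:7, 15:17] <- TRUE
  d1 <- nearest_neighbor(extract_components(list(s = src, t = t1),
                                            pixel_size = 1), "s", "t")
  d2 <- nearest_neighbor(extract_components(list(s = src, t = t2),
                                            pixel_size = 1), "s", "t")
  expect_lte(d2$distance_um, d1$distance_um)
})

test_that("nearest-neighbour analysis is asymmetric", {
  # one source near two targets: source->target is short for the source,
  # while one of the targets is far from everything in the reverse direction
  s <- matrix(FALSE, 40, 40); s[5, 5] <- TRUE
  t <- matrix(FALSE, 40, 40); t[5, 8] <- TRUE; t[35, 35] <- TRUE
  tab <- extract_components(list(s = s, t = t), pixel_size = 1)
  st <- nearest_neighbor(tab, "s", "t")$distance_um
  ts <- nearest_neighbor(tab, "t", "s")$distance_um
  expect_false(isTRUE(all.equal(stats::median(st), stats::median(ts))))
})

test_that("proximity histogram bins half-open intervals and conserves totals", {
  rec <- data.frame(distance_um = c(0.5, 3, 12, 25),
                    centroid_x = 0, centroid_y = 0)
  h <- proximity_histogram(rec, bin_width_um = 10, n_bins = 3)
  expect_equal(as.integer(h), c(2L, 1L, 1L))
  expect_equal(attr(h, "overflow"), 0L)
  h2 <- proximity_histogram(rec, bin_width_um = 5, n_bins = 2)
  expect_equal(sum(h2) + attr(h2, "overflow"), 4L)
  expect_equal(sum(proximity_histogram(rec[0, ], 10, 4)), 0L)
  # boundary value 10 falls in the second bin
  h3 <- proximity_histogram(data.frame(distance_um = 10), 10, 2)
  expect_equal(as.integer(h3), c(0L, 1L))
})

test_that("tile aggregation computes per-tile medians and a cross-tile mean", {
  rec <- data.frame(distance_um = c(1, 2, 3, 4, 4, 4),
                    centroid_x = c(10, 20, 30, 2100, 2200, 2300),
                    centroid_y = 10)
  agg <- tile_aggregate(rec, tile_px = 2000L)
  expect_equal(nrow(agg$per_tile), 2L)
  expect_equal(sort(agg$per_tile$value), c(2, 4))  # medians per tile
  expect_equal(agg$summary, 3)                     # mean of medians
  # all in one tile: summary is that tile's median
  one <- tile_aggregate(rec[1:3, ], tile_px = 2000L)
  expect_equal(one$summary, 2)
  # half-open tiling: centroid x = 2000 belongs to tile column 1
  edge <- tile_aggregate(data.frame(distance_um = 1, centroid_x = 2000,
                                    centroid_y = 0), tile_px = 2000L)
  expect_equal(edge$per_tile$tile_col, 1)
})

test_that("region restriction keeps components centred inside the region", {
  m <- matrix(FALSE, 20, 20)
  m[2:4, 2:4] <- TRUE      # centroid (3,3) -> left half
  m[2:4, 15:17] <- TRUE    # centroid (3,16) -> right half
  tab <- extract_components(list(X = m))
  full <- restrict_to_region(tab, matrix(TRUE, 20, 20))
  expect_equal(nrow(full), 2L)
  none <- restrict_to_region(tab, matrix(FALSE, 20, 20))
  expect_equal(nrow(none), 0L)
  left <- matrix(FALSE, 20, 20); left[, 1:10] <- TRUE
  kept <- restrict_to_region(tab, left)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$centroid_x, 2)  # 0-based
  expect_error(restrict_to_region(tab, matrix(TRUE, 5, 5)), "shape")
})

test_that("planted immune-to-tumor offsets are recovered", {
  # tumor nest disk at centre, immune cells at known edge-to-edge gaps
  H <- 128; ps <- 0.5
  tumor <- matrix(FALSE, H, H)
  tumor[mihcseg:::.disk_pixels(64, 64, 20, H, H)] <- TRUE
  gaps_px <- c(5, 12, 25)
  immune <- matrix(FALSE, H, H)
  # radius-4 disks with their near edge exactly g pixels from the tumor
  # edge, alternating sides so the disks stay disjoint
  immune[mihcseg:::.disk_pixels(64, 64 + 20 + 5 + 4, 4, H, H)] <- TRUE
  immune[mihcseg:::.disk_pixels(64, 64 - 20 - 12 - 4, 4, H, H)] <- TRUE
  immune[mihcseg:::.disk_pixels(64, 64 + 20 + 25 + 4, 4, H, H)] <- TRUE
  tab <- extract_components(list(CD8 = immune, K17 = tumor),
                            pixel_size = ps)
  rec <- nearest_neighbor(tab, "CD8", "K17")
  expect_equal(sort(rec$distance_um), sort(gaps_px * ps),
               tolerance = 1.5 * ps / min(gaps_px * ps))
  for (i in seq_along(gaps_px)) {
    expect_lte(abs(sort(rec$distance_um)[i] - sort(gaps_px * ps)[i]),
               1.5 * ps)
  }
})
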