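test_that("superpixels partition the image into connected segments", {
  # uniform image with target the full area: one segment
  flat <- array(0.5, c(16, 16, 3))
  expect_equal(compute_superpixels(flat, 16 * 16), matrix(1L, 16, 16))

  p <- generate_patch(fixture_spec(6))
  sp <- compute_superpixels(p$image, target_segment_size_px = 100)
  # every pixel carries exactly one id, ids are 1..K
  expect_true(all(sp >= 1L))
  expect_setequal(unique(as.vector(sp)), seq_len(max(sp)))
  # each segment is one connected region
  for (s in sample(max(sp), min(10, max(sp)))) {
    expect_equal(max(mihcseg:::.label_mask_cpp(sp == s, 8L)), 1L)
  }
  # segment count within a factor 2 of area / target
  expect_gte(max(sp), 64 * 64 / 100 / 2)
  expect_lte(max(sp), 64 * 64 / 100 * 2)
})

test_that("superpixels keep cell interiors pure at default settings", {
  # fraction of cell-interior pixels whose segment contains no other-class
  # truth pixels, measured on generator ground truth over several patches
  purity <- vapply(11:15, function(s) {
    p <- generate_patch(fixture_spec(s))
    lab <- p$truth$label_map
    sp <- compute_superpixels(p$image, target_segment_size_px = 100)
    ok <- 0; tot <- 0
    for (k in 1:6) {
      idx <- which(lab == k)
      if (!length(idx)) next
      other <- unique(sp[lab > 0 & lab != k])
      ok <- ok + sum(!(sp[idx] %in% other))
      tot <- tot + length(idx)
    }
    ok / tot
  }, numeric(1))
  expect_gte(mean(purity), 0.9)
})

test_that("seed-containing segments take their seed's class, rest background", {
  # constructed 3-segment map
  sp <- matrix(1L, 6, 9)
  sp[, 4:6] <- 2L; sp[, 7:9] <- 3L
  seeds <- data.frame(x = c(1, 4), y = c(2, 3), class = c(2L, 5L))
  lab <- seeds_to_superpixel_labels(sp, seeds)
  expect_true(all(lab[, 1:3] == 2L))
  expect_true(all(lab[, 4:6] == 5L))
  expect_true(all(lab[, 7:9] == 0L))
  # label support is exactly the union of seed-containing segments
  expect_identical(lab > 0, sp %in% c(1L, 2L) & matrix(TRUE, 6, 9))
  # no seeds -> all background
  expect_true(all(seeds_to_superpixel_labels(sp, seeds[0, ]) == 0L))
  # every seed pixel keeps its own class
  expect_equal(lab[cbind(seeds$y + 1, seeds$x + 1)], seeds$class)
})

test_that("multi-class segments resolve to the seed nearest the centroid", {
  sp <- matrix(1L, 5, 11)
  # centroid at column 6; class 4 seed sits on it, class 1 seed at the edge
  seeds <- data.frame(x = c(0, 5), y = c(0, 2), class = c(1L, 4L))
  expect_warning(lab <- seeds_to_superpixel_labels(sp, seeds),
                 "classes \\{1,4\\}")
  expect_true(all(lab == 4L))
})

test_that("out-of-bounds seeds raise an annotation error naming the record", {
  sp <- matrix(1L, 4, 4)
  seeds <- data.frame(x = c(1, 9), y = c(1, 1), class = c(1L, 2L))
  expect_error(seeds_to_superpixel_labels(sp, seeds), "seed 2")
})

test_that("disk labels use the documented radius and keep per-seed identity", {
  # 10.5 um diameter at 0.175 um/px is exactly a 30 px radius
  d <- seeds_to_disk_labels(data.frame(x = 100, y = 100, class = 3L),
                            201, 201)
  expect_equal(d$radius_px, 30)
  # discrete disk area within 2% of pi r^2
  expect_lt(abs(sum(d$masks$CD8) - pi * 30^2) / (pi * 30^2), 0.02)
  # number of disks equals number of seeds even when masks merge
  seeds <- data.frame(x = c(30, 34, 90), y = c(30, 30, 60),
                      class = c(2L, 2L, 2L))
  dm <- seeds_to_disk_labels(seeds, 120, 120, diameter_um = 10.5,
                             pixel_size_um = 0.35)
  expect_equal(nrow(dm$disks), 3L)
  expect_equal(max(mihcseg:::.label_mask_cpp(dm$masks$CD4, 8L)), 2L)
  # no seeds -> empty masks; bad diameter errors
  empty <- seeds_to_disk_labels(seeds[0, ], 32, 32)
  expect_true(all(!unlist(empty$masks)))
  expect_error(seeds_to_disk_labels(seeds, 32, 32, diameter_um = 0),
               "parameter error")
})
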