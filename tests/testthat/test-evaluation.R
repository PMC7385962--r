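test_that("dice matches its closed form and is a proper overlap score", {
  a <- matrix(FALSE, 4, 4); b <- a
  a[1:2, 1:2] <- TRUE            # |A| = 4
  b[2:3, 1:3] <- TRUE            # |B| = 6, |A n B| = 2
  expect_equal(dice(a, b), 2 * 2 / (4 + 6))
  # constructed |A| = |B| = 4 with overlap 2 gives exactly 0.5
  b2 <- matrix(FALSE, 4, 4); b2[2, 1:4] <- TRUE
  a2 <- matrix(FALSE, 4, 4); a2[1:2, 1:2] <- TRUE
  expect_equal(dice(a2, b2), 0.5)
  expect_equal(dice(a, a), 1)
  disjoint <- matrix(FALSE, 4, 4); disjoint[4, 3:4] <- TRUE
  expect_equal(dice(a, disjoint), 0)
  expect_equal(dice(a, b), dice(b, a))
  expect_warning(v <- dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)),
                 "both masks empty")
  expect_equal(v, 1)
  expect_error(dice(a, matrix(FALSE, 3, 3)), "shapes differ")
})

test_that("ssim matches an independent textbook implementation", {
  set.seed(21)
  a <- matrix(stats::runif(16 * 16), 16, 16)
  b <- a + matrix(stats::rnorm(256, 0, 0.1), 16, 16)
  b[b < 0] <- 0; b[b > 1] <- 1
  expect_equal(ssim(a, b), oracle_ssim(a, b), tolerance = 1e-6)
  expect_equal(ssim(a, a), 1)
  # a large constant luminance offset lowers similarity
  expect_lt(ssim(a * 0.5, a * 0.5 + 0.4), 1)
  expect_error(ssim(matrix(0, 8, 8), matrix(0, 8, 8), window = 11),
               "window larger")
})

test_that("detection counting follows the component/disk definition", {
  # empty mask, 3 disks: all FN
  disks <- data.frame(x = c(5, 15, 25), y = c(5, 5, 5), radius_px = 2)
  cnt <- match_detections(matrix(FALSE, 32, 32), disks)
  expect_equal(unclass(cnt)[c("tp", "fp", "fn")],
               list(tp = 0L, fp = 0L, fn = 3L))
  # one component overlapping one of two disks, plus one stray component
  m <- matrix(FALSE, 32, 32)
  m[4:7, 4:7] <- TRUE      # hits disk at (5,5)
  m[25:28, 25:28] <- TRUE  # hits nothing
  disks2 <- data.frame(x = c(5, 15), y = c(5, 5), radius_px = 2)
  cnt2 <- match_detections(m, disks2)
  expect_equal(c(cnt2$tp, cnt2$fp, cnt2$fn), c(1L, 1L, 1L))
  # a component spanning two disks counts once and clears both disks
  m3 <- matrix(FALSE, 32, 32); m3[5, 2:30] <- TRUE
  disks3 <- data.frame(x = c(5, 25), y = c(4, 4), radius_px = 2)
  cnt3 <- match_detections(m3, disks3)
  expect_equal(c(cnt3$tp, cnt3$fp, cnt3$fn), c(1L, 0L, 0L))
})

test_that("detection counting equals the brute-force oracle on random layouts", {
  set.seed(31)
  for (rep in 1:25) {
    m <- random_mask(64, 64, p = 0.04)
    disks <- data.frame(x = sample(0:63, 5), y = sample(0:63, 5),
                        radius_px = sample(2:6, 5, replace = TRUE))
    got <- match_detections(m, disks)
    want <- oracle_match(m, disks)
    expect_equal(c(got$tp, got$fp, got$fn),
                 c(want$tp, want$fp, want$fn))
  }
})

test_that("aggregation pools counts and leaves undefined ratios as NA", {
  one <- aggregate_and_score(list(list(tp = 1, fp = 1, fn = 1)))
  expect_equal(c(one$precision, one$recall, one$f1), c(0.5, 0.5, 0.5))
  perfect <- aggregate_and_score(list(list(tp = 4, fp = 0, fn = 0)))
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1), c(1, 1, 1))
  pooled <- aggregate_and_score(list(list(tp = 1, fp = 0, fn = 1),
                                     list(tp = 1, fp = 2, fn = 0)))
  expect_equal(c(pooled$tp, pooled$fp, pooled$fn), c(2, 2, 1))
  expect_equal(pooled$precision, 0.5)
  expect_equal(pooled$recall, 2 / 3)
  nothing <- aggregate_and_score(list(list(tp = 0, fp = 0, fn = 0)))
  expect_true(is.na(nothing$precision) && is.na(nothing$recall) &&
                is.na(nothing$f1))
})

test_that("pooled micro-metrics equal metrics on concatenated patches", {
  set.seed(41)
  masks <- list(); disks <- list(); counts <- list()
  for (i in 1:3) {
    m <- matrix(FALSE, 32, 32)
    m[8:12, (4 + i):(10 + i)] <- TRUE
    d <- data.frame(x = c(7, 25), y = c(10, 25), radius_px = 3)
    masks[[i]] <- m; disks[[i]] <- d
    counts[[i]] <- match_detections(m, d)
  }
  pooled <- aggregate_and_score(counts)
  big <- do.call(rbind, masks)  # no components touch patch borders
  bigd <- do.call(rbind, lapply(1:3, function(i) {
    transform(disks[[i]], y = y + (i - 1) * 32)
  }))
  direct <- aggregate_and_score(match_detections(big, bigd))
  expect_equal(pooled[c("tp", "fp", "fn")], direct[c("tp", "fp", "fn")])
})
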