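test_that("forward probabilities are normalised per pixel", {
  model <- unet_init(width = 4L, seed = 4)
  set.seed(91)
  img <- array(stats::runif(16 * 12 * 3), c(16, 12, 3))
  probs <- unet_forward(model, img)
  expect_equal(dim(probs), c(16, 12, 7))
  expect_true(all(probs >= 0 & probs <= 1))
  expect_equal(apply(probs, c(1, 2), sum), matrix(1, 16, 12),
               tolerance = 1e-5)
  # inference is deterministic (dropout off)
  expect_identical(probs, unet_forward(model, img))
  # odd sizes are padded and cropped
  expect_equal(dim(unet_forward(model, array(0.5, c(9, 14, 3)))),
               c(9, 14, 7))
})

test_that("weighted cross-entropy matches hand computation", {
  # perfect one-hot prediction has zero loss
  p <- array(0, c(1, 2, 3))
  p[1, 1, ] <- c(1, 0, 0); p[1, 2, ] <- c(0, 0, 1)
  lab <- matrix(c(0L, 2L), 1, 2)
  expect_equal(weighted_cross_entropy(p, lab, rep(1, 3)), 0)
  # two-pixel case by hand
  p2 <- array(0, c(1, 2, 3))
  p2[1, 1, ] <- c(0.7, 0.2, 0.1)
  p2[1, 2, ] <- c(0.1, 0.3, 0.6)
  w <- c(2, 1, 0.5)
  hand <- mean(c(2 * -log(0.7), 0.5 * -log(0.6)))
  expect_equal(weighted_cross_entropy(p2, lab, w), hand)
  # uniform weights reduce to plain cross-entropy
  expect_equal(weighted_cross_entropy(p2, lab, rep(1, 3)),
               mean(c(-log(0.7), -log(0.6))))
  # zero probability at the labelled class is clamped, not infinite
  expect_true(is.finite(weighted_cross_entropy(p, matrix(c(1L, 0L), 1, 2),
                                               rep(1, 3))))
})

test_that("class weights are inverse frequency, mean one, absent classes one", {
  # balanced labels give uniform weights
  bal <- matrix(rep(0:6, each = 7), 7, 7)
  expect_equal(compute_class_weights(list(bal)), rep(1, 7))
  # a class twice as frequent gets half the weight before normalisation
  lab <- matrix(c(rep(1L, 20), rep(2L, 10)), 5, 6)
  w <- compute_class_weights(list(lab), n_classes = 7)
  expect_equal(w[2] / w[3], 0.5)
  expect_equal(mean(w[c(2, 3)]), 1)   # normalised over present classes
  expect_equal(w[c(1, 4:7)], rep(1, 5))  # absent classes
  # hand computation on a constructed 3-class map
  lab3 <- matrix(c(rep(0L, 12), rep(3L, 6), rep(5L, 6)), 4, 6)
  w3 <- compute_class_weights(list(lab3), n_classes = 7)
  raw <- 1 / c(0.5, 0.25, 0.25)
  expect_equal(w3[c(1, 4, 6)], raw / mean(raw))
  expect_error(compute_class_weights(list()), "empty dataset")
})

test_that("training reduces the loss and is reproducible", {
  ds <- lapply(1:6, function(i) {
    p <- generate_patch(fixture_spec(i))
    sp <- compute_superpixels(p$image, target_segment_size_px = 100)
    list(image = p$image,
         labels = suppressWarnings(seeds_to_superpixel_labels(sp,
                                                              p$truth$seeds)))
  })
  cfg <- train_config(epochs = 3, seed = 6)
  fit <- train_unet(ds, cfg)
  expect_lt(fit$log$ce_loss[3], fit$log$ce_loss[1])
  fit2 <- train_unet(ds, cfg)
  expect_equal(fit$log$ce_loss[1], fit2$log$ce_loss[1])
  # trained model inference is deterministic
  probs <- unet_forward(fit$model, ds[[1]]$image)
  expect_identical(probs, unet_forward(fit$model, ds[[1]]$image))
})

test_that("probability maps convert to disjoint filtered masks", {
  probs <- array(0, c(12, 12, 7))
  probs[, , 1] <- 0.9  # background everywhere
  m <- probs_to_masks(probs, min_area_px = 1)
  expect_true(all(!unlist(m)))
  # a 10-px class-3 blob survives, a 3-px one is filtered at min_area 5
  probs2 <- array(0, c(12, 12, 7)); probs2[, , 1] <- 0.6
  probs2[3:7, 3:4, 4] <- 0.9   # class 3, 10 px
  probs2[10:12, 10, 4] <- 0.9  # class 3, 3 px
  m2 <- probs_to_masks(probs2, min_area_px = 5)
  expect_equal(sum(m2$CD8), 10L)
  expect_equal(max(mihcseg:::.label_mask_cpp(m2$CD8, 8L)), 1L)
  # per-pixel argmax makes class masks mutually disjoint
  set.seed(92)
  pr <- array(stats::runif(10 * 10 * 7), c(10, 10, 7))
  mm <- probs_to_masks(pr, min_area_px = 1)
  overlap <- Reduce(`+`, mm)
  expect_true(all(overlap <= 1))
})
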