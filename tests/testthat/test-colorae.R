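test_that("forward output has the contracted shape and nonnegativity", {
  pal <- fixture_palette()
  model <- colorae_init(pal, width = 4L, seed = 1)
  set.seed(81)
  img <- array(stats::runif(24 * 16 * 3), c(24, 16, 3))
  conc <- colorae_forward(model, img)
  expect_equal(dim(conc), c(24, 16, 8))
  expect_true(all(conc >= 0))
  # sizes not divisible by 4 are padded and cropped back
  odd <- array(stats::runif(13 * 10 * 3), c(13, 10, 3))
  expect_equal(dim(colorae_forward(model, odd)), c(13, 10, 8))
})

test_that("reconstruction loss is an exact MSE with its symmetries", {
  pal <- fixture_palette()
  set.seed(82)
  conc <- array(stats::runif(2 * 2 * 8, 0, 0.8), c(2, 2, 8))
  img <- render_beer_lambert(conc, pal, 0)
  # exact reconstruction gives zero loss
  expect_equal(reconstruction_loss(conc, pal, img), 0)
  # brute-force sum of squared differences on a 2x2 image
  other <- array(stats::runif(2 * 2 * 8, 0, 0.8), c(2, 2, 8))
  recon <- render_beer_lambert(other, pal, 0)
  expect_equal(reconstruction_loss(other, pal, img),
               sum((recon - img)^2) / length(img))
  # permuting two stain channels together with their palette vectors
  perm <- c(2, 1, 3:8)
  pal_p <- stain_palette(pal$names[perm], pal$od_vectors[, perm],
                         pal$white_point)
  expect_equal(reconstruction_loss(other[, , perm], pal_p, img),
               reconstruction_loss(other, pal, img))
})

test_that("label-consistency loss re-renders only the allowed channels", {
  pal <- fixture_palette()
  hema <- match("hematoxylin", pal$names)
  bg <- match("background", pal$names)
  # a pixel labelled class 3 whose concentration is entirely on channel 3
  conc <- array(0, c(1, 1, 8)); conc[1, 1, 3] <- 0.9
  img <- render_beer_lambert(conc, pal, 0)
  lab <- matrix(3L, 1, 1)
  expect_equal(label_consistency_loss(conc, lab, pal, img), 0)
  # hand-computed one-pixel case: label 2, concentration on channels 2 and 5;
  # the disallowed channel 5 is dropped from the re-rendering
  conc2 <- array(0, c(1, 1, 8))
  conc2[1, 1, 2] <- 0.4; conc2[1, 1, 5] <- 0.7; conc2[1, 1, hema] <- 0.2
  img2 <- render_beer_lambert(conc2, pal, 0)
  allowed <- conc2; allowed[1, 1, 5] <- 0
  hand <- mean((render_beer_lambert(allowed, pal, 0) - img2)^2)
  expect_equal(label_consistency_loss(conc2, matrix(2L, 1, 1), pal, img2),
               hand)
  # background-labelled pixels contribute through hema/background only
  conc3 <- array(0, c(1, 1, 8)); conc3[1, 1, bg] <- 0.3
  img3 <- render_beer_lambert(conc3, pal, 0)
  expect_equal(label_consistency_loss(conc3, matrix(0L, 1, 1), pal, img3), 0)
  # empty label support warns and returns 0
  expect_warning(
    v <- label_consistency_loss(conc3, matrix(NA_integer_, 1, 1), pal, img3),
    "empty label support")
  expect_equal(v, 0)
})

test_that("training reduces the loss, reproducibly, and lambda = 0 is pure AE", {
  pal <- fixture_palette()
  ds <- lapply(1:6, function(i) {
    p <- generate_patch(fixture_spec(i))
    sp <- compute_superpixels(p$image, target_segment_size_px = 100)
    list(image = p$image,
         labels = suppressWarnings(seeds_to_superpixel_labels(sp,
                                                              p$truth$seeds)))
  })
  cfg <- train_config(epochs = 3, seed = 5, lr = 2e-3)
  fit <- train_colorae(ds, pal, cfg)
  total <- fit$log$rec_loss + fit$log$label_loss
  expect_lt(total[nrow(fit$log)], total[1])
  # identical epoch-1 losses across two seeded runs
  fit2 <- train_colorae(ds, pal, cfg)
  expect_equal(fit$log[1, ], fit2$log[1, ])
  # lambda = 0: label loss never evaluated (logged as 0), even without labels
  ds0 <- lapply(ds, function(s) list(image = s$image, labels = NULL))
  fit0 <- train_colorae(ds0, pal, train_config(epochs = 1, seed = 5,
                                               lambda = 0))
  expect_equal(fit0$log$label_loss, 0)
})

test_that("concentration thresholding and area filtering behave as specified", {
  # all-zero concentrations produce empty masks
  z <- concentrations_to_masks(array(0, c(8, 8, 8)), tau = 0.5,
                               min_area_px = 1)
  expect_true(all(!unlist(z)))
  # a single strong pixel lands only in its own class mask
  conc <- array(0, c(8, 8, 8)); conc[3, 3, 1] <- 1
  m <- concentrations_to_masks(conc, tau = 0.5, min_area_px = 1)
  expect_true(m$CD3[3, 3])
  expect_equal(sum(unlist(m)), 1L)
  # min_area = 5 removes a 4-px component and keeps a 5-px one
  conc2 <- array(0, c(10, 10, 8))
  conc2[1:2, 1:2, 2] <- 1          # 4 px
  conc2[6:10, 6, 2] <- 1           # 5 px
  m2 <- concentrations_to_masks(conc2, tau = 0.5, min_area_px = 5)
  expect_equal(sum(m2$CD4), 5L)
  expect_true(all(m2$CD4[6:10, 6]))
  expect_error(concentrations_to_masks(conc2, tau = -1), "parameter error")
})
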