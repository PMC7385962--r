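#' U-Net cell classifier
#'
#' A compact U-Net (two pooling levels, skip connections between the encoding
#' and decoding paths, base width 16, dropout at the deepest level) that
#' labels every pixel with one of the six cell classes or background.
#' Hematoxylin-only pixels count as background, matching the weak-label
#' convention. Trained on superpixel labels with weighted cross-entropy to
#' counter class imbalance.
#'
#' @param n_classes number of output classes including background (default 7;
#'   channel 1 is background, channels 2..7 the stain classes).
#' @param width base channel width.
#' @param seed RNG seed for initialisation.
#' @return an untrained `unet_model`.
#' @export
unet_init <- function(n_classes = 7L, width = 16L, seed = 1L) {
  set.seed(seed)
  w1 <- width; w2 <- 2L * width; w3 <- 4L * width
  params <- list(
    d1a = .conv_param(3, w1),       d1b = .conv_param(w1, w1),
    d2a = .conv_param(w1, w2),      d2b = .conv_param(w2, w2),
    bott = .conv_param(w2, w3),
    u2 = .conv_param(w3 + w2, w2),
    u1 = .conv_param(w2 + w1, w1),
    out = .conv_param(w1, n_classes, gain = 1))
  structure(list(params = params, n_classes = as.integer(n_classes),
                 width = width, downsample = 4L,
                 legend = c("background", mihc_class_names())),
            class = "unet_model")
}

.cat3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

.unet_forward_full <- function(params, x, dropout = 0, rng = FALSE) {
  z1a <- .conv3_fwd_cpp(x, params$d1a$w, params$d1a$b); a1a <- .relu(z1a)
  z1b <- .conv3_fwd_cpp(a1a, params$d1b$w, params$d1b$b); s1 <- .relu(z1b)
  p1 <- .maxpool2_fwd_cpp(s1)
  z2a <- .conv3_fwd_cpp(p1$y, params$d2a$w, params$d2a$b); a2a <- .relu(z2a)
  z2b <- .conv3_fwd_cpp(a2a, params$d2b$w, params$d2b$b); s2 <- .relu(z2b)
  p2 <- .maxpool2_fwd_cpp(s2)
  zb <- .conv3_fwd_cpp(p2$y, params$bott$w, params$bott$b); ab <- .relu(zb)
  dmask <- NULL
  if (dropout > 0 && rng) {
    dmask <- array(stats::rbinom(length(ab), 1, 1 - dropout) / (1 - dropout),
                   dim = dim(ab))
    ab <- ab * dmask
  }
  up2 <- .upsample2_fwd_cpp(ab)
  cat2 <- .cat3(up2, s2)
  z3 <- .conv3_fwd_cpp(cat2, params$u2$w, params$u2$b); a3 <- .relu(z3)
  up1 <- .upsample2_fwd_cpp(a3)
  cat1 <- .cat3(up1, s1)
  z4 <- .conv3_fwd_cpp(cat1, params$u1$w, params$u1$b); a4 <- .relu(z4)
  logits <- .conv3_fwd_cpp(a4, params$out$w, params$out$b)
  list(logits = logits,
       cache = list(x = x, z1a = z1a, a1a = a1a, z1b = z1b, s1 = s1, p1 = p1,
                    z2a = z2a, a2a = a2a, z2b = z2b, s2 = s2, p2 = p2,
                    zb = zb, ab = ab, dmask = dmask, cat2 = cat2, z3 = z3,
                    a3 = a3, cat1 = cat1, z4 = z4, a4 = a4))
}

.unet_backward <- function(params, cache, dlogits) {
  bout <- .conv3_bwd_cpp(cache$a4, params$out$w, dlogits)
  g <- .relu_bwd(bout$gx, cache$z4)
  bu1 <- .conv3_bwd_cpp(cache$cat1, params$u1$w, g)
  nw1 <- dim(cache$a3)[3]  # channels arriving from below at level 1
  g_up1 <- bu1$gx[, , seq_len(nw1), drop = FALSE]
  g_s1 <- bu1$gx[, , -seq_len(nw1), drop = FALSE]
  g <- .upsample2_bwd_cpp(g_up1)
  g <- .relu_bwd(g, cache$z3)
  bu2 <- .conv3_bwd_cpp(cache$cat2, params$u2$w, g)
  nwb <- dim(cache$ab)[3]
  g_up2 <- bu2$gx[, , seq_len(nwb), drop = FALSE]
  g_s2 <- bu2$gx[, , -seq_len(nwb), drop = FALSE]
  g <- .upsample2_bwd_cpp(g_up2)
  if (!is.null(cache$dmask)) g <- g * cache$dmask
  g <- .relu_bwd(g, cache$zb)
  bb <- .conv3_bwd_cpp(cache$p2$y, params$bott$w, g)
  g <- .maxpool2_bwd_cpp(bb$gx, cache$p2$idx, dim(cache$s2)[1],
                         dim(cache$s2)[2])
  g <- g + g_s2
  g <- .relu_bwd(g, cache$z2b)
  b2b <- .conv3_bwd_cpp(cache$a2a, params$d2b$w, g)
  g <- .relu_bwd(b2b$gx, cache$z2a)
  b2a <- .conv3_bwd_cpp(cache$p1$y, params$d2a$w, g)
  g <- .maxpool2_bwd_cpp(b2a$gx, cache$p1$idx, dim(cache$s1)[1],
                         dim(cache$s1)[2])
  g <- g + g_s1
  g <- .relu_bwd(g, cache$z1b)
  b1b <- .conv3_bwd_cpp(cache$a1a, params$d1b$w, g)
  g <- .relu_bwd(b1b$gx, cache$z1a)
  b1a <- .conv3_bwd_cpp(cache$x, params$d1a$w, g)
  list(d1a = list(w = b1a$gw, b = b1a$gb), d1b = list(w = b1b$gw, b = b1b$gb),
       d2a = list(w = b2a$gw, b = b2a$gb), d2b = list(w = b2b$gw, b = b2b$gb),
       bott = list(w = bb$gw, b = bb$gb), u2 = list(w = bu2$gw, b = bu2$gb),
       u1 = list(w = bu1$gw, b = bu1$gb), out = list(w = bout$gw,
                                                     b = bout$gb))
}

#' Per-pixel class probabilities
#'
#' Dropout is inactive at inference, so repeated forward passes are
#' bitwise identical. Sizes not divisible by 4 are edge-padded and cropped.
#'
#' @param model a `unet_model`.
#' @param img H x W x 3 RGB array in \[0, 1\].
#' @return H x W x n_classes array of probabilities summing to 1 per pixel
#'   (channel 1 = background).
#' @export
unet_forward <- function(model, img) {
  img <- as_rgb_array(img)
  p <- .pad_to_multiple(img, model$downsample)
  logits <- .unet_forward_full(model$params, p$x)$logits
  probs <- .softmax3(logits)
  probs[seq_len(p$H), seq_len(p$W), , drop = FALSE]
}

#' Weighted cross-entropy
#'
#' \eqn{-\mathrm{mean}_i\, w_{y_i} \log p_i(y_i)} over all pixels, with one
#' positive weight per class to counter class imbalance; uniform weights
#' reduce to plain cross-entropy. Probabilities are clamped at 1e-12.
#'
#' @param probs H x W x n_classes probability array.
#' @param labels integer matrix with values 0 (background) .. n_classes - 1.
#' @param weights positive numeric vector, one entry per class (background
#'   first).
#' @return scalar loss.
#' @export
weighted_cross_entropy <- function(probs, labels,
                                   weights = rep(1, dim(probs)[3])) {
  d <- dim(probs)
  stopifnot(all(weights > 0), length(weights) == d[3])
  n <- d[1] * d[2]
  pm <- matrix(probs, n, d[3])
  y <- as.vector(labels) + 1L
  py <- pmax(pm[cbind(seq_len(n), y)], 1e-12)
  mean(weights[y] * (-log(py)))
}

#' Inverse-frequency class weights
#'
#' Weights are 1/frequency over all labelled pixels of the dataset,
#' normalised to mean 1 over the classes present; absent classes get
#' weight 1. A class twice as frequent gets half the weight.
#'
#' @param labels_list list of integer label matrices (values 0 ..
#'   n_classes - 1).
#' @param n_classes total class count including background.
#' @return numeric weight vector of length `n_classes`.
#' @export
compute_class_weights <- function(labels_list, n_classes = 7L) {
  if (length(labels_list) == 0L) stop("empty dataset", call. = FALSE)
  counts <- numeric(n_classes)
  for (lab in labels_list) {
    t <- tabulate(as.vector(lab) + 1L, n_classes)
    counts <- counts + t
  }
  present <- counts > 0
  w <- rep(1, n_classes)
  if (any(present)) {
    freq <- counts[present] / sum(counts)
    wi <- 1 / freq
    w[present] <- wi / mean(wi)
  }
  w
}

#' Train the U-Net
#'
#' Minimises the weighted cross-entropy against the (superpixel or disk)
#' labels by Adam with per-image updates; dropout is active during training
#' only. Reproducible given `cfg$seed`.
#'
#' @param dataset list of samples with `image` and `labels` (0 = background,
#'   1..6 = classes).
#' @param cfg a [train_config()].
#' @param weights class weights (default [compute_class_weights()] on the
#'   dataset labels).
#' @return list with `model` (a `unet_model`) and `log` (data.frame `epoch`,
#'   `ce_loss`).
#' @export
train_unet <- function(dataset, cfg = train_config(), weights = NULL) {
  if (length(dataset) == 0L) stop("empty dataset", call. = FALSE)
  set.seed(cfg$seed)
  model <- unet_init(seed = cfg$seed)
  nc <- model$n_classes
  if (is.null(weights)) {
    weights <- compute_class_weights(lapply(dataset, `[[`, "labels"), nc)
  }
  params <- .flatten_params(model$params)
  state <- .adam_init(params)
  log <- data.frame(epoch = integer(0), ce_loss = numeric(0))
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(length(dataset))
    tot <- 0
    for (i in ord) {
      img <- dataset[[i]]$image
      lab <- dataset[[i]]$labels
      if (cfg$augment) {
        k <- sample(0:7, 1)
        img <- .augment_geom(img, k)
        lab <- .augment_geom(lab, k)
      }
      sp <- .unflatten_params(params)
      fw <- .unet_forward_full(sp, img, dropout = cfg$dropout, rng = TRUE)
      d <- dim(fw$logits)
      n <- d[1] * d[2]
      pm <- matrix(.softmax3(fw$logits), n, nc)
      y <- as.vector(lab) + 1L
      py <- pmax(pm[cbind(seq_len(n), y)], 1e-12)
      wy <- weights[y]
      tot <- tot + mean(wy * (-log(py)))
      gz <- pm * (wy / n)
      gz[cbind(seq_len(n), y)] <- gz[cbind(seq_len(n), y)] - wy / n
      grads <- .flatten_params(
        .unet_backward(sp, fw$cache, array(gz, dim = d)))
      upd <- .adam_step(params, grads, state, cfg$lr)
      params <- upd$params
      state <- upd$state
    }
    log <- rbind(log, data.frame(epoch = ep, ce_loss = tot / length(dataset)))
  }
  model$params <- .unflatten_params(params)
  model$class_weights <- weights
  list(model = model, log = log)
}

#' Convert class probabilities to per-class masks
#'
#' Per-pixel argmax; the background class is dropped; per-class connected
#' components below `min_area_px` are removed with the same filter as the
#' autoencoder masks. The six masks are mutually disjoint by construction.
#'
#' @param probs H x W x n_classes probability array from [unet_forward()].
#' @param min_area_px minimum component area (default: 3-micron-disk area).
#' @param pixel_size microns per pixel for the default `min_area_px`.
#' @return named list of 6 logical masks with provenance `"unet"`.
#' @export
probs_to_masks <- function(probs, min_area_px = NULL, pixel_size = 0.175) {
  if (is.null(min_area_px)) min_area_px <- round(pi * (1.5 / pixel_size)^2)
  d <- dim(probs)
  pm <- matrix(probs, d[1] * d[2], d[3])
  am <- max.col(pm, ties.method = "first")
  masks <- lapply(1:6, function(k) {
    filter_small_components(matrix(am == k + 1L, d[1], d[2]), min_area_px)
  })
  names(masks) <- mihc_class_names()
  attr(masks, "provenance") <- "unet"
  masks
}
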