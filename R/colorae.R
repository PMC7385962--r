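#' The colour-decomposition autoencoder (ColorAE)
#'
#' ColorAE maps an RGB mIHC patch to an 8-channel nonnegative concentration
#' map (six chromogens, hematoxylin, background) through a convolutional
#' encoder-decoder: the input is contracted to a low-resolution, higher
#' dimensional representation and expanded back to full resolution, with a
#' softplus output enforcing nonnegativity. Training minimises a
#' reconstruction loss (Beer-Lambert re-rendering of the predicted
#' concentrations versus the input, in intensity space) plus `lambda` times a
#' label-consistency loss that re-renders each weakly labelled pixel using
#' only its labelled stain channel plus hematoxylin (always allowed, since
#' counterstained pixels are otherwise unreconstructable); the background
#' channel participates only at background-labelled pixels, because a grey
#' background "ink" can mimic dark stains and would defeat the purpose of the
#' label loss. The label loss resolves the colour-decomposition ambiguity
#' that reconstruction alone leaves when more than three stains are present.
#'
#' @param palette a [stain_palette()]; the model's output channel order is
#'   bound to it.
#' @param width base channel width of the encoder (default 16).
#' @param seed RNG seed for initialisation.
#' @return an untrained `colorae_model`.
#' @export
colorae_init <- function(palette, width = 16L, seed = 1L) {
  validate_palette(palette)
  set.seed(seed)
  K <- length(palette$names)
  w1 <- width; w2 <- 2L * width
  params <- list(
    c1 = .conv_param(3, w1), c2 = .conv_param(w1, w2),
    c3 = .conv_param(w2, w2), c4 = .conv_param(w2, w1),
    c5 = .conv_param(w1, w1), c6 = .conv_param(w1, K, gain = 1))
  # orthogonal output columns: concentration channels must not start
  # entangled, or a channel whose stain colour is close to hematoxylin's can
  # be absorbed by it early and never recover its role
  # (orthonormal columns have unit norm, matching a gain-1 fan-in scale)
  params$c6$w <- qr.Q(qr(matrix(stats::rnorm(9 * w1 * K), 9 * w1, K)))
  # start near zero concentration but on the live part of the softplus, so
  # early large reconstruction gradients cannot saturate the output layer
  params$c6$b[] <- -3
  structure(list(params = params, palette = palette, width = width,
                 channels = palette$names, downsample = 4L),
            class = "colorae_model")
}

.cae_forward <- function(params, x) {
  z1 <- .conv3_fwd_cpp(x, params$c1$w, params$c1$b);  a1 <- .relu(z1)
  p1 <- .maxpool2_fwd_cpp(a1)
  z2 <- .conv3_fwd_cpp(p1$y, params$c2$w, params$c2$b); a2 <- .relu(z2)
  p2 <- .maxpool2_fwd_cpp(a2)
  z3 <- .conv3_fwd_cpp(p2$y, params$c3$w, params$c3$b); a3 <- .relu(z3)
  u1 <- .upsample2_fwd_cpp(a3)
  z4 <- .conv3_fwd_cpp(u1, params$c4$w, params$c4$b);  a4 <- .relu(z4)
  u2 <- .upsample2_fwd_cpp(a4)
  z5 <- .conv3_fwd_cpp(u2, params$c5$w, params$c5$b);  a5 <- .relu(z5)
  z6 <- .conv3_fwd_cpp(a5, params$c6$w, params$c6$b)
  out <- .softplus(z6)
  list(out = out, cache = list(x = x, z1 = z1, a1 = a1, p1 = p1, z2 = z2,
                               a2 = a2, p2 = p2, z3 = z3, a3 = a3, u1 = u1,
                               z4 = z4, a4 = a4, u2 = u2, z5 = z5, a5 = a5,
                               z6 = z6))
}

.cae_backward <- function(params, cache, dout) {
  g <- dout * .sigmoid(cache$z6)
  b6 <- .conv3_bwd_cpp(cache$a5, params$c6$w, g)
  g <- .relu_bwd(b6$gx, cache$z5)
  b5 <- .conv3_bwd_cpp(cache$u2, params$c5$w, g)
  g <- .upsample2_bwd_cpp(b5$gx)
  g <- .relu_bwd(g, cache$z4)
  b4 <- .conv3_bwd_cpp(cache$u1, params$c4$w, g)
  g <- .upsample2_bwd_cpp(b4$gx)
  g <- .relu_bwd(g, cache$z3)
  b3 <- .conv3_bwd_cpp(cache$p2$y, params$c3$w, g)
  g <- .maxpool2_bwd_cpp(b3$gx, cache$p2$idx, dim(cache$a2)[1],
                         dim(cache$a2)[2])
  g <- .relu_bwd(g, cache$z2)
  b2 <- .conv3_bwd_cpp(cache$p1$y, params$c2$w, g)
  g <- .maxpool2_bwd_cpp(b2$gx, cache$p1$idx, dim(cache$a1)[1],
                         dim(cache$a1)[2])
  g <- .relu_bwd(g, cache$z1)
  b1 <- .conv3_bwd_cpp(cache$x, params$c1$w, g)
  list(c1 = list(w = b1$gw, b = b1$gb), c2 = list(w = b2$gw, b = b2$gb),
       c3 = list(w = b3$gw, b = b3$gb), c4 = list(w = b4$gw, b = b4$gb),
       c5 = list(w = b5$gw, b = b5$gb), c6 = list(w = b6$gw, b = b6$gb))
}

#' Predict concentration maps
#'
#' @param model a trained (or fresh) `colorae_model`.
#' @param img H x W x 3 RGB array in \[0, 1\]. Sizes not divisible by the
#'   model's downsampling factor are edge-padded and cropped back.
#' @return H x W x 8 nonnegative concentration array in palette channel
#'   order.
#' @export
colorae_forward <- function(model, img) {
  img <- as_rgb_array(img)
  p <- .pad_to_multiple(img, model$downsample)
  out <- .cae_forward(model$params, p$x)$out
  out[seq_len(p$H), seq_len(p$W), , drop = FALSE]
}

#' ColorAE losses
#'
#' `reconstruction_loss` is the pixelwise MSE, on the \[0, 1\] intensity
#' scale, between the input image and the Beer-Lambert rendering of the
#' predicted concentrations. `label_consistency_loss` re-renders each
#' labelled pixel using only its labelled stain channel plus hematoxylin
#' (background-labelled pixels use hematoxylin plus the background channel)
#' and takes the MSE over labelled pixels (labels are 0 = background .. 6;
#' `NA` pixels are excluded; an empty label support returns 0 with a
#' warning).
#'
#' @param conc H x W x 8 concentration array.
#' @param palette the bound [stain_palette()].
#' @param img H x W x 3 input image.
#' @param labels integer label matrix for the label-consistency loss.
#' @return scalar loss.
#' @export
reconstruction_loss <- function(conc, palette, img) {
  .rec_loss_grad(conc, palette, img, want_grad = FALSE)$loss
}

.rec_loss_grad <- function(conc, palette, img, want_grad = TRUE) {
  d <- dim(conc)
  n <- d[1] * d[2]
  V <- palette$od_vectors  # 3 x K
  cm <- matrix(conc, n, d[3])
  R <- exp(-(cm %*% t(V)))
  R <- sweep(R, 2, palette$white_point, "*")
  imat <- matrix(img, n, 3)
  diff <- R - imat
  loss <- mean(diff^2)
  if (!want_grad) return(list(loss = loss))
  gR <- 2 * diff / (3 * n)
  gC <- -(gR * R) %*% V  # n x K
  list(loss = loss, grad = array(gC, dim = d))
}

#' @rdname reconstruction_loss
#' @export
label_consistency_loss <- function(conc, labels, palette, img) {
  .label_loss_grad(conc, labels, palette, img, want_grad = FALSE)$loss
}

.label_loss_grad <- function(conc, labels, palette, img, want_grad = TRUE) {
  d <- dim(conc)
  n <- d[1] * d[2]
  K <- d[3]
  lab <- as.vector(labels)
  labeled <- which(!is.na(lab))
  if (length(labeled) == 0L) {
    warning("empty label support; label-consistency loss is 0",
            call. = FALSE)
    return(list(loss = 0,
                grad = if (want_grad) array(0, dim = d) else NULL))
  }
  V <- palette$od_vectors
  hema <- match("hematoxylin", palette$names)
  bg <- match("background", palette$names)
  M <- matrix(0, n, K)
  # the hematoxylin counterstain is always allowed (nuclei are everywhere);
  # the background channel only where the label says background, otherwise
  # grey background "ink" could mimic dark stains and the label loss would
  # no longer pin down the stain channels
  M[labeled, hema] <- 1
  pos <- labeled[lab[labeled] > 0L]
  if (length(pos)) M[cbind(pos, lab[pos])] <- 1
  M[labeled[lab[labeled] == 0L], bg] <- 1
  cm <- matrix(conc, n, K) * M
  R <- exp(-(cm %*% t(V)))
  R <- sweep(R, 2, palette$white_point, "*")
  imat <- matrix(img, n, 3)
  diff <- (R - imat)[labeled, , drop = FALSE]
  loss <- mean(diff^2)
  if (!want_grad) return(list(loss = loss))
  gR <- matrix(0, n, 3)
  gR[labeled, ] <- 2 * diff / (3 * length(labeled))
  gC <- (-(gR * R) %*% V) * M
  list(loss = loss, grad = array(gC, dim = d))
}

# Bootstrap concentration targets from weak labels: at a labelled pixel only
# two channels are allowed ({label stain, hematoxylin}, or {hematoxylin,
# background} on background), so the Beer-Lambert system is overdetermined
# and the exact least-squares fit of deconvolve_linear applies per pixel.
# Regressing the network onto these targets for the first epochs routes every
# output channel to its own stain deterministically, from any initialisation;
# the reconstruction + label-consistency losses then refine the result where
# the two-channel fit is too rigid (overlapping cells, compound colours).
.weak_conc_targets <- function(img, labels, palette) {
  d <- dim(img)
  n <- d[1] * d[2]
  K <- length(palette$names)
  lab <- as.vector(labels)
  labeled <- which(!is.na(lab))
  tgt <- matrix(0, n, K)
  if (length(labeled) == 0L) return(list(t = tgt, labeled = labeled))
  od <- matrix(rgb_to_od(img, palette$white_point), n, 3)
  hema <- match("hematoxylin", palette$names)
  bg <- match("background", palette$names)
  for (k in sort(unique(lab[labeled]))) {
    sel <- labeled[lab[labeled] == k]
    allowed <- if (k == 0L) c(hema, bg) else c(k, hema)
    A <- palette$od_vectors[, allowed, drop = FALSE]
    sol <- t(qr.solve(A, t(od[sel, , drop = FALSE])))
    sol[sol < 0] <- 0
    # weak labels are imperfect: a dark (mislabelled) pixel restricted to
    # {hematoxylin, background} can blow the fit up to huge concentrations
    # that would dominate the regression, so targets are capped at a
    # physically plausible ceiling
    sol[sol > 3] <- 3
    tgt[sel, allowed] <- sol
  }
  list(t = tgt, labeled = labeled)
}

#' Train ColorAE
#'
#' Minimises `reconstruction_loss + lambda * label_consistency_loss` by Adam
#' with per-image updates; with `lambda = 0` the label loss is never
#' evaluated and training degenerates to pure autoencoding. When weak labels
#' are available, the first quarter of the epochs regresses the output
#' directly onto per-pixel least-squares concentration targets derived from
#' the labels (the channel-routing bootstrap; see the methods vignette),
#' which makes the channel-to-stain assignment reliable across seeds. Fully
#' reproducible given `cfg$seed` (single-threaded CPU).
#'
#' @param dataset list of samples, each a list with `image` (H x W x 3 array,
#'   sizes divisible by 4) and `labels` (integer matrix, 0 = background,
#'   1..6 = stain classes).
#' @param palette the [stain_palette()] the output channels bind to.
#' @param cfg a [train_config()].
#' @return list with `model` (a `colorae_model`) and `log` (data.frame
#'   `epoch`, `rec_loss`, `label_loss`).
#' @export
train_colorae <- function(dataset, palette, cfg = train_config()) {
  if (length(dataset) == 0L) stop("empty dataset", call. = FALSE)
  set.seed(cfg$seed)
  model <- colorae_init(palette, seed = cfg$seed)
  params <- .flatten_params(model$params)
  state <- .adam_init(params)
  log <- data.frame(epoch = integer(0), rec_loss = numeric(0),
                    label_loss = numeric(0))
  # channel-routing bootstrap (see .weak_conc_targets) for the first quarter
  # of the schedule, when weak labels are available
  n_boot <- if (cfg$lambda > 0) max(2L, ceiling(cfg$epochs / 4)) else 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(length(dataset))
    rl <- 0; ll <- 0
    for (i in ord) {
      img <- dataset[[i]]$image
      lab <- dataset[[i]]$labels
      if (cfg$augment) {
        k <- sample(0:7, 1)
        img <- .augment_geom(img, k)
        if (!is.null(lab)) lab <- .augment_geom(lab, k)
      }
      sp <- .unflatten_params(params)
      fw <- .cae_forward(sp, img)
      rec <- .rec_loss_grad(fw$out, palette, img)
      lab_loss <- 0
      if (ep <= n_boot && !is.null(lab)) {
        # pure regression onto the two-channel least-squares targets: the
        # reconstruction loss joins only after the channels are routed,
        # otherwise its pull toward arbitrary colour mixtures competes with
        # the routing
        bt <- .weak_conc_targets(img, lab, palette)
        d <- dim(fw$out)
        cm <- matrix(fw$out, d[1] * d[2], d[3])
        gb <- matrix(0, d[1] * d[2], d[3])
        if (length(bt$labeled)) {
          gb[bt$labeled, ] <- 2 * (cm - bt$t)[bt$labeled, , drop = FALSE] /
            (length(bt$labeled) * d[3])
        }
        g <- array(gb, dim = d)
        if (cfg$lambda > 0) {
          lab_loss <- .label_loss_grad(fw$out, lab, palette, img,
                                       want_grad = FALSE)$loss
        }
      } else {
        g <- rec$grad
        if (cfg$lambda > 0) {
          lcl <- .label_loss_grad(fw$out, lab, palette, img)
          lab_loss <- lcl$loss
          g <- g + cfg$lambda * lcl$grad
        }
      }
      grads <- .flatten_params(.cae_backward(sp, fw$cache, g))
      upd <- .adam_step(params, grads, state, cfg$lr)
      params <- upd$params
      state <- upd$state
      rl <- rl + rec$loss
      ll <- ll + lab_loss
    }
    log <- rbind(log, data.frame(epoch = ep, rec_loss = rl / length(dataset),
                                 label_loss = ll / length(dataset)))
  }
  model$params <- .unflatten_params(params)
  list(model = model, log = log)
}

.flatten_params <- function(nested) {
  out <- list()
  for (nm in names(nested)) {
    out[[paste0(nm, ".w")]] <- nested[[nm]]$w
    out[[paste0(nm, ".b")]] <- nested[[nm]]$b
  }
  out
}

.unflatten_params <- function(flat) {
  nms <- unique(sub("\\.[wb]$", "", names(flat)))
  out <- lapply(nms, function(nm) list(w = flat[[paste0(nm, ".w")]],
                                       b = flat[[paste0(nm, ".b")]]))
  names(out) <- nms
  out
}

#' Threshold concentration maps into per-class masks
#'
#' A pixel belongs to stain s when its predicted concentration is at least
#' `tau[s]` and s is the argmax over the six stain channels; connected
#' components smaller than `min_area_px` are then removed per class
#' (post-filtering of sub-cellular specks). By default `tau` is chosen
#' per channel by Otsu's method on the concentration histogram, and
#' `min_area_px` is the pixel area of a 3-micron disk.
#'
#' @param conc H x W x 8 concentration array.
#' @param tau scalar or 6-vector of thresholds (default: per-channel Otsu).
#' @param min_area_px minimum component area in pixels.
#' @param pixel_size microns per pixel, used for the default `min_area_px`.
#' @return named list of 6 logical masks with provenance `"colorae"`.
#' @export
concentrations_to_masks <- function(conc, tau = NULL, min_area_px = NULL,
                                    pixel_size = 0.175) {
  if (!is.null(tau) && any(tau < 0)) {
    stop("parameter error: tau must be nonnegative", call. = FALSE)
  }
  if (is.null(min_area_px)) {
    min_area_px <- round(pi * (1.5 / pixel_size)^2)
  }
  d <- dim(conc)
  stains <- matrix(conc[, , 1:6], d[1] * d[2], 6)
  if (is.null(tau)) {
    tau <- apply(stains, 2, .otsu_threshold)
  } else if (length(tau) == 1L) {
    tau <- rep(tau, 6)
  }
  am <- max.col(stains, ties.method = "first")
  masks <- lapply(1:6, function(k) {
    m <- matrix(am == k & stains[, k] >= tau[k], d[1], d[2])
    filter_small_components(m, min_area_px)
  })
  names(masks) <- mihc_class_names()
  attr(masks, "provenance") <- "colorae"
  masks
}

#' Remove small connected components from a binary mask
#'
#' Shared post-filter of the autoencoder and U-Net mask generation (8-connected
#' components below `min_area_px` pixels are dropped).
#'
#' @param mask logical matrix.
#' @param min_area_px minimum retained component area.
#' @return filtered logical matrix.
#' @export
filter_small_components <- function(mask, min_area_px) {
  if (min_area_px <= 1L || !any(mask)) return(mask)
  lab <- .label_mask_cpp(mask, 8L)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_area_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

# Otsu's threshold on a 256-bin histogram
.otsu_threshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1] + 1e-9)
  h <- tabulate(pmin(nbins, 1L + floor((x - rng[1]) / diff(rng) * nbins)),
                nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- 0
  mids[which.max(sb2)]
}
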