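# Small convolutional-network engine: 3x3 same-padding convolutions, 2x2 max
# pooling, nearest-neighbour upsampling (C++ kernels), ReLU/softplus/softmax,
# inverted dropout, and Adam. All parameters live in flat named lists of
# arrays so optimiser state and serialisation stay trivial.

.relu <- function(x) {
  x[x < 0] <- 0
  x
}

.relu_bwd <- function(g, z) {
  g[z <= 0] <- 0
  g
}

.softplus <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

.sigmoid <- function(z) 1 / (1 + exp(-z))

.conv_param <- function(cin, cout, gain = 2) {
  list(w = matrix(stats::rnorm(9 * cin * cout, 0,
                               sqrt(gain / (9 * cin))), 9 * cin, cout),
       b = numeric(cout))
}

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

# eps is deliberately large (1e-4, not the usual 1e-8): with a softplus
# output head, a channel being suppressed has a tiny but consistent negative
# gradient, and a small eps lets Adam renormalise it to full-size steps that
# drive the pre-activation tens of units into saturation, killing the
# channel irrecoverably. The large eps damps vanishing gradients instead of
# amplifying them, so unused channels park just below threshold and remain
# recoverable by the label-consistency loss.
.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-4, weight_decay = 0) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] - lr * (state$m[[nm]] / corr1) /
      (sqrt(state$v[[nm]] / corr2) + eps)
    if (weight_decay > 0) {
      # decoupled decay; also the escape route out of saturated (zero
      # gradient) activations, whose parameters otherwise never move again
      params[[nm]] <- params[[nm]] * (1 - lr * weight_decay)
    }
  }
  list(params = params, state = state)
}

# pad H and W up to a multiple of `mult` by edge replication; returns padded
# array and the original size for cropping
.pad_to_multiple <- function(x, mult) {
  d <- dim(x)
  H2 <- ceiling(d[1] / mult) * mult
  W2 <- ceiling(d[2] / mult) * mult
  if (H2 == d[1] && W2 == d[2]) return(list(x = x, H = d[1], W = d[2]))
  ri <- c(seq_len(d[1]), rep(d[1], H2 - d[1]))
  ci <- c(seq_len(d[2]), rep(d[2], W2 - d[2]))
  list(x = x[ri, ci, , drop = FALSE], H = d[1], W = d[2])
}

.softmax3 <- function(z) {
  m <- apply(z, c(1, 2), max)
  e <- exp(sweep(z, c(1, 2), m))
  sweep(e, c(1, 2), apply(e, c(1, 2), sum), "/")
}

# geometric augmentation shared by image arrays and label matrices:
# k in 0..7 = rotation by 0/90/180/270, optionally mirrored
.augment_geom <- function(x, k) {
  flip <- k >= 4L
  rot <- k %% 4L
  rot_mat <- function(m, r) {
    if (r == 0L) m
    else if (r == 1L) t(m)[ncol(m):1, , drop = FALSE]
    else if (r == 2L) m[nrow(m):1, ncol(m):1, drop = FALSE]
    else t(m)[, nrow(m):1, drop = FALSE]
  }
  f <- function(m) {
    if (flip) m <- m[, ncol(m):1, drop = FALSE]
    rot_mat(m, rot)
  }
  if (is.matrix(x)) return(f(x))
  slices <- lapply(seq_len(dim(x)[3]), function(i) f(x[, , i]))
  array(unlist(slices), dim = c(dim(slices[[1]]), dim(x)[3]))
}

#' Training configuration
#'
#' Hyperparameters shared by [train_colorae()] and [train_unet()].
#'
#' @param epochs number of passes over the dataset.
#' @param batch_size images per optimiser step (the engine updates per image;
#'   kept for interface completeness and must be 1).
#' @param lr Adam learning rate.
#' @param lambda weight of the label-consistency loss relative to the
#'   reconstruction loss (ColorAE only; `lambda = 0` is pure autoencoding).
#' @param seed RNG seed fixing initialisation, shuffling, dropout and
#'   augmentation.
#' @param augment apply random flips and 90-degree rotations (colour jitter
#'   is deliberately excluded: it would corrupt the stain signal).
#' @param dropout dropout rate at the deepest level (U-Net only).
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 10L, batch_size = 1L, lr = 2e-3,
                         lambda = 1, seed = 1L, augment = TRUE,
                         dropout = 0.2) {
  stopifnot(epochs >= 1, batch_size == 1L, lr > 0, lambda >= 0,
            dropout >= 0, dropout < 1)
  structure(list(epochs = as.integer(epochs), batch_size = 1L, lr = lr,
                 lambda = lambda, seed = as.integer(seed),
                 augment = isTRUE(augment), dropout = dropout),
            class = "train_config")
}

#' Save / load a trained model
#'
#' Checkpoints are single serialised files embedding the parameters, the
#' stain palette / class legend and the channel order.
#'
#' @param model a `colorae_model` or `unet_model`.
#' @param path checkpoint file path.
#' @return `load_model` returns the model object.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
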