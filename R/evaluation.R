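#' DICE score between two binary masks
#'
#' \deqn{DSC = 2|A \cap B| / (|A| + |B|)}. If both masks are empty the score
#' is defined as 1 (perfect agreement on absence) and a warning is emitted.
#'
#' @param a,b logical matrices of equal shape.
#' @return DICE coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask shapes differ", call. = FALSE)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) {
    warning("both masks empty; DICE defined as 1", call. = FALSE)
    return(1)
  }
  2 * sum(a & b) / (sa + sb)
}

#' Structural similarity index (SSIM)
#'
#' Mean of the local SSIM map computed over Gaussian-weighted sliding windows
#' (window 11, sigma 1.5, k1 = 0.01, k2 = 0.03 -- the standard published
#' constants). Only windows fully inside the image contribute. Multi-channel
#' inputs are averaged per channel first.
#'
#' @param a,b single-channel matrices (or H x W x C arrays, averaged over C)
#'   of equal shape, values on a common `data_range` scale.
#' @param window odd window size in pixels.
#' @param sigma Gaussian window standard deviation.
#' @param k1,k2 stabilisation constants.
#' @param data_range dynamic range of the data (1 for \[0,1\] images).
#' @return mean SSIM in \[-1, 1\].
#' @export
ssim <- function(a, b, window = 11L, sigma = 1.5, k1 = 0.01, k2 = 0.03,
                 data_range = 1) {
  to_gray <- function(x) {
    if (length(dim(x)) == 3L) apply(x, c(1, 2), mean) else as.matrix(x)
  }
  a <- to_gray(a); b <- to_gray(b)
  if (!all(dim(a) == dim(b))) stop("image shapes differ", call. = FALSE)
  if (window > min(dim(a))) {
    stop("parameter error: window larger than image", call. = FALSE)
  }
  half <- (window - 1L) %/% 2L
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  g <- g / sum(g)
  smooth <- function(x) .sep_filter_valid(x, g)
  mu_a <- smooth(a); mu_b <- smooth(b)
  s_aa <- smooth(a * a) - mu_a^2
  s_bb <- smooth(b * b) - mu_b^2
  s_ab <- smooth(a * b) - mu_a * mu_b
  c1 <- (k1 * data_range)^2
  c2 <- (k2 * data_range)^2
  num <- (2 * mu_a * mu_b + c1) * (2 * s_ab + c2)
  den <- (mu_a^2 + mu_b^2 + c1) * (s_aa + s_bb + c2)
  mean(num / den)
}

# separable correlation with a symmetric 1-D kernel, valid region only
.sep_filter_valid <- function(x, g) {
  w <- length(g)
  H <- nrow(x); W <- ncol(x)
  # along rows (vertical)
  v <- matrix(0, H - w + 1L, W)
  for (k in seq_len(w)) v <- v + g[k] * x[k:(H - w + k), , drop = FALSE]
  out <- matrix(0, H - w + 1L, W - w + 1L)
  for (k in seq_len(w)) out <- out + g[k] * v[, k:(W - w + k), drop = FALSE]
  out
}

#' Dilated-seed detection counts
#'
#' The detection protocol counts connected components of a prediction mask
#' against the per-seed disks: TP is the number of mask components that
#' overlap at least one disk, FP the number of components overlapping no
#' disk, and FN the number of disks that overlap no mask pixel. Overlap means
#' at least one shared pixel; counting is literal (a component spanning two
#' disks is a single TP and clears both disks).
#'
#' @param mask logical prediction mask for one class.
#' @param disks a `disk_labels` object from [seeds_to_disk_labels()], or a
#'   data.frame `x`, `y`, `radius_px` of individual disks.
#' @param class_id class whose disks to use when `disks` is a `disk_labels`
#'   object (default: all rows).
#' @return a `detection_counts` list with integer `tp`, `fp`, `fn`.
#' @export
match_detections <- function(mask, disks, class_id = NULL) {
  H <- nrow(mask); W <- ncol(mask)
  df <- if (inherits(disks, "disk_labels")) {
    if (!is.null(disks$height) && (disks$height != H || disks$width != W)) {
      stop("mask shape differs from disk canvas", call. = FALSE)
    }
    d <- disks$disks
    if (!is.null(class_id)) d <- d[d$class == class_id, , drop = FALSE]
    d
  } else {
    disks
  }
  lab <- .label_mask_cpp(mask, 8L)
  n_comp <- max(lab)
  hit <- logical(n_comp)
  fn <- 0L
  if (nrow(df) > 0) {
    for (i in seq_len(nrow(df))) {
      idx <- .disk_pixels(df$y[i] + 1L, df$x[i] + 1L, df$radius_px[i], H, W)
      comps <- unique(lab[idx])
      comps <- comps[comps > 0L]
      if (length(comps) == 0L) fn <- fn + 1L else hit[comps] <- TRUE
    }
  }
  structure(list(tp = sum(hit), fp = n_comp - sum(hit), fn = fn),
            class = "detection_counts")
}

#' Pool detection counts and compute precision / recall / F1
#'
#' Counts are additive across patches; precision = TP/(TP+FP), recall =
#' TP/(TP+FN), F1 their harmonic mean. A zero denominator yields `NA`
#' (undefined), never a silent 0.
#'
#' @param counts a list of `detection_counts` (or of lists with `tp`, `fp`,
#'   `fn`).
#' @return list with pooled `tp`, `fp`, `fn` and `precision`, `recall`, `f1`.
#' @export
aggregate_and_score <- function(counts) {
  if (length(counts) == 0L) stop("no counts to aggregate", call. = FALSE)
  if (!is.null(counts$tp)) counts <- list(counts)
  tp <- sum(vapply(counts, function(x) x$tp, numeric(1)))
  fp <- sum(vapply(counts, function(x) x$fp, numeric(1)))
  fn <- sum(vapply(counts, function(x) x$fn, numeric(1)))
  p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  r <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r)
        else NA_real_
  list(tp = tp, fp = fp, fn = fn, precision = p, recall = r, f1 = f1)
}

#' Per-class metric report for a set of predictions
#'
#' Convenience wrapper building the model-by-class grid of the detection
#' protocol: for each class, counts are pooled over patches and
#' precision/recall/F1 computed; per-class DICE against truth masks is added
#' when truth is supplied.
#'
#' @param pred_masks list over patches of named per-class mask lists.
#' @param disk_sets list over patches of `disk_labels` objects.
#' @param truth_masks optional list over patches of named truth mask lists.
#' @param classes class names (default the mIHC panel).
#' @return data.frame with one row per class.
#' @export
metric_report <- function(pred_masks, disk_sets, truth_masks = NULL,
                          classes = mihc_class_names()) {
  rows <- lapply(seq_along(classes), function(k) {
    cls <- classes[k]
    counts <- lapply(seq_along(pred_masks), function(i) {
      match_detections(pred_masks[[i]][[cls]], disk_sets[[i]], class_id = k)
    })
    sc <- aggregate_and_score(counts)
    dsc <- NA_real_
    if (!is.null(truth_masks)) {
      pa <- do.call(rbind, lapply(pred_masks, function(m) m[[cls]]))
      ta <- do.call(rbind, lapply(truth_masks, function(m) m[[cls]]))
      dsc <- suppressWarnings(dice(pa, ta))
    }
    data.frame(class = cls, tp = sc$tp, fp = sc$fp, fn = sc$fn,
               precision = sc$precision, recall = sc$recall, f1 = sc$f1,
               dice = dsc)
  })
  do.call(rbind, rows)
}
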