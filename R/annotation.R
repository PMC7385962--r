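#' SLIC-style superpixels
#'
#' Partitions an image into compact, colour-homogeneous segments by k-means
#' in combined colour + space coordinates (colour channels scaled to 0-100 so
#' the conventional compactness of 10 trades a full-range colour difference
#' against one grid step). Connectivity is enforced afterwards: each maximal
#' connected region of the k-means assignment becomes its own segment, and
#' fragments smaller than a quarter of the target size are merged into the
#' neighbouring segment with which they share the longest border.
#'
#' @param img H x W x 3 RGB array in \[0, 1\].
#' @param target_segment_size_px intended segment area in pixels; the default
#'   is the squared lymphocyte diameter, (10.5 / pixel_size)^2.
#' @param compactness spatial-regularity weight (default 10).
#' @param pixel_size microns per pixel, used only for the default target size.
#' @param iters k-means iterations.
#' @return integer matrix of 1-based segment ids; every pixel belongs to
#'   exactly one connected segment.
#' @export
compute_superpixels <- function(img, target_segment_size_px = NULL,
                                compactness = 10, pixel_size = 0.175,
                                iters = 10L) {
  img <- as_rgb_array(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  if (H < 1 || W < 1) stop("empty image", call. = FALSE)
  if (is.null(target_segment_size_px)) {
    target_segment_size_px <- (10.5 / pixel_size)^2
  }
  if (target_segment_size_px >= H * W) {
    return(matrix(1L, H, W))  # single segment
  }
  step <- max(2, sqrt(target_segment_size_px))
  assign <- .slic_assign_cpp(as.numeric(img), H, W, step, compactness,
                             as.integer(iters))
  sp <- .label_partition_cpp(assign, 4L)
  .merge_small_segments(sp, min_size = max(1L, floor(target_segment_size_px /
                                                       4)))
}

# merge segments below min_size into the neighbour sharing the longest border
.merge_small_segments <- function(sp, min_size) {
  H <- nrow(sp); W <- ncol(sp)
  repeat {
    sizes <- tabulate(sp)
    small <- which(sizes > 0 & sizes < min_size)
    if (length(small) == 0L || max(sp) == 1L) break
    changed <- FALSE
    # horizontal and vertical adjacencies
    a <- c(sp[-H, ], sp[, -W]); b <- c(sp[-1, ], sp[, -1])
    diff <- a != b
    pairs <- cbind(c(a[diff], b[diff]), c(b[diff], a[diff]))
    for (s in small) {
      nb <- pairs[pairs[, 1] == s, 2]
      nb <- nb[nb != s]
      if (length(nb) == 0L) next
      tgt <- as.integer(names(which.max(table(nb))))
      sp[sp == s] <- tgt
      changed <- TRUE
      break  # adjacency table is stale after a merge
    }
    if (!changed) break
  }
  # compact ids to 1..K
  matrix(match(sp, sort(unique(as.vector(sp)))), H, W)
}

#' Superpixel weak labels from seed annotations
#'
#' Every segment containing at least one seed receives that seed's class; all
#' other segments are background (0). If one segment contains seeds of
#' several classes, the class of the seed nearest the segment centroid wins
#' and a warning reports the conflict.
#'
#' @param sp integer matrix of segment ids (from [compute_superpixels()]).
#' @param seeds data.frame with 0-based `x`, `y` and `class` (1..6).
#' @return integer label matrix (0 = background).
#' @export
seeds_to_superpixel_labels <- function(sp, seeds) {
  H <- nrow(sp); W <- ncol(sp)
  lab <- matrix(0L, H, W)
  if (nrow(seeds) == 0L) return(lab)
  bad <- seeds$x < 0 | seeds$x >= W | seeds$y < 0 | seeds$y >= H
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("annotation error: seed %d at (x=%s, y=%s) out of bounds",
                 i, seeds$x[i], seeds$y[i]), call. = FALSE)
  }
  seg_of_seed <- sp[cbind(seeds$y + 1L, seeds$x + 1L)]
  for (s in unique(seg_of_seed)) {
    in_seg <- which(seg_of_seed == s)
    cls <- unique(seeds$class[in_seg])
    if (length(cls) == 1L) {
      lab[sp == s] <- cls
    } else {
      idx <- which(sp == s)
      cr <- mean((idx - 1L) %% H + 1L)
      cc <- mean((idx - 1L) %/% H + 1L)
      d2 <- (seeds$y[in_seg] + 1L - cr)^2 + (seeds$x[in_seg] + 1L - cc)^2
      win <- seeds$class[in_seg][which.min(d2)]
      warning(sprintf(
        "segment %d contains seeds of classes {%s}; assigned class %d (seed nearest the segment centroid)",
        s, paste(sort(cls), collapse = ","), win), call. = FALSE)
      lab[sp == s] <- win
    }
  }
  lab
}

#' Dilate seed annotations into disk labels
#'
#' Each seed becomes a filled disk of radius `round(diameter / 2 /
#' pixel_size)` pixels centred on the seed. Disks of the same class may merge
#' in the per-class masks, but each seed's disk is retained individually for
#' the detection protocol ([match_detections()]). The 10.5 um default matches
#' the average lymphocyte; the 2 um variant is the conservative training
#' baseline.
#'
#' @param seeds data.frame with 0-based `x`, `y`, `class`.
#' @param height,width image size in pixels.
#' @param diameter_um disk diameter in microns (default 10.5).
#' @param pixel_size_um microns per pixel (default 0.175).
#' @return an object of class `disk_labels`: list with `masks` (named list of
#'   per-class logical matrices), `disks` (data.frame `x`, `y`, `class`,
#'   `radius_px`) and `radius_px`.
#' @export
seeds_to_disk_labels <- function(seeds, height, width, diameter_um = 10.5,
                                 pixel_size_um = 0.175) {
  if (diameter_um <= 0) {
    stop("parameter error: diameter must be positive", call. = FALSE)
  }
  r <- as.integer(round(diameter_um / 2 / pixel_size_um))
  masks <- lapply(1:6, function(k) matrix(FALSE, height, width))
  names(masks) <- mihc_class_names()
  if (nrow(seeds) > 0) {
    for (i in seq_len(nrow(seeds))) {
      idx <- .disk_pixels(seeds$y[i] + 1L, seeds$x[i] + 1L, r, height, width)
      m <- masks[[seeds$class[i]]]
      m[idx] <- TRUE
      masks[[seeds$class[i]]] <- m
    }
  }
  structure(list(masks = masks,
                 disks = data.frame(x = seeds$x, y = seeds$y,
                                    class = seeds$class,
                                    radius_px = rep(r, nrow(seeds))),
                 radius_px = r, height = height, width = width),
            class = "disk_labels")
}

# linear indices of a filled disk (pixel centres within radius r of (row, col))
.disk_pixels <- function(row, col, r, H, W) {
  rs <- max(1L, floor(row - r)):min(H, ceiling(row + r))
  cs <- max(1L, floor(col - r)):min(W, ceiling(col + r))
  dy <- rep(rs - row, times = length(cs))
  dx <- rep(cs - col, each = length(rs))
  keep <- dx^2 + dy^2 <= r^2
  (rep(rs, times = length(cs)))[keep] +
    ((rep(cs, each = length(rs)))[keep] - 1L) * H
}
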