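#' Extract connected components from a mask set
#'
#' Labels each class mask with the shared 8-connectivity routine and tabulates
#' per-component area, centroid and boundary. The boundary of a component is
#' the set of its pixels with a 4-neighbour outside the component (or on the
#' image edge).
#'
#' @param masks named list of per-class logical matrices.
#' @param pixel_size microns per pixel (stored for downstream conversions).
#' @return a `component_table`: data.frame with columns `class`, `id`,
#'   `area_px`, `centroid_x`, `centroid_y` (0-based pixel coordinates) plus
#'   attributes `pixels`/`boundary` (lists of linear index vectors), `img_dim` and
#'   `pixel_size`.
#' @export
extract_components <- function(masks, pixel_size = 0.175) {
  stopifnot(is.list(masks), length(masks) > 0)
  H <- nrow(masks[[1]]); W <- ncol(masks[[1]])
  rows <- list(); pix <- list(); bnd <- list()
  for (cls in names(masks)) {
    m <- masks[[cls]]
    lab <- .label_mask_cpp(m, 8L)
    n <- max(lab)
    if (n == 0L) next
    interior <- m
    interior[] <- m &
      rbind(FALSE, m[-H, , drop = FALSE]) &
      rbind(m[-1, , drop = FALSE], FALSE) &
      cbind(FALSE, m[, -W, drop = FALSE]) &
      cbind(m[, -1, drop = FALSE], FALSE)
    for (i in seq_len(n)) {
      idx <- which(lab == i)
      r <- (idx - 1L) %% H + 1L
      c <- (idx - 1L) %/% H + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        class = cls, id = i, area_px = length(idx),
        centroid_x = mean(c) - 1, centroid_y = mean(r) - 1)
      pix[[length(pix) + 1L]] <- idx
      bnd[[length(bnd) + 1L]] <- idx[!interior[idx]]
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(class = character(0), id = integer(0), area_px = integer(0),
               centroid_x = numeric(0), centroid_y = numeric(0))
  structure(tab, pixels = pix, boundary = bnd, img_dim = c(H, W),
            pixel_size = pixel_size, class = c("component_table",
                                               "data.frame"))
}

#' Per-class mask counts and areas
#'
#' @param table a `component_table` from [extract_components()].
#' @return data.frame with per-class component count, total area in pixels
#'   and in square microns (area_px * pixel_size^2).
#' @export
count_masks <- function(table) {
  ps <- attr(table, "pixel_size")
  if (nrow(table) == 0L) {
    return(data.frame(class = character(0), n = integer(0),
                      area_px = numeric(0), area_um2 = numeric(0)))
  }
  agg <- stats::aggregate(area_px ~ class, data = as.data.frame(table), sum)
  cnt <- stats::aggregate(id ~ class, data = as.data.frame(table), length)
  out <- merge(cnt, agg, by = "class")
  names(out) <- c("class", "n", "area_px")
  out$area_um2 <- out$area_px * ps^2
  out
}

#' Edge-to-edge nearest-neighbour distances
#'
#' For every component of the source class, the nearest-neighbour distance
#' NNDist is the minimum Euclidean distance between its pixel centres and the
#' pixel centres of any target-class component, i.e. the edge-to-edge
#' distance; overlapping components give 0 and 8-adjacent (touching)
#' components give 1 or sqrt(2) pixels. Computed exactly via a Euclidean
#' distance transform of the target union. NNDist is asymmetric: source ->
#' target generally differs from target -> source.
#'
#' @param table a `component_table`.
#' @param source_class,target_class class names present in the table's mask
#'   set.
#' @return data.frame (`nn_records`) with columns `source_class`, `source_id`,
#'   `target_class`, `distance_um`, `centroid_x`, `centroid_y` and logical
#'   `unreachable` (TRUE with `distance_um = NA` when the target class has no
#'   components).
#' @export
nearest_neighbor <- function(table, source_class, target_class) {
  ps <- attr(table, "pixel_size")
  dims <- attr(table, "img_dim")
  pix <- attr(table, "pixels")
  src <- which(table$class == source_class)
  tgt <- which(table$class == target_class)
  if (length(src) == 0L) {
    return(data.frame(source_class = character(0), source_id = integer(0),
                      target_class = character(0), distance_um = numeric(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      unreachable = logical(0)))
  }
  if (length(tgt) == 0L) {
    return(data.frame(source_class = source_class,
                      source_id = table$id[src], target_class = target_class,
                      distance_um = NA_real_,
                      centroid_x = table$centroid_x[src],
                      centroid_y = table$centroid_y[src], unreachable = TRUE))
  }
  target_mask <- matrix(FALSE, dims[1], dims[2])
  # the source class may equal the target class in principle; distances are
  # taken to the union of all target components
  for (j in tgt) target_mask[pix[[j]]] <- TRUE
  d2 <- .edt_sq_cpp(target_mask)
  dist_px <- vapply(src, function(i) sqrt(min(d2[pix[[i]]])), numeric(1))
  data.frame(source_class = source_class, source_id = table$id[src],
             target_class = target_class, distance_um = dist_px * ps,
             centroid_x = table$centroid_x[src],
             centroid_y = table$centroid_y[src], unreachable = FALSE)
}

#' Proximity histogram
#'
#' Counts nearest-neighbour records in half-open distance intervals
#' `[k*w, (k+1)*w)` from the target boundary (the classic "cells within 10 um
#' bands of the tumor edge" plot). Records at or beyond `n_bins * w` are
#' reported in the `overflow` attribute; unreachable records are ignored.
#'
#' @param records an `nn_records` data.frame from [nearest_neighbor()].
#' @param bin_width_um interval width in microns (default 10).
#' @param n_bins number of intervals.
#' @return integer vector of counts (named by interval), with attribute
#'   `overflow`.
#' @export
proximity_histogram <- function(records, bin_width_um = 10, n_bins = 10L) {
  stopifnot(bin_width_um > 0, n_bins >= 1)
  d <- records$distance_um[!is.na(records$distance_um)]
  bin <- floor(d / bin_width_um)
  counts <- vapply(0:(n_bins - 1L), function(k) sum(bin == k), integer(1))
  names(counts) <- sprintf("[%g,%g)", (0:(n_bins - 1L)) * bin_width_um,
                           (1:n_bins) * bin_width_um)
  attr(counts, "overflow") <- sum(bin >= n_bins)
  counts
}

#' Tile-based aggregation of nearest-neighbour distances
#'
#' Records are assigned to square tiles by their source-component centroid
#' (half-open tiling: a centroid at x = tile_px belongs to the next column).
#' The per-tile statistic (default median) is computed for tiles containing
#' at least one record and then summarised across tiles (default mean),
#' mirroring the whole-slide practice of averaging per-tile medians within
#' the annotated tumor region.
#'
#' @param records an `nn_records` data.frame.
#' @param tile_px tile side length in pixels (default 2000).
#' @param tile_stat per-tile summary function (default `median`).
#' @param cross_stat cross-tile summary function (default `mean`).
#' @return list with `per_tile` (data.frame `tile_row`, `tile_col`, `n`,
#'   `value`) and scalar `summary`.
#' @export
tile_aggregate <- function(records, tile_px = 2000L, tile_stat = stats::median,
                           cross_stat = mean) {
  stopifnot(tile_px > 0)
  rec <- records[!is.na(records$distance_um), , drop = FALSE]
  if (nrow(rec) == 0L) {
    return(list(per_tile = data.frame(tile_row = integer(0),
                                      tile_col = integer(0), n = integer(0),
                                      value = numeric(0)),
                summary = NA_real_))
  }
  tr <- floor(rec$centroid_y / tile_px)
  tc <- floor(rec$centroid_x / tile_px)
  key <- paste(tr, tc)
  per <- lapply(unique(key), function(k) {
    sel <- key == k
    data.frame(tile_row = tr[sel][1], tile_col = tc[sel][1], n = sum(sel),
               value = tile_stat(rec$distance_um[sel]))
  })
  per <- do.call(rbind, per)
  list(per_tile = per, summary = cross_stat(per$value))
}

#' Restrict a component table to a region of interest
#'
#' Components whose centroid (rounded to the nearest pixel) lies inside the
#' region mask are kept; everything else is dropped. Used to confine spatial
#' statistics to a pathologist-annotated tumor region.
#'
#' @param table a `component_table`.
#' @param region logical matrix of the same shape as the source masks.
#' @return a filtered `component_table`.
#' @export
restrict_to_region <- function(table, region) {
  dims <- attr(table, "img_dim")
  if (!all(dim(region) == dims)) stop("region shape differs", call. = FALSE)
  if (nrow(table) == 0L) return(table)
  r <- pmin(pmax(round(table$centroid_y) + 1L, 1L), dims[1])
  c <- pmin(pmax(round(table$centroid_x) + 1L, 1L), dims[2])
  keep <- region[cbind(r, c)]
  out <- table[keep, , drop = FALSE]
  attr(out, "pixels") <- attr(table, "pixels")[keep]
  attr(out, "boundary") <- attr(table, "boundary")[keep]
  attr(out, "img_dim") <- dims
  attr(out, "pixel_size") <- attr(table, "pixel_size")
  class(out) <- c("component_table", "data.frame")
  out
}

#' Write nearest-neighbour records to CSV
#'
#' @param records an `nn_records` data.frame.
#' @param path output CSV path.
#' @param tile_px tile size used to annotate tile coordinates.
#' @return `path`, invisibly.
#' @export
write_nn_records <- function(records, path, tile_px = 2000L) {
  rec <- records
  rec$tile_row <- floor(rec$centroid_y / tile_px)
  rec$tile_col <- floor(rec$centroid_x / tile_px)
  utils::write.csv(rec[, c("source_class", "source_id", "target_class",
                           "distance_um", "tile_row", "tile_col")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
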