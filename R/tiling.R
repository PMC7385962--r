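#' Partition an image into overlapping patches
#'
#' Patches of `patch` pixels are laid on a grid with `overlap` pixels of
#' overlap; the last row/column is shifted inward so every pixel is covered.
#' A patch larger than the image yields a single patch.
#'
#' @param img H x W x C array (or matrix).
#' @param patch patch side length in pixels.
#' @param overlap overlap between neighbouring patches (must be < `patch`).
#' @return list with `patches` (list of arrays) and `offsets` (data.frame
#'   `row`, `col`, 1-based top-left corners).
#' @export
tile_image <- function(img, patch, overlap = 0L) {
  stopifnot(overlap < patch, patch > 0)
  d <- dim(img)
  H <- d[1]; W <- d[2]
  starts <- function(n) {
    if (patch >= n) return(1L)
    s <- seq(1L, n - patch + 1L, by = patch - overlap)
    if (s[length(s)] + patch - 1L < n) s <- c(s, n - patch + 1L)
    s
  }
  rs <- starts(H); cs <- starts(W)
  offsets <- expand.grid(row = rs, col = cs)
  patches <- lapply(seq_len(nrow(offsets)), function(i) {
    r0 <- offsets$row[i]; c0 <- offsets$col[i]
    ri <- r0:min(H, r0 + patch - 1L)
    ci <- c0:min(W, c0 + patch - 1L)
    if (length(d) == 3L) img[ri, ci, , drop = FALSE]
    else img[ri, ci, drop = FALSE]
  })
  list(patches = patches, offsets = offsets)
}

#' Stitch binary mask patches back to full size
#'
#' The inverse of [tile_image()] for mask data: overlapping regions are
#' combined by OR, so stitching is exact when the overlaps agree.
#'
#' @param patches list of logical matrices.
#' @param offsets data.frame `row`, `col` as returned by [tile_image()].
#' @param height,width output size.
#' @return logical matrix.
#' @export
stitch_masks <- function(patches, offsets, height, width) {
  out <- matrix(FALSE, height, width)
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    r0 <- offsets$row[i]; c0 <- offsets$col[i]
    ri <- r0:(r0 + nrow(p) - 1L)
    ci <- c0:(c0 + ncol(p) - 1L)
    out[ri, ci] <- out[ri, ci] | p
  }
  out
}
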