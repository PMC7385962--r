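#' Mask ensemble operators
#'
#' The four operators combining per-class binary predictions from the colour
#' autoencoder and the U-Net:
#' \describe{
#'   \item{`mask_union`}{pixelwise OR -- predictions from both models,
#'     overlaps merged into a single mask.}
#'   \item{`mask_intersection`}{pixelwise AND -- only pixels identified by
#'     both models.}
#'   \item{`union_anchor`}{the union restricted to connected components that
#'     contain at least one pixel of the anchor mask:
#'     `union_anchor(colorae, unet)` keeps union components containing
#'     autoencoder pixels ("union anchor AE"); swapping arguments gives
#'     "union anchor U-Net".}
#' }
#' Components use the package-wide 8-connectivity convention. Operators act
#' on one class at a time; use [ensemble_masksets()] for whole mask sets.
#'
#' @param a,b,anchor,other logical matrices of equal shape.
#' @return logical matrix.
#' @export
mask_union <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask shapes differ", call. = FALSE)
  a | b
}

#' @rdname mask_union
#' @export
mask_intersection <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask shapes differ", call. = FALSE)
  a & b
}

#' @rdname mask_union
#' @export
union_anchor <- function(anchor, other) {
  if (!all(dim(anchor) == dim(other))) {
    stop("mask shapes differ", call. = FALSE)
  }
  u <- anchor | other
  lab <- .label_mask_cpp(u, 8L)
  keep <- unique(lab[anchor])
  keep <- keep[keep > 0L]
  matrix(lab %in% keep, nrow(u), ncol(u))
}

#' Apply an ensemble operator to two mask sets
#'
#' Classes are combined independently; cross-class overlap between the two
#' models is preserved (a pixel may stay positive in masks of different
#' classes -- both labels are treated as valid).
#'
#' @param colorae_masks,unet_masks named lists of per-class logical masks.
#' @param operator one of `"union"`, `"intersection"`, `"union_anchor_ae"`,
#'   `"union_anchor_unet"`.
#' @return named list of combined masks with a `provenance` attribute.
#' @export
ensemble_masksets <- function(colorae_masks, unet_masks,
                              operator = c("union", "intersection",
                                           "union_anchor_ae",
                                           "union_anchor_unet")) {
  operator <- match.arg(operator)
  stopifnot(identical(names(colorae_masks), names(unet_masks)))
  f <- switch(operator,
    union = mask_union,
    intersection = mask_intersection,
    union_anchor_ae = union_anchor,
    union_anchor_unet = function(a, b) union_anchor(b, a))
  out <- lapply(names(colorae_masks), function(nm) {
    f(colorae_masks[[nm]], unet_masks[[nm]])
  })
  names(out) <- names(colorae_masks)
  attr(out, "provenance") <- paste0("ensemble:", operator)
  out
}
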