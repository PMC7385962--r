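#' Read and write RGB images
#'
#' Images are handled internally as H x W x 3 double arrays on a \[0, 1\]
#' intensity scale; 8-bit PNG and TIFF are converted on read/write (format
#' chosen by file extension).
#'
#' @param path file path (`.png`, `.tif` or `.tiff`).
#' @return `read_image_rgb` returns an H x W x 3 array in \[0, 1\].
#' @export
read_image_rgb <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("the 'tiff' package is required to read TIFF files",
             call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' @rdname read_image_rgb
#' @param img H x W x 3 array in \[0, 1\].
#' @export
write_image_rgb <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("the 'tiff' package is required to write TIFF files",
             call. = FALSE)
      }
      tiff::writeTIFF(img, path, bits.per.sample = 8L)
    },
    stop("unsupported image format: ", ext, call. = FALSE))
  invisible(path)
}

#' Read and write seed (dot) annotations
#'
#' Seeds are CSV records with columns `x`, `y`, `class`: 0-based pixel
#' coordinates (`x` = column, `y` = row, pixel centres at integer
#' coordinates) and an integer class id in 1..6.
#'
#' @param path CSV file path.
#' @return `read_seeds` returns a data.frame with columns `x`, `y`, `class`.
#' @export
read_seeds <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  stopifnot(all(c("x", "y", "class") %in% names(df)))
  df[, c("x", "y", "class")]
}

#' @rdname read_seeds
#' @param seeds data.frame with columns `x`, `y`, `class`.
#' @export
write_seeds <- function(seeds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# x,y: 0-based pixel coordinates (x = column, y = row)", con)
  utils::write.csv(seeds[, c("x", "y", "class")], con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read and write per-pixel label maps
#'
#' Label maps (integer matrices; 0 = background, 1..6 the stain classes,
#' optionally 7 = hematoxylin) are stored as indexed 8-bit grayscale PNGs
#' whose pixel value is the class id, with a sidecar JSON legend mapping ids
#' to class names.
#'
#' @param labels integer matrix of class ids.
#' @param path PNG file path; the legend is written to `<path>.legend.json`.
#' @param legend named character vector mapping ids to class names.
#' @return `read_label_png` returns an integer matrix with a `legend`
#'   attribute when the sidecar is present.
#' @export
write_label_png <- function(labels, path,
                            legend = stats::setNames(mihc_class_names(),
                                                     1:6)) {
  png::writePNG(labels / 255, path)
  jsonlite::write_json(as.list(legend), paste0(path, ".legend.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_label_png
#' @export
read_label_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  lab <- matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  legend_path <- paste0(path, ".legend.json")
  if (file.exists(legend_path)) {
    attr(lab, "legend") <- unlist(jsonlite::read_json(legend_path))
  }
  lab
}

#' Class names of the mIHC panel
#'
#' @return the six chromogen-labelled cell classes, in channel order.
#' @export
mihc_class_names <- function() c("CD3", "CD4", "CD8", "CD20", "CD16", "K17")

#' Read and write a set of per-class binary masks
#'
#' A mask set is a named list of H x W logical matrices (one per class, names
#' from the class legend) with a `provenance` attribute
#' (`"colorae"`, `"unet"` or `"ensemble:<name>"`). On disk it is a directory
#' of binary PNGs `<class>.png` plus `masks.json` metadata.
#'
#' @param masks named list of logical matrices.
#' @param dir directory to write to (created if missing).
#' @return `read_maskset` returns the named list with provenance restored.
#' @export
write_maskset <- function(masks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(masks)) {
    png::writePNG(masks[[nm]] * 1, file.path(dir, paste0(nm, ".png")))
  }
  meta <- list(classes = names(masks),
               provenance = attr(masks, "provenance") %||% "unknown")
  jsonlite::write_json(meta, file.path(dir, "masks.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_maskset
#' @export
read_maskset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "masks.json"),
                              simplifyVector = TRUE)
  masks <- lapply(meta$classes, function(nm) {
    m <- png::readPNG(file.path(dir, paste0(nm, ".png")))
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m > 0.5
  })
  names(masks) <- meta$classes
  attr(masks, "provenance") <- meta$provenance
  masks
}

`%||%` <- function(a, b) if (is.null(a)) b else a
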