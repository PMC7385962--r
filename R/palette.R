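#' Stain palette
#'
#' A stain palette binds channel names to optical-density (OD) colour vectors
#' and records the white point \eqn{I_0} of the Beer-Lambert model. The
#' conventional mIHC panel has six chromogen channels (yellow CD3, teal CD4,
#' purple CD8, red CD20, black CD16, brown K17) plus the hematoxylin
#' counterstain and a grey background channel.
#'
#' @param names character vector of channel names.
#' @param od_vectors numeric 3 x K matrix; column k is the OD 3-vector of
#'   channel k per unit concentration (natural-log convention).
#' @param white_point RGB intensity triple on the internal \[0, 1\] scale;
#'   strictly positive.
#' @return An object of class `stain_palette`.
#' @export
stain_palette <- function(names, od_vectors, white_point = c(1, 1, 1)) {
  od_vectors <- as.matrix(od_vectors)
  if (nrow(od_vectors) != 3L || ncol(od_vectors) != length(names)) {
    stop("od_vectors must be a 3 x length(names) matrix", call. = FALSE)
  }
  if (any(!is.finite(od_vectors)) || any(od_vectors < 0)) {
    stop("invalid palette: od_vectors must be finite and nonnegative",
         call. = FALSE)
  }
  if (length(white_point) != 3L || any(!is.finite(white_point)) ||
      any(white_point <= 0)) {
    stop("invalid palette: white_point must be strictly positive",
         call. = FALSE)
  }
  colnames(od_vectors) <- names
  obj <- structure(
    list(names = as.character(names), od_vectors = od_vectors,
         white_point = as.numeric(white_point)),
    class = "stain_palette")
  validate_palette(obj)
  obj
}

#' @rdname stain_palette
#' @param x a `stain_palette`.
#' @export
validate_palette <- function(x) {
  stopifnot(inherits(x, "stain_palette"))
  nrm <- sqrt(colSums(x$od_vectors^2))
  stain_idx <- which(!x$names %in% c("hematoxylin", "background"))
  if (any(nrm[stain_idx] <= 0)) {
    stop("invalid palette: stain OD vectors must have positive norm",
         call. = FALSE)
  }
  if (length(stain_idx) >= 2) {
    ang <- palette_min_angle(x, stain_idx)
    if (ang <= 0) {
      stop("invalid palette: stain OD vectors must be pairwise non-parallel",
           call. = FALSE)
    }
  }
  invisible(x)
}

#' Minimum pairwise angle between stain vectors
#'
#' @param palette a `stain_palette`.
#' @param idx indices of the channels to compare (default: all channels that
#'   are neither hematoxylin nor background).
#' @return smallest pairwise angle in degrees.
#' @export
palette_min_angle <- function(palette,
                              idx = which(!palette$names %in%
                                            c("hematoxylin", "background"))) {
  v <- palette$od_vectors[, idx, drop = FALSE]
  v <- sweep(v, 2, sqrt(colSums(v^2)), "/")
  ang <- Inf
  n <- ncol(v)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cs <- min(1, max(-1, sum(v[, i] * v[, j])))
      ang <- min(ang, acos(cs) * 180 / pi)
    }
  }
  ang
}

#' @export
print.stain_palette <- function(x, ...) {
  cat("stain_palette with", length(x$names), "channels:",
      paste(x$names, collapse = ", "), "\n")
  cat("white point:", paste(signif(x$white_point, 4), collapse = " "), "\n")
  invisible(x)
}

#' Read / write a stain palette
#'
#' Palettes are serialised as YAML (or JSON, by file extension): channel
#' names, per-channel OD 3-vectors, and the white point.
#'
#' @param palette a `stain_palette`.
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_palette` returns a `stain_palette`; `write_palette` returns
#'   `path` invisibly.
#' @export
write_palette <- function(palette, path) {
  validate_palette(palette)
  rec <- list(
    names = palette$names,
    od_vectors = lapply(seq_along(palette$names),
                        function(i) as.numeric(palette$od_vectors[, i])),
    white_point = palette$white_point)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(rec, path, auto_unbox = FALSE, digits = NA)
  } else {
    yaml::write_yaml(rec, path, precision = 15L)
  }
  invisible(path)
}

#' @rdname write_palette
#' @export
read_palette <- function(path) {
  ext <- tolower(tools::file_ext(path))
  rec <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  od <- if (is.matrix(rec$od_vectors)) {
    t(rec$od_vectors)  # readers may simplify the vector list to channels x 3
  } else {
    do.call(cbind, lapply(rec$od_vectors, as.numeric))
  }
  stain_palette(rec$names, od, as.numeric(rec$white_point))
}

#' Generate a reproducible mIHC stain palette
#'
#' Builds the six-chromogen panel (yellow, teal, purple, red, black, brown)
#' plus hematoxylin and grey background from reference chromogen colours with
#' a small seeded jitter, re-drawing until the six stain vectors are pairwise
#' separated by at least `min_angle_deg`.
#'
#' @param seed integer RNG seed; the palette is deterministic given the seed.
#' @param min_angle_deg minimum pairwise angle (degrees) between the six
#'   stain OD vectors (default 15).
#' @return a `stain_palette` with channels
#'   `c("CD3","CD4","CD8","CD20","CD16","K17","hematoxylin","background")`.
#' @export
generate_palette <- function(seed = 1L, min_angle_deg = 15) {
  base_rgb <- rbind(
    CD3  = c(0.93, 0.88, 0.22),  # yellow
    CD4  = c(0.20, 0.75, 0.75),  # teal
    CD8  = c(0.52, 0.22, 0.62),  # purple
    CD20 = c(0.85, 0.16, 0.22),  # red
    CD16 = c(0.25, 0.25, 0.30),  # silver-black
    K17  = c(0.58, 0.37, 0.16),  # DAB brown
    hematoxylin = c(0.45, 0.47, 0.80),
    background  = c(0.93, 0.93, 0.93))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  for (attempt in 1:50) {
    jit <- matrix(stats::runif(24, -0.04, 0.04), 8, 3)
    rgb <- pmax(pmin(base_rgb + jit, 0.98), 0.02)
    od <- t(-log(rgb))  # 3 x 8, natural log, white point 1
    pal <- stain_palette(rownames(base_rgb), od, c(1, 1, 1))
    if (palette_min_angle(pal, 1:6) >= min_angle_deg) return(pal)
  }
  stop("could not generate a palette with the requested angular separation",
       call. = FALSE)
}
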