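#' Optical-density transforms
#'
#' Under the Beer-Lambert law the optical density of a pixel,
#' \eqn{OD = -\log(I / I_0)} (natural log), is additive over absorbing
#' stains: \eqn{OD = \sum_s c_s v_s} with \eqn{c_s \ge 0} the stain
#' concentration and \eqn{v_s} the stain's OD colour vector. `rgb_to_od`
#' maps intensities to OD; `od_to_rgb` is its exact inverse. Intensities are
#' floored at `eps` times the white point before the log so saturated (black)
#' pixels stay finite.
#'
#' @param img H x W x 3 array of RGB intensities on the internal \[0, 1\]
#'   scale (or a length-3 vector for a single pixel).
#' @param white_point strictly positive RGB triple \eqn{I_0}.
#' @param eps intensity floor as a fraction of the white point
#'   (default 1/255).
#' @return `rgb_to_od`: array of the same shape holding nonnegative optical
#'   densities; `od_to_rgb`: intensities in `(0, white_point]`.
#' @export
rgb_to_od <- function(img, white_point = c(1, 1, 1), eps = 1 / 255) {
  if (any(!is.finite(white_point)) || any(white_point <= 0)) {
    stop("invalid palette: white_point must be strictly positive",
         call. = FALSE)
  }
  x <- as_rgb_array(img)
  od <- x
  for (k in 1:3) {
    ik <- pmin(pmax(x[, , k], eps * white_point[k]), white_point[k])
    od[, , k] <- -log(ik / white_point[k])
  }
  od
}

#' @rdname rgb_to_od
#' @param od H x W x 3 array of nonnegative optical densities.
#' @export
od_to_rgb <- function(od, white_point = c(1, 1, 1)) {
  if (any(!is.finite(white_point)) || any(white_point <= 0)) {
    stop("invalid palette: white_point must be strictly positive",
         call. = FALSE)
  }
  x <- as_rgb_array(od)
  if (any(x < 0)) stop("optical densities must be nonnegative", call. = FALSE)
  out <- x
  for (k in 1:3) out[, , k] <- white_point[k] * exp(-x[, , k])
  out
}

as_rgb_array <- function(img) {
  if (is.null(dim(img)) && length(img) == 3L) {
    img <- array(rep(img, each = 1), dim = c(1, 1, 3))
  }
  if (length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop("expected an H x W x 3 array", call. = FALSE)
  }
  if (any(!is.finite(img))) stop("non-finite intensities", call. = FALSE)
  img
}

#' Render an image from stain concentrations (Beer-Lambert forward model)
#'
#' Per pixel, \eqn{OD = \sum_s c_s v_s} over the palette channels, converted
#' to intensities by `od_to_rgb`, with optional additive Gaussian noise
#' (clipped back to \[0, white point\]).
#'
#' @param conc H x W x K concentration array, channel order matching
#'   `palette$names`.
#' @param palette a [stain_palette()].
#' @param noise_sd standard deviation of additive intensity noise (0 = none).
#' @return H x W x 3 RGB array.
#' @export
render_beer_lambert <- function(conc, palette, noise_sd = 0) {
  validate_palette(palette)
  d <- dim(conc)
  if (length(d) != 3L || d[3] != length(palette$names)) {
    stop(sprintf("concentration channels (%d) do not match palette (%d)",
                 if (length(d) == 3L) d[3] else -1L, length(palette$names)),
         call. = FALSE)
  }
  if (any(conc < 0)) stop("concentrations must be nonnegative", call. = FALSE)
  n <- d[1] * d[2]
  cmat <- matrix(conc, n, d[3])
  od <- cmat %*% t(palette$od_vectors)  # n x 3
  img <- array(0, dim = c(d[1], d[2], 3))
  for (k in 1:3) {
    img[, , k] <- palette$white_point[k] * exp(-matrix(od[, k], d[1], d[2]))
  }
  if (noise_sd > 0) {
    img <- img + array(stats::rnorm(3 * n, 0, noise_sd), dim = dim(img))
    for (k in 1:3) {
      img[, , k] <- pmin(pmax(img[, , k], 0), palette$white_point[k])
    }
  }
  img
}

#' Exact linear stain deconvolution (up to three stains)
#'
#' With at most three stains the Beer-Lambert system \eqn{OD = V c} is
#' determined and is solved per pixel by least squares; negative components
#' are clipped to zero. With more than three stains the system is
#' underdetermined and an error is raised (that regime is what the
#' autoencoder is for; see [train_colorae()]).
#'
#' @param img H x W x 3 RGB array.
#' @param palette a [stain_palette()] restricted to at most 3 channels.
#' @param eps intensity floor passed to [rgb_to_od()].
#' @return H x W x K nonnegative concentration array in palette order.
#' @export
deconvolve_linear <- function(img, palette, eps = 1 / 255) {
  validate_palette(palette)
  K <- length(palette$names)
  if (K > 3L) {
    stop("more than 3 stains: the linear equation system becomes ",
         "underdetermined; use the autoencoder instead", call. = FALSE)
  }
  V <- palette$od_vectors
  if (qr(V)$rank < K) {
    stop("singular palette: stain vectors are linearly dependent",
         call. = FALSE)
  }
  od <- rgb_to_od(img, palette$white_point, eps = eps)
  d <- dim(od)
  odm <- matrix(od, d[1] * d[2], 3)
  sol <- t(qr.solve(V, t(odm)))  # least squares, n x K
  sol[sol < 0] <- 0
  array(sol, dim = c(d[1], d[2], K))
}
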