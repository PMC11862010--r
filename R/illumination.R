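# Retrospective flat-field illumination correction: estimate a smooth
# per-channel correction surface from the mean of many well images, and
# divide it out. Standard divisive correction for uneven excitation /
# vignetting in fluorescence microscopy.

# Gaussian smoothing with replicate (edge-extension) boundary. The brush is
# capped to the image size; a circular boundary would wrap intensity across
# edges and distort gradients there.
.smooth2d <- function(mat, sigma) {
  size <- 2L * ceiling(2 * sigma) + 1L
  size <- min(size, min(dim(mat)))
  if (size %% 2L == 0L) size <- size - 1L
  size <- max(3L, size)
  brush <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  as.matrix(EBImage::filter2(mat, brush, boundary = "replicate"))
}

#' Estimate a per-channel illumination profile
#'
#' Averages a collection of well images per channel and smooths the result
#' at a large spatial scale, yielding a strictly positive, mean-1
#' correction surface per channel (retrospective flat-fielding: the
#' biology averages out across wells, the optics do not).
#'
#' @param images list of `3 x H x W` arrays (or a single array), all the
#'   same shape.
#' @param smoothing_scale Gaussian sigma in pixels; default is 1/4 of the
#'   image side, large enough that individual cells do not imprint on the
#'   profile.
#' @return An `illumination_profile`: array `3 x H x W`, each channel
#'   strictly positive with mean 1 (to within 1e-6).
#' @export
estimate_illumination <- function(images, smoothing_scale = NULL) {
  if (is.array(images) && !is.list(images)) images <- list(images)
  if (length(images) == 0) stop("need at least one image to estimate illumination")
  d <- dim(images[[1]])
  if (length(d) != 3) stop("images must be channels x H x W arrays")
  for (im in images) {
    if (!identical(dim(im), d)) stop("all images must share the same shape")
  }
  if (is.null(smoothing_scale)) smoothing_scale <- min(d[2], d[3]) / 4
  stopifnot(smoothing_scale > 0)

  mean_img <- Reduce(`+`, images) / length(images)
  prof <- array(1, dim = d, dimnames = dimnames(images[[1]]))
  for (ch in seq_len(d[1])) {
    sm <- .smooth2d(matrix(mean_img[ch, , ], d[2], d[3]), smoothing_scale)
    sm <- pmax(sm, 1e-8)       # strictly positive even for empty channels
    prof[ch, , ] <- sm / mean(sm)
  }
  class(prof) <- c("illumination_profile", class(prof))
  prof
}

#' Apply divisive illumination correction
#'
#' @param image `3 x H x W` array.
#' @param profile an [estimate_illumination()] profile of the same shape.
#' @return The corrected image, `image / profile` element-wise; nonnegative
#'   inputs stay nonnegative because the profile is strictly positive.
#' @export
apply_illumination <- function(image, profile) {
  if (!identical(dim(image), dim(unclass(profile))))
    stop("image and illumination profile shapes differ")
  out <- image / unclass(profile)
  dimnames(out) <- dimnames(image)
  out
}

#' Percentile intensity normalization of one channel
#'
#' Rescales a channel so its `q`-th percentile maps to `out_max`, then
#' clips to `[0, out_max]`: `clip(pixels / percentile_q * out_max, 0,
#' out_max)`. With the defaults (q = 99, out_max = 255) this is the usual
#' contrast standardisation applied to fluorescence channels before
#' feeding crops to a pre-trained network: the brightest 1% of pixels
#' saturate at 255 and the rest use the full dynamic range.
#'
#' Percentiles use linear interpolation between order statistics
#' (`quantile(..., type = 7)`).
#'
#' @param channel numeric matrix or vector of nonnegative intensities.
#' @param q percentile in `(0, 100]`.
#' @param out_max output ceiling.
#' @return Channel of the same shape with values in `[0, out_max]`. An
#'   all-zero channel (percentile 0) is returned as all zeros with a
#'   warning rather than dividing by zero.
#' @export
percentile_normalize <- function(channel, q = 99, out_max = 255) {
  stopifnot(length(channel) > 0, q > 0, q <= 100, out_max > 0)
  p <- stats::quantile(channel, q / 100, names = FALSE, type = 7)
  if (p <= 0) {
    warning("channel percentile is 0 (all-zero channel?); returning zeros")
    channel[] <- 0
    return(channel)
  }
  out <- channel / p * out_max
  out[out > out_max] <- out_max
  out[out < 0] <- 0
  out
}
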