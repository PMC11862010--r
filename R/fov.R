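# Field-of-view tiling. A well is imaged as four overlapping camera tiles
# (2 x 2); split_into_fovs cuts a well image into those tiles and
# merge_fovs reassembles them. The two are exact inverses: overlap pixels
# in the tiles are copies of the parent image, and merge keeps the
# top-/left-most tile's pixels in each overlap band.

.as_chw <- function(image) {
  if (is.matrix(image)) {
    array(image, dim = c(1L, nrow(image), ncol(image)))
  } else if (is.array(image) && length(dim(image)) == 3) {
    image
  } else stop("image must be a matrix or a channels x H x W array")
}

#' Split a well image into four overlapping fields of view
#'
#' Cuts a square image into a 2 x 2 tiling in which adjacent tiles share
#' `overlap_px` identical rows/columns, mimicking a microscope acquiring
#' four FOVs with a small percentage overlap.
#'
#' @param image matrix (`H x W`) or array (`channels x H x W`); must be
#'   square with side `S` such that `(S + overlap_px) / 2` is an integer.
#' @param overlap_px number of shared pixels between adjacent tiles
#'   (`0 <= overlap_px < tile side`).
#' @return List of four tiles (`top_left`, `top_right`, `bottom_left`,
#'   `bottom_right`), each of the input's type.
#' @seealso [merge_fovs()] for the exact inverse.
#' @export
split_into_fovs <- function(image, overlap_px) {
  was_matrix <- is.matrix(image)
  x <- .as_chw(image)
  d <- dim(x)
  if (d[2] != d[3]) stop("image must be square, got ", d[2], " x ", d[3])
  S <- d[2]
  stopifnot(.is_count(overlap_px), overlap_px >= 0)
  if ((S + overlap_px) %% 2 != 0)
    stop("side length ", S, " is incompatible with overlap ", overlap_px,
         ": (side + overlap) must be even")
  t <- (S + overlap_px) / 2
  if (overlap_px >= t)
    stop("overlap ", overlap_px, " must be smaller than the tile side ", t)
  first <- 1:t
  second <- (t - overlap_px + 1):S
  cn <- dimnames(x)[1]
  take <- function(r, c) {
    out <- x[, r, c, drop = FALSE]
    dim(out) <- c(d[1], t, t)
    if (was_matrix) out <- matrix(out[1, , ], t, t)
    else if (!is.null(cn[[1]])) dimnames(out) <- c(cn, list(NULL, NULL))
    out
  }
  list(top_left = take(first, first), top_right = take(first, second),
       bottom_left = take(second, first), bottom_right = take(second, second))
}

#' Merge four fields of view into a well-level image
#'
#' Stacks the tiles horizontally in pairs and then vertically, accounting
#' for the edge overlap: the output side is `2 * tile_side - overlap_px`,
#' and each overlap band keeps the pixels of the top-/left-most tile.
#'
#' @param tiles list of four tiles as produced by [split_into_fovs()]
#'   (order: top_left, top_right, bottom_left, bottom_right), all of
#'   identical shape.
#' @param overlap_px shared pixels between adjacent tiles.
#' @return Merged image of the tiles' type (matrix or `channels x H x W`).
#' @export
merge_fovs <- function(tiles, overlap_px) {
  if (length(tiles) != 4) stop("expected exactly four tiles")
  was_matrix <- is.matrix(tiles[[1]])
  xs <- lapply(tiles, .as_chw)
  dims <- vapply(xs, dim, integer(3))
  if (any(dims != dims[, 1]))
    stop("all four tiles must have identical shape")
  d <- dims[, 1]
  if (d[2] != d[3]) stop("tiles must be square")
  t <- d[2]
  stopifnot(.is_count(overlap_px), overlap_px >= 0)
  if (overlap_px >= t) stop("overlap must be smaller than the tile side ", t)
  S <- 2 * t - overlap_px
  out <- array(vector(typeof(xs[[1]]), d[1] * S * S), dim = c(d[1], S, S))
  first <- 1:t
  second <- (t - overlap_px + 1):S
  # later assignments win, so paint in reverse priority order:
  out[, second, second] <- xs[[4]]
  out[, second, first] <- xs[[3]]
  out[, first, second] <- xs[[2]]
  out[, first, first] <- xs[[1]]
  if (was_matrix) {
    out <- matrix(out[1, , ], S, S)
  } else {
    cn <- dimnames(xs[[1]])[1]
    if (!is.null(cn[[1]])) dimnames(out) <- c(cn, list(NULL, NULL))
  }
  out
}
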