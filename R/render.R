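#' Scene specification for the synthetic well renderer
#'
#' One row per cell to draw. Cells are rendered as ellipses (thresholded
#' anisotropic Gaussian blobs) whose area matches a disk of radius `size`;
#' `eccentricity` stretches the ellipse at constant area, so fibroblasts
#' can be given their characteristic elongated shape.
#'
#' @param population `"cancer"` or `"fibroblast"` per cell.
#' @param centroid_row,centroid_col cell centres, 0-based pixel coordinates.
#' @param size equivalent disk radius in pixels.
#' @param orientation major-axis angle in radians.
#' @param eccentricity target eccentricity in `[0, 1)`.
#' @return A `scene_spec` data frame.
#' @export
scene_spec <- function(population, centroid_row, centroid_col, size,
                       orientation = 0, eccentricity = 0) {
  stopifnot(all(population %in% c("cancer", "fibroblast")),
            all(size > 0), all(eccentricity >= 0), all(eccentricity < 1))
  out <- data.frame(
    population = as.character(population),
    centroid_row = centroid_row, centroid_col = centroid_col,
    size = size, orientation = rep_len(orientation, length(population)),
    eccentricity = rep_len(eccentricity, length(population)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("scene_spec", "data.frame")
  out
}

#' Draw a random non-overlapping scene
#'
#' Places cancer cells (round, `eccentricity ~ 0.3`) and fibroblasts
#' (elongated, `eccentricity ~ 0.9`) at random positions with a minimum
#' centre distance, by rejection sampling.
#'
#' @param n_cancer,n_fibroblast cell counts (>= 0).
#' @param image_size `(H, W)` in pixels.
#' @param cancer_size,fibroblast_size equivalent-radius ranges.
#' @param min_dist minimum centre-to-centre distance in pixels.
#' @param seed integer seed.
#' @return A [scene_spec()].
#' @export
random_scene <- function(n_cancer, n_fibroblast, image_size = c(195, 195),
                         cancer_size = c(6, 10), fibroblast_size = c(8, 12),
                         min_dist = 22, seed = 1) {
  stopifnot(n_cancer >= 0, n_fibroblast >= 0, all(image_size > 0))
  n <- n_cancer + n_fibroblast
  if (n == 0) {
    return(scene_spec(character(0), numeric(0), numeric(0), numeric(0)))
  }
  margin <- max(cancer_size[2], fibroblast_size[2]) + 2
  withr::with_seed(seed, {
    pts <- matrix(NA_real_, 0, 2)
    tries <- 0
    while (nrow(pts) < n && tries < 200 * n) {
      cand <- c(stats::runif(1, margin, image_size[1] - 1 - margin),
                stats::runif(1, margin, image_size[2] - 1 - margin))
      if (nrow(pts) == 0 ||
          min(sqrt(rowSums(sweep(pts, 2, cand)^2))) >= min_dist)
        pts <- rbind(pts, cand)
      tries <- tries + 1
    }
    if (nrow(pts) < n)
      stop("could not place ", n, " cells at min_dist = ", min_dist,
           " in a ", image_size[1], "x", image_size[2], " image")
    pop <- c(rep("cancer", n_cancer), rep("fibroblast", n_fibroblast))
    sz <- ifelse(pop == "cancer",
                 stats::runif(n, cancer_size[1], cancer_size[2]),
                 stats::runif(n, fibroblast_size[1], fibroblast_size[2]))
    ecc <- ifelse(pop == "cancer",
                  stats::runif(n, 0.1, 0.45), stats::runif(n, 0.85, 0.95))
    scene_spec(pop, pts[, 1], pts[, 2], sz,
               orientation = stats::runif(n, 0, pi), eccentricity = ecc)
  })
}

# Logical H x W matrix of pixels inside the ellipse of equivalent radius
# `size`, eccentricity e and orientation theta centred at (r0, c0).
# Semi-axes preserve area: a*b = size^2, b/a = sqrt(1 - e^2).
.ellipse_pixels <- function(H, W, r0, c0, size, theta, e) {
  a <- size / (1 - e^2)^0.25
  b <- size * (1 - e^2)^0.25
  rows <- matrix(seq_len(H) - 1 - r0, H, W)
  cols <- matrix(rep(seq_len(W) - 1 - c0, each = H), H, W)
  u <- rows * cos(theta) + cols * sin(theta)
  v <- -rows * sin(theta) + cols * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Render a synthetic three-channel well image with a ground-truth mask
#'
#' Emulates the staining scheme of a cancer/fibroblast co-culture assay:
#' channel 1 (CK8/18) marks cancer-cell bodies, channel 2 (vimentin) marks
#' fibroblast bodies, and channel 3 (Hoechst) marks every nucleus. The
#' label mask covers cancer objects only (background 0, labels consecutive
#' from 1), matching what an external segmenter of the cancer channel
#' would produce.
#'
#' @param scene a [scene_spec()]; may be empty.
#' @param image_size `(H, W)` in pixels.
#' @param illumination `NULL` for flat illumination, or a list
#'   `list(type = "linear"|"radial", strength = s)` giving a smooth
#'   multiplicative field of mean ~1 (strength = peak-to-mean deviation).
#' @param noise_sd additive Gaussian noise sd (intensities clipped at 0).
#' @param background background intensity level.
#' @param cell_intensity mean cell-body intensity in its population channel.
#' @param seed integer seed (noise and per-cell brightness jitter).
#' @return List with `image` (array `3 x H x W`, channels ck818, vimentin,
#'   hoechst) and `mask` (integer `H x W` matrix).
#' @export
render_well_image <- function(scene, image_size = c(195, 195),
                              illumination = NULL, noise_sd = 0.01,
                              background = 0.05, cell_intensity = 0.8,
                              seed = 1) {
  stopifnot(length(image_size) == 2, all(image_size >= 1))
  H <- as.integer(image_size[1]); W <- as.integer(image_size[2])
  if (nrow(scene)) {
    stopifnot(all(scene$centroid_row >= 0), all(scene$centroid_row <= H - 1),
              all(scene$centroid_col >= 0), all(scene$centroid_col <= W - 1))
  }
  ck <- matrix(0, H, W); vim <- matrix(0, H, W); hoe <- matrix(0, H, W)
  mask <- matrix(0L, H, W)

  withr::with_seed(seed, {
    next_label <- 1L
    for (i in seq_len(nrow(scene))) {
      s <- scene[i, ]
      body <- .ellipse_pixels(H, W, s$centroid_row, s$centroid_col,
                              s$size, s$orientation, s$eccentricity)
      bright <- cell_intensity * stats::runif(1, 0.85, 1.15)
      nuc <- .ellipse_pixels(H, W, s$centroid_row, s$centroid_col,
                             max(2, s$size / 2.5), 0, 0)
      if (s$population == "cancer") {
        ck[body] <- pmax(ck[body], bright)
        mask[body] <- next_label
        next_label <- next_label + 1L
      } else {
        vim[body] <- pmax(vim[body], bright)
      }
      hoe[nuc] <- pmax(hoe[nuc], bright)
    }
    # relabel so labels are consecutive from 1 even if a cell was painted over
    labs <- sort(unique(mask[mask > 0L]))
    if (length(labs)) mask[] <- match(mask, c(0L, labs)) - 1L

    illum <- .illumination_field(H, W, illumination)
    img <- array(0, dim = c(3L, H, W),
                 dimnames = list(c("ck818", "vimentin", "hoechst"), NULL, NULL))
    for (ch in 1:3) {
      base <- switch(ch, ck, vim, hoe) + background
      noisy <- base * illum +
        matrix(stats::rnorm(H * W, sd = noise_sd), H, W)
      img[ch, , ] <- pmax(noisy, 0)
    }
  })
  list(image = img, mask = mask)
}

.illumination_field <- function(H, W, illumination) {
  if (is.null(illumination)) return(matrix(1, H, W))
  stopifnot(is.list(illumination), !is.null(illumination$type))
  s <- if (is.null(illumination$strength)) 0.2 else illumination$strength
  f <- switch(
    illumination$type,
    linear = matrix(rep(seq(1 - s, 1 + s, length.out = W), each = H), H, W),
    radial = {
      rows <- matrix(seq_len(H) - (H + 1) / 2, H, W)
      cols <- matrix(rep(seq_len(W) - (W + 1) / 2, each = H), H, W)
      d2 <- (rows / H)^2 + (cols / W)^2
      1 + s - 2 * s * d2 / max(d2)
    },
    stop("unknown illumination type: ", illumination$type)
  )
  f / mean(f)
}
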