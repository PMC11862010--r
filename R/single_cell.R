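# Single-cell extraction from integer label masks. Pixel coordinates in
# this module are 0-based (row, col), row-major, matching the conventions
# of common image-analysis tooling; R's 1-based matrix indexing is an
# internal detail.

#' Region properties of a label mask
#'
#' Computes, for every distinct positive label, the centroid (mean of
#' member pixel coordinates), area, bounding box, perimeter, and the
#' eccentricity of the ellipse with matching second central moments (0 =
#' circle, values near 1 = line). A per-axis variance of 1/12 (the variance
#' of a unit pixel) is added to the moments so eccentricity stays strictly
#' below 1 even for 1-pixel-wide regions.
#'
#' Perimeter uses the crack-length convention: the number of pixel edges
#' between the region and its complement (a single pixel has perimeter 4).
#'
#' @param mask integer `H x W` matrix; 0 = background, each positive value
#'   one cell object.
#' @return Data frame with one row per label: `label`, `centroid_row`,
#'   `centroid_col` (0-based), `area`, `eccentricity`, `perimeter`, and the
#'   half-open bounding box `bbox_min_row`, `bbox_min_col`, `bbox_max_row`,
#'   `bbox_max_col`. Empty mask gives a zero-row frame.
#' @export
regions_from_mask <- function(mask) {
  stopifnot(is.matrix(mask))
  if (any(mask < 0)) stop("label mask must be nonnegative")
  H <- nrow(mask)
  idx <- which(mask > 0)
  empty <- data.frame(
    label = integer(0), centroid_row = numeric(0), centroid_col = numeric(0),
    area = integer(0), eccentricity = numeric(0), perimeter = numeric(0),
    bbox_min_row = integer(0), bbox_min_col = integer(0),
    bbox_max_row = integer(0), bbox_max_col = integer(0)
  )
  if (!length(idx)) return(empty)
  lab <- as.integer(mask[idx])
  r <- (idx - 1L) %% H          # 0-based row
  cc <- (idx - 1L) %/% H        # 0-based col
  f <- factor(lab)
  labels <- as.integer(levels(f))
  area <- as.integer(tabulate(f))
  cr <- as.numeric(tapply(r, f, mean))
  ccm <- as.numeric(tapply(cc, f, mean))

  # second central moments (per-pixel variance 1/12 added on each axis)
  mu20 <- as.numeric(tapply(r, f, stats::var)) * (area - 1) / area + 1 / 12
  mu02 <- as.numeric(tapply(cc, f, stats::var)) * (area - 1) / area + 1 / 12
  mu20[is.na(mu20)] <- 1 / 12
  mu02[is.na(mu02)] <- 1 / 12
  mu11 <- mapply(function(l) {
    sel <- lab == l
    if (sum(sel) < 2) return(0)
    mean((r[sel] - mean(r[sel])) * (cc[sel] - mean(cc[sel])))
  }, labels)
  half_tr <- (mu20 + mu02) / 2
  det_rt <- sqrt(pmax(0, ((mu20 - mu02) / 2)^2 + mu11^2))
  l1 <- half_tr + det_rt
  l2 <- half_tr - det_rt
  ecc <- ifelse(l1 > 0, sqrt(pmax(0, 1 - l2 / l1)), 0)

  perim <- vapply(labels, function(l) .crack_perimeter(mask == l), numeric(1))

  data.frame(
    label = labels, centroid_row = cr, centroid_col = ccm,
    area = area, eccentricity = ecc, perimeter = perim,
    bbox_min_row = as.integer(tapply(r, f, min)),
    bbox_min_col = as.integer(tapply(cc, f, min)),
    bbox_max_row = as.integer(tapply(r, f, max)) + 1L,
    bbox_max_col = as.integer(tapply(cc, f, max)) + 1L
  )
}

# pixel edges between TRUE pixels and FALSE/outside pixels
.crack_perimeter <- function(px) {
  H <- nrow(px); W <- ncol(px)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- px
  core <- pad[2:(H + 1), 2:(W + 1)]
  sum(core & !pad[1:H, 2:(W + 1)]) + sum(core & !pad[3:(H + 2), 2:(W + 1)]) +
    sum(core & !pad[2:(H + 1), 1:W]) + sum(core & !pad[2:(H + 1), 3:(W + 2)])
}

#' Extract fixed-size single-cell crops around mask centroids
#'
#' For every labelled cell, places a `box_size x box_size` box centred at
#' the floored centroid: rows `[r - floor(box/2), r - floor(box/2) + box)`
#' and likewise for columns (0-based, half-open). Cells whose box does not
#' fit inside the image are excluded and counted. In masked mode every
#' pixel whose mask label differs from the cell's label is zeroed in all
#' three channels, so the crop contains the target cell only; unmasked
#' crops keep neighbouring cells' pixels.
#'
#' @param image `3 x H x W` array.
#' @param mask integer `H x W` label mask of the same spatial shape.
#' @param box_size crop side in pixels (conventionally 50 unmasked, 90
#'   masked).
#' @param masked logical; zero out pixels outside the target label.
#' @return List of crops, each a `box_size x box_size x 3` array with
#'   attributes `label`, `origin` (0-based top-left `(row, col)`) and
#'   `masked`; the list carries attributes `n_excluded` and
#'   `excluded_labels` for edge cells that did not yield a complete box.
#' @export
crop_cells <- function(image, mask, box_size = 50, masked = FALSE) {
  stopifnot(length(dim(image)) == 3, is.matrix(mask),
            .is_count(box_size), box_size >= 1)
  H <- dim(image)[2]; W <- dim(image)[3]
  if (nrow(mask) != H || ncol(mask) != W)
    stop("image and mask spatial shapes differ")
  regions <- regions_from_mask(mask)
  half <- box_size %/% 2
  crops <- list()
  excluded <- integer(0)
  for (i in seq_len(nrow(regions))) {
    r0 <- floor(regions$centroid_row[i]) - half
    c0 <- floor(regions$centroid_col[i]) - half
    if (r0 < 0 || c0 < 0 || r0 + box_size > H || c0 + box_size > W) {
      excluded <- c(excluded, regions$label[i])
      next
    }
    rows <- (r0 + 1):(r0 + box_size)
    cols <- (c0 + 1):(c0 + box_size)
    blk <- image[, rows, cols, drop = FALSE]
    crop <- aperm(array(blk, dim = c(3, box_size, box_size)), c(2, 3, 1))
    if (masked) {
      keep <- mask[rows, cols] == regions$label[i]
      crop <- crop * as.numeric(keep)   # recycles over the 3 channels
    }
    attr(crop, "label") <- regions$label[i]
    attr(crop, "origin") <- c(r0, c0)
    attr(crop, "masked") <- masked
    crops[[length(crops) + 1L]] <- crop
  }
  attr(crops, "n_excluded") <- length(excluded)
  attr(crops, "excluded_labels") <- excluded
  crops
}

#' Handcrafted morphology and intensity features for one cell
#'
#' A compact, deterministic feature set standing in for a full
#' image-cytometry feature battery: shape descriptors of the labelled
#' region (area, perimeter, eccentricity, solidity, extent) plus
#' per-channel intensity statistics over the region's pixels (mean, sd,
#' median, 10th/90th percentile, integrated intensity), in a fixed,
#' documented order.
#'
#' Conventions: a 1-pixel region has perimeter 4 (crack length), sd 0,
#' solidity 1; solidity uses the pixel-centre convex hull rasterised back
#' to the grid, and degenerate (collinear) regions get solidity 1.
#'
#' @param image `3 x H x W` array (channels ck818, vimentin, hoechst).
#' @param region one row of [regions_from_mask()] output.
#' @param mask the label mask the region came from.
#' @return Named numeric vector of length 23: `area`, `perimeter`,
#'   `eccentricity`, `solidity`, `extent`, then
#'   `<channel>_{mean,sd,median,p10,p90,integrated}` for each channel.
#' @export
handcrafted_features <- function(image, region, mask) {
  stopifnot(length(dim(image)) == 3, is.matrix(mask))
  lab <- region$label
  sel <- which(mask == lab)
  if (!length(sel)) stop("region label ", lab, " not present in mask")
  H <- nrow(mask)
  r <- (sel - 1L) %% H
  cc <- (sel - 1L) %/% H

  bbox_area <- (region$bbox_max_row - region$bbox_min_row) *
    (region$bbox_max_col - region$bbox_min_col)
  shape <- c(
    area = as.numeric(region$area),
    perimeter = as.numeric(region$perimeter),
    eccentricity = region$eccentricity,
    solidity = .solidity(r, cc),
    extent = region$area / bbox_area
  )
  ch_names <- dimnames(image)[[1]]
  if (is.null(ch_names)) ch_names <- c("ck818", "vimentin", "hoechst")
  ints <- lapply(1:3, function(ch) {
    v <- image[ch, , ][sel]
    c(mean = mean(v),
      sd = if (length(v) > 1) stats::sd(v) else 0,
      median = stats::median(v),
      p10 = stats::quantile(v, 0.1, names = FALSE, type = 7),
      p90 = stats::quantile(v, 0.9, names = FALSE, type = 7),
      integrated = sum(v))
  })
  names(ints) <- ch_names
  out <- c(shape, unlist(ints))
  names(out) <- sub("\\.", "_", names(out))
  out
}

# area / rasterised convex-hull area, using pixel centres
.solidity <- function(r, cc) {
  n <- length(r)
  if (n <= 2) return(1)
  hull <- grDevices::chull(cc, r)
  hx <- cc[hull]; hy <- r[hull]
  # shoelace area; collinear pixel sets have no interior
  a2 <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy))
  if (a2 < 1e-9) return(1)
  gr <- seq(min(r), max(r))
  gc <- seq(min(cc), max(cc))
  pts_r <- rep(gr, times = length(gc))
  pts_c <- rep(gc, each = length(gr))
  inside <- pracma::inpolygon(pts_c, pts_r, hx, hy, boundary = TRUE)
  convex_area <- sum(inside)
  min(1, n / convex_area)
}

#' Cell feature table for one well image
#'
#' Convenience wrapper: runs [regions_from_mask()] and
#' [handcrafted_features()] over every cell of a well and returns rows
#' keyed by plate and well, ready for [aggregate_well()].
#'
#' @param image `3 x H x W` array.
#' @param mask label mask.
#' @param plate_id,well_id keys attached to every row.
#' @return Data frame: `plate_id`, `well_id`, `cell_id` (the mask label),
#'   and the feature columns of [handcrafted_features()].
#' @export
well_cell_features <- function(image, mask, plate_id, well_id) {
  regions <- regions_from_mask(mask)
  if (!nrow(regions)) {
    return(data.frame(plate_id = character(0), well_id = character(0),
                      cell_id = integer(0)))
  }
  feats <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    handcrafted_features(image, regions[i, ], mask)
  }))
  cbind(data.frame(plate_id = plate_id, well_id = well_id,
                   cell_id = regions$label, stringsAsFactors = FALSE),
        as.data.frame(feats))
}

#' Embed single-cell crops with a pluggable feature extractor
#'
#' Applies an opaque extractor (any function mapping one crop to a
#' fixed-length numeric vector — e.g. the global-average-pooled embedding
#' layer of a pre-trained CNN) to each crop. The pipeline only relies on
#' this contract; [make_mock_extractor()] ships as a deterministic
#' reference extractor for testing.
#'
#' @param crops list of `box x box x 3` crops (all the same size).
#' @param extractor function: crop -> numeric vector of fixed length.
#' @return Numeric matrix, one row per crop.
#' @export
embed_features <- function(crops, extractor) {
  stopifnot(is.list(crops), is.function(extractor))
  if (!length(crops)) return(matrix(numeric(0), 0, 0))
  rows <- lapply(crops, extractor)
  lens <- lengths(rows)
  if (length(unique(lens)) != 1)
    stop("extractor returned inconsistent output lengths: ",
         paste(unique(lens), collapse = ", "))
  do.call(rbind, rows)
}

#' Deterministic mock embedding extractor
#'
#' Builds a seeded random projection of pooled per-channel statistics
#' (mean, sd, quartiles per channel) through a tanh nonlinearity. It is a
#' stand-in for a real CNN embedding with the same contract: deterministic,
#' fixed output length, sensitive to crop content.
#'
#' @param n_features embedding dimension.
#' @param seed integer seed fixing the projection.
#' @return A function: crop (`box x box x 3`) -> numeric vector of length
#'   `n_features`.
#' @export
make_mock_extractor <- function(n_features = 64, seed = 1) {
  stopifnot(.is_count(n_features), n_features >= 1)
  W <- withr::with_seed(seed,
    matrix(stats::rnorm(15 * n_features), 15, n_features))
  function(crop) {
    stopifnot(length(dim(crop)) == 3, dim(crop)[3] == 3)
    pooled <- unlist(lapply(1:3, function(ch) {
      v <- as.numeric(crop[, , ch])
      c(mean(v), stats::sd(v), stats::quantile(v, c(0.25, 0.5, 0.75),
                                               names = FALSE, type = 7))
    }))
    as.numeric(tanh(pooled %*% W))
  }
}
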