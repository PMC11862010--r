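make_test_image <- function(mask, seed = 1) {
  withr::with_seed(seed, {
    img <- array(runif(3 * nrow(mask) * ncol(mask)), c(3, nrow(mask), ncol(mask)))
  })
  img
}

test_that("region properties match symmetry, oracles and shape intuition", {
  mask <- matrix(0L, 40, 40)
  mask[11:13, 21:23] <- 1L           # 0-based rows 10..12, cols 20..22
  r <- regions_from_mask(mask)
  expect_equal(r$centroid_row, 11)
  expect_equal(r$centroid_col, 21)
  expect_equal(r$area, 9L)
  expect_equal(r$bbox_min_row, 10L)
  expect_equal(r$bbox_max_row, 13L)  # half-open
  expect_equal(r$eccentricity, 0)

  # disk vs thin bar eccentricity (0 = round, near 1 = line)
  sc <- scene_spec("cancer", 30, 30, 10)
  disk <- render_well_image(sc, c(61, 61), seed = 1)$mask
  expect_lt(regions_from_mask(disk)$eccentricity, 0.1)
  bar <- matrix(0L, 30, 30); bar[15, 5:24] <- 1L
  ecc <- regions_from_mask(bar)$eccentricity
  expect_gt(ecc, 0.99)
  expect_lt(ecc, 1)

  # area equals a brute-force pixel count for random blobs
  withr::with_seed(8, {
    m <- matrix(0L, 50, 50)
    for (l in 1:5) {
      i <- sample(10:40, 1); j <- sample(10:40, 1)
      m[i:(i + sample(2:8, 1)), j:(j + sample(2:8, 1))] <- l
    }
  })
  r <- regions_from_mask(m)
  for (k in seq_len(nrow(r)))
    expect_equal(r$area[k], sum(m == r$label[k]))
  expect_equal(nrow(regions_from_mask(matrix(0L, 5, 5))), 0)
})

test_that("region moments agree with an independent image-analysis library", {
  sc <- scene_spec(c("cancer", "cancer"), c(25, 60), c(25, 60), c(8, 6),
                   orientation = c(0.7, 0), eccentricity = c(0.8, 0.1))
  mask <- render_well_image(sc, c(90, 90), seed = 2)$mask
  r <- regions_from_mask(mask)
  # EBImage works on x/y (transposed) images; centroids swap accordingly
  mom <- EBImage::computeFeatures.moment(t(mask))
  expect_equal(r$centroid_col, mom[, "m.cx"] - 1, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(r$centroid_row, mom[, "m.cy"] - 1, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(r$eccentricity, mom[, "m.eccentricity"], tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("crops follow the centroid/box convention and exclude edge cells", {
  mask <- matrix(0L, 100, 100)
  mask[44:48, 44:48] <- 1L          # centroid (45, 45) 0-based
  img <- make_test_image(mask)
  cr <- crop_cells(img, mask, box_size = 50)
  expect_length(cr, 1)
  expect_equal(attr(cr[[1]], "origin"), c(20, 20))   # rows/cols 20..69
  expect_equal(dim(cr[[1]]), c(50, 50, 3))
  expect_equal(cr[[1]][1, 1, 1], img[1, 21, 21])     # 0-based 20 -> R 21
  expect_equal(attr(cr, "n_excluded"), 0)

  # a cell at (10, 10) cannot yield a complete 50 x 50 box
  mask2 <- matrix(0L, 100, 100)
  mask2[10:12, 10:12] <- 1L
  mask2[50:54, 50:54] <- 2L
  cr2 <- crop_cells(img, mask2, box_size = 50)
  expect_length(cr2, 1)
  expect_equal(attr(cr2, "n_excluded"), 1)
  expect_equal(attr(cr2, "excluded_labels"), 1L)
  # conservation: crops + exclusions = labels in mask
  expect_equal(length(cr2) + attr(cr2, "n_excluded"),
               length(setdiff(unique(as.vector(mask2)), 0L)))
})

test_that("masked crops zero every pixel outside the target label", {
  mask <- matrix(0L, 80, 80)
  mask[30:40, 30:40] <- 1L
  mask[30:40, 41:50] <- 2L          # adjacent neighbour
  img <- make_test_image(mask)
  img <- img + 0.5                  # keep everything strictly positive
  cr <- crop_cells(img, mask, box_size = 40, masked = TRUE)
  for (crop in cr) {
    o <- attr(crop, "origin")
    blk <- mask[(o[1] + 1):(o[1] + 40), (o[2] + 1):(o[2] + 40)]
    outside <- blk != attr(crop, "label")
    for (ch in 1:3) {
      expect_true(all(crop[, , ch][outside] == 0))
      expect_true(all(crop[, , ch][!outside] > 0))
    }
    # nonzero fraction bounded by region area / box area
    area <- sum(mask == attr(crop, "label"))
    expect_lte(sum(crop[, , 1] != 0), area)
  }
  # unmasked crops keep the neighbour's pixels
  cru <- crop_cells(img, mask, box_size = 40, masked = FALSE)
  expect_true(all(cru[[1]] > 0))
})

test_that("handcrafted features match their oracles and conventions", {
  sc <- scene_spec("cancer", 40, 40, 9)
  rw <- render_well_image(sc, c(81, 81), noise_sd = 0, seed = 3)
  reg <- regions_from_mask(rw$mask)
  f <- handcrafted_features(rw$image, reg[1, ], rw$mask)
  expect_named(f, c("area", "perimeter", "eccentricity", "solidity", "extent",
                    paste0(rep(c("ck818", "vimentin", "hoechst"), each = 6),
                           "_", rep(c("mean", "sd", "median", "p10", "p90",
                                      "integrated"), 3))))
  expect_equal(unname(f["area"]), reg$area[1])
  # noiseless uniform disk: sd 0, mean equals the constant intensity
  vals <- rw$image[1, , ][rw$mask == 1]
  expect_equal(unname(f["ck818_sd"]), 0, tolerance = 1e-12)
  expect_equal(unname(f["ck818_mean"]), vals[1])
  # integrated intensity equals a brute-force sum over labelled pixels
  expect_equal(unname(f["ck818_integrated"]), sum(vals))
  expect_gt(f["solidity"], 0.9)   # disks are convex
  expect_lte(f["solidity"], 1)

  # degenerate 1-pixel region: documented conventions
  m1 <- matrix(0L, 20, 20); m1[5, 5] <- 1L
  img <- make_test_image(m1)
  f1 <- handcrafted_features(img, regions_from_mask(m1)[1, ], m1)
  expect_equal(unname(f1[c("area", "perimeter", "solidity")]), c(1, 4, 1))
  expect_equal(unname(f1["ck818_sd"]), 0)
})

test_that("handcrafted features are invariant under image translation", {
  sc <- scene_spec(c("cancer", "cancer"), c(30, 60), c(30, 60), c(8, 7),
                   eccentricity = c(0.5, 0.2), orientation = c(0.4, 1.2))
  rw <- render_well_image(sc, c(101, 101), noise_sd = 0, seed = 4)
  sc2 <- sc; sc2$centroid_row <- sc2$centroid_row + 7
  sc2$centroid_col <- sc2$centroid_col + 4
  rw2 <- render_well_image(sc2, c(101, 101), noise_sd = 0, seed = 4)
  r1 <- regions_from_mask(rw$mask); r2 <- regions_from_mask(rw2$mask)
  for (k in 1:2) {
    f1 <- handcrafted_features(rw$image, r1[k, ], rw$mask)
    f2 <- handcrafted_features(rw2$image, r2[k, ], rw2$mask)
    expect_equal(f1, f2, tolerance = 1e-8)
  }
})

test_that("embedding respects the extractor contract", {
  mask <- matrix(0L, 120, 120)
  mask[20:30, 20:30] <- 1L; mask[60:75, 60:70] <- 2L; mask[90:95, 40:55] <- 3L
  img <- make_test_image(mask)
  crops <- crop_cells(img, mask, box_size = 30)
  ext <- make_mock_extractor(n_features = 16, seed = 5)
  M <- embed_features(crops, ext)
  expect_equal(dim(M), c(3, 16))
  # identical crops give identical rows; different content differs
  expect_identical(embed_features(list(crops[[1]], crops[[1]]), ext)[1, ],
                   embed_features(list(crops[[1]], crops[[1]]), ext)[2, ])
  zero <- array(0, c(30, 30, 3))
  expect_false(isTRUE(all.equal(ext(zero), ext(crops[[2]]))))
  # deterministic across extractor instances with the same seed
  expect_identical(ext(crops[[1]]),
                   make_mock_extractor(n_features = 16, seed = 5)(crops[[1]]))
  bad <- function(crop) numeric(sample(2:3, 1))
  withr::with_seed(1,
    expect_error(embed_features(crops, bad), "inconsistent"))
})
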