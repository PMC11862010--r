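# File IO: layouts / feature tables / profiles as CSV (default) or
# Parquet (via the arrow package, by file extension), images and masks as
# TIFF. Unknown columns are tolerated on read with a warning; missing
# required columns are an error.

.is_parquet <- function(path) grepl("\\.parquet$", path, ignore.case = TRUE)

.read_table <- function(path) {
  if (.is_parquet(path)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("reading parquet requires the 'arrow' package")
    as.data.frame(arrow::read_parquet(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}

.write_table <- function(df, path) {
  if (.is_parquet(path)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("writing parquet requires the 'arrow' package")
    arrow::write_parquet(as.data.frame(df), path)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

.check_schema <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " is missing required columns: ", paste(miss, collapse = ", "))
  extra <- setdiff(names(df), required)
  extra <- extra[!grepl("^f_", extra) & !(extra %in% .annotation_cols)]
  if (length(extra))
    warning(what, " has unknown columns (kept): ",
            paste(extra, collapse = ", "))
  invisible(df)
}

#' Read / write a plate layout table
#'
#' @param path CSV or `.parquet` file.
#' @return `read_layout`: a validated `plate_layout` data frame.
#' @export
read_layout <- function(path) {
  df <- .read_table(path)
  .check_schema(df, c("plate_id", "well_id", "role", "compound_id",
                      "concentration_index", "moa_label"), "layout")
  validate_plate_layout(df)
  class(df) <- c("plate_layout", "data.frame")
  df
}

#' @rdname read_layout
#' @param layout a `plate_layout` data frame.
#' @export
write_layout <- function(layout, path) {
  validate_plate_layout(layout)
  .write_table(as.data.frame(layout), path)
}

#' Read / write cell-level feature tables and well profiles
#'
#' Format is chosen by extension (`.parquet` via arrow, anything else
#' CSV). `read_profiles` restores the `well_profiles` class and feature
#' column attribute.
#'
#' @param path file path.
#' @return The table read, or (for writers) the path invisibly.
#' @export
read_cell_features <- function(path) {
  df <- .read_table(path)
  .check_schema(df, c("plate_id", "well_id", "cell_id"), "cell feature table")
  df
}

#' @rdname read_cell_features
#' @param cells cell-level feature table.
#' @export
write_cell_features <- function(cells, path) .write_table(cells, path)

#' @rdname read_cell_features
#' @export
read_profiles <- function(path) {
  df <- .read_table(path)
  .check_schema(df, c("plate_id", "well_id", "cell_count"), "profile table")
  attr(df, "feature_cols") <- .feature_cols(df)
  class(df) <- c("well_profiles", "data.frame")
  df
}

#' @rdname read_cell_features
#' @param profiles a `well_profiles` data frame.
#' @export
write_profiles <- function(profiles, path) .write_table(as.data.frame(profiles), path)

#' Read / write multi-channel images and label masks as TIFF
#'
#' Images are stored as multi-page float TIFFs (one page per channel,
#' intensities as-is); masks as 16-bit integer TIFFs (labels up to 65535).
#'
#' @param path TIFF file path.
#' @return `read_image_tiff`: a `3 x H x W` array; `read_mask_tiff`: an
#'   integer matrix.
#' @export
read_image_tiff <- function(path, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  out <- array(0, dim = c(length(pages), H, W))
  for (i in seq_along(pages)) out[i, , ] <- pages[[i]] * scale
  if (length(pages) == 3)
    dimnames(out) <- list(c("ck818", "vimentin", "hoechst"), NULL, NULL)
  out
}

#' @rdname read_image_tiff
#' @param image `3 x H x W` array of nonnegative intensities.
#' @param scale intensity divisor applied before writing (TIFF float pages
#'   hold `[0, 1]`); the default is the smallest power of two that
#'   contains the data. `read_image_tiff` multiplies it back. Values
#'   round-trip to 32-bit float precision.
#' @export
write_image_tiff <- function(image, path, scale = NULL) {
  stopifnot(length(dim(image)) == 3, all(image >= 0))
  if (is.null(scale)) scale <- 2^max(0, ceiling(log2(max(image, 1e-12))))
  pages <- lapply(seq_len(dim(image)[1]),
                  function(ch) matrix(image[ch, , ] / scale, dim(image)[2]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  invisible(scale)
}

#' @rdname read_image_tiff
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_image_tiff
#' @param mask integer label matrix (values < 65536).
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(is.matrix(mask), all(mask >= 0), all(mask < 65536))
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16, reduce = FALSE)
  invisible(path)
}
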